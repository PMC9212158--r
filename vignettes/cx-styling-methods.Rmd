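---
title: "Styling, laying out and exporting CX networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Styling, laying out and exporting CX networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxviz)
```

`cxviz` implements the computational core of data-dependent network
visualization over the Cytoscape Exchange (CX) format: a lossless document
model, attribute-to-visual mappings, attribute exploration, graph layouts
and rendering. This vignette explains the procedures, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic networks used by the tests do and do not establish about real
data.

## The CX document model

A CX document is a JSON array of single-key *aspect fragments*. The core
aspects (`nodes`, `edges`, the three attribute aspects, `cartesianLayout`,
`cyVisualProperties`) are lifted into typed tibbles; everything else is
carried opaquely, element for element. Two properties are contractual:

* **Lossless round trips.** `parse_cx()` keeps the scalar-versus-array and
  empty-object-versus-empty-array distinctions of the source JSON, and the
  hand-written emitter inverts them exactly, so custom aspects survive
  `parse → serialize → parse` untouched.
* **Deterministic output.** Serialization of a given model is byte-stable:
  aspect order follows the source document (canonical order for generated
  models), attribute datatypes default to `string`, and numbers are printed
  as the shortest decimal that the JSON parser reads back to the identical
  double (verified against the parser itself, since correctly-printed
  16-digit decimals can round differently across number parsers). Integral
  values print without a decimal point, which keeps element ids and the
  2^48 − 1 `numberVerification` probe exact.

Validation returns violations as data rather than raising: severity
`error` (dangling edge endpoints, duplicate ids, orphaned attributes or
layout points) blocks serialization and rendering; `warning` (duplicate
attribute with last-wins resolution, unsorted mapping thresholds, a mapped
column absent from the data) does not. This mirrors how permissive readers
in the ecosystem treat imperfect files: load what is loadable, report the
rest.

## Attribute-to-visual mappings

A mapping binds one data column to one visual property; one column may
drive any number of properties, each through its own mapping, and one
mapping slot exists per (element class, property) — installing a second
replaces the first with a warning.

**Discrete** mappings are exact-match lookups after coercing the value to
the column datatype; a missing entry yields "absent", and the caller falls
back along the precedence chain.

**Continuous** mappings are threshold-anchored piecewise-linear functions,
restricted to numeric columns (string values have no order to interpolate
over). Each anchor point may carry three values — `lesser`, `equal`,
`greater` — used respectively below the first threshold, exactly at the
threshold, and above the last threshold; strictly between two thresholds
the result interpolates from the left point's `greater` to the right
point's `lesser` value. This three-slot semantics is the desktop-tool
convention and is what the CX definition strings encode, so adopting it is
required for cross-tool consistency. Points carrying no value for the
property are skipped as gaps. Colors interpolate per RGB channel with
round-half-up and uppercase `#RRGGBB` output; the midpoint of white to red
is therefore exactly `#FF8080`. Duplicate thresholds — the community's
workaround for step-like color changes — are flagged as a validation
warning rather than promoted to a distinct mapping type, since their
at-threshold behavior is ambiguous by construction.

**Pass-through** mappings forward the attribute value, coerced to the
property's value kind. Targeting a numeric property through pass-through
is supported but warned about, as a continuous mapping expresses the same
intent with control over the scale.

**Resolution** is total by design: bypass (per-element override) beats the
mapping result, which beats the class default, which beats a built-in
default table covering every renderable property (node fill `#FFFFFF`,
size 35, shape `ELLIPSE`, edge width 2, …). Totality is what lets the
renderer consume resolved styles without conditionals.

The **definition-string dialect** (`COL=…,T=…` with indexed
`K/V/L/E/G/OV` tokens and `\,` escapes) follows the convention used inside
the `cyVisualProperties` aspect. Serialization emits indices contiguous
from zero with continuous points sorted by threshold, making
parse/serialize a bijection on well-formed definitions — the property the
tests enforce on a generated corpus.

## Attribute exploration

`summarize_attribute()` reports coverage (fraction of the class carrying a
value), distinct-value counts and, for numeric datatypes, the range.
`compute_histogram()` bins non-missing values into equal-width bins over
`[min, max]`, half-open `[a, b)` with a closed last bin so the maximum is
counted; a single distinct value would give a zero-width range, so the bin
is widened to unit width around it. Highlight rules are single predicates
(`==`, `!=`, order comparisons, inclusive `between`, substring
`contains`); missing values never match, and numeric operators on
non-numeric columns are usage errors. Rule conjunction is deliberately not
offered — compose selections with set operations in R instead.

## Layout algorithms

All layouts use screen coordinates (y downward) and return a tibble of
per-node positions; `store_layout()` writes them to the `cartesianLayout`
aspect (preserving any stored z), and `apply_preset()` reads them back, so
the pair is an identity on coordinates.

* **random**: i.i.d. uniform over the viewport (default 600×600), seeded.
* **grid**: id-sorted, `ceiling(sqrt(n))` columns — a square-ish default
  since nothing in the format prescribes a column count; pitch 40 units.
* **circular**: equal angular steps clockwise from the top (−90°).
* **concentric**: nodes ranked by degree descending (ties by id) fill
  rings of radius `k · ring_gap`; ring k holds up to `floor(2πk)` nodes so
  circumferential spacing tracks the radial gap. Degree ranking matches
  the common rendering-library default and puts hubs innermost.
* **breadth-first**: undirected traversal; the default root per connected
  component is the max-degree node (min id on ties) — a hub-out view of the
  topology; depth sets y, siblings spread in x, components get disjoint
  bounding boxes.
* **cose** (spring embedder): spring force `k_s (d − L)` along edges toward
  the ideal length `L` (default 50), pairwise repulsion `k_r / d²`
  (`k_r = 100`), weak centroid gravity (`g = 0.001`), displacement capped
  by a linearly cooling temperature starting at `L/10`. A step that would
  increase the total energy (spring + `k_r/d` repulsion potential +
  quadratic gravity) is rejected and the step scale halved, which makes
  the energy trace monotonically non-increasing and the result
  deterministic for a fixed seed. With these constants the analytic
  two-node equilibrium sits at ≈ 1.003 L, well inside the 5% band the
  tests assert; only equilibrium properties, not exact coordinates, are
  contractual, and all constants are exposed as arguments.

## Rendering and export

`resolve_styles()` materializes the full precedence chain for every
element; `render_svg()` draws background, then edges, then nodes in id
order (nodes on top), then labels, with deterministic number formatting so
identical inputs give byte-identical SVG. The seven node shapes are drawn
natively; an unknown shape falls back to an ellipse with a warning rather
than failing an export. Bounds are the node extents (position ± half node
size, where an explicit `NODE_WIDTH`/`NODE_HEIGHT` overrides the square
`NODE_SIZE`) plus a 10-unit margin; a viewport clip intersects, and a
`max_dimensions` cap rescales uniformly.

Rasterization replays the package's own SVG subset onto R's cairo
devices, which keeps pixel dimensions exact: `round(svg size × scale)`.
PNG honors a transparent background with a real alpha channel; JPEG
cannot, so transparency requests are composited onto white with a warning.
Label glyph rendering depends on the device's font stack and is therefore
not part of the byte-determinism contract (the SVG text is; the raster
geometry is).

## The synthetic network generator

`generate_fixture()` emulates the structure of the public breast-cancer
protein–protein interaction demonstration network: a simple undirected
graph, a boolean bait flag and a string bait attribute on
`floor(coverage · n)` nodes (default coverage 0.25), and an edge
differential-interaction score uniform over `[-1, 1]` — the range that
attribute spans in the demonstration data. Defaults of 50 nodes and 100
edges give the sparse, hub-containing topology typical of curated
interactomes at desk scale. Optionally the fixture ships a preset layout,
a style exercising all three mapping kinds, and a small custom aspect so
opaque-aspect preservation is always on the tested path.

What the generator does *not* emulate: the degree distribution of real
interactomes (edges are sampled uniformly over node pairs, not
preferentially attached), multi-valued and list-typed attributes,
sub-network/view-specific styles, and documents produced by other writers
(different key orders, string-encoded numerics, nonstandard aspects with
internal cross-references). Passing tests on fixtures therefore establish
the algebraic contracts — round-trip fidelity, mapping semantics, layout
geometry, render determinism — not robustness to every CX dialect in the
wild; the permissive validator and raw-value retention are the mitigations
for the latter.

## Problem sizes and reproducibility

The test suite and the acceptance script run at deliberately desk-scale
sizes — fixtures up to 200 nodes, 100 round-trip documents, 1000
mapping-oracle pairs, a few hundred spring-embedder iterations — chosen so
the whole suite re-runs in a couple of minutes on one core while still
exercising every contract; all randomness flows from explicit integer
seeds. The continuous-mapping evaluator is checked against an independent
dense-grid piecewise-linear oracle (`stats::approx` per channel) rather
than against itself, and graph-theoretic quantities (degree sums, BFS
depths) are cross-checked against `igraph` where available.

## Known limitations

CX2 (the successor format) is out of scope, as are streaming parses of
multi-gigabyte documents, sub-network and view-specific mappings, style
templates imported from other networks, compound-node handling in the
spring embedder, edge bends and arrowheads, and any interactive editing.
The NDEx client covers fetch, create and update over the v2 REST API
behind a mockable transport; it deliberately does not wrap the platform's
search or permission endpoints.
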