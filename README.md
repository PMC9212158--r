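# cxviz

Data-dependent styling, layout and export of biological networks stored in
the Cytoscape Exchange (CX) format.

Biological networks — protein–protein interactomes, pathway models,
co-expression graphs — carry far more information than their topology: nodes
and edges hold attributes (bait flags, interaction scores, annotations) that
only become interpretable through a suitable visualization. The established
way to encode such visualizations is the *attribute-to-visual mapping*: a
rule translating a data attribute into a visual property such as node fill
color, node shape or edge width. CX stores the network topology, the
attributes and these mappings together as an ordered list of JSON "aspects",
so the same file renders identically across the tools that speak the format.

`cxviz` is an R toolkit and command-line tool for working with that model
headlessly: it reads and writes CX losslessly (custom aspects included),
applies and validates the three mapping kinds, summarizes attribute
distributions, computes graph layouts, and exports styled networks as CX,
SVG, PNG or JPEG. An optional thin client moves networks to and from the
NDEx exchange platform.

It is written tidyverse-style: models are lists of tibbles, user-facing
functions take the data frame first and return tibbles, results have
`tidy()`, `glance()` and `autoplot()` methods.

## The model in brief

**Mappings.** For a data column *a* and visual property *p*:

* *discrete*: an explicit lookup table `value(a) → value(p)`; values without
  an entry fall through to defaults.
* *continuous* (numeric columns only): anchor points at thresholds
  `t_1 < t_2 < … < t_k`, each carrying visual values for *below* (`lesser`),
  *at* (`equal`) and *above* (`greater`) the threshold. For
  `t_i < v < t_(i+1)` the result is the affine interpolation between point
  *i*'s `greater` and point *i+1*'s `lesser` value — componentwise for
  numbers, per RGB channel (rounded half up) for `#RRGGBB` colors. Outside
  the anchored range the first/last values clamp.
* *pass-through*: the attribute value itself becomes the visual value
  (typically node labels).

**Resolution precedence** per element and property:
`bypass > mapping > class default > built-in default`, so every renderable
property always resolves to exactly one value.

**Layouts.** Seven algorithms: random (uniform over a viewport), grid
(id-sorted, `⌈√n⌉` columns), circular, concentric (degree-ranked, densest at
the center), breadth-first (depth-stacked), a force-directed spring embedder
(springs toward an ideal edge length, inverse-square repulsion, weak
centroid gravity, monotonically decreasing energy), and restoration of the
preset layout stored in the file. Coordinates persist in the
`cartesianLayout` aspect; y grows downward (screen convention).

## Worked example

```r
library(cxviz)

# a seeded protein-interaction-style network: boolean bait flags on a
# quarter of the nodes, edge scores uniform in [-1, 1], one mapping of
# each kind already attached
net <- generate_fixture(n_nodes = 50, n_edges = 100, seed = 7)
net
#> <cx_network> 50 nodes, 100 edges, 125 attribute values, layout: yes, 3 mapping(s), 1 opaque aspect(s)

summarize_attribute(net, "edge", "diff_score")
#> # A tibble: 1 × 8
#>   owner_class name       datatype coverage n_values n_distinct    min   max
#>   <chr>       <chr>      <chr>       <dbl>    <int>      <int>  <dbl> <dbl>
#> 1 edge        diff_score double          1      100        100 -0.967 0.935
```

Coverage 1 means every edge carries a score; the range stays inside the
declared `[-1, 1]`. The score drives a blue–white–red edge gradient through
a continuous mapping; evaluating it at the midpoint of its range:

```r
m <- net$style$mappings$edge$EDGE_STROKE_UNSELECTED_PAINT
apply_continuous(m, c(-1, -0.5, 0, 1))
#> [1] "#0000FF" "#8080FF" "#FFFFFF" "#FF0000"

interpolate_color("#FFFFFF", "#FF0000", 0.5)
#> [1] "#FF8080"
```

Lay the network out with the spring embedder, store the coordinates and
export:

```r
net <- store_layout(net, layout_cose(net, ideal_edge_length = 50, seed = 7))
write_cx(net, "net.cx")
render_network(net, "net.png", options = render_options(scale = 2))
```

The same pipeline from a shell:

```sh
inst/cli/cxviz fixture --nodes 50 --edges 100 --seed 7 -o net.cx
inst/cli/cxviz layout net.cx --algorithm cose -o laid.cx
inst/cli/cxviz render laid.cx --format png --scale 2 -o net.png
inst/cli/cxviz validate laid.cx
#> 0 errors, 0 warnings
```

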