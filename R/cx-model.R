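#' @import tibble
#' @importFrom dplyr %>% filter mutate select arrange group_by summarise ungroup
#'   bind_rows distinct left_join n row_number slice desc across all_of
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom purrr map map_chr map_dbl map_lgl map2 keep discard compact
NULL

empty_nodes <- function() {
  tibble(id = double(), name = character(), represents = character())
}

empty_edges <- function() {
  tibble(id = double(), source = double(), target = double(),
         interaction = character())
}

empty_attributes <- function() {
  tibble(owner_class = character(), owner = double(), name = character(),
         value = list(), datatype = character())
}

empty_layout <- function() {
  tibble(node = double(), x = double(), y = double(), z = double())
}

#' Construct a network model
#'
#' A `cx_network` is the typed view of a CX document's core aspects: node and
#' edge tables, attributes for nodes, edges and the network itself, an
#' optional cartesian layout, a visual style, and any custom aspects carried
#' through untouched. All cross-references between tables use the CX element
#' id.
#'
#' @param nodes Tibble with columns `id`, `name`, `represents`.
#' @param edges Tibble with columns `id`, `source`, `target`, `interaction`;
#'   `source`/`target` reference node ids.
#' @param attributes Tibble with columns `owner_class` (`"node"`, `"edge"` or
#'   `"network"`), `owner` (element id, `NA` for network attributes), `name`,
#'   `value` (list column) and `datatype` (CX datatype string).
#' @param layout Tibble with columns `node`, `x`, `y`, `z` (canvas units,
#'   y growing downward).
#' @param style A [cx_style()] object.
#' @param opaque List of custom aspect fragments, each
#'   `list(name =, elements =)`, preserved verbatim.
#' @param aspect_order Character vector of aspect names recording the
#'   fragment order of the source document, preserved on serialization.
#'
#' @return A `cx_network` object (a list of tibbles).
#' @export
#' @examples
#' net <- cx_network(
#'   nodes = tibble::tibble(id = c(0, 1), name = c("BRCA1", "TP53"),
#'                          represents = NA_character_),
#'   edges = tibble::tibble(id = 0, source = 0, target = 1,
#'                          interaction = "interacts-with")
#' )
#' validate_network(net)
cx_network <- function(nodes = empty_nodes(), edges = empty_edges(),
                       attributes = empty_attributes(), layout = empty_layout(),
                       style = cx_style(), opaque = list(),
                       aspect_order = character()) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  for (col in c("name", "represents")) {
    if (!col %in% names(nodes)) nodes[[col]] <- rep(NA_character_, nrow(nodes))
  }
  if (!"interaction" %in% names(edges)) {
    edges$interaction <- rep(NA_character_, nrow(edges))
  }
  layout <- as_tibble(layout)
  if (!"z" %in% names(layout)) layout$z <- rep(NA_real_, nrow(layout))
  structure(
    list(
      nodes = nodes[c("id", "name", "represents")],
      edges = edges[c("id", "source", "target", "interaction")],
      attributes = as_tibble(attributes),
      layout = layout[c("node", "x", "y", "z")],
      style = style,
      opaque = opaque,
      aspect_order = aspect_order,
      parse_violations = empty_violations()
    ),
    class = "cx_network"
  )
}

#' @export
print.cx_network <- function(x, ...) {
  cat(sprintf(
    "<cx_network> %d nodes, %d edges, %d attribute values, layout: %s, %d mapping(s), %d opaque aspect(s)\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$attributes),
    if (nrow(x$layout) > 0) "yes" else "none",
    length(x$style$mappings$node) + length(x$style$mappings$edge),
    length(x$opaque)
  ))
  invisible(x)
}

empty_violations <- function() {
  tibble(code = character(), severity = character(), message = character(),
         ids = list())
}

violation <- function(code, severity, message, ids = list()) {
  tibble(code = code, severity = severity, message = message,
         ids = list(ids))
}

#' Validate a network model
#'
#' Checks the referential integrity of a network: unique node and edge ids,
#' edge endpoints and attribute owners resolving to existing elements, at
#' most one layout point per node, and consistency of the visual style with
#' the attribute tables. Violations are returned as data, never raised:
#' severity `"error"` marks conditions that break export or rendering,
#' `"warning"` marks tolerated irregularities (e.g. a duplicate attribute,
#' where the last value wins).
#'
#' @param model A [cx_network()].
#' @return A tibble with columns `code`, `severity`, `message` and `ids`
#'   (list column of offending element ids); zero rows iff the model is
#'   internally consistent.
#' @export
validate_network <- function(model) {
  stopifnot(inherits(model, "cx_network"))
  v <- list(model$parse_violations)

  dup_nodes <- model$nodes$id[duplicated(model$nodes$id)]
  if (length(dup_nodes) > 0) {
    v <- c(v, list(violation("duplicate_node_id", "error",
                             "duplicate node id", unique(dup_nodes))))
  }
  dup_edges <- model$edges$id[duplicated(model$edges$id)]
  if (length(dup_edges) > 0) {
    v <- c(v, list(violation("duplicate_edge_id", "error",
                             "duplicate edge id", unique(dup_edges))))
  }

  node_ids <- model$nodes$id
  for (end in c("source", "target")) {
    missing <- model$edges$id[!model$edges[[end]] %in% node_ids]
    if (length(missing) > 0) {
      v <- c(v, list(violation("edge_endpoint_missing", "error",
                               sprintf("edge endpoint missing (%s)", end),
                               missing)))
    }
  }

  att <- model$attributes
  if (nrow(att) > 0) {
    own_node <- att %>% filter(.data$owner_class == "node",
                               !.data$owner %in% node_ids)
    own_edge <- att %>% filter(.data$owner_class == "edge",
                               !.data$owner %in% model$edges$id)
    if (nrow(own_node) + nrow(own_edge) > 0) {
      v <- c(v, list(violation("attribute_owner_missing", "error",
                               "attribute owner missing",
                               unique(c(own_node$owner, own_edge$owner)))))
    }
    dups <- att %>%
      filter(.data$owner_class != "network") %>%
      group_by(.data$owner_class, .data$owner, .data$name) %>%
      filter(n() > 1) %>%
      ungroup()
    if (nrow(dups) > 0) {
      v <- c(v, list(violation("duplicate_attribute", "warning",
                               "duplicate (owner, name) attribute; last value wins",
                               unique(dups$owner))))
    }
  }

  lay <- model$layout
  if (nrow(lay) > 0) {
    orphan <- lay$node[!lay$node %in% node_ids]
    if (length(orphan) > 0) {
      v <- c(v, list(violation("layout_node_missing", "error",
                               "layout point for unknown node", orphan)))
    }
    dup <- lay$node[duplicated(lay$node)]
    if (length(dup) > 0) {
      v <- c(v, list(violation("duplicate_layout_point", "error",
                               "more than one layout point for node",
                               unique(dup))))
    }
  }

  v <- c(v, list(validate_style(model$style, model)))
  out <- bind_rows(v)
  # order-independent: sort for a stable violation listing
  out %>% arrange(.data$severity, .data$code, .data$message)
}

#' Degree of a node
#'
#' Counts edges incident to a node, with self-loops counting twice (each
#' loop contributes both endpoints). Used by the concentric and
#' breadth-first layouts to rank nodes.
#'
#' @param model A [cx_network()].
#' @param node_id Node id (scalar or vector); defaults to all nodes.
#' @return A tibble with columns `id` and `degree`, one row per requested
#'   node in the requested order.
#' @export
#' @examples
#' net <- generate_fixture(n_nodes = 6, n_edges = 5, seed = 1)
#' node_degree(net)
node_degree <- function(model, node_id = model$nodes$id) {
  stopifnot(inherits(model, "cx_network"))
  unknown <- setdiff(node_id, model$nodes$id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown node id(s): %s",
                  paste(format(unknown, scientific = FALSE), collapse = ", ")))
  }
  ends <- c(model$edges$source, model$edges$target)
  deg <- vapply(node_id, function(i) sum(ends == i), numeric(1))
  tibble(id = as.numeric(node_id), degree = deg)
}

# Per-element attribute values for one (class, name): one row per owning
# element, last declaration winning for duplicates.
attribute_values <- function(model, owner_class, name) {
  model$attributes %>%
    filter(.data$owner_class == !!owner_class, .data$name == !!name) %>%
    group_by(.data$owner) %>%
    slice(n()) %>%
    ungroup() %>%
    select("owner", "value", "datatype")
}
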