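#' Generate a synthetic protein-interaction network
#'
#' Builds a seeded, reproducible network emulating the structure of the
#' breast-cancer protein-protein interaction demonstration network: a
#' simple undirected graph whose nodes carry a boolean bait flag
#' (`BaitBoolean`) and a string bait attribute (`Bait`) on a configurable
#' fraction of nodes, and whose edges carry a numeric differential
#' interaction score (`diff_score`) spanning -1 to +1. Optionally the
#' network ships with a preset layout, a style holding one discrete, one
#' continuous and one pass-through mapping, and a small custom aspect so
#' opaque-aspect handling is exercised.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges; must not exceed `n_nodes * (n_nodes - 1) / 2`
#'   (the graph is simple: no self-loops, no duplicate edges).
#' @param seed Integer seed; the same spec and seed always yield the same
#'   network, byte for byte after serialization.
#' @param node_bool Node boolean attribute plan:
#'   `list(name =, coverage =)`; exactly `floor(coverage * n_nodes)` nodes
#'   carry the attribute.
#' @param node_string Node string attribute plan: `list(name =, values =)`;
#'   placed on the same nodes as the boolean flag.
#' @param edge_numeric Edge numeric attribute plan:
#'   `list(name =, low =, high =)`, values uniform over `[low, high]`.
#' @param include_layout Add a preset cartesian layout.
#' @param include_style Add a style with one mapping of each kind.
#' @param include_opaque Add a small custom aspect (preserved verbatim by
#'   the CX round trip).
#' @return A [cx_network()] that passes [validate_network()] with zero
#'   errors.
#' @export
#' @examples
#' net <- generate_fixture(n_nodes = 10, n_edges = 15, seed = 7)
#' net
generate_fixture <- function(n_nodes = 50, n_edges = 100, seed = 1L,
                             node_bool = list(name = "BaitBoolean",
                                              coverage = 0.25),
                             node_string = list(name = "Bait",
                                                values = c("MCF7", "MDA-MB-231",
                                                           "MCF10A")),
                             edge_numeric = list(name = "diff_score",
                                                 low = -1, high = 1),
                             include_layout = TRUE, include_style = TRUE,
                             include_opaque = TRUE) {
  if (n_nodes < 1) abort("n_nodes must be >= 1")
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    abort(sprintf("a simple graph on %d nodes holds at most %d edges",
                  n_nodes, max_edges))
  }
  if (node_bool$coverage < 0 || node_bool$coverage > 1) {
    abort("coverage must lie in [0, 1]")
  }
  if (edge_numeric$low >= edge_numeric$high) {
    abort("edge attribute range must have low < high")
  }

  withr::with_seed(seed, {
    node_ids <- as.numeric(seq_len(n_nodes) - 1L)
    nodes <- tibble(id = node_ids,
                    name = sprintf("PROT%03d", seq_len(n_nodes)),
                    represents = NA_character_)

    # unranked sample of unordered node pairs -> simple undirected graph
    pair_idx <- sort(sample.int(max_edges, n_edges))
    row <- floor((1 + sqrt(8 * (pair_idx - 1) + 1)) / 2)
    col <- pair_idx - 1 - row * (row - 1) / 2
    edges <- tibble(id = as.numeric(seq_len(n_edges) - 1L),
                    source = as.numeric(col),
                    target = as.numeric(row),
                    interaction = "interacts-with")

    n_covered <- floor(node_bool$coverage * n_nodes)
    covered <- sort(sample(node_ids, n_covered))
    attrs <- list(empty_attributes())
    if (n_covered > 0) {
      attrs <- c(attrs, list(
        tibble(owner_class = "node", owner = covered, name = node_bool$name,
               value = as.list(rep(TRUE, n_covered)), datatype = "boolean"),
        tibble(owner_class = "node", owner = covered, name = node_string$name,
               value = as.list(sample(node_string$values, n_covered,
                                      replace = TRUE)),
               datatype = "string")
      ))
    }
    scores <- stats::runif(n_edges, edge_numeric$low, edge_numeric$high)
    attrs <- c(attrs, list(
      tibble(owner_class = "edge", owner = edges$id, name = edge_numeric$name,
             value = as.list(scores), datatype = "double"),
      tibble(owner_class = "network", owner = NA_real_, name = "name",
             value = list("synthetic breast-cancer PPI emulation"),
             datatype = "string")
    ))

    model <- cx_network(nodes = nodes, edges = edges,
                        attributes = bind_rows(attrs))

    if (include_style) {
      mid <- (edge_numeric$low + edge_numeric$high) / 2
      model$style <- cx_style(
        defaults = list(
          network = list(NETWORK_BACKGROUND_PAINT = "#FFFFFF"),
          node = list(NODE_FILL_COLOR = "#CCCCCC", NODE_SIZE = "30"),
          edge = list(EDGE_WIDTH = "2")
        ),
        mappings = list(
          node = list(
            NODE_FILL_COLOR = cx_mapping(
              "DISCRETE", node_bool$name, "boolean", "NODE_FILL_COLOR",
              entries = tibble(key = "true", value = "#FF9900")),
            NODE_LABEL = cx_mapping("PASSTHROUGH", "name", "string",
                                    "NODE_LABEL")
          ),
          edge = list(
            EDGE_STROKE_UNSELECTED_PAINT = cx_mapping(
              "CONTINUOUS", edge_numeric$name, "double",
              "EDGE_STROKE_UNSELECTED_PAINT",
              points = tibble(
                threshold = c(edge_numeric$low, mid, edge_numeric$high),
                lesser = c("#0000FF", "#FFFFFF", "#FF0000"),
                equal = c("#0000FF", "#FFFFFF", "#FF0000"),
                greater = c("#0000FF", "#FFFFFF", "#FF0000")))
          )
        )
      )
    }

    if (include_layout) {
      model <- store_layout(
        model, layout_random(model, cx_viewport(600, 600), seed))
    }

    if (include_opaque) {
      model$opaque <- list(list(
        name = "provenanceTrace",
        elements = list(list(generator = "cxviz", seed = as.integer(seed),
                             tags = list("synthetic", "ppi")))
      ))
      model$aspect_order <- c(model$aspect_order, "provenanceTrace")
    }
    model
  })
}

# name-column ambiguity: passthrough on "name" reads the node's core name
# field when no attribute of that name exists; expose it as an attribute
# lookup so mappings see it uniformly.
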