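# Hand-built miniature networks used across the suite.

path_model <- function(ids = c(0, 1, 2)) {
  # simple path a-b-c
  cx_network(
    nodes = tibble::tibble(id = ids),
    edges = tibble::tibble(id = seq_along(ids[-1]) - 1,
                           source = ids[-length(ids)], target = ids[-1])
  )
}

star_model <- function(n_leaves = 5) {
  cx_network(
    nodes = tibble::tibble(id = 0:n_leaves),
    edges = tibble::tibble(id = 0:(n_leaves - 1), source = 0,
                           target = 1:n_leaves)
  )
}

minimal_cx_text <- function() {
  paste0(
    '[{"numberVerification":[{"longNumber":281474976710655}]},',
    '{"metaData":[{"name":"nodes","elementCount":2},{"name":"edges","elementCount":1}]},',
    '{"nodes":[{"@id":0,"n":"BRCA1"},{"@id":1,"n":"TP53"}]},',
    '{"edges":[{"@id":0,"s":0,"t":1,"i":"interacts-with"}]},',
    '{"status":[{"error":"","success":true}]}]'
  )
}

# a model with one attribute of each owner class and a style exercising all
# three mapping kinds
styled_model <- function() {
  net <- cx_network(
    nodes = tibble::tibble(id = c(0, 1, 2, 3),
                           name = c("A", "B", "C", "D"),
                           represents = NA_character_),
    edges = tibble::tibble(id = c(0, 1), source = c(0, 1), target = c(1, 2),
                           interaction = NA_character_),
    attributes = tibble::tibble(
      owner_class = c("node", "node", "node", "edge", "edge"),
      owner = c(0, 1, 2, 0, 1),
      name = c("Bait", "Bait", "Bait", "diff_score", "diff_score"),
      value = list(TRUE, FALSE, TRUE, -0.5, 0.7),
      datatype = c("boolean", "boolean", "boolean", "double", "double")
    )
  )
  net$style <- cx_style(
    defaults = list(network = list(NETWORK_BACKGROUND_PAINT = "#EEEEEE"),
                    node = list(NODE_FILL_COLOR = "#999999"),
                    edge = list()),
    mappings = list(
      node = list(
        NODE_SHAPE = cx_mapping("DISCRETE", "Bait", "boolean", "NODE_SHAPE",
                                entries = tibble::tibble(key = "true",
                                                         value = "DIAMOND")),
        NODE_LABEL = cx_mapping("PASSTHROUGH", "name", "string", "NODE_LABEL")
      ),
      edge = list(
        EDGE_WIDTH = cx_mapping(
          "CONTINUOUS", "diff_score", "double", "EDGE_WIDTH",
          points = tibble::tibble(threshold = c(-1, 1),
                                  lesser = c("1", "8"),
                                  equal = c("1", "8"),
                                  greater = c("1", "8")))
      )
    )
  )
  net
}

# random continuous mapping whose points carry a single value (L = E = G),
# so an independent piecewise-linear oracle applies everywhere
random_continuous_mapping <- function(color = FALSE, n_points = NULL) {
  n_points <- n_points %||% sample(2:5, 1)
  th <- sort(stats::runif(n_points, -10, 10))
  while (anyDuplicated(th)) th <- sort(stats::runif(n_points, -10, 10))
  if (color) {
    vals <- sprintf("#%02X%02X%02X", sample(0:255, n_points, TRUE),
                    sample(0:255, n_points, TRUE),
                    sample(0:255, n_points, TRUE))
    prop <- "EDGE_STROKE_UNSELECTED_PAINT"
  } else {
    vals <- as.character(round(stats::runif(n_points, 0, 20), 3))
    prop <- "EDGE_WIDTH"
  }
  cx_mapping("CONTINUOUS", "score", "double", prop,
             points = tibble::tibble(threshold = th, lesser = vals,
                                     equal = vals, greater = vals))
}

# dense-grid oracle: piecewise-linear interpolation through the anchors via
# stats::approx (per channel for colors), with clamping outside the range
oracle_continuous <- function(m, v) {
  pts <- m$points[order(m$points$threshold), ]
  if (all(grepl("^#", pts$equal))) {
    ch <- grDevices::col2rgb(pts$equal)
    rgb <- vapply(1:3, function(k) {
      stats::approx(pts$threshold, ch[k, ], xout = v, rule = 2)$y
    }, numeric(length(v)))
    rgb <- matrix(rgb, ncol = 3)
    sprintf("#%02X%02X%02X", floor(rgb[, 1] + 0.5), floor(rgb[, 2] + 0.5),
            floor(rgb[, 3] + 0.5))
  } else {
    as.character(stats::approx(pts$threshold, as.numeric(pts$equal),
                               xout = v, rule = 2)$y)
  }
}

channel_distance <- function(c1, c2) {
  max(abs(grDevices::col2rgb(c1) - grDevices::col2rgb(c2)))
}
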