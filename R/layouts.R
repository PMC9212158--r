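#' Construct a viewport
#'
#' The rectangular canvas region used by the random layout and optional
#' render clipping. Origin at (0, 0), x rightward, y downward (screen
#' convention).
#'
#' @param width,height Positive extents in canvas units.
#' @return A `cx_viewport`.
#' @export
cx_viewport <- function(width, height) {
  if (width <= 0 || height <= 0) abort("viewport dimensions must be positive")
  structure(list(width = width, height = height), class = "cx_viewport")
}

new_layout <- function(coordinates, algorithm, parameters = list(), seed = NULL) {
  stopifnot(all(is.finite(coordinates$x)), all(is.finite(coordinates$y)))
  structure(list(coordinates = as_tibble(coordinates), algorithm = algorithm,
                 parameters = parameters, seed = seed),
            class = "cx_layout")
}

#' @export
print.cx_layout <- function(x, ...) {
  cat(sprintf("<cx_layout> %s: %d node position(s)\n", x$algorithm,
              nrow(x$coordinates)))
  invisible(x)
}

#' @export
#' @rdname cxviz-tidiers
tidy.cx_layout <- function(x, ...) x$coordinates

#' @export
#' @rdname cxviz-tidiers
glance.cx_layout <- function(x, ...) {
  co <- x$coordinates
  tibble(algorithm = x$algorithm, n_nodes = nrow(co),
         width = if (nrow(co) > 0) diff(range(co$x)) else 0,
         height = if (nrow(co) > 0) diff(range(co$y)) else 0,
         seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed))
}

#' @export
#' @rdname cxviz-autoplot
autoplot.cx_layout <- function(object, model = NULL, ...) {
  co <- object$coordinates
  p <- ggplot2::ggplot(co, ggplot2::aes(.data$x, .data$y))
  if (!is.null(model)) {
    seg <- model$edges %>%
      left_join(co, by = c(source = "node")) %>%
      left_join(co, by = c(target = "node"), suffix = c("", "_t"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_t, yend = .data$y_t),
      color = "grey70")
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Random layout
#'
#' Distributes nodes independently and uniformly across the viewport;
#' reproducible for a fixed seed.
#'
#' @param model A [cx_network()].
#' @param viewport A [cx_viewport()].
#' @param seed Integer seed.
#' @return A `cx_layout`.
#' @export
layout_random <- function(model, viewport = cx_viewport(600, 600), seed = 1L) {
  stopifnot(inherits(viewport, "cx_viewport"))
  n <- nrow(model$nodes)
  co <- withr::with_seed(seed, tibble(
    node = model$nodes$id,
    x = stats::runif(n, 0, viewport$width),
    y = stats::runif(n, 0, viewport$height)
  ))
  new_layout(co, "random",
             list(width = viewport$width, height = viewport$height), seed)
}

#' Grid layout
#'
#' Nodes sorted ascending by id fill the rows of a `ceiling(sqrt(n))`-column
#' grid, left to right then top to bottom, with the given pitch. Puts the
#' focus on the nodes themselves.
#'
#' @param model A [cx_network()].
#' @param spacing Grid pitch in canvas units (> 0).
#' @return A `cx_layout`.
#' @export
layout_grid <- function(model, spacing = 40) {
  if (spacing <= 0) abort("spacing must be positive")
  ids <- sort(model$nodes$id)
  n <- length(ids)
  cols <- max(1L, ceiling(sqrt(n)))
  k <- seq_len(n) - 1L
  co <- tibble(node = ids,
               x = (k %% cols) * spacing,
               y = (k %/% cols) * spacing)
  new_layout(co, "grid", list(spacing = spacing))
}

#' Circular layout
#'
#' Nodes sorted by id are placed at equal angular steps on one circle,
#' clockwise in screen coordinates from the start angle, so the focus lies
#' on the edges between them.
#'
#' @param model A [cx_network()].
#' @param radius Circle radius (> 0).
#' @param start_angle Angle of the first node in degrees; the default -90
#'   places it at the top.
#' @param center Circle center `c(x, y)`, typically the viewport center.
#' @return A `cx_layout`.
#' @export
layout_circle <- function(model, radius = 100, start_angle = -90,
                          center = c(0, 0)) {
  if (radius <= 0) abort("radius must be positive")
  ids <- sort(model$nodes$id)
  n <- length(ids)
  ang <- (start_angle + (seq_len(n) - 1L) * 360 / max(n, 1L)) * pi / 180
  co <- tibble(node = ids,
               x = center[[1]] + radius * cos(ang),
               y = center[[2]] + radius * sin(ang))
  new_layout(co, "circle",
             list(radius = radius, start_angle = start_angle))
}

#' Concentric layout
#'
#' Nodes ranked by degree (descending, ties broken by ascending id) are
#' placed on concentric circles: the highest-degree nodes sit innermost and
#' each ring's radius is a multiple of `ring_gap`, giving a denser picture
#' than the single circle. Ring `k` holds up to `floor(2 * pi * k)` nodes so
#' spacing along the circumference stays comparable to the gap.
#'
#' @param model A [cx_network()].
#' @param ring_gap Radial distance between rings (> 0).
#' @param center Center `c(x, y)`.
#' @return A `cx_layout`.
#' @export
layout_concentric <- function(model, ring_gap = 60, center = c(0, 0)) {
  if (ring_gap <= 0) abort("ring_gap must be positive")
  deg <- node_degree(model)
  ranked <- deg %>% arrange(desc(.data$degree), .data$id)
  n <- nrow(ranked)
  ring <- integer(n); pos_in_ring <- integer(n); ring_size <- integer(n)
  i <- 1L; k <- 0L
  while (i <= n) {
    cap <- if (k == 0L) 1L else max(1L, floor(2 * pi * k))
    take <- min(cap, n - i + 1L)
    ring[i:(i + take - 1L)] <- k
    pos_in_ring[i:(i + take - 1L)] <- seq_len(take) - 1L
    ring_size[i:(i + take - 1L)] <- take
    i <- i + take
    k <- k + 1L
  }
  ang <- (-90 + pos_in_ring * 360 / pmax(ring_size, 1L)) * pi / 180
  r <- ring * ring_gap
  co <- tibble(node = ranked$id,
               x = center[[1]] + r * cos(ang),
               y = center[[2]] + r * sin(ang))
  new_layout(co, "concentric", list(ring_gap = ring_gap))
}

# undirected adjacency list keyed by node id (as character)
adjacency_list <- function(model) {
  adj <- stats::setNames(vector("list", nrow(model$nodes)),
                         as.character(model$nodes$id))
  for (i in seq_len(nrow(model$edges))) {
    s <- as.character(model$edges$source[[i]])
    t <- as.character(model$edges$target[[i]])
    adj[[s]] <- c(adj[[s]], model$edges$target[[i]])
    adj[[t]] <- c(adj[[t]], model$edges$source[[i]])
  }
  adj
}

# connected components as a list of id vectors (undirected)
components_of <- function(model) {
  ids <- model$nodes$id
  adj <- adjacency_list(model)
  seen <- stats::setNames(rep(FALSE, length(ids)), as.character(ids))
  comps <- list()
  for (start in ids) {
    if (seen[[as.character(start)]]) next
    queue <- start; seen[[as.character(start)]] <- TRUE
    comp <- numeric()
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[as.character(v)]]) {
        if (!seen[[as.character(w)]]) {
          seen[[as.character(w)]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps <- c(comps, list(sort(comp)))
  }
  comps
}

bfs_depths <- function(adj, root) {
  depth <- stats::setNames(numeric(0), character(0))
  queue <- root; depth[as.character(root)] <- 0
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[as.character(v)]]) {
      key <- as.character(w)
      if (is.na(depth[key])) {
        depth[key] <- depth[[as.character(v)]] + 1
        queue <- c(queue, w)
      }
    }
  }
  depth
}

#' Breadth-first (hierarchical) layout
#'
#' Performs an undirected breadth-first traversal from one root per
#' connected component and stacks nodes by their BFS depth, which
#' illustrates the topology of the network. The default root of a component
#' is its node of maximal degree (ties broken by minimal id). Components
#' are laid out side by side with disjoint bounding boxes.
#'
#' @param model A [cx_network()].
#' @param roots Optional vector of root node ids; components not containing
#'   a supplied root fall back to the default rule.
#' @param level_gap Vertical distance between depths, and horizontal pitch
#'   within a depth (> 0).
#' @return A `cx_layout`.
#' @export
layout_breadthfirst <- function(model, roots = NULL, level_gap = 60) {
  if (level_gap <= 0) abort("level_gap must be positive")
  if (!is.null(roots)) {
    unknown <- setdiff(roots, model$nodes$id)
    if (length(unknown) > 0) {
      abort(sprintf("root(s) not in network: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  adj <- adjacency_list(model)
  deg <- node_degree(model)
  comps <- components_of(model)
  rows <- list()
  x_offset <- 0
  for (comp in comps) {
    root <- intersect(roots, comp)
    if (length(root) == 0) {
      cand <- deg %>% filter(.data$id %in% comp) %>%
        arrange(desc(.data$degree), .data$id)
      root <- cand$id[[1]]
    } else {
      root <- min(root)
    }
    depth <- bfs_depths(adj, root)
    d <- tibble(node = as.numeric(names(depth)), depth = as.numeric(depth)) %>%
      arrange(.data$depth, .data$node) %>%
      group_by(.data$depth) %>%
      mutate(x = x_offset + (row_number() - 1) * level_gap) %>%
      ungroup() %>%
      mutate(y = .data$depth * level_gap)
    rows <- c(rows, list(d %>% select("node", "x", "y")))
    x_offset <- max(d$x) + 2 * level_gap
  }
  co <- bind_rows(rows) %>% arrange(.data$node)
  new_layout(co, "breadthfirst", list(level_gap = level_gap))
}

layout_energy <- function(pos, edge_idx, ideal, k_spring, k_repulse, gravity) {
  e <- 0
  if (nrow(edge_idx) > 0) {
    d <- sqrt((pos$x[edge_idx$si] - pos$x[edge_idx$ti])^2 +
              (pos$y[edge_idx$si] - pos$y[edge_idx$ti])^2)
    e <- e + sum(0.5 * k_spring * (d - ideal)^2)
  }
  n <- nrow(pos)
  if (n > 1) {
    dm <- as.matrix(stats::dist(cbind(pos$x, pos$y)))
    dm[dm < 1e-6] <- 1e-6
    e <- e + sum(k_repulse / dm[upper.tri(dm)])
  }
  cx <- mean(pos$x); cy <- mean(pos$y)
  e + 0.5 * gravity * sum((pos$x - cx)^2 + (pos$y - cy)^2)
}

#' Force-directed (spring embedder) layout
#'
#' A physics simulation in the compound-spring-embedder family: edges act
#' as springs pulling node pairs toward the ideal edge length, all node
#' pairs repel with a force proportional to the inverse square of their
#' distance, and a weak gravity pulls nodes toward the layout centroid to
#' keep components together. Positions start from [layout_random()] with
#' the given seed and are updated with a linearly cooling step cap; a step
#' that would increase the total layout energy is rejected and the step
#' scale halved, so the energy decreases monotonically. Deterministic for
#' a fixed seed.
#'
#' @param model A [cx_network()].
#' @param ideal_edge_length Target spring length (canvas units).
#' @param iterations Number of simulation steps (>= 1).
#' @param seed Integer seed for the initial placement.
#' @param k_spring Spring constant (force per unit extension).
#' @param k_repulse Repulsion constant (force = `k_repulse / d^2`).
#' @param gravity Centroid attraction constant.
#' @return A `cx_layout`; its `parameters$energy` traces the accepted
#'   energy at each iteration.
#' @export
layout_cose <- function(model, ideal_edge_length = 50, iterations = 500,
                        seed = 1L, k_spring = 0.1, k_repulse = 100,
                        gravity = 0.001) {
  if (iterations < 1) abort("iterations must be >= 1")
  n <- nrow(model$nodes)
  side <- ideal_edge_length * max(1, ceiling(sqrt(max(n, 1))))
  pos <- layout_random(model, cx_viewport(side, side), seed)$coordinates
  if (n <= 1) {
    return(new_layout(pos, "cose",
                      list(ideal_edge_length = ideal_edge_length,
                           iterations = iterations, energy = numeric()), seed))
  }
  idx <- stats::setNames(seq_len(n), as.character(pos$node))
  edge_idx <- tibble(si = idx[as.character(model$edges$source)],
                     ti = idx[as.character(model$edges$target)]) %>%
    filter(.data$si != .data$ti)  # self-loops exert no layout force

  energy <- layout_energy(pos, edge_idx, ideal_edge_length,
                          k_spring, k_repulse, gravity)
  trace <- numeric(iterations)
  t0 <- ideal_edge_length / 10
  damp <- 1
  for (it in seq_len(iterations)) {
    temp <- t0 * (1 - (it - 1) / iterations) * damp
    dx_mat <- outer(pos$x, pos$x, "-")
    dy_mat <- outer(pos$y, pos$y, "-")
    dm <- sqrt(dx_mat^2 + dy_mat^2)
    dm[dm < 1e-6] <- 1e-6
    # repulsion: away from every other node
    rep_f <- k_repulse / dm^2
    diag(rep_f) <- 0
    fx <- rowSums(rep_f * dx_mat / dm)
    fy <- rowSums(rep_f * dy_mat / dm)
    # springs along edges toward the ideal length
    if (nrow(edge_idx) > 0) {
      ex <- pos$x[edge_idx$si] - pos$x[edge_idx$ti]
      ey <- pos$y[edge_idx$si] - pos$y[edge_idx$ti]
      ed <- pmax(sqrt(ex^2 + ey^2), 1e-6)
      f <- k_spring * (ed - ideal_edge_length)
      for (j in seq_len(nrow(edge_idx))) {
        si <- edge_idx$si[[j]]; ti <- edge_idx$ti[[j]]
        fx[si] <- fx[si] - f[j] * ex[j] / ed[j]
        fy[si] <- fy[si] - f[j] * ey[j] / ed[j]
        fx[ti] <- fx[ti] + f[j] * ex[j] / ed[j]
        fy[ti] <- fy[ti] + f[j] * ey[j] / ed[j]
      }
    }
    # gravity toward the centroid
    fx <- fx + gravity * (mean(pos$x) - pos$x)
    fy <- fy + gravity * (mean(pos$y) - pos$y)
    mag <- pmax(sqrt(fx^2 + fy^2), 1e-12)
    scale <- pmin(1, temp / mag)
    cand <- pos
    cand$x <- pos$x + fx * scale
    cand$y <- pos$y + fy * scale
    e_new <- layout_energy(cand, edge_idx, ideal_edge_length,
                           k_spring, k_repulse, gravity)
    if (e_new <= energy) {
      pos <- cand
      energy <- e_new
    } else {
      damp <- damp / 2
    }
    trace[it] <- energy
  }
  new_layout(pos, "cose",
             list(ideal_edge_length = ideal_edge_length,
                  iterations = iterations, k_spring = k_spring,
                  k_repulse = k_repulse, gravity = gravity, energy = trace),
             seed)
}

#' Restore the preset layout stored in the network
#'
#' Takes coordinates verbatim from the model's cartesian-layout aspect (the
#' layout saved when the network was exported). Nodes missing from the
#' aspect are placed on a grid appended below the preset's bounding box.
#'
#' @param model A [cx_network()].
#' @param spacing Grid pitch for nodes without a stored coordinate.
#' @return A `cx_layout`.
#' @export
apply_preset <- function(model, spacing = 40) {
  if (nrow(model$layout) == 0 && nrow(model$nodes) > 0) {
    abort("network carries no cartesian layout; apply a layout algorithm instead")
  }
  preset <- model$layout %>%
    filter(.data$node %in% model$nodes$id) %>%
    select("node", "x", "y")
  missing <- setdiff(model$nodes$id, preset$node)
  if (length(missing) > 0) {
    sub <- cx_network(nodes = model$nodes %>% filter(.data$id %in% missing))
    grid <- layout_grid(sub, spacing)$coordinates
    grid$x <- grid$x + if (nrow(preset) > 0) min(preset$x) else 0
    grid$y <- grid$y + if (nrow(preset) > 0) max(preset$y) + spacing else 0
    preset <- bind_rows(preset, grid)
  }
  new_layout(preset %>% arrange(.data$node), "preset", list())
}

#' Store a layout result in the network
#'
#' Replaces the model's cartesian-layout aspect with the result's
#' coordinates (z values already stored for a node are preserved), so the
#' layout round-trips through [serialize_cx()] at full precision.
#'
#' @param model A [cx_network()].
#' @param result A `cx_layout` covering every node of the model.
#' @return The modified model.
#' @export
store_layout <- function(model, result) {
  stopifnot(inherits(result, "cx_layout"))
  co <- result$coordinates
  missing <- setdiff(model$nodes$id, co$node)
  if (length(missing) > 0) {
    abort(sprintf("layout result misses %d node(s); refusing partial store",
                  length(missing)))
  }
  old_z <- model$layout %>% select("node", "z")
  lay <- co %>%
    filter(.data$node %in% model$nodes$id) %>%
    left_join(old_z, by = "node") %>%
    arrange(.data$node)
  if (!"z" %in% names(lay)) lay$z <- rep(NA_real_, nrow(lay))
  model$layout <- lay[c("node", "x", "y", "z")]
  if (!"cartesianLayout" %in% model$aspect_order) {
    model$aspect_order <- c(model$aspect_order, "cartesianLayout")
  }
  model
}
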