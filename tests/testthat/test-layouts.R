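test_that("random layout is seeded, bounded and uniform in expectation", {
  net <- generate_fixture(n_nodes = 1000, n_edges = 1500, seed = 1,
                          include_style = FALSE, include_layout = FALSE,
                          include_opaque = FALSE)
  vp <- cx_viewport(100, 100)
  l1 <- layout_random(net, vp, seed = 5)
  l2 <- layout_random(net, vp, seed = 5)
  expect_identical(l1$coordinates, l2$coordinates)
  co <- l1$coordinates
  expect_true(all(co$x >= 0 & co$x <= 100 & co$y >= 0 & co$y <= 100))
  # mean of U(0,100) is 50 with s.e. 100/sqrt(12*n)
  se <- 100 / sqrt(12 * nrow(co))
  expect_lt(abs(mean(co$x) - 50), 3 * se)
  expect_lt(abs(mean(co$y) - 50), 3 * se)
})

test_that("grid layout fills rows sorted by node id", {
  net <- cx_network(nodes = tibble::tibble(id = c(3, 1, 2, 0)))
  co <- tidy(layout_grid(net, 40))
  expect_equal(co, tibble::tibble(node = c(0, 1, 2, 3),
                                  x = c(0, 40, 0, 40),
                                  y = c(0, 0, 40, 40)))
  single <- tidy(layout_grid(cx_network(nodes = tibble::tibble(id = 9)), 40))
  expect_equal(c(single$x, single$y), c(0, 0))
  five <- tidy(layout_grid(cx_network(nodes = tibble::tibble(id = 0:4)), 10))
  expect_equal(max(five$x) / 10 + 1, 3)       # ceiling(sqrt(5)) = 3 columns
  expect_equal(sum(five$y == max(five$y)), 2) # last row holds 2 nodes
})

test_that("circular layout spaces nodes clockwise from the top", {
  net <- cx_network(nodes = tibble::tibble(id = 0:3))
  co <- tidy(layout_circle(net, radius = 100, start_angle = -90))
  expect_equal(co$x, c(0, 100, 0, -100), tolerance = 1e-9)
  expect_equal(co$y, c(-100, 0, 100, 0), tolerance = 1e-9)
  # radius constancy for arbitrary n
  big <- tidy(layout_circle(cx_network(nodes = tibble::tibble(id = 0:16)),
                            radius = 55))
  expect_equal(sqrt(big$x^2 + big$y^2), rep(55, 17), tolerance = 1e-9)
  one <- tidy(layout_circle(cx_network(nodes = tibble::tibble(id = 0)), 10))
  expect_equal(c(one$x, one$y), c(0, -10), tolerance = 1e-9)
})

test_that("concentric layout places high-degree nodes innermost on gap multiples", {
  star <- star_model(5)
  co <- tidy(layout_concentric(star, ring_gap = 60))
  r <- sqrt(co$x^2 + co$y^2)
  hub <- r[co$node == 0]
  expect_true(all(hub < r[co$node != 0]))
  expect_equal(sort(unique(round(r / 60, 9)) %% 1), rep(0, length(unique(round(r / 60, 9)))))
  # regular graph: tie-break by id, ring assignment deterministic
  ring <- cx_network(nodes = tibble::tibble(id = 0:5),
                     edges = tibble::tibble(id = 0:5, source = 0:5,
                                            target = c(1:5, 0)))
  c1 <- tidy(layout_concentric(ring, 40))
  c2 <- tidy(layout_concentric(ring, 40))
  expect_identical(c1, c2)
  expect_equal(c1$node[which.min(sqrt(c1$x^2 + c1$y^2))], 0)
})

test_that("breadth-first layout stacks nodes by BFS depth", {
  p <- path_model(c(0, 1, 2))
  co <- tidy(layout_breadthfirst(p, roots = 0, level_gap = 50))
  expect_equal(co$y[order(co$node)], c(0, 50, 100))
  expect_error(layout_breadthfirst(p, roots = 42), "not in network")
})

test_that("breadth-first depths agree with igraph on random trees", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(6:20, 1)
    parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), numeric(1)))
    net <- cx_network(
      nodes = tibble::tibble(id = as.numeric(0:(n - 1))),
      edges = tibble::tibble(id = as.numeric(seq_len(n - 1) - 1),
                             source = parent[-1] - 1,
                             target = as.numeric(1:(n - 1)))
    )
    co <- tidy(layout_breadthfirst(net, roots = 0, level_gap = 10))
    g <- igraph::graph_from_data_frame(net$edges[c("source", "target")],
                                       directed = FALSE,
                                       vertices = data.frame(name = net$nodes$id))
    depth <- as.numeric(igraph::distances(g, v = "0")[1, as.character(co$node)])
    expect_equal(co$y, depth * 10)
    # every child strictly below its parent
    for (i in 2:n) {
      expect_gt(co$y[co$node == i - 1], co$y[co$node == parent[i] - 1])
    }
  }
})

test_that("disconnected components get disjoint bounding boxes", {
  two_tri <- cx_network(
    nodes = tibble::tibble(id = 0:5),
    edges = tibble::tibble(id = 0:5,
                           source = c(0, 1, 2, 3, 4, 5),
                           target = c(1, 2, 0, 4, 5, 3))
  )
  co <- tidy(layout_breadthfirst(two_tri, level_gap = 30))
  a <- co[co$node <= 2, ]; b <- co[co$node >= 3, ]
  expect_true(max(a$x) < min(b$x) || max(b$x) < min(a$x))
})

test_that("the spring embedder reaches the two-node equilibrium deterministically", {
  two <- cx_network(nodes = tibble::tibble(id = c(0, 1)),
                    edges = tibble::tibble(id = 0, source = 0, target = 1))
  l1 <- layout_cose(two, ideal_edge_length = 50, iterations = 400, seed = 3)
  l2 <- layout_cose(two, ideal_edge_length = 50, iterations = 400, seed = 3)
  expect_identical(l1$coordinates, l2$coordinates)
  d <- as.numeric(dist(as.matrix(l1$coordinates[c("x", "y")])))
  expect_lt(abs(d - 50) / 50, 0.05)

  tri <- cx_network(nodes = tibble::tibble(id = 0:2),
                    edges = tibble::tibble(id = 0:2, source = c(0, 1, 2),
                                           target = c(1, 2, 0)))
  lt <- layout_cose(tri, 50, 400, seed = 4)
  dd <- as.numeric(dist(as.matrix(lt$coordinates[c("x", "y")])))
  expect_lt((max(dd) - min(dd)) / mean(dd), 0.05)
})

test_that("spring-embedder energy decreases monotonically", {
  net <- generate_fixture(n_nodes = 20, n_edges = 30, seed = 6,
                          include_style = FALSE, include_layout = FALSE)
  l <- layout_cose(net, 50, 150, seed = 2)
  trace <- l$parameters$energy
  checkpoints <- trace[seq(1, length(trace), by = 10)]
  expect_false(is.unsorted(rev(checkpoints)))
  expect_lt(trace[length(trace)], trace[1])
})

test_that("every layout algorithm yields finite coordinates for every node", {
  net <- generate_fixture(n_nodes = 17, n_edges = 24, seed = 31)
  layouts <- list(
    layout_random(net, seed = 1),
    layout_grid(net),
    layout_circle(net),
    layout_concentric(net),
    layout_breadthfirst(net),
    layout_cose(net, iterations = 30, seed = 1),
    apply_preset(net)
  )
  for (l in layouts) {
    co <- l$coordinates
    expect_setequal(co$node, net$nodes$id)
    expect_true(all(is.finite(co$x) & is.finite(co$y)))
  }
})

test_that("preset restoration and storage are inverse operations", {
  net <- generate_fixture(n_nodes = 9, n_edges = 12, seed = 8)
  preset <- apply_preset(net)
  expect_equal(dplyr::arrange(preset$coordinates, node)[c("node", "x", "y")],
               dplyr::arrange(net$layout, node)[c("node", "x", "y")])
  stored <- store_layout(net, preset)
  expect_equal(dplyr::arrange(stored$layout, node)[c("node", "x", "y")],
               dplyr::arrange(net$layout, node)[c("node", "x", "y")])

  # partial preset: covered nodes verbatim, the rest grid-placed below
  partial <- net
  partial$layout <- partial$layout[1:2, ]
  res <- apply_preset(partial)
  kept <- res$coordinates[res$coordinates$node %in% partial$layout$node, ]
  expect_equal(dplyr::arrange(kept, node)$x,
               dplyr::arrange(partial$layout, node)$x)
  added <- res$coordinates[!res$coordinates$node %in% partial$layout$node, ]
  expect_true(all(added$y > max(partial$layout$y)))

  bare <- generate_fixture(n_nodes = 3, n_edges = 2, seed = 1,
                           include_layout = FALSE)
  expect_error(apply_preset(bare), "no cartesian layout")
  expect_error(store_layout(bare, layout_grid(path_model(c(0, 1)))),
               "misses")
})

test_that("stored layouts create the aspect and update metadata counts", {
  net <- generate_fixture(n_nodes = 6, n_edges = 8, seed = 4,
                          include_layout = FALSE)
  expect_equal(nrow(net$layout), 0)
  stored <- store_layout(net, layout_grid(net, 30))
  doc <- parse_cx(serialize_cx(stored))
  meta <- doc$pre_metadata
  names(meta) <- vapply(meta, `[[`, character(1), "name")
  expect_equal(meta[["cartesianLayout"]]$elementCount, 6)
})
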