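test_that("discrete lookup matches exactly and falls through otherwise", {
  m <- cx_mapping("DISCRETE", "Bait", "boolean", "NODE_SHAPE",
                  entries = tibble::tibble(key = "true", value = "ELLIPSE"))
  expect_equal(apply_discrete(m, TRUE), "ELLIPSE")
  expect_equal(apply_discrete(m, "true"), "ELLIPSE")  # coerced before lookup
  expect_true(is.na(apply_discrete(m, FALSE)))

  m2 <- cx_mapping("DISCRETE", "type", "string", "NODE_FILL_COLOR",
                   entries = tibble::tibble(key = c("A", "B"),
                                            value = c("#FF0000", "#00FF00")))
  # exhaustive lookup over all keys and a miss
  expect_equal(apply_discrete(m2, c("A", "B", "C")),
               c("#FF0000", "#00FF00", NA))
})

test_that("continuous mapping interpolates, clamps and honors at-threshold values", {
  m <- cx_mapping("CONTINUOUS", "w", "double", "EDGE_WIDTH",
                  points = tibble::tibble(threshold = c(0, 10),
                                          lesser = c("1", "5"),
                                          equal = c("1", "5"),
                                          greater = c("1", "5")))
  expect_equal(as.numeric(apply_continuous(m, 2.5)), 2.0)
  expect_equal(as.numeric(apply_continuous(m, -3)), 1.0)   # lesser clamp
  expect_equal(as.numeric(apply_continuous(m, 42)), 5.0)   # greater clamp
  expect_equal(as.numeric(apply_continuous(m, c(0, 10))), c(1, 5))
  expect_error(apply_continuous(m, "x"), "numeric")

  mc <- cx_mapping("CONTINUOUS", "diff_score", "double",
                   "EDGE_STROKE_UNSELECTED_PAINT",
                   points = tibble::tibble(threshold = c(-1, 1),
                                           lesser = c("#0000FF", "#FF0000"),
                                           equal = c("#0000FF", "#FF0000"),
                                           greater = c("#0000FF", "#FF0000")))
  expect_equal(apply_continuous(mc, 0), "#800080")  # per-channel round half up

  # distinct lesser/equal/greater: boundary semantics are exact
  mb <- cx_mapping("CONTINUOUS", "w", "double", "EDGE_WIDTH",
                   points = tibble::tibble(threshold = c(0, 10),
                                           lesser = c("0.5", "4"),
                                           equal = c("1", "5"),
                                           greater = c("2", "9")))
  expect_equal(as.numeric(apply_continuous(mb, -1)), 0.5)
  expect_equal(as.numeric(apply_continuous(mb, 0)), 1)
  expect_equal(as.numeric(apply_continuous(mb, 10)), 5)
  expect_equal(as.numeric(apply_continuous(mb, 11)), 9)
  expect_equal(as.numeric(apply_continuous(mb, 5)), (2 + 4) / 2)
})

test_that("continuous mapping skips anchor points that carry no values", {
  m <- cx_mapping("CONTINUOUS", "w", "double", "EDGE_WIDTH",
                  points = tibble::tibble(
                    threshold = c(0, 5, 10),
                    lesser = c("1", NA, "5"),
                    equal = c("1", NA, "5"),
                    greater = c("1", NA, "5")))
  # the empty middle point is invisible: straight line from 0 to 10
  expect_equal(as.numeric(apply_continuous(m, 5)), 3)
})

test_that("continuous mapping agrees with a dense-grid oracle", {
  set.seed(42)
  n_checked <- 0
  while (n_checked < 1000) {
    color <- n_checked %% 2 == 0
    m <- random_continuous_mapping(color = color)
    th <- m$points$threshold
    vs <- c(runif(6, min(th) - 2, max(th) + 2), th)
    got <- apply_continuous(m, vs)
    want <- oracle_continuous(m, vs)
    if (color) {
      d <- mapply(channel_distance, got, want)
      expect_true(all(d <= 1))
    } else {
      expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-9)
    }
    n_checked <- n_checked + length(vs)
  }
})

test_that("continuous numeric mapping is monotone between thresholds", {
  set.seed(7)
  for (rep in 1:20) {
    th <- sort(runif(3, -5, 5))
    vals <- as.character(sort(runif(3, 0, 10)))
    m <- cx_mapping("CONTINUOUS", "w", "double", "EDGE_WIDTH",
                    points = tibble::tibble(threshold = th, lesser = vals,
                                            equal = vals, greater = vals))
    grid <- seq(th[1], th[3], length.out = 41)
    out <- as.numeric(apply_continuous(m, grid))
    expect_false(is.unsorted(out))
  }
})

test_that("pass-through forwards values with value-kind coercion", {
  m <- cx_mapping("PASSTHROUGH", "name", "string", "NODE_LABEL")
  expect_equal(apply_passthrough(m, "BRCA1"), "BRCA1")
  expect_true(is.na(apply_passthrough(m, NA)))
  mn <- cx_mapping("PASSTHROUGH", "count", "integer", "NODE_LABEL")
  expect_equal(apply_passthrough(mn, 3), "3")
  ms <- cx_mapping("PASSTHROUGH", "size", "string", "NODE_SIZE")
  expect_equal(apply_passthrough(ms, "17.5"), "17.5")
  expect_true(is.na(apply_passthrough(ms, "not-a-number")))
})

test_that("color interpolation is exact at endpoints and symmetric", {
  expect_equal(interpolate_color("#FFFFFF", "#FF0000", 0.5), "#FF8080")
  expect_equal(interpolate_color("#123456", "#123456", 0.7), "#123456")
  expect_equal(interpolate_color("#000000", "#FFFFFF", 0), "#000000")
  expect_equal(interpolate_color("#000000", "#FFFFFF", 1), "#FFFFFF")
  expect_error(interpolate_color("red", "#000000", 0.5), "hexadecimal")

  set.seed(3)
  for (rep in 1:200) {
    c1 <- sprintf("#%06X", sample(0:16777215, 1))
    c2 <- sprintf("#%06X", sample(0:16777215, 1))
    t <- runif(1)
    a <- interpolate_color(c1, c2, t)
    b <- interpolate_color(c2, c1, 1 - t)
    # rounding half up can differ by one channel unit when the exact value
    # sits on .5 from both directions; symmetric inputs must agree closely
    expect_lte(channel_distance(a, b), 1)
  }
})

test_that("the worked definition strings parse to their stated structures", {
  d <- parse_mapping_definition("DISCRETE",
                                "COL=Bait,T=boolean,K=0=true,V=0=#FF0000")
  expect_equal(d$column, "Bait")
  expect_equal(d$datatype, "boolean")
  expect_equal(d$entries$key, "true")
  expect_equal(d$entries$value, "#FF0000")

  p <- parse_mapping_definition("PASSTHROUGH", "COL=name,T=string")
  expect_equal(p$kind, "PASSTHROUGH")
  expect_equal(p$column, "name")

  c <- parse_mapping_definition("CONTINUOUS", paste0(
    "COL=diff_score,T=double,",
    "L=0=#0000FF,E=0=#0000FF,G=0=#0000FF,OV=0=-1.0,",
    "L=1=#FF0000,E=1=#FF0000,G=1=#FF0000,OV=1=1.0"))
  expect_equal(c$column, "diff_score")
  expect_equal(c$points$threshold, c(-1, 1))
  expect_equal(c$points$lesser, c("#0000FF", "#FF0000"))
})

test_that("definition grammar errors are rejected", {
  expect_error(parse_mapping_definition("DISCRETE", "K=0=a,V=0=b"), "COL and T")
  expect_error(parse_mapping_definition("DISCRETE", "COL=x,T=string,V=0=b"),
               "without matching K")
  expect_error(parse_mapping_definition("CONTINUOUS",
                                        "COL=x,T=double,E=0=1,OV=0=abc"),
               "non-numeric OV")
  expect_error(parse_mapping_definition("CONTINUOUS",
                                        "COL=x,T=double,E=0=1"),
               "lacks OV")
})

test_that("definition strings round-trip as a bijection on a mixed corpus", {
  set.seed(99)
  corpus <- character()
  for (i in 1:20) {  # discrete, with escaped commas in keys and values
    n <- sample(1:4, 1)
    m <- cx_mapping("DISCRETE", paste0("col", i), "string", "NODE_FILL_COLOR",
                    entries = tibble::tibble(
                      key = paste0("k,", seq_len(n), sample(letters, n)),
                      value = sprintf("#%06X", sample(0:16777215, n))))
    corpus <- c(corpus, serialize_mapping_definition(m))
  }
  for (i in 1:20) {  # continuous, some with gaps
    n <- sample(2:4, 1)
    th <- sort(round(runif(n, -5, 5), 2))
    vals <- as.character(round(runif(n, 0, 9), 2))
    pts <- tibble::tibble(threshold = th, lesser = vals, equal = vals,
                          greater = vals)
    if (i %% 2 == 0) pts$lesser[1] <- NA  # gap
    m <- cx_mapping("CONTINUOUS", "score", "double", "EDGE_WIDTH",
                    points = pts)
    corpus <- c(corpus, serialize_mapping_definition(m))
  }
  corpus <- c(corpus, replicate(10, serialize_mapping_definition(
    cx_mapping("PASSTHROUGH", paste0(sample(letters, 5, TRUE), collapse = ""),
               "string", "NODE_LABEL"))))
  expect_gte(length(corpus), 50)

  kinds <- rep(c("DISCRETE", "CONTINUOUS", "PASSTHROUGH"), c(20, 20, 10))
  for (j in seq_along(corpus)) {
    m1 <- parse_mapping_definition(kinds[[j]], corpus[[j]], "X")
    s1 <- serialize_mapping_definition(m1)
    expect_identical(s1, corpus[[j]])
    m2 <- parse_mapping_definition(kinds[[j]], s1, "X")
    expect_equal(m1, m2)
  }
})

test_that("escaped commas survive the definition round trip", {
  m <- cx_mapping("DISCRETE", "c,ol", "string", "NODE_LABEL",
                  entries = tibble::tibble(key = "a,b", value = "x,y"))
  s <- serialize_mapping_definition(m)
  expect_match(s, "a\\,b", fixed = TRUE)
  back <- parse_mapping_definition("DISCRETE", s, "NODE_LABEL")
  expect_equal(back$column, "c,ol")
  expect_equal(back$entries$key, "a,b")
  expect_equal(back$entries$value, "x,y")
})

test_that("continuous points are emitted sorted by threshold", {
  m <- cx_mapping("CONTINUOUS", "s", "double", "EDGE_WIDTH",
                  points = tibble::tibble(threshold = c(5, -5),
                                          lesser = c("9", "1"),
                                          equal = c("9", "1"),
                                          greater = c("9", "1")))
  s <- serialize_mapping_definition(m)
  back <- parse_mapping_definition("CONTINUOUS", s, "EDGE_WIDTH")
  expect_equal(back$points$threshold, c(-5, 5))
})

test_that("mapping validation catches type and threshold problems", {
  bad <- cx_mapping("CONTINUOUS", "name", "string", "EDGE_WIDTH",
                    points = tibble::tibble(threshold = 0, lesser = "1",
                                            equal = "1", greater = "1"))
  v <- validate_mapping(bad)
  expect_true("continuous_on_non_numeric" %in% v$code)
  expect_equal(v$severity[v$code == "continuous_on_non_numeric"], "error")

  dup <- cx_mapping("CONTINUOUS", "s", "double", "EDGE_WIDTH",
                    points = tibble::tibble(threshold = c(0.5, 0.5),
                                            lesser = c("1", "2"),
                                            equal = c("1", "2"),
                                            greater = c("1", "2")))
  expect_true("duplicate_threshold" %in% validate_mapping(dup)$code)
  expect_equal(validate_mapping(dup)$severity[
    validate_mapping(dup)$code == "duplicate_threshold"], "warning")

  ok <- cx_mapping("DISCRETE", "Bait", "boolean", "NODE_SHAPE",
                   entries = tibble::tibble(key = "true", value = "ELLIPSE"))
  expect_equal(nrow(validate_mapping(
    ok, tibble::tibble(name = "Bait", datatype = "boolean"))), 0)

  absent <- validate_mapping(ok, tibble::tibble(name = "Other",
                                                datatype = "string"))
  expect_true("mapping_column_absent" %in% absent$code)

  wrongkind <- cx_mapping("DISCRETE", "Bait", "boolean", "NODE_FILL_COLOR",
                          entries = tibble::tibble(key = "true",
                                                   value = "ELLIPSE"))
  expect_true("visual_value_kind_mismatch" %in% validate_mapping(wrongkind)$code)
})

test_that("element style resolution applies bypass > mapping > default > built-in", {
  net <- styled_model()
  # node 3 has no Bait value: class default fill, built-in shape
  s3 <- resolve_element_style(net$style, "node", 3,
                              list(name = "D"))
  expect_equal(s3$NODE_FILL_COLOR, "#999999")
  expect_equal(s3$NODE_SHAPE, "ELLIPSE")
  expect_equal(s3$NODE_LABEL, "D")
  # node 0 has Bait=true: discrete shape wins over built-in
  s0 <- resolve_element_style(net$style, "node", 0, list(Bait = TRUE, name = "A"))
  expect_equal(s0$NODE_SHAPE, "DIAMOND")
  # bypass beats the mapping
  net$style$bypasses <- tibble::tibble(owner_class = "node", owner = 0,
                                       property = "NODE_SHAPE",
                                       value = "HEXAGON")
  s0b <- resolve_element_style(net$style, "node", 0, list(Bait = TRUE))
  expect_equal(s0b$NODE_SHAPE, "HEXAGON")
  # totality: every renderable node property has exactly one value
  reg <- cxviz:::visual_properties()
  node_props <- reg$name[reg$class == "node"]
  expect_true(all(node_props %in% names(s0b)))
  expect_true(all(!vapply(s0b[node_props], is.null, logical(1))))
})

test_that("replacing a mapping for an occupied slot warns", {
  net <- styled_model()
  m <- cx_mapping("DISCRETE", "Bait", "boolean", "NODE_SHAPE",
                  entries = tibble::tibble(key = "false", value = "TRIANGLE"))
  expect_warning(set_mapping(net, "node", m), "replacing")
})
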