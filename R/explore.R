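#' Summarize one attribute of a network
#'
#' Reports how well an attribute covers its element class and how its
#' values are distributed: coverage (fraction of elements carrying a
#' value), number of distinct values, and for numeric datatypes the value
#' range.
#'
#' @param model A [cx_network()].
#' @param owner_class `"node"`, `"edge"` or `"network"`.
#' @param name Attribute name.
#' @return One-row tibble: `owner_class`, `name`, `datatype`, `coverage`,
#'   `n_values`, `n_distinct`, `min`, `max` (`NA` unless numeric).
#' @export
#' @examples
#' net <- generate_fixture(n_nodes = 8, n_edges = 12, seed = 3)
#' summarize_attribute(net, "edge", "diff_score")
summarize_attribute <- function(model, owner_class, name) {
  owner_class <- match.arg(owner_class, c("node", "edge", "network"))
  present <- model$attributes %>%
    filter(.data$owner_class == !!owner_class, .data$name == !!name)
  if (nrow(present) == 0) {
    abort(sprintf("no %s attribute named '%s'", owner_class, name))
  }
  vals <- attribute_values(model, owner_class, name)
  datatype <- present$datatype[[1]]
  total <- switch(owner_class, node = nrow(model$nodes),
                  edge = nrow(model$edges), network = 1L)
  non_missing <- vals$value %>% discard(~ length(.x) == 1 && is.na(.x))
  numeric_vals <- if (is_numeric_datatype(datatype)) {
    as.numeric(unlist(non_missing))
  } else numeric()
  tibble(
    owner_class = owner_class, name = name, datatype = datatype,
    coverage = if (total == 0) 0 else length(non_missing) / total,
    n_values = length(non_missing),
    n_distinct = length(unique(map_chr(non_missing, cx_value_text))),
    min = if (length(numeric_vals) > 0) min(numeric_vals) else NA_real_,
    max = if (length(numeric_vals) > 0) max(numeric_vals) else NA_real_
  )
}

#' Summarize all attributes of a network
#'
#' @param model A [cx_network()].
#' @param owner_class Optional filter: `"node"`, `"edge"` or `"network"`.
#' @return Tibble with one row per (class, attribute), see
#'   [summarize_attribute()].
#' @export
summarize_attributes <- function(model, owner_class = NULL) {
  keys <- model$attributes %>% distinct(.data$owner_class, .data$name)
  if (!is.null(owner_class)) {
    keys <- keys %>% filter(.data$owner_class %in% !!owner_class)
  }
  if (nrow(keys) == 0) {
    return(tibble(owner_class = character(), name = character(),
                  datatype = character(), coverage = double(),
                  n_values = integer(), n_distinct = integer(),
                  min = double(), max = double()))
  }
  bind_rows(map2(keys$owner_class, keys$name,
                 ~ summarize_attribute(model, .x, .y)))
}

#' Histogram of numeric values
#'
#' Bins non-missing values into `bins` equal-width bins spanning
#' `[min, max]`; bins are half-open `[a, b)` except the last, which is
#' closed so the maximum is counted. A single distinct value yields one
#' bin widened to unit width around it.
#'
#' @param values Numeric vector (NAs dropped).
#' @param bins Number of bins (positive integer).
#' @return A `cx_histogram`: list with `edges` (length `bins + 1`) and
#'   `counts` (length `bins`); [generics::tidy()] returns it as a tibble.
#' @export
#' @examples
#' compute_histogram(c(-1, -0.5, 0, 0.5, 1), bins = 2)
compute_histogram <- function(values, bins) {
  if (!is.numeric(bins) || length(bins) != 1 || bins < 1 || bins != trunc(bins)) {
    abort("bins must be a positive integer")
  }
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no non-missing numeric values to bin")
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    edges <- c(lo - 0.5, lo + 0.5)
    counts <- length(values)
  } else {
    edges <- seq(lo, hi, length.out = bins + 1)
    counts <- graphics::hist(values, breaks = edges, right = FALSE,
                             include.lowest = TRUE, plot = FALSE)$counts
  }
  structure(list(edges = edges, counts = as.integer(counts),
                 n = length(values)),
            class = "cx_histogram")
}

#' @export
print.cx_histogram <- function(x, ...) {
  cat(sprintf("<cx_histogram> %d values in %d bin(s) over [%s, %s]\n",
              x$n, length(x$counts), format(min(x$edges)), format(max(x$edges))))
  invisible(x)
}

#' @export
#' @rdname cxviz-tidiers
tidy.cx_histogram <- function(x, ...) {
  tibble(bin = seq_along(x$counts),
         left = x$edges[-length(x$edges)],
         right = x$edges[-1],
         count = x$counts)
}

#' @export
#' @rdname cxviz-autoplot
autoplot.cx_histogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$left, xmax = .data$right,
                                  ymin = 0, ymax = .data$count)) +
    ggplot2::geom_rect(fill = "grey35", color = "white") +
    ggplot2::labs(x = "value", y = "count") +
    ggplot2::theme_minimal()
}

#' Preview a continuous color mapping as gradient stops
#'
#' Samples the mapping on an evenly spaced grid so the gradient between
#' thresholds can be displayed next to a histogram of the data.
#'
#' @param m A continuous [cx_mapping()] onto a color property.
#' @param n Number of samples.
#' @return Tibble with columns `value` and `color`.
#' @export
gradient_preview <- function(m, n = 64) {
  stopifnot(inherits(m, "cx_mapping"), m$kind == "CONTINUOUS")
  pts <- usable_points(m)
  if (nrow(pts) == 0) abort("mapping has no usable points")
  grid <- seq(min(pts$threshold), max(pts$threshold), length.out = n)
  tibble(value = grid, color = apply_continuous(m, grid))
}

#' Construct a highlight rule
#'
#' A single predicate over one attribute, used to select elements for
#' highlighting. Numeric operators require a numeric attribute;
#' `"between"` is inclusive on both ends; missing values never match.
#'
#' @param owner_class `"node"` or `"edge"`.
#' @param name Attribute name.
#' @param op One of `"=="`, `"!="`, `"<"`, `"<="`, `">"`, `">="`,
#'   `"between"`, `"contains"`.
#' @param value Operand (for `"between"`, the lower bound).
#' @param value2 Upper bound for `"between"`.
#' @return A `cx_highlight_rule`.
#' @export
highlight_rule <- function(owner_class, name, op, value, value2 = NULL) {
  owner_class <- match.arg(owner_class, c("node", "edge"))
  op <- match.arg(op, c("==", "!=", "<", "<=", ">", ">=", "between", "contains"))
  if (op == "between" && is.null(value2)) {
    abort("'between' needs both bounds")
  }
  structure(list(owner_class = owner_class, name = name, op = op,
                 value = value, value2 = value2),
            class = "cx_highlight_rule")
}

#' Select the elements matching a highlight rule
#'
#' @param model A [cx_network()].
#' @param rule A [highlight_rule()].
#' @return Sorted numeric vector of matching element ids; elements without
#'   a value for the attribute never match.
#' @export
#' @examples
#' net <- generate_fixture(n_nodes = 10, n_edges = 15, seed = 2)
#' select_highlighted(net, highlight_rule("edge", "diff_score", ">", 0))
select_highlighted <- function(model, rule) {
  stopifnot(inherits(rule, "cx_highlight_rule"))
  vals <- attribute_values(model, rule$owner_class, rule$name)
  if (nrow(vals) == 0) return(numeric())
  numeric_ops <- c("<", "<=", ">", ">=", "between")
  datatype <- vals$datatype[[1]]
  if (rule$op %in% numeric_ops && !is_numeric_datatype(datatype)) {
    abort(sprintf("operator '%s' needs a numeric attribute ('%s' is %s)",
                  rule$op, rule$name, datatype))
  }
  match_one <- function(v) {
    if (length(v) == 1 && is.na(v)) return(FALSE)
    if (rule$op %in% numeric_ops) {
      x <- as.numeric(v)
      return(switch(rule$op,
        "<" = x < rule$value, "<=" = x <= rule$value,
        ">" = x > rule$value, ">=" = x >= rule$value,
        between = x >= rule$value & x <= rule$value2))
    }
    txt <- cx_value_text(v)
    ref <- cx_value_text(coerce_cx_value(rule$value, datatype)$value)
    switch(rule$op,
      "==" = identical(txt, ref),
      "!=" = !identical(txt, ref),
      contains = grepl(as.character(rule$value), txt, fixed = TRUE))
  }
  hits <- vals$owner[map_lgl(vals$value, match_one)]
  sort(hits)
}
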