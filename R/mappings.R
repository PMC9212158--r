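#' Construct an attribute-to-visual mapping
#'
#' A mapping binds one data column (a node or edge attribute) to one visual
#' property. Three kinds exist, mirroring the Cytoscape/CX model:
#'
#' * `DISCRETE` — an explicit lookup table from attribute values to visual
#'   values; attribute values without an entry fall back to defaults.
#' * `CONTINUOUS` — a piecewise-linear function anchored at thresholds.
#'   Each anchor point carries up to three visual values: `lesser` (used for
#'   attribute values below the first threshold), `equal` (used exactly at
#'   the threshold) and `greater` (used above the last threshold and as the
#'   left endpoint of interpolation toward the next point's `lesser` value).
#'   Only numeric columns are eligible.
#' * `PASSTHROUGH` — the attribute value itself becomes the visual value,
#'   coerced to the property's value kind (typically labels).
#'
#' @param kind `"DISCRETE"`, `"CONTINUOUS"` or `"PASSTHROUGH"`.
#' @param column Attribute name driving the mapping.
#' @param datatype CX datatype of the column (e.g. `"double"`, `"boolean"`).
#' @param visual_property Visual property name, e.g. `"NODE_FILL_COLOR"`.
#' @param entries For discrete mappings: tibble with columns `key`, `value`.
#' @param points For continuous mappings: tibble with columns `threshold`,
#'   `lesser`, `equal`, `greater` (visual values as text, `NA` = gap).
#' @return A `cx_mapping` object.
#' @export
#' @examples
#' m <- cx_mapping("CONTINUOUS", "diff_score", "double", "EDGE_WIDTH",
#'                 points = tibble::tibble(threshold = c(0, 10),
#'                                         lesser = c("1", "5"),
#'                                         equal = c("1", "5"),
#'                                         greater = c("1", "5")))
#' apply_continuous(m, 2.5)
cx_mapping <- function(kind, column, datatype, visual_property,
                       entries = NULL, points = NULL) {
  kind <- match.arg(kind, c("DISCRETE", "CONTINUOUS", "PASSTHROUGH"))
  if (kind == "DISCRETE") {
    entries <- as_tibble(entries %||% tibble(key = character(), value = character()))
    stopifnot(all(c("key", "value") %in% names(entries)))
  }
  if (kind == "CONTINUOUS") {
    points <- as_tibble(points %||% tibble(threshold = double(),
                                           lesser = character(),
                                           equal = character(),
                                           greater = character()))
    for (col in c("lesser", "equal", "greater")) {
      if (!col %in% names(points)) points[[col]] <- rep(NA_character_, nrow(points))
    }
    points <- points[c("threshold", "lesser", "equal", "greater")]
  }
  structure(
    list(kind = kind, column = column, datatype = datatype,
         visual_property = visual_property, entries = entries, points = points),
    class = "cx_mapping"
  )
}

#' @export
print.cx_mapping <- function(x, ...) {
  n <- switch(x$kind, DISCRETE = nrow(x$entries), CONTINUOUS = nrow(x$points), 0L)
  cat(sprintf("<cx_mapping> %s %s <- %s (%s)%s\n", x$kind,
              x$visual_property, x$column, x$datatype,
              if (x$kind != "PASSTHROUGH") sprintf(", %d %s", n,
                if (x$kind == "DISCRETE") "entries" else "points") else ""))
  invisible(x)
}

#' Apply a discrete mapping to one attribute value
#'
#' Performs an exact-match lookup after coercing the value to the mapping's
#' column datatype. Values without an entry yield `NA` so the caller can
#' fall back to default properties.
#'
#' @param m A discrete [cx_mapping()].
#' @param v An attribute value (scalar or vector).
#' @return Character vector of visual values, `NA` where no entry matches.
#' @export
apply_discrete <- function(m, v) {
  stopifnot(inherits(m, "cx_mapping"), m$kind == "DISCRETE")
  keys <- vapply(m$entries$key, function(k) {
    cx_value_text(coerce_cx_value(k, m$datatype)$value)
  }, character(1))
  vapply(v, function(x) {
    key <- cx_value_text(coerce_cx_value(x, m$datatype)$value)
    if (is.na(key)) return(NA_character_)
    i <- match(key, keys)
    if (is.na(i)) NA_character_ else m$entries$value[[i]]
  }, character(1), USE.NAMES = FALSE)
}

#' Interpolate between two hexadecimal colors
#'
#' Each of the red, green and blue channels is interpolated independently
#' (affine in `t`), rounded half up to an integer, and re-encoded as
#' uppercase `#RRGGBB`. `t = 0` returns `c1`, `t = 1` returns `c2`.
#'
#' @param c1,c2 Colors as `#RRGGBB` strings.
#' @param t Interpolation parameter in `[0, 1]` (vectorized).
#' @return Uppercase `#RRGGBB` string(s).
#' @export
#' @examples
#' interpolate_color("#FFFFFF", "#FF0000", 0.5)  # "#FF8080"
interpolate_color <- function(c1, c2, t) {
  if (!all(is_hex_color(c(c1, c2)))) {
    abort("colors must be #RRGGBB hexadecimal strings")
  }
  ch1 <- t(grDevices::col2rgb(c1))
  ch2 <- t(grDevices::col2rgb(c2))
  out <- vapply(t, function(tt) {
    mixed <- floor(ch1 + tt * (ch2 - ch1) + 0.5)
    sprintf("#%02X%02X%02X", mixed[1], mixed[2], mixed[3])
  }, character(1))
  out
}

# Anchor points of a continuous mapping usable for evaluation: points whose
# three values are all gaps are skipped; missing lesser/greater slots fall
# back to the point's equal value.
usable_points <- function(m) {
  pts <- m$points %>% arrange(.data$threshold)
  keep <- !(is.na(pts$lesser) & is.na(pts$equal) & is.na(pts$greater))
  pts <- pts[keep, , drop = FALSE]
  pts$lesser <- ifelse(is.na(pts$lesser), pts$equal, pts$lesser)
  pts$greater <- ifelse(is.na(pts$greater), pts$equal, pts$greater)
  pts$equal <- ifelse(is.na(pts$equal), pts$greater, pts$equal)
  pts
}

continuous_is_color <- function(m) {
  kind <- visual_property_kind(m$visual_property)
  if (!is.na(kind)) return(kind == "color")
  vals <- c(m$points$lesser, m$points$equal, m$points$greater)
  vals <- vals[!is.na(vals)]
  length(vals) > 0 && all(is_hex_color(vals))
}

#' Apply a continuous mapping to numeric attribute values
#'
#' Evaluates the threshold-anchored piecewise-linear function: values below
#' the first threshold take its `lesser` value, values above the last take
#' its `greater` value, values exactly at a threshold take its `equal`
#' value, and values between two thresholds are interpolated linearly
#' between the left point's `greater` and the right point's `lesser` value
#' (componentwise for numbers, per color channel for `#RRGGBB` colors).
#' Anchor points with no values for this property are skipped.
#'
#' @param m A continuous [cx_mapping()].
#' @param v Numeric value(s) of the mapped attribute.
#' @return Character vector of visual values (`NA` for missing input or a
#'   mapping with no usable points).
#' @export
apply_continuous <- function(m, v) {
  stopifnot(inherits(m, "cx_mapping"), m$kind == "CONTINUOUS")
  if (!is.numeric(v)) abort("continuous mappings apply to numeric values only")
  pts <- usable_points(m)
  if (nrow(pts) == 0) return(rep(NA_character_, length(v)))
  color <- continuous_is_color(m)

  one <- function(x) {
    if (is.na(x)) return(NA_character_)
    th <- pts$threshold
    if (x < th[1]) return(pts$lesser[1])
    n <- length(th)
    if (x > th[n]) return(pts$greater[n])
    hit <- which(th == x)
    if (length(hit) > 0) return(pts$equal[hit[1]])
    i <- max(which(th < x))
    t0 <- (x - th[i]) / (th[i + 1] - th[i])
    a <- pts$greater[i]
    b <- pts$lesser[i + 1]
    if (color) {
      interpolate_color(a, b, t0)
    } else {
      json_num(as.numeric(a) + t0 * (as.numeric(b) - as.numeric(a)))
    }
  }
  vapply(v, one, character(1), USE.NAMES = FALSE)
}

#' Apply a pass-through mapping to one attribute value
#'
#' The attribute value itself becomes the visual value, rendered as text
#' for label-like properties or coerced to the property's value kind.
#' Missing or uncoercible values yield `NA` (treated as absent).
#'
#' @param m A pass-through [cx_mapping()].
#' @param v Attribute value(s).
#' @return Character vector of visual values.
#' @export
apply_passthrough <- function(m, v) {
  stopifnot(inherits(m, "cx_mapping"), m$kind == "PASSTHROUGH")
  kind <- visual_property_kind(m$visual_property)
  vapply(v, function(x) {
    txt <- cx_value_text(coerce_cx_value(x, m$datatype)$value)
    if (is.na(txt)) return(NA_character_)
    if (is.na(kind) || kind %in% c("text", "enum", "font")) return(txt)
    if (kind == "numeric") {
      num <- suppressWarnings(as.numeric(txt))
      return(if (is.na(num)) NA_character_ else json_num(num))
    }
    if (kind == "color") {
      return(if (is_hex_color(txt)) toupper(txt) else NA_character_)
    }
    txt
  }, character(1), USE.NAMES = FALSE)
}

#' Apply any mapping kind to attribute values
#'
#' Dispatches to [apply_discrete()], [apply_continuous()] or
#' [apply_passthrough()] by the mapping's kind. Continuous mappings receive
#' values coerced to numeric first.
#'
#' @inheritParams apply_discrete
#' @return Character vector of visual values (`NA` = no result).
#' @export
apply_mapping <- function(m, v) {
  switch(m$kind,
    DISCRETE = apply_discrete(m, v),
    CONTINUOUS = {
      num <- vapply(v, function(x) {
        out <- coerce_cx_value(x, m$datatype)$value
        if (is.numeric(out)) out else NA_real_
      }, numeric(1), USE.NAMES = FALSE)
      apply_continuous(m, num)
    },
    PASSTHROUGH = apply_passthrough(m, v)
  )
}

# ---- mapping definition strings (Cytoscape dialect) -----------------------

split_definition <- function(text) {
  tokens <- strsplit(text, "(?<!\\\\),", perl = TRUE)[[1]]
  gsub("\\,", ",", tokens, fixed = TRUE)
}

escape_definition_value <- function(x) {
  gsub(",", "\\,", x, fixed = TRUE)
}

#' Parse a mapping-definition string
#'
#' Parses the comma-separated `KEY=value` dialect used inside the CX
#' `cyVisualProperties` aspect: `COL` (column) and `T` (datatype) for all
#' kinds; `K=i=key,V=i=value` pairs for discrete mappings; `L=i=`, `E=i=`,
#' `G=i=` (lesser/equal/greater visual values) and `OV=i=` (threshold) for
#' continuous mappings. Literal commas inside values are escaped as `\\,`.
#'
#' @param kind `"DISCRETE"`, `"CONTINUOUS"` or `"PASSTHROUGH"`.
#' @param definition Definition text.
#' @param visual_property Visual property the mapping targets (optional but
#'   needed for value-kind validation and resolution).
#' @return A [cx_mapping()].
#' @export
#' @examples
#' parse_mapping_definition("DISCRETE",
#'   "COL=Bait,T=boolean,K=0=true,V=0=#FF0000", "NODE_FILL_COLOR")
parse_mapping_definition <- function(kind, definition,
                                     visual_property = NA_character_) {
  kind <- match.arg(kind, c("DISCRETE", "CONTINUOUS", "PASSTHROUGH"))
  tokens <- split_definition(definition)
  col <- NULL; datatype <- NULL
  idx <- list(K = list(), V = list(), L = list(), E = list(), G = list(),
              OV = list())
  for (tok in tokens) {
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq < 0) abort(sprintf("malformed definition token: '%s'", tok))
    key <- substr(tok, 1, eq - 1)
    rest <- substr(tok, eq + 1, nchar(tok))
    if (key == "COL") { col <- rest; next }
    if (key == "T") { datatype <- rest; next }
    if (key %in% names(idx)) {
      eq2 <- regexpr("=", rest, fixed = TRUE)
      if (eq2 < 0) abort(sprintf("indexed token '%s' lacks an index", tok))
      i <- suppressWarnings(as.integer(substr(rest, 1, eq2 - 1)))
      if (is.na(i)) abort(sprintf("non-integer index in token '%s'", tok))
      idx[[key]][[as.character(i)]] <- substr(rest, eq2 + 1, nchar(rest))
      next
    }
    # unknown keys are tolerated and dropped (forward compatibility)
  }
  if (is.null(col) || is.null(datatype)) {
    abort("mapping definition must declare COL and T")
  }

  if (kind == "DISCRETE") {
    ks <- sort(as.integer(names(idx$K)))
    vs <- as.integer(names(idx$V))
    if (length(setdiff(vs, ks)) > 0) {
      abort("discrete definition has V entries without matching K")
    }
    entries <- tibble(
      key = vapply(as.character(ks), function(i) idx$K[[i]], character(1),
                   USE.NAMES = FALSE),
      value = vapply(as.character(ks), function(i) idx$V[[i]] %||% NA_character_,
                     character(1), USE.NAMES = FALSE)
    ) %>% filter(!is.na(.data$value))
    return(cx_mapping(kind, col, datatype, visual_property, entries = entries))
  }

  if (kind == "CONTINUOUS") {
    is_ <- sort(unique(as.integer(c(names(idx$L), names(idx$E), names(idx$G),
                                    names(idx$OV)))))
    pts <- purrr::map(as.character(is_), function(i) {
      ov <- idx$OV[[i]]
      if (is.null(ov)) abort(sprintf("continuous point %s lacks OV threshold", i))
      th <- suppressWarnings(as.numeric(ov))
      if (is.na(th)) abort(sprintf("non-numeric OV threshold '%s'", ov))
      tibble(threshold = th,
             lesser = idx$L[[i]] %||% NA_character_,
             equal = idx$E[[i]] %||% NA_character_,
             greater = idx$G[[i]] %||% NA_character_)
    })
    return(cx_mapping(kind, col, datatype, visual_property,
                      points = bind_rows(pts)))
  }

  cx_mapping(kind, col, datatype, visual_property)
}

#' Serialize a mapping to its definition string
#'
#' Inverse of [parse_mapping_definition()]: emits `COL`/`T` first, then the
#' payload with indices contiguous from 0 (continuous points sorted by
#' threshold); commas inside values are escaped as `\\,`.
#'
#' @param m A [cx_mapping()].
#' @return Definition text.
#' @export
serialize_mapping_definition <- function(m) {
  stopifnot(inherits(m, "cx_mapping"))
  head <- sprintf("COL=%s,T=%s", escape_definition_value(m$column),
                  escape_definition_value(m$datatype))
  if (m$kind == "PASSTHROUGH") return(head)
  if (m$kind == "DISCRETE") {
    if (nrow(m$entries) == 0) return(head)
    body <- purrr::map_chr(seq_len(nrow(m$entries)), function(i) {
      sprintf("K=%d=%s,V=%d=%s", i - 1L,
              escape_definition_value(m$entries$key[[i]]),
              i - 1L, escape_definition_value(m$entries$value[[i]]))
    })
    return(paste(c(head, body), collapse = ","))
  }
  pts <- m$points %>% arrange(.data$threshold)
  body <- purrr::map_chr(seq_len(nrow(pts)), function(i) {
    parts <- character()
    for (slot in c("lesser", "equal", "greater")) {
      val <- pts[[slot]][[i]]
      if (!is.na(val)) {
        parts <- c(parts, sprintf("%s=%d=%s",
                                  c(lesser = "L", equal = "E", greater = "G")[[slot]],
                                  i - 1L, escape_definition_value(val)))
      }
    }
    parts <- c(parts, sprintf("OV=%d=%s", i - 1L, json_num(pts$threshold[[i]])))
    paste(parts, collapse = ",")
  })
  paste(c(head, body), collapse = ",")
}

#' Validate a mapping against attribute metadata
#'
#' Returns violations as data: continuous mappings on non-numeric columns
#' and payload values that do not conform to the visual property's value
#' kind are errors; duplicate or unsorted thresholds (which make a rapid
#' color change ambiguous), a column absent from the data, and pass-through
#' mappings onto numeric properties are warnings.
#'
#' @param m A [cx_mapping()].
#' @param attribute_metadata Optional tibble with columns `name` and
#'   `datatype` describing the attributes available for the mapping's
#'   element class (e.g. from [summarize_attributes()]).
#' @return A violations tibble (see [validate_network()]).
#' @export
validate_mapping <- function(m, attribute_metadata = NULL) {
  v <- list(empty_violations())
  if (m$kind == "CONTINUOUS" && !is_numeric_datatype(m$datatype)) {
    v <- c(v, list(violation("continuous_on_non_numeric", "error",
      sprintf("continuous requires numeric column ('%s' is %s)",
              m$column, m$datatype))))
  }
  payload <- switch(m$kind,
    DISCRETE = m$entries$value,
    CONTINUOUS = c(m$points$lesser, m$points$equal, m$points$greater),
    character())
  payload <- payload[!is.na(payload)]
  if (!is.na(m$visual_property) && length(payload) > 0) {
    bad <- payload[!vapply(payload, visual_value_ok,
                           logical(1), property = m$visual_property)]
    if (length(bad) > 0) {
      v <- c(v, list(violation("visual_value_kind_mismatch", "error",
        sprintf("value(s) %s do not fit %s",
                paste(sQuote(unique(bad)), collapse = ", "),
                m$visual_property))))
    }
  }
  if (m$kind == "CONTINUOUS" && nrow(m$points) > 1) {
    th <- m$points$threshold
    if (anyDuplicated(th)) {
      v <- c(v, list(violation("duplicate_threshold", "warning",
        "duplicate threshold: rapid value change at a point is ambiguous")))
    } else if (is.unsorted(th)) {
      v <- c(v, list(violation("unsorted_thresholds", "warning",
        "thresholds not in increasing order; they are sorted on application")))
    }
  }
  if (m$kind == "PASSTHROUGH" && !is.na(m$visual_property) &&
      identical(visual_property_kind(m$visual_property), "numeric")) {
    v <- c(v, list(violation("passthrough_numeric_target", "warning",
      "pass-through onto a numeric property; a continuous mapping is usually more flexible")))
  }
  if (!is.null(attribute_metadata) && !m$column %in% attribute_metadata$name) {
    v <- c(v, list(violation("mapping_column_absent", "warning",
      sprintf("mapped column '%s' not present in the data", m$column))))
  }
  bind_rows(v)
}
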