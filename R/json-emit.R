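# Deterministic JSON emitter for CX output.
#
# jsonlite parses CX with simplifyVector = FALSE, which maps JSON objects to
# named lists, arrays to unnamed lists and scalars to length-1 atomics.  This
# emitter is the exact inverse, so opaque aspects survive a parse/serialize
# cycle with their scalar/array and {}/[] distinctions intact, and output for
# a given model is byte-identical across runs.

json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  # remaining control characters, rare in practice
  bad <- vapply(x, function(s) any(utf8ToInt(s) < 32L), logical(1))
  if (any(bad)) {
    x[bad] <- vapply(x[bad], function(s) {
      cp <- utf8ToInt(s)
      paste(ifelse(cp < 32L, sprintf("\\u%04x", cp), intToUtf8(cp, multiple = TRUE)),
            collapse = "")
    }, character(1))
  }
  x
}

# Shortest decimal representation that round-trips back to the same double
# through the JSON parser itself (jsonlite's number parsing can differ from
# as.numeric by one ulp on borderline 16-digit decimals); integers within
# the 2^53 exact range print without a decimal point so element ids and
# long counters round-trip losslessly.
json_num <- function(x) {
  if (is.na(x)) return("null")
  if (!is.finite(x)) stop("cannot emit non-finite number as JSON", call. = FALSE)
  if (x == trunc(x) && abs(x) < 2^53) return(sprintf("%.0f", x))
  for (d in 15:17) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x && jsonlite::fromJSON(s) == x) return(s)
  }
  s
}

json_scalar <- function(x) {
  if (is.null(x)) return("null")
  if (is.na(x)) return("null")
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(json_num(x))
  paste0("\"", json_escape(as.character(x)), "\"")
}

#' Serialize an R object (as produced by `jsonlite::fromJSON(simplifyVector
#' = FALSE)`) back to JSON text, deterministically.
#' @noRd
json_emit <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      # JSON object (possibly empty): keys kept in stored order
      body <- vapply(seq_along(x), function(i) {
        paste0("\"", json_escape(nm[[i]]), "\":", json_emit(x[[i]]))
      }, character(1))
      return(paste0("{", paste(body, collapse = ","), "}"))
    }
    body <- vapply(x, json_emit, character(1))
    return(paste0("[", paste(body, collapse = ","), "]"))
  }
  if (length(x) == 1L) return(json_scalar(x))
  paste0("[", paste(vapply(x, json_scalar, character(1)), collapse = ","), "]")
}
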