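# CX attribute datatype handling.  Declared datatypes are the CX vocabulary:
# string, boolean, integer, long, double and their list_of_* forms; an
# element without a "d" field defaults to string.

cx_scalar_datatypes <- c("string", "boolean", "integer", "long", "double")

is_numeric_datatype <- function(datatype) {
  datatype %in% c("integer", "long", "double")
}

# Coerce one raw value (as parsed from JSON) to its declared datatype.
# Returns list(value = coerced-or-raw, ok = logical); on mismatch the raw
# text is kept so nothing is silently dropped.
coerce_cx_scalar <- function(raw, datatype) {
  if (is.null(raw) || (length(raw) == 1L && is.na(raw))) {
    return(list(value = NA, ok = TRUE))
  }
  out <- switch(datatype,
    string = as.character(raw),
    boolean = {
      if (is.logical(raw)) raw
      else if (tolower(as.character(raw)) %in% c("true", "false")) {
        tolower(as.character(raw)) == "true"
      } else NULL
    },
    integer = ,
    long = ,
    double = {
      num <- suppressWarnings(as.numeric(raw))
      if (is.na(num)) NULL else num
    },
    as.character(raw)
  )
  if (is.null(out)) list(value = as.character(raw), ok = FALSE)
  else list(value = out, ok = TRUE)
}

coerce_cx_value <- function(raw, datatype) {
  if (is.null(datatype) || is.na(datatype) || !nzchar(datatype)) {
    datatype <- "string"
  }
  if (startsWith(datatype, "list_of_")) {
    inner <- sub("^list_of_", "", datatype)
    raw_list <- if (is.list(raw)) raw else as.list(raw)
    parts <- lapply(raw_list, coerce_cx_scalar, datatype = inner)
    list(value = lapply(parts, `[[`, "value"),
         ok = all(vapply(parts, `[[`, logical(1), "ok")))
  } else {
    coerce_cx_scalar(raw, datatype)
  }
}

# Canonical text form of a coerced value, used for discrete-mapping key
# matching and pass-through labels.
cx_value_text <- function(v) {
  if (is.null(v) || (length(v) == 1L && is.na(v))) return(NA_character_)
  if (is.list(v)) {
    return(paste(vapply(v, cx_value_text, character(1)), collapse = ","))
  }
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(json_num(v))
  as.character(v)
}
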