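#' Construct a visual style
#'
#' A style bundles class-level default properties, attribute-to-visual
#' mappings and per-element bypasses, mirroring the CX `cyVisualProperties`
#' aspect. Resolution precedence, highest first: bypass, mapping, class
#' default, built-in default.
#'
#' @param defaults Named list with elements `network`, `node`, `edge`, each a
#'   named list of visual-property values.
#' @param mappings Named list with elements `node` and `edge`, each a named
#'   list keyed by visual property holding one [cx_mapping()].
#' @param bypasses Tibble with columns `owner_class`, `owner`, `property`,
#'   `value`: per-element overrides.
#' @param dependencies Named list (`network`/`node`/`edge`) of dependency
#'   records, carried through CX opaquely (e.g. node size locking).
#' @return A `cx_style` object.
#' @export
cx_style <- function(defaults = list(network = list(), node = list(), edge = list()),
                     mappings = list(node = list(), edge = list()),
                     bypasses = NULL,
                     dependencies = list(network = NULL, node = NULL, edge = NULL)) {
  bypasses <- as_tibble(bypasses %||% tibble(owner_class = character(),
                                             owner = double(),
                                             property = character(),
                                             value = character()))
  structure(
    list(defaults = defaults, mappings = mappings, bypasses = bypasses,
         dependencies = dependencies),
    class = "cx_style"
  )
}

#' @export
print.cx_style <- function(x, ...) {
  cat(sprintf("<cx_style> %d node mapping(s), %d edge mapping(s), %d bypass value(s)\n",
              length(x$mappings$node), length(x$mappings$edge),
              nrow(x$bypasses)))
  invisible(x)
}

validate_style <- function(style, model = NULL) {
  v <- list(empty_violations())
  for (cls in c("node", "edge")) {
    meta <- NULL
    if (!is.null(model)) {
      core <- if (cls == "node") c("name", "represents") else "interaction"
      meta <- bind_rows(
        model$attributes %>%
          filter(.data$owner_class == cls) %>%
          distinct(.data$name, .data$datatype),
        tibble(name = core, datatype = "string")
      )
    }
    for (m in style$mappings[[cls]]) {
      v <- c(v, list(validate_mapping(m, meta)))
    }
  }
  bind_rows(v)
}

#' Add or replace a mapping in a network's style
#'
#' One mapping is kept per (element class, visual property); adding a second
#' for the same pair replaces the first with a warning.
#'
#' @param model A [cx_network()].
#' @param class `"node"` or `"edge"`.
#' @param mapping A [cx_mapping()]; its `visual_property` keys the slot.
#' @return The modified model.
#' @export
set_mapping <- function(model, class, mapping) {
  class <- match.arg(class, c("node", "edge"))
  stopifnot(inherits(mapping, "cx_mapping"))
  prop <- mapping$visual_property
  if (is.na(prop)) abort("mapping must name a visual property to be attached")
  if (!is.null(model$style$mappings[[class]][[prop]])) {
    warn(sprintf("replacing existing %s mapping on %s", class, prop))
  }
  model$style$mappings[[class]][[prop]] <- mapping
  model
}

#' Remove a mapping from a network's style
#'
#' @inheritParams set_mapping
#' @param property Visual property whose mapping is removed.
#' @return The modified model.
#' @export
remove_mapping <- function(model, class, property) {
  class <- match.arg(class, c("node", "edge"))
  model$style$mappings[[class]][[property]] <- NULL
  model
}

#' List the mappings of a network as a tibble
#'
#' @param model A [cx_network()].
#' @return Tibble with one row per mapping: `owner_class`, `visual_property`,
#'   `kind`, `column`, `datatype`, `definition` (the serialized dialect
#'   string).
#' @export
list_mappings <- function(model) {
  rows <- list()
  for (cls in c("node", "edge")) {
    for (prop in names(model$style$mappings[[cls]])) {
      m <- model$style$mappings[[cls]][[prop]]
      rows <- c(rows, list(tibble(
        owner_class = cls, visual_property = prop, kind = m$kind,
        column = m$column, datatype = m$datatype,
        definition = serialize_mapping_definition(m)
      )))
    }
  }
  bind_rows(c(list(tibble(owner_class = character(), visual_property = character(),
                          kind = character(), column = character(),
                          datatype = character(), definition = character())),
              rows))
}

builtin_defaults <- function(class) {
  reg <- visual_properties() %>% filter(.data$class == !!class)
  stats::setNames(as.list(reg$default), reg$name)
}

#' Resolve the final visual properties of one element
#'
#' Applies the full precedence chain for every renderable visual property of
#' the element's class: a per-element bypass wins over the element's mapping
#' result, which wins over the class default, which wins over the built-in
#' default. The result is total: every renderable property receives exactly
#' one value.
#'
#' @param style A [cx_style()].
#' @param class `"node"` or `"edge"`.
#' @param id Element id (used for bypass lookup).
#' @param attrs Named list of the element's attribute values (coerced), as
#'   assembled by [resolve_styles()].
#' @return Named list, visual property -> value (as text).
#' @export
resolve_element_style <- function(style, class, id, attrs = list()) {
  class <- match.arg(class, c("node", "edge"))
  out <- builtin_defaults(class)
  for (prop in names(style$defaults[[class]])) {
    out[[prop]] <- as.character(style$defaults[[class]][[prop]])
  }
  for (prop in names(style$mappings[[class]])) {
    m <- style$mappings[[class]][[prop]]
    v <- attrs[[m$column]]
    res <- apply_mapping(m, if (is.null(v)) NA else list(v))
    if (!is.na(res)) out[[prop]] <- res
  }
  bp <- style$bypasses %>%
    filter(.data$owner_class == class, .data$owner == id)
  for (i in seq_len(nrow(bp))) {
    out[[bp$property[[i]]]] <- bp$value[[i]]
  }
  out
}
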