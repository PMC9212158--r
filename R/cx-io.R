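CORE_ASPECTS <- c("nodes", "edges", "networkAttributes", "nodeAttributes",
                  "edgeAttributes", "cartesianLayout", "cyVisualProperties")
META_ASPECTS <- c("numberVerification", "metaData", "status")

# 2^48 - 1, the conventional CX numberVerification probe: a long that must
# survive the JSON round trip without precision loss.
NUMBER_VERIFICATION <- 281474976710655

#' Parse a CX document
#'
#' Reads a CX document (a JSON array of single-key aspect fragments) into a
#' `cx_document`: fragments in original order, pre/post metadata and status
#' separated out. Unknown aspects are kept verbatim. Use [to_model()] to
#' lift the core aspects into a typed [cx_network()].
#'
#' @param text CX document text (single string or lines), or a file path via
#'   [read_cx()].
#' @return A `cx_document` object.
#' @export
#' @examples
#' doc <- parse_cx('[{"nodes": [{"@id": 0, "n": "BRCA1"}]}, {"status": [{"error": "", "success": true}]}]')
#' length(doc$fragments)
parse_cx <- function(text) {
  text <- paste(text, collapse = "\n")
  parsed <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) abort(sprintf("CX parse error: %s", conditionMessage(e)))
  )
  if (!is.list(parsed) || !is.null(names(parsed))) {
    abort("CX format error: top level must be a JSON array of aspect fragments")
  }
  fragments <- list()
  pre_meta <- list(); post_meta <- list()
  status <- NULL; numver <- NULL
  seen_data <- FALSE
  for (frag in parsed) {
    if (!is.list(frag) || is.null(names(frag)) || length(frag) < 1L) {
      abort("CX format error: each fragment must be a single-key object")
    }
    name <- names(frag)[[1]]
    elements <- frag[[1]]
    if (name == "numberVerification") {
      numver <- elements[[1]]$longNumber
    } else if (name == "metaData") {
      if (seen_data) post_meta <- c(post_meta, elements)
      else pre_meta <- c(pre_meta, elements)
    } else if (name == "status") {
      st <- elements[[1]]
      status <- list(success = isTRUE(st$success), error = st$error %||% "")
    } else {
      seen_data <- TRUE
      fragments <- c(fragments, list(list(name = name, elements = elements)))
    }
  }
  structure(
    list(fragments = fragments, pre_metadata = pre_meta,
         post_metadata = post_meta, status = status,
         number_verification = numver),
    class = "cx_document"
  )
}

#' @export
print.cx_document <- function(x, ...) {
  cat(sprintf("<cx_document> %d fragment(s): %s\n", length(x$fragments),
              paste(unique(vapply(x$fragments, `[[`, character(1), "name")),
                    collapse = ", ")))
  invisible(x)
}

#' Read a CX file
#'
#' @param path Path to a CX (JSON) file, read as UTF-8.
#' @return A `cx_document` (see [parse_cx()]).
#' @export
read_cx <- function(path) {
  parse_cx(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

# elements of all fragments of one aspect, concatenated in document order
aspect_elements <- function(doc, name) {
  frs <- keep(doc$fragments, ~ .x$name == name)
  do.call(c, c(list(list()), map(frs, "elements")))
}

#' Lift a CX document into a typed network model
#'
#' Extracts the core aspects (`nodes`, `edges`, node/edge/network
#' attributes, `cartesianLayout`, `cyVisualProperties`) into tibbles and a
#' style object; every other aspect is kept opaque. Attribute values are
#' coerced to their declared datatype (`string` when none is declared);
#' values that fail to parse are recorded as violations with the raw text
#' kept.
#'
#' @param doc A `cx_document` from [parse_cx()].
#' @return A [cx_network()].
#' @export
to_model <- function(doc) {
  stopifnot(inherits(doc, "cx_document"))
  aspect_names <- unique(vapply(doc$fragments, `[[`, character(1), "name"))
  viols <- list(empty_violations())

  nodes_el <- aspect_elements(doc, "nodes")
  nodes <- tibble(
    id = map_dbl(nodes_el, ~ as.numeric(.x[["@id"]] %||%
                                          abort("node element lacks @id"))),
    name = map_chr(nodes_el, ~ as.character(.x[["n"]] %||% NA_character_)),
    represents = map_chr(nodes_el, ~ as.character(.x[["r"]] %||% NA_character_))
  )
  if (anyDuplicated(nodes$id)) {
    abort(sprintf("duplicate node id(s): %s",
                  paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")))
  }

  edges_el <- aspect_elements(doc, "edges")
  edges <- tibble(
    id = map_dbl(edges_el, ~ as.numeric(.x[["@id"]] %||%
                                          abort("edge element lacks @id"))),
    source = map_dbl(edges_el, ~ as.numeric(.x[["s"]])),
    target = map_dbl(edges_el, ~ as.numeric(.x[["t"]])),
    interaction = map_chr(edges_el, ~ as.character(.x[["i"]] %||% NA_character_))
  )

  parse_attrs <- function(aspect, owner_class) {
    els <- aspect_elements(doc, aspect)
    if (length(els) == 0) return(empty_attributes())
    rows <- map(els, function(el) {
      d <- as.character(el[["d"]] %||% "string")
      coerced <- coerce_cx_value(el[["v"]], d)
      if (!coerced$ok) {
        viols[[length(viols) + 1L]] <<- violation(
          "attribute_datatype_mismatch", "warning",
          sprintf("%s attribute '%s': value does not parse as %s; raw text kept",
                  owner_class, as.character(el[["n"]]), d),
          el[["po"]] %||% numeric())
      }
      tibble(owner_class = owner_class,
             owner = if (owner_class == "network") NA_real_
                     else as.numeric(el[["po"]]),
             name = as.character(el[["n"]]),
             value = list(coerced$value),
             datatype = d)
    })
    bind_rows(rows)
  }
  attributes <- bind_rows(parse_attrs("nodeAttributes", "node"),
                          parse_attrs("edgeAttributes", "edge"),
                          parse_attrs("networkAttributes", "network"))

  layout_el <- aspect_elements(doc, "cartesianLayout")
  layout <- tibble(
    node = map_dbl(layout_el, ~ as.numeric(.x[["node"]])),
    x = map_dbl(layout_el, ~ as.numeric(.x[["x"]])),
    y = map_dbl(layout_el, ~ as.numeric(.x[["y"]])),
    z = map_dbl(layout_el, ~ as.numeric(.x[["z"]] %||% NA_real_))
  )

  style <- parse_style_aspect(aspect_elements(doc, "cyVisualProperties"))

  opaque <- keep(doc$fragments, ~ !.x$name %in% CORE_ASPECTS)

  model <- cx_network(nodes = nodes, edges = edges, attributes = attributes,
                      layout = layout, style = style, opaque = opaque,
                      aspect_order = aspect_names)
  model$parse_violations <- bind_rows(viols)
  model
}

parse_style_aspect <- function(elements) {
  style <- cx_style()
  bypass_rows <- list()
  for (el in elements) {
    po <- el$properties_of %||% ""
    props <- el$properties %||% list()
    props <- stats::setNames(as.list(vapply(props, as.character, character(1))),
                             names(props))
    cls <- switch(po,
      "network" = "network", "nodes:default" = "node",
      "edges:default" = "edge", "nodes" = "node_bypass",
      "edges" = "edge_bypass", NULL)
    if (is.null(cls)) next
    if (cls %in% c("network", "node", "edge")) {
      style$defaults[[cls]] <- utils::modifyList(style$defaults[[cls]], props)
      if (!is.null(el$dependencies)) style$dependencies[[cls]] <- el$dependencies
      for (prop in names(el$mappings %||% list())) {
        mp <- el$mappings[[prop]]
        style$mappings[[cls]][[prop]] <-
          parse_mapping_definition(toupper(mp$type), mp$definition, prop)
      }
    } else {
      owner_class <- if (cls == "node_bypass") "node" else "edge"
      owner <- as.numeric(el$applies_to)
      if (length(props) > 0) {
        bypass_rows <- c(bypass_rows, list(tibble(
          owner_class = owner_class, owner = owner,
          property = names(props),
          value = unlist(props, use.names = FALSE))))
      }
    }
  }
  style$bypasses <- bind_rows(c(list(style$bypasses), bypass_rows))
  style
}

serialize_style_aspect <- function(style) {
  els <- list()
  emit_entry <- function(properties_of, cls) {
    defaults <- style$defaults[[cls]]
    maps <- if (cls == "network") list() else style$mappings[[cls]]
    deps <- style$dependencies[[cls]]
    if (length(defaults) == 0 && length(maps) == 0 && is.null(deps)) return(NULL)
    el <- list(properties_of = properties_of)
    if (length(defaults) > 0) {
      el$properties <- defaults[order(names(defaults))]
    }
    if (!is.null(deps)) el$dependencies <- deps
    if (length(maps) > 0) {
      el$mappings <- map(maps[order(names(maps))], function(m) {
        list(type = m$kind, definition = serialize_mapping_definition(m))
      })
    }
    el
  }
  for (spec in list(c("network", "network"), c("nodes:default", "node"),
                    c("edges:default", "edge"))) {
    el <- emit_entry(spec[[1]], spec[[2]])
    if (!is.null(el)) els <- c(els, list(el))
  }
  bp <- style$bypasses
  if (nrow(bp) > 0) {
    bp <- bp %>% arrange(.data$owner_class, .data$owner, .data$property)
    for (key in unique(paste(bp$owner_class, bp$owner))) {
      rows <- bp[paste(bp$owner_class, bp$owner) == key, ]
      els <- c(els, list(list(
        properties_of = if (rows$owner_class[[1]] == "node") "nodes" else "edges",
        applies_to = rows$owner[[1]],
        properties = stats::setNames(as.list(rows$value), rows$property)
      )))
    }
  }
  els
}

emit_attr_value <- function(v) {
  if (is.list(v)) return(v)  # list datatype: emitted as JSON array
  v
}

serialize_aspect_elements <- function(model, name) {
  switch(name,
    nodes = map(seq_len(nrow(model$nodes)), function(i) {
      r <- model$nodes[i, ]
      el <- list(`@id` = r$id)
      if (!is.na(r$name)) el$n <- r$name
      if (!is.na(r$represents)) el$r <- r$represents
      el
    }),
    edges = map(seq_len(nrow(model$edges)), function(i) {
      r <- model$edges[i, ]
      el <- list(`@id` = r$id, s = r$source, t = r$target)
      if (!is.na(r$interaction)) el$i <- r$interaction
      el
    }),
    nodeAttributes = ,
    edgeAttributes = ,
    networkAttributes = {
      cls <- switch(name, nodeAttributes = "node", edgeAttributes = "edge",
                    "network")
      att <- model$attributes %>% filter(.data$owner_class == cls)
      map(seq_len(nrow(att)), function(i) {
        el <- list()
        if (cls != "network") el$po <- att$owner[[i]]
        el$n <- att$name[[i]]
        el$v <- emit_attr_value(att$value[[i]])
        if (!identical(att$datatype[[i]], "string")) el$d <- att$datatype[[i]]
        el
      })
    },
    cartesianLayout = map(seq_len(nrow(model$layout)), function(i) {
      r <- model$layout[i, ]
      el <- list(node = r$node, x = r$x, y = r$y)
      if (!is.na(r$z)) el$z <- r$z
      el
    }),
    cyVisualProperties = serialize_style_aspect(model$style),
    {
      frs <- keep(model$opaque, ~ .x$name == name)
      do.call(c, c(list(list()), map(frs, "elements")))
    }
  )
}

#' Serialize a network model to CX text
#'
#' Emits a complete CX document: `numberVerification` first, then
#' pre-metadata covering every emitted aspect with its element count,
#' the aspect fragments (custom aspects verbatim, in their original
#' position), and a success `status`. Output is deterministic: the same
#' model always yields byte-identical text. A model whose
#' [validate_network()] report contains errors is refused (warnings are
#' tolerated).
#'
#' @param model A [cx_network()].
#' @return A single string of CX JSON.
#' @export
serialize_cx <- function(model) {
  stopifnot(inherits(model, "cx_network"))
  viol <- validate_network(model)
  errs <- viol %>% filter(.data$severity == "error")
  if (nrow(errs) > 0) {
    abort(paste0("refusing to serialize a network with validation errors:\n",
                 paste(sprintf("- [%s] %s", errs$code, errs$message),
                       collapse = "\n")))
  }

  order <- model$aspect_order
  opaque_names <- unique(vapply(model$opaque, `[[`, character(1), "name"))
  order <- unique(c(order, CORE_ASPECTS, opaque_names))
  order <- setdiff(order, META_ASPECTS)

  aspects <- list()
  for (name in order) {
    els <- serialize_aspect_elements(model, name)
    if (length(els) > 0) aspects[[name]] <- els
  }

  meta <- map(names(aspects), function(name) {
    md <- list(name = name, elementCount = length(aspects[[name]]))
    if (name %in% c("nodes", "edges")) {
      ids <- if (name == "nodes") model$nodes$id else model$edges$id
      md$idCounter <- if (length(ids) > 0) max(ids) + 1 else 0
    }
    md$version <- "1.0"
    md$consistencyGroup <- 1
    md
  })

  frags <- c(
    list(list(numberVerification = list(list(longNumber = NUMBER_VERIFICATION)))),
    list(list(metaData = meta)),
    map(names(aspects), function(name) stats::setNames(list(aspects[[name]]), name)),
    list(list(status = list(list(error = "", success = TRUE))))
  )
  json_emit(frags)
}

#' Write a network model to a CX file
#'
#' @param model A [cx_network()].
#' @param path Output file path (UTF-8).
#' @return `path`, invisibly.
#' @export
write_cx <- function(model, path) {
  writeLines(serialize_cx(model), path, useBytes = TRUE)
  invisible(path)
}

canonical_attributes <- function(att) {
  att %>%
    mutate(value_txt = map_chr(.data$value, cx_value_text),
           owner_key = ifelse(is.na(.data$owner), -1, .data$owner)) %>%
    # last declaration wins, matching resolution behavior
    group_by(.data$owner_class, .data$owner_key, .data$name) %>%
    slice(n()) %>%
    ungroup() %>%
    arrange(.data$owner_class, .data$owner_key, .data$name) %>%
    select("owner_class", "owner_key", "name", "value_txt", "datatype")
}

canonical_mappings <- function(style) {
  for (cls in c("node", "edge")) {
    ms <- style$mappings[[cls]]
    style$mappings[[cls]] <- map(ms[order(names(ms))], function(m) {
      if (m$kind == "CONTINUOUS") m$points <- m$points %>% arrange(.data$threshold)
      m
    })
  }
  style$bypasses <- style$bypasses %>%
    arrange(.data$owner_class, .data$owner, .data$property)
  for (cls in c("network", "node", "edge")) {
    d <- style$defaults[[cls]]
    style$defaults[[cls]] <- d[order(names(d))]
  }
  style
}

#' Test two network models for semantic equality
#'
#' Aspect-wise comparison after canonicalization: nodes, edges and layout
#' sorted by id, attributes deduplicated (last wins) and compared by
#' canonical value text, style compared with sorted mappings/defaults/
#' bypasses, and opaque custom aspects compared element-for-element. The
#' fragment order itself is not part of the comparison.
#'
#' @param a,b [cx_network()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
cx_equivalent <- function(a, b) {
  sort_by_id <- function(x, col) x %>% arrange(.data[[col]])
  if (!isTRUE(all.equal(sort_by_id(a$nodes, "id"), sort_by_id(b$nodes, "id")))) {
    return(FALSE)
  }
  if (!isTRUE(all.equal(sort_by_id(a$edges, "id"), sort_by_id(b$edges, "id")))) {
    return(FALSE)
  }
  if (!isTRUE(all.equal(canonical_attributes(a$attributes),
                        canonical_attributes(b$attributes)))) {
    return(FALSE)
  }
  if (!isTRUE(all.equal(sort_by_id(a$layout, "node"),
                        sort_by_id(b$layout, "node")))) {
    return(FALSE)
  }
  sa <- canonical_mappings(a$style); sb <- canonical_mappings(b$style)
  if (!isTRUE(all.equal(sa$defaults, sb$defaults)) ||
      !isTRUE(all.equal(sa$mappings, sb$mappings, check.attributes = FALSE)) ||
      !isTRUE(all.equal(sa$bypasses, sb$bypasses))) {
    return(FALSE)
  }
  collect_opaque <- function(m) {
    nms <- sort(unique(vapply(m$opaque, `[[`, character(1), "name")))
    stats::setNames(map(nms, function(nm) {
      do.call(c, c(list(list()), map(keep(m$opaque, ~ .x$name == nm), "elements")))
    }), nms)
  }
  identical(collect_opaque(a), collect_opaque(b))
}
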