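#' Rendering options
#'
#' @param scale Raster multiplier (> 0): pixel dimensions are the scene
#'   bounds times `scale`, so larger factors produce more detailed images.
#' @param clip `NULL` for the full network extent, or a [cx_viewport()] to
#'   capture only the viewport region.
#' @param max_dimensions Optional `c(width, height)` cap; the scene is
#'   rescaled uniformly (aspect-preserving) to fit.
#' @param background `NULL` to use the network's background property, a
#'   `#RRGGBB` color, or `"transparent"` (honored by PNG only; JPEG is
#'   composited onto white with a warning).
#' @param hide_labels Suppress all label text.
#' @param margin Margin around the node extents, canvas units.
#' @return A `cx_render_options` object.
#' @export
render_options <- function(scale = 1, clip = NULL, max_dimensions = NULL,
                           background = NULL, hide_labels = FALSE,
                           margin = 10) {
  if (scale <= 0) abort("scale must be positive")
  if (!is.null(clip)) stopifnot(inherits(clip, "cx_viewport"))
  if (!is.null(max_dimensions)) {
    stopifnot(length(max_dimensions) == 2, all(max_dimensions > 0))
  }
  if (!is.null(background) && !identical(background, "transparent") &&
      !is_hex_color(background)) {
    abort("background must be #RRGGBB or 'transparent'")
  }
  structure(list(scale = scale, clip = clip, max_dimensions = max_dimensions,
                 background = background, hide_labels = hide_labels,
                 margin = margin),
            class = "cx_render_options")
}

#' Resolve the final visual style of every element
#'
#' Applies [resolve_element_style()] to every node and edge: bypasses win
#' over mapping results, which win over class defaults, which win over
#' built-in defaults. One attribute may drive several visual properties at
#' once (each through its own mapping).
#'
#' @param model A [cx_network()].
#' @return A `cx_resolved_style`: list with `nodes` and `edges` tibbles (one
#'   column per renderable visual property, values as text) and `network`, a
#'   named list of network-level properties.
#' @export
resolve_styles <- function(model) {
  attrs_by_owner <- function(cls) {
    att <- model$attributes %>%
      filter(.data$owner_class == cls) %>%
      group_by(.data$owner, .data$name) %>%
      slice(n()) %>%
      ungroup()
    by_owner <- split(stats::setNames(att$value, att$name), att$owner)
    # core element fields are visible to mappings like declared attributes
    core <- if (cls == "node") {
      model$nodes %>% select("id", "name", "represents")
    } else {
      model$edges %>% select("id", "interaction")
    }
    for (i in seq_len(nrow(core))) {
      key <- as.character(core$id[[i]])
      for (fld in setdiff(names(core), "id")) {
        v <- core[[fld]][[i]]
        if (!is.na(v) && is.null(by_owner[[key]][[fld]])) {
          by_owner[[key]][[fld]] <- v
        }
      }
    }
    by_owner
  }
  resolve_class <- function(cls, ids) {
    owner_attrs <- attrs_by_owner(cls)
    props <- visual_properties() %>% filter(.data$class == cls)
    rows <- map(ids, function(i) {
      attrs <- owner_attrs[[as.character(i)]] %||% list()
      vals <- resolve_element_style(model$style, cls, i, attrs)
      as_tibble(c(list(id = i), vals[props$name]))
    })
    bind_rows(c(list(as_tibble(stats::setNames(
      c(list(double()), map(props$name, ~ character())),
      c("id", props$name)))), rows))
  }
  network <- builtin_defaults("network")
  for (prop in names(model$style$defaults$network)) {
    network[[prop]] <- as.character(model$style$defaults$network[[prop]])
  }
  structure(
    list(nodes = resolve_class("node", model$nodes$id),
         edges = resolve_class("edge", model$edges$id),
         network = network),
    class = "cx_resolved_style"
  )
}

#' @export
print.cx_resolved_style <- function(x, ...) {
  cat(sprintf("<cx_resolved_style> %d node(s) x %d properties, %d edge(s) x %d properties\n",
              nrow(x$nodes), ncol(x$nodes) - 1L,
              nrow(x$edges), ncol(x$edges) - 1L))
  invisible(x)
}

#' @export
#' @rdname cxviz-tidiers
tidy.cx_resolved_style <- function(x, ...) {
  bind_rows(
    x$nodes %>% mutate(owner_class = "node"),
    x$edges %>% mutate(owner_class = "edge")
  ) %>%
    tidyr::pivot_longer(cols = -c("id", "owner_class"),
                        names_to = "property", values_to = "value") %>%
    filter(!is.na(.data$value)) %>%
    select("owner_class", "id", "property", "value")
}

# Effective node width/height: explicit NODE_WIDTH/HEIGHT wins, otherwise
# NODE_SIZE (locked square dimensions, matching common size-lock behavior).
node_dims <- function(resolved_nodes) {
  def_w <- builtin_defaults("node")[["NODE_WIDTH"]]
  size <- as.numeric(resolved_nodes$NODE_SIZE)
  w <- as.numeric(resolved_nodes$NODE_WIDTH)
  h <- as.numeric(resolved_nodes$NODE_HEIGHT)
  tibble(
    width = ifelse(resolved_nodes$NODE_WIDTH != def_w, w, size),
    height = ifelse(resolved_nodes$NODE_HEIGHT != def_w, h, size)
  )
}

#' Compute the scene bounding box
#'
#' A tight box over all node extents (position plus half the node size)
#' plus the option margin. With a viewport clip the box is intersected with
#' the viewport; a `max_dimensions` cap yields a uniform fit scale.
#'
#' @param model A [cx_network()] with a layout covering all nodes.
#' @param resolved A `cx_resolved_style` from [resolve_styles()].
#' @param options A [render_options()].
#' @return List `x`, `y`, `w`, `h` (canvas units) and `fit_scale`.
#' @export
compute_bounds <- function(model, resolved = resolve_styles(model),
                           options = render_options()) {
  if (nrow(model$nodes) > 0 &&
      length(setdiff(model$nodes$id, model$layout$node)) > 0) {
    abort("nodes without coordinates; run a layout algorithm first")
  }
  if (nrow(model$nodes) == 0) {
    box <- list(x = 0, y = 0, w = 1, h = 1)
  } else {
    lay <- model$layout %>% arrange(.data$node)
    res <- resolved$nodes %>% arrange(.data$id)
    dims <- node_dims(res)
    m <- options$margin
    box <- list(
      x = min(lay$x - dims$width / 2) - m,
      y = min(lay$y - dims$height / 2) - m,
      w = NA, h = NA
    )
    box$w <- max(lay$x + dims$width / 2) + m - box$x
    box$h <- max(lay$y + dims$height / 2) + m - box$y
  }
  if (!is.null(options$clip)) {
    x2 <- min(box$x + box$w, options$clip$width)
    y2 <- min(box$y + box$h, options$clip$height)
    box$x <- max(box$x, 0); box$y <- max(box$y, 0)
    box$w <- max(x2 - box$x, 1)
    box$h <- max(y2 - box$y, 1)
  }
  fit <- 1
  if (!is.null(options$max_dimensions)) {
    fit <- min(options$max_dimensions[[1]] / box$w,
               options$max_dimensions[[2]] / box$h, 1)
  }
  c(box, list(fit_scale = fit))
}

svg_num <- function(x) vapply(round(x, 6), json_num, character(1))

shape_svg <- function(shape, cx, cy, rx, ry, fill, stroke, stroke_width) {
  sty <- sprintf(' fill="%s" stroke="%s" stroke-width="%s"',
                 fill, stroke, svg_num(stroke_width))
  poly <- function(angles_deg) {
    a <- angles_deg * pi / 180
    pts <- paste(sprintf("%s,%s", svg_num(cx + rx * cos(a)),
                         svg_num(cy + ry * sin(a))), collapse = " ")
    sprintf('<polygon points="%s"%s/>', pts, sty)
  }
  switch(shape,
    ELLIPSE = sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s"%s/>',
                      svg_num(cx), svg_num(cy), svg_num(rx), svg_num(ry), sty),
    RECTANGLE = sprintf('<rect x="%s" y="%s" width="%s" height="%s"%s/>',
                        svg_num(cx - rx), svg_num(cy - ry),
                        svg_num(2 * rx), svg_num(2 * ry), sty),
    ROUND_RECTANGLE = sprintf('<rect x="%s" y="%s" width="%s" height="%s" rx="%s"%s/>',
                              svg_num(cx - rx), svg_num(cy - ry),
                              svg_num(2 * rx), svg_num(2 * ry),
                              svg_num(min(rx, ry) / 4), sty),
    TRIANGLE = poly(c(-90, 30, 150)),
    DIAMOND = poly(c(-90, 0, 90, 180)),
    HEXAGON = poly(seq(0, 300, by = 60)),
    OCTAGON = poly(seq(-67.5, 247.5, by = 45)),
    {
      warn(sprintf("unknown node shape '%s'; falling back to ellipse", shape))
      sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s"%s/>',
              svg_num(cx), svg_num(cy), svg_num(rx), svg_num(ry), sty)
    }
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a network to SVG text
#'
#' Draws the styled network as a deterministic SVG document: a background
#' rectangle (unless transparent), then all edges, then all nodes in id
#' order (so nodes sit on top), then labels. The seven node shapes
#' (ellipse, rectangle, round-rectangle, triangle, diamond, hexagon,
#' octagon) are honored; an unknown shape falls back to an ellipse with a
#' warning.
#'
#' @param model A [cx_network()] with a full layout.
#' @param resolved A `cx_resolved_style`; computed from the model if `NULL`.
#' @param options A [render_options()].
#' @return SVG document text (single string).
#' @export
render_svg <- function(model, resolved = NULL, options = render_options()) {
  resolved <- resolved %||% resolve_styles(model)
  b <- compute_bounds(model, resolved, options)
  bg <- options$background %||% resolved$network[["NETWORK_BACKGROUND_PAINT"]]
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="%s %s %s %s">',
            svg_num(b$w * b$fit_scale), svg_num(b$h * b$fit_scale),
            svg_num(b$x), svg_num(b$y), svg_num(b$w), svg_num(b$h))
  )
  if (!identical(bg, "transparent")) {
    out <- c(out, sprintf('<rect class="background" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                          svg_num(b$x), svg_num(b$y), svg_num(b$w), svg_num(b$h), bg))
  }

  lay <- model$layout
  coord <- function(ids, col) {
    lay[[col]][match(ids, lay$node)]
  }

  out <- c(out, '<g class="edges">')
  er <- resolved$edges %>% arrange(.data$id)
  edges <- model$edges %>% arrange(.data$id)
  for (i in seq_len(nrow(edges))) {
    ri <- match(edges$id[[i]], er$id)
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
                          svg_num(coord(edges$source[[i]], "x")),
                          svg_num(coord(edges$source[[i]], "y")),
                          svg_num(coord(edges$target[[i]], "x")),
                          svg_num(coord(edges$target[[i]], "y")),
                          er$EDGE_STROKE_UNSELECTED_PAINT[[ri]],
                          svg_num(as.numeric(er$EDGE_WIDTH[[ri]]))))
  }
  out <- c(out, '</g>', '<g class="nodes">')
  nr <- resolved$nodes %>% arrange(.data$id)
  dims <- node_dims(nr)
  for (i in seq_len(nrow(nr))) {
    id <- nr$id[[i]]
    out <- c(out, shape_svg(nr$NODE_SHAPE[[i]],
                            coord(id, "x"), coord(id, "y"),
                            dims$width[[i]] / 2, dims$height[[i]] / 2,
                            nr$NODE_FILL_COLOR[[i]], nr$NODE_BORDER_PAINT[[i]],
                            as.numeric(nr$NODE_BORDER_WIDTH[[i]])))
  }
  out <- c(out, '</g>')

  if (!options$hide_labels) {
    labels <- character()
    for (i in seq_len(nrow(nr))) {
      lab <- nr$NODE_LABEL[[i]]
      if (!is.na(lab) && nzchar(lab)) {
        id <- nr$id[[i]]
        labels <- c(labels, sprintf(
          '<text x="%s" y="%s" fill="%s" font-size="%s" text-anchor="middle">%s</text>',
          svg_num(coord(id, "x")), svg_num(coord(id, "y")),
          nr$NODE_LABEL_COLOR[[i]],
          svg_num(as.numeric(nr$NODE_LABEL_FONT_SIZE[[i]])),
          xml_escape(lab)))
      }
    }
    for (i in seq_len(nrow(edges))) {
      ri <- match(edges$id[[i]], er$id)
      lab <- er$EDGE_LABEL[[ri]]
      if (!is.na(lab) && nzchar(lab)) {
        labels <- c(labels, sprintf(
          '<text x="%s" y="%s" fill="%s" font-size="%s" text-anchor="middle">%s</text>',
          svg_num((coord(edges$source[[i]], "x") + coord(edges$target[[i]], "x")) / 2),
          svg_num((coord(edges$source[[i]], "y") + coord(edges$target[[i]], "y")) / 2),
          er$EDGE_LABEL_COLOR[[ri]],
          svg_num(as.numeric(er$EDGE_LABEL_FONT_SIZE[[ri]])),
          xml_escape(lab)))
      }
    }
    if (length(labels) > 0) {
      out <- c(out, '<g class="labels">', labels, '</g>')
    }
  }
  paste(c(out, '</svg>'), collapse = "\n")
}

parse_svg_points <- function(points) {
  pairs <- strsplit(strsplit(points, " ", fixed = TRUE)[[1]], ",", fixed = TRUE)
  list(x = vapply(pairs, function(p) as.numeric(p[[1]]), numeric(1)),
       y = vapply(pairs, function(p) as.numeric(p[[2]]), numeric(1)))
}

#' Rasterize an SVG scene to PNG or JPEG bytes
#'
#' Replays the SVG subset emitted by [render_svg()] onto an R raster
#' device. Pixel dimensions are the SVG dimensions times the option scale.
#' PNG supports an alpha channel when the background is transparent; JPEG
#' cannot carry transparency, so a transparent background request is
#' composited onto white with a warning.
#'
#' @param svg_text SVG document text from [render_svg()].
#' @param format `"png"` or `"jpeg"`.
#' @param options A [render_options()] (its `scale` and `background` are
#'   honored here).
#' @param path Optional output file; otherwise a temporary file is used.
#' @return Raw vector of encoded image bytes, invisibly `path`-attributed;
#'   the pixel dimensions are `round(svg width * scale)` by
#'   `round(svg height * scale)`.
#' @export
render_raster <- function(svg_text, format = c("png", "jpeg"),
                          options = render_options(), path = NULL) {
  format <- match.arg(format)
  doc <- xml2::read_xml(svg_text)
  vb <- as.numeric(strsplit(xml2::xml_attr(doc, "viewBox"), " ")[[1]])
  w_svg <- as.numeric(xml2::xml_attr(doc, "width"))
  h_svg <- as.numeric(xml2::xml_attr(doc, "height"))
  wpx <- max(1L, round(w_svg * options$scale))
  hpx <- max(1L, round(h_svg * options$scale))

  transparent <- identical(options$background, "transparent")
  if (transparent && format == "jpeg") {
    warn("JPEG cannot be transparent; compositing onto a white background")
  }
  bg <- if (transparent) {
    if (format == "png") "transparent" else "#FFFFFF"
  } else "transparent"  # non-transparent scenes carry their own background rect

  out_path <- path %||% tempfile(fileext = paste0(".", format))
  if (format == "png") {
    grDevices::png(out_path, width = wpx, height = hpx, bg = bg, type = "cairo")
  } else {
    grDevices::jpeg(out_path, width = wpx, height = hpx,
                    bg = if (identical(bg, "transparent")) "white" else bg,
                    quality = 90, type = "cairo")
  }
  on.exit(if (!is.null(grDevices::dev.list())) grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(vb[1], vb[1] + vb[3]),
                        ylim = c(vb[2] + vb[4], vb[2]))

  px_per_unit <- wpx / vb[3]
  draw <- function(el) {
    tag <- xml2::xml_name(el)
    at <- function(a) xml2::xml_attr(el, a)
    num <- function(a) as.numeric(at(a))
    if (tag == "rect") {
      graphics::rect(num("x"), num("y") + (num("height")),
                     num("x") + num("width"), num("y"),
                     col = at("fill") %||% NA,
                     border = if (is.na(at("stroke"))) NA else at("stroke"))
    } else if (tag == "line") {
      graphics::segments(num("x1"), num("y1"), num("x2"), num("y2"),
                         col = at("stroke"),
                         lwd = max(num("stroke-width") * px_per_unit, 0.1))
    } else if (tag == "ellipse") {
      a <- seq(0, 2 * pi, length.out = 65)
      sw <- at("stroke-width"); if (is.na(sw)) sw <- "1"
      graphics::polygon(num("cx") + num("rx") * cos(a),
                        num("cy") + num("ry") * sin(a),
                        col = at("fill"), border = at("stroke"),
                        lwd = max(as.numeric(sw) * px_per_unit, 0.1))
    } else if (tag == "polygon") {
      pts <- parse_svg_points(at("points"))
      sw <- at("stroke-width"); if (is.na(sw)) sw <- "1"
      graphics::polygon(pts$x, pts$y, col = at("fill"), border = at("stroke"),
                        lwd = max(as.numeric(sw) * px_per_unit, 0.1))
    } else if (tag == "text") {
      fs <- at("font-size"); if (is.na(fs)) fs <- "12"
      graphics::text(num("x"), num("y"), xml2::xml_text(el),
                     col = at("fill"),
                     cex = as.numeric(fs) * px_per_unit / 12)
    } else if (tag == "g") {
      purrr::walk(xml2::xml_children(el), draw)
    }
  }
  purrr::walk(xml2::xml_children(doc), draw)
  grDevices::dev.off()

  bytes <- readBin(out_path, "raw", n = file.info(out_path)$size)
  if (is.null(path)) unlink(out_path)
  invisible(bytes)
}

#' Render a network straight to a file
#'
#' Convenience wrapper: resolves styles, renders the SVG scene and, for
#' raster formats, rasterizes it.
#'
#' @param model A [cx_network()] with a full layout.
#' @param path Output file.
#' @param format `"svg"`, `"png"` or `"jpeg"`; default from the file
#'   extension.
#' @param options A [render_options()].
#' @return `path`, invisibly.
#' @export
render_network <- function(model, path,
                           format = tolower(tools::file_ext(path)),
                           options = render_options()) {
  if (format == "jpg") format <- "jpeg"
  format <- match.arg(format, c("svg", "png", "jpeg"))
  svg <- render_svg(model, options = options)
  if (format == "svg") {
    writeLines(svg, path, useBytes = TRUE)
  } else {
    render_raster(svg, format, options, path = path)
  }
  invisible(path)
}
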