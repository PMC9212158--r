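# Registry of the visual properties the renderer understands.  Unknown
# properties still flow through styles and CX untouched; they are simply not
# drawn.  value kinds: numeric, color (#RRGGBB), enum (fixed vocabulary,
# e.g. node shapes), text (labels), font ("family,style,size" triple).

visual_properties <- function() {
  tibble::tribble(
    ~name,                          ~class,    ~kind,     ~default,
    "NODE_FILL_COLOR",              "node",    "color",   "#FFFFFF",
    "NODE_SIZE",                    "node",    "numeric", "35",
    "NODE_WIDTH",                   "node",    "numeric", "35",
    "NODE_HEIGHT",                  "node",    "numeric", "35",
    "NODE_SHAPE",                   "node",    "enum",    "ELLIPSE",
    "NODE_BORDER_PAINT",            "node",    "color",   "#333333",
    "NODE_BORDER_WIDTH",            "node",    "numeric", "1",
    "NODE_LABEL",                   "node",    "text",    "",
    "NODE_LABEL_COLOR",             "node",    "color",   "#000000",
    "NODE_LABEL_FONT_SIZE",         "node",    "numeric", "12",
    "NODE_LABEL_FONT_FACE",         "node",    "font",    "Dialog,plain,12",
    "EDGE_WIDTH",                   "edge",    "numeric", "2",
    "EDGE_STROKE_UNSELECTED_PAINT", "edge",    "color",   "#848484",
    "EDGE_LABEL",                   "edge",    "text",    "",
    "EDGE_LABEL_COLOR",             "edge",    "color",   "#000000",
    "EDGE_LABEL_FONT_SIZE",         "edge",    "numeric", "10",
    "NETWORK_BACKGROUND_PAINT",     "network", "color",   "#FFFFFF"
  )
}

node_shapes <- function() {
  c("ELLIPSE", "RECTANGLE", "ROUND_RECTANGLE", "TRIANGLE", "DIAMOND",
    "HEXAGON", "OCTAGON")
}

visual_property_kind <- function(property) {
  reg <- visual_properties()
  i <- match(property, reg$name)
  ifelse(is.na(i), NA_character_, reg$kind[i])
}

is_hex_color <- function(x) {
  grepl("^#[0-9A-Fa-f]{6}$", x)
}

# Validate a visual value against a property's kind; returns TRUE for
# properties outside the registry (carried, not drawn).
visual_value_ok <- function(property, value) {
  kind <- visual_property_kind(property)
  if (is.na(kind)) return(TRUE)
  switch(kind,
    numeric = !is.na(suppressWarnings(as.numeric(value))),
    color   = is_hex_color(value),
    enum    = TRUE,   # unknown shapes fall back at render time, not here
    text    = TRUE,
    font    = TRUE
  )
}
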