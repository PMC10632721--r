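#' The six fruit and vegetable food groups
#'
#' The fruit-and-vegetable component of the Global Dietary Recommendation
#' (GDR) score counts consumption of six mutually exclusive food groups:
#' vitamin A-rich vegetables, dark green leafy vegetables, other vegetables,
#' vitamin A-rich fruits, citrus, and other fruits. All tables in this
#' package use the codes returned here, in this fixed order, as column
#' names and group identifiers.
#'
#' @return `fv_groups()`: character vector of the six group codes in
#'   canonical order. `fv_group_labels()`: named character vector mapping
#'   each code to its display label.
#' @examples
#' fv_groups()
#' fv_group_labels()[["dglv"]]
#' @export
fv_groups <- function() {
  c("va_veg", "dglv", "other_veg", "va_fruit", "citrus", "other_fruit")
}

#' @rdname fv_groups
#' @export
fv_group_labels <- function() {
  c(
    va_veg      = "Vitamin A-rich vegetables",
    dglv        = "Dark green leafy vegetables",
    other_veg   = "Other vegetables",
    va_fruit    = "Vitamin A-rich fruits",
    citrus      = "Citrus",
    other_fruit = "Other fruits"
  )
}

# Canonicalise group codes case-insensitively; unknown codes map to NA.
canonical_group <- function(x) {
  codes <- fv_groups()
  codes[match(tolower(trimws(as.character(x))), codes)]
}

# Stop unless `g` is a single valid group code; returns the canonical code.
check_group <- function(g) {
  cg <- canonical_group(g)
  if (length(cg) != 1L || is.na(cg)) {
    abort(sprintf(
      "`group` must be one of %s, not \"%s\".",
      paste0("\"", fv_groups(), "\"", collapse = ", "), as.character(g)[1]
    ))
  }
  cg
}
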