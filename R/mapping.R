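# Item names are matched exactly after case-folding and whitespace
# normalisation (trim + collapse internal runs); no fuzzy matching.
normalize_item <- function(x) {
  gsub("\\s+", " ", tolower(trimws(as.character(x))))
}

#' Build a food-item to food-group mapping
#'
#' A mapping assigns each fruit or vegetable food item to exactly one of the
#' six food groups (see [fv_groups()]) and flags whether the item is a
#' *sentinel* item, i.e. one of the commonly consumed, country-specific
#' foods listed under the corresponding questionnaire question. Items absent
#' from the mapping are treated as non-fruit/vegetable foods (e.g. rice) and
#' are excluded from all fruit-and-vegetable computations.
#'
#' Item names are normalised (case-folded, whitespace collapsed) before
#' storage and lookup. Rows that are duplicates after normalisation are
#' collapsed; duplicates that disagree on group or sentinel status are an
#' error.
#'
#' @param item Character vector of food-item names.
#' @param group Character vector of group codes (case-insensitive; must be
#'   among [fv_groups()]).
#' @param sentinel Logical (or 0/1) vector flagging sentinel items.
#' @param country_tag Optional free-text tag describing the food list's
#'   provenance (e.g. a country).
#' @return A tibble of class `fv_mapping` with columns `item` (normalised),
#'   `group`, `sentinel`, and a `country_tag` attribute.
#' @seealso [load_mapping()] to read a mapping from CSV, [classify_item()]
#'   for lookups.
#' @examples
#' m <- fv_mapping(
#'   item = c("carrot", "spinach", "mushroom"),
#'   group = c("va_veg", "dglv", "other_veg"),
#'   sentinel = c(TRUE, TRUE, FALSE)
#' )
#' classify_item(c("Carrot", "rice"), m)
#' @export
fv_mapping <- function(item, group, sentinel, country_tag = NA_character_) {
  if (length(item) != length(group) || length(item) != length(sentinel)) {
    abort("`item`, `group` and `sentinel` must have equal length.")
  }
  if (is.numeric(sentinel)) {
    if (!all(sentinel %in% c(0, 1))) {
      abort("`sentinel` must contain only 0/1 (or logical) values.")
    }
    sentinel <- sentinel == 1
  }
  sentinel <- as.logical(sentinel)
  if (anyNA(sentinel)) abort("`sentinel` must not contain missing values.")

  grp <- canonical_group(group)
  if (anyNA(grp)) {
    bad <- which(is.na(grp))[1]
    abort(sprintf(
      "Unknown food group code \"%s\" (row %d, item \"%s\"). Valid codes: %s.",
      as.character(group)[bad], bad, as.character(item)[bad],
      paste(fv_groups(), collapse = ", ")
    ))
  }

  m <- tibble(
    item = normalize_item(item),
    group = grp,
    sentinel = sentinel
  )
  m <- distinct(m)
  dup <- m$item[duplicated(m$item)]
  if (length(dup) > 0) {
    abort(sprintf(
      "Item \"%s\" is mapped more than once with conflicting group or sentinel status.",
      dup[1]
    ))
  }
  attr(m, "country_tag") <- country_tag
  class(m) <- c("fv_mapping", class(m))
  m
}

#' Read a food-group mapping file
#'
#' Reads a CSV with header `item,group,sentinel` (sentinel coded 0/1) into
#' an [fv_mapping()] object, validating group codes against [fv_groups()].
#'
#' @param path Path to the mapping CSV.
#' @param country_tag Optional provenance tag stored on the mapping.
#' @return An `fv_mapping` tibble.
#' @export
load_mapping <- function(path, country_tag = NA_character_) {
  df <- read_checked_csv(path, c("item", "group", "sentinel"))
  if (!all(df$sentinel %in% c(0, 1))) {
    bad <- which(!df$sentinel %in% c(0, 1))[1]
    abort(sprintf(
      "Column `sentinel` must be 0 or 1; row %d of %s has \"%s\".",
      bad, path, as.character(df$sentinel[bad])
    ))
  }
  fv_mapping(df$item, df$group, df$sentinel, country_tag = country_tag)
}

#' Classify food items into fruit and vegetable groups
#'
#' Looks up (normalised) item names in a mapping. Items not present are
#' returned as `NA`: they are considered non-fruit/vegetable foods and never
#' raise an error.
#'
#' @param name Character vector of food-item names.
#' @param mapping An [fv_mapping()] object.
#' @return Character vector of group codes, `NA` where the item is not a
#'   mapped fruit or vegetable.
#' @export
classify_item <- function(name, mapping) {
  stopifnot(inherits(mapping, "fv_mapping"))
  mapping$group[match(normalize_item(name), mapping$item)]
}

# Sentinel status lookup; NA for unmapped items.
item_is_sentinel <- function(name, mapping) {
  mapping$sentinel[match(normalize_item(name), mapping$item)]
}
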