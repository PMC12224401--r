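#' Outlet categories and health groups
#'
#' The classification scheme distinguishes eight food outlet categories,
#' grouped into three health-related groups according to the typical
#' healthfulness of the food offer:
#' \itemize{
#'   \item most healthy: fruit/vegetable stores, fresh food retail
#'     (bakeries, butchers, fishmongers)
#'   \item mixed: small food retail (corner shops, grocers), supermarkets,
#'     ready-for-consumption outlets (restaurants, cafes, takeaway)
#'   \item less healthy: candy/ice-cream shops, fast-food chains,
#'     chain convenience stores
#' }
#' Establishments that cannot be classified are labelled with the
#' sentinel \code{"unclassified"}, which belongs to no health group.
#'
#' @return \code{food_categories()} returns the character vector of the
#'   eight category labels; \code{health_groups()} the three group labels.
#' @export
food_categories <- function() {
  c("fruit_vegetable_store", "fresh_food_retail",
    "small_food_retail", "supermarket", "ready_for_consumption",
    "convenience_store", "fast_food_chain", "candy_ice_cream")
}

#' @rdname food_categories
#' @export
health_groups <- function() {
  c("most_healthy", "mixed", "less_healthy")
}

.health_map <- c(
  fruit_vegetable_store = "most_healthy",
  fresh_food_retail     = "most_healthy",
  small_food_retail     = "mixed",
  supermarket           = "mixed",
  ready_for_consumption = "mixed",
  candy_ice_cream       = "less_healthy",
  fast_food_chain       = "less_healthy",
  convenience_store     = "less_healthy"
)

#' Map an outlet category to its health group
#'
#' @param category character vector of category labels (see
#'   \code{\link{food_categories}}).
#' @return character vector of health-group labels, same length.
#'   \code{"unclassified"} input is an error: unclassified establishments
#'   must be excluded from any health-group-stratified output by the
#'   caller.
#' @examples
#' health_group("supermarket")       # "mixed"
#' health_group("fast_food_chain")   # "less_healthy"
#' @export
health_group <- function(category) {
  if (any(category == "unclassified"))
    stop("health_group() is undefined for 'unclassified'; exclude such records first")
  bad <- setdiff(unique(category), food_categories())
  if (length(bad))
    stop("unknown category: ", paste(bad, collapse = ", "))
  unname(.health_map[category])
}

#' Normalize an establishment or term string for matching
#'
#' Lowercases, folds Spanish accents/diacritics to ASCII, strips
#' punctuation, and collapses whitespace, so that e.g. "Almacén" and
#' "almacen" compare equal.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- chartr("áéíóúüñÁÉÍÓÚÜÑ",
              "aeiouunAEIOUUN", as.character(x))
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}
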