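#' Social environment index
#'
#' Composite neighbourhood index of the census dimension scores
#' (sanitation, housing, employment, education in the default
#' generator). Each dimension is z-scored across the full analysis set
#' (pooled across cities, so the index lives on one common scale),
#' optionally sign-flipped so that higher always means a more
#' favourable social environment, then averaged with equal weight.
#'
#' @param neighbourhoods data.frame with \code{id} and \code{dim_*}
#'   columns.
#' @param directions named numeric vector of +1/-1 per dimension column;
#'   default +1 for all (dimensions already coded higher = better). Any
#'   deprivation-coded variable must be declared with -1.
#' @return data.frame with columns \code{id}, \code{sei}.
#' @export
social_environment_index <- function(neighbourhoods, directions = NULL) {
  dims <- grep("^dim_", names(neighbourhoods), value = TRUE)
  if (!length(dims)) stop("no dim_* columns found")
  if (nrow(neighbourhoods) < 2)
    stop("social_environment_index needs >= 2 neighbourhoods")
  if (is.null(directions)) directions <- stats::setNames(rep(1, length(dims)), dims)
  if (!all(dims %in% names(directions)))
    stop("directions must name every dim_* column")
  z <- sapply(dims, function(d) {
    v <- neighbourhoods[[d]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("dimension '", d, "' has zero variance; cannot z-score")
    directions[[d]] * (v - mean(v)) / s
  })
  data.frame(id = neighbourhoods$id, sei = rowMeans(z),
             stringsAsFactors = FALSE)
}

.cells_containing <- function(nb, x, y) {
  which(nb$x0 <= x & x <= nb$x1 & nb$y0 <= y & y <= nb$y1)
}

#' Assign establishment points to neighbourhoods
#'
#' Point-in-polygon assignment for rectangular neighbourhood cells
#' (closed boundaries). A point lying on a shared boundary is assigned
#' to the containing neighbourhood with the lexicographically smallest
#' id, a deterministic tie-break. Points outside every cell are left
#' unassigned and counted.
#'
#' @param points data.frame with \code{x}, \code{y} (and ideally an id
#'   column); its \code{crs} attribute must match the neighbourhoods'.
#' @param neighbourhoods neighbourhood data.frame with cell bounds.
#' @return character vector of neighbourhood ids (NA = unassigned), one
#'   per point, with attribute \code{n_unassigned}.
#' @export
assign_points <- function(points, neighbourhoods) {
  crs_p <- attr(points, "crs"); crs_n <- attr(neighbourhoods, "crs")
  if (!is.null(crs_p) && !is.null(crs_n) && !identical(crs_p, crs_n))
    stop("CRS mismatch: points '", crs_p, "' vs neighbourhoods '", crs_n, "'")
  n <- nrow(points)
  if (!n) return(structure(character(0), n_unassigned = 0L))
  nb <- neighbourhoods

  # fast path: locate candidate cell via the sorted lattice of lower
  # edges, then verify containment; exact-boundary points and fast-path
  # misses fall back to a full scan with the min-id tie-break
  ux0 <- sort(unique(nb$x0)); uy0 <- sort(unique(nb$y0))
  ix <- findInterval(points$x, ux0); iy <- findInterval(points$y, uy0)
  key_nb <- paste(nb$x0, nb$y0)
  cand <- match(paste(ifelse(ix >= 1, ux0[ix], NA),
                      ifelse(iy >= 1, uy0[iy], NA)), key_nb)
  ok <- !is.na(cand) &
    nb$x0[cand] <= points$x & points$x <= nb$x1[cand] &
    nb$y0[cand] <= points$y & points$y <= nb$y1[cand]
  on_edge <- points$x %in% c(nb$x0, nb$x1) | points$y %in% c(nb$y0, nb$y1)
  assigned <- ifelse(ok & !on_edge, nb$id[cand], NA_character_)
  for (i in which(on_edge | !ok)) {
    hits <- .cells_containing(nb, points$x[i], points$y[i])
    if (length(hits)) assigned[i] <- min(nb$id[hits])
  }
  n_un <- sum(is.na(assigned))
  if (n_un > 0)
    message(n_un, " point(s) fall outside every neighbourhood; left unassigned")
  structure(assigned, n_unassigned = n_un)
}

#' Neighbourhood-level food environment metrics
#'
#' Establishment density (count per km2) for the full registry and per
#' category and health group, plus population density and the social
#' environment index. Unclassified establishments count toward the
#' total density only; category and health-group densities are over
#' classified establishments.
#'
#' @param neighbourhoods neighbourhood data.frame.
#' @param establishments classified establishments (output of
#'   \code{\link{classify_establishments}}), with an
#'   \code{assigned_id} column or coordinates to assign via
#'   \code{\link{assign_points}}.
#' @param directions passed to \code{\link{social_environment_index}}.
#' @return data.frame of class \code{neighbourhood_metrics}: one row per
#'   neighbourhood with \code{id}, \code{city}, \code{area_km2},
#'   \code{population}, \code{popdens}, \code{sei},
#'   \code{density_total}, \code{density_<category>} and
#'   \code{density_<health group>} columns; attribute
#'   \code{n_unassigned}.
#' @export
neighbourhood_metrics <- function(neighbourhoods, establishments,
                                  directions = NULL) {
  if (any(neighbourhoods$area_km2 <= 0)) stop("all areas must be positive")
  if (is.null(establishments$assigned_id)) {
    establishments$assigned_id <- as.character(
      assign_points(establishments, neighbourhoods))
  }
  if (is.null(establishments$category))
    stop("establishments must carry a 'category' column; run classify_establishments() first")
  lev <- neighbourhoods$id
  m <- data.frame(id = neighbourhoods$id, city = neighbourhoods$city,
                  area_km2 = neighbourhoods$area_km2,
                  population = neighbourhoods$population,
                  stringsAsFactors = FALSE)
  m$popdens <- m$population / m$area_km2
  m$sei <- social_environment_index(neighbourhoods, directions)$sei
  a <- m$area_km2
  fid <- factor(establishments$assigned_id, levels = lev)
  m$density_total <- as.numeric(table(fid)) / a
  for (ct in food_categories()) {
    sel <- establishments$category == ct
    m[[paste0("density_", ct)]] <- as.numeric(table(fid[sel])) / a
  }
  for (hg in health_groups()) {
    cats <- names(.health_map)[.health_map == hg]
    sel <- establishments$category %in% cats
    m[[paste0("density_", hg)]] <- as.numeric(table(fid[sel])) / a
  }
  attr(m, "n_unassigned") <- sum(is.na(fid))
  class(m) <- c("neighbourhood_metrics", "data.frame")
  m
}

#' Density per unit area
#'
#' @param count establishment count(s).
#' @param area_km2 area(s), km2, > 0.
#' @return count / area, establishments per km2.
#' @export
compute_density <- function(count, area_km2) {
  if (any(area_km2 <= 0)) stop("area must be positive")
  count / area_km2
}

#' Quartile-stratified density table
#'
#' Mean and median of each density column by quartile of a
#' neighbourhood-level stratifier (population density or social
#' environment index). Quartiles use the default linear-interpolation
#' quantile convention (type 7); heavy ties that collapse quartile
#' breaks produce fewer, unequal bins with a warning.
#'
#' @param metrics a \code{\link{neighbourhood_metrics}} data.frame.
#' @param stratifier \code{"popdens"} or \code{"sei"} (any numeric
#'   column name is accepted).
#' @return data.frame in long layout: \code{quartile} (Q1 low .. Q4
#'   high), \code{n} neighbourhoods, then \code{<density>_mean} and
#'   \code{<density>_median} per density column.
#' @export
quartile_table <- function(metrics, stratifier = c("popdens", "sei")) {
  stratifier <- stratifier[1]
  if (!stratifier %in% names(metrics)) stop("unknown stratifier: ", stratifier)
  if (nrow(metrics) < 4) stop("need >= 4 neighbourhoods for quartiles")
  s <- metrics[[stratifier]]
  br <- stats::quantile(s, probs = seq(0, 1, 0.25), type = 7, names = FALSE)
  if (anyDuplicated(br)) {
    warning("stratifier quartile breaks contain ties; bins will be unequal")
    br <- unique(br)
  }
  if (length(br) < 2) stop("stratifier '", stratifier, "' is constant; cannot stratify")
  q <- cut(s, breaks = br, include.lowest = TRUE,
           labels = paste0("Q", seq_len(length(br) - 1)))
  dens_cols <- grep("^density_", names(metrics), value = TRUE)
  out <- data.frame(quartile = levels(q), n = as.integer(table(q)),
                    stringsAsFactors = FALSE)
  for (dc in dens_cols) {
    out[[paste0(dc, "_mean")]] <- as.numeric(
      tapply(metrics[[dc]], q, mean))
    out[[paste0(dc, "_median")]] <- as.numeric(
      tapply(metrics[[dc]], q, stats::median))
  }
  out
}
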