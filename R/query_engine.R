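#' Grid specification for area-covering POI queries
#'
#' A regular lattice of query points per city bounding box. The
#' coverage invariant \code{search_radius >= spacing / sqrt(2)}
#' guarantees that the union of search discs covers every point of the
#' box, so no establishment inside the study area can be missed for
#' geometric reasons.
#'
#' @param bboxes data.frame with columns \code{city}, \code{xmin},
#'   \code{ymin}, \code{xmax}, \code{ymax} (km on the planar CRS, or
#'   degrees when \code{crs = "lonlat"}).
#' @param spacing lattice spacing, same units as the box.
#' @param search_radius provider search radius, same units.
#' @param crs \code{"planar_km"} or \code{"lonlat"}.
#' @return list of class \code{grid_spec}.
#' @export
grid_spec <- function(bboxes, spacing, search_radius, crs = "planar_km") {
  stopifnot(is.data.frame(bboxes),
            all(c("city", "xmin", "ymin", "xmax", "ymax") %in% names(bboxes)))
  if (spacing <= 0) stop("spacing must be positive")
  if (search_radius < spacing / sqrt(2))
    stop("search_radius must be >= spacing/sqrt(2) to guarantee disc coverage")
  structure(list(bboxes = bboxes, spacing = spacing,
                 search_radius = search_radius, crs = crs),
            class = "grid_spec")
}

#' Bounding boxes of a neighbourhood set, one per city
#'
#' @param neighbourhoods neighbourhood data.frame with cell bounds.
#' @return data.frame suitable for \code{\link{grid_spec}}.
#' @export
city_bboxes <- function(neighbourhoods) {
  sp <- split(neighbourhoods, neighbourhoods$city)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(city = d$city[1], xmin = min(d$x0), ymin = min(d$y0),
               xmax = max(d$x1), ymax = max(d$y1), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$city), , drop = FALSE]
}

# lattice covering [lo, hi]: regular steps plus the far edge if needed
.gseq <- function(lo, hi, by) {
  p <- seq(lo, hi, by = by)
  if (p[length(p)] < hi) p <- c(p, hi)
  p
}

#' Build the ordered list of query points
#'
#' Regular lattice at \code{spacing} covering each city box inclusive of
#' edges (the far edge is appended when the extent is not a multiple of
#' the spacing), emitted in deterministic city-then-row-major order.
#' A degenerate box (zero width or height) collapses to a line or a
#' single point, with a warning.
#'
#' @param spec a \code{\link{grid_spec}}.
#' @return data.frame with columns \code{city}, \code{x}, \code{y}.
#' @export
make_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  out <- lapply(seq_len(nrow(spec$bboxes)), function(i) {
    b <- spec$bboxes[i, ]
    if (b$xmax - b$xmin <= 0 || b$ymax - b$ymin <= 0)
      warning("degenerate bounding box for city '", b$city, "'")
    xs <- .gseq(b$xmin, b$xmax, spec$spacing)
    ys <- .gseq(b$ymin, b$ymax, spec$spacing)
    data.frame(city = b$city,
               x = rep(xs, times = length(ys)),
               y = rep(ys, each = length(xs)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.dist_km <- function(x1, y1, x2, y2, crs) {
  if (identical(crs, "lonlat"))
    geosphere::distHaversine(cbind(x1, y1), cbind(x2, y2)) / 1000
  else
    sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Mock point-of-interest provider
#'
#' Implements the provider search contract over a fixed registry (e.g.
#' the synthetic establishment file): \code{search(term, x, y, radius)}
#' returns every registry record whose name contains the term on a word
#' boundary (after normalization) or whose primary/secondary type label
#' equals the term, and whose location lies within \code{radius} of the
#' query point. Idempotent and deterministic. Per-term name matches are
#' memoised, so repeated grid queries cost one scan per term.
#'
#' A live adapter for a commercial places service would implement the
#' same contract; none ships.
#'
#' @param registry data.frame with \code{est_id}, \code{name},
#'   \code{x}, \code{y}, \code{primary_type}, \code{secondary_types}
#'   (";"-separated) and optionally \code{address}.
#' @param crs coordinate system of the registry.
#' @param fail_at optional function(term, x, y) returning TRUE to
#'   simulate a transient provider failure (used in tests of the retry
#'   path).
#' @return object of class \code{poi_provider} with a \code{search}
#'   function.
#' @export
mock_provider <- function(registry, crs = "planar_km", fail_at = NULL) {
  stopifnot(all(c("est_id", "name", "x", "y", "primary_type") %in% names(registry)))
  if (is.null(registry$secondary_types)) registry$secondary_types <- ""
  if (is.null(registry$address)) registry$address <- ""
  name_norm <- normalize_name(registry$name)
  type_norm <- lapply(seq_len(nrow(registry)), function(i) {
    normalize_name(c(registry$primary_type[i],
                     strsplit(registry$secondary_types[i], ";")[[1]]))
  })
  memo <- new.env(parent = emptyenv())
  term_rows <- function(term) {
    tn <- normalize_name(term)
    if (!is.null(memo[[tn]])) return(memo[[tn]])
    by_name <- grepl(paste0("\\b", tn, "\\b"), name_norm, perl = TRUE)
    by_type <- vapply(type_norm, function(tt) tn %in% tt, logical(1))
    rows <- which(by_name | by_type)
    memo[[tn]] <- rows
    rows
  }
  search <- function(term, x, y, radius) {
    if (!is.null(fail_at) && isTRUE(fail_at(term, x, y)))
      stop("provider failure (simulated)")
    rows <- term_rows(term)
    if (!length(rows)) return(registry[0, c("est_id", "name", "address", "x", "y",
                                            "primary_type", "secondary_types")])
    d <- .dist_km(registry$x[rows], registry$y[rows], x, y, crs)
    hit <- rows[d <= radius]
    out <- registry[hit, c("est_id", "name", "address", "x", "y",
                           "primary_type", "secondary_types")]
    names(out)[names(out) == "est_id"] <- "provider_id"
    rownames(out) <- NULL
    out
  }
  structure(list(search = search, crs = crs, n_registry = nrow(registry)),
            class = "poi_provider")
}

#' Run the grid query
#'
#' Issues \code{search(term, point, radius)} for every term at every
#' grid point, in deterministic order, concatenating the raw results
#' (duplicates expected; see \code{\link{deduplicate}}). A provider
#' failure at a point is retried once and then skipped with a warning;
#' the run continues.
#'
#' @param provider a \code{\link{mock_provider}}-style object.
#' @param spec a \code{\link{grid_spec}} (or a precomputed grid
#'   data.frame with \code{x}, \code{y}).
#' @param terms non-empty character vector of search terms.
#' @return raw data.frame of provider records; attributes
#'   \code{hits_per_term} (named counts) and \code{n_failed_points}.
#' @export
run_query <- function(provider, spec, terms) {
  if (!length(terms)) stop("term list must be non-empty")
  grid <- if (inherits(spec, "grid_spec")) make_grid(spec) else spec
  radius <- if (inherits(spec, "grid_spec")) spec$search_radius else
    stop("a grid_spec is required to know the search radius")
  acc <- vector("list", length(terms) * nrow(grid))
  hits <- stats::setNames(numeric(length(terms)), terms)
  n_failed <- 0L
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    for (tm in terms) {
      res <- tryCatch(
        provider$search(tm, grid$x[g], grid$y[g], radius),
        error = function(e) tryCatch(  # one retry, then skip
          provider$search(tm, grid$x[g], grid$y[g], radius),
          error = function(e2) e2))
      if (inherits(res, "error")) {
        warning("provider failed twice at point ", g, " for term '", tm,
                "'; skipped: ", conditionMessage(res))
        n_failed <- n_failed + 1L
        next
      }
      if (nrow(res)) {
        k <- k + 1L
        acc[[k]] <- res
        hits[tm] <- hits[tm] + nrow(res)
      }
    }
  }
  raw <- if (k) do.call(rbind, acc[seq_len(k)]) else
    data.frame(provider_id = character(0), name = character(0),
               address = character(0), x = numeric(0), y = numeric(0),
               primary_type = character(0), secondary_types = character(0),
               stringsAsFactors = FALSE)
  rownames(raw) <- NULL
  attr(raw, "hits_per_term") <- hits
  attr(raw, "n_failed_points") <- n_failed
  raw
}

#' De-duplicate raw query results
#'
#' One record per \code{provider_id} (first occurrence wins). Records
#' without a provider id are merged when their normalized names are
#' equal and they lie within \code{epsilon_km} of an earlier record of
#' the same name (first occurrence wins), so two branches of a chain
#' further apart than epsilon stay distinct.
#'
#' @param raw data.frame from \code{\link{run_query}}.
#' @param epsilon_km merge distance for id-less records (default 25 m).
#' @param crs coordinate system for the distance.
#' @return unique data.frame; attribute \code{n_merged} counts removed
#'   duplicates.
#' @export
deduplicate <- function(raw, epsilon_km = 0.025, crs = "planar_km") {
  if (!nrow(raw)) {
    attr(raw, "n_merged") <- 0L
    return(raw)
  }
  has_id <- if (is.null(raw$provider_id)) rep(FALSE, nrow(raw)) else
    !is.na(raw$provider_id) & nzchar(raw$provider_id)
  keep <- logical(nrow(raw))
  keep[has_id] <- !duplicated(raw$provider_id[has_id])
  idless <- which(!has_id)
  if (length(idless)) {
    nn <- normalize_name(raw$name[idless])
    for (grp in split(idless, nn)) {
      reps <- integer(0)
      for (i in grp) {
        if (!length(reps)) {
          keep[i] <- TRUE; reps <- i
        } else {
          d <- .dist_km(raw$x[reps], raw$y[reps], raw$x[i], raw$y[i], crs)
          if (all(d > epsilon_km)) {
            keep[i] <- TRUE; reps <- c(reps, i)
          }
        }
      }
    }
  }
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_merged") <- nrow(raw) - nrow(out)
  attr(out, "crs") <- crs
  out
}
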