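#' Write neighbourhoods as GeoJSON
#'
#' Each neighbourhood becomes a Polygon feature (closed ring of its
#' rectangular cell) with properties \code{id}, \code{city},
#' \code{area_km2}, \code{population} and the \code{dim_*} scores. The
#' planar-vs-geographic coordinate convention is recorded in a
#' top-level \code{crs_flag} member.
#'
#' @param neighbourhoods neighbourhood data.frame.
#' @param path output file.
#' @export
write_neighbourhoods_geojson <- function(neighbourhoods, path) {
  dims <- grep("^dim_", names(neighbourhoods), value = TRUE)
  feats <- lapply(seq_len(nrow(neighbourhoods)), function(i) {
    r <- neighbourhoods[i, ]
    ring <- list(c(r$x0, r$y0), c(r$x1, r$y0), c(r$x1, r$y1),
                 c(r$x0, r$y1), c(r$x0, r$y0))
    props <- c(list(id = r$id, city = r$city, area_km2 = r$area_km2,
                    population = r$population, popdens = r$popdens),
               stats::setNames(as.list(as.numeric(r[dims])), dims))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection",
              crs_flag = attr(neighbourhoods, "crs") %||% "planar_km",
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read neighbourhoods from GeoJSON
#'
#' Inverse of \code{\link{write_neighbourhoods_geojson}}: rectangular
#' cell bounds are recovered as the coordinate range of each polygon
#' ring.
#'
#' @param path GeoJSON file.
#' @return \code{neighbourhoods} data.frame with \code{crs} attribute.
#' @export
read_neighbourhoods_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$features, function(f) {
    cc <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                function(p) unlist(p)))
    p <- f$properties
    out <- data.frame(id = p$id, city = p$city,
                      x0 = min(cc[, 1]), y0 = min(cc[, 2]),
                      x1 = max(cc[, 1]), y1 = max(cc[, 2]),
                      area_km2 = p$area_km2, population = p$population,
                      popdens = p$popdens, stringsAsFactors = FALSE)
    for (d in grep("^dim_", names(p), value = TRUE)) out[[d]] <- p[[d]]
    out
  })
  nb <- do.call(rbind, rows)
  rownames(nb) <- NULL
  attr(nb, "crs") <- obj$crs_flag %||% "planar_km"
  class(nb) <- c("neighbourhoods", "data.frame")
  nb
}

#' Write a full synthetic city to disk
#'
#' Neighbourhoods as GeoJSON, establishments and participants as CSV,
#' and the configuration as YAML, under one directory.
#'
#' @param sim output of \code{\link{simulate_city}}.
#' @param dir output directory (created if absent).
#' @return invisible named vector of file paths.
#' @export
write_city <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(neighbourhoods = file.path(dir, "neighbourhoods.geojson"),
             establishments = file.path(dir, "establishments.csv"),
             participants = file.path(dir, "participants.csv"),
             config = file.path(dir, "config.yaml"))
  write_neighbourhoods_geojson(sim$neighbourhoods, paths["neighbourhoods"])
  utils::write.csv(sim$establishments, paths["establishments"], row.names = FALSE)
  utils::write.csv(sim$participants, paths["participants"], row.names = FALSE)
  write_config_yaml(sim$config, paths["config"])
  invisible(paths)
}

#' Write / read a city configuration as YAML
#'
#' @param config a \code{\link{city_config}}.
#' @param path YAML file.
#' @export
write_config_yaml <- function(config, path) {
  lst <- unclass(config)
  lst$outcome_model <- unclass(lst$outcome_model)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  om <- do.call(outcome_truth, lst$outcome_model)
  lst$outcome_model <- om
  do.call(city_config, lst[setdiff(names(lst), character(0))])
}
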