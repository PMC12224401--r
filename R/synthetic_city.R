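#' Configuration for the synthetic city generator
#'
#' The generator emulates the structure of a multi-city observational
#' study of the community food environment: census-tract-like
#' neighbourhoods ("zonas censales", square grid cells on planar km
#' coordinates), a registry of named food establishments whose counts
#' are overdispersed and increase with population density and with a
#' more favourable social environment, and survey respondents nested in
#' a subset of neighbourhoods with a binary non-daily fruit/vegetable
#' (FV) consumption outcome generated from a random-intercept logistic
#' model.
#'
#' Defaults mirror the study conditions the package targets: 2,442
#' neighbourhoods across three cities (split 1,700/386/356), lognormal
#' population density with median ~9,810 persons/km2, an establishment
#' registry of roughly 48,000 outlets with a heavily
#' ready-for-consumption category mix, ~17.3% non-daily FV prevalence
#' among 1,275 respondents in 319 neighbourhoods.
#'
#' @param n_neighbourhoods total neighbourhood count across cities.
#' @param city_labels city identifiers.
#' @param city_weights expected share of neighbourhoods per city.
#' @param cell_size_km side of the square neighbourhood cell, km.
#' @param popdens_meanlog,popdens_sdlog lognormal parameters of
#'   population density (persons/km2).
#' @param sei_dimension_count number of census dimension scores.
#' @param sei_popdens_correlation target correlation between each raw
#'   dimension score and log population density, in [-1, 1].
#' @param establishments_per_capita expected establishments per person
#'   at social environment index (SEI) zero.
#' @param category_mix probability vector over the eight outlet
#'   categories (order of \code{\link{food_categories}}); must sum to 1.
#' @param density_sei_gradient log-linear effect of SEI on establishment
#'   intensity (>0: more outlets in more favourable environments).
#' @param nb_dispersion negative-binomial size parameter for
#'   per-neighbourhood establishment counts (smaller = heavier tail).
#' @param label_noise_rate probability that a provider primary label is
#'   replaced by a random (possibly uninformative) label.
#' @param ambiguous_fraction fraction of establishments given a name
#'   with no inventory term and an uninformative provider label, to
#'   exercise the unclassified path.
#' @param n_participants survey respondents to generate.
#' @param participant_neighbourhoods number of neighbourhoods respondents
#'   are drawn from.
#' @param exposure_category density used as the true exposure in the
#'   outcome model (a category label, a health group, or "total").
#' @param outcome_model an \code{\link{outcome_truth}} object.
#' @param seed integer; fixes every random draw of every stage.
#' @return validated list of class \code{city_config}.
#' @export
city_config <- function(n_neighbourhoods = 2442,
                        city_labels = c("Santiago", "Valparaiso", "Concepcion"),
                        city_weights = c(1700, 386, 356) / 2442,
                        cell_size_km = 0.45,
                        popdens_meanlog = log(9810),
                        popdens_sdlog = 0.6,
                        sei_dimension_count = 4,
                        sei_popdens_correlation = 0.3,
                        establishments_per_capita = 0.008,
                        category_mix = c(1.01, 2.13, 10.76, 6.97, 66.01,
                                         7.47, 0.96, 1.68) / 96.99,
                        density_sei_gradient = 0.3,
                        nb_dispersion = 1.2,
                        label_noise_rate = 0.05,
                        ambiguous_fraction = 0.03,
                        n_participants = 1275,
                        participant_neighbourhoods = 319,
                        exposure_category = "small_food_retail",
                        outcome_model = outcome_truth(),
                        seed = 1L) {
  cfg <- list(n_neighbourhoods = as.integer(n_neighbourhoods),
              city_labels = city_labels,
              city_weights = city_weights / sum(city_weights),
              cell_size_km = cell_size_km,
              popdens_meanlog = popdens_meanlog,
              popdens_sdlog = popdens_sdlog,
              sei_dimension_count = as.integer(sei_dimension_count),
              sei_popdens_correlation = sei_popdens_correlation,
              establishments_per_capita = establishments_per_capita,
              category_mix = category_mix,
              density_sei_gradient = density_sei_gradient,
              nb_dispersion = nb_dispersion,
              label_noise_rate = label_noise_rate,
              ambiguous_fraction = ambiguous_fraction,
              n_participants = as.integer(n_participants),
              participant_neighbourhoods = as.integer(participant_neighbourhoods),
              exposure_category = exposure_category,
              outcome_model = outcome_model,
              seed = as.integer(seed))
  validate_city_config(cfg)
  class(cfg) <- "city_config"
  cfg
}

#' True parameters of the generative outcome model
#'
#' Fixed and random effects of the random-intercept logistic model that
#' generates the non-daily FV outcome: logit P(non-daily) = intercept +
#' beta_exposure * z(exposure density) + beta_age * z(age) + beta_male *
#' male + beta_education * low-education + u_j, with u_j ~ N(0,
#' sigma_u^2) per neighbourhood. The default intercept (-2.228) is
#' calibrated by numerically averaging the inverse logit over the
#' default covariate distribution and random intercept, so the marginal
#' non-daily prevalence under the default effects is 17.3%; the default
#' exposure effect corresponds to an odds ratio near 1.2 per SD.
#'
#' @param intercept log-odds at covariate zero.
#' @param beta_exposure log-odds per 1 SD of the exposure density.
#' @param beta_age log-odds per 1 SD of age.
#' @param beta_male log-odds for male vs female.
#' @param beta_education log-odds for below-secondary education.
#' @param sigma_u random-intercept SD (log-odds scale), >= 0.
#' @return list of class \code{outcome_truth}.
#' @export
outcome_truth <- function(intercept = -2.228,
                          beta_exposure = 0.18,
                          beta_age = -0.5,
                          beta_male = 0.75,
                          beta_education = 0.3,
                          sigma_u = 0.5) {
  if (sigma_u < 0) stop("sigma_u must be >= 0")
  structure(list(intercept = intercept, beta_exposure = beta_exposure,
                 beta_age = beta_age, beta_male = beta_male,
                 beta_education = beta_education, sigma_u = sigma_u),
            class = "outcome_truth")
}

validate_city_config <- function(cfg) {
  chk <- function(ok, field, why) if (!ok) stop("invalid config field '", field, "': ", why)
  chk(cfg$n_neighbourhoods >= 1, "n_neighbourhoods", "must be positive")
  chk(length(cfg$city_labels) >= 1 && !anyDuplicated(cfg$city_labels),
      "city_labels", "must be non-empty and unique")
  chk(length(cfg$city_weights) == length(cfg$city_labels) && all(cfg$city_weights > 0),
      "city_weights", "one positive weight per city")
  chk(cfg$cell_size_km > 0, "cell_size_km", "must be positive")
  chk(cfg$popdens_sdlog > 0, "popdens_sdlog", "must be positive")
  chk(cfg$sei_dimension_count >= 1, "sei_dimension_count", "must be positive")
  chk(abs(cfg$sei_popdens_correlation) <= 1, "sei_popdens_correlation", "must be in [-1,1]")
  chk(cfg$establishments_per_capita >= 0, "establishments_per_capita", "must be >= 0")
  chk(length(cfg$category_mix) == length(food_categories()),
      "category_mix", sprintf("needs %d entries (one per category)", length(food_categories())))
  chk(abs(sum(cfg$category_mix) - 1) < 1e-9, "category_mix", "must sum to 1 within 1e-9")
  chk(all(cfg$category_mix >= 0), "category_mix", "entries must be >= 0")
  chk(cfg$nb_dispersion > 0, "nb_dispersion", "must be positive")
  chk(cfg$label_noise_rate >= 0 && cfg$label_noise_rate <= 1, "label_noise_rate", "must be in [0,1]")
  chk(cfg$ambiguous_fraction >= 0 && cfg$ambiguous_fraction <= 1, "ambiguous_fraction", "must be in [0,1]")
  chk(cfg$n_participants >= 0, "n_participants", "must be >= 0")
  chk(cfg$participant_neighbourhoods >= 1, "participant_neighbourhoods", "must be positive")
  chk(inherits(cfg$outcome_model, "outcome_truth"), "outcome_model", "must be an outcome_truth()")
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  invisible(cfg)
}

# apportion n among weights, largest-remainder, deterministic
.apportion <- function(n, w) {
  raw <- n * w / sum(w)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

#' Generate neighbourhoods
#'
#' Tiles each city's bounding box with square cells of side
#' \code{cell_size_km} on planar km coordinates (cities are placed in
#' disjoint coordinate blocks). Population density is lognormal;
#' population = density x area. Each of the census dimension scores is
#' generated to correlate with log population density at
#' \code{sei_popdens_correlation} and is stored on a raw
#' (location/scale-arbitrary) scale, as census variables would be.
#'
#' @param config a \code{\link{city_config}}.
#' @return data.frame of class \code{neighbourhoods} with columns
#'   \code{id}, \code{city}, cell bounds \code{x0,y0,x1,y1} (km),
#'   \code{area_km2}, \code{population}, \code{popdens}, and
#'   \code{dim_1..dim_k}; attribute \code{crs = "planar_km"}.
#' @export
generate_neighbourhoods <- function(config) {
  validate_city_config(config)
  set.seed(config$seed)
  n_city <- .apportion(config$n_neighbourhoods, config$city_weights)
  s <- config$cell_size_km
  out <- vector("list", length(config$city_labels))
  for (ci in seq_along(config$city_labels)) {
    n <- n_city[ci]
    if (n == 0) next
    ncol_ <- ceiling(sqrt(n))
    idx <- seq_len(n) - 1L
    col <- idx %% ncol_
    row <- idx %/% ncol_
    xoff <- (ci - 1) * 1000  # disjoint 1000-km blocks per city
    out[[ci]] <- data.frame(
      id = sprintf("%s_%05d", config$city_labels[ci], seq_len(n)),
      city = config$city_labels[ci],
      x0 = xoff + col * s, y0 = row * s,
      x1 = xoff + (col + 1) * s, y1 = (row + 1) * s,
      stringsAsFactors = FALSE)
  }
  nb <- do.call(rbind, out)
  rownames(nb) <- NULL
  nb$area_km2 <- (nb$x1 - nb$x0) * (nb$y1 - nb$y0)
  nb$popdens <- stats::rlnorm(nrow(nb), config$popdens_meanlog, config$popdens_sdlog)
  nb$population <- nb$popdens * nb$area_km2
  z <- as.numeric(scale(log(nb$popdens)))
  rho <- config$sei_popdens_correlation
  for (k in seq_len(config$sei_dimension_count)) {
    latent <- rho * z + sqrt(1 - rho^2) * stats::rnorm(nrow(nb))
    nb[[paste0("dim_", k)]] <- 50 + 10 * latent  # arbitrary census-like scale
  }
  attr(nb, "crs") <- "planar_km"
  class(nb) <- c("neighbourhoods", "data.frame")
  nb
}

.provider_primary_by_category <- list(
  fruit_vegetable_store = "greengrocer",
  fresh_food_retail     = c("bakery", "butcher_shop", "fish_market"),
  small_food_retail     = "grocery_store",
  supermarket           = "supermarket",
  ready_for_consumption = c("restaurant", "cafe", "meal_takeaway"),
  convenience_store     = "convenience_store",
  fast_food_chain       = "fast_food_restaurant",
  candy_ice_cream       = c("ice_cream_shop", "candy_store")
)

.uninformative_types <- c("store", "establishment", "point_of_interest")

.proper_nouns <- c("El Sol", "La Estrella", "Don José", "Doña Rosa",
                   "Los Andes", "San Martín", "Santa Ana", "El Trébol",
                   "Tres Hermanos", "El Valle", "Las Flores", "Central",
                   "Del Parque", "La Cumbre", "El Faro", "Bellavista")

.ambiguous_names <- c("Donde Carmen", "Lo de Juanito", "Lola's", "Casa Esperanza",
                      "El Paradero", "La Esquina Amarilla", "Don Pepe",
                      "Villa Alegre", "Los Castaños", "El Rincón Azul")

#' Generate the establishment registry
#'
#' Per-neighbourhood establishment counts are negative binomial with
#' log-intensity linear in log population (via the per-capita rate) and
#' in the social environment index (slope \code{density_sei_gradient}),
#' capturing the overdispersed, socially graded counts seen in real
#' registries. Each establishment gets uniform coordinates within its
#' cell, a name built from a category term plus a proper noun, and
#' provider primary/secondary type labels consistent with its category
#' subject to \code{label_noise_rate}; a fraction
#' \code{ambiguous_fraction} instead gets a term-free name and
#' uninformative labels.
#'
#' @param neighbourhoods output of \code{\link{generate_neighbourhoods}}.
#' @param config the same \code{\link{city_config}}.
#' @param inventory term inventory used to draw category name terms.
#' @return data.frame with columns \code{est_id}, \code{name},
#'   \code{address}, \code{x}, \code{y}, \code{city},
#'   \code{neighbourhood_id} (generating cell), \code{true_category},
#'   \code{primary_type}, \code{secondary_types} (";"-separated),
#'   \code{ambiguous}; attribute \code{crs} copied from the
#'   neighbourhoods.
#' @export
generate_establishments <- function(neighbourhoods, config,
                                    inventory = read_term_inventory()) {
  validate_city_config(config)
  if (!nrow(neighbourhoods)) stop("neighbourhoods must be non-empty")
  set.seed(config$seed + 1L)
  sei <- social_environment_index(neighbourhoods)$sei
  mu <- config$establishments_per_capita * neighbourhoods$population *
    exp(config$density_sei_gradient * sei)
  counts <- stats::rnbinom(nrow(neighbourhoods), size = config$nb_dispersion, mu = mu)
  total <- sum(counts)
  if (total == 0) {
    emp <- data.frame(est_id = character(0), name = character(0),
                      address = character(0), x = numeric(0), y = numeric(0),
                      city = character(0), neighbourhood_id = character(0),
                      true_category = character(0), primary_type = character(0),
                      secondary_types = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
    attr(emp, "crs") <- attr(neighbourhoods, "crs")
    return(emp)
  }
  j <- rep(seq_len(nrow(neighbourhoods)), counts)
  cats <- food_categories()
  true_cat <- sample(cats, total, replace = TRUE, prob = config$category_mix)
  ambiguous <- stats::runif(total) < config$ambiguous_fraction

  # names: "<Term> <Proper Noun>" or an inventory-term-free fantasy name
  nm_terms <- inventory[inventory$match_kind %in% c("name", "both"), ]
  term_pool <- split(nm_terms$term, nm_terms$category)
  cap <- function(s) gsub("\\b([a-záéíóúñ])",
                          "\\U\\1", s, perl = TRUE)
  term_of <- vapply(true_cat, function(ct) sample(term_pool[[ct]], 1), character(1))
  name <- paste(cap(term_of), sample(.proper_nouns, total, replace = TRUE))
  name[ambiguous] <- paste(sample(.ambiguous_names, sum(ambiguous), replace = TRUE),
                           sample(LETTERS, sum(ambiguous), replace = TRUE))

  # provider labels: canonical for the category, noised at label_noise_rate
  prim <- vapply(true_cat, function(ct)
    sample(rep(.provider_primary_by_category[[ct]], 2), 1), character(1))
  all_types <- c(unlist(.provider_primary_by_category, use.names = FALSE),
                 .uninformative_types)
  noisy <- stats::runif(total) < config$label_noise_rate
  prim[noisy] <- sample(all_types, sum(noisy), replace = TRUE)
  prim[ambiguous] <- sample(.uninformative_types, sum(ambiguous), replace = TRUE)
  n_sec <- sample(0:3, total, replace = TRUE)
  sec <- vapply(seq_len(total), function(i) {
    if (n_sec[i] == 0) return("")
    paste(sample(.uninformative_types, n_sec[i], replace = TRUE), collapse = ";")
  }, character(1))
  sec[ambiguous] <- ""

  nbj <- neighbourhoods[j, ]
  est <- data.frame(
    est_id = sprintf("E%06d", seq_len(total)),
    name = name,
    address = sprintf("Calle %d, %s", sample(1:9999, total, replace = TRUE), nbj$city),
    x = stats::runif(total, nbj$x0, nbj$x1),
    y = stats::runif(total, nbj$y0, nbj$y1),
    city = nbj$city,
    neighbourhood_id = nbj$id,
    true_category = true_cat,
    primary_type = prim,
    secondary_types = sec,
    ambiguous = ambiguous,
    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  attr(est, "crs") <- attr(neighbourhoods, "crs")
  est
}

# admissible (fruit, veg) day pairs by outcome; uniform over each set
.fv_pairs <- local({
  grid <- expand.grid(fruit_days = 0:7, veg_days = 0:7)
  list(daily = grid[grid$fruit_days + grid$veg_days >= 7, ],
       non_daily = grid[grid$fruit_days + grid$veg_days <= 6, ])
})

#' Generate survey participants
#'
#' Respondents are assigned (uniformly) to a random subset of
#' neighbourhoods. The binary non-daily FV outcome is drawn from the
#' random-intercept logistic model in \code{config$outcome_model}, with
#' the exposure being the z-scored density (per participant) of
#' \code{config$exposure_category} computed from the true categories in
#' the registry. Weekly fruit/vegetable day counts are then back-filled
#' consistently with the outcome: daily consumers get a (fruit, veg)
#' pair with capped sum 7, non-daily a pair with sum <= 6, uniform over
#' the admissible pairs.
#'
#' @param neighbourhoods,config as above.
#' @param establishments registry from
#'   \code{\link{generate_establishments}}; may be \code{NULL} when
#'   \code{beta_exposure} is 0 (exposure then taken as 0).
#' @return data.frame with columns \code{participant_id},
#'   \code{neighbourhood_id}, \code{age}, \code{gender},
#'   \code{education} (4 ordered levels), \code{fruit_days},
#'   \code{veg_days}; attribute \code{truth} carries the generative
#'   linear predictor pieces for recovery checks.
#' @export
generate_participants <- function(neighbourhoods, config, establishments = NULL) {
  validate_city_config(config)
  set.seed(config$seed + 2L)
  tr <- config$outcome_model
  n <- config$n_participants
  if (n == 0) {
    return(data.frame(participant_id = character(0), neighbourhood_id = character(0),
                      age = numeric(0), gender = character(0), education = character(0),
                      fruit_days = integer(0), veg_days = integer(0)))
  }
  k <- min(config$participant_neighbourhoods, nrow(neighbourhoods))
  picked <- sort(sample(neighbourhoods$id, k))
  nb_id <- sample(picked, n, replace = TRUE)

  # true exposure density from the registry's true categories
  if (!is.null(establishments) && nrow(establishments)) {
    sel <- establishments$true_category == config$exposure_category
    if (config$exposure_category == "total") sel <- rep(TRUE, nrow(establishments))
    cnt <- table(factor(establishments$neighbourhood_id[sel],
                        levels = neighbourhoods$id))
    dens <- as.numeric(cnt) / neighbourhoods$area_km2
    names(dens) <- neighbourhoods$id
    exposure_raw <- unname(dens[nb_id])
  } else {
    exposure_raw <- rep(0, n)
  }
  z_exp <- if (stats::sd(exposure_raw) > 0)
    as.numeric(scale(exposure_raw)) else rep(0, n)

  age <- round(pmin(pmax(stats::rnorm(n, 50, 18), 20), 95))
  z_age <- if (stats::sd(age) > 0) as.numeric(scale(age)) else rep(0, n)
  male <- stats::rbinom(n, 1, 0.384)
  edu_levels <- c("<primary", "primary", "secondary", "university")
  education <- sample(edu_levels, n, replace = TRUE,
                      prob = c(0.107, 0.455, 0.308, 0.130))
  low_educ <- as.integer(education %in% c("<primary", "primary"))

  u <- stats::rnorm(k, 0, tr$sigma_u)
  names(u) <- picked
  eta <- tr$intercept + tr$beta_exposure * z_exp + tr$beta_age * z_age +
    tr$beta_male * male + tr$beta_education * low_educ + unname(u[nb_id])
  non_daily <- stats::rbinom(n, 1, stats::plogis(eta)) == 1

  pairs <- matrix(NA_integer_, n, 2)
  for (lab in c("daily", "non_daily")) {
    idx <- if (lab == "daily") which(!non_daily) else which(non_daily)
    if (length(idx)) {
      adm <- .fv_pairs[[lab]]
      pick <- sample(nrow(adm), length(idx), replace = TRUE)
      pairs[idx, 1] <- adm$fruit_days[pick]
      pairs[idx, 2] <- adm$veg_days[pick]
    }
  }

  pp <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    neighbourhood_id = nb_id,
    age = age,
    gender = ifelse(male == 1, "male", "female"),
    education = education,
    fruit_days = pairs[, 1],
    veg_days = pairs[, 2],
    stringsAsFactors = FALSE)
  attr(pp, "truth") <- list(outcome_model = tr, u = u,
                            exposure_raw = exposure_raw, z_exposure = z_exp,
                            non_daily = non_daily)
  pp
}

#' Run the full generator
#'
#' @param config a \code{\link{city_config}}.
#' @return list with \code{neighbourhoods}, \code{establishments},
#'   \code{participants} and the \code{config}.
#' @export
simulate_city <- function(config = city_config()) {
  nb <- generate_neighbourhoods(config)
  est <- generate_establishments(nb, config)
  pp <- generate_participants(nb, config, est)
  list(neighbourhoods = nb, establishments = est, participants = pp,
       config = config)
}
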