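test_that("config validation names the offending field", {
  expect_error(city_config(n_neighbourhoods = 0), "n_neighbourhoods")
  expect_error(city_config(cell_size_km = -1), "cell_size_km")
  expect_error(city_config(category_mix = rep(1, 8)), "category_mix")
  expect_error(city_config(category_mix = rep(0.2, 5)), "category_mix")
  expect_error(city_config(sei_popdens_correlation = 2), "sei_popdens_correlation")
  expect_error(outcome_truth(sigma_u = -0.1), "sigma_u")
})

test_that("same seed and config give identical outputs at every stage", {
  s1 <- simulate_city(small_config(seed = 7))
  s2 <- simulate_city(small_config(seed = 7))
  expect_identical(s1$neighbourhoods, s2$neighbourhoods)
  expect_identical(s1$establishments, s2$establishments)
  expect_identical(s1$participants, s2$participants)
  s3 <- simulate_city(small_config(seed = 8))
  expect_false(identical(s1$establishments, s3$establishments))
})

test_that("population is area times density and ids are unique", {
  nb <- generate_neighbourhoods(small_config(cell_size_km = 1))
  expect_equal(nb$population, nb$popdens * nb$area_km2)
  expect_equal(nb$area_km2, rep(1, nrow(nb)))
  expect_false(anyDuplicated(nb$id) > 0)
  expect_true(all(nb$x1 > nb$x0 & nb$y1 > nb$y0))
})

test_that("study-scale generation completes with the full neighbourhood count", {
  cfg <- city_config(seed = 3)
  nb <- generate_neighbourhoods(cfg)
  expect_equal(nrow(nb), 2442)
  expect_equal(length(unique(nb$id)), 2442)
  expect_equal(sort(unique(nb$city)), sort(cfg$city_labels))
  expect_equal(as.integer(table(nb$city)[cfg$city_labels]), c(1700, 386, 356))
})

test_that("census dimensions correlate with log population density as configured", {
  nb <- generate_neighbourhoods(city_config(n_neighbourhoods = 2000,
                                            sei_popdens_correlation = 0.5,
                                            seed = 21))
  r <- sapply(paste0("dim_", 1:4), function(d) cor(nb[[d]], log(nb$popdens)))
  expect_true(all(abs(r - 0.5) < 0.08))
})

test_that("establishment coordinates fall inside their generating cell", {
  sim <- simulate_city(small_config(seed = 5))
  est <- sim$establishments
  nb <- sim$neighbourhoods[match(est$neighbourhood_id, sim$neighbourhoods$id), ]
  expect_true(all(est$x >= nb$x0 & est$x <= nb$x1))
  expect_true(all(est$y >= nb$y0 & est$y <= nb$y1))
})

test_that("zero establishments per capita gives an empty registry", {
  cfg <- small_config(establishments_per_capita = 0)
  est <- generate_establishments(generate_neighbourhoods(cfg), cfg)
  expect_equal(nrow(est), 0)
})

test_that("ambiguous fraction controls the share of term-free names", {
  cfg <- city_config(n_neighbourhoods = 400, ambiguous_fraction = 0.03,
                     label_noise_rate = 0, seed = 13)
  est <- generate_establishments(generate_neighbourhoods(cfg), cfg)
  expect_gt(nrow(est), 3000)
  frac <- mean(est$ambiguous)
  expect_lt(abs(frac - 0.03), 3 * sqrt(0.03 * 0.97 / nrow(est)) + 0.002)
  # ambiguous names carry no inventory term
  inv <- read_term_inventory()
  amb <- normalize_name(est$name[est$ambiguous])
  nm_terms <- inv$term_norm[inv$match_kind %in% c("name", "both")]
  hits <- Reduce(`|`, lapply(nm_terms, function(tm)
    grepl(paste0("\\b", tm, "\\b"), amb, perl = TRUE)))
  expect_false(any(hits))
})

test_that("a positive social gradient raises establishment counts with SEI", {
  # Monte-Carlo sign check across independent seeded replicates
  rhos <- vapply(1:25, function(s) {
    cfg <- city_config(n_neighbourhoods = 150, density_sei_gradient = 0.4,
                       seed = 1000 + s)
    nb <- generate_neighbourhoods(cfg)
    est <- generate_establishments(nb, cfg)
    sei <- social_environment_index(nb)$sei
    cnt <- as.integer(table(factor(est$neighbourhood_id, levels = nb$id)))
    cor(sei, cnt, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0))
  expect_gt(mean(rhos), 0.2)
})

test_that("participants live in existing neighbourhoods and day counts match the outcome", {
  sim <- simulate_city(small_config(seed = 9))
  pp <- sim$participants
  expect_true(all(pp$neighbourhood_id %in% sim$neighbourhoods$id))
  expect_lte(length(unique(pp$neighbourhood_id)), 60)
  truth <- attr(pp, "truth")
  derived <- derive_outcome(pp$fruit_days, pp$veg_days)
  expect_equal(derived$non_daily, truth$non_daily)
})

test_that("null outcome model reproduces the target marginal prevalence", {
  cfg <- city_config(n_neighbourhoods = 300, n_participants = 20000,
                     participant_neighbourhoods = 300,
                     outcome_model = outcome_truth(
                       intercept = qlogis(0.173), beta_exposure = 0,
                       beta_age = 0, beta_male = 0, beta_education = 0,
                       sigma_u = 0),
                     seed = 17)
  pp <- generate_participants(generate_neighbourhoods(cfg), cfg)
  prev <- mean(derive_outcome(pp$fruit_days, pp$veg_days)$non_daily)
  expect_lt(abs(prev - 0.173), 3 * sqrt(0.173 * 0.827 / 20000))
})

test_that("simulated prevalence matches the closed-form marginal over the random intercept", {
  sig <- 0.8; int <- qlogis(0.2)
  cfg <- city_config(n_neighbourhoods = 400, n_participants = 30000,
                     participant_neighbourhoods = 400,
                     outcome_model = outcome_truth(
                       intercept = int, beta_exposure = 0, beta_age = 0,
                       beta_male = 0, beta_education = 0, sigma_u = sig),
                     seed = 19)
  pp <- generate_participants(generate_neighbourhoods(cfg), cfg)
  prev <- mean(derive_outcome(pp$fruit_days, pp$veg_days)$non_daily)
  marginal <- integrate(function(u) plogis(int + u) * dnorm(u, 0, sig),
                        -10, 10)$value
  # MC error includes the cluster-level random intercept draws
  expect_lt(abs(prev - marginal), 0.02)
})

test_that("an infinitely negative intercept yields only daily consumers", {
  cfg <- small_config(outcome_model = outcome_truth(intercept = -Inf,
                                                    beta_exposure = 0,
                                                    beta_age = 0, beta_male = 0,
                                                    beta_education = 0,
                                                    sigma_u = 0))
  pp <- generate_participants(generate_neighbourhoods(cfg), cfg)
  expect_true(all(derive_outcome(pp$fruit_days, pp$veg_days)$non_daily == FALSE))
})
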