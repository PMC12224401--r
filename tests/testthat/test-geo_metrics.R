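toy_neighbourhoods <- function() {
  nb <- data.frame(
    id = c("A", "B", "C", "D"),
    city = "X",
    x0 = c(0, 1, 0, 1), y0 = c(0, 0, 1, 1),
    x1 = c(1, 2, 1, 2), y1 = c(1, 1, 2, 2),
    area_km2 = 1,
    population = c(1000, 2000, 3000, 4000),
    stringsAsFactors = FALSE)
  nb$popdens <- nb$population / nb$area_km2
  nb$dim_1 <- c(1, 2, 3, 4); nb$dim_2 <- c(2, 4, 6, 8)
  nb$dim_3 <- c(10, 20, 30, 40); nb$dim_4 <- c(0, 1, 2, 3)
  attr(nb, "crs") <- "planar_km"
  nb
}

test_that("the social environment index is the mean of pooled z-scores", {
  nb <- toy_neighbourhoods()
  sei <- social_environment_index(nb)$sei
  # all four dimensions are affinely identical, so sei = z of the common score
  expect_equal(sei, as.numeric(scale(nb$dim_1)))
  expect_lt(abs(mean(sei)), 1e-9)
  # affine rescaling of any dimension is absorbed
  nb2 <- nb; nb2$dim_3 <- nb$dim_3 * 17 - 123
  expect_equal(social_environment_index(nb2)$sei, sei)
  # sign flip for a deprivation-coded dimension
  nb3 <- nb; nb3$dim_2 <- -nb$dim_2
  dirs <- c(dim_1 = 1, dim_2 = -1, dim_3 = 1, dim_4 = 1)
  expect_equal(social_environment_index(nb3, dirs)$sei, sei)
})

test_that("degenerate index inputs fail loudly", {
  nb <- toy_neighbourhoods()
  nb$dim_2 <- 5
  expect_error(social_environment_index(nb), "dim_2")
  expect_error(social_environment_index(nb[1, ]), ">= 2")
})

test_that("points are assigned by containment with a min-id boundary tie-break", {
  nb <- toy_neighbourhoods()
  pts <- data.frame(x = c(0.5, 1.5, 1.0, 0.5, 5.0),
                    y = c(0.5, 0.5, 0.5, 1.0, 5.0))
  attr(pts, "crs") <- "planar_km"
  suppressMessages(a <- assign_points(pts, nb))
  expect_equal(as.character(a[1:2]), c("A", "B"))
  expect_equal(as.character(a[3]), "A")  # on A|B edge -> min(A, B)
  expect_equal(as.character(a[4]), "A")  # on A|C edge -> min(A, C)
  expect_true(is.na(a[5]))
  expect_equal(attr(a, "n_unassigned"), 1L)
  pts2 <- pts; attr(pts2, "crs") <- "lonlat"
  expect_error(assign_points(pts2, nb), "CRS mismatch")
})

test_that("uniform points over the tiling are all assigned, agreeing with brute force", {
  sim_nb <- generate_neighbourhoods(small_config(seed = 37))
  set.seed(37)
  idx <- sample(nrow(sim_nb), 200, replace = TRUE)
  pts <- data.frame(x = runif(200, sim_nb$x0[idx], sim_nb$x1[idx]),
                    y = runif(200, sim_nb$y0[idx], sim_nb$y1[idx]))
  attr(pts, "crs") <- "planar_km"
  a <- assign_points(pts, sim_nb)
  expect_equal(attr(a, "n_unassigned"), 0L)
  brute <- vapply(seq_len(200), function(i) {
    hits <- which(sim_nb$x0 <= pts$x[i] & pts$x[i] <= sim_nb$x1 &
                  sim_nb$y0 <= pts$y[i] & pts$y[i] <= sim_nb$y1)
    min(sim_nb$id[hits])
  }, character(1))
  expect_equal(as.character(a), brute)
})

test_that("densities are counts per area with the stated conservation rules", {
  expect_equal(compute_density(10, 2), 5)
  expect_equal(compute_density(0, 3), 0)
  expect_error(compute_density(1, 0), "positive")

  nb <- toy_neighbourhoods()
  est <- data.frame(
    x = c(rep(0.5, 3), rep(1.5, 2), 0.5, 3.0),
    y = c(rep(0.5, 3), rep(0.5, 2), 1.5, 3.0),
    category = c("supermarket", "supermarket", "unclassified",
                 "ready_for_consumption", "fast_food_chain",
                 "fruit_vegetable_store", "supermarket"),
    stringsAsFactors = FALSE)
  attr(est, "crs") <- "planar_km"
  suppressMessages(m <- neighbourhood_metrics(nb, est))
  # unclassified counts toward the total only
  expect_equal(m$density_total, c(3, 2, 1, 0))
  expect_equal(m$density_supermarket, c(2, 0, 0, 0))
  expect_equal(m$density_most_healthy, c(0, 0, 1, 0))
  expect_equal(m$density_mixed, c(2, 1, 0, 0))
  expect_equal(m$density_less_healthy, c(0, 1, 0, 0))
  # conservation: assigned + unassigned = registry
  expect_equal(sum(m$density_total * m$area_km2) + attr(m, "n_unassigned"),
               nrow(est))
  # category densities never exceed the total
  cat_cols <- paste0("density_", food_categories())
  expect_true(all(rowSums(m[cat_cols]) <= m$density_total + 1e-12))
})

test_that("doubling every area halves every density exactly", {
  nb <- toy_neighbourhoods()
  est <- data.frame(x = runif(40, 0, 2), y = runif(40, 0, 2),
                    category = sample(food_categories(), 40, replace = TRUE),
                    stringsAsFactors = FALSE)
  attr(est, "crs") <- "planar_km"
  m1 <- neighbourhood_metrics(nb, est)
  nb2 <- nb; nb2$area_km2 <- nb$area_km2 * 2
  m2 <- neighbourhood_metrics(nb2, est)
  for (dc in grep("^density_", names(m1), value = TRUE))
    expect_equal(m2[[dc]], m1[[dc]] / 2)
})

test_that("quartile tables stratify correctly and conserve row counts", {
  m <- data.frame(id = letters[1:8], popdens = 1:8, sei = 0,
                  density_total = 1:8)
  tab <- quartile_table(m, "popdens")
  expect_equal(tab$n, rep(2L, 4))
  expect_equal(sum(tab$n), 8)
  expect_equal(tab$density_total_mean, c(1.5, 3.5, 5.5, 7.5))
  expect_equal(tab$density_total_median, c(1.5, 3.5, 5.5, 7.5))
  suppressWarnings(expect_error(quartile_table(m, "sei"), "constant"))
  expect_error(quartile_table(m[1:3, ], "popdens"), ">= 4")
  m$popdens <- c(1, 1, 1, 1, 1, 2, 3, 4)
  expect_warning(quartile_table(m, "popdens"), "ties")
})

test_that("a positive SEI gradient shows up as a Q4 > Q1 median density contrast", {
  cfg <- city_config(n_neighbourhoods = 200, density_sei_gradient = 0.4,
                     seed = 41)
  nb <- generate_neighbourhoods(cfg)
  est <- generate_establishments(nb, cfg)
  est$category <- est$true_category
  m <- neighbourhood_metrics(nb, est)
  tab <- quartile_table(m, "sei")
  expect_gt(tab$density_total_median[4], tab$density_total_median[1])
})
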