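one_city_box <- function(xmax = 10, ymax = 10) {
  data.frame(city = "A", xmin = 0, ymin = 0, xmax = xmax, ymax = ymax)
}

tiny_registry <- function(n = 30, seed = 2, box = 10) {
  set.seed(seed)
  data.frame(est_id = sprintf("R%03d", seq_len(n)),
             name = paste("Supermercado", sprintf("Reg%03d", seq_len(n))),
             x = runif(n, 0, box), y = runif(n, 0, box),
             primary_type = "supermarket", secondary_types = "",
             stringsAsFactors = FALSE)
}

test_that("grid covers the box inclusive of edges in row-major order", {
  gs <- grid_spec(one_city_box(), spacing = 5, search_radius = 5)
  g <- make_grid(gs)
  expect_equal(nrow(g), 9)
  expect_equal(g$x[1:3], c(0, 5, 10))
  expect_equal(g$y[1:3], c(0, 0, 0))
  # extent not a multiple of the spacing: far edge appended
  gs2 <- grid_spec(one_city_box(12, 12), spacing = 5, search_radius = 5)
  g2 <- make_grid(gs2)
  expect_true(all(c(0, 5, 10, 12) %in% g2$x))
})

test_that("spacing beyond the box extent still emits corner and far-edge points", {
  gs <- grid_spec(one_city_box(3, 3), spacing = 10, search_radius = 8)
  g <- make_grid(gs)
  expect_equal(nrow(g), 4)
  expect_setequal(paste(g$x, g$y), c("0 0", "3 0", "0 3", "3 3"))
})

test_that("the coverage invariant is enforced and the disc union covers the box", {
  expect_error(grid_spec(one_city_box(), spacing = 2, search_radius = 1),
               "sqrt\\(2\\)")
  gs <- grid_spec(one_city_box(13, 9), spacing = 2, search_radius = 2 / sqrt(2))
  g <- make_grid(gs)
  set.seed(4)
  px <- runif(1e4, 0, 13); py <- runif(1e4, 0, 9)
  covered <- vapply(seq_along(px), function(i)
    any((g$x - px[i])^2 + (g$y - py[i])^2 <= gs$search_radius^2 + 1e-12),
    logical(1))
  expect_true(all(covered))
})

test_that("degenerate bounding box warns and collapses", {
  gs <- grid_spec(data.frame(city = "A", xmin = 1, ymin = 2, xmax = 1, ymax = 2),
                  spacing = 1, search_radius = 1)
  expect_warning(g <- make_grid(gs), "degenerate")
  expect_equal(nrow(g), 1)
})

test_that("the provider search respects term, radius and determinism", {
  reg <- tiny_registry()
  prov <- mock_provider(reg)
  r1 <- prov$search("supermercado", 5, 5, 20)
  expect_equal(nrow(r1), nrow(reg))        # name term matches all
  r2 <- prov$search("supermarket", 5, 5, 20)
  expect_equal(nrow(r2), nrow(reg))        # provider-type label matches all
  r3 <- prov$search("farmacia", 5, 5, 20)
  expect_equal(nrow(r3), 0)
  r4 <- prov$search("supermercado", 0, 0, 2)
  d <- sqrt(reg$x^2 + reg$y^2)
  expect_equal(sort(r4$provider_id), sort(reg$est_id[d <= 2]))
  expect_identical(r1, prov$search("supermercado", 5, 5, 20))  # idempotent
})

test_that("an empty term list is an error and a no-hit term yields zero records", {
  reg <- tiny_registry()
  prov <- mock_provider(reg)
  gs <- grid_spec(one_city_box(), spacing = 5, search_radius = 5)
  expect_error(run_query(prov, gs, character(0)), "non-empty")
  raw <- run_query(prov, gs, "farmacia")
  expect_equal(nrow(raw), 0)
  expect_equal(attr(raw, "n_failed_points"), 0)
})

test_that("provider failures are retried once then skipped, and the run continues", {
  reg <- tiny_registry()
  calls <- new.env(); calls$n <- 0L
  # fails permanently at the first grid point only
  prov <- mock_provider(reg, fail_at = function(term, x, y) {
    x == 0 && y == 0
  })
  gs <- grid_spec(one_city_box(), spacing = 10, search_radius = 10)
  expect_warning(raw <- run_query(prov, gs, "supermercado"), "skipped")
  expect_equal(attr(raw, "n_failed_points"), 1)
  # the other grid points still retrieve the whole registry
  expect_setequal(unique(raw$provider_id), reg$est_id)
})

test_that("dedup keeps one record per provider id, first occurrence wins", {
  reg <- tiny_registry(5)
  raw <- reg[rep(1:5, 4), ]
  names(raw)[names(raw) == "est_id"] <- "provider_id"
  out <- deduplicate(raw)
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "n_merged"), 15)
  expect_identical(deduplicate(out)$provider_id, out$provider_id)  # idempotent
})

test_that("id-less records merge by normalized name within epsilon only", {
  raw <- data.frame(
    provider_id = NA_character_,
    name = c("Almacén Don Pepe", "almacen  don pepe", "Almacén Don Pepe"),
    x = c(0, 0.010, 2), y = c(0, 0, 0),
    primary_type = "", secondary_types = "", stringsAsFactors = FALSE)
  out <- deduplicate(raw, epsilon_km = 0.025)
  # accent/case/whitespace variants 10 m apart merge; the 2 km branch stays
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$x), c(0, 2))
})

test_that("grid query retrieves exactly the registry and is monotone in terms", {
  reg <- tiny_registry(200, seed = 6)
  reg$name[1:50] <- paste("Panadería", sprintf("Reg%03d", 1:50))
  reg$primary_type[1:50] <- "bakery"
  prov <- mock_provider(reg)
  gs <- grid_spec(one_city_box(), spacing = 4, search_radius = 3)
  raw_half <- run_query(prov, gs, "supermercado")
  raw_full <- run_query(prov, gs, c("supermercado", "panadería"))
  got_half <- deduplicate(raw_half)
  got_full <- deduplicate(raw_full)
  expect_true(all(got_half$provider_id %in% got_full$provider_id))
  expect_setequal(got_full$provider_id, reg$est_id)          # completeness
  expect_equal(nrow(got_full), nrow(reg))                    # cardinality oracle
})
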