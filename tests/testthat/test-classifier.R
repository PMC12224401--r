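inv <- read_term_inventory()

test_that("the shipped inventory is well-formed", {
  expect_setequal(unique(inv$category), food_categories())
  expect_true(all(inv$match_kind %in% c("name", "provider_type", "both")))
  # >= 60 terms spanning all eight categories
  expect_gte(nrow(inv), 60)
})

test_that("name terms are the preferred source of classification", {
  expect_equal(classify("Supermercado El Sol"), "supermarket")
  expect_equal(classify("SUPERMERCADO EL SOL", "restaurant"), "supermarket")
  # accent folding: un-accented spelling still matches
  expect_equal(classify("Panaderia San Martín"), "fresh_food_retail")
  # conflicting provider label loses against the name term
  expect_equal(classify("Verdulería La Esquina", "fast_food_restaurant"),
               "fruit_vegetable_store")
})

test_that("provider types are the fallback and unclassified the residue", {
  expect_equal(classify("Donde Juanito", "restaurant"), "ready_for_consumption")
  expect_equal(classify("Donde Juanito", "establishment",
                        c("store", "bakery")), "fresh_food_retail")
  expect_equal(classify("Lola's"), "unclassified")
  expect_equal(classify("", ""), "unclassified")
  df <- classify_establishments(
    data.frame(name = c("Supermercado X", "Donde J", "Lola's"),
               primary_type = c("", "restaurant", ""),
               stringsAsFactors = FALSE), inv)
  expect_equal(df$match_path, c("name", "provider_primary", "none"))
})

test_that("matching is word-boundary, with priority then longest-term tie-breaks", {
  # 'supermercado' must not be matched by any shorter embedded term
  expect_equal(classify("Supermercado Central"), "supermarket")
  # multi-word term beats its shorter substring term by priority/length
  expect_equal(classify("Tienda de Abarrotes El Valle"), "small_food_retail")
  # a name with terms of two categories: higher priority wins
  expect_equal(classify("Minimarket OXXO"), "convenience_store")
})

test_that("classification is deterministic and order-invariant", {
  sim <- simulate_city(small_config(seed = 23))
  est <- sim$establishments
  a <- classify_establishments(est, inv)
  perm <- sample(nrow(est))
  b <- classify_establishments(est[perm, ], inv)
  expect_equal(a$category[perm], b$category)
})

test_that("category counts plus unclassified always conserve the total", {
  sim <- simulate_city(small_config(seed = 29))
  cl <- classify_establishments(sim$establishments, inv)
  s <- classification_summary(cl)
  expect_equal(sum(s$by_category$n) + s$n_unclassified, nrow(cl))
  expect_equal(sum(s$by_health_group$n), s$n_classified)
  expect_setequal(s$by_health_group$health_group, health_groups())
})

test_that("noise-free generation with a 3% ambiguous share classifies about 97%", {
  cfg <- city_config(n_neighbourhoods = 400, label_noise_rate = 0,
                     ambiguous_fraction = 0.03, seed = 31)
  est <- generate_establishments(generate_neighbourhoods(cfg), cfg)
  s <- classification_summary(classify_establishments(est, inv))
  expect_gt(s$pct_classified, 95)
  expect_lt(s$pct_classified, 99)
  # with no noise, classified records recover the generating category
  cl <- classify_establishments(est, inv)
  ok <- cl$category != "unclassified"
  expect_true(all(cl$category[ok] == cl$true_category[ok]))
})

test_that("summary proportions are over classified establishments only", {
  df <- data.frame(category = c(rep("ready_for_consumption", 6),
                                rep("small_food_retail", 4),
                                rep("unclassified", 2)))
  s <- classification_summary(df)
  expect_equal(s$n_total, 12)
  expect_equal(s$n_unclassified, 2)
  expect_equal(s$by_category$pct[s$by_category$category == "ready_for_consumption"], 60)
  expect_equal(s$by_category$pct[s$by_category$category == "small_food_retail"], 40)
})

test_that("an all-unclassified input reports undefined proportions", {
  s <- classification_summary(data.frame(category = rep("unclassified", 3)))
  expect_equal(s$n_classified, 0)
  expect_true(all(is.na(s$by_category$pct)))
  expect_warning(classification_summary(data.frame(category = character(0))),
                 "empty")
})

test_that("health groups partition the eight categories as fixed", {
  expect_equal(health_group("fruit_vegetable_store"), "most_healthy")
  expect_equal(health_group("fresh_food_retail"), "most_healthy")
  expect_equal(health_group(c("small_food_retail", "supermarket",
                              "ready_for_consumption")),
               rep("mixed", 3))
  expect_equal(health_group(c("candy_ice_cream", "fast_food_chain",
                              "convenience_store")),
               rep("less_healthy", 3))
  expect_error(health_group("unclassified"), "exclude")
  expect_error(health_group("bodega"), "unknown")
  # partition: every category maps to exactly one of the three groups
  expect_setequal(unique(health_group(food_categories())), health_groups())
})

test_that("the review queue lists unclassified records with nearest-miss terms", {
  df <- classify_establishments(
    data.frame(name = c("Supermercado X", "Panadera Rosa", "Zzz Qqq"),
               primary_type = "", stringsAsFactors = FALSE), inv)
  q <- review_queue(df, inv)
  expect_equal(nrow(q), 2)
  expect_equal(q$nearest_term[q$name == "Panadera Rosa"], "panaderia")
  expect_equal(q$nearest_distance[q$name == "Panadera Rosa"], 1)
})
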