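model <- read_npm_model(emr_model_file())

test_that("auto-prohibited categories are rejected regardless of composition", {
  withr::local_seed(11)
  for (cid in c("1", "3a", "3d", "4", "6", "14")) {
    prods <- random_products(10, model)
    prods$category_id <- cid
    dec <- evaluate_products(prods, model)
    expect_true(all(!dec$permitted))
    expect_true(all(dec$status == "not_permitted"))
    # exactly one violation, the category rule itself
    expect_true(all(vapply(dec$violations, nrow, integer(1)) == 1))
    expect_true(all(vapply(dec$violations, function(v) v$rule_id, character(1)) ==
                      "auto_category"))
  }
})

test_that("global trans-fat and alcohol rules apply at their stated boundaries", {
  base <- tiny_products()[1, ]  # all-zero water profile, category 3e
  base$category_id <- "9"
  base$basis <- "per_100_g"

  tfa_at <- dplyr::mutate(base, industrial_tfa_g_per_100g_fat = 1)
  expect_true(evaluate_product(tfa_at, model)$permitted)   # > 1 fails, = 1 passes
  tfa_over <- dplyr::mutate(base, industrial_tfa_g_per_100g_fat = 1.01)
  d <- evaluate_product(tfa_over, model)
  expect_false(d$permitted)
  expect_true("trans_fat" %in% d$violations[[1]]$rule_id)

  alc_at <- dplyr::mutate(base, alcohol_pct_energy = 0.5)
  d <- evaluate_product(alc_at, model)                     # >= 0.5 fails exactly
  expect_false(d$permitted)
  expect_equal(d$violations[[1]]$rule_id, "alcohol_energy")
  alc_under <- dplyr::mutate(base, alcohol_pct_energy = 0.49)
  expect_true(evaluate_product(alc_under, model)$permitted)
})

test_that("threshold comparison is strict: equal to threshold passes", {
  thr <- model$thresholds[[match("2", model$category_id)]]
  prod <- tiny_products()[1, ]
  prod$category_id <- "2"
  prod$basis <- "per_100_g"
  for (k in names(thr)) prod[[k]] <- thr[[k]]
  prod <- dplyr::mutate(prod, total_fat_g = max(total_fat_g, saturated_fat_g),
                        total_sugars_g = max(total_sugars_g, added_sugars_g))
  expect_true(evaluate_product(prod, model)$permitted)
  over <- prod
  over$salt_g <- thr[["salt_g"]] + 0.001
  d <- evaluate_product(over, model)
  expect_false(d$permitted)
  expect_equal(d$violations[[1]]$key, "salt_g")
})

test_that("an all-zero mineral-water profile in beverages subcategory 3e is permitted", {
  water <- tiny_products()[1, ]
  expect_true(evaluate_product(water, model)$permitted)
})

test_that("sweetener prohibition only binds where the category declares it", {
  sweet <- dplyr::mutate(tiny_products()[1, ], has_nonsugar_sweeteners = TRUE)
  d <- evaluate_product(sweet, model)  # 3e prohibits sweeteners
  expect_false(d$permitted)
  expect_true("sweetener" %in% d$violations[[1]]$rule_id)
  sweet$category_id <- "9"             # cheeses do not
  sweet$basis <- "per_100_g"
  expect_true(evaluate_product(sweet, model)$permitted)
})

test_that("missing applicable composition is insufficient data, not a verdict", {
  p <- tiny_products()[1, ]
  p$category_id <- "2"
  p$basis <- "per_100_g"
  p$salt_g <- NA_real_
  expect_error(evaluate_product(p, model), "insufficient",
               class = "npmtv_insufficient_data")
  dec <- evaluate_products(p, model)
  expect_identical(dec$status, "insufficient_data")
  expect_true(is.na(dec$permitted))
  # a nutrient not applicable to the category may be missing freely
  q <- tiny_products()[1, ]
  q$category_id <- "9"
  q$basis <- "per_100_g"
  q$energy_kcal <- NA_real_  # cheeses: only fat and salt thresholds apply
  expect_true(evaluate_product(q, model)$permitted)
})

test_that("extension categories are not assessable under the model basis", {
  beer <- tiny_products()[3, ]
  d <- evaluate_product(beer, model)
  expect_false(d$assessable)
  expect_identical(d$status, "not_assessable")
  expect_true(is.na(d$permitted))
})

test_that("unknown categories are an error", {
  p <- dplyr::mutate(tiny_products()[1, ], category_id = "99")
  expect_error(evaluate_product(p, model), "unknown category",
               class = "npmtv_model_error")
})

test_that("verdicts match the brute-force rule oracle on fuzzed products", {
  withr::local_seed(202)
  prods <- dplyr::bind_rows(
    random_products(200, model),
    random_products(50, model, p_missing = 0.15)
  )
  prods$product_id <- paste0(prods$product_id, "-", seq_len(nrow(prods)))
  dec <- evaluate_products(prods, model)
  expected <- vapply(seq_len(nrow(prods)),
                     function(i) oracle_decide(as.list(prods[i, ]), model),
                     character(1))
  expect_identical(dec$status, expected)
  # verdict/violation consistency on every fuzzed input
  n_viol <- vapply(dec$violations, function(v) sum(v$rule_id != "missing_value"),
                   integer(1))
  decided <- dec$status %in% c("permitted", "not_permitted")
  expect_identical(dec$permitted[decided], n_viol[decided] == 0)
})

test_that("verdicts are monotone in the applicable nutrients", {
  withr::local_seed(31)
  non_auto <- model$category_id[!model$auto_not_permitted & model$is_model_category]
  for (rep in 1:40) {
    cid <- sample(non_auto, 1)
    thr <- model$thresholds[[match(cid, model$category_id)]]
    p <- random_products(1, model)
    p$category_id <- cid
    # floor the product at compliance: every rule satisfied -> permitted
    for (k in names(thr)) p[[k]] <- thr[[k]] * runif(1)
    p$industrial_tfa_g_per_100g_fat <- runif(1)
    p$alcohol_pct_energy <- runif(1, 0, 0.49)
    p$has_nonsugar_sweeteners <- FALSE
    p$saturated_fat_g <- min(p$saturated_fat_g, p$total_fat_g)
    p$added_sugars_g <- min(p$added_sugars_g, p$total_sugars_g)
    expect_true(evaluate_products(p, model)$permitted)
    if (length(thr)) {
      # raising any single applicable nutrient above threshold flips it
      k <- sample(names(thr), 1)
      worse <- p
      worse[[k]] <- thr[[k]] + runif(1, 0.01, 10)
      worse$total_fat_g <- max(worse$total_fat_g, worse$saturated_fat_g)
      worse$total_sugars_g <- max(worse$total_sugars_g, worse$added_sugars_g)
      expect_false(evaluate_products(worse, model)$permitted)
    }
  }
})

test_that("a composite meal is the conjunction of its component verdicts", {
  prods <- tiny_products()
  ok2 <- dplyr::mutate(prods[1, ], product_id = "water2")
  processed <- dplyr::mutate(prods[1, ], product_id = "salami",
                             category_id = "14", basis = "per_100_g")
  catalogue <- dplyr::bind_rows(prods, ok2, processed)

  both_ok <- tibble::tibble(meal_id = "m1",
                            component_product_id = c("water", "water2"))
  d <- evaluate_composite(both_ok, model, catalogue)
  expect_true(d$permitted)
  expect_equal(nrow(d$violations[[1]]), 0)

  with_processed <- tibble::tibble(meal_id = "m2",
                                   component_product_id = c("water", "salami"))
  d <- evaluate_composite(with_processed, model, catalogue)
  expect_false(d$permitted)
  expect_equal(d$violations[[1]]$rule_id, "component_failed")
  expect_equal(d$violations[[1]]$key, "salami")

  expect_error(evaluate_composite(both_ok[0, ], model, catalogue), "empty",
               class = "npmtv_validation_error")
  expect_error(
    evaluate_composite(tibble::tibble(meal_id = "m3",
                                      component_product_id = "ghost"),
                       model, catalogue),
    "unresolved", class = "npmtv_validation_error"
  )
})

test_that("random composites equal the AND of per-component verdicts", {
  withr::local_seed(77)
  prods <- random_products(60, model)
  prods <- prods[!is.na(prods$product_id), ]
  dec <- evaluate_products(prods, model)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    comp_ids <- sample(prods$product_id, k)
    comps <- tibble::tibble(meal_id = "meal", component_product_id = comp_ids)
    meal <- evaluate_composite(comps, model, prods)
    part <- dec$status[match(comp_ids, dec$product_id)]
    expected <- if (any(part == "insufficient_data")) {
      "insufficient_data"
    } else if (all(part == "permitted")) "permitted" else "not_permitted"
    expect_identical(meal$status, expected)
  }
})
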