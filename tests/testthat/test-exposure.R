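# Expected values below are hand-computed from the tiny corpus:
# C: 2 food (both claims) + 3 nonfood; G week1: 4 choc + 2 beer (disclaimers)
# + 6 nonfood; G week2: 1 choc + 2 nonfood. Blocks: C 2 h, G 4 + 2 h.
model <- read_npm_model(emr_model_file())

test_that("food-ad shares are exact ratios at one-decimal half-up rounding", {
  ads <- tiny_corpus()
  overall <- food_ad_share(ads)
  expect_equal(overall$n_food, 9)
  expect_equal(overall$n_total, 20)
  expect_equal(overall$pct, 45.0)
  by_rating <- food_ad_share(ads, by = "rating")
  expect_equal(by_rating$pct[by_rating$program_rating == "C"],
               round(100 * 2 / 5, 1))
  rw <- food_ad_share(ads, by = "rating_week")
  expect_equal(rw$pct[rw$program_rating == "G" & rw$week_id == 2],
               round(100 * 1 / 3, 1))
})

test_that("a stratum with no food ads reports a 0% share", {
  ads <- dplyr::mutate(tiny_corpus(),
                       ad_class = ifelse(program_rating == "C", "nonfood", ad_class),
                       product_id = ifelse(program_rating == "C", NA, product_id),
                       category_id = ifelse(program_rating == "C", NA, category_id),
                       has_claim = ifelse(program_rating == "C", FALSE, has_claim))
  by_rating <- food_ad_share(ads, by = "rating")
  expect_equal(by_rating$pct[by_rating$program_rating == "C"], 0)
})

test_that("hourly frequencies divide food counts by analyzed hours", {
  ads <- tiny_corpus()
  blocks <- tiny_blocks()
  overall <- hourly_frequency(ads, blocks)
  expect_equal(overall$freq_per_hour, round_half_up(9 / 8, 1))
  by_rating <- hourly_frequency(ads, blocks, by = "rating")
  expect_equal(by_rating$freq_per_hour[by_rating$program_rating == "G"],
               round_half_up(7 / 6, 1))
  # zero food ads over positive hours is a 0.0 rate, not an error
  nofood <- dplyr::filter(ads, ad_class == "nonfood")
  expect_equal(hourly_frequency(nofood, blocks)$freq_per_hour, 0)
})

test_that("category distributions normalize within stratum to the column sums", {
  ads <- tiny_corpus()
  cd <- category_distribution(ads, by = "rating")
  g <- cd[cd$program_rating == "G", ]
  expect_equal(sum(g$n), 7)
  expect_equal(unique(g$total), 7)
  expect_equal(g$pct[g$category_id == "1"], round_half_up(100 * 5 / 7, 1))
  single <- category_distribution(dplyr::filter(ads, category_id == "1"),
                                  by = "overall")
  expect_equal(single$pct, 100)
})

test_that("uncategorized food records are excluded loudly from category shares", {
  ads <- tiny_corpus()
  ads$category_id[1] <- NA
  ads$product_id[1] <- "mystery"
  expect_warning(cd <- category_distribution(ads, by = "overall"), "exclude")
  expect_equal(unique(cd$total), 8)
})

test_that("permitted shares partition the basis denominator", {
  ads <- tiny_corpus()
  prods <- tiny_products()
  emr <- permitted_share(ads, prods, model, basis = "emr18")
  ov <- emr[emr$program_rating == "overall", ]
  # beer (category 19) is outside the 18-category basis
  expect_equal(ov$n_food, 7)
  expect_equal(ov$n_permitted, 2)   # the two water ads
  expect_equal(ov$n_not_permitted, 5)
  expect_equal(ov$pct_permitted, round_half_up(100 * 2 / 7, 1))
  expect_equal(ov$n_permitted + ov$n_not_permitted + ov$n_insufficient, ov$n_food)

  ext <- permitted_share(ads, prods, model, basis = "extended")
  ove <- ext[ext$program_rating == "overall", ]
  expect_equal(ove$n_food, 9)
  expect_equal(ove$n_not_permitted, 7)
  expect_equal(ove$pct_not_permitted, round_half_up(100 * 7 / 9, 1))
})

test_that("extended-basis not-permitted equals the model basis plus extensions", {
  withr::local_seed(5)
  sim <- generate_corpus(sim_config(rng_seed = 5))
  emr <- permitted_share(sim$ads, sim$products, model, basis = "emr18")
  ext <- permitted_share(sim$ads, sim$products, model, basis = "extended")
  n_ext_ads <- sum(sim$ads$category_id %in% c("19", "20"), na.rm = TRUE)
  for (r in intersect(c("C", "G", "PG", "overall"), emr$program_rating)) {
    a <- emr[emr$program_rating == r, ]
    b <- ext[ext$program_rating == r, ]
    n_ext_r <- if (r == "overall") n_ext_ads else {
      sum(sim$ads$category_id %in% c("19", "20") &
            sim$ads$program_rating == r, na.rm = TRUE)
    }
    expect_equal(b$n_not_permitted, a$n_not_permitted + n_ext_r)
    expect_equal(b$n_permitted, a$n_permitted)
  }
})

test_that("data-insufficient products are reported, never silently dropped", {
  ads <- tiny_corpus()
  prods <- tiny_products()
  prods$energy_kcal[1] <- NA_real_  # water: 3e requires energy
  emr <- permitted_share(ads, prods, model, basis = "emr18")
  ov <- emr[emr$program_rating == "overall", ]
  expect_equal(ov$n_insufficient, 2)
  expect_equal(ov$n_permitted + ov$n_not_permitted + ov$n_insufficient, ov$n_food)
})

test_that("unresolved products abort the permitted-share computation", {
  ads <- tiny_corpus()
  prods <- tiny_products()[-1, ]
  expect_error(permitted_share(ads, prods, model), "missing from the catalogue",
               class = "npmtv_validation_error")
})

test_that("claim and disclaimer shares use food-ad denominators at 2 dp", {
  ads <- tiny_corpus()
  cl <- claims_share(ads)
  expect_equal(cl$n, 2)
  expect_equal(cl$n_food, 9)
  expect_equal(cl$pct, round_half_up(100 * 2 / 9, 2))
  dc <- disclaimers_share(ads, by = "rating")
  expect_equal(dc$pct[dc$program_rating == "G"], round_half_up(100 * 2 / 7, 2))
  expect_equal(dc$pct[dc$program_rating == "C"], 0)
})

test_that("table builders are pure: identical inputs give identical tables", {
  ads <- tiny_corpus()
  expect_identical(food_ad_share(ads, by = "rating_week"),
                   food_ad_share(ads, by = "rating_week"))
  expect_identical(claims_share(ads, by = "rating"), claims_share(ads, by = "rating"))
})

test_that("half-up rounding matches the table conventions", {
  expect_equal(round_half_up(16.35, 1), 16.4)   # round() would give 16.3
  expect_equal(round_half_up(14.285, 2), 14.29)
  expect_equal(round_half_up(-0.5, 0), -1)
  expect_equal(round_half_up(2.44999, 1), 2.4)
})
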