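# Independent brute-force oracle: re-checks every marketing rule with plain
# base-R conditionals, one product at a time. Deliberately written without the
# package's engine internals so the two can disagree.

oracle_decide <- function(p, model) {
  i <- which(model$category_id == p$category_id)
  stopifnot(length(i) == 1)
  if (!model$is_model_category[i]) {
    return("not_assessable")
  }
  if (model$auto_not_permitted[i]) {
    return("not_permitted")
  }
  thr <- model$thresholds[[i]]
  fields <- c("industrial_tfa_g_per_100g_fat", "alcohol_pct_energy", names(thr))
  if (model$sweeteners_prohibited[i]) fields <- c(fields, "has_nonsugar_sweeteners")
  for (f in fields) {
    if (is.na(p[[f]])) return("insufficient_data")
  }
  failed <- FALSE
  if (p$industrial_tfa_g_per_100g_fat > 1) failed <- TRUE
  if (p$alcohol_pct_energy >= 0.5) failed <- TRUE
  if (model$sweeteners_prohibited[i] && p$has_nonsugar_sweeteners) failed <- TRUE
  for (k in names(thr)) {
    if (p[[k]] > thr[[k]]) failed <- TRUE
  }
  if (failed) "not_permitted" else "permitted"
}

# random product rows honouring the composition invariants; with
# p_missing > 0 some nutrient fields are knocked out to NA
random_products <- function(n, model, p_missing = 0) {
  cats <- model$category_id
  rows <- lapply(seq_len(n), function(i) {
    total_fat <- runif(1, 0, 40)
    sugars <- runif(1, 0, 60)
    p <- list(
      product_id = paste0("fz-", i),
      brand = "fuzz",
      category_id = sample(cats, 1),
      basis = sample(c("per_100_g", "per_100_mL"), 1),
      energy_kcal = runif(1, 0, 600),
      total_fat_g = total_fat,
      saturated_fat_g = runif(1, 0, total_fat),
      industrial_tfa_g_per_100g_fat = rexp(1, 2),
      total_sugars_g = sugars,
      added_sugars_g = runif(1, 0, sugars),
      has_nonsugar_sweeteners = runif(1) < 0.3,
      salt_g = runif(1, 0, 3),
      alcohol_pct_energy = if (runif(1) < 0.15) runif(1, 0, 5) else 0,
      composition_source = "label",
      salt_from_sodium = FALSE
    )
    if (p_missing > 0) {
      for (k in c("energy_kcal", "total_fat_g", "saturated_fat_g",
                  "total_sugars_g", "added_sugars_g", "salt_g",
                  "industrial_tfa_g_per_100g_fat", "alcohol_pct_energy")) {
        if (runif(1) < p_missing) p[[k]] <- NA_real_
      }
    }
    tibble::as_tibble(p)
  })
  dplyr::bind_rows(rows)
}

# a hand-sized corpus with known counts, used by the exposure tests
tiny_corpus <- function() {
  mk <- function(rating, week, class, product = NA, category = NA,
                 claim = FALSE, disc = FALSE, n = 1) {
    tibble::tibble(
      channel = "A", week_id = as.integer(week), day_kind = "weekday",
      airtime = "16:00", program_rating = rating, ad_class = class,
      product_id = as.character(product), category_id = as.character(category),
      has_claim = claim, has_disclaimer = disc,
      claim_text = NA_character_
    )[rep(1L, n), ]
  }
  dplyr::bind_rows(
    mk("C", 1, "food", "water", "3e", claim = TRUE, n = 2),
    mk("C", 1, "nonfood", n = 3),
    mk("G", 1, "food", "choc", "1", n = 4),
    mk("G", 1, "food", "beer", "19", disc = TRUE, n = 2),
    mk("G", 1, "nonfood", n = 6),
    mk("G", 2, "food", "choc", "1", n = 1),
    mk("G", 2, "nonfood", n = 2)
  )
}

tiny_blocks <- function() {
  tibble::tibble(
    channel = "A",
    week_id = c(1L, 1L, 2L),
    program_rating = c("C", "G", "G"),
    hours_analyzed = c(2, 4, 2)
  )
}

tiny_products <- function() {
  tibble::tibble(
    product_id = c("water", "choc", "beer"),
    brand = "t", category_id = c("3e", "1", "19"),
    basis = c("per_100_mL", "per_100_g", "per_100_mL"),
    energy_kcal = 0, total_fat_g = 0, saturated_fat_g = 0,
    industrial_tfa_g_per_100g_fat = 0, total_sugars_g = 0,
    added_sugars_g = 0, has_nonsugar_sweeteners = FALSE, salt_g = 0,
    alcohol_pct_energy = c(0, 0, 40), composition_source = "label",
    salt_from_sodium = FALSE
  )
}
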