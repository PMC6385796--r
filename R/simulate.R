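#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic broadcast-log
#' generator. The defaults emulate the study conditions of a three-channel,
#' four-week children's-viewing-time sampling frame: three weekdays (window
#' 15:00-22:00) and one weekend day (window 08:00-22:00) per week, C/G/PG
#' program blocks with hours heavily skewed toward G and PG, around 20
#' advertisements per analyzed hour, per-rating food-ad probabilities of
#' 0.43 (C), 0.32 (G) and 0.29 (PG), a food-category mixture matching the
#' observed corpus (confectionery and sweet baked goods dominant, alcoholic
#' drinks and coffee present in G/PG airtime), and claim/disclaimer rates of
#' 0.18 and 0.04 among food advertisements.
#'
#' @param n_channels Number of broadcast channels (labelled `A`, `B`, ...).
#' @param n_weeks Number of study weeks.
#' @param hours_per_channel_week Expected analyzed hours per channel per week.
#' @param rating_hour_mix Named proportions of analyzed hours by rating
#'   (must sum to 1).
#' @param ads_per_hour Expected advertisements per analyzed hour.
#' @param food_p Named per-rating probability that an advertisement is for
#'   food or drink.
#' @param category_mix Named mixture over category ids for food
#'   advertisements (must sum to 1).
#' @param claim_rate,disclaimer_rate Bernoulli rates of health/nutrition
#'   claims and disclaimers among food advertisements.
#' @param straddle_margin Relative margin by which generated passing products
#'   sit below, and failing products above, the category thresholds.
#' @param p_product_below Probability that a generated non-auto product is the
#'   below-threshold (permitted) variant.
#' @param rng_seed Mandatory integer seed; corpora are byte-identical across
#'   runs with equal seeds.
#' @return A validated config object (class `npmtv_sim_config`).
#' @export
sim_config <- function(n_channels = 3,
                       n_weeks = 4,
                       hours_per_channel_week = 20.6,
                       rating_hour_mix = c(C = 0.048, G = 0.588, PG = 0.364),
                       ads_per_hour = 19.9,
                       food_p = c(C = 0.432, G = 0.320, PG = 0.288),
                       category_mix = default_category_mix(),
                       claim_rate = 0.179,
                       disclaimer_rate = 0.039,
                       straddle_margin = 0.25,
                       p_product_below = 0.3,
                       rng_seed = NULL) {
  if (is.null(rng_seed)) {
    rlang::abort("rng_seed is mandatory: seeded generation is the reproducibility contract",
                 class = "npmtv_validation_error")
  }
  probs <- c(claim_rate, disclaimer_rate, straddle_margin, p_product_below, food_p)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("rates, probabilities and margins must lie in [0, 1]",
                 class = "npmtv_validation_error")
  }
  if (!setequal(names(food_p), RATINGS) || !setequal(names(rating_hour_mix), RATINGS)) {
    rlang::abort("food_p and rating_hour_mix need entries for C, G and PG",
                 class = "npmtv_validation_error")
  }
  if (sum(category_mix) <= 0) {
    rlang::abort("degenerate category mixture: all weights zero",
                 class = "npmtv_validation_error")
  }
  if (abs(sum(rating_hour_mix) - 1) > 1e-8) {
    rlang::abort("rating_hour_mix must sum to 1", class = "npmtv_validation_error")
  }
  category_mix <- category_mix / sum(category_mix)
  structure(
    list(
      n_channels = as.integer(n_channels), n_weeks = as.integer(n_weeks),
      hours_per_channel_week = hours_per_channel_week,
      rating_hour_mix = rating_hour_mix[RATINGS],
      ads_per_hour = ads_per_hour, food_p = food_p[RATINGS],
      category_mix = category_mix, claim_rate = claim_rate,
      disclaimer_rate = disclaimer_rate, straddle_margin = straddle_margin,
      p_product_below = p_product_below, rng_seed = as.integer(rng_seed)
    ),
    class = "npmtv_sim_config"
  )
}

# observed corpus composition over the advertised categories
default_category_mix <- function() {
  c("1" = 208, "2" = 104, "3a" = 11, "3c" = 52, "3d" = 42, "3e" = 59,
    "5" = 4, "6" = 255, "8" = 28, "9" = 71, "10" = 19, "12" = 2,
    "13" = 131, "14" = 40, "18" = 45, "19" = 228, "20" = 137) / 1436
}

#' Generate a synthetic broadcast corpus
#'
#' Draws an analyzed-hours table, a coded advertisement log and a matching
#' product catalogue from the configured sampling frame. Per channel-week the
#' analyzed hours are jittered around their expectation and split over ratings
#' by the configured mix; advertisement counts per block are Poisson in the
#' analyzed hours; each advertisement is food with the rating's probability;
#' food advertisements draw a category from the mixture, a product uniformly
#' from that category's generated products, and claim/disclaimer flags as
#' independent Bernoullis. Generated products in non-auto categories straddle
#' their category thresholds at the configured margin (below-threshold
#' variants are permitted, above-threshold variants are not); products in
#' auto-prohibited categories get arbitrary composition since their verdict
#' is composition-independent.
#'
#' @param config A [sim_config()] object.
#' @param model Model tibble the catalogue is generated against; defaults to
#'   the shipped reference instance.
#' @return A list with `ads`, `blocks`, `products` (the same dialects consumed
#'   by the analysis functions) and `config`.
#' @examples
#' sim <- generate_corpus(sim_config(rng_seed = 1))
#' food_ad_share(sim$ads)
#' @export
generate_corpus <- function(config, model = read_npm_model(emr_model_file())) {
  stopifnot(inherits(config, "npmtv_sim_config"))
  withr::with_seed(config$rng_seed, {
    products <- sim_products(config, model)
    blocks <- sim_blocks(config)
    ads <- sim_ads(config, blocks, products)
    list(ads = ads, blocks = blocks, products = products, config = config)
  })
}

sim_blocks <- function(config) {
  grid <- tidyr::expand_grid(
    channel = LETTERS[seq_len(config$n_channels)],
    week_id = seq_len(config$n_weeks)
  )
  # +/-10% jitter keeps hours fractional and channel-weeks unequal
  total <- config$hours_per_channel_week *
    stats::runif(nrow(grid), 0.9, 1.1)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    tibble::tibble(
      channel = grid$channel[[i]],
      week_id = as.integer(grid$week_id[[i]]),
      program_rating = RATINGS,
      hours_analyzed = unname(round(total[[i]] * config$rating_hour_mix, 2))
    )
  }) |>
    dplyr::filter(hours_analyzed > 0)
}

sim_products <- function(config, model) {
  m <- config$straddle_margin
  liquid <- c("3a", "3b", "3c", "3d", "3e", "19", "20")
  purrr::map_dfr(names(config$category_mix), function(cid) {
    i <- match(cid, model$category_id)
    if (is.na(i)) {
      rlang::abort(paste0("category_mix references unknown category ", cid),
                   class = "npmtv_model_error")
    }
    basis <- if (cid %in% liquid) "per_100_mL" else "per_100_g"
    blank <- tibble::tibble(
      brand = "sim", category_id = cid, basis = basis,
      energy_kcal = 0, total_fat_g = 0, saturated_fat_g = 0,
      industrial_tfa_g_per_100g_fat = 0, total_sugars_g = 0,
      added_sugars_g = 0, has_nonsugar_sweeteners = FALSE, salt_g = 0,
      alcohol_pct_energy = 0, composition_source = "label",
      salt_from_sodium = FALSE
    )
    if (model$auto_not_permitted[[i]] || !model$is_model_category[[i]]) {
      # composition never drives the verdict here; draw it freely
      p <- blank
      p$energy_kcal <- round(stats::runif(1, 0, 600), 1)
      p$total_fat_g <- round(stats::runif(1, 0, 40), 1)
      p$saturated_fat_g <- round(stats::runif(1, 0, p$total_fat_g), 1)
      p$total_sugars_g <- round(stats::runif(1, 0, 60), 1)
      p$added_sugars_g <- round(stats::runif(1, 0, p$total_sugars_g), 1)
      p$salt_g <- round(stats::runif(1, 0, 3), 2)
      return(dplyr::mutate(p, product_id = paste0("sim-", cid, "-1")))
    }
    thr <- model$thresholds[[i]]
    make <- function(suffix, above) {
      p <- blank
      for (k in names(thr)) {
        p[[k]] <- if (above) thr[[k]] * (1 + m) + m else thr[[k]] * (1 - m)
      }
      if (above && !length(thr)) p$industrial_tfa_g_per_100g_fat <- 1 + m
      p <- repair_profile(p)
      dplyr::mutate(p, product_id = paste0("sim-", cid, "-", suffix))
    }
    dplyr::bind_rows(make("below", FALSE), make("above", TRUE))
  }) |>
    dplyr::select(dplyr::all_of(PRODUCT_COLS), salt_from_sodium)
}

sim_ads <- function(config, blocks, products) {
  by_cat <- split(products$product_id, products$category_id)
  cat_ids <- names(config$category_mix)
  purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    n <- stats::rpois(1, config$ads_per_hour * b$hours_analyzed)
    if (n == 0) return(NULL)
    is_food <- stats::runif(n) < config$food_p[[b$program_rating]]
    cat_vec <- rep(NA_character_, n)
    prod_vec <- rep(NA_character_, n)
    if (any(is_food)) {
      draw <- sample(cat_ids, sum(is_food), replace = TRUE,
                     prob = config$category_mix)
      cat_vec[is_food] <- draw
      prod_vec[is_food] <- vapply(draw, function(cid) {
        pool <- by_cat[[cid]]
        below <- grepl("-below$", pool)
        if (any(below) && length(pool) > 1) {
          if (stats::runif(1) < config$p_product_below) pool[below][1] else pool[!below][1]
        } else {
          pool[[sample.int(length(pool), 1)]]
        }
      }, character(1))
    }
    day_kind <- sample(DAY_KINDS, n, replace = TRUE, prob = c(21, 14) / 35)
    w <- WINDOWS
    mins <- ifelse(
      day_kind == "weekday",
      w$weekday[1] + floor(stats::runif(n) * (w$weekday[2] - w$weekday[1])),
      w$weekend[1] + floor(stats::runif(n) * (w$weekend[2] - w$weekend[1]))
    )
    tibble::tibble(
      channel = b$channel,
      week_id = b$week_id,
      day_kind = day_kind,
      airtime = minutes_to_hhmm(as.integer(mins)),
      program_rating = b$program_rating,
      ad_class = ifelse(is_food, "food", "nonfood"),
      product_id = prod_vec,
      category_id = cat_vec,
      has_claim = is_food & stats::runif(n) < config$claim_rate,
      has_disclaimer = is_food & stats::runif(n) < config$disclaimer_rate,
      claim_text = NA_character_
    )
  })
}
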