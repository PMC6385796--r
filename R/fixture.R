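#' Deterministic reference corpus
#'
#' Builds, entirely in code and without randomness, a benchmark broadcast
#' corpus whose marginal counts equal the embedded reference tables: 4,510
#' advertisements (1,393 food) over 226.46 analyzed hours across 3 channels,
#' 4 study weeks and C/G/PG program ratings, with per-rating-by-week totals,
#' per-category counts, claim/disclaimer counts and permitted/not-permitted
#' counts all fixed. The product catalogue is constructed against the shipped
#' model instance so that the decision engine — not a lookup — reproduces the
#' permitted counts (0 of 35 C, 88 of 596 G, 80 of 397 PG under the
#' 18-category basis).
#'
#' Only marginals are fixed; the joint allocation of categories, claims and
#' products to rating-by-week cells is a documented deterministic greedy fill
#' and is not unique.
#'
#' The source tabulation is internally inconsistent in one place: the
#' per-category counts sum to 36/845/555 per rating, while the food-ad totals
#' are 35/818/540. The main `ads` table is consistent with the food-ad totals
#' (per-category counts reduced by a deterministic greedy rule: repeatedly
#' decrement the largest category, ties to the lower id; extension categories
#' 19/20 are kept exact). A separate `category_ads` view carries the
#' per-category counts exactly and is intended only for
#' [category_distribution()]. The discrepancy is surfaced in `meta`.
#'
#' @return A list with elements `ads`, `blocks`, `products`, `model`,
#'   `category_ads` and `meta`.
#' @examples
#' fx <- reference_corpus()
#' nrow(fx$ads)                      # 4510
#' sum(fx$ads$ad_class == "food")    # 1393
#' @export
reference_corpus <- function() {
  model <- read_npm_model(emr_model_file())
  rw <- fixture_rating_week()
  cr <- fixture_category_rating()
  perm <- fixture_permitted()
  claims <- fixture_claims()

  products <- fixture_products(model)

  # per-rating category counts inside `ads`: printed counts, extensions kept
  # exact, model categories reduced to match the rating food-ad totals
  ads <- purrr::map_dfr(RATINGS, function(r) {
    counts <- stats::setNames(cr[[r]], cr$category_id)
    counts <- counts[counts > 0]
    ext <- counts[names(counts) %in% c("19", "20")]
    mod <- counts[!names(counts) %in% c("19", "20")]
    target_mod <- sum(rw$n_food[rw$program_rating == r]) - sum(ext)
    mod <- greedy_reduce(mod, sum(mod) - target_mod)
    n_perm <- perm$n_permitted[perm$program_rating == r]
    food <- fixture_food_records(r, c(mod, ext), n_perm, model, rw,
                                 claims[claims$program_rating == r, ])
    nonfood <- fixture_nonfood_records(r, rw)
    dplyr::bind_rows(food, nonfood)
  })

  ads <- assign_channels(ads)
  ads <- assign_airtimes(ads)
  ads <- dplyr::select(ads, dplyr::all_of(AD_COLS))

  blocks <- fixture_blocks(rw)

  # category-distribution view: printed per-category counts, exactly
  category_ads <- purrr::map_dfr(RATINGS, function(r) {
    counts <- stats::setNames(cr[[r]], cr$category_id)
    counts <- counts[counts > 0]
    if (!length(counts)) return(NULL)
    cat_vec <- rep(names(counts), counts)
    tibble::tibble(
      channel = "A",
      week_id = rep_len(1:4, length(cat_vec)),
      day_kind = "weekday",
      airtime = "16:00",
      program_rating = r,
      ad_class = "food",
      product_id = fixture_product_for(cat_vec, rep(FALSE, length(cat_vec)), model),
      category_id = cat_vec,
      has_claim = FALSE,
      has_disclaimer = FALSE,
      claim_text = NA_character_
    )
  })

  meta <- list(
    categorized_food_counts = c(C = 36L, G = 845L, PG = 555L),
    food_ad_totals = c(C = 35L, G = 818L, PG = 540L),
    note = paste(
      "The per-category counts exceed the per-rating food-ad totals by",
      "1/27/15 records; `ads` follows the food-ad totals, `category_ads`",
      "the per-category counts. Joint cell allocation is a deterministic",
      "greedy fill and is not unique."
    )
  )

  list(ads = ads, blocks = blocks, products = products, model = model,
       category_ads = category_ads, meta = meta)
}

# remove `k` units from a named count vector, one at a time from the largest
# entry (ties broken toward the lexicographically smaller name)
greedy_reduce <- function(counts, k) {
  stopifnot(k >= 0, sum(counts) >= k)
  ord_names <- names(sort(counts))  # stable name order for ties
  for (i in seq_len(k)) {
    j <- order(-counts, names(counts))[1]
    counts[j] <- counts[j] - 1L
  }
  counts[counts > 0]
}

# categories whose passing product may absorb permitted ads, in fill order
PERMITTED_FILL_ORDER <- c("3e", "10", "12", "13", "18", "2", "5", "8", "9")

fixture_food_records <- function(rating, counts, n_permitted, model, rw, claim_row) {
  counts <- counts[order(names(counts))]
  cat_vec <- rep(names(counts), counts)

  # allocate the permitted verdicts across permit-capable categories
  perm_alloc <- stats::setNames(integer(length(counts)), names(counts))
  left <- n_permitted
  for (cid in PERMITTED_FILL_ORDER) {
    if (left == 0) break
    if (!cid %in% names(counts)) next
    take <- min(counts[[cid]], left)
    perm_alloc[[cid]] <- take
    left <- left - take
  }
  if (left > 0) {
    rlang::abort("cannot allocate permitted verdicts to available categories")
  }
  perm_vec <- unlist(purrr::map(names(counts), function(cid) {
    c(rep(TRUE, perm_alloc[[cid]]), rep(FALSE, counts[[cid]] - perm_alloc[[cid]]))
  }), use.names = FALSE)

  n <- length(cat_vec)
  weeks <- rw[rw$program_rating == rating, ]
  week_vec <- rep(weeks$week_id, weeks$n_food)
  stopifnot(length(week_vec) == n)

  tibble::tibble(
    channel = NA_character_,
    week_id = week_vec,
    day_kind = NA_character_,
    airtime = NA_character_,
    program_rating = rating,
    ad_class = "food",
    product_id = fixture_product_for(cat_vec, perm_vec, model),
    category_id = cat_vec,
    has_claim = seq_len(n) <= claim_row$n_claims,
    has_disclaimer = seq_len(n) <= claim_row$n_disclaimers,
    claim_text = NA_character_
  )
}

fixture_nonfood_records <- function(rating, rw) {
  weeks <- rw[rw$program_rating == rating, ]
  n_nonfood <- weeks$n_total - weeks$n_food
  tibble::tibble(
    channel = NA_character_,
    week_id = rep(weeks$week_id, n_nonfood),
    day_kind = NA_character_,
    airtime = NA_character_,
    program_rating = rating,
    ad_class = "nonfood",
    product_id = NA_character_,
    category_id = NA_character_,
    has_claim = FALSE,
    has_disclaimer = FALSE,
    claim_text = NA_character_
  )
}

# product id implied by category + intended verdict under the shipped model
fixture_product_for <- function(category_id, permitted, model) {
  auto <- model$category_id[model$auto_not_permitted]
  ext <- model$category_id[!model$is_model_category]
  dplyr::case_when(
    category_id %in% auto ~ paste0("p", category_id, "-auto"),
    category_id %in% ext ~ paste0("p", category_id, "-ext"),
    permitted ~ paste0("p", category_id, "-ok"),
    TRUE ~ paste0("p", category_id, "-bad")
  )
}

# build the catalogue: for every model category a passing and a failing
# product relative to the loaded thresholds; auto/extension categories one
# product each (their composition never drives the verdict)
fixture_products <- function(model) {
  liquid <- c("3a", "3b", "3c", "3d", "3e", "19", "20")
  purrr::map_dfr(seq_len(nrow(model)), function(i) {
    cid <- model$category_id[[i]]
    basis <- if (cid %in% liquid) "per_100_mL" else "per_100_g"
    base <- tibble::tibble(
      brand = "fixture", category_id = cid, basis = basis,
      energy_kcal = 0, total_fat_g = 0, saturated_fat_g = 0,
      industrial_tfa_g_per_100g_fat = 0, total_sugars_g = 0,
      added_sugars_g = 0, has_nonsugar_sweeteners = FALSE, salt_g = 0,
      alcohol_pct_energy = 0, composition_source = "label",
      salt_from_sodium = FALSE
    )
    if (model$auto_not_permitted[[i]]) {
      return(dplyr::mutate(base, product_id = paste0("p", cid, "-auto")))
    }
    if (!model$is_model_category[[i]]) {
      return(dplyr::mutate(base, product_id = paste0("p", cid, "-ext")))
    }
    thr <- model$thresholds[[i]]
    ok <- base
    for (k in names(thr)) ok[[k]] <- thr[[k]] / 2
    ok <- repair_profile(ok)
    bad <- ok
    if (length(thr)) {
      k <- names(thr)[[1]]
      bad[[k]] <- thr[[k]] * 2 + 1
      bad <- repair_profile(bad)
    } else {
      bad$industrial_tfa_g_per_100g_fat <- 2  # trans-fat rule carries the failure
    }
    dplyr::bind_rows(
      dplyr::mutate(ok, product_id = paste0("p", cid, "-ok")),
      dplyr::mutate(bad, product_id = paste0("p", cid, "-bad"))
    )
  }) |>
    dplyr::select(dplyr::all_of(PRODUCT_COLS), salt_from_sodium)
}

# keep composition invariants after threshold-relative edits
repair_profile <- function(p) {
  p$total_sugars_g <- max(p$total_sugars_g, p$added_sugars_g)
  p$total_fat_g <- max(p$total_fat_g, p$saturated_fat_g)
  p
}

# fractional rating x week hours apportioned across channels in proportion to
# each channel's analyzed hours that week (a channel with no recordings in a
# week contributes no block)
fixture_blocks <- function(rw) {
  cw <- fixture_channel_week_hours()
  purrr::map_dfr(seq_len(nrow(rw)), function(i) {
    wk <- cw[cw$week_id == rw$week_id[[i]], ]
    wk <- wk[wk$hours > 0, ]
    tibble::tibble(
      channel = wk$channel,
      week_id = rw$week_id[[i]],
      program_rating = rw$program_rating[[i]],
      hours_analyzed = rw$hours[[i]] * wk$hours / sum(wk$hours)
    )
  }) |>
    dplyr::arrange(channel, week_id, program_rating)
}

# deterministic largest-remainder split of each rating x week cell over the
# channels active that week
assign_channels <- function(ads) {
  cw <- fixture_channel_week_hours()
  ads |>
    dplyr::group_by(program_rating, week_id) |>
    dplyr::group_modify(function(df, key) {
      wk <- cw[cw$week_id == key$week_id & cw$hours > 0, ]
      share <- wk$hours / sum(wk$hours)
      n <- nrow(df)
      base <- floor(n * share)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(-(n * share - base), wk$channel)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      df$channel <- rep(wk$channel, base)
      df
    }) |>
    dplyr::ungroup()
}

# cycle three weekdays then one weekend day; spread airtimes over the window
assign_airtimes <- function(ads) {
  ads |>
    dplyr::group_by(program_rating, week_id) |>
    dplyr::group_modify(function(df, key) {
      j <- seq_len(nrow(df)) - 1L
      df$day_kind <- ifelse(j %% 4L == 3L, "weekend", "weekday")
      wd <- WINDOWS$weekday
      we <- WINDOWS$weekend
      df$airtime <- ifelse(
        df$day_kind == "weekday",
        minutes_to_hhmm(wd[1] + (j * 7L) %% (wd[2] - wd[1])),
        minutes_to_hhmm(we[1] + (j * 11L) %% (we[2] - we[1]))
      )
      df
    }) |>
    dplyr::ungroup()
}
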