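# Descriptive exposure analytics: every output is a tidy proportion/rate table
# (group columns + numerator + denominator + rounded percentage or rate).

group_cols_for <- function(by) {
  switch(by,
    overall = character(),
    rating = "program_rating",
    week = "week_id",
    rating_week = c("program_rating", "week_id"),
    rlang::abort(paste0("unknown grouping: ", by), class = "npmtv_validation_error")
  )
}

#' Share of advertisements that are for food or drink
#'
#' The headline exposure proportion: food advertisements over all
#' advertisements, overall or stratified by program rating, study week, or
#' both. Percentages are rounded half-up to one decimal, matching the
#' reporting convention of broadcast content analyses.
#'
#' @param ads Advertisement tibble ([read_ads()] dialect).
#' @param by Grouping: `"overall"`, `"rating"`, `"week"` or `"rating_week"`.
#' @return A tibble with the grouping columns plus `n_food`, `n_total`, `pct`.
#' @examples
#' fx <- reference_corpus()
#' food_ad_share(fx$ads)                 # overall share
#' food_ad_share(fx$ads, by = "rating")  # by program rating
#' @export
food_ad_share <- function(ads, by = c("overall", "rating", "week", "rating_week")) {
  by <- rlang::arg_match(by)
  gc <- group_cols_for(by)
  ads |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gc))) |>
    dplyr::summarise(
      n_food = sum(ad_class == "food"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct = round_half_up(100 * n_food / n_total, 1))
}

#' Hourly frequency of food advertisements
#'
#' Food advertisements per analyzed broadcast hour: the count of food records
#' divided by the summed `hours_analyzed` of the matching blocks, rounded
#' half-up to one decimal. Grouping must be supported by both tables (weeks
#' and ratings are recorded in blocks; channels are ignored here).
#'
#' @inheritParams food_ad_share
#' @param blocks Analyzed-hours tibble ([read_blocks()] dialect).
#' @return A tibble with the grouping columns plus `n_food`, `hours`,
#'   `freq_per_hour`.
#' @export
hourly_frequency <- function(ads, blocks,
                             by = c("overall", "rating", "week", "rating_week")) {
  by <- rlang::arg_match(by)
  gc <- group_cols_for(by)
  validate_blocks(blocks)
  hrs <- blocks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gc))) |>
    dplyr::summarise(hours = sum(hours_analyzed), .groups = "drop")
  if (any(hrs$hours <= 0)) {
    rlang::abort("a group has zero analyzed hours", class = "npmtv_validation_error")
  }
  food <- ads |>
    dplyr::filter(ad_class == "food") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gc))) |>
    dplyr::summarise(n_food = dplyr::n(), .groups = "drop")
  out <- if (length(gc)) {
    dplyr::left_join(hrs, food, by = gc)
  } else {
    dplyr::bind_cols(hrs, food)
  }
  out |>
    dplyr::mutate(
      n_food = dplyr::coalesce(n_food, 0L),
      freq_per_hour = round_half_up(n_food / hours, 1)
    ) |>
    dplyr::select(dplyr::all_of(gc), n_food, hours, freq_per_hour)
}

#' Distribution of food advertisements over food categories
#'
#' For each program rating (or overall), the share of categorized food
#' advertisements falling in each food category. The denominator is the sum
#' of categorized food advertisements within the stratum — the column-sum
#' convention of category breakdown tables. Food records lacking a category
#' are excluded from the denominator with a warning, never silently.
#'
#' @inheritParams food_ad_share
#' @param by `"rating"` (one block of rows per program rating) or
#'   `"overall"`.
#' @return A tibble with `program_rating` (unless overall), `category_id`,
#'   `n`, `total`, `pct` (half-up, one decimal).
#' @export
category_distribution <- function(ads, by = c("rating", "overall")) {
  by <- rlang::arg_match(by)
  gc <- group_cols_for(by)
  food <- dplyr::filter(ads, ad_class == "food")
  uncat <- is.na(food$category_id) | food$category_id == ""
  if (any(uncat)) {
    rlang::warn(paste0(sum(uncat), " food record(s) lack a category_id and are ",
                       "excluded from the category denominator"))
    food <- food[!uncat, , drop = FALSE]
  }
  food |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(gc, "category_id")))) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(total = sum(n), pct = round_half_up(100 * n / total, 1)) |>
    dplyr::ungroup()
}

#' Permitted / not-permitted shares of food advertising
#'
#' Joins each food advertisement to its product's marketing decision under the
#' nutrient-profile model and tabulates permitted and not-permitted shares per
#' program rating and overall, under one of two bases:
#'
#' * `"emr18"` — only advertisements for products in the 18 model categories
#'   count (extension categories such as alcoholic drinks and coffee are
#'   excluded from the denominator);
#' * `"extended"` — every food advertisement counts, with extension-category
#'   products deterministically not permitted.
#'
#' Advertisements whose product is data-insufficient are reported in
#' `n_insufficient` (inside the denominator), never dropped.
#'
#' @inheritParams food_ad_share
#' @param products Product catalogue tibble (see [read_products()]).
#' @param model Model tibble from [read_npm_model()].
#' @param basis `"emr18"` or `"extended"`.
#' @param components Optional composite-meal table passed through to
#'   [evaluate_products()].
#' @return A tibble with one row per program rating plus an `"overall"` row:
#'   `program_rating`, `n_food`, `n_permitted`, `pct_permitted`,
#'   `n_not_permitted`, `pct_not_permitted`, `n_insufficient` (percentages
#'   half-up, one decimal).
#' @examples
#' fx <- reference_corpus()
#' permitted_share(fx$ads, fx$products, fx$model, basis = "emr18")
#' @export
permitted_share <- function(ads, products, model,
                            basis = c("emr18", "extended"), components = NULL) {
  basis <- rlang::arg_match(basis)
  decisions <- evaluate_products(products, model, components)
  food <- dplyr::filter(ads, ad_class == "food")
  unresolved <- setdiff(food$product_id, decisions$product_id)
  if (length(unresolved)) {
    rlang::abort(c("food advertisement(s) reference products missing from the catalogue:",
                   utils::head(unique(unresolved), 10)),
                 class = "npmtv_validation_error")
  }
  scored <- dplyr::left_join(
    food,
    dplyr::select(decisions, product_id, assessable, status),
    by = "product_id"
  )
  if (basis == "emr18") {
    scored <- dplyr::filter(scored, assessable)
  } else {
    # extension categories are non-assessable under the model but counted as
    # not permitted on the all-categories basis
    scored <- dplyr::mutate(
      scored,
      status = dplyr::if_else(status == "not_assessable", "not_permitted", status)
    )
  }
  tally <- function(df, label) {
    tibble::tibble(
      program_rating = label,
      n_food = nrow(df),
      n_permitted = sum(df$status == "permitted"),
      n_not_permitted = sum(df$status == "not_permitted"),
      n_insufficient = sum(df$status == "insufficient_data")
    )
  }
  per_rating <- purrr::map_dfr(
    intersect(RATINGS, unique(scored$program_rating)),
    function(r) tally(scored[scored$program_rating == r, , drop = FALSE], r)
  )
  dplyr::bind_rows(per_rating, tally(scored, "overall")) |>
    dplyr::mutate(
      pct_permitted = round_half_up(100 * n_permitted / n_food, 1),
      pct_not_permitted = round_half_up(100 * n_not_permitted / n_food, 1)
    ) |>
    dplyr::select(program_rating, n_food, n_permitted, pct_permitted,
                  n_not_permitted, pct_not_permitted, n_insufficient)
}

claims_like_share <- function(ads, flag_col, by) {
  gc <- group_cols_for(by)
  ads |>
    dplyr::filter(ad_class == "food") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gc))) |>
    dplyr::summarise(
      n = sum(.data[[flag_col]]),
      n_food = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct = round_half_up(100 * n / n_food, 2))
}

#' Share of food advertisements carrying health or nutrition claims
#'
#' Numerator: food advertisements flagged as containing a health or nutrition
#' claim in the stratum; denominator: all food advertisements in the stratum.
#' Reported to two decimals (half-up), the claim-table convention.
#'
#' @inheritParams food_ad_share
#' @param by `"overall"`, `"rating"`, `"week"` or `"rating_week"`.
#' @return A tibble with the grouping columns plus `n`, `n_food`, `pct`.
#' @export
claims_share <- function(ads, by = c("overall", "rating", "week", "rating_week")) {
  by <- rlang::arg_match(by)
  claims_like_share(ads, "has_claim", by)
}

#' Share of food advertisements carrying health disclaimers
#'
#' Same construction as [claims_share()] with the disclaimer flag (on-ad
#' warnings about excess consumption or harmful consequences) as numerator.
#'
#' @inheritParams claims_share
#' @return A tibble with the grouping columns plus `n`, `n_food`, `pct`.
#' @export
disclaimers_share <- function(ads, by = c("overall", "rating", "week", "rating_week")) {
  by <- rlang::arg_match(by)
  claims_like_share(ads, "has_disclaimer", by)
}
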