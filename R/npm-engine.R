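# Decision engine: cross-checks per-100 g/mL composition against the loaded
# category thresholds and the two global rules (industrial trans fat, alcohol).

#' Classify products as permitted or not permitted for marketing to children
#'
#' Applies a nutrient-profile model to a product catalogue. For each product
#' the rules are applied in order: auto-prohibited category, industrial trans
#' fat (> 1 g per 100 g of total fat), alcohol (>= 0.5 % of total energy),
#' non-sugar sweeteners where the category prohibits them, then every nutrient
#' threshold applicable to the category (strictly greater than the threshold
#' fails; equal passes). A product is permitted exactly when no rule is
#' violated. Products in extension categories (outside the model, e.g.
#' alcoholic drinks or coffee) are returned with `assessable = FALSE` and no
#' verdict. A product missing a value for any applicable nutrient yields
#' `status = "insufficient_data"` rather than a verdict: absent composition is
#' never treated as zero.
#'
#' @param products Product catalogue tibble, one row per simple product, with
#'   columns `product_id`, `category_id`, `basis` (`"per_100_g"` or
#'   `"per_100_mL"`), the six nutrient columns (`energy_kcal`, `total_fat_g`,
#'   `saturated_fat_g`, `total_sugars_g`, `added_sugars_g`, `salt_g`),
#'   `industrial_tfa_g_per_100g_fat`, `alcohol_pct_energy` and
#'   `has_nonsugar_sweeteners`. `NA` marks a missing (not zero) value.
#' @param model Model tibble from [read_npm_model()].
#' @param components Optional composite-meal table (`meal_id`,
#'   `component_product_id`); per-meal decisions (the conjunction of the
#'   component verdicts) are appended, see [evaluate_composite()].
#' @return A tibble with one row per product (and per meal): `product_id`,
#'   `category_id`, `assessable`, `permitted` (`NA` when not assessable or
#'   data-insufficient), `status` (`"permitted"`, `"not_permitted"`,
#'   `"insufficient_data"` or `"not_assessable"`) and a `violations`
#'   list-column of tibbles (`rule_id`, `key`, `observed`, `threshold`).
#' @examples
#' model <- read_npm_model(emr_model_file())
#' prods <- tibble::tibble(
#'   product_id = c("choc-1", "water-1"), category_id = c("1", "3e"),
#'   basis = c("per_100_g", "per_100_mL"), energy_kcal = c(520, 0),
#'   total_fat_g = c(30, 0), saturated_fat_g = c(18, 0),
#'   total_sugars_g = c(50, 0), added_sugars_g = c(45, 0), salt_g = c(0.2, 0),
#'   industrial_tfa_g_per_100g_fat = 0, alcohol_pct_energy = 0,
#'   has_nonsugar_sweeteners = FALSE
#' )
#' evaluate_products(prods, model)
#' @export
evaluate_products <- function(products, model, components = NULL) {
  validate_npm_model(model)
  validate_products(products)
  decisions <- if (nrow(products)) {
    purrr::map_dfr(seq_len(nrow(products)), function(i) {
      decide_one(as.list(products[i, ]), model)
    })
  } else {
    tibble::tibble(
      product_id = character(), category_id = character(),
      assessable = logical(), permitted = logical(), status = character(),
      violations = list()
    )
  }
  if (!is.null(components)) {
    decisions <- dplyr::bind_rows(
      decisions,
      evaluate_composite(components, model, products)
    )
  }
  decisions
}

#' Classify a single product
#'
#' Single-product form of [evaluate_products()]. Unlike the vectorized form,
#' missing applicable composition raises a classed error
#' (`npmtv_insufficient_data`) instead of returning a flagged row, so callers
#' scoring one product cannot mistake "no data" for a verdict.
#'
#' @inheritParams evaluate_products
#' @param product A one-row product tibble (or named list) with the catalogue
#'   columns.
#' @return A one-row decision tibble (see [evaluate_products()]).
#' @export
evaluate_product <- function(product, model) {
  validate_npm_model(model)
  d <- decide_one(as.list(tibble::as_tibble(product)[1, ]), model)
  if (d$status == "insufficient_data") {
    rlang::abort(
      paste0("insufficient composition data for product ", d$product_id,
             ": missing ", paste(d$violations[[1]]$key, collapse = ", ")),
      class = "npmtv_insufficient_data"
    )
  }
  d
}

#' Classify composite or restaurant meals
#'
#' A composite meal is permitted only when every component, examined
#' individually against the model, is permitted. Component failures are
#' aggregated as `component_failed` violations carrying the failing component's
#' product id; a data-insufficient component makes the meal
#' data-insufficient.
#'
#' @param components Tibble with columns `meal_id` and `component_product_id`;
#'   every meal needs at least one component and every component id must
#'   resolve in `products`.
#' @inheritParams evaluate_products
#' @return A decision tibble with one row per meal (`product_id` = meal id,
#'   `category_id` = `NA`).
#' @export
evaluate_composite <- function(components, model, products) {
  stopifnot(is.data.frame(components))
  need <- c("meal_id", "component_product_id")
  if (!all(need %in% names(components))) {
    rlang::abort("components table needs columns meal_id, component_product_id",
                 class = "npmtv_validation_error")
  }
  if (!nrow(components)) {
    rlang::abort("components table is empty: a composite meal needs >= 1 component",
                 class = "npmtv_validation_error")
  }
  unresolved <- setdiff(components$component_product_id, products$product_id)
  if (length(unresolved)) {
    rlang::abort(paste0("unresolved component product id(s): ",
                        paste(unique(unresolved), collapse = ", ")),
                 class = "npmtv_validation_error")
  }
  part_decisions <- evaluate_products(
    products[products$product_id %in% components$component_product_id, , drop = FALSE],
    model
  )
  components |>
    dplyr::left_join(part_decisions, by = c(component_product_id = "product_id")) |>
    dplyr::group_by(meal_id) |>
    dplyr::summarise(
      product_id = meal_id[[1]],
      category_id = NA_character_,
      assessable = all(assessable),
      # violations must be computed before `status` is overwritten by the
      # meal-level summary of the same name
      violations = list(tibble::tibble(
        rule_id = rep("component_failed", sum(status != "permitted")),
        key = component_product_id[status != "permitted"],
        observed = NA_real_,
        threshold = NA_real_
      )),
      status = dplyr::case_when(
        any(status == "insufficient_data") ~ "insufficient_data",
        any(status %in% c("not_permitted", "not_assessable")) ~ "not_permitted",
        TRUE ~ "permitted"
      ),
      permitted = dplyr::if_else(status == "insufficient_data", NA, status == "permitted"),
      .groups = "drop"
    ) |>
    dplyr::select(product_id, category_id, assessable, permitted, status, violations)
}

# One product -> one decision row. `p` is a named list; thresholds are looked
# up from the category row; NA composition for an applicable field makes the
# product data-insufficient, never a pass or fail.
decide_one <- function(p, model) {
  idx <- match(p$category_id, model$category_id)
  if (is.na(idx)) {
    rlang::abort(paste0("unknown category_id: ", p$category_id),
                 class = "npmtv_model_error")
  }
  cat_row <- model[idx, ]
  row <- function(assessable, permitted, status, violations) {
    tibble::tibble(
      product_id = as.character(p$product_id),
      category_id = as.character(p$category_id),
      assessable = assessable, permitted = permitted, status = status,
      violations = list(violations)
    )
  }
  no_viol <- tibble::tibble(rule_id = character(), key = character(),
                            observed = double(), threshold = double())

  if (!cat_row$is_model_category) {
    return(row(FALSE, NA, "not_assessable", no_viol))
  }
  if (cat_row$auto_not_permitted) {
    v <- tibble::tibble(rule_id = "auto_category", key = NA_character_,
                        observed = NA_real_, threshold = NA_real_)
    return(row(TRUE, FALSE, "not_permitted", v))
  }

  thr <- cat_row$thresholds[[1]]
  applicable <- c("industrial_tfa_g_per_100g_fat", "alcohol_pct_energy", names(thr))
  if (isTRUE(cat_row$sweeteners_prohibited)) {
    applicable <- c(applicable, "has_nonsugar_sweeteners")
  }
  missing_keys <- applicable[vapply(applicable, function(k) {
    is.null(p[[k]]) || is.na(p[[k]])
  }, logical(1))]
  if (length(missing_keys)) {
    v <- tibble::tibble(rule_id = "missing_value", key = missing_keys,
                        observed = NA_real_, threshold = NA_real_)
    return(row(TRUE, NA, "insufficient_data", v))
  }

  viols <- list()
  if (p$industrial_tfa_g_per_100g_fat > 1) {
    viols <- c(viols, list(tibble::tibble(
      rule_id = "trans_fat", key = "industrial_tfa_g_per_100g_fat",
      observed = p$industrial_tfa_g_per_100g_fat, threshold = 1
    )))
  }
  if (p$alcohol_pct_energy >= 0.5) {
    viols <- c(viols, list(tibble::tibble(
      rule_id = "alcohol_energy", key = "alcohol_pct_energy",
      observed = p$alcohol_pct_energy, threshold = 0.5
    )))
  }
  if (isTRUE(cat_row$sweeteners_prohibited) && isTRUE(p$has_nonsugar_sweeteners)) {
    viols <- c(viols, list(tibble::tibble(
      rule_id = "sweetener", key = "has_nonsugar_sweeteners",
      observed = 1, threshold = 0
    )))
  }
  for (k in names(thr)) {
    if (p[[k]] > thr[[k]]) {
      viols <- c(viols, list(tibble::tibble(
        rule_id = "threshold_exceeded", key = k,
        observed = as.numeric(p[[k]]), threshold = as.numeric(thr[[k]])
      )))
    }
  }
  viols <- dplyr::bind_rows(no_viol, viols)
  if (nrow(viols)) {
    row(TRUE, FALSE, "not_permitted", viols)
  } else {
    row(TRUE, TRUE, "permitted", no_viol)
  }
}
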