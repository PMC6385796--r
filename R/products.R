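# Product catalogue I/O. One CSV row per simple product; composite meals live
# in a companion CSV of (meal_id, component_product_id) pairs.

PRODUCT_COLS <- c(
  "product_id", "brand", "category_id", "basis",
  "energy_kcal", "total_fat_g", "saturated_fat_g",
  "industrial_tfa_g_per_100g_fat", "total_sugars_g", "added_sugars_g",
  "has_nonsugar_sweeteners", "salt_g", "alcohol_pct_energy",
  "composition_source"
)

#' Read a product catalogue
#'
#' Reads the documented product CSV dialect (UTF-8, comma separated, header
#' required). The evaluation basis (`per_100_g` for solids, `per_100_mL` for
#' liquids) is declared per product, never inferred. As a loader convenience a
#' `sodium_g` column is accepted in place of `salt_g` and converted at
#' salt = sodium x 2.5; converted rows are marked in a `salt_from_sodium`
#' column so the provenance of the value stays visible.
#'
#' @param path Path to the catalogue CSV.
#' @return A validated product tibble (see [evaluate_products()] for the
#'   column contract).
#' @export
read_products <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    product_id = readr::col_character(),
    brand = readr::col_character(),
    category_id = readr::col_character(),
    basis = readr::col_character(),
    has_nonsugar_sweeteners = readr::col_logical(),
    salt_from_sodium = readr::col_logical(),
    composition_source = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!"salt_g" %in% names(df) && "sodium_g" %in% names(df)) {
    df$salt_g <- df$sodium_g * 2.5
    df$salt_from_sodium <- !is.na(df$sodium_g)
    df$sodium_g <- NULL
  } else if (!"salt_from_sodium" %in% names(df)) {
    df$salt_from_sodium <- FALSE
  }
  validate_products(df)
  df
}

#' Write a product catalogue
#'
#' @param products Product tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path) {
  validate_products(products)
  ord <- c(intersect(PRODUCT_COLS, names(products)),
           setdiff(names(products), PRODUCT_COLS))
  readr::write_csv(products[ord], path, progress = FALSE)
  invisible(path)
}

#' Read a composite-meal component table
#'
#' @param path CSV with columns `meal_id`, `component_product_id`.
#' @return A tibble of meal/component pairs.
#' @export
read_components <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    meal_id = readr::col_character(),
    component_product_id = readr::col_character()
  ), progress = FALSE)
  if (!all(c("meal_id", "component_product_id") %in% names(df))) {
    rlang::abort("components CSV needs columns meal_id, component_product_id",
                 class = "npmtv_validation_error")
  }
  df
}

#' Validate a product catalogue
#'
#' Enforces the composition invariants: non-negative masses and energy,
#' saturated fat bounded by total fat, added sugars bounded by total sugars,
#' alcohol percent-energy in \[0, 100\], a declared basis, and unique product
#' ids. `NA` values are allowed anywhere (missing, distinct from zero);
#' bounds are only checked where both operands are present.
#'
#' @param products Product tibble.
#' @return The catalogue, invisibly, if valid; otherwise a classed error
#'   listing every offending row.
#' @export
validate_products <- function(products) {
  stopifnot(is.data.frame(products))
  missing_cols <- setdiff(setdiff(PRODUCT_COLS, "brand"), names(products))
  if (length(missing_cols)) {
    rlang::abort(paste0("product catalogue lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "npmtv_validation_error")
  }
  probs <- character()
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) probs <<- c(probs, paste0("row ", idx, ": ", msg))
  }
  if (anyDuplicated(products$product_id)) {
    bad(duplicated(products$product_id), "duplicate product_id")
  }
  bad(!products$basis %in% BASES | is.na(products$basis),
      "basis must be per_100_g or per_100_mL")
  for (k in c(NUTRIENT_KEYS, "industrial_tfa_g_per_100g_fat")) {
    bad(!is.na(products[[k]]) & products[[k]] < 0, paste0(k, " < 0"))
  }
  bad(!is.na(products$saturated_fat_g) & !is.na(products$total_fat_g) &
        products$saturated_fat_g > products$total_fat_g,
      "saturated_fat_g > total_fat_g")
  bad(!is.na(products$added_sugars_g) & !is.na(products$total_sugars_g) &
        products$added_sugars_g > products$total_sugars_g,
      "added_sugars_g > total_sugars_g")
  bad(!is.na(products$alcohol_pct_energy) &
        (products$alcohol_pct_energy < 0 | products$alcohol_pct_energy > 100),
      "alcohol_pct_energy outside [0, 100]")
  if (length(probs)) {
    rlang::abort(c("invalid product catalogue", probs),
                 class = "npmtv_validation_error")
  }
  invisible(products)
}
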