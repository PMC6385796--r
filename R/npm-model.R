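#' Read a nutrient-profile model definition
#'
#' Loads a category taxonomy with per-100 g/mL nutrient thresholds from a YAML
#' (or JSON) model file. Each category either carries a named set of maximum
#' values over the fixed nutrient vocabulary (`energy_kcal`, `total_fat_g`,
#' `saturated_fat_g`, `total_sugars_g`, `added_sugars_g`, `salt_g`) or is
#' flagged `auto_not_permitted`, in which case marketing is disallowed
#' regardless of composition and no thresholds may be present. Categories with
#' `is_model_category: false` are extensions outside the profiling model
#' (e.g. alcoholic drinks, coffee): they are recorded in corpora but are not
#' assessable against thresholds.
#'
#' @param path Path to the model file (`.yaml`/`.yml` or `.json`).
#' @return A tibble with one row per category: `category_id`, `name`,
#'   `auto_not_permitted`, `sweeteners_prohibited`, `is_model_category`, and a
#'   `thresholds` list-column of named numeric vectors (empty when none apply).
#' @seealso [emr_model_file()] for the shipped reference instance,
#'   [evaluate_products()] for applying a model.
#' @export
read_npm_model <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("model file not found: ", path), class = "npmtv_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cats <- raw[["categories"]] %||% raw
  if (!length(cats)) {
    rlang::abort("model file defines no categories", class = "npmtv_model_error")
  }
  model <- purrr::map_dfr(cats, function(cat) {
    thr <- cat[["thresholds"]] %||% list()
    tibble::tibble(
      category_id = as.character(cat[["category_id"]] %||% cat[["id"]]),
      name = as.character(cat[["name"]] %||% ""),
      auto_not_permitted = isTRUE(cat[["auto_not_permitted"]]),
      sweeteners_prohibited = isTRUE(cat[["sweeteners_prohibited"]]),
      is_model_category = !isFALSE(cat[["is_model_category"]]),
      thresholds = list(purrr::map_dbl(thr, as.numeric))
    )
  })
  validate_npm_model(model)
}

#' Validate a nutrient-profile model table
#'
#' Checks the structural invariants of a model table: unique category ids,
#' non-negative thresholds over known nutrient keys only, and no thresholds on
#' auto-not-permitted categories. Called by [read_npm_model()]; exported so
#' programmatically built models can be checked the same way.
#'
#' @param model A model tibble as returned by [read_npm_model()].
#' @return The validated model, invisibly unchanged.
#' @export
validate_npm_model <- function(model) {
  stopifnot(is.data.frame(model))
  need <- c("category_id", "auto_not_permitted", "sweeteners_prohibited",
            "is_model_category", "thresholds")
  missing_cols <- setdiff(need, names(model))
  if (length(missing_cols)) {
    rlang::abort(paste0("model table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "npmtv_model_error")
  }
  if (anyDuplicated(model$category_id)) {
    dup <- unique(model$category_id[duplicated(model$category_id)])
    rlang::abort(paste0("duplicate category_id: ", paste(dup, collapse = ", ")),
                 class = "npmtv_model_error")
  }
  for (i in seq_len(nrow(model))) {
    thr <- model$thresholds[[i]]
    id <- model$category_id[[i]]
    if (length(thr)) {
      bad_key <- setdiff(names(thr), NUTRIENT_KEYS)
      if (length(bad_key)) {
        rlang::abort(paste0("category ", id, ": unknown nutrient key ",
                            paste(bad_key, collapse = ", ")),
                     class = "npmtv_model_error")
      }
      if (any(!is.finite(thr)) || any(thr < 0)) {
        rlang::abort(paste0("category ", id, ": thresholds must be finite and >= 0"),
                     class = "npmtv_model_error")
      }
      if (model$auto_not_permitted[[i]]) {
        rlang::abort(paste0("category ", id,
                            ": auto-not-permitted category must not carry thresholds"),
                     class = "npmtv_model_error")
      }
    }
  }
  invisible(model)
}

#' Path to the shipped reference model instance
#'
#' The package ships one model file covering the 18-category Eastern
#' Mediterranean taxonomy (with beverage subcategories 3a-3e) plus the two
#' extension categories for alcoholic drinks ("19") and coffee ("20").
#' Categories 1 (chocolate and sugar confectionery), 4 (edible ices),
#' 6 (cakes, sweet biscuits and pastries), 14 (processed meat and poultry) and
#' beverage subcategories 3a (fruit juices) and 3d (energy drinks) are
#' auto-not-permitted. The file's *threshold values are synthetic*: the
#' taxonomy and auto-prohibition flags follow the regional model, but the
#' numeric limits are plausible placeholders, not the officially published
#' ones. Regulatory use requires populating a model file from the official
#' threshold appendix; the engine itself is threshold-agnostic.
#'
#' @return Path to the installed YAML model file.
#' @export
emr_model_file <- function() {
  system.file("extdata", "emr_model_synthetic.yaml", package = "npmtv", mustWork = TRUE)
}
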