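# Coded advertisement logs and analyzed-hours tables: schema, validation, I/O,
# and the intercoder percent-agreement statistic.

AD_COLS <- c(
  "channel", "week_id", "day_kind", "airtime", "program_rating", "ad_class",
  "product_id", "category_id", "has_claim", "has_disclaimer", "claim_text"
)
BLOCK_COLS <- c("channel", "week_id", "program_rating", "hours_analyzed")

#' Validate an advertisement log
#'
#' Checks every coded record against the corpus schema: known channel letter,
#' week in 1-4, `weekday`/`weekend` day kind, a `HH:MM` airtime inside the
#' recorded viewing window (15:00-22:00 on weekdays, 08:00-22:00 on weekend
#' days), a `C`/`G`/`PG` program rating, and the food/nonfood contract (food
#' records must carry `product_id` and `category_id`; nonfood records must
#' carry neither). Validation is total: every malformed row yields a
#' diagnostic, nothing is silently dropped.
#'
#' @param ads Advertisement tibble (see [read_ads()] for the dialect).
#' @return A diagnostics tibble (`row`, `field`, `message`); zero rows when
#'   the log is valid.
#' @export
validate_ads <- function(ads) {
  stopifnot(is.data.frame(ads))
  missing_cols <- setdiff(setdiff(AD_COLS, "claim_text"), names(ads))
  if (length(missing_cols)) {
    rlang::abort(paste0("ads table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "npmtv_validation_error")
  }
  diag <- list()
  flag <- function(cond, field, message) {
    idx <- which(cond)
    if (length(idx)) {
      diag[[length(diag) + 1]] <<- tibble::tibble(row = idx, field = field,
                                                  message = message)
    }
  }
  flag(is.na(ads$channel) | !ads$channel %in% LETTERS, "channel",
       "channel must be a single capital letter")
  flag(is.na(ads$week_id) | !ads$week_id %in% 1:4, "week_id",
       "week_id must be in 1..4")
  flag(is.na(ads$day_kind) | !ads$day_kind %in% DAY_KINDS, "day_kind",
       "day_kind must be weekday or weekend")
  flag(is.na(ads$program_rating) | !ads$program_rating %in% RATINGS,
       "program_rating", "program_rating must be C, G or PG")
  flag(is.na(ads$ad_class) | !ads$ad_class %in% AD_CLASSES, "ad_class",
       "ad_class must be food or nonfood")

  mins <- hhmm_to_minutes(ads$airtime)
  flag(is.na(mins), "airtime", "airtime must be HH:MM (24-hour)")
  for (dk in DAY_KINDS) {
    w <- WINDOWS[[dk]]
    in_kind <- !is.na(ads$day_kind) & ads$day_kind == dk & !is.na(mins)
    flag(in_kind & (mins < w[1] | mins > w[2]), "airtime",
         paste0(dk, " airtime outside ", minutes_to_hhmm(w[1]), "-",
                minutes_to_hhmm(w[2])))
  }

  is_food <- !is.na(ads$ad_class) & ads$ad_class == "food"
  blank <- function(x) is.na(x) | x == ""
  flag(is_food & blank(ads$product_id), "product_id",
       "food record must carry a product_id")
  flag(is_food & blank(ads$category_id), "category_id",
       "food record must carry a category_id")
  is_nonfood <- !is.na(ads$ad_class) & ads$ad_class == "nonfood"
  flag(is_nonfood & (!blank(ads$product_id) | !blank(ads$category_id)),
       "ad_class", "nonfood record must not carry product/category ids")
  flag(is.na(ads$has_claim), "has_claim", "has_claim must be TRUE/FALSE")
  flag(is.na(ads$has_disclaimer), "has_disclaimer",
       "has_disclaimer must be TRUE/FALSE")

  if (length(diag)) {
    dplyr::arrange(dplyr::bind_rows(diag), row, field)
  } else {
    tibble::tibble(row = integer(), field = character(), message = character())
  }
}

#' Read a coded advertisement log
#'
#' CSV dialect: UTF-8, comma separated, header required, airtimes as `HH:MM`
#' 24-hour clock. Any invalid row aborts the read with row-numbered
#' diagnostics attached to the condition (`diagnostics` field), so a corpus is
#' either loaded whole or rejected loudly.
#'
#' @param path Path to the `ads.csv` file.
#' @return A validated tibble of advertisement records.
#' @export
read_ads <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    channel = readr::col_character(),
    week_id = readr::col_integer(),
    day_kind = readr::col_character(),
    airtime = readr::col_character(),
    program_rating = readr::col_character(),
    ad_class = readr::col_character(),
    product_id = readr::col_character(),
    category_id = readr::col_character(),
    has_claim = readr::col_logical(),
    has_disclaimer = readr::col_logical(),
    claim_text = readr::col_character()
  ), progress = FALSE)
  if (!"claim_text" %in% names(df)) df$claim_text <- NA_character_
  diag <- validate_ads(df)
  if (nrow(diag)) {
    rlang::abort(
      c(paste0(nrow(diag), " invalid advertisement record(s) in ", path),
        utils::head(paste0("row ", diag$row, " [", diag$field, "]: ",
                           diag$message), 10)),
      class = "npmtv_validation_error",
      diagnostics = diag
    )
  }
  df
}

#' Write a coded advertisement log
#'
#' Inverse of [read_ads()]: writing then reading reproduces the records
#' exactly (round-trip identity).
#'
#' @param ads Advertisement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ads <- function(ads, path) {
  diag <- validate_ads(ads)
  if (nrow(diag)) {
    rlang::abort("refusing to write an invalid advertisement log",
                 class = "npmtv_validation_error", diagnostics = diag)
  }
  readr::write_csv(ads[AD_COLS], path, progress = FALSE, na = "")
  invisible(path)
}

#' Read / write an analyzed-hours table
#'
#' One row per channel x week x program-rating cell with the fractional hours
#' of broadcast actually analyzed; these are the denominators of the hourly
#' advertisement frequencies.
#'
#' @param path Path to the `blocks.csv` file.
#' @return A tibble with columns `channel`, `week_id`, `program_rating`,
#'   `hours_analyzed` (all `hours_analyzed` > 0).
#' @export
read_blocks <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    channel = readr::col_character(),
    week_id = readr::col_integer(),
    program_rating = readr::col_character(),
    hours_analyzed = readr::col_double()
  ), progress = FALSE)
  validate_blocks(df)
  df
}

#' @rdname read_blocks
#' @param blocks Analyzed-hours tibble.
#' @export
write_blocks <- function(blocks, path) {
  validate_blocks(blocks)
  readr::write_csv(blocks[BLOCK_COLS], path, progress = FALSE)
  invisible(path)
}

validate_blocks <- function(blocks) {
  missing_cols <- setdiff(BLOCK_COLS, names(blocks))
  if (length(missing_cols)) {
    rlang::abort(paste0("blocks table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "npmtv_validation_error")
  }
  if (any(is.na(blocks$hours_analyzed) | blocks$hours_analyzed <= 0)) {
    rlang::abort("hours_analyzed must be > 0 in every block",
                 class = "npmtv_validation_error")
  }
  if (any(!blocks$program_rating %in% RATINGS)) {
    rlang::abort("program_rating must be C, G or PG",
                 class = "npmtv_validation_error")
  }
  if (anyDuplicated(blocks[c("channel", "week_id", "program_rating")])) {
    rlang::abort("duplicate channel/week/rating block",
                 class = "npmtv_validation_error")
  }
  invisible(blocks)
}

#' Intercoder percent agreement
#'
#' Percent agreement between two independent coders on a double-coded sample:
#' `100 * agreements / (agreements + disagreements)`. The statistic is
#' scale-invariant in the tallies.
#'
#' @param n_agreements Number of coding decisions on which the coders agreed.
#' @param n_disagreements Number on which they disagreed.
#' @return Percent agreement, a bare number in \[0, 100\].
#' @examples
#' intercoder_reliability(97, 3)
#' @export
intercoder_reliability <- function(n_agreements, n_disagreements) {
  if (length(n_agreements) != 1 || length(n_disagreements) != 1 ||
      is.na(n_agreements) || is.na(n_disagreements) ||
      n_agreements < 0 || n_disagreements < 0) {
    rlang::abort("counts must be single non-negative numbers",
                 class = "npmtv_validation_error")
  }
  total <- n_agreements + n_disagreements
  if (total == 0) {
    rlang::abort("at least one coded item is required (both counts are zero)",
                 class = "npmtv_validation_error")
  }
  100 * n_agreements / total
}
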