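# Shared vocabulary and small numeric helpers.

# Nutrient keys a category threshold table may reference (per 100 g or 100 mL).
NUTRIENT_KEYS <- c(
  "energy_kcal", "total_fat_g", "saturated_fat_g",
  "total_sugars_g", "added_sugars_g", "salt_g"
)

RATINGS <- c("C", "G", "PG")
DAY_KINDS <- c("weekday", "weekend")
AD_CLASSES <- c("food", "nonfood")
BASES <- c("per_100_g", "per_100_mL")
COMPOSITION_SOURCES <- c("label", "website_or_manufacturer", "fct_middle_east", "usda_fcd")

# Viewing windows, minutes from midnight. Weekday coverage starts after the
# school day; weekend coverage starts in the morning.
WINDOWS <- list(
  weekday = c(15L * 60L, 22L * 60L),
  weekend = c(8L * 60L, 22L * 60L)
)

#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), the convention used by the
#' printed exposure tables, as opposed to [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.25), 0)
#' round_half_up(16.342, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  scale <- 10^digits
  # tiny epsilon guards exact .5 ties against binary representation error
  floor(abs(x) * scale + 0.5 + 1e-9) / scale * sign(x)
}

minutes_to_hhmm <- function(m) {
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

hhmm_to_minutes <- function(x) {
  ok <- grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(substr(x[ok], 1, 2)) * 60L + as.integer(substr(x[ok], 4, 5))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
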