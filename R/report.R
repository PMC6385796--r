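# Pipeline orchestration: profile a catalogue, analyze a corpus into report
# tables, or emit a simulated corpus. Every report directory embeds a run
# manifest; the data files are byte-stable given equal inputs.

run_manifest <- function(inputs, extra = list()) {
  c(
    list(
      tool = "npmtv",
      version = as.character(utils::packageVersion("npmtv")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      inputs = inputs
    ),
    extra
  )
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

flatten_decisions <- function(decisions) {
  decisions |>
    dplyr::mutate(violations = purrr::map_chr(violations, function(v) {
      if (!nrow(v)) return("")
      paste(ifelse(is.na(v$key), v$rule_id, paste0(v$rule_id, ":", v$key)),
            collapse = ";")
    }))
}

#' Profile a product catalogue
#'
#' Scores every product (and composite meal) in a catalogue against a
#' nutrient-profile model and writes one decision row per product to
#' `decisions.csv` in the output directory, with violated rules flattened to a
#' `rule:key` list. Data-insufficient products are flagged, never dropped.
#'
#' @param products Product tibble or path to a catalogue CSV.
#' @param model Model tibble or path to a model file.
#' @param out_dir Output directory (created if needed).
#' @param components Optional composite table or path to its CSV.
#' @return The decisions tibble, invisibly.
#' @export
run_profile <- function(products, model, out_dir, components = NULL) {
  if (is.character(products)) products <- read_products(products)
  if (is.character(model)) model <- read_npm_model(model)
  if (is.character(components)) components <- read_components(components)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  decisions <- evaluate_products(products, model, components)
  readr::write_csv(flatten_decisions(decisions),
                   file.path(out_dir, "decisions.csv"), progress = FALSE)
  write_manifest(run_manifest(list(n_products = nrow(products))), out_dir)
  invisible(decisions)
}

#' Analyze a corpus into exposure report tables
#'
#' Runs the full descriptive pipeline on a coded corpus and writes the
#' standard report set to `out_dir`: food-ad shares overall/by rating/by
#' rating-week (`food_share*.csv`), hourly frequencies (`frequency.csv`),
#' the category distribution (`categories.csv`), permitted/not-permitted
#' shares under the requested basis (`permitted.csv`), claim and disclaimer
#' shares (`claims.csv`), a machine-readable `summary.json`, and a
#' `manifest.json`.
#'
#' @param ads Advertisement tibble or path to `ads.csv`.
#' @param blocks Analyzed-hours tibble or path to `blocks.csv`.
#' @param products Product tibble or path to the catalogue CSV.
#' @param model Model tibble or path to a model file.
#' @param basis `"emr18"` or `"extended"` (see [permitted_share()]).
#' @param out_dir Output directory (created if needed).
#' @param components Optional composite table or path.
#' @return A named list of the report tibbles, invisibly.
#' @export
run_analyze <- function(ads, blocks, products, model,
                        basis = c("emr18", "extended"), out_dir,
                        components = NULL) {
  basis <- rlang::arg_match(basis)
  if (is.character(ads)) ads <- read_ads(ads)
  if (is.character(blocks)) blocks <- read_blocks(blocks)
  if (is.character(products)) products <- read_products(products)
  if (is.character(model)) model <- read_npm_model(model)
  if (is.character(components)) components <- read_components(components)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- list(
    food_share_overall = food_ad_share(ads, by = "overall"),
    food_share_rating = food_ad_share(ads, by = "rating"),
    food_share_rating_week = food_ad_share(ads, by = "rating_week"),
    frequency = dplyr::bind_rows(
      hourly_frequency(ads, blocks, by = "rating"),
      dplyr::mutate(hourly_frequency(ads, blocks, by = "overall"),
                    program_rating = "overall")
    ),
    categories = category_distribution(ads, by = "rating"),
    permitted = permitted_share(ads, products, model, basis = basis,
                                components = components),
    claims = dplyr::bind_rows(
      dplyr::mutate(claims_share(ads, by = "rating"), kind = "claim"),
      dplyr::mutate(claims_share(ads, by = "overall"),
                    program_rating = "overall", kind = "claim"),
      dplyr::mutate(disclaimers_share(ads, by = "rating"), kind = "disclaimer"),
      dplyr::mutate(disclaimers_share(ads, by = "overall"),
                    program_rating = "overall", kind = "disclaimer")
    )
  )
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  summary <- list(
    n_ads = nrow(ads),
    n_food_ads = sum(ads$ad_class == "food"),
    hours_analyzed = sum(blocks$hours_analyzed),
    food_share_pct = tables$food_share_overall$pct,
    freq_per_hour = tables$frequency$freq_per_hour[
      tables$frequency$program_rating == "overall"],
    basis = basis,
    permitted_overall_pct = tables$permitted$pct_permitted[
      tables$permitted$program_rating == "overall"]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(run_manifest(list(n_ads = nrow(ads), basis = basis)), out_dir)
  invisible(tables)
}

#' Simulate a corpus to disk
#'
#' Generates a synthetic corpus (see [generate_corpus()]) and writes
#' `ads.csv`, `blocks.csv`, `products.csv`, the configuration as
#' `config.yaml`, and a manifest to the output directory.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return The generated corpus list, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  sim <- generate_corpus(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ads(sim$ads, file.path(out_dir, "ads.csv"))
  write_blocks(sim$blocks, file.path(out_dir, "blocks.csv"))
  write_products(sim$products, file.path(out_dir, "products.csv"))
  yaml::write_yaml(
    purrr::map(unclass(config), function(x) {
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
    }),
    file.path(out_dir, "config.yaml")
  )
  write_manifest(run_manifest(list(seed = config$rng_seed)), out_dir)
  invisible(sim)
}

#' Bar chart of food-advertisement shares
#'
#' Renders a share table from [food_ad_share()] as a grouped bar chart
#' (percent of advertisements that are for food, by program rating and, when
#' present, study week).
#'
#' @param share A tibble from [food_ad_share()].
#' @return A ggplot object.
#' @export
plot_food_ad_share <- function(share) {
  stopifnot(is.data.frame(share), "pct" %in% names(share))
  if ("week_id" %in% names(share) && "program_rating" %in% names(share)) {
    ggplot2::ggplot(share, ggplot2::aes(
      x = factor(week_id), y = pct, fill = program_rating
    )) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "Study week", y = "Food advertisements (%)",
                    fill = "Program rating")
  } else if ("program_rating" %in% names(share)) {
    ggplot2::ggplot(share, ggplot2::aes(x = program_rating, y = pct)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "Program rating", y = "Food advertisements (%)")
  } else {
    ggplot2::ggplot(share, ggplot2::aes(x = "overall", y = pct)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "Food advertisements (%)")
  }
}
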