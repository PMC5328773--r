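#' Run the full colony surveillance pipeline
#'
#' Executes validate -> Mendelian segregation (standard and Mendelian2) ->
#' mortality -> growth -> composition over a colony record set, writing TSV
#' tables, a full-precision JSON summary, a human-readable report laid out as
#' observed / Mendelian / delta / chi-square rows, and a run manifest. When
#' no colony is supplied one is simulated from `config` (plus growth and
#' composition records), so the pipeline is fully reproducible from a seed
#' alone. Reports round to display precision (2 decimals for chi-square
#' components, 3 for proportions); the JSON carries full precision.
#'
#' @param colony optional `list(litters, pups)`; simulated when NULL.
#' @param weights optional long weight table; simulated when NULL and the
#'   colony was simulated.
#' @param composition optional QMR record table; simulated likewise.
#' @param config [colony_config()] used when simulating.
#' @param seed integer seed governing every simulated stage.
#' @param out_dir output directory (created if needed); NULL to skip writing.
#' @return invisibly, a list with each stage's results and the manifest.
#' @export
run_colony_pipeline <- function(colony = NULL, weights = NULL,
                                composition = NULL,
                                config = colony_config(), seed = 1,
                                out_dir = NULL) {
  simulated <- is.null(colony)
  if (simulated) {
    colony <- simulate_colony(config, seed)
    if (is.null(weights)) weights <- simulate_growth(colony$pups, seed = seed)
    if (is.null(composition)) {
      adults <- colony$pups[colony$pups$weaned & !is.na(colony$pups$genotype), ]
      mice <- data.frame(mouse_id = adults$pup_id,
                         category = pup_category(adults$sex, adults$genotype))
      composition <- simulate_composition(mice, seed = seed)
    }
  }
  validate_colony(colony$pups, colony$litters)
  if (nrow(colony$pups) == 0) stop("empty colony", call. = FALSE)

  weaned_counts <- suppressMessages(tally_categories(
    colony$pups, "six", filter = colony$pups$weaned))
  standard <- chi_square_fit(weaned_counts)
  m2 <- mendelian2_estimate(weaned_counts)
  sexes <- sex_ratio_test(sum(colony$pups$sex == "M" & colony$pups$weaned),
                          sum(colony$pups$sex == "F" & colony$pups$weaned))
  mortality <- list(
    timecourse = death_timecourse(colony$pups),
    periods = period_proportions(colony$pups, colony$litters),
    success = litter_success(colony$litters, colony$pups))

  growth <- composition_summary <- plane <- NULL
  if (!is.null(weights) && nrow(weights)) {
    gains <- weekly_gains(weights)
    growth <- list(gains = gains,
                   first_pause = first_pause_distribution(gains))
  }
  if (!is.null(composition) && nrow(composition)) {
    props <- composition_proportions(composition)
    props$hydration <- hydration_ratio(props$total_water_p, props$free_water_p,
                                       props$lean_p)
    composition_summary <- stats::aggregate(
      cbind(lean_p, fat_p, total_water_p, free_water_p, total_p, hydration) ~
        category, props, mean)
    fitset <- props[props$category %in% c("mWT", "fWT", "mhet", "fhet"), ]
    if (nrow(fitset) >= 3)
      plane <- fit_plane_rotation(fitset$lean_p, fitset$fat_p,
                                  fitset$specific_water_p)
  }

  manifest <- list(seed = seed, simulated = simulated,
                   n_litters = nrow(colony$litters),
                   n_pups = nrow(colony$pups),
                   tool_version = as.character(utils::packageVersion("bkcolony")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  result <- list(weaned_counts = weaned_counts, standard = standard,
                 mendelian2 = m2, sex_ratio = sexes, mortality = mortality,
                 growth = growth, composition = composition_summary,
                 plane = plane, manifest = manifest)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", row.names = FALSE, quote = FALSE)

  fit_table <- function(fit) data.frame(
    category = names(fit$observed),
    observed = as.integer(fit$observed),
    expected = fit$expected,
    delta = fit$observed - fit$expected,
    component = fit$components,
    flagged = names(fit$observed) %in% fit$flagged)
  tsv(fit_table(result$standard), "mendelian_standard.tsv")
  tsv(fit_table(result$mendelian2$fit), "mendelian2.tsv")
  tsv(result$mortality$timecourse$by_day, "mortality_timecourse.tsv")
  tsv(result$mortality$periods, "mortality_periods.tsv")
  tsv(result$mortality$success$per_litter, "litter_success.tsv")
  if (!is.null(result$composition)) tsv(result$composition, "composition_summary.tsv")

  summary_json <- list(
    mendelian = list(
      observed = as.list(result$weaned_counts),
      standard = list(total_chi2 = result$standard$total_chi2,
                      df = result$standard$df,
                      p_value = result$standard$p_value,
                      flagged = result$standard$flagged),
      mendelian2 = list(seed_total = result$mendelian2$seed_total,
                        refined_total = result$mendelian2$refined_total,
                        total_chi2 = result$mendelian2$fit$total_chi2)),
    sex_ratio = result$sex_ratio,
    mortality = list(early = result$mortality$timecourse$early,
                     late = result$mortality$timecourse$late,
                     undated = result$mortality$timecourse$undated),
    plane = if (!is.null(result$plane))
      list(phi = result$plane$phi, psi = result$plane$psi,
           coefficients = as.list(result$plane$coefficients),
           residual_ss = result$plane$residual_ss),
    manifest = result$manifest)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  rep <- file.path(out_dir, "report.txt")
  con <- file(rep, "w"); on.exit(close(con))
  row6 <- function(label, v, dig = 0)
    writeLines(sprintf("%-11s %s", label,
                       paste(formatC(v, digits = dig, format = "f", width = 7),
                             collapse = " ")), con)
  writeLines("Weaned pups: sex-by-genotype segregation", con)
  writeLines(paste("           ", paste(sprintf("%7s", names(result$weaned_counts)),
                                        collapse = " ")), con)
  row6("Observed", result$weaned_counts)
  row6("Mendelian", result$standard$expected, 2)
  row6("Delta", result$weaned_counts - result$standard$expected, 2)
  row6("Chi-sq", result$standard$components, 2)
  writeLines(sprintf("total chi-square %.2f, df %d, P = %.3g",
                     result$standard$total_chi2, result$standard$df,
                     result$standard$p_value), con)
  writeLines(sprintf("Mendelian2 refined total: %d (seed %.1f)",
                     result$mendelian2$refined_total,
                     result$mendelian2$seed_total), con)
  row6("Mendelian2", result$mendelian2$fit$expected, 2)
  row6("Chi-sq", result$mendelian2$fit$components, 2)
  writeLines(sprintf("male proportion of weaned pups %.3f (chi2 %.2f, P = %.2g)",
                     result$sex_ratio$male_prop, result$sex_ratio$chi2,
                     result$sex_ratio$p_value), con)
  invisible(rep)
}
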