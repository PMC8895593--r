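#' Derive menopausal status for a cohort (full algorithm)
#'
#' Runs the complete derivation on a cohort: Step 1 (intervention
#' categories), Step 2 (detailed derived status under `policy`), Step 3A
#' (age-threshold estimation with the chosen method, unless a manual
#' `threshold_age` is given) and Step 3B (consolidation, optionally
#' re-classifying detailed `unknown` records by age).
#'
#' @param cohort A `meno_cohort` from [read_cohort()], [as_cohort()] or
#'   [simulate_cohort()].
#' @param policy A [classification_policy()].
#' @param method Threshold method, see [estimate_threshold()].
#' @param cut_point Cut-point for the threshold estimation (default 0.90).
#' @param threshold_age Optional manual integer threshold, bypassing
#'   estimation.
#' @param reclassify_unknown Re-classify detailed `unknown` records at or
#'   above the threshold (default `TRUE`)?
#'
#' @return An object of class `meno_derivation`: list with `results` (per
#'   record: `id`, `intervention_category`, `detailed`, `consolidated`,
#'   `flags`), `threshold` (`meno_threshold` or the manual age),
#'   `comparison` (from [compare_to_self_report()]), `interventions` (from
#'   [tabulate_interventions()]), `policy`, `n`, and the input `cohort`.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 5000, seed = 7))
#' fit <- derive_menopause(cohort)
#' summary(fit)
#' @export
derive_menopause <- function(cohort, policy = classification_policy(),
                             method = "reference", cut_point = 0.90,
                             threshold_age = NULL,
                             reclassify_unknown = TRUE) {
  results <- classify_cohort(cohort, policy)
  thr <- if (!is.null(threshold_age)) {
    as.integer(threshold_age)
  } else {
    estimate_threshold(cohort, results,
                       spec = threshold_spec(method = method,
                                             cut_point = cut_point))
  }
  results <- consolidate_cohort(results, cohort, thr, reclassify_unknown)
  df <- as.data.frame(cohort)
  structure(list(
    results = results,
    threshold = thr,
    comparison = compare_to_self_report(df$menopause, results$consolidated),
    interventions = tabulate_interventions(cohort),
    policy = policy,
    reclassify_unknown = reclassify_unknown,
    n = nrow(df),
    cohort = cohort), class = "meno_derivation")
}

#' @noRd
.threshold_age_of <- function(thr) {
  if (inherits(thr, "meno_threshold")) thr$threshold_age else thr
}

#' @export
print.meno_derivation <- function(x, ...) {
  cat("Derived menopausal status for ", x$n, " women\n", sep = "")
  cat("  age threshold: >= ", .threshold_age_of(x$threshold), " years",
      if (inherits(x$threshold, "meno_threshold"))
        paste0(" (", x$threshold$method, " method)"), "\n", sep = "")
  tab <- table(factor(x$results$consolidated, consolidated_levels()))
  for (lv in names(tab))
    cat(sprintf("  %-15s %7d (%.1f%%)\n", lv, tab[[lv]],
                100 * tab[[lv]] / max(x$n, 1)))
  invisible(x)
}

#' @export
summary.meno_derivation <- function(object, ...) {
  structure(list(
    n = object$n,
    threshold_age = .threshold_age_of(object$threshold),
    comparison = object$comparison,
    detailed_counts = table(factor(object$results$detailed,
                                   detailed_levels())),
    crosstab = crosstab(object$cohort$menopause,
                        object$results$consolidated,
                        derived_levels = consolidated_levels())),
    class = "summary.meno_derivation")
}

#' @export
print.summary.meno_derivation <- function(x, ...) {
  cat("Derivation summary (n = ", x$n, ", threshold >= ", x$threshold_age,
      " years)\n\nDetailed derived status:\n", sep = "")
  print(x$detailed_counts)
  cat("\nSelf-reported vs consolidated derived status:\n")
  print(x$crosstab)
  cat("\nPer-category comparison with direct self-report:\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Run the full pipeline and write its artifacts
#'
#' Executes simulate-or-read, classify, threshold estimation, consolidation
#' and reporting, writing all artifacts under `out_dir`: `results.csv`
#' (records + derived columns), `interventions.csv`,
#' `threshold_<method>.csv` (scan table), `thresholds.csv` (summary),
#' `crosstab.csv`, `changes.csv`, `flow.csv` and `run_metadata.json`
#' (package version, configuration and seed). Identical configuration gives
#' byte-identical outputs.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `input` (CSV path) or `simulate` (list of [cohort_params()] arguments),
#'   optional `schema` (YAML path), `policy` (list of
#'   [classification_policy()] arguments or YAML path), `method` (default
#'   `"reference"`), `cut_point` (default 0.90), `reclassify_unknown`
#'   (default `TRUE`), `out_dir` (default `"menoderive-output"`).
#' @return Invisibly, the `meno_derivation` object, with the written paths in
#'   `attr(, "paths")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- .read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "menoderive-output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (!is.null(config$input)) {
    schema <- if (!is.null(config$schema)) read_schema(config$schema) else
      cohort_schema()
    read_cohort(config$input, schema)
  } else if (!is.null(config$simulate)) {
    simulate_cohort(do.call(cohort_params, config$simulate))
  } else {
    stop("config must provide either 'input' or 'simulate'")
  }
  policy <- if (is.null(config$policy)) classification_policy()
    else if (is.character(config$policy)) read_policy(config$policy)
    else do.call(classification_policy, config$policy)

  fit <- derive_menopause(
    cohort, policy,
    method = config$method %||% "reference",
    cut_point = config$cut_point %||% 0.90,
    threshold_age = config$threshold_age,
    reclassify_unknown = config$reclassify_unknown %||% TRUE)

  paths <- c(results = file.path(out_dir, "results.csv"))
  write_results(cohort, fit$results, paths[["results"]])
  p <- file.path(out_dir, "interventions.csv")
  utils::write.csv(fit$interventions, p, row.names = FALSE)
  paths["interventions"] <- p
  if (inherits(fit$threshold, "meno_threshold")) {
    p <- file.path(out_dir, paste0("threshold_", fit$threshold$method, ".csv"))
    utils::write.csv(fit$threshold$table, p, row.names = FALSE)
    paths["threshold_table"] <- p
    p <- file.path(out_dir, "thresholds.csv")
    utils::write.csv(data.frame(method = fit$threshold$method,
                                threshold_age = fit$threshold$threshold_age,
                                cut_point = fit$threshold$cut_point,
                                n_eligible = fit$threshold$n_eligible),
                     p, row.names = FALSE)
    paths["thresholds"] <- p
  }
  df <- as.data.frame(cohort)
  p <- file.path(out_dir, "crosstab.csv")
  utils::write.csv(as.data.frame(crosstab(
    df$menopause, fit$results$consolidated,
    derived_levels = consolidated_levels())), p, row.names = FALSE)
  paths["crosstab"] <- p
  p <- file.path(out_dir, "changes.csv")
  utils::write.csv(fit$comparison, p, row.names = FALSE)
  paths["changes"] <- p
  p <- file.path(out_dir, "flow.csv")
  utils::write.csv(flow_table(df$menopause, fit$results$detailed,
                              fit$results$consolidated), p, row.names = FALSE)
  paths["flow"] <- p
  meta <- list(
    package = "menoderive",
    version = as.character(utils::packageVersion("menoderive")),
    config = config,
    threshold_age = .threshold_age_of(fit$threshold))
  p <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths["metadata"] <- p
  attr(fit, "paths") <- paths
  invisible(fit)
}
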