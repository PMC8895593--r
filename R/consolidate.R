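## Step 3B: collapse the seven detailed categories to four, re-classifying
## masked or unknown status to post-menopause at or above the age threshold.

#' Consolidate a detailed status to one of four categories (Step 3B)
#'
#' Vectorised mapping from the detailed derived status to
#' `post/peri/pre_menopause/unknown`:
#' * `natural_menopause` and `menopause_from_oophorectomy` with self-reported
#'   menopause are always `post_menopause`;
#' * `peri_menopause` and `pre_menopause` pass through unchanged (never
#'   re-classified);
#' * potentially masked statuses (`mht_before_periods_stopped`,
#'   `no_periods_hysterectomy`, and `menopause_from_oophorectomy` without
#'   self-reported menopause, which may indicate a unilateral oophorectomy)
#'   become `post_menopause` when the baseline age is at or above the
#'   threshold, `unknown` otherwise;
#' * `unknown` is re-classified the same way when `reclassify_unknown` is
#'   `TRUE`, else stays `unknown`.
#'
#' A threshold of `t` means "aged >= t years at baseline". Records without a
#' baseline age cannot be re-classified and stay `unknown`.
#'
#' @param detailed Character vector of detailed statuses.
#' @param menopause Aligned self-reported menopause responses.
#' @param age_at_baseline Aligned baseline ages (years).
#' @param threshold_age Integer age threshold.
#' @param reclassify_unknown Re-classify detailed `unknown` by age?
#' @return Character vector of consolidated statuses.
#' @examples
#' consolidate_status("no_periods_hysterectomy", "not_sure", 60, 55)  # post
#' consolidate_status("no_periods_hysterectomy", "not_sure", 52, 55)  # unknown
#' @export
consolidate_status <- function(detailed, menopause, age_at_baseline,
                               threshold_age, reclassify_unknown = TRUE) {
  stopifnot(length(threshold_age) == 1, !is.na(threshold_age))
  n <- length(detailed)
  out <- rep(NA_character_, n)
  above <- !is.na(age_at_baseline) & age_at_baseline >= threshold_age

  out[detailed == "natural_menopause"] <- "post_menopause"
  ooph <- detailed == "menopause_from_oophorectomy"
  out[ooph & menopause == "yes"] <- "post_menopause"
  out[detailed == "peri_menopause"] <- "peri_menopause"
  out[detailed == "pre_menopause"] <- "pre_menopause"

  masked <- detailed %in% c("mht_before_periods_stopped",
                            "no_periods_hysterectomy") |
    (ooph & menopause != "yes")
  out[masked] <- ifelse(above[masked], "post_menopause", "unknown")

  unk <- detailed == "unknown"
  out[unk] <- if (reclassify_unknown)
    ifelse(above[unk], "post_menopause", "unknown") else "unknown"
  out
}

#' Consolidate a classified cohort (Step 3B)
#'
#' Fills the `consolidated` column of the classification results using an
#' estimated (or manually chosen) age threshold. Refuses a threshold that was
#' not attained. Records lacking a baseline age that would need
#' re-classification stay `unknown` and receive the flag
#' `MISSING_BASELINE_AGE`.
#'
#' @param results Classification results from [classify_cohort()].
#' @param cohort The aligned `meno_cohort`.
#' @param threshold A `meno_threshold` from [estimate_threshold()], or a
#'   single integer age.
#' @param reclassify_unknown Re-classify detailed `unknown` by age
#'   (default `TRUE`)?
#' @return `results` with the `consolidated` column filled (one of
#'   [consolidated_levels()] per record).
#' @export
consolidate_cohort <- function(results, cohort, threshold,
                               reclassify_unknown = TRUE) {
  if (inherits(threshold, "meno_threshold")) {
    if (!threshold$attained)
      stop("age threshold not attained (", threshold$message,
           "); cannot consolidate")
    threshold <- threshold$threshold_age
  }
  df <- as.data.frame(cohort)
  if (nrow(results) != nrow(df) ||
      !identical(as.character(results$id), as.character(df$id)))
    stop("cohort and results are not aligned by participant id")
  results$consolidated <- consolidate_status(
    results$detailed, df$menopause, df$age_baseline, threshold,
    reclassify_unknown)
  needs_age <- results$detailed %in%
    c("mht_before_periods_stopped", "no_periods_hysterectomy", "unknown") |
    (results$detailed == "menopause_from_oophorectomy" &
       df$menopause != "yes")
  noage <- needs_age & is.na(df$age_baseline) &
    !(results$detailed == "unknown" & !reclassify_unknown)
  if (any(noage))
    results$flags[noage] <- ifelse(
      results$flags[noage] == "", "MISSING_BASELINE_AGE",
      paste(results$flags[noage], "MISSING_BASELINE_AGE", sep = ";"))
  results
}
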