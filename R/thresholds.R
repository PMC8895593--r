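## Step 3A: estimate the baseline-age threshold above which women with masked
## or unknown status are highly likely to be post-menopausal. Three methods,
## all restricted to women whose status no intervention could have affected
## (never MHT, no hysterectomy, no bilateral oophorectomy, no current hormonal
## contraception):
##   reference ........... cumulative distribution of the reported age at
##                         natural menopause among women aged >= 55 at
##                         baseline; threshold = first age below which >= 90%
##                         of reported menopause ages fall.
##   conservative ........ per single-year baseline-age group, proportion
##                         self-reporting menopause; threshold = first age
##                         from which every sufficiently large group is >= 90%.
##   least conservative .. tail proportion with detailed status
##                         natural_menopause among women at or above each
##                         baseline age; threshold = first age whose tail
##                         reaches 90%.

#' Specification of a threshold-estimation method
#'
#' @param method One of `reference`, `conservative`, `least_conservative`.
#' @param cut_point Proportion in (0, 1) that defines "highly likely to be
#'   post-menopausal" (default 0.90; higher values trade the number of women
#'   re-classified for specificity).
#' @param min_baseline_age_reference Minimum baseline age (years) for the
#'   reference method's eligible set (default 55): younger women could
#'   misinterpret a temporary irregularity as menopause.
#' @param min_group_n Minimum single-year group size for the conservative
#'   method (default 50); smaller (extreme-age) groups are ignored.
#' @param age_scan_range Integer ages scanned, default `c(45, 100)`.
#' @return An object of class `meno_threshold_spec`.
#' @export
threshold_spec <- function(method = c("reference", "conservative",
                                      "least_conservative"),
                           cut_point = 0.90,
                           min_baseline_age_reference = 55,
                           min_group_n = 50,
                           age_scan_range = c(45, 100)) {
  method <- match.arg(method)
  stopifnot(cut_point > 0, cut_point < 1,
            length(age_scan_range) == 2,
            age_scan_range[1] <= age_scan_range[2],
            min_group_n >= 1)
  structure(list(method = method, cut_point = cut_point,
                 min_baseline_age_reference = min_baseline_age_reference,
                 min_group_n = min_group_n,
                 age_scan_range = as.integer(age_scan_range)),
            class = "meno_threshold_spec")
}

#' Select the threshold-eligible subcohort
#'
#' All methods include only women whose menopausal status could not have been
#' affected by an intervention: never used MHT, no hysterectomy, no bilateral
#' oophorectomy, and not currently using hormonal contraception (a `missing`
#' response on any of these excludes the record). The reference method
#' additionally requires a detailed derived status of `natural_menopause`, a
#' reported age at menopause, and baseline age at or above
#' `min_baseline_age_reference`.
#'
#' @param cohort A `meno_cohort` or canonical data frame.
#' @param results Aligned classification results from [classify_cohort()]
#'   (needed for `reference` and `least_conservative`).
#' @param spec A [threshold_spec()].
#' @return The eligible records with the `detailed` status column attached.
#' @export
eligible_subcohort <- function(cohort, results = NULL,
                               spec = threshold_spec()) {
  df <- as.data.frame(cohort)
  if (!is.null(results)) {
    if (nrow(results) != nrow(df) ||
        !identical(as.character(results$id), as.character(df$id)))
      stop("cohort and results are not aligned by participant id")
    df$detailed <- results$detailed
  }
  keep <- df$mht == "never" & df$hysterectomy == "no" &
    df$oophorectomy == "no" & df$oc_current == "no"
  if (spec$method == "reference") {
    if (is.null(results))
      stop("the reference method needs classification results")
    keep <- keep & df$detailed == "natural_menopause" &
      !is.na(df$age_menopause) & !is.na(df$age_baseline) &
      df$age_baseline >= spec$min_baseline_age_reference
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the post-menopause age threshold (Step 3A)
#'
#' Filters the cohort with [eligible_subcohort()] and scans integer ages for
#' the smallest threshold at which the method's criterion reaches
#' `cut_point`. When no age in the scan range qualifies (or the eligible set
#' is empty, or no single-year group reaches `min_group_n` for the
#' conservative method), the threshold is reported as not attained rather
#' than an error; [consolidate_cohort()] refuses such a threshold.
#'
#' @inheritParams eligible_subcohort
#' @param method Shorthand to build a default [threshold_spec()] for one
#'   method; ignored when `spec` is given.
#' @param spec A [threshold_spec()].
#' @return An object of class `meno_threshold` with elements `method`,
#'   `threshold_age` (integer, `NA` when not attained), `attained`,
#'   `cut_point`, `n_eligible`, `table` (one row per scanned age: `age`,
#'   `numerator`, `denominator`, `proportion`) and `message`.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 2000, seed = 1))
#' res <- classify_cohort(cohort)
#' estimate_threshold(cohort, res, method = "reference")
#' @export
estimate_threshold <- function(cohort, results = NULL,
                               method = "reference", spec = NULL) {
  if (is.null(spec)) spec <- threshold_spec(method = method)
  if (is.null(results) &&
      spec$method %in% c("reference", "least_conservative"))
    results <- classify_cohort(cohort)
  elig <- eligible_subcohort(cohort, results, spec)
  scan <- seq(spec$age_scan_range[1], spec$age_scan_range[2])
  cut <- spec$cut_point

  tab <- switch(spec$method,
    reference = {
      ages <- elig$age_menopause
      num <- vapply(scan, function(a) sum(ages < a), integer(1))
      data.frame(age = scan, numerator = num,
                 denominator = rep(length(ages), length(scan)))
    },
    conservative = {
      grp <- floor(elig$age_baseline)
      den <- vapply(scan, function(a) sum(grp == a, na.rm = TRUE), integer(1))
      num <- vapply(scan, function(a)
        sum(grp == a & elig$menopause == "yes", na.rm = TRUE), integer(1))
      data.frame(age = scan, numerator = num, denominator = den)
    },
    least_conservative = {
      ab <- elig$age_baseline
      den <- vapply(scan, function(a) sum(ab >= a, na.rm = TRUE), integer(1))
      num <- vapply(scan, function(a)
        sum(ab >= a & elig$detailed == "natural_menopause", na.rm = TRUE),
        integer(1))
      data.frame(age = scan, numerator = num, denominator = den)
    })
  tab$proportion <- ifelse(tab$denominator > 0,
                           tab$numerator / tab$denominator, NA_real_)

  if (spec$method == "conservative") {
    qualifying <- tab$denominator >= spec$min_group_n
    if (!any(qualifying)) {
      return(.threshold_result(spec, NA_integer_, nrow(elig), tab,
        sprintf("no single-year group reaches min_group_n = %d",
                spec$min_group_n)))
    }
    ok <- !qualifying | (tab$proportion >= cut)
    from_here_on <- rev(cumprod(rev(ok))) > 0
    idx <- which(from_here_on)
  } else {
    if (nrow(elig) == 0 || all(tab$denominator == 0)) {
      return(.threshold_result(spec, NA_integer_, nrow(elig), tab,
                               "eligible set is empty"))
    }
    idx <- which(!is.na(tab$proportion) & tab$proportion >= cut)
  }
  if (!length(idx))
    return(.threshold_result(spec, NA_integer_, nrow(elig), tab,
      sprintf("no age in [%d, %d] reaches the %.0f%% cut-point",
              spec$age_scan_range[1], spec$age_scan_range[2], 100 * cut)))
  .threshold_result(spec, as.integer(scan[idx[1]]), nrow(elig), tab, NULL)
}

#' @noRd
.threshold_result <- function(spec, age, n_eligible, tab, message) {
  structure(list(method = spec$method,
                 threshold_age = age,
                 attained = !is.na(age),
                 cut_point = spec$cut_point,
                 n_eligible = n_eligible,
                 table = tab,
                 message = message),
            class = "meno_threshold")
}

#' @export
print.meno_threshold <- function(x, ...) {
  cat("Post-menopause age threshold (", x$method, " method, ",
      sprintf("%.0f%%", 100 * x$cut_point), " cut-point)\n", sep = "")
  cat("  eligible women: ", x$n_eligible, "\n", sep = "")
  if (x$attained) {
    cat("  threshold: baseline age >= ", x$threshold_age, " years\n", sep = "")
  } else {
    cat("  threshold: NOT ATTAINED (", x$message, ")\n", sep = "")
  }
  invisible(x)
}

#' Plot the scan behind an estimated threshold
#'
#' Shows the scanned proportion against age with the cut-point and, when
#' attained, the selected threshold.
#'
#' @param x A `meno_threshold`.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.meno_threshold <- function(x, ...) {
  tab <- x$table[!is.na(x$table$proportion), ]
  plot(tab$age, tab$proportion, type = "s", xlab = "age (years)",
       ylab = switch(x$method,
         reference = "cumulative proportion of reported menopause ages below age",
         conservative = "proportion self-reporting menopause in single-year group",
         least_conservative = "proportion natural menopause at or above age"),
       ylim = c(0, 1), main = paste("threshold scan:", x$method), ...)
  graphics::abline(h = x$cut_point, lty = 2)
  if (x$attained) graphics::abline(v = x$threshold_age, lty = 3)
  invisible(x)
}
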