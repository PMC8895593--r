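## Comparison outputs: cross-tabulations of self-reported against derived
## status, percentages of total, percentage-point and relative changes, and
## the three-level flow table. Percentages are computed on unrounded ratios
## and rounded half-up (half away from zero) to one decimal exactly once, at
## display.

#' Round half away from zero
#'
#' Decimal rounding as printed in epidemiological tables: exact halves round
#' away from zero (`round_half_up(0.25, 1)` is 0.3), unlike base [round()]'s
#' round-half-to-even. A tiny relative tolerance absorbs binary
#' representation error in ratios.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a total, one decimal
#'
#' @param count,total Non-negative counts; `total` must be positive.
#' @return `100 * count / total` rounded half-up to one decimal.
#' @examples
#' percent_of_total(93107, 142973)  # 65.1
#' @export
percent_of_total <- function(count, total) {
  if (any(total <= 0)) stop("percent_of_total is undefined for total <= 0")
  round_half_up(100 * count / total, 1)
}

#' Relative change between two counts, one decimal
#'
#' @param before,after Counts; `before` must be positive.
#' @return Signed percentage `100 * (after - before) / before`, half-up to
#'   one decimal.
#' @examples
#' relative_change(93107, 105817)  # 13.7
#' relative_change(22860, 10789)   # -52.8
#' @export
relative_change <- function(before, after) {
  if (any(before <= 0)) stop("relative_change is undefined for before <= 0")
  round_half_up(100 * (after - before) / before, 1)
}

#' Percentage-point change between two counts of a common total
#'
#' Both percentages are formed on the unrounded ratios; only the difference
#' is rounded (half-up, one decimal).
#'
#' @param count_a,count_b Counts sharing `total`.
#' @param total Positive total.
#' @return Signed percentage-point difference.
#' @examples
#' pp_change(105817, 93107, 142973)  # 8.9
#' @export
pp_change <- function(count_a, count_b, total) {
  if (any(total <= 0)) stop("pp_change is undefined for total <= 0")
  round_half_up(100 * count_a / total - 100 * count_b / total, 1)
}

#' Cross-tabulate self-reported against derived status
#'
#' @param self_reported Character vector of self-reported responses.
#' @param derived Aligned character vector of derived statuses (detailed or
#'   consolidated).
#' @param self_levels,derived_levels Optional level orders for the margins.
#' @return A contingency `table` (class `meno_crosstab`) whose row and column
#'   margins each sum to the number of records.
#' @export
crosstab <- function(self_reported, derived,
                     self_levels = .menopause_levels,
                     derived_levels = sort(unique(derived))) {
  if (length(self_reported) != length(derived))
    stop("self-reported and derived vectors differ in length")
  tab <- table(self_reported = factor(self_reported, levels = self_levels),
               derived = factor(derived, levels = derived_levels))
  class(tab) <- c("meno_crosstab", class(tab))
  tab
}

#' @export
print.meno_crosstab <- function(x, ...) {
  y <- x
  class(y) <- "table"
  print(stats::addmargins(y))
  invisible(x)
}

#' Three-level flow table: self-reported, detailed, consolidated
#'
#' Counts every observed (self-reported, detailed, consolidated) path; the
#' level-wise margins each sum to the number of records. Suitable for
#' external Sankey rendering after [utils::write.csv()].
#'
#' @param self_reported,detailed,consolidated Aligned status vectors.
#' @return Data frame with columns `self_reported`, `detailed`,
#'   `consolidated`, `n` (only paths with `n > 0`).
#' @export
flow_table <- function(self_reported, detailed, consolidated) {
  n <- length(self_reported)
  if (length(detailed) != n || length(consolidated) != n)
    stop("flow_table inputs differ in length")
  if (n == 0)
    return(data.frame(self_reported = character(), detailed = character(),
                      consolidated = character(), n = integer()))
  agg <- stats::aggregate(
    list(n = rep(1L, n)),
    by = list(self_reported = self_reported, detailed = detailed,
              consolidated = consolidated),
    FUN = sum)
  agg <- agg[order(agg$self_reported, agg$detailed, agg$consolidated), ]
  rownames(agg) <- NULL
  agg
}

#' Map self-reported responses to the four consolidated categories
#'
#' The direct reading of the questionnaire: "yes" is post-menopause,
#' "irregular" peri-menopause, "no" pre-menopause, and "not sure" or missing
#' unknown. This is the baseline against which the derived classification is
#' compared.
#'
#' @param menopause Character vector of self-reported responses.
#' @return Character vector of consolidated category codes.
#' @export
self_report_status <- function(menopause) {
  c(yes = "post_menopause", irregular = "peri_menopause",
    no = "pre_menopause", not_sure = "unknown",
    missing = "unknown")[menopause]
}

#' Compare derived consolidated counts with direct self-report
#'
#' Builds the per-category comparison: counts, percentages of total,
#' percentage-point change and relative change of the consolidated derived
#' status against the direct self-report mapping ([self_report_status()]).
#'
#' @param menopause Self-reported responses.
#' @param consolidated Aligned consolidated derived statuses.
#' @return Data frame with one row per consolidated category: `category`,
#'   `n_self`, `pct_self`, `n_derived`, `pct_derived`, `pp_change`,
#'   `rel_change` (relative change `NA` where the self-reported count is 0).
#' @export
compare_to_self_report <- function(menopause, consolidated) {
  if (length(menopause) != length(consolidated))
    stop("inputs differ in length")
  total <- length(menopause)
  lv <- consolidated_levels()
  n_self <- as.integer(table(factor(self_report_status(menopause), lv)))
  n_der <- as.integer(table(factor(consolidated, lv)))
  data.frame(
    category = lv,
    n_self = n_self,
    pct_self = percent_of_total(n_self, total),
    n_derived = n_der,
    pct_derived = percent_of_total(n_der, total),
    pp_change = pp_change(n_der, n_self, total),
    rel_change = ifelse(n_self > 0,
                        round_half_up(100 * (n_der - n_self) / n_self, 1),
                        NA_real_),
    stringsAsFactors = FALSE)
}
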