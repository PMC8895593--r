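## Step 2: the detailed derived menopausal status. A total, deterministic
## decision table over the self-reported menopause response, the three
## intervention responses and the ordering of event ages.
##
## Outline (defaults; every open cell is a policy knob):
##   any core response missing ............. unknown + MISSING_CORE
##   any event age > baseline + slack ...... unknown + INCONSISTENT
##   menopause = yes: test interventions in masking precedence order
##     (oophorectomy, hysterectomy, MHT). An intervention masks when its age
##     precedes the reported menopause age (oophorectomy: at or before, up to
##     the policy tolerance — a same-age oophorectomy is the proximate cause);
##     a needed age missing -> unknown + MISSING_EVENT_AGE; a later
##     (post-menopausal) intervention is non-masking and the scan continues;
##     nothing masks -> natural_menopause.
##   menopause = no: hysterectomy -> no_periods_hysterectomy; current MHT ->
##     mht_before_periods_stopped; else pre_menopause. A bilateral
##     oophorectomy reported together with "no" is treated as unilateral
##     (flag ASSUMED_UNILATERAL_OOPH).
##   menopause = irregular: current MHT -> mht_before_periods_stopped (MHT can
##     cause bleeding); surgery -> unknown + INCONSISTENT (bleeding
##     contradicts it); else peri_menopause.
##   menopause = not sure: first matching intervention in priority order
##     (oophorectomy -> menopause_from_oophorectomy, current MHT ->
##     mht_before_periods_stopped, hysterectomy -> no_periods_hysterectomy);
##     none -> peri_menopause (age at menopause unknown; flagged when the
##     target is unknown).

#' Classify a cohort into the seven detailed statuses (Step 2)
#'
#' Applies the decision table described in the package vignette to every
#' record. The classification is total (every record receives exactly one of
#' the seven statuses, with `unknown` absorbing inconsistent or insufficient
#' responses) and deterministic, and depends only on the record fields and the
#' policy.
#'
#' @param cohort A `meno_cohort` or data frame in canonical layout.
#' @param policy A [classification_policy()].
#' @return A data frame with one row per record: `id`,
#'   `intervention_category` (Step 1), `detailed` (one of
#'   [detailed_levels()]), and `flags` (semicolon-joined codes among
#'   `MISSING_CORE`, `MISSING_EVENT_AGE`, `INCONSISTENT`,
#'   `ASSUMED_UNILATERAL_OOPH`; every `unknown` carries at least one).
#' @examples
#' cohort <- as_cohort(data.frame(
#'   id = "w1", age_baseline = 60, menopause = "yes", mht = "never",
#'   hysterectomy = "no", oophorectomy = "no", oc_current = "no",
#'   age_menopause = 50, age_mht_start = NA, age_hysterectomy = NA,
#'   age_oophorectomy = NA))
#' classify_cohort(cohort)$detailed   # "natural_menopause"
#' @export
classify_cohort <- function(cohort, policy = classification_policy()) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  men <- df$menopause; mht <- df$mht
  hy <- df$hysterectomy; oo <- df$oophorectomy
  am <- df$age_menopause; ah <- df$age_hysterectomy
  ao <- df$age_oophorectomy; at <- df$age_mht_start
  ab <- df$age_baseline

  status <- rep(NA_character_, n)
  flags <- vector("list", n)
  addf <- function(idx, code) {
    for (j in idx) flags[[j]] <<- c(flags[[j]], code)
    invisible(NULL)
  }

  core_missing <- men == "missing" | mht == "missing" |
    hy == "missing" | oo == "missing"
  status[core_missing] <- "unknown"
  addf(which(core_missing), "MISSING_CORE")

  ev <- cbind(am, ah, ao, at)
  evmax <- suppressWarnings(do.call(pmax, c(as.data.frame(ev), na.rm = TRUE)))
  incons <- !core_missing & !is.na(ab) & !is.na(evmax) &
    evmax > ab + policy$baseline_slack
  status[incons] <- "unknown"
  addf(which(incons), "INCONSISTENT")

  pending <- !core_missing & !incons

  ## menopause = yes: masking-precedence scan against the reported age
  still <- pending & men == "yes"
  tol <- policy$oophorectomy_menopause_tolerance
  for (stage in policy$masking_precedence_for_yes) {
    if (stage == "oophorectomy") {
      app <- still & oo == "yes"
      both <- app & !is.na(am) & !is.na(ao)
      hit <- both & (ao <= am + tol)
      miss <- app & (is.na(am) | is.na(ao))
      status[hit] <- "menopause_from_oophorectomy"
    } else if (stage == "hysterectomy") {
      app <- still & hy == "yes"
      both <- app & !is.na(am) & !is.na(ah)
      hit <- both & (ah < am)
      miss <- app & (is.na(am) | is.na(ah))
      status[hit] <- "no_periods_hysterectomy"
    } else {
      app <- still & mht %in% c("former", "current")
      both <- app & !is.na(am) & !is.na(at)
      hit <- both & (at < am)
      miss <- app & (is.na(am) | is.na(at))
      status[hit] <- "mht_before_periods_stopped"
    }
    status[miss] <- "unknown"
    addf(which(miss), "MISSING_EVENT_AGE")
    still <- still & !hit & !miss
  }
  nat <- still
  noage <- nat & is.na(am)
  if (policy$natural_menopause_requires_age) {
    status[nat & !noage] <- "natural_menopause"
    status[noage] <- "unknown"
  } else {
    status[nat] <- "natural_menopause"
  }
  addf(which(noage), "MISSING_EVENT_AGE")

  ## menopause = no
  b <- pending & men == "no"
  h1 <- b & hy == "yes"
  status[h1] <- "no_periods_hysterectomy"
  m1 <- b & !h1 & mht == "current"
  status[m1] <- "mht_before_periods_stopped"
  status[b & !h1 & !m1] <- "pre_menopause"
  addf(which(b & oo == "yes"), "ASSUMED_UNILATERAL_OOPH")

  ## menopause = irregular
  b <- pending & men == "irregular"
  m1 <- b & mht == "current"
  status[m1] <- policy$irregular_with_current_mht
  s1 <- b & !m1 & oo == "yes"
  status[s1] <- policy$irregular_with_oophorectomy
  s2 <- b & !m1 & !s1 & hy == "yes"
  status[s2] <- policy$irregular_with_hysterectomy
  status[b & !m1 & !s1 & !s2] <- "peri_menopause"
  if (policy$irregular_with_oophorectomy == "unknown") addf(which(s1), "INCONSISTENT")
  if (policy$irregular_with_hysterectomy == "unknown") addf(which(s2), "INCONSISTENT")
  if (policy$irregular_with_current_mht == "unknown") addf(which(m1), "INCONSISTENT")

  ## menopause = not sure: intervention priority; no age comparison is
  ## possible because the age at menopause is unknown for these women
  still <- pending & men == "not_sure"
  for (p in policy$not_sure_priority) {
    hit <- switch(p,
      oophorectomy = still & oo == "yes",
      current_mht  = still & mht == "current",
      hysterectomy = still & hy == "yes")
    status[hit] <- switch(p,
      oophorectomy = "menopause_from_oophorectomy",
      current_mht  = "mht_before_periods_stopped",
      hysterectomy = "no_periods_hysterectomy")
    still <- still & !hit
  }
  status[still] <- policy$not_sure_unmasked_target
  if (policy$not_sure_unmasked_target == "unknown")
    addf(which(still), "MISSING_EVENT_AGE")

  data.frame(
    id = df$id,
    intervention_category = assign_intervention_category(df),
    detailed = status,
    flags = vapply(flags, function(f)
      paste(unique(f), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Classify a single record
#'
#' Convenience wrapper around [classify_cohort()] for one record, given as a
#' one-row data frame or a named list of canonical fields (unspecified event
#' ages default to absent).
#'
#' @param record One-row data frame or named list of canonical fields.
#' @param policy A [classification_policy()].
#' @return A one-row classification result data frame (see
#'   [classify_cohort()]).
#' @export
classify_detailed <- function(record, policy = classification_policy()) {
  if (!is.data.frame(record)) {
    rec <- .empty_records(1)
    rec$id <- "r1"
    for (f in intersect(names(record), .schema_columns))
      rec[[f]] <- record[[f]]
    record <- rec
  }
  classify_cohort(as_cohort(record, slack = policy$baseline_slack), policy)
}
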