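#' Classification policy for the detailed derived status (Step 2)
#'
#' Bundles the configurable rules of the detailed-status decision table. The
#' defaults reproduce the published algorithm's behaviour; each knob exposes a
#' point where the original decision table either states a priority explicitly
#' (the "not sure" intervention priority) or leaves a cell open to
#' reconstruction.
#'
#' @param not_sure_priority Order in which self-reported interventions resolve
#'   a "not sure" response; a permutation of
#'   `c("oophorectomy", "current_mht", "hysterectomy")`.
#' @param not_sure_unmasked_target Detailed status for "not sure" with no
#'   masking intervention (default `peri_menopause`).
#' @param irregular_with_hysterectomy,irregular_with_oophorectomy Detailed
#'   status when irregular periods are reported together with the surgery
#'   (default `unknown`: bleeding contradicts the intervention).
#' @param irregular_with_current_mht Detailed status for irregular periods
#'   under current MHT (default `mht_before_periods_stopped`: MHT itself can
#'   cause bleeding).
#' @param oophorectomy_menopause_tolerance Years by which the oophorectomy age
#'   may exceed the reported menopause age and still count as its cause
#'   (default 0: at or before the reported age).
#' @param natural_menopause_requires_age If `TRUE`, self-reported menopause
#'   without interventions but without a reported age becomes `unknown`
#'   instead of `natural_menopause` + flag.
#' @param masking_precedence_for_yes Order in which interventions are tested
#'   against the reported menopause age for self-reported menopause; a
#'   permutation of `c("oophorectomy", "hysterectomy", "mht")`. Oophorectomy
#'   first because it is causal, then hysterectomy (physically ends periods),
#'   then MHT (only obscures them).
#' @param baseline_slack Years an event age may exceed the baseline age before
#'   the record is declared inconsistent (`unknown` + flag).
#'
#' @return An object of class `meno_policy`.
#' @export
classification_policy <- function(
    not_sure_priority = c("oophorectomy", "current_mht", "hysterectomy"),
    not_sure_unmasked_target = "peri_menopause",
    irregular_with_hysterectomy = "unknown",
    irregular_with_oophorectomy = "unknown",
    irregular_with_current_mht = "mht_before_periods_stopped",
    oophorectomy_menopause_tolerance = 0,
    natural_menopause_requires_age = FALSE,
    masking_precedence_for_yes = c("oophorectomy", "hysterectomy", "mht"),
    baseline_slack = 1.0) {
  if (!setequal(not_sure_priority, c("oophorectomy", "current_mht", "hysterectomy")))
    stop("not_sure_priority must be a permutation of oophorectomy/current_mht/hysterectomy")
  if (!setequal(masking_precedence_for_yes, c("oophorectomy", "hysterectomy", "mht")))
    stop("masking_precedence_for_yes must be a permutation of oophorectomy/hysterectomy/mht")
  stopifnot(oophorectomy_menopause_tolerance >= 0, baseline_slack >= 0)
  targets <- c(not_sure_unmasked_target, irregular_with_hysterectomy,
               irregular_with_oophorectomy, irregular_with_current_mht)
  bad <- setdiff(targets, detailed_levels())
  if (length(bad)) stop("invalid detailed status target(s): ",
                        paste(bad, collapse = ", "))
  structure(list(
    not_sure_priority = not_sure_priority,
    not_sure_unmasked_target = not_sure_unmasked_target,
    irregular_with_hysterectomy = irregular_with_hysterectomy,
    irregular_with_oophorectomy = irregular_with_oophorectomy,
    irregular_with_current_mht = irregular_with_current_mht,
    oophorectomy_menopause_tolerance = oophorectomy_menopause_tolerance,
    natural_menopause_requires_age = natural_menopause_requires_age,
    masking_precedence_for_yes = masking_precedence_for_yes,
    baseline_slack = baseline_slack), class = "meno_policy")
}

#' Read a classification policy from a YAML file
#'
#' @param path Path to a YAML file whose keys are [classification_policy()]
#'   arguments; unspecified keys keep their defaults.
#' @return A `meno_policy`.
#' @export
read_policy <- function(path) {
  y <- .read_yaml(path)
  unknown <- setdiff(names(y), names(formals(classification_policy)))
  if (length(unknown))
    stop("unknown policy key(s): ", paste(unknown, collapse = ", "))
  do.call(classification_policy, y)
}

#' @export
print.meno_policy <- function(x, ...) {
  cat("Detailed-status classification policy\n")
  for (f in names(x)) cat("  ", f, ": ", paste(x[[f]], collapse = " > "),
                          "\n", sep = "")
  invisible(x)
}
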