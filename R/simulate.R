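## Seeded synthetic cohorts with the statistical structure of a large
## population survey of women aged >= 45: baseline-age distribution matched to
## median 59.9 / IQR 52.8-69.0, age at natural menopause matched to median 50 /
## IQR 48-53, 46.9% of women with no menopause-masking intervention, and
## realistic missingness/inconsistency corruption. Each cohort carries its
## latent truth (true menopausal state and menopause age) as an attribute so
## recovery of the truth by the derivation pipeline can be measured exactly.

#' Parameters for the synthetic cohort generator
#'
#' Baseline ages follow a two-piece (quantile-spliced) normal, truncated at
#' `age_min`, whose parameters are calibrated at construction time so the
#' truncated distribution attains the configured median and quartiles. Ages at
#' natural menopause follow a truncated normal. The intervention mix assigns
#' `p_no_intervention` to the no-intervention category and by default spreads
#' the rest uniformly over the 11 intervention combinations (per-category
#' population frequencies being unavailable, this is an explicit placeholder;
#' supply `intervention_mix` to impose any composition).
#'
#' @param n Cohort size.
#' @param seed Integer seed; the generator is deterministic given `seed`.
#' @param baseline_median,baseline_q1,baseline_q3 Target quartiles (years) of
#'   the truncated baseline-age distribution.
#' @param age_min Lower support bound of baseline ages (cohort definition).
#' @param menopause_age_mean,menopause_age_sd Location and scale (years) of
#'   the latent age at natural menopause (defaults 50 and 3.7, giving median
#'   50 and IQR 48-53).
#' @param menopause_age_support Truncation bounds of the menopause age.
#' @param p_no_intervention Probability of the no-intervention category.
#' @param intervention_mix Optional named probabilities over the 11
#'   non-empty intervention combinations (need not be normalised; scaled to
#'   `1 - p_no_intervention`).
#' @param p_not_sure_given_masked Probability that a woman whose status is
#'   masked answers "not sure" instead of her bleeding-pattern answer.
#' @param missing_core_rate Probability that the self-reported menopause
#'   response is missing.
#' @param missing_intervention_rate Per-field probability that an intervention
#'   response (MHT / hysterectomy / oophorectomy) is missing, producing
#'   `incomplete` intervention categories.
#' @param missing_event_age_rate Per-age probability that a present event age
#'   is missing.
#' @param inconsistency_rate Probability that one of a record's event ages is
#'   corrupted to exceed the baseline age (injected inconsistency).
#' @param p_oc_current Probability of current hormonal contraceptive use.
#' @return An object of class `meno_sim_params`.
#' @export
cohort_params <- function(n = 10000, seed = 1,
                          baseline_median = 59.9,
                          baseline_q1 = 52.8, baseline_q3 = 69.0,
                          age_min = 45,
                          menopause_age_mean = 50, menopause_age_sd = 3.7,
                          menopause_age_support = c(35, 60),
                          p_no_intervention = 0.469,
                          intervention_mix = NULL,
                          p_not_sure_given_masked = 0.6,
                          missing_core_rate = 0.03,
                          missing_intervention_rate = 0.005,
                          missing_event_age_rate = 0.05,
                          inconsistency_rate = 0.01,
                          p_oc_current = 0.02) {
  stopifnot(n >= 0, p_no_intervention >= 0, p_no_intervention <= 1,
            baseline_q1 < baseline_median, baseline_median < baseline_q3,
            age_min < baseline_q1)
  probs <- c(p_not_sure_given_masked, missing_core_rate,
             missing_intervention_rate, missing_event_age_rate,
             inconsistency_rate, p_oc_current)
  stopifnot(all(probs >= 0), all(probs <= 1))
  cats <- setdiff(intervention_levels(), c("none", "incomplete"))
  if (is.null(intervention_mix)) {
    intervention_mix <- stats::setNames(rep(1, length(cats)), cats)
  } else {
    if (!setequal(names(intervention_mix), cats) || any(intervention_mix < 0))
      stop("intervention_mix must be non-negative and named by the 11 ",
           "intervention categories")
    if (sum(intervention_mix) <= 0 && p_no_intervention < 1)
      stop("intervention_mix must have positive mass")
  }
  mix <- c(none = p_no_intervention,
           intervention_mix / sum(intervention_mix) * (1 - p_no_intervention))
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    baseline = .calibrate_two_piece(baseline_median, baseline_q1,
                                    baseline_q3, age_min),
    age_min = age_min,
    menopause_age_mean = menopause_age_mean,
    menopause_age_sd = menopause_age_sd,
    menopause_age_support = menopause_age_support,
    mix = mix,
    p_not_sure_given_masked = p_not_sure_given_masked,
    missing_core_rate = missing_core_rate,
    missing_intervention_rate = missing_intervention_rate,
    missing_event_age_rate = missing_event_age_rate,
    inconsistency_rate = inconsistency_rate,
    p_oc_current = p_oc_current), class = "meno_sim_params")
}

## Two-piece normal in quantile form: Q(p) = m + s1*qnorm(p) below the median
## and m + s2*qnorm(p) above it; truncation at `lower` by restricting p to
## (F(lower), 1). Parameters are solved so the *truncated* quartiles match.
#' @noRd
.two_piece_q <- function(p, m, s1, s2, lower) {
  a <- stats::pnorm(lower, m, s1)
  u <- a + p * (1 - a)
  ifelse(u < 0.5, stats::qnorm(u, m, s1), stats::qnorm(u, m, s2))
}

#' @noRd
.calibrate_two_piece <- function(med, q1, q3, lower) {
  z75 <- stats::qnorm(0.75)
  target <- c(q1, med, q3)
  obj <- function(th) {
    got <- .two_piece_q(c(0.25, 0.5, 0.75), th[1], exp(th[2]), exp(th[3]),
                        lower)
    sum((got - target)^2)
  }
  start <- c(med, log((med - q1) / z75), log((q3 - med) / z75))
  fit <- stats::optim(start, obj, control = list(maxit = 2000,
                                                 reltol = 1e-12))
  list(m = fit$par[1], s1 = exp(fit$par[2]), s2 = exp(fit$par[3]),
       lower = lower)
}

#' @noRd
.rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic cohort with latent truth
#'
#' Simulates `n` participant records through a latent-history model: each
#' woman has a latent age at natural menopause; a bilateral oophorectomy
#' before that age induces menopause at the surgery age; hysterectomy and MHT
#' never change the latent state, only its reporting (the masking concept).
#' Unmasked women answer the menopause question from their latent state
#' (post: "yes" with their menopause age; within 2 years before menopause:
#' "irregular"; earlier: "no"); masked women (hysterectomy before the latent
#' menopause, or current MHT) answer "not sure" with probability
#' `p_not_sure_given_masked` and from their latent state otherwise. Responses
#' and event ages are then corrupted at the configured missingness and
#' inconsistency rates. All ages are reported to one decimal.
#'
#' @param params A [cohort_params()] object.
#' @return A `meno_cohort` of `n` records. The latent truth is attached as
#'   `attr(, "truth")`: a data frame with `id`, `latent_state`
#'   (`pre`/`peri`/`post`), `latent_menopause_age`, `masked` and
#'   `ooph_induced`. The truth never appears in the record fields consumed by
#'   the classifiers.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 500, seed = 42))
#' table(attr(cohort, "truth")$latent_state)
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "meno_sim_params"))
  n <- params$n
  if (n == 0) {
    out <- .finalise_cohort(.empty_records(), list(), 1.0)
    attr(out, "truth") <- data.frame(id = character(),
                                     latent_state = character(),
                                     latent_menopause_age = numeric(),
                                     masked = logical(),
                                     ooph_induced = logical())
    return(out)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  id <- sprintf("S%07d", seq_len(n))
  bp <- params$baseline
  ab <- round(.two_piece_q(stats::runif(n), bp$m, bp$s1, bp$s2, bp$lower), 1)
  M <- .rtnorm(n, params$menopause_age_mean, params$menopause_age_sd,
               params$menopause_age_support[1], params$menopause_age_support[2])

  cat13 <- sample(names(params$mix), n, replace = TRUE, prob = params$mix)
  mht <- ifelse(grepl("mht_current", cat13), "current",
         ifelse(grepl("mht_former", cat13), "former", "never"))
  hy <- ifelse(grepl("hyst", cat13), "yes", "no")
  oo <- ifelse(grepl("ooph", cat13), "yes", "no")

  ## event ages, always before baseline: surgeries in mid-life, MHT started
  ## around the individual latent menopause age
  ao <- rep(NA_real_, n)
  io <- oo == "yes"
  ao[io] <- .rtnorm(sum(io), 47, 6, 28, ab[io])
  ah <- rep(NA_real_, n)
  ih <- hy == "yes"
  ah[ih] <- .rtnorm(sum(ih), 45, 7, 28, ab[ih])
  at <- rep(NA_real_, n)
  im <- mht != "never"
  at[im] <- .rtnorm(sum(im), M[im], 2.5, 35, ab[im])

  ooph_induced <- io & ao < M
  Mtrue <- ifelse(ooph_induced, ao, M)
  latent_state <- ifelse(ab >= Mtrue, "post",
                  ifelse(ab >= Mtrue - 2, "peri", "pre"))
  masked <- (ih & !is.na(ah) & ah < Mtrue) | mht == "current"

  men <- unname(c(pre = "no", peri = "irregular", post = "yes")[latent_state])
  ns <- masked & stats::runif(n) < params$p_not_sure_given_masked
  men[ns] <- "not_sure"
  am <- ifelse(men == "yes", round(Mtrue, 1), NA_real_)
  ao <- round(ao, 1); ah <- round(ah, 1); at <- round(at, 1)

  ## corruption: missing responses, missing event ages, injected inconsistency
  men[stats::runif(n) < params$missing_core_rate] <- "missing"
  for (f in c("mht", "hy", "oo")) {
    hit <- stats::runif(n) < params$missing_intervention_rate
    v <- get(f); v[hit] <- "missing"; assign(f, v)
    ## a missing intervention response carries no event age
    av <- switch(f, mht = "at", hy = "ah", oo = "ao")
    w <- get(av); w[hit] <- NA_real_; assign(av, w)
  }
  am[men != "yes"] <- NA_real_
  for (av in c("am", "at", "ah", "ao")) {
    w <- get(av)
    hit <- !is.na(w) & stats::runif(n) < params$missing_event_age_rate
    w[hit] <- NA_real_
    assign(av, w)
  }
  bad <- stats::runif(n) < params$inconsistency_rate
  for (i in which(bad)) {
    present <- c(am = !is.na(am[i]), at = !is.na(at[i]),
                 ah = !is.na(ah[i]), ao = !is.na(ao[i]))
    if (!any(present)) next
    pick <- names(present)[present][1]
    v <- get(pick); v[i] <- round(ab[i] + 5, 1); assign(pick, v)
  }
  oc <- ifelse(stats::runif(n) < params$p_oc_current, "yes", "no")

  cohort <- as_cohort(data.frame(
    id = id, age_baseline = ab, menopause = unname(men), mht = mht,
    hysterectomy = hy, oophorectomy = oo, oc_current = oc,
    age_menopause = am, age_mht_start = at, age_hysterectomy = ah,
    age_oophorectomy = ao, stringsAsFactors = FALSE))
  attr(cohort, "truth") <- data.frame(
    id = id, latent_state = unname(latent_state),
    latent_menopause_age = round(Mtrue, 1),
    masked = unname(masked), ooph_induced = unname(ooph_induced),
    stringsAsFactors = FALSE)
  cohort
}

#' Cross-tabulate latent truth against consolidated status
#'
#' Confronts the generator's latent menopausal state with the pipeline's
#' consolidated derived status and reports the sensitivity for
#' post-menopause: the proportion of latently post-menopausal women assigned
#' consolidated `post_menopause`. With no latently post-menopausal women the
#' sensitivity is undefined and reported as `NA`.
#'
#' @param cohort A simulated `meno_cohort` (with its `truth` attribute), or a
#'   truth data frame.
#' @param results Aligned results with a `consolidated` column.
#' @return An object of class `meno_confusion`: `table` (latent state by
#'   consolidated status counts), `post_sensitivity`, and `n`.
#' @export
truth_confusion <- function(cohort, results) {
  truth <- if (is.data.frame(cohort) && !is.null(attr(cohort, "truth")))
    attr(cohort, "truth") else cohort
  if (is.null(truth$latent_state))
    stop("no latent truth found; pass a simulated cohort or a truth table")
  if (nrow(truth) != nrow(results) ||
      !identical(as.character(truth$id), as.character(results$id)))
    stop("truth and results are not aligned by participant id")
  if (is.null(results$consolidated) || anyNA(results$consolidated))
    stop("results must carry a complete consolidated status")
  tab <- table(latent = factor(truth$latent_state,
                               levels = c("pre", "peri", "post")),
               consolidated = factor(results$consolidated,
                                     levels = consolidated_levels()))
  npost <- sum(tab["post", ])
  sens <- if (npost > 0) tab["post", "post_menopause"] / npost else NA_real_
  structure(list(table = tab, post_sensitivity = sens, n = nrow(truth)),
            class = "meno_confusion")
}

#' @export
print.meno_confusion <- function(x, ...) {
  cat("Latent truth vs consolidated derived status (n = ", x$n, ")\n",
      sep = "")
  print(x$table)
  if (is.na(x$post_sensitivity)) {
    cat("post-menopause sensitivity: undefined (no latently post-menopausal women)\n")
  } else {
    cat(sprintf("post-menopause sensitivity: %.3f\n", x$post_sensitivity))
  }
  invisible(x)
}
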