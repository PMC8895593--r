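# Builders for hand-constructed records and independent brute-force oracles
# for the threshold methods. The oracles deliberately use naive per-record
# loops, independent of the package's vectorised scans.

make_record <- function(id = "r1", age_baseline = 60, menopause = "yes",
                        mht = "never", hysterectomy = "no",
                        oophorectomy = "no", oc_current = "no",
                        age_menopause = NA_real_, age_mht_start = NA_real_,
                        age_hysterectomy = NA_real_,
                        age_oophorectomy = NA_real_) {
  data.frame(id = id, age_baseline = age_baseline, menopause = menopause,
             mht = mht, hysterectomy = hysterectomy,
             oophorectomy = oophorectomy, oc_current = oc_current,
             age_menopause = age_menopause, age_mht_start = age_mht_start,
             age_hysterectomy = age_hysterectomy,
             age_oophorectomy = age_oophorectomy, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) rows[[i]]$id <- paste0("r", i)
  as_cohort(do.call(rbind, rows))
}

# random raw cohort exercising all codes, missingness and odd age orderings
random_cohort <- function(n) {
  r <- function(lv) sample(lv, n, replace = TRUE)
  maybe_age <- function(lo, hi, p_na = 0.3) {
    x <- round(runif(n, lo, hi), 1)
    x[runif(n) < p_na] <- NA_real_
    x
  }
  as_cohort(data.frame(
    id = paste0("x", seq_len(n)),
    age_baseline = round(runif(n, 45, 90), 1),
    menopause = r(c("no", "not_sure", "irregular", "yes", "missing")),
    mht = r(c("never", "former", "current", "missing")),
    hysterectomy = r(c("yes", "no", "missing")),
    oophorectomy = r(c("yes", "no", "missing")),
    oc_current = r(c("yes", "no", "missing")),
    age_menopause = maybe_age(35, 60),
    age_mht_start = maybe_age(35, 70),
    age_hysterectomy = maybe_age(25, 70),
    age_oophorectomy = maybe_age(25, 70),
    stringsAsFactors = FALSE))
}

# --- brute-force threshold oracles -----------------------------------------

oracle_reference <- function(ages, cut = 0.9, scan = 45:100) {
  if (!length(ages)) return(NA_integer_)
  for (a in scan) {
    below <- 0
    for (x in ages) if (x < a) below <- below + 1
    if (below / length(ages) >= cut) return(a)
  }
  NA_integer_
}

oracle_conservative <- function(age_baseline, menopause, cut = 0.9,
                                min_n = 50, scan = 45:100) {
  grp <- floor(age_baseline)
  any_qualifying <- FALSE
  for (g in scan) if (sum(grp == g, na.rm = TRUE) >= min_n)
    any_qualifying <- TRUE
  if (!any_qualifying) return(NA_integer_)
  for (a in scan) {
    ok <- TRUE
    for (g in scan[scan >= a]) {
      idx <- !is.na(grp) & grp == g
      if (sum(idx) >= min_n && mean(menopause[idx] == "yes") < cut)
        ok <- FALSE
    }
    if (ok) return(a)
  }
  NA_integer_
}

oracle_least_conservative <- function(age_baseline, detailed, cut = 0.9,
                                      scan = 45:100) {
  for (a in scan) {
    idx <- !is.na(age_baseline) & age_baseline >= a
    if (sum(idx) > 0 &&
        mean(detailed[idx] == "natural_menopause") >= cut) return(a)
  }
  NA_integer_
}

expect_threshold_equals_oracle <- function(cohort, results, cut = 0.9) {
  spec_r <- threshold_spec("reference", cut_point = cut)
  el <- eligible_subcohort(cohort, results, spec_r)
  expect_identical(
    estimate_threshold(cohort, results, spec = spec_r)$threshold_age,
    oracle_reference(el$age_menopause, cut))
  spec_c <- threshold_spec("conservative", cut_point = cut, min_group_n = 5)
  el <- eligible_subcohort(cohort, results, spec_c)
  expect_identical(
    estimate_threshold(cohort, results, spec = spec_c)$threshold_age,
    oracle_conservative(el$age_baseline, el$menopause, cut, min_n = 5))
  spec_l <- threshold_spec("least_conservative", cut_point = cut)
  el <- eligible_subcohort(cohort, results, spec_l)
  expect_identical(
    estimate_threshold(cohort, results, spec = spec_l)$threshold_age,
    oracle_least_conservative(el$age_baseline, el$detailed, cut))
}
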