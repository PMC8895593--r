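# Step 3A: eligibility filters and the three threshold methods.

# cohort of intervention-free women reporting menopause at given ages
ref_cohort <- function(menopause_ages, baseline = 70) {
  rows <- lapply(seq_along(menopause_ages), function(i)
    make_record(id = paste0("r", i), age_baseline = baseline,
                menopause = "yes", age_menopause = menopause_ages[i]))
  as_cohort(do.call(rbind, rows))
}

test_that("eligibility excludes every woman with a potentially masking exposure", {
  co <- make_cohort(
    make_record(mht = "former", age_mht_start = 50),               # excluded
    make_record(hysterectomy = "yes", age_hysterectomy = 50),      # excluded
    make_record(oophorectomy = "yes", age_oophorectomy = 50),      # excluded
    make_record(oc_current = "yes"),                               # excluded
    make_record(mht = "missing"),                                  # excluded
    make_record(menopause = "yes", age_menopause = 50,
                age_baseline = 65.1),                              # eligible
    make_record(menopause = "no", age_baseline = 50))              # eligible*
  res <- classify_cohort(co)
  el <- eligible_subcohort(co, res, threshold_spec("conservative"))
  expect_equal(el$id, c("r6", "r7"))
  # reference additionally needs natural menopause, an age, and baseline >= 55
  el_ref <- eligible_subcohort(co, res, threshold_spec("reference"))
  expect_equal(el_ref$id, "r6")
})

test_that("reference threshold: cumulative fraction of menopause ages below age", {
  # all ages equal 50: the cumulative fraction jumps 0 -> 1 at 51
  th <- estimate_threshold(ref_cohort(rep(50, 20)), method = "reference")
  expect_equal(th$threshold_age, 51L)
  # 9 x 48, 1 x 60 at 90% cut: 9/10 below 49
  co <- ref_cohort(c(rep(48, 9), 60))
  th <- estimate_threshold(co, method = "reference")
  expect_equal(th$threshold_age, 49L)
  el <- eligible_subcohort(co, classify_cohort(co),
                           threshold_spec("reference"))
  expect_equal(th$threshold_age, oracle_reference(el$age_menopause))
  # cumulative table is non-decreasing and spans the scan range
  expect_equal(th$table$age, 45:100)
  expect_true(all(diff(th$table$proportion) >= 0))
})

test_that("conservative threshold: every qualifying single-year group from a onwards", {
  grp_cohort <- function(props, n_per = 20) {
    rows <- list()
    for (i in seq_along(props)) {
      age <- 44 + i
      nyes <- round(props[i] * n_per)
      for (j in seq_len(n_per))
        rows[[length(rows) + 1]] <- make_record(
          id = sprintf("g%d_%d", age, j), age_baseline = age + 0.3,
          menopause = if (j <= nyes) "yes" else "no",
          age_menopause = if (j <= nyes) age - 5 else NA_real_)
    }
    as_cohort(do.call(rbind, rows))
  }
  # groups 45-56 at 50%, 57+ all reporting menopause -> threshold 57
  co <- grp_cohort(c(rep(0.5, 12), rep(1, 6)))
  spec <- threshold_spec("conservative", min_group_n = 10)
  expect_equal(estimate_threshold(co, spec = spec)$threshold_age, 57L)
  # non-monotone pattern: (55: .95, 56: .85, 57: .92, 58+: >= .9) -> 57
  co <- grp_cohort(c(rep(0.5, 10), 0.95, 0.85, 0.92, 0.95, 1, 1))
  expect_equal(estimate_threshold(co, spec = spec)$threshold_age, 57L)
  # all groups at 100%: lower end of the scan range
  co <- grp_cohort(rep(1, 5))
  expect_equal(estimate_threshold(co, spec = spec)$threshold_age, 45L)
  # no group reaches min_group_n: not attained
  th <- estimate_threshold(grp_cohort(1, n_per = 3),
                           spec = threshold_spec("conservative"))
  expect_false(th$attained)
  expect_true(is.na(th$threshold_age))
})

test_that("least-conservative threshold: tail proportion with natural menopause", {
  # every eligible woman natural menopause: lower end of the scan range
  co <- ref_cohort(rep(50, 30))
  res <- classify_cohort(co)
  th <- estimate_threshold(co, res, method = "least_conservative")
  expect_equal(th$threshold_age, 45L)
  # tail proportions (>= 54: 0.91 approx, >= 53: below cut) -> 54
  rows <- c(
    lapply(1:9, function(i) make_record(id = paste0("a", i),
      age_baseline = 53.5, menopause = "no")),        # dilute below 54
    lapply(1:91, function(i) make_record(id = paste0("b", i),
      age_baseline = 60, menopause = "yes", age_menopause = 50)),
    lapply(1:9, function(i) make_record(id = paste0("c", i),
      age_baseline = 60, menopause = "no")))
  co <- as_cohort(do.call(rbind, rows))
  res <- classify_cohort(co)
  # tail at 54: 91/100 = 0.91 >= 0.9; tail at 53: 91/109 = 0.835
  th <- estimate_threshold(co, res, method = "least_conservative")
  expect_equal(th$threshold_age, 54L)
  el <- eligible_subcohort(co, res, threshold_spec("least_conservative"))
  expect_equal(th$threshold_age,
               oracle_least_conservative(el$age_baseline, el$detailed))
})

test_that("an empty eligible set is reported as not attained, with a message", {
  co <- make_cohort(make_record(mht = "current", age_mht_start = 50))
  res <- classify_cohort(co)
  for (m in c("reference", "least_conservative")) {
    th <- estimate_threshold(co, res, method = m)
    expect_false(th$attained)
    expect_true(nzchar(th$message))
  }
})

test_that("each method equals its brute-force oracle on random cohorts", {
  set.seed(31)
  for (rep in 1:25) {
    co <- random_cohort(sample(50:400, 1))
    res <- classify_cohort(co)
    expect_threshold_equals_oracle(co, res,
                                   cut = sample(c(0.5, 0.8, 0.9, 0.95), 1))
  }
})

test_that("raising the cut-point never lowers a threshold", {
  set.seed(37)
  for (rep in 1:8) {
    co <- simulate_cohort(cohort_params(n = 3000, seed = rep))
    res <- classify_cohort(co)
    for (m in c("reference", "conservative", "least_conservative")) {
      lo <- estimate_threshold(co, res,
        spec = threshold_spec(m, cut_point = 0.8, min_group_n = 20))
      hi <- estimate_threshold(co, res,
        spec = threshold_spec(m, cut_point = 0.95, min_group_n = 20))
      if (lo$attained && hi$attained)
        expect_gte(hi$threshold_age, lo$threshold_age)
    }
  }
})

test_that("on default synthetic cohorts the method ordering is least <= reference <= conservative", {
  agree <- 0
  for (s in 1:5) {
    co <- simulate_cohort(cohort_params(n = 20000, seed = 100 + s))
    res <- classify_cohort(co)
    t_ref <- estimate_threshold(co, res, method = "reference")$threshold_age
    t_con <- estimate_threshold(co, res, method = "conservative")$threshold_age
    t_lst <- estimate_threshold(co, res,
                                method = "least_conservative")$threshold_age
    if (t_lst <= t_ref && t_ref <= t_con) agree <- agree + 1
  }
  expect_gte(agree, 4)
})
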