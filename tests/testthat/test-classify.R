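# Step 2: the detailed-status decision table.

d_of <- function(rec, policy = classification_policy())
  classify_cohort(rec, policy)$detailed

f_of <- function(rec, policy = classification_policy())
  classify_cohort(rec, policy)$flags

test_that("canonical single-record assignments match the decision table", {
  # natural menopause: self-reported menopause, no interventions
  r <- make_record(menopause = "yes", age_menopause = 50)
  expect_equal(d_of(as_cohort(r)), "natural_menopause")
  # assumed unilateral oophorectomy: "no" + bilateral oophorectomy
  r <- make_record(menopause = "no", age_baseline = 50, oophorectomy = "yes",
                   age_oophorectomy = 45)
  out <- classify_cohort(as_cohort(r))
  expect_equal(out$detailed, "pre_menopause")
  expect_match(out$flags, "ASSUMED_UNILATERAL_OOPH")
  # not sure with all three interventions: oophorectomy has priority
  r <- make_record(menopause = "not_sure", oophorectomy = "yes",
                   hysterectomy = "yes", mht = "current",
                   age_oophorectomy = 45, age_hysterectomy = 45,
                   age_mht_start = 45)
  expect_equal(d_of(as_cohort(r)), "menopause_from_oophorectomy")
  # missing ages for key interventions: unknown
  r <- make_record(menopause = "yes", hysterectomy = "yes")
  out <- classify_cohort(as_cohort(r))
  expect_equal(out$detailed, "unknown")
  expect_match(out$flags, "MISSING_EVENT_AGE")
  # MHT started before the reported menopause age
  r <- make_record(menopause = "yes", mht = "former", age_menopause = 52,
                   age_mht_start = 47)
  expect_equal(d_of(as_cohort(r)), "mht_before_periods_stopped")
})

test_that("cohort classification is an order-preserving, count-preserving map", {
  co <- make_cohort(
    make_record(menopause = "yes", age_menopause = 50),
    make_record(menopause = "no", age_baseline = 50, oophorectomy = "yes",
                age_oophorectomy = 45),
    make_record(menopause = "not_sure", oophorectomy = "yes",
                hysterectomy = "yes", mht = "current",
                age_oophorectomy = 45, age_hysterectomy = 45,
                age_mht_start = 45),
    make_record(menopause = "yes", hysterectomy = "yes"),
    make_record(menopause = "yes", mht = "former", age_menopause = 52,
                age_mht_start = 47))
  out <- classify_cohort(co)
  expect_equal(out$id, co$id)
  expect_equal(out$detailed,
               c("natural_menopause", "pre_menopause",
                 "menopause_from_oophorectomy", "unknown",
                 "mht_before_periods_stopped"))
  expect_equal(nrow(classify_cohort(co[0, ])), 0)
})

test_that("missing core responses always give unknown + MISSING_CORE", {
  for (field in c("menopause", "mht", "hysterectomy", "oophorectomy")) {
    r <- make_record(menopause = "yes", age_menopause = 50)
    r[[field]] <- "missing"
    out <- classify_cohort(as_cohort(r))
    expect_equal(out$detailed, "unknown", info = field)
    expect_match(out$flags, "MISSING_CORE", info = field)
  }
})

test_that("no-intervention identity: the direct mapping of each response", {
  targets <- c(yes = "natural_menopause", irregular = "peri_menopause",
               no = "pre_menopause", not_sure = "peri_menopause")
  for (resp in names(targets)) {
    r <- make_record(menopause = resp,
                     age_menopause = if (resp == "yes") 50 else NA_real_)
    expect_equal(d_of(as_cohort(r)), unname(targets[resp]), info = resp)
  }
  # the not-sure target is a policy knob
  pol <- classification_policy(not_sure_unmasked_target = "unknown")
  out <- classify_cohort(as_cohort(make_record(menopause = "not_sure")), pol)
  expect_equal(out$detailed, "unknown")
  expect_true(nzchar(out$flags))
})

test_that("event-age ordering decides masking for self-reported menopause", {
  # oophorectomy at the same age as menopause: proximate cause (tolerance 0)
  r <- make_record(menopause = "yes", oophorectomy = "yes",
                   age_menopause = 50, age_oophorectomy = 50)
  expect_equal(d_of(as_cohort(r)), "menopause_from_oophorectomy")
  # oophorectomy after menopause: non-masking, natural
  r <- make_record(menopause = "yes", oophorectomy = "yes",
                   age_menopause = 50, age_oophorectomy = 55)
  expect_equal(d_of(as_cohort(r)), "natural_menopause")
  # hysterectomy at the same age: strict inequality, not masking
  r <- make_record(menopause = "yes", hysterectomy = "yes",
                   age_menopause = 50, age_hysterectomy = 50)
  expect_equal(d_of(as_cohort(r)), "natural_menopause")
  r <- make_record(menopause = "yes", hysterectomy = "yes",
                   age_menopause = 50, age_hysterectomy = 49)
  expect_equal(d_of(as_cohort(r)), "no_periods_hysterectomy")
  # MHT at the same age as menopause: not masking
  r <- make_record(menopause = "yes", mht = "current",
                   age_menopause = 50, age_mht_start = 50)
  expect_equal(d_of(as_cohort(r)), "natural_menopause")
  # tolerance widens the oophorectomy window
  pol <- classification_policy(oophorectomy_menopause_tolerance = 2)
  r <- make_record(menopause = "yes", oophorectomy = "yes",
                   age_menopause = 50, age_oophorectomy = 51.5)
  expect_equal(d_of(as_cohort(r), pol), "menopause_from_oophorectomy")
})

test_that("irregular periods: MHT can explain bleeding, surgery contradicts it", {
  r <- make_record(menopause = "irregular", mht = "current",
                   age_mht_start = 50)
  expect_equal(d_of(as_cohort(r)), "mht_before_periods_stopped")
  for (surgery in c("hysterectomy", "oophorectomy")) {
    r <- make_record(menopause = "irregular")
    r[[surgery]] <- "yes"
    r[[paste0("age_", surgery)]] <- 45
    out <- classify_cohort(as_cohort(r))
    expect_equal(out$detailed, "unknown", info = surgery)
    expect_match(out$flags, "INCONSISTENT", info = surgery)
  }
  expect_equal(d_of(as_cohort(make_record(menopause = "irregular"))),
               "peri_menopause")
})

test_that("former MHT is non-masking for 'no' and 'not sure' responses", {
  r <- make_record(menopause = "no", age_baseline = 48, mht = "former",
                   age_mht_start = 46)
  expect_equal(d_of(as_cohort(r)), "pre_menopause")
  r <- make_record(menopause = "not_sure", mht = "former", age_mht_start = 46)
  expect_equal(d_of(as_cohort(r)), "peri_menopause")
  # but current MHT masks
  r <- make_record(menopause = "no", age_baseline = 48, mht = "current",
                   age_mht_start = 46)
  expect_equal(d_of(as_cohort(r)), "mht_before_periods_stopped")
})

test_that("inconsistent event ages (beyond baseline + slack) give unknown", {
  r <- make_record(menopause = "yes", age_baseline = 60, age_menopause = 70)
  out <- classify_cohort(as_cohort(r))
  expect_equal(out$detailed, "unknown")
  expect_match(out$flags, "INCONSISTENT")
  # within the slack year: accepted
  r <- make_record(menopause = "yes", age_baseline = 60, age_menopause = 60.9)
  expect_equal(d_of(as_cohort(r)), "natural_menopause")
})

test_that("natural menopause without a reported age is flagged or unknown by policy", {
  r <- make_record(menopause = "yes")
  out <- classify_cohort(as_cohort(r))
  expect_equal(out$detailed, "natural_menopause")
  expect_match(out$flags, "MISSING_EVENT_AGE")
  pol <- classification_policy(natural_menopause_requires_age = TRUE)
  expect_equal(d_of(as_cohort(r), pol), "unknown")
})

test_that("classification is total, deterministic, and respects the invariants", {
  set.seed(23)
  for (rep in 1:5) {
    co <- random_cohort(200)
    out <- classify_cohort(co)
    expect_false(anyNA(out$detailed))
    expect_true(all(out$detailed %in% detailed_levels()))
    expect_identical(classify_cohort(co), out)
    # masked statuses require their masking intervention
    expect_true(all(co$mht[out$detailed == "mht_before_periods_stopped"] %in%
                      c("former", "current")))
    expect_true(all(co$hysterectomy[out$detailed == "no_periods_hysterectomy"]
                    == "yes"))
    expect_true(all(co$oophorectomy[out$detailed ==
                                      "menopause_from_oophorectomy"] == "yes"))
    # every unknown carries a machine-readable reason
    expect_true(all(nzchar(out$flags[out$detailed == "unknown"])))
  }
})

test_that("masking precedence for self-reported menopause is configurable", {
  r <- make_record(menopause = "yes", hysterectomy = "yes",
                   oophorectomy = "yes", age_menopause = 50,
                   age_hysterectomy = 45, age_oophorectomy = 48)
  expect_equal(d_of(as_cohort(r)), "menopause_from_oophorectomy")
  pol <- classification_policy(
    masking_precedence_for_yes = c("hysterectomy", "oophorectomy", "mht"))
  expect_equal(d_of(as_cohort(r), pol), "no_periods_hysterectomy")
})

test_that("classify_detailed accepts a named list for one record", {
  out <- classify_detailed(list(menopause = "yes", age_baseline = 60,
                                age_menopause = 50, mht = "never",
                                hysterectomy = "no", oophorectomy = "no"))
  expect_equal(out$detailed, "natural_menopause")
})
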