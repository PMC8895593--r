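---
title: "Deriving menopausal status from survey data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving menopausal status from survey data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menoderive)
```

## The problem

Menopausal status — pre-, peri- or post-menopause — is a key determinant of
risk for many conditions, but the direct survey question "Have you been
through menopause?" is unreliable for a large fraction of women aged 45 and
over. Three interventions can *mask* the natural signal:

* a **hysterectomy** without oophorectomy ends menstrual bleeding while
  ovulation continues;
* **menopausal hormone therapy (MHT)** can cause bleeding after menopause;
* a **bilateral oophorectomy** induces menopause at the age of surgery
  (a unilateral oophorectomy does not).

menoderive implements a transparent rule-based derivation that combines the
direct self-report with intervention history and the *ordering of event ages*
(baseline, menopause, MHT start, hysterectomy, oophorectomy), then uses the
cohort's own age structure to re-classify women whose status is masked or
unknown but who are, by age alone, highly likely to be post-menopausal.

## The algorithm

**Step 1 — intervention categories.** Each woman's MHT use
(never/former/current), hysterectomy (yes/no) and bilateral oophorectomy
(yes/no) responses map to one of 13 categories: the 12 complete triples plus
`incomplete` when any response is missing. The downstream steps consume the
underlying fields, so this enumeration affects only reporting; it is produced
by `assign_intervention_category()` and `tabulate_interventions()`.

**Step 2 — detailed derived status.** `classify_cohort()` assigns one of
seven categories: `natural_menopause`, `peri_menopause`, `pre_menopause`,
`unknown`, `mht_before_periods_stopped`, `no_periods_hysterectomy`,
`menopause_from_oophorectomy`. The decision table is total and deterministic:

* any missing core response (menopause, MHT, hysterectomy, oophorectomy)
  gives `unknown` (flag `MISSING_CORE`);
* an event age more than `baseline_slack` (default 1 year, a reporting-lag
  tolerance) beyond the baseline age gives `unknown` (flag `INCONSISTENT`);
* self-reported menopause is tested against interventions in a configurable
  *masking precedence* (default oophorectomy, then hysterectomy, then MHT —
  oophorectomy is causal, hysterectomy physically ends periods, MHT only
  obscures them). An oophorectomy at or before the reported menopause age
  (tolerance configurable, default 0: a same-age surgery is the proximate
  cause) gives `menopause_from_oophorectomy`; a hysterectomy or an MHT start
  strictly before the reported age gives the corresponding masked status
  (same-age hysterectomy/MHT after the final period is common practice and
  does not mask); a missing age needed for a comparison gives `unknown`
  (flag `MISSING_EVENT_AGE`); an intervention after the reported age is
  non-masking and the scan continues; nothing masking gives
  `natural_menopause`;
* "no": hysterectomy, then current MHT, can explain absent or misread
  bleeding; otherwise `pre_menopause`. A bilateral oophorectomy reported
  together with "no" is treated as a probable unilateral oophorectomy
  (flag `ASSUMED_UNILATERAL_OOPH`) — an explicit reconciliation assumption
  that can misclassify some women;
* "irregular periods": current MHT can itself cause bleeding
  (`mht_before_periods_stopped`); reported surgery contradicts ongoing
  bleeding (`unknown` + `INCONSISTENT`); otherwise `peri_menopause`;
* "not sure": the age at menopause is unknown for these women, so
  self-reported interventions are applied in a stated priority order —
  bilateral oophorectomy, current MHT use, hysterectomy; with none of them
  the default target is `peri_menopause`. This default is the arithmetic
  reconstruction consistent with the published consolidated peri-menopause
  count exceeding the self-reported one; `unknown` is selectable via
  `classification_policy(not_sure_unmasked_target=)`.

Former MHT masks only a "yes" response (where the start age can be compared);
for "no"/"not sure" only *current* MHT masks.

**Step 3A — age thresholds.** `estimate_threshold()` estimates the baseline
age above which masked/unknown women are highly likely to be post-menopausal,
from the cohort itself. All methods use only women whose status no
intervention could affect: never MHT, no hysterectomy, no bilateral
oophorectomy, not currently using hormonal contraception (current hormonal
contraception is retained in the schema *only* for this eligibility filter).

* **reference**: the cumulative distribution of the reported age at natural
  menopause among women aged ≥ 55 at baseline (younger women could mistake a
  temporary irregularity for menopause); the threshold is the smallest
  integer age below which at least 90% of reported menopause ages fall.
  "Below" is read strictly (`age < a`).
* **conservative**: per single-year baseline-age group, the proportion
  self-reporting menopause ("yes" in the numerator; not-sure, irregular, no
  and missing all in the denominator); the threshold is the smallest age from
  which *every* group of at least `min_group_n` women (default 50, to
  suppress noisy extreme-age groups) reaches 90%.
* **least conservative**: the smallest age at which the tail proportion of
  women (at or above that age) with detailed status `natural_menopause`
  reaches 90%.

The 90% cut-point is configurable (`cut_point`); lowering it re-classifies
more women as post-menopausal at the cost of specificity. A threshold that is
never reached is reported as *not attained* and refused downstream, never
silently substituted.

**Step 3B — consolidation.** `consolidate_cohort()` collapses the seven
categories to `post/peri/pre_menopause/unknown`. Natural menopause, and
oophorectomy-induced menopause with self-reported menopause, are always
post-menopause. Peri and pre pass through and are never re-classified.
Potentially masked statuses — MHT before periods stopped, no periods due to
hysterectomy, and menopause-from-oophorectomy *without* self-reported
menopause (possibly unilateral) — become post-menopause when the baseline age
is **at or above** the threshold ("threshold 55" means "aged ≥ 55 years at
baseline") and `unknown` otherwise; detailed `unknown` is re-classified the
same way when `reclassify_unknown = TRUE` (the default; the no-reclassify
variant reproduces the published sensitivity analysis). A record without a
baseline age cannot be re-classified and stays `unknown`
(`MISSING_BASELINE_AGE`).

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so `simulate_cohort()`
generates seeded cohorts with the published marginal structure, plus the
latent truth needed to measure recovery:

* **baseline age**: a two-piece (quantile-spliced) normal — scale
  `s1` below the median, `s2` above — truncated at 45. The three parameters
  are calibrated numerically at construction so the *truncated* distribution
  attains median 59.9 and quartiles 52.8/69.0. The family is a choice (only
  the quartiles are published); it reproduces the documented right skew with
  the fewest parameters.
* **age at natural menopause**: normal, location 50, scale 3.7, truncated to
  (35, 60). Location and scale follow from the published quantiles
  (median 50; IQR 48–53 gives 5/1.349 ≈ 3.7); the implied 90th percentile is
  ≈ 54.7 years, which is what makes the reference method's expected
  threshold 55.
* **interventions**: no-intervention probability 0.469; the remaining mass
  is spread uniformly over the 11 intervention combinations because
  per-category population frequencies are not published — an explicit
  placeholder, replaceable via `intervention_mix`. Ages at surgery are
  mid-life normals truncated at the baseline age; MHT starts near the
  individual's latent menopause age.
* **latent history**: a bilateral oophorectomy before the latent natural
  menopause age induces menopause at the surgery age; hysterectomy and MHT
  never change the latent state, only its reporting. A woman is *masked*
  when her hysterectomy preceded her latent menopause or she currently uses
  MHT. Unmasked women answer from their latent state (post: "yes" with their
  menopause age; within 2 years before menopause: "irregular"; earlier:
  "no"); masked women answer "not sure" with probability 0.6, otherwise from
  their latent state.
* **corruption**: the menopause response is blanked at rate 0.03; each
  intervention response at rate 0.005 (yielding ≈ 1.5% `incomplete`
  records); each present event age at rate 0.05; with probability 0.01 one
  event age is corrupted to exceed the baseline age (an injected
  inconsistency); current hormonal contraception is assigned independently
  at 2%.

All ages are reported to one decimal, as in surveys that compute ages from
dates. The generator is deterministic given its seed, and the latent truth
travels as an attribute, never in the record fields the classifiers read.

What the generator does **not** emulate: misreporting of ages or statuses by
unmasked women, the "no + bilateral oophorectomy" pattern (in the generator a
pre-baseline bilateral oophorectomy always implies latent post-menopause, so
that rule is exercised by constructed records in the tests), correlations of
intervention history with socioeconomic factors, and any secular trend.
Passing tests on synthetic cohorts therefore show that the algorithm recovers
a *known* latent structure under realistic missingness — not that real
cohorts satisfy these distributional assumptions.

Because the generator's peri-menopausal women report "irregular" rather than
"yes", the synthetic conservative threshold lands near the point where the
latent post-menopause proportion crosses the cut (≈ 55–56) instead of the
published 57, which also reflects real-data reporting noise. The ordering
least-conservative ≤ reference ≤ conservative matches the published instance
(54 ≤ 55 ≤ 57) and is asserted as a seed-averaged property.

## Numerical choices

* Percentages, percentage-point and relative changes are computed on
  unrounded ratios and rounded **half away from zero** to one decimal exactly
  once, at display (`round_half_up()`); this reproduces the published worked
  examples (65.1, 74.0, +8.9, +6.2, +13.7, −52.8). A few published table
  cells are not reproducible from their own printed counts under any
  single-step rounding and are excluded from the worked-example checks.
* Thresholds are integer years; fractional baseline ages are compared as-is
  against them (`age >= a`).
* Tie-breaks in Step 2 are explicit policy: oophorectomy at the reported
  menopause age masks (≤, tolerance 0); hysterectomy/MHT at that age do not
  (strict <).
* The conservative method's "every group from `a` onwards" predicate is
  vacuously true above the last qualifying group; it is *not attained* only
  when no group reaches `min_group_n`.

## Worked example

```{r example}
cohort <- simulate_cohort(cohort_params(n = 20000, seed = 3))
fit <- derive_menopause(cohort, method = "reference")
fit
fit$threshold
head(fit$comparison)
truth_confusion(cohort, fit$results)
```

The problem sizes used by the package's own checks — 200 random cohorts of at
most 1,000 records for oracle equivalence, 12 seeds at n = 30,000 for
threshold recovery, n = 50,000 for the masking-recovery comparison — were
chosen so each property is measured with margins of many binomial standard
errors.

## Known limitations

* The decision table reconciles inconsistent answers by assumption (e.g. the
  unilateral-oophorectomy reading); it cannot be validated against measured
  hormone levels here, and records failing the consistency rules are
  deliberately parked in `unknown` rather than guessed.
* The thresholds are cohort-specific by design: a cohort with a different
  age-at-menopause distribution yields different thresholds, which is the
  point of estimating them from the data.
* The algorithm classifies status at a single survey time point; it does not
  model status after baseline, nor women younger than 45 (for surveys
  including them, the same scan logic could be adapted to classify likely
  pre-menopause, which this package does not implement).
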