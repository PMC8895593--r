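# menoderive

Rule-based derivation of menopausal status from survey data.

## The problem

Cohort studies of women's health need each participant's menopausal status
(pre-, peri- or post-menopause), but the direct survey question *"Have you
been through menopause?"* is unreliable for a large share of women aged 45
and over: a hysterectomy without oophorectomy ends menstrual bleeding without
stopping ovulation, menopausal hormone therapy (MHT) can cause bleeding after
menopause, and a bilateral oophorectomy induces menopause at the surgery age.
Dropping all such women wastes power; keeping them unclassified biases
analyses restricted to post-menopausal women.

menoderive is for epidemiologists and data managers who need a transparent,
reproducible, configurable derivation of menopausal status from coded
questionnaire exports. It implements a step-by-step algorithm:

1. **Intervention categories** — MHT use × hysterectomy × bilateral
   oophorectomy, 13 categories (12 complete combinations + incomplete).
2. **Detailed derived status** (7 categories) — self-report combined with the
   intervention history and the ordering of event ages: for self-reported
   menopause at age *m*, an oophorectomy at age *a*<sub>o</sub> ≤ *m* is its
   cause, a hysterectomy at *a*<sub>h</sub> < *m* or an MHT start at
   *a*<sub>t</sub> < *m* masks it; "not sure" is resolved by intervention
   priority (oophorectomy ≻ current MHT ≻ hysterectomy); inconsistent or
   insufficient responses become `unknown`, never a guess.
3. **Age threshold** — the baseline age *T* above which women are highly
   likely to be post-menopausal, estimated from the cohort itself among
   intervention-free women: *reference* (smallest integer *a* with
   P(age at natural menopause < *a*) ≥ 0.90 among women aged ≥ 55),
   *conservative* (every single-year age group from *a* onwards ≥ 90%
   self-reported menopause) and *least-conservative* (tail proportion with
   natural menopause ≥ 90%) methods.
4. **Consolidation** (4 categories) — masked/unknown status becomes
   post-menopause when baseline age ≥ *T*, unknown otherwise; pre/peri are
   never re-classified.

A seeded synthetic-cohort generator with latent truth, cross-tabulation /
reclassification reporting, and a command-line pipeline
(`inst/cli/menoderive.R`) round out the package. See the vignette
`vignettes/deriving-menopausal-status.Rmd` for the full decision table and
design rationale.

## Worked example

```r
library(menoderive)

cohort <- simulate_cohort(cohort_params(n = 20000, seed = 3))
fit <- derive_menopause(cohort, method = "reference")
fit
#> Derived menopausal status for 20000 women
#>   age threshold: >= 55 years (reference method)
#>   post_menopause    16024 (80.1%)
#>   peri_menopause      579 (2.9%)
#>   pre_menopause      1042 (5.2%)
#>   unknown            2355 (11.8%)

fit$comparison
#>        category n_self pct_self n_derived pct_derived pp_change rel_change
#>  post_menopause  13769     68.8     16024        80.1      11.3       16.4
#>  peri_menopause    660      3.3       579         2.9      -0.4      -12.3
#>   pre_menopause   1240      6.2      1042         5.2      -1.0      -16.0
#>         unknown   4331     21.7      2355        11.8      -9.9      -45.6

truth_confusion(cohort, fit$results)
#> Latent truth vs consolidated derived status (n = 20000)
#>       consolidated
#> latent post_menopause peri_menopause pre_menopause unknown
#>   pre               8              0          1042     452
#>   peri             12            579             0     220
#>   post          16004              0             0    1683
#> post-menopause sensitivity: 0.905
```

Reading: the reference method estimates the threshold ≥ 55 years from this
cohort's own age-at-natural-menopause distribution. Derivation raises the
post-menopause count from 13,769 (direct self-report) to 16,024 (+16.4%
relative, +11.3 percentage points) and nearly halves the unknowns (−45.6%).
Against the generator's latent truth, the derived classification recovers
90.5% of truly post-menopausal women, versus 78% answering "yes" directly —
the gain comes from women whose menopause was masked by hysterectomy or MHT.

Reading real data instead:

```r
cohort <- read_cohort("survey.csv", cohort_schema(
  columns = c(id = "participant_id"),
  codes = list(menopause = c("1" = "no", "2" = "not_sure",
                             "3" = "irregular", "4" = "yes"))))
fit <- derive_menopause(cohort)
write_results(cohort, fit$results, "classified.csv")
```

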