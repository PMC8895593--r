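## Step 1: map MHT use x hysterectomy x bilateral oophorectomy to one of 13
## intervention-combination categories. The 12 complete triples plus one
## "incomplete" category (any of the three responses missing) partition all
## possible response combinations.

#' Assign the intervention-combination category (Step 1)
#'
#' Maps each record's MHT use, hysterectomy and bilateral oophorectomy
#' responses to one of the 13 categories listed by [intervention_levels()].
#' The mapping is total: any `missing` among the three responses yields
#' `incomplete`; otherwise the unique matching triple. It depends only on
#' these three fields.
#'
#' @param mht Character vector in `never/former/current/missing`, or a
#'   cohort data frame with columns `mht`, `hysterectomy`, `oophorectomy`.
#' @param hysterectomy,oophorectomy Character vectors in `yes/no/missing`
#'   (ignored when `mht` is a data frame).
#' @return Character vector of category codes, one per record.
#' @examples
#' assign_intervention_category("never", "no", "no")        # "none"
#' assign_intervention_category("current", "no", "yes")     # "ooph_mht_current"
#' assign_intervention_category("missing", "yes", "no")     # "incomplete"
#' @export
assign_intervention_category <- function(mht, hysterectomy = NULL,
                                         oophorectomy = NULL) {
  if (is.data.frame(mht)) {
    d <- mht
    mht <- d$mht; hysterectomy <- d$hysterectomy; oophorectomy <- d$oophorectomy
  }
  n <- length(mht)
  out <- rep("incomplete", n)
  complete <- mht %in% c("never", "former", "current") &
    hysterectomy %in% c("yes", "no") & oophorectomy %in% c("yes", "no")
  hy <- hysterectomy == "yes"
  oo <- oophorectomy == "yes"
  base <- ifelse(hy & oo, "hyst_ooph",
          ifelse(hy, "hyst", ifelse(oo, "ooph", "")))
  mhtpart <- ifelse(mht == "never", "", paste0("mht_", mht))
  code <- ifelse(base == "" & mhtpart == "", "none",
          ifelse(mhtpart == "",
                 ifelse(base == "hyst_ooph", base, paste0(base, "_only")),
          ifelse(base == "", paste0(mhtpart, "_only"),
                 paste(base, mhtpart, sep = "_"))))
  out[complete] <- code[complete]
  out
}

#' Tabulate intervention-combination categories
#'
#' @param cohort A `meno_cohort` or data frame with the three intervention
#'   columns.
#' @return A data frame with one row per category (all 13 always present):
#'   `category`, `count`, `proportion`. Counts sum to the cohort size;
#'   proportions sum to 1. For an empty cohort counts are zero and proportions
#'   `NA` (undefined).
#' @export
tabulate_interventions <- function(cohort) {
  cats <- assign_intervention_category(as.data.frame(cohort))
  counts <- table(factor(cats, levels = intervention_levels()))
  n <- length(cats)
  data.frame(category = intervention_levels(),
             count = as.integer(counts),
             proportion = if (n > 0) as.numeric(counts) / n else
               rep(NA_real_, length(counts)),
             row.names = NULL, stringsAsFactors = FALSE)
}
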