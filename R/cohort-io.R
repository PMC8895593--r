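## Cohort ingest: lenient, flagging parser for coded questionnaire exports.
## Unrecognised categorical codes become "missing", unparseable ages become NA;
## both are flagged, never dropped. Consistency violations (event age beyond
## baseline age + slack) are flagged here and resolved by the classifier.

.FLAG_MESSAGES <- c(
  UNRECOGNISED_CODE    = "categorical code not in schema; set to missing",
  UNPARSEABLE_AGE      = "age could not be parsed as a number; set to absent",
  NONPOSITIVE_AGE      = "event age not > 0; set to absent",
  AGE_EXCEEDS_BASELINE = "event age exceeds baseline age + slack",
  BASELINE_UNDER_MIN   = "baseline age below cohort minimum of 45 years"
)

#' @noRd
.new_validation <- function(n_read, flags) {
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(id = character(), code = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(n_read = n_read,
                 n_flagged = length(unique(flags$id)),
                 flags = flags),
            class = "meno_validation")
}

#' @export
print.meno_validation <- function(x, ...) {
  cat("Cohort validation: ", x$n_read, " records read, ", x$n_flagged,
      " flagged\n", sep = "")
  if (nrow(x$flags)) {
    tab <- table(x$flags$code)
    for (cd in names(tab)) cat("  ", cd, ": ", tab[[cd]], "\n", sep = "")
  }
  invisible(x)
}

#' Construct a cohort from a data frame of canonical fields
#'
#' Accepts a data frame already using the canonical column names and codes
#' (see [cohort_schema()]), coerces types, and attaches a validation report
#' with record-level consistency flags. Invalid categorical codes are an error
#' here (use [read_cohort()] for lenient parsing of raw files).
#'
#' @param df A data frame with columns `id`, `age_baseline`, `menopause`,
#'   `mht`, `hysterectomy`, `oophorectomy`, `oc_current`, `age_menopause`,
#'   `age_mht_start`, `age_hysterectomy`, `age_oophorectomy`.
#' @param slack Years an event age may exceed the baseline age before the
#'   record is flagged `AGE_EXCEEDS_BASELINE` (reporting-lag tolerance).
#'
#' @return A `meno_cohort`: the data frame with a `meno_validation` report in
#'   `attr(, "validation")`.
#' @export
as_cohort <- function(df, slack = 1.0) {
  missing_cols <- setdiff(.schema_columns, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  out <- df[.schema_columns]
  out$id <- as.character(out$id)
  for (f in .age_fields) out[[f]] <- as.numeric(out[[f]])
  for (f in .categorical_fields) {
    v <- as.character(out[[f]])
    v[is.na(v) | v == ""] <- "missing"
    bad <- setdiff(unique(v), .field_levels(f))
    if (length(bad))
      stop("invalid code(s) in '", f, "': ", paste(bad, collapse = ", "))
    out[[f]] <- v
  }
  rownames(out) <- NULL
  .finalise_cohort(out, flags = list(), slack = slack)
}

#' @noRd
.finalise_cohort <- function(out, flags, slack) {
  n <- nrow(out)
  add <- function(ids, code) {
    if (!length(ids)) return(NULL)
    data.frame(id = ids, code = code, message = unname(.FLAG_MESSAGES[code]),
               stringsAsFactors = FALSE)
  }
  # nonpositive event ages: invariant says present event ages are > 0
  for (f in setdiff(.age_fields, "age_baseline")) {
    bad <- !is.na(out[[f]]) & out[[f]] <= 0
    if (any(bad)) {
      flags <- c(flags, list(add(out$id[bad], "NONPOSITIVE_AGE")))
      out[[f]][bad] <- NA_real_
    }
  }
  under <- !is.na(out$age_baseline) & out$age_baseline < 45
  if (any(under)) flags <- c(flags, list(add(out$id[under], "BASELINE_UNDER_MIN")))
  ev <- as.matrix(out[setdiff(.age_fields, "age_baseline")])
  evmax <- suppressWarnings(apply(ev, 1L, max, na.rm = TRUE))
  over <- !is.na(out$age_baseline) & is.finite(evmax) &
    evmax > out$age_baseline + slack
  if (any(over)) flags <- c(flags, list(add(out$id[over], "AGE_EXCEEDS_BASELINE")))
  attr(out, "validation") <- .new_validation(n, Filter(Negate(is.null), flags))
  class(out) <- c("meno_cohort", "data.frame")
  out
}

#' Read a participant cohort from a delimited file
#'
#' Reads a CSV of coded questionnaire responses into the canonical record
#' layout. Parsing is lenient and row-preserving: unrecognised categorical
#' codes become `missing` (flag `UNRECOGNISED_CODE`), unparseable or
#' non-positive ages become absent (flags `UNPARSEABLE_AGE`,
#' `NONPOSITIVE_AGE`), and internally inconsistent records (an event age more
#' than `slack` years beyond the baseline age) are retained with flag
#' `AGE_EXCEEDS_BASELINE`. A file with a header and no data rows — or an empty
#' file — yields an empty cohort, not an error.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param schema A [cohort_schema()] mapping file columns and codes; the
#'   default expects the canonical names and codes.
#' @param slack Consistency tolerance in years, see [as_cohort()].
#'
#' @return A `meno_cohort` data frame; inspect `attr(x, "validation")` (a
#'   `meno_validation`) for the per-record flags.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "id,age_baseline,menopause,mht,hysterectomy,oophorectomy,oc_current,age_menopause,age_mht_start,age_hysterectomy,age_oophorectomy",
#'   "w1,60,yes,never,no,no,no,50,,,"), f)
#' cohort <- read_cohort(f)
#' attr(cohort, "validation")
#' @export
read_cohort <- function(path, schema = cohort_schema(), slack = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(.finalise_cohort(.empty_records(), list(), slack))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8", strip.white = TRUE)
  absent <- setdiff(unname(schema$columns), names(raw))
  if (length(absent))
    stop("input is missing required column(s): ",
         paste(absent, collapse = ", "))
  if (nrow(raw) == 0)
    return(.finalise_cohort(.empty_records(), list(), slack))

  out <- .empty_records(nrow(raw))
  flags <- list()
  add <- function(ids, code) {
    data.frame(id = ids, code = code, message = unname(.FLAG_MESSAGES[code]),
               stringsAsFactors = FALSE)
  }
  out$id <- raw[[schema$columns[["id"]]]]
  for (f in .categorical_fields) {
    v <- raw[[schema$columns[[f]]]]
    mapped <- rep(NA_character_, length(v))
    blank <- is.na(v) | v == ""
    mapped[blank] <- "missing"
    known <- !blank & v %in% names(schema$codes[[f]])
    mapped[known] <- unname(schema$codes[[f]][v[known]])
    unknown <- !blank & !known
    if (any(unknown)) {
      mapped[unknown] <- "missing"
      flags <- c(flags, list(add(out$id[unknown], "UNRECOGNISED_CODE")))
    }
    out[[f]] <- mapped
  }
  for (f in .age_fields) {
    v <- raw[[schema$columns[[f]]]]
    blank <- is.na(v) | v == ""
    num <- suppressWarnings(as.numeric(v))
    badparse <- !blank & is.na(num)
    if (any(badparse))
      flags <- c(flags, list(add(out$id[badparse], "UNPARSEABLE_AGE")))
    out[[f]] <- num
  }
  .finalise_cohort(out, flags, slack)
}

#' @noRd
.empty_records <- function(n = 0) {
  out <- data.frame(id = character(n), stringsAsFactors = FALSE)
  for (f in .schema_columns[-1])
    out[[f]] <- if (f %in% .age_fields) rep(NA_real_, n) else
      rep("missing", n)
  out
}

#' @export
print.meno_cohort <- function(x, ...) {
  v <- attr(x, "validation")
  cat("<meno_cohort> ", nrow(x), " records",
      if (!is.null(v) && v$n_flagged) paste0(" (", v$n_flagged, " flagged)"),
      "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Write records and their classifications to a delimited file
#'
#' Appends the derived columns (`intervention_category`, `detailed_status`,
#' `consolidated_status`, `flags`) to the canonical input columns and writes a
#' UTF-8 CSV. Missing categorical responses are written as empty strings and
#' absent ages as empty cells, so re-reading with [read_cohort()] reproduces
#' every input field exactly.
#'
#' @param cohort A `meno_cohort` (or data frame in canonical layout).
#' @param results A classification result data frame aligned with `cohort` by
#'   `id` (as returned by [classify_cohort()] / [consolidate_cohort()]);
#'   `NULL` to write the records alone.
#' @param path Output file path.
#' @return Invisibly, the output path.
#' @export
write_results <- function(cohort, results = NULL, path) {
  out <- as.data.frame(cohort)[.schema_columns]
  if (!is.null(results)) {
    if (nrow(results) != nrow(out) || !identical(as.character(results$id), out$id))
      stop("records and results are not aligned by participant id")
    out$intervention_category <- results$intervention_category
    out$detailed_status <- results$detailed
    out$consolidated_status <-
      if ("consolidated" %in% names(results)) results$consolidated else
        character(nrow(out))
    out$flags <- results$flags
  }
  for (f in .categorical_fields) out[[f]][out[[f]] == "missing"] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
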