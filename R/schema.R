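#' Default cohort input schema
#'
#' Describes how a delimiter-separated survey export maps onto the canonical
#' participant record. `columns` maps canonical field names to file column
#' names; `codes` maps, per categorical field, file codes to canonical codes.
#' Empty strings are always read as `missing` (for categorical fields) or as an
#' absent age. Any survey export can be adapted by remapping either part, in R
#' or via a YAML file (see [read_schema()]).
#'
#' @param columns Named character vector overriding file column names for some
#'   or all canonical fields (`id`, `age_baseline`, `menopause`, `mht`,
#'   `hysterectomy`, `oophorectomy`, `oc_current`, `age_menopause`,
#'   `age_mht_start`, `age_hysterectomy`, `age_oophorectomy`).
#' @param codes Named list of named character vectors overriding, per
#'   categorical field, the mapping from file codes to canonical codes.
#'
#' @return An object of class `meno_schema`.
#' @examples
#' sc <- cohort_schema(columns = c(id = "participant"),
#'                     codes = list(menopause = c(Y = "yes", N = "no")))
#' @export
cohort_schema <- function(columns = character(), codes = list()) {
  cols <- stats::setNames(.schema_columns, .schema_columns)
  if (length(columns)) {
    unknown <- setdiff(names(columns), .schema_columns)
    if (length(unknown))
      stop("unknown schema field(s): ", paste(unknown, collapse = ", "))
    cols[names(columns)] <- columns
  }
  code_maps <- list(
    menopause    = stats::setNames(.menopause_levels, .menopause_levels),
    mht          = stats::setNames(.mht_levels, .mht_levels),
    hysterectomy = stats::setNames(.yesno_levels, .yesno_levels),
    oophorectomy = stats::setNames(.yesno_levels, .yesno_levels),
    oc_current   = stats::setNames(.yesno_levels, .yesno_levels)
  )
  if (length(codes)) {
    unknown <- setdiff(names(codes), names(code_maps))
    if (length(unknown))
      stop("unknown categorical field(s) in codes: ",
           paste(unknown, collapse = ", "))
    for (f in names(codes)) {
      map <- codes[[f]]
      bad <- setdiff(unname(map), .field_levels(f))
      if (length(bad))
        stop("codes for '", f, "' map to invalid value(s): ",
             paste(bad, collapse = ", "))
      code_maps[[f]] <- map
    }
  }
  structure(list(columns = cols, codes = code_maps), class = "meno_schema")
}

#' @noRd
.field_levels <- function(field) {
  switch(field,
         menopause = .menopause_levels,
         mht = .mht_levels,
         .yesno_levels)
}

#' Read a schema from a YAML file
#'
#' The file may contain top-level keys `columns` (field: column name) and
#' `codes` (field: {file code: canonical code}).
#'
#' @param path Path to a YAML file.
#' @return An object of class `meno_schema`.
#' @export
read_schema <- function(path) {
  y <- .read_yaml(path)
  cohort_schema(columns = unlist(y$columns %||% list()),
                codes = lapply(y$codes %||% list(), unlist))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## yaml 1.1 resolves bare n/y/no/yes (also as mapping keys) to booleans; keep
## them literal so a key like `n:` survives, while true/false stay logical
#' @noRd
.read_yaml <- function(path) {
  keep <- function(x)
    if (tolower(x) %in% c("true", "false")) tolower(x) == "true" else x
  yaml::read_yaml(path, handlers = list("bool#yes" = keep, "bool#no" = keep))
}

#' @export
print.meno_schema <- function(x, ...) {
  cat("Cohort schema\n  columns:",
      paste(names(x$columns), x$columns, sep = "=", collapse = ", "), "\n")
  for (f in names(x$codes))
    cat("  codes[", f, "]: ",
        paste(names(x$codes[[f]]), x$codes[[f]], sep = "->", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
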