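#' Read an Utstein-style registry export
#'
#' Parses a delimited text file of one row per out-of-hospital cardiac
#' arrest case into a typed tibble with the canonical fields. Cells that
#' match a missing code, or that cannot be parsed under the dialect (an
#' unmapped enum code, a non-numeric age), become `NA` — never a silent
#' default — so the selection filters can account for them explicitly.
#' The row count of the file is always preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect An [abc_dialect()] describing the file layout.
#' @return A tibble with one row per data row and the canonical columns:
#'   `record_id` (character), `age` (integer years), `cause`, `witnessed`
#'   (logical), `no_flow_time` (minutes, meaningful only when witnessed),
#'   `first_rhythm`, `pad_performed`, `prehospital_rosc`,
#'   `resuscitation_attempted` (logical), `region`, `year` (integer),
#'   `cpc` (integer 1--5, `NA` = unknown).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_registry(synthetic_cohort_example(5), f)
#' read_registry(f)
#' @export
read_registry <- function(path, dialect = abc_dialect()) {
  stopifnot(inherits(dialect, "abc_dialect"))
  raw <- read.csv(path, sep = dialect$delim, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
  missing_col <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing_col) > 0) {
    abort(sprintf("registry file is missing required column(s): %s",
                  paste(missing_col, collapse = ", ")))
  }
  blank <- function(x) {
    x[x %in% dialect$missing_codes] <- NA_character_
    x
  }
  as_int <- function(x) suppressWarnings(as.integer(blank(x)))
  as_num <- function(x) suppressWarnings(as.numeric(blank(x)))
  as_lgl <- function(x) {
    x <- blank(x)
    out <- rep(NA, length(x))
    out[x %in% dialect$true_codes] <- TRUE
    out[x %in% dialect$false_codes] <- FALSE
    out
  }
  as_enum <- function(x, field) {
    m <- dialect$values[[field]]
    unname(m[match(blank(x), names(m))])
  }
  col <- function(f) raw[[dialect$columns[[f]]]]

  cpc <- as_int(col("cpc"))
  cpc[!cpc %in% 1:5] <- NA_integer_

  out <- tibble::tibble(
    record_id = blank(col("record_id")),
    age = as_int(col("age")),
    cause = as_enum(col("cause"), "cause"),
    witnessed = as_lgl(col("witnessed")),
    no_flow_time = as_num(col("no_flow_time")),
    first_rhythm = as_enum(col("first_rhythm"), "first_rhythm"),
    pad_performed = as_lgl(col("pad_performed")),
    prehospital_rosc = as_lgl(col("prehospital_rosc")),
    resuscitation_attempted = as_lgl(col("resuscitation_attempted")),
    region = as_enum(col("region"), "region"),
    year = as_int(col("year")),
    cpc = cpc
  )
  ids <- out$record_id[!is.na(out$record_id)]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate record_id value(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out
}

#' Write records in a registry dialect
#'
#' Inverse of [read_registry()] under the same dialect: canonical values
#' are mapped back to the dialect's codes, missing values to its first
#' missing code, and columns are written in the stable canonical order.
#'
#' @param records Tibble of canonical Utstein-style records.
#' @param path Output file path.
#' @param dialect An [abc_dialect()].
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path, dialect = abc_dialect()) {
  stopifnot(inherits(dialect, "abc_dialect"))
  miss <- dialect$missing_codes[1]
  enc_chr <- function(x) ifelse(is.na(x), miss, as.character(x))
  enc_lgl <- function(x) {
    ifelse(is.na(x), miss,
           ifelse(x, dialect$true_codes[1], dialect$false_codes[1]))
  }
  enc_enum <- function(x, field) {
    m <- dialect$values[[field]]
    # invert the code -> canonical map; first code wins for each level
    inv <- setNames(names(m), unname(m))[!duplicated(unname(m))]
    ifelse(is.na(x), miss, unname(inv[x]))
  }
  df <- data.frame(
    enc_chr(records$record_id),
    enc_chr(records$age),
    enc_enum(records$cause, "cause"),
    enc_lgl(records$witnessed),
    enc_chr(records$no_flow_time),
    enc_enum(records$first_rhythm, "first_rhythm"),
    enc_lgl(records$pad_performed),
    enc_lgl(records$prehospital_rosc),
    enc_lgl(records$resuscitation_attempted),
    enc_enum(records$region, "region"),
    enc_chr(records$year),
    enc_chr(records$cpc),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(df) <- unname(dialect$columns[utstein_fields()])
  write.table(df, path, sep = dialect$delim, quote = TRUE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Guideline-period assignment
#'
#' Maps a calendar year of arrest to the international resuscitation
#' guideline era analysed: 2007--2009 to the 2005-guideline group,
#' 2012--2014 to the 2010 group, and 2017--2019 to the 2015 group.
#' Guideline revision years and the years immediately following them are
#' transition periods and are excluded from analysis, as are all other
#' years.
#'
#' @param year Integer vector of calendar years.
#' @return Factor with levels `G2005`, `G2010`, `G2015`,
#'   `transition_excluded`.
#' @examples
#' assign_guideline_group(c(2008, 2010, 2019))
#' @export
assign_guideline_group <- function(year) {
  out <- rep("transition_excluded", length(year))
  out[year %in% 2007:2009] <- "G2005"
  out[year %in% 2012:2014] <- "G2010"
  out[year %in% 2017:2019] <- "G2015"
  out[is.na(year)] <- "transition_excluded"
  factor(out, levels = c("G2005", "G2010", "G2015", "transition_excluded"))
}

#' Analysis years per guideline group
#'
#' @return Named list of integer year vectors.
#' @export
guideline_years <- function() {
  list(G2005 = 2007:2009, G2010 = 2012:2014, G2015 = 2017:2019)
}

exclusion_steps <- function() {
  c("not_attempted_or_under_18", "external_cause", "score_not_computable",
    "outcome_unknown", "prehospital_rosc", "kanto_region", "transition_year")
}

#' Cohort selection filters
#'
#' Applies the eligibility criteria of the validation design in a fixed
#' order, attributing each excluded record to the first criterion it
#' fails, so the exclusion tally is deterministic and sums exactly to the
#' number removed. Retained records have: a resuscitation attempt, age
#' >= 18 (inclusive), an internal (medical) arrest cause, a computable
#' ABC score (age and witnessed status present; no-flow time present when
#' witnessed; first monitored rhythm present unless public-access
#' defibrillation was performed, which determines the cardiogram
#' component by itself), a known 1-month cerebral performance category,
#' no prehospital return of spontaneous circulation, a region outside
#' Kanto (the score's derivation region, excluded for external
#' validation), and an arrest year inside one of the three guideline
#' periods.
#'
#' Records whose cause or region is missing cannot be confirmed eligible
#' and are excluded at the `external_cause` / `kanto_region` steps
#' respectively; a record with public-access defibrillation but missing
#' witnessed status is excluded at `score_not_computable` because the
#' bystander component cannot be resolved.
#'
#' @param records Tibble of canonical Utstein-style records.
#' @return The retained cohort tibble, with the exclusion log attached as
#'   attribute `"exclusion_log"` (retrieve with [exclusion_log()]).
#' @examples
#' cohort <- apply_selection_filters(synthetic_cohort_example(200))
#' exclusion_log(cohort)
#' @export
apply_selection_filters <- function(records) {
  n <- nrow(records)
  steps <- exclusion_steps()
  fails <- list(
    not_attempted_or_under_18 =
      !(records$resuscitation_attempted %in% TRUE) |
      is.na(records$age) | records$age < 18,
    external_cause =
      is.na(records$cause) | records$cause != "internal",
    score_not_computable =
      is.na(records$age) | is.na(records$witnessed) |
      (records$witnessed %in% TRUE & is.na(records$no_flow_time)) |
      (is.na(records$first_rhythm) & !(records$pad_performed %in% TRUE)),
    outcome_unknown = is.na(records$cpc),
    prehospital_rosc =
      is.na(records$prehospital_rosc) | records$prehospital_rosc,
    kanto_region = is.na(records$region) | records$region == "kanto",
    transition_year =
      assign_guideline_group(records$year) == "transition_excluded"
  )
  fail_at <- rep(0L, n)
  for (i in seq_along(steps)) {
    hit <- fail_at == 0L & fails[[steps[i]]]
    fail_at[hit] <- i
  }
  tally <- tabulate(fail_at, nbins = length(steps))
  cohort <- records[fail_at == 0L, , drop = FALSE]
  log <- tibble::tibble(
    step = factor(steps, levels = steps),
    n_excluded = tally
  )
  attr(log, "n_input") <- n
  attr(log, "n_retained") <- nrow(cohort)
  class(log) <- c("exclusion_log", class(log))
  attr(cohort, "exclusion_log") <- log
  cohort
}

#' Retrieve the exclusion log of a filtered cohort
#'
#' @param cohort A cohort returned by [apply_selection_filters()].
#' @return A tibble with columns `step` and `n_excluded`, plus attributes
#'   `n_input` and `n_retained`.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) {
    abort("no exclusion log attached; was this cohort produced by apply_selection_filters()?")
  }
  log
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Selection funnel: %d records in, %d retained\n",
              attr(x, "n_input"), attr(x, "n_retained")))
  NextMethod()
}
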