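#' Registry file dialect
#'
#' Describes how an Utstein-style registry export encodes the canonical
#' per-patient fields: the delimiter, the column names, the codes used for
#' each enumerated value, the spellings of logical values, and the codes
#' standing for a missing value. Registries export in locally defined
#' layouts, so all of this is user-editable; the default is the plain CSV
#' dialect this package writes.
#'
#' @param delim Single-character field delimiter.
#' @param missing_codes Character vector of cell values read as missing.
#'   The first element is also used when writing missing values.
#' @param columns Named character vector mapping canonical field names
#'   (`record_id`, `age`, `cause`, `witnessed`, `no_flow_time`,
#'   `first_rhythm`, `pad_performed`, `prehospital_rosc`,
#'   `resuscitation_attempted`, `region`, `year`, `cpc`) to the column
#'   headers used in the file. Defaults to the identity mapping.
#' @param values Named list of named character vectors mapping file codes
#'   to canonical values, for the enumerated fields `cause`,
#'   `first_rhythm` and `region`. Defaults to identity maps over the
#'   canonical levels.
#' @param true_codes,false_codes Character vectors of spellings accepted
#'   for logical `TRUE` / `FALSE`; the first element of each is used when
#'   writing.
#' @return A list with class `"abc_dialect"`.
#' @seealso [read_registry()], [write_registry()], [dialect_from_yaml()]
#' @examples
#' d <- abc_dialect(values = list(first_rhythm = c(vf = "VF", vt = "VT")))
#' d$values$first_rhythm
#' @export
abc_dialect <- function(delim = ",",
                        missing_codes = c("", "NA"),
                        columns = NULL,
                        values = NULL,
                        true_codes = c("TRUE", "true", "1"),
                        false_codes = c("FALSE", "false", "0")) {
  fields <- utstein_fields()
  cols <- setNames(fields, fields)
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), fields)
    if (length(bad) > 0) {
      abort(sprintf("unknown canonical field(s) in `columns`: %s",
                    paste(bad, collapse = ", ")))
    }
    cols[names(columns)] <- columns
  }
  vmaps <- list(
    cause        = setNames(cause_levels(), cause_levels()),
    first_rhythm = setNames(rhythm_levels(), rhythm_levels()),
    region       = setNames(region_levels(), region_levels())
  )
  if (!is.null(values)) {
    bad <- setdiff(names(values), names(vmaps))
    if (length(bad) > 0) {
      abort(sprintf("unknown enum field(s) in `values`: %s",
                    paste(bad, collapse = ", ")))
    }
    for (f in names(values)) {
      m <- values[[f]]
      unknown <- setdiff(unname(m), names(vmaps[[f]]))
      if (length(unknown) > 0) {
        abort(sprintf("dialect maps code(s) to unknown %s level(s): %s",
                      f, paste(unknown, collapse = ", ")))
      }
      vmaps[[f]] <- setNames(unname(m), names(m))
    }
  }
  structure(
    list(delim = delim, missing_codes = missing_codes, columns = cols,
         values = vmaps, true_codes = true_codes, false_codes = false_codes),
    class = "abc_dialect"
  )
}

#' Read or write a dialect configuration file
#'
#' Dialects serialize to YAML (or JSON, which YAML subsumes) so a site's
#' registry layout can be kept alongside its data.
#'
#' @param path File path.
#' @param dialect An [abc_dialect()] object.
#' @return `dialect_from_yaml()` returns an `abc_dialect`;
#'   `dialect_to_yaml()` returns `path` invisibly.
#' @export
dialect_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  abc_dialect(
    delim = x$delim %||% ",",
    missing_codes = x$missing_codes %||% c("", "NA"),
    columns = unlist(x$columns),
    values = lapply(x$values, unlist),
    true_codes = x$true_codes %||% c("TRUE", "true", "1"),
    false_codes = x$false_codes %||% c("FALSE", "false", "0")
  )
}

#' @rdname dialect_from_yaml
#' @export
dialect_to_yaml <- function(dialect, path) {
  stopifnot(inherits(dialect, "abc_dialect"))
  yaml::write_yaml(
    list(delim = dialect$delim,
         missing_codes = dialect$missing_codes,
         columns = as.list(dialect$columns),
         values = lapply(dialect$values, as.list),
         true_codes = dialect$true_codes,
         false_codes = dialect$false_codes),
    path
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
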