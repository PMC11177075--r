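#' Published cumulative validation counts
#'
#' Aggregate counts transcribed from the nationwide Japanese OHCA
#' registry validation of the ABC score (guideline-period cohorts
#' 2007--2009, 2012--2014, 2017--2019, patients without prehospital
#' ROSC). For each group: the cohort size `N`, the favourable-outcome
#' total `P`, and the patient / favourable counts at score thresholds
#' >=1, >=2 and =3. No record-level data are public; these cumulative
#' counts fully determine each group's 4 x 2 score-by-outcome table via
#' [strata_from_cumulative()], and the differenced per-score sizes agree
#' exactly with the published per-score distribution.
#'
#' @param path Optional path to a CSV with the same layout; defaults to
#'   the copy shipped with the package.
#' @return A tibble with columns `group`, `N`, `P`, `n_ge1`, `n_ge2`,
#'   `n_eq3`, `pos_ge1`, `pos_ge2`, `pos_eq3`.
#' @examples
#' counts <- published_cumulative_counts()
#' published_stratum_tables(counts)$G2005
#' @export
published_cumulative_counts <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cumulative_counts.csv",
                                package = "abcscore", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname published_cumulative_counts
#' @param counts A tibble as returned by [published_cumulative_counts()].
#' @return `published_stratum_tables()`: a named list of
#'   [stratum_table()] objects, one per group.
#' @export
published_stratum_tables <- function(counts = published_cumulative_counts()) {
  out <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    strata_from_cumulative(
      N = r$N, P = r$P,
      n_cum = c(r$n_ge1, r$n_ge2, r$n_eq3),
      pos_cum = c(r$pos_ge1, r$pos_ge2, r$pos_eq3),
      group = r$group
    )
  })
  setNames(out, counts$group)
}
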