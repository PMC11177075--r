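#' Score-stratum contingency table
#'
#' The validation analysis reduces a scored, outcome-labelled cohort to a
#' 4 x 2 table: for each ABC score s in 0..3, the number of patients
#' `n_s` and the number with a favourable outcome (CPC 1--2) `pos_s`.
#' All downstream quantities — test characteristics at each threshold,
#' the tie-corrected AUROC, the Youden cutoff, and the calibration table
#' — are functions of this table alone.
#'
#' @param n,pos Integer vectors of length 4 (scores 0,1,2,3).
#' @param group Optional label for the guideline group.
#' @return An object of class `stratum_table`.
#' @export
stratum_table <- function(n, pos, group = NA_character_) {
  n <- as.numeric(n); pos <- as.numeric(pos)
  if (length(n) != 4 || length(pos) != 4) {
    abort("`n` and `pos` must each have one entry per score 0..3")
  }
  if (any(n < 0) || any(pos < 0) || any(pos > n)) {
    abort("invalid stratum counts: need 0 <= pos_s <= n_s for every score")
  }
  structure(
    list(group = as.character(group),
         strata = tibble::tibble(score = 0:3, n = n, pos = pos),
         N = sum(n), P = sum(pos)),
    class = "stratum_table"
  )
}

#' Build the score-stratum table from a scored cohort
#'
#' @param scored Tibble with columns `abc_total` and `cpc` (all known),
#'   e.g. the output of [compute_abc_score()] on a filtered cohort.
#' @param group Optional group label; if missing and the cohort has a
#'   `year` column mapping to a single guideline group, that label is
#'   used.
#' @return A [stratum_table()].
#' @examples
#' cohort <- apply_selection_filters(synthetic_cohort_example(1000))
#' build_stratum_table(compute_abc_score(cohort))
#' @export
build_stratum_table <- function(scored, group = NULL) {
  if (any(is.na(scored$cpc))) {
    abort("unknown CPC present; apply_selection_filters() should have removed it")
  }
  if (is.null(group)) {
    group <- NA_character_
    if ("year" %in% names(scored) && nrow(scored) > 0) {
      g <- unique(as.character(assign_guideline_group(scored$year)))
      if (length(g) == 1 && g != "transition_excluded") group <- g
    }
  }
  s <- scored$abc_total
  fav <- scored$cpc %in% c(1L, 2L)
  n <- tabulate(s + 1L, nbins = 4L)
  pos <- tabulate(s[fav] + 1L, nbins = 4L)
  stratum_table(n, pos, group = group)
}

#' Cumulative threshold counts
#'
#' Published validation tables report, for each guideline group, the
#' total cohort size `N`, the total favourable-outcome count `P`, and at
#' each score threshold t in {>=1, >=2, =3} the number of patients `n_t`
#' and favourable outcomes `pos_t`. These cumulative counts determine the
#' per-score strata by successive differences, and vice versa.
#'
#' `cumulative_from_strata()` is the forward direction;
#' `strata_from_cumulative()` inverts it, validating the monotonicity
#' `n_{>=1} >= n_{>=2} >= n_{=3}` (and the same for `pos`) before
#' differencing.
#'
#' @param table A [stratum_table()].
#' @return `cumulative_from_strata()`: an object of class
#'   `cumulative_strata` (list with `group`, `N`, `P` and a tibble
#'   `thresholds` with columns `threshold`, `n`, `pos`).
#' @examples
#' tab <- stratum_table(n = c(50, 30, 15, 5), pos = c(1, 2, 3, 2))
#' cum <- cumulative_from_strata(tab)
#' identical(tidy(strata_from_cumulative(cum)), tidy(tab))
#' @export
cumulative_from_strata <- function(table) {
  stopifnot(inherits(table, "stratum_table"))
  n <- table$strata$n; pos <- table$strata$pos
  structure(
    list(group = table$group, N = table$N, P = table$P,
         thresholds = tibble::tibble(
           threshold = 1:3,
           n = rev(cumsum(rev(n)))[2:4],
           pos = rev(cumsum(rev(pos)))[2:4]
         )),
    class = "cumulative_strata"
  )
}

#' @rdname cumulative_from_strata
#' @param cum A `cumulative_strata` object, or `NULL` when the raw
#'   counts are supplied directly.
#' @param N,P Totals (patients; favourable outcomes).
#' @param n_cum,pos_cum Length-3 vectors of counts at thresholds
#'   >=1, >=2, =3.
#' @param group Optional group label.
#' @export
strata_from_cumulative <- function(cum = NULL, N = NULL, P = NULL,
                                   n_cum = NULL, pos_cum = NULL,
                                   group = NA_character_) {
  if (!is.null(cum)) {
    stopifnot(inherits(cum, "cumulative_strata"))
    N <- cum$N; P <- cum$P
    n_cum <- cum$thresholds$n; pos_cum <- cum$thresholds$pos
    group <- cum$group
  }
  if (length(n_cum) != 3 || length(pos_cum) != 3) {
    abort("need counts at exactly the three thresholds >=1, >=2, =3")
  }
  if (is.unsorted(rev(n_cum)) || is.unsorted(rev(pos_cum))) {
    abort("cumulative counts must be non-increasing in the threshold")
  }
  if (n_cum[1] > N || pos_cum[1] > P) {
    abort("cumulative counts exceed the group totals")
  }
  n <- c(N - n_cum[1], -diff(n_cum), n_cum[3])
  pos <- c(P - pos_cum[1], -diff(pos_cum), pos_cum[3])
  stratum_table(n, pos, group = group)
}

#' @export
print.stratum_table <- function(x, ...) {
  cat(sprintf("Score-stratum table%s: N = %s, favourable (CPC 1-2) = %s\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              format(x$N, big.mark = ","), format(x$P, big.mark = ",")))
  print(x$strata)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a score-stratum table
#'
#' @param x A [stratum_table()].
#' @param ... Unused.
#' @return A tibble with one row per score: `score`, `n`, `pos` and the
#'   observed favourable proportion.
#' @method tidy stratum_table
#' @export
tidy.stratum_table <- function(x, ...) {
  dplyr::mutate(x$strata,
                proportion = ifelse(.data$n > 0, .data$pos / .data$n, NA_real_))
}

#' @rdname tidy.stratum_table
#' @return `glance()`: a one-row tibble with `group`, `N`, `P` and the
#'   overall favourable proportion.
#' @method glance stratum_table
#' @export
glance.stratum_table <- function(x, ...) {
  tibble::tibble(group = x$group, N = x$N, P = x$P,
                 prevalence = if (x$N > 0) x$P / x$N else NA_real_)
}

#' @rdname plot_abc
#' @method autoplot stratum_table
#' @export
autoplot.stratum_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$score), y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "ABC score", y = "Observed CPC 1–2 proportion",
                  title = object$group) +
    ggplot2::theme_minimal()
}
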