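#' ROC curve and tie-corrected AUROC of the ordinal score
#'
#' Builds the receiver operating characteristic curve of the 0--3 ABC
#' score for the favourable outcome, one operating point per threshold
#' t in {1, 2, 3} (predicted positive iff score >= t) plus the (0,0) and
#' (1,1) corners. The area under the curve is computed two ways — by the
#' trapezoidal rule over the points, and by the tie-corrected rank form
#'
#' \deqn{AUROC = \frac{\sum_{s > s'} pos_s \, neg_{s'} + \tfrac12 \sum_s pos_s \, neg_s}{P (N-P)}}
#'
#' where `neg_s = n_s - pos_s`. For an ordinal predictor with ties these
#' are algebraically identical; both are computed and required to agree
#' to 1e-12 as an internal consistency check. Because any strictly
#' monotone transform of the score leaves the ranking unchanged, the
#' AUROC is the same whether computed on the raw score or any
#' probability transform of it.
#'
#' The Youden index J(t) = sensitivity(t) + specificity(t) - 1 is
#' evaluated at each threshold; the optimal cutoff maximizes J, with
#' ties broken toward the larger (more specific) threshold. A
#' Hanley–McNeil confidence interval for the AUROC is attached as a
#' descriptive extra.
#'
#' @param table A [stratum_table()] with both outcome classes non-empty.
#' @param level Confidence level for the Hanley–McNeil interval.
#' @return An object of class `abc_roc`: list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auroc`, `auroc_low`, `auroc_high`,
#'   `youden` (tibble of `threshold`, `sensitivity`, `specificity`, `j`),
#'   `optimal_threshold`, `n_pos`, `n_neg`, `group`.
#' @examples
#' tab <- stratum_table(n = c(87474, 58603, 13928, 2705),
#'                      pos = c(157, 338, 408, 258), group = "G2005")
#' roc <- roc_from_strata(tab)
#' glance(roc)
#' @export
roc_from_strata <- function(table, level = 0.95) {
  stopifnot(inherits(table, "stratum_table"))
  P <- table$P
  Npos <- P
  Nneg <- table$N - P
  if (Npos == 0) abort("degenerate input: no favourable (positive) outcomes")
  if (Nneg == 0) abort("degenerate input: no unfavourable (negative) outcomes")
  st <- table$strata
  pos <- st$pos
  neg <- st$n - st$pos

  op <- purrr::map_dfr(1:3, function(t) {
    hi <- st$score >= t
    tibble::tibble(threshold = t,
                   fpr = sum(neg[hi]) / Nneg,
                   tpr = sum(pos[hi]) / Npos)
  })
  points <- dplyr::arrange(
    dplyr::bind_rows(tibble::tibble(threshold = NA_integer_, fpr = 0, tpr = 0),
                     op,
                     tibble::tibble(threshold = NA_integer_, fpr = 1, tpr = 1)),
    .data$fpr, .data$tpr
  )

  # rank form with half-credit for ties
  cum_neg_below <- c(0, cumsum(neg))[1:4]
  auc_rank <- sum(pos * (cum_neg_below + neg / 2)) / (Npos * Nneg)
  # trapezoid over the ROC points
  auc_trap <- sum(diff(points$fpr) *
                    (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  if (abs(auc_rank - auc_trap) > 1e-12) {
    abort("internal error: rank-form and trapezoidal AUROC disagree")
  }

  youden <- dplyr::mutate(op,
                          sensitivity = .data$tpr,
                          specificity = 1 - .data$fpr,
                          j = .data$tpr - .data$fpr)
  youden <- dplyr::select(youden, "threshold", "sensitivity", "specificity", "j")
  best <- max(youden$threshold[youden$j == max(youden$j)])

  ci <- hanley_mcneil_ci(auc_rank, Npos, Nneg, level)
  structure(
    list(points = points, auroc = auc_rank,
         auroc_low = ci[1], auroc_high = ci[2],
         youden = youden, optimal_threshold = as.integer(best),
         n_pos = Npos, n_neg = Nneg, group = table$group),
    class = "abc_roc"
  )
}

# Hanley & McNeil (1982) standard error for an AUROC
hanley_mcneil_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' Youden-optimal threshold
#'
#' The score threshold maximizing J = sensitivity + specificity - 1,
#' ties broken toward the larger threshold.
#'
#' @param x An `abc_roc` object or a [stratum_table()].
#' @return Integer threshold in 1..3.
#' @export
youden_optimal <- function(x) {
  if (inherits(x, "stratum_table")) x <- roc_from_strata(x)
  stopifnot(inherits(x, "abc_roc"))
  x$optimal_threshold
}

#' @export
print.abc_roc <- function(x, ...) {
  cat(sprintf(
    "ROC of the ABC score%s: AUROC = %.3f (%.3f-%.3f), Youden-optimal threshold >= %d\n",
    if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    x$auroc, x$auroc_low, x$auroc_high, x$optimal_threshold))
  invisible(x)
}

#' @rdname roc_from_strata
#' @param x An `abc_roc` object.
#' @param ... Unused.
#' @return `tidy()`: the operating points; `glance()`: a one-row summary.
#' @method tidy abc_roc
#' @export
tidy.abc_roc <- function(x, ...) x$points

#' @rdname roc_from_strata
#' @method glance abc_roc
#' @export
glance.abc_roc <- function(x, ...) {
  tibble::tibble(group = x$group, auroc = x$auroc,
                 auroc_low = x$auroc_low, auroc_high = x$auroc_high,
                 optimal_threshold = x$optimal_threshold,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname plot_abc
#' @method autoplot abc_roc
#' @export
autoplot.abc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, !is.na(.data$threshold))) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ABC score ROC%s, AUROC = %.3f",
                      if (is.na(object$group)) "" else paste0(" (", object$group, ")"),
                      object$auroc)) +
    ggplot2::theme_minimal()
}
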