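#' Calibration table: predicted versus observed probabilities
#'
#' Pairs an externally supplied predicted probability of a favourable
#' outcome at each score value with the proportion observed in the
#' cohort, plus a confidence interval on the observed proportion. The
#' predicted values are a required input (typically the per-score rates
#' from the score's derivation cohort); the package ships example values
#' in the group configuration files under
#' `system.file("extdata", "configs", package = "abcscore")`.
#'
#' @param table A [stratum_table()].
#' @param predicted Predicted probabilities per score: a numeric vector
#'   of length 4 (scores 0..3) or a named vector/list with names
#'   `"0"`..`"3"` covering every occupied score.
#' @param level Confidence level for the observed-proportion intervals.
#' @param ci_method See [proportion_ci()].
#' @return A tibble of class `abc_calibration` with columns `group`,
#'   `score`, `n`, `predicted`, `observed`, `conf_low`, `conf_high`.
#'   Empty strata are dropped.
#' @examples
#' tab <- stratum_table(n = c(87474, 58603, 13928, 2705),
#'                      pos = c(157, 338, 408, 258), group = "G2005")
#' calibration_table(tab, predicted = c(0.002, 0.006, 0.029, 0.095))
#' @export
calibration_table <- function(table, predicted, level = 0.95,
                              ci_method = "clopper_pearson") {
  stopifnot(inherits(table, "stratum_table"))
  pred <- unlist(predicted)
  if (is.null(names(pred))) {
    if (length(pred) != 4) {
      abort("unnamed `predicted` must have one probability per score 0..3")
    }
    names(pred) <- as.character(0:3)
  }
  occupied <- table$strata$score[table$strata$n > 0]
  missing_scores <- setdiff(as.character(occupied), names(pred))
  if (length(missing_scores) > 0) {
    abort(sprintf("no predicted probability for occupied score(s): %s",
                  paste(missing_scores, collapse = ", ")))
  }
  if (any(pred < 0 | pred > 1)) abort("predicted probabilities must lie in [0, 1]")

  obs <- observed_proportions_by_score(table, level, ci_method)
  obs <- dplyr::filter(obs, !.data$undefined)
  out <- tibble::tibble(
    group = obs$group, score = obs$score, n = obs$n,
    predicted = unname(pred[as.character(obs$score)]),
    observed = obs$proportion,
    conf_low = obs$conf_low, conf_high = obs$conf_high
  )
  class(out) <- c("abc_calibration", class(out))
  out
}

#' Plots of validation results
#'
#' `autoplot()` methods for the result objects: the per-score outcome
#' gradient of a [stratum_table()], the ROC curve of an `abc_roc`, and
#' the predicted-versus-observed calibration plot (observed points with
#' confidence-interval bars against the identity line of perfect
#' calibration).
#'
#' @param object A `stratum_table`, `abc_roc` or `abc_calibration`
#'   object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plot_abc
NULL

#' @rdname plot_abc
#' @method autoplot abc_calibration
#' @export
autoplot.abc_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(linetype = "dotted", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      width = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$score)), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Predicted probability of CPC 1–2",
                  y = "Observed probability of CPC 1–2",
                  colour = "ABC score",
                  title = object$group[1]) +
    ggplot2::theme_minimal()
}
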