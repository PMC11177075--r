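#' Compute the ABC score
#'
#' Scores each record on the three-component ABC rule for out-of-hospital
#' cardiac arrest without prehospital ROSC:
#'
#' * **A (age)** — 1 point if age is 70 years or younger (inclusive);
#' * **B (bystander factor)** — 1 point if the arrest was witnessed and
#'   the no-flow time (collapse to first chest compression) is 5 minutes
#'   or less (inclusive; 0 is a real value, meaning immediate
#'   compressions). An unwitnessed arrest scores 0 regardless of any
#'   recorded no-flow time;
#' * **C (cardiogram)** — 1 point if the first monitored rhythm is
#'   ventricular tachycardia or fibrillation, *or* public-access
#'   defibrillation was performed by a bystander (an OR: PAD grants the
#'   point even when the monitored rhythm is non-shockable).
#'
#' The total ranges 0--3. Scoring is a pure, deterministic function of
#' the record; it is monotone in each component's input. No-flow times
#' are compared as non-negative reals, without flooring.
#'
#' @param records Tibble of records that passed
#'   [apply_selection_filters()], so every needed field is resolvable.
#' @return `records` with integer columns `a`, `b`, `c` and `abc_total`
#'   appended.
#' @examples
#' cohort <- apply_selection_filters(synthetic_cohort_example(100))
#' dplyr::count(compute_abc_score(cohort), abc_total)
#' @export
compute_abc_score <- function(records) {
  if (any(is.na(records$age))) {
    abort("cannot compute component A (age): missing age")
  }
  if (any(is.na(records$witnessed))) {
    abort("cannot compute component B (bystander): missing witnessed status")
  }
  wit <- records$witnessed
  if (any(wit & is.na(records$no_flow_time))) {
    abort("cannot compute component B (bystander): witnessed arrest with missing no-flow time")
  }
  pad <- records$pad_performed %in% TRUE
  if (any(!pad & is.na(records$first_rhythm))) {
    abort("cannot compute component C (cardiogram): missing first rhythm without public-access defibrillation")
  }
  a <- as.integer(records$age <= 70)
  b <- as.integer(wit & !is.na(records$no_flow_time) & records$no_flow_time <= 5)
  b[!wit] <- 0L
  c_ <- as.integer(pad | records$first_rhythm %in% c("VT", "VF"))
  dplyr::mutate(records, a = a, b = b, c = c_, abc_total = a + b + c_)
}

#' Label the favourable-outcome indicator
#'
#' The 1-month cerebral performance category (CPC) is dichotomized as
#' favourable (CPC 1--2) versus unfavourable (CPC 3--5).
#'
#' @param records Tibble with a known integer `cpc` column.
#' @return `records` with a logical `favourable` column appended.
#' @export
label_outcome <- function(records) {
  if (any(is.na(records$cpc))) {
    abort("unknown CPC present; apply_selection_filters() should have removed it")
  }
  dplyr::mutate(records, favourable = .data$cpc %in% c(1L, 2L))
}
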