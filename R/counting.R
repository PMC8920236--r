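#' Subsampling/counting design for aliquot counting
#'
#' Captures the laboratory protocol constants: samples are diluted to a
#' target concentration band (organisms per ml), and 1-ml aliquots are
#' enumerated between a minimum and maximum number of aliquots until a
#' target total organism count is reached.
#'
#' @param concentration_range Length-2 numeric, organisms per ml
#'   (default `c(200, 400)`).
#' @param aliquot_range Length-2 integer, number of 1-ml aliquots
#'   (default `c(5, 20)`).
#' @param target_total Minimum organisms before stopping (default 400).
#' @return A `counting_design` list.
#' @export
counting_design <- function(concentration_range = c(200, 400),
                            aliquot_range = c(5, 20), target_total = 400) {
  stopifnot(length(concentration_range) == 2, length(aliquot_range) == 2)
  if (any(c(concentration_range, aliquot_range, target_total) <= 0)) {
    stop("all design constants must be positive", call. = FALSE)
  }
  if (concentration_range[1] > concentration_range[2] ||
      aliquot_range[1] > aliquot_range[2]) {
    stop("ranges must be ordered low <= high", call. = FALSE)
  }
  structure(list(concentration_range = concentration_range,
                 aliquot_range = aliquot_range,
                 target_total = target_total),
            class = "counting_design")
}

#' Relative precision of an abundance estimate from n counted organisms
#'
#' Under Poisson counting, the 95% confidence half-width of a count n is
#' about `1.96 * sqrt(n)`, so the relative precision is `1.96 / sqrt(n)` —
#' the classic result that counting 400 organisms gives roughly +/-10%.
#' `method = "exact"` uses the exact Poisson interval (chi-squared bounds)
#' instead of the normal approximation.
#'
#' @param n Organisms counted (positive integer vector).
#' @param method `"normal"` (default) or `"exact"`.
#' @param percent Return a percent rounded to the nearest integer instead of
#'   a fraction.
#' @return Relative 95% CI half-width, as a fraction (or rounded percent).
#' @examples
#' poisson_precision(400)                  # ~0.098
#' poisson_precision(400, percent = TRUE)  # 10
#' @export
poisson_precision <- function(n, method = c("normal", "exact"),
                              percent = FALSE) {
  method <- match.arg(method)
  if (any(n <= 0 | n != round(n))) {
    stop("n must be a positive integer count", call. = FALSE)
  }
  rel <- if (method == "normal") {
    1.96 / sqrt(n)
  } else {
    lower <- stats::qchisq(0.025, 2 * n) / 2
    upper <- stats::qchisq(0.975, 2 * n + 2) / 2
    (upper - lower) / 2 / n
  }
  if (percent) round(100 * rel) else rel
}

#' Organism-count bounds implied by a counting design
#'
#' The minimum is the low target concentration times the minimum number of
#' aliquots; the maximum is the high concentration times the maximum number.
#' The default protocol (200-400 organisms/ml, 5-20 aliquots) bounds counts
#' between 1,000 and 8,000 organisms per sample.
#'
#' @param design A [counting_design()].
#' @return Named numeric `c(min = , max = )`.
#' @export
count_bounds <- function(design = counting_design()) {
  stopifnot(inherits(design, "counting_design"))
  c(min = design$concentration_range[1] * design$aliquot_range[1],
    max = design$concentration_range[2] * design$aliquot_range[2])
}
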