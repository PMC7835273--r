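#' Ordinal diagnostic grade scale
#'
#' Defines the correspondence between the 5-point diagnostic certainty scale
#' (1 = definitely absent ... 5 = definitely present) and metastasis
#' probabilities, together with the integer-percent bins used to convert a
#' continuous probability back into a grade. The canonical map is
#' 1 -> 0\%, 2 -> 25\%, 3 -> 50\%, 4 -> 75\%, 5 -> 100\%, and the regrade bins
#' are 0-20\% -> 1, 21-40\% -> 2, 41-60\% -> 3, 61-80\% -> 4, 81-100\% -> 5.
#'
#' @param grade_to_prob numeric length-5 vector, strictly increasing, the
#'   probability assigned to each grade.
#' @param bin_upper_percents integer length-5 vector of upper bin bounds in
#'   percent; bins partition 0-100.
#' @return an object of class `grade_scale`.
#' @examples
#' s <- grade_scale()
#' grade_to_probability(2, s)   # 0.25
#' @export
grade_scale <- function(grade_to_prob = c(0, 0.25, 0.5, 0.75, 1),
                        bin_upper_percents = c(20L, 40L, 60L, 80L, 100L)) {
  stopifnot(length(grade_to_prob) == 5, length(bin_upper_percents) == 5)
  assert_probability(grade_to_prob, "grade_to_prob")
  if (any(diff(grade_to_prob) <= 0)) {
    stop("grade_to_prob must be strictly increasing in grade", call. = FALSE)
  }
  bins <- as.integer(bin_upper_percents)
  if (any(diff(bins) <= 0) || bins[5] != 100L || any(bins < 0L)) {
    stop("bin_upper_percents must increase and end at 100", call. = FALSE)
  }
  structure(list(grade_to_prob = grade_to_prob,
                 bin_upper_percents = bins),
            class = "grade_scale")
}

#' Fusion configuration
#'
#' Holds the confidence-gate settings of the AI-assisted diagnosis: an AI
#' prediction is adopted only when its confidence `Max(p_ai, 1 - p_ai)`
#' exceeds `confidence_threshold` (strictly, by default). Continuous blended
#' probabilities are converted to integer percents by half-away-from-zero
#' rounding before binning, which makes the printed bin ranges exact.
#'
#' @param confidence_threshold scalar in [0.5, 1]; default 0.95.
#' @param gate_comparison `"strict_greater"` (default) or `"greater_equal"`.
#' @return an object of class `fusion_config`.
#' @export
fusion_config <- function(confidence_threshold = 0.95,
                          gate_comparison = c("strict_greater", "greater_equal")) {
  gate_comparison <- match.arg(gate_comparison)
  stopifnot(is.numeric(confidence_threshold), length(confidence_threshold) == 1)
  if (confidence_threshold < 0.5 || confidence_threshold > 1) {
    stop("confidence_threshold must lie in [0.5, 1]", call. = FALSE)
  }
  structure(list(confidence_threshold = confidence_threshold,
                 gate_comparison = gate_comparison,
                 percent_rounding = "half_away_from_zero"),
            class = "fusion_config")
}

#' Convert grades to canonical probabilities
#'
#' @param grade integer vector of grades in 1..5.
#' @param scale a [grade_scale()].
#' @return numeric vector of metastasis probabilities.
#' @export
grade_to_probability <- function(grade, scale = grade_scale()) {
  grade <- assert_grade(grade)
  scale$grade_to_prob[grade]
}

#' Convert probabilities to grades by integer-percent binning
#'
#' The probability is first rounded to an integer percent (half away from
#' zero), then binned: with the default scale 0-20 -> 1, 21-40 -> 2,
#' 41-60 -> 3, 61-80 -> 4, 81-100 -> 5.
#'
#' @param p numeric vector of probabilities in [0, 1].
#' @param scale a [grade_scale()].
#' @param config a [fusion_config()] (fixes the rounding convention).
#' @return integer vector of grades.
#' @examples
#' probability_to_grade(0.4375)  # 44% -> grade 3
#' @export
probability_to_grade <- function(p, scale = grade_scale(),
                                 config = fusion_config()) {
  assert_probability(p)
  percent <- round_half_away(p * 100)
  g <- findInterval(percent, scale$bin_upper_percents[-5] + 1L) + 1L
  as.integer(g)
}

#' Clinician confidence weight
#'
#' `alpha = Max(p_cli, 1 - p_cli)`; lies in [0.5, 1] and equals 1 at the
#' certain grades (1 and 5), which makes those grades fixed points of the
#' blending.
#'
#' @param p_cli clinician probability in [0, 1].
#' @return numeric vector of weights.
#' @export
confidence_weight <- function(p_cli) {
  assert_probability(p_cli)
  pmax(p_cli, 1 - p_cli)
}

#' AI prediction confidence
#'
#' `Max(p_ai, 1 - p_ai)`, the distance of the AI probability from maximal
#' uncertainty; compared against the gate threshold to decide whether the AI
#' diagnosis is adopted.
#'
#' @param p_ai AI metastasis probability in [0, 1].
#' @return numeric vector of confidences in [0.5, 1].
#' @export
ai_confidence <- function(p_ai) {
  assert_probability(p_ai)
  pmax(p_ai, 1 - p_ai)
}

#' Confidence-weighted probability blend
#'
#' `p_blend = alpha * p_cli + (1 - alpha) * p_ai` with
#' `alpha = confidence_weight(p_cli)`. The blend is deliberately biased toward
#' the clinician: the more certain the clinician (p_cli near 0 or 1), the less
#' weight the AI probability receives, and at grades 1 and 5 it receives none.
#'
#' @param p_cli clinician probability.
#' @param p_ai AI probability.
#' @return blended probability in [0, 1].
#' @examples
#' blend(0.25, 0.98)  # 0.4325
#' @export
blend <- function(p_cli, p_ai) {
  assert_probability(p_cli)
  assert_probability(p_ai)
  alpha <- confidence_weight(p_cli)
  alpha * p_cli + (1 - alpha) * p_ai
}
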