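#' Fuse one clinician grade with an AI probability
#'
#' Applies the AI-assisted diagnosis rule to a single observation: the grade is
#' mapped to its canonical probability `p_cli`, the AI probability passes the
#' confidence gate only if `Max(p_ai, 1 - p_ai)` exceeds the threshold, and a
#' gated-in prediction is blended as
#' `p_blend = alpha * p_cli + (1 - alpha) * p_ai` and regraded by
#' integer-percent binning. Ungated records pass through unchanged. Grades 1
#' and 5 are unchanged for every `p_ai` because their confidence weight is 1.
#'
#' @param sample_id identifier carried through to the output.
#' @param grade_in clinician grade, integer in 1..5.
#' @param p_ai AI metastasis probability in [0, 1].
#' @param scale a [grade_scale()].
#' @param config a [fusion_config()].
#' @return a `fusion_record`: list with fields `sample_id`, `grade_in`,
#'   `p_cli`, `alpha`, `p_ai`, `ai_confidence`, `gated`, `p_blend`,
#'   `grade_out`.
#' @examples
#' fuse_record("s1", grade_in = 2, p_ai = 0.98)$grade_out  # 3
#' @export
fuse_record <- function(sample_id, grade_in, p_ai,
                        scale = grade_scale(), config = fusion_config()) {
  grade_in <- assert_grade(grade_in)
  assert_probability(p_ai)
  stopifnot(length(grade_in) == 1, length(p_ai) == 1)

  p_cli <- grade_to_probability(grade_in, scale)
  alpha <- confidence_weight(p_cli)
  conf <- ai_confidence(p_ai)
  gated <- if (config$gate_comparison == "strict_greater") {
    conf > config$confidence_threshold
  } else {
    conf >= config$confidence_threshold
  }
  if (gated) {
    p_blend <- blend(p_cli, p_ai)
    grade_out <- probability_to_grade(p_blend, scale, config)
  } else {
    p_blend <- p_cli
    grade_out <- grade_in
  }
  structure(list(sample_id = sample_id, grade_in = grade_in, p_cli = p_cli,
                 alpha = alpha, p_ai = p_ai, ai_confidence = conf,
                 gated = gated, p_blend = p_blend, grade_out = grade_out),
            class = "fusion_record")
}

#' Fuse a table of diagnosis records
#'
#' Vectorized form of [fuse_record()] over a records data frame (the CSV
#' schema used throughout the package). Appends the fusion columns and, when
#' pathology truth is available, the effect classification of each regrade.
#'
#' @param records data frame with columns `sample_id`, `grade`, `p_ai`, and
#'   optionally `patient_id`, `side`, `pathology` (0/1).
#' @param scale a [grade_scale()].
#' @param config a [fusion_config()].
#' @return the input data frame with columns `p_cli`, `alpha`,
#'   `ai_confidence`, `gated`, `p_blend`, `grade_out` appended, plus `effect`
#'   when `pathology` is present.
#' @export
fuse_records <- function(records, scale = grade_scale(),
                         config = fusion_config()) {
  stopifnot(is.data.frame(records))
  needed <- c("sample_id", "grade", "p_ai")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  grade_in <- assert_grade(records$grade, "grade")
  assert_probability(records$p_ai, "p_ai")

  p_cli <- grade_to_probability(grade_in, scale)
  alpha <- confidence_weight(p_cli)
  conf <- ai_confidence(records$p_ai)
  gated <- if (config$gate_comparison == "strict_greater") {
    conf > config$confidence_threshold
  } else {
    conf >= config$confidence_threshold
  }
  p_blend <- ifelse(gated, blend(p_cli, records$p_ai), p_cli)
  grade_out <- ifelse(gated, probability_to_grade(p_blend, scale, config),
                      grade_in)

  out <- records
  out$p_cli <- p_cli
  out$alpha <- alpha
  out$ai_confidence <- conf
  out$gated <- gated
  out$p_blend <- p_blend
  out$grade_out <- as.integer(grade_out)
  if (!is.null(records$pathology)) {
    out$effect <- classify_effect(grade_in, out$grade_out, records$pathology)
  }
  out
}

#' Classify the effect of a regrade against pathology truth
#'
#' Labels each (input grade, output grade, pathology) triple:
#' * `unaffected` — grade unchanged, or input grade 1/5 (never regraded);
#' * `corrected` — a false positive or false negative pulled to grade 3
#'   (2->3 for positives, 4->3 for negatives), a grade-3 case pushed toward
#'   its pathology (3->4 positive, 3->2 negative), or certainty correctly
#'   enhanced (2->1 negative, 4->5 positive);
#' * `mistaken` — a true positive or true negative pulled to grade 3
#'   (4->3 positive, 2->3 negative), or a grade-3 case pushed away from its
#'   pathology;
#' * `neutral` — the remaining transitions (e.g. certainty enhanced in the
#'   wrong direction: 2->1 for a positive).
#'
#' @param grade_in,grade_out integer grades in 1..5.
#' @param pathology truth labels: 0/1, logical, or `"positive"`/`"negative"`.
#' @return character vector of effect labels.
#' @export
classify_effect <- function(grade_in, grade_out, pathology) {
  grade_in <- assert_grade(grade_in, "grade_in")
  grade_out <- assert_grade(grade_out, "grade_out")
  pos <- parse_pathology(pathology)
  n <- max(length(grade_in), length(grade_out), length(pos))
  grade_in <- rep_len(grade_in, n)
  grade_out <- rep_len(grade_out, n)
  pos <- rep_len(pos, n)

  eff <- rep("neutral", n)
  corrected <-
    (grade_in == 2L & pos  & grade_out == 3L) |
    (grade_in == 4L & !pos & grade_out == 3L) |
    (grade_in == 3L & pos  & grade_out == 4L) |
    (grade_in == 3L & !pos & grade_out == 2L) |
    (grade_in == 2L & !pos & grade_out == 1L) |
    (grade_in == 4L & pos  & grade_out == 5L)
  mistaken <-
    (grade_in == 2L & !pos & grade_out == 3L) |
    (grade_in == 4L & pos  & grade_out == 3L) |
    (grade_in == 3L & pos  & grade_out == 2L) |
    (grade_in == 3L & !pos & grade_out == 4L)
  eff[corrected] <- "corrected"
  eff[mistaken] <- "mistaken"
  eff[grade_in == grade_out | grade_in %in% c(1L, 5L)] <- "unaffected"
  eff
}

# Accept 0/1, logical, or "positive"/"negative" truth labels.
parse_pathology <- function(pathology) {
  if (is.character(pathology) || is.factor(pathology)) {
    lab <- tolower(as.character(pathology))
    if (!all(lab %in% c("positive", "negative"))) {
      stop("pathology labels must be 'positive'/'negative' or 0/1",
           call. = FALSE)
    }
    return(lab == "positive")
  }
  if (anyNA(pathology)) {
    stop("pathology contains missing values", call. = FALSE)
  }
  if (is.logical(pathology)) return(pathology)
  if (is.numeric(pathology) && all(pathology %in% c(0, 1))) {
    return(pathology == 1)
  }
  stop("pathology labels must be 'positive'/'negative' or 0/1", call. = FALSE)
}
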