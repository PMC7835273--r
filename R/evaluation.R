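#' Per-grade pathology tallies
#'
#' Builds the 5 x 2 table underlying the diagnostic-performance analysis:
#' counts of pathology-positive and pathology-negative sides at each grade.
#'
#' @param positives,negatives integer length-5 vectors of counts per grade.
#' @return an object of class `grade_counts`.
#' @export
grade_counts <- function(positives, negatives) {
  stopifnot(length(positives) == 5, length(negatives) == 5)
  if (any(positives < 0) || any(negatives < 0) ||
      any(positives != round(positives)) || any(negatives != round(negatives))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(list(positives = as.integer(positives),
                 negatives = as.integer(negatives)),
            class = "grade_counts")
}

#' Tally graded records by pathology
#'
#' @param records data frame with columns `grade` (1..5) and `pathology`
#'   (0/1 or positive/negative); rows with missing grade (e.g. normal sides)
#'   are not allowed — subset to graded sides first.
#' @return a [grade_counts()] object; positives + negatives total the number
#'   of records.
#' @export
tally_grades <- function(records) {
  stopifnot(is.data.frame(records))
  if (is.null(records$grade) || is.null(records$pathology)) {
    stop("records must have `grade` and `pathology` columns", call. = FALSE)
  }
  if (nrow(records) == 0) return(grade_counts(integer(5), integer(5)))
  g <- assert_grade(records$grade, "grade")
  pos <- parse_pathology(records$pathology)
  grade_counts(tabulate(g[pos], nbins = 5), tabulate(g[!pos], nbins = 5))
}

#' Dichotomized diagnostic metrics at a grade cutoff
#'
#' Collapses the 5-grade table to a binary test by declaring a set of grades
#' positive (the study uses the nested cutoffs \{5\}, \{4,5\}, \{3,4,5\}) and
#' reports sensitivity, specificity and accuracy as percentages rounded half
#' away from zero to one decimal, alongside the raw confusion counts.
#'
#' @param counts a [grade_counts()] object.
#' @param positive_grades nonempty subset of 1..5 treated as test-positive.
#' @return an object of class `binary_metrics`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' a <- grade_counts(c(19, 34, 29, 46, 76), c(110, 93, 5, 2, 0))
#' dichotomize(a, 4:5)$sensitivity  # 59.8
#' @export
dichotomize <- function(counts, positive_grades) {
  stopifnot(inherits(counts, "grade_counts"))
  if (length(positive_grades) == 0) {
    stop("positive_grades must be nonempty", call. = FALSE)
  }
  positive_grades <- assert_grade(positive_grades, "positive_grades")
  sel <- seq_len(5) %in% positive_grades
  tp <- sum(counts$positives[sel])
  fn <- sum(counts$positives[!sel])
  fp <- sum(counts$negatives[sel])
  tn <- sum(counts$negatives[!sel])
  total <- tp + fp + tn + fn
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = round_half_away(100 * tp / (tp + fn), 1),
    specificity = round_half_away(100 * tn / (tn + fp), 1),
    accuracy = round_half_away(100 * (tp + tn) / total, 1)
  ), class = "binary_metrics")
}

#' Empirical ROC curve with trapezoidal AUC
#'
#' Sweeps every distinct score as a positivity threshold (score >= threshold
#' predicts positive) and records (threshold, FPR, TPR, Youden J) per point.
#' The AUC is the trapezoidal area, which with tied scores equals the
#' probability that a random positive outscores a random negative plus half
#' the tie probability.
#'
#' @param scores numeric prediction scores (higher = more likely positive).
#' @param labels truth labels (0/1 or positive/negative); at least one of
#'   each class is required.
#' @return object of class `roc_curve`: data frame `points` with columns
#'   `threshold`, `fpr`, `tpr`, `youden_j`; scalars `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  pos <- parse_pathology(labels)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC/AUC is undefined without both a positive and a negative",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  # collapse tied scores: cumulative counts at the trailing edge of each tie
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fpc <- cumsum(!y)[last_of_tie]
  thr <- s[last_of_tie]
  points <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, fpc / n_neg),
    tpr = c(0, tp / n_pos)
  )
  points$youden_j <- points$tpr - points$fpr
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Youden-optimal operating point
#'
#' Returns the ROC point maximizing J = sensitivity + specificity - 1
#' (equivalently TPR - FPR). Ties are broken toward the lowest threshold.
#'
#' @param curve a [roc_curve()].
#' @return list with `threshold`, `youden_j` and the [dichotomize()]-style
#'   `metrics` (counts reconstructed from the curve's class sizes).
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points
  if (nrow(pts) == 0) stop("empty ROC curve", call. = FALSE)
  best_j <- max(pts$youden_j)
  cand <- which(pts$youden_j == best_j)
  i <- cand[which.min(pts$threshold[cand])]
  tp <- round(pts$tpr[i] * curve$n_pos)
  fp <- round(pts$fpr[i] * curve$n_neg)
  tn <- curve$n_neg - fp
  fn <- curve$n_pos - tp
  total <- curve$n_pos + curve$n_neg
  metrics <- structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = round_half_away(100 * tp / curve$n_pos, 1),
    specificity = round_half_away(100 * tn / curve$n_neg, 1),
    accuracy = round_half_away(100 * (tp + tn) / total, 1)
  ), class = "binary_metrics")
  list(threshold = pts$threshold[i], youden_j = best_j, metrics = metrics)
}

#' Regrade transition table
#'
#' Cross-tabulates input grade, output grade and pathology over fused records
#' and annotates every cell with its [classify_effect()] label, the structure
#' behind per-clinician regrade audit tables.
#'
#' @param fused data frame from [fuse_records()] with columns `grade`
#'   (or `grade_in`), `grade_out` and `pathology`.
#' @return object of class `transition_table`: `counts`, a 5 x 5 x 2 array
#'   indexed (grade_in, grade_out, pathology in negative/positive), and
#'   `effects`, the parallel array of effect labels.
#' @export
transition_table <- function(fused) {
  stopifnot(is.data.frame(fused))
  gi_col <- if (!is.null(fused$grade_in)) "grade_in" else "grade"
  if (is.null(fused[[gi_col]]) || is.null(fused$grade_out)) {
    stop("fused records need `grade`/`grade_in` and `grade_out`", call. = FALSE)
  }
  if (is.null(fused$pathology)) {
    stop("fused records need a `pathology` column", call. = FALSE)
  }
  gi <- assert_grade(fused[[gi_col]], "grade_in")
  go <- assert_grade(fused$grade_out, "grade_out")
  pos <- parse_pathology(fused$pathology)

  dn <- list(grade_in = 1:5, grade_out = 1:5,
             pathology = c("negative", "positive"))
  counts <- array(0L, dim = c(5, 5, 2), dimnames = dn)
  tab <- table(factor(gi, 1:5), factor(go, 1:5),
               factor(ifelse(pos, "positive", "negative"),
                      c("negative", "positive")))
  counts[] <- as.integer(tab)
  grid <- expand.grid(gi = 1:5, go = 1:5, pos = c(FALSE, TRUE))
  effects <- array(classify_effect(grid$gi, grid$go,
                                   ifelse(grid$pos, "positive", "negative")),
                   dim = c(5, 5, 2), dimnames = dn)
  structure(list(counts = counts, effects = effects), class = "transition_table")
}

#' Confidence-retention curve
#'
#' For each threshold in a grid, the fraction of AI predictions whose
#' confidence `Max(p_ai, 1 - p_ai)` is strictly greater than the threshold.
#' Used to pick the gate threshold: the curve decays slowly up to the knee
#' (about 0.95 in practice) and fast beyond it.
#'
#' @param p_ai nonempty vector of AI probabilities.
#' @param thresholds increasing grid in [0.5, 1].
#' @return object of class `retention_curve`: data frame with `threshold`
#'   and `retained_ratio` (nonincreasing).
#' @export
retention_curve <- function(p_ai, thresholds = seq(0.5, 1, by = 0.01)) {
  if (length(p_ai) == 0) stop("p_ai must be nonempty", call. = FALSE)
  assert_probability(p_ai)
  stopifnot(all(diff(thresholds) > 0), all(thresholds >= 0.5),
            all(thresholds <= 1))
  conf <- ai_confidence(p_ai)
  ratio <- vapply(thresholds, function(t) mean(conf > t), numeric(1))
  structure(list(curve = data.frame(threshold = thresholds,
                                    retained_ratio = ratio)),
            class = "retention_curve")
}

#' Patient-level k-fold split
#'
#' Partitions patients (not sides) into k folds of sizes differing by at most
#' one, so both sides of every patient — including bilateral cancers — stay in
#' the same fold. Deterministic given the seed.
#'
#' @param patient_ids vector of patient identifiers (repeats allowed; the
#'   split is over unique patients).
#' @param k number of folds, `2 <= k <=` number of unique patients.
#' @param seed integer seed for the shuffle.
#' @return list of k elements, each `list(train = , test = )` of patient ids.
#' @export
kfold_patient_split <- function(patient_ids, k, seed = 1L) {
  patients <- unique(patient_ids)
  n <- length(patients)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 2 || k > n) {
    stop("k must be an integer with 2 <= k <= number of patients",
         call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(patients))
  fold_of <- rep(seq_len(k), length.out = n)  # balanced: sizes differ by <= 1
  lapply(seq_len(k), function(f) {
    list(train = shuffled[fold_of != f], test = shuffled[fold_of == f])
  })
}
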