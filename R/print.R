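#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("binary metrics: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn,
              x$fn))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @export
print.grade_counts <- function(x, ...) {
  m <- rbind(positive = x$positives, negative = x$negatives)
  colnames(m) <- paste0("g", 1:5)
  print(m)
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.3f (%d pos / %d neg)\n",
              nrow(x$points), x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.fusion_record <- function(x, ...) {
  cat(sprintf(
    "fusion: grade %d (p_cli %.2f, alpha %.2f) + p_ai %.3f [conf %.3f, %s]\n",
    x$grade_in, x$p_cli, x$alpha, x$p_ai, x$ai_confidence,
    if (x$gated) "gated in" else "gated out"))
  cat(sprintf("  -> p_blend %.4f, grade %d\n", x$p_blend, x$grade_out))
  invisible(x)
}

#' @export
print.ax_network <- function(x, ...) {
  cat(sprintf(
    "3D residual attention network: %d residual units, width %d, input %s\n",
    x$config$n_residual_units, x$config$channel_width,
    paste(x$input_shape, collapse = "x")))
  invisible(x)
}
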