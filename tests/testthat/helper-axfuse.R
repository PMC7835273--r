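# Shared fixtures: reconstructed per-grade reader tables and the toy phantom
# geometry used by the network tests.

# Per-grade pathology tallies of the two readers on the 414 cancer sides
# (positives sum to 204, negatives to 210).
reader_a_counts <- function() {
  grade_counts(positives = c(19, 34, 29, 46, 76),
               negatives = c(110, 93, 5, 2, 0))
}

reader_b_counts <- function() {
  grade_counts(positives = c(56, 8, 23, 48, 69),
               negatives = c(204, 4, 1, 1, 0))
}

# Small phantom geometry: whole chest 10 x 12 x 8 so each half-chest is
# 10 x 12 x 4 (all dimensions even, one pooling stage -> 5 x 6 x 2 maps).
# The node is rendered salient (bright and hypodense) so the three classes
# are unambiguously separable at this resolution.
toy_phantom_spec <- function(seed = 1L) {
  phantom_spec(volume_shape = c(10L, 12L, 8L), tumor_sigma = 1.2,
               node_sigma = 1.0, node_suv = 6, noise_sd = 0.02, seed = seed)
}
toy_input_shape <- c(10L, 12L, 4L)

# Build preprocessed half-chest samples from n whole-chest phantoms with
# alternating cancer labels; each phantom also contributes its healthy side.
toy_sample_set <- function(n, seed, spec = toy_phantom_spec()) {
  labels <- rep(c("cancer_no_LNM", "cancer_LNM"), length.out = n)
  out <- vector("list", 2L * n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      halves <- split_sides(generate_phantom(labels[i], spec))
      for (k in 1:2) {
        h <- halves[[k]]
        out[[2L * (i - 1L) + k]] <- list(
          x = preprocess(h), label = h$label,
          mask = h$tumor_mask | h$node_mask)
      }
    }
  })
  out
}

# Toy-scale training protocol: SGD with momentum, warmup, decay, clipping,
# early stop once the training loss shows full convergence.
toy_train_config <- function(seed) {
  train_config(learning_rate = 0.05, momentum = 0.9, epochs = 200L,
               batch_size = 16L, clip_norm = 0.5, lr_decay = 0.985,
               warmup_epochs = 10L, early_stop_loss = 0.3, seed = seed)
}

# Multi-start training: a narrow network under SGD breaks through on most
# but not all initializations, so train up to `max_starts` candidates from
# different parameter/shuffle seeds and keep the one that ranks its own
# TRAINING cancer halves best (training-set AUC of the LNM probability —
# no held-out data enters the selection); stop as soon as a candidate
# ranks them essentially perfectly.
toy_train_best <- function(samples, input_shape, seed, max_starts = 4) {
  cancer <- Filter(function(s) s$label != "normal", samples)
  y <- vapply(cancer, function(s) as.integer(s$label == "cancer_LNM"),
              integer(1))
  best <- NULL
  for (k in seq_len(max_starts)) {
    sk <- seed + 1000L * (k - 1L)
    model <- build_network(network_config(), input_shape = input_shape,
                           seed = sk)
    fit <- train_network(model, samples, toy_train_config(sk))
    p <- vapply(cancer, function(s) predict_lnm_probability(fit$model, s$x),
                numeric(1))
    tauc <- roc_curve(p, y)$auc
    floss <- tail(fit$loss_trace$loss, 1)
    # candidates that rank their training halves essentially perfectly come
    # first; among those, the one that converged furthest
    score <- 10 * (tauc >= 0.98) + tauc - floss
    if (is.null(best) || score > best$score) {
      best <- list(fit = fit, score = score, tauc = tauc, floss = floss)
    }
    # a candidate that ranks perfectly and has mostly converged is enough
    if (best$tauc >= 0.98 && best$floss < 1) break
  }
  best$fit
}

# with_seed is internal to the package; re-export for helpers/tests
with_seed <- axfuse:::with_seed

# random diagnosis records for property tests
random_records <- function(n, seed) {
  with_seed(seed, data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    patient_id = sprintf("p%04d", ceiling(seq_len(n) / 2)),
    side = rep_len(c("left", "right"), n),
    grade = sample(1:5, n, replace = TRUE),
    p_ai = runif(n),
    pathology = rbinom(n, 1, 0.5)
  ))
}
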