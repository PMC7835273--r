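test_that("grade tallies are exact and conserve totals", {
  recs <- data.frame(grade = c(4L, 4L, 2L),
                     pathology = c(1L, 1L, 0L))
  tc <- tally_grades(recs)
  expect_identical(tc$positives, c(0L, 0L, 0L, 2L, 0L))
  expect_identical(tc$negatives, c(0L, 1L, 0L, 0L, 0L))

  empty <- tally_grades(data.frame(grade = integer(0), pathology = integer(0)))
  expect_identical(empty$positives, integer(5))
  expect_identical(empty$negatives, integer(5))

  # independent loop oracle on 1000 random records
  recs <- random_records(1000, seed = 2)
  tc <- tally_grades(recs)
  pos <- integer(5); neg <- integer(5)
  for (i in seq_len(nrow(recs))) {
    g <- recs$grade[i]
    if (recs$pathology[i] == 1) pos[g] <- pos[g] + 1L else neg[g] <- neg[g] + 1L
  }
  expect_identical(tc$positives, pos)
  expect_identical(tc$negatives, neg)
  expect_identical(sum(tc$positives) + sum(tc$negatives), 1000L)

  expect_error(tally_grades(data.frame(grade = 1:3)), "pathology")
})

test_that("dichotomized metrics handle perfect and degenerate readers", {
  perfect <- grade_counts(c(0, 0, 0, 0, 50), c(60, 0, 0, 0, 0))
  m <- dichotomize(perfect, 4:5)
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(100, 100, 100))
  expect_error(dichotomize(perfect, integer(0)), "nonempty")
})

test_that("nested cutoffs order sensitivity up and specificity down", {
  with_seed(7, {
    for (rep in 1:25) {
      gc <- grade_counts(rpois(5, 20), rpois(5, 20))
      if (sum(gc$positives) == 0 || sum(gc$negatives) == 0) next
      m5 <- dichotomize(gc, 5L)
      m45 <- dichotomize(gc, 4:5)
      m345 <- dichotomize(gc, 3:5)
      expect_true(m5$sensitivity <= m45$sensitivity)
      expect_true(m45$sensitivity <= m345$sensitivity)
      expect_true(m5$specificity >= m45$specificity)
      expect_true(m45$specificity >= m345$specificity)
    }
  })
})

# exhaustive pair-counting oracle: P(pos > neg) + 0.5 P(tie)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

test_that("trapezoidal AUC equals the pair-counting probability", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_curve(c(0.6, 0.6), c(1, 0))$auc, 0.5)

  # all instances up to 12 samples drawn from a small score alphabet so that
  # ties are frequent
  with_seed(11, {
    for (rep in 1:60) {
      n <- sample(2:12, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes present
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      expect_equal(roc_curve(scores, labels)$auc,
                   auc_pair_oracle(scores, labels))
    }
    # and on a larger continuous instance
    scores <- runif(50)
    labels <- rbinom(50, 1, 0.4)
    expect_equal(roc_curve(scores, labels)$auc,
                 auc_pair_oracle(scores, labels))
  })
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "positive and a negative")
})

test_that("AUC agrees with an independent ROC implementation", {
  with_seed(13, {
    scores <- runif(80)
    labels <- rbinom(80, 1, 0.5)
  })
  ref <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE, direction = "<"))
  expect_equal(roc_curve(scores, labels)$auc, as.numeric(ref))
})

test_that("ROC curves are monotone with Youden J = TPR - FPR", {
  with_seed(17, {
    scores <- round(runif(60), 2)
    labels <- rbinom(60, 1, 0.5)
  })
  curve <- roc_curve(scores, labels)
  expect_true(all(diff(curve$points$fpr) >= 0))
  expect_true(all(diff(curve$points$tpr) >= 0))
  expect_equal(curve$points$youden_j,
               curve$points$tpr - curve$points$fpr)
})

test_that("the Youden-optimal point maximizes TPR - FPR", {
  perfect <- roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  yj <- youden_optimal(perfect)
  expect_equal(yj$youden_j, 1)
  expect_equal(yj$metrics$sensitivity, 100)
  expect_equal(yj$metrics$specificity, 100)

  ties <- roc_curve(c(0.6, 0.6), c(1, 0))
  expect_equal(youden_optimal(ties)$youden_j, 0)

  # brute-force threshold scan oracle on a random instance
  with_seed(19, {
    scores <- round(runif(50), 2)
    labels <- rbinom(50, 1, 0.5)
  })
  curve <- roc_curve(scores, labels)
  yj <- youden_optimal(curve)
  best <- -Inf
  for (t in unique(scores)) {
    tpr <- mean(scores[labels == 1] >= t)
    fpr <- mean(scores[labels == 0] >= t)
    best <- max(best, tpr - fpr)
  }
  expect_equal(yj$youden_j, best)
})

test_that("transition tables count regrades and conserve marginals", {
  one <- data.frame(grade = 2L, grade_out = 3L, pathology = 1L)
  tt <- transition_table(one)
  expect_identical(sum(tt$counts), 1L)
  expect_identical(tt$counts[2, 3, "positive"], 1L)
  expect_identical(tt$effects[2, 3, "positive"], "corrected")
  expect_identical(tt$effects[4, 3, "positive"], "mistaken")

  # unchanged records give a diagonal table
  recs <- random_records(100, seed = 23)
  recs$grade_out <- recs$grade
  td <- transition_table(recs)
  for (p in 1:2) {
    expect_true(all(td$counts[, , p][row(diag(5)) != col(diag(5))] == 0))
  }

  # marginal conservation over fused records
  fused <- fuse_records(random_records(500, seed = 29))
  tt <- transition_table(fused)
  tc <- tally_grades(fused)
  expect_identical(as.integer(rowSums(tt$counts[, , "positive"])),
                   tc$positives)
  expect_identical(as.integer(rowSums(tt$counts[, , "negative"])),
                   tc$negatives)
  out_counts <- tally_grades(data.frame(grade = fused$grade_out,
                                        pathology = fused$pathology))
  expect_identical(as.integer(colSums(tt$counts[, , "positive"])),
                   out_counts$positives)
})

test_that("retention curves are nonincreasing with strict comparison", {
  allsure <- retention_curve(rep(1, 10), thresholds = c(0.6, 0.9, 0.99))
  expect_equal(allsure$curve$retained_ratio, c(1, 1, 1))

  # confidence of a uniform p_ai on [0,1] is uniform on [0.5, 1]
  with_seed(37, {
    p <- runif(20000)
    rc <- retention_curve(p, thresholds = c(0.75))
    expect_lt(abs(rc$curve$retained_ratio - 0.5), 0.02)
  })

  single <- retention_curve(0.95, thresholds = c(0.94, 0.95))
  expect_equal(single$curve$retained_ratio, c(1, 0))

  rc <- retention_curve(runif(500), thresholds = seq(0.5, 1, by = 0.01))
  expect_true(all(diff(rc$curve$retained_ratio) <= 0))
  expect_error(retention_curve(numeric(0)), "nonempty")
})

test_that("patient-level folds are balanced, disjoint and reproducible", {
  ids10 <- sprintf("p%02d", 1:10)
  folds <- kfold_patient_split(ids10, k = 5, seed = 3)
  expect_length(folds, 5)
  test_sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_identical(test_sizes, rep(2L, 5))
  expect_setequal(unlist(lapply(folds, `[[`, "test")), ids10)

  # a cohort-sized split: 407 = 5 * 81 + 2
  ids407 <- sprintf("p%03d", 1:407)
  folds <- kfold_patient_split(ids407, k = 5, seed = 3)
  sizes <- sort(vapply(folds, function(f) length(f$test), integer(1)))
  expect_identical(sizes, c(81L, 81L, 81L, 82L, 82L))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids407)
  }

  expect_identical(kfold_patient_split(ids407, 5, seed = 42),
                   kfold_patient_split(ids407, 5, seed = 42))

  # repeated ids (both sides of a patient) stay together by construction
  sides <- rep(ids10, each = 2)
  folds <- kfold_patient_split(sides, k = 5, seed = 1)
  expect_setequal(unlist(lapply(folds, `[[`, "test")), ids10)

  expect_error(kfold_patient_split(ids10, 1), "k must be")
  expect_error(kfold_patient_split(ids10, 11), "k must be")
})
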