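# brute-force one-vs-rest counting oracle, independent of confusion()
ovr_counts_oracle <- function(truth, pred) {
  lev <- grade_levels()
  agg <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (g in lev) {
    agg["tp"] <- agg["tp"] + sum(truth == g & pred == g)
    agg["fn"] <- agg["fn"] + sum(truth == g & pred != g)
    agg["fp"] <- agg["fp"] + sum(truth != g & pred == g)
    agg["tn"] <- agg["tn"] + sum(truth != g & pred != g)
  }
  agg
}

test_that("confusion builds the matrix and one-vs-rest aggregates", {
  truth <- rep(grade_levels(), each = 3)
  cm <- confusion(truth, truth)
  expect_identical(unname(diag(cm$matrix)), rep(3L, 4L))
  expect_identical(cm$fp, 0L)
  expect_identical(cm$fn, 0L)
  expect_identical(cm$tp, 12L)

  # one NORMAL misclassified as WET among 4 samples
  truth2 <- grade_levels()
  pred2 <- c("WET", "INTERMEDIATE", "GA", "WET")
  cm2 <- confusion(truth2, pred2)
  expect_identical(c(cm2$tp, cm2$fn, cm2$fp, cm2$tn), c(3L, 1L, 1L, 11L))
  oracle <- ovr_counts_oracle(truth2, pred2)
  expect_identical(c(tp = cm2$tp, tn = cm2$tn, fp = cm2$fp, fn = cm2$fn),
                   c(tp = 3L, tn = 11L, fp = 1L, fn = 1L))
  expect_equal(unname(oracle), c(3, 11, 1, 1))

  expect_error(confusion(truth2, pred2[1:3]), "equal length")
  expect_error(confusion(c("NORMAL", "BAD"), c("NORMAL", "GA")), "unknown grade")
})

test_that("aggregated fp equals fn for any single-label prediction set", {
  set.seed(31)
  for (rep_ in 1:5) {
    truth <- sample(grade_levels(), 40, replace = TRUE)
    pred <- sample(grade_levels(), 40, replace = TRUE)
    cm <- confusion(truth, pred)
    expect_identical(cm$fp, cm$fn)
    expect_identical(cm$tp + cm$fn, cm$n)
    expect_identical(cm$tp + cm$tn + cm$fp + cm$fn, 4L * cm$n)
    # and micro metrics then collapse: precision = sensitivity = accuracy
    mm <- micro_metrics(cm)
    expect_equal(mm$precision, mm$sensitivity)
    expect_equal(mm$sensitivity, mm$accuracy)
  }
})

test_that("micro metrics reproduce published worked examples from raw counts", {
  # SGD comparison table, scale-adaptive + ResNet50 row
  m1 <- micro_metrics(127, 392, 4, 5)
  expect_equal(round(m1$precision, 4), 0.9695)
  expect_equal(round(100 * m1$sensitivity, 2), 96.21)
  expect_equal(round(100 * m1$f1, 1), 96.6)
  expect_equal(round(100 * m1$specificity, 0), 99)
  expect_equal(round(100 * m1$accuracy, 1), 96.2)

  # Adam comparison table, scale-adaptive + ResNet50 row
  m2 <- micro_metrics(129, 393, 3, 3)
  expect_equal(round(m2$precision, 3), 0.977)
  expect_equal(round(100 * m2$sensitivity, 1), 97.7)
  expect_equal(round(100 * m2$specificity, 1), 99.2)
  expect_equal(round(100 * m2$accuracy, 1), 97.7)

  # perfect counts give all ones
  m3 <- micro_metrics(10, 30, 0, 0)
  expect_equal(unlist(m3[c("precision", "sensitivity", "specificity",
                           "f1", "accuracy")]),
               c(precision = 1, sensitivity = 1, specificity = 1,
                 f1 = 1, accuracy = 1))
})

test_that("zero denominators are flagged undefined, not silently zero", {
  m <- micro_metrics(0, 10, 0, 0)
  expect_true("precision" %in% m$undefined)
  expect_true(is.na(m$precision))
  expect_false(is.na(m$specificity))
})

test_that("f1 is the harmonic mean of precision and sensitivity", {
  m <- micro_metrics(80, 300, 20, 10)
  expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                 (m$precision + m$sensitivity))
})

test_that("per-class metrics match hand counts and recall-weighting identity", {
  m <- matrix(0L, 4, 4, dimnames = list(grade_levels(), grade_levels()))
  m[1:2, 1:2] <- matrix(c(3L, 0L, 1L, 4L), 2, 2)  # [[3,1],[0,4]] padded
  pc <- per_class_metrics(m)
  expect_equal(pc$recall[1], 0.75)
  expect_equal(pc$precision[1], 1.0)

  # identity-scaled matrix: all defined metrics are 1
  pc2 <- per_class_metrics(diag(c(5L, 5L, 5L, 5L)))
  expect_equal(pc2$precision, rep(1, 4))
  expect_equal(pc2$recall, rep(1, 4))

  # row-sum-weighted recalls equal overall accuracy
  set.seed(32)
  truth <- sample(grade_levels(), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(grade_levels(), 60, TRUE))
  cm <- confusion(truth, pred)
  pc3 <- per_class_metrics(cm$matrix)
  w <- rowSums(cm$matrix) / sum(cm$matrix)
  ok <- !is.na(pc3$recall)
  expect_equal(sum((w * pc3$recall)[ok]), mean(pred == truth))
})

# exhaustive threshold-enumeration AUC oracle on the flattened
# one-vs-rest problem
auc_oracle <- function(one_hot, scores) {
  y <- as.vector(one_hot); s <- as.vector(scores)
  ths <- sort(unique(c(-Inf, s, Inf)), decreasing = TRUE)
  tpr <- vapply(ths, function(t) mean(s[y == 1] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(s[y == 0] >= t), numeric(1))
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
}

test_that("micro-averaged AUC matches the threshold-enumeration oracle", {
  set.seed(33)
  truth <- c("NORMAL", "INTERMEDIATE", "GA", "WET", "GA", "NORMAL")
  oh <- grade_one_hot(truth)
  scores <- matrix(runif(24), 6, 4)
  scores <- scores / rowSums(scores)
  r <- roc_auc(oh, scores)
  expect_equal(r$auc, auc_oracle(oh, scores), tolerance = 1e-12)

  # perfect scores: auc 1; label-independent scores: auc 0.5
  expect_equal(roc_auc(oh, oh)$auc, 1)
  flat <- matrix(0.25, 6, 4)
  expect_equal(roc_auc(oh, flat)$auc, 0.5)
})

test_that("AUC is invariant under monotone score transformations", {
  set.seed(34)
  oh <- grade_one_hot(sample(grade_levels(), 10, replace = TRUE))
  scores <- matrix(runif(40), 10, 4)
  a1 <- roc_auc(oh, scores)$auc
  a2 <- roc_auc(oh, scores^3)$auc
  a3 <- roc_auc(oh, plogis(5 * scores))$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("stratified k-fold partitions exactly and summarizes correctly", {
  manifest <- data.frame(id = sprintf("i%02d", 1:40),
                         grade = rep(grade_levels(), each = 10))
  seen <- integer(0)
  cv <- kfold_cv(manifest, 5, seed = 1, train_fn = function(tr, va, fold) {
    expect_identical(nrow(va), 8L)
    expect_identical(as.vector(table(va$grade)), rep(2L, 4L))
    seen <<- c(seen, match(va$id, manifest$id))
    0.9
  })
  expect_identical(sort(seen), 1:40)  # union is the full set, disjoint
  expect_equal(cv$mean, 0.9)
  expect_equal(cv$std, 0)

  # closed-form mean/std for two folds (test mode)
  accs <- c(0.8, 1.0)
  i <- 0
  cv2 <- kfold_cv(manifest, 2, seed = 1,
                  train_fn = function(tr, va, fold) { i <<- i + 1; accs[i] })
  expect_equal(cv2$mean, 0.9)
  expect_equal(cv2$std, sqrt(0.02), tolerance = 1e-12)
  expect_equal(cv2$std, stats::sd(accs))

  # mean/std recomputation from per-fold values is exact
  expect_equal(cv2$mean, mean(cv2$per_fold_accuracy), tolerance = 1e-12)
  expect_equal(cv2$std, stats::sd(cv2$per_fold_accuracy), tolerance = 1e-12)

  expect_error(kfold_cv(manifest[1:4, ], 5, function(...) 1), "at least k")
})

test_that("kfold_cv is reproducible for a deterministic training closure", {
  manifest <- data.frame(id = sprintf("i%02d", 1:24),
                         grade = rep(grade_levels(), each = 6))
  fn <- function(tr, va, fold) mean(va$grade == "GA")
  a <- kfold_cv(manifest, 3, fn, seed = 7)
  b <- kfold_cv(manifest, 3, fn, seed = 7)
  expect_identical(a$per_fold_accuracy, b$per_fold_accuracy)
  expect_identical(a$folds, b$folds)
})

test_that("feature maps extract per-filter activations with exact stubs", {
  # stub conv layer averaging channels through an identity-like kernel
  stub <- list(fundusSA:::layer_conv("avg_stub", 3L, 1L, k = 1L, pad = 0L))
  stub[[1]]$params$W <- matrix(1 / 3, 3, 1)
  stub[[1]]$params$b <- 0
  px <- random_image(16, 16, seed = 8)
  fm <- feature_maps(stub, "avg_stub", px, normalize = FALSE)
  expect_equal(fm[, , 1], (px[, , 1] + px[, , 2] + px[, , 3]) / 3,
               tolerance = 1e-12)

  # all-zero input with zero bias gives all-zero maps
  fm0 <- feature_maps(stub, 1L, array(0, c(16, 16, 3)), normalize = FALSE)
  expect_true(all(fm0 == 0))

  # first conv layer of a backbone yields one spatial map per filter
  clf <- build_classifier("TINY", head_config(c(4L, 4L, 4L)), seed = 0)
  maps <- feature_maps(clf, 1L, random_image(224, 224, seed = 9))
  expect_identical(dim(maps)[3], 8L)
  expect_gte(min(maps), 0)
  expect_lte(max(maps), 1)
  expect_error(feature_maps(clf, "nope", px), "unknown layer")
})
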