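#' Confusion matrix and aggregated one-vs-rest counts
#'
#' Builds the 4 x 4 confusion matrix (rows = true grade, columns = predicted
#' grade) and the micro-aggregated one-vs-rest counts: for each grade `c`,
#' TP is the diagonal cell, FN the rest of its row, FP the rest of its
#' column, TN everything else; the four per-grade counts are summed. For any
#' single-label prediction set the aggregated FP equals the aggregated FN
#' (each error is one FN for the true grade and one FP for the predicted
#' one), TP equals the trace, and TP + TN + FP + FN equals 4x the sample
#' count.
#'
#' @param true_labels,predicted_labels equal-length vectors of grade names.
#' @param order optional alternative grade ordering.
#' @return a `confusion_counts` list with `matrix`, `tp`, `tn`, `fp`, `fn`
#'   and `n`.
#' @export
confusion <- function(true_labels, predicted_labels, order = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  tf <- grade_factor(true_labels, order)
  pf <- grade_factor(predicted_labels, order)
  m <- table(true = tf, predicted = pf)
  m <- matrix(as.integer(m), 4L, 4L, dimnames = dimnames(m))
  n <- length(tf)
  tp <- as.integer(sum(diag(m)))
  fn <- as.integer(sum(rowSums(m) - diag(m)))
  fp <- as.integer(sum(colSums(m) - diag(m)))
  tn <- 4L * n - tp - fn - fp
  structure(list(matrix = m, tp = tp, tn = tn, fp = fp, fn = fn, n = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(x$matrix)
  cat(sprintf("aggregated one-vs-rest: TP %d  TN %d  FP %d  FN %d (n = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$n))
  invisible(x)
}

#' Micro-averaged performance metrics from aggregated counts
#'
#' Applies the metric formulas to aggregated one-vs-rest counts:
#' precision `tp/(tp+fp)`, sensitivity (recall) `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, F1 the harmonic mean of precision and sensitivity, and
#' accuracy `tp/(tp+fn)` — for counts derived from a single-label confusion
#' matrix this equals ordinary sample-level accuracy (and, since `fp = fn`
#' there, also precision and sensitivity). Counts may also be supplied
#' directly (e.g. from a published table) and the formulas are applied as
#' given. A zero denominator flags the affected metric as undefined (`NA`)
#' rather than silently returning 0.
#'
#' @param counts a `confusion_counts`, or `tp` given as a single count with
#'   `tn`, `fp`, `fn`.
#' @param tn,fp,fn counts when `counts` is given as the `tp` scalar.
#' @param auc optional AUC to carry into the report.
#' @return a `metrics_report` list with fields `precision`, `sensitivity`,
#'   `specificity`, `f1`, `accuracy`, `auc` and `undefined` (names of
#'   metrics with zero denominators).
#' @examples
#' micro_metrics(127, 392, 4, 5)  # precision 0.9695, accuracy 0.962
#' @export
micro_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL, auc = NA_real_) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  } else {
    tp <- counts
    if (is.null(tn) || is.null(fp) || is.null(fn))
      stop("supply tn, fp and fn alongside the tp count")
  }
  undefined <- character()
  div <- function(num, den, metric) {
    if (den == 0) { undefined <<- c(undefined, metric); return(NA_real_) }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  sensitivity <- div(tp, tp + fn, "sensitivity")
  specificity <- div(tn, tn + fp, "specificity")
  accuracy <- div(tp, tp + fn, "accuracy")
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            (precision + sensitivity) == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * precision * sensitivity / (precision + sensitivity)
  structure(list(precision = precision, sensitivity = sensitivity,
                 specificity = specificity, f1 = f1, accuracy = accuracy,
                 auc = auc, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.4f  sensitivity %.2f%%  F1 %.2f%%  specificity %.2f%%  accuracy %.2f%%",
              x$precision, 100 * x$sensitivity, 100 * x$f1,
              100 * x$specificity, 100 * x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.2f%%", 100 * x$auc))
  cat("\n")
  if (length(x$undefined))
    cat("undefined metrics:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Per-grade precision, recall and F1
#'
#' For grade `c`: precision is the diagonal cell over its column sum, recall
#' over its row sum, F1 their harmonic mean; zero denominators yield `NA`.
#' Row-sum-weighted recalls average to the overall accuracy.
#'
#' @param m 4 x 4 confusion matrix (rows = true, columns = predicted) or a
#'   `confusion_counts`.
#' @return data frame `grade,precision,recall,f1`.
#' @export
per_class_metrics <- function(m) {
  if (inherits(m, "confusion_counts")) m <- m$matrix
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("m must be a square confusion matrix")
  grades <- rownames(m) %||% paste0("class", seq_len(nrow(m)) - 1L)
  rows <- lapply(seq_len(nrow(m)), function(c_) {
    tp <- m[c_, c_]
    prec <- if (sum(m[, c_]) == 0) NA_real_ else tp / sum(m[, c_])
    rec <- if (sum(m[c_, ]) == 0) NA_real_ else tp / sum(m[c_, ])
    f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    data.frame(grade = grades[c_], precision = prec, recall = rec, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Micro-averaged ROC curve and AUC
#'
#' Flattens one-vs-rest decisions across all classes (every sample
#' contributes one positive and `K - 1` negative score entries), sweeps the
#' decision threshold over all scores, and integrates the ROC curve by the
#' trapezoid rule. AUC is invariant to any strictly monotone transformation
#' of the scores.
#'
#' @param true_one_hot `N x K` 0/1 matrix of true classes.
#' @param score_matrix `N x K` score matrix in `[0, 1]` (rows approximately
#'   summing to 1 for probability scores).
#' @return a list with `auc` and `roc` (data frame `fpr,tpr` including the
#'   (0,0) and (1,1) endpoints), plus `undefined` flag when only one class is
#'   present in the flattened labels.
#' @export
roc_auc <- function(true_one_hot, score_matrix) {
  if (!all(dim(true_one_hot) == dim(score_matrix)))
    stop("shape mismatch between labels and scores")
  y <- as.vector(true_one_hot)
  s <- as.vector(score_matrix)
  pos <- sum(y == 1); neg <- sum(y == 0)
  if (pos == 0 || neg == 0)
    return(list(auc = NA_real_, roc = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                undefined = TRUE))
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tps <- cumsum(y == 1)
  fps <- cumsum(y == 0)
  # keep the last index of each tied score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tps[keep] / pos, 1)
  fpr <- c(0, fps[keep] / neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr), undefined = FALSE)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the manifest into `k` stratified folds (per-grade fold sizes
#' differing by at most one), trains via the supplied closure with each fold
#' held out in turn, and summarizes the per-fold accuracies with their mean
#' and sample (n-1) standard deviation.
#'
#' @param manifest data frame with a `grade` column; every grade must have at
#'   least `k` rows.
#' @param k number of folds (typically 3, 5 or 10).
#' @param train_fn closure `function(train_manifest, val_manifest, fold)`
#'   returning the fold accuracy as a single number.
#' @param seed integer seed for the fold assignment.
#' @return a `cv_summary` list with `k`, `per_fold_accuracy`, `mean`, `std`
#'   and `folds` (the fold id per manifest row).
#' @export
kfold_cv <- function(manifest, k, train_fn, seed = 0L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  tab <- table(manifest$grade)
  if (any(tab < k))
    stop("every grade needs at least k samples; short: ",
         paste(names(tab)[tab < k], collapse = ", "))
  old <- local_rng(seed)
  fold <- integer(nrow(manifest))
  for (g in unique(manifest$grade)) {
    idx <- which(manifest$grade == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  restore_rng(old)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    acc[f] <- train_fn(manifest[fold != f, , drop = FALSE],
                       manifest[fold == f, , drop = FALSE], f)
  }
  structure(list(k = k, per_fold_accuracy = acc, mean = mean(acc),
                 std = stats::sd(acc), folds = fold),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy: %.2f%% +/- %.2f%%\n",
              x$k, 100 * x$mean, 100 * x$std))
  invisible(x)
}

#' Convolutional feature-map extraction
#'
#' Runs an image through a model and returns the activation maps of one
#' convolution layer, one 2-D map per filter, optionally normalized to
#' `[0, 1]` per map (constant maps normalize to 0) and truncated to the
#' first `max_maps` filters for grid export.
#'
#' @param model a `grading_classifier` (its backbone is used), an
#'   `sa_model`, or a plain layer list.
#' @param layer_selector layer name, or integer index among the model's
#'   convolution layers (1 = first conv layer).
#' @param image a `fundus_image` or pixel array.
#' @param max_maps cap on the number of returned maps (default 64).
#' @param normalize rescale each map to `[0, 1]` (default `TRUE`).
#' @return an `H x W x n_filters` array of activation maps.
#' @export
feature_maps <- function(model, layer_selector, image, max_maps = 64L,
                         normalize = TRUE) {
  px <- as_pixels(image)
  record <- new.env()
  record$acts <- list(); record$types <- list()
  if (inherits(model, "grading_classifier")) {
    seq_record(model$backbone$layers, px, record)
  } else if (inherits(model, "sa_model")) {
    latent <- seq_record(model$trunk, px, record)
    seq_record(model$low, latent, record)
    seq_record(model$high, latent, record)
  } else {
    seq_record(model, px, record)
  }
  conv_names <- names(record$types)[unlist(record$types) == "conv"]
  name <- if (is.character(layer_selector)) {
    if (!layer_selector %in% names(record$acts))
      stop("unknown layer: ", layer_selector)
    layer_selector
  } else {
    i <- as.integer(layer_selector)
    if (i < 1L || i > length(conv_names))
      stop("convolution layer index out of range (1..", length(conv_names), ")")
    conv_names[i]
  }
  act <- record$acts[[name]]
  if (length(dim(act)) != 3L)
    stop("layer '", name, "' is not convolutional")
  nf <- min(dim(act)[3], max_maps)
  act <- act[, , seq_len(nf), drop = FALSE]
  if (normalize) {
    for (f in seq_len(nf)) {
      m <- act[, , f]
      rng <- range(m)
      act[, , f] <- if (diff(rng) == 0) 0 else (m - rng[1]) / diff(rng)
    }
  }
  act
}

# forward pass recording every layer's activation (descending into
# composites so named conv sub-layers are addressable)
seq_record <- function(layers, x, record) {
  for (ly in layers) {
    if (ly$type == "residual") {
      body_out <- seq_record(ly$body, x, record)
      short_out <- if (length(ly$shortcut)) seq_record(ly$shortcut, x, record) else x
      x <- pmax(body_out + short_out, 0)
    } else if (ly$type == "branch_concat") {
      outs <- lapply(ly$branches, function(br) seq_record(br, x, record))
      chans <- vapply(outs, function(o) dim(o)[3], integer(1))
      d1 <- dim(outs[[1]])
      out <- array(0, c(d1[1], d1[2], sum(chans)))
      at <- 0L
      for (i in seq_along(outs)) {
        out[, , at + seq_len(chans[i])] <- outs[[i]]
        at <- at + chans[i]
      }
      x <- out
    } else {
      x <- layer_fwd(ly, x, training = FALSE, need_cache = FALSE)$out
    }
    record$acts[[ly$name]] <- x
    record$types[[ly$name]] <- ly$type
  }
  x
}

#' Export a metrics report as a table row
#'
#' Serializes counts and metrics in the standard comparison-table column
#' order `model,tp,tn,fp,fn,precision,sensitivity,f1,specificity,accuracy,auc`.
#'
#' @param model_name row label.
#' @param counts a `confusion_counts` (or list with tp/tn/fp/fn).
#' @param report a `metrics_report` from [micro_metrics()].
#' @return one-row data frame in the canonical column order.
#' @export
metrics_row <- function(model_name, counts, report) {
  data.frame(model = model_name, tp = counts$tp, tn = counts$tn,
             fp = counts$fp, fn = counts$fn,
             precision = report$precision, sensitivity = report$sensitivity,
             f1 = report$f1, specificity = report$specificity,
             accuracy = report$accuracy, auc = report$auc)
}
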