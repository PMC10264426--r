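#' Dense head configuration for the grading network
#'
#' The classification head sits on the pooled backbone features: three
#' repeated blocks of dense (ReLU), batch normalization, dropout; then a
#' 4-unit softmax output layer, one unit per AMD grade.
#'
#' @param dense_widths three positive integers (default 1024, 512, 256).
#' @param dropout_rate dropout probability in `[0, 1)` (default 0.5).
#' @param n_classes number of output classes (4 grades).
#' @return a `head_config` list.
#' @export
head_config <- function(dense_widths = c(1024L, 512L, 256L),
                        dropout_rate = 0.5, n_classes = 4L) {
  dense_widths <- as.integer(dense_widths)
  if (length(dense_widths) != 3L || any(dense_widths < 1L))
    stop("dense_widths must be exactly 3 positive integers")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (n_classes != 4L) stop("the grading head has 4 output classes")
  structure(list(dense_widths = dense_widths, dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes)),
            class = "head_config")
}

#' Augmentation specification
#'
#' Training-time augmentation expands every image into 4: the original, one
#' copy rotated by `rotation_deg` about the center (black corner fill, frame
#' size kept), a horizontal flip and a vertical flip. Augmentation is never
#' applied at validation or test time.
#'
#' @param rotation_deg single rotation angle in degrees (default 50).
#' @param hflip,vflip include the horizontal / vertical mirror copies.
#' @return an `augmentation_spec` list.
#' @export
augmentation_spec <- function(rotation_deg = 50, hflip = TRUE, vflip = TRUE) {
  structure(list(rotation_deg = rotation_deg, hflip = isTRUE(hflip),
                 vflip = isTRUE(vflip), apply_phase = "TRAIN_ONLY"),
            class = "augmentation_spec")
}

#' Expand one image into its augmented copies
#'
#' @param image a `fundus_image` or pixel array.
#' @param spec an [augmentation_spec()].
#' @return a list of pixel arrays: original, rotated, then the enabled flips
#'   (length 4 with the default spec).
#' @export
augment <- function(image, spec = augmentation_spec()) {
  px <- as_pixels(image)
  out <- list(px, rotate_image(px, spec$rotation_deg))
  if (spec$hflip) out <- c(out, list(flip_horizontal(px)))
  if (spec$vflip) out <- c(out, list(flip_vertical(px)))
  out
}

#' Classifier training configuration
#'
#' Defaults follow the published recipe: SGD starting at learning rate 0.001
#' reduced on plateau, 300 epochs, batch size 64, a stratified 70/15/15
#' train/validation/test split, and train-only augmentation. The backbone is
#' used as a frozen feature extractor by default (`train_backbone = FALSE`):
#' pooled features are computed once per (augmented) image and the dense head
#' is optimized on them.
#'
#' @param backbone backbone name, see [backbone_names()].
#' @param pretrained load pretrained backbone weights from
#'   `pretrained_path` (an RDS of a flat parameter list). `FALSE` (random
#'   initialization) is the offline default.
#' @param pretrained_path checkpoint path used when `pretrained = TRUE`.
#' @param optimizer `"SGD"` or `"ADAM"`.
#' @param initial_lr starting learning rate.
#' @param plateau list with `factor`, `patience` and `min_lr` for the
#'   reduce-on-plateau schedule monitoring validation loss.
#' @param epochs training epochs.
#' @param batch_size minibatch size for the head optimizer.
#' @param split length-3 fractions (train, validation, test) summing to 1.
#' @param augmentation an [augmentation_spec()].
#' @param head a [head_config()].
#' @param seed integer seed.
#' @return a `clf_train_config` list.
#' @export
clf_train_config <- function(backbone = "RESNET50", pretrained = FALSE,
                             pretrained_path = NULL,
                             optimizer = "SGD", initial_lr = 0.001,
                             plateau = list(factor = 0.1, patience = 10L,
                                            min_lr = 1e-6),
                             epochs = 300L, batch_size = 64L,
                             split = c(0.70, 0.15, 0.15),
                             augmentation = augmentation_spec(),
                             head = head_config(), seed = 0L) {
  backbone <- toupper(backbone)
  if (!backbone %in% backbone_names())
    stop("configuration error: unknown backbone '", backbone, "'")
  optimizer <- toupper(optimizer)
  if (!optimizer %in% c("SGD", "ADAM")) stop("optimizer must be SGD or ADAM")
  if (initial_lr <= 0) stop("initial_lr must be positive")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (length(split) != 3L || any(split < 0)) stop("split must be 3 nonnegative fractions")
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  plateau <- utils::modifyList(list(factor = 0.1, patience = 10L, min_lr = 1e-6),
                               plateau)
  if (isTRUE(pretrained) && is.null(pretrained_path))
    stop("pretrained = TRUE requires pretrained_path (no weights are bundled)")
  stopifnot(inherits(head, "head_config"), inherits(augmentation, "augmentation_spec"))
  structure(list(backbone = backbone, pretrained = isTRUE(pretrained),
                 pretrained_path = pretrained_path,
                 optimizer = optimizer, initial_lr = initial_lr,
                 plateau = plateau, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 augmentation = augmentation, head = head,
                 seed = as.integer(seed)),
            class = "clf_train_config")
}

build_head_layers <- function(feature_dim, head) {
  w <- head$dense_widths
  layers <- list()
  in_dim <- feature_dim
  for (i in 1:3) {
    layers <- c(layers, list(
      layer_dense(sprintf("head_d%d", i), in_dim, w[i], init = "he"),
      layer_act(sprintf("head_relu%d", i), "relu"),
      layer_bn(sprintf("head_bn%d", i), w[i], spatial = FALSE),
      layer_dropout(sprintf("head_drop%d", i), head$dropout_rate)))
    in_dim <- w[i]
  }
  c(layers, list(layer_dense("head_out", in_dim, head$n_classes, init = "glorot")))
}

#' Build the four-grade classification network
#'
#' Assembles backbone conv stack -> global average pooling -> flatten ->
#' 3 x (dense-ReLU, batch norm, dropout) -> dense(4, softmax), and reports
#' parameter counts. With `pretrained = FALSE` all weights are random
#' (seeded); the model is then trained offline.
#'
#' @param backbone backbone name (see [backbone_names()]).
#' @param head a [head_config()].
#' @param seed integer seed.
#' @param grade_order optional alternative grade ordering for the softmax
#'   units (default canonical, see [grade_levels()]).
#' @return a `grading_classifier` with fields `backbone`, `head_layers`,
#'   `feature_dim` and `param_counts` (`total`, `trainable` — batch-norm
#'   running statistics are the non-trainable parameters).
#' @export
build_classifier <- function(backbone = "RESNET50", head = head_config(),
                             seed = 0L, grade_order = NULL) {
  bb <- build_backbone(backbone, seed = seed)
  old <- local_rng(derive_seed(seed, 17L))
  on.exit(restore_rng(old), add = TRUE)
  head_layers <- build_head_layers(bb$feature_dim, head)
  counts_bb <- count_params(bb$layers)
  counts_head <- count_params(head_layers)
  structure(list(backbone = bb, head_layers = head_layers,
                 head_config = head, feature_dim = bb$feature_dim,
                 grade_order = grade_levels(grade_order),
                 param_counts = list(
                   total = unname(counts_bb["trainable"] + counts_bb["stats"] +
                                  counts_head["trainable"] + counts_head["stats"]),
                   trainable = unname(counts_bb["trainable"] + counts_head["trainable"]),
                   head_total = unname(counts_head["trainable"] + counts_head["stats"]),
                   head_trainable = unname(counts_head["trainable"]))),
            class = "grading_classifier")
}

#' @export
print.grading_classifier <- function(x, ...) {
  cat(sprintf("<grading_classifier> %s backbone, head %s, %s total / %s trainable parameters\n",
              x$backbone$name,
              paste(x$head_config$dense_widths, collapse = "/"),
              format(x$param_counts$total, big.mark = ","),
              format(x$param_counts$trainable, big.mark = ",")))
  invisible(x)
}

#' Reduce-on-plateau learning-rate schedule
#'
#' Stateful schedule that multiplies the learning rate by `factor` whenever
#' the monitored loss has not improved for `patience` consecutive updates.
#'
#' @param lr initial learning rate.
#' @param factor multiplicative reduction factor in (0, 1).
#' @param patience number of non-improving updates tolerated before reducing.
#' @param min_lr floor for the learning rate.
#' @param min_delta minimum decrease counted as an improvement.
#' @return `plateau_init()` returns a schedule state; `plateau_update()`
#'   consumes one metric observation and returns the updated state, whose
#'   `lr` field is the rate to use next.
#' @export
plateau_init <- function(lr, factor = 0.1, patience = 10L, min_lr = 1e-6,
                         min_delta = 1e-8) {
  list(lr = lr, factor = factor, patience = as.integer(patience),
       min_lr = min_lr, min_delta = min_delta, best = Inf, wait = 0L)
}

#' @rdname plateau_init
#' @param state a schedule state from [plateau_init()].
#' @param metric the monitored loss value for this epoch (lower is better).
#' @export
plateau_update <- function(state, metric) {
  if (metric < state$best - state$min_delta) {
    state$best <- metric
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$min_lr)
      state$wait <- 0L
    }
  }
  state
}

#' Stratified train/validation/test split
#'
#' Splits a manifest by grade so per-grade proportions are preserved within
#' one sample. Within each grade, `floor(n * p_train)` rows go to training
#' and `floor(n * p_val)` to validation; the remainder is the test set.
#'
#' @param manifest data frame with a `grade` column.
#' @param split length-3 fractions summing to 1.
#' @param seed integer seed for the within-grade shuffle.
#' @return the manifest with an added `split` column
#'   (`"train"/"val"/"test"`).
#' @export
stratified_split <- function(manifest, split = c(0.70, 0.15, 0.15), seed = 0L) {
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  manifest$split <- NA_character_
  for (g in unique(manifest$grade)) {
    idx <- which(manifest$grade == g)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_train <- floor(n * split[1])
    n_val <- floor(n * split[2])
    manifest$split[idx[seq_len(n_train)]] <- "train"
    if (n_val > 0)
      manifest$split[idx[n_train + seq_len(n_val)]] <- "val"
    manifest$split[setdiff(idx, idx[seq_len(n_train + n_val)])] <- "test"
  }
  manifest
}

# resolve images for a manifest: from a named list if supplied, else PNGs
manifest_images <- function(manifest, images = NULL) {
  if (!is.null(images)) {
    if (is.null(names(images))) names(images) <- vapply(images, `[[`, "", "id")
    return(images[manifest$id])
  }
  dir <- attr(manifest, "dir")
  if (is.null(dir)) stop("manifest has no image directory; supply images=")
  out <- lapply(seq_len(nrow(manifest)), function(i)
    read_fundus_png(file.path(dir, manifest$filename[i]),
                    label = manifest$grade[i], id = manifest$id[i]))
  names(out) <- manifest$id
  out
}

resize_for_clf <- function(sa_model, px) {
  if (is.null(sa_model)) resize_bilinear(px, 224L, 224L)
  else sa_resize(sa_model, px)
}

head_forward <- function(clf, feats, training = FALSE, need_cache = FALSE) {
  seq_fwd(clf$head_layers, feats, training = training, need_cache = need_cache)
}

#' Train the grading classifier
#'
#' Pipeline per the integrated model: every image is resized through the
#' scale-adaptive network (or a bilinear stub when `sa_model` is `NULL`),
#' training images are expanded by the augmentation spec (validation/test
#' never are), pooled backbone features are extracted, and the dense head is
#' optimized under categorical cross-entropy with the configured optimizer
#' and a reduce-on-plateau learning-rate schedule monitoring validation loss.
#'
#' @param manifest manifest data frame (see [generate_dataset()]); a `split`
#'   column is honored if present, otherwise a stratified split is drawn.
#' @param sa_model trained `sa_model`, or `NULL` for a bilinear-resize stub.
#' @param config a [clf_train_config()].
#' @param images optional named list of in-memory `fundus_image`s keyed by
#'   manifest id (skips file reading).
#' @param verbose print per-epoch progress.
#' @return a list with `model` (a `grading_classifier` with trained head),
#'   `history` (data frame `epoch,split,loss,accuracy`), and `manifest` (with
#'   the split column used).
#' @export
train_classifier <- function(manifest, sa_model = NULL,
                             config = clf_train_config(), images = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(config, "clf_train_config"))
  if (!"split" %in% names(manifest))
    manifest <- stratified_split(manifest, config$split,
                                 seed = derive_seed(config$seed, 3L))
  if (!all(grade_levels() %in% manifest$grade[manifest$split == "train"]))
    stop("stratification error: every grade must appear in the training split")

  clf <- build_classifier(config$backbone, config$head, seed = config$seed)
  if (config$pretrained) {
    flat <- readRDS(config$pretrained_path)
    clf$backbone$layers <- assign_params(clf$backbone$layers, flat)
  }
  imgs <- manifest_images(manifest, images)
  feats_of <- function(px) backbone_features(clf$backbone, px)

  # build the design matrices: augmented train set, plain val/test
  feat_rows <- list(); labels <- character(); splits <- character()
  for (i in seq_len(nrow(manifest))) {
    px224 <- resize_for_clf(sa_model, as_pixels(imgs[[manifest$id[i]]]))
    sp <- manifest$split[i]
    copies <- if (sp == "train") augment(px224, config$augmentation) else list(px224)
    for (cp in copies) {
      feat_rows[[length(feat_rows) + 1L]] <- feats_of(cp)
      labels <- c(labels, manifest$grade[i])
      splits <- c(splits, sp)
    }
  }
  X <- do.call(rbind, feat_rows)
  Y <- grade_one_hot(labels, order = NULL)

  tr <- which(splits == "train")
  va <- which(splits == "val")
  if (!length(va)) va <- tr  # tiny runs without a val split monitor train loss

  old <- local_rng(derive_seed(config$seed, 5L))
  on.exit(restore_rng(old), add = TRUE)

  params <- collect_params(clf$head_layers)
  opt <- opt_init(tolower(config$optimizer), lr = config$initial_lr)
  sched <- plateau_init(config$initial_lr, config$plateau$factor,
                        config$plateau$patience, config$plateau$min_lr)
  bs <- min(config$batch_size, length(tr))
  hist_rows <- vector("list", 2L * config$epochs)

  eval_split <- function(idx) {
    pass <- head_forward(clf, X[idx, , drop = FALSE], training = FALSE)
    sx <- softmax_xent(pass$out, Y[idx, , drop = FALSE])
    pred <- max.col(sx$probs, ties.method = "first")
    truth <- max.col(Y[idx, , drop = FALSE], ties.method = "first")
    c(loss = sx$loss, accuracy = mean(pred == truth))
  }

  for (epoch in seq_len(config$epochs)) {
    opt$lr <- sched$lr
    order_tr <- tr[sample.int(length(tr))]
    for (b0 in seq(1L, length(order_tr), by = bs)) {
      idx <- order_tr[b0:min(b0 + bs - 1L, length(order_tr))]
      pass <- seq_fwd(clf$head_layers, X[idx, , drop = FALSE],
                      training = TRUE, need_cache = TRUE)
      sx <- softmax_xent(pass$out, Y[idx, , drop = FALSE])
      bwd <- seq_bwd(clf$head_layers, pass$caches, sx$dlogits)
      clf$head_layers <- update_bn_state(clf$head_layers, pass$caches)
      step <- opt_step(opt, params, bwd$grads)
      opt <- step$opt; params <- step$params
      clf$head_layers <- assign_params(clf$head_layers, params)
    }
    m_tr <- eval_split(tr)
    m_va <- eval_split(va)
    sched <- plateau_update(sched, m_va["loss"])
    hist_rows[[2L * epoch - 1L]] <- data.frame(
      epoch = epoch, split = "train", loss = unname(m_tr["loss"]),
      accuracy = unname(m_tr["accuracy"]), lr = opt$lr)
    hist_rows[[2L * epoch]] <- data.frame(
      epoch = epoch, split = "val", loss = unname(m_va["loss"]),
      accuracy = unname(m_va["accuracy"]), lr = opt$lr)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, m_tr["loss"], m_tr["accuracy"],
                      m_va["loss"], m_va["accuracy"]))
  }
  list(model = clf, history = do.call(rbind, hist_rows), manifest = manifest)
}

#' Predict the AMD grade of one image
#'
#' @param model a `grading_classifier`.
#' @param sa_model trained `sa_model` or `NULL` for a bilinear-resize stub.
#' @param image a `fundus_image` or pixel array.
#' @return a list with `probs` (named 4-vector summing to 1) and `label`
#'   (argmax grade; exact ties resolve to the lowest index, i.e. the first
#'   grade in the canonical order).
#' @export
predict_grade <- function(model, sa_model = NULL, image) {
  stopifnot(inherits(model, "grading_classifier"))
  px <- resize_for_clf(sa_model, as_pixels(image))
  feats <- matrix(backbone_features(model$backbone, px), 1L)
  logits <- head_forward(model, feats, training = FALSE)$out
  probs <- drop(softmax_rows(logits))
  names(probs) <- model$grade_order
  list(probs = probs,
       label = model$grade_order[which.max(probs)])
}
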