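#' Scale-adaptive auto-encoder architecture
#'
#' Configuration of the resizing auto-encoder. A variable-size `H x W x 3`
#' fundus image (any `H, W >= 224`) passes through two same-padded
#' convolution stages with tanh activations, a 2 x 2 max-pool, and an
#' adaptive average-pooling stage that lands on a fixed 112 x 112 latent
#' grid regardless of the input size. The network then splits into two
#' decoder branches, each a convolution followed by a 2 x 2 stride-2
#' transpose convolution:
#' \itemize{
#'   \item the \emph{low-resolution branch} emits the 224 x 224 x 3 resized
#'     image that downstream classifiers consume;
#'   \item the \emph{high-resolution branch} emits a packed 224 x 224 x 12
#'     tensor that rearranges losslessly (2 x 2 depth-to-space) into a
#'     448 x 448 x 3 reconstruction of the input.
#' }
#' Concatenated, the branches form the 224 x 224 x 15 output described by the
#' architecture. tanh outputs are mapped affinely to `[0, 1]` via
#' `(x + 1) / 2`.
#'
#' The latent grid is constrained by the output contract: a stride-2
#' upsampling of the grid must produce exactly 224 x 224, and the packed
#' high-resolution tensor must hold exactly `224 * 224 * 12 = 602112`
#' elements, so any grid other than 112 x 112 is rejected at build time.
#'
#' @param latent_grid length-2 integer vector, the adaptive-pooling target
#'   (default `c(112, 112)`).
#' @param kernel convolution kernel size (default 3).
#' @param filters length-2 integer vector of encoder filter counts
#'   (default `c(16, 32)`).
#' @param branch_filters length-2 integer vector of decoder filter counts for
#'   the low and high branch convolutions (default `c(16, 48)`: the high
#'   branch renders four times the output volume of the low branch, so it
#'   carries proportionally more filters).
#' @return an `sa_architecture` list.
#' @export
sa_architecture <- function(latent_grid = c(112L, 112L), kernel = 3L,
                            filters = c(16L, 32L),
                            branch_filters = c(16L, 48L)) {
  latent_grid <- as.integer(latent_grid)
  if (length(latent_grid) != 2L || any(latent_grid < 1L))
    stop("latent_grid must be two positive integers")
  if (kernel < 1L || kernel %% 2L != 1L) stop("kernel must be odd and positive")
  filters <- as.integer(filters); branch_filters <- as.integer(branch_filters)
  if (length(filters) != 2L || any(filters < 1L))
    stop("filters must be two positive integers")
  if (length(branch_filters) != 2L || any(branch_filters < 1L))
    stop("branch_filters must be two positive integers")
  structure(list(latent_grid = latent_grid, kernel = as.integer(kernel),
                 filters = filters, branch_filters = branch_filters),
            class = "sa_architecture")
}

#' Build the scale-adaptive auto-encoder
#'
#' Initializes the network of [sa_architecture()] with Glorot-scaled random
#' weights. The same seed always produces identical initial weights.
#'
#' @param arch an [sa_architecture()].
#' @param seed integer seed for weight initialization.
#' @return an `sa_model` object.
#' @export
build_sa <- function(arch = sa_architecture(), seed = 0L) {
  stopifnot(inherits(arch, "sa_architecture"))
  lg <- arch$latent_grid
  if (!identical(2L * lg, c(224L, 224L)) ||
      prod(lg) * 48L != 224L * 224L * 12L)
    stop("configuration error: latent grid ", lg[1], "x", lg[2],
         " cannot be upsampled/reshaped to the 224x224x12 target (",
         prod(lg) * 48L, " elements != 602112); use a 112x112 grid")
  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  k <- arch$kernel; f <- arch$filters; bf <- arch$branch_filters
  trunk <- list(
    layer_conv("enc_conv1", 3L, f[1], k = k, init = "glorot"),
    layer_act("enc_act1", "tanh"),
    layer_conv("enc_conv2", f[1], f[2], k = k, init = "glorot"),
    layer_act("enc_act2", "tanh"),
    layer_maxpool("enc_pool", 2L, 2L),
    layer_adaptive_avgpool("latent_pool", lg[1], lg[2])
  )
  # 2x2 stride-2 transpose convolution realized exactly as a 1x1
  # convolution onto 4x the target channels followed by 2x2 depth-to-space
  low <- list(
    layer_conv("low_conv", f[2], bf[1], k = k, init = "glorot"),
    layer_act("low_act", "tanh"),
    layer_conv("low_tconv", bf[1], 12L, k = 1L, init = "glorot"),
    layer_depth_to_space("low_shuffle"),
    layer_act("low_out_act", "tanh")
  )
  high <- list(
    layer_conv("high_conv", f[2], bf[2], k = k, init = "glorot"),
    layer_act("high_act", "tanh"),
    layer_conv("high_tconv", bf[2], 48L, k = 1L, init = "glorot"),
    layer_depth_to_space("high_shuffle"),
    layer_act("high_out_act", "tanh")
  )
  structure(list(arch = arch, trunk = trunk, low = low, high = high,
                 seed = as.integer(seed)),
            class = "sa_model")
}

#' @export
print.sa_model <- function(x, ...) {
  np <- count_params(c(x$trunk, x$low, x$high))
  cat(sprintf("<sa_model> latent %dx%d, filters %s, %d parameters\n",
              x$arch$latent_grid[1], x$arch$latent_grid[2],
              paste(x$arch$filters, collapse = "/"), np["trainable"]))
  invisible(x)
}

#' Scaled output pair
#'
#' Container for the two outputs of the scale-adaptive network: the
#' 224 x 224 x 3 low-resolution image and the packed 224 x 224 x 12
#' high-resolution tensor (equivalent to a 448 x 448 x 3 image via
#' [unpack_depth()]).
#'
#' @param low 224 x 224 x 3 array in `[0, 1]`.
#' @param high 224 x 224 x 12 array in `[0, 1]`.
#' @return a `scaled_pair` list.
#' @export
scaled_pair <- function(low, high) {
  if (!identical(dim(low), c(224L, 224L, 3L)))
    stop("low must be 224x224x3")
  if (!identical(dim(high), c(224L, 224L, 12L)))
    stop("high must be 224x224x12")
  structure(list(low = low, high = high), class = "scaled_pair")
}

#' Lossless packing between 448x448x3 and 224x224x12
#'
#' `pack_depth()` rearranges a `448 x 448 x 3` image into the `224 x 224 x 12`
#' tensor emitted by the high-resolution branch (2 x 2 space-to-depth);
#' `unpack_depth()` is its exact inverse. Channel block `q` (0-based, blocks
#' of 3 channels) carries the sub-pixel at row offset `q %% 2` and column
#' offset `q %/% 2` of each 2 x 2 spatial block: output pixel `(i, j)` of the
#' unpacked image equals element `(ceiling(i/2), ceiling(j/2))` of channel
#' block `(i - 1) %% 2 + 2 * ((j - 1) %% 2)`.
#'
#' @param high a `448 x 448 x 3` array.
#' @param packed a `224 x 224 x 12` array.
#' @return the rearranged array; `unpack_depth(pack_depth(x))` is `x` exactly.
#' @export
pack_depth <- function(high) {
  if (!identical(dim(high), c(448L, 448L, 3L)))
    stop("pack_depth expects a 448x448x3 array")
  space_to_depth2(high)
}

#' @rdname pack_depth
#' @export
unpack_depth <- function(packed) {
  if (!identical(dim(packed), c(224L, 224L, 12L)))
    stop("unpack_depth expects a 224x224x12 array")
  depth_to_space2(packed)
}

sa_forward_internal <- function(model, px, training = FALSE,
                                need_cache = FALSE) {
  trunk <- seq_fwd(model$trunk, px, training, need_cache)
  low <- seq_fwd(model$low, trunk$out, training, need_cache)
  high <- seq_fwd(model$high, trunk$out, training, need_cache)
  # map tanh range [-1, 1] to [0, 1]
  list(low = (low$out + 1) / 2, high = (high$out + 1) / 2,
       caches = if (need_cache) list(trunk = trunk$caches, low = low$caches,
                                     high = high$caches) else NULL)
}

#' Run the scale-adaptive network on an image
#'
#' @param model an `sa_model` from [build_sa()] or [train_sa()].
#' @param image a `fundus_image` or `H x W x 3` array with `H, W >= 224`.
#' @return [sa_forward()] returns a [scaled_pair()]; [sa_resize()] returns
#'   just the 224 x 224 x 3 low-resolution output (the tensor handed to the
#'   classifier).
#' @export
sa_forward <- function(model, image) {
  stopifnot(inherits(model, "sa_model"))
  px <- as_pixels(image)
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L) stop("input must be H x W x 3")
  if (d[1] < 224L || d[2] < 224L)
    stop("input must be at least 224x224 (got ", d[1], "x", d[2], ")")
  out <- sa_forward_internal(model, px)
  scaled_pair(out$low, out$high)
}

#' @rdname sa_forward
#' @export
sa_resize <- function(model, image) {
  sa_forward(model, image)$low
}

#' Training configuration for the scale-adaptive network
#'
#' Defaults follow the published recipe: Adam with a fixed 0.001 learning
#' rate, 100 epochs, batch size 1, tanh activations, and the dual
#' reconstruction loss of [sa_loss_config()].
#'
#' @param optimizer `"ADAM"` or `"SGD"`.
#' @param learning_rate positive learning rate (0 is additionally accepted to
#'   express a frozen no-update run).
#' @param epochs number of passes over the image set.
#' @param batch_size images per gradient step (default 1).
#' @param loss an [sa_loss_config()].
#' @param seed integer seed controlling any stochastic part of training.
#' @return an `sa_train_config` list.
#' @export
sa_train_config <- function(optimizer = "ADAM", learning_rate = 0.001,
                            epochs = 100L, batch_size = 1L,
                            loss = sa_loss_config(), seed = 0L) {
  optimizer <- toupper(optimizer)
  if (!optimizer %in% c("ADAM", "SGD")) stop("optimizer must be ADAM or SGD")
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  stopifnot(inherits(loss, "sa_loss_config"))
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 loss = loss, seed = as.integer(seed)),
            class = "sa_train_config")
}

# reconstruction targets: bilinear resamples of the input at the two branch
# resolutions
sa_targets <- function(px) {
  list(low = resize_bilinear(px, 224L, 224L),
       high = resize_bilinear(px, 448L, 448L))
}

#' Train the scale-adaptive auto-encoder
#'
#' Minimizes the combined dual-resolution loss over the image set. Targets
#' per image are bilinear resamples of that image at 224 x 224 (low branch)
#' and 448 x 448 (high branch). Images are visited in a fixed order, so a
#' fixed seed and config reproduce the loss history exactly on a given
#' machine.
#'
#' @param model an `sa_model`.
#' @param images nonempty list of `fundus_image`s (or pixel arrays).
#' @param config an [sa_train_config()].
#' @param verbose print per-epoch loss.
#' @return a list with elements `model` (trained) and `history`
#'   (data frame `epoch,loss` of the mean combined loss per epoch, evaluated
#'   at the weights current when each image was visited).
#' @export
train_sa <- function(model, images, config = sa_train_config(),
                     verbose = FALSE) {
  stopifnot(inherits(model, "sa_model"), inherits(config, "sa_train_config"))
  if (!length(images)) stop("images must be a nonempty list")
  old <- local_rng(config$seed)
  on.exit(restore_rng(old), add = TRUE)

  pixels <- lapply(images, as_pixels)
  for (px in pixels) {
    d <- dim(px)
    if (d[1] < 224L || d[2] < 224L) stop("all images must be at least 224x224")
  }
  targets <- lapply(pixels, sa_targets)
  lc <- config$loss

  params <- collect_params(c(model$trunk, model$low, model$high))
  opt <- opt_init(tolower(config$optimizer), lr = config$learning_rate)
  history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    epoch_loss <- 0
    batch_grads <- list(); in_batch <- 0L
    for (i in seq_along(pixels)) {
      fwd <- sa_forward_internal(model, pixels[[i]], training = TRUE,
                                 need_cache = TRUE)
      high_img <- unpack_depth(fwd$high)
      l_high <- eval_branch_loss(lc$high_loss, high_img, targets[[i]]$high, lc$delta)
      l_low <- eval_branch_loss(lc$low_loss, fwd$low, targets[[i]]$low, lc$delta)
      epoch_loss <- epoch_loss + lc$w_high * l_high + lc$w_low * l_low

      # gradient of the combined loss w.r.t. the two branch outputs; the
      # 1/2 factor undoes the (x+1)/2 output mapping
      d_high <- lc$w_high *
        loss_grad(lc$high_loss, high_img, targets[[i]]$high, lc$delta)
      d_high <- pack_depth(d_high) / 2
      d_low <- lc$w_low *
        loss_grad(lc$low_loss, fwd$low, targets[[i]]$low, lc$delta) / 2

      bh <- seq_bwd(model$high, fwd$caches$high, d_high)
      bl <- seq_bwd(model$low, fwd$caches$low, d_low)
      bt <- seq_bwd(model$trunk, fwd$caches$trunk, bh$dx + bl$dx)
      g <- c(bt$grads, bl$grads, bh$grads)

      batch_grads <- add_grads(batch_grads, g)
      in_batch <- in_batch + 1L
      if (in_batch == config$batch_size || i == length(pixels)) {
        step <- opt_step(opt, params, scale_grads(batch_grads, 1 / in_batch))
        opt <- step$opt
        params <- step$params
        model$trunk <- assign_params(model$trunk, params)
        model$low <- assign_params(model$low, params)
        model$high <- assign_params(model$high, params)
        batch_grads <- list(); in_batch <- 0L
      }
    }
    history[epoch] <- epoch_loss / length(pixels)
    if (verbose)
      message(sprintf("epoch %3d  loss %.6f", epoch, history[epoch]))
  }
  list(model = model,
       history = data.frame(epoch = seq_len(config$epochs), loss = history))
}

#' Image-quality evaluation of the scale-adaptive network
#'
#' For every image, computes SSIM and RMSE between the unpacked
#' high-resolution reconstruction and the 448 x 448 bilinear target.
#'
#' @param model an `sa_model`.
#' @param images nonempty list of `fundus_image`s or pixel arrays.
#' @return a data frame `id,ssim,rmse`, one row per image.
#' @export
evaluate_sa <- function(model, images) {
  if (!length(images)) stop("images must be a nonempty list")
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    id <- if (inherits(img, "fundus_image")) img$id else paste0("img", i)
    pair <- sa_forward(model, img)
    target <- resize_bilinear(as_pixels(img), 448L, 448L)
    quality_report(unpack_depth(pair$high), target, id = id)
  })
  do.call(rbind, rows)
}

#' Export a per-epoch loss history
#'
#' @param history data frame `epoch,loss` as returned by [train_sa()].
#' @param path CSV output path.
#' @export
write_loss_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
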