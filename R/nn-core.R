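# Minimal CPU neural-network engine.
#
# Convolutional tensors are single images stored as H x W x C arrays; dense
# tensors are N x D matrices. Convolutions are evaluated as im2col patch
# matrices multiplied through BLAS. Every layer implements a forward pass
# (returning output + cache) and a backward pass (returning input gradient +
# parameter gradients), so any composed model can be trained end to end.
#
# Layers are plain lists with fields:
#   type   - dispatch string
#   name   - unique id used to address parameters
#   params - named list of trainable arrays
#   state  - named list of non-trainable arrays (batch-norm running stats)
# Composite layers ("residual", "branch_concat") hold sub-layer lists.

new_layer <- function(type, name, params = list(), state = list(), ...) {
  c(list(type = type, name = name, params = params, state = state), list(...))
}

# He/Glorot-style fan-based init; tanh nets use Glorot, ReLU nets He.
init_weights <- function(n_in, n_out, shape, gain = c("glorot", "he")) {
  gain <- match.arg(gain)
  sd <- if (gain == "he") sqrt(2 / n_in) else sqrt(2 / (n_in + n_out))
  array(stats::rnorm(prod(shape), 0, sd), shape)
}

layer_conv <- function(name, in_ch, out_ch, k = 3L, stride = 1L, pad = NULL,
                       init = "glorot") {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  W <- init_weights(k * k * in_ch, out_ch, c(k * k * in_ch, out_ch), init)
  new_layer("conv", name, params = list(W = W, b = numeric(out_ch)),
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), in_ch = in_ch, out_ch = out_ch)
}

layer_dense <- function(name, n_in, n_out, init = "he") {
  W <- init_weights(n_in, n_out, c(n_in, n_out), init)
  new_layer("dense", name, params = list(W = W, b = numeric(n_out)))
}

layer_bn <- function(name, n_ch, spatial = FALSE, momentum = 0.9, eps = 1e-5) {
  new_layer("bn", name,
            params = list(gamma = rep(1, n_ch), beta = numeric(n_ch)),
            state = list(mean = numeric(n_ch), var = rep(1, n_ch)),
            spatial = spatial, momentum = momentum, eps = eps)
}

layer_act <- function(name, fun = c("relu", "tanh")) {
  new_layer("act", name, fun = match.arg(fun))
}

layer_maxpool <- function(name, k = 2L, stride = k, pad = 0L) {
  new_layer("maxpool", name, k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

layer_avgpool <- function(name, k = 3L, stride = 1L, pad = 1L) {
  new_layer("avgpool", name, k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

layer_adaptive_avgpool <- function(name, out_h, out_w) {
  new_layer("adaptive_avgpool", name, out_h = as.integer(out_h),
            out_w = as.integer(out_w))
}

layer_global_avgpool <- function(name) new_layer("global_avgpool", name)

# depth-to-space, factor 2: H x W x 4C -> 2H x 2W x C.
# Channel block q (0-based) carries the sub-pixel at row offset q %% 2 and
# column offset q %/% 2 of each 2 x 2 output block.
layer_depth_to_space <- function(name) new_layer("depth_to_space", name)

layer_dropout <- function(name, rate = 0.5) {
  new_layer("dropout", name, rate = rate)
}

# out = relu(body(x) + shortcut(x)); empty shortcut list means identity
layer_residual <- function(name, body, shortcut = list()) {
  new_layer("residual", name, body = body, shortcut = shortcut)
}

# channel-wise concatenation of parallel branches
layer_branch_concat <- function(name, branches) {
  new_layer("branch_concat", name, branches = branches)
}

## ---- depth/space rearrangement -------------------------------------------

# channel block q (0-based, c fastest within block) carries the sub-pixel at
# row offset q %% 2, column offset q %/% 2 of each 2 x 2 output block
depth_to_space2 <- function(x) {
  d <- dim(x)
  if (d[3] %% 4L != 0L) stop("channel count must be divisible by 4")
  C <- d[3] %/% 4L
  x5 <- x
  dim(x5) <- c(d[1], d[2], C, 2L, 2L)
  out <- aperm(x5, c(4L, 1L, 5L, 2L, 3L))
  dim(out) <- c(2L * d[1], 2L * d[2], C)
  out
}

space_to_depth2 <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("spatial dimensions must be even")
  H <- d[1] %/% 2L; W <- d[2] %/% 2L; C <- d[3]
  x5 <- x
  dim(x5) <- c(2L, H, 2L, W, C)
  out <- aperm(x5, c(2L, 4L, 5L, 1L, 3L))
  dim(out) <- c(H, W, 4L * C)
  out
}

## ---- conv / pool kernels --------------------------------------------------

pad_array <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

# patch matrices above this element count are built in output-column chunks
# (forward only) so very large inputs never materialize a huge im2col matrix
conv_chunk_limit <- 3e7

conv_fwd <- function(layer, x, need_cache = TRUE) {
  d <- dim(x); k <- layer$k; s <- layer$stride; p <- layer$pad
  Ho <- (d[1] + 2L * p - k) %/% s + 1L
  Wo <- (d[2] + 2L * p - k) %/% s + 1L
  if (k == 1L && s == 1L && p == 0L) {
    cols <- matrix(x, d[1] * d[2], d[3])   # pointwise: plain matrix multiply
  } else if (!need_cache &&
             as.double(Ho) * Wo * k * k * d[3] > conv_chunk_limit) {
    n_out <- ncol(layer$params$W)
    out <- array(0, c(Ho, Wo, n_out))
    step <- max(1L, as.integer(conv_chunk_limit / (Ho * k * k * d[3])))
    for (oj0 in seq(0L, Wo - 1L, by = step)) {
      oj1 <- min(oj0 + step - 1L, Wo - 1L)
      blk <- cpp_im2col(x, k, s, p, oj0, oj1) %*% layer$params$W
      blk <- blk + rep(layer$params$b, each = nrow(blk))
      out[, (oj0 + 1L):(oj1 + 1L), ] <- array(blk, c(Ho, oj1 - oj0 + 1L, n_out))
    }
    return(list(out = out, cache = NULL))
  } else {
    cols <- cpp_im2col(x, k, s, p, 0L, Wo - 1L)
  }
  out_mat <- cols %*% layer$params$W
  out_mat <- out_mat + rep(layer$params$b, each = nrow(out_mat))
  out <- array(out_mat, c(Ho, Wo, ncol(out_mat)))
  cache <- if (need_cache) list(cols = cols, in_dim = d, Ho = Ho, Wo = Wo) else NULL
  list(out = out, cache = cache)
}

conv_bwd <- function(layer, cache, dout) {
  k <- layer$k; s <- layer$stride; p <- layer$pad
  d <- cache$in_dim; Ho <- cache$Ho; Wo <- cache$Wo
  dout_mat <- matrix(dout, Ho * Wo, dim(dout)[3])
  dW <- crossprod(cache$cols, dout_mat)
  db <- colSums(dout_mat)
  dcols <- tcrossprod(dout_mat, layer$params$W)
  dx <- if (k == 1L && s == 1L && p == 0L) array(dcols, d)
        else cpp_col2im(dcols, d[1], d[2], d[3], k, s, p)
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool_fwd <- function(layer, x, need_cache = TRUE) {
  res <- cpp_maxpool_fwd(x, layer$k, layer$stride, layer$pad)
  cache <- if (need_cache) list(argmax = res$argmax, in_dim = dim(x)) else NULL
  list(out = res$out, cache = cache)
}

maxpool_bwd <- function(layer, cache, dout) {
  d <- cache$in_dim
  # argmax is a 0-based linear index into the input array
  list(dx = cpp_maxpool_bwd(dout, cache$argmax, d[1], d[2], d[3]),
       grads = list())
}

avgpool_fwd <- function(layer, x, need_cache = TRUE) {
  out <- cpp_avgpool_fwd(x, layer$k, layer$stride, layer$pad)
  cache <- if (need_cache) list(in_dim = dim(x)) else NULL
  list(out = out, cache = cache)
}

avgpool_bwd <- function(layer, cache, dout) {
  d <- cache$in_dim
  list(dx = cpp_avgpool_bwd(dout, d[1], d[2], d[3],
                            layer$k, layer$stride, layer$pad),
       grads = list())
}

# interval-averaging matrix used by adaptive average pooling: output bin i
# averages input positions floor(i*n/m) .. ceil((i+1)*n/m) - 1
adaptive_pool_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out) - 1L) {
    s <- floor(i * n_in / n_out)
    e <- ceiling((i + 1) * n_in / n_out)
    M[i + 1L, (s + 1L):e] <- 1 / (e - s)
  }
  M
}

adaptive_avgpool_fwd <- function(layer, x, need_cache = TRUE) {
  d <- dim(x)
  Ph <- adaptive_pool_matrix(d[1], layer$out_h)
  Pw <- adaptive_pool_matrix(d[2], layer$out_w)
  out <- array(0, c(layer$out_h, layer$out_w, d[3]))
  for (c_ in seq_len(d[3])) out[, , c_] <- Ph %*% x[, , c_] %*% t(Pw)
  cache <- if (need_cache) list(Ph = Ph, Pw = Pw, in_dim = d) else NULL
  list(out = out, cache = cache)
}

adaptive_avgpool_bwd <- function(layer, cache, dout) {
  d <- cache$in_dim
  dx <- array(0, d)
  for (c_ in seq_len(d[3]))
    dx[, , c_] <- t(cache$Ph) %*% dout[, , c_] %*% cache$Pw
  list(dx = dx, grads = list())
}

bn_fwd <- function(layer, x, training, need_cache = TRUE) {
  eps <- layer$eps
  spatial <- isTRUE(layer$spatial)
  if (spatial) {
    d <- dim(x)
    xm <- matrix(x, d[1] * d[2], d[3])
  } else xm <- x
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = nrow(xm))
    v <- colMeans(xc * xc)
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
    xc <- xm - rep(mu, each = nrow(xm))
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = nrow(xm))
  out <- xhat * rep(layer$params$gamma, each = nrow(xm)) +
    rep(layer$params$beta, each = nrow(xm))
  if (spatial) out <- array(out, dim(x))
  cache <- if (need_cache)
    list(xhat = xhat, inv = inv, spatial = spatial,
         in_dim = if (spatial) dim(x) else dim(xm),
         batch_mean = if (training) mu else NULL,
         batch_var = if (training) v else NULL,
         training = training) else NULL
  list(out = out, cache = cache)
}

bn_bwd <- function(layer, cache, dout) {
  if (cache$spatial) {
    d <- cache$in_dim
    dom <- matrix(dout, d[1] * d[2], d[3])
  } else dom <- dout
  n <- nrow(dom)
  xhat <- cache$xhat
  dgamma <- colSums(dom * xhat)
  dbeta <- colSums(dom)
  dxhat <- dom * rep(layer$params$gamma, each = n)
  if (cache$training) {
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
             xhat * rep(colMeans(dxhat * xhat), each = n)) *
      rep(cache$inv, each = n)
  } else {
    dx <- dxhat * rep(cache$inv, each = n)
  }
  if (cache$spatial) dx <- array(dx, cache$in_dim)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- generic layer dispatch ----------------------------------------------

layer_fwd <- function(layer, x, training = FALSE, need_cache = TRUE) {
  switch(layer$type,
    conv = conv_fwd(layer, x, need_cache),
    dense = {
      out <- x %*% layer$params$W
      out <- out + rep(layer$params$b, each = nrow(out))
      list(out = out, cache = if (need_cache) list(x = x) else NULL)
    },
    bn = bn_fwd(layer, x, training, need_cache),
    act = {
      out <- if (layer$fun == "relu") pmax(x, 0) else tanh(x)
      list(out = out, cache = if (need_cache) list(out = out) else NULL)
    },
    maxpool = maxpool_fwd(layer, x, need_cache),
    avgpool = avgpool_fwd(layer, x, need_cache),
    adaptive_avgpool = adaptive_avgpool_fwd(layer, x, need_cache),
    global_avgpool = {
      d <- dim(x)
      out <- matrix(colMeans(matrix(x, d[1] * d[2], d[3])), 1L)
      list(out = out, cache = if (need_cache) list(in_dim = d) else NULL)
    },
    depth_to_space = list(out = depth_to_space2(x), cache = if (need_cache) list() else NULL),
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- (array(stats::runif(length(x)), dim(x) %||% length(x)) < keep) / keep
        list(out = x * mask, cache = if (need_cache) list(mask = mask) else NULL)
      } else list(out = x, cache = if (need_cache) list(mask = NULL) else NULL)
    },
    residual = {
      body_pass <- seq_fwd(layer$body, x, training, need_cache)
      short_pass <- seq_fwd(layer$shortcut, x, training, need_cache)
      pre <- body_pass$out + short_pass$out
      out <- pmax(pre, 0)
      list(out = out,
           cache = if (need_cache) list(body = body_pass$caches,
                                        shortcut = short_pass$caches,
                                        pre = pre) else NULL)
    },
    branch_concat = {
      outs <- vector("list", length(layer$branches))
      caches <- vector("list", length(layer$branches))
      for (i in seq_along(layer$branches)) {
        pass <- seq_fwd(layer$branches[[i]], x, training, need_cache)
        outs[[i]] <- pass$out
        caches[[i]] <- pass$caches
      }
      chans <- vapply(outs, function(o) dim(o)[3], integer(1))
      d1 <- dim(outs[[1]])
      out <- array(0, c(d1[1], d1[2], sum(chans)))
      at <- 0L
      for (i in seq_along(outs)) {
        out[, , at + seq_len(chans[i])] <- outs[[i]]
        at <- at + chans[i]
      }
      list(out = out,
           cache = if (need_cache) list(branches = caches, chans = chans) else NULL)
    },
    stop("unknown layer type: ", layer$type))
}

layer_bwd <- function(layer, cache, dout) {
  switch(layer$type,
    conv = conv_bwd(layer, cache, dout),
    dense = list(dx = tcrossprod(dout, layer$params$W),
                 grads = list(W = crossprod(cache$x, dout), b = colSums(dout))),
    bn = bn_bwd(layer, cache, dout),
    act = {
      dx <- if (layer$fun == "relu") dout * (cache$out > 0)
            else dout * (1 - cache$out^2)
      list(dx = dx, grads = list())
    },
    maxpool = maxpool_bwd(layer, cache, dout),
    avgpool = avgpool_bwd(layer, cache, dout),
    adaptive_avgpool = adaptive_avgpool_bwd(layer, cache, dout),
    global_avgpool = {
      d <- cache$in_dim
      dx <- array(rep(dout / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx, grads = list())
    },
    depth_to_space = list(dx = space_to_depth2(dout), grads = list()),
    dropout = {
      dx <- if (is.null(cache$mask)) dout else dout * cache$mask
      list(dx = dx, grads = list())
    },
    residual = {
      dpre <- dout * (cache$pre > 0)
      body_b <- seq_bwd(layer$body, cache$body, dpre)
      short_b <- seq_bwd(layer$shortcut, cache$shortcut, dpre)
      list(dx = body_b$dx + short_b$dx,
           grads = c(body_b$grads, short_b$grads))
    },
    branch_concat = {
      at <- 0L
      dx <- NULL
      grads <- list()
      for (i in seq_along(layer$branches)) {
        d_i <- dout[, , at + seq_len(cache$chans[i]), drop = FALSE]
        at <- at + cache$chans[i]
        b <- seq_bwd(layer$branches[[i]], cache$branches[[i]], d_i)
        dx <- if (is.null(dx)) b$dx else dx + b$dx
        grads <- c(grads, b$grads)
      }
      list(dx = dx, grads = grads)
    },
    stop("unknown layer type: ", layer$type))
}

## ---- sequences ------------------------------------------------------------

seq_fwd <- function(layers, x, training = FALSE, need_cache = TRUE,
                    record = NULL) {
  caches <- if (need_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    pass <- layer_fwd(layers[[i]], x, training, need_cache)
    x <- pass$out
    if (need_cache) caches[[i]] <- pass$cache
    if (!is.null(record)) {
      record$acts[[layers[[i]]$name]] <- x
      record$types[[layers[[i]]$name]] <- layers[[i]]$type
    }
  }
  list(out = x, caches = caches)
}

# backward through a layer sequence; grads is a flat named list keyed by
# "<layer name>.<param name>" (grads of composite sub-layers are already flat)
seq_bwd <- function(layers, caches, dout) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    b <- layer_bwd(layers[[i]], caches[[i]], dout)
    dout <- b$dx
    if (length(b$grads)) {
      if (layers[[i]]$type %in% c("residual", "branch_concat")) {
        grads <- c(grads, b$grads)
      } else {
        names(b$grads) <- paste0(layers[[i]]$name, ".", names(b$grads))
        grads <- c(grads, b$grads)
      }
    }
  }
  list(dx = dout, grads = grads)
}

## ---- parameter plumbing ----------------------------------------------------

collect_params <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (ly$type == "residual") {
      out <- c(out, collect_params(ly$body), collect_params(ly$shortcut))
    } else if (ly$type == "branch_concat") {
      for (br in ly$branches) out <- c(out, collect_params(br))
    } else if (length(ly$params)) {
      p <- ly$params
      names(p) <- paste0(ly$name, ".", names(p))
      out <- c(out, p)
    }
  }
  out
}

assign_params <- function(layers, flat) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "residual") {
      layers[[i]]$body <- assign_params(ly$body, flat)
      layers[[i]]$shortcut <- assign_params(ly$shortcut, flat)
    } else if (ly$type == "branch_concat") {
      for (j in seq_along(ly$branches))
        layers[[i]]$branches[[j]] <- assign_params(ly$branches[[j]], flat)
    } else if (length(ly$params)) {
      for (pn in names(ly$params)) {
        key <- paste0(ly$name, ".", pn)
        if (!is.null(flat[[key]])) layers[[i]]$params[[pn]] <- flat[[key]]
      }
    }
  }
  layers
}

count_params <- function(layers) {
  trainable <- 0; stats <- 0
  for (ly in layers) {
    if (ly$type == "residual") {
      sub <- count_params(c(ly$body, ly$shortcut))
      trainable <- trainable + sub["trainable"]; stats <- stats + sub["stats"]
    } else if (ly$type == "branch_concat") {
      for (br in ly$branches) {
        sub <- count_params(br)
        trainable <- trainable + sub["trainable"]; stats <- stats + sub["stats"]
      }
    } else {
      trainable <- trainable + sum(vapply(ly$params, length, integer(1)))
      stats <- stats + sum(vapply(ly$state, length, integer(1)))
    }
  }
  c(trainable = unname(trainable), stats = unname(stats))
}

# update batch-norm running statistics in place after a training pass
update_bn_state <- function(layers, caches) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "bn" && !is.null(caches[[i]]$batch_mean)) {
      m <- ly$momentum
      layers[[i]]$state$mean <- m * ly$state$mean + (1 - m) * caches[[i]]$batch_mean
      layers[[i]]$state$var <- m * ly$state$var + (1 - m) * caches[[i]]$batch_var
    } else if (ly$type == "residual") {
      layers[[i]]$body <- update_bn_state(ly$body, caches[[i]]$body)
      layers[[i]]$shortcut <- update_bn_state(ly$shortcut, caches[[i]]$shortcut)
    } else if (ly$type == "branch_concat") {
      for (j in seq_along(ly$branches))
        layers[[i]]$branches[[j]] <-
          update_bn_state(ly$branches[[j]], caches[[i]]$branches[[j]])
    }
  }
  layers
}

## ---- optimizers ------------------------------------------------------------

opt_init <- function(kind = c("adam", "sgd"), lr, momentum = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, momentum = momentum,
       beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, slots = list())
}

# grads may cover a subset of params (e.g. a frozen backbone contributes none)
opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (key in names(grads)) {
    g <- grads[[key]]
    p <- params[[key]]
    if (is.null(p)) next
    if (opt$kind == "sgd") {
      if (opt$momentum > 0) {
        v <- opt$slots[[key]] %||% array(0, dim(p) %||% length(p))
        v <- opt$momentum * v + g
        opt$slots[[key]] <- v
        params[[key]] <- p - opt$lr * v
      } else {
        params[[key]] <- p - opt$lr * g
      }
    } else {
      slot <- opt$slots[[key]] %||%
        list(m = array(0, dim(p) %||% length(p)),
             v = array(0, dim(p) %||% length(p)))
      slot$m <- opt$beta1 * slot$m + (1 - opt$beta1) * g
      slot$v <- opt$beta2 * slot$v + (1 - opt$beta2) * g^2
      opt$slots[[key]] <- slot
      mhat <- slot$m / (1 - opt$beta1^opt$t)
      vhat <- slot$v / (1 - opt$beta2^opt$t)
      params[[key]] <- p - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  list(opt = opt, params = params)
}

# accumulate two flat gradient lists
add_grads <- function(a, b) {
  if (!length(a)) return(b)
  for (key in names(b)) a[[key]] <- if (is.null(a[[key]])) b[[key]] else a[[key]] + b[[key]]
  a
}

scale_grads <- function(g, s) {
  for (key in names(g)) g[[key]] <- g[[key]] * s
  g
}

# softmax with row-wise max shift; input N x K logits
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# categorical cross-entropy over an N x K one-hot target; returns the loss
# and the gradient w.r.t. the logits
softmax_xent <- function(logits, one_hot) {
  p <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(rowSums(one_hot * log(p + eps)))
  list(loss = loss, probs = p, dlogits = (p - one_hot) / nrow(logits))
}
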