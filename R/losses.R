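#' Reconstruction loss primitives
#'
#' The four elementwise regression losses used by the scale-adaptive
#' auto-encoder, each reduced by the mean over all elements:
#' \describe{
#'   \item{MSE}{mean of squared residuals \eqn{r^2}.}
#'   \item{MSLE}{mean of \eqn{(\log(1+t) - \log(1+p))^2}; inputs must be
#'     nonnegative.}
#'   \item{Pseudo-Huber}{mean of \eqn{\delta^2(\sqrt{1+(r/\delta)^2}-1)}:
#'     quadratic for small residuals (\eqn{\approx r^2/2} when
#'     \eqn{|r| \ll \delta}), linear for large ones.}
#'   \item{log-cosh}{mean of \eqn{\log\cosh r}, computed overflow-safely as
#'     \eqn{|r| + \log(1+e^{-2|r|}) - \log 2} so residuals of any size are
#'     handled.}
#' }
#' All four are nonnegative and zero exactly when `pred == target` (within
#' the valid domain).
#'
#' @param pred,target numeric arrays of identical shape with finite values.
#' @param delta Pseudo-Huber scale parameter, positive (default 1).
#' @return a single nonnegative number.
#' @examples
#' loss_mse(c(1, 1), c(0, 0))        # 1
#' loss_pseudo_huber(3, 0, delta = 1)  # sqrt(10) - 1
#' loss_log_cosh(1, 0)               # log(cosh(1))
#' @export
loss_mse <- function(pred, target) {
  check_same_shape(pred, target)
  mean((pred - target)^2)
}

#' @rdname loss_mse
#' @export
loss_msle <- function(pred, target) {
  check_same_shape(pred, target)
  if (any(pred < 0) || any(target < 0))
    stop("MSLE requires nonnegative inputs")
  mean((log1p(target) - log1p(pred))^2)
}

#' @rdname loss_mse
#' @export
loss_pseudo_huber <- function(pred, target, delta = 1) {
  check_same_shape(pred, target)
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("delta must be a positive scalar")
  r <- pred - target
  mean(delta^2 * (sqrt(1 + (r / delta)^2) - 1))
}

#' @rdname loss_mse
#' @export
loss_log_cosh <- function(pred, target) {
  check_same_shape(pred, target)
  r <- abs(pred - target)
  mean(r + log1p(exp(-2 * r)) - log(2))
}

# gradients of the mean-reduced losses w.r.t. pred (same shape as pred)
loss_grad <- function(name, pred, target, delta = 1) {
  n <- length(pred)
  r <- pred - target
  switch(name,
    MSE = 2 * r / n,
    MSLE = -2 * (log1p(target) - log1p(pred)) / (1 + pred) / n,
    PSEUDO_HUBER = r / sqrt(1 + (r / delta)^2) / n,
    LOG_COSH = tanh(r) / n,
    stop("unknown loss: ", name))
}

loss_fn <- function(name) {
  switch(name,
    MSE = loss_mse,
    MSLE = loss_msle,
    PSEUDO_HUBER = loss_pseudo_huber,
    LOG_COSH = loss_log_cosh,
    stop("unknown loss: ", name))
}

#' Dual-resolution loss configuration
#'
#' The scale-adaptive auto-encoder is trained under a weighted sum of one
#' loss on the unpacked high-resolution reconstruction (weight `w_high`,
#' default 0.25) and one loss on the low-resolution 224 x 224 output (weight
#' `w_low`, default 0.075).
#'
#' @param high_loss,low_loss loss names from `MSE`, `MSLE`, `PSEUDO_HUBER`,
#'   `LOG_COSH`.
#' @param w_high,w_low positive branch weights.
#' @param delta Pseudo-Huber scale (used when either branch selects
#'   `PSEUDO_HUBER`).
#' @return a `sa_loss_config` list.
#' @export
sa_loss_config <- function(high_loss = "PSEUDO_HUBER", low_loss = "LOG_COSH",
                           w_high = 0.25, w_low = 0.075, delta = 1) {
  valid <- c("MSE", "MSLE", "PSEUDO_HUBER", "LOG_COSH")
  high_loss <- toupper(high_loss); low_loss <- toupper(low_loss)
  if (!high_loss %in% valid) stop("unknown high_loss: ", high_loss)
  if (!low_loss %in% valid) stop("unknown low_loss: ", low_loss)
  if (w_high <= 0) stop("w_high must be positive")
  if (w_low <= 0) stop("w_low must be positive")
  if (delta <= 0) stop("delta must be positive")
  structure(list(high_loss = high_loss, low_loss = low_loss,
                 w_high = w_high, w_low = w_low, delta = delta),
            class = "sa_loss_config")
}

eval_branch_loss <- function(name, pred, target, delta) {
  if (name == "PSEUDO_HUBER") loss_pseudo_huber(pred, target, delta)
  else loss_fn(name)(pred, target)
}

#' Combined dual-resolution reconstruction loss
#'
#' `w_high * L_high(unpack(pair$high), target_high) +
#'  w_low * L_low(pair$low, target_low)` for a [scaled_pair()] emitted by the
#' scale-adaptive network.
#'
#' @param pair a `scaled_pair` (fields `low`: 224 x 224 x 3, `high`:
#'   224 x 224 x 12).
#' @param target_low 224 x 224 x 3 target (bilinear resample of the input).
#' @param target_high 448 x 448 x 3 target.
#' @param config an [sa_loss_config()].
#' @return a single nonnegative number.
#' @export
combined_sa_loss <- function(pair, target_low, target_high,
                             config = sa_loss_config()) {
  stopifnot(inherits(config, "sa_loss_config"))
  high <- unpack_depth(pair$high)
  check_same_shape(high, target_high)
  check_same_shape(pair$low, target_low)
  config$w_high * eval_branch_loss(config$high_loss, high, target_high, config$delta) +
    config$w_low * eval_branch_loss(config$low_loss, pair$low, target_low, config$delta)
}
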