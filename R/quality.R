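#' Structural similarity index (SSIM)
#'
#' Mean local SSIM between two images with values in `[0, 1]` (declared data
#' range 1.0), using the standard Gaussian window convention: an 11 x 11
#' window with sigma 1.5, stability constants `C1 = (0.01)^2` and
#' `C2 = (0.03)^2`, population (window-weighted) variances, and the mean taken
#' over window positions whose support lies fully inside the image. For
#' 3-channel input the per-channel SSIM values are averaged.
#'
#' SSIM is 1 exactly for identical images, symmetric in its arguments, and
#' bounded above by 1 (it can be negative for anti-correlated structure).
#'
#' @param a,b images (`H x W` or `H x W x C` arrays, or `fundus_image`s) of
#'   identical shape with values in `[0, 1]`.
#' @param win_size odd window size in pixels (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param k1,k2 stability constants (defaults 0.01, 0.03).
#' @return a single number `<= 1`.
#' @examples
#' x <- array(runif(30 * 30 * 3), c(30, 30, 3))
#' ssim_index(x, x)  # 1
#' @export
ssim_index <- function(a, b, win_size = 11L, sigma = 1.5,
                       k1 = 0.01, k2 = 0.03) {
  a <- as_pixels(a); b <- as_pixels(b)
  check_same_shape(a, b)
  if (win_size %% 2L != 1L) stop("win_size must be odd")
  d <- dim(a) %||% c(length(a), 1L)
  if (length(d) == 2L) {
    a <- array(a, c(d, 1L)); b <- array(b, c(d, 1L)); d <- dim(a)
  }
  if (d[1] < win_size || d[2] < win_size)
    stop("window larger than image")
  pad <- (win_size - 1L) %/% 2L
  g <- exp(-0.5 * ((-pad:pad) / sigma)^2)
  g <- g / sum(g)
  Fh <- band_filter_matrix(d[1], g)
  Fw <- band_filter_matrix(d[2], g)
  c1 <- k1^2; c2 <- k2^2
  keep_r <- (pad + 1L):(d[1] - pad)
  keep_c <- (pad + 1L):(d[2] - pad)
  vals <- numeric(d[3])
  for (ch in seq_len(d[3])) {
    x <- a[, , ch]; y <- b[, , ch]
    smooth <- function(z) Fh %*% z %*% t(Fw)
    ux <- smooth(x); uy <- smooth(y)
    vx <- smooth(x * x) - ux * ux
    vy <- smooth(y * y) - uy * uy
    vxy <- smooth(x * y) - ux * uy
    s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
         ((ux * ux + uy * uy + c1) * (vx + vy + c2))
    vals[ch] <- mean(s[keep_r, keep_c])
  }
  mean(vals)
}

# banded 1-D filtering matrix with zero padding at the borders; border rows
# are never used because the SSIM mean is taken over fully supported windows
band_filter_matrix <- function(n, g) {
  pad <- (length(g) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (k in -pad:pad) {
    idx <- seq_len(n)
    src <- idx + k
    ok <- src >= 1L & src <= n
    M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + g[k + pad + 1L]
  }
  M
}

#' Root mean square error between two images
#'
#' `sqrt(loss_mse(a, b))`.
#'
#' @inheritParams ssim_index
#' @return a single nonnegative number.
#' @export
rmse <- function(a, b) {
  a <- as_pixels(a); b <- as_pixels(b)
  sqrt(loss_mse(a, b))
}

#' @rdname ssim_index
#' @param id image identifier for the report row.
#' @return `quality_report()` returns a one-row data frame `id,ssim,rmse`.
#' @export
quality_report <- function(a, b, id = "img") {
  data.frame(id = id, ssim = ssim_index(a, b), rmse = rmse(a, b))
}
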