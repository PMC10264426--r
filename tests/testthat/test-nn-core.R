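# Backpropagation correctness: analytic gradients of each layer type are
# checked against central finite differences through a composed network.

numgrad_check <- function(layers, x, n_probe = 4, tol = 1e-5) {
  loss_of <- function(ls, xx)
    sum(fundusSA:::seq_fwd(ls, xx, need_cache = FALSE)$out^2) / 2
  pass <- fundusSA:::seq_fwd(layers, x, need_cache = TRUE)
  bwd <- fundusSA:::seq_bwd(layers, pass$caches, pass$out)
  params <- fundusSA:::collect_params(layers)
  eps <- 1e-5
  for (key in names(bwd$grads)) {
    for (probe in seq_len(min(n_probe, length(params[[key]])))) {
      i <- sample.int(length(params[[key]]), 1)
      up <- params; up[[key]][i] <- up[[key]][i] + eps
      dn <- params; dn[[key]][i] <- dn[[key]][i] - eps
      num <- (loss_of(fundusSA:::assign_params(layers, up), x) -
                loss_of(fundusSA:::assign_params(layers, dn), x)) / (2 * eps)
      expect_equal(bwd$grads[[key]][i], num, tolerance = tol,
                   label = paste("grad", key))
    }
  }
  i <- sample.int(length(x), 1)
  up <- x; up[i] <- up[i] + eps
  dn <- x; dn[i] <- dn[i] - eps
  num <- (loss_of(layers, up) - loss_of(layers, dn)) / (2 * eps)
  expect_equal(bwd$dx[i], num, tolerance = tol, label = "input gradient")
}

test_that("conv/pool/activation gradients match finite differences", {
  set.seed(11)
  layers <- list(
    fundusSA:::layer_conv("c1", 2L, 3L, k = 3L),
    fundusSA:::layer_act("a1", "tanh"),
    fundusSA:::layer_maxpool("p1", 2L, 2L),
    fundusSA:::layer_conv("c2", 3L, 5L, k = 3L, stride = 2L, pad = 1L),
    fundusSA:::layer_act("a2", "relu"),
    fundusSA:::layer_adaptive_avgpool("ap", 2L, 2L),
    fundusSA:::layer_conv("c3", 5L, 4L, k = 1L, pad = 0L),
    fundusSA:::layer_depth_to_space("ds")
  )
  x <- array(rnorm(10 * 12 * 2), c(10, 12, 2))
  numgrad_check(layers, x)
})

test_that("residual blocks and spatial batch norm backpropagate correctly", {
  set.seed(12)
  layers <- list(
    fundusSA:::bb_basic_block("rb", 2L, 4L, stride = 2L),
    fundusSA:::layer_avgpool("avg", 3L, 1L, 1L)
  )
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  # batch-norm uses batch statistics in training mode, so check there
  loss_of <- function(ls, xx)
    sum(fundusSA:::seq_fwd(ls, xx, training = TRUE, need_cache = FALSE)$out^2) / 2
  pass <- fundusSA:::seq_fwd(layers, x, training = TRUE, need_cache = TRUE)
  bwd <- fundusSA:::seq_bwd(layers, pass$caches, pass$out)
  params <- fundusSA:::collect_params(layers)
  eps <- 1e-5
  for (key in names(bwd$grads)[1:6]) {
    i <- sample.int(length(params[[key]]), 1)
    up <- params; up[[key]][i] <- up[[key]][i] + eps
    dn <- params; dn[[key]][i] <- dn[[key]][i] - eps
    num <- (loss_of(fundusSA:::assign_params(layers, up), x) -
              loss_of(fundusSA:::assign_params(layers, dn), x)) / (2 * eps)
    expect_equal(bwd$grads[[key]][i], num, tolerance = 1e-4,
                 label = paste("grad", key))
  }
})

test_that("dense head layers (dense, bn, dropout eval mode) backpropagate", {
  set.seed(13)
  layers <- list(
    fundusSA:::layer_dense("d1", 6L, 5L),
    fundusSA:::layer_act("r1", "relu"),
    fundusSA:::layer_bn("b1", 5L, spatial = FALSE),
    fundusSA:::layer_dense("d2", 5L, 3L)
  )
  x <- matrix(rnorm(4 * 6), 4, 6)
  loss_of <- function(ls, xx)
    sum(fundusSA:::seq_fwd(ls, xx, training = TRUE, need_cache = FALSE)$out^2) / 2
  pass <- fundusSA:::seq_fwd(layers, x, training = TRUE, need_cache = TRUE)
  bwd <- fundusSA:::seq_bwd(layers, pass$caches, pass$out)
  params <- fundusSA:::collect_params(layers)
  eps <- 1e-5
  for (key in names(bwd$grads)) {
    i <- sample.int(length(params[[key]]), 1)
    up <- params; up[[key]][i] <- up[[key]][i] + eps
    dn <- params; dn[[key]][i] <- dn[[key]][i] - eps
    num <- (loss_of(fundusSA:::assign_params(layers, up), x) -
              loss_of(fundusSA:::assign_params(layers, dn), x)) / (2 * eps)
    expect_equal(bwd$grads[[key]][i], num, tolerance = 1e-4)
  }
})

test_that("softmax cross-entropy produces normalized probabilities and exact gradient", {
  set.seed(14)
  logits <- matrix(rnorm(12), 3, 4)
  y <- fundusSA:::softmax_xent(logits, grade_one_hot(c("NORMAL", "GA", "WET")))
  expect_equal(rowSums(y$probs), rep(1, 3), tolerance = 1e-12)
  eps <- 1e-6
  i <- 7
  up <- logits; up[i] <- up[i] + eps
  dn <- logits; dn[i] <- dn[i] - eps
  oh <- grade_one_hot(c("NORMAL", "GA", "WET"))
  num <- (fundusSA:::softmax_xent(up, oh)$loss -
            fundusSA:::softmax_xent(dn, oh)$loss) / (2 * eps)
  expect_equal(y$dlogits[i], num, tolerance = 1e-6)
})

test_that("adaptive average pooling averages exact bins and is size-agnostic", {
  x <- array(1, c(13, 7, 2))
  out <- fundusSA:::adaptive_avgpool_fwd(
    fundusSA:::layer_adaptive_avgpool("ap", 4L, 4L), x)$out
  expect_identical(dim(out), c(4L, 4L, 2L))
  expect_equal(as.vector(out), rep(1, 32))
  # divisible case reduces to exact block means
  y <- array(seq_len(4 * 4), c(4, 4, 1))
  out2 <- fundusSA:::adaptive_avgpool_fwd(
    fundusSA:::layer_adaptive_avgpool("ap", 2L, 2L), y)$out
  expect_equal(out2[1, 1, 1], mean(y[1:2, 1:2, 1]))
  expect_equal(out2[2, 2, 1], mean(y[3:4, 3:4, 1]))
})

test_that("optimizers are exact on a quadratic step", {
  params <- list(w = c(1, -2))
  grads <- list(w = c(0.5, -0.5))
  sgd <- fundusSA:::opt_init("sgd", lr = 0.1)
  st <- fundusSA:::opt_step(sgd, params, grads)
  expect_equal(st$params$w, c(1, -2) - 0.1 * c(0.5, -0.5))
  adam <- fundusSA:::opt_init("adam", lr = 0.1)
  st2 <- fundusSA:::opt_step(adam, params, grads)
  # first Adam step moves each coordinate by lr * sign(g)
  expect_equal(as.vector(st2$params$w), c(1, -2) - 0.1 * sign(c(0.5, -0.5)),
               tolerance = 1e-6)
})
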