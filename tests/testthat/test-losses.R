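# scalar-loop oracle evaluating each loss definition elementwise,
# independent of the vectorized implementations
oracle_loss <- function(name, pred, target, delta = 1) {
  vals <- mapply(function(p, t) {
    r <- p - t
    switch(name,
           MSE = r^2,
           MSLE = (log(1 + t) - log(1 + p))^2,
           PSEUDO_HUBER = delta^2 * (sqrt(1 + (r / delta)^2) - 1),
           LOG_COSH = log(cosh(r)))
  }, as.vector(pred), as.vector(target))
  mean(vals)
}

test_that("losses vanish at pred == target and match unit-residual values", {
  x <- runif(10)
  expect_identical(loss_mse(x, x), 0)
  expect_identical(loss_msle(x, x), 0)
  expect_identical(loss_pseudo_huber(x, x), 0)
  expect_equal(loss_log_cosh(x, x), 0)
  expect_equal(loss_mse(c(1, 1), c(0, 0)), 1)
})

test_that("losses match closed forms", {
  # msle: pred 0 vs target e - 1 gives exactly 1
  expect_equal(loss_msle(0, exp(1) - 1), 1, tolerance = 1e-12)
  # pseudo-huber single residual r = 3, delta = 1: sqrt(10) - 1
  expect_equal(loss_pseudo_huber(3, 0, delta = 1), sqrt(10) - 1,
               tolerance = 1e-12)
  # log-cosh at r = 1
  expect_equal(loss_log_cosh(1, 0), log(cosh(1)), tolerance = 1e-12)
  expect_equal(loss_log_cosh(1, 0), 0.4337808304830271, tolerance = 1e-9)
})

test_that("losses match a scalar-loop oracle on random arrays", {
  set.seed(42)
  pred <- array(runif(60), c(5, 4, 3))
  target <- array(runif(60), c(5, 4, 3))
  expect_equal(loss_mse(pred, target), oracle_loss("MSE", pred, target))
  expect_equal(loss_msle(pred, target), oracle_loss("MSLE", pred, target))
  for (delta in c(0.5, 1, 2))
    expect_equal(loss_pseudo_huber(pred, target, delta),
                 oracle_loss("PSEUDO_HUBER", pred, target, delta))
  expect_equal(loss_log_cosh(pred, target),
               oracle_loss("LOG_COSH", pred, target))
  expect_equal(loss_mse(c(0.5, 0.1, 0.9), c(0.2, 0.4, 0.3)),
               mean(c(0.3, -0.3, 0.6)^2))
})

test_that("pseudo-huber approaches r^2/2 for small residuals and log-cosh is overflow-safe", {
  r <- seq(-0.1, 0.1, by = 0.01)
  expect_equal(loss_pseudo_huber(r, 0 * r, delta = 1), mean(r^2 / 2),
               tolerance = 0.01)
  # asymptote |r| - log 2 without overflow
  expect_equal(loss_log_cosh(50, 0), 50 - log(2), tolerance = 1e-9)
  expect_equal(loss_log_cosh(500, 0), 500 - log(2), tolerance = 1e-9)
})

test_that("loss domain and shape violations raise errors", {
  expect_error(loss_mse(1:3, 1:4), "shape")
  expect_error(loss_msle(-0.1, 0.2), "nonnegative")
  expect_error(loss_pseudo_huber(1, 0, delta = 0), "positive")
  expect_error(sa_loss_config(w_low = -1), "w_low")
})

test_that("pseudo-huber is monotone in |r| and log-cosh is even", {
  rs <- seq(0, 5, by = 0.25)
  ph <- vapply(rs, function(r) loss_pseudo_huber(r, 0), numeric(1))
  expect_true(all(diff(ph) >= 0))
  for (r in c(0.3, 1.7, 4))
    expect_equal(loss_log_cosh(r, 0), loss_log_cosh(-r, 0))
})

test_that("analytic loss gradients match finite differences", {
  set.seed(7)
  pred <- runif(20, 0.05, 0.95)
  target <- runif(20, 0.05, 0.95)
  eps <- 1e-6
  for (name in c("MSE", "MSLE", "PSEUDO_HUBER", "LOG_COSH")) {
    g <- fundusSA:::loss_grad(name, pred, target, delta = 0.7)
    i <- 11
    up <- pred; up[i] <- up[i] + eps
    dn <- pred; dn[i] <- dn[i] - eps
    f <- function(p) switch(name,
      MSE = loss_mse(p, target), MSLE = loss_msle(p, target),
      PSEUDO_HUBER = loss_pseudo_huber(p, target, 0.7),
      LOG_COSH = loss_log_cosh(p, target))
    expect_equal(g[i], (f(up) - f(dn)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("combined loss weights the two branches linearly", {
  low <- array(runif(224 * 224 * 3), c(224, 224, 3))
  high448 <- array(runif(448 * 448 * 3), c(448, 448, 3))
  pair <- scaled_pair(low, pack_depth(high448))

  # identical outputs and targets: zero
  expect_equal(combined_sa_loss(pair, low, high448), 0)

  # zero low-branch error with unit-MSE high branch and default weights: 0.25
  ones <- array(1, c(448, 448, 3))
  zeros <- array(0, c(448, 448, 3))
  pair2 <- scaled_pair(low, pack_depth(ones))
  cfg <- sa_loss_config(high_loss = "MSE", low_loss = "MSE")
  expect_equal(combined_sa_loss(pair2, low, zeros, cfg), 0.25)

  # random pair: equals the weighted sum of two independent loss calls
  t_low <- array(runif(224 * 224 * 3), c(224, 224, 3))
  t_high <- array(runif(448 * 448 * 3), c(448, 448, 3))
  cfg2 <- sa_loss_config("PSEUDO_HUBER", "LOG_COSH")
  expect_equal(combined_sa_loss(pair, t_low, t_high, cfg2),
               0.25 * loss_pseudo_huber(high448, t_high, 1) +
                 0.075 * loss_log_cosh(low, t_low))
  # linearity in each branch weight
  cfg3 <- sa_loss_config("PSEUDO_HUBER", "LOG_COSH", w_high = 0.5, w_low = 0.15)
  expect_equal(combined_sa_loss(pair, t_low, t_high, cfg3),
               2 * combined_sa_loss(pair, t_low, t_high, cfg2))
})
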