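test_that("network construction matches the parameter-count formula and is seeded", {
  expect_equal(n_parameters(build_network(5, 40, 45)), 8441)   # 1840 + 4*1640 + 41
  expect_equal(n_parameters(build_network(1, 3, 45)), 142)     # 138 + 4
  expect_equal(n_parameters(build_network(10, 20, 45)),
               (45 * 20 + 20) + 9 * (20 * 20 + 20) + 21)
  a <- build_network(2, 4, 3, seed = 11)
  b <- build_network(2, 4, 3, seed = 11)
  expect_identical(a$W, b$W)
  expect_identical(a$b, b$b)
  expect_false(identical(a$W, build_network(2, 4, 3, seed = 12)$W))
  expect_true(all(abs(unlist(a$W)) <= 0.5))
})

test_that("the optimizer's trajectory matches an independent normal-equations oracle", {
  # 2-parameter exponential-decay least squares
  set.seed(42)
  x <- seq(0, 2, length.out = 15)
  y <- 2.5 * exp(-1.3 * x) + rnorm(15, 0, 0.05)
  rfun <- function(th) y - th[1] * exp(th[2] * x)
  jfun <- function(th) cbind(exp(th[2] * x), th[1] * x * exp(th[2] * x))
  rj <- function(th) list(residuals = rfun(th), jacobian = jfun(th))
  th0 <- c(1, -0.5)
  for (n_epochs in c(1, 2, 5, 10)) {
    got <- lm_optimize(rj, th0, training_config(max_epochs = n_epochs, min_gradient = 0))
    want <- oracle_lm(rfun, jfun, th0, n_epochs)
    expect_equal(got$theta, want, tolerance = 1e-8)
  }
})

test_that("a linearly representable target is fit to numerical exactness", {
  set.seed(9)
  x <- matrix(runif(120, -2, 2), ncol = 1)
  y <- 3.2 * x[, 1] - 1.7
  net <- build_network(1, 3, 1, seed = 4, activation = "linear")
  fit <- lm_train(net, x, y, training_config(max_epochs = 50, seed = 2))
  expect_lt(fit$train_mse, 1e-10)
})

test_that("training error is non-increasing over accepted epochs", {
  set.seed(10)
  X <- matrix(runif(450, -1, 1), ncol = 3)
  y <- sin(2 * X[, 1]) + X[, 2] * X[, 3]
  fit <- lm_train(build_network(1, 8, 3, seed = 5), X, y,
                  training_config(max_epochs = 40, seed = 2))
  expect_true(all(diff(fit$trace$train_mse) <= 1e-12))
})

test_that("a stalled validation criterion stops training after exactly six failures", {
  set.seed(12)
  X <- matrix(runif(300, -1, 1), ncol = 3)
  y <- sin(2 * X[, 1]) + 0.5 * X[, 2]
  net <- build_network(1, 6, 3, seed = 3)
  rj <- function(theta) {
    cand <- crcrisk:::unpack_params(net, theta)
    out <- crcrisk:::network_jacobian(cand, X)
    list(residuals = y - out$yhat, jacobian = out$J)
  }
  # constant validation MSE: improvement only on the first epoch, then six
  # consecutive failures
  fit <- lm_optimize(rj, crcrisk:::pack_params(net),
                     training_config(max_epochs = 200, min_gradient = 0),
                     validation_mse = function(theta) 1)
  expect_equal(fit$stop_reason, "validation_failures")
  expect_equal(fit$epochs, 7)
})

test_that("an unsolvable step at maximal damping stops with a diagnostic", {
  rj <- function(theta) list(residuals = c(1, 1), jacobian = matrix(0, 2, 2))
  fit <- lm_optimize(rj, c(0, 0), training_config(max_epochs = 10, min_gradient = 0))
  expect_equal(fit$stop_reason, "mu_max")
})

test_that("the reported gradient is the Euclidean norm of J'e, confirmed by finite differences", {
  set.seed(14)
  X <- matrix(runif(60, -1, 1), ncol = 3)
  y <- X[, 1]^2 - X[, 3]
  net <- build_network(2, 4, 3, seed = 8)
  theta <- crcrisk:::pack_params(net)
  out <- crcrisk:::network_jacobian(net, X)
  e <- y - out$yhat
  grad <- as.numeric(crossprod(out$J, e))
  # d/dtheta of 0.5 * sum(e^2) equals -J'e; check by central differences
  f <- function(th) {
    yh <- crcrisk:::forward_pass(crcrisk:::unpack_params(net, th), X)$yhat
    0.5 * sum((y - yh)^2)
  }
  idx <- sample(length(theta), 12)
  for (i in idx) {
    h <- 1e-6 * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    fd <- (f(tp) - f(tm)) / (2 * h)
    expect_equal(fd, -grad[i], tolerance = 1e-4 * max(1, abs(grad[i])))
  }
  fit <- lm_train(net, X, y, training_config(max_epochs = 3, seed = 2))
  rj_best <- crcrisk:::network_jacobian(fit$network,
                                       crcrisk:::apply_scaler(X, fit$scaler)[fit$split$train, ])
  e_best <- y[fit$split$train] - rj_best$yhat
  expect_equal(fit$gradient, sqrt(sum(crossprod(rj_best$J, e_best)^2)), tolerance = 1e-10)
})

test_that("the data division is seeded, disjoint and 60/20/20 on 900 records", {
  s1 <- crcrisk:::lm_split(900, c(0.6, 0.2, 0.2), seed = 5)
  s2 <- crcrisk:::lm_split(900, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(s1, s2)
  expect_equal(length(s1$train), 540)
  expect_equal(length(s1$val), 180)
  expect_equal(length(s1$test), 180)
  expect_equal(sort(c(s1$train, s1$val, s1$test)), 1:900)
  expect_false(identical(s1, crcrisk:::lm_split(900, c(0.6, 0.2, 0.2), seed = 6)))
})

test_that("tolerance-band regression accuracy counts predictions near the truth", {
  expect_equal(regression_accuracy(c(10, 20), c(10, 20)), 100)
  expect_equal(regression_accuracy(c(10, 30), c(10, 20), tolerance = 5), 50)
  expect_equal(regression_accuracy(c(10.4, 19.8), c(10, 20), tolerance = 0.5), 100)
  expect_error(regression_accuracy(numeric(0), numeric(0)), "non-empty")
})
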