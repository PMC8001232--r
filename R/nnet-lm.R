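#' Build a feedforward network
#'
#' A fully connected multilayer perceptron: `n_inputs` inputs, `hidden_layers`
#' hidden layers of `neurons` units each (uniform width), one linear output
#' unit. Hidden activations are `tanh` by default; the `"linear"` activation
#' makes the network an exactly affine map, useful for targets that are
#' linearly representable. Weights and biases are initialized uniformly on
#' `[-0.5, 0.5]`, seeded, so identical seeds give identical networks. The
#' parameter count is `n_inputs*m + m` for the first layer, `m^2 + m` per
#' further hidden layer, and `m + 1` for the output.
#'
#' @param hidden_layers Number of hidden layers (>= 1).
#' @param neurons Units per hidden layer (>= 1).
#' @param n_inputs Input dimension.
#' @param seed Integer seed for the initialization.
#' @param activation Hidden activation: `"tanh"` (default) or `"linear"`.
#' @return A `crc_network` list with weight matrices `W` (one per layer,
#'   rows = units, cols = inputs of the layer) and bias vectors `b`.
#' @export
build_network <- function(hidden_layers, neurons, n_inputs, seed = 1L,
                          activation = c("tanh", "linear")) {
  stopifnot(hidden_layers >= 1, neurons >= 1, n_inputs >= 1)
  activation <- match.arg(activation)
  sizes <- c(n_inputs, rep(neurons, hidden_layers), 1L)
  withr::with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::runif(sizes[l + 1] * sizes[l], -0.5, 0.5),
                       nrow = sizes[l + 1], ncol = sizes[l])
      b[[l]] <- stats::runif(sizes[l + 1], -0.5, 0.5)
    }
  })
  structure(list(W = W, b = b, sizes = sizes, activation = activation,
                 hidden_layers = as.integer(hidden_layers),
                 neurons = as.integer(neurons)),
            class = "crc_network")
}

#' Number of trainable parameters of a network
#' @param net A `crc_network`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(vapply(seq_along(net$W), function(l) length(net$W[[l]]) + length(net$b[[l]]),
             numeric(1)))
}

# Flatten / restore parameters. Order: per layer, vec(W) column-major, then b.
pack_params <- function(net) {
  unlist(lapply(seq_along(net$W), function(l) c(as.vector(net$W[[l]]), net$b[[l]])))
}

unpack_params <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(net$b[[l]])
    net$b[[l]][] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  net
}

hidden_act <- function(z, activation) if (activation == "tanh") tanh(z) else z
hidden_act_grad <- function(a, activation) if (activation == "tanh") 1 - a^2 else array(1, dim(a))

# Forward pass; returns predictions and, when keep = TRUE, the layer
# activations needed for the Jacobian.
forward_pass <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  a <- X
  acts <- if (keep) vector("list", L + 1L) else NULL
  if (keep) acts[[1L]] <- a
  for (l in seq_len(L - 1L)) {
    z <- a %*% t(net$W[[l]])
    z <- sweep(z, 2L, net$b[[l]], `+`)
    a <- hidden_act(z, net$activation)
    if (keep) acts[[l + 1L]] <- a
  }
  yhat <- as.numeric(a %*% t(net$W[[L]]) + net$b[[L]])
  list(yhat = yhat, acts = acts)
}

#' Predict with a network on already-scaled inputs
#' @param object A `crc_network`.
#' @param newdata Numeric matrix of inputs (one row per sample).
#' @param ... Unused.
#' @return Numeric vector of outputs.
#' @export
predict.crc_network <- function(object, newdata, ...) {
  forward_pass(object, as.matrix(newdata))$yhat
}

# Jacobian d yhat / d theta (n x p), column order matching pack_params().
network_jacobian <- function(net, X) {
  n <- nrow(X)
  L <- length(net$W)
  fw <- forward_pass(net, X, keep = TRUE)
  # deltas[[l]] = d yhat / d z_l  (n x width of layer l); output layer linear.
  deltas <- vector("list", L)
  deltas[[L]] <- matrix(1, n, 1L)
  for (l in rev(seq_len(L - 1L))) {
    upstream <- deltas[[l + 1L]] %*% net$W[[l + 1L]]
    deltas[[l]] <- upstream * hidden_act_grad(fw$acts[[l + 1L]], net$activation)
  }
  blocks <- vector("list", L)
  for (l in seq_len(L)) {
    a_prev <- fw$acts[[l]]
    m <- ncol(deltas[[l]])
    mp <- ncol(a_prev)
    wb <- a_prev[, rep(seq_len(mp), each = m), drop = FALSE] *
      deltas[[l]][, rep(seq_len(m), times = mp), drop = FALSE]
    blocks[[l]] <- cbind(wb, deltas[[l]])
  }
  list(yhat = fw$yhat, J = do.call(cbind, blocks))
}

#' Configure Levenberg-Marquardt training
#'
#' Defaults follow the standard damped Gauss-Newton schedule: damping starts
#' at `mu_init`, is multiplied by `mu_inc` whenever a step fails to reduce
#' the training error and by `mu_dec` when it succeeds, and training aborts
#' if it reaches `mu_max`. Early stopping halts training after
#' `max_validation_failures` consecutive epochs without improvement of the
#' validation MSE (6 validation checks by default), returning the
#' best-validation weights. Data are divided 60/20/20 into training,
#' validation and test partitions.
#'
#' @param fractions Train/validation/test fractions, summing to 1.
#' @param max_validation_failures Early-stopping patience (default 6).
#' @param max_epochs Epoch cap (default 1000); one epoch is one accepted pass
#'   over the training set.
#' @param min_gradient Stop when the Euclidean norm of the error gradient
#'   falls below this (default 1e-7).
#' @param mu_init,mu_inc,mu_dec,mu_max Damping schedule (0.001, 10, 0.1, 1e10).
#' @param seed Seed for the data division and weight initialization.
#' @return A `crc_training_config` list.
#' @export
training_config <- function(fractions = c(0.6, 0.2, 0.2),
                            max_validation_failures = 6L,
                            max_epochs = 1000L,
                            min_gradient = 1e-7,
                            mu_init = 1e-3, mu_inc = 10, mu_dec = 0.1,
                            mu_max = 1e10, seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0), max_validation_failures >= 1, max_epochs >= 1,
            min_gradient >= 0, mu_init > 0, mu_inc > 1, mu_dec < 1, mu_dec > 0)
  structure(list(fractions = fractions,
                 max_validation_failures = as.integer(max_validation_failures),
                 max_epochs = as.integer(max_epochs),
                 min_gradient = min_gradient,
                 mu_init = mu_init, mu_inc = mu_inc, mu_dec = mu_dec,
                 mu_max = mu_max, seed = as.integer(seed)),
            class = "crc_training_config")
}

# Seeded 60/20/20 (or custom) division of n samples.
lm_split <- function(n, fractions, seed) {
  withr::with_seed(seed, {
    idx <- sample.int(n)
    n_train <- round(fractions[1] * n)
    n_val <- round(fractions[2] * n)
    list(train = idx[seq_len(n_train)],
         val = idx[n_train + seq_len(n_val)],
         test = idx[-seq_len(n_train + n_val)])
  })
}

# Min-max scaling of inputs to [-1, 1] fitted on the training partition.
fit_scaler <- function(X_train) {
  lo <- apply(X_train, 2L, min)
  hi <- apply(X_train, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1  # constant columns map to -1 uniformly; harmless
  list(lo = lo, span = span)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$lo), 2L, scaler$span, `/`) * 2 - 1
}

#' Core Levenberg-Marquardt least-squares loop
#'
#' Iterates the damped normal-equation update `(J'J + mu I) delta = J' e`,
#' where `e = y - yhat` are the residuals and `J = d yhat / d theta` the
#' Jacobian at the current parameters. Each accepted step (one that reduces
#' the training SSE) counts as one epoch; rejected steps raise the damping
#' within the same epoch. Optional validation-based early stopping with the
#' patience rule of [training_config()]. When the parameter count exceeds the
#' sample count the update is solved through the equivalent dual system
#' `delta = J' (J J' + mu I)^{-1} e`, which is exact and much smaller.
#'
#' This engine is model-agnostic: `residual_jacobian(theta)` must return
#' `list(residuals = , jacobian = )` for any parameter vector, which is what
#' [lm_train()] supplies for networks and what toy least-squares problems can
#' supply directly.
#'
#' @param residual_jacobian Function of `theta` returning residuals `e` and
#'   Jacobian `J` (of the model output, so the descent direction is `J' e`).
#' @param theta0 Initial parameter vector.
#' @param config A [training_config()].
#' @param validation_mse Optional function of `theta` returning the
#'   validation MSE; enables early stopping and best-weight tracking.
#' @return List: `theta` (best-validation weights, or final when no
#'   validation), `epochs`, `stop_reason` (`"validation_failures"`,
#'   `"min_gradient"`, `"max_epochs"` or `"mu_max"`), `gradient` (Euclidean
#'   norm of `J' e` at the returned weights), `mse` (best validation MSE, or
#'   final training MSE), `train_mse`, and a per-epoch `trace` tibble.
#' @export
lm_optimize <- function(residual_jacobian, theta0, config = training_config(),
                        validation_mse = NULL) {
  theta <- theta0
  mu <- config$mu_init
  rj <- residual_jacobian(theta)
  sse <- sum(rj$residuals^2)
  n_res <- length(rj$residuals)
  best_val <- Inf
  best_theta <- theta
  fails <- 0L
  epoch <- 0L
  stop_reason <- "max_epochs"
  trace <- list()

  repeat {
    grad <- crossprod(rj$jacobian, rj$residuals)
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < config$min_gradient) { stop_reason <- "min_gradient"; break }
    if (epoch >= config$max_epochs) { stop_reason <- "max_epochs"; break }

    accepted <- FALSE
    while (!accepted) {
      delta <- lm_step(rj$jacobian, rj$residuals, mu)
      if (is.null(delta)) {
        mu <- mu * config$mu_inc
      } else {
        cand <- theta + delta
        rj_cand <- residual_jacobian(cand)
        sse_cand <- sum(rj_cand$residuals^2)
        if (is.finite(sse_cand) && sse_cand < sse) {
          theta <- cand; rj <- rj_cand; sse <- sse_cand
          mu <- max(mu * config$mu_dec, 1e-20)
          accepted <- TRUE
        } else {
          mu <- mu * config$mu_inc
        }
      }
      if (!accepted && mu > config$mu_max) break
    }
    if (!accepted) { stop_reason <- "mu_max"; break }

    epoch <- epoch + 1L
    val <- if (is.null(validation_mse)) NA_real_ else validation_mse(theta)
    trace[[epoch]] <- tibble::tibble(epoch = epoch, mu = mu,
                                     train_mse = sse / n_res,
                                     val_mse = val, gradient = gnorm)
    if (!is.null(validation_mse)) {
      if (val < best_val - 1e-15) {
        best_val <- val; best_theta <- theta; fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= config$max_validation_failures) {
          stop_reason <- "validation_failures"
          break
        }
      }
    }
  }

  if (is.null(validation_mse)) {
    best_theta <- theta; best_val <- sse / n_res
  } else if (!is.finite(best_val)) {
    best_theta <- theta; best_val <- validation_mse(theta)
  }
  rj_best <- residual_jacobian(best_theta)
  grad_best <- crossprod(rj_best$jacobian, rj_best$residuals)
  list(theta = best_theta,
       epochs = max(epoch, 1L),
       stop_reason = stop_reason,
       gradient = sqrt(sum(grad_best^2)),
       mse = best_val,
       train_mse = sum(rj_best$residuals^2) / n_res,
       trace = if (length(trace)) dplyr::bind_rows(trace) else tibble::tibble())
}

# One damped step; NULL when the system cannot be solved at this damping.
lm_step <- function(J, e, mu) {
  n <- nrow(J); p <- ncol(J)
  out <- tryCatch({
    if (p <= n) {
      as.numeric(solve(crossprod(J) + diag(mu, p), crossprod(J, e)))
    } else {
      as.numeric(crossprod(J, solve(tcrossprod(J) + diag(mu, n), e)))
    }
  }, error = function(err) NULL)
  if (!is.null(out) && !all(is.finite(out))) out <- NULL
  out
}

#' Train a network with Levenberg-Marquardt
#'
#' Divides the data 60/20/20 into training, validation and test partitions
#' (seeded), scales each input to `[-1, 1]` using the training partition's
#' min/max (the same transform is applied to the other partitions), and runs
#' [lm_optimize()] on the training residuals with validation-based early
#' stopping. The reported performance (MSE) is the validation MSE at the
#' best-validation weights — the weights the fitted model keeps — with the
#' training and test MSE alongside.
#'
#' @param net A [build_network()] network (or `NULL` with `arch` given).
#' @param inputs Data frame or matrix of continuous inputs, one row per
#'   sample.
#' @param response Numeric response vector (the 0-100 normalized risk score
#'   in the benchmark).
#' @param config A [training_config()].
#' @return A `crc_training` object: the fitted network, the report fields
#'   (`epochs`, `mse`, `train_mse`, `test_mse`, `gradient`, `seconds`,
#'   `stop_reason`), partition indices and the per-epoch trace.
#' @export
lm_train <- function(net, inputs, response, config = training_config()) {
  stopifnot(inherits(net, "crc_network"), inherits(config, "crc_training_config"))
  X <- as.matrix(inputs)
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  if (nrow(X) != length(y)) abort_format("inputs and response are not aligned")
  if (ncol(X) != net$sizes[1]) abort_format("input dimension does not match the network")

  split <- lm_split(nrow(X), config$fractions, config$seed)
  scaler <- fit_scaler(X[split$train, , drop = FALSE])
  Xs <- apply_scaler(X, scaler)
  Xtr <- Xs[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- Xs[split$val, , drop = FALSE]; yva <- y[split$val]
  Xte <- Xs[split$test, , drop = FALSE]; yte <- y[split$test]

  rj <- function(theta) {
    cand <- unpack_params(net, theta)
    out <- network_jacobian(cand, Xtr)
    list(residuals = ytr - out$yhat, jacobian = out$J)
  }
  val_fn <- if (length(yva) > 0) {
    function(theta) mean((yva - forward_pass(unpack_params(net, theta), Xva)$yhat)^2)
  } else NULL

  t0 <- proc.time()[["elapsed"]]
  fit <- lm_optimize(rj, pack_params(net), config, validation_mse = val_fn)
  seconds <- proc.time()[["elapsed"]] - t0

  trained <- unpack_params(net, fit$theta)
  test_mse <- if (length(yte) > 0) {
    mean((yte - forward_pass(trained, Xte)$yhat)^2)
  } else NA_real_
  structure(list(network = trained, scaler = scaler, split = split,
                 epochs = fit$epochs, mse = fit$mse, train_mse = fit$train_mse,
                 test_mse = test_mse, gradient = fit$gradient,
                 seconds = seconds, stop_reason = fit$stop_reason,
                 trace = fit$trace, config = config),
            class = "crc_training")
}

#' @export
print.crc_training <- function(x, ...) {
  cat("<crc_training> ", x$network$hidden_layers, " hidden layer(s) x ",
      x$network$neurons, " neuron(s); ", n_parameters(x$network),
      " parameters\n", sep = "")
  cat("  epochs: ", x$epochs, "  stop: ", x$stop_reason, "\n", sep = "")
  cat(sprintf("  MSE (validation): %.6g  train: %.6g  test: %.6g\n",
              x$mse, x$train_mse, x$test_mse))
  cat(sprintf("  gradient: %.4g  time: %.2fs\n", x$gradient, x$seconds))
  invisible(x)
}

#' Predict from a fitted training run
#' @param object A `crc_training`.
#' @param newdata Data frame or matrix of raw (unscaled) inputs.
#' @param ... Unused.
#' @return Numeric predictions on the response scale.
#' @export
predict.crc_training <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  forward_pass(object$network, apply_scaler(X, object$scaler))$yhat
}
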