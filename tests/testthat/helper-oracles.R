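# Independent oracles, deliberately written as plain loops sharing no code
# with the package's implementation paths.

# Direct formula evaluation of the worst-case-normalized risk score.
brute_force_scores <- function(schema, records, scheme) {
  vars <- schema$variables
  p <- length(vars)
  raws <- numeric(p)
  for (j in seq_len(p)) {
    v <- vars[[j]]
    if (v$kind == "qualitative") { raws[j] <- 1; next }
    lo_d <- if (v$healthy_lo > v$extreme_lo) (v$healthy_lo - v$extreme_lo) / v$healthy_lo else 0
    hi_d <- if (v$extreme_hi > v$healthy_hi) (v$extreme_hi - v$healthy_hi) / v$healthy_hi else 0
    raws[j] <- (lo_d + hi_d) / 2
  }
  wts <- switch(scheme,
    convergent = rep(1 / p, p),
    deflection = raws,
    combined = if (max(raws) - min(raws) < 1e-12) rep(0.02, p)
               else 0.01 + 0.02 * (raws - min(raws)) / (max(raws) - min(raws)))
  wts <- wts / sum(wts)
  dev_one <- function(x, v) {
    if (v$kind == "qualitative") return(if (x %in% v$benign) 0 else 100)
    if (x > v$healthy_hi) return(100 * (x - v$healthy_hi) / v$healthy_hi)
    if (x < v$healthy_lo) return(100 * (v$healthy_lo - x) / v$healthy_lo)
    0
  }
  max_dev <- numeric(p)
  for (j in seq_len(p)) {
    v <- vars[[j]]
    max_dev[j] <- if (v$kind == "qualitative") 100 else {
      lo_d <- if (v$healthy_lo > v$extreme_lo) 100 * (v$healthy_lo - v$extreme_lo) / v$healthy_lo else 0
      hi_d <- if (v$extreme_hi > v$healthy_hi) 100 * (v$extreme_hi - v$healthy_hi) / v$healthy_hi else 0
      max(lo_d, hi_d)
    }
  }
  worst <- sum(wts * max_dev)
  out <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    acc <- 0
    for (j in seq_len(p)) acc <- acc + wts[j] * dev_one(records[[j]][i], vars[[j]])
    out[i] <- 100 * acc / worst
  }
  out
}

# Explicit damped normal-equations loop, same accept/reject schedule.
oracle_lm <- function(rfun, jfun, theta, n_epochs, mu = 1e-3, inc = 10, dec = 0.1,
                      mu_max = 1e10) {
  for (epoch in seq_len(n_epochs)) {
    e <- rfun(theta)
    J <- jfun(theta)
    sse <- sum(e^2)
    repeat {
      delta <- solve(t(J) %*% J + mu * diag(ncol(J)), t(J) %*% e)
      cand <- theta + as.numeric(delta)
      if (sum(rfun(cand)^2) < sse) {
        theta <- cand
        mu <- max(mu * dec, 1e-20)
        break
      }
      mu <- mu * inc
      if (mu > mu_max) return(theta)
    }
  }
  theta
}
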