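# Independent oracles used to check the package's own numerics.

# Fine-step classic RK4 integration of the state equation with the input
# held constant over each feature bin (the same zero-order hold the model
# integrator is defined with), so the comparison isolates integrator error.
rk4_zoh_oracle <- function(coupling, input, v, times, substeps = 100) {
  nk <- coupling$n_states
  Bsum <- Reduce(`+`, coupling$B, matrix(0, nk, nk))
  M <- (coupling$A + v * Bsum) / coupling$tau
  u <- evaluate_input(input, times)
  dt <- diff(times)[1]
  h <- dt / substeps
  g <- matrix(0, nk, length(times))
  for (i in seq_len(length(times) - 1L)) {
    x <- g[, i]
    b <- as.vector(coupling$C %*% u[i]) / coupling$tau
    for (s in seq_len(substeps)) {
      k1 <- M %*% x + b
      k2 <- M %*% (x + h / 2 * k1) + b
      k3 <- M %*% (x + h / 2 * k2) + b
      k4 <- M %*% (x + h * k3) + b
      x <- x + h / 6 * as.vector(k1 + 2 * k2 + 2 * k3 + k4)
    }
    g[, i + 1L] <- x
  }
  g
}

# Closed-form Bayesian linear regression: posterior and log marginal
# likelihood of y = X theta + e with e ~ N(0, I/prec), theta ~ N(mu0, diag(v0)).
linear_gaussian_oracle <- function(X, y, mu0, v0, prec) {
  p <- length(mu0)
  S <- solve(diag(1 / v0, p) + prec * crossprod(X))
  mu <- S %*% (prec * crossprod(X, y) + mu0 / v0)
  Sig_y <- diag(1 / prec, nrow(X)) + X %*% diag(v0, p) %*% t(X)
  ch <- chol(Sig_y)
  r <- y - X %*% mu0
  z <- backsolve(ch, r, transpose = TRUE)
  log_ev <- -0.5 * (nrow(X) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  list(mean = as.vector(mu), cov = S, log_evidence = log_ev)
}

# Sinusoidal burst epochs with optional uniform latency jitter: the classic
# generator separating induced (jittered) from evoked (phase-locked) power.
burst_epochs <- function(n_trials, jitter_ms = 0, noise_sd = 0,
                         burst_freq = 15, sfreq = 128,
                         epoch = c(-500, 1000), centre_ms = 300,
                         width_ms = 120, seed = 1) {
  set.seed(seed)
  times <- seq(epoch[1], epoch[2], by = 1000 / sfreq)
  nt <- length(times)
  data <- array(0, c(n_trials, 1, nt))
  for (tr in seq_len(n_trials)) {
    lat <- centre_ms + stats::runif(1, -jitter_ms, jitter_ms)
    env <- exp(-(times - lat)^2 / (2 * width_ms^2))
    data[tr, 1, ] <- env * sin(2 * pi * burst_freq * (times - lat) / 1000) +
      stats::rnorm(nt, 0, noise_sd)
  }
  epoched_series(data, sfreq, epoch)
}

# largest principal angle (radians) between the column spaces of two bases
subspace_angle <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  s <- svd(crossprod(qu, qv))$d
  acos(min(1, max(-1, min(s))))
}
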