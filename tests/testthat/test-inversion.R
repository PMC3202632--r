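# a moderate-noise fit reused by several blocks below
fit_cache <- local({
  truth <- two_area_truth("er+ir")
  data <- simulate_dataset(simulation_recipe(truth$coupling, truth$graph,
                                             snr_db = 20, seed = 9))
  post <- variational_laplace(data, truth$graph)
  list(truth = truth, data = data, post = post)
})

test_that("predict_features is consistent with the generator", {
  truth <- two_area_truth("er+ir")
  times <- seq(-500, 1000, by = 1000 / 240)
  pred <- predict_features(truth$coupling, gamma_input(), times)
  sim <- simulate_dataset(simulation_recipe(truth$coupling, truth$graph, snr_db = Inf))
  expect_equal(pred$values, sim$values)

  # B = 0 makes the two condition predictions identical
  er <- two_area_truth("er")
  p0 <- predict_features(er$coupling, gamma_input(), times)
  expect_equal(p0$values[, , 1], p0$values[, , 2])

  # zero input weights and zero start give a zero prediction
  z <- coupling_set(er$coupling$A, er$coupling$B, matrix(0, 4, 1), tau = 100)
  expect_equal(predict_features(z, gamma_input(), times)$values,
               array(0, c(4, length(times), 2)))
})

test_that("variational Laplace matches closed-form Bayesian linear regression", {
  set.seed(21)
  n <- 60; p <- 3
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  theta_true <- c(0.5, -1, 2)
  prec <- 4
  y <- as.vector(X %*% theta_true) + rnorm(n, 0, 1 / sqrt(prec))
  mu0 <- rep(0, p); v0 <- c(4, 1, 1)

  oracle <- linear_gaussian_oracle(X, y, mu0, v0, prec)
  fit <- laplace_fit(y, function(th) as.vector(X %*% th), mu0, v0,
                     fixed_lambda = log(prec), tol = 1e-10, patience = 3)

  expect_lt(max(abs(fit$theta - oracle$mean)), 1e-6)
  expect_lt(max(abs(fit$Sigma - oracle$cov)), 1e-6)
  expect_lt(abs(free_energy(fit) - oracle$log_evidence), 1e-6)
})

test_that("an irrelevant free parameter decreases the evidence (Occam penalty)", {
  set.seed(22)
  n <- 60
  X <- cbind(1, rnorm(n))
  y <- as.vector(X %*% c(1, 0.5)) + rnorm(n, 0, 0.5)
  f2 <- laplace_fit(y, function(th) as.vector(X %*% th),
                    rep(0, 2), rep(1, 2), fixed_lambda = log(4), tol = 1e-8)
  # third regressor carries no true effect: complexity rises, accuracy barely
  X3 <- cbind(X, rnorm(n))
  f3 <- laplace_fit(y, function(th) as.vector(X3 %*% th),
                    rep(0, 3), rep(1, 3), fixed_lambda = log(4), tol = 1e-8)
  expect_lt(free_energy(f3), free_energy(f2))
  # and the penalty agrees with the closed-form evidence gap
  o2 <- linear_gaussian_oracle(X, y, rep(0, 2), rep(1, 2), 4)
  o3 <- linear_gaussian_oracle(X3, y, rep(0, 3), rep(1, 3), 4)
  expect_equal(free_energy(f3) - free_energy(f2),
               o3$log_evidence - o2$log_evidence, tolerance = 1e-6)
})

test_that("with uninformative priors squeezed shut the posterior stays at the prior", {
  set.seed(23)
  y <- rnorm(30)
  fit <- laplace_fit(y, function(th) rep(th, 30), mu0 = 0.7, v0 = 1e-10)
  expect_equal(fit$theta, 0.7, tolerance = 1e-6)
})

test_that("free energy is monotone over accepted iterations", {
  expect_true(all(diff(fit_cache$post$trace) > 0))
  expect_true(is.finite(free_energy(fit_cache$post)))
  # posterior covariance is symmetric positive semi-definite
  S <- fit_cache$post$covariance
  expect_equal(S, t(S), tolerance = 1e-8)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("posterior uncertainty shrinks as SNR increases", {
  truth <- fit_cache$truth
  lo <- simulate_dataset(simulation_recipe(truth$coupling, truth$graph,
                                           snr_db = 5, seed = 9))
  post_lo <- variational_laplace(lo, truth$graph)
  expect_lt(sum(diag(fit_cache$post$covariance)), sum(diag(post_lo$covariance)))
})

test_that("moderate-noise estimates stay within three posterior deviations of truth", {
  est <- tidy(fit_cache$post)
  truth <- fit_cache$truth
  true_vals <- c(truth$coupling$A[truth$graph$a_mask],
                 truth$coupling$B[[1]][truth$graph$b_masks[[1]]],
                 truth$coupling$C[truth$graph$c_mask],
                 log(truth$coupling$tau))
  dev <- abs(est$estimate - true_vals) / est$std.error
  expect_lt(max(dev), 3)
})

test_that("mse_percent implements the normalised percentage error", {
  g <- model_graph(1, 2, a_mask = matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2),
                   c_mask = matrix(c(TRUE, FALSE), 2, 1))
  mk <- function(a12, a21) {
    A <- diag(-1, 2); A[1, 2] <- a12; A[2, 1] <- a21
    coupling_set(A, C = matrix(c(1, 0), 2, 1), tau = 1)
  }
  truth <- mk(1, 2)
  expect_equal(mse_percent(mk(1, 2), truth, graph = g), 0)
  expect_equal(mse_percent(mk(0, 0), truth, graph = g), 100)
  expect_equal(mse_percent(mk(1.1, 1.8), truth, graph = g), 1)

  zero_truth <- mk(0, 0)
  expect_error(mse_percent(mk(1, 1), zero_truth, graph = model_graph(
    1, 2, a_mask = matrix(FALSE, 2, 2))), "truth")
})
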