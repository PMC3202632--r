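#' Prior specification for model inversion
#'
#' Builds the Gaussian priors over the free parameters implied by a model
#' graph. Free coupling parameters get zero-mean Gaussians with mild
#' shrinkage; the decay time constant and the gamma input parameters are
#' carried on log scale so that positivity is enforced with normal priors.
#' A prior variance of exactly 0 fixes a parameter at its prior mean; the
#' exogenous input parameters are fixed by default (the input is treated as
#' known and shared across candidate models) and become estimable by setting
#' `input_var > 0`. Masked-out coupling entries are not parameters at all.
#'
#' @param graph a [model_graph()].
#' @param input the [gamma_input()] whose (log) shape and rate set the input
#'   prior means.
#' @param coupling_mean,coupling_var prior mean/variance for A and B entries.
#' @param c_var prior variance for input weight (C) entries.
#' @param tau_mean,tau_var prior mean/variance of log tau (ms); default
#'   centres tau on 100 ms.
#' @param input_var prior variance of the log input shape/rate (0 = fixed).
#' @param noise_shape,noise_rate Gamma hyperprior on each noise precision.
#' @return an object of class `dcm_priors`: a parameter table plus the noise
#'   hyperprior.
#' @export
dcm_priors <- function(graph, input = gamma_input(),
                       coupling_mean = 0, coupling_var = 1 / 8,
                       c_var = 1,
                       tau_mean = log(100), tau_var = 1 / 16,
                       input_var = 0,
                       noise_shape = 1e-3, noise_rate = 1e-3) {
  stopifnot(inherits(graph, "model_graph"), inherits(input, "exogenous_input"))
  rows <- list()
  add <- function(block, idx, mean, var) {
    if (length(idx) == 0L) return()
    ij <- which(idx, arr.ind = TRUE)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      term = sprintf("%s[%d,%d]", block, ij[, 1], ij[, 2]),
      block = block, i = ij[, 1], j = ij[, 2],
      mean = mean, var = var)
  }
  add("A", graph$a_mask, coupling_mean, coupling_var)
  for (e in seq_along(graph$b_masks)) {
    add(sprintf("B%d", e), graph$b_masks[[e]], coupling_mean, coupling_var)
  }
  add("C", graph$c_mask, 0, c_var)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    term = c("log_tau", "log_input_shape", "log_input_rate"),
    block = c("tau", "input", "input"), i = NA_integer_, j = NA_integer_,
    mean = c(tau_mean, log(input$shape), log(input$rate)),
    var = c(tau_var, input_var, input_var))
  table <- do.call(rbind, rows)
  structure(list(table = table, graph = graph, input = input,
                 noise_shape = noise_shape, noise_rate = noise_rate),
            class = "dcm_priors")
}

#' @export
print.dcm_priors <- function(x, ...) {
  cat(sprintf("<dcm_priors> %d parameter(s), %d free\n",
              nrow(x$table), sum(x$table$var > 0)))
  print(x$table, n = 8)
  invisible(x)
}

# rebuild a coupling set and input from a full parameter vector
unpack_parameters <- function(theta, priors) {
  graph <- priors$graph
  tab <- priors$table
  nk <- graph$n_states
  A <- diag(-1, nk)
  sel <- tab$block == "A"
  A[cbind(tab$i[sel], tab$j[sel])] <- theta[sel]
  B <- lapply(seq_along(graph$b_masks), function(e) {
    m <- matrix(0, nk, nk)
    sel <- tab$block == sprintf("B%d", e)
    m[cbind(tab$i[sel], tab$j[sel])] <- theta[sel]
    m
  })
  C <- matrix(0, nk, graph$n_inputs)
  sel <- tab$block == "C"
  C[cbind(tab$i[sel], tab$j[sel])] <- theta[sel]
  tau <- exp(theta[tab$term == "log_tau"])
  input <- gamma_input(shape = exp(theta[tab$term == "log_input_shape"]),
                       rate = exp(theta[tab$term == "log_input_rate"]),
                       amplitude = priors$input$amplitude,
                       onset = priors$input$onset)
  list(coupling = coupling_set(A, B, C, tau), input = input)
}

#' Model prediction of the evoked and induced features
#'
#' Integrates the state equation once with `v = 0` (evoked) and once with
#' `v = 1` (induced) and stacks the two trajectories on the observation
#' grid.
#'
#' @param coupling a [coupling_set()].
#' @param input an exogenous input.
#' @param times uniform observation grid (ms).
#' @param g0 initial state (default zero).
#' @return a [subject_features()] object.
#' @export
predict_features <- function(coupling, input, times, g0 = NULL) {
  values <- array(0, c(coupling$n_states, length(times), 2L))
  for (v in 0:1) {
    values[, , v + 1L] <- integrate_trajectory(coupling, input, v, times, g0)$g
  }
  subject_features(values, times)
}

#' Generic variational Laplace optimizer
#'
#' Maximises the variational free energy of the nonlinear-Gaussian model
#' `y = f(theta) + e`, `e ~ N(0, diag(1/exp(lambda_g)))` per noise group,
#' with Gaussian prior `theta ~ N(mu0, diag(v0))`: Gauss-Newton updates of
#' the conditional mean using a central finite-difference Jacobian,
#' Levenberg-Marquardt damping with escalation on free-energy decreases, a
#' closed-form Laplace covariance, and an EM update of each group's noise
#' log precision. Iterates until the free-energy gain stays below `tol` or
#' `max_iter` is reached, returning the best state visited.
#'
#' @param y numeric data vector.
#' @param f prediction function taking the free parameter vector.
#' @param mu0,v0 prior mean and variance vectors (all `v0 > 0`).
#' @param noise_groups factor/integer vector along `y`; one precision per level.
#' @param fixed_lambda optional fixed log precisions per group (skips the EM
#'   noise update; used e.g. when the noise level is known).
#' @param noise_shape,noise_rate Gamma hyperprior on each precision.
#' @param max_iter,tol,patience stopping rule: stop after `patience`
#'   consecutive accepted steps improving by less than `tol` nats.
#' @param lambda_cap bound on each log precision.
#' @return an object of class `laplace_fit` with elements `theta`, `Sigma`,
#'   `lambda`, `free_energy`, `trace` (accepted free energies),
#'   `converged`, `status`, `predicted`.
#' @export
laplace_fit <- function(y, f, mu0, v0, noise_groups = rep(1L, length(y)),
                        fixed_lambda = NULL,
                        noise_shape = 1e-3, noise_rate = 1e-3,
                        max_iter = 128L, tol = 1e-2, patience = 2L,
                        lambda_cap = 32) {
  p <- length(mu0)
  if (p < 1L) stop("at least one free parameter is required", call. = FALSE)
  if (any(v0 <= 0)) stop("laplace_fit requires v0 > 0 for every parameter", call. = FALSE)
  assert_finite(y, "y")
  groups <- as.integer(factor(noise_groups))
  ng <- max(groups)
  idx_g <- lapply(seq_len(ng), function(g) which(groups == g))
  n_g <- lengths(idx_g)

  iS0 <- diag(1 / v0, p)
  log_det_v0 <- sum(log(v0))
  h <- 1e-3 * pmax(sqrt(v0), 1e-2)   # adaptive central-difference steps

  theta <- mu0
  lambda <- if (is.null(fixed_lambda)) {
    rep(min(lambda_cap, log(1 / max(stats::var(y), 1e-12))), ng)
  } else rep(fixed_lambda, length.out = ng)

  free_energy_terms <- function(resid, J, S, lam, th) {
    Pi <- exp(lam)[groups]
    tr_obs <- sum(((J %*% S) * J) * Pi)
    acc <- -0.5 * sum(Pi * resid^2) - 0.5 * tr_obs +
      0.5 * sum(n_g * (lam - log(2 * pi)))
    d <- th - mu0
    kl <- 0.5 * (sum(diag(iS0 %*% S)) + sum(d * (iS0 %*% d)) - p +
                   log_det_v0 - as.numeric(determinant(S)$modulus))
    acc - kl
  }

  F_best <- -Inf
  S_best <- diag(v0, p)
  trace <- numeric(0)
  delta <- 1e-6
  small_steps <- 0L
  status <- "max_iter"
  pred_best <- f(theta)

  for (iter in seq_len(max_iter)) {
    f0 <- f(theta)
    J <- matrix(0, length(y), p)
    for (k in seq_len(p)) {
      ek <- rep(0, p); ek[k] <- h[k]
      J[, k] <- (f(theta + ek) - f(theta - ek)) / (2 * h[k])
    }
    improved <- FALSE
    for (attempt in 1:12) {
      Pi <- exp(lambda)[groups]
      JP <- J * Pi
      P <- iS0 + crossprod(JP, J)
      r <- y - f0
      step <- tryCatch(
        solve(P + delta * diag(p), crossprod(JP, r) - iS0 %*% (theta - mu0)),
        error = function(e) NULL)
      if (is.null(step)) { delta <- delta * 8; next }
      cand <- theta + as.vector(step)
      fc <- f(cand)
      if (!all(is.finite(fc))) { delta <- delta * 8; next }
      rc <- y - fc
      S <- tryCatch(solve(P), error = function(e) NULL)
      if (is.null(S)) { delta <- delta * 8; next }
      lam_c <- lambda
      if (is.null(fixed_lambda)) {
        for (g in seq_len(ng)) {
          ii <- idx_g[[g]]
          tr_g <- sum((J[ii, , drop = FALSE] %*% S) * J[ii, , drop = FALSE])
          lam_c[g] <- min(lambda_cap,
                          log((n_g[g] / 2 + noise_shape) /
                                ((sum(rc[ii]^2) + tr_g) / 2 + noise_rate)))
        }
      }
      Fc <- free_energy_terms(rc, J, S, lam_c, cand)
      if (is.finite(Fc) && Fc > F_best) {
        dF <- Fc - F_best
        theta <- cand; lambda <- lam_c; S_best <- S; pred_best <- fc
        F_best <- Fc
        trace <- c(trace, Fc)
        delta <- max(delta / 2, 1e-8)
        improved <- TRUE
        break
      }
      delta <- delta * 8
    }
    if (!improved) { status <- "stalled"; break }
    small_steps <- if (iter > 1L && dF < tol) small_steps + 1L else 0L
    if (small_steps >= patience) { status <- "tolerance"; break }
  }

  structure(list(theta = theta, Sigma = S_best, lambda = lambda,
                 free_energy = F_best, trace = trace,
                 iterations = length(trace),
                 converged = status == "tolerance", status = status,
                 predicted = pred_best, residuals = y - pred_best),
            class = "laplace_fit")
}

#' Invert a spectral DCM by variational Laplace
#'
#' Fits the bilinear spectral model to a subject's evoked and induced mode
#' coefficients, returning the posterior over coupling parameters and the
#' free-energy approximation to the log model evidence. Each condition has
#' its own noise precision (evoked and induced features arise from
#' different amounts of trial averaging).
#'
#' @param data a [subject_features()] object with evoked and induced
#'   conditions.
#' @param graph the candidate [model_graph()].
#' @param priors a [dcm_priors()] object; defaults to `dcm_priors(graph, input)`.
#' @param input the exogenous input (used when the input parameters are
#'   fixed, and as prior centre when they are free).
#' @param g0 initial state, default zero.
#' @param shared_noise use a single noise precision for both conditions.
#' @param ... further arguments passed to [laplace_fit()] (e.g. `max_iter`,
#'   `tol`, `fixed_lambda`).
#' @return an object of class `dcm_posterior`.
#' @export
variational_laplace <- function(data, graph, priors = NULL,
                                input = gamma_input(), g0 = NULL,
                                shared_noise = FALSE, ...) {
  stopifnot(inherits(data, "subject_features"), inherits(graph, "model_graph"))
  if (is.null(priors)) priors <- dcm_priors(graph, input)
  stopifnot(inherits(priors, "dcm_priors"))
  if (dim(data$values)[1L] != graph$n_states) {
    stop_dim("data has %d states but graph expects %d",
             dim(data$values)[1L], graph$n_states)
  }
  assert_finite(data$values, "data")
  tab <- priors$table
  free <- tab$var > 0
  if (!any(free)) stop("model has no free parameters", call. = FALSE)
  theta_full <- tab$mean
  nk <- graph$n_states; nt <- length(data$times)

  f <- function(theta_free) {
    theta_full[free] <- theta_free
    z <- unpack_parameters(theta_full, priors)
    pred <- predict_features(z$coupling, z$input, data$times, g0)
    as.vector(pred$values)
  }
  y <- as.vector(data$values)
  groups <- if (shared_noise) rep(1L, length(y)) else rep(1:2, each = nk * nt)

  fit <- laplace_fit(y, f, mu0 = tab$mean[free], v0 = tab$var[free],
                     noise_groups = groups,
                     noise_shape = priors$noise_shape,
                     noise_rate = priors$noise_rate, ...)

  theta_full[free] <- fit$theta
  z <- unpack_parameters(theta_full, priors)
  predicted <- subject_features(array(fit$predicted, dim(data$values)),
                                data$times, conditions = data$conditions,
                                state_labels = data$state_labels)
  structure(list(mean = stats::setNames(fit$theta, tab$term[free]),
                 covariance = fit$Sigma,
                 free_energy = fit$free_energy,
                 lambda = fit$lambda,
                 coupling = z$coupling, input = z$input,
                 graph = graph, priors = priors, free = free,
                 predicted = predicted, data = data,
                 trace = fit$trace, iterations = fit$iterations,
                 converged = fit$converged, status = fit$status),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("<dcm_posterior> %d free parameter(s), F = %.2f nats (%s after %d accepted steps)\n",
              length(x$mean), x$free_energy, x$status, x$iterations))
  invisible(x)
}

#' Free energy (log-evidence approximation) of a fit
#'
#' The variational free energy balances accuracy (expected log likelihood)
#' against complexity (KL divergence from prior to posterior); it is the
#' model-comparison currency fed to Bayesian model selection.
#'
#' @param x a `dcm_posterior` or `laplace_fit`.
#' @return free energy in nats.
#' @export
free_energy <- function(x) {
  stopifnot(inherits(x, c("dcm_posterior", "laplace_fit")))
  x$free_energy
}

#' Tidy posterior coupling estimates
#'
#' @param x a `dcm_posterior`.
#' @param ... unused.
#' @return tibble with `term`, `block`, `estimate`, `std.error`,
#'   `prior.mean`, `prior.sd`.
#' @method tidy dcm_posterior
#' @export
tidy.dcm_posterior <- function(x, ...) {
  tab <- x$priors$table[x$free, ]
  tibble::tibble(term = tab$term, block = tab$block,
                 estimate = unname(x$mean),
                 std.error = sqrt(pmax(diag(x$covariance), 0)),
                 prior.mean = tab$mean, prior.sd = sqrt(tab$var))
}

#' One-line summary of a fitted spectral DCM
#'
#' @param x a `dcm_posterior`.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance dcm_posterior
#' @export
glance.dcm_posterior <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy,
                 n_free = length(x$mean),
                 iterations = x$iterations,
                 converged = x$converged,
                 noise_log_precision_evoked = x$lambda[1],
                 noise_log_precision_induced = x$lambda[length(x$lambda)])
}

#' @importFrom generics glance
#' @export
generics::glance

#' Plot observed against predicted mode time courses
#'
#' @param object a `dcm_posterior`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dcm_posterior
#' @export
autoplot.dcm_posterior <- function(object, ...) {
  obs <- tidy.subject_features(object$data)
  obs$kind <- "observed"
  fit <- tidy.subject_features(object$predicted)
  fit$kind <- "predicted"
  d <- rbind(obs, fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$state,
                                  linetype = .data$kind,
                                  alpha = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_alpha_manual(values = c(observed = 0.4, predicted = 1)) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "peristimulus time (ms)", y = "mode coefficient") +
    ggplot2::theme_minimal()
}

#' Normalised percentage MSE of coupling estimates
#'
#' `100 * sum((est - true)^2) / sum(true^2)` over the union of free coupling
#' parameters: A off-diagonals and modulation (B) entries that are nonzero
#' in the truth or estimable in the fitted model. Input weights (C) and the
#' time constant are excluded. Perfect estimates give 0%; all-zero estimates
#' give exactly 100%.
#'
#' @param posterior a `dcm_posterior`, or a [coupling_set()] of estimates
#'   (then `graph` must be supplied).
#' @param truth the generating [coupling_set()].
#' @param graph model graph of the estimates (taken from the posterior when
#'   omitted).
#' @return percentage MSE (scalar).
#' @export
mse_percent <- function(posterior, truth, graph = NULL) {
  stopifnot(inherits(truth, "coupling_set"))
  if (inherits(posterior, "dcm_posterior")) {
    est <- posterior$coupling
    graph <- posterior$graph
  } else {
    est <- posterior
    if (is.null(graph)) stop("graph must be supplied with raw coupling estimates", call. = FALSE)
  }
  nk <- truth$n_states
  off <- row(truth$A) != col(truth$A)
  a_union <- off & (truth$A != 0 | graph$a_mask)
  Bt <- total_modulation(truth)
  Bm <- if (length(graph$b_masks)) Reduce(`|`, graph$b_masks) else matrix(FALSE, nk, nk)
  b_union <- (Bt != 0) | Bm
  Be <- total_modulation(est)
  num <- sum((est$A[a_union] - truth$A[a_union])^2) + sum((Be[b_union] - Bt[b_union])^2)
  den <- sum(truth$A[a_union]^2) + sum(Bt[b_union]^2)
  if (den == 0) stop("all-zero truth over the compared parameters", call. = FALSE)
  100 * num / den
}
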