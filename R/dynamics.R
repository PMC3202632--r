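#' Instantaneous rate of change of the mode amplitudes
#'
#' Evaluates the right-hand side of the bilinear state equation,
#' `((A + vB) g + C u) / tau`, where `B` is the sum of the active
#' condition-effect matrices when `v = 1`.
#'
#' @param g numeric state vector of mode amplitudes.
#' @param coupling a [coupling_set()].
#' @param v condition indicator, 0 (evoked) or 1 (induced).
#' @param u input value(s), one per input channel.
#' @return the mode-velocity vector.
#' @export
coupling_flow <- function(g, coupling, v, u) {
  stopifnot(inherits(coupling, "coupling_set"))
  if (length(g) != coupling$n_states) {
    stop_dim("g has length %d, expected %d", length(g), coupling$n_states)
  }
  if (length(u) != ncol(coupling$C)) {
    stop_dim("u has length %d, expected %d inputs", length(u), ncol(coupling$C))
  }
  if (!v %in% c(0, 1)) stop("v must be 0 or 1", call. = FALSE)
  assert_finite(g, "g"); assert_finite(u, "u")
  M <- coupling$A + v * total_modulation(coupling)
  as.vector(M %*% g + coupling$C %*% u) / coupling$tau
}

#' Integrate the spectral state equation over an epoch
#'
#' Integrates `tau * dg/dt = (A + vB) g + C u(t)` on a uniform time grid by
#' zero-order-hold matrix-exponential stepping: with `M = (A + vB)/tau` and
#' step `D`,
#' `g(t + D) = e^{MD} g(t) + M^{-1}(e^{MD} - I) C u(t)/tau`
#' which is exact for input held constant over each step (a pseudo-inverse
#' is used when `M` is singular).
#'
#' @param coupling a [coupling_set()].
#' @param input an [gamma_input()] (or any `exogenous_input`).
#' @param v condition indicator, 0 (evoked) or 1 (induced).
#' @param times uniform time grid (ms).
#' @param g0 initial state; defaults to zero.
#' @return a `spectral_trajectory`: list with `times`, matrix `g`
#'   (`n_states x length(times)`), and the condition indicator.
#' @export
integrate_trajectory <- function(coupling, input, v, times, g0 = NULL) {
  stopifnot(inherits(coupling, "coupling_set"))
  if (!v %in% c(0, 1)) stop("v must be 0 or 1", call. = FALSE)
  dt <- assert_uniform_grid(times)
  nk <- coupling$n_states
  if (is.null(g0)) g0 <- numeric(nk)
  if (length(g0) != nk) stop_dim("g0 has length %d, expected %d", length(g0), nk)
  M <- (coupling$A + v * total_modulation(coupling)) / coupling$tau
  assert_finite(M, "system matrix")
  step <- zoh_step(M, coupling$C / coupling$tau, dt)
  u <- evaluate_input(input, times)
  u <- matrix(u, nrow = ncol(coupling$C), ncol = length(times), byrow = TRUE)
  g <- matrix(0, nk, length(times))
  g[, 1L] <- g0
  guard <- 1e8 * max(1, sqrt(sum(g0^2)), max(abs(u)) * max(abs(coupling$C)), 1)
  for (i in seq_len(length(times) - 1L)) {
    g[, i + 1L] <- step$Phi %*% g[, i] + step$Gamma %*% u[, i]
    if (any(abs(g[, i + 1L]) > guard)) {
      ev <- eigen(M, only.values = TRUE)$values
      worst <- ev[which.max(Re(ev))]
      stop(sprintf(
        "trajectory diverged at t = %g ms; most unstable eigenvalue of (A + vB)/tau: %g %+gi",
        times[i + 1L], Re(worst), Im(worst)), call. = FALSE)
    }
  }
  spectral_trajectory(times, g, v,
                      state_labels = rownames(coupling$A) %||% paste0("state", seq_len(nk)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# discrete-time propagators for one zero-order-hold step
zoh_step <- function(M, Cs, dt) {
  nk <- nrow(M)
  Phi <- as.matrix(Matrix::expm(M * dt))
  rhs <- (Phi - diag(nk)) %*% Cs
  Gamma <- tryCatch(solve(M, rhs), error = function(e) {
    # singular M: fall back to the Moore-Penrose pseudo-inverse
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-12
    Minv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    Minv %*% rhs
  })
  list(Phi = Phi, Gamma = Gamma)
}

#' Construct a spectral trajectory object
#'
#' @param times strictly increasing time grid (ms).
#' @param g `n_states x length(times)` matrix of mode coefficients.
#' @param condition 0 (evoked) or 1 (induced), or a label `"evoked"`/`"induced"`.
#' @param state_labels optional state labels.
#' @return an object of class `spectral_trajectory`.
#' @export
spectral_trajectory <- function(times, g, condition,
                                state_labels = paste0("state", seq_len(nrow(g)))) {
  g <- as.matrix(g)
  if (ncol(g) != length(times)) {
    stop_dim("g has %d columns but times has length %d", ncol(g), length(times))
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (is.character(condition)) {
    condition <- match.arg(condition, c("evoked", "induced"))
    v <- if (condition == "induced") 1 else 0
  } else {
    v <- condition
    condition <- if (v == 1) "induced" else "evoked"
  }
  structure(list(times = times, g = g, v = v, condition = condition,
                 state_labels = state_labels),
            class = "spectral_trajectory")
}

#' @export
print.spectral_trajectory <- function(x, ...) {
  cat(sprintf("<spectral_trajectory> %d states x %d bins, %g..%g ms, condition: %s\n",
              nrow(x$g), ncol(x$g), min(x$times), max(x$times), x$condition))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a spectral trajectory into a long tibble
#'
#' @param x a `spectral_trajectory`.
#' @param ... unused.
#' @return a tibble with columns `time`, `state`, `amplitude`, `condition`.
#' @method tidy spectral_trajectory
#' @export
tidy.spectral_trajectory <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, each = nrow(x$g)),
    state = rep(x$state_labels, ncol(x$g)),
    amplitude = as.vector(x$g),
    condition = x$condition)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mode-amplitude time courses
#'
#' @param object a `spectral_trajectory`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot spectral_trajectory
#' @export
autoplot.spectral_trajectory <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$amplitude,
                                  colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "peristimulus time (ms)", y = "mode amplitude",
                  title = sprintf("%s condition", object$condition)) +
    ggplot2::theme_minimal()
}

#' Serialize a trajectory to JSON
#' @param traj a `spectral_trajectory`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_trajectory <- function(traj, path = NULL) {
  obj <- list(times = traj$times, g = unname(traj$g), condition = traj$condition,
              state_labels = traj$state_labels)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a trajectory from JSON
#' @param path file path or JSON string produced by [write_trajectory()].
#' @return a `spectral_trajectory`.
#' @export
read_trajectory <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  spectral_trajectory(obj$times, obj$g, obj$condition, obj$state_labels)
}
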