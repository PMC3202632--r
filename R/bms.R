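#' Subjects x models log-evidence table
#'
#' @param log_evidence numeric matrix (subjects x models) of log evidences
#'   (variational free energies) in nats.
#' @param model_labels,subject_labels optional labels.
#' @return an object of class `evidence_table`.
#' @export
evidence_table <- function(log_evidence,
                           model_labels = colnames(log_evidence),
                           subject_labels = rownames(log_evidence)) {
  log_evidence <- as.matrix(log_evidence)
  assert_finite(log_evidence, "log_evidence")
  if (is.null(model_labels)) model_labels <- paste0("model", seq_len(ncol(log_evidence)))
  if (is.null(subject_labels)) subject_labels <- paste0("subject", seq_len(nrow(log_evidence)))
  dimnames(log_evidence) <- list(subject_labels, model_labels)
  structure(list(log_evidence = log_evidence,
                 model_labels = model_labels, subject_labels = subject_labels),
            class = "evidence_table")
}

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("<evidence_table> %d subject(s) x %d model(s)\n",
              nrow(x$log_evidence), ncol(x$log_evidence)))
  print(round(x$log_evidence, 1))
  invisible(x)
}

#' Fixed-effects Bayesian model selection
#'
#' Pools log evidence over subjects under the assumption that every subject
#' uses the same model: group evidence is the column sum, and posterior
#' model probabilities follow from a uniform model prior,
#' `p(m | y) = exp(F_m - max) / sum(exp(F - max))`.
#'
#' @param table an [evidence_table()].
#' @return a `bms_fixed` object: tibble of per-model summed evidence,
#'   relative log evidence and posterior probability, plus the pairwise
#'   log-evidence-difference matrix.
#' @export
fixed_effects_bms <- function(table) {
  stopifnot(inherits(table, "evidence_table"))
  le <- colSums(table$log_evidence)
  m <- max(le)
  prob <- exp(le - m) / sum(exp(le - m))
  ord <- order(le, decreasing = TRUE)
  rel_best <- if (length(le) > 1) le[ord[1]] - le[ord[2]] else Inf
  structure(list(
    summary = tibble::tibble(model = table$model_labels,
                             summed_log_evidence = unname(le),
                             relative_log_evidence = unname(le - m),
                             posterior_probability = unname(prob)),
    best = table$model_labels[ord[1]],
    relative_log_evidence = unname(rel_best),
    pairwise = outer(le, le, `-`)),
    class = "bms_fixed")
}

#' @export
print.bms_fixed <- function(x, ...) {
  cat(sprintf("<bms_fixed> best: %s (relative log evidence %.1f)\n",
              x$best, x$relative_log_evidence))
  print(x$summary)
  invisible(x)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model as a random effect across subjects: each subject's
#' model label is multinomial with Dirichlet-distributed frequencies.
#' The variational scheme alternates subject-wise posterior model
#' assignments, `u[n, k] = exp(F[n, k] + digamma(alpha[k]) -
#' digamma(sum(alpha)))` (normalised per subject), with the concentration
#' update `alpha = alpha0 + colSums(u)`, until convergence. Exceedance
#' probabilities (the probability that a model is more frequent than all
#' competitors) are estimated by Monte Carlo sampling of the Dirichlet
#' posterior; the two-model case admits an exact Beta-tail answer used to
#' cross-check the sampler.
#'
#' @param table an [evidence_table()].
#' @param prior_alpha Dirichlet prior concentration per model (default 1).
#' @param n_samples Dirichlet samples for exceedance probabilities.
#' @param seed integer seed for the sampler.
#' @param max_iter,tol convergence controls for the alpha updates.
#' @return a `bms_random` object: `alpha`, expected model probabilities,
#'   exceedance probabilities, assignment matrix, convergence flag.
#' @export
random_effects_bms <- function(table, prior_alpha = 1, n_samples = 1e6,
                               seed = NULL, max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(table, "evidence_table"))
  le <- table$log_evidence
  n_models <- ncol(le)
  if (n_models < 2L) stop("random-effects BMS needs at least 2 models", call. = FALSE)
  alpha0 <- rep(prior_alpha, n_models)
  alpha <- alpha0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lu <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; converged <- TRUE; break }
    alpha <- alpha_new
  }
  xp <- exceedance_probabilities(alpha, n_samples = n_samples, seed = seed)
  structure(list(
    alpha = stats::setNames(alpha, table$model_labels),
    expected_probability = stats::setNames(alpha / sum(alpha), table$model_labels),
    exceedance_probability = stats::setNames(xp, table$model_labels),
    assignments = u, prior_alpha = prior_alpha,
    n_samples = n_samples, seed = seed,
    converged = converged, iterations = iter),
    class = "bms_random")
}

#' @export
print.bms_random <- function(x, ...) {
  cat("<bms_random>", if (!x$converged) "(NOT converged)" else "", "\n")
  print(tibble::tibble(model = names(x$alpha), alpha = unname(x$alpha),
                       expected = unname(x$expected_probability),
                       exceedance = unname(x$exceedance_probability)))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Fraction of Dirichlet draws in which each model's sampled frequency is
#' strictly maximal (exact ties broken uniformly at random).
#'
#' @param alpha Dirichlet concentration parameters (all positive).
#' @param n_samples number of Monte Carlo draws.
#' @param seed optional integer seed.
#' @return probability per model, summing to 1.
#' @export
exceedance_probabilities <- function(alpha, n_samples = 1e6, seed = NULL) {
  if (any(alpha <= 0)) stop("all alpha must be positive", call. = FALSE)
  k <- length(alpha)
  if (k == 1L) return(1)
  if (!is.null(seed)) set.seed(seed)
  counts <- numeric(k)
  # sample in blocks to bound memory
  left <- n_samples
  while (left > 0) {
    nb <- min(left, 2e5)
    draws <- matrix(stats::rgamma(nb * k, shape = rep(alpha, each = nb)), nb, k)
    win <- max.col(draws, ties.method = "random")
    counts <- counts + tabulate(win, nbins = k)
    left <- left - nb
  }
  counts / n_samples
}

#' Combined Bayesian model selection
#'
#' Runs both fixed-effects and random-effects schemes on the same evidence
#' table.
#'
#' @inheritParams random_effects_bms
#' @return a `bms_result` with components `fixed` and `random`.
#' @export
bms <- function(table, prior_alpha = 1, n_samples = 1e6, seed = NULL) {
  structure(list(fixed = fixed_effects_bms(table),
                 random = random_effects_bms(table, prior_alpha = prior_alpha,
                                             n_samples = n_samples, seed = seed)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  print(x$fixed); print(x$random); invisible(x)
}

#' Tidy model-selection results
#' @param x a `bms_result`.
#' @param ... unused.
#' @return tibble with one row per model and both schemes' quantities.
#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) {
  out <- x$fixed$summary
  out$expected_probability <- unname(x$random$expected_probability)
  out$exceedance_probability <- unname(x$random$exceedance_probability)
  out
}

#' Plot model posterior and exceedance probabilities
#' @param object a `bms_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  d <- tidy(object)
  long <- tibble::tibble(
    model = rep(d$model, 2),
    scheme = rep(c("fixed effects: posterior", "random effects: exceedance"),
                 each = nrow(d)),
    probability = c(d$posterior_probability, d$exceedance_probability))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
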