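#' Stack of subject-level frequency-space coupling maps
#'
#' Subject-specific modulation (B) estimates for one connection,
#' back-projected to frequency space (subjects have different subject-specific
#' mode bases, so group statistics are formed in the common frequency space).
#'
#' @param maps numeric array `subjects x freqs x freqs` (rows of each map:
#'   target frequency; columns: source frequency).
#' @param freqs shared frequency grid (Hz).
#' @param connection label, e.g. `"SMA->LPM"`.
#' @return an object of class `coupling_map_stack`.
#' @export
coupling_map_stack <- function(maps, freqs, connection = "connection") {
  maps <- unclass(maps)
  if (length(dim(maps)) != 3L) {
    stop("maps must be a 3-d array (subjects x freqs x freqs)", call. = FALSE)
  }
  if (length(freqs) < 2L) stop("need at least 2 frequencies", call. = FALSE)
  if (dim(maps)[2L] != length(freqs) || dim(maps)[3L] != length(freqs)) {
    stop_dim("map dims (%s) inconsistent with %d frequencies",
             paste(dim(maps), collapse = " x "), length(freqs))
  }
  assert_finite(maps, "maps")
  structure(list(maps = maps, freqs = freqs, connection = connection),
            class = "coupling_map_stack")
}

#' Smooth a frequency-frequency map with a Gaussian kernel
#'
#' Separable 2-d Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' on each axis, accommodating inter-subject variability in
#' frequency-to-frequency coupling. Boundaries are handled by renormalised
#' truncation (the kernel mass inside the grid is rescaled to 1), so a
#' constant map is preserved exactly.
#'
#' @param map `F x F` numeric matrix.
#' @param fwhm_hz kernel full width at half maximum (Hz).
#' @param freqs uniform frequency grid (Hz).
#' @return smoothed matrix.
#' @export
smooth_map <- function(map, fwhm_hz, freqs) {
  map <- as.matrix(map)
  if (fwhm_hz <= 0) stop("fwhm_hz must be positive", call. = FALSE)
  df <- assert_uniform_grid(freqs)
  if (nrow(map) != length(freqs) || ncol(map) != length(freqs)) {
    stop_dim("map must be %d x %d", length(freqs), length(freqs))
  }
  sigma <- fwhm_hz / (2 * sqrt(2 * log(2))) / df     # in bins
  half <- max(1L, ceiling(4 * sigma))
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  smooth_axis <- function(m) {    # along rows (dimension 1)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i, ] <- crossprod(w, m[lo:hi, , drop = FALSE]) / sum(w)
    }
    out
  }
  t(smooth_axis(t(smooth_axis(map))))
}

#' Element-wise one-sample t-maps over subjects
#'
#' Tests each frequency-frequency element of the stacked subject maps
#' against zero, producing separate suprathreshold masks for excitatory
#' (positive) and inhibitory (negative) effects at an uncorrected one-tailed
#' threshold. Elements with zero between-subject variance are reported as
#' `+/-Inf` and flagged.
#'
#' @param stack a [coupling_map_stack()].
#' @param p_threshold uncorrected one-tailed p threshold (default 0.005).
#' @param correction `"none"` (default), `"bonferroni"` or `"fdr"` across
#'   the map's elements.
#' @return a `tstat_map`: `t` matrix, `df`, the critical value, masks
#'   `mask_positive` / `mask_negative`, and a zero-variance flag count.
#' @export
tmap <- function(stack, p_threshold = 0.005,
                 correction = c("none", "bonferroni", "fdr")) {
  stopifnot(inherits(stack, "coupling_map_stack"))
  correction <- match.arg(correction)
  n <- dim(stack$maps)[1L]
  if (n < 3L) stop("need at least 3 subjects for a t-map", call. = FALSE)
  m <- apply(stack$maps, c(2, 3), mean)
  s <- apply(stack$maps, c(2, 3), stats::sd)
  zero_var <- s == 0
  t <- m / (s / sqrt(n))
  t[zero_var] <- sign(m[zero_var]) * Inf
  t[zero_var & m == 0] <- 0
  df <- n - 1L
  p_pos <- stats::pt(t, df, lower.tail = FALSE)
  p_neg <- stats::pt(t, df, lower.tail = TRUE)
  adj <- function(p) switch(correction,
                            none = p,
                            bonferroni = pmin(1, p * length(p)),
                            fdr = matrix(stats::p.adjust(p, "fdr"), nrow(p), ncol(p)))
  structure(list(t = t, df = df,
                 p_threshold = p_threshold, correction = correction,
                 critical = stats::qt(1 - p_threshold, df),
                 mask_positive = adj(p_pos) < p_threshold,
                 mask_negative = adj(p_neg) < p_threshold,
                 n_zero_variance = sum(zero_var),
                 freqs = stack$freqs, connection = stack$connection),
            class = "tstat_map")
}

#' @export
print.tstat_map <- function(x, ...) {
  cat(sprintf("<tstat_map> %s, df = %d, p < %g one-tailed (%s): %d positive, %d negative suprathreshold element(s)\n",
              x$connection, x$df, x$p_threshold, x$correction,
              sum(x$mask_positive), sum(x$mask_negative)))
  invisible(x)
}

#' Tidy a t-map into a long tibble
#' @param x a `tstat_map`.
#' @param ... unused.
#' @return tibble with `freq_to`, `freq_from`, `t`, `excitatory`, `inhibitory`.
#' @method tidy tstat_map
#' @export
tidy.tstat_map <- function(x, ...) {
  nf <- length(x$freqs)
  tibble::tibble(
    freq_to = rep(x$freqs, nf),
    freq_from = rep(x$freqs, each = nf),
    t = as.vector(x$t),
    excitatory = as.vector(x$mask_positive),
    inhibitory = as.vector(x$mask_negative))
}

#' Plot a thresholded t-map
#' @param object a `tstat_map`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tstat_map
#' @export
autoplot.tstat_map <- function(object, ...) {
  d <- tidy(object)
  d$t_thresholded <- ifelse(d$excitatory | d$inhibitory, d$t, NA_real_)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq_from, y = .data$freq_to,
                                  fill = .data$t_thresholded)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "red", na.value = "grey95") +
    ggplot2::labs(x = "source frequency (Hz)", y = "target frequency (Hz)",
                  fill = "t", title = object$connection) +
    ggplot2::theme_minimal()
}
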