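#' Epoched multi-source time series
#'
#' Container for epoched data, either in channel space (before source
#' projection) or in source space.
#'
#' @param data numeric array `trials x sources x samples`.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window numeric length-2, epoch start and end in ms.
#' @param source_labels optional labels for the second dimension.
#' @return an object of class `epoched_series`.
#' @export
epoched_series <- function(data, sampling_rate, epoch_window,
                           source_labels = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) {
    stop("data must be a 3-d array (trials x sources x samples)", call. = FALSE)
  }
  assert_finite(data, "data")
  assert_scalar_number(sampling_rate, "sampling_rate")
  stopifnot(length(epoch_window) == 2L, epoch_window[2] > epoch_window[1])
  expected <- diff(epoch_window) / 1000 * sampling_rate + 1
  if (abs(dim(data)[3L] - expected) > 1) {
    stop(sprintf("sample count %d inconsistent with epoch window and rate (expected ~%g)",
                 dim(data)[3L], expected), call. = FALSE)
  }
  if (is.null(source_labels)) source_labels <- paste0("src", seq_len(dim(data)[2L]))
  times <- seq(epoch_window[1], epoch_window[2], length.out = dim(data)[3L])
  structure(list(data = data, sampling_rate = sampling_rate,
                 epoch_window = epoch_window, times = times,
                 source_labels = source_labels),
            class = "epoched_series")
}

#' @export
print.epoched_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_series> %d trial(s) x %d source(s) x %d samples @ %g Hz, %g..%g ms\n",
              d[1], d[2], d[3], x$sampling_rate, x$epoch_window[1], x$epoch_window[2]))
  invisible(x)
}

#' Project channel data to source space
#'
#' Applies the Moore-Penrose generalised inverse of the lead-field matrix to
#' every time sample of every trial, mapping channel-space epochs onto the
#' chosen sources.
#'
#' @param channel_data an [epoched_series()] in channel space
#'   (`trials x channels x samples`).
#' @param lead_field numeric `channels x sources` matrix of full column rank.
#' @param source_labels optional labels for the sources.
#' @return an [epoched_series()] in source space.
#' @export
project_to_sources <- function(channel_data, lead_field,
                               source_labels = NULL) {
  stopifnot(inherits(channel_data, "epoched_series"))
  lead_field <- as.matrix(lead_field)
  d <- dim(channel_data$data)
  if (nrow(lead_field) != d[2L]) {
    stop_dim("lead field has %d rows but data has %d channels",
             nrow(lead_field), d[2L])
  }
  sv <- svd(lead_field)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < ncol(lead_field)) {
    stop(sprintf("lead field is rank deficient (rank %d < %d sources)",
                 rank, ncol(lead_field)), call. = FALSE)
  }
  pinv <- sv$v %*% (t(sv$u) / sv$d)   # sources x channels
  out <- array(0, c(d[1L], ncol(lead_field), d[3L]))
  for (tr in seq_len(d[1L])) {
    out[tr, , ] <- pinv %*% channel_data$data[tr, , ]
  }
  epoched_series(out, channel_data$sampling_rate, channel_data$epoch_window,
                 source_labels %||% paste0("src", seq_len(ncol(lead_field))))
}

#' Continuous Morlet wavelet transform
#'
#' Convolves a signal with complex Morlet wavelets whose number of cycles is
#' constant across frequencies (`wavelet_number`), giving the usual
#' frequency-proportional time-frequency resolution trade-off. Wavelets are
#' L2-normalised by default so power is comparable across frequencies;
#' `normalisation = "l1"` preserves the amplitude of a pure oscillation
#' instead.
#'
#' @param signal numeric vector.
#' @param sampling_rate Hz.
#' @param freqs analysis frequencies (Hz), all positive and below Nyquist.
#' @param wavelet_number number of cycles per wavelet (>= 1).
#' @param normalisation `"l2"` (default) or `"l1"`.
#' @return complex matrix `length(freqs) x length(signal)` of coefficients;
#'   the squared magnitude is power.
#' @export
morlet_transform <- function(signal, sampling_rate, freqs, wavelet_number = 7,
                             normalisation = c("l2", "l1")) {
  normalisation <- match.arg(normalisation)
  assert_finite(signal, "signal")
  if (wavelet_number < 1) stop("wavelet_number must be >= 1", call. = FALSE)
  nyq <- sampling_rate / 2
  if (any(freqs <= 0) || any(freqs >= nyq)) {
    stop(sprintf("freqs must lie in (0, %g) Hz (Nyquist)", nyq), call. = FALSE)
  }
  n <- length(signal)
  out <- matrix(0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma_t <- wavelet_number / (2 * pi * f)             # seconds
    half <- ceiling(4 * sigma_t * sampling_rate)
    tt <- seq(-half, half) / sampling_rate
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- switch(normalisation,
                l2 = w / sqrt(sum(Mod(w)^2)),
                l1 = w * 2 / sum(Mod(w)))
    out[k, ] <- convolve_same(signal, w)
  }
  dimnames(out) <- list(paste0(freqs, "Hz"), NULL)
  out
}

# centered ("same") complex convolution via FFT
convolve_same <- function(x, w) {
  n <- length(x); m <- length(w)
  nf <- n + m - 1L
  full <- stats::fft(stats::fft(c(x, rep(0, nf - n))) *
                       stats::fft(c(w, rep(0, nf - m))), inverse = TRUE) / nf
  start <- (m - 1L) %/% 2L + 1L
  full[start:(start + n - 1L)]
}

#' Build the evoked and induced spectral conditions
#'
#' The evoked condition is the time-frequency transform of the trial-averaged
#' signal; the induced condition is the trial average of single-trial
#' transform magnitudes. Phase-locked activity survives trial averaging and
#' appears in both; activity with trial-to-trial latency jitter is cancelled
#' by averaging and appears only in the induced condition.
#'
#' Values are magnitudes (not squared magnitudes); set `measure = "power"`
#' for squared magnitudes.
#'
#' @param epochs an [epoched_series()] in source space.
#' @param freqs analysis frequencies (Hz); defaults to 4-48 Hz in 1 Hz steps.
#' @param wavelet_number Morlet cycles, default 7.
#' @param measure `"magnitude"` (default) or `"power"`.
#' @return a `tf_spectra` object: array `conditions x sources x freqs x times`
#'   with conditions `evoked` and `induced`.
#' @export
build_conditions <- function(epochs, freqs = 4:48, wavelet_number = 7,
                             measure = c("magnitude", "power")) {
  stopifnot(inherits(epochs, "epoched_series"))
  measure <- match.arg(measure)
  d <- dim(epochs$data)
  if (d[1L] < 2L) {
    warning("single trial: evoked and induced conditions coincide by construction")
  }
  nf <- length(freqs); nt <- d[3L]; ns <- d[2L]
  power <- array(0, c(2L, ns, nf, nt))
  for (s in seq_len(ns)) {
    avg <- colMeans(matrix(epochs$data[, s, ], nrow = d[1L]))
    ev <- Mod(morlet_transform(avg, epochs$sampling_rate, freqs, wavelet_number))
    ind <- matrix(0, nf, nt)
    for (tr in seq_len(d[1L])) {
      ind <- ind + Mod(morlet_transform(epochs$data[tr, s, ], epochs$sampling_rate,
                                        freqs, wavelet_number))
    }
    ind <- ind / d[1L]
    if (measure == "power") { ev <- ev^2; ind <- ind^2 }
    power[1L, s, , ] <- ev
    power[2L, s, , ] <- ind
  }
  tf_spectra(power, freqs, epochs$times, epochs$source_labels)
}

#' Construct a time-frequency spectra container
#'
#' @param power nonnegative array `conditions x sources x freqs x times`.
#' @param freqs frequency grid (Hz).
#' @param times time grid (ms).
#' @param source_labels,condition_labels optional labels.
#' @return an object of class `tf_spectra`.
#' @export
tf_spectra <- function(power, freqs, times,
                       source_labels = paste0("src", seq_len(dim(power)[2L])),
                       condition_labels = c("evoked", "induced")) {
  power <- unclass(power)
  if (length(dim(power)) != 4L) {
    stop("power must be a 4-d array (conditions x sources x freqs x times)",
         call. = FALSE)
  }
  if (dim(power)[3L] != length(freqs) || dim(power)[4L] != length(times)) {
    stop_dim("power dims (%s) inconsistent with freqs (%d) / times (%d)",
             paste(dim(power), collapse = " x "), length(freqs), length(times))
  }
  structure(list(power = power, freqs = freqs, times = times,
                 source_labels = source_labels,
                 condition_labels = condition_labels,
                 baseline_corrected = FALSE),
            class = "tf_spectra")
}

#' @export
print.tf_spectra <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tf_spectra> %d condition(s) x %d source(s) x %d freqs x %d bins%s\n",
              d[1], d[2], d[3], d[4],
              if (isTRUE(x$baseline_corrected)) " (baseline corrected)" else ""))
  invisible(x)
}

#' Remove baseline power
#'
#' Subtracts, for each condition, source and frequency, the power at the
#' first time bin, so the first bin becomes exactly zero and the remaining
#' values are deviations from the pre-stimulus spectral profile. Idempotent.
#'
#' @param spectra a [tf_spectra()].
#' @param reference `"first"` uses the very first time bin; `"first_valid"`
#'   uses the first bin outside the longest wavelet's edge zone, which must
#'   be supplied as `margin` bins.
#' @param margin number of edge bins to skip for `reference = "first_valid"`.
#' @return a baseline-corrected [tf_spectra()].
#' @export
baseline_correct <- function(spectra, reference = c("first", "first_valid"),
                             margin = 0L) {
  stopifnot(inherits(spectra, "tf_spectra"))
  reference <- match.arg(reference)
  ref_bin <- if (reference == "first") 1L else 1L + as.integer(margin)
  p <- spectra$power
  base <- p[, , , ref_bin, drop = FALSE]
  spectra$power <- sweep(p, c(1, 2, 3), array(base, dim(p)[1:3]), `-`)
  spectra$baseline_corrected <- TRUE
  spectra
}

#' Normalise spectra per subject
#'
#' Divides by the maximum absolute value across the whole container so that
#' baseline-corrected spectral deviations are on a common scale across
#' subjects (and the coupling priors are comparable between subjects).
#'
#' @param spectra a [tf_spectra()].
#' @return the normalised [tf_spectra()].
#' @export
normalise_spectra <- function(spectra) {
  stopifnot(inherits(spectra, "tf_spectra"))
  m <- max(abs(spectra$power))
  if (m > 0) spectra$power <- spectra$power / m
  spectra
}

#' Extract principal frequency modes by SVD
#'
#' Unfolds the spectra to a `freqs x (condition * source * time)` matrix and
#' takes the first `K` left singular vectors as orthonormal frequency-mode
#' profiles. One subject-specific basis is computed jointly over conditions
#' and sources, since the model shares modes across conditions.
#'
#' @param spectra a [tf_spectra()].
#' @param K number of modes to keep.
#' @return a `frequency_modes` object with orthonormal `profiles`
#'   (`freqs x K`), `singular_values`, and per-mode / cumulative
#'   `variance_explained`.
#' @export
extract_modes <- function(spectra, K) {
  stopifnot(inherits(spectra, "tf_spectra"))
  nf <- length(spectra$freqs)
  if (K > nf) stop_dim("K = %d exceeds the %d available frequencies", K, nf)
  unfolded <- unfold_freq(spectra$power)
  sv <- svd(unfolded)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (K > rank) {
    stop(sprintf("K = %d exceeds the rank (%d) of the spectra", K, rank),
         call. = FALSE)
  }
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(profiles = sv$u[, seq_len(K), drop = FALSE],
                 singular_values = sv$d,
                 variance_explained = ve[seq_len(K)],
                 cumulative_variance = cumsum(ve)[seq_len(K)],
                 freqs = spectra$freqs, K = K),
            class = "frequency_modes")
}

# freqs x (condition * source * time) unfolding
unfold_freq <- function(power) {
  d <- dim(power)
  m <- aperm(power, c(3, 1, 2, 4))
  dim(m) <- c(d[3L], d[1L] * d[2L] * d[4L])
  m
}

#' @export
print.frequency_modes <- function(x, ...) {
  cat(sprintf("<frequency_modes> %d mode(s) over %d frequencies; cumulative variance %.1f%%\n",
              x$K, length(x$freqs), 100 * x$cumulative_variance[x$K]))
  invisible(x)
}

#' Project spectra onto frequency modes
#'
#' Reduces each condition/source spectrum to `K` mode-coefficient time
#' courses, `coefficients = t(profiles) %*% spectra`. The result is the
#' observation container the model is fitted to, with states ordered
#' source-major to match [coupling_set()].
#'
#' @param spectra a [tf_spectra()].
#' @param modes a `frequency_modes` object on the same frequency grid.
#' @return a [subject_features()] object.
#' @export
project_to_modes <- function(spectra, modes) {
  stopifnot(inherits(spectra, "tf_spectra"), inherits(modes, "frequency_modes"))
  if (!isTRUE(all.equal(spectra$freqs, modes$freqs))) {
    stop("frequency grids of spectra and modes do not match", call. = FALSE)
  }
  d <- dim(spectra$power)
  nc <- d[1L]; ns <- d[2L]; nt <- d[4L]; K <- modes$K
  values <- array(0, c(ns * K, nt, nc))
  for (ci in seq_len(nc)) {
    for (s in seq_len(ns)) {
      rows <- (s - 1L) * K + seq_len(K)
      values[rows, , ci] <- t(modes$profiles) %*% spectra$power[ci, s, , ]
    }
  }
  subject_features(values, spectra$times,
                   conditions = spectra$condition_labels,
                   state_labels = as.vector(t(outer(spectra$source_labels,
                                                    paste0("mode", seq_len(K)),
                                                    paste, sep = "."))),
                   modes = modes)
}

#' Observation container: mode coefficients per condition
#'
#' @param values array `n_states x n_times x n_conditions` of mode
#'   coefficients (states ordered source-major).
#' @param times time grid (ms).
#' @param conditions condition labels, default `evoked` and `induced`.
#' @param state_labels optional state labels.
#' @param modes optional `frequency_modes` used for the reduction (kept for
#'   back-projection with [coupling_to_frequency()]).
#' @return an object of class `subject_features`.
#' @export
subject_features <- function(values, times,
                             conditions = c("evoked", "induced"),
                             state_labels = paste0("state", seq_len(dim(values)[1L])),
                             modes = NULL) {
  values <- unclass(values)
  if (length(dim(values)) != 3L) {
    stop("values must be a 3-d array (states x times x conditions)", call. = FALSE)
  }
  if (dim(values)[2L] != length(times) || dim(values)[3L] != length(conditions)) {
    stop_dim("values dims (%s) inconsistent with times (%d) / conditions (%d)",
             paste(dim(values), collapse = " x "), length(times), length(conditions))
  }
  structure(list(values = values, times = times, conditions = conditions,
                 state_labels = state_labels, modes = modes),
            class = "subject_features")
}

#' @export
print.subject_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<subject_features> %d state(s) x %d bins x %d condition(s) (%s)\n",
              d[1], d[2], d[3], paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Tidy subject features into a long tibble
#' @param x a `subject_features` object.
#' @param ... unused.
#' @return a tibble with columns `time`, `state`, `condition`, `value`.
#' @method tidy subject_features
#' @export
tidy.subject_features <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    time = rep(x$times, each = d[1L], times = d[3L]),
    state = rep(x$state_labels, times = d[2L] * d[3L]),
    condition = rep(x$conditions, each = d[1L] * d[2L]),
    value = as.vector(x$values))
}

#' Plot mode-coefficient time courses per condition
#' @param object a `subject_features` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot subject_features
#' @export
autoplot.subject_features <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "peristimulus time (ms)", y = "mode coefficient") +
    ggplot2::theme_minimal()
}

#' Back-project a mode-space coupling matrix to frequency space
#'
#' A `K x K` coupling block between the frequency modes of two sources maps
#' to a `freqs x freqs` matrix `profiles %*% M %*% t(profiles)` that
#' summarises the frequency-to-frequency coupling carried by that
#' connection.
#'
#' @param M `K x K` mode-space coupling block.
#' @param modes a `frequency_modes` object.
#' @return `freqs x freqs` matrix.
#' @export
coupling_to_frequency <- function(M, modes) {
  stopifnot(inherits(modes, "frequency_modes"))
  M <- as.matrix(M)
  if (nrow(M) != modes$K || ncol(M) != modes$K) {
    stop_dim("M must be %d x %d (mode space), got %d x %d",
             modes$K, modes$K, nrow(M), ncol(M))
  }
  modes$profiles %*% M %*% t(modes$profiles)
}
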