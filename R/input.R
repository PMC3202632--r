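#' Gamma-shaped exogenous input
#'
#' The stimulus-locked drive `u(t)` is modelled as a gamma density in
#' peristimulus time, scaled by `amplitude` and shifted to `onset`. The two
#' shape parameters are carried on log scale internally during estimation so
#' that they have unconstrained (normal) support.
#'
#' @param shape,rate positive gamma parameters; `rate` is in 1/ms, so the
#'   bump peaks at `(shape - 1) / rate` ms after `onset`.
#' @param amplitude scale factor; `u` integrates to `amplitude` over an
#'   epoch long enough to contain the bump.
#' @param onset time (ms) before which `u` is exactly zero.
#' @return an object of class `exogenous_input`.
#' @export
gamma_input <- function(shape = 6, rate = 0.048, amplitude = 125, onset = 0) {
  assert_scalar_number(shape, "shape"); assert_scalar_number(rate, "rate")
  assert_scalar_number(amplitude, "amplitude"); assert_scalar_number(onset, "onset")
  if (shape <= 0 || rate <= 0) {
    stop("shape and rate must be positive", call. = FALSE)
  }
  structure(list(shape = shape, rate = rate, amplitude = amplitude, onset = onset),
            class = "exogenous_input")
}

#' @export
print.exogenous_input <- function(x, ...) {
  cat(sprintf("<exogenous_input> gamma(shape = %g, rate = %g /ms), amplitude %g, onset %g ms (peak %g ms)\n",
              x$shape, x$rate, x$amplitude, x$onset,
              x$onset + max(0, (x$shape - 1)) / x$rate))
  invisible(x)
}

#' Evaluate an exogenous input on a time grid
#'
#' @param input an [gamma_input()] object.
#' @param times numeric vector of times (ms).
#' @return numeric vector `u(times)`, zero before the onset.
#' @export
evaluate_input <- function(input, times) {
  stopifnot(inherits(input, "exogenous_input"))
  assert_finite(times, "times")
  u <- numeric(length(times))
  after <- times >= input$onset
  u[after] <- input$amplitude *
    stats::dgamma(times[after] - input$onset, shape = input$shape, rate = input$rate)
  u
}
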