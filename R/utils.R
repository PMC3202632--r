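# internal assertion helpers -------------------------------------------------

stop_dim <- function(...) stop(sprintf(...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

assert_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}

assert_uniform_grid <- function(times, tol = 1e-6) {
  if (length(times) < 2L) stop("time grid needs at least two points", call. = FALSE)
  d <- diff(times)
  if (any(d <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (diff(range(d)) > tol * mean(d)) {
    stop("times must form a uniform grid", call. = FALSE)
  }
  invisible(mean(d))
}

# logical matrix coercion with shape check
as_mask <- function(x, nrow, ncol, what) {
  x <- as.matrix(x)
  if (!identical(dim(x), c(as.integer(nrow), as.integer(ncol)))) {
    stop_dim("%s must be %d x %d, got %d x %d", what, nrow, ncol, nrow(x), ncol(x))
  }
  storage.mode(x) <- "logical"
  x
}
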