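#' Coupling parameters of the spectral state equation
#'
#' Collects the coupling matrices of the bilinear state equation
#' \deqn{\tau \dot g = (A + v B) g + C u}
#' where `g` holds the frequency-mode amplitudes of all sources, `v` is the
#' condition indicator (0 = evoked, 1 = induced) and `u(t)` the exogenous
#' input. Off-diagonal entries of `A` couple modes within and between
#' sources (within-mode entries are linear coupling, between-mode entries
#' nonlinear, cross-frequency coupling); the diagonal is fixed at -1 so each
#' mode decays with time constant `tau` in isolation.
#'
#' @param A `nK x nK` matrix; its diagonal must equal -1.
#' @param B a matrix or list of matrices of condition-specific coupling
#'   changes (one per condition effect); defaults to none.
#' @param C `nK x n_inputs` input weight matrix.
#' @param tau positive time constant (ms).
#' @param graph optional [model_graph()]; when supplied, entries outside the
#'   graph's masks must be zero.
#'
#' @return an object of class `coupling_set`.
#' @export
coupling_set <- function(A, B = list(), C, tau, graph = NULL) {
  A <- as.matrix(A)
  nk <- nrow(A)
  if (ncol(A) != nk) stop_dim("A must be square, got %d x %d", nrow(A), ncol(A))
  assert_finite(A, "A")
  if (any(abs(diag(A) + 1) > 1e-12)) {
    stop("diagonal of A must equal -1 (fixed self-decay)", call. = FALSE)
  }
  if (is.matrix(B)) B <- list(B)
  B <- lapply(B, function(m) {
    m <- as.matrix(m)
    if (!identical(dim(m), dim(A))) stop_dim("B matrices must match A's shape")
    assert_finite(m, "B")
    m
  })
  C <- as.matrix(C)
  if (nrow(C) != nk) stop_dim("C must have %d rows, got %d", nk, nrow(C))
  assert_finite(C, "C")
  assert_scalar_number(tau, "tau")
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (!is.null(graph)) {
    off <- row(A) != col(A)
    if (any(A[off & !graph$a_mask] != 0)) {
      stop("A has nonzero entries outside the graph's a_mask", call. = FALSE)
    }
    if (length(B) != length(graph$b_masks)) {
      stop("number of B matrices must match the graph's b_masks", call. = FALSE)
    }
    for (i in seq_along(B)) {
      if (any(B[[i]][!graph$b_masks[[i]]] != 0)) {
        stop("B has nonzero entries outside the graph's b_mask", call. = FALSE)
      }
    }
    if (any(C[!graph$c_mask] != 0)) {
      stop("C has nonzero entries outside the graph's c_mask", call. = FALSE)
    }
  }
  structure(list(A = A, B = B, C = C, tau = tau, n_states = nk),
            class = "coupling_set")
}

#' @export
print.coupling_set <- function(x, ...) {
  cat(sprintf("<coupling_set> %d states, %d condition effect(s), tau = %g ms\n",
              x$n_states, length(x$B), x$tau))
  cat("A:\n"); print(round(x$A, 3))
  for (i in seq_along(x$B)) { cat(sprintf("B[[%d]]:\n", i)); print(round(x$B[[i]], 3)) }
  cat("C:\n"); print(round(x$C, 3))
  invisible(x)
}

# sum of active condition-effect matrices (zero matrix when none)
total_modulation <- function(coupling) {
  Reduce(`+`, coupling$B, matrix(0, coupling$n_states, coupling$n_states))
}

#' Serialize a coupling set to JSON
#'
#' Matrices are written as nested arrays in row-major order.
#' @param coupling a [coupling_set()].
#' @param path file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_coupling <- function(coupling, path = NULL) {
  obj <- list(A = unname(coupling$A),
              B = lapply(coupling$B, unname),
              C = unname(coupling$C),
              tau = coupling$tau)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a coupling set from JSON
#' @param path file path or JSON string produced by [write_coupling()].
#' @return a [coupling_set()].
#' @export
read_coupling <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  B <- obj$B
  if (is.array(B) && length(dim(B)) == 3L) {
    B <- lapply(seq_len(dim(B)[1L]), function(i) B[i, , ])
  } else if (!is.list(B)) {
    B <- list()
  }
  coupling_set(obj$A, B, obj$C, obj$tau)
}
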