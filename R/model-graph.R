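#' Specify which coupling parameters a model may estimate
#'
#' A model graph fixes the sparsity structure of a spectral DCM: which
#' entries of the intrinsic/extrinsic coupling matrix `A`, of the
#' condition-specific modulation matrices `B`, and of the input matrix `C`
#' are free parameters. States are frequency-mode amplitudes, ordered
#' source-major: `(source 1, mode 1), (source 1, mode 2), ...`.
#'
#' The leading diagonal of `A` is never estimable: it is fixed at -1 so that
#' every frequency mode has an intrinsic tendency to decay. By default a
#' modulatory entry (`b_masks`) must sit on an existing connection
#' (`a_mask`); set `allow_pure_modulatory = TRUE` to lift that constraint.
#'
#' @param n_sources number of sources (areas).
#' @param n_modes number of frequency modes per source (`K`).
#' @param a_mask logical `nK x nK` matrix marking estimable `A` entries
#'   (`nK = n_sources * n_modes`). Diagonal entries must be `FALSE`.
#' @param b_masks a single logical `nK x nK` matrix or a list of them, one
#'   per condition effect. Defaults to no modulatory effects.
#' @param c_mask logical `nK x n_inputs` matrix marking estimable input
#'   weights. Defaults to a single input driving every mode of source 1.
#' @param source_labels,mode_labels optional character labels.
#' @param allow_pure_modulatory allow `B` entries outside `a_mask`.
#'
#' @return an object of class `model_graph`.
#' @seealso [coupling_set()], [two_area_truth()]
#' @export
model_graph <- function(n_sources, n_modes, a_mask,
                        b_masks = list(),
                        c_mask = NULL,
                        source_labels = paste0("src", seq_len(n_sources)),
                        mode_labels = paste0("mode", seq_len(n_modes)),
                        allow_pure_modulatory = FALSE) {
  n_sources <- as.integer(n_sources)
  n_modes <- as.integer(n_modes)
  nk <- n_sources * n_modes
  a_mask <- as_mask(a_mask, nk, nk, "a_mask")
  if (any(diag(a_mask))) {
    stop("diagonal entries of a_mask must be FALSE (self-decay is fixed)", call. = FALSE)
  }
  if (is.matrix(b_masks)) b_masks <- list(b_masks)
  b_masks <- lapply(seq_along(b_masks), function(i) {
    m <- as_mask(b_masks[[i]], nk, nk, sprintf("b_masks[[%d]]", i))
    if (!allow_pure_modulatory && any(m & !a_mask & row(m) != col(m))) {
      stop("b_mask entries must lie within a_mask (or set allow_pure_modulatory)",
           call. = FALSE)
    }
    m
  })
  if (is.null(c_mask)) {
    c_mask <- matrix(FALSE, nk, 1L)
    c_mask[seq_len(n_modes), 1L] <- TRUE
  }
  c_mask <- as_mask(c_mask, nk, ncol(as.matrix(c_mask)), "c_mask")
  state_labels <- as.vector(t(outer(source_labels, mode_labels, paste, sep = ".")))
  structure(
    list(n_sources = n_sources, n_modes = n_modes, n_states = nk,
         n_inputs = ncol(c_mask),
         a_mask = a_mask, b_masks = b_masks, c_mask = c_mask,
         source_labels = source_labels, mode_labels = mode_labels,
         state_labels = state_labels),
    class = "model_graph")
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("<model_graph> %d source(s) x %d mode(s) = %d states, %d input(s)\n",
              x$n_sources, x$n_modes, x$n_states, x$n_inputs))
  cat(sprintf("  free A entries: %d, B effects: %d (%s), free C entries: %d\n",
              sum(x$a_mask), length(x$b_masks),
              paste(vapply(x$b_masks, sum, 0L), collapse = ", "),
              sum(x$c_mask)))
  invisible(x)
}

n_free_coupling <- function(graph) {
  sum(graph$a_mask) + sum(vapply(graph$b_masks, sum, 0L)) + sum(graph$c_mask)
}

#' Serialize a model graph to JSON
#'
#' Masks are written as nested 0/1 arrays in row-major order.
#'
#' @param graph a [model_graph()].
#' @param path file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_model_graph <- function(graph, path = NULL) {
  obj <- list(
    n_sources = graph$n_sources, n_modes = graph$n_modes,
    a_mask = unname(graph$a_mask * 1L),
    b_masks = lapply(graph$b_masks, function(m) unname(m * 1L)),
    c_mask = unname(graph$c_mask * 1L),
    source_labels = graph$source_labels, mode_labels = graph$mode_labels)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a model graph from JSON
#' @param path file path or JSON string produced by [write_model_graph()].
#' @return a [model_graph()].
#' @export
read_model_graph <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  bm <- obj$b_masks
  if (is.array(bm) && length(dim(bm)) == 3L) {
    bm <- lapply(seq_len(dim(bm)[1L]), function(i) bm[i, , ] == 1)
  } else if (is.list(bm)) {
    bm <- lapply(bm, function(m) m == 1)
  } else {
    bm <- list()
  }
  model_graph(obj$n_sources, obj$n_modes,
              a_mask = obj$a_mask == 1, b_masks = bm,
              c_mask = obj$c_mask == 1,
              source_labels = obj$source_labels, mode_labels = obj$mode_labels)
}
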