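#' Model-identification study on the two-area synthetic datasets
#'
#' The face-validity exercise for the scheme: generate the `er+ir` and `er`
#' datasets from the published two-area parameters at a stated SNR, invert
#' all three candidate models ([candidate_models()]) against each dataset,
#' and record the free energy and the normalised percentage MSE of the
#' coupling estimates. A correct scheme selects (by free energy) the
#' generating model for each dataset.
#'
#' @param seeds integer vector of noise seeds, one replicate per seed.
#' @param snr_db observation SNR in dB (default 13.8).
#' @param input exogenous input of the generating system.
#' @param tau generating decay time constant (ms).
#' @param variants dataset variants to simulate.
#' @param models named list of candidate [model_graph()]s.
#' @param verbose print one line per replicate.
#' @param ... passed to [variational_laplace()].
#' @return a tibble with columns `seed`, `dataset`, `model`, `free_energy`,
#'   `mse_percent`, `selected` (model with the highest free energy within
#'   the replicate) and `correct` (selected model matches the generator).
#' @export
identification_study <- function(seeds = 1:10, snr_db = 13.8,
                                 input = gamma_input(), tau = 100,
                                 variants = c("er+ir", "er"),
                                 models = candidate_models(),
                                 verbose = FALSE, ...) {
  generating <- c("er+ir" = "er_ir", "er" = "er1")
  rows <- list()
  for (seed in seeds) {
    for (variant in variants) {
      truth <- two_area_truth(variant, tau = tau)
      recipe <- simulation_recipe(truth$coupling, truth$graph, input = input,
                                  snr_db = snr_db, seed = seed)
      data <- simulate_dataset(recipe)
      fe <- mse <- stats::setNames(numeric(length(models)), names(models))
      for (nm in names(models)) {
        post <- variational_laplace(data, models[[nm]], input = input, ...)
        fe[nm] <- free_energy(post)
        mse[nm] <- mse_percent(post, truth$coupling)
      }
      sel <- names(models)[which.max(fe)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = seed, dataset = variant, model = names(models),
        free_energy = unname(fe), mse_percent = unname(mse),
        selected = sel, correct = sel == generating[[variant]])
      if (verbose) {
        message(sprintf("seed %d, %s data: selected %s (%s)",
                        seed, variant, sel,
                        if (sel == generating[[variant]]) "correct" else "wrong"))
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise an identification study
#'
#' @param study tibble returned by [identification_study()].
#' @return a tibble with, per dataset: the fraction of replicates selecting
#'   the generating model, and per model the median MSE.
#' @export
summarise_identification <- function(study) {
  datasets <- unique(study$dataset)
  out <- lapply(datasets, function(ds) {
    d <- study[study$dataset == ds, ]
    per_seed <- d[!duplicated(d$seed), ]
    med <- tapply(d$mse_percent, d$model, stats::median)
    tibble::tibble(dataset = ds,
                   n_replicates = length(unique(d$seed)),
                   selection_rate = mean(per_seed$correct),
                   model = names(med), median_mse = as.numeric(med))
  })
  do.call(rbind, out)
}
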