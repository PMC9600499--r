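# Packaged end-to-end synthetic experiments. These
# drivers define the study conditions (corpus sizes, seeds, splits) once so
# the test suite and the acceptance script run exactly the same protocol.

#' Learn-a-force-field-from-energies experiment
#'
#' Generates 300 valence-legal C/H/O molecules (seed 7, 3-12 heavy atoms,
#' no 3-/4-membered rings), assigns toy-force-field reference parameters
#' and charges, samples 50 thermal snapshots per molecule at 300 K with
#' toy-potential energies, splits 80:10:10 by molecule (seed 7), trains
#' the model on per-molecule mean-centered energies (surrogate warm start
#' followed by Adam with early stopping on the validation loss), and
#' evaluates held-out centered-energy RMSE and bond/angle parameter
#' recovery.
#'
#' @param model_seed seed for weight initialization (the corpus seeds are
#'   part of the experiment definition).
#' @param n_boot bootstrap replicates for the metric report.
#' @param warm_epochs,epochs distillation and fine-tuning epochs.
#' @param verbose print training progress.
#' @return list with `dataset`, `model`, `log`, `report` (a
#'   `metric_report`), and `rmse` (held-out centered-energy RMSE,
#'   kcal/mol).
#' @export
recovery_experiment <- function(model_seed = 3L, n_boot = 1000L,
                                warm_epochs = 350L, epochs = 200L,
                                verbose = FALSE) {
  gen <- generator_config(n_molecules = 300L, heavy_range = c(3L, 12L),
                          seed = 7L, n_snapshots = 50L, temperature = 300)
  d <- make_toy_dataset(gen)
  d <- split_by_molecule(d, c(0.8, 0.1, 0.1), seed = 7L)
  mcfg <- mm_config(n_layers = 2L, hidden_dim = 48L, embedding_dim = 48L,
                    pooling_hidden = 48L, pooling_dim = 32L,
                    readout_hidden = 64L, seed = model_seed)
  fit <- fit_model(mm_model(mcfg), d,
                   fit_config(epochs = epochs, lr = 7e-4, lr_min = 5e-5,
                              patience = 60L, warm_start = TRUE,
                              warm_epochs = warm_epochs, verbose = verbose))
  report <- evaluate_model(fit$model, d, "test", n_boot = n_boot)
  list(dataset = d, model = fit$model, log = fit$log, report = report,
       rmse = report$estimate[report$quantity == "energy_rmse"])
}

#' Discrete atom-type recovery experiment
#'
#' Trains the Stage-1 network plus classification readout against the
#' 8-type toy typer on 500 generated molecules (seed 7, molecule-level
#' 80:10:10 split) and reports held-out per-atom accuracy.
#'
#' @param model_seed seed for weight initialization.
#' @return list with `dataset`, `model`, and `accuracy`.
#' @export
typing_experiment <- function(model_seed = 3L) {
  d <- make_toy_dataset(generator_config(n_molecules = 500L, seed = 7L),
                        conformations = FALSE)
  d <- split_by_molecule(d, c(0.8, 0.1, 0.1), seed = 7L)
  m <- mm_model(mm_config(n_layers = 2L, hidden_dim = 32L,
                          embedding_dim = 32L, pooling_hidden = 16L,
                          pooling_dim = 16L, readout_hidden = 32L,
                          type_vocab = TOY_TYPES, seed = model_seed))
  fit <- fit_model(m, d, fit_config(
    loss_weights = c(energy = 0, charge = 0, type = 1),
    epochs = 250L, lr = 5e-3, patience = 250L))
  te <- split_idx(d, "test")
  correct <- unlist(lapply(te, function(mi) {
    g <- d$molecules[[mi]]$graph
    lg <- type_logits(atom_embeddings(g, fit$model), fit$model)
    colnames(lg)[max.col(lg)] == d$molecules[[mi]]$ref_types
  }))
  list(dataset = d, model = fit$model, accuracy = mean(correct))
}

#' Charge-model recovery experiment
#'
#' Trains the charge-equilibration readout against toy reference charges
#' on 300 generated molecules (topology only; the charge model is
#' conformation-independent) and reports held-out per-atom charge RMSE.
#'
#' @param model_seed seed for weight initialization.
#' @return list with `dataset`, `model`, and `rmse` (e).
#' @export
charge_experiment <- function(model_seed = 3L) {
  d <- make_toy_dataset(generator_config(n_molecules = 300L, seed = 7L),
                        conformations = FALSE)
  d <- split_by_molecule(d, c(0.8, 0.1, 0.1), seed = 7L)
  m <- mm_model(mm_config(n_layers = 2L, hidden_dim = 32L,
                          embedding_dim = 32L, pooling_hidden = 16L,
                          pooling_dim = 16L, readout_hidden = 48L,
                          seed = model_seed))
  fit <- fit_model(m, d, fit_config(
    loss_weights = c(energy = 0, charge = 1, type = 0),
    epochs = 900L, lr = 7e-3, lr_min = 1e-4, patience = 900L))
  te <- split_idx(d, "test")
  err2 <- unlist(lapply(te, function(mi) {
    (predict_charges(d$molecules[[mi]]$graph, fit$model) -
       d$molecules[[mi]]$ref_charges)^2
  }))
  list(dataset = d, model = fit$model, rmse = sqrt(mean(err2)))
}
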