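# Optional ggplot2-based diagnostics.

utils::globalVariables(c("reference", "predicted", "epoch", "loss", "set"))

#' Plot predicted vs reference centered snapshot energies
#'
#' @param model an [mm_model()].
#' @param d a split [snapshot_dataset()].
#' @param split which split to plot.
#' @return a ggplot object (requires ggplot2).
#' @export
plot_energy_fit <- function(model, d, split = "test") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  idx <- split_idx(d, split)
  batch <- build_training_batch(d, model, idx, with_energy = TRUE)
  fw <- batch_forward(model, batch, list(energy = TRUE))
  df <- data.frame(reference = batch$energy$ref_cent,
                   predicted = fw$E_cent,
                   molecule = batch$energy$snap_mol)
  rmse <- sqrt(mean((df$predicted - df$reference)^2))
  ggplot2::ggplot(df, ggplot2::aes(x = reference, y = predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(
      x = "reference centered energy (kcal/mol)",
      y = "predicted centered energy (kcal/mol)",
      title = sprintf("%s split: centered-energy RMSE %.4f kcal/mol",
                      split, rmse)) +
    ggplot2::theme_minimal()
}

#' Plot the training log
#' @param log data.frame from [fit_model()].
#' @return a ggplot object (requires ggplot2).
#' @export
plot_training_log <- function(log) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- rbind(data.frame(epoch = log$epoch, loss = log$train, set = "train"),
              data.frame(epoch = log$epoch, loss = log$validate,
                         set = "validate"))
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = loss, colour = set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "loss", title = "training curve") +
    ggplot2::theme_minimal()
}
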