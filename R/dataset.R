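# Snapshot datasets: per-molecule conformations with reference energies,
# parameters, charges and types, plus molecule-level splits.

#' Assemble a snapshot dataset
#'
#' @param molecules list of per-molecule records, each a list with fields
#'   `graph` ([mol_graph()]), `topo` ([enumerate_terms()]), and optionally
#'   `coords` (list of n x 3 matrices), `energies` (total, kcal/mol),
#'   `valence` (valence-only energies), `ref_params` (a `parameter_set`),
#'   `ref_charges`, `ref_types`.
#' @param split optional character vector ("train"/"validate"/"test"), one
#'   per molecule.
#' @return object of class `snapshot_dataset`.
#' @export
snapshot_dataset <- function(molecules, split = NULL) {
  if (!length(molecules)) stop("empty dataset")
  if (is.null(split)) split <- rep(NA_character_, length(molecules))
  stopifnot(length(split) == length(molecules))
  structure(list(molecules = molecules, split = split),
            class = "snapshot_dataset")
}

#' @export
print.snapshot_dataset <- function(x, ...) {
  ns <- vapply(x$molecules, function(m)
    if (is.null(m$coords)) 0L else length(m$coords), 1L)
  cat(sprintf("<snapshot_dataset: %d molecules, %d snapshots; split: %s>\n",
              length(x$molecules), sum(ns),
              if (all(is.na(x$split))) "none" else
                paste(names(table(x$split)), table(x$split),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Generate the full synthetic training corpus
#'
#' Pipeline driver: generate molecules, assign toy-force-field reference
#' parameters/types/charges, and (optionally) sample thermal conformations
#' with reference energies.
#'
#' @param gen_cfg a [generator_config()].
#' @param ff a [toy_forcefield()].
#' @param conformations sample snapshots (set FALSE for typing/charge-only
#'   experiments, which need no geometry).
#' @param sample_args extra arguments passed to
#'   [sample_conformations_many()].
#' @return a [snapshot_dataset()].
#' @export
make_toy_dataset <- function(gen_cfg, ff = toy_forcefield(),
                             conformations = TRUE, sample_args = list()) {
  graphs <- generate_molecules(gen_cfg)
  topos <- lapply(graphs, enumerate_terms)
  refs <- lapply(seq_along(graphs), function(m)
    assign_reference(ff, graphs[[m]], topos[[m]]))
  mols <- lapply(seq_along(graphs), function(m) {
    list(graph = graphs[[m]], topo = topos[[m]],
         ref_params = refs[[m]]$params, ref_charges = refs[[m]]$charges,
         ref_types = refs[[m]]$types)
  })
  if (conformations) {
    sc <- do.call(sample_conformations_many, c(
      list(graphs = graphs, params_list = lapply(refs, `[[`, "params"),
           topos = topos, n_snapshots = gen_cfg$n_snapshots,
           temperature = gen_cfg$temperature,
           seed = gen_cfg$seed + 1L),
      sample_args))
    for (m in seq_along(mols)) {
      mols[[m]]$coords <- sc[[m]]$coords
      mols[[m]]$energies <- sc[[m]]$energies
      mols[[m]]$valence <- sc[[m]]$valence
      mols[[m]]$components <- sc[[m]]$components
    }
  }
  snapshot_dataset(mols)
}

#' Partition a dataset by molecule
#'
#' Molecules (never individual snapshots) are shuffled with the given seed
#' and assigned to train/validate/test in the given fractions.
#'
#' @param d a [snapshot_dataset()].
#' @param fractions length-3 numeric summing to 1 (train, validate, test).
#' @param seed RNG seed; the same seed always yields the same assignment.
#' @return the dataset with its `split` field populated.
#' @export
split_by_molecule <- function(d, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  M <- length(d$molecules)
  n_train <- floor(M * fractions[1])
  n_val <- floor(M * fractions[2])
  n_test <- M - n_train - n_val
  sizes <- c(n_train, n_val, n_test)
  if (any(sizes == 0 & fractions > 0)) {
    stop("too few molecules (", M, ") for fractions ",
         paste(fractions, collapse = ":"))
  }
  perm <- with_seed(seed, sample.int(M))
  split <- character(M)
  split[perm] <- rep(c("train", "validate", "test"), times = sizes)
  d$split <- split
  d
}

split_idx <- function(d, which) {
  idx <- which(d$split == which)
  if (!length(idx)) stop("no molecules in split '", which, "'")
  idx
}
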