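# Model container: configuration, weight initialization, checkpointing.

MODEL_FORMAT_VERSION <- "graphmm-model-1"

#' Model configuration
#'
#' Hyperparameters of the three-stage parameter-assignment network plus the
#' charge/type readouts. Defaults give the reference architecture; smaller
#' dimensions are often sufficient (and faster) for the packaged synthetic
#' experiments.
#'
#' @param elements element alphabet for the one-hot feature block.
#' @param n_layers number of message-passing layers (>= 1). This bounds the
#'   graph radius an atom embedding can perceive.
#' @param hidden_dim,embedding_dim GNN hidden and output width.
#' @param pooling_hidden,pooling_dim symmetry-pooling MLP sizes.
#' @param readout_hidden hidden width of all parameter readouts.
#' @param activation "tanh" (default, smooth; exact finite-difference
#'   gradient checks) or "relu".
#' @param aggregation neighbor aggregation; "sum" uses a value-sorted
#'   summation so embeddings are bitwise equivariant under atom relabeling.
#' @param type_vocab character vector of discrete atom-type labels for the
#'   classification readout, or NULL to omit it.
#' @param lj_mode "legacy" (Lennard-Jones parameters passed through from a
#'   reference force field) or "predicted".
#' @param bond_grid,angle_grid fixed quadratic-basis grid points for the
#'   harmonic readouts (Angstrom / radians).
#' @param c_scale_bond,c_scale_angle output scaling of the nonnegative basis
#'   coefficients (kcal/mol/A^2 resp. kcal/mol/rad^2 per unit softplus).
#' @param c_floor additive floor on basis coefficients (guarantees k > 0).
#' @param s_floor additive floor on the charge-model hardness (kcal/mol/e^2).
#' @param seed RNG seed for weight initialization.
#' @return a named list of class `mm_config`.
#' @export
mm_config <- function(elements = DEFAULT_ELEMENTS,
                      n_layers = 3L,
                      hidden_dim = 128L,
                      embedding_dim = 128L,
                      pooling_hidden = 128L,
                      pooling_dim = 128L,
                      readout_hidden = 128L,
                      activation = "tanh",
                      aggregation = "sum",
                      type_vocab = NULL,
                      lj_mode = c("legacy", "predicted"),
                      bond_grid = seq(0.7, 2.2, length.out = 8),
                      angle_grid = seq(0.52, 3.14, length.out = 8),
                      c_scale_bond = 50,
                      c_scale_angle = 10,
                      c_floor = 1e-6,
                      s_floor = 1e-3,
                      seed = 0L) {
  stopifnot(n_layers >= 1, hidden_dim >= 1, embedding_dim >= 1)
  cfg <- list(elements = elements, n_layers = as.integer(n_layers),
              hidden_dim = as.integer(hidden_dim),
              embedding_dim = as.integer(embedding_dim),
              pooling_hidden = as.integer(pooling_hidden),
              pooling_dim = as.integer(pooling_dim),
              readout_hidden = as.integer(readout_hidden),
              activation = activation, aggregation = aggregation,
              type_vocab = type_vocab, lj_mode = match.arg(lj_mode),
              bond_grid = bond_grid, angle_grid = angle_grid,
              c_scale_bond = c_scale_bond, c_scale_angle = c_scale_angle,
              c_floor = c_floor, s_floor = s_floor,
              seed = as.integer(seed),
              feature_layout = "fl-1", version = MODEL_FORMAT_VERSION)
  class(cfg) <- "mm_config"
  cfg
}

#' Construct a parameter-assignment model with freshly initialized weights
#'
#' All trainable weights of the embedding GNN, symmetry pooling, parameter
#' readouts, and the charge (and optional type) readouts. Initialization is
#' fan-in-scaled Gaussian, fully determined by `config$seed`.
#'
#' @param config an [mm_config()].
#' @return object of class `mm_model` with fields `config` and `weights`.
#' @export
mm_model <- function(config = mm_config()) {
  fd <- feature_dim(config$elements)
  e <- config$embedding_dim
  h <- config$hidden_dim
  ph <- config$pooling_hidden
  pd <- config$pooling_dim
  rh <- config$readout_hidden
  weights <- with_seed(config$seed, {
    gnn <- vector("list", config$n_layers)
    d_in <- fd
    for (l in seq_len(config$n_layers)) {
      d_out <- if (l == config$n_layers) e else h
      gnn[[l]] <- list(self = init_linear(d_in, d_out),
                       neigh = init_linear(d_in, d_out))
      d_in <- d_out
    }
    names(gnn) <- paste0("layer", seq_len(config$n_layers))
    w <- list(
      gnn = gnn,
      pool = list(
        bond = init_mlp(2 * e, ph, pd),
        angle = init_mlp(3 * e, ph, pd),
        torsion = init_mlp(4 * e, ph, pd)
      ),
      readout = list(
        bond = init_mlp(pd, rh, length(config$bond_grid)),
        angle = init_mlp(pd, rh, length(config$angle_grid)),
        torsion = init_mlp(pd, rh, 6L),
        improper = init_mlp(pd, rh, 6L),
        charge = init_mlp(e, rh, 2L)
      )
    )
    if (config$lj_mode == "predicted") w$readout$lj <- init_mlp(e, rh, 2L)
    if (!is.null(config$type_vocab)) {
      if (length(config$type_vocab) == 0) stop("empty type vocabulary")
      w$readout$type <- init_mlp(e, rh, length(config$type_vocab))
    }
    w
  })
  structure(list(config = config, weights = weights), class = "mm_model")
}

#' @export
print.mm_model <- function(x, ...) {
  np <- length(tree_flatten(x$weights))
  cat(sprintf(
    "<mm_model: %d layers, embedding %d, %s LJ, %s type readout, %d weights>\n",
    x$config$n_layers, x$config$embedding_dim, x$config$lj_mode,
    if (is.null(x$config$type_vocab)) "no" else
      sprintf("%d-class", length(x$config$type_vocab)), np))
  invisible(x)
}

# --- checkpointing ----------------------------------------------------------

encode_array <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       data = jsonlite::base64_enc(writeBin(as.vector(x), raw(),
                                            size = 8, endian = "little")))
}

decode_array <- function(obj) {
  d <- as.integer(unlist(obj$dim))
  x <- readBin(jsonlite::base64_dec(obj$data), "double",
               n = prod(d), size = 8, endian = "little")
  if (length(d) == 2) dim(x) <- d
  x
}

encode_tree <- function(a) {
  if (is.list(a)) list(node = lapply(a, encode_tree)) else encode_array(a)
}

decode_tree <- function(a) {
  if (!is.null(a$node)) lapply(a$node, decode_tree) else decode_array(a)
}

#' Save a model checkpoint
#'
#' Single-file JSON archive carrying the configuration, the feature-layout
#' version, and all weights base64-encoded at full binary precision, so a
#' load/save round trip reproduces predictions bitwise.
#'
#' @param model an [mm_model()].
#' @param path output file.
#' @export
save_model <- function(model, path) {
  obj <- list(version = MODEL_FORMAT_VERSION,
              config = unclass(model$config),
              weights = encode_tree(model$weights))
  writeLines(as.character(jsonlite::toJSON(
    obj, auto_unbox = TRUE, digits = NA, null = "null")), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path checkpoint file.
#' @return an [mm_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(obj$version, MODEL_FORMAT_VERSION)) {
    stop("checkpoint format '", obj$version, "' not supported (expected '",
         MODEL_FORMAT_VERSION, "')")
  }
  cfg <- obj$config
  cfg$elements <- unlist(cfg$elements)
  cfg$bond_grid <- unlist(cfg$bond_grid)
  cfg$angle_grid <- unlist(cfg$angle_grid)
  if (!is.null(cfg$type_vocab)) cfg$type_vocab <- unlist(cfg$type_vocab)
  class(cfg) <- "mm_config"
  structure(list(config = cfg, weights = decode_tree(obj$weights)),
            class = "mm_model")
}
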