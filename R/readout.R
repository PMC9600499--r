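# Stage 3: neural readouts mapping term embeddings to MM parameters.
#
# Harmonic terms use a nonnegative mixture of quadratic bases on a fixed
# grid: E(x) = sum_b c_b (x - x_b)^2 with c_b >= 0, which is algebraically
# the harmonic form (k/2)(x - x0)^2 + const with k = 2 sum_b c_b and
# x0 = sum_b c_b x_b / sum_b c_b. The readout emits raw values mapped to
# c_b by a scaled softplus plus a small floor, so k > 0 always holds.
# Torsions are a six-term cosine series sum_n K_n (1 + cos(n phi)) with
# phases fixed at zero and unconstrained amplitudes K_n.

# positive-map constants for the (optional) Lennard-Jones readout:
# eps = softplus(raw) * LJ_EPS_SCALE, sigma = softplus(raw) * LJ_SIGMA_SCALE
LJ_EPS_SCALE <- 0.1
LJ_SIGMA_SCALE <- 2.0

basis_coefficients <- function(raw, scale, floor) {
  softplus(raw) * scale + floor
}

#' Convert quadratic-basis coefficients to harmonic (k, x0) form
#' @param c_mat nonnegative coefficient matrix, terms x grid points.
#' @param grid basis grid points.
#' @return data.frame with columns `k` and `x0`.
#' @export
basis_to_harmonic <- function(c_mat, grid) {
  c_mat <- matrix(c_mat, ncol = length(grid))
  s <- rowSums(c_mat)
  stopifnot(all(s > 0))
  # row-wise weighted mean (not a matvec) so identical coefficient rows
  # give bitwise-identical x0 wherever they sit in the batch
  gx <- rowSums(c_mat * matrix(grid, nrow(c_mat), length(grid), byrow = TRUE))
  data.frame(k = 2 * s, x0 = gx / s)
}

#' Bond-parameter readout
#'
#' Maps bond embeddings to harmonic parameters through the quadratic-basis
#' mixture on the model's bond grid.
#'
#' @param h_r one or more bond embedding rows from [pool_bonds()].
#' @param model an [mm_model()].
#' @return data.frame with `k_r` (kcal/mol/A^2, > 0) and `r_0` (Angstrom).
#' @export
readout_bond <- function(h_r, model) {
  h_r <- matrix(h_r, ncol = model$config$pooling_dim)
  raw <- with_rowsafe(mlp_forward(h_r, model$weights$readout$bond,
                                  model$config$activation)$out)
  cc <- basis_coefficients(raw, model$config$c_scale_bond,
                           model$config$c_floor)
  kh <- basis_to_harmonic(cc, model$config$bond_grid)
  data.frame(k_r = kh$k, r_0 = kh$x0)
}

#' Angle-parameter readout
#'
#' As [readout_bond()] on the angle grid; the equilibrium angle is clamped
#' to the open interval (0, pi).
#'
#' @param h_theta angle embedding rows from [pool_angles()].
#' @param model an [mm_model()].
#' @return data.frame with `k_theta` (kcal/mol/rad^2, > 0), `theta_0` (rad).
#' @export
readout_angle <- function(h_theta, model) {
  h_theta <- matrix(h_theta, ncol = model$config$pooling_dim)
  raw <- with_rowsafe(mlp_forward(h_theta, model$weights$readout$angle,
                                  model$config$activation)$out)
  cc <- basis_coefficients(raw, model$config$c_scale_angle,
                           model$config$c_floor)
  kh <- basis_to_harmonic(cc, model$config$angle_grid)
  data.frame(k_theta = kh$k,
             theta_0 = pmin(pmax(kh$x0, 1e-6), pi - 1e-6))
}

#' Torsion-amplitude readout
#'
#' Six unconstrained cosine-series amplitudes per torsion; the energy
#' contribution of a torsion is sum_n K_n (1 + cos(n phi)) with phases
#' fixed at zero. Negative K_n reproduces a phase of pi up to an additive
#' constant.
#'
#' @param h_phi torsion embedding rows.
#' @param model an [mm_model()].
#' @param improper use the improper readout head instead of the proper one.
#' @return data.frame with columns `K1` .. `K6` (kcal/mol).
#' @export
readout_torsion <- function(h_phi, model, improper = FALSE) {
  h_phi <- matrix(h_phi, ncol = model$config$pooling_dim)
  net <- if (improper) model$weights$readout$improper else
    model$weights$readout$torsion
  K <- with_rowsafe(mlp_forward(h_phi, net, model$config$activation)$out)
  K <- as.data.frame(K)
  names(K) <- paste0("K", 1:6)
  K
}

#' Lennard-Jones readout (predicted mode only)
#'
#' Smooth positive maps guarantee eps >= 0 and sigma > 0; at zero raw
#' output they evaluate to softplus(0) * 0.1 = 0.0693 kcal/mol and
#' softplus(0) * 2.0 = 1.3863 Angstrom respectively.
#'
#' @param h_v atom embedding rows.
#' @param model an [mm_model()] with `lj_mode = "predicted"`.
#' @return data.frame with `epsilon` (kcal/mol) and `sigma` (Angstrom).
#' @export
readout_lj <- function(h_v, model) {
  if (model$config$lj_mode != "predicted") {
    stop("model is in legacy LJ mode; supply legacy parameters instead")
  }
  h_v <- matrix(h_v, ncol = model$config$embedding_dim)
  raw <- with_rowsafe(mlp_forward(h_v, model$weights$readout$lj,
                                  model$config$activation)$out)
  data.frame(epsilon = softplus(raw[, 1]) * LJ_EPS_SCALE,
             sigma = softplus(raw[, 2]) * LJ_SIGMA_SCALE)
}

#' Assign a full MM parameter set to a molecule
#'
#' Runs all three stages plus the charge-equilibration model once and
#' returns every per-term parameter. Symmetry-equivalent terms receive
#' identical parameters by construction of the pooling stage.
#'
#' @param g a [mol_graph()].
#' @param model an [mm_model()].
#' @param legacy optional list with pass-through nonbonded values:
#'   `lj` = data.frame(epsilon, sigma) per atom (required in legacy LJ
#'   mode) and optionally `charges` (per-atom vector, e).
#' @param charges "predicted" (charge-equilibration readout) or "legacy"
#'   (requires `legacy$charges`).
#' @return object of class `parameter_set`: data.frames `bonds`, `angles`,
#'   `propers`, `impropers`, `atoms` plus metadata. Harmonic convention:
#'   E = (k/2)(x - x0)^2.
#' @export
assign_parameters <- function(g, model, legacy = NULL,
                              charges = c("predicted", "legacy")) {
  charges <- match.arg(charges)
  t <- enumerate_terms(g)
  h <- atom_embeddings(g, model)
  bond_p <- readout_bond(pool_bonds(h, t, model), model)
  angle_p <- readout_angle(pool_angles(h, t, model), model)
  proper_p <- readout_torsion(pool_propers(h, t, model), model)
  improper_p <- readout_torsion(pool_impropers(h, t, model), model,
                                improper = TRUE)
  if (model$config$lj_mode == "legacy") {
    if (is.null(legacy$lj)) {
      stop("model is in legacy LJ mode but no legacy LJ values supplied")
    }
    stopifnot(nrow(legacy$lj) == n_atoms(g))
    lj <- data.frame(epsilon = legacy$lj$epsilon, sigma = legacy$lj$sigma)
    lj_src <- "legacy"
  } else {
    lj <- readout_lj(h, model)
    lj_src <- "predicted"
  }
  if (charges == "legacy") {
    if (is.null(legacy$charges)) stop("charges = 'legacy' but none supplied")
    q <- legacy$charges
    q_src <- "legacy"
  } else {
    es <- readout_en_hardness(h, model)
    q <- solve_charges(es$e, es$s, g$Q)
    q_src <- "predicted"
  }
  ps <- list(
    bonds = cbind(t$bonds, bond_p),
    angles = cbind(t$angles, angle_p),
    propers = cbind(t$propers, proper_p),
    impropers = cbind(t$impropers, improper_p),
    atoms = data.frame(element = g$atoms$element, epsilon = lj$epsilon,
                       sigma = lj$sigma, q = q),
    meta = list(name = g$name, Q = g$Q,
                provenance = list(lj = lj_src, charges = q_src),
                convention = "E = (k/2) (x - x0)^2; torsion sum K_n (1 + cos(n phi))",
                units = list(energy = "kcal/mol", length = "Angstrom",
                             angle = "rad", charge = "e"),
                version = "paramset-1")
  )
  class(ps) <- "parameter_set"
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "<parameter_set '%s': %d bonds, %d angles, %d propers, %d improper tuples; LJ %s, charges %s>\n",
    x$meta$name, nrow(x$bonds), nrow(x$angles), nrow(x$propers),
    nrow(x$impropers), x$meta$provenance$lj, x$meta$provenance$charges))
  invisible(x)
}

#' Write a parameter set to versioned JSON
#' @param ps a `parameter_set`.
#' @param path output file, or NULL to return the JSON string.
#' @export
write_params_json <- function(ps, path = NULL) {
  js <- jsonlite::toJSON(
    list(schema = "paramset-1", meta = ps$meta, atoms = ps$atoms,
         bonds = ps$bonds, angles = ps$angles, propers = ps$propers,
         impropers = ps$impropers),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a parameter set written by [write_params_json()]
#' @param path JSON file.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema, "paramset-1")) {
    stop("unknown parameter_set schema: ", obj$schema)
  }
  fix_empty <- function(df, cols) {
    df <- as.data.frame(df)
    if (nrow(df) == 0) {
      df <- as.data.frame(matrix(numeric(0), 0, length(cols),
                                 dimnames = list(NULL, cols)))
    }
    df
  }
  ps <- list(
    bonds = fix_empty(obj$bonds, c("i", "j", "k_r", "r_0")),
    angles = fix_empty(obj$angles, c("i", "j", "k", "k_theta", "theta_0")),
    propers = fix_empty(obj$propers,
                        c("i", "j", "k", "l", paste0("K", 1:6))),
    impropers = fix_empty(obj$impropers,
                          c("site", "k", "i", "j", "l", paste0("K", 1:6))),
    atoms = as.data.frame(obj$atoms), meta = obj$meta)
  class(ps) <- "parameter_set"
  ps
}
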