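# Charge equilibration: per-atom electronegativity e_i and hardness s_i are
# predicted from atom embeddings, and partial charges minimize the quadratic
# pseudo-energy  E(q) = sum_i e_i q_i + (s_i / 2) q_i^2  subject to
# sum_i q_i = Q. With a Lagrange multiplier the solution is analytic:
#   q_i = -(e_i + lambda) / s_i,
#   lambda = -(Q + sum_j e_j / s_j) / (sum_j 1 / s_j),
# which conserves the total charge exactly and is smooth in (e, s).

#' Electronegativity / hardness readout
#'
#' Hardness is kept strictly positive by a softplus map with an additive
#' floor (`s_floor`, default 1e-3 kcal/mol/e^2); electronegativity is
#' unconstrained. Both are learned latent physical parameters with no
#' absolute calibration.
#'
#' @param h atom embeddings from [atom_embeddings()].
#' @param model an [mm_model()].
#' @return list with vectors `e` (kcal/mol/e) and `s` (kcal/mol/e^2, > 0).
#' @export
readout_en_hardness <- function(h, model) {
  raw <- with_rowsafe(mlp_forward(h, model$weights$readout$charge,
                                  model$config$activation)$out)
  list(e = raw[, 1], s = softplus(raw[, 2]) + model$config$s_floor)
}

#' Analytic constrained charge solve
#'
#' Minimizes sum_i [e_i q_i + (s_i/2) q_i^2] subject to sum_i q_i = Q.
#'
#' @param e electronegativities (kcal/mol/e).
#' @param s hardnesses (kcal/mol/e^2), all strictly positive.
#' @param Q total molecular charge (e).
#' @return vector of partial charges summing to Q (to ~1e-10 e absolute;
#'   the residual is redistributed proportionally to 1/s to pin the
#'   constraint at machine precision).
#' @export
solve_charges <- function(e, s, Q) {
  if (length(e) == 0) stop("empty atom list")
  if (length(e) != length(s)) stop("e and s must have equal length")
  if (any(!is.finite(e)) || any(!is.finite(s))) stop("non-finite input")
  if (any(s <= 0)) stop("hardness must be strictly positive")
  a <- 1 / s
  lambda <- -(Q + sum(e * a)) / sum(a)
  q <- -(e + lambda) * a
  # pin the linear constraint at machine precision
  q + (Q - sum(q)) * a / sum(a)
}

# vectorized multi-molecule version used in training:
# mol: integer group id per atom; Q: per-group totals
solve_charges_grouped <- function(e, s, mol, Q) {
  a <- 1 / s
  S <- as.vector(index_rowsum(a, mol, length(Q)))
  Te <- as.vector(index_rowsum(e * a, mol, length(Q)))
  lambda <- -(Q + Te) / S
  q <- -(e + lambda[mol]) * a
  resid <- Q - as.vector(index_rowsum(q, mol, length(Q)))
  list(q = q + resid[mol] * a / S[mol], lambda = lambda, a = a, S = S)
}

# adjoint of the analytic solve: given dL/dq, return dL/de and dL/ds
solve_charges_backward <- function(dq, e, s, mol, Q, sol) {
  a <- sol$a; S <- sol$S; lambda <- sol$lambda
  ga <- as.vector(index_rowsum(dq * a, mol, length(Q)))  # sum_i g_i a_i per mol
  de <- -dq * a + (ga[mol] / S[mol]) * a
  ds <- (e + lambda[mol]) * a * a * (dq - ga[mol] / S[mol])
  list(de = de, ds = ds)
}

#' Mean squared error between predicted and reference charges
#'
#' @param q_pred,q_ref equal-length charge vectors (e).
#' @return scalar MSE in e^2.
#' @export
charge_loss <- function(q_pred, q_ref) {
  if (length(q_pred) != length(q_ref)) {
    stop("charge vectors differ in length (", length(q_pred), " vs ",
         length(q_ref), ")")
  }
  mean((q_pred - q_ref)^2)
}

#' Predict partial charges for a molecule
#'
#' Convenience wrapper: embeddings -> (e, s) readout -> analytic solve,
#' with the total charge taken from the molecular graph unless overridden.
#'
#' @param g a [mol_graph()].
#' @param model an [mm_model()].
#' @param Q total charge; defaults to the graph's net formal charge.
#' @return vector of per-atom charges (e).
#' @export
predict_charges <- function(g, model, Q = g$Q) {
  h <- atom_embeddings(g, model)
  es <- readout_en_hardness(h, model)
  solve_charges(es$e, es$s, Q)
}

#' Write per-atom charges as a plain-text column file
#' @param q charge vector (e).
#' @param path output path.
#' @param elements optional element column.
#' @export
write_charges_txt <- function(q, path, elements = NULL) {
  df <- data.frame(index = seq_along(q) - 1L, q = q)
  if (!is.null(elements)) df <- cbind(df[1], element = elements, df[2])
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
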