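# Stage 2: symmetry-preserving (Janossy) pooling.
#
# Every term embedding is the sum of one MLP evaluated on the forward and
# on the reversed concatenation of its atom embeddings. Because floating
# point addition of two summands is commutative, the embedding of a term
# and of its reversed image are bitwise identical by construction.

# idx: n_terms x k matrix of 1-based atom rows; net: an mlp weight node
pool_forward <- function(H, idx, net, activation) {
  if (nrow(idx) == 0) {
    d_out <- length(net$l2$b)
    return(list(out = matrix(0, 0, d_out), cache = NULL))
  }
  k <- ncol(idx)
  gather <- function(ix) do.call(cbind, lapply(seq_len(k), function(c)
    H[ix[, c], , drop = FALSE]))
  Xf <- gather(idx)
  Xr <- gather(idx[, rev(seq_len(k)), drop = FALSE])
  mf <- mlp_forward(Xf, net, activation)
  mr <- mlp_forward(Xr, net, activation)
  list(out = mf$out + mr$out, cache = list(mf = mf$cache, mr = mr$cache,
                                           idx = idx, k = k))
}

# returns list(grad = mlp grads, dH = gradient w.r.t. atom embeddings)
pool_backward <- function(dOut, cache, net, activation, n_atoms, e_dim) {
  if (is.null(cache)) {
    return(list(grad = tree_zeros_like(net), dH = matrix(0, n_atoms, e_dim)))
  }
  bf <- mlp_backward(dOut, cache$mf, net, activation)
  br <- mlp_backward(dOut, cache$mr, net, activation)
  grad <- tree_map2(`+`, bf$grad, br$grad)
  k <- cache$k
  idx_f <- cache$idx
  idx_r <- idx_f[, rev(seq_len(k)), drop = FALSE]
  dH <- matrix(0, n_atoms, e_dim)
  for (c in seq_len(k)) {
    cols <- ((c - 1) * e_dim + 1):(c * e_dim)
    dH <- dH + index_rowsum(bf$dX[, cols, drop = FALSE], idx_f[, c], n_atoms)
    dH <- dH + index_rowsum(br$dX[, cols, drop = FALSE], idx_r[, c], n_atoms)
  }
  list(grad = grad, dH = dH)
}

# map a term_topology onto 1-based index matrices (optionally offset)
topology_index <- function(t, offset = 0L) {
  list(
    bonds = as.matrix(t$bonds[, c("i", "j")]) + 1L + offset,
    angles = as.matrix(t$angles[, c("i", "j", "k")]) + 1L + offset,
    propers = as.matrix(t$propers[, c("i", "j", "k", "l")]) + 1L + offset,
    impropers = as.matrix(t$impropers[, c("k", "i", "j", "l")]) + 1L + offset
  )
}

pool_net <- function(model, class) {
  switch(class,
    bond = model$weights$pool$bond,
    angle = model$weights$pool$angle,
    proper = model$weights$pool$torsion,
    improper = model$weights$pool$torsion,
    stop("unknown term class: ", class))
}

#' Symmetry-pooled embedding of arbitrary atom tuples
#'
#' Low-level entry point used by the per-class wrappers and by symmetry
#' checks: rows of `idx` are atom index tuples (0-based) and each output
#' row is NN(concat forward) + NN(concat reversed) for the class's pooling
#' network. Proper and improper torsions share the 4-tuple network.
#'
#' @param h atom embeddings from [atom_embeddings()].
#' @param idx integer matrix of 0-based atom tuples (2, 3 or 4 columns).
#' @param model an [mm_model()].
#' @param class one of "bond", "angle", "proper", "improper".
#' @return matrix with one embedding row per tuple.
#' @export
term_embedding <- function(h, idx, model, class) {
  idx <- matrix(as.integer(idx), ncol = ncol(idx))
  with_rowsafe(pool_forward(h, idx + 1L, pool_net(model, class),
                            model$config$activation)$out)
}

#' Bond embeddings for all bonds of a topology
#' @param h atom embeddings; rows must match the topology's atoms.
#' @param t a [enumerate_terms()] topology.
#' @param model an [mm_model()].
#' @return matrix n_bonds x pooling_dim, rows in topology order.
#' @export
pool_bonds <- function(h, t, model) {
  term_embedding(h, as.matrix(t$bonds[, c("i", "j")]), model, "bond")
}

#' Angle embeddings (central atom in position 2)
#' @inheritParams pool_bonds
#' @export
pool_angles <- function(h, t, model) {
  term_embedding(h, as.matrix(t$angles[, c("i", "j", "k")]), model, "angle")
}

#' Proper-torsion embeddings
#' @inheritParams pool_bonds
#' @export
pool_propers <- function(h, t, model) {
  term_embedding(h, as.matrix(t$propers[, c("i", "j", "k", "l")]),
                 model, "proper")
}

#' Improper-torsion embeddings (three rows per trivalent site)
#'
#' Rows follow the topology's enumeration (k,i,j,l), (k,j,l,i), (k,l,i,j)
#' with the central atom first; the set of three rows per site is invariant
#' under cyclic relabeling of the peripheral atoms.
#' @inheritParams pool_bonds
#' @export
pool_impropers <- function(h, t, model) {
  term_embedding(h, as.matrix(t$impropers[, c("k", "i", "j", "l")]),
                 model, "improper")
}
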