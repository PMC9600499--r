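# Stage 1: message-passing atom embeddings.
#
# Neighbor aggregation sums each atom's neighbor vectors in coordinate-wise
# sorted order (a small pmin/pmax sorting network per degree class), so the
# result is exactly independent of atom numbering: relabeling a molecule
# permutes embedding rows bitwise.

# insertion-sort network (pairs of column indices) for d elements
sort_network <- function(d) {
  swaps <- list()
  if (d >= 2) {
    for (a in 2:d) for (b in seq(a, 2)) {
      swaps[[length(swaps) + 1L]] <- c(b - 1L, b)
    }
  }
  swaps
}

# Batch one or more molecular graphs into a single "plan" for the GNN.
build_graph_plan <- function(graphs, elements = DEFAULT_ELEMENTS) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  feats <- lapply(graphs, featurize_atoms, elements = elements)
  sizes <- vapply(feats, nrow, 1L)
  offsets <- c(0L, cumsum(sizes))
  n <- offsets[length(offsets)]
  X <- do.call(rbind, feats)
  src <- integer(0); dst <- integer(0)
  for (m in seq_along(graphs)) {
    b <- graphs[[m]]$bonds
    if (nrow(b)) {
      i <- b$i + 1L + offsets[m]; j <- b$j + 1L + offsets[m]
      src <- c(src, i, j); dst <- c(dst, j, i)
    }
  }
  deg <- tabulate(dst, nbins = n)
  groups <- list()
  ord <- order(dst, src)
  src_o <- src[ord]; dst_o <- dst[ord]
  for (d in sort(unique(deg[deg > 0]))) {
    targets <- which(deg == d)
    sel <- dst_o %in% targets
    nbrs <- matrix(src_o[sel], ncol = d, byrow = TRUE)
    groups[[length(groups) + 1L]] <- list(d = d, targets = targets, nbrs = nbrs)
  }
  list(X = X, n = n, src = src, dst = dst, groups = groups,
       mol_id = rep(seq_along(graphs), sizes), offsets = offsets,
       sizes = sizes)
}

agg_forward <- function(H, plan) {
  out <- matrix(0, plan$n, ncol(H))
  for (g in plan$groups) {
    if (g$d == 1) {
      out[g$targets, ] <- H[g$nbrs[, 1], , drop = FALSE]
    } else {
      Xs <- lapply(seq_len(g$d), function(c) H[g$nbrs[, c], , drop = FALSE])
      for (sw in sort_network(g$d)) {
        lo <- pmin(Xs[[sw[1]]], Xs[[sw[2]]])
        hi <- pmax(Xs[[sw[1]]], Xs[[sw[2]]])
        Xs[[sw[1]]] <- lo; Xs[[sw[2]]] <- hi
      }
      acc <- Xs[[1]]
      for (c in 2:g$d) acc <- acc + Xs[[c]]
      out[g$targets, ] <- acc
    }
  }
  out
}

# adjoint of agg_forward: each directed edge passes the target's gradient
# back to its source unchanged (summation order does not affect gradients)
agg_backward <- function(dAgg, plan) {
  index_rowsum(dAgg[plan$dst, , drop = FALSE], plan$src, plan$n)
}

gnn_forward <- function(weights, X, plan, activation) {
  L <- length(weights$gnn)
  cache <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    A <- agg_forward(H, plan)
    P <- linear_forward(H, weights$gnn[[l]]$self) +
         linear_forward(A, weights$gnn[[l]]$neigh)
    Hn <- act_forward(P, activation)
    cache[[l]] <- list(H_in = H, A_in = A, H_out = Hn)
    H <- Hn
  }
  list(H = H, cache = cache)
}

gnn_backward <- function(dH, cache, weights, plan, activation) {
  L <- length(weights$gnn)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    cc <- cache[[l]]
    dP <- act_backward(dH, cc$H_out, activation)
    bs <- linear_backward(dP, cc$H_in, weights$gnn[[l]]$self)
    bn <- linear_backward(dP, cc$A_in, weights$gnn[[l]]$neigh)
    grads[[l]] <- list(self = bs$grad, neigh = bn$grad)
    dH <- bs$dX + agg_backward(bn$dX, plan)
  }
  names(grads) <- names(weights$gnn)
  list(grads = list(gnn = grads), dX = dH)
}

#' Compute continuous atom embeddings
#'
#' Runs the message-passing network on one molecule. Embeddings are
#' deterministic, equivariant under atom relabeling (rows permute with the
#' atoms, bitwise), and identical for atoms whose k-hop neighborhoods are
#' identical (k = number of layers).
#'
#' @param g a [mol_graph()].
#' @param f its feature matrix from [featurize_atoms()] (recomputed if NULL).
#' @param model an [mm_model()].
#' @return numeric matrix, atoms x embedding_dim.
#' @export
atom_embeddings <- function(g, model, f = NULL) {
  plan <- build_graph_plan(g, model$config$elements)
  if (!is.null(f)) {
    if (!identical(dim(f), dim(plan$X))) {
      stop(sprintf(
        "feature matrix is %d x %d but model layout '%s' expects %d x %d",
        nrow(f), ncol(f), model$config$feature_layout,
        nrow(plan$X), ncol(plan$X)))
    }
    plan$X <- f
  }
  with_rowsafe(
    gnn_forward(model$weights, plan$X, plan, model$config$activation)$H)
}

#' Discrete atom-type scores from atom embeddings
#'
#' The classification readout used to measure how well continuous
#' embeddings capture a discrete typing scheme; the predicted type of an
#' atom is the argmax of its score row.
#'
#' @param h embeddings from [atom_embeddings()].
#' @param model an [mm_model()] configured with a `type_vocab`.
#' @return matrix of logits, atoms x types, columns named by the vocabulary.
#' @export
type_logits <- function(h, model) {
  if (is.null(model$config$type_vocab)) {
    stop("model has no type vocabulary configured")
  }
  out <- with_rowsafe(mlp_forward(h, model$weights$readout$type,
                                  model$config$activation)$out)
  colnames(out) <- model$config$type_vocab
  out
}

#' Cross-entropy of type logits against reference labels
#' @param logits matrix from [type_logits()].
#' @param labels character vector of reference types (or integer indices).
#' @return mean per-atom cross-entropy (nats).
#' @export
type_cross_entropy <- function(logits, labels) {
  if (is.character(labels)) labels <- match(labels, colnames(logits))
  if (anyNA(labels)) stop("labels outside the model's type vocabulary")
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), labels)])
}
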