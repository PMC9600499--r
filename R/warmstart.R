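# Energy-only warm start for training.
#
# Because the MM energy is linear in the harmonic coefficients (k/2, k*x0)
# and the cosine amplitudes K_n, snapshot energies admit a global linear
# least-squares fit once parameters are tied across local-environment
# classes (atom features refined by the neighbor-element multiset — a
# coarse, generic Weisfeiler-Leman-style coloring). The fitted per-class
# parameters are then distilled into the network with a supervised
# parameter-matching loss, and end-to-end energy training fine-tunes from
# there. All three phases consume only molecular graphs and snapshot
# energies.

# one Weisfeiler-Leman refinement round over the atom-feature coloring:
# own features plus the sorted multiset of neighbor feature rows (the same
# information a single message-passing layer can resolve)
env_colors <- function(g) {
  f <- featurize_atoms(g)
  col <- apply(f, 1, paste, collapse = ",")
  adj <- adjacency_list(g)
  vapply(seq_along(col), function(a)
    paste(col[a], paste(sort(col[adj[[a]]]), collapse = "|"), sep = ";"), "")
}

# canonical environment keys per term class
term_env_keys <- function(g, t) {
  col <- env_colors(g)
  ty <- function(v) col[v + 1]
  bond <- if (nrow(t$bonds)) {
    paste(pmin(ty(t$bonds$i), ty(t$bonds$j)),
          pmax(ty(t$bonds$i), ty(t$bonds$j)))
  } else character(0)
  angle <- if (nrow(t$angles)) {
    paste(pmin(ty(t$angles$i), ty(t$angles$k)), ty(t$angles$j),
          pmax(ty(t$angles$i), ty(t$angles$k)))
  } else character(0)
  proper <- if (nrow(t$propers)) {
    fw <- paste(ty(t$propers$i), ty(t$propers$j), ty(t$propers$k),
                ty(t$propers$l))
    bw <- paste(ty(t$propers$l), ty(t$propers$k), ty(t$propers$j),
                ty(t$propers$i))
    pmin(fw, bw)
  } else character(0)
  improper <- if (nrow(t$impropers)) paste("imp", ty(t$impropers$k)) else
    character(0)
  list(bonds = bond, angles = angle, propers = proper, impropers = improper)
}

#' Closed-form surrogate force-field fit from snapshot energies
#'
#' Fits per-environment-class MM parameters (harmonic bonds/angles in the
#' linear (k/2, k x0) parameterization, six cosine amplitudes per torsion
#' class) to per-molecule mean-centered snapshot energies by
#' column-normalized ridge least squares. Exact when the data-generating
#' potential is constant on the environment classes; otherwise the best
#' linear surrogate.
#'
#' @param d a [snapshot_dataset()] with conformations and valence energies.
#' @param mol_idx molecules to fit on (typically the training split).
#' @param lambda ridge penalty on the column-normalized harmonic columns.
#' @param lambda_torsion stronger ridge on cosine-amplitude columns; the
#'   torsion expansion is the degenerate part of the basis, and shrinking
#'   it keeps amplitudes in a physical range without hurting the fit.
#' @return list with per-class coefficient tables (`keys`, `coef`,
#'   per-class mean geometries `mu`), the achieved residual RMSE, and the
#'   ridge settings used.
#' @details Harmonic terms are parameterized as
#'   a (x - mu)^2 + b (x - mu) with mu the class's mean geometry over the
#'   fit data, which makes the two columns nearly orthogonal under thermal
#'   sampling (k = 2a, x0 = mu - b / (2a)).
#' @export
linear_reference_fit <- function(d, mol_idx, lambda = 1e-6,
                                 lambda_torsion = 1e-4) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required for linear_reference_fit")
  }
  classes <- c("bonds", "angles", "propers", "impropers")
  kper <- c(bonds = 2L, angles = 2L, propers = 6L, impropers = 6L)
  keys_by_mol <- lapply(mol_idx, function(m)
    term_env_keys(d$molecules[[m]]$graph, d$molecules[[m]]$topo))
  uniq <- lapply(stats::setNames(classes, classes), function(cl)
    unique(unlist(lapply(keys_by_mol, `[[`, cl))))
  off <- c(0L, cumsum(vapply(classes, function(cl)
    kper[[cl]] * length(uniq[[cl]]), 1L)))
  names(off) <- c(classes, "end")
  n_cols <- off[["end"]]
  # pass 1: per-class mean geometry of the harmonic classes
  mu_sum <- list(bonds = numeric(length(uniq$bonds)),
                 angles = numeric(length(uniq$angles)))
  mu_n <- list(bonds = numeric(length(uniq$bonds)),
               angles = numeric(length(uniq$angles)))
  geom_cache <- vector("list", length(mol_idx))
  for (mi in seq_along(mol_idx)) {
    mol <- d$molecules[[mol_idx[mi]]]
    t <- mol$topo; ns <- length(mol$coords)
    nm_at <- n_atoms(mol$graph)
    coords <- do.call(rbind, mol$coords)
    li <- topology_index(t)
    rep_local <- function(loc) {
      nt <- nrow(loc)
      off2 <- rep((seq_len(ns) - 1L) * nm_at, each = nt)
      loc[rep(seq_len(nt), ns), , drop = FALSE] + off2
    }
    gc <- list()
    for (cl in classes) {
      nt <- nrow(li[[cl]])
      if (nt == 0) { gc[[cl]] <- NULL; next }
      x <- if (cl == "bonds") geom_distance(coords, rep_local(li[[cl]]))$r
      else if (cl == "angles") geom_angle(coords, rep_local(li[[cl]]))$theta
      else geom_dihedral(coords, rep_local(li[[cl]]))$phi
      gc[[cl]] <- matrix(x, nt, ns)
      if (cl %in% c("bonds", "angles")) {
        ki <- match(keys_by_mol[[mi]][[cl]], uniq[[cl]])
        mu_sum[[cl]] <- mu_sum[[cl]] +
          as.vector(index_rowsum(rowSums(gc[[cl]]), ki, length(uniq[[cl]])))
        mu_n[[cl]] <- mu_n[[cl]] +
          as.vector(index_rowsum(rep(ns, nt), ki, length(uniq[[cl]])))
      }
    }
    geom_cache[[mi]] <- gc
  }
  mu <- list(bonds = mu_sum$bonds / pmax(mu_n$bonds, 1),
             angles = mu_sum$angles / pmax(mu_n$angles, 1))
  # pass 2: assemble the sparse design on centered features
  trip_i <- list(); trip_j <- list(); trip_x <- list(); yy <- list()
  row0 <- 0L
  for (mi in seq_along(mol_idx)) {
    mol <- d$molecules[[mol_idx[mi]]]
    ns <- length(mol$coords)
    for (cl in classes) {
      xm <- geom_cache[[mi]][[cl]]
      if (is.null(xm)) next
      nt <- nrow(xm)
      ki <- match(keys_by_mol[[mi]][[cl]], uniq[[cl]])
      feats <- if (kper[[cl]] == 2) {
        dx <- xm - mu[[cl]][ki]
        list(dx * dx, dx)
      } else lapply(1:6, function(n) cos(n * xm))
      for (s in seq_along(feats)) {
        vc <- feats[[s]] - rowMeans(feats[[s]])  # per-molecule centering
        trip_i[[length(trip_i) + 1L]] <- rep(row0 + seq_len(ns), each = nt)
        trip_j[[length(trip_j) + 1L]] <-
          rep(off[[cl]] + (ki - 1L) * kper[[cl]] + s, ns)
        trip_x[[length(trip_x) + 1L]] <- as.vector(vc)
      }
    }
    yy[[mi]] <- center_energies(mol$valence)
    row0 <- row0 + ns
  }
  G <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(row0, n_cols))
  y <- unlist(yy)
  cn <- sqrt(Matrix::colSums(G^2))
  cn[cn < 1e-8] <- 1
  Gs <- G %*% Matrix::Diagonal(x = 1 / cn)
  GtG <- Matrix::crossprod(Gs)
  lam_vec <- c(rep(lambda, off[["propers"]]),
               rep(lambda_torsion, n_cols - off[["propers"]]))
  Matrix::diag(GtG) <- Matrix::diag(GtG) + lam_vec
  z <- as.vector(Matrix::solve(
    Matrix::Cholesky(Matrix::forceSymmetric(GtG), LDL = FALSE),
    as.vector(Matrix::crossprod(Gs, y))))
  x_coef <- z / cn
  coef <- lapply(stats::setNames(classes, classes), function(cl) {
    k <- length(uniq[[cl]])
    if (k == 0) return(matrix(0, 0, kper[[cl]]))
    matrix(x_coef[(off[[cl]] + 1):(off[[cl]] + k * kper[[cl]])],
           nrow = k, ncol = kper[[cl]], byrow = TRUE)
  })
  resid <- sqrt(mean((as.vector(G %*% x_coef) - y)^2))
  list(keys = uniq, coef = coef, mu = mu, rmse = resid, lambda = lambda,
       lambda_torsion = lambda_torsion)
}

# per-term distillation targets from a linear_reference_fit; harmonic
# coefficients are converted to (k, x0) with guards for weakly-determined
# classes
warmstart_targets <- function(lf, d, model, mol_idx) {
  cfg <- model$config
  guards <- list(
    bonds = list(k = c(20, 1500), x0 = range(cfg$bond_grid)),
    angles = list(k = c(10, 400), x0 = range(cfg$angle_grid)))
  out <- list()
  for (cl in c("bonds", "angles", "propers", "impropers")) {
    tg <- list()
    for (mi in seq_along(mol_idx)) {
      mol <- d$molecules[[mol_idx[mi]]]
      keys <- term_env_keys(mol$graph, mol$topo)[[cl]]
      ki <- match(keys, lf$keys[[cl]])
      cf <- lf$coef[[cl]][ki, , drop = FALSE]
      if (cl %in% c("bonds", "angles")) {
        k <- 2 * cf[, 1]
        x0 <- ifelse(k != 0, lf$mu[[cl]][ki] - cf[, 2] / k, NA_real_)
        g <- guards[[cl]]
        bad <- !is.finite(k) | !is.finite(x0) | k < g$k[1] | k > g$k[2] |
          x0 < g$x0[1] | x0 > g$x0[2]
        tg[[mi]] <- cbind(k = k, x0 = x0, ok = as.numeric(!bad))
      } else {
        bad <- !is.finite(rowSums(cf))
        cf <- pmin(pmax(cf, -4), 4)  # degenerate outliers: clip to a physical band
        tg[[mi]] <- cbind(cf, ok = as.numeric(!bad))
      }
    }
    out[[cl]] <- do.call(rbind, tg)
  }
  out
}

# supervised parameter-matching loss + gradients (shares the model's
# pooling/readout path with the energy loss)
distill_loss_and_grads <- function(model, batch, targets) {
  cfg <- model$config
  act <- cfg$activation
  gf <- gnn_forward(model$weights, batch$plan$X, batch$plan, act)
  H <- gf$H
  grads <- tree_zeros_like(model$weights)
  dH <- matrix(0, batch$n_atoms, cfg$embedding_dim)
  scales <- list(bonds = c(k = 60, x0 = 0.02),
                 angles = c(k = 25, x0 = 0.02),
                 torsion = 0.5)
  loss <- 0
  for (cl in c("bonds", "angles", "propers", "impropers")) {
    if (nrow(batch$gidx[[cl]]) == 0) next
    tgt <- targets[[cl]]
    ok <- tgt[, "ok"] > 0
    if (!any(ok)) next
    net <- switch(cl, bonds = model$weights$pool$bond,
                  angles = model$weights$pool$angle,
                  model$weights$pool$torsion)
    pf <- pool_forward(H, batch$gidx[[cl]], net, act)
    rnet_name <- switch(cl, bonds = "bond", angles = "angle",
                        propers = "torsion", impropers = "improper")
    rf <- mlp_forward(pf$out, model$weights$readout[[rnet_name]], act)
    nt <- sum(ok)
    if (cl %in% c("bonds", "angles")) {
      scale_c <- if (cl == "bonds") cfg$c_scale_bond else cfg$c_scale_angle
      grid <- if (cl == "bonds") cfg$bond_grid else cfg$angle_grid
      cc <- basis_coefficients(rf$out, scale_c, cfg$c_floor)
      S <- rowSums(cc)
      k <- 2 * S
      x0 <- as.vector(cc %*% grid) / S
      sc <- scales[[cl]]
      rk <- (k - tgt[, "k"]) / sc["k"]
      rx <- (x0 - tgt[, "x0"]) / sc["x0"]
      rk[!ok] <- 0; rx[!ok] <- 0
      loss <- loss + (sum(rk^2) + sum(rx^2)) / nt
      dk <- 2 * rk / (nt * sc["k"])
      dx0 <- 2 * rx / (nt * sc["x0"])
      # k = 2 sum c; x0 = sum c g / sum c
      dC <- matrix(2 * dk, length(k), length(grid)) +
        (dx0 / S) * (matrix(grid, length(k), length(grid), byrow = TRUE) - x0)
      dRaw <- dC * sigmoid(rf$out) * scale_c
    } else {
      K <- rf$out
      rr <- (K - tgt[, 1:6, drop = FALSE]) / scales$torsion
      rr[!ok, ] <- 0
      loss <- loss + sum(rr * rr) / nt
      dRaw <- 2 * rr / (nt * scales$torsion)
    }
    rb <- mlp_backward(dRaw, rf$cache, model$weights$readout[[rnet_name]], act)
    grads$readout[[rnet_name]] <-
      tree_map2(`+`, grads$readout[[rnet_name]], rb$grad)
    pnet_name <- switch(cl, bonds = "bond", angles = "angle", "torsion")
    pb <- pool_backward(rb$dX, pf$cache, model$weights$pool[[pnet_name]],
                        act, batch$n_atoms, cfg$embedding_dim)
    grads$pool[[pnet_name]] <- tree_map2(`+`, grads$pool[[pnet_name]], pb$grad)
    dH <- dH + pb$dH
  }
  gb <- gnn_backward(dH, cache = gf$cache, weights = model$weights,
                     plan = batch$plan, activation = act)
  grads$gnn <- gb$grads$gnn
  list(loss = as.numeric(loss), grads = grads)
}

# run phases A (closed-form fit) and B (distillation); returns the model
warmstart_model <- function(model, d, tr_idx, tr_batch, epochs = 250L,
                            lr = 3e-3, verbose = FALSE) {
  lf <- linear_reference_fit(d, tr_idx)
  if (verbose) {
    message(sprintf("warm start: surrogate fit RMSE %.5f kcal/mol", lf$rmse))
  }
  targets <- warmstart_targets(lf, d, model, tr_idx)
  st <- adam_init(model$weights)
  for (ep in seq_len(epochs)) {
    lg <- distill_loss_and_grads(model, tr_batch, targets)
    if (!is.finite(lg$loss)) stop("non-finite distillation loss")
    lr_ep <- lr * (0.5 + 0.5 * cos(pi * (ep - 1) / epochs)) + 1e-5
    upd <- adam_step(model$weights, lg$grads, st, lr_ep)
    model$weights <- upd$weights
    st <- upd$state
    if (verbose && ep %% 50 == 0) {
      message(sprintf("  distill epoch %d loss %.6g", ep, lg$loss))
    }
  }
  model
}
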