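# Loss assembly with exact hand-derived backpropagation, the training
# loop (Adam, full batch, early stopping with best-checkpoint restore),
# and evaluation statistics (RMSE / MAPE with molecule-level bootstrap).

#' Precompute a training batch
#'
#' Stacks the selected molecules into one batched graph and precomputes
#' everything the losses need: quadratic-basis features (r - x_b)^2 and
#' (theta - x_b)^2 and cosine features (1 + cos(n phi)) for every
#' (term, snapshot) pair, centered reference valence energies, and the
#' reference charges/types. Since snapshot geometries are fixed during
#' training, the predicted energy is linear in the readout coefficients
#' and these features are reused every epoch.
#'
#' @param d a [snapshot_dataset()].
#' @param model an [mm_model()] (for the feature layout and basis grids).
#' @param mol_idx molecule indices to include.
#' @param with_energy precompute energy features (requires conformations).
#' @return an opaque batch object for [energy_loss()], [loss_and_grads()]
#'   and [fit_model()].
#' @export
build_training_batch <- function(d, model, mol_idx, with_energy = TRUE) {
  cfg <- model$config
  graphs <- lapply(d$molecules[mol_idx], `[[`, "graph")
  topos <- lapply(d$molecules[mol_idx], `[[`, "topo")
  M <- length(graphs)
  plan <- build_graph_plan(graphs, cfg$elements)
  idx <- lapply(seq_len(M), function(m)
    topology_index(topos[[m]], plan$offsets[m]))
  classes <- c("bonds", "angles", "propers", "impropers")
  gidx <- lapply(stats::setNames(classes, classes), function(cl)
    do.call(rbind, lapply(idx, `[[`, cl)))
  batch <- list(plan = plan, gidx = gidx, M = M, mol_idx = mol_idx,
                n_atoms = plan$n)
  # reference charges / types / total charge
  batch$Q <- vapply(graphs, `[[`, numeric(1), "Q")
  rc <- lapply(d$molecules[mol_idx], `[[`, "ref_charges")
  if (!any(vapply(rc, is.null, TRUE))) batch$ref_charges <- unlist(rc)
  rt <- lapply(d$molecules[mol_idx], `[[`, "ref_types")
  if (!any(vapply(rt, is.null, TRUE))) batch$ref_types <- unlist(rt)
  if (!with_energy) return(batch)

  n_snap <- vapply(d$molecules[mol_idx], function(m) length(m$coords), 1L)
  if (any(n_snap == 0)) stop("molecule without conformations in batch")
  if (any(n_snap < 2)) {
    warning("molecule(s) with < 2 snapshots contribute zero centered loss")
  }
  snap_off <- c(0L, cumsum(n_snap))
  S <- snap_off[M + 1]
  feats <- list(bonds = list(), angles = list(), propers = list(),
                impropers = list())
  row_term <- list(bonds = list(), angles = list(), propers = list(),
                   impropers = list())
  row_snap <- row_term
  term_count <- c(bonds = 0L, angles = 0L, propers = 0L, impropers = 0L)
  ref_cent <- numeric(S); snap_mol <- integer(S); w_snap <- numeric(S)
  for (m in seq_len(M)) {
    t <- topos[[m]]
    nm_at <- n_atoms(graphs[[m]])
    ns <- n_snap[m]
    coords <- do.call(rbind, d$molecules[[mol_idx[m]]]$coords)
    snaps <- (snap_off[m] + 1):snap_off[m + 1]
    snap_mol[snaps] <- m
    w_snap[snaps] <- 1 / (M * ns)
    ref_cent[snaps] <- center_energies(d$molecules[[mol_idx[m]]]$valence)
    rep_local <- function(loc_idx) {
      nt <- nrow(loc_idx)
      if (nt == 0) return(NULL)
      off <- rep((seq_len(ns) - 1L) * nm_at, each = nt)
      loc_idx[rep(seq_len(nt), ns), , drop = FALSE] + off
    }
    li <- topology_index(t)
    for (cl in classes) {
      nt <- nrow(li[[cl]])
      if (nt == 0) next
      ridx <- rep_local(li[[cl]])
      x <- if (cl == "bonds") geom_distance(coords, ridx)$r
      else if (cl == "angles") geom_angle(coords, ridx)$theta
      else geom_dihedral(coords, ridx)$phi
      f <- if (cl == "bonds") {
        outer(x, cfg$bond_grid, function(a, b) (a - b)^2)
      } else if (cl == "angles") {
        outer(x, cfg$angle_grid, function(a, b) (a - b)^2)
      } else {
        outer(x, 1:6, function(a, b) 1 + cos(b * a))
      }
      feats[[cl]][[length(feats[[cl]]) + 1L]] <- f
      row_term[[cl]][[length(row_term[[cl]]) + 1L]] <-
        rep(term_count[cl] + seq_len(nt), ns)
      row_snap[[cl]][[length(row_snap[[cl]]) + 1L]] <-
        rep(snaps, each = nt)
      term_count[cl] <- term_count[cl] + nt
    }
  }
  batch$energy <- list(
    feats = lapply(feats, function(x) if (length(x)) do.call(rbind, x) else NULL),
    row_term = lapply(row_term, function(x) unlist(x)),
    row_snap = lapply(row_snap, function(x) unlist(x)),
    term_count = term_count, S = S, snap_mol = snap_mol,
    w_snap = w_snap, ref_cent = ref_cent, n_snap = n_snap)
  batch
}

# --- forward ----------------------------------------------------------------

# forward pass over a batch; heads is a logical list (energy, charge, type)
batch_forward <- function(model, batch, heads, keep_cache = FALSE) {
  cfg <- model$config
  act <- cfg$activation
  gf <- gnn_forward(model$weights, batch$plan$X, batch$plan, act)
  H <- gf$H
  out <- list(H = H)
  cache <- list(gnn = gf$cache)
  if (isTRUE(heads$energy)) {
    eb <- batch$energy
    pools <- list(); raws <- list(); coefs <- list()
    E <- numeric(eb$S)
    for (cl in c("bonds", "angles", "propers", "impropers")) {
      if (is.null(eb$feats[[cl]]) || nrow(batch$gidx[[cl]]) == 0) next
      net <- switch(cl, bonds = model$weights$pool$bond,
                    angles = model$weights$pool$angle,
                    model$weights$pool$torsion)
      pf <- pool_forward(H, batch$gidx[[cl]], net, act)
      rnet <- switch(cl, bonds = model$weights$readout$bond,
                     angles = model$weights$readout$angle,
                     propers = model$weights$readout$torsion,
                     impropers = model$weights$readout$improper)
      rf <- mlp_forward(pf$out, rnet, act)
      cc <- if (cl == "bonds") {
        basis_coefficients(rf$out, cfg$c_scale_bond, cfg$c_floor)
      } else if (cl == "angles") {
        basis_coefficients(rf$out, cfg$c_scale_angle, cfg$c_floor)
      } else rf$out
      rows <- rowSums(eb$feats[[cl]] * cc[eb$row_term[[cl]], , drop = FALSE])
      E <- E + as.vector(index_rowsum(rows, eb$row_snap[[cl]], eb$S))
      pools[[cl]] <- pf; raws[[cl]] <- rf; coefs[[cl]] <- cc
    }
    mean_mol <- as.vector(index_rowsum(E, eb$snap_mol, batch$M)) / eb$n_snap
    E_cent <- E - mean_mol[eb$snap_mol]
    out$E_snap <- E; out$E_cent <- E_cent
    out$coefs <- coefs
    cache$pools <- pools; cache$raws <- raws
  }
  if (isTRUE(heads$charge)) {
    rf <- mlp_forward(H, model$weights$readout$charge, act)
    e <- rf$out[, 1]
    s <- softplus(rf$out[, 2]) + cfg$s_floor
    sol <- solve_charges_grouped(e, s, batch$plan$mol_id, batch$Q)
    out$q <- sol$q; out$e <- e; out$s <- s
    cache$charge <- list(rf = rf$cache, sol = sol, raw = rf$out)
  }
  if (isTRUE(heads$type)) {
    rf <- mlp_forward(H, model$weights$readout$type, act)
    out$logits <- rf$out
    cache$type <- rf$cache
  }
  if (keep_cache) out$cache <- cache
  out
}

#' Combined loss and exact gradients over a batch
#'
#' Energy: per-molecule mean-centered snapshot MSE averaged over
#' molecules. Charge: MSE over atoms, backpropagated through the analytic
#' charge solve. Type: mean per-atom cross-entropy. The returned gradient
#' tree matches the model's weight tree.
#'
#' @param model an [mm_model()].
#' @param batch from [build_training_batch()].
#' @param weights named loss weights (energy, charge, type); zero disables
#'   a head.
#' @return list(loss, parts, grads).
#' @export
loss_and_grads <- function(model, batch,
                           weights = c(energy = 1, charge = 0, type = 0)) {
  cfg <- model$config
  act <- cfg$activation
  heads <- list(energy = weights["energy"] > 0,
                charge = weights["charge"] > 0,
                type = weights["type"] > 0)
  fw <- batch_forward(model, batch, heads, keep_cache = TRUE)
  cache <- fw$cache
  grads <- tree_zeros_like(model$weights)
  dH <- matrix(0, batch$n_atoms, cfg$embedding_dim)
  parts <- c(energy = NA_real_, charge = NA_real_, type = NA_real_)
  loss <- 0
  if (heads$energy) {
    eb <- batch$energy
    res <- fw$E_cent - eb$ref_cent
    parts["energy"] <- sum(eb$w_snap * res * res)
    loss <- loss + weights["energy"] * parts["energy"]
    dE <- 2 * weights["energy"] * eb$w_snap * res
    for (cl in names(cache$pools)) {
      pf <- cache$pools[[cl]]; rf <- cache$raws[[cl]]
      dRows <- dE[eb$row_snap[[cl]]]
      dC <- index_rowsum(eb$feats[[cl]] * dRows, eb$row_term[[cl]],
                         eb$term_count[[cl]])
      dRaw <- if (cl == "bonds") {
        dC * sigmoid(rf$out) * cfg$c_scale_bond
      } else if (cl == "angles") {
        dC * sigmoid(rf$out) * cfg$c_scale_angle
      } else dC
      rnet_name <- switch(cl, bonds = "bond", angles = "angle",
                          propers = "torsion", impropers = "improper")
      rb <- mlp_backward(dRaw, rf$cache, model$weights$readout[[rnet_name]], act)
      grads$readout[[rnet_name] ] <-
        tree_map2(`+`, grads$readout[[rnet_name]], rb$grad)
      pnet_name <- switch(cl, bonds = "bond", angles = "angle", "torsion")
      pb <- pool_backward(rb$dX, pf$cache, model$weights$pool[[pnet_name]],
                          act, batch$n_atoms, cfg$embedding_dim)
      grads$pool[[pnet_name]] <-
        tree_map2(`+`, grads$pool[[pnet_name]], pb$grad)
      dH <- dH + pb$dH
    }
  }
  if (heads$charge) {
    if (is.null(batch$ref_charges)) stop("batch has no reference charges")
    dq0 <- fw$q - batch$ref_charges
    parts["charge"] <- mean(dq0 * dq0)
    loss <- loss + weights["charge"] * parts["charge"]
    dq <- 2 * weights["charge"] * dq0 / length(dq0)
    sb <- solve_charges_backward(dq, fw$e, fw$s, batch$plan$mol_id,
                                 batch$Q, cache$charge$sol)
    dRaw <- cbind(sb$de, sb$ds * sigmoid(cache$charge$raw[, 2]))
    rb <- mlp_backward(dRaw, cache$charge$rf, model$weights$readout$charge, act)
    grads$readout$charge <- tree_map2(`+`, grads$readout$charge, rb$grad)
    dH <- dH + rb$dX
  }
  if (heads$type) {
    if (is.null(batch$ref_types)) stop("batch has no reference types")
    lab <- match(batch$ref_types, cfg$type_vocab)
    if (anyNA(lab)) stop("reference types outside model vocabulary")
    lg <- fw$logits
    mx <- apply(lg, 1, max)
    P <- exp(lg - mx)
    P <- P / rowSums(P)
    n <- nrow(lg)
    picked <- cbind(seq_len(n), lab)
    parts["type"] <- -mean(log(pmax(P[picked], 1e-300)))
    loss <- loss + weights["type"] * parts["type"]
    dLg <- P
    dLg[picked] <- dLg[picked] - 1
    dLg <- dLg * (weights["type"] / n)
    rb <- mlp_backward(dLg, cache$type, model$weights$readout$type, act)
    grads$readout$type <- tree_map2(`+`, grads$readout$type, rb$grad)
    dH <- dH + rb$dX
  }
  gb <- gnn_backward(dH, cache$gnn, model$weights, batch$plan, act)
  grads$gnn <- gb$grads$gnn
  list(loss = as.numeric(loss), parts = parts, grads = grads)
}

#' Energy loss of a model over a batch
#'
#' Mean squared error between per-molecule mean-centered predicted and
#' reference snapshot energies, averaged over molecules.
#'
#' @param model an [mm_model()].
#' @param batch from [build_training_batch()] (with energy features).
#' @return scalar loss (kcal^2/mol^2).
#' @export
energy_loss <- function(model, batch) {
  fw <- batch_forward(model, batch, list(energy = TRUE))
  res <- fw$E_cent - batch$energy$ref_cent
  sum(batch$energy$w_snap * res * res)
}

# --- fitting ----------------------------------------------------------------

#' Training configuration
#'
#' @param loss_weights named weights for the energy/charge/type losses;
#'   zero disables a head; at least one must be positive.
#' @param epochs maximum epochs (full-batch steps).
#' @param lr,lr_min Adam learning rate and its cosine-decay floor.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed RNG seed (reserved; the loop itself is deterministic).
#' @param verbose print progress every 50 epochs.
#' @export
#' @param warm_start for energy training: precede end-to-end optimization
#'   with a closed-form surrogate force-field fit on the training energies
#'   ([linear_reference_fit()]) distilled into the network. Uses training
#'   energies and graphs only.
#' @param warm_epochs,warm_lr distillation epochs and learning rate.
#' @rdname fit_config
#' @export
fit_config <- function(loss_weights = c(energy = 1, charge = 0, type = 0),
                       epochs = 500L, lr = 3e-3, lr_min = 2e-4,
                       patience = 50L, seed = 0L, verbose = FALSE,
                       warm_start = FALSE, warm_epochs = 250L,
                       warm_lr = 3e-3) {
  stopifnot(all(loss_weights >= 0), any(loss_weights > 0), patience >= 1)
  list(loss_weights = loss_weights, epochs = as.integer(epochs), lr = lr,
       lr_min = lr_min, patience = as.integer(patience),
       seed = as.integer(seed), verbose = isTRUE(verbose),
       warm_start = isTRUE(warm_start),
       warm_epochs = as.integer(warm_epochs), warm_lr = warm_lr)
}

#' Fit a model to a split dataset
#'
#' Full-batch Adam with cosine learning-rate decay and early stopping on
#' the validation loss; the weights achieving the best validation loss are
#' restored. Fully deterministic given the model's initialization seed and
#' the configuration.
#'
#' @param model an [mm_model()].
#' @param d a [snapshot_dataset()] with train/validate splits assigned.
#' @param cfg a [fit_config()].
#' @return list(model, log) where `log` is a per-epoch data.frame of train
#'   and validation losses.
#' @export
fit_model <- function(model, d, cfg = fit_config()) {
  w <- cfg$loss_weights
  need_energy <- w["energy"] > 0
  tr_idx <- split_idx(d, "train")
  va_idx <- split_idx(d, "validate")
  tr <- build_training_batch(d, model, tr_idx, with_energy = need_energy)
  va <- build_training_batch(d, model, va_idx, with_energy = need_energy)
  val_loss <- function() {
    lp <- batch_loss_only(model, va, w)
    lp
  }
  if (cfg$epochs == 0) {
    return(list(model = model,
                log = data.frame(epoch = integer(), train = numeric(),
                                 validate = numeric())))
  }
  if (cfg$warm_start && need_energy) {
    model <- warmstart_model(model, d, tr_idx, tr, epochs = cfg$warm_epochs,
                             lr = cfg$warm_lr, verbose = cfg$verbose)
  }
  st <- adam_init(model$weights)
  best <- list(val = Inf, weights = model$weights, epoch = 0L)
  log <- data.frame(epoch = seq_len(cfg$epochs), train = NA_real_,
                    validate = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    lg <- loss_and_grads(model, tr, w)
    if (!is.finite(lg$loss)) {
      bad <- diagnose_nonfinite(model, tr, d, w)
      stop("non-finite training loss at epoch ", ep,
           if (nzchar(bad)) paste0(" (molecule '", bad, "')") else "")
    }
    lr_ep <- cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) *
      (1 + cos(pi * (ep - 1) / cfg$epochs))
    upd <- adam_step(model$weights, lg$grads, st, lr_ep)
    model$weights <- upd$weights
    st <- upd$state
    vl <- val_loss()
    log$train[ep] <- lg$loss
    log$validate[ep] <- vl
    if (vl < best$val) {
      best <- list(val = vl, weights = model$weights, epoch = ep)
    }
    if (cfg$verbose && ep %% 50 == 0) {
      message(sprintf("epoch %4d train %.6g val %.6g (best %.6g @%d)",
                      ep, lg$loss, vl, best$val, best$epoch))
    }
    if (ep - best$epoch >= cfg$patience) break
  }
  model$weights <- best$weights
  list(model = model, log = log[!is.na(log$train), ],
       best_epoch = best$epoch, best_validation = best$val)
}

batch_loss_only <- function(model, batch, w) {
  heads <- list(energy = w["energy"] > 0, charge = w["charge"] > 0,
                type = w["type"] > 0)
  fw <- batch_forward(model, batch, heads)
  loss <- 0
  if (heads$energy) {
    res <- fw$E_cent - batch$energy$ref_cent
    loss <- loss + w["energy"] * sum(batch$energy$w_snap * res * res)
  }
  if (heads$charge) {
    loss <- loss + w["charge"] * mean((fw$q - batch$ref_charges)^2)
  }
  if (heads$type) {
    loss <- loss + w["type"] * type_cross_entropy_idx(
      fw$logits, match(batch$ref_types, model$config$type_vocab))
  }
  as.numeric(loss)
}

type_cross_entropy_idx <- function(logits, lab) {
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), lab)])
}

diagnose_nonfinite <- function(model, batch, d, w) {
  out <- tryCatch({
    fw <- batch_forward(model, batch, list(energy = w["energy"] > 0))
    if (!is.null(fw$E_snap) && any(!is.finite(fw$E_snap))) {
      m <- batch$energy$snap_mol[which(!is.finite(fw$E_snap))[1]]
      d$molecules[[batch$mol_idx[m]]]$graph$name
    } else ""
  }, error = function(e) "")
  out
}

# --- evaluation -------------------------------------------------------------

#' Torsion energy profile from cosine amplitudes
#' @param K numeric vector of six amplitudes (kcal/mol).
#' @param phi angles (rad) at which to evaluate.
#' @return sum_n K_n (1 + cos(n phi)) at each angle.
#' @export
torsion_profile <- function(K, phi = seq(-pi, pi, length.out = 360)) {
  stopifnot(length(K) == 6)
  out <- numeric(length(phi))
  for (n in 1:6) out <- out + K[n] * (1 + cos(n * phi))
  out
}

#' Evaluate a trained model on one split
#'
#' Centered-energy RMSE over the split's snapshots, and mean absolute
#' percentage error (MAPE) of the recovered bond/angle parameters against
#' the reference parameter set, with 95% confidence intervals from
#' molecule-level bootstrap. Torsion amplitudes are excluded from MAPE
#' because the six-periodicity expansion makes them degenerate.
#'
#' @param model an [mm_model()].
#' @param d a split [snapshot_dataset()] with reference parameters.
#' @param split which split to evaluate.
#' @param n_boot bootstrap replicates.
#' @param boot_seed seed for the bootstrap resampling.
#' @return object of class `metric_report`: data.frame with columns
#'   quantity, estimate, ci_lo, ci_hi, n.
#' @export
evaluate_model <- function(model, d, split = "test", n_boot = 1000L,
                           boot_seed = 0L) {
  idx <- split_idx(d, split)
  has_energy <- !is.null(d$molecules[[idx[1]]]$coords)
  batch <- build_training_batch(d, model, idx, with_energy = has_energy)
  fw <- batch_forward(model, batch, list(energy = has_energy))
  per_mol <- list()
  if (has_energy) {
    eb <- batch$energy
    sq <- (fw$E_cent - eb$ref_cent)^2
    per_mol$energy_sq <- split(sq, eb$snap_mol)
  }
  # parameter recovery per molecule
  mape_terms <- list(k_r = list(), r_0 = list(), k_theta = list(),
                     theta_0 = list())
  if (!is.null(fw$coefs$bonds)) {
    kb <- basis_to_harmonic(fw$coefs$bonds, model$config$bond_grid)
    ka <- basis_to_harmonic(fw$coefs$angles, model$config$angle_grid)
    bond_mol <- rep(seq_along(idx), vapply(d$molecules[idx], function(m)
      nrow(m$topo$bonds), 1L))
    angle_mol <- rep(seq_along(idx), vapply(d$molecules[idx], function(m)
      nrow(m$topo$angles), 1L))
    ref_b <- do.call(rbind, lapply(d$molecules[idx], function(m)
      m$ref_params$bonds[, c("k_r", "r_0")]))
    ref_a <- do.call(rbind, lapply(d$molecules[idx], function(m)
      m$ref_params$angles[, c("k_theta", "theta_0")]))
    mape_terms$k_r <- split(abs(kb$k - ref_b$k_r) / abs(ref_b$k_r), bond_mol)
    mape_terms$r_0 <- split(abs(kb$x0 - ref_b$r_0) / abs(ref_b$r_0), bond_mol)
    mape_terms$k_theta <- split(abs(ka$k - ref_a$k_theta) / abs(ref_a$k_theta),
                                angle_mol)
    th <- pmin(pmax(ka$x0, 1e-6), pi - 1e-6)
    mape_terms$theta_0 <- split(abs(th - ref_a$theta_0) / abs(ref_a$theta_0),
                                angle_mol)
  }
  boot_stat <- function(per_mol_vals, stat) {
    point <- stat(unlist(per_mol_vals))
    M <- length(per_mol_vals)
    reps <- with_seed(boot_seed, vapply(seq_len(n_boot), function(b) {
      stat(unlist(per_mol_vals[sample.int(M, M, replace = TRUE)]))
    }, numeric(1)))
    c(point, stats::quantile(reps, c(0.025, 0.975), names = FALSE))
  }
  rows <- list()
  if (has_energy) {
    st <- boot_stat(per_mol$energy_sq, function(x) sqrt(mean(x)))
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "energy_rmse", estimate = st[1], ci_lo = min(st[2], st[1]),
      ci_hi = max(st[3], st[1]), n = length(unlist(per_mol$energy_sq)))
  }
  for (nm in names(mape_terms)) {
    if (!length(mape_terms[[nm]])) next
    st <- boot_stat(mape_terms[[nm]], mean)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("mape_", nm), estimate = st[1],
      ci_lo = min(st[2], st[1]), ci_hi = max(st[3], st[1]),
      n = length(unlist(mape_terms[[nm]])))
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("metric_report", "data.frame")
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric report (95% molecule-bootstrap CIs):\n")
  for (r in seq_len(nrow(x))) {
    cat(sprintf("  %-14s %10.6f  [%.6f, %.6f]  (n = %d)\n",
                x$quantity[r], x$estimate[r], x$ci_lo[r], x$ci_hi[r], x$n[r]))
  }
  invisible(x)
}
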