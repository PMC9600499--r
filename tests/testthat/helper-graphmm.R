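# Shared fixtures and independent oracles for the test suite.

# small model for fast tests
tiny_model <- function(seed = 0L, ...) {
  mm_model(mm_config(n_layers = 3L, hidden_dim = 12L, embedding_dim = 12L,
                     pooling_hidden = 12L, pooling_dim = 12L,
                     readout_hidden = 12L, seed = seed, ...))
}

# a deterministic pool of random valence-legal molecules
test_molecules <- local({
  cache <- NULL
  function(n = 10L) {
    if (is.null(cache)) {
      cache <<- generate_molecules(generator_config(
        n_molecules = 25L, heavy_range = c(3L, 9L), seed = 421L))
    }
    cache[seq_len(n)]
  }
})

# relabel the atoms of a molecular graph by a permutation `perm`
# (perm[old_index_1based] = new 0-based index)
permute_graph <- function(g, perm0) {
  n <- n_atoms(g)
  stopifnot(length(perm0) == n)
  atoms <- g$atoms[order(perm0), , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- data.frame(i = perm0[g$bonds$i + 1L], j = perm0[g$bonds$j + 1L],
                      order = g$bonds$order)
  mol_graph(atoms, bonds, name = g$name, perceive = FALSE)
}

# --- independent enumeration oracle ----------------------------------------
# brute force over all atom tuples with explicit symmetry deduplication;
# shares no code with enumerate_terms()
oracle_enumerate <- function(g) {
  n <- n_atoms(g)
  bonded <- matrix(FALSE, n, n)
  for (b in seq_len(nrow(g$bonds))) {
    bonded[g$bonds$i[b] + 1, g$bonds$j[b] + 1] <- TRUE
    bonded[g$bonds$j[b] + 1, g$bonds$i[b] + 1] <- TRUE
  }
  bonds <- list(); angles <- list(); propers <- list(); sites <- 0L
  for (i in 1:n) for (j in 1:n) {
    if (i < j && bonded[i, j]) bonds[[length(bonds) + 1]] <- c(i, j)
  }
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i < k && i != j && j != k && bonded[i, j] && bonded[j, k]) {
      angles[[length(angles) + 1]] <- c(i, j, k)
    }
  }
  seen <- character(0)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
    if (length(unique(c(i, j, k, l))) == 4 &&
        bonded[i, j] && bonded[j, k] && bonded[k, l]) {
      key <- paste(min(paste(c(i, j, k, l), collapse = ","),
                       paste(c(l, k, j, i), collapse = ",")))
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        propers[[length(propers) + 1]] <- c(i, j, k, l)
      }
    }
  }
  for (k in 1:n) if (sum(bonded[k, ]) == 3) sites <- sites + 1L
  list(n_bonds = length(bonds), n_angles = length(angles),
       n_propers = length(propers), n_improper_sites = sites)
}

# --- independent constrained quadratic minimizer ---------------------------
# minimize sum e_i q_i + (s_i/2) q_i^2 s.t. sum q = Q, by unconstrained
# BFGS over the first n-1 charges (the last is Q - sum of the others)
oracle_charges <- function(e, s, Q) {
  n <- length(e)
  if (n == 1) return(Q)
  fn <- function(qh) {
    q <- c(qh, Q - sum(qh))
    sum(e * q + 0.5 * s * q * q)
  }
  gr <- function(qh) {
    q <- c(qh, Q - sum(qh))
    g <- e + s * q
    g[seq_len(n - 1)] - g[n]
  }
  start <- rep(Q / n, n - 1)
  res <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  # polish: the objective is quadratic, so one Newton step with a
  # finite-difference Hessian lands on the exact minimizer
  H <- stats::optimHess(res$par, fn, gr)
  qh <- res$par - solve(H, gr(res$par))
  c(qh, Q - sum(qh))
}

# direct two-evaluation pooling oracle (re-implements Janossy sum by hand)
oracle_pool <- function(h, tuple0, net, activation) {
  ev <- function(x) {
    hh <- graphmm:::act_forward(x %*% net$l1$W + matrix(net$l1$b, 1, length(net$l1$b),
                                              byrow = TRUE), activation)
    hh %*% net$l2$W + matrix(net$l2$b, 1, length(net$l2$b), byrow = TRUE)
  }
  fwd <- matrix(as.vector(t(h[tuple0 + 1, , drop = FALSE])), nrow = 1)
  rev_ <- matrix(as.vector(t(h[rev(tuple0) + 1, , drop = FALSE])), nrow = 1)
  ev(fwd) + ev(rev_)
}

# benzene and friends parsed once
fixture_mol <- local({
  cache <- list()
  function(smiles) {
    if (is.null(cache[[smiles]])) cache[[smiles]] <<- parse_molecule(smiles)
    cache[[smiles]]
  }
})
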