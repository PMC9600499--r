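# Synthetic data: seeded valence-legal C/H/O molecule generation (phenyl
# rings, alkanes, ethers, alcohols, carbonyls; no 3-/4-membered rings),
# repeat polymers for the parameter-stability experiment, and thermal
# conformations from overdamped Langevin sampling on the toy potential.

#' Generator configuration
#'
#' @param n_molecules number of molecules to generate.
#' @param heavy_range min/max heavy-atom (C, O) count.
#' @param elements heavy-element set (only C/O supported by the built-in
#'   chemistry rules; H is implicit).
#' @param ring_sizes allowed ring sizes for aliphatic ring closures
#'   (default 5-8; 3- and 4-membered rings are never produced).
#' @param p_aromatic probability a molecule is grown from a benzene core.
#' @param p_ring probability of one extra aliphatic ring closure.
#' @param p_oxygen probability a new heavy atom is oxygen.
#' @param p_carbonyl probability an oxygen attaches as a C=O double bond.
#' @param n_snapshots conformations per molecule.
#' @param temperature sampling temperature (K).
#' @param seed mandatory RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_molecules = 100L,
                             heavy_range = c(3L, 12L),
                             elements = c("C", "H", "O"),
                             ring_sizes = 5:8,
                             p_aromatic = 0.25,
                             p_ring = 0.2,
                             p_oxygen = 0.25,
                             p_carbonyl = 0.3,
                             n_snapshots = 100L,
                             temperature = 300,
                             seed) {
  if (missing(seed)) stop("generator seed is mandatory")
  stopifnot(n_molecules >= 1, heavy_range[1] >= 1,
            heavy_range[2] >= heavy_range[1],
            all(ring_sizes >= 5), n_snapshots >= 1, temperature > 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 heavy_range = as.integer(heavy_range),
                 elements = elements, ring_sizes = as.integer(ring_sizes),
                 p_aromatic = p_aromatic, p_ring = p_ring,
                 p_oxygen = p_oxygen, p_carbonyl = p_carbonyl,
                 n_snapshots = as.integer(n_snapshots),
                 temperature = temperature, seed = as.integer(seed)),
            class = "generator_config")
}

FREE_VALENCE <- c(C = 4L, O = 2L)

# one random valence-legal molecule; called inside a seeded RNG scope
random_molecule <- function(cfg, name) {
  n_heavy <- sample(cfg$heavy_range[1]:cfg$heavy_range[2], 1)
  el <- character(0)
  bi <- integer(0); bj <- integer(0); bo <- character(0)
  free <- integer(0)
  add_bond <- function(a, b, order_num) {
    bi <<- c(bi, a); bj <<- c(bj, b)
    bo <<- c(bo, c("single", "double")[order_num])
    free[a] <<- free[a] - order_num
    free[b] <<- free[b] - order_num
  }
  in_benzene <- logical(0)
  if (stats::runif(1) < cfg$p_aromatic && n_heavy >= 6 &&
      "C" %in% cfg$elements) {
    el <- rep("C", 6); free <- rep(4L, 6); in_benzene <- rep(TRUE, 6)
    for (s in 1:6) add_bond(s, if (s == 6) 1L else s + 1L,
                            if (s %% 2 == 1) 2L else 1L)
  } else {
    el <- "C"; free <- 4L; in_benzene <- FALSE
  }
  while (length(el) < n_heavy) {
    open <- which(free > 0)
    if (!length(open)) break
    parent <- if (length(open) == 1) open else sample(open, 1)
    new_el <- if ("O" %in% cfg$elements && el[parent] == "C" &&
                  stats::runif(1) < cfg$p_oxygen) "O" else "C"
    el <- c(el, new_el); free <- c(free, FREE_VALENCE[new_el])
    in_benzene <- c(in_benzene, FALSE)
    a <- length(el)
    dbl <- new_el == "O" && !in_benzene[parent] && free[parent] >= 2 &&
      !any(bo[bi == parent | bj == parent] == "double") &&
      stats::runif(1) < cfg$p_carbonyl
    add_bond(parent, a, if (dbl) 2L else 1L)
  }
  # optional aliphatic ring closure (creates a ring of an allowed size)
  if (stats::runif(1) < cfg$p_ring && length(el) >= min(cfg$ring_sizes)) {
    adj <- vector("list", length(el))
    for (b in seq_along(bi)) {
      adj[[bi[b]]] <- c(adj[[bi[b]]], bj[b])
      adj[[bj[b]]] <- c(adj[[bj[b]]], bi[b])
    }
    dist_from <- function(s) {
      d <- rep(Inf, length(el)); d[s] <- 0; q <- s
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        for (w in adj[[v]]) if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; q <- c(q, w) }
      }
      d
    }
    cand <- which(free > 0 & !in_benzene)
    pairs <- list()
    for (a in cand) {
      d <- dist_from(a)
      for (b in cand[cand > a]) {
        if ((d[b] + 1) %in% cfg$ring_sizes &&
            !(el[a] == "O" && el[b] == "O")) {
          pairs[[length(pairs) + 1L]] <- c(a, b)
        }
      }
    }
    if (length(pairs)) {
      pick <- pairs[[if (length(pairs) == 1) 1L else sample(length(pairs), 1)]]
      add_bond(pick[1], pick[2], 1L)
    }
  }
  # fill remaining valence with hydrogens
  n_h0 <- length(el)
  for (a in seq_len(n_h0)) {
    while (free[a] > 0) {
      el <- c(el, "H"); free <- c(free, 0L)
      bi <- c(bi, a); bj <- c(bj, length(el)); bo <- c(bo, "single")
      free[a] <- free[a] - 1L
    }
  }
  mol_graph(data.frame(element = el),
            data.frame(i = bi - 1L, j = bj - 1L, order = bo),
            name = name)
}

#' Generate random valence-legal C/H/O molecules
#'
#' Connected graphs with explicit hydrogens, exact valences (C 4, O 2,
#' H 1), optional benzene cores and aliphatic rings of size 5-8 only, and
#' optional carbonyls/hydroxyls/ethers. Deterministic per seed.
#'
#' @param cfg a [generator_config()].
#' @return list of [mol_graph()].
#' @export
generate_molecules <- function(cfg) {
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_molecules), function(i) {
      for (try in 1:20) {
        g <- tryCatch(random_molecule(cfg, sprintf("gen-%04d", i)),
                      error = function(e) NULL)
        if (!is.null(g)) return(g)
      }
      stop("molecule generation failed repeatedly at index ", i)
    })
  })
}

#' Linear repeat polymer with distinct end caps
#'
#' A C/H/O ether-alcohol repeat unit [-CH2-CH(OH)-O-] chained n times
#' between a methyl start cap and a methyl end cap, emulating a capped
#' repeat-residue biopolymer on the default element alphabet. Atoms carry
#' a `unit` column: 0 for the start cap, 1..n for repeat units, n+1 for
#' the end cap.
#'
#' @param n_repeats number of repeat units (>= 1).
#' @return a [mol_graph()] with per-atom `unit` metadata.
#' @export
generate_polymer <- function(n_repeats) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  el <- character(0); unit <- integer(0)
  bi <- integer(0); bj <- integer(0)
  add_atom <- function(e, u) {
    el <<- c(el, e); unit <<- c(unit, u)
    length(el)
  }
  add_bond <- function(a, b) { bi <<- c(bi, a); bj <<- c(bj, b) }
  cap <- add_atom("C", 0L)
  for (h in 1:3) add_bond(cap, add_atom("H", 0L))
  tail_atom <- cap
  for (u in seq_len(n_repeats)) {
    c1 <- add_atom("C", u)
    add_bond(tail_atom, c1)
    for (h in 1:2) add_bond(c1, add_atom("H", u))
    c2 <- add_atom("C", u)
    add_bond(c1, c2)
    add_bond(c2, add_atom("H", u))
    o_h <- add_atom("O", u)          # hydroxyl substituent
    add_bond(c2, o_h)
    add_bond(o_h, add_atom("H", u))
    o_b <- add_atom("O", u)          # backbone ether oxygen
    add_bond(c2, o_b)
    tail_atom <- o_b
  }
  endc <- add_atom("C", n_repeats + 1L)
  add_bond(tail_atom, endc)
  for (h in 1:3) add_bond(endc, add_atom("H", n_repeats + 1L))
  g <- mol_graph(data.frame(element = el),
                 data.frame(i = bi - 1L, j = bj - 1L, order = "single"),
                 name = sprintf("polymer-n%d", n_repeats))
  g$atoms$unit <- unit
  g
}

# --- initial geometry -------------------------------------------------------

# BFS tree layout at ideal bond lengths with randomized branch directions;
# ring-closure strain is relaxed by the minimizer afterwards
tree_layout <- function(g, params) {
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  r0 <- rep(1.4, n)  # per-bond lookup below
  bond_key <- paste(pmin(g$bonds$i, g$bonds$j), pmax(g$bonds$i, g$bonds$j))
  bond_r0 <- function(a, b) {
    k <- match(paste(min(a, b) - 1L, max(a, b) - 1L), bond_key)
    params$bonds$r_0[k]
  }
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- 0
  parent <- rep(NA_integer_, n)
  queue <- 1L
  placed <- c(TRUE, rep(FALSE, n - 1))
  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v * v))
  }
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (placed[w]) next
      dir <- if (is.na(parent[v])) rand_unit() else {
        away <- coords[v, ] - coords[parent[v], ]
        away <- away / sqrt(sum(away * away))
        d <- away * 0.7 + rand_unit()
        d / sqrt(sum(d * d))
      }
      coords[w, ] <- coords[v, ] + dir * bond_r0(v, w)
      parent[w] <- v
      placed[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  coords + 0.05 * matrix(stats::rnorm(3 * n), n, 3)  # break collinearity
}

# rotatable bonds: single, acyclic, both ends with >= 2 neighbors; returns
# list of (i, j, moving-atom index set) with 1-based ids, where "moving"
# is the connected component containing j after deleting the bond
rotatable_bonds <- function(g) {
  adj <- adjacency_list(g)
  deg <- lengths(adj)
  out <- list()
  in_ring <- rowSums(as.matrix(g$atoms[paste0("ring", 3:8)])) > 0
  for (b in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[b] != "single") next
    i <- g$bonds$i[b] + 1L; j <- g$bonds$j[b] + 1L
    if (deg[i] < 2 || deg[j] < 2) next
    if (in_ring[i] && in_ring[j]) next  # conservative ring-bond skip
    # component containing j with the i-j edge removed
    seen <- logical(n_atoms(g)); seen[i] <- TRUE; seen[j] <- TRUE
    queue <- j; comp <- j
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w)
        }
      }
    }
    if (length(comp) < n_atoms(g)) {  # acyclic split
      out[[length(out) + 1L]] <- list(i = i, j = j, moving = setdiff(comp, j))
    }
  }
  out
}

# rotate `moving` atoms around the i->j axis by angle phi
rotate_about_bond <- function(coords, i, j, moving, phi) {
  if (!length(moving)) return(coords)
  axis <- coords[j, ] - coords[i, ]
  axis <- axis / sqrt(sum(axis^2))
  x <- sweep(coords[moving, , drop = FALSE], 2, coords[j, ])
  c1 <- cos(phi); s1 <- sin(phi)
  dotp <- as.vector(x %*% axis)
  crossp <- cbind(axis[2] * x[, 3] - axis[3] * x[, 2],
                  axis[3] * x[, 1] - axis[1] * x[, 3],
                  axis[1] * x[, 2] - axis[2] * x[, 1])
  xr <- x * c1 + crossp * s1 + outer(dotp * (1 - c1), axis)
  coords[moving, ] <- sweep(xr, 2, coords[j, ], "+")
  coords
}

# damped gradient descent with per-step displacement cap
minimize_coords <- function(sys, coords, n_steps = 400, max_disp = 0.15,
                            tol = 0.5) {
  step <- 1e-3
  ev <- ff_eval(sys, coords, forces = TRUE)
  for (it in seq_len(n_steps)) {
    g <- ev$grad
    gmax <- max(abs(g))
    if (gmax < tol) break
    disp <- -g * min(step, max_disp / gmax)
    trial <- coords + disp
    ev_t <- tryCatch(ff_eval(sys, trial, forces = TRUE), error = function(e) NULL)
    if (!is.null(ev_t) && sum(ev_t$total) <= sum(ev$total)) {
      coords <- trial; ev <- ev_t
      step <- min(step * 1.25, 5e-3)
    } else {
      step <- step / 2
      if (step < 1e-8) break
    }
  }
  coords
}

#' Sample thermal conformations on a reference potential
#'
#' An initial geometry is built by tree layout at ideal bond lengths and
#' relaxed on the supplied potential. `n_chains` chains are then started
#' from Gaussian-perturbed copies of the minimum and evolved with
#' overdamped Langevin dynamics (position update
#' x <- x - D grad E + sqrt(2 D kT) xi) at the requested temperature;
#' after `burn_in` steps, every `thin`-th frame of every chain is recorded
#' until `n_snapshots` conformations are collected. Snapshot energies are
#' evaluated on the same potential. With `burn_in = 0` and `thin = 0` all
#' snapshots equal the minimized structure.
#'
#' @param g a [mol_graph()].
#' @param params its reference `parameter_set`.
#' @param n_snapshots number of snapshots.
#' @param temperature Kelvin.
#' @param seed RNG seed.
#' @param n_chains independent chains per molecule.
#' @param burn_in equilibration steps before recording.
#' @param thin steps between recorded frames.
#' @param D position-diffusion step dt/gamma (A^2 mol/kcal).
#' @param perturb stddev (A) of the per-chain initial perturbation.
#' @param t optional precomputed topology.
#' @return list with `coords` (list of n x 3 matrices), `energies` (total,
#'   kcal/mol), `components` (snapshot x 6 matrix) and `valence` (bond +
#'   angle + torsion energies).
#' @export
sample_conformations <- function(g, params, n_snapshots = 100L,
                                 temperature = 300, seed = 0L,
                                 n_chains = 10L, burn_in = 60L, thin = 15L,
                                 D = 2.5e-4, perturb = 0.08, t = NULL) {
  if (is.null(t)) t <- enumerate_terms(g)
  sample_conformations_many(list(g), list(params), list(t),
                            n_snapshots = n_snapshots,
                            temperature = temperature, seed = seed,
                            n_chains = n_chains, burn_in = burn_in,
                            thin = thin, D = D, perturb = perturb)[[1]]
}

#' Sample conformations for many molecules in one vectorized run
#'
#' Same protocol as [sample_conformations()], but molecules are processed
#' in groups as one block-diagonal system so minimization and Langevin
#' steps are single array operations. One seed governs the whole run.
#'
#' @param graphs list of [mol_graph()].
#' @param params_list matching list of reference `parameter_set`s.
#' @param topos optional matching list of topologies.
#' @param group_size molecules per block.
#' @inheritParams sample_conformations
#' @return list (one element per molecule) of [sample_conformations()]
#'   results.
#' @export
sample_conformations_many <- function(graphs, params_list, topos = NULL,
                                      n_snapshots = 100L, temperature = 300,
                                      seed = 0L, n_chains = 10L,
                                      burn_in = 60L, thin = 15L, D = 2.5e-4,
                                      perturb = 0.08, group_size = 25L) {
  if (is.null(topos)) topos <- lapply(graphs, enumerate_terms)
  M <- length(graphs)
  out <- vector("list", M)
  kT <- KB_KCAL * temperature
  noise_sd <- sqrt(2 * D * kT)
  n_chains <- min(n_chains, n_snapshots)
  per_chain <- ceiling(n_snapshots / n_chains)
  with_seed(seed, {
    for (g0 in seq_len(ceiling(M / group_size))) {
      sel <- ((g0 - 1) * group_size + 1):min(g0 * group_size, M)
      sys1 <- lapply(sel, function(m)
        compile_system(params_list[[m]], topos[[m]], "full"))
      nat <- vapply(sel, function(m) n_atoms(graphs[[m]]), 1L)
      x0 <- do.call(rbind, lapply(seq_along(sel), function(s)
        tree_layout(graphs[[sel[s]]], params_list[[sel[s]]])))
      comb1 <- combine_systems(sys1)
      x0 <- minimize_coords(comb1, x0)
      # split minimized coords per molecule, replicate to chains
      off1 <- c(0L, cumsum(nat))
      combC <- combine_systems(lapply(sys1, replicate_system,
                                      n_rep = n_chains))
      do_sample <- burn_in + thin > 0
      X <- do.call(rbind, lapply(seq_along(sel), function(s) {
        xm <- x0[(off1[s] + 1):off1[s + 1], , drop = FALSE]
        g <- graphs[[sel[s]]]
        rb <- if (do_sample) rotatable_bonds(g) else list()
        # each chain starts from its own torsion-randomized conformer so
        # snapshots sample conformers, not just one local basin
        do.call(rbind, lapply(seq_len(n_chains), function(ch) {
          xc <- xm
          if (ch > 1) {
            for (r in rb) {
              # rotamer-like torsion randomization: staggered wells + noise
              dphi <- sample(c(-2, 0, 2) * pi / 3, 1) + stats::rnorm(1, 0, 0.3)
              xc <- rotate_about_bond(xc, r$i, r$j, r$moving, dphi)
            }
          }
          xc
        }))
      }))
      frames <- vector("list", per_chain)
      if (do_sample) {
        # relax rotated conformers (clash removal), then thermalize
        X <- minimize_coords(combC, X, n_steps = 250, tol = 1)
        X <- X + perturb * matrix(stats::rnorm(length(X)), nrow(X), 3)
        step_once <- function(X) {
          gr <- ff_eval(combC, X, forces = TRUE)$grad
          gr[gr > 2000] <- 2000; gr[gr < -2000] <- -2000
          X - D * gr + noise_sd * matrix(stats::rnorm(length(X)), nrow(X), 3)
        }
        for (s in seq_len(burn_in)) X <- step_once(X)
        for (f in seq_len(per_chain)) {
          if (f > 1) for (s in seq_len(thin)) X <- step_once(X)
          frames[[f]] <- X
        }
      } else {
        frames <- rep(list(X), per_chain)
      }
      # per molecule: collect chain-major snapshots, trim to n_snapshots
      for (s in seq_along(sel)) {
        rows0 <- off1[s] * n_chains  # start of molecule s block in X
        coords <- vector("list", n_chains * per_chain)
        k <- 0L
        for (ch in seq_len(n_chains)) for (f in seq_len(per_chain)) {
          k <- k + 1L
          a0 <- rows0 + (ch - 1L) * nat[s]
          coords[[k]] <- frames[[f]][(a0 + 1):(a0 + nat[s]), , drop = FALSE]
        }
        coords <- coords[seq_len(n_snapshots)]
        sysE <- replicate_system(sys1[[s]], n_snapshots)
        ev <- ff_eval(sysE, do.call(rbind, coords), forces = FALSE)
        comp <- ev$components
        if (!all(is.finite(comp))) {
          stop("non-finite snapshot energy for '", graphs[[sel[s]]]$name, "'")
        }
        out[[sel[s]]] <- list(
          coords = coords, energies = ev$total, components = comp,
          valence = rowSums(comp[, c("bond", "angle", "proper", "improper"),
                                 drop = FALSE]))
      }
    }
  })
  out
}
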