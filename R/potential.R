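# Differentiable MM potential: energies, per-component breakdowns and
# analytic coordinate gradients. All geometry code is vectorized over term
# lists and over stacked replicas of a system (used by the conformation
# sampler), with coordinates in Angstrom and energies in kcal/mol.

rownorm3 <- function(x) sqrt(x[, 1]^2 + x[, 2]^2 + x[, 3]^2)
dot3 <- function(a, b) a[, 1] * b[, 1] + a[, 2] * b[, 2] + a[, 3] * b[, 3]
cross3 <- function(a, b) {
  out <- matrix(0, nrow(a), 3)
  out[, 1] <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  out[, 2] <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  out[, 3] <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  out
}

# --- internal geometry with gradients --------------------------------------

# idx: m x 2 (1-based); returns r and optionally d(r)/d(p1), d(r)/d(p2)
geom_distance <- function(coords, idx, grad = FALSE) {
  d <- coords[idx[, 2], , drop = FALSE] - coords[idx[, 1], , drop = FALSE]
  r <- rownorm3(d)
  if (!grad) return(list(r = r))
  u <- d / r
  list(r = r, g1 = -u, g2 = u)
}

# idx: m x 3, central atom second
geom_angle <- function(coords, idx, grad = FALSE) {
  u <- coords[idx[, 1], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  v <- coords[idx[, 3], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  nu <- rownorm3(u); nv <- rownorm3(v)
  cu <- u / nu; cv <- v / nv
  cosb <- pmin(pmax(dot3(cu, cv), -1), 1)
  sinb <- rownorm3(cross3(cu, cv))
  theta <- atan2(sinb, cosb)
  if (!grad) return(list(theta = theta))
  s <- pmax(sinb, 1e-12)  # guard exactly linear angles
  g1 <- (cosb * cu - cv) / (nu * s)
  g3 <- (cosb * cv - cu) / (nv * s)
  list(theta = theta, g1 = g1, g2 = -(g1 + g3), g3 = g3)
}

# idx: m x 4 in torsion order p1-p2-p3-p4; signed angle in (-pi, pi]
geom_dihedral <- function(coords, idx, grad = FALSE) {
  p1 <- coords[idx[, 1], , drop = FALSE]; p2 <- coords[idx[, 2], , drop = FALSE]
  p3 <- coords[idx[, 3], , drop = FALSE]; p4 <- coords[idx[, 4], , drop = FALSE]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- rownorm3(b2)
  x <- dot3(n1, n2)
  y <- dot3(cross3(n1, n2), b2 / nb2)
  phi <- atan2(y, x)
  if (!grad) return(list(phi = phi))
  sn1 <- pmax(rowSums(n1 * n1), 1e-24)
  sn2 <- pmax(rowSums(n2 * n2), 1e-24)
  gA <- -(nb2 / sn1) * n1           # d phi / d p1
  gD <- (nb2 / sn2) * n2            # d phi / d p4
  c12 <- dot3(b1, b2) / (nb2 * nb2)
  c32 <- dot3(b3, b2) / (nb2 * nb2)
  gB <- -(1 + c12) * gA + c32 * gD
  gC <- c12 * gA - (1 + c32) * gD
  list(phi = phi, g1 = gA, g2 = gB, g3 = gC, g4 = gD)
}

# --- compiled systems -------------------------------------------------------

# Pre-assemble index matrices and parameter vectors from a parameter_set +
# term_topology so energies/forces over (replicated) coordinates are pure
# array operations.
compile_system <- function(p, t, nb_mode = c("full", "none"),
                           scale14_elec = 1 / 1.2, scale14_lj = 0.5) {
  nb_mode <- match.arg(nb_mode)
  n <- nrow(p$atoms)
  sys <- list(n_atoms = n, n_rep = 1L, N = n)
  sys$bonds <- list(idx = as.matrix(t$bonds[, c("i", "j")]) + 1L,
                    k = p$bonds$k_r, x0 = p$bonds$r_0)
  sys$angles <- list(idx = as.matrix(t$angles[, c("i", "j", "k")]) + 1L,
                     k = p$angles$k_theta, x0 = p$angles$theta_0)
  Kp <- as.matrix(p$propers[, paste0("K", 1:6)])
  if (nrow(t$propers) == 0) Kp <- matrix(0, 0, 6)
  sys$propers <- list(idx = as.matrix(t$propers[, c("i", "j", "k", "l")]) + 1L,
                      K = Kp)
  Ki <- as.matrix(p$impropers[, paste0("K", 1:6)])
  if (nrow(t$impropers) == 0) Ki <- matrix(0, 0, 6)
  sys$impropers <- list(idx = as.matrix(t$impropers[, c("k", "i", "j", "l")]) + 1L,
                        K = Ki)
  if (nb_mode == "full" && nrow(t$nonbonded)) {
    keep <- t$nonbonded$class %in% c("scaled_14", "full")
    nb <- t$nonbonded[keep, , drop = FALSE]
    i <- nb$i + 1L; j <- nb$j + 1L
    s14 <- nb$class == "scaled_14"
    eps <- sqrt(p$atoms$epsilon[i] * p$atoms$epsilon[j]) *
      ifelse(s14, scale14_lj, 1)
    sig <- (p$atoms$sigma[i] + p$atoms$sigma[j]) / 2
    qq <- COULOMB_KCAL * p$atoms$q[i] * p$atoms$q[j] *
      ifelse(s14, scale14_elec, 1)
    sys$nb <- list(idx = cbind(i, j), eps = eps, sig = sig, qq = qq)
  } else {
    sys$nb <- list(idx = matrix(0L, 0, 2), eps = numeric(0),
                   sig = numeric(0), qq = numeric(0))
  }
  for (nm in c("bonds", "angles", "propers", "impropers", "nb")) {
    sys[[nm]]$rid <- rep(1L, nrow(sys[[nm]]$idx))
  }
  build_scatter_plan(sys)
}

# Precompute the force scatter-add: all term-column atom indices in a fixed
# canonical order, their sorting permutation, and segment boundaries, so
# per-evaluation accumulation is a cumsum over presorted rows.
build_scatter_plan <- function(sys) {
  n_cols <- c(bonds = 2L, angles = 3L, propers = 4L, impropers = 4L, nb = 2L)
  idx_all <- integer(0); ranges <- list(); pos <- 0L
  for (nm in names(n_cols)) {
    m <- nrow(sys[[nm]]$idx)
    for (c in seq_len(n_cols[[nm]])) {
      ranges[[paste0(nm, c)]] <- if (m) (pos + 1L):(pos + m) else integer(0)
      if (m) idx_all <- c(idx_all, sys[[nm]]$idx[, c])
      pos <- pos + m
    }
  }
  ord <- order(idx_all)
  sorted <- idx_all[ord]
  ends <- c(which(diff(sorted) != 0L), length(sorted))
  sys$splan <- list(ranges = ranges, ord = ord, ends = ends,
                    atoms = sorted[ends], total = pos)
  sys
}

# block-diagonal union of (possibly replicated) systems; replica ids are
# offset so each input system's replicas stay distinct
combine_systems <- function(sys_list) {
  out <- list(n_atoms = NA_integer_,
              n_rep = sum(vapply(sys_list, `[[`, 1L, "n_rep")),
              N = sum(vapply(sys_list, `[[`, 1L, "N")))
  atom_off <- 0L; rep_off <- 0L
  parts <- list()
  for (sys in sys_list) {
    for (nm in c("bonds", "angles", "propers", "impropers", "nb")) {
      term <- sys[[nm]]
      term$idx <- term$idx + atom_off
      term$rid <- term$rid + rep_off
      parts[[nm]] <- c(parts[[nm]], list(term))
    }
    atom_off <- atom_off + sys$N
    rep_off <- rep_off + sys$n_rep
  }
  for (nm in c("bonds", "angles", "propers", "impropers", "nb")) {
    fields <- setdiff(names(parts[[nm]][[1]]), "splan")
    out[[nm]] <- lapply(stats::setNames(fields, fields), function(f) {
      vals <- lapply(parts[[nm]], `[[`, f)
      if (is.matrix(vals[[1]])) do.call(rbind, vals) else unlist(vals)
    })
  }
  build_scatter_plan(out)
}

# stack n_rep non-interacting copies of a system (replica r uses atom rows
# (r-1)*n_atoms + 1 .. r*n_atoms of the stacked coordinate matrix)
replicate_system <- function(sys, n_rep) {
  if (n_rep == 1) return(sys)
  n <- sys$n_atoms
  stopifnot(sys$n_rep == 1L)
  rep_idx <- function(idx) {
    m <- nrow(idx)
    if (m == 0) return(list(idx = idx, rid = integer(0)))
    off <- rep((seq_len(n_rep) - 1L) * n, each = m)
    list(idx = idx[rep(seq_len(m), n_rep), , drop = FALSE] + off,
         rid = rep(seq_len(n_rep), each = m))
  }
  out <- sys
  for (nm in c("bonds", "angles", "propers", "impropers", "nb")) {
    r <- rep_idx(sys[[nm]]$idx)
    out[[nm]]$idx <- r$idx
    out[[nm]]$rid <- r$rid
    for (f in setdiff(names(sys[[nm]]), c("idx", "rid"))) {
      v <- sys[[nm]][[f]]
      out[[nm]][[f]] <- if (is.matrix(v)) {
        v[rep(seq_len(nrow(v)), n_rep), , drop = FALSE]
      } else rep(v, n_rep)
    }
  }
  out$n_rep <- as.integer(n_rep)
  out$N <- as.integer(n * n_rep)
  build_scatter_plan(out)
}

# component energies (n_rep x 6 matrix) and optional gradient (N x 3)
ff_eval <- function(sys, coords, forces = FALSE) {
  n_rep <- sys$n_rep
  N <- sys$N
  comp <- matrix(0, n_rep, 6,
                 dimnames = list(NULL, c("bond", "angle", "proper",
                                         "improper", "lj", "coulomb")))
  V <- if (forces) matrix(0, sys$splan$total, 3) else NULL
  rid_of <- function(term) term$rid
  acc <- function(comp_name, rid, e) {
    if (length(e)) {
      comp[, comp_name] <<- comp[, comp_name] +
        as.vector(index_rowsum(e, rid, n_rep))
    }
  }
  scatter <- function(tag, g) {
    V[sys$splan$ranges[[tag]], ] <<- g
  }
  # harmonic bonds
  if (nrow(sys$bonds$idx)) {
    gg <- geom_distance(coords, sys$bonds$idx, grad = forces)
    dx <- gg$r - sys$bonds$x0
    acc("bond", rid_of(sys$bonds), 0.5 * sys$bonds$k * dx * dx)
    if (forces) {
      de <- sys$bonds$k * dx
      scatter("bonds1", de * gg$g1)
      scatter("bonds2", de * gg$g2)
    }
  }
  # harmonic angles
  if (nrow(sys$angles$idx)) {
    gg <- geom_angle(coords, sys$angles$idx, grad = forces)
    dx <- gg$theta - sys$angles$x0
    acc("angle", rid_of(sys$angles), 0.5 * sys$angles$k * dx * dx)
    if (forces) {
      de <- sys$angles$k * dx
      for (c in 1:3) scatter(paste0("angles", c), de * gg[[paste0("g", c)]])
    }
  }
  # cosine-series torsions (proper and improper streams); cos/sin of the
  # higher periodicities come from the Chebyshev-style recurrence
  for (nm in c("propers", "impropers")) {
    term <- sys[[nm]]
    if (!nrow(term$idx)) next
    gg <- geom_dihedral(coords, term$idx, grad = forces)
    m <- nrow(term$idx)
    e <- numeric(m); dedphi <- numeric(m)
    c1 <- cos(gg$phi); s1 <- sin(gg$phi)
    cprev <- rep(1, m); sprev <- numeric(m)
    ccur <- c1; scur <- s1
    for (nper in 1:6) {
      Kn <- term$K[, nper]
      e <- e + Kn * (1 + ccur)
      if (forces) dedphi <- dedphi - Kn * nper * scur
      cnext <- 2 * c1 * ccur - cprev
      snext <- 2 * c1 * scur - sprev
      cprev <- ccur; sprev <- scur
      ccur <- cnext; scur <- snext
    }
    acc(if (nm == "propers") "proper" else "improper", rid_of(term), e)
    if (forces) {
      for (c in 1:4) scatter(paste0(nm, c), dedphi * gg[[paste0("g", c)]])
    }
  }
  # nonbonded
  if (nrow(sys$nb$idx)) {
    gg <- geom_distance(coords, sys$nb$idx, grad = forces)
    r <- gg$r
    if (any(r < 1e-6)) {
      stop("overlapping atoms in nonbonded pair (r < 1e-6 A)")
    }
    sr6 <- (sys$nb$sig / r)^6
    e_lj <- 4 * sys$nb$eps * (sr6 * sr6 - sr6)
    e_cl <- sys$nb$qq / r
    rid <- rid_of(sys$nb)
    acc("lj", rid, e_lj)
    acc("coulomb", rid, e_cl)
    if (forces) {
      de <- 4 * sys$nb$eps * (-12 * sr6 * sr6 + 6 * sr6) / r - e_cl / r
      scatter("nb1", de * gg$g1)
      scatter("nb2", de * gg$g2)
    }
  }
  grad <- NULL
  if (forces) {
    grad <- matrix(0, N, 3)
    sp <- sys$splan
    Vo <- V[sp$ord, , drop = FALSE]
    for (c in 1:3) {
      cs <- cumsum(Vo[, c])
      grad[sp$atoms, c] <- diff(c(0, cs[sp$ends]))
    }
  }
  list(components = comp, total = rowSums(comp), grad = grad)
}

# --- public API -------------------------------------------------------------

#' Evaluate the MM energy of one conformation
#'
#' Bond: sum (k_r/2)(r - r_0)^2; angle: sum (k_theta/2)(theta - theta_0)^2;
#' torsions: sum_n K_n (1 + cos(n phi)) over proper and improper tuples;
#' Lennard-Jones 12-6 with Lorentz-Berthelot combining; Coulomb q_i q_j / r
#' in kcal/mol. 1-2 and 1-3 pairs are excluded, 1-4 pairs scaled
#' (electrostatics x 1/1.2, LJ x 1/2 by default, Amber-family convention);
#' all-pairs gas-phase treatment, no cutoffs.
#'
#' @param p a `parameter_set` from [assign_parameters()] or
#'   [assign_reference()].
#' @param t the molecule's [enumerate_terms()] topology.
#' @param coords numeric n_atoms x 3 matrix (Angstrom).
#' @param nb_mode "full" (default) or "none" (valence terms only).
#' @param scale14_elec,scale14_lj 1-4 scaling factors.
#' @return object of class `energy_breakdown`: list with components
#'   `bond`, `angle`, `proper`, `improper`, `lj`, `coulomb`, `total`
#'   (kcal/mol), where total equals the sum of components.
#' @export
evaluate_energy <- function(p, t, coords, nb_mode = c("full", "none"),
                            scale14_elec = 1 / 1.2, scale14_lj = 0.5) {
  nb_mode <- match.arg(nb_mode)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (nrow(coords) != nrow(p$atoms)) {
    stop("coordinate rows (", nrow(coords), ") do not match atom count (",
         nrow(p$atoms), ")")
  }
  sys <- compile_system(p, t, nb_mode, scale14_elec, scale14_lj)
  ev <- ff_eval(sys, coords, forces = FALSE)
  out <- as.list(ev$components[1, ])
  out$total <- ev$total[1]
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy breakdown (kcal/mol):\n")
  for (nm in c("bond", "angle", "proper", "improper", "lj", "coulomb",
               "total")) {
    cat(sprintf("  %-9s %12.6f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Analytic gradient of the MM energy with respect to coordinates
#' @inheritParams evaluate_energy
#' @return n_atoms x 3 matrix, kcal/mol/Angstrom.
#' @export
energy_gradient <- function(p, t, coords, nb_mode = c("full", "none"),
                            scale14_elec = 1 / 1.2, scale14_lj = 0.5) {
  nb_mode <- match.arg(nb_mode)
  sys <- compile_system(p, t, nb_mode, scale14_elec, scale14_lj)
  ff_eval(sys, as.matrix(coords), forces = TRUE)$grad
}

#' Center per-snapshot energies of one molecule to zero mean
#' @param values numeric vector of snapshot energies.
#' @return the values minus their mean.
#' @export
center_energies <- function(values) {
  if (length(values) == 0) stop("no energies to center")
  values - mean(values)
}

# --- XYZ I/O ----------------------------------------------------------------

#' Read a (multi-frame) XYZ file
#' @param path XYZ file; a comment line containing `energy=<x>` populates
#'   the returned `energies`.
#' @return list(coords = list of n x 3 matrices, elements, energies).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  coords <- list(); energies <- numeric(0); elements <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- as.integer(trimws(lines[pos]))
    comment <- lines[pos + 1L]
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    elements <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    coords[[length(coords) + 1L]] <- xyz
    en <- regmatches(comment, regexpr("energy=([-0-9.eE+]+)", comment))
    energies <- c(energies,
                  if (length(en)) as.numeric(sub("energy=", "", en)) else NA_real_)
    pos <- pos + 2L + n
  }
  list(coords = coords, elements = elements, energies = energies)
}

#' Write conformations to a multi-frame XYZ file
#' @param coords list of n x 3 matrices (or a single matrix).
#' @param elements element symbols.
#' @param path output path.
#' @param energies optional per-frame energies stored on comment lines.
#' @export
write_xyz <- function(coords, elements, path, energies = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(coords)) {
    m <- coords[[f]]
    writeLines(as.character(nrow(m)), con)
    writeLines(if (!is.null(energies)) {
      sprintf("frame %d energy=%.10g", f, energies[f])
    } else sprintf("frame %d", f), con)
    writeLines(sprintf("%-2s %16.8f %16.8f %16.8f",
                       elements, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
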