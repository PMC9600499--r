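# A deterministic rule-based reference force field over C/H/O chemistry.
# It plays the role a legacy general force field plays for real molecules:
# an ordered rule list maps atoms to 8 discrete types, parameters are
# looked up per type tuple, and reference charges come from per-type
# electronegativity/hardness solved with the same constrained quadratic
# model the learned charge readout uses. Parameter tables are generated in
# closed form: class-typical base values plus a deterministic per-tuple
# jitter derived from a string hash, so every type tuple is covered and
# two molecules sharing a type tuple always share parameters exactly.

#' The eight toy atom types
#'
#' Vocabulary of the rule-based toy typer; also the natural `type_vocab`
#' for the classification readout.
#' @export
TOY_TYPES <- c("C_sp3", "C_aromatic", "C_carbonyl", "O_hydroxyl",
               "O_ether", "O_carbonyl", "H_on_C", "H_on_O")

# deterministic hash of a string onto [0, 1)
hash01 <- function(key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 100003
  h / 100003
}

# symmetric jitter in [-1, 1] keyed by string
hash_pm <- function(key) 2 * hash01(key) - 1

#' The packaged toy reference force field
#'
#' @return object of class `toy_forcefield` carrying the type vocabulary,
#'   per-type Lennard-Jones and electronegativity/hardness tables, and the
#'   improper table. Bond/angle/torsion parameters are produced on demand
#'   per type tuple (deterministically).
#' @export
toy_forcefield <- function() {
  lj <- data.frame(
    type = TOY_TYPES,
    epsilon = c(0.1094, 0.0860, 0.0860, 0.2104, 0.1700, 0.2100,
                0.0157, 0.0157),
    sigma = c(3.3997, 3.3997, 3.3997, 3.0665, 3.0000, 2.9599,
              2.6495, 0.6000)
  )
  chg <- data.frame(
    type = TOY_TYPES,
    e0 = c(35, 40, 55, 75, 72, 80, 28, 45),   # electronegativity, kcal/mol/e
    s0 = c(65, 70, 60, 35, 40, 38, 90, 55)    # hardness, kcal/mol/e^2
  )
  imp <- data.frame(
    type = c("C_aromatic", "C_carbonyl"),
    K2 = c(1.5, 3.5)                            # per tuple, kcal/mol
  )
  structure(list(types = TOY_TYPES, lj = lj, charge = chg, improper = imp),
            class = "toy_forcefield")
}

#' @export
print.toy_forcefield <- function(x, ...) {
  cat("<toy_forcefield: 8 types over C/H/O, rule-based typer,",
      "hash-jittered parameter tables>\n")
  invisible(x)
}

#' Assign toy atom types by the ordered rule list
#'
#' Rules, first match wins: H bonded to O -> H_on_O; H -> H_on_C;
#' aromatic C -> C_aromatic; C double-bonded to O -> C_carbonyl;
#' saturated C -> C_sp3; O with a double bond -> O_carbonyl; O bonded to
#' H -> O_hydroxyl; remaining O -> O_ether.
#'
#' @param ff a [toy_forcefield()].
#' @param g a [mol_graph()].
#' @return character vector of types, one per atom.
#' @export
toy_atom_types <- function(ff, g) {
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  el <- g$atoms$element
  # per-atom double-bond partners
  dbl_to <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[b] == "double") {
      i <- g$bonds$i[b] + 1L; j <- g$bonds$j[b] + 1L
      dbl_to[[i]] <- c(dbl_to[[i]], j)
      dbl_to[[j]] <- c(dbl_to[[j]], i)
    }
  }
  types <- character(n)
  for (a in seq_len(n)) {
    nb_el <- el[adj[[a]]]
    types[a] <- if (el[a] == "H") {
      if ("O" %in% nb_el) "H_on_O" else if ("C" %in% nb_el) "H_on_C" else NA
    } else if (el[a] == "C") {
      if (g$atoms$aromatic[a]) "C_aromatic"
      else if (any(el[dbl_to[[a]]] == "O")) "C_carbonyl"
      else if (g$atoms$hybridization[a] == "sp3") "C_sp3"
      else NA
    } else if (el[a] == "O") {
      if (length(dbl_to[[a]])) "O_carbonyl"
      else if ("H" %in% nb_el) "O_hydroxyl"
      else "O_ether"
    } else NA
    if (is.na(types[a])) {
      stop("atom ", a - 1L, " (", el[a], ") in molecule '", g$name,
           "' is not typeable by the toy force field")
    }
  }
  types
}

# --- per-tuple parameter rules ---------------------------------------------

toy_elem <- function(type) substr(type, 1, 1)

toy_bond_params <- function(t1, t2) {
  key <- paste(sort(c(t1, t2)), collapse = "|")
  pair <- sort(c(t1, t2))
  e <- paste(sort(c(toy_elem(t1), toy_elem(t2))), collapse = "")
  base <- if (identical(pair, c("C_carbonyl", "O_carbonyl"))) {
    c(r0 = 1.22, k = 650)
  } else if (identical(pair, c("C_aromatic", "C_aromatic"))) {
    c(r0 = 1.39, k = 470)
  } else if (e == "CC") c(r0 = 1.525, k = 330)
  else if (e == "CO") c(r0 = 1.42, k = 370)
  else if (e == "CH") c(r0 = 1.09, k = 340)
  else if (e == "HO") c(r0 = 0.96, k = 560)
  else if (e == "OO") c(r0 = 1.46, k = 300)
  else stop("toy force field: no bond rule for ", key)
  data.frame(k_r = base["k"] * (1 + 0.20 * hash_pm(paste0("bk|", key))),
             r_0 = base["r0"] * (1 + 0.015 * hash_pm(paste0("br|", key))),
             row.names = NULL)
}

toy_angle_params <- function(ti, tj, tk) {
  ends <- sort(c(ti, tk))
  key <- paste(ends[1], tj, ends[2], sep = "|")
  th0 <- if (tj %in% c("C_aromatic", "C_carbonyl")) 2.0944
  else if (toy_elem(tj) == "O") 1.8937
  else 1.9111
  n_h <- sum(c(ti, tk) %in% c("H_on_C", "H_on_O"))
  k0 <- c(85, 55, 38)[n_h + 1]
  data.frame(k_theta = k0 * (1 + 0.20 * hash_pm(paste0("ak|", key))),
             theta_0 = th0 * (1 + 0.02 * hash_pm(paste0("a0|", key))),
             row.names = NULL)
}

# 1-3 nonzero cosine amplitudes per proper type tuple, mixed signs
toy_proper_params <- function(ti, tj, tk, tl) {
  tup <- c(ti, tj, tk, tl)
  rev_tup <- rev(tup)
  if (paste(rev_tup, collapse = "|") < paste(tup, collapse = "|")) {
    tup <- rev_tup
  }
  key <- paste(tup, collapse = "|")
  K <- numeric(6)
  n_terms <- 1L + (floor(hash01(paste0("tn|", key)) * 3)) %% 3L
  for (m in seq_len(n_terms)) {
    per <- 1L + floor(hash01(paste0("tp|", key, "|", m)) * 6) %% 6L
    K[per] <- round(1.2 * hash_pm(paste0("ta|", key, "|", m)), 4)
  }
  out <- as.data.frame(matrix(K, 1))
  names(out) <- paste0("K", 1:6)
  out
}

toy_improper_params <- function(ff, center_type) {
  K <- numeric(6)
  hit <- match(center_type, ff$improper$type)
  if (!is.na(hit)) K[2] <- ff$improper$K2[hit]
  out <- as.data.frame(matrix(K, 1))
  names(out) <- paste0("K", 1:6)
  out
}

#' Assign reference parameters, types and charges with the toy force field
#'
#' Deterministic look-up of every MM term of a molecule: parameters are
#' constant on type-tuple classes, and reference charges solve the per-type
#' electronegativity/hardness model under the molecule's total charge.
#'
#' @param ff a [toy_forcefield()].
#' @param g a [mol_graph()].
#' @param t optional precomputed [enumerate_terms()] topology.
#' @return list with `params` (a `parameter_set`), `types` (character) and
#'   `charges` (numeric, summing to the molecular charge).
#' @export
assign_reference <- function(ff, g, t = NULL) {
  if (is.null(t)) t <- enumerate_terms(g)
  types <- toy_atom_types(ff, g)
  ty <- function(col0) types[col0 + 1L]
  bonds <- if (nrow(t$bonds)) {
    cbind(t$bonds, do.call(rbind, Map(function(i, j) toy_bond_params(ty(i), ty(j)),
                                      t$bonds$i, t$bonds$j)))
  } else cbind(t$bonds, data.frame(k_r = numeric(0), r_0 = numeric(0)))
  angles <- if (nrow(t$angles)) {
    cbind(t$angles, do.call(rbind, Map(function(i, j, k)
      toy_angle_params(ty(i), ty(j), ty(k)),
      t$angles$i, t$angles$j, t$angles$k)))
  } else cbind(t$angles, data.frame(k_theta = numeric(0), theta_0 = numeric(0)))
  empty_K <- function(df) {
    K <- as.data.frame(matrix(numeric(0), 0, 6))
    names(K) <- paste0("K", 1:6)
    cbind(df, K)
  }
  propers <- if (nrow(t$propers)) {
    cbind(t$propers, do.call(rbind, Map(function(i, j, k, l)
      toy_proper_params(ty(i), ty(j), ty(k), ty(l)),
      t$propers$i, t$propers$j, t$propers$k, t$propers$l)))
  } else empty_K(t$propers)
  impropers <- if (nrow(t$impropers)) {
    cbind(t$impropers, do.call(rbind, lapply(t$impropers$k, function(k0)
      toy_improper_params(ff, ty(k0)))))
  } else empty_K(t$impropers)
  lj <- ff$lj[match(types, ff$lj$type), c("epsilon", "sigma")]
  e0 <- ff$charge$e0[match(types, ff$charge$type)]
  s0 <- ff$charge$s0[match(types, ff$charge$type)]
  q <- solve_charges(e0, s0, g$Q)
  ps <- list(bonds = bonds, angles = angles, propers = propers,
             impropers = impropers,
             atoms = data.frame(element = g$atoms$element,
                                epsilon = lj$epsilon, sigma = lj$sigma, q = q),
             meta = list(name = g$name, Q = g$Q,
                         provenance = list(lj = "toy_reference",
                                           charges = "toy_reference"),
                         convention = "E = (k/2) (x - x0)^2; torsion sum K_n (1 + cos(n phi))",
                         units = list(energy = "kcal/mol", length = "Angstrom",
                                      angle = "rad", charge = "e"),
                         version = "paramset-1"))
  class(ps) <- "parameter_set"
  list(params = ps, types = types, charges = q)
}
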