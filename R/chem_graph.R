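# Molecular graphs: parsing, chemical perception, atom features, and
# enumeration of MM interaction terms.
#
# Conventions: atom indices are 0-based and contiguous in every public data
# structure and serialized format (they are shifted to 1-based only at the
# point of indexing R objects). Angles store the central atom in position 2
# of 3; improper tuples store the central atom first.

# default element alphabet; anything outside is a hard error
DEFAULT_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

# standard valences; allowed valence is base + formal charge
BASE_VALENCE <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 3,
                  F = 1, Cl = 1, Br = 1, I = 1)

BOND_ORDER_NUM <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

#' Construct a molecular graph
#'
#' Builds the annotated graph used throughout the package: per-atom element,
#' formal charge, aromaticity, hybridization and ring-size membership, plus
#' a bond list with categorical orders. Aromaticity, hybridization and ring
#' flags are (re)perceived from the connectivity unless `perceive = FALSE`.
#'
#' @param atoms data.frame with at least `element` and optionally
#'   `formal_charge`; perception fills the remaining annotation columns.
#' @param bonds data.frame with 0-based columns `i`, `j` and `order`
#'   (one of "single", "double", "triple", "aromatic").
#' @param name molecule name.
#' @param perceive run ring/aromaticity/hybridization perception.
#' @param validate check valences and graph invariants.
#' @return an object of class `mol_graph` with fields `atoms`, `bonds`,
#'   `Q` (net charge, e) and `name`.
#' @export
mol_graph <- function(atoms, bonds, name = "mol", perceive = TRUE,
                      validate = TRUE) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  atoms$element <- as.character(atoms$element)
  if (nrow(bonds)) {
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  g <- structure(
    list(atoms = atoms, bonds = bonds,
         Q = sum(atoms$formal_charge), name = name),
    class = "mol_graph"
  )
  if (perceive) g <- perceive_chemistry(g)
  if (validate) validate_mol_graph(g)
  g
}

#' Number of atoms in a molecular graph
#' @param g a `mol_graph`.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph '%s': %d atoms, %d bonds, Q = %+d>\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$Q))
  invisible(x)
}

# adjacency list, 1-based atom ids
adjacency_list <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    i <- g$bonds$i + 1L; j <- g$bonds$j + 1L
    for (b in seq_along(i)) {
      adj[[i[b]]] <- c(adj[[i[b]]], j[b])
      adj[[j[b]]] <- c(adj[[j[b]]], i[b])
    }
  }
  lapply(adj, sort)
}

validate_mol_graph <- function(g) {
  n <- n_atoms(g)
  if (n < 1) stop("molecule '", g$name, "' has no atoms")
  bad <- setdiff(g$atoms$element, DEFAULT_ELEMENTS)
  if (length(bad)) {
    stop("molecule '", g$name, "': unsupported element(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(g$bonds)) {
    if (any(g$bonds$i == g$bonds$j)) stop("self-bond in '", g$name, "'")
    if (any(g$bonds$i < 0 | g$bonds$j >= n)) stop("bond index out of range")
    key <- paste(g$bonds$i, g$bonds$j)
    if (anyDuplicated(key)) stop("duplicate bond in '", g$name, "'")
  }
  # connectivity
  if (n > 1) {
    adj <- adjacency_list(g)
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (!all(seen)) stop("molecule '", g$name, "' is not connected")
  }
  # valence check on numeric bond orders
  val <- numeric(n)
  if (nrow(g$bonds)) {
    ord <- BOND_ORDER_NUM[g$bonds$order]
    val <- index_rowsum(c(ord, ord), c(g$bonds$i + 1L, g$bonds$j + 1L), n)[, 1]
  }
  allowed <- BASE_VALENCE[g$atoms$element] + g$atoms$formal_charge
  if (any(abs(val - allowed) > 1e-9)) {
    k <- which(abs(val - allowed) > 1e-9)[1]
    stop(sprintf(
      "molecule '%s': valence violation at atom %d (%s): total bond order %.1f, allowed %.1f",
      g$name, k - 1L, g$atoms$element[k], val[k], allowed[k]))
  }
  if (g$Q != sum(g$atoms$formal_charge)) stop("net charge inconsistent")
  invisible(TRUE)
}

# --- ring perception --------------------------------------------------------

# all simple cycles of length 3..max_size, as lists of 1-based atom vectors
find_rings <- function(g, max_size = 8L) {
  adj <- adjacency_list(g)
  nb_ <- nrow(g$bonds)
  seen <- new.env(parent = emptyenv())
  rings <- list()
  if (nb_ == 0) return(rings)
  bi <- g$bonds$i + 1L; bj <- g$bonds$j + 1L
  for (b in seq_len(nb_)) {
    u <- bi[b]; v <- bj[b]
    # DFS for simple paths u -> v of length <= max_size-1, avoiding edge (u,v)
    stack <- list(list(path = u, last = u))
    while (length(stack)) {
      st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (length(st$path) > max_size) next
      for (w in adj[[st$last]]) {
        if (st$last == u && w == v) next  # skip the closing edge itself
        if (w == v && length(st$path) >= 2) {
          cyc <- sort(c(st$path, v))
          key <- paste(cyc, collapse = ",")
          if (!exists(key, envir = seen)) {
            assign(key, TRUE, envir = seen)
            rings[[length(rings) + 1L]] <- c(st$path, v)
          }
        } else if (!(w %in% st$path) && length(st$path) < max_size - 1L) {
          stack[[length(stack) + 1L]] <- list(path = c(st$path, w), last = w)
        }
      }
    }
  }
  rings
}

# simplified Hueckel perception on simple rings of size 5-7; kekulized
# integer bond orders in, per-atom aromatic flags and ring-bond labels out
perceive_chemistry <- function(g) {
  n <- n_atoms(g)
  rings <- find_rings(g, 8L)
  for (k in 3:8) g$atoms[[paste0("ring", k)]] <- FALSE
  for (r in rings) {
    k <- length(r)
    if (k <= 8) g$atoms[[paste0("ring", k)]][r] <- TRUE
  }
  # bond order bookkeeping (kekulized orders expected at this point)
  nb <- nrow(g$bonds)
  has_double <- logical(n); has_triple <- logical(n); n_double <- integer(n)
  if (nb) {
    for (b in seq_len(nb)) {
      o <- g$bonds$order[b]
      a1 <- g$bonds$i[b] + 1L; a2 <- g$bonds$j[b] + 1L
      if (o == "double") {
        has_double[c(a1, a2)] <- TRUE
        n_double[c(a1, a2)] <- n_double[c(a1, a2)] + 1L
      }
      if (o == "triple") has_triple[c(a1, a2)] <- TRUE
    }
  }
  aromatic <- logical(n)
  if (nb) {
    bond_key <- paste(g$bonds$i, g$bonds$j)
    ord <- g$bonds$order
    already_ar <- ord == "aromatic"  # honour generator-supplied labels
    aromatic_bond <- already_ar
    aromatic[g$bonds$i[already_ar] + 1L] <- TRUE
    aromatic[g$bonds$j[already_ar] + 1L] <- TRUE
    for (r in rings) {
      k <- length(r)
      if (k < 5 || k > 7) next
      ring_set <- r
      pi_e <- 0L; ok <- TRUE
      for (a in ring_set) {
        el <- g$atoms$element[a]
        # in-ring double bond?
        nb_ring <- intersect(which_neighbors(g, a), ring_set)
        in_ring_double <- FALSE
        for (w in nb_ring) {
          bidx <- match(paste(min(a, w) - 1L, max(a, w) - 1L), bond_key)
          if (!is.na(bidx) && ord[bidx] == "double") in_ring_double <- TRUE
        }
        if (in_ring_double) {
          pi_e <- pi_e + 1L          # 1 per atom = 2 per in-ring double bond
        } else if (el %in% c("O", "N", "S") && !has_double[a] && !has_triple[a]) {
          pi_e <- pi_e + 2L          # lone-pair donor
        } else if (has_double[a]) {
          pi_e <- pi_e + 0L          # exocyclic double bond: no contribution
        } else {
          ok <- FALSE; break         # saturated atom breaks conjugation
        }
      }
      if (ok && pi_e == 6L) {
        aromatic[ring_set] <- TRUE
        # label the ring bonds aromatic
        m <- length(ring_set)
        path <- r
        for (s in seq_len(m)) {
          a <- path[s]; b2 <- path[if (s == m) 1L else s + 1L]
          bidx <- match(paste(min(a, b2) - 1L, max(a, b2) - 1L), bond_key)
          if (!is.na(bidx)) aromatic_bond[bidx] <- TRUE
        }
      }
    }
    g$bonds$order[aromatic_bond] <- "aromatic"
  }
  g$atoms$aromatic <- aromatic
  # hybridization from pre-aromatization multiplicities + aromatic flag
  hyb <- character(n)
  for (a in seq_len(n)) {
    el <- g$atoms$element[a]
    if (el %in% c("C", "N", "O", "S")) {
      if (has_triple[a] || n_double[a] >= 2) hyb[a] <- "sp"
      else if (has_double[a] || aromatic[a]) hyb[a] <- "sp2"
      else hyb[a] <- "sp3"
    } else hyb[a] <- "other"
  }
  g$atoms$hybridization <- hyb
  g
}

which_neighbors <- function(g, a1) {
  # a1 is 1-based
  i <- g$bonds$i + 1L; j <- g$bonds$j + 1L
  sort(c(j[i == a1], i[j == a1]))
}

# --- parsing ----------------------------------------------------------------

CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

#' Parse a molecule from SMILES or an SDF (V2000) block
#'
#' Conversion and initial perception are delegated to OpenBabel (via
#' ChemmineOB); hydrogens are made explicit, then valences are validated
#' and aromaticity/hybridization/ring membership are annotated.
#'
#' @param text a SMILES string or the text of one SDF record.
#' @param format "smiles" or "sdf".
#' @param name molecule name (defaults to the SDF title or the SMILES).
#' @return a [mol_graph()].
#' @export
parse_molecule <- function(text, format = c("smiles", "sdf"), name = NULL) {
  format <- match.arg(format)
  src <- if (format == "smiles") "SMI" else "SDF"
  sdf_txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      src, "SDF", source = text,
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))),
    error = function(e) {
      stop("cannot parse ", format, " input '",
           substr(gsub("\n.*", "", text), 1, 60), "': ", conditionMessage(e))
    })
  if (!nzchar(gsub("[[:space:]]", "", sdf_txt))) {
    stop("cannot parse ", format, " input '",
         substr(gsub("\n.*", "", text), 1, 60), "': empty conversion result")
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  charge <- CHARGE_CODE[as.character(ab[, "C6"])]
  charge[is.na(charge)] <- 0L
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  order_map <- c(`1` = "single", `2` = "double", `3` = "triple", `4` = "aromatic")
  bonds <- data.frame(
    i = as.integer(bb[, 1]) - 1L,
    j = as.integer(bb[, 2]) - 1L,
    order = unname(order_map[as.character(as.integer(bb[, 3]))]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(bonds$order))) stop("unsupported bond order in input")
  if (is.null(name)) {
    name <- if (format == "smiles") gsub("[[:space:]].*$", "", text) else {
      ttl <- strsplit(sdf_txt, "\n")[[1]][1]
      if (nzchar(trimws(ttl))) trimws(ttl) else "mol"
    }
  }
  atoms <- data.frame(element = element, formal_charge = as.integer(charge),
                      stringsAsFactors = FALSE)
  mol_graph(atoms, bonds, name = name)
}

#' Read molecules from a SMILES file (one per line)
#' @param path file path; lines may carry an optional name after whitespace.
#' @return list of [mol_graph()].
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    parse_molecule(parts[1], "smiles",
                   name = if (length(parts) > 1) parts[2] else parts[1])
  })
}

#' Read molecules from an SDF (V2000) file
#' @param path file path with one or more `$$$$`-terminated records.
#' @return list of [mol_graph()].
#' @export
read_sdf_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", txt)
  if (!length(ends)) ends <- length(txt)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    rec <- paste(txt[starts[k]:ends[k]], collapse = "\n")
    out[[k]] <- tryCatch(parse_molecule(rec, "sdf"), error = function(e) {
      stop("SDF record ", k, " in '", path, "': ", conditionMessage(e))
    })
  }
  out
}

# --- atom features ----------------------------------------------------------

HYB_LEVELS <- c("sp", "sp2", "sp3", "other")

#' Per-atom input features for the graph neural network
#'
#' One row per atom: one-hot element over the configured alphabet, one-hot
#' hybridization (sp/sp2/sp3/other), aromaticity flag, formal charge, and
#' ring-membership flags for ring sizes 3-8. Layout version "fl-1".
#'
#' @param g a [mol_graph()].
#' @param elements element alphabet (columns of the one-hot block).
#' @return numeric matrix, atoms x features, with column names.
#' @export
featurize_atoms <- function(g, elements = DEFAULT_ELEMENTS) {
  n <- n_atoms(g)
  bad <- setdiff(g$atoms$element, elements)
  if (length(bad)) stop("element(s) outside configured alphabet: ",
                        paste(bad, collapse = ", "))
  elem <- outer(g$atoms$element, elements, "==") * 1
  colnames(elem) <- paste0("elem_", elements)
  hyb <- outer(g$atoms$hybridization, HYB_LEVELS, "==") * 1
  colnames(hyb) <- paste0("hyb_", HYB_LEVELS)
  rings <- sapply(3:8, function(k) g$atoms[[paste0("ring", k)]] * 1)
  if (n == 1) rings <- matrix(rings, nrow = 1)
  colnames(rings) <- paste0("ring", 3:8)
  out <- cbind(elem, hyb,
               aromatic = g$atoms$aromatic * 1,
               formal_charge = as.numeric(g$atoms$formal_charge),
               rings)
  stopifnot(all(rowSums(elem) == 1), all(rowSums(hyb) == 1))
  out
}

feature_dim <- function(elements = DEFAULT_ELEMENTS) length(elements) + 12L

# --- term enumeration -------------------------------------------------------

#' Enumerate MM interaction terms of a molecular graph
#'
#' Bonds as ordered pairs (i<j); angles as (i,j,k) with central atom j and
#' i<k; proper torsions (i,j,k,l) unique up to full reversal (canonical
#' direction has j<k); improper sites at every atom with exactly three
#' neighbors, each contributing the three tuples (k,i,j,l), (k,j,l,i),
#' (k,l,i,j) with central atom k first; and nonbonded pairs labeled by
#' graph distance: excluded_12, excluded_13, scaled_14, full.
#'
#' @param g a [mol_graph()].
#' @return object of class `term_topology` with data.frame fields `bonds`,
#'   `angles`, `propers`, `impropers` (with `site` id), `nonbonded`.
#' @export
enumerate_terms <- function(g) {
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  b <- g$bonds[, c("i", "j")]
  rownames(b) <- NULL

  angles <- list()
  for (jc in seq_len(n)) {
    nb <- adj[[jc]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      angles[[length(angles) + 1L]] <-
        data.frame(i = cmb[1, ] - 1L, j = jc - 1L, k = cmb[2, ] - 1L)
    }
  }
  angles <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(), j = integer(), k = integer())
  angles <- angles[order(angles$i, angles$j, angles$k), , drop = FALSE]
  rownames(angles) <- NULL

  propers <- list()
  if (nrow(b)) {
    for (e in seq_len(nrow(b))) {
      jc <- b$i[e] + 1L; kc <- b$j[e] + 1L  # canonical direction: j < k
      for (i0 in setdiff(adj[[jc]], kc)) {
        for (l0 in setdiff(adj[[kc]], jc)) {
          if (i0 == l0) next  # degenerate (3-ring)
          propers[[length(propers) + 1L]] <-
            c(i0 - 1L, jc - 1L, kc - 1L, l0 - 1L)
        }
      }
    }
  }
  propers <- if (length(propers)) {
    m <- do.call(rbind, propers)
    m <- as.data.frame(m); names(m) <- c("i", "j", "k", "l")
    m <- m[order(m$i, m$j, m$k, m$l), , drop = FALSE]
    rownames(m) <- NULL
    m
  } else data.frame(i = integer(), j = integer(), k = integer(), l = integer())

  imp <- list(); site <- 0L
  for (kc in seq_len(n)) {
    nb <- adj[[kc]]
    if (length(nb) == 3) {
      site <- site + 1L
      i0 <- nb[1] - 1L; j0 <- nb[2] - 1L; l0 <- nb[3] - 1L
      k0 <- kc - 1L
      imp[[length(imp) + 1L]] <- data.frame(
        site = site,
        k = k0,
        i = c(i0, j0, l0),
        j = c(j0, l0, i0),
        l = c(l0, i0, j0))
    }
  }
  impropers <- if (length(imp)) do.call(rbind, imp) else
    data.frame(site = integer(), k = integer(), i = integer(),
               j = integer(), l = integer())
  rownames(impropers) <- NULL

  # graph distances for nonbonded classification
  nonbonded <- data.frame(i = integer(), j = integer(),
                          class = character(), stringsAsFactors = FALSE)
  if (n >= 2) {
    dist <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
      dist[s, s] <- 0
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if (dist[s, w] > dist[s, v] + 1) {
            dist[s, w] <- dist[s, v] + 1
            queue <- c(queue, w)
          }
        }
      }
    }
    pr <- which(upper.tri(dist), arr.ind = TRUE)
    d <- dist[pr]
    cls <- ifelse(d == 1, "excluded_12",
           ifelse(d == 2, "excluded_13",
           ifelse(d == 3, "scaled_14", "full")))
    nonbonded <- data.frame(i = pr[, 1] - 1L, j = pr[, 2] - 1L,
                            class = cls, stringsAsFactors = FALSE)
    nonbonded <- nonbonded[order(nonbonded$i, nonbonded$j), , drop = FALSE]
    rownames(nonbonded) <- NULL
  }

  structure(list(bonds = b, angles = angles, propers = propers,
                 impropers = impropers, nonbonded = nonbonded),
            class = "term_topology")
}

#' @export
print.term_topology <- function(x, ...) {
  cat(sprintf(
    "<term_topology: %d bonds, %d angles, %d propers, %d improper sites>\n",
    nrow(x$bonds), nrow(x$angles), nrow(x$propers),
    length(unique(x$impropers$site))))
  invisible(x)
}

# --- serialization ----------------------------------------------------------

#' Serialize a molecular graph to canonical JSON
#'
#' Schema version "mol_graph-1": fields `schema`, `name`, `Q`, `atoms`
#' (element, formal_charge, aromatic, hybridization, ring3..ring8) and
#' `bonds` (0-based i, j, order).
#'
#' @param g a [mol_graph()].
#' @param path optional output file; if NULL the JSON string is returned.
#' @export
write_mol_json <- function(g, path = NULL) {
  obj <- list(schema = "mol_graph-1", name = g$name, Q = g$Q,
              atoms = g$atoms, bonds = g$bonds)
  js <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a molecular graph from its canonical JSON dump
#' @param path file produced by [write_mol_json()].
#' @export
read_mol_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema, "mol_graph-1")) {
    stop("unknown mol_graph schema: ", obj$schema)
  }
  mol_graph(as.data.frame(obj$atoms), as.data.frame(obj$bonds),
            name = obj$name, perceive = FALSE)
}
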