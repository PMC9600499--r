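test_that("SMILES parsing yields annotated, valence-checked graphs", {
  w <- parse_molecule("O")
  expect_equal(n_atoms(w), 3)
  expect_equal(nrow(w$bonds), 2)
  expect_equal(w$Q, 0)
  expect_equal(sort(table(w$atoms$element), decreasing = TRUE),
               sort(c(H = 2, O = 1), decreasing = TRUE), ignore_attr = TRUE)

  b <- fixture_mol("c1ccccc1")
  expect_equal(n_atoms(b), 12)
  expect_equal(nrow(b$bonds), 12)
  carbons <- b$atoms$element == "C"
  expect_true(all(b$atoms$aromatic[carbons]))
  expect_true(all(b$atoms$ring6[carbons]))
  expect_true(all(b$atoms$hybridization[carbons] == "sp2"))

  nh4 <- parse_molecule("[NH4+]")
  expect_equal(nh4$Q, 1)
  expect_equal(nh4$atoms$formal_charge[nh4$atoms$element == "N"], 1)

  expect_error(parse_molecule("C(C)(C)(C)(C)C"), "valence")
  expect_error(parse_molecule("not_a_smiles(("), "parse")
})

test_that("SDF input is parsed with explicit hydrogens", {
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", "CCO",
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))
  g <- parse_molecule(sdf, format = "sdf")
  expect_equal(n_atoms(g), 9)
  expect_equal(sum(g$atoms$element == "H"), 6)
})

test_that("atom features follow the documented layout", {
  m <- fixture_mol("C")
  f <- featurize_atoms(m)
  expect_equal(ncol(f), 22)
  cidx <- which(m$atoms$element == "C")
  expect_equal(unname(f[cidx, "elem_C"]), 1)
  expect_equal(unname(f[cidx, "hyb_sp3"]), 1)
  expect_equal(unname(f[cidx, "aromatic"]), 0)
  expect_true(all(f[cidx, paste0("ring", 3:8)] == 0))

  b <- fixture_mol("c1ccccc1")
  fb <- featurize_atoms(b)
  ci <- b$atoms$element == "C"
  expect_true(all(fb[ci, "aromatic"] == 1))
  expect_true(all(fb[ci, "ring6"] == 1))
  expect_true(all(fb[ci, "hyb_sp2"] == 1))

  nh4 <- parse_molecule("[NH4+]")
  fn <- featurize_atoms(nh4)
  expect_equal(unname(fn[nh4$atoms$element == "N", "formal_charge"]), 1)

  # one-hot blocks always sum to one
  for (g in test_molecules(5)) {
    fg <- featurize_atoms(g)
    expect_true(all(rowSums(fg[, 1:10, drop = FALSE]) == 1))
    expect_true(all(rowSums(fg[, 11:14, drop = FALSE]) == 1))
  }
  expect_error(featurize_atoms(fixture_mol("C"), elements = c("H", "O")),
               "alphabet")
})

test_that("term enumeration matches an exhaustive oracle", {
  cases <- list(water = "O", ethane = "CC", formaldehyde = "C=O",
                ethanol = "CCO", benzene = "c1ccccc1")
  for (nm in names(cases)) {
    g <- fixture_mol(cases[[nm]])
    t <- enumerate_terms(g)
    o <- oracle_enumerate(g)
    expect_equal(nrow(t$bonds), o$n_bonds, label = nm)
    expect_equal(nrow(t$angles), o$n_angles, label = nm)
    expect_equal(nrow(t$propers), o$n_propers, label = nm)
    expect_equal(length(unique(t$impropers$site)), o$n_improper_sites,
                 label = nm)
    expect_equal(nrow(t$impropers), 3L * o$n_improper_sites, label = nm)
  }
  # frozen expected values
  tw <- enumerate_terms(fixture_mol("O"))
  expect_equal(c(nrow(tw$bonds), nrow(tw$angles), nrow(tw$propers)),
               c(2L, 1L, 0L))
  te <- enumerate_terms(fixture_mol("CC"))
  expect_equal(c(nrow(te$bonds), nrow(te$angles), nrow(te$propers)),
               c(7L, 12L, 9L))
  tf <- enumerate_terms(fixture_mol("C=O"))
  expect_equal(c(nrow(tf$bonds), nrow(tf$angles), nrow(tf$propers),
                 nrow(tf$impropers)), c(3L, 3L, 0L, 3L))
})

test_that("every proper satisfies the chain-bond invariant", {
  for (g in test_molecules(8)) {
    t <- enumerate_terms(g)
    if (!nrow(t$propers)) next
    key <- paste(pmin(g$bonds$i, g$bonds$j), pmax(g$bonds$i, g$bonds$j))
    chk <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% key
    expect_true(all(chk(t$propers$i, t$propers$j)))
    expect_true(all(chk(t$propers$j, t$propers$k)))
    expect_true(all(chk(t$propers$k, t$propers$l)))
    expect_true(all(t$propers$i != t$propers$k))
    expect_true(all(t$propers$j != t$propers$l))
  }
})

test_that("topology is invariant under atom relabeling", {
  set.seed(99)
  mols <- test_molecules(10)
  canon <- function(t) {
    list(b = t$bonds[order(t$bonds$i, t$bonds$j), ],
         a = t$angles[order(t$angles$i, t$angles$j, t$angles$k), ],
         p = t$propers[do.call(order, t$propers), ],
         ns = length(unique(t$impropers$site)))
  }
  for (g in mols) {
    t0 <- enumerate_terms(g)
    for (rep in 1:5) {
      perm0 <- sample(n_atoms(g)) - 1L
      gp <- permute_graph(g, perm0)
      tp <- enumerate_terms(gp)
      # map back and compare canonical forms
      inv <- order(perm0)  # inv[new+1] = old 1-based
      back <- function(v) inv[v + 1L] - 1L
      tb <- tp
      for (cl in c("bonds", "angles", "propers")) {
        for (cc in intersect(c("i", "j", "k", "l"), names(tb[[cl]]))) {
          tb[[cl]][[cc]] <- back(tb[[cl]][[cc]])
        }
      }
      swap <- tb$bonds$i > tb$bonds$j
      tmp <- tb$bonds$i[swap]; tb$bonds$i[swap] <- tb$bonds$j[swap]
      tb$bonds$j[swap] <- tmp
      swap <- tb$angles$i > tb$angles$k
      tmp <- tb$angles$i[swap]; tb$angles$i[swap] <- tb$angles$k[swap]
      tb$angles$k[swap] <- tmp
      flip <- tb$propers$j > tb$propers$k |
        (tb$propers$j == tb$propers$k & tb$propers$i > tb$propers$l)
      tb$propers[flip, c("i", "j", "k", "l")] <-
        tb$propers[flip, c("l", "k", "j", "i")]
      c0 <- canon(t0); cb <- canon(tb)
      expect_equal(cb$b, c0$b, ignore_attr = TRUE)
      expect_equal(cb$a, c0$a, ignore_attr = TRUE)
      expect_equal(cb$p, c0$p, ignore_attr = TRUE)
      expect_equal(cb$ns, c0$ns)
    }
  }
})

test_that("nonbonded classes partition pairs by graph distance", {
  for (g in test_molecules(6)) {
    t <- enumerate_terms(g)
    n <- n_atoms(g)
    expect_equal(nrow(t$nonbonded), n * (n - 1) / 2)
    # 1-2 pairs are exactly the bonds
    nb12 <- t$nonbonded[t$nonbonded$class == "excluded_12", c("i", "j")]
    expect_equal(nb12[order(nb12$i, nb12$j), ], t$bonds, ignore_attr = TRUE)
    # 1-3 pairs are exactly the angle end pairs
    a13 <- unique(data.frame(i = pmin(t$angles$i, t$angles$k),
                             j = pmax(t$angles$i, t$angles$k)))
    nb13 <- t$nonbonded[t$nonbonded$class == "excluded_13", c("i", "j")]
    expect_equal(nb13[order(nb13$i, nb13$j), ],
                 a13[order(a13$i, a13$j), ], ignore_attr = TRUE)
  }
})

test_that("molecular-graph JSON round-trips", {
  g <- test_molecules(3)[[3]]
  path <- tempfile(fileext = ".json")
  write_mol_json(g, path)
  g2 <- read_mol_json(path)
  expect_equal(g2$atoms, g$atoms, ignore_attr = TRUE)
  expect_equal(g2$bonds, g$bonds, ignore_attr = TRUE)
  expect_equal(g2$Q, g$Q)
})
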