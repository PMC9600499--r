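test_that("generated molecules are valence-legal and ring-policy compliant", {
  cfg <- generator_config(n_molecules = 40, seed = 2024)
  mols <- generate_molecules(cfg)
  expect_length(mols, 40)
  for (g in mols) {
    # exact valences enforced by the constructor; re-check independently
    ord <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)[g$bonds$order]
    val <- numeric(n_atoms(g))
    for (b in seq_along(ord)) {
      val[g$bonds$i[b] + 1] <- val[g$bonds$i[b] + 1] + ord[b]
      val[g$bonds$j[b] + 1] <- val[g$bonds$j[b] + 1] + ord[b]
    }
    expected <- c(C = 4, O = 2, H = 1)[g$atoms$element]
    expect_equal(val, unname(expected), tolerance = 1e-9)
    # no 3- or 4-membered rings
    expect_false(any(g$atoms$ring3))
    expect_false(any(g$atoms$ring4))
  }
})

test_that("generation is bit-reproducible per seed", {
  cfg <- generator_config(n_molecules = 8, seed = 77)
  a <- generate_molecules(cfg)
  b <- generate_molecules(cfg)
  expect_identical(lapply(a, write_mol_json), lapply(b, write_mol_json))
  c2 <- generate_molecules(generator_config(n_molecules = 8, seed = 78))
  expect_false(identical(lapply(a, write_mol_json),
                         lapply(c2, write_mol_json)))
})

test_that("toy typer covers the generated chemistry with all eight types", {
  ff <- toy_forcefield()
  mols <- generate_molecules(generator_config(n_molecules = 60, seed = 3))
  types <- unlist(lapply(mols, function(g) toy_atom_types(ff, g)))
  expect_setequal(unique(types), TOY_TYPES)
  # rule checks on known molecules
  expect_true(all(toy_atom_types(ff, fixture_mol("c1ccccc1"))[
    fixture_mol("c1ccccc1")$atoms$element == "C"] == "C_aromatic"))
  et <- fixture_mol("CCO")
  tt <- toy_atom_types(ff, et)
  expect_equal(tt[et$atoms$element == "O"], "O_hydroxyl")
  expect_error(toy_atom_types(ff, parse_molecule("C#C")), "typeable")
})

test_that("reference parameters are deterministic type-tuple lookups", {
  ff <- toy_forcefield()
  etoh <- fixture_mol("CCO")
  meoh <- fixture_mol("CO")
  r1 <- assign_reference(ff, etoh)
  r2 <- assign_reference(ff, meoh)
  oh1 <- r1$params$bonds[etoh$atoms$element[r1$params$bonds$i + 1] == "O" |
                         etoh$atoms$element[r1$params$bonds$j + 1] == "O", ]
  # the O-H bond has identical parameters in ethanol and methanol
  ohb <- function(r, g) {
    b <- r$params$bonds
    el <- g$atoms$element
    b[(el[b$i + 1] == "O" & el[b$j + 1] == "H") |
      (el[b$i + 1] == "H" & el[b$j + 1] == "O"), c("k_r", "r_0")]
  }
  expect_equal(ohb(r1, etoh), ohb(r2, meoh), ignore_attr = TRUE)
  # charges conserve the molecular total
  for (g in test_molecules(10)) {
    r <- assign_reference(ff, g)
    expect_lt(abs(sum(r$charges) - g$Q), 1e-10)
    expect_true(all(r$params$bonds$k_r > 0))
    expect_true(all(r$params$angles$k_theta > 0))
  }
  # repeatable
  expect_identical(assign_reference(ff, etoh)$params$bonds,
                   r1$params$bonds)
})

test_that("snapshot sampling respects counts and the zero-step limit", {
  g <- fixture_mol("CCO")
  ref <- assign_reference(toy_forcefield(), g)
  sc <- sample_conformations(g, ref$params, n_snapshots = 12, seed = 6,
                             n_chains = 4, burn_in = 20, thin = 5)
  expect_length(sc$coords, 12)
  expect_length(sc$energies, 12)
  expect_true(all(is.finite(sc$energies)))
  expect_gt(stats::sd(sc$energies), 0)  # centering is nontrivial
  # zero steps: every snapshot equals the minimized structure
  sc0 <- sample_conformations(g, ref$params, n_snapshots = 5, seed = 6,
                              burn_in = 0, thin = 0)
  for (f in 2:5) expect_identical(sc0$coords[[f]], sc0$coords[[1]])
  expect_equal(stats::sd(sc0$energies), 0)
  # same seed twice is bit-reproducible
  sc2 <- sample_conformations(g, ref$params, n_snapshots = 12, seed = 6,
                              n_chains = 4, burn_in = 20, thin = 5)
  expect_identical(sc$energies, sc2$energies)
})

test_that("long sampling of a stiff diatomic satisfies equipartition", {
  k <- 400; r0 <- 1.0
  ps <- list(
    bonds = data.frame(i = 0L, j = 1L, k_r = k, r_0 = r0),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        k_theta = numeric(), theta_0 = numeric()),
    propers = cbind(data.frame(i = integer(), j = integer(), k = integer(),
                               l = integer()),
                    as.data.frame(matrix(numeric(0), 0, 6,
                                         dimnames = list(NULL, paste0("K", 1:6))))),
    impropers = cbind(data.frame(site = integer(), k = integer(),
                                 i = integer(), j = integer(), l = integer()),
                      as.data.frame(matrix(numeric(0), 0, 6,
                                           dimnames = list(NULL, paste0("K", 1:6))))),
    atoms = data.frame(element = c("H", "H"), epsilon = 0, sigma = 1, q = 0),
    meta = list(name = "stiff-diatomic", Q = 0))
  class(ps) <- "parameter_set"
  g <- mol_graph(data.frame(element = c("H", "H")),
                 data.frame(i = 0L, j = 1L, order = "single"),
                 validate = FALSE)
  sc <- sample_conformations(g, ps, n_snapshots = 400, temperature = 300,
                             seed = 11, n_chains = 40, burn_in = 80,
                             thin = 12)
  kT <- 0.0019872041 * 300
  mean_bond <- mean(sc$components[, "bond"])
  expect_lt(abs(mean_bond - kT / 2) / (kT / 2), 0.2)
})

test_that("repeat polymers grow affinely with valid chemistry", {
  g1 <- generate_polymer(1)
  expect_error(generate_polymer(0), "n_repeats")
  unit_size <- n_atoms(generate_polymer(2)) - n_atoms(g1)
  for (n in c(3, 5, 8)) {
    gn <- generate_polymer(n)
    expect_equal(n_atoms(gn), n_atoms(g1) + (n - 1) * unit_size)
    expect_equal(sort(unique(gn$atoms$unit)), 0:(n + 1))
    # typeable by the toy force field (valence-legal C/H/O chemistry)
    expect_silent(toy_atom_types(toy_forcefield(), gn))
  }
})

test_that("central-unit parameters converge with chain length", {
  # identical k-hop environments make interior units exactly equivalent
  m <- tiny_model(seed = 19)
  central_bonds <- function(n) {
    g <- generate_polymer(n)
    u <- floor((n + 1) / 2)
    ref <- assign_reference(toy_forcefield(), g)
    ps <- assign_parameters(g, m, legacy = list(
      lj = ref$params$atoms[, c("epsilon", "sigma")]))
    keep <- g$atoms$unit[ps$bonds$i + 1] == u & g$atoms$unit[ps$bonds$j + 1] == u
    b <- ps$bonds[keep, ]
    b[order(b$i - min(b$i), b$j - min(b$j)), c("k_r", "r_0")]
  }
  b5 <- central_bonds(5)
  b10 <- central_bonds(10)
  expect_equal(nrow(b5), nrow(b10))
  expect_lt(max(abs(as.matrix(b5) - as.matrix(b10))), 1e-6)
})
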