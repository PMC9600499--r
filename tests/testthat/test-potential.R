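# a hand-built diatomic parameter set (not tied to the toy force field)
diatomic_params <- function(k = 100, r0 = 1.2) {
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
    meta = list(name = "diatomic", Q = 0))
  class(ps) <- "parameter_set"
  ps
}

diatomic_topo <- function() {
  g <- mol_graph(data.frame(element = c("H", "H")),
                 data.frame(i = 0L, j = 1L, order = "single"),
                 name = "h2", perceive = TRUE, validate = FALSE)
  enumerate_terms(g)
}

test_that("harmonic bond energies follow (k/2)(r - r0)^2", {
  ps <- diatomic_params(k = 100, r0 = 1.2)
  t <- diatomic_topo()
  at_r0 <- matrix(c(0, 0, 0, 1.2, 0, 0), 2, 3, byrow = TRUE)
  br <- evaluate_energy(ps, t, at_r0, nb_mode = "none")
  expect_equal(br$bond, 0, tolerance = 1e-12)
  displaced <- matrix(c(0, 0, 0, 1.3, 0, 0), 2, 3, byrow = TRUE)
  br2 <- evaluate_energy(ps, t, displaced, nb_mode = "none")
  expect_equal(br2$bond, 0.5, tolerance = 1e-10)
  expect_equal(br2$total, sum(br2$bond, br2$angle, br2$proper, br2$improper,
                              br2$lj, br2$coulomb), tolerance = 1e-10)
})

test_that("analytic coordinate gradients match finite differences", {
  g <- test_molecules(3)[[3]]
  ref <- assign_reference(toy_forcefield(), g)
  t <- enumerate_terms(g)
  sc <- sample_conformations(g, ref$params, n_snapshots = 2, seed = 4,
                             n_chains = 2, burn_in = 30, thin = 5)
  X <- sc$coords[[1]]
  gr <- energy_gradient(ref$params, t, X)
  h <- 1e-5
  worst <- 0
  for (a in seq_len(nrow(X))) for (c in 1:3) {
    Xp <- X; Xp[a, c] <- Xp[a, c] + h
    Xm <- X; Xm[a, c] <- Xm[a, c] - h
    fd <- (evaluate_energy(ref$params, t, Xp)$total -
           evaluate_energy(ref$params, t, Xm)$total) / (2 * h)
    worst <- max(worst, abs(fd - gr[a, c]))
  }
  expect_lt(worst, 1e-4)
})

test_that("energy is invariant under rigid motions and mirror images", {
  g <- test_molecules(2)[[2]]
  ref <- assign_reference(toy_forcefield(), g)
  t <- enumerate_terms(g)
  sc <- sample_conformations(g, ref$params, n_snapshots = 1, seed = 9,
                             n_chains = 1, burn_in = 30, thin = 5)
  X <- sc$coords[[1]]
  e0 <- evaluate_energy(ref$params, t, X)$total
  set.seed(10)
  for (trial in 1:5) {
    # random rotation via QR of a random matrix
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    Xr <- X %*% R + matrix(rnorm(3), nrow(X), 3, byrow = TRUE)
    expect_lt(abs(evaluate_energy(ref$params, t, Xr)$total - e0), 1e-8)
  }
  # mirror image: valence terms unchanged (cosine is even, phases zero)
  Xm <- X; Xm[, 1] <- -Xm[, 1]
  em <- evaluate_energy(ref$params, t, Xm)
  e0b <- evaluate_energy(ref$params, t, X)
  expect_equal(em$total, e0b$total, tolerance = 1e-10)
})

test_that("components are additive: removing a term removes its energy", {
  g <- test_molecules(7)[[7]]
  ref <- assign_reference(toy_forcefield(), g)
  t <- enumerate_terms(g)
  sc <- sample_conformations(g, ref$params, n_snapshots = 1, seed = 2,
                             n_chains = 1, burn_in = 20, thin = 5)
  X <- sc$coords[[1]]
  full <- evaluate_energy(ref$params, t, X)
  noang <- ref$params
  noang$angles$k_theta[] <- 0
  e2 <- evaluate_energy(noang, t, X)
  expect_equal(full$total - e2$total, full$angle, tolerance = 1e-10)
  expect_equal(e2$angle, 0)
  # nb_mode = "none" drops exactly the nonbonded components
  ev <- evaluate_energy(ref$params, t, X, nb_mode = "none")
  expect_equal(ev$lj, 0)
  expect_equal(ev$coulomb, 0)
  expect_equal(ev$total, full$total - full$lj - full$coulomb,
               tolerance = 1e-10)
})

test_that("overlapping nonbonded atoms raise an explicit error", {
  # need a >=1-4 pair for a nonbonded interaction: use a butane chain
  g <- fixture_mol("CCCC")
  ref <- assign_reference(toy_forcefield(), g)
  t <- enumerate_terms(g)
  X <- matrix(rnorm(3 * n_atoms(g)), ncol = 3)
  X[2, ] <- X[14, ]  # force a coincident pair
  expect_error(evaluate_energy(ref$params, t, X), "overlap")
})

test_that("energy centering has the defined algebra", {
  expect_equal(center_energies(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(center_energies(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(center_energies(numeric(0)), "no energies")
  # RMSE between centered series is invariant to per-series constants
  set.seed(6)
  a <- rnorm(50); b <- rnorm(50)
  rmse <- function(x, y) sqrt(mean((x - y)^2))
  r0 <- rmse(center_energies(a), center_energies(b))
  r1 <- rmse(center_energies(a + 17.3), center_energies(b - 4.4))
  expect_equal(r0, r1, tolerance = 1e-12)
  expect_lt(abs(mean(center_energies(rnorm(9)))), 1e-12)
})

test_that("XYZ files round-trip coordinates and energies", {
  g <- fixture_mol("CO")
  ref <- assign_reference(toy_forcefield(), g)
  sc <- sample_conformations(g, ref$params, n_snapshots = 3, seed = 5,
                             n_chains = 3, burn_in = 10, thin = 5)
  path <- tempfile(fileext = ".xyz")
  write_xyz(sc$coords, g$atoms$element, path, energies = sc$energies)
  back <- read_xyz(path)
  expect_equal(length(back$coords), 3)
  expect_equal(back$elements, g$atoms$element)
  for (f in 1:3) expect_equal(back$coords[[f]], sc$coords[[f]],
                              tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$energies, sc$energies, tolerance = 1e-8)
})
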