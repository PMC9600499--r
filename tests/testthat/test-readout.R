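test_that("basis-to-harmonic conversion is exact algebra", {
  # single active coefficient at 1.5 A
  kh <- basis_to_harmonic(matrix(c(1), 1, 1), grid = 1.5)
  expect_equal(kh$k, 2)
  expect_equal(kh$x0, 1.5)
  # two equal coefficients
  kh2 <- basis_to_harmonic(matrix(c(1, 1), 1, 2), grid = c(1.0, 2.0))
  expect_equal(kh2$k, 4)
  expect_equal(kh2$x0, 1.5)
  # angle-grid examples
  kh3 <- basis_to_harmonic(matrix(c(0.5, 0.5), 1, 2), grid = c(1.5, 2.0))
  expect_equal(kh3$x0, 1.75)
})

test_that("quadratic mixture equals the harmonic form on dense grids", {
  grid <- seq(0.7, 2.2, length.out = 8)
  xs <- seq(0.5, 2.5, length.out = 400)
  set.seed(42)
  for (case in 1:1000) {
    cc <- runif(8, 0, 5)
    kh <- basis_to_harmonic(matrix(cc, 1), grid)
    mix <- colSums(cc * outer(grid, xs, function(b, x) (x - b)^2))
    harm <- (kh$k / 2) * (xs - kh$x0)^2
    const <- mix[which.min(abs(xs - kh$x0))] -
      harm[which.min(abs(xs - kh$x0))]
    expect_lt(max(abs(mix - harm - const)), 1e-8)
  }
})

test_that("readout outputs satisfy their range constraints", {
  m <- tiny_model(seed = 31)
  set.seed(1)
  h <- matrix(rnorm(200 * m$config$pooling_dim), 200)
  bp <- readout_bond(h, m)
  expect_true(all(bp$k_r > 0))
  expect_true(all(bp$r_0 > 0))
  ap <- readout_angle(h, m)
  expect_true(all(ap$k_theta > 0))
  expect_true(all(ap$theta_0 > 0 & ap$theta_0 < pi))
  tp <- readout_torsion(h, m)
  expect_equal(names(tp), paste0("K", 1:6))
})

test_that("torsion profiles follow the cosine-series semantics", {
  phi <- seq(-pi, pi, length.out = 360)
  expect_true(all(torsion_profile(rep(0, 6), phi) == 0))
  # K1 < 0 mimics a phase of pi up to an additive constant
  p_neg <- torsion_profile(c(-1, 0, 0, 0, 0, 0), phi)
  p_pi <- 1 * (1 + cos(phi - pi))
  expect_lt(max(abs((p_neg - p_pi) - (p_neg - p_pi)[1])), 1e-12)
  # random amplitudes match a term-by-term oracle
  set.seed(3)
  K <- rnorm(6)
  oracle <- rowSums(sapply(1:6, function(n) K[n] * (1 + cos(n * phi))))
  expect_equal(torsion_profile(K, phi), oracle, tolerance = 1e-12)
})

test_that("LJ readout: positivity, documented zero point, legacy passthrough", {
  m <- mm_model(mm_config(n_layers = 2, hidden_dim = 8, embedding_dim = 8,
                          pooling_hidden = 8, pooling_dim = 8,
                          readout_hidden = 8, lj_mode = "predicted",
                          seed = 77))
  # zero raw outputs -> softplus(0) * scale constants
  m0 <- m
  m0$weights$readout$lj <- graphmm:::tree_zeros_like(m0$weights$readout$lj)
  lj0 <- readout_lj(matrix(0, 1, 8), m0)
  expect_equal(lj0$epsilon, log(2) * 0.1, tolerance = 1e-12)
  expect_equal(lj0$sigma, log(2) * 2.0, tolerance = 1e-12)
  # positivity sweep
  set.seed(8)
  lj <- readout_lj(matrix(rnorm(1000 * 8, sd = 3), 1000), m)
  expect_true(all(lj$epsilon >= 0))
  expect_true(all(lj$sigma > 0))
  # legacy mode: passthrough unchanged, predicted readout refused
  mlg <- tiny_model(seed = 1)
  expect_error(readout_lj(matrix(0, 1, 12), mlg), "legacy")
  g <- fixture_mol("C")
  legacy <- list(lj = data.frame(epsilon = rep(0.1094, 5),
                                 sigma = rep(3.3997, 5)),
                 charges = rep(0, 5))
  ps <- assign_parameters(g, mlg, legacy = legacy, charges = "legacy")
  expect_equal(ps$atoms$epsilon, rep(0.1094, 5))
  expect_equal(ps$atoms$sigma, rep(3.3997, 5))
  expect_identical(ps$meta$provenance$lj, "legacy")
  expect_error(assign_parameters(g, mlg), "legacy")
})

test_that("assigned parameters are constant on symmetry orbits", {
  b <- fixture_mol("c1ccccc1")
  m <- tiny_model(seed = 17)
  ref <- assign_reference(toy_forcefield(), b)
  ps <- assign_parameters(b, m, legacy = list(
    lj = ref$params$atoms[, c("epsilon", "sigma")]))
  cc <- ps$bonds[ps$bonds$k_r > 0 & ref$params$atoms$element[ps$bonds$i + 1] == "C" &
                 ref$params$atoms$element[ps$bonds$j + 1] == "C", ]
  expect_equal(nrow(cc), 6)  # six aromatic C-C bonds
  expect_true(all(cc$k_r == cc$k_r[1]))
  expect_true(all(cc$r_0 == cc$r_0[1]))
  # total charge conservation through the charge model
  expect_lt(abs(sum(ps$atoms$q) - b$Q), 1e-10)
})

test_that("parameter assignment is invariant under relabeling", {
  g <- test_molecules(6)[[6]]
  m <- tiny_model(seed = 23)
  ref <- assign_reference(toy_forcefield(), g)
  legacy <- list(lj = ref$params$atoms[, c("epsilon", "sigma")])
  ps0 <- assign_parameters(g, m, legacy = legacy)
  set.seed(5)
  perm0 <- sample(n_atoms(g)) - 1L
  gp <- permute_graph(g, perm0)
  refp <- assign_reference(toy_forcefield(), gp)
  psp <- assign_parameters(gp, m, legacy = list(
    lj = refp$params$atoms[, c("epsilon", "sigma")]))
  # match bonds through the permutation
  key0 <- paste(pmin(perm0[ps0$bonds$i + 1], perm0[ps0$bonds$j + 1]),
                pmax(perm0[ps0$bonds$i + 1], perm0[ps0$bonds$j + 1]))
  keyp <- paste(pmin(psp$bonds$i, psp$bonds$j),
                pmax(psp$bonds$i, psp$bonds$j))
  mt <- match(key0, keyp)
  expect_false(anyNA(mt))
  expect_equal(ps0$bonds$k_r, psp$bonds$k_r[mt], tolerance = 1e-12)
  expect_equal(ps0$bonds$r_0, psp$bonds$r_0[mt], tolerance = 1e-12)
  expect_equal(ps0$atoms$q, psp$atoms$q[perm0 + 1L], tolerance = 1e-12)
})

test_that("parameter sets serialize and reload", {
  g <- fixture_mol("CCO")
  m <- tiny_model(seed = 2)
  ref <- assign_reference(toy_forcefield(), g)
  ps <- assign_parameters(g, m, legacy = list(
    lj = ref$params$atoms[, c("epsilon", "sigma")]))
  path <- tempfile(fileext = ".json")
  write_params_json(ps, path)
  ps2 <- read_params_json(path)
  expect_equal(ps2$bonds, ps$bonds, ignore_attr = TRUE)
  expect_equal(ps2$atoms$q, ps$atoms$q)
})
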