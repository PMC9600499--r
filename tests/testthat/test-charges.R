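test_that("analytic charge solve matches closed-case expectations", {
  # symmetric case: equal split of the total charge
  expect_equal(solve_charges(rep(2, 5), rep(7, 5), 1), rep(0.2, 5),
               tolerance = 1e-12)
  # hand-checkable two-atom case, verified against the numeric oracle
  q <- solve_charges(c(0, 1), c(1, 1), 0)
  expect_equal(q, c(0.5, -0.5), tolerance = 1e-10)
  expect_equal(q, oracle_charges(c(0, 1), c(1, 1), 0), tolerance = 1e-8)
})

test_that("analytic solve agrees with a numeric constrained minimizer", {
  set.seed(1234)
  worst <- 0
  for (case in 1:1000) {
    n <- sample(2:8, 1)
    e <- rnorm(n, sd = 20)
    s <- runif(n, 0.5, 50)
    Q <- sample(-2:2, 1)
    q <- solve_charges(e, s, Q)
    expect_lt(abs(sum(q) - Q), 1e-10)
    worst <- max(worst, max(abs(q - oracle_charges(e, s, Q))))
  }
  expect_lt(worst, 1e-6)
})

test_that("solver input validation", {
  expect_error(solve_charges(numeric(0), numeric(0), 0), "empty")
  expect_error(solve_charges(c(1, 2), c(1, -1), 0), "positive")
  expect_error(solve_charges(c(1, 2), c(1), 0), "length")
  expect_error(solve_charges(c(1, NA), c(1, 1), 0), "finite")
})

test_that("solution is invariant under a joint electronegativity shift", {
  set.seed(2)
  e <- rnorm(6); s <- runif(6, 0.5, 5)
  q1 <- solve_charges(e, s, -1)
  q2 <- solve_charges(e + 12.34, s, -1)
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("hardness readout is strictly positive everywhere", {
  m <- tiny_model(seed = 41)
  set.seed(3)
  ok <- TRUE
  for (g in test_molecules(10)) {
    h <- atom_embeddings(g, m)
    es <- readout_en_hardness(h, m)
    ok <- ok && all(es$s > 0)
  }
  expect_true(ok)
  # orbit symmetry: benzene carbons share (e, s)
  b <- fixture_mol("c1ccccc1")
  es <- readout_en_hardness(atom_embeddings(b, m), m)
  ci <- which(b$atoms$element == "C")
  expect_true(all(es$e[ci] == es$e[ci[1]]))
  expect_true(all(es$s[ci] == es$s[ci[1]]))
  # zero-weight readout: constant across atoms
  m0 <- m
  m0$weights$readout$charge <- graphmm:::tree_zeros_like(m0$weights$readout$charge)
  es0 <- readout_en_hardness(atom_embeddings(b, m0), m0)
  expect_true(all(es0$e == 0))
  expect_equal(unique(es0$s), log(2) + 1e-3, tolerance = 1e-12)
})

test_that("charge loss semantics and gradient flow", {
  expect_equal(charge_loss(c(0.1, -0.1), c(0.1, -0.1)), 0)
  # constant offset c on N atoms gives loss c^2
  expect_equal(charge_loss(c(0.3, 0.2, -0.5) + 0.05, c(0.3, 0.2, -0.5)),
               0.05^2, tolerance = 1e-12)
  expect_error(charge_loss(1:3, 1:2), "length")
})

test_that("charge-loss gradients match finite differences", {
  d <- make_toy_dataset(generator_config(n_molecules = 3, seed = 31,
                                         n_snapshots = 2))
  m <- tiny_model(seed = 8)
  batch <- build_training_batch(d, m, 1:3, with_energy = FALSE)
  w <- c(energy = 0, charge = 1, type = 0)
  lg <- loss_and_grads(m, batch, w)
  flat <- graphmm:::tree_flatten(m$weights)
  gflat <- graphmm:::tree_flatten(lg$grads)
  h <- 1e-5
  set.seed(4)
  idx <- sample(which(abs(gflat) > 1e-10), 12)
  for (i in idx) {
    m2 <- m
    fp <- flat; fp[i] <- fp[i] + h
    m2$weights <- graphmm:::tree_unflatten(m$weights, fp)
    lp <- graphmm:::batch_loss_only(m2, batch, w)
    fm <- flat; fm[i] <- fm[i] - h
    m2$weights <- graphmm:::tree_unflatten(m$weights, fm)
    lm <- graphmm:::batch_loss_only(m2, batch, w)
    fd <- (lp - lm) / (2 * h)
    expect_lt(abs(fd - gflat[i]) / max(1e-8, abs(fd) + abs(gflat[i])), 1e-5)
  }
})

test_that("predicted charges conserve the molecular total exactly", {
  m <- tiny_model(seed = 12)
  for (g in test_molecules(8)) {
    q <- predict_charges(g, m)
    expect_lt(abs(sum(q) - g$Q), 1e-10)
  }
  # override the total
  q2 <- predict_charges(test_molecules(1)[[1]], m, Q = -1)
  expect_lt(abs(sum(q2) + 1), 1e-10)
})
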