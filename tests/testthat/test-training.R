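# lightweight dataset shared across training tests
train_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_toy_dataset(generator_config(n_molecules = 12, seed = 55,
                                             n_snapshots = 8))
      cache <<- split_by_molecule(d, c(0.5, 0.25, 0.25), seed = 1)
    }
    cache
  }
})

test_that("molecule-level splits have the right sizes and are disjoint", {
  mols <- replicate(100, list(graph = fixture_mol("O"),
                              topo = enumerate_terms(fixture_mol("O"))),
                    simplify = FALSE)
  d <- snapshot_dataset(mols)
  ds <- split_by_molecule(d, c(0.8, 0.1, 0.1), seed = 42)
  expect_equal(unname(table(ds$split)[c("train", "validate", "test")]),
               c(80L, 10L, 10L), ignore_attr = TRUE)
  # deterministic given the seed
  ds2 <- split_by_molecule(d, c(0.8, 0.1, 0.1), seed = 42)
  expect_identical(ds$split, ds2$split)
  ds3 <- split_by_molecule(d, c(0.8, 0.1, 0.1), seed = 43)
  expect_false(identical(ds$split, ds3$split))
  # partition: every molecule in exactly one split
  expect_false(anyNA(ds$split))
  expect_error(split_by_molecule(snapshot_dataset(mols[1:2]),
                                 c(0.8, 0.1, 0.1), 1), "too few")
})

test_that("energy loss vanishes for exact (shifted) predictions", {
  d <- train_fixture()
  m <- tiny_model(seed = 101)
  idx <- which(d$split == "train")
  batch <- build_training_batch(d, m, idx)
  fw <- graphmm:::batch_forward(m, batch, list(energy = TRUE))
  # make the references equal the model's own predictions plus offsets
  d2 <- d
  pos <- 0L
  for (mi in idx) {
    ns <- length(d2$molecules[[mi]]$coords)
    d2$molecules[[mi]]$valence <- fw$E_snap[(pos + 1):(pos + ns)] + 3.21 * mi
    pos <- pos + ns
  }
  batch2 <- build_training_batch(d2, m, idx)
  expect_lt(energy_loss(m, batch2), 1e-18)
})

test_that("energy-loss gradients match finite differences", {
  d <- train_fixture()
  m <- tiny_model(seed = 7)
  batch <- build_training_batch(d, m, which(d$split == "train"))
  w <- c(energy = 1, charge = 0, type = 0)
  lg <- loss_and_grads(m, batch, w)
  flat <- graphmm:::tree_flatten(m$weights)
  gflat <- graphmm:::tree_flatten(lg$grads)
  set.seed(3)
  idx <- sample(which(abs(gflat) > 1e-9), 12)
  h <- 1e-5
  for (i in idx) {
    m2 <- m
    fp <- flat; fp[i] <- fp[i] + h
    m2$weights <- graphmm:::tree_unflatten(m$weights, fp)
    lp <- graphmm:::batch_loss_only(m2, batch, w)
    fm <- flat; fm[i] <- fm[i] - h
    m2$weights <- graphmm:::tree_unflatten(m$weights, fm)
    lm <- graphmm:::batch_loss_only(m2, batch, w)
    fd <- (lp - lm) / (2 * h)
    expect_lt(abs(fd - gflat[i]) / max(1e-8, abs(fd) + abs(gflat[i])), 1e-4)
  }
})

test_that("fitting honours the zero-epoch and determinism contracts", {
  d <- train_fixture()
  m <- tiny_model(seed = 5)
  r0 <- fit_model(m, d, fit_config(epochs = 0))
  expect_identical(r0$model$weights, m$weights)
  expect_equal(nrow(r0$log), 0)
  cfg <- fit_config(epochs = 8, lr = 1e-3, patience = 8)
  r1 <- fit_model(m, d, cfg)
  r2 <- fit_model(m, d, cfg)
  expect_identical(r1$log$validate, r2$log$validate)
  expect_identical(graphmm:::tree_flatten(r1$model$weights),
                   graphmm:::tree_flatten(r2$model$weights))
  # log covers both losses per epoch
  expect_true(all(is.finite(r1$log$train)))
  expect_true(all(is.finite(r1$log$validate)))
})

test_that("best-validation checkpoint is restored", {
  d <- train_fixture()
  m <- tiny_model(seed = 15)
  r <- fit_model(m, d, fit_config(epochs = 25, lr = 5e-3, patience = 25))
  vb <- graphmm:::batch_loss_only(
    r$model, build_training_batch(d, r$model, which(d$split == "validate")),
    c(energy = 1, charge = 0, type = 0))
  expect_equal(vb, min(r$log$validate), tolerance = 1e-10)
})

test_that("evaluation statistics behave as defined", {
  d <- train_fixture()
  m <- tiny_model(seed = 3)
  rep <- evaluate_model(m, d, "test", n_boot = 200)
  expect_s3_class(rep, "metric_report")
  expect_true(all(rep$ci_lo <= rep$estimate + 1e-12))
  expect_true(all(rep$ci_hi >= rep$estimate - 1e-12))
  expect_setequal(rep$quantity, c("energy_rmse", "mape_k_r", "mape_r_0",
                                  "mape_k_theta", "mape_theta_0"))
  # single-molecule split: bootstrap over one molecule has zero CI width
  d1 <- d
  d1$split[d1$split == "test"][-1] <- "train"
  rep1 <- evaluate_model(m, d1, "test", n_boot = 100)
  e <- rep1[rep1$quantity == "energy_rmse", ]
  expect_equal(e$ci_lo, e$estimate, tolerance = 1e-12)
  expect_equal(e$ci_hi, e$estimate, tolerance = 1e-12)
})

test_that("bootstrap CIs bracket the point estimate for random data", {
  set.seed(12)
  d <- train_fixture()
  m <- tiny_model(seed = 3)
  ok <- TRUE
  for (trial in 1:20) {
    rep <- evaluate_model(m, d, "test", n_boot = 120, boot_seed = trial)
    ok <- ok && all(rep$ci_lo <= rep$estimate & rep$estimate <= rep$ci_hi)
  }
  expect_true(ok)
})

test_that("joint energy+charge training keeps charge accuracy comparable", {
  d <- make_toy_dataset(generator_config(n_molecules = 24, seed = 91,
                                         n_snapshots = 6))
  d <- split_by_molecule(d, c(0.6, 0.2, 0.2), seed = 2)
  te <- which(d$split == "test")
  charge_rmse <- function(model) {
    err2 <- unlist(lapply(te, function(mi) {
      (predict_charges(d$molecules[[mi]]$graph, model) -
         d$molecules[[mi]]$ref_charges)^2
    }))
    sqrt(mean(err2))
  }
  m <- mm_model(mm_config(n_layers = 2, hidden_dim = 24, embedding_dim = 24,
                          pooling_hidden = 16, pooling_dim = 16,
                          readout_hidden = 24, seed = 3))
  budget <- fit_config(loss_weights = c(energy = 0, charge = 1, type = 0),
                       epochs = 300, lr = 5e-3, patience = 300)
  r_solo <- fit_model(m, d, budget)
  # the two losses live on very different scales (kcal^2 vs e^2); weight
  # the charge term up so both heads receive comparable gradient signal
  budget$loss_weights <- c(energy = 1, charge = 100, type = 0)
  r_joint <- fit_model(m, d, budget)
  e_solo <- charge_rmse(r_solo$model)
  e_joint <- charge_rmse(r_joint$model)
  expect_lt(e_joint, 2 * e_solo + 1e-6)
})
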