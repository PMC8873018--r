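test_that("trajectory predictions follow the fitted polynomial exactly", {
  sim <- tiny_sim(seed = 91, n = 20L, subdiv = 0L)
  fit <- surf_lmm(sim$dataset)
  cf <- coef(fit)
  ac <- fit$age_center
  rng <- range(fit$dataset$metadata$age)
  ages <- seq(ceiling(rng[1L]), floor(rng[2L]), length.out = 5L)

  for (a in ages) {
    d <- a - ac
    ref <- cf[, "(Intercept)"] + cf[, "age"] * d + cf[, "age2"] * d^2
    expect_lt(max(abs(predict_trajectory(fit, "control", a) - ref)), 1e-9)
    case <- ref + cf[, "groupcase"] + cf[, "groupcase:age"] * d +
      cf[, "groupcase:age2"] * d^2
    expect_lt(max(abs(predict_trajectory(fit, "case", a) - case)), 1e-9)
  }

  expect_error(predict_trajectory(fit, "case", rng[2L] + 5),
               "outside observed range")
  expect_error(predict_trajectory(fit, "nosuch", 20), "unknown group")
})

test_that("an order-0 vertex predicts a flat line with zero rate", {
  cfg <- simulation_config(
    mesh_subdivisions = 0L, groups = c(control = 20L, case = 20L),
    baseline_curve = c(3, 0, 0),
    random_sd = c(intercept = 0.2, slope = 0, cor = 0), seed = 92)
  ds <- simulate_dataset(cfg)$dataset
  vf <- fit_vertex(ds$measures[, 1L], ds, 0L)
  expect_equal(predict_trajectory(vf, "control", 10),
               predict_trajectory(vf, "control", 30))
  expect_identical(annual_rate(vf, "control", 12), 0)
  expect_identical(annual_rate(vf, "case", 31), 0)
})

test_that("predictions are linear in age for order <= 1 fits", {
  sim <- tiny_sim(seed = 93, n = 15L, subdiv = 0L,
                  baseline_curve = c(3.6, -0.02, 0))
  fit <- surf_lmm(sim$dataset, allowed_orders = 1L)
  p10 <- predict_trajectory(fit, "case", 10)
  p20 <- predict_trajectory(fit, "case", 20)
  p15 <- predict_trajectory(fit, "case", 15)
  expect_lt(max(abs((p10 + p20) / 2 - p15)), 1e-10)
})

test_that("annual rate matches the analytic derivative and finite differences", {
  # hand-built check: beta_a1 = -0.02, beta_a2 = 0.001 at center + 10
  sim <- tiny_sim(seed = 94, n = 20L, subdiv = 0L)
  ds <- sim$dataset
  vf <- fit_vertex(ds$measures[, 2L], ds, 2L)
  vf$beta[c("age", "age2", "groupcase:age", "groupcase:age2")] <-
    c(-0.02, 0.001, 0, 0)
  expect_equal(annual_rate(vf, "control", vf$age_center + 10), 0,
               tolerance = 1e-12)

  fit <- surf_lmm(ds)
  rng <- range(ds$metadata$age)
  h <- 1e-4
  for (a in c(ceiling(rng[1L]) + 1, 20, floor(rng[2L]) - 1)) {
    for (g in c("control", "case")) {
      fd <- (predict_trajectory(fit, g, a + h) -
             predict_trajectory(fit, g, a - h)) / (2 * h)
      expect_lt(max(abs(annual_rate(fit, g, a) - fd)), 1e-6)
    }
  }
})

test_that("snapshot series equal the closed-form group contrast", {
  sim <- tiny_sim(seed = 95, n = 20L, subdiv = 1L,
                  effect_clusters = list(list(seed_vertex = 3L,
                                              radius_hops = 1L,
                                              beta_g = 0.3,
                                              beta_ag1 = -0.02)))
  fit <- surf_lmm(sim$dataset)
  ss <- snapshot_series(fit)
  cf <- coef(fit)
  ac <- fit$age_center
  for (i in seq_along(ss$ages)) {
    d <- ss$ages[i] - ac
    closed <- cf[, "groupcase"] + cf[, "groupcase:age"] * d +
      cf[, "groupcase:age2"] * d^2
    expect_lt(max(abs(ss$difference_maps[, i] - closed)), 1e-9)
    closed_rate <- cf[, "groupcase:age"] + 2 * cf[, "groupcase:age2"] * d
    expect_lt(max(abs(ss$rate_difference_maps[, i] - closed_rate)), 1e-9)
  }
  expect_true(all(ss$ages >= min(sim$dataset$metadata$age)))
  expect_true(all(ss$ages <= max(sim$dataset$metadata$age)))
})

test_that("without group effects the difference maps are near zero", {
  cfg <- noiseless_config(seed = 96, n = 10L)
  fit <- surf_lmm(simulate_dataset(cfg)$dataset, allowed_orders = 2L,
                  covariates = character(0))
  ss <- snapshot_series(fit)
  expect_lt(max(abs(ss$difference_maps)), 1e-6)
  expect_lt(max(abs(ss$rate_difference_maps)), 1e-6)
})

test_that("snapshot export writes one map per age per quantity", {
  sim <- tiny_sim(seed = 97, n = 10L, subdiv = 0L)
  fit <- surf_lmm(sim$dataset, allowed_orders = 1L)
  ss <- snapshot_series(fit, ages = c(10, 20, 30), guard = Inf)
  d <- tempfile()
  export_snapshots(ss, d, n_vertices(sim$dataset$mesh))
  files <- list.files(d)
  expect_length(grep("^difference_", files), 3L)
  expect_length(grep("^rate_difference_", files), 3L)
  expect_true("manifest.json" %in% files)
  m <- read_matrix_tsv(file.path(d, grep("^difference_", files,
                                         value = TRUE)[1L]))
  expect_equal(ncol(m), 12L)
})
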