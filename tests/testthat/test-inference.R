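test_that("likelihood-ratio test handles degenerate and textbook cases", {
  sim <- tiny_sim(seed = 81, n = 12L)
  ds <- sim$dataset
  y <- ds$measures[, 3L]
  full <- fit_vertex(y, ds, 1L)

  same <- lrt(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # chi-square df = 1: statistic 3.841 sits at p ~ 0.05
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)

  expect_error(lrt(full, fit_vertex(y, ds, 0L)), "not comparable")
})

test_that("LRT statistic equals twice the oracle log-likelihood gap", {
  sim <- tiny_sim(seed = 82, n = 15L)
  ds <- sim$dataset
  y <- ds$measures[, 2L]
  d_full <- build_design(ds, 1L)
  d_red <- surflmm:::.reduce_design(
    d_full, c("group", "group_age", "group_age2"))
  full <- surflmm:::.fit_batch(matrix(y, ncol = 1L), d_full, q = 2L,
                               allow_fallback = FALSE)
  red <- surflmm:::.fit_batch(matrix(y, ncol = 1L), d_red, q = 2L,
                              allow_fallback = FALSE)
  stat <- 2 * (full$loglik[1L] - red$loglik[1L])

  ll_o_full <- marginal_loglik(
    y, d_full$X, d_full$subj, d_full$age_c, full$beta[, 1L],
    surflmm:::.re_covariance(full$theta[, 1L], full$sigma2[1L], 2L),
    full$sigma2[1L])
  ll_o_red <- marginal_loglik(
    y, d_red$X, d_red$subj, d_red$age_c, red$beta[, 1L],
    surflmm:::.re_covariance(red$theta[, 1L], red$sigma2[1L], 2L),
    red$sigma2[1L])
  expect_equal(stat, 2 * (ll_o_full - ll_o_red), tolerance = 1e-6)
})

test_that("shape effect is undefined (p = 1) at constant-order vertices", {
  cfg <- simulation_config(
    mesh_subdivisions = 0L, groups = c(control = 30L, case = 30L),
    baseline_curve = c(3, 0, 0),
    random_sd = c(intercept = 0.2, slope = 0, cor = 0), seed = 83)
  fit <- surf_lmm(simulate_dataset(cfg)$dataset, allowed_orders = 0L)
  pm <- surf_lrt(fit, "shape")
  expect_true(all(pm$p[fit$mask_idx] == 1))
  pg <- surf_lrt(fit, "group")
  expect_true(any(pg$p[fit$mask_idx] < 1))
})

test_that("cluster formation matches an independent flood fill", {
  mesh <- make_mesh(1L)
  far <- surflmm:::.farthest_vertex(mesh, 1L)
  patchA <- hop_ball(mesh, 1L, 1L)
  patchB <- hop_ball(mesh, far, 1L)
  p <- rep(0.5, n_vertices(mesh))
  p[c(patchA, patchB)] <- 0.001
  cl <- find_clusters(p, mesh, forming_threshold = 0.01)
  expect_length(cl$clusters, 2L)
  got <- lapply(cl$clusters, `[[`, "vertex_ids")
  oracle <- oracle_components(which(p < 0.01), mesh$adjacency)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(oracle, paste, collapse = ","))

  # no suprathreshold vertices
  expect_length(find_clusters(rep(0.5, 42), mesh, 0.01)$clusters, 0L)

  # whole mask below threshold: one cluster with every masked vertex
  cl_all <- find_clusters(rep(1e-4, 42), mesh, 0.01)
  expect_length(cl_all$clusters, 1L)
  expect_equal(cl_all$clusters[[1L]]$vertex_ids, 1:42)

  # peak vertex carries the smallest p
  p2 <- rep(0.5, 42)
  p2[patchA] <- c(0.005, rep(0.009, length(patchA) - 1L))
  cl2 <- find_clusters(p2, mesh, 0.01)
  expect_equal(cl2$clusters[[1L]]$peak_vertex, patchA[1L])
})

test_that("cluster correction implements the add-one estimator", {
  mesh <- make_mesh(0L)
  p <- rep(0.5, 12L)
  p[1:3] <- 0.001
  cl <- find_clusters(p, mesh, 0.01)

  null_lo <- rep(0, 99L)
  cc <- cluster_correct(cl, null_lo)
  expect_equal(cc$clusters[[1L]]$corrected_p, 0.01)

  null_hi <- rep(10, 99L)
  cc2 <- cluster_correct(cl, null_hi)
  expect_equal(cc2$clusters[[1L]]$corrected_p, 1)

  # corrected p is non-increasing in the cluster statistic
  nullv <- c(0, 1, 1, 2, 3, 5, 8)
  ps <- vapply(1:8, function(s) {
    fake <- cl
    fake$clusters[[1L]]$cluster_stat <- s
    cluster_correct(fake, nullv)$clusters[[1L]]$corrected_p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0))
})

test_that("tiny designs fall back to exhaustive enumeration", {
  cfg <- simulation_config(
    mesh_subdivisions = 0L, groups = c(control = 2L, case = 2L),
    scans_per_subject = c(0, 0, 1, 0, 0, 0), seed = 84)
  fit <- surf_lmm(simulate_dataset(cfg)$dataset, allowed_orders = 0L,
                  covariates = character(0))
  expect_warning(
    nullv <- permutation_null(fit, "group", n_perm = 99L, seed = 1L),
    "exhaustive")
  expect_length(nullv, choose(4, 2) - 1L)
  expect_true(attr(nullv, "exhaustive"))
})

test_that("the permutation null is reproducible and label-invariant at identity", {
  sim <- tiny_sim(seed = 85, n = 8L, subdiv = 1L)
  fit <- surf_lmm(sim$dataset, allowed_orders = 0:1)

  n1 <- permutation_null(fit, "group", n_perm = 15L, seed = 42L)
  n2 <- permutation_null(fit, "group", n_perm = 15L, seed = 42L)
  expect_identical(as.numeric(n1), as.numeric(n2))
  n3 <- permutation_null(fit, "group", n_perm = 15L, seed = 43L)
  expect_false(identical(as.numeric(n1), as.numeric(n3)))

  # relabeling with the observed assignment reproduces the observed p map
  md <- fit$dataset$metadata
  subjects <- unique(md$subject_id)
  identity_assign <- factor(md$group[match(subjects, md$subject_id)],
                            levels = fit$group_levels)
  for (eff in c("group", "shape")) {
    obs <- surf_lrt(fit, eff)
    rec <- surflmm:::.pmap_internal(fit, eff, assignment = identity_assign)
    expect_identical(rec$p, unname(obs$p[fit$mask_idx]))
  }
})

test_that("vertex-wise type-I error is near nominal under the null", {
  ps <- c()
  for (r in 1:25) {
    cfg <- simulation_config(mesh_subdivisions = 0L,
                             groups = c(control = 50L, case = 50L),
                             seed = 8600 + r)
    fit <- surf_lmm(simulate_dataset(cfg)$dataset, allowed_orders = 1L)
    pm <- surf_lrt(fit, "group")
    ps <- c(ps, pm$p[fit$mask_idx])
  }
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})
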