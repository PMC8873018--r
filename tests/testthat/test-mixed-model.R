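test_that("design matrices have the canonical columns", {
  sim <- tiny_sim(seed = 3, n = 10L)
  ds <- sim$dataset

  d0 <- build_design(ds, 0L, covariates = character(0))
  expect_equal(ncol(d0$X), 2L)
  expect_equal(d0$terms, c("intercept", "group"))
  expect_equal(d0$q, 1L)

  d2 <- build_design(ds, 2L)  # sex + 3 scanner levels
  expect_equal(ncol(d2$X), 9L)
  expect_equal(d2$terms,
               c("intercept", "group", "age", "group_age", "age2",
                 "group_age2", "sex", "scanner", "scanner"))
  expect_equal(d2$q, 2L)

  # three groups, order 1: intercept + 2 dummies + age + 2 interactions
  cfg3 <- simulation_config(mesh_subdivisions = 0L,
                            groups = c(a = 6L, b = 6L, c = 6L), seed = 5)
  ds3 <- simulate_dataset(cfg3)$dataset
  d1 <- build_design(ds3, 1L, covariates = character(0))
  expect_equal(ncol(d1$X), 6L)

  expect_error(build_design(ds, 1L, covariates = c("sex", "icv")), "SA")
})

test_that("marginal log-likelihood oracle matches closed forms", {
  # one subject, one scan, standard normal at 0
  X <- matrix(1, 1L, 1L)
  ll1 <- marginal_loglik(0, X, subj = 0L, age_c = 0, beta = 0,
                         G = matrix(0, 1, 1), sigma2 = 1)
  expect_equal(ll1, -0.5 * log(2 * pi), tolerance = 1e-12)

  # two independent scans: additivity
  X2 <- matrix(1, 2L, 1L)
  ll2 <- marginal_loglik(c(0, 0), X2, subj = c(0L, 1L), age_c = c(0, 0),
                         beta = 0, G = matrix(0, 1, 1), sigma2 = 1)
  expect_equal(ll2, -log(2 * pi), tolerance = 1e-12)

  # 3 subjects x 2 scans vs a dense 6x6 multivariate normal density
  set.seed(7)
  subj <- rep(0:2, each = 2L)
  age_c <- rnorm(6)
  X <- cbind(1, age_c)
  beta <- c(3, -0.05)
  G <- diag(c(0.04, 0))
  sigma2 <- 0.01
  y <- rnorm(6, 3)
  V <- matrix(0, 6, 6)
  for (s in 0:2) {
    idx <- which(subj == s)
    Z <- cbind(1, age_c[idx])
    V[idx, idx] <- Z %*% G %*% t(Z)
  }
  V <- V + diag(sigma2, 6)
  r <- y - X %*% beta
  dense <- -0.5 * (6 * log(2 * pi) + determinant(V)$modulus[1] +
                   t(r) %*% solve(V) %*% r)
  expect_equal(marginal_loglik(y, X, subj, age_c, beta, G, sigma2),
               as.numeric(dense), tolerance = 1e-9)

  expect_error(marginal_loglik(0, matrix(1, 1, 1), 0L, 0, 0,
                               matrix(0, 1, 1), 0), "singular")
})

test_that("optimizer log-likelihood equals the oracle at fitted parameters", {
  for (s in 1:10) {
    set.seed(800 + s)
    sim <- tiny_sim(seed = 800 + s, n = sample(4:5, 1L),
                    scans_per_subject = c(0, 0.4, 0.4, 0.2, 0, 0))
    ds <- sim$dataset
    o <- sample(0:2, 1L)
    v <- sample.int(12L, 1L)
    vf <- fit_vertex(ds$measures[, v], ds, o)
    expect_true(vf$converged)
    d <- build_design(ds, o)
    ll <- marginal_loglik(ds$measures[, v], d$X, d$subj, d$age_c, vf$beta,
                          if (vf$q == 1L) vf$G[1L, 1L, drop = FALSE] else vf$G,
                          vf$sigma2)
    expect_equal(vf$loglik, ll, tolerance = 1e-6)
  }
})

test_that("noiseless data are interpolated exactly at every order", {
  cfg <- noiseless_config(seed = 11, n = 10L,
                          effect_clusters = list(list(
                            seed_vertex = 1L, radius_hops = 0L,
                            beta_g = -0.2, beta_ag1 = -0.01,
                            beta_ag2 = 5e-4)))
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  ac <- mean(ds$metadata$age)
  base_c <- center_poly(cfg$baseline_curve, ac)

  vf2 <- fit_vertex(ds$measures[, 1L], ds, 2L, covariates = character(0))
  expect_lt(max(abs(vf2$beta[c("(Intercept)", "age", "age2")] - base_c)),
            1e-6)
  delta_c <- center_poly(c(-0.2, -0.01, 5e-4), ac)
  expect_lt(max(abs(vf2$beta[c("groupcase", "groupcase:age",
                               "groupcase:age2")] - delta_c)), 1e-6)

  # a vertex without planted effects, generated by a pure quadratic
  vf2b <- fit_vertex(ds$measures[, 5L], ds, 2L, covariates = character(0))
  expect_lt(max(abs(vf2b$beta[c("(Intercept)", "age", "age2")] - base_c)),
            1e-6)
  expect_lt(max(abs(vf2b$beta[c("groupcase", "groupcase:age",
                                "groupcase:age2")])), 1e-6)

  # linear and constant generators recovered at their own orders
  cfg1 <- noiseless_config(seed = 12, n = 10L,
                           baseline_curve = c(3.5, -0.02, 0))
  ds1 <- simulate_dataset(cfg1)$dataset
  vf1 <- fit_vertex(ds1$measures[, 2L], ds1, 1L, covariates = character(0))
  ac1 <- mean(ds1$metadata$age)
  expect_lt(max(abs(vf1$beta[c("(Intercept)", "age")] -
                    center_poly(c(3.5, -0.02, 0), ac1)[1:2])), 1e-6)

  cfg0 <- noiseless_config(seed = 13, n = 10L,
                           baseline_curve = c(2.8, 0, 0))
  ds0 <- simulate_dataset(cfg0)$dataset
  vf0 <- fit_vertex(ds0$measures[, 3L], ds0, 0L, covariates = character(0))
  expect_lt(abs(vf0$beta[["(Intercept)"]] - 2.8), 1e-6)
  expect_lte(vf0$sigma2, 1e-8)
  expect_true(vf0$converged)
})

test_that("ML fit is at least as likely as the generating parameters", {
  cfg <- simulation_config(mesh_subdivisions = 0L,
                           groups = c(control = 15L, case = 15L), seed = 21)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  d <- build_design(ds, 1L, covariates = c("sex", "scanner"))
  ac <- d$age_center
  for (v in c(1L, 6L)) {
    vf <- fit_vertex(ds$measures[, v], ds, 1L)
    # generating parameters mapped to the centered-age design
    base_c <- center_poly(cfg$baseline_curve, ac)
    beta_gen <- setNames(numeric(ncol(d$X)), colnames(d$X))
    beta_gen["(Intercept)"] <- base_c[1L]
    beta_gen["age"] <- base_c[2L]
    beta_gen["sexM"] <- cfg$sex_effect
    beta_gen[grep("scanner", names(beta_gen))] <-
      cfg$scanner_offsets[2:3] - cfg$scanner_offsets[1L]
    # raw-age random effects re-expressed at the centered origin
    sdu <- cfg$random_sd
    Gr <- matrix(c(sdu[["intercept"]]^2,
                   sdu[["cor"]] * sdu[["intercept"]] * sdu[["slope"]],
                   sdu[["cor"]] * sdu[["intercept"]] * sdu[["slope"]],
                   sdu[["slope"]]^2), 2, 2)
    Tm <- matrix(c(1, 0, ac, 1), 2, 2)
    Gc <- Tm %*% Gr %*% t(Tm)
    ll_gen <- marginal_loglik(ds$measures[, v], d$X, d$subj, d$age_c,
                              beta_gen, Gc, cfg$residual_sd^2)
    expect_gte(vf$loglik + 1e-6, ll_gen)
  }
})

test_that("log-likelihood is monotone under nesting", {
  sim <- tiny_sim(seed = 31, n = 12L)
  ds <- sim$dataset
  y <- ds$measures[, 4L]
  ll <- vapply(0:2, function(o) fit_vertex(y, ds, o)$loglik, numeric(1))
  expect_true(all(diff(ll) >= -1e-6))

  # adding group terms never decreases the maximum
  d1 <- build_design(ds, 1L)
  full <- surflmm:::.fit_batch(matrix(y, ncol = 1L), d1, q = 2L)
  red <- surflmm:::.fit_batch(
    matrix(y, ncol = 1L),
    surflmm:::.reduce_design(d1, c("group", "group_age", "group_age2")),
    q = 2L)
  expect_gte(full$loglik[1L] + 1e-6, red$loglik[1L])
})

test_that("shifting the age center changes coefficients but not the likelihood", {
  sim <- tiny_sim(seed = 41, n = 12L)
  ds <- sim$dataset
  y <- ds$measures[, 2L]
  f1 <- fit_vertex(y, ds, 2L, age_center = 15)
  f2 <- fit_vertex(y, ds, 2L, age_center = 25)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-6 * (1 + abs(f1$loglik)))
  # polynomial reparameterization identity: center 15 = center 25 shifted
  # by -10 on the centered axis
  b <- f2$beta
  shift <- -10
  expect_lt(abs(f1$beta[["age2"]] - b[["age2"]]), 1e-5)
  expect_lt(abs(f1$beta[["age"]] - (b[["age"]] + 2 * b[["age2"]] * shift)),
            1e-4)
  expect_lt(abs(f1$beta[["(Intercept)"]] -
                (b[["(Intercept)"]] + b[["age"]] * shift +
                 b[["age2"]] * shift^2)), 1e-4)
})

test_that("fit agrees with lme4 on a moderate fixture", {
  skip_if_not_installed("lme4")
  sim <- tiny_sim(seed = 51, n = 25L)
  ds <- sim$dataset
  y <- ds$measures[, 8L]
  md <- ds$metadata
  md$age_c <- md$age - mean(md$age)
  lf <- lme4::lmer(y ~ group * age_c + sex + scanner +
                     (1 + age_c | subject_id),
                   md, REML = FALSE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore"))
  vf <- fit_vertex(y, ds, 1L)
  expect_equal(vf$loglik, as.numeric(logLik(lf)), tolerance = 1e-4)
  expect_equal(unname(vf$beta[["groupcase:age"]]),
               unname(lme4::fixef(lf)[["groupcase:age_c"]]),
               tolerance = 1e-3)
})

test_that("surface fits honor the mask and are deterministic", {
  sim <- tiny_sim(seed = 61, n = 10L, subdiv = 1L)
  ds <- sim$dataset
  ds$mesh <- set_mesh_mask(ds$mesh, c(rep(FALSE, 10L), rep(TRUE, 32L)))
  f <- fit_surface(ds, 1L)
  expect_equal(length(f$loglik), 32L)
  expect_true(all(f$converged))
  f2 <- fit_surface(ds, 1L)
  expect_identical(f$loglik, f2$loglik)
  expect_identical(f$beta, f2$beta)
})

test_that("fixed-effect estimates are unbiased on replicated simulations", {
  # modest Monte-Carlo check: group-by-age interaction at a planted vertex
  reps <- 30L
  est <- numeric(reps)
  truth <- -0.02
  for (r in seq_len(reps)) {
    cfg <- simulation_config(
      mesh_subdivisions = 0L, groups = c(control = 40L, case = 40L),
      effect_clusters = list(list(seed_vertex = 1L, radius_hops = 0L,
                                  beta_ag1 = truth)),
      seed = 7100 + r)
    ds <- simulate_dataset(cfg)$dataset
    vf <- fit_vertex(ds$measures[, 1L], ds, 1L)
    est[r] <- vf$beta[["groupcase:age"]]
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - truth), 2.5 * mc_se + 1e-4)
})
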