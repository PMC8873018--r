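test_that("scan bookkeeping is exact for degenerate weight configurations", {
  cfg <- simulation_config(mesh_subdivisions = 0L,
                           groups = c(control = 10L, case = 10L),
                           scans_per_subject = c(0, 1, 0, 0, 0, 0),
                           seed = 101)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$dataset$metadata), 40L)
  expect_equal(length(unique(sim$dataset$metadata$subject_id)), 20L)
  tab <- table(table(sim$dataset$metadata$subject_id))
  expect_identical(names(tab), "2")
})

test_that("simulation is a deterministic function of the config seed", {
  cfg <- simulation_config(groups = c(control = 10L, case = 10L), seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$measures, b$dataset$measures)
  expect_identical(a$dataset$metadata, b$dataset$metadata)
  expect_identical(a$truth$u, b$truth$u)

  cfg2 <- simulation_config(groups = c(control = 10L, case = 10L), seed = 6)
  c_ <- simulate_dataset(cfg2)
  expect_false(identical(a$dataset$measures, c_$dataset$measures))
  # truth structure (planted effects) is seed-independent
  expect_identical(a$truth$beta_g, c_$truth$beta_g)
})

test_that("ages respect the configured range and visit spacing", {
  cfg <- simulation_config(groups = c(control = 40L, case = 40L), seed = 7)
  md <- simulate_dataset(cfg)$dataset$metadata
  expect_true(all(md$age >= 5 & md$age <= 35))
  spans <- tapply(md$age, md$subject_id, function(a) diff(sort(a)))
  gaps <- unlist(spans)
  expect_true(all(gaps <= 4 + 1e-9))
})

test_that("realized random effects match the configured moments", {
  us <- do.call(rbind, lapply(1:25, function(r) {
    cfg <- simulation_config(mesh_subdivisions = 0L,
                             groups = c(control = 60L, case = 60L),
                             seed = 1100 + r)
    simulate_dataset(cfg)$truth$u
  }))
  expect_lt(abs(var(us[, 1L]) / 0.25^2 - 1), 0.15)
  expect_lt(abs(var(us[, 2L]) / 0.01^2 - 1), 0.15)
  expect_lt(abs(cor(us[, 1L], us[, 2L]) - (-0.2)), 0.08)
})

test_that("planted effect clusters are connected and correctly placed", {
  mesh <- make_mesh(1L)
  far <- surflmm:::.farthest_vertex(mesh, 1L)
  cfg <- simulation_config(
    groups = c(control = 10L, case = 10L),
    effect_clusters = list(
      list(seed_vertex = 1L, radius_hops = 1L, beta_g = 0.5),
      list(seed_vertex = far, radius_hops = 2L, beta_ag1 = -0.03)),
    seed = 8)
  sim <- simulate_dataset(cfg)
  memb <- sim$truth$cluster_membership
  expect_equal(which(memb[, 1L]), hop_ball(mesh, 1L, 1L))
  expect_equal(which(memb[, 2L]), hop_ball(mesh, far, 2L))
  for (ci in 1:2) {
    comp <- oracle_components(which(memb[, ci]), mesh$adjacency)
    expect_length(comp, 1L)
  }
  expect_true(all(sim$truth$beta_g[memb[, 1L], 2L] == 0.5))
  expect_true(all(sim$truth$beta_g[!memb[, 1L], 2L] == 0))
})

test_that("the study replica reproduces the printed design exactly at scale 1", {
  cfg <- study_design_replica(1, "case_control", seed = 3)
  sim <- simulate_dataset(cfg)
  md <- sim$dataset$metadata
  expect_equal(length(unique(md$subject_id)), 324L)
  expect_equal(nrow(md), 636L)
  expect_equal(as.numeric(table(md$group)), c(302, 334))
  subj_first <- md[!duplicated(md$subject_id), ]
  expect_equal(as.numeric(table(subj_first$group)), c(176, 148))
  # female counts and scanner quotas from the printed tables
  expect_equal(sum(subj_first$sex == "F" & subj_first$group == "control"),
               86L)
  expect_equal(sum(subj_first$sex == "F" & subj_first$group == "case22q"),
               75L)
  expect_equal(as.numeric(table(md$scanner)), c(158, 300, 178))
  expect_true(all(md$age >= 5 & md$age <= 35))
  expect_lte(max(table(md$subject_id)), 6L)

  cfg2 <- study_design_replica(1, "subgroup", seed = 3)
  sim2 <- simulate_dataset(cfg2)
  md2 <- sim2$dataset$metadata
  expect_equal(length(unique(md2$subject_id)), 108L)
  expect_equal(nrow(md2), 244L)
  expect_equal(as.numeric(table(md2$group)), c(98, 146))
  expect_lte(max(table(md2$subject_id)), 5L)
  expect_true(all(md2$age >= 6 & md2$age <= 28))
})

test_that("scaled-down replicas keep the invariants", {
  cfg <- study_design_replica(0.1, "case_control", seed = 4)
  sim <- simulate_dataset(cfg)
  md <- sim$dataset$metadata
  subj_first <- md[!duplicated(md$subject_id), ]
  expect_equal(as.numeric(table(subj_first$group)), c(18, 15))
  expect_true(all(table(md$subject_id) >= 1))
  expect_true(all(table(md$subject_id) <= 6))
  expect_s3_class(sim$dataset, "surf_dataset")
})

test_that("presets build valid configurations", {
  for (nm in c("null", "case-control-default", "study-replica",
               "subgroup-replica")) {
    cfg <- preset_config(nm, seed = 2)
    expect_s3_class(cfg, "sim_config")
  }
  cfg <- preset_config("case-control-default")
  expect_length(cfg$effect_clusters, 2L)
  expect_error(preset_config("nope"), "arg")
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(groups = c(a = 0L, b = 5L)),
               "at least one subject")
  expect_error(simulation_config(groups = c(5L, 5L)), "named")
  expect_error(simulation_config(scans_per_subject = c(0.5, 0.4)),
               "sum to 1")
  expect_error(simulation_config(residual_sd = 0), "residual_sd")
})
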