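#' Icosphere test mesh
#'
#' Builds a closed triangulated sphere by repeated edge-midpoint
#' subdivision of a regular icosahedron, projecting new vertices onto the
#' sphere. Vertex count is `10 * 4^s + 2`. The radius (50 mm by default)
#' puts triangle areas on the scale of a coarsely decimated cortical
#' hemisphere.
#'
#' @param subdivisions subdivision level `s` in 0..4.
#' @param radius sphere radius in mm.
#' @return a [surface_mesh()].
#' @export
make_mesh <- function(subdivisions = 1L, radius = 50) {
  stopifnot(subdivisions %in% 0:4)
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(rowSums(verts^2))
  tris <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- get0(key, envir = mid_cache, inherits = FALSE)
      if (!is.null(idx)) return(idx)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      assign(key, idx, envir = mid_cache)
      idx
    }
    new_tris <- matrix(0L, 0L, 3L)
    for (t in seq_len(nrow(tris))) {
      a <- tris[t, 1L]; b <- tris[t, 2L]; c_ <- tris[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      new_tris <- rbind(new_tris, c(a, ab, ca), c(b, bc, ab),
                        c(c_, ca, bc), c(ab, bc, ca))
    }
    tris <- new_tris
  }
  surface_mesh(verts * radius, tris)
}

#' Vertices within a hop radius on the mesh
#'
#' Breadth-first ball of the adjacency graph around a seed vertex; used to
#' plant connected effect clusters.
#'
#' @param mesh a [surface_mesh()].
#' @param seed_vertex 1-based seed vertex.
#' @param hops number of adjacency hops (0 = the seed alone).
#' @return sorted integer vector of vertex ids.
#' @export
hop_ball <- function(mesh, seed_vertex, hops) {
  stopifnot(hops >= 0)
  current <- seed_vertex
  ball <- seed_vertex
  for (h in seq_len(hops)) {
    nb <- unique(unlist(mesh$adjacency[current]))
    current <- setdiff(nb, ball)
    ball <- c(ball, current)
  }
  sort(unique(ball))
}

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the generating process: an icosphere mesh, two or more groups,
#' 1-6 scans per subject, ages in a range, a shared quadratic baseline
#' growth curve, planted group-effect clusters, subject random intercepts
#' and slopes shared across vertices, scanner and sex offsets, and
#' vertex-independent Gaussian noise. Defaults emulate a longitudinal
#' developmental case-control cohort: thickness near 3.3 mm in childhood,
#' thinning at about 0.05 mm/year around age 8 and decelerating to zero by
#' age 30 (a clearly quadratic maturation curve), subject SD 0.25 mm, scan
#' noise 0.1 mm.
#'
#' @param mesh_subdivisions icosphere level (0: 12 vertices, 1: 42,
#'   2: 162).
#' @param groups named integer vector of subjects per group; the first
#'   name is the reference group.
#' @param scans_per_subject probability weights over 1..`length(weights)`
#'   scans.
#' @param scan_counts optional list (one element per group) of exact
#'   per-subject scan counts, overriding random draws — used by the design
#'   replica so printed totals are met exactly.
#' @param age_range first-visit age range (years).
#' @param interscan_interval range of the uniform inter-scan interval
#'   (years).
#' @param baseline_curve coefficients (mm, mm/yr, mm/yr^2) of the shared
#'   trajectory as a polynomial in age.
#' @param effect_clusters list of planted effects; each element is a list
#'   with `seed_vertex`, `radius_hops`, optional `group` (label of the
#'   affected non-reference group; default second group) and any of
#'   `beta_g` (mm), `beta_ag1` (mm/yr), `beta_ag2` (mm/yr^2) added to that
#'   group's fixed effects inside the cluster.
#' @param random_sd named vector `c(intercept =, slope =, cor =)`: SDs of
#'   the subject random intercept (mm) and slope (mm/yr) on the raw age
#'   scale and their correlation.
#' @param residual_sd scan-level noise SD (mm).
#' @param scanner_offsets additive per-scanner offsets (mm); length =
#'   number of scanner levels.
#' @param scanner_props scan proportions per scanner level.
#' @param sex_effect additive offset for the second sex level (mm).
#' @param female_prop proportion of female subjects per group (recycled).
#' @param measure_floor lower clamp on simulated values (mm), keeping
#'   thickness physiological at extreme ages.
#' @param seed integer seed; the dataset is a deterministic function of
#'   the config.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(mesh_subdivisions = 1L,
                              groups = c(control = 100L, case = 100L),
                              scans_per_subject = c(0.25, 0.30, 0.20, 0.15,
                                                    0.07, 0.03),
                              scan_counts = NULL,
                              age_range = c(5, 35),
                              interscan_interval = c(1, 4),
                              baseline_curve = c(3.81, -0.0682, 0.001136),
                              effect_clusters = list(),
                              random_sd = c(intercept = 0.25, slope = 0.01,
                                            cor = -0.2),
                              residual_sd = 0.1,
                              scanner_offsets = c(0, 0.05, -0.03),
                              scanner_props = NULL,
                              sex_effect = 0.05,
                              female_prop = 0.5,
                              measure_floor = 0.5,
                              seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named vector")
  }
  if (any(groups < 1L)) stop("every group needs at least one subject")
  if (abs(sum(scans_per_subject) - 1) > 1e-8) {
    stop("scans_per_subject weights must sum to 1")
  }
  if (residual_sd <= 0) stop("residual_sd must be > 0")
  if (is.null(scanner_props)) {
    scanner_props <- rep(1 / length(scanner_offsets),
                         length(scanner_offsets))
  }
  stopifnot(length(scanner_props) == length(scanner_offsets))
  for (cl in effect_clusters) {
    if (is.null(cl$seed_vertex) || is.null(cl$radius_hops) ||
        cl$radius_hops < 0) {
      stop("each effect cluster needs seed_vertex and radius_hops >= 0")
    }
  }
  structure(list(
    mesh_subdivisions = as.integer(mesh_subdivisions), groups = groups,
    scans_per_subject = scans_per_subject, scan_counts = scan_counts,
    age_range = age_range, interscan_interval = interscan_interval,
    baseline_curve = baseline_curve, effect_clusters = effect_clusters,
    random_sd = random_sd, residual_sd = residual_sd,
    scanner_offsets = scanner_offsets, scanner_props = scanner_props,
    sex_effect = sex_effect,
    female_prop = rep(female_prop, length.out = length(groups)),
    measure_floor = measure_floor, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      paste(sprintf("%s n=%d", names(x$groups), x$groups), collapse = ", "),
      sprintf("| mesh s=%d | ages %g-%g | %d planted cluster(s) | seed %d\n",
              x$mesh_subdivisions, x$age_range[1L], x$age_range[2L],
              length(x$effect_clusters), x$seed))
  invisible(x)
}

# Integer quota allocation of n items to categories by proportions
# (largest-remainder rounding; deterministic).
.quota_alloc <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic longitudinal surface dataset with known truth
#'
#' Draws subjects, visit schedules, covariates, subject random effects
#' (shared across vertices) and scan noise (independent across vertices),
#' and evaluates the generating fixed-effect surface: baseline curve plus
#' planted cluster effects for the affected groups. Reproducible: the same
#' config yields a bitwise identical dataset.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (a `surf_dataset`) and `truth`
#'   (per-vertex generating coefficients, realized random effects,
#'   cluster membership and the config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  mesh <- make_mesh(config$mesh_subdivisions)
  nv <- n_vertices(mesh)
  glab <- names(config$groups)
  n_subj <- sum(config$groups)

  subj_group <- factor(rep(glab, config$groups), levels = glab)
  # sex by per-group quota so stated proportions are met exactly
  subj_sex <- unlist(lapply(seq_along(glab), function(gi) {
    ng <- config$groups[gi]
    nf <- round(ng * config$female_prop[gi])
    sample(rep(c("F", "M"), c(nf, ng - nf)))
  }))
  subj_sex <- factor(subj_sex, levels = c("F", "M"))
  subj_id <- sprintf("S%03d", seq_len(n_subj))

  # scans per subject: exact allocation if provided, else i.i.d. weights
  if (!is.null(config$scan_counts)) {
    n_scans <- unlist(lapply(seq_along(glab), function(gi) {
      cnt <- config$scan_counts[[gi]]
      if (length(cnt) != config$groups[gi]) {
        stop("scan_counts[[", gi, "]] length != group size")
      }
      sample(cnt)  # shuffle within group
    }))
  } else {
    n_scans <- sample(seq_along(config$scans_per_subject), n_subj,
                      replace = TRUE, prob = config$scans_per_subject)
  }

  # visit schedules: inter-scan intervals uniform in the configured range;
  # the first visit is placed uniformly in the feasible window, and the
  # whole schedule is compressed into the age range if it cannot fit
  amin <- config$age_range[1L]
  amax <- config$age_range[2L]
  ages <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    k <- n_scans[i]
    gaps <- if (k > 1L) runif(k - 1L, config$interscan_interval[1L],
                              config$interscan_interval[2L]) else numeric(0)
    span <- sum(gaps)
    if (span <= amax - amin) {
      a0 <- runif(1L, amin, amax - span)
    } else {
      a0 <- amin
      gaps <- gaps * (amax - amin) / span
    }
    ages[[i]] <- a0 + c(0, cumsum(gaps))
  }

  total_scans <- sum(n_scans)
  scan_subj <- rep(seq_len(n_subj), n_scans)
  scan_age <- unlist(ages)
  scanner <- factor(sample(rep(paste0("scanner", seq_along(config$scanner_offsets)),
                               .quota_alloc(total_scans, config$scanner_props))),
                    levels = paste0("scanner",
                                    seq_along(config$scanner_offsets)))

  # subject random effects (one intercept/slope pair, shared across
  # vertices), raw-age parameterization
  sd_u <- config$random_sd
  Sigma <- matrix(c(sd_u[["intercept"]]^2,
                    sd_u[["cor"]] * sd_u[["intercept"]] * sd_u[["slope"]],
                    sd_u[["cor"]] * sd_u[["intercept"]] * sd_u[["slope"]],
                    sd_u[["slope"]]^2), 2L, 2L)
  u <- matrix(0, n_subj, 2L)
  if (any(diag(Sigma) > 0)) {
    ev <- eigen(Sigma, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2L)
    u <- matrix(rnorm(2L * n_subj), n_subj, 2L) %*% t(L)
  }

  # per-vertex generating fixed effects: baseline + planted cluster deltas
  bc <- config$baseline_curve
  beta_g <- matrix(0, nv, length(glab))    # per-group intercept offset
  beta_ag1 <- matrix(0, nv, length(glab))  # per-group linear age delta
  beta_ag2 <- matrix(0, nv, length(glab))  # per-group quadratic delta
  member <- matrix(FALSE, nv, max(1L, length(config$effect_clusters)))
  for (ci in seq_along(config$effect_clusters)) {
    cl <- config$effect_clusters[[ci]]
    ball <- hop_ball(mesh, cl$seed_vertex, cl$radius_hops)
    member[ball, ci] <- TRUE
    gi <- if (is.null(cl$group)) 2L else match(cl$group, glab)
    if (is.na(gi)) stop("unknown cluster group label: ", cl$group)
    if (!is.null(cl$beta_g)) beta_g[ball, gi] <- beta_g[ball, gi] + cl$beta_g
    if (!is.null(cl$beta_ag1)) {
      beta_ag1[ball, gi] <- beta_ag1[ball, gi] + cl$beta_ag1
    }
    if (!is.null(cl$beta_ag2)) {
      beta_ag2[ball, gi] <- beta_ag2[ball, gi] + cl$beta_ag2
    }
  }

  gi_scan <- as.integer(subj_group)[scan_subj]
  base_scan <- bc[1L] + bc[2L] * scan_age + bc[3L] * scan_age^2 +
    config$scanner_offsets[as.integer(scanner)] +
    config$sex_effect * (subj_sex[scan_subj] == "M") +
    u[scan_subj, 1L] + u[scan_subj, 2L] * scan_age

  measures <- matrix(rnorm(total_scans * nv, 0, config$residual_sd),
                     total_scans, nv)
  measures <- measures + base_scan
  # add vertex-specific group effects: for scan s with group g,
  # beta_g[v,g] + beta_ag1[v,g]*age + beta_ag2[v,g]*age^2
  measures <- measures + t(beta_g[, gi_scan, drop = FALSE]) +
    t(beta_ag1[, gi_scan, drop = FALSE]) * scan_age +
    t(beta_ag2[, gi_scan, drop = FALSE]) * scan_age^2
  measures[measures < config$measure_floor] <- config$measure_floor

  metadata <- data.frame(
    subject_id = subj_id[scan_subj],
    scan_id = sprintf("scan%04d", seq_len(total_scans)),
    group = factor(as.character(subj_group[scan_subj]), levels = glab),
    age = scan_age,
    sex = subj_sex[scan_subj],
    scanner = scanner
  )
  dataset <- longitudinal_dataset(mesh, metadata, measures,
                                  measure_kind = "CT")
  truth <- list(
    baseline_curve = bc, beta_g = beta_g, beta_ag1 = beta_ag1,
    beta_ag2 = beta_ag2, u = u, subject_group = subj_group,
    cluster_membership = member[, seq_along(config$effect_clusters),
                                drop = FALSE],
    config = config
  )
  list(dataset = dataset, truth = truth)
}
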