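# Deterministic per-subject scan-count allocation matching given subject
# and scan totals: truncated-geometric weights fitted to the required mean,
# largest-remainder rounding, then minimal integer moves between adjacent
# counts until the scan total is exact.
.fit_scan_counts <- function(n_subjects, n_scans, max_scans) {
  stopifnot(n_scans >= n_subjects, n_scans <= n_subjects * max_scans)
  K <- max_scans
  target_mean <- n_scans / n_subjects
  geo_mean <- function(lr) {
    w <- exp(lr)^(0:(K - 1L))
    sum((1:K) * w) / sum(w)
  }
  if (abs(target_mean - (K + 1) / 2) < 1e-12) {
    w <- rep(1 / K, K)
  } else {
    lr <- uniroot(function(x) geo_mean(x) - target_mean, c(-20, 20),
                  tol = 1e-12)$root
    w <- exp(lr)^(0:(K - 1L))
    w <- w / sum(w)
  }
  counts <- .quota_alloc(n_subjects, w)
  tot <- function(cnt) sum((1:K) * cnt)
  guard <- 0L
  while (tot(counts) != n_scans && (guard <- guard + 1L) < 10000L) {
    if (tot(counts) < n_scans) {
      c_ <- which.max(counts[1:(K - 1L)])
      counts[c_] <- counts[c_] - 1L
      counts[c_ + 1L] <- counts[c_ + 1L] + 1L
    } else {
      c_ <- which.max(counts[2:K]) + 1L
      counts[c_] <- counts[c_] - 1L
      counts[c_ - 1L] <- counts[c_ - 1L] + 1L
    }
  }
  if (tot(counts) != n_scans) stop("scan-count allocation failed")
  list(counts = counts, weights = w,
       per_subject = rep(1:K, counts))
}

#' Simulation config replicating the study design's printed totals
#'
#' Builds a [simulation_config()] whose group sizes, per-group scan
#' totals, female counts, age range and scanner proportions reproduce a
#' two-group longitudinal developmental cohort: at `scale = 1`,
#' case-control = 176 controls (302 scans) vs 148 cases (334 scans), ages
#' 5-35, up to 6 scans per subject, 636 scans on three scanners
#' (158/300/178); subgroup = 47 vs 61 subjects (98/146 scans), ages 6-28,
#' up to 5 scans, 244 scans total. Scans-per-subject counts are allocated
#' deterministically so the totals are met exactly (see
#' `scan_counts` in [simulation_config()]).
#'
#' @param scale sampling fraction in (0, 1]; subject and scan totals are
#'   scaled and rounded, keeping at least 2 subjects per group.
#' @param variant `"case_control"` or `"subgroup"`.
#' @param seed integer seed stored in the config.
#' @param effect_clusters planted effects (default none: a pure design
#'   replica).
#' @return a `sim_config`.
#' @export
study_design_replica <- function(scale = 1,
                                 variant = c("case_control", "subgroup"),
                                 seed = 1L, effect_clusters = list()) {
  stopifnot(scale > 0, scale <= 1)
  variant <- match.arg(variant)
  des <- if (variant == "case_control") {
    list(groups = c(control = 176L, case22q = 148L),
         scans = c(302L, 334L), female = c(86L, 75L),
         age_range = c(5, 35), max_scans = 6L,
         scanner_props = c(158, 300, 178) / 636)
  } else {
    list(groups = c(NPS = 47L, LAPS = 61L),
         scans = c(98L, 146L), female = c(23L, 29L),
         age_range = c(6, 28), max_scans = 5L,
         scanner_props = c(158, 300, 178) / 636)
  }
  ng <- pmax(2L, as.integer(round(des$groups * scale)))
  ns <- as.integer(round(des$scans * scale))
  ns <- pmax(ns, ng)
  ns <- pmin(ns, ng * des$max_scans)

  alloc <- lapply(seq_along(ng), function(i) {
    .fit_scan_counts(ng[i], ns[i], des$max_scans)
  })
  weights <- Reduce(`+`, lapply(seq_along(ng),
                                function(i) alloc[[i]]$weights * ng[i]))
  weights <- weights / sum(weights)

  simulation_config(
    mesh_subdivisions = 1L,
    groups = setNames(ng, names(des$groups)),
    scans_per_subject = weights,
    scan_counts = lapply(alloc, `[[`, "per_subject"),
    age_range = des$age_range,
    effect_clusters = effect_clusters,
    scanner_props = des$scanner_props,
    female_prop = des$female / des$groups,
    seed = seed
  )
}

#' Named simulation presets
#'
#' * `"null"`: two groups of 30 subjects, 42-vertex icosphere, no planted
#'   effects — for calibration and family-wise error studies.
#' * `"case-control-default"`: two groups of 100 subjects with two planted
#'   clusters: a group-offset cluster (+0.2 mm) and, at the most distant
#'   vertex, a group-by-age interaction cluster (-0.025 mm/yr accelerated
#'   thinning).
#' * `"study-replica"` / `"subgroup-replica"`: [study_design_replica()]
#'   designs with no planted effects.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
preset_config <- function(name = c("null", "case-control-default",
                                   "study-replica", "subgroup-replica"),
                          seed = 1L) {
  name <- match.arg(name)
  if (name == "null") {
    simulation_config(groups = c(control = 30L, case = 30L), seed = seed)
  } else if (name == "case-control-default") {
    mesh <- make_mesh(1L)
    far <- .farthest_vertex(mesh, 1L)
    simulation_config(
      groups = c(control = 100L, case = 100L),
      effect_clusters = list(
        list(seed_vertex = 1L, radius_hops = 1L, beta_g = 0.2),
        list(seed_vertex = far, radius_hops = 1L, beta_ag1 = -0.025)
      ),
      seed = seed)
  } else if (name == "study-replica") {
    study_design_replica(1, "case_control", seed = seed)
  } else {
    study_design_replica(1, "subgroup", seed = seed)
  }
}

# Vertex with the largest hop distance from `from` (smallest id on ties).
.farthest_vertex <- function(mesh, from) {
  dist <- rep(NA_integer_, n_vertices(mesh))
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nb <- unique(unlist(mesh$adjacency[frontier]))
    nb <- nb[is.na(dist[nb])]
    dist[nb] <- d
    frontier <- nb
  }
  which.max(dist)
}
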