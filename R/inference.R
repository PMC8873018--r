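#' Likelihood-ratio test between two nested vertex fits
#'
#' `2 * (logLik(full) - logLik(reduced))` referred to the upper tail of a
#' chi-square with degrees of freedom equal to the difference in
#' fixed-effect count. The statistic is clamped at 0 (small negative values
#' can arise from finite optimizer tolerance). Both fits must use the same
#' data and random structure and the reduced fixed effects must be a subset
#' of the full ones.
#'
#' @param full,reduced `vertex_fit` objects from [fit_vertex()].
#' @return list with `statistic`, `df`, `p` and `converged`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "vertex_fit"), inherits(reduced, "vertex_fit"))
  if (full$n_obs != reduced$n_obs || full$q != reduced$q) {
    stop("fits are not comparable (different data or random structure)")
  }
  cnt_f <- table(full$terms)
  cnt_r <- table(reduced$terms)
  if (!all(names(cnt_r) %in% names(cnt_f)) ||
      any(cnt_f[names(cnt_r)] < cnt_r)) {
    stop("models are not nested (reduced terms not a subset of full terms)")
  }
  df <- full$n_fixed - reduced$n_fixed
  if (!full$converged || !reduced$converged) {
    return(list(statistic = NA_real_, df = df, p = 1, converged = FALSE))
  }
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6) warning("negative LRT statistic beyond tolerance: ", stat)
  stat <- max(0, stat)
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  if (stat == 0) p <- 1
  list(statistic = stat, df = df, p = p, converged = TRUE)
}

# Rebuild the fixed design of a template with new per-scan group dummies
# (permutation machinery; the non-group columns are untouched).
.perm_X <- function(design, gd) {
  X <- design$X
  gi <- which(design$terms == "group")
  X[, gi] <- gd
  ga <- which(design$terms == "group_age")
  if (length(ga)) X[, ga] <- gd * design$age_c
  ga2 <- which(design$terms == "group_age2")
  if (length(ga2)) X[, ga2] <- gd * design$age_c^2
  X
}

# Per-scan group dummy matrix from a per-subject assignment factor.
.scan_dummies <- function(assignment, subj, group_levels) {
  k <- length(group_levels)
  per_scan <- assignment[subj + 1L]
  gd <- matrix(0, length(subj), k - 1L)
  for (j in 2:k) gd[, j - 1L] <- as.numeric(per_scan == group_levels[j])
  gd
}

# Vertex-wise LRT p map for one effect, optionally under a permuted
# per-subject group assignment. The per-vertex model order and random
# structure are frozen at their observed values. Reduced-model fits that do
# not involve group labels (effect = "group") are memoized in `cache` (an
# environment) so permutation loops compute them once.
.pmap_internal <- function(fit, effect, assignment = NULL, cache = NULL) {
  k <- length(fit$group_levels)
  nmask <- length(fit$mask_idx)
  p <- rep(1, nmask)
  stat <- rep(0, nmask)
  df <- rep(0L, nmask)
  drop_terms <- if (effect == "group") {
    c("group", "group_age", "group_age2")
  } else {
    c("group_age", "group_age2")
  }
  Y_all <- fit$dataset$measures

  for (o in fit$allowed_orders) {
    vsel <- which(fit$orders[fit$mask_idx] == o)
    if (!length(vsel)) next
    if (effect == "shape" && o == 0L) next  # no shape terms to test: p = 1
    f <- fit$order_fits[[as.character(o)]]
    design <- f$design
    red_design <- .reduce_design(design, drop_terms)
    # df = dropped columns: (k - 1) * (1 + order) for "group",
    # (k - 1) * order for "shape"
    eff_df <- design$n_fixed - red_design$n_fixed

    gd <- if (is.null(assignment)) NULL else {
      .scan_dummies(assignment, design$subj, fit$group_levels)
    }

    for (qv in unique(f$q[vsel])) {
      vq <- vsel[f$q[vsel] == qv]
      Y <- Y_all[, fit$mask_idx[vq], drop = FALSE]

      if (is.null(assignment)) {
        ll_full <- f$loglik[vq]
        conv_full <- f$converged[vq]
      } else {
        d2 <- design
        d2$X <- .perm_X(design, gd)
        rb <- .fit_batch(Y, d2, fit$control, q = qv, allow_fallback = FALSE)
        ll_full <- rb$loglik
        conv_full <- rb$converged
      }

      if (effect == "group") {
        key <- paste0("o", o, "_q", qv)
        red <- if (is.environment(cache)) {
          get0(key, envir = cache, inherits = FALSE)
        } else NULL
        if (is.null(red)) {
          red <- .fit_batch(Y, red_design, fit$control, q = qv,
                            allow_fallback = FALSE)
          if (is.environment(cache)) assign(key, red, envir = cache)
        }
      } else {
        rd <- red_design
        if (!is.null(assignment)) {
          # reduced model keeps the group main effect, which moves with the
          # permuted labels
          full_X <- .perm_X(design, gd)
          keep <- !(design$terms %in% drop_terms)
          rd$X <- full_X[, keep, drop = FALSE]
        }
        red <- .fit_batch(Y, rd, fit$control, q = qv, allow_fallback = FALSE)
      }

      s <- pmax(0, 2 * (ll_full - red$loglik[seq_along(vq)]))
      ok <- conv_full & red$converged[seq_along(vq)]
      pv <- pchisq(s, eff_df, lower.tail = FALSE)
      pv[!ok] <- 1
      s[!ok] <- 0
      p[vq] <- pv
      stat[vq] <- s
      df[vq] <- eff_df
    }
  }
  list(p = p, statistic = stat, df = df)
}

#' Vertex-wise likelihood-ratio p map for a group or shape effect
#'
#' At each masked vertex the full model is the BIC-selected order with all
#' group terms; the reduced model removes, for `effect = "group"`, every
#' group-related term (offset and interactions: a model without group
#' differences), or, for `effect = "shape"`, only the group-by-age
#' interaction terms (same curve shape in all groups). Vertices with a
#' selected order of 0 have no shape terms and return p = 1 for the shape
#' effect. Non-converged fits propagate as p = 1.
#'
#' @param fit a [surf_lmm()] object.
#' @param effect `"group"` or `"shape"`.
#' @return object of class `surf_pmap`: per-vertex `p` (NA outside the
#'   mask), `statistic`, `df`, and the effect label.
#' @export
surf_lrt <- function(fit, effect = c("group", "shape")) {
  stopifnot(inherits(fit, "surf_lmm"))
  effect <- match.arg(effect)
  res <- .pmap_internal(fit, effect)
  nv <- n_vertices(fit$dataset$mesh)
  expand <- function(v, fill = NA_real_) {
    out <- rep(fill, nv)
    out[fit$mask_idx] <- v
    out
  }
  structure(list(p = expand(res$p), statistic = expand(res$statistic),
                 df = expand(res$df), effect = effect,
                 mask_idx = fit$mask_idx),
            class = "surf_pmap")
}

#' @export
print.surf_pmap <- function(x, ...) {
  pm <- x$p[x$mask_idx]
  cat(sprintf("surf_pmap (%s effect): %d vertices, %d with p < 0.05, min p = %.4g\n",
              x$effect, length(pm), sum(pm < 0.05), min(pm)))
  invisible(x)
}

#' Suprathreshold clusters on the mesh
#'
#' Connected components (vertices adjacent when they share a triangle edge)
#' of the set of masked vertices with vertex-wise p below the
#' cluster-forming threshold. Clusters are ordered by decreasing cluster
#' statistic, ties broken by smallest member vertex id.
#'
#' @param pmap numeric per-vertex p values or a `surf_pmap`.
#' @param mesh a [surface_mesh()].
#' @param forming_threshold vertex-wise p threshold in (0, 1) defining
#'   suprathreshold vertices.
#' @param stat cluster statistic: `"count"` (number of vertices) or
#'   `"area"` (summed vertex areas, mm^2).
#' @return object of class `surf_clusters`: a list of clusters, each with
#'   `vertex_ids` (1-based), `cluster_stat`, `peak_vertex`, `peak_p` and
#'   `corrected_p` (NA until [cluster_correct()]).
#' @export
find_clusters <- function(pmap, mesh, forming_threshold = 0.01,
                          stat = c("count", "area")) {
  stat <- match.arg(stat)
  if (inherits(pmap, "surf_pmap")) pmap <- pmap$p
  stopifnot(forming_threshold > 0, forming_threshold < 1)
  supra <- which(mesh$mask & !is.na(pmap) & pmap < forming_threshold)
  clusters <- list()
  if (length(supra)) {
    in_supra <- logical(n_vertices(mesh))
    in_supra[supra] <- TRUE
    visited <- logical(n_vertices(mesh))
    for (v0 in supra) {
      if (visited[v0]) next
      # breadth-first flood fill within the suprathreshold set
      comp <- integer(0)
      queue <- v0
      visited[v0] <- TRUE
      while (length(queue)) {
        v <- queue[1L]
        queue <- queue[-1L]
        comp <- c(comp, v)
        nb <- mesh$adjacency[[v]]
        nb <- nb[in_supra[nb] & !visited[nb]]
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
      comp <- sort(comp)
      cs <- if (stat == "count") length(comp) else sum(mesh$areas[comp])
      pk <- comp[which.min(pmap[comp])]
      clusters[[length(clusters) + 1L]] <- list(
        vertex_ids = comp, cluster_stat = cs, peak_vertex = pk,
        peak_p = pmap[pk], corrected_p = NA_real_)
    }
    ord <- order(-vapply(clusters, `[[`, numeric(1), "cluster_stat"),
                 vapply(clusters, function(cl) min(cl$vertex_ids),
                        numeric(1)))
    clusters <- clusters[ord]
  }
  structure(list(clusters = clusters, forming_threshold = forming_threshold,
                 stat = stat, n_perm = NA_integer_),
            class = "surf_clusters")
}

#' @export
print.surf_clusters <- function(x, ...) {
  cat(sprintf("surf_clusters: %d cluster(s), forming threshold p < %g, stat = %s\n",
              length(x$clusters), x$forming_threshold, x$stat))
  if (length(x$clusters)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.surf_clusters <- function(x, ...) {
  if (!length(x$clusters)) {
    return(data.frame(cluster_id = integer(0), n_vertices = integer(0),
                      peak_vertex = integer(0), peak_p = numeric(0),
                      cluster_stat = numeric(0), corrected_p = numeric(0)))
  }
  data.frame(
    cluster_id = seq_along(x$clusters),
    n_vertices = vapply(x$clusters, function(cl) length(cl$vertex_ids), 1L),
    peak_vertex = vapply(x$clusters, `[[`, 1L, "peak_vertex"),
    peak_p = vapply(x$clusters, `[[`, 1, "peak_p"),
    cluster_stat = vapply(x$clusters, `[[`, 1, "cluster_stat"),
    corrected_p = vapply(x$clusters, `[[`, 1, "corrected_p")
  )
}

#' Monte-Carlo permutation null distribution of the maximum cluster statistic
#'
#' Group labels are shuffled across subjects (all scans of a subject move
#' together; sex and scanner stay attached to their scans), the vertex-wise
#' p map is recomputed with the per-vertex model order frozen at its
#' observed value, and the maximum cluster statistic (0 when no cluster
#' forms) is recorded per permutation. When the design admits fewer
#' distinct two-group label assignments than `n_perm`, all non-identity
#' assignments are enumerated instead (with a warning).
#'
#' @inheritParams surf_lrt
#' @inheritParams find_clusters
#' @param n_perm number of permutations.
#' @param seed integer seed; the null vector is reproducible given the
#'   seed.
#' @return numeric vector of max cluster statistics, one per permutation,
#'   with attribute `exhaustive`.
#' @export
permutation_null <- function(fit, effect = c("group", "shape"),
                             forming_threshold = 0.01,
                             stat = c("count", "area"), n_perm = 99L,
                             seed = 1L) {
  stopifnot(inherits(fit, "surf_lmm"), n_perm >= 1L)
  effect <- match.arg(effect)
  stat <- match.arg(stat)
  md <- fit$dataset$metadata
  subjects <- unique(md$subject_id)
  obs_groups <- factor(md$group[match(subjects, md$subject_id)],
                       levels = fit$group_levels)
  m <- length(subjects)
  if (min(table(obs_groups)) < 2L) stop("need >= 2 subjects per group")

  k <- length(fit$group_levels)
  exhaustive <- FALSE
  assignments <- NULL
  if (k == 2L) {
    n1 <- sum(obs_groups == fit$group_levels[2L])
    n_distinct <- choose(m, n1)
    if (n_distinct - 1 <= n_perm) {
      warning("fewer distinct label assignments (", n_distinct - 1,
              ") than n_perm; using exhaustive enumeration")
      exhaustive <- TRUE
      sets <- combn(m, n1)
      obs_set <- sort(which(obs_groups == fit$group_levels[2L]))
      keep <- apply(sets, 2L, function(s) !identical(sort(s), obs_set))
      sets <- sets[, keep, drop = FALSE]
      assignments <- lapply(seq_len(ncol(sets)), function(i) {
        a <- rep(fit$group_levels[1L], m)
        a[sets[, i]] <- fit$group_levels[2L]
        factor(a, levels = fit$group_levels)
      })
    }
  }

  cache <- new.env(parent = emptyenv())
  run_one <- function(assignment) {
    res <- .pmap_internal(fit, effect, assignment = assignment,
                          cache = cache)
    pmap <- rep(NA_real_, n_vertices(fit$dataset$mesh))
    pmap[fit$mask_idx] <- res$p
    cl <- find_clusters(pmap, fit$dataset$mesh, forming_threshold, stat)
    if (length(cl$clusters)) cl$clusters[[1L]]$cluster_stat else 0
  }

  if (exhaustive) {
    null_stats <- vapply(assignments, run_one, numeric(1))
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
    null_stats <- vapply(seq_len(n_perm), function(i) {
      run_one(sample(obs_groups))
    }, numeric(1))
  }
  attr(null_stats, "exhaustive") <- exhaustive
  null_stats
}

#' Permutation-corrected cluster p values
#'
#' Add-one Monte-Carlo estimator: `corrected_p = (1 + #\{null >= stat\}) /
#' (1 + n_perm)`, so the observed statistic inserted into its own null can
#' never yield 0.
#'
#' @param clusters a `surf_clusters` object from [find_clusters()].
#' @param null_vector permutation null from [permutation_null()].
#' @return the `surf_clusters` object with `corrected_p` filled in.
#' @export
cluster_correct <- function(clusters, null_vector) {
  stopifnot(inherits(clusters, "surf_clusters"), length(null_vector) >= 1L)
  for (i in seq_along(clusters$clusters)) {
    cs <- clusters$clusters[[i]]$cluster_stat
    clusters$clusters[[i]]$corrected_p <-
      (1 + sum(null_vector >= cs)) / (1 + length(null_vector))
  }
  clusters$n_perm <- length(null_vector)
  clusters
}

#' Cluster-wise permutation inference for one effect
#'
#' Convenience wrapper: computes the observed vertex-wise p map
#' ([surf_lrt()]), forms suprathreshold clusters ([find_clusters()]),
#' builds the permutation null ([permutation_null()]) and attaches
#' corrected p values ([cluster_correct()]).
#'
#' @inheritParams permutation_null
#' @param alpha significance level on corrected p values (used by the
#'   summary only; all clusters are returned).
#' @return a `surf_clusters` object with corrected p values and the
#'   observed `surf_pmap` attached as attribute `pmap`.
#' @export
cluster_inference <- function(fit, effect = c("group", "shape"),
                              forming_threshold = 0.01,
                              stat = c("count", "area"), n_perm = 99L,
                              seed = 1L, alpha = 0.05) {
  effect <- match.arg(effect)
  stat <- match.arg(stat)
  pmap <- surf_lrt(fit, effect)
  clusters <- find_clusters(pmap, fit$dataset$mesh, forming_threshold, stat)
  nullv <- permutation_null(fit, effect, forming_threshold, stat, n_perm,
                            seed)
  clusters <- cluster_correct(clusters, nullv)
  clusters$effect <- effect
  clusters$alpha <- alpha
  attr(clusters, "pmap") <- pmap
  attr(clusters, "null") <- nullv
  clusters
}

#' Export a cluster table as TSV
#'
#' One row per cluster: id, effect, vertex count, area, peak vertex
#' (0-based, matching the on-disk map dialects), peak vertex-wise p and
#' corrected p.
#'
#' @param clusters a `surf_clusters`.
#' @param mesh the mesh the clusters live on (for areas).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, mesh, path) {
  base <- as.data.frame(clusters)
  eff <- if (is.null(clusters$effect)) NA_character_ else clusters$effect
  df <- data.frame(
    cluster_id = base$cluster_id,
    effect = rep(eff, nrow(base)),
    n_vertices = base$n_vertices,
    area_mm2 = vapply(clusters$clusters, function(cl) {
      sum(mesh$areas[cl$vertex_ids])
    }, numeric(1)),
    peak_vertex = base$peak_vertex - 1L,  # 0-based on disk
    peak_p = base$peak_p,
    corrected_p = base$corrected_p
  )
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
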