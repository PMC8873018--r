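#' Vertex-wise longitudinal mixed-model fit with BIC order selection
#'
#' Fits constant, linear and/or quadratic random-slope mixed models at every
#' masked vertex by maximum likelihood and selects the polynomial order per
#' vertex with the Bayesian Information Criterion (ties broken toward the
#' lower order). This is the central model-fitting entry point; inference
#' ([surf_lrt()], [cluster_inference()]) and trajectory evaluation
#' ([snapshot_series()], [predict.surf_lmm()]) operate on its result.
#'
#' The model at a vertex, for subject i and scan j with group g and age a,
#' is
#' \deqn{y_{ij} = \beta_0 + \beta_{g1} g_i + \beta_{a1} a_{ij} +
#'   \beta_{ag1} g_i a_{ij} + \beta_{a2} a_{ij}^2 + \beta_{ag2} g_i a_{ij}^2
#'   + (covariates) + u_{i0} + u_{i1} a_{ij} + \varepsilon_{ij}}
#' with jointly normal subject random effects and residuals. Order 0 drops
#' all age terms (random intercept only); order 1 drops the quadratic
#' terms. Estimation is ML (not REML) so BIC and likelihood-ratio
#' comparisons across fixed-effect specifications are valid.
#'
#' @param dataset a `surf_dataset` from [longitudinal_dataset()] or
#'   [simulate_dataset()].
#' @param allowed_orders subset of `0:2`; use `0:1` for small samples to
#'   avoid overfitting.
#' @param covariates subset of `c("sex", "scanner", "icv")` entered as
#'   fixed-effect nuisance columns; `"icv"` only for surface-area data.
#' @param age_center centering constant for age (years); default pooled
#'   mean age.
#' @param control optimizer settings, see [lmm_control()].
#' @return object of class `surf_lmm`: per-vertex selected orders (`orders`,
#'   NA outside the analysis mask), the full BIC audit table (`bic`), all
#'   candidate fits (`order_fits`), and the assembled selected-model
#'   parameters used by the method functions.
#' @seealso [bic()], [surf_lrt()], [cluster_inference()],
#'   [snapshot_series()]
#' @export
surf_lmm <- function(dataset, allowed_orders = 0:2,
                     covariates = c("sex", "scanner"), age_center = NULL,
                     control = lmm_control()) {
  stopifnot(inherits(dataset, "surf_dataset"))
  allowed_orders <- sort(unique(as.integer(allowed_orders)))
  if (!length(allowed_orders) || !all(allowed_orders %in% 0:2)) {
    stop("allowed_orders must be a non-empty subset of 0:2")
  }
  if (is.null(age_center)) age_center <- mean(dataset$metadata$age)

  mask_idx <- which(dataset$mesh$mask)
  n_obs <- nrow(dataset$metadata)
  order_fits <- list()
  for (o in allowed_orders) {
    order_fits[[as.character(o)]] <-
      fit_surface(dataset, o, covariates, age_center, control)
  }

  bic_tab <- vapply(order_fits, function(f) {
    ifelse(f$converged, -2 * f$loglik + f$n_params * log(n_obs), Inf)
  }, numeric(length(mask_idx)))
  bic_tab <- matrix(bic_tab, nrow = length(mask_idx),
                    dimnames = list(NULL, names(order_fits)))

  # argmin with ties (|dBIC| < 1e-9) to the lower order; candidates are in
  # ascending order so the first minimum wins
  sel_col <- apply(bic_tab, 1L, function(b) {
    which(b <= min(b) + 1e-9)[1L]
  })
  dropped <- which(!is.finite(bic_tab[cbind(seq_along(sel_col), sel_col)]))
  if (length(dropped)) {
    warning(length(dropped),
            " vertex/vertices dropped: no candidate model converged")
  }

  orders <- rep(NA_integer_, n_vertices(dataset$mesh))
  orders[mask_idx] <- allowed_orders[sel_col]
  orders[mask_idx[dropped]] <- NA_integer_

  fit <- structure(list(
    dataset = dataset,
    covariates = covariates,
    allowed_orders = allowed_orders,
    age_center = age_center,
    control = control,
    group_levels = levels(dataset$metadata$group),
    mask_idx = mask_idx,
    dropped_idx = mask_idx[dropped],
    orders = orders,
    bic = bic_tab,
    order_fits = order_fits,
    n_obs = n_obs
  ), class = "surf_lmm")
  fit
}

#' Bayesian Information Criterion of a vertex fit
#'
#' `-2 logLik + n_params log(n_obs)` with `n_obs` the number of scans used
#' at the vertex. Non-converged fits score `+Inf` so they are never
#' selected.
#'
#' @param fit a `vertex_fit` from [fit_vertex()].
#' @return scalar BIC.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "vertex_fit"))
  if (!fit$converged) return(Inf)
  -2 * fit$loglik + fit$n_params * log(fit$n_obs)
}

#' Per-vertex BIC model-order selection
#'
#' Convenience wrapper around [surf_lmm()] returning just the order map and
#' BIC audit table.
#'
#' @inheritParams surf_lmm
#' @return list with `order` (integer per vertex, NA outside mask) and
#'   `bic_values` (masked-vertices x candidate-orders matrix).
#' @export
select_orders <- function(dataset, allowed_orders = 0:2,
                          covariates = c("sex", "scanner"),
                          age_center = NULL, control = lmm_control()) {
  fit <- surf_lmm(dataset, allowed_orders, covariates, age_center, control)
  list(order = fit$orders, bic_values = fit$bic)
}

# Selected-model per-vertex quantity lookup: returns vector over mask_idx.
.sel_get <- function(fit, what) {
  out <- rep(NA_real_, length(fit$mask_idx))
  for (oi in seq_along(fit$allowed_orders)) {
    o <- fit$allowed_orders[oi]
    sel <- which(fit$orders[fit$mask_idx] == o)
    if (!length(sel)) next
    f <- fit$order_fits[[as.character(o)]]
    out[sel] <- switch(what,
      loglik = f$loglik[sel],
      sigma2 = f$sigma2[sel],
      n_params = f$n_params[sel],
      q = f$q[sel],
      converged = as.numeric(f$converged[sel]),
      fallback = as.numeric(f$fallback[sel]),
      stop("unknown field"))
  }
  out
}

# Selected-model coefficient for one canonical term, 0 where the term is
# absent from the selected order. term: one of the build_design term labels;
# for multi-column terms (k > 2 groups) `level_index` picks the dummy.
.sel_coef <- function(fit, term, level_index = 1L) {
  out <- rep(0, length(fit$mask_idx))
  for (o in fit$allowed_orders) {
    sel <- which(fit$orders[fit$mask_idx] == o)
    if (!length(sel)) next
    f <- fit$order_fits[[as.character(o)]]
    cols <- which(f$design$terms == term)
    if (length(cols) >= level_index) {
      out[sel] <- f$beta[cols[level_index], sel]
    }
  }
  out
}

#' Extract a single vertex's selected fit
#'
#' @param fit a `surf_lmm` object.
#' @param vertex 1-based vertex index (must be inside the analysis mask).
#' @return a `vertex_fit`.
#' @export
vertex_fit_at <- function(fit, vertex) {
  j <- match(vertex, fit$mask_idx)
  if (is.na(j)) stop("vertex ", vertex, " is not in the analysis mask")
  o <- fit$orders[vertex]
  if (is.na(o)) stop("vertex ", vertex, " has no converged fit")
  f <- fit$order_fits[[as.character(o)]]
  .make_vertex_fit(f, f$design, j, o, fit$n_obs)
}

# ---------------------------------------------------------------------------
# Methods

#' @export
print.surf_lmm <- function(x, ...) {
  cat(sprintf("surf_lmm: %d masked vertices, %d scans, %d subjects\n",
              length(x$mask_idx), x$n_obs,
              length(unique(x$dataset$metadata$subject_id))))
  cat("  groups:", paste(x$group_levels, collapse = ", "),
      sprintf("(reference: %s)\n", x$group_levels[1L]))
  tab <- table(factor(x$orders[x$mask_idx], levels = x$allowed_orders))
  cat("  selected orders:",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  age centered at %.2f years\n", x$age_center))
  invisible(x)
}

#' @export
summary.surf_lmm <- function(object, ...) {
  ll <- .sel_get(object, "loglik")
  out <- list(
    n_vertices = length(object$mask_idx),
    n_obs = object$n_obs,
    n_subjects = length(unique(object$dataset$metadata$subject_id)),
    group_levels = object$group_levels,
    order_table = table(factor(object$orders[object$mask_idx],
                               levels = object$allowed_orders)),
    n_fallback = sum(.sel_get(object, "fallback"), na.rm = TRUE),
    n_dropped = length(object$dropped_idx),
    loglik_total = sum(ll, na.rm = TRUE),
    age_center = object$age_center
  )
  class(out) <- "summary.surf_lmm"
  out
}

#' @export
print.summary.surf_lmm <- function(x, ...) {
  cat(sprintf("Vertex-wise mixed-model fit: %d vertices, %d scans, %d subjects\n",
              x$n_vertices, x$n_obs, x$n_subjects))
  cat("Selected model orders (BIC):\n")
  print(x$order_table)
  cat(sprintf("Intercept-only fallbacks: %d; dropped vertices: %d\n",
              x$n_fallback, x$n_dropped))
  cat(sprintf("Total log-likelihood (selected models): %.2f\n",
              x$loglik_total))
  invisible(x)
}

#' @describeIn surf_lmm selected-model fixed effects, one row per masked
#'   vertex in the canonical column layout (terms absent from the selected
#'   order are 0).
#' @param object,x a `surf_lmm` object.
#' @param ... unused.
#' @export
coef.surf_lmm <- function(object, ...) {
  k <- length(object$group_levels)
  cols <- c("(Intercept)",
            paste0("group", object$group_levels[-1L]),
            "age", paste0("group", object$group_levels[-1L], ":age"),
            "age2", paste0("group", object$group_levels[-1L], ":age2"))
  term_of <- c("intercept", rep("group", k - 1L), "age",
               rep("group_age", k - 1L), "age2", rep("group_age2", k - 1L))
  lvl_of <- c(1L, seq_len(k - 1L), 1L, seq_len(k - 1L), 1L, seq_len(k - 1L))
  m <- vapply(seq_along(cols), function(i) {
    .sel_coef(object, term_of[i], lvl_of[i])
  }, numeric(length(object$mask_idx)))
  m <- matrix(m, ncol = length(cols), dimnames = list(NULL, cols))
  rownames(m) <- as.character(object$mask_idx)
  m
}

#' @export
logLik.surf_lmm <- function(object, ...) {
  ll <- .sel_get(object, "loglik")
  structure(sum(ll, na.rm = TRUE),
            df = sum(.sel_get(object, "n_params"), na.rm = TRUE),
            nobs = object$n_obs, class = "logLik")
}

#' @describeIn surf_lmm marginal residuals (observed minus fixed-effect
#'   prediction), scans x masked vertices.
#' @export
residuals.surf_lmm <- function(object, ...) {
  out <- matrix(NA_real_, object$n_obs, length(object$mask_idx))
  for (o in object$allowed_orders) {
    sel <- which(object$orders[object$mask_idx] == o)
    if (!length(sel)) next
    f <- object$order_fits[[as.character(o)]]
    pred <- f$design$X %*% f$beta[, sel, drop = FALSE]
    out[, sel] <- object$dataset$measures[, object$mask_idx[sel]] - pred
  }
  out
}

#' @describeIn surf_lmm fixed-effect predictions at reference covariate
#'   levels. `newdata` needs columns `age` and `group`; returns a
#'   masked-vertices x rows matrix.
#' @param newdata data frame with columns `age` (years) and `group`.
#' @export
predict.surf_lmm <- function(object, newdata, ...) {
  stopifnot(all(c("age", "group") %in% names(newdata)))
  out <- vapply(seq_len(nrow(newdata)), function(i) {
    predict_trajectory(object, group = as.character(newdata$group[i]),
                       age = newdata$age[i], guard = Inf)
  }, numeric(length(object$mask_idx)))
  matrix(out, ncol = nrow(newdata))
}

#' @describeIn surf_lmm spaghetti plot of the data and fitted group
#'   trajectories at one vertex.
#' @param vertex 1-based vertex index to plot.
#' @export
plot.surf_lmm <- function(x, vertex = x$mask_idx[1L], ...) {
  md <- x$dataset$metadata
  y <- x$dataset$measures[, vertex]
  glev <- x$group_levels
  cols <- setNames(seq_along(glev) + 1L, glev)
  graphics::plot(md$age, y, col = cols[as.character(md$group)], pch = 16,
                 cex = 0.6, xlab = "age (years)",
                 ylab = x$dataset$measure_kind,
                 main = sprintf("vertex %d (order %d)", vertex,
                                x$orders[vertex]), ...)
  for (s in unique(md$subject_id)) {
    idx <- which(md$subject_id == s)
    if (length(idx) > 1L) {
      ord <- idx[order(md$age[idx])]
      graphics::lines(md$age[ord], y[ord], col = "grey80")
    }
  }
  ages <- seq(min(md$age), max(md$age), length.out = 60L)
  for (g in glev) {
    tr <- vapply(ages, function(a) {
      predict_trajectory(x, g, a)[match(vertex, x$mask_idx)]
    }, numeric(1))
    graphics::lines(ages, tr, col = cols[g], lwd = 2)
  }
  graphics::legend("topright", legend = glev, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' @describeIn surf_lmm simulate new measure matrices from the selected
#'   per-vertex models (independent random effects per vertex).
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @export
simulate.surf_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  md <- object$dataset$metadata
  subj <- match(md$subject_id, unique(md$subject_id))
  m <- max(subj)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    sim <- matrix(NA_real_, object$n_obs, length(object$mask_idx))
    for (o in object$allowed_orders) {
      sel <- which(object$orders[object$mask_idx] == o)
      if (!length(sel)) next
      f <- object$order_fits[[as.character(o)]]
      pred <- f$design$X %*% f$beta[, sel, drop = FALSE]
      for (jj in seq_along(sel)) {
        j <- sel[jj]
        G <- .re_covariance(f$theta[, j], f$sigma2[j], f$q[j])
        L <- chol(G + diag(1e-12, nrow(G)))
        u <- t(L) %*% matrix(rnorm(nrow(G) * m), nrow(G), m)
        re <- u[1L, subj]
        if (nrow(G) == 2L) re <- re + u[2L, subj] * f$design$age_c
        sim[, j] <- pred[, jj] + re + rnorm(object$n_obs, 0,
                                            sqrt(f$sigma2[j]))
      }
    }
    out[[r]] <- sim
  }
  if (nsim == 1L) out[[1L]] else out
}
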