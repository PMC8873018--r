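#' Numerical control parameters for the mixed-model optimizer
#'
#' @param tol relative convergence tolerance on the profiled deviance.
#' @param maxit maximum Nelder-Mead iterations per start.
#' @param sigma_floor lower bound on the residual variance (mm^2); reached
#'   only for degenerate (noise-free) data.
#' @param fallback_tol relative random-slope standard deviation below which
#'   the slope variance is deemed singular and the vertex is refit with a
#'   random intercept only.
#' @return list of control values.
#' @export
lmm_control <- function(tol = 1e-8, maxit = 500L, sigma_floor = 1e-10,
                        fallback_tol = 1e-4) {
  list(tol = tol, maxit = as.integer(maxit), sigma_floor = sigma_floor,
       fallback_tol = fallback_tol)
}

# Fixed deterministic multi-start points on the relative Cholesky scale.
# Intercept scale ~ residual scale (theta11 = 1) is the usual OLS-residual
# split heuristic; the slope scale is normalized by the age spread.
.fit_starts <- function(q, age_c) {
  if (q == 1L) {
    matrix(c(1, 0.1), nrow = 1L)
  } else {
    s <- 1 / max(sd(age_c), 1e-8)
    cbind(c(0.1, 0, 0.1 * s), c(1, 0, s))
  }
}

# Batched per-vertex ML fit for one design; handles the singular-slope
# fallback (refit with q = 1). Y: scans x vertices.
.fit_batch <- function(Y, design, control = lmm_control(), q = design$q,
                       allow_fallback = TRUE) {
  Y <- as.matrix(Y)
  res <- .cpp_fit_surface(Y, design$X, design$age_c, design$subj, q,
                          .fit_starts(q, design$age_c), control$tol,
                          control$maxit, control$sigma_floor)
  nv <- ncol(Y)
  out <- list(beta = res$beta, theta = res$theta, sigma2 = res$sigma2,
              loglik = res$loglik, converged = res$converged == 1L,
              fallback = rep(FALSE, nv), q = rep(q, nv),
              n_fixed = design$n_fixed,
              n_params = rep(design$n_fixed + ifelse(q == 2L, 4L, 2L), nv))
  if (q == 2L && allow_fallback) {
    slope_sd <- sqrt(res$theta[2L, ]^2 + res$theta[3L, ]^2)
    redo <- which(slope_sd < control$fallback_tol | !out$converged)
    if (length(redo)) {
      res1 <- .cpp_fit_surface(Y[, redo, drop = FALSE], design$X,
                               design$age_c, design$subj, 1L,
                               .fit_starts(1L, design$age_c), control$tol,
                               control$maxit, control$sigma_floor)
      out$beta[, redo] <- res1$beta
      out$theta[, redo] <- rbind(res1$theta, 0, 0)
      out$sigma2[redo] <- res1$sigma2
      out$loglik[redo] <- res1$loglik
      out$converged[redo] <- res1$converged == 1L
      out$fallback[redo] <- TRUE
      out$q[redo] <- 1L
      out$n_params[redo] <- design$n_fixed + 2L
    }
  }
  out
}

# Random-effect covariance G (absolute scale, centered-age parameterization)
# from the relative Cholesky factor and sigma2, for one vertex.
.re_covariance <- function(theta, sigma2, q) {
  if (q == 1L) {
    matrix(sigma2 * theta[1L]^2, 1L, 1L)
  } else {
    L <- matrix(c(theta[1L], theta[2L], 0, theta[3L]), 2L, 2L)
    sigma2 * (L %*% t(L))
  }
}

#' Exact marginal log-likelihood of the random-slope model
#'
#' Independent verification oracle: evaluates the log-density of the
#' observation vector under the marginal multivariate normal implied by the
#' mixed model, mean `X beta` and block-diagonal covariance
#' `Z_i G Z_i' + sigma2 I` per subject, by direct dense linear algebra.
#' It shares no code with the optimizer.
#'
#' @param y numeric vector of per-scan measures (one vertex).
#' @param X fixed-effect design matrix.
#' @param subj 0-based subject index per scan.
#' @param age_c centered age per scan.
#' @param beta fixed-effect coefficients.
#' @param G random-effect covariance: 1x1 (intercept) or 2x2
#'   (intercept + slope on centered age).
#' @param sigma2 residual variance (> 0).
#' @return the exact log-likelihood (scalar).
#' @export
marginal_loglik <- function(y, X, subj, age_c, beta, G, sigma2) {
  G <- as.matrix(G)
  q <- nrow(G)
  stopifnot(q %in% 1:2, length(y) == nrow(X), length(beta) == ncol(X))
  r <- y - as.numeric(X %*% beta)
  ll <- 0
  for (s in unique(subj)) {
    idx <- which(subj == s)
    Z <- if (q == 1L) matrix(1, length(idx), 1L) else cbind(1, age_c[idx])
    V <- Z %*% G %*% t(Z) + diag(sigma2, length(idx))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) stop("singular block covariance for subject index ", s)
    ri <- r[idx]
    w <- backsolve(ch, ri, transpose = TRUE)
    ll <- ll - 0.5 * (length(idx) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                      sum(w^2))
  }
  ll
}

.make_vertex_fit <- function(batch, design, j, order, n_obs) {
  q <- batch$q[j]
  structure(list(
    order = order,
    beta = setNames(batch$beta[, j], colnames(design$X)),
    terms = design$terms,
    theta = batch$theta[seq_len(if (q == 2L) 3L else 1L), j],
    G = .re_covariance(batch$theta[, j], batch$sigma2[j], q),
    sigma2 = batch$sigma2[j],
    loglik = batch$loglik[j],
    n_obs = n_obs,
    n_fixed = batch$n_fixed,
    n_params = batch$n_params[j],
    q = q,
    converged = batch$converged[j],
    fallback_applied = batch$fallback[j],
    age_center = design$age_center,
    group_levels = design$group_levels
  ), class = "vertex_fit")
}

#' Fit the mixed model at a single vertex
#'
#' Maximum-likelihood fit of the polynomial random-slope model for one
#' per-vertex measure vector. Order 0 carries a random intercept only;
#' orders 1-2 carry an unstructured random intercept + slope, with an
#' automatic fallback to intercept-only when the slope variance is
#' singular. The fit is deterministic (fixed multi-start strategy).
#'
#' @param y numeric vector, one measure per scan (dataset row order).
#' @param dataset a `surf_dataset` supplying the metadata.
#' @inheritParams build_design
#' @param control see [lmm_control()].
#' @return an object of class `vertex_fit` with elements `beta`, `G`,
#'   `sigma2`, `loglik`, `n_obs`, `n_params`, `converged`,
#'   `fallback_applied`.
#' @export
fit_vertex <- function(y, dataset, order, covariates = c("sex", "scanner"),
                       age_center = NULL, control = lmm_control()) {
  design <- build_design(dataset, order, covariates, age_center)
  if (length(y) != nrow(design$X)) stop("y length != number of scans")
  if (length(y) < design$n_fixed + if (design$q == 2L) 4L else 2L) {
    stop("fewer observations than parameters")
  }
  batch <- .fit_batch(matrix(y, ncol = 1L), design, control)
  .make_vertex_fit(batch, design, 1L, order, length(y))
}

#' @export
print.vertex_fit <- function(x, ...) {
  cat(sprintf("vertex_fit: order %d, logLik %.4f, n = %d, %s%s\n", x$order,
              x$loglik, x$n_obs,
              if (x$converged) "converged" else "NOT converged",
              if (x$fallback_applied) " (intercept-only fallback)" else ""))
  print(round(x$beta, 5))
  invisible(x)
}

#' @export
logLik.vertex_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.vertex_fit <- function(object, ...) object$beta

#' Fit per-vertex mixed models across the surface
#'
#' Workhorse behind [surf_lmm()]: fits the model of the given order at
#' every masked vertex. Results are independent of vertex evaluation order.
#'
#' @inheritParams fit_vertex
#' @param dataset a `surf_dataset`.
#' @param order polynomial order (0, 1 or 2).
#' @return list with per-masked-vertex parameter arrays (`beta`, `theta`,
#'   `sigma2`, `loglik`, `converged`, `fallback`, `q`, `n_params`) plus the
#'   `design` used and `mask_idx` (vertex indices fitted).
#' @export
fit_surface <- function(dataset, order, covariates = c("sex", "scanner"),
                        age_center = NULL, control = lmm_control()) {
  design <- build_design(dataset, order, covariates, age_center)
  mask_idx <- which(dataset$mesh$mask)
  batch <- .fit_batch(dataset$measures[, mask_idx, drop = FALSE], design,
                      control)
  batch$design <- design
  batch$mask_idx <- mask_idx
  batch$order <- order
  batch
}
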