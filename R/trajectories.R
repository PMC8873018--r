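#' Fitted group trajectory at a given age
#'
#' Fixed-effect prediction of the selected per-vertex models for one group
#' at one age, with covariates held at their reference levels (first factor
#' level; standardized ICV at its mean). Ages are supplied on the original
#' scale; centering is internal.
#'
#' @param fit a [surf_lmm()] object (or a single `vertex_fit`).
#' @param group group level label.
#' @param age age in years.
#' @param guard extrapolation guard in years beyond the observed age range
#'   (default 0: predictions outside the observed range error out).
#' @return numeric vector of predictions over masked vertices (or a scalar
#'   for a `vertex_fit`).
#' @export
predict_trajectory <- function(fit, group, age, guard = 0) {
  UseMethod("predict_trajectory")
}

.check_age_guard <- function(age, rng, guard) {
  if (any(age < rng[1L] - guard | age > rng[2L] + guard)) {
    stop(sprintf("age %.2f outside observed range [%.1f, %.1f] + guard %g",
                 age[which(age < rng[1L] - guard | age > rng[2L] + guard)][1L],
                 rng[1L], rng[2L], guard))
  }
}

.group_index <- function(group, levels) {
  gi <- match(group, levels)
  if (is.na(gi)) stop("unknown group level: ", group)
  gi
}

#' @export
predict_trajectory.surf_lmm <- function(fit, group, age, guard = 0) {
  rng <- range(fit$dataset$metadata$age)
  .check_age_guard(age, rng, guard)
  gi <- .group_index(group, fit$group_levels)
  a <- age - fit$age_center
  b0 <- .sel_coef(fit, "intercept")
  ba1 <- .sel_coef(fit, "age")
  ba2 <- .sel_coef(fit, "age2")
  pred <- b0 + ba1 * a + ba2 * a^2
  if (gi > 1L) {
    pred <- pred + .sel_coef(fit, "group", gi - 1L) +
      .sel_coef(fit, "group_age", gi - 1L) * a +
      .sel_coef(fit, "group_age2", gi - 1L) * a^2
  }
  pred
}

#' @export
predict_trajectory.vertex_fit <- function(fit, group, age, guard = Inf) {
  gi <- .group_index(group, fit$group_levels)
  a <- age - fit$age_center
  g <- function(term, li = 1L) {
    cols <- which(fit$terms == term)
    if (length(cols) >= li) fit$beta[cols[li]] else 0
  }
  pred <- g("intercept") + g("age") * a + g("age2") * a^2
  if (gi > 1L) {
    pred <- pred + g("group", gi - 1L) + g("group_age", gi - 1L) * a +
      g("group_age2", gi - 1L) * a^2
  }
  unname(pred)
}

#' Annualized rate of change of the fitted trajectory
#'
#' Analytic derivative of the fitted polynomial with respect to age:
#' `beta_a1 + beta_ag1 g + 2 (beta_a2 + beta_ag2 g) (age - center)`,
#' in measure units per year (negative values = thinning for CT). Order-0
#' vertices have rate 0 at every age.
#'
#' @inheritParams predict_trajectory
#' @return numeric vector over masked vertices (or scalar for a
#'   `vertex_fit`).
#' @export
annual_rate <- function(fit, group, age, guard = 0) {
  UseMethod("annual_rate")
}

#' @export
annual_rate.surf_lmm <- function(fit, group, age, guard = 0) {
  rng <- range(fit$dataset$metadata$age)
  .check_age_guard(age, rng, guard)
  gi <- .group_index(group, fit$group_levels)
  a <- age - fit$age_center
  rate <- .sel_coef(fit, "age") + 2 * .sel_coef(fit, "age2") * a
  if (gi > 1L) {
    rate <- rate + .sel_coef(fit, "group_age", gi - 1L) +
      2 * .sel_coef(fit, "group_age2", gi - 1L) * a
  }
  rate
}

#' @export
annual_rate.vertex_fit <- function(fit, group, age, guard = Inf) {
  gi <- .group_index(group, fit$group_levels)
  a <- age - fit$age_center
  g <- function(term, li = 1L) {
    cols <- which(fit$terms == term)
    if (length(cols) >= li) fit$beta[cols[li]] else 0
  }
  rate <- g("age") + 2 * g("age2") * a
  if (gi > 1L) {
    rate <- rate + g("group_age", gi - 1L) + 2 * g("group_age2", gi - 1L) * a
  }
  unname(rate)
}

#' Age-resolved snapshot maps of group differences
#'
#' For every age on the grid, computes the per-vertex difference between
#' the two groups' fitted trajectories (mm) and between their annualized
#' rates of change (mm/year). Sign convention: first listed group minus
#' second. Covariates are at reference levels.
#'
#' @inheritParams predict_trajectory
#' @param ages numeric grid of ages (years); default integer years spanning
#'   the observed range.
#' @param groups length-2 character vector; default: second group level
#'   minus the reference level.
#' @return object of class `snapshot_series` with `ages`,
#'   `difference_maps` and `rate_difference_maps` (masked-vertices x ages
#'   matrices), `groups` and `mask_idx`.
#' @export
snapshot_series <- function(fit, ages = NULL, groups = NULL, guard = 0) {
  stopifnot(inherits(fit, "surf_lmm"))
  rng <- range(fit$dataset$metadata$age)
  if (is.null(ages)) ages <- seq(ceiling(rng[1L]), floor(rng[2L]), by = 1)
  if (is.null(groups)) groups <- c(fit$group_levels[2L], fit$group_levels[1L])
  stopifnot(length(groups) == 2L)
  diff_m <- vapply(ages, function(a) {
    predict_trajectory(fit, groups[1L], a, guard) -
      predict_trajectory(fit, groups[2L], a, guard)
  }, numeric(length(fit$mask_idx)))
  rate_m <- vapply(ages, function(a) {
    annual_rate(fit, groups[1L], a, guard) -
      annual_rate(fit, groups[2L], a, guard)
  }, numeric(length(fit$mask_idx)))
  structure(list(ages = ages,
                 difference_maps = matrix(diff_m, ncol = length(ages)),
                 rate_difference_maps = matrix(rate_m, ncol = length(ages)),
                 groups = groups, mask_idx = fit$mask_idx,
                 reference_covariates = "all covariates at reference levels"),
            class = "snapshot_series")
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat(sprintf("snapshot_series: %s - %s, ages %g..%g (%d snapshots), %d vertices\n",
              x$groups[1L], x$groups[2L], min(x$ages), max(x$ages),
              length(x$ages), length(x$mask_idx)))
  invisible(x)
}

#' Export snapshot maps to a directory
#'
#' Writes one vertex map per age per quantity in the TSV map dialect
#' (values at unmasked vertices are NA) plus a `manifest.json`.
#'
#' @param x a `snapshot_series`.
#' @param dir output directory (created if needed).
#' @param n_vertices total vertex count of the mesh the series was
#'   computed on.
#' @return the directory path, invisibly.
#' @export
export_snapshots <- function(x, dir, n_vertices) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(x$ages)) {
    for (kind in c("difference", "rate_difference")) {
      v <- rep(NA_real_, n_vertices)
      v[x$mask_idx] <- if (kind == "difference") {
        x$difference_maps[, i]
      } else {
        x$rate_difference_maps[, i]
      }
      f <- file.path(dir, sprintf("%s_age%03d.tsv", kind,
                                  round(x$ages[i] * 10)))
      write_matrix_tsv(v, f)
      files <- c(files, basename(f))
    }
  }
  jsonlite::write_json(
    list(ages = x$ages, groups = x$groups, files = files,
         reference_covariates = x$reference_covariates),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
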