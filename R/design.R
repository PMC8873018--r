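#' Build fixed- and random-effect design matrices for one model order
#'
#' Constructs the fixed-effect design for the polynomial group-by-age model
#' in the canonical column order: intercept, group dummies, age, group x
#' age, age^2, group x age^2, sex dummy, scanner dummies, intracranial
#' volume. Age enters centered at `age_center`; the random-effect design per
#' scan is `[1]` (order 0) or `[1, age - age_center]` (orders 1-2).
#'
#' The intracranial-volume covariate is standardized (zero mean, unit
#' standard deviation) for numerical conditioning; its coefficient is per
#' standard deviation of ICV.
#'
#' @param dataset a `surf_dataset`.
#' @param order polynomial order of the age trend: 0 (constant), 1 (linear)
#'   or 2 (quadratic).
#' @param covariates subset of `c("sex", "scanner", "icv")`; `"icv"` is only
#'   allowed for surface-area datasets.
#' @param age_center centering constant in years; default pooled mean age.
#' @return list with `X` (fixed design), `terms` (column term labels),
#'   `age_c` (centered ages), `subj` (0-based subject index per scan),
#'   `subjects` (subject ids in index order), `q` (random-effect columns:
#'   1 or 2), `group_levels`, `age_center`, `n_fixed`.
#' @export
build_design <- function(dataset, order, covariates = c("sex", "scanner"),
                         age_center = NULL) {
  stopifnot(inherits(dataset, "surf_dataset"), order %in% 0:2)
  md <- dataset$metadata
  if (length(covariates)) {
    covariates <- match.arg(covariates, c("sex", "scanner", "icv"),
                            several.ok = TRUE)
  }
  if ("icv" %in% covariates) {
    if (dataset$measure_kind != "SA") {
      stop("icv covariate is only supported for surface-area (SA) analyses")
    }
    if (!"icv" %in% names(md)) stop("metadata has no icv column")
  }
  if (is.null(age_center)) age_center <- mean(md$age)
  age_c <- md$age - age_center
  glev <- levels(md$group)
  k <- length(glev)

  gdum <- matrix(0, nrow(md), k - 1L)
  for (j in 2:k) gdum[, j - 1L] <- as.numeric(md$group == glev[j])
  colnames(gdum) <- paste0("group", glev[-1L])

  cols <- list(`(Intercept)` = rep(1, nrow(md)))
  for (j in seq_len(k - 1L)) cols[[colnames(gdum)[j]]] <- gdum[, j]
  terms <- c("intercept", rep("group", k - 1L))
  if (order >= 1L) {
    cols$age <- age_c
    terms <- c(terms, "age")
    for (j in seq_len(k - 1L)) {
      cols[[paste0(colnames(gdum)[j], ":age")]] <- gdum[, j] * age_c
    }
    terms <- c(terms, rep("group_age", k - 1L))
  }
  if (order >= 2L) {
    cols$age2 <- age_c^2
    terms <- c(terms, "age2")
    for (j in seq_len(k - 1L)) {
      cols[[paste0(colnames(gdum)[j], ":age2")]] <- gdum[, j] * age_c^2
    }
    terms <- c(terms, rep("group_age2", k - 1L))
  }
  if ("sex" %in% covariates && nlevels(md$sex) > 1L) {
    for (lv in levels(md$sex)[-1L]) {
      cols[[paste0("sex", lv)]] <- as.numeric(md$sex == lv)
      terms <- c(terms, "sex")
    }
  }
  if ("scanner" %in% covariates && nlevels(md$scanner) > 1L) {
    for (lv in levels(md$scanner)[-1L]) {
      cols[[paste0("scanner", lv)]] <- as.numeric(md$scanner == lv)
      terms <- c(terms, "scanner")
    }
  }
  if ("icv" %in% covariates) {
    cols$icv <- as.numeric(scale(md$icv))
    terms <- c(terms, "icv")
  }

  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X)) {
    warning("rank-deficient fixed-effect design (confounded covariates); ",
            "columns retained, inference relies on likelihood ratios")
  }
  subjects <- unique(md$subject_id)
  subj <- match(md$subject_id, subjects) - 1L

  list(X = X, terms = terms, age_c = age_c, subj = subj,
       subjects = subjects, q = if (order == 0L) 1L else 2L,
       group_levels = glev, age_center = age_center, n_fixed = ncol(X))
}

# Drop term groups from a built design (for reduced models in LRTs).
.reduce_design <- function(design, drop_terms) {
  keep <- !(design$terms %in% drop_terms)
  design$X <- design$X[, keep, drop = FALSE]
  design$terms <- design$terms[keep]
  design$n_fixed <- ncol(design$X)
  design
}
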