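#' Assemble and validate a longitudinal surface dataset
#'
#' Bundles a mesh, per-scan metadata and the scans-by-vertices measure
#' matrix into the unit of analysis, enforcing the structural invariants
#' the modelling code relies on: one metadata row per measure row, ages in
#' a plausible range, consistent group/sex within subject, and no missing
#' values inside the analysis mask.
#'
#' @param mesh a [surface_mesh()].
#' @param metadata data frame with one row per scan and columns
#'   `subject_id`, `scan_id`, `group`, `age`, `sex`, `scanner`, optionally
#'   `icv`. `group`, `sex` and `scanner` are coerced to factors; their first
#'   level is the reference level for modelling, so relevel beforehand to
#'   declare a different reference (e.g. controls).
#' @param measures numeric matrix, rows = scans in metadata order, columns =
#'   mesh vertices; mm for thickness, mm^2 for area.
#' @param measure_kind `"CT"` (thickness) or `"SA"` (area). The intracranial
#'   volume covariate is accepted only for `"SA"`.
#' @param age_range plausible age bounds in years used for validation.
#' @return an object of class `surf_dataset`.
#' @export
longitudinal_dataset <- function(mesh, metadata, measures,
                                 measure_kind = c("CT", "SA"),
                                 age_range = c(0, 100)) {
  measure_kind <- match.arg(measure_kind)
  stopifnot(inherits(mesh, "surface_mesh"))
  metadata <- as.data.frame(metadata)
  required <- c("subject_id", "scan_id", "group", "age", "sex", "scanner")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop("metadata lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  measures <- as.matrix(measures)
  storage.mode(measures) <- "double"

  problems <- character(0)
  if (nrow(measures) != nrow(metadata)) {
    problems <- c(problems, sprintf(
      "measure rows (%d) != metadata rows (%d)", nrow(measures),
      nrow(metadata)))
  }
  if (ncol(measures) != n_vertices(mesh)) {
    problems <- c(problems, sprintf(
      "measure columns (%d) != mesh vertices (%d)", ncol(measures),
      n_vertices(mesh)))
  }
  if (anyDuplicated(metadata$scan_id)) {
    problems <- c(problems, sprintf(
      "duplicate scan_id: %s",
      metadata$scan_id[anyDuplicated(metadata$scan_id)]))
  }
  bad_age <- which(metadata$age < age_range[1L] | metadata$age > age_range[2L] |
                   !is.finite(metadata$age))
  if (length(bad_age)) {
    problems <- c(problems, sprintf(
      "age out of range [%g, %g] at scan row(s) %s", age_range[1L],
      age_range[2L], paste(head(bad_age, 5L), collapse = ", ")))
  }
  for (col in c("group", "sex")) {
    tab <- tapply(as.character(metadata[[col]]), metadata$subject_id,
                  function(x) length(unique(x)))
    bad <- names(tab)[tab > 1L]
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "subject(s) with inconsistent %s: %s", col,
        paste(head(bad, 5L), collapse = ", ")))
    }
  }
  if (nrow(measures) == nrow(metadata) &&
      ncol(measures) == n_vertices(mesh) && any(mesh$mask)) {
    nas <- which(is.na(measures[, mesh$mask, drop = FALSE]), arr.ind = TRUE)
    if (nrow(nas)) {
      v <- which(mesh$mask)[nas[1L, 2L]]
      problems <- c(problems, sprintf(
        "missing measure inside mask: scan row %d, vertex %d (%d value(s) total)",
        nas[1L, 1L], v, nrow(nas)))
    }
  }
  if (length(problems)) {
    stop("invalid longitudinal dataset:\n  - ",
         paste(problems, collapse = "\n  - "))
  }

  for (col in c("group", "sex", "scanner")) {
    if (!is.factor(metadata[[col]])) metadata[[col]] <- factor(metadata[[col]])
    metadata[[col]] <- droplevels(metadata[[col]])
  }
  if (nlevels(metadata$group) < 2L) {
    stop("group must have at least 2 levels with scans")
  }
  if (measure_kind == "CT" && "icv" %in% names(metadata)) {
    # tolerated in metadata, but the model builder refuses icv for CT
  }

  structure(list(mesh = mesh, metadata = metadata, measures = measures,
                 measure_kind = measure_kind),
            class = "surf_dataset")
}

#' @export
print.surf_dataset <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("surf_dataset (%s): %d scans from %d subjects, %d vertices\n",
              x$measure_kind, nrow(md), length(unique(md$subject_id)),
              ncol(x$measures)))
  cat("  groups: ",
      paste(sprintf("%s (%d scans)", levels(md$group), table(md$group)),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  age range: %.1f-%.1f years\n", min(md$age), max(md$age)))
  invisible(x)
}

#' Load per-scan vertex maps plus metadata into a dataset
#'
#' Accepts either one map file per metadata row (`curv`/`mgh`) or a single
#' scans-by-vertices TSV matrix in the package's dialect.
#'
#' @param paths character vector of per-scan map files (in metadata row
#'   order), or a single TSV matrix path when `format = "tsv_matrix"`.
#' @param mesh a [surface_mesh()].
#' @param metadata_path CSV file with the columns documented in
#'   [longitudinal_dataset()].
#' @param format `"tsv_matrix"`, `"curv"` or `"mgh"`.
#' @inheritParams longitudinal_dataset
#' @return a `surf_dataset`.
#' @export
load_vertex_maps <- function(paths, mesh, metadata_path,
                             format = c("tsv_matrix", "curv", "mgh"),
                             measure_kind = c("CT", "SA")) {
  format <- match.arg(format)
  metadata <- read.csv(metadata_path)
  if (format == "tsv_matrix") {
    if (length(paths) != 1L) stop("tsv_matrix expects a single path")
    measures <- read_matrix_tsv(paths)
  } else {
    if (length(paths) != nrow(metadata)) {
      stop(sprintf("got %d map files for %d metadata rows", length(paths),
                   nrow(metadata)))
    }
    rows <- lapply(paths, read_vertex_map, format = format)
    len <- vapply(rows, length, integer(1))
    if (any(len != n_vertices(mesh))) {
      bad <- which(len != n_vertices(mesh))[1L]
      stop(sprintf("map %s has %d values; mesh has %d vertices", paths[bad],
                   len[bad], n_vertices(mesh)))
    }
    measures <- do.call(rbind, rows)
  }
  longitudinal_dataset(mesh, metadata, measures, measure_kind = measure_kind)
}

#' Classify lifetime attenuated positive psychotic symptoms
#'
#' Applies the ultra-high-risk attenuated positive symptoms criterion to
#' repeated SIPS assessments: a subject is `LA-PS` if any of the positive
#' subscales P1-P5 reaches a score of 3 or more at any assessment, and
#' `N-PS` otherwise. The result is invariant to the order of assessments
#' and of subscales.
#'
#' @param scores data frame with columns `subject_id` and `p1`..`p5`
#'   (integer scores 0-6), one row per assessment.
#' @return factor with levels `N-PS`, `LA-PS`, named by subject, the
#'   reference level being `N-PS`.
#' @export
classify_psychosis_status <- function(scores) {
  scores <- as.data.frame(scores)
  pcols <- paste0("p", 1:5)
  if (!all(c("subject_id", pcols) %in% names(scores))) {
    stop("scores needs columns subject_id, p1..p5")
  }
  if (nrow(scores) == 0L) stop("empty score set")
  vals <- as.matrix(scores[, pcols])
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 6)) {
    stop("SIPS scores must be finite and within 0-6")
  }
  mx <- tapply(apply(vals, 1L, max), scores$subject_id, max)
  factor(ifelse(mx >= 3, "LA-PS", "N-PS"), levels = c("N-PS", "LA-PS"))
}
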