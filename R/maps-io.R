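#' Read a single per-vertex scalar map
#'
#' Supported formats: FreeSurfer `curv` ("new" binary format, magic
#' 0xFFFFFF, big-endian float32) and single-frame `MGH` volumes holding one
#' value per vertex (uncompressed `.mgh`).
#'
#' @param path file to read.
#' @param format `"curv"` or `"mgh"`.
#' @return numeric vector, one value per vertex.
#' @export
read_vertex_map <- function(path, format = c("curv", "mgh")) {
  format <- match.arg(format)
  if (format == "curv") .read_curv(path) else .read_mgh(path)
}

#' Write a single per-vertex scalar map
#'
#' @inheritParams read_vertex_map
#' @param x numeric vector of per-vertex values.
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(x, path, format = c("curv", "mgh")) {
  format <- match.arg(format)
  if (format == "curv") .write_curv(x, path) else .write_mgh(x, path)
  invisible(path)
}

.read_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (magic[1L] * 65536 + magic[2L] * 256 + magic[3L] != 16777215) {
    stop("not a new-format FreeSurfer curv file (bad magic)")
  }
  vnum <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  readBin(con, "integer", n = 1L, size = 4L, endian = "big")  # fnum, unused
  vals_per <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (vals_per != 1L) stop("curv with vals_per_vertex != 1 unsupported")
  readBin(con, "numeric", n = vnum, size = 4L, endian = "big")
}

.write_curv <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xff)), con)
  writeBin(as.integer(length(x)), con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(as.numeric(x), con, size = 4L, endian = "big")
}

.read_mgh <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (version != 1L) stop("unsupported MGH version: ", version)
  dims <- readBin(con, "integer", n = 4L, size = 4L, endian = "big")
  type <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (type != 3L) stop("only MRI_FLOAT (type 3) MGH maps are supported")
  readBin(con, "integer", n = 1L, size = 4L, endian = "big")  # dof
  seek(con, 284L)  # header is padded to 284 bytes
  nvals <- prod(dims)
  readBin(con, "numeric", n = nvals, size = 4L, endian = "big")
}

.write_mgh <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(c(as.integer(length(x)), 1L, 1L, 1L), con, size = 4L,
           endian = "big")
  writeBin(3L, con, size = 4L, endian = "big")            # MRI_FLOAT
  writeBin(0L, con, size = 4L, endian = "big")            # dof
  writeBin(0L, con, size = 2L, endian = "big")            # goodRASflag
  writeBin(raw(284L - 30L), con)                          # pad header
  writeBin(as.numeric(x), con, size = 4L, endian = "big")
}

#' Read or write a scans-by-vertices matrix as TSV
#'
#' The package's plain-text matrix dialect: a header row of 0-based vertex
#' indices, then one row per scan. Used for measure matrices and exported
#' result maps.
#'
#' @param path file path.
#' @return for `read_matrix_tsv`, a numeric matrix (rows = scans).
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(read.delim(path, check.names = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param x numeric matrix or vector (a vector is written as one row).
#' @export
write_matrix_tsv <- function(x, path) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  colnames(x) <- as.character(seq_len(ncol(x)) - 1L)
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
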