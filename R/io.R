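# File I/O for the standard interchange formats used by the pipeline:
# NIfTI-1 volumes, CSV/JSON point sets, JSON meshes, MRtrix .tck tractograms
# and FSL-style bvec/bval direction schemes.
#
# World units are micrometers throughout; the NIfTI affine is written with
# the voxel spacing on its diagonal and the origin in the last column, and
# only axis-aligned (diagonal, positive) affines are accepted on read.

#' Read a NIfTI volume as a voxel grid
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [voxel_grid]; spacing and origin are taken from the affine.
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  lin <- aff[1:3, 1:3]
  if (max(abs(lin - diag(diag(lin)))) > 1e-4 * max(abs(diag(lin))) ||
    any(diag(lin) <= 0)) {
    stop("only axis-aligned affines with positive spacing are supported")
  }
  data <- array(as.numeric(img), dim = dim(img))
  voxel_grid(data, spacing = diag(lin), origin = aff[1:3, 4])
}

#' Write a voxel grid as a NIfTI volume
#'
#' @param grid A [voxel_grid].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_grid <- function(grid, path) {
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  img <- RNifti::asNifti(grid$data)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a point set from CSV
#'
#' Expects a header row with columns `x,y,z` and optionally `value` and/or
#' `label` (the CSV dialect used for cell locations and landmarks).
#'
#' @param path CSV file path.
#' @return A [point_set].
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) stop("CSV must have columns x,y,z")
  point_set(
    as.matrix(df[, need]),
    value = if ("value" %in% names(df)) df$value else NULL,
    label = if ("label" %in% names(df)) df$label else NULL
  )
}

#' Write a point set to CSV
#'
#' @param ps A [point_set].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(ps, path) {
  df <- data.frame(x = ps$points[, 1], y = ps$points[, 2], z = ps$points[, 3])
  if (!is.null(ps$value)) df$value <- ps$value
  if (!is.null(ps$label)) df$label <- ps$label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a point set as JSON
#'
#' @param path JSON file path.
#' @return A [point_set] (read) or `path` invisibly (write).
#' @export
read_points_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  point_set(matrix(unlist(o$points), ncol = 3L, byrow = FALSE),
    value = o$value, label = o$label
  )
}

#' @rdname read_points_json
#' @param ps A [point_set].
#' @export
write_points_json <- function(ps, path) {
  jsonlite::write_json(
    list(points = ps$points, value = ps$value, label = ps$label),
    path,
    digits = NA, auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' Read / write a surface mesh as JSON
#'
#' The documented mesh interchange format: an object with `vertices`
#' (n x 3, micrometers), `triangles` (m x 3, 0-based in the file) and
#' `flat_uv` (n x 2 in `[0,1]^2`).
#'
#' @param path JSON file path.
#' @return A [surface_mesh] (read) or `path` invisibly (write).
#' @export
read_mesh_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  surface_mesh(o$vertices, matrix(o$triangles, ncol = 3L) + 1L, o$flat_uv)
}

#' @rdname read_mesh_json
#' @param mesh A [surface_mesh].
#' @export
write_mesh_json <- function(mesh, path) {
  jsonlite::write_json(
    list(
      vertices = mesh$vertices, triangles = mesh$triangles - 1L,
      flat_uv = mesh$flat_uv
    ),
    path,
    digits = NA
  )
  invisible(path)
}

#' Read an MRtrix .tck tractogram
#'
#' Supports the Float32LE datatype written by [write_tck()].
#'
#' @param path `.tck` file path.
#' @return A [tractogram] (coordinates as stored; this package stores
#'   micrometers).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) stop("not an MRtrix .tck file")
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unterminated .tck header")
    if (identical(line, "END")) break
    kv <- sub(":.*$", "", line)
    val <- trimws(sub("^[^:]*:", "", line))
    if (kv == "file") offset <- as.integer(sub("^\\. ", "", val))
    if (kv == "datatype") datatype <- val
  }
  if (!identical(datatype, "Float32LE")) {
    stop("unsupported .tck datatype: ", datatype)
  }
  seek(con, where = offset, origin = "start")
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
    endian = "little"
  )
  m <- matrix(raw[seq_len(3 * (length(raw) %/% 3))], ncol = 3L, byrow = TRUE)
  breaks <- which(is.nan(m[, 1]) | is.infinite(m[, 1]))
  streamlines <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) streamlines[[length(streamlines) + 1L]] <-
        m[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
    if (is.infinite(m[b, 1])) break
  }
  tractogram(streamlines)
}

#' Write a tractogram as an MRtrix .tck file
#'
#' @param t A [tractogram].
#' @param path Output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(t, path) {
  hdr <- paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    sprintf("count: %d\n", length(t$streamlines))
  )
  # reserve room for the file offset line
  off_line <- function(o) sprintf("file: . %d\nEND\n", o)
  offset <- nchar(hdr, type = "bytes") + nchar(off_line(100000L), type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeChar(sprintf("file: . %6d\nEND\n", offset), con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read / write FSL-style bvec/bval direction schemes
#'
#' `bvecs` is a 3 x n whitespace-separated table of unit vectors; `bvals`
#' one row of b-values (s/mm^2).
#'
#' @param bvec_path,bval_path File paths.
#' @return A list with `directions` (n x 3) and `bvals` (length n).
#' @export
read_bvec_bval <- function(bvec_path, bval_path) {
  v <- as.matrix(utils::read.table(bvec_path))
  b <- as.numeric(utils::read.table(bval_path))
  if (nrow(v) != 3L) stop("bvec file must have 3 rows")
  list(directions = t(v), bvals = b)
}

#' @rdname read_bvec_bval
#' @param directions n x 3 unit vectors.
#' @param bvals Length-n b-values.
#' @export
write_bvec_bval <- function(directions, bvals, bvec_path, bval_path) {
  utils::write.table(t(directions), bvec_path,
    row.names = FALSE, col.names = FALSE
  )
  cat(paste(bvals, collapse = " "), "\n", file = bval_path)
  invisible(c(bvec_path, bval_path))
}
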