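# File-format adapters. CSV is the canonical tabular interchange; volumes
# travel as NIfTI (through RNifti) and surfaces as ASCII PLY. NIfTI sform
# matrices address voxel *centres* at integer indices, whereas the in-memory
# affine uses the half-open corner convention (centre at index + 0.5); the
# adapters shift the translation column by half a voxel on the way in/out so
# a round trip preserves the affine exactly.

affine_to_nifti <- function(affine) {
  out <- affine
  out[1:3, 4L] <- affine[1:3, 4L] + affine[1:3, 1:3] %*% rep(0.5, 3L)
  out
}

affine_from_nifti <- function(sform) {
  out <- sform
  out[1:3, 4L] <- sform[1:3, 4L] - sform[1:3, 1:3] %*% rep(0.5, 3L)
  out
}

#' Write a volume to NIfTI
#'
#' Invalid voxels of a scalar volume are stored as NaN; label volumes are
#' stored as integers.
#'
#' @param vol a [scalar_volume()] or [label_volume()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  if (inherits(vol, "scalar_volume")) {
    vals <- vol$values
    vals[!vol$valid] <- NaN
    affine <- vol$affine
  } else if (inherits(vol, "label_volume")) {
    vals <- vol$labels
    affine <- vol$affine
  } else stop("`vol` must be a scalar_volume or label_volume")
  img <- RNifti::asNifti(vals)
  # pixdim must agree with the sform scales or RNifti renormalizes them
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::`sform<-`(img, structure(affine_to_nifti(affine), code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine_to_nifti(affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @param labels read as an integer [label_volume()] instead of a
#'   [scalar_volume()].
#' @return A [scalar_volume()] (NaN voxels marked invalid) or
#'   [label_volume()].
#' @export
read_volume_nifti <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("missing input file: ", path)
  img <- RNifti::readNifti(path)
  affine <- affine_from_nifti(unclass(RNifti::xform(img))[1:4, 1:4])
  arr <- array(as.numeric(img), dim = dim(img))
  if (labels) label_volume(array(as.integer(round(arr)), dim(arr)), affine)
  else scalar_volume(arr, affine)
}

#' Write a triangle mesh as ASCII PLY
#'
#' @param vertices n x 3 coordinates (mm).
#' @param triangles m x 3 1-based vertex indices (stored 0-based in the
#'   file, per PLY convention).
#' @param path output `.ply` file.
#' @return The path, invisibly.
#' @export
write_ply <- function(vertices, triangles, path) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     vertices[, 1L], vertices[, 2L], vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", triangles[, 1L] - 1L,
                     triangles[, 2L] - 1L, triangles[, 3L] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY triangle mesh
#'
#' @param path `.ply` file.
#' @return List with `vertices` (n x 3) and `triangles` (m x 3, 1-based).
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1L] != "ply" ||
      !grepl("^format ascii", lines[2L]))
    stop("malformed PLY header in ", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("malformed PLY header (no end_header) in ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header in ", path)
  vtx <- do.call(rbind, lapply(strsplit(lines[endh + seq_len(nv)], " "),
                               function(x) as.numeric(x[1:3])))
  fc <- do.call(rbind, lapply(strsplit(lines[endh + nv + seq_len(nf)], " "),
                              function(x) as.integer(x[2:4]) + 1L))
  list(vertices = vtx, triangles = fc)
}

#' Write / read a surface pair as two PLY files
#'
#' @param surfaces a [cortical_surface_pair()].
#' @param prefix path prefix; `<prefix>_white.ply` and `<prefix>_pial.ply`
#'   are written.
#' @return The two paths, invisibly.
#' @export
write_surface_pair <- function(surfaces, prefix) {
  stopifnot(inherits(surfaces, "cortical_surface_pair"))
  pw <- paste0(prefix, "_white.ply")
  pp <- paste0(prefix, "_pial.ply")
  write_ply(surfaces$white_vertices, surfaces$triangles, pw)
  write_ply(surfaces$pial_vertices, surfaces$triangles, pp)
  invisible(c(white = pw, pial = pp))
}

#' @rdname write_surface_pair
#' @export
read_surface_pair <- function(prefix) {
  w <- read_ply(paste0(prefix, "_white.ply"))
  p <- read_ply(paste0(prefix, "_pial.ply"))
  cortical_surface_pair(w$vertices, p$vertices, w$triangles)
}

#' Write / read a vertex parcellation as CSV
#'
#' Columns: `vertex_id`, `region_id` and (optionally) `region_name`.
#'
#' @param parcellation data frame with `vertex_id`, `region_id`.
#' @param path CSV file.
#' @return The path (write) or the parcellation data frame (read).
#' @export
write_parcellation_csv <- function(parcellation, path) {
  utils::write.csv(parcellation, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation_csv
#' @export
read_parcellation_csv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  out <- utils::read.csv(path)
  if (!all(c("vertex_id", "region_id") %in% names(out)))
    stop("parcellation CSV must have vertex_id and region_id columns")
  out
}

#' Write / read a long-format cohort table as CSV
#'
#' @param cohort cohort data frame.
#' @param path CSV file.
#' @return The path (write) or the cohort data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.csv(path)
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; identical configurations hash
#' identically across sessions.
#'
#' @param config any JSON-serializable list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
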