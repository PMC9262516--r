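#' Construct a scalar intensity volume
#'
#' A scalar volume bundles a 3-D grid of intensities with a voxel-to-world
#' affine and a per-voxel validity mask. Continuous voxel coordinates follow
#' the half-open corner convention: voxel \eqn{(i, j, k)} (0-based) spans
#' \eqn{[i, i+1)} along each axis, so its centre maps through the affine at
#' \eqn{(i+0.5, j+0.5, k+0.5)}. Invalid voxels carry `NA` values; they are
#' treated as missing (never as zeros) by downstream sampling.
#'
#' @param values 3-D numeric array of intensities.
#' @param affine 4x4 invertible voxel-to-world transform (mm).
#' @param valid_mask optional logical array of the same shape; defaults to
#'   `is.finite(values)`.
#' @return An object of class `"scalar_volume"` with fields `values`,
#'   `affine` and `valid`.
#' @export
scalar_volume <- function(values, affine, valid_mask = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  storage.mode(values) <- "double"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (!all(is.finite(affine)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be finite and invertible")
  if (is.null(valid_mask)) {
    valid_mask <- is.finite(values)
  } else {
    if (!identical(dim(valid_mask), dim(values)))
      stop("`valid_mask` must have the same shape as `values`")
    valid_mask <- valid_mask & is.finite(values)
  }
  structure(list(values = values, affine = affine, valid = valid_mask),
            class = "scalar_volume")
}

#' Construct a label volume
#'
#' Integer tissue labels on the same grid convention as [scalar_volume()]:
#' 0 = non-brain, 1 = gray matter (GM), 2 = white matter (WM).
#'
#' @param labels 3-D integer array.
#' @param affine 4x4 voxel-to-world transform (mm).
#' @return An object of class `"label_volume"`.
#' @export
label_volume <- function(labels, affine) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be a 4x4 invertible matrix")
  structure(list(labels = labels, affine = affine), class = "label_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$values), collapse = " x "),
      " grid, ", sum(x$valid), " valid voxels\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " grid, ", sum(x$labels == 1L), " GM voxels\n", sep = "")
  invisible(x)
}

grid_of <- function(vol) {
  if (inherits(vol, "scalar_volume")) dim(vol$values) else dim(vol$labels)
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(grid_of(a), grid_of(b)) && max(abs(a$affine - b$affine)) <= tol
}

#' Voxelwise T1w/T2w intensity ratio
#'
#' Computes R = T1/T2 at every voxel where the T2 intensity exceeds a floor
#' `epsilon`. Voxels with T2 at or below the floor, or invalid in either
#' input, are marked invalid and carry no number. The floor defaults to
#' 1e-6 times the 99th percentile of valid T2 intensities, so it is
#' insensitive to the (arbitrary) intensity units of the scanner.
#'
#' @param t1,t2 co-registered [scalar_volume()]s on the same grid.
#' @param epsilon intensity floor for the denominator; `NULL` for the
#'   relative default.
#' @return A [scalar_volume()] holding R, with attribute `"epsilon"`.
#' @export
compute_ratio_volume <- function(t1, t2, epsilon = NULL) {
  stopifnot(inherits(t1, "scalar_volume"), inherits(t2, "scalar_volume"))
  if (!same_grid(t1, t2))
    stop("T1 and T2 volumes must share grid shape and affine")
  if (any(t1$values[t1$valid] < 0) || any(t2$values[t2$valid] < 0))
    stop("negative intensities are not permitted")
  if (is.null(epsilon)) {
    t2v <- t2$values[t2$valid]
    epsilon <- 1e-6 * stats::quantile(t2v, 0.99, names = FALSE)
  }
  valid <- t1$valid & t2$valid & (t2$values > epsilon)
  r <- array(NA_real_, dim(t1$values))
  r[valid] <- t1$values[valid] / t2$values[valid]
  out <- scalar_volume(r, t1$affine, valid)
  attr(out, "epsilon") <- epsilon
  out
}

#' Restrict a ratio volume to gray matter
#'
#' Marks valid only those voxels that are valid in the input and labelled GM
#' (label 1). The returned volume carries `n_valid` and `empty` fields so a
#' degenerate (empty) mask is detectable without scanning the array.
#'
#' @param r a [scalar_volume()] of ratio values.
#' @param labels a [label_volume()] on the same grid.
#' @return A [scalar_volume()] with extra fields `n_valid` and `empty`.
#' @export
mask_to_gm <- function(r, labels) {
  stopifnot(inherits(r, "scalar_volume"), inherits(labels, "label_volume"))
  if (!same_grid(r, labels))
    stop("ratio and label volumes must share grid shape and affine")
  valid <- r$valid & (labels$labels == 1L)
  vals <- array(NA_real_, dim(r$values))
  vals[valid] <- r$values[valid]
  out <- scalar_volume(vals, r$affine, valid)
  out$n_valid <- sum(valid)
  out$empty <- out$n_valid == 0L
  out
}
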