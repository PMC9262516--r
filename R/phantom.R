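#' Specification for a spherical-shell cortex phantom
#'
#' The phantom is a pair of concentric sphere meshes (white and pial surfaces
#' of a cortical shell) embedded in an isotropic voxel grid. It is
#' deliberately unfolded: a spherical shell is sufficient to exercise
#' transcortical segment tracing, vertex pairing and parcel statistics, while
#' keeping every geometric ground truth available in closed form.
#'
#' @param n_subdivisions icosphere subdivision level (0 = icosahedron,
#'   each level quadruples the triangle count; level 3 gives 642 vertices).
#' @param inner_radius_mm radius of the white (GM/WM interface) sphere.
#' @param thickness_mm radial pial-minus-white offset; the pial radius is
#'   `inner_radius_mm + thickness_mm`.
#' @param n_regions number of equal angular-sector parcels (>= 2).
#' @param voxel_size_mm isotropic voxel spacing of the intensity grid.
#' @param grid_shape integer vector of 3 voxel counts per axis.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_subdivisions = 3L, inner_radius_mm = 60,
                         thickness_mm = 3, n_regions = 8L,
                         voxel_size_mm = 2, grid_shape = c(64L, 64L, 64L)) {
  if (thickness_mm <= 0) stop("`thickness_mm` must be > 0")
  if (inner_radius_mm <= 0) stop("`inner_radius_mm` must be > 0")
  if (voxel_size_mm <= 0) stop("`voxel_size_mm` must be > 0")
  if (n_regions < 2L) stop("`n_regions` must be >= 2")
  if (n_subdivisions < 0L) stop("`n_subdivisions` must be >= 0")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive integers")
  structure(list(n_subdivisions = as.integer(n_subdivisions),
                 inner_radius_mm = inner_radius_mm,
                 thickness_mm = thickness_mm,
                 pial_radius_mm = inner_radius_mm + thickness_mm,
                 n_regions = as.integer(n_regions),
                 voxel_size_mm = voxel_size_mm,
                 grid_shape = grid_shape),
            class = "phantom_spec")
}

# Unit icosphere: subdivided icosahedron reprojected to the unit sphere.
icosphere <- function(n_subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(n_subdivisions)) {
    nf <- nrow(f)
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    first <- !duplicated(key)
    mid_of <- nrow(v) + match(key, key[first])
    newv <- (v[e[first, 1L], , drop = FALSE] + v[e[first, 2L], , drop = FALSE]) / 2
    newv <- newv / sqrt(rowSums(newv^2))
    v <- rbind(v, newv)
    m12 <- mid_of[seq_len(nf)]
    m23 <- mid_of[nf + seq_len(nf)]
    m31 <- mid_of[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1L], m12, m31),
               cbind(f[, 2L], m23, m12),
               cbind(f[, 3L], m31, m23),
               cbind(m12, m23, m31))
  }
  dimnames(v) <- NULL
  dimnames(f) <- NULL
  list(vertices = v, triangles = f)
}

# Angular-sector parcel of a set of directions (equal azimuthal slices).
region_of_direction <- function(points, n_regions) {
  phi <- atan2(points[, 2L], points[, 1L]) %% (2 * pi)
  as.integer(pmin(floor(phi / (2 * pi / n_regions)), n_regions - 1L)) + 1L
}

#' Paired white/pial cortical surface meshes
#'
#' @param white_vertices,pial_vertices n x 3 world-mm vertex coordinates.
#' @param triangles m x 3 1-based vertex index triplets (shared by both
#'   surfaces).
#' @param correspondence white-vertex index -> pial-vertex index (a
#'   bijection); defaults to the identity.
#' @return An object of class `"cortical_surface_pair"`.
#' @export
cortical_surface_pair <- function(white_vertices, pial_vertices, triangles,
                                  correspondence = seq_len(nrow(white_vertices))) {
  white_vertices <- as.matrix(white_vertices)
  pial_vertices <- as.matrix(pial_vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  n <- nrow(white_vertices)
  if (nrow(pial_vertices) != n)
    stop("white and pial surfaces must have equal vertex counts")
  if (ncol(white_vertices) != 3L || ncol(pial_vertices) != 3L)
    stop("vertices must be n x 3 matrices")
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangles reference invalid vertex indices")
  correspondence <- as.integer(correspondence)
  if (length(correspondence) != n || !setequal(correspondence, seq_len(n)))
    stop("`correspondence` must be a bijection over vertex indices")
  structure(list(white_vertices = white_vertices,
                 pial_vertices = pial_vertices,
                 triangles = triangles,
                 correspondence = correspondence),
            class = "cortical_surface_pair")
}

#' @export
print.cortical_surface_pair <- function(x, ...) {
  cat("<cortical_surface_pair> ", nrow(x$white_vertices), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

#' Template phantom geometry: concentric sphere meshes plus a parcellation
#'
#' Builds the white and pial surfaces of a spherical cortical shell with
#' identical triangulation, index-corresponded vertices, and a parcellation
#' of the sphere into `n_regions` contiguous angular sectors.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer; accepted for interface uniformity (the template is
#'   deterministic).
#' @return A list with elements `surfaces` (a [cortical_surface_pair()]) and
#'   `parcellation` (data frame with `vertex_id`, `region_id`).
#' @export
make_template_geometry <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  sph <- icosphere(spec$n_subdivisions)
  white <- sph$vertices * spec$inner_radius_mm
  pial <- sph$vertices * spec$pial_radius_mm
  surfaces <- cortical_surface_pair(white, pial, sph$triangles)
  parcellation <- data.frame(
    vertex_id = seq_len(nrow(white)),
    region_id = region_of_direction(sph$vertices, spec$n_regions))
  list(surfaces = surfaces, parcellation = parcellation)
}

#' Jitter a pial surface (for pairing robustness experiments)
#'
#' Adds isotropic Gaussian noise to the pial vertex coordinates, leaving the
#' white surface and the triangulation untouched.
#'
#' @param surfaces a [cortical_surface_pair()].
#' @param sd_mm noise standard deviation (mm).
#' @param seed integer RNG seed.
#' @return A perturbed [cortical_surface_pair()].
#' @export
perturb_pial_surface <- function(surfaces, sd_mm, seed = 1L) {
  stopifnot(inherits(surfaces, "cortical_surface_pair"), sd_mm >= 0)
  set.seed(seed)
  p <- surfaces$pial_vertices +
    matrix(stats::rnorm(length(surfaces$pial_vertices), 0, sd_mm),
           ncol = 3L)
  cortical_surface_pair(surfaces$white_vertices, p, surfaces$triangles,
                        surfaces$correspondence)
}

phantom_affine <- function(spec) {
  a <- diag(c(rep(spec$voxel_size_mm, 3L), 1))
  a[1:3, 4L] <- -spec$voxel_size_mm * spec$grid_shape / 2
  a
}

#' Synthetic T1/T2 intensity volumes for a phantom
#'
#' Fills the voxel grid of `spec` with T1 and T2 intensities such that,
#' inside gray matter of region r, the expected voxelwise T1/T2 ratio equals
#' the region's baseline ratio from `profile`. Noise, when requested, is
#' multiplicative log-normal applied independently to T1 and T2 (mean factor
#' 1), so intensities remain positive and the noisy ratio stays log-normal.
#'
#' @param geometry output of [make_template_geometry()].
#' @param parcellation vertex-level parcellation (unused directly; the
#'   voxel-level parcel is recomputed from voxel-centre directions so that
#'   voxels and vertices share sector boundaries).
#' @param profile a [regional_profile()] supplying `baseline_r` per region.
#' @param spec the [phantom_spec()] used to build the geometry.
#' @param noise_sd fractional noise level (sd of the multiplicative factor).
#' @param seed integer RNG seed.
#' @return A list with `t1`, `t2` ([scalar_volume()]), `gm`
#'   ([label_volume()]; 0 background, 1 GM, 2 WM) and `region` (integer array
#'   of GM voxel parcels, 0 outside GM).
#' @export
make_intensity_volumes <- function(geometry, parcellation, profile, spec,
                                   noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), noise_sd >= 0)
  n <- spec$grid_shape
  half_extent <- min(n) * spec$voxel_size_mm / 2
  if (spec$pial_radius_mm >= half_extent)
    stop("geometry exceeds grid bounds: enlarge `grid_shape` or shrink radii")
  a <- phantom_affine(spec)
  vx <- spec$voxel_size_mm
  cx <- vx * ((seq_len(n[1L]) - 0.5)) - vx * n[1L] / 2
  cy <- vx * ((seq_len(n[2L]) - 0.5)) - vx * n[2L] / 2
  cz <- vx * ((seq_len(n[3L]) - 0.5)) - vx * n[3L] / 2
  x <- array(cx, dim = n)
  y <- array(rep(cy, each = n[1L]), dim = n)
  z <- array(rep(cz, each = n[1L] * n[2L]), dim = n)
  rad <- sqrt(x^2 + y^2 + z^2)
  gm <- rad >= spec$inner_radius_mm & rad < spec$pial_radius_mm
  wm <- rad < spec$inner_radius_mm
  labels <- array(0L, n)
  labels[wm] <- 2L
  labels[gm] <- 1L
  region <- array(0L, n)
  region[gm] <- region_of_direction(cbind(x[gm], y[gm], z[gm]), spec$n_regions)
  t1 <- array(0.5, n)  # dim background
  t2 <- array(1.0, n)
  t1[wm] <- 1.4        # heavily myelinated WM
  bl <- profile$baseline_r[match(region[gm], profile$region_id)]
  if (anyNA(bl)) stop("`profile` does not cover every phantom region")
  t1[gm] <- bl
  if (noise_sd > 0) {
    set.seed(seed)
    s <- sqrt(log1p(noise_sd^2))
    t1 <- t1 * exp(stats::rnorm(length(t1), -s^2 / 2, s))
    t2 <- t2 * exp(stats::rnorm(length(t2), -s^2 / 2, s))
  }
  list(t1 = scalar_volume(t1, a), t2 = scalar_volume(t2, a),
       gm = label_volume(labels, a), region = region)
}
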