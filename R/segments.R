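#' Transcortical segments joining paired white and pial vertices
#'
#' @param white_points,pial_points n x 3 world-mm endpoint coordinates.
#' @return An object of class `"transcortical_segments"` with fields
#'   `white`, `pial` and `length_mm`.
#' @export
transcortical_segments <- function(white_points, pial_points) {
  white_points <- as.matrix(white_points)
  pial_points <- as.matrix(pial_points)
  if (!identical(dim(white_points), dim(pial_points)) ||
      ncol(white_points) != 3L)
    stop("endpoints must be matching n x 3 matrices")
  if (!all(is.finite(white_points)) || !all(is.finite(pial_points)))
    stop("endpoints must be finite")
  structure(list(white = white_points, pial = pial_points,
                 length_mm = sqrt(rowSums((pial_points - white_points)^2))),
            class = "transcortical_segments")
}

#' @export
print.transcortical_segments <- function(x, ...) {
  cat("<transcortical_segments> ", nrow(x$white), " segments, mean length ",
      format(mean(x$length_mm), digits = 4), " mm\n", sep = "")
  invisible(x)
}

# k-ring vertex neighbourhoods (including the seed vertex) from a triangle
# list; ring 0 is the vertex itself.
k_ring_neighbors <- function(triangles, n_vertices, k) {
  edges <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
                 triangles[, c(3L, 1L)])
  edges <- rbind(edges, edges[, c(2L, 1L)])
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(n_vertices)))
  adj <- lapply(adj, unique)
  ring <- as.list(seq_len(n_vertices))
  for (step in seq_len(k))
    ring <- lapply(ring, function(s) unique(c(s, unlist(adj[s], use.names = FALSE))))
  ring
}

#' Pair white vertices with pial vertices
#'
#' With `search_ring = 0` the pairing is the stored index correspondence
#' (FreeSurfer-style surfaces share vertex indexing). With `search_ring = k`
#' the pial endpoint of each segment is instead the *nearest* pial vertex
#' within the k-ring mesh neighbourhood of the index-corresponded pial
#' vertex; restricting the search to the neighbourhood is the topological
#' constraint that prevents pairing with a geometrically close but
#' topologically distant vertex. Ties resolve to the lowest vertex index.
#'
#' @param surfaces a [cortical_surface_pair()].
#' @param search_ring non-negative integer neighbourhood depth.
#' @return A list with `segments` (a [transcortical_segments()]) and
#'   `pial_index` (chosen pial vertex per white vertex).
#' @export
pair_vertices <- function(surfaces, search_ring = 0L) {
  stopifnot(inherits(surfaces, "cortical_surface_pair"), search_ring >= 0L)
  corr <- surfaces$correspondence
  n <- nrow(surfaces$white_vertices)
  if (search_ring == 0L) {
    pidx <- corr
  } else {
    nb <- k_ring_neighbors(surfaces$triangles, n, search_ring)
    pidx <- integer(n)
    for (i in seq_len(n)) {
      cand <- sort(nb[[corr[i]]])
      d2 <- rowSums((surfaces$pial_vertices[cand, , drop = FALSE] -
                       matrix(surfaces$white_vertices[i, ], length(cand), 3L,
                              byrow = TRUE))^2)
      pidx[i] <- cand[which.min(d2)]
    }
  }
  list(segments = transcortical_segments(surfaces$white_vertices,
                                         surfaces$pial_vertices[pidx, , drop = FALSE]),
       pial_index = pidx)
}

#' Exact ray-voxel traversal of one transcortical segment
#'
#' Maps the segment endpoints into continuous voxel coordinates through the
#' inverse affine and marches the straight line through the grid by exact
#' plane-crossing computation. Voxel \eqn{(i,j,k)} spans \eqn{[i, i+1)}
#' (half-open), so boundary crossings belong deterministically to the
#' entering voxel. The returned in-voxel lengths sum to the (clipped) segment
#' length to floating-point precision.
#'
#' @param white_point,pial_point world-mm endpoints.
#' @param vol a [scalar_volume()] or [label_volume()] supplying the grid.
#' @return A data frame with 0-based voxel indices `i`, `j`, `k` and
#'   `length_mm`, in traversal order (white to pial). A zero-length segment
#'   yields its single containing voxel with zero length; a segment entirely
#'   outside the grid yields zero rows (with a warning when clipping occurs).
#' @export
trace_segment_voxels <- function(white_point, pial_point, vol) {
  dims <- grid_of(vol)
  affine <- if (inherits(vol, "scalar_volume") || inherits(vol, "label_volume"))
    vol$affine else stop("`vol` must be a scalar_volume or label_volume")
  ainv <- solve(affine)
  g0 <- (ainv %*% c(white_point, 1))[1:3]
  g1 <- (ainv %*% c(pial_point, 1))[1:3]
  len <- sqrt(sum((pial_point - white_point)^2))
  empty <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      length_mm = numeric(0))
  if (len == 0) {
    cell <- pmin(pmax(floor(g0), 0), dims - 1L)
    if (any(g0 < 0 | g0 >= dims)) {
      warning("zero-length segment outside grid bounds")
      return(empty)
    }
    return(data.frame(i = cell[1L], j = cell[2L], k = cell[3L],
                      length_mm = 0))
  }
  d <- g1 - g0
  # clip the parameter range [0, 1] to the grid box (slab method)
  tlo <- 0
  thi <- 1
  for (ax in 1:3) {
    if (d[ax] == 0) {
      if (g0[ax] < 0 || g0[ax] >= dims[ax]) {
        warning("segment outside grid bounds; clipped away entirely")
        return(empty)
      }
    } else {
      ta <- (0 - g0[ax]) / d[ax]
      tb <- (dims[ax] - g0[ax]) / d[ax]
      tlo <- max(tlo, min(ta, tb))
      thi <- min(thi, max(ta, tb))
    }
  }
  if (tlo > 0 || thi < 1) {
    warning("segment endpoints outside grid bounds; traversal clipped")
    if (tlo >= thi) return(empty)
  }
  ga <- g0 + tlo * d
  gb <- g0 + thi * d
  tcross <- numeric(0)
  for (ax in 1:3) {
    if (d[ax] == 0) next
    lo <- min(ga[ax], gb[ax])
    hi <- max(ga[ax], gb[ax])
    planes <- seq.int(floor(lo) + 1, ceiling(hi) - 1)
    planes <- planes[planes > lo & planes < hi]
    if (length(planes)) tcross <- c(tcross, (planes - g0[ax]) / d[ax])
  }
  ts <- sort(unique(c(tlo, tcross, thi)))
  ts <- ts[ts >= tlo & ts <= thi]
  mids <- (ts[-1L] + ts[-length(ts)]) / 2
  gmid <- matrix(g0, length(mids), 3L, byrow = TRUE) + outer(mids, d)
  cells <- floor(gmid)
  cells[, 1L] <- pmin(pmax(cells[, 1L], 0), dims[1L] - 1L)
  cells[, 2L] <- pmin(pmax(cells[, 2L], 0), dims[2L] - 1L)
  cells[, 3L] <- pmin(pmax(cells[, 3L], 0), dims[3L] - 1L)
  data.frame(i = as.integer(cells[, 1L]), j = as.integer(cells[, 2L]),
             k = as.integer(cells[, 3L]), length_mm = diff(ts) * len)
}

#' Length-weighted ratio sample along one transcortical segment
#'
#' Averages the ratio values of the gray-matter voxels traversed by the
#' segment, weighting each voxel by the in-voxel length of the segment.
#' Non-GM and invalid voxels contribute neither value nor weight (the
#' average renormalizes over the remaining length); if no traversed voxel
#' qualifies the sample is missing.
#'
#' @param white_point,pial_point world-mm endpoints.
#' @param r ratio [scalar_volume()].
#' @param gm [label_volume()] on the same grid.
#' @return A list with `value`, `missing` and `n_voxels`.
#' @export
sample_vertex_ratio <- function(white_point, pial_point, r, gm) {
  stopifnot(inherits(r, "scalar_volume"), inherits(gm, "label_volume"))
  if (!same_grid(r, gm))
    stop("ratio and label volumes must share grid shape and affine")
  tv <- trace_segment_voxels(white_point, pial_point, r)
  if (nrow(tv) == 0L)
    return(list(value = NA_real_, missing = TRUE, n_voxels = 0L))
  idx <- cbind(tv$i + 1L, tv$j + 1L, tv$k + 1L)
  keep <- gm$labels[idx] == 1L & r$valid[idx] & tv$length_mm > 0
  if (!any(keep) || sum(tv$length_mm[keep]) == 0)
    return(list(value = NA_real_, missing = TRUE, n_voxels = 0L))
  w <- tv$length_mm[keep]
  list(value = sum(w * r$values[idx[keep, , drop = FALSE]]) / sum(w),
       missing = FALSE, n_voxels = sum(keep))
}

#' Sample a whole vertex map of ratio values
#'
#' Applies [sample_vertex_ratio()] to every segment, producing a per-vertex
#' scalar map with an explicit missing mask.
#'
#' @param segments a [transcortical_segments()].
#' @param r ratio [scalar_volume()].
#' @param gm [label_volume()] on the same grid.
#' @return A list with numeric `values` (NA where missing) and logical
#'   `missing`, one entry per vertex.
#' @export
sample_vertex_map <- function(segments, r, gm) {
  stopifnot(inherits(segments, "transcortical_segments"))
  n <- nrow(segments$white)
  values <- rep(NA_real_, n)
  missing <- rep(TRUE, n)
  for (v in seq_len(n)) {
    s <- sample_vertex_ratio(segments$white[v, ], segments$pial[v, ], r, gm)
    values[v] <- s$value
    missing[v] <- s$missing
  }
  list(values = values, missing = missing)
}

#' Transcortical segment length as a thickness measure
#'
#' @param segments a [transcortical_segments()].
#' @return Numeric vector of segment lengths (mm).
#' @export
segment_thickness <- function(segments) {
  stopifnot(inherits(segments, "transcortical_segments"))
  segments$length_mm
}

#' Normalize a regional measure by intracranial volume
#'
#' @param value numeric measure (e.g., regional volume in mm^3).
#' @param icv total intracranial volume (mm^3), > 0.
#' @return `value / icv` (dimensionless).
#' @export
normalize_by_icv <- function(value, icv) {
  if (!is.numeric(icv) || length(icv) != 1L || !is.finite(icv) || icv <= 0)
    stop("`icv` must be a single positive number")
  value / icv
}
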