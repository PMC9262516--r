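# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: traversal is checked against dense point
# sampling, regional aggregation against explicit nested loops, and the
# mixed-model likelihood against a direct marginal-Gaussian evaluation.

# Dense-sampling traversal oracle: drop n_points midpoints uniformly along
# the segment, bin each by its containing voxel, and credit each point with
# length/n_points.
dense_trace_oracle <- function(p0, p1, vol, n_points = 1e4) {
  ainv <- solve(vol$affine)
  len <- sqrt(sum((p1 - p0)^2))
  t <- (seq_len(n_points) - 0.5) / n_points
  pts <- cbind(outer(t, p1[1] - p0[1]) + p0[1],
               outer(t, p1[2] - p0[2]) + p0[2],
               outer(t, p1[3] - p0[3]) + p0[3])
  g <- t(ainv %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
  cells <- floor(g)
  key <- paste(cells[, 1], cells[, 2], cells[, 3])
  w <- table(key) * len / n_points
  out <- do.call(rbind, strsplit(names(w), " "))
  data.frame(i = as.integer(out[, 1]), j = as.integer(out[, 2]),
             k = as.integer(out[, 3]), length_mm = as.numeric(w))
}

# Dense-sampling weighted-value oracle restricted to valid GM voxels.
dense_value_oracle <- function(p0, p1, r, gm, n_points = 1e4) {
  tv <- dense_trace_oracle(p0, p1, r, n_points)
  idx <- cbind(tv$i + 1L, tv$j + 1L, tv$k + 1L)
  inside <- tv$i >= 0 & tv$j >= 0 & tv$k >= 0 &
    tv$i < dim(r$values)[1] & tv$j < dim(r$values)[2] & tv$k < dim(r$values)[3]
  keep <- inside
  keep[inside] <- gm$labels[idx[inside, , drop = FALSE]] == 1L &
    r$valid[idx[inside, , drop = FALSE]]
  if (!any(keep)) return(NA_real_)
  w <- tv$length_mm[keep]
  sum(w * r$values[idx[keep, , drop = FALSE]]) / sum(w)
}

# Explicit two-stage (subjects-then-vertices) aggregation oracle.
nested_loop_region_oracle <- function(maps, region, groups) {
  out <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    for (r in sort(unique(region))) {
      verts <- which(region == r)
      vmeans <- c()
      for (v in verts) {
        vals <- maps[v, cols]
        vals <- vals[!is.na(vals)]
        if (length(vals)) vmeans <- c(vmeans, mean(vals))
      }
      out[[paste(g, r)]] <- data.frame(group = g, region_id = r,
                                       mean_r = if (length(vmeans))
                                         mean(vmeans) else NA_real_)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Direct marginal log-likelihood of the mixed model with independent
# per-subject random intercept and slope on delta_t.
direct_lmm_loglik <- function(data, beta, sigma0_sq, sigma1_sq, sigma_sq,
                              include_diagnosis = TRUE) {
  des <- build_lmm_design(data, include_diagnosis = include_diagnosis)
  resid <- des$y - as.numeric(des$X %*% beta)
  ll <- 0
  for (s in levels(des$grouping)) {
    sel <- des$grouping == s
    dt <- des$delta_t[sel]
    v <- sigma0_sq + sigma1_sq * outer(dt, dt) + diag(sigma_sq, sum(sel))
    r <- resid[sel]
    ll <- ll - 0.5 * (sum(sel) * log(2 * pi) + determinant(v)$modulus +
                        sum(r * solve(v, r)))
  }
  as.numeric(ll)
}

# k-ring neighbourhood via boolean adjacency-matrix powers (independent of
# the package's BFS implementation).
matrix_k_ring <- function(triangles, n_vertices, k) {
  adj <- matrix(FALSE, n_vertices, n_vertices)
  for (row in seq_len(nrow(triangles))) {
    tri <- triangles[row, ]
    adj[tri[1], tri[2]] <- adj[tri[2], tri[1]] <- TRUE
    adj[tri[2], tri[3]] <- adj[tri[3], tri[2]] <- TRUE
    adj[tri[3], tri[1]] <- adj[tri[1], tri[3]] <- TRUE
  }
  reach <- diag(TRUE, n_vertices)
  for (step in seq_len(k)) reach <- reach | (reach %*% adj > 0)
  lapply(seq_len(n_vertices), function(i) which(reach[i, ]))
}

# Small deterministic cohort for statistical unit tests.
tiny_cohort <- function(seed = 1, n = 20, n_regions = 4) {
  make_longitudinal_cohort(
    cohort_config(n_hc = n, n_mtbi = n, seed = seed),
    default_regional_profile(n_regions))
}
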