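test_that("axis-aligned traversal matches the analytic plane crossings", {
  vol <- scalar_volume(array(1, c(4, 4, 4)), diag(4))
  tv <- trace_segment_voxels(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5), vol)
  expect_equal(tv$i, c(0L, 1L, 2L))
  expect_equal(tv$j, c(0L, 0L, 0L))
  expect_equal(tv$k, c(0L, 0L, 0L))
  expect_equal(tv$length_mm, c(0.5, 1, 0.5), tolerance = 1e-12)
})

test_that("in-voxel lengths always sum to the segment length", {
  set.seed(21)
  aff <- diag(c(1.7, 2.1, 0.9, 1))
  aff[1:3, 4] <- c(-20, -25, -10)
  vol <- scalar_volume(array(1, c(24, 24, 24)), aff)
  for (rep in 1:200) {
    p0 <- runif(3, -9, 9)
    p1 <- runif(3, -9, 9)
    tv <- trace_segment_voxels(p0, p1, vol)
    expect_lt(abs(sum(tv$length_mm) - sqrt(sum((p1 - p0)^2))), 1e-9)
  }
  # zero-length segment: single voxel, zero length
  tv0 <- trace_segment_voxels(c(0, 0, 0), c(0, 0, 0), vol)
  expect_equal(nrow(tv0), 1L)
  expect_equal(tv0$length_mm, 0)
  # endpoints outside the grid are clipped with a warning
  expect_warning(tvc <- trace_segment_voxels(c(-40, 0, 0), c(0, 0, 0), vol),
                 "clipped")
  expect_lt(sum(tvc$length_mm), 40)
})

test_that("oblique traversal agrees with dense point sampling", {
  set.seed(22)
  aff <- diag(c(1.3, 1.3, 1.3, 1))
  aff[1:3, 4] <- c(-8, -8, -8)
  vol <- scalar_volume(array(1, c(12, 12, 12)), aff)
  for (rep in 1:30) {
    p0 <- runif(3, -6, 6)
    p1 <- runif(3, -6, 6)
    tv <- trace_segment_voxels(p0, p1, vol)
    or <- dense_trace_oracle(p0, p1, vol, n_points = 1e4)
    key_t <- paste(tv$i, tv$j, tv$k)
    key_o <- paste(or$i, or$j, or$k)
    lens <- merge(data.frame(key = key_t, a = tv$length_mm),
                  data.frame(key = key_o, b = or$length_mm),
                  by = "key", all = TRUE)
    lens[is.na(lens)] <- 0
    # each voxel boundary is located to within L / n_points by the oracle
    quant <- 2.5 * sqrt(sum((p1 - p0)^2)) / 1e4
    expect_lt(max(abs(lens$a - lens$b)), max(1e-3, quant))
  }
})

test_that("vertex pairing honours the ring constraint and its oracle", {
  spec <- phantom_spec(n_subdivisions = 2, inner_radius_mm = 20,
                       thickness_mm = 2, n_regions = 4)
  geom <- make_template_geometry(spec)
  # concentric spheres: radial segments of exactly the shell thickness
  pr0 <- pair_vertices(geom$surfaces, search_ring = 0)
  expect_equal(pr0$pial_index, geom$surfaces$correspondence)
  expect_true(all(abs(pr0$segments$length_mm - 2) < 1e-9))
  # perturbed pial sphere: chosen vertex is the 2-ring distance argmin
  pert <- perturb_pial_surface(geom$surfaces, sd_mm = 0.5, seed = 8)
  pr2 <- pair_vertices(pert, search_ring = 2)
  rings <- matrix_k_ring(pert$triangles, nrow(pert$white_vertices), 2)
  for (i in seq(1, nrow(pert$white_vertices), by = 7)) {
    cand <- rings[[pert$correspondence[i]]]
    d2 <- rowSums((pert$pial_vertices[cand, , drop = FALSE] -
                     matrix(pert$white_vertices[i, ], length(cand), 3,
                            byrow = TRUE))^2)
    expect_equal(min(d2),
                 sum((pert$pial_vertices[pr2$pial_index[i], ] -
                        pert$white_vertices[i, ])^2),
                 tolerance = 1e-12)
  }
})

test_that("length-weighted sampling averages exactly over GM voxels", {
  aff <- diag(4)
  r_vals <- array(NA_real_, c(4, 1, 1))
  r_vals[1:4, 1, 1] <- c(1, 2, 5, 7)
  r <- scalar_volume(r_vals, aff)
  gm <- label_volume(array(1L, c(4, 1, 1)), aff)
  # half in voxel 0 (R = 1), half in voxel 1 (R = 2)
  s <- sample_vertex_ratio(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5), r, gm)
  expect_false(s$missing)
  expect_equal(s$value, 1.5, tolerance = 1e-12)
  # segment through non-GM voxels only: missing
  gm0 <- label_volume(array(0L, c(4, 1, 1)), aff)
  s0 <- sample_vertex_ratio(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5), r, gm0)
  expect_true(s0$missing)
  # non-GM span renormalizes over the remaining length
  gm_mix <- label_volume(array(c(1L, 0L, 1L, 1L), c(4, 1, 1)), aff)
  sm <- sample_vertex_ratio(c(0.2, 0.5, 0.5), c(3.0, 0.5, 0.5), r, gm_mix)
  expect_equal(sm$value, (0.8 * 1 + 1 * 5) / 1.8, tolerance = 1e-12)
})

test_that("a uniform ratio field yields a constant vertex map", {
  spec <- phantom_spec(n_subdivisions = 2, inner_radius_mm = 20,
                       thickness_mm = 3, n_regions = 4,
                       voxel_size_mm = 1.5, grid_shape = c(36, 36, 36))
  geom <- make_template_geometry(spec)
  prof <- regional_profile(1:4, rep(1.25, 4), 0, 0)
  vols <- make_intensity_volumes(geom, geom$parcellation, prof, spec)
  rr <- mask_to_gm(compute_ratio_volume(vols$t1, vols$t2), vols$gm)
  vm <- sample_vertex_map(pair_vertices(geom$surfaces)$segments, rr, vols$gm)
  expect_false(any(vm$missing))
  expect_equal(vm$values, rep(1.25, length(vm$values)), tolerance = 1e-12)
})

test_that("sampled vertex values match the dense oracle on a varying field", {
  set.seed(33)
  aff <- diag(c(1.2, 1.2, 1.2, 1))
  aff[1:3, 4] <- c(-9, -9, -9)
  dims <- c(15, 15, 15)
  r <- scalar_volume(array(runif(prod(dims), 0.8, 1.6), dims), aff)
  lab <- array(1L, dims)
  lab[sample(prod(dims), 400)] <- 0L
  gm <- label_volume(lab, aff)
  for (rep in 1:25) {
    p0 <- runif(3, -7, 7)
    p1 <- runif(3, -7, 7)
    s <- sample_vertex_ratio(p0, p1, r, gm)
    o <- dense_value_oracle(p0, p1, r, gm, n_points = 1e4)
    if (is.na(o)) expect_true(s$missing)
    else expect_lt(abs(s$value - o) / abs(o), 1e-3)
  }
})

test_that("segment thickness and ICV normalization behave as stated", {
  spec <- phantom_spec(n_subdivisions = 1, inner_radius_mm = 30,
                       thickness_mm = 3, n_regions = 2)
  geom <- make_template_geometry(spec)
  seg <- pair_vertices(geom$surfaces)$segments
  expect_equal(segment_thickness(seg), rep(3, nrow(seg$white)),
               tolerance = 1e-9)
  expect_equal(normalize_by_icv(1500, 1.5e6), 1e-3, tolerance = 1e-15)
  expect_equal(normalize_by_icv(2 * 1500, 2 * 1.5e6), 1e-3,
               tolerance = 1e-15)
  expect_error(normalize_by_icv(1, 0), "positive")
  expect_error(normalize_by_icv(1, -2), "positive")
})

test_that("regional aggregation follows the subjects-then-vertices order", {
  spec <- phantom_spec(n_subdivisions = 1, n_regions = 3)
  geom <- make_template_geometry(spec)
  nv <- nrow(geom$surfaces$white_vertices)
  # constant maps: every region mean equals the constant
  mc <- matrix(1.1, nv, 3, dimnames = list(NULL, paste0("S", 1:3)))
  agg <- vertex_map_to_regions(mc, geom$parcellation, rep("HC", 3))
  expect_equal(agg$group_region$mean_r, rep(1.1, 3), tolerance = 1e-12)
  # two subjects c and 3c: means 2c under either averaging order
  m2 <- cbind(S1 = rep(0.7, nv), S2 = rep(2.1, nv))
  agg2 <- vertex_map_to_regions(m2, geom$parcellation, rep("HC", 2))
  expect_equal(agg2$group_region$mean_r, rep(1.4, 3), tolerance = 1e-12)
  # subject-specific missing vertices: equality with the nested-loop oracle
  set.seed(4)
  mm <- matrix(rnorm(nv * 5, 1.1, 0.1), nv, 5,
               dimnames = list(NULL, paste0("S", 1:5)))
  mm[sample(length(mm), round(0.2 * length(mm)))] <- NA
  groups <- c("HC", "HC", "mTBI", "mTBI", "mTBI")
  agg3 <- vertex_map_to_regions(mm, geom$parcellation, groups)
  oracle <- nested_loop_region_oracle(mm, geom$parcellation$region_id, groups)
  m <- merge(agg3$group_region, oracle, by = c("group", "region_id"))
  expect_equal(m$mean_r.x, m$mean_r.y, tolerance = 1e-12)
  # per-subject means agree with direct computation
  s3 <- agg3$subject_region
  v <- mm[geom$parcellation$region_id == 2, "S4"]
  expect_equal(s3$mean_r[s3$subject == "S4" & s3$region_id == 2],
               mean(v[!is.na(v)]), tolerance = 1e-12)
})

test_that("noiseless phantom recovery hits regional truth within 1%", {
  spec <- phantom_spec(n_subdivisions = 2, inner_radius_mm = 40,
                       thickness_mm = 3, n_regions = 8,
                       voxel_size_mm = 2, grid_shape = c(48, 48, 48))
  geom <- make_template_geometry(spec)
  prof <- default_regional_profile()
  vols <- make_intensity_volumes(geom, geom$parcellation, prof, spec)
  rr <- mask_to_gm(compute_ratio_volume(vols$t1, vols$t2), vols$gm)
  vm <- sample_vertex_map(pair_vertices(geom$surfaces)$segments, rr, vols$gm)
  agg <- vertex_map_to_regions(
    matrix(vm$values, ncol = 1, dimnames = list(NULL, "S1")),
    geom$parcellation, "HC")
  m <- merge(agg$group_region, prof, by = "region_id")
  expect_true(all(abs(m$mean_r / m$baseline_r - 1) < 0.01))
})
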