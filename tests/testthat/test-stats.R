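test_that("ISI deviations center on the grand mean across both groups", {
  expect_equal(isi_deviations(c(2, 4)), c(1, -1), tolerance = 1e-15)
  expect_equal(isi_deviations(rep(3.3, 5)), rep(0, 5), tolerance = 1e-15)
  expect_error(isi_deviations(numeric(0)), "empty")
  expect_error(isi_deviations(c(1, -2)), "positive")
  # grand-mean centering differs from group-wise centering
  isi <- c(rep(3.3, 4), rep(0.5, 6))
  dev <- isi_deviations(isi)
  expect_equal(dev, mean(isi) - isi, tolerance = 1e-15)
  groupwise <- c(rep(0, 4), rep(0, 6))
  expect_false(isTRUE(all.equal(dev, groupwise)))
  expect_equal(sum(dev), 0, tolerance = 1e-12)
})

test_that("confound adjustment removes age/sex effects and keeps the mean", {
  set.seed(6)
  age <- runif(30, 40, 90)
  sex <- rbinom(30, 1, 0.5)
  # pure age effect collapses to the grand mean
  v <- 2 + 0.01 * age
  adj <- adjust_for_confounds(v, age, sex)
  expect_equal(adj, rep(mean(v), 30), tolerance = 1e-10)
  # general case: orthogonality and mean preservation
  v2 <- 1.1 + 0.005 * age - 0.02 * sex + rnorm(30, 0, 0.05)
  adj2 <- adjust_for_confounds(v2, age, sex)
  expect_lt(abs(cor(adj2, age)), 1e-10)
  expect_lt(abs(cor(adj2, sex)), 1e-10)
  expect_equal(mean(adj2), mean(v2), tolerance = 1e-12)
  # values already orthogonal to the confounds are nearly untouched
  v3 <- rnorm(30)
  v3 <- v3 - stats::lm.fit(cbind(1, age, sex), v3)$fitted.values
  expect_equal(adjust_for_confounds(v3 + 5, age, sex), v3 + 5,
               tolerance = 1e-10)
  expect_error(adjust_for_confounds(v, age, rep(1, 30)), "rank")
})

test_that("fractional change and its linear rescaling are exact", {
  expect_equal(compute_delta_r(1.0, 0.8), -0.200, tolerance = 1e-15)
  expect_equal(compute_delta_r(1.3, 1.3), 0, tolerance = 1e-15)
  expect_equal(compute_delta_r(0.96, 0.96 * 0.737), -0.263, tolerance = 1e-12)
  expect_error(compute_delta_r(0, 1), "positive")
  expect_equal(rescale_delta_linear(-0.066, 3.3, 0.5), -0.01,
               tolerance = 1e-15)
  expect_equal(rescale_delta_linear(-0.2, 0.5, 0.5), -0.2, tolerance = 1e-15)
  expect_equal(rescale_delta_linear(0, 1.7, 0.5), 0, tolerance = 1e-15)
  expect_error(rescale_delta_linear(-0.1, 0, 0.5), "positive")
})

test_that("reference interpolation recovers the constant-rate decline", {
  cfg <- cohort_config(n_hc = 8, n_mtbi = 3,
                       isi_hc = list(mean = 3.3, sd = 0.6),
                       isi_mtbi = list(mean = 0.5, sd = 0),
                       subject_random_sd = 0, measurement_sd = 0, seed = 13)
  sim <- make_longitudinal_cohort(cfg, default_regional_profile(4))
  hc <- sim$cohort[sim$cohort$group == "HC", ]
  ref <- interpolate_reference_delta(hc, 0.5)
  expect_equal(ref$delta_r, rep(-0.02 * 0.5, 4), tolerance = 1e-12)
  # all ISIs equal to the target: reduces to the plain per-region mean
  cfg2 <- cohort_config(n_hc = 5, n_mtbi = 3,
                        isi_hc = list(mean = 0.5, sd = 0),
                        isi_mtbi = list(mean = 0.5, sd = 0),
                        subject_random_sd = 0.1, measurement_sd = 0.004,
                        seed = 14)
  sim2 <- make_longitudinal_cohort(cfg2, default_regional_profile(4))
  hc2 <- sim2$cohort[sim2$cohort$group == "HC", ]
  wide2 <- myelinmap:::pivot_visits(hc2)
  plain <- tapply(compute_delta_r(wide2$R_b, wide2$R_f), wide2$region_id,
                  mean)
  ref2 <- interpolate_reference_delta(hc2, 0.5)
  expect_equal(ref2$delta_r, as.numeric(plain), tolerance = 1e-12)
  # single subject: equals that subject's rescaled change
  one <- hc2[hc2$subject_id == hc2$subject_id[1], ]
  wide1 <- myelinmap:::pivot_visits(one)
  ref1 <- interpolate_reference_delta(one, 0.25)
  expect_equal(ref1$delta_r,
               rescale_delta_linear(compute_delta_r(wide1$R_b, wide1$R_f),
                                    wide1$isi_years, 0.25),
               tolerance = 1e-12)
  # a subject missing the follow-up visit is dropped with a warning
  broken <- hc2[!(hc2$subject_id == hc2$subject_id[1] &
                    hc2$visit == "followup"), ]
  expect_warning(interpolate_reference_delta(broken, 0.5), "dropped")
})

test_that("paired and Welch tests match the textbook formulas", {
  x <- c(1.2, 1.5, 1.1, 1.4, 1.3)
  y <- c(1.0, 1.4, 1.0, 1.1, 1.2)
  pt <- paired_t(x, y)
  d <- y - x
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(pt$statistic, t_hand, tolerance = 1e-12)
  expect_equal(pt$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # identical samples: degenerate, p = 1
  expect_equal(paired_t(x, x)$p_value, 1)
  wt <- welch_t(x, y)
  v1 <- var(x) / 5
  v2 <- var(y) / 5
  t_w <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df_w <- (v1 + v2)^2 / (v1^2 / 4 + v2^2 / 4)
  expect_equal(wt$statistic, t_w, tolerance = 1e-12)
  expect_equal(wt$df, df_w, tolerance = 1e-12)
  expect_equal(wt$p_value, 2 * pt(-abs(t_w), df_w), tolerance = 1e-12)
  expect_equal(welch_t(rep(1, 4), rep(1, 5))$p_value, 1)
})

test_that("Welch test keeps its size under unequal variances", {
  set.seed(99)
  n_rep <- 4000
  hits <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(12, 0, 1)
    b <- rnorm(30, 0, 3)
    if (welch_t(a, b)$p_value < 0.05) hits <- hits + 1L
  }
  rate <- hits / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.045 - 2 * se)
  expect_lt(rate, 0.055 + 2 * se)
})

test_that("family-wise correction follows the Holm step-down rule", {
  expect_equal(fwe_correct(0.03)$p_adjusted, 0.03)
  h <- fwe_correct(c(0.01, 0.04))
  expect_equal(h$p_adjusted, c(0.02, 0.04), tolerance = 1e-15)
  expect_true(all(h$reject))
  all1 <- fwe_correct(rep(1, 6))
  expect_false(any(all1$reject))
  # adjusted values are monotone and never below raw
  set.seed(2)
  p <- runif(20)
  adj <- fwe_correct(p)$p_adjusted
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  # bonferroni alternative
  expect_equal(fwe_correct(c(0.01, 0.04), method = "bonferroni")$p_adjusted,
               c(0.02, 0.08), tolerance = 1e-15)
})

test_that("group-standardized z profiles behave as an affine-free contrast", {
  set.seed(8)
  n <- 30
  regions <- rep(1:5, each = 2 * n)
  group <- rep(rep(c("HC", "mTBI"), each = n), 5)
  vals <- rnorm(length(group), 1.1, 0.05)
  z <- region_zscores(vals, group)
  for (g in c("HC", "mTBI")) {
    expect_equal(mean(z[group == g]), 0, tolerance = 1e-12)
    expect_equal(sd(z[group == g]), 1, tolerance = 1e-12)
  }
  # identical group distributions: delta_z is noise around zero;
  # exact zero when the groups carry identical values
  vals_eq <- rep(rnorm(n * 5, 1.1, 0.05), times = 2)
  group_eq <- rep(c("HC", "mTBI"), each = n * 5)
  region_eq <- rep(rep(1:5, each = n), 2)
  dz0 <- delta_z_map(vals_eq, group_eq, region_eq)
  expect_equal(dz0$delta_z, rep(0, 5), tolerance = 1e-12)
  # an injected deficit in one region of the mTBI group shows up negative
  vals_inj <- vals
  vals_inj[group == "mTBI" & regions == 3] <-
    vals_inj[group == "mTBI" & regions == 3] - 0.05
  dz <- delta_z_map(vals_inj, group, regions)
  expect_equal(which.min(dz$delta_z), 3L)
  expect_lt(dz$delta_z[3], 0)
  # invariance under affine rescaling of one group's values
  vals_aff <- vals_inj
  vals_aff[group == "mTBI"] <- 3.7 * vals_aff[group == "mTBI"] + 12
  dz_aff <- delta_z_map(vals_aff, group, regions)
  expect_equal(dz_aff$delta_z, dz$delta_z, tolerance = 1e-9)
  expect_error(region_zscores(rep(1, 10), rep("HC", 10)), "zero")
})

test_that("vulnerability applies the leave-one-out formula", {
  v <- vulnerability(c(-0.10, -0.20, -0.30))
  expect_equal(v$v[1], -0.60, tolerance = 1e-12)
  expect_equal(v$v[2], (-0.20 + 0.20) / -0.20, tolerance = 1e-12)
  expect_equal(v$v[3], (-0.30 + 0.15) / -0.15, tolerance = 1e-12)
  expect_equal(vulnerability(rep(-0.1, 6))$v, rep(0, 6), tolerance = 1e-12)
  expect_error(vulnerability(-0.1), "2 regions")
  und <- vulnerability(c(0.1, -0.1, 0.5))
  expect_true(und$undefined[3])
  expect_true(is.na(und$v[3]))
})

test_that("group difference maps subtract and antisymmetrize", {
  tbi <- data.frame(region_id = 1:3, delta_r = c(-0.20, -0.21, -0.15))
  hc <- data.frame(region_id = 1:3, delta_r = c(-0.01, -0.012, -0.011))
  d <- group_delta_difference(tbi, hc)
  expect_equal(d$diff, tbi$delta_r - hc$delta_r, tolerance = 1e-15)
  swap <- group_delta_difference(hc, tbi)
  expect_equal(swap$diff, -d$diff, tolerance = 1e-15)
  # identical groups: zero map
  expect_equal(group_delta_difference(hc, hc)$diff, rep(0, 3))
  # a region absent on one side is flagged
  d2 <- group_delta_difference(tbi[1:2, ], hc)
  expect_true(d2$missing_group[d2$region_id == 3])
})

test_that("age-overlap subsetting applies the strict range rule", {
  cohort <- data.frame(
    subject_id = c("h1", "h2", "t1", "t2"),
    group = c("HC", "HC", "mTBI", "mTBI"),
    age_years = c(60, 80, 40, 79))
  sub <- age_overlap_subset(cohort)
  expect_setequal(sub$subject_id, c("h1", "t2"))
  expect_equal(attr(sub, "n_hc"), 1L)
  expect_equal(attr(sub, "n_mtbi"), 1L)
  # fully overlapping ages: identity
  cohort2 <- data.frame(subject_id = c("h1", "h2", "t1", "t2"),
                        group = c("HC", "HC", "mTBI", "mTBI"),
                        age_years = c(50, 70, 55, 75))
  expect_equal(nrow(age_overlap_subset(cohort2)), 4L)
  # disjoint ranges empty a group
  cohort3 <- data.frame(subject_id = c("h1", "t1", "t2"),
                        group = c("HC", "mTBI", "mTBI"),
                        age_years = c(90, 20, 30))
  expect_error(age_overlap_subset(cohort3), "empties")
})

test_that("regional analysis is robust to confound injection", {
  prof <- default_regional_profile(4)
  base_cfg <- function(...) cohort_config(n_hc = 30, n_mtbi = 30, seed = 55,
                                          ...)
  st0 <- region_stats(make_longitudinal_cohort(base_cfg(), prof)$cohort,
                      target_isi_years = 0.5)
  # a pure age effect on R leaves the adjusted group difference unchanged
  st_age <- region_stats(
    make_longitudinal_cohort(base_cfg(age_effect_frac_per_year = 0.004),
                             prof)$cohort, target_isi_years = 0.5)
  expect_equal(st_age$diff, st0$diff, tolerance = 0.01)
  # a multiplicative scanner scale on the GE-scanned HCs cancels in delta R
  st_sc <- region_stats(
    make_longitudinal_cohort(base_cfg(scanner_scale = 1.25), prof)$cohort,
    target_isi_years = 0.5)
  expect_equal(st_sc$diff, st0$diff, tolerance = 2e-3)
  expect_identical(st_sc$significant, st0$significant)
  # internal identity: diff column is exactly the rescaled group difference
  expect_equal(st0$diff, st0$delta_r_tbi_rescaled - st0$delta_r_hc_rescaled,
               tolerance = 1e-15)
})
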