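#' Interscan-interval deviations from the grand mean
#'
#' Computes, for each subject, the deviation of the interscan interval (ISI)
#' from the grand mean ISI taken across *both* diagnostic groups. Grand-mean
#' (rather than group-mean) centering preserves the time-by-diagnosis
#' interaction while treating ISI variability identically across groups.
#'
#' @param isi_years positive per-subject ISIs (years).
#' @return Per-subject deviations `mean(isi) - isi` (years).
#' @export
isi_deviations <- function(isi_years) {
  if (length(isi_years) == 0L) stop("empty cohort: no ISIs supplied")
  if (any(!is.finite(isi_years)) || any(isi_years <= 0))
    stop("ISIs must be positive and finite")
  mean(isi_years) - isi_years
}

#' Regress age and sex out of a per-subject measure
#'
#' Fits ordinary least squares of the values on (intercept, age, sex) and
#' returns the residuals plus the original grand mean, so adjusted values are
#' uncorrelated with age and sex while keeping the raw mean. The interscan
#' interval is deliberately *not* among the confounds: its effect carries the
#' longitudinal signal of interest.
#'
#' @param values numeric per-subject measurements.
#' @param age,sex numeric covariates of the same length.
#' @return Adjusted values.
#' @export
adjust_for_confounds <- function(values, age, sex) {
  n <- length(values)
  if (length(age) != n || length(sex) != n)
    stop("`values`, `age` and `sex` must have equal length")
  x <- cbind(1, age, sex)
  p <- qr(x)$rank
  if (n <= ncol(x))
    stop("too few observations to adjust for the confounds")
  if (p < ncol(x))
    stop("rank-deficient confound matrix (age or sex constant?)")
  fit <- stats::lm.fit(x, values)
  fit$residuals + mean(values)
}

#' Fractional change in R between baseline and follow-up
#'
#' @param r_baseline,r_followup positive baseline and follow-up values.
#' @return `(r_followup - r_baseline) / r_baseline` (a fraction; -0.20 means
#'   a 20% loss).
#' @export
compute_delta_r <- function(r_baseline, r_followup) {
  if (any(!is.finite(r_baseline)) || any(r_baseline <= 0))
    stop("baseline values must be positive")
  (r_followup - r_baseline) / r_baseline
}

#' Rescale a fractional change to a target interval
#'
#' Assumes a constant rate of change, so the fractional change scales
#' linearly with the interval length.
#'
#' @param delta_r fractional change observed over `isi_years`.
#' @param isi_years observed interval (years), > 0.
#' @param target_isi_years target interval (years), > 0.
#' @return Fractional change expected over the target interval.
#' @export
rescale_delta_linear <- function(delta_r, isi_years, target_isi_years) {
  if (any(isi_years <= 0) || any(target_isi_years <= 0))
    stop("intervals must be positive")
  delta_r * target_isi_years / isi_years
}

#' Expected per-region HC change interpolated to a target interval
#'
#' From the two repeated measures of each healthy-control subject, computes
#' the subject's fractional change, rescales it linearly to the target
#' interval, and averages per region. Subjects missing a visit are dropped
#' with a warning.
#'
#' @param hc_table long-format cohort rows (typically the HC subset) with
#'   columns `subject_id`, `visit`, `isi_years`, `region_id`, `R`.
#' @param target_isi_years target interval (years).
#' @return Data frame with `region_id` and `delta_r` (expected fractional
#'   change over the target interval).
#' @export
interpolate_reference_delta <- function(hc_table, target_isi_years) {
  wide <- pivot_visits(hc_table)
  n_before <- length(unique(hc_table$subject_id))
  n_after <- length(unique(wide$subject_id))
  if (n_after < n_before)
    warning(sprintf("%d subject(s) dropped: missing a visit",
                    n_before - n_after))
  if (n_after == 0L) stop("no subject has both visits")
  d <- compute_delta_r(wide$R_b, wide$R_f)
  d <- rescale_delta_linear(d, wide$isi_years, target_isi_years)
  agg <- stats::aggregate(d, by = list(region_id = wide$region_id), FUN = mean)
  data.frame(region_id = agg$region_id, delta_r = agg$x)
}

# Long cohort rows -> one row per subject x region with R_b and R_f.
pivot_visits <- function(tab) {
  b <- tab[tab$visit == "baseline", ]
  f <- tab[tab$visit == "followup", ]
  key_b <- paste(b$subject_id, b$region_id)
  key_f <- paste(f$subject_id, f$region_id)
  common <- intersect(key_b, key_f)
  b <- b[match(common, key_b), ]
  f <- f[match(common, key_f), ]
  out <- b[, setdiff(names(b), c("visit", "R"))]
  out$R_b <- b$R
  out$R_f <- f$R
  rownames(out) <- NULL
  out
}

#' Paired-sample t test
#'
#' Two-sided paired t test of no mean difference between baseline and
#' follow-up. When both samples are identical (zero-variance differences
#' with zero mean) the test is degenerate and `p = 1` by convention.
#'
#' @param baseline,followup paired numeric samples, n >= 3.
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t <- function(baseline, followup) {
  n <- length(baseline)
  if (length(followup) != n) stop("samples must be paired (equal length)")
  if (n < 3L) stop("paired t test needs n >= 3")
  d <- followup - baseline
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(statistic = 0, df = n - 1, p_value = 1, mean_diff = 0))
    return(list(statistic = sign(mean(d)) * Inf, df = n - 1, p_value = 0,
                mean_diff = mean(d)))
  }
  ht <- stats::t.test(followup, baseline, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Welch's two-sided t test
#'
#' Heteroskedastic two-sample comparison with Satterthwaite degrees of
#' freedom. If both samples have zero variance and equal means, `p = 1` by
#' convention.
#'
#' @param x,y numeric samples, n >= 3 each.
#' @return List with `statistic`, `df`, `p_value`, `mean_diff` (mean(x) -
#'   mean(y)).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) stop("Welch test needs n >= 3 per sample")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    md <- mean(x) - mean(y)
    if (md == 0)
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1, mean_diff = 0))
    return(list(statistic = sign(md) * Inf, df = length(x) + length(y) - 2,
                p_value = 0, mean_diff = md))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(diff(rev(ht$estimate))))
}

#' Family-wise error correction across regions
#'
#' Step-down Holm adjustment by default (uniformly more powerful than
#' Bonferroni with the same family-wise guarantee); plain Bonferroni is
#' available as an alternative.
#'
#' @param p raw p values in `[0, 1]`.
#' @param alpha family-wise significance level.
#' @param method `"holm"` or `"bonferroni"`.
#' @return List with `p_adjusted` and logical `reject`.
#' @export
fwe_correct <- function(p, alpha = 0.05, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = method)
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Group-standardized z-scores of regional values
#'
#' Standardizes each observation against the pooled mean and standard
#' deviation of *its own group's* values (over all subjects and regions), so
#' the distribution parameters of the two groups are never assumed shared
#' and any affine intensity rescaling of one group cancels. Within a group
#' the z values pool to mean 0, sd 1.
#'
#' @param values numeric regional values (one per subject x region).
#' @param group group label per value.
#' @return Numeric z-scores.
#' @export
region_zscores <- function(values, group) {
  if (length(values) != length(group)) stop("`values` and `group` lengths differ")
  z <- rep(NA_real_, length(values))
  for (g in unique(group)) {
    sel <- group == g
    s <- stats::sd(values[sel])
    if (!is.finite(s) || s == 0)
      stop(sprintf("zero within-group variance in group '%s'", g))
    z[sel] <- (values[sel] - mean(values[sel])) / s
  }
  z
}

#' Between-group difference in standardized regional profiles
#'
#' Computes group-standardized z-scores via [region_zscores()] and, per
#' region, the difference between the group-mean z of the mTBI-labelled and
#' control-labelled groups. Negative values flag regions whose standing in
#' the mTBI group's distribution is lower than the region's standing among
#' controls.
#'
#' @param values regional values, one per subject x region.
#' @param group group label per value; `tbi_group` identifies the group whose
#'   z enters with positive sign.
#' @param region_id region label per value.
#' @param tbi_group,hc_group group labels to contrast.
#' @return Data frame with `region_id` and `delta_z`.
#' @export
delta_z_map <- function(values, group, region_id,
                        tbi_group = "mTBI", hc_group = "HC") {
  z <- region_zscores(values, group)
  zt <- stats::aggregate(z[group == tbi_group],
                         by = list(region_id = region_id[group == tbi_group]),
                         FUN = mean)
  zh <- stats::aggregate(z[group == hc_group],
                         by = list(region_id = region_id[group == hc_group]),
                         FUN = mean)
  m <- merge(zt, zh, by = "region_id", suffixes = c("_tbi", "_hc"))
  data.frame(region_id = m$region_id, delta_z = m$x_tbi - m$x_hc)
}

#' Regional vulnerability relative to the rest of the cortex
#'
#' Leave-one-out score `v_r = (d_r - mean(d_others)) / mean(d_others)` on
#' mean regional fractional changes `d`. With losses (negative `d`), a
#' positive `v` means the region experiences `v x 100%` more demyelination
#' than the rest of the cortex. Regions whose leave-one-out mean is zero are
#' flagged undefined (`NA`).
#'
#' @param delta_r mean fractional change per region (>= 2 regions).
#' @param region_id optional region identifiers.
#' @return Data frame with `region_id`, `v` and logical `undefined`.
#' @export
vulnerability <- function(delta_r, region_id = seq_along(delta_r)) {
  n <- length(delta_r)
  if (n < 2L) stop("vulnerability needs at least 2 regions")
  loo <- (sum(delta_r) - delta_r) / (n - 1)
  undef <- loo == 0
  v <- ifelse(undef, NA_real_, (delta_r - loo) / loo)
  data.frame(region_id = region_id, v = v, undefined = undef)
}

#' Between-group difference of regional changes
#'
#' Elementwise `delta_r` difference (mTBI minus reference) over regions;
#' regions absent from either side are flagged with `NA`.
#'
#' @param tbi data frame with `region_id`, `delta_r` for the mTBI group.
#' @param hc data frame with `region_id`, `delta_r` for the reference group
#'   (typically interpolated to the mTBI mean ISI).
#' @return Data frame with `region_id`, `diff` and logical `missing_group`.
#' @export
group_delta_difference <- function(tbi, hc) {
  m <- merge(tbi, hc, by = "region_id", all = TRUE,
             suffixes = c("_tbi", "_hc"))
  data.frame(region_id = m$region_id,
             diff = m$delta_r_tbi - m$delta_r_hc,
             missing_group = is.na(m$delta_r_tbi) | is.na(m$delta_r_hc))
}

#' Restrict a cohort to the age-overlap subgroups
#'
#' Keeps healthy controls younger than the oldest mTBI subject and mTBI
#' subjects older than the youngest control, producing subgroups with
#' identical age ranges for the age sensitivity analysis.
#'
#' @param cohort long-format cohort table with `subject_id`, `group`,
#'   `age_years`.
#' @return The restricted cohort, with attributes `n_hc` and `n_mtbi` giving
#'   the retained subject counts.
#' @export
age_overlap_subset <- function(cohort) {
  hc <- cohort$group == "HC"
  tbi <- cohort$group == "mTBI"
  if (!any(hc) || !any(tbi)) stop("both groups must be present")
  max_tbi <- max(cohort$age_years[tbi])
  min_hc <- min(cohort$age_years[hc])
  keep <- (hc & cohort$age_years < max_tbi) |
    (tbi & cohort$age_years > min_hc)
  out <- cohort[keep, , drop = FALSE]
  if (!any(out$group == "HC") || !any(out$group == "mTBI"))
    stop("age-overlap subset empties a group")
  rownames(out) <- NULL
  attr(out, "n_hc") <- length(unique(out$subject_id[out$group == "HC"]))
  attr(out, "n_mtbi") <- length(unique(out$subject_id[out$group == "mTBI"]))
  out
}

#' Full regional longitudinal analysis
#'
#' Runs the within-subject change analysis for every region: age/sex
#' adjustment of baseline and follow-up R (per diagnostic group), fractional
#' change per subject, linear rescaling to a common target interval
#' (defaulting to the mTBI group's mean ISI), Welch's test of the group
#' difference in rescaled change with family-wise correction, paired t tests
#' within group, leave-one-out vulnerability per group, and the baseline
#' z-score difference map.
#'
#' @param cohort long-format cohort table (see
#'   [make_longitudinal_cohort()]).
#' @param target_isi_years interval to which changes are rescaled; default is
#'   the mTBI group's mean ISI.
#' @param alpha significance level.
#' @param correction `"holm"` or `"bonferroni"`.
#' @return A data frame of class `"region_stats"`, one row per region, with
#'   native and rescaled group mean changes, their difference, vulnerability
#'   per group, `delta_z`, and raw/adjusted p values. Attributes record
#'   `alpha`, `correction`, `target_isi_years` and subject counts.
#' @export
region_stats <- function(cohort, target_isi_years = NULL, alpha = 0.05,
                         correction = c("holm", "bonferroni")) {
  correction <- match.arg(correction)
  need <- c("subject_id", "group", "sex", "age_years", "visit",
            "isi_years", "region_id", "R")
  if (!all(need %in% names(cohort)))
    stop("cohort table lacks required columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "))
  if (is.null(target_isi_years)) {
    tbi_first <- !duplicated(cohort$subject_id) & cohort$group == "mTBI"
    if (!any(tbi_first)) stop("no mTBI subjects to define the target ISI")
    target_isi_years <- mean(cohort$isi_years[tbi_first])
  }
  wide <- pivot_visits(cohort)
  regions <- sort(unique(wide$region_id))
  rn <- if ("region_name" %in% names(wide))
    wide$region_name[match(regions, wide$region_id)] else as.character(regions)

  adj_b <- rep(NA_real_, nrow(wide))
  adj_f <- rep(NA_real_, nrow(wide))
  for (g in unique(wide$group)) {
    for (r in regions) {
      sel <- wide$group == g & wide$region_id == r
      adj_b[sel] <- adjust_for_confounds(wide$R_b[sel], wide$age_years[sel],
                                         wide$sex[sel])
      adj_f[sel] <- adjust_for_confounds(wide$R_f[sel], wide$age_years[sel],
                                         wide$sex[sel])
    }
  }
  wide$delta_r <- compute_delta_r(adj_b, adj_f)
  wide$delta_r_rescaled <- rescale_delta_linear(wide$delta_r, wide$isi_years,
                                                target_isi_years)

  mean_by <- function(v, sel) {
    vapply(regions,
           function(r) mean(v[sel & wide$region_id == r]), numeric(1))
  }
  is_hc <- wide$group == "HC"
  is_tbi <- wide$group == "mTBI"
  if (!any(is_hc) || !any(is_tbi))
    stop("both diagnostic groups are required")
  d_hc <- mean_by(wide$delta_r, is_hc)
  d_tbi <- mean_by(wide$delta_r, is_tbi)
  d_hc_resc <- mean_by(wide$delta_r_rescaled, is_hc)
  d_tbi_resc <- mean_by(wide$delta_r_rescaled, is_tbi)

  p_welch <- numeric(length(regions))
  p_paired_hc <- numeric(length(regions))
  p_paired_tbi <- numeric(length(regions))
  for (ix in seq_along(regions)) {
    r <- regions[ix]
    sel <- wide$region_id == r
    p_welch[ix] <- welch_t(wide$delta_r_rescaled[sel & is_tbi],
                           wide$delta_r_rescaled[sel & is_hc])$p_value
    p_paired_hc[ix] <- paired_t(adj_b[sel & is_hc], adj_f[sel & is_hc])$p_value
    p_paired_tbi[ix] <- paired_t(adj_b[sel & is_tbi], adj_f[sel & is_tbi])$p_value
  }
  fw <- fwe_correct(p_welch, alpha, correction)

  v_hc <- vulnerability(d_hc_resc, regions)$v
  v_tbi <- vulnerability(d_tbi_resc, regions)$v
  dz <- delta_z_map(adj_b, wide$group, wide$region_id)
  dz <- dz$delta_z[match(regions, dz$region_id)]

  out <- data.frame(
    region_id = regions, region_name = rn,
    n_hc = vapply(regions, function(r) sum(is_hc & wide$region_id == r),
                  numeric(1)),
    n_tbi = vapply(regions, function(r) sum(is_tbi & wide$region_id == r),
                   numeric(1)),
    delta_r_hc = d_hc, delta_r_tbi = d_tbi,
    delta_r_hc_rescaled = d_hc_resc, delta_r_tbi_rescaled = d_tbi_resc,
    diff = d_tbi_resc - d_hc_resc,
    v_hc = v_hc, v_tbi = v_tbi, delta_z = dz,
    p_raw = p_welch, p_adjusted = fw$p_adjusted, significant = fw$reject,
    p_paired_hc = p_paired_hc, p_paired_tbi = p_paired_tbi)
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  attr(out, "target_isi_years") <- target_isi_years
  attr(out, "n_subjects_hc") <- length(unique(wide$subject_id[is_hc]))
  attr(out, "n_subjects_tbi") <- length(unique(wide$subject_id[is_tbi]))
  class(out) <- c("region_stats", "data.frame")
  out
}
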