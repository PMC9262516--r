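#' Regional baseline-ratio and decline profile
#'
#' Ground-truth trajectory parameters per cortical region: the baseline
#' T1w/T2w ratio and the group-specific fractional decline per year (a
#' decline of 0.02 means the region loses 2% of its baseline ratio per year).
#'
#' @param region_id integer region identifiers.
#' @param baseline_r positive baseline ratio per region.
#' @param decline_hc,decline_mtbi fractional decline per year for the healthy
#'   control and mTBI groups.
#' @param region_name optional region names.
#' @return A data frame of class `"regional_profile"`.
#' @export
regional_profile <- function(region_id, baseline_r, decline_hc, decline_mtbi,
                             region_name = NULL) {
  n <- length(region_id)
  if (any(baseline_r <= 0)) stop("`baseline_r` must be positive")
  if (is.null(region_name)) region_name <- sprintf("region_%02d", region_id)
  decline_hc <- rep_len(decline_hc, n)
  decline_mtbi <- rep_len(decline_mtbi, n)
  out <- data.frame(region_id = as.integer(region_id),
                    region_name = region_name,
                    baseline_r = baseline_r,
                    decline_hc = decline_hc,
                    decline_mtbi = decline_mtbi)
  class(out) <- c("regional_profile", "data.frame")
  out
}

#' Default regional profile
#'
#' For 8 regions, baseline ratios are anchored to printed healthy-control
#' regional values spanning the physiological range (inferior occipital 1.25
#' down to temporal pole 0.96). Declines default to the study conditions:
#' healthy controls lose 2% of baseline per year; the mTBI group loses 20%
#' per half-year (0.40/yr), except the occipital pole, which is injected at
#' 22% below the rest (0.312/yr) as the designated low-vulnerability region.
#' For other region counts, baselines interpolate linearly over the same
#' range and declines are uniform.
#'
#' @param n_regions number of regions.
#' @return A [regional_profile()].
#' @export
default_regional_profile <- function(n_regions = 8L) {
  if (n_regions == 8L) {
    regional_profile(
      region_id = 1:8,
      baseline_r = c(1.25, 1.23, 1.21, 1.19, 1.18, 1.16, 1.08, 0.96),
      decline_hc = 0.02,
      decline_mtbi = c(0.40, 0.40, 0.312, 0.40, 0.40, 0.40, 0.40, 0.40),
      region_name = c("inferior_occipital", "anterior_transverse_temporal",
                      "occipital_pole", "transverse_frontopolar",
                      "subcentral", "precentral",
                      "posterior_dorsal_cingulate", "temporal_pole"))
  } else {
    regional_profile(
      region_id = seq_len(n_regions),
      baseline_r = seq(1.25, 0.96, length.out = n_regions),
      decline_hc = 0.02, decline_mtbi = 0.40)
  }
}

#' Configuration of a synthetic two-group longitudinal cohort
#'
#' Defaults emulate the study conditions: 80 healthy controls (HC) and 97
#' mTBI subjects; HC ages 60-90 y (mean 75.4), mTBI ages 19-79 y (mean
#' 43.1); male fractions 0.53 and 0.63; mean interscan intervals (ISI) 3.3 y
#' (HC) and 0.5 y (mTBI); 70 of the HCs scanned on a GE scanner and the
#' remainder, plus all mTBI subjects, on Siemens (scanner coded 0 = Siemens,
#' 1 = GE). `subject_random_sd` is the fractional spread of the
#' subject-specific decline rate; `measurement_sd` the additive observation
#' noise on regional R. Optional age/sex/scanner effects on R support
#' confound-robustness experiments and default to none.
#'
#' @param n_hc,n_mtbi subjects per group.
#' @param age_hc,age_mtbi lists with `mean`, `sd`, `min`, `max` (years).
#' @param male_fraction named vector of male fractions (`hc`, `mtbi`).
#' @param isi_hc,isi_mtbi lists with `mean`, `sd` (years); draws truncated
#'   strictly positive.
#' @param n_hc_ge number of HCs assigned to the GE scanner.
#' @param subject_random_sd sd of the per-subject decline-rate multiplier
#'   around 1.
#' @param measurement_sd additive per-region, per-visit noise sd on R.
#' @param region_noise_cor within-subject correlation of regional noise at a
#'   visit (shared-component model), in `[0, 1)`.
#' @param age_effect_frac_per_year fractional change in R per year of age
#'   (applied multiplicatively to both visits).
#' @param sex_effect_frac fractional change in R for males.
#' @param scanner_scale multiplicative intensity-scale factor applied to R
#'   for scanner code 1 (GE).
#' @param seed integer RNG seed; identical seed and configuration give a
#'   byte-identical cohort.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_hc = 80L, n_mtbi = 97L,
                          age_hc = list(mean = 75.4, sd = 7, min = 60, max = 90),
                          age_mtbi = list(mean = 43.1, sd = 15, min = 19, max = 79),
                          male_fraction = c(hc = 0.53, mtbi = 0.63),
                          isi_hc = list(mean = 3.3, sd = 0.8),
                          isi_mtbi = list(mean = 0.5, sd = 0.1),
                          n_hc_ge = round(n_hc * 70 / 80),
                          subject_random_sd = 0.13,
                          measurement_sd = 0.005,
                          region_noise_cor = 0,
                          age_effect_frac_per_year = 0,
                          sex_effect_frac = 0,
                          scanner_scale = 1,
                          seed = 1L) {
  if (n_hc < 1L || n_mtbi < 1L) stop("both groups need at least one subject")
  if (subject_random_sd < 0 || measurement_sd < 0)
    stop("standard deviations must be >= 0")
  if (isi_hc$sd < 0 || isi_mtbi$sd < 0 || isi_hc$mean <= 0 || isi_mtbi$mean <= 0)
    stop("ISI means must be positive and sds >= 0")
  if (any(male_fraction < 0 | male_fraction > 1))
    stop("`male_fraction` must lie in [0, 1]")
  if (region_noise_cor < 0 || region_noise_cor >= 1)
    stop("`region_noise_cor` must lie in [0, 1)")
  if (n_hc_ge < 0L || n_hc_ge > n_hc) stop("`n_hc_ge` must lie in [0, n_hc]")
  if (scanner_scale <= 0) stop("`scanner_scale` must be positive")
  structure(list(n_hc = as.integer(n_hc), n_mtbi = as.integer(n_mtbi),
                 age_hc = age_hc, age_mtbi = age_mtbi,
                 male_fraction = male_fraction,
                 isi_hc = isi_hc, isi_mtbi = isi_mtbi,
                 n_hc_ge = as.integer(n_hc_ge),
                 subject_random_sd = subject_random_sd,
                 measurement_sd = measurement_sd,
                 region_noise_cor = region_noise_cor,
                 age_effect_frac_per_year = age_effect_frac_per_year,
                 sex_effect_frac = sex_effect_frac,
                 scanner_scale = scanner_scale,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic two-group longitudinal cohort
#'
#' Each subject receives two visits. True follow-up regional R is
#' `baseline * (1 - rate * mult * ISI)`, where `rate` is the group- and
#' region-specific fractional decline per year and `mult` the subject's
#' decline-rate multiplier; additive measurement noise is applied to the
#' observed R of both visits. Ground-truth trajectories are returned
#' alongside for recovery testing. With `fidelity = "image"`, per-visit
#' phantom intensity volumes are generated instead of (in addition to the
#' covariates of) the region table, for a reduced number of subjects.
#'
#' @param config a [cohort_config()].
#' @param profile a [regional_profile()].
#' @param fidelity `"region"` (fast, region-table) or `"image"` (full
#'   phantom volumes per subject and visit).
#' @param spec a [phantom_spec()], required for image fidelity.
#' @param n_image_subjects subjects per group for image fidelity.
#' @param image_noise_sd multiplicative intensity noise for image fidelity.
#' @return For region fidelity, a list with `cohort` (long-format data frame
#'   with columns `subject_id`, `group`, `sex`, `age_years`, `scanner`,
#'   `visit`, `isi_years`, `region_id`, `region_name`, `R`) and `truth`
#'   (per-subject parameters, profile, config). For image fidelity, the
#'   geometry, parcellation, per-subject per-visit volume sets and `truth`.
#' @export
make_longitudinal_cohort <- function(config, profile = default_regional_profile(),
                                     fidelity = c("region", "image"),
                                     spec = NULL, n_image_subjects = 2L,
                                     image_noise_sd = 0) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(profile, "regional_profile"))
  fidelity <- match.arg(fidelity)
  set.seed(config$seed)

  draw_group <- function(group, n, age, isi, male_frac, id0) {
    data.frame(
      subject_id = sprintf("%s_%03d", group, id0 + seq_len(n)),
      group = group,
      age_years = rtruncnorm1(n, age$mean, age$sd, age$min, age$max),
      sex = stats::rbinom(n, 1L, male_frac),
      isi_years = rtruncnorm1(n, isi$mean, isi$sd, lo = 0.01),
      mult = 1 + stats::rnorm(n, 0, config$subject_random_sd))
  }
  hc <- draw_group("HC", config$n_hc, config$age_hc, config$isi_hc,
                   config$male_fraction[["hc"]], 0L)
  hc$scanner <- 0L
  if (config$n_hc_ge > 0L)
    hc$scanner[sample.int(config$n_hc, config$n_hc_ge)] <- 1L
  tbi <- draw_group("mTBI", config$n_mtbi, config$age_mtbi, config$isi_mtbi,
                    config$male_fraction[["mtbi"]], 0L)
  tbi$scanner <- 0L
  subjects <- rbind(hc, tbi)

  if (fidelity == "image") {
    if (is.null(spec)) stop("image fidelity requires a `phantom_spec`")
    keep <- c(seq_len(min(n_image_subjects, config$n_hc)),
              config$n_hc + seq_len(min(n_image_subjects, config$n_mtbi)))
    subjects <- subjects[keep, , drop = FALSE]
    geom <- make_template_geometry(spec)
    out_subj <- vector("list", nrow(subjects))
    for (s in seq_len(nrow(subjects))) {
      rate <- if (subjects$group[s] == "HC") profile$decline_hc else profile$decline_mtbi
      fup <- profile
      fup$baseline_r <- profile$baseline_r *
        (1 - rate * subjects$mult[s] * subjects$isi_years[s])
      if (any(fup$baseline_r <= 0))
        stop("decline configuration drives R non-positive")
      out_subj[[s]] <- list(
        subject_id = subjects$subject_id[s],
        baseline = make_intensity_volumes(geom, geom$parcellation, profile,
                                          spec, image_noise_sd,
                                          seed = config$seed + 7L * s),
        followup = make_intensity_volumes(geom, geom$parcellation, fup,
                                          spec, image_noise_sd,
                                          seed = config$seed + 7L * s + 3L))
    }
    return(list(geometry = geom$surfaces, parcellation = geom$parcellation,
                subjects = out_subj,
                truth = list(subjects = subjects, profile = profile,
                             config = config)))
  }

  nreg <- nrow(profile)
  nsub <- nrow(subjects)
  rows <- vector("list", nsub)
  for (s in seq_len(nsub)) {
    sub <- subjects[s, ]
    rate <- if (sub$group == "HC") profile$decline_hc else profile$decline_mtbi
    # age/sex act on the biological signal; the scanner factor is an
    # instrumental intensity scale applied to the measured value below
    bio_scale <- (1 + config$age_effect_frac_per_year * (sub$age_years - 60)) *
      (1 + config$sex_effect_frac * sub$sex)
    scan_scale <- config$scanner_scale^sub$scanner
    true_b <- profile$baseline_r * bio_scale
    true_f <- true_b * (1 - rate * sub$mult * sub$isi_years)
    if (any(true_f <= 0))
      stop("decline configuration drives R non-positive")
    noise_visit <- function() {
      if (config$region_noise_cor > 0) {
        shared <- stats::rnorm(1)
        config$measurement_sd * (sqrt(config$region_noise_cor) * shared +
                                   sqrt(1 - config$region_noise_cor) *
                                     stats::rnorm(nreg))
      } else {
        stats::rnorm(nreg, 0, config$measurement_sd)
      }
    }
    obs_b <- (true_b + noise_visit()) * scan_scale
    obs_f <- (true_f + noise_visit()) * scan_scale
    rows[[s]] <- data.frame(
      subject_id = sub$subject_id, group = sub$group, sex = sub$sex,
      age_years = sub$age_years, scanner = sub$scanner,
      visit = rep(c("baseline", "followup"), each = nreg),
      isi_years = sub$isi_years,
      region_id = rep(profile$region_id, 2L),
      region_name = rep(profile$region_name, 2L),
      R = c(obs_b, obs_f))
  }
  cohort <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(cohort = cohort,
       truth = list(subjects = subjects, profile = profile, config = config))
}

#' Synthetic cognitive scores coupled to cortical mean R
#'
#' Six test scores (EVMI, EVMD, WMS, VF, IR, PS) per subject and visit,
#' generated as a linear function of the subject's cortex-mean R plus
#' Gaussian noise. Per-visit score means and scales default to the observed
#' mTBI cohort values; the same baseline values are emitted as
#' self-consistent reference norms for z-scoring.
#'
#' @param cohort long-format cohort table (see
#'   [make_longitudinal_cohort()]).
#' @param coupling slope of each score on mean R, in units of the test's
#'   per-visit sd per unit R spread (0 = no association).
#' @param noise_sd residual noise, as a fraction of the test's per-visit sd.
#' @param reference optional data frame of norms (`test`, `mu`, `sigma`);
#'   defaults to the baseline score scales.
#' @param seed integer RNG seed.
#' @return A list with `scores` (wide data frame: `subject_id`, `group`,
#'   `visit`, one column per test) and `norms`.
#' @export
make_cognition_scores <- function(cohort, coupling = 0, noise_sd = 1,
                                  reference = NULL, seed = 1L) {
  scales <- data.frame(
    test = rep(c("EVMI", "EVMD", "WMS", "VF", "IR", "PS"), 2L),
    visit = rep(c("baseline", "followup"), each = 6L),
    mu = c(3.46, 2.24, 3.69, 12.41, 1.40, 27.20,
           5.06, 2.83, 4.52, 16.72, 2.10, 32.63),
    sigma = c(2.82, 2.26, 1.57, 6.99, 1.24, 13.95,
              2.67, 2.45, 1.61, 7.95, 1.50, 14.85))
  set.seed(seed)
  mean_r <- stats::aggregate(R ~ subject_id + group + visit, data = cohort,
                             FUN = mean)
  names(mean_r)[names(mean_r) == "R"] <- "mean_r"
  out <- mean_r[order(mean_r$visit, mean_r$subject_id), , drop = FALSE]
  for (tn in unique(scales$test)) out[[tn]] <- NA_real_
  for (vis in c("baseline", "followup")) {
    sel <- out$visit == vis
    r <- out$mean_r[sel]
    rs <- if (stats::sd(r) > 0) (r - mean(r)) / stats::sd(r) else r * 0
    for (tn in unique(scales$test)) {
      sc <- scales[scales$test == tn & scales$visit == vis, ]
      out[[tn]][sel] <- sc$mu + coupling * sc$sigma * rs +
        stats::rnorm(sum(sel), 0, noise_sd * sc$sigma)
    }
  }
  if (is.null(reference))
    reference <- data.frame(test = scales$test[scales$visit == "baseline"],
                            mu = scales$mu[scales$visit == "baseline"],
                            sigma = scales$sigma[scales$visit == "baseline"])
  rownames(out) <- NULL
  list(scores = out[, c("subject_id", "group", "visit", "mean_r",
                        unique(scales$test))],
       norms = reference)
}
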