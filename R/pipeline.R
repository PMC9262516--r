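#' Configuration for a full pipeline run
#'
#' Bundles every tunable of the end-to-end analysis: the cohort and regional
#' ground-truth configuration, the statistical options, the vertex-pairing
#' mode and, for image fidelity, the phantom geometry. All randomness is
#' funnelled through `seed`.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed.
#' @param fidelity `"region"` (fast region tables) or `"image"` (phantom
#'   volumes, surface sampling and all).
#' @param alpha family-wise significance level.
#' @param correction `"holm"` or `"bonferroni"`.
#' @param target_isi_years interval for rescaled changes (`NULL`: mTBI mean
#'   ISI).
#' @param search_ring vertex-pairing neighbourhood depth (0 = index
#'   correspondence).
#' @param age_powers highest age power in the mixed-model fixed effects.
#' @param cohort a [cohort_config()]; its seed is overridden by `seed`.
#' @param profile a [regional_profile()].
#' @param cognition list with `coupling` and `noise_sd` for
#'   [make_cognition_scores()].
#' @param phantom a [phantom_spec()] (image fidelity only).
#' @param n_image_subjects subjects per group for image fidelity.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(out_dir, seed = 1L, fidelity = c("region", "image"),
                       alpha = 0.05, correction = "holm",
                       target_isi_years = NULL, search_ring = 0L,
                       age_powers = 1L,
                       cohort = cohort_config(seed = seed),
                       profile = default_regional_profile(),
                       cognition = list(coupling = 0, noise_sd = 1),
                       phantom = phantom_spec(),
                       n_image_subjects = 2L) {
  fidelity <- match.arg(fidelity)
  if (missing(out_dir) || !is.character(out_dir) || !nzchar(out_dir))
    stop("`out_dir` is required")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (!correction %in% c("holm", "bonferroni"))
    stop("`correction` must be 'holm' or 'bonferroni'")
  if (search_ring < 0L) stop("`search_ring` must be >= 0")
  if (!age_powers %in% 1:4) stop("`age_powers` must be 1-4")
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 fidelity = fidelity, alpha = alpha, correction = correction,
                 target_isi_years = target_isi_years,
                 search_ring = as.integer(search_ring),
                 age_powers = as.integer(age_powers),
                 cohort = cohort, profile = profile, cognition = cognition,
                 phantom = phantom,
                 n_image_subjects = as.integer(n_image_subjects)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or, in image fidelity, renders and then samples) the cohort,
#' runs the regional longitudinal analysis, fits the full and
#' diagnosis-free mixed models with their likelihood-ratio comparison,
#' generates and correlates cognitive scores, and writes every product to
#' `out_dir`: `cohort.csv`, `region_statistics.csv`, `lmm_report.json`,
#' `cognition_correlations.csv` and `provenance.json` (configuration hash,
#' seed, package version). Runs are deterministic given the seed: two runs
#' with the same configuration produce byte-identical statistics files.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", config$out_dir)
  paths <- list()

  if (config$fidelity == "image") {
    sim <- make_longitudinal_cohort(config$cohort, config$profile,
                                    fidelity = "image",
                                    spec = config$phantom,
                                    n_image_subjects = config$n_image_subjects)
    geom_dir <- file.path(config$out_dir, "geometry")
    dir.create(geom_dir, showWarnings = FALSE)
    paths$surfaces <- write_surface_pair(sim$geometry,
                                         file.path(geom_dir, "template"))
    paths$parcellation <- write_parcellation_csv(
      sim$parcellation, file.path(geom_dir, "parcellation.csv"))
    pairing <- pair_vertices(sim$geometry, config$search_ring)
    maps <- list()
    subj_meta <- sim$truth$subjects
    for (s in seq_along(sim$subjects)) {
      rec <- sim$subjects[[s]]
      for (vis in c("baseline", "followup")) {
        vols <- rec[[vis]]
        rr <- mask_to_gm(compute_ratio_volume(vols$t1, vols$t2), vols$gm)
        vm <- sample_vertex_map(pairing$segments, rr, vols$gm)
        maps[[paste(rec$subject_id, vis, sep = ".")]] <- vm$values
        paths[[paste0("r_", rec$subject_id, "_", vis)]] <-
          write_volume_nifti(rr, file.path(config$out_dir,
                                           sprintf("r_%s_%s.nii.gz",
                                                   rec$subject_id, vis)))
      }
    }
    mapmat <- do.call(cbind, maps)
    col_ids <- sub("\\..*$", "", colnames(mapmat))
    reg <- vertex_map_to_regions(
      mapmat, sim$parcellation,
      subj_meta$group[match(col_ids, subj_meta$subject_id)])
    # assemble a long cohort table from the sampled regional means
    sr <- reg$subject_region
    ids <- sub("\\..*$", "", sr$subject)
    meta <- subj_meta[match(ids, subj_meta$subject_id), ]
    cohort_tab <- data.frame(
      subject_id = ids, group = meta$group,
      sex = meta$sex, age_years = meta$age_years, scanner = meta$scanner,
      visit = sub("^.*\\.", "", sr$subject), isi_years = meta$isi_years,
      region_id = sr$region_id, R = sr$mean_r)
    truth <- sim$truth
  } else {
    sim <- make_longitudinal_cohort(config$cohort, config$profile)
    cohort_tab <- sim$cohort
    truth <- sim$truth
  }

  paths$cohort <- write_cohort_csv(cohort_tab,
                                   file.path(config$out_dir, "cohort.csv"))

  # statistical stage needs a handful of subjects per group; an image-fidelity
  # run with very few rendered subjects stops after the sampling products
  n_per_group <- table(cohort_tab$group[!duplicated(cohort_tab$subject_id)])
  if (length(n_per_group) < 2L || min(n_per_group) < 4L) {
    prov <- list(package = "myelinmap",
                 version = as.character(utils::packageVersion("myelinmap")),
                 seed = config$seed, fidelity = config$fidelity,
                 note = "too few subjects per group for the statistical stage",
                 files = basename(unlist(paths)))
    paths$provenance <- file.path(config$out_dir, "provenance.json")
    jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE)
    return(invisible(list(cohort = cohort_tab, truth = truth, paths = paths)))
  }

  stats_tab <- region_stats(cohort_tab,
                            target_isi_years = config$target_isi_years,
                            alpha = config$alpha,
                            correction = config$correction)
  paths$region_statistics <- file.path(config$out_dir,
                                       "region_statistics.csv")
  utils::write.csv(stats_tab, paths$region_statistics, row.names = FALSE)

  tab <- lmm_table(cohort_tab)
  fit_full <- fit_lmm(tab, age_powers = config$age_powers)
  fit_null <- fit_lmm(tab, age_powers = config$age_powers,
                      include_diagnosis = FALSE)
  cmp <- compare_models(fit_full, fit_null)
  lmm_report <- list(
    fixed_effects = fit_full$beta,
    sigma0_sq = fit_full$sigma0_sq, sigma1_sq = fit_full$sigma1_sq,
    resid_sigma_sq = fit_full$resid_sigma_sq,
    loglik = fit_full$loglik, aic = fit_full$aic, bic = fit_full$bic,
    converged = fit_full$converged,
    diagnosis_lr = cmp$lr, diagnosis_lr_df = cmp$df,
    diagnosis_lr_p = cmp$p_value,
    aic_reduced = fit_null$aic, bic_reduced = fit_null$bic)
  paths$lmm_report <- file.path(config$out_dir, "lmm_report.json")
  jsonlite::write_json(lmm_report, paths$lmm_report, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  cog <- make_cognition_scores(cohort_tab,
                               coupling = config$cognition$coupling,
                               noise_sd = config$cognition$noise_sd,
                               seed = config$seed + 1000L)
  cog_cor <- correlate_cognition(cohort_tab, cog$scores, q = config$alpha)
  paths$cognition <- file.path(config$out_dir, "cognition_correlations.csv")
  utils::write.csv(cog_cor, paths$cognition, row.names = FALSE)

  # the hash covers the scientific configuration, not the output location
  serializable <- config[setdiff(names(config), c("profile", "out_dir"))]
  serializable$profile <- as.list(as.data.frame(config$profile))
  prov <- list(package = "myelinmap",
               version = as.character(utils::packageVersion("myelinmap")),
               seed = config$seed,
               config_hash = config_hash(serializable),
               fidelity = config$fidelity,
               files = basename(unlist(paths)))
  paths$provenance <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE)

  invisible(list(cohort = cohort_tab, truth = truth,
                 region_statistics = stats_tab,
                 lmm = fit_full, lmm_comparison = cmp,
                 cognition = cog_cor, paths = paths))
}
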