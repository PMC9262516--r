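#' Aggregate per-subject vertex maps to regional summaries
#'
#' Group-level regional values follow the two-stage averaging order used for
#' cortical maps: at each vertex, average over the subjects of a group first
#' (ignoring subjects missing at that vertex), then average the vertex means
#' within each parcel (ignoring vertices with no valid subject). Per-subject
#' regional means (each subject's average over the non-missing vertices of a
#' parcel) are emitted alongside for subject-level statistics.
#'
#' @param maps numeric matrix, vertices x subjects, `NA` marking missing
#'   vertex samples; column names identify subjects.
#' @param parcellation data frame with `vertex_id` and `region_id`, one row
#'   per vertex of the template mesh.
#' @param groups character/factor of group labels, one per subject (column).
#' @return A list with data frames `group_region` (`group`, `region_id`,
#'   `mean_r`, `n_vertices`) and `subject_region` (`subject`, `group`,
#'   `region_id`, `mean_r`).
#' @export
vertex_map_to_regions <- function(maps, parcellation, groups) {
  maps <- as.matrix(maps)
  if (nrow(maps) != nrow(parcellation))
    stop("parcellation and vertex maps disagree on mesh size")
  if (length(groups) != ncol(maps))
    stop("`groups` must have one label per subject (column)")
  subjects <- colnames(maps)
  if (is.null(subjects)) subjects <- paste0("S", seq_len(ncol(maps)))
  region <- parcellation$region_id
  regions <- sort(unique(region))
  groups <- as.character(groups)

  group_rows <- list()
  for (g in unique(groups)) {
    sub <- maps[, groups == g, drop = FALSE]
    vmean <- rowMeans(sub, na.rm = TRUE)
    vmean[!is.finite(vmean)] <- NA_real_  # vertices missing in all subjects
    rm_ <- vapply(regions, function(r) {
      v <- vmean[region == r]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    nv <- vapply(regions, function(r) sum(region == r & !is.na(vmean)),
                 integer(1))
    group_rows[[g]] <- data.frame(group = g, region_id = regions,
                                  mean_r = rm_, n_vertices = nv)
  }

  subj_rows <- vector("list", ncol(maps))
  for (s in seq_len(ncol(maps))) {
    v <- maps[, s]
    rm_ <- vapply(regions, function(r) {
      x <- v[region == r]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    subj_rows[[s]] <- data.frame(subject = subjects[s], group = groups[s],
                                 region_id = regions, mean_r = rm_)
  }

  list(group_region = do.call(rbind, c(group_rows, list(make.row.names = FALSE))),
       subject_region = do.call(rbind, c(subj_rows, list(make.row.names = FALSE))))
}
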