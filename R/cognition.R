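#' Standardize raw scores against reference norms
#'
#' @param x raw score(s).
#' @param mu,sigma reference mean and standard deviation (sigma > 0).
#' @return z-scores `(x - mu) / sigma`.
#' @export
zscore_against_reference <- function(x, mu, sigma) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)))
    stop("reference norms are missing")
  if (any(sigma <= 0)) stop("reference sigma must be positive")
  (x - mu) / sigma
}

#' Spearman rank correlation with two-sided p value
#'
#' Rank correlation with average ranks for ties. The p value uses the exact
#' null distribution for small samples (n <= 10, untied) and the
#' t-distribution approximation otherwise.
#'
#' @param a,b numeric vectors, n >= 4, neither constant.
#' @return List with `r`, `p_value`, `n`, `method`.
#' @export
spearman_correlation <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 4L) stop("Spearman correlation needs n >= 4")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: rank correlation undefined")
  ties <- anyDuplicated(a) > 0L || anyDuplicated(b) > 0L
  exact <- n <= 10L && !ties
  ht <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = exact))
  list(r = unname(ht$estimate), p_value = ht$p.value, n = n,
       method = if (exact) "exact" else "t-approximation")
}

#' Benjamini-Yekutieli false discovery rate control
#'
#' Step-up procedure valid under arbitrary dependence, with the
#' harmonic-sum penalty c(m) = sum(1/i). Adjusted p values are monotone and
#' BY rejections are always a subset of Benjamini-Hochberg rejections at
#' the same level.
#'
#' @param p raw p values in `[0, 1]`.
#' @param q target false discovery rate.
#' @return List with `p_adjusted` and logical `reject`.
#' @export
by_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BY")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Correlate cognitive scores with myelin measures
#'
#' Builds the full battery: each myelin measure (fractional change, baseline
#' R, follow-up R; cortex means per subject) against each of the six test
#' scores at each cognition timepoint, with Spearman correlations and one
#' Benjamini-Yekutieli family per analysis block (configurable: the whole
#' table by default).
#'
#' @param cohort long-format cohort table (used for per-subject cortex-mean
#'   R at both visits).
#' @param scores wide score table from [make_cognition_scores()].
#' @param group restrict to one diagnostic group (default `"mTBI"`); `NULL`
#'   for all subjects.
#' @param q false discovery rate.
#' @param family `"all"` treats the whole battery as one family;
#'   `"cog_visit"` corrects within each cognition timepoint separately.
#' @return Data frame with `measure`, `test`, `cog_visit`, `r`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
correlate_cognition <- function(cohort, scores, group = "mTBI", q = 0.05,
                                family = c("all", "cog_visit")) {
  family <- match.arg(family)
  if (!is.null(group)) {
    cohort <- cohort[cohort$group %in% group, ]
    scores <- scores[scores$group %in% group, ]
  }
  agg <- stats::aggregate(R ~ subject_id + visit, data = cohort, FUN = mean)
  rb <- agg[agg$visit == "baseline", ]
  rf <- agg[agg$visit == "followup", ]
  ids <- intersect(rb$subject_id, rf$subject_id)
  rb <- rb$R[match(ids, rb$subject_id)]
  rf <- rf$R[match(ids, rf$subject_id)]
  measures <- list(delta_r = compute_delta_r(rb, rf), r_baseline = rb,
                   r_followup = rf)
  tests <- c("EVMI", "EVMD", "WMS", "VF", "IR", "PS")
  rows <- list()
  for (vis in unique(scores$visit)) {
    sc <- scores[scores$visit == vis, ]
    m <- match(ids, sc$subject_id)
    for (mn in names(measures)) {
      for (tn in tests) {
        x <- measures[[mn]]
        y <- sc[[tn]][m]
        ct <- spearman_correlation(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = mn, test = tn, cog_visit = vis,
          r = ct$r, p = ct$p_value)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (family == "all") {
    fd <- by_fdr(out$p, q)
    out$p_adjusted <- fd$p_adjusted
    out$significant <- fd$reject
  } else {
    out$p_adjusted <- NA_real_
    out$significant <- NA
    for (vis in unique(out$cog_visit)) {
      sel <- out$cog_visit == vis
      fd <- by_fdr(out$p[sel], q)
      out$p_adjusted[sel] <- fd$p_adjusted
      out$significant[sel] <- fd$reject
    }
  }
  out
}
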