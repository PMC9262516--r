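#' Build the observation table for the longitudinal mixed model
#'
#' Aggregates the cohort to one response per subject and visit (the mean R
#' across regions by default, or a single region's R), and attaches the
#' model covariates. The random-effect covariate `delta_t` is 0 at baseline
#' and the deviation of the subject's ISI from the grand-mean ISI (across
#' both groups) at follow-up, so the follow-up deviations sum to zero.
#'
#' @param cohort long-format cohort table.
#' @param region optional region id; `NULL` averages across regions.
#' @return Data frame with `y`, `diagnosis`, `age`, `sex`, `scanner`,
#'   `delta_t`, `visit`, `subject`.
#' @export
lmm_table <- function(cohort, region = NULL) {
  tab <- if (is.null(region)) cohort else cohort[cohort$region_id == region, ]
  if (nrow(tab) == 0L) stop("no rows for the requested region")
  agg <- stats::aggregate(R ~ subject_id + group + sex + age_years +
                            scanner + isi_years + visit,
                          data = tab, FUN = mean)
  first <- !duplicated(agg$subject_id)
  dev <- isi_deviations(agg$isi_years[first])
  names(dev) <- agg$subject_id[first]
  data.frame(
    y = agg$R,
    diagnosis = as.integer(agg$group == "mTBI"),
    age = agg$age_years,
    sex = agg$sex,
    scanner = agg$scanner,
    delta_t = ifelse(agg$visit == "followup",
                     dev[agg$subject_id], 0),
    visit = agg$visit,
    subject = agg$subject_id)
}

lmm_fixed_formula <- function(include_diagnosis = TRUE, age_powers = 1L) {
  terms <- c(if (include_diagnosis) "diagnosis", "age",
             if (age_powers >= 2L)
               paste0("I(age^", 2:age_powers, ")"),
             "sex", "scanner", "age:sex")
  stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

#' Design matrices for the longitudinal mixed model
#'
#' Fixed effects: intercept, diagnosis, age (optionally powers up to
#' `age_powers`), sex, scanner and the age-by-sex interaction. Random
#' effects: per-subject intercept and slope on `delta_t`.
#'
#' @param data observation table from [lmm_table()].
#' @param age_powers highest age power in the fixed effects (1-4).
#' @param include_diagnosis whether the diagnosis fixed effect is present.
#' @return List with the fixed-effect matrix `X`, `delta_t`, `grouping`
#'   (subject factor) and the response `y`.
#' @export
build_lmm_design <- function(data, age_powers = 1L, include_diagnosis = TRUE) {
  fm <- lmm_fixed_formula(include_diagnosis, age_powers)
  x <- stats::model.matrix(stats::delete.response(stats::terms(fm)), data)
  if (qr(x)$rank < ncol(x))
    stop("fixed-effects design is rank deficient")
  list(X = x, delta_t = data$delta_t, grouping = factor(data$subject),
       y = data$y)
}

#' Fit the longitudinal mixed-effects model
#'
#' Fits `y = X beta + Z u + e` by maximum likelihood, with per-subject
#' random intercepts and random slopes on the ISI deviation `delta_t`
#' (independent by default, matching separate priors N(0, sigma0^2) and
#' N(0, sigma1^2); a correlated pair is available behind `correlated`).
#' The optimizer mirrors the reference tolerances: absolute step tolerance
#' 1e-12 and an iteration cap of 1e5; convergence additionally requires a
#' positive-definite Hessian of the deviance at the optimum.
#'
#' @param data observation table from [lmm_table()].
#' @param correlated allow correlation between random intercept and slope.
#' @param age_powers highest age power in the fixed effects.
#' @param include_diagnosis drop the diagnosis term to obtain the nested
#'   null model.
#' @return An object of class `"lmm_fit"` with fixed-effect estimates and
#'   standard errors, variance components `sigma0_sq` (intercept),
#'   `sigma1_sq` (slope), `resid_sigma_sq`, the maximized `loglik`, `aic`,
#'   `bic`, parameter count `n_par` and a `converged` flag. The underlying
#'   lme4 fit is kept in `$model`.
#' @export
fit_lmm <- function(data, correlated = FALSE, age_powers = 1L,
                    include_diagnosis = TRUE) {
  des <- build_lmm_design(data, age_powers, include_diagnosis)
  fixed <- lmm_fixed_formula(include_diagnosis, age_powers)
  ran <- if (correlated) "(1 + delta_t | subject)" else
    "(1 | subject) + (0 + delta_t | subject)"
  fm <- stats::as.formula(paste(deparse(fixed), "+", ran))
  # with two visits per subject the correlated intercept+slope pair has as
  # many random effects as observations; the likelihood is still proper, so
  # the dimension guards are relaxed rather than the model changed
  ctrl <- lme4::lmerControl(
    optCtrl = list(maxeval = 1e5, xtol_abs = 1e-12, ftol_abs = 1e-12),
    check.nobs.vs.nRE = "ignore", check.nobs.vs.rankZ = "ignore",
    check.conv.singular = lme4::.makeCC(action = "message", tol = 1e-4))
  # optimizer diagnostics are folded into the `converged` flag below
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fm, data = data, REML = FALSE, control = ctrl)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp, var) {
    i <- which(vc$grp == grp & vc$var1 == var & is.na(vc$var2))
    if (length(i)) vc$vcov[i[1]] else NA_real_
  }
  sigma0_sq <- sum(vc$vcov[vc$var1 == "(Intercept)" & is.na(vc$var2)],
                   na.rm = TRUE)
  sigma1_sq <- sum(vc$vcov[vc$var1 == "delta_t" & is.na(vc$var2)],
                   na.rm = TRUE)
  resid_sq <- vc$vcov[vc$grp == "Residual"]
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  hess <- fit@optinfo$derivs$Hessian
  # positive (semi-)definite curvature at the optimum; a variance component
  # estimated on the boundary legitimately yields a zero eigenvalue
  hess_pd <- if (is.null(hess)) TRUE else {
    ev <- eigen(as.matrix(hess), symmetric = TRUE, only.values = TRUE)$values
    all(ev > -1e-6 * max(abs(ev)))
  }
  msgs <- fit@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  if (length(msgs) == 0L) msgs <- NULL
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  out <- list(beta = data.frame(term = names(beta), estimate = unname(beta),
                                se = unname(se)),
              sigma0_sq = sigma0_sq, sigma1_sq = sigma1_sq,
              resid_sigma_sq = resid_sq,
              loglik = as.numeric(ll), n_par = k, n_obs = n,
              n_subjects = nlevels(des$grouping),
              aic = 2 * k - 2 * as.numeric(ll),
              bic = k * log(n) - 2 * as.numeric(ll),
              converged = is.null(msgs) && hess_pd,
              correlated = correlated,
              include_diagnosis = include_diagnosis,
              data_checksum = c(n, sum(data$y), sum(data$y^2)),
              model = fit)
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Longitudinal mixed model (ML)\n")
  cat(sprintf("  %d observations, %d subjects; logLik %.3f, AIC %.2f, BIC %.2f\n",
              x$n_obs, x$n_subjects, x$loglik, x$aic, x$bic))
  cat(sprintf("  sigma0^2 (intercept) %.4g, sigma1^2 (delta_t slope) %.4g, residual %.4g\n",
              x$sigma0_sq, x$sigma1_sq, x$resid_sigma_sq))
  cat(if (x$converged) "  converged\n" else "  NOT converged\n")
  invisible(x)
}

#' @export
summary.lmm_fit <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  b <- object$beta
  b$z <- b$estimate / b$se
  print(b, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.lmm_fit <- function(object, ...) {
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.lmm_fit <- function(object, ...) stats::fitted(object$model)

#' @export
residuals.lmm_fit <- function(object, ...) stats::residuals(object$model)

#' Likelihood-ratio comparison of two nested mixed models
#'
#' Both models must be ML fits on identical data, with the reduced model's
#' fixed effects a subset of the full model's. Reports the likelihood-ratio
#' statistic, its chi-square p value, and AIC/BIC for both models.
#'
#' @param full,reduced `"lmm_fit"` objects (full and nested reduced model).
#' @return List with `lr`, `df`, `p_value`, and named `aic`/`bic` vectors.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (!isTRUE(all.equal(full$data_checksum, reduced$data_checksum)))
    stop("models were fitted on different data")
  if (!all(reduced$beta$term %in% full$beta$term))
    stop("models are not nested (reduced terms not a subset)")
  df <- full$n_par - reduced$n_par
  if (df < 0) stop("`full` has fewer parameters than `reduced`")
  lr <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  list(lr = lr, df = df, p_value = p,
       aic = c(full = full$aic, reduced = reduced$aic),
       bic = c(full = full$bic, reduced = reduced$bic))
}

#' Simulate a response from the mixed model
#'
#' Draws `y = X beta + b0[subject] + b1[subject] * delta_t + e` with
#' independent Gaussian random effects and errors, for calibration and
#' parameter-recovery studies.
#'
#' @param data observation table from [lmm_table()] (its `y` is ignored).
#' @param beta fixed-effect vector, ordered as the columns of the design
#'   built by [build_lmm_design()].
#' @param sigma0,sigma1 random intercept/slope standard deviations.
#' @param sigma residual standard deviation.
#' @param age_powers,include_diagnosis design options, as in [fit_lmm()].
#' @param seed optional integer seed.
#' @return Numeric response vector.
#' @export
simulate_lmm_response <- function(data, beta, sigma0, sigma1, sigma,
                                  age_powers = 1L, include_diagnosis = TRUE,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  des <- build_lmm_design(data, age_powers, include_diagnosis)
  if (length(beta) != ncol(des$X))
    stop(sprintf("`beta` must have %d entries (design columns: %s)",
                 ncol(des$X), paste(colnames(des$X), collapse = ", ")))
  subj <- des$grouping
  b0 <- stats::rnorm(nlevels(subj), 0, sigma0)
  b1 <- stats::rnorm(nlevels(subj), 0, sigma1)
  as.numeric(des$X %*% beta) + b0[as.integer(subj)] +
    b1[as.integer(subj)] * des$delta_t +
    stats::rnorm(nrow(des$X), 0, sigma)
}
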