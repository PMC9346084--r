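# Tube-level binomial mixed models.  The response is cbind(alive, dead)
# with a logit link; random intercepts for family and (optionally) for the
# observation level, the standard overdispersion correction.  Fitting
# delegates to stats::glm (no random terms) or lme4::glmer (Laplace); the
# returned object exposes the maximized log-likelihood so likelihood-ratio
# tests can be run against nested fits.

# Treatment-coded references: ancestral population, first clutch, control
# parents, home regime in phase 1.
factor_reference_levels <- function() {
  c(population = "SFB84", clutch = "1", parental_treatment = "control",
    regime = "T_SFB", phase1_regime = "T_SFB", microbiome = "LAB",
    cross_status = "own", experiment = "additive")
}

prepare_model_frame <- function(table, vars) {
  df <- as.data.frame(table)
  voc <- survival_vocab()
  refs <- factor_reference_levels()
  for (v in vars) {
    if (!v %in% names(df)) {
      ad_stop("ad_schema_error", "model factor '%s' not in table", v)
    }
    if (v %in% names(voc)) {
      x <- factor(df[[v]], levels = voc[[v]])
      x <- droplevels(x)
      if (refs[[v]] %in% levels(x)) x <- stats::relevel(x, refs[[v]])
      df[[v]] <- x
    }
  }
  df$.n_dead <- df$n_total - df$n_alive
  df$.obs <- factor(seq_len(nrow(df)))
  df
}

#' Fit a tube-level binomial mixed model
#'
#' Maximizes the marginal binomial likelihood (Laplace approximation for
#' random intercepts) of
#' `cbind(n_alive, n_dead) ~ fixed (+ (1 | family_id)) (+ (1 | obs))`.
#' Non-convergence is flagged on the returned object, never silent;
#' coefficients whose magnitude and standard error both explode are flagged
#' as separated.
#'
#' @param table A `survival_table`.
#' @param fixed One-sided formula of fixed factors and interactions,
#'   e.g. `~ population * clutch`.
#' @param family_re Include a per-family random intercept (requires
#'   non-missing `family_id` throughout).
#' @param obs_re Include an observation-level random intercept (the
#'   overdispersion correction).
#' @return A `glmm_fit` with elements `coefficients`, `se`, `vcov`,
#'   `varcomp`, `logLik`, `n_params`, `df_residual`, `converged`,
#'   `separated`, `descriptor`, `model`.
#' @export
fit_binomial_glmm <- function(table, fixed = ~population,
                              family_re = FALSE, obs_re = FALSE) {
  if (!nrow(table)) ad_stop("ad_schema_error", "empty survival table")
  vars <- all.vars(fixed)
  df <- prepare_model_frame(table, vars)
  if (family_re && anyNA(df$family_id)) {
    ad_stop("ad_fit_error", "family_re = TRUE but family_id has missing values")
  }
  rhs <- paste(deparse(fixed[[2]]), collapse = " ")
  re_terms <- c(if (family_re) "(1 | family_id)", if (obs_re) "(1 | .obs)")
  form <- stats::as.formula(paste("cbind(n_alive, .n_dead) ~", rhs,
                                  if (length(re_terms))
                                    paste("+", paste(re_terms, collapse = " + "))
                                  else ""))
  mixed <- family_re || obs_re
  if (mixed) {
    fit <- lme4::glmer(form, data = df, family = stats::binomial())
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- fit@optinfo$conv$opt == 0 && is.null(msgs)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- lme4::VarCorr(fit)
    varcomp <- c(
      family = if (family_re) as.numeric(vc$family_id[1, 1]) else NA_real_,
      obs    = if (obs_re) as.numeric(vc$.obs[1, 1]) else NA_real_
    )
    n_vc <- family_re + obs_re
  } else {
    fit <- stats::glm(form, data = df, family = stats::binomial())
    converged <- fit$converged
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    varcomp <- c(family = NA_real_, obs = NA_real_)
    n_vc <- 0L
  }
  se <- sqrt(diag(V))
  separated <- names(beta)[!is.na(beta) & abs(beta) > 10 & se > 10]
  if (length(separated)) {
    warning(sprintf("possible separation in coefficient(s): %s",
                    paste(separated, collapse = ", ")))
  }
  if (!converged) warning("model did not converge; fit flagged")
  n_par <- sum(!is.na(beta)) + n_vc
  out <- structure(list(
    coefficients = beta, se = se, vcov = V, varcomp = varcomp,
    logLik = as.numeric(stats::logLik(fit)),
    n_params = n_par, nobs = nrow(df),
    df_residual = nrow(df) - n_par,
    converged = converged, separated = separated,
    descriptor = list(fixed = rhs,
                      fixed_terms = attr(stats::terms(fixed), "term.labels"),
                      family_re = family_re, obs_re = obs_re),
    factor_levels = lapply(df[intersect(vars, names(survival_vocab()))],
                           levels),
    model = fit
  ), class = "glmm_fit")
  ad_log("fit-survival", fixed = rhs, family_re = family_re, obs_re = obs_re,
         logLik = out$logLik, converged = converged,
         coef = paste(sprintf("%s=%.5g", names(beta), beta), collapse = ";"))
  out
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("binomial GLMM: ~ %s%s%s\n", x$descriptor$fixed,
              if (x$descriptor$family_re) " + (1|family)" else "",
              if (x$descriptor$obs_re) " + (1|obs)" else ""))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    z = x$coefficients / x$se)
  print(round(tab, 4))
  if (any(!is.na(x$varcomp))) {
    cat("variance components:",
        paste(sprintf("%s = %.4g", names(x$varcomp)[!is.na(x$varcomp)],
                      x$varcomp[!is.na(x$varcomp)]), collapse = ", "), "\n")
  }
  cat(sprintf("logLik %.3f on %d parameters; converged: %s\n",
              x$logLik, x$n_params, x$converged))
  invisible(x)
}

#' @export
coef.glmm_fit <- function(object, ...) object$coefficients

#' @export
vcov.glmm_fit <- function(object, ...) object$vcov

#' @export
logLik.glmm_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, class = "logLik")
}

#' Pearson dispersion ratio of a fitted binomial model
#'
#' Sum of squared Pearson residuals over residual degrees of freedom. A
#' ratio near 1 is consistent with binomial sampling; callers add the
#' observation-level random intercept when the ratio exceeds their
#' threshold (1.4 by default in [extract_effect_sizes()]).
#'
#' @param fit A `glmm_fit` without an observation-level term.
#' @return The dispersion ratio (> 0).
#' @export
assess_overdispersion <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (fit$descriptor$obs_re) {
    ad_stop("ad_spec_error",
            "dispersion is assessed on the model without the observation-level term")
  }
  if (fit$df_residual <= 0) {
    ad_stop("ad_degenerate_error", "zero residual degrees of freedom")
  }
  r <- stats::residuals(fit$model, type = "pearson")
  ratio <- sum(r^2) / fit$df_residual
  ad_log("fit-survival", dispersion_ratio = ratio)
  ratio
}

#' Likelihood-ratio test between nested fits
#'
#' `chi_sq = 2 (ll_full - ll_reduced)` clipped at zero, compared to a
#' chi-square reference with df equal to the parameter-count difference.
#'
#' @param full,reduced `glmm_fit` objects; the reduced model's fixed terms
#'   and random structure must be nested in the full model's.
#' @return A list `chi_sq`, `df`, `p`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "glmm_fit"), inherits(reduced, "glmm_fit"))
  ok <- all(reduced$descriptor$fixed_terms %in% full$descriptor$fixed_terms) &&
    (!reduced$descriptor$family_re || full$descriptor$family_re) &&
    (!reduced$descriptor$obs_re || full$descriptor$obs_re)
  if (!ok) ad_stop("ad_nesting_error", "reduced model is not nested in full")
  if (full$nobs != reduced$nobs) {
    ad_stop("ad_nesting_error", "models fitted to different data")
  }
  if (!full$converged || !reduced$converged) {
    warning("likelihood-ratio test on non-converged fit(s)")
  }
  chi_sq <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$n_params - reduced$n_params
  p <- if (df > 0) stats::pchisq(chi_sq, df, lower.tail = FALSE) else NA_real_
  ad_log("fit-survival", lrt_chisq = chi_sq, lrt_df = df, lrt_p = p)
  list(chi_sq = chi_sq, df = df, p = p)
}

#' Pairwise z contrasts with single-step (Tukey-family) adjustment
#'
#' Core contrast engine: for per-level estimates with covariance `V`,
#' computes every pairwise difference, its standard error, z score, and a
#' single-step adjusted p-value from the joint multivariate-normal
#' distribution of the contrasts (the Tukey family). With a single contrast
#' the adjusted p equals the unadjusted one.
#'
#' @param estimates Named per-level estimates (reference level at 0).
#' @param V Covariance matrix of the estimates (same order).
#' @return Data frame: `pair`, `estimate`, `se`, `z`, `p`, `p_adjusted`.
#' @export
pairwise_z <- function(estimates, V) {
  k <- length(estimates)
  if (k < 2) ad_stop("ad_spec_error", "need >= 2 levels for pairwise contrasts")
  V <- as.matrix(V)
  lev <- names(estimates)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  C <- matrix(0, m, k)
  for (j in seq_len(m)) {
    C[j, pairs[1, j]] <- 1
    C[j, pairs[2, j]] <- -1
  }
  est <- as.numeric(C %*% estimates)
  Vd <- C %*% V %*% t(C)
  se <- sqrt(diag(Vd))
  if (any(!is.finite(se)) || any(se <= 0)) {
    ad_stop("ad_estimability_error", "inestimable contrast (zero or non-finite SE)")
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  if (m == 1) {
    p_adj <- p
  } else {
    R <- stats::cov2cor(Vd)
    p_adj <- vapply(seq_len(m), function(j) {
      if (abs(z[j]) < .Machine$double.eps^0.5) return(1)
      1 - mvtnorm::pmvnorm(lower = rep(-abs(z[j]), m),
                           upper = rep(abs(z[j]), m), corr = R,
                           algorithm = mvtnorm::GenzBretz(abseps = 1e-6))[1]
    }, numeric(1))
    p_adj <- pmin(pmax(p_adj, p), 1) # adjusted never below unadjusted
  }
  data.frame(pair = paste(lev[pairs[1, ]], lev[pairs[2, ]], sep = " - "),
             estimate = est, se = se, z = z, p = p, p_adjusted = p_adj)
}

#' Post hoc pairwise comparisons of a fitted factor
#'
#' Tukey-style all-pairs comparisons of the levels of a treatment-coded
#' factor in a `glmm_fit`, using [pairwise_z()] on the fitted coefficients
#' and their covariance (the reference level enters at 0 with zero
#' variance).
#'
#' @param fit A `glmm_fit`.
#' @param factor_name Name of a factor with >= 2 levels in the fit.
#' @return Data frame as in [pairwise_z()].
#' @export
posthoc_pairwise <- function(fit, factor_name) {
  stopifnot(inherits(fit, "glmm_fit"))
  lev <- fit$factor_levels[[factor_name]]
  if (is.null(lev) || length(lev) < 2) {
    ad_stop("ad_spec_error", "factor '%s' has fewer than 2 levels in the fit",
            factor_name)
  }
  cn <- paste0(factor_name, lev[-1])
  if (!all(cn %in% names(fit$coefficients))) {
    ad_stop("ad_estimability_error",
            "coefficients for factor '%s' not all estimable", factor_name)
  }
  est <- c(0, fit$coefficients[cn])
  names(est) <- lev
  V <- matrix(0, length(lev), length(lev),
              dimnames = list(lev, lev))
  V[-1, -1] <- fit$vcov[cn, cn]
  res <- pairwise_z(est, V)
  ad_log("fit-survival", posthoc = paste(
    sprintf("%s:z=%.3f,p=%.4g", res$pair, res$z, res$p_adjusted),
    collapse = ";"))
  res
}
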