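# Multilevel random-effects meta-analysis of log odds ratios, written from
# the marginal likelihood: y_ij = mu + beta * pop_ij + u_j + e_ij, with
# u_j ~ N(0, tau^2) per experiment and e_ij ~ N(0, v_ij) with v_ij known.
# tau^2 is profiled out by 1-d optimisation on the log scale (boundary
# tau^2 = 0 checked explicitly); fixed effects come from GLS at the
# optimum.  tau^2 is reported under REML; likelihood-ratio tests of fixed
# effects refit under ML.

meta_design <- function(effects, moderator, intercept = TRUE) {
  y <- effects$log_or
  k <- length(y)
  X <- if (intercept) matrix(1, k, 1, dimnames = list(NULL, "intercept"))
       else matrix(0, k, 0)
  if (moderator) {
    pops <- unique(effects$population)
    # chronological order (ancestral first) where the labels are known,
    # so the intercept is the earlier-collected population's mean
    ord <- match(pops, names(population_time_codes()))
    pops <- pops[order(ifelse(is.na(ord), length(ord) + 99L, ord), pops)]
    if (length(pops) < 2) {
      ad_stop("ad_spec_error", "moderator requested but only one population")
    }
    # intercept = first population's mean; indicators for the others
    for (pop in pops[-1]) {
      X <- cbind(X, as.numeric(effects$population == pop))
      colnames(X)[ncol(X)] <- paste0("population", pop)
    }
  }
  X
}

# -2 log-likelihood (ML or REML) at a given tau2, with profiled GLS betas.
meta_neg2ll <- function(tau2, y, v, X, exper, reml) {
  k <- length(y)
  Z <- outer(exper, unique(exper), "==") * 1
  V <- diag(v, k) + tau2 * tcrossprod(Z)
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  if (ncol(X) > 0) {
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    b <- solve(XtViX, crossprod(Vi_X, y))
    r <- y - X %*% b
  } else {
    XtViX <- matrix(0, 0, 0)
    b <- numeric(0)
    r <- y
  }
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- sum(r * Vi_r)
  n2ll <- logdetV + quad + k * log(2 * pi)
  if (reml && ncol(X) > 0) {
    n2ll <- n2ll + determinant(XtViX, logarithm = TRUE)$modulus[1] -
      ncol(X) * log(2 * pi)
  }
  list(n2ll = as.numeric(n2ll), b = as.numeric(b), XtViX = XtViX)
}

#' Fit the multilevel random-effects meta-analysis
#'
#' @param effects An `effect_sizes` data frame (columns `log_or`, `var`,
#'   `population`, `experiment`), every variance > 0.
#' @param moderator Include the population moderator (indicator for the
#'   later-collected population; the intercept is then the
#'   earlier-collected population's mean).
#' @param method `"REML"` (variance reporting, the default) or `"ML"`
#'   (used internally for likelihood-ratio tests).
#' @param intercept Drop with `FALSE` to fit the zero-mean null model
#'   (used by [meta_mean_test()]).
#' @param fixed_tau2 Optionally fix the between-experiment variance instead
#'   of estimating it (e.g. `0` for a fixed-effect / common-effect fit).
#' @return A `meta_lor` object: coefficients `b` with `se` and `vcov`,
#'   `tau2`, `logLik`, `method`, `k`.
#' @export
fit_multilevel_meta <- function(effects, moderator = TRUE,
                                method = c("REML", "ML"), intercept = TRUE,
                                fixed_tau2 = NULL) {
  method <- match.arg(method)
  if (!nrow(effects)) ad_stop("ad_spec_error", "no effects supplied")
  if (is.null(effects$experiment)) {
    ad_stop("ad_schema_error", "every effect needs an experiment label")
  }
  v <- effects$var
  if (any(is.na(v)) || any(v <= 0)) {
    ad_stop("ad_schema_error", "every effect needs sampling variance > 0")
  }
  y <- effects$log_or
  exper <- as.character(effects$experiment)
  X <- meta_design(effects, moderator, intercept)
  k <- length(y)
  p <- ncol(X)
  if (k < max(p, 1L)) {
    ad_stop("ad_insufficient_error",
            "k = %d effects cannot identify %d fixed parameters", k, p)
  }
  reml <- method == "REML"
  crit <- function(tau2) meta_neg2ll(tau2, y, v, X, exper, reml)$n2ll
  if (is.null(fixed_tau2)) {
    at0 <- crit(0)
    upper <- max(if (k > 1) stats::var(y) * 10 else 0, max(v) * 10, 1)
    opt <- stats::optimize(function(lt) crit(exp(lt)),
                           interval = c(log(1e-12), log(upper)), tol = 1e-10)
    tau2 <- if (opt$objective < at0 - 1e-12) exp(opt$minimum) else 0
  } else {
    if (fixed_tau2 < 0) ad_stop("ad_spec_error", "fixed_tau2 must be >= 0")
    tau2 <- fixed_tau2
  }
  sol <- meta_neg2ll(tau2, y, v, X, exper, reml)
  if (p > 0) {
    Vb <- solve(sol$XtViX)
    se <- sqrt(diag(Vb))
    names(sol$b) <- colnames(X)
    names(se) <- colnames(X)
    dimnames(Vb) <- list(colnames(X), colnames(X))
  } else {
    Vb <- matrix(0, 0, 0); se <- numeric(0)
  }
  out <- structure(list(
    b = sol$b, se = se, vcov = Vb, tau2 = tau2,
    logLik = -sol$n2ll / 2, method = method, k = k, p = p,
    moderator = moderator, intercept = intercept,
    effects = data.frame(log_or = y, var = v, experiment = exper,
                         population = effects$population %||%
                           rep(NA_character_, k))
  ), class = "meta_lor")
  ad_log("meta", method = method, k = k, tau2 = tau2, logLik = out$logLik,
         coef = paste(sprintf("%s=%.5g", names(sol$b), sol$b), collapse = ";"))
  out
}

#' @export
print.meta_lor <- function(x, ...) {
  cat(sprintf("multilevel meta-analysis (%s), k = %d effects\n",
              x$method, x$k))
  if (x$p > 0) {
    tab <- data.frame(estimate = x$b, se = x$se, z = x$b / x$se)
    print(round(tab, 4))
  } else cat("  (zero-mean model, no fixed effects)\n")
  cat(sprintf("between-experiment variance tau^2 = %.5g\n", x$tau2))
  cat(sprintf("logLik (%s) = %.4f\n", x$method, x$logLik))
  invisible(x)
}

#' @export
summary.meta_lor <- function(object, ...) {
  z <- if (object$p > 0) object$b / object$se else numeric(0)
  structure(list(fit = object,
                 table = data.frame(estimate = object$b, se = object$se,
                                    z = z, p = 2 * stats::pnorm(-abs(z)))),
            class = "summary.meta_lor")
}

#' @export
print.summary.meta_lor <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @export
coef.meta_lor <- function(object, ...) object$b

#' @export
vcov.meta_lor <- function(object, ...) object$vcov

#' @export
logLik.meta_lor <- function(object, ...) {
  structure(object$logLik, df = object$p + 1L, class = "logLik")
}

refit_ml <- function(fit) {
  if (fit$method == "ML") return(fit)
  fit_multilevel_meta(fit$effects, moderator = fit$moderator,
                      method = "ML", intercept = fit$intercept)
}

#' Likelihood-ratio test between nested meta-analysis models
#'
#' Both models are (re)fitted by maximum likelihood for the comparison;
#' REML likelihoods are not comparable across fixed-effect structures.
#'
#' @param full,reduced `meta_lor` fits on the same effect set, reduced
#'   nested in full.
#' @return A list `chi_sq`, `df`, `p`.
#' @export
meta_lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "meta_lor"), inherits(reduced, "meta_lor"))
  same <- isTRUE(all.equal(full$effects$log_or, reduced$effects$log_or)) &&
    isTRUE(all.equal(full$effects$var, reduced$effects$var)) &&
    identical(full$effects$experiment, reduced$effects$experiment)
  if (!same) ad_stop("ad_mismatch_error", "fits use different effect sets")
  if (reduced$p > full$p) {
    ad_stop("ad_nesting_error", "reduced model has more parameters than full")
  }
  full <- refit_ml(full)
  reduced <- refit_ml(reduced)
  chi_sq <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$p - reduced$p
  p <- if (df > 0) stats::pchisq(chi_sq, df, lower.tail = FALSE) else NA_real_
  ad_log("meta", lrt_chisq = chi_sq, lrt_df = df, lrt_p = p)
  list(chi_sq = chi_sq, df = df, p = p)
}

#' 1-df test of the population moderator
#'
#' Compares the moderated model (separate means for the two derived
#' populations) to the common-mean model by ML likelihood ratio.
#'
#' @param effects An `effect_sizes` data frame.
#' @return A list `chi_sq`, `df`, `p`.
#' @export
meta_moderator_test <- function(effects) {
  full <- fit_multilevel_meta(effects, moderator = TRUE, method = "ML")
  reduced <- fit_multilevel_meta(effects, moderator = FALSE, method = "ML")
  meta_lr_test(full, reduced)
}

#' Auxiliary 1-df test of "overall mean effect = 0"
#'
#' Compares the common-mean model to the zero-mean null by ML likelihood
#' ratio. Exposed alongside [meta_moderator_test()] because a 1-df
#' chi-square on two derived populations can refer to either null.
#'
#' @param effects An `effect_sizes` data frame.
#' @return A list `chi_sq`, `df`, `p`.
#' @export
meta_mean_test <- function(effects) {
  full <- fit_multilevel_meta(effects, moderator = FALSE, method = "ML")
  reduced <- fit_multilevel_meta(effects, moderator = FALSE, method = "ML",
                                 intercept = FALSE)
  meta_lr_test(full, reduced)
}
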