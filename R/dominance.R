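# Dominance of the evolved phenotypic change, estimated from the slopes of
# the log-odds-ratio trajectories of own-bred vs crossed populations.  The
# ancestral population is anchored at (time 0, effect 0) with zero variance,
# so slopes are fitted through the origin; the dominance coefficient is the
# ratio of the crossed to the own-bred slope (0.5 = additive, because
# crossed offspring carry the evolved paternal alleles heterozygously).

#' Map population labels to trajectory time codes
#'
#' The resurrected populations are coded as time 0 (ancestral), 1 and 2
#' (collections ~13 and ~24 years after introduction).
#'
#' @return Named integer vector.
#' @export
population_time_codes <- function() {
  c(SFB84 = 0L, VCH97 = 1L, VCH08 = 2L)
}

#' Inverse-variance weighted slope of log odds through time
#'
#' Weighted least squares through the origin: the ancestral anchor (0, 0)
#' is exact, so the model has no intercept. Weights are `1/var`; effects
#' with `var = 0` at time 0 are the anchor itself, and if every non-anchor
#' variance is zero (noiseless input) the fit is unweighted.
#'
#' @param effects Data frame with columns `log_or` and `var`, plus either
#'   `time` or `population` (mapped through [population_time_codes()]).
#' @param weighted Use inverse-variance weights (default) or ordinary LS.
#' @return A `slope_estimate` list: `slope`, `se`, `n`.
#' @export
log_odds_slope <- function(effects, weighted = TRUE) {
  if (is.null(effects$time)) {
    codes <- population_time_codes()
    if (is.null(effects$population) ||
        !all(effects$population %in% names(codes))) {
      ad_stop("ad_schema_error",
              "effects need a 'time' column or known population labels")
    }
    effects$time <- codes[effects$population]
  }
  t <- as.numeric(effects$time)
  y <- as.numeric(effects$log_or)
  v <- as.numeric(effects$var %||% rep(NA_real_, length(t)))
  keep <- t != 0 # the origin is exact and carries no information
  t <- t[keep]; y <- y[keep]; v <- v[keep]
  if (length(unique(t)) < 1L || length(t) < 1L) {
    ad_stop("ad_degenerate_error", "need effects at >= 1 nonzero time code")
  }
  if (!weighted || any(is.na(v)) || all(v == 0)) {
    w <- rep(1, length(t))
    known_var <- FALSE
  } else {
    if (any(v == 0)) {
      ad_stop("ad_schema_error", "zero sampling variance at nonzero time")
    }
    w <- 1 / v
    known_var <- TRUE
  }
  sw <- sum(w * t^2)
  slope <- sum(w * t * y) / sw
  if (known_var) {
    se <- sqrt(1 / sw)
  } else {
    # residual-based SE; zero for exactly linear (noiseless) input
    df <- max(length(t) - 1L, 1L)
    s2 <- sum(w * (y - slope * t)^2) / df
    se <- sqrt(s2 / sw)
  }
  structure(list(slope = slope, se = se, n = length(t)),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("log-odds slope: %.4f (SE %.4f, n = %d)\n", x$slope, x$se, x$n))
  invisible(x)
}

#' Estimate the dominance of the evolved change from two slopes
#'
#' `h = crossed.slope / own.slope` under the model that crossed offspring
#' carry the evolved alleles heterozygously (heterozygote effect = h x
#' homozygote effect; h = 0.5 is additive). The CI is a parametric
#' bootstrap: slopes are resampled from Normal(slope, SE^2) and the ratio's
#' percentile interval is reported. The estimate is flagged unstable when
#' the own-bred slope is indistinguishable from zero (|slope| < 2 SE).
#'
#' @param uncrossed,crossed `slope_estimate` objects for the own-bred and
#'   crossed trajectories.
#' @param n_boot Bootstrap draws (default 10000; 0 skips the CI).
#' @param seed Integer seed for the bootstrap (mandatory when `n_boot > 0`).
#' @param level CI level, default 0.95.
#' @return A `dominance_estimate` list: `h`, `ci`, `unstable`, `slopes`.
#' @export
estimate_dominance <- function(uncrossed, crossed, n_boot = 10000L,
                               seed = NULL, level = 0.95) {
  stopifnot(inherits(uncrossed, "slope_estimate"),
            inherits(crossed, "slope_estimate"))
  if (uncrossed$slope == 0) {
    ad_stop("ad_degenerate_error", "own-bred slope is exactly zero")
  }
  h <- crossed$slope / uncrossed$slope
  unstable <- abs(uncrossed$slope) < 2 * uncrossed$se
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (is.null(seed)) {
      ad_stop("ad_spec_error", "a seed is required for the bootstrap")
    }
    set.seed(as.integer(seed))
    bu <- stats::rnorm(n_boot, uncrossed$slope, uncrossed$se)
    bc <- stats::rnorm(n_boot, crossed$slope, crossed$se)
    ratio <- bc / bu
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(ratio, c(alpha, 1 - alpha), names = FALSE))
  }
  structure(list(h = h, ci = ci, level = level, unstable = unstable,
                 method = "slope ratio, parametric bootstrap CI",
                 slopes = list(own = uncrossed, crossed = crossed),
                 n_boot = as.integer(n_boot)),
            class = "dominance_estimate")
}

#' @export
print.dominance_estimate <- function(x, ...) {
  cat(sprintf("dominance h = %.3f", x$h))
  if (!is.na(x$ci[1])) {
    cat(sprintf(" [%.0f%% CI %.3f, %.3f]", 100 * x$level, x$ci[1], x$ci[2]))
  }
  if (x$unstable) cat("  (unstable: own-bred slope < 2 SE from 0)")
  cat("\n")
  cat(sprintf("  own slope %.4f (SE %.4f); crossed slope %.4f (SE %.4f)\n",
              x$slopes$own$slope, x$slopes$own$se,
              x$slopes$crossed$slope, x$slopes$crossed$se))
  invisible(x)
}
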