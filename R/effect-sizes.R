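# Extraction of log-odds-ratio effect sizes (each derived population vs the
# ancestral reference) from the pooled "control" subsets of the four
# common-garden experiments.  One effect per derived population per control
# subset per regime; its sampling variance is the squared SE of the
# population coefficient from the subset's binomial model.

#' Define the pooled control subsets
#'
#' The four control subsets: first clutches of the parental-acclimation
#' experiment; its second clutches from unexposed (control) parents; the
#' lab-microbiome tubes of the microbiome experiment; and the
#' juvenile-acclimation tubes whose phase-1 regime matched the assay
#' regime. Empty subsets are dropped.
#'
#' @param table A `survival_table`.
#' @return Named list of `survival_table` subsets.
#' @export
control_subsets <- function(table) {
  df <- as.data.frame(table)
  pick <- function(keep) {
    sub <- df[keep & !is.na(keep), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    validate_survival_table(sub)
  }
  subs <- list(
    parental_clutch1 = pick(df$experiment == "parental" & df$clutch == "1"),
    parental_clutch2_control = pick(df$experiment == "parental" &
                                      df$clutch == "2" &
                                      df$parental_treatment == "control"),
    microbiome_lab = pick(df$experiment == "microbiome" &
                            df$microbiome == "LAB"),
    juvenile_same_regime = pick(df$experiment == "juvenile" &
                                  df$phase1_regime == df$regime)
  )
  subs[!vapply(subs, is.null, logical(1))]
}

#' Extract per-population log-odds-ratio effect sizes
#'
#' For each control subset at the given regime, fits a binomial model with
#' population as the only fixed factor (family random intercept where
#' family structure exists; observation-level intercept added when the
#' Pearson dispersion ratio exceeds `overdispersion_threshold`), then
#' extracts each derived population's coefficient (the log odds ratio
#' against the ancestral reference) and its squared SE.
#'
#' @param table A `survival_table` (or a named list of subsets, as from
#'   [control_subsets()]).
#' @param regime `"T_SFB"` or `"T_VCH"`; the two regimes are always
#'   analyzed separately.
#' @param overdispersion_threshold Dispersion ratio above which the
#'   observation-level term is added (default 1.4; the decision is logged).
#' @return An `effect_sizes` data frame: `population`, `experiment`
#'   (subset label), `regime`, `log_or`, `var`, `se`.
#' @export
extract_effect_sizes <- function(table, regime,
                                 overdispersion_threshold = 1.4) {
  stopifnot(regime %in% survival_vocab()$regime)
  subs <- if (is.list(table) && !is.data.frame(table)) table
          else control_subsets(table)
  rows <- list()
  for (label in names(subs)) {
    sub <- as.data.frame(subs[[label]])
    sub <- sub[sub$regime == regime, , drop = FALSE]
    if (!nrow(sub)) next
    pops <- unique(sub$population)
    if (!"SFB84" %in% pops) {
      ad_stop("ad_subset_error",
              "control subset '%s' lacks the ancestral reference SFB84", label)
    }
    vch <- setdiff(pops, "SFB84")
    if (!length(vch)) {
      ad_stop("ad_subset_error",
              "control subset '%s' has no derived population", label)
    }
    sub <- validate_survival_table(sub)
    family_re <- !anyNA(sub$family_id)
    fit <- fit_binomial_glmm(sub, ~population, family_re = family_re)
    obs_added <- FALSE
    if (fit$df_residual > 0) {
      ratio <- assess_overdispersion(fit)
      if (ratio > overdispersion_threshold) {
        fit <- fit_binomial_glmm(sub, ~population, family_re = family_re,
                                 obs_re = TRUE)
        obs_added <- TRUE
      }
      ad_log("extract-effects", subset = label, regime = regime,
             dispersion_ratio = ratio, obs_re_added = obs_added)
    }
    for (pop in sort(vch)) {
      cn <- paste0("population", pop)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, experiment = label, regime = regime,
        log_or = unname(fit$coefficients[cn]),
        var = unname(fit$se[cn])^2, se = unname(fit$se[cn]))
    }
  }
  if (!length(rows)) ad_stop("ad_subset_error", "no control subsets at %s", regime)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_sizes", "data.frame")
  out
}

#' Write / read the tidy effects table
#'
#' @param x An `effect_sizes` data frame.
#' @param path TSV path.
#' @return `path` (writer) or the effects data frame (reader).
#' @export
write_effect_sizes <- function(x, path) {
  x <- x[order(x$experiment, x$population), , drop = FALSE]
  lines <- c("population\texperiment\tregime\tlog_or\tvar",
             if (nrow(x)) paste(x$population, x$experiment, x$regime,
                                fmt_num(x$log_or), fmt_num(x$var), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_effect_sizes
#' @export
read_effect_sizes <- function(path) {
  if (!file.exists(path)) ad_stop("ad_io_error", "file not found: %s", path)
  df <- utils::read.delim(path)
  need <- c("population", "experiment", "regime", "log_or", "var")
  if (!all(need %in% names(df))) {
    ad_stop("ad_schema_error", "effects table needs columns: %s",
            paste(need, collapse = ", "))
  }
  if (any(df$var <= 0)) ad_stop("ad_schema_error", "variances must be > 0")
  df$se <- sqrt(df$var)
  class(df) <- c("effect_sizes", "data.frame")
  df
}
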