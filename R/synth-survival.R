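# Synthetic tube-level survival data.  A design describes the tubes (factor
# levels, families, individuals per tube); an effect specification describes
# the logit-scale data-generating process: a baseline log-odds, fixed shifts
# attached to factor-level combinations, a family random intercept and an
# observation-level random intercept (the overdispersion device).

#' Specify the logit-scale data-generating process for tube survival
#'
#' @param baseline_logit Log-odds of survival for the reference cell
#'   (ancestral population at its home regime).
#' @param terms List of fixed-effect terms. Each term is a list with
#'   elements `shift` (numeric logit shift) and `when` (named character
#'   vector of `factor = level` conditions that must all hold for the shift
#'   to apply; conditions on several factors encode interactions).
#' @param sigma_family SD (>= 0) of the per-family random intercept.
#' @param sigma_obs SD (>= 0) of the observation-level (per-tube) random
#'   intercept, the standard device for binomial overdispersion.
#' @return An `effect_spec` list.
#' @export
#' @examples
#' effect_spec(0, terms = list(list(shift = 1, when = c(population = "VCH08"))))
effect_spec <- function(baseline_logit = 0, terms = list(),
                        sigma_family = 0, sigma_obs = 0) {
  stopifnot(is.numeric(baseline_logit), length(baseline_logit) == 1L)
  if (sigma_family < 0 || sigma_obs < 0) {
    ad_stop("ad_spec_error", "random-effect SDs must be >= 0")
  }
  voc <- survival_vocab()
  for (tm in terms) {
    if (!is.list(tm) || is.null(tm$shift) || is.null(tm$when)) {
      ad_stop("ad_spec_error", "each term needs elements 'shift' and 'when'")
    }
    for (f in names(tm$when)) {
      if (!f %in% names(voc)) {
        ad_stop("ad_spec_error", "unknown factor '%s' in effect term", f)
      }
      if (!tm$when[[f]] %in% voc[[f]]) {
        ad_stop("ad_spec_error", "unknown level '%s' for factor '%s'",
                tm$when[[f]], f)
      }
    }
  }
  structure(list(baseline_logit = baseline_logit, terms = terms,
                 sigma_family = sigma_family, sigma_obs = sigma_obs),
            class = "effect_spec")
}

#' Construct a tube-level experimental design
#'
#' Low-level constructor: one row per tube with its factor levels,
#' family and number of individuals. The preset constructors
#' [design_additive()], [design_parental_acclimation()],
#' [design_juvenile_acclimation()] and [design_microbiome()] reproduce the
#' study's four common-garden experiments at their reported sizes.
#'
#' @param tubes Data frame with columns `experiment`, `regime`,
#'   `population`, `cross_status`, `clutch`, `parental_treatment`,
#'   `phase1_regime`, `microbiome`, `family_id`, `n_per_tube`.
#' @return An `experiment_design` data frame.
#' @export
experiment_design <- function(tubes) {
  need <- c("experiment", "regime", "population", "cross_status", "clutch",
            "parental_treatment", "phase1_regime", "microbiome", "family_id",
            "n_per_tube")
  missing <- setdiff(need, names(tubes))
  if (length(missing)) {
    ad_stop("ad_spec_error", "design missing column(s): %s",
            paste(missing, collapse = ", "))
  }
  if (any(tubes$n_per_tube < 1)) {
    ad_stop("ad_spec_error", "individuals per tube must be >= 1")
  }
  voc <- survival_vocab()
  for (col in names(voc)) {
    x <- as.character(tubes[[col]])
    ok_na <- col %in% na_ok_factors()
    if (!all(x %in% voc[[col]] | (ok_na & is.na(x)))) {
      ad_stop("ad_spec_error", "design column %s has unknown level", col)
    }
  }
  tubes <- tubes[need]
  rownames(tubes) <- NULL
  class(tubes) <- c("experiment_design", "data.frame")
  tubes
}

# Split `total` individuals over n_families families in tubes of tube_size,
# then spread each family's tubes round-robin over the given condition cells.
# Exact integer arithmetic: requires tube_size | total.
allocate_tubes <- function(total, n_families, cells, tube_size = 10L) {
  if (total %% tube_size != 0) {
    ad_stop("ad_spec_error", "total %d not divisible by tube size %d",
            total, tube_size)
  }
  n_tubes <- total %/% tube_size
  base <- n_tubes %/% n_families
  extra <- n_tubes %% n_families
  per_family <- rep(base, n_families) + c(rep(1L, extra),
                                          rep(0L, n_families - extra))
  out <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    idx <- (seq_len(per_family[f]) - 1L + (f - 1L)) %% nrow(cells) + 1L
    cc <- cells[idx, , drop = FALSE]
    cc$family_index <- f
    out[[f]] <- cc
  }
  res <- do.call(rbind, out)
  res$n_per_tube <- tube_size
  rownames(res) <- NULL
  res
}

blank_design_row <- function() {
  data.frame(experiment = NA_character_, regime = NA_character_,
             population = NA_character_, cross_status = NA_character_,
             clutch = NA_character_, parental_treatment = NA_character_,
             phase1_regime = NA_character_, microbiome = NA_character_,
             family_id = NA_character_, n_per_tube = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Preset design: additive genetic effects experiment
#'
#' Males from each population crossed to a common reference maternal stock
#' (`cross_status = "crossed"`), or own-population mass crosses
#' (`cross_status = "own"`); no family structure (mass crosses). 183 tubes
#' of 10 individuals split over 3 populations x 2 regimes (1830 individuals,
#' 30-31 tubes per cell).
#'
#' @param cross_status `"own"` or `"crossed"`.
#' @param total Total individuals (default 1830).
#' @return An `experiment_design`.
#' @export
design_additive <- function(cross_status = "crossed", total = 1830L) {
  cells <- expand.grid(population = c("SFB84", "VCH97", "VCH08"),
                       regime = c("T_SFB", "T_VCH"),
                       stringsAsFactors = FALSE)
  alloc <- allocate_tubes(total, 1L, cells)
  d <- blank_design_row()[rep(1, nrow(alloc)), ]
  d$experiment <- "additive"
  d$regime <- alloc$regime
  d$population <- alloc$population
  d$cross_status <- cross_status
  d$n_per_tube <- alloc$n_per_tube
  experiment_design(d)
}

#' Preset design: parental acclimation experiment
#'
#' Single-pair families per population; each family contributes first- and
#' second-clutch tubes at both regimes, and is assigned one parental
#' treatment (control / mother exposed / father exposed) applied between
#' clutches. Defaults reproduce the study's sizes: 54, 48 and 56 couples
#' and 4470, 3500 and 4720 offspring for the ancestral and the two derived
#' populations, 12,690 individuals in all, in tubes of 10.
#'
#' @param totals Named total individuals per population.
#' @param families Named number of families (couples) per population.
#' @return An `experiment_design`.
#' @export
design_parental_acclimation <- function(
    totals = c(SFB84 = 4470L, VCH97 = 3500L, VCH08 = 4720L),
    families = c(SFB84 = 54L, VCH97 = 48L, VCH08 = 56L)) {
  stopifnot(identical(names(totals), names(families)))
  cells <- expand.grid(clutch = c("1", "2"),
                       regime = c("T_SFB", "T_VCH"),
                       stringsAsFactors = FALSE)
  treatments <- c("control", "mother", "father")
  parts <- lapply(names(totals), function(pop) {
    alloc <- allocate_tubes(totals[[pop]], families[[pop]], cells)
    d <- blank_design_row()[rep(1, nrow(alloc)), ]
    d$experiment <- "parental"
    d$regime <- alloc$regime
    d$population <- pop
    d$cross_status <- "own"
    d$clutch <- alloc$clutch
    d$family_id <- sprintf("%s_f%02d", pop, alloc$family_index)
    d$parental_treatment <- treatments[(alloc$family_index - 1L) %% 3L + 1L]
    d$n_per_tube <- alloc$n_per_tube
    d
  })
  experiment_design(do.call(rbind, parts))
}

#' Preset design: juvenile acclimation experiment
#'
#' Two-phase exposure: phase-1 regime is a factor (`phase1_regime`), phase-2
#' survival is the response. 44 tubes of 10 per population x phase-1 x
#' phase-2 combination by default, with single-pair families.
#'
#' @param tubes_per_cell Tubes per (population, phase1, phase2) cell.
#' @param n_families Families per population.
#' @return An `experiment_design`.
#' @export
design_juvenile_acclimation <- function(tubes_per_cell = 44L,
                                        n_families = 30L) {
  cells <- expand.grid(phase1_regime = c("T_SFB", "T_VCH"),
                       regime = c("T_SFB", "T_VCH"),
                       stringsAsFactors = FALSE)
  parts <- lapply(c("SFB84", "VCH97", "VCH08"), function(pop) {
    alloc <- allocate_tubes(tubes_per_cell * nrow(cells) * 10L,
                            n_families, cells)
    d <- blank_design_row()[rep(1, nrow(alloc)), ]
    d$experiment <- "juvenile"
    d$regime <- alloc$regime
    d$phase1_regime <- alloc$phase1_regime
    d$population <- pop
    d$cross_status <- "own"
    d$family_id <- sprintf("%s_f%02d", pop, alloc$family_index)
    d$n_per_tube <- alloc$n_per_tube
    d
  })
  experiment_design(do.call(rbind, parts))
}

#' Preset design: microbiome experiment
#'
#' Axenic juveniles inoculated with one of three microbiota (ancestral-site,
#' derived-site, or laboratory) and assayed at both regimes; mass crosses,
#' no family structure. 563 tubes of 10 (5630 individuals) spread over the
#' 18 (population x microbiome x regime) cells by default.
#'
#' @param total Total individuals (default 5630).
#' @return An `experiment_design`.
#' @export
design_microbiome <- function(total = 5630L) {
  cells <- expand.grid(population = c("SFB84", "VCH97", "VCH08"),
                       microbiome = c("SFB", "VCH", "LAB"),
                       regime = c("T_SFB", "T_VCH"),
                       stringsAsFactors = FALSE)
  alloc <- allocate_tubes(total, 1L, cells)
  d <- blank_design_row()[rep(1, nrow(alloc)), ]
  d$experiment <- "microbiome"
  d$regime <- alloc$regime
  d$population <- alloc$population
  d$microbiome <- alloc$microbiome
  d$cross_status <- "own"
  d$n_per_tube <- alloc$n_per_tube
  experiment_design(d)
}

#' Simulate a tube-level survival experiment
#'
#' Each tube's `n_alive` is Binomial(`n_per_tube`, expit(lp)) with
#' `lp = baseline + fixed shifts + family RE + observation RE`; the family
#' random intercept is shared across all tubes of one family. Identical
#' (design, effects, seed) give byte-identical tables. The generating
#' parameters are attached as `attr(x, "truth")`.
#'
#' @param design An [experiment_design()].
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @return A `survival_table` with one row per tube.
#' @export
simulate_survival_experiment <- function(design, effects, seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(effects, "effect_spec"))
  set.seed(as.integer(seed))
  n <- nrow(design)
  lp <- rep(effects$baseline_logit, n)
  for (tm in effects$terms) {
    match_row <- rep(TRUE, n)
    for (f in names(tm$when)) {
      v <- as.character(design[[f]])
      match_row <- match_row & !is.na(v) & v == tm$when[[f]]
    }
    lp <- lp + tm$shift * match_row
  }
  fam <- as.character(design$family_id)
  fam_levels <- unique(fam[!is.na(fam)])
  if (length(fam_levels) && effects$sigma_family > 0) {
    re <- stats::rnorm(length(fam_levels), 0, effects$sigma_family)
    names(re) <- fam_levels
    lp <- lp + ifelse(is.na(fam), 0, re[fam])
  }
  if (effects$sigma_obs > 0) {
    lp <- lp + stats::rnorm(n, 0, effects$sigma_obs)
  }
  p <- stats::plogis(lp)
  n_total <- as.integer(design$n_per_tube)
  n_alive <- stats::rbinom(n, n_total, p)
  out <- as.data.frame(design)
  out$n_per_tube <- NULL
  out$tube_id <- sprintf("%s_%05d", out$experiment, seq_len(n))
  out$n_total <- n_total
  out$n_alive <- n_alive
  out <- validate_survival_table(out)
  attr(out, "truth") <- list(effects = unclass(effects), seed = as.integer(seed))
  out
}
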