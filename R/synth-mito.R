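# Pooled mitochondrial sequencing simulator: per-individual base-fraction
# profiles for each lineage representative, and per-year cyst-pool profiles
# whose alternative-base fractions are binomially resampled around the true
# cumulative frequencies, with a symmetric per-base error.

#' Simulate a mitochondrial sequencing dataset from a mitotype population
#'
#' Emits a long base-fraction table covering every SNP position, for the
#' population's lineage representatives (one "individual" sample each) and
#' one pool sample per year (optionally replicated). Pool counts at a
#' position are Multinomial(coverage, q) with `q` mixing the true
#' alternative-base frequency and a symmetric base error applied at rate
#' `error_rate / 3` to each non-true base; coverage is Poisson around the
#' mean. In analytic mode (infinite-coverage limit) fractions equal their
#' expectations exactly and coverages are fixed at their means.
#'
#' @param pop A [mitotype_population()].
#' @param mean_coverage Mean pool coverage (>= 1; Poisson per position).
#' @param individual_coverage Mean coverage for individual samples.
#' @param error_rate Per-base error rate in `[0, 0.01]`.
#' @param seed Integer seed.
#' @param analytic Infinite-coverage noiseless mode.
#' @param replicate_years Years whose pool is sequenced twice with
#'   independent noise (replicate suffixes `_r1`, `_r2`).
#' @return A list: `table` (a `base_fraction_table` with `samples`,
#'   `reference` and `excluded_regions` attributes), `genotypes`
#'   (data frame of carried SNPs per individual), `truth`
#'   (per-year true SNP frequencies, as from [population_true_freqs()]).
#' @export
simulate_mito_dataset <- function(pop, mean_coverage = 3000L,
                                  individual_coverage = 200L,
                                  error_rate = 0.001, seed = 1L,
                                  analytic = FALSE,
                                  replicate_years = integer(0)) {
  stopifnot(inherits(pop, "mitotype_population"))
  if (error_rate < 0 || error_rate > 0.01) {
    ad_stop("ad_spec_error", "error_rate must lie in [0, 0.01]")
  }
  if (mean_coverage < 1) ad_stop("ad_spec_error", "mean_coverage must be >= 1")
  set.seed(as.integer(seed))
  snps <- population_snps(pop)
  truth <- population_true_freqs(pop)
  bases <- c("A", "C", "G", "T")

  base_probs <- function(ref, alt, f) {
    # each read's true base is alt w.p. f, ref otherwise; sequencing error
    # moves it to each of the three other bases at error_rate/3
    q <- stats::setNames(rep(error_rate / 3, 4), bases)
    q[alt] <- f * (1 - error_rate) + (1 - f) * error_rate / 3
    q[ref] <- (1 - f) * (1 - error_rate) + f * error_rate / 3
    q
  }
  emit <- function(sample_id, position, ref, alt, f, mean_cov) {
    q <- base_probs(ref, alt, f)
    if (analytic) {
      cov <- as.integer(mean_cov)
      frac <- q
    } else {
      cov <- max(1L, stats::rpois(1, mean_cov))
      counts <- stats::rmultinom(1, cov, q)[, 1]
      frac <- counts / cov
    }
    data.frame(sample = sample_id, position = position, base = bases,
               fraction = unname(frac), coverage = cov)
  }

  rows <- list()
  meta <- list()
  # individual samples: each lineage representative once
  carried <- list()
  for (g in pop$groups) {
    for (ind in names(g$members)) {
      sid <- paste0("ind_", ind)
      own <- snps[(snps$type == "shared" & snps$mitotype == g$id) |
                    (snps$type == "private" & !is.na(snps$individual) &
                       snps$individual == ind), , drop = FALSE]
      carried[[length(carried) + 1L]] <- if (nrow(own)) {
        data.frame(individual = ind, position = own$position,
                   ref = own$ref, alt = own$alt, type = own$type)
      }
      has <- snps$position %in% own$position
      for (i in seq_len(nrow(snps))) {
        rows[[length(rows) + 1L]] <-
          emit(sid, snps$position[i], snps$ref[i], snps$alt[i],
               if (has[i]) 1 else 0, individual_coverage)
      }
      meta[[length(meta) + 1L]] <- data.frame(
        sample = sid, type = "individual",
        year = g$members[[ind]]$year_sampled, replicate = NA_character_)
    }
  }
  # pool samples per year (replicated where requested)
  for (yr in pop$years) {
    reps <- if (yr %in% replicate_years) c("r1", "r2") else NA_character_
    tf <- truth[truth$year == yr, ]
    tf <- tf[match(snps$position, tf$position), ]
    for (rp in reps) {
      sid <- if (is.na(rp)) paste0("pool_", yr) else
        paste0("pool_", yr, "_", rp)
      for (i in seq_len(nrow(snps))) {
        rows[[length(rows) + 1L]] <-
          emit(sid, snps$position[i], snps$ref[i], snps$alt[i],
               tf$freq[i], mean_coverage)
      }
      meta[[length(meta) + 1L]] <- data.frame(
        sample = sid, type = "pool", year = yr,
        replicate = if (is.na(rp)) NA_character_ else rp)
    }
  }
  tab <- validate_base_fraction_table(do.call(rbind, rows))
  attr(tab, "samples") <- do.call(rbind, meta)
  attr(tab, "reference") <- data.frame(position = snps$position,
                                       ref = snps$ref)
  attr(tab, "excluded_regions") <- pop$excluded_regions
  list(table = tab,
       genotypes = do.call(rbind, carried),
       truth = truth)
}

#' Marginal draws of a pooled alternative-base fraction
#'
#' The multinomial read-count model of [simulate_mito_dataset()],
#' marginalised to the alternative base: coverage is Poisson around the
#' mean (floored at 1) and the alternative-base count is
#' Binomial(coverage, f(1-e) + (1-f)e/3).
#'
#' @param f True alternative-base frequency.
#' @param mean_coverage Mean coverage.
#' @param error_rate Per-base error rate.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of `n` observed fractions.
#' @export
pool_fraction_draws <- function(f, mean_coverage, error_rate = 0, n = 1,
                                seed = 1) {
  set.seed(as.integer(seed))
  cov <- pmax(1L, stats::rpois(n, mean_coverage))
  q <- f * (1 - error_rate) + (1 - f) * error_rate / 3
  stats::rbinom(n, cov, q) / cov
}
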