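# Synthetic own-bred vs crossed log-odds trajectories with a known
# dominance coefficient, for parameter-recovery tests of the dominance
# estimator.  The crossed offspring carry the evolved (paternal) alleles
# heterozygously, so under the single-locus-equivalent aggregation their
# expected log-odds shift is h times the own-bred (homozygous) shift.

#' Simulate log-odds effect trajectories for own-bred and crossed populations
#'
#' Time codes index the resurrected populations (ancestral = 0, later
#' collections = 1, 2, ...). The own-bred ("own") effect at time `t` has
#' mean `delta * t`; the crossed effect has mean `h_true * delta * t`;
#' both are perturbed by Normal(0, `sampling_sd`^2) noise, and the sampling
#' variance `sampling_sd^2` is attached to every non-anchor effect.
#'
#' @param h_true Dominance coefficient in `[0, 1]` (0 recessive,
#'   0.5 additive, 1 dominant).
#' @param delta Per-time-step log-odds shift for own-bred (homozygous)
#'   populations.
#' @param times Integer time codes; must be nonempty.
#' @param sampling_sd Sampling SD (>= 0) of each observed effect.
#' @param seed Integer seed.
#' @return A data frame of effects: `time`, `cross_status`, `log_or`, `var`.
#' @export
simulate_adaptation_history <- function(h_true, delta, times = 0:2,
                                        sampling_sd = 0.1, seed = 1) {
  if (h_true < 0 || h_true > 1) {
    ad_stop("ad_spec_error", "h_true must lie in [0, 1]")
  }
  if (!length(times)) ad_stop("ad_spec_error", "times must be nonempty")
  if (sampling_sd < 0) ad_stop("ad_spec_error", "sampling_sd must be >= 0")
  set.seed(as.integer(seed))
  times <- as.numeric(times)
  mk <- function(status, slope) {
    mu <- slope * times
    y <- mu + if (sampling_sd > 0) stats::rnorm(length(times), 0, sampling_sd)
         else 0
    y[times == 0] <- 0 # the ancestral population is its own reference
    data.frame(time = times, cross_status = status, log_or = y,
               var = ifelse(times == 0, 0, sampling_sd^2))
  }
  out <- rbind(mk("own", delta), mk("crossed", h_true * delta))
  attr(out, "truth") <- list(h_true = h_true, delta = delta,
                             sampling_sd = sampling_sd)
  out
}
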