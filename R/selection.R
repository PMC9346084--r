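# Deterministic and stochastic Wright-Fisher trajectories of a beneficial
# allele A with dominance, fitnesses 1 : 1+hs : 1+s for aa : Aa : AA, and a
# sweep-feasibility report.  Stochastic runs sample 2N allele copies
# binomially in frequency space, so runtime per replicate is O(generations)
# regardless of N.

#' Parameters for a single-locus selection model
#'
#' @param s Selection coefficient (>= 0); fitnesses are 1, 1+h*s, 1+s for
#'   the aa, Aa and AA genotypes. "Recessive" beneficial alleles have
#'   h = 0 on this scale, additive h = 0.5.
#' @param h Dominance of the beneficial allele, in `[0, 1]`.
#' @param N Diploid population size (>= 1).
#' @param p0 Initial allele frequency in `[0, 1]`; default `1/(2N)`,
#'   a single new mutant copy.
#' @param generations Number of generations to iterate (>= 0).
#' @return A validated `selection_params` list.
#' @export
#' @examples
#' selection_params(s = 0.3, h = 0, N = 1e6, p0 = 0.5, generations = 1)
selection_params <- function(s, h, N, p0 = 1 / (2 * N), generations) {
  if (s < 0) ad_stop("ad_spec_error", "s must be >= 0")
  if (h < 0 || h > 1) ad_stop("ad_spec_error", "h must lie in [0, 1]")
  if (N < 1 || N != round(N)) ad_stop("ad_spec_error", "N must be an integer >= 1")
  if (p0 < 0 || p0 > 1) ad_stop("ad_spec_error", "p0 must lie in [0, 1]")
  if (generations < 0 || generations != round(generations)) {
    ad_stop("ad_spec_error", "generations must be an integer >= 0")
  }
  structure(list(s = s, h = h, N = N, p0 = p0,
                 generations = as.integer(generations)),
            class = "selection_params")
}

#' Standing-variation starting frequency preset
#'
#' Mutation-selection balance for a (partially) recessive deleterious state
#' of the ancestral allele: `p0 = sqrt(mu / s)`.
#'
#' @param s Selection coefficient.
#' @param mu Mutation rate per generation (default 1e-8).
#' @return Starting frequency.
#' @export
standing_variation_p0 <- function(s, mu = 1e-8) sqrt(mu / s)

# One generation of the deterministic recursion (vectorised over p).
selection_update <- function(p, s, h) {
  wbar <- p^2 * (1 + s) + 2 * p * (1 - p) * (1 + h * s) + (1 - p)^2
  (p^2 * (1 + s) + p * (1 - p) * (1 + h * s)) / wbar
}

#' Deterministic allele-frequency trajectory under selection
#'
#' Iterates `p' = [p^2 (1+s) + p(1-p)(1+h s)] / wbar` with
#' `wbar = p^2 (1+s) + 2 p (1-p)(1+h s) + (1-p)^2`.
#'
#' @param params A [selection_params()] object.
#' @return Numeric vector `p_0, ..., p_G` of length `generations + 1`.
#' @export
deterministic_trajectory <- function(params) {
  stopifnot(inherits(params, "selection_params"))
  p <- numeric(params$generations + 1L)
  p[1] <- params$p0
  for (t in seq_len(params$generations)) {
    p[t + 1L] <- selection_update(p[t], params$s, params$h)
  }
  p
}

#' Stochastic Wright-Fisher trajectories
#'
#' Each generation draws `2N` allele copies binomially with success
#' probability equal to the deterministic update of the current frequency.
#' Sampling is done in frequency space (never individual-based), so
#' `N = 1e7` costs the same as `N = 100`.
#'
#' @param params A [selection_params()] object.
#' @param n_replicates Number of independent trajectories.
#' @param seed Integer seed.
#' @return A `(generations + 1) x n_replicates` matrix of frequencies.
#' @export
wright_fisher_trajectory <- function(params, n_replicates, seed) {
  stopifnot(inherits(params, "selection_params"), n_replicates >= 1)
  set.seed(as.integer(seed))
  two_n <- 2 * params$N
  p <- matrix(0, nrow = params$generations + 1L, ncol = n_replicates)
  p[1, ] <- round(params$p0 * two_n) / two_n # p0 as a realisable count
  for (t in seq_len(params$generations)) {
    expected <- selection_update(p[t, ], params$s, params$h)
    p[t + 1L, ] <- stats::rbinom(n_replicates, two_n, expected) / two_n
  }
  p
}

#' Sweep feasibility report
#'
#' Combines the deterministic recursion and stochastic replicates into a
#' report of whether an allele with the given selection and dominance
#' parameters can plausibly reach `target_freq` within the stated number of
#' generations.
#'
#' @param params A [selection_params()] object.
#' @param target_freq Target frequency in `(0, 1]`.
#' @param n_replicates Stochastic replicates.
#' @param seed Integer seed.
#' @return A `sweep_report` list: inputs, deterministic final frequency,
#'   deterministic generations to target (NA if never reached), and the
#'   fraction of stochastic replicates at or above the target in the final
#'   generation.
#' @export
sweep_feasibility <- function(params, target_freq, n_replicates = 100L,
                              seed = 1L) {
  stopifnot(inherits(params, "selection_params"))
  if (target_freq <= 0 || target_freq > 1) {
    ad_stop("ad_spec_error", "target_freq must lie in (0, 1]")
  }
  det <- deterministic_trajectory(params)
  hit <- which(det >= target_freq)
  gen_to_target <- if (length(hit)) hit[1] - 1L else NA_integer_
  traj <- wright_fisher_trajectory(params, n_replicates, seed)
  frac <- mean(traj[nrow(traj), ] >= target_freq)
  out <- structure(list(params = params, target_freq = target_freq,
                        n_replicates = as.integer(n_replicates),
                        seed = as.integer(seed),
                        deterministic_final = det[length(det)],
                        generations_to_target = gen_to_target,
                        fraction_reaching_target = frac,
                        deterministic = det, stochastic = traj),
                   class = "sweep_report")
  ad_log("sweep", s = params$s, h = params$h, N = params$N, p0 = params$p0,
         generations = params$generations, target = target_freq,
         deterministic_final = out$deterministic_final,
         fraction_reaching_target = frac)
  out
}

#' @export
print.sweep_report <- function(x, ...) {
  p <- x$params
  cat(sprintf("sweep feasibility: s = %g, h = %g, N = %g, p0 = %g, G = %d\n",
              p$s, p$h, p$N, p$p0, p$generations))
  cat(sprintf("  deterministic final frequency: %.6g\n", x$deterministic_final))
  cat(sprintf("  deterministic generations to reach %.3g: %s\n", x$target_freq,
              if (is.na(x$generations_to_target)) "never"
              else as.character(x$generations_to_target)))
  cat(sprintf("  stochastic replicates at/above target at G: %.3f (of %d)\n",
              x$fraction_reaching_target, x$n_replicates))
  invisible(x)
}
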