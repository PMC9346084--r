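# Run configuration: one global seed, per-stage parameter blocks with
# defaults, unknown keys rejected by name.

config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    verbosity = "info",
    survival_sim = list(
      experiment = "parental",
      baseline_logit = 0.5,
      population_shift_VCH97 = 0.6,
      population_shift_VCH08 = 1.0,
      sigma_family = 0.5,
      sigma_obs = 0.3
    ),
    mito_sim = list(
      mean_coverage = 3000L,
      individual_coverage = 200L,
      error_rate = 0.001,
      analytic = FALSE
    ),
    glmm = list(
      overdispersion_threshold = 1.4
    ),
    meta = list(
      method = "REML"
    ),
    dominance = list(
      n_boot = 10000L,
      weighted = TRUE
    ),
    sweep = list(
      s = 0.3, h = 0.1, N = 1e6, p0 = NA_real_,
      generations = 100L, target = 0.5, replicates = 100L
    ),
    mitotypes = list(
      min_alt_fraction = 0.8,
      min_coverage = 20L
    )
  )
}

#' Build a validated run configuration
#'
#' Merges user-supplied values over the stage defaults. Unknown top-level
#' keys or unknown keys inside a stage block raise a named
#' `ad_config_error`; every stage block has complete defaults so an empty
#' configuration is valid.
#'
#' @param x A named list (e.g. parsed from YAML) or `NULL` for defaults.
#' @return A `run_config` list.
#' @export
#' @examples
#' cfg <- run_config(list(seed = 42, sweep = list(h = 0.5)))
#' cfg$sweep$h
run_config <- function(x = NULL) {
  def <- config_defaults()
  if (is.null(x)) x <- list()
  if (!is.list(x)) ad_stop("ad_config_error", "configuration must be a list")
  unknown <- setdiff(names(x), names(def))
  if (length(unknown)) {
    ad_stop("ad_config_error", "unknown configuration key(s): %s",
            paste(unknown, collapse = ", "))
  }
  out <- def
  for (k in names(x)) {
    if (is.list(def[[k]])) {
      if (!is.list(x[[k]])) {
        ad_stop("ad_config_error", "stage block '%s' must be a list", k)
      }
      bad <- setdiff(names(x[[k]]), names(def[[k]]))
      if (length(bad)) {
        ad_stop("ad_config_error", "unknown key(s) in stage '%s': %s",
                k, paste(bad, collapse = ", "))
      }
      out[[k]][names(x[[k]])] <- x[[k]]
    } else {
      out[[k]] <- x[[k]]
    }
  }
  if (!is.numeric(out$seed) || length(out$seed) != 1L || out$seed < 0) {
    ad_stop("ad_config_error", "seed must be a single integer >= 0")
  }
  out$seed <- as.integer(out$seed)
  out$verbosity <- match.arg(out$verbosity, c("quiet", "info", "debug"))
  class(out) <- c("run_config", "list")
  out
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ad_stop("ad_io_error", "file not found: %s", path)
  run_config(yaml::read_yaml(path))
}
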