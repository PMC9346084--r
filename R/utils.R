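# Internal helpers: classed conditions, seed substreams, key=value logging.

ad_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "artemiadapt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage draws its random numbers from a substream derived
#' deterministically from the global seed and the stage name, so a stage can
#' be re-run in isolation and still reproduce the run it belonged to.
#'
#' @param seed Global integer seed (>= 0).
#' @param stage Stage name, e.g. `"simulate-survival"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "meta") != stage_seed(1, "sweep")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps results in integer range
  h <- (seed %% m)
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h)
}

ad_verbosity <- function() {
  v <- getOption("artemiadapt.verbosity", "info")
  match.arg(v, c("quiet", "info", "debug"))
}

# key=value logging; every fitted number a stage produces is echoed here.
ad_log <- function(stage, ..., level = "info") {
  rank <- c(quiet = 0L, info = 1L, debug = 2L)
  if (rank[[level]] > rank[[ad_verbosity()]]) return(invisible(NULL))
  vals <- list(...)
  kv <- vapply(names(vals), function(k) {
    v <- vals[[k]]
    if (is.numeric(v)) v <- paste(format(v, digits = 8), collapse = ",")
    paste0(k, "=", paste(as.character(v), collapse = ","))
  }, character(1))
  message(paste(c(paste0("stage=", stage), kv), collapse = " "))
  invisible(NULL)
}

fmt_num <- function(x) {
  # canonical float formatting for on-disk tables: 9 significant digits,
  # enough for exact value round trips at the precision the tables carry
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "NA"
  out
}
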