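# The mitochondrial pipeline downstream of read mapping: SNP calling from
# base-fraction tables, shared/private classification, mitotype definition
# with a sharing dendrogram, per-year frequency envelopes from pooled
# samples, the no-recombination consistency check, and replicate
# concordance.

in_excluded <- function(position, excluded) {
  if (is.null(excluded) || !nrow(excluded)) return(rep(FALSE, length(position)))
  out <- rep(FALSE, length(position))
  for (i in seq_len(nrow(excluded))) {
    out <- out | (position >= excluded$start[i] & position <= excluded$end[i])
  }
  out
}

resolve_reference <- function(table, samples, reference) {
  if (!is.null(reference)) return(reference)
  reference <- attr(table, "reference")
  if (!is.null(reference)) return(reference)
  # fall back: the majority base across individual samples at each position
  ind <- samples$sample[samples$type == "individual"]
  sub <- table[table$sample %in% ind, ]
  agg <- stats::aggregate(fraction ~ position + base, sub, sum)
  agg <- agg[order(agg$position, -agg$fraction), ]
  ref <- agg[!duplicated(agg$position), c("position", "base")]
  names(ref) <- c("position", "ref")
  ref
}

#' Call SNPs in individually sequenced samples
#'
#' A position is a variant in an individual iff a single non-reference base
#' reaches `min_alt_fraction` at coverage of at least `min_coverage`.
#' Positions inside excluded regions are dropped; only single-base
#' substitutions are considered (indels never enter base-fraction tables).
#' Individuals with more than 20% of their positions under the coverage
#' floor trigger a logged warning.
#'
#' @param table A `base_fraction_table`.
#' @param samples Sample metadata (`sample`, `type`, `year`, `replicate`);
#'   defaults to `attr(table, "samples")`.
#' @param reference Data frame `position`, `ref`; defaults to
#'   `attr(table, "reference")`, else inferred as the majority base across
#'   individuals.
#' @param min_alt_fraction Minimum alternative-base fraction (default 0.8).
#' @param min_coverage Minimum coverage (default 20).
#' @param excluded_regions Data frame `start`, `end`; defaults to
#'   `attr(table, "excluded_regions")`.
#' @return A `snp_calls` data frame: `individual`, `position`, `ref`,
#'   `alt`, `fraction`, `coverage`.
#' @export
call_individual_snps <- function(table, samples = NULL, reference = NULL,
                                 min_alt_fraction = 0.8, min_coverage = 20L,
                                 excluded_regions = NULL) {
  samples <- samples %||% attr(table, "samples")
  if (is.null(samples)) {
    ad_stop("ad_schema_error", "sample metadata required to flag individuals")
  }
  excluded <- excluded_regions %||% attr(table, "excluded_regions")
  ref <- resolve_reference(table, samples, reference)
  ind_samples <- samples[samples$type == "individual", , drop = FALSE]
  if (!nrow(ind_samples)) {
    ad_stop("ad_schema_error", "no individual samples in metadata")
  }
  df <- as.data.frame(table)
  df <- df[df$sample %in% ind_samples$sample, , drop = FALSE]
  df <- df[!in_excluded(df$position, excluded), , drop = FALSE]
  df$ref <- ref$ref[match(df$position, ref$position)]
  df <- df[!is.na(df$ref), , drop = FALSE]
  calls <- df[df$base != df$ref &
                df$fraction >= min_alt_fraction &
                df$coverage >= min_coverage, , drop = FALSE]
  # low-coverage warning per individual
  for (sid in ind_samples$sample) {
    sub <- df[df$sample == sid, ]
    if (!nrow(sub)) next
    pos_cov <- tapply(sub$coverage, sub$position, max)
    low <- mean(pos_cov < min_coverage)
    if (low > 0.2) {
      ad_log("mitotypes", warning = "low_coverage", sample = sid,
             fraction_below_floor = low)
      warning(sprintf("individual %s: %.0f%% of positions below coverage %d",
                      sid, 100 * low, min_coverage))
    }
  }
  ind_map <- stats::setNames(
    sub("^ind_", "", ind_samples$sample), ind_samples$sample)
  out <- data.frame(individual = unname(ind_map[calls$sample]),
                    position = calls$position, ref = calls$ref,
                    alt = calls$base, fraction = calls$fraction,
                    coverage = calls$coverage)
  out <- out[order(out$position, out$individual), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_calls", "data.frame")
  out
}

#' Classify calls as shared or private
#'
#' A variant (position + alternative base) is shared iff carried by at
#' least two individuals, private iff carried by exactly one.
#'
#' @param calls A `snp_calls` data frame.
#' @return The calls with columns `class` and `n_carriers` added; counts of
#'   each class are logged.
#' @export
classify_shared_private <- function(calls) {
  if (!nrow(calls)) {
    calls$class <- character(0); calls$n_carriers <- integer(0)
    return(calls)
  }
  key <- paste(calls$position, calls$alt, sep = ":")
  carriers <- tapply(calls$individual, key, function(x) length(unique(x)))
  calls$n_carriers <- as.integer(carriers[key])
  calls$class <- ifelse(calls$n_carriers >= 2, "shared", "private")
  n_shared <- length(unique(key[calls$class == "shared"]))
  n_private <- length(unique(key[calls$class == "private"]))
  ad_log("mitotypes", n_shared_snps = n_shared, n_private_snps = n_private)
  attr(calls, "counts") <- c(shared = n_shared, private = n_private)
  calls
}

#' Define mitotypes from classified calls
#'
#' Individuals with identical shared-SNP profiles form one mitotype;
#' individuals with no shared SNPs become singleton mitotypes. Profiles
#' that partially overlap (neither nested nor disjoint — a pattern
#' implying recombination) are flagged, never merged. A single-linkage
#' dendrogram on the Hamming distance between shared-SNP profiles is
#' attached (singletons, at mutual distance zero, group together).
#'
#' @param calls Classified calls (from [classify_shared_private()]).
#' @param individuals Character vector of all sequenced individuals
#'   (defaults to those appearing in `calls`; individuals without any call
#'   still form singleton mitotypes when listed here).
#' @return A `mitotype_set`: list of mitotypes (`id`, `members`,
#'   `shared_snps`, `private_snps`, `singleton`), `newick` dendrogram
#'   string (NULL with < 2 individuals), `conflicts`.
#' @export
define_mitotypes <- function(calls, individuals = NULL) {
  individuals <- individuals %||% unique(calls$individual)
  individuals <- sort(as.character(individuals))
  shared <- calls[calls$class == "shared", , drop = FALSE]
  priv <- calls[calls$class == "private", , drop = FALSE]
  keys <- sort(unique(paste(shared$position, shared$alt, sep = ":")))
  prof <- matrix(0L, length(individuals), length(keys),
                 dimnames = list(individuals, keys))
  if (nrow(shared)) {
    k <- paste(shared$position, shared$alt, sep = ":")
    prof[cbind(match(shared$individual, individuals), match(k, keys))] <- 1L
  }
  # recombination-like conflicts: two shared SNPs whose carrier sets
  # partially overlap cannot sit on one mutation tree
  conflicts <- list()
  if (length(keys) > 1) {
    for (i in seq_len(length(keys) - 1)) {
      for (j in (i + 1):length(keys)) {
        a <- prof[, i] == 1L; b <- prof[, j] == 1L
        inter <- sum(a & b)
        if (inter > 0 && inter < sum(a) && inter < sum(b)) {
          conflicts[[length(conflicts) + 1L]] <- c(keys[i], keys[j])
        }
      }
    }
    if (length(conflicts)) {
      warning(sprintf("%d shared-SNP pair(s) with partially overlapping carriers (recombination-like); profiles not merged",
                      length(conflicts)))
    }
  }
  sig <- apply(prof, 1, paste, collapse = "")
  empty <- rowSums(prof) == 0
  mitotypes <- list()
  # multi-SNP profiles first, in order of first appearance
  for (s in unique(sig[!empty])) {
    members <- individuals[sig == s & !empty]
    snp_keys <- keys[prof[members[1], ] == 1L]
    shared_snps <- unique(shared[paste(shared$position, shared$alt, sep = ":")
                                 %in% snp_keys, c("position", "ref", "alt")])
    priv_snps <- unique(priv[priv$individual %in% members,
                             c("individual", "position", "ref", "alt")])
    mitotypes[[length(mitotypes) + 1L]] <- list(
      id = paste0("M_", paste(members, collapse = "_")),
      members = members, singleton = FALSE,
      shared_snps = shared_snps[order(shared_snps$position), , drop = FALSE],
      private_snps = priv_snps[order(priv_snps$position), , drop = FALSE])
  }
  for (m in individuals[empty]) {
    priv_snps <- unique(priv[priv$individual == m,
                             c("individual", "position", "ref", "alt")])
    mitotypes[[length(mitotypes) + 1L]] <- list(
      id = paste0("M_", m), members = m, singleton = TRUE,
      shared_snps = data.frame(position = integer(0), ref = character(0),
                               alt = character(0)),
      private_snps = priv_snps[order(priv_snps$position), , drop = FALSE])
  }
  newick <- NULL
  if (length(individuals) >= 3) {
    pm <- if (length(keys)) prof else
      matrix(0, length(individuals), 1, dimnames = list(individuals, NULL))
    d <- stats::dist(pm, method = "manhattan") # Hamming for 0/1 profiles
    hc <- stats::hclust(d, method = "single")
    newick <- ape::write.tree(ape::as.phylo(hc))
  }
  structure(list(mitotypes = mitotypes, individuals = individuals,
                 newick = newick, conflicts = conflicts),
            class = "mitotype_set")
}

#' @export
print.mitotype_set <- function(x, ...) {
  cat(sprintf("%d mitotype(s) over %d individual(s)\n",
              length(x$mitotypes), length(x$individuals)))
  for (m in x$mitotypes) {
    cat(sprintf("  %s: members {%s}, %d shared, %d private%s\n", m$id,
                paste(m$members, collapse = ", "), nrow(m$shared_snps),
                nrow(m$private_snps),
                if (m$singleton) " [singleton]" else ""))
  }
  if (length(x$conflicts)) {
    cat(sprintf("  ! %d recombination-like profile conflict(s)\n",
                length(x$conflicts)))
  }
  invisible(x)
}

# Per-year pooled frequency of each (position, alt): replicate pools of one
# year are averaged; also returns mean coverage.
pool_snp_frequencies <- function(table, samples, snp_keys) {
  pools <- samples[samples$type == "pool", , drop = FALSE]
  if (!nrow(pools)) ad_stop("ad_schema_error", "no pool samples in metadata")
  df <- as.data.frame(table)
  df <- df[df$sample %in% pools$sample, , drop = FALSE]
  df$year <- pools$year[match(df$sample, pools$sample)]
  df$key <- paste(df$position, df$base, sep = ":")
  df <- df[df$key %in% snp_keys, , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(key = character(0), year = integer(0),
                      freq = numeric(0), coverage = numeric(0)))
  }
  agg_f <- stats::aggregate(fraction ~ key + year, df, mean)
  agg_c <- stats::aggregate(coverage ~ key + year, df, mean)
  out <- merge(agg_f, agg_c, by = c("key", "year"))
  names(out) <- c("key", "year", "freq", "coverage")
  out
}

#' Per-year frequency envelopes of each mitotype
#'
#' The envelope of a multi-member mitotype in a year is the pooled
#' frequency of its most frequent shared SNP that year (per-year maximum
#' by default; set `global_argmax = TRUE` to fix the SNP at its
#' overall-maximum choice instead). Singleton mitotypes use their most
#' frequent private SNP. A mitotype SNP absent from a year's pool table is
#' treated as frequency 0, with a logged note.
#'
#' @param mset A `mitotype_set`.
#' @param table A `base_fraction_table` containing pool samples.
#' @param samples Sample metadata; defaults to `attr(table, "samples")`.
#' @param global_argmax Use one globally most frequent SNP per mitotype
#'   instead of the per-year maximum.
#' @return A `frequency_envelopes` object: `envelopes` (data frame
#'   `mitotype`, `year`, `frequency`), `snp_series` (per-SNP pooled series
#'   with coverage), `years`.
#' @export
compute_frequency_envelopes <- function(mset, table, samples = NULL,
                                        global_argmax = FALSE) {
  stopifnot(inherits(mset, "mitotype_set"))
  samples <- samples %||% attr(table, "samples")
  if (is.null(samples)) ad_stop("ad_schema_error", "sample metadata required")
  pools <- samples[samples$type == "pool", , drop = FALSE]
  years <- sort(unique(pools$year))
  all_keys <- unlist(lapply(mset$mitotypes, function(m) {
    c(paste(m$shared_snps$position, m$shared_snps$alt, sep = ":"),
      paste(m$private_snps$position, m$private_snps$alt, sep = ":"))
  }))
  freqs <- pool_snp_frequencies(table, samples, all_keys)
  lookup <- function(key, yr) {
    hit <- freqs[freqs$key == key & freqs$year == yr, ]
    if (!nrow(hit)) {
      ad_log("mitotypes", note = "snp_absent_from_pool", key = key, year = yr,
             level = "debug")
      return(c(freq = 0, coverage = NA_real_))
    }
    c(freq = hit$freq[1], coverage = hit$coverage[1])
  }
  env_rows <- list(); series_rows <- list()
  for (m in mset$mitotypes) {
    use <- if (m$singleton) m$private_snps else m$shared_snps
    use_keys <- paste(use$position, use$alt, sep = ":")
    all_m <- rbind(
      if (nrow(m$shared_snps))
        data.frame(key = paste(m$shared_snps$position, m$shared_snps$alt,
                               sep = ":"), type = "shared"),
      if (nrow(m$private_snps))
        data.frame(key = paste(m$private_snps$position, m$private_snps$alt,
                               sep = ":"), type = "private"))
    series <- NULL
    for (yr in years) {
      vals <- vapply(all_m$key, lookup, numeric(2), yr = yr)
      series_rows[[length(series_rows) + 1L]] <- data.frame(
        mitotype = m$id, snp = all_m$key, type = all_m$type, year = yr,
        frequency = vals["freq", ], coverage = vals["coverage", ])
    }
    msr <- do.call(rbind, series_rows[
      (length(series_rows) - length(years) + 1):length(series_rows)])
    env_src <- msr[msr$snp %in% use_keys, , drop = FALSE]
    if (global_argmax && nrow(env_src)) {
      tot <- tapply(env_src$frequency, env_src$snp, max)
      pick <- names(tot)[which.max(tot)]
      env_src <- env_src[env_src$snp == pick, , drop = FALSE]
    }
    for (yr in years) {
      sub <- env_src[env_src$year == yr, ]
      env_rows[[length(env_rows) + 1L]] <- data.frame(
        mitotype = m$id, year = yr,
        frequency = if (nrow(sub)) max(sub$frequency) else 0)
    }
  }
  env <- do.call(rbind, env_rows)
  rownames(env) <- NULL
  structure(list(envelopes = env,
                 snp_series = do.call(rbind, series_rows),
                 years = years),
            class = "frequency_envelopes")
}

#' @export
print.frequency_envelopes <- function(x, ...) {
  wide <- stats::reshape(x$envelopes, idvar = "mitotype", timevar = "year",
                         direction = "wide")
  names(wide) <- sub("^frequency\\.", "", names(wide))
  cat("mitotype frequency envelopes by year:\n")
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' No-recombination consistency check
#'
#' Without recombination, the summed pooled frequency of a mitotype's
#' private SNPs cannot exceed its top shared-SNP frequency. Checked per
#' multi-member mitotype and year with margin
#' `shared_max - private_sum` and a tolerance of 3 pooled-binomial SDs at
#' the observed coverages; singleton mitotypes (no shared SNPs) pass
#' trivially, as do mitotypes without private SNPs.
#'
#' @param mset A `mitotype_set`.
#' @param envelopes A `frequency_envelopes` for the same mitotypes.
#' @return Data frame: `mitotype`, `year`, `private_sum`, `shared_max`,
#'   `tolerance`, `margin`, `pass`; violations are the rows with
#'   `pass = FALSE`.
#' @export
check_no_recombination_invariant <- function(mset, envelopes) {
  stopifnot(inherits(mset, "mitotype_set"),
            inherits(envelopes, "frequency_envelopes"))
  ser <- envelopes$snp_series
  rows <- list()
  for (m in mset$mitotypes) {
    if (m$singleton || !nrow(m$private_snps)) next
    for (yr in envelopes$years) {
      sh <- ser[ser$mitotype == m$id & ser$type == "shared" &
                  ser$year == yr, ]
      pv <- ser[ser$mitotype == m$id & ser$type == "private" &
                  ser$year == yr, ]
      shared_max <- if (nrow(sh)) max(sh$frequency) else 0
      private_sum <- if (nrow(pv)) sum(pv$frequency) else 0
      binom_var <- function(f, c) ifelse(is.na(c) | c <= 0, 0,
                                         f * (1 - f) / c)
      tol <- 3 * sqrt(sum(binom_var(pv$frequency, pv$coverage)) +
                        if (nrow(sh)) {
                          i <- which.max(sh$frequency)
                          binom_var(sh$frequency[i], sh$coverage[i])
                        } else 0)
      margin <- shared_max - private_sum
      rows[[length(rows) + 1L]] <- data.frame(
        mitotype = m$id, year = yr, private_sum = private_sum,
        shared_max = shared_max, tolerance = tol, margin = margin,
        pass = margin >= -tol)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mitotype = character(0), year = integer(0),
               private_sum = numeric(0), shared_max = numeric(0),
               tolerance = numeric(0), margin = numeric(0),
               pass = logical(0))
  if (any(!out$pass)) {
    ad_log("mitotypes", invariant_violations = sum(!out$pass))
  }
  out
}

#' Squared Pearson correlation between replicate frequency vectors
#'
#' @param freqs_a,freqs_b Matched per-SNP pooled frequencies from two
#'   replicate extractions of the same year (>= 3 SNPs).
#' @return R-squared.
#' @export
replicate_concordance <- function(freqs_a, freqs_b) {
  if (length(freqs_a) != length(freqs_b) || length(freqs_a) < 3) {
    ad_stop("ad_spec_error", "need >= 3 matched SNP frequencies")
  }
  if (stats::sd(freqs_a) == 0 || stats::sd(freqs_b) == 0) {
    ad_stop("ad_degenerate_error", "zero variance in a replicate vector")
  }
  stats::cor(freqs_a, freqs_b)^2
}
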