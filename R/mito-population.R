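# A recombination-free mitochondrial population model for the synthetic
# generator.  The population is a set of maternal lineages, one per
# sequenced individual; lineages are grouped into mitotypes.  Every member
# of a mitotype carries its shared SNPs, so a shared SNP's pool frequency
# is the mitotype's cumulative (summed member-lineage) frequency.  Each
# private SNP marks a sub-clade within its carrier's lineage: its pool
# frequency is `weight * lineage frequency`.  Within a non-singleton
# member the weights sum to at most 1, which makes the no-recombination
# bound (sum of private frequencies <= top shared frequency) hold exactly;
# a singleton's most frequent private SNP has weight 1, so its envelope
# equals the lineage frequency.

check_positions <- function(pos, ref_length, excluded) {
  if (any(pos < 1 | pos > ref_length)) {
    ad_stop("ad_spec_error", "SNP position outside 1..%d", ref_length)
  }
  if (!is.null(excluded) && nrow(excluded)) {
    for (i in seq_len(nrow(excluded))) {
      if (any(pos >= excluded$start[i] & pos <= excluded$end[i])) {
        ad_stop("ad_spec_error",
                "SNP position inside excluded region %d-%d",
                excluded$start[i], excluded$end[i])
      }
    }
  }
}

#' Construct a recombination-free mitotype population
#'
#' @param ref_length Length of the circular reference (bp).
#' @param years Integer vector of sampled years.
#' @param groups List of mitotype groups. Each group is a list with `id`,
#'   `shared` (data frame `position`, `ref`, `alt`; empty or NULL for
#'   singleton groups), and `members`: a named list (individual id) of
#'   lists with `year_sampled`, `freq` (named numeric per year, the
#'   lineage frequency) and `private` (data frame `position`, `ref`,
#'   `alt`, `weight`).
#' @param excluded_regions Optional data frame (`start`, `end`) of 1-based
#'   intervals SNPs must avoid (defaults to none).
#' @return A validated `mitotype_population`.
#' @export
mitotype_population <- function(ref_length, years, groups,
                                excluded_regions = NULL) {
  years <- as.integer(years)
  all_pos <- integer(0)
  totals <- stats::setNames(numeric(length(years)), years)
  for (g in groups) {
    if (is.null(g$id) || is.null(g$members) || !length(g$members)) {
      ad_stop("ad_spec_error", "each group needs an id and >= 1 member")
    }
    shared <- g$shared
    n_shared <- if (is.null(shared)) 0L else nrow(shared)
    if (n_shared > 0 && length(g$members) < 2) {
      ad_stop("ad_spec_error",
              "group %s: shared SNPs require >= 2 members", g$id)
    }
    if (n_shared == 0 && length(g$members) != 1) {
      ad_stop("ad_spec_error",
              "group %s: a group without shared SNPs must be a singleton", g$id)
    }
    if (n_shared > 0) {
      check_positions(shared$position, ref_length, excluded_regions)
      all_pos <- c(all_pos, shared$position)
      stopifnot(all(shared$ref %in% c("A", "C", "G", "T")),
                all(shared$alt %in% c("A", "C", "G", "T")),
                all(shared$ref != shared$alt))
    }
    for (ind in names(g$members)) {
      m <- g$members[[ind]]
      if (is.null(m$freq) || !all(as.character(years) %in% names(m$freq))) {
        ad_stop("ad_spec_error",
                "member %s: lineage frequency needed for every year", ind)
      }
      f <- m$freq[as.character(years)]
      if (any(f < 0)) ad_stop("ad_spec_error", "negative lineage frequency")
      totals <- totals + f
      priv <- m$private
      if (!is.null(priv) && nrow(priv)) {
        check_positions(priv$position, ref_length, excluded_regions)
        all_pos <- c(all_pos, priv$position)
        stopifnot(all(priv$ref != priv$alt),
                  all(priv$weight >= 0 & priv$weight <= 1))
        if (n_shared > 0 && sum(priv$weight) > 1 + 1e-9) {
          ad_stop("ad_spec_error",
                  "member %s: private-SNP weights must sum to <= 1", ind)
        }
      }
    }
  }
  if (anyDuplicated(all_pos)) {
    ad_stop("ad_spec_error", "SNP position reused: %d",
            all_pos[duplicated(all_pos)][1])
  }
  if (any(totals > 1 + 1e-9)) {
    ad_stop("ad_freq_error",
            "lineage frequencies sum to > 1 in year %s",
            names(totals)[which(totals > 1 + 1e-9)[1]])
  }
  structure(list(ref_length = as.integer(ref_length), years = years,
                 groups = groups,
                 excluded_regions = excluded_regions %||%
                   data.frame(start = integer(0), end = integer(0))),
            class = "mitotype_population")
}

#' Flat SNP table of a mitotype population
#'
#' @param pop A `mitotype_population`.
#' @return Data frame: `position`, `ref`, `alt`, `type`
#'   (`shared`/`private`), `mitotype`, `individual` (NA for shared),
#'   `weight` (1 for shared).
#' @export
population_snps <- function(pop) {
  rows <- list()
  for (g in pop$groups) {
    if (!is.null(g$shared) && nrow(g$shared)) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = g$shared$position, ref = g$shared$ref,
        alt = g$shared$alt, type = "shared", mitotype = g$id,
        individual = NA_character_, weight = 1)
    }
    for (ind in names(g$members)) {
      priv <- g$members[[ind]]$private
      if (!is.null(priv) && nrow(priv)) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = priv$position, ref = priv$ref, alt = priv$alt,
          type = "private", mitotype = g$id, individual = ind,
          weight = priv$weight)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), ref = character(0),
               alt = character(0), type = character(0),
               mitotype = character(0), individual = character(0),
               weight = numeric(0))
  out[order(out$position), , drop = FALSE]
}

#' True per-year pool frequency of every SNP
#'
#' Shared SNPs: the mitotype's cumulative lineage frequency. Private SNPs:
#' `weight * carrier lineage frequency`.
#'
#' @param pop A `mitotype_population`.
#' @return Data frame: `position`, `alt`, `type`, `mitotype`,
#'   `individual`, `year`, `freq`.
#' @export
population_true_freqs <- function(pop) {
  yrs <- pop$years
  rows <- list()
  for (g in pop$groups) {
    cum <- stats::setNames(numeric(length(yrs)), yrs)
    for (ind in names(g$members)) {
      cum <- cum + g$members[[ind]]$freq[as.character(yrs)]
    }
    if (!is.null(g$shared) && nrow(g$shared)) {
      for (i in seq_len(nrow(g$shared))) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = g$shared$position[i], alt = g$shared$alt[i],
          type = "shared", mitotype = g$id, individual = NA_character_,
          year = yrs, freq = unname(cum))
      }
    }
    for (ind in names(g$members)) {
      m <- g$members[[ind]]
      if (!is.null(m$private) && nrow(m$private)) {
        f <- m$freq[as.character(yrs)]
        for (i in seq_len(nrow(m$private))) {
          rows[[length(rows) + 1L]] <- data.frame(
            position = m$private$position[i], alt = m$private$alt[i],
            type = "private", mitotype = g$id, individual = ind,
            year = yrs, freq = unname(m$private$weight[i] * f))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' True mitotype cumulative frequencies per year
#'
#' @param pop A `mitotype_population`.
#' @return Data frame: `mitotype`, `year`, `freq`.
#' @export
population_true_envelopes <- function(pop) {
  yrs <- pop$years
  rows <- lapply(pop$groups, function(g) {
    cum <- stats::setNames(numeric(length(yrs)), yrs)
    for (ind in names(g$members)) {
      cum <- cum + g$members[[ind]]$freq[as.character(yrs)]
    }
    data.frame(mitotype = g$id, year = yrs, freq = unname(cum))
  })
  do.call(rbind, rows)
}

#' The study-structure mitotype population
#'
#' A synthetic reconstruction of the published mitochondrial structure:
#' ten sequenced individuals (1-5 sampled in 1984, 6-10 in 2008), three
#' multi-member mitotypes (members 7+10, 5+6, and 2+4+8) defined by seven
#' shared SNPs in total, three singleton groups (individuals 1, 3, 9), and
#' 32 private SNPs; eight pool-sampled years between 1984 and 2008 with
#' stable lineage frequencies whose mitotype total is ~0.80. All SNP
#' positions avoid the excluded low-coverage regions. The frequencies and
#' positions are synthetic stand-ins; only the sharing structure and counts
#' follow the published description.
#'
#' @return A `mitotype_population`.
#' @export
study_mitotype_population <- function() {
  years <- c(1984L, 1987L, 1988L, 1993L, 1994L, 1997L, 1998L, 2008L)
  positions <- seq(500L, by = 347L, length.out = 39L) # all < 14045
  bases <- c("A", "C", "G", "T")
  refs <- bases[(seq_along(positions) - 1L) %% 4L + 1L]
  alts <- bases[seq_along(positions) %% 4L + 1L]
  ip <- 0L
  take <- function(n) {
    idx <- ip + seq_len(n); ip <<- ip + n
    data.frame(position = positions[idx], ref = refs[idx], alt = alts[idx])
  }
  flat <- function(x) stats::setNames(rep(x, length(years)), years)
  member <- function(year, f, n_private, weights) {
    list(year_sampled = year, freq = flat(f),
         private = cbind(take(n_private), weight = weights))
  }
  # 7 shared SNPs: 2 + 2 + 3; 32 private: 2,3,3 | 3,3 | 3,3,3 | 4,4,4
  groups <- list(
    list(id = "M_7_10", shared = take(2L), members = list(
      `7`  = member(2008L, 0.11, 2L, c(0.40, 0.25)),
      `10` = member(2008L, 0.11, 3L, c(0.35, 0.25, 0.15)))),
    list(id = "M_5_6", shared = take(2L), members = list(
      `5` = member(1984L, 0.10, 3L, c(0.40, 0.30, 0.20)),
      `6` = member(2008L, 0.10, 3L, c(0.45, 0.25, 0.15)))),
    list(id = "M_2_4_8", shared = take(3L), members = list(
      `2` = member(1984L, 0.06, 3L, c(0.40, 0.30, 0.20)),
      `4` = member(1984L, 0.06, 3L, c(0.50, 0.25, 0.15)),
      `8` = member(2008L, 0.06, 3L, c(0.45, 0.30, 0.15)))),
    list(id = "M_1", shared = NULL, members = list(
      `1` = member(1984L, 0.08, 4L, c(1, 0.5, 0.3, 0.2)))),
    list(id = "M_3", shared = NULL, members = list(
      `3` = member(1984L, 0.07, 4L, c(1, 0.6, 0.3, 0.15)))),
    list(id = "M_9", shared = NULL, members = list(
      `9` = member(2008L, 0.05, 4L, c(1, 0.5, 0.25, 0.1))))
  )
  mitotype_population(15822L, years, groups,
                      excluded_regions = study_excluded_regions())
}

#' Random mitotype population for property-based tests
#'
#' Draws a random recombination-free structure: up to `max_individuals`
#' lineages partitioned into multi-member mitotypes and singletons, up to
#' `max_snps` SNPs split into shared (>= 1 per multi-member group) and
#' private (>= 1 per singleton, so every lineage is detectable), with
#' lineage frequencies scaled so each year's total is below 1.
#'
#' @param seed Integer seed.
#' @param max_individuals,max_snps Structure bounds.
#' @param years Sampled years.
#' @return A `mitotype_population`.
#' @export
random_mitotype_population <- function(seed, max_individuals = 12L,
                                       max_snps = 60L,
                                       years = c(1984L, 1997L, 2008L)) {
  set.seed(as.integer(seed))
  n_ind <- sample(4:max_individuals, 1)
  sizes <- integer(0)
  left <- n_ind
  while (left > 0) {
    s <- sample(1:min(3, left), 1)
    if (s == 2 && left - s == 1 && stats::runif(1) < 0.5) s <- 3
    sizes <- c(sizes, s); left <- left - s
  }
  n_groups <- length(sizes)
  shared_counts <- ifelse(sizes > 1, sample(1:3, n_groups, replace = TRUE), 0L)
  n_shared <- sum(shared_counts)
  n_priv_per_ind <- sample(0:2, n_ind, replace = TRUE)
  n_priv_per_ind[cumsum(sizes)[sizes == 1]] <-
    pmax(1, n_priv_per_ind[cumsum(sizes)[sizes == 1]]) # singletons detectable
  total_snps <- n_shared + sum(n_priv_per_ind)
  if (total_snps > max_snps) {
    ad_stop("ad_spec_error", "random structure exceeded max_snps")
  }
  positions <- sort(sample(100:10000, total_snps))
  bases <- c("A", "C", "G", "T")
  refs <- sample(bases, total_snps, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(bases, r), 1), character(1))
  ip <- 0L
  take <- function(n) {
    idx <- ip + seq_len(n); ip <<- ip + n
    data.frame(position = positions[idx], ref = refs[idx], alt = alts[idx])
  }
  raw <- matrix(stats::runif(n_ind * length(years), 0.02, 1),
                n_ind, length(years))
  freqs <- sweep(raw, 2, colSums(raw), "/") * stats::runif(1, 0.5, 0.9)
  ind <- 0L
  groups <- list()
  for (gi in seq_len(n_groups)) {
    sz <- sizes[gi]
    members <- list()
    for (j in seq_len(sz)) {
      ind <- ind + 1L
      npv <- n_priv_per_ind[ind]
      priv <- if (npv > 0) {
        w <- if (sz == 1) c(1, stats::runif(max(npv - 1L, 0), 0.1, 0.9))
             else { u <- stats::runif(npv, 0.1, 1); u / sum(u) * stats::runif(1, 0.3, 1) }
        cbind(take(npv), weight = w[seq_len(npv)])
      } else NULL
      members[[as.character(ind)]] <- list(
        year_sampled = years[1],
        freq = stats::setNames(freqs[ind, ], years),
        private = priv)
    }
    groups[[gi]] <- list(
      id = sprintf("G%02d", gi),
      shared = if (sz > 1) take(shared_counts[gi]) else NULL,
      members = members)
  }
  mitotype_population(12000L, years, groups)
}
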