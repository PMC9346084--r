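# The mitochondrial pipeline: calling thresholds, excluded regions,
# shared/private classification, mitotype definition, envelopes, the
# no-recombination check, and replicate concordance.

mk_bft <- function(rows, samples, reference = NULL) {
  tab <- validate_base_fraction_table(rows)
  attr(tab, "samples") <- samples
  attr(tab, "reference") <- reference
  tab
}

ind_meta <- function(ids) {
  data.frame(sample = paste0("ind_", ids), type = "individual",
             year = 1984L, replicate = NA_character_)
}

test_that("calling applies thresholds, reference matching and exclusions", {
  samples <- ind_meta(c("1", "2"))
  ref <- data.frame(position = c(100L, 200L, 300L, 14100L),
                    ref = c("A", "A", "A", "A"))
  rows <- expand.grid(sample = samples$sample,
                      position = ref$position, stringsAsFactors = FALSE)
  rows$base <- "A"; rows$fraction <- 1; rows$coverage <- 100L
  # reference-matching everywhere: no calls
  expect_equal(nrow(call_individual_snps(mk_bft(rows, samples, ref))), 0L)

  # one alt above both floors -> exactly one call
  rows2 <- rows
  rows2$fraction[rows2$sample == "ind_1" & rows2$position == 200] <- 0.1
  rows2 <- rbind(rows2, data.frame(sample = "ind_1", position = 200L,
                                   base = "G", fraction = 0.9,
                                   coverage = 100L))
  calls <- call_individual_snps(mk_bft(rows2, samples, ref))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 200L)
  expect_equal(calls$alt, "G")

  # below the fraction floor or the coverage floor: not called
  rows3 <- rows2
  rows3$fraction[rows3$base == "G"] <- 0.7
  expect_equal(nrow(call_individual_snps(mk_bft(rows3, samples, ref))), 0L)
  rows4 <- rows2
  rows4$coverage[rows4$base == "G"] <- 10L
  expect_equal(nrow(call_individual_snps(mk_bft(rows4, samples, ref))), 0L)

  # a fixed difference inside an excluded region is dropped
  rows5 <- rows
  rows5$base[rows5$sample == "ind_1" & rows5$position == 14100] <- "T"
  calls5 <- call_individual_snps(mk_bft(rows5, samples, ref),
                                 excluded_regions = study_excluded_regions())
  expect_equal(nrow(calls5), 0L)
})

test_that("shared/private classification counts carriers", {
  calls <- data.frame(individual = c("1", "2", "3"),
                      position = c(100L, 100L, 200L),
                      ref = "A", alt = c("G", "G", "T"),
                      fraction = 1, coverage = 100L)
  cl <- classify_shared_private(calls)
  expect_equal(cl$class[cl$position == 100], c("shared", "shared"))
  expect_equal(cl$class[cl$position == 200], "private")
  expect_equal(unname(attr(cl, "counts")), c(1L, 1L))

  solo <- classify_shared_private(calls[calls$individual == "1", ])
  expect_true(all(solo$class == "private"))
})

test_that("the study sharing pattern yields six mitotypes, grouped as printed", {
  pop <- study_mitotype_population()
  ds <- simulate_mito_dataset(pop, error_rate = 0, analytic = TRUE, seed = 1)
  calls <- classify_shared_private(call_individual_snps(ds$table))
  expect_equal(unname(attr(calls, "counts")), c(7L, 32L))
  mset <- define_mitotypes(calls, individuals = as.character(1:10))
  expect_equal(length(mset$mitotypes), 6L)
  members <- lapply(mset$mitotypes, `[[`, "members")
  expect_true(all(c(list(c("10", "7"), c("5", "6"), c("2", "4", "8")),
                    list("1", "3", "9")) %in%
                    lapply(members, sort)))
  singles <- vapply(mset$mitotypes, `[[`, logical(1), "singleton")
  expect_equal(sum(singles), 3L)
  # the dendrogram groups the three no-shared-SNP individuals together:
  # zero cophenetic distance among them, positive to everyone else
  tree <- ape::read.tree(text = mset$newick)
  expect_s3_class(tree, "phylo")
  coph <- ape::cophenetic.phylo(tree)
  expect_equal(max(coph[c("1", "3", "9"), c("1", "3", "9")]), 0)
  expect_true(all(coph[c("1", "3", "9"),
                       setdiff(rownames(coph), c("1", "3", "9"))] > 0))
})

test_that("nested shared profiles split into distinct mitotypes", {
  calls <- classify_shared_private(data.frame(
    individual = c("1", "2", "3", "1", "2"),
    position = c(100L, 100L, 100L, 200L, 200L),
    ref = "A", alt = "G", fraction = 1, coverage = 100L))
  mset <- define_mitotypes(calls)
  members <- lapply(mset$mitotypes, function(m) sort(m$members))
  expect_equal(length(mset$mitotypes), 2L)
  expect_true(list(c("1", "2")) %in% members)
  expect_true(list("3") %in% members)
  expect_false(any(vapply(mset$mitotypes, `[[`, logical(1), "singleton")))
  expect_equal(length(mset$conflicts), 0L)
  # individuals 1+2 join before the nested profile {alpha} attaches
  tree <- ape::read.tree(text = define_mitotypes(
    calls, individuals = c("1", "2", "3", "4"))$newick)
  coph <- ape::cophenetic.phylo(tree)
  expect_equal(coph["1", "2"], 0)
  expect_gt(coph["1", "3"], 0)
  expect_lte(coph["1", "3"], coph["1", "4"])
})

test_that("partially overlapping profiles are flagged, not merged", {
  calls <- classify_shared_private(data.frame(
    individual = c("1", "2", "2", "3"),
    position = c(100L, 100L, 200L, 200L),
    ref = "A", alt = "G", fraction = 1, coverage = 100L))
  expect_warning(mset <- define_mitotypes(calls), "overlap")
  expect_gt(length(mset$conflicts), 0)
  expect_equal(length(mset$mitotypes), 3L) # distinct profiles stay distinct
})

test_that("four individuals without shared SNPs are four singletons", {
  calls <- classify_shared_private(data.frame(
    individual = c("1", "2", "3", "4"),
    position = c(100L, 200L, 300L, 400L),
    ref = "A", alt = "G", fraction = 1, coverage = 100L))
  mset <- define_mitotypes(calls)
  expect_equal(length(mset$mitotypes), 4L)
  expect_true(all(vapply(mset$mitotypes, `[[`, logical(1), "singleton")))
})

test_that("envelopes take the per-year maximum over the defining SNPs", {
  pool_meta <- data.frame(sample = "pool_1984", type = "pool", year = 1984L,
                          replicate = NA_character_)
  samples <- rbind(ind_meta(c("1", "2")), pool_meta)
  ref <- data.frame(position = c(100L, 200L), ref = c("A", "A"))
  ind_rows <- expand.grid(sample = c("ind_1", "ind_2"),
                          position = c(100L, 200L), stringsAsFactors = FALSE)
  ind_rows$base <- "G"; ind_rows$fraction <- 1; ind_rows$coverage <- 100L
  pool_rows <- data.frame(sample = "pool_1984", position = c(100L, 200L),
                          base = "G", fraction = c(0.12, 0.15),
                          coverage = 3000L)
  tab <- mk_bft(rbind(ind_rows, pool_rows), samples, ref)
  calls <- classify_shared_private(call_individual_snps(tab))
  mset <- define_mitotypes(calls)
  env <- compute_frequency_envelopes(mset, tab)
  expect_equal(env$envelopes$frequency, 0.15)
  # single-SNP identity case
  tab1 <- mk_bft(rbind(ind_rows[ind_rows$position == 100, ],
                       pool_rows[1, ]), samples,
                 ref[ref$position == 100, , drop = FALSE])
  calls1 <- classify_shared_private(call_individual_snps(tab1))
  env1 <- compute_frequency_envelopes(define_mitotypes(calls1), tab1)
  expect_equal(env1$envelopes$frequency, 0.12)
})

test_that("noiseless synthetic data is recovered exactly, envelopes included", {
  for (seed in c(1, 4, 9, 16, 25)) {
    pop <- random_mitotype_population(seed)
    ds <- simulate_mito_dataset(pop, error_rate = 0, analytic = TRUE,
                                seed = seed)
    inds <- unique(ds$genotypes$individual)
    calls <- classify_shared_private(call_individual_snps(ds$table))
    mset <- define_mitotypes(calls, individuals = inds)
    # true partition: members grouped by generator mitotype
    truth_parts <- lapply(pop$groups, function(g) sort(names(g$members)))
    got_parts <- lapply(mset$mitotypes, function(m) sort(m$members))
    expect_setequal(got_parts, truth_parts)
    # envelopes equal the true cumulative frequencies
    env <- compute_frequency_envelopes(mset, ds$table)
    tr <- population_true_envelopes(pop)
    id_map <- vapply(pop$groups, function(g)
      paste0("M_", paste(sort(names(g$members)), collapse = "_")),
      character(1))
    names(id_map) <- vapply(pop$groups, `[[`, character(1), "id")
    for (i in seq_len(nrow(tr))) {
      got <- env$envelopes$frequency[
        env$envelopes$mitotype == id_map[tr$mitotype[i]] &
          env$envelopes$year == tr$year[i]]
      expect_equal(got, tr$freq[i], tolerance = 1e-12)
    }
    inv <- check_no_recombination_invariant(mset, env)
    if (nrow(inv)) expect_gte(min(inv$margin), 0)
  }
})

test_that("envelope error shrinks with pooled coverage", {
  pop <- study_mitotype_population()
  err_at <- function(cov) {
    ds <- simulate_mito_dataset(pop, mean_coverage = cov, error_rate = 0,
                                seed = 31)
    calls <- classify_shared_private(call_individual_snps(ds$table))
    mset <- define_mitotypes(calls, individuals = as.character(1:10))
    env <- compute_frequency_envelopes(mset, ds$table)
    tr <- population_true_envelopes(pop)
    id_map <- vapply(pop$groups, function(g)
      paste0("M_", paste(sort(names(g$members)), collapse = "_")),
      character(1))
    names(id_map) <- vapply(pop$groups, `[[`, character(1), "id")
    tr$got <- mapply(function(m, y)
      env$envelopes$frequency[env$envelopes$mitotype == id_map[m] &
                                env$envelopes$year == y],
      tr$mitotype, tr$year)
    mean(abs(tr$got - tr$freq))
  }
  e100 <- err_at(100); e10000 <- err_at(10000)
  expect_lt(e10000, e100)
  expect_lt(e10000, 0.01)
})

test_that("a constructed violation is reported with its negative margin", {
  pool_meta <- data.frame(sample = "pool_1984", type = "pool", year = 1984L,
                          replicate = NA_character_)
  samples <- rbind(ind_meta(c("1", "2")), pool_meta)
  ref <- data.frame(position = c(100L, 200L), ref = c("A", "A"))
  ind_rows <- rbind(
    data.frame(sample = c("ind_1", "ind_2"), position = 100L, base = "G",
               fraction = 1, coverage = 100L),          # shared by both
    data.frame(sample = "ind_1", position = 200L, base = "T",
               fraction = 1, coverage = 100L))          # private to 1
  pool_rows <- data.frame(sample = "pool_1984", position = c(100L, 200L),
                          base = c("G", "T"), fraction = c(0.2, 0.3),
                          coverage = c(1e6L, 1e6L))
  tab <- mk_bft(rbind(ind_rows, pool_rows), samples, ref)
  calls <- classify_shared_private(call_individual_snps(tab))
  mset <- define_mitotypes(calls)
  env <- compute_frequency_envelopes(mset, tab)
  inv <- check_no_recombination_invariant(mset, env)
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$margin, -0.1, tolerance = 1e-9)
  expect_false(inv$pass)
})

test_that("classification is invariant to sample order", {
  pop <- random_mitotype_population(42)
  ds <- simulate_mito_dataset(pop, error_rate = 0, analytic = TRUE, seed = 2)
  tab <- as.data.frame(ds$table)
  shuf <- validate_base_fraction_table(tab[rev(seq_len(nrow(tab))), ])
  attr(shuf, "samples") <- attr(ds$table, "samples")
  attr(shuf, "reference") <- attr(ds$table, "reference")
  a <- classify_shared_private(call_individual_snps(ds$table))
  b <- classify_shared_private(call_individual_snps(shuf))
  expect_identical(attr(a, "counts"), attr(b, "counts"))
})

test_that("replicate concordance computes R-squared with guards", {
  expect_equal(replicate_concordance(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 1)
  expect_equal(replicate_concordance(c(0.1, 0.2, 0.3), c(0.1, 0.25, 0.3)),
               cor(c(0.1, 0.2, 0.3), c(0.1, 0.25, 0.3))^2)
  expect_equal(round(replicate_concordance(c(0.1, 0.2, 0.3),
                                           c(0.1, 0.25, 0.3)), 3), 0.923)
  expect_error(replicate_concordance(c(0.1, 0.2), c(0.1, 0.2)),
               class = "ad_spec_error")
  expect_error(replicate_concordance(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.3)),
               class = "ad_degenerate_error")
})
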