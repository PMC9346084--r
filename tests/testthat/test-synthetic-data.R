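# The synthetic generators: closed-form means, reproducibility, dispersion
# structure, and the study-size design presets.

test_that("survival generator matches the expit of its linear predictor", {
  # all effects zero: mean survival near expit(0) = 0.5
  tab <- simulate_survival_experiment(
    flat_design("SFB84", 1000), effect_spec(0), seed = 1)
  expect_equal(sum(tab$n_alive) / sum(tab$n_total), 0.5, tolerance = 0.015)

  # +1 logit shift for the later-derived population, no random terms
  eff <- effect_spec(0.2, terms = list(
    list(shift = 1, when = c(population = "VCH08"))))
  tab2 <- simulate_survival_experiment(
    flat_design(c("SFB84", "VCH08"), 500), eff, seed = 2)
  frac <- tapply(tab2$n_alive, tab2$population, sum) /
    tapply(tab2$n_total, tab2$population, sum)
  expect_equal(unname(frac["SFB84"]), plogis(0.2), tolerance = 0.02)
  expect_equal(unname(frac["VCH08"]), plogis(1.2), tolerance = 0.02)

  expect_error(
    effect_spec(0, terms = list(list(shift = 1, when = c(population = "XX")))),
    class = "ad_spec_error")
})

test_that("identical (design, effects, seed) give identical tables", {
  des <- recovery_design(20L)
  eff <- effect_spec(0.5, sigma_family = 0.5, sigma_obs = 0.3)
  a <- simulate_survival_experiment(des, eff, 42)
  b <- simulate_survival_experiment(des, eff, 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_survival_experiment(des, eff, 43)
  expect_false(identical(a$n_alive, c$n_alive))
})

test_that("random terms inflate tube-level dispersion iff their SD > 0", {
  des <- flat_design("SFB84", 100)
  disp <- function(sigma_obs, seed) {
    tab <- simulate_survival_experiment(
      des, effect_spec(0, sigma_obs = sigma_obs), seed)
    fit <- fit_binomial_glmm(tab, ~1)
    assess_overdispersion(fit)
  }
  ratios0 <- vapply(1:50, function(s) disp(0, s), numeric(1))
  ratios1 <- vapply(1:50, function(s) disp(1, s), numeric(1))
  expect_equal(mean(ratios0), 1, tolerance = 0.1)
  expect_gt(mean(ratios1 > 1.5), 0.95)
})

test_that("the parental-acclimation preset reproduces the study totals", {
  d <- design_parental_acclimation()
  expect_equal(sum(d$n_per_tube), 12690L)
  per_pop <- tapply(d$n_per_tube, d$population, sum)
  expect_equal(as.vector(per_pop[c("SFB84", "VCH97", "VCH08")]),
               c(4470L, 3500L, 4720L))
  expect_equal(length(unique(d$family_id[d$population == "SFB84"])), 54L)
  expect_equal(length(unique(d$family_id[d$population == "VCH97"])), 48L)
  expect_equal(length(unique(d$family_id[d$population == "VCH08"])), 56L)
  # each family has one parental treatment, evenly assigned
  byfam <- unique(d[, c("family_id", "parental_treatment")])
  expect_equal(nrow(byfam), 54L + 48L + 56L)
})

test_that("adaptation histories have the stated noiseless means", {
  h <- simulate_adaptation_history(0.5, 1, 0:2, sampling_sd = 0, seed = 1)
  crossed <- h[h$cross_status == "crossed", ]
  expect_equal(crossed$log_or[order(crossed$time)], c(0, 0.5, 1.0))
  h0 <- simulate_adaptation_history(0, 1, 0:2, sampling_sd = 0, seed = 1)
  expect_true(all(h0$log_or[h0$cross_status == "crossed"] == 0))
})

test_that("pool fraction noise follows the binomial SD at the coverage", {
  draws <- pool_fraction_draws(0.2, 3000, error_rate = 0, n = 1e4, seed = 9)
  expect_equal(sd(draws), sqrt(0.2 * 0.8 / 3000), tolerance = 0.1)
  expect_equal(mean(draws), 0.2, tolerance = 0.001)
})

test_that("noiseless pools equal the true cumulative frequencies exactly", {
  pop <- study_mitotype_population()
  ds <- simulate_mito_dataset(pop, error_rate = 0, analytic = TRUE, seed = 1)
  tab <- as.data.frame(ds$table)
  truth <- ds$truth
  pools <- attr(ds$table, "samples")
  pools <- pools[pools$type == "pool", ]
  for (i in sample(nrow(truth), 50)) {
    sid <- pools$sample[match(truth$year[i], pools$year)]
    row <- tab[tab$sample == sid & tab$position == truth$position[i] &
                 tab$base == truth$alt[i], ]
    expect_equal(row$fraction, truth$freq[i], tolerance = 1e-12)
  }
})

test_that("private-SNP pool frequencies never exceed the mitotype's shared max", {
  for (seed in c(2, 5, 8)) {
    pop <- random_mitotype_population(seed)
    tf <- population_true_freqs(pop)
    for (g in pop$groups) {
      sh <- tf[tf$mitotype == g$id & tf$type == "shared", ]
      pv <- tf[tf$mitotype == g$id & tf$type == "private", ]
      if (!nrow(sh) || !nrow(pv)) next
      for (yr in pop$years) {
        expect_lte(max(pv$freq[pv$year == yr]),
                   max(sh$freq[sh$year == yr]) + 1e-12)
      }
    }
  }
})

test_that("frequency budgets over 1 are rejected", {
  yrs <- 1984L
  member <- function(f) list(year_sampled = 1984L,
                             freq = c(`1984` = f),
                             private = data.frame(position = sample(1e3, 1),
                                                  ref = "A", alt = "C",
                                                  weight = 1))
  g <- list(list(id = "a", shared = NULL,
                 members = list(`1` = list(year_sampled = 1984L,
                                           freq = c(`1984` = 0.7),
                                           private = data.frame(
                                             position = 10L, ref = "A",
                                             alt = "C", weight = 1)))),
            list(id = "b", shared = NULL,
                 members = list(`2` = list(year_sampled = 1984L,
                                           freq = c(`1984` = 0.6),
                                           private = data.frame(
                                             position = 20L, ref = "A",
                                             alt = "G", weight = 1)))))
  expect_error(mitotype_population(1000L, yrs, g), class = "ad_freq_error")
})
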