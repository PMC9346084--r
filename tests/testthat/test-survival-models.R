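# Binomial GLMMs: oracle equivalence against brute-force likelihood
# maximization, LRT behaviour, post hoc contrasts, dispersion, effect-size
# extraction.

test_that("a perfectly balanced null gives a zero population coefficient", {
  tab <- tiny_survival_table(rep(c("SFB84", "VCH08"), each = 4),
                             rep(5L, 8), rep(10L, 8))
  fit <- fit_binomial_glmm(tab, ~population)
  expect_lt(abs(fit$coefficients["populationVCH08"]), 1e-6)
})

test_that("fixed-effect fits match brute-force likelihood maximization", {
  tab <- simulate_survival_experiment(
    flat_design(c("SFB84", "VCH97", "VCH08"), 66),
    effect_spec(0.2, terms = list(
      list(shift = 0.5, when = c(population = "VCH97")),
      list(shift = 1.0, when = c(population = "VCH08")))), seed = 3)
  expect_lte(nrow(tab), 200)
  fit <- fit_binomial_glmm(tab, ~population)
  X <- model.matrix(~population,
                    data.frame(population = factor(tab$population,
                                                   c("SFB84", "VCH97", "VCH08"))))
  oracle <- brute_force_logistic(X, tab$n_alive, tab$n_total)
  expect_equal(unname(fit$coefficients), unname(oracle$coef), tolerance = 1e-4)
  expect_equal(fit$logLik, oracle$logLik, tolerance = 1e-4)
})

test_that("swapping population labels negates the coefficient", {
  tab <- simulate_survival_experiment(
    flat_design(c("SFB84", "VCH08"), 30),
    effect_spec(0, terms = list(list(shift = 1, when = c(population = "VCH08")))),
    seed = 4)
  fit <- fit_binomial_glmm(tab, ~population)
  swapped <- as.data.frame(tab)
  swapped$population <- ifelse(swapped$population == "SFB84", "VCH08", "SFB84")
  fit2 <- fit_binomial_glmm(validate_survival_table(swapped), ~population)
  expect_equal(unname(fit$coefficients["populationVCH08"]),
               -unname(fit2$coefficients["populationVCH08"]),
               tolerance = 1e-6)
})

test_that("likelihood-ratio tests agree with the brute-force oracle", {
  tab <- simulate_survival_experiment(
    flat_design(c("SFB84", "VCH08"), 40),
    effect_spec(0.1, terms = list(list(shift = 0.6,
                                       when = c(population = "VCH08")))),
    seed = 5)
  full <- fit_binomial_glmm(tab, ~population)
  reduced <- fit_binomial_glmm(tab, ~1)
  lrt <- lr_test(full, reduced)
  pop <- factor(tab$population, c("SFB84", "VCH08"))
  o_full <- brute_force_logistic(model.matrix(~pop), tab$n_alive, tab$n_total)
  o_red <- brute_force_logistic(matrix(1, nrow(tab), 1), tab$n_alive,
                                tab$n_total)
  expect_equal(lrt$chi_sq, 2 * (o_full$logLik - o_red$logLik),
               tolerance = 1e-6)
  expect_equal(lrt$df, 1L)

  # identical models: zero statistic; reordering levels leaves it unchanged
  expect_equal(lr_test(full, full)$chi_sq, 0)
  relab <- as.data.frame(tab)
  relab <- relab[rev(seq_len(nrow(relab))), ]
  fit_r <- fit_binomial_glmm(validate_survival_table(relab), ~population)
  red_r <- fit_binomial_glmm(validate_survival_table(relab), ~1)
  expect_equal(lr_test(fit_r, red_r)$chi_sq, lrt$chi_sq, tolerance = 1e-6)

  # non-nested models are refused
  expect_error(lr_test(reduced, full), class = "ad_nesting_error")
})

test_that("LRT power exceeds 0.9 for a +1 logit effect at study-like n", {
  des <- flat_design(c("SFB84", "VCH08"), 30)
  eff <- effect_spec(0, terms = list(list(shift = 1,
                                          when = c(population = "VCH08"))))
  pvals <- vapply(1:200, function(s) {
    tab <- simulate_survival_experiment(des, eff, s)
    lr_test(fit_binomial_glmm(tab, ~population),
            fit_binomial_glmm(tab, ~1))$p
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.9)
})

test_that("dispersion ratio is near 1 under the null and errors at 0 df", {
  tab <- simulate_survival_experiment(flat_design("SFB84", 400),
                                      effect_spec(0), seed = 6)
  fit <- fit_binomial_glmm(tab, ~1)
  expect_equal(assess_overdispersion(fit), 1, tolerance = 0.15)

  sat <- tiny_survival_table(c("SFB84", "VCH08"), c(5, 6), c(10, 10))
  fit_sat <- fit_binomial_glmm(sat, ~population)
  expect_error(assess_overdispersion(fit_sat), class = "ad_degenerate_error")

  fit_obs <- fit_binomial_glmm(tab, ~1, obs_re = TRUE)
  expect_error(assess_overdispersion(fit_obs), class = "ad_spec_error")
})

test_that("pairwise z contrasts match hand arithmetic and Tukey adjustment", {
  # two independent effects 1.0 (SE 0.2) and 0.4 (SE 0.25)
  res <- pairwise_z(c(VCH97 = 1.0, VCH08 = 0.4),
                    diag(c(0.04, 0.0625)))
  expect_equal(res$z, 0.6 / sqrt(0.04 + 0.0625), tolerance = 1e-10)
  # a single contrast: adjusted p equals unadjusted
  expect_equal(res$p_adjusted, res$p)
  # equal coefficients: z = 0
  res0 <- pairwise_z(c(a = 0.5, b = 0.5), diag(c(0.01, 0.01)))
  expect_equal(res0$z, 0)

  # 3-level adjustment agrees with multcomp's single-step method
  tab <- simulate_survival_experiment(
    flat_design(c("SFB84", "VCH97", "VCH08"), 25),
    effect_spec(0, terms = list(
      list(shift = 0.4, when = c(population = "VCH97")),
      list(shift = 0.9, when = c(population = "VCH08")))), seed = 7)
  fit <- fit_binomial_glmm(tab, ~population)
  mine <- posthoc_pairwise(fit, "population")
  glht_fit <- multcomp::glht(
    fit$model, linfct = multcomp::mcp(population = "Tukey"))
  ref <- summary(glht_fit, test = multcomp::adjusted("single-step"))
  expect_equal(sort(abs(mine$z)), sort(abs(unname(ref$test$tstat))),
               tolerance = 1e-6)
  expect_equal(sort(mine$p_adjusted), sort(unname(ref$test$pvalues)),
               tolerance = 2e-3)
})

test_that("mixed-model recovery: unbiased effects, calibrated CIs, variances", {
  des <- recovery_design()
  eff <- effect_spec(0, terms = list(list(shift = 1,
                                          when = c(population = "VCH08"))),
                     sigma_family = 0.5)
  n_rep <- 60
  est <- se <- vc <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tab <- simulate_survival_experiment(des, eff, 1000 + i)
    fit <- fit_binomial_glmm(tab, ~population, family_re = TRUE)
    est[i] <- fit$coefficients["populationVCH08"]
    se[i] <- fit$se["populationVCH08"]
    vc[i] <- fit$varcomp["family"]
  }
  expect_lt(abs(mean(est) - 1), 0.1)
  coverage <- mean(est - 1.96 * se <= 1 & est + 1.96 * se >= 1)
  expect_gte(coverage, 0.85)
  expect_lt(abs(mean(vc) - 0.25) / 0.25, 0.25) # family variance within 25%
})

test_that("effect sizes reproduce 2x2 log odds ratios and subset structure", {
  # single-tube contrast: 80/100 vs 50/100 gives log OR = ln 4
  tab <- tiny_survival_table(c("SFB84", "VCH08"), c(50L, 80L), c(100L, 100L))
  eff <- extract_effect_sizes(list(toy = tab), "T_VCH")
  expect_equal(eff$log_or, log(4), tolerance = 1e-6)

  # identical survival: log OR 0
  tab0 <- tiny_survival_table(c("SFB84", "VCH08"), c(50L, 50L), c(100L, 100L))
  eff0 <- extract_effect_sizes(list(toy = tab0), "T_VCH")
  expect_lt(abs(eff0$log_or), 1e-6)

  # missing reference population is a named error
  no_ref <- tiny_survival_table(c("VCH97", "VCH08"), c(5L, 6L), c(10L, 10L))
  expect_error(extract_effect_sizes(list(toy = no_ref), "T_VCH"),
               class = "ad_subset_error")

  # the four control subsets x two derived populations = 8 effects per regime
  full <- rbind(
    simulate_survival_experiment(design_parental_acclimation(),
                                 effect_spec(0.3, sigma_family = 0.3), 11),
    simulate_survival_experiment(design_juvenile_acclimation(),
                                 effect_spec(0.3, sigma_family = 0.3), 12),
    simulate_survival_experiment(design_microbiome(), effect_spec(0.3), 13))
  full <- validate_survival_table(full)
  effs <- extract_effect_sizes(full, "T_VCH")
  expect_equal(nrow(effs), 8L)
  expect_setequal(unique(effs$experiment),
                  c("parental_clutch1", "parental_clutch2_control",
                    "microbiome_lab", "juvenile_same_regime"))
  expect_true(all(effs$var > 0))
})
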