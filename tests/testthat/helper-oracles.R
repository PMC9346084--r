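# Independent oracles and small design builders used across the suite.

options(artemiadapt.verbosity = "quiet")

# Brute-force maximization of the binomial (logistic) log-likelihood for a
# fixed-effects-only model: independent of stats::glm and lme4.
brute_force_logistic <- function(X, n_alive, n_total) {
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(n_alive * log(p) + (n_total - n_alive) * log(1 - p))
  }
  opt <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  list(coef = setNames(opt$par, colnames(X)),
       # log-likelihood including the binomial coefficient, to match glm
       logLik = -opt$value + sum(lchoose(n_total, n_alive)))
}

# Direct weighted normal equations for a through-origin regression.
wls_origin_oracle <- function(t, y, w) {
  A <- sum(w * t^2)
  list(slope = sum(w * t * y) / A, se = sqrt(1 / A))
}

# Grid search of the REML criterion for the intercept-only two-level meta
# model (known within-study variances v, per-effect experiments).
reml_grid_tau2 <- function(y, v, grid = seq(0, 2, by = 1e-4)) {
  crit <- vapply(grid, function(tau2) {
    V <- diag(v + tau2)
    Vi <- solve(V)
    X <- matrix(1, length(y), 1)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    as.numeric(determinant(V, TRUE)$modulus +
                 determinant(t(X) %*% Vi %*% X, TRUE)$modulus +
                 t(r) %*% Vi %*% r)
  }, numeric(1))
  grid[which.min(crit)]
}

# Two-population recovery design: n_fam families split between the
# ancestral and the later-derived population, tubes of 10.
recovery_design <- function(n_fam = 60L, tubes_per_family = 4L) {
  rows <- expand.grid(family = seq_len(n_fam), tube = seq_len(tubes_per_family))
  rows$population <- ifelse(rows$family <= n_fam / 2, "SFB84", "VCH08")
  experiment_design(data.frame(
    experiment = "parental", regime = "T_VCH", population = rows$population,
    cross_status = "own", clutch = "1", parental_treatment = "control",
    phase1_regime = NA_character_, microbiome = NA_character_,
    family_id = sprintf("f%02d", rows$family), n_per_tube = 10L))
}

# Minimal single-factor design without families.
flat_design <- function(populations, tubes_each, regime = "T_VCH",
                        n_per_tube = 10L) {
  experiment_design(data.frame(
    experiment = "additive", regime = regime,
    population = rep(populations, each = tubes_each),
    cross_status = "own", clutch = NA_character_,
    parental_treatment = NA_character_, phase1_regime = NA_character_,
    microbiome = NA_character_, family_id = NA_character_,
    n_per_tube = n_per_tube))
}

# Hand-built survival table from per-tube counts.
tiny_survival_table <- function(population, n_alive, n_total,
                                regime = "T_VCH") {
  validate_survival_table(data.frame(
    experiment = "additive", regime = regime, population = population,
    cross_status = "own", clutch = NA, parental_treatment = NA,
    phase1_regime = NA, microbiome = NA, family_id = NA,
    tube_id = sprintf("t%03d", seq_along(population)),
    n_total = n_total, n_alive = n_alive))
}

# Null-generating meta effect sets: k = 8 effects (2 populations x 4
# experiments), tau2 = 0.05 between experiments, study-like sampling
# variances, identical population means.
meta_null_effects <- function(seed, mu = 0.5, beta = 0, tau2 = 0.05) {
  set.seed(seed)
  exper <- rep(paste0("e", 1:4), each = 2)
  pop <- rep(c("VCH97", "VCH08"), 4)
  v <- runif(8, 0.02, 0.09)
  u <- rnorm(4, 0, sqrt(tau2))
  y <- mu + beta * (pop == "VCH08") + u[rep(1:4, each = 2)] +
    rnorm(8, 0, sqrt(v))
  data.frame(log_or = y, var = v, experiment = exper, population = pop)
}
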