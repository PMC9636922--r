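test_that("va_locus matches printed-formula arithmetic at anchor points", {
  eff <- locus_effects_set(rbind(l = c(F = 1, M = 1)))
  v <- va_locus(c(0, 1), eff, "l")
  expect_equal(v$va, c(0, 0))
  v5 <- va_locus(0.5, eff, "l")
  expect_equal(v5$va_F, 0.5); expect_equal(v5$va_M, 0.5)
  expect_equal(v5$ca_FM, 0.5); expect_equal(v5$va, 0.5)
  ## estimation-error bias: Var[a] = 0.04 at p = 0.5 removes 0.02
  nm <- c("l_a_F", "l_a_M", "l_d_F", "l_d_M")
  V <- matrix(0, 4, 4, dimnames = list(nm, nm))
  V["l_a_F", "l_a_F"] <- 0.04
  effb <- locus_effects_set(rbind(l = c(F = 1, M = 1)), vcov = V)
  vb <- va_locus(0.5, effb, "l")
  expect_equal(vb$va_F, 0.48)
  expect_equal(vb$va_M, 0.5)
})

test_that("va_locus equals the brute-force HWE substitution oracle", {
  set.seed(77)
  grid <- seq(0.01, 0.99, by = 0.07)
  for (rep in 1:6) {
    aF <- rnorm(1); aM <- rnorm(1); dF <- rnorm(1, 0, 0.5); dM <- rnorm(1, 0, 0.5)
    eff <- locus_effects_set(rbind(l = c(F = aF, M = aM)),
                             rbind(l = c(F = dF, M = dM)))
    for (p in grid) {
      got <- va_locus(p, eff, "l")
      want <- oracle_va(p, aF, dF, aM, dM)
      expect_equal(got$va_F, want$va_F, tolerance = 1e-12)
      expect_equal(got$va_M, want$va_M, tolerance = 1e-12)
      expect_equal(got$ca_FM, want$ca_FM, tolerance = 1e-12)
      expect_equal(got$va, want$va, tolerance = 1e-12)
    }
  }
})

test_that("va_small clamps and computes", {
  expect_warning(v <- va_small(0, 0.31, c(0.05, 0.02)), "clamped")
  expect_equal(v, 0)
  expect_equal(va_small(0.5, 0.31, c(0.05, 0.02)), 0.085)
  expect_equal(va_small(1, 0.31, numeric()), 0.31)
})

test_that("optimum and selection_gradient follow the displayed maps", {
  expect_equal(optimum(log(41), 9.26, 1, log(41)), 9.26)
  expect_equal(optimum(log(17), 9.26, 1, log(41)), 9.26 + log(17 / 41))
  expect_equal(optimum(log(17), 9.26, 0, log(41)), 9.26)
  sg <- selection_gradient(9.26, 9.26, -2)
  expect_equal(sg$beta, 0); expect_equal(sg$s, 0)
  sg2 <- selection_gradient(9.76, 9.26, 0, VP = 0.31)
  expect_equal(sg2$beta, -0.5); expect_equal(sg2$s, -0.155)
  expect_equal(selection_gradient(10.26, 9.26, -2)$beta, -exp(-2))
})

test_that("delta_p matches arithmetic, the exact-selection oracle, and handles zero effects", {
  eff <- locus_effects_set(rbind(l = c(F = 1, M = 1)))
  expect_equal(delta_p(0.5, eff, "l", 0), 0)
  expect_equal(delta_p(0.5, eff, "l", 0.1), 0.025, tolerance = 1e-12)
  ## first-order agreement with exact one-generation selection
  set.seed(15)
  for (rep in 1:5) {
    aF <- runif(1, 0.2, 1); aM <- runif(1, 0.2, 1)
    dF <- runif(1, -0.3, 0.3); dM <- runif(1, -0.3, 0.3)
    p <- runif(1, 0.1, 0.9)
    eff2 <- locus_effects_set(rbind(l = c(F = aF, M = aM)),
                              rbind(l = c(F = dF, M = dM)))
    beta <- 1e-3
    got <- delta_p(p, eff2, "l", beta)
    want <- oracle_delta_p_exact(p, aF, dF, aM, dM, beta)
    expect_lt(abs(got - want) / abs(want), 1e-4)
  }
  ## moderate beta still within 1% of the brute-force update
  got <- delta_p(0.4, eff, "l", 0.05)
  want <- oracle_delta_p_exact(0.4, 1, 0, 1, 0, 0.05)
  expect_lt(abs(got - want) / abs(want), 0.01)
  ## a = d = 0: no selection on the locus, dp = 0 (no error)
  eff0 <- locus_effects_set(rbind(l = c(F = 0, M = 0)))
  expect_equal(delta_p(0.5, eff0, "l", 0.3), 0)
  ## genuine degenerate configuration (zero average excess but nonzero
  ## bias-corrected variance) errors
  nm <- c("l_a_F", "l_a_M", "l_d_F", "l_d_M")
  V <- matrix(0, 4, 4, dimnames = list(nm, nm)); V["l_a_F", "l_a_F"] <- 0.04
  effd <- locus_effects_set(rbind(l = c(F = 0, M = 1)),
                            rbind(l = c(F = 0.5, M = 0)), vcov = V)
  expect_error(delta_p(0.5, effd, "l", 0.1), "vanishing")
})

test_that("forward_recursion sits at its fixed point and matches the scalar oracle", {
  eff <- default_effects()
  flow <- flow_series(1940:2000, rep(41, 61))
  pars <- adaptive_params()
  tr <- forward_recursion(pars, dynamics_constants(), age_weights(), eff, flow)
  expect_equal(tr$zbar, rep(9.26, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$p_vgll3, rep(0.72, nrow(tr)), tolerance = 1e-12)
  ## effects-free model against the independently coded scalar recursion
  eff0 <- locus_effects_set(rbind(vgll3 = c(F = 0, M = 0),
                                  six6 = c(F = 0, M = 0)))
  flow2 <- flow_series(1940:2000, c(rep(41, 13), rep(17, 48)))
  tr2 <- forward_recursion(pars, dynamics_constants(), age_weights(), eff0,
                           flow2)
  w <- age_weights()
  theta <- 9.26 + 1 * (log(flow2$flow_m3s) - log(41))
  want <- oracle_scalar_recursion(rep(9.26, 8), 0.5 * 0.31, -2, theta, w)
  expect_equal(tr2$zbar, want, tolerance = 1e-12)
  ## geometric relaxation toward the new optimum
  expect_true(all(diff(tr2$zbar[tr2$year >= 1953]) <= 1e-12))
  expect_gt(tr2$zbar[tr2$year == 2000], theta[length(theta)])
})

test_that("shifting the age structure by +2 years delays adaptation", {
  eff <- default_effects()
  flow <- flow_series(1940:2016, c(rep(41, 13), rep(17, 64)))
  pars <- adaptive_params(q = -0.5, init_zbar = rep(9.26, 8))
  pars10 <- adaptive_params(q = -0.5, init_zbar = rep(9.26, 10))
  tr0 <- forward_recursion(pars, dynamics_constants(), age_weights(), eff, flow)
  tr2 <- forward_recursion(pars10, dynamics_constants(),
                           age_weights(shift = 2), eff, flow)
  gap0 <- tr0$zbar - tr0$theta
  gap2 <- tr2$zbar - tr2$theta
  ## delayed dynamics: larger cumulative lag behind the optimum, and the
  ## shifted trajectory is everywhere at or above the unshifted one
  expect_gt(sum(gap2), sum(gap0))
  expect_true(all(gap2 - gap0 > -1e-9))
})

test_that("neg_log_posterior reduces to normalisation terms in the residual-free case", {
  eff <- default_effects()
  flow <- flow_series(1940:1990, c(rep(41, 13), rep(17, 38)))
  pars <- adaptive_params(sigma_e2 = 0.01)
  tr <- forward_recursion(pars, dynamics_constants(), age_weights(), eff, flow)
  yrs <- seq(1941, 1989, by = 2)
  i <- match(yrs, tr$year)
  se <- rep(0.05, length(yrs))
  ph <- data.frame(year = yrs, n = 50,
                   mean_ln_mass = tr$zbar[i] + pars$delta * tr$s[i],
                   se_ln_mass = se, sd_ln_mass = NA, mean_mass_kg = NA)
  nll <- neg_log_posterior(pars, list(phenotypes = ph, focal_counts = NULL,
                                      flow = flow),
                           dynamics_constants(), age_weights(), eff)
  v <- pars$sigma_e2 + se^2
  norm_only <- sum(0.5 * log(2 * pi * v))
  priors <- default_priors()
  pen <- -sum(dnorm(pars$init_zbar, 9.26, 0.14, log = TRUE)) -
    dnorm(pars$q, -2, 1, log = TRUE) -
    dnorm(qlogis(pars$h2), 0, 1, log = TRUE) -
    dnorm(qlogis(pars$delta), 0, 2.5, log = TRUE) -
    dnorm(qlogis(0.72), 0.99, 0.20, log = TRUE) -
    dnorm(qlogis(0.94), 2.94, 0.80, log = TRUE)
  expect_equal(nll, norm_only + pen, tolerance = 1e-9)
})

test_that("the optimizer objective agrees with neg_log_posterior and its gradient checks out", {
  sc <- sim_scenario(seed = 44, n_neutral = 4, catch_years = seq(1940, 2016, 2),
                     catch_n = 30)
  sim <- simulate_study(sc)
  ph <- annual_summary(sim$catch, years = 1940:2016)
  cnt <- count_alleles(sim$panel, drop_fixed = TRUE)
  fc <- NULL
  for (t in 2:3) {
    sub <- cnt[cnt$class == "focal" & cnt$period == sc$sample_plan$period[t], ]
    fc <- rbind(fc, data.frame(locus = sub$locus_id,
                               year = sc$sample_plan$year[t],
                               A = sub$T - sub$A, T = sub$T))
  }
  data <- list(phenotypes = ph, focal_counts = fc, flow = sim$flow)
  f <- salmodyn:::.make_nll(data, dynamics_constants(), age_weights(),
                            sc$effects, default_priors(), adaptive_params())
  pars <- adaptive_params(q = -1.6, b = 0.7, delta = 0.45, h2 = 0.47)
  x0 <- salmodyn:::.pack_params(pars)
  slow <- neg_log_posterior(pars, data, dynamics_constants(), age_weights(),
                            sc$effects)
  expect_equal(f(x0), slow, tolerance = 1e-9)
  ## gradient: Richardson-extrapolated numDeriv vs plain central differences
  g1 <- numDeriv::grad(f, x0)
  h <- 1e-6 * pmax(1, abs(x0))
  g2 <- vapply(seq_along(x0), function(j) {
    e <- numeric(length(x0)); e[j] <- h[j]
    (f(x0 + e) - f(x0 - e)) / (2 * h[j])
  }, numeric(1))
  expect_lt(max(abs(g1 - g2) / pmax(abs(g1), 1e-4)), 1e-6)
})

test_that("fit_dynamics runs, converges, and reports sane uncertainty", {
  sc <- sim_scenario(seed = 50)
  sim <- simulate_study(sc)
  ph <- annual_summary(sim$catch, years = 1940:2016)
  cnt <- count_alleles(sim$panel, drop_fixed = TRUE)
  fc <- NULL
  for (t in 2:3) {
    sub <- cnt[cnt$class == "focal" & cnt$period == sc$sample_plan$period[t], ]
    fc <- rbind(fc, data.frame(locus = sub$locus_id,
                               year = sc$sample_plan$year[t],
                               A = sub$T - sub$A, T = sub$T))
  }
  fit <- fit_dynamics(list(phenotypes = ph, focal_counts = fc,
                           flow = sim$flow),
                      effects = sc$effects, n_restarts = 1, seed = 3,
                      start = adaptive_params(q = -1.5, b = 0.7, delta = 0.5,
                                              h2 = 0.4))
  expect_true(any(fit$convergence == 0))
  expect_true(all(is.finite(fit$se)))
  expect_lt(abs(fit$params$q - (-2)), 2 * fit$se[["q"]] + 0.5)
  expect_s3_class(fit$trajectory, "trajectory")
  ## variance partition sums to 100 exactly
  ve <- variance_explained(fit)
  expect_equal(unname(sum(ve)), 100, tolerance = 1e-12)
})

test_that("variance_explained hits its closed-form corners", {
  ph <- data.frame(year = 1:10, n = 5, mean_ln_mass = rnorm(10),
                   se_ln_mass = 0, sd_ln_mass = NA, mean_mass_kg = NA)
  fake <- list(params = list(sigma_e2 = 0), data = list(phenotypes = ph))
  ve <- variance_explained(fake)
  expect_equal(unname(ve), c(100, 0, 0))
  fake$data$phenotypes <- ph[1:2, ]
  expect_error(variance_explained(fake), ">= 3")
})

test_that("evolvability and genetic load follow their closed forms", {
  expect_equal(evolvability(0), 0)
  expect_equal(evolvability(0.05), 100 * (exp(0.05) - 1))
  expect_equal(evolvability(0.1), 10.517, tolerance = 1e-4)
  expect_equal(genetic_load(9.26, 9.26, -2, 0), 0)
  ## closed form vs Monte-Carlo integration oracle
  set.seed(61)
  z <- rnorm(4e5, 9.26, sqrt(0.31))
  w <- exp(-0.5 * exp(-2) * (z - 9.26)^2)
  expect_lt(abs(genetic_load(9.26, 9.26, -2, 0.31) - (1 - mean(w))), 1e-3)
  expect_equal(genetic_load(9.26, 9.26, -2, 0.31),
               1 - (1 + 0.31 * exp(-2))^(-0.5), tolerance = 1e-12)
  ## monotone in the mismatch
  g <- genetic_load(9.26 + seq(0, 1, 0.1), 9.26, -2, 0.31)
  expect_true(all(diff(g) > 0))
})
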