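test_that("simulate_flow reproduces the stepped schedule and is seed-stable", {
  sc <- sim_scenario(seed = 1, flow_schedule = NULL)
  f <- simulate_flow(sc)
  expect_true(all(f$flow_m3s == 41))
  ## default schedule: 40% of 41 from 1975 on (the historical ~17 m3/s)
  f2 <- simulate_flow(sim_scenario())
  expect_equal(f2$flow_m3s[f2$year == 1976], 0.40 * 41)
  expect_equal(f2$flow_m3s[f2$year == 1950], 41)
  expect_equal(f2$flow_m3s[f2$year == 1965], 0.5 * 41)
  sc3 <- sim_scenario(seed = 8, flow_cv = 0.1)
  expect_identical(simulate_flow(sc3), simulate_flow(sc3))
})

test_that("trajectory fixed points and limits behave", {
  ## optimum constant, start at optimum -> nothing moves
  sc <- sim_scenario(params = adaptive_params(b = 0), flow_cv = 0)
  tr <- simulate_trajectory(sc)
  expect_equal(tr$zbar, rep(9.26, nrow(tr)), tolerance = 1e-12)
  expect_equal(max(abs(tr$dp_vgll3)), 0, tolerance = 1e-14)
  expect_equal(tr$p_six6, rep(0.94, nrow(tr)), tolerance = 1e-12)
  ## selection off (exp(q) -> 0): frequencies frozen even off-optimum
  sc2 <- sim_scenario(params = adaptive_params(q = -60, theta_ref = 8.0))
  tr2 <- simulate_trajectory(sc2)
  expect_equal(tr2$p_vgll3, rep(0.72, nrow(tr2)), tolerance = 1e-12)
  ## paper-like scenario: mass declines after the flow cuts, E rises
  tr3 <- simulate_trajectory(sim_scenario())
  expect_lt(tr3$zbar[tr3$year == 2016], tr3$zbar[tr3$year == 1953])
  expect_lt(tr3$p_vgll3[tr3$year == 2016], 0.72)   # L falls = E rises
  expect_lt(tr3$p_six6[tr3$year == 2016], 0.94)
  expect_true(all(diff(tr3$zbar[tr3$year >= 1953]) <= 1e-12))
})

test_that("sample_genotypes honours degenerate and asymptotic regimes", {
  ## zeta = 0: neutral frequencies identical across periods before sampling
  sc <- sim_scenario(seed = 4, zeta = c(0, 0), n_neutral = 10,
                     catch_years = 1940:1941, catch_n = 5)
  sim <- simulate_study(sc)
  nf <- attr(sim$panel, "neutral_freq")
  expect_equal(nf[1, ], nf[2, ], tolerance = 1e-14)
  expect_equal(nf[2, ], nf[3, ], tolerance = 1e-14)
  ## big sample: observed frequency within 3 binomial SE of the truth
  sc2 <- sim_scenario(seed = 6, zeta = 0.001, n_neutral = 3,
                      sample_plan = data.frame(period = c("a", "b"),
                                               year = c(1950L, 1990L),
                                               n = c(10000L, 100L),
                                               hatchery_frac = 0),
                      catch_years = 1940:1941, catch_n = 5)
  sim2 <- simulate_study(sc2)
  nf2 <- attr(sim2$panel, "neutral_freq")
  rows <- sim2$panel$info$period == "a"
  for (j in 1:3) {
    phat <- mean(sim2$panel$calls[rows, j]) / 2
    se <- sqrt(nf2[1, j] * (1 - nf2[1, j]) / (2 * 10000))
    expect_lt(abs(phat - nf2[1, j]), 3 * se + 1e-12)
  }
})

test_that("sample_catch matches the lognormal-mean oracle and the VP contract", {
  ## no genetic effects, at optimum: mean kg = exp(zbar + VP/2)/1000
  eff0 <- locus_effects_set(rbind(vgll3 = c(F = 0, M = 0),
                                  six6 = c(F = 0, M = 0)))
  sc <- sim_scenario(seed = 11, effects = eff0, n_neutral = 2,
                     params = adaptive_params(b = 0, sigma_e2 = 1e-10),
                     catch_years = 1950L, catch_n = 40000)
  sim <- simulate_study(sc)
  mkg <- mean(sim$catch$mass_kg[sim$catch$year == 1950])
  expect_equal(mkg, exp(9.26 + 0.31 / 2) / 1000, tolerance = 0.02)
  ## within-year variance of ln mass converges to VP (3% at n = 1e5)
  sc2 <- sim_scenario(seed = 12, n_neutral = 2,
                      params = adaptive_params(b = 0, sigma_e2 = 1e-10),
                      catch_years = 1950L, catch_n = 100000)
  sim2 <- simulate_study(sc2)
  v <- var(log(sim2$catch$mass_kg[sim2$catch$year == 1950] * 1000))
  expect_equal(v, 0.31, tolerance = 0.03)
  ## VP -> 0 with no genotype effects: everyone identical
  sc3 <- sim_scenario(seed = 13, effects = eff0, VP = 1e-12, n_neutral = 2,
                      params = adaptive_params(b = 0, sigma_e2 = 1e-12),
                      catch_years = 1950L, catch_n = 50)
  sim3 <- simulate_study(sc3)
  expect_lt(diff(range(sim3$catch$mass_kg[sim3$catch$year == 1950])), 1e-3)
})

test_that("generator output is reproducible bit-for-bit under a seed", {
  sc <- sim_scenario(seed = 99, n_neutral = 6, catch_years = 1940:1945,
                     catch_n = 10)
  a <- simulate_study(sc); b <- simulate_study(sc)
  expect_identical(a$panel$calls, b$panel$calls)
  expect_identical(a$catch, b$catch)
  expect_identical(a$flow, b$flow)
})

test_that("with selection off, neutral and focal frequency changes are exchangeable", {
  ## zeta = 0 and q -> -inf: both classes change only by binomial sampling.
  ## Standardized changes compared by a two-sample KS over 200 replicates.
  zn <- zf <- numeric(200)
  for (r in 1:200) {
    sc <- sim_scenario(seed = 3000 + r, zeta = 0, n_neutral = 1,
                       params = adaptive_params(q = -60),
                       sample_plan = data.frame(period = c("a", "b"),
                                                year = c(1950L, 1990L),
                                                n = c(60L, 60L),
                                                hatchery_frac = 0),
                       catch_years = 1940L, catch_n = 2)
    flow <- simulate_flow(sc)
    traj <- simulate_trajectory(sc, flow)
    pan <- sample_genotypes(traj, sc)
    cnt <- count_alleles(pan, drop_fixed = FALSE)
    std <- function(lid) {
      d <- cnt[cnt$locus_id == lid, ]
      p <- d$A / d$T
      (p[2] - p[1]) / sqrt(sum(p * (1 - p) / d$T) + 1e-12)
    }
    zn[r] <- std("snp1")
    zf[r] <- std("vgll3")
  }
  ks <- suppressWarnings(stats::ks.test(zn, zf))
  expect_gt(ks$p.value, 0.01)
})
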