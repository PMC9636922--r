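truth_a <- list(vgll3 = c(F = 0.43, M = 0.66), six6 = c(F = 0.33, M = 0.28))
truth_d <- list(vgll3 = c(F = 0.15, M = -0.15), six6 = c(F = 0, M = 0))

test_that("fit_effect_model recovers sex-specific effects and reports exclusions", {
  d <- make_effect_data(4000, truth_a, truth_d, seed = 42)
  d$origin[1:50] <- "hatchery"
  d$sex[51:80] <- "unknown"
  fit <- fit_effect_model(d)
  expect_equal(fit$n_used + fit$n_excluded, 4000)
  expect_equal(fit$n_excluded, 80)
  for (nm in c("vgll3_a_F", "vgll3_a_M", "six6_a_F", "six6_a_M")) {
    parts <- strsplit(nm, "_")[[1]]
    tr <- truth_a[[parts[1]]][[parts[3]]]
    se <- sqrt(fit$vcov[nm, nm])
    expect_lt(abs(fit$coefficients[[nm]] - tr), 3 * se)
  }
  expect_lt(abs(fit$coefficients[["vgll3_d_F"]] - 0.15),
            3 * sqrt(fit$vcov["vgll3_d_F", "vgll3_d_F"]))
})

test_that("monomorphic locus triggers a singularity error naming the term", {
  d <- make_effect_data(200, truth_a, truth_d, seed = 2)
  d$six6 <- 2L
  expect_error(fit_effect_model(d), "six6")
})

test_that("genotype_mass_ratio inverts the printed ratio algebra", {
  fake <- structure(list(
    coefficients = c(vgll3_a_M = log(3.77) / 2),
    vcov = matrix(0, 1, 1, dimnames = list("vgll3_a_M", "vgll3_a_M"))),
    class = "effect_fit")
  r <- genotype_mass_ratio(fake, "vgll3", "M", n_draws = 100)
  expect_equal(unname(r["ratio"]), 3.77, tolerance = 1e-12)
  expect_equal(unname(r["lo"]), 3.77, tolerance = 1e-9)  # degenerate CI
  ## a = 0 -> ratio exactly 1
  fake$coefficients[] <- 0
  expect_equal(unname(genotype_mass_ratio(fake, "vgll3", "M",
                                          n_draws = 100)["ratio"]), 1)
  ## determinism under seed
  d <- make_effect_data(800, truth_a, truth_d, seed = 5)
  fit <- fit_effect_model(d)
  r1 <- genotype_mass_ratio(fit, "vgll3", "M", n_draws = 2000, seed = 11)
  r2 <- genotype_mass_ratio(fit, "vgll3", "M", n_draws = 2000, seed = 11)
  expect_identical(r1, r2)
})

test_that("relabeling E <-> L flips a and inverts the ratio", {
  d <- make_effect_data(1500, truth_a, truth_d, seed = 7)
  fit1 <- fit_effect_model(d)
  d2 <- d
  d2$vgll3 <- 2L - d2$vgll3
  d2$six6 <- 2L - d2$six6
  fit2 <- fit_effect_model(d2)
  expect_equal(fit2$coefficients[["vgll3_a_M"]],
               -fit1$coefficients[["vgll3_a_M"]], tolerance = 1e-9)
  r1 <- genotype_mass_ratio(fit1, "vgll3", "M", n_draws = 100)
  r2 <- genotype_mass_ratio(fit2, "vgll3", "M", n_draws = 100)
  expect_equal(unname(r2["ratio"]), 1 / unname(r1["ratio"]), tolerance = 1e-9)
})

test_that("within year-sex centring makes effects invariant to year-sex shifts", {
  d <- make_effect_data(1200, truth_a, truth_d, seed = 8)
  fit1 <- fit_effect_model(d)
  d2 <- d
  shift <- interaction(d2$year, d2$sex)
  d2$ln_mass <- d2$ln_mass + as.numeric(shift) * 1.7
  ## period must absorb the shift: make period the year so the factor matches
  fit2 <- fit_effect_model(d2)
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-9)
})

test_that("predict_change_fraction follows the HWE mean algebra", {
  eff <- locus_effects_set(rbind(l1 = c(F = 0.5, M = 0.5)))
  ## p constant -> zero fraction
  z <- predict_change_fraction(eff, c(l1 = 0.3), c(l1 = 0.3), -1, "F")
  expect_equal(z$fraction, 0)
  ## hand-computed: a = 0.5, p 0.2 -> 0.8: predicted 0.6; observed -1.2
  h <- predict_change_fraction(eff, c(l1 = 0.2), c(l1 = 0.8), -1.2, "F")
  expect_equal(h$predicted_delta, 0.6, tolerance = 1e-12)
  expect_equal(abs(h$fraction), 0.5, tolerance = 1e-12)
  expect_error(predict_change_fraction(eff, c(l1 = 0.2), c(l1 = 0.8), 0, "F"),
               "non-zero")
  ## additive over loci, linear in a
  eff2 <- locus_effects_set(rbind(l1 = c(F = 0.5, M = 0.5),
                                  l2 = c(F = 0.2, M = 0.2)),
                            rbind(l1 = c(F = 0.1, M = 0.1),
                                  l2 = c(F = 0, M = 0)))
  pb <- c(l1 = 0.2, l2 = 0.5); pa <- c(l1 = 0.6, l2 = 0.7)
  both <- predict_change_fraction(eff2, pb, pa, 1, "F")$predicted_delta
  one <- function(l) {
    e <- locus_effects_set(eff2$a[l, , drop = FALSE], eff2$d[l, , drop = FALSE])
    predict_change_fraction(e, pb[l], pa[l], 1, "F")$predicted_delta
  }
  expect_equal(both, one("l1") + one("l2"), tolerance = 1e-12)
  eff3 <- locus_effects_set(2 * eff2$a["l1", , drop = FALSE])
  expect_equal(predict_change_fraction(eff3, pb["l1"], pa["l1"], 1,
                                       "F")$predicted_delta,
               2 * predict_change_fraction(
                 locus_effects_set(eff2$a["l1", , drop = FALSE]),
                 pb["l1"], pa["l1"], 1, "F")$predicted_delta,
               tolerance = 1e-12)
})

test_that("stocking_comparison finds no signal when groups are identical", {
  set.seed(30)
  calls <- rbind(matrix(rbinom(200 * 1, 2, 0.4), 200, 1),
                 matrix(rbinom(200 * 1, 2, 0.4), 200, 1))
  panel <- make_panel(calls,
                      period = rep(c("1987", "2016"), each = 200),
                      origin = rep(rep(c("wild", "hatchery"), each = 100), 2),
                      class = "focal")
  sc <- stocking_comparison(panel, "L1")
  expect_lt(abs(sc$log_odds_diff), 3 * sc$se)
  expect_equal(nrow(sc$by_group), 4)
  expect_true(all(sc$by_group$q2.5 <= sc$by_group$freq_median))
})

test_that("stocking_comparison recovers a known log-odds difference", {
  ## 2x odds difference, 500/group/year. The quasi-binomial dispersion is
  ## estimated from the cell residuals, so the 95% check uses the matching
  ## t quantile ("2 SE" at moderate df) and enough years for the dispersion
  ## estimate to stabilise.
  hits <- 0; seeds <- 1:100
  per <- as.character(1981:2005)
  for (s in seeds) {
    set.seed(s)
    p_w <- 0.4
    p_h <- plogis(qlogis(p_w) + log(2))
    calls <- c(); origin <- c(); period <- c()
    for (y in per) {
      calls <- c(calls, rbinom(500, 2, p_w), rbinom(500, 2, p_h))
      origin <- c(origin, rep(c("wild", "hatchery"), each = 500))
      period <- c(period, rep(y, 1000))
    }
    panel <- make_panel(matrix(calls, ncol = 1), period = period,
                        origin = origin, class = "focal")
    sc <- stocking_comparison(panel, "L1")
    crit <- qt(0.975, df.residual(sc$glm)) * sc$se
    if (abs(sc$log_odds_diff - log(2)) < crit) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
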