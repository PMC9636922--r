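#' Default focal-locus effect truth for simulations
#'
#' Additive effects back-computed from the reported LL/EE mass ratios
#' (`a = ln(ratio)/2`): vgll3 0.663 (M) and 0.431 (F); six6 0.283 (M) and
#' 0.331 (F). Dominance at vgll3 is set to +/-0.15 with reversed sign
#' between the sexes (the direction of reversal is a simulation choice); no
#' dominance at six6.
#'
#' @return a [locus_effects_set()] with rows `vgll3`, `six6`.
#' @export
default_effects <- function() {
  a <- rbind(vgll3 = c(F = log(2.37) / 2, M = log(3.77) / 2),
             six6 = c(F = log(1.94) / 2, M = log(1.76) / 2))
  d <- rbind(vgll3 = c(F = 0.15, M = -0.15),
             six6 = c(F = 0, M = 0))
  locus_effects_set(a, d)
}

#' Simulation scenario: the stated world of the study design
#'
#' Defaults emulate the study: waterflow 41 m^3/s stepped down to 60%, 50%
#' and 40% of the original in 1953, 1962 and 1975; 67 neutral biallelic
#' SNPs sampled at three periods (1925-1926 n = 77, 1987 n = 120, 2016
#' n = 149) drifting with per-interval intensities `zeta = g/2Ne` of 0.002
#' and 0.031; two focal loci with the [default_effects()]; catch of ~100
#' fish per year (1925-1926 and 1940-2016, with the 1958-1965 gap) with
#' within-year ln-mass variance `VP = 0.31`; hatchery fractions 0, 0.12 and
#' 0.51 in the three genotyped periods.
#'
#' @param seed integer master seed.
#' @param years modelled year range (flow coverage).
#' @param base_flow pre-development flow, m^3/s.
#' @param flow_schedule data.frame `year`, `mult` of step multipliers
#'   applied to `base_flow` from `year` onward.
#' @param flow_cv lognormal coefficient of variation of annual flow noise
#'   (0 = deterministic steps).
#' @param params true [adaptive_params()].
#' @param effects true [locus_effects_set()].
#' @param n_neutral number of neutral loci.
#' @param zeta numeric vector of drift intensities, one per consecutive
#'   period pair.
#' @param sample_plan data.frame `period`, `year`, `n`, `hatchery_frac`.
#' @param catch_years integer vector of catch years.
#' @param catch_n fish per catch year.
#' @param VP total within-year phenotypic variance of ln mass.
#' @param wf_exact simulate neutral drift by exact Wright-Fisher binomial
#'   steps instead of the truncated-normal approximation.
#' @param generation_time generations per interval use `interval /
#'   generation_time` when `wf_exact` (default 6 y).
#' @param hatchery_logodds shift in focal-allele log-odds for
#'   hatchery-origin fish (0 = stocking null).
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 42L,
                         years = 1940:2016,
                         base_flow = 41,
                         flow_schedule = data.frame(
                           year = c(1953, 1962, 1975),
                           mult = c(0.6, 0.5, 0.4)),
                         flow_cv = 0,
                         params = adaptive_params(),
                         effects = default_effects(),
                         n_neutral = 67L,
                         zeta = c(0.002, 0.031),
                         sample_plan = data.frame(
                           period = c("1925-1926", "1987", "2016"),
                           year = c(1925L, 1987L, 2016L),
                           n = c(77L, 120L, 149L),
                           hatchery_frac = c(0, 0.12, 0.51)),
                         catch_years = c(1925L, 1926L,
                                         setdiff(1940:2016, 1958:1965)),
                         catch_n = 100L,
                         VP = 0.31,
                         wf_exact = FALSE,
                         generation_time = 6,
                         hatchery_logodds = 0) {
  stopifnot(nrow(sample_plan) >= 2,
            length(zeta) == nrow(sample_plan) - 1,
            all(zeta >= 0), VP > 0, base_flow > 0)
  structure(as.list(environment()), class = "sim_scenario")
}

#' Simulate the annual waterflow series
#'
#' Piecewise-constant steps per the scenario schedule, optionally with
#' lognormal annual noise of coefficient of variation `flow_cv`.
#'
#' @param scenario a [sim_scenario()].
#' @return a [flow_series()].
#' @export
simulate_flow <- function(scenario) {
  yrs <- scenario$years
  mult <- rep(1, length(yrs))
  sched <- scenario$flow_schedule
  if (!is.null(sched) && nrow(sched)) {
    if (any(!(sched$year %in% c(yrs, min(yrs) - 1))) &&
        any(sched$year > max(yrs)))
      stop("flow schedule years outside scenario range", call. = FALSE)
    for (k in seq_len(nrow(sched)))
      mult[yrs >= sched$year[k]] <- sched$mult[k]
  }
  flow <- scenario$base_flow * mult
  if (scenario$flow_cv > 0) {
    set.seed(scenario$seed + 101L)
    sdlog <- sqrt(log(1 + scenario$flow_cv^2))
    flow <- flow * exp(stats::rnorm(length(flow), -sdlog^2 / 2, sdlog))
  }
  flow_series(yrs, flow)
}

#' True trajectory of the scenario
#'
#' Deterministic forward run of the moving-optimum recursion at the
#' scenario's true parameters (see [forward_recursion()]).
#'
#' @param scenario a [sim_scenario()].
#' @param flow a [flow_series()]; defaults to [simulate_flow()].
#' @return a `trajectory` data.frame.
#' @export
simulate_trajectory <- function(scenario, flow = simulate_flow(scenario)) {
  forward_recursion(scenario$params,
                    dynamics_constants(VP = scenario$VP,
                                       start_year = min(scenario$years)),
                    age_weights(), scenario$effects, flow)
}

## focal L-allele frequency at an arbitrary year (init value before start);
## obs = TRUE gives the observation-layer frequency p + delta * dp
.focal_p_at <- function(trajectory, scenario, locus, year, obs = FALSE) {
  if (year < min(trajectory$year)) return(scenario$params$init_p[[locus]])
  i <- match(year, trajectory$year)
  p <- trajectory[[paste0("p_", locus)]][i]
  if (obs)
    p <- p + scenario$params$delta * trajectory[[paste0("dp_", locus)]][i]
  min(max(p, 0), 1)
}

## one drift interval for a vector of frequencies
.drift_step <- function(x, zeta, wf_exact = FALSE, n_gen = 1) {
  if (zeta == 0) return(x)
  if (wf_exact) {
    Ne <- max(1, round(n_gen / (2 * zeta)))
    for (g in seq_len(max(1, round(n_gen))))
      x <- stats::rbinom(length(x), 2 * Ne, x) / (2 * Ne)
    return(x)
  }
  v <- x * (1 - x) * zeta
  lo <- stats::pnorm(0, x, sqrt(v)); hi <- stats::pnorm(1, x, sqrt(v))
  u <- stats::runif(length(x), lo, hi)
  out <- stats::qnorm(u, x, sqrt(v))
  out[v == 0] <- x[v == 0]
  pmin(pmax(out, 0), 1)
}

#' Sample a genotype panel from the scenario
#'
#' Neutral loci start at frequencies Uniform(0.05, 0.95) and drift between
#' sampling periods with the scenario's per-interval `zeta` (truncated-
#' normal approximation by default, exact Wright-Fisher optionally); focal
#' loci follow the trajectory's frequencies. Individual calls are
#' `Binomial(2, p)` draws; focal calls count the early `E` allele
#' (`p_E = 1 - p_L`). Sex is assigned 50/50; origin is hatchery with the
#' period's `hatchery_frac`, with focal log-odds shifted by
#' `hatchery_logodds` for hatchery fish.
#'
#' @param trajectory a trajectory from [simulate_trajectory()].
#' @param scenario a [sim_scenario()].
#' @return a [genotype_panel()]; the true neutral frequencies per period are
#'   attached as attribute `neutral_freq`.
#' @export
sample_genotypes <- function(trajectory, scenario) {
  set.seed(scenario$seed + 202L)
  plan <- scenario$sample_plan
  loci_f <- names(scenario$params$init_p)
  nP <- nrow(plan)
  x <- matrix(NA_real_, nP, scenario$n_neutral)
  x[1, ] <- stats::runif(scenario$n_neutral, 0.05, 0.95)
  for (t in 2:nP) {
    n_gen <- max(1, round((plan$year[t] - plan$year[t - 1]) /
                            scenario$generation_time))
    x[t, ] <- .drift_step(x[t - 1, ], scenario$zeta[t - 1],
                          scenario$wf_exact, n_gen)
  }
  loci <- data.frame(
    locus_id = c(paste0("snp", seq_len(scenario$n_neutral)), loci_f),
    class = c(rep("neutral", scenario$n_neutral), rep("focal", length(loci_f))),
    tracked_allele = c(rep("A1", scenario$n_neutral), rep("E", length(loci_f))),
    stringsAsFactors = FALSE)
  calls <- NULL; info <- NULL
  for (t in seq_len(nP)) {
    n <- plan$n[t]
    origin <- ifelse(stats::runif(n) < plan$hatchery_frac[t],
                     "hatchery", "wild")
    pE <- vapply(loci_f, function(l)
      1 - .focal_p_at(trajectory, scenario, l, plan$year[t], obs = TRUE),
      numeric(1))
    g_neutral <- vapply(seq_len(scenario$n_neutral), function(j)
      stats::rbinom(n, 2, x[t, j]), integer(n))
    g_focal <- vapply(seq_along(loci_f), function(j) {
      p <- rep(pE[j], n)
      if (scenario$hatchery_logodds != 0) {
        sh <- .inv_logit(.logit(pmin(pmax(p, 1e-9), 1 - 1e-9)) +
                           scenario$hatchery_logodds)
        p[origin == "hatchery"] <- sh[origin == "hatchery"]
      }
      stats::rbinom(n, 2, p)
    }, integer(n))
    if (n == 1) {                      # vapply drops to vector at n = 1
      g_neutral <- matrix(g_neutral, 1)
      g_focal <- matrix(g_focal, 1)
    }
    calls <- rbind(calls, cbind(g_neutral, g_focal))
    info <- rbind(info, data.frame(
      individual_id = sprintf("P%d_%03d", t, seq_len(n)),
      period = plan$period[t],
      sex = sample(c("F", "M"), n, replace = TRUE),
      origin = origin, stringsAsFactors = FALSE))
  }
  out <- genotype_panel(calls, info, loci)
  attr(out, "neutral_freq") <- x
  out
}

## sex-specific genotypic value and its mean/variance under HWE
.gvalue <- function(code_L, het, a, d) a * code_L + d * het
.gmoments <- function(p, a, d) {
  q <- 1 - p
  vals <- c(-a, d, a)
  pr <- c(q^2, 2 * p * q, p^2)
  m <- sum(pr * vals)
  list(mean = m, var = sum(pr * (vals - m)^2))
}

#' Sample individual catch records from the scenario
#'
#' Individual ln masses are Normal around the year's observation-layer mean
#' `zbar_t + delta s_t + e_t` (with `e_t ~ N(0, sigma_e2)` a year-level
#' residual, so the fitted observation model matches the generating world)
#' with total within-year variance `VP`: each fish gets sex (50/50), focal
#' genotypes drawn at the year's frequencies under Hardy-Weinberg
#' proportions, the centred sex-specific genotypic value, and a residual
#' whose variance is `VP` minus the genotypic variance for that sex. Years
#' before the model start use the initial trait mean and frequencies (and
#' no selection shift). Masses are emitted in kg; sea age is total age
#' (drawn from the age weights) minus a smolt age of 2.
#'
#' @param trajectory a trajectory from [simulate_trajectory()].
#' @param scenario a [sim_scenario()].
#' @param panel optional [genotype_panel()] from [sample_genotypes()];
#'   its individuals are appended as catch rows in their period years with
#'   masses consistent with their focal genotypes.
#' @return a [catch_table()].
#' @export
sample_catch <- function(trajectory, scenario, panel = NULL) {
  set.seed(scenario$seed + 303L)
  loci_f <- names(scenario$params$init_p)
  eff <- scenario$effects
  w <- age_weights()
  all_years <- sort(unique(c(scenario$catch_years, scenario$sample_plan$year)))
  e_year <- stats::setNames(
    stats::rnorm(length(all_years), 0, sqrt(scenario$params$sigma_e2)),
    all_years)
  zbar_at <- function(year) {
    e <- e_year[[as.character(year)]]
    if (year < min(trajectory$year))
      return(mean(scenario$params$init_zbar) + e)
    i <- match(year, trajectory$year)
    trajectory$zbar[i] + scenario$params$delta * trajectory$s[i] + e
  }
  gen_year <- function(year, n, sex = NULL, g_focal = NULL, ids = NULL,
                       origin = "wild") {
    pL <- vapply(loci_f, function(l)
      .focal_p_at(trajectory, scenario, l, year, obs = TRUE), numeric(1))
    if (is.null(sex)) sex <- sample(c("F", "M"), n, replace = TRUE)
    if (is.null(g_focal)) {
      g_focal <- vapply(seq_along(loci_f), function(j)
        stats::rbinom(n, 2, pL[j]), integer(n))
      if (n == 1) g_focal <- matrix(g_focal, 1)
    }
    lnm <- numeric(n)
    for (s in c("F", "M")) {
      idx <- sex == s
      if (!any(idx)) next
      gm <- lapply(seq_along(loci_f), function(j)
        .gmoments(pL[j], eff$a[loci_f[j], s], eff$d[loci_f[j], s]))
      gdev <- rep(0, sum(idx))
      for (j in seq_along(loci_f)) {
        code <- g_focal[idx, j] - 1L
        het <- as.integer(g_focal[idx, j] == 1L)
        gdev <- gdev + .gvalue(code, het, eff$a[loci_f[j], s],
                               eff$d[loci_f[j], s]) - gm[[j]]$mean
      }
      gvar <- sum(vapply(gm, `[[`, numeric(1), "var"))
      rvar <- scenario$VP - gvar
      if (rvar < 0) {
        warning("sample_catch: genotypic variance exceeds VP; residual floored")
        rvar <- 1e-6
      }
      lnm[idx] <- zbar_at(year) + gdev + stats::rnorm(sum(idx), 0, sqrt(rvar))
    }
    total_age <- sample(as.integer(names(w)), n, replace = TRUE, prob = w)
    data.frame(individual_id = if (is.null(ids))
      sprintf("C%d_%03d", year, seq_len(n)) else ids,
      year = year, mass_kg = exp(lnm) / 1000,
      sea_age = pmax(1L, total_age - 2L), smolt_age = 2L,
      sex = sex, origin = origin, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(scenario$catch_years, function(y)
    gen_year(y, scenario$catch_n)))
  if (!is.null(panel)) {
    plan <- scenario$sample_plan
    fidx <- match(loci_f, panel$loci$locus_id)
    for (t in seq_len(nrow(plan))) {
      rows <- which(panel$info$period == plan$period[t])
      gE <- panel$calls[rows, fidx, drop = FALSE]
      gL <- 2L - gE                    # panel counts E; catch model uses L
      out <- rbind(out, gen_year(plan$year[t], length(rows),
                                 sex = panel$info$sex[rows],
                                 g_focal = gL,
                                 ids = panel$info$individual_id[rows],
                                 origin = panel$info$origin[rows]))
    }
  }
  catch_table(out)
}

#' Simulate a full study data set with ground truth
#'
#' Runs [simulate_flow()], [simulate_trajectory()], [sample_genotypes()] and
#' [sample_catch()] and bundles the results with the generating truth.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `flow`, `trajectory`, `panel`, `catch`, and `truth`
#'   (scenario parameters, effects, zeta, neutral frequencies).
#' @export
simulate_study <- function(scenario = sim_scenario()) {
  flow <- simulate_flow(scenario)
  traj <- simulate_trajectory(scenario, flow)
  panel <- sample_genotypes(traj, scenario)
  catch <- sample_catch(traj, scenario, panel)
  list(flow = flow, trajectory = traj, panel = panel, catch = catch,
       truth = list(params = scenario$params, effects = scenario$effects,
                    zeta = scenario$zeta,
                    neutral_freq = attr(panel, "neutral_freq")))
}
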