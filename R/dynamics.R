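#' Age-at-return weights for overlapping generations
#'
#' Proportion of returning adults that were eggs `k` years earlier. Defaults
#' are the observed age distribution across all data: total ages 4-8 years
#' with weights 0.114, 0.336, 0.308, 0.181 and 0.061. An integer `shift`
#' moves the whole distribution to older ages (a +2 shift gives ages 6-10),
#' used as a sensitivity setting for the model's constant-age-structure
#' assumption.
#'
#' @param w named numeric vector of weights; names are ages in years.
#' @param shift integer shift in years applied to the ages.
#' @return object of class `age_weights`: weights summing to one, names the
#'   (shifted) ages.
#' @export
age_weights <- function(w = c(`4` = 0.114, `5` = 0.336, `6` = 0.308,
                              `7` = 0.181, `8` = 0.061),
                        shift = 0L) {
  stopifnot(all(w >= 0), length(w) >= 1)
  if (abs(sum(w) - 1) > 1e-8)
    stop("age weights must sum to 1", call. = FALSE)
  ages <- as.integer(names(w)) + as.integer(shift)
  if (any(is.na(ages)) || any(ages < 1))
    stop("age weights need integer age names >= 1 after shifting", call. = FALSE)
  names(w) <- ages
  structure(w, class = "age_weights")
}

#' Focal-locus genetic effects
#'
#' Container for sex-specific additive (`a`) and dominance (`d`) effects of
#' the focal loci on ln mass, under the natural-effect coding: the additive
#' code counts copies of the large/late `L` allele (-1, 0, +1 for EE, EL,
#' LL), so `a` is half the LL-EE contrast and the LL/EE mass ratio is
#' `exp(2a)`; `d` is the heterozygote deviation from the homozygote
#' midpoint. The error (co)variance matrix of the estimates enters the
#' additive-variance bias corrections.
#'
#' @param a matrix loci x sexes (`F`, `M`) of additive effects (ln-mass units).
#' @param d matrix of dominance effects, same shape; use 0 where not
#'   estimated (e.g. six6).
#' @param vcov error covariance matrix of the stacked effects, with
#'   row/column names `"<locus>_a_<sex>"` / `"<locus>_d_<sex>"`; defaults to
#'   all-zero (effects treated as known).
#' @return object of class `locus_effects`.
#' @export
locus_effects_set <- function(a, d = NULL, vcov = NULL) {
  a <- as.matrix(a)
  if (is.null(colnames(a))) colnames(a) <- c("F", "M")
  if (is.null(d)) d <- a * 0
  d <- as.matrix(d)
  stopifnot(identical(dim(a), dim(d)))
  if (is.null(rownames(a))) rownames(a) <- paste0("locus", seq_len(nrow(a)))
  rownames(d) <- rownames(a); colnames(d) <- colnames(a)
  nm <- as.vector(outer(rownames(a), colnames(a), function(l, s)
    paste0(l, "_a_", s)))
  nm <- c(nm, as.vector(outer(rownames(a), colnames(a), function(l, s)
    paste0(l, "_d_", s))))
  if (is.null(vcov)) {
    vcov <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  } else {
    vcov <- as.matrix(vcov)
    if (is.null(rownames(vcov))) dimnames(vcov) <- list(nm, nm)
    miss <- setdiff(nm, rownames(vcov))
    if (length(miss)) {  # pad unknown terms with zero error
      old <- vcov
      vcov <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
      vcov[rownames(old), colnames(old)] <- old
    } else {
      vcov <- vcov[nm, nm]
    }
    if (max(abs(vcov - t(vcov))) > 1e-10)
      stop("effect vcov must be symmetric", call. = FALSE)
  }
  structure(list(a = a, d = d, vcov = vcov), class = "locus_effects")
}

.eff_var <- function(eff, locus, term1, sex1, term2 = term1, sex2 = sex1) {
  eff$vcov[paste0(locus, "_", term1, "_", sex1),
           paste0(locus, "_", term2, "_", sex2)]
}

#' Additive genetic variance contributed by one locus
#'
#' Sex-specific additive variances and the cross-sex covariance for a
#' biallelic locus under Hardy-Weinberg proportions, each with a bias
#' correction for estimation error in the effects:
#' \deqn{V_A[j] = 2p(1-p)\,(a_j + d_j(1-2p))^2 - B_j,}
#' \deqn{B_j = 2p(1-p)\,(Var[a_j] + (1-2p)^2 Var[d_j] + 2(1-2p)Cov[a_j,d_j]),}
#' \deqn{C_A[F,M] = 2p(1-p)(a_F + d_F(1-2p))(a_M + d_M(1-2p)) - B_{FM},}
#' with the covariance bias built from the four cross-sex covariances. The
#' combined (sex-averaged) contribution is
#' `V_A = (V_A[F] + V_A[M] + 2 C_A[F,M]) / 4`.
#'
#' @param p frequency of the allele whose homozygote carries value `+a`
#'   (the `L` allele under the package's coding); may be a vector.
#' @param effects a [locus_effects_set()].
#' @param locus locus name (row of `effects$a`).
#' @return list with vectors `va_F`, `va_M`, `ca_FM`, `va` (combined).
#' @export
va_locus <- function(p, effects, locus) {
  stopifnot(all(p >= 0 & p <= 1))
  aF <- effects$a[locus, "F"]; aM <- effects$a[locus, "M"]
  dF <- effects$d[locus, "F"]; dM <- effects$d[locus, "M"]
  het <- 2 * p * (1 - p)
  u <- 1 - 2 * p
  alF <- aF + dF * u
  alM <- aM + dM * u
  biasF <- het * (.eff_var(effects, locus, "a", "F") +
                    u^2 * .eff_var(effects, locus, "d", "F") +
                    2 * u * .eff_var(effects, locus, "a", "F", "d", "F"))
  biasM <- het * (.eff_var(effects, locus, "a", "M") +
                    u^2 * .eff_var(effects, locus, "d", "M") +
                    2 * u * .eff_var(effects, locus, "a", "M", "d", "M"))
  biasC <- het * (.eff_var(effects, locus, "a", "F", "a", "M") +
                    u * .eff_var(effects, locus, "a", "F", "d", "M") +
                    u * .eff_var(effects, locus, "d", "F", "a", "M") +
                    u^2 * .eff_var(effects, locus, "d", "F", "d", "M"))
  vaF <- het * alF^2 - biasF
  vaM <- het * alM^2 - biasM
  caFM <- het * alF * alM - biasC
  list(va_F = vaF, va_M = vaM, ca_FM = caFM,
       va = (vaF + vaM + 2 * caFM) / 4)
}

#' Small-effect (background) additive variance
#'
#' `V_A(small) = h^2 V_P - V_A(vgll3, init) - V_A(six6, init)`, the residual
#' heritable variance after removing the initial (pre-model) contributions of
#' the two large-effect loci; held constant through time. Negative values
#' (possible when `h^2 V_P` is below the locus contributions) are clamped to
#' zero with a warning.
#'
#' @param h2 heritability in (0,1).
#' @param VP within-year phenotypic variance of ln mass (default 0.31).
#' @param va_init numeric vector of initial per-locus additive variances.
#' @return non-negative scalar variance.
#' @export
va_small <- function(h2, VP = 0.31, va_init = numeric()) {
  raw <- h2 * VP - sum(va_init)
  if (raw < 0) {
    warning(sprintf("va_small: h2*VP (%.4f) below initial locus variances (%.4f); clamped to 0",
                    h2 * VP, sum(va_init)))
    raw <- 0
  }
  raw
}

#' Moving optimum as a log-linear function of waterflow
#'
#' `theta_t = theta_1940 + b (xbar_t - xbar_1940)`, with `xbar` the log of
#' the June-September mean flow; `b = 1` means the optimal mass is
#' proportional to waterflow.
#'
#' @param ln_flow log flow covariate at year t (vectorised).
#' @param theta_ref optimum at the reference year (ln g).
#' @param b slope on log flow.
#' @param ln_flow_ref log flow at the reference year.
#' @return optimum trait value(s), ln g.
#' @export
optimum <- function(ln_flow, theta_ref, b, ln_flow_ref) {
  theta_ref + b * (ln_flow - ln_flow_ref)
}

#' Selection gradient under quadratic stabilizing selection
#'
#' `beta_t = -exp(q) (zbar_t - theta_t)`; the selection differential is
#' `s_t = V_P beta_t`. On a ln-scale trait, `beta` is directly comparable to
#' a mean-standardized gradient.
#'
#' @param zbar mean trait before selection (ln g).
#' @param theta optimum (ln g).
#' @param q log selection strength.
#' @param VP phenotypic variance (for `s`).
#' @return list with `beta` and `s`.
#' @export
selection_gradient <- function(zbar, theta, q, VP = 0.31) {
  beta <- -exp(q) * (zbar - theta)
  list(beta = beta, s = VP * beta)
}

#' Per-generation allele-frequency change under selection
#'
#' Two-term sex-specific weak-selection approximation derived from
#' `2 dp (a + d(1-2p)) = V_A(i) beta`:
#' \deqn{\Delta p = \frac{(V_A[F] + C_A[F,M])\beta}{8(a_F + d_F(1-2p))}
#'              + \frac{(V_A[M] + C_A[F,M])\beta}{8(a_M + d_M(1-2p))}.}
#' Accurate for small frequency changes or little dominance.
#'
#' @param p current allele frequency (of the `+a` allele).
#' @param effects a [locus_effects_set()].
#' @param locus locus name.
#' @param beta selection gradient.
#' @return `dp`, the per-generation change.
#' @export
delta_p <- function(p, effects, locus, beta) {
  v <- va_locus(p, effects, locus)
  u <- 1 - 2 * p
  denF <- effects$a[locus, "F"] + effects$d[locus, "F"] * u
  denM <- effects$a[locus, "M"] + effects$d[locus, "M"] * u
  term <- function(num, den) {
    out <- num * beta / (8 * den)
    zero <- abs(den) < 1e-12
    if (any(zero)) {
      if (any(abs(num[zero]) > 1e-12))
        stop(sprintf("delta_p: vanishing average excess at locus %s (a + d(1-2p) = 0)",
                     locus), call. = FALSE)
      out[zero] <- 0               # no effect at all: no selection on the locus
    }
    out
  }
  term(v$va_F + v$ca_FM, denF) + term(v$va_M + v$ca_FM, denM)
}

#' Constants of the dynamics model
#'
#' @param VP within-year phenotypic variance of ln mass; the study estimate
#'   before the first development, 0.31 (ln g)^2, is the default.
#' @param start_year first modelled year (needs both phenotype and flow
#'   data; default 1940).
#' @param eps clamp width for frequencies/probabilities.
#' @return list of constants.
#' @export
dynamics_constants <- function(VP = 0.31, start_year = 1940L, eps = 1e-9) {
  list(VP = VP, start_year = as.integer(start_year), eps = eps)
}

#' Default penalty (prior) specification
#'
#' Gaussian penalties applied on the scales the parameters are estimated on:
#' pre-start cohort trait means `N(9.26, 0.14^2)` ln g (the pre-development
#' average, about 10.5 kg); `q ~ N(-2, 1^2)`; `logit h2 ~ N(0, 1^2)`;
#' initial logit L-allele frequencies `N(0.99, 0.20^2)` (vgll3) and
#' `N(2.94, 0.80^2)` (six6). `theta_ref`, `b`, `logit delta` and
#' `log sigma_e` are unpenalized fixed effects.
#'
#' A weak `logit delta ~ N(0, 2.5^2)` ridge is added on top of the study's
#' penalties: `delta` is only weakly identified and otherwise collapses to
#' the boundary of (0,1), which destroys its Wald interval; the ridge is
#' flat over (0.01, 0.99) for practical purposes.
#'
#' @return list of `(mean, sd)` pairs by parameter.
#' @export
default_priors <- function() {
  list(init_zbar = c(mean = 9.26, sd = 0.14),
       q = c(mean = -2, sd = 1),
       logit_h2 = c(mean = 0, sd = 1),
       logit_delta = c(mean = 0, sd = 2.5),
       logit_p_init = list(vgll3 = c(mean = 0.99, sd = 0.20),
                           six6 = c(mean = 2.94, sd = 0.80)))
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

#' Parameter vector of the dynamics model
#'
#' @param q log selection strength.
#' @param theta_ref optimum at the start year (ln g).
#' @param b optimum slope on log flow.
#' @param delta fraction of selection occurring before the catch is
#'   observed, in (0,1).
#' @param h2 heritability in (0,1).
#' @param sigma_e2 residual variance of annual mean ln mass.
#' @param init_zbar numeric vector of cohort trait means for the
#'   `max(age)` years before the start year, oldest first (default length 8,
#'   all 9.26).
#' @param init_p named vector of initial L-allele frequencies per focal
#'   locus.
#' @return list of class `adaptive_params`.
#' @export
adaptive_params <- function(q = -2, theta_ref = 9.26, b = 1, delta = 0.5,
                            h2 = 0.5, sigma_e2 = 0.02,
                            init_zbar = rep(9.26, 8),
                            init_p = c(vgll3 = 0.72, six6 = 0.94)) {
  stopifnot(h2 > 0, h2 < 1, delta > 0, delta < 1, sigma_e2 >= 0,
            all(init_p > 0 & init_p < 1))
  structure(list(q = q, theta_ref = theta_ref, b = b, delta = delta,
                 h2 = h2, sigma_e2 = sigma_e2, init_zbar = init_zbar,
                 init_p = init_p),
            class = "adaptive_params")
}

#' Deterministic forward recursion of the moving-optimum model
#'
#' Runs the cohort-weighted recursions
#' `zbar_t = sum_k w_k (zbar_{t-k} + V_A(t-k) beta_{t-k})` and
#' `p_{i,t} = sum_k w_k (p_{i,t-k} + dp_{i,t-k})` from the start year to the
#' end of the flow series. Years before the start year take the initial
#' cohort trait means / initial frequencies and contribute no selection
#' response. `V_A(t)` is recomputed each year from the current frequencies;
#' `V_A(small)` uses the initial frequencies and is constant.
#'
#' @param params an [adaptive_params()].
#' @param constants a [dynamics_constants()].
#' @param weights an [age_weights()].
#' @param effects a [locus_effects_set()] with rows matching
#'   `names(params$init_p)`.
#' @param flow a [flow_series()] covering `start_year:end`.
#' @return data.frame of class `trajectory` with per-year state: `zbar`,
#'   `theta`, `beta`, `s`, per-locus `p_*`, `dp_*`, `va_*`, `va_small`,
#'   `va_total`, `evolvability_pct`, `load`.
#' @export
forward_recursion <- function(params, constants, weights, effects, flow) {
  loci <- names(params$init_p)
  ages <- as.integer(names(weights))
  kmax <- max(ages)
  if (length(params$init_zbar) != kmax)
    stop(sprintf("init_zbar must have length %d (max age)", kmax), call. = FALSE)
  start <- constants$start_year
  yrs <- flow$year
  if (yrs[1] > start || !(start %in% yrs))
    stop("flow series must cover the start year", call. = FALSE)
  flow <- flow[flow$year >= start, , drop = FALSE]
  years <- flow$year
  nT <- length(years)
  ln_flow_ref <- flow$ln_flow[flow$year == start]

  va0 <- vapply(loci, function(l) va_locus(params$init_p[[l]], effects, l)$va,
                numeric(1))
  vsmall <- va_small(params$h2, constants$VP, va0)

  ## state vectors indexed by offset year - (start - kmax) + 1
  all_years <- (start - kmax):years[nT]
  nA <- length(all_years)
  zbar <- rep(NA_real_, nA)
  resp <- rep(0, nA)                      # V_A * beta, response term
  pmat <- matrix(NA_real_, nA, length(loci), dimnames = list(NULL, loci))
  dpmat <- matrix(0, nA, length(loci), dimnames = list(NULL, loci))
  pre <- all_years < start
  zbar[pre] <- params$init_zbar
  pmat[pre, ] <- matrix(params$init_p, sum(pre), length(loci), byrow = TRUE)

  theta_all <- optimum(flow$ln_flow, params$theta_ref, params$b, ln_flow_ref)
  beta_v <- s_v <- va_tot <- rep(NA_real_, nT)
  clipped <- FALSE
  eps <- constants$eps
  for (t in seq_len(nT)) {
    i <- which(all_years == years[t])
    lag <- i - ages
    zbar[i] <- sum(weights * (zbar[lag] + resp[lag]))
    for (l in seq_along(loci)) {
      pnew <- sum(weights * (pmat[lag, l] + dpmat[lag, l]))
      if (pnew < eps || pnew > 1 - eps) {
        pnew <- min(max(pnew, eps), 1 - eps)
        clipped <- TRUE
      }
      pmat[i, l] <- pnew
    }
    va_l <- vapply(loci, function(l) va_locus(pmat[i, l], effects, l)$va,
                   numeric(1))
    va_l <- pmax(va_l, 0)
    va_tot[t] <- sum(va_l) + vsmall
    sg <- selection_gradient(zbar[i], theta_all[t], params$q, constants$VP)
    beta_v[t] <- sg$beta; s_v[t] <- sg$s
    resp[i] <- va_tot[t] * sg$beta
    for (l in seq_along(loci))
      dpmat[i, l] <- delta_p(pmat[i, l], effects, loci[l], sg$beta)
  }
  if (clipped) warning("forward_recursion: allele frequency clipped to [eps, 1-eps]")

  idx <- match(years, all_years)
  out <- data.frame(year = years, zbar = zbar[idx], theta = theta_all,
                    beta = beta_v, s = s_v)
  for (l in loci) {
    out[[paste0("p_", l)]] <- pmat[idx, l]
    out[[paste0("dp_", l)]] <- dpmat[idx, l]
    out[[paste0("va_", l)]] <-
      pmax(vapply(pmat[idx, l], function(p) va_locus(p, effects, l)$va,
                  numeric(1)), 0)
  }
  out$va_small <- vsmall
  out$va_total <- va_tot
  out$evolvability_pct <- evolvability(out$va_total)
  out$load <- genetic_load(out$zbar, out$theta, params$q, constants$VP)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Penalized negative log-likelihood of the dynamics model
#'
#' Observation models: annual mean ln mass
#' `zobs_t ~ N(zbar_t + delta s_t, sigma_e^2 + SE_t^2)` for years with catch
#' data, and tracked-allele counts `A_{i,t} ~ Bin(T_{i,t}, p_{i,t} + delta
#' dp_{i,t})` at genotyped years after the start year. Gaussian penalties
#' from `priors` complete the objective. Missing years contribute nothing.
#'
#' @param params an [adaptive_params()].
#' @param data list with `phenotypes` (an [annual_summary()] result),
#'   `focal_counts` (data.frame `locus`, `year`, `A`, `T` with `A` counting
#'   the L allele), `flow` (a [flow_series()]).
#' @param constants,weights,effects as for [forward_recursion()].
#' @param priors penalty specification, see [default_priors()].
#' @return scalar penalized negative log-likelihood.
#' @export
neg_log_posterior <- function(params, data, constants, weights, effects,
                              priors = default_priors()) {
  traj <- suppressWarnings(
    forward_recursion(params, constants, weights, effects, data$flow))
  eps <- constants$eps
  nll <- 0
  ph <- data$phenotypes
  ph <- ph[ph$year %in% traj$year & ph$n > 0 & !is.na(ph$se_ln_mass), ,
           drop = FALSE]
  if (nrow(ph)) {
    i <- match(ph$year, traj$year)
    mu <- traj$zbar[i] + params$delta * traj$s[i]
    nll <- nll - sum(stats::dnorm(ph$mean_ln_mass, mu,
                                  sqrt(params$sigma_e2 + ph$se_ln_mass^2),
                                  log = TRUE))
  }
  fc <- data$focal_counts
  if (!is.null(fc) && nrow(fc)) {
    fc <- fc[fc$year %in% traj$year, , drop = FALSE]
    for (r in seq_len(nrow(fc))) {
      i <- match(fc$year[r], traj$year)
      pr <- traj[[paste0("p_", fc$locus[r])]][i] +
        params$delta * traj[[paste0("dp_", fc$locus[r])]][i]
      pr <- min(max(pr, eps), 1 - eps)
      nll <- nll - stats::dbinom(fc$A[r], fc$T[r], pr, log = TRUE)
    }
  }
  ## Gaussian penalties
  pen <- function(x, ms) -stats::dnorm(x, ms[["mean"]], ms[["sd"]], log = TRUE)
  nll <- nll + sum(pen(params$init_zbar, priors$init_zbar))
  nll <- nll + pen(params$q, priors$q)
  nll <- nll + pen(.logit(params$h2), priors$logit_h2)
  if (!is.null(priors$logit_delta))
    nll <- nll + pen(.logit(params$delta), priors$logit_delta)
  for (l in names(params$init_p))
    nll <- nll + pen(.logit(params$init_p[[l]]), priors$logit_p_init[[l]])
  nll
}

## Fast penalized-NLL closure used inside fit_dynamics: same model as
## neg_log_posterior() (their agreement is asserted in the test suite) but
## with per-locus effect constants precomputed and the recursion inlined.
.make_nll <- function(data, constants, weights, effects, priors, template) {
  loci <- names(template$init_p)
  nl <- length(loci)
  ages <- as.integer(names(weights))
  w <- as.numeric(weights)
  kmax <- max(ages)
  start <- constants$start_year
  flow <- data$flow[data$flow$year >= start, , drop = FALSE]
  years <- flow$year
  nT <- length(years)
  ln_flow <- flow$ln_flow
  ln_flow_ref <- ln_flow[years == start]
  VP <- constants$VP; eps <- constants$eps
  ## effect constants per locus
  aF <- effects$a[loci, "F"]; aM <- effects$a[loci, "M"]
  dF <- effects$d[loci, "F"]; dM <- effects$d[loci, "M"]
  gv <- function(l, t1, s1, t2 = t1, s2 = s1) .eff_var(effects, l, t1, s1, t2, s2)
  vaaF <- vapply(loci, gv, numeric(1), t1 = "a", s1 = "F")
  vddF <- vapply(loci, gv, numeric(1), t1 = "d", s1 = "F")
  vadF <- vapply(loci, function(l) gv(l, "a", "F", "d", "F"), numeric(1))
  vaaM <- vapply(loci, gv, numeric(1), t1 = "a", s1 = "M")
  vddM <- vapply(loci, gv, numeric(1), t1 = "d", s1 = "M")
  vadM <- vapply(loci, function(l) gv(l, "a", "M", "d", "M"), numeric(1))
  caa <- vapply(loci, function(l) gv(l, "a", "F", "a", "M"), numeric(1))
  cad <- vapply(loci, function(l) gv(l, "a", "F", "d", "M"), numeric(1))
  cda <- vapply(loci, function(l) gv(l, "d", "F", "a", "M"), numeric(1))
  cdd <- vapply(loci, function(l) gv(l, "d", "F", "d", "M"), numeric(1))
  ## observations
  ph <- data$phenotypes
  ph <- ph[ph$year %in% years & ph$n > 0 & !is.na(ph$se_ln_mass), ,
           drop = FALSE]
  obs_i <- match(ph$year, years)
  obs_z <- ph$mean_ln_mass; obs_se2 <- ph$se_ln_mass^2
  fc <- data$focal_counts
  if (!is.null(fc)) fc <- fc[fc$year %in% years, , drop = FALSE]
  fc_i <- if (!is.null(fc) && nrow(fc)) match(fc$year, years) else integer(0)
  fc_l <- if (length(fc_i)) match(fc$locus, loci) else integer(0)
  pri <- priors
  nz <- kmax

  ## positional layout must match .pack_params (numDeriv strips names)
  function(x) {
    x <- unname(x)
    q <- x[1]; theta_ref <- x[2]; b <- x[3]
    ldelta <- x[4]; lh2 <- x[5]; lse <- x[6]
    delta <- .inv_logit(ldelta); h2 <- .inv_logit(lh2)
    sigma_e2 <- exp(2 * lse)
    init_zbar <- x[6 + seq_len(nz)]
    lp <- x[6 + nz + seq_len(nl)]
    init_p <- .inv_logit(lp)
    if (any(!is.finite(c(q, theta_ref, b, delta, h2, sigma_e2, init_zbar,
                         init_p)))) return(1e10)
    eq <- exp(q)
    het0 <- 2 * init_p * (1 - init_p); u0 <- 1 - 2 * init_p
    alF0 <- aF + dF * u0; alM0 <- aM + dM * u0
    va0 <- (het0 * alF0^2 - het0 * (vaaF + u0^2 * vddF + 2 * u0 * vadF) +
              het0 * alM0^2 - het0 * (vaaM + u0^2 * vddM + 2 * u0 * vadM) +
              2 * (het0 * alF0 * alM0 -
                     het0 * (caa + u0 * cad + u0 * cda + u0^2 * cdd))) / 4
    vsmall <- h2 * VP - sum(va0)
    if (vsmall < 0) vsmall <- 0
    nA <- kmax + nT
    zbar <- c(init_zbar, numeric(nT))
    resp <- numeric(nA)
    pmat <- rbind(matrix(init_p, kmax, nl, byrow = TRUE),
                  matrix(0, nT, nl))
    dpmat <- matrix(0, nA, nl)
    theta <- theta_ref + b * (ln_flow - ln_flow_ref)
    beta_v <- s_v <- numeric(nT)
    for (t in seq_len(nT)) {
      i <- kmax + t
      lag <- i - ages
      zbar[i] <- sum(w * (zbar[lag] + resp[lag]))
      p_t <- numeric(nl)
      for (l in seq_len(nl)) {
        p <- sum(w * (pmat[lag, l] + dpmat[lag, l]))
        if (p < eps) p <- eps else if (p > 1 - eps) p <- 1 - eps
        p_t[l] <- p
      }
      het <- 2 * p_t * (1 - p_t); u <- 1 - 2 * p_t
      alF <- aF + dF * u; alM <- aM + dM * u
      vF <- het * alF^2 - het * (vaaF + u^2 * vddF + 2 * u * vadF)
      vM <- het * alM^2 - het * (vaaM + u^2 * vddM + 2 * u * vadM)
      cFM <- het * alF * alM - het * (caa + u * cad + u * cda + u^2 * cdd)
      va_l <- pmax((vF + vM + 2 * cFM) / 4, 0)
      va_t <- vsmall + sum(va_l)
      beta <- -eq * (zbar[i] - theta[t])
      beta_v[t] <- beta; s_v[t] <- VP * beta
      resp[i] <- va_t * beta
      tF <- ifelse(abs(alF) < 1e-12, 0, (vF + cFM) * beta / (8 * alF))
      tM <- ifelse(abs(alM) < 1e-12, 0, (vM + cFM) * beta / (8 * alM))
      dpmat[i, ] <- tF + tM
      pmat[i, ] <- p_t
    }
    nll <- 0
    if (length(obs_i)) {
      mu <- zbar[kmax + obs_i] + delta * s_v[obs_i]
      v <- sigma_e2 + obs_se2
      nll <- nll + 0.5 * sum(log(2 * pi * v) + (obs_z - mu)^2 / v)
    }
    if (length(fc_i)) {
      pr <- pmat[cbind(kmax + fc_i, fc_l)] +
        delta * dpmat[cbind(kmax + fc_i, fc_l)]
      pr <- pmin(pmax(pr, eps), 1 - eps)
      nll <- nll - sum(stats::dbinom(fc$A, fc$T, pr, log = TRUE))
    }
    pen <- function(v, ms) 0.5 * sum(log(2 * pi * ms[["sd"]]^2) +
                                       (v - ms[["mean"]])^2 / ms[["sd"]]^2)
    nll <- nll + pen(init_zbar, pri$init_zbar) + pen(q, pri$q) +
      pen(lh2, pri$logit_h2)
    if (!is.null(pri$logit_delta)) nll <- nll + pen(ldelta, pri$logit_delta)
    for (l in seq_len(nl))
      nll <- nll + pen(lp[l], pri$logit_p_init[[loci[l]]])
    if (!is.finite(nll)) 1e10 else nll
  }
}

## pack/unpack between adaptive_params and the unconstrained optimizer vector
.pack_params <- function(params) {
  c(q = params$q, theta_ref = params$theta_ref, b = params$b,
    logit_delta = .logit(params$delta), logit_h2 = .logit(params$h2),
    log_sigma_e = log(sqrt(max(params$sigma_e2, 1e-12))),
    stats::setNames(params$init_zbar,
                    paste0("init_zbar", seq_along(params$init_zbar))),
    stats::setNames(.logit(params$init_p),
                    paste0("logit_p_", names(params$init_p))))
}

.unpack_params <- function(x, template) {
  nz <- length(template$init_zbar)
  loci <- names(template$init_p)
  adaptive_params(
    q = x[["q"]], theta_ref = x[["theta_ref"]], b = x[["b"]],
    delta = .inv_logit(x[["logit_delta"]]),
    h2 = .inv_logit(x[["logit_h2"]]),
    sigma_e2 = exp(2 * x[["log_sigma_e"]]),
    init_zbar = unname(x[paste0("init_zbar", seq_len(nz))]),
    init_p = stats::setNames(.inv_logit(x[paste0("logit_p_", loci)]), loci))
}

#' Fit the moving-optimum model by penalized maximum likelihood
#'
#' Minimizes [neg_log_posterior()] over the transformed parameter vector
#' (`delta`, `h2`, initial frequencies on logit scale; `sigma_e` on log
#' scale) by BFGS from `n_restarts` jittered starts; standard errors come
#' from the inverse Hessian at the optimum with delta-method back-
#' transformation.
#'
#' @param data as for [neg_log_posterior()].
#' @param constants,weights,effects model structure.
#' @param priors penalties, see [default_priors()].
#' @param start an [adaptive_params()] used as the central start.
#' @param n_restarts number of jittered starts (default 5).
#' @param jitter_sd standard deviation of the start jitter on the
#'   transformed scale.
#' @param seed integer seed for the jitter.
#' @param maxit BFGS iteration cap per start.
#' @param reltol BFGS relative convergence tolerance.
#' @return list of class `dynamics_fit`: `params` (an [adaptive_params()]),
#'   `se` (natural-scale standard errors for `q`, `theta_ref`, `b`, `delta`,
#'   `h2`, `sigma_e2`), `vcov` (transformed scale), `trajectory`, `nll`,
#'   `convergence` (per-start codes), `data`.
#' @export
fit_dynamics <- function(data, constants = dynamics_constants(),
                         weights = age_weights(), effects,
                         priors = default_priors(),
                         start = adaptive_params(), n_restarts = 5,
                         jitter_sd = 0.25, seed = 1, maxit = 500,
                         reltol = 1e-9) {
  if (sum(data$phenotypes$n > 0, na.rm = TRUE) < 10)
    stop("need >= 10 observed years to fit the dynamics model", call. = FALSE)
  obj <- .make_nll(data, constants, weights, effects, priors, start)
  x0 <- .pack_params(start)
  set.seed(seed)
  starts <- list(x0)
  if (n_restarts > 1)
    for (k in 2:n_restarts)
      starts[[k]] <- x0 + stats::rnorm(length(x0), 0, jitter_sd)
  best <- NULL; codes <- integer(0)
  for (st in starts) {
    fit <- try(stats::optim(st, obj, method = "BFGS",
                            control = list(maxit = maxit, reltol = reltol)),
               silent = TRUE)
    if (inherits(fit, "try-error")) { codes <- c(codes, NA_integer_); next }
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("fit_dynamics: all restarts failed; convergence codes: ",
         paste(codes, collapse = ","), call. = FALSE)
  H <- try(numDeriv::hessian(obj, best$par), silent = TRUE)
  vc <- NULL
  if (!inherits(H, "try-error")) {
    vc <- try(solve(H), silent = TRUE)
    if (inherits(vc, "try-error") || any(!is.finite(vc)) ||
        any(diag(vc) < 0)) vc <- NULL
    else dimnames(vc) <- list(names(best$par), names(best$par))
  }
  pars <- .unpack_params(best$par, start)
  se <- rep(NA_real_, 6)
  names(se) <- c("q", "theta_ref", "b", "delta", "h2", "sigma_e2")
  if (!is.null(vc)) {
    sdx <- sqrt(diag(vc))
    se["q"] <- sdx["q"]; se["theta_ref"] <- sdx["theta_ref"]
    se["b"] <- sdx["b"]
    se["delta"] <- sdx["logit_delta"] * pars$delta * (1 - pars$delta)
    se["h2"] <- sdx["logit_h2"] * pars$h2 * (1 - pars$h2)
    se["sigma_e2"] <- sdx["log_sigma_e"] * 2 * pars$sigma_e2
  }
  traj <- suppressWarnings(
    forward_recursion(pars, constants, weights, effects, data$flow))
  structure(list(params = pars, se = se, vcov = vc, trajectory = traj,
                 nll = best$value, convergence = codes, data = data,
                 constants = constants, weights = weights,
                 effects = effects),
            class = "dynamics_fit")
}

#' @export
print.dynamics_fit <- function(x, ...) {
  cat("Moving-optimum dynamics fit (penalized ML)\n")
  est <- c(q = x$params$q, theta_ref = x$params$theta_ref, b = x$params$b,
           delta = x$params$delta, h2 = x$params$h2,
           sigma_e2 = x$params$sigma_e2)
  print(round(rbind(estimate = est, se = x$se[names(est)]), 4))
  cat(sprintf("penalized NLL: %.3f; restarts converged: %d/%d\n",
              x$nll, sum(x$convergence == 0, na.rm = TRUE),
              length(x$convergence)))
  invisible(x)
}

#' Partition of observed yearly variance in mean ln mass
#'
#' Splits `Var_t(zobs)` into model-explained, measurement
#' (`mean(SE_t^2)/Var`) and residual (`sigma_e^2/Var`) percentages; the
#' explained share is the complement, so the three sum to exactly 100.
#'
#' @param fit a [fit_dynamics()] result.
#' @return named numeric: `explained_pct`, `measurement_pct`, `residual_pct`.
#' @export
variance_explained <- function(fit) {
  ph <- fit$data$phenotypes
  ph <- ph[ph$n > 0 & !is.na(ph$mean_ln_mass) & !is.na(ph$se_ln_mass), ,
           drop = FALSE]
  if (nrow(ph) < 3) stop("need >= 3 observed years", call. = FALSE)
  v_obs <- stats::var(ph$mean_ln_mass)
  meas <- mean(ph$se_ln_mass^2) / v_obs * 100
  resid <- fit$params$sigma_e2 / v_obs * 100
  c(explained_pct = 100 - meas - resid, measurement_pct = meas,
    residual_pct = resid)
}

#' Evolvability of a ln-scale trait
#'
#' Percent expected change of the trait mean under unit selection
#' (`beta = 1`): `100 (e^{V_A} - 1)`.
#'
#' @param va additive genetic variance on the natural-log scale (vectorised).
#' @return evolvability in percent.
#' @export
evolvability <- function(va) {
  stopifnot(all(va >= 0, na.rm = TRUE))
  100 * (exp(va) - 1)
}

#' Genetic load under Gaussian stabilizing selection
#'
#' With fitness `W(z) = exp(-exp(q)(z - theta)^2 / 2)` and phenotypes
#' `N(zbar, VP)`, the proportional reduction of mean fitness below the
#' optimal phenotype's fitness is
#' `1 - (1 + exp(q) VP)^{-1/2} exp(-exp(q)(zbar - theta)^2 / (2(1 + exp(q) VP)))`.
#' This is a reconstruction of the fitness-reduction summary; the form is
#' the canonical Gaussian-fitness result.
#'
#' @param zbar,theta mean trait and optimum (ln g); vectorised.
#' @param q log selection strength.
#' @param VP phenotypic variance.
#' @return load in `[0, 1)`.
#' @export
genetic_load <- function(zbar, theta, q, VP = 0.31) {
  w <- exp(q)
  1 - (1 + w * VP)^(-0.5) * exp(-w * (zbar - theta)^2 / (2 * (1 + w * VP)))
}
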