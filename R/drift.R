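#' Configuration for the drift null model sampler
#'
#' The study's full settings were 770,000 iterations with a 370,000 burn-in,
#' thinning 1/40, two chains; the defaults here are scaled down for
#' desk-scale runs and should be raised for production analyses.
#'
#' @param n_chains number of MCMC chains (>= 2 for convergence diagnostics).
#' @param n_iter total iterations per chain.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep one draw in `thin`.
#' @param zeta_bounds uniform prior bounds for the drift intensity
#'   `zeta = g/2Ne`; the study used (0.0001, 1).
#' @param rhat_threshold potential scale reduction factor above which the
#'   result is flagged unconverged (default 1.1).
#' @param seed integer RNG seed.
#' @param step_x,step_zeta random-walk step sizes (logit frequency / log
#'   zeta scales); adapted during burn-in.
#' @return list of class `drift_config`.
#' @export
drift_config <- function(n_chains = 2L, n_iter = 20000L, burn_in = 10000L,
                         thin = 10L, zeta_bounds = c(1e-4, 1),
                         rhat_threshold = 1.1, seed = 1L,
                         step_x = 0.4, step_zeta = 0.6) {
  stopifnot(burn_in < n_iter, n_chains >= 1,
            zeta_bounds[1] > 0, zeta_bounds[2] <= 1,
            zeta_bounds[1] < zeta_bounds[2])
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 zeta_bounds = zeta_bounds, rhat_threshold = rhat_threshold,
                 seed = as.integer(seed), step_x = step_x,
                 step_zeta = step_zeta),
            class = "drift_config")
}

## log truncated-normal transition density on [0,1]:
## x_t | x_{t-1} ~ N(x_{t-1}, x_{t-1}(1-x_{t-1}) * zeta), renormalized
.ln_trans <- function(xt, xprev, zeta) {
  s <- sqrt(pmax(xprev * (1 - xprev) * zeta, 1e-300))
  z <- pmax(stats::pnorm(1, xprev, s) - stats::pnorm(0, xprev, s), 1e-300)
  stats::dnorm(xt, xprev, s, log = TRUE) - log(z)
}

## wide A/T matrices (loci x periods) from an allele_counts table
.counts_wide <- function(counts, class = "neutral") {
  counts <- counts[counts$class == class, , drop = FALSE]
  if (!nrow(counts)) stop("no loci of class ", class, call. = FALSE)
  periods <- unique(counts$period)
  loci <- unique(counts$locus_id)
  A <- T_ <- matrix(NA_real_, length(loci), length(periods),
                    dimnames = list(loci, periods))
  idx <- cbind(match(counts$locus_id, loci), match(counts$period, periods))
  A[idx] <- counts$A
  T_[idx] <- counts$T
  list(A = A, T = T_, periods = periods, loci = loci)
}

#' Fit the temporal Wright-Fisher drift null model
#'
#' Estimates the drift intensity `zeta_t = g_t / 2 N_t` per consecutive
#' period pair, shared across loci, from neutral-locus allele counts.
#' Sampling model: `A(i,t) ~ Bin(T(i,t), x(i,t))`; latent frequencies follow
#' `x(i,t) | x(i,t-1) ~ N(x(i,t-1), x(i,t-1)(1-x(i,t-1)) zeta_t)` truncated
#' to `[0,1]`, with Beta(1,1) initial-period priors and a uniform prior on
#' `zeta`. A Metropolis-within-Gibbs sampler (random walk on logit
#' frequencies and log zeta, vectorised over loci) replaces the original
#' Gibbs engine; equivalence is established by parameter recovery, not
#' sampler identity.
#'
#' @param counts an [count_alleles()] table (neutral loci are selected by
#'   class); fixed loci must already be dropped.
#' @param config a [drift_config()].
#' @return list of class `drift_posterior`: `zeta` (draw matrix, columns per
#'   interval), `zeta_summary`, `x_draws` (draws x loci x periods array),
#'   `rhat` (per parameter), `converged`, `periods`, `config`.
#' @export
fit_drift_model <- function(counts, config = drift_config()) {
  w <- .counts_wide(counts, "neutral")
  A <- w$A; T_ <- w$T
  nL <- nrow(A); nP <- ncol(A)
  if (nP < 2) stop("need >= 2 periods", call. = FALSE)
  if (nL < 10)
    warning("fewer than 10 polymorphic neutral loci; zeta will be poorly resolved")
  fixed <- rowSums(A == 0, na.rm = TRUE) == rowSums(!is.na(A)) |
    rowSums(A == T_, na.rm = TRUE) == rowSums(!is.na(A))
  if (any(fixed))
    stop("fixed locus in neutral panel; rerun count_alleles(drop_fixed = TRUE)",
         call. = FALSE)
  A[is.na(A)] <- 0; T_[is.na(T_)] <- 0    # missing (locus, period): no data

  lb <- config$zeta_bounds[1]; ub <- config$zeta_bounds[2]
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  zeta_ch <- array(NA_real_, c(n_keep, nP - 1, config$n_chains))
  x_ch <- array(NA_real_, c(n_keep, nL, nP, config$n_chains))

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * ch)
    x <- (A + 1) / (T_ + 2)
    x <- pmin(pmax(x + stats::rnorm(length(x), 0, 0.02), 1e-4), 1 - 1e-4)
    zeta <- exp(stats::runif(nP - 1, log(lb * 10), log(min(ub, 0.1))))
    sx <- rep(config$step_x, nP)
    sz <- rep(config$step_zeta, nP - 1)
    acc_x <- att_x <- rep(0, nP)
    acc_z <- att_z <- rep(0, nP - 1)
    keep <- 0L
    ## log-likelihood pieces, vectorised over loci
    lbin <- function(xt, t) A[, t] * log(xt) + (T_[, t] - A[, t]) * log1p(-xt)
    for (it in seq_len(config$n_iter)) {
      for (t in seq_len(nP)) {
        cur <- x[, t]
        lo <- .logit(cur) + stats::rnorm(nL, 0, sx[t])
        prop <- .inv_logit(lo)
        prop <- pmin(pmax(prop, 1e-12), 1 - 1e-12)
        d <- lbin(prop, t) - lbin(cur, t) +
          log(prop * (1 - prop)) - log(cur * (1 - cur))
        if (t > 1)
          d <- d + .ln_trans(prop, x[, t - 1], zeta[t - 1]) -
            .ln_trans(cur, x[, t - 1], zeta[t - 1])
        if (t < nP)
          d <- d + .ln_trans(x[, t + 1], prop, zeta[t]) -
            .ln_trans(x[, t + 1], cur, zeta[t])
        acc <- log(stats::runif(nL)) < d
        x[acc, t] <- prop[acc]
        acc_x[t] <- acc_x[t] + mean(acc); att_x[t] <- att_x[t] + 1
      }
      for (t in seq_len(nP - 1)) {
        zp <- exp(log(zeta[t]) + stats::rnorm(1, 0, sz[t]))
        att_z[t] <- att_z[t] + 1
        if (zp < lb || zp > ub) next
        d <- sum(.ln_trans(x[, t + 1], x[, t], zp) -
                   .ln_trans(x[, t + 1], x[, t], zeta[t])) +
          log(zp) - log(zeta[t])
        if (log(stats::runif(1)) < d) {
          zeta[t] <- zp
          acc_z[t] <- acc_z[t] + 1
        }
      }
      ## crude step adaptation during burn-in, frozen afterwards
      if (it <= config$burn_in && it %% 200 == 0) {
        rx <- acc_x / pmax(att_x, 1); rz <- acc_z / pmax(att_z, 1)
        sx <- sx * exp((rx - 0.3))
        sz <- sz * exp((rz - 0.3))
        acc_x[] <- att_x[] <- 0; acc_z[] <- att_z[] <- 0
      }
      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0) {
        keep <- keep + 1L
        zeta_ch[keep, , ch] <- zeta
        x_ch[keep, , , ch] <- x
      }
    }
  }

  ## convergence diagnostics across chains
  rhat <- c()
  if (config$n_chains >= 2) {
    for (t in seq_len(nP - 1)) {
      chains <- lapply(seq_len(config$n_chains), function(ch)
        log(zeta_ch[, t, ch]))
      rhat[paste0("zeta_", t)] <- gelman_rubin(chains)
    }
    ## latent frequencies: diagnose a spread of loci to bound cost
    for (i in unique(round(seq(1, nL, length.out = min(nL, 10)))))
      for (t in seq_len(nP)) {
        chains <- lapply(seq_len(config$n_chains), function(ch)
          x_ch[, i, t, ch])
        rhat[sprintf("x_%s_t%d", w$loci[i], t)] <- gelman_rubin(chains)
      }
  }
  converged <- all(rhat < config$rhat_threshold)
  if (length(rhat) && !converged)
    warning(sprintf("drift model not converged: max Rhat = %.3f (threshold %.2f)",
                    max(rhat), config$rhat_threshold))

  zeta_all <- do.call(rbind, lapply(seq_len(config$n_chains),
                                    function(ch) zeta_ch[, , ch, drop = FALSE][, , 1]))
  if (nP == 2) zeta_all <- matrix(zeta_all, ncol = 1)
  colnames(zeta_all) <- paste(w$periods[-nP], w$periods[-1], sep = "->")
  zsum <- t(apply(zeta_all, 2, function(v)
    c(median = stats::median(v),
      q2.5 = stats::quantile(v, 0.025, names = FALSE),
      q97.5 = stats::quantile(v, 0.975, names = FALSE))))
  x_all <- array(aperm(x_ch, c(1, 4, 2, 3)),
                 c(n_keep * config$n_chains, nL, nP),
                 dimnames = list(NULL, w$loci, w$periods))
  structure(list(zeta = zeta_all, zeta_summary = zsum, x_draws = x_all,
                 rhat = rhat, converged = converged, periods = w$periods,
                 config = config),
            class = "drift_posterior")
}

#' @export
print.drift_posterior <- function(x, ...) {
  cat("Temporal drift null model posterior\n")
  print(round(x$zeta_summary, 5))
  cat(sprintf("converged: %s (max Rhat %.3f)\n", x$converged,
              if (length(x$rhat)) max(x$rhat) else NA))
  invisible(x)
}

#' Beta-binomial posteriors for focal-locus frequencies and changes
#'
#' Per period, the tracked-allele frequency posterior is
#' `Beta(1 + A, 1 + T - A)`; the change posterior between consecutive
#' periods is the difference of independent draws.
#'
#' @param counts an [count_alleles()] table; loci of class `focal` are used
#'   unless `class = "neutral"`.
#' @param n_draws posterior draws per period (default 10,000).
#' @param seed RNG seed.
#' @param class locus class to analyse.
#' @return list of class `focal_posterior`: `freq` (draw matrices per locus
#'   x period), `change` (per locus x interval), `summary` data.frame with
#'   medians and central 95% intervals.
#' @export
focal_posterior <- function(counts, n_draws = 10000L, seed = 1L,
                            class = "focal") {
  w <- .counts_wide(counts, class)
  set.seed(seed)
  freq <- list(); change <- list(); rows <- list()
  for (i in seq_along(w$loci)) {
    l <- w$loci[i]
    freq[[l]] <- sapply(seq_along(w$periods), function(t) {
      if (is.na(w$T[i, t]) || w$T[i, t] == 0) {
        warning(sprintf("focal_posterior: locus %s period %s has T = 0; skipped",
                        l, w$periods[t]))
        return(rep(NA_real_, n_draws))
      }
      stats::rbeta(n_draws, 1 + w$A[i, t], 1 + w$T[i, t] - w$A[i, t])
    })
    colnames(freq[[l]]) <- w$periods
    if (length(w$periods) > 1) {
      ch <- freq[[l]][, -1, drop = FALSE] -
        freq[[l]][, -length(w$periods), drop = FALSE]
      colnames(ch) <- paste(w$periods[-length(w$periods)], w$periods[-1],
                            sep = "->")
      change[[l]] <- ch
      for (k in seq_len(ncol(ch)))
        rows[[length(rows) + 1]] <- data.frame(
          locus_id = l, interval = colnames(ch)[k],
          change_median = stats::median(ch[, k]),
          change_q2.5 = stats::quantile(ch[, k], 0.025, names = FALSE),
          change_q97.5 = stats::quantile(ch[, k], 0.975, names = FALSE))
    }
  }
  structure(list(freq = freq, change = change,
                 summary = if (length(rows)) do.call(rbind, rows) else NULL,
                 periods = w$periods),
            class = "focal_posterior")
}

## truncated-normal drift CDF helper: P(X <= y), X ~ TN(p0, p0(1-p0)zeta; [0,1])
.tn_cdf <- function(y, p0, s) {
  z <- pmax(stats::pnorm(1, p0, s) - stats::pnorm(0, p0, s), 1e-300)
  pmin(pmax((stats::pnorm(pmin(pmax(y, 0), 1), p0, s) -
               stats::pnorm(0, p0, s)) / z, 0), 1)
}

## P(|X - p0| <= c) for the truncated-normal drift law
.tn_central <- function(c, p0, s) {
  .tn_cdf(p0 + c, p0, s) - .tn_cdf(p0 - c, p0, s)
}

#' Drift envelope: 95th quantile of absolute frequency change
#'
#' For each zeta draw, the central quantile `c` solving
#' `P(|X - p0| <= c) = prob` under the truncated-normal drift law from
#' `p0`; the returned envelope is the posterior mean of `c` over draws,
#' vectorised over a grid of starting frequencies.
#'
#' @param p0 starting frequency or vector/grid of frequencies in (0,1).
#' @param zeta_draws numeric vector of drift-intensity draws (a scalar gives
#'   the fixed-zeta envelope).
#' @param prob central probability (default 0.95).
#' @return numeric vector, the envelope per `p0`.
#' @export
drift_envelope <- function(p0, zeta_draws, prob = 0.95) {
  stopifnot(all(p0 > 0 & p0 < 1), all(zeta_draws >= 0))
  vapply(p0, function(p) {
    mean(vapply(zeta_draws, function(z) {
      if (z == 0) return(0)
      s <- sqrt(p * (1 - p) * z)
      cmax <- max(p, 1 - p)
      if (.tn_central(cmax, p, s) <= prob) return(cmax)
      stats::uniroot(function(c) .tn_central(c, p, s) - prob,
                     c(0, cmax), tol = 1e-9)$root
    }, numeric(1)))
  }, numeric(1))
}

#' Probability that an observed change is within drift expectations
#'
#' For each joint posterior draw `(delta_obs, p0, zeta)`, computes
#' `P(|X - p0| >= |delta_obs|)` under the truncated-normal drift law and
#' returns the mean over draws: the probability that drift alone produces a
#' change at least as large as the one observed.
#'
#' @param delta_draws posterior draws of the observed frequency change.
#' @param p0_draws posterior draws of the starting frequency.
#' @param zeta_draws posterior draws of the drift intensity.
#' @param seed seed used to resample the draw vectors to a common length.
#' @return scalar mean drift probability.
#' @export
drift_probability <- function(delta_draws, p0_draws, zeta_draws, seed = 1L) {
  n <- max(length(delta_draws), length(p0_draws), length(zeta_draws))
  set.seed(seed)
  rs <- function(v) if (length(v) == n) v else v[sample.int(length(v), n,
                                                            replace = TRUE)]
  d <- abs(rs(delta_draws)); p0 <- rs(p0_draws); z <- rs(zeta_draws)
  p0 <- pmin(pmax(p0, 1e-12), 1 - 1e-12)
  s <- sqrt(p0 * (1 - p0) * z)
  pr <- ifelse(s == 0, as.numeric(d <= 0), 1 - .tn_central(d, p0, s))
  mean(pr)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF from between- and within-chain variances:
#' `Rhat = sqrt(((n-1)/n W + (1 + 1/m) B/n) / W)`.
#'
#' @param chains list (length >= 2) of equal-length numeric vectors, one per
#'   chain, for a single parameter.
#' @return scalar `Rhat`.
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("gelman_rubin needs >= 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal lengths", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B_n <- stats::var(means)              # B/n
  if (W == 0) return(1)
  vhat <- (n - 1) / n * W + (1 + 1 / m) * B_n
  sqrt(vhat / W)
}

#' Multi-locus Weir-Cockerham F_ST between two panels
#'
#' Ratio-of-sums theta over the shared neutral loci of two genotype panels
#' (two-population case of the Weir & Cockerham variance-components
#' estimator, using observed heterozygosity).
#'
#' @param panelA,panelB [genotype_panel()] objects sharing neutral loci.
#' @return scalar theta.
#' @export
wc_fst <- function(panelA, panelB) {
  sharedn <- intersect(panelA$loci$locus_id[panelA$loci$class == "neutral"],
                       panelB$loci$locus_id[panelB$loci$class == "neutral"])
  if (!length(sharedn)) stop("no shared neutral loci", call. = FALSE)
  num <- den <- 0
  any_poly <- FALSE
  for (l in sharedn) {
    gA <- panelA$calls[, l]; gB <- panelB$calls[, l]
    n1 <- sum(!is.na(gA)); n2 <- sum(!is.na(gB))
    if (n1 == 0 || n2 == 0) next
    p1 <- mean(gA, na.rm = TRUE) / 2; p2 <- mean(gB, na.rm = TRUE) / 2
    h1 <- mean(gA == 1, na.rm = TRUE); h2 <- mean(gB == 1, na.rm = TRUE)
    r <- 2
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    any_poly <- TRUE
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (!any_poly || den == 0)
    stop("no shared polymorphic neutral loci", call. = FALSE)
  num / den
}
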