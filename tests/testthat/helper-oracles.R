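## Independent oracles used across the suite. These deliberately do NOT share
## code paths with the package implementation.

## Brute-force additive variance of a biallelic locus with sex-specific
## effects under HWE: least-squares allele substitution via weighted lm on
## the enumerated genotypes. Returns the same four quantities as va_locus
## (error terms zero).
oracle_va <- function(p, aF, dF, aM, dM) {
  g <- 0:2                       # copies of the +a allele
  freq <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  vF <- c(-aF, dF, aF)
  vM <- c(-aM, dM, aM)
  slope <- function(v) {
    fit <- stats::lm(v ~ g, weights = freq)
    stats::coef(fit)[["g"]]
  }
  varg <- sum(freq * g^2) - sum(freq * g)^2     # = 2p(1-p)
  bF <- slope(vF); bM <- slope(vM)
  list(va_F = bF^2 * varg, va_M = bM^2 * varg, ca_FM = bF * bM * varg,
       va = (bF^2 * varg + bM^2 * varg + 2 * bF * bM * varg) / 4)
}

## Exact one-generation deterministic selection at a single locus with
## linearized fitness w(z) = 1 + beta (z - mean z), sexes selected
## separately then averaged.
oracle_delta_p_exact <- function(p, aF, dF, aM, dM, beta) {
  g <- 0:2
  freq <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  after <- function(v) {
    w <- 1 + beta * (v - sum(freq * v))
    f2 <- freq * w / sum(freq * w)
    sum(f2 * g / 2)
  }
  (after(c(-aF, dF, aF)) + after(c(-aM, dM, aM))) / 2 - p
}

## Weir-Cockerham theta via the nested allele-level ANOVA (variance
## components from sums of squares), ratio of sums over loci.
oracle_wc_theta <- function(callsA, callsB) {
  r <- 2
  num <- den <- 0
  for (l in seq_len(ncol(callsA))) {
    gA <- callsA[, l]; gB <- callsB[, l]
    gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
    n <- c(length(gA), length(gB))
    if (any(n == 0)) next
    p_i <- c(mean(gA) / 2, mean(gB) / 2)
    N <- sum(n)
    pbar <- sum(n * p_i) / N
    if (pbar <= 0 || pbar >= 1) next
    ## allele-level sums of squares: y = allele indicator; individuals are
    ## the middle stratum. A heterozygote holds alleles {0,1}, mean 0.5,
    ## within-individual SS 0.5; homozygotes contribute 0.
    ind_p <- c(gA, gB) / 2                     # per-individual allele mean
    pop <- rep(1:2, n)
    SSG <- sum(c(gA, gB) == 1) * 0.5
    SSI <- 2 * sum((ind_p - p_i[pop])^2)
    SSP <- 2 * sum(n * (p_i - pbar)^2)
    MSP <- SSP / (r - 1)
    MSI <- SSI / (N - r)
    MSG <- SSG / N
    nc <- (N - sum(n^2) / N) / (r - 1)
    s2G <- MSG
    s2I <- (MSI - MSG) / 2
    s2P <- (MSP - MSI) / (2 * nc)
    num <- num + s2P
    den <- den + s2P + s2I + s2G
  }
  num / den
}

## Independent scalar recursion for the effects-free model: only V_A(small),
## fixed weights; coded as a direct loop on plain vectors.
oracle_scalar_recursion <- function(init_z, vsmall, q, theta, w_named) {
  ages <- as.integer(names(w_named))
  kmax <- max(ages)
  nT <- length(theta)
  z <- c(init_z, numeric(nT))
  r <- numeric(kmax + nT)
  for (t in seq_len(nT)) {
    i <- kmax + t
    z[i] <- sum(w_named * (z[i - ages] + r[i - ages]))
    beta <- -exp(q) * (z[i] - theta[t])
    r[i] <- vsmall * beta
  }
  z[(kmax + 1):(kmax + nT)]
}

## Tiny genotype panel fixtures -------------------------------------------
make_panel <- function(calls, period = rep("p1", nrow(calls)),
                       sex = rep("F", nrow(calls)),
                       origin = rep("wild", nrow(calls)),
                       class = rep("neutral", ncol(calls))) {
  genotype_panel(calls,
                 data.frame(individual_id = paste0("i", seq_len(nrow(calls))),
                            period = period, sex = sex, origin = origin),
                 data.frame(locus_id = paste0("L", seq_len(ncol(calls))),
                            class = class,
                            tracked_allele = ifelse(class == "focal", "E", "A1")))
}

## allele-count table straight from A/T matrices (loci x periods)
make_counts <- function(A, T_, class = "neutral") {
  periods <- paste0("t", seq_len(ncol(A)))
  do.call(rbind, lapply(seq_len(ncol(A)), function(t)
    data.frame(locus_id = paste0("L", seq_len(nrow(A))), class = class,
               period = periods[t], A = A[, t], T = T_[, t])))
}

## simulated effect-model data with known truth (join_panel_catch layout)
make_effect_data <- function(n, a_truth, d_truth, p = c(vgll3 = 0.6, six6 = 0.8),
                             years = 2000:2004, resid_sd = 0.4, seed = 1) {
  set.seed(seed)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  year <- sample(years, n, replace = TRUE)
  d <- data.frame(individual_id = paste0("i", seq_len(n)),
                  period = as.character(year), year = year, sex = sex,
                  origin = "wild", ln_mass = 0)
  mu <- stats::rnorm(length(years), 9, 0.3)   # year effects
  d$ln_mass <- mu[match(year, years)]
  for (l in names(p)) {
    g <- stats::rbinom(n, 2, p[[l]])
    d[[l]] <- g
    code <- g - 1
    het <- as.numeric(g == 1)
    d$ln_mass <- d$ln_mass + a_truth[[l]][sex] * code + d_truth[[l]][sex] * het
  }
  d$ln_mass <- d$ln_mass + stats::rnorm(n, 0, resid_sd)
  d
}
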