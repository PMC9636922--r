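#' Join a genotype panel to catch records
#'
#' Inner join by `individual_id`, keeping mass, sex, year and the focal-
#' locus calls (tracked-allele `E` counts converted to `L` counts so the
#' additive code counts the large/late allele).
#'
#' @param panel a [genotype_panel()].
#' @param catch a [catch_table()] containing the panel individuals.
#' @return data.frame with `individual_id`, `period`, `year`, `sex`,
#'   `origin`, `ln_mass` (ln g) and one `L`-count column per focal locus.
#' @export
join_panel_catch <- function(panel, catch) {
  floci <- panel$loci$locus_id[panel$loci$class == "focal"]
  if (!length(floci)) stop("panel has no focal loci", call. = FALSE)
  idx <- match(panel$info$individual_id, catch$individual_id)
  keep <- !is.na(idx)
  out <- data.frame(individual_id = panel$info$individual_id[keep],
                    period = panel$info$period[keep],
                    year = catch$year[idx[keep]],
                    sex = panel$info$sex[keep],
                    origin = panel$info$origin[keep],
                    ln_mass = log(catch$mass_kg[idx[keep]] * 1000),
                    stringsAsFactors = FALSE)
  for (l in floci)
    out[[l]] <- 2L - panel$calls[keep, l]   # E counts -> L counts
  out
}

#' Fit the sex-specific natural genetic effect model for ln mass
#'
#' Ordinary least squares of individual ln mass on, per focal locus and
#' sex, the additive code (-1, 0, +1 for EE, EL, LL) and, where requested,
#' a heterozygote dominance indicator, both centred on their within-year
#' means for each sex; catch period x sex enters as a fixed factor.
#' Hatchery-origin fish and fish with unknown sex or missing focal genotype
#' are excluded (counts reported). The centring makes the genetic effects
#' invariant to year-by-sex shifts of mass.
#'
#' @param data a [join_panel_catch()] result (or equivalent data.frame).
#' @param loci focal locus names; default all genotype columns present.
#' @param dominance locus names for which a dominance effect is estimated
#'   (the study estimated `d` for vgll3 only, six6's rare `EE` class being
#'   too small).
#' @param exclude_hatchery drop hatchery-origin fish (default `TRUE`).
#' @return list of class `effect_fit`: `coefficients`, `vcov`, `lm` (the
#'   underlying fit), `n_used`, `n_excluded`, `loci`, `dominance`.
#' @export
fit_effect_model <- function(data, loci = NULL, dominance = intersect("vgll3", names(data)),
                             exclude_hatchery = TRUE) {
  if (is.null(loci))
    loci <- setdiff(names(data),
                    c("individual_id", "period", "year", "sex", "origin",
                      "ln_mass"))
  if (!length(loci)) stop("no focal locus columns found", call. = FALSE)
  n_in <- nrow(data)
  keep <- data$sex %in% c("F", "M")
  if (exclude_hatchery) keep <- keep & data$origin != "hatchery"
  for (l in loci) keep <- keep & !is.na(data[[l]])
  keep <- keep & is.finite(data$ln_mass)
  d <- data[keep, , drop = FALSE]
  if (!nrow(d)) stop("no usable individuals after exclusions", call. = FALSE)
  for (l in loci)
    if (length(unique(d[[l]])) < 2)
      stop(sprintf("locus %s is monomorphic in the usable data (singular additive term)",
                   l), call. = FALSE)

  ys <- interaction(d$year, d$sex, drop = TRUE)
  center <- function(v) v - stats::ave(v, ys)
  X <- list()
  for (l in loci) {
    add <- d[[l]] - 1                    # -1/0/+1 counting L
    het <- as.numeric(d[[l]] == 1L)
    for (s in c("F", "M")) {
      ind <- as.numeric(d$sex == s)
      X[[paste0(l, "_a_", s)]] <- center(add * ind) * ind
      if (l %in% dominance)
        X[[paste0(l, "_d_", s)]] <- center(het * ind) * ind
    }
  }
  Xm <- do.call(cbind, X)
  mf <- data.frame(ln_mass = d$ln_mass,
                   period_sex = interaction(d$period, d$sex, drop = TRUE))
  fit <- stats::lm(ln_mass ~ period_sex + Xm, data = mf)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    bad <- names(cf)[is.na(cf)]
    stop("singular design; offending term(s): ",
         paste(sub("^Xm", "", bad), collapse = ", "), call. = FALSE)
  }
  eff_idx <- grep("^Xm", names(cf))
  co <- cf[eff_idx]
  names(co) <- sub("^Xm", "", names(co))
  V <- stats::vcov(fit)[eff_idx, eff_idx, drop = FALSE]
  dimnames(V) <- list(names(co), names(co))
  structure(list(coefficients = co, vcov = V, lm = fit,
                 n_used = nrow(d), n_excluded = n_in - nrow(d),
                 loci = loci, dominance = dominance),
            class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("Natural genetic effect model: n = %d used, %d excluded\n",
              x$n_used, x$n_excluded))
  out <- cbind(estimate = x$coefficients, se = sqrt(diag(x$vcov)))
  print(round(out, 4))
  invisible(x)
}

#' Convert an effect fit into a [locus_effects_set()]
#'
#' Effects absent from the fit (unestimated dominance) are set to zero with
#' zero error variance.
#'
#' @param fit an [fit_effect_model()] result.
#' @return a [locus_effects_set()].
#' @export
as_locus_effects <- function(fit) {
  a <- matrix(0, length(fit$loci), 2,
              dimnames = list(fit$loci, c("F", "M")))
  d <- a
  for (l in fit$loci)
    for (s in c("F", "M")) {
      a[l, s] <- fit$coefficients[[paste0(l, "_a_", s)]]
      dn <- paste0(l, "_d_", s)
      if (dn %in% names(fit$coefficients)) d[l, s] <- fit$coefficients[[dn]]
    }
  nm <- c(as.vector(outer(fit$loci, c("F", "M"), function(l, s)
    paste0(l, "_a_", s))),
    as.vector(outer(fit$loci, c("F", "M"), function(l, s)
      paste0(l, "_d_", s))))
  V <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  have <- intersect(nm, rownames(fit$vcov))
  V[have, have] <- fit$vcov[have, have]
  locus_effects_set(a, d, V)
}

#' Genotype mass ratio with Monte-Carlo confidence interval
#'
#' The LL/EE mass ratio for a locus and sex is `exp(2a)`; `EL/EE` is
#' `exp(a + d)`. The CI comes from `n_draws` multivariate-normal draws of
#' the coefficient vector at its estimated error covariance (percentile
#' interval); the study used 50,000 draws.
#'
#' @param fit an [fit_effect_model()] result.
#' @param locus,sex which effect to invert.
#' @param contrast `"LL/EE"` (default) or `"EL/EE"`.
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @return named numeric: `ratio`, `lo`, `hi` (95% CI).
#' @export
genotype_mass_ratio <- function(fit, locus, sex, contrast = c("LL/EE", "EL/EE"),
                                n_draws = 50000L, seed = 1L) {
  contrast <- match.arg(contrast)
  co <- fit$coefficients
  V <- fit$vcov
  an <- paste0(locus, "_a_", sex)
  dn <- paste0(locus, "_d_", sex)
  if (!an %in% names(co)) stop("unknown effect ", an, call. = FALSE)
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, co, V)
  trans <- function(a, d) if (contrast == "LL/EE") exp(2 * a) else exp(a + d)
  dval <- if (dn %in% names(co)) co[[dn]] else 0
  ddraw <- if (dn %in% names(co)) draws[, dn] else 0
  r <- trans(draws[, an], ddraw)
  c(ratio = trans(co[[an]], dval),
    lo = stats::quantile(r, 0.025, names = FALSE),
    hi = stats::quantile(r, 0.975, names = FALSE))
}

#' Fraction of an observed trait change predicted by allele-frequency change
#'
#' Under Hardy-Weinberg proportions and the natural-effect coding, the mean
#' genotypic value at `L`-frequency `p` is `a(2p - 1) + 2 d p (1 - p)` per
#' locus; the predicted change in mean ln mass is the sum over loci of the
#' difference of this quantity between the two frequency sets, and the
#' returned fraction is `predicted / observed`.
#'
#' @param effects a [locus_effects_set()].
#' @param p_before,p_after named vectors of `L`-allele frequencies per locus.
#' @param observed_delta observed change in mean ln mass (non-zero).
#' @param sex `F` or `M`.
#' @return list with `fraction` (as a proportion), `predicted_delta`.
#' @export
predict_change_fraction <- function(effects, p_before, p_after,
                                    observed_delta, sex) {
  if (observed_delta == 0)
    stop("observed_delta must be non-zero", call. = FALSE)
  stopifnot(all(p_before >= 0 & p_before <= 1),
            all(p_after >= 0 & p_after <= 1))
  loci <- rownames(effects$a)
  hwe_mean <- function(p, l)
    effects$a[l, sex] * (2 * p - 1) + 2 * effects$d[l, sex] * p * (1 - p)
  pred <- sum(vapply(loci, function(l)
    hwe_mean(p_after[[l]], l) - hwe_mean(p_before[[l]], l), numeric(1)))
  list(fraction = pred / observed_delta, predicted_delta = pred)
}

#' Wild versus hatchery allele-frequency comparison
#'
#' Two views of the stocking question: (i) per origin x period
#' `Beta(1 + A, 1 + T - A)` posteriors with central 95% credible intervals;
#' (ii) a quasi-binomial GLM of tracked-allele counts on year and origin,
#' whose origin coefficient is the hatchery-wild log-odds difference.
#'
#' @param panel a [genotype_panel()] with both origins present.
#' @param locus focal locus name.
#' @param periods optional subset of periods.
#' @param n_draws posterior draws for the beta intervals.
#' @param seed RNG seed.
#' @return list of class `stocking_comparison`: `by_group` (data.frame of
#'   per-group posteriors), `log_odds_diff`, `se`, `p_value`, `glm`.
#' @export
stocking_comparison <- function(panel, locus, periods = NULL,
                                n_draws = 10000L, seed = 1L) {
  info <- panel$info
  keep <- if (is.null(periods)) rep(TRUE, nrow(info)) else info$period %in% periods
  calls <- panel$calls[keep, locus]
  info <- info[keep, , drop = FALSE]
  ok <- !is.na(calls) & info$origin %in% c("wild", "hatchery")
  calls <- calls[ok]; info <- info[ok, , drop = FALSE]
  if (!all(c("wild", "hatchery") %in% info$origin))
    stop("both wild and hatchery origins must be present", call. = FALSE)
  grp <- interaction(info$origin, info$period, drop = TRUE)
  A <- tapply(calls, grp, sum)
  T_ <- tapply(calls, grp, function(v) 2 * length(v))
  set.seed(seed)
  by_group <- do.call(rbind, lapply(levels(grp), function(g) {
    dr <- stats::rbeta(n_draws, 1 + A[[g]], 1 + T_[[g]] - A[[g]])
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(origin = parts[1], period = paste(parts[-1], collapse = "."),
               A = A[[g]], T = T_[[g]],
               freq_median = stats::median(dr),
               q2.5 = stats::quantile(dr, 0.025, names = FALSE),
               q97.5 = stats::quantile(dr, 0.975, names = FALSE))
  }))
  tab <- data.frame(origin = info$origin, period = info$period, calls = calls)
  cnt <- stats::aggregate(calls ~ origin + period, tab,
                          function(v) c(A = sum(v), T = 2 * length(v)))
  cnt <- cbind(cnt[c("origin", "period")], as.data.frame(cnt$calls))
  cnt$origin <- stats::relevel(factor(cnt$origin), ref = "wild")
  form <- if (length(unique(cnt$period)) > 1)
    cbind(A, T - A) ~ factor(period) + origin else cbind(A, T - A) ~ origin
  g <- stats::glm(form, family = stats::quasibinomial(), data = cnt)
  sm <- summary(g)$coefficients
  row <- grep("^originhatchery$", rownames(sm))
  structure(list(by_group = by_group,
                 log_odds_diff = sm[row, "Estimate"],
                 se = sm[row, "Std. Error"],
                 p_value = sm[row, "Pr(>|t|)"],
                 glm = g),
            class = "stocking_comparison")
}
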