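---
title: "Models and methods in salmodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in salmodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The scientific setting

A wild Atlantic salmon population experienced a stepwise reduction of river
flow (to 60%, 50% and finally 40% of its historical level) over three
hydropower developments. Body mass at return correlates with sea age, whose
genetic architecture is dominated by two large-effect loci, *vgll3* and
*six6*; at each, an "early" allele E is associated with younger sea age and
smaller mass, a "late" allele L with the opposite. The package asks three
questions of such data: are focal-locus frequency changes larger than
genetic drift can explain; how large are the loci's effects on ln mass;
and can a moving phenotypic optimum driven by flow account for the joint
phenotype/allele-frequency trajectory.

Mass is analysed throughout as ln(grams): a pre-development mean of
~10.5 kg is 9.26 ln g, and the within-year phenotypic variance V~P~ = 0.31
(ln g)² is treated as a known constant. Genotypes are coded as counts of a
tracked allele; for focal loci the tracked allele in the data model is E
(matching how E-allele frequencies are reported), while the dynamics and
effect models internally count L, the allele whose homozygote carries +a.

## Drift null model

Neutral-locus counts follow `A(i,t) ~ Bin(T(i,t), x(i,t))`; latent
frequencies follow a truncated-normal approximation to Wright–Fisher
drift, `x_t | x_{t-1} ~ N(x_{t-1}, x_{t-1}(1 - x_{t-1}) ζ_t)` on [0,1],
with `ζ_t = g_t / 2N_t` shared across loci and given a Uniform(10⁻⁴, 1)
prior; initial frequencies are Beta(1,1). The truncation is implemented as
a renormalized truncated-normal density (a proper likelihood), which is
the closest reading of the original interval-censoring device.

The sampler is Metropolis-within-Gibbs: random-walk updates on logit
frequencies (vectorised across loci, which are conditionally independent
given ζ) and on log ζ, with step sizes adapted toward 30% acceptance
during burn-in only. The original analysis used a general-purpose Gibbs
engine; equivalence is asserted by parameter recovery (95% credible
intervals cover a known ζ = 0.002 in ≥ 90% of seeded replicates at the
study's design of 67 loci and ~100 diploids per period), not by sampler
identity. Default iteration counts are desk-scale (20,000/10,000, thin
10); the study-scale settings (770,000/370,000, thin 40, two chains)
remain available through `drift_config()`. Convergence is monitored with
the Gelman–Rubin potential scale reduction factor at the conventional 1.1
threshold; unconverged results are flagged with a warning, never silently
returned.

Focal-locus frequencies deliberately bypass the drift prior: per period
the posterior is the conjugate Beta(1 + A, 1 + T − A), change posteriors
are differences of independent draws, and `drift_probability()` computes,
per joint draw of (observed change, starting frequency, ζ), the truncated-
normal tail probability that drift alone moves the frequency at least as
far — averaged over draws. Two open points were resolved as follows: the
average is taken over joint posterior draws, and the envelope/probability
condition on the posterior starting frequency rather than the raw sample
frequency. The tail is computed from the truncated-normal CDF in closed
form; the test suite validates it against Monte-Carlo simulation.

A note on calibration: the drift probability is a posterior-predictive
quantity, and such p-values are only uniform under the null in the limit
where sampling noise is negligible relative to drift. The calibration test
therefore uses a drift-dominated design (T = 2000 alleles, ζ = 0.05). At
designs where binomial sampling noise rivals drift the statistic is
conservative — worth remembering when interpreting values near the middle
of (0,1); values in the far tail are unambiguous either way.

## Natural genetic effect model

Individual ln mass is regressed on, per locus and sex, an additive code
(−1, 0, +1 for EE/EL/LL) and — for *vgll3* only, the rare *six6* EE class
being too thin to support it — a heterozygote dominance indicator, both
centred on within-year means for each sex, plus catch-period × sex fixed
factors. Under this coding `a` is half the LL−EE contrast, so the LL/EE
mass ratio is `exp(2a)`; this is the variant of the natural-effect model
that reproduces the reported ratio algebra. Hatchery-origin fish and fish
of unknown sex or missing genotype are excluded (and counted). CIs for
ratios use 50,000 multivariate-normal draws from the coefficient
covariance (reducible in tests); percentile intervals are reported.

`predict_change_fraction()` converts frequency changes to predicted mean
changes with the Hardy–Weinberg mean `a(2p − 1) + 2dp(1 − p)` per locus,
summed over loci; it is linear in `a` and additive over loci, properties
the suite asserts numerically. The stocking comparison pairs per-group
Beta(1+A, 1+T−A) posteriors with a quasi-binomial GLM of counts on year
and origin; the origin coefficient is the wild-vs-hatchery log-odds
difference. Because the quasi-likelihood dispersion is estimated from few
cells, its Wald checks in the tests use the matching t quantile.

## Moving-optimum state-space model

The deterministic core iterates, for year t from 1940 (the first year with
both phenotype and flow data):

* optimum: `θ_t = θ_1940 + b (x̄_t − x̄_1940)` with `x̄` = ln flow;
* selection: `β_t = −exp(q)(z̄_t − θ_t)`, differential `s_t = V_P β_t`;
* additive variance: per focal locus
  `V_A = (V_A[F] + V_A[M] + 2C_A[F,M])/4` with
  `V_A[j] = 2p(1−p)(a_j + d_j(1−2p))² − Bias_j` and the analogous
  cross-sex covariance, each bias correcting for estimation error in the
  effects; plus a constant small-effect remainder
  `V_A(small) = h²V_P − V_A(vgll3, init) − V_A(six6, init)`;
* allele-frequency response: the two-term sex-specific weak-selection
  approximation derived from `2Δp(a + d(1−2p)) ≈ V_A(i)β`;
* overlapping generations: cohort-weighted recursions
  `z̄_t = Σ_k w_k (z̄_{t−k} + V_A(t−k) β_{t−k})` and
  `p_t = Σ_k w_k (p_{t−k} + Δp_{t−k})`, with the age-at-return weights
  w₄…w₈ = 0.114, 0.336, 0.308, 0.181, 0.061 (an optional integer shift
  probes the constant-age-structure assumption).

Pre-1940 cohort years carry eight free initial trait means and one initial
frequency per locus, and contribute no selection-response terms — the
model is silent about selection before its start, and this is the only
reading under which the eight initial values close the recursion.

The observation layer is `z̄obs(t) = z̄_t + δ s_t + e_t + m_t` with
`e_t ~ N(0, σ_e²)`, `m_t ~ N(0, SE_t²)` (per-year standard errors, used
per-year rather than averaged), and `A_{i,t} ~ Bin(T, p_{i,t} + δΔp_{i,t})`
at the two later genotyped years only; the earliest period informs the
initial frequencies through their priors instead. δ is the fraction of
selection completed before the catch samples the population.

Fitting is penalized maximum likelihood: Gaussian penalties on the stated
scales — initial trait means N(9.26, 0.14²), q ~ N(−2, 1²) (the source's
"N(−2,12)" is read as SD 1, consistent with the same notation for logit
h²), logit h² ~ N(0, 1²), initial logit frequencies N(0.99, 0.20²) and
N(2.94, 0.80²) — added to the negative log-likelihood. Because the
trajectory is deterministic given parameters, no Laplace approximation is
needed. One penalty is this package's own: a weak logit δ ~ N(0, 2.5²)
ridge, because δ is near-unidentified in many data sets and otherwise runs
to the boundary of (0,1), destroying its Wald interval; the ridge is
effectively flat over (0.01, 0.99).

Numerics: δ, h² and the initial frequencies are optimized on logit scale
and σ_e on log scale (delta-method back-transformation for SEs); BFGS from
jittered starts; gradients by central finite differences (no automatic
differentiation engine is assumed; the suite checks two independent
difference schemes against each other); standard errors from the inverse
numerical Hessian. Frequencies and binomial success probabilities are
clamped to [10⁻⁹, 1 − 10⁻⁹] with clamp events flagged; a negative
`V_A(small)` (possible when h²V_P falls below the initial locus variances)
is clamped to zero with a warning. The optimizer uses an inlined
re-implementation of the recursion for speed; its exact agreement with the
readable `forward_recursion()`/`neg_log_posterior()` pair is part of the
test suite, so the fast path can never drift from the documented model.

Derived quantities: `variance_explained()` partitions the observed yearly
variance of mean ln mass into measurement (`mean SE_t²/Var`), residual
(`σ̂_e²/Var`) and model-explained (the complement, so the three always sum
to 100%) — the only definition consistent with reporting the three shares
together. Evolvability is `100(e^{V_A} − 1)` percent for a ln-scale trait.
Genetic load is reconstructed (no closed formula was published) under
Gaussian stabilizing fitness `W(z) = exp(−exp(q)(z − θ)²/2)`:
`1 − (1 + exp(q)V_P)^{−1/2} exp(−exp(q)(z̄−θ)²/(2(1 + exp(q)V_P)))`.

## The synthetic world

`sim_scenario()` defaults are the stated study conditions: flow stepping
41 → 60% → 50% → 40% at 1953/1962/1975; 67 neutral SNPs sampled in
1925–1926 (n = 77), 1987 (n = 120) and 2016 (n = 149); drift intensities
0.002 and 0.031 for the two intervals; ~100 catches per year over
1925–1926 and 1940–2016 with the 1958–1965 gap; V_P = 0.31; hatchery
fractions 0/0.12/0.51. Where the sources state no value, one was chosen
once and is documented here: additive effects back-computed from the
reported LL/EE mass ratios (`a = ln(ratio)/2`); vgll3 dominance ±0.15 with
reversed sign between sexes (the reversal direction is a simulation
choice); h² = 0.5, the smallest round value for which `h²V_P` exceeds the
two initial locus variances so `V_A(small)` is positive; σ_e² = 0.02,
giving ~±0.14 annual deviations matching the stated pre-development
annual variation; neutral starting frequencies Uniform(0.05, 0.95);
within-year masses lognormal (no within-year distribution family is
stated; lognormal is the natural partner of modeling ln mass); a 50/50
sex ratio and HWE genotype draws within years.

Two deliberate design decisions: drift is simulated with the same
truncated-normal approximation the inference assumes, so recovery tests
measure estimator error, not model misspecification (an exact
Wright–Fisher binomial option, `wf_exact`, exists for robustness checks);
and the generator shares the effect parameterization and the forward
recursion with the inference modules, so the two sides have a single
ground truth. The observation layer of the world matches the fitted one:
year means include `δ s_t` and a year-level `e_t`, and genotyped samples
draw at `p + δΔp`.

What the generator does *not* emulate: age-structure evolution (sea age is
drawn independently of mass within a year, so the sea-age decomposition on
synthetic data is structurally uninformative), marine-environment shifts,
size-selective harvest, farmed-ancestry introgression, and linkage between
markers. A green recovery test therefore establishes that the estimators
invert the assumed world, not that the assumed world is right — the latter
question belongs to the original study's sensitivity analyses and is out
of scope here.

## Known limitations

* ζ is estimated per consecutive period pair shared across loci; g and N_e
  are not separable.
* The Δp approximation degrades with strong dominance and large β; its
  first-order agreement with exact one-generation selection is tested at
  β = 10⁻³.
* `fit_dynamics()` treats the effect estimates and their covariance as
  known constants, as in the source analysis; joint estimation is a
  non-goal.
* The real-data acceptance targets need the archived deposit
  (10.5281/zenodo.7049816) and are represented by an intentionally failing
  test in offline environments.
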