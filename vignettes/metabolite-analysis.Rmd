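---
title: "Bayesian and frequentist analysis of two-group metabolite cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian and frequentist analysis of two-group metabolite cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsbayes)
```

## The problem

Small clinical MRS studies compare a brain metabolite — here glutathione
(GSH), measured in millimolar units within a single cortical voxel — between
a clinical high-risk (CHR) group and healthy controls (HC), and ask whether
the metabolite tracks a clinical score such as social and occupational
functioning (SOFAS). Two features make routine statistics awkward at this
scale. First, group sizes are small and unbalanced (around 13 vs 30), so
point estimates are noisy and interval statements matter more than p-values.
Second, clinical scores are ordinal-ish and often tied, so rank correlation
is the natural association measure — but the classical Spearman test gives
no principled statement of evidence *for* the null, which is exactly what a
null result in the control group needs.

`mrsbayes` implements the full analysis pipeline for such a study: spectral
quality filtering, a Bayesian Spearman correlation with Bayes factors, two
hierarchical Bayesian group-comparison models, a frequentist replication
suite, and a synthetic-cohort generator used for all testing, since raw
participant-level data in this field are typically available only on
request.

## Bayesian rank correlation by data augmentation

Observed scores are modelled as degraded views of latent continuous
variables: each pair \((x_i, y_i)\) is assumed to arise from a bivariate
normal with standard margins and correlation \(\rho\), observed only through
the midranks of each margin. The sampler alternates:

1. **Latent scores.** Each latent \(z^x_i\) is drawn from
   \(N(\rho\, z^y_i,\ 1 - \rho^2)\) truncated to the interval between the
   largest latent value at any strictly lower rank and the smallest at any
   strictly higher rank. Tied observations constrain each other only
   through non-tied neighbours, so a block of ties is exchangeable.
2. **Correlation.** A random-walk Metropolis step on \(\rho\) under a
   Uniform\((-1, 1)\) prior with the bivariate-normal likelihood of the
   latent pairs.

The truncated-normal sweep is implemented as a two-colour blocked Gibbs
update over rank *levels* (distinct rank values in increasing order). When
the current state is rank-consistent, the truncation bounds of a level
depend only on the two adjacent levels; adjacent levels always have opposite
parity, so all even levels can be updated simultaneously given the odd ones
and vice versa. Each half-update factorises into independent truncated
normals and is vectorised — no per-observation loop, and still exact Gibbs.

Truncated normals are drawn by inversion on the standardized scale. When
the probability interval collapses numerically (deep truncation at extreme
\(|\rho|\)), the draw falls back to a point strictly inside the bounds
(interval midpoint, or one proposal-scale unit inside a one-sided bound)
rather than ever returning an order-violating value.

The proposal scale adapts every 50 burn-in iterations toward a 40%
acceptance rate and is frozen afterwards, so the retained chain is a fixed
Metropolis kernel. Defaults mirror the study design: 11,000 retained draws,
thinning 10, and 1,000 retained-scale burn-in iterations. Whether a quoted
sample count refers to pre- or post-thinning draws is ambiguous in this
literature; `count_after_thinning = FALSE` switches to the raw-count
reading.

Evidence is summarized by the Savage–Dickey density ratio
\(\mathrm{BF}_{10} = p(\rho = 0 \mid \text{prior}) / p(\rho = 0 \mid
\text{posterior})\), with the prior density \(0.5\) under the uniform prior
and the posterior density estimated from the draws by the same
boundary-reflected kernel density estimate used for the posterior mode. A
parametric posterior family is deliberately not assumed: the latent-rank
posterior has no closed form.

```{r}
p <- generate_rank_pair(30, rho_s = 0.5, seed = 7)
fit <- bayesian_spearman(p$x, p$y, n_kept = 2000, thin = 2,
                         burn_in = 500, seed = 1)
fit
```

## Hierarchical group-comparison models

Clinical scores are compared between groups with a normal-likelihood model

\[ \mathrm{score}_i = \beta_0 + \textstyle\sum_g \beta_g x_{g(i)} +
   \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma_i^2), \]

and the metabolite with the same model plus a SOFAS covariate slope
\(\beta_{\mathrm{sofas}}\). All priors are data-scaled:

| parameter | prior | default scale |
|---|---|---|
| \(\beta_0\) | \(N(\bar y,\ (5\,\mathrm{SD}_y)^2)\) | wide, anchored at the data mean |
| \(\beta_g\) | \(N(0, \sigma_\beta^2)\) | shrinkage toward no group effect |
| \(\sigma_\beta\) | Gamma(shape \(\mathrm{SD}_y/2\), rate \(2\,\mathrm{SD}_y\)) | data-scaled hyperprior |
| \(\sigma_i\) | Uniform(\(\mathrm{SD}_y/1000,\ 1000\,\mathrm{SD}_y\)) | effectively unbounded |
| \(\beta_{\mathrm{sofas}}\) | \(N(0,\ (2\,\mathrm{SD}_y/\mathrm{SD}_x)^2)\) | scale-free in the covariate units |

Two readings deserve a note. The quoted dispersion expressions of the form
\(1/(5\,\mathrm{SD})^2\) are treated as *precisions* — the parameterisation
used by JAGS-family software — giving prior SDs of \(5\,\mathrm{SD}_y\) and
\(2\,\mathrm{SD}_y/\mathrm{SD}_x\); only under this reading are the priors
genuinely wide. The gamma hyperprior is taken literally in the shape/rate
parameterisation. The uniform bounds on \(\sigma_i\) are not stated anywhere
in this literature; \((\mathrm{SD}_y/1000,\ 1000\,\mathrm{SD}_y)\) is wide
enough that the bounds never bind in practice.

Sampling is Metropolis-within-Gibbs: the location parameters
(\(\beta_0\), each \(\beta_g\), \(\beta_{\mathrm{sofas}}\)) have conjugate
normal full conditionals and are Gibbs-updated; \(\log \sigma_i\) and
\(\log \sigma_\beta\) take adapted random-walk steps. Because only the sum
\(\beta_0 + \beta_g\) is likelihood-identified, every retained draw is
recentred to the sum-to-zero deflection parameterisation; with two groups
the deflections are stored as \(\pm(\beta_1 - \beta_2)/2\), which makes
them *exact* floating-point negatives. The covariate is mean-centred so
\(\beta_0\) keeps its data-mean anchoring (whether the original analyses
centred is unstated; centring is the choice here, and it only relabels
\(\beta_0\)).

The between-group difference is summarized per draw as
\(\beta_{HC} - \beta_{CHR}\), and the effect size as that difference
divided by the same draw's \(\sigma_i\). The effect-size definition is an
inference — it is the only reading arithmetically consistent with published
posterior tables in which a difference of about \(-0.27\) and a residual SD
mode of \(0.264\) accompany an effect size of about \(-1.06\).

The sampler is cross-checked in the test suite against an independent JAGS
fit of the identical model (rjags), agreeing in posterior means and SDs of
every parameter; the package's own sampler is always the implementation and
JAGS only the oracle.

Mixing note: with only two groups the \(\sigma_\beta\)–deflection funnel
makes the hyperprior the slowest-mixing parameter (roughly 0.25 effective
draws per retained draw at thinning 10). At the default 11,000 retained
draws every parameter clears 2,000 effective samples.

## Quality control and cohort model

Spectral fits with a glutathione Cramér–Rao lower bound at or above 30% are
excluded before any statistic, using a strict `<` comparison at the
threshold, consistent with a "CRLB < 30%" inclusion rule. Missing values
are empty CSV cells; every analysis applies listwise deletion on just the
variables it uses, which matches the per-test sample sizes such studies
report. Group labels are case-insensitive and canonicalized on read.

## The synthetic cohort

`generate_cohort()` emulates the study conditions the pipeline assumes:
groups of 13 (CHR) and 30 (HC); SOFAS 67.7 ± 9.5 vs 82.7 ± 3.8; CAST
11.4 ± 7.8 vs 6.2 ± 0.8 on the 6–30 scale; AUDIT-C 5.5 ± 3.8 vs 5.9 ± 2.5
on 0–12; SOPS 8.4 ± 5.0 in CHR only; GSH residual SD 0.27 mM; within-group
GSH–SOFAS Spearman targets 0.58 (CHR) and 0.11 (HC); CRLB 10 ± 4% and
11 ± 4%. Group-level GSH means (1.74 / 1.47 mM) are synthetic choices
placed around a 1.60 mM median-split threshold so the adjusted group
difference is about 0.27 mM — published tables report only model-scale
summaries, never raw metabolite means, so these two numbers are declared
approximations rather than study facts.

The dependence mechanism is a Gaussian copula: a target Spearman
\(\rho_s\) is induced by drawing latent bivariate normals at Pearson
\(2\sin(\pi \rho_s / 6)\). Bounded scores are drawn on the latent normal
scale, clipped to their bounds and rounded; the HC CAST marginal sits at
the scale floor of 6, so clipping reproduces its floor pile-up
qualitatively. GSH is resampled (not clipped) until positive, and CRLB
until above 1%.

What the generator does *not* emulate: discreteness artifacts of real
Likert totals beyond rounding, any CRLB–concentration coupling, missing
data patterns, and site or scanner effects. Passing calibration tests on
these cohorts therefore demonstrates correctness of the samplers under the
assumed data-generating mechanism, not robustness to real-data pathology.

## Numerical and design choices

- **HDI**: shortest interval of the sorted draws containing
  \(\lceil 0.95\, n \rceil\) points — exact for unimodal samples,
  deterministic given draws.
- **Mode and Savage–Dickey density**: Gaussian KDE with Silverman
  bandwidth, reflected at hard support bounds (\(\rho \in [-1, 1]\),
  \(\sigma > 0\)) so boundary-adjacent posteriors are not biased inward;
  the mode is the argmax over a 512-point grid, clipped to the draw range.
- **Posterior proportion**: the dominant-sign fraction of draws, clamped
  to \([0.5, 1]\); draws exactly at zero count to neither side.
- **Median split**: values at the sample median go to the *low* subgroup —
  the convention forced by a 7/6 split of 13 patients.
- **Chi-squared**: Pearson, df 1, no continuity correction — the only
  variant that reproduces the published gender statistic (1.948) from its
  2×2 counts. Published 2×2 statistics for marital status and cannabis use
  are not recoverable from their printed counts under any standard formula
  (Pearson, Yates, likelihood ratio) and are treated as a source
  discrepancy, not chased.
- **t-tests**: pooled variance by default, Welch by flag; printed t values
  in the source tables are not exactly recoverable from rounded
  means/SDs under either formula, so neither is used as an exact target.
- **Dummy coding** in the hierarchical regression: CHR = 0, HC = 1.
- **Per-stage seeds**: derived from the master seed and the stage name so
  any stage reruns identically in isolation; all derived seeds stay below
  \(2^{31}\).

## Test and verification scale

The statistical test suite runs its chains at 1,000–2,000 retained draws
with thinning 2–10 and calibration loops of 10–20 replicates at cohort
sizes 30–430; these sizes give each check comfortable Monte-Carlo margins
while keeping the suite fast. Null calibration (20 independent-pair
datasets, n = 30) requires the median \(\mathrm{BF}_{10}\) below 1; recovery
at n = 200 requires the posterior mode within ±0.1 of the classical
Spearman coefficient and 95% HDI coverage of the generating copula value in
at least 17 of 20 replicates; the covariate model must recover a 0.15 mM
group difference and a 0.01 mM-per-point slope inside its 95% HDIs at ten
times the cohort size. Published Bayes factors and posterior tables from
the motivating study design are *not* reproduction targets: they require
the raw data, which are unavailable, so the pipeline is validated by these
structural and calibration properties instead.

## Known limitations

- Exactly two groups; the deflection machinery generalises but is untested
  beyond two.
- Normal likelihoods only; no robust or ordinal response variants.
- No informed priors on \(\rho\) (stretched-beta etc.); only
  Uniform\((-1, 1)\).
- The Savage–Dickey estimate inherits KDE bias when the posterior is
  extremely concentrated away from the null; in that regime the Bayes
  factor is effectively "very large" rather than precisely estimated.
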