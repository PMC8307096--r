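# mrsbayes

Bayesian and frequentist analysis of small two-group brain-metabolite
cohorts: clinical high-risk (CHR) versus healthy-control (HC) studies in
which a metabolite measured by magnetic resonance spectroscopy — here
glutathione (GSH), in mM — is related to clinical scores such as social and
occupational functioning (SOFAS), symptom totals (SOPS), and substance-use
screens (CAST, AUDIT-C).

The package is written for researchers running or re-analysing studies of
this design, where groups are small (tens of participants), scores are
tied and ordinal-ish, and a defensible statement of evidence *for* a null
association matters as much as evidence against it.

## What it implements

**Bayesian Spearman correlation** (`bayesian_spearman`). Observed scores
are treated as degraded ranks of latent bivariate-normal variables with
correlation ρ. A Metropolis-within-Gibbs sampler alternates truncated-normal
Gibbs draws of the rank-consistent latent scores with a random-walk
Metropolis update of ρ under a Uniform(−1, 1) prior. Evidence is the
Savage–Dickey Bayes factor BF₁₀ = p(ρ=0 | prior) / p(ρ=0 | posterior), with
the posterior density at the null estimated from the draws by a
boundary-reflected Gaussian KDE.

**Hierarchical Bayesian group models** (`fit_group_model`,
`fit_group_covariate_model`). Normal-likelihood models

    score_i = β0 + Σ_g β_g x_g(i)                         (clinical scores)
    GSH_i   = β0 + Σ_g β_g x_g(i) + β_sofas x_sofas(i)    (metabolite)

with data-scaled priors: β0 ~ N(mean(y), (5 SD(y))²), group deflections
β_g ~ N(0, σ_β²) with a Gamma(SD(y)/2, 2 SD(y)) hyperprior on σ_β (so the
groups shrink each other), σ_i ~ Uniform(SD(y)/1000, 1000 SD(y)), and
β_sofas ~ N(0, (2 SD(y)/SD(x))²). Deflections are recentred per draw to an
exact sum-to-zero parameterisation; the group difference β_HC − β_CHR and
its effect size (difference / σ_i, per draw) are summarized by posterior
mean/median/KDE-mode, 95% highest-density interval, and the posterior
proportion on the dominant side of zero.

**Frequentist replication suite** (`pearson_chi2`, `two_sample_t`,
`spearman_corr`, `hierarchical_regression`, `median_split`, `anova_tukey`):
chi-squared demographics, t-tests, tie-safe Spearman correlation, two-step
hierarchical regression with the R²-change F-test, median split of the
patient-group metabolite, and one-way ANOVA with Tukey HSD.

**Synthetic cohorts** (`generate_cohort`, `synthetic_config`,
`generate_rank_pair`): Gaussian-copula cohorts matching the study-scale
marginals (13 CHR / 30 HC, SOFAS 67.7±9.5 vs 82.7±3.8, bounded CAST and
AUDIT-C, GSH residual SD 0.27 mM, per-group GSH–SOFAS Spearman targets
0.58 / 0.11, CRLB 10±4% / 11±4%), used everywhere raw data would be needed.

**Pipeline** (`run_full_analysis`, `render_report`): CRLB < 30% quality
filter, all four rank correlations, all four group models, the frequentist
suite, rendered as JSON/CSV/text with per-stage seeds derived from one
master seed.

## Worked example

```r
library(mrsbayes)

co <- generate_cohort(synthetic_config(seed = 42))
f  <- filter_by_crlb(co, 30)
chr <- f[f$group == "CHR", ]

bayesian_spearman(chr$gsh, chr$sofas, n_kept = 2000, thin = 2,
                  burn_in = 500, seed = 42)
#> Bayesian Spearman correlation (n = 13)
#>   mode rho = 0.762, 95% HDI [0.256, 0.910], PP = 1.00, BF10 = 6.82

ok <- !is.na(f$gsh) & !is.na(f$sofas)
fit_group_covariate_model(f$gsh[ok], f$group[ok], f$sofas[ok],
                          n_kept = 2000, thin = 2, burn_in = 500, seed = 42)
#> Hierarchical Bayesian group model (CHR vs HC), 2000 retained draws
#>              mean median   mode hdi_low hdi_high    pp
#> beta0       1.709  1.708  1.704   1.623    1.798 1.000
#> beta_CHR    0.309  0.311  0.315   0.205    0.415 1.000
#> beta_HC    -0.309 -0.311 -0.315  -0.415   -0.205 1.000
#> sigma_beta  0.652  0.486  0.316   0.123    1.711 1.000
#> sigma_i     0.249  0.246  0.241   0.202    0.316 1.000
#> beta_sofas  0.014  0.014  0.015   0.005    0.024 0.997
#> difference (HC - CHR): mode -0.630, 95% HDI [-0.830, -0.409], PP 1.00
```

Reading the output: in this synthetic CHR group the metabolite and the
functioning score are strongly rank-correlated (posterior mode 0.76, BF₁₀
≈ 6.8, i.e. the data favour an association about 7:1 over the null). In
the covariate-adjusted model the HC deflection is negative: after
accounting for SOFAS, controls carry about 0.63 mM less GSH than CHR in
this particular draw of the generator (the generating difference is
0.27 mM; a 43-person cohort is noisy, which is rather the point).
`run_full_analysis()` assembles these pieces plus the frequentist suite
into one reproducible report.

The methods vignette (`vignettes/metabolite-analysis.Rmd`) documents the
samplers, priors, numerical choices, and what the synthetic cohorts do and
do not emulate.

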