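#' Synthetic clinical-cohort generator
#'
#' Generates two-group cohorts with the statistical structure the analysis
#' pipeline assumes: published-scale marginal means and SDs per group, score
#' bounds enforced by construction, and a configurable within-group Spearman
#' correlation between the metabolite and the functioning score, induced by
#' a Gaussian copula (Pearson parameter `2 sin(pi * rho_s / 6)` for target
#' Spearman `rho_s`). Raw participant-level data for studies of this kind
#' are typically unavailable, so these cohorts stand in for them in every
#' test of the pipeline.
#'
#' @name synthetic-data
NULL

#' Configuration of the synthetic cohort
#'
#' Defaults describe the cohort structure the package was designed around:
#' 13 clinical high-risk (CHR) and 30 healthy control (HC) volunteers, SOFAS
#' 67.7 +/- 9.5 vs 82.7 +/- 3.8, CAST 11.4 +/- 7.8 vs 6.2 +/- 0.8 bounded to
#' [6, 30], AUDIT-C 5.5 +/- 3.8 vs 5.9 +/- 2.5 bounded to [0, 12], SOPS
#' 8.4 +/- 5.0 (CHR only), glutathione with residual SD 0.27 mM and group
#' means 1.74 (CHR) / 1.47 (HC) mM — synthetic values placed around the
#' 1.60 mM median-split threshold so the group difference is about 0.27 mM —
#' within-group GSH-SOFAS Spearman targets 0.58 (CHR) / 0.11 (HC), and
#' per-subject CRLB 10 +/- 4 % (CHR) and 11 +/- 4 % (HC), truncated at 1%.
#' Per-group values are given as `c(chr = , hc = )` vectors.
#'
#' @param n_chr,n_hc group sizes.
#' @param sofas_mean,sofas_sd,cast_mean,cast_sd,audit_c_mean,audit_c_sd
#'   per-group marginal moments of the clinical scores.
#' @param sops_mean,sops_sd CHR-only symptom-total moments.
#' @param gsh_mean per-group metabolite means (mM); `gsh_sd` the residual SD.
#' @param rho_gsh_sofas per-group target Spearman correlation, inside (-1, 1).
#' @param crlb_mean,crlb_sd per-group CRLB moments (percent).
#' @param p_male per-group probability of a male participant.
#' @param age_mean,age_sd per-group age moments (years).
#' @param seed integer seed making the generated table fully reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chr = 13L, n_hc = 30L,
                             sofas_mean = c(chr = 67.7, hc = 82.7),
                             sofas_sd = c(chr = 9.5, hc = 3.8),
                             cast_mean = c(chr = 11.4, hc = 6.2),
                             cast_sd = c(chr = 7.8, hc = 0.8),
                             audit_c_mean = c(chr = 5.5, hc = 5.9),
                             audit_c_sd = c(chr = 3.8, hc = 2.5),
                             sops_mean = 8.4, sops_sd = 5.0,
                             gsh_mean = c(chr = 1.74, hc = 1.47),
                             gsh_sd = 0.27,
                             rho_gsh_sofas = c(chr = 0.58, hc = 0.11),
                             crlb_mean = c(chr = 10, hc = 11),
                             crlb_sd = c(chr = 4, hc = 4),
                             p_male = c(chr = 11 / 13, hc = 19 / 30),
                             age_mean = c(chr = 22.2, hc = 21.8),
                             age_sd = c(chr = 4.0, hc = 3.7),
                             seed = 1L) {
  per_group <- function(v) {
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L) stop("per-group fields need one value per group")
    stats::setNames(as.numeric(v), c("chr", "hc"))
  }
  cfg <- list(n_chr = as.integer(n_chr), n_hc = as.integer(n_hc),
              sofas_mean = per_group(sofas_mean), sofas_sd = per_group(sofas_sd),
              cast_mean = per_group(cast_mean), cast_sd = per_group(cast_sd),
              audit_c_mean = per_group(audit_c_mean),
              audit_c_sd = per_group(audit_c_sd),
              sops_mean = sops_mean, sops_sd = sops_sd,
              gsh_mean = per_group(gsh_mean), gsh_sd = gsh_sd,
              rho_gsh_sofas = per_group(rho_gsh_sofas),
              crlb_mean = per_group(crlb_mean), crlb_sd = per_group(crlb_sd),
              p_male = per_group(p_male), age_mean = per_group(age_mean),
              age_sd = per_group(age_sd),
              seed = as.integer(seed))
  if (cfg$n_chr < 1L || cfg$n_hc < 1L) stop("group sizes must be positive")
  sds <- c(cfg$sofas_sd, cfg$cast_sd, cfg$audit_c_sd, cfg$sops_sd,
           cfg$gsh_sd, cfg$crlb_sd, cfg$age_sd)
  if (any(sds <= 0)) stop("all SDs must be positive")
  if (any(abs(cfg$rho_gsh_sofas) >= 1)) stop("|rho| targets must be < 1")
  if (any(cfg$p_male < 0 | cfg$p_male > 1)) stop("p_male must be in [0, 1]")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Spearman-to-Pearson copula conversion
#'
#' For a bivariate Gaussian copula, population Spearman `rho_s` corresponds
#' to the Pearson parameter `2 sin(pi * rho_s / 6)`.
#'
#' @param rho_s target Spearman correlation, inside (-1, 1).
#' @return The Pearson correlation of the latent normal.
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(abs(rho_s) >= 1)) stop("|rho_s| must be < 1")
  2 * sin(pi * rho_s / 6)
}

# Correlated standard-normal pair of length n at Pearson correlation r.
rbvn <- function(n, r) {
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  cbind(z1, z2)
}

# Normal draws resampled (not clipped) until all exceed `floor`.
rnorm_above <- function(n, mean, sd, floor) {
  x <- stats::rnorm(n, mean, sd)
  for (tries in 1:100) {
    bad <- x <= floor
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, floor + sd * 1e-6)
}

clip_round <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

#' Generate a synthetic cohort
#'
#' Per group, (GSH, SOFAS) are drawn from a bivariate normal whose Pearson
#' parameter is the copula conversion of the target Spearman correlation,
#' then scaled to the configured moments; bounded integer scores are drawn
#' on the latent normal scale, clipped to their bounds and rounded; GSH is
#' resampled until positive; SOPS exists for CHR only; CRLB values are
#' truncated-normal above 1%. Bit-for-bit reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A [cohort_table()] whose provenance records the seed.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  one_group <- function(g, n, prefix) {
    r <- spearman_to_pearson(config$rho_gsh_sofas[[g]])
    z <- rbvn(n, r)
    gsh <- config$gsh_mean[[g]] + config$gsh_sd * z[, 1L]
    neg <- gsh <= 0
    if (any(neg))
      gsh[neg] <- rnorm_above(sum(neg), config$gsh_mean[[g]], config$gsh_sd, 0)
    sofas <- clip_round(config$sofas_mean[[g]] + config$sofas_sd[[g]] * z[, 2L],
                        0, 100)
    tibble::tibble(
      id = sprintf("%s-%02d", prefix, seq_len(n)),
      group = toupper(prefix),
      gsh = gsh,
      gsh_crlb = rnorm_above(n, config$crlb_mean[[g]], config$crlb_sd[[g]], 1),
      sofas = sofas,
      sops_total = if (g == "chr")
        clip_round(stats::rnorm(n, config$sops_mean, config$sops_sd), 0, Inf)
        else NA_real_,
      cast = clip_round(stats::rnorm(n, config$cast_mean[[g]], config$cast_sd[[g]]),
                        6, 30),
      audit_c = clip_round(stats::rnorm(n, config$audit_c_mean[[g]],
                                        config$audit_c_sd[[g]]), 0, 12),
      age = round(stats::rnorm(n, config$age_mean[[g]], config$age_sd[[g]]), 1),
      gender = ifelse(stats::runif(n) < config$p_male[[g]], "male", "female")
    )
  }
  records <- rbind(one_group("chr", config$n_chr, "CHR"),
                   one_group("hc", config$n_hc, "HC"))
  cohort_table(records, provenance = sprintf("synthetic:seed=%d", config$seed))
}

#' Generate a correlated pair at a target Spearman correlation
#'
#' Bivariate standard-normal pair with the copula-converted Pearson
#' parameter; the empirical Spearman correlation converges to `rho_s` as
#' `n` grows. Used as the calibration harness for the rank-correlation
#' sampler.
#'
#' @param n number of pairs (at least 5).
#' @param rho_s target Spearman correlation, inside (-1, 1).
#' @param seed integer seed.
#' @return A list with numeric vectors `x` and `y` of length `n`.
#' @export
generate_rank_pair <- function(n, rho_s, seed = 1L) {
  if (n < 5L) stop("need n >= 5")
  set.seed(as.integer(seed))
  z <- rbvn(n, spearman_to_pearson(rho_s))
  list(x = z[, 1L], y = z[, 2L])
}
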