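#' Hierarchical Bayesian group-comparison linear models
#'
#' Two normal-likelihood models with data-scaled priors:
#' \deqn{score_i = \beta_0 + \sum_g \beta_g x_{g(i)}}
#' for the clinical scores, and for the metabolite
#' \deqn{[GSH]_i = \beta_0 + \sum_g \beta_g x_{g(i)} + \beta_{sofas} x_{sofas(i)}}
#' with a SOFAS covariate. Group deflections share a zero-mean normal prior
#' whose standard deviation sigma_beta carries a data-scaled gamma hyperprior,
#' so the groups act as shrinkage priors on each other. Sampling is
#' Metropolis-within-Gibbs: conjugate normal updates for the location
#' parameters, random walks on log sigma_i and log sigma_beta. Retained draws
#' are recentred per draw to the sum-to-zero deflection parameterisation.
#'
#' @name hier-glm
NULL

#' Data-scaled prior specification
#'
#' All hyperparameters derive from the observed response (and covariate)
#' scale: the baseline gets a normal prior centred at the data mean with SD
#' `5 * SD(y)` (a wide prior, reading the stated precision `1/(5 SD)^2` on
#' the precision scale); the residual SD a wide uniform; the deflection-SD
#' hyperprior a Gamma with shape `SD(y)/2` and rate `2 SD(y)`; and the
#' covariate slope, when present, a zero-mean normal with SD
#' `2 SD(y) / SD(covariate)`.
#'
#' @param y numeric response vector (at least 3 values, nonzero SD).
#' @param covariate optional numeric covariate vector.
#' @return A list of class `glm_prior_spec`.
#' @export
build_priors <- function(y, covariate = NULL) {
  y <- y[!is.na(y)]
  if (length(y) < 3L) stop("need at least 3 observed responses")
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) stop("zero-variance response: priors undefined")
  spec <- list(
    beta0_mean = mean(y),
    beta0_sd = 5 * sd_y,
    sigma_i_low = sd_y / 1000,
    sigma_i_high = sd_y * 1000,
    sigma_beta_shape = sd_y / 2,
    sigma_beta_rate = 2 * sd_y,
    beta_cov_sd = NULL
  )
  if (!is.null(covariate)) {
    covariate <- covariate[!is.na(covariate)]
    sd_x <- stats::sd(covariate)
    if (!is.finite(sd_x) || sd_x == 0) stop("zero-variance covariate: prior undefined")
    spec$beta_cov_sd <- 2 * sd_y / sd_x
  }
  class(spec) <- "glm_prior_spec"
  spec
}

# Geyer initial-monotone-sequence effective sample size (no dependencies).
ess <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  lag_max <- min(n - 1L, 2000L)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  npairs <- floor(length(ac) / 2)
  tau <- 1
  prev <- Inf
  for (m in seq_len(npairs)) {
    g <- ac[2 * m - 1L] + ac[2 * m]
    if (g < 0) break
    g <- min(g, prev)   # enforce monotone decrease
    tau <- tau + 2 * g
    prev <- g
  }
  n / tau
}

# Core Metropolis-within-Gibbs sampler shared by both model fits.
fit_hier_glm <- function(y, groups, covariate = NULL, spec,
                         n_kept = 11000L, thin = 10L, burn_in = 1000L,
                         seed = 1L) {
  ok <- !is.na(y) & !is.na(groups)
  if (!is.null(covariate)) ok <- ok & !is.na(covariate)
  y <- y[ok]; groups <- as.character(groups)[ok]
  if (!is.null(covariate)) covariate <- covariate[ok]
  labels <- sort(unique(groups))
  if (length(labels) != 2L) stop("exactly two group labels required, got: ",
                                 paste(labels, collapse = ", "))
  n_g <- table(factor(groups, levels = labels))
  if (any(n_g == 0L)) stop("empty group: ", labels[n_g == 0L][1L])
  if (any(n_g < 2L))
    warning("group with fewer than 2 members: posterior will be wide")
  if (n_kept < 1000L) stop("n_kept must be at least 1000 retained draws")
  g_idx <- match(groups, labels)
  n <- length(y)

  has_cov <- !is.null(covariate) && any(covariate != mean(covariate))
  if (has_cov) {
    xc <- covariate - mean(covariate)   # centred so beta0 keeps its anchoring
    if (is.null(spec$beta_cov_sd)) stop("prior spec lacks beta_cov_sd for the covariate")
    sxx <- sum(xc^2)
  } else xc <- rep(0, n)

  set.seed(as.integer(seed))
  # initial state from data moments
  b0 <- mean(y)
  beta <- tapply(y, g_idx, mean) - b0
  bs <- 0
  sig <- max(stats::sd(y), spec$sigma_i_low * 2)
  sb <- max(stats::sd(beta), sig / 2)
  step_sig <- 0.3; step_sb <- 0.5
  acc_sig_w <- 0L; acc_sb_w <- 0L
  acc_sig <- 0L; acc_sb <- 0L; n_post <- 0L

  n_burn_raw <- burn_in * thin
  n_total <- n_burn_raw + n_kept * thin
  cols <- c("beta0", paste0("beta_", labels), "sigma_beta", "sigma_i",
            if (has_cov) "beta_sofas")
  out <- matrix(NA_real_, n_kept, length(cols), dimnames = list(NULL, cols))
  k <- 0L

  log_post_sig <- function(s) {
    if (s < spec$sigma_i_low || s > spec$sigma_i_high) return(-Inf)
    ssr <- sum((y - b0 - beta[g_idx] - bs * xc)^2)
    -n * log(s) - ssr / (2 * s^2)
  }
  log_post_sb <- function(s) {
    if (s <= 0) return(-Inf)
    (spec$sigma_beta_shape - 1) * log(s) - spec$sigma_beta_rate * s -
      2 * log(s) - sum(beta^2) / (2 * s^2)
  }

  for (it in seq_len(n_total)) {
    # conjugate update: baseline
    r <- y - beta[g_idx] - bs * xc
    prec <- n / sig^2 + 1 / spec$beta0_sd^2
    m <- (sum(r) / sig^2 + spec$beta0_mean / spec$beta0_sd^2) / prec
    b0 <- stats::rnorm(1L, m, 1 / sqrt(prec))
    # conjugate update: each group deflection
    for (g in 1:2) {
      rg <- y[g_idx == g] - b0 - bs * xc[g_idx == g]
      prec <- n_g[g] / sig^2 + 1 / sb^2
      m <- (sum(rg) / sig^2) / prec
      beta[g] <- stats::rnorm(1L, m, 1 / sqrt(prec))
    }
    # conjugate update: covariate slope
    if (has_cov) {
      rc <- y - b0 - beta[g_idx]
      prec <- sxx / sig^2 + 1 / spec$beta_cov_sd^2
      m <- (sum(xc * rc) / sig^2) / prec
      bs <- stats::rnorm(1L, m, 1 / sqrt(prec))
    }
    # random walk on log sigma_i (uniform prior; +log(s) Jacobian)
    prop <- sig * exp(stats::rnorm(1L, 0, step_sig))
    la <- (log_post_sig(prop) + log(prop)) - (log_post_sig(sig) + log(sig))
    if (is.finite(la) && log(stats::runif(1L)) < la) {
      sig <- prop; acc_sig_w <- acc_sig_w + 1L
      if (it > n_burn_raw) acc_sig <- acc_sig + 1L
    }
    # random walk on log sigma_beta (gamma hyperprior; +log(s) Jacobian)
    prop <- sb * exp(stats::rnorm(1L, 0, step_sb))
    la <- (log_post_sb(prop) + log(prop)) - (log_post_sb(sb) + log(sb))
    if (is.finite(la) && log(stats::runif(1L)) < la) {
      sb <- prop; acc_sb_w <- acc_sb_w + 1L
      if (it > n_burn_raw) acc_sb <- acc_sb + 1L
    }
    if (it > n_burn_raw) n_post <- n_post + 1L
    if (it <= n_burn_raw && it %% 50L == 0L) {
      step_sig <- step_sig * exp(acc_sig_w / 50 - 0.4)
      step_sb <- step_sb * exp(acc_sb_w / 50 - 0.4)
      acc_sig_w <- 0L; acc_sb_w <- 0L
    }
    if (it > n_burn_raw && (it - n_burn_raw) %% thin == 0L) {
      k <- k + 1L
      # exact sum-to-zero recentring: deflections stored as +/- half-difference
      d <- (beta[1L] - beta[2L]) / 2
      row <- c(b0 + (beta[1L] + beta[2L]) / 2, d, -d, sb, sig,
               if (has_cov) bs)
      out[k, ] <- row
    }
  }

  samples <- posterior_samples(out, thin = thin, burn_in = burn_in, seed = seed)
  diff_draws <- out[, paste0("beta_", labels[2L])] - out[, paste0("beta_", labels[1L])]
  es_draws <- diff_draws / out[, "sigma_i"]
  summaries <- lapply(seq_len(ncol(out)), function(j) {
    supp <- if (cols[j] %in% c("sigma_beta", "sigma_i")) c(0, Inf) else NULL
    posterior_summary(out[, j], support = supp)
  })
  names(summaries) <- cols
  structure(
    list(samples = samples,
         summaries = summaries,
         difference = posterior_summary(diff_draws),
         effect_size = posterior_summary(es_draws),
         labels = labels,
         prior_spec = spec,
         acceptance = c(sigma_i = acc_sig / max(n_post, 1L),
                        sigma_beta = acc_sb / max(n_post, 1L)),
         ess = vapply(seq_len(ncol(out)), function(j) ess(out[, j]), 0)),
    class = "glm_posterior"
  )
}

#' Fit the group-deflection model to a clinical score
#'
#' @param y numeric response (one clinical score per participant).
#' @param groups two-level group label vector aligned with `y`.
#' @param spec a [build_priors()] specification (defaults to priors built
#'   from `y`).
#' @param n_kept,thin,burn_in chain settings; defaults 11000 retained draws,
#'   thinning 10, 1000 retained-scale burn-in iterations.
#' @param seed integer seed.
#' @return An object of class `glm_posterior`: `samples`
#'   (a [posterior_samples()] with columns `beta0`, `beta_<label>` for each
#'   group, `sigma_beta`, `sigma_i`), per-column `summaries`, and posterior
#'   summaries of the between-group `difference` (second label minus first,
#'   alphabetical) and its `effect_size` (difference / sigma_i, per draw).
#' @export
fit_group_model <- function(y, groups, spec = build_priors(y),
                            n_kept = 11000L, thin = 10L, burn_in = 1000L,
                            seed = 1L) {
  fit_hier_glm(y, groups, covariate = NULL, spec = spec, n_kept = n_kept,
               thin = thin, burn_in = burn_in, seed = seed)
}

#' Fit the group + covariate model to the metabolite
#'
#' Same model as [fit_group_model()] plus a covariate slope (mean-centred
#' before fitting) with a zero-mean normal prior of SD
#' `2 SD(y) / SD(covariate)`. A covariate that is identically zero reduces
#' the fit to the plain group model (same draws under the same seed).
#'
#' @param gsh numeric response (metabolite concentration, mM).
#' @param groups two-level group label vector.
#' @param sofas numeric covariate aligned with `gsh`.
#' @inheritParams fit_group_model
#' @return A `glm_posterior` whose `samples` carry the extra column
#'   `beta_sofas`.
#' @export
fit_group_covariate_model <- function(gsh, groups, sofas,
                                      spec = build_priors(gsh, covariate = sofas),
                                      n_kept = 11000L, thin = 10L,
                                      burn_in = 1000L, seed = 1L) {
  if (length(sofas) != length(gsh)) stop("covariate must match the response length")
  fit_hier_glm(gsh, groups, covariate = sofas, spec = spec, n_kept = n_kept,
               thin = thin, burn_in = burn_in, seed = seed)
}

#' Posterior of a between-group difference and its effect size
#'
#' Per-draw difference `beta_a - beta_b` and per-draw effect size
#' `(beta_a - beta_b) / sigma_i`, each summarized by [posterior_summary()].
#'
#' @param post a `glm_posterior`.
#' @param a,b group labels present in the fit.
#' @return A list with elements `difference` and `effect_size`.
#' @export
group_difference <- function(post, a, b) {
  stopifnot(inherits(post, "glm_posterior"))
  for (lab in c(a, b))
    if (!lab %in% post$labels) stop("unknown group label: ", lab)
  dr <- post$samples$draws
  diff_draws <- dr[, paste0("beta_", a)] - dr[, paste0("beta_", b)]
  es_draws <- diff_draws / dr[, "sigma_i"]
  list(difference = posterior_summary(diff_draws),
       effect_size = posterior_summary(es_draws))
}

#' @export
print.glm_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical Bayesian group model (%s vs %s), %d retained draws\n",
              x$labels[1L], x$labels[2L], x$samples$n_kept))
  tab <- do.call(rbind, lapply(x$summaries, as.data.frame))
  print(round(tab, 3))
  d <- x$difference
  cat(sprintf("difference (%s - %s): mode %.3f, 95%% HDI [%.3f, %.3f], PP %.2f\n",
              x$labels[2L], x$labels[1L], d$mode, d$hdi_low, d$hdi_high, d$pp))
  invisible(x)
}
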