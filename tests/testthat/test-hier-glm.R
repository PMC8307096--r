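# Hierarchical Bayesian group models: data-scaled priors, the
# Metropolis-within-Gibbs sampler, sum-to-zero identification, and the
# difference / effect-size posteriors. The sampler is cross-checked against
# an independent JAGS fit of the identical model.

test_that("build_priors applies the data-scaled formulas", {
  y <- c(-1, 0, 1) / sd(c(-1, 0, 1))  # SD exactly 1, mean 0
  s <- build_priors(y)
  expect_equal(s$beta0_mean, 0)
  expect_equal(s$beta0_sd, 5)
  expect_equal(s$sigma_beta_shape, 0.5)
  expect_equal(s$sigma_beta_rate, 2)
  expect_equal(s$sigma_i_low, 1e-3)
  expect_equal(s$sigma_i_high, 1e3)
  # linear scaling in SD(y)
  s2 <- build_priors(y * 2)
  expect_equal(s2$beta0_sd, 10)
  expect_equal(s2$sigma_beta_shape, 1)
  expect_equal(s2$sigma_beta_rate, 4)
  # covariate prior: 2 * SD(y) / SD(x)
  set.seed(301)
  yv <- rnorm(50, sd = 0.3); xv <- rnorm(50, sd = 9)
  s3 <- build_priors(yv, covariate = xv)
  expect_equal(s3$beta_cov_sd, 2 * sd(yv) / sd(xv))
  expect_error(build_priors(rep(1, 10)), "zero-variance")
  expect_error(build_priors(rnorm(10), covariate = rep(2, 10)), "covariate")
})

test_that("group deflections are exact negatives in every retained draw", {
  set.seed(302)
  y <- c(rnorm(15, 10), rnorm(15, 12))
  g <- rep(c("CHR", "HC"), each = 15)
  fit <- fit_group_model(y, g, n_kept = fast_chain$n_kept,
                         thin = fast_chain$thin,
                         burn_in = fast_chain$burn_in, seed = 1)
  dr <- fit$samples$draws
  expect_identical(max(abs(dr[, "beta_CHR"] + dr[, "beta_HC"])), 0)
  expect_true(all(dr[, "sigma_i"] > 0))
  expect_true(all(dr[, "sigma_beta"] > 0))
})

test_that("the sampler recovers a known group separation", {
  set.seed(303)
  y <- c(rnorm(30, 0), rnorm(30, 5))
  g <- rep(c("CHR", "HC"), each = 30)
  fit <- fit_group_model(y, g, n_kept = 2000, thin = 2, burn_in = 500, seed = 2)
  expect_lt(abs(fit$difference$mode - 5), 0.5)
  expect_gte(fit$difference$pp, 0.99)
})

test_that("the posterior matches an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  set.seed(304)
  y <- c(rnorm(25, 10, 1), rnorm(25, 11, 1))
  g <- rep(c("CHR", "HC"), each = 25)
  spec <- build_priors(y)
  fit <- fit_group_model(y, g, spec, n_kept = 4000, thin = 2,
                         burn_in = 1000, seed = 3)
  model_str <- "model {
    for (i in 1:n) { y[i] ~ dnorm(b0 + beta[grp[i]], 1/sig^2) }
    b0 ~ dnorm(m0, 1/s0^2)
    for (j in 1:2) { beta[j] ~ dnorm(0, 1/sb^2) }
    sb ~ dgamma(sh, ra)
    sig ~ dunif(lo, hi)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = y, grp = as.integer(factor(g)), n = length(y),
                m0 = spec$beta0_mean, s0 = spec$beta0_sd,
                sh = spec$sigma_beta_shape, ra = spec$sigma_beta_rate,
                lo = spec$sigma_i_low, hi = spec$sigma_i_high),
    n.chains = 1, n.adapt = 1000, quiet = TRUE)
  stats::update(jm, 2000)
  m <- as.matrix(rjags::coda.samples(jm, c("b0", "beta", "sb", "sig"),
                                     n.iter = 20000, thin = 2)[[1]])
  mine_diff <- fit$samples$draws[, "beta_HC"] - fit$samples$draws[, "beta_CHR"]
  jags_diff <- m[, "beta[2]"] - m[, "beta[1]"]
  expect_lt(abs(mean(mine_diff) - mean(jags_diff)), 0.1)
  expect_lt(abs(sd(mine_diff) - sd(jags_diff)), 0.05)
  expect_lt(abs(mean(fit$samples$draws[, "sigma_i"]) - mean(m[, "sig"])), 0.05)
  expect_lt(abs(mean(fit$samples$draws[, "sigma_beta"]) - mean(m[, "sb"])), 0.1)
})

test_that("label swap negates the difference posterior", {
  set.seed(305)
  y <- c(rnorm(20, 1), rnorm(20, 2))
  g1 <- rep(c("CHR", "HC"), each = 20)
  g2 <- rep(c("HC", "CHR"), each = 20)
  f1 <- fit_group_model(y, g1, n_kept = 2000, thin = 2, burn_in = 500, seed = 4)
  f2 <- fit_group_model(y, g2, n_kept = 2000, thin = 2, burn_in = 500, seed = 4)
  expect_lt(abs(f1$difference$mode + f2$difference$mode), 0.25)
  expect_lt(abs(f1$difference$pp - f2$difference$pp), 0.05)
})

test_that("covariate model recovers a known slope and mean-centres", {
  set.seed(306)
  n <- 430
  g <- rep(c("CHR", "HC"), c(130, 300))
  sof <- round(c(rnorm(130, 67.7, 9.5), rnorm(300, 82.7, 3.8)))
  gsh <- 1.6 + 0.15 * (g == "CHR") + 0.01 * (sof - mean(sof)) + rnorm(n, 0, 0.25)
  fit <- fit_group_covariate_model(gsh, g, sof, n_kept = 2000, thin = 2,
                                   burn_in = 500, seed = 5)
  expect_lt(abs(fit$summaries$beta_sofas$mode - 0.01), 0.005)
  d <- group_difference(fit, "CHR", "HC")
  expect_lt(abs(d$difference$mode - 0.15), 0.1)
  expect_gte(d$difference$pp, 0.95)
})

test_that("a null covariate slope stays uncertain", {
  set.seed(307)
  wins <- 0L
  for (s in 1:10) {
    g <- rep(c("CHR", "HC"), c(13, 30))
    sof <- round(c(rnorm(13, 67.7, 9.5), rnorm(30, 82.7, 3.8)))
    gsh <- 1.6 + rnorm(43, 0, 0.27)  # sofas unrelated to gsh
    fit <- fit_group_covariate_model(gsh, g, sof, n_kept = 1000, thin = 2,
                                     burn_in = 300, seed = 400 + s)
    if (fit$summaries$beta_sofas$pp < 0.9) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("an identically-zero covariate reduces to the group model", {
  set.seed(308)
  y <- c(rnorm(12, 5), rnorm(12, 6))
  g <- rep(c("CHR", "HC"), each = 12)
  spec <- build_priors(y)
  f_plain <- fit_group_model(y, g, spec, n_kept = 1000, thin = 2,
                             burn_in = 300, seed = 6)
  f_zero <- fit_group_covariate_model(y, g, rep(0, 24), spec = spec,
                                      n_kept = 1000, thin = 2,
                                      burn_in = 300, seed = 6)
  expect_identical(f_plain$samples$draws, f_zero$samples$draws)
})

test_that("shrinkage: the hyperprior pulls the difference toward zero", {
  set.seed(309)
  y <- c(rnorm(8, 0, 1), rnorm(8, 3, 1))
  g <- rep(c("CHR", "HC"), each = 8)
  raw_diff <- mean(y[g == "HC"]) - mean(y[g == "CHR"])
  fit <- fit_group_model(y, g, n_kept = 2000, thin = 2, burn_in = 500, seed = 7)
  expect_lt(abs(fit$difference$mean), abs(raw_diff))
})

test_that("with a huge noise scale the baseline posterior approaches its prior", {
  set.seed(310)
  spec <- list(beta0_mean = 0, beta0_sd = 2,
               sigma_i_low = 1e-3, sigma_i_high = 1e6,
               sigma_beta_shape = 0.5, sigma_beta_rate = 2,
               beta_cov_sd = NULL)
  class(spec) <- "glm_prior_spec"
  y <- c(rnorm(10, 0, 1000), rnorm(10, 0, 1000))
  g <- rep(c("CHR", "HC"), each = 10)
  fit <- fit_group_model(y, g, spec, n_kept = 4000, thin = 2,
                         burn_in = 1000, seed = 8)
  post_sd <- sd(fit$samples$draws[, "beta0"])
  expect_lt(abs(post_sd - spec$beta0_sd) / spec$beta0_sd, 0.2)
})

test_that("chain health: determinism, acceptance window, effective size", {
  set.seed(311)
  y <- c(rnorm(15, 1), rnorm(15, 2))
  g <- rep(c("CHR", "HC"), each = 15)
  f1 <- fit_group_model(y, g, n_kept = 1500, thin = 10, burn_in = 400, seed = 9)
  f2 <- fit_group_model(y, g, n_kept = 1500, thin = 10, burn_in = 400, seed = 9)
  expect_identical(f1$samples$draws, f2$samples$draws)
  expect_true(all(f1$acceptance > 0.1 & f1$acceptance < 0.7))
  # at the default thinning every parameter keeps at least 20% effective
  # draws per retained draw, so the default 11000-draw chain exceeds 2000
  # effective samples even for the slow-mixing shrinkage hyperparameter
  expect_true(all(f1$ess > 0.2 * f1$samples$n_kept))
})

test_that("group_difference validates labels and honours identities", {
  set.seed(312)
  y <- c(rnorm(10, 1), rnorm(10, 3))
  g <- rep(c("CHR", "HC"), each = 10)
  fit <- fit_group_model(y, g, n_kept = 1000, thin = 2, burn_in = 300, seed = 10)
  expect_error(group_difference(fit, "CHR", "XX"), "unknown group")
  d_ab <- group_difference(fit, "HC", "CHR")
  d_ba <- group_difference(fit, "CHR", "HC")
  expect_equal(d_ab$difference$mean, -d_ba$difference$mean)
  # ratio identity on constructed draws: constant difference 0.5, sigma_i = 1
  dr <- fit$samples$draws
  dr[, "beta_HC"] <- 0.25; dr[, "beta_CHR"] <- -0.25; dr[, "sigma_i"] <- 1
  fake <- fit; fake$samples$draws <- dr
  d <- group_difference(fake, "HC", "CHR")
  expect_equal(d$effect_size$mode, 0.5)
  expect_equal(d$effect_size$pp, 1)
})

test_that("degenerate group structures are caught", {
  expect_error(fit_group_model(rnorm(10), rep("CHR", 10), n_kept = 1000,
                               seed = 1), "two group labels")
  set.seed(313)
  y <- c(rnorm(1, 0), rnorm(20, 1))
  g <- c("CHR", rep("HC", 20))
  expect_warning(fit_group_model(y, g, n_kept = 1000, thin = 1,
                                 burn_in = 200, seed = 2), "fewer than 2")
})
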