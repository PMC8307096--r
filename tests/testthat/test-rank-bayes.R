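# Bayesian Spearman correlation: midranks, the latent truncated-normal
# Gibbs sweep, and the full Metropolis-within-Gibbs sampler.

test_that("midranks use the average-tie convention and sum to n(n+1)/2", {
  expect_equal(midranks(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(midranks(c(10, 10, 30)), c(1.5, 1.5, 3))
  set.seed(201)
  for (n in c(5, 17, 50)) {
    v <- sample(n)
    expect_equal(midranks(v), as.numeric(v))  # a permutation ranks to itself
    expect_equal(sum(midranks(rnorm(n))), n * (n + 1) / 2)
  }
  expect_error(midranks(c(NA_real_, NA_real_)), "missing")
  expect_error(midranks(1), "at least 2")
})

test_that("latent sweep respects rank order and tie freedom", {
  set.seed(202)
  # n = 2, forced ordering: latent1 < latent2 always
  for (i in 1:200) {
    z <- sample_latent_scores(c(1, 2), rnorm(2), rho = 0)
    expect_lt(z[1], z[2])
  }
  # all tied: unconstrained normal draws at the conditional moments
  zt <- replicate(3000, sample_latent_scores(rep(1, 4), rep(0, 4), rho = 0)[1])
  expect_lt(abs(mean(zt)), 0.1)
  expect_lt(abs(sd(zt) - 1), 0.1)
  # general case: sorting latents reproduces the strict rank order
  r <- midranks(c(3, 1, 4, 1, 5, 9, 2, 6))
  z <- stats::qnorm((r - 0.5) / 8)
  for (i in 1:100) {
    z <- sample_latent_scores(r, rnorm(8), rho = 0.3, current = z)
    expect_true(all(diff(z[order(r)])[diff(sort(r)) > 0] > 0))
  }
})

test_that("latent sweep tracks a strongly correlated partner", {
  set.seed(203)
  partner <- sort(rnorm(20))
  ranks <- 1:20
  cors <- replicate(1000, {
    z <- sample_latent_scores(ranks, partner, rho = 0.99)
    cor(z, partner)
  })
  expect_gt(mean(cors), 0.9)  # conditional mean rho * partner dominates
})

test_that("concordant data drive the posterior toward rho = 1", {
  set.seed(204)
  x <- rnorm(13)
  y <- exp(x)  # strictly increasing transform: identical ranks
  r <- bayesian_spearman(x, y, n_kept = fast_chain$n_kept,
                         thin = fast_chain$thin,
                         burn_in = fast_chain$burn_in, seed = 1)
  expect_gte(r$rho_summary$pp, 0.99)
  expect_gt(r$rho_summary$mode, 0.8)
  expect_gt(r$bf10, 1)
})

test_that("the sampler is deterministic under a fixed seed", {
  p <- generate_rank_pair(15, 0.4, seed = 3)
  r1 <- bayesian_spearman(p$x, p$y, n_kept = 1000, thin = 2,
                          burn_in = 200, seed = 42)
  r2 <- bayesian_spearman(p$x, p$y, n_kept = 1000, thin = 2,
                          burn_in = 200, seed = 42)
  expect_identical(r1$draws$draws, r2$draws$draws)
  expect_identical(r1$bf10, r2$bf10)
})

test_that("every retained draw lies strictly inside (-1, 1)", {
  p <- generate_rank_pair(20, 0.7, seed = 4)
  r <- bayesian_spearman(p$x, p$y, n_kept = 1500, thin = 2,
                         burn_in = 300, seed = 5)
  expect_true(all(abs(r$draws$draws[, "rho"]) < 1))
})

test_that("sign symmetry: negating y reflects the rho posterior", {
  p <- generate_rank_pair(25, 0.5, seed = 6)
  r_pos <- bayesian_spearman(p$x, p$y, n_kept = 1500, thin = 2,
                             burn_in = 300, seed = 7)
  r_neg <- bayesian_spearman(p$x, -p$y, n_kept = 1500, thin = 2,
                             burn_in = 300, seed = 7)
  expect_lt(abs(r_pos$rho_summary$mode + r_neg$rho_summary$mode), 0.1)
  expect_lt(abs(r_pos$rho_summary$pp - r_neg$rho_summary$pp), 0.05)
})

test_that("large-sample posterior mode agrees with the classical coefficient", {
  p <- generate_rank_pair(200, 0.5, seed = 8)
  classical <- cor(rank(p$x), rank(p$y))
  r <- bayesian_spearman(p$x, p$y, n_kept = 1500, thin = 2,
                         burn_in = 300, seed = 9)
  expect_lt(abs(r$rho_summary$mode - classical), 0.1)
})

test_that("acceptance rate lands in a healthy band after adaptation", {
  p <- generate_rank_pair(30, 0.3, seed = 10)
  r <- bayesian_spearman(p$x, p$y, n_kept = 1500, thin = 2,
                         burn_in = 300, seed = 11)
  expect_gte(r$acceptance_rate, 0.1)
  expect_lte(r$acceptance_rate, 0.7)
})

test_that("ties are handled: tied data still sample and stay calibrated", {
  set.seed(212)
  x <- sample(1:5, 30, replace = TRUE)  # heavy ties
  y <- x + sample(0:2, 30, replace = TRUE)
  r <- bayesian_spearman(x, y, n_kept = 1000, thin = 2, burn_in = 300, seed = 12)
  expect_gt(r$rho_summary$mode, 0)
  expect_true(all(abs(r$draws$draws) < 1))
})

test_that("degenerate and malformed inputs are rejected", {
  expect_error(bayesian_spearman(rep(1, 10), rnorm(10), n_kept = 1000,
                                 seed = 1), "degenerate")
  expect_error(bayesian_spearman(rnorm(10), rnorm(9), n_kept = 1000,
                                 seed = 1), "same length")
  expect_error(bayesian_spearman(rnorm(4), rnorm(4), n_kept = 1000,
                                 seed = 1), "at least 5")
  expect_error(bayesian_spearman(rnorm(10), rnorm(10), n_kept = 500,
                                 seed = 1), "1000")
})

test_that("missing pairs are listwise-deleted before ranking", {
  p <- generate_rank_pair(25, 0.5, seed = 13)
  x <- p$x; y <- p$y
  x[c(2, 5)] <- NA; y[7] <- NA
  r <- bayesian_spearman(x, y, n_kept = 1000, thin = 2, burn_in = 300, seed = 14)
  expect_equal(r$n, 22L)
})

test_that("raw-count configuration divides by the thinning interval", {
  p <- generate_rank_pair(15, 0.4, seed = 15)
  r <- bayesian_spearman(p$x, p$y, n_kept = 4000, thin = 4, burn_in = 200,
                         seed = 16, count_after_thinning = FALSE)
  expect_equal(r$draws$n_kept, 1000L)
})
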