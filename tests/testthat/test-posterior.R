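# independent oracle: posterior moments by adaptive numeric integration,
# entirely separate from the grid-quadrature engine under test
integrate_posterior_mean_prob <- function(y, n, prior) {
  mu <- prior$mu_logit
  sigma <- prior$sigma_logit
  kern <- function(a) exp(log_posterior(a, y, n, prior))
  lims <- c(mu - 12 * sigma - 20, mu + 12 * sigma + 20)
  z <- stats::integrate(kern, lims[1], lims[2], rel.tol = 1e-10)$value
  stats::integrate(function(a) plogis(a) * kern(a), lims[1], lims[2],
                   rel.tol = 1e-10)$value / z
}

test_that("log posterior kernel has the closed-form structure", {
  pr <- prior_spec(0.5, sigma_logit = 2)
  # likelihood term vanishes when there is no data: pure prior kernel
  a <- seq(-3, 3, by = 0.5)
  expect_equal(log_posterior(a, 0, 0, pr), -a^2 / (2 * 4), tolerance = 1e-12)
  # antisymmetry identity at mu = 0:
  # lp(alpha) - lp(-alpha) = (y - n/2) * 2 * alpha
  y <- 113; n <- 231
  expect_equal(log_posterior(2.5, y, n, pr) - log_posterior(-2.5, y, n, pr),
               (y - n / 2) * 2 * 2.5, tolerance = 1e-9)
  # numerically stable far into the tails
  expect_true(is.finite(log_posterior(40, 5, 10, pr)))
  expect_true(is.finite(log_posterior(-40, 5, 10, pr)))
  expect_error(log_posterior(0, -1, 10, pr), "\\[0, n\\]")
  expect_error(log_posterior(0, 5, 10, list(mu = 0, sigma = 0)), "positive")
})

test_that("flat-prior posterior maximizes at the MLE", {
  pr <- flat_prior()
  opt <- optimize(log_posterior, c(-5, 5), y = 113, n = 231, prior = pr,
                  maximum = TRUE, tol = 1e-9)
  expect_equal(opt$maximum, qlogis(113 / 231), tolerance = 1e-3)
})

test_that("quadrature pseudo-draws reproduce integration-oracle moments", {
  cases <- list(
    list(y = 113, n = 231, p = 113 / 231, s = 0.29),
    list(y = 80, n = 231, p = 80 / 231, s = 0.32),
    list(y = 8, n = 455, p = 8 / 455, s = 1.2),
    list(y = 0, n = 50, p = 0.5 / 51, s = 0.8)
  )
  for (cs in cases) {
    pr <- prior_spec(cs$p, sigma_logit = cs$s)
    qd <- posterior_quadrature(cs$y, cs$n, pr, draws = 4000)
    # midpoint pseudo-draws carry a small tail discretization bias, well
    # under the Monte-Carlo error of a 4000-draw sampler (~5e-4 here)
    expect_lt(abs(mean(qd$draws_prob) -
                    integrate_posterior_mean_prob(cs$y, cs$n, pr)), 5e-4)
  }
})

test_that("no-data quadrature returns the prior pushforward", {
  pr <- prior_spec(0.3, sigma_logit = 0.4)
  qd <- posterior_quadrature(0, 0, pr, draws = 4000)
  set.seed(10)
  prior_push <- mean(plogis(rnorm(2e5, pr$mu_logit, pr$sigma_logit)))
  expect_equal(mean(qd$draws_prob), prior_push, tolerance = 0.002)
})

test_that("posterior draws satisfy the probability-scale invariants", {
  pr <- prior_spec(0.346, sigma_logit = 0.3)
  for (fitd in list(posterior_quadrature(80, 231, pr),
                    posterior_mcmc(80, 231, pr, seed = 3))) {
    expect_equal(fitd$draws_prob, plogis(fitd$draws_logit), tolerance = 1e-12)
    expect_true(all(fitd$draws_prob > 0 & fitd$draws_prob < 1))
    expect_equal(length(fitd$draws_logit), 4000)
  }
})

test_that("flat-prior and rigid-prior limits bracket the posterior", {
  # sigma -> infinity: posterior mean -> y/n
  qd <- posterior_quadrature(113, 231, flat_prior())
  expect_lt(abs(mean(qd$draws_prob) - 113 / 231), 0.005)
  mc <- posterior_mcmc(113, 231, flat_prior(), seed = 8)
  expect_lt(abs(mean(mc$draws_prob) - 113 / 231), 0.005)
  # sigma -> 0: posterior collapses to the prior center
  qd0 <- posterior_quadrature(113, 231, rigid_prior(0.25))
  expect_lt(abs(mean(qd0$draws_prob) - 0.25), 0.005)
})

test_that("skeptical prior never widens inference when data are informative", {
  pr <- tune_sigma(0.346, 10, seed = 2)
  post_sd <- sd(posterior_quadrature(80, 231, pr)$draws_prob)
  set.seed(11)
  prior_sd <- sd(plogis(rnorm(2e5, pr$mu_logit, pr$sigma_logit)))
  expect_lt(post_sd, prior_sd)
})

test_that("MCMC chains converge, adapt, and match the quadrature oracle", {
  pr <- tune_sigma(80 / 231, 10, seed = 2)
  mc <- posterior_mcmc(80, 231, pr, seed = 21, variable = "lateral hit to head")
  expect_equal(mc$convergence$n_chains, 4)
  expect_equal(mc$convergence$iterations_per_chain, 2000)
  expect_lt(mc$convergence$rhat, 1.01)
  expect_true(mc$convergence$passed)
  qd <- posterior_quadrature(80, 231, pr)
  se <- mcmc_se(mc$draws_prob, mc$chain, "mean")
  expect_lt(abs(mean(mc$draws_prob) - mean(qd$draws_prob)), 3 * se)
  se_sd <- mcmc_se(mc$draws_prob, mc$chain, "sd")
  expect_lt(abs(sd(mc$draws_prob) - sd(qd$draws_prob)), 3 * se_sd)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(5)
  # four iid chains from one distribution: converged
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(iid), 1.01)
  # two long identical-generator chains: ~1
  set.seed(6)
  two <- matrix(rnorm(20000), ncol = 2)
  expect_lt(split_rhat(two), 1.005)
  # chains separated by 10 SDs: far above the gate
  sep <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(split_rhat(sep), 1.01)
  # a within-chain trend (first half vs second half) is also flagged
  trend <- matrix(rnorm(2000) + rep(c(0, 5), each = 500), ncol = 2)
  expect_gt(split_rhat(trend), 1.01)
  # minimal legal input: finite, no crash
  tiny <- matrix(rnorm(8), ncol = 2)
  expect_true(is.finite(split_rhat(tiny)))
  # constant chains: undefined, not a number
  expect_true(is.na(split_rhat(matrix(1, nrow = 10, ncol = 2))))
  expect_error(split_rhat(matrix(rnorm(10), ncol = 1)), "at least 2 chains")
  expect_error(split_rhat(list(rnorm(10), rnorm(5))), "equal length")
})
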