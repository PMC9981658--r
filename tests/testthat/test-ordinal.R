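# Independent brute-force log-likelihood: per-observation loop over
# cumulative logistic differences, no shared code with the package path.
oracle_loglik <- function(y, x, theta, beta) {
  ll <- 0
  J <- length(theta) + 1
  for (i in seq_along(y)) {
    cum <- c(0, 1 / (1 + exp(-(theta - beta * x[i]))), 1)
    ll <- ll + log(cum[y[i] + 1] - cum[y[i]])
  }
  ll
}

test_that("the ordinal log-likelihood matches the brute-force oracle", {
  with_seed(123, {
    for (rep in 1:50) {
      J <- sample(3:10, 1)
      n <- sample(5:40, 1)
      y <- sample.int(J, n, replace = TRUE)
      x <- rbinom(n, 1, 0.5)
      theta <- sort(rnorm(J - 1, 0, 2))
      beta <- rnorm(1)
      expect_equal(ordinal_loglik(y, x, theta, beta),
                   oracle_loglik(y, x, theta, beta), tolerance = 1e-12)
    }
  })
})

test_that("likelihood edge cases behave as contracted", {
  # single observation, theta_1 = 0, beta = 0 -> log(1/2)
  expect_equal(ordinal_loglik(1, 0, 0, 0), log(0.5))
  # beta = 0 makes the covariate drop out
  y <- c(1, 2, 3, 2)
  expect_equal(ordinal_loglik(y, c(0, 1, 0, 1), c(-1, 1), 0),
               ordinal_loglik(y, c(1, 0, 1, 0), c(-1, 1), 0))
  # category probabilities sum to one for any (theta, beta, x)
  theta <- c(-2, -0.5, 1, 2.5)
  for (x in 0:1) {
    pr <- exp(vapply(1:5, function(j) ordinal_loglik(j, x, theta, 0.7),
                     numeric(1)))
    expect_equal(sum(pr), 1)
  }
  # non-increasing cutpoints have zero prior mass
  expect_identical(ordinal_loglik(c(1, 2), c(0, 1), c(1, 0.5), 0), -Inf)
})

test_that("the fit recovers beta and agrees with an ML oracle", {
  skip_if_not_installed("MASS")
  d <- sim_po_data(1000, beta = 1, seed = 31)
  fit <- fit_proportional_odds(d$y, d$x, mcmc_config(seed = 8))
  mle <- MASS::polr(factor(d$y, ordered = TRUE) ~ d$x)
  expect_lt(abs(coef(fit)[["beta"]] - unname(coef(mle))), 0.3)
  expect_true(all(fit$rhat < 1.1))
  # cutpoints stay strictly increasing in every retained draw
  th <- apply(fit$draws[, seq_len(9), , drop = FALSE], c(1, 3), diff)
  expect_true(all(th > 0))
  # acceptance in a healthy random-walk range
  expect_true(all(fit$acceptance > 0.1 & fit$acceptance < 0.6))
})

test_that("the same seed reproduces the fit exactly", {
  d <- sim_po_data(300, beta = 0.5, seed = 4)
  f1 <- fit_proportional_odds(d$y, d$x, mcmc_config(seed = 99, sampling = 200,
                                                    burn_in = 200))
  f2 <- fit_proportional_odds(d$y, d$x, mcmc_config(seed = 99, sampling = 200,
                                                    burn_in = 200))
  expect_identical(f1$draws, f2$draws)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_proportional_odds(rep(5, 50), rep(0:1, 25)), "identical")
  expect_error(fit_proportional_odds(rep(1:5, 10), rep(0, 50)), "non-empty")
})

test_that("rhat separates mixed from unmixed chains", {
  with_seed(21, {
    iid <- matrix(rnorm(4000), ncol = 4)
    expect_lt(rhat(iid), 1.05)
    off <- cbind(rnorm(1000), rnorm(1000) + 5)
    expect_gt(rhat(off), 1.1)
    copies <- matrix(rep(rnorm(1000), 4), ncol = 4)
    expect_lt(rhat(copies), 1.02)  # B ~ 0: only split-half drift remains
    expect_error(rhat(matrix(rnorm(100), ncol = 1)), "two chains")
  })
})

test_that("the HDI is the narrowest window of sorted draws", {
  h <- hdi(1:100, 0.75)
  expect_equal(unname(h[2] - h[1]), 74)
  with_seed(6, {
    z <- rnorm(10000)
    h2 <- hdi(z, 0.75)
    expect_equal(unname(h2), c(-1.15, 1.15), tolerance = 0.05)
  })
  expect_equal(unname(diff(hdi(rep(3.3, 50)))), 0)
  # skewed draws: HDI must beat the equal-tail interval in width
  with_seed(7, {
    g <- rgamma(5000, shape = 2)
    h3 <- hdi(g, 0.75)
    q <- quantile(g, c(0.125, 0.875))
    expect_lt(diff(h3), q[2] - q[1])
  })
})

test_that("probability columns are coherent and respect the sign convention", {
  d <- sim_po_data(800, beta = -1, seed = 12)  # beta < 0: menses shifts down
  fit <- fit_proportional_odds(d$y, d$x, mcmc_config(seed = 3))
  pt <- probability_table(fit)
  sums <- tapply(pt$mean, pt$status, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-8)
  expect_true(all(pt$lower <= pt$mean + 1e-12 & pt$mean <= pt$upper + 1e-12))
  # with beta < 0, P(Y <= j | menses) grows: low scores more likely in menses
  low <- pt$score <= 3
  expect_gt(sum(pt$mean[pt$status == "menses" & low]),
            sum(pt$mean[pt$status == "no_menses" & low]))
  pr <- predict(fit)
  expect_equal(colSums(pr), c(`menses=0` = 1, `menses=1` = 1))
  sim <- simulate(fit, nsim = 2, seed = 5)
  expect_equal(dim(sim), c(fit$n, 2L))
  expect_true(all(unlist(sim) %in% fit$categories))
})
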