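# Sigmoid belief nets: ancestral sampling, exact posteriors (explaining
# away), the delta rule, and variational free energy.

test_that("the two-cause fixture reproduces the stated arithmetic", {
  net <- toy_jump_net()
  a <- sigmoid(-10)
  # prior odds of each cause being off
  expect_equal((1 - a) / a, exp(10), tolerance = 1e-12)
  # jump input with exactly one cause active is zero
  expect_equal(net$biases[[2]] + net$weights[[1]][1, 1], 0)
  # jump odds with no cause active
  p0 <- sigmoid(net$biases[[2]])
  expect_equal(p0 / (1 - p0), exp(-20), tolerance = 1e-12)
  # both causes together are approximately e^-20 a priori
  expect_equal(a^2, exp(-20), tolerance = 1e-3)
})

test_that("observing the effect makes the two causes anti-correlated", {
  post <- sbn_posterior(toy_jump_net(), visible = 1)
  expect_equal(sum(post$probs), 1, tolerance = 1e-12)
  p <- function(e, t) post$probs[post$states[, 1] == e & post$states[, 2] == t]
  expect_equal(p(1, 0), 0.49995, tolerance = 1e-4)
  expect_equal(p(0, 1), p(1, 0), tolerance = 1e-12)
  expect_equal(p(1, 1), 4.5e-5, tolerance = 0.02)
  m1 <- sum(post$probs * post$states[, 1])
  m2 <- sum(post$probs * post$states[, 2])
  cov12 <- sum(post$probs * post$states[, 1] * post$states[, 2]) - m1 * m2
  expect_lt(cov12, 0)
})

test_that("ancestral sampling follows the generative model", {
  off <- sbn(c(2, 1), list(matrix(0, 1, 2)), list(c(-1e3, -1e3), -1e3))
  s <- sbn_sample(off, seed = 1)
  expect_identical(unlist(s), c(0, 0, 0))

  s1 <- sbn_sample(toy_jump_net(), n = 5, seed = 7)
  s2 <- sbn_sample(toy_jump_net(), n = 5, seed = 7)
  expect_identical(s1, s2)

  # frequency of the effect matches the enumerated marginal
  net <- toy_jump_net()
  n <- 1e6
  draws <- sbn_sample(net, n = n, seed = 3)
  p_jump <- exp(sbn_log_marginal(net, 1))
  expect_lt(abs(mean(draws[[2]]) - p_jump), 3 * sqrt(p_jump * (1 - p_jump) / n))
})

test_that("exact posterior normalizes and reduces to the prior without
           weights", {
  set.seed(4)
  net <- sbn(c(2, 2), list(matrix(0, 2, 2)),
             list(stats::rnorm(2), stats::rnorm(2)))
  post <- sbn_posterior(net, c(1, 0))
  expect_equal(sum(post$probs), 1, tolerance = 1e-12)
  prior <- sigmoid(net$biases[[1]])
  expect_equal(as.numeric(post$probs %*% post$states), prior,
               tolerance = 1e-12)
})

test_that("delta rule: zero presynaptic or matched prediction gives zero
           update; expectation equals the likelihood gradient", {
  net <- toy_jump_net()
  up <- sbn_delta_update(net, list(c(0, 0), 1), learning_rate = 0.5)
  expect_identical(up$weights[[1]], net$weights[[1]])  # presynaptic off

  set.seed(12)
  net2 <- sbn(c(2, 1), list(matrix(stats::rnorm(2), 1, 2)),
              list(stats::rnorm(2), stats::rnorm(1)))
  v <- 1
  post <- sbn_posterior(net2, v)
  expW <- matrix(0, 1, 2)
  for (r in seq_len(nrow(post$states))) {
    s <- post$states[r, ]
    upd <- sbn_delta_update(net2, list(s, v), 1)
    expW <- expW + post$probs[r] * (upd$weights[[1]] - net2$weights[[1]])
  }
  eps <- 1e-6
  for (j in 1:2) {
    np <- net2; np$weights[[1]][1, j] <- np$weights[[1]][1, j] + eps
    nm <- net2; nm$weights[[1]][1, j] <- nm$weights[[1]][1, j] - eps
    num <- (sbn_log_marginal(np, v) - sbn_log_marginal(nm, v)) / (2 * eps)
    expect_equal(expW[1, j], num, tolerance = 1e-3)
  }
})

test_that("variational free energy is a lower bound with non-negative gap", {
  set.seed(6)
  net <- sbn(c(3, 2), list(matrix(stats::rnorm(6), 2, 3)),
             list(stats::rnorm(3), stats::rnorm(2)))
  v <- c(1, 0)
  for (k in 1:100) {
    q <- stats::runif(3)
    rep <- sbn_free_energy(net, v, q)
    expect_gte(rep$kl_gap, -1e-12)
    expect_equal(rep$neg_free_energy, rep$log_likelihood - rep$kl_gap,
                 tolerance = 1e-10)
  }
  expect_error(sbn_free_energy(net, v, c(1.2, 0.1, 0.3)), "\\[0, 1\\]")
})

test_that("mean-field fit: ascent is monotone, one-unit posteriors are
           recovered exactly, explaining away leaves a positive gap", {
  net1 <- sbn(c(1, 1), list(matrix(2)), list(0.3, -1))
  fit1 <- sbn_fit_q(net1, 1, iters = 2000, tol = 1e-14)
  expect_true(fit1$converged)
  expect_lt(abs(sbn_free_energy(net1, 1, fit1$q)$kl_gap), 1e-10)

  # zero-weight net: q equals the prior
  net0 <- sbn(c(2, 1), list(matrix(0, 1, 2)), list(c(0.7, -0.4), 0.2))
  fit0 <- sbn_fit_q(net0, 1, iters = 500)
  expect_equal(fit0$q, sigmoid(c(0.7, -0.4)), tolerance = 1e-8)

  fitj <- sbn_fit_q(toy_jump_net(), 1, iters = 300)
  expect_true(all(diff(fitj$neg_free_energy) > -1e-9))
  gap <- sbn_free_energy(toy_jump_net(), 1, fitj$q)$kl_gap
  expect_gt(gap, 0.1)  # the factorial family cannot represent the posterior
})
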