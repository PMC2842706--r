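# Restricted Boltzmann machine: energy arithmetic, enumeration oracles,
# Gibbs sampling, exact and contrastive-divergence gradients.

test_that("energy matches direct term-by-term summation", {
  m0 <- rbm(2, 2, weights = matrix(0, 2, 2))
  expect_identical(rbm_energy(m0, c(0, 0), c(0, 0)), 0)
  m1 <- rbm(1, 1, weights = matrix(1, 1, 1))
  expect_identical(rbm_energy(m1, 1, 1), -1)

  m <- random_rbm(3, 2, seed = 11)
  v <- c(1, 0, 1); h <- c(1, 1)
  by_hand <- 0
  for (i in 1:3) for (j in 1:2) by_hand <- by_hand + v[i] * m$weights[i, j] * h[j]
  by_hand <- by_hand + sum(v * m$visible_bias) + sum(h * m$hidden_bias)
  expect_equal(rbm_energy(m, v, h), -by_hand, tolerance = 1e-12)

  expect_error(rbm_energy(m, c(1, 0), h), "length")
})

test_that("partition function and joint distribution are exact", {
  expect_equal(rbm_partition(rbm(2, 1, weights = matrix(0, 2, 1))), 8)
  expect_equal(rbm_partition(rbm(1, 1, weights = matrix(1, 1, 1))),
               3 + exp(1), tolerance = 1e-12)
  m <- random_rbm(3, 2, seed = 5)
  expect_equal(sum(rbm_joint(m)), 1, tolerance = 1e-12)
  expect_equal(rowSums(rbm_joint(m)), rbm_marginal(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(rbm_partition(rbm(20, 20)), "capacity")
})

test_that("conditionals factorize and match the Bayes oracle", {
  m0 <- rbm(3, 2, weights = matrix(0, 3, 2))
  expect_equal(rbm_conditional(m0, c(1, 0, 1)), rep(0.5, 2))

  m <- random_rbm(3, 2, seed = 7)
  H <- binary_states(2)
  for (v in asplit(binary_states(3), 1)) {
    exact <- as.numeric(joint_hidden_conditional(m, v) %*% H)
    expect_equal(rbm_conditional(m, as.numeric(v)), exact, tolerance = 1e-12)
  }

  # a bias of -10 makes a disconnected unit e^10 times likelier off than on
  mb <- rbm(1, 1, weights = matrix(0), hidden_bias = -10)
  p_on <- rbm_conditional(mb, 0)
  expect_equal(p_on, 1 / (1 + exp(10)), tolerance = 1e-12)
  expect_equal((1 - p_on) / p_on, exp(10), tolerance = 1e-10)

  expect_error(rbm_conditional(m, c(1, 0, 1), "sideways"))
})

test_that("Gibbs sampling is seed-reproducible and hits the Boltzmann
           distribution on an enumerable model", {
  m <- random_rbm(2, 2, seed = 3, scale = 0.8)
  s1 <- rbm_gibbs_step(m, c(1, 0), seed = 42)
  s2 <- rbm_gibbs_step(m, c(1, 0), seed = 42)
  expect_identical(s1, s2)

  m0 <- rbm(2, 1, weights = matrix(0, 2, 1))
  set.seed(9)
  out <- rbm_gibbs_step(m0, matrix(0, 4000, 2))
  expect_true(all(abs(colMeans(out$v_next) - 0.5) < 3 * sqrt(0.25 / 4000)))

  # long-run visible marginal: total variation against enumeration
  draws <- sample_rbm_data(m, 2e5, burn_in = 40, seed = 13)
  emp <- tabulate(apply(draws, 1, state_index), 4) / 2e5
  tv <- 0.5 * sum(abs(emp - rbm_marginal(m)))
  expect_lt(tv, 0.02)
})

test_that("exact ML gradient vanishes at the generating distribution and
           matches central differences", {
  m <- random_rbm(3, 2, seed = 21, scale = 0.7)
  g0 <- rbm_ml_gradient(m, binary_states(3), data_weights = rbm_marginal(m))
  expect_lt(max(abs(unlist(g0))), 1e-12)

  data <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 0), 3, byrow = TRUE)
  g <- rbm_ml_gradient(m, data)
  ll <- function(mm) mean(log(rbm_marginal(mm)[apply(data, 1, state_index)]))
  eps <- 1e-5
  for (i in 1:3) for (j in 1:2) {
    mp <- m; mp$weights[i, j] <- mp$weights[i, j] + eps
    mm2 <- m; mm2$weights[i, j] <- mm2$weights[i, j] - eps
    expect_equal(g$d_weights[i, j], (ll(mp) - ll(mm2)) / (2 * eps),
                 tolerance = 1e-6)
  }
  for (i in 1:3) {
    mp <- m; mp$visible_bias[i] <- mp$visible_bias[i] + eps
    mm2 <- m; mm2$visible_bias[i] <- mm2$visible_bias[i] - eps
    expect_equal(g$d_visible_bias[i], (ll(mp) - ll(mm2)) / (2 * eps),
                 tolerance = 1e-6)
  }

  # hand-computed case: single training vector, zero-initialized 1v/1h model
  mz <- rbm(1, 1, weights = matrix(0, 1, 1))
  gz <- rbm_ml_gradient(mz, matrix(1, 1, 1))
  expect_equal(gz$d_weights[1, 1], 0.25, tolerance = 1e-12)
  expect_equal(gz$d_visible_bias, 0.5, tolerance = 1e-12)
  expect_equal(gz$d_hidden_bias, 0, tolerance = 1e-12)
})

test_that("CD update: vanishing step size leaves parameters unchanged and
           the expected update is centred at zero for a matched model", {
  m <- random_rbm(3, 2, seed = 2)
  batch <- matrix(c(1, 0, 1, 0, 0, 1), 2, byrow = TRUE)
  up <- rbm_cd1(m, batch, train_config(learning_rate = 1e-300), seed = 1)
  expect_identical(up$model$weights, m$weights)
  expect_identical(up$model$visible_bias, m$visible_bias)
  expect_error(rbm_cd1(m, batch[0, , drop = FALSE]), "empty")

  # zero model: its marginal is uniform; batches drawn uniformly
  m0 <- rbm(2, 1, weights = matrix(0, 2, 1))
  set.seed(17)
  n_rep <- 4000
  acc <- replicate(n_rep, {
    batch <- matrix(stats::rbinom(16, 1, 0.5), 8, 2)
    rbmstack:::cd_statistics(m0, batch)$d_weights
  })
  se <- apply(acc, 1, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(rowMeans(acc)) < 3 * se + 1e-12))
})

test_that("expected CD-1 update points within 90 degrees of the exact ML
           gradient", {
  m <- random_rbm(3, 2, seed = 31, scale = 0.6)
  data <- binary_states(3)[c(2, 4, 7, 8), ]
  g_ml <- rbm_ml_gradient(m, data)
  set.seed(8)
  acc <- replicate(3000, rbmstack:::cd_statistics(m, data)$d_weights)
  g_cd <- rowMeans(acc)
  cosine <- sum(g_cd * as.numeric(g_ml$d_weights)) /
    sqrt(sum(g_cd^2) * sum(g_ml$d_weights^2))
  expect_gt(cosine, 0)
})

test_that("analytic free energy agrees with hidden-state enumeration", {
  m <- random_rbm(3, 6, seed = 41, scale = 0.5)
  H <- binary_states(6)
  for (v in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    e <- vapply(asplit(H, 1), function(h) rbm_energy(m, v, as.numeric(h)),
                numeric(1))
    expect_equal(rbm_free_energy(m, v), -log(sum(exp(-e))), tolerance = 1e-10)
  }
  m0 <- rbm(4, 6, weights = matrix(0, 4, 6))
  expect_equal(rbm_free_energy(m0, c(1, 0, 1, 1)), -6 * log(2),
               tolerance = 1e-12)
  # exp(-F)/Z equals the enumerated marginal
  m2 <- random_rbm(3, 2, seed = 43)
  z <- rbm_partition(m2)
  f <- rbm_free_energy(m2, binary_states(3))
  expect_equal(exp(-f) / z, rbm_marginal(m2), tolerance = 1e-12)
})
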