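# Factored third-order model: tensor/factored energy equivalence, factor
# messages, gated sampling, mean-field reconstruction, CD learning and
# the cubic gain control.

test_that("three-way and factored energies agree through the composed
           tensor", {
  tz <- array(0.5, dim = c(2, 2, 1))
  expect_equal(threeway_energy(tz, c(1, 1), 0), 0)
  expect_equal(threeway_energy(tz, c(1, 1), 1), -2)

  m1 <- gated_rbm(2, 1, 1, vis_to_factor = matrix(c(1, 1), 2, 1),
                  factor_to_hidden = matrix(2, 1, 1))
  expect_equal(as.numeric(compose_tensor(m1)), rep(2, 4))
  expect_equal(gated_energy(m1, c(1, 1), 1), -8)
  mz <- gated_rbm(2, 2, 1, vis_to_factor = matrix(0, 2, 2),
                  factor_to_hidden = matrix(0, 2, 1))
  expect_true(all(compose_tensor(mz) == 0))
  expect_equal(gated_energy(m1, c(1, 1), 0), 0)

  # exhaustive equivalence up to 4 visibles / 3 hiddens / 3 factors
  for (cfg in list(c(2, 1, 1), c(3, 2, 2), c(4, 3, 3))) {
    m <- random_gated(cfg[1], cfg[3], cfg[2], seed = sum(cfg) * 7)
    m$hidden_bias[] <- 0; m$visible_bias[] <- 0
    tens <- compose_tensor(m)
    for (v in asplit(binary_states(cfg[1]), 1)) {
      for (h in asplit(binary_states(cfg[2]), 1)) {
        expect_equal(threeway_energy(tens, as.numeric(v), as.numeric(h)),
                     gated_energy(m, as.numeric(v), as.numeric(h)),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("factor messages square the filter output and reproduce the
           hidden energy difference", {
  m <- random_gated(3, 2, 2, seed = 77)
  v <- c(1, 0, 1); h <- c(1, 0)
  msg <- factor_messages(m, v, h)
  filt <- as.numeric(v %*% m$vis_to_factor)
  expect_equal(msg$to_hidden, filt^2, tolerance = 1e-12)
  expect_equal(factor_messages(m, v, c(0, 0))$to_visible, c(0, 0))

  inp <- m$hidden_bias + as.numeric(msg$to_hidden %*% m$factor_to_hidden)
  for (k in 1:2) {
    h1 <- h; h1[k] <- 1
    h0 <- h; h0[k] <- 0
    expect_equal(inp[k], gated_energy(m, v, h0) - gated_energy(m, v, h1),
                 tolerance = 1e-10)
  }
})

test_that("gated hidden conditionals match enumeration and are monotone
           in the gating weight", {
  m0 <- gated_rbm(3, 2, 2, vis_to_factor = matrix(0, 3, 2),
                  factor_to_hidden = matrix(0, 2, 2))
  expect_equal(gated_sample_hidden(m0, c(1, 0, 1), seed = 1)$probs,
               rep(0.5, 2))

  m <- random_gated(3, 2, 2, seed = 55)
  J <- gated_joint(m)
  H <- binary_states(2)
  for (vs in seq_len(8)) {
    v <- binary_states(3)[vs, ]
    exact <- as.numeric((J[vs, ] / sum(J[vs, ])) %*% H)
    expect_equal(gated_sample_hidden(m, as.numeric(v))$probs, exact,
                 tolerance = 1e-12)
  }

  v <- c(1, 1, 0)
  p0 <- gated_sample_hidden(m, v)$probs[1]
  m2 <- m; m2$factor_to_hidden[, 1] <- m2$factor_to_hidden[, 1] + 0.5
  expect_gte(gated_sample_hidden(m2, v)$probs[1], p0)
})

test_that("the visible units do not factorize given the hidden states", {
  m <- random_gated(3, 2, 2, seed = 91, scale = 1.2)
  J <- gated_joint(m)
  pv_h <- J[, 4] / sum(J[, 4])
  V <- binary_states(3)
  marg <- as.numeric(pv_h %*% V)
  prod_p <- apply(V, 1, function(v) prod(ifelse(v == 1, marg, 1 - marg)))
  expect_gt(max(abs(prod_p - pv_h)), 1e-4)
})

test_that("damped mean field reaches a logistic fixed point", {
  m0 <- gated_rbm(3, 2, 2, vis_to_factor = matrix(0.3, 3, 2),
                  factor_to_hidden = matrix(0.3, 2, 2))
  mf0 <- gated_mean_field(m0, c(0, 0), c(1, 0, 1), lambda = 0.5, iters = 100,
                          tol = 1e-10)
  expect_equal(mf0$r, rep(0.5, 3), tolerance = 1e-8)
  expect_lt(mf0$residual, 1e-8)

  m <- random_gated(4, 3, 2, seed = 13, scale = 0.5)
  mf <- gated_mean_field(m, c(1, 0), c(1, 1, 0, 0), lambda = 0.5,
                         iters = 500, tol = 1e-12)
  field <- rbmstack:::gated_visible_field(m, matrix(mf$r, 1),
                                          matrix(c(1, 0), 1))
  expect_lt(max(abs(mf$r - sigmoid(field))), 1e-6)

  # an attractive single-factor model keeps the aligned pattern closer
  ma <- gated_rbm(4, 1, 1, vis_to_factor = matrix(c(1, 1, -1, -1), 4, 1),
                  factor_to_hidden = matrix(1.5, 1, 1))
  pat <- c(1, 1, 0, 0); anti <- c(0, 0, 1, 1)
  r_pat <- gated_mean_field(ma, 1, pat, iters = 50)$r
  r_anti <- gated_mean_field(ma, 1, anti, iters = 50)$r
  expect_lt(sum((r_pat - pat)^2), sum((r_anti - pat)^2))
})

test_that("gated CD: vanishing step leaves parameters unchanged and
           training reduces the reconstruction error", {
  m <- random_gated(4, 2, 2, seed = 3, scale = 0.3)
  batch <- binary_states(4)[c(2, 5, 9), ]
  up <- gated_cd_update(m, batch, train_config(learning_rate = 1e-300),
                        seed = 2)
  expect_identical(up$model$vis_to_factor, m$vis_to_factor)
  expect_identical(up$model$factor_to_hidden, m$factor_to_hidden)
  expect_error(gated_cd_update(m, batch[0, , drop = FALSE]), "empty")

  drops <- vapply(1:5, function(s) {
    data <- make_oriented_strokes(4, 2, 1, 200, seed = 40 + s)
    fit <- train_gated_rbm(data, 6, 6,
                           train_config(epochs = 20, learning_rate = 0.05,
                                        batch_size = 20, seed = s),
                           gating = "tied", normalize_filters = TRUE)
    utils::tail(fit$recon_error, 1) < fit$recon_error[1]
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("tensor-path oracle agrees with the factored path on composed
           models", {
  m <- random_gated(3, 2, 2, seed = 8, scale = 0.6)
  m$visible_bias[] <- 0
  tens <- compose_tensor(m)
  for (v in asplit(binary_states(3), 1)) {
    expect_equal(
      rbmstack:::threeway_hidden_input(tens, m$hidden_bias, as.numeric(v)),
      as.numeric(rbmstack:::gated_hidden_input(m, matrix(as.numeric(v), 1))),
      tolerance = 1e-10)
  }
  up <- threeway_cd_update(tens, m$hidden_bias, m$visible_bias,
                           binary_states(3)[c(2, 7), ],
                           train_config(learning_rate = 0.1), seed = 5)
  expect_equal(dim(up$tensor), dim(tens))
  expect_true(all(is.finite(up$tensor)))
})

test_that("gain control is cubic in activity and demands negative
           weights", {
  w <- matrix(c(-1, -1), 2, 1)
  expect_equal(gain_control_energy(w, c(1, 1)), 8)
  expect_equal(gain_control_energy(w, c(2, 2)), 64)
  expect_equal(gain_control_energy(w, c(0, 0)), 0)
  expect_gte(gain_control_energy(matrix(-stats::runif(6), 3, 2),
                                 stats::runif(3)), 0)
  expect_error(gain_control_energy(matrix(c(1, -1), 2, 1), c(1, 1)),
               "non-positive")
  expect_error(gain_control_energy(w, c(-1, 1)), "non-negative")
})
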