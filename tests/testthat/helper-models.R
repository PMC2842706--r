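# Shared fixtures: small random models built in code.

random_rbm <- function(nv, nh, seed, scale = 1) {
  set.seed(seed)
  rbm(nv, nh,
      weights = matrix(stats::rnorm(nv * nh, sd = scale), nv, nh),
      visible_bias = stats::rnorm(nv, sd = scale),
      hidden_bias = stats::rnorm(nh, sd = scale))
}

random_gated <- function(nv, nf, nh, seed, scale = 0.8) {
  set.seed(seed)
  gated_rbm(nv, nf, nh,
            vis_to_factor = matrix(stats::rnorm(nv * nf, sd = scale), nv, nf),
            factor_to_hidden = matrix(stats::rnorm(nf * nh, sd = scale), nf, nh),
            hidden_bias = stats::rnorm(nh, sd = scale),
            visible_bias = stats::rnorm(nv, sd = scale))
}

# exact p(h | v) of an RBM from the enumerated joint (Bayes oracle)
joint_hidden_conditional <- function(model, v) {
  J <- rbm_joint(model)
  row <- J[state_index(v), ]
  row / sum(row)
}
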