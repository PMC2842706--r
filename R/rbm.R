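# Restricted Boltzmann machine: energy, exact enumeration oracles on small
# instances, Gibbs sampling, the exact maximum-likelihood gradient, and
# one-step contrastive-divergence learning.

#' Construct a restricted Boltzmann machine
#'
#' An RBM is an undirected two-layer model over binary visible and hidden
#' units with no within-layer connections.  The probability of a joint
#' configuration `(v, h)` is `exp(-E(v, h)) / Z` with energy
#' \deqn{E(v,h) = -v^T b - h^T c - v^T W h,}
#' where `W` is the symmetric weight matrix and `b`, `c` the visible and
#' hidden biases.  Because there are no within-layer connections, each
#' layer is conditionally independent given the other, which is what makes
#' inference and contrastive-divergence learning fast.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param weights optional `n_visible x n_hidden` weight matrix.  If
#'   omitted, weights are drawn i.i.d. from a zero-mean Gaussian with
#'   standard deviation `init_sd`.
#' @param visible_bias,hidden_bias optional bias vectors (default 0).
#' @param init_sd standard deviation of the random weight initialization.
#' @param seed optional seed for the random initialization.
#' @return an object of class `"rbm"` with elements `weights`,
#'   `visible_bias`, `hidden_bias`.
#' @examples
#' m <- rbm(4, 3, seed = 1)
#' rbm_energy(m, c(1, 0, 1, 0), c(0, 1, 1))
#' @export
rbm <- function(n_visible, n_hidden, weights = NULL, visible_bias = NULL,
                hidden_bias = NULL, init_sd = 0.01, seed = NULL) {
  stopifnot(n_visible >= 1, n_hidden >= 1)
  maybe_seed(seed)
  if (is.null(weights)) {
    weights <- matrix(stats::rnorm(n_visible * n_hidden, sd = init_sd),
                      n_visible, n_hidden)
  }
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(n_visible, n_hidden))) {
    stop("`weights` must be ", n_visible, " x ", n_hidden, call. = FALSE)
  }
  if (is.null(visible_bias)) visible_bias <- numeric(n_visible)
  if (is.null(hidden_bias)) hidden_bias <- numeric(n_hidden)
  check_length(visible_bias, n_visible)
  check_length(hidden_bias, n_hidden)
  stopifnot(all(is.finite(weights)), all(is.finite(visible_bias)),
            all(is.finite(hidden_bias)))
  structure(list(weights = weights,
                 visible_bias = as.numeric(visible_bias),
                 hidden_bias = as.numeric(hidden_bias)),
            class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat("Restricted Boltzmann machine:", nrow(x$weights), "visible,",
      ncol(x$weights), "hidden units\n")
  invisible(x)
}

n_visible <- function(m) nrow(m$weights)
n_hidden <- function(m) ncol(m$weights)

#' Energy of a joint configuration
#'
#' Computes `E(v, h) = -(v . b + h . c + v' W h)`.  Lower energy means
#' higher probability under the Boltzmann distribution.
#'
#' @param model an [rbm()].
#' @param v,h 0/1 state vectors for the visible and hidden layer.
#' @return a single number.
#' @export
rbm_energy <- function(model, v, h) {
  check_binary(v); check_binary(h)
  check_length(v, n_visible(model))
  check_length(h, n_hidden(model))
  -(sum(v * model$visible_bias) + sum(h * model$hidden_bias) +
      as.numeric(v %*% model$weights %*% h))
}

#' Free energy of a visible vector
#'
#' The unnormalized log-probability of `v` with the hidden layer summed
#' out analytically:
#' \deqn{F(v) = -v^T b - \sum_k \log(1 + e^{c_k + (W^T v)_k}),}
#' so that `p(v) = exp(-F(v)) / Z`.  Costs one matrix-vector product; no
#' enumeration over hidden states is involved, which is what makes exact
#' label posteriors affordable in time linear in the number of labels.
#'
#' @param model an [rbm()].
#' @param v 0/1 visible vector, or a matrix with one state per row.
#' @return numeric scalar (or vector, one entry per row of `v`).
#' @export
rbm_free_energy <- function(model, v) {
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  v <- check_dataset(v, n_visible(model))
  x <- sweep(v %*% model$weights, 2, model$hidden_bias, "+")
  f <- -as.numeric(v %*% model$visible_bias) - rowSums(softplus(x))
  if (length(f) == 1) f[[1]] else f
}

#' Partition function by enumeration
#'
#' Sums `exp(-E)` over all joint states.  The hidden (or visible,
#' whichever is smaller) layer is summed analytically through
#' [rbm_free_energy()], so the enumeration runs over a single layer.
#' Guarded to models with at most 24 total units.
#'
#' @param model an [rbm()].
#' @return the scalar normalizer `Z`.
#' @examples
#' rbm_partition(rbm(2, 1, weights = matrix(0, 2, 1)))  # 8: all E = 0
#' @export
rbm_partition <- function(model) {
  guard_units(n_visible(model) + n_hidden(model))
  v <- binary_states(n_visible(model))
  sum(exp(-rbm_free_energy(model, v)))
}

#' Exact marginal distribution over visible states
#'
#' Returns `p(v)` for every visible configuration, indexed in the order of
#' [binary_states()].
#'
#' @param model an [rbm()] small enough to enumerate.
#' @return numeric vector of length `2^n_visible` summing to 1.
#' @export
rbm_marginal <- function(model) {
  guard_units(n_visible(model) + n_hidden(model))
  f <- rbm_free_energy(model, binary_states(n_visible(model)))
  w <- exp(-(f - min(f)))
  w / sum(w)
}

#' Exact joint distribution table
#'
#' Enumerates `p(v, h)` for every joint configuration of a small RBM.
#' This is the brute-force oracle against which the analytic conditionals
#' and free energies are verified.
#'
#' @param model an [rbm()] with at most 24 total units.
#' @return matrix of probabilities, rows indexing visible states and
#'   columns hidden states in [binary_states()] order.
#' @export
rbm_joint <- function(model) {
  nv <- n_visible(model); nh <- n_hidden(model)
  guard_units(nv + nh)
  V <- binary_states(nv); H <- binary_states(nh)
  # -E(v,h) = v.b + h.c + v'Wh for all pairs at once
  neg_e <- outer(as.numeric(V %*% model$visible_bias),
                 as.numeric(H %*% model$hidden_bias), "+") +
    (V %*% model$weights) %*% t(H)
  p <- exp(neg_e - max(neg_e))
  p / sum(p)
}

#' Conditional activation probabilities of one layer given the other
#'
#' Each unit of the target layer turns on independently with probability
#' `sigmoid(bias + weighted input)`; conditional independence within a
#' layer is exact in an RBM.
#'
#' @param model an [rbm()].
#' @param given 0/1 state of the conditioning layer (or a matrix of
#'   states, one per row).
#' @param direction `"hidden_given_visible"` or `"visible_given_hidden"`.
#' @return vector (or matrix) of per-unit on-probabilities.
#' @export
rbm_conditional <- function(model,
                            given,
                            direction = c("hidden_given_visible",
                                          "visible_given_hidden")) {
  direction <- match.arg(direction)
  single <- !is.matrix(given)
  if (single) given <- matrix(given, nrow = 1)
  if (direction == "hidden_given_visible") {
    given <- check_dataset(given, n_visible(model))
    p <- sigmoid(sweep(given %*% model$weights, 2, model$hidden_bias, "+"))
  } else {
    given <- check_dataset(given, n_hidden(model))
    p <- sigmoid(sweep(given %*% t(model$weights), 2, model$visible_bias, "+"))
  }
  if (single) as.numeric(p) else p
}

#' One full step of alternating Gibbs sampling
#'
#' Samples the hidden layer from `p(h | v)`, then the visible layer from
#' `p(v | h)`.  Operates on a matrix of visible states so that many
#' independent chains run in parallel.
#'
#' @param model an [rbm()].
#' @param v 0/1 visible vector or matrix (one chain per row).
#' @param seed optional seed.
#' @return list with elements `h`, `v_next` (sampled states), `p_hidden`,
#'   `p_visible` (the probabilities used).
#' @export
rbm_gibbs_step <- function(model, v, seed = NULL) {
  maybe_seed(seed)
  single <- !is.matrix(v)
  if (single) v <- matrix(v, nrow = 1)
  ph <- rbm_conditional(model, v, "hidden_given_visible")
  h <- rbernoulli(ph)
  pv <- rbm_conditional(model, h, "visible_given_hidden")
  v2 <- rbernoulli(pv)
  if (single) {
    list(h = as.numeric(h), v_next = as.numeric(v2),
         p_hidden = as.numeric(ph), p_visible = as.numeric(pv))
  } else {
    list(h = h, v_next = v2, p_hidden = ph, p_visible = pv)
  }
}

#' Exact maximum-likelihood gradient
#'
#' The gradient of the average log-likelihood of a dataset is the
#' difference of two expectations,
#' `<v_i h_j>_data - <v_i h_j>_model`, with bias analogues.  The data term
#' uses the exact conditional hidden probabilities; the model term is
#' computed from the enumerated model distribution (Rao-Blackwellized over
#' the hidden layer), so the result is exact.  Only available under the
#' 24-unit enumeration guard.
#'
#' @param model an [rbm()].
#' @param data matrix of 0/1 training vectors, one per row, or a list of
#'   vectors.
#' @param data_weights optional probability weights over the rows of
#'   `data` (default uniform); lets the caller pass a distribution over
#'   visible states rather than a sample.
#' @return list with `d_weights`, `d_visible_bias`, `d_hidden_bias`: the
#'   ascent direction on the average log-likelihood.
#' @export
rbm_ml_gradient <- function(model, data, data_weights = NULL) {
  guard_units(n_visible(model) + n_hidden(model))
  if (is.list(data)) data <- do.call(rbind, data)
  data <- check_dataset(data, n_visible(model))
  if (is.null(data_weights)) {
    data_weights <- rep(1 / nrow(data), nrow(data))
  }
  stopifnot(length(data_weights) == nrow(data))
  data_weights <- data_weights / sum(data_weights)

  ph <- rbm_conditional(model, data, "hidden_given_visible")
  pos_w <- t(data * data_weights) %*% ph
  pos_vb <- as.numeric(data_weights %*% data)
  pos_hb <- as.numeric(data_weights %*% ph)

  V <- binary_states(n_visible(model))
  pv <- rbm_marginal(model)
  phv <- rbm_conditional(model, V, "hidden_given_visible")
  neg_w <- t(V * pv) %*% phv
  neg_vb <- as.numeric(pv %*% V)
  neg_hb <- as.numeric(pv %*% phv)

  list(d_weights = pos_w - neg_w,
       d_visible_bias = pos_vb - neg_vb,
       d_hidden_bias = pos_hb - neg_hb)
}

#' Training configuration
#'
#' Bundles the knobs of stochastic gradient training.  `learning_rate` is
#' the proportionality constant of the learning rules; `cd_steps` the
#' number of sample-reconstruct alternations in contrastive divergence.
#'
#' @param learning_rate positive step size.
#' @param cd_steps number of CD alternations (>= 1).
#' @param epochs passes over the training set.
#' @param batch_size cases per stochastic update.
#' @param seed integer seed for the run.
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.1, cd_steps = 1, epochs = 10,
                         batch_size = 10, seed = 1) {
  stopifnot(learning_rate > 0, cd_steps >= 1, epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, cd_steps = as.integer(cd_steps),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# One CD cycle's sufficient statistics for a batch.
# The data-side hidden statistic always uses probabilities and the chain
# is driven by sampled hidden states.  Two conventions for the negative
# phase: "sample" reconstructs stochastic binary visibles and takes the
# negative statistic at (v1, p(h|v1)); "mean_field" keeps real-valued
# visible probabilities and uses probabilities on both sides.  The
# sampled convention follows the Gibbs chain faithfully and reaches a
# noticeably better fixed point on multimodal targets; mean_field has
# lower variance per update.
cd_statistics <- function(model, batch, cd_steps = 1,
                          statistics = c("sample", "mean_field")) {
  statistics <- match.arg(statistics)
  ph0 <- rbm_conditional(model, batch, "hidden_given_visible")
  h <- rbernoulli(ph0)
  for (s in seq_len(cd_steps)) {
    pv <- rbm_conditional(model, h, "visible_given_hidden")
    vneg <- if (statistics == "sample") rbernoulli(pv) else pv
    ph <- sigmoid(sweep(vneg %*% model$weights, 2, model$hidden_bias, "+"))
    if (s < cd_steps) h <- rbernoulli(ph)
  }
  n <- nrow(batch)
  list(d_weights = (t(batch) %*% ph0 - t(vneg) %*% ph) / n,
       d_visible_bias = colMeans(batch) - colMeans(vneg),
       d_hidden_bias = colMeans(ph0) - colMeans(ph),
       recon = pv)
}

#' One contrastive-divergence parameter update
#'
#' Applies `learning_rate * (<v_i h_j>_data - <v_i h_j>_recon)` (and the
#' bias analogues) estimated from one sample-reconstruct-resample cycle
#' per training case.
#'
#' @param model an [rbm()].
#' @param batch matrix of 0/1 rows (nonempty).
#' @param config a [train_config()].
#' @param statistics negative-phase convention: `"sample"` (default,
#'   stochastic binary reconstructions) or `"mean_field"` (real-valued
#'   visible probabilities, lower variance).
#' @param seed optional seed.
#' @return list with the updated `model` and `recon_error`, the mean
#'   squared difference between the batch and its mean-field
#'   reconstruction.
#' @export
rbm_cd1 <- function(model, batch, config = train_config(),
                    statistics = c("sample", "mean_field"), seed = NULL) {
  maybe_seed(seed)
  if (is.list(batch)) batch <- do.call(rbind, batch)
  batch <- check_dataset(batch, n_visible(model))
  if (nrow(batch) == 0) stop("empty batch", call. = FALSE)
  st <- cd_statistics(model, batch, config$cd_steps, statistics)
  lr <- config$learning_rate
  model$weights <- model$weights + lr * st$d_weights
  model$visible_bias <- model$visible_bias + lr * st$d_visible_bias
  model$hidden_bias <- model$hidden_bias + lr * st$d_hidden_bias
  list(model = model, recon_error = mean((batch - st$recon)^2))
}

#' Train an RBM by contrastive divergence
#'
#' Plain minibatch stochastic gradient with the CD update; no momentum or
#' weight decay.  Cases are reshuffled every epoch.
#'
#' @param data 0/1 matrix, one case per row.
#' @param n_hidden number of hidden units.
#' @param config a [train_config()]; its `seed` drives initialization,
#'   shuffling and all sampling.
#' @param model optional starting [rbm()] (overrides `n_hidden`).
#' @param statistics negative-phase convention, see [rbm_cd1()].
#' @return list with `model` and `recon_error`, the per-epoch mean
#'   reconstruction error.
#' @export
train_rbm <- function(data, n_hidden, config = train_config(), model = NULL,
                      statistics = c("sample", "mean_field")) {
  statistics <- match.arg(statistics)
  data <- as.matrix(data)
  set.seed(config$seed)
  if (is.null(model)) model <- rbm(ncol(data), n_hidden)
  data <- check_dataset(data, n_visible(model))
  errs <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(nrow(data))
    starts <- seq(1, nrow(data), by = config$batch_size)
    e <- 0
    for (s in starts) {
      b <- data[idx[s:min(s + config$batch_size - 1, nrow(data))], ,
                drop = FALSE]
      up <- rbm_cd1(model, b, config, statistics)
      model <- up$model
      e <- e + up$recon_error * nrow(b)
    }
    errs[ep] <- e / nrow(data)
  }
  list(model = model, recon_error = errs)
}

#' Kullback-Leibler divergence from a data distribution to the model
#'
#' Computes `KL(p_data || p_model)` by enumerating the model's visible
#' marginal.  `p_data` is a probability vector over all visible states in
#' [binary_states()] order (see [bars_stripes_distribution()] for an
#' example source).
#'
#' @param model an [rbm()] small enough to enumerate.
#' @param p_data probability vector of length `2^n_visible`.
#' @return KL divergence in nats.
#' @export
rbm_kl <- function(model, p_data) {
  stopifnot(length(p_data) == 2^n_visible(model),
            all(p_data >= 0), abs(sum(p_data) - 1) < 1e-8)
  pm <- rbm_marginal(model)
  s <- p_data > 0
  sum(p_data[s] * (log(p_data[s]) - log(pm[s])))
}
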