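# Third-order energy models in which hidden units gate pairwise
# interactions between visible units: the full three-way tensor form, the
# factored low-rank form, factor message passing, gated hidden sampling,
# damped mean-field reconstruction, CD learning and the cubic
# gain-control energy.

#' Factored third-order (gated) RBM
#'
#' The full three-way energy `-sum_{ijk} v_i v_j h_k w_ijk` lets each
#' hidden unit modulate every pairwise interaction between visible
#' units, but has far too many parameters.  The factored form writes the
#' tensor as a sum of rank-one "factors",
#' `w_ijk = sum_f w_if w_jf w_kf`, with the same visible-to-factor
#' weights used in both visible sums, so each factor is a linear filter
#' whose *squared* output is sent to the hidden units -- the classic
#' oriented-energy arrangement of simple and complex cells.
#'
#' @param n_visible,n_factors,n_hidden sizes.
#' @param vis_to_factor optional `n_visible x n_factors` matrix `w_if`.
#' @param factor_to_hidden optional `n_factors x n_hidden` matrix `w_kf`
#'   (stored with factors on rows).
#' @param hidden_bias,visible_bias optional bias vectors (default 0; the
#'   visible bias enters the mean-field reconstruction field).
#' @param init_sd standard deviation of random initialization.
#' @param seed optional seed.
#' @return an object of class `"gated_rbm"`.
#' @export
gated_rbm <- function(n_visible, n_factors, n_hidden, vis_to_factor = NULL,
                      factor_to_hidden = NULL, hidden_bias = NULL,
                      visible_bias = NULL, init_sd = 0.05, seed = NULL) {
  stopifnot(n_visible >= 1, n_factors >= 1, n_hidden >= 1)
  maybe_seed(seed)
  if (is.null(vis_to_factor)) {
    vis_to_factor <- matrix(stats::rnorm(n_visible * n_factors, sd = init_sd),
                            n_visible, n_factors)
  }
  if (is.null(factor_to_hidden)) {
    factor_to_hidden <- matrix(stats::rnorm(n_factors * n_hidden, sd = init_sd),
                               n_factors, n_hidden)
  }
  vis_to_factor <- as.matrix(vis_to_factor)
  factor_to_hidden <- as.matrix(factor_to_hidden)
  stopifnot(all(dim(vis_to_factor) == c(n_visible, n_factors)),
            all(dim(factor_to_hidden) == c(n_factors, n_hidden)),
            all(is.finite(vis_to_factor)), all(is.finite(factor_to_hidden)))
  if (is.null(hidden_bias)) hidden_bias <- numeric(n_hidden)
  if (is.null(visible_bias)) visible_bias <- numeric(n_visible)
  check_length(hidden_bias, n_hidden)
  check_length(visible_bias, n_visible)
  structure(list(vis_to_factor = vis_to_factor,
                 factor_to_hidden = factor_to_hidden,
                 hidden_bias = as.numeric(hidden_bias),
                 visible_bias = as.numeric(visible_bias)),
            class = "gated_rbm")
}

#' @export
print.gated_rbm <- function(x, ...) {
  cat("Factored third-order RBM:", nrow(x$vis_to_factor), "visible,",
      ncol(x$vis_to_factor), "factors,", ncol(x$factor_to_hidden),
      "hidden units\n")
  invisible(x)
}

gated_sizes <- function(m) {
  c(nv = nrow(m$vis_to_factor), nf = ncol(m$vis_to_factor),
    nh = ncol(m$factor_to_hidden))
}

#' Energy of the full three-way tensor model
#'
#' `E(v, h) = -sum_{i,j,k} v_i v_j h_k w_ijk`, the sum running over all
#' ordered pairs `(i, j)` including the diagonal.
#'
#' @param tensor numeric array indexed (visible i, visible j, hidden k).
#' @param v,h 0/1 (or real-valued in `[0,1]`) state vectors.
#' @return a single number.
#' @export
threeway_energy <- function(tensor, v, h) {
  d <- dim(tensor)
  stopifnot(length(d) == 3, d[1] == d[2])
  check_length(v, d[1]); check_length(h, d[3])
  -sum(tensor * outer(outer(v, v), h))
}

#' Compose the three-way tensor from factored parameters
#'
#' `w_ijk = sum_f w_if w_jf w_kf`.  The composed tensor reproduces the
#' factored energy exactly (up to the bias terms, which the tensor form
#' does not carry); it is the oracle for the energy-path equivalence
#' checks.
#'
#' @param model a [gated_rbm()].
#' @return numeric array `n_visible x n_visible x n_hidden`.
#' @export
compose_tensor <- function(model) {
  s <- gated_sizes(model)
  W <- model$vis_to_factor; P <- model$factor_to_hidden
  tensor <- array(0, dim = c(s["nv"], s["nv"], s["nh"]))
  for (f in seq_len(s["nf"])) {
    tensor <- tensor + outer(outer(W[, f], W[, f]), P[f, ])
  }
  tensor
}

#' Energy of the factored model
#'
#' `E(v, h) = -sum_f (v . w_f)^2 (h . w_f') - h . hidden_bias -
#' v . visible_bias`, with both visible sums sharing `vis_to_factor`.
#'
#' @param model a [gated_rbm()].
#' @param v,h state vectors (binary or mean-field real values).
#' @return a single number.
#' @export
gated_energy <- function(model, v, h) {
  s <- gated_sizes(model)
  check_length(v, s[["nv"]]); check_length(h, s[["nh"]])
  filt <- as.numeric(v %*% model$vis_to_factor)
  gate <- as.numeric(model$factor_to_hidden %*% h)
  -sum(filt * filt * gate) - sum(h * model$hidden_bias) -
    sum(v * model$visible_bias)
}

#' Messages from factors to the stochastic units
#'
#' Factors are deterministic and must send different messages to
#' different units.  To each hidden unit, factor `f` sends its squared
#' filter output `(v . w_f)^2`; to each visible unit it sends
#' `(v . w_f)(h . w_f')`.  Routing the square through the factors is what
#' keeps the hidden units conditionally independent given the image.
#'
#' @param model a [gated_rbm()].
#' @param v visible state (binary or mean-field values).
#' @param h hidden state.
#' @return list with per-factor vectors `to_hidden` and `to_visible`.
#' @export
factor_messages <- function(model, v, h) {
  s <- gated_sizes(model)
  check_length(v, s[["nv"]]); check_length(h, s[["nh"]])
  filt <- as.numeric(v %*% model$vis_to_factor)
  gate <- as.numeric(model$factor_to_hidden %*% h)
  list(to_hidden = filt^2, to_visible = filt * gate)
}

# Total input of every hidden unit: bias + sum_f w_kf (v.w_f)^2.
# Equals the energy drop E(h_k = 0) - E(h_k = 1), because the energy is
# linear in each hidden state.
gated_hidden_input <- function(model, V) {
  filt <- V %*% model$vis_to_factor
  sweep(filt^2 %*% model$factor_to_hidden, 2, model$hidden_bias, "+")
}

#' Sample the gated hidden units given the visible units
#'
#' `p(h_k = 1 | v) = sigmoid(bias_k + sum_f w_kf (v . w_f)^2)`; the
#' hidden units are exactly conditionally independent given `v`.
#'
#' @param model a [gated_rbm()].
#' @param v visible vector or matrix of rows (binary or mean-field).
#' @param seed optional seed.
#' @return list with sampled `h` and the probabilities `probs`.
#' @export
gated_sample_hidden <- function(model, v, seed = NULL) {
  maybe_seed(seed)
  single <- !is.matrix(v)
  if (single) v <- matrix(v, nrow = 1)
  p <- sigmoid(gated_hidden_input(model, v))
  h <- rbernoulli(p)
  if (single) list(h = as.numeric(h), probs = as.numeric(p))
  else list(h = h, probs = p)
}

# Mean-field visible field assembled from factor-to-visible messages:
# field_i = visible_bias_i + sum_f w_if (r . w_f)(h . w_f').
gated_visible_field <- function(model, R, H) {
  filt <- R %*% model$vis_to_factor
  gate <- H %*% t(model$factor_to_hidden)
  sweep((filt * gate) %*% t(model$vis_to_factor), 2, model$visible_bias, "+")
}

#' Damped mean-field reconstruction of the visible units
#'
#' Given hidden states the visible units are *not* independent, so
#' reconstruction uses a deterministic damped fixed-point iteration on
#' real-valued activities `r` starting at the data vector:
#' `r <- (1 - lambda) r + lambda sigmoid(field(r))`, with the field
#' assembled from the factor-to-visible messages.  `lambda` must be
#' large enough to make progress but small enough to prevent
#' oscillations.
#'
#' @param model a [gated_rbm()].
#' @param h hidden state vector (or matrix of rows).
#' @param v_start starting activities, typically the data vector.
#' @param lambda damping in (0, 1).
#' @param iters maximum iterations.
#' @param tol stop when `max |r(t) - r(t-1)| < tol`.
#' @return list with `r` (final activities), `damping`, `iterations`
#'   (performed), `residual` (last max absolute change).
#' @export
gated_mean_field <- function(model, h, v_start, lambda = 0.5, iters = 20,
                             tol = 1e-6) {
  stopifnot(lambda > 0, lambda < 1, iters >= 1)
  single <- !is.matrix(h)
  H <- if (single) matrix(h, nrow = 1) else h
  R <- if (single) matrix(v_start, nrow = 1) else v_start
  s <- gated_sizes(model)
  stopifnot(ncol(H) == s[["nh"]], ncol(R) == s[["nv"]])
  resid <- Inf
  it <- 0L
  for (t in seq_len(iters)) {
    R_new <- (1 - lambda) * R + lambda * sigmoid(gated_visible_field(model, R, H))
    resid <- max(abs(R_new - R))
    R <- R_new
    it <- t
    if (resid < tol) break
  }
  list(r = if (single) as.numeric(R) else R,
       damping = lambda, iterations = it, residual = resid)
}

#' One contrastive-divergence update for the factored model
#'
#' One CD cycle: hidden probabilities from the data, a stochastic hidden
#' sample to drive a damped mean-field reconstruction of the visibles,
#' then hidden probabilities again with the mean-field activities in
#' place of the data.  Factor-to-hidden weights move by the difference of
#' `<h_k (v . w_f)^2>` statistics, visible-to-factor weights by the
#' difference of `<v_i (v . w_f)(h . w_f')>` statistics; hidden
#' statistics use probabilities on both sides.
#'
#' @param model a [gated_rbm()].
#' @param batch 0/1 matrix, one case per row (nonempty).
#' @param config [train_config()].
#' @param lambda,mf_iters mean-field damping and iteration budget.
#' @param seed optional seed.
#' @return list with the updated `model` and `recon_error` (mean squared
#'   data/reconstruction difference).
#' @export
gated_cd_update <- function(model, batch, config = train_config(),
                            lambda = 0.5, mf_iters = 20, seed = NULL) {
  maybe_seed(seed)
  s <- gated_sizes(model)
  batch <- check_dataset(batch, s[["nv"]])
  if (nrow(batch) == 0) stop("empty batch", call. = FALSE)
  n <- nrow(batch)
  W <- model$vis_to_factor; P <- model$factor_to_hidden

  S0 <- batch %*% W
  ph0 <- sigmoid(sweep(S0^2 %*% P, 2, model$hidden_bias, "+"))
  h0 <- rbernoulli(ph0)
  R <- gated_mean_field(model, h0, batch, lambda, mf_iters)$r
  S1 <- R %*% W
  ph1 <- sigmoid(sweep(S1^2 %*% P, 2, model$hidden_bias, "+"))

  gate0 <- ph0 %*% t(P)   # n x nf: <h . w_f'> under data-side probs
  gate1 <- ph1 %*% t(P)
  d_P <- (t(S0^2) %*% ph0 - t(S1^2) %*% ph1) / n
  d_W <- (t(batch) %*% (S0 * gate0) - t(R) %*% (S1 * gate1)) / n
  d_hb <- colMeans(ph0) - colMeans(ph1)
  d_vb <- colMeans(batch) - colMeans(R)

  lr <- config$learning_rate
  model$vis_to_factor <- W + lr * d_W
  model$factor_to_hidden <- P + lr * d_P
  model$hidden_bias <- model$hidden_bias + lr * d_hb
  model$visible_bias <- model$visible_bias + lr * d_vb
  list(model = model, recon_error = mean((batch - R)^2))
}

#' Train a factored third-order RBM by contrastive divergence
#'
#' Minibatch CD with damped mean-field reconstruction.  Two optional
#' constraints, both standard practice for covariance models of images,
#' stabilize receptive-field learning: `normalize_filters` rescales each
#' visible-to-factor column to unit norm after every update (preventing
#' a few factors from absorbing all the energy), and `gating = "tied"`
#' fixes the factor-to-hidden weights at `gate_strength` times the
#' identity -- one hidden unit per factor, the classical oriented-energy
#' arrangement in which each "complex cell" pools the squared output of
#' its own filter.  With learned gating, symmetric mixtures of stimulus
#' orientations can satisfy the pairwise statistics just as well as
#' single orientations, so filters are slower to specialize.
#'
#' @param data 0/1 matrix, one case per row.
#' @param n_factors,n_hidden sizes; tied gating requires
#'   `n_hidden == n_factors`.
#' @param config [train_config()].
#' @param lambda,mf_iters mean-field settings.
#' @param init_sd initialization scale.
#' @param gating `"learned"` (default) or `"tied"`.
#' @param gate_strength gate weight under tied gating.
#' @param normalize_filters keep visible-to-factor columns at unit norm.
#' @return list with `model` and per-epoch `recon_error`.
#' @export
train_gated_rbm <- function(data, n_factors, n_hidden,
                            config = train_config(), lambda = 0.5,
                            mf_iters = 20, init_sd = 0.05,
                            gating = c("learned", "tied"),
                            gate_strength = 1, normalize_filters = FALSE) {
  gating <- match.arg(gating)
  data <- as.matrix(data)
  set.seed(config$seed)
  model <- gated_rbm(ncol(data), n_factors, n_hidden, init_sd = init_sd)
  if (gating == "tied") {
    if (n_hidden != n_factors) {
      stop("tied gating requires n_hidden == n_factors", call. = FALSE)
    }
    model$factor_to_hidden <- diag(n_factors) * gate_strength
  }
  errs <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(nrow(data))
    starts <- seq(1, nrow(data), by = config$batch_size)
    e <- 0
    for (st in starts) {
      b <- data[idx[st:min(st + config$batch_size - 1, nrow(data))], ,
                drop = FALSE]
      P_old <- model$factor_to_hidden
      up <- gated_cd_update(model, b, config, lambda, mf_iters)
      model <- up$model
      if (gating == "tied") model$factor_to_hidden <- P_old
      if (normalize_filters) {
        W <- model$vis_to_factor
        model$vis_to_factor <- sweep(W, 2, pmax(sqrt(colSums(W^2)), 1e-8),
                                     "/")
      }
      e <- e + up$recon_error * nrow(b)
    }
    errs[ep] <- e / nrow(data)
  }
  list(model = model, recon_error = errs)
}

#' Exact joint distribution of a small gated model
#'
#' Enumerates `p(v, h) \propto exp(-E)` with the factored energy
#' (including biases); the oracle for the conditional-independence and
#' message-consistency checks.  At most 20 total stochastic units.
#'
#' @param model a [gated_rbm()].
#' @return probability matrix, visible states on rows, hidden states on
#'   columns, in [binary_states()] order.
#' @export
gated_joint <- function(model) {
  s <- gated_sizes(model)
  guard_units(s[["nv"]] + s[["nh"]], 20)
  V <- binary_states(s[["nv"]]); H <- binary_states(s[["nh"]])
  neg_e <- matrix(0, nrow(V), nrow(H))
  for (hs in seq_len(nrow(H))) {
    for (vs in seq_len(nrow(V))) {
      neg_e[vs, hs] <- -gated_energy(model, V[vs, ], H[hs, ])
    }
  }
  p <- exp(neg_e - max(neg_e))
  p / sum(p)
}

#' Cubic gain-control energy of all-negative visible-only factors
#'
#' A factor connected only to visible units, with all its weights
#' negative and activities constrained non-negative, contributes energy
#' `-sum_f (v . w_f)^3 >= 0` that grows cubically with activity: a gain
#' control resembling an inhibitory interneuron, one way to implement
#' divisive normalization.
#'
#' @param vis_to_factor_neg matrix of non-positive visible-to-factor
#'   weights.
#' @param v non-negative activity vector.
#' @return the (non-negative) energy contribution.
#' @export
gain_control_energy <- function(vis_to_factor_neg, v) {
  vis_to_factor_neg <- as.matrix(vis_to_factor_neg)
  if (any(vis_to_factor_neg > 0)) {
    stop("gain-control factors require non-positive weights", call. = FALSE)
  }
  if (any(v < 0)) stop("activities must be non-negative", call. = FALSE)
  check_length(v, nrow(vis_to_factor_neg))
  filt <- as.numeric(v %*% vis_to_factor_neg)
  -sum(filt^3)
}

# ---- Unfactored tensor path (enumeration-scale oracle) ----------------

# Hidden-unit total input under the explicit tensor:
# bias_k + sum_{ij} v_i v_j w_ijk.
threeway_hidden_input <- function(tensor, hidden_bias, v) {
  d <- dim(tensor)
  check_length(v, d[1])
  hidden_bias + apply(tensor, 3, function(w) as.numeric(v %*% w %*% v))
}

#' CD update for the explicit three-way tensor
#'
#' The unfactored learning rule
#' `Delta w_ijk \propto <v_i v_j h_k>_data - <r_i r_j h_k>_recon`,
#' implemented for enumeration-scale models as an oracle for the factored
#' path; the mean-field field of the tensor model coincides with the
#' factored field when the tensor is composed from the factors.
#'
#' @param tensor three-way array.
#' @param hidden_bias,visible_bias bias vectors.
#' @param batch 0/1 matrix.
#' @param config [train_config()].
#' @param lambda,mf_iters mean-field settings.
#' @param seed optional seed.
#' @return list with updated `tensor`, `hidden_bias`, `visible_bias`.
#' @export
threeway_cd_update <- function(tensor, hidden_bias, visible_bias, batch,
                               config = train_config(), lambda = 0.5,
                               mf_iters = 20, seed = NULL) {
  maybe_seed(seed)
  d <- dim(tensor)
  batch <- check_dataset(batch, d[1])
  n <- nrow(batch)
  pos <- array(0, d); neg <- array(0, d)
  d_hb <- numeric(d[3]); d_vb <- numeric(d[1])
  for (r in seq_len(n)) {
    v <- batch[r, ]
    ph0 <- sigmoid(threeway_hidden_input(tensor, hidden_bias, v))
    h0 <- rbernoulli(ph0)
    rr <- v
    for (t in seq_len(mf_iters)) {
      # message field: sum_{j,k} w_ijk r_j h_k (tensor symmetric in i,j)
      field <- visible_bias + vapply(seq_len(d[1]), function(i) {
        sum(tensor[i, , ] * outer(rr, h0))
      }, numeric(1))
      rr <- (1 - lambda) * rr + lambda * sigmoid(field)
    }
    ph1 <- sigmoid(threeway_hidden_input(tensor, hidden_bias, rr))
    pos <- pos + outer(outer(v, v), ph0)
    neg <- neg + outer(outer(rr, rr), ph1)
    d_hb <- d_hb + ph0 - ph1
    d_vb <- d_vb + v - rr
  }
  lr <- config$learning_rate
  list(tensor = tensor + lr * (pos - neg) / n,
       hidden_bias = hidden_bias + lr * d_hb / n,
       visible_bias = visible_bias + lr * d_vb / n)
}
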