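# Greedy layerwise construction of deep belief nets from RBMs: growing the
# stack, generation, bottom-up inference, the exact composite marginal, and
# the variational bound that justifies greedy training.

#' Deep belief net as a stack of RBMs
#'
#' A DBN built greedily is not a multilayer Boltzmann machine: only the
#' top pair of layers is undirected (the top RBM); every lower weight
#' matrix is frozen and acts as a top-down directed sigmoid layer.  The
#' same weights, transposed, serve for fast bottom-up inference.
#'
#' @param ... one or more [rbm()] objects, bottom to top.  Adjacent sizes
#'   must chain: the hidden size of each RBM equals the visible size of
#'   the next.
#' @return an object of class `"dbn"`.
#' @export
dbn <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "rbm")) {
    layers <- layers[[1]]
  }
  stopifnot(length(layers) >= 1)
  for (m in layers) stopifnot(inherits(m, "rbm"))
  for (k in seq_len(length(layers) - 1)) {
    if (n_hidden(layers[[k]]) != n_visible(layers[[k + 1]])) {
      stop("layer sizes do not chain at position ", k, call. = FALSE)
    }
  }
  structure(list(layers = layers), class = "dbn")
}

#' @export
print.dbn <- function(x, ...) {
  sizes <- c(n_visible(x$layers[[1]]), vapply(x$layers, n_hidden, 1L))
  cat("Deep belief net, layer sizes:", paste(sizes, collapse = "-"), "\n")
  invisible(x)
}

dbn_sizes <- function(stack) {
  c(n_visible(stack$layers[[1]]), vapply(stack$layers, n_hidden, 1L))
}

# Propagate a data matrix to the activities of the current top hidden
# layer; stochastic binary samples by default.
propagate_up <- function(stack, data, stochastic = TRUE) {
  x <- data
  for (m in stack$layers) {
    p <- rbm_conditional(m, x, "hidden_given_visible")
    x <- if (stochastic) rbernoulli(p) else p
  }
  x
}

#' Grow a deep belief net by one greedily trained layer
#'
#' Each training case is propagated to the current top layer (stochastic
#' binary activations by default) and those activities become the "data"
#' for a new top RBM.  The new RBM is initialized as the transpose of the
#' current top RBM -- with its visible/hidden biases swapped in -- which
#' leaves the composite distribution over visible vectors exactly
#' unchanged before training; CD training of the new layer then improves
#' a variational bound on the training data (see [dbn_bound()]).
#'
#' @param stack a [dbn()] (or a single [rbm()] for the first growth).
#' @param data 0/1 matrix matching the bottom layer.
#' @param config [train_config()] for the new layer; `epochs = 0` leaves
#'   the transpose initialization untrained.
#' @param stochastic_prop propagate samples (default) or probabilities.
#' @return the extended [dbn()].
#' @export
dbn_grow <- function(stack, data, config = train_config(),
                     stochastic_prop = TRUE) {
  if (inherits(stack, "rbm")) stack <- dbn(list(stack))
  data <- check_dataset(data, dbn_sizes(stack)[1])
  set.seed(config$seed)
  top <- stack$layers[[length(stack$layers)]]
  new_rbm <- rbm(n_hidden(top), n_visible(top),
                 weights = t(top$weights),
                 visible_bias = top$hidden_bias,
                 hidden_bias = top$visible_bias)
  if (config$epochs > 0) {
    hid <- propagate_up(stack, data, stochastic = stochastic_prop)
    new_rbm <- train_rbm(hid, config = config, model = new_rbm)$model
  }
  stack$layers <- c(stack$layers, list(new_rbm))
  stack
}

#' Generate visible samples from a deep belief net
#'
#' Runs alternating Gibbs sampling in the top RBM for `burn_in` full
#' alternations (independently for each of `n` parallel chains started at
#' Bernoulli(1/2) states), then performs a single directed top-down pass
#' through the frozen layers.
#'
#' @param stack a [dbn()].
#' @param n number of samples (independent chains).
#' @param burn_in Gibbs alternations in the top RBM (>= 1).
#' @param seed optional seed.
#' @return 0/1 matrix with `n` rows of visible samples.
#' @export
dbn_generate <- function(stack, n = 1, burn_in = 50, seed = NULL) {
  stopifnot(burn_in >= 1)
  maybe_seed(seed)
  L <- length(stack$layers)
  top <- stack$layers[[L]]
  v <- matrix(rbernoulli(matrix(0.5, n, n_visible(top))), n)
  for (s in seq_len(burn_in)) v <- rbm_gibbs_step(top, v)$v_next
  # one top-down directed pass through the frozen layers
  for (k in rev(seq_len(L - 1))) {
    m <- stack$layers[[k]]
    v <- rbernoulli(rbm_conditional(m, v, "visible_given_hidden"))
  }
  v
}

#' Bottom-up inference through a deep belief net
#'
#' Uses the generative weights in the reverse direction for a fast
#' layerwise upward pass.  `"stochastic"` samples binary states at each
#' layer; `"mean_field"` propagates real-valued probabilities.
#'
#' @param stack a [dbn()].
#' @param v 0/1 visible vector or matrix (one case per row).
#' @param mode `"stochastic"` or `"mean_field"`.
#' @param seed optional seed.
#' @return list of per-hidden-layer states/probabilities, bottom to top.
#' @export
dbn_infer <- function(stack, v, mode = c("stochastic", "mean_field"),
                      seed = NULL) {
  mode <- match.arg(mode)
  maybe_seed(seed)
  single <- !is.matrix(v)
  if (single) v <- matrix(v, nrow = 1)
  out <- vector("list", length(stack$layers))
  x <- v
  for (k in seq_along(stack$layers)) {
    p <- rbm_conditional(stack$layers[[k]], x, "hidden_given_visible")
    x <- if (mode == "stochastic") rbernoulli(p) else p
    out[[k]] <- if (single) as.numeric(x) else x
  }
  out
}

#' Exact marginal of the composite model
#'
#' Enumerates every hidden layer to compute the probability the DBN
#' assigns to visible vectors: the top RBM defines a (correlated) prior
#' over the top hidden layer pair, and each directed layer below
#' transforms that distribution through its factorial conditionals.
#' Guarded to stacks with at most 20 total units.
#'
#' @param stack a [dbn()].
#' @param v optional 0/1 visible vector; if omitted the full probability
#'   vector over all visible states ([binary_states()] order) is
#'   returned.
#' @return probability (or vector of probabilities summing to 1).
#' @export
dbn_marginal_exact <- function(stack, v = NULL) {
  sizes <- dbn_sizes(stack)
  guard_units(sum(sizes), 20)
  L <- length(stack$layers)
  # distribution over the visible layer of the top RBM
  p <- rbm_marginal(stack$layers[[L]])
  for (k in rev(seq_len(L - 1))) {
    m <- stack$layers[[k]]
    H <- binary_states(n_hidden(m))
    V <- binary_states(n_visible(m))
    pv_h <- rbm_conditional(m, H, "visible_given_hidden")  # 2^nh x nv
    # conditional table C[s_v, s_h] = prod_i p_i^{v_i} (1-p_i)^{1-v_i}
    logC <- V %*% t(log(pv_h)) + (1 - V) %*% t(log1p(-pv_h))
    p <- as.numeric(exp(logC) %*% p)
  }
  if (is.null(v)) p else p[state_index(check_length(v, sizes[1]))]
}

#' Variational bound on the log-likelihood of a two-layer stack
#'
#' The greedy justification for stacking: with `Q(h1 | v)` fixed to the
#' bottom RBM's factorial posterior, the bound
#' `sum_h1 Q(h1|v) [log p_top(h1) + log p(v | h1)] + H(Q)` equals
#' `log p(v)` of the base RBM at the transpose initialization and can
#' only be pushed up as the top RBM learns a better prior for `h1`.
#' Computed exactly by enumeration; small stacks only.
#'
#' @param stack a two-layer [dbn()].
#' @param data 0/1 matrix of visible vectors.
#' @return mean bound over the rows of `data`, in nats.
#' @export
dbn_bound <- function(stack, data) {
  stopifnot(length(stack$layers) == 2)
  base <- stack$layers[[1]]; top <- stack$layers[[2]]
  data <- check_dataset(data, n_visible(base))
  guard_units(n_visible(top) + n_hidden(top))
  H1 <- binary_states(n_hidden(base))
  log_prior <- log(rbm_marginal(top))            # over h1 states
  pv_h <- rbm_conditional(base, H1, "visible_given_hidden")
  vals <- numeric(nrow(data))
  for (r in seq_len(nrow(data))) {
    v <- data[r, ]
    q <- rbm_conditional(base, v, "hidden_given_visible")
    w <- factorial_weights(H1, q)
    log_lik <- as.numeric(log(pv_h) %*% v + log1p(-pv_h) %*% (1 - v))
    keep <- w > 0
    vals[r] <- sum(w[keep] * (log_prior[keep] + log_lik[keep])) + q_entropy(q)
  }
  mean(vals)
}

#' Train a deep belief net greedily, layer by layer
#'
#' Trains the first RBM on the data, then repeatedly grows the stack with
#' [dbn_grow()], treating each new top layer's propagated activities as
#' data.
#'
#' @param data 0/1 matrix, one case per row.
#' @param hidden_sizes integer vector of hidden layer widths, bottom to
#'   top.
#' @param config [train_config()] applied to every layer.
#' @return a [dbn()].
#' @export
train_dbn <- function(data, hidden_sizes, config = train_config()) {
  stopifnot(length(hidden_sizes) >= 1)
  data <- as.matrix(data)
  base <- train_rbm(data, hidden_sizes[1], config)$model
  stack <- dbn(list(base))
  for (k in seq_along(hidden_sizes)[-1]) {
    cfg <- config
    cfg$seed <- config$seed + k
    # transpose initialization fixes the new width at the top RBM's
    # visible size; any other width starts from a fresh RBM
    if (n_visible(stack$layers[[length(stack$layers)]]) != hidden_sizes[k]) {
      # free-size growth: fresh RBM rather than transpose initialization
      hid <- propagate_up(stack, data)
      new_rbm <- train_rbm(hid, hidden_sizes[k], cfg)$model
      stack$layers <- c(stack$layers, list(new_rbm))
    } else {
      stack <- dbn_grow(stack, data, cfg)
    }
  }
  stack
}
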