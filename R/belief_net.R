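# Directed sigmoid belief nets: ancestral sampling, exact posteriors by
# enumeration (the explaining-away oracle), the delta learning rule, and
# variational free energy with a factorial approximate posterior.

#' Construct a sigmoid belief net
#'
#' A directed generative model of layered binary units.  Layer 1 is the
#' deepest (top) layer; the last layer is the visible layer.  During
#' generation each unit in layer `L + 1` turns on with probability
#' `sigmoid(bias + W_L %*% state of layer L)`: the weights point top-down.
#'
#' @param layer_sizes integer vector of layer widths, top to bottom.
#' @param weights list of `length(layer_sizes) - 1` matrices;
#'   `weights[[L]]` is `layer_sizes[L + 1] x layer_sizes[L]` and maps the
#'   states of layer `L` to the inputs of layer `L + 1`.
#' @param biases list of per-layer bias vectors; the top layer has only
#'   biases.
#' @return an object of class `"sbn"`.
#' @seealso [toy_jump_net()] for a worked two-cause example.
#' @export
sbn <- function(layer_sizes, weights, biases) {
  L <- length(layer_sizes)
  stopifnot(L >= 1, length(weights) == L - 1, length(biases) == L)
  for (k in seq_len(L)) {
    check_length(biases[[k]], layer_sizes[k], "biases")
    # finite surrogate for clamped-off units; keeps arithmetic finite
    stopifnot(all(abs(biases[[k]]) <= 1e3))
  }
  for (k in seq_len(L - 1)) {
    w <- as.matrix(weights[[k]])
    stopifnot(all(dim(w) == c(layer_sizes[k + 1], layer_sizes[k])),
              all(is.finite(w)))
    weights[[k]] <- w
  }
  structure(list(layer_sizes = as.integer(layer_sizes),
                 weights = weights,
                 biases = lapply(biases, as.numeric)),
            class = "sbn")
}

#' @export
print.sbn <- function(x, ...) {
  cat("Sigmoid belief net, layers (top to bottom):",
      paste(x$layer_sizes, collapse = "-"), "\n")
  invisible(x)
}

#' The two-cause explaining-away network
#'
#' A three-unit fixture: two rare independent hidden causes (an earthquake
#' and a truck hitting the house) each with bias -10, and one visible
#' effect (the house jumps) with bias -20 receiving weight +20 from each
#' cause.  Consequences of these numbers: each cause's prior odds of
#' being off are `e^10`; with exactly one cause active the jump unit's
#' total input is 0 (even odds); with no cause active the jump odds are
#' `e^-20`; and both causes together have prior probability close to
#' `e^-20`.  Conditioned on a jump, the two causes become strongly
#' anti-correlated: one active cause explains the jump away.
#'
#' @return an [sbn()] with layers 2 (causes) and 1 (effect).
#' @examples
#' post <- sbn_posterior(toy_jump_net(), visible = 1)
#' cbind(post$states, p = round(post$probs, 5))
#' @export
toy_jump_net <- function() {
  sbn(layer_sizes = c(2, 1),
      weights = list(matrix(c(20, 20), nrow = 1)),
      biases = list(c(-10, -10), -20))
}

# Per-unit on-probabilities of layer L+1 given the state of layer L.
sbn_layer_probs <- function(net, L, state_above) {
  sigmoid(net$biases[[L + 1]] + as.numeric(net$weights[[L]] %*% state_above))
}

#' Ancestral sampling from a belief net
#'
#' The top layer is sampled from its bias-only Bernoulli priors; each
#' lower layer is then sampled given the sampled states above (an
#' "ancestral pass").
#'
#' @param net an [sbn()].
#' @param n number of independent samples.
#' @param seed optional seed.
#' @return for `n = 1`, a list of 0/1 vectors (one per layer, top to
#'   bottom); otherwise a list of matrices with one sample per row.
#' @export
sbn_sample <- function(net, n = 1, seed = NULL) {
  maybe_seed(seed)
  L <- length(net$layer_sizes)
  out <- vector("list", L)
  p <- matrix(sigmoid(net$biases[[1]]), n, net$layer_sizes[1], byrow = TRUE)
  out[[1]] <- rbernoulli(p)
  for (k in seq_len(L - 1)) {
    inp <- sweep(out[[k]] %*% t(net$weights[[k]]), 2, net$biases[[k + 1]], "+")
    out[[k + 1]] <- rbernoulli(sigmoid(inp))
  }
  if (n == 1) lapply(out, as.numeric) else out
}

# Enumerate all joint hidden configurations (layers 1..L-1) and return the
# log joint probability log p(hidden, v) for each.
sbn_enumerate <- function(net, visible) {
  L <- length(net$layer_sizes)
  stopifnot(L >= 2)
  check_binary(visible)
  check_length(visible, net$layer_sizes[L])
  n_hid <- sum(net$layer_sizes[-L])
  guard_units(n_hid, 20)

  layer_states <- lapply(net$layer_sizes[-L], binary_states)
  grid <- do.call(expand.grid, lapply(layer_states, function(s) seq_len(nrow(s))))
  logp <- numeric(nrow(grid))
  states <- matrix(0, nrow(grid), n_hid)
  off <- cumsum(c(0, net$layer_sizes[-L]))
  for (r in seq_len(nrow(grid))) {
    lp <- 0
    prev <- NULL
    for (k in seq_len(L - 1)) {
      s <- layer_states[[k]][grid[r, k], ]
      p <- if (k == 1) sigmoid(net$biases[[1]]) else sbn_layer_probs(net, k - 1, prev)
      lp <- lp + sum(s * log(p) + (1 - s) * log1p(-p))
      states[r, (off[k] + 1):off[k + 1]] <- s
      prev <- s
    }
    pv <- sbn_layer_probs(net, L - 1, prev)
    lp <- lp + sum(visible * log(pv) + (1 - visible) * log1p(-pv))
    logp[r] <- lp
  }
  list(states = states, logp = logp)
}

#' Exact posterior over hidden configurations
#'
#' Enumerates every joint configuration of the hidden layers and returns
#' the normalized posterior given the observed visible vector.  This is
#' the oracle that makes explaining away visible: in [toy_jump_net()]
#' conditioned on a jump, the two single-cause configurations each carry
#' essentially half the mass and the both-causes configuration almost
#' none.
#'
#' @param net an [sbn()] with at most 20 hidden units.
#' @param visible observed 0/1 visible vector.
#' @return list with `states` (matrix, one hidden configuration per row,
#'   layers concatenated top to bottom), `probs` (posterior), and
#'   `log_marginal` (`log p(v)`).
#' @export
sbn_posterior <- function(net, visible) {
  en <- sbn_enumerate(net, visible)
  m <- max(en$logp)
  w <- exp(en$logp - m)
  list(states = en$states, probs = w / sum(w),
       log_marginal = m + log(sum(w)))
}

#' Enumerated marginal probability of a visible vector
#'
#' @param net an [sbn()] with at most 20 hidden units.
#' @param visible 0/1 vector.
#' @return `log p(visible)`.
#' @export
sbn_log_marginal <- function(net, visible) {
  sbn_posterior(net, visible)$log_marginal
}

#' Delta-rule parameter update from sampled states
#'
#' The online steepest-ascent maximum-likelihood rule for a belief net:
#' given sampled binary states of every layer, each weight moves by
#' `learning_rate * h_above * (h_below - p_below)` where `p_below` is the
#' top-down prediction from the sampled layer above; biases move as if
#' driven by an always-on presynaptic unit.  Unbiased when the hidden
#' states are posterior samples; with samples from an approximate
#' posterior it performs ascent on the variational bound instead.
#'
#' @param net an [sbn()].
#' @param states list of 0/1 vectors, one per layer, top to bottom.
#' @param learning_rate positive step size.
#' @return the updated [sbn()].
#' @export
sbn_delta_update <- function(net, states, learning_rate) {
  L <- length(net$layer_sizes)
  stopifnot(length(states) == L, learning_rate > 0)
  for (k in seq_len(L)) check_length(states[[k]], net$layer_sizes[k], "states")
  p_top <- sigmoid(net$biases[[1]])
  net$biases[[1]] <- net$biases[[1]] + learning_rate * (states[[1]] - p_top)
  for (k in seq_len(L - 1)) {
    p <- sbn_layer_probs(net, k, states[[k]])
    resid <- states[[k + 1]] - p
    net$weights[[k]] <- net$weights[[k]] +
      learning_rate * outer(resid, states[[k]])
    net$biases[[k + 1]] <- net$biases[[k + 1]] + learning_rate * resid
  }
  net
}

q_entropy <- function(q) {
  t1 <- ifelse(q > 0, -q * log(q), 0)
  t2 <- ifelse(q < 1, -(1 - q) * log1p(-q), 0)
  sum(t1 + t2)
}

# Factorial weights of each enumerated configuration under q, optionally
# leaving one unit out of the product.
factorial_weights <- function(states, q, leave_out = NULL) {
  w <- rep(1, nrow(states))
  for (i in seq_along(q)) {
    if (!is.null(leave_out) && i == leave_out) next
    w <- w * ifelse(states[, i] == 1, q[i], 1 - q[i])
  }
  w
}

#' Variational free energy of a factorial posterior
#'
#' For an approximating distribution `q` that treats the hidden units as
#' independent given the data, the negative free energy
#' `-F = E_q[log p(v, h)] + H(q)` is a lower bound on `log p(v)`; the gap
#' is the Kullback-Leibler divergence from `q` to the true posterior.
#' Both the bound and (on enumerable nets) the exact `log p(v)` are
#' returned, so the gap is computed rather than assumed.
#'
#' @param net an [sbn()] with at most 20 hidden units.
#' @param visible observed 0/1 vector.
#' @param q vector of per-hidden-unit on-probabilities in `[0, 1]`,
#'   hidden layers concatenated top to bottom.
#' @return list with `neg_free_energy`, `log_likelihood`, `kl_gap`
#'   (`= log_likelihood - neg_free_energy`, always `>= 0` up to rounding).
#' @export
sbn_free_energy <- function(net, visible, q) {
  if (any(q < 0 | q > 1)) stop("q entries must lie in [0, 1]", call. = FALSE)
  en <- sbn_enumerate(net, visible)
  check_length(q, ncol(en$states), "q")
  w <- factorial_weights(en$states, q)
  keep <- w > 0
  neg_f <- sum(w[keep] * en$logp[keep]) + q_entropy(q)
  m <- max(en$logp)
  ll <- m + log(sum(exp(en$logp - m)))
  list(neg_free_energy = neg_f, log_likelihood = ll, kl_gap = ll - neg_f)
}

#' Mean-field fit of the factorial posterior
#'
#' Coordinate-ascent maximization of the negative variational free energy
#' for a single-hidden-layer net.  Each unit's update is the exact
#' coordinate optimum `sigmoid(E_q[log-odds])`, applied with damping
#' `damping` in sequential unit order; since the objective is strictly
#' concave in each coordinate, every damped step is an ascent step and
#' the bound is monotone over sweeps.
#'
#' @param net an [sbn()] with exactly one hidden layer.
#' @param visible observed 0/1 vector.
#' @param iters maximum number of sweeps.
#' @param tol stop when no unit moves by more than `tol` in one sweep.
#' @param damping fraction of the coordinate optimum taken per step.
#' @param q_init optional starting point (default: prior probabilities).
#' @return list with `q`, `converged`, `neg_free_energy` (trajectory, one
#'   entry per sweep).
#' @export
sbn_fit_q <- function(net, visible, iters = 100, tol = 1e-10, damping = 0.5,
                      q_init = NULL) {
  stopifnot(length(net$layer_sizes) == 2)
  nh <- net$layer_sizes[1]
  en <- sbn_enumerate(net, visible)
  # log p(v | h) for every hidden configuration, plus per-unit prior odds
  prior_p <- sigmoid(net$biases[[1]])
  loglik_h <- en$logp -
    as.numeric(en$states %*% log(prior_p) +
                 (1 - en$states) %*% log1p(-prior_p))
  q <- if (is.null(q_init)) prior_p else as.numeric(q_init)
  check_length(q, nh, "q_init")
  traj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(iters)) {
    delta_max <- 0
    for (i in seq_len(nh)) {
      w <- factorial_weights(en$states, q, leave_out = i)
      on <- en$states[, i] == 1
      # E_{q_{-i}} of the likelihood log-odds for unit i, plus prior odds
      d <- net$biases[[1]][i] +
        sum(w[on] * loglik_h[on]) - sum(w[!on] * loglik_h[!on])
      q_new <- (1 - damping) * q[i] + damping * sigmoid(d)
      delta_max <- max(delta_max, abs(q_new - q[i]))
      q[i] <- q_new
    }
    traj <- c(traj, sbn_free_energy(net, visible, q)$neg_free_energy)
    if (delta_max < tol) { converged <- TRUE; break }
  }
  list(q = q, converged = converged, neg_free_energy = traj)
}
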