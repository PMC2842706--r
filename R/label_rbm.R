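# Joint RBM over concatenated feature vectors and one-hot labels: exact
# free-energy classification, the exact discriminative gradient, CD
# training with a softmax label block, and noisy-label inference.

#' RBM over features concatenated with a one-hot label block
#'
#' The visible layer is split into a feature block of `n_features` units
#' and a label block with one unit per class; training data carry exactly
#' one active label unit.  Because the free energy of any complete
#' visible vector is analytic, the class posterior
#' `p(label | features)` is exact and costs one free energy per class.
#'
#' @param n_features,n_labels block sizes.
#' @param rbm optional underlying [rbm()] with
#'   `n_features + n_labels` visible units (random initialization
#'   otherwise).
#' @param n_hidden hidden layer size when `rbm` is not supplied.
#' @param seed optional seed for initialization.
#' @return an object of class `"labeled_rbm"`.
#' @export
labeled_rbm <- function(n_features, n_labels, n_hidden = NULL, rbm = NULL,
                        seed = NULL) {
  stopifnot(n_features >= 1, n_labels >= 2)
  if (is.null(rbm)) {
    stopifnot(!is.null(n_hidden))
    rbm <- rbm(n_features + n_labels, n_hidden, seed = seed)
  }
  stopifnot(inherits(rbm, "rbm"), n_visible(rbm) == n_features + n_labels)
  structure(list(rbm = rbm, n_features = as.integer(n_features),
                 n_labels = as.integer(n_labels)),
            class = "labeled_rbm")
}

#' @export
print.labeled_rbm <- function(x, ...) {
  cat("Joint feature-label RBM:", x$n_features, "feature units,",
      x$n_labels, "label units,", n_hidden(x$rbm), "hidden units\n")
  invisible(x)
}

#' One-hot encoding of integer class labels
#'
#' @param labels integer vector of class indices in `1..n_labels`.
#' @param n_labels number of classes.
#' @return 0/1 matrix, one row per label.
#' @export
one_hot <- function(labels, n_labels) {
  stopifnot(all(labels >= 1), all(labels <= n_labels))
  m <- matrix(0, length(labels), n_labels)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

label_block_cols <- function(model) {
  model$n_features + seq_len(model$n_labels)
}

#' Exact class posterior from free energies
#'
#' For each candidate class the one-hot label block is clamped and the
#' free energy of the completed visible vector computed analytically; the
#' posterior is the softmax of the negative free energies.  Exact, with
#' cost linear in the number of classes -- no enumeration over hidden
#' states.
#'
#' @param model a [labeled_rbm()].
#' @param features 0/1 vector of length `n_features`, or a matrix of
#'   feature rows.
#' @return probability vector over classes (or a matrix, one row per
#'   case), summing to 1.
#' @export
rbm_classify <- function(model, features) {
  single <- !is.matrix(features)
  if (single) features <- matrix(features, nrow = 1)
  features <- check_dataset(features, model$n_features)
  K <- model$n_labels
  f <- matrix(0, nrow(features), K)
  for (c in seq_len(K)) {
    vc <- cbind(features, matrix(one_hot(rep(c, nrow(features)), K),
                                 nrow(features)))
    f[, c] <- rbm_free_energy(model$rbm, vc)
  }
  negf <- -f
  p <- exp(negf - apply(negf, 1, max))
  p <- p / rowSums(p)
  if (single) as.numeric(p) else p
}

#' Exact gradient of the discriminative log-likelihood
#'
#' Gradient of `log p(true_label | features)` with respect to all RBM
#' parameters, assembled from the per-class free energies and their
#' analytic parameter derivatives: the clamped-true-label statistics
#' minus the posterior-averaged statistics over classes.
#'
#' @param model a [labeled_rbm()].
#' @param features 0/1 feature vector.
#' @param true_label class index in `1..n_labels`.
#' @return list with `d_weights`, `d_visible_bias`, `d_hidden_bias`
#'   (ascent direction).
#' @export
rbm_label_gradient <- function(model, features, true_label) {
  stopifnot(true_label >= 1, true_label <= model$n_labels)
  check_length(features, model$n_features)
  K <- model$n_labels
  m <- model$rbm
  p <- rbm_classify(model, features)
  V <- cbind(matrix(features, K, model$n_features, byrow = TRUE), diag(K))
  PH <- sigmoid(sweep(V %*% m$weights, 2, m$hidden_bias, "+"))  # K x nh
  # d(-F_c)/dW_ik = v_i sigmoid(x_k); gradient = clamped - posterior avg
  vt <- V[true_label, ]
  d_w <- outer(vt, PH[true_label, ]) - t(V * p) %*% PH
  d_vb <- vt - as.numeric(p %*% V)
  d_hb <- PH[true_label, ] - as.numeric(p %*% PH)
  list(d_weights = d_w, d_visible_bias = d_vb, d_hidden_bias = d_hb)
}

#' Posterior over true labels given features and a noisy observed label
#'
#' Treats the provided label as a noisy observation of the true label
#' through a fixed row-stochastic confusion matrix:
#' `p(t | features, observed) \propto p(t | features) * confusion[t, observed]`.
#' Information from the features can thus overrule an obviously wrong
#' label, while an identity confusion matrix defers entirely to the
#' observation.
#'
#' @param model a [labeled_rbm()].
#' @param features 0/1 feature vector.
#' @param observed_label observed class index.
#' @param confusion `n_labels x n_labels` row-stochastic matrix; entry
#'   `(t, o)` is the probability that true class `t` is reported as `o`.
#' @return posterior probability vector over true classes.
#' @export
infer_true_label <- function(model, features, observed_label, confusion) {
  K <- model$n_labels
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(K, K)), all(confusion >= 0),
            max(abs(rowSums(confusion) - 1)) < 1e-8,
            observed_label >= 1, observed_label <= K)
  post <- rbm_classify(model, features) * confusion[, observed_label]
  post / sum(post)
}

#' Train a joint feature-label RBM by contrastive divergence
#'
#' CD-1 on the concatenated (features, one-hot label) vectors.  The
#' reconstruction of the label block goes through a softmax over the
#' label units' inputs -- preserving the one-hot semantics -- while the
#' feature block uses the usual independent logistic reconstruction.
#' With the default `"sample"` statistics the negative phase uses
#' stochastic binary feature reconstructions and a single label drawn
#' from the softmax; `"mean_field"` keeps the probabilities.  An
#' optional discriminative term ([rbm_label_gradient()]) can be mixed in
#' with weight `discriminative_weight` (default 0: pure generative).
#'
#' @param features 0/1 matrix of training cases.
#' @param labels integer class labels aligned with the rows.
#' @param n_labels number of classes.
#' @param n_hidden hidden layer size.
#' @param config [train_config()].
#' @param discriminative_weight coefficient on the exact discriminative
#'   gradient added to the generative CD update.
#' @param statistics negative-phase convention, see [rbm_cd1()].
#' @return list with `model` (a [labeled_rbm()]) and `recon_error` per
#'   epoch.
#' @export
train_labeled_rbm <- function(features, labels, n_labels, n_hidden,
                              config = train_config(),
                              discriminative_weight = 0,
                              statistics = c("sample", "mean_field")) {
  statistics <- match.arg(statistics)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  set.seed(config$seed)
  model <- labeled_rbm(ncol(features), n_labels, n_hidden = n_hidden)
  lab_cols <- label_block_cols(model)
  data <- cbind(features, one_hot(labels, n_labels))
  errs <- numeric(config$epochs)
  lr <- config$learning_rate
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(nrow(data))
    starts <- seq(1, nrow(data), by = config$batch_size)
    e <- 0
    for (s in starts) {
      rows <- idx[s:min(s + config$batch_size - 1, nrow(data))]
      batch <- data[rows, , drop = FALSE]
      m <- model$rbm
      ph0 <- rbm_conditional(m, batch, "hidden_given_visible")
      h <- rbernoulli(ph0)
      inp <- sweep(h %*% t(m$weights), 2, m$visible_bias, "+")
      pv <- sigmoid(inp)
      # softmax reconstruction of the one-hot label block
      lab_in <- inp[, lab_cols, drop = FALSE]
      lab_p <- exp(lab_in - apply(lab_in, 1, max))
      lab_p <- lab_p / rowSums(lab_p)
      if (statistics == "sample") {
        vneg <- rbernoulli(pv)
        drawn <- vapply(seq_len(nrow(lab_p)), function(r)
          sample.int(ncol(lab_p), 1, prob = lab_p[r, ]), integer(1))
        vneg[, lab_cols] <- one_hot(drawn, model$n_labels)
      } else {
        vneg <- pv
        vneg[, lab_cols] <- lab_p
      }
      pv[, lab_cols] <- lab_p
      ph1 <- sigmoid(sweep(vneg %*% m$weights, 2, m$hidden_bias, "+"))
      n <- nrow(batch)
      m$weights <- m$weights + lr * (t(batch) %*% ph0 - t(vneg) %*% ph1) / n
      m$visible_bias <- m$visible_bias + lr * (colMeans(batch) - colMeans(vneg))
      m$hidden_bias <- m$hidden_bias + lr * (colMeans(ph0) - colMeans(ph1))
      if (discriminative_weight > 0) {
        model$rbm <- m
        for (r in seq_len(n)) {
          g <- rbm_label_gradient(model, batch[r, seq_len(model$n_features)],
                                  which.max(batch[r, lab_cols]))
          m$weights <- m$weights +
            lr * discriminative_weight * g$d_weights / n
          m$visible_bias <- m$visible_bias +
            lr * discriminative_weight * g$d_visible_bias / n
          m$hidden_bias <- m$hidden_bias +
            lr * discriminative_weight * g$d_hidden_bias / n
        }
      }
      model$rbm <- m
      e <- e + mean((batch - pv)^2) * n
    }
    errs[ep] <- e / nrow(data)
  }
  list(model = model, recon_error = errs)
}
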