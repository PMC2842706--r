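# Seeded synthetic-data generators: bars-and-stripes images, oriented
# strokes, samples from ground-truth models, and noisy-label sets.  Every
# generator is a pure function of its parameters and seed, so no external
# dataset is ever needed.

#' Bars-and-stripes images
#'
#' The classic toy distribution for binary generative models: each image
#' picks an orientation uniformly (rows or columns) and then switches
#' each row (respectively column) on independently with probability 1/2.
#'
#' @param side image side length (images are `side x side`, flattened
#'   row-major into vectors of length `side^2`).
#' @param n_cases number of images.
#' @param seed integer seed; the same `(side, n_cases, seed)` always
#'   yields bit-identical output.
#' @return 0/1 matrix with `n_cases` rows.
#' @export
make_bars_stripes <- function(side, n_cases, seed = 1) {
  stopifnot(side >= 1, n_cases >= 1)
  set.seed(seed)
  out <- matrix(0, n_cases, side * side)
  horiz <- stats::runif(n_cases) < 0.5
  on <- matrix(stats::runif(n_cases * side) < 0.5, n_cases, side)
  for (r in seq_len(n_cases)) {
    img <- matrix(0, side, side)
    if (horiz[r]) img[on[r, ], ] <- 1 else img[, on[r, ]] <- 1
    out[r, ] <- as.numeric(t(img))
  }
  out
}

#' Exact bars-and-stripes distribution
#'
#' Closed-form probability of every visible state under the
#' [make_bars_stripes()] generator, indexed in [binary_states()] order:
#' each of the `2^side` row patterns and `2^side` column patterns carries
#' mass `2^-(side+1)`, with the all-on and all-off images (which are both)
#' receiving twice that.
#'
#' @param side image side, `side^2 <= 24`.
#' @return probability vector of length `2^(side^2)` summing to 1.
#' @export
bars_stripes_distribution <- function(side) {
  guard_units(side * side)
  p <- numeric(2^(side * side))
  pat <- binary_states(side)
  for (r in seq_len(nrow(pat))) {
    img_rows <- matrix(rep(pat[r, ], each = side), side, side, byrow = TRUE)
    img_cols <- t(img_rows)
    w <- 0.5 * (1 / 2^side)
    p[state_index(as.numeric(t(img_rows)))] <-
      p[state_index(as.numeric(t(img_rows)))] + w
    p[state_index(as.numeric(t(img_cols)))] <-
      p[state_index(as.numeric(t(img_cols)))] + w
  }
  p
}

#' Oriented-stroke images
#'
#' Each image contains one straight stroke: an orientation is drawn from
#' `n_orientations` equally spaced angles in `[0, pi)`, a center pixel is
#' drawn uniformly, and every pixel whose perpendicular distance to the
#' line through the center is below `stroke_width / 2` is switched on.
#' Strokes run the full frame, so pixel pairs along the stroke direction
#' are positively correlated across the ensemble while pairs separated
#' orthogonally by about the stroke width are anti-correlated -- the
#' covariance structure an oriented-energy model should discover.
#'
#' @param side image side (>= 4).
#' @param n_orientations number of equally spaced stroke orientations.
#' @param stroke_width width in pixels.
#' @param n_cases number of images.
#' @param seed integer seed.
#' @return 0/1 matrix with `n_cases` rows of flattened (row-major)
#'   images.
#' @export
make_oriented_strokes <- function(side, n_orientations = 4, stroke_width = 1,
                                  n_cases = 100, seed = 1) {
  stopifnot(side >= 4, n_orientations >= 1, stroke_width >= 1)
  set.seed(seed)
  xs <- rep(0:(side - 1), each = side)   # row-major: row index varies slowest
  ys <- rep(0:(side - 1), times = side)
  angles <- (seq_len(n_orientations) - 1) * pi / n_orientations
  out <- matrix(0, n_cases, side * side)
  th <- sample(angles, n_cases, replace = TRUE)
  # for even widths the stroke center sits between pixel rows
  shift <- if (stroke_width %% 2 == 0) 0.5 else 0
  cx <- sample(0:(side - 1 - (stroke_width %% 2 == 0)), n_cases,
               replace = TRUE) + shift
  cy <- sample(0:(side - 1 - (stroke_width %% 2 == 0)), n_cases,
               replace = TRUE) + shift
  for (r in seq_len(n_cases)) {
    # perpendicular distance of each pixel center to the stroke line
    d <- abs(-sin(th[r]) * (xs - cx[r]) + cos(th[r]) * (ys - cy[r]))
    out[r, d < stroke_width / 2] <- 1
  }
  out
}

#' Gibbs samples from a ground-truth RBM
#'
#' Draws visible vectors from a given RBM by running `n_cases`
#' independent, vectorized Gibbs chains for `burn_in + thin - 1` full
#' alternations each and keeping the final visible state of every chain.
#' For enumeration-scale models the empirical marginal converges to the
#' exact one, enabling parameter-recovery tests.
#'
#' @param model an [rbm()].
#' @param n_cases number of samples.
#' @param burn_in alternations before the kept state (>= 1).
#' @param thin extra alternations per chain (>= 1).
#' @param seed integer seed.
#' @return 0/1 matrix with `n_cases` rows.
#' @export
sample_rbm_data <- function(model, n_cases, burn_in = 50, thin = 1, seed = 1) {
  stopifnot(n_cases >= 1, burn_in >= 1, thin >= 1)
  set.seed(seed)
  v <- matrix(rbernoulli(matrix(0.5, n_cases, n_visible(model))), n_cases)
  for (s in seq_len(burn_in + thin - 1)) v <- rbm_gibbs_step(model, v)$v_next
  v
}

#' Class-conditional features with corrupted labels
#'
#' Generates a separable multi-class set: class `c` has a deterministic
#' block prototype (`block_size = n_features / n_classes` consecutive
#' units on) and each case flips every prototype bit independently with
#' probability `bit_noise`.  Each true label is then replaced, with
#' probability `flip_rate`, by a label drawn uniformly over all classes
#' (`flip_mode = "uniform_all"`, so a fraction `flip_rate / n_classes` of
#' the flips restore the truth) or over the other classes
#' (`"uniform_other"`).
#'
#' @param n_classes number of classes (`n_features` must be a multiple).
#' @param n_features feature vector length.
#' @param n_cases number of cases.
#' @param flip_rate probability a label is replaced, in `[0, 1]`.
#' @param bit_noise per-bit flip probability of the features.
#' @param flip_mode `"uniform_all"` (default) or `"uniform_other"`.
#' @param seed integer seed.
#' @return list with `features` (0/1 matrix), `observed_labels`,
#'   `true_labels` (integer vectors).
#' @export
make_noisy_labels <- function(n_classes = 4, n_features = 16, n_cases = 100,
                              flip_rate = 0.5, bit_noise = 0.05,
                              flip_mode = c("uniform_all", "uniform_other"),
                              seed = 1) {
  flip_mode <- match.arg(flip_mode)
  stopifnot(n_features %% n_classes == 0, flip_rate >= 0, flip_rate <= 1,
            bit_noise >= 0, bit_noise < 0.5)
  set.seed(seed)
  block <- n_features / n_classes
  protos <- matrix(0, n_classes, n_features)
  for (c in seq_len(n_classes)) protos[c, (c - 1) * block + seq_len(block)] <- 1
  true_labels <- sample.int(n_classes, n_cases, replace = TRUE)
  feats <- protos[true_labels, , drop = FALSE]
  flips <- matrix(stats::runif(n_cases * n_features) < bit_noise,
                  n_cases, n_features)
  feats <- abs(feats - flips)
  observed <- true_labels
  corrupt <- stats::runif(n_cases) < flip_rate
  if (any(corrupt)) {
    if (flip_mode == "uniform_all") {
      observed[corrupt] <- sample.int(n_classes, sum(corrupt), replace = TRUE)
    } else {
      observed[corrupt] <- vapply(true_labels[corrupt], function(t) {
        sample(setdiff(seq_len(n_classes), t), 1)
      }, integer(1))
    }
  }
  list(features = feats, observed_labels = observed, true_labels = true_labels)
}
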