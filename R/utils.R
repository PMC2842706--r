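# Shared numerical helpers: logistic, stable softplus, binary-state
# enumeration and small input-validation utilities used across models.

#' Logistic sigmoid
#'
#' `sigmoid(x)` computes `1 / (1 + exp(-x))`, the activation probability of
#' a binary stochastic unit with total input `x`.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with values in (0, 1).
#' @export
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

#' Numerically stable softplus
#'
#' `softplus(x)` computes `log(1 + exp(x))` without overflow for large `x`.
#' It is the per-hidden-unit contribution to an RBM free energy.
#'
#' @param x numeric vector or matrix.
#' @return same shape as `x`.
#' @export
softplus <- function(x) {
  # log(1+exp(x)) = max(x,0) + log1p(exp(-|x|))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Enumerate all binary states of n units
#'
#' Returns a `2^n` by `n` matrix whose rows are all 0/1 configurations of
#' `n` binary units.  Row `s` encodes the integer `s - 1` with bit `i`
#' (least significant first) in column `i`; every enumeration oracle in the
#' package indexes states with this convention.
#'
#' @param n number of units; must satisfy `n <= 24`.
#' @return integer matrix of 0s and 1s.
#' @export
binary_states <- function(n) {
  stopifnot(n >= 0)
  if (n > 24) {
    stop("enumeration over ", n, " units exceeds the 24-unit capacity guard",
         call. = FALSE)
  }
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  s <- 0:(2^n - 1)
  m <- matrix(0L, nrow = length(s), ncol = n)
  for (i in seq_len(n)) {
    m[, i] <- bitwAnd(bitwShiftR(s, i - 1L), 1L)
  }
  m
}

#' Index of a binary state in the enumeration order
#'
#' Inverse of the row convention of [binary_states()]: returns the 1-based
#' row at which the 0/1 vector `v` appears.
#'
#' @param v 0/1 vector.
#' @return integer row index.
#' @export
state_index <- function(v) {
  check_binary(v)
  as.integer(sum(v * 2^(seq_along(v) - 1))) + 1L
}

check_binary <- function(v, name = deparse(substitute(v))) {
  if (!is.numeric(v) || any(v != 0 & v != 1)) {
    stop("`", name, "` must be a vector of 0s and 1s", call. = FALSE)
  }
  invisible(v)
}

check_length <- function(v, n, name = deparse(substitute(v))) {
  if (length(v) != n) {
    stop("`", name, "` has length ", length(v), ", expected ", n,
         call. = FALSE)
  }
  invisible(v)
}

guard_units <- function(total, limit = 24) {
  if (total > limit) {
    stop("model with ", total, " total units is too large to enumerate ",
         "(capacity guard: ", limit, " units)", call. = FALSE)
  }
  invisible(total)
}

# Draw a Bernoulli matrix/vector with the same shape as p.
rbernoulli <- function(p) {
  r <- (stats::runif(length(p)) < p) * 1
  if (is.matrix(p)) dim(r) <- dim(p)
  r
}

# Rows of a data matrix with nv columns; entries must lie in [0,1]
# (binary states or mean-field activities -- the standard real-valued
# extension is accepted everywhere the algebra allows it).
check_dataset <- function(x, nv) {
  x <- as.matrix(x)
  if (ncol(x) != nv) {
    stop("dataset has ", ncol(x), " columns, model expects ", nv, call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop("dataset entries must lie in [0, 1]", call. = FALSE)
  }
  x
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
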