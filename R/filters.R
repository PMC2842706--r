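# Receptive-field visualization and a quantitative orientation
# selectivity index used to characterize learned filters.

filter_matrix <- function(model) {
  switch(class(model)[1],
         rbm = model$weights,
         gated_rbm = model$vis_to_factor,
         labeled_rbm = model$rbm$weights[seq_len(model$n_features), ,
                                         drop = FALSE],
         stop("model has no per-unit visible weight vectors", call. = FALSE))
}

#' Export per-unit receptive fields as a tiled grayscale image
#'
#' Writes one square tile per hidden unit (RBM) or per factor (gated
#' model): the unit's visible weight vector reshaped to an image,
#' linearly rescaled to the 0-255 range independently per tile.  The
#' original scale of every tile (its weight minimum and maximum) is
#' recorded in a plain-text sidecar `<path>.txt`, so the image remains
#' quantitatively recoverable.
#'
#' @param model an [rbm()], [gated_rbm()] or [labeled_rbm()] whose
#'   visible layer is a square image.
#' @param path output PGM file; the sidecar goes to `paste0(path, ".txt")`.
#' @param grid_shape optional `c(rows, cols)` of the tile grid; must hold
#'   all units.
#' @return invisibly, a list with the tile `grid_shape` and the per-tile
#'   `ranges` matrix.
#' @export
export_filters <- function(model, path, grid_shape = NULL) {
  W <- filter_matrix(model)
  side <- sqrt(nrow(W))
  if (side != round(side)) {
    stop("visible layer is not a square image", call. = FALSE)
  }
  side <- as.integer(side)
  n <- ncol(W)
  if (is.null(grid_shape)) {
    cols <- ceiling(sqrt(n))
    grid_shape <- c(ceiling(n / cols), cols)
  }
  if (prod(grid_shape) < n) {
    stop("grid ", grid_shape[1], "x", grid_shape[2], " too small for ", n,
         " units", call. = FALSE)
  }
  pad <- 1L  # one-pixel separator between tiles
  img <- matrix(0, grid_shape[1] * (side + pad) - pad,
                grid_shape[2] * (side + pad) - pad)
  ranges <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("min", "max")))
  for (k in seq_len(n)) {
    tile <- matrix(W[, k], side, side, byrow = TRUE)
    lo <- min(tile); hi <- max(tile)
    ranges[k, ] <- c(lo, hi)
    scaled <- if (hi > lo) (tile - lo) / (hi - lo) * 255 else
      matrix(127.5, side, side)
    r0 <- ((k - 1) %/% grid_shape[2]) * (side + pad)
    c0 <- ((k - 1) %% grid_shape[2]) * (side + pad)
    img[r0 + seq_len(side), c0 + seq_len(side)] <- scaled
  }
  write_pgm(img, path)
  writeLines(c("tile min max",
               sprintf("%d %s %s", seq_len(n), fmt_num(ranges[, 1]),
                       fmt_num(ranges[, 2]))),
             paste0(path, ".txt"))
  invisible(list(grid_shape = grid_shape, ranges = ranges))
}

#' Orientation selectivity of a square filter
#'
#' Gradient structure-tensor coherence of the filter image: with
#' `J = sum over pixels of [gx^2, gx gy; gx gy, gy^2]` from central
#' differences, the index is
#' `sqrt((Jxx - Jyy)^2 + 4 Jxy^2) / (Jxx + Jyy)`, which is 0 for an
#' isotropic filter and 1 for a perfectly oriented one.  Filters that
#' align with a single stroke direction (bar-shaped receptive fields)
#' score high; unstructured noise filters score low.
#'
#' @param w filter as a numeric vector (length `side^2`, row-major) or a
#'   square matrix.
#' @return selectivity index in `[0, 1]`.
#' @export
orientation_selectivity <- function(w) {
  if (!is.matrix(w)) {
    side <- sqrt(length(w))
    stopifnot(side == round(side))
    w <- matrix(w, side, side, byrow = TRUE)
  }
  stopifnot(nrow(w) == ncol(w), nrow(w) >= 3)
  n <- nrow(w)
  inner <- 2:(n - 1)
  gx <- (w[3:n, inner] - w[1:(n - 2), inner]) / 2
  gy <- (w[inner, 3:n] - w[inner, 1:(n - 2)]) / 2
  jxx <- sum(gx^2); jyy <- sum(gy^2); jxy <- sum(gx * gy)
  tr <- jxx + jyy
  if (tr == 0) return(0)
  sqrt((jxx - jyy)^2 + 4 * jxy^2) / tr
}
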