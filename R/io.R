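# Serialization and file formats: the versioned plain-text model
# container, 0/1 dataset matrices, and 8-bit PGM images.  Floats are
# written with 17 significant digits so a save/load round trip is
# bit-exact and a second save is byte-identical.

CONTAINER_MAGIC <- "rbmstack-container"
CONTAINER_VERSION <- 1L
MODEL_KINDS <- c("rbm", "sbn", "stack", "labeled_joint", "gated")

fmt_num <- function(x) sprintf("%.17g", x)

container_lines <- function(kind, blocks, meta = list()) {
  lines <- c(paste(CONTAINER_MAGIC, CONTAINER_VERSION),
             paste("model_kind:", kind))
  for (nm in names(meta)) {
    lines <- c(lines, paste0("meta ", nm, ": ", meta[[nm]]))
  }
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!is.matrix(b)) b <- matrix(b, nrow = 1)
    lines <- c(lines, paste("block", nm, nrow(b), ncol(b)),
               apply(b, 1, function(r) paste(fmt_num(r), collapse = " ")))
  }
  c(lines, paste("end", CONTAINER_MAGIC))
}

model_kind <- function(model) {
  switch(class(model)[1],
         rbm = "rbm", sbn = "sbn", dbn = "stack",
         labeled_rbm = "labeled_joint", gated_rbm = "gated",
         stop("cannot serialize objects of class ", class(model)[1],
              call. = FALSE))
}

model_blocks <- function(model) {
  switch(model_kind(model),
    rbm = list(weights = model$weights,
               visible_bias = model$visible_bias,
               hidden_bias = model$hidden_bias),
    sbn = {
      L <- length(model$layer_sizes)
      b <- list(layer_sizes = as.numeric(model$layer_sizes))
      for (k in seq_len(L)) b[[paste0("biases_", k)]] <- model$biases[[k]]
      for (k in seq_len(L - 1)) b[[paste0("weights_", k)]] <- model$weights[[k]]
      b
    },
    stack = {
      b <- list(n_layers = length(model$layers))
      for (k in seq_along(model$layers)) {
        m <- model$layers[[k]]
        b[[paste0("layer", k, "_weights")]] <- m$weights
        b[[paste0("layer", k, "_visible_bias")]] <- m$visible_bias
        b[[paste0("layer", k, "_hidden_bias")]] <- m$hidden_bias
      }
      b
    },
    labeled_joint = list(block_sizes = c(model$n_features, model$n_labels),
                         weights = model$rbm$weights,
                         visible_bias = model$rbm$visible_bias,
                         hidden_bias = model$rbm$hidden_bias),
    gated = list(vis_to_factor = model$vis_to_factor,
                 factor_to_hidden = model$factor_to_hidden,
                 hidden_bias = model$hidden_bias,
                 visible_bias = model$visible_bias))
}

#' Save a model to the plain-text container format
#'
#' All five model kinds (`rbm`, `sbn`, `dbn` stacks, `labeled_rbm`,
#' `gated_rbm`) share one versioned, line-oriented text format: a magic
#' header with the format version, the model kind, optional metadata
#' lines, named numeric blocks with their dimensions, and an end marker
#' that makes truncation detectable.  Numbers carry 17 significant
#' digits, so `save -> load -> save` is byte-identical.
#'
#' @param model a model object from this package.
#' @param path file to write.
#' @param meta optional named list of metadata strings (e.g. the creation
#'   config and seed) echoed into the header.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, meta = list()) {
  writeLines(container_lines(model_kind(model), model_blocks(model), meta),
             path)
  invisible(path)
}

parse_block_matrix <- function(lines, at, nr, nc, name) {
  if (at + nr - 1 > length(lines)) {
    stop("corrupt container file: block `", name, "` is truncated",
         call. = FALSE)
  }
  vals <- lapply(lines[at:(at + nr - 1)], function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  })
  if (any(vapply(vals, length, 1L) != nc) || anyNA(unlist(vals))) {
    stop("corrupt container file: block `", name, "` is malformed",
         call. = FALSE)
  }
  matrix(unlist(vals), nrow = nr, ncol = nc, byrow = TRUE)
}

#' Load a model from the container format
#'
#' Reverses [save_model()], reconstructing the original S3 object.
#' A wrong magic line or missing end marker raises a corrupt-file error,
#' an unsupported `format_version` a version-mismatch error, and an
#' unrecognized kind an unknown-model-kind error.
#'
#' @param path file written by [save_model()].
#' @return the model object; metadata lines are attached as the
#'   `"meta"` attribute.
#' @export
load_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    stop("corrupt container file: too short", call. = FALSE)
  }
  head <- strsplit(lines[1], " ")[[1]]
  if (!identical(head[1], CONTAINER_MAGIC)) {
    stop("corrupt container file: bad header", call. = FALSE)
  }
  if (as.integer(head[2]) != CONTAINER_VERSION) {
    stop("container format version mismatch: file has version ", head[2],
         ", reader supports ", CONTAINER_VERSION, call. = FALSE)
  }
  kind <- sub("^model_kind: *", "", lines[2])
  if (!kind %in% MODEL_KINDS) {
    stop("unknown model kind `", kind, "`", call. = FALSE)
  }
  if (lines[length(lines)] != paste("end", CONTAINER_MAGIC)) {
    stop("corrupt container file: missing end marker (truncated?)",
         call. = FALSE)
  }
  blocks <- list(); meta <- list()
  i <- 3
  while (i < length(lines)) {
    l <- lines[i]
    if (startsWith(l, "meta ")) {
      kv <- sub("^meta ", "", l)
      key <- sub(":.*$", "", kv)
      meta[[key]] <- sub("^[^:]*: *", "", kv)
      i <- i + 1
    } else if (startsWith(l, "block ")) {
      parts <- strsplit(l, " ")[[1]]
      nr <- as.integer(parts[3]); nc <- as.integer(parts[4])
      blocks[[parts[2]]] <- parse_block_matrix(lines, i + 1, nr, nc, parts[2])
      i <- i + 1 + nr
    } else {
      stop("corrupt container file: unexpected line ", i, call. = FALSE)
    }
  }
  model <- rebuild_model(kind, blocks)
  attr(model, "meta") <- meta
  model
}

as_vec <- function(b) as.numeric(b)

rebuild_model <- function(kind, blocks) {
  switch(kind,
    rbm = rbm(nrow(blocks$weights), ncol(blocks$weights),
              weights = blocks$weights,
              visible_bias = as_vec(blocks$visible_bias),
              hidden_bias = as_vec(blocks$hidden_bias)),
    sbn = {
      sizes <- as.integer(as_vec(blocks$layer_sizes))
      L <- length(sizes)
      sbn(sizes,
          weights = lapply(seq_len(L - 1), function(k)
            blocks[[paste0("weights_", k)]]),
          biases = lapply(seq_len(L), function(k)
            as_vec(blocks[[paste0("biases_", k)]])))
    },
    stack = {
      n <- as.integer(as_vec(blocks$n_layers))
      dbn(lapply(seq_len(n), function(k) {
        w <- blocks[[paste0("layer", k, "_weights")]]
        rbm(nrow(w), ncol(w), weights = w,
            visible_bias = as_vec(blocks[[paste0("layer", k, "_visible_bias")]]),
            hidden_bias = as_vec(blocks[[paste0("layer", k, "_hidden_bias")]]))
      }))
    },
    labeled_joint = {
      bs <- as.integer(as_vec(blocks$block_sizes))
      w <- blocks$weights
      labeled_rbm(bs[1], bs[2],
                  rbm = rbm(nrow(w), ncol(w), weights = w,
                            visible_bias = as_vec(blocks$visible_bias),
                            hidden_bias = as_vec(blocks$hidden_bias)))
    },
    gated = gated_rbm(nrow(blocks$vis_to_factor), ncol(blocks$vis_to_factor),
                      ncol(blocks$factor_to_hidden),
                      vis_to_factor = blocks$vis_to_factor,
                      factor_to_hidden = blocks$factor_to_hidden,
                      hidden_bias = as_vec(blocks$hidden_bias),
                      visible_bias = as_vec(blocks$visible_bias)))
}

#' Read and write plain-text 0/1 dataset matrices
#'
#' One case per row, space-separated 0/1 entries.
#'
#' @param data 0/1 matrix.
#' @param path file path.
#' @return `read_dataset` returns the matrix; `write_dataset` returns
#'   `path` invisibly.
#' @export
write_dataset <- function(data, path) {
  data <- as.matrix(data)
  stopifnot(all(data %in% c(0, 1)))
  writeLines(apply(data, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  })
  m <- do.call(rbind, rows)
  if (anyNA(m) || any(m != 0 & m != 1)) {
    stop("not a 0/1 dataset file: ", path, call. = FALSE)
  }
  m
}

#' Write and read 8-bit binary PGM (P5) images
#'
#' @param img numeric matrix; values are clamped to `[0, 255]` and
#'   rounded.
#' @param path file path.
#' @param maxval maximum grey value recorded in the header.
#' @return `read_pgm` returns an integer matrix; `write_pgm` returns
#'   `path` invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255) {
  img <- pmin(pmax(round(img), 0), maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval), con,
            eos = NULL)
  writeBin(as.integer(t(img)), con, size = 1)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  while (length(tok) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PGM", call. = FALSE)
    if (grepl("[[:space:]]", ch)) next
    word <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
      word <- paste0(word, ch)
    }
    tok <- c(tok, word)
  }
  stopifnot(tok[1] == "P5")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  px <- readBin(con, "integer", n = w * h, size = 1, signed = FALSE)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
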