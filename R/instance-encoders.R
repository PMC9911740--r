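#' Dense feature-block weights
#'
#' One fully connected hidden layer per feature block: weights `V` (input
#' dim x hidden dim) and bias `b`, Gaussian-initialized with scale
#' 1/sqrt(input dim).
#'
#' @param in_dim Input dimension of the raw feature vector.
#' @param h Hidden dimension of the block.
#' @param seed RNG seed.
#' @export
dense_block_weights <- function(in_dim, h, seed = 1L) {
  stopifnot(h >= 1, in_dim >= 1)
  with_seed(seed, list(
    V = matrix(stats::rnorm(in_dim * h, sd = 1 / sqrt(in_dim)), in_dim, h),
    b = numeric(h)
  ))
}

#' Encode one feature block
#'
#' Applies the block's fully connected transform with a ReLU nonlinearity:
#' `relu(x V + b)`. A pure function of (weights, input).
#'
#' @param x Numeric vector, or matrix with one instance per row.
#' @param weights A [dense_block_weights()] list.
#' @return Encoded vector / matrix with the block's hidden dimension.
#' @export
encode_feature_block <- function(x, weights) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nrow(weights$V)) {
    stop(sprintf("feature dimension %d does not match weights (%d)",
                 ncol(X), nrow(weights$V)))
  }
  H <- pmax(sweep(X %*% weights$V, 2, weights$b, `+`), 0)
  if (is.matrix(x)) H else drop(H)
}

#' Concatenate encoded feature blocks into one instance embedding
#'
#' @param encoded Named list of encoded vectors (or matrices with matching
#'   row counts), in layout order.
#' @param layout Named integer vector giving each block's hidden dimension,
#'   in the model's fixed order.
#' @return Concatenated embedding with a `block_layout` attribute.
#' @export
concat_blocks <- function(encoded, layout) {
  if (!identical(names(encoded), names(layout))) {
    stop("block names/order do not match the layout: expected ",
         paste(names(layout), collapse = ", "))
  }
  dims <- vapply(encoded, function(e) if (is.matrix(e)) ncol(e) else length(e), 0L)
  if (!all(dims == unname(layout))) stop("block dimensions do not match layout")
  out <- if (is.matrix(encoded[[1]])) do.call(cbind, encoded) else
    unlist(encoded, use.names = FALSE)
  attr(out, "block_layout") <- layout
  out
}

#' Convolutional sequence-encoder configuration
#'
#' Multi-scale 1-d convolution over one-hot residue sequences: 16 kernel
#' sizes 8, 16, ..., 128, each with 512 filters, globally max-pooled per
#' kernel size and concatenated, giving a 16 x 512 = 8192-dimensional
#' sequence embedding under the defaults. The alphabet is the 20 standard
#' amino acids plus `X` (unknown residue) and `-` (pad), one-hot width 22;
#' sequences are zero-padded or truncated to `max_length`.
#'
#' @param kernel_sizes Strictly increasing integer kernel widths.
#' @param filters_per_kernel Filters per kernel size.
#' @param alphabet Residue symbols; the last symbol is the pad.
#' @param max_length Padded/truncated sequence length L.
#' @export
seq_encoder_config <- function(kernel_sizes = seq(8L, 128L, by = 8L),
                               filters_per_kernel = 512L,
                               alphabet = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                            "X", "-"),
                               max_length = 2000L) {
  stopifnot(all(diff(kernel_sizes) > 0), filters_per_kernel >= 1,
            max_length >= max(kernel_sizes))
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 filters_per_kernel = as.integer(filters_per_kernel),
                 alphabet = alphabet, max_length = as.integer(max_length)),
            class = "seq_encoder_config")
}

#' @rdname seq_encoder_config
#' @param cfg A `seq_encoder_config`.
#' @export
seq_embedding_dim <- function(cfg = seq_encoder_config()) {
  length(cfg$kernel_sizes) * cfg$filters_per_kernel
}

#' Random convolution weights for the sequence encoder
#'
#' @inheritParams seq_embedding_dim
#' @param seed RNG seed.
#' @return List with one `(kernel_size * alphabet) x filters` weight matrix
#'   and bias vector per kernel size.
#' @export
sequence_cnn_weights <- function(cfg = seq_encoder_config(), seed = 1L) {
  a <- length(cfg$alphabet)
  with_seed(seed, lapply(cfg$kernel_sizes, function(k) {
    list(W = matrix(stats::rnorm(k * a * cfg$filters_per_kernel,
                                 sd = 1 / sqrt(k * a)),
                    k * a, cfg$filters_per_kernel),
         b = numeric(cfg$filters_per_kernel))
  }))
}

# one-hot encode a residue string to max_length x |alphabet|;
# out-of-alphabet symbols map to X, padding uses the pad symbol.
one_hot_sequence <- function(seq, cfg) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  pad <- cfg$alphabet[length(cfg$alphabet)]
  chars[!(chars %in% cfg$alphabet)] <- "X"
  L <- cfg$max_length
  if (length(chars) > L) chars <- chars[seq_len(L)]
  if (length(chars) < L) chars <- c(chars, rep(pad, L - length(chars)))
  X <- matrix(0, L, length(cfg$alphabet))
  X[cbind(seq_len(L), match(chars, cfg$alphabet))] <- 1
  X
}

#' Encode a residue sequence with the multi-kernel CNN
#'
#' One-hot encodes the sequence (padded/truncated to `max_length`), runs a
#' 1-d convolution with ReLU for each kernel size, max-pools each filter
#' over all positions, and concatenates the pooled vectors: output length is
#' `length(kernel_sizes) * filters_per_kernel` (8192 under defaults).
#'
#' @param seq Residue string over the configured alphabet.
#' @param cfg A [seq_encoder_config()].
#' @param weights From [sequence_cnn_weights()].
#' @export
encode_sequence_cnn <- function(seq, cfg = seq_encoder_config(),
                                weights = sequence_cnn_weights(cfg)) {
  X <- one_hot_sequence(seq, cfg)
  a <- length(cfg$alphabet)
  xv <- as.vector(t(X))  # row-major: position-contiguous blocks of width a
  out <- vector("list", length(cfg$kernel_sizes))
  for (i in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[i]
    np <- cfg$max_length - k + 1L
    idx <- outer((seq_len(np) - 1L) * a, seq_len(k * a), `+`)
    conv <- pmax(sweep(matrix(xv[idx], np) %*% weights[[i]]$W, 2,
                       weights[[i]]$b, `+`), 0)
    out[[i]] <- apply(conv, 2, max)
  }
  unlist(out, use.names = FALSE)
}

#' Default per-modality encoder layouts
#'
#' Protein instances are embedded from three feature blocks (sequence CNN
#' output, description embedding, network embedding), each passed through a
#' fully connected block of hidden size 1500 (total 4500). Expression
#' profiles use a single fully connected block of hidden size 30. Drugs use
#' SMILES-derived features (a transformer encoder where available, a hashed
#' n-gram fingerprint otherwise); phenotypes and genes use precomputed or
#' diffusion-derived network features.
#'
#' @param modality Optional modality name (`"protein"`, `"expression"`,
#'   `"drug"`, `"phenotype"`); `NULL` returns the full table.
#' @export
default_modality_configs <- function(modality = NULL) {
  cfgs <- list(
    protein = list(blocks = c(sequence = 1500L, description = 1500L,
                              network = 1500L)),
    expression = list(blocks = c(expression = 30L)),
    drug = list(blocks = c(smiles = 256L),
                note = "transformer SMILES encoder when available; hashed n-gram fingerprint fallback"),
    phenotype = list(blocks = c(network = 256L),
                     note = "precomputed or diffusion-derived node features")
  )
  if (is.null(modality)) return(cfgs)
  if (!modality %in% names(cfgs)) stop("unknown modality: ", modality)
  cfgs[[modality]]
}

#' Hashed n-gram fingerprint for SMILES strings
#'
#' Deterministic character 1-3-gram signed hashing into `d` buckets,
#' L2-normalized; an offline-friendly molecular feature vector for the drug
#' modality.
#'
#' @param smiles Character vector of SMILES strings.
#' @param d Fingerprint dimension.
#' @param seed Hash seed.
#' @return Matrix with one row per molecule.
#' @export
smiles_fingerprint <- function(smiles, d = 256L, seed = 1L) {
  stopifnot(d >= 8)
  out <- matrix(0, length(smiles), d)
  rownames(out) <- names(smiles)
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (!nzchar(s)) stop("empty SMILES string")
    chars <- strsplit(s, "")[[1]]
    v <- numeric(d)
    for (n in 1:3) {
      if (length(chars) < n) break
      for (p in seq_len(length(chars) - n + 1L)) {
        h <- hash_token(paste(chars[p:(p + n - 1L)], collapse = ""), seed)
        b <- (h %% d) + 1L
        v[b] <- v[b] + if ((h %/% d) %% 2 == 0) 1 else -1
      }
    }
    out[i, ] <- l2_normalize(v)
  }
  out
}

#' Library-size normalize and log-transform a count matrix
#'
#' Standard expression preprocessing ahead of the expression encoder:
#' counts are scaled so each cell sums to `scale` and then log1p-transformed.
#'
#' @param counts cells x genes count matrix.
#' @param scale Target library size.
#' @export
normalize_expression <- function(counts, scale = 1e4) {
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  log1p(counts / lib * scale)
}
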