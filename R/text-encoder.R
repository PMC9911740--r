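#' Encoder configuration
#'
#' Hyperparameters for text encoding and contrastive fine-tuning. Defaults
#' follow the settings used for fine-tuning a biomedical transformer encoder
#' on ontology description corpora: Adam at learning rate 1e-5, batch size
#' 16, descriptions truncated at 256 tokens, output dimension 768. The
#' small trainable backends shipped here accept the same configuration; for
#' them a larger learning rate (around 1e-3) is appropriate to their scale.
#'
#' @param d_bio Embedding dimension.
#' @param max_tokens Maximum description length in tokens before truncation.
#' @param learning_rate Adam learning rate.
#' @param batch_size Pairs per contrastive batch.
#' @param epochs Fine-tuning epochs.
#' @param temperature Softmax temperature dividing cosine similarities.
#' @param seed RNG seed for shuffling and initialization.
#' @export
encoder_config <- function(d_bio = 768L, max_tokens = 256L,
                           learning_rate = 1e-5, batch_size = 16L,
                           epochs = 5L, temperature = 1.0, seed = 1L) {
  stopifnot(max_tokens >= 1, learning_rate > 0, temperature > 0, d_bio >= 1)
  structure(list(d_bio = as.integer(d_bio), max_tokens = as.integer(max_tokens),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), temperature = temperature,
                 seed = as.integer(seed)), class = "encoder_config")
}

#' Deterministic hashing text encoder
#'
#' A training-free encoder: each token is hashed (with a seed-mixed 31-bit
#' string hash) into one of `d_bio` signed buckets and the resulting
#' bag-of-tokens vector is L2-normalized. Texts sharing more tokens have
#' higher cosine similarity; token-disjoint texts have expected cosine near
#' zero because bucket signs are balanced. Deterministic given (seed, text).
#'
#' @param d_bio Embedding dimension (>= 8).
#' @param seed Integer mixed into the token hash.
#' @param max_tokens Truncation length applied before encoding.
#' @return A `text_encoder` object.
#' @export
hashing_encoder <- function(d_bio = 768L, seed = 1L, max_tokens = 256L) {
  stopifnot(d_bio >= 8)
  structure(list(backend = "hashing", d_bio = as.integer(d_bio),
                 seed = as.integer(seed), max_tokens = as.integer(max_tokens),
                 trainable = FALSE),
            class = c("hashing_encoder", "text_encoder"))
}

#' Small trainable embedding-bag text encoder
#'
#' Holds one trainable embedding vector per vocabulary token (plus an
#' out-of-vocabulary row); a text is encoded as the mean of its token
#' embeddings. This backend supports [contrastive_finetune()] at desk scale
#' and stands in for a transformer encoder in tests; the encoder contract
#' (encode a character vector to a fixed-dimension matrix) is identical, so
#' a pretrained-transformer backend can be plugged in behind the same
#' interface.
#'
#' @param vocab Character vector of tokens, or texts from which the
#'   vocabulary is collected.
#' @param d_bio Embedding dimension.
#' @param seed Seed for the Gaussian initialization.
#' @param max_tokens Truncation length.
#' @export
embedding_bag_encoder <- function(vocab, d_bio = 64L, seed = 1L,
                                  max_tokens = 256L) {
  toks <- sort(unique(unlist(lapply(vocab, tokenize_text))))
  E <- with_seed(seed, matrix(stats::rnorm((length(toks) + 1L) * d_bio,
                                           sd = 1 / sqrt(d_bio)),
                              nrow = length(toks) + 1L))
  rownames(E) <- c(toks, "<unk>")
  structure(list(backend = "embedding_bag", d_bio = as.integer(d_bio),
                 seed = as.integer(seed), max_tokens = as.integer(max_tokens),
                 vocab = toks, E = E, trainable = TRUE),
            class = c("embedding_bag_encoder", "text_encoder"))
}

# token index rows for one text under an embedding-bag encoder
bag_rows <- function(encoder, text) {
  toks <- tokenize_text(text, encoder$max_tokens)
  idx <- match(toks, encoder$vocab)
  idx[is.na(idx)] <- length(encoder$vocab) + 1L
  idx
}

#' Encode texts into the shared embedding space
#'
#' Pure function of (encoder state, text): identical inputs give identical
#' vectors, and truncation at `max_tokens` is applied before encoding, so a
#' text and its `max_tokens`-token prefix encode identically.
#'
#' @param texts Character vector of non-empty descriptions.
#' @param encoder A `text_encoder`.
#' @return Numeric matrix, one row per text, `d_bio` columns.
#' @export
encode_texts <- function(texts, encoder) {
  stopifnot(inherits(encoder, "text_encoder"))
  if (length(texts) == 0L) stop("no texts to encode")
  if (any(!nzchar(trimws(texts)))) stop("empty text cannot be encoded")
  out <- matrix(0, length(texts), encoder$d_bio)
  rownames(out) <- names(texts)
  if (encoder$backend == "hashing") {
    d <- encoder$d_bio
    for (i in seq_along(texts)) {
      toks <- tokenize_text(texts[i], encoder$max_tokens)
      v <- numeric(d)
      for (tk in toks) {
        h <- hash_token(tk, encoder$seed)
        b <- (h %% d) + 1L
        s <- if ((h %/% d) %% 2 == 0) 1 else -1
        v[b] <- v[b] + s
      }
      out[i, ] <- l2_normalize(v)
    }
  } else if (encoder$backend == "embedding_bag") {
    for (i in seq_along(texts)) {
      rows <- bag_rows(encoder, texts[i])
      out[i, ] <- colMeans(encoder$E[rows, , drop = FALSE])
    }
  } else {
    stop("unknown encoder backend: ", encoder$backend)
  }
  out
}

#' Positive pairs from ontology neighbours
#'
#' Descriptions of terms joined by an ontology edge form the positive pairs
#' for contrastive fine-tuning; all non-matching pairs within a batch act as
#' implicit negatives. Pair order is shuffled under the seed.
#'
#' @param g An [ontology_graph()].
#' @param seed Shuffle seed.
#' @param relations Edge relations treated as neighbourhood.
#' @return List with a data.frame `pairs` (id_a, id_b, text_a, text_b) and
#'   the seed.
#' @export
build_neighbor_pairs <- function(g, seed = 1L, relations = c("is_a", "part_of")) {
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  if (nrow(e) == 0L) stop("ontology has no edges under the chosen relations")
  desc <- term_description(g)
  keep <- e$child %in% names(desc) & e$parent %in% names(desc)
  e <- e[keep, , drop = FALSE]
  ord <- with_seed(seed, sample.int(nrow(e)))
  pairs <- data.frame(id_a = e$child[ord], id_b = e$parent[ord],
                      text_a = unname(desc[e$child[ord]]),
                      text_b = unname(desc[e$parent[ord]]),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, seed = as.integer(seed))
}

#' In-batch contrastive (InfoNCE) loss over a batch of embedding pairs
#'
#' Given embeddings of B positive pairs, forms the B x B cosine-similarity
#' matrix, divides by the temperature, and scores it against diagonal
#' targets with softmax cross-entropy, symmetrized over rows (a -> b) and
#' columns (b -> a).
#'
#' @param Za,Zb Numeric matrices (B x d), row i of `Za` paired with row i of
#'   `Zb`.
#' @param temperature Positive scalar dividing the similarities.
#' @return Scalar loss (mean over the batch of the two directions' mean).
#' @export
contrastive_loss <- function(Za, Zb, temperature = 1.0) {
  contrastive_loss_grad(Za, Zb, temperature, grad = FALSE)$loss
}

contrastive_loss_grad <- function(Za, Zb, temperature = 1.0, grad = TRUE) {
  B <- nrow(Za)
  An <- l2_normalize(Za)
  Bn <- l2_normalize(Zb)
  S <- (An %*% t(Bn)) / temperature
  # row-wise and column-wise softmax cross-entropy with diagonal targets
  lse_r <- apply(S, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  lse_c <- apply(S, 2, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  loss <- mean(c(lse_r - diag(S), lse_c - diag(S))) # = (row CE + col CE)/2
  if (!is.finite(loss)) stop("non-finite contrastive loss")
  if (!grad) return(list(loss = loss))
  Pr <- exp(S - lse_r)          # row softmax
  Pc <- t(exp(t(S) - lse_c))    # column softmax
  G <- ((Pr - diag(B)) + (Pc - diag(B))) / (2 * B * temperature)
  gAn <- G %*% Bn
  gBn <- t(G) %*% An
  # back through L2 normalization: u = x/|x|; dx = (du - (du.u)u)/|x|
  unnorm <- function(Z, U, gU) {
    nrm <- sqrt(rowSums(Z^2)); nrm[nrm == 0] <- 1
    (gU - U * rowSums(gU * U)) / nrm
  }
  list(loss = loss, gZa = unnorm(Za, An, gAn), gZb = unnorm(Zb, Bn, gBn))
}

#' Contrastively fine-tune a trainable text encoder
#'
#' Pulls ontology-neighbour descriptions together and pushes unrelated
#' descriptions apart: for each batch of pairs the in-batch similarity
#' matrix is scored against diagonal targets ([contrastive_loss()]) and the
#' encoder parameters are updated with Adam. With `epochs = 0` the encoder
#' is returned unchanged. Only trainable backends (the embedding bag) can be
#' fine-tuned.
#'
#' @param encoder A trainable `text_encoder`.
#' @param pairs Result of [build_neighbor_pairs()].
#' @param cfg An [encoder_config()].
#' @param verbose Print per-epoch mean loss.
#' @return The fine-tuned encoder (with a `loss_history` attribute).
#' @export
contrastive_finetune <- function(encoder, pairs, cfg = encoder_config(),
                                 verbose = FALSE) {
  stopifnot(inherits(encoder, "text_encoder"))
  if (cfg$epochs == 0L) return(encoder)
  if (!isTRUE(encoder$trainable)) stop("encoder backend is not trainable")
  P <- pairs$pairs
  if (cfg$batch_size > nrow(P)) stop("batch_size exceeds number of pairs")
  rows_a <- lapply(P$text_a, function(t) bag_rows(encoder, t))
  rows_b <- lapply(P$text_b, function(t) bag_rows(encoder, t))
  params <- list(E = encoder$E)
  opt <- adam_init(params, lr = cfg$learning_rate)
  history <- numeric(0)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(P))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (b in batches) {
        if (length(b) < 2L) next
        Za <- t(vapply(rows_a[b], function(r) colMeans(params$E[r, , drop = FALSE]),
                       numeric(encoder$d_bio)))
        Zb <- t(vapply(rows_b[b], function(r) colMeans(params$E[r, , drop = FALSE]),
                       numeric(encoder$d_bio)))
        lg <- contrastive_loss_grad(Za, Zb, cfg$temperature)
        gE <- matrix(0, nrow(params$E), ncol(params$E))
        for (i in seq_along(b)) {
          ra <- rows_a[[b[i]]]; rb <- rows_b[[b[i]]]
          for (r in ra) gE[r, ] <- gE[r, ] + lg$gZa[i, ] / length(ra)
          for (r in rb) gE[r, ] <- gE[r, ] + lg$gZb[i, ] / length(rb)
        }
        st <- adam_step(opt, params, list(E = gE))
        opt <- st$state; params <- st$params
        ep_loss <- ep_loss + lg$loss * length(b)
      }
      history <- c(history, ep_loss / nrow(P))
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
    }
  })
  encoder$E <- params$E
  attr(encoder, "loss_history") <- history
  encoder
}

#' Mean cosine gap between neighbour pairs and random pairs
#'
#' Diagnostic used to measure the effect of contrastive fine-tuning: the
#' mean cosine similarity of ontology-neighbour description embeddings minus
#' that of seeded random non-neighbour description pairs.
#'
#' @param encoder A `text_encoder`.
#' @param g An [ontology_graph()].
#' @param n_random Number of random non-neighbour pairs sampled.
#' @param seed Seed for the random pairs.
#' @inheritParams build_neighbor_pairs
#' @export
neighbor_cosine_gap <- function(encoder, g, n_random = 200L, seed = 1L,
                                relations = c("is_a", "part_of")) {
  desc <- term_description(g)
  Z <- l2_normalize(encode_texts(desc, encoder))
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  adj <- paste(e$child, e$parent)
  nb <- mean(rowSums(Z[e$child, , drop = FALSE] * Z[e$parent, , drop = FALSE]))
  ids <- names(desc)
  rnd <- with_seed(seed, {
    sims <- numeric(0)
    while (length(sims) < n_random) {
      a <- sample(ids, 1); b <- sample(ids, 1)
      if (a == b || paste(a, b) %in% adj || paste(b, a) %in% adj) next
      sims <- c(sims, sum(Z[a, ] * Z[b, ]))
    }
    sims
  })
  nb - mean(rnd)
}
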