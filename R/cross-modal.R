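#' Train a modality-to-text translator
#'
#' A translator maps one biological modality (genes, drugs, phenotypes,
#' pathways, ...) into the shared text-embedding space: an optional dense
#' instance encoder followed by a bilinear weight matrix `W_m`. It is
#' trained on (feature, description) pairs from that modality alone, in the
#' items-as-classes form of the multi-label objective: each item's own
#' description is its positive class and every other item's description a
#' negative, so no cross-modal pairs are ever needed.
#'
#' @param features Items x dim feature matrix with unique row ids.
#' @param descriptions Character vector of textual descriptions, one per
#'   row of `features`.
#' @param encoder A `text_encoder` shared across modalities (the pivot
#'   space).
#' @param cfg A [train_config()].
#' @param hidden `NULL` for identity features, or integer hidden dimension
#'   of the dense encoder block.
#' @param modality Label recorded on the translator.
#' @param center Center features on the corpus mean (stored and re-applied
#'   at prediction time). The bilinear form has no intercept, so an
#'   uncentered feature cloud leaks a rank-one location component into
#'   every logit that swamps the item-specific signal.
#' @return A `modality_translator`.
#' @export
train_translator <- function(features, descriptions, encoder,
                             cfg = train_config(), hidden = NULL,
                             modality = "generic", center = TRUE) {
  stopifnot(is.matrix(features), nrow(features) == length(descriptions))
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  if (anyDuplicated(ids)) stop("duplicate item ids in translator corpus")
  rownames(features) <- ids
  mu <- if (center) colMeans(features) else numeric(ncol(features))
  features <- sweep(features, 2, mu)
  ann <- annotation_matrix(A = diag(nrow(features)), instance_ids = ids,
                           term_ids = ids, propagated = TRUE)
  names(descriptions) <- ids
  if (!is.null(hidden)) hidden <- c(x = as.integer(hidden))
  model <- train_zero_shot(features, ann, descriptions, encoder, cfg,
                           hidden = hidden)
  structure(list(modality = modality, blocks = model$blocks, W = model$W,
                 d_bio = ncol(model$W), hidden = hidden, center = mu,
                 loss_history = model$loss_history),
            class = "modality_translator")
}

#' @export
print.modality_translator <- function(x, ...) {
  cat(sprintf("modality_translator (%s): W %dx%d\n", x$modality,
              nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Project modality features into the shared text space
#'
#' @param translator A `modality_translator`.
#' @param features Feature vector or items x dim matrix.
#' @return Items x d_bio matrix of text-space projections.
#' @export
translate_features <- function(translator, features) {
  Fm <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  Fm <- sweep(Fm, 2, translator$center %||% numeric(ncol(Fm)))
  Fe <- if (is.null(translator$blocks)) Fm else
    encode_feature_block(Fm, translator$blocks[[1]])
  if (ncol(Fe) != nrow(translator$W)) stop("feature dimension mismatch")
  out <- Fe %*% translator$W
  rownames(out) <- rownames(Fm)
  out
}

#' Cross-modal association probability
#'
#' Probability that an instance of modality a is paired with an instance of
#' modality b, with text as the pivot: the logistic of the dot product of
#' the two text-space projections, `logistic((W_a' F_a) . (W_b' F_b))`.
#' Symmetric in argument order. With matrix inputs returns the full
#' (items a) x (items b) probability matrix.
#'
#' @param t_a,t_b `modality_translator`s sharing the same d_bio.
#' @param F_a,F_b Feature vector(s) for each modality.
#' @export
cross_modal_score <- function(t_a, F_a, t_b, F_b) {
  if (t_a$d_bio != t_b$d_bio) stop("translators do not share d_bio")
  Pa <- translate_features(t_a, F_a)
  Pb <- translate_features(t_b, F_b)
  S <- sigmoid(Pa %*% t(Pb))
  if (!is.matrix(F_a) && !is.matrix(F_b)) drop(S) else S
}

#' Pathway embedding by sum pooling member genes
#'
#' A pathway's text-space embedding is the elementwise sum (not mean) of
#' its member genes' projections, so pathway size is reflected in the
#' embedding norm.
#'
#' @param gene_embeddings Matrix with one member gene projection per row,
#'   or list of vectors.
#' @export
pathway_embedding <- function(gene_embeddings) {
  M <- if (is.list(gene_embeddings)) do.call(rbind, gene_embeddings) else
    gene_embeddings
  if (is.null(M) || nrow(M) == 0L) stop("empty pathway")
  colSums(M)
}

#' Diffusion node features for a graph
#'
#' Network-topology features in the spirit of random-walk embedding
#' pipelines: a random-walk-with-restart proximity matrix over the graph is
#' factorized with a truncated SVD, giving each node a `dim`-dimensional
#' feature vector. Disconnected components never mix (their proximities are
#' exactly zero), and singular-vector signs are fixed so the output is
#' deterministic.
#'
#' @param g An `igraph` object, or a two-column edge data.frame.
#' @param dim Embedding dimension (must be < number of nodes).
#' @param restart Restart probability of the random walk.
#' @return Nodes x dim feature matrix with node names as row names.
#' @export
graph_node_features <- function(g, dim, restart = 0.5) {
  ig <- if (inherits(g, "igraph")) g else
    igraph::graph_from_data_frame(g, directed = FALSE)
  n <- igraph::vcount(ig)
  if (dim >= n) stop("dim must be smaller than the node count")
  A <- as.matrix(igraph::as_adjacency_matrix(ig))
  deg <- rowSums(A); deg[deg == 0] <- 1
  P <- A / deg
  Q <- restart * solve(diag(n) - (1 - restart) * P)
  S <- (Q + t(Q)) / 2
  sv <- svd(S, nu = dim, nv = 0)
  U <- sv$u
  for (j in seq_len(dim)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  X <- U %*% diag(sqrt(sv$d[seq_len(dim)]), dim)
  rownames(X) <- igraph::V(ig)$name
  X
}

#' Rank candidate instances for a query projection
#'
#' Orders candidates by descending cross-modal probability against the
#' query's text-space projection; ties broken by candidate id.
#'
#' @param query A text-space projection vector (see
#'   [translate_features()]).
#' @param candidates Matrix of candidate projections, one per row, with
#'   row-name ids.
#' @return data.frame (candidate_id, probability, rank), best first.
#' @export
rank_candidates <- function(query, candidates) {
  stopifnot(is.matrix(candidates), nrow(candidates) >= 1)
  ids <- rownames(candidates) %||% as.character(seq_len(nrow(candidates)))
  p <- drop(sigmoid(candidates %*% query))
  ord <- order(-p, ids)
  data.frame(candidate_id = ids[ord], probability = p[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Write a cross-modal prediction table
#'
#' @param t_a,t_b Translators.
#' @param F_a,F_b Feature matrices with row-name ids.
#' @param path Output TSV path (query_id, candidate_id, probability, rank).
#' @export
write_cross_modal_predictions <- function(t_a, F_a, t_b, F_b, path) {
  P <- cross_modal_score(t_a, F_a, t_b, F_b)
  rows <- lapply(seq_len(nrow(P)), function(i) {
    ord <- order(-P[i, ], colnames(P))
    data.frame(query_id = rownames(P)[i], candidate_id = colnames(P)[ord],
               probability = P[i, ord], rank = seq_along(ord),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
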