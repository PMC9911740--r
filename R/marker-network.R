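#' Marker genes by expression-probability correlation
#'
#' For one cell type, correlates each gene's expression across cells with
#' the per-cell probability of belonging to that type (from a trained or
#' zero-shot classifier): the Spearman rank correlation is used as the
#' gene's marker score. Because the probability vector can come from a
#' class seen only as text, this works for unseen cell types. Genes with
#' constant expression get score 0.
#'
#' @param expr Cells x genes expression matrix.
#' @param probs Numeric vector, one probability per cell.
#' @param cell_type_id Optional label recorded on the table.
#' @return data.frame (gene_id, score) with attributes `method` and
#'   `cell_type_id`.
#' @export
marker_by_correlation <- function(expr, probs, cell_type_id = NA_character_) {
  stopifnot(is.matrix(expr), nrow(expr) == length(probs))
  if (nrow(expr) < 3L) stop("need at least 3 cells")
  rp <- rank(probs)
  scores <- apply(expr, 2, function(gv) {
    if (stats::sd(gv) == 0) return(0)
    stats::cor(rank(gv), rp)
  })
  out <- data.frame(gene_id = colnames(expr) %||% as.character(seq_len(ncol(expr))),
                    score = unname(scores), stringsAsFactors = FALSE)
  attr(out, "method") <- "spearman"
  attr(out, "cell_type_id") <- cell_type_id
  out
}

#' Marker genes from embeddings alone
#'
#' Scores candidate genes for a cell type without any expression data: the
#' probability of gene g being a marker of the type with text embedding
#' `Y_CL` is the logistic of the bilinear form `F_gene' W Y_CL`, the same
#' functional form as the zero-shot class score, with `W` taken from a
#' trained gene-to-text model. The cell type may be absent from any
#' ontology; only its free-text description is needed.
#'
#' @param F_gene Gene feature vector, or genes x dim matrix.
#' @param W Bilinear weights of a trained gene-to-text model.
#' @param Y_CL Text embedding of the cell type description.
#' @param cell_type_id Optional label.
#' @return Probability vector, or a marker table as in
#'   [marker_by_correlation()] when `F_gene` is a matrix.
#' @export
marker_by_embedding <- function(F_gene, W, Y_CL, cell_type_id = NA_character_) {
  p <- bilinear_score(F_gene, W, Y_CL)
  if (!is.matrix(F_gene)) return(drop(p))
  out <- data.frame(gene_id = rownames(F_gene) %||%
                      as.character(seq_len(nrow(F_gene))),
                    score = drop(p), stringsAsFactors = FALSE)
  attr(out, "method") <- "embedding"
  attr(out, "cell_type_id") <- cell_type_id
  out
}

#' AUROC of marker recovery
#'
#' @param scores A marker table from [marker_by_correlation()] /
#'   [marker_by_embedding()], or a numeric score vector.
#' @param truth Binary vector: 1 for known markers.
#' @export
marker_auroc <- function(scores, truth) {
  s <- if (is.data.frame(scores)) scores$score else scores
  auroc(s, truth)
}

#' Build the cell-type--gene similarity network
#'
#' Nodes are cell types and genes with text-space embeddings; an undirected
#' edge connects two nodes whose embedding cosine similarity reaches the
#' threshold. Communities are found by seeded modularity (Louvain)
#' optimization.
#'
#' @param embeddings Nodes x dim matrix with row-name ids.
#' @param node_types Character vector (`"cell_type"`/`"gene"`) per node.
#' @param similarity_threshold Cosine threshold for drawing an edge.
#' @param seed Seed for the community detection.
#' @return A `type_gene_network`: igraph `graph`, `nodes` table, `edges`
#'   table, `membership` community partition.
#' @export
build_network <- function(embeddings, node_types = NULL,
                          similarity_threshold = 0.9, seed = 1L) {
  stopifnot(is.matrix(embeddings), nrow(embeddings) >= 2)
  ids <- rownames(embeddings) %||% as.character(seq_len(nrow(embeddings)))
  node_types <- node_types %||% rep("gene", length(ids))
  Zn <- l2_normalize(embeddings)
  S <- Zn %*% t(Zn)
  idx <- which(upper.tri(S) & S >= similarity_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) warning("similarity threshold yields an empty edge set")
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = S[idx], stringsAsFactors = FALSE)
  gr <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, type = node_types))
  memb <- with_seed(seed, igraph::membership(igraph::cluster_louvain(gr)))
  structure(list(graph = gr,
                 nodes = data.frame(id = ids, type = node_types,
                                    community = as.integer(memb[ids]),
                                    stringsAsFactors = FALSE),
                 edges = edges, membership = memb),
            class = "type_gene_network")
}

#' @export
print.type_gene_network <- function(x, ...) {
  cat(sprintf("type_gene_network: %d nodes, %d edges, %d communities\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$community))))
  invisible(x)
}

#' Shortest-path distance between two network nodes
#'
#' @param network A `type_gene_network`.
#' @param a,b Node ids.
#' @export
network_path_distance <- function(network, a, b) {
  d <- igraph::distances(network$graph, v = a, to = b)[1, 1]
  if (is.infinite(d)) NA_integer_ else as.integer(d)
}

#' Export a network for external visualization
#'
#' Writes the edge list as TSV and, optionally, GraphML.
#'
#' @param network A `type_gene_network`.
#' @param path Edge-list TSV path.
#' @param graphml Optional GraphML path.
#' @export
write_network_edges <- function(network, path, graphml = NULL) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) igraph::write_graph(network$graph, graphml,
                                             format = "graphml")
  invisible(path)
}

#' Annotate a network community with its nearest valid GO term
#'
#' The community embedding is the mean of its member embeddings; the
#' returned term is the GO term with the highest cosine similarity to it
#' whose annotated-gene count lies in the size window (default 100-2500
#' genes). If the most similar term fails the window, a breadth-first
#' search over its ancestors and descendants in the ontology returns the
#' nearest valid term (nearer level preferred, ties broken by id).
#'
#' @param member_embeddings Matrix of community-member embeddings.
#' @param go_embeddings Terms x dim matrix of GO text embeddings with
#'   row-name term ids.
#' @param go_counts Named vector of annotated-gene counts per term.
#' @param g The GO [ontology_graph()].
#' @param size_window Allowed annotation-count range.
#' @param relations Relations defining the hierarchy for the search.
#' @return List with `term_id` (NA if no valid term is reachable),
#'   `best_match` (the unconstrained nearest term) and `hops` (BFS level at
#'   which the returned term was found).
#' @export
community_enrichment <- function(member_embeddings, go_embeddings, go_counts,
                                 g, size_window = c(100, 2500),
                                 relations = c("is_a", "part_of")) {
  M <- if (is.matrix(member_embeddings)) member_embeddings else
    matrix(member_embeddings, nrow = 1)
  if (nrow(M) == 0L) stop("empty community")
  ce <- colMeans(M)
  Zn <- l2_normalize(go_embeddings)
  sims <- drop(Zn %*% (ce / sqrt(sum(ce^2))))
  ids <- rownames(go_embeddings)
  best <- ids[order(-sims, ids)][1]
  valid <- function(t) {
    cnt <- go_counts[t]
    !is.na(cnt) && cnt >= size_window[1] && cnt <= size_window[2]
  }
  if (valid(best)) {
    return(list(term_id = best, best_match = best, hops = 0L))
  }
  ig <- og_igraph(g, relations)
  seen <- best
  frontier <- best
  hops <- 0L
  while (length(frontier) > 0L) {
    hops <- hops + 1L
    nxt <- unique(unlist(lapply(frontier, function(t) {
      igraph::neighbors(ig, t, mode = "all")$name
    })))
    nxt <- sort(setdiff(nxt, seen))
    ok <- nxt[vapply(nxt, valid, TRUE)]
    if (length(ok) > 0L) {
      return(list(term_id = ok[1], best_match = best, hops = hops))
    }
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  list(term_id = NA_character_, best_match = best, hops = NA_integer_)
}
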