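ngram_counts <- function(toks, n) {
  if (length(toks) < n) return(table(character(0)))
  grams <- vapply(seq_len(length(toks) - n + 1L), function(i) {
    paste(toks[i:(i + n - 1L)], collapse = "\x1f")
  }, "")
  table(grams)
}

#' BLEU similarity between two texts
#'
#' Text-based similarity of class descriptions: the geometric mean of the
#' modified 1- to 4-gram precisions of `a` against `b`, with the standard
#' brevity penalty; ranges over 0-1 and equals 1 when the texts are
#' identical. For candidates shorter than 4 tokens only the attainable
#' n-gram orders enter the geometric mean (so identical short texts still
#' score 1). BLEU is directional; `symmetric = TRUE` averages both
#' directions. Unsmoothed BLEU is 0 whenever one n-gram order has no
#' matches; `smooth = TRUE` applies add-one smoothing, useful for very
#' short definitions.
#'
#' @param a Candidate text.
#' @param b Reference text.
#' @param max_n Highest n-gram order (default 4).
#' @param smooth Add-one smoothing of the n-gram precisions.
#' @param symmetric Average of both directions.
#' @export
bleu_similarity <- function(a, b, max_n = 4L, smooth = FALSE,
                            symmetric = FALSE) {
  if (symmetric) {
    return((bleu_similarity(a, b, max_n, smooth) +
              bleu_similarity(b, a, max_n, smooth)) / 2)
  }
  ta <- tokenize_text(a); tb <- tokenize_text(b)
  if (length(ta) == 0L || length(tb) == 0L) stop("empty text")
  orders <- seq_len(min(max_n, length(ta)))
  logp <- numeric(length(orders))
  for (n in orders) {
    ca <- ngram_counts(ta, n); cb <- ngram_counts(tb, n)
    total <- sum(ca)
    shared <- intersect(names(ca), names(cb))
    clipped <- sum(pmin(ca[shared], cb[shared]))
    p <- if (smooth) (clipped + 1) / (total + 1) else clipped / total
    if (p == 0) return(0)
    logp[n] <- log(p)
  }
  bp <- if (length(ta) < length(tb)) exp(1 - length(tb) / length(ta)) else 1
  bp * exp(mean(logp))
}

#' Graph distance between two ontology terms
#'
#' Shortest-path length between two terms, treating is_a/part_of edges as
#' undirected; 0 for a term with itself, `NA` when unreachable.
#'
#' @param a,b Term ids.
#' @param g An [ontology_graph()].
#' @param relations Edge relations included.
#' @export
graph_distance <- function(a, b, g, relations = c("is_a", "part_of")) {
  ig <- og_igraph(g, relations, directed = FALSE)
  nm <- igraph::V(ig)$name
  if (!(a %in% nm)) stop("unknown term id: ", a)
  if (!(b %in% nm)) stop("unknown term id: ", b)
  d <- igraph::distances(ig, v = a, to = b)[1, 1]
  if (is.infinite(d)) NA_integer_ else as.integer(d)
}

#' Annotation-based similarity between two terms
#'
#' Cosine similarity of the two terms' binary annotation vectors over
#' instances, where a component is 1 when the instance is annotated to the
#' term or to any of its descendants (i.e. the true-path-propagated
#' matrix); pass a propagated [annotation_matrix()].
#'
#' @param a,b Term ids with at least one annotation each.
#' @param ann A propagated [annotation_matrix()].
#' @export
annotation_cosine <- function(a, b, ann) {
  stopifnot(inherits(ann, "annotation_matrix"))
  if (!all(c(a, b) %in% ann$term_ids)) stop("unknown term id")
  va <- ann$A[, a]; vb <- ann$A[, b]
  if (sum(va) == 0 || sum(vb) == 0) {
    stop("annotation similarity undefined for a term with no annotations")
  }
  sum(va * vb) / sqrt(sum(va) * sum(vb))
}

#' Jaccard similarity between two gene sets
#'
#' @param s1,s2 Non-empty character vectors of gene ids.
#' @export
jaccard_gene_sets <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0L || length(s2) == 0L) stop("empty gene set")
  length(intersect(s1, s2)) / length(union(s1, s2))
}

#' Nearest gene sets by Jaccard similarity
#'
#' Retrieves the k corpus gene sets most similar to the query (default
#' k = 5), ties broken by id.
#'
#' @param query Character vector of gene ids.
#' @param corpus Named list of gene sets.
#' @param k Number of sets to return.
#' @return data.frame (set_id, jaccard) ordered best-first.
#' @export
nearest_gene_sets <- function(query, corpus, k = 5L) {
  stopifnot(length(corpus) >= 1, !is.null(names(corpus)))
  if (k > length(corpus)) {
    warning("k exceeds corpus size; returning all sets")
    k <- length(corpus)
  }
  j <- vapply(corpus, function(s) jaccard_gene_sets(query, s), 0)
  ord <- order(-j, names(corpus))[seq_len(k)]
  data.frame(set_id = names(corpus)[ord], jaccard = unname(j[ord]),
             stringsAsFactors = FALSE)
}

#' Binned one-way ANOVA association between two similarity measures
#'
#' Groups the response `y` by which bin of `bin_edges` the matched value of
#' `x` falls into (default bins 0-0.2, 0.2-0.4, 0.4-0.6, 0.6-0.8, >0.8),
#' drops empty bins, and tests whether the group means of `y` differ with a
#' one-way ANOVA. Used to test whether, e.g., terms with more similar
#' annotations also have more similar textual descriptions.
#'
#' @param x Grouping similarity values.
#' @param y Response similarity values (same length).
#' @param bin_edges Increasing bin edges; the last bin is open-ended.
#' @return List with `F`, `p`, `df`, and the per-bin counts.
#' @export
binned_association_test <- function(x, y,
                                    bin_edges = c(0, 0.2, 0.4, 0.6, 0.8, Inf)) {
  stopifnot(length(x) == length(y))
  grp <- cut(x, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  keep <- !is.na(grp) & !is.na(y)
  if (!any(keep)) stop("bin edges exclude all data")
  grp <- droplevels(grp[keep]); yv <- y[keep]
  if (nlevels(grp) < 2L) stop("all values fall in one bin")
  fit <- stats::aov(yv ~ grp)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]), counts = table(grp))
}

#' Pairwise similarity table over ontology terms
#'
#' For every (sampled) unordered pair of terms computes the symmetrized
#' BLEU text similarity of their descriptions, their undirected graph
#' distance, and (when a propagated annotation matrix is given) their
#' annotation cosine.
#'
#' @param g An [ontology_graph()].
#' @param ann Optional propagated [annotation_matrix()].
#' @param ids Term ids (default: all non-obsolete).
#' @param max_pairs Subsample at most this many pairs (seeded).
#' @param seed Seed for the pair subsample.
#' @param smooth Passed to [bleu_similarity()].
#' @return data.frame (id_a, id_b, text_sim, graph_dist, annotation_sim).
#' @export
similarity_table <- function(g, ann = NULL, ids = NULL, max_pairs = Inf,
                             seed = 1L, smooth = TRUE) {
  ids <- ids %||% active_terms(g)
  desc <- term_description(g, ids)
  prs <- utils::combn(ids, 2)
  if (ncol(prs) > max_pairs) {
    prs <- prs[, with_seed(seed, sample.int(ncol(prs), max_pairs)), drop = FALSE]
  }
  ig <- og_igraph(g, directed = FALSE)
  D <- igraph::distances(ig)
  out <- data.frame(id_a = prs[1, ], id_b = prs[2, ], stringsAsFactors = FALSE)
  out$text_sim <- mapply(function(a, b) {
    bleu_similarity(desc[a], desc[b], smooth = smooth, symmetric = TRUE)
  }, out$id_a, out$id_b)
  out$graph_dist <- mapply(function(a, b) {
    d <- D[a, b]; if (is.infinite(d)) NA_integer_ else as.integer(d)
  }, out$id_a, out$id_b)
  if (!is.null(ann)) {
    out$annotation_sim <- mapply(function(a, b) {
      if (sum(ann$A[, a]) == 0 || sum(ann$A[, b]) == 0) return(NA_real_)
      annotation_cosine(a, b, ann)
    }, out$id_a, out$id_b)
  }
  out
}
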