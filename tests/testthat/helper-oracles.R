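# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# all ancestors of `id` by repeated edge-list scanning
bf_ancestors <- function(edges, id) {
  anc <- character(0)
  frontier <- id
  repeat {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, c(anc, id))
    if (length(nxt) == 0) break
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  anc
}

# AUROC by explicit pair counting with half-credit ties
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# naive directional BLEU, written independently (string-paste n-grams,
# loop-based clipping, explicit log-sum)
bf_bleu <- function(a, b, max_n = 4) {
  tok <- function(x) {
    x <- tolower(gsub("[^a-z0-9 ]+", " ", x))
    strsplit(trimws(x), "\\s+")[[1]]
  }
  ta <- tok(a); tb <- tok(b)
  logs <- c()
  for (n in seq_len(min(max_n, length(ta)))) {
    ga <- sapply(seq_len(length(ta) - n + 1), function(i) paste(ta[i:(i + n - 1)], collapse = "|"))
    gb <- if (length(tb) >= n) {
      sapply(seq_len(length(tb) - n + 1), function(i) paste(tb[i:(i + n - 1)], collapse = "|"))
    } else character(0)
    hits <- 0
    remaining <- gb
    for (g in ga) {
      j <- match(g, remaining)
      if (!is.na(j)) { hits <- hits + 1; remaining <- remaining[-j] }
    }
    p <- hits / length(ga)
    if (p == 0) return(0)
    logs <- c(logs, log(p))
  }
  bp <- if (length(ta) < length(tb)) exp(1 - length(tb) / length(ta)) else 1
  bp * exp(mean(logs))
}

# a small fixed ontology: root A; B,C children of A; D child of B and C
diamond_graph <- function() {
  ontology_graph(
    data.frame(id = c("A", "B", "C", "D"),
               name = paste("term", c("A", "B", "C", "D")),
               definition = c("the root term", "left branch term",
                              "right branch term", "the sink term"),
               obsolete = FALSE),
    data.frame(child = c("B", "C", "D", "D"),
               parent = c("A", "A", "B", "C"),
               relation = c("is_a", "is_a", "is_a", "part_of")))
}

# random DAG on n nodes: edges only from higher to lower index
random_dag_graph <- function(n, p_edge = 0.08, seed = 1) {
  withr::with_seed(seed, {
    terms <- data.frame(id = sprintf("N%03d", seq_len(n)),
                        name = sprintf("node %d", seq_len(n)),
                        definition = "", obsolete = FALSE)
    edges <- NULL
    for (i in 2:n) {
      parents <- which(stats::runif(i - 1) < p_edge)
      if (length(parents) == 0) parents <- sample.int(i - 1, 1)
      edges <- rbind(edges, data.frame(
        child = terms$id[i], parent = terms$id[parents],
        relation = sample(c("is_a", "part_of"), length(parents), TRUE)))
    }
    ontology_graph(terms, edges)
  })
}
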