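test_that("BLEU is 1 for identical texts and 0 for disjoint ones", {
  expect_equal(bleu_similarity("the cell cycle process", "the cell cycle process"), 1)
  expect_equal(bleu_similarity("one", "one"), 1)  # shorter than 4 tokens
  expect_equal(bleu_similarity("alpha beta gamma delta", "zeta eta theta iota"), 0)
  expect_error(bleu_similarity("", "x"), "empty")
})

test_that("BLEU matches an independent reference implementation", {
  set.seed(33)
  vocab <- c("cell", "type", "immune", "process", "regulation", "of",
             "signal", "membrane", "protein", "binding", "activity", "the")
  for (r in 1:20) {
    a <- paste(sample(vocab, sample(5:12, 1), replace = TRUE), collapse = " ")
    b <- paste(sample(vocab, sample(5:12, 1), replace = TRUE), collapse = " ")
    expect_equal(bleu_similarity(a, b), bf_bleu(a, b), tolerance = 1e-9)
  }
  # brevity penalty: a short candidate is penalized against a long reference
  long <- "a b c d e f g h"
  short <- "a b c d"
  expect_equal(bleu_similarity(short, long),
               exp(1 - 8 / 4) * bf_bleu(short, substr(long, 1, 7)),
               tolerance = 1e-9)
  # smoothing keeps partially matching short texts away from hard zero
  expect_gt(bleu_similarity("cell type alpha", "cell type beta", smooth = TRUE), 0)
  # symmetric mode averages the two directions
  expect_equal(bleu_similarity(short, long, symmetric = TRUE),
               (bleu_similarity(short, long) + bleu_similarity(long, short)) / 2)
})

test_that("graph distances are undirected shortest paths with NA when unreachable", {
  dg <- diamond_graph()
  expect_equal(graph_distance("A", "A", dg), 0L)
  expect_equal(graph_distance("B", "A", dg), 1L)
  expect_equal(graph_distance("B", "C", dg), 2L)  # across the diamond
  expect_equal(graph_distance("A", "D", dg), 2L)
  expect_error(graph_distance("A", "nope", dg), "unknown term")
  two <- ontology_graph(data.frame(id = c("x", "y"), name = c("x", "y")))
  expect_true(is.na(graph_distance("x", "y", two)))
})

test_that("graph distance matches a BFS oracle and the triangle inequality", {
  g <- random_dag_graph(25, seed = 6)
  ig_o <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = g$terms$id)
  D <- igraph::distances(ig_o)
  ids <- withr::with_seed(8, replicate(15, sample(g$terms$id, 3)))
  for (k in seq_len(ncol(ids))) {
    a <- ids[1, k]; b <- ids[2, k]; c <- ids[3, k]
    dab <- graph_distance(a, b, g)
    expect_equal(dab, as.integer(D[a, b]))
    dac <- graph_distance(a, c, g); dcb <- graph_distance(c, b, g)
    if (!anyNA(c(dab, dac, dcb))) expect_lte(dab, dac + dcb)
  }
})

test_that("annotation cosine follows the closed form on binary supports", {
  A <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0,
                1, 0, 1, 0,
                0, 0, 0, 1), 4, 4,
              dimnames = list(paste0("i", 1:4), c("t1", "t2", "t3", "t4")))
  ann <- annotation_matrix(A = A, propagated = TRUE)
  expect_equal(annotation_cosine("t1", "t2", ann), 1)        # identical
  expect_equal(annotation_cosine("t2", "t4", ann), 0)        # disjoint
  expect_equal(annotation_cosine("t2", "t3", ann), 0.5)      # 1/sqrt(2*2)
  ann$A[, "t4"] <- 0
  expect_error(annotation_cosine("t1", "t4", ann), "no annotations")
})

test_that("Jaccard and nearest-gene-set retrieval behave on closed-form cases", {
  expect_equal(jaccard_gene_sets(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_gene_sets(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_gene_sets(c("a", "b"), c("b", "c")), 1 / 3)
  expect_error(jaccard_gene_sets(character(0), "a"), "empty")
  corpus <- list(s1 = c("a", "b", "c"), s2 = c("a", "b"), s3 = c("x", "y"),
                 s4 = c("a"), s5 = c("b", "c"), s6 = c("z"))
  got <- nearest_gene_sets(c("a", "b"), corpus)  # default k = 5
  expect_equal(nrow(got), 5)
  expect_equal(got$set_id[1], "s2")
  # k = 1 equals an argmax oracle
  j <- sapply(corpus, function(s) jaccard_gene_sets(c("a", "b"), s))
  expect_equal(nearest_gene_sets(c("a", "b"), corpus, k = 1)$set_id,
               names(corpus)[order(-j, names(corpus))][1])
  expect_warning(all6 <- nearest_gene_sets(c("a"), corpus, k = 10), "corpus size")
  expect_equal(nrow(all6), 6)
  # all-disjoint corpus: deterministic id order
  dis <- list(p2 = "q", p1 = "r")
  expect_equal(nearest_gene_sets(c("a"), dis, k = 2)$set_id, c("p1", "p2"))
})

test_that("the binned ANOVA matches its formula and degenerates correctly", {
  # identical group distributions: F = 0, p = 1
  x <- c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5)
  y <- c(1, 2, 3, 1, 2, 3)
  r <- binned_association_test(x, y)
  expect_equal(r$F, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  # two separated groups against the hand-computed between/within ratio
  x2 <- c(rep(0.1, 4), rep(0.9, 4))
  y2 <- c(1, 2, 1.5, 1.5, 5, 6, 5.5, 5.5)
  r2 <- binned_association_test(x2, y2)
  grand <- mean(y2); m1 <- mean(y2[1:4]); m2 <- mean(y2[5:8])
  ssb <- 4 * (m1 - grand)^2 + 4 * (m2 - grand)^2
  ssw <- sum((y2[1:4] - m1)^2) + sum((y2[5:8] - m2)^2)
  expect_equal(r2$F, (ssb / 1) / (ssw / 6), tolerance = 1e-10)
  expect_error(binned_association_test(rep(0.1, 5), rnorm(5)), "one bin")
  expect_error(binned_association_test(rep(-3, 5), rnorm(5)), "exclude")
})

test_that("similarity tables pair text, graph and annotation measures", {
  g <- generate_ontology(fixture_spec(n_terms = 12L), seed = 5)
  enc <- hashing_encoder(32, seed = 1)
  inst <- generate_instances(g, enc, fixture_spec(n_terms = 12L,
                                                  n_instances = 4L), seed = 5)
  tab <- similarity_table(g, inst$annotations, max_pairs = 30, seed = 2)
  expect_lte(nrow(tab), 30)
  expect_true(all(tab$text_sim >= 0 & tab$text_sim <= 1))
  expect_true(all(tab$graph_dist >= 1, na.rm = TRUE))
  expect_true(all(tab$annotation_sim >= 0 & tab$annotation_sim <= 1,
                  na.rm = TRUE))
})
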