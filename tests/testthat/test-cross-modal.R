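# hand-built translators with identity encoders for the score identities
mk_translator <- function(W, modality = "m") {
  structure(list(modality = modality, blocks = NULL, W = W,
                 d_bio = ncol(W), hidden = NULL,
                 center = numeric(nrow(W))),
            class = "modality_translator")
}

test_that("the cross-modal score is the logistic dot product of projections", {
  set.seed(13)
  Wg <- matrix(rnorm(4 * 5), 4, 5)
  Wd <- matrix(rnorm(3 * 5), 3, 5)
  tg <- mk_translator(Wg, "gene"); td <- mk_translator(Wd, "drug")
  fg <- rnorm(4); fd <- rnorm(3)
  # explicit loop oracle for F_g' W_g W_d' F_d
  z <- 0
  for (i in 1:4) for (k in 1:5) for (j in 1:3) {
    z <- z + fg[i] * Wg[i, k] * Wd[j, k] * fd[j]
  }
  expect_equal(cross_modal_score(tg, fg, td, fd), 1 / (1 + exp(-z)),
               tolerance = 1e-10)
  # symmetric in argument order
  expect_equal(cross_modal_score(tg, fg, td, fd),
               cross_modal_score(td, fd, tg, fg), tolerance = 1e-12)
  # a zero text-space projection gives one half
  expect_equal(cross_modal_score(mk_translator(matrix(0, 4, 5)), fg, td, fd), 0.5)
  expect_error(cross_modal_score(tg, fg, mk_translator(matrix(0, 3, 4)), fd),
               "d_bio")
})

test_that("pathway embeddings sum member genes and ignore their order", {
  g1 <- c(1, 2, 3); g2 <- c(0.5, -1, 4)
  expect_equal(pathway_embedding(matrix(g1, 1)), g1)
  expect_equal(pathway_embedding(rbind(g1, g2)), g1 + g2)
  set.seed(2)
  M <- matrix(rnorm(30), 10)
  expect_equal(pathway_embedding(M), pathway_embedding(M[sample(10), ]))
  # oracle: loop accumulation
  acc <- numeric(3)
  for (i in 1:10) acc <- acc + M[i, ]
  expect_equal(pathway_embedding(M), acc)
  expect_error(pathway_embedding(M[0, , drop = FALSE]), "empty")
})

test_that("diffusion node features separate components and respect symmetry", {
  # two disconnected cliques of different sizes (identical components would
  # have degenerate spectra, leaving the factorization free to mix them)
  cl <- function(ids) as.data.frame(t(combn(ids, 2)))
  edges <- rbind(cl(paste0("a", 1:5)), cl(paste0("b", 1:4)))
  X <- graph_node_features(edges, dim = 6)
  cosm <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ca <- paste0("a", 1:5); cb <- paste0("b", 1:4)
  within <- c(combn(ca, 2, function(p) cosm(X[p[1], ], X[p[2], ])),
              combn(cb, 2, function(p) cosm(X[p[1], ], X[p[2], ])))
  across <- as.vector(outer(ca, cb,
                            Vectorize(function(i, j) cosm(X[i, ], X[j, ]))))
  expect_gt(min(within), max(across))
  # a relabelled isomorphic graph embeds identically up to the permutation
  g0 <- random_dag_graph(12, seed = 41)$edges[, 1:2]
  X1 <- graph_node_features(g0, dim = 3)
  relab <- setNames(sprintf("m%02d", seq_along(unique(unlist(g0)))),
                    unique(unlist(g0)))
  g1 <- data.frame(child = relab[g0$child], parent = relab[g0$parent])
  X2 <- graph_node_features(g1, dim = 3)
  expect_equal(abs(X2[relab[rownames(X1)], ]), abs(X1), tolerance = 1e-8,
               ignore_attr = TRUE)
  # star: the hub is distinguishable from the leaves at dim 1
  star <- data.frame(from = "hub", to = paste0("leaf", 1:4))
  Xs <- graph_node_features(star, dim = 1)
  expect_gt(abs(Xs["hub", 1]), max(abs(Xs[paste0("leaf", 1:4), 1])))
  expect_error(graph_node_features(star, dim = 5), "smaller")
})

test_that("candidate ranking is score-descending with id tie-breaks", {
  q <- c(1, 0)
  cand <- rbind(hit = c(2, 0), mid = c(1, 0), far = c(-1, 0), tie = c(1, 0))
  r <- rank_candidates(q, cand)
  expect_equal(r$candidate_id[1], "hit")
  expect_equal(r$rank, 1:4)
  # ties broken by id: "mid" < "tie"
  expect_lt(which(r$candidate_id == "mid"), which(r$candidate_id == "tie"))
  # reversed scores reverse the order
  r2 <- rank_candidates(-q, cand[c("hit", "far"), ])
  expect_equal(r2$candidate_id, c("far", "hit"))
  # full-sort oracle
  set.seed(5)
  cand3 <- matrix(rnorm(20), 10)
  rownames(cand3) <- sprintf("c%02d", 1:10)
  p <- drop(1 / (1 + exp(-cand3 %*% c(0.3, -1))))
  r3 <- rank_candidates(c(0.3, -1), cand3)
  expect_equal(r3$candidate_id, rownames(cand3)[order(-p, rownames(cand3))])
})

test_that("translator training fits its corpus and keeps the text dimension", {
  px <- generate_paired_modalities(fixture_spec(n_latent = 60L), seed = 2)
  enc <- hashing_encoder(64, seed = 1)
  cfg0 <- train_config(0.1, 128, 0L, seed = 2, init_sd = 1e-4, adam_eps = 1e-2)
  t0 <- train_translator(px$corpus_a$features, px$corpus_a$descriptions, enc, cfg0)
  expect_equal(ncol(translate_features(t0, px$corpus_a$features)), 64)
  expect_length(t0$loss_history, 0)
  cfg <- train_config(0.1, 128, 30L, seed = 2, weight_decay = 1e-3,
                      init_sd = 1e-4, adam_eps = 1e-2)
  t1 <- train_translator(px$corpus_a$features, px$corpus_a$descriptions, enc, cfg)
  expect_lt(tail(t1$loss_history, 1), t1$loss_history[1])
  dup <- px$corpus_a$features[c(1, 1), ]
  expect_error(train_translator(dup, rep("x y", 2), enc, cfg), "duplicate")
})

test_that("prediction tables are written query-major with ranks", {
  set.seed(3)
  tg <- mk_translator(matrix(rnorm(8), 2, 4), "g")
  td <- mk_translator(matrix(rnorm(8), 2, 4), "d")
  Fa <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), NULL))
  Fb <- matrix(rnorm(4), 2, 2, dimnames = list(paste0("d", 1:2), NULL))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cross_modal_predictions(tg, Fa, td, Fb, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$rank[tab$query_id == "g1"], 1:2)
  expect_true(all(diff(tab$probability[tab$query_id == "g2"]) <= 0))
})
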