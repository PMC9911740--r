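# End-to-end evaluation protocols on the synthetic fixtures. Each protocol
# is a pure function of (spec, seed) and returns the measured quantity, so
# the same code path serves the test suite and the acceptance script.

default_bench_config <- function(seed, epochs = 200L) {
  # Classifier-protocol settings at the fixture scale (small dense models,
  # a few hundred instances): the 1e-4 / 15-30-epoch defaults of
  # train_config() target full-size encoders and much larger corpora.
  train_config(learning_rate = 1e-2, batch_size = 128L, epochs = epochs,
               seed = seed, init_sd = 1)
}

translator_bench_config <- function(seed, epochs = 200L) {
  # Translator-protocol settings: items-as-classes training transfers
  # through the direction of W, so the initialization is kept negligibly
  # small, Adam updates proportional to the gradient (large eps), and a
  # light ridge keeps the solution away from per-item memorization.
  train_config(learning_rate = 0.1, batch_size = 128L, epochs = epochs,
               seed = seed, weight_decay = 1e-3, init_sd = 1e-4,
               adam_eps = 1e-2)
}

#' Zero-shot recovery of held-out leaf classes on the synthetic fixture
#'
#' Generates an ontology and text-aligned instances, holds out `n_unseen`
#' annotated leaf classes together with every instance annotated to them,
#' trains the bi-nonlinear classifier on the remaining (seen) classes, and
#' scores the held-out instances against the unseen classes from their
#' descriptions alone. Returns the mean one-vs-rest AUROC over unseen
#' classes.
#'
#' @param spec A [fixture_spec()].
#' @param seed Seed for generation, splitting and training.
#' @param n_unseen Number of held-out leaf classes.
#' @param cfg Training configuration.
#' @return List: `auroc` (mean over unseen classes), `per_class`,
#'   `n_train`, `n_test`.
#' @export
benchmark_zero_shot <- function(spec = fixture_spec(), seed = 1L,
                                n_unseen = 20L,
                                cfg = default_bench_config(seed)) {
  g <- generate_ontology(spec, seed)
  enc <- hashing_encoder(spec$d_bio, seed = 1L)
  inst <- generate_instances(g, enc, spec, seed + 1000L)
  ann <- inst$annotations
  leaves <- sort(intersect(leaf_terms(g), ann$term_ids[colSums(ann$A) > 0]))
  if (length(leaves) <= n_unseen) stop("fixture has too few annotated leaves")
  unseen <- with_seed(seed, sort(sample(leaves, n_unseen)))
  held_out <- rowSums(ann$A[, unseen, drop = FALSE]) > 0
  train_ids <- ann$instance_ids[!held_out]
  test_ids <- ann$instance_ids[held_out]

  train_ann <- annotation_matrix(A = ann$A[train_ids, , drop = FALSE],
                                 instance_ids = train_ids,
                                 term_ids = ann$term_ids, propagated = TRUE)
  desc <- term_description(g)
  model <- train_zero_shot(inst$features[train_ids, , drop = FALSE],
                           train_ann, desc, enc, cfg)
  scores <- zero_shot_annotate(inst$features[test_ids, , drop = FALSE],
                               desc[unseen], model)
  per_class <- vapply(unseen, function(t) {
    auroc(scores$probabilities[, t], ann$A[test_ids, t])
  }, 0)
  list(auroc = mean(per_class), per_class = per_class,
       n_train = length(train_ids), n_test = length(test_ids))
}

#' Cross-modal retrieval with zero paired training examples
#'
#' Trains one modality-to-text translator per modality on that modality's
#' own (feature, description) corpus, then scores every held-out modality-A
#' item against every held-out modality-B item. True pairs (same latent
#' item) are the positives; the AUROC over all test-pair scores measures
#' transfer through the shared text space without any paired data.
#'
#' @inheritParams benchmark_zero_shot
#' @return List: `auroc`, `n_pairs`.
#' @export
benchmark_cross_modal <- function(spec = fixture_spec(), seed = 1L,
                                  cfg = translator_bench_config(seed)) {
  px <- generate_paired_modalities(spec, seed)
  enc <- hashing_encoder(spec$d_bio, seed = 1L)
  t_a <- train_translator(px$corpus_a$features, px$corpus_a$descriptions,
                          enc, cfg, modality = "a")
  t_b <- train_translator(px$corpus_b$features, px$corpus_b$descriptions,
                          enc, cfg, modality = "b")
  P <- cross_modal_score(t_a, px$test_a, t_b, px$test_b)
  truth <- diag(nrow(P))
  list(auroc = auroc(as.vector(P), as.vector(truth)), n_pairs = nrow(P))
}

#' Recovery of planted marker genes by both marker procedures
#'
#' On the planted-marker expression fixture: (1) trains the expression
#' classifier (hidden dimension 30) on type-labelled cells, takes each
#' type's per-cell probability, and scores genes by Spearman correlation
#' with it; (2) trains a gene-to-text translator on the fixture's gene
#' features/descriptions and scores genes against each type's description
#' embedding through the bilinear form. Returns the mean AUROC of each
#' procedure against the planted marker truth.
#'
#' @inheritParams benchmark_zero_shot
#' @param cfg_translator Training configuration for the gene-to-text
#'   translator behind the embedding-based procedure.
#' @return List: `spearman_auroc`, `embedding_auroc` (means over types).
#' @export
benchmark_markers <- function(spec = fixture_spec(), seed = 1L,
                              cfg = default_bench_config(seed),
                              cfg_translator = translator_bench_config(seed)) {
  ex <- generate_expression(spec, seed)
  enc <- hashing_encoder(spec$d_bio, seed = 1L)
  expr <- normalize_expression(ex$counts)
  types <- colnames(ex$markers)
  ann <- annotation_matrix(
    data.frame(instance_id = rownames(expr), term_id = ex$labels,
               stringsAsFactors = FALSE),
    instance_ids = rownames(expr), term_ids = types)
  model <- train_zero_shot(expr, ann, ex$type_descriptions, enc, cfg,
                           hidden = c(x = 30L))
  probs <- zero_shot_annotate(expr, ex$type_descriptions, model)
  sp <- vapply(types, function(t) {
    tab <- marker_by_correlation(expr, probs$probabilities[, t], t)
    marker_auroc(tab, ex$markers[, t])
  }, 0)

  t_gene <- train_translator(ex$gene_features, ex$gene_descriptions, enc,
                             cfg_translator, modality = "gene")
  Yt <- encode_texts(ex$type_descriptions, enc)
  em <- vapply(seq_along(types), function(k) {
    tab <- marker_by_embedding(ex$gene_features, t_gene$W, Yt[k, ], types[k])
    marker_auroc(tab, ex$markers[, k])
  }, 0)
  list(spearman_auroc = mean(sp), embedding_auroc = mean(em))
}

#' Effect of contrastive fine-tuning on the neighbour cosine gap
#'
#' Initializes a small trainable embedding-bag encoder on a fixture
#' ontology whose neighbouring terms share description tokens, measures
#' the neighbour-vs-random cosine gap, fine-tunes contrastively, and
#' measures the gap again.
#'
#' @param spec A [fixture_spec()] (a 30-term ontology by default).
#' @param seed Seed.
#' @param cfg An [encoder_config()]; the default uses a learning rate of
#'   1e-3, matching the embedding-bag scale.
#' @return List: `gap_before`, `gap_after`, `loss_history`.
#' @export
benchmark_contrastive <- function(spec = fixture_spec(n_terms = 30L),
                                  seed = 1L,
                                  cfg = encoder_config(d_bio = 64L,
                                                       learning_rate = 1e-3,
                                                       batch_size = 8L,
                                                       epochs = 5L,
                                                       seed = seed)) {
  g <- generate_ontology(spec, seed)
  desc <- term_description(g)
  enc0 <- embedding_bag_encoder(desc, d_bio = cfg$d_bio, seed = seed)
  gap0 <- neighbor_cosine_gap(enc0, g, seed = seed)
  pairs <- build_neighbor_pairs(g, seed)
  enc1 <- contrastive_finetune(enc0, pairs, cfg)
  gap1 <- neighbor_cosine_gap(enc1, g, seed = seed)
  list(gap_before = gap0, gap_after = gap1,
       loss_history = attr(enc1, "loss_history"))
}

#' Calibration of the binned similarity association test
#'
#' On a fixture ontology, computes the pairwise annotation-based and
#' text-based similarities, runs the binned ANOVA of text similarity
#' grouped by annotation-similarity bin, and estimates the test's type-I
#' error rate by permuting the response `n_perm` times.
#'
#' @inheritParams benchmark_zero_shot
#' @param n_perm Label permutations for the null rate.
#' @param alpha Nominal level for the null rejection rate.
#' @return List: `F`, `p`, `type1_rate`, `n_pairs`.
#' @export
benchmark_association <- function(spec = fixture_spec(), seed = 1L,
                                  n_perm = 200L, alpha = 0.05) {
  g <- generate_ontology(spec, seed)
  enc <- hashing_encoder(spec$d_bio, seed = 1L)
  inst <- generate_instances(g, enc, spec, seed + 1000L)
  tab <- similarity_table(g, inst$annotations, smooth = TRUE)
  keep <- !is.na(tab$annotation_sim)
  x <- tab$annotation_sim[keep]; y <- tab$text_sim[keep]
  obs <- binned_association_test(x, y)
  rejections <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
    binned_association_test(x, sample(y))$p < alpha
  }, TRUE))
  list(F = obs$F, p = obs$p, type1_rate = mean(rejections),
       n_pairs = length(x))
}
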