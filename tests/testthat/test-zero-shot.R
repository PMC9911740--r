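test_that("the bilinear score is the logistic of F'WY", {
  set.seed(7)
  W <- matrix(rnorm(12), 4, 3)
  F_vec <- rnorm(4); Y_vec <- rnorm(3)
  # triple-loop oracle
  z <- 0
  for (i in 1:4) for (j in 1:3) z <- z + F_vec[i] * W[i, j] * Y_vec[j]
  expect_equal(bilinear_score(F_vec, W, Y_vec), 1 / (1 + exp(-z)),
               tolerance = 1e-12)
  # zero feature vector scores exactly one half
  expect_identical(bilinear_score(numeric(4), W, Y_vec), 0.5)
  # monotone in the bilinear form: doubling Y with positive logit raises p
  if (z < 0) Y_vec <- -Y_vec
  expect_gt(bilinear_score(F_vec, W, 2 * Y_vec),
            bilinear_score(F_vec, W, Y_vec))
  expect_error(bilinear_score(numeric(3), W, Y_vec), "mismatch")
})

test_that("the multi-label loss matches closed forms and an elementwise oracle", {
  # one instance, one class, logit 0, A = 1 -> ln 2
  expect_equal(bilinear_loss(matrix(0, 1, 2), matrix(1, 1, 3), matrix(1, 1, 1),
                             matrix(0, 2, 3)),
               log(2), tolerance = 1e-12)
  # saturated correct predictions cost (almost) nothing
  W <- matrix(c(20, 0), 1, 2)
  F1 <- matrix(1, 2, 1)
  Y <- matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE)  # logits +20, -20
  A <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_lt(bilinear_loss(F1, Y, A, W), 1e-6)
  # random case against an independent per-entry binary cross-entropy sum
  set.seed(11)
  Fm <- matrix(rnorm(10 * 4), 10); Ym <- matrix(rnorm(5 * 3), 5)
  Wm <- matrix(rnorm(4 * 3), 4); Am <- matrix(rbinom(50, 1, 0.3), 10)
  oracle <- 0
  for (i in 1:10) for (j in 1:5) {
    z <- drop(Fm[i, ] %*% Wm %*% Ym[j, ])
    p <- 1 / (1 + exp(-z))
    oracle <- oracle - Am[i, j] * log(p) - (1 - Am[i, j]) * log(1 - p)
  }
  expect_equal(bilinear_loss(Fm, Ym, Am, Wm, reduction = "sum"), oracle,
               tolerance = 1e-8)
  expect_equal(bilinear_loss(Fm, Ym, Am, Wm), oracle / 50, tolerance = 1e-8)
  expect_error(bilinear_loss(Fm, Ym, Am * 2, Wm), "binary")
})

test_that("training is seeded, reducible to its initialization, and decreases loss", {
  g <- generate_ontology(fixture_spec(n_terms = 15L), seed = 3)
  enc <- hashing_encoder(32, seed = 1)
  spec <- fixture_spec(n_terms = 15L, n_instances = 8L, feature_dim = 16L,
                       d_bio = 32L)
  inst <- generate_instances(g, enc, spec, seed = 3)
  desc <- term_description(g)
  cfg0 <- train_config(1e-2, 64, 0L, seed = 5)
  m0 <- train_zero_shot(inst$features, inst$annotations, desc, enc, cfg0)
  m0b <- train_zero_shot(inst$features, inst$annotations, desc, enc, cfg0)
  expect_identical(m0$W, m0b$W)  # epochs = 0: the seeded initialization
  cfg <- train_config(1e-2, 64, 10L, seed = 5)
  m1 <- train_zero_shot(inst$features, inst$annotations, desc, enc, cfg)
  m1b <- train_zero_shot(inst$features, inst$annotations, desc, enc, cfg)
  expect_identical(m1$W, m1b$W)  # bit-identical reruns under one seed
  A <- inst$annotations$A[, m1$term_ids]
  loss_init <- bilinear_loss(inst$features, m0$Y, A, m0$W)
  loss_trained <- bilinear_loss(inst$features, m1$Y, A, m1$W)
  expect_lt(loss_trained, loss_init)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
})

test_that("zero-shot annotation embeds novel text and scores instances", {
  g <- generate_ontology(fixture_spec(n_terms = 15L), seed = 3)
  enc <- hashing_encoder(32, seed = 1)
  spec <- fixture_spec(n_terms = 15L, n_instances = 8L, feature_dim = 16L,
                       d_bio = 32L)
  inst <- generate_instances(g, enc, spec, seed = 3)
  model <- train_zero_shot(inst$features, inst$annotations,
                           term_description(g), enc,
                           train_config(1e-2, 64, 5L, seed = 5))
  sc <- zero_shot_annotate(inst$features[1:4, ],
                           c(n1 = "some novel cell", n2 = "some novel cell"),
                           model)
  expect_equal(dim(sc$probabilities), c(4L, 2L))
  expect_true(all(sc$probabilities > 0 & sc$probabilities < 1))
  # duplicate descriptions give identical score columns
  expect_equal(sc$probabilities[, 1], sc$probabilities[, 2])
  # an all-zero instance is scored one half for every class
  sc0 <- zero_shot_annotate(matrix(0, 1, ncol(inst$features)),
                            c(x = "anything at all"), model)
  expect_equal(unname(drop(sc0$probabilities)), 0.5)
  expect_error(zero_shot_annotate(inst$features[1:2, ], c(""), model),
               "non-empty")
})

test_that("auroc is the Mann-Whitney statistic with half-credit ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.1, 0.2, 0.8), c(1, 1, 0)), 0)
  expect_equal(auroc(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0.5)
  for (s in 1:5) {
    set.seed(s)
    scores <- sample(seq(0, 1, 0.1), 30, replace = TRUE)  # many ties
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), bf_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  set.seed(99)
  expect_equal(auroc(runif(1000), rbinom(1000, 1, 0.5)), 0.5,
               tolerance = 0.05)
  expect_error(auroc(1:3, c(1, 1, 1)), "one class")
})

test_that("model bundles round-trip through the plain-text manifest", {
  g <- generate_ontology(fixture_spec(n_terms = 12L), seed = 2)
  enc <- hashing_encoder(16, seed = 1)
  spec <- fixture_spec(n_terms = 12L, n_instances = 4L, feature_dim = 8L,
                       d_bio = 16L)
  inst <- generate_instances(g, enc, spec, seed = 2)
  model <- train_zero_shot(inst$features, inst$annotations,
                           term_description(g), enc,
                           train_config(1e-2, 64, 3L, seed = 1),
                           hidden = c(x = 6L))
  dir <- withr::local_tempdir()
  save_zero_shot_model(model, dir)
  m2 <- load_zero_shot_model(dir)
  expect_equal(m2$W, unname(model$W), tolerance = 1e-6)
  expect_equal(m2$term_ids, model$term_ids)
  sc1 <- zero_shot_annotate(inst$features, c(n = "novel thing"), model)
  sc2 <- zero_shot_annotate(inst$features, c(n = "novel thing"), m2)
  expect_equal(sc1$probabilities, sc2$probabilities, tolerance = 1e-6)
})
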