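test_that("parse_obo reads stanzas, relations, definitions and obsolete flags", {
  txt <- c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: alpha",
    'def: "The first term." [PMID:1]', "",
    "[Term]", "id: T:2", "name: beta", "is_a: T:1 ! alpha",
    "relationship: part_of T:1", "",
    "[Term]", "id: T:3", "name: gone", "is_obsolete: true", "")
  g <- parse_obo(paste(txt, collapse = "\n"))
  expect_equal(nrow(g$terms), 3)
  expect_equal(sum(g$terms$obsolete), 1)
  expect_setequal(active_terms <- g$terms$id[!g$terms$obsolete], c("T:1", "T:2"))
  expect_equal(nrow(g$edges), 2)
  expect_setequal(g$edges$relation, c("is_a", "part_of"))
  # quotes and dbxref bracket stripped
  expect_equal(g$terms$definition[g$terms$id == "T:1"], "The first term.")
})

test_that("parse errors name the offending line and dangling edges are dropped", {
  bad <- c("[Term]", "id: T:1", "name: x", "garbage line without separator")
  expect_error(parse_obo(paste(bad, collapse = "\n")), "line 4")
  dangling <- c("[Term]", "id: T:1", "name: x", "is_a: T:99")
  expect_warning(g <- parse_obo(paste(dangling, collapse = "\n")), "unknown target")
  expect_equal(nrow(g$edges), 0)
})

test_that("a generated 50-term ontology round-trips through write + parse", {
  g <- generate_ontology(fixture_spec(n_terms = 50L), seed = 7)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(g, path)
  g2 <- parse_obo(path)
  expect_equal(g2$terms[order(g2$terms$id), ],
               g$terms[order(g$terms$id), ], ignore_attr = TRUE)
  key <- function(e) sort(paste(e$child, e$parent, e$relation))
  expect_equal(key(g2$edges), key(g$edges))
  # parse determinism: identical bytes -> identical graph
  expect_identical(parse_obo(path), g2)
})

test_that("term_description joins name and definition per contract", {
  g <- ontology_graph(data.frame(
    id = c("a", "b"), name = c("T cell", "X"),
    definition = c("A lymphocyte of the adaptive immune system.", "")))
  expect_equal(unname(term_description(g, "a")),
               "T cell. A lymphocyte of the adaptive immune system.")
  expect_equal(unname(term_description(g, "b")), "X")
  g$terms$name[1] <- ""
  expect_error(term_description(g, "a"), "empty name")
  toy <- generate_ontology(fixture_spec(n_terms = 5L), seed = 1)
  expect_equal(length(unique(term_description(toy))), 5)
})

test_that("annotation propagation performs the true-path closure", {
  chain <- ontology_graph(
    data.frame(id = c("a", "b", "c"), name = c("a", "b", "c")),
    data.frame(child = c("c", "b"), parent = c("b", "a"),
               relation = "is_a"))
  ann <- annotation_matrix(data.frame(instance_id = "i1", term_id = "c"),
                           term_ids = c("a", "b", "c"))
  prop <- propagate_annotations(ann, chain)
  expect_equal(unname(prop$A["i1", c("a", "b", "c")]), c(1, 1, 1))
  # diamond: annotating the sink reaches all four corners
  dg <- diamond_graph()
  ann2 <- annotation_matrix(data.frame(instance_id = "i1", term_id = "D"),
                            term_ids = c("A", "B", "C", "D"))
  prop2 <- propagate_annotations(ann2, dg)
  expect_equal(sum(prop2$A), 4)
  # idempotence
  expect_equal(propagate_annotations(prop2, dg)$A, prop2$A)
})

test_that("propagation matches a brute-force reachability oracle on random DAGs", {
  for (s in 1:10) {
    g <- random_dag_graph(40, seed = s)
    terms <- g$terms$id
    picks <- withr::with_seed(s, data.frame(
      instance_id = sprintf("i%d", 1:8),
      term_id = sample(terms, 8, replace = TRUE)))
    ann <- annotation_matrix(picks, term_ids = terms)
    prop <- propagate_annotations(ann, g)
    for (r in seq_len(nrow(picks))) {
      expected <- unique(c(picks$term_id[r],
                           bf_ancestors(g$edges, picks$term_id[r])))
      got <- terms[prop$A[picks$instance_id[r], ] == 1]
      expect_true(all(expected %in% got))
    }
    # no spurious positives: every positive is reachable from a direct one
    for (i in unique(picks$instance_id)) {
      direct <- picks$term_id[picks$instance_id == i]
      reach <- unique(c(direct, unlist(lapply(direct, bf_ancestors,
                                              edges = g$edges))))
      expect_setequal(terms[prop$A[i, ] == 1], reach)
    }
  }
})

test_that("propagation refuses cyclic relations", {
  cyc <- ontology_graph(
    data.frame(id = c("a", "b"), name = c("a", "b")),
    data.frame(child = c("a", "b"), parent = c("b", "a"), relation = "is_a"))
  ann <- annotation_matrix(data.frame(instance_id = "i", term_id = "a"),
                           term_ids = c("a", "b"))
  expect_error(propagate_annotations(ann, cyc), "cycle")
})

test_that("leaf_terms agrees with an in-degree scan", {
  chain <- ontology_graph(
    data.frame(id = c("a", "b", "c"), name = c("a", "b", "c")),
    data.frame(child = c("c", "b"), parent = c("b", "a"), relation = "is_a"))
  expect_equal(leaf_terms(chain), "c")
  star <- ontology_graph(
    data.frame(id = c("hub", "x", "y", "z"), name = c("hub", "x", "y", "z")),
    data.frame(child = c("x", "y", "z"), parent = "hub", relation = "is_a"))
  expect_setequal(leaf_terms(star), c("x", "y", "z"))
  g <- random_dag_graph(60, seed = 3)
  scan <- setdiff(g$terms$id, unique(g$edges$parent))
  expect_setequal(leaf_terms(g), scan)
})

test_that("unseen splits have the right size, leak nothing, and are reproducible", {
  g <- generate_ontology(fixture_spec(n_terms = 30L), seed = 2)
  enc <- hashing_encoder(32, seed = 1)
  inst <- generate_instances(g, enc, fixture_spec(n_terms = 30L,
                                                  n_instances = 5L), seed = 2)
  sp <- make_unseen_split(inst$annotations, g, mode = "fraction",
                          fraction = 0.5, seed = 9)
  annotated <- inst$annotations$term_ids[colSums(inst$annotations$A) > 0]
  expect_equal(length(sp$unseen_terms), round(0.5 * length(annotated)))
  # leakage: no training instance carries a positive for any unseen term
  expect_equal(sum(inst$annotations$A[sp$train_instances, sp$unseen_terms]), 0)
  expect_identical(sp, make_unseen_split(inst$annotations, g,
                                         mode = "fraction", fraction = 0.5,
                                         seed = 9))
  # leaf mode: instances annotated only to leaves leave nothing to train on
  expect_error(make_unseen_split(inst$annotations, g, mode = "leaf"),
               "zero training")
  # with some instances annotated to internal terms, leaf mode holds out
  # exactly the annotated leaves and keeps the internal-term instances
  internal <- setdiff(g$terms$id, leaf_terms(g))
  extra <- data.frame(instance_id = sprintf("int%02d", seq_along(internal)),
                      term_id = internal)
  leafy <- data.frame(instance_id = "leafcase",
                      term_id = leaf_terms(g)[1])
  ann2 <- propagate_annotations(
    annotation_matrix(rbind(extra, leafy), term_ids = g$terms$id), g)
  sp_leaf <- make_unseen_split(ann2, g, mode = "leaf")
  expect_setequal(sp_leaf$unseen_terms,
                  intersect(leaf_terms(g), ann2$term_ids[colSums(ann2$A) > 0]))
  expect_false("leafcase" %in% sp_leaf$train_instances)
  expect_true(all(extra$instance_id %in% sp_leaf$train_instances))
})

test_that("split manifests survive a JSON round trip", {
  g <- generate_ontology(fixture_spec(n_terms = 20L), seed = 4)
  enc <- hashing_encoder(32, seed = 1)
  inst <- generate_instances(g, enc, fixture_spec(n_terms = 20L,
                                                  n_instances = 3L), seed = 4)
  sp <- make_unseen_split(inst$annotations, g, mode = "fraction",
                          fraction = 0.3, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(sp, path)
  sp2 <- read_split_manifest(path)
  expect_equal(sp2$unseen_terms, sp$unseen_terms)
  expect_equal(sp2$train_instances, sp$train_instances)
  expect_equal(sp2$seed, sp$seed)
})

test_that("annotation tables read from TSV match their in-memory construction", {
  df <- data.frame(instance_id = c("i1", "i1", "i2"),
                   term_id = c("a", "b", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ann <- read_annotations(path)
  expect_equal(ann$A, annotation_matrix(df)$A)
  expect_error(annotation_matrix(A = matrix(2, 1, 1)), "0/1")
})
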