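#' Synthetic-fixture specification
#'
#' One specification object drives every generator: ontology shape,
#' description vocabulary, per-class instance counts, feature dimensions and
#' noise, expression/marker structure, and the latent-class count for the
#' paired-modality corpus. Defaults are sized so that a full zero-shot
#' train/evaluate cycle runs in well under two minutes on one CPU: 60
#' terms, 30 instances per leaf class, 64-dimensional features.
#'
#' The generators emulate the statistical structure the zero-shot method
#' exploits -- classes annotated to similar instances have similar textual
#' descriptions -- by (a) composing each child term's description partly
#' from contiguous chunks of its parent's description, so neighbouring
#' terms share tokens and n-grams, and (b) drawing instance features as a
#' fixed random linear image of the class text embedding plus Gaussian
#' noise.
#'
#' @param n_terms Ontology size.
#' @param branching Mean number of children per internal term (controls
#'   tree shape via preferential attachment to recent terms).
#' @param vocab_size Description vocabulary size.
#' @param tokens_per_description Tokens per term definition.
#' @param n_instances Instances per leaf class (and cells per type).
#' @param feature_dim Instance feature dimension.
#' @param noise_sd Gaussian feature noise standard deviation (features have
#'   roughly unit scale).
#' @param n_markers Planted marker genes per cell type.
#' @param d_bio Text-embedding dimension used by the fixture encoders. Kept
#'   at the fixture's instance-feature scale (64, not the full-size 768) so
#'   that the several dozen seen classes span the text space -- zero-shot
#'   transfer presupposes unseen class embeddings are expressible through
#'   seen ones.
#' @param n_types Cell types in the expression fixture.
#' @param n_genes Genes in the expression fixture.
#' @param nb_mu,nb_size Negative-binomial background mean and dispersion.
#' @param marker_fold Mean fold-change of a marker in its own type.
#' @param n_latent Latent classes in the paired-modality fixture.
#' @param token_mix Fraction of a child description inherited from its
#'   parent.
#' @param part_of_prob Probability an edge is `part_of` rather than `is_a`.
#' @param seed Base seed recorded in every emitted artifact.
#' @export
fixture_spec <- function(n_terms = 60L, branching = 3L, vocab_size = 200L,
                         tokens_per_description = 12L, n_instances = 30L,
                         feature_dim = 64L, noise_sd = 0.3, n_markers = 10L,
                         d_bio = 64L, n_types = 8L, n_genes = 200L,
                         nb_mu = 2, nb_size = 2, marker_fold = 4,
                         n_latent = 150L, token_mix = 0.5,
                         part_of_prob = 0.1, seed = 1L) {
  spec <- list(n_terms = as.integer(n_terms), branching = as.integer(branching),
               vocab_size = as.integer(vocab_size),
               tokens_per_description = as.integer(tokens_per_description),
               n_instances = as.integer(n_instances),
               feature_dim = as.integer(feature_dim), noise_sd = noise_sd,
               n_markers = as.integer(n_markers), d_bio = as.integer(d_bio),
               n_types = as.integer(n_types), n_genes = as.integer(n_genes),
               nb_mu = nb_mu, nb_size = nb_size, marker_fold = marker_fold,
               n_latent = as.integer(n_latent), token_mix = token_mix,
               part_of_prob = part_of_prob, seed = as.integer(seed))
  stopifnot(all(vapply(spec[c("n_terms", "vocab_size", "n_instances",
                              "feature_dim", "n_types", "n_genes")],
                       function(v) v > 0, TRUE)))
  structure(spec, class = "fixture_spec")
}

fixture_vocab <- function(spec) sprintf("tok%03d", seq_len(spec$vocab_size))

#' Generate a synthetic ontology with token-correlated descriptions
#'
#' Builds a random tree (occasionally a DAG via a second parent) of
#' `n_terms` terms. Each term's definition inherits a contiguous chunk of
#' its parent's definition and fills the rest with fresh vocabulary tokens,
#' so graph neighbours share more description tokens (and n-grams) than
#' random term pairs.
#'
#' @param spec A [fixture_spec()].
#' @param seed Seed (default: the spec's).
#' @return An [ontology_graph()].
#' @export
generate_ontology <- function(spec = fixture_spec(), seed = spec$seed) {
  stopifnot(spec$n_terms >= 3)
  vocab <- fixture_vocab(spec)
  with_seed(seed, {
    n <- spec$n_terms
    ids <- sprintf("FX:%04d", seq_len(n))
    defs <- character(n)
    parent <- rep(NA_integer_, n)
    defs[1] <- paste(sample(vocab, spec$tokens_per_description), collapse = " ")
    edges <- list()
    n_children <- integer(n)
    for (i in 2:n) {
      # fill parents up to the branching factor: ~branching children each,
      # so roughly (branching-1)/branching of the terms end up as leaves
      open <- which(n_children[seq_len(i - 1L)] < spec$branching)
      # fill the oldest open slots first (with a little jitter): yields a
      # near-complete branching-ary tree, ~(branching-1)/branching leaves
      parent[i] <- open[sample.int(min(length(open), spec$branching), 1L)]
      n_children[parent[i]] <- n_children[parent[i]] + 1L
      ptoks <- strsplit(defs[parent[i]], " ")[[1]]
      n_keep <- round(spec$token_mix * spec$tokens_per_description)
      n_keep <- min(n_keep, length(ptoks))
      start <- sample.int(length(ptoks) - n_keep + 1L, 1L)
      kept <- ptoks[start:(start + n_keep - 1L)]
      fresh <- sample(vocab, spec$tokens_per_description - n_keep)
      defs[i] <- paste(c(kept, fresh), collapse = " ")
      rel <- if (stats::runif(1) < spec$part_of_prob) "part_of" else "is_a"
      edges[[length(edges) + 1L]] <- data.frame(
        child = ids[i], parent = ids[parent[i]], relation = rel,
        stringsAsFactors = FALSE)
      if (parent[i] > 1L && stats::runif(1) < 0.1) {
        p2 <- sample.int(parent[i] - 1L, 1L)  # extra parent keeps acyclicity
        edges[[length(edges) + 1L]] <- data.frame(
          child = ids[i], parent = ids[p2], relation = "is_a",
          stringsAsFactors = FALSE)
      }
    }
    g <- ontology_graph(
      data.frame(id = ids, name = paste("class", seq_len(n)),
                 definition = defs, obsolete = FALSE, stringsAsFactors = FALSE),
      do.call(rbind, edges))
    attr(g, "seed") <- as.integer(seed)
    g
  })
}

#' Generate annotated instances whose features mirror class text
#'
#' Every leaf class receives `n_instances` instances; an instance of class
#' t has feature vector `M Y_t + noise`, where `Y_t` is the class
#' description's text embedding under `encoder` and `M` is one fixed random
#' linear map shared by all classes. Annotations are true-path propagated.
#'
#' @param g An [ontology_graph()] from [generate_ontology()].
#' @param encoder A `text_encoder` (the fixture convention is the hashing
#'   encoder at the spec's `d_bio`).
#' @param spec A [fixture_spec()].
#' @param seed Seed.
#' @return List: `features` (instances x feature_dim), `annotations`
#'   (propagated), `direct` (leaf-level annotations), `M`, `seed`.
#' @export
generate_instances <- function(g, encoder, spec = fixture_spec(),
                               seed = spec$seed) {
  desc <- term_description(g)
  Y <- encode_texts(desc, encoder)
  leaves <- leaf_terms(g)
  with_seed(seed, {
    M <- matrix(stats::rnorm(spec$feature_dim * ncol(Y)), spec$feature_dim)
    inst_term <- rep(leaves, each = spec$n_instances)
    ids <- sprintf("inst%04d", seq_along(inst_term))
    Fm <- t(M %*% t(Y[inst_term, , drop = FALSE])) +
      matrix(stats::rnorm(length(inst_term) * spec$feature_dim,
                          sd = spec$noise_sd), length(inst_term))
    rownames(Fm) <- ids
    direct <- annotation_matrix(
      data.frame(instance_id = ids, term_id = inst_term,
                 stringsAsFactors = FALSE),
      instance_ids = ids, term_ids = names(desc))
    list(features = Fm, annotations = propagate_annotations(direct, g),
         direct = direct, M = M, seed = as.integer(seed))
  })
}

#' Generate an expression matrix with planted marker genes
#'
#' Cells x genes counts with negative-binomial background expression; each
#' cell type owns a disjoint block of marker genes whose mean is up-shifted
#' by `marker_fold` in cells of that type. Per-type textual descriptions
#' and text-aligned gene features (markers of a type are linear images of
#' that type's description embedding) are emitted alongside, so both the
#' correlation-based and the embedding-based marker procedures can be
#' evaluated against the same planted truth.
#'
#' @param spec A [fixture_spec()].
#' @param seed Seed.
#' @param encoder Text encoder for type/gene descriptions (default hashing
#'   at the spec's `d_bio`).
#' @return List: `counts`, `labels`, `markers` (genes x types binary),
#'   `type_descriptions`, `gene_descriptions`, `gene_features`, `seed`.
#' @export
generate_expression <- function(spec = fixture_spec(), seed = spec$seed,
                                encoder = hashing_encoder(spec$d_bio, seed = 1L)) {
  stopifnot(spec$n_markers * spec$n_types <= spec$n_genes)
  vocab <- fixture_vocab(spec)
  with_seed(seed, {
    types <- sprintf("CT:%02d", seq_len(spec$n_types))
    genes <- sprintf("g%03d", seq_len(spec$n_genes))
    n_cells <- spec$n_types * spec$n_instances
    labels <- rep(types, each = spec$n_instances)
    markers <- matrix(0L, spec$n_genes, spec$n_types,
                      dimnames = list(genes, types))
    for (k in seq_len(spec$n_types)) {
      markers[(k - 1L) * spec$n_markers + seq_len(spec$n_markers), k] <- 1L
    }
    mu <- matrix(spec$nb_mu, n_cells, spec$n_genes)
    for (k in seq_len(spec$n_types)) {
      mu[labels == types[k], markers[, k] == 1L] <- spec$nb_mu * spec$marker_fold
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = spec$nb_size),
                     n_cells, spec$n_genes,
                     dimnames = list(sprintf("cell%04d", seq_len(n_cells)), genes))
    type_desc <- stats::setNames(vapply(types, function(t) {
      paste(sample(vocab, spec$tokens_per_description), collapse = " ")
    }, ""), types)
    # marker genes inherit tokens from their type's description
    gene_desc <- stats::setNames(vapply(seq_len(spec$n_genes), function(j) {
      own <- paste(sample(vocab, 4), collapse = " ")
      k <- which(markers[j, ] == 1L)
      if (length(k) == 1L) {
        toks <- strsplit(type_desc[k], " ")[[1]]
        paste(c(toks[seq_len(8)], own), collapse = " ")
      } else own
    }, ""), genes)
    Yg <- encode_texts(gene_desc, encoder)
    Mg <- matrix(stats::rnorm(spec$feature_dim * ncol(Yg)), spec$feature_dim)
    Fg <- t(Mg %*% t(Yg)) +
      matrix(stats::rnorm(spec$n_genes * spec$feature_dim,
                          sd = spec$noise_sd), spec$n_genes)
    rownames(Fg) <- genes
    list(counts = counts, labels = labels, markers = markers,
         type_descriptions = type_desc, gene_descriptions = gene_desc,
         gene_features = Fg, seed = as.integer(seed))
  })
}

#' Generate two modalities sharing a latent text space, with no pairs
#'
#' Draws `n_latent` latent items, each with a textual description; modality
#' A features are `M_A Y + noise` and modality B features `M_B Y + noise`
#' with independent random maps. Items are split three ways: an A-only
#' training corpus (features + descriptions), a B-only training corpus, and
#' held-out true cross-modal pairs whose ids appear in neither corpus and
#' whose descriptions are never exposed.
#'
#' @param spec A [fixture_spec()].
#' @param seed Seed.
#' @param encoder Text encoder for the latent descriptions.
#' @return List with `corpus_a`, `corpus_b` (each `features` +
#'   `descriptions`), `test_a`, `test_b` (feature matrices of the held-out
#'   items, pairs aligned by row), `pair_ids`, `seed`.
#' @export
generate_paired_modalities <- function(spec = fixture_spec(), seed = spec$seed,
                                       encoder = hashing_encoder(spec$d_bio,
                                                                 seed = 1L)) {
  vocab <- fixture_vocab(spec)
  with_seed(seed, {
    n <- spec$n_latent
    ids <- sprintf("item%04d", seq_len(n))
    desc <- stats::setNames(vapply(ids, function(i) {
      paste(sample(vocab, spec$tokens_per_description), collapse = " ")
    }, ""), ids)
    Y <- encode_texts(desc, encoder)
    Ma <- matrix(stats::rnorm(spec$feature_dim * ncol(Y)), spec$feature_dim)
    Mb <- matrix(stats::rnorm(spec$feature_dim * ncol(Y)), spec$feature_dim)
    noise <- function(k) matrix(stats::rnorm(k * spec$feature_dim,
                                             sd = spec$noise_sd), k)
    Fa <- t(Ma %*% t(Y)) + noise(n); rownames(Fa) <- ids
    Fb <- t(Mb %*% t(Y)) + noise(n); rownames(Fb) <- ids
    grp <- sample(rep(c("a", "b", "test"), times = round(n * c(0.4, 0.4, 0.2)))[seq_len(n)])
    list(corpus_a = list(features = Fa[grp == "a", , drop = FALSE],
                         descriptions = desc[grp == "a"]),
         corpus_b = list(features = Fb[grp == "b", , drop = FALSE],
                         descriptions = desc[grp == "b"]),
         test_a = Fa[grp == "test", , drop = FALSE],
         test_b = Fb[grp == "test", , drop = FALSE],
         pair_ids = ids[grp == "test"], seed = as.integer(seed))
  })
}

#' Write a fixture bundle to disk in plain-text formats
#'
#' Emits the OBO ontology, the two-column annotation table and the feature
#' matrix for a generated instance fixture.
#'
#' @param g Ontology from [generate_ontology()].
#' @param inst Result of [generate_instances()].
#' @param dir Output directory (created if needed).
#' @export
write_fixture_bundle <- function(g, inst, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(g, file.path(dir, "ontology.obo"))
  idx <- which(inst$direct$A == 1, arr.ind = TRUE)
  utils::write.table(
    data.frame(instance_id = inst$direct$instance_ids[idx[, 1]],
               term_id = inst$direct$term_ids[idx[, 2]]),
    file.path(dir, "annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_feature_matrix(inst$features, file.path(dir, "features.tsv"))
  invisible(dir)
}
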