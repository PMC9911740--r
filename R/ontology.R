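#' Construct an ontology graph
#'
#' An `ontology_graph` holds a table of terms (id, name, definition, obsolete
#' flag) and a table of directed child-to-parent edges labelled with their
#' relation (`is_a` or `part_of`). It is the backbone for term descriptions,
#' annotation propagation, graph distances and unseen-class splits.
#'
#' @param terms data.frame with columns `id`, `name`, `definition`,
#'   `obsolete` (logical). Missing `definition`/`obsolete` columns are filled.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges = NULL) {
  stopifnot(is.data.frame(terms), "id" %in% names(terms), "name" %in% names(terms))
  if (anyDuplicated(terms$id)) stop("duplicate term ids")
  if (is.null(terms$definition)) terms$definition <- ""
  if (is.null(terms$obsolete)) terms$obsolete <- FALSE
  terms <- terms[, c("id", "name", "definition", "obsolete")]
  terms$id <- as.character(terms$id)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
    edges <- edges[, c("child", "parent", "relation")]
    bad <- !(edges$child %in% terms$id & edges$parent %in% terms$id)
    if (any(bad)) stop("edge endpoint not present in terms table")
  }
  structure(list(terms = terms, edges = edges), class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms (%d obsolete), %d edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  invisible(x)
}

#' Ids of the non-obsolete terms of an ontology
#'
#' @param g An [ontology_graph()].
#' @export
active_terms <- function(g) g$terms$id[!g$terms$obsolete]

# igraph view over the chosen relation subset (child -> parent edges);
# directed by default, undirectable for distance queries.
og_igraph <- function(g, relations = c("is_a", "part_of"), directed = TRUE) {
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  igraph::graph_from_data_frame(
    e[, c("child", "parent")],
    directed = directed,
    vertices = data.frame(name = active_terms(g))
  )
}

#' Parse an OBO ontology file
#'
#' Reads the OBO 1.2/1.4 flat-file dialect: one term per `[Term]` stanza with
#' `id`, `name`, `def`, `is_a` and `relationship: part_of` lines. Quoted
#' definitions have their surrounding quotes and trailing dbxref bracket
#' stripped. Obsolete terms are kept in the term table, flagged, and excluded
#' from the edge set. Edges whose target id does not correspond to any parsed
#' term are dropped with a warning.
#'
#' @param path Path to an OBO file, or a character vector of OBO lines.
#' @return An [ontology_graph()].
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }

  stanza_starts <- which(trimws(lines) == "[Term]")
  other_stanzas <- which(grepl("^\\[", trimws(lines)) & trimws(lines) != "[Term]")
  terms <- list()
  edges <- list()

  for (s in stanza_starts) {
    nxt <- c(stanza_starts[stanza_starts > s], other_stanzas[other_stanzas > s],
             length(lines) + 1L)
    block <- lines[(s + 1L):(min(nxt) - 1L)]
    rec <- list(id = NA_character_, name = "", definition = "",
                obsolete = FALSE, parents = list())
    for (k in seq_along(block)) {
      ln <- trimws(block[k])
      if (!nzchar(ln) || startsWith(ln, "!")) next
      if (!grepl(":", ln, fixed = TRUE)) {
        stop(sprintf("malformed OBO stanza at line %d: '%s'", s + k, ln))
      }
      key <- sub(":.*$", "", ln)
      val <- trimws(sub("^[^:]+:", "", ln))
      val <- sub("\\s*!.*$", "", val)  # trailing comment
      if (key == "id") rec$id <- val
      else if (key == "name") rec$name <- val
      else if (key == "def") {
        m <- regmatches(val, regexec('^"(.*)"', val))[[1]]
        rec$definition <- if (length(m) == 2L) m[2] else val
      } else if (key == "is_a") {
        rec$parents[[length(rec$parents) + 1L]] <- c("is_a", val)
      } else if (key == "relationship") {
        parts <- strsplit(val, "\\s+")[[1]]
        if (length(parts) >= 2L && parts[1] == "part_of") {
          rec$parents[[length(rec$parents) + 1L]] <- c("part_of", parts[2])
        }
      } else if (key == "is_obsolete") {
        rec$obsolete <- identical(tolower(val), "true")
      }
    }
    if (is.na(rec$id)) stop(sprintf("malformed OBO stanza at line %d: missing id", s))
    terms[[rec$id]] <- rec
  }

  term_df <- data.frame(
    id = vapply(terms, `[[`, "", "id"),
    name = vapply(terms, `[[`, "", "name"),
    definition = vapply(terms, `[[`, "", "definition"),
    obsolete = vapply(terms, `[[`, FALSE, "obsolete"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ok_ids <- term_df$id[!term_df$obsolete]
  for (rec in terms) {
    if (rec$obsolete) next
    for (p in rec$parents) {
      if (!(p[2] %in% ok_ids)) {
        warning(sprintf("dropping edge %s -> %s: unknown target", rec$id, p[2]))
        next
      }
      edges[[length(edges) + 1L]] <- data.frame(
        child = rec$id, parent = p[2], relation = p[1], stringsAsFactors = FALSE)
    }
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else NULL
  ontology_graph(term_df, edge_df)
}

#' Write an ontology graph as an OBO file
#'
#' Emits one `[Term]` stanza per term, in term-table order, using the same
#' subset of the format that [parse_obo()] reads, so a written graph
#' round-trips through parsing.
#'
#' @param g An [ontology_graph()].
#' @param path Output path.
#' @export
write_obo <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(g$terms))) {
    t <- g$terms[i, ]
    out <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (nzchar(t$definition)) {
      out <- c(out, sprintf('def: "%s" []', t$definition))
    }
    e <- g$edges[g$edges$child == t$id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[j] == "is_a") {
        paste0("is_a: ", e$parent[j])
      } else {
        paste0("relationship: part_of ", e$parent[j])
      })
    }
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Build class descriptions from term name and definition
#'
#' The free-text description of a class is its ontology name concatenated
#' with its definition; classifiers and encoders consume this single string.
#'
#' @param g An [ontology_graph()].
#' @param ids Term ids (default: all non-obsolete terms).
#' @param sep Delimiter between name and definition.
#' @return Named character vector of descriptions.
#' @export
term_description <- function(g, ids = NULL, sep = ". ") {
  if (is.null(ids)) ids <- active_terms(g)
  idx <- match(ids, g$terms$id)
  if (anyNA(idx)) stop("unknown term id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  nm <- g$terms$name[idx]
  df <- g$terms$definition[idx]
  if (any(!nzchar(nm))) stop("term(s) with empty name: ",
                             paste(ids[!nzchar(nm)], collapse = ", "))
  out <- ifelse(nzchar(df), paste0(nm, sep, df), nm)
  names(out) <- ids
  out
}

#' Ancestors of a term under chosen relations
#'
#' @param g An [ontology_graph()].
#' @param id A single term id.
#' @param relations Relation labels whose edges are followed.
#' @return Character vector of ancestor ids (excluding `id` itself).
#' @export
term_ancestors <- function(g, id, relations = c("is_a", "part_of")) {
  ig <- og_igraph(g, relations)
  if (!(id %in% igraph::V(ig)$name)) stop("unknown term id: ", id)
  anc <- igraph::subcomponent(ig, id, mode = "out")$name
  setdiff(anc, id)
}

#' Binary instance-by-term annotation matrix
#'
#' @param pairs data.frame with columns `instance_id`, `term_id`, or `NULL`
#'   when `A` is given directly.
#' @param instance_ids,term_ids Row/column universes; defaults are the ids
#'   observed in `pairs`.
#' @param A Optional pre-built binary matrix (instances x terms).
#' @param propagated Whether the matrix is already true-path closed.
#' @return An object of class `annotation_matrix` with a 0/1 `A` matrix.
#' @export
annotation_matrix <- function(pairs = NULL, instance_ids = NULL, term_ids = NULL,
                              A = NULL, propagated = FALSE) {
  if (is.null(A)) {
    stopifnot(is.data.frame(pairs),
              all(c("instance_id", "term_id") %in% names(pairs)))
    instance_ids <- instance_ids %||% sort(unique(as.character(pairs$instance_id)))
    term_ids <- term_ids %||% sort(unique(as.character(pairs$term_id)))
    A <- matrix(0, length(instance_ids), length(term_ids),
                dimnames = list(instance_ids, term_ids))
    ri <- match(as.character(pairs$instance_id), instance_ids)
    ci <- match(as.character(pairs$term_id), term_ids)
    if (anyNA(ri) || anyNA(ci)) stop("pair outside the given id universes")
    A[cbind(ri, ci)] <- 1
  } else {
    instance_ids <- instance_ids %||% rownames(A)
    term_ids <- term_ids %||% colnames(A)
    A <- as.matrix(A)
    if (!all(A %in% c(0, 1))) stop("annotation matrix entries must be 0/1")
    dimnames(A) <- list(instance_ids, term_ids)
  }
  structure(list(A = A, instance_ids = instance_ids, term_ids = term_ids,
                 propagated = propagated), class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation_matrix: %d instances x %d terms, %d positive%s\n",
              nrow(x$A), ncol(x$A), sum(x$A),
              if (x$propagated) " (propagated)" else ""))
  invisible(x)
}

#' Read a two-column annotation table
#'
#' @param path TSV with columns instance_id, term_id (no header by default).
#' @param header Whether the file has a header line.
#' @inheritParams annotation_matrix
#' @export
read_annotations <- function(path, instance_ids = NULL, term_ids = NULL,
                             header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          col.names = if (header) NULL else c("instance_id", "term_id"),
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("instance_id", "term_id")
  annotation_matrix(df, instance_ids = instance_ids, term_ids = term_ids)
}

#' True-path propagation of annotations
#'
#' Copies every positive annotation to all ancestors of its term reachable
#' over the chosen relations (the true-path rule): an instance annotated to a
#' term is implicitly annotated to every ancestor of that term. Idempotent.
#'
#' @param ann An [annotation_matrix()]; its `term_ids` must all exist in `g`.
#' @param g An [ontology_graph()].
#' @param relations Relations over which ancestors are collected.
#' @return A propagated [annotation_matrix()].
#' @export
propagate_annotations <- function(ann, g, relations = c("is_a", "part_of")) {
  stopifnot(inherits(ann, "annotation_matrix"), inherits(g, "ontology_graph"))
  if (!all(ann$term_ids %in% g$terms$id)) {
    stop("annotation term ids not all present in the ontology")
  }
  ig <- og_igraph(g, relations)
  if (!igraph::is_dag(ig)) stop("cycle detected under relations ",
                                paste(relations, collapse = "+"))
  A <- ann$A
  present <- ann$term_ids[ann$term_ids %in% igraph::V(ig)$name]
  for (t in present) {
    if (!any(A[, t] > 0)) next
    anc <- intersect(setdiff(igraph::subcomponent(ig, t, mode = "out")$name, t),
                     ann$term_ids)
    for (u in anc) A[, u] <- pmax(A[, u], A[, t])
  }
  annotation_matrix(A = A, instance_ids = ann$instance_ids,
                    term_ids = ann$term_ids, propagated = TRUE)
}

#' Leaf terms of an ontology
#'
#' Leaves are the most specific classes: non-obsolete terms that are not the
#' parent of any other term under the chosen relations.
#'
#' @inheritParams propagate_annotations
#' @return Character vector of leaf ids.
#' @export
leaf_terms <- function(g, relations = c("is_a", "part_of")) {
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  setdiff(active_terms(g), unique(e$parent))
}

#' Hold out classes for zero-shot evaluation
#'
#' Selects a set of unseen (test) terms -- either the annotated leaves of the
#' ontology or a seeded random fraction of the annotated terms -- and removes
#' from training every instance annotated, after propagation, to any unseen
#' term, so that no information about held-out classes leaks into training.
#' Terms with no annotations are never selectable as unseen.
#'
#' @param ann An [annotation_matrix()].
#' @param g An [ontology_graph()].
#' @param mode `"leaf"` or `"fraction"`.
#' @param fraction Fraction of annotated terms held out when `mode="fraction"`.
#' @param seed Integer seed controlling the random selection.
#' @param relations Relations used for propagation when checking leakage.
#' @return List with `train_instances`, `train_terms`, `unseen_terms`,
#'   `mode`, `fraction`, `seed`.
#' @export
make_unseen_split <- function(ann, g, mode = c("leaf", "fraction"),
                              fraction = 0.5, seed = 1L,
                              relations = c("is_a", "part_of")) {
  mode <- match.arg(mode)
  prop <- if (ann$propagated) ann else propagate_annotations(ann, g, relations)
  annotated <- prop$term_ids[colSums(prop$A) > 0]
  unseen <- if (mode == "leaf") {
    intersect(leaf_terms(g, relations), annotated)
  } else {
    if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
    with_seed(seed, sample(annotated, round(fraction * length(annotated))))
  }
  if (length(unseen) == 0L) stop("no unseen terms selectable")
  hit <- rowSums(prop$A[, unseen, drop = FALSE]) > 0
  train_instances <- prop$instance_ids[!hit]
  if (length(train_instances) == 0L) stop("split leaves zero training instances")
  keep <- prop$A[train_instances, , drop = FALSE]
  train_terms <- setdiff(prop$term_ids[colSums(keep) > 0], unseen)
  list(train_instances = train_instances, train_terms = train_terms,
       unseen_terms = sort(unseen), mode = mode,
       fraction = if (mode == "fraction") fraction else NA_real_,
       seed = as.integer(seed))
}

#' Write / read a split manifest as JSON
#'
#' @param split Result of [make_unseen_split()].
#' @param path JSON file path.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(split, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$seed <- as.integer(s$seed)
  s
}
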