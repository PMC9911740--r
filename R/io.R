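# Readers/writers for the delimited formats used around the models.

#' Read a delimited feature matrix
#'
#' First column holds instance/gene ids; remaining columns are numeric
#' features.
#'
#' @param path TSV path with a header line.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_feature_matrix
#' @param m Matrix with row-name ids.
#' @param id_col Name of the id column written first.
#' @export
write_feature_matrix <- function(m, path, id_col = "id") {
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then member genes, tab-separated.
#'
#' @param path GMT path.
#' @return Named list of character vectors; descriptions kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene sets.
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_sequences_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readAAStringSet(path)
    out <- as.character(s)
    names(out) <- sub("\\s.*$", "", names(s))
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  stats::setNames(unname(seqs), id)
}

#' Read SMILES strings, one molecule per line
#'
#' Accepts `id<TAB>smiles` or bare SMILES lines.
#'
#' @param path Input path.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  two <- all(lengths(parts) >= 2L)
  smiles <- vapply(parts, function(p) if (two) p[2] else p[1], "")
  names(smiles) <- if (two) vapply(parts, `[[`, "", 1L) else
    as.character(seq_along(smiles))
  smiles
}

#' Write instance scores for one novel class as TSV
#'
#' @param scores A `score_matrix` from [zero_shot_annotate()].
#' @param path Output TSV (instance_id, one probability column per class).
#' @export
write_score_table <- function(scores, path) {
  df <- data.frame(instance_id = scores$instance_ids, scores$probabilities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- scores$term_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
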