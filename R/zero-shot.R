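#' Bilinear class-probability score
#'
#' The core zero-shot score: the probability that instance embedding `F`
#' belongs to the class with text embedding `Y` is the logistic of the
#' bilinear form `F' W Y`. Accepts a single instance and class (vectors) or
#' matrices (instances x dim, classes x d_bio), returning a probability or
#' an instances x classes matrix of probabilities, all strictly in (0, 1).
#'
#' @param F_mat Instance embedding vector, or matrix with one row per
#'   instance.
#' @param W Bilinear weight matrix, (instance dim) x d_bio.
#' @param Y Class text embedding vector, or matrix with one row per class.
#' @export
bilinear_score <- function(F_mat, W, Y) {
  Fm <- if (is.matrix(F_mat)) F_mat else matrix(F_mat, nrow = 1)
  Ym <- if (is.matrix(Y)) Y else matrix(Y, nrow = 1)
  if (ncol(Fm) != nrow(W) || ncol(Ym) != ncol(W)) {
    stop(sprintf("shape mismatch: F has %d cols, W is %dx%d, Y has %d cols",
                 ncol(Fm), nrow(W), ncol(W), ncol(Ym)))
  }
  P <- sigmoid(Fm %*% W %*% t(Ym))
  rownames(P) <- rownames(Fm); colnames(P) <- rownames(Ym)
  if (!is.matrix(F_mat) && !is.matrix(Y)) drop(P) else P
}

#' Multi-label binary cross-entropy over the bilinear logits
#'
#' Sums (or averages) over instances i and classes j the binary
#' cross-entropy between the annotation A[i,j] and the logistic of
#' `F_i' W Y_j` -- the independent-per-class multi-label objective (no
#' softmax across classes). Computed on the logit scale so it stays finite
#' for saturated predictions.
#'
#' @param F_mat Instances x dim matrix of instance embeddings.
#' @param Y Classes x d_bio matrix of class text embeddings.
#' @param A Binary instances x classes annotation matrix.
#' @param W Bilinear weights.
#' @param reduction `"mean"` (over all entries) or `"sum"`.
#' @export
bilinear_loss <- function(F_mat, Y, A, W, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("annotation matrix must be binary")
  Z <- F_mat %*% W %*% t(Y)
  if (!all(dim(Z) == dim(A))) stop("annotation shape does not match logits")
  # -A*log(sigma(z)) - (1-A)*log(1-sigma(z)) = log1pexp(z) - A*z  ... for z<=0
  # use the symmetric stable form
  ell <- log1pexp(-abs(Z)) + pmax(Z, 0) - A * Z
  if (reduction == "mean") mean(ell) else sum(ell)
}

#' Training configuration for the bi-nonlinear classifier
#'
#' Defaults: Adam at learning rate 1e-4, batch size 128, 15 epochs (the
#' cell-type setting; protein-function models train for 30).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Instances per minibatch.
#' @param epochs Training epochs.
#' @param seed Seed controlling initialization and shuffling.
#' @param weight_decay L2 penalty on the bilinear weights. Zero by default;
#'   useful when each training item is its own class (translator training),
#'   where unpenalized margin maximization erases the cross-item similarity
#'   structure that transfer relies on.
#' @param init_sd Scale of the Gaussian initialization of `W` (entries are
#'   drawn with standard deviation `init_sd / sqrt(dim F)`). Because the
#'   bilinear score's ranking is scale-invariant, the initialization only
#'   matters through its direction: it must be small relative to the
#'   displacement training produces, or random init noise dominates the
#'   learned structure.
#' @param adam_eps Adam denominator constant. The conventional 1e-8 makes
#'   every coordinate's first updates equal to +/- learning_rate regardless
#'   of gradient magnitude; for the small-scale bilinear models trained
#'   here a larger value keeps updates proportional to the gradient (and
#'   hence to its low-rank structure), which matters for transfer.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         epochs = 15L, seed = 1L, weight_decay = 0,
                         init_sd = 0.01, adam_eps = 1e-8) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0, weight_decay >= 0,
            adam_eps > 0, init_sd > 0)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 weight_decay = weight_decay, init_sd = init_sd,
                 adam_eps = adam_eps),
            class = "train_config")
}

# forward pass through the dense blocks; returns F and per-block hidden
# activations for backprop. blocks=NULL means identity features.
zs_forward <- function(X_list, blocks) {
  if (is.null(blocks)) {
    Fm <- do.call(cbind, X_list)
    return(list(F = Fm, H = NULL))
  }
  H <- mapply(function(X, w) encode_feature_block(X, w),
              X_list, blocks, SIMPLIFY = FALSE)
  list(F = do.call(cbind, H), H = H)
}

#' Train the bi-nonlinear zero-shot classifier on seen classes
#'
#' Class text embeddings `Y` are computed once from the supplied encoder and
#' frozen; the per-block instance encoders (optional fully connected + ReLU
#' layers) and the bilinear weights `W` are then optimized jointly with Adam
#' against the multi-label cross-entropy [bilinear_loss()]. Training classes
#' are the annotation columns with at least one positive among the training
#' instances.
#'
#' @param features Instances x dim numeric matrix, or named list of such
#'   matrices (one per feature block) with identical row ids.
#' @param annotations An [annotation_matrix()] (propagate first if the
#'   true-path rule should hold).
#' @param class_texts Named character vector of class descriptions; names
#'   must cover the annotation's term ids.
#' @param encoder A `text_encoder` used once to embed `class_texts`.
#' @param cfg A [train_config()].
#' @param hidden `NULL` for identity features (W applied to raw features),
#'   or a named integer vector of per-block hidden dimensions.
#' @return A `zero_shot_model` with elements `blocks`, `W`, `Y`, `term_ids`,
#'   `encoder`, `layout` and a `loss_history`.
#' @export
train_zero_shot <- function(features, annotations, class_texts, encoder,
                            cfg = train_config(), hidden = NULL) {
  stopifnot(inherits(annotations, "annotation_matrix"))
  X_list <- if (is.matrix(features)) list(x = features) else features
  n <- nrow(X_list[[1]])
  stopifnot(all(vapply(X_list, nrow, 0L) == n))
  ids <- rownames(X_list[[1]]) %||% as.character(seq_len(n))

  keep <- match(ids, annotations$instance_ids)
  if (anyNA(keep)) stop("feature rows missing from the annotation matrix")
  A_all <- annotations$A[keep, , drop = FALSE]
  term_ids <- annotations$term_ids[colSums(A_all) > 0]
  A_all <- A_all[, term_ids, drop = FALSE]
  if (!all(term_ids %in% names(class_texts))) {
    stop("class description missing for: ",
         paste(setdiff(term_ids, names(class_texts))[1:5], collapse = ", "))
  }
  Y <- encode_texts(class_texts[term_ids], encoder)
  d_bio <- ncol(Y)

  blocks <- NULL
  if (!is.null(hidden)) {
    if (is.null(names(hidden)) && length(hidden) == length(X_list)) {
      names(hidden) <- names(X_list)
    }
    stopifnot(identical(names(hidden), names(X_list)))
  }
  dimF <- if (is.null(hidden)) sum(vapply(X_list, ncol, 0L)) else sum(hidden)
  history <- numeric(0)

  with_seed(cfg$seed, {
    if (!is.null(hidden)) {
      blocks <- mapply(function(X, h) {
        list(V = matrix(stats::rnorm(ncol(X) * h, sd = 1 / sqrt(ncol(X))),
                        ncol(X), h),
             b = numeric(h))
      }, X_list, hidden, SIMPLIFY = FALSE)
    }
    W <- matrix(stats::rnorm(dimF * d_bio, sd = cfg$init_sd / sqrt(dimF)),
                dimF, d_bio)
    params <- list(W = W)
    if (!is.null(blocks)) {
      for (nm in names(blocks)) {
        params[[paste0("V.", nm)]] <- blocks[[nm]]$V
        params[[paste0("b.", nm)]] <- blocks[[nm]]$b
      }
    }
    opt <- adam_init(params, lr = cfg$learning_rate, eps = cfg$adam_eps)

    get_blocks <- function(params) {
      if (is.null(blocks)) return(NULL)
      stats::setNames(lapply(names(blocks), function(nm) {
        list(V = params[[paste0("V.", nm)]], b = params[[paste0("b.", nm)]])
      }), names(blocks))
    }

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        Xb <- lapply(X_list, function(X) X[bi, , drop = FALSE])
        fw <- zs_forward(Xb, get_blocks(params))
        Ab <- A_all[bi, , drop = FALSE]
        Z <- fw$F %*% params$W %*% t(Y)
        loss <- mean(log1pexp(-abs(Z)) + pmax(Z, 0) - Ab * Z)
        if (!is.finite(loss)) stop("non-finite training loss; aborting")
        G <- (sigmoid(Z) - Ab) / length(Z)
        grads <- list(W = t(fw$F) %*% G %*% Y)
        if (cfg$weight_decay > 0) {
          grads$W <- grads$W + cfg$weight_decay * params$W
        }
        if (!is.null(blocks)) {
          dF <- G %*% Y %*% t(params$W)
          off <- 0L
          for (nm in names(blocks)) {
            h <- ncol(params[[paste0("V.", nm)]])
            dH <- dF[, (off + 1L):(off + h), drop = FALSE] *
              (fw$H[[nm]] > 0)
            grads[[paste0("V.", nm)]] <- t(Xb[[nm]]) %*% dH
            grads[[paste0("b.", nm)]] <- colSums(dH)
            off <- off + h
          }
        }
        st <- adam_step(opt, params, grads)
        opt <- st$state; params <- st$params
        ep_loss <- ep_loss + loss * length(bi)
      }
      history <- c(history, ep_loss / n)
    }
    W <- params$W
    blocks <- get_blocks(params)
  })

  structure(list(blocks = blocks, W = W, Y = Y, term_ids = term_ids,
                 encoder = encoder, hidden = hidden,
                 layout = if (is.null(hidden))
                   vapply(X_list, ncol, 0L) else hidden,
                 cfg = cfg, loss_history = history),
            class = "zero_shot_model")
}

#' @export
print.zero_shot_model <- function(x, ...) {
  cat(sprintf("zero_shot_model: %d training classes, W %dx%d, %s features\n",
              length(x$term_ids), nrow(x$W), ncol(x$W),
              if (is.null(x$blocks)) "identity" else
                paste(names(x$layout), x$layout, sep = "=", collapse = "+")))
  invisible(x)
}

# embed raw features through the model's blocks
model_embed <- function(model, features) {
  X_list <- if (is.matrix(features)) list(x = features) else features
  zs_forward(X_list, model$blocks)$F
}

#' Zero-shot annotation of instances against novel classes
#'
#' Embeds each novel class from its free-text description alone, then
#' scores every instance against every novel class with [bilinear_score()].
#' No annotations of the novel classes are consulted: this is how classes
#' never seen in training are predicted.
#'
#' @param features As in [train_zero_shot()] (same block structure).
#' @param novel_descriptions Named character vector of class descriptions.
#' @param model A trained `zero_shot_model`.
#' @return A list of class `score_matrix`: `probabilities` (instances x
#'   classes, entries in (0,1)), `instance_ids`, `term_ids`.
#' @export
zero_shot_annotate <- function(features, novel_descriptions, model) {
  stopifnot(inherits(model, "zero_shot_model"))
  if (length(novel_descriptions) == 0L || any(!nzchar(trimws(novel_descriptions)))) {
    stop("novel class descriptions must be non-empty")
  }
  Yn <- encode_texts(novel_descriptions, model$encoder)
  Fm <- model_embed(model, features)
  P <- bilinear_score(Fm, model$W, Yn)
  P <- if (is.matrix(P)) P else matrix(P, nrow(Fm), nrow(Yn))
  structure(list(probabilities = P,
                 instance_ids = rownames(Fm) %||% as.character(seq_len(nrow(Fm))),
                 term_ids = names(novel_descriptions) %||%
                   as.character(seq_len(nrow(Yn)))),
            class = "score_matrix")
}

#' Area under the ROC curve
#'
#' Rank-based AUROC (equivalent to the Mann-Whitney U statistic divided by
#' n1*n0), with tied scores counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: labels contain one class only")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Save / load a trained model as a plain-text directory bundle
#'
#' The bundle holds a JSON manifest (term ids, layout, encoder settings)
#' plus one delimited file per weight matrix, so models move between
#' machines without binary serialization. Hashing and embedding-bag
#' encoders are restored exactly; transformer backends should be
#' checkpointed with their own native tooling.
#'
#' @param model A `zero_shot_model`.
#' @param dir Bundle directory (created if needed).
#' @export
save_zero_shot_model <- function(model, dir) {
  stopifnot(inherits(model, "zero_shot_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enc <- model$encoder
  manifest <- list(
    term_ids = model$term_ids,
    hidden = as.list(model$hidden),
    layout = as.list(model$layout),
    encoder = list(backend = enc$backend, d_bio = enc$d_bio,
                   seed = enc$seed, max_tokens = enc$max_tokens),
    loss_history = model$loss_history
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  wm <- function(m, f) {
    utils::write.table(m, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  wm(model$W, "W.tsv")
  wm(model$Y, "Y.tsv")
  if (!is.null(model$blocks)) {
    for (nm in names(model$blocks)) {
      wm(model$blocks[[nm]]$V, paste0("V.", nm, ".tsv"))
      wm(matrix(model$blocks[[nm]]$b, nrow = 1), paste0("b.", nm, ".tsv"))
    }
  }
  if (enc$backend == "embedding_bag") {
    utils::write.table(data.frame(token = rownames(enc$E), enc$E),
                       file.path(dir, "encoder_E.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_zero_shot_model
#' @export
load_zero_shot_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rm_ <- function(f) as.matrix(utils::read.table(file.path(dir, f),
                                                 sep = "\t", header = FALSE))
  W <- unname(rm_("W.tsv")); Y <- unname(rm_("Y.tsv"))
  rownames(Y) <- man$term_ids
  hidden <- if (length(man$hidden)) unlist(man$hidden) else NULL
  blocks <- NULL
  if (!is.null(hidden)) {
    blocks <- stats::setNames(lapply(names(hidden), function(nm) {
      list(V = unname(rm_(paste0("V.", nm, ".tsv"))),
           b = drop(unname(rm_(paste0("b.", nm, ".tsv")))))
    }), names(hidden))
  }
  enc <- if (man$encoder$backend == "hashing") {
    hashing_encoder(man$encoder$d_bio, man$encoder$seed,
                    man$encoder$max_tokens)
  } else if (man$encoder$backend == "embedding_bag") {
    tab <- utils::read.table(file.path(dir, "encoder_E.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)
    E <- as.matrix(tab[, -1]); rownames(E) <- tab[[1]]
    colnames(E) <- NULL
    e <- embedding_bag_encoder("x", d_bio = ncol(E),
                               seed = man$encoder$seed,
                               max_tokens = man$encoder$max_tokens)
    e$vocab <- utils::head(rownames(E), -1)
    e$E <- E
    e
  } else {
    stop("cannot restore encoder backend: ", man$encoder$backend)
  }
  structure(list(blocks = blocks, W = W, Y = Y, term_ids = man$term_ids,
                 encoder = enc, hidden = hidden,
                 layout = unlist(man$layout),
                 cfg = NULL, loss_history = man$loss_history),
            class = "zero_shot_model")
}
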