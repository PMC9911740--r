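# Internal numerical and RNG helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow for large |x|
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 35
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  dim(out) <- dim(x)
  out
}

l2_normalize <- function(x) {
  if (is.matrix(x)) {
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm == 0] <- 1
    x / nrm
  } else {
    nrm <- sqrt(sum(x^2))
    if (nrm == 0) x else x / nrm
  }
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Lowercase word tokenizer: punctuation stripped, whitespace split.
tokenize_text <- function(text, max_tokens = Inf) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  toks
}

# Deterministic 31-bit string hash with seed mixing; stays in exact
# double-precision integer range.
hash_token <- function(token, seed = 0L) {
  m <- 2^31
  h <- 0
  for (c in utf8ToInt(token)) h <- (h * 31 + c) %% m
  (h * 69069 + as.numeric(seed) * 40503 + 1013904223) %% m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adam optimizer state over a named list of parameter arrays.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  )
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}
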