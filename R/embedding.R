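# Continuous-bag-of-words k-mer embeddings.
#
# Segments are treated as sentences of overlapping k-mers (stride 1).
# The CBOW objective predicts each token from the mean of the embedding
# vectors of its context window via a full softmax over the vocabulary
# (at most 4^k tokens, so the exact softmax is cheap), trained by
# vectorized full-batch gradient descent.  Training is deterministic
# given the seed: randomness enters only through the initialization.

#' Tokenize sequences into overlapping k-mers
#'
#' @param x [SegmentSet-class] or character vector.
#' @param k k-mer size (default 3).
#' @return List of character vectors, one per sequence (length L - k + 1).
#' @export
tokenizeSegments <- function(x, k = 3L) {
  s <- if (is(x, "SegmentSet")) as.character(x) else
    .normalizeSeq(as.character(x))
  k <- as.integer(k)
  lapply(s, function(si) {
    n <- nchar(si)
    if (n < k) character() else substring(si, 1:(n - k + 1L), k:n)
  })
}

#' Train a CBOW k-mer embedding on a segment corpus
#'
#' @param x Training [SegmentSet-class] (use training-split segments
#'   only, never test segments).
#' @param dim Embedding dimension (default 100).
#' @param k k-mer size of the tokenizer (default 3).
#' @param window Context half-window in tokens (default 5).
#' @param epochs Gradient-descent epochs (default 20).
#' @param lr Learning rate (default 0.25).
#' @param seed Seed for the initialization (default 1).
#' @return A [Word2VecModel-class].
#' @export
trainEmbedding <- function(x, dim = 100L, k = 3L, window = 5L,
                           epochs = 20L, lr = 0.25, seed = 1L) {
  toks <- tokenizeSegments(x, k = k)
  toks <- toks[lengths(toks) >= 2L]
  if (!length(toks))
    stop("corpus is empty or shorter than the context window")
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  V <- length(vocab)
  # one training example per token position: (context index rows, target)
  tgt_l <- vector("list", length(toks))
  ci_l <- vector("list", length(toks))
  cn_l <- vector("list", length(toks))
  ex <- 0L
  for (si in seq_along(toks)) {
    ids <- match(toks[[si]], vocab)
    nt <- length(ids)
    ctx <- vector("list", nt)
    for (p in seq_len(nt))
      ctx[[p]] <- ids[setdiff(max(1L, p - window):min(nt, p + window), p)]
    tgt_l[[si]] <- ids
    ci_l[[si]] <- unlist(ctx, use.names = FALSE)
    cn_l[[si]] <- rep.int(ex + seq_len(nt), lengths(ctx))
    ex <- ex + nt
  }
  tgt <- unlist(tgt_l, use.names = FALSE)
  ci <- unlist(ci_l, use.names = FALSE)
  cn <- unlist(cn_l, use.names = FALSE)
  N <- ex
  # sparse N x V matrix averaging each example's context embeddings
  wts <- 1 / tabulate(cn, nbins = N)[cn]
  C <- Matrix::sparseMatrix(i = cn, j = ci, x = wts, dims = c(N, V))
  Y <- Matrix::sparseMatrix(i = seq_len(N), j = tgt, x = 1,
                            dims = c(N, V))
  set.seed(as.integer(seed))
  Win <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
  Wout <- matrix(0, dim, V)
  Yd <- as.matrix(Y)
  for (e in seq_len(as.integer(epochs))) {
    H <- as.matrix(C %*% Win)            # N x dim
    Z <- H %*% Wout                      # N x V
    Z <- Z - Z[cbind(seq_len(N), max.col(Z, ties.method = "first"))]
    P <- exp(Z)
    P <- P / rowSums(P)
    dZ <- (P - Yd) / N
    dWout <- crossprod(H, dZ)
    dH <- dZ %*% t(Wout)
    dWin <- as.matrix(Matrix::crossprod(C, dH))
    Wout <- Wout - lr * dWout
    Win <- Win - lr * dWin
  }
  rownames(Win) <- vocab
  new("Word2VecModel", vectors = Win, k = as.integer(k),
      window = as.integer(window), epochs = as.integer(epochs),
      seed = as.integer(seed))
}

#' @describeIn Word2VecModel-class Token-by-dimension embedding matrix.
#' @param x,object A `Word2VecModel`.
#' @export
setMethod("tokenVectors", "Word2VecModel", function(x) x@vectors)

#' @describeIn Word2VecModel-class Display a summary.
#' @export
setMethod("show", "Word2VecModel", function(object) {
  cat("Word2VecModel (CBOW):", nrow(object@vectors), "tokens x",
      ncol(object@vectors), "dimensions; k =", object@k,
      ", window =", object@window, ", epochs =", object@epochs, "\n")
})

#' Encode segments as mean k-mer embedding vectors
#'
#' Segments are tokenized exactly as during training; the feature vector
#' is the mean of the token vectors, with out-of-vocabulary tokens
#' contributing zero vectors.
#'
#' @param x [SegmentSet-class] or character vector.
#' @param model A trained [Word2VecModel-class].
#' @return Numeric matrix with columns `W2V_1..W2V_<dim>`.
#' @export
encodeWord2Vec <- function(x, model) {
  stopifnot(is(model, "Word2VecModel"))
  toks <- tokenizeSegments(x, k = model@k)
  W <- model@vectors
  d <- ncol(W)
  out <- t(vapply(toks, function(tk) {
    if (!length(tk)) return(numeric(d))
    idx <- match(tk, rownames(W))
    M <- matrix(0, length(tk), d)
    M[!is.na(idx), ] <- W[idx[!is.na(idx)], , drop = FALSE]
    colMeans(M)
  }, numeric(d)))
  colnames(out) <- paste0("W2V_", seq_len(d))
  rownames(out) <- if (is(x, "SegmentSet")) names(x) else names(toks)
  out
}

#' Write / read an embedding model as plain text
#'
#' The model is stored as a TSV of token vectors plus a JSON config.
#'
#' @param model A [Word2VecModel-class].
#' @param dir Directory to write into (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEmbedding <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(token = rownames(model@vectors), model@vectors),
    file.path(dir, "vectors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(k = model@k, window = model@window, epochs = model@epochs,
         seed = model@seed),
    file.path(dir, "embedding.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(dir) {
  df <- utils::read.delim(file.path(dir, "vectors.tsv"))
  cfg <- jsonlite::read_json(file.path(dir, "embedding.json"),
                             simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$token
  colnames(m) <- NULL
  new("Word2VecModel", vectors = m, k = as.integer(cfg$k),
      window = as.integer(cfg$window), epochs = as.integer(cfg$epochs),
      seed = as.integer(cfg$seed))
}
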