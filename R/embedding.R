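# Residue-level paragraph-vector embeddings. Each protein is a document,
# each residue a word (1-gram); the distributed-memory architecture (PV-DM)
# learns word and document vectors jointly and the word vectors become the
# pre-trained weights of the model's embedding layer. With a 25-word
# vocabulary a full softmax output is cheap, so no negative sampling or
# hierarchical softmax is used and training is exactly reproducible.

#' Build an embedding-training corpus from protein records
#'
#' Converts records to residue-token documents, excluding any record whose
#' sequence string occurs in `exclude` (exact match, id-independent) so the
#' corpus shares no sequence with the interaction data it will serve.
#'
#' @param records Protein records data.frame.
#' @param exclude Optional protein records whose sequences must not appear
#'   in the corpus.
#' @return An object of class `ppi_corpus`: a list of integer token vectors
#'   (tokens 0..24; no padding token).
#' @export
build_corpus <- function(records, exclude = NULL) {
  records <- as_protein_records(records)
  seqs <- toupper(records$sequence)
  if (!is.null(exclude) && nrow(exclude) > 0L)
    seqs <- seqs[!(seqs %in% toupper(exclude$sequence))]
  docs <- lapply(seqs, function(s) tokenize_and_pad(s, nchar(s)))
  structure(docs, class = "ppi_corpus")
}

#' Embedding training configuration
#'
#' @param dim Embedding dimension (default 32, the best-performing value in
#'   the dimension sweep \{8, 16, 32, 64, 128\}).
#' @param epochs Passes over the corpus (default 10).
#' @param window Context half-width in residues (default 5).
#' @param min_count Minimum token count (default 1; the vocabulary has only
#'   25 residue tokens and none may be dropped).
#' @param alpha Learning rate (default 0.05).
#' @param seed Integer seed controlling initialization and document order.
#' @return A list with class `embedding_config`.
#' @export
embedding_config <- function(dim = 32L, epochs = 10L, window = 5L,
                             min_count = 1L, alpha = 0.05, seed = 1L) {
  dim <- as.integer(dim)
  if (dim < 1L) stop("embedding dimension must be positive")
  structure(list(dim = dim, epochs = as.integer(epochs),
                 window = as.integer(window), min_count = as.integer(min_count),
                 alpha = alpha, seed = as.integer(seed)),
            class = "embedding_config")
}

#' Train amino-acid embeddings with the distributed-memory paragraph-vector
#' model
#'
#' For every position of every document, the document vector and the word
#' vectors of the surrounding window are averaged and a full-softmax
#' classifier predicts the center token; word vectors, document vectors and
#' the output weights are updated by stochastic gradient descent (one
#' document per update). Document vectors are discarded; the word vectors
#' are returned as a 26 x dim embedding matrix whose padding row (token 25)
#' is all zeros. Training is single-threaded and bitwise-reproducible from
#' the seed.
#'
#' @param corpus A [build_corpus()] result.
#' @param cfg An [embedding_config()].
#' @return An `embedding_matrix`: 26 x dim numeric matrix, row `t + 1`
#'   holding the vector of token t; row 26 (padding) is zero.
#' @export
train_embeddings <- function(corpus, cfg = embedding_config()) {
  if (!inherits(corpus, "ppi_corpus")) stop("corpus must come from build_corpus()")
  if (length(corpus) == 0L) stop("corpus is empty")
  d <- cfg$dim
  vocab <- 25L  # residue tokens 0..24; padding is never a corpus word
  counts <- tabulate(unlist(corpus) + 1L, vocab)
  keep <- counts >= cfg$min_count
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  W <- matrix(stats::runif(vocab * d, -0.5, 0.5) / d, nrow = vocab) # word vecs
  D <- matrix(stats::runif(length(corpus) * d, -0.5, 0.5) / d,
              nrow = length(corpus))                                # doc vecs
  U <- matrix(0, nrow = d, ncol = vocab)                            # softmax
  win <- cfg$window
  for (epoch in seq_len(cfg$epochs)) {
    order_docs <- sample.int(length(corpus))
    for (di in order_docs) {
      doc <- corpus[[di]] + 1L
      L <- length(doc)
      if (L < 2L) next
      # context of position t: positions j != t with |j - t| <= window,
      # summed via prefix sums over the document's word vectors
      Wdoc <- W[doc, , drop = FALSE]
      cum <- apply(rbind(0, Wdoc), 2L, cumsum)  # (L+1) x d prefix sums
      lo <- pmax(seq_len(L) - win, 1L)
      hi <- pmin(seq_len(L) + win, L)
      ctx_sum <- cum[hi + 1L, , drop = FALSE] - cum[lo, , drop = FALSE] - Wdoc
      ctx_n <- hi - lo  # window size minus the center itself
      denom <- ctx_n + 1L
      H <- (ctx_sum + matrix(D[di, ], L, d, byrow = TRUE)) / denom
      scores <- H %*% U
      scores <- scores - apply(scores, 1L, max)
      P <- exp(scores)
      P <- P / rowSums(P)
      P[cbind(seq_len(L), doc)] <- P[cbind(seq_len(L), doc)] - 1  # dscore
      dU <- crossprod(H, P)
      dH <- P %*% t(U)
      # distribute dH equally over the doc vector and the context words
      dHs <- dH / denom
      D[di, ] <- D[di, ] - cfg$alpha * colSums(dHs)
      # scatter-add the context-word gradient: position j receives the
      # summed dHs of all centers whose window covers j
      cumg <- apply(rbind(0, dHs), 2L, cumsum)
      gword <- cumg[hi + 1L, , drop = FALSE] - cumg[lo, , drop = FALSE] - dHs
      gtok <- rowsum(gword, doc)
      rows <- as.integer(rownames(gtok))
      W[rows, ] <- W[rows, ] - cfg$alpha * gtok
      U <- U - cfg$alpha * dU
    }
  }
  W[!keep, ] <- 0
  out <- rbind(W, 0)  # padding row, token 25
  rownames(out) <- c(AA_STANDARD, AA_NONSTANDARD, "-")
  structure(out, class = "embedding_matrix")
}

#' Save an embedding matrix as headered TSV
#'
#' @param matrix An `embedding_matrix` (26 x dim).
#' @param path Output path.
#' @export
save_embeddings <- function(matrix, path) {
  check_embedding_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dfppi-embeddings v1 vocab=%d dim=%d",
                     nrow(matrix), ncol(matrix)), con)
  writeLines(paste(c("token", paste0("d", seq_len(ncol(matrix)))),
                   collapse = "\t"), con)
  lines <- vapply(seq_len(nrow(matrix)), function(i)
    paste(c(rownames(matrix)[i],
            formatC(matrix[i, ], format = "g", digits = 17)), collapse = "\t"),
    "")
  writeLines(lines, con)
  invisible(path)
}

#' Load an embedding matrix written by [save_embeddings()]
#'
#' @param path Path to the TSV file.
#' @param expect_dim Optional dimension the consumer requires; a mismatch is
#'   an error naming both dimensions.
#' @return An `embedding_matrix`.
#' @export
load_embeddings <- function(path, expect_dim = NULL) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#dfppi-embeddings v1 ", header))
    stop("not a dfppi embedding file: ", path)
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  dimnames(m)[[2]] <- NULL
  if (nrow(m) != TOKEN_VOCAB_SIZE)
    stop("embedding vocabulary must have ", TOKEN_VOCAB_SIZE,
         " rows, found ", nrow(m))
  if (!is.null(expect_dim) && ncol(m) != expect_dim)
    stop("embedding dimension ", ncol(m),
         " does not match the expected dimension ", expect_dim)
  structure(m, class = "embedding_matrix")
}

check_embedding_matrix <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != TOKEN_VOCAB_SIZE)
    stop("an embedding matrix must have ", TOKEN_VOCAB_SIZE, " rows")
  if (any(matrix[TOKEN_PAD + 1L, ] != 0))
    stop("the padding row of an embedding matrix must be all zeros")
  if (!all(is.finite(matrix))) stop("embedding matrix contains non-finite values")
  invisible(matrix)
}
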