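# Static unigram word embeddings: skip-gram with negative sampling, trained on
# the training split only. Written in vectorised base R; gradient updates are
# aggregated over mini-chunks of (center, context) pairs, which converges to
# the same solution as per-pair SGD at these learning rates.

#' Train static word embeddings on the training split
#'
#' Learns skip-gram-with-negative-sampling embeddings from the sentences of
#' the training-split documents only, so the vocabulary can never leak tokens
#' that occur exclusively in the tuning or testing folds. Embeddings are
#' static: downstream model training never modifies them.
#'
#' @param train_documents List of `soep_document`s from the training fold.
#' @param dim Embedding dimension (>= 2).
#' @param window Symmetric context window size.
#' @param min_count Minimum training-split token frequency for vocabulary
#'   membership.
#' @param epochs Passes over the (center, context) pairs.
#' @param seed Integer seed; training is deterministic (single worker).
#' @param negative Negative samples per positive pair.
#' @param learning_rate Initial SGD learning rate, decayed linearly.
#' @param subsample Frequent-word subsampling threshold `t`: an occurrence of
#'   a token with corpus frequency `f` is kept with probability
#'   `min(1, sqrt(t / f))`. Set to `Inf` to disable.
#' @param normalize Post-process the final vectors: subtract the mean vector,
#'   remove the `remove_top` dominant principal components, and L2-normalize
#'   rows. Skip-gram vectors trained on small corpora are strongly
#'   anisotropic (a few global directions swamp token identity); this
#'   all-but-the-top style correction restores the isotropy downstream
#'   encoders need.
#' @param remove_top Number of dominant components removed when
#'   `normalize = TRUE`.
#' @return A list of class `"embedding_model"`: `vocab` (token -> row index),
#'   `matrix` (V x d, rownames are tokens), `dim`, `window`, `min_count`,
#'   `seed`. Out-of-vocabulary lookup returns the all-zeros UNK vector.
#' @export
train_embeddings <- function(train_documents, dim = 100L, window = 5L,
                             min_count = 5L, epochs = 5L, seed = 1L,
                             negative = 5L, learning_rate = 0.025,
                             subsample = 1e-3, normalize = TRUE,
                             remove_top = 3L) {
  if (length(train_documents) == 0L) stop_config("train_embeddings: empty corpus")
  stopifnot(dim >= 2L, window >= 1L, epochs >= 0L)
  sentences <- unlist(lapply(train_documents, function(d) d$sentences),
                      recursive = FALSE)
  tokens <- unlist(sentences, use.names = FALSE)
  if (length(tokens) == 0L) stop_config("train_embeddings: empty corpus")
  freq <- table(tokens)
  freq <- freq[freq >= min_count]
  if (length(freq) == 0L) {
    stop_config("train_embeddings: empty vocabulary (min_count=%d exceeds all token frequencies)",
                min_count)
  }
  freq <- freq[order(-as.integer(freq), names(freq))]
  vocab <- stats::setNames(seq_along(freq), names(freq))
  V <- length(vocab)

  # integer sequences per sentence, OOV dropped
  seqs <- lapply(sentences, function(s) {
    ix <- unname(vocab[s])
    ix[!is.na(ix)]
  })
  seqs <- seqs[lengths(seqs) >= 2L]

  with_seed(seed, {
    # frequent-word subsampling: thins the Zipf head (and the ubiquitous
    # SOEP marker tokens) so rarer tokens get a fair share of updates
    if (is.finite(subsample)) {
      n_tok <- sum(lengths(seqs))
      keep_p <- pmin(1, sqrt(subsample / (as.numeric(freq) / n_tok)))
      seqs <- lapply(seqs, function(s) s[stats::runif(length(s)) < keep_p[s]])
      seqs <- seqs[lengths(seqs) >= 2L]
    }

    # (center, context) pairs for all symmetric offsets up to `window`
    centers <- integer(0); contexts <- integer(0)
    for (off in seq_len(window)) {
      long <- seqs[lengths(seqs) > off]
      if (length(long) == 0L) next
      a <- unlist(lapply(long, function(s) s[seq_len(length(s) - off)]),
                  use.names = FALSE)
      b <- unlist(lapply(long, function(s) s[(off + 1L):length(s)]),
                  use.names = FALSE)
      centers <- c(centers, a, b)
      contexts <- c(contexts, b, a)
    }

    W <- matrix(stats::runif(V * dim, -0.5 / dim, 0.5 / dim), V, dim)
    C <- matrix(0, V, dim)
    n_pairs <- length(centers)
    if (n_pairs > 0L && epochs > 0L) {
      noise <- as.numeric(freq)^0.75
      noise <- noise / sum(noise)
      # small chunks approximate sequential per-pair SGD (stale reads over a
      # few dozen pairs are negligible); large chunks either cancel the
      # structure-bearing update components (averaging) or blow up on
      # frequent tokens (summing)
      chunk <- 64L
      n_chunks_total <- epochs * ceiling(n_pairs / chunk)
      done <- 0L
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n_pairs)
        for (start in seq(1L, n_pairs, by = chunk)) {
          take <- ord[start:min(start + chunk - 1L, n_pairs)]
          m <- length(take)
          lr <- learning_rate * max(1e-4, 1 - done / n_chunks_total)
          ci <- centers[take]; oi <- contexts[take]
          vc <- W[ci, , drop = FALSE]
          uo <- C[oi, , drop = FALSE]
          gpos <- sigmoid(rowSums(vc * uo)) - 1
          ni <- sample.int(V, m * negative, replace = TRUE, prob = noise)
          rep_ix <- rep.int(seq_len(m), negative)
          vcr <- vc[rep_ix, , drop = FALSE]
          un <- C[ni, , drop = FALSE]
          gneg <- sigmoid(rowSums(vcr * un))
          dW <- rowsum(rbind(gpos * uo, gneg * un), c(ci, ci[rep_ix]))
          wi <- as.integer(rownames(dW))
          W[wi, ] <- W[wi, ] - lr * dW
          dC <- rowsum(rbind(gpos * vc, gneg * vcr), c(oi, ni))
          ui <- as.integer(rownames(dC))
          C[ui, ] <- C[ui, ] - lr * dC
          done <- done + 1L
        }
      }
    }
    if (normalize) {
      W <- sweep(W, 2, colMeans(W))
      k <- min(remove_top, dim - 1L)
      if (k > 0L) {
        sv <- svd(W, nu = 0, nv = k)
        W <- W - (W %*% sv$v) %*% t(sv$v)
      }
      nrm <- sqrt(rowSums(W^2))
      nz <- nrm > 0
      W[nz, ] <- W[nz, , drop = FALSE] / nrm[nz]
    }
    rownames(W) <- names(vocab)
    model <- list(vocab = vocab, matrix = W, dim = as.integer(dim),
                  window = as.integer(window), min_count = as.integer(min_count),
                  seed = as.integer(seed))
    class(model) <- "embedding_model"
    model
  })
}

#' Look up the embedding of a token
#'
#' In-vocabulary tokens return their matrix row; any other token returns the
#' designated UNK vector (all zeros), never an error, so tuning/testing-fold
#' novelties contribute nothing to the recurrent input.
#'
#' @param model An `embedding_model`.
#' @param token A single token.
#' @return Numeric vector of length `model$dim`.
#' @export
embedding_lookup <- function(model, token) {
  i <- model$vocab[token]
  if (length(i) == 1L && !is.na(i)) model$matrix[i, ] else numeric(model$dim)
}

# Token vector -> embedding row indices, 0 = UNK.
token_indices <- function(model, tokens) {
  ix <- unname(model$vocab[tokens])
  ix[is.na(ix)] <- 0L
  as.integer(ix)
}

#' Persist / load embeddings in the plain-text word2vec format
#'
#' Header line `"V d"`, then one line per token: the token followed by `d`
#' floats.
#'
#' @param model An `embedding_model`.
#' @param path File path.
#' @return `write_embeddings()` returns `path` invisibly; `read_embeddings()`
#'   an `embedding_model` (with `window`/`min_count`/`seed` metadata set to
#'   `NA`, which the file format does not carry).
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- nrow(model$matrix)
  writeLines(sprintf("%d %d", V, model$dim), con)
  for (i in seq_len(V)) {
    writeLines(paste(rownames(model$matrix)[i],
                     paste(sprintf("%.9g", model$matrix[i, ]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  V <- hdr[1]; d <- hdr[2]
  toks <- character(V)
  W <- matrix(0, V, d)
  for (i in seq_len(V)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    toks[i] <- parts[1]
    W[i, ] <- as.numeric(parts[-1])
  }
  rownames(W) <- toks
  model <- list(vocab = stats::setNames(seq_len(V), toks), matrix = W,
                dim = d, window = NA_integer_, min_count = NA_integer_,
                seed = NA_integer_)
  class(model) <- "embedding_model"
  model
}
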