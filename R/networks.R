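# Model architectures: hierarchical attention networks (text-only and
# late-fusion combined) and the four ablations (hierarchy-without-attention,
# flat BiLSTM, phrase-skip-gram neural network, two-layer CNN). Each is a pure
# forward computation over embedded documents plus a matching hand-written
# backward pass; static embeddings are frozen (no gradient reaches them).

MODEL_KINDS <- c("han_text", "han_combined", "hn", "lstm", "psgnn", "cnn")

#' Architecture configuration
#'
#' @param kind One of `"han_text"`, `"han_combined"`, `"hn"` (hierarchy
#'   without attention), `"lstm"` (flat BiLSTM), `"psgnn"` (phrase skip-gram
#'   neural network), `"cnn"` (two-layer convolutional network).
#' @param embed_dim Embedding dimension (must match the embedding model).
#' @param word_hidden,sent_hidden Per-direction recurrent widths of the word-
#'   and sentence-level BiLSTM encoders.
#' @param attn_dim Attention projection dimension.
#' @param struct_hidden Width of the ReLU hidden layer over structured
#'   predictors (combined model only).
#' @param n_struct Length of the structured predictor vector (default 13:
#'   age, sex and the 11 ICPC code counts).
#' @param lambda_rep Target-replication factor, in \[0, 1\].
#' @param dropout Dropout probability on the document representation during
#'   training.
#' @param seed Seed for parameter initialisation.
#' @param cnn_filters Filter counts of the two convolution layers.
#' @param cnn_kernel Convolution kernel width (odd).
#' @param psg_hidden Hidden width of the phrase network.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(kind = "han_text", embed_dim = 100L,
                         word_hidden = 50L, sent_hidden = 50L,
                         attn_dim = 100L, struct_hidden = 16L,
                         n_struct = 13L, lambda_rep = 0.5, dropout = 0,
                         seed = 1L, cnn_filters = c(32L, 32L),
                         cnn_kernel = 3L, psg_hidden = 32L) {
  kind <- match.arg(kind, MODEL_KINDS)
  widths <- c(embed_dim, word_hidden, sent_hidden, attn_dim, struct_hidden,
              n_struct, cnn_filters, cnn_kernel, psg_hidden)
  if (any(widths < 1)) stop_config("model_config: widths must be positive")
  if (!is.numeric(lambda_rep) || lambda_rep < 0 || lambda_rep > 1) {
    stop_config("model_config: lambda_rep must be in [0, 1]")
  }
  if (dropout < 0 || dropout >= 1) stop_config("model_config: dropout must be in [0, 1)")
  cfg <- list(kind = kind, embed_dim = as.integer(embed_dim),
              word_hidden = as.integer(word_hidden),
              sent_hidden = as.integer(sent_hidden),
              attn_dim = as.integer(attn_dim),
              struct_hidden = as.integer(struct_hidden),
              n_struct = as.integer(n_struct), lambda_rep = lambda_rep,
              dropout = dropout, seed = as.integer(seed),
              cnn_filters = as.integer(cnn_filters),
              cnn_kernel = as.integer(cnn_kernel),
              psg_hidden = as.integer(psg_hidden))
  class(cfg) <- "model_config"
  cfg
}

init_params <- function(cfg) {
  with_seed(cfg$seed, {
    d <- cfg$embed_dim
    switch(cfg$kind,
      han_text = ,
      han_combined = ,
      hn = {
        p <- list(
          word_rnn = init_bilstm(d, cfg$word_hidden),
          sent_rnn = init_bilstm(2L * cfg$word_hidden, cfg$sent_hidden),
          visit_head = init_head(2L * cfg$sent_hidden)
        )
        if (cfg$kind != "hn") {
          p$word_attn <- init_attn(2L * cfg$word_hidden, cfg$attn_dim)
          p$sent_attn <- init_attn(2L * cfg$sent_hidden, cfg$attn_dim)
        }
        out_dim <- 2L * cfg$sent_hidden
        if (cfg$kind == "han_combined") {
          p$struct <- init_dense(cfg$n_struct, cfg$struct_hidden)
          out_dim <- out_dim + cfg$struct_hidden
        }
        p$out <- init_head(out_dim)
        p
      },
      lstm = list(
        word_rnn = init_bilstm(d, cfg$word_hidden),
        visit_head = init_head(2L * cfg$word_hidden),
        out = init_head(2L * cfg$word_hidden)
      ),
      psgnn = list(
        hidden = init_dense(3L * d, cfg$psg_hidden),
        out = init_head(cfg$psg_hidden)
      ),
      cnn = list(
        conv1 = init_dense(cfg$cnn_kernel * d, cfg$cnn_filters[1]),
        conv2 = init_dense(cfg$cnn_kernel * cfg$cnn_filters[1], cfg$cnn_filters[2]),
        visit_head = init_head(cfg$cnn_filters[2]),
        out = init_head(cfg$cnn_filters[2])
      )
    )
  })
}

#' Build a network (main architectures and ablations)
#'
#' Constructs an untrained network of the requested kind with freshly
#' initialised parameters. `build_ablation()` is an alias restricted to the
#' four ablation kinds.
#'
#' @param config A [model_config()].
#' @return A list of class `"han_network"` with `config` and `params`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config, params = init_params(config)),
            class = "han_network")
}

#' @rdname build_network
#' @param kind Ablation kind: `"hn"`, `"lstm"`, `"psgnn"` or `"cnn"`.
#' @export
build_ablation <- function(kind, config = model_config(kind)) {
  kind <- match.arg(kind, c("hn", "lstm", "psgnn", "cnn"))
  config$kind <- kind
  build_network(config)
}

#' Architectural feature flags by introspection
#'
#' Inspects a built network's parameter groups and reports which of the three
#' design features it realises: a word/sentence hierarchy (a second-level
#' encoder), attention pooling, and target replication (a per-visit
#' probability head).
#'
#' @param network A `"han_network"` (or fitted `"han_fit"`).
#' @return Named logical vector `c(hierarchical=, attention=, replication=)`.
#' @export
model_features <- function(network) {
  p <- network$params
  c(hierarchical = !is.null(p$sent_rnn) || !is.null(p$conv2),
    attention = !is.null(p$word_attn) || !is.null(p$sent_attn),
    replication = !is.null(p$visit_head))
}

n_parameters <- function(network) length(unlist(network$params))

# ---- document batching ---------------------------------------------------

# Convert documents to embedding-row indices once; row 0 means UNK.
index_documents <- function(documents, emb) {
  lapply(documents, function(d) {
    list(patient_id = d$patient_id,
         sent_idx = lapply(d$sentences, function(s) token_indices(emb, s)),
         structured = d$structured,
         label = as.integer(d$label))
  })
}

# Word-level batch for one document: all sentences in parallel, right-padded.
# The padded embedding matrix has the UNK zero-row first, so index+1 maps
# UNK (0) to the zero vector.
doc_word_batch <- function(idoc, EMB) {
  lens <- lengths(idoc$sent_idx)
  S <- length(lens)
  Tmax <- max(lens)
  idx <- matrix(0L, S, Tmax)
  for (s in seq_len(S)) {
    if (lens[s] > 0L) idx[s, seq_len(lens[s])] <- idoc$sent_idx[[s]]
  }
  M <- outer(seq_len(S), seq_len(Tmax), function(s, t) t <= lens[s])
  X <- lapply(seq_len(Tmax), function(t) EMB[idx[, t] + 1L, , drop = FALSE])
  list(X = X, M = M, lens = lens)
}

padded_embeddings <- function(emb) rbind(numeric(emb$dim), emb$matrix)

# ---- exported encoder operations ----------------------------------------

#' Encode one sentence (word level)
#'
#' Bidirectional recurrent encoding of the word vectors followed by additive
#' attention: `u_t = tanh(W h_t + b)`, `alpha = softmax(u_t . v)` over
#' unmasked positions, sentence vector `sum_t alpha_t h_t`. Masked positions
#' receive zero attention; an all-masked sentence is an error.
#'
#' @param word_vectors `T x d` matrix of word embeddings.
#' @param mask Logical vector of length `T` (`TRUE` = real token).
#' @param params List with `rnn` (BiLSTM parameters) and, unless
#'   `pooling = "mean"`, `attn` (attention parameters), as produced inside
#'   [build_network()].
#' @param pooling `"attention"` or `"mean"`.
#' @return List with `sentence_vector` (length `2 * word_hidden`) and
#'   `word_attention` (length `T`, summing to 1 over unmasked positions).
#' @export
encode_sentence <- function(word_vectors, mask = NULL, params,
                            pooling = c("attention", "mean")) {
  pooling <- match.arg(pooling)
  Tn <- nrow(word_vectors)
  if (is.null(mask)) mask <- rep(TRUE, Tn)
  if (!any(mask)) stop_config("encode_sentence: all positions are masked")
  X <- lapply(seq_len(Tn), function(t) word_vectors[t, , drop = FALSE])
  M <- matrix(mask, 1L, Tn)
  wb <- bilstm_forward(X, M, params$rnn)
  pool <- if (pooling == "attention") attn_forward(wb$H, M, params$attn)
          else meanpool_forward(wb$H, M)
  list(sentence_vector = as.numeric(pool$ctx),
       word_attention = as.numeric(pool$alpha))
}

#' Encode a document (sentence level)
#'
#' Same recurrent + attention scheme applied to the sequence of sentence
#' vectors; additionally returns the per-visit recurrent states used by the
#' target-replication heads.
#'
#' @param sentence_vectors `S x D` matrix of sentence vectors (date order).
#' @param mask Logical vector of length `S`.
#' @param params List with `rnn` and (for attention pooling) `attn`.
#' @inheritParams encode_sentence
#' @return List with `doc_vector`, `visit_states` (`S x 2*sent_hidden`) and
#'   `sentence_attention`.
#' @export
encode_document <- function(sentence_vectors, mask = NULL, params,
                            pooling = c("attention", "mean")) {
  pooling <- match.arg(pooling)
  S <- nrow(sentence_vectors)
  if (is.null(mask)) mask <- rep(TRUE, S)
  if (!any(mask)) stop_config("encode_document: all sentences are masked")
  X <- lapply(seq_len(S), function(i) sentence_vectors[i, , drop = FALSE])
  M <- matrix(mask, 1L, S)
  sb <- bilstm_forward(X, M, params$rnn)
  pool <- if (pooling == "attention") attn_forward(sb$H, M, params$attn)
          else meanpool_forward(sb$H, M)
  list(doc_vector = as.numeric(pool$ctx),
       visit_states = do.call(rbind, sb$H),
       sentence_attention = as.numeric(pool$alpha))
}

# ---- per-architecture forward passes -------------------------------------

head_logit <- function(z, head) sum(z * head$w) + head$b

# Forward pass for one indexed document. Returns the forward output plus the
# caches needed by the backward pass. `drop_mask` (NULL outside training)
# implements inverted dropout on the document representation.
forward_doc <- function(params, cfg, idoc, EMB, drop_mask = NULL,
                        structured = NULL) {
  if (!is.null(structured) && !cfg$kind %in% "han_combined") {
    stop_config("structured input supplied to text-only model kind '%s'", cfg$kind)
  }
  switch(cfg$kind,
    han_text = ,
    han_combined = ,
    hn = forward_han(params, cfg, idoc, EMB, drop_mask, structured),
    lstm = forward_flat_lstm(params, cfg, idoc, EMB, drop_mask),
    psgnn = forward_psgnn(params, cfg, idoc, EMB, drop_mask),
    cnn = forward_cnn(params, cfg, idoc, EMB, drop_mask)
  )
}

apply_head_and_fuse <- function(params, cfg, doc_vec, idoc, drop_mask,
                                structured = NULL) {
  z <- doc_vec
  struct_cache <- NULL
  if (cfg$kind == "han_combined") {
    x <- structured %||% as.numeric(idoc$structured)
    if (length(x) != cfg$n_struct) {
      stop_config("expected %d structured predictors, got %d", cfg$n_struct, length(x))
    }
    a <- as.numeric(x %*% params$struct$W) + params$struct$b
    r <- relu(a)
    struct_cache <- list(x = x, a = a)
    z <- c(doc_vec, r)
  }
  if (!is.null(drop_mask)) z <- z * drop_mask
  logit <- head_logit(z, params$out)
  list(z = z, logit = logit, prob = sigmoid(logit), struct_cache = struct_cache)
}

forward_han <- function(params, cfg, idoc, EMB, drop_mask, structured) {
  wbatch <- doc_word_batch(idoc, EMB)
  attn <- cfg$kind != "hn"
  wb <- bilstm_forward(wbatch$X, wbatch$M, params$word_rnn)
  wpool <- if (attn) attn_forward(wb$H, wbatch$M, params$word_attn)
           else meanpool_forward(wb$H, wbatch$M)
  SV <- wpool$ctx # S x 2wh
  S <- nrow(SV)
  X2 <- lapply(seq_len(S), function(i) SV[i, , drop = FALSE])
  M2 <- matrix(TRUE, 1L, S)
  sb <- bilstm_forward(X2, M2, params$sent_rnn)
  spool <- if (attn) attn_forward(sb$H, M2, params$sent_attn)
           else meanpool_forward(sb$H, M2)
  doc_vec <- as.numeric(spool$ctx)
  visit_states <- do.call(rbind, sb$H) # S x 2sh
  visit_logits <- as.numeric(visit_states %*% params$visit_head$w) +
    params$visit_head$b
  out <- apply_head_and_fuse(params, cfg, doc_vec, idoc, drop_mask, structured)
  list(final_prob = out$prob, visit_probs = sigmoid(visit_logits),
       word_attention = wpool$alpha, sentence_attention = as.numeric(spool$alpha),
       cache = list(wbatch = wbatch, wb = wb, wpool = wpool, SV = SV,
                    X2 = X2, M2 = M2, sb = sb, spool = spool,
                    visit_states = visit_states, out = out,
                    drop_mask = drop_mask))
}

forward_flat_lstm <- function(params, cfg, idoc, EMB, drop_mask) {
  wbatch <- doc_word_batch(idoc, EMB)
  wb <- bilstm_forward(wbatch$X, wbatch$M, params$word_rnn)
  wpool <- meanpool_forward(wb$H, wbatch$M)
  SV <- wpool$ctx # S x 2wh, one vector per note
  S <- nrow(SV)
  doc_vec <- colMeans(SV)
  visit_logits <- as.numeric(SV %*% params$visit_head$w) + params$visit_head$b
  out <- apply_head_and_fuse(params, cfg, doc_vec, idoc, drop_mask)
  list(final_prob = out$prob, visit_probs = sigmoid(visit_logits),
       word_attention = wpool$alpha, sentence_attention = rep(1 / S, S),
       cache = list(wbatch = wbatch, wb = wb, SV = SV, out = out,
                    drop_mask = drop_mask))
}

# Concatenated word stream of a document plus the visit span of each word.
doc_word_stream <- function(idoc, EMB) {
  idx <- unlist(idoc$sent_idx, use.names = FALSE)
  spans <- rep.int(seq_along(idoc$sent_idx), lengths(idoc$sent_idx))
  X <- EMB[idx + 1L, , drop = FALSE]
  list(X = X, spans = spans)
}

forward_psgnn <- function(params, cfg, idoc, EMB, drop_mask) {
  st <- doc_word_stream(idoc, EMB)
  X <- st$X
  d <- ncol(X)
  if (nrow(X) < 3L) X <- rbind(X, matrix(0, 3L - nrow(X), d))
  np <- nrow(X) - 2L
  P <- cbind(X[seq_len(np), , drop = FALSE],
             X[1L + seq_len(np), , drop = FALSE],
             X[2L + seq_len(np), , drop = FALSE])
  A <- P %*% params$hidden$W + rep(params$hidden$b, each = np)
  Hh <- relu(A)
  doc_vec <- colMeans(Hh)
  out <- apply_head_and_fuse(params, cfg, doc_vec, idoc, drop_mask)
  list(final_prob = out$prob, visit_probs = NULL,
       word_attention = NULL, sentence_attention = NULL, n_phrases = np,
       cache = list(P = P, A = A, Hh = Hh, out = out, drop_mask = drop_mask))
}

forward_cnn <- function(params, cfg, idoc, EMB, drop_mask) {
  st <- doc_word_stream(idoc, EMB)
  k <- cfg$cnn_kernel
  U1 <- unfold_seq(st$X, k)
  Z1 <- U1 %*% params$conv1$W + rep(params$conv1$b, each = nrow(U1))
  C1 <- relu(Z1)
  U2 <- unfold_seq(C1, k)
  Z2 <- U2 %*% params$conv2$W + rep(params$conv2$b, each = nrow(U2))
  C2 <- relu(Z2)
  S <- length(idoc$sent_idx)
  visit_pool <- lapply(seq_len(S), function(i) {
    rows <- which(st$spans == i)
    if (length(rows) == 0L) return(NULL)
    maxpool_rows(C2, rows)
  })
  keep <- !vapply(visit_pool, is.null, logical(1))
  doc_pool <- maxpool_rows(C2, seq_len(nrow(C2)))
  doc_vec <- doc_pool$v
  Vmat <- do.call(rbind, lapply(visit_pool[keep], function(p) p$v))
  visit_logits <- as.numeric(Vmat %*% params$visit_head$w) + params$visit_head$b
  out <- apply_head_and_fuse(params, cfg, doc_vec, idoc, drop_mask)
  list(final_prob = out$prob, visit_probs = sigmoid(visit_logits),
       word_attention = NULL, sentence_attention = NULL,
       cache = list(st = st, U1 = U1, Z1 = Z1, C1 = C1, U2 = U2, Z2 = Z2,
                    C2 = C2, visit_pool = visit_pool, keep = keep,
                    doc_pool = doc_pool, out = out, drop_mask = drop_mask))
}
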