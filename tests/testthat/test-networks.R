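# Architecture contracts: attention normalisation, padding invariance,
# dimension bookkeeping, ablation structure, order sensitivity.

han_params_for <- function(kind = "han_text", d = 8L) {
  cfg <- model_config(kind, embed_dim = d, word_hidden = 4, sent_hidden = 3,
                      attn_dim = 5, struct_hidden = 4, seed = 11,
                      cnn_filters = c(4, 4), psg_hidden = 4)
  list(cfg = cfg, params = hanrisk:::init_params(cfg))
}

test_that("word attention is a proper distribution over unmasked positions", {
  m <- han_params_for()
  wp <- list(rnn = m$params$word_rnn, attn = m$params$word_attn)
  # singleton: softmax of one element
  one <- encode_sentence(matrix(rnorm(8), 1), params = wp)
  expect_identical(one$word_attention, 1)
  # identical recurrent states at every position (forced by zeroed encoder
  # weights, so no state accumulates) give uniform attention by symmetry
  wp0 <- wp
  for (dir in c("fwd", "bwd")) {
    wp0$rnn[[dir]]$Wh[] <- 0
    wp0$rnn[[dir]]$Wx[] <- 0
    wp0$rnn[[dir]]$b[] <- 0
  }
  same <- encode_sentence(matrix(rep(rnorm(8), each = 5), 5, byrow = FALSE),
                          params = wp0)
  expect_equal(same$word_attention, rep(0.2, 5), tolerance = 1e-12)
  # random case: weights sum to one and match the direct formula
  set.seed(2)
  X <- matrix(rnorm(6 * 8), 6)
  out <- encode_sentence(X, params = wp)
  expect_equal(sum(out$word_attention), 1, tolerance = 1e-9)
  # independent reference: softmax(tanh(H W + b) . v) then weighted state sum
  Xl <- lapply(1:6, function(t) X[t, , drop = FALSE])
  H <- hanrisk:::bilstm_forward(Xl, matrix(TRUE, 1, 6), wp$rnn)$H
  Hm <- do.call(rbind, H)
  u <- tanh(sweep(Hm %*% wp$attn$Wa, 2, wp$attn$ba, `+`))
  s <- drop(u %*% wp$attn$v)
  alpha_ref <- exp(s - max(s)) / sum(exp(s - max(s)))
  expect_equal(out$word_attention, alpha_ref, tolerance = 1e-10)
  expect_equal(out$sentence_vector, drop(alpha_ref %*% Hm), tolerance = 1e-10)
})

test_that("document encoder returns attention, states and the weighted sum", {
  m <- han_params_for()
  sp <- list(rnn = m$params$sent_rnn, attn = m$params$sent_attn)
  one <- encode_document(matrix(rnorm(8), 1), params = sp)
  expect_identical(one$sentence_attention, 1)
  expect_equal(one$doc_vector, drop(one$visit_states), tolerance = 1e-12)
  set.seed(3)
  SV <- matrix(rnorm(4 * 8), 4)
  out <- encode_document(SV, params = sp)
  expect_equal(sum(out$sentence_attention), 1, tolerance = 1e-9)
  expect_equal(out$doc_vector,
               drop(out$sentence_attention %*% out$visit_states),
               tolerance = 1e-10)
  expect_error(encode_document(SV, mask = rep(FALSE, 4), params = sp),
               "masked")
})

test_that("appending padded positions never changes encoder output", {
  m <- han_params_for()
  wp <- list(rnn = m$params$word_rnn, attn = m$params$word_attn)
  set.seed(4)
  X <- matrix(rnorm(5 * 8), 5)
  base <- encode_sentence(X, params = wp)
  padded <- encode_sentence(rbind(X, matrix(0, 3, 8)),
                            mask = c(rep(TRUE, 5), rep(FALSE, 3)),
                            params = wp)
  expect_equal(padded$sentence_vector, base$sentence_vector, tolerance = 1e-6)
  expect_equal(padded$word_attention[1:5], base$word_attention,
               tolerance = 1e-6)
  expect_identical(padded$word_attention[6:8], rep(0, 3))
  # same at the document level, and with mean pooling
  sp <- list(rnn = m$params$sent_rnn, attn = m$params$sent_attn)
  SV <- matrix(rnorm(3 * 8), 3)
  b2 <- encode_document(SV, params = sp)
  p2 <- encode_document(rbind(SV, matrix(9, 2, 8)),
                        mask = c(TRUE, TRUE, TRUE, FALSE, FALSE), params = sp)
  expect_equal(p2$doc_vector, b2$doc_vector, tolerance = 1e-6)
  hn <- han_params_for("hn")
  mp <- list(rnn = hn$params$word_rnn)
  b3 <- encode_sentence(X, params = mp, pooling = "mean")
  p3 <- encode_sentence(rbind(X, matrix(7, 2, 8)),
                        mask = c(rep(TRUE, 5), FALSE, FALSE),
                        params = mp, pooling = "mean")
  expect_equal(p3$sentence_vector, b3$sentence_vector, tolerance = 1e-6)
})

test_that("forward pass honours the output-head contract", {
  emb <- toy_embeddings()
  EMB <- hanrisk:::padded_embeddings(emb)
  set.seed(5)
  doc <- toy_document(S = 3)
  idoc <- hanrisk:::index_documents(list(doc), emb)[[1]]
  # all-zero parameters: sigmoid(0) = 0.5 exactly
  m <- han_params_for()
  zero <- utils::relist(rep(0, length(unlist(m$params))), m$params)
  out <- hanrisk:::forward_doc(zero, m$cfg, idoc, EMB)
  expect_identical(out$final_prob, 0.5)
  expect_identical(unique(out$visit_probs), 0.5)
  # probabilities in (0,1); attention rows sum to 1 over unmasked positions
  out2 <- hanrisk:::forward_doc(m$params, m$cfg, idoc, EMB)
  expect_true(out2$final_prob > 0 && out2$final_prob < 1)
  expect_true(all(out2$visit_probs > 0 & out2$visit_probs < 1))
  expect_equal(unname(rowSums(out2$word_attention)), rep(1, 3),
               tolerance = 1e-9)
  expect_equal(sum(out2$sentence_attention), 1, tolerance = 1e-9)
})

test_that("combined model fuses text and structured branches with the right widths", {
  mc <- han_params_for("han_combined")
  emb <- toy_embeddings()
  EMB <- hanrisk:::padded_embeddings(emb)
  set.seed(6)
  idoc <- hanrisk:::index_documents(list(toy_document(S = 2)), emb)[[1]]
  out <- hanrisk:::forward_doc(mc$params, mc$cfg, idoc, EMB)
  # fused vector length = 2*sent_hidden + struct_hidden
  expect_length(mc$params$out$w, 2 * mc$cfg$sent_hidden + mc$cfg$struct_hidden)
  expect_length(out$cache$out$z, 2 * 3 + 4)
  # default config accepts the 13 structured predictors
  def <- model_config("han_combined", embed_dim = 8)
  expect_identical(def$n_struct, 13L)
  expect_length(idoc$structured, 13L)
  # structured input to a text-only kind is an error
  mt <- han_params_for("han_text")
  expect_error(
    hanrisk:::forward_doc(mt$params, mt$cfg, idoc, EMB,
                          structured = idoc$structured),
    "text-only")
  # wrong structured width is an error
  expect_error(
    hanrisk:::forward_doc(mc$params, mc$cfg, idoc, EMB,
                          structured = numeric(5)),
    "structured predictors")
})

test_that("ablations realise the published feature matrix", {
  feats <- t(vapply(c(han_text = "han_text", hn = "hn", lstm = "lstm",
                      psgnn = "psgnn", cnn = "cnn"), function(k) {
    model_features(build_network(model_config(k, embed_dim = 8)))
  }, logical(3)))
  expected <- rbind(
    han_text = c(hierarchical = TRUE, attention = TRUE, replication = TRUE),
    hn = c(TRUE, FALSE, TRUE),
    lstm = c(FALSE, FALSE, TRUE),
    psgnn = c(FALSE, FALSE, FALSE),
    cnn = c(TRUE, FALSE, TRUE)
  )
  colnames(expected) <- c("hierarchical", "attention", "replication")
  expect_identical(feats, expected)
})

test_that("removing attention removes exactly the attention parameters", {
  han <- build_network(model_config("han_text", embed_dim = 8,
                                    word_hidden = 4, sent_hidden = 3,
                                    attn_dim = 5))
  hn <- build_ablation("hn", model_config("hn", embed_dim = 8,
                                          word_hidden = 4, sent_hidden = 3,
                                          attn_dim = 5))
  expect_false(any(grepl("attn", names(unlist(hn$params)))))
  n_attn <- length(unlist(han$params[c("word_attn", "sent_attn")]))
  expect_identical(hanrisk:::n_parameters(han),
                   hanrisk:::n_parameters(hn) + n_attn)
  expect_error(build_ablation("transformer"), "arg")
})

test_that("the phrase network slides one window over a 3-word document", {
  m <- han_params_for("psgnn")
  emb <- toy_embeddings()
  EMB <- hanrisk:::padded_embeddings(emb)
  doc <- structure(list(patient_id = "P1",
                        sentences = list(c("t1", "t2", "t3")),
                        structured = numeric(13), label = 0L),
                   class = "soep_document")
  idoc <- hanrisk:::index_documents(list(doc), emb)[[1]]
  out <- hanrisk:::forward_doc(m$params, m$cfg, idoc, EMB)
  expect_identical(out$n_phrases, 1L)
  expect_null(out$visit_probs)
})

test_that("sentence order changes the hierarchical output but not the flat mean", {
  emb <- toy_embeddings()
  EMB <- hanrisk:::padded_embeddings(emb)
  set.seed(8)
  doc <- toy_document(S = 4)
  perm <- doc
  perm$sentences <- perm$sentences[c(3, 1, 4, 2)]
  i1 <- hanrisk:::index_documents(list(doc), emb)[[1]]
  i2 <- hanrisk:::index_documents(list(perm), emb)[[1]]
  m <- han_params_for("han_text")
  p1 <- hanrisk:::forward_doc(m$params, m$cfg, i1, EMB)$final_prob
  p2 <- hanrisk:::forward_doc(m$params, m$cfg, i2, EMB)$final_prob
  expect_gt(abs(p1 - p2), 1e-8)
  fl <- han_params_for("lstm")
  q1 <- hanrisk:::forward_doc(fl$params, fl$cfg, i1, EMB)$final_prob
  q2 <- hanrisk:::forward_doc(fl$params, fl$cfg, i2, EMB)$final_prob
  expect_equal(q1, q2, tolerance = 1e-12)
})
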