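# Backward passes for each architecture: gradient of the target-replication
# loss with respect to every trainable parameter (embeddings are frozen).
# The gradient structure mirrors the parameter structure exactly so that
# unlist()/relist() round-trips support flat optimiser updates.

# Gradient through the output head and (for the combined model) the fused
# structured branch. Returns the gradient on the document vector plus the
# head/struct parameter gradients.
backward_head <- function(params, cfg, cache_out, dlogit, doc_dim) {
  z <- cache_out$z
  dw_out <- dlogit * z
  db_out <- dlogit
  dz <- dlogit * params$out$w
  if (!is.null(cache_out$drop_mask)) dz <- dz * cache_out$drop_mask
  g <- list(out = list(w = dw_out, b = db_out))
  ddoc <- dz[seq_len(doc_dim)]
  if (cfg$kind == "han_combined") {
    sc <- cache_out$struct_cache
    dr <- dz[doc_dim + seq_len(cfg$struct_hidden)]
    da <- dr * as.numeric(sc$a > 0)
    g$struct <- list(W = outer(sc$x, da), b = da)
  }
  list(ddoc = ddoc, grads = g)
}

visit_head_grads <- function(dvl, states, w) {
  list(w = colSums(dvl * states), b = sum(dvl))
}

backward_han <- function(params, cfg, idoc, fwd, y) {
  cc <- fwd$cache
  attn <- cfg$kind != "hn"
  lam <- cfg$lambda_rep
  dlogit <- (1 - lam) * (fwd$final_prob - y)
  cc$out$drop_mask <- cc$drop_mask
  hb <- backward_head(params, cfg, cc$out, dlogit, 2L * cfg$sent_hidden)
  vp <- fwd$visit_probs
  Tn <- length(vp)
  dvl <- (lam / Tn) * (vp - y)
  g <- hb$grads
  g$visit_head <- visit_head_grads(dvl, cc$visit_states, params$visit_head$w)
  ddoc <- matrix(hb$ddoc, 1L)
  if (attn) {
    ab <- attn_backward(ddoc, cc$spool, cc$sb$H, cc$M2, params$sent_attn)
    dH2 <- ab$dH
    g$sent_attn <- ab$grads
  } else {
    dH2 <- meanpool_backward(ddoc, cc$M2)
  }
  for (i in seq_len(Tn)) {
    dH2[[i]] <- dH2[[i]] + dvl[i] * matrix(params$visit_head$w, 1L)
  }
  sbk <- bilstm_backward(dH2, cc$sb, params$sent_rnn)
  g$sent_rnn <- sbk$grads
  dSV <- do.call(rbind, sbk$dX)
  if (attn) {
    wab <- attn_backward(dSV, cc$wpool, cc$wb$H, cc$wbatch$M, params$word_attn)
    dH1 <- wab$dH
    g$word_attn <- wab$grads
  } else {
    dH1 <- meanpool_backward(dSV, cc$wbatch$M)
  }
  wbk <- bilstm_backward(dH1, cc$wb, params$word_rnn)
  g$word_rnn <- wbk$grads
  g[names(params)]
}

backward_flat_lstm <- function(params, cfg, idoc, fwd, y) {
  cc <- fwd$cache
  lam <- cfg$lambda_rep
  dlogit <- (1 - lam) * (fwd$final_prob - y)
  cc$out$drop_mask <- cc$drop_mask
  hb <- backward_head(params, cfg, cc$out, dlogit, 2L * cfg$word_hidden)
  vp <- fwd$visit_probs
  S <- length(vp)
  dvl <- (lam / S) * (vp - y)
  g <- hb$grads
  g$visit_head <- visit_head_grads(dvl, cc$SV, params$visit_head$w)
  dSV <- matrix(hb$ddoc / S, S, length(hb$ddoc), byrow = TRUE) +
    outer(dvl, params$visit_head$w)
  dH1 <- meanpool_backward(dSV, cc$wbatch$M)
  wbk <- bilstm_backward(dH1, cc$wb, params$word_rnn)
  g$word_rnn <- wbk$grads
  g[names(params)]
}

backward_psgnn <- function(params, cfg, idoc, fwd, y) {
  cc <- fwd$cache
  dlogit <- fwd$final_prob - y # no replication in this architecture
  cc$out$drop_mask <- cc$drop_mask
  hb <- backward_head(params, cfg, cc$out, dlogit, cfg$psg_hidden)
  np <- nrow(cc$Hh)
  dHh <- matrix(hb$ddoc / np, np, length(hb$ddoc), byrow = TRUE)
  dA <- dHh * (cc$A > 0)
  g <- hb$grads
  g$hidden <- list(W = crossprod(cc$P, dA), b = colSums(dA))
  g[names(params)]
}

backward_cnn <- function(params, cfg, idoc, fwd, y) {
  cc <- fwd$cache
  lam <- cfg$lambda_rep
  dlogit <- (1 - lam) * (fwd$final_prob - y)
  cc$out$drop_mask <- cc$drop_mask
  F2 <- cfg$cnn_filters[2]
  hb <- backward_head(params, cfg, cc$out, dlogit, F2)
  vp <- fwd$visit_probs
  Tn <- length(vp)
  dvl <- (lam / Tn) * (vp - y)
  Vmat <- do.call(rbind, lapply(cc$visit_pool[cc$keep], function(p) p$v))
  g <- hb$grads
  g$visit_head <- visit_head_grads(dvl, Vmat, params$visit_head$w)
  dC2 <- matrix(0, nrow(cc$C2), F2)
  ix <- cbind(cc$doc_pool$arg, seq_len(F2))
  dC2[ix] <- dC2[ix] + hb$ddoc
  kept <- which(cc$keep)
  for (j in seq_along(kept)) {
    ivp <- cc$visit_pool[[kept[j]]]
    ix <- cbind(ivp$arg, seq_len(F2))
    dC2[ix] <- dC2[ix] + dvl[j] * params$visit_head$w
  }
  dZ2 <- dC2 * (cc$Z2 > 0)
  g$conv2 <- list(W = crossprod(cc$U2, dZ2), b = colSums(dZ2))
  dU2 <- dZ2 %*% t(params$conv2$W)
  dC1 <- fold_seq_grad(dU2, cfg$cnn_kernel, cfg$cnn_filters[1], nrow(cc$C1))
  dZ1 <- dC1 * (cc$Z1 > 0)
  g$conv1 <- list(W = crossprod(cc$U1, dZ1), b = colSums(dZ1))
  g[names(params)]
}

# Loss and full parameter gradient for one document.
loss_and_grads <- function(params, cfg, idoc, EMB, drop_mask = NULL) {
  fwd <- forward_doc(params, cfg, idoc, EMB, drop_mask = drop_mask)
  y <- idoc$label
  loss <- target_replication_loss(fwd$final_prob, fwd$visit_probs, y,
                                  if (is.null(fwd$visit_probs)) 0 else cfg$lambda_rep)
  grads <- switch(cfg$kind,
    han_text = ,
    han_combined = ,
    hn = backward_han(params, cfg, idoc, fwd, y),
    lstm = backward_flat_lstm(params, cfg, idoc, fwd, y),
    psgnn = backward_psgnn(params, cfg, idoc, fwd, y),
    cnn = backward_cnn(params, cfg, idoc, fwd, y)
  )
  list(loss = loss, grads = grads, final_prob = fwd$final_prob)
}
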