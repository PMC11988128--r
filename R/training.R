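# Target-replication objective and the optimisation loop with tuning-split
# model selection.

#' Target-replication loss
#'
#' The training objective `L = (1 - lambda) * l(final_prob, y) +
#' (lambda / T) * sum_i l(p_i, y)` where `l` is binary cross-entropy and the
#' `p_i` are the per-visit probabilities. At `lambda = 0` it reduces exactly
#' to the final-step cross-entropy; replicating the outcome target at every
#' intermediate visit supervises the recurrent states directly and markedly
#' speeds up learning on long histories.
#'
#' @param final_prob Final predicted probability (scalar in (0,1)).
#' @param visit_probs Per-visit probabilities (masked visits excluded);
#'   `NULL` or empty for architectures without replication.
#' @param label Observed outcome, 0 or 1.
#' @param lambda Replication factor in \[0, 1\].
#' @return Scalar loss.
#' @export
target_replication_loss <- function(final_prob, visit_probs, label, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop_config("target_replication_loss: lambda must be in [0, 1]")
  }
  l_final <- bce(final_prob, label)
  if (is.null(visit_probs) || length(visit_probs) == 0L) {
    # architectures without replication heads train on the final loss alone
    return(l_final)
  }
  (1 - lambda) * l_final + lambda * mean(bce(visit_probs, label))
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mh <- st$m / (1 - beta1^st$t)
  vh <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = st)
}

clip_global_norm <- function(g, max_norm) {
  nrm <- sqrt(sum(g^2))
  if (is.finite(nrm) && nrm > max_norm) g * (max_norm / nrm) else g
}

#' Fit a risk network with target replication
#'
#' Mini-batch Adam optimisation of the target-replication loss, with
#' tuning-split AUROC computed after each epoch, best-epoch parameter
#' retention and early stopping. Embeddings are frozen throughout: the word
#' vectors are looked up, never updated. Fully reproducible given `seed`.
#'
#' @param config A [model_config()] (its `kind` selects the architecture).
#' @param train_docs,tune_docs Disjoint document folds (see
#'   [prepare_cohort()]).
#' @param embeddings An `embedding_model` trained on the training fold.
#' @param epochs Maximum epochs (0 returns the initial parameters untouched).
#' @param batch_size Documents per gradient step.
#' @param lr Adam learning rate.
#' @param patience Early-stop patience in epochs without tuning-AUROC
#'   improvement.
#' @param clip Global gradient-norm clip.
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"han_fit"`: `config`, `params` (best-epoch),
#'   `embeddings`, `history` (data.frame epoch/train_loss/tune_auroc),
#'   `best_epoch`, `n_params`.
#' @export
han_fit <- function(config, train_docs, tune_docs, embeddings,
                    epochs = 50L, batch_size = 32L, lr = 1e-3,
                    patience = 5L, clip = 5, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  if (length(train_docs) == 0L || length(tune_docs) == 0L) {
    stop_config("han_fit: empty training or tuning fold")
  }
  if (config$embed_dim != embeddings$dim) {
    stop_config("han_fit: config embed_dim (%d) != embedding dim (%d)",
                config$embed_dim, embeddings$dim)
  }
  EMB <- padded_embeddings(embeddings)
  itrain <- index_documents(train_docs, embeddings)
  itune <- index_documents(tune_docs, embeddings)
  z_dim <- NULL # dropout mask length, resolved lazily from the first forward
  with_seed(seed, {
    params <- init_params(config)
    # start the output heads at the log-odds of the training prevalence, so
    # the first epochs work on discrimination instead of the base rate
    base <- mean(vapply(itrain, `[[`, integer(1), "label"))
    blogit <- stats::qlogis(min(max(base, 1e-4), 1 - 1e-4))
    params$out$b <- blogit
    if (!is.null(params$visit_head)) params$visit_head$b <- blogit
    skeleton <- params
    theta <- unlist(params, use.names = FALSE)
    st <- adam_state(length(theta))
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          tune_auroc = numeric(0))
    best <- list(theta = theta, auroc = -Inf, epoch = 0L)
    stall <- 0L
    n <- length(itrain)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        take <- ord[start:min(start + batch_size - 1L, n)]
        gacc <- numeric(length(theta))
        bl <- 0
        for (j in take) {
          dm <- NULL
          if (config$dropout > 0) {
            if (is.null(z_dim)) {
              f0 <- forward_doc(params, config, itrain[[j]], EMB)
              z_dim <- length(f0$cache$out$z)
            }
            dm <- (stats::runif(z_dim) >= config$dropout) / (1 - config$dropout)
          }
          lg <- loss_and_grads(params, config, itrain[[j]], EMB, drop_mask = dm)
          gacc <- gacc + unlist(lg$grads, use.names = FALSE)
          bl <- bl + lg$loss
        }
        gacc <- clip_global_norm(gacc / length(take), clip)
        upd <- adam_step(theta, gacc, st, lr)
        theta <- upd$theta
        st <- upd$state
        params <- utils::relist(theta, skeleton)
        ep_loss <- ep_loss + bl
      }
      preds <- predict_indexed(params, config, itune, EMB)
      tune_auroc <- auroc_values(vapply(itune, `[[`, integer(1), "label"), preds)
      history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / n,
                                           tune_auroc = tune_auroc))
      if (verbose) {
        message(sprintf("epoch %d loss %.4f tune AUROC %.4f", ep,
                        ep_loss / n, tune_auroc))
      }
      if (tune_auroc > best$auroc + 1e-8) {
        best <- list(theta = theta, auroc = tune_auroc, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    params <- utils::relist(if (best$epoch > 0L) best$theta else theta, skeleton)
    fit <- list(config = config, params = params, embeddings = embeddings,
                history = history, best_epoch = best$epoch,
                best_tune_auroc = best$auroc,
                n_params = length(theta), seed = as.integer(seed))
    class(fit) <- c("han_fit", "han_network")
    fit
  })
}

predict_indexed <- function(params, cfg, idocs, EMB) {
  vapply(idocs, function(d) forward_doc(params, cfg, d, EMB)$final_prob,
         numeric(1))
}

#' Predict outcome probabilities for documents
#'
#' @param object A fitted `"han_fit"`.
#' @param documents List of `soep_document`s.
#' @param ... Unused.
#' @return A prediction set: data.frame with `patient_id`, `label`,
#'   `probability`.
#' @export
predict.han_fit <- function(object, documents, ...) {
  EMB <- padded_embeddings(object$embeddings)
  idocs <- index_documents(documents, object$embeddings)
  data.frame(
    patient_id = vapply(idocs, `[[`, character(1), "patient_id"),
    label = vapply(idocs, `[[`, integer(1), "label"),
    probability = predict_indexed(object$params, object$config, idocs, EMB),
    stringsAsFactors = FALSE
  )
}

#' Full forward output (probabilities and attention weights) for one document
#'
#' @param object A fitted `"han_fit"` (or a `"han_network"` with an
#'   `embeddings` element supplied).
#' @param document A `soep_document`.
#' @param embeddings Optional `embedding_model` if `object` carries none.
#' @return List with `final_prob`, `visit_probs`, `word_attention`,
#'   `sentence_attention`.
#' @export
forward_output <- function(object, document, embeddings = NULL) {
  emb <- embeddings %||% object$embeddings
  EMB <- padded_embeddings(emb)
  idoc <- index_documents(list(document), emb)[[1]]
  fwd <- forward_doc(object$params, object$config, idoc, EMB)
  fwd$cache <- NULL
  fwd
}

#' @export
print.han_fit <- function(x, ...) {
  cat(sprintf("Risk network fit: kind=%s, %d parameters\n", x$config$kind,
              x$n_params))
  cat(sprintf("  lambda_rep=%.2f, word_hidden=%d, sent_hidden=%d\n",
              x$config$lambda_rep, x$config$word_hidden, x$config$sent_hidden))
  if (nrow(x$history)) {
    cat(sprintf("  trained %d epochs; best epoch %d (tuning AUROC %.4f)\n",
                max(x$history$epoch), x$best_epoch, x$best_tune_auroc))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' @export
summary.han_fit <- function(object, ...) {
  feats <- model_features(object)
  cat(sprintf("Architecture: %s (hierarchical=%s, attention=%s, replication=%s)\n",
              object$config$kind, feats["hierarchical"], feats["attention"],
              feats["replication"]))
  print(object)
  if (nrow(object$history)) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.han_fit <- function(object, ...) unlist(object$params)

#' @export
plot.han_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
       ylab = "training loss", main = x$config$kind, ...)
  plot(h$epoch, h$tune_auroc, type = "b", xlab = "epoch",
       ylab = "tuning AUROC", main = "model selection", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Exhaustive hyperparameter search on the tuning fold
#'
#' Fits one model per grid point and selects the configuration with the best
#' tuning-fold AUROC. The test fold is never seen: selection reads the tuning
#' fold only, by construction of the function signature. Ties are broken by
#' smaller `lambda_rep`, then smaller `word_hidden`.
#'
#' @param kind Architecture kind.
#' @param grid A data.frame whose columns are [model_config()] argument names
#'   (e.g. `lambda_rep`, `word_hidden`); one row per candidate.
#' @param train_docs,tune_docs Document folds.
#' @param embeddings Training-fold `embedding_model`.
#' @param base_config Baseline [model_config()] the grid rows override.
#' @param seed Seed shared by all candidate fits.
#' @param ... Passed to [han_fit()] (e.g. `epochs`, `batch_size`).
#' @return List with `best` (the selected row as a list), `results`
#'   (grid + tuning AUROC) and `fit` (the refitted best model).
#' @export
tune_grid <- function(kind, grid, train_docs, tune_docs, embeddings,
                      base_config = NULL, seed = 1L, ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  base_config <- base_config %||% model_config(kind, embed_dim = embeddings$dim)
  scores <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
    cfg$kind <- kind
    fits[[i]] <- han_fit(cfg, train_docs, tune_docs, embeddings,
                         seed = seed, ...)
    scores[i] <- fits[[i]]$best_tune_auroc
  }
  lam <- if ("lambda_rep" %in% names(grid)) grid$lambda_rep else
    rep(base_config$lambda_rep, nrow(grid))
  wh <- if ("word_hidden" %in% names(grid)) grid$word_hidden else
    rep(base_config$word_hidden, nrow(grid))
  best_i <- order(-scores, lam, wh)[1]
  list(best = as.list(grid[best_i, , drop = FALSE]),
       results = cbind(grid, tune_auroc = scores),
       fit = fits[[best_i]])
}
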