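# Batched forward/backward over B equal-length sequences.
#
# Token-wise operations (projections, feed-forward, layer norm, embedding)
# run on the stacked (B*L) x d matrices in single BLAS calls; only the
# attention score/context products loop over samples and heads, because
# attention is per-sample (and may carry per-sample masks). Numerically
# identical to the per-sample path in transformer.R, which remains the
# reference implementation for single-sample uses (attention extraction,
# embeddings) and for the dense-oracle tests.

tf_forward_b <- function(params, cfg, ids_list, key_mask_list,
                         qk_mask_list = NULL, override_rows = NULL,
                         override_values = NULL, need_cache = TRUE,
                         collect_cls_layers = NULL) {
  B <- length(ids_list)
  L <- length(ids_list[[1L]])
  d <- cfg$hidden_size
  h <- cfg$n_heads
  dk <- d %/% h
  eps <- cfg$layer_norm_eps
  ids_all <- unlist(ids_list, use.names = FALSE)

  E <- params$tok_emb[ids_all, , drop = FALSE]
  if (!is.null(params$emb_proj)) E <- E %*% params$emb_proj
  ov_rows_global <- NULL
  if (!is.null(override_rows)) {
    ov_rows_global <- unlist(lapply(seq_len(B), function(s) {
      override_rows[[s]] + (s - 1L) * L
    }), use.names = FALSE)
    if (length(ov_rows_global)) {
      E[ov_rows_global, ] <- rep(override_values, each =
                                   length(ov_rows_global))
    }
  }
  pos_idx <- rep(seq_len(L), B)
  X0 <- E + params$pos_emb[pos_idx, , drop = FALSE]
  ln_e <- layer_norm_fwd(X0, params$emb_ln_g, params$emb_ln_b, eps)
  X <- ln_e$y

  km_mat <- do.call(rbind, key_mask_list)
  caches <- vector("list", cfg$n_layers)
  cls_q <- NULL; cls_k <- NULL
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[if (cfg$share_layers) 1L else l]]
    Q <- addb(X %*% lp$Wq, lp$bq)
    K <- addb(X %*% lp$Wk, lp$bk)
    V <- addb(X %*% lp$Wv, lp$bv)
    collect_here <- !is.null(collect_cls_layers) && l %in% collect_cls_layers
    att <- attn_forward_cpp(Q, K, V, km_mat, qk_mask_list, B, L, h,
                            collect_here)
    C <- att$C
    if (collect_here) {
      cls_q <- if (is.null(cls_q)) att$cls_q else cls_q + att$cls_q
      cls_k <- if (is.null(cls_k)) att$cls_k else cls_k + att$cls_k
    }
    O <- addb(C %*% lp$Wo, lp$bo)
    ln1 <- layer_norm_fwd(X + O, lp$ln1_g, lp$ln1_b, eps)
    X1 <- ln1$y
    F1 <- addb(X1 %*% lp$W1, lp$b1)
    G <- gelu(F1)
    F2 <- addb(G %*% lp$W2, lp$b2)
    ln2 <- layer_norm_fwd(X1 + F2, lp$ln2_g, lp$ln2_b, eps)
    if (need_cache) {
      caches[[l]] <- list(X_in = X, Q = Q, K = K, V = V, C = C,
                          ln1 = ln1, X1 = X1, F1 = F1, G = G, ln2 = ln2)
    }
    X <- ln2$y
  }
  cls_attn <- NULL
  if (!is.null(collect_cls_layers)) {
    cls_attn <- lapply(seq_len(B), function(s) {
      list(query = cls_q[s, ], key = cls_k[s, ])
    })
  }
  list(h = X,
       cache = if (need_cache) list(ids_all = ids_all, B = B, L = L,
                                    pos_idx = pos_idx,
                                    ov_rows = ov_rows_global,
                                    ln_e = ln_e, layers = caches,
                                    km_mat = km_mat,
                                    qk_mask_list = qk_mask_list)
               else NULL,
       cls_attn = cls_attn)
}

# Batched per-sample word-importance scores for one model: last-layer
# [CLS]-anchored token scores (summed over heads) aggregated to words.
# Returns a list of data.frame-compatible lists (words, roles, scores).
batch_word_scores <- function(model, dataset, direction = "cls-query",
                              max_len = 100L, batch_size = 32L,
                              layers = "all", enc_list = NULL) {
  cfg <- model$config
  lset <- resolve_layers(layers, cfg$n_layers)
  if (is.null(enc_list)) {
    sents <- process_dataset(dataset)
    enc_list <- lapply(sents, function(s) encode(model$tokenizer, s,
                                                 max_len))
  }
  out <- vector("list", length(enc_list))
  for (b in split(seq_along(enc_list),
                  ceiling(seq_along(enc_list) / batch_size))) {
    its <- trim_items(lapply(enc_list[b], function(e) {
      list(input_ids = e$input_ids, key_mask = key_mask_of(e))
    }))
    fw <- tf_forward_b(model$params, cfg,
                       lapply(its, `[[`, "input_ids"),
                       lapply(its, `[[`, "key_mask"),
                       need_cache = FALSE, collect_cls_layers = lset)
    for (j in seq_along(b)) {
      enc <- enc_list[[b[j]]]
      tok_scores <- if (direction == "cls-query") {
        fw$cls_attn[[j]]$query
      } else {
        fw$cls_attn[[j]]$key
      }
      n_words <- length(enc$words)
      wid <- enc$word_ids
      ws <- vapply(seq_len(n_words), function(w) {
        sum(tok_scores[which(!is.na(wid) & wid == w)])
      }, numeric(1))
      out[[b[j]]] <- list(words = enc$words, roles = enc$word_roles,
                          scores = ws)
    }
  }
  out
}

# Word scores averaged over the word-piece members, batched; the fast
# counterpart of calling ensemble_token_importance() per sample.
batch_ensemble_word_scores <- function(models, dataset,
                                       direction = "cls-query",
                                       max_len = 100L, layers = "all") {
  if (inherits(models, "methylm_ensemble")) models <- models$members
  if (inherits(models, "methylm_lm")) models <- list(models)
  models <- Filter(function(m) m$tokenizer$algorithm == "wordpiece",
                   models)
  if (!length(models)) {
    stop("no word-piece members available for importance averaging",
         call. = FALSE)
  }
  # models trained on the same corpus often share an identical vocabulary;
  # encode once per distinct tokenizer
  tok_key <- vapply(models, function(m) rlang::hash(m$tokenizer$tokens),
                    character(1))
  enc_cache <- list()
  sents <- process_dataset(dataset)
  per_model <- lapply(seq_along(models), function(mi) {
    key <- tok_key[mi]
    if (is.null(enc_cache[[key]])) {
      enc_cache[[key]] <<- lapply(sents, function(s) {
        encode(models[[mi]]$tokenizer, s, max_len)
      })
    }
    batch_word_scores(models[[mi]], dataset, direction = direction,
                      max_len = max_len, layers = layers,
                      enc_list = enc_cache[[key]])
  })
  n <- nrow(dataset)
  lapply(seq_len(n), function(i) {
    base <- per_model[[1L]][[i]]
    acc <- base$scores
    if (length(per_model) > 1L) {
      for (m in 2L:length(per_model)) {
        other <- per_model[[m]][[i]]
        if (!identical(other$words, base$words)) {
          stop("member tokenizations disagree at word level; cannot align",
               call. = FALSE)
        }
        acc <- acc + other$scores
      }
    }
    list(words = base$words, roles = base$roles,
         scores = acc / length(per_model))
  })
}

# Returns a dense gradient tree shaped like params (tok_emb folded with
# rowsum), ready for the optimizer.
tf_backward_b <- function(params, cfg, cache, dH) {
  d <- cfg$hidden_size
  h <- cfg$n_heads
  dk <- d %/% h
  B <- cache$B
  L <- cache$L
  g <- list(tok_emb = NULL, emb_proj = if (!is.null(params$emb_proj))
              params$emb_proj * 0 else NULL,
            pos_emb = NULL, emb_ln_g = numeric(d), emb_ln_b = numeric(d),
            layers = lapply(params$layers, zero_layer_grads))

  dX <- dH
  for (l in rev(seq_len(cfg$n_layers))) {
    sl <- if (cfg$share_layers) 1L else l
    lp <- params$layers[[sl]]
    cc <- cache$layers[[l]]
    gl <- g$layers[[sl]]

    b2 <- layer_norm_bwd(dX, cc$ln2, lp$ln2_g)
    gl$ln2_g <- gl$ln2_g + b2$dg; gl$ln2_b <- gl$ln2_b + b2$db
    dres2 <- b2$dx
    dF2 <- dres2
    gl$W2 <- gl$W2 + crossprod(cc$G, dF2)
    gl$b2 <- gl$b2 + colSums(dF2)
    dG <- tcrossprod(dF2, lp$W2)
    dF1 <- dG * gelu_grad(cc$F1)
    gl$W1 <- gl$W1 + crossprod(cc$X1, dF1)
    gl$b1 <- gl$b1 + colSums(dF1)
    dX1 <- dres2 + tcrossprod(dF1, lp$W1)

    b1g <- layer_norm_bwd(dX1, cc$ln1, lp$ln1_g)
    gl$ln1_g <- gl$ln1_g + b1g$dg; gl$ln1_b <- gl$ln1_b + b1g$db
    dres1 <- b1g$dx
    dO <- dres1
    gl$Wo <- gl$Wo + crossprod(cc$C, dO)
    gl$bo <- gl$bo + colSums(dO)
    dC <- tcrossprod(dO, lp$Wo)

    ab <- attn_backward_cpp(cc$Q, cc$K, cc$V, dC, cache$km_mat,
                            cache$qk_mask_list, B, L, h)
    dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
    X_in <- cc$X_in
    gl$Wq <- gl$Wq + crossprod(X_in, dQ); gl$bq <- gl$bq + colSums(dQ)
    gl$Wk <- gl$Wk + crossprod(X_in, dK); gl$bk <- gl$bk + colSums(dK)
    gl$Wv <- gl$Wv + crossprod(X_in, dV); gl$bv <- gl$bv + colSums(dV)
    dX <- dres1 + tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
      tcrossprod(dV, lp$Wv)
    g$layers[[sl]] <- gl
  }

  be <- layer_norm_bwd(dX, cache$ln_e, params$emb_ln_g)
  g$emb_ln_g <- be$dg; g$emb_ln_b <- be$db
  dX0 <- be$dx
  g$pos_emb <- rowsum_into(dX0, cache$pos_idx, nrow(params$pos_emb))
  dE <- dX0
  if (!is.null(cache$ov_rows) && length(cache$ov_rows)) {
    g$mask_emb <- colSums(dE[cache$ov_rows, , drop = FALSE])
    dE[cache$ov_rows, ] <- 0
  }
  if (!is.null(params$emb_proj)) {
    Erows <- params$tok_emb[cache$ids_all, , drop = FALSE]
    g$emb_proj <- g$emb_proj + crossprod(Erows, dE)
    dE <- tcrossprod(dE, params$emb_proj)
  }
  g$tok_emb <- rowsum_into(dE, cache$ids_all, nrow(params$tok_emb))
  g
}

# Batched [CLS] classifier head.
head_cls_b <- function(params, cfg, H, B, L, labels01) {
  cls_rows <- (seq_len(B) - 1L) * L + 1L
  X <- H[cls_rows, , drop = FALSE]
  A <- addb(X %*% params$pool_W, params$pool_b)
  Z <- tanh(A)
  logits <- addb(Z %*% params$cls_W, params$cls_b)
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits)
  P <- P / rowSums(P)
  yi <- cbind(seq_len(B), labels01 + 1L)
  loss <- -sum(log(pmax(P[yi], 1e-12)))
  dlog <- P
  dlog[yi] <- dlog[yi] - 1
  g <- list(cls_W = crossprod(Z, dlog), cls_b = colSums(dlog))
  dZ <- tcrossprod(dlog, params$cls_W)
  dA <- dZ * (1 - Z * Z)
  g$pool_W <- crossprod(X, dA)
  g$pool_b <- colSums(dA)
  dXc <- tcrossprod(dA, params$pool_W)
  dH <- matrix(0, nrow(H), ncol(H))
  dH[cls_rows, ] <- dXc
  list(loss = loss, n = B, dH = dH, head = g)
}

# Truncate a batch to its longest content length: hidden states at content
# positions are exactly independent of trailing [PAD]s (their keys are
# masked and nothing reads their rows), so this is a pure speedup.
trim_items <- function(items) {
  n_content <- vapply(items, function(it) sum(it$key_mask == 0),
                      integer(1))
  L_eff <- max(n_content)
  L <- length(items[[1L]]$input_ids)
  if (L_eff >= L) return(items)
  lapply(items, function(it) {
    it$input_ids <- it$input_ids[seq_len(L_eff)]
    it$key_mask <- it$key_mask[seq_len(L_eff)]
    if (!is.null(it$qk_mask)) {
      it$qk_mask <- it$qk_mask[seq_len(L_eff), seq_len(L_eff),
                               drop = FALSE]
    }
    it
  })
}

# Batched objective step: forward, head, backward; returns loss, count and
# a dense grad tree (head grads merged in).
batch_loss_grad <- function(params, cfg, items, objective) {
  items <- trim_items(items)
  B <- length(items)
  L <- length(items[[1L]]$input_ids)
  ids_list <- lapply(items, `[[`, "input_ids")
  km_list <- lapply(items, `[[`, "key_mask")
  if (objective == "cls") {
    fw <- tf_forward_b(params, cfg, ids_list, km_list)
    hd <- head_cls_b(params, cfg, fw$h, B, L,
                     vapply(items, `[[`, integer(1), "label01"))
  } else if (objective == "mlm") {
    fw <- tf_forward_b(params, cfg, ids_list, km_list)
    sel <- unlist(lapply(seq_len(B), function(s) {
      items[[s]]$sel + (s - 1L) * L
    }), use.names = FALSE)
    targets <- unlist(lapply(items, `[[`, "targets"), use.names = FALSE)
    hd <- head_lm(params, cfg, fw$h, sel, targets)
  } else if (objective == "rtd") {
    fw <- tf_forward_b(params, cfg, ids_list, km_list)
    content <- unlist(lapply(seq_len(B), function(s) {
      items[[s]]$content + (s - 1L) * L
    }), use.names = FALSE)
    replaced <- unlist(lapply(items, `[[`, "replaced"), use.names = FALSE)
    hd <- head_rtd(params, cfg, fw$h, content, replaced)
  } else {  # plm
    fw <- tf_forward_b(params, cfg, ids_list, km_list,
                       qk_mask_list = lapply(items, `[[`, "qk_mask"),
                       override_rows = lapply(items, `[[`, "targets_pos"),
                       override_values = params$mask_emb)
    sel <- unlist(lapply(seq_len(B), function(s) {
      items[[s]]$targets_pos + (s - 1L) * L
    }), use.names = FALSE)
    targets <- unlist(lapply(items, `[[`, "targets_ids"),
                      use.names = FALSE)
    hd <- head_lm(params, cfg, fw$h, sel, targets)
  }
  g <- tf_backward_b(params, cfg, fw$cache, hd$dH)
  for (nm in names(hd$head)) {
    g[[nm]] <- if (is.null(g[[nm]])) hd$head[[nm]] else g[[nm]] +
      hd$head[[nm]]
  }
  list(loss = hd$loss, n = hd$n, grads = g)
}

# Batched forward-only loss for held-out evaluation.
batch_loss_eval <- function(params, cfg, items, objective) {
  total <- 0; n <- 0L
  bs <- 32L
  for (b in split(seq_along(items), ceiling(seq_along(items) / bs))) {
    its <- trim_items(items[b])
    B <- length(its)
    L <- length(its[[1L]]$input_ids)
    ids_list <- lapply(its, `[[`, "input_ids")
    km_list <- lapply(its, `[[`, "key_mask")
    if (objective == "plm") {
      fw <- tf_forward_b(params, cfg, ids_list, km_list,
                         qk_mask_list = lapply(its, `[[`, "qk_mask"),
                         override_rows = lapply(its, `[[`, "targets_pos"),
                         override_values = params$mask_emb,
                         need_cache = FALSE)
      sel <- unlist(lapply(seq_len(B), function(s) {
        its[[s]]$targets_pos + (s - 1L) * L
      }), use.names = FALSE)
      hd <- head_lm(params, cfg, fw$h, sel,
                    unlist(lapply(its, `[[`, "targets_ids"),
                           use.names = FALSE))
    } else if (objective == "rtd") {
      fw <- tf_forward_b(params, cfg, ids_list, km_list,
                         need_cache = FALSE)
      content <- unlist(lapply(seq_len(B), function(s) {
        its[[s]]$content + (s - 1L) * L
      }), use.names = FALSE)
      hd <- head_rtd(params, cfg, fw$h, content,
                     unlist(lapply(its, `[[`, "replaced"),
                            use.names = FALSE))
    } else if (objective == "mlm") {
      fw <- tf_forward_b(params, cfg, ids_list, km_list,
                         need_cache = FALSE)
      sel <- unlist(lapply(seq_len(B), function(s) {
        its[[s]]$sel + (s - 1L) * L
      }), use.names = FALSE)
      hd <- head_lm(params, cfg, fw$h, sel,
                    unlist(lapply(its, `[[`, "targets"),
                           use.names = FALSE))
    } else {  # cls
      fw <- tf_forward_b(params, cfg, ids_list, km_list,
                         need_cache = FALSE)
      hd <- head_cls_b(params, cfg, fw$h, B, L,
                       vapply(its, `[[`, integer(1), "label01"))
    }
    total <- total + hd$loss
    n <- n + hd$n
  }
  total / max(n, 1L)
}

# Batched positive-class probabilities for encoded samples.
batch_cls_probs <- function(params, cfg, enc_list, batch_size = 32L) {
  out <- numeric(length(enc_list))
  for (b in split(seq_along(enc_list),
                  ceiling(seq_along(enc_list) / batch_size))) {
    its <- trim_items(lapply(enc_list[b], function(e) {
      list(input_ids = e$input_ids, key_mask = key_mask_of(e))
    }))
    B <- length(its)
    L <- length(its[[1L]]$input_ids)
    fw <- tf_forward_b(params, cfg, lapply(its, `[[`, "input_ids"),
                       lapply(its, `[[`, "key_mask"), need_cache = FALSE)
    cls_rows <- (seq_len(B) - 1L) * L + 1L
    X <- fw$h[cls_rows, , drop = FALSE]
    Z <- tanh(addb(X %*% params$pool_W, params$pool_b))
    logits <- addb(Z %*% params$cls_W, params$cls_b)
    logits <- logits - apply(logits, 1, max)
    P <- exp(logits)
    out[b] <- (P / rowSums(P))[, 2L]
  }
  out
}
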