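# Minimal trainable transformer encoder in base R matrix code.
#
# Post-layer-norm encoder blocks (multi-head scaled dot-product
# self-attention + GELU feed-forward, residual connections), learned
# absolute position embeddings, tied input/output embeddings. Forward and
# backward passes are written out explicitly; all heavy lifting is BLAS
# matrix multiplication, which is fast enough for the tiny presets this
# package trains on one CPU.
#
# Family presets:
#   BERT / ELECTRA  : standard encoder stack
#   DistilBERT      : same blocks, half the layers at paper scale
#   ALBERT          : cross-layer parameter sharing + factorized embeddings
#   XLNet           : standard blocks here (absolute positions); its
#                     permutation-LM objective lives in the pretraining code

#' Transformer model configuration
#'
#' @param family model family, one of `"BERT"`, `"DistilBERT"`, `"ALBERT"`,
#'   `"XLNet"`, `"ELECTRA"`.
#' @param preset `"tiny"` (2 layers, 64 hidden, 4 heads — the desk-scale
#'   default) or `"paper"` (12 layers, 768 hidden, 12 heads; 6 layers for
#'   DistilBERT).
#' @param vocab_size vocabulary size; must match the tokenizer.
#' @param max_position maximum sequence length supported.
#' @param n_layers,n_heads,hidden_size,intermediate_size,embedding_size
#'   overrides for individual architecture dimensions.
#' @return a list of class `"methylm_config"`. `hidden_size` must be
#'   divisible by `n_heads`; head dims are `d_k = d_v = hidden_size /
#'   n_heads`.
#' @export
model_config <- function(family = "BERT", preset = c("tiny", "paper"),
                         vocab_size = 25000L, max_position = 128L,
                         n_layers = NULL, n_heads = NULL, hidden_size = NULL,
                         intermediate_size = NULL, embedding_size = NULL) {
  family <- match.arg(family, MODEL_FAMILIES)
  preset <- match.arg(preset)
  if (preset == "paper") {
    def <- list(n_layers = if (family == "DistilBERT") 6L else 12L,
                n_heads = 12L, hidden_size = 768L, intermediate_size = 3072L,
                embedding_size = if (family == "ALBERT") 128L else 768L,
                max_position = 512L)
  } else {
    # desk-scale preset: feed-forward at 2x hidden keeps the per-sample
    # cost dominated by attention + projections rather than the FFN
    def <- list(n_layers = 2L, n_heads = 4L, hidden_size = 64L,
                intermediate_size = 128L,
                embedding_size = if (family == "ALBERT") 32L else 64L,
                max_position = as.integer(max_position))
  }
  hidden <- as.integer(hidden_size %||% def$hidden_size)
  # non-ALBERT families tie the embedding width to the hidden width; only
  # ALBERT factorizes them
  emb_default <- if (family == "ALBERT") def$embedding_size else hidden
  cfg <- list(family = family, preset = preset,
              n_layers = as.integer(n_layers %||% def$n_layers),
              n_heads = as.integer(n_heads %||% def$n_heads),
              hidden_size = hidden,
              intermediate_size = as.integer(intermediate_size %||%
                                             def$intermediate_size),
              embedding_size = as.integer(embedding_size %||% emb_default),
              vocab_size = as.integer(vocab_size),
              max_position = as.integer(def$max_position),
              share_layers = family == "ALBERT",
              objective = switch(family, ELECTRA = "rtd", XLNet = "plm",
                                 "mlm"),
              layer_norm_eps = 1e-12, init_range = 0.02,
              # At tiny hidden sizes a 0.02 init leaves all attention
              # logits near 0, so the softmax starts (and tends to stay)
              # uniform; a larger query/key init gives heads initial
              # content preferences that training can amplify. The paper
              # preset keeps the standard 0.02.
              qk_init_range = if (preset == "tiny") 0.4 else 0.02,
              pos_init_range = 0.02)
  if (cfg$hidden_size %% cfg$n_heads != 0L) {
    stop("hidden_size (", cfg$hidden_size,
         ") must be divisible by n_heads (", cfg$n_heads, ")", call. = FALSE)
  }
  class(cfg) <- "methylm_config"
  cfg
}

#' @export
print.methylm_config <- function(x, ...) {
  cat("<config> ", x$family, " ", x$preset, ": ", x$n_layers, " layers, ",
      x$hidden_size, " hidden, ", x$n_heads, " heads, vocab ",
      x$vocab_size, ", objective ", x$objective, "\n", sep = "")
  invisible(x)
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

init_layer <- function(d, m, sd, qk_sd = sd) {
  list(Wq = rmat(d, d, qk_sd), bq = numeric(d),
       Wk = rmat(d, d, qk_sd), bk = numeric(d),
       Wv = rmat(d, d, sd), bv = numeric(d),
       Wo = rmat(d, d, sd), bo = numeric(d),
       ln1_g = rep(1, d), ln1_b = numeric(d),
       W1 = rmat(d, m, sd), b1 = numeric(m),
       W2 = rmat(m, d, sd), b2 = numeric(d),
       ln2_g = rep(1, d), ln2_b = numeric(d))
}

init_params <- function(cfg, seed = 1L) {
  local_seed(seed, {
    d <- cfg$hidden_size; e <- cfg$embedding_size; sd <- cfg$init_range
    n_stored <- if (cfg$share_layers) 1L else cfg$n_layers
    p <- list(tok_emb = rmat(cfg$vocab_size, e, sd),
              emb_proj = if (e != d) rmat(e, d, sd) else NULL,
              pos_emb = rmat(cfg$max_position, d,
                             cfg$pos_init_range %||% sd),
              emb_ln_g = rep(1, d), emb_ln_b = numeric(d),
              mlm_bias = numeric(cfg$vocab_size),
              layers = lapply(seq_len(n_stored),
                              function(i) init_layer(d, cfg$intermediate_size,
                                                     sd,
                                                     cfg$qk_init_range %||%
                                                       sd)))
    if (cfg$objective == "rtd") {
      p$rtd_w <- stats::rnorm(d, 0, sd); p$rtd_b <- 0
    }
    if (cfg$objective == "plm") {
      p$mask_emb <- stats::rnorm(d, 0, sd)
    }
    p
  })
}

layer_norm_fwd <- function(x, g, b, eps) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  list(y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, inv_sd = inv_sd)
}

layer_norm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- cache$inv_sd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# Stabilized by the global max: attention scores are bounded well within
# double range once the largest is subtracted (masked entries at -1e9
# underflow to exactly 0, which is the intent).
row_softmax <- function(s) {
  e <- exp(s - max(s))
  e / rowSums(e)
}

# Sigmoid approximation of GELU (x * sigmoid(1.702 x)); cheap and within
# ~1e-2 of the exact form over the working range.
gelu <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

addb <- function(x, b) x + rep(b, each = nrow(x))

# Forward pass over one encoded sequence.
#
# ids:            integer vector (1-based vocab ids), length L
# key_mask:       additive vector length L (0 content, -1e9 pad keys)
# qk_mask:        optional additive L x L matrix (permutation-LM masks)
# emb_override:   optional list(rows, values) replacing the token embedding
#                 of given rows with a fixed d-vector (permutation-LM
#                 placeholder)
# collect:        also return attention [layer, head, L, L]
tf_forward <- function(params, cfg, ids, key_mask = NULL, qk_mask = NULL,
                       emb_override = NULL, collect = FALSE,
                       need_cache = TRUE) {
  L <- length(ids)
  d <- cfg$hidden_size
  h <- cfg$n_heads
  dk <- d %/% h
  eps <- cfg$layer_norm_eps
  if (is.null(key_mask)) key_mask <- numeric(L)

  E <- params$tok_emb[ids, , drop = FALSE]
  if (!is.null(params$emb_proj)) E <- E %*% params$emb_proj
  if (!is.null(emb_override)) {
    for (r in emb_override$rows) E[r, ] <- emb_override$values
  }
  X0 <- E + params$pos_emb[seq_len(L), , drop = FALSE]
  ln_e <- layer_norm_fwd(X0, params$emb_ln_g, params$emb_ln_b, eps)
  X <- ln_e$y

  attn <- if (collect) array(0, c(cfg$n_layers, h, L, L)) else NULL
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[if (cfg$share_layers) 1L else l]]
    Q <- addb(X %*% lp$Wq, lp$bq)
    K <- addb(X %*% lp$Wk, lp$bk)
    V <- addb(X %*% lp$Wv, lp$bv)
    C <- matrix(0, L, d)
    A_heads <- vector("list", h)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dk + 1L):(i * dk)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
        sqrt(dk)
      S <- S + rep(key_mask, each = L)
      if (!is.null(qk_mask)) S <- S + qk_mask
      A <- row_softmax(S)
      A_heads[[i]] <- A
      if (collect) attn[l, i, , ] <- A
      C[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    O <- addb(C %*% lp$Wo, lp$bo)
    ln1 <- layer_norm_fwd(X + O, lp$ln1_g, lp$ln1_b, eps)
    X1 <- ln1$y
    F1 <- addb(X1 %*% lp$W1, lp$b1)
    G <- gelu(F1)
    F2 <- addb(G %*% lp$W2, lp$b2)
    ln2 <- layer_norm_fwd(X1 + F2, lp$ln2_g, lp$ln2_b, eps)
    if (need_cache) {
      caches[[l]] <- list(X_in = X, Q = Q, K = K, V = V, A = A_heads, C = C,
                          ln1 = ln1, X1 = X1, F1 = F1, G = G, ln2 = ln2)
    }
    X <- ln2$y
  }
  list(h = X,
       cache = if (need_cache) list(ids = ids, L = L, E_rows = emb_override,
                                    ln_e = ln_e, layers = caches,
                                    key_mask = key_mask, qk_mask = qk_mask)
               else NULL,
       attention = attn)
}

zero_layer_grads <- function(lp) lapply(lp, function(x) x * 0)

# Backward pass; dH is the gradient at the final hidden states (L x d).
# Returns gradients for all parameters touched by the encoder trunk
# (embeddings, layers); head gradients are handled by the callers.
tf_backward <- function(params, cfg, cache, dH) {
  d <- cfg$hidden_size
  h <- cfg$n_heads
  dk <- d %/% h
  L <- cache$L
  n_stored <- length(params$layers)
  g <- list(tok_emb = NULL,  # accumulated sparsely at the end
            emb_proj = if (!is.null(params$emb_proj))
              params$emb_proj * 0 else NULL,
            pos_emb = NULL,
            emb_ln_g = numeric(d), emb_ln_b = numeric(d),
            layers = lapply(params$layers, zero_layer_grads))

  dX <- dH
  for (l in rev(seq_len(cfg$n_layers))) {
    sl <- if (cfg$share_layers) 1L else l
    lp <- params$layers[[sl]]
    cc <- cache$layers[[l]]
    gl <- g$layers[[sl]]

    b2 <- layer_norm_bwd(dX, cc$ln2, lp$ln2_g)
    gl$ln2_g <- gl$ln2_g + b2$dg; gl$ln2_b <- gl$ln2_b + b2$db
    dres2 <- b2$dx                      # grad at X1 + F2
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
    dres1 <- b1g$dx                     # grad at X_in + O
    dO <- dres1
    gl$Wo <- gl$Wo + crossprod(cc$C, dO)
    gl$bo <- gl$bo + colSums(dO)
    dC <- tcrossprod(dO, lp$Wo)

    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dk + 1L):(i * dk)
      A <- cc$A[[i]]
      dCh <- dC[, cols, drop = FALSE]
      dA <- tcrossprod(dCh, cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dCh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dk)
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dk)
    }
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
  g$pos_emb <- list(rows = seq_len(L), grad = dX0)
  dE <- dX0
  dmask_emb <- NULL
  if (!is.null(cache$E_rows)) {
    rows <- cache$E_rows$rows
    if (length(rows)) {
      dmask_emb <- colSums(dE[rows, , drop = FALSE])
      dE[rows, ] <- 0
    }
  }
  if (!is.null(params$emb_proj)) {
    Erows <- params$tok_emb[cache$ids, , drop = FALSE]
    g$emb_proj <- g$emb_proj + crossprod(Erows, dE)
    dE <- tcrossprod(dE, params$emb_proj)
  }
  g$tok_emb <- list(ids = cache$ids, grad = dE)
  g$dmask_emb <- dmask_emb
  g
}

# ---- parameter-tree utilities (used by the Adam optimizer) -------------

tree_leaves_apply <- function(tree, f, path = character(0)) {
  if (is.list(tree)) {
    for (nm in names(tree)) {
      tree[[nm]] <- tree_leaves_apply(tree[[nm]], f, c(path, nm))
    }
    tree
  } else if (is.numeric(tree)) {
    f(tree, path)
  } else {
    tree
  }
}

tree_zero_like <- function(tree) tree_leaves_apply(tree, function(x, p) x * 0)

new_adam_state <- function(params) {
  list(m = tree_zero_like(params), v = tree_zero_like(params), t = 0L)
}

# Accumulate sparse trunk gradients (as returned by tf_backward) into a
# dense gradient tree shaped like `params`.
accumulate_grads <- function(acc, g, params, cfg) {
  acc$tok_emb <- acc$tok_emb +
    rowsum_into(g$tok_emb$grad, g$tok_emb$ids, nrow(params$tok_emb))
  if (!is.null(g$emb_proj)) acc$emb_proj <- acc$emb_proj + g$emb_proj
  pe <- g$pos_emb
  acc$pos_emb[pe$rows, ] <- acc$pos_emb[pe$rows, , drop = FALSE] + pe$grad
  acc$emb_ln_g <- acc$emb_ln_g + g$emb_ln_g
  acc$emb_ln_b <- acc$emb_ln_b + g$emb_ln_b
  if (!is.null(g$dmask_emb) && !is.null(acc$mask_emb)) {
    acc$mask_emb <- acc$mask_emb + g$dmask_emb
  }
  for (i in seq_along(g$layers)) {
    for (nm in names(g$layers[[i]])) {
      acc$layers[[i]][[nm]] <- acc$layers[[i]][[nm]] + g$layers[[i]][[nm]]
    }
  }
  acc
}

rowsum_into <- function(grad, ids, n_rows) {
  out <- matrix(0, n_rows, ncol(grad))
  rs <- rowsum(grad, group = ids)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# AdamW: decoupled weight decay applied to weight matrices only (not to
# biases or layer-norm parameters), as in the reference BERT optimizer.
# Besides regularization, the decay matters for interpretability: attention
# head preferences that never receive gradient (loss-neutral directions
# inherited from the initialization) shrink away instead of persisting.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0.01, grad_scale = 1) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else if (is.numeric(p)) {
      if (grad_scale != 1) g <- g * grad_scale
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      step <- mhat / (sqrt(vhat) + eps)
      if (weight_decay > 0 && is.matrix(p)) step <- step + weight_decay * p
      list(p = p - lr * step, m = m, v = v)
    } else {
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Linear warmup to `lr`, then constant.
lr_at <- function(step, lr, warmup) {
  if (warmup > 0 && step < warmup) lr * step / warmup else lr
}
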