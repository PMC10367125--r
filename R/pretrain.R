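# Self-supervised pretraining on the 6-mer + lineage corpus.
#
# Objectives by family:
#   BERT / DistilBERT / ALBERT — masked language modeling (MLM) with the
#     classic 15% selection and 80/10/10 [MASK]/random/keep policy;
#   ELECTRA — replaced-token detection (tokens corrupted by draws from the
#     corpus unigram distribution; per-token binary discriminator head);
#   XLNet — permutation LM (one-stream approximation: the last ~15% of a
#     sampled factorization order are predicted, their inputs replaced by a
#     learned placeholder, with an attention mask hiding each target from
#     itself and from later-in-order targets).

#' Masking policy for masked language modeling
#'
#' Non-special tokens are selected independently with probability
#' `select_rate`; of the selected, `mask_rate` become `[MASK]`,
#' `random_rate` become a uniformly random non-special vocabulary token and
#' `keep_rate` stay unchanged. Rates of the three outcomes must sum to 1.
#'
#' @param select_rate candidate selection probability (default 0.15).
#' @param mask_rate,random_rate,keep_rate outcome shares among selected
#'   tokens (defaults 0.8 / 0.1 / 0.1).
#' @return list of class `"masking_policy"`.
#' @export
masking_policy <- function(select_rate = 0.15, mask_rate = 0.8,
                           random_rate = 0.1, keep_rate = 0.1) {
  if (abs(mask_rate + random_rate + keep_rate - 1) > 1e-9) {
    stop("mask_rate + random_rate + keep_rate must equal 1", call. = FALSE)
  }
  if (select_rate < 0 || select_rate > 1) {
    stop("select_rate must be in [0,1]", call. = FALSE)
  }
  structure(list(select_rate = select_rate, mask_rate = mask_rate,
                 random_rate = random_rate, keep_rate = keep_rate),
            class = "masking_policy")
}

#' Apply MLM masking to an encoded sample
#'
#' Special tokens (`[CLS]`, `[SEP]`, `[PAD]`, `[MASK]`, `[UNK]`) are never
#' candidates. Uses the current RNG stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param encoded an [encode()]d sample.
#' @param tokenizer the tokenizer (for the vocabulary size).
#' @param policy a [masking_policy()].
#' @return list with `input_ids` (masked), `mlm_labels` (original ids at
#'   selected positions, `NA` elsewhere) and `selected` (logical).
#' @export
mask_tokens <- function(encoded, tokenizer, policy = masking_policy()) {
  ids <- encoded$input_ids
  n_special <- length(SPECIAL_TOKENS)
  maskable <- encoded$attention_mask == 1L & ids > n_special
  sel <- maskable & stats::runif(length(ids)) < policy$select_rate
  labels <- rep(NA_integer_, length(ids))
  labels[sel] <- ids[sel]
  out <- ids
  idx <- which(sel)
  if (length(idx)) {
    u <- stats::runif(length(idx))
    to_mask <- u < policy$mask_rate
    to_rand <- !to_mask & u < policy$mask_rate + policy$random_rate
    out[idx[to_mask]] <- MASK_ID
    if (any(to_rand)) {
      out[idx[to_rand]] <- sample.int(tokenizer$vocab_size - n_special,
                                      sum(to_rand), replace = TRUE) +
        n_special
    }
  }
  list(input_ids = out, mlm_labels = labels, selected = sel)
}

# ---- objective heads ---------------------------------------------------

# Tied-embedding LM head over selected positions. Returns loss (sum over
# positions), dH (L x d), and dense head gradients.
head_lm <- function(params, cfg, H, sel, target_ids) {
  Hsel <- H[sel, , drop = FALSE]
  n <- length(sel)
  if (!is.null(params$emb_proj)) {
    P <- tcrossprod(Hsel, params$emb_proj)           # n x E
    logits <- tcrossprod(P, params$tok_emb)          # n x V
  } else {
    logits <- tcrossprod(Hsel, params$tok_emb)
  }
  logits <- logits + rep(params$mlm_bias, each = n)
  logits <- logits - max(logits)
  expl <- exp(logits)
  probs <- expl / rowSums(expl)
  loss <- -sum(log(pmax(probs[cbind(seq_len(n), target_ids)], 1e-12)))
  dlogits <- probs
  dlogits[cbind(seq_len(n), target_ids)] <-
    dlogits[cbind(seq_len(n), target_ids)] - 1
  head_g <- list(mlm_bias = colSums(dlogits))
  if (!is.null(params$emb_proj)) {
    head_g$tok_emb <- crossprod(dlogits, P)                       # V x E
    dP <- dlogits %*% params$tok_emb                              # n x E
    head_g$emb_proj <- crossprod(dP, Hsel)                        # E x d
    dHsel <- dP %*% params$emb_proj
  } else {
    head_g$tok_emb <- crossprod(dlogits, Hsel)                    # V x d
    dHsel <- dlogits %*% params$tok_emb
  }
  dH <- matrix(0, nrow(H), ncol(H))
  dH[sel, ] <- dHsel
  list(loss = loss, n = n, dH = dH, head = head_g)
}

# Replaced-token-detection head: binary logistic loss over content
# positions (1 = token was replaced).
head_rtd <- function(params, cfg, H, content, replaced) {
  Hc <- H[content, , drop = FALSE]
  z <- drop(Hc %*% params$rtd_w) + params$rtd_b
  p <- 1 / (1 + exp(-z))
  y <- as.numeric(replaced)
  loss <- -sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  dz <- p - y
  dH <- matrix(0, nrow(H), ncol(H))
  dH[content, ] <- outer(dz, params$rtd_w)
  list(loss = loss, n = length(content), dH = dH,
       head = list(rtd_w = drop(crossprod(Hc, dz)), rtd_b = sum(dz)))
}

# ---- per-sample loss/gradient closures ---------------------------------

# Each item preparer returns a function(params) -> list(loss, n, trunk
# gradients from tf_backward, head gradients).
loss_grad_mlm <- function(params, cfg, item) {
  fw <- tf_forward(params, cfg, item$input_ids, key_mask = item$key_mask)
  hd <- head_lm(params, cfg, fw$h, item$sel, item$targets)
  trunk <- tf_backward(params, cfg, fw$cache, hd$dH)
  list(loss = hd$loss, n = hd$n, trunk = trunk, head = hd$head)
}

loss_grad_rtd <- function(params, cfg, item) {
  fw <- tf_forward(params, cfg, item$input_ids, key_mask = item$key_mask)
  hd <- head_rtd(params, cfg, fw$h, item$content, item$replaced)
  trunk <- tf_backward(params, cfg, fw$cache, hd$dH)
  list(loss = hd$loss, n = hd$n, trunk = trunk, head = hd$head)
}

loss_grad_plm <- function(params, cfg, item) {
  fw <- tf_forward(params, cfg, item$input_ids, key_mask = item$key_mask,
                   qk_mask = item$qk_mask,
                   emb_override = list(rows = item$targets_pos,
                                       values = params$mask_emb))
  hd <- head_lm(params, cfg, fw$h, item$targets_pos, item$targets_ids)
  trunk <- tf_backward(params, cfg, fw$cache, hd$dH)
  list(loss = hd$loss, n = hd$n, trunk = trunk, head = hd$head)
}

key_mask_of <- function(encoded) (1 - encoded$attention_mask) * -1e9

content_positions <- function(encoded) {
  which(encoded$attention_mask == 1L &
          encoded$input_ids > length(SPECIAL_TOKENS))
}

# Prepare one training item for the family objective. Consumes RNG.
prepare_item <- function(encoded, tokenizer, cfg, policy, unigram_ids = NULL,
                         unigram_w = NULL) {
  km <- key_mask_of(encoded)
  if (cfg$objective == "mlm") {
    mk <- mask_tokens(encoded, tokenizer, policy)
    sel <- which(mk$selected)
    if (!length(sel)) return(NULL)
    list(input_ids = mk$input_ids, key_mask = km, sel = sel,
         targets = mk$mlm_labels[sel])
  } else if (cfg$objective == "rtd") {
    content <- content_positions(encoded)
    if (!length(content)) return(NULL)
    sel <- stats::runif(length(content)) < policy$select_rate
    ids <- encoded$input_ids
    if (any(sel)) {
      repl <- sample(unigram_ids, sum(sel), replace = TRUE,
                     prob = unigram_w)
      ids[content[sel]] <- repl
    }
    replaced <- ids[content] != encoded$input_ids[content]
    list(input_ids = ids, key_mask = km, content = content,
         replaced = replaced)
  } else {
    content <- content_positions(encoded)
    if (length(content) < 2L) return(NULL)
    perm <- sample(content)
    m <- max(1L, ceiling(policy$select_rate * length(content)))
    targets <- perm[(length(perm) - m + 1L):length(perm)]
    rank <- setNames(integer(length(encoded$input_ids)),
                     NULL)
    rank[perm] <- seq_along(perm)
    L <- length(encoded$input_ids)
    qk <- matrix(0, L, L)
    # query q may see target key k only if rank[k] < rank[q]
    for (k in targets) {
      blocked <- rank <= rank[k]
      qk[blocked, k] <- -1e9
    }
    list(input_ids = encoded$input_ids, key_mask = km, qk_mask = qk,
         targets_pos = targets, targets_ids = encoded$input_ids[targets])
  }
}

# ---- generic Adam training loop ----------------------------------------

# items_fn(epoch) returns the (already shuffled) list of prepared items for
# that epoch; batches run through the batched forward/backward. eval_fn, if
# given, is called after each epoch and its value logged.
train_loop <- function(params, cfg, train, items_fn, objective,
                       eval_fn = NULL, verbose = FALSE) {
  state <- new_adam_state(params)
  step <- 0L
  logs <- list()
  eval_log <- list()
  for (epoch in seq_len(train$epochs)) {
    items <- items_fn(epoch)
    if (!length(items)) next
    batches <- split(seq_along(items),
                     ceiling(seq_along(items) / train$batch_size))
    for (b in batches) {
      r <- batch_loss_grad(params, cfg, items[b], objective)
      step <- step + 1L
      upd <- adam_step(params, r$grads, state,
                       lr_at(step, train$learning_rate, train$warmup_steps),
                       weight_decay = train$weight_decay %||% 0.01,
                       grad_scale = 1 / max(r$n, 1L))
      params <- upd$params
      state <- upd$state
      logs[[length(logs) + 1L]] <-
        data.frame(step = step, epoch = epoch,
                   loss = r$loss / max(r$n, 1L))
    }
    if (!is.null(eval_fn)) {
      eval_log[[length(eval_log) + 1L]] <-
        data.frame(epoch = epoch, eval = eval_fn(params))
    }
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f", epoch,
                      logs[[length(logs)]]$loss))
    }
  }
  list(params = params,
       logs = if (length(logs)) do.call(rbind, logs) else
         data.frame(step = integer(0), epoch = integer(0),
                    loss = numeric(0)),
       eval_log = if (length(eval_log)) do.call(rbind, eval_log) else NULL)
}

#' Training hyperparameters
#'
#' Defaults follow the pretraining recipe (8 epochs, batch 64, learning
#' rate 5e-4 reached after 100 warmup steps); fine-tuning overrides them
#' (max 32 epochs, learning rate 1e-5, early stopping).
#'
#' @param epochs maximum number of passes over the training data.
#' @param batch_size samples per optimizer step.
#' @param learning_rate peak Adam learning rate.
#' @param warmup_steps linear warmup steps to the peak rate.
#' @param patience early-stopping patience (evaluations without
#'   validation-loss improvement; fine-tuning only).
#' @param weight_decay decoupled (AdamW) weight decay on weight matrices.
#' @param seed RNG seed for shuffling, masking and initialization.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(epochs = 8L, batch_size = 64L,
                         learning_rate = 5e-4, warmup_steps = 100L,
                         patience = 3L, weight_decay = 0.01, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0,
            warmup_steps >= 0, patience >= 1, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 warmup_steps = as.integer(warmup_steps),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Pretrain a language model on a corpus
#'
#' Encodes every corpus sentence, holds out a slice for evaluation, and
#' trains the family's self-supervised objective (MLM, replaced-token
#' detection for ELECTRA, permutation LM for XLNet). The embedding size is
#' checked against the tokenizer vocabulary before training.
#'
#' @param corpus a [build_corpus()] object.
#' @param tokenizer a tokenizer trained on the same corpus.
#' @param config a [model_config()]; `config$vocab_size` must equal the
#'   tokenizer vocabulary size.
#' @param train a [train_config()].
#' @param policy a [masking_policy()].
#' @param max_len encoded length (default 100).
#' @param holdout_fraction corpus fraction held out for the loss-decrease
#'   check (default 0.1).
#' @param verbose print per-epoch loss.
#' @return object of class `"methylm_lm"`: list with `config`, `tokenizer`,
#'   `params`, `stage = "pretrained"`, training `logs` and `holdout`
#'   (initial/final held-out loss).
#' @export
pretrain_lm <- function(corpus, tokenizer, config, train = train_config(),
                        policy = masking_policy(), max_len = 100L,
                        holdout_fraction = 0.1, verbose = FALSE) {
  if (config$vocab_size != tokenizer$vocab_size) {
    stop("config embedding/vocab size (", config$vocab_size,
         ") does not match tokenizer vocabulary (", tokenizer$vocab_size,
         ")", call. = FALSE)
  }
  sentences <- corpus$sentences
  encoded <- lapply(sentences, function(s) encode(tokenizer, s, max_len))

  unigram_ids <- NULL; unigram_w <- NULL
  if (config$objective == "rtd") {
    cnt <- table(unlist(lapply(encoded, function(e)
      e$input_ids[content_positions(e)]), use.names = FALSE))
    unigram_ids <- as.integer(names(cnt))
    unigram_w <- as.numeric(cnt)
  }

  n <- length(encoded)
  n_hold <- max(if (n > 1) 1L else 0L, floor(holdout_fraction * n))
  hold_idx <- integer(0)
  params <- NULL
  result <- NULL
  local_seed(train$seed, {
    if (n_hold > 0) hold_idx <- sample.int(n, n_hold)
    params <- init_params(config, seed = sample.int(.Machine$integer.max, 1))
    train_idx <- setdiff(seq_len(n), hold_idx)

    eval_items <- lapply(encoded[hold_idx], prepare_item, tokenizer =
                           tokenizer, cfg = config, policy = policy,
                         unigram_ids = unigram_ids, unigram_w = unigram_w)
    eval_items <- Filter(Negate(is.null), eval_items)
    eval_fn <- function(p) batch_loss_eval(p, config, eval_items,
                                           config$objective)
    initial <- if (length(eval_items)) eval_fn(params) else NA_real_

    items_fn <- function(epoch) {
      idx <- sample(train_idx)
      items <- lapply(encoded[idx], prepare_item, tokenizer = tokenizer,
                      cfg = config, policy = policy,
                      unigram_ids = unigram_ids, unigram_w = unigram_w)
      Filter(Negate(is.null), items)
    }
    result <- train_loop(params, config, train, items_fn, config$objective,
                         eval_fn = if (length(eval_items)) eval_fn else NULL,
                         verbose = verbose)
    result$initial_eval <- initial
  })
  structure(list(config = config, tokenizer = tokenizer,
                 params = result$params, stage = "pretrained",
                 logs = result$logs,
                 holdout = list(initial = result$initial_eval,
                                final = if (!is.null(result$eval_log))
                                  utils::tail(result$eval_log$eval, 1)
                                else NA_real_)),
            class = "methylm_lm")
}

#' @export
print.methylm_lm <- function(x, ...) {
  cat("<language model> ", x$config$family, " (", x$config$preset,
      "), stage: ", x$stage, "\n", sep = "")
  invisible(x)
}
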