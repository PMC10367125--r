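# Supervised fine-tuning for methylation-site classification.
#
# A softmax classifier head sits on the [CLS] token (tanh pooler + linear
# map to 2 logits). Fine-tuning for the three site types follows the
# cascade pretrained -> 6mA -> 4mC -> 5hmC, ordered by decreasing training
# set size, so that the smaller subsets start from an already specialised
# model.

CASCADE_ORDER <- c("6mA", "4mC", "5hmC")

init_cls_head <- function(cfg, seed = 1L) {
  local_seed(seed, {
    d <- cfg$hidden_size
    list(pool_W = rmat(d, d, cfg$init_range), pool_b = numeric(d),
         cls_W = rmat(d, 2L, cfg$init_range), cls_b = numeric(2L))
  })
}

# [CLS] classifier forward/backward. Returns loss, dH and head grads.
head_cls <- function(params, cfg, H, label01) {
  x <- H[1L, ]
  a <- drop(x %*% params$pool_W) + params$pool_b
  z <- tanh(a)
  logits <- drop(z %*% params$cls_W) + params$cls_b
  logits <- logits - max(logits)
  p <- exp(logits) / sum(exp(logits))
  y <- label01 + 1L  # 1 = negative, 2 = positive
  loss <- -log(pmax(p[y], 1e-12))
  dlog <- p
  dlog[y] <- dlog[y] - 1
  g <- list(cls_W = outer(z, dlog), cls_b = dlog)
  dz <- drop(params$cls_W %*% dlog)
  da <- dz * (1 - z^2)
  g$pool_W <- outer(x, da)
  g$pool_b <- da
  dx <- drop(params$pool_W %*% da)
  dH <- matrix(0, nrow(H), ncol(H))
  dH[1L, ] <- dx
  list(loss = loss, n = 1L, dH = dH, head = g)
}

loss_grad_cls <- function(params, cfg, item) {
  fw <- tf_forward(params, cfg, item$input_ids, key_mask = item$key_mask)
  hd <- head_cls(params, cfg, fw$h, item$label01)
  trunk <- tf_backward(params, cfg, fw$cache, hd$dH)
  list(loss = hd$loss, n = hd$n, trunk = trunk, head = hd$head)
}

cls_forward_prob <- function(params, cfg, ids, key_mask) {
  fw <- tf_forward(params, cfg, ids, key_mask = key_mask,
                   need_cache = FALSE)
  x <- fw$h[1L, ]
  z <- tanh(drop(x %*% params$pool_W) + params$pool_b)
  logits <- drop(z %*% params$cls_W) + params$cls_b
  logits <- logits - max(logits)
  p <- exp(logits) / sum(exp(logits))
  p[2L]  # positive-class probability
}

encode_dataset <- function(model, dataset, max_len = 100L) {
  sents <- process_dataset(dataset)
  lapply(sents, function(s) encode(model$tokenizer, s, max_len))
}

model_hash <- function(model) {
  rlang::hash(list(model$params, model$stage, model$config$family))
}

#' Fine-tune a language model for one methylation type
#'
#' Splits the subset 8:2 into training and validation parts (stratified),
#' trains the [CLS] classifier with early stopping on validation loss, and
#' returns the best-validation checkpoint. With `train$epochs = 0` the
#' classifier head is initialized but the base model is unchanged.
#'
#' @param model a pretrained [pretrain_lm()] model or an already fine-tuned
#'   model (cascade stage).
#' @param subset a [methyl_dataset()] containing a single methylation type.
#' @param train a [train_config()]; fine-tuning defaults are max 32 epochs,
#'   batch 64, learning rate 1e-5 with 100 warmup steps.
#' @param val_ratio validation fraction (default 0.2 for the 8:2 split).
#' @param max_len encoded length.
#' @param verbose print per-epoch losses.
#' @return object of class `"methylm_finetuned"`: the base fields plus
#'   `methyl_type`, `provenance` (chain of parent checkpoint hashes) and
#'   `history` (per-epoch train/validation loss).
#' @export
finetune <- function(model, subset,
                     train = train_config(epochs = 32L, batch_size = 64L,
                                          learning_rate = 1e-5,
                                          warmup_steps = 100L),
                     val_ratio = 0.2, max_len = 100L, verbose = FALSE) {
  if (!nrow(subset)) stop("fine-tuning subset is empty", call. = FALSE)
  types <- unique(subset$methyl_type)
  if (length(types) != 1L) {
    stop("fine-tuning subset mixes methylation types: ",
         paste(types, collapse = ", "), call. = FALSE)
  }
  cfg <- model$config
  parent_hash <- model_hash(model)
  provenance <- c(if (inherits(model, "methylm_finetuned"))
    model$provenance, parent_hash)

  params <- model$params
  if (is.null(params$pool_W)) {
    params <- c(params, init_cls_head(cfg, seed = train$seed + 1L))
  }

  out_params <- params
  history <- NULL
  local_seed(train$seed, {
    if (train$epochs > 0L) {
      sp <- train_val_split(subset, ratio = 1 - val_ratio,
                            seed = sample.int(.Machine$integer.max, 1))
      enc_train <- encode_dataset(model, sp$train, max_len)
      enc_val <- encode_dataset(model, sp$val, max_len)
      lab_train <- as.integer(sp$train$label == "positive")
      lab_val <- as.integer(sp$val$label == "positive")
      items_train <- lapply(seq_along(enc_train), function(i) {
        list(input_ids = enc_train[[i]]$input_ids,
             key_mask = key_mask_of(enc_train[[i]]),
             label01 = lab_train[i])
      })
      items_val <- lapply(seq_along(enc_val), function(i) {
        list(input_ids = enc_val[[i]]$input_ids,
             key_mask = key_mask_of(enc_val[[i]]),
             label01 = lab_val[i])
      })
      val_loss <- function(p) batch_loss_eval(p, cfg, items_val, "cls")

      state <- new_adam_state(params)
      step <- 0L
      best_loss <- Inf
      best_params <- params
      stale <- 0L
      hist <- list()
      for (epoch in seq_len(train$epochs)) {
        idx <- sample(seq_along(items_train))
        batches <- split(idx, ceiling(seq_along(idx) / train$batch_size))
        ep_loss <- 0; ep_n <- 0L
        for (b in batches) {
          r <- batch_loss_grad(params, cfg, items_train[b], "cls")
          step <- step + 1L
          upd <- adam_step(params, r$grads, state,
                           lr_at(step, train$learning_rate,
                                 train$warmup_steps),
                           weight_decay = train$weight_decay %||% 0.01,
                           grad_scale = 1 / max(r$n, 1L))
          params <- upd$params
          state <- upd$state
          ep_loss <- ep_loss + r$loss
          ep_n <- ep_n + r$n
        }
        vl <- val_loss(params)
        hist[[epoch]] <- data.frame(epoch = epoch,
                                    train_loss = ep_loss / max(ep_n, 1L),
                                    val_loss = vl)
        if (verbose) {
          message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                          ep_loss / max(ep_n, 1L), vl))
        }
        if (vl < best_loss - 1e-9) {
          best_loss <- vl
          best_params <- params
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= train$patience) break
        }
      }
      out_params <- best_params
      history <- do.call(rbind, hist)
    }
  })

  structure(list(config = cfg, tokenizer = model$tokenizer,
                 params = out_params,
                 stage = paste0("finetuned-", types),
                 methyl_type = types, provenance = provenance,
                 history = history),
            class = c("methylm_finetuned", "methylm_lm"))
}

#' Cascaded fine-tuning over the three methylation types
#'
#' Fine-tunes 6mA from the pretrained model, 4mC from the 6mA model, and
#' 5hmC from the 4mC model. Empty subsets are skipped with a warning; the
#' next stage then starts from the most recent available model.
#'
#' @param pretrained a [pretrain_lm()] model.
#' @param subsets named list of [methyl_dataset()]s (names among `"6mA"`,
#'   `"4mC"`, `"5hmC"`), e.g. from [split_by_type()].
#' @param train a [train_config()].
#' @param ... passed to [finetune()].
#' @return named list of fine-tuned models (present stages only).
#' @export
cascade_finetune <- function(pretrained, subsets,
                             train = train_config(epochs = 32L,
                                                  batch_size = 64L,
                                                  learning_rate = 1e-5,
                                                  warmup_steps = 100L),
                             ...) {
  out <- list()
  current <- pretrained
  for (tp in CASCADE_ORDER) {
    subset <- subsets[[tp]]
    if (is.null(subset) || !nrow(subset)) {
      warning("no samples for ", tp, "; cascade stage skipped",
              call. = FALSE)
      next
    }
    current <- finetune(current, subset, train = train, ...)
    out[[tp]] <- current
  }
  out
}

#' Predict positive-class probabilities for samples
#'
#' Deterministic (evaluation-mode) forward pass; per-sample encoding
#' failures (e.g. N-containing sequences) yield `NA` with a warning rather
#' than aborting the batch.
#'
#' @param model a fine-tuned model.
#' @param samples a [methyl_dataset()].
#' @param max_len encoded length.
#' @return numeric vector of probabilities in `[0, 1]`, `NA` where encoding
#'   failed.
#' @export
predict_proba <- function(model, samples, max_len = 100L) {
  if (!inherits(model, "methylm_finetuned")) {
    stop("predict_proba requires a fine-tuned model", call. = FALSE)
  }
  cfg <- model$config
  enc_list <- lapply(seq_len(nrow(samples)), function(i) {
    tryCatch({
      s <- build_sentence(samples$sequence[i], sample_lineage(samples, i),
                          samples$id[i])
      encode(model$tokenizer, s, max_len)
    }, error = function(e) {
      warning("sample '", samples$id[i], "' could not be encoded: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  out <- rep(NA_real_, nrow(samples))
  ok <- which(!vapply(enc_list, is.null, logical(1)))
  if (length(ok)) {
    out[ok] <- batch_cls_probs(model$params, cfg, enc_list[ok])
  }
  out
}

#' Save / load a model checkpoint
#'
#' Writes the transformer-checkpoint layout: `config.json`, `weights.rds`
#' and a `tokenizer/` directory with plain-text vocabulary files.
#'
#' @param model a pretrained or fine-tuned model.
#' @param dir checkpoint directory.
#' @return `dir` (or the loaded model), invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- unclass(model$config)
  meta$stage <- model$stage
  meta$methyl_type <- model$methyl_type
  meta$provenance <- model$provenance
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  save_tokenizer(model$tokenizer, file.path(dir, "tokenizer"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  stage <- meta$stage
  methyl_type <- meta$methyl_type
  provenance <- unlist(meta$provenance)
  meta$stage <- NULL; meta$methyl_type <- NULL; meta$provenance <- NULL
  cfg <- meta
  for (nm in c("n_layers", "n_heads", "hidden_size", "intermediate_size",
               "embedding_size", "vocab_size", "max_position")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  cfg$share_layers <- isTRUE(cfg$share_layers)
  for (nm in c("layer_norm_eps", "init_range")) {
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  }
  class(cfg) <- "methylm_config"
  model <- list(config = cfg,
                tokenizer = load_tokenizer(file.path(dir, "tokenizer")),
                params = readRDS(file.path(dir, "weights.rds")),
                stage = stage, methyl_type = methyl_type,
                provenance = provenance)
  cls <- if (!is.null(stage) && startsWith(stage, "finetuned")) {
    c("methylm_finetuned", "methylm_lm")
  } else {
    "methylm_lm"
  }
  structure(model, class = cls)
}
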