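# Masking policy, objectives and pretraining behaviour.

test_that("masking policy validates its rates", {
  expect_error(masking_policy(mask_rate = 0.7), "must equal 1")
  expect_error(masking_policy(select_rate = 1.2), "select_rate")
  p <- masking_policy()
  expect_equal(p$mask_rate + p$random_rate + p$keep_rate, 1)
})

test_that("a zero selection rate leaves the sample untouched", {
  tok <- fx_tokenizer("BERT")
  enc <- encode(tok, process_dataset(fx_dataset()$dataset[1, ])[[1]])
  set.seed(1)
  mk <- mask_tokens(enc, tok, masking_policy(select_rate = 0))
  expect_identical(mk$input_ids, enc$input_ids)
  expect_true(all(is.na(mk$mlm_labels)))
  expect_false(any(mk$selected))
})

test_that("masking never touches special or padding tokens", {
  tok <- fx_tokenizer("BERT")
  enc <- encode(tok, process_dataset(fx_dataset()$dataset[2, ])[[1]])
  special <- enc$tokens %in% c("[CLS]", "[SEP]", "[PAD]")
  set.seed(2)
  for (i in 1:20) {
    mk <- mask_tokens(enc, tok, masking_policy(select_rate = 0.5))
    expect_false(any(mk$selected[special]))
    expect_identical(mk$input_ids[special], enc$input_ids[special])
    # label bookkeeping: non-ignored labels exactly at selected positions
    expect_equal(which(!is.na(mk$mlm_labels)), which(mk$selected))
    expect_identical(mk$mlm_labels[mk$selected],
                     enc$input_ids[mk$selected])
  }
})

test_that("masking statistics match the 15/80/10 policy", {
  tok <- fx_tokenizer("BERT")
  ds <- fx_dataset()$dataset
  encs <- lapply(process_dataset(ds[1:40, ]), function(s) encode(tok, s))
  set.seed(3)
  n_maskable <- 0L; n_sel <- 0L; n_masked <- 0L; n_random <- 0L
  for (r in 1:50) {
    for (enc in encs) {
      mk <- mask_tokens(enc, tok)
      maskable <- enc$attention_mask == 1L &
        enc$input_ids > length(methylm:::SPECIAL_TOKENS)
      n_maskable <- n_maskable + sum(maskable)
      sel <- which(mk$selected)
      n_sel <- n_sel + length(sel)
      n_masked <- n_masked + sum(mk$input_ids[sel] == methylm:::MASK_ID)
      n_random <- n_random + sum(mk$input_ids[sel] != methylm:::MASK_ID &
                                   mk$input_ids[sel] != enc$input_ids[sel])
    }
  }
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(n_sel / n_maskable - 0.15), 3 * se(0.15, n_maskable))
  expect_lt(abs(n_masked / n_sel - 0.80), 3 * se(0.80, n_sel))
  expect_lt(abs(n_random / n_sel - 0.10), 3 * se(0.10, n_sel) + 1e-3)
})

test_that("masking replays identically under a fixed RNG state", {
  tok <- fx_tokenizer("BERT")
  enc <- encode(tok, process_dataset(fx_dataset()$dataset[3, ])[[1]])
  set.seed(99)
  a <- mask_tokens(enc, tok)
  set.seed(99)
  b <- mask_tokens(enc, tok)
  expect_identical(a, b)
})

test_that("pretraining rejects a vocab/embedding mismatch", {
  tok <- fx_tokenizer("BERT")
  cfg <- model_config("BERT", "tiny", vocab_size = tok$vocab_size + 5L)
  expect_error(pretrain_lm(fx_corpus(), tok, cfg, train_config(epochs = 0)),
               "does not match")
})

test_that("zero-epoch pretraining returns the initialization unchanged", {
  lm1 <- fx_lm0("BERT", seed = 5)
  lm2 <- fx_lm0("BERT", seed = 5)
  expect_identical(lm1$params, lm2$params)
  expect_equal(lm1$stage, "pretrained")
  expect_equal(nrow(lm1$logs), 0)
})

test_that("held-out MLM loss decreases on a small synthetic corpus", {
  gen <- generate_dataset(100, 100, "6mA", seed = 51)
  corpus <- build_corpus(gen$dataset)
  tok <- train_tokenizer(corpus, "BERT")
  cfg <- model_config("BERT", "tiny", vocab_size = tok$vocab_size)
  lm <- pretrain_lm(corpus, tok, cfg,
                    train_config(epochs = 3, batch_size = 16,
                                 learning_rate = 1e-3, warmup_steps = 20,
                                 seed = 6))
  expect_lt(lm$holdout$final, lm$holdout$initial)
  # training loss was logged per step
  expect_gt(nrow(lm$logs), 0)
})

test_that("ELECTRA and XLNet objectives train and evaluate", {
  gen <- generate_dataset(60, 60, "6mA", seed = 52)
  corpus <- build_corpus(gen$dataset)
  for (fam in c("ELECTRA", "XLNet")) {
    tok <- train_tokenizer(corpus, fam)
    cfg <- model_config(fam, "tiny", vocab_size = tok$vocab_size)
    expect_equal(cfg$objective, if (fam == "ELECTRA") "rtd" else "plm")
    lm <- pretrain_lm(corpus, tok, cfg,
                      train_config(epochs = 1, batch_size = 16,
                                   learning_rate = 1e-3,
                                   warmup_steps = 10, seed = 7))
    expect_s3_class(lm, "methylm_lm")
    expect_true(is.finite(lm$holdout$final))
  }
})

test_that("pretraining is reproducible for a fixed seed", {
  gen <- generate_dataset(30, 30, "6mA", seed = 53)
  corpus <- build_corpus(gen$dataset)
  tok <- train_tokenizer(corpus, "BERT")
  cfg <- model_config("BERT", "tiny", vocab_size = tok$vocab_size)
  tc <- train_config(epochs = 1, batch_size = 8, learning_rate = 1e-3,
                     warmup_steps = 5, seed = 88)
  lm1 <- pretrain_lm(corpus, tok, cfg, tc)
  lm2 <- pretrain_lm(corpus, tok, cfg, tc)
  expect_identical(lm1$params$layers[[1]]$Wq, lm2$params$layers[[1]]$Wq)
  expect_identical(lm1$logs$loss, lm2$logs$loss)
})

test_that("batched and per-sample forward/backward agree", {
  tok <- fx_tokenizer("BERT")
  cfg <- model_config("BERT", "tiny", vocab_size = tok$vocab_size)
  params <- c(methylm:::init_params(cfg, 1),
              methylm:::init_cls_head(cfg, 2))
  encs <- lapply(process_dataset(fx_dataset()$dataset[1:4, ]),
                 function(s) encode(tok, s))
  items <- lapply(seq_along(encs), function(i) {
    list(input_ids = encs[[i]]$input_ids,
         key_mask = methylm:::key_mask_of(encs[[i]]),
         label01 = as.integer(i %% 2))
  })
  rb <- methylm:::batch_loss_grad(params, cfg, items, "cls")
  loss_sum <- 0
  acc_wq <- params$layers[[1]]$Wq * 0
  for (it in items) {
    r <- methylm:::loss_grad_cls(params, cfg, it)
    loss_sum <- loss_sum + r$loss
    acc_wq <- acc_wq + r$trunk$layers[[1]]$Wq
  }
  expect_equal(rb$loss, loss_sum, tolerance = 1e-10)
  expect_equal(rb$grads$layers[[1]]$Wq, acc_wq, tolerance = 1e-10)
})
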