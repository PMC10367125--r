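# Shared fixtures, built lazily and cached for the whole test run.
# Training fixtures use the tiny preset and small planted-motif datasets so
# the full pipeline (tokenize -> pretrain -> cascade -> ensemble ->
# interpret -> scan) stays exercisable on one CPU.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

fx_dataset <- function() {
  fixture("dataset", function() {
    generate_dataset(200, 200, "6mA", seed = 101)
  })
}

fx_corpus <- function() {
  fixture("corpus", function() build_corpus(fx_dataset()$dataset))
}

fx_tokenizer <- function(family = "BERT") {
  fixture(paste0("tok_", family), function() {
    train_tokenizer(fx_corpus(), family, vocab_size = 25000)
  })
}

# An untrained (randomly initialized) language model handle.
fx_lm0 <- function(family = "BERT", seed = 7L) {
  tok <- fx_tokenizer(family)
  cfg <- model_config(family, "tiny", vocab_size = tok$vocab_size)
  pretrain_lm(fx_corpus(), tok, cfg, train_config(epochs = 0, seed = seed))
}

fx_family_index <- function(family) {
  match(family, c("BERT", "DistilBERT", "ELECTRA", "ALBERT", "XLNet"))
}

# A briefly pretrained base per family (family objective: MLM / RTD / PLM).
fx_pretrained <- function(family = "BERT") {
  fixture(paste0("pre_", family), function() {
    k <- fx_family_index(family)
    tok <- fx_tokenizer(family)
    cfg <- model_config(family, "tiny", vocab_size = tok$vocab_size)
    pretrain_lm(fx_corpus(), tok, cfg,
                train_config(epochs = 2, batch_size = 16,
                             learning_rate = 1e-3, warmup_steps = 20,
                             seed = 40 + k))
  })
}

fx_subsets <- function() {
  fixture("subsets", function() {
    list("6mA" = fx_dataset()$dataset,
         "4mC" = generate_dataset(30, 30, "4mC", seed = 102)$dataset,
         "5hmC" = generate_dataset(25, 25, "5hmC", seed = 103)$dataset)
  })
}

# Full cascade (6mA -> 4mC -> 5hmC) per family from the pretrained base.
fx_cascade <- function(family = "BERT") {
  fixture(paste0("cascade_", family), function() {
    k <- fx_family_index(family)
    cascade_finetune(fx_pretrained(family), fx_subsets(),
                     train = train_config(epochs = 6, batch_size = 16,
                                          learning_rate = 5e-4,
                                          warmup_steps = 20, patience = 3,
                                          seed = 200 + k))
  })
}

# The 6mA stage of the cascade; reused by the interpretability and
# scanning tests.
fx_finetuned <- function(family = "BERT") {
  fx_cascade(family)[["6mA"]]
}

# Five-member ensemble for 6mA (one model per family).
fx_ensemble <- function() {
  fixture("ensemble", function() {
    members <- lapply(c("BERT", "DistilBERT", "ALBERT", "XLNet",
                        "ELECTRA"), fx_finetuned)
    names(members) <- c("BERT", "DistilBERT", "ALBERT", "XLNet", "ELECTRA")
    ensemble_model(members)
  })
}

fx_heldout <- function() {
  fixture("heldout", function() {
    generate_dataset(60, 60, "6mA", seed = 777)
  })
}

# A tiny hand-weighted 1-layer, 1-head model for dense-oracle tests.
fx_hand_model <- function(uniform_attention = FALSE, seed = 33L) {
  tok <- fx_tokenizer("BERT")
  cfg <- model_config("BERT", "tiny", vocab_size = tok$vocab_size,
                      n_layers = 1L, n_heads = 1L, hidden_size = 8L,
                      intermediate_size = 16L)
  params <- methylm:::init_params(cfg, seed = seed)
  if (uniform_attention) {
    params$layers[[1]]$Wq[] <- 0
    params$layers[[1]]$Wk[] <- 0
    params$layers[[1]]$bq[] <- 0
    params$layers[[1]]$bk[] <- 0
  }
  params <- c(params, methylm:::init_cls_head(cfg, seed = seed + 1L))
  structure(list(config = cfg, tokenizer = tok, params = params,
                 stage = "finetuned-6mA", methyl_type = "6mA",
                 provenance = "hand", history = NULL),
            class = c("methylm_finetuned", "methylm_lm"))
}

expect_setequal_df <- function(a, b) {
  expect_equal(a[order(a$id), , drop = FALSE]$id,
               b[order(b$id), , drop = FALSE]$id)
}
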