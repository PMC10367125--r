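# Attention extraction and attention-derived importance.

test_that("attention rows are probability distributions over content keys", {
  model <- fx_finetuned("BERT")
  sample <- fx_heldout()$dataset[1, , drop = FALSE]
  att <- attention_matrices(model, sample)
  A <- att$values
  dims <- dim(A)
  expect_equal(dims[1], model$config$n_layers)
  expect_equal(dims[2], model$config$n_heads)
  n_content <- sum(att$encoded$attention_mask)
  for (l in seq_len(dims[1])) {
    for (h in seq_len(dims[2])) {
      rs <- rowSums(A[l, h, , ])
      expect_true(all(abs(rs - 1) < 1e-5))
      # no weight ever lands on padding keys
      expect_true(all(A[l, h, , (n_content + 1):dims[4]] == 0))
      expect_true(all(A[l, h, , ] >= 0))
    }
  }
})

test_that("attention matches a dense recomputation from the stored weights", {
  model <- fx_hand_model()
  sample <- fx_heldout()$dataset[2, , drop = FALSE]
  att <- attention_matrices(model, sample)
  enc <- att$encoded
  p <- model$params
  cfg <- model$config
  L <- length(enc$input_ids)

  # independent dense forward: embeddings -> layer norm -> Q,K -> softmax
  X0 <- p$tok_emb[enc$input_ids, ] + p$pos_emb[1:L, ]
  ln <- function(x, g, b) {
    t(apply(x, 1, function(r) {
      g * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + cfg$layer_norm_eps) + b
    }))
  }
  X <- ln(X0, p$emb_ln_g, p$emb_ln_b)
  Q <- X %*% p$layers[[1]]$Wq + matrix(p$layers[[1]]$bq, L, 8, byrow = TRUE)
  K <- X %*% p$layers[[1]]$Wk + matrix(p$layers[[1]]$bk, L, 8, byrow = TRUE)
  S <- Q %*% t(K) / sqrt(8)
  S[, enc$attention_mask == 0] <- -Inf
  A_oracle <- t(apply(S, 1, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  expect_equal(att$values[1, 1, , ], A_oracle, tolerance = 1e-8)
})

test_that("token importance sums [CLS]-anchored weights over heads and layers", {
  model <- fx_finetuned("BERT")
  sample <- fx_heldout()$dataset[3, , drop = FALSE]
  ti <- token_importance(model, sample)
  att <- attention_matrices(model, sample)
  A <- att$values
  # tensor-slicing oracle: [CLS]-as-Query rows over all layers and heads
  oracle <- apply(A[, , 1, , drop = FALSE], 4, sum)
  expect_equal(unname(as.numeric(ti)), oracle, tolerance = 1e-12)
  expect_true(all(ti >= 0))
  # conservation: content total equals heads x layers
  expect_equal(sum(ti), model$config$n_heads * model$config$n_layers,
               tolerance = 1e-6)

  # last-layer restriction slices only the final layer
  ti_last <- token_importance(model, sample, layers = "last")
  last <- dim(A)[1]
  expect_equal(unname(as.numeric(ti_last)), colSums(A[last, , 1, ]),
               tolerance = 1e-12)

  # opposite direction slices the [CLS] column instead
  tk <- token_importance(model, sample, direction = "cls-key")
  expect_equal(unname(as.numeric(tk)),
               apply(A[, , , 1, drop = FALSE], 3, sum), tolerance = 1e-12)
})

test_that("uniform attention gives tied content-token importances", {
  model <- fx_hand_model(uniform_attention = TRUE)
  sample <- fx_heldout()$dataset[4, , drop = FALSE]
  ti <- token_importance(model, sample)
  enc <- attr(ti, "encoded")
  content <- which(enc$attention_mask == 1L)
  expect_lt(diff(range(ti[content])), 1e-10)
  expect_true(all(ti[-content] == 0))
})

test_that("word importance aggregates token scores by source word", {
  model <- fx_finetuned("BERT")
  sample <- fx_heldout()$dataset[5, , drop = FALSE]
  wi <- word_importance(model, sample)
  ti <- token_importance(model, sample)
  enc <- attr(ti, "encoded")
  expect_equal(nrow(wi), length(enc$words))
  expect_equal(sum(wi$role == "dna"), 36)
  i <- which(wi$role == "dna")[7]
  expect_equal(wi$score[i],
               sum(ti[which(!is.na(enc$word_ids) & enc$word_ids == i)]))
})

test_that("model-averaged importance is the word-wise mean", {
  models <- list(fx_finetuned("BERT"), fx_finetuned("DistilBERT"),
                 fx_finetuned("ELECTRA"))
  sample <- fx_heldout()$dataset[6, , drop = FALSE]
  avg <- ensemble_token_importance(models, sample)
  singles <- lapply(models, word_importance, sample = sample)
  manual <- rowMeans(do.call(cbind, lapply(singles, `[[`, "score")))
  expect_equal(avg$score, manual, tolerance = 1e-12)

  # single-model identity
  one <- ensemble_token_importance(models[1], sample)
  expect_equal(one$score, singles[[1]]$score)

  # unigram members are dropped with a warning; none left is an error
  expect_warning(
    mixed <- ensemble_token_importance(list(models[[1]],
                                            fx_finetuned("ALBERT")),
                                       sample),
    "dropped")
  expect_equal(mixed$score, singles[[1]]$score)
  expect_error(
    suppressWarnings(
      ensemble_token_importance(list(fx_finetuned("ALBERT")), sample)),
    "no word-piece")
})

test_that("position importance merges covering 6-mer scores", {
  # constant profile stays constant under mean merging
  expect_equal(position_importance(rep(2.5, 36)), rep(2.5, 41))
  # support case: only word 1 nonzero touches positions 1..6
  w <- c(3, rep(0, 35))
  pi1 <- position_importance(w)
  expect_true(all(pi1[1:6] > 0))
  expect_true(all(pi1[7:41] == 0))
  # coverage-enumeration oracle on random scores, mean and sum rules
  set.seed(18)
  ws <- runif(36)
  cover <- lapply(1:41, function(p) {
    Filter(function(j) j >= 1 && j <= 36, (p - 5):p)
  })
  expect_equal(position_importance(ws),
               vapply(cover, function(cv) mean(ws[cv]), numeric(1)))
  expect_equal(position_importance(ws, merge = "sum"),
               vapply(cover, function(cv) sum(ws[cv]), numeric(1)))
  # between 1 and 6 covering words, min(p, 41 - p + 1, 6) of them
  expect_equal(lengths(cover),
               pmin(1:41, 41 - (1:41) + 1, 6))
})

test_that("DNA-to-taxonomy attention has the 36 x 8 contract", {
  model <- fx_finetuned("BERT")
  sample <- fx_heldout()$dataset[7, , drop = FALSE]
  M <- dna_to_taxonomy_attention(model, sample)
  expect_equal(dim(M), c(36, 8))
  expect_equal(colnames(M), c("species", "genus", "family", "order",
                              "class", "phylum", "kingdom", "domain"))
  expect_true(all(M >= 0, na.rm = TRUE))

  # tensor-slicing oracle for one cell
  att <- attention_matrices(model, sample)
  enc <- att$encoded
  A <- att$values
  last <- dim(A)[1]
  q_tokens <- which(!is.na(enc$word_ids) & enc$word_ids == 5)
  sp <- enc$taxonomy_token_spans$genus
  oracle <- sum(A[last, , q_tokens, sp[1]:sp[2]])
  expect_equal(M[5, "genus"], oracle, tolerance = 1e-12)
})

test_that("uniform attention gives taxonomy cells scaled by span length", {
  model <- fx_hand_model(uniform_attention = TRUE)
  sample <- fx_heldout()$dataset[8, , drop = FALSE]
  M <- dna_to_taxonomy_attention(model, sample)
  att <- attention_matrices(model, sample)
  span_len <- vapply(att$encoded$taxonomy_token_spans,
                     function(s) s[2] - s[1] + 1L, integer(1))
  # cells for equal-length spans are identical under uniform attention
  for (r1 in names(span_len)) for (r2 in names(span_len)) {
    if (span_len[r1] == span_len[r2]) {
      expect_equal(M[1, r1], M[1, r2], tolerance = 1e-10)
    }
  }
})

test_that("motif ranking equals an independent group-by-mean", {
  model <- fx_finetuned("BERT")
  pos <- fx_heldout()$dataset[1:12, , drop = FALSE]
  tm <- top_motifs(model, pos, n = 10)
  expect_lte(nrow(tm), 10)
  expect_true(all(diff(tm$mean_score) <= 0))

  # tabulation oracle
  words <- c(); scores <- c()
  for (i in 1:12) {
    wi <- word_importance(model, pos[i, , drop = FALSE])
    dna <- wi[wi$role == "dna", ]
    words <- c(words, toupper(dna$word)); scores <- c(scores, dna$score)
  }
  agg <- sort(tapply(scores, words, mean), decreasing = TRUE)
  expect_equal(tm$mean_score[1], unname(agg[1]), tolerance = 1e-12)
  expect_equal(tm$motif[1], names(agg)[1])
  cnt <- table(words)
  expect_equal(tm$count, as.integer(cnt[tm$motif]))
})

test_that("[CLS] embeddings have hidden_size length and match a dense pass", {
  model <- fx_finetuned("BERT")
  sample <- fx_heldout()$dataset[9, , drop = FALSE]
  e1 <- cls_embedding(model, sample)
  expect_length(e1, model$config$hidden_size)
  expect_identical(e1, cls_embedding(model, sample))

  # dense forward oracle via the reference per-sample path
  enc <- methylm:::to_encoded(model, sample)
  fw <- methylm:::tf_forward(model$params, model$config, enc$input_ids,
                             key_mask = methylm:::key_mask_of(enc),
                             need_cache = FALSE)
  expect_equal(e1, fw$h[1, ], tolerance = 1e-12)
})

test_that("importance is invariant to padding beyond the content", {
  model <- fx_finetuned("BERT")
  sample <- fx_heldout()$dataset[10, , drop = FALSE]
  ti_100 <- token_importance(model, sample, max_len = 100)
  ti_120 <- token_importance(model, sample, max_len = 120)
  n <- sum(attr(ti_100, "encoded")$attention_mask)
  expect_equal(unname(ti_100[1:n]), unname(ti_120[1:n]),
               tolerance = 1e-10)
})
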