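# Custom tokenizer training and fixed-length encoding.

all_6mers_corpus <- function() {
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases, bases, bases),
                 1, paste, collapse = "")
  # pack all 4096 6-mers into sentences of 64 words each
  sentences <- vapply(split(kmers, ceiling(seq_along(kmers) / 64)),
                      paste, character(1), collapse = " ")
  unname(sentences)
}

test_that("every 6-mer becomes a single token at the 25k vocab target", {
  corp <- all_6mers_corpus()
  for (fam in c("BERT", "ALBERT")) {   # one word-piece, one unigram family
    tok <- train_tokenizer(corp, fam, vocab_size = 25000)
    kmers <- tolower(unlist(strsplit(corp, " ")))
    pieces <- lapply(unique(kmers), function(w) {
      methylm:::tokenize_word(tok, w)
    })
    expect_true(all(lengths(pieces) == 1L))
    expect_equal(unlist(pieces), unique(kmers))
  }
})

test_that("tokenizer training is deterministic and words round-trip", {
  co <- fx_corpus()
  tok1 <- train_tokenizer(co, "BERT")
  tok2 <- train_tokenizer(co, "BERT")
  expect_identical(tok1$tokens, tok2$tokens)

  # round-trip oracle over the corpus vocabulary, word by word
  words <- unique(unlist(lapply(co$sentences[1:20],
                                methylm:::pretokenize)))
  for (w in words) {
    pieces <- methylm:::tokenize_word(tok1, w)
    expect_gte(length(pieces), 1L)
    rejoined <- paste(sub("^##", "", pieces), collapse = "")
    expect_equal(rejoined, w)
  }
  expect_error(train_tokenizer(co, "BERT", vocab_size = 3), "special")
})

test_that("special tokens occupy distinct reserved ids", {
  tok <- fx_tokenizer("BERT")
  ids <- tok$vocab[c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")]
  expect_equal(unname(ids), 1:5)
})

test_that("encoding produces the fixed [CLS] ... [SEP] [PAD]* layout", {
  tok <- fx_tokenizer("BERT")
  sent <- process_dataset(fx_dataset()$dataset[1, ])[[1]]
  enc <- encode(tok, sent, max_len = 100)

  expect_length(enc$input_ids, 100)
  expect_equal(enc$tokens[1], "[CLS]")
  first_pad <- match("[PAD]", enc$tokens)
  expect_equal(enc$tokens[first_pad - 1L], "[SEP]")
  expect_true(all(enc$tokens[first_pad:100] == "[PAD]"))
  expect_equal(enc$attention_mask,
               as.integer(seq_len(100) < first_pad))
  # positional scan oracle
  expect_equal(sum(enc$attention_mask), first_pad - 1L)

  # determinism
  enc2 <- encode(tok, sent, max_len = 100)
  expect_identical(enc$input_ids, enc2$input_ids)
})

test_that("encoding an empty text yields [CLS][SEP] plus padding", {
  tok <- fx_tokenizer("BERT")
  enc <- encode(tok, "", max_len = 100)
  expect_equal(enc$tokens[1:2], c("[CLS]", "[SEP]"))
  expect_true(all(enc$tokens[3:100] == "[PAD]"))
  expect_equal(sum(enc$attention_mask), 2L)
})

test_that("attention-mask sum matches the first-pad index on random inputs", {
  tok <- fx_tokenizer("BERT")
  ds <- fx_dataset()$dataset
  set.seed(41)
  for (i in sample(nrow(ds), 10)) {
    enc <- encode(tok, process_dataset(ds[i, ])[[1]])
    expect_equal(sum(enc$attention_mask),
                 match("[PAD]", enc$tokens) - 1L)
  }
})

test_that("DNA and taxonomy token spans are recorded and disjoint", {
  tok <- fx_tokenizer("BERT")
  ds <- fx_dataset()$dataset
  enc <- encode(tok, process_dataset(ds[1, ])[[1]])
  sp <- enc$dna_token_span
  expect_equal(sp[2] - sp[1] + 1L, 36L)   # word-piece: one token per 6-mer
  tax <- enc$taxonomy_token_spans
  expect_length(tax, 8)
  for (r in names(tax)) {
    expect_true(tax[[r]][1] > sp[2] || tax[[r]][2] < sp[1])
  }
  # spans really cover the rank names
  expect_equal(enc$tokens[tax$species[1]:tax$species[2]],
               tolower(strsplit(ds$species[1], " ")[[1]]))
})

test_that("decoding restores the DNA words of an encoded sentence", {
  tok <- fx_tokenizer("BERT")
  sent <- process_dataset(fx_dataset()$dataset[2, ])[[1]]
  enc <- encode(tok, sent)
  sp <- enc$dna_token_span
  decoded <- decode(tok, enc$input_ids[sp[1]:sp[2]])
  expect_equal(decoded, tolower(paste(sent$dna_words, collapse = " ")))
})

test_that("overflow truncates the taxonomy tail, never DNA words", {
  tok <- fx_tokenizer("BERT")
  long_lineage <- taxonomic_lineage(
    species = paste(rep("Very long species epithet", 8), collapse = " "),
    genus = paste(rep("genuslike", 10), collapse = " "))
  ds <- fx_dataset()$dataset
  sent <- build_sentence(ds$sequence[1], long_lineage, "long")
  enc <- encode(tok, sent, max_len = 100)
  expect_length(enc$input_ids, 100)
  sp <- enc$dna_token_span
  expect_equal(sp[2] - sp[1] + 1L, 36L)
  # dropped ranks are simply absent from the span map
  expect_lt(length(enc$taxonomy_token_spans), 8)
})

test_that("unigram and word-piece tokenizers agree on single-token words", {
  tok_u <- fx_tokenizer("XLNet")
  expect_equal(tok_u$algorithm, "unigram")
  enc <- encode(tok_u, process_dataset(fx_dataset()$dataset[1, ])[[1]])
  sp <- enc$dna_token_span
  expect_equal(sp[2] - sp[1] + 1L, 36L)
})

test_that("tokenizers round-trip through their saved directory layout", {
  for (fam in c("BERT", "ALBERT")) {
    tok <- fx_tokenizer(fam)
    dir <- tempfile()
    save_tokenizer(tok, dir)
    expect_true(file.exists(file.path(dir, "vocab.txt")))
    back <- load_tokenizer(dir)
    expect_identical(back$tokens, tok$tokens)
    expect_equal(back$algorithm, tok$algorithm)
    sent <- process_dataset(fx_dataset()$dataset[3, ])[[1]]
    expect_identical(encode(back, sent)$input_ids,
                     encode(tok, sent)$input_ids)
  }
})
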