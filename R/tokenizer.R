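# Custom subword tokenizers trained on the 6-mer + lineage corpus.
#
# Two algorithms cover the five model families:
#   * word-piece (BERT, DistilBERT, ELECTRA): frequency-ranked whole words
#     plus character fallback pieces ("##x" continuations), greedy
#     longest-match encoding — word-aligned tokens for in-vocabulary words.
#   * unigram (ALBERT, XLNet): the same inventory scored by log relative
#     frequency, Viterbi (maximum-likelihood) segmentation.
# Both guarantee that every corpus word at or above `min_frequency` —
# in particular every 6-mer — is a single vocabulary token as long as the
# vocabulary budget allows, which a 25,000-token target always does for the
# 4096 possible 6-mers.

MODEL_FAMILIES <- c("BERT", "DistilBERT", "ALBERT", "XLNet", "ELECTRA")

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
PAD_ID <- 1L; UNK_ID <- 2L; CLS_ID <- 3L; SEP_ID <- 4L; MASK_ID <- 5L

family_algorithm <- function(family) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (family %in% c("ALBERT", "XLNet")) "unigram" else "wordpiece"
}

# Lowercase (uncased families) and split into words; punctuation becomes
# its own word, as in standard BERT pre-tokenization.
pretokenize <- function(text, lowercase = TRUE) {
  if (lowercase) text <- tolower(text)
  text <- gsub("([],.;:!?()[])", " \\1 ", text)
  words <- strsplit(trimws(text), "\\s+")[[1]]
  words[nzchar(words)]
}

#' Train a custom tokenizer on a corpus
#'
#' Builds the subword vocabulary for one model family from the corpus word
#' frequencies: special tokens, all single characters (plus `##`
#' continuation pieces for word-piece), then whole words by decreasing
#' frequency until `vocab_size` is reached. Deterministic for a fixed corpus
#' and settings (frequency ties are broken lexicographically).
#'
#' @param corpus a [build_corpus()] object (or character vector of sentences).
#' @param family one of `"BERT"`, `"DistilBERT"`, `"ALBERT"`, `"XLNet"`,
#'   `"ELECTRA"`; picks the subword algorithm (word-piece or unigram).
#' @param vocab_size vocabulary budget; defaults to the corpus target.
#' @param min_frequency minimum corpus count for a whole word to become a
#'   vocabulary token (default 1).
#' @return object of class `"methylm_tokenizer"`.
#' @export
train_tokenizer <- function(corpus, family = "BERT", vocab_size = NULL,
                            min_frequency = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  sentences <- if (inherits(corpus, "methylm_corpus")) corpus$sentences
               else as.character(corpus)
  if (!length(sentences)) stop("corpus is empty", call. = FALSE)
  if (is.null(vocab_size)) {
    vocab_size <- if (inherits(corpus, "methylm_corpus"))
      corpus$vocab_size_target else 25000L
  }
  vocab_size <- as.integer(vocab_size)
  if (vocab_size <= length(SPECIAL_TOKENS)) {
    stop("vocab_size (", vocab_size, ") must exceed the ",
         length(SPECIAL_TOKENS), " special tokens", call. = FALSE)
  }
  algorithm <- family_algorithm(family)

  words <- unlist(lapply(sentences, pretokenize), use.names = FALSE)
  freq <- table(words)
  freq <- freq[freq >= min_frequency]
  # deterministic rank: frequency desc, then lexicographic
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  ranked <- names(freq)[ord]
  ranked_counts <- as.integer(freq)[ord]

  chars <- sort(unique(strsplit(paste(names(freq), collapse = ""), "")[[1]]))
  base_pieces <- if (algorithm == "wordpiece") {
    c(chars, paste0("##", chars))
  } else {
    chars
  }
  budget <- vocab_size - length(SPECIAL_TOKENS) - length(base_pieces)
  keep <- ranked[!(ranked %in% base_pieces)]
  keep_counts <- ranked_counts[!(ranked %in% base_pieces)]
  if (length(keep) > budget) {
    keep_counts <- keep_counts[seq_len(budget)]
    keep <- keep[seq_len(budget)]
  }
  tokens <- c(SPECIAL_TOKENS, base_pieces, keep)
  vocab <- setNames(seq_along(tokens), tokens)

  scores <- NULL
  if (algorithm == "unigram") {
    # log relative frequency; characters get a floor pseudo-count so every
    # string remains segmentable but whole words always win the Viterbi.
    cnt <- setNames(rep(0.5, length(tokens)), tokens)
    cnt[keep] <- keep_counts
    seen_chars <- table(unlist(strsplit(words, ""), use.names = FALSE))
    hit <- intersect(names(seen_chars), tokens)
    cnt[hit] <- pmax(cnt[hit], as.numeric(seen_chars[hit]) * 1e-3)
    cnt[SPECIAL_TOKENS] <- 1
    scores <- log(cnt / sum(cnt))
  }

  new_tokenizer(family, algorithm, tokens, scores,
                min_frequency = as.integer(min_frequency))
}

# Assembles the tokenizer object, including the hashed id lookup and the
# word-segmentation memoisation cache (environments, so they survive the
# object being passed around by value).
new_tokenizer <- function(family, algorithm, tokens, scores = NULL,
                          lowercase = TRUE, min_frequency = 1L) {
  vocab <- setNames(seq_along(tokens), tokens)
  lookup <- list2env(as.list(vocab), hash = TRUE, size = length(tokens))
  score_env <- NULL
  if (!is.null(scores)) {
    score_env <- list2env(as.list(scores), hash = TRUE,
                          size = length(scores))
  }
  structure(list(family = family, algorithm = algorithm, vocab = vocab,
                 tokens = tokens, scores = scores, lowercase = lowercase,
                 min_frequency = as.integer(min_frequency),
                 vocab_size = length(tokens), lookup = lookup,
                 score_env = score_env,
                 word_cache = new.env(hash = TRUE, parent = emptyenv())),
            class = "methylm_tokenizer")
}

vocab_id <- function(tokenizer, token) {
  get0(token, envir = tokenizer$lookup, inherits = FALSE,
       ifnotfound = NA_integer_)
}

#' @export
print.methylm_tokenizer <- function(x, ...) {
  cat("<tokenizer> ", x$family, " (", x$algorithm, "), ",
      x$vocab_size, " tokens\n", sep = "")
  invisible(x)
}

# Greedy longest-match word-piece segmentation of one word.
wordpiece_word <- function(tokenizer, word) {
  pieces <- character(0)
  rest <- word
  first <- TRUE
  while (nchar(rest)) {
    found <- NA_character_
    for (len in seq(min(nchar(rest), 24L), 1L)) {
      cand <- substr(rest, 1L, len)
      if (!first) cand <- paste0("##", cand)
      if (!is.na(vocab_id(tokenizer, cand))) { found <- cand; break }
    }
    if (is.na(found)) return("[UNK]")
    pieces <- c(pieces, found)
    rest <- substr(rest, nchar(found) - (if (first) 0L else 2L) + 1L,
                   nchar(rest))
    first <- FALSE
  }
  pieces
}

# Viterbi maximum-likelihood unigram segmentation of one word.
unigram_word <- function(tokenizer, word) {
  n <- nchar(word)
  best <- c(0, rep(-Inf, n))
  back <- integer(n)
  for (j in seq_len(n)) {
    for (i in seq(max(1L, j - 23L), j)) {
      piece <- substr(word, i, j)
      s <- get0(piece, envir = tokenizer$score_env, inherits = FALSE,
                ifnotfound = NA_real_)
      if (!is.na(s) && best[i] + s > best[j + 1L]) {
        best[j + 1L] <- best[i] + s
        back[j] <- i
      }
    }
  }
  if (!is.finite(best[n + 1L])) return("[UNK]")
  pieces <- character(0)
  j <- n
  while (j > 0L) {
    i <- back[j]
    pieces <- c(substr(word, i, j), pieces)
    j <- i - 1L
  }
  pieces
}

tokenize_word <- function(tokenizer, word) {
  if (word %in% SPECIAL_TOKENS) return(word)
  hit <- get0(word, envir = tokenizer$word_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  pieces <- if (tokenizer$algorithm == "wordpiece") {
    wordpiece_word(tokenizer, word)
  } else {
    unigram_word(tokenizer, word)
  }
  assign(word, pieces, envir = tokenizer$word_cache)
  pieces
}

# Annotated word list of a processed sentence: word, role (dna / template /
# rank_name / punct / other), rank (for rank_name words).
sentence_words <- function(sentence) {
  if (inherits(sentence, "processed_sentence")) {
    dna <- sentence$dna_words
    lineage <- sentence$lineage
  } else {
    text <- as.character(sentence)
    lineage <- parse_lineage_sentence(sub("^.*?(For this organism, .*)$",
                                          "\\1", text))
    words_all <- pretokenize(text, lowercase = FALSE)
    if (is.null(lineage)) {
      return(data.frame(word = words_all, role = "other",
                        rank = NA_character_, stringsAsFactors = FALSE))
    }
    dna_part <- sub("\\s*For this organism, .*$", "", text)
    dna <- pretokenize(dna_part, lowercase = FALSE)
  }
  words <- dna
  roles <- rep("dna", length(dna))
  ranks <- rep(NA_character_, length(dna))
  add <- function(w, role, rank = NA_character_) {
    words <<- c(words, w)
    roles <<- c(roles, rep(role, length(w)))
    ranks <<- c(ranks, rep(rank, length(w)))
  }
  add(c("For", "this", "organism"), "template")
  add(",", "punct")
  for (k in seq_along(LINEAGE_RANKS)) {
    r <- LINEAGE_RANKS[k]
    add(c("its", r, "is"), "template")
    add(strsplit(unclass(lineage)[[r]], "\\s+")[[1]], "rank_name", r)
    add(if (k < length(LINEAGE_RANKS)) "," else ".", "punct")
  }
  data.frame(word = words, role = roles, rank = ranks,
             stringsAsFactors = FALSE)
}

#' Encode a processed sentence to a fixed-length token sequence
#'
#' Produces the transformer input: `[CLS]`, the sentence tokens, `[SEP]`,
#' padded with `[PAD]` to exactly `max_len`. If the tokenized sentence would
#' overflow, words are dropped from the tail of the taxonomy clause — never
#' from the 36 DNA words, which always fit.
#'
#' Word/token alignment and the spans of the DNA words and of each
#' taxonomic rank name are recorded for interpretability.
#'
#' @param tokenizer a [train_tokenizer()] result.
#' @param sentence a [build_sentence()] object (or raw sentence text).
#' @param max_len output length (default 100).
#' @return object of class `"encoded_sample"`: list with `input_ids`,
#'   `attention_mask`, `tokens`, `word_ids`, `words`, `word_roles`,
#'   `dna_token_span` (c(start, end) or NULL) and `taxonomy_token_spans`
#'   (named list rank -> c(start, end)).
#' @export
encode <- function(tokenizer, sentence, max_len = 100L) {
  max_len <- as.integer(max_len)
  if (max_len < 2L) stop("max_len must be at least 2", call. = FALSE)
  wd <- if (is.character(sentence) && !nzchar(trimws(sentence[1]))) {
    data.frame(word = character(0), role = character(0),
               rank = character(0), stringsAsFactors = FALSE)
  } else {
    sentence_words(sentence)
  }
  if (tokenizer$lowercase && nrow(wd)) wd$word <- tolower(wd$word)

  piece_list <- lapply(wd$word, function(w) tokenize_word(tokenizer, w))
  n_pieces <- lengths(piece_list)

  # overflow: drop non-DNA words from the tail until [CLS] + pieces + [SEP]
  # fits; DNA words are only touched in the (impossible for 41-nt input)
  # case that they alone overflow.
  keep <- rep(TRUE, nrow(wd))
  total <- sum(n_pieces) + 2L
  if (total > max_len) {
    for (i in rev(seq_len(nrow(wd)))) {
      if (wd$role[i] == "dna") next
      keep[i] <- FALSE
      total <- total - n_pieces[i]
      if (total <= max_len) break
    }
    if (total > max_len) {
      for (i in rev(which(keep))) {
        keep[i] <- FALSE
        total <- total - n_pieces[i]
        if (total <= max_len) break
      }
    }
  }

  tokens <- "[CLS]"
  word_ids <- NA_integer_
  for (i in which(keep)) {
    tokens <- c(tokens, piece_list[[i]])
    word_ids <- c(word_ids, rep(i, n_pieces[i]))
  }
  tokens <- c(tokens, "[SEP]")
  word_ids <- c(word_ids, NA_integer_)
  n_content <- length(tokens)
  n_pad <- max_len - n_content
  tokens <- c(tokens, rep("[PAD]", n_pad))
  word_ids <- c(word_ids, rep(NA_integer_, n_pad))

  ids <- vapply(tokens, function(t) vocab_id(tokenizer, t), integer(1),
                USE.NAMES = FALSE)
  ids[is.na(ids)] <- UNK_ID
  mask <- as.integer(seq_len(max_len) <= n_content)

  span_of <- function(sel) {
    pos <- which(!is.na(word_ids) & word_ids %in% which(sel & keep))
    if (!length(pos)) NULL else c(min(pos), max(pos))
  }
  dna_span <- if (nrow(wd)) span_of(wd$role == "dna") else NULL
  tax_spans <- list()
  if (nrow(wd)) {
    for (r in LINEAGE_RANKS) {
      sp <- span_of(wd$role == "rank_name" & !is.na(wd$rank) & wd$rank == r)
      if (!is.null(sp)) tax_spans[[r]] <- sp
    }
  }

  structure(list(input_ids = as.integer(ids), attention_mask = mask,
                 tokens = tokens, word_ids = word_ids,
                 words = wd$word[keep], word_roles = wd$role[keep],
                 word_ranks = wd$rank[keep],
                 dna_token_span = dna_span,
                 taxonomy_token_spans = tax_spans,
                 source_id = if (inherits(sentence, "processed_sentence"))
                   sentence$source_id else NA_character_),
            class = "encoded_sample")
}

#' @export
print.encoded_sample <- function(x, ...) {
  cat("<encoded_sample> ", sum(x$attention_mask), " content tokens of ",
      length(x$input_ids), "\n", sep = "")
  invisible(x)
}

#' Decode token ids back to text
#'
#' Joins word pieces (`##` continuations for word-piece vocabularies) and
#' drops special tokens.
#'
#' @param tokenizer the tokenizer that produced the ids.
#' @param ids integer token ids.
#' @return single string.
#' @export
decode <- function(tokenizer, ids) {
  toks <- tokenizer$tokens[ids]
  toks <- toks[!(toks %in% SPECIAL_TOKENS)]
  out <- character(0)
  for (t in toks) {
    if (startsWith(t, "##") && length(out)) {
      out[length(out)] <- paste0(out[length(out)], substr(t, 3, nchar(t)))
    } else {
      out <- c(out, t)
    }
  }
  paste(out, collapse = " ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a tokenizer as plain-text files
#'
#' Writes `vocab.txt` (one token per line, line number = id) and
#' `tokenizer.json` (family, algorithm, settings, unigram scores).
#'
#' @param tokenizer a tokenizer.
#' @param dir directory to create/populate.
#' @return `dir`, invisibly.
#' @export
save_tokenizer <- function(tokenizer, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(tokenizer$tokens, file.path(dir, "vocab.txt"))
  meta <- list(family = tokenizer$family, algorithm = tokenizer$algorithm,
               lowercase = tokenizer$lowercase,
               min_frequency = tokenizer$min_frequency,
               scores = as.list(tokenizer$scores))
  jsonlite::write_json(meta, file.path(dir, "tokenizer.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_tokenizer
#' @export
load_tokenizer <- function(dir) {
  tokens <- readLines(file.path(dir, "vocab.txt"))
  meta <- jsonlite::read_json(file.path(dir, "tokenizer.json"))
  scores <- NULL
  if (length(meta$scores)) {
    scores <- setNames(vapply(meta$scores, as.numeric, numeric(1)),
                       names(meta$scores))
  }
  new_tokenizer(meta$family, meta$algorithm, tokens, scores,
                lowercase = isTRUE(meta$lowercase),
                min_frequency = as.integer(meta$min_frequency))
}
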