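# Attention-based interpretability.
#
# Token importance is the [CLS]-anchored attention in the final encoder
# layer summed over heads: the row with [CLS] as Query is the distribution
# the classifier consumes, so its weight on token j is read as j's
# contribution to the prediction (the opposite direction — [CLS] as Key —
# is available via `direction = "cls-key"`). Word-piece tokenizers give
# word-aligned tokens, so word scores from the BERT / DistilBERT / ELECTRA
# submodels can be averaged into a single profile, merged into per-position
# scores over the 41-nt window, and tabulated into motif rankings.

to_encoded <- function(model, sample, max_len = 100L) {
  if (inherits(sample, "encoded_sample")) return(sample)
  if (inherits(sample, "processed_sentence")) {
    return(encode(model$tokenizer, sample, max_len))
  }
  if (is.data.frame(sample)) {
    if (nrow(sample) != 1L) {
      stop("expected a single sample (one row)", call. = FALSE)
    }
    s <- build_sentence(sample$sequence[1], sample_lineage(sample, 1),
                        sample$id[1])
    return(encode(model$tokenizer, s, max_len))
  }
  stop("cannot interpret 'sample' input", call. = FALSE)
}

#' Extract the full attention tensor for one sample
#'
#' Runs the encoder forward and collects, for every layer and head, the
#' post-softmax attention matrix `softmax(Q K^T / sqrt(d_k))` over the
#' encoded tokens. Padding keys are masked out, so each (layer, head,
#' query) row sums to 1 over the content keys.
#'
#' @param model a pretrained or fine-tuned model.
#' @param sample a one-row [methyl_dataset()], a [build_sentence()] result,
#'   or an [encode()]d sample.
#' @param max_len encoded length.
#' @return object of class `"methylm_attention"`: list with `values` (array
#'   `[layer, head, query, key]`), `encoded` (the encoded sample) and `d_k`.
#' @export
attention_matrices <- function(model, sample, max_len = 100L) {
  enc <- to_encoded(model, sample, max_len)
  fw <- tf_forward(model$params, model$config, enc$input_ids,
                   key_mask = key_mask_of(enc), collect = TRUE,
                   need_cache = FALSE)
  structure(list(values = fw$attention, encoded = enc,
                 d_k = model$config$hidden_size %/% model$config$n_heads),
            class = "methylm_attention")
}

#' Per-token importance scores from [CLS]-anchored attention
#'
#' For each token, the attention weights linking it to `[CLS]` are summed
#' over heads and over the selected encoder layers. The default sums over
#' all layers: the classifier reads the final `[CLS]` state, and content
#' reaches that state through the residual stream via the attention of
#' every layer, so restricting to one layer can miss where a small model
#' happens to place its content-selective heads. Scores are nonnegative;
#' with `direction = "cls-query"` they sum to (heads x layers) over the
#' content keys.
#'
#' @inheritParams attention_matrices
#' @param direction `"cls-query"` (default: the [CLS]-as-Query rows, i.e.
#'   the distribution consumed by the classifier head) or `"cls-key"`
#'   (each token's attention toward [CLS]).
#' @param layers `"all"` (default), `"last"`, or an integer vector of
#'   encoder layer indices to sum over.
#' @return numeric vector of length `max_len`, named by token, with the
#'   encoded sample attached as attribute `"encoded"`.
#' @export
token_importance <- function(model, sample, direction = c("cls-query",
                                                          "cls-key"),
                             max_len = 100L, layers = "all") {
  direction <- match.arg(direction)
  att <- attention_matrices(model, sample, max_len)
  A <- att$values
  lset <- resolve_layers(layers, dim(A)[1])
  nh <- dim(A)[2]
  L <- dim(A)[3]
  scores <- numeric(L)
  for (l in lset) {
    for (h in seq_len(nh)) {
      scores <- scores + if (direction == "cls-query") A[l, h, 1L, ]
                         else A[l, h, , 1L]
    }
  }
  names(scores) <- att$encoded$tokens
  attr(scores, "encoded") <- att$encoded
  scores
}

resolve_layers <- function(layers, n_layers) {
  if (identical(layers, "all")) return(seq_len(n_layers))
  if (identical(layers, "last")) return(n_layers)
  layers <- as.integer(layers)
  if (any(layers < 1L | layers > n_layers)) {
    stop("layer indices must be in 1..", n_layers, call. = FALSE)
  }
  layers
}

#' Word-level importance scores
#'
#' Aggregates [token_importance()] to the sentence words (summing over the
#' pieces of multi-piece words); special tokens carry no word and are
#' excluded.
#'
#' @inheritParams token_importance
#' @return data.frame with columns `word_index`, `word`, `role` (`dna`,
#'   `template`, `rank_name`, `punct`), `rank` and `score`.
#' @export
word_importance <- function(model, sample, direction = "cls-query",
                            max_len = 100L, layers = "all") {
  ti <- token_importance(model, sample, direction, max_len, layers)
  enc <- attr(ti, "encoded")
  n_words <- length(enc$words)
  score <- vapply(seq_len(n_words), function(i) {
    sum(ti[which(!is.na(enc$word_ids) & enc$word_ids == i)])
  }, numeric(1))
  wd <- sentence_role_frame(enc)
  wd$score <- score
  wd
}

sentence_role_frame <- function(enc) {
  data.frame(word_index = seq_along(enc$words), word = enc$words,
             role = enc$word_roles,
             rank = enc$word_ranks %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Word importance averaged over the word-piece submodels
#'
#' The framework-level importance profile: the per-word scores of the
#' word-piece-tokenizer members (BERT, DistilBERT, ELECTRA) fine-tuned for
#' the sample's methylation type, averaged word by word. Members with a
#' non-word-piece tokenizer (ALBERT, XLNet) are dropped with a warning;
#' differing word segmentations are an alignment error.
#'
#' @param models list of fine-tuned models (or a `methylm_ensemble`).
#' @inheritParams token_importance
#' @return data.frame as [word_importance()], scores averaged over models.
#' @export
ensemble_token_importance <- function(models, sample,
                                      direction = "cls-query",
                                      max_len = 100L, layers = "all") {
  if (inherits(models, "methylm_ensemble")) models <- models$members
  if (inherits(models, "methylm_lm")) models <- list(models)
  wordwise <- vapply(models, function(m) {
    m$tokenizer$algorithm == "wordpiece"
  }, logical(1))
  if (!all(wordwise)) {
    warning(sum(!wordwise),
            " member(s) without word-aligned tokenization dropped from ",
            "importance averaging", call. = FALSE)
    models <- models[wordwise]
  }
  if (!length(models)) {
    stop("no word-piece members available for importance averaging",
         call. = FALSE)
  }
  profs <- lapply(models, word_importance, sample = sample,
                  direction = direction, max_len = max_len,
                  layers = layers)
  n_words <- unique(vapply(profs, nrow, integer(1)))
  if (length(n_words) != 1L ||
      length(unique(lapply(profs, function(p) p$word))) != 1L) {
    stop("member tokenizations disagree at word level; cannot align",
         call. = FALSE)
  }
  out <- profs[[1L]]
  out$score <- rowMeans(do.call(cbind, lapply(profs, `[[`, "score")))
  out
}

#' Merge 6-mer word scores into per-position scores
#'
#' Position p of the 41-nt window is covered by between 1 and 6 of the 36
#' overlapping 6-mers (those starting in `max(1, p-5) ... min(36, p)`); its
#' score is the mean (or, with `merge = "sum"`, the sum) of the covering
#' word scores.
#'
#' @param word_scores numeric vector of scores for the 36 DNA words (or a
#'   [word_importance()] data.frame, from which the `dna` rows are taken).
#' @param merge `"mean"` (default) or `"sum"`.
#' @param k k-mer length (default 6).
#' @return numeric vector of length 41 (`length(word_scores) + k - 1`).
#' @export
position_importance <- function(word_scores, merge = c("mean", "sum"),
                                k = KMER_K) {
  merge <- match.arg(merge)
  if (is.data.frame(word_scores)) {
    word_scores <- word_scores$score[word_scores$role == "dna"]
  }
  n_words <- length(word_scores)
  n_pos <- n_words + k - 1L
  vapply(seq_len(n_pos), function(p) {
    covering <- max(1L, p - k + 1L):min(n_words, p)
    if (merge == "mean") mean(word_scores[covering])
    else sum(word_scores[covering])
  }, numeric(1))
}

#' Attention from DNA words to taxonomic-rank names
#'
#' For each of the 36 DNA words and each of the 8 lineage ranks, the
#' final-layer attention weights assigned by the DNA word's tokens (as
#' Query) to the rank-name tokens (as Key), summed over heads and token
#' pairs.
#'
#' @inheritParams token_importance
#' @return 36 x 8 matrix (DNA words x ranks, columns in species-to-domain
#'   order); `NA` columns for ranks truncated out of the encoding.
#' @export
dna_to_taxonomy_attention <- function(model, sample, max_len = 100L) {
  att <- attention_matrices(model, sample, max_len)
  enc <- att$encoded
  A <- att$values
  last <- dim(A)[1]
  heads_sum <- apply(A[last, , , , drop = FALSE], c(3, 4), sum)
  dna_words <- which(enc$word_roles == "dna")
  out <- matrix(NA_real_, length(dna_words), length(LINEAGE_RANKS),
                dimnames = list(enc$words[dna_words], LINEAGE_RANKS))
  for (wi in seq_along(dna_words)) {
    q_tokens <- which(!is.na(enc$word_ids) &
                        enc$word_ids == dna_words[wi])
    for (r in LINEAGE_RANKS) {
      sp <- enc$taxonomy_token_spans[[r]]
      if (is.null(sp)) next
      out[wi, r] <- sum(heads_sum[q_tokens, sp[1]:sp[2]])
    }
  }
  out
}

#' Rank 6-mers by mean importance over positive samples
#'
#' Computes a word-importance profile per sample ([ensemble_token_importance()]
#' when several models are given) and tabulates, for every distinct 6-mer,
#' the mean score over all its occurrences and the occurrence count. The
#' top `n` by mean score are returned.
#'
#' @param models a fine-tuned model, list of models, or ensemble.
#' @param positives a [methyl_dataset()] of (typically positive) samples.
#' @param n number of motifs to report (default 10).
#' @param direction attention direction, see [token_importance()].
#' @param max_len encoded length.
#' @return data.frame with columns `motif`, `mean_score`, `count`, sorted
#'   by decreasing mean score.
#' @export
top_motifs <- function(models, positives, n = 10L,
                       direction = "cls-query", max_len = 100L,
                       layers = "all") {
  if (!nrow(positives)) stop("no samples provided", call. = FALSE)
  profs <- batch_ensemble_word_scores(models, positives,
                                      direction = direction,
                                      max_len = max_len, layers = layers)
  words_all <- unlist(lapply(profs, function(p) {
    toupper(p$words[p$roles == "dna"])
  }), use.names = FALSE)
  scores_all <- unlist(lapply(profs, function(p) {
    p$scores[p$roles == "dna"]
  }), use.names = FALSE)
  agg <- tapply(scores_all, words_all, mean)
  cnt <- tapply(scores_all, words_all, length)
  out <- data.frame(motif = names(agg),
                    mean_score = as.numeric(agg),
                    count = as.integer(cnt), stringsAsFactors = FALSE)
  out <- out[order(-out$mean_score, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Final-layer [CLS] embedding of a sample
#'
#' The sentence-level representation: the final encoder hidden state at the
#' `[CLS]` position, of length `hidden_size`.
#'
#' @inheritParams token_importance
#' @return numeric vector of length `model$config$hidden_size`.
#' @export
cls_embedding <- function(model, sample, max_len = 100L) {
  enc <- to_encoded(model, sample, max_len)
  fw <- tf_forward(model$params, model$config, enc$input_ids,
                   key_mask = key_mask_of(enc), need_cache = FALSE)
  fw$h[1L, ]
}

#' Write an importance profile or motif table as TSV
#'
#' @param x a [word_importance()] data.frame, [position_importance()]
#'   vector, or [top_motifs()] table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  if (is.numeric(x) && is.null(dim(x))) {
    x <- data.frame(position = seq_along(x), score = as.numeric(x))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
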