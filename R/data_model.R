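# Domain types and sample-to-sentence encoding.
#
# The atomic unit is a 41-nt DNA window (a "sample") labelled
# positive/negative for one methylation type and annotated with an
# 8-rank taxonomic lineage.  Samples are held in an ordinary data.frame
# (class "methyl_dataset") with one column per field and the 8 lineage
# ranks as columns, which keeps TSV round-trips trivial.

#' @importFrom stats rbinom runif setNames quantile
#' @importFrom utils head read.delim write.table
NULL

# Rank order is fixed: most specific first, as in the lineage sentence.
LINEAGE_RANKS <- c("species", "genus", "family", "order",
                   "class", "phylum", "kingdom", "domain")

METHYL_TYPES <- c("6mA", "4mC", "5hmC")

WINDOW_LENGTH <- 41L
CENTER_POS <- 21L   # 1-based center of a 41-nt window
KMER_K <- 6L

#' Target base for a methylation type
#'
#' 6mA marks adenine; 4mC and 5hmC mark cytosine.
#'
#' @param methyl_type one of `"6mA"`, `"4mC"`, `"5hmC"`.
#' @return a single character, `"A"` or `"C"`.
#' @export
target_base <- function(methyl_type) {
  methyl_type <- match.arg(methyl_type, METHYL_TYPES)
  if (methyl_type == "6mA") "A" else "C"
}

#' Construct a taxonomic lineage
#'
#' An 8-rank lineage ordered species to domain. Missing ranks are stored as
#' the literal placeholder `"unknown"`, never as an empty string.
#'
#' @param species,genus,family,order,class,phylum,kingdom,domain rank names.
#' @return a named character vector of length 8, class `"methylm_lineage"`.
#' @examples
#' taxonomic_lineage(species = "Homo sapiens", genus = "Homo",
#'                   domain = "Eukaryota")
#' @export
taxonomic_lineage <- function(species = "unknown", genus = "unknown",
                              family = "unknown", order = "unknown",
                              class = "unknown", phylum = "unknown",
                              kingdom = "unknown", domain = "unknown") {
  lin <- c(species = species, genus = genus, family = family, order = order,
           class = class, phylum = phylum, kingdom = kingdom, domain = domain)
  lin <- vapply(lin, as.character, character(1))
  bad <- !nzchar(trimws(lin)) | is.na(lin)
  lin[bad] <- "unknown"
  structure(lin, class = "methylm_lineage")
}

as_lineage <- function(x) {
  if (inherits(x, "methylm_lineage")) return(x)
  if (is.character(x) && all(LINEAGE_RANKS %in% names(x))) {
    return(do.call(taxonomic_lineage, as.list(x[LINEAGE_RANKS])))
  }
  if (is.list(x) && all(LINEAGE_RANKS %in% names(x))) {
    return(do.call(taxonomic_lineage, x[LINEAGE_RANKS]))
  }
  stop("cannot interpret object as a taxonomic lineage", call. = FALSE)
}

#' @export
print.methylm_lineage <- function(x, ...) {
  cat("<lineage> ", paste(unclass(x), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Construct a single methylation sample
#'
#' @param id unique sample identifier.
#' @param sequence 41-nt DNA string over `{A,C,G,T}` (N tolerated at parse
#'   time but rejected later at sentence encoding).
#' @param label `"positive"` or `"negative"`.
#' @param methyl_type one of `"6mA"`, `"4mC"`, `"5hmC"`.
#' @param lineage a [taxonomic_lineage()] (or coercible named vector/list).
#' @return a one-row [methyl_dataset()].
#' @export
methyl_sample <- function(id, sequence, label, methyl_type, lineage) {
  lineage <- as_lineage(lineage)
  df <- data.frame(id = as.character(id),
                   sequence = toupper(as.character(sequence)),
                   label = match.arg(label, c("positive", "negative")),
                   methyl_type = match.arg(methyl_type, METHYL_TYPES),
                   stringsAsFactors = FALSE)
  for (r in LINEAGE_RANKS) df[[r]] <- unname(lineage[[r]])
  methyl_dataset(df)
}

#' Construct and validate a methylation dataset
#'
#' Validates the container invariants: unique ids, 41-nt sequences over
#' `{A,C,G,T,N}`, known labels and types, and for positive samples the
#' correct target base (A for 6mA, C for 4mC/5hmC) at the center position 21.
#'
#' @param df data.frame with columns `id`, `sequence`, `label`,
#'   `methyl_type` and the 8 lineage ranks `species` ... `domain`.
#' @param validate set `FALSE` to skip invariant checks (internal use).
#' @return `df` with class `"methyl_dataset"` prepended.
#' @export
methyl_dataset <- function(df, validate = TRUE) {
  needed <- c("id", "sequence", "label", "methyl_type", LINEAGE_RANKS)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("dataset is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (validate && nrow(df)) {
    if (anyDuplicated(df$id)) {
      stop("duplicate sample ids: ",
           paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
           call. = FALSE)
    }
    len <- nchar(df$sequence)
    if (any(len != WINDOW_LENGTH)) {
      stop("all sequences must be ", WINDOW_LENGTH, " nt; found lengths ",
           paste(unique(len[len != WINDOW_LENGTH]), collapse = ", "),
           call. = FALSE)
    }
    if (any(grepl("[^ACGTN]", df$sequence))) {
      stop("sequences may only contain A, C, G, T or N", call. = FALSE)
    }
    if (!all(df$label %in% c("positive", "negative"))) {
      stop("labels must be 'positive' or 'negative'", call. = FALSE)
    }
    if (!all(df$methyl_type %in% METHYL_TYPES)) {
      stop("methyl_type must be one of ", paste(METHYL_TYPES, collapse = ", "),
           call. = FALSE)
    }
    pos <- df$label == "positive"
    if (any(pos)) {
      ctr <- substr(df$sequence[pos], CENTER_POS, CENTER_POS)
      want <- vapply(df$methyl_type[pos], target_base, character(1))
      if (any(ctr != want)) {
        bad <- df$id[pos][ctr != want]
        stop("positive samples must carry the target base at position ",
             CENTER_POS, "; offending ids: ",
             paste(head(bad, 5), collapse = ", "), call. = FALSE)
      }
    }
    miss <- vapply(df[LINEAGE_RANKS], function(x) any(!nzchar(x) | is.na(x)),
                   logical(1))
    if (any(miss)) {
      for (r in LINEAGE_RANKS[miss]) {
        x <- df[[r]]
        x[!nzchar(x) | is.na(x)] <- "unknown"
        df[[r]] <- x
      }
    }
  }
  class(df) <- unique(c("methyl_dataset", class(df)))
  df
}

sample_lineage <- function(dataset, i) {
  do.call(taxonomic_lineage,
          as.list(vapply(LINEAGE_RANKS, function(r) dataset[[r]][i],
                         character(1))))
}

#' Extract overlapping k-mers with a sliding window
#'
#' A length-L sequence yields exactly `L - k + 1` k-mers at consecutive
#' offsets; a 41-nt window with k = 6 yields 36.
#'
#' @param sequence nucleotide string over `{A,C,G,T,N}`.
#' @param k window length (default 6).
#' @return character vector of `nchar(sequence) - k + 1` k-mers, in order.
#' @examples
#' extract_kmers("ACGTACGT", 6)  # "ACGTAC" "CGTACG" "GTACGT"
#' @export
extract_kmers <- function(sequence, k = KMER_K) {
  sequence <- toupper(as.character(sequence))
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  n <- nchar(sequence)
  if (n < k) {
    stop("sequence of length ", n, " is shorter than k = ", k, call. = FALSE)
  }
  starts <- seq_len(n - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

#' Render a lineage as the templated sentence
#'
#' @param lineage a [taxonomic_lineage()].
#' @return the sentence `"For this organism, its species is S, its genus is
#'   G, ..., its domain is D."` with the 8 rank names substituted.
#' @export
lineage_sentence <- function(lineage) {
  lineage <- as_lineage(lineage)
  clauses <- paste0("its ", LINEAGE_RANKS, " is ", unclass(lineage))
  paste0("For this organism, ", paste(clauses, collapse = ", "), ".")
}

#' Parse a lineage sentence back into its 8 rank names
#'
#' Inverse of [lineage_sentence()]; used for round-trips and to recover the
#' rank-name spans when only raw text is available.
#'
#' @param text a sentence produced by [lineage_sentence()].
#' @return a [taxonomic_lineage()], or `NULL` if the template is absent.
#' @export
parse_lineage_sentence <- function(text) {
  pat <- paste0("For this organism, ",
                paste(paste0("its ", LINEAGE_RANKS, " is (.+?)"),
                      collapse = ", "),
                "\\.$")
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (length(m) != 9L) return(NULL)
  do.call(taxonomic_lineage, as.list(setNames(m[-1], LINEAGE_RANKS)))
}

#' Encode one sample as a processed sentence
#'
#' The textual representation consumed by the tokenizer: the 36 overlapping
#' 6-mers of the window, space separated, followed by the templated lineage
#' description.
#'
#' @param sequence 41-nt DNA string (no N: the 6-mer vocabulary is defined
#'   over ACGT only).
#' @param lineage a [taxonomic_lineage()].
#' @param id source sample id carried along for bookkeeping.
#' @return an object of class `"processed_sentence"`: list with `text`,
#'   `source_id`, `dna_words` (the 6-mers) and `lineage`.
#' @export
build_sentence <- function(sequence, lineage, id = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence of sample '", id,
         "' contains non-ACGT characters and cannot be sentence-encoded",
         call. = FALSE)
  }
  lineage <- as_lineage(lineage)
  dna_words <- extract_kmers(sequence, KMER_K)
  text <- paste(paste(dna_words, collapse = " "), lineage_sentence(lineage))
  structure(list(text = text, source_id = as.character(id),
                 dna_words = dna_words, lineage = lineage),
            class = "processed_sentence")
}

#' @export
print.processed_sentence <- function(x, ...) {
  cat("<processed_sentence> ", x$source_id, "\n  ",
      substr(x$text, 1, 70), "...\n", sep = "")
  invisible(x)
}

#' Process every sample of a dataset into sentences
#'
#' @param dataset a [methyl_dataset()].
#' @return list of [build_sentence()] results, one per sample, in order.
#' @export
process_dataset <- function(dataset) {
  lapply(seq_len(nrow(dataset)), function(i) {
    build_sentence(dataset$sequence[i], sample_lineage(dataset, i),
                   dataset$id[i])
  })
}

#' Partition a dataset by methylation type
#'
#' @param dataset a [methyl_dataset()].
#' @return named list with one (possibly empty) [methyl_dataset()] per type,
#'   in cascade order 6mA, 4mC, 5hmC. The parts are disjoint and their
#'   union is the input.
#' @export
split_by_type <- function(dataset) {
  out <- lapply(METHYL_TYPES, function(tp) {
    methyl_dataset(dataset[dataset$methyl_type == tp, , drop = FALSE],
                   validate = FALSE)
  })
  names(out) <- METHYL_TYPES
  out
}

#' Stratified train/validation split
#'
#' Splits a dataset into a training part of size `ceiling(ratio * n)` and a
#' validation part with the rest, preserving the positive/negative balance
#' within one sample per class (largest-remainder allocation across
#' classes). Reproducible for a fixed seed.
#'
#' @param dataset a non-empty [methyl_dataset()].
#' @param ratio training fraction in (0, 1); default 0.8 for an 8:2 split.
#' @param seed integer seed for the shuffle.
#' @return list with elements `train` and `val`.
#' @export
train_val_split <- function(dataset, ratio = 0.8, seed = 1L) {
  if (!nrow(dataset)) stop("cannot split an empty dataset", call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0,1)", call. = FALSE)
  n <- nrow(dataset)
  n_train <- ceiling(ratio * n)
  classes <- sort(unique(dataset$label))
  n_c <- vapply(classes, function(cl) sum(dataset$label == cl), integer(1))
  base <- floor(ratio * n_c)
  rem <- n_train - sum(base)
  frac <- ratio * n_c - base
  # largest remainder first; ties broken by class order for determinism
  extra_order <- order(-frac, seq_along(classes))
  take <- base
  if (rem > 0) {
    idx <- extra_order[seq_len(min(rem, length(classes)))]
    take[idx] <- take[idx] + 1L
    rem <- rem - length(idx)
    while (rem > 0) {  # ratio > 1 cannot happen; loop guards tiny classes
      take[extra_order[1L]] <- take[extra_order[1L]] + 1L
      rem <- rem - 1L
    }
  }
  take <- pmin(take, n_c)
  train_idx <- integer(0)
  local_seed(seed, {
    for (j in seq_along(classes)) {
      pool <- which(dataset$label == classes[j])
      train_idx <- c(train_idx, sample(pool)[seq_len(take[j])])
    }
  })
  train_idx <- sort(train_idx)
  list(train = methyl_dataset(dataset[train_idx, , drop = FALSE],
                              validate = FALSE),
       val = methyl_dataset(dataset[-train_idx, , drop = FALSE],
                            validate = FALSE))
}

#' Assemble the pretraining corpus
#'
#' The corpus is the processed training dataset (one sentence per sample, in
#' input order) plus one lineage sentence for every extra lineage whose
#' 8-rank tuple does not already occur among the training samples.
#' Deduplication is by exact 8-tuple match; sentences themselves are not
#' deduplicated and input order is preserved.
#'
#' @param dataset a [methyl_dataset()] (typically the training split).
#' @param extra_lineages list of [taxonomic_lineage()] objects, e.g. from a
#'   pre-extracted taxonomy TSV ([read_lineages_tsv()]).
#' @param vocab_size_target vocabulary size the tokenizer will aim for
#'   (default 25000).
#' @return object of class `"methylm_corpus"`: list with `sentences`,
#'   `vocab_size_target` and `metadata`.
#' @export
build_corpus <- function(dataset, extra_lineages = list(),
                         vocab_size_target = 25000L) {
  sentences <- vapply(process_dataset(dataset), `[[`, character(1), "text")
  seen <- unique(vapply(seq_len(nrow(dataset)), function(i) {
    paste(vapply(LINEAGE_RANKS, function(r) dataset[[r]][i], character(1)),
          collapse = "\r")
  }, character(1)))
  n_extra <- 0L
  for (lin in extra_lineages) {
    lin <- as_lineage(lin)
    key <- paste(unclass(lin), collapse = "\r")
    if (!(key %in% seen)) {
      sentences <- c(sentences, lineage_sentence(lin))
      seen <- c(seen, key)
      n_extra <- n_extra + 1L
    }
  }
  structure(list(sentences = sentences,
                 vocab_size_target = as.integer(vocab_size_target),
                 metadata = list(n_samples = nrow(dataset),
                                 n_extra_lineages = n_extra)),
            class = "methylm_corpus")
}

#' @export
print.methylm_corpus <- function(x, ...) {
  cat("<corpus> ", length(x$sentences), " sentences (",
      x$metadata$n_samples, " from samples, ",
      x$metadata$n_extra_lineages, " extra lineages), vocab target ",
      x$vocab_size_target, "\n", sep = "")
  invisible(x)
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
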