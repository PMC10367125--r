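# Whole-sequence methylation-site calling.
#
# Candidate 41-nt windows are extracted around every occurrence of the
# target base (A for 6mA, C for 4mC/5hmC), classified by the ensemble, and
# the threshold-passing calls are filtered by the center-max rule: a site
# is retained only if its 41-position importance profile attains its
# maximum at the window center (position 21).

#' Extract candidate windows centered on the target base
#'
#' One window per occurrence of the target base at positions 21 to L-20
#' (1-based); windows containing non-ACGT characters are skipped and their
#' count reported as attribute `"n_skipped"`.
#'
#' @param sequence nucleotide string (length >= 41 for any windows).
#' @param methyl_type methylation type selecting the center base.
#' @param contig contig name recorded with each window.
#' @return data.frame with columns `contig`, `center` (1-based), `sequence`
#'   (41 nt) and `center_base`.
#' @export
extract_windows <- function(sequence, methyl_type, contig = "seq") {
  sequence <- toupper(as.character(sequence))
  base <- target_base(methyl_type)
  L <- nchar(sequence)
  empty <- data.frame(contig = character(0), center = integer(0),
                      sequence = character(0), center_base = character(0),
                      stringsAsFactors = FALSE)
  if (L < WINDOW_LENGTH) {
    warning("sequence of length ", L, " is shorter than ", WINDOW_LENGTH,
            "; no windows extracted", call. = FALSE)
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  chars <- strsplit(sequence, "")[[1]]
  centers <- which(chars == base)
  centers <- centers[centers >= CENTER_POS & centers <= L - CENTER_POS + 1L]
  if (!length(centers)) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  wins <- substring(sequence, centers - (CENTER_POS - 1L),
                    centers + (WINDOW_LENGTH - CENTER_POS))
  ok <- !grepl("[^ACGT]", wins)
  n_skipped <- sum(!ok)
  if (n_skipped) {
    message(n_skipped, " window(s) skipped for non-ACGT characters")
  }
  out <- data.frame(contig = rep(contig, sum(ok)), center = centers[ok],
                    sequence = wins[ok],
                    center_base = rep(base, sum(ok)),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Scan a sequence for methylation sites
#'
#' Step 1: [ensemble_predict()] on every candidate window, keeping those
#' with probability at or above the ensemble threshold. Step 2: for each
#' kept window, the 41-position importance profile (averaged over the
#' word-piece members, or over `importance_models` if given) is computed
#' and the call is flagged `retained` only when the center position is in
#' the profile's argmax set (`strict = TRUE` demands a unique maximum at
#' the center). The retained calls are always a subset of the
#' threshold-passing ones.
#'
#' @param sequence nucleotide string to scan.
#' @param lineage [taxonomic_lineage()] of the organism.
#' @param methyl_type methylation type to call.
#' @param ensemble trained [ensemble_model()].
#' @param importance_models models used for the importance profile (default:
#'   the ensemble's word-piece members).
#' @param threshold probability threshold (default: the ensemble's).
#' @param strict require a unique center maximum (default `FALSE`: a
#'   plateau that includes the center retains the site).
#' @param merge position-merging rule, `"mean"` or `"sum"`.
#' @param contig contig name for the calls.
#' @param both_strands also scan the reverse complement (default `FALSE`:
#'   training samples are single-stranded windows); reverse-strand calls
#'   are reported in forward coordinates with `strand = "-"`.
#' @param max_len encoded length.
#' @return data.frame of class `"methylm_sites"`: `contig`, `position`
#'   (1-based center on the forward strand), `strand`, `probability`,
#'   `retained`.
#' @export
scan_sequence <- function(sequence, lineage, methyl_type, ensemble,
                          importance_models = NULL, threshold = NULL,
                          strict = FALSE, merge = "mean", contig = "seq",
                          both_strands = FALSE, max_len = 100L) {
  out <- scan_one_strand(sequence, lineage, methyl_type, ensemble,
                         importance_models, threshold, strict, merge,
                         contig, max_len, strand = "+")
  if (both_strands) {
    rc <- reverse_complement(sequence)
    rev_calls <- scan_one_strand(rc, lineage, methyl_type, ensemble,
                                 importance_models, threshold, strict,
                                 merge, contig, max_len, strand = "-")
    if (nrow(rev_calls)) {
      rev_calls$position <- nchar(sequence) - rev_calls$position + 1L
    }
    out <- rbind(out, rev_calls)
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("methylm_sites", "data.frame")
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param sequence nucleotide string (IUPAC N preserved).
#' @return the reverse complement.
#' @export
reverse_complement <- function(sequence) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(sequence, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

scan_one_strand <- function(sequence, lineage, methyl_type, ensemble,
                            importance_models, threshold, strict, merge,
                            contig, max_len, strand) {
  threshold <- threshold %||% ensemble$threshold
  lineage <- as_lineage(lineage)
  windows <- extract_windows(sequence, methyl_type, contig)
  empty <- data.frame(contig = character(0), position = integer(0),
                      strand = character(0), probability = numeric(0),
                      retained = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("methylm_sites", class(empty))
  if (!nrow(windows)) return(empty)

  df <- data.frame(id = paste0(contig, ":", strand, windows$center),
                   sequence = windows$sequence, label = "negative",
                   methyl_type = methyl_type, stringsAsFactors = FALSE)
  for (r in LINEAGE_RANKS) df[[r]] <- unname(lineage[[r]])
  samples <- methyl_dataset(df, validate = FALSE)
  probs <- ensemble_predict(ensemble, samples, max_len = max_len)

  keep <- which(!is.na(probs) & probs >= threshold)
  if (!length(keep)) return(empty)
  models <- importance_models %||% ensemble
  profs <- batch_ensemble_word_scores(models,
                                      samples[keep, , drop = FALSE],
                                      max_len = max_len)
  retained <- vapply(profs, function(p) {
    pos <- position_importance(p$scores[p$roles == "dna"], merge = merge)
    mx <- max(pos)
    if (strict) {
      pos[CENTER_POS] == mx && sum(pos == mx) == 1L
    } else {
      pos[CENTER_POS] == mx
    }
  }, logical(1))

  out <- data.frame(contig = rep(contig, length(keep)),
                    position = windows$center[keep],
                    strand = rep(strand, length(keep)),
                    probability = probs[keep], retained = retained,
                    stringsAsFactors = FALSE)
  class(out) <- c("methylm_sites", class(out))
  out
}

#' Write site calls as TSV or BED
#'
#' TSV mirrors the call fields (round-trippable with
#' [read_sites_tsv()]). BED writes the retained calls as 0-based
#' half-open single-base intervals `(center - 1, center)` with the
#' probability as score.
#'
#' @param calls a [scan_sequence()] result.
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(calls, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(calls), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    kept <- calls[calls$retained, , drop = FALSE]
    nm <- if (nrow(kept)) paste0("site_", seq_len(nrow(kept)))
          else character(0)
    bed <- data.frame(chrom = kept$contig,
                      start = kept$position - 1L,
                      end = kept$position,
                      name = nm,
                      score = kept$probability,
                      strand = kept$strand %||% rep("+", nrow(kept)))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$retained <- as.logical(df$retained)
  class(df) <- c("methylm_sites", class(df))
  df
}

#' Read a (multi-record) FASTA file
#'
#' Uses Biostrings when available.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.character(x), names(x)))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (!length(idx)) stop("not a FASTA file: ", path, call. = FALSE)
  starts <- idx + 1L
  ends <- c(idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  stats::setNames(toupper(seqs), sub("^>\\s*(\\S+).*$", "\\1", lines[idx]))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}
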