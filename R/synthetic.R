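# Synthetic benchmark generator.
#
# Emulates the structure of the public 41-nt methylation benchmarks:
# balanced positive/negative windows, positives centered on the
# methylatable base and carrying a plantable consensus motif near the
# center, every sample tagged with an 8-rank lineage. Provides matching
# synthetic chromosomes with recorded planted-site truth so the scanning
# mode can be scored exactly.

#' Specification of a plantable motif
#'
#' @param consensus motif string over `{A,C,G,T}` (default a 6-mer).
#' @param sub_prob per-position substitution probability in `[0, 1)`
#'   applied when the motif is written into a positive sample (0 = exact
#'   consensus).
#' @param offset_range integer range (relative to the window center) for
#'   the motif start. The default (`NULL`) samples uniformly among all
#'   center-overlapping placements whose consensus base over the center
#'   equals the methylation target, so the planted copy is never corrupted
#'   when the center base is forced. Narrow the range (e.g. `c(-1, -1)`)
#'   for fixed-phase placement.
#' @return list of class `"motif_spec"`.
#' @export
motif_spec <- function(consensus = "CATACA", sub_prob = 0,
                       offset_range = NULL) {
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) {
    stop("motif consensus must be over A, C, G, T", call. = FALSE)
  }
  if (sub_prob < 0 || sub_prob >= 1) {
    stop("sub_prob must be in [0, 1)", call. = FALSE)
  }
  k <- nchar(consensus)
  if (!is.null(offset_range)) {
    offset_range <- as.integer(offset_range)
    if (offset_range[1] > offset_range[2]) {
      stop("offset_range must be increasing", call. = FALSE)
    }
  }
  structure(list(consensus = consensus, k = k, sub_prob = sub_prob,
                 offset_range = offset_range),
            class = "motif_spec")
}

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

mutate_motif <- function(motif) {
  if (motif$sub_prob <= 0) return(motif$consensus)
  chars <- strsplit(motif$consensus, "")[[1]]
  hit <- stats::runif(length(chars)) < motif$sub_prob
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(BASES, b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

plant <- function(sequence, motif_seq, start) {
  paste0(substr(sequence, 1L, start - 1L), motif_seq,
         substr(sequence, start + nchar(motif_seq), nchar(sequence)))
}

set_center <- function(sequence, base) {
  paste0(substr(sequence, 1L, CENTER_POS - 1L), base,
         substr(sequence, CENTER_POS + 1L, nchar(sequence)))
}

# Offsets (motif start relative to the center) where the motif overlaps the
# center AND its consensus base over the center equals the target base, so
# forcing the center never corrupts a planted consensus. These are the
# placements at which the planted base is actually the methylatable one.
compatible_offsets <- function(motif, base) {
  range <- motif$offset_range %||% c(-(motif$k - 1L), 0L)
  cand <- seq(range[1], range[2])
  cand <- cand[cand >= -(motif$k - 1L) & cand <= 0L]
  ok <- vapply(cand, function(off) {
    substr(motif$consensus, 1L - off, 1L - off) == base
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand)) {
    stop("motif consensus '", motif$consensus, "' contains no '", base,
         "' at any center-overlapping placement in its offset range",
         call. = FALSE)
  }
  cand
}

#' Built-in example lineages
#'
#' A small set of complete 8-rank lineages used as defaults by the
#' generator (assigned to samples round-robin).
#'
#' @return list of [taxonomic_lineage()] objects.
#' @export
default_lineages <- function() {
  list(
    taxonomic_lineage("Escherichia coli", "Escherichia",
                      "Enterobacteriaceae", "Enterobacterales",
                      "Gammaproteobacteria", "Pseudomonadota", "Bacteria",
                      "Bacteria"),
    taxonomic_lineage("Homo sapiens", "Homo", "Hominidae", "Primates",
                      "Mammalia", "Chordata", "Metazoa", "Eukaryota"),
    taxonomic_lineage("Arabidopsis thaliana", "Arabidopsis",
                      "Brassicaceae", "Brassicales", "Magnoliopsida",
                      "Streptophyta", "Viridiplantae", "Eukaryota"))
}

#' Generate a balanced labeled dataset with a planted motif
#'
#' Positives are uniform-random 41-mers with the motif written at an offset
#' sampled from the motif's placement range (overlapping the center) and
#' the center base forced to the methylation target; negatives are
#' uniform-random 41-mers with the target base at the center,
#' rejection-sampled so they never contain the exact consensus. Lineages
#' are assigned round-robin. Byte-identical for a fixed seed.
#'
#' @param n_pos,n_neg numbers of positive and negative samples.
#' @param methyl_type methylation type of every sample.
#' @param motif a [motif_spec()]; must be at most 41 nt.
#' @param lineages list of lineages (default [default_lineages()]).
#' @param seed RNG seed.
#' @return list with `dataset` (a [methyl_dataset()]) and `truth` (class
#'   `"synthetic_truth"`: motif, per-positive planted offsets, seed).
#' @export
generate_dataset <- function(n_pos, n_neg, methyl_type = "6mA",
                             motif = motif_spec(), lineages = NULL,
                             seed = 1L) {
  if (motif$k > WINDOW_LENGTH) {
    stop("motif (", motif$k, " nt) longer than the ", WINDOW_LENGTH,
         "-nt window", call. = FALSE)
  }
  methyl_type <- match.arg(methyl_type, METHYL_TYPES)
  lineages <- lineages %||% default_lineages()
  base <- target_base(methyl_type)
  valid_off <- compatible_offsets(motif, base)
  offsets <- integer(n_pos)
  rows <- vector("list", n_pos + n_neg)
  local_seed(seed, {
    for (i in seq_len(n_pos)) {
      s <- random_seq(WINDOW_LENGTH)
      off <- valid_off[sample.int(length(valid_off), 1L)]
      start <- CENTER_POS + off
      s <- plant(s, mutate_motif(motif), start)
      s <- set_center(s, base)
      offsets[i] <- off
      rows[[i]] <- s
    }
    for (i in seq_len(n_neg)) {
      repeat {
        s <- set_center(random_seq(WINDOW_LENGTH), base)
        if (!grepl(motif$consensus, s, fixed = TRUE)) break
      }
      rows[[n_pos + i]] <- s
    }
  })
  lin_idx <- (seq_len(n_pos + n_neg) - 1L) %% length(lineages) + 1L
  df <- data.frame(
    id = c(sprintf("pos_%05d", seq_len(n_pos)),
           sprintf("neg_%05d", seq_len(n_neg))),
    sequence = unlist(rows),
    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
    methyl_type = methyl_type, stringsAsFactors = FALSE)
  for (r in LINEAGE_RANKS) {
    df[[r]] <- vapply(lin_idx, function(j) unname(lineages[[j]][[r]]),
                      character(1))
  }
  truth <- structure(list(motif = motif, methyl_type = methyl_type,
                          planted_offsets = offsets, seed = seed,
                          n_pos = n_pos, n_neg = n_neg),
                     class = "synthetic_truth")
  list(dataset = methyl_dataset(df), truth = truth)
}

#' Generate a synthetic chromosome with planted methylation sites
#'
#' Uniform-random background with `n_sites` motif-bearing 41-nt segments
#' planted at recorded centers (minimum spacing 41 nt, so planted windows
#' never overlap). Each planted center carries the methylation target base.
#'
#' @param length chromosome length.
#' @param n_sites number of planted sites.
#' @param methyl_type methylation type of the planted sites.
#' @param motif a [motif_spec()].
#' @param seed RNG seed.
#' @return list with `sequence` (single string) and `truth` (class
#'   `"synthetic_truth"` with data.frame `sites`: center positions and
#'   motif offsets).
#' @export
generate_genome <- function(length, n_sites, methyl_type = "6mA",
                            motif = motif_spec(), seed = 1L) {
  length <- as.integer(length)
  base <- target_base(methyl_type)
  lo <- CENTER_POS
  hi <- length - (WINDOW_LENGTH - CENTER_POS)
  if (n_sites > 0 && (hi < lo ||
                      (hi - lo) %/% WINDOW_LENGTH + 1L < n_sites)) {
    stop("cannot place ", n_sites, " non-overlapping sites on a length-",
         length, " sequence", call. = FALSE)
  }
  valid_off <- compatible_offsets(motif, base)
  seq_str <- NULL
  centers <- integer(0)
  offsets <- integer(0)
  local_seed(seed, {
    seq_str <- random_seq(length)
    if (n_sites > 0) {
      # rejection-sample centers with min spacing 41
      repeat {
        cand <- sort(sample(seq(lo, hi), n_sites))
        if (n_sites == 1L || all(diff(cand) >= WINDOW_LENGTH)) break
      }
      centers <- cand
      for (ct in centers) {
        off <- valid_off[sample.int(length(valid_off), 1L)]
        start <- ct + off
        seq_str <- plant(seq_str, mutate_motif(motif), start)
        seq_str <- paste0(substr(seq_str, 1L, ct - 1L), base,
                          substr(seq_str, ct + 1L, nchar(seq_str)))
        offsets <- c(offsets, off)
      }
    }
  })
  truth <- structure(list(motif = motif, methyl_type = methyl_type,
                          sites = data.frame(center = centers,
                                             offset = offsets),
                          seed = seed),
                     class = "synthetic_truth")
  list(sequence = seq_str, truth = truth)
}

#' Write the planted-site truth as BED
#'
#' Single-base 0-based half-open intervals at the planted centers.
#'
#' @param truth a [generate_genome()] truth object.
#' @param path output BED path.
#' @param contig contig name.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path, contig = "synthetic_chr") {
  n <- nrow(truth$sites)
  bed <- data.frame(chrom = rep(contig, n),
                    start = truth$sites$center - 1L,
                    end = truth$sites$center,
                    name = if (n) paste0("planted_", seq_len(n))
                           else character(0))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
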