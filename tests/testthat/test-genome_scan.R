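# Candidate window extraction, scanning and site output.

test_that("window extraction centers on the target base", {
  # single-window case: length 41 with A at the center
  s41 <- generate_dataset(1, 0, "6mA", seed = 71)$dataset$sequence[1]
  w <- extract_windows(s41, "6mA")
  expect_equal(nrow(w), sum(strsplit(s41, "")[[1]][21] == "A"))
  if (nrow(w)) {
    expect_equal(w$center, 21L)
    expect_equal(nchar(w$sequence), 41L)
  }

  # too short: zero windows with a warning
  expect_warning(w0 <- extract_windows(strrep("A", 40), "6mA"), "shorter")
  expect_equal(nrow(w0), 0)

  # base-counting oracle on a random length-60 sequence, type 4mC
  set.seed(72)
  s60 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  w4 <- extract_windows(s60, "4mC")
  chars <- strsplit(s60, "")[[1]]
  expect_equal(nrow(w4), sum(chars[21:40] == "C"))
  expect_true(all(substr(w4$sequence, 21, 21) == "C"))
  expect_true(all(nchar(w4$sequence) == 41))
  # each window is the matching substring
  for (i in seq_len(nrow(w4))) {
    expect_equal(w4$sequence[i],
                 substr(s60, w4$center[i] - 20, w4$center[i] + 20))
  }
})

test_that("windows containing ambiguous bases are skipped and counted", {
  s <- paste0(strrep("A", 25), "N", strrep("A", 34))
  w <- extract_windows(s, "6mA")
  expect_gt(attr(w, "n_skipped"), 0)
  expect_false(any(grepl("N", w$sequence)))
})

test_that("scanning reports threshold-passing calls with center-max flags", {
  ens <- fx_ensemble()
  gg <- generate_genome(1200, 4, "6mA", seed = 73)
  lin <- default_lineages()[[1]]
  calls <- scan_sequence(gg$sequence, lin, "6mA", ens,
                         contig = "chr_test")
  expect_s3_class(calls, "methylm_sites")
  expect_true(all(calls$probability >= ens$threshold))
  expect_true(all(calls$position >= 21 &
                    calls$position <= nchar(gg$sequence) - 20))
  # retained set is a subset of the threshold-passing calls
  expect_lte(sum(calls$retained), nrow(calls))
  # every call's center base is the 6mA target
  chars <- strsplit(gg$sequence, "")[[1]]
  expect_true(all(chars[calls$position] == "A"))

  # center-max filter oracle on a couple of kept windows
  if (nrow(calls)) {
    i <- 1L
    win <- substr(gg$sequence, calls$position[i] - 20,
                  calls$position[i] + 20)
    df <- methyl_dataset(
      data.frame(id = "w", sequence = win, label = "negative",
                 methyl_type = "6mA", species = lin[["species"]],
                 genus = lin[["genus"]], family = lin[["family"]],
                 order = lin[["order"]], class = lin[["class"]],
                 phylum = lin[["phylum"]], kingdom = lin[["kingdom"]],
                 domain = lin[["domain"]], stringsAsFactors = FALSE),
      validate = FALSE)
    prof <- suppressWarnings(ensemble_token_importance(ens, df))
    pp <- position_importance(prof)
    expect_equal(unname(calls$retained[i]),
                 pp[21] == max(pp))
  }
})

test_that("an impossible threshold yields an empty call list", {
  ens <- fx_ensemble()
  ens$threshold <- 1.0000
  gg <- generate_genome(300, 1, "6mA", seed = 74)
  calls <- scan_sequence(gg$sequence, default_lineages()[[1]], "6mA",
                         ens, threshold = 1)
  expect_equal(nrow(calls), 0)
})

test_that("scanning N-separated contigs equals the union of per-contig scans", {
  ens <- fx_ensemble()
  lin <- default_lineages()[[2]]
  g1 <- generate_genome(400, 2, "6mA", seed = 75)
  g2 <- generate_genome(400, 2, "6mA", seed = 76)
  joint <- paste0(g1$sequence, strrep("N", 41), g2$sequence)

  c1 <- scan_sequence(g1$sequence, lin, "6mA", ens)
  c2 <- scan_sequence(g2$sequence, lin, "6mA", ens)
  cj <- scan_sequence(joint, lin, "6mA", ens)

  expected <- sort(c(c1$position, c2$position + 400 + 41))
  expect_equal(sort(cj$position), expected)
})

test_that("site calls round-trip through TSV and obey BED conventions", {
  calls <- structure(
    data.frame(contig = "chr1", position = c(21L, 99L),
               probability = c(0.91, 0.73), retained = c(TRUE, FALSE),
               stringsAsFactors = FALSE),
    class = c("methylm_sites", "data.frame"))
  tsv <- tempfile(fileext = ".tsv")
  write_sites(calls, tsv, "tsv")
  back <- read_sites_tsv(tsv)
  expect_equal(as.data.frame(back), as.data.frame(calls))

  bed <- tempfile(fileext = ".bed")
  write_sites(calls, bed, "bed")
  lines <- read.delim(bed, header = FALSE)
  # only the retained call, as a 0-based half-open single-base interval
  expect_equal(nrow(lines), 1)
  expect_equal(lines$V2, 20)
  expect_equal(lines$V3, 21)

  # empty calls still produce a valid TSV with a header
  empty <- calls[0, ]
  tsv0 <- tempfile(fileext = ".tsv")
  write_sites(empty, tsv0, "tsv")
  expect_equal(nrow(read_sites_tsv(tsv0)), 0)
})

test_that("reverse-strand scanning maps calls to forward coordinates", {
  expect_equal(reverse_complement("ACGTN"), "NACGT")
  expect_equal(reverse_complement(reverse_complement("GATTACA")),
               "GATTACA")

  ens <- fx_ensemble()
  gg <- generate_genome(400, 2, "6mA", seed = 77)
  lin <- default_lineages()[[3]]
  fwd <- scan_sequence(gg$sequence, lin, "6mA", ens)
  both <- scan_sequence(gg$sequence, lin, "6mA", ens,
                        both_strands = TRUE)
  expect_true(all(c("+", "-") %in% both$strand) || nrow(both) == 0 ||
                all(both$strand == "+"))
  # forward-strand calls are unchanged by adding the reverse scan
  expect_setequal(both$position[both$strand == "+"], fwd$position)
  # a reverse call at forward position p means the reverse complement has
  # the target base at its own center there
  rc <- reverse_complement(gg$sequence)
  for (p in both$position[both$strand == "-"]) {
    expect_equal(substr(rc, 400 - p + 1, 400 - p + 1), "A")
  }
})

test_that("FASTA round-trips", {
  seqs <- c(chrA = strrep("ACGT", 30), chrB = strrep("GATTACA", 10))
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(back, seqs)
})
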