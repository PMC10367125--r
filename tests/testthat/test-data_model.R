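# Sample-to-sentence encoding, splitting and corpus assembly.

sample_lineage_of <- function(ds, i) {
  methylm:::sample_lineage(ds, i)
}

test_that("extract_kmers enumerates all sliding windows", {
  # brute-force oracle: substrings at every start offset
  brute <- function(s, k) {
    vapply(seq_len(nchar(s) - k + 1L),
           function(i) substr(s, i, i + k - 1L), character(1))
  }
  expect_equal(extract_kmers("ACGTAC", 6), "ACGTAC")
  expect_equal(extract_kmers("ACGTACGT", 6), brute("ACGTACGT", 6))
  expect_length(extract_kmers(substr(strrep("ACGT", 11), 1, 41), 6),
                41 - 6 + 1)

  set.seed(11)
  for (i in 1:25) {
    L <- sample(6:60, 1)
    k <- sample(1:min(8, L), 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    got <- extract_kmers(s, k)
    expect_length(got, L - k + 1L)
    expect_equal(got, brute(s, k))
  }
  expect_error(extract_kmers("ACG", 6), "shorter than")
})

test_that("a 41-nt window yields exactly 36 six-mers", {
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE),
             collapse = "")
  expect_length(extract_kmers(s, 6), 36)
})

test_that("lineage sentences follow the template and round-trip", {
  lin <- taxonomic_lineage(species = "Homo sapiens", genus = "Homo",
                           family = "Hominidae", order = "Primates",
                           class = "Mammalia", phylum = "Chordata",
                           kingdom = "Metazoa", domain = "Eukaryota")
  s <- lineage_sentence(lin)
  expect_match(s, "^For this organism, its species is Homo sapiens, its genus is Homo,")
  expect_match(s, "its domain is Eukaryota\\.$")

  # placeholder lineage: well-formed with "unknown" eight times
  s_u <- lineage_sentence(taxonomic_lineage())
  expect_equal(lengths(regmatches(s_u, gregexpr("unknown", s_u))), 8L)

  # inverse-parse oracle over random lineages
  set.seed(21)
  for (i in 1:10) {
    ranks <- replicate(8, paste(sample(letters, 6), collapse = ""))
    lin_i <- do.call(taxonomic_lineage, as.list(ranks))
    back <- parse_lineage_sentence(lineage_sentence(lin_i))
    expect_equal(unclass(back), unclass(lin_i))
  }
})

test_that("empty rank names become the 'unknown' placeholder", {
  lin <- taxonomic_lineage(species = "X", genus = "")
  expect_equal(unname(unclass(lin)["genus"]), "unknown")
})

test_that("build_sentence composes 36 DNA words plus the lineage clause", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE),
             collapse = "")
  lin1 <- taxonomic_lineage(species = "Escherichia coli")
  lin2 <- taxonomic_lineage(species = "Homo sapiens")
  ps1 <- build_sentence(s, lin1, "a")
  ps2 <- build_sentence(s, lin2, "b")

  dna_part <- strsplit(ps1$text, " For this organism")[[1]][1]
  expect_length(strsplit(dna_part, " ")[[1]], 36)

  # identical sequence, different lineages: texts agree on the DNA part
  expect_equal(strsplit(ps2$text, " For this organism")[[1]][1], dna_part)
  expect_false(ps1$text == ps2$text)

  # word count = 36 + words of the lineage clause (independent count)
  n_total <- length(strsplit(ps1$text, "\\s+")[[1]])
  n_lineage <- length(strsplit(lineage_sentence(lin1), "\\s+")[[1]])
  expect_equal(n_total, 36 + n_lineage)

  expect_error(build_sentence(paste0(substr(s, 1, 40), "N"), lin1, "c"),
               "non-ACGT")
})

test_that("split_by_type partitions the dataset", {
  g6 <- generate_dataset(10, 10, "6mA", seed = 1)$dataset
  g4 <- generate_dataset(7, 7, "4mC", seed = 2)$dataset
  g4$id <- paste0("b_", g4$id)
  mixed <- methyl_dataset(rbind(g6, g4))
  parts <- split_by_type(mixed)
  expect_named(parts, c("6mA", "4mC", "5hmC"))
  expect_equal(nrow(parts[["6mA"]]), 20)
  expect_equal(nrow(parts[["4mC"]]), 14)
  expect_equal(nrow(parts[["5hmC"]]), 0)
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(mixed))
  # concatenation is a permutation of the input
  expect_setequal(do.call(rbind, parts)$id, mixed$id)
  # independent tally
  expect_equal(nrow(parts[["4mC"]]), sum(mixed$methyl_type == "4mC"))

  only6 <- split_by_type(g6)
  expect_equal(nrow(only6[["6mA"]]), 20)
  expect_equal(nrow(only6[["4mC"]]) + nrow(only6[["5hmC"]]), 0)
})

test_that("train_val_split is stratified, sized and reproducible", {
  ds <- generate_dataset(5, 5, "6mA", seed = 3)$dataset
  sp <- train_val_split(ds, ratio = 0.8, seed = 9)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$val), 2)
  expect_length(intersect(sp$train$id, sp$val$id), 0)

  sp2 <- train_val_split(ds, ratio = 0.8, seed = 9)
  expect_identical(sp$train$id, sp2$train$id)
  expect_identical(sp$val$id, sp2$val$id)

  # per-class arithmetic oracle: class counts within 1 of ratio * n_class,
  # overall train size exactly ceiling(ratio * n)
  set.seed(31)
  for (i in 1:8) {
    n_pos <- sample(3:40, 1); n_neg <- sample(3:40, 1)
    r <- runif(1, 0.5, 0.9)
    ds_i <- generate_dataset(n_pos, n_neg, "6mA", seed = i)$dataset
    sp_i <- train_val_split(ds_i, ratio = r, seed = i)
    expect_equal(nrow(sp_i$train), ceiling(r * (n_pos + n_neg)))
    got_pos <- sum(sp_i$train$label == "positive")
    expect_lte(abs(got_pos - r * n_pos), 1)
  }
  expect_error(train_val_split(ds[0, ], 0.8, 1), "empty")
})

test_that("build_corpus augments with novel lineages only", {
  gen <- generate_dataset(6, 6, "6mA", seed = 5)
  ds <- gen$dataset
  co0 <- build_corpus(ds)
  expect_equal(length(co0$sentences), nrow(ds))

  dup <- sample_lineage_of(ds, 1)
  novel <- taxonomic_lineage(species = "Methanococcus maripaludis",
                             genus = "Methanococcus", domain = "Archaea")
  co <- build_corpus(ds, list(dup, novel, novel))
  # duplicate lineage not added; the identical novel lineage added once
  expect_equal(length(co$sentences), nrow(ds) + 1)

  # set-difference oracle
  train_keys <- unique(apply(ds[, c("species", "genus", "family", "order",
                                    "class", "phylum", "kingdom",
                                    "domain")], 1, paste, collapse = "|"))
  extra_keys <- unique(vapply(list(dup, novel),
                              function(l) paste(unclass(l), collapse = "|"),
                              character(1)))
  expect_equal(length(co$sentences),
               nrow(ds) + length(setdiff(extra_keys, train_keys)))
})

test_that("dataset validation enforces the window invariants", {
  ds <- generate_dataset(3, 3, "6mA", seed = 6)$dataset
  bad <- ds; bad$sequence[1] <- substr(bad$sequence[1], 1, 40)
  expect_error(methyl_dataset(bad), "41")
  bad2 <- ds; bad2$id[2] <- bad2$id[1]
  expect_error(methyl_dataset(bad2), "duplicate")
  # positive with the wrong center base
  bad3 <- ds
  s <- bad3$sequence[1]
  substr(s, 21, 21) <- "G"
  bad3$sequence[1] <- s
  expect_error(methyl_dataset(bad3), "target base")
})

test_that("sample tables round-trip through TSV", {
  ds <- generate_dataset(4, 4, "4mC", seed = 8)$dataset
  path <- tempfile(fileext = ".tsv")
  write_samples_tsv(ds, path)
  back <- read_samples_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
})
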