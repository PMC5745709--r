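test_that("FASTA parsing handles headers, case, U->T, and bad input", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT"), tf)
  recs <- read_fasta(tf)
  expect_length(recs, 1L)
  expect_equal(recs$x$seq, "ACGT")
  expect_false(recs$x$circular)

  writeLines(c(">c circular=true", "acgu", "ttnn"), tf)
  rec <- read_fasta(tf)$c
  expect_true(rec$circular)
  expect_equal(rec$seq, "ACGTTTNN")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), tf)
  expect_error(read_fasta(tf), "duplicate identifier")
  writeLines(c(">b", "ACXT"), tf)
  expect_error(read_fasta(tf), "illegal residue")
  writeLines(c("ACGT"), tf)
  expect_error(read_fasta(tf), "before any header")
})

test_that("FASTA round-trip is the identity on a simulated genome", {
  sim <- make_reference_genome(seed = 42L)
  rec <- as_seq_record(sim)
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, tf)
  back <- read_fasta(tf)[[rec$id]]
  expect_identical(back$seq, rec$seq)
  expect_identical(back$circular, TRUE)
})

test_that("feature-table coordinates convert between disk and memory", {
  tf <- withr::local_tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               "g\tsrc\ttRNA\t1\t3\t.\t+\t.\tlabel=trnF"), tf)
  ft <- read_feature_table(tf)
  expect_equal(ft$start, 0L)
  expect_equal(ft$end, 3L)
  expect_equal(ft$strand, 1L)
})

test_that("origin-wrapping features are decoded with the genome length", {
  # internally [15900, 16120) on a 16000-bp circle spans 220 bp; on disk the
  # row is 1-based with end < start
  tf <- withr::local_tempfile(fileext = ".gff")
  writeLines("g\tsrc\tspacer\t15901\t120\t.\t+\t.\tlabel=CR", tf)
  ft <- read_feature_table(tf, genome_lengths = c(g = 16000L))
  expect_equal(ft$start, 15900L)
  expect_equal(ft$end, 16120L)
  expect_equal(ft$end - ft$start, 220L)
  expect_error(read_feature_table(tf), "no genome length")
})

test_that("a simulated 37-gene table round-trips losslessly", {
  sim <- make_reference_genome(seed = 7L)
  ft <- as_feature_table(sim)
  tf <- withr::local_tempfile(fileext = ".gff")
  gl <- setNames(genome_length(sim), sim$seq_id)
  write_feature_table(ft, tf, genome_lengths = gl)
  back <- read_feature_table(tf, genome_lengths = gl)
  expect_equal(back$start, ft$start)
  expect_equal(back$end, ft$end)
  expect_equal(back$label, ft$label)
  expect_equal(back$feature_class, ft$feature_class)
  expect_equal(back$strand, ft$strand)
})

test_that("feature validation rejects bad classes and empty spans", {
  expect_error(feature_table("g", "x", "gene", 0, 10), "unknown feature_class")
  expect_error(feature_table("g", "x", "tRNA", 5, 5), "length >= 1")
})

test_that("extract_feature_sequence honours strand and origin wrap", {
  rec <- seq_record("g", "ACGTT")
  plus <- list(start = 0L, end = 4L, strand = 1L)
  expect_equal(extract_feature_sequence(rec, plus), "ACGT")
  minus <- list(start = 0L, end = 4L, strand = -1L)
  expect_equal(extract_feature_sequence(rec, minus),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ACGT"))))
  # non-palindromic minus-strand case checked against Biostrings
  rec2 <- seq_record("g2", "AAGTC")
  m2 <- list(start = 1L, end = 5L, strand = -1L)
  expect_equal(extract_feature_sequence(rec2, m2),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("AGTC"))))

  circ <- seq_record("c", "AAACCC", circular = TRUE)
  wrap <- list(start = 4L, end = 8L, strand = 1L)
  # brute-force rotation oracle
  rot <- paste(rep(strsplit("AAACCC", "")[[1]], 2)[5:8], collapse = "")
  expect_equal(extract_feature_sequence(circ, wrap), rot)
  expect_equal(extract_feature_sequence(circ, wrap), "CCAA")
  lin <- seq_record("l", "AAACCC", circular = FALSE)
  expect_error(extract_feature_sequence(lin, wrap), "linear")
})

test_that("depth tracks read from BED-like intervals", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("g\t0\t5\t10", "g\t5\t10\t30"), tf)
  tr <- read_depth_track(tf, genome_length = 10L)
  expect_equal(tr$depths, c(rep(10L, 5), rep(30L, 5)))
  expect_error(depth_track("g", c(1, -2)), ">= 0")
})
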