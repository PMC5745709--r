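test_that("self-alignment is gap-free with identity 1 and score match*L", {
  set.seed(41)
  for (L in c(1, 5, 40, 200)) {
    x <- random_dna_str(L)
    aln <- global_align(x, x)
    expect_equal(aln$score, L * scoring_scheme()$match)
    ds <- summarize_differences(aln)
    expect_equal(ds$identity, 1.0)
    expect_equal(ds$insertion_bp + ds$deletion_bp, 0L)
  }
})

test_that("alignment scores equal brute-force enumeration on short pairs", {
  expect_equal(global_align("ACGT", "AGT")$score,
               bf_align_score("ACGT", "AGT"))
  set.seed(42)
  schemes <- list(scoring_scheme(),
                  scoring_scheme(match = 2, mismatch = -3,
                                 gap_open = -4, gap_extend = -2))
  for (rep in 1:60) {
    sc <- schemes[[1 + rep %% 2]]
    a <- random_dna_str(sample(1:7, 1))
    b <- random_dna_str(sample(1:7, 1))
    expect_equal(global_align(a, b, sc)$score, bf_align_score(a, b, sc),
                 info = paste(a, b))
  }
})

test_that("alignment invariants hold: rows strip to inputs, columns add up", {
  set.seed(43)
  for (rep in 1:15) {
    a <- random_dna_str(sample(5:60, 1))
    b <- random_dna_str(sample(5:60, 1))
    aln <- global_align(a, b)
    expect_equal(gsub("-", "", aln$row_ref, fixed = TRUE), a)
    expect_equal(gsub("-", "", aln$row_qry, fixed = TRUE), b)
    ds <- summarize_differences(aln)
    expect_equal(ds$columns, ds$matches + ds$substitutions + ds$ambiguous +
                   ds$insertion_bp + ds$deletion_bp)
    # length bookkeeping: query = reference - deletions + insertions
    expect_equal(nchar(b), nchar(a) - ds$deletion_bp + ds$insertion_bp)
  }
})

test_that("N-containing columns count as ambiguous, never match/substitution", {
  aln <- pairwise_alignment("ACNT", "ACNA")
  ds <- summarize_differences(aln)
  expect_equal(ds$matches, 2L)
  expect_equal(ds$substitutions, 1L)
  expect_equal(ds$ambiguous, 1L)
})

test_that("difference summaries recover planted edits", {
  set.seed(44)
  # published worked example: 682-bp gene, 30 substitutions, one 2-bp
  # deletion, two insertions totalling 5 bp -> 687 columns, identity 94.6%
  ref <- random_dna_str(682)
  sp <- random_planted_edits(682, 30, ins_lens = c(2, 3), del_lens = 2)
  pl <- plant_edits(ref, sub_pos = sp$sub_pos, ins = sp$ins, del = sp$del)
  ds <- summarize_differences(pl$alignment)
  expect_equal(ds$columns, 687L)
  expect_equal(ds$matches, 650L)
  expect_equal(round(100 * ds$identity, 1), 94.6)
  # re-aligning from scratch recovers the same counts
  ds2 <- summarize_differences(global_align(ref, pl$query))
  expect_equal(ds2$substitutions, 30L)
  expect_equal(ds2$insertion_events, 2L)
  expect_equal(ds2$insertion_bp, 5L)
  expect_equal(ds2$deletion_events, 1L)
  expect_equal(ds2$deletion_bp, 2L)

  # random planted batteries with well-separated edits recover exactly
  for (rep in 1:10) {
    L <- sample(200:500, 1)
    nsub <- sample(3:12, 1)
    sp <- random_planted_edits(L, nsub,
                               ins_lens = sample(1:3, sample(0:2, 1),
                                                 replace = TRUE),
                               del_lens = sample(1:3, sample(0:2, 1),
                                                 replace = TRUE))
    refL <- random_dna_str(L)
    pl <- plant_edits(refL, sub_pos = sp$sub_pos, ins = sp$ins, del = sp$del)
    got <- summarize_differences(global_align(refL, pl$query))
    expect_equal(got$substitutions, length(sp$sub_pos))
    expect_equal(got$insertion_events, length(sp$ins))
    expect_equal(got$deletion_events, length(sp$del))
  }
})

test_that("ORF scanning follows the vertebrate mitochondrial code", {
  expect_equal(scan_orfs("ATGAAATAA")$orfs$aa_length[1], 2L)
  # no start codon in any frame -> no ORFs
  expect_equal(scan_orfs("TAACCCTAA")$longest_aa, 0L)
  # AGA/AGG are stops in the vertebrate mitochondrial code
  expect_equal(scan_orfs("ATGAAAAGA")$orfs$aa_length[1], 2L)
  # open-ended ORF reaching the sequence end
  rep <- scan_orfs("ATGAAAAAA")
  expect_true(rep$orfs$open_ended[1])
  expect_equal(rep$longest_aa, 3L)

  # planted premature stop: longest ORF ends right before it
  set.seed(45)
  cds <- rand_cds_for_test(60)  # 20 codons: ATG + 18 sense + TAA
  stopped <- paste0(substr(cds, 1, 30), "TAA", substr(cds, 34, 60))
  expect_equal(scan_orfs(stopped)$orfs$aa_length[1], 10L)
})

test_that("paralog classification separates intact, pseudogene, unrecognizable", {
  set.seed(46)
  cds <- rand_cds_for_test(519)
  expect_equal(classify_paralog(cds, cds)$call, "intact")

  # ~97% identity with a premature stop: a recognizable pseudogene
  subs <- plan_stop_subs_for_test(cds, 10L)
  pl <- plant_edits(cds, sub_pos = subs$pos, sub_alt = subs$alt,
                    ins = list(list(pos = 250L, len = 2L)))
  st <- classify_paralog(cds, pl$query)
  expect_equal(st$call, "pseudogene")
  expect_true(st$evidence$premature_stop)
  expect_gt(st$evidence$identity, 0.95)

  # unrelated random sequence: no recognizable similarity
  unrel <- random_dna_str(519)
  st2 <- classify_paralog(cds, unrel)
  expect_equal(st2$call, "unrecognizable")
  expect_lt(st2$evidence$identity, 0.5)

  # heavy truncation alone disrupts a copy
  st3 <- classify_paralog(cds, substr(cds, 1, 300))
  expect_equal(st3$call, "pseudogene")
  expect_lt(st3$evidence$length_ratio, 0.9)
})
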