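test_that("the reference template has 37 genes and valid protein ORFs", {
  sim <- make_reference_genome(seed = 71L)
  genes <- sim$segments$feature_class %in% c("protein", "rRNA", "tRNA")
  expect_equal(sum(genes), 37L)
  expect_equal(sum(sim$segments$feature_class == "protein"), 13L)
  expect_equal(sum(sim$segments$feature_class == "rRNA"), 2L)
  expect_equal(sum(sim$segments$feature_class == "tRNA"), 22L)

  rec <- as_seq_record(sim)
  ft <- as_feature_table(sim)
  for (i in which(ft$feature_class == "protein")) {
    cds <- extract_feature_sequence(rec, ft[i, ])
    rep <- scan_orfs(cds)
    expect_equal(rep$longest_aa, nchar(cds) %/% 3L - 1L,
                 info = ft$label[i])
  }
})

test_that("genome generation is deterministic per seed", {
  a <- make_reference_genome(seed = 72L)
  b <- make_reference_genome(seed = 72L)
  expect_identical(genome_sequence(a), genome_sequence(b))
  c <- make_reference_genome(seed = 73L)
  expect_false(identical(genome_sequence(a), genome_sequence(c)))
})

test_that("tandem duplication grows the genome by exactly the span", {
  sim <- make_reference_genome(seed = 74L)
  L0 <- genome_length(sim)
  span <- c("ND6", "trnE", "CYTB", "trnT", "IGS", "trnP")
  out <- apply_duplication(sim, span)
  expect_equal(genome_length(out$genome), L0 + out$truth$span_bp)
  # each span gene now occurs twice, in tandem
  go <- sim_gene_order(out$genome)
  for (lab in span) {
    expect_equal(sum(go$labels == lab),
                 sum(sim_gene_order(sim)$labels == lab) + 1L)
  }
  tags <- out$genome$segments$paralog_tag
  expect_equal(sum(!is.na(tags) & tags == "copy1"), 6L)
  expect_equal(sum(!is.na(tags) & tags == "copy2"), 6L)
})

test_that("duplicating the rRNA/control-region arc emulates the recent event", {
  sim <- make_reference_genome(seed = 75L)
  span <- c("trnP", "CR", "trnF", "rrnS", "trnV", "rrnL", "trnL2", "ND1")
  out <- apply_duplication(sim, span)
  go <- sim_gene_order(out$genome)
  for (lab in c("CR", "rrnS", "rrnL", "ND1", "trnF", "trnV", "trnL2")) {
    expect_equal(sum(go$labels == lab), 2L, info = lab)
  }
})

test_that("evolution at rate zero is the identity", {
  sim <- make_reference_genome(seed = 76L)
  out <- evolve(sim, mutation_params(sub_rate = 0, indel_rate = 0),
                targets = 1:5)
  expect_identical(genome_sequence(out$genome), genome_sequence(sim))
})

test_that("planted substitution counts follow the binomial expectation", {
  set.seed(77)
  sim <- make_reference_genome()
  i <- which(sim$segments$label == "ND5")
  L <- nchar(sim$segments$seq[i])
  r <- 0.02
  counts <- replicate(100, {
    evolve(sim, mutation_params(sub_rate = r, indel_rate = 0),
           targets = i)$truth$per_segment[[1]]$substitutions
  })
  expect_lt(abs(mean(counts) - r * L), 4 * sqrt(L * r * (1 - r) / 100))
})

test_that("decay pipeline recovers what evolution planted", {
  set.seed(78)
  sim <- make_reference_genome()
  i <- which(sim$segments$label == "COX1")
  functional <- sim$segments$seq[i]
  out <- evolve(sim, mutation_params(sub_rate = 0.03, indel_rate = 0.001),
                targets = i)
  truth <- out$truth$per_segment[[1]]
  ds <- summarize_differences(global_align(functional,
                                           out$genome$segments$seq[i]))
  expect_lt(abs(ds$substitutions - truth$substitutions),
            max(2, 0.1 * truth$substitutions) + 1)
  expect_equal(ds$insertion_bp - ds$deletion_bp,
               truth$insertion_bp - truth$deletion_bp)
})

test_that("segmental deletions keep exact length books", {
  sim <- make_reference_genome(seed = 79L)
  L0 <- genome_length(sim)
  expect_identical(genome_sequence(
    apply_segmental_deletion(sim, c(100, 100))$genome),
    genome_sequence(sim))
  set.seed(80)
  for (rep in 1:10) {
    a <- sample.int(L0 - 1L, 1L)
    b <- min(L0, a + sample.int(2000L, 1L))
    out <- apply_segmental_deletion(sim, c(a, b))
    expect_equal(genome_length(out$genome), L0 - (b - a))
  }
  expect_error(apply_segmental_deletion(sim, c(0, L0)), "whole genome")
})

test_that("the two-event scenario reproduces the published decay anatomy", {
  sc <- aneides_preset(seed = 81L)
  seg <- sc$hardii$segments
  psnd6 <- seg$seq[seg$label == "ND6" & seg$feature_class == "pseudogene"]
  expect_equal(nchar(psnd6), 521L)   # 519 bp + one 2-bp insertion
  rem <- seg$seq[seg$label == "REP"]
  expect_equal(nchar(rem), 111L)     # rRNA-block remnant
  st <- classify_paralog(sc$reference$segments$seq[
    sc$reference$segments$label == "rrnL"][1], rem, is_protein = FALSE)
  expect_equal(st$call, "unrecognizable")
  # duplicated pseudogene ND6: recognizable, stop-disrupted
  functional <- mitodrl:::revcomp(seg$seq[seg$label == "ND6" &
                                            seg$feature_class == "protein"])
  st2 <- classify_paralog(functional, mitodrl:::revcomp(psnd6))
  expect_equal(st2$call, "pseudogene")
  expect_true(st2$evidence$premature_stop)
})

test_that("replaying the truth record reproduces final genomes exactly", {
  set.seed(82)
  for (rep in 1:6) {
    seed <- sample.int(10000L, 1L)
    sc <- aneides_preset(seed = seed)
    expect_identical(genome_sequence(truth_replay(sc$reference,
                                                  sc$events_basal)),
                     genome_sequence(sc$aneides))
    expect_identical(genome_sequence(truth_replay(sc$aneides,
                                                  sc$events_recent)),
                     genome_sequence(sc$hardii))
  }
})

test_that("single-DRL inference recovers both planted spans end-to-end", {
  sc <- aneides_preset(seed = 83L)
  go_ref <- sim_gene_order(sc$reference)
  go_an <- sim_gene_order(sc$aneides)
  go_ha <- sim_gene_order(sc$hardii, drop_labels = "REP")

  s1 <- infer_single_drl(go_ref, go_an)
  labs1 <- lapply(s1, `[[`, "span_labels")
  expect_true(any(vapply(labs1, function(l) identical(l, sc$spans$basal),
                         logical(1))))
  s2 <- infer_single_drl(go_an, go_ha)
  labs2 <- lapply(s2, `[[`, "span_labels")
  expect_true(any(vapply(labs2, function(l) identical(l, sc$spans$recent),
                         logical(1))))
  # the smallest minimal span matches the planted one in both events
  expect_equal(min(drl_spans(s1)$span_length), length(sc$spans$basal))
  expect_equal(min(drl_spans(s2)$span_length), length(sc$spans$recent))
})

test_that("datasets write reproducibly and round-trip through the readers", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_dataset(list(preset = "aneides", n_replicates = 1),
                         seed = 84L, out_dir = d1)
  m2 <- simulate_dataset(list(preset = "aneides", n_replicates = 1),
                         seed = 84L, out_dir = d2)
  f1 <- m1[[1]]$paths[["fasta"]]
  expect_identical(readLines(f1), readLines(m2[[1]]$paths[["fasta"]]))
  expect_identical(readLines(m1[[1]]$paths[["truth"]]),
                   readLines(m2[[1]]$paths[["truth"]]))

  sc <- m1[[1]]$scenario
  recs <- read_fasta(f1)
  expect_identical(recs[[sc$reference$seq_id]]$seq,
                   genome_sequence(sc$reference))
  gl <- setNames(genome_length(sc$hardii), sc$hardii$seq_id)
  ft <- read_feature_table(file.path(dirname(f1), "hardii_sim.gff"), gl)
  expect_gt(nrow(ft), 37L)
})
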