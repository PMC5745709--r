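#' Simulate the two-event plethodontid rearrangement scenario
#'
#' Builds a three-genome series emulating the rearrangement history of
#' *Aneides* mitogenomes:
#'
#' 1. A typical-vertebrate reference genome.
#' 2. A basal event: tandem duplication of the `ND6, trnE, CYTB, trnT,
#'    IGS, trnP` arc, excision of one `ND6 + trnE` copy and of the other
#'    copy's `CYTB + trnT`, and decay of the surviving duplicate `trnP` to
#'    a recognizable pseudogene. This swaps ND6/CYTB order - the derived
#'    genus-wide arrangement.
#' 3. A recent species-level event on that background: duplication of the
#'    arc from ND6 through ND1 (control region, both rRNAs and tRNAs F, V,
#'    L included), near-complete deletion of the duplicate rRNA block
#'    (only a 111-bp unrecognizable remnant, relabelled `REP`, remains),
#'    deletion of the duplicate control region, decay of the duplicate
#'    ND6 (10 substitutions including a premature stop, one 2-bp
#'    insertion) and ND1 (truncation to its first 682 bp, 30
#'    substitutions, one 2-bp deletion, two insertions of 5 bp total) to
#'    pseudogenes, and light decay of the duplicate trnL and trnF copies.
#'
#' All events carry truth records; replaying them on the reference
#' reproduces each genome byte-for-byte.
#'
#' @param seed Integer seed.
#' @return List with `reference`, `aneides`, `hardii` (`sim_genome`s),
#'   `events_basal`, `events_recent` (truth event lists), `spans` (the two
#'   planted spans), and `decay` (planted alignments/counts for the
#'   pseudogenes).
#' @export
aneides_preset <- function(seed = 1L) {
  set.seed(seed)
  ref <- make_reference_genome(seed = NULL)

  # --- basal event -------------------------------------------------------
  span1 <- c("ND6", "trnE", "CYTB", "trnT", "IGS", "trnP")
  g <- ref
  ev1 <- list()
  d1 <- apply_duplication(g, span1)
  g <- d1$genome; ev1 <- c(ev1, list(d1$truth))
  seg_idx <- function(label, tag) {
    which(g$segments$label == label &
            !is.na(g$segments$paralog_tag) & g$segments$paralog_tag == tag)
  }
  dl <- delete_segments(g, c(seg_idx("ND6", "copy1"), seg_idx("trnE", "copy1")))
  g <- dl$genome; ev1 <- c(ev1, dl$truth)
  dl <- delete_segments(g, c(seg_idx("CYTB", "copy2"), seg_idx("trnT", "copy2")))
  g <- dl$genome; ev1 <- c(ev1, dl$truth)
  i_psP <- seg_idx("trnP", "copy1")
  evp <- evolve(g, mutation_params(sub_rate = 0.08, indel_rate = 0.005),
                targets = i_psP)
  g <- evp$genome; ev1 <- c(ev1, list(evp$truth))
  g$segments$feature_class[i_psP] <- "pseudogene"
  g$segments$status[i_psP] <- "pseudogene"
  g$seq_id <- "aneides_sim"
  aneides <- g

  # --- recent (species-level) event -------------------------------------
  span2 <- c("ND6", "trnE", "IGS", "trnP", "CR", "trnF", "rrnS", "trnV",
             "rrnL", "trnL2", "ND1")
  ev2 <- list()
  d2 <- apply_duplication(g, span2)
  g <- d2$genome; ev2 <- c(ev2, list(d2$truth))

  # duplicate control region excised outright
  dl <- delete_segments(g, seg_idx("CR", "copy1"))
  g <- dl$genome; ev2 <- c(ev2, dl$truth)

  # duplicate rRNA block deleted except a 111-bp remnant of rrnL
  i_rs <- seg_idx("rrnS", "copy1"); i_rl <- seg_idx("rrnL", "copy1")
  lens <- nchar(g$segments$seq)
  seg_end <- cumsum(lens); seg_start <- seg_end - lens
  dl <- apply_segmental_deletion(g, c(seg_start[i_rs], seg_end[i_rl] - 111L))
  g <- dl$genome; ev2 <- c(ev2, list(dl$truth))
  i_rem <- seg_idx("rrnL", "copy1")
  rem_edits <- rbind(edit_row("del", 1L, g$segments$seq[i_rem], ""),
                     edit_row("ins", 0L, "", rand_dna(111L)))
  ed <- edit_segment(g, i_rem, rem_edits)
  g <- ed$genome; ev2 <- c(ev2, list(ed$truth))
  g$segments$label[i_rem] <- "REP"
  g$segments$feature_class[i_rem] <- "spacer"
  g$segments$status[i_rem] <- "unrecognizable"
  ev2 <- c(ev2, list(list(type = "relabel", segment_index = i_rem,
                          label = "REP", feature_class = "spacer")))

  decay <- list()

  # psi-ND6: minus strand; decay planned in coding orientation
  i_nd6 <- seg_idx("ND6", "copy1")
  coding <- revcomp(g$segments$seq[i_nd6])
  subs <- plan_protein_decay_subs(coding, 10L)
  ins_pos <- sample(setdiff(seq(4L, nchar(coding) - 3L), subs$pos), 1L)
  planted <- plant_edits(coding, sub_pos = subs$pos, sub_alt = subs$alt,
                         ins = list(list(pos = ins_pos, len = 2L)))
  ed <- edit_segment(g, i_nd6, flip_edits(planted$edits, nchar(coding)),
                     mark_pseudogene = TRUE)
  g <- ed$genome; ev2 <- c(ev2, list(ed$truth))
  decay$psND6 <- list(functional = coding, planted = planted)

  # psi-ND1: plus strand; truncated to its first 682 bp, then decayed
  i_nd1 <- seg_idx("ND1", "copy1")
  nd1 <- g$segments$seq[i_nd1]
  spots <- random_planted_edits(682L, n_sub = 30L, ins_lens = c(2L, 3L),
                                del_lens = 2L)
  planted <- plant_edits(substr(nd1, 1L, 682L), sub_pos = spots$sub_pos,
                         ins = spots$ins, del = spots$del)
  tail_del <- edit_row("del", 683L, substr(nd1, 683L, nchar(nd1)), "")
  ed <- edit_segment(g, i_nd1, rbind(tail_del, planted$edits),
                     mark_pseudogene = TRUE)
  g <- ed$genome; ev2 <- c(ev2, list(ed$truth))
  decay$psND1 <- list(functional = substr(nd1, 1L, 682L), planted = planted)

  # duplicate tRNA copies: trnL with two substitutions, trnF with three
  for (sp in list(list("trnL2", 2L), list("trnF", 3L))) {
    i_t <- seg_idx(sp[[1L]], "copy1")
    tseq <- g$segments$seq[i_t]
    pos <- sort(sample.int(nchar(tseq), sp[[2L]]))
    pl <- plant_edits(tseq, sub_pos = pos)
    ed <- edit_segment(g, i_t, pl$edits)
    g <- ed$genome; ev2 <- c(ev2, list(ed$truth))
    decay[[paste0(sp[[1L]], "_copy")]] <- list(functional = tseq, planted = pl)
  }

  g$seq_id <- "hardii_sim"
  list(reference = ref, aneides = aneides, hardii = g,
       events_basal = ev1, events_recent = ev2,
       spans = list(basal = span1, recent = span2),
       decay = decay)
}

#' Write a simulated genome and its annotation to disk
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the paths written.
#' @export
write_sim_genome <- function(sim, dir, prefix = sim$seq_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".gff"))
  write_fasta(as_seq_record(sim), fa)
  write_feature_table(as_feature_table(sim), gff,
                      genome_lengths = setNames(genome_length(sim),
                                                sim$seq_id))
  c(fasta = fa, features = gff)
}

#' Simulate a dataset of annotated genomes with ground truth
#'
#' Runs the configured scenario per replicate and writes FASTA, a
#' GFF3-subset feature table and a truth JSON for each genome; fully
#' reproducible for a given seed.
#'
#' @param config List: `preset` one of `"reference"`, `"aneides"`;
#'   `n_replicates` (default 1).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Manifest: list (one element per replicate) of written paths and
#'   in-memory scenario objects, invisibly.
#' @export
simulate_dataset <- function(config = list(preset = "aneides",
                                           n_replicates = 1L),
                             seed = 1L, out_dir) {
  preset <- config$preset %||% "aneides"
  n_rep <- config$n_replicates %||% 1L
  manifest <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    rep_seed <- seed + 7919L * (r - 1L)
    rep_dir <- file.path(out_dir, sprintf("rep%02d", r))
    if (preset == "reference") {
      sim <- make_reference_genome(seed = rep_seed)
      paths <- write_sim_genome(sim, rep_dir)
      truth <- list(preset = "reference", seed = rep_seed, events = list())
      obj <- list(reference = sim)
    } else if (preset == "aneides") {
      sc <- aneides_preset(seed = rep_seed)
      paths <- c(write_sim_genome(sc$reference, rep_dir),
                 write_sim_genome(sc$aneides, rep_dir),
                 write_sim_genome(sc$hardii, rep_dir))
      truth <- list(preset = "aneides", seed = rep_seed,
                    spans = sc$spans,
                    events = list(basal = sc$events_basal,
                                  recent = sc$events_recent))
      obj <- sc
    } else stop("unknown preset '", preset, "'")
    tj <- file.path(rep_dir, "truth.json")
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    manifest[[r]] <- list(paths = c(paths, truth = tj), scenario = obj,
                          seed = rep_seed)
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report as JSON
#'
#' Fixed top-level schema shared by all pipeline stages:
#' `tool_version`, `inputs`, `parameters`, `results`.
#'
#' @param results Named list of stage results.
#' @param path Output path.
#' @param inputs,parameters Named lists describing provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, inputs = list(), parameters = list()) {
  jsonlite::write_json(
    list(tool_version = as.character(utils::packageVersion("mitodrl")),
         inputs = inputs, parameters = parameters, results = results),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
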