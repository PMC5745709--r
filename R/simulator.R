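#' Template for a simulated vertebrate mitochondrial genome
#'
#' Returns the segment layout of a typical circular vertebrate mitogenome:
#' 13 protein-coding genes, 2 rRNAs and 22 tRNAs in the standard vertebrate
#' order, plus one intergenic spacer (between trnT and trnP, the spacer
#' that participates in the plethodontid rearrangement) and the control
#' region. Default lengths are typical vertebrate values; ND6 (519 bp),
#' ND1 (960 bp) and the rRNA block (rrnS + trnV + rrnL = 2520 bp) use the
#' published *Aneides hardii* lengths so worked examples carry realistic
#' sizes. Protein lengths are multiples of 3.
#'
#' @param trna_length tRNA gene length (bp).
#' @param igs_length Intergenic-spacer length (bp).
#' @param cr_length Control-region length (bp).
#' @param randomize Draw gene lengths uniformly from per-class ranges
#'   instead of the fixed template (proteins 300-1800 rounded to codons,
#'   rRNAs 800-1700, tRNAs 65-75).
#' @return Data frame with columns `label`, `feature_class`, `strand`,
#'   `length`; 39 segments of which 37 are genes.
#' @export
genome_spec <- function(trna_length = 70L, igs_length = 100L,
                        cr_length = 1000L, randomize = FALSE) {
  p <- function(label, len) list(label, "protein", 1L, len)
  t_ <- function(label, strand = 1L) list(label, "tRNA", strand, trna_length)
  spec <- list(
    t_("trnF"), list("rrnS", "rRNA", 1L, 850L), t_("trnV"),
    list("rrnL", "rRNA", 1L, 1600L), t_("trnL2"),
    p("ND1", 960L), t_("trnI"), t_("trnQ", -1L), t_("trnM"),
    p("ND2", 1038L), t_("trnW"), t_("trnA", -1L), t_("trnN", -1L),
    t_("trnC", -1L), t_("trnY", -1L),
    p("COX1", 1551L), t_("trnS2", -1L), t_("trnD"),
    p("COX2", 690L), t_("trnK"),
    p("ATP8", 168L), p("ATP6", 681L), p("COX3", 786L), t_("trnG"),
    p("ND3", 348L), t_("trnR"), p("ND4L", 294L), p("ND4", 1380L),
    t_("trnH"), t_("trnS1"), t_("trnL1"),
    p("ND5", 1812L), list("ND6", "protein", -1L, 519L), t_("trnE", -1L),
    p("CYTB", 1140L), t_("trnT"),
    list("IGS", "spacer", 1L, igs_length), t_("trnP", -1L),
    list("CR", "control_region", 1L, cr_length))
  df <- do.call(rbind, lapply(spec, function(x) {
    data.frame(label = x[[1]], feature_class = x[[2]], strand = x[[3]],
               length = x[[4]], stringsAsFactors = FALSE)
  }))
  if (randomize) {
    pr <- df$feature_class == "protein"
    df$length[pr] <- 3L * as.integer(round(runif(sum(pr), 100, 600)))
    rr <- df$feature_class == "rRNA"
    df$length[rr] <- as.integer(round(runif(sum(rr), 800, 1700)))
    tr <- df$feature_class == "tRNA"
    df$length[tr] <- as.integer(round(runif(sum(tr), 65, 75)))
  }
  df
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "AGA", "AGG"))
})

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG",
         paste(sample(setdiff(NON_STOP_CODONS, c("ATG", "ATA", "GTG")),
                      len %/% 3L - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

#' Build a simulated annotated reference mitogenome
#'
#' Generates a circular genome whose segments tile the circle exactly:
#' every protein gene is a valid ORF under the vertebrate mitochondrial
#' code (start codon, no internal in-frame stop, terminal stop);
#' minus-strand genes are stored reverse-complemented on the genomic
#' strand. Deterministic for a given seed.
#'
#' @param spec A [genome_spec()] layout.
#' @param seed Integer seed (set when not `NULL`).
#' @param seq_id Identifier for the genome.
#' @return A `sim_genome`: list with `seq_id`, `circular` and a `segments`
#'   data frame (`label`, `feature_class`, `strand`, `paralog_tag`,
#'   `status`, `seq`).
#' @export
make_reference_genome <- function(spec = genome_spec(), seed = NULL,
                                  seq_id = "mito_sim") {
  if (!is.null(seed)) set.seed(seed)
  seqs <- character(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    seqs[[i]] <- if (spec$feature_class[i] == "protein") {
      cds <- rand_cds(spec$length[i])
      if (spec$strand[i] < 0L) revcomp(cds) else cds
    } else {
      rand_dna(spec$length[i])
    }
  }
  structure(list(seq_id = seq_id, circular = TRUE,
                 segments = data.frame(label = spec$label,
                                       feature_class = spec$feature_class,
                                       strand = spec$strand,
                                       paralog_tag = NA_character_,
                                       status = "intact",
                                       seq = seqs,
                                       stringsAsFactors = FALSE)),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %d bp, %d segments (%d genes)\n", x$seq_id,
              genome_length(x), nrow(x$segments),
              sum(x$segments$feature_class %in% c("protein", "rRNA", "tRNA"))))
  invisible(x)
}

#' @rdname make_reference_genome
#' @param sim A `sim_genome`.
#' @export
genome_sequence <- function(sim) paste(sim$segments$seq, collapse = "")

#' @rdname make_reference_genome
#' @export
genome_length <- function(sim) sum(nchar(sim$segments$seq))

#' Convert a simulated genome to I/O types
#'
#' @param sim A `sim_genome`.
#' @return `as_seq_record()` gives a [seq_record]; `as_feature_table()` a
#'   `feature_table` with cumulative 0-based half-open coordinates.
#' @export
as_seq_record <- function(sim) seq_record(sim$seq_id, genome_sequence(sim),
                                          circular = sim$circular)

#' @rdname as_seq_record
#' @export
as_feature_table <- function(sim) {
  lens <- nchar(sim$segments$seq)
  ends <- cumsum(lens)
  feature_table(sim$seq_id, sim$segments$label, sim$segments$feature_class,
                ends - lens, ends, sim$segments$strand,
                sim$segments$paralog_tag)
}

#' @rdname as_seq_record
#' @param drop_labels Labels excluded from the gene order (unrecognizable
#'   repeat tracts).
#' @export
sim_gene_order <- function(sim, drop_labels = character()) {
  extract_gene_order(as_feature_table(sim), genome_length(sim),
                     circular = sim$circular, drop_labels = drop_labels)
}

#' Locate a contiguous run of segment labels
#'
#' @param sim A `sim_genome`.
#' @param labels Character vector of consecutive segment labels; the run
#'   may wrap the origin of a circular genome.
#' @param paralog_tag Optional tag the first matched segment must carry.
#' @return Integer vector of segment indices.
#' @export
find_span <- function(sim, labels, paralog_tag = NULL) {
  n <- nrow(sim$segments)
  k <- length(labels)
  for (s in seq_len(n)) {
    idx <- ((s - 1L + seq_len(k) - 1L) %% n) + 1L
    if (!sim$circular && any(diff(idx) != 1L)) next
    if (identical(sim$segments$label[idx], labels) &&
        (is.null(paralog_tag) ||
         identical(sim$segments$paralog_tag[idx[[1L]]], paralog_tag))) {
      return(idx)
    }
  }
  stop("no contiguous segment run matching: ", paste(labels, collapse = ", "))
}

#' Tandem duplication of a contiguous span
#'
#' Inserts a copy of the span immediately after itself; the originals are
#' tagged `copy1`, the new copies `copy2`. Genome length grows by exactly
#' the span's length in bp.
#'
#' @param sim A `sim_genome`.
#' @param span Character vector of consecutive segment labels, or integer
#'   segment indices.
#' @return List with the new `genome` and a `truth` event record.
#' @export
apply_duplication <- function(sim, span) {
  idx <- if (is.character(span)) find_span(sim, span) else as.integer(span)
  shift <- 0L
  if (any(diff(idx) != 1L)) {
    # wrapped run on a circular genome: rotate so the span is contiguous
    if (!sim$circular) stop("span is not contiguous")
    shift <- idx[[1L]] - 1L
    n <- nrow(sim$segments)
    sim$segments <- sim$segments[((seq_len(n) - 1L + shift) %% n) + 1L, ,
                                 drop = FALSE]
    rownames(sim$segments) <- NULL
    idx <- seq_along(idx)
  }
  seg <- sim$segments
  dup <- seg[idx, , drop = FALSE]
  seg$paralog_tag[idx] <- "copy1"
  dup$paralog_tag <- "copy2"
  sim$segments <- rbind(seg[seq_len(max(idx)), , drop = FALSE], dup,
                        if (max(idx) < nrow(seg))
                          seg[(max(idx) + 1L):nrow(seg), , drop = FALSE])
  rownames(sim$segments) <- NULL
  truth <- list(type = "duplication", start_index = idx[[1L]],
                length = length(idx), shift = shift,
                span_labels = dup$label,
                span_bp = sum(nchar(dup$seq)))
  list(genome = sim, truth = truth)
}

#' Mutation process parameters
#'
#' @param sub_rate Per-site substitution probability (replacement uniform
#'   over the three other bases).
#' @param indel_rate Expected indel events per site (Poisson).
#' @param indel_mean Mean indel length (geometric, support 1,2,...).
#' @param seed Optional seed consumed when the parameters are used.
#' @return A `mutation_params` list.
#' @export
mutation_params <- function(sub_rate = 0.02, indel_rate = 0.002,
                            indel_mean = 2, seed = NULL) {
  stopifnot(sub_rate >= 0, indel_rate >= 0, indel_mean >= 1)
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_mean = indel_mean, seed = seed),
            class = "mutation_params")
}

# apply a sequential edit list to a sequence; each row's position refers to
# the sequence state at application time
apply_edit_list <- function(seq, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(seq)
  for (e in seq_len(nrow(edits))) {
    kind <- edits$kind[e]; pos <- edits$pos[e]
    if (kind == "sub") {
      if (substr(seq, pos, pos) != edits$ref[e]) {
        stop("substitution ref mismatch at ", pos)
      }
      substr(seq, pos, pos) <- edits$alt[e]
    } else if (kind == "ins") {
      seq <- paste0(substr(seq, 1L, pos), edits$alt[e],
                    substr(seq, pos + 1L, nchar(seq)))
    } else if (kind == "del") {
      len <- nchar(edits$ref[e])
      if (substr(seq, pos, pos + len - 1L) != edits$ref[e]) {
        stop("deletion ref mismatch at ", pos)
      }
      seq <- paste0(substr(seq, 1L, pos - 1L),
                    substr(seq, pos + len, nchar(seq)))
    } else stop("unknown edit kind '", kind, "'")
  }
  seq
}

edit_row <- function(kind, pos, ref = "", alt = "") {
  data.frame(kind = kind, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

empty_edits <- function() {
  data.frame(kind = character(0), pos = integer(0), ref = character(0),
             alt = character(0), stringsAsFactors = FALSE)
}

#' Evolve target segments under a substitution/indel process
#'
#' Substitutions are Bernoulli per site at `sub_rate` with the replacement
#' base uniform over the three alternatives (the Jukes-Cantor process at
#' small divergence); indel events are Poisson at `indel_rate` per site
#' with geometric lengths. Every edit is recorded so the event can be
#' replayed exactly; coordinates of downstream segments need no adjustment
#' because the genome is stored segment-wise.
#'
#' @param sim A `sim_genome`.
#' @param params [mutation_params()].
#' @param targets Integer indices of the segments to evolve.
#' @return List with the new `genome` and a `truth` event carrying the
#'   per-segment edit lists and planted counts.
#' @export
evolve <- function(sim, params = mutation_params(), targets) {
  if (!is.null(params$seed)) set.seed(params$seed)
  targets <- as.integer(targets)
  stopifnot(all(targets >= 1L), all(targets <= nrow(sim$segments)))
  per_segment <- list()
  for (i in targets) {
    seqi <- sim$segments$seq[i]
    L <- nchar(seqi)
    chars <- strsplit(seqi, "", fixed = TRUE)[[1]]
    n_sub <- rbinom(1L, L, params$sub_rate)
    sub_pos <- sort(sample.int(L, n_sub))
    edits <- list()
    for (p in sub_pos) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), chars[[p]]), 1L)
      edits[[length(edits) + 1L]] <- edit_row("sub", p, chars[[p]], alt)
    }
    n_ind <- rpois(1L, params$indel_rate * L)
    ins_ev <- 0L; ins_bp <- 0L; del_ev <- 0L; del_bp <- 0L
    seq_now <- apply_edit_list(seqi, if (length(edits))
      do.call(rbind, edits) else NULL)
    for (e in seq_len(n_ind)) {
      len <- 1L + rgeom(1L, 1 / params$indel_mean)
      Lnow <- nchar(seq_now)
      if (runif(1) < 0.5) {
        pos <- sample.int(Lnow + 1L, 1L) - 1L
        alt <- rand_dna(len)
        row <- edit_row("ins", pos, "", alt)
        ins_ev <- ins_ev + 1L; ins_bp <- ins_bp + len
      } else {
        if (Lnow <= len) next
        pos <- sample.int(Lnow - len, 1L)
        row <- edit_row("del", pos, substr(seq_now, pos, pos + len - 1L), "")
        del_ev <- del_ev + 1L; del_bp <- del_bp + len
      }
      seq_now <- apply_edit_list(seq_now, row)
      edits[[length(edits) + 1L]] <- row
    }
    edits <- if (length(edits)) do.call(rbind, edits) else
      empty_edits()
    sim$segments$seq[i] <- seq_now
    per_segment[[as.character(i)]] <- list(
      segment_index = i, label = sim$segments$label[i],
      edits = edits,
      substitutions = n_sub, insertion_events = ins_ev, insertion_bp = ins_bp,
      deletion_events = del_ev, deletion_bp = del_bp)
  }
  list(genome = sim,
       truth = list(type = "evolve", per_segment = per_segment))
}

#' Apply a deterministic edit list to one segment
#'
#' Used to plant exact published edit counts (e.g. pseudogene decay with a
#' known number of substitutions); records the same event structure as
#' [evolve()].
#'
#' @param sim A `sim_genome`.
#' @param index Segment index.
#' @param edits Sequential edit data frame (`kind`, `pos`, `ref`, `alt`).
#' @param mark_pseudogene Also set the segment's class to `pseudogene`.
#' @return List with `genome` and `truth`.
#' @export
edit_segment <- function(sim, index, edits, mark_pseudogene = FALSE) {
  sim$segments$seq[index] <- apply_edit_list(sim$segments$seq[index], edits)
  if (mark_pseudogene) {
    sim$segments$feature_class[index] <- "pseudogene"
    sim$segments$status[index] <- "pseudogene"
  }
  cnt <- table(factor(edits$kind, levels = c("sub", "ins", "del")))
  list(genome = sim,
       truth = list(type = "evolve", per_segment = setNames(list(list(
         segment_index = index, label = sim$segments$label[index],
         edits = edits,
         substitutions = unname(cnt[["sub"]]),
         insertion_events = unname(cnt[["ins"]]),
         insertion_bp = sum(nchar(edits$alt[edits$kind == "ins"])),
         deletion_events = unname(cnt[["del"]]),
         deletion_bp = sum(nchar(edits$ref[edits$kind == "del"])))),
         as.character(index))))
}

#' Excise a genomic region
#'
#' Removes the bases in `region` (0-based half-open, non-wrapping).
#' Segments that fall entirely inside the region are deleted; segments
#' partially overlapping it are truncated and, when they are genes, marked
#' as pseudogene candidates. A zero-length region is the identity.
#'
#' @param sim A `sim_genome`.
#' @param region `c(start, end)` in bp on the current genome.
#' @return List with `genome` and a `truth` event recording the
#'   per-segment actions.
#' @export
apply_segmental_deletion <- function(sim, region) {
  L <- genome_length(sim)
  start <- region[[1L]]; end <- region[[2L]]
  if (start < 0L || end > L || end < start) stop("region outside genome")
  if (end - start >= L) stop("cannot delete the whole genome")
  if (end == start) {
    return(list(genome = sim,
                truth = list(type = "deletion", region = region,
                             actions = list())))
  }
  lens <- nchar(sim$segments$seq)
  seg_end <- cumsum(lens)
  seg_start <- seg_end - lens
  actions <- list()
  drop <- logical(nrow(sim$segments))
  for (i in seq_len(nrow(sim$segments))) {
    os <- max(start, seg_start[i]); oe <- min(end, seg_end[i])
    if (oe <= os) next
    if (os == seg_start[i] && oe == seg_end[i]) {
      drop[i] <- TRUE
      actions[[length(actions) + 1L]] <- list(segment_index = i,
                                              label = sim$segments$label[i],
                                              action = "deleted")
    } else {
      rel_s <- os - seg_start[i] + 1L
      rel_e <- oe - seg_start[i]
      sim$segments$seq[i] <- paste0(
        substr(sim$segments$seq[i], 1L, rel_s - 1L),
        substr(sim$segments$seq[i], rel_e + 1L, lens[i]))
      if (sim$segments$feature_class[i] %in% c("protein", "rRNA", "tRNA")) {
        sim$segments$feature_class[i] <- "pseudogene"
      }
      sim$segments$status[i] <- "pseudogene_candidate"
      actions[[length(actions) + 1L]] <- list(
        segment_index = i, label = sim$segments$label[i],
        action = "truncated", removed = c(rel_s, rel_e))
    }
  }
  sim$segments <- sim$segments[!drop, , drop = FALSE]
  rownames(sim$segments) <- NULL
  list(genome = sim,
       truth = list(type = "deletion", region = c(start, end),
                    actions = actions))
}

#' Delete whole segments by index
#'
#' Convenience wrapper over [apply_segmental_deletion()] translating
#' segment indices into bp regions (one event per contiguous run,
#' processed right to left so earlier coordinates stay valid).
#'
#' @param sim A `sim_genome`.
#' @param idx Integer segment indices to remove.
#' @return List with `genome` and a list of `truth` events.
#' @export
delete_segments <- function(sim, idx) {
  idx <- sort(unique(as.integer(idx)))
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  events <- list()
  for (r in rev(runs)) {
    lens <- nchar(sim$segments$seq)
    seg_end <- cumsum(lens)
    seg_start <- seg_end - lens
    out <- apply_segmental_deletion(sim, c(seg_start[r[[1L]]],
                                           seg_end[r[[length(r)]]]))
    sim <- out$genome
    events[[length(events) + 1L]] <- out$truth
  }
  list(genome = sim, truth = events)
}

#' Replay recorded events on an ancestral genome
#'
#' Applies a list of truth events (duplication, evolve, deletion) to the
#' ancestral genome; the result must reproduce the final genome
#' byte-for-byte, which is the simulator's core bookkeeping invariant.
#'
#' @param sim The ancestral `sim_genome`.
#' @param events List of truth events as produced by the simulator
#'   operations.
#' @return The replayed `sim_genome`.
#' @export
truth_replay <- function(sim, events) {
  for (ev in events) {
    sim <- switch(ev$type,
      duplication = {
        if (!is.null(ev$shift) && ev$shift > 0L) {
          n <- nrow(sim$segments)
          sim$segments <- sim$segments[((seq_len(n) - 1L + ev$shift) %% n) + 1L, ,
                                       drop = FALSE]
          rownames(sim$segments) <- NULL
        }
        idx <- ev$start_index + seq_len(ev$length) - 1L
        apply_duplication(sim, idx)$genome
      },
      evolve = {
        for (ps in ev$per_segment) {
          sim$segments$seq[ps$segment_index] <-
            apply_edit_list(sim$segments$seq[ps$segment_index], ps$edits)
        }
        sim
      },
      deletion = apply_segmental_deletion(sim, ev$region)$genome,
      relabel = {
        sim$segments$label[ev$segment_index] <- ev$label
        sim$segments$feature_class[ev$segment_index] <- ev$feature_class
        sim
      },
      stop("unknown event type '", ev$type, "'"))
  }
  sim
}
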