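#' Plant deterministic edits into a sequence
#'
#' Applies a chosen set of substitutions, insertions and deletions to a
#' sequence and returns the mutated copy together with the true alignment
#' (built by replaying the edits, bypassing any aligner) and the edit
#' counts. All edits must be disjoint: substitution positions distinct and
#' outside deletions; deletion ranges disjoint; insertion anchors distinct
#' and outside deletions.
#'
#' @param seq Gap-free nucleotide string (the reference).
#' @param sub_pos Integer positions to substitute (1-based).
#' @param sub_alt Optional replacement bases (sampled uniformly from the
#'   three alternatives when `NULL`).
#' @param ins List of insertions, each `list(pos =, len =)` or
#'   `list(pos =, seq =)`; `pos` is the reference position after which the
#'   bases are inserted (0 allowed).
#' @param del List of deletions, each `list(pos =, len =)`.
#' @return List with `query` (the mutated sequence), `alignment` (a
#'   `pairwise_alignment` with the reference on top), `edits` (sequential
#'   edit data frame usable with [edit_segment()]), and `counts`.
#' @export
plant_edits <- function(seq, sub_pos = integer(), sub_alt = NULL,
                        ins = list(), del = list()) {
  r <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(r)
  sub_pos <- as.integer(sub_pos)
  stopifnot(!anyDuplicated(sub_pos), all(sub_pos >= 1L), all(sub_pos <= L))
  del_cover <- unlist(lapply(del, function(d) d$pos + seq_len(d$len) - 1L))
  stopifnot(!anyDuplicated(del_cover), all(del_cover <= L),
            !any(sub_pos %in% del_cover))
  ins_anchor <- vapply(ins, function(x) as.integer(x$pos), integer(1))
  stopifnot(!anyDuplicated(ins_anchor), all(ins_anchor >= 0L),
            all(ins_anchor <= L), !any(ins_anchor %in% del_cover))
  if (is.null(sub_alt)) {
    sub_alt <- vapply(sub_pos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"), r[[p]]), 1L)
    }, character(1))
  }
  ins_seq <- lapply(ins, function(x) {
    if (!is.null(x$seq)) toupper(x$seq) else rand_dna(x$len)
  })

  q <- r
  q[sub_pos] <- sub_alt
  q[del_cover] <- "-"
  ins_at <- setNames(ins_seq, as.character(ins_anchor))
  row_ref <- character(); row_qry <- character()
  emit_ins <- function(p) {
    s <- ins_at[[as.character(p)]]
    if (!is.null(s)) {
      row_ref <<- c(row_ref, strsplit(strrep("-", nchar(s)), "")[[1]])
      row_qry <<- c(row_qry, strsplit(s, "")[[1]])
    }
  }
  emit_ins(0L)
  for (p in seq_len(L)) {
    row_ref <- c(row_ref, r[[p]])
    row_qry <- c(row_qry, q[[p]])
    emit_ins(p)
  }
  aln <- pairwise_alignment(paste(row_ref, collapse = ""),
                            paste(row_qry, collapse = ""))
  query <- gsub("-", "", aln$row_qry, fixed = TRUE)

  # sequential edit list: substitutions first (positions unchanged), then
  # indels right-to-left so earlier coordinates stay valid
  edits <- list()
  for (i in seq_along(sub_pos)) {
    edits[[length(edits) + 1L]] <-
      edit_row("sub", sub_pos[[i]], r[[sub_pos[[i]]]], sub_alt[[i]])
  }
  indels <- c(lapply(seq_along(ins), function(i) {
    list(kind = "ins", pos = ins_anchor[[i]], ref = "", alt = ins_seq[[i]])
  }), lapply(del, function(d) {
    list(kind = "del", pos = d$pos,
         ref = substr(seq, d$pos, d$pos + d$len - 1L), alt = "")
  }))
  if (length(indels)) {
    ord <- order(vapply(indels, `[[`, numeric(1), "pos"), decreasing = TRUE)
    for (x in indels[ord]) {
      edits[[length(edits) + 1L]] <- edit_row(x$kind, x$pos, x$ref, x$alt)
    }
  }
  edits <- if (length(edits)) do.call(rbind, edits) else
    empty_edits()
  counts <- list(substitutions = length(sub_pos),
                 insertion_events = length(ins),
                 insertion_bp = sum(vapply(ins_seq, nchar, integer(1))),
                 deletion_events = length(del),
                 deletion_bp = length(del_cover))
  list(query = query, alignment = aln, edits = edits, counts = counts)
}

#' Draw well-separated random edit positions
#'
#' Chooses substitution positions and indel placements so that no two
#' edits are closer than `min_gap` bp — alignment of such planted edits is
#' unambiguous and their counts are recoverable exactly.
#'
#' @param L Reference length.
#' @param n_sub Number of substitutions.
#' @param ins_lens,del_lens Integer vectors of indel lengths.
#' @param min_gap Minimum distance between any two edits.
#' @return Arguments for [plant_edits()] (`sub_pos`, `ins`, `del`).
#' @export
random_planted_edits <- function(L, n_sub, ins_lens = integer(),
                                 del_lens = integer(), min_gap = 3L) {
  taken <- logical(L)
  block <- function(lo, hi) {
    lo <- max(1L, lo); hi <- min(L, hi)
    if (hi >= lo) taken[lo:hi] <<- TRUE
  }
  pick_range <- function(len) {
    for (try in 1:500) {
      p <- sample.int(L - len, 1L)
      if (!any(taken[max(1L, p - min_gap):min(L, p + len + min_gap)])) {
        block(p - min_gap, p + len + min_gap)
        return(p)
      }
    }
    stop("could not place edits with the requested separation")
  }
  del <- lapply(as.integer(del_lens), function(len) {
    list(pos = pick_range(len), len = len)
  })
  ins <- lapply(as.integer(ins_lens), function(len) {
    list(pos = pick_range(1L), len = len)
  })
  sub_pos <- integer()
  for (i in seq_len(n_sub)) sub_pos <- c(sub_pos, pick_range(1L))
  list(sub_pos = sub_pos, ins = ins, del = del)
}

#' Evolve a sequence along a branch under the Jukes-Cantor model
#'
#' Each site changes with the exact JC transition probability
#' `3/4 (1 - exp(-4 d / 3))` for branch length `d` substitutions per site,
#' with the replacement base uniform over the three alternatives. Branch
#' lengths are additive, so two sequences evolved `d/2` from a common
#' ancestor sit at JC distance `d` in expectation.
#'
#' @param seq Nucleotide string.
#' @param d Branch length (substitutions per site).
#' @return The evolved sequence.
#' @export
evolve_jc <- function(seq, d) {
  stopifnot(d >= 0)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(chars)) < p)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[i]]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate two haplotype groups at a planted divergence
#'
#' Builds a random ancestor and evolves one representative per group along
#' a `d/2` branch under JC; individuals within a group share the haplotype
#' (the setting of two mitochondrial gene-order haplotypes segregating
#' within one species).
#'
#' @param d Planted between-group JC distance.
#' @param L Sequence length (sites).
#' @param n_per_group Individuals per group.
#' @param seed Optional integer seed.
#' @return List with character vectors `group_a`, `group_b`.
#' @export
sim_divergent_groups <- function(d = 0.024, L = 10000L, n_per_group = 2L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- rand_dna(L)
  a <- evolve_jc(anc, d / 2)
  b <- evolve_jc(anc, d / 2)
  list(group_a = rep(a, n_per_group), group_b = rep(b, n_per_group))
}

#' Generate a random single-DRL test case
#'
#' Draws a random circular gene order, a random contiguous span, and a
#' random per-position retention pattern (each span gene survives in the
#' first copy, the second, or both; surviving copies may decay to marked
#' pseudogenes), then replays the event forward.
#'
#' @param n_genes Number of ancestral elements.
#' @param circular Logical.
#' @param pseudo_prob Probability that a surviving duplicate copy carries a
#'   pseudogene mark.
#' @param repeat_prob Probability of drawing labels with repeats (paralogs
#'   already present ancestrally).
#' @return List with `ancestral`, `derived`, `span_start`, `span_length`,
#'   and the retention pattern used.
#' @export
random_drl_case <- function(n_genes = 6L, circular = TRUE,
                            pseudo_prob = 0.15, repeat_prob = 0.2) {
  labels <- paste0("g", seq_len(n_genes))
  if (runif(1) < repeat_prob && n_genes >= 3L) {
    labels[[n_genes]] <- labels[[1L]]
  }
  strands <- sample(c(-1L, 1L), n_genes, replace = TRUE)
  anc <- gene_order(labels, strands, circular = circular)
  k <- sample.int(n_genes, 1L)
  s <- if (circular) sample.int(n_genes, 1L) else
    sample.int(n_genes - k + 1L, 1L)
  retention <- sample(c("first", "second", "both"), k, replace = TRUE)
  in1 <- retention %in% c("first", "both")
  in2 <- retention %in% c("second", "both")
  ps1 <- in1 & runif(k) < pseudo_prob & retention == "both"
  ps2 <- in2 & runif(k) < pseudo_prob & retention == "both" & !ps1
  der <- drl_apply(anc, s, k, in1, in2, ps1, ps2)
  list(ancestral = anc, derived = der, span_start = s, span_length = k,
       retention = retention)
}

# targeted substitution set creating one in-frame stop codon; returns
# coding-orientation positions/alts for n_sub total substitutions
plan_protein_decay_subs <- function(coding, n_sub) {
  L <- nchar(coding)
  ncod <- L %/% 3L
  codons <- substring(coding, 3L * (seq_len(ncod) - 1L) + 1L,
                      3L * seq_len(ncod))
  # interior codon one substitution away from TAA
  cand <- which(codons %in% c("TAC", "TAT", "CAA", "GAA", "TCA", "TGA",
                              "AAA", "TAC"))
  cand <- cand[cand > 5L & cand < ncod - 1L]
  stop_edit <- NULL
  if (length(cand)) {
    j <- cand[[ceiling(length(cand) / 2)]]
    cd <- codons[[j]]
    off_alt <- if (cd %in% c("TAC", "TAT")) c(3L, "A")
      else if (cd %in% c("CAA", "GAA", "AAA")) c(1L, "T")
      else if (cd == "TCA") c(2L, "A")
      else c(2L, "A")  # TGA -> TAA
    pos <- 3L * (j - 1L) + as.integer(off_alt[[1L]])
    stop_edit <- list(pos = pos, alt = off_alt[[2L]])
  }
  n_rand <- n_sub - as.integer(!is.null(stop_edit))
  forbidden <- if (is.null(stop_edit)) integer() else stop_edit$pos
  pool <- setdiff(seq(4L, L - 3L), forbidden)
  pos <- sort(c(sample(pool, n_rand), forbidden))
  alts <- vapply(pos, function(p) {
    if (!is.null(stop_edit) && p == stop_edit$pos) return(stop_edit$alt)
    sample(setdiff(c("A", "C", "G", "T"), substr(coding, p, p)), 1L)
  }, character(1))
  list(pos = pos, alt = alts)
}

# convert coding-orientation edits (from plant_edits) to genomic-strand
# coordinates for a minus-strand segment of original length L
flip_edits <- function(edits, L) {
  comp <- function(s) chartr("ACGTN", "TGCAN", s)
  out <- edits
  for (i in seq_len(nrow(edits))) {
    if (edits$kind[i] == "sub") {
      out$pos[i] <- L - edits$pos[i] + 1L
      out$ref[i] <- comp(edits$ref[i])
      out$alt[i] <- comp(edits$alt[i])
    } else if (edits$kind[i] == "ins") {
      out$pos[i] <- L - edits$pos[i]
      out$alt[i] <- revcomp(edits$alt[i])
    } else {
      len <- nchar(edits$ref[i])
      out$pos[i] <- L - (edits$pos[i] + len - 1L) + 1L
      out$ref[i] <- revcomp(edits$ref[i])
    }
  }
  # re-order: substitutions first, indels right-to-left in genomic coords
  subs <- out[out$kind == "sub", , drop = FALSE]
  ind <- out[out$kind != "sub", , drop = FALSE]
  rbind(subs, ind[order(ind$pos, decreasing = TRUE), , drop = FALSE])
}
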