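# Independent oracles used across the suite. These deliberately use naive
# exhaustive strategies (full enumeration, plain recursion) so they share no
# code path with the implementations they check.

# exhaustive global affine-gap alignment score by depth-first enumeration of
# all alignments (feasible for sequences up to ~8 bp)
bf_align_score <- function(a, b, sc = scoring_scheme()) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(ca); lb <- length(cb)
  rec <- function(i, j, last) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la && j < lb) {
      s <- if (ca[[i + 1L]] == cb[[j + 1L]] && ca[[i + 1L]] != "N") {
        sc$match
      } else sc$mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i < la) {
      open <- if (last == "X") 0 else sc$gap_open
      best <- max(best, open + sc$gap_extend + rec(i + 1L, j, "X"))
    }
    if (j < lb) {
      open <- if (last == "Y") 0 else sc$gap_open
      best <- max(best, open + sc$gap_extend + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(0L, 0L, "M")
}

# position-set signature of a span on an n-element circular order
posset_sig <- function(start, len, n) {
  paste(sort(((start - 1L + seq_len(len) - 1L) %% n) + 1L), collapse = ",")
}

# exhaustive single-DRL oracle: enumerate every span and every per-position
# retention pattern, replay naively, and return the containment-minimal
# span position-set signatures that can reproduce the derived order
oracle_drl_possets <- function(anc, der) {
  n <- length(anc$labels); m <- length(der$labels)
  if (m < n || m > 2L * n) return(character())
  anc_key <- paste0(anc$labels, "/", anc$strands)
  der_key <- paste0(der$labels, "/", der$strands)
  hits <- list()
  for (k in seq_len(n)) {
    q <- m - n + k
    if (q < k || q > 2L * k) next
    starts <- if (anc$circular) seq_len(n) else seq_len(n - k + 1L)
    for (s in starts) {
      sp <- ((s - 1L + seq_len(k) - 1L) %% n) + 1L
      out <- ((s - 1L + k + seq_len(n - k) - 1L) %% n) + 1L
      found <- FALSE
      pats <- expand.grid(rep(list(1:3), k))
      for (pi in seq_len(nrow(pats))) {
        pat <- as.integer(pats[pi, ])
        in1 <- pat %in% c(1L, 3L); in2 <- pat %in% c(2L, 3L)
        if (anc$circular) {
          idx <- c(sp[in1], sp[in2], out)
          is_out <- c(rep(FALSE, sum(in1) + sum(in2)), rep(TRUE, n - k))
        } else {
          pre <- seq_len(s - 1L)
          post <- if (s + k <= n) (s + k):n else integer()
          idx <- c(pre, sp[in1], sp[in2], post)
          is_out <- c(rep(TRUE, length(pre)),
                      rep(FALSE, sum(in1) + sum(in2)),
                      rep(TRUE, length(post)))
        }
        if (length(idx) != m) next
        keys <- anc_key[idx]
        out_pseudo <- ifelse(is_out, anc$pseudo[idx], NA)
        rots <- if (anc$circular) 0:(m - 1L) else 0L
        for (r in rots) {
          rot <- ((r + seq_len(m) - 1L) %% m) + 1L
          if (!identical(der_key[rot], keys)) next
          okp <- all(der$pseudo[rot][is_out] == out_pseudo[is_out])
          if (okp) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) {
        hits[[length(hits) + 1L]] <- list(start = s, len = k)
      }
    }
  }
  if (length(hits) == 0L) return(character())
  sigs <- vapply(hits, function(h) posset_sig(h$start, h$len, n), character(1))
  sets <- lapply(hits, function(h) {
    sort(((h$start - 1L + seq_len(h$len) - 1L) %% n) + 1L)
  })
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      i != j && length(sets[[j]]) < length(sets[[i]]) &&
        all(sets[[j]] %in% sets[[i]])
    }, logical(1)))
  }, logical(1))
  unique(sigs[keep])
}

# span signatures actually reported by the implementation
impl_drl_possets <- function(scenarios, n) {
  if (length(scenarios) == 0L) return(character())
  unique(vapply(scenarios, function(sc) {
    posset_sig(sc$span_start, sc$span_length, n)
  }, character(1)))
}

# exhaustive Fitch oracle: minimum over all internal-node state assignments
# of the number of edges whose endpoints differ
oracle_fitch_min <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  levs <- sort(unique(unname(states[tree$tip.label])))
  node_state <- character(ntip + nnode)
  node_state[seq_len(ntip)] <- unname(states[tree$tip.label])
  grid <- expand.grid(rep(list(levs), nnode), stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    node_state[(ntip + 1L):(ntip + nnode)] <- as.character(grid[g, ])
    ch <- sum(node_state[tree$edge[, 1L]] != node_state[tree$edge[, 2L]])
    best <- min(best, ch)
  }
  best
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# thin wrappers over internal simulator helpers used as fixtures
rand_cds_for_test <- function(L) mitodrl:::rand_cds(L)
plan_stop_subs_for_test <- function(coding, n) {
  mitodrl:::plan_protein_decay_subs(coding, n)
}

# random rooted binary tree with simple tip labels
random_tree <- function(ntips) {
  tr <- ape::rtree(ntips, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(ntips))
  tr
}

# the study topology: two outgroup taxa, aeneus sister to the rest, hardii
# (four individuals, two per gene-order haplotype, clustered by population)
# sister to the coastal clade
study_tree <- function() {
  ape::read.tree(text = paste0(
    "((Desmognathus,Phaeognathus),(aeneus,(((hardii_RAC27,hardii_RAC28),",
    "(hardii_RAC20,hardii_RAC25)),(lugubris,(flavipunctatus,",
    "(ferreus,vagrans))))));"))
}

study_states <- function() {
  c(Desmognathus = "typical_vertebrate", Phaeognathus = "typical_vertebrate",
    aeneus = "aneides_order", hardii_RAC27 = "aneides_order",
    hardii_RAC28 = "aneides_order", hardii_RAC20 = "hardii_duplicated",
    hardii_RAC25 = "hardii_duplicated", lugubris = "aneides_order",
    flavipunctatus = "aneides_order", ferreus = "aneides_order",
    vagrans = "aneides_order")
}
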