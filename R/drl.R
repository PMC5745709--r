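#' Replay a duplication-random-loss event on a gene order
#'
#' Applies the DRL mechanism forward: a contiguous arc (the span) is
#' duplicated in tandem, then per-copy losses are applied. The surviving
#' arrangement reads the retained elements of the first copy in span order,
#' then the retained elements of the second copy, followed by the genes
#' outside the span.
#'
#' @param ancestral A [gene_order].
#' @param span_start 1-based index of the first span element in `ancestral`.
#' @param span_length Number of span elements (1..length of order).
#' @param copy1_keep,copy2_keep Logical vectors (length `span_length`):
#'   which span positions survive in the first/second copy.
#' @param copy1_pseudo,copy2_pseudo Logical vectors: surviving copies that
#'   have decayed to recognizable pseudogenes.
#' @return The derived [gene_order].
#' @export
drl_apply <- function(ancestral, span_start, span_length,
                      copy1_keep, copy2_keep,
                      copy1_pseudo = rep(FALSE, span_length),
                      copy2_pseudo = rep(FALSE, span_length)) {
  n <- length(ancestral$labels)
  if (span_length < 1L || span_length > n) stop("invalid span length")
  if (!ancestral$circular && span_start + span_length - 1L > n) {
    stop("span runs off a linear order")
  }
  if (any(!(copy1_keep | copy2_keep))) {
    stop("every span position must retain at least one copy")
  }
  sp <- ((span_start - 1L + seq_len(span_length) - 1L) %% n) + 1L
  idx1 <- sp[copy1_keep]; idx2 <- sp[copy2_keep]
  if (ancestral$circular) {
    # build from the span onwards; a rotation of the true circle, which is
    # the same circular order
    pre <- integer()
    post <- ((span_start - 1L + span_length +
                seq_len(n - span_length) - 1L) %% n) + 1L
  } else {
    pre <- seq_len(span_start - 1L)
    post <- if (span_start + span_length <= n)
      (span_start + span_length):n else integer()
  }
  gene_order(c(ancestral$labels[pre], ancestral$labels[idx1],
               ancestral$labels[idx2], ancestral$labels[post]),
             c(ancestral$strands[pre], ancestral$strands[idx1],
               ancestral$strands[idx2], ancestral$strands[post]),
             c(ancestral$pseudo[pre], copy1_pseudo[copy1_keep],
               copy2_pseudo[copy2_keep], ancestral$pseudo[post]),
             ancestral$circular)
}

# strictly-increasing position assignments of `keys` onto span positions
# (matching span_keys), positions > nothing repeated; returns list of
# integer vectors (possibly empty list when no assignment exists)
assign_ascending <- function(keys, span_keys) {
  k <- length(span_keys)
  res <- list()
  rec <- function(i, lastp, acc) {
    if (i > length(keys)) {
      res[[length(res) + 1L]] <<- acc
      return(invisible())
    }
    cand <- which(span_keys == keys[[i]])
    for (p in cand[cand > lastp]) rec(i + 1L, p, c(acc, p))
  }
  rec(1L, 0L, integer())
  res
}

#' Infer single duplication-random-loss scenarios
#'
#' Finds every containment-minimal contiguous arc of the ancestral order
#' whose tandem duplication, followed by per-copy losses, reproduces the
#' derived order exactly. The derived arrangement of span-gene copies must
#' read as the survivors of the first copy in span order followed by the
#' survivors of the second copy; every span gene must survive in at least
#' one copy. Pseudogene-marked elements in the derived order are treated
#' as retained-but-decayed (remnant) copies. Strand changes are never
#' produced by DRL, so any strand difference rejects a scenario.
#'
#' An empty result means no single DRL event explains the derivation.
#'
#' @param ancestral,derived [gene_order] objects (both circular or both
#'   linear). Pseudogene elements already present in the ancestral order
#'   (from earlier events) are matched as-is outside the span.
#' @return List of scenarios, each a list with elements `span_start`,
#'   `span_length`, `span_labels`, `retention` (per span position, one of
#'   `"first"`, `"second"`, `"both"`, `"remnant"`), `copies` (data frame of
#'   surviving copies with pseudogene flags) and `identity_consistent`.
#' @export
infer_single_drl <- function(ancestral, derived) {
  if (ancestral$circular != derived$circular) {
    stop("ancestral and derived must both be circular or both linear")
  }
  missing <- setdiff(unique(derived$labels), unique(ancestral$labels))
  if (length(missing)) {
    stop("label(s) present in derived but absent in ancestral: ",
         paste(missing, collapse = ", "))
  }
  n <- length(ancestral$labels)
  m <- length(derived$labels)
  if (m < n || m > 2L * n) return(list())
  anc_key <- paste0(ancestral$labels, "/", ancestral$strands)
  der_key <- paste0(derived$labels, "/", derived$strands)
  identity_consistent <- orders_equivalent(ancestral, derived)

  scenarios <- list()
  seen <- character()
  add_scenario <- function(s, k, sp_idx, in1, ps1, in2, ps2) {
    sig <- paste(s, k, paste(in1, ps1, in2, ps2, collapse = ";"))
    if (sig %in% seen) return(invisible())
    replay <- drl_apply(ancestral, s, k, in1, in2,
                        ifelse(in1, ps1, FALSE), ifelse(in2, ps2, FALSE))
    if (!orders_equivalent(replay, derived)) return(invisible())
    seen <<- c(seen, sig)
    retention <- vapply(seq_len(k), function(p) {
      if (in1[p] && in2[p]) return("both")
      if (in1[p]) return(if (ps1[p]) "remnant" else "first")
      if (ps2[p]) "remnant" else "second"
    }, character(1))
    copies <- data.frame(
      position = rep(seq_len(k), times = in1 + in2),
      copy = unlist(lapply(seq_len(k), function(p) {
        c(if (in1[p]) 1L, if (in2[p]) 2L)
      })),
      pseudo = unlist(lapply(seq_len(k), function(p) {
        c(if (in1[p]) ps1[p], if (in2[p]) ps2[p])
      })))
    scenarios[[length(scenarios) + 1L]] <<- list(
      span_start = s, span_length = k,
      span_labels = ancestral$labels[sp_idx],
      retention = retention, copies = copies,
      identity_consistent = identity_consistent)
    invisible()
  }

  for (k in seq_len(n)) {
    q <- m - n + k
    if (q < k || q > 2L * k) next
    starts <- if (ancestral$circular) seq_len(n) else seq_len(n - k + 1L)
    for (s in starts) {
      sp_idx <- ((s - 1L + seq_len(k) - 1L) %% n) + 1L
      span_keys <- anc_key[sp_idx]
      # candidate placements of the duplicated region inside the derived
      # order; the genes outside the span must flank it unchanged
      placements <- list()
      if (ancestral$circular) {
        out_idx <- ((s - 1L + k + seq_len(n - k) - 1L) %% n) + 1L
        out_keys <- anc_key[out_idx]
        out_pseudo <- ancestral$pseudo[out_idx]
        rot <- if (n - k > 0L) {
          which(der_key == out_keys[[1L]] & derived$pseudo == out_pseudo[[1L]]) - 1L
        } else 0:(m - 1L)
        for (r in rot) {
          if (n - k > 0L) {
            pos <- ((r + seq_len(n - k) - 1L) %% m) + 1L
            if (!identical(der_key[pos], out_keys) ||
                !identical(derived$pseudo[pos], out_pseudo)) {
              next
            }
            placements[[length(placements) + 1L]] <-
              ((r + (n - k) + seq_len(q) - 1L) %% m) + 1L
          } else {
            placements[[length(placements) + 1L]] <-
              ((r + seq_len(q) - 1L) %% m) + 1L
          }
        }
      } else {
        pre <- seq_len(s - 1L)
        suf <- if (s + k <= n) (s + q):m else integer()
        pos <- c(pre, suf)
        out_anc <- c(pre, if (s + k <= n) (s + k):n else integer())
        if (identical(der_key[pos], anc_key[out_anc]) &&
            identical(derived$pseudo[pos], ancestral$pseudo[out_anc])) {
          placements[[1L]] <- s:(s + q - 1L)
        }
      }
      for (reg_pos in placements) {
        reg_keys <- der_key[reg_pos]
        reg_pseudo <- derived$pseudo[reg_pos]
        for (t in 0:q) {
          a1 <- assign_ascending(reg_keys[seq_len(t)], span_keys)
          if (length(a1) == 0L) next
          a2 <- assign_ascending(if (t < q) reg_keys[(t + 1L):q] else character(),
                                 span_keys)
          for (p1 in a1) for (p2 in a2) {
            if (length(union(p1, p2)) != k) next
            in1 <- seq_len(k) %in% p1
            in2 <- seq_len(k) %in% p2
            ps1 <- logical(k); ps2 <- logical(k)
            if (t > 0L) ps1[p1] <- reg_pseudo[seq_len(t)]
            if (q > t) ps2[p2] <- reg_pseudo[(t + 1L):q]
            add_scenario(s, k, sp_idx, in1, ps1, in2, ps2)
          }
        }
      }
    }
  }
  minimal_spans(scenarios, n, circular = ancestral$circular)
}

# circular position set of a span
span_posset <- function(sc, n) {
  sort(((sc$span_start - 1L + seq_len(sc$span_length) - 1L) %% n) + 1L)
}

# keep scenarios whose span does not strictly contain another reported span
minimal_spans <- function(scenarios, n, circular) {
  if (length(scenarios) <= 1L) return(scenarios)
  sets <- lapply(scenarios, span_posset, n = n)
  keep <- vapply(seq_along(scenarios), function(i) {
    !any(vapply(seq_along(scenarios), function(j) {
      i != j && length(sets[[j]]) < length(sets[[i]]) &&
        all(sets[[j]] %in% sets[[i]])
    }, logical(1)))
  }, logical(1))
  scenarios[keep]
}

#' Distinct spans among inferred DRL scenarios
#'
#' @param scenarios Result of [infer_single_drl()].
#' @return Data frame with one row per distinct `(span_start, span_length)`.
#' @export
drl_spans <- function(scenarios) {
  if (length(scenarios) == 0L) {
    return(data.frame(span_start = integer(), span_length = integer()))
  }
  df <- unique(data.frame(
    span_start = vapply(scenarios, `[[`, integer(1), "span_start"),
    span_length = vapply(scenarios, `[[`, integer(1), "span_length")))
  rownames(df) <- NULL
  df
}
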