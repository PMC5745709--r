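#' Construct a gene order
#'
#' A gene order is an ordered sequence of strand-signed gene labels, the
#' unit that the duplication-random-loss algebra acts on. Circular orders
#' compare equal under rotation. Labels may repeat (paralogs, spacers);
#' elements may carry a pseudogene mark.
#'
#' @param labels Character vector of gene labels (e.g. `"ND6"`, `"trnE"`,
#'   `"IGS"`, `"CR"`).
#' @param strands Integer vector of +1/-1, recycled.
#' @param pseudo Logical vector marking recognizable pseudogene copies,
#'   recycled.
#' @param circular Logical; circular order (the default for mitogenomes).
#' @return An object of class `gene_order`.
#' @export
gene_order <- function(labels, strands = 1L, pseudo = FALSE, circular = TRUE) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("a gene order must be non-empty")
  n <- length(labels)
  strands <- rep_len(as.integer(strands), n)
  pseudo <- rep_len(as.logical(pseudo), n)
  if (!all(strands %in% c(-1L, 1L))) stop("strands must be +1 or -1")
  structure(list(labels = labels, strands = strands, pseudo = pseudo,
                 circular = isTRUE(circular)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  sym <- paste0(ifelse(x$strands < 0L, "-", ""), x$labels,
                ifelse(x$pseudo, "ψ", ""))
  cat(sprintf("<gene_order> %s, %d elements:\n  %s\n",
              if (x$circular) "circular" else "linear", length(x$labels),
              paste(sym, collapse = " ")))
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$labels)

order_keys <- function(o) {
  paste0(o$labels, "/", o$strands, "/", ifelse(o$pseudo, "p", "f"))
}

rotate_order <- function(o, k) {
  n <- length(o$labels)
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  gene_order(o$labels[idx], o$strands[idx], o$pseudo[idx], o$circular)
}

#' Canonicalize a gene order
#'
#' Circular orders are rotated so that the anchor label comes first:
#' `"trnF"` when present (the conventional start of the vertebrate
#' mitochondrial order), otherwise the lexicographically smallest label.
#' If the anchor occurs several times, the rotation giving the
#' lexicographically smallest element sequence is chosen. Idempotent;
#' linear orders are returned unchanged.
#'
#' @param order A [gene_order].
#' @param anchor Preferred anchor label.
#' @return The canonical [gene_order].
#' @export
canonicalize <- function(order, anchor = "trnF") {
  if (!order$circular || length(order$labels) == 1L) return(order)
  a <- if (anchor %in% order$labels) anchor else min(order$labels)
  starts <- which(order$labels == a) - 1L
  rots <- lapply(starts, function(k) rotate_order(order, k))
  keys <- vapply(rots, function(r) paste(order_keys(r), collapse = "\r"),
                 character(1))
  rots[[order(keys)[1L]]]
}

#' Test two gene orders for equivalence
#'
#' Circular orders are equivalent when some rotation makes them element-wise
#' equal (labels, strands and pseudogene marks); linear orders must be
#' element-wise equal. This is an equivalence relation.
#'
#' @param a,b [gene_order] objects.
#' @return Logical.
#' @export
orders_equivalent <- function(a, b) {
  if (a$circular != b$circular || length(a$labels) != length(b$labels)) {
    return(FALSE)
  }
  ca <- canonicalize(a); cb <- canonicalize(b)
  identical(order_keys(ca), order_keys(cb))
}

#' Extract the gene order from a feature table
#'
#' Features are sorted by start position around the molecule; spacers (IGS)
#' and the control region are first-class order elements. Pseudogene
#' features enter the order with a pseudogene mark. Overlap between two
#' coding features (protein/rRNA/tRNA) beyond a small tolerance is an
#' annotation error.
#'
#' @param features A `feature_table` for one sequence.
#' @param genome_length Length of the genome in bp.
#' @param circular Logical.
#' @param overlap_tol Maximum tolerated overlap (bp) between coding
#'   features.
#' @param drop_labels Labels excluded from the order (e.g. unrecognizable
#'   repeat tracts).
#' @return A canonical [gene_order].
#' @export
extract_gene_order <- function(features, genome_length, circular = TRUE,
                               overlap_tol = 10L, drop_labels = character()) {
  if (length(unique(features$seq_id)) != 1L) {
    stop("features must all lie on one sequence")
  }
  f <- features[order(features$start %% genome_length), , drop = FALSE]
  coding <- f$feature_class %in% c("protein", "rRNA", "tRNA")
  fc <- f[coding, , drop = FALSE]
  if (nrow(fc) > 1L) {
    for (i in seq_len(nrow(fc))) {
      j <- if (i == nrow(fc)) 1L else i + 1L
      ov <- fc$end[i] - fc$start[j]
      if (i == nrow(fc) && circular) ov <- fc$end[i] - genome_length - fc$start[j]
      if (i == nrow(fc) && !circular) next
      if (ov > overlap_tol) {
        stop("coding features '", fc$label[i], "' and '", fc$label[j],
             "' overlap by ", ov, " bp (> ", overlap_tol, ")")
      }
    }
  }
  keep <- !(f$label %in% drop_labels)
  f <- f[keep, , drop = FALSE]
  if (nrow(f) == 0L) stop("no features left after dropping labels")
  canonicalize(gene_order(f$label, f$strand,
                          f$feature_class == "pseudogene", circular))
}

#' Read-depth ratio of a candidate duplicated region
#'
#' Compares mean read depth inside a region against a trimmed-mean
#' background (the genome minus the region and any excluded regions, e.g.
#' other suspected repeats). A ratio of at least `flag_at` is consistent
#' with the region being present in two or more copies.
#'
#' @param track A `depth_track`.
#' @param region `c(start, end)`, 0-based half-open.
#' @param background_exclusions List of `c(start, end)` regions excluded
#'   from the background.
#' @param trim Trim fraction per tail for the background mean (robustness
#'   against control-region pileups).
#' @param flag_at Ratio threshold for the multi-copy flag.
#' @return List with `ratio`, `region_mean`, `background_mean` and logical
#'   `multi_copy`.
#' @export
depth_ratio <- function(track, region, background_exclusions = list(),
                        trim = 0.05, flag_at = 2.0) {
  L <- length(track$depths)
  span_idx <- function(r) {
    if (r[1] < 0 || r[2] > L || r[2] <= r[1]) stop("region outside genome")
    (r[1] + 1L):r[2]
  }
  inside <- span_idx(region)
  excl <- unique(unlist(lapply(background_exclusions, span_idx)))
  bg <- setdiff(seq_len(L), union(inside, excl))
  if (length(bg) == 0L) stop("background is empty")
  bg_mean <- mean(track$depths[bg], trim = trim)
  if (bg_mean == 0) stop("background mean depth is zero")
  ratio <- mean(track$depths[inside]) / bg_mean
  list(ratio = ratio, region_mean = mean(track$depths[inside]),
       background_mean = bg_mean, multi_copy = ratio >= flag_at)
}
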