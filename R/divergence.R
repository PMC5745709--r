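#' Concatenate aligned protein-coding genes per individual
#'
#' @param genes Named list (one element per individual); each element is a
#'   named list/character vector mapping gene label to its aligned
#'   sequence. Per-gene sequences must already be aligned across
#'   individuals (equal length per label).
#' @param gene_order Character vector giving the concatenation order.
#' @return Named character vector, one concatenated sequence per
#'   individual.
#' @export
concatenate_coding <- function(genes, gene_order) {
  out <- vapply(names(genes), function(ind) {
    g <- genes[[ind]]
    missing <- setdiff(gene_order, names(g))
    if (length(missing)) {
      stop("individual '", ind, "' is missing gene(s): ",
           paste(missing, collapse = ", "))
    }
    paste(unlist(g[gene_order]), collapse = "")
  }, character(1))
  for (lab in gene_order) {
    lens <- vapply(genes, function(g) nchar(g[[lab]]), integer(1))
    if (length(unique(lens)) != 1L) {
      stop("gene '", lab, "' has unequal aligned lengths across individuals")
    }
  }
  out
}

#' Proportion of differing sites between two aligned sequences
#'
#' Pairwise complete deletion: columns containing a gap or `N` in either
#' sequence are excluded from the comparison.
#'
#' @param a,b Aligned nucleotide strings of equal length (may contain `-`
#'   and `N`).
#' @return List with `p` (differing / comparable sites) and `n_sites`
#'   (comparable sites).
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal aligned length")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- !(ca %in% c("-", "N")) & !(cb %in% c("-", "N"))
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites")
  list(p = sum(ca[ok] != cb[ok]) / n, n_sites = n)
}

#' Jukes-Cantor distance correction
#'
#' Corrects an observed proportion of differing sites for multiple hits
#' under the one-parameter substitution model:
#' `d = -(3/4) * log(1 - 4p/3)`. Defined for `0 <= p < 0.75`; the
#' correction is monotone and `d >= p`.
#'
#' @param p Observed proportion of differing sites.
#' @return Corrected distance (substitutions per site).
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) {
    stop("p >= 0.75: Jukes-Cantor distance is undefined (saturation)")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Average pairwise divergence between two groups (D_XY)
#'
#' Mean proportion of differing sites over all between-group pairs,
#' corrected with the Jukes-Cantor model. By default the correction is
#' applied to the mean p (the usual D_XY definition); alternatively each
#' pair can be corrected before averaging.
#'
#' @param group_a,group_b Character vectors of aligned sequences (equal
#'   lengths).
#' @param per_pair Apply the JC correction per pair and average the
#'   corrected distances, instead of correcting the mean p.
#' @return A `divergence_estimate`: list with `p_mean`, `d_xy`, `n_pairs`,
#'   `n_sites_min`.
#' @export
dxy <- function(group_a, group_b, per_pair = FALSE) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  pairs <- expand.grid(i = seq_along(group_a), j = seq_along(group_b))
  pd <- Map(function(i, j) p_distance(group_a[[i]], group_b[[j]]),
            pairs$i, pairs$j)
  ps <- vapply(pd, `[[`, numeric(1), "p")
  ns <- vapply(pd, `[[`, numeric(1), "n_sites")
  p_mean <- mean(ps)
  d <- if (per_pair) mean(vapply(ps, jukes_cantor, numeric(1))) else
    jukes_cantor(p_mean)
  structure(list(p_mean = p_mean, d_xy = d, n_pairs = nrow(pairs),
                 n_sites_min = min(ns), per_pair = per_pair),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate> D_XY = %.4g (mean p = %.4g over %d pairs)\n",
              x$d_xy, x$p_mean, x$n_pairs))
  invisible(x)
}
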