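MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")
MITO_STARTS <- c("ATG", "ATA", "GTG")

#' Scan open reading frames under the vertebrate mitochondrial code
#'
#' Scans the three forward frames (optionally also the reverse strand) for
#' ORFs: a start codon (`ATG`, `ATA`, `GTG`) up to the next stop codon
#' (`TAA`, `TAG`, `AGA`, `AGG` — the vertebrate mitochondrial code reads
#' `AGA`/`AGG` as stops) or the sequence end. Within a stop-free stretch
#' only the leftmost start codon is reported (nested shorter ORFs add no
#' information about residual coding potential). `aa_length` counts codons
#' from the start codon up to but excluding the stop.
#'
#' @param seq Gap-free nucleotide string.
#' @param min_aa Minimum `aa_length` for an ORF to be reported.
#' @param both_strands Also scan the reverse complement. Duplicate gene
#'   copies retain the strand of their functional paralog, so the default
#'   scans forward frames only.
#' @return An `orf_report`: list with data frame `orfs` (columns `frame`,
#'   `start`, `aa_length`, `open_ended`, `strand`) and `longest_aa` (the
#'   maximum over all ORFs found, before the `min_aa` filter; 0 if none).
#' @export
scan_orfs <- function(seq, min_aa = 1L, both_strands = FALSE) {
  check_alignable(seq, "input")
  scan1 <- function(s, strand) {
    n <- nchar(s)
    rows <- list()
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 1L) next
      starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% MITO_STOPS
      is_start <- codons %in% MITO_STARTS
      seg_start <- 1L
      stops <- c(which(is_stop), ncod + 1L)
      for (t in stops) {
        if (t > seg_start) {
          cand <- which(is_start[seg_start:(t - 1L)])
          if (length(cand)) {
            c0 <- seg_start + cand[[1L]] - 1L
            rows[[length(rows) + 1L]] <- data.frame(
              frame = frame, start = starts[[c0]] - 1L,
              aa_length = t - c0, open_ended = t == ncod + 1L,
              strand = strand)
          }
        }
        seg_start <- t + 1L
      }
    }
    rows
  }
  rows <- scan1(seq, 1L)
  if (both_strands) rows <- c(rows, scan1(revcomp(seq), -1L))
  orfs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), start = integer(), aa_length = integer(),
               open_ended = logical(), strand = integer())
  longest <- if (nrow(orfs)) max(orfs$aa_length) else 0L
  structure(list(orfs = orfs[orfs$aa_length >= min_aa, , drop = FALSE],
                 longest_aa = longest),
            class = "orf_report")
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf("<orf_report> %d ORF(s), longest %d aa\n", nrow(x$orfs),
              x$longest_aa))
  invisible(x)
}
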