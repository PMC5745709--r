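#' Thresholds for paralog status calls
#'
#' @param intact_identity Minimum alignment identity for an `intact` call.
#' @param recognizable_identity Minimum identity below which a candidate is
#'   `unrecognizable` (random unrelated DNA aligns near 0.25-0.5 identity
#'   depending on gap placement).
#' @param min_length_ratio Candidate/functional length ratio below which a
#'   copy counts as disrupted.
#' @return A `decay_thresholds` list.
#' @export
decay_thresholds <- function(intact_identity = 0.98,
                             recognizable_identity = 0.50,
                             min_length_ratio = 0.9) {
  structure(list(intact_identity = intact_identity,
                 recognizable_identity = recognizable_identity,
                 min_length_ratio = min_length_ratio),
            class = "decay_thresholds")
}

#' Call the status of a candidate gene duplicate
#'
#' Aligns the candidate against its functional paralog and calls one of
#' `intact` (recognizable, full-length and undisrupted — for protein genes
#' this requires an intact full-length ORF), `pseudogene` (recognizable
#' similarity but a premature stop, frameshifting indel or substantial
#' truncation), or `unrecognizable` (identity below the recognizable
#' threshold). Loss of function is thus called on positive disruption
#' evidence, not on divergence alone: duplicate tRNAs a few substitutions
#' from their paralog remain `intact`.
#'
#' @param functional Nucleotide string of the intact copy (coding strand).
#' @param candidate Nucleotide string of the duplicate copy.
#' @param scoring A [scoring_scheme()].
#' @param thresholds A [decay_thresholds()].
#' @param is_protein Is this a protein-coding gene? If so the candidate is
#'   ORF-scanned under the vertebrate mitochondrial code.
#' @return A `paralog_status`: list with `call` and `evidence` (identity,
#'   premature-stop flag, frameshift flag, length ratio, longest ORF),
#'   plus the underlying alignment and difference summary.
#' @export
classify_paralog <- function(functional, candidate,
                             scoring = scoring_scheme(),
                             thresholds = decay_thresholds(),
                             is_protein = TRUE) {
  aln <- global_align(functional, candidate, scoring)
  ds <- summarize_differences(aln)
  length_ratio <- nchar(candidate) / nchar(functional)
  orf <- if (is_protein) scan_orfs(candidate) else NULL
  full_aa <- nchar(functional) %/% 3L - 1L  # minus the terminal stop
  premature_stop <- is_protein && orf$longest_aa < full_aa
  frameshift <- (ds$insertion_bp - ds$deletion_bp) %% 3L != 0L
  disrupted <- premature_stop || frameshift ||
    length_ratio < thresholds$min_length_ratio
  call <- if (ds$identity < thresholds$recognizable_identity) {
    "unrecognizable"
  } else if (disrupted) {
    "pseudogene"
  } else if (ds$identity >= thresholds$intact_identity) {
    "intact"
  } else {
    # recognizable, full-length, undisrupted: divergent but apparently
    # functional (duplicate tRNAs behave this way)
    "intact"
  }
  structure(list(
    call = call,
    evidence = list(identity = ds$identity,
                    premature_stop = premature_stop,
                    frameshift = frameshift,
                    length_ratio = length_ratio,
                    longest_orf_aa = if (is_protein) orf$longest_aa else NA_integer_),
    summary = ds, alignment = aln),
    class = "paralog_status")
}

#' @export
print.paralog_status <- function(x, ...) {
  cat(sprintf("<paralog_status> %s (identity %.1f%%, length ratio %.2f)\n",
              x$call, 100 * x$evidence$identity, x$evidence$length_ratio))
  invisible(x)
}
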