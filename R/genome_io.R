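FEATURE_CLASSES <- c("protein", "rRNA", "tRNA", "spacer", "control_region",
                     "pseudogene")

#' Construct a sequence record
#'
#' A sequence record holds one nucleotide sequence (alphabet `A,C,G,T,N`),
#' its identifier, and whether the molecule is circular. Mitochondrial
#' genomes are circular; individual gene sequences are not.
#'
#' @param id Short unique identifier.
#' @param seq Nucleotide string over `A,C,G,T,N` (lower case accepted,
#'   `U` mapped to `T`).
#' @param circular Logical; is the molecule circular?
#' @return An object of class `seq_record` with fields `id`, `seq`,
#'   `circular`.
#' @export
seq_record <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- chartr("u", "t", seq)
  seq <- toupper(chartr("U", "T", seq))
  if (!nzchar(seq)) stop("sequence for '", id, "' is empty")
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("illegal residue character(s) '",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""),
         "' in sequence '", id, "'")
  }
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp, %s\n", x$id, nchar(x$seq),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Headers may carry the token `circular=true` after the identifier to flag
#' a circular molecule. Residues are uppercased and `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  id <- NULL; circ <- FALSE; buf <- character(); hdr_line <- 0L
  flush <- function() {
    if (is.null(id)) return()
    seq <- paste(buf, collapse = "")
    if (!nzchar(seq)) {
      stop("record '", id, "' (header at line ", hdr_line, ") has no sequence")
    }
    rec <- tryCatch(seq_record(id, seq, circ), error = function(e) {
      stop("near line ", hdr_line, ": ", conditionMessage(e), call. = FALSE)
    })
    if (id %in% names(recs)) {
      stop("duplicate identifier '", id, "' at line ", hdr_line)
    }
    recs[[id]] <<- rec
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      flush()
      toks <- strsplit(sub("^>\\s*", "", ln), "\\s+")[[1]]
      if (length(toks) == 0L || !nzchar(toks[[1]])) {
        stop("malformed FASTA header at line ", i)
      }
      id <- toks[[1]]
      circ <- any(tolower(toks[-1]) == "circular=true")
      buf <- character(); hdr_line <- i
    } else if (nzchar(trimws(ln))) {
      if (is.null(id)) stop("sequence data before any header at line ", i)
      buf <- c(buf, trimws(ln))
    }
  }
  flush()
  if (length(recs) == 0L) stop("no FASTA records in '", path, "'")
  recs
}

#' Write sequence records to a FASTA file
#'
#' @param records A [seq_record] or list of them.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- paste0(">", r$id, if (r$circular) " circular=true" else "")
    writeLines(hdr, con)
    starts <- seq(1L, nchar(r$seq), by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L, nchar(r$seq))),
               con)
  }
  invisible(path)
}

#' Construct a feature table
#'
#' Coordinates are 0-based half-open. On a circular sequence a feature may
#' wrap the origin, encoded as `end > genome length`; positions are reduced
#' modulo the genome length on use.
#'
#' @param seq_id,label,feature_class,start,end,strand,paralog_tag Vectors,
#'   recycled to a common length. `feature_class` must be one of
#'   `r paste(FEATURE_CLASSES, collapse=", ")`. `strand` is +1 or -1.
#' @return A `feature_table` data frame.
#' @export
feature_table <- function(seq_id, label, feature_class, start, end,
                          strand = 1L, paralog_tag = NA_character_) {
  df <- data.frame(seq_id = as.character(seq_id),
                   label = as.character(label),
                   feature_class = as.character(feature_class),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.integer(strand),
                   paralog_tag = as.character(paralog_tag),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$feature_class), FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature_class: ", paste(bad, collapse = ", "))
  if (any(df$start < 0L)) stop("negative feature start")
  if (any(df$end <= df$start)) stop("feature span must have length >= 1")
  if (!all(df$strand %in% c(-1L, 1L))) stop("strand must be +1 or -1")
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read a GFF3-subset feature table
#'
#' Nine tab-separated columns (seqid, source, type, start, end, score,
#' strand, frame, attributes); `type` carries the feature class and the
#' attributes column carries `label=` and optional `paralog_tag=` keys.
#' On-disk coordinates are 1-based inclusive; rows with `end < start` on a
#' circular sequence denote origin-wrapping features and require the genome
#' length to lift the end coordinate.
#'
#' @param path Path to the table.
#' @param genome_lengths Optional named integer vector (names = seqids)
#'   used to decode origin-wrapping rows.
#' @return A `feature_table` data frame (0-based half-open coordinates).
#' @export
read_feature_table <- function(path, genome_lengths = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[[k]]
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) stop("line ", i, ": expected 9 tab-separated fields")
    start1 <- suppressWarnings(as.integer(f[[4]]))
    end1 <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(start1) || is.na(end1)) stop("line ", i, ": non-integer coordinate")
    attrs <- parse_gff_attributes(f[[9]])
    if (is.null(attrs$label)) stop("line ", i, ": missing 'label' attribute")
    if (!f[[3]] %in% FEATURE_CLASSES) {
      stop("line ", i, ": unknown feature class '", f[[3]], "'")
    }
    start0 <- start1 - 1L
    end0 <- end1
    if (end1 < start1) {
      len <- genome_lengths[[f[[1]]]]
      if (is.null(len) || is.na(len)) {
        stop("line ", i, ": end < start (origin wrap?) but no genome length ",
             "given for '", f[[1]], "'")
      }
      end0 <- end1 + as.integer(len)
      if (end0 <= start0) stop("line ", i, ": invalid wrapped coordinates")
    }
    strand <- switch(f[[7]], "+" = 1L, "-" = -1L,
                     stop("line ", i, ": strand must be '+' or '-'"))
    out[[k]] <- list(seq_id = f[[1]], label = attrs$label,
                     feature_class = f[[3]], start = start0, end = end0,
                     strand = strand,
                     paralog_tag = if (is.null(attrs$paralog_tag))
                       NA_character_ else attrs$paralog_tag)
  }
  if (length(out) == 0L) stop("no feature rows in '", path, "'")
  df <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  feature_table(df$seq_id, df$label, df$feature_class, df$start, df$end,
                df$strand, df$paralog_tag)
}

parse_gff_attributes <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) == 2L) out[[trimws(p[[1]])]] <- trimws(p[[2]])
  }
  out
}

#' Write a feature table as GFF3-subset
#'
#' Inverse of [read_feature_table()]: internal 0-based half-open coordinates
#' become 1-based inclusive; origin-wrapping features (`end > genome length`)
#' are written with `end < start`.
#'
#' @param features A `feature_table`.
#' @param path Output path.
#' @param genome_lengths Named integer vector of genome lengths, needed to
#'   encode origin-wrapping rows.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, genome_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    start1 <- f$start + 1L
    end1 <- f$end
    len <- if (!is.null(genome_lengths)) genome_lengths[[f$seq_id]] else NULL
    if (!is.null(len) && !is.na(len) && f$end > len) end1 <- f$end - as.integer(len)
    attrs <- paste0("label=", f$label)
    if (!is.na(f$paralog_tag)) attrs <- paste0(attrs, ";paralog_tag=", f$paralog_tag)
    writeLines(paste(f$seq_id, "mitodrl", f$feature_class, start1, end1, ".",
                     if (f$strand > 0) "+" else "-", ".", attrs, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq Nucleotide string over `A,C,G,T,N`.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Extract the sequence of an annotated feature
#'
#' Minus-strand features are reverse-complemented; features wrapping the
#' origin of a circular sequence are concatenated across the origin.
#'
#' @param record A [seq_record].
#' @param feature One row of a `feature_table` (or a list with `start`,
#'   `end`, `strand`).
#' @return Nucleotide string.
#' @export
extract_feature_sequence <- function(record, feature) {
  L <- nchar(record$seq)
  start <- feature$start; end <- feature$end
  if (start < 0L || start >= L) stop("feature start outside sequence")
  if (end > L) {
    if (!record$circular) stop("feature runs off the end of a linear sequence")
    if (end - L > start) stop("feature longer than the genome")
    s <- paste0(substr(record$seq, start + 1L, L), substr(record$seq, 1L, end - L))
  } else {
    s <- substr(record$seq, start + 1L, end)
  }
  if (feature$strand < 0L) s <- revcomp(s)
  s
}

#' Read a BED-like per-base depth track
#'
#' Four tab-separated columns: seqid, start (0-based), end (half-open),
#' depth. Intervals are expanded to one depth value per genome position.
#'
#' @param path Path to the track.
#' @param genome_length Genome length; uncovered positions get depth 0.
#' @param seq_id Optional; restrict to this seqid.
#' @return A `depth_track`: list with `seq_id` and integer vector `depths`.
#' @export
read_depth_track <- function(path, genome_length, seq_id = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("seq_id", "start", "end", "depth"),
                           stringsAsFactors = FALSE)
  if (!is.null(seq_id)) tab <- tab[tab$seq_id == seq_id, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no depth rows")
  depth_track(tab$seq_id[[1]], {
    d <- integer(genome_length)
    for (i in seq_len(nrow(tab))) {
      if (tab$end[i] > genome_length) stop("depth interval outside genome")
      d[(tab$start[i] + 1L):tab$end[i]] <- tab$depth[i]
    }
    d
  })
}

#' Construct a depth track
#'
#' @param seq_id Sequence identifier.
#' @param depths Integer vector, one non-negative value per genome position.
#' @return A `depth_track` object.
#' @export
depth_track <- function(seq_id, depths) {
  depths <- as.integer(depths)
  if (any(is.na(depths)) || any(depths < 0L)) stop("depths must be >= 0")
  if (length(depths) == 0L) stop("empty depth track")
  structure(list(seq_id = seq_id, depths = depths), class = "depth_track")
}
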