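#' Genomic interval
#'
#' A 1-based, fully closed genomic interval. Strand is metadata only: all
#' sequences and reads handled by the package are stored in forward-strand
#' orientation, so a minus-strand gene is represented by its forward-strand
#' sequence with `strand = "-"` recorded here.
#'
#' @param contig Contig/chromosome name.
#' @param start,end 1-based inclusive bounds; `start >= 1`, `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr7", 32320394, 34315743)
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  stopifnot(is.character(contig), length(contig) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || start < 1L) stop("interval start must be >= 1")
  if (is.na(end) || end < start) stop("interval end must be >= start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$contig, x$start, x$end, x$strand))
  invisible(x)
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%d-%d", x$contig, x$start, x$end)
}

interval_width <- function(x) x$end - x$start + 1L

#' Sequence record
#'
#' A named DNA sequence over the alphabet `A`, `C`, `G`, `T`, `N`. Sequences
#' are stored uppercase.
#'
#' @param id Record identifier.
#' @param sequence DNA sequence string; lowercase input is uppercased; `U` is
#'   rejected.
#' @return An object of class `seq_record` with elements `id` and `sequence`.
#' @export
seq_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(gsub("[ACGTN]", "", sequence), "")[[1]]),
               collapse = ","))
  structure(list(id = id, sequence = sequence), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$sequence)
  shown <- if (n > 60) paste0(substr(x$sequence, 1, 57), "...") else x$sequence
  cat(sprintf("<seq_record> %s (%d bp)\n  %s\n", x$id, n, shown))
  invisible(x)
}

#' Candidate variant
#'
#' A small variant at a duplicated locus. `pseudo_homolog_base` is the
#' pseudogene base at the column homologous to the variant position; it is the
#' key quantity for artefact reasoning — when it equals `alt`, mis-mapped
#' pseudogene reads mimic a heterozygous variant call.
#'
#' @param contig,pos Variant location (1-based).
#' @param ref,alt Reference and alternate alleles; must differ.
#' @param pseudo_homolog_base Pseudogene base at the homologous column, or
#'   `NA` when unknown.
#' @return An object of class `candidate_variant`.
#' @export
candidate_variant <- function(contig, pos, ref, alt, pseudo_homolog_base = NA) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (identical(ref, alt)) stop("ref and alt must differ")
  structure(list(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
                 pseudo_homolog_base = if (is.na(pseudo_homolog_base)) NA_character_
                                       else toupper(pseudo_homolog_base)),
            class = "candidate_variant")
}

#' @export
print.candidate_variant <- function(x, ...) {
  cat(sprintf("<variant> %s:%d%s>%s (pseudogene homolog base: %s)\n",
              x$contig, x$pos, x$ref, x$alt,
              ifelse(is.na(x$pseudo_homolog_base), "unknown",
                     x$pseudo_homolog_base)))
  invisible(x)
}

variant_id <- function(v) sprintf("%s:%d%s>%s", v$contig, v$pos, v$ref, v$alt)

#' Construct a set of aligned reads
#'
#' Reads are held as a data frame (class `read_set`) with one row per read.
#' `aln` is the reference-projected read sequence: one character per reference
#' base from `start` to `end`, with `"-"` at deleted positions; insertions and
#' soft-clipped bases do not appear. This projection is what every downstream
#' base query ([base_at()]) operates on, so CIGAR handling happens exactly
#' once, at construction.
#'
#' @param id,contig,start Read name, reference contig and 1-based leftmost
#'   mapped position.
#' @param aln Reference-projected sequence (see above).
#' @param origin_truth Optional simulation truth label per read
#'   (`"gene"`, `"pseudogene"` or `"unknown"`).
#' @return A `read_set` data frame with columns `id`, `contig`, `start`,
#'   `end`, `aln`, `origin_truth`.
#' @export
read_set <- function(id, contig, start, aln, origin_truth = NA_character_) {
  n <- length(id)
  start <- as.integer(start)
  df <- data.frame(id = as.character(id),
                   contig = rep_len(as.character(contig), n),
                   start = start,
                   end = start + nchar(aln) - 1L,
                   aln = as.character(aln),
                   origin_truth = rep_len(as.character(origin_truth), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

empty_read_set <- function() {
  read_set(character(), character(), integer(), character())
}

#' Base carried by each read at a reference position
#'
#' @param reads A `read_set`.
#' @param pos 1-based reference position.
#' @param contig Optional contig filter; reads on other contigs return `NA`.
#' @return Character vector, one element per read: the read base at `pos`,
#'   `"-"` if the read has a deletion there, `NA` if the read does not cover
#'   `pos`.
#' @export
base_at <- function(reads, pos, contig = NULL) {
  covered <- reads$start <= pos & reads$end >= pos
  if (!is.null(contig)) covered <- covered & reads$contig == contig
  out <- rep(NA_character_, nrow(reads))
  if (any(covered)) {
    off <- pos - reads$start[covered] + 1L
    out[covered] <- substr(reads$aln[covered], off, off)
  }
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(" on %s, span %d-%d",
                paste(unique(x$contig), collapse = ","),
                min(x$start), max(x$end)))
    if (any(!is.na(x$origin_truth))) cat(" [truth-labelled]")
  }
  cat("\n")
  invisible(x)
}
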