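#' Pair a gene and pseudogene segment
#'
#' Bundles the two homologous sequences with their genomic anchoring. The
#' alignment slot is filled by [align_pair()].
#'
#' @param gene,pseudogene [seq_record()] objects.
#' @param gene_interval,pseudo_interval Optional [genomic_interval()]s; when
#'   given, their widths must equal the sequence lengths and diagnostic
#'   positions are reported in genomic coordinates. Defaults anchor each
#'   sequence at position 1 of a contig named after the record.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(gene, pseudogene,
                           gene_interval = NULL, pseudo_interval = NULL) {
  stopifnot(inherits(gene, "seq_record"), inherits(pseudogene, "seq_record"))
  if (is.null(gene_interval))
    gene_interval <- genomic_interval(gene$id, 1L, nchar(gene$sequence))
  if (is.null(pseudo_interval))
    pseudo_interval <- genomic_interval(pseudogene$id, 1L,
                                        nchar(pseudogene$sequence))
  if (interval_width(gene_interval) != nchar(gene$sequence))
    stop("gene interval width must equal gene sequence length")
  if (interval_width(pseudo_interval) != nchar(pseudogene$sequence))
    stop("pseudogene interval width must equal pseudogene sequence length")
  structure(list(gene = gene, pseudogene = pseudogene,
                 gene_interval = gene_interval,
                 pseudo_interval = pseudo_interval,
                 alignment = NULL),
            class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf("<reference_pair> gene %s (%d bp) vs pseudogene %s (%d bp)%s\n",
              x$gene$id, nchar(x$gene$sequence),
              x$pseudogene$id, nchar(x$pseudogene$sequence),
              if (is.null(x$alignment)) "" else " [aligned]"))
  invisible(x)
}

#' Globally align a gene/pseudogene pair
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed by
#' [Biostrings::pairwiseAlignment()]. Defaults (match +1, mismatch -2, gap
#' open -6, gap extend -1) are tuned for ~90%-identical paralogs: gaps cost
#' substantially more than mismatches, so true substitutions stay aligned as
#' substitution columns rather than being absorbed into spurious indels.
#'
#' @param gene,pseudogene [seq_record()]s, or a [reference_pair()] as the
#'   first argument.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   negative).
#' @return Object of class `paralog_alignment`: gapped tracks, per-column
#'   1-based source offsets (genomic when the pair carries intervals, `NA` at
#'   gaps) and the alignment score. When called on a `reference_pair` the
#'   filled pair is returned instead, with the alignment in `$alignment`.
#' @export
align_pair <- function(gene, pseudogene = NULL, match = 1, mismatch = -2,
                       gap_open = -6, gap_extend = -1) {
  if (inherits(gene, "reference_pair")) {
    pair <- gene
    pair$alignment <- align_pair(pair$gene, pair$pseudogene, match = match,
                                 mismatch = mismatch, gap_open = gap_open,
                                 gap_extend = gap_extend)
    pair$alignment$gene_anchor <- pair$gene_interval$start
    pair$alignment$pseudo_anchor <- pair$pseudo_interval$start
    pair$alignment$gene_pos <- pair$alignment$gene_offset +
      pair$gene_interval$start - 1L
    pair$alignment$pseudo_pos <- pair$alignment$pseudo_offset +
      pair$pseudo_interval$start - 1L
    return(pair)
  }
  stopifnot(inherits(gene, "seq_record"), inherits(pseudogene, "seq_record"))
  for (s in list(gene, pseudogene)) {
    n_frac <- lengths(regmatches(s$sequence, gregexpr("N", s$sequence))) /
      nchar(s$sequence)
    if (n_frac > 0.5)
      stop("refusing to align '", s$id, "': more than half the bases are N")
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(gene$sequence),
    Biostrings::DNAString(pseudogene$sequence),
    type = "global", substitutionMatrix = sm,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  g <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  p <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  g_off <- ifelse(g == "-", NA_integer_, cumsum(g != "-"))
  p_off <- ifelse(p == "-", NA_integer_, cumsum(p != "-"))
  structure(list(gene_track = g, pseudo_track = p,
                 gene_offset = g_off, pseudo_offset = p_off,
                 gene_pos = g_off, pseudo_pos = p_off,
                 gene_anchor = 1L, pseudo_anchor = 1L,
                 gene_id = gene$id, pseudo_id = pseudogene$id,
                 score = Biostrings::score(aln),
                 params = c(match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend)),
            class = "paralog_alignment")
}

#' @export
print.paralog_alignment <- function(x, ...) {
  mm <- sum(x$gene_track != x$pseudo_track &
              x$gene_track != "-" & x$pseudo_track != "-")
  gaps <- sum(x$gene_track == "-" | x$pseudo_track == "-")
  cat(sprintf(
    "<paralog_alignment> %s vs %s: %d columns, %d substitutions, %d gap columns, score %.1f\n",
    x$gene_id, x$pseudo_id, length(x$gene_track), mm, gaps, x$score))
  invisible(x)
}

get_alignment <- function(x) {
  if (inherits(x, "reference_pair")) {
    if (is.null(x$alignment)) stop("pair has no alignment; call align_pair()")
    x$alignment
  } else if (inherits(x, "paralog_alignment")) x
  else stop("expected a paralog_alignment or aligned reference_pair")
}

#' Identity over an alignment window around a position
#'
#' The window is measured in alignment columns: `flank` columns either side
#' of the column holding `center_gene_pos` (2*flank+1 columns when the window
#' is gap-free). Gap columns count as non-matches.
#'
#' @param aln A `paralog_alignment` (or aligned `reference_pair`).
#' @param center_gene_pos Gene (genomic) position at the window centre.
#' @param flank Number of columns either side.
#' @return List with `matches`, `columns`, `mismatch_count`, `identity`.
#' @export
window_identity <- function(aln, center_gene_pos, flank = 60L) {
  aln <- get_alignment(aln)
  stopifnot(flank >= 0)
  ci <- match(as.integer(center_gene_pos), aln$gene_pos)
  if (is.na(ci))
    stop("range error: gene position ", center_gene_pos,
         " is not covered by the alignment")
  idx <- max(1L, ci - flank):min(length(aln$gene_track), ci + flank)
  g <- aln$gene_track[idx]; p <- aln$pseudo_track[idx]
  matches <- sum(g == p & g != "-")
  cols <- length(idx)
  list(matches = matches, columns = cols,
       mismatch_count = cols - matches,
       identity = matches / cols)
}

#' Percent identity over a gene region
#'
#' Identity is matches over alignment columns, with gap columns counted as
#' non-matches — for near-identical paralogs this coincides with the
#' matches-over-alignment-length convention BLAST reports.
#'
#' @param aln A `paralog_alignment` (or aligned `reference_pair`).
#' @param gene_region A [genomic_interval()] or a `c(start, end)` pair in
#'   gene coordinates.
#' @return Percent identity (0-100).
#' @export
region_identity <- function(aln, gene_region) {
  aln <- get_alignment(aln)
  if (inherits(gene_region, "genomic_interval"))
    gene_region <- c(gene_region$start, gene_region$end)
  s <- as.integer(gene_region[1]); e <- as.integer(gene_region[2])
  inside <- which(!is.na(aln$gene_pos) & aln$gene_pos >= s & aln$gene_pos <= e)
  if (!length(inside)) stop("empty region: no alignment columns in ", s, "-", e)
  idx <- min(inside):max(inside)  # keep interior gap-in-gene columns
  g <- aln$gene_track[idx]; p <- aln$pseudo_track[idx]
  100 * sum(g == p & g != "-") / length(idx)
}

#' Diagnostic positions (PSVs) of an aligned pair
#'
#' A diagnostic position — a paralogous sequence variant — is an alignment
#' column where the gene and pseudogene bases both exist and differ. These
#' fixed differences are the evidence units used to assign individual reads
#' to their locus of origin. Gap columns are excluded from the PSV list but
#' their count is reported as an attribute.
#'
#' @param aln A `paralog_alignment` (or aligned `reference_pair`).
#' @return Data frame with `gene_pos`, `pseudo_pos`, `gene_base`,
#'   `pseudo_base`, sorted by `gene_pos`; attribute `gap_columns` gives the
#'   number of gap columns seen.
#' @export
find_diagnostic_positions <- function(aln) {
  aln <- get_alignment(aln)
  sub <- which(aln$gene_track != aln$pseudo_track &
                 aln$gene_track != "-" & aln$pseudo_track != "-")
  out <- data.frame(gene_pos = aln$gene_pos[sub],
                    pseudo_pos = aln$pseudo_pos[sub],
                    gene_base = aln$gene_track[sub],
                    pseudo_base = aln$pseudo_track[sub],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gap_columns") <- sum(aln$gene_track == "-" |
                                    aln$pseudo_track == "-")
  out
}

#' Write / read a PSV table
#'
#' @param psvs Data frame from [find_diagnostic_positions()].
#' @param path TSV path.
#' @return `path` (write) or the PSV data frame (read).
#' @export
write_psv_table <- function(psvs, path) {
  write.table(psvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psv_table
#' @export
read_psv_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_pos", "pseudo_pos", "gene_base", "pseudo_base")
  if (!all(need %in% names(df)))
    stop("format error: PSV table needs columns ", paste(need, collapse = ", "))
  df
}

#' Primer pair
#'
#' @param forward,reverse Primer sequences, each written 5'->3'.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 15 || nchar(reverse) < 15)
    stop("primers must be at least 15 bases long")
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## Primer sites allowing <= max_mismatch mismatches outside the 3 terminal
## 3'-end bases, which must match exactly (standard specificity heuristic).
## `three_prime` is "right" for a forward primer and "left" for the
## reverse-complemented reverse primer.
primer_sites <- function(pattern, template, max_mismatch, three_prime) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(template),
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE)
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  }
  pat <- strsplit(pattern, "")[[1]]
  keep <- logical(length(hits)); mm <- integer(length(hits))
  starts <- Biostrings::start(hits); ends <- Biostrings::end(hits)
  for (i in seq_along(hits)) {
    seg <- strsplit(substr(template, starts[i], ends[i]), "")[[1]]
    diffs <- which(seg != pat)
    term <- if (three_prime == "right")
      (length(pat) - 2L):length(pat) else 1:3
    keep[i] <- !any(diffs %in% term)
    mm[i] <- length(diffs)
  }
  data.frame(start = starts[keep], end = ends[keep], mismatches = mm[keep])
}

#' In-silico PCR
#'
#' Predicts products of a primer pair on a template: forward-primer sites on
#' the forward strand paired with downstream reverse-primer sites (matched as
#' the reverse complement). Up to `max_mismatch` mismatches are tolerated per
#' primer outside its 3 terminal 3'-end bases, which must match exactly.
#' Product size is outer edge to outer edge, inclusive of both primer
#' footprints.
#'
#' @param template A [seq_record()] (or plain sequence string).
#' @param primers A [primer_pair()].
#' @param max_mismatch Mismatches tolerated per primer outside the 3' end.
#' @param max_product Longest product reported, in bp.
#' @return Data frame with `start`, `end`, `product_size`, `mismatches` (sum
#'   over the two primers), one row per predicted product.
#' @export
in_silico_pcr <- function(template, primers, max_mismatch = 2L,
                          max_product = 20000L) {
  if (inherits(template, "seq_record")) template <- template$sequence
  template <- toupper(template)
  if (!nzchar(template)) stop("template must be non-empty")
  stopifnot(inherits(primers, "primer_pair"))
  fwd <- primer_sites(primers$forward, template, max_mismatch, "right")
  rev <- primer_sites(revcomp(primers$reverse), template, max_mismatch, "left")
  out <- data.frame(start = integer(), end = integer(),
                    product_size = integer(), mismatches = integer())
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
    if (rev$start[j] > fwd$end[i]) {
      size <- rev$end[j] - fwd$start[i] + 1L
      if (size <= max_product)
        out <- rbind(out, data.frame(start = fwd$start[i], end = rev$end[j],
                                     product_size = size,
                                     mismatches = fwd$mismatches[i] +
                                       rev$mismatches[j]))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Primer specificity on a gene/pseudogene pair
#'
#' A primer pair intended to amplify one locus of a duplicated pair is
#' flagged nonspecific when it yields a product on both sequences — the
#' co-amplification mechanism by which pseudogene alleles masquerade as gene
#' variants in Sanger and amplicon assays.
#'
#' @param pair A [reference_pair()].
#' @inheritParams in_silico_pcr
#' @return List with per-locus product tables and logical `nonspecific`.
#' @export
primer_specificity <- function(pair, primers, max_mismatch = 2L,
                               max_product = 20000L) {
  stopifnot(inherits(pair, "reference_pair"))
  on_gene <- in_silico_pcr(pair$gene, primers, max_mismatch, max_product)
  on_pseudo <- in_silico_pcr(pair$pseudogene, primers, max_mismatch,
                             max_product)
  list(gene_products = on_gene, pseudogene_products = on_pseudo,
       nonspecific = nrow(on_gene) > 0 && nrow(on_pseudo) > 0)
}
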