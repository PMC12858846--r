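#' Assign reads to gene or pseudogene by PSV voting
#'
#' Each read votes at every diagnostic position it covers: a read base equal
#' to the gene base votes gene, equal to the pseudogene base votes
#' pseudogene, and any other base (sequencing error, deletion, third allele)
#' abstains rather than counting against either origin. The label is the
#' strict majority when the read covers at least `min_informative` PSVs;
#' ties, sparse reads and vote-free reads are `ambiguous`.
#'
#' @param reads A [read_set()].
#' @param psvs PSV table ([find_diagnostic_positions()]), sorted by
#'   `gene_pos`.
#' @param min_informative Minimum PSVs a read must cover before a call is
#'   made. Single-PSV calls are fragile to sequencing error, hence the
#'   default of 2.
#' @return Data frame with one row per read: `id`, `label` (`gene`,
#'   `pseudogene`, `ambiguous`), `gene_votes`, `pseudo_votes`,
#'   `informative_sites`.
#' @export
classify_reads <- function(reads, psvs, min_informative = 2L) {
  if (is.unsorted(psvs$gene_pos)) psvs <- psvs[order(psvs$gene_pos), ]
  n <- nrow(reads)
  gene_votes <- pseudo_votes <- informative <- integer(n)
  for (i in seq_len(nrow(psvs))) {
    b <- base_at(reads, psvs$gene_pos[i])
    covered <- !is.na(b)
    informative <- informative + covered
    gene_votes <- gene_votes + (covered & b == psvs$gene_base[i])
    pseudo_votes <- pseudo_votes + (covered & b == psvs$pseudo_base[i])
  }
  label <- rep("ambiguous", n)
  callable <- informative >= min_informative
  label[callable & gene_votes > pseudo_votes] <- "gene"
  label[callable & pseudo_votes > gene_votes] <- "pseudogene"
  data.frame(id = reads$id, label = label, gene_votes = gene_votes,
             pseudo_votes = pseudo_votes, informative_sites = informative,
             stringsAsFactors = FALSE)
}

#' @rdname classify_reads
#' @param read A single-row `read_set`.
#' @return `classify_read()` returns a list (`label`, `gene_votes`,
#'   `pseudo_votes`, `informative_sites`) for one read.
#' @export
classify_read <- function(read, psvs, min_informative = 2L) {
  stopifnot(nrow(read) == 1L)
  as.list(classify_reads(read, psvs, min_informative)[1, -1])
}

#' Adjudication parameters
#'
#' @param min_depth Minimum covering reads before any verdict is attempted.
#' @param min_alt_reads Minimum alt-supporting reads behind a positive call.
#' @param het_band Allowed alt-allele fraction among gene-labelled reads for
#'   a germline heterozygous variant.
#' @param min_informative Passed to [classify_reads()].
#' @return List of class `adjudication_params`.
#' @export
adjudication_params <- function(min_depth = 20L, min_alt_reads = 5L,
                                het_band = c(0.2, 0.8),
                                min_informative = 2L) {
  stopifnot(min_depth >= 1, min_alt_reads >= 1,
            length(het_band) == 2L, het_band[1] < het_band[2])
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_reads = as.integer(min_alt_reads),
                 het_band = as.numeric(het_band),
                 min_informative = as.integer(min_informative)),
            class = "adjudication_params")
}

#' Adjudicate a candidate variant at a duplicated locus
#'
#' Decides whether a candidate variant is carried by the gene or could be an
#' artefact of mis-mapped (or co-amplified) pseudogene reads. The decisive
#' configuration is the pseudogene base at the homologous column:
#'
#' * If it differs from the alt allele, pseudogene bleed-through cannot
#'   create the alt reads; the verdict is `gene_derived` when enough alt
#'   reads exist and the alt fraction among gene-labelled reads sits in the
#'   heterozygous band.
#' * If it equals the alt allele, an artefact is plausible: mis-mapped
#'   pseudogene reads carry the alt base. The verdict is
#'   `gene_derived_confirmed` only when enough gene-labelled reads carry the
#'   alt; otherwise `pseudogene_artefact_possible`.
#' * Insufficient coverage yields `indeterminate` (with the reason), never an
#'   error.
#'
#' PSVs at the variant position itself are excluded from read voting — the
#' site under test must not double as its own evidence.
#'
#' @param variant A [candidate_variant()]; `pseudo_homolog_base` drives the
#'   artefact logic (unknown is treated like the non-artefact configuration).
#' @param reads A [read_set()] covering the variant.
#' @param psvs PSV table for the locus.
#' @param params [adjudication_params()].
#' @return Object of class `adjudication`: `verdict`, `rule`, `reason` and a
#'   `counts` list (depth, per-origin and per-allele read counts, alt
#'   fraction among gene-labelled reads).
#' @export
adjudicate_variant <- function(variant, reads, psvs,
                               params = adjudication_params()) {
  stopifnot(inherits(variant, "candidate_variant"))
  psvs <- psvs[psvs$gene_pos != variant$pos, , drop = FALSE]
  b <- base_at(reads, variant$pos, contig = variant$contig)
  covering <- !is.na(b) & b != "-"
  depth <- sum(covering)
  counts <- list(depth = depth, n_alt = NA_integer_, n_ref = NA_integer_,
                 gene_reads = NA_integer_, pseudo_reads = NA_integer_,
                 ambiguous_reads = NA_integer_, gene_alt = NA_integer_,
                 alt_fraction_gene = NA_real_)
  finish <- function(verdict, rule, reason = NA_character_) {
    structure(list(variant = variant, verdict = verdict, rule = rule,
                   reason = reason, counts = counts, params = params),
              class = "adjudication")
  }
  if (depth < params$min_depth)
    return(finish("indeterminate", "min_depth",
                  sprintf("depth %d below minimum %d", depth,
                          params$min_depth)))
  calls <- classify_reads(reads[covering, , drop = FALSE], psvs,
                          params$min_informative)
  bb <- b[covering]
  gene_lab <- calls$label == "gene"
  counts$n_alt <- sum(bb == variant$alt)
  counts$n_ref <- sum(bb == variant$ref)
  counts$gene_reads <- sum(gene_lab)
  counts$pseudo_reads <- sum(calls$label == "pseudogene")
  counts$ambiguous_reads <- sum(calls$label == "ambiguous")
  counts$gene_alt <- sum(gene_lab & bb == variant$alt)
  counts$alt_fraction_gene <-
    if (counts$gene_reads > 0) counts$gene_alt / counts$gene_reads else NA_real_
  artefact_config <- !is.na(variant$pseudo_homolog_base) &&
    variant$pseudo_homolog_base == variant$alt
  if (!artefact_config) {
    ## Pseudogene homolog differs from alt: bleed-through cannot explain
    ## alt reads.
    if (counts$n_alt < params$min_alt_reads)
      return(finish("indeterminate", "min_alt_reads",
                    sprintf("only %d alt reads (need %d)", counts$n_alt,
                            params$min_alt_reads)))
    if (is.na(counts$alt_fraction_gene))
      return(finish("indeterminate", "no_gene_labelled_reads",
                    "no reads could be assigned to the gene"))
    if (counts$alt_fraction_gene >= params$het_band[1] &&
        counts$alt_fraction_gene <= params$het_band[2])
      return(finish("gene_derived", "alt_not_pseudo_homolog"))
    return(finish("indeterminate", "alt_fraction_outside_het_band",
                  sprintf("alt fraction %.3f among gene-labelled reads",
                          counts$alt_fraction_gene)))
  }
  ## D170G-style configuration: pseudogene carries the alt base.
  if (counts$n_alt == 0)
    return(finish("indeterminate", "no_alt_reads",
                  "no alt-supporting reads at the site"))
  if (counts$gene_alt >= params$min_alt_reads)
    return(finish("gene_derived_confirmed", "gene_labelled_alt_reads"))
  finish("pseudogene_artefact_possible", "alt_reads_not_gene_labelled",
         sprintf("%d alt reads but only %d assigned to the gene",
                 counts$n_alt, counts$gene_alt))
}

#' @export
print.adjudication <- function(x, ...) {
  cat(sprintf("<adjudication> %s -> %s (rule: %s)\n",
              variant_id(x$variant), x$verdict, x$rule))
  with(x$counts, cat(sprintf(
    "  depth %d | alt %s ref %s | gene %s pseudo %s ambiguous %s | gene-alt %s (fraction %s)\n",
    depth, n_alt, n_ref, gene_reads, pseudo_reads, ambiguous_reads, gene_alt,
    ifelse(is.na(alt_fraction_gene), "NA",
           sprintf("%.2f", alt_fraction_gene)))))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}
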