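## Base counts (A,C,G,T) per reference position over a read set.
## Uniform full-span read sets (amplicon reads) take a fast byte-matrix path.
pileup_counts <- function(reads, positions) {
  positions <- as.integer(positions)
  out <- matrix(0L, nrow = length(positions), ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  if (!nrow(reads) || !length(positions)) return(out)
  uniform <- length(unique(reads$start)) == 1L &&
    length(unique(nchar(reads$aln))) == 1L
  if (uniform) {
    start <- reads$start[1]
    m <- matrix(unlist(lapply(reads$aln, charToRaw), use.names = FALSE),
                ncol = nrow(reads))
    ok <- positions >= start & positions <= reads$end[1]
    rows <- positions[ok] - start + 1L
    bases <- c(A = 65L, C = 67L, G = 71L, T = 84L)
    for (b in names(bases)) {
      cnt <- rowSums(m[rows, , drop = FALSE] == as.raw(bases[[b]]))
      out[ok, b] <- as.integer(cnt)
    }
    return(out)
  }
  for (k in seq_along(positions)) {
    b <- base_at(reads, positions[k])
    tb <- table(factor(b, levels = c("A", "C", "G", "T")))
    out[k, ] <- as.integer(tb)
  }
  out
}

#' Split reads by the allele carried at an anchor variant
#'
#' Partitions a read set by the base each read carries at the anchor
#' position: reads carrying the reference allele, reads carrying the
#' alternate allele, and reads that either do not cover the anchor or carry
#' another base. This is the allele-split that turns a pot of amplicon reads
#' into two per-allele haplotype pileups.
#'
#' @param reads A [read_set()].
#' @param anchor A [candidate_variant()] giving contig, position and the two
#'   alleles.
#' @return Object of class `allele_split` with `ref_reads`, `alt_reads`
#'   (read sets) and `unassigned` (count). Zero anchor coverage produces an
#'   empty split with a warning, not an error.
#' @export
split_by_anchor <- function(reads, anchor) {
  stopifnot(inherits(anchor, "candidate_variant"))
  b <- base_at(reads, anchor$pos, contig = anchor$contig)
  if (!any(!is.na(b)))
    warning("no reads cover the anchor at ", variant_id(anchor))
  is_ref <- !is.na(b) & b == anchor$ref
  is_alt <- !is.na(b) & b == anchor$alt
  structure(list(anchor = anchor,
                 ref_reads = reads[is_ref, , drop = FALSE],
                 alt_reads = reads[is_alt, , drop = FALSE],
                 unassigned = sum(!is_ref & !is_alt)),
            class = "allele_split")
}

#' @export
print.allele_split <- function(x, ...) {
  cat(sprintf("<allele_split> %s: %d ref / %d alt / %d unassigned\n",
              variant_id(x$anchor), nrow(x$ref_reads), nrow(x$alt_reads),
              x$unassigned))
  invisible(x)
}

#' Call a consensus haplotype from one allele's reads
#'
#' At each requested position the consensus allele is called when coverage
#' reaches `min_depth` and the majority base reaches `min_majority` of the
#' called bases; otherwise the position is a no-call. Deterministic: ties
#' cannot satisfy a majority threshold above 0.5.
#'
#' @param reads A [read_set()] (typically one side of an [split_by_anchor()]
#'   split).
#' @param positions Reference positions to genotype.
#' @param min_depth,min_majority Consensus thresholds.
#' @param sample_id,anchor_allele,role Metadata carried on the haplotype;
#'   `role` is `"variant"` or `"other"` relative to the anchor.
#' @return Object of class `haplotype`: `calls` data frame (`pos`, `allele`,
#'   `depth`, `majority_fraction`) for called sites, plus `no_call_count`.
#' @export
call_haplotype <- function(reads, positions, min_depth = 20L,
                           min_majority = 0.8, sample_id = NA_character_,
                           anchor_allele = NA_character_,
                           role = NA_character_) {
  stopifnot(min_majority >= 0.5, min_majority <= 1)
  positions <- sort(unique(as.integer(positions)))
  cnt <- pileup_counts(reads, positions)
  depth <- rowSums(cnt)
  major_i <- max.col(cnt, ties.method = "first")
  major_n <- cnt[cbind(seq_along(positions), major_i)]
  frac <- ifelse(depth > 0, major_n / depth, 0)
  called <- depth >= min_depth & frac >= min_majority
  calls <- data.frame(pos = positions[called],
                      allele = colnames(cnt)[major_i[called]],
                      depth = depth[called],
                      majority_fraction = frac[called],
                      stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, anchor_allele = anchor_allele,
                 role = role, calls = calls,
                 no_call_count = sum(!called)),
            class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("<haplotype> %s [%s allele %s]: %d called sites, %d no-calls\n",
              x$sample_id, x$role, x$anchor_allele, nrow(x$calls),
              x$no_call_count))
  invisible(x)
}

#' Discover heterozygous sites from an allele split
#'
#' Sites where the two per-allele consensi are both confidently called and
#' disagree — the data-driven SNP panel on which per-sample haplotypes are
#' compared. The anchor position itself is excluded (it disagrees by
#' construction).
#'
#' @param split An [split_by_anchor()] result.
#' @param min_depth,min_majority Consensus thresholds per side.
#' @return Integer vector of heterozygous positions.
#' @export
discover_het_sites <- function(split, min_depth = 20L, min_majority = 0.8) {
  stopifnot(inherits(split, "allele_split"))
  if (!nrow(split$ref_reads) || !nrow(split$alt_reads)) return(integer())
  lo <- max(min(split$ref_reads$start), min(split$alt_reads$start))
  hi <- min(max(split$ref_reads$end), max(split$alt_reads$end))
  if (hi < lo) return(integer())
  positions <- lo:hi
  consensus_of <- function(rd) {
    cnt <- pileup_counts(rd, positions)
    depth <- rowSums(cnt)
    major_i <- max.col(cnt, ties.method = "first")
    frac <- ifelse(depth > 0, cnt[cbind(seq_along(positions), major_i)] / depth, 0)
    allele <- colnames(cnt)[major_i]
    allele[!(depth >= min_depth & frac >= min_majority)] <- NA
    allele
  }
  a <- consensus_of(split$ref_reads)
  b <- consensus_of(split$alt_reads)
  het <- positions[!is.na(a) & !is.na(b) & a != b]
  setdiff(het, split$anchor$pos)
}

#' Seeded subsampling of a read set to a depth cap
#'
#' Mirrors capping amplicon pots to a fixed depth before haplotype calling;
#' seeded so the subsample is reproducible. For full-span amplicon reads the
#' read count equals the depth.
#'
#' @param reads A [read_set()].
#' @param depth_cap Maximum reads retained.
#' @param seed RNG seed.
#' @return The subsampled `read_set`.
#' @export
subsample_reads <- function(reads, depth_cap, seed = 1L) {
  if (nrow(reads) <= depth_cap) return(reads)
  keep <- with_seed(seed, sort(sample.int(nrow(reads), depth_cap)))
  reads[keep, , drop = FALSE]
}

#' Per-sample allele-split haplotyping
#'
#' Convenience wrapper running the full per-sample chain: optional seeded
#' depth capping, allele split at the anchor, heterozygous-site discovery,
#' and consensus haplotype calls for the variant-carrying and the other
#' allele.
#'
#' @param reads Long reads for one sample.
#' @param anchor The anchor [candidate_variant()].
#' @param sample_id Sample label carried onto the haplotypes.
#' @param positions SNP positions to genotype; default discovers them from
#'   the split ([discover_het_sites()]).
#' @param min_depth,min_majority Consensus thresholds.
#' @param depth_cap,seed Optional per-allele depth cap (seeded).
#' @return List with `variant` and `other` [call_haplotype()] results and
#'   the `split`.
#' @export
sample_haplotypes <- function(reads, anchor, sample_id,
                              positions = NULL, min_depth = 20L,
                              min_majority = 0.8, depth_cap = NULL,
                              seed = 1L) {
  split <- split_by_anchor(reads, anchor)
  if (!is.null(depth_cap)) {
    split$ref_reads <- subsample_reads(split$ref_reads, depth_cap, seed)
    split$alt_reads <- subsample_reads(split$alt_reads, depth_cap, seed + 1L)
  }
  if (is.null(positions))
    positions <- discover_het_sites(split, min_depth, min_majority)
  list(variant = call_haplotype(split$alt_reads, positions, min_depth,
                                min_majority, sample_id,
                                anchor_allele = anchor$alt, role = "variant"),
       other = call_haplotype(split$ref_reads, positions, min_depth,
                              min_majority, sample_id,
                              anchor_allele = anchor$ref, role = "other"),
       split = split)
}

#' Compare variant-anchored haplotypes across samples for founder sharing
#'
#' Consistency with a single founder requires (i) every variant-anchored
#' haplotype to carry identical alleles at every jointly-called site and
#' (ii) each sample's variant haplotype to differ from that sample's
#' non-variant haplotype at one or more sites — otherwise there is no
#' haplotype signal distinguishing the chromosomes at all.
#'
#' @param haps List of [call_haplotype()] objects, the variant and
#'   non-variant haplotype of each sample (as produced by
#'   [sample_haplotypes()], concatenated across samples).
#' @param flanking_genotypes Optional data frame of flanking-SNP genotypes
#'   appended verbatim to the report (phase there being unobservable from
#'   the amplicon).
#' @return Object of class `founder_report`: `samples`, `shared_sites`,
#'   `compared_sites`, `concordance`, `founder_consistent` (`NA` and flagged
#'   when no jointly-called sites exist), and per-sample
#'   `distinct_from_other` flags.
#' @export
compare_haplotypes <- function(haps, flanking_genotypes = NULL) {
  roles <- vapply(haps, `[[`, "", "role")
  variant_haps <- haps[roles == "variant"]
  other_haps <- haps[roles == "other"]
  if (length(variant_haps) < 2L)
    stop("need at least two variant-anchored haplotypes to compare")
  samples <- vapply(variant_haps, `[[`, "", "sample_id")
  joint <- Reduce(intersect, lapply(variant_haps, function(h) h$calls$pos))
  allele_at <- function(h, pos) h$calls$allele[match(pos, h$calls$pos)]
  if (!length(joint)) {
    return(structure(list(samples = samples, shared_sites = 0L,
                          compared_sites = 0L, concordance = NA_real_,
                          founder_consistent = NA,
                          distinct_from_other = NULL,
                          flanking_genotypes = flanking_genotypes,
                          flag = "no jointly-called sites"),
                     class = "founder_report"))
  }
  mat <- vapply(variant_haps, allele_at, character(length(joint)), pos = joint)
  mat <- matrix(mat, nrow = length(joint))
  agree <- apply(mat, 1L, function(r) length(unique(r)) == 1L)
  shared <- sum(agree)
  distinct <- vapply(seq_along(variant_haps), function(i) {
    oh <- Filter(function(h) identical(h$sample_id, samples[i]), other_haps)
    if (!length(oh)) return(NA)
    both <- intersect(variant_haps[[i]]$calls$pos, oh[[1]]$calls$pos)
    if (!length(both)) return(NA)
    any(allele_at(variant_haps[[i]], both) != allele_at(oh[[1]], both))
  }, NA)
  structure(list(samples = samples, shared_sites = shared,
                 compared_sites = length(joint),
                 concordance = shared / length(joint),
                 founder_consistent = shared == length(joint) &&
                   all(!is.na(distinct)) && all(distinct),
                 distinct_from_other = setNames(distinct, samples),
                 flanking_genotypes = flanking_genotypes, flag = NULL),
            class = "founder_report")
}

#' @export
print.founder_report <- function(x, ...) {
  cat(sprintf("<founder_report> %d samples: %d/%d jointly-called sites shared (concordance %s)\n",
              length(x$samples), x$shared_sites, x$compared_sites,
              ifelse(is.na(x$concordance), "NA",
                     sprintf("%.3f", x$concordance))))
  cat("  founder-consistent:",
      if (is.na(x$founder_consistent)) paste0("NA (", x$flag, ")")
      else x$founder_consistent, "\n")
  invisible(x)
}

#' Meioses separating two individuals through common ancestors
#'
#' The meiotic path length through a shared ancestral couple is the sum of
#' the generation counts down each side; e.g. two individuals each seven
#' generations below the common ancestors are fourteen meioses apart (sixth
#' cousins).
#'
#' @param gen1,gen2 Generations from each individual up to the common
#'   ancestor (non-negative integers).
#' @return Integer meiotic distance.
#' @export
meiotic_distance <- function(gen1, gen2) {
  gen1 <- as.integer(gen1); gen2 <- as.integer(gen2)
  if (is.na(gen1) || is.na(gen2) || gen1 < 0L || gen2 < 0L)
    stop("generation counts must be non-negative integers")
  gen1 + gen2
}
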