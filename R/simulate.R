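#' Simulation configuration
#'
#' Study conditions for the synthetic duplicated locus: a gene copy and a
#' pseudogene copy at a controlled sequence identity, a planted heterozygous
#' candidate variant in one of two artefact-relevant configurations, short
#' paired-end-scale reads and long amplicon-scale reads with uniform
#' substitution error, and a founder haplotype shared across carriers.
#' Defaults mirror the RP9/RP9P-like setting the package targets: ~87.5%
#' gene/pseudogene identity, 150 bp short reads at 30x, ~9 kb amplicon reads
#' at 2000x per allele, 1% substitution error, 4 carriers sharing a 12-SNP
#' founder haplotype.
#'
#' @param seed Integer seed; every simulation stream derives from it.
#' @param gene_length Length of the simulated gene segment (bp).
#' @param identity Gene/pseudogene sequence identity in (0.5, 1).
#' @param variant_scenario `"h137l_like"` (pseudogene homolog equals the
#'   gene reference base), `"d170g_like"` (pseudogene homolog equals the
#'   alt), or `"none"`.
#' @param short_read_len,short_depth Short-read length and per-locus depth.
#' @param long_read_len,long_depth Amplicon length (full-length long reads)
#'   and per-allele depth.
#' @param error_rate Per-base substitution error rate in [0, 0.2].
#' @param carriers Number of simulated founder-variant carriers.
#' @param founder_hap_snps SNPs on the shared founder haplotype.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, gene_length = 10000L, identity = 0.875,
                       variant_scenario = c("none", "h137l_like",
                                            "d170g_like"),
                       short_read_len = 150L, short_depth = 30L,
                       long_read_len = 9000L, long_depth = 2000L,
                       error_rate = 0.01, carriers = 4L,
                       founder_hap_snps = 12L) {
  variant_scenario <- match.arg(variant_scenario)
  stopifnot(identity > 0.5, identity < 1 || identity == 1,
            short_depth > 0, long_depth > 0,
            error_rate >= 0, error_rate <= 0.2,
            gene_length >= 2L * short_read_len)
  structure(list(seed = as.integer(seed),
                 gene_length = as.integer(gene_length), identity = identity,
                 variant_scenario = variant_scenario,
                 short_read_len = as.integer(short_read_len),
                 short_depth = short_depth,
                 long_read_len = as.integer(long_read_len),
                 long_depth = long_depth, error_rate = error_rate,
                 carriers = as.integer(carriers),
                 founder_hap_snps = as.integer(founder_hap_snps)),
            class = "sim_config")
}

## Substitution errors on a character vector of bases.
inject_errors <- function(chars, rate) {
  if (rate <= 0) return(chars)
  n_err <- rbinom(1L, length(chars), rate)
  if (n_err > 0) {
    at <- sample.int(length(chars), n_err)
    chars[at] <- other_base(chars[at])
  }
  chars
}

#' Generate a homologous gene/pseudogene reference pair
#'
#' The gene is a uniform random sequence; the pseudogene is a copy with
#' exactly `round((1 - identity) * L)` substitutions at distinct seeded
#' positions (no indels), so the planted substitution set is the exact truth
#' for diagnostic-position discovery.
#'
#' @param cfg A [sim_config()].
#' @return List: `pair` (a [reference_pair()] on contigs `"gene"` /
#'   `"pseudogene"`) and `psvs` (the planted truth table, same columns as
#'   [find_diagnostic_positions()]).
#' @export
generate_reference_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$gene_length
  n_sub <- round((1 - cfg$identity) * L)
  if (n_sub > L) stop("identity too low: cannot place ", n_sub,
                      " distinct substitutions in ", L, " bases")
  with_seed(cfg$seed, {
    gene <- random_dna(L)
    gchars <- strsplit(gene, "")[[1]]
    pchars <- gchars
    pos <- if (n_sub > 0) sort(sample.int(L, n_sub)) else integer()
    pchars[pos] <- other_base(pchars[pos])
    list(pair = reference_pair(seq_record("gene", gene),
                               seq_record("pseudogene",
                                          paste(pchars, collapse = ""))),
         psvs = data.frame(gene_pos = pos, pseudo_pos = pos,
                           gene_base = gchars[pos], pseudo_base = pchars[pos],
                           stringsAsFactors = FALSE))
  })
}

#' Plant a heterozygous candidate variant on the gene copy
#'
#' Site selection realises the two artefact-relevant configurations. In the
#' `h137l_like` configuration the site is not a diagnostic position: gene
#' and pseudogene share the reference base, so pseudogene bleed-through can
#' only add reference alleles. In the `d170g_like` configuration the site is
#' a diagnostic position and the alt allele is chosen equal to the
#' pseudogene base, so mis-mapped pseudogene reads mimic the variant. Sites
#' are drawn from the central half of the segment so simulated reads cover
#' them well.
#'
#' @param sim Output of [generate_reference_pair()].
#' @param scenario `"h137l_like"` or `"d170g_like"`.
#' @param seed Seed for site choice.
#' @return A [candidate_variant()] with `pseudo_homolog_base` filled.
#' @export
plant_variant <- function(sim, scenario = c("h137l_like", "d170g_like"),
                          seed = 1L) {
  scenario <- match.arg(scenario)
  L <- nchar(sim$pair$gene$sequence)
  central <- seq.int(ceiling(L / 4), floor(3 * L / 4))
  with_seed(seed, {
    if (scenario == "h137l_like") {
      eligible <- setdiff(central, sim$psvs$gene_pos)
      if (!length(eligible)) stop("no eligible non-PSV site for h137l_like")
      pos <- sample(eligible, 1L)
      ref <- substr(sim$pair$gene$sequence, pos, pos)
      candidate_variant("gene", pos, ref, other_base(ref),
                        pseudo_homolog_base = ref)
    } else {
      eligible <- intersect(central, sim$psvs$gene_pos)
      if (!length(eligible)) stop("no eligible PSV site for d170g_like")
      pos <- sample(eligible, 1L)
      i <- match(pos, sim$psvs$gene_pos)
      candidate_variant("gene", pos, sim$psvs$gene_base[i],
                        sim$psvs$pseudo_base[i],
                        pseudo_homolog_base = sim$psvs$pseudo_base[i])
    }
  })
}

make_reads <- function(hap_chars, starts, len, rate, contig, prefix, truth,
                       offset = 0L) {
  aln <- vapply(starts, function(s) {
    paste(inject_errors(hap_chars[s:(s + len - 1L)], rate), collapse = "")
  }, "")
  read_set(id = sprintf("%s_%06d", prefix, seq_along(starts)),
           contig = contig, start = starts + offset, aln = aln,
           origin_truth = truth)
}

#' Simulate short reads from the duplicated locus
#'
#' Each locus (the diploid gene and the pseudogene) is sequenced at
#' `cfg$short_depth`, i.e. `round(depth * L / read_len)` reads per locus.
#' Gene reads are drawn evenly from the two gene haplotypes; with a planted
#' variant one haplotype carries the alt allele. Pseudogene reads are
#' emitted at their source coordinates *on the gene coordinate system*,
#' modelling mis-mapping of pseudogene reads onto the gene directly rather
#' than simulating an aligner — the artefact mechanism under test. Every
#' read carries an `origin_truth` label.
#'
#' @param sim Output of [generate_reference_pair()].
#' @param variant A [candidate_variant()] from [plant_variant()], or `NULL`.
#' @param cfg A [sim_config()].
#' @param plant Plant the alt allele on gene haplotype A? Set `FALSE` to
#'   simulate the artefact-only situation in which the claimed variant does
#'   not exist and the apparent alt reads are all mis-mapped pseudogene
#'   reads.
#' @return A truth-labelled [read_set()] on contig `"gene"`.
#' @export
simulate_reads <- function(sim, variant, cfg, plant = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- nchar(sim$pair$gene$sequence)
  len <- cfg$short_read_len
  n <- round(cfg$short_depth * L / len)
  gA <- strsplit(sim$pair$gene$sequence, "")[[1]]
  gB <- gA
  if (!is.null(variant) && plant) gA[variant$pos] <- variant$alt
  pse <- strsplit(sim$pair$pseudogene$sequence, "")[[1]]
  with_seed(cfg$seed + 2L, {
    gene_starts <- sample.int(L - len + 1L, n, replace = TRUE)
    from_a <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pse_starts <- sample.int(L - len + 1L, n, replace = TRUE)
    ra <- make_reads(gA, gene_starts[from_a], len, cfg$error_rate, "gene",
                     "geneA", "gene")
    rb <- make_reads(gB, gene_starts[!from_a], len, cfg$error_rate, "gene",
                     "geneB", "gene")
    rp <- make_reads(pse, pse_starts, len, cfg$error_rate, "gene",
                     "pseudo", "pseudogene")
    out <- rbind(ra, rb, rp)
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Simulate a founder cohort of long amplicon reads
#'
#' Builds one amplicon reference, an anchor variant at its centre, and a
#' founder haplotype of `cfg$founder_hap_snps` SNP alleles shared by the
#' variant-bearing chromosome of every carrier. Each carrier's non-variant
#' chromosome carries its own independent random background haplotype.
#' Full-length amplicon reads are drawn at `cfg$long_depth` per allele with
#' uniform substitution error. Optionally one carrier's variant chromosome
#' is given an independent haplotype instead of the founder's, for negative
#' controls.
#'
#' @param cfg A [sim_config()].
#' @param independent_carrier Index of a carrier whose variant haplotype is
#'   made independent of the founder's (0 = none).
#' @return List: `anchor` ([candidate_variant()] on contig `"amplicon"`),
#'   `reads` (named list of per-carrier truth-labelled [read_set()]s),
#'   and `truth` (founder SNP positions/alleles, per-carrier backgrounds,
#'   and the independent-carrier index).
#' @export
simulate_founder_cohort <- function(cfg, independent_carrier = 0L) {
  stopifnot(inherits(cfg, "sim_config"), cfg$carriers >= 2L)
  L <- cfg$long_read_len
  with_seed(cfg$seed + 3L, {
    amplicon <- strsplit(random_dna(L), "")[[1]]
    anchor_pos <- L %/% 2L
    anchor_ref <- amplicon[anchor_pos]
    anchor_alt <- other_base(anchor_ref)
    usable <- setdiff(seq.int(50L, L - 50L), anchor_pos)
    founder_pos <- sort(sample(usable, cfg$founder_hap_snps))
    founder_alleles <- other_base(amplicon[founder_pos])
    reads <- list(); backgrounds <- list(); indep <- NULL
    for (k in seq_len(cfg$carriers)) {
      hap_var <- amplicon
      hap_var[anchor_pos] <- anchor_alt
      if (k == independent_carrier && cfg$founder_hap_snps > 0) {
        ipos <- sort(sample(setdiff(usable, founder_pos),
                            cfg$founder_hap_snps))
        ial <- other_base(amplicon[ipos])
        hap_var[ipos] <- ial
        indep <- data.frame(pos = ipos, allele = ial,
                            stringsAsFactors = FALSE)
      } else {
        hap_var[founder_pos] <- founder_alleles
      }
      bg_pos <- sort(sample(setdiff(usable, founder_pos),
                            cfg$founder_hap_snps))
      bg_al <- other_base(amplicon[bg_pos])
      hap_other <- amplicon
      hap_other[bg_pos] <- bg_al
      backgrounds[[k]] <- data.frame(pos = bg_pos, allele = bg_al,
                                     stringsAsFactors = FALSE)
      rv <- make_reads(hap_var, rep(1L, cfg$long_depth), L, cfg$error_rate,
                       "amplicon", sprintf("c%d_var", k), "gene")
      ro <- make_reads(hap_other, rep(1L, cfg$long_depth), L, cfg$error_rate,
                       "amplicon", sprintf("c%d_oth", k), "gene")
      rr <- rbind(rv, ro)
      class(rr) <- c("read_set", "data.frame")
      reads[[sprintf("carrier%d", k)]] <- rr
    }
    list(anchor = candidate_variant("amplicon", anchor_pos, anchor_ref,
                                    anchor_alt),
         reads = reads,
         truth = list(founder_positions = founder_pos,
                      founder_alleles = founder_alleles,
                      backgrounds = backgrounds,
                      independent_carrier = independent_carrier,
                      independent_haplotype = indep))
  })
}

#' Build a case-control allele table from cohort counts
#'
#' Heterozygous carriers contribute one variant allele each; probands are
#' diploid, so `n_case_probands` probands contribute `2 * n_case_probands`
#' case alleles.
#'
#' @param n_case_probands Number of case probands.
#' @param n_control_alleles Total control alleles observed.
#' @param case_carriers Heterozygous carriers among the cases.
#' @param seed Seed for assigning which probands carry the variant.
#' @param control_carriers Variant alleles among controls.
#' @return List: `table` (a [contingency_table()]) and `genotypes` (per-
#'   proband genotype data frame).
#' @export
simulate_cohort_counts <- function(n_case_probands, n_control_alleles,
                                   case_carriers, seed = 1L,
                                   control_carriers = 0L) {
  stopifnot(case_carriers <= n_case_probands)
  gt <- data.frame(sample = sprintf("case_%04d", seq_len(n_case_probands)),
                   genotype = "hom_ref", stringsAsFactors = FALSE)
  if (case_carriers > 0) {
    who <- with_seed(seed, sample.int(n_case_probands, case_carriers))
    gt$genotype[who] <- "het"
  }
  list(table = contingency_table(case_carriers,
                                 2L * n_case_probands - case_carriers,
                                 control_carriers,
                                 n_control_alleles - control_carriers),
       genotypes = gt)
}
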