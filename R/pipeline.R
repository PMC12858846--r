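#' Run a full adjudication scenario end-to-end on synthetic data
#'
#' Chains the pipeline the way it runs on real data: generate (or accept) a
#' gene/pseudogene pair, align it, discover diagnostic positions, plant the
#' scenario's candidate variant, simulate truth-labelled short reads, and
#' adjudicate the variant. The discovered — not the planted — PSVs feed the
#' adjudication, so the chain exercises alignment and read assignment
#' together.
#'
#' @param cfg A [sim_config()] with `variant_scenario` set.
#' @param plant Plant the variant on a gene haplotype (`FALSE` simulates the
#'   artefact-only situation for the `d170g_like` configuration).
#' @param params [adjudication_params()].
#' @return List: `adjudication`, `variant`, `psvs` (discovered),
#'   `psvs_truth` (planted), `reads`, `sim`.
#' @export
run_adjudication_scenario <- function(cfg, plant = TRUE,
                                      params = adjudication_params()) {
  stopifnot(inherits(cfg, "sim_config"),
            cfg$variant_scenario != "none")
  sim <- generate_reference_pair(cfg)
  aligned <- align_pair(sim$pair)
  psvs <- find_diagnostic_positions(aligned)
  variant <- plant_variant(sim, cfg$variant_scenario, seed = cfg$seed + 1L)
  reads <- simulate_reads(sim, variant, cfg, plant = plant)
  adj <- adjudicate_variant(variant, reads, psvs, params)
  list(adjudication = adj, variant = variant, psvs = psvs,
       psvs_truth = sim$psvs, reads = reads, sim = sim)
}

#' Run the founder-haplotype analysis on a simulated carrier cohort
#'
#' Splits each carrier's amplicon reads at the anchor, discovers
#' heterozygous sites per carrier, then genotypes every carrier's two
#' allele-split haplotypes on the *union* of the discovered sites — a
#' carrier homozygous at another carrier's site is simply called homozygous
#' there, keeping the panels comparable across samples.
#'
#' @param cfg A [sim_config()].
#' @param independent_carrier Passed to [simulate_founder_cohort()].
#' @param min_depth,min_majority Consensus thresholds.
#' @return List: `report` (a [compare_haplotypes()] result), `haplotypes`,
#'   `positions` (the union SNP panel), `cohort` (the simulation with
#'   truth).
#' @export
run_founder_scenario <- function(cfg, independent_carrier = 0L,
                                 min_depth = 20L, min_majority = 0.8) {
  cohort <- simulate_founder_cohort(cfg, independent_carrier)
  splits <- lapply(cohort$reads, split_by_anchor, anchor = cohort$anchor)
  panel <- sort(unique(unlist(lapply(splits, discover_het_sites,
                                     min_depth = min_depth,
                                     min_majority = min_majority))))
  haps <- list()
  for (nm in names(splits)) {
    sp <- splits[[nm]]
    haps <- c(haps, list(
      call_haplotype(sp$alt_reads, panel, min_depth, min_majority,
                     sample_id = nm, anchor_allele = cohort$anchor$alt,
                     role = "variant"),
      call_haplotype(sp$ref_reads, panel, min_depth, min_majority,
                     sample_id = nm, anchor_allele = cohort$anchor$ref,
                     role = "other")))
  }
  list(report = compare_haplotypes(haps), haplotypes = haps,
       positions = panel, cohort = cohort)
}
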