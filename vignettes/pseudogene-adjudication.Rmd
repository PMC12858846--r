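---
title: "Adjudicating variants at gene/pseudogene loci: methods and design"
author: "psvkit"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Adjudicating variants at gene/pseudogene loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psvkit)
```

## The problem

A candidate disease variant that falls near a highly homologous pseudogene is
suspect by construction. Short reads from the pseudogene mis-map onto the
gene; PCR primers co-amplify both loci; and when the pseudogene's fixed base
at the homologous column happens to equal the candidate's alternate allele,
an entirely wild-type gene can present as a heterozygous variant call. The
classic instances are the SMN1/SMN2 pair in spinal muscular atrophy and the
RP9/RP9P pair in dominant retinitis pigmentosa; psvkit implements the
inference chain needed to adjudicate such variants, as a reusable, tested
pipeline:

1. **Paralog alignment and PSV discovery** — align the gene and pseudogene
   segments globally, quantify local identity, and extract *paralogous
   sequence variants* (PSVs): alignment columns where the two copies carry
   different bases.
2. **Read adjudication** — assign each read to gene or pseudogene by PSV
   voting, then decide whether the candidate variant is gene-derived or a
   plausible pseudogene artefact.
3. **Allele-split haplotyping** — partition long amplicon reads by the base
   at an anchor variant, call per-allele consensus haplotypes, and test
   whether variant-bearing haplotypes across carriers are consistent with a
   single founder.
4. **Locus filtering** — triage linked-locus candidates by shared
   heterozygosity, population rarity, microsatellite context and in-silico
   scores.
5. **Exact enrichment** — Fisher's exact test computed from hypergeometric
   point probabilities, sized for population-database margins.
6. **ACMG combination** — a rule engine for the ACMG/AMP evidence framework
   with support for manually re-weighted strengths.
7. **Synthetic data** — a seeded simulator that generates every input the
   pipeline needs, with complete truth labels.

## Read adjudication model

### PSV voting

A read covering a PSV carries either the gene base (a *gene vote*), the
pseudogene base (a *pseudogene vote*), or some third base — a sequencing
error or a genuine rare allele — which **abstains**. Abstention, rather than
counting against an origin, makes single errors harmless: at 1% substitution
error, two thirds of errors at a PSV produce an off-paralog base that simply
drops out of the tally. A read is labelled by strict majority vote, and only
when it covers at least `min_informative` PSVs (default 2): a single-PSV
call would let one error flip a read's origin, and the published practice
this replaces — visual inspection of read stacks in a genome browser —
implicitly demands the same redundancy.

With the package's default divergence (87.5% identity, i.e. one PSV per 8 bp
on average), a 150 bp read covers ~18 PSVs, so the label is effectively
always available and essentially always correct; the property suite verifies
100% accuracy at zero error and ≥95% at 1% error for reads with ≥3 PSVs.

### The two artefact configurations

Let `ref` and `alt` be the candidate's alleles and `q` the pseudogene base
at the homologous column:

* **`q ≠ alt`** (the H137L-like configuration, which includes `q = ref`):
  mis-mapped pseudogene reads can only contribute non-alt bases, so alt
  reads cannot be bleed-through. The verdict is `gene_derived` when at least
  `min_alt_reads` (default 5) alt reads exist and the alt fraction among
  gene-labelled reads lies in the heterozygous band `[0.2, 0.8]` — the
  conventional germline-het expectation.
* **`q = alt`** (the D170G-like configuration): the artefact is live, since
  every mis-mapped pseudogene read carries the alt base. The verdict is
  `gene_derived_confirmed` only when at least `min_alt_reads` *gene-labelled*
  reads carry the alt; otherwise `pseudogene_artefact_possible`.

Coverage below `min_depth` (default 20) returns `indeterminate` with a
reason, never an error. One subtlety: in the `q = alt` configuration the
variant site is itself a PSV, and a true variant-bearing gene read would
"vote pseudogene" there. The adjudicator therefore excludes any PSV at the
variant position from voting — the site under test must not double as its
own evidence.

Defaults (`min_depth` 20, `min_alt_reads` 5) are chosen to be comfortably
met by ~30× whole-genome short-read data and by deeply sequenced amplicons;
they are deliberately conservative for lower-coverage data.

## Allele-split founder analysis

Amplicon long reads spanning an anchor variant are split by the base they
carry at the anchor; each side is then a pot of reads from a single
chromosome. Consensus calling at a position requires depth ≥ `min_depth`
(default 20) and a majority fraction ≥ `min_majority` (default 0.8);
anything weaker is a no-call. The SNP panel is data-driven: all positions
where a sample's two splits are confidently called and disagree
(heterozygous sites), pooled across samples into a union panel so that every
sample is genotyped at every site — a sample homozygous at another sample's
site is simply recorded as homozygous there, keeping panels comparable.

Founder consistency requires two things: all variant-anchored haplotypes
identical at every jointly-called site, **and** each sample's variant
haplotype differing from that sample's own non-variant haplotype at one or
more sites. The second condition guards against vacuous consistency when
there is no haplotype signal at all. With no jointly-called sites the report
is flagged rather than decided. The package reports concordance; whether a
given concordance establishes a founder allele in real cohorts (where
population haplotype sharing is possible) is left to the analyst.

Flanking-SNP genotypes — sites outside the amplicon whose phase cannot be
observed from it — can be attached to the report as a genotype-concordance
table but never enter the consistency decision.

## Exact enrichment test

`fisher_exact()` computes the hypergeometric point probabilities of all
tables with the observed margins in log space via `lchoose` (log-gamma),
summing with the usual max-shift. Margins of order 10^6 — a handful of case
alleles against a population database — overflow naive factorials, which is
why the log-space route is mandatory rather than an optimisation. One-sided
(greater) is the upper tail of the case-variant cell; two-sided is the
conventional sum of point probabilities not exceeding the observed table's
(relative tolerance 1e-7, matching `stats::fisher.test`). The test suite
cross-checks against full-table enumeration for small margins and against
`phyper` for the million-scale table, keeping implementation and oracle on
distinct code paths.

Frequency arithmetic uses round-half-even significant-figure rounding
(`signif`), so e.g. pooled counts of 237 variant alleles in 1,812,154 round
to 0.00013 at two significant figures, and the "1 in N alleles" form is
`round(1/rounded)`. The dominant-disease sanity check compares the expected
carrier frequency `2f(1-f)·penetrance` against a disease prevalence and
flags incompatibility with a fully penetrant dominant cause.

## Locus filtering

The triage keeps variants that are inside the linked region, heterozygous in
every named sample, and have population MAF strictly below `maf_max`
(default 0.001). A missing MAF is kept: absence from population databases is
itself evidence of rarity. Score classification is deliberately a single
configurable rule — deleterious iff CADD > 15, or SpliceAI > 0.4, or both
FATHMM-MKL scores (coding and non-coding p-values) > 0.5 — with all
comparisons strict, because the thresholds are quoted as strict
inequalities. ReMM is carried through for reporting but not thresholded: the
service's own cut-off is not published, and reverse-engineering one from a
handful of labelled rows would be curve-fitting, not a method.

The microsatellite test calls an indel context repetitive when the position
lies in a perfect tandem repeat of unit 1–6 bp with at least 3 full copies
and a tract of at least 8 bases — conventional short-tandem-repeat bounds.
An exhaustive brute-force scanner serves as the oracle in tests.

## ACMG engine

Evidence items carry a code and an *applied* strength that defaults to the
code's guideline level but may be re-weighted (PS4 applied at strong on
enrichment evidence; PP1 escalated to very strong on deep cosegregation, per
published cosegregation-upgrade practice). The combining table follows the
published guideline: e.g. pathogenic from one very-strong plus one strong
criterion, or two strong, or one strong plus three moderate; likely
pathogenic from one strong plus one or two moderate, three moderate, and so
on; benign from one stand-alone or two strong-benign; conflicting
pathogenic-side and benign-side rules yield uncertain significance. One
addition beyond the published table: two very-strong criteria classify as
pathogenic. The guideline's table omits this combination (it rarely arises
without re-weighting), but with re-weighting permitted its absence would
make the engine non-monotone — upgrading a strong criterion to very strong
could *downgrade* a pathogenic classification — so the engine closes the
gap in the only direction consistent with evidence ordering. A property
test enforces monotonicity: adding or upgrading pathogenic evidence never
moves the class toward benign.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults are the package's reference study conditions:

| parameter | default | rationale |
|---|---|---|
| `gene_length` | 10,000 bp | a gene-scale segment |
| `identity` | 0.875 | the RP9/RP9P-like divergence class (~1 PSV / 8 bp) |
| `short_read_len` / `short_depth` | 150 bp / 30× | standard WGS |
| `long_read_len` / `long_depth` | 9,000 bp / 2,000× | long-range amplicon sequencing |
| `error_rate` | 0.01 | uniform substitution error |
| `carriers` / `founder_hap_snps` | 4 / 12 | founder cohort scale |

The pseudogene is the gene with exactly `round((1-identity)·L)` seeded
substitutions — no indels by default, so the planted substitution set is the
exact truth for PSV discovery and counts are deterministic. Short reads are
drawn per locus at the stated depth (the diploid gene yields
`round(depth·L/len)` reads split between its two haplotypes, and the
pseudogene the same number again), and pseudogene reads are emitted directly
in gene coordinates. This models the mis-mapping artefact itself rather than
simulating an aligner: read placement is exact by construction, so what the
tests exercise is the adjudication logic, isolated from aligner behaviour.
Amplicon reads are full-length, as dominant read-length distributions from a
single long-range product approximately are.

What the simulator deliberately does **not** emulate: indel-dominated
long-read error profiles (errors are uniform substitutions at the same rate
for both read types), quality scores, coverage bias, chimeric reads,
alignment ambiguity at the locus boundary, and population haplotype
structure (background haplotypes are independent random draws). Passing
tests therefore demonstrate that the inference chain is correct when
mis-mapping is the only confounder — they do not certify performance on
real nanopore error profiles or real population LD.

## Numerical choices

* **Alignment scoring** (match +1, mismatch −2, gap open −6, gap extend −1):
  for ~90%-identical paralogs these penalties keep true substitutions
  aligned as substitution columns instead of absorbing them into spurious
  indels, which is what PSV extraction needs. Alignment is delegated to
  `Biostrings::pairwiseAlignment`, whose traceback is deterministic for
  fixed parameters; because mismatch (−2) is strictly cheaper than any gap
  (≤ −7), mismatches are preferred over gaps wherever possible, and residual
  exact ties follow the aligner's canonical traceback order.
* **Window and region identity** are measured in alignment columns (the
  windows the method inspects are alignments, not genomic intervals); gap
  columns count as non-matches. For near-identical paralogs this coincides
  with BLAST's matches-over-alignment-length convention.
* **In-silico PCR** tolerates `max_mismatch` (default 2) mismatches per
  primer outside the 3 terminal 3'-end bases, which must match exactly —
  the standard polymerase-extension specificity heuristic. Product size is
  outer edge to outer edge, inclusive of both primer footprints.
* **Sequences with more than 50% N** are refused by the aligner rather than
  silently producing a garbage alignment.
* **Consensus ties** cannot arise: the majority threshold is ≥ 0.8 > 0.5.
* **Seeding**: every stochastic routine takes an explicit seed (or derives
  offsets from `sim_config$seed`) and restores the caller's RNG state, so
  simulations are reproducible and composable.

## Problem sizes in the test suite

The suite runs the full chain at sizes chosen to exercise every code path
with comfortable statistical margins: scenario-recovery replicates use a
4 kb locus at 30× per locus (≈500 PSVs, ~60× at the variant site);
read-classification accuracy uses a 10 kb locus with ≥10,000 reads; founder
replicates use the full 9 kb amplicon with 12 founder SNPs at 200× per
allele — at which depth the per-site consensus error probability is
negligible, so 20/20 replicate recovery is the expected outcome, not a
lucky draw. The acceptance script (`scripts/acceptance.R`) re-runs the same
computations from scratch at fixed, documented sizes.

## Known limitations

* The alignment is global; segments must already be trimmed to roughly
  homologous regions (genome-wide paralog discovery is out of scope).
* No statistical phasing: haplotypes come only from physical allele splits
  of reads spanning the anchor. Variants outside the amplicon cannot be
  phased, only tabulated.
* The filter operates on small variants; CNV/SV evidence is consumed
  elsewhere.
* The ACMG engine covers criterion *combination*, not criterion
  *assignment*: apart from PS4-from-enrichment, deciding which criteria
  apply remains the analyst's job.
* Identity, error and depth defaults describe one locus family; other
  gene/pseudogene pairs (e.g. higher identity, lower PSV density) may need
  `min_informative` and read-length reconsidered — at 99.9% identity a
  150 bp read often covers no PSV at all.
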