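Package: psvkit
Title: Gene-Pseudogene Read Adjudication and Founder Haplotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adjudicating candidate disease variants that fall in
    genomic regions duplicated as highly homologous pseudogenes. Aligns gene
    and pseudogene segments to discover paralogous sequence variants (PSVs),
    assigns short and long reads to their locus of origin by PSV voting,
    decides whether a candidate variant is gene-derived or a pseudogene
    artefact, splits long amplicon reads by the allele at an anchor variant to
    call per-allele haplotypes and test founder sharing across carriers,
    filters linked-locus candidate variants by shared heterozygosity, rarity,
    microsatellite context and in-silico scores, computes exact case-control
    allele enrichment from the hypergeometric distribution, and combines ACMG
    evidence criteria into a five-tier classification. Includes a seeded
    simulator that generates homologous reference pairs, planted variants,
    labelled reads and cohorts so the whole pipeline is testable without
    external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    GenomicAlignments,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
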