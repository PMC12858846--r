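anchor_t_a <- function(pos = 50L)
  candidate_variant("amp", pos, "T", "A")

test_that("allele splitting partitions reads by the anchor base", {
  aln_t <- paste0(strrep("C", 49), "T", strrep("C", 50))
  aln_a <- paste0(strrep("C", 49), "A", strrep("C", 50))
  reads <- read_set(sprintf("r%d", 1:10), "amp", rep(1L, 10),
                    c(rep(aln_t, 5), rep(aln_a, 5)))
  sp <- split_by_anchor(reads, anchor_t_a())
  expect_equal(nrow(sp$ref_reads), 5)
  expect_equal(nrow(sp$alt_reads), 5)
  expect_equal(sp$unassigned, 0)

  # a read not covering the anchor is unassigned
  reads2 <- rbind(reads, read_set("far", "amp", 200L, strrep("G", 30)))
  class(reads2) <- c("read_set", "data.frame")
  sp2 <- split_by_anchor(reads2, anchor_t_a())
  expect_equal(sp2$unassigned, 1)
  expect_equal(nrow(sp2$ref_reads) + nrow(sp2$alt_reads) + sp2$unassigned,
               nrow(reads2))
})

test_that("splitting a simulated heterozygote stays within binomial bounds", {
  set.seed(51)
  n <- 2000
  allele <- sample(c("T", "A"), n, replace = TRUE)
  aln <- paste0(strrep("G", 49), allele, strrep("G", 50))
  reads <- read_set(sprintf("r%d", 1:n), "amp", rep(1L, n), aln)
  sp <- split_by_anchor(reads, anchor_t_a())
  expect_equal(nrow(sp$ref_reads) + nrow(sp$alt_reads), n)
  lo <- qbinom(0.005, n, 0.5); hi <- qbinom(0.995, n, 0.5)
  expect_gte(nrow(sp$alt_reads), lo)
  expect_lte(nrow(sp$alt_reads), hi)
})

test_that("zero anchor coverage gives an empty split with a warning", {
  reads <- read_set("r1", "amp", 200L, strrep("G", 30))
  expect_warning(sp <- split_by_anchor(reads, anchor_t_a()), "no reads")
  expect_equal(nrow(sp$ref_reads), 0)
  expect_equal(sp$unassigned, 1)
})

test_that("consensus calling recovers an error-free planted haplotype", {
  set.seed(52)
  hap <- strsplit(random_seq(200), "")[[1]]
  positions <- c(20L, 80L, 150L)
  reads <- read_set(sprintf("r%d", 1:30), "amp", rep(1L, 30),
                    rep(paste(hap, collapse = ""), 30))
  h <- call_haplotype(reads, positions, min_depth = 20, min_majority = 0.8)
  expect_equal(h$calls$pos, positions)
  expect_equal(h$calls$allele, hap[positions])
  expect_equal(h$no_call_count, 0)
  expect_true(all(h$calls$majority_fraction == 1))
})

test_that("low depth is a no-call and a 90% majority beats a 0.8 threshold", {
  hap <- strrep("A", 100)
  reads <- read_set(sprintf("r%d", 1:10), "amp", rep(1L, 10), rep(hap, 10))
  h <- call_haplotype(reads, c(50L), min_depth = 20)
  expect_equal(nrow(h$calls), 0)
  expect_equal(h$no_call_count, 1)

  # 10% discordant reads at one site
  aln <- c(rep(strrep("A", 100), 18),
           rep(paste0(strrep("A", 49), "C", strrep("A", 50)), 2))
  reads2 <- read_set(sprintf("r%d", 1:20), "amp", rep(1L, 20), aln)
  h2 <- call_haplotype(reads2, c(50L), min_depth = 20, min_majority = 0.8)
  expect_equal(h2$calls$allele, "A")
  expect_equal(h2$calls$majority_fraction, 0.9)
})

test_that("founder comparison requires identity across variant haplotypes and contrast within samples", {
  mk <- function(sample, role, alleles, pos = c(10L, 20L, 30L)) {
    structure(list(sample_id = sample, anchor_allele = "A", role = role,
                   calls = data.frame(pos = pos, allele = alleles,
                                      depth = 100,
                                      majority_fraction = 1,
                                      stringsAsFactors = FALSE),
                   no_call_count = 0L),
              class = "haplotype")
  }
  founder <- c("A", "C", "G")
  bg1 <- c("T", "C", "G"); bg2 <- c("A", "T", "G")
  haps <- list(mk("s1", "variant", founder), mk("s1", "other", bg1),
               mk("s2", "variant", founder), mk("s2", "other", bg2))
  rep1 <- compare_haplotypes(haps)
  expect_equal(rep1$concordance, 1.0)
  expect_true(rep1$founder_consistent)

  # one discordant jointly-called site
  haps2 <- haps
  haps2[[3]] <- mk("s2", "variant", c("A", "C", "T"))
  rep2 <- compare_haplotypes(haps2)
  expect_lt(rep2$concordance, 1)
  expect_false(rep2$founder_consistent)

  # variant haplotype identical to the sample's own background: no contrast
  haps3 <- list(mk("s1", "variant", founder), mk("s1", "other", founder),
                mk("s2", "variant", founder), mk("s2", "other", bg2))
  expect_false(compare_haplotypes(haps3)$founder_consistent)

  # disjoint panels: flagged, not an error
  haps4 <- list(mk("s1", "variant", founder),
                mk("s2", "variant", founder, pos = c(40L, 50L, 60L)))
  rep4 <- compare_haplotypes(haps4)
  expect_equal(rep4$compared_sites, 0)
  expect_true(is.na(rep4$founder_consistent))
})

test_that("simulated carrier cohorts are recognised as founder-consistent", {
  cfg <- sim_config(seed = 61, long_read_len = 3000, long_depth = 60,
                    carriers = 3)
  pos_res <- run_founder_scenario(cfg)
  expect_true(pos_res$report$founder_consistent)
  expect_true(all(pos_res$cohort$truth$founder_positions %in%
                    pos_res$positions))
  neg_res <- run_founder_scenario(cfg, independent_carrier = 2)
  expect_false(neg_res$report$founder_consistent)
})

test_that("depth-capped subsampling is seeded and reproducible", {
  set.seed(62)
  reads <- read_set(sprintf("r%d", 1:500), "amp", rep(1L, 500),
                    replicate(500, random_seq(40)))
  a <- subsample_reads(reads, 100, seed = 9)
  b <- subsample_reads(reads, 100, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 100)
  expect_identical(subsample_reads(reads, 1000, seed = 9), reads)
})

test_that("meiotic distance adds the generation counts and is symmetric", {
  expect_equal(meiotic_distance(7, 7), 14)
  expect_equal(meiotic_distance(0, 5), 5)
  expect_equal(meiotic_distance(1, 1), 2)
  for (i in 1:5) {
    g <- sample(0:10, 2)
    expect_equal(meiotic_distance(g[1], g[2]), meiotic_distance(g[2], g[1]))
  }
  expect_error(meiotic_distance(-1, 3), "non-negative")
})
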