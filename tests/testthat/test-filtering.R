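toy_records <- function() {
  df <- data.frame(
    contig = c("chr7", "chr7", "chr7", "chr7", "chr1", "chr7"),
    pos = c(33096550L, 33500000L, 33600000L, 33700000L, 500000L, 33800000L),
    ref = c("T", "G", "C", "A", "T", "C"),
    alt = c("A", "A", "T", "G", "C", "G"),
    maf = c(NA, 0.0001, NA, 0.05, NA, NA),
    A = c("het", "het", "hom_alt", "het", "het", "het"),
    B = c("het", "het", "hom_alt", "het", "het", "hom_ref"),
    stringsAsFactors = FALSE)
  df
}

test_that("shared-het, rarity and region filters keep exactly the expected variants", {
  cfg <- rp9_filter_config()
  res <- filter_candidates(toy_records(), c("A", "B"), cfg)
  kept <- sprintf("%s:%d", res$snvs$contig, res$snvs$pos)
  expect_equal(sort(kept), c("chr7:33096550", "chr7:33500000"))
  expect_equal(nrow(res$indels), 0)
  expect_equal(nrow(res$exclusions), 4)
  expect_setequal(res$exclusions$rule,
                  c("not_shared_het", "maf_not_rare", "outside_region"))
})

test_that("every dropped variant is logged and order does not matter", {
  cfg <- rp9_filter_config()
  rec <- toy_records()
  res1 <- filter_candidates(rec, c("A", "B"), cfg)
  shuffled <- rec[c(4, 2, 6, 1, 5, 3), ]
  res2 <- filter_candidates(shuffled, c("A", "B"), cfg)
  expect_equal(nrow(res1$snvs) + nrow(res1$indels) + nrow(res1$exclusions),
               nrow(rec))
  expect_setequal(sprintf("%s:%d", res2$snvs$contig, res2$snvs$pos),
                  sprintf("%s:%d", res1$snvs$contig, res1$snvs$pos))
  expect_setequal(res2$exclusions$variant, res1$exclusions$variant)
})

test_that("MAF exactly at the threshold is excluded and empty input passes through", {
  cfg <- rp9_filter_config()
  rec <- toy_records()[1, ]
  rec$maf <- 0.001
  res <- filter_candidates(rec, c("A", "B"), cfg)
  expect_equal(nrow(res$snvs), 0)
  expect_equal(res$exclusions$rule, "maf_not_rare")

  res0 <- filter_candidates(toy_records()[0, ], c("A", "B"), cfg)
  expect_equal(nrow(res0$snvs), 0)
  expect_equal(nrow(res0$exclusions), 0)
})

test_that("indels are returned separately from SNVs", {
  rec <- toy_records()[1:2, ]
  rec$ref[2] <- "GAA"      # 3-bp deletion, left-anchored
  res <- filter_candidates(rec, c("A", "B"), rp9_filter_config())
  expect_equal(nrow(res$snvs), 1)
  expect_equal(nrow(res$indels), 1)
})

test_that("a missing sample is an error naming it", {
  expect_error(filter_candidates(toy_records(), c("A", "Z"),
                                 rp9_filter_config()),
               "Z")
})

test_that("microsatellite context detects planted repeat tracts", {
  win <- paste0(strrep("G", 15), "ACACACACACAC", strrep("G", 15))
  res <- microsatellite_context(win, 20)
  expect_true(res$is_microsatellite)
  expect_equal(res$unit, "AC")
  expect_equal(res$copies, 6)

  hom <- paste0(strrep("CGT", 6), "AAAAAAAA", strrep("CGT", 6))
  res2 <- microsatellite_context(hom, 22)
  expect_true(res2$is_microsatellite)
  expect_equal(res2$unit, "A")
  expect_equal(res2$copies, 8)

  expect_error(microsatellite_context("ACGT", 2), "40")
})

test_that("a position outside any tract is not called a microsatellite", {
  win <- paste0("ACACACACACAC", strrep("G", 10), "TCGATCGTTAGCGTACGGAT")
  expect_false(microsatellite_context(win, 30)$is_microsatellite)
})

test_that("microsatellite calls agree with an exhaustive scanner on random 60-mers", {
  set.seed(71)
  n_checked <- 0
  for (i in 1:1000) {
    s <- random_seq(60)
    # occasionally plant a repeat so positives are represented
    if (i %% 4 == 0) {
      unit <- random_seq(sample(1:6, 1))
      copies <- sample(3:8, 1)
      tract <- strrep(unit, copies)
      if (nchar(tract) < 50) {
        at <- sample(1:(60 - nchar(tract)), 1)
        s <- paste0(substr(s, 1, at - 1), tract,
                    substr(s, at + nchar(tract), 60))
        s <- substr(s, 1, 60)
      }
    }
    pos <- sample(5:55, 1)
    got <- microsatellite_context(s, pos)$is_microsatellite
    expect_equal(got, oracle_in_str(s, pos), info = paste(s, pos))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
})

test_that("score classification reproduces the shipped 11-row score table row-for-row", {
  tab <- read_annotation_table(table1_path())
  cls <- classify_annotation_table(tab, rp9_filter_config())
  expect_equal(sum(cls$label == "deleterious"), 1)
  expect_equal(cls$position[cls$label == "deleterious"], "chr7:33096550T>A")
  expect_equal(sum(cls$label == "low_evidence"), 10)
})

test_that("score thresholds are strict and missing scores never fire a clause", {
  cfg <- rp9_filter_config()
  at_cut <- list(cadd = 15.0, splice_ai = NA, fathmm_coding = NA,
                 fathmm_noncoding = NA)
  expect_equal(score_classify(at_cut, cfg)$label, "low_evidence")
  above <- list(cadd = 15.01, splice_ai = NA, fathmm_coding = NA,
                fathmm_noncoding = NA)
  expect_equal(score_classify(above, cfg)$label, "deleterious")
  splice <- list(cadd = 1, splice_ai = 0.41, fathmm_coding = NA,
                 fathmm_noncoding = NA)
  expect_equal(score_classify(splice, cfg)$label, "deleterious")
  fathmm_half <- list(cadd = 1, splice_ai = NA, fathmm_coding = 0.9,
                      fathmm_noncoding = NA)
  expect_equal(score_classify(fathmm_half, cfg)$label, "low_evidence")
  expect_error(score_classify(list(cadd = NA, splice_ai = NA,
                                   fathmm_coding = NA,
                                   fathmm_noncoding = NA), cfg),
               "missing")
})
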