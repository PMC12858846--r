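test_that("identity and single-substitution alignments are exact", {
  a <- align_pair(seq_record("g", "ACGT"), seq_record("p", "ACGT"))
  expect_equal(length(a$gene_track), 4)
  expect_equal(nrow(find_diagnostic_positions(a)), 0)

  b <- align_pair(seq_record("g", "ACGT"), seq_record("p", "AGGT"))
  psv <- find_diagnostic_positions(b)
  expect_equal(nrow(psv), 1)
  expect_equal(psv$gene_pos, 2L)
  expect_equal(psv$gene_base, "C")
  expect_equal(psv$pseudo_base, "G")
})

test_that("planted substitutions are recovered as mismatch columns", {
  set.seed(101)
  g <- random_seq(300)
  mut <- mutate_at(g, 7)
  a <- align_pair(seq_record("g", g), seq_record("p", mut$mutated))
  psv <- find_diagnostic_positions(a)
  expect_equal(psv$gene_pos, mut$pos)
  expect_equal(psv$gene_base, mut$from)
  expect_equal(psv$pseudo_base, mut$to)
})

test_that("alignment tracks reconstruct the inputs after gap stripping", {
  set.seed(7)
  for (i in 1:15) {
    g <- random_seq(sample(80:300, 1))
    # substitutions plus a short indel to force gap columns
    mut <- mutate_at(g, sample(3:10, 1))
    p <- mut$mutated
    cut <- sample(20:(nchar(p) - 20), 1)
    p_del <- paste0(substr(p, 1, cut - 1),
                    substr(p, cut + sample(1:4, 1), nchar(p)))
    a <- align_pair(seq_record("g", g), seq_record("p", p_del))
    expect_identical(paste(a$gene_track[a$gene_track != "-"], collapse = ""), g)
    expect_identical(paste(a$pseudo_track[a$pseudo_track != "-"],
                           collapse = ""), p_del)
    expect_false(is.unsorted(a$gene_pos[!is.na(a$gene_pos)], strictly = TRUE))
    expect_false(is.unsorted(a$pseudo_pos[!is.na(a$pseudo_pos)],
                             strictly = TRUE))
  }
})

test_that("gap columns are excluded from the PSV list but counted", {
  g <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  # three substitutions and one single-base deletion
  p <- strsplit(g, "")[[1]]
  p[c(3, 11, 22)] <- c("T", "C", "G")
  p <- paste(p[-16], collapse = "")
  a <- align_pair(seq_record("g", g), seq_record("p", p))
  psv <- find_diagnostic_positions(a)
  expect_equal(nrow(psv), 3)
  expect_equal(attr(psv, "gap_columns"), 1)
})

test_that("window identity counts mismatches in alignment columns", {
  set.seed(3)
  g <- random_seq(200)
  a <- align_pair(seq_record("g", g), seq_record("p", g))
  w <- window_identity(a, 100, 60)
  expect_equal(w$mismatch_count, 0)
  expect_equal(w$identity, 1.0)
  expect_equal(w$columns, 121)

  # toy 21-column window with 2 planted mismatches
  x <- strsplit(g, "")[[1]]
  x[c(95, 104)] <- vapply(x[c(95, 104)],
                          function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  a2 <- align_pair(seq_record("g", g), seq_record("p", paste(x, collapse = "")))
  w2 <- window_identity(a2, 100, 10)
  expect_equal(w2$columns, 21)
  expect_equal(w2$mismatch_count, 2)
  expect_equal(w2$matches, 19)

  expect_error(window_identity(a, 5000, 60), "range error")
})

test_that("a PSV-dense 121-column window built like the target locus yields 11 mismatches", {
  set.seed(11)
  g <- random_seq(2001)
  x <- strsplit(g, "")[[1]]
  center <- 1001L
  planted <- sort(sample(setdiff((center - 60):(center + 60), center), 11))
  x[planted] <- vapply(x[planted],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  a <- align_pair(seq_record("g", g), seq_record("p", paste(x, collapse = "")))
  w <- window_identity(a, center, 60)
  expect_equal(w$columns, 121)
  expect_equal(w$mismatch_count, 11)
})

test_that("region identity reproduces a planted divergence level", {
  set.seed(5)
  g <- random_seq(1000)
  mut <- mutate_at(g, 125)
  a <- align_pair(seq_record("g", g), seq_record("p", mut$mutated))
  expect_equal(region_identity(a, c(1, 1000)), 87.5)
  a_id <- align_pair(seq_record("g", substr(g, 1, 100)),
                     seq_record("p", substr(g, 1, 100)))
  expect_equal(region_identity(a_id, c(1, 100)), 100.0)
  expect_error(region_identity(a, c(2000, 3000)), "empty region")
})

test_that("region identity is invariant under reverse-complementing both sequences", {
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  set.seed(9)
  for (i in 1:5) {
    g <- random_seq(400)
    mut <- mutate_at(g, 30)
    a_f <- align_pair(seq_record("g", g), seq_record("p", mut$mutated))
    a_r <- align_pair(seq_record("g", rc(g)), seq_record("p", rc(mut$mutated)))
    expect_equal(region_identity(a_f, c(51, 350)),
                 region_identity(a_r, c(400 - 350 + 1, 400 - 51 + 1)))
  }
})

test_that("N-dominated sequences are refused", {
  expect_error(align_pair(seq_record("g", strrep("N", 30)),
                          seq_record("p", random_seq(30))),
               "more than half")
})

test_that("PSV tables round-trip through TSV", {
  set.seed(13)
  g <- random_seq(150)
  mut <- mutate_at(g, 5)
  psv <- find_diagnostic_positions(
    align_pair(seq_record("g", g), seq_record("p", mut$mutated)))
  p <- tempfile(fileext = ".tsv")
  write_psv_table(psv, p)
  back <- read_psv_table(p)
  expect_equal(back$gene_pos, psv$gene_pos)
  expect_equal(back$pseudo_base, psv$pseudo_base)
})

test_that("in-silico PCR finds a planted product of known size", {
  set.seed(21)
  fwd <- random_seq(20)
  rev <- random_seq(20)
  insert <- random_seq(480)
  template <- paste0(random_seq(250), fwd, insert,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(rev))), random_seq(250))
  hits <- in_silico_pcr(seq_record("t", template), primer_pair(fwd, rev))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$product_size, 20 + 480 + 20)
  expect_equal(hits$mismatches, 0)
})

test_that("in-silico PCR product sizes match planted constructions", {
  set.seed(22)
  for (i in 1:200) {
    fwd <- random_seq(sample(18:24, 1))
    rev <- random_seq(sample(18:24, 1))
    gap <- sample(50:900, 1)
    template <- paste0(random_seq(sample(30:150, 1)), fwd, random_seq(gap),
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(rev))),
                       random_seq(sample(30:150, 1)))
    hits <- in_silico_pcr(template, primer_pair(fwd, rev))
    expect_true(nrow(hits) >= 1)
    expect_true((nchar(fwd) + gap + nchar(rev)) %in% hits$product_size)
  }
})

test_that("absent primers yield no product and short primers error", {
  expect_equal(nrow(in_silico_pcr(random_seq(500),
                                  primer_pair(strrep("A", 20),
                                              strrep("C", 20)))), 0)
  expect_error(primer_pair("ACGTACGTACGT", strrep("A", 20)), "15")
})

test_that("3'-end mismatches disqualify a primer site", {
  set.seed(23)
  fwd <- random_seq(20)
  rev <- random_seq(20)
  rc_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  # break the forward primer's terminal 3' base at its only site
  fwd_site <- strsplit(fwd, "")[[1]]
  fwd_site[20] <- setdiff(c("A", "C", "G", "T"), fwd_site[20])[1]
  template <- paste0(random_seq(100), paste(fwd_site, collapse = ""),
                     random_seq(300), rc_rev, random_seq(100))
  expect_equal(nrow(in_silico_pcr(template, primer_pair(fwd, rev))), 0)
  # an internal mismatch (outside the last 3 bases) is tolerated
  fwd_site2 <- strsplit(fwd, "")[[1]]
  fwd_site2[5] <- setdiff(c("A", "C", "G", "T"), fwd_site2[5])[1]
  template2 <- paste0(random_seq(100), paste(fwd_site2, collapse = ""),
                      random_seq(300), rc_rev, random_seq(100))
  hits <- in_silico_pcr(template2, primer_pair(fwd, rev))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 1)
})

test_that("primer specificity flags pairs amplifying both loci", {
  set.seed(24)
  fwd <- random_seq(20); rev <- random_seq(20)
  rc_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  shared <- paste0(random_seq(60), fwd, random_seq(200), rc_rev, random_seq(60))
  pair_both <- reference_pair(seq_record("gene", shared),
                              seq_record("pseudogene", shared))
  expect_true(primer_specificity(pair_both, primer_pair(fwd, rev))$nonspecific)
  pair_one <- reference_pair(seq_record("gene", shared),
                             seq_record("pseudogene", random_seq(nchar(shared))))
  expect_false(primer_specificity(pair_one, primer_pair(fwd, rev))$nonspecific)
})
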