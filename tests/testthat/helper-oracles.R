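# Independent oracles and small construction helpers. Each oracle uses a
# different code path from the implementation it checks.

# Reference-span oracle: GenomicAlignments' CIGAR machinery.
oracle_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

oracle_query_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                               after.soft.clipping = FALSE)
}

random_cigar <- function() {
  n_ops <- sample(1:5, 1)
  ops <- character(0)
  last <- ""
  for (i in seq_len(n_ops)) {
    op <- sample(setdiff(c("M", "I", "D", "=", "X"), last), 1)
    # no I/D adjacency artifacts needed; just avoid repeats of same op
    ops <- c(ops, op)
    last <- op
  }
  # CIGARs must begin and end with a query-consuming anchor
  if (ops[1] %in% c("D")) ops <- c("M", ops)
  if (ops[length(ops)] %in% c("D")) ops <- c(ops, "M")
  lens <- sample(1:20, length(ops), replace = TRUE)
  if (sample(c(TRUE, FALSE), 1)) { ops <- c("S", ops); lens <- c(sample(1:5, 1), lens) }
  if (sample(c(TRUE, FALSE), 1)) { ops <- c(ops, "S"); lens <- c(lens, sample(1:5, 1)) }
  paste0(lens, ops, collapse = "")
}

# Full hypergeometric enumeration over all tables with the observed margins.
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  support <- max(0, k - r2):min(r1, k)
  p <- choose(r1, support) * choose(r2, k - support) / choose(n, k)
  obs <- p[match(a, support)]
  list(one_sided = sum(p[support >= a]),
       two_sided = sum(p[p <= obs * (1 + 1e-7)]))
}

# Log-gamma hypergeometric tail, via stats::phyper/dhyper (distinct path
# from the package's lchoose-based summation).
oracle_fisher_phyper <- function(a, b, c, d) {
  stats::dhyper(a, a + b, c + d, a + c) +
    stats::phyper(a, a + b, c + d, a + c, lower.tail = FALSE)
}

# Exhaustive tandem-repeat scan: try every unit length, start and extension.
oracle_in_str <- function(s, pos) {
  x <- strsplit(toupper(s), "")[[1]]
  n <- length(x)
  for (u in 1:6) {
    for (st in seq_len(n - u)) {
      len <- u
      while (st + len <= n && x[st + len] == x[st + len - u]) len <- len + 1
      if (len >= 8 && len %/% u >= 3 && pos >= st && pos <= st + len - 1)
        return(TRUE)
    }
  }
  FALSE
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Mutate k distinct positions of a sequence; returns the mutated copy and
# the planted positions/bases.
mutate_at <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sort(sample(length(x), k))
  old <- x[pos]
  new <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                "", USE.NAMES = FALSE)
  x[pos] <- new
  list(mutated = paste(x, collapse = ""), pos = pos, from = old, to = new)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

table1_path <- function() system.file("extdata", "table1.tsv", package = "psvkit")

rp9_filter_config <- function()
  filter_config(genomic_interval("chr7", 32320394, 34315743))
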