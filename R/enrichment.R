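#' 2x2 contingency table of allele counts
#'
#' Rows are cases/controls, columns variant/non-variant alleles:
#' `a` case variant alleles, `b` case non-variant alleles, `c` control
#' variant alleles, `d` control non-variant alleles.
#'
#' @param a,b,c,d Non-negative integer cell counts; at least one margin must
#'   be positive.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("at least one margin must be positive")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("cases", "controls"),
                              c("variant", "non-variant")))
  print(m)
  invisible(x)
}

#' Fisher's exact test from hypergeometric point probabilities
#'
#' Computes the exact test directly from hypergeometric point probabilities
#' in log space (log-gamma binomial coefficients), with no normal
#' approximation — margins near a million, as arise when a handful of case
#' alleles is compared against population-database allele counts, overflow
#' naive factorials. The one-sided p-value is `P(A >= a | margins)` for the
#' case-variant cell; the two-sided p-value is the conventional sum of all
#' point probabilities not exceeding the observed table's (within relative
#' tolerance 1e-7), matching [stats::fisher.test()].
#'
#' @param t A [contingency_table()] (or numbers `a, b, c, d`).
#' @param ... When `t` is a single count, the remaining three cells.
#' @return Object of class `fisher_result`: `p_one_sided_greater`,
#'   `p_one_sided_less`, `p_two_sided`, and `odds_ratio` (sample odds
#'   ratio, Haldane-corrected when a cell is zero).
#' @export
fisher_exact <- function(t, ...) {
  if (!inherits(t, "contingency_table")) t <- contingency_table(t, ...)
  a <- t$a; r1 <- t$a + t$b; r2 <- t$c + t$d; k <- t$a + t$c
  n <- r1 + r2
  support <- max(0, k - r2):min(r1, k)
  logp <- lchoose(r1, support) + lchoose(r2, k - support) - lchoose(n, k)
  obs <- logp[match(a, support)]
  p_greater <- min(1, exp(logsumexp(logp[support >= a])))
  p_less <- min(1, exp(logsumexp(logp[support <= a])))
  p_two <- min(1, exp(logsumexp(logp[logp <= obs + log1p(1e-7)])))
  haldane <- any(c(t$a, t$b, t$c, t$d) == 0)
  or <- if (haldane)
    ((t$a + 0.5) * (t$d + 0.5)) / ((t$b + 0.5) * (t$c + 0.5))
  else (t$a * t$d) / (t$b * t$c)
  structure(list(p_one_sided_greater = p_greater,
                 p_one_sided_less = p_less, p_two_sided = p_two,
                 odds_ratio = or, haldane_corrected = haldane, table = t),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher_result> one-sided (greater) p = %.3g, two-sided p = %.3g\n",
              x$p_one_sided_greater, x$p_two_sided))
  cat(sprintf("  odds ratio %.3g%s\n", x$odds_ratio,
              if (x$haldane_corrected) " (Haldane-corrected)" else ""))
  invisible(x)
}

#' Allele frequency with significant-figure rounding
#'
#' @param count Variant allele count.
#' @param total Total alleles observed (> 0, >= count).
#' @param sig_figs Significant figures for the rounded frequency
#'   (round-half-even, via [signif()]).
#' @return Object of class `freq_estimate`: `count`, `total`, `frequency`,
#'   `rounded` and `one_in` (`round(1/rounded)`, the "1 in N alleles" form).
#' @export
allele_frequency <- function(count, total, sig_figs = 2L) {
  if (total <= 0) stop("total must be positive")
  if (count < 0 || count > total) stop("count must be in [0, total]")
  f <- count / total
  r <- signif(f, sig_figs)
  structure(list(count = count, total = total, frequency = f,
                 rounded = r, sig_figs = as.integer(sig_figs),
                 one_in = if (r > 0) round(1 / r) else Inf),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("<freq_estimate> %d/%d = %.6g (~%s; 1 in %s alleles)\n",
              x$count, x$total, x$frequency, format(x$rounded),
              format(x$one_in)))
  invisible(x)
}

#' Population-frequency vs disease-prevalence consistency
#'
#' For a dominant, fully penetrant cause, the carrier frequency
#' `2*f*(1-f)*penetrance` cannot exceed the disease prevalence. A variant
#' whose expected carrier frequency is larger than the prevalence of the
#' whole disease class is flagged as incompatible with being a fully
#' penetrant dominant cause.
#'
#' @param allele_freq Population allele frequency (0 allowed).
#' @param disease_prevalence Disease prevalence in (0, 1].
#' @param assumed_penetrance Penetrance assumed for the comparison, in
#'   (0, 1].
#' @return List: `carrier_frequency`, `disease_prevalence`,
#'   `incompatible_with_fully_penetrant_dominant_cause` (logical).
#' @export
prevalence_consistency <- function(allele_freq, disease_prevalence,
                                   assumed_penetrance = 1) {
  stopifnot(allele_freq >= 0, allele_freq <= 1,
            disease_prevalence > 0, disease_prevalence <= 1,
            assumed_penetrance > 0, assumed_penetrance <= 1)
  carrier <- 2 * allele_freq * (1 - allele_freq) * assumed_penetrance
  list(carrier_frequency = carrier,
       disease_prevalence = disease_prevalence,
       assumed_penetrance = assumed_penetrance,
       incompatible_with_fully_penetrant_dominant_cause =
         carrier > disease_prevalence)
}
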