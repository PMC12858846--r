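#' Locus filter configuration
#'
#' Thresholds for the linked-locus candidate triage: shared heterozygosity
#' across the named samples, population rarity, and in-silico deleteriousness
#' scores. Comparisons are strict (`maf < maf_max`, `cadd > cadd_min`,
#' `splice_ai > splice_ai_min`, FATHMM p-values `> fathmm_cut`).
#'
#' @param region [genomic_interval()] bounding the linked locus.
#' @param maf_max Maximum population minor allele frequency (exclusive).
#' @param cadd_min CADD-style score threshold (exclusive).
#' @param splice_ai_min SpliceAI delta-score threshold (exclusive).
#' @param fathmm_cut FATHMM-MKL p-value threshold (exclusive); both coding
#'   and non-coding scores must exceed it.
#' @param require_shared_het Require the variant heterozygous in every named
#'   sample.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(region, maf_max = 0.001, cadd_min = 15,
                          splice_ai_min = 0.4, fathmm_cut = 0.5,
                          require_shared_het = TRUE) {
  stopifnot(inherits(region, "genomic_interval"),
            maf_max >= 0, maf_max <= 1, cadd_min >= 0,
            splice_ai_min >= 0, splice_ai_min <= 1,
            fathmm_cut >= 0, fathmm_cut <= 1)
  structure(list(region = region, maf_max = maf_max, cadd_min = cadd_min,
                 splice_ai_min = splice_ai_min, fathmm_cut = fathmm_cut,
                 require_shared_het = require_shared_het),
            class = "filter_config")
}

#' Triage linked-locus candidate variants
#'
#' Keeps variants that fall inside the configured region, are heterozygous in
#' every named sample (dominant-disease sharing), and are rarer than
#' `maf_max` in the population. A missing MAF is treated as absence from the
#' population databases — i.e. evidence of rarity — and kept. Surviving SNVs
#' and indels are returned separately (indels feed the microsatellite
#' check); every exclusion is logged with the rule that removed it.
#'
#' @param records An `annotation_table` (see [read_annotation_table()]) whose
#'   per-sample genotype columns are named by sample id with values `het`,
#'   `hom_ref`, `hom_alt` or `missing`.
#' @param samples Sample ids that must share the variant.
#' @param cfg A [filter_config()].
#' @return List with `snvs`, `indels` (surviving rows) and `exclusions`
#'   (data frame `variant`, `rule`).
#' @export
filter_candidates <- function(records, samples, cfg) {
  stopifnot(inherits(cfg, "filter_config"), length(samples) >= 1L)
  missing_samples <- setdiff(samples, names(records))
  if (length(missing_samples))
    stop("sample(s) absent from genotype columns: ",
         paste(missing_samples, collapse = ", "))
  n <- nrow(records)
  vid <- sprintf("%s:%d%s>%s", records$contig, records$pos, records$ref,
                 records$alt)
  rule <- rep(NA_character_, n)
  in_region <- records$contig == cfg$region$contig &
    records$pos >= cfg$region$start & records$pos <= cfg$region$end
  rule[!in_region] <- "outside_region"
  if (cfg$require_shared_het) {
    shared_het <- Reduce(`&`, lapply(samples, function(s)
      !is.na(records[[s]]) & records[[s]] == "het"))
    rule[is.na(rule) & !shared_het] <- "not_shared_het"
  }
  rare <- is.na(records$maf) | records$maf < cfg$maf_max
  rule[is.na(rule) & !rare] <- "maf_not_rare"
  keep <- is.na(rule)
  surviving <- records[keep, , drop = FALSE]
  is_indel <- nchar(surviving$ref) != 1L | nchar(surviving$alt) != 1L
  list(snvs = surviving[!is_indel, , drop = FALSE],
       indels = surviving[is_indel, , drop = FALSE],
       exclusions = data.frame(variant = vid[!keep], rule = rule[!keep],
                               stringsAsFactors = FALSE))
}

#' Microsatellite context of an indel
#'
#' Tests whether an indel position lies inside a perfect tandem repeat
#' (short tandem repeat / microsatellite): repeat unit 1-6 bp, at least 3
#' full copies, tract length at least 8 bases. Non-coding microsatellite
#' indels are routinely excluded from dominant-disease candidate lists as
#' polymerase-slippage-prone and near-universally polymorphic.
#'
#' @param sequence_window Sequence of at least 40 bases centred on the
#'   indel.
#' @param indel_pos 1-based position of the indel within the window;
#'   defaults to the centre.
#' @return List: `is_microsatellite`, and when true the `unit`, `copies`,
#'   `start`, `end` of the longest qualifying tract covering the position
#'   (smallest unit wins ties).
#' @export
microsatellite_context <- function(sequence_window,
                                   indel_pos = (nchar(sequence_window) + 1L) %/% 2L) {
  s <- toupper(sequence_window)
  n <- nchar(s)
  if (n < 40L) stop("sequence window must be at least 40 bases")
  stopifnot(indel_pos >= 1L, indel_pos <= n)
  x <- strsplit(s, "")[[1]]
  best <- NULL
  for (u in 1:6) {
    if (n < u * 3L) next
    eq <- x[seq_len(n - u)] == x[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      tract_start <- starts[j]
      tract_end <- ends[j] + u          # run of u-periodic matches spans +u
      len <- tract_end - tract_start + 1L
      copies <- len %/% u
      if (len >= 8L && copies >= 3L &&
          indel_pos >= tract_start && indel_pos <= tract_end) {
        if (is.null(best) || len > best$len ||
            (len == best$len && u < nchar(best$unit))) {
          best <- list(unit = substr(s, tract_start, tract_start + u - 1L),
                       copies = copies, start = tract_start,
                       end = tract_end, len = len)
        }
      }
    }
  }
  if (is.null(best))
    return(list(is_microsatellite = FALSE, unit = NA_character_,
                copies = NA_integer_, start = NA_integer_,
                end = NA_integer_))
  list(is_microsatellite = TRUE, unit = best$unit, copies = best$copies,
       start = best$start, end = best$end)
}

#' Classify a variant by its in-silico scores
#'
#' A variant is `deleterious` when any configured clause fires: CADD above
#' `cadd_min`, SpliceAI above `splice_ai_min`, or both FATHMM-MKL scores
#' (coding and non-coding) above `fathmm_cut`. Missing scores never satisfy
#' a clause. ReMM scores are reported alongside but not thresholded (the
#' service's own cut-off is not published). All comparisons strict.
#'
#' @param rec One annotation row (list or single-row data frame) with
#'   `cadd`, `splice_ai`, `fathmm_coding`, `fathmm_noncoding` fields.
#' @param cfg A [filter_config()].
#' @return List: `label` (`"deleterious"` or `"low_evidence"`) and a
#'   `rationale` string.
#' @export
score_classify <- function(rec, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  g <- function(f) if (!is.null(rec[[f]]) && !is.na(rec[[f]]))
    as.numeric(rec[[f]]) else NA_real_
  cadd <- g("cadd"); sai <- g("splice_ai")
  fc <- g("fathmm_coding"); fn <- g("fathmm_noncoding")
  if (all(is.na(c(cadd, sai, fc, fn))))
    stop("all scores missing; cannot classify")
  fired <- character()
  if (!is.na(cadd) && cadd > cfg$cadd_min)
    fired <- c(fired, sprintf("CADD %.1f > %.1f", cadd, cfg$cadd_min))
  if (!is.na(sai) && sai > cfg$splice_ai_min)
    fired <- c(fired, sprintf("SpliceAI %.2f > %.2f", sai, cfg$splice_ai_min))
  if (!is.na(fc) && !is.na(fn) && fc > cfg$fathmm_cut && fn > cfg$fathmm_cut)
    fired <- c(fired, sprintf("FATHMM coding %.3f & non-coding %.3f > %.2f",
                              fc, fn, cfg$fathmm_cut))
  if (length(fired))
    list(label = "deleterious", rationale = paste(fired, collapse = "; "))
  else
    list(label = "low_evidence",
         rationale = "no score exceeded its threshold")
}

#' @rdname score_classify
#' @param records An `annotation_table`.
#' @return `classify_annotation_table()` returns the table with `label` and
#'   `rationale` columns appended.
#' @export
classify_annotation_table <- function(records, cfg) {
  res <- lapply(seq_len(nrow(records)), function(i)
    score_classify(as.list(records[i, ]), cfg))
  records$label <- vapply(res, `[[`, "", "label")
  records$rationale <- vapply(res, `[[`, "", "rationale")
  records
}
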