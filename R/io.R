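#' Read a FASTA file into sequence records
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] with the package's
#' validation rules: sequences are uppercased, `U` (RNA) is rejected, and
#' duplicate record ids or an empty file are format errors.
#'
#' @param path FASTA file path.
#' @return List of [seq_record()] objects, one per header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!length(raw) || !any(grepl("^>", raw)))
    stop("format error: ", path, " contains no FASTA records")
  if (any(grepl("[Uu]", raw[!grepl("^>", raw)])))
    stop("format error: RNA base 'U' not allowed")
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("format error: duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(seq_along(set), function(i)
    seq_record(ids[i], as.character(set[[i]])))
}

#' Write sequence records as FASTA
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

## CIGAR ops consuming query / reference, restricted subset used throughout.
.cigar_ops <- c(M = "MM", `=` = "MM", X = "MM", I = "Q-", D = "-R",
                S = "Q-", H = "--")

parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([A-Z=])", cigar, perl = TRUE)
  if (m[[1]][1] == -1L ||
      sum(attr(m[[1]], "match.length")) != nchar(cigar))
    stop("format error: malformed CIGAR '", cigar, "'")
  toks <- regmatches(cigar, m)[[1]]
  ops <- substring(toks, nchar(toks))
  lens <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  bad <- setdiff(ops, names(.cigar_ops))
  if (length(bad))
    stop("format error: unsupported CIGAR op '", bad[1], "' in '", cigar, "'")
  list(op = ops, len = lens)
}

## Project a read sequence onto reference coordinates: one char per reference
## base covered, "-" at deletions; insertions/clips dropped.
project_cigar <- function(cigar, seq) {
  cg <- parse_cigar(cigar)
  out <- character(length(cg$op))
  qpos <- 1L
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      out[i] <- substr(seq, qpos, qpos + len - 1L)
      qpos <- qpos + len
    } else if (op == "D") {
      out[i] <- strrep("-", len)
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } # H consumes nothing
  }
  paste(out, collapse = "")
}

cigar_ref_width <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "=", "X", "D")])
}

#' Read a SAM-subset text file
#'
#' Parses the plain-text tab-separated SAM subset this package exchanges:
#' header lines (`@`) are skipped, unmapped records (FLAG bit 0x4) are
#' dropped (their count is reported), and only CIGAR operations
#' `M`, `=`, `X`, `I`, `D`, `S`, `H` are accepted. Optional fields are
#' ignored; an `ot:Z:` tag, when present, is read back as the simulation
#' origin-truth label. This is deliberately not a BAM/CRAM reader.
#'
#' @param path SAM text file.
#' @return A [read_set()]; attribute `unmapped_dropped` holds the number of
#'   unmapped records excluded.
#' @export
read_sam_subset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines)) {
    out <- empty_read_set()
    attr(out, "unmapped_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("format error: SAM record with fewer than 6 fields at line ",
         which(nf < 6L)[1])
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  unmapped <- bitwAnd(flag, 4L) != 0L
  fields <- fields[!unmapped]
  n_dropped <- sum(unmapped)
  if (!length(fields)) {
    out <- empty_read_set()
    attr(out, "unmapped_dropped") <- n_dropped
    return(out)
  }
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  if (anyNA(pos) || any(pos < 1L))
    stop("format error: POS must be a positive integer")
  ## Two layouts, both in SAM column order: the full 11-column record
  ## (MAPQ in col 5, CIGAR col 6, SEQ col 10) and the minimal 6-column
  ## subset QNAME FLAG RNAME POS CIGAR SEQ.
  full <- vapply(fields, length, 1L) >= 10L
  cigars <- mapply(function(f, isf) f[[if (isf) 6L else 5L]], fields, full)
  seqs <- toupper(mapply(function(f, isf) f[[if (isf) 10L else 6L]],
                         fields, full))
  aln <- mapply(project_cigar, cigars, seqs, USE.NAMES = FALSE)
  truth <- vapply(fields, function(f) {
    tag <- grep("^ot:Z:", f, value = TRUE)
    if (length(tag)) sub("^ot:Z:", "", tag[1]) else NA_character_
  }, "")
  out <- read_set(id = vapply(fields, `[[`, "", 1L),
                  contig = vapply(fields, `[[`, "", 3L),
                  start = pos, aln = aln, origin_truth = truth)
  attr(out, "unmapped_dropped") <- n_dropped
  out
}

#' Write a read set as SAM-subset text
#'
#' Reads produced by the simulator are projection-only (no indels), so the
#' CIGAR is a single match run. Origin-truth labels are carried in an
#' `ot:Z:` optional tag so that a round-trip preserves them.
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam_subset <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ctg in unique(reads$contig))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg,
                       max(reads$end[reads$contig == ctg])), con)
  if (nrow(reads)) {
    body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                    reads$id, reads$contig, reads$start,
                    nchar(reads$aln), reads$aln)
    has_truth <- !is.na(reads$origin_truth)
    body[has_truth] <- paste0(body[has_truth], "\tot:Z:",
                              reads$origin_truth[has_truth])
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a variant annotation table
#'
#' Expects a TSV with columns `position` (e.g. `chr7:33096550T>A`), `gene`,
#' `cadd`, `fathmm_noncoding`, `fathmm_coding`, `remm`, `maf`, `splice_ai`.
#' Empty cells are missing values (`NA`), never zero. Additional columns
#' (per-sample genotypes among them) are passed through untouched.
#'
#' @param path TSV path.
#' @return Data frame of class `annotation_table`, with parsed `contig`,
#'   `pos`, `ref`, `alt` columns prepended.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), check.names = FALSE)
  need <- c("position", "gene", "cadd", "fathmm_noncoding", "fathmm_coding",
            "remm", "maf", "splice_ai")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing columns: ", paste(miss, collapse = ", "))
  for (col in c("cadd", "fathmm_noncoding", "fathmm_coding", "remm", "maf",
                "splice_ai")) {
    v <- df[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("format error: non-numeric value '", v[bad[1]], "' in column ",
             col, ", row ", bad[1])
      df[[col]] <- num
    }
  }
  m <- regmatches(df$position,
                  regexec("^(\\w+):(\\d+)([ACGT]+)>([ACGT]+)$", df$position))
  bad <- which(lengths(m) != 5L)
  if (length(bad))
    stop("format error: unparseable position '", df$position[bad[1]],
         "', row ", bad[1])
  df <- cbind(data.frame(contig = vapply(m, `[[`, "", 2L),
                         pos = as.integer(vapply(m, `[[`, "", 3L)),
                         ref = vapply(m, `[[`, "", 4L),
                         alt = vapply(m, `[[`, "", 5L),
                         stringsAsFactors = FALSE),
              df)
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Write variant adjudication verdicts as VCF-lite
#'
#' Minimal VCF: `##fileformat` header plus the eight fixed columns, with the
#' adjudication verdict in `INFO` under `PARALOG_VERDICT`. Positions are
#' 1-based; indels use the left-anchored REF/ALT convention.
#'
#' @param variants List of [candidate_variant()] objects.
#' @param verdicts Character vector of verdicts, parallel to `variants` (or
#'   named by [variant_id]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjudication_vcf <- function(variants, verdicts, path) {
  if (length(variants) && is.null(names(verdicts)) &&
      length(verdicts) != length(variants))
    stop("verdicts must be parallel to variants or named by variant id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=PARALOG_VERDICT,Number=1,Type=String,Description=\"Gene-vs-pseudogene adjudication verdict\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    if (!grepl("^[ACGTN]+$", v$ref) || !grepl("^[ACGTN]+$", v$alt))
      stop("REF/ALT must be DNA strings (left-anchored for indels): ",
           variant_id(v))
    verdict <- if (!is.null(names(verdicts))) verdicts[[variant_id(v)]]
               else verdicts[[i]]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tPARALOG_VERDICT=%s",
                       v$contig, v$pos, v$ref, v$alt, verdict), con)
  }
  invisible(path)
}

#' Read a VCF-lite adjudication file
#'
#' @param path VCF-lite file written by [write_adjudication_vcf()].
#' @return Data frame with `contig`, `pos`, `ref`, `alt`, `verdict`.
#' @export
read_adjudication_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat"))
    stop("format error: missing ##fileformat header")
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      verdict = character(), stringsAsFactors = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  data.frame(contig = vapply(f, `[[`, "", 1L),
             pos = as.integer(vapply(f, `[[`, "", 2L)),
             ref = vapply(f, `[[`, "", 4L),
             alt = vapply(f, `[[`, "", 5L),
             verdict = sub("^.*PARALOG_VERDICT=([^;]*).*$", "\\1",
                           vapply(f, `[[`, "", 8L)),
             stringsAsFactors = FALSE)
}
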