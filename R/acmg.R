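.path_strengths <- c("very_strong", "strong", "moderate", "supporting")
.benign_strengths <- c("stand_alone_benign", "strong_benign",
                       "supporting_benign")

default_strength <- function(code) {
  switch(substr(code, 1, 3),
         PVS = "very_strong",
         BA1 = , BA2 = , BA3 = "stand_alone_benign",
         switch(substr(code, 1, 2),
                PS = "strong", PM = "moderate", PP = "supporting",
                BA = "stand_alone_benign", BS = "strong_benign",
                BP = "supporting_benign",
                stop("unknown ACMG code prefix: ", code)))
}

#' ACMG evidence item
#'
#' One ACMG/AMP criterion applied at a strength. The strength defaults to
#' the code's guideline level (PVS very strong, PS strong, PM moderate, PP
#' supporting; BA stand-alone, BS strong, BP supporting benign) but can be
#' re-weighted, mirroring manual strength escalation such as applying PS4 at
#' strong on enrichment evidence or PP1 at very strong on deep
#' cosegregation. Pathogenic codes must carry pathogenic strengths and
#' benign codes benign strengths.
#'
#' @param code Criterion code, e.g. `"PM2"`, `"PP3"`, `"PS4"`, `"PP1"`,
#'   `"BA1"`.
#' @param strength Applied strength; default per the code.
#' @return Object of class `evidence_item`.
#' @export
evidence_item <- function(code, strength = NULL) {
  code <- toupper(code)
  def <- default_strength(code)
  if (is.null(strength)) strength <- def
  pathogenic <- def %in% .path_strengths
  ok <- if (pathogenic) .path_strengths else .benign_strengths
  if (!strength %in% c(.path_strengths, .benign_strengths))
    stop("unknown strength: ", strength)
  if (!strength %in% ok)
    stop(code, " is a ", if (pathogenic) "pathogenic" else "benign",
         " criterion and cannot carry strength '", strength, "'")
  structure(list(code = code, default_strength = def,
                 applied_strength = strength, pathogenic = pathogenic),
            class = "evidence_item")
}

#' @export
print.evidence_item <- function(x, ...) {
  cat(sprintf("%s@%s%s\n", x$code, x$applied_strength,
              if (x$applied_strength != x$default_strength)
                sprintf(" (default %s)", x$default_strength) else ""))
  invisible(x)
}

#' Parse "CODE:strength" evidence strings
#'
#' @param spec Character vector like `c("PM2", "PS4:strong",
#'   "PP1:very_strong")`.
#' @return List of [evidence_item()]s.
#' @export
parse_evidence <- function(spec) {
  lapply(spec, function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    evidence_item(parts[1], if (length(parts) > 1L) parts[2] else NULL)
  })
}

#' Combine ACMG evidence into a five-tier classification
#'
#' Implements the published ACMG/AMP combining rules over applied strengths.
#' Pathogenic requires, e.g., one very strong criterion plus one strong, or
#' two strong, or one strong plus three moderate; likely pathogenic one
#' strong plus one or two moderate, three moderate, and so on; benign one
#' stand-alone or two strong benign; likely benign one strong plus one
#' supporting benign or two supporting benign. When both a pathogenic-side
#' and a benign-side rule fire, the evidence is contradictory and the class
#' is uncertain significance. No evidence is likewise uncertain
#' significance.
#'
#' @param evidence List of [evidence_item()]s (duplicate codes are an
#'   error).
#' @return Object of class `acmg_classification`: `classification` (one of
#'   `pathogenic`, `likely_pathogenic`, `uncertain_significance`,
#'   `likely_benign`, `benign`) and `fired_rule`.
#' @export
combine_criteria <- function(evidence) {
  if (length(evidence) && !all(vapply(evidence, inherits, TRUE,
                                      "evidence_item")))
    evidence <- parse_evidence(unlist(evidence))
  codes <- vapply(evidence, `[[`, "", "code")
  if (anyDuplicated(codes))
    stop("duplicate evidence codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  s <- vapply(evidence, `[[`, "", "applied_strength")
  pvs <- sum(s == "very_strong"); ps <- sum(s == "strong")
  pm <- sum(s == "moderate"); pp <- sum(s == "supporting")
  ba <- sum(s == "stand_alone_benign"); bs <- sum(s == "strong_benign")
  bp <- sum(s == "supporting_benign")

  path_rule <- if (pvs >= 2) "2PVS"
    else if (pvs >= 1 && ps >= 1) "PVS1+PS"
    else if (pvs >= 1 && pm >= 2) "PVS1+2PM"
    else if (pvs >= 1 && pm == 1 && pp >= 1) "PVS1+PM+PP"
    else if (pvs >= 1 && pp >= 2) "PVS1+2PP"
    else if (ps >= 2) "2PS"
    else if (ps == 1 && pm >= 3) "PS+3PM"
    else if (ps == 1 && pm == 2 && pp >= 2) "PS+2PM+2PP"
    else if (ps == 1 && pm == 1 && pp >= 4) "PS+PM+4PP"
    else NULL
  lp_rule <- if (pvs == 1 && pm == 1) "PVS1+PM"
    else if (ps == 1 && pm >= 1 && pm <= 2) "PS+1-2PM"
    else if (ps == 1 && pp >= 2) "PS+2PP"
    else if (pm >= 3) "3PM"
    else if (pm == 2 && pp >= 2) "2PM+2PP"
    else if (pm == 1 && pp >= 4) "PM+4PP"
    else NULL
  benign_rule <- if (ba >= 1) "BA1"
    else if (bs >= 2) "2BS"
    else NULL
  lb_rule <- if (bs == 1 && bp >= 1) "BS+BP"
    else if (bp >= 2) "2BP"
    else NULL

  path_class <- if (!is.null(path_rule)) c("pathogenic", path_rule)
    else if (!is.null(lp_rule)) c("likely_pathogenic", lp_rule)
    else NULL
  ben_class <- if (!is.null(benign_rule)) c("benign", benign_rule)
    else if (!is.null(lb_rule)) c("likely_benign", lb_rule)
    else NULL

  res <- if (!is.null(path_class) && !is.null(ben_class))
    c("uncertain_significance", "conflicting_pathogenic_and_benign")
  else if (!is.null(path_class)) path_class
  else if (!is.null(ben_class)) ben_class
  else c("uncertain_significance", "criteria_not_met")

  structure(list(classification = res[1], fired_rule = res[2],
                 evidence = evidence,
                 counts = c(very_strong = pvs, strong = ps, moderate = pm,
                            supporting = pp, stand_alone_benign = ba,
                            strong_benign = bs, supporting_benign = bp)),
            class = "acmg_classification")
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat(sprintf("<acmg> %s (rule: %s)\n  evidence: %s\n",
              x$classification, x$fired_rule,
              if (length(x$evidence))
                paste(vapply(x$evidence, function(e)
                  paste0(e$code, "@", e$applied_strength), ""),
                  collapse = ", ")
              else "none"))
  invisible(x)
}

#' PS4 evidence from a case-control enrichment p-value
#'
#' Converts an exact enrichment test into the ACMG PS4 criterion (variant
#' prevalence significantly increased in affected individuals): PS4 at
#' strong when `p < alpha`, otherwise no item.
#'
#' @param fisher_p Enrichment p-value in (0, 1].
#' @param alpha Significance threshold (strict).
#' @return An [evidence_item()] (`PS4@strong`) or `NULL`.
#' @export
evidence_from_enrichment <- function(fisher_p, alpha = 1e-4) {
  stopifnot(fisher_p > 0, fisher_p <= 1)
  if (fisher_p < alpha) evidence_item("PS4", "strong") else NULL
}
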