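# Novel-lncRNA identification cascade: assembler class codes -> structural
# rules -> coding-exon overlap -> database annotation -> coding-potential
# intersection; plus five-way positional classification.

.FILTER_RULES <- c("class_code", "length", "exon_count", "coding_overlap",
                   "known_annotation", "coding_potential")

#' Select novel transcript candidates by assembler class code
#'
#' Keeps transcripts whose class code is one of `i, j, x, u, c, e, o`
#' (novel relative to the reference annotation). Unknown class-code
#' characters raise a warning and are excluded; known codes such as `"="`
#' are dropped silently.
#'
#' @param ts A [TranscriptSet-class].
#' @return A [TranscriptSet-class] of candidates.
#' @export
selectNovelCandidates <- function(ts) {
  cc <- txData(ts)$class_code
  known <- c("=", "s", "p", "r", ".")
  unknown <- !(cc %in% c(.NOVEL_CLASS_CODES, known))
  if (any(unknown))
    warning("unknown class code(s) excluded: ",
            paste(unique(cc[unknown]), collapse = ", "))
  ts[cc %in% .NOVEL_CLASS_CODES]
}

.newReport <- function(ids) {
  data.frame(transcript_id = ids, passed = TRUE,
             failed_rules = I(replicate(length(ids), character(),
                                        simplify = FALSE)),
             stringsAsFactors = FALSE)
}

.failRule <- function(report, which, rule) {
  idx <- which(which)
  report$passed[idx] <- FALSE
  for (i in idx)
    report$failed_rules[[i]] <- union(report$failed_rules[[i]], rule)
  report
}

#' Apply structural filters (length, exon count)
#'
#' A candidate fails `length` iff its summed exon length is `<= minLength`
#' (the rule keeps transcripts *longer than* 200 bp) and fails
#' `exon_count` iff it has fewer than `minExons` exons. With
#' `strictExons = TRUE` the exon rule instead requires strictly more than
#' `minExons` exons.
#'
#' @param candidates A [TranscriptSet-class].
#' @param minLength Length cutoff in bp (default 200; pass means > 200).
#' @param minExons Minimum exon count (default 2; pass means >= 2).
#' @param strictExons Require exon count strictly greater than `minExons`.
#' @return FilterReport data.frame: `transcript_id`, `passed`,
#'   `failed_rules` (list column).
#' @export
applyStructuralFilters <- function(candidates, minLength = 200L,
                                   minExons = 2L, strictExons = FALSE) {
  rep <- .newReport(names(candidates))
  rep <- .failRule(rep, txLength(candidates) <= minLength, "length")
  ec <- exonCount(candidates)
  fails <- if (strictExons) ec <= minExons else ec < minExons
  .failRule(rep, fails, "exon_count")
}

#' Remove candidates overlapping protein-coding exons
#'
#' A candidate fails iff any of its exons shares at least one base with any
#' mRNA exon, on the same strand by default (`ignoreStrand = TRUE` checks
#' both strands).
#'
#' @param candidates A [TranscriptSet-class].
#' @param mrnas A [TranscriptSet-class] of protein-coding transcripts (or
#'   any object with a `txExons` method); if empty, all candidates pass.
#' @param ignoreStrand Also remove opposite-strand exon overlaps.
#' @return FilterReport data.frame (rule `coding_overlap`).
#' @export
removeCodingOverlap <- function(candidates, mrnas, ignoreStrand = FALSE) {
  rep <- .newReport(names(candidates))
  if (missing(mrnas) || length(mrnas) == 0L) return(rep)
  codingExons <- unlist(txExons(mrnas), use.names = FALSE)
  hits <- overlapsAny(txExons(candidates), codingExons,
                      ignore.strand = ignoreStrand)
  .failRule(rep, hits, "coding_overlap")
}

#' Flag candidates matched by protein/ncRNA database annotation
#'
#' Database lookup (Nr/KEGG/GO-style) is modelled as a per-transcript
#' boolean `db_annotated` supplied with the annotation; annotated
#' candidates fail rule `known_annotation`.
#'
#' @param candidates A [TranscriptSet-class].
#' @return FilterReport data.frame.
#' @export
removeAnnotated <- function(candidates) {
  .failRule(.newReport(names(candidates)),
            isTRUE_v(txData(candidates)$db_annotated), "known_annotation")
}

isTRUE_v <- function(x) !is.na(x) & x

#' Intersect coding-potential predictions
#'
#' A candidate passes iff *both* coding-potential predictors called it
#' noncoding (`coding_call_a` and `coding_call_b` both `FALSE`); the kept
#' set is the intersection of the two predictors' noncoding sets.
#'
#' @param candidates A [TranscriptSet-class] with both calls populated.
#' @return FilterReport data.frame (rule `coding_potential`).
#' @export
callNoncoding <- function(candidates) {
  td <- txData(candidates)
  miss <- is.na(td$coding_call_a) | is.na(td$coding_call_b)
  if (any(miss))
    stop("missing coding-potential call for: ",
         paste(td$transcript_id[miss], collapse = ", "))
  .failRule(.newReport(names(candidates)),
            td$coding_call_a | td$coding_call_b, "coding_potential")
}

#' Run the full novel-lncRNA filter cascade
#'
#' Applies, in one pass, the class-code rule, the structural rules, the
#' coding-exon overlap rule, the database-annotation rule and the
#' coding-potential intersection. Rules are evaluated independently, so
#' the pass set does not depend on any application order and every
#' violated rule is recorded.
#'
#' @param ts A [TranscriptSet-class] (mRNAs included; they provide the
#'   coding exons and are themselves reported as failing `class_code`).
#' @param minLength,minExons,strictExons See [applyStructuralFilters()].
#' @param ignoreStrand See [removeCodingOverlap()].
#' @return List with `report` (FilterReport over all non-mRNA transcripts
#'   with class-code-novel candidates fully evaluated) and `lncrnas`
#'   (a [TranscriptSet-class] of transcripts passing every rule).
#' @export
filterLncrna <- function(ts, minLength = 200L, minExons = 2L,
                         strictExons = FALSE, ignoreStrand = FALSE) {
  td <- txData(ts)
  cand <- ts[td$biotype %in% c("novel_candidate")]
  rep <- .newReport(names(cand))
  cc <- txData(cand)$class_code
  rep <- .failRule(rep, !(cc %in% .NOVEL_CLASS_CODES), "class_code")
  sr <- applyStructuralFilters(cand, minLength, minExons, strictExons)
  ov <- removeCodingOverlap(cand, ts[td$biotype == "mRNA"], ignoreStrand)
  an <- removeAnnotated(cand)
  np <- callNoncoding(cand)
  for (other in list(sr, ov, an, np)) {
    stopifnot(identical(other$transcript_id, rep$transcript_id))
    for (i in seq_len(nrow(rep)))
      rep$failed_rules[[i]] <- union(rep$failed_rules[[i]],
                                     other$failed_rules[[i]])
  }
  rep$passed <- lengths(rep$failed_rules) == 0L
  list(report = rep, lncrnas = cand[rep$passed])
}

#' Classify lncRNA position relative to coding genes
#'
#' Five mutually exclusive classes, assigned in precedence order:
#' `sense_overlapping` (exonic overlap, same strand), `antisense` (any
#' overlap, opposite strand), `intronic` (span fully inside one intron of
#' a gene), `bidirectional` (no overlap, 5' end within `bidiWindow` bp of
#' a gene 5' end on the opposite strand), else `intergenic`.
#'
#' @param lncs A [TranscriptSet-class] of lncRNAs.
#' @param codingGenes A [TranscriptSet-class] of coding transcripts.
#' @param bidiWindow Divergent-promoter window in bp (default 1000).
#' @return Named character vector, one class per lncRNA.
#' @export
classifyPosition <- function(lncs, codingGenes, bidiWindow = 1000L) {
  lspan <- txSpan(lncs)
  gspan <- txSpan(codingGenes)
  gex <- unlist(txExons(codingGenes), use.names = FALSE)
  lex <- txExons(lncs)

  senseEx <- overlapsAny(lex, gex, ignore.strand = FALSE)
  spanHitAny <- overlapsAny(lspan, gspan, ignore.strand = TRUE)
  oppHit <- overlapsAny(lspan, invertStrand(gspan), ignore.strand = FALSE)
  anti <- !senseEx & oppHit

  introns <- psetdiff(unlist(range(txExons(codingGenes))), txExons(codingGenes))
  intronGr <- unlist(introns, use.names = FALSE)
  intronic <- if (length(intronGr))
    overlapsAny(lspan, intronGr, type = "within", ignore.strand = TRUE)
  else rep(FALSE, length(lspan))

  tss <- resize(gspan, width = 1L, fix = "start")
  ltss <- resize(lspan, width = 1L, fix = "start")
  bidi <- rep(FALSE, length(lspan))
  if (length(tss)) {
    opp <- invertStrand(ltss)
    hits <- findOverlaps(opp, tss, maxgap = bidiWindow)
    bidi[unique(queryHits(hits))] <- TRUE
  }

  cls <- ifelse(senseEx, "sense_overlapping",
         ifelse(anti, "antisense",
         ifelse(intronic, "intronic",
         ifelse(!spanHitAny & bidi, "bidirectional", "intergenic"))))
  setNames(cls, names(lncs))
}
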