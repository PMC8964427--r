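# FPKM computation and staged differential expression.

#' Compute FPKM from counts
#'
#' `FPKM = count * 1e9 / (length * libsize)` — fragments per kilobase of
#' transcript per million mapped fragments.
#'
#' @param counts Feature-by-sample count matrix.
#' @param lengths Transcript lengths in bp (named or ordered as rows).
#' @param libsizes Mapped fragments per sample (named or ordered as cols).
#' @param stage Per-sample stage labels for the result.
#' @param layer RNA layer label.
#' @return An [ExpressionMatrix-class] of FPKM values.
#' @export
computeFpkm <- function(counts, lengths, libsizes, stage,
                        layer = c("lncRNA", "miRNA", "mRNA")) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (!is.null(names(libsizes))) libsizes <- libsizes[colnames(counts)]
  if (any(lengths <= 0)) stop("transcript lengths must be > 0")
  if (any(libsizes <= 0)) stop("library sizes must be > 0")
  fpkm <- counts * 1e9 / outer(as.numeric(lengths), as.numeric(libsizes))
  dimnames(fpkm) <- dimnames(counts)
  ExpressionMatrix(fpkm, stage = stage, layer = match.arg(layer))
}

#' Differential expression between two stages
#'
#' For every feature expressed in at least one of the two groups:
#' `log2FC = log2((mean_B + pseudocount) / (mean_A + pseudocount))`, a
#' Welch two-sample t-test on `log2(FPKM + pseudocount)`, and
#' Benjamini-Hochberg FDR across all tested features. A feature is called
#' DE iff `fdr < alphaFdr` and `|log2FC| > minAbsLog2fc`. Features with
#' all-zero abundance in both groups are excluded before testing.
#'
#' @param em An [ExpressionMatrix-class].
#' @param stageA,stageB Stage labels present in the design (each with at
#'   least 2 replicates).
#' @param pseudocount Added before log transform and fold change
#'   (default 1).
#' @param alphaFdr FDR threshold (default 0.05).
#' @param minAbsLog2fc Fold-change threshold (default 1).
#' @return data.frame: `feature_id`, `comparison`, `mean_a`, `mean_b`,
#'   `log2fc`, `p_value`, `fdr`, `is_de`, `direction` (up/down in
#'   `stageB` relative to `stageA`).
#' @export
differentialExpression <- function(em, stageA, stageB, pseudocount = 1,
                                   alphaFdr = 0.05, minAbsLog2fc = 1) {
  st <- stages(em)
  a <- abundance(em)[, st == stageA, drop = FALSE]
  b <- abundance(em)[, st == stageB, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each stage needs at least 2 replicates (",
         stageA, ": ", ncol(a), ", ", stageB, ": ", ncol(b), ")")
  keep <- rowSums(a) + rowSums(b) > 0
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  p <- vapply(seq_len(nrow(a)), function(i) {
    tryCatch(t.test(lb[i, ], la[i, ])$p.value, error = function(e) 1)
  }, 0)
  log2fc <- log2((rowMeans(b) + pseudocount) / (rowMeans(a) + pseudocount))
  fdr <- p.adjust(p, method = "BH")
  res <- data.frame(
    feature_id = rownames(a),
    comparison = paste(stageA, "vs", stageB),
    mean_a = rowMeans(a), mean_b = rowMeans(b),
    log2fc = log2fc, p_value = p, fdr = fdr,
    is_de = fdr < alphaFdr & abs(log2fc) > minAbsLog2fc,
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none")),
    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p_value, res$feature_id, method = "radix"), ]
}

#' Run all stage comparisons of a staged design
#'
#' Defaults to contiguous-stage comparisons plus first-vs-last (for four
#' stages: 1v2, 2v3, 3v4, 1v4).
#'
#' @param em An [ExpressionMatrix-class].
#' @param comparisons List of `c(stageA, stageB)` pairs; `NULL` uses the
#'   default scheme over the stages in column order.
#' @param ... Passed to [differentialExpression()].
#' @return Named list of per-comparison result data.frames.
#' @export
runComparisons <- function(em, comparisons = NULL, ...) {
  if (is.null(comparisons))
    comparisons <- .stageComparisons(unique(stages(em)))
  res <- lapply(comparisons, function(cmp)
    differentialExpression(em, cmp[1], cmp[2], ...))
  names(res) <- vapply(comparisons, function(cmp)
    paste(cmp[1], "vs", cmp[2]), "")
  res
}

#' Summarize DE results across comparisons
#'
#' @param results Named list of [differentialExpression()] outputs.
#' @return List with `counts` (per-comparison total/up/down DE counts),
#'   `de_sets` (DE feature ids per comparison), `shared` (features DE in
#'   every comparison) and `unique_sets` (features DE in exactly one).
#' @export
deSummary <- function(results) {
  sets <- lapply(results, function(r) r$feature_id[r$is_de])
  counts <- data.frame(
    comparison = names(results),
    n_de = vapply(sets, length, 0L),
    n_up = vapply(results, function(r) sum(r$is_de & r$direction == "up"), 0L),
    n_down = vapply(results, function(r) sum(r$is_de & r$direction == "down"), 0L),
    row.names = NULL)
  all_feats <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_feats %in% s,
                   logical(length(all_feats)))
  if (length(all_feats) == 1L) member <- matrix(member, nrow = 1)
  shared <- all_feats[rowSums(member) == length(sets)]
  uniq <- lapply(seq_along(sets), function(j)
    all_feats[member[, j] & rowSums(member) == 1L])
  names(uniq) <- names(results)
  list(counts = counts, de_sets = sets, shared = shared, unique_sets = uniq)
}
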