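# Cis (genomic proximity) and trans (expression correlation) lncRNA target
# prediction.

#' Predict cis target genes by genomic proximity
#'
#' A (lncRNA, gene) pair is emitted iff the gap between their transcript
#' spans is at most `window` bp on the same chromosome (boundary
#' inclusive: a gap of exactly `window` passes; overlapping spans have
#' distance 0). Strand is ignored.
#'
#' @param lncs [TranscriptSet-class] or `GRanges` of lncRNA spans.
#' @param genes [TranscriptSet-class] or `GRanges` of gene spans.
#' @param window Maximum span gap in bp (default 100000, the usual
#'   "within about 100 kb" rule).
#' @return data.frame: `lncRNA_id`, `gene_id`, `mode = "cis"`, `distance`.
#' @export
predictCis <- function(lncs, genes, window = 100000L) {
  lspan <- if (is(lncs, "TranscriptSet")) txSpan(lncs) else lncs
  gspan <- if (is(genes, "TranscriptSet")) txSpan(genes) else genes
  hits <- findOverlaps(lspan, gspan, maxgap = window, ignore.strand = TRUE)
  d <- distance(lspan[queryHits(hits)], gspan[subjectHits(hits)],
                ignore.strand = TRUE)
  keep <- !is.na(d) & d <= window
  lid <- names(lspan) %||% as.character(seq_along(lspan))
  gid <- names(gspan) %||% as.character(seq_along(gspan))
  out <- data.frame(
    lncRNA_id = lid[queryHits(hits)][keep],
    gene_id = gid[subjectHits(hits)][keep],
    mode = rep("cis", sum(keep)),
    distance = d[keep],
    stringsAsFactors = FALSE)
  out[order(out$lncRNA_id, out$gene_id, method = "radix"), , drop = FALSE]
}

#' Predict trans target genes by expression correlation
#'
#' Correlates every lncRNA with every gene across shared samples (Pearson
#' on `log2(abundance + 1)` by default, Spearman available) and emits
#' pairs with `|r|` strictly above `threshold`. Zero-variance features
#' are skipped with a warning.
#'
#' @param lncEm,geneEm [ExpressionMatrix-class] objects on the same
#'   samples (at least 3).
#' @param threshold Absolute-correlation cutoff (default 0.999).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: `lncRNA_id`, `gene_id`, `mode = "trans"`,
#'   `correlation`.
#' @export
predictTrans <- function(lncEm, geneEm, threshold = 0.999,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- log2(abundance(lncEm) + 1)
  y <- log2(abundance(geneEm) + 1)
  if (!identical(colnames(x), colnames(y)))
    stop("expression matrices must share the same samples")
  if (ncol(x) < 3L) stop("need at least 3 shared samples")
  r <- .corScreen(x, y, method)
  pass <- which(.strictAbove(abs(r), threshold), arr.ind = TRUE)
  out <- data.frame(
    lncRNA_id = rownames(r)[pass[, 1]],
    gene_id = colnames(r)[pass[, 2]],
    mode = rep("trans", nrow(pass)),
    correlation = r[pass],
    stringsAsFactors = FALSE)
  out[order(out$lncRNA_id, out$gene_id, method = "radix"), , drop = FALSE]
}

# cross-feature correlation between the rows of two matrices; zero-variance
# rows are dropped with one warning and yield no pairs
.corScreen <- function(x, y, method = "pearson") {
  vx <- apply(x, 1, var); vy <- apply(y, 1, var)
  if (any(vx == 0) || any(vy == 0)) {
    bad <- c(rownames(x)[vx == 0], rownames(y)[vy == 0])
    warning("zero-variance feature(s) skipped: ",
            paste(head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ...")
    x <- x[vx > 0, , drop = FALSE]
    y <- y[vy > 0, , drop = FALSE]
  }
  cor(t(x), t(y), method = method)
}
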