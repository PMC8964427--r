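# ceRNA network construction: (a) Spearman screen for negatively
# co-expressed miRNA pairs, (b) Pearson screen for co-expressed
# lncRNA-mRNA pairs, (c) hypergeometric test on the shared sponge-miRNA
# sets of each co-expressed pair.

# exact upper-tail hypergeometric P(X >= x), X ~ Hyper(N, K, M): the one
# p-value machine behind both the sponge test and over-representation
.phyperUpper <- function(x, K, M, N) {
  if (x <= 0) return(1)
  phyper(x - 1, K, N - K, M, lower.tail = FALSE)
}

#' Screen negatively co-expressed miRNA pairs (Spearman)
#'
#' Spearman rank correlation (average ranks for ties) between every
#' feature of `em` (lncRNA or mRNA layer) and every miRNA; pairs with
#' `SCC < sccCut` (strictly) are retained as candidate sponge
#' interactions. Zero-variance features are skipped with a warning.
#'
#' @param em lncRNA or mRNA [ExpressionMatrix-class].
#' @param mirEm miRNA [ExpressionMatrix-class] on the same samples (at
#'   least 4).
#' @param sccCut Retention cutoff (default -0.7).
#' @return data.frame: `node_a` (feature), `node_b` (miRNA), `kind`
#'   (`lnc_mir` or `mir_mrna`), `statistic` (SCC).
#' @export
screenNegativePairs <- function(em, mirEm, sccCut = -0.7) {
  if (ncol(em) < 4L) stop("need at least 4 shared samples")
  if (!identical(colnames(em), colnames(mirEm)))
    stop("expression matrices must share the same samples")
  r <- .corScreen(log2(abundance(em) + 1), log2(abundance(mirEm) + 1),
                  method = "spearman")
  pass <- which(.strictBelow(r, sccCut), arr.ind = TRUE)
  kind <- if (layerType(em) == "mRNA") "mir_mrna" else "lnc_mir"
  out <- data.frame(
    node_a = rownames(r)[pass[, 1]],
    node_b = colnames(r)[pass[, 2]],
    kind = rep(kind, nrow(pass)),
    statistic = r[pass],
    stringsAsFactors = FALSE)
  out[order(out$node_a, out$node_b, method = "radix"), , drop = FALSE]
}

#' Screen co-expressed lncRNA-mRNA pairs (Pearson)
#'
#' Pearson correlation on `log2(abundance + 1)`; pairs with
#' `PCC > pccCut` (strictly) are retained.
#'
#' @param lncEm,mrnaEm [ExpressionMatrix-class] objects on the same
#'   samples (at least 3).
#' @param pccCut Retention cutoff (default 0.9).
#' @return data.frame: `node_a` (lncRNA), `node_b` (mRNA),
#'   `kind = "lnc_mrna"`, `statistic` (PCC).
#' @export
screenCoexpressedPairs <- function(lncEm, mrnaEm, pccCut = 0.9) {
  if (ncol(lncEm) < 3L) stop("need at least 3 shared samples")
  if (!identical(colnames(lncEm), colnames(mrnaEm)))
    stop("expression matrices must share the same samples")
  r <- .corScreen(log2(abundance(lncEm) + 1), log2(abundance(mrnaEm) + 1),
                  method = "pearson")
  pass <- which(.strictAbove(r, pccCut), arr.ind = TRUE)
  out <- data.frame(
    node_a = rownames(r)[pass[, 1]],
    node_b = colnames(r)[pass[, 2]],
    kind = rep("lnc_mrna", nrow(pass)),
    statistic = r[pass],
    stringsAsFactors = FALSE)
  out[order(out$node_a, out$node_b, method = "radix"), , drop = FALSE]
}

#' Hypergeometric shared-sponge test
#'
#' Exact upper-tail probability `P(X >= x)` that two genes drawing sponge
#' sets of sizes `K` and `M` from a universe of `N` miRNAs share at least
#' `x`, with `X ~ Hypergeometric(N, K, M)`. Exact (no normal
#' approximation).
#'
#' @param x Observed shared-miRNA count.
#' @param K,M Sponge-set sizes of the two genes.
#' @param N miRNA universe size.
#' @return The p-value, in (0, 1].
#' @examples
#' spongeOverlapTest(4, 4, 5, 10)  # 6/252
#' @export
spongeOverlapTest <- function(x, K, M, N) {
  if (any(c(x, K, M, N) < 0) || x > min(K, M) || K > N || M > N)
    stop("inconsistent counts: need 0 <= x <= min(K, M) <= N")
  .phyperUpper(x, K, M, N)
}

#' Build the lncRNA-miRNA-mRNA ceRNA network
#'
#' For each co-expressed (lncRNA, mRNA) pair, the sponge set of either
#' gene is the set of miRNAs that both target it (per `targetSets`) and
#' form a retained negative pair with it; the pair becomes a triad iff it
#' shares at least one sponge miRNA and the hypergeometric overlap
#' p-value is below `alpha` (optionally BH-adjusted). The network is the
#' union of the constituent lncRNA-miRNA and miRNA-mRNA edges of the kept
#' triads.
#'
#' @param negPairs Combined [screenNegativePairs()] output for both
#'   layers (rbind of the lnc-miR and miR-mRNA screens).
#' @param coexPairs [screenCoexpressedPairs()] output.
#' @param targetSets Named list: miRNA id -> targeted feature ids.
#' @param mirUniverse miRNA universe for the test (e.g. miRNAs expressed
#'   in at least one sample).
#' @param alpha Significance level on the sponge test (default 0.05, raw
#'   p as is conventional for this screen).
#' @param adjust Apply Benjamini-Hochberg across candidate pairs before
#'   thresholding (off by default).
#' @return A [CernaNetwork-class].
#' @export
buildCernaNetwork <- function(negPairs, coexPairs, targetSets, mirUniverse,
                              alpha = 0.05, adjust = FALSE) {
  N <- length(unique(mirUniverse))
  negKey <- paste(negPairs$node_a, negPairs$node_b)
  spongeSet <- function(g) {
    tgt <- names(targetSets)[vapply(targetSets, function(s) g %in% s, NA)]
    tgt[paste(g, tgt) %in% negKey]
  }
  n <- nrow(coexPairs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lnc <- coexPairs$node_a[i]; mrna <- coexPairs$node_b[i]
    sl <- spongeSet(lnc); sm <- spongeSet(mrna)
    shared <- intersect(sl, sm)
    if (!length(shared)) next  # x = 0 would give p = 1 regardless
    rows[[i]] <- list(lncRNA = lnc, mRNA = mrna, shared = shared,
                      x = length(shared), K = length(sl), M = length(sm),
                      pcc = coexPairs$statistic[i])
  }
  rows <- rows[!vapply(rows, is.null, NA)]
  p <- vapply(rows, function(r) .phyperUpper(r$x, r$K, r$M, N), 0)
  padj <- if (adjust) p.adjust(p, method = "BH") else p
  keep <- which(padj < alpha)
  tri <- DataFrame(
    lncRNA = vapply(rows, `[[`, "", "lncRNA")[keep],
    mRNA = vapply(rows, `[[`, "", "mRNA")[keep],
    x = vapply(rows, `[[`, 0L, "x")[keep],
    K = vapply(rows, `[[`, 0L, "K")[keep],
    M = vapply(rows, `[[`, 0L, "M")[keep],
    N = if (length(keep)) N else integer(),
    p_hyper = p[keep],
    pcc = vapply(rows, `[[`, 0, "pcc")[keep])
  tri$shared_mirnas <- CharacterList(lapply(rows[keep], `[[`, "shared"))
  o <- order(tri$lncRNA, tri$mRNA, method = "radix")
  tri <- tri[o, , drop = FALSE]

  statOf <- setNames(negPairs$statistic, negKey)
  edges <- list()
  for (i in seq_len(nrow(tri))) {
    for (m in tri$shared_mirnas[[i]]) {
      edges[[paste(tri$lncRNA[i], m)]] <- data.frame(
        source = tri$lncRNA[i], target = m, type = "lnc_mir",
        statistic = unname(statOf[paste(tri$lncRNA[i], m)]),
        p_value = tri$p_hyper[i], stringsAsFactors = FALSE)
      edges[[paste(m, tri$mRNA[i])]] <- data.frame(
        source = m, target = tri$mRNA[i], type = "mir_mrna",
        statistic = unname(statOf[paste(tri$mRNA[i], m)]),
        p_value = tri$p_hyper[i], stringsAsFactors = FALSE)
    }
  }
  ed <- if (length(edges)) do.call(rbind, unname(edges)) else
    data.frame(source = character(), target = character(),
               type = character(), statistic = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$source, ed$target, ed$type)), , drop = FALSE]
  ed <- ed[order(ed$source, ed$target, method = "radix"), , drop = FALSE]
  rownames(ed) <- NULL
  new("CernaNetwork", triads = tri, edges = as(ed, "DataFrame"),
      params = list(alpha = alpha, adjust = adjust, N = N))
}

#' Node and edge counts of a ceRNA network
#'
#' @param network A [CernaNetwork-class].
#' @return List: `n_lncrna`, `n_mirna`, `n_mrna`, `n_lnc_mir_edges`,
#'   `n_mir_mrna_edges`, `n_triads`.
#' @export
networkStats <- function(network) {
  tri <- triads(network)
  ed <- networkEdges(network)
  list(
    n_lncrna = length(unique(tri$lncRNA)),
    n_mirna = length(unique(unlist(tri$shared_mirnas))),
    n_mrna = length(unique(tri$mRNA)),
    n_lnc_mir_edges = sum(ed$type == "lnc_mir"),
    n_mir_mrna_edges = sum(ed$type == "mir_mrna"),
    n_triads = nrow(tri))
}
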