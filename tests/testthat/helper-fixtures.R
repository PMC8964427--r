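# Constructed fixtures and independent oracles shared across tests.

`%//%` <- function(a, b) if (is.null(a)) b else a

# small TranscriptSet from a named list of transcript descriptions
tsFixture <- function(txs) {
  exl <- GenomicRanges::GRangesList(lapply(txs, function(t)
    GenomicRanges::GRanges(t$chrom %//% "chr1",
                           IRanges::IRanges(start = t$starts, width = t$widths),
                           strand = t$strand %//% "+")))
  names(exl) <- names(txs)
  td <- S4Vectors::DataFrame(
    transcript_id = names(txs),
    gene_id = vapply(txs, function(t) t$gene %//% "g1", ""),
    class_code = vapply(txs, function(t) t$class_code %//% "u", ""),
    orf_length = vapply(txs, function(t) as.integer(t$orf %//% 50L), 1L),
    coding_call_a = vapply(txs, function(t) t$callA %//% FALSE, NA),
    coding_call_b = vapply(txs, function(t) t$callB %//% FALSE, NA),
    coding_score = 0.1,
    biotype = vapply(txs, function(t) t$biotype %//% "novel_candidate", ""),
    db_annotated = vapply(txs, function(t) t$annotated %//% FALSE, NA))
  TranscriptSet(exl, td)
}

# ExpressionMatrix from a plain matrix
emFixture <- function(values, layer = "lncRNA", stage = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(stage))
    stage <- rep(c("A", "B"), length.out = ncol(values))
  ExpressionMatrix(values, stage = stage, layer = layer)
}

# ExpressionMatrix whose log2(abundance + 1) equals `l` exactly (l >= 0)
emFromLog <- function(l, layer = "lncRNA", stage = NULL)
  emFixture(2^as.matrix(l) - 1, layer = layer, stage = stage)

# a small-but-complete simulation design, fast enough to re-run many times
smallConfig <- function(seed = 5, ...) {
  defaults <- list(seed = seed, nMrna = 40L, nKnownLnc = 4L, nNovelLnc = 10L,
                   nMirna = 12L, nPlantedTriads = 3L, nSharedMirnas = 2L,
                   nPlantedDe = 1L, nCisNear = 2L, nCisFar = 2L,
                   nDecoysPerRule = 1L, nTraits = 6L)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

# exhaustive hypergeometric upper-tail oracle: enumerate every M-subset of
# an N-item universe whose first K items are the successes
hyperEnumOracle <- function(x, K, M, N) {
  if (M == 0L || N == 0L) return(as.numeric(x <= 0))
  draws <- utils::combn(N, M)
  succ <- colSums(draws <= K)
  mean(succ >= x)
}

# Duncan non-separation oracle: a sorted pair is non-significant iff some
# covering stretch of p means has range <= the least significant range at
# Duncan's protected level (direct enumeration over all stretches)
duncanOracleNonsig <- function(means, df, mse, nh, alpha = 0.05) {
  m <- sort(means, decreasing = TRUE)
  k <- length(m)
  lsr <- function(p) qtukey((1 - alpha)^(p - 1), p, df) * sqrt(mse / nh)
  ns <- diag(k) > 0
  for (a in seq_len(k)) for (b in seq(a, k)) {
    if (b > a && (m[a] - m[b]) <= lsr(b - a + 1))
      ns[a:b, a:b] <- TRUE
  }
  ns
}

# Benjamini-Hochberg step-up, written out directly
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
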