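# Over-representation analysis against user-supplied term annotations
# (GO/KEGG-style), sharing the exact hypergeometric machinery of the
# sponge test.

#' Over-representation (enrichment) test
#'
#' For each term with at least one annotated gene in the universe,
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' universe size, `K` the term's annotated genes in the universe, `n` the
#' study-set size and `k` the study hits; q-values by Benjamini-Hochberg
#' across tested terms. One-sided (enrichment only).
#'
#' @param study Character vector of study genes (must be a subset of
#'   `universe`).
#' @param annotation Term-to-gene mapping: either a named list
#'   (term -> genes) or a two-column data.frame `(term, gene)`. Genes
#'   outside the universe are ignored.
#' @param universe Character vector of background genes.
#' @param termNames Optional data.frame `(term, name)`.
#' @return data.frame sorted by p-value: `term_id`, `term_name`, `k`,
#'   `n`, `K`, `N`, `p_value`, `q_value`.
#' @examples
#' overrepresentation(c("g1", "g2"), list(T1 = c("g1", "g2", "g3")),
#'                    universe = paste0("g", 1:20))
#' @export
overrepresentation <- function(study, annotation, universe,
                               termNames = NULL) {
  study <- unique(study)
  universe <- unique(universe)
  off <- setdiff(study, universe)
  if (length(off))
    stop("study gene(s) absent from universe: ",
         paste(head(off, 10), collapse = ", "))
  if (is.data.frame(annotation))
    annotation <- split(as.character(annotation[[2]]),
                        as.character(annotation[[1]]))
  sets <- lapply(annotation, intersect, universe)
  sets <- sets[lengths(sets) > 0L]  # K = 0 terms are untestable
  N <- length(universe)
  n <- length(study)
  res <- data.frame(
    term_id = names(sets),
    k = vapply(sets, function(s) length(intersect(study, s)), 0L),
    n = n,
    K = lengths(sets),
    N = N,
    row.names = NULL, stringsAsFactors = FALSE)
  res$p_value <- vapply(seq_len(nrow(res)), function(i)
    .phyperUpper(res$k[i], res$K[i], n, N), 0)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  if (!is.null(termNames))
    res$term_name <- termNames$name[match(res$term_id, termNames$term)]
  else res$term_name <- res$term_id
  res <- res[, c("term_id", "term_name", "k", "n", "K", "N",
                 "p_value", "q_value")]
  res[order(res$p_value, res$term_id, method = "radix"), , drop = FALSE]
}
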