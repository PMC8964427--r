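# Validation and phenotype statistics: 2^-ddCt relative quantification,
# expression-trait Pearson correlations, Duncan's multiple range test with
# letter groupings, and fatty-acid class ratios.

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per record: `dCt = ct_target - ct_reference`; `ddCt` subtracts the
#' calibrator group's mean dCt for the same target; relative expression is
#' `2^-ddCt`. By construction the calibrator group's geometric mean fold
#' change is exactly 1, and adding a constant to all Ct values changes
#' nothing.
#'
#' @param records data.frame with `sample_id`, `group`, `target_id`,
#'   `ct_target`, `ct_reference` (see [simulateQpcr()]).
#' @param calibratorGroup Calibrator group label; defaults to the group of
#'   the first record (conventionally the earliest stage).
#' @return `records` with added `dct`, `ddct`, `rel_expr` columns.
#' @export
ddct <- function(records, calibratorGroup = NULL) {
  need <- c("sample_id", "group", "target_id", "ct_target", "ct_reference")
  miss <- setdiff(need, colnames(records))
  if (length(miss)) stop("Ct table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(records$ct_reference))
    stop("missing reference Ct for sample(s): ",
         paste(unique(records$sample_id[is.na(records$ct_reference)]),
               collapse = ", "))
  if (is.null(calibratorGroup)) calibratorGroup <- records$group[1]
  if (!any(records$group == calibratorGroup))
    stop("calibrator group '", calibratorGroup, "' not present")
  records$dct <- records$ct_target - records$ct_reference
  cal <- tapply(records$dct[records$group == calibratorGroup],
                records$target_id[records$group == calibratorGroup], mean)
  if (!all(unique(records$target_id) %in% names(cal)))
    stop("calibrator group lacks measurements for some targets")
  records$ddct <- records$dct - as.vector(cal[records$target_id])
  records$rel_expr <- 2^(-records$ddct)
  records
}

#' Pearson correlations between expression and traits
#'
#' For each (feature, trait) pair: Pearson r across shared samples and a
#' two-tailed p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom, with significance stars at 0.05 / 0.01 / 0.001.
#' Zero-variance pairs are reported as `NA`. No multiplicity correction is
#' applied across the grid by default (`adjust = TRUE` adds BH q-values).
#'
#' @param expr Feature-by-sample numeric matrix, or an
#'   [ExpressionMatrix-class] (then `log2(abundance + 1)` is used).
#' @param traits Sample-by-trait data.frame/matrix; rownames must match
#'   the expression samples (at least 3 shared).
#' @param adjust Add BH-adjusted p-values (`q` matrix) to the result.
#' @return List of feature-by-trait matrices `r`, `p`, `stars` (and `q`
#'   when requested), plus `n`.
#' @export
traitCorrelation <- function(expr, traits, adjust = FALSE) {
  if (is(expr, "ExpressionMatrix")) expr <- log2(abundance(expr) + 1)
  expr <- as.matrix(expr)
  tr <- as.matrix(traits)
  shared <- intersect(colnames(expr), rownames(tr))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  x <- expr[, shared, drop = FALSE]
  y <- tr[shared, , drop = FALSE]
  vx <- apply(x, 1, var); vy <- apply(y, 2, var)
  r <- suppressWarnings(cor(t(x), y))
  r[vx == 0, ] <- NA
  r[, vy == 0] <- NA
  n <- length(shared)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[is.nan(p)] <- 0  # |r| = 1 exactly
  stars <- matrix(symnum(p, cutpoints = c(0, 0.001, 0.01, 0.05, 1),
                         symbols = c("***", "**", "*", ""), corr = FALSE,
                         na = ""),
                  nrow(p), ncol(p), dimnames = dimnames(p))
  out <- list(r = r, p = p, stars = stars, n = n)
  if (adjust) {
    q <- p
    q[] <- p.adjust(as.vector(p), method = "BH")
    out$q <- q
  }
  out
}

# Duncan's least significant range for a stretch of p ordered means:
# studentized range at protected level 1 - (1 - alpha)^(p - 1)
.duncanLSR <- function(p, df, mse, nh, alpha) {
  qtukey(1 - (1 - (1 - alpha)^(p - 1)), nmeans = p, df = df) * sqrt(mse / nh)
}

#' Duncan's multiple range test with letter groupings
#'
#' One-way layout: the pooled ANOVA mean square error and residual df are
#' computed, group means are sorted, and each stretch of `p` consecutive
#' means is compared against the least significant range
#' `q(1 - (1 - alpha)^(p - 1), p, df) * sqrt(MSE / n_h)` (harmonic-mean
#' group size for unbalanced data) by the usual step-down procedure: a
#' stretch whose range does not exceed its critical value is declared
#' homogeneous and not subdivided. Letters are assigned so that two
#' groups share a letter iff the procedure did not separate their means.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (at least 2 groups, each with at least 2
#'   observations).
#' @param alpha Protection level (default 0.05).
#' @return List: `letters` (named character, one per group), `means`
#'   (named, descending), `mse`, `df`, `nonsig` (logical matrix of the
#'   pairwise non-separation relation, in descending-mean order).
#' @export
duncanGroups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ns <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(ns < 2L)) stop("each group needs at least 2 observations: ",
                         paste(names(ns)[ns < 2], collapse = ", "))
  gm <- tapply(values, groups, mean)
  sse <- sum((values - gm[groups])^2)
  df <- length(values) - nlevels(groups)
  mse <- sse / df
  nh <- nlevels(groups) / sum(1 / ns)
  means <- sort(gm, decreasing = TRUE)
  k <- length(means)

  nonsig <- diag(k) > 0
  if (mse == 0) {
    # zero residual variance: any nonzero difference separates
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      nonsig[i, j] <- nonsig[j, i] <- means[i] == means[j]
  } else {
    mark <- function(i, j) {
      if (j <= i) return(invisible())
      if (nonsig[i, j]) return(invisible())  # already covered
      p <- j - i + 1L
      if (means[i] - means[j] <= .duncanLSR(p, df, mse, nh, alpha)) {
        nonsig[i:j, i:j] <<- TRUE
      } else {
        mark(i, j - 1L)
        mark(i + 1L, j)
      }
      invisible()
    }
    mark(1L, k)
  }

  # letters: maximal homogeneous stretches of the sorted means
  stretches <- list()
  i <- 1L
  lastEnd <- 0L
  for (i in seq_len(k)) {
    j <- max(which(nonsig[i, ]))
    if (j > lastEnd) {
      stretches[[length(stretches) + 1L]] <- c(i, j)
      lastEnd <- j
    }
  }
  lab <- rep("", k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]]
    lab[rng[1]:rng[2]] <- paste0(lab[rng[1]:rng[2]], letters[s])
  }
  letters_out <- setNames(lab, names(means))[levels(groups)]
  list(letters = letters_out, means = means, mse = mse, df = df,
       nonsig = nonsig)
}

#' Fatty-acid class sums and nutritional ratios
#'
#' Per-sample totals of each labelled class (SFA, MUFA, PUFA) and the
#' PUFA/SFA and n-6/n-3 ratios; a zero denominator yields `NA`. Traits
#' with class `"other"` (e.g. IMF) are excluded from the sums.
#'
#' @param traits Sample-by-trait data.frame/matrix (values >= 0).
#' @param classes data.frame with columns `trait`, `class`
#'   (SFA/MUFA/PUFA/other) and `family` (`"n-3"`, `"n-6"` or `NA`), one
#'   row per trait column.
#' @return data.frame per sample: `SFA`, `MUFA`, `PUFA`, `n6`, `n3`,
#'   `pufa_sfa`, `n6_n3`.
#' @export
fattyAcidRatios <- function(traits, classes) {
  tr <- as.matrix(traits)
  unlabeled <- setdiff(colnames(tr), classes$trait)
  if (length(unlabeled))
    stop("trait(s) without class label: ", paste(unlabeled, collapse = ", "))
  cls <- classes$class[match(colnames(tr), classes$trait)]
  fam <- classes$family[match(colnames(tr), classes$trait)]
  sumOf <- function(sel)
    if (any(sel)) rowSums(tr[, sel, drop = FALSE]) else
      rep(0, nrow(tr))
  sfa <- sumOf(cls == "SFA"); mufa <- sumOf(cls == "MUFA")
  pufa <- sumOf(cls == "PUFA")
  n6 <- sumOf(!is.na(fam) & fam == "n-6")
  n3 <- sumOf(!is.na(fam) & fam == "n-3")
  data.frame(
    SFA = sfa, MUFA = mufa, PUFA = pufa, n6 = n6, n3 = n3,
    pufa_sfa = ifelse(sfa > 0, pufa / sfa, NA_real_),
    n6_n3 = ifelse(n3 > 0, n6 / n3, NA_real_),
    row.names = rownames(tr))
}
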