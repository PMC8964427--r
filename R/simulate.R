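# Synthetic ceRNA study generator. One integer seed drives everything;
# each operation derives its own sub-seed so outputs are bit-identical for
# identical configs regardless of call order.

.simSeed <- function(config, k) (config@seed %% 1000003L) * 1000L + k

.GENE_SPACE <- 2e6

# exon GRanges for one transcript laid left-to-right from `start`
.makeExons <- function(chrom, start, exonWidths, intronWidths, strand) {
  stopifnot(length(intronWidths) == length(exonWidths) - 1L)
  starts <- start + cumsum(c(0L, head(exonWidths, -1) + intronWidths))
  GRanges(chrom, IRanges(start = starts, width = exonWidths), strand = strand)
}

.lncStructure <- function() {
  nEx <- sample(2:4, 1)
  ew <- sample(150:900, nEx, replace = TRUE)
  iw <- if (nEx > 1) sample(200:2000, nEx - 1, replace = TRUE) else integer()
  list(ew = ew, iw = iw)
}

#' Simulate an assembled transcript annotation with labelled decoys
#'
#' Generates mRNAs (2-10 kb, 4-20 exons, ORF about one third of length,
#' high coding score) and lncRNAs (0.2-3 kb, 2-4 exons, ORF < 300 nt, low
#' coding score), spaced 2 Mb apart on one chromosome. Among the novel
#' candidates it plants: cis pairs within the 100-kb window (and decoy loci
#' beyond it), intronic / antisense / bidirectional / intergenic positional
#' classes, and per-rule filter decoys (too short, single exon, same-strand
#' exonic overlap with an mRNA, coding-potential calls, known class code,
#' database annotation) each violating exactly the recorded rule.
#'
#' @param config A [SimConfig-class].
#' @return A list with `transcripts` (a [TranscriptSet-class]) and `truth`,
#'   a list holding `novel_true`, `decoys` (transcript_id, rule),
#'   `cis_near` / `cis_far` (lncRNA, gene, distance) and `positional`
#'   (lncRNA, class).
#' @export
simulateAnnotation <- function(config) {
  validObject(config)
  set.seed(.simSeed(config, 1L))
  nIntronic <- min(2L, max(0L, config@nNovelLnc - config@nCisNear))
  nAnti <- min(2L, max(0L, config@nNovelLnc - config@nCisNear - nIntronic))
  nBidi <- min(2L, max(0L, config@nNovelLnc - config@nCisNear - nIntronic - nAnti))
  nInter <- config@nNovelLnc - config@nCisNear - nIntronic - nAnti - nBidi
  if (nInter < 0)
    stop("nNovelLnc too small for the requested cis placements")
  nHosts <- config@nCisNear + config@nCisFar + nIntronic + nAnti + nBidi +
    config@nDecoysPerRule  # coding-overlap decoys need hosts too
  if (nHosts > config@nMrna)
    stop("nMrna too small to host the requested placements/decoys")
  hostGene <- seq_len(nHosts)          # genes forced to '+' strand
  intronicHosts <- hostGene[config@nCisNear + config@nCisFar + seq_len(nIntronic)]

  ## ---- mRNAs -------------------------------------------------------------
  mrnaIds <- sprintf("MRNA.%04d", seq_len(config@nMrna))
  geneIds <- sprintf("GENE.%04d", seq_len(config@nMrna))
  mEx <- vector("list", config@nMrna)
  mOrf <- integer(config@nMrna)
  for (i in seq_len(config@nMrna)) {
    nEx <- sample(4:20, 1)
    L <- runif(1, 2000, 10000)
    w <- runif(nEx)
    ew <- pmax(60L, as.integer(round(w / sum(w) * L)))
    iw <- sample(200:5000, nEx - 1, replace = TRUE)
    if (i %in% intronicHosts) iw[1] <- 60000L
    strand <- if (i %in% hostGene) "+" else sample(c("+", "-"), 1)
    mEx[[i]] <- .makeExons("chr1", (i - 1) * .GENE_SPACE + 10001, ew, iw, strand)
    mOrf[i] <- max(300L, as.integer(round(sum(ew) / 3)))
  }
  mrnaTd <- DataFrame(
    transcript_id = mrnaIds, gene_id = geneIds, class_code = "=",
    orf_length = mOrf, coding_call_a = TRUE, coding_call_b = TRUE,
    coding_score = runif(config@nMrna, 0.8, 1), biotype = "mRNA",
    db_annotated = TRUE)
  mrnaSpan <- unlist(range(GRangesList(mEx)))

  ## ---- lncRNA placement helpers -------------------------------------------
  slot <- 0L
  midGapStart <- function() {  # a fresh collision-free slot far from any gene
    slot <<- slot + 1L
    g <- ((slot - 1L) %% config@nMrna)
    off <- 600000 + ((slot - 1L) %/% config@nMrna) * 25000 +
      (slot %% 12L) * 25000
    as.integer(g * .GENE_SPACE + 10001 + off)
  }
  lncGRanges <- function(start, strand = "+") {
    st <- .lncStructure()
    .makeExons("chr1", start, st$ew, st$iw, strand)
  }

  exList <- list(); tdList <- list()
  addTx <- function(id, exons, class_code, orf, callA, callB, score, biotype,
                    annotated = FALSE, gene = id) {
    exList[[id]] <<- exons
    tdList[[id]] <<- DataFrame(
      transcript_id = id, gene_id = gene, class_code = class_code,
      orf_length = as.integer(orf), coding_call_a = callA,
      coding_call_b = callB, coding_score = score, biotype = biotype,
      db_annotated = annotated)
  }

  ## ---- known lncRNAs -------------------------------------------------------
  for (i in seq_len(config@nKnownLnc))
    addTx(sprintf("LNC.K.%03d", i), lncGRanges(midGapStart()), "=",
          sample(30:290, 1), FALSE, FALSE, runif(1, 0, 0.3), "known_lncRNA",
          annotated = TRUE)

  ## ---- novel lncRNAs (true positives) --------------------------------------
  novelIds <- sprintf("MSTRG.%d.1", 100 + seq_len(config@nNovelLnc))
  cisNear <- cisFar <- list(); positional <- list()
  gi <- 0L
  newNovel <- function(id, exons, posClass) {
    addTx(id, exons, sample(.NOVEL_CLASS_CODES, 1), sample(30:290, 1),
          FALSE, FALSE, runif(1, 0, 0.3), "novel_candidate")
    positional[[id]] <<- data.frame(lncRNA = id, class = posClass)
  }
  k <- 0L
  for (j in seq_len(config@nCisNear)) {          # within-window cis pairs
    k <- k + 1L; gi <- gi + 1L
    d <- sample(0:100000, 1)
    start <- end(mrnaSpan[gi]) + d + 1L
    newNovel(novelIds[k], lncGRanges(start, "+"), "intergenic")
    cisNear[[novelIds[k]]] <- data.frame(
      lncRNA = novelIds[k], gene = mrnaIds[gi], distance = d)
  }
  for (j in seq_len(config@nCisFar)) {           # beyond-window decoy loci
    gi <- gi + 1L
    d <- sample(150000:400000, 1)
    id <- sprintf("MSTRG.F%d.1", j)
    addTx(id, lncGRanges(end(mrnaSpan[gi]) + d + 1L, "+"),
          sample(.NOVEL_CLASS_CODES, 1), sample(30:290, 1), FALSE, FALSE,
          runif(1, 0, 0.3), "novel_candidate")
    positional[[id]] <- data.frame(lncRNA = id, class = "intergenic")
    cisFar[[id]] <- data.frame(lncRNA = id, gene = mrnaIds[gi], distance = d)
  }
  for (j in seq_len(nIntronic)) {                # inside a forced 60-kb intron
    k <- k + 1L; gi <- gi + 1L
    firstExonEnd <- end(mEx[[gi]][1])
    newNovel(novelIds[k],
             .makeExons("chr1", firstExonEnd + 2000L,
                        c(150L, 150L), 300L, "+"), "intronic")
  }
  for (j in seq_len(nAnti)) {                    # opposite-strand overlap
    k <- k + 1L; gi <- gi + 1L
    newNovel(novelIds[k],
             lncGRanges(start(mrnaSpan[gi]) + 50L, "-"), "antisense")
  }
  for (j in seq_len(nBidi)) {                    # divergent promoter partner
    k <- k + 1L; gi <- gi + 1L
    st <- .lncStructure()
    spanW <- sum(st$ew) + sum(st$iw)
    lstart <- start(mrnaSpan[gi]) - sample(200:800, 1) - spanW
    newNovel(novelIds[k], .makeExons("chr1", lstart, st$ew, st$iw, "-"),
             "bidirectional")
  }
  for (j in seq_len(nInter))  {                  # plain intergenic
    k <- k + 1L
    newNovel(novelIds[k], lncGRanges(midGapStart()), "intergenic")
  }

  ## ---- filter decoys (each violates exactly one rule) ----------------------
  decoys <- list()
  addDecoy <- function(id, exons, rule, class_code = "u", callA = FALSE,
                       callB = FALSE, annotated = FALSE) {
    addTx(id, exons, class_code, 25L, callA, callB, runif(1, 0, 0.3),
          "novel_candidate", annotated = annotated)
    decoys[[id]] <<- data.frame(transcript_id = id, rule = rule)
  }
  for (j in seq_len(config@nDecoysPerRule)) {
    addDecoy(sprintf("DECOY.len.%02d", j),
             .makeExons("chr1", midGapStart(), c(70L, 80L), 400L, "+"),
             "length")
    addDecoy(sprintf("DECOY.exon.%02d", j),
             GRanges("chr1", IRanges(midGapStart(), width = 500), strand = "+"),
             "exon_count")
    gi <- gi + 1L                                # same-strand exonic overlap
    e1 <- mEx[[gi]][1]
    addDecoy(sprintf("DECOY.olap.%02d", j),
             GRanges("chr1",
                     IRanges(start = c(start(e1) + 10L, end(mrnaSpan[gi]) + 5000L),
                             width = c(min(150L, width(e1) - 20L), 200L)),
                     strand = "+"),
             "coding_overlap")
    addDecoy(sprintf("DECOY.code.%02d", j), lncGRanges(midGapStart()),
             "coding_potential", callA = (j %% 2L == 0L), callB = TRUE)
    addDecoy(sprintf("DECOY.class.%02d", j), lncGRanges(midGapStart()),
             "class_code", class_code = "=")
    addDecoy(sprintf("DECOY.anno.%02d", j), lncGRanges(midGapStart()),
             "known_annotation", annotated = TRUE)
  }

  td <- rbind(mrnaTd, do.call(rbind, unname(tdList)))
  exl <- GRangesList(c(setNames(mEx, mrnaIds), exList))
  ts <- TranscriptSet(exl[td$transcript_id], td)
  truth <- list(
    novel_true = novelIds,
    expected_pass = c(novelIds, names(cisFar)),
    decoys = do.call(rbind, c(unname(decoys),
                              list(data.frame(transcript_id = character(),
                                              rule = character())))),
    cis_near = do.call(rbind, c(unname(cisNear),
                                list(data.frame(lncRNA = character(),
                                                gene = character(),
                                                distance = integer())))),
    cis_far = do.call(rbind, c(unname(cisFar),
                               list(data.frame(lncRNA = character(),
                                               gene = character(),
                                               distance = integer())))),
    positional = do.call(rbind, unname(positional)))
  list(transcripts = ts, truth = truth)
}

.stageComparisons <- function(stageLabels) {
  n <- length(stageLabels)
  idx <- cbind(seq_len(n - 1), 2:n)
  if (n > 2) idx <- rbind(idx, c(1L, n))
  lapply(seq_len(nrow(idx)),
         function(i) c(stageLabels[idx[i, 1]], stageLabels[idx[i, 2]]))
}

#' Simulate tri-layer expression with planted DE features and ceRNA triads
#'
#' Baseline abundances are log-normal with lncRNA means below mRNA means
#' (and novel lncRNAs slightly above known ones). Planted DE lncRNAs are
#' shifted by `deLog2fc` in one stage of their designated comparison.
#' Each planted triad shares a latent factor: its lncRNA and mRNA load
#' `+triadEffect`, its sponge miRNAs `-triadEffect`, plus
#' `N(0, noiseSd^2)` replicate noise on the log2 scale, inducing strong
#' positive lncRNA-mRNA and negative miRNA correlations.
#'
#' @param annotation Result of [simulateAnnotation()] (list) or a
#'   [TranscriptSet-class].
#' @param config A [SimConfig-class].
#' @param truth Truth ledger to extend (defaults to `annotation$truth`).
#' @return List with `lnc`, `mir`, `mrna` ([ExpressionMatrix-class]) and
#'   `truth` gaining `planted_de` (comparison, feature, direction) and
#'   `planted_triads` (lncRNA, mRNA, mirnas list-column).
#' @export
simulateExpression <- function(annotation, config, truth = NULL) {
  ts <- if (is(annotation, "TranscriptSet")) annotation else annotation$transcripts
  if (is.null(truth))
    truth <- if (is.list(annotation)) annotation$truth else list()
  set.seed(.simSeed(config, 2L))
  td <- txData(ts)
  lncIds <- td$transcript_id[td$biotype %in% c("known_lncRNA", "novel_candidate")]
  mrnaIds <- td$transcript_id[td$biotype == "mRNA"]
  mirIds <- sprintf("miR-%03d", seq_len(config@nMirna))
  stage <- rep(config@stageLabels, each = config@nReps)
  samples <- paste0(stage, "_r", rep(seq_len(config@nReps), config@nStages))
  nS <- length(samples)

  mu <- c(setNames(ifelse(td[lncIds, "biotype"] == "known_lncRNA",
                          rnorm(length(lncIds), 1.5, 1),
                          rnorm(length(lncIds), 2, 1)), lncIds),
          setNames(rnorm(length(mrnaIds), 5, 1), mrnaIds),
          setNames(rnorm(length(mirIds), 4, 1), mirIds))
  log2m <- matrix(mu, nrow = length(mu), ncol = nS,
                  dimnames = list(names(mu), samples))

  ## planted triads: shared latent factor per triad
  novel <- truth$novel_true %||% lncIds
  if (config@nPlantedTriads > 0) {
    tl <- novel[seq_len(config@nPlantedTriads)]
    tm <- sample(mrnaIds, config@nPlantedTriads)
    mirPool <- sample(mirIds)
    msets <- vector("list", config@nPlantedTriads)
    for (t in seq_len(config@nPlantedTriads)) {
      mset <- mirPool[(t - 1) * config@nSharedMirnas + seq_len(config@nSharedMirnas)]
      f <- rnorm(nS)
      log2m[tl[t], ] <- log2m[tl[t], ] + config@triadEffect * f
      log2m[tm[t], ] <- log2m[tm[t], ] + config@triadEffect * f
      for (m in mset) log2m[m, ] <- log2m[m, ] - config@triadEffect * f
      msets[[t]] <- mset
    }
    plantedTriads <- data.frame(lncRNA = tl, mRNA = tm,
                                stringsAsFactors = FALSE)
    plantedTriads$mirnas <- msets
  } else {
    plantedTriads <- data.frame(lncRNA = character(), mRNA = character(),
                                stringsAsFactors = FALSE)
    plantedTriads$mirnas <- list()
  }

  ## planted DE lncRNAs, disjoint from triad members
  comparisons <- .stageComparisons(config@stageLabels)
  plantedDe <- data.frame(comparison = character(), feature = character(),
                          direction = character())
  if (config@nPlantedDe > 0) {
    pool <- setdiff(novel, plantedTriads$lncRNA)
    need <- config@nPlantedDe * length(comparisons)
    if (length(pool) < need)
      stop("not enough non-triad novel lncRNAs for the requested planted DE")
    pool <- sample(pool, need)
    k <- 0L
    for (cmp in comparisons) {
      for (j in seq_len(config@nPlantedDe)) {
        k <- k + 1L
        dir <- if (j %% 2L == 1L) "up" else "down"
        shift <- if (dir == "up") config@deLog2fc else -config@deLog2fc
        log2m[pool[k], stage == cmp[2]] <-
          log2m[pool[k], stage == cmp[2]] + shift
        plantedDe <- rbind(plantedDe, data.frame(
          comparison = paste(cmp[1], "vs", cmp[2]),
          feature = pool[k], direction = dir))
      }
    }
  }

  if (config@noiseSd > 0)
    log2m <- log2m + matrix(rnorm(length(log2m), 0, config@noiseSd),
                            nrow = nrow(log2m))
  ab <- 2^log2m

  mk <- function(ids, layer)
    ExpressionMatrix(ab[ids, , drop = FALSE], stage = stage, layer = layer)
  truth$planted_de <- plantedDe
  truth$planted_triads <- plantedTriads
  list(lnc = mk(lncIds, "lncRNA"), mir = mk(mirIds, "miRNA"),
       mrna = mk(mrnaIds, "mRNA"), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate miRNA target sets
#'
#' Every planted triad's shared miRNAs target both its lncRNA and mRNA;
#' background miRNA-target assignments are drawn uniformly at density
#' `targetDensity` over all (miRNA, feature) pairs.
#'
#' @param config A [SimConfig-class].
#' @param truth Truth ledger holding `planted_triads`.
#' @param lncIds,mrnaIds,mirIds Feature universes (e.g. rownames of the
#'   simulated matrices).
#' @return Named list: miRNA id -> character vector of target feature ids.
#' @export
simulateTargetSets <- function(config, truth, lncIds, mrnaIds, mirIds) {
  set.seed(.simSeed(config, 3L))
  targets <- setNames(vector("list", length(mirIds)), mirIds)
  for (m in mirIds) targets[[m]] <- character()
  pt <- truth$planted_triads
  if (!is.null(pt) && nrow(pt))
    for (t in seq_len(nrow(pt)))
      for (m in pt$mirnas[[t]])
        targets[[m]] <- union(targets[[m]], c(pt$lncRNA[t], pt$mRNA[t]))
  if (config@targetDensity > 0) {
    feats <- c(lncIds, mrnaIds)
    for (m in mirIds) {
      bg <- feats[runif(length(feats)) < config@targetDensity]
      targets[[m]] <- union(targets[[m]], bg)
    }
  }
  targets
}

.FATTY_ACID_CLASSES <- data.frame(
  trait = c("C14:0", "C16:0", "C18:0", "C14:1", "C16:1", "C17:1",
            "C18:1n9", "C18:2n6", "C18:3n3", "C20:4n6", "C20:5n3", "IMF"),
  class = c("SFA", "SFA", "SFA", "MUFA", "MUFA", "MUFA", "MUFA",
            "PUFA", "PUFA", "PUFA", "PUFA", "other"),
  family = c(NA, NA, NA, NA, NA, NA, NA, "n-6", "n-3", "n-6", "n-3", NA),
  stringsAsFactors = FALSE)

#' Simulate trait tables (fatty acids, IMF) tied to lncRNA expression
#'
#' Planted (lncRNA, trait) pairs are generated as
#' `trait = r * z(expr) + sqrt(1 - r^2) * noise` on a standardized scale
#' (then shifted to positive units), so the population correlation with
#' log2 expression equals `traitEffectR` (alternating sign across planted
#' pairs). Remaining traits are independent noise. Traits carry fatty-acid
#' class labels (SFA/MUFA/PUFA, n-3/n-6) for ratio computation.
#'
#' @param lncEm lncRNA [ExpressionMatrix-class].
#' @param config A [SimConfig-class].
#' @param truth Truth ledger to extend.
#' @return List with `traits` (sample-by-trait data.frame), `classes`
#'   (trait, class, family) and `truth` gaining `planted_traits`
#'   (lncRNA, trait, r).
#' @export
simulateTraits <- function(lncEm, config, truth = list()) {
  set.seed(.simSeed(config, 4L))
  classes <- .FATTY_ACID_CLASSES[seq_len(min(config@nTraits,
                                             nrow(.FATTY_ACID_CLASSES))), ]
  samples <- colnames(lncEm)
  nS <- length(samples)
  lncIds <- intersect(truth$novel_true %||% rownames(lncEm), rownames(lncEm))
  traits <- matrix(NA_real_, nS, nrow(classes),
                   dimnames = list(samples, classes$trait))
  planted <- data.frame(lncRNA = character(), trait = character(),
                        r = numeric())
  nPlant <- min(nrow(classes), length(lncIds))
  logx <- log2(abundance(lncEm) + 1)
  for (j in seq_len(nrow(classes))) {
    if (j <= nPlant) {
      r <- config@traitEffectR * (-1)^(j + 1)
      x <- logx[lncIds[j], ]
      z <- if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, nS)
      tz <- r * z + sqrt(max(0, 1 - r^2)) * rnorm(nS)
      planted <- rbind(planted, data.frame(
        lncRNA = lncIds[j], trait = classes$trait[j], r = r))
    } else tz <- rnorm(nS)
    traits[, j] <- 10 + tz
  }
  truth$planted_traits <- planted
  list(traits = as.data.frame(traits), classes = classes, truth = truth)
}

#' Simulate a qPCR Ct table from expression values
#'
#' `Ct = c0 - log2(abundance) + noise`, with a constant-abundance reference
#' feature (a beta-actin analogue) shared by all targets of a sample.
#'
#' @param em An [ExpressionMatrix-class].
#' @param features Feature ids to assay (default: up to 10 rows of `em`).
#' @param config A [SimConfig-class] (seed and noise; Ct noise sd is
#'   `noiseSd`).
#' @param c0 Intercept cycles (default 25).
#' @param refCt Reference-gene Ct (default 15).
#' @return data.frame with `sample_id`, `group`, `target_id`, `ct_target`,
#'   `ct_reference`.
#' @export
simulateQpcr <- function(em, features = head(rownames(em), 10), config,
                         c0 = 25, refCt = 15) {
  set.seed(.simSeed(config, 5L))
  ab <- abundance(em)[features, , drop = FALSE]
  stage <- stages(em)
  refs <- refCt + rnorm(ncol(ab), 0, config@noiseSd)
  recs <- lapply(seq_along(features), function(i) {
    data.frame(sample_id = colnames(ab), group = unname(stage),
               target_id = features[i],
               ct_target = c0 - log2(ab[i, ]) + rnorm(ncol(ab), 0, config@noiseSd),
               ct_reference = refs, row.names = NULL)
  })
  do.call(rbind, recs)
}

#' Simulate a term-to-gene annotation with one enriched term
#'
#' Term `T01` ("lipid metabolic process" analogue) is loaded with the
#' planted triad mRNAs plus a few background genes; remaining terms draw
#' random gene sets. Supports end-to-end over-representation testing.
#'
#' @param config A [SimConfig-class].
#' @param truth Truth ledger holding `planted_triads`.
#' @param mrnaIds mRNA universe.
#' @param nTerms Number of terms (default 10).
#' @return List with `annotation` (term, gene) and `termNames`
#'   (term, name).
#' @export
simulateTermAnnotation <- function(config, truth, mrnaIds, nTerms = 10L) {
  set.seed(.simSeed(config, 6L))
  terms <- sprintf("T%02d", seq_len(nTerms))
  planted <- unique(truth$planted_triads$mRNA)
  ann <- list(data.frame(
    term = terms[1],
    gene = union(planted, sample(mrnaIds, min(5L, length(mrnaIds))))))
  for (t in terms[-1]) {
    sz <- sample(5:30, 1)
    ann[[t]] <- data.frame(term = t, gene = sample(mrnaIds, min(sz, length(mrnaIds))))
  }
  list(annotation = do.call(rbind, ann),
       termNames = data.frame(
         term = terms,
         name = c("lipid metabolic process",
                  paste("background process", seq_len(nTerms - 1)))))
}

#' Simulate a complete staged ceRNA study
#'
#' Runs [simulateAnnotation()], [simulateExpression()],
#' [simulateTargetSets()], [simulateTraits()], [simulateQpcr()] and
#' [simulateTermAnnotation()] under one config and merges the truth ledger.
#'
#' @param config A [SimConfig-class].
#' @return List: `transcripts`, `lnc`, `mir`, `mrna`, `targets`, `traits`,
#'   `traitClasses`, `qpcr`, `terms`, `truth`.
#' @export
simulateCeRNAStudy <- function(config = simConfig()) {
  ann <- simulateAnnotation(config)
  expr <- simulateExpression(ann, config)
  targets <- simulateTargetSets(config, expr$truth,
                                lncIds = rownames(expr$lnc),
                                mrnaIds = rownames(expr$mrna),
                                mirIds = rownames(expr$mir))
  tr <- simulateTraits(expr$lnc, config, expr$truth)
  qpcr <- simulateQpcr(expr$lnc,
                       features = head(expr$truth$novel_true, 10),
                       config = config)
  terms <- simulateTermAnnotation(config, tr$truth, rownames(expr$mrna))
  list(transcripts = ann$transcripts, lnc = expr$lnc, mir = expr$mir,
       mrna = expr$mrna, targets = targets, traits = tr$traits,
       traitClasses = tr$classes, qpcr = qpcr, terms = terms,
       truth = tr$truth)
}
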