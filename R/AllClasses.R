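#' TranscriptSet: assembled transcripts with exon structure and evidence
#'
#' Container for a set of assembled transcripts. Exon structure lives in a
#' named [GenomicRanges::GRangesList] (one element per transcript, exons
#' sorted and disjoint, all on one chromosome and strand); per-transcript
#' evidence lives in a parallel [S4Vectors::DataFrame] with columns
#' `transcript_id`, `gene_id`, `class_code` (assembler class code such as
#' `"u"` or `"="`), `orf_length` (nt, `NA` if unknown), `coding_call_a` /
#' `coding_call_b` (logical; `TRUE` means the predictor called the
#' transcript *coding*), `coding_score`, `biotype` (one of `mRNA`,
#' `known_lncRNA`, `novel_candidate`, `other_ncRNA`) and `db_annotated`
#' (logical; `TRUE` if the transcript matched a protein/ncRNA database
#' entry).
#'
#' @slot exons A named `GRangesList` of exons per transcript.
#' @slot txData A `DataFrame` of per-transcript metadata, rows parallel to
#'   `exons`.
#' @seealso [TranscriptSet()], [readGtf()], [txLength()], [txSpan()]
#' @export
setClass("TranscriptSet",
         slots = c(exons = "GRangesList", txData = "DataFrame"))

.TX_BIOTYPES <- c("mRNA", "known_lncRNA", "novel_candidate", "other_ncRNA")
.TX_COLS <- c("transcript_id", "gene_id", "class_code", "orf_length",
              "coding_call_a", "coding_call_b", "coding_score", "biotype",
              "db_annotated")

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  msg <- character()
  if (length(ex) != nrow(td))
    return("exons and txData have different lengths")
  miss <- setdiff(.TX_COLS, colnames(td))
  if (length(miss))
    return(paste("txData missing columns:", paste(miss, collapse = ", ")))
  if (!identical(names(ex), as.character(td$transcript_id)))
    msg <- c(msg, "names(exons) must equal txData$transcript_id")
  if (anyDuplicated(td$transcript_id))
    msg <- c(msg, "duplicated transcript_id")
  if (length(ex)) {
    nchrom <- elementNROWS(runValue(seqnames(ex)))
    nstr <- elementNROWS(runValue(strand(ex)))
    if (any(nchrom != 1L))
      msg <- c(msg, paste("transcripts on mixed chromosomes:",
                          paste(head(names(ex)[nchrom != 1L], 3), collapse = ", ")))
    if (any(nstr != 1L))
      msg <- c(msg, "transcripts on mixed strands")
    if (!all(unlist(lapply(start(ex), function(s) !is.unsorted(s, strictly = TRUE)))))
      msg <- c(msg, "exons must be sorted by start within each transcript")
    if (any(!isDisjoint(ex)))
      msg <- c(msg, "exons overlap within a transcript")
    len <- sum(width(ex))
    if (any(len <= 0L))
      msg <- c(msg, "transcript length must be positive")
    bad_orf <- !is.na(td$orf_length) & td$orf_length > len
    if (any(bad_orf))
      msg <- c(msg, "orf_length exceeds transcript length")
    if (!all(td$biotype %in% .TX_BIOTYPES))
      msg <- c(msg, "invalid biotype")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons Named `GRangesList` of exons, one element per transcript.
#'   Elements are sorted by start internally.
#' @param txData `DataFrame`/`data.frame` of per-transcript metadata with a
#'   `transcript_id` column matching `names(exons)`. Missing evidence
#'   columns are filled with `NA`/defaults (`db_annotated = FALSE`).
#' @return A [TranscriptSet-class] object.
#' @export
TranscriptSet <- function(exons, txData) {
  td <- as(txData, "DataFrame")
  if (is.null(td$transcript_id))
    stop("txData must carry a transcript_id column")
  td$transcript_id <- as.character(td$transcript_id)
  if (is.null(td$gene_id)) td$gene_id <- td$transcript_id
  if (is.null(td$class_code)) td$class_code <- "="
  if (is.null(td$orf_length)) td$orf_length <- NA_integer_
  if (is.null(td$coding_call_a)) td$coding_call_a <- NA
  if (is.null(td$coding_call_b)) td$coding_call_b <- NA
  if (is.null(td$coding_score)) td$coding_score <- NA_real_
  if (is.null(td$biotype))
    td$biotype <- ifelse(td$class_code %in% .NOVEL_CLASS_CODES,
                         "novel_candidate", "mRNA")
  if (is.null(td$db_annotated)) td$db_annotated <- FALSE
  ex <- sort(exons)
  ex <- ex[td$transcript_id]
  rownames(td) <- td$transcript_id
  new("TranscriptSet", exons = ex, txData = td)
}

setMethod("show", "TranscriptSet", function(object) {
  tab <- table(object@txData$biotype)
  cat("TranscriptSet with", length(object@exons), "transcripts\n")
  if (length(tab))
    cat("  biotypes:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
})

#' ExpressionMatrix: one RNA layer of a staged expression study
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' feature-by-sample abundance assay (`"abundance"`, non-negative, FPKM or
#' counts), a column design with `stage` and `replicate`, and the RNA layer
#' (`lncRNA`, `miRNA` or `mRNA`) in `metadata(x)$layer`.
#'
#' @seealso [ExpressionMatrix()], [abundance()], [stages()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (anyNA(a)) msg <- c(msg, "abundance contains NA")
  else if (any(a < 0)) msg <- c(msg, "abundance contains negative values")
  if (!"stage" %in% colnames(colData(object)))
    msg <- c(msg, "colData must carry a stage column")
  ly <- metadata(object)$layer
  if (is.null(ly) || !ly %in% c("lncRNA", "miRNA", "mRNA"))
    msg <- c(msg, "metadata layer must be one of lncRNA/miRNA/mRNA")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated feature ids")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values Numeric feature-by-sample matrix (non-negative; FPKM or
#'   counts), with feature ids as rownames and sample ids as colnames.
#' @param stage Character/factor of per-sample stage labels.
#' @param replicate Optional per-sample replicate labels; defaults to a
#'   running index within stage.
#' @param layer RNA layer, one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @return An [ExpressionMatrix-class].
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' ExpressionMatrix(m, stage = c("4m", "1.5y"), layer = "lncRNA")
#' @export
ExpressionMatrix <- function(values, stage,
                             replicate = NULL,
                             layer = c("lncRNA", "miRNA", "mRNA")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  stage <- as.character(stage)
  if (length(stage) != ncol(values))
    stop("stage must have one entry per sample column")
  if (is.null(replicate))
    replicate <- as.integer(stats::ave(seq_along(stage), stage, FUN = seq_along))
  se <- SummarizedExperiment(
    assays = list(abundance = values),
    colData = DataFrame(stage = stage, replicate = replicate,
                        row.names = colnames(values)),
    metadata = list(layer = layer))
  new("ExpressionMatrix", se)
}

#' SimConfig: parameters of the synthetic ceRNA study generator
#'
#' Defaults describe the simulated study design: 4 stages x 4 replicates
#' (16 samples), 200 mRNAs, 20 known + 20 novel lncRNAs, 50 miRNAs,
#' 10 planted ceRNA triads with effect 0.95 under log-scale noise sd 0.1,
#' 2 planted DE lncRNAs per stage comparison at |log2FC| = 2, and planted
#' lncRNA-trait correlations of magnitude 0.65.
#'
#' @slot seed integer; single seed governing all generator randomness.
#' @slot nMrna,nKnownLnc,nNovelLnc,nMirna feature counts per layer.
#' @slot nStages,nReps design dimensions.
#' @slot stageLabels stage names, oldest last.
#' @slot nPlantedDe planted DE lncRNAs per comparison.
#' @slot deLog2fc planted log2 fold change (> 0).
#' @slot nPlantedTriads planted ceRNA triads.
#' @slot triadEffect latent-factor loading in (0, 1]; the population
#'   lncRNA-mRNA correlation is `triadEffect^2 / (triadEffect^2 + noiseSd^2)`.
#' @slot nSharedMirnas shared sponge miRNAs per planted triad.
#' @slot noiseSd log2-scale replicate noise sd.
#' @slot targetDensity background miRNA-target density in \[0, 1\].
#' @slot nTraits number of simulated traits (fatty acids / IMF).
#' @slot traitEffectR planted lncRNA-trait correlation in (-1, 1).
#' @slot nCisNear,nCisFar planted cis pairs within / beyond the window.
#' @slot nDecoysPerRule labelled filter decoys per violated rule.
#' @seealso [simConfig()], [simulateCeRNAStudy()]
#' @export
setClass("SimConfig", slots = c(
  seed = "integer",
  nMrna = "integer", nKnownLnc = "integer", nNovelLnc = "integer",
  nMirna = "integer", nStages = "integer", nReps = "integer",
  stageLabels = "character",
  nPlantedDe = "integer", deLog2fc = "numeric",
  nPlantedTriads = "integer", triadEffect = "numeric",
  nSharedMirnas = "integer", noiseSd = "numeric",
  targetDensity = "numeric",
  nTraits = "integer", traitEffectR = "numeric",
  nCisNear = "integer", nCisFar = "integer",
  nDecoysPerRule = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(object@nMrna, object@nKnownLnc, object@nNovelLnc, object@nMirna,
           object@nStages, object@nReps, object@nPlantedDe,
           object@nPlantedTriads, object@nSharedMirnas, object@nTraits,
           object@nCisNear, object@nCisFar, object@nDecoysPerRule)
  if (any(cnt < 0L)) msg <- c(msg, "counts must be >= 0")
  if (object@deLog2fc <= 0) msg <- c(msg, "deLog2fc must be > 0")
  if (object@triadEffect <= 0 || object@triadEffect > 1)
    msg <- c(msg, "triadEffect must be in (0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@targetDensity < 0 || object@targetDensity > 1)
    msg <- c(msg, "targetDensity must be in [0, 1]")
  if (abs(object@traitEffectR) > 1)
    msg <- c(msg, "traitEffectR must be in [-1, 1]")
  if (length(object@stageLabels) != object@nStages)
    msg <- c(msg, "stageLabels must have nStages entries")
  if (object@nPlantedTriads > 0) {
    if (object@nPlantedTriads > min(object@nNovelLnc, object@nMrna))
      msg <- c(msg, "more planted triads than available lncRNAs/mRNAs")
    if (object@nPlantedTriads * object@nSharedMirnas > object@nMirna)
      msg <- c(msg, "not enough miRNAs for the requested triads")
  }
  if (length(msg)) msg else TRUE
})

#' Build a SimConfig
#'
#' @param seed Integer seed for the single generator stream.
#' @param nMrna,nKnownLnc,nNovelLnc,nMirna Feature counts.
#' @param nStages,nReps,stageLabels Study design.
#' @param nPlantedDe,deLog2fc Planted differential expression.
#' @param nPlantedTriads,triadEffect,nSharedMirnas Planted ceRNA triads.
#' @param noiseSd Log2-scale noise sd.
#' @param targetDensity Background miRNA-target density.
#' @param nTraits,traitEffectR Planted trait correlations.
#' @param nCisNear,nCisFar Planted cis pairs inside/outside the 100-kb window.
#' @param nDecoysPerRule Labelled filter decoys per rule.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      nMrna = 200L, nKnownLnc = 20L, nNovelLnc = 20L,
                      nMirna = 50L, nStages = 4L, nReps = 4L,
                      stageLabels = c("4m", "1.5y", "3.5y", "6y"),
                      nPlantedDe = 2L, deLog2fc = 2,
                      nPlantedTriads = 10L, triadEffect = 0.95,
                      nSharedMirnas = 3L, noiseSd = 0.1,
                      targetDensity = 0.02,
                      nTraits = 10L, traitEffectR = 0.65,
                      nCisNear = 5L, nCisFar = 5L,
                      nDecoysPerRule = 3L) {
  new("SimConfig",
      seed = as.integer(seed),
      nMrna = as.integer(nMrna), nKnownLnc = as.integer(nKnownLnc),
      nNovelLnc = as.integer(nNovelLnc), nMirna = as.integer(nMirna),
      nStages = as.integer(nStages), nReps = as.integer(nReps),
      stageLabels = as.character(stageLabels),
      nPlantedDe = as.integer(nPlantedDe), deLog2fc = as.numeric(deLog2fc),
      nPlantedTriads = as.integer(nPlantedTriads),
      triadEffect = as.numeric(triadEffect),
      nSharedMirnas = as.integer(nSharedMirnas),
      noiseSd = as.numeric(noiseSd),
      targetDensity = as.numeric(targetDensity),
      nTraits = as.integer(nTraits), traitEffectR = as.numeric(traitEffectR),
      nCisNear = as.integer(nCisNear), nCisFar = as.integer(nCisFar),
      nDecoysPerRule = as.integer(nDecoysPerRule))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|",
      object@nMrna, "mRNA,", object@nKnownLnc, "known +",
      object@nNovelLnc, "novel lncRNA,", object@nMirna, "miRNA |",
      object@nStages, "stages x", object@nReps, "reps |",
      object@nPlantedTriads, "triads (effect", object@triadEffect,
      ", noise", object@noiseSd, ")\n")
})

#' CernaNetwork: lncRNA-miRNA-mRNA competing-endogenous-RNA network
#'
#' Result of [buildCernaNetwork()]: significant lncRNA-mRNA sponge pairs
#' (triads) with their shared miRNAs and hypergeometric p-values, plus the
#' constituent lncRNA-miRNA and miRNA-mRNA edges.
#'
#' @slot triads `DataFrame` with columns `lncRNA`, `mRNA`, `x` (shared
#'   miRNAs), `K`/`M` (per-gene sponge counts), `N` (miRNA universe),
#'   `p_hyper`, and a `shared_mirnas` `CharacterList`.
#' @slot edges `DataFrame` of typed edges (`source`, `target`, `type`,
#'   `statistic`, `p_value`).
#' @slot params List of thresholds used.
#' @seealso [buildCernaNetwork()], [networkStats()]
#' @export
setClass("CernaNetwork",
         slots = c(triads = "DataFrame", edges = "DataFrame",
                   params = "list"))

setMethod("show", "CernaNetwork", function(object) {
  st <- networkStats(object)
  cat("CernaNetwork:", nrow(object@triads), "triads |",
      st$n_lncrna, "lncRNA,", st$n_mirna, "miRNA,", st$n_mrna, "mRNA |",
      st$n_lnc_mir_edges, "lnc-miR +", st$n_mir_mrna_edges, "miR-mRNA edges\n")
})
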