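# End-to-end orchestration: simulate -> filter -> DE -> targets -> ceRNA
# -> enrichment -> validation, under one config, with a deterministic
# manifest.

#' Pipeline configuration
#'
#' All thresholds default to the conventional printed values of this
#' analysis family: transcript length > 200 bp, >= 2 exons, FDR < 0.05,
#' |log2FC| > 1, 100-kb cis window, trans |r| > 0.999, SCC < -0.7,
#' PCC > 0.9, sponge-test P < 0.05.
#'
#' @param sim A [SimConfig-class] describing the synthetic study (its
#'   seed drives all randomness).
#' @param outDir Output directory (`NULL` for no file output).
#' @param minLength,minExons,strictExons lncRNA filter thresholds.
#' @param alphaFdr,minAbsLog2fc DE thresholds.
#' @param cisWindow,transR Target-prediction thresholds.
#' @param sccCut,pccCut,alpha ceRNA network thresholds.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = simConfig(), outDir = NULL,
                           minLength = 200L, minExons = 2L,
                           strictExons = FALSE,
                           alphaFdr = 0.05, minAbsLog2fc = 1,
                           cisWindow = 100000L, transR = 0.999,
                           sccCut = -0.7, pccCut = 0.9, alpha = 0.05) {
  stopifnot(alphaFdr > 0, alphaFdr <= 1, alpha >= 0, alpha <= 1,
            cisWindow >= 0, transR >= 0, transR <= 1,
            sccCut >= -1, sccCut <= 0, pccCut >= 0, pccCut <= 1)
  structure(list(sim = sim, outDir = outDir, minLength = minLength,
                 minExons = minExons, strictExons = strictExons,
                 alphaFdr = alphaFdr, minAbsLog2fc = minAbsLog2fc,
                 cisWindow = cisWindow, transR = transR, sccCut = sccCut,
                 pccCut = pccCut, alpha = alpha),
            class = "PipelineConfig")
}

#' Run the full staged ceRNA analysis pipeline
#'
#' Stages, in order: data generation ([simulateCeRNAStudy()]), novel-lncRNA
#' filtering, staged differential expression of the lncRNA layer, cis and
#' trans target prediction, ceRNA network construction, enrichment of the
#' network mRNAs, and validation statistics (qPCR 2^-ddCt and
#' expression-trait correlations). When `config$outDir` is set, per-stage
#' TSV/GTF/SIF outputs and a `manifest.tsv` of record counts are written;
#' reruns with the same config produce byte-identical files.
#'
#' @param config A [pipelineConfig()] list.
#' @return List with all stage results (`data`, `filter`, `de`,
#'   `de_summary`, `cis`, `trans`, `network`, `network_stats`,
#'   `enrichment`, `qpcr`, `trait_cor`, `ratios`) and `manifest`, a
#'   data.frame of per-stage record counts.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dat <- stage("simulate", simulateCeRNAStudy(config$sim))

  flt <- stage("filter_lncrna",
               filterLncrna(dat$transcripts, minLength = config$minLength,
                            minExons = config$minExons,
                            strictExons = config$strictExons))
  lncIds <- names(flt$lncrnas)
  td <- txData(dat$transcripts)
  mrnas <- dat$transcripts[td$biotype == "mRNA"]
  posClass <- stage("classify_position",
                    classifyPosition(flt$lncrnas, mrnas))

  de <- stage("de", runComparisons(dat$lnc[lncIds, ],
                                   alphaFdr = config$alphaFdr,
                                   minAbsLog2fc = config$minAbsLog2fc))
  des <- deSummary(de)

  cis <- stage("cis_targets",
               predictCis(flt$lncrnas, mrnas, window = config$cisWindow))
  trans <- stage("trans_targets",
                 predictTrans(dat$lnc[lncIds, ], dat$mrna,
                              threshold = config$transR))

  neg <- stage("scc_screen", rbind(
    screenNegativePairs(dat$lnc[lncIds, ], dat$mir, sccCut = config$sccCut),
    screenNegativePairs(dat$mrna, dat$mir, sccCut = config$sccCut)))
  coex <- stage("pcc_screen",
                screenCoexpressedPairs(dat$lnc[lncIds, ], dat$mrna,
                                       pccCut = config$pccCut))
  expressedMir <- rownames(dat$mir)[rowSums(abundance(dat$mir)) > 0]
  net <- stage("cerna_network",
               buildCernaNetwork(neg, coex, dat$targets,
                                 mirUniverse = expressedMir,
                                 alpha = config$alpha))
  nst <- networkStats(net)

  enr <- stage("enrichment", {
    netMrnas <- unique(triads(net)$mRNA)
    if (length(netMrnas))
      overrepresentation(netMrnas, dat$terms$annotation,
                         universe = rownames(dat$mrna),
                         termNames = dat$terms$termNames)
    else NULL
  })

  qp <- stage("qpcr", ddct(dat$qpcr,
                           calibratorGroup = config$sim@stageLabels[1]))
  tc <- stage("trait_correlation",
              traitCorrelation(dat$lnc[intersect(lncIds, rownames(dat$lnc)), ],
                               dat$traits))
  ratios <- stage("ratios", fattyAcidRatios(dat$traits, dat$traitClasses))

  manifest <- data.frame(
    stage = c("transcripts", "novel_lncrnas", "de_comparisons", "de_total",
              "cis_pairs", "trans_pairs", "neg_pairs", "coex_pairs",
              "triads", "network_edges", "enriched_terms", "qpcr_records",
              "traits"),
    n = c(length(dat$transcripts), length(lncIds), length(de),
          sum(des$counts$n_de), nrow(cis), nrow(trans), nrow(neg),
          nrow(coex), nrow(triads(net)), nrow(networkEdges(net)),
          if (is.null(enr)) 0L else sum(enr$p_value < config$alpha),
          nrow(qp), ncol(dat$traits)))

  out <- list(data = dat, filter = flt, positional = posClass, de = de,
              de_summary = des, cis = cis, trans = trans, network = net,
              network_stats = nst, enrichment = enr, qpcr = qp,
              trait_cor = tc, ratios = ratios, manifest = manifest,
              config = config)
  if (!is.null(config$outDir)) .writePipelineOutputs(out, config$outDir)
  out
}

.writePipelineOutputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  writeGtf(res$filter$lncrnas, file.path(dir, "novel_lncrnas.gtf"))
  rep <- res$filter$report
  w(data.frame(transcript_id = rep$transcript_id, passed = rep$passed,
               failed_rules = vapply(rep$failed_rules, paste, "",
                                     collapse = ",")),
    "filter_report.tsv")
  w(data.frame(lncRNA = names(res$positional), class = res$positional),
    "positional_class.tsv")
  for (nm in names(res$de))
    w(res$de[[nm]], paste0("de_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv"))
  w(res$de_summary$counts, "de_summary.tsv")
  w(res$cis, "cis_targets.tsv")
  w(res$trans, "trans_targets.tsv")
  tri <- as.data.frame(triads(res$network))
  if (nrow(tri))
    tri$shared_mirnas <- vapply(triads(res$network)$shared_mirnas,
                                paste, "", collapse = ",")
  w(tri, "cerna_triads.tsv")
  writeEdgeList(as.data.frame(networkEdges(res$network)),
                file.path(dir, "cerna_network.sif"),
                file.path(dir, "cerna_edges.tsv"))
  if (!is.null(res$enrichment)) w(res$enrichment, "enrichment.tsv")
  w(res$qpcr, "qpcr_ddct.tsv")
  w(res$ratios, "fatty_acid_ratios.tsv")
  w(res$manifest, "manifest.tsv")
  invisible(dir)
}
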