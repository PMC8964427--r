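# GTF / TSV / SIF input-output. GTF parsing and writing go through
# rtracklayer; coordinates are GRanges (1-based, closed) throughout.

.NOVEL_CLASS_CODES <- c("i", "j", "x", "u", "c", "e", "o")

#' Read a StringTie-style GTF into a TranscriptSet
#'
#' Exon features are grouped by `transcript_id`; `gene_id`, `class_code`
#' and any evidence attributes written by [writeGtf()] (`orf_length`,
#' `coding_call_a`, `coding_call_b`, `coding_score`, `biotype`,
#' `db_annotated`) are recovered. A missing `class_code` defaults to `"="`
#' (known transcript).
#'
#' @param path Path to a GTF file with exon features.
#' @return A [TranscriptSet-class].
#' @seealso [writeGtf()]
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 9L)
      stop("malformed GTF record at line ", lineno[k], ": expected 9 columns")
    if (f[3] == "exon" && !grepl("transcript_id", f[9], fixed = TRUE))
      stop("malformed attribute column at line ", lineno[k],
           ": missing transcript_id")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  ids <- as.character(ex$transcript_id)
  exl <- split(granges(ex), factor(ids, levels = unique(ids)))
  first <- ex[!duplicated(ids)]
  mc <- mcols(first)
  pick <- function(col, default, coerce = identity) {
    if (col %in% colnames(mc)) {
      v <- coerce(as.character(mc[[col]]))
      v[is.na(v) & !is.na(default)] <- default
      v
    } else rep(default, length(first))
  }
  td <- DataFrame(
    transcript_id = as.character(first$transcript_id),
    gene_id = pick("gene_id", NA_character_),
    class_code = pick("class_code", "="),
    orf_length = suppressWarnings(pick("orf_length", NA_integer_, as.integer)),
    coding_call_a = pick("coding_call_a", NA, as.logical),
    coding_call_b = pick("coding_call_b", NA, as.logical),
    coding_score = suppressWarnings(pick("coding_score", NA_real_, as.numeric)),
    biotype = pick("biotype", NA_character_),
    db_annotated = pick("db_annotated", FALSE, as.logical))
  td$gene_id[is.na(td$gene_id)] <- td$transcript_id[is.na(td$gene_id)]
  na_bt <- is.na(td$biotype)
  td$biotype[na_bt] <- ifelse(td$class_code[na_bt] %in% .NOVEL_CLASS_CODES,
                              "novel_candidate", "mRNA")
  TranscriptSet(exl, td)
}

#' Write a TranscriptSet as GTF
#'
#' One exon feature line per exon; transcript-level evidence columns are
#' carried as GTF attributes so that `readGtf(writeGtf(x))` round-trips.
#' Output is deterministic for identical input.
#'
#' @param ts A [TranscriptSet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGtf <- function(ts, path) {
  td <- ts@txData
  n <- elementNROWS(ts@exons)
  gr <- unlist(ts@exons, use.names = FALSE)
  idx <- rep(seq_len(nrow(td)), n)
  mcols(gr) <- DataFrame(
    source = "ceRNAforge", type = "exon",
    transcript_id = td$transcript_id[idx],
    gene_id = td$gene_id[idx],
    class_code = td$class_code[idx],
    orf_length = as.character(td$orf_length[idx]),
    coding_call_a = as.character(td$coding_call_a[idx]),
    coding_call_b = as.character(td$coding_call_b[idx]),
    coding_score = as.character(td$coding_score[idx]),
    biotype = td$biotype[idx],
    db_annotated = as.character(td$db_annotated[idx]))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a feature-by-sample expression TSV
#'
#' First column holds feature ids, remaining columns one sample each.
#' Stage/replicate metadata comes from `design` (a data.frame or TSV path
#' with columns `sample`, `stage`, optionally `replicate`) or, failing
#' that, from sample ids of the form `<stage>_r<replicate>`.
#'
#' @param path TSV path.
#' @param design Optional design table or path to one.
#' @param layer RNA layer label for the result.
#' @return An [ExpressionMatrix-class]; all-zero features are flagged in
#'   `rowData(x)$expressed`.
#' @export
readExpressionTable <- function(path, design = NULL,
                                layer = c("lncRNA", "miRNA", "mRNA")) {
  layer <- match.arg(layer)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("NA value at feature '", ids[bad[1]], "', sample '",
         colnames(m)[bad[2]], "'")
  }
  if (any(m < 0)) stop("negative expression values in ", path)
  if (is.character(design)) design <- read.delim(design, stringsAsFactors = FALSE)
  if (!is.null(design)) {
    i <- match(colnames(m), design$sample)
    if (anyNA(i)) stop("design table missing samples: ",
                       paste(colnames(m)[is.na(i)], collapse = ", "))
    stage <- design$stage[i]
    repl <- if ("replicate" %in% colnames(design)) design$replicate[i] else NULL
  } else {
    parts <- regmatches(colnames(m), regexec("^(.*)_r?([0-9]+)$", colnames(m)))
    if (any(lengths(parts) != 3L))
      stop("cannot parse stage/replicate from sample ids; supply a design table")
    stage <- vapply(parts, `[`, "", 2L)
    repl <- as.integer(vapply(parts, `[`, "", 3L))
  }
  em <- ExpressionMatrix(m, stage = stage, replicate = repl, layer = layer)
  SummarizedExperiment::rowData(em)$expressed <- rowSums(m) > 0
  em
}

#' Write an ExpressionMatrix as TSV
#'
#' @param em An [ExpressionMatrix-class].
#' @param path Output TSV path (first column `feature_id`).
#' @param designPath Optional path for a sample/stage/replicate design TSV.
#' @return Invisibly, `path`.
#' @export
writeExpressionTable <- function(em, path, designPath = NULL) {
  m <- abundance(em)
  out <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(designPath)) {
    cd <- colData(em)
    write.table(
      data.frame(sample = rownames(cd), stage = cd$stage,
                 replicate = cd$replicate),
      designPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a typed edge list as SIF plus an attribute TSV
#'
#' The SIF file holds `source <TAB> type <TAB> target`; the attribute TSV
#' holds the full edge table. Rows are ordered lexicographically (C locale)
#' by source then target then type, so identical networks produce
#' byte-identical files.
#'
#' @param edges A data.frame/DataFrame with columns `source`, `target`,
#'   `type`, `statistic`, `p_value` (e.g. [networkEdges()] output).
#' @param sifPath,attrPath Output paths.
#' @return Invisibly, `sifPath`.
#' @export
writeEdgeList <- function(edges, sifPath, attrPath) {
  edges <- as.data.frame(edges)
  need <- c("source", "target", "type", "statistic", "p_value")
  miss <- setdiff(need, colnames(edges))
  if (length(miss)) stop("edge table missing columns: ",
                         paste(miss, collapse = ", "))
  o <- order(edges$source, edges$target, edges$type, method = "radix")
  edges <- edges[o, need, drop = FALSE]
  sif <- if (nrow(edges))
    paste(edges$source, edges$type, edges$target, sep = "\t") else character()
  writeLines(sif, sifPath)
  write.table(edges, attrPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sifPath)
}
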