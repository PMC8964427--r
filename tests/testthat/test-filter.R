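baseTx <- function(starts = c(1001, 2001), widths = c(150, 150), ...)
  c(list(starts = starts, widths = widths), list(...))

test_that("class-code selection keeps the seven novel codes only", {
  ts <- tsFixture(list(
    u1 = baseTx(class_code = "u"), i1 = baseTx(class_code = "i"),
    eq1 = baseTx(class_code = "="), s1 = baseTx(class_code = "s")))
  kept <- selectNovelCandidates(ts)
  expect_setequal(names(kept), c("u1", "i1"))
  expect_length(selectNovelCandidates(ts[0]), 0)
  ts2 <- tsFixture(list(q1 = baseTx(class_code = "?")))
  expect_warning(kept2 <- selectNovelCandidates(ts2), "unknown class code")
  expect_length(kept2, 0)
})

test_that("structural rules follow the >200 bp and >=2 exon conventions", {
  ts <- tsFixture(list(
    ok = baseTx(widths = c(100, 101)),            # length 201, 2 exons
    short = baseTx(widths = c(70, 80)),           # length 150
    boundary = baseTx(widths = c(100, 100)),      # length exactly 200
    mono = list(starts = 1001, widths = 500),     # 1 exon
    three = baseTx(starts = c(1001, 2001, 3001), widths = c(80, 80, 80))))
  rep <- applyStructuralFilters(ts)
  got <- setNames(rep$failed_rules, rep$transcript_id)
  expect_identical(got[["ok"]], character(0))
  expect_identical(got[["short"]], "length")
  expect_identical(got[["boundary"]], "length")  # rule is strictly longer than
  expect_identical(got[["mono"]], "exon_count")
  expect_identical(got[["three"]], character(0))
  # strict mode excludes 2-exon transcripts
  strict <- applyStructuralFilters(ts, strictExons = TRUE)
  expect_false(strict$passed[strict$transcript_id == "ok"])
  expect_true(strict$passed[strict$transcript_id == "three"])
})

test_that("coding overlap needs >= 1 shared exonic base on the same strand", {
  mrna <- tsFixture(list(m1 = list(starts = 199, widths = 102,
                                   biotype = "mRNA", class_code = "=",
                                   callA = TRUE, callB = TRUE, orf = 90)))
  cands <- tsFixture(list(
    hit = list(starts = c(100, 400), widths = c(100, 150)),   # exon ends 199
    adj = list(starts = c(1, 301), widths = c(99, 150)),      # gap to 199
    opp = list(starts = c(100, 400), widths = c(100, 150), strand = "-")))
  rep <- removeCodingOverlap(cands, mrna)
  got <- setNames(rep$passed, rep$transcript_id)
  expect_false(got[["hit"]])
  expect_true(got[["adj"]])
  expect_true(got[["opp"]])  # opposite strand ignored by default
  repAll <- removeCodingOverlap(cands, mrna, ignoreStrand = TRUE)
  expect_false(repAll$passed[repAll$transcript_id == "opp"])
  expect_true(all(removeCodingOverlap(cands, mrna[0])$passed))
})

test_that("coding-potential intersection requires both predictors noncoding", {
  ts <- tsFixture(list(
    nn = baseTx(callA = FALSE, callB = FALSE),
    nc = baseTx(callA = FALSE, callB = TRUE),
    cc = baseTx(callA = TRUE, callB = TRUE)))
  rep <- callNoncoding(ts)
  expect_identical(rep$passed, c(TRUE, FALSE, FALSE))
  miss <- tsFixture(list(na1 = baseTx(callA = NA, callB = FALSE)))
  expect_error(callNoncoding(miss), "na1")
})

test_that("positional classification assigns exactly one of the five classes", {
  gene <- tsFixture(list(g1 = list(
    starts = c(10000, 30000, 50000), widths = c(500, 500, 500),
    biotype = "mRNA", class_code = "=", callA = TRUE, callB = TRUE,
    orf = 400)))
  lncs <- tsFixture(list(
    sense = list(starts = c(10200, 12000), widths = c(200, 150)),
    anti = list(starts = c(10200, 12000), widths = c(200, 150), strand = "-"),
    intr = list(starts = c(31000, 32000), widths = c(200, 200)),
    bidi = list(starts = c(8500, 9200), widths = c(200, 300), strand = "-"),
    inter = list(starts = c(9e6, 9e6 + 1000), widths = c(300, 300))))
  cls <- classifyPosition(lncs, gene, bidiWindow = 1000)
  expect_identical(unname(cls),
                   c("sense_overlapping", "antisense", "intronic",
                     "bidirectional", "intergenic"))
  expect_true(all(cls %in% c("intergenic", "bidirectional", "intronic",
                             "antisense", "sense_overlapping")))
})

test_that("the cascade's pass set is order-independent and matches truth", {
  dat <- simulateAnnotation(smallConfig(seed = 21))
  ts <- dat$transcripts
  flt <- filterLncrna(ts)
  expect_setequal(names(flt$lncrnas), dat$truth$expected_pass)

  # apply single rules in two different orders; intersect stepwise
  td <- txData(ts)
  cand <- ts[td$biotype == "novel_candidate"]
  mrna <- ts[td$biotype == "mRNA"]
  passOf <- function(rep) rep$transcript_id[rep$passed]
  codePass <- names(cand)[txData(cand)$class_code %in%
                            c("i", "j", "x", "u", "c", "e", "o")]
  sets <- list(codePass,
               passOf(applyStructuralFilters(cand)),
               passOf(removeCodingOverlap(cand, mrna)),
               passOf(removeAnnotated(cand)),
               passOf(callNoncoding(cand)))
  fwd <- Reduce(intersect, sets)
  rev_ <- Reduce(intersect, rev(sets))
  expect_setequal(fwd, rev_)
  expect_setequal(fwd, names(flt$lncrnas))

  # every decoy fails exactly the rule(s) recorded in the truth ledger
  rep <- flt$report
  for (i in seq_len(nrow(dat$truth$decoys))) {
    id <- dat$truth$decoys$transcript_id[i]
    expect_identical(rep$failed_rules[[which(rep$transcript_id == id)]],
                     dat$truth$decoys$rule[i])
  }
})
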