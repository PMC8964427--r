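test_that("identical configs give bit-identical simulations", {
  a <- simulateCeRNAStudy(smallConfig(seed = 9))
  b <- simulateCeRNAStudy(smallConfig(seed = 9))
  expect_identical(abundance(a$lnc), abundance(b$lnc))
  expect_identical(abundance(a$mir), abundance(b$mir))
  expect_identical(abundance(a$mrna), abundance(b$mrna))
  expect_identical(unname(txExons(a$transcripts)), unname(txExons(b$transcripts)))
  expect_identical(a$targets, b$targets)
  expect_identical(a$traits, b$traits)
  expect_identical(a$qpcr, b$qpcr)
  expect_identical(a$truth$planted_triads, b$truth$planted_triads)
  c <- simulateCeRNAStudy(smallConfig(seed = 10))
  expect_false(identical(abundance(a$lnc), abundance(c$lnc)))
})

test_that("simulated lncRNAs are shorter, fewer-exoned and lower-expressed than mRNAs", {
  dat <- simulateCeRNAStudy(smallConfig(seed = 2))
  td <- txData(dat$transcripts)
  len <- txLength(dat$transcripts)
  nex <- exonCount(dat$transcripts)
  isM <- td$biotype == "mRNA"
  isL <- td$biotype %in% c("known_lncRNA", "novel_candidate")
  expect_gt(median(len[isM]), median(len[isL]))
  expect_gt(median(nex[isM]), median(nex[isL]))
  orf <- td$orf_length
  expect_true(all(orf[isL] < 300))
  expect_true(all(orf[isM] >= 300))
  expect_gt(median(abundance(dat$mrna)), median(abundance(dat$lnc)))
  # novel candidates carry novel class codes, expressed above known lncRNAs
  novel <- td$transcript_id %in% dat$truth$novel_true
  expect_true(all(td$class_code[novel] %in% c("i", "j", "x", "u", "c", "e", "o")))
})

test_that("empty novel-candidate configurations produce no candidates", {
  cfg <- simConfig(seed = 1, nNovelLnc = 0L, nCisNear = 0L, nCisFar = 0L,
                   nPlantedTriads = 0L, nPlantedDe = 0L, nDecoysPerRule = 0L,
                   nMrna = 30L)
  ann <- simulateAnnotation(cfg)
  expect_equal(sum(txData(ann$transcripts)$biotype == "novel_candidate"), 0)
  expect_equal(length(ann$truth$novel_true), 0)
})

test_that("noise-free planted DE features shift by exactly the requested fold", {
  cfg <- smallConfig(seed = 4, noiseSd = 0, nPlantedTriads = 0L, deLog2fc = 2)
  dat <- simulateExpression(simulateAnnotation(cfg), cfg)
  pd <- dat$truth$planted_de
  expect_gt(nrow(pd), 0)
  st <- stages(dat$lnc)
  for (i in seq_len(nrow(pd))) {
    cmp <- strsplit(pd$comparison[i], " vs ")[[1]]
    ab <- abundance(dat$lnc)[pd$feature[i], ]
    ratio <- mean(ab[st == cmp[2]]) / mean(ab[st == cmp[1]])
    expect_equal(ratio, if (pd$direction[i] == "up") 4 else 0.25)
  }
})

test_that("the noiseless full-effect limit gives perfect triad correlations", {
  cfg <- smallConfig(seed = 6, noiseSd = 0, triadEffect = 1)
  dat <- simulateExpression(simulateAnnotation(cfg), cfg)
  tt <- dat$truth$planted_triads
  for (i in seq_len(nrow(tt))) {
    l <- log2(abundance(dat$lnc)[tt$lncRNA[i], ])
    m <- log2(abundance(dat$mrna)[tt$mRNA[i], ])
    expect_equal(cor(l, m), 1)
    for (mir in tt$mirnas[[i]]) {
      v <- log2(abundance(dat$mir)[mir, ])
      expect_equal(cor(l, v, method = "spearman"), -1)
    }
  }
})

test_that("target sets contain every planted sponge and respect density zero", {
  cfg <- smallConfig(seed = 3, targetDensity = 0)
  dat <- simulateCeRNAStudy(cfg)
  tt <- dat$truth$planted_triads
  for (i in seq_len(nrow(tt)))
    for (mir in tt$mirnas[[i]]) {
      expect_true(tt$lncRNA[i] %in% dat$targets[[mir]])
      expect_true(tt$mRNA[i] %in% dat$targets[[mir]])
    }
  planted_mirs <- unique(unlist(tt$mirnas))
  expect_true(all(lengths(dat$targets[setdiff(names(dat$targets),
                                              planted_mirs)]) == 0))
})

test_that("perfect planted trait correlation is recovered exactly", {
  cfg <- smallConfig(seed = 8, traitEffectR = 1)
  dat <- simulateExpression(simulateAnnotation(cfg), cfg)
  tr <- simulateTraits(dat$lnc, cfg, dat$truth)
  pt <- tr$truth$planted_traits
  x <- log2(abundance(dat$lnc)[pt$lncRNA[1], ] + 1)
  expect_equal(abs(cor(x, tr$traits[[pt$trait[1]]])), 1)
  expect_true(all(as.matrix(tr$traits) >= 0))
  expect_true(all(tr$classes$trait == colnames(tr$traits)))
})

test_that("simulated qPCR obeys the Ct model", {
  cfg <- smallConfig(seed = 12, noiseSd = 0)
  dat <- simulateExpression(simulateAnnotation(cfg), cfg)
  qp <- simulateQpcr(dat$lnc, features = rownames(dat$lnc)[1:3], config = cfg)
  # noiseless: reference identical across samples, Ct = c0 - log2(abundance)
  expect_equal(length(unique(qp$ct_reference)), 1L)
  ab <- abundance(dat$lnc)
  one <- qp[qp$target_id == rownames(dat$lnc)[1], ]
  expect_equal(one$ct_target, 25 - log2(ab[1, one$sample_id]),
               ignore_attr = TRUE)
  # a 4-fold abundance ratio is a -2 cycle dCt difference
  i <- which.max(ab[1, ]); j <- which.min(ab[1, ])
  expect_equal(one$ct_target[i] - one$ct_target[j],
               -log2(ab[1, i] / ab[1, j]))
})
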