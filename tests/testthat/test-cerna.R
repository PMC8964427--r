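test_that("sponge overlap test matches exact combinatorics", {
  expect_equal(spongeOverlapTest(0, 3, 4, 10), 1)        # P(X >= 0)
  expect_equal(spongeOverlapTest(4, 4, 5, 10), 6 / 252)  # C(4,4)C(6,1)/C(10,5)
  expect_equal(spongeOverlapTest(5, 5, 5, 5), 1)         # degenerate K = M = N
  expect_error(spongeOverlapTest(3, 2, 5, 10), "inconsistent")
  expect_error(spongeOverlapTest(1, 4, 12, 10), "inconsistent")
})

test_that("sponge p-values agree with subset enumeration on random cases", {
  set.seed(11)
  for (rep in 1:40) {
    N <- sample(2:11, 1)
    K <- sample(0:N, 1)
    M <- sample(0:N, 1)
    x <- sample(0:min(K, M), 1)
    expect_equal(spongeOverlapTest(x, K, M, N), hyperEnumOracle(x, K, M, N),
                 tolerance = 1e-12)
  }
})

test_that("sponge p is monotone in x and the pmf sums to one", {
  N <- 30; K <- 12; M <- 9
  p <- vapply(0:min(K, M), function(x) spongeOverlapTest(x, K, M, N), 0)
  expect_true(all(diff(p) <= 0))
  pmf <- c(-diff(p), p[length(p)])
  expect_equal(sum(pmf), 1)
})

test_that("correlation screens enforce strict inequality at the cutoffs", {
  st <- rep(c("A", "B"), c(3, 2))
  x <- 1:5
  lnc <- emFromLog(matrix(x, 1, dimnames = list("L1", NULL)), stage = st)
  # Spearman exactly -0.7: ranks (5,3,2,4,1) against 1..5
  mir_at <- emFromLog(matrix(c(5, 3, 2, 4, 1), 1, dimnames = list("m1", NULL)),
                      layer = "miRNA", stage = st)
  expect_equal(cor(x, c(5, 3, 2, 4, 1), method = "spearman"), -0.7)
  expect_equal(nrow(screenNegativePairs(lnc, mir_at)), 0)
  # Spearman -0.9 passes
  mir_below <- emFromLog(matrix(c(5, 4, 2, 3, 1), 1,
                                dimnames = list("m1", NULL)),
                         layer = "miRNA", stage = st)
  got <- screenNegativePairs(lnc, mir_below)
  expect_equal(got$statistic, -0.9)
  expect_equal(got$kind, "lnc_mir")
  # Pearson exactly 0.9 is excluded, above passes
  u <- c(-2, -1, 0, 1, 2) / sqrt(10)
  v <- c(2, -1, -2, -1, 2) / sqrt(14)
  y <- 0.9 * u + sqrt(1 - 0.81) * v
  lncP <- emFromLog(matrix(u - min(u), 1, dimnames = list("L1", NULL)),
                    stage = st)
  mrnaP <- emFromLog(matrix(y - min(y), 1, dimnames = list("G1", NULL)),
                     layer = "mRNA", stage = st)
  expect_equal(cor(u, y), 0.9, tolerance = 1e-12)
  expect_equal(nrow(screenCoexpressedPairs(lncP, mrnaP)), 0)
  expect_equal(nrow(screenCoexpressedPairs(lncP, mrnaP, pccCut = 0.85)), 1)
  # monotone increasing relation is dropped by the negative screen
  mir_up <- emFromLog(matrix(x + 1, 1, dimnames = list("m1", NULL)),
                      layer = "miRNA", stage = st)
  expect_equal(nrow(screenNegativePairs(lnc, mir_up)), 0)
})

test_that("a single strong planted triad is recovered exactly on clean background", {
  cfg <- smallConfig(seed = 51, nPlantedTriads = 1L, nSharedMirnas = 3L,
                     targetDensity = 0, noiseSd = 0.05)
  dat <- simulateCeRNAStudy(cfg)
  neg <- rbind(screenNegativePairs(dat$lnc, dat$mir),
               screenNegativePairs(dat$mrna, dat$mir))
  coex <- screenCoexpressedPairs(dat$lnc, dat$mrna)
  net <- buildCernaNetwork(neg, coex, dat$targets,
                           mirUniverse = rownames(dat$mir))
  tt <- dat$truth$planted_triads
  tri <- triads(net)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$lncRNA, tt$lncRNA)
  expect_equal(tri$mRNA, tt$mRNA)
  expect_setequal(tri$shared_mirnas[[1]], tt$mirnas[[1]])
  expect_lt(tri$p_hyper, 0.05)
  # alpha = 0 empties the network; so does an empty co-expression screen
  expect_equal(nrow(triads(buildCernaNetwork(neg, coex, dat$targets,
                                             rownames(dat$mir), alpha = 0))), 0)
  expect_equal(nrow(triads(buildCernaNetwork(neg, coex[0, ], dat$targets,
                                             rownames(dat$mir)))), 0)
})

test_that("tightening any threshold never adds triads", {
  cfg <- smallConfig(seed = 52)
  dat <- simulateCeRNAStudy(cfg)
  build <- function(scc = -0.7, pcc = 0.9, alpha = 0.05) {
    neg <- rbind(screenNegativePairs(dat$lnc, dat$mir, sccCut = scc),
                 screenNegativePairs(dat$mrna, dat$mir, sccCut = scc))
    coex <- screenCoexpressedPairs(dat$lnc, dat$mrna, pccCut = pcc)
    tri <- triads(buildCernaNetwork(neg, coex, dat$targets,
                                    rownames(dat$mir), alpha = alpha))
    paste(tri$lncRNA, tri$mRNA)
  }
  base <- build()
  expect_true(all(build(scc = -0.85) %in% base))
  expect_true(all(build(pcc = 0.95) %in% base))
  expect_true(all(build(alpha = 0.001) %in% base))
})

test_that("network statistics report exact cardinalities", {
  empty <- buildCernaNetwork(
    data.frame(node_a = character(), node_b = character(),
               kind = character(), statistic = numeric()),
    data.frame(node_a = character(), node_b = character(),
               kind = character(), statistic = numeric()),
    list(), mirUniverse = character())
  st0 <- networkStats(empty)
  expect_true(all(unlist(st0) == 0))

  cfg <- smallConfig(seed = 53, nPlantedTriads = 1L, nSharedMirnas = 2L,
                     targetDensity = 0, noiseSd = 0.05)
  dat <- simulateCeRNAStudy(cfg)
  neg <- rbind(screenNegativePairs(dat$lnc, dat$mir),
               screenNegativePairs(dat$mrna, dat$mir))
  coex <- screenCoexpressedPairs(dat$lnc, dat$mrna)
  net <- buildCernaNetwork(neg, coex, dat$targets, rownames(dat$mir))
  st <- networkStats(net)
  expect_equal(st$n_lncrna, 1)
  expect_equal(st$n_mirna, 2)
  expect_equal(st$n_mrna, 1)
  expect_equal(st$n_lnc_mir_edges, 2)
  expect_equal(st$n_mir_mrna_edges, 2)
})
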