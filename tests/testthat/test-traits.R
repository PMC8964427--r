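qpcrRec <- function(group, ct, ref, target = "L1") {
  data.frame(sample_id = paste0(group, "_", seq_along(ct)), group = group,
             target_id = target, ct_target = ct, ct_reference = ref)
}

test_that("2^-ddCt identities hold", {
  recs <- rbind(qpcrRec("cal", c(22, 22), 15), qpcrRec("trt", c(20, 20), 15))
  out <- ddct(recs, calibratorGroup = "cal")
  # calibrator: ddCt = 0 -> fold change 1
  expect_equal(out$rel_expr[out$group == "cal"], c(1, 1))
  # worked case: (20,15) against calibrator (22,15) -> ddCt -2, fold 4
  expect_equal(out$ddct[out$group == "trt"], c(-2, -2))
  expect_equal(out$rel_expr[out$group == "trt"], c(4, 4))
  # shifting every Ct by a constant changes nothing
  shifted <- recs
  shifted$ct_target <- shifted$ct_target + 3.7
  shifted$ct_reference <- shifted$ct_reference + 3.7
  expect_equal(ddct(shifted, "cal")$rel_expr, out$rel_expr)
  # calibrator geometric mean is exactly 1 even with within-group spread
  recs2 <- rbind(qpcrRec("cal", c(21, 23, 22), 15), qpcrRec("trt", 20, 15))
  out2 <- ddct(recs2, "cal")
  expect_equal(exp(mean(log(out2$rel_expr[out2$group == "cal"]))), 1)
  # missing reference errors
  bad <- recs; bad$ct_reference[2] <- NA
  expect_error(ddct(bad, "cal"), "missing reference")
})

test_that("trait correlations match cor.test and handle exact cases", {
  expr <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("L1", paste0("s", 1:6)))
  tr <- data.frame(fa = 2 * expr[1, ], row.names = colnames(expr))
  out <- traitCorrelation(expr, tr)
  expect_equal(out$r[1, 1], 1)
  expect_equal(out$p[1, 1], 0)
  # r = 0 exactly -> p = 1
  tr0 <- data.frame(fa = c(1, -1, 0, 0, 1, -1), row.names = colnames(expr))
  tr0$fa <- tr0$fa - cov(tr0$fa, expr[1, ]) / var(expr[1, ]) * expr[1, ]
  out0 <- traitCorrelation(expr, tr0)
  expect_equal(out0$r[1, 1], 0)
  expect_equal(out0$p[1, 1], 1)
  # random pairs agree with stats::cor.test (independent route)
  set.seed(42)
  em <- matrix(rnorm(3 * 16), 3, dimnames = list(paste0("L", 1:3),
                                                 paste0("s", 1:16)))
  tr2 <- data.frame(a = rnorm(16), b = rnorm(16),
                    row.names = colnames(em))
  out2 <- traitCorrelation(em, tr2)
  for (i in 1:3) for (j in 1:2) {
    ct <- cor.test(em[i, ], tr2[[j]])
    expect_equal(out2$r[i, j], unname(ct$estimate))
    expect_equal(out2$p[i, j], ct$p.value)
  }
  expect_equal(out2$n, 16)
  # zero variance -> missing
  emz <- rbind(em, Lz = rep(1, 16))
  outz <- traitCorrelation(emz, tr2)
  expect_true(all(is.na(outz$r["Lz", ])))
})

test_that("Duncan letters separate means the way the range oracle does", {
  set.seed(7)
  for (case in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(3:6, 1)
    mu <- cumsum(runif(k, 0, 2))        # some close, some separated
    v <- unlist(lapply(mu, function(m) rnorm(n, m, 1)))
    g <- rep(paste0("g", seq_len(k)), each = n)
    d <- duncanGroups(v, g)
    oracle <- duncanOracleNonsig(d$means, d$df, d$mse,
                                 nh = k / sum(1 / table(g)))
    expect_identical(unname(d$nonsig), unname(oracle))
    # letter sharing reflects exactly the non-separation relation
    lt <- d$letters[names(d$means)]
    share <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
      length(intersect(strsplit(lt[i], "")[[1]],
                       strsplit(lt[j], "")[[1]])) > 0))
    expect_identical(share, d$nonsig)
  }
})

test_that("Duncan handles clear separations, identical groups and bad input", {
  d <- duncanGroups(c(rnorm(4, 0, 1), rnorm(4, 100, 1)),
                    rep(c("lo", "hi"), each = 4))
  expect_identical(sort(unname(d$letters)), c("a", "b"))
  expect_equal(unname(d$letters["hi"]), "a")  # largest mean gets "a"
  same <- duncanGroups(rep(c(5, 6, 7), 4), rep(c("a", "b", "c"), each = 4))
  expect_true(all(same$letters == "a"))
  # invariance to group input order
  set.seed(30)
  v <- c(rnorm(4, 0), rnorm(4, 1), rnorm(4, 5))
  g <- rep(c("x", "y", "z"), each = 4)
  o <- sample(length(v))
  expect_identical(duncanGroups(v, g)$letters, duncanGroups(v[o], g[o])$letters)
  expect_error(duncanGroups(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})

test_that("fatty-acid class sums and ratios behave", {
  classes <- data.frame(
    trait = c("sfa1", "sfa2", "mufa1", "pufa6", "pufa3"),
    class = c("SFA", "SFA", "MUFA", "PUFA", "PUFA"),
    family = c(NA, NA, NA, "n-6", "n-3"))
  tr <- data.frame(sfa1 = c(1, 2), sfa2 = c(3, 2), mufa1 = c(1, 1),
                   pufa6 = c(1.5, 0.5), pufa3 = c(0.5, 0),
                   row.names = c("s1", "s2"))
  out <- fattyAcidRatios(tr, classes)
  expect_equal(out$SFA, c(4, 4))
  expect_equal(out$PUFA, c(2, 0.5))
  expect_equal(out$pufa_sfa, c(0.5, 0.125))
  expect_equal(out$n6_n3, c(3, NA))  # zero n-3 -> missing
  # class sums are conserved under splitting one trait into two
  tr2 <- tr; tr2$sfa1 <- NULL
  tr2$sfa1a <- c(0.4, 1.1); tr2$sfa1b <- c(0.6, 0.9)
  cl2 <- rbind(classes[classes$trait != "sfa1", ],
               data.frame(trait = c("sfa1a", "sfa1b"), class = "SFA",
                          family = NA))
  expect_equal(fattyAcidRatios(tr2, cl2)$SFA, out$SFA)
  expect_error(fattyAcidRatios(cbind(tr, mystery = 1), classes),
               "without class label")
})
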