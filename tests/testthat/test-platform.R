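mkProbes <- function(ids, tx, suffix = "", evalue = 0, I) {
  d <- data.frame(probeset_id = ids, suffix_class = suffix,
                  transcript_id = tx, evalue = evalue,
                  stringsAsFactors = FALSE)
  colnames(I) <- berryStages()
  cbind(d, I)
}

test_that("matched-pair construction applies suffix, e-value and best-probeset rules", {
  r <- rbind(t1 = c(1, 2, 4, 8), t2 = c(8, 4, 2, 1))
  colnames(r) <- berryStages()
  probes <- rbind(
    mkProbes("p1", "t1", I = matrix(c(1, 2, 3, 4), 1)),            # eligible
    mkProbes("p2", "t1", suffix = "_x", I = matrix(c(9, 9, 9, 1), 1)),
    mkProbes("p3", "t2", evalue = 1e-20, I = matrix(c(4, 3, 2, 1), 1)),
    mkProbes("p4", "t2", I = matrix(c(4, 3, 2, 1), 1)))
  pairs <- buildMatchedPairs(probes, r)
  expect_setequal(pairs$probeset_id, c("p1", "p4"))

  # unknown transcript dropped with a warning
  bad <- rbind(probes, mkProbes("p5", "zz", I = matrix(1:4, 1)))
  expect_warning(buildMatchedPairs(bad, r), "absent")

  # two eligible probesets: the better-correlating pattern wins
  two <- rbind(
    mkProbes("good", "t1", I = matrix(c(1, 2, 3, 4), 1)),   # rho 1 with t1
    mkProbes("bad",  "t1", I = matrix(c(2, 1, 3, 4), 1)))   # rho 0.8
  p2 <- buildMatchedPairs(two, r["t1", , drop = FALSE])
  expect_identical(p2$probeset_id, "good")
})

test_that("expression floors: percentile threshold, RPKM floor, boundaries", {
  set.seed(13)
  n <- 100
  I <- matrix(rep(sort(runif(n, 2, 12)), 4), n)  # distinct means
  R <- matrix(log2(runif(4 * n, 0, 20) + 1), n)
  pairs <- cbind(
    data.frame(transcript_id = sprintf("t%03d", 1:n),
               probeset_id = sprintf("p%03d", 1:n)),
    setNames(as.data.frame(I), paste0("intensity.", berryStages())),
    setNames(as.data.frame(R), paste0("logrpkm.", berryStages())))
  fl <- applyExpressionFloors(pairs)
  # by construction of the 25th percentile, exactly 25 of 100 fall below
  expect_identical(sum(!fl$expressed_intensity), 25L)
  # a pair exactly at the threshold is included
  thr <- attr(fl, "intensityThreshold")
  at <- which.min(abs(rowMeans(I) - thr))
  if (rowMeans(I)[at] == thr) expect_true(fl$expressed_intensity[at])

  # all-zero RPKM is never expressed on the sequencing side
  z <- pairs; z[, paste0("logrpkm.", berryStages())] <- 0
  expect_false(any(applyExpressionFloors(z)$expressed_rnaseq))

  # floor order independence: intersecting the two single-floor keeps
  # equals the joint keep
  keepI <- fl$expressed_intensity; keepR <- fl$expressed_rnaseq
  expect_identical(which(keepI & keepR), intersect(which(keepI), which(keepR)))
})

test_that("global stage correlation: monotone data, hand-ranked case, minimum n", {
  r <- matrix(seq(0.5, 20, length.out = 10), 10, 4,
              dimnames = list(sprintf("t%02d", 1:10), berryStages()))
  probes <- mkProbes(sprintf("p%02d", 1:10), rownames(r),
                     I = 1 + 0.5 * log2(r + 1))
  pairs <- buildMatchedPairs(probes, r)
  gc_ <- globalStageCorrelation(pairs, expressedOnly = FALSE)
  expect_equal(unname(gc_$perStage), rep(1, 4))
  expect_equal(gc_$mean, 1)

  # (1,2),(2,1),(3,3): rho = 0.5
  expect_equal(cor(c(1, 2, 3), c(2, 1, 3), method = "spearman"), 0.5)
  expect_error(globalStageCorrelation(pairs[1:2, ], expressedOnly = FALSE),
               "fewer than 3")
})

test_that("pattern correlations: worked 4-point cases and undefined bin", {
  r <- rbind(same = c(1, 2, 3, 4), rev = c(4, 3, 2, 1),
             swap = c(1, 2, 4, 3), const = c(2, 2, 2, 2))
  colnames(r) <- berryStages()
  I <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  probes <- mkProbes(paste0("p", 1:4), rownames(r), I = I)
  pairs <- buildMatchedPairs(probes, r)  # log2(r + 1) is strictly monotone
  h <- patternCorrelationHistogram(pairs, expressedOnly = FALSE)
  expect_equal(unname(h$rho[c("same", "rev", "swap")]), c(1, -1, 0.8))
  expect_true(is.na(h$rho[["const"]]))
  expect_identical(unname(h$counts[["undefined"]]), 1L)
  expect_identical(sum(h$counts), 4L)
})

test_that("4-point Spearman attains only the 11 enumerated values; invariances", {
  perms <- rbind(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2),
                 c(1,4,2,3), c(1,4,3,2), c(2,1,3,4), c(2,1,4,3),
                 c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
                 c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1),
                 c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                 c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  rhos <- apply(perms, 1, function(p) cor(1:4, p, method = "spearman"))
  expect_equal(sort(unique(round(rhos, 10))),
               seq(-1, 1, by = 0.2))
  # formula oracle and monotone-transform invariance
  for (i in 1:5) {
    p <- perms[sample(24, 1), ]
    expect_equal(cor(1:4, p, method = "spearman"),
                 spearmanByFormula(1:4, p))
    expect_equal(cor(exp(1:4), p^3, method = "spearman"),
                 cor(1:4, p, method = "spearman"))
  }
})

test_that("planted platform correlation is recovered at ~2000 pairs", {
  rhos <- sapply(1:2, function(s) {
    g <- generateCatalog(3000, seed = 100 + s)
    pr <- generateProbesets(g$truth, g$catalog, seed = 200 + s)
    pairs <- buildMatchedPairs(pr, g$truth$true_rpkm)
    expect_gt(nrow(pairs), 1800)
    globalStageCorrelation(pairs, expressedOnly = FALSE)$mean
  })
  expect_lt(max(abs(rhos - 0.7)), 0.05)
})
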