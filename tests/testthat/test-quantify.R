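mkReads <- function(len, amb) data.frame(
  read_id = sprintf("r%d", seq_along(len)),
  length_after_trim = len, ambiguous_count = amb,
  stringsAsFactors = FALSE)

test_that("read QC keeps >= 60 nt with <= 2 ambiguous bases, preserving order", {
  r <- mkReads(c(59, 100, 60, 96), c(0, 2, 3, 1))
  kept <- filterReads(r)
  expect_identical(kept$read_id, c("r2", "r4"))
  expect_identical(filterReads(r[0, ]), r[0, ])
  expect_error(filterReads(r, minLength = 0), "positive")
})

test_that("alignment acceptance is strict on both identity and aligned fraction", {
  cand <- data.frame(read_id = c("a", "b", "c"),
                     transcript_id = "t",
                     percent_identity = c(0.99, 0.98, 1.0),
                     aligned_fraction = c(0.6, 0.6, 0.5))
  acc <- filterAlignments(cand)
  expect_identical(acc$read_id, "a")
  reads <- mkReads(96, 0)  # only read r1
  expect_error(filterAlignments(cand, reads = reads), "absent")
})

test_that("proportional allocation follows the two-pass rule", {
  # 8 unique on A, 2 on B, one read hits both -> A += 0.8, B += 0.2
  cand <- data.frame(
    read_id = c(sprintf("u%02d", 1:10), "m1", "m1"),
    transcript_id = c(rep("A", 8), rep("B", 2), "A", "B"))
  out <- allocateReads(cand)
  expect_identical(out$unique_reads, c(8L, 2L))
  expect_equal(out$allocated_reads, c(8.8, 2.2))

  # no multi-mapped reads: allocated == unique
  uni <- cand[1:10, ]
  out2 <- allocateReads(uni)
  expect_equal(out2$allocated_reads, as.numeric(out2$unique_reads))

  # 0/0 proportional rule: equal split
  tie <- data.frame(read_id = c("m", "m"), transcript_id = c("A", "B"))
  out3 <- allocateReads(tie)
  expect_equal(out3$allocated_reads, c(0.5, 0.5))
  expect_identical(out3$unique_reads, c(0L, 0L))
})

test_that("allocation matches the brute-force oracle on small instances", {
  set.seed(41)
  for (i in 1:40) {
    inst <- randomAllocationInstance()
    inst <- unique(inst)
    tx <- sort(unique(inst$transcript_id))
    got <- allocateReads(inst, transcriptIds = tx)
    want <- bruteAllocate(inst, tx)
    expect_equal(setNames(got$allocated_reads, got$transcript_id),
                 want$allocated, tolerance = 1e-12)
    expect_equal(setNames(as.numeric(got$unique_reads), got$transcript_id),
                 want$unique)
    # conservation: total mass equals number of reads with a candidate
    expect_equal(sum(got$allocated_reads), length(unique(inst$read_id)),
                 tolerance = 1e-6)
  }
})

test_that("RPKM formula, worked coverage example, and edge errors", {
  cnt <- data.frame(transcript_id = "t", unique_reads = 20L,
                    allocated_reads = 20)
  expect_equal(unname(computeRPKM(cnt, c(t = 1000), totalMapped = 40e6)), 0.5)
  cnt0 <- data.frame(transcript_id = "t", unique_reads = 0L,
                     allocated_reads = 0)
  expect_equal(unname(computeRPKM(cnt0, c(t = 1000), totalMapped = 1e6)), 0)
  cnt2 <- data.frame(transcript_id = "t", unique_reads = 10L,
                     allocated_reads = 10)
  expect_equal(unname(computeRPKM(cnt2, c(t = 2000), totalMapped = 1e6)), 5)
  expect_error(computeRPKM(cnt, c(t = 1000), totalMapped = 0), "positive")
  expect_error(computeRPKM(cnt, c(u = 1000), totalMapped = 1e6), "missing")

  expect_equal(expectedCoverage(0.5, 1000, 100, 40), 2)
  expect_equal(expectedCoverage(0, 1000, 100, 40), 0)
  expect_equal(expectedCoverage(1.0, 1000, 100, 40), 4)
  expect_error(expectedCoverage(0.5, 0, 100, 40), "positive")
})

test_that("RPKM is scale-invariant and monotone in added unique reads", {
  set.seed(7)
  cnt <- data.frame(transcript_id = sprintf("t%d", 1:20),
                    unique_reads = rpois(20, 50),
                    allocated_reads = rpois(20, 50) + runif(20))
  len <- setNames(sample(500:3000, 20), cnt$transcript_id)
  tot <- sum(cnt$allocated_reads)
  base <- computeRPKM(cnt, len, totalMapped = tot)
  scl <- cnt; scl$allocated_reads <- scl$allocated_reads * 7
  expect_equal(computeRPKM(scl, len, totalMapped = tot * 7), base)

  # one more unique read on t1 (and in the total) never lowers rpkm(t1)
  plus <- cnt; plus$allocated_reads[1] <- plus$allocated_reads[1] + 1
  after <- computeRPKM(plus, len, totalMapped = tot + 1)
  expect_gte(after[["t1"]], base[["t1"]])
})

test_that("detection rule: RPKM floor or unique-read rescue", {
  r <- matrix(c(0.4, 0.6, 0.4), 3, 1,
              dimnames = list(c("a", "b", "c"), "EL31"))
  u <- matrix(c(5L, 0L, 4L), 3, 1, dimnames = dimnames(r))
  d <- detectExpressed(r, u)
  expect_identical(unname(d[, 1]), c(TRUE, TRUE, FALSE))
})

test_that("abundance bins partition detected transcripts per stage", {
  r0 <- matrix(0, 3, 4, dimnames = list(letters[1:3], berryStages()))
  u0 <- matrix(0L, 3, 4, dimnames = dimnames(r0))
  expect_true(all(abundanceBins(r0, u0) == 0L))

  # boundary: 200 is not ">200"
  r1 <- matrix(c(200, 201, 10, 9.99), 4, 1,
               dimnames = list(letters[1:4], "EL31"))
  u1 <- matrix(0L, 4, 1, dimnames = dimnames(r1))
  b <- abundanceBins(r1, u1)
  expect_identical(b[">200", 1], 1L)
  expect_identical(b["10-200", 1], 2L)
  expect_identical(b["0.5-10", 1], 1L)

  # random planted values vs direct tally; bins sum to detected totals
  set.seed(9)
  r <- randomRpkmMatrix(200, maxRpkm = 400)
  u <- matrix(rpois(800, 3), 200, dimnames = dimnames(r))
  b2 <- abundanceBins(r, u)
  tally <- sapply(berryStages(), function(s) c(
    sum(r[, s] > 200), sum(r[, s] >= 10 & r[, s] <= 200),
    sum(r[, s] >= 0.5 & r[, s] < 10),
    sum(r[, s] < 0.5 & u[, s] >= 5)))
  expect_equal(unname(b2), unname(tally), ignore_attr = TRUE)
  expect_equal(unname(colSums(b2)), unname(attr(b2, "detected")))
})

test_that("stage quantification conserves filtered reads with accepted candidates", {
  g <- generateCatalog(120, seed = 21)
  sim <- generateAlignments(g$truth, g$catalog, readsPerStage = 4000,
                            seed = 22)
  se <- quantifyStages(sim$reads, sim$alignments, g$catalog)
  kept <- filterReads(sim$reads)
  for (s in berryStages()) {
    sr <- kept[kept$stage == s, ]
    cand <- sim$alignments[sim$alignments$read_id %in% sr$read_id, ]
    acc <- filterAlignments(cand)
    expect_equal(sum(allocatedReads(se)[, s]), length(unique(acc$read_id)),
                 tolerance = 1e-6)
    expect_equal(totalMapped(se)[[s]], sum(allocatedReads(se)[, s]),
                 tolerance = 1e-9)
  }
  expect_true(validObject(se))
})
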