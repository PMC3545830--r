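normTemplates <- function(templates = berryArchetypes())
  t(vapply(templates, function(v) {
    s <- v / sqrt(sum(v^2)); s - mean(s)
  }, numeric(4)))

test_that("normalization scales to unit sum of squares, centres, and filters", {
  m <- rbind(ones = c(1, 1, 1, 1),
             low  = c(0.4, 0.4, 0.4, 0.4),
             spike = c(3, 0, 0, 0))
  colnames(m) <- berryStages()
  p <- normalizeProfiles(m)
  expect_identical(unname(p@reasons),
                   c("low_range", "all_low", "kept"))
  expect_equal(unname(p@scaled["spike", ]), c(1, 0, 0, 0))
  expect_equal(unname(p@normalized["spike", ]), c(0.75, -0.25, -0.25, -0.25))
  # the flat row scales to four 0.5s (sum of squares 1) before filtering
  expect_equal(sum((c(1, 1, 1, 1) / sqrt(4))^2), 1)
})

test_that("unit sum of squares holds for every kept row (property)", {
  set.seed(5)
  m <- randomRpkmMatrix(200, maxRpkm = 50)
  p <- normalizeProfiles(m)
  expect_gt(nrow(p@scaled), 0)
  expect_equal(unname(rowSums(p@scaled^2)),
               rep(1, nrow(p@scaled)), tolerance = 1e-9)
  expect_equal(unname(rowMeans(p@normalized)),
               rep(0, nrow(p@normalized)), tolerance = 1e-9)
  # idempotence: re-scaling an already unit-sum-of-squares row is a no-op
  r <- p@scaled[1, ]
  expect_equal(r / sqrt(sum(r^2)), r, tolerance = 1e-12)
})

test_that("k-means recovers well-separated planted groups with full stability", {
  Tm <- normTemplates(berryArchetypes()[c("young_specific", "veraison_up",
                                          "ripe_specific", "decreasing")])
  X <- Tm[rep(1:4, each = 12), ]
  rownames(X) <- sprintf("p%02d", 1:48)
  res <- kmeansStable(X, k = 4, nRuns = 25, seed = 2)
  expect_equal(bestObjective(res), 0, tolerance = 1e-12)
  expect_identical(timesFound(res), 25L)
  planted <- rep(1:4, each = 12)
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(res), planted), 1)
  # objective equals within-cluster SS of the reported solution
  wss <- sum((X - centroids(res)[clusterAssignments(res), ])^2)
  expect_equal(wss, bestObjective(res), tolerance = 1e-6)
})

test_that("k equal to the number of profiles gives singleton clusters", {
  set.seed(4)
  X <- matrix(rnorm(20), 5, 4, dimnames = list(letters[1:5], berryStages()))
  res <- kmeansStable(X, k = 5, nRuns = 5, seed = 1)
  expect_equal(bestObjective(res), 0, tolerance = 1e-12)
  expect_identical(sort(unname(clusterAssignments(res))), 1:5)
  expect_error(kmeansStable(X, k = 6, nRuns = 2), "fewer profiles")
})

test_that("repeated calls with the same seed are identical; row order only relabels", {
  set.seed(6)
  Tm <- normTemplates()
  X <- Tm[rep(1:10, each = 8), ] + matrix(rnorm(320, 0, 0.02), 80)
  rownames(X) <- sprintf("p%02d", 1:80)
  a <- kmeansStable(X, k = 10, nRuns = 200, seed = 9)
  b <- kmeansStable(X, k = 10, nRuns = 200, seed = 9)
  expect_identical(clusterAssignments(a), clusterAssignments(b))
  expect_equal(bestObjective(a), bestObjective(b))
  perm <- sample(nrow(X))
  c_ <- kmeansStable(X[perm, ], k = 10, nRuns = 200, seed = 9)
  expect_equal(mclust::adjustedRandIndex(
    clusterAssignments(c_)[rownames(X)], clusterAssignments(a)), 1)
})

test_that("best objective matches an independent k-means implementation", {
  set.seed(21)
  Tm <- normTemplates()
  X <- Tm[rep(1:10, each = 15), ] + matrix(rnorm(600, 0, 0.03), 150)
  rownames(X) <- sprintf("p%03d", 1:150)
  ours <- kmeansStable(X, k = 10, nRuns = 200, seed = 22)
  ref <- suppressWarnings(
    stats::kmeans(X, centers = 10, nstart = 100, iter.max = 100))
  # never worse than the reference's best restart
  expect_lte(bestObjective(ours), ref$tot.withinss + 1e-8)
  # the reference confirms our solution as a fixed point with the same
  # objective when initialized at our centroids
  conf <- suppressWarnings(
    stats::kmeans(X, centers = centroids(ours), iter.max = 100))
  expect_equal(conf$tot.withinss, bestObjective(ours), tolerance = 1e-6)
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(ours),
                                         conf$cluster), 1)
})

test_that("within one run the objective trace is non-increasing", {
  set.seed(11)
  X <- matrix(rnorm(400), 100, 4)
  C0 <- X[sample(100, 7), ]
  fit <- BerrySeq:::.lloyd(X, C0)
  expect_true(all(diff(fit$trace) <= 1e-10))
})

test_that("centroid labelling: perfect match, anticorrelation, tie-break", {
  Tm <- normTemplates()
  res <- new("ClusterResult", k = 3L,
             assignments = setNames(1:3, c("a", "b", "c")),
             centroids = rbind(Tm["young_specific", ],
                               -Tm["young_specific", ],
                               Tm["increasing", ]),
             nRuns = 1L, bestObjective = 0, timesFound = 1L,
             archetypeLabels = character(0))
  lab <- archetypeLabels(labelArchetypes(res))
  expect_identical(lab[1], "young_specific")
  expect_identical(lab[2], "unlabeled")
  expect_identical(lab[3], "increasing")
  # exact tie between two identical templates -> alphabetically first name
  twin <- list(zeta = c(4, 1, 1, 1), alpha = c(4, 1, 1, 1))
  lab2 <- archetypeLabels(labelArchetypes(res, templates = twin))
  expect_identical(lab2[1], "alpha")
  expect_error(labelArchetypes(res, templates = list()), "non-empty")
})

test_that("planted archetype partition is recovered at low noise (ARI > 0.9)", {
  fr <- defaultArchetypeFractions()
  g <- generateCatalog(500, archetypeFractions = fr / sum(fr) * 0.99,
                       noiseSd = 0.05, seed = 14)
  prof <- normalizeProfiles(g$truth$true_rpkm)
  res <- suppressWarnings(kmeansStable(prof, k = 10, nRuns = 300, seed = 15))
  planted <- g$truth$archetype_assignments[names(clusterAssignments(res))]
  expect_gt(mclust::adjustedRandIndex(clusterAssignments(res), planted), 0.9)
})
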