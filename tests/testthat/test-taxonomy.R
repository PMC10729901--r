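test_that("a 1-D manifold yields a path tree", {
  set.seed(1)
  X <- cbind(seq(0, 5, length.out = 100), rnorm(100, 0, 0.02))
  fit <- fitDDRtree(X, K = 15, seed = 1)
  deg <- hcmtax:::centerDegrees(fit@edges, nrow(fit@Y))
  expect_lte(max(deg), 2)
  expect_warning(ba <- extractBranches(fit), "path-only")
  expect_true(all(branchLabels(ba) == 1))
})

test_that("a planted 3-arm star is recovered", {
  d <- starData(n = 150, noise = 0.05, seed = 4)
  fit <- fitDDRtree(d$X, K = 20, seed = 4)
  deg <- hcmtax:::centerDegrees(fit@edges, nrow(fit@Y))
  expect_identical(sum(deg >= 3), 1L)
  ba <- extractBranches(fit)
  lab <- branchLabels(ba)
  arms <- lab <= 3
  agree <- mclust::adjustedRandIndex(lab[arms], d$arm[arms])
  expect_gte(agree, 0.9)
  expect_true(validObject(fit))
  expect_true(validObject(ba))
})

test_that("block-coordinate descent never increases the objective", {
  set.seed(10)
  for (rep in 1:5) {
    n <- sample(40:120, 1)
    X <- matrix(rnorm(n * 4), n, 4) + rep(rnorm(4, 0, 2), each = n)
    fit <- fitDDRtree(X, K = sample(5:15, 1), seed = rep)
    d <- diff(fit@objective)
    expect_true(all(d <= 1e-7 * max(1, abs(fit@objective[1]))))
    # spanning-tree validity on every fit
    expect_identical(nrow(fit@edges), nrow(fit@Y) - 1L)
    expect_true(hcmtax:::isConnectedTree(fit@edges, nrow(fit@Y)))
    expect_equal(max(abs(rowSums(fit@R) - 1)), 0, tolerance = 1e-9)
  }
})

test_that("fits are deterministic for a fixed seed", {
  d <- starData(n = 80, seed = 2)
  f1 <- fitDDRtree(d$X, K = 12, seed = 3)
  f2 <- fitDDRtree(d$X, K = 12, seed = 3)
  expect_identical(f1@Z, f2@Z)
  expect_identical(f1@edges, f2@edges)
  expect_identical(f1@objective, f2@objective)
})

test_that("topology recovery holds across seeds for 2, 3 and 4 arms", {
  # a junction may be represented by adjacent degree-3 centers, so the
  # recovered quantity is the number of junction clusters
  for (arms in 2:4) {
    hit <- 0L
    for (s in 1:10) {
      d <- starData(n = 120, noise = 0.04, seed = 100 * arms + s, arms = arms)
      fit <- fitDDRtree(d$X, K = 18, seed = s)
      hit <- hit + as.integer(branchPointClusters(fit) ==
                                as.integer(arms > 2))
    }
    expect_gte(hit, 9L)
  }
})

test_that("responsibility ties go to the lower-indexed center", {
  ## hand-built model: two centers symmetric about a patient at the origin
  Y <- rbind(c(-1, 0), c(1, 0))
  Z <- rbind(c(0, 0), c(-1, 0.1), c(1, -0.1))
  D <- hcmtax:::sqDist(Z, Y)
  E <- exp(-(D - apply(D, 1, min)) / 0.01)
  R <- E / rowSums(E)
  fit <- new("DDRTreeFit", W = diag(2), Z = Z, Y = Y,
             edges = matrix(c(1L, 2L), 1), R = R,
             params = list(), objective = c(1, 0.5))
  expect_warning(ba <- extractBranches(fit), "path-only")
  best <- max.col(R, ties.method = "first")
  expect_identical(best[1], 1L)             # exact tie -> center 1
})

test_that("invalid tree configurations error", {
  X <- matrix(rnorm(60), 30, 2)
  expect_error(fitDDRtree(X, K = 50), "K must not exceed")
  expect_error(fitDDRtree(matrix(rnorm(30), 30, 1)), "p >= 2")
  expect_error(branchStability(X, nBoot = 0), "nBoot")
})

test_that("bootstrap stability separates structure from noise", {
  d <- starData(n = 150, noise = 0.04, seed = 6)
  st <- branchStability(d$X, params = list(K = 18, seed = 6), nBoot = 8,
                        seed = 6)
  expect_gte(min(st$meanJaccard[1:3]), 0.75)   # the three planted arms
  expect_identical(st$failures, 0L)
  set.seed(7)
  noise <- matrix(rnorm(300), 150, 2)
  stN <- branchStability(noise, params = list(K = 18, seed = 7), nBoot = 8,
                         seed = 7)
  # noise partitions are substantially less stable than planted structure
  # (not exactly 0: the embedding splits space deterministically)
  expect_lt(stN$meanARI, 0.5)
  expect_lt(stN$meanARI, st$meanARI)
})

test_that("ED and ES trees can be compared by adjusted Rand", {
  coh <- quickCohort(n = 90, nv = 200, seed = 12)
  clin <- clinicalTable(coh)
  ariByPhase <- sapply(c("ED", "ES"), function(ph) {
    adj <- residualizeMaps(thicknessMaps(coh, ph), clin)
    tr <- fitMorphologyTree(adj$residuals, K = 15, seed = 1)
    branchLabels(extractBranches(tr$fit))
  })
  ari <- mclust::adjustedRandIndex(ariByPhase[, 1], ariByPhase[, 2])
  expect_true(is.finite(ari))                 # reported, not thresholded
})
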