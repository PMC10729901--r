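# Independent oracles and small fixture builders used across the suite.

# brute-force trustworthiness: full rank tables, double loop, ties by index
bruteM1 <- function(original, embedded, k) {
  Do <- as.matrix(dist(original))
  De <- as.matrix(dist(embedded))
  n <- nrow(Do)
  pen <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    rO <- setNames(rank(Do[i, others], ties.method = "first"), others)
    rE <- setNames(rank(De[i, others], ties.method = "first"), others)
    for (j in others) {
      if (rE[as.character(j)] <= k && rO[as.character(j)] > k)
        pen <- pen + (rO[as.character(j)] - k)
    }
  }
  unname(1 - 2 * pen / (n * k * (2 * n - 3 * k - 1)))
}

# brute-force 1-NN with lower-index tie rule
bruteNN <- function(q, ref) {
  apply(q, 1, function(p) {
    d <- colSums((t(ref) - p)^2)
    which(d == min(d))[1]
  })
}

# planted 3-arm star in 2-D
starData <- function(n = 150, noise = 0.05, seed = 4, arms = 3) {
  set.seed(seed)
  arm <- sample(seq_len(arms), n, TRUE)
  ang <- 2 * pi * (arm - 1) / arms
  r <- runif(n, 0.15, 1)
  list(X = cbind(r * cos(ang), r * sin(ang)) +
         matrix(rnorm(2 * n, 0, noise), n, 2),
       arm = arm)
}

# small quick cohort for pipeline tests
quickCohort <- function(n = 80, nv = 200, seed = 3, ...) {
  simulateCohort(cohortConfig(nPatients = n, nVertices = nv, seed = seed, ...))
}

# planted Gaussian blobs
blobData <- function(nPer, centers, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(nPer * ncol(centers), 0, sd), nPer), 2,
          centers[i, ], "+")))
  list(X = X, lab = rep(seq_len(nrow(centers)), each = nPer))
}

# unit cube surface mesh (12 triangles), outward oriented
unitCubeMesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),       # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),       # z = 1
    c(1, 2, 5), c(2, 6, 5),       # y = 0
    c(3, 7, 4), c(4, 7, 8),       # y = 1
    c(1, 5, 3), c(3, 5, 7),       # x = 0
    c(2, 4, 6), c(4, 8, 6))       # x = 1
  list(vertices = v, faces = f)
}
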