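## Phenomapping: unsupervised clustering of the clinical/imaging feature
## table.  The 2-D view is a neighborhood-preserving nonlinear spectral
## embedding (symmetrized kNN graph with locally scaled Gaussian
## affinities, normalized-Laplacian eigenvectors); clusters come from
## silhouette-optimized K-means.

#' Standardize a clinical feature table for phenomapping
#'
#' Continuous features are z-scored (median-imputed when missing);
#' binary/categorical features are reference-coded 0/1 indicators with an
#' explicit "missing" level when needed.
#'
#' @param clinical data.frame.
#' @param continuous,categorical character vectors of column names; by
#'   default inferred from column types.
#' @return numeric matrix, one standardized column per feature/indicator.
#' @export
standardizeFeatures <- function(clinical, continuous = NULL,
                                categorical = NULL) {
  if (is.null(continuous))
    continuous <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
  if (is.null(categorical))
    categorical <- setdiff(names(clinical)[vapply(clinical, function(x)
      is.factor(x) || is.character(x) || is.logical(x), logical(1))],
      c("id"))
  if (anyDuplicated(c(continuous, categorical)))
    stop("a feature is listed twice")
  missing <- setdiff(c(continuous, categorical), names(clinical))
  if (length(missing))
    stop("feature column(s) not found: ", paste(missing, collapse = ", "))
  cols <- list()
  for (nm in continuous) {
    v <- clinical[[nm]]
    v[is.na(v)] <- median(v, na.rm = TRUE)
    s <- sd(v)
    cols[[nm]] <- if (s > 0) (v - mean(v)) / s else v * 0
  }
  for (nm in categorical) {
    f <- as.factor(clinical[[nm]])
    if (anyNA(f)) {
      f <- addNA(f)
      levels(f)[is.na(levels(f))] <- "missing"
    }
    for (li in seq_along(levels(f))[-1]) {
      x <- as.numeric(as.integer(f) == li)
      s <- sd(x)
      cols[[paste0(nm, ".", levels(f)[li])]] <-
        if (s > 0) (x - mean(x)) / s else x * 0
    }
  }
  do.call(cbind, cols)
}

#' Nonlinear 2-D neighborhood embedding
#'
#' Spectral neighbor embedding: a symmetrized k-nearest-neighbor graph
#' with locally scaled Gaussian affinities (scale = distance to the 7th
#' neighbor), augmented with minimum-spanning-tree edges so the graph is
#' connected, embedded by the two nontrivial eigenvectors of the
#' normalized graph Laplacian.  Deterministic; duplicate rows receive
#' identical coordinates.  Embedding trustworthiness is reported via
#' \code{\link{trustworthinessM1}}.
#'
#' @param x standardized feature matrix (>= 10 rows).
#' @param nNeighbors neighborhood size of the kNN graph.
#' @param seed integer seed (kept for interface stability; the embedding
#'   is deterministic).
#' @param trustK neighborhood size at which trustworthiness is reported.
#' @return list with \code{coords} (n x 2), \code{trustworthiness}.
#' @export
embedFeatures <- function(x, nNeighbors = 15L, seed = 0L, trustK = 10L) {
  x <- as.matrix(x)
  nAll <- nrow(x)
  if (nAll < 10) stop("need at least 10 patients")
  ## exact duplicate rows share the graph vertex (and thus coordinates)
  key <- apply(x, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  mapBack <- match(key, key[uniq])
  xu <- x[uniq, , drop = FALSE]
  n <- nrow(xu)
  D <- as.matrix(dist(xu))
  if (max(D) == 0 || n < 4) stop("degenerate input: all rows identical")
  set.seed(seed)
  k <- min(nNeighbors, n - 1L)
  ## local scale: distance to the 7th (or k-th if smaller) neighbor
  kS <- min(7L, k)
  sig <- apply(D, 1, function(d) sort(d)[kS + 1L])
  sig[sig == 0] <- min(sig[sig > 0], 1e-8)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nb <- ord[ord != i][seq_len(k)]          # self excluded even under ties
    W[i, nb] <- exp(-D[i, nb]^2 / (sig[i] * sig[nb]))
  }
  W <- pmax(W, t(W))
  ## connect components through the MST of the full distance matrix
  mstE <- primMST(D^2)
  for (e in seq_len(nrow(mstE))) {
    i <- mstE[e, 1]; j <- mstE[e, 2]
    if (W[i, j] == 0)
      W[i, j] <- W[j, i] <- exp(-D[i, j]^2 / (sig[i] * sig[j]))
  }
  dg <- rowSums(W)
  dg[dg == 0] <- 1e-12
  S <- W / sqrt(dg) / rep(sqrt(dg), each = n)
  ev <- eigen(S, symmetric = TRUE)
  coords <- ev$vectors[, 2:3, drop = FALSE] / sqrt(dg)
  ## deterministic sign convention
  for (j in 1:2) {
    i0 <- which.max(abs(coords[, j]))
    if (coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  coords <- scale(coords, center = TRUE, scale = FALSE)
  coords <- unname(coords[mapBack, , drop = FALSE])
  tw <- trustworthinessM1(x, coords, k = min(trustK, floor((nAll - 1) / 2)))
  list(coords = coords, trustworthiness = tw)
}

#' Silhouette-optimized K-means clustering
#'
#' Runs K-means (k-means++-style multiple restarts via \code{nstart}) for
#' every k in the search range, computes the mean silhouette width on the
#' same space, and selects the k with maximal silhouette (ties to the
#' smaller k).  A low-confidence flag is raised when even the best mean
#' silhouette is below 0.5 (weak cluster structure).
#'
#' @param points numeric matrix (embedding coordinates or standardized
#'   features).
#' @param kRange integer vector of candidate k.
#' @param nstart K-means restarts.
#' @param seed integer seed.
#' @return list with \code{kSelected}, \code{labels}, \code{silhouetteByK}
#'   (data.frame), \code{lowConfidence}.
#' @export
selectKClusters <- function(points, kRange = 2:8, nstart = 25L, seed = 0L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (max(kRange) >= n) stop("invalid config: kRange must be below n")
  D <- dist(points)
  sil <- numeric(length(kRange))
  labs <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    set.seed(seed + i)
    km <- kmeans(points, centers = kRange[i], nstart = nstart, iter.max = 100)
    labs[[i]] <- km$cluster
    sil[i] <- mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
  }
  lowConf <- max(sil) < 0.5
  ## no real cluster structure anywhere in the range: report the range
  ## minimum rather than an arbitrary winner among equally weak splits
  best <- if (lowConf) 1L else which(sil == max(sil))[1]  # ties: smaller k
  list(kSelected = as.integer(kRange[best]), labels = labs[[best]],
       silhouetteByK = data.frame(k = kRange, meanSilhouette = sil),
       lowConfidence = lowConf)
}

#' Cluster enrichment profiling
#'
#' Tests every clinical feature across clusters: Kruskal-Wallis for
#' continuous features, chi-squared for categorical ones (Fisher's exact
#' test when any expected cell count is < 5), with Benjamini-Hochberg
#' correction over all tested features.  Constant features get p = 1 by
#' convention.  Per-cluster means (continuous) or prevalences are
#' attached.
#'
#' @param labels per-patient cluster labels.
#' @param clinical aligned clinical data.frame.
#' @param features optional subset of column names to test.
#' @return data.frame with feature, type, p, p_adj and per-cluster
#'   summaries; zero rows if there is a single cluster.
#' @export
clusterEnrichment <- function(labels, clinical, features = NULL) {
  if (length(labels) != nrow(clinical))
    stop("labels and clinical table are not aligned")
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    return(data.frame(feature = character(), type = character(),
                      p = numeric(), p_adj = numeric()))
  if (is.null(features)) features <- setdiff(names(clinical), "id")
  rows <- lapply(features, function(nm) {
    v <- clinical[[nm]]
    ok <- !is.na(v)
    if (is.numeric(v) && !is.factor(v)) {
      p <- if (length(unique(v[ok])) < 2) 1
           else kruskal.test(v[ok], labels[ok])$p.value
      per <- tapply(v[ok], labels[ok], mean)
      data.frame(feature = nm, type = "continuous", p = p,
                 t(as.matrix(per)), check.names = FALSE)
    } else {
      f <- droplevels(as.factor(v[ok]))
      if (nlevels(f) < 2) {
        p <- 1
      } else {
        tab <- table(f, labels[ok])
        expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        p <- if (any(expd < 5))
          fisher.test(tab, simulate.p.value = length(tab) > 10,
                      B = 1e4)$p.value
        else chisq.test(tab)$p.value
      }
      f2 <- droplevels(as.factor(v[ok]))
      prev <- tapply(f2 == levels(f2)[nlevels(f2)], labels[ok], mean)
      data.frame(feature = nm, type = "categorical", p = p,
                 t(as.matrix(prev)), check.names = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
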