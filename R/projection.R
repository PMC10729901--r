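## External projection and validation of a fitted morphology tree:
## random-forest regression of the two tree coordinates on adjusted vertex
## features, nearest-neighbor branch labelling, rank-based embedding
## trustworthiness and a cohort-consistency screen.

#' Fit the coordinate-regression model
#'
#' One random-forest regressor per tree coordinate (x and y), trained on
#' the adjusted development-cohort features.
#'
#' @param features n x p development feature matrix.
#' @param coords n x 2 tree coordinates.
#' @param nTree forest size.
#' @param seed integer seed.
#' @return list of class \code{"CoordinateModel"} with the two forests and
#'   the training feature schema.
#' @export
fitCoordinateModel <- function(features, coords, nTree = 500L, seed = 0L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  set.seed(seed)
  rfx <- randomForest::randomForest(features, coords[, 1], ntree = nTree)
  set.seed(seed + 1L)
  rfy <- randomForest::randomForest(features, coords[, 2], ntree = nTree)
  structure(list(rfx = rfx, rfy = rfy, schema = colnames(features),
                 devCoords = coords, seed = seed),
            class = "CoordinateModel")
}

#' Predict tree coordinates for external patients
#'
#' Enforces the training feature schema, predicts both coordinates, and
#' flags external patients whose nearest development-cohort distance in
#' coordinate space exceeds the development cohort's 99th percentile of
#' nearest-neighbor distances (an outlier screen for points falling far
#' from the tree).
#'
#' @param model a \code{"CoordinateModel"}.
#' @param features external adjusted feature matrix with the training
#'   columns.
#' @return data.frame with x, y, outlier.
#' @export
projectExternal <- function(model, features) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (!identical(colnames(features), model$schema)) {
    miss <- setdiff(model$schema, colnames(features))
    extra <- setdiff(colnames(features), model$schema)
    if (length(miss) || length(extra))
      stop("feature schema mismatch; missing: [",
           paste(miss, collapse = ", "), "] unexpected: [",
           paste(extra, collapse = ", "), "]")
    features <- features[, model$schema, drop = FALSE]
  }
  px <- predict(model$rfx, features)
  py <- predict(model$rfy, features)
  dev <- model$devCoords
  devNN <- apply(sqDist(dev, dev) + diag(Inf, nrow(dev)), 1, min)
  thr <- quantile(sqrt(devNN), 0.99)
  extNN <- sqrt(apply(sqDist(cbind(px, py), dev), 1, min))
  data.frame(x = px, y = py, outlier = extNN > thr)
}

#' Cross-validated coordinate-regression R-squared
#'
#' Repeated k-fold cross-validation of the coordinate model on the
#' development cohort: out-of-fold predictions are pooled within each
#' repeat, R^2 = 1 - SSE/SST per axis, averaged over repeats.
#'
#' @param features n x p feature matrix.
#' @param coords n x 2 tree coordinates.
#' @param folds number of folds (default 10).
#' @param repeats number of repetitions (default 3).
#' @param nTree forest size.
#' @param seed integer seed.
#' @return list with \code{r2_x}, \code{r2_y} and the per-repeat values.
#' @export
crossvalCoordinateR2 <- function(features, coords, folds = 10L,
                                 repeats = 3L, nTree = 500L, seed = 0L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < folds) stop("invalid config: fewer patients than folds")
  r2 <- matrix(NA_real_, repeats, 2, dimnames = list(NULL, c("x", "y")))
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold <- sample(rep(seq_len(folds), length.out = n))
    pred <- matrix(NA_real_, n, 2)
    for (f in seq_len(folds)) {
      tr <- fold != f
      for (ax in 1:2) {
        set.seed(seed + 1000L * r + 2L * f + ax)
        rf <- randomForest::randomForest(features[tr, , drop = FALSE],
                                         coords[tr, ax], ntree = nTree)
        pred[!tr, ax] <- predict(rf, features[!tr, , drop = FALSE])
      }
    }
    for (ax in 1:2)
      r2[r, ax] <- 1 - sum((coords[, ax] - pred[, ax])^2) /
                       sum((coords[, ax] - mean(coords[, ax]))^2)
  }
  list(r2_x = mean(r2[, 1]), r2_y = mean(r2[, 2]), byRepeat = r2)
}

#' Nearest-neighbor branch labels for external patients
#'
#' Euclidean 1-NN in tree-coordinate space; distance ties go to the lower
#' development-patient index.
#'
#' @param predCoords external n x 2 predicted coordinates.
#' @param devCoords development m x 2 coordinates.
#' @param devBranch development branch labels (length m).
#' @return external branch labels.
#' @export
nearestNeighborBranch <- function(predCoords, devCoords, devBranch) {
  if (nrow(devCoords) == 0) stop("empty development set")
  D <- sqDist(as.matrix(predCoords), as.matrix(devCoords))
  devBranch[max.col(-D, ties.method = "first")]
}

#' Embedding trustworthiness M1
#'
#' Rank-based measure of false neighbors:
#' M1(k) = 1 - 2/(n k (2n - 3k - 1)) * sum_i sum_{j in U_k(i)} (r(i,j) - k),
#' where U_k(i) are the k nearest neighbors of i in the embedding that are
#' not among its k nearest neighbors in the original space, and r(i,j) is
#' the original-space neighbor rank of j for i.  Distance ties are broken
#' by index; requires 1 <= k < n/2.
#'
#' @param original n x p original-space feature matrix.
#' @param embedded n x d embedding coordinates.
#' @param k neighborhood size.
#' @return M1 in [0, 1].
#' @export
trustworthinessM1 <- function(original, embedded, k) {
  original <- as.matrix(original)
  embedded <- as.matrix(embedded)
  n <- nrow(original)
  if (k < 1 || k >= n / 2) stop("invalid config: need 1 <= k < n/2")
  Do <- as.matrix(dist(original))
  De <- as.matrix(dist(embedded))
  pen <- 0
  for (i in seq_len(n)) {
    oo <- order(Do[i, -i], seq_len(n - 1))   # ties by index
    oRank <- integer(n); oRank[setdiff(seq_len(n), i)[oo]] <- seq_len(n - 1)
    oe <- order(De[i, -i], seq_len(n - 1))
    eNN <- setdiff(seq_len(n), i)[oe][seq_len(k)]
    U <- eNN[oRank[eNN] > k]
    pen <- pen + sum(oRank[U] - k)
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * pen
}

#' Trustworthiness over a grid of neighborhood sizes
#'
#' @param original,embedded as in \code{\link{trustworthinessM1}}.
#' @param kGrid neighborhood sizes (values >= n/2 are dropped).
#' @return data.frame with k and M1; attributes \code{range} = c(min, max).
#' @export
trustworthinessRange <- function(original, embedded,
                                 kGrid = c(5L, 10L, 15L, 20L)) {
  kGrid <- as.integer(kGrid[kGrid >= 1 & kGrid < nrow(as.matrix(original)) / 2])
  m1 <- vapply(kGrid, function(k)
    trustworthinessM1(original, embedded, k), numeric(1))
  out <- data.frame(k = kGrid, M1 = m1)
  attr(out, "range") <- range(m1)
  out
}

#' Cohort-consistency screen
#'
#' Within each cohort, computes the correlation of every feature with each
#' embedding axis; the two resulting correlation distributions are
#' compared by a two-sample Kolmogorov-Smirnov test.  Degenerate
#' (constant) features are dropped with a note.
#'
#' @param devFeatures,devCoords development features and coordinates.
#' @param extFeatures,extCoords external features and coordinates.
#' @return list with \code{statistic}, \code{p}, the two correlation
#'   vectors and \code{dropped} (count of degenerate features).
#' @export
cohortConsistency <- function(devFeatures, devCoords,
                              extFeatures, extCoords) {
  if (nrow(as.matrix(devFeatures)) < 10 || nrow(as.matrix(extFeatures)) < 10)
    stop("both cohorts must have at least 10 patients")
  corVec <- function(f, z) {
    f <- as.matrix(f); z <- as.matrix(z)
    v <- as.vector(vapply(1:2, function(ax)
      suppressWarnings(cor(f, z[, ax]))[, 1], numeric(ncol(f))))
    v
  }
  cd <- corVec(devFeatures, devCoords)
  ce <- corVec(extFeatures, extCoords)
  drop <- sum(is.na(cd)) + sum(is.na(ce))
  if (drop > 0) message(drop, " degenerate correlation(s) dropped")
  cd <- cd[!is.na(cd)]; ce <- ce[!is.na(ce)]
  if (identical(cd, ce))
    return(list(statistic = 0, p = 1, dev = cd, ext = ce, dropped = drop))
  kt <- suppressWarnings(ks.test(cd, ce))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       dev = cd, ext = ce, dropped = drop)
}
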