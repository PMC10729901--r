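## Reversed graph embedding (DDRtree): jointly learn an orthonormal linear
## projection W, 2-D latent sample coordinates Z, latent centers Y and a
## spanning tree B over the centers by block-coordinate descent on
##
##   sum_i ||x_i - W z_i||^2
##   + lambda * sum_{(k,k') in B} ||y_k - y_k'||^2
##   + gamma  * sum_i sum_k r_ik (||z_i - y_k||^2 + sigma log r_ik)
##
## Every block update is an exact minimizer, so the objective never
## increases: B is the minimum spanning tree over center distances, R the
## softmax responsibilities at bandwidth sigma, W the orthogonal Procrustes
## solution, and Z and Y closed-form linear solves.

## Prim's MST with lexicographic tie-breaking (smallest center index wins)
primMST <- function(D) {
  K <- nrow(D)
  if (K == 1L) return(matrix(integer(0), 0, 2))
  inTree <- c(TRUE, rep(FALSE, K - 1))
  best <- D[1, ]; parent <- rep(1L, K)
  edges <- matrix(0L, K - 1L, 2L)
  for (step in seq_len(K - 1L)) {
    cand <- which(!inTree)
    nxt <- cand[which.min(best[cand])]       # which.min takes lowest index on ties
    edges[step, ] <- c(parent[nxt], nxt)
    inTree[nxt] <- TRUE
    upd <- !inTree & D[nxt, ] < best
    best[upd] <- D[nxt, upd]
    parent[upd] <- nxt
  }
  edges
}

isConnectedTree <- function(edges, K) {
  if (K == 1L) return(nrow(edges) == 0L)
  if (nrow(edges) != K - 1L) return(FALSE)
  seen <- rep(FALSE, K); seen[1] <- TRUE
  repeat {
    hit <- seen[edges[, 1]] | seen[edges[, 2]]
    nsee <- seen
    nsee[edges[hit, 1]] <- TRUE
    nsee[edges[hit, 2]] <- TRUE
    if (identical(nsee, seen)) break
    seen <- nsee
  }
  all(seen)
}

sqDist <- function(A, B) {
  ## ||a_i - b_j||^2, rows of A vs rows of B
  d <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

#' Fit a reversed-graph-embedding (DDRtree) model
#'
#' Learns a 2-D tree-structured embedding of a feature matrix by
#' alternating exact block updates (see source header for the objective).
#' Initialisation: Z from the first two principal components, Y from
#' K-means on Z.  The fit is deterministic for a fixed seed, and the
#' objective trace is checked to be non-increasing.
#'
#' @param X n x p feature matrix (column-centered internally), p >= 2.
#' @param lambda graph (tree-length) regularization weight.
#' @param sigma responsibility bandwidth.
#' @param gamma center-attraction weight.
#' @param K number of latent centers (default min(n/5, 50), at least 2).
#' @param maxIter maximum iterations.
#' @param tol relative objective-change stopping tolerance.
#' @param seed integer seed (K-means initialisation).
#' @return a \linkS4class{DDRTreeFit}.
#' @examples
#' X <- cbind(seq(0, 5, length.out = 60), rnorm(60, 0, 0.05))
#' fit <- fitDDRtree(X, K = 10)
#' @export
fitDDRtree <- function(X, lambda = 5, sigma = 0.01, gamma = 10,
                       K = NULL, maxIter = 100L, tol = 1e-4, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("invalid config: need p >= 2 features")
  if (is.null(K)) K <- max(2L, min(floor(n / 5), 50L))
  if (K > n) stop("invalid config: K must not exceed n")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  set.seed(seed)
  pc <- prcomp(Xc, center = FALSE, rank. = 2)
  Z <- pc$x[, 1:2, drop = FALSE]
  if (ncol(Z) < 2) Z <- cbind(Z, 0)
  W <- pc$rotation[, 1:2, drop = FALSE]
  nuniq <- nrow(unique(Z))
  K <- min(K, nuniq)
  km <- kmeans(Z, centers = K, nstart = 5, iter.max = 50)
  Y <- km$centers

  obj <- numeric(0)
  edges <- primMST(as.matrix(dist(Y))^2)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    ## (i) spanning tree over current centers
    edges <- primMST(as.matrix(dist(Y))^2)
    ## (ii) softmax responsibilities (log-sum-exp stabilised)
    D <- sqDist(Z, Y)                        # n x K
    m <- apply(D, 1, min)
    E <- exp(-(D - m) / sigma)
    R <- E / rowSums(E)
    ## (iii) orthonormal W by Procrustes on crossprod(X, Z)
    sv <- svd(crossprod(Xc, Z))
    W <- sv$u %*% t(sv$v)
    ## (iv) closed-form Z then Y
    Z <- (Xc %*% W + gamma * (R %*% Y)) / (1 + gamma)
    L <- treeLaplacian(edges, K)
    A <- lambda * L + gamma * diag(colSums(R), K)
    Y <- solve(A, gamma * crossprod(R, Z))
    ## objective (entropy-collapsed assignment term:
    ## sum_k r(d + sigma log r) = -sigma * logsumexp(-d/sigma))
    D <- sqDist(Z, Y)
    m <- apply(D, 1, min)
    assign <- m - sigma * log(rowSums(exp(-(D - m) / sigma)))
    de <- Y[edges[, 1], , drop = FALSE] - Y[edges[, 2], , drop = FALSE]
    o <- sum((Xc - Z %*% t(W))^2) + lambda * sum(de^2) + gamma * sum(assign)
    if (!is.finite(o))
      stop("numerical failure: non-finite objective at iteration ", it)
    obj <- c(obj, o)
    if (it > 1 && abs(obj[it - 1] - o) < tol * abs(obj[it - 1])) {
      converged <- TRUE
      break
    }
  }
  ## final responsibilities consistent with returned Z, Y
  D <- sqDist(Z, Y)
  m <- apply(D, 1, min)
  E <- exp(-(D - m) / sigma)
  R <- E / rowSums(E)
  edges <- primMST(as.matrix(dist(Y))^2)
  new("DDRTreeFit", W = W, Z = unname(Z), Y = unname(Y),
      edges = edges, R = R,
      params = list(lambda = lambda, sigma = sigma, gamma = gamma, K = K,
                    maxIter = maxIter, tol = tol, seed = seed,
                    converged = converged, center = attr(Xc, "scaled:center")),
      objective = obj)
}

treeLaplacian <- function(edges, K) {
  L <- matrix(0, K, K)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
  }
  L
}

centerDegrees <- function(edges, K)
  tabulate(c(edges[, 1], edges[, 2]), K)

#' Count distinct branch points (junction clusters) of a fitted tree
#'
#' A junction of the underlying manifold may be represented by several
#' adjacent degree->=3 centers (a degree-4 junction typically appears as
#' two adjacent degree-3 centers in a tree).  This counts connected
#' components of the subgraph induced by degree->=3 centers, i.e. distinct
#' junctions.
#'
#' @param fit a \linkS4class{DDRTreeFit}.
#' @return integer number of junction clusters (0 for a path).
#' @export
branchPointClusters <- function(fit) {
  K <- nrow(fit@Y)
  deg <- centerDegrees(fit@edges, K)
  bp <- which(deg >= 3L)
  if (!length(bp)) return(0L)
  sub <- fit@edges[fit@edges[, 1] %in% bp & fit@edges[, 2] %in% bp, ,
                   drop = FALSE]
  comp <- seq_along(bp)
  names(comp) <- bp
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (e in seq_len(nrow(sub))) {
    a <- find(match(sub[e, 1], bp)); b <- find(match(sub[e, 2], bp))
    if (a != b) comp[b] <- a
  }
  length(unique(vapply(seq_along(bp), find, numeric(1))))
}

#' Extract branches from a fitted tree
#'
#' Centers of tree degree >= 3 are branch points; the maximal center paths
#' between branch points and leaves are the branches.  Branch points and
#' centers within Euclidean radius \code{rho} of a branch point (default:
#' the median tree edge length) form the undifferentiated "core" branch,
#' which receives the highest branch id.  Each patient is assigned the
#' branch of its highest-responsibility center (ties go to the
#' lower-indexed center).
#'
#' @param fit a \linkS4class{DDRTreeFit}.
#' @param rho core radius; \code{NULL} for the median edge length.
#' @return a \linkS4class{BranchAssignment}.
#' @export
extractBranches <- function(fit, rho = NULL) {
  K <- nrow(fit@Y)
  edges <- fit@edges
  deg <- centerDegrees(edges, K)
  bp <- which(deg >= 3L)
  adj <- lapply(seq_len(K), function(k)
    sort(c(edges[edges[, 1] == k, 2], edges[edges[, 2] == k, 1])))
  terminals <- if (length(bp)) sort(unique(c(bp, which(deg == 1L))))
               else which(deg <= 1L)
  centerBranch <- integer(K)
  if (length(bp) == 0L) {
    warning("path-only tree: single branch, empty core")
    centerBranch[] <- 1L
    hasCore <- FALSE
  } else {
    ## walk maximal paths between terminals; label interior + leaf ends
    paths <- list()
    seenEdge <- matrix(FALSE, K, K)
    for (t0 in terminals) for (nb in adj[[t0]]) {
      if (seenEdge[t0, nb]) next
      path <- c(t0, nb)
      prev <- t0; cur <- nb
      while (!(cur %in% terminals)) {
        nxt <- setdiff(adj[[cur]], prev)[1]
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      seenEdge[t0, path[2]] <- TRUE
      seenEdge[cur, path[length(path) - 1]] <- TRUE
      paths[[length(paths) + 1L]] <- path
    }
    ## deterministic branch order: by smallest interior/leaf center index
    ord <- order(vapply(paths, function(p)
      min(setdiff(p, bp), Inf), numeric(1)))
    paths <- paths[ord]
    bId <- 0L
    for (p in paths) {
      own <- setdiff(p, bp)
      if (!length(own)) next
      bId <- bId + 1L
      centerBranch[own] <- bId
    }
    ## core: branch points + centers within rho of any branch point
    if (is.null(rho)) {
      el <- sqrt(rowSums((fit@Y[edges[, 1], , drop = FALSE] -
                          fit@Y[edges[, 2], , drop = FALSE])^2))
      rho <- median(el)
    }
    dbp <- sqDist(fit@Y, fit@Y[bp, , drop = FALSE])
    core <- deg >= 3L | apply(dbp, 1, min) <= rho^2
    centerBranch[core] <- bId + 1L           # core takes the highest id
    hasCore <- TRUE
    ## a branch may be swallowed whole by the core: re-compact ids, which
    ## keeps them contiguous and leaves the core as the maximum id
    ids <- sort(unique(centerBranch[centerBranch > 0L]))
    centerBranch[centerBranch > 0L] <- match(centerBranch[centerBranch > 0L], ids)
  }
  ## unlabelled centers (can only happen in degenerate geometries): nearest
  ## labelled center
  if (any(centerBranch == 0L)) {
    lab <- which(centerBranch > 0L)
    d0 <- sqDist(fit@Y[centerBranch == 0L, , drop = FALSE],
                 fit@Y[lab, , drop = FALSE])
    centerBranch[centerBranch == 0L] <- centerBranch[lab[max.col(-d0, "first")]]
  }
  best <- max.col(fit@R, ties.method = "first")
  new("BranchAssignment", branch = centerBranch[best], coords = fit@Z,
      centerBranch = centerBranch, branchPoints = as.integer(bp),
      hasCore = isTRUE(hasCore))
}

#' PCA-reduce adjusted maps and fit the morphology tree
#'
#' Convenience wrapper implementing the full taxonomy input pipeline:
#' covariate-adjusted per-vertex maps are reduced to the leading principal
#' components capturing \code{varExplained} of the variance (vertex space
#' has p >> n) and passed to \code{\link{fitDDRtree}}.
#'
#' @param maps patients x vertices matrix (typically residualized).
#' @param varExplained variance fraction retained by the PCA reduction.
#' @param ... passed to \code{\link{fitDDRtree}}.
#' @return list with \code{fit} (\linkS4class{DDRTreeFit}), \code{features}
#'   (the PCA scores fed to the tree) and \code{rotation}.
#' @export
fitMorphologyTree <- function(maps, varExplained = 0.99, ...) {
  pc <- prcomp(as.matrix(maps), center = TRUE)
  nc <- max(2L, which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= varExplained)[1])
  feats <- pc$x[, seq_len(nc), drop = FALSE]
  list(fit = fitDDRtree(feats, ...), features = feats,
       rotation = pc$rotation[, seq_len(nc), drop = FALSE],
       center = pc$center)
}

#' Bootstrap stability of the branch partition
#'
#' Resamples patients with replacement, refits the tree with the same
#' hyperparameters, maps each original branch to its best-matching
#' bootstrap branch by Jaccard index over the resampled patients, and
#' reports per-branch maximal Jaccard and the adjusted Rand index between
#' the partitions (mean and sd over resamples).  Refit failures are
#' counted, not fatal.
#'
#' @param X feature matrix fed to \code{\link{fitDDRtree}}.
#' @param params list of fitDDRtree arguments (lambda, sigma, gamma, K...).
#' @param nBoot number of bootstrap resamples (>= 1; spec floor 20 for
#'   reporting).
#' @param seed integer seed.
#' @return list with \code{jaccard} (branches x resamples matrix),
#'   \code{meanJaccard}, \code{ari} (per resample), \code{meanARI},
#'   \code{sdARI}, \code{failures}.
#' @export
branchStability <- function(X, params = list(), nBoot = 20L, seed = 0L) {
  if (nBoot < 1) stop("invalid config: nBoot must be >= 1")
  base <- do.call(fitDDRtree, c(list(X = X), params))
  orig <- branchLabels(extractBranches(base))
  nb <- length(unique(orig))
  jac <- matrix(NA_real_, nb, nBoot)
  ari <- rep(NA_real_, nBoot)
  fail <- 0L
  for (b in seq_len(nBoot)) {
    set.seed(seed + b)
    idx <- sample(nrow(X), replace = TRUE)
    res <- try({
      pb <- params
      pb$seed <- seed + b
      fb <- do.call(fitDDRtree, c(list(X = X[idx, , drop = FALSE]), pb))
      bb <- branchLabels(extractBranches(fb))
      u <- !duplicated(idx)
      oi <- orig[idx][u]; bi <- bb[u]
      ari[b] <- mclust::adjustedRandIndex(oi, bi)
      for (g in seq_len(nb)) {
        og <- sort(unique(orig))[g]
        jac[g, b] <- max(vapply(unique(bi), function(h) {
          a <- oi == og; c_ <- bi == h
          sum(a & c_) / sum(a | c_)
        }, numeric(1)))
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) fail <- fail + 1L
  }
  list(jaccard = jac, meanJaccard = rowMeans(jac, na.rm = TRUE),
       ari = ari, meanARI = mean(ari, na.rm = TRUE),
       sdARI = sd(ari, na.rm = TRUE), failures = fail)
}
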