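## Vertex-wise mass-univariate association maps: independent OLS per
## vertex with a predictor of interest (genotype contrast or branch
## indicator) and age/sex/race covariates, standardized coefficients,
## and family-wise (permutation max-T) or FDR multiplicity correction.

#' Build a genotype-contrast design
#'
#' Pairwise contrasts mirror panel-style comparisons: the cohort is
#' subset to the two genotype groups and the predictor is the indicator
#' of the first-named group.
#'
#' @param clinical clinical table with genotype, age, sex, race.
#' @param contrast one of \code{"plp_vs_neg"}, \code{"plp_vs_vus"},
#'   \code{"vus_vs_neg"}.
#' @return list with \code{keep} (row index), \code{predictor} (0/1) and
#'   \code{covariates} (data.frame age/sex/race).
#' @export
genotypeContrast <- function(clinical,
                             contrast = c("plp_vs_neg", "plp_vs_vus",
                                          "vus_vs_neg")) {
  contrast <- match.arg(contrast)
  code <- c(plp = "SARC-P/LP", vus = "SARC-VUS", neg = "SARC-NEG")
  parts <- strsplit(contrast, "_vs_")[[1]]
  keep <- which(clinical$genotype %in% code[parts])
  list(keep = keep,
       predictor = as.numeric(clinical$genotype[keep] == code[parts[1]]),
       covariates = clinical[keep, intersect(c("age", "sex", "race"),
                                             colnames(clinical)),
                             drop = FALSE])
}

## expand covariate data.frame to a numeric matrix (one-hot, drop reference)
covariateMatrix <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0) return(NULL)
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1); colnames(m) <- nm; m
    } else {
      f <- droplevels(as.factor(v))
      if (nlevels(f) < 2) {
        m <- matrix(numeric(length(f)), ncol = 1)
        colnames(m) <- paste0(nm, levels(f)[1]); m
      } else {
        m <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(m) <- paste0(nm, levels(f)[-1]); m
      }
    }
  })
  do.call(cbind, cols)
}

#' Vertex-wise linear association maps
#'
#' Fits an independent ordinary-least-squares model at every vertex with
#' the shared design [intercept, covariates, predictor] and returns the
#' predictor's raw and standardized coefficient, t statistic and two-sided
#' p value per vertex.  The standardized coefficient is
#' beta * sd(predictor) / sd(response at the vertex).
#'
#' @param maps patients x vertices response matrix.
#' @param predictor numeric vector of length n (the contrast of interest).
#' @param covariates optional data.frame of adjustment covariates
#'   (age, sex, race ...); categorical columns are one-hot coded.
#' @return list of class \code{"AssociationMaps"}: beta, beta_std, tstat,
#'   p_raw (each per vertex), df, and the design pieces needed for
#'   permutation correction.
#' @export
vertexwiseGLM <- function(maps, predictor, covariates = NULL) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  C <- covariateMatrix(covariates)
  X <- if (is.null(C)) cbind(`(Intercept)` = rep(1, n), predictor = predictor)
       else cbind(`(Intercept)` = rep(1, n), C, predictor = predictor)
  if (n <= ncol(X) + 2)
    stop("need n > rank(design) + 2 patients")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ## residualize both sides on [1, covariates]; the predictor t statistic
  ## of the full model equals the simple regression on these residuals
  ## with df = n - ncol(X)
  X0 <- X[, -ncol(X), drop = FALSE]
  q0 <- qr(X0)
  pres <- qr.resid(q0, predictor)
  yres <- qr.resid(q0, maps)
  df <- n - ncol(X)
  pp <- sum(pres^2)
  beta <- as.vector(crossprod(pres, yres)) / pp
  sse <- colSums(yres^2) - beta^2 * pp
  sse[sse < 0] <- 0
  tstat <- beta / sqrt(sse / df / pp)
  tstat[is.nan(tstat)] <- 0              # 0/0 at a degenerate vertex
  sdY <- unname(apply(maps, 2, sd))
  tstat[sdY == 0] <- 0                   # constant response: no evidence
  beta[sdY == 0] <- 0
  pRaw <- 2 * pt(-abs(tstat), df)
  betaStd <- unname(beta * sd(predictor) / ifelse(sdY > 0, sdY, Inf))
  structure(list(beta = beta, beta_std = betaStd, tstat = tstat,
                 p_raw = pRaw, df = df,
                 .pres = pres, .yres = yres, n = n, k = ncol(X)),
            class = "AssociationMaps")
}

#' Multiple-testing correction for association maps
#'
#' \code{"maxT"} performs Freedman-Lane-style permutation: the
#' covariate-residualized predictor is permuted, vertex t statistics are
#' recomputed against the covariate-residualized responses, and the
#' family-wise corrected p value at a vertex is the rank of its observed
#' |t| within the permutation distribution of the maximum |t|, with the
#' add-one tie rule p = (1 + #\{perm >= obs\}) / (1 + nPerm).
#' \code{"BH"} is the standard step-up false-discovery-rate control over
#' vertices.
#'
#' @param assoc an \code{"AssociationMaps"} from \code{\link{vertexwiseGLM}}.
#' @param method \code{"maxT"} or \code{"BH"}.
#' @param nPerm number of permutations (>= 100) for maxT.
#' @param seed integer seed for the permutation stream.
#' @param alpha significance level for the mask.
#' @return the input with \code{p_corr}, \code{sig_mask}, \code{method}
#'   and \code{alpha} added.
#' @export
correctMultiplicity <- function(assoc, method = c("maxT", "BH"),
                                nPerm = 1000L, seed = 0L, alpha = 0.05) {
  method <- match.arg(method)
  if (method == "BH") {
    assoc$p_corr <- p.adjust(assoc$p_raw, "BH")
  } else {
    if (nPerm < 100) {
      warning("nPerm < 100: minimum attainable corrected p is ",
              signif(1 / (1 + nPerm), 3))
    }
    set.seed(seed)
    pres <- assoc$.pres
    yres <- assoc$.yres
    n <- assoc$n
    df <- assoc$df
    ## permutation t statistics in one matrix product per batch:
    ## P (nPerm x n) of permuted residualized predictors
    P <- t(replicate(nPerm, pres[sample.int(n)]))
    pp <- rowSums(P^2)
    B <- (P %*% yres) / pp                     # nPerm x V
    y2 <- colSums(yres^2)
    sse <- pmax(outer(rep(1, nPerm), y2) - B^2 * pp, 0)
    Tm <- abs(B) / sqrt(sse / df / pp)
    Tm[!is.finite(Tm)] <- 0
    maxT <- apply(Tm, 1, max)
    obs <- abs(assoc$tstat)
    assoc$p_corr <- (1 + vapply(obs, function(t0) sum(maxT >= t0),
                                numeric(1))) / (1 + nPerm)
  }
  assoc$sig_mask <- assoc$p_corr < alpha
  assoc$method <- method
  assoc$alpha <- alpha
  assoc
}

#' Significance contour on the template mesh
#'
#' Edges of the template whose endpoints disagree in the significance
#' mask: the discrete boundary of the significant region.
#'
#' @param sigMask per-vertex logical mask.
#' @param template a \linkS4class{TemplateMesh}.
#' @return 2-column matrix of vertex index pairs (possibly 0 rows).
#' @export
significanceContour <- function(sigMask, template) {
  if (length(sigMask) != nrow(template@vertices))
    stop("alignment error: mask length != template vertex count")
  e <- meshEdges(template)
  e[xor(sigMask[e[, 1]], sigMask[e[, 2]]), , drop = FALSE]
}

#' Branch-versus-rest shape contrasts
#'
#' For every branch with at least \code{minSize} patients, fits
#' \code{\link{vertexwiseGLM}} with the branch indicator as predictor and
#' the given covariates, then applies multiplicity correction.
#'
#' @param branchLabels integer/factor per-patient branch labels.
#' @param maps patients x vertices matrix.
#' @param covariates adjustment covariates (age/sex/race).
#' @param method,nPerm,seed,alpha passed to
#'   \code{\link{correctMultiplicity}}.
#' @param minSize smallest branch analysed (smaller ones are skipped with
#'   a warning).
#' @return named list of corrected \code{"AssociationMaps"}, one per branch.
#' @export
branchShapeContrast <- function(branchLabels, maps, covariates = NULL,
                                method = "maxT", nPerm = 1000L, seed = 0L,
                                alpha = 0.05, minSize = 5L) {
  lv <- sort(unique(branchLabels))
  if (length(lv) < 2) stop("need at least 2 branches")
  out <- list()
  for (b in lv) {
    ind <- as.numeric(branchLabels == b)
    if (sum(ind) < minSize) {
      warning("branch ", b, " has fewer than ", minSize,
              " patients; skipped")
      next
    }
    a <- vertexwiseGLM(maps, ind, covariates)
    out[[paste0("branch", b)]] <-
      correctMultiplicity(a, method = method, nPerm = nPerm,
                          seed = seed, alpha = alpha)
  }
  out
}
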