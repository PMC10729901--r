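#' @import methods
#' @importFrom stats coef cor dist dexp kmeans kruskal.test chisq.test
#'   fisher.test ks.test lm.fit median na.omit p.adjust pexp pnorm predict pt
#'   qnorm quantile rbinom rexp rnorm runif sd setNames var prcomp glm
#'   binomial rmultinom aggregate complete.cases
#' @importFrom utils head read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData "colData<-" rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Triangulated left-ventricular template surface
#'
#' The shared reference space for all per-vertex maps: a closed, manifold
#' triangulated surface approximating the LV epicardium as a truncated
#' prolate spheroid with a flat basal cap.  Every patient map in a cohort is
#' a scalar field over the vertices of one such template.
#'
#' @slot vertices numeric matrix (nVertices x 3), coordinates in mm; long
#'   axis along z with the apex at z = 0.
#' @slot faces integer matrix (nFaces x 3) of 1-based vertex indices with
#'   consistent outward orientation.
#' @slot region factor of length nVertices with levels
#'   \code{<level>-<sector>} for level in basal/mid/apical and sector in
#'   septal/anterior/lateral/inferior (12 regions).
#' @slot vertexArea numeric, one third of the total area of incident faces
#'   (mm^2); sums to the total surface area.
#' @slot normals numeric matrix (nVertices x 3) of outward unit normals.
#'
#' @exportClass TemplateMesh
setClass("TemplateMesh",
  representation(
    vertices   = "matrix",
    faces      = "matrix",
    region     = "factor",
    vertexArea = "numeric",
    normals    = "matrix"
  )
)

setValidity("TemplateMesh", function(object) {
  msg <- character()
  nv <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  if (length(object@region) != nv) msg <- c(msg, "region length != n vertices")
  if (length(object@vertexArea) != nv) msg <- c(msg, "vertexArea length != n vertices")
  if (any(object@faces < 1L) || any(object@faces > nv))
    msg <- c(msg, "face indices out of range")
  ## manifold closed surface: every undirected edge in exactly two faces,
  ## traversed once in each direction
  e <- rbind(object@faces[, c(1, 2)], object@faces[, c(2, 3)], object@faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(key) != 2L)) msg <- c(msg, "surface is not closed/manifold")
  if (!"basal-septal" %in% levels(object@region) ||
      sum(object@region == "basal-septal") == 0L)
    msg <- c(msg, "basal-septal region is empty")
  ta <- sum(faceAreas(object@vertices, object@faces))
  if (abs(sum(object@vertexArea) - ta) > 1e-6 * ta)
    msg <- c(msg, "vertex areas do not sum to total surface area")
  if (length(msg)) msg else TRUE
})

#' Synthetic HCM shape cohort
#'
#' A \linkS4class{SummarizedExperiment} with vertices as rows and patients as
#' columns.  Assays \code{ED} and \code{ES} hold per-vertex wall thickness
#' (mm) at end diastole and end systole; \code{colData} is the clinical
#' table (age, sex, race, genotype, pgs, hypertension, lvoto,
#' family_history, lge_grade, followup_time, died, and for synthetic cohorts
#' the planted \code{true_branch} and \code{severity}).  The template mesh
#' lives in \code{metadata(x)$template}.
#'
#' @exportClass ShapeCohort
setClass("ShapeCohort", contains = "SummarizedExperiment")

setValidity("ShapeCohort", function(object) {
  msg <- character()
  if (!all(c("ED", "ES") %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays ED and ES are required")
  tpl <- S4Vectors::metadata(object)$template
  if (is.null(tpl) || !is(tpl, "TemplateMesh"))
    msg <- c(msg, "metadata$template must be a TemplateMesh")
  else if (nrow(object) != nrow(tpl@vertices))
    msg <- c(msg, "row count != template vertex count")
  if (any(SummarizedExperiment::assay(object, "ED") <= 0))
    msg <- c(msg, "non-positive wall thickness in ED assay")
  cd <- SummarizedExperiment::colData(object)
  if ("followup_time" %in% colnames(cd) && any(cd$followup_time <= 0))
    msg <- c(msg, "non-positive follow-up time")
  if (length(msg)) msg else TRUE
})

#' Fitted reversed-graph-embedding (DDRtree) model
#'
#' State of the alternating minimisation that jointly learns a 2-D linear
#' projection, latent sample coordinates, latent centers and a spanning tree
#' over the centers.
#'
#' @slot W p x 2 orthonormal feature-to-latent map.
#' @slot Z n x 2 latent sample coordinates (the tree coordinates).
#' @slot Y K x 2 latent centers.
#' @slot edges (K-1) x 2 integer matrix, the spanning tree over centers.
#' @slot R n x K soft assignment matrix; rows sum to 1.
#' @slot params list of hyperparameters (lambda, sigma, gamma, K, maxIter,
#'   tol, seed) and convergence info.
#' @slot objective numeric vector of per-iteration objective values
#'   (non-increasing).
#'
#' @exportClass DDRTreeFit
setClass("DDRTreeFit",
  representation(
    W = "matrix", Z = "matrix", Y = "matrix",
    edges = "matrix", R = "matrix",
    params = "list", objective = "numeric"
  )
)

setValidity("DDRTreeFit", function(object) {
  msg <- character()
  K <- nrow(object@Y)
  if (nrow(object@edges) != K - 1L) msg <- c(msg, "tree must have K-1 edges")
  if (!isConnectedTree(object@edges, K)) msg <- c(msg, "edges are not a spanning tree")
  if (max(abs(rowSums(object@R) - 1)) > 1e-9) msg <- c(msg, "R rows must sum to 1")
  if (max(abs(crossprod(object@W) - diag(2))) > 1e-8)
    msg <- c(msg, "W is not orthonormal")
  d <- diff(object@objective)
  if (length(d) && any(d > 1e-7 * max(1, abs(object@objective[1]))))
    msg <- c(msg, "objective trace increased")
  if (length(msg)) msg else TRUE
})

#' Branch assignment of patients on a fitted morphology tree
#'
#' @slot branch integer vector, per-patient branch id (contiguous from 1;
#'   the highest id is the undifferentiated core when \code{hasCore}).
#' @slot coords n x 2 matrix of per-patient tree coordinates.
#' @slot centerBranch integer vector, branch id of every latent center.
#' @slot branchPoints integer vector of center indices with tree degree >= 3.
#' @slot hasCore logical, whether an undifferentiated core branch exists.
#'
#' @exportClass BranchAssignment
setClass("BranchAssignment",
  representation(
    branch = "integer", coords = "matrix",
    centerBranch = "integer", branchPoints = "integer",
    hasCore = "logical"
  )
)

setValidity("BranchAssignment", function(object) {
  msg <- character()
  if (nrow(object@coords) != length(object@branch))
    msg <- c(msg, "coords/branch length mismatch")
  b <- sort(unique(object@centerBranch))
  if (!identical(b, seq_along(b))) msg <- c(msg, "branch ids not contiguous from 1")
  if (any(!object@branch %in% b)) msg <- c(msg, "patient branch id outside center branches")
  if (length(msg)) msg else TRUE
})
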