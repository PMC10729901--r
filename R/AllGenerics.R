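#' @rdname ShapeCohort-class
#' @param x a \linkS4class{ShapeCohort}
#' @export
setGeneric("templateMesh", function(x) standardGeneric("templateMesh"))

#' @rdname ShapeCohort-class
#' @param phase cardiac phase, \code{"ED"} or \code{"ES"}
#' @export
setGeneric("thicknessMaps", function(x, phase = c("ED", "ES"))
  standardGeneric("thicknessMaps"))

#' @rdname ShapeCohort-class
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' @rdname DDRTreeFit-class
#' @param x a fitted object
#' @export
setGeneric("treeCoordinates", function(x) standardGeneric("treeCoordinates"))

#' @rdname BranchAssignment-class
#' @export
setGeneric("branchLabels", function(x) standardGeneric("branchLabels"))

#' @rdname BranchAssignment-class
#' @export
setGeneric("branchCounts", function(x) standardGeneric("branchCounts"))

setMethod("templateMesh", "ShapeCohort", function(x)
  S4Vectors::metadata(x)$template)

setMethod("thicknessMaps", "ShapeCohort", function(x, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  ## patients x vertices orientation, the shape all statistics work on
  t(SummarizedExperiment::assay(x, phase))
})

setMethod("clinicalTable", "ShapeCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

setMethod("treeCoordinates", "DDRTreeFit", function(x) x@Z)
setMethod("treeCoordinates", "BranchAssignment", function(x) x@coords)

setMethod("branchLabels", "BranchAssignment", function(x) x@branch)

setMethod("branchCounts", "BranchAssignment", function(x) {
  tab <- table(factor(x@branch, levels = sort(unique(x@centerBranch))))
  names(tab) <- branchNames(x)
  tab
})

#' @rdname BranchAssignment-class
#' @param x a \linkS4class{BranchAssignment}
#' @export
branchNames <- function(x) {
  ids <- sort(unique(x@centerBranch))
  nm <- paste0("branch", ids)
  if (x@hasCore) nm[length(nm)] <- "core"
  nm
}

setMethod("show", "TemplateMesh", function(object) {
  cat("TemplateMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces\n")
  cat("  surface area:", round(sum(object@vertexArea), 1), "mm^2;",
      "regions:", nlevels(object@region), "\n")
})

setMethod("show", "ShapeCohort", function(object) {
  cat("ShapeCohort:", ncol(object), "patients,", nrow(object),
      "vertices; phases:", paste(SummarizedExperiment::assayNames(object),
      collapse = ", "), "\n")
  g <- SummarizedExperiment::colData(object)$genotype
  if (!is.null(g)) {
    tab <- table(g, useNA = "no")
    cat("  genotype:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "DDRTreeFit", function(object) {
  cat("DDRTreeFit:", nrow(object@Z), "samples,", nrow(object@Y),
      "centers,", nrow(object@edges), "tree edges\n")
  cat("  converged:", isTRUE(object@params$converged), "after",
      length(object@objective), "iterations; final objective",
      format(object@objective[length(object@objective)], digits = 6), "\n")
})

setMethod("show", "BranchAssignment", function(object) {
  tab <- branchCounts(object)
  cat("BranchAssignment:", length(object@branch), "patients in",
      length(tab), "branches\n")
  cat(" ", paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})
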