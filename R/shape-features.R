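## Global CMR-style metrics from per-vertex maps, covariate residualization
## and printed-style cohort summary tables.

#' Left-ventricular mass from a thickness map
#'
#' Myocardial volume is the surface integral of wall thickness,
#' discretized as \code{sum(vertexArea * thickness)}; mass uses the
#' standard myocardial density convention of 1.05 g/mL.
#'
#' @param template a \linkS4class{TemplateMesh}.
#' @param thickness per-vertex wall thickness in mm.
#' @param density myocardial density in g/mL.
#' @return mass in grams.
#' @export
lvMass <- function(template, thickness, density = 1.05) {
  if (length(thickness) != nrow(template@vertices))
    stop("alignment error: thickness length != template vertex count")
  density * sum(template@vertexArea * thickness) / 1000
}

#' Global metrics for every patient in a cohort
#'
#' Cavity volumes are obtained by offsetting the epicardial template
#' inward along the vertex normals by the local wall thickness and taking
#' the enclosed volume of the resulting endocardial surface (EDV at end
#' diastole, ESV at end systole).
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @param density myocardial density in g/mL.
#' @return data.frame with lv_mass (g), edv, esv, stroke_volume (mL),
#'   mass_volume_ratio (g/mL) and max_wall_thickness (mm) per patient.
#' @export
globalMetrics <- function(cohort, density = 1.05) {
  tpl <- templateMesh(cohort)
  ed <- thicknessMaps(cohort, "ED")
  es <- thicknessMaps(cohort, "ES")
  cavity <- function(thk) {
    v <- tpl@vertices - tpl@normals * thk
    enclosedVolume(v, tpl@faces)
  }
  edv <- apply(ed, 1, cavity)
  esv <- apply(es, 1, cavity)
  mass <- apply(ed, 1, function(t) lvMass(tpl, t, density))
  data.frame(id = colnames(cohort), lv_mass = mass, edv = edv, esv = esv,
             stroke_volume = edv - esv, mass_volume_ratio = mass / edv,
             max_wall_thickness = apply(ed, 1, max), row.names = NULL)
}

#' Residualize vertex maps against age and sex
#'
#' Per-vertex ordinary least squares of thickness on [1, age, sex]; since
#' the design is shared across vertices the fit is a single multi-response
#' solve.  The returned object stores the development-cohort coefficients
#' so the identical adjustment can be applied to external patients with
#' \code{\link{adjustMaps}} (no refitting on external data).
#'
#' @param maps patients x vertices matrix.
#' @param covariates data.frame with \code{age} (numeric) and \code{sex}
#'   (factor or character; reference level female).
#' @return list of class \code{"MapAdjustment"} with \code{residuals}
#'   (patients x vertices), \code{coefficients} (3 x vertices) and the
#'   design description.
#' @export
residualizeMaps <- function(maps, covariates) {
  maps <- as.matrix(maps)
  if (nrow(maps) != nrow(covariates))
    stop("alignment error: maps and covariates differ in patient count")
  X <- adjustmentDesign(covariates)
  if (nrow(maps) < ncol(X) + 3)
    stop("need at least 3 more patients than covariates")
  qrX <- qr(X)
  coefs <- matrix(0, ncol(X), ncol(maps),
                  dimnames = list(colnames(X), colnames(maps)))
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("rank-deficient adjustment design; coefficient(s) set to 0 for: ",
            paste(dropped, collapse = ", "))
    coefs[keep, ] <- qr.coef(qr(X[, keep, drop = FALSE]), maps)
  } else {
    coefs[, ] <- qr.coef(qrX, maps)
  }
  res <- maps - X %*% coefs
  structure(list(residuals = res, coefficients = coefs),
            class = "MapAdjustment")
}

adjustmentDesign <- function(covariates) {
  sex <- covariates$sex
  male <- if (is.numeric(sex)) sex else as.numeric(sex %in% c("M", "male", "Male"))
  cbind(`(Intercept)` = 1, age = covariates$age, sexM = male)
}

#' Apply a development-cohort adjustment to new maps
#'
#' @param adjustment a \code{"MapAdjustment"} from
#'   \code{\link{residualizeMaps}}.
#' @param maps patients x vertices matrix for the new patients.
#' @param covariates their age/sex table.
#' @return adjusted (residual) maps.
#' @export
adjustMaps <- function(adjustment, maps, covariates) {
  X <- adjustmentDesign(covariates)
  as.matrix(maps) - X %*% adjustment$coefficients
}

roundHalfAway <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Cohort summary with printed-style percentages
#'
#' Counts and one-decimal percentages (rounded half away from zero) by
#' genotype, deaths and death percentages by genotype, overall mortality
#' over the full cohort, and median/IQR age by genotype.  Genotype
#' percentages are computed over the classified subtotal (patients with a
#' missing genotype enter only the overall denominator).
#'
#' @param cohort a \linkS4class{ShapeCohort} or data.frame with
#'   \code{genotype} and (optionally) \code{died} and \code{age}.
#' @return list with \code{n}, \code{genotype} (count/percent table),
#'   \code{mortality} (deaths/percent by genotype), \code{overall_mortality_pct}
#'   and \code{age} (median/IQR by genotype).
#' @export
cohortSummary <- function(cohort) {
  clin <- if (is(cohort, "ShapeCohort")) clinicalTable(cohort) else cohort
  if (nrow(clin) == 0) stop("empty cohort")
  g <- factor(clin$genotype, levels = GENOTYPES)
  counts <- table(g)
  gtab <- data.frame(genotype = names(counts), n = as.integer(counts),
                     pct = roundHalfAway(100 * as.integer(counts) /
                                           sum(counts)), row.names = NULL)
  out <- list(n = nrow(clin), genotype = gtab)
  if (!is.null(clin$died)) {
    d <- tapply(clin$died, g, sum)
    d[is.na(d)] <- 0L
    out$mortality <- data.frame(genotype = names(counts),
                                deaths = as.integer(d),
                                pct = roundHalfAway(100 * as.integer(d) /
                                                      as.integer(counts)),
                                row.names = NULL)
    out$overall_mortality_pct <-
      roundHalfAway(100 * sum(clin$died, na.rm = TRUE) / nrow(clin))
  }
  if (!is.null(clin$age)) {
    out$age <- do.call(rbind, lapply(levels(g), function(lv) {
      a <- clin$age[!is.na(g) & g == lv]
      data.frame(genotype = lv, median = median(a),
                 q1 = unname(quantile(a, 0.25)), q3 = unname(quantile(a, 0.75)))
    }))
  }
  out
}
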