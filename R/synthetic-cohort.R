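## Seeded synthetic HCM cohorts with the statistical structure the
## downstream analyses assume: genotype-dependent regional wall-thickness
## effects (P/LP carriers thicker in the basal septum, thinner elsewhere),
## four branch archetypes plus an undifferentiated core with continuous
## severity gradients, genotype-conditional polygenic scores (higher in
## genotype-negative patients) and genotype-dependent mortality.

GENOTYPES <- c("SARC-NEG", "SARC-VUS", "SARC-P/LP")

#' Configuration for the synthetic cohort generator
#'
#' Returns a validated configuration list.  Defaults encode the study
#' conditions the generator is meant to emulate: 436 patients with genotype
#' mix 66.0/9.4/24.6% (NEG/VUS/P-LP), 71.1% men, 80.1% European ancestry,
#' genotype-specific median ages (62/61/49 years), a P/LP effect field of
#' +3 mm in the basal septum and -1 mm elsewhere, four morphological branch
#' archetypes plus an undifferentiated core, polygenic score shifted higher
#' in genotype-negative patients, and a planted mortality hazard ratio of
#' 2.66 for P/LP versus genotype-negative carriers.
#'
#' @param nPatients cohort size.
#' @param nVertices template mesh resolution (>= 100).
#' @param genotypeProbs named simplex over SARC-NEG / SARC-VUS / SARC-P-LP.
#' @param effectSpec per-genotype region offsets, each a numeric
#'   \code{c(basalSeptal=, elsewhere=)} in mm.
#' @param archetypes list of branch archetypes; each has \code{name},
#'   \code{weight} and \code{field}, a function of (region, zrel) returning
#'   a per-vertex severity-gradient field in mm.
#' @param baselineMm baseline wall thickness in mm.
#' @param baselineSeptalMm additional baseline septal thickness in mm.
#' @param noiseSd per-vertex Gaussian noise SD in mm (before smoothing).
#' @param smoothingPasses number of neighbour-averaging smoothing passes.
#' @param covariateModel age/sex/race distributions and per-vertex
#'   thickness slopes (mm per year, mm for male sex).
#' @param pgsModel genotype-conditional mean/sd of the standardized
#'   polygenic score.
#' @param hazardModel \code{baseRate} (events/year for SARC-NEG),
#'   \code{logHR} per genotype, \code{censoring} = target censored fraction
#'   in [0, 1).
#' @param systolicThickeningMm mean additive systolic thickening in mm.
#' @param seed integer seed.
#' @return a list of class \code{"SyntheticCohortConfig"}.
#' @export
cohortConfig <- function(nPatients = 436L,
                         nVertices = 1000L,
                         genotypeProbs = c("SARC-NEG" = 0.66,
                                           "SARC-VUS" = 0.094,
                                           "SARC-P/LP" = 0.246),
                         effectSpec = list(
                           "SARC-NEG"  = c(basalSeptal = 0,   elsewhere = 0),
                           "SARC-VUS"  = c(basalSeptal = 1,   elsewhere = -0.3),
                           "SARC-P/LP" = c(basalSeptal = 3,   elsewhere = -1)),
                         archetypes = defaultArchetypes(),
                         baselineMm = 9,
                         baselineSeptalMm = 1,
                         noiseSd = 1,
                         smoothingPasses = 10L,
                         covariateModel = list(
                           ageMean = c("SARC-NEG" = 62, "SARC-VUS" = 61,
                                       "SARC-P/LP" = 49),
                           ageSd = 12,
                           pMale = 0.711,
                           raceProbs = c(European = 0.801, Asian = 0.10,
                                         Other = 0.099),
                           slopes = c(age = 0.02, male = 0.8)),
                         pgsModel = list(
                           mean = c("SARC-NEG" = 0.3, "SARC-VUS" = 0,
                                    "SARC-P/LP" = -0.3),
                           sd = c("SARC-NEG" = 1, "SARC-VUS" = 1,
                                  "SARC-P/LP" = 1)),
                         hazardModel = list(
                           baseRate = 0.018,
                           logHR = c("SARC-NEG" = 0, "SARC-VUS" = 0.18,
                                     "SARC-P/LP" = log(2.66)),
                           censoring = 0.8),
                         systolicThickeningMm = 2.5,
                         seed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients),
              nVertices = as.integer(nVertices),
              genotypeProbs = genotypeProbs, effectSpec = effectSpec,
              archetypes = archetypes, baselineMm = baselineMm,
              baselineSeptalMm = baselineSeptalMm, noiseSd = noiseSd,
              smoothingPasses = as.integer(smoothingPasses),
              covariateModel = covariateModel, pgsModel = pgsModel,
              hazardModel = hazardModel,
              systolicThickeningMm = systolicThickeningMm,
              seed = as.integer(seed))
  class(cfg) <- "SyntheticCohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  if (cfg$nVertices < 100L)
    stop("invalid config: nVertices must be >= 100")
  if (cfg$nPatients < 1L)
    stop("invalid config: nPatients must be positive")
  p <- cfg$genotypeProbs
  if (!identical(sort(names(p)), sort(GENOTYPES)))
    stop("invalid config: genotypeProbs must be named over ",
         paste(GENOTYPES, collapse = ", "))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("invalid config: genotypeProbs must be a simplex (sum to 1)")
  if (cfg$noiseSd < 0) stop("invalid config: noiseSd must be >= 0")
  w <- vapply(cfg$archetypes, `[[`, numeric(1), "weight")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("invalid config: archetype weights must be a simplex")
  h <- cfg$hazardModel
  if (h$baseRate <= 0) stop("invalid config: hazard baseRate must be > 0")
  if (h$censoring < 0 || h$censoring >= 1)
    stop("invalid config: censoring must be in [0, 1)")
  invisible(TRUE)
}

#' Default branch archetypes
#'
#' Four morphological archetypes plus an undifferentiated core (zero
#' field), qualitatively following the branch phenotypes the taxonomy is
#' designed to resolve: (1) mid-to-apical hypertrophy with hypertension,
#' (2) diffuse hypertrophy with basal asymmetry and outflow-tract
#' obstruction, (3) isolated basal hypertrophy, (4) mild diffuse
#' hypertrophy enriched for familial sarcomeric disease.  Fields are in mm
#' at severity 1; per-patient severity scales them continuously.
#'
#' @return list of archetype definitions.
#' @export
defaultArchetypes <- function() {
  lev <- function(region) sub("-.*", "", as.character(region))
  sec <- function(region) sub(".*-", "", as.character(region))
  list(
    list(name = "branch1", weight = 0.20,
         field = function(region, zrel)
           4.5 * (lev(region) %in% c("mid", "apical")),
         hypertension = 0.70, lvoto = 0.20, famHist = 0.20),
    list(name = "branch2", weight = 0.20,
         field = function(region, zrel)
           2.0 + 2.5 * (lev(region) == "basal" & sec(region) == "septal"),
         hypertension = 0.40, lvoto = 0.70, famHist = 0.25),
    list(name = "branch3", weight = 0.20,
         field = function(region, zrel) 4.0 * (lev(region) == "basal"),
         hypertension = 0.40, lvoto = 0.25, famHist = 0.20),
    list(name = "branch4", weight = 0.20,
         field = function(region, zrel) rep(1.2, length(region)),
         hypertension = 0.20, lvoto = 0.10, famHist = 0.55),
    list(name = "core", weight = 0.20,
         field = function(region, zrel) rep(0, length(region)),
         hypertension = 0.35, lvoto = 0.20, famHist = 0.25)
  )
}

## per-genotype per-vertex mean offset fields from a region spec (or pass a
## precomputed nVertices x 3 matrix through unchanged)
makeEffectFields <- function(template, effectSpec) {
  if (is.matrix(effectSpec)) return(effectSpec)
  bs <- template@region == "basal-septal"
  vapply(GENOTYPES, function(g) {
    e <- effectSpec[[g]]
    ifelse(bs, e[["basalSeptal"]], e[["elsewhere"]])
  }, numeric(nrow(template@vertices)))
}

## white Gaussian per-vertex noise smoothed by k neighbour-averaging passes;
## rows = patients
smoothedNoise <- function(n, template, sd, passes) {
  if (sd == 0) return(matrix(0, n, nrow(template@vertices)))
  M <- matrix(rnorm(n * nrow(template@vertices), 0, sd),
              nrow(template@vertices), n)
  S <- smoothingOperator(template)
  for (i in seq_len(passes)) M <- S %*% M
  t(as.matrix(M))
}

#' Simulate a synthetic HCM shape cohort
#'
#' Draws a seeded cohort on a shared template mesh.  Per-patient ED wall
#' thickness is baseline + covariate slopes x covariates + genotype effect
#' field + archetype severity x archetype field + spatially smoothed
#' Gaussian noise, clipped to >= 1 mm; the ES map adds a systolic
#' thickening field.  Polygenic score is drawn conditional on genotype;
#' hypertension, outflow-tract obstruction and family history are enriched
#' by archetype; follow-up and vital status come from
#' \code{\link{simulateSurvival}}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param template optional \linkS4class{TemplateMesh}; built from
#'   \code{config$nVertices} when missing.
#' @param survival logical, also simulate follow-up/death (default TRUE).
#' @return a \linkS4class{ShapeCohort}.
#' @examples
#' coh <- simulateCohort(cohortConfig(nPatients = 40, nVertices = 200))
#' coh
#' @export
simulateCohort <- function(config = cohortConfig(), template = NULL,
                           survival = TRUE) {
  validateCohortConfig(config)
  set.seed(config$seed)
  if (is.null(template)) template <- buildTemplateMesh(config$nVertices)
  n <- config$nPatients
  nv <- nrow(template@vertices)
  region <- template@region
  zrel <- template@vertices[, 3] / max(template@vertices[, 3])

  genotype <- sample(GENOTYPES, n, replace = TRUE,
                     prob = config$genotypeProbs[GENOTYPES])
  cm <- config$covariateModel
  age <- pmin(90, pmax(18, rnorm(n, cm$ageMean[genotype], cm$ageSd)))
  sex <- ifelse(runif(n) < cm$pMale, "M", "F")
  race <- sample(names(cm$raceProbs), n, replace = TRUE, prob = cm$raceProbs)

  arch <- config$archetypes
  aIdx <- sample(seq_along(arch), n, replace = TRUE,
                 prob = vapply(arch, `[[`, numeric(1), "weight"))
  aName <- vapply(arch, `[[`, character(1), "name")[aIdx]
  severity <- ifelse(aName == "core", 0, runif(n))

  baseline <- config$baselineMm +
    config$baselineSeptalMm * (sub(".*-", "", as.character(region)) == "septal")
  eff <- makeEffectFields(template, config$effectSpec)
  archFields <- vapply(arch, function(a) a$field(region, zrel), numeric(nv))

  ed <- matrix(baseline, n, nv, byrow = TRUE)
  ed <- ed + outer(cm$slopes[["age"]] * (age - mean(cm$ageMean)) +
                   cm$slopes[["male"]] * (sex == "M"), rep(1, nv))
  ed <- ed + t(eff[, match(genotype, GENOTYPES), drop = FALSE])
  ed <- ed + severity * t(archFields[, aIdx, drop = FALSE])
  ed <- ed + smoothedNoise(n, template, config$noiseSd, config$smoothingPasses)
  ed <- pmax(ed, 1)

  thick <- config$systolicThickeningMm * (1 + 0.3 * severity)
  es <- ed + outer(thick, 0.7 + 0.6 * (1 - zrel)) +
    smoothedNoise(n, template, config$noiseSd / 2, config$smoothingPasses)
  es <- pmax(es, 1)

  pm <- config$pgsModel
  pgs <- rnorm(n, pm$mean[genotype], pm$sd[genotype])
  pHyp <- vapply(arch, function(a) a$hypertension, numeric(1))[aIdx]
  pLvo <- vapply(arch, function(a) a$lvoto, numeric(1))[aIdx]
  pFam <- vapply(arch, function(a) a$famHist, numeric(1))[aIdx] +
    0.2 * (genotype == "SARC-P/LP")
  clin <- data.frame(
    id = sprintf("pat%04d", seq_len(n)),
    age = age, sex = factor(sex, c("F", "M")),
    race = factor(race, names(cm$raceProbs)),
    genotype = factor(genotype, GENOTYPES),
    pgs = pgs,
    hypertension = runif(n) < pHyp,
    lvoto = runif(n) < pLvo,
    family_history = runif(n) < pmin(pFam, 0.95),
    lge_grade = ordered(1L + findInterval(pmin(severity +
      0.25 * rnorm(n), 0.999), c(0.35, 0.6, 0.85)), levels = 1:4),
    true_branch = factor(aName, vapply(arch, `[[`, character(1), "name")),
    severity = severity,
    stringsAsFactors = FALSE)

  dimnames(ed) <- dimnames(es) <- list(clin$id, NULL)
  cohort <- new("ShapeCohort", SummarizedExperiment::SummarizedExperiment(
    assays = list(ED = t(ed), ES = t(es)),
    colData = S4Vectors::DataFrame(clin, row.names = clin$id),
    rowData = S4Vectors::DataFrame(region = region),
    metadata = list(template = template, config = config)))
  if (survival)
    cohort <- simulateSurvival(cohort, config$hazardModel,
                               seed = config$seed + 1L)
  cohort
}

#' Simulate genotype-dependent survival
#'
#' Event times are exponential with per-genotype rate
#' \code{baseRate * exp(logHR[genotype])}; censoring is an independent
#' exponential whose rate is chosen so the expected censored fraction
#' equals \code{hazardModel$censoring} (0 disables censoring);
#' \code{died} marks events occurring before the censoring time.
#'
#' @param cohort a \linkS4class{ShapeCohort} or a data.frame with a
#'   \code{genotype} column.
#' @param hazardModel list with \code{baseRate}, \code{logHR} (named per
#'   genotype) and \code{censoring} in [0, 1).
#' @param seed integer seed.
#' @return the input with \code{followup_time} (years) and \code{died}
#'   (logical) columns added/replaced.
#' @export
simulateSurvival <- function(cohort, hazardModel, seed = 1L) {
  if (is(cohort, "ShapeCohort")) {
    cd <- SummarizedExperiment::colData(cohort)
    res <- simulateSurvival(as.data.frame(cd), hazardModel, seed)
    cd$followup_time <- res$followup_time
    cd$died <- res$died
    SummarizedExperiment::colData(cohort) <- cd
    return(cohort)
  }
  h <- hazardModel
  if (h$baseRate <= 0) stop("invalid config: hazard rates must be > 0")
  if (h$censoring < 0 || h$censoring >= 1)
    stop("invalid config: censoring must be in [0, 1)")
  set.seed(seed)
  g <- as.character(cohort$genotype)
  rate <- h$baseRate * exp(unname(h$logHR[g]))
  tEvent <- rexp(nrow(cohort), rate)
  if (h$censoring > 0) {
    ## exponential censoring rate giving the target censored fraction under
    ## the cohort-average event rate: P(censor first) = mu / (mu + rate)
    mu <- h$censoring * mean(rate) / (1 - h$censoring)
    tCens <- rexp(nrow(cohort), mu)
  } else tCens <- rep(Inf, nrow(cohort))
  cohort$followup_time <- pmin(tEvent, tCens)
  cohort$died <- tEvent <= tCens
  cohort
}
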