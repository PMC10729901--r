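test_that("config validation rejects degenerate inputs", {
  expect_error(cohortConfig(nVertices = 50), "nVertices")
  expect_error(cohortConfig(genotypeProbs = c("SARC-NEG" = 0.5,
    "SARC-VUS" = 0.2, "SARC-P/LP" = 0.2)), "simplex")
  expect_error(cohortConfig(noiseSd = -1), "noiseSd")
  expect_error(cohortConfig(hazardModel = list(baseRate = 0.02,
    logHR = c("SARC-NEG" = 0, "SARC-VUS" = 0, "SARC-P/LP" = 0),
    censoring = 1)), "censoring")
})

test_that("zero noise and zero effects reproduce the baseline field exactly", {
  cfg <- cohortConfig(nPatients = 10, nVertices = 150, noiseSd = 0,
    effectSpec = list("SARC-NEG" = c(basalSeptal = 0, elsewhere = 0),
                      "SARC-VUS" = c(basalSeptal = 0, elsewhere = 0),
                      "SARC-P/LP" = c(basalSeptal = 0, elsewhere = 0)),
    archetypes = list(list(name = "core", weight = 1,
      field = function(region, zrel) rep(0, length(region)),
      hypertension = 0.3, lvoto = 0.2, famHist = 0.2)),
    covariateModel = list(ageMean = c("SARC-NEG" = 60, "SARC-VUS" = 60,
      "SARC-P/LP" = 60), ageSd = 10, pMale = 0.5,
      raceProbs = c(European = 1), slopes = c(age = 0, male = 0)),
    seed = 2)
  coh <- simulateCohort(cfg)
  tpl <- templateMesh(coh)
  baseline <- 9 + 1 * (sub(".*-", "", as.character(tpl@region)) == "septal")
  maps <- thicknessMaps(coh, "ED")
  for (i in seq_len(nrow(maps)))
    expect_equal(unname(maps[i, ]), baseline)
})

test_that("planted genotype effect field is recovered by group means", {
  cfg <- cohortConfig(nPatients = 400, nVertices = 200,
    genotypeProbs = c("SARC-NEG" = 0.5, "SARC-VUS" = 0, "SARC-P/LP" = 0.5),
    archetypes = list(list(name = "core", weight = 1,
      field = function(region, zrel) rep(0, length(region)),
      hypertension = 0.3, lvoto = 0.2, famHist = 0.2)),
    covariateModel = list(ageMean = c("SARC-NEG" = 60, "SARC-VUS" = 60,
      "SARC-P/LP" = 60), ageSd = 10, pMale = 0.5,
      raceProbs = c(European = 1), slopes = c(age = 0, male = 0)),
    seed = 11)
  coh <- simulateCohort(cfg)
  tpl <- templateMesh(coh)
  clin <- clinicalTable(coh)
  maps <- thicknessMaps(coh, "ED")
  plp <- clin$genotype == "SARC-P/LP"
  diffMap <- colMeans(maps[plp, ]) - colMeans(maps[!plp, ])
  planted <- ifelse(tpl@region == "basal-septal", 3, -1)
  sem <- sqrt(apply(maps[plp, ], 2, var) / sum(plp) +
              apply(maps[!plp, ], 2, var) / sum(!plp))
  z <- abs(diffMap - planted) / sem
  # per-vertex 2*SEM holds for ~95% of vertices by construction
  expect_gte(mean(z <= 2), 0.90)
  expect_true(all(z <= 4.5))
})

test_that("genotype draws match the configured mix at the study size", {
  coh <- simulateCohort(cohortConfig(nPatients = 436, nVertices = 150,
                                     seed = 1))
  counts <- table(clinicalTable(coh)$genotype)
  probs <- c(0.66, 0.094, 0.246)
  for (i in 1:3) {
    lo <- qbinom(0.005, 436, probs[i])
    hi <- qbinom(0.995, 436, probs[i])
    expect_gte(counts[i], lo)
    expect_lte(counts[i], hi)
  }
})

test_that("generation is deterministic under a fixed config and seed", {
  a <- quickCohort(n = 25, nv = 150, seed = 9)
  b <- quickCohort(n = 25, nv = 150, seed = 9)
  expect_identical(SummarizedExperiment::assay(a, "ED"),
                   SummarizedExperiment::assay(b, "ED"))
  expect_identical(clinicalTable(a), clinicalTable(b))
})

test_that("generated cohorts never contain invalid thickness or follow-up", {
  coh <- quickCohort(n = 300, nv = 150, seed = 13)
  expect_true(all(SummarizedExperiment::assay(coh, "ED") >= 1))
  expect_true(all(SummarizedExperiment::assay(coh, "ES") >= 1))
  clin <- clinicalTable(coh)
  expect_true(all(clin$followup_time > 0))
  expect_true(validObject(coh))
})

test_that("survival generator respects planted hazards", {
  clin <- data.frame(genotype = rep(c("SARC-NEG", "SARC-P/LP"), each = 1000))
  # null contrast: equal death proportions
  h0 <- list(baseRate = 0.03, logHR = c("SARC-NEG" = 0, "SARC-VUS" = 0,
             "SARC-P/LP" = 0), censoring = 0.5)
  s0 <- simulateSurvival(clin, h0, seed = 5)
  p <- tapply(s0$died, s0$genotype, mean)
  expect_lt(abs(p[1] - p[2]), 0.06)
  # planted HR 2.66 recovered by a Cox fit
  h1 <- list(baseRate = 0.02, logHR = c("SARC-NEG" = 0, "SARC-VUS" = 0,
             "SARC-P/LP" = log(2.66)), censoring = 0.6)
  s1 <- simulateSurvival(clin, h1, seed = 3)
  fit <- survival::coxph(survival::Surv(followup_time, died) ~ genotype,
                         data = s1)
  expect_lt(abs(unname(coef(fit)) - log(2.66)), 0.15)
  # censoring -> 1 leaves almost everyone alive
  h2 <- list(baseRate = 0.02, logHR = h0$logHR, censoring = 0.999)
  s2 <- simulateSurvival(clin, h2, seed = 7)
  expect_lt(mean(s2$died), 0.01)
  expect_true(all(s2$followup_time > 0))
})

test_that("planted field means converge at large n", {
  # planted-truth recoverability: with effects and slopes off, the
  # per-vertex mean converges to the baseline field within 3*SEM
  cfg <- cohortConfig(nPatients = 5000, nVertices = 120, noiseSd = 0.8,
    effectSpec = list("SARC-NEG" = c(basalSeptal = 0, elsewhere = 0),
                      "SARC-VUS" = c(basalSeptal = 0, elsewhere = 0),
                      "SARC-P/LP" = c(basalSeptal = 0, elsewhere = 0)),
    archetypes = list(list(name = "core", weight = 1,
      field = function(region, zrel) rep(0, length(region)),
      hypertension = 0.3, lvoto = 0.2, famHist = 0.2)),
    covariateModel = list(ageMean = c("SARC-NEG" = 60, "SARC-VUS" = 60,
      "SARC-P/LP" = 60), ageSd = 10, pMale = 0.5,
      raceProbs = c(European = 1), slopes = c(age = 0, male = 0)),
    seed = 21)
  coh <- simulateCohort(cfg, survival = FALSE)
  tpl <- templateMesh(coh)
  maps <- thicknessMaps(coh, "ED")
  baseline <- 9 + 1 * (sub(".*-", "", as.character(tpl@region)) == "septal")
  sem <- apply(maps, 2, sd) / sqrt(nrow(maps))
  expect_gte(mean(abs(colMeans(maps) - baseline) <= 3 * sem), 0.95)
})
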