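test_that("logistic overlays localize a planted axis association", {
  set.seed(1)
  n <- 400
  coords <- matrix(rnorm(2 * n), n, 2)
  outcome <- rbinom(n, 1, plogis(1.5 * coords[, 2]))   # vertical-axis risk
  ov <- overlayLogistic(coords, outcome)
  expect_lt(ov$p_y, 0.001)
  expect_gt(ov$p_x, 0.05)
  expect_true(all(ov$grid$prob > 0 & ov$grid$prob < 1))
  expect_true(all(ov$fitted > 0 & ov$fitted < 1))
  # grid covers all patient coordinates
  expect_true(all(coords[, 1] >= min(ov$grid$x) &
                  coords[, 1] <= max(ov$grid$x)))
  expect_error(overlayLogistic(coords, rep(1, n)), "single class")
})

test_that("logistic overlay p values are calibrated under the null", {
  set.seed(2)
  hits <- replicate(60, {
    coords <- matrix(rnorm(160), 80, 2)
    ov <- overlayLogistic(coords, rbinom(80, 1, 0.4))
    c(ov$p_x < 0.05, ov$p_y < 0.05)
  })
  rate <- mean(hits)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 120))
})

test_that("separation triggers the penalized refit", {
  coords <- cbind(c(rep(-2, 20), rep(2, 20)), rnorm(40))
  outcome <- coords[, 1] > 0
  expect_warning(ov <- overlayLogistic(coords, outcome), "separation")
  expect_true(all(is.finite(ov$coefficients)))
})

test_that("branch odds ratios recover planted prevalences", {
  set.seed(6)
  br <- rep(c(1, 2), each = 150)
  carrierNull <- runif(300) < 0.3
  orN <- branchOddsRatio(br, carrierNull, 2, 1, nBoot = 600, seed = 6)
  expect_gte(orN$or, 0.7)
  expect_lte(orN$or, 1.4)
  set.seed(7)
  br2 <- rep(c(1, 2), each = 100)
  carrier <- c(runif(100) < 0.15, runif(100) < 0.40)
  or2 <- branchOddsRatio(br2, carrier, 2, 1, nBoot = 1000, seed = 7)
  target <- (0.40 / 0.60) / (0.15 / 0.85)
  expect_gt(or2$or, target / 2)
  expect_lt(or2$or, target * 2)
  expect_gt(or2$ci[1], 1)                  # CI excludes 1
  expect_lt(or2$p, 0.05)
})

test_that("zero cells use the continuity correction and are flagged", {
  br <- rep(c(1, 2), each = 30)
  carrier <- c(rep(FALSE, 30), rep(TRUE, 10), rep(FALSE, 20))
  expect_message(or0 <- branchOddsRatio(br, carrier, 2, 1, nBoot = 200,
                                        seed = 1), "correction")
  expect_true(is.finite(or0$or))
  expect_true(or0$corrected)
  expect_error(branchOddsRatio(br, carrier, 2, 9, nBoot = 10), "empty branch")
})

test_that("bootstrap median OR converges to the sample OR", {
  set.seed(8)
  br <- rep(c(1, 2), each = 200)
  carrier <- c(runif(200) < 0.2, runif(200) < 0.45)
  or <- branchOddsRatio(br, carrier, 2, 1, nBoot = 10000, seed = 8)
  expect_equal(or$or, or$observed, tolerance = 0.02)
})

test_that("Cox fits recover planted hazards and demand events", {
  clin <- data.frame(genotype = factor(rep(c("SARC-NEG", "SARC-P/LP"),
                                           each = 1000),
                                       c("SARC-NEG", "SARC-P/LP")))
  h <- list(baseRate = 0.02, logHR = c("SARC-NEG" = 0, "SARC-VUS" = 0,
            "SARC-P/LP" = log(2.66)), censoring = 0.6)
  s <- simulateSurvival(clin, h, seed = 3)
  cx <- coxHazard(s)
  expect_lt(abs(log(unname(cx$hr)) - log(2.66)), 0.15)
  expect_true(cx$ci[1, 1] <= cx$hr & cx$hr <= cx$ci[1, 2])
  expect_gt(cx$phTestP, 0.001)             # PH holds for exponential draws
  few <- s[1:8, ]
  expect_error(coxHazard(few), "10 events")
})

test_that("survival surfaces respond to planted coordinate effects", {
  set.seed(4)
  n <- 500
  coords <- matrix(rnorm(2 * n), n, 2)
  age <- runif(n, 40, 70)
  rate <- 0.03 * exp(0.8 * coords[, 1])    # hazard increases along x
  clin <- data.frame(age = age, followup_time = rexp(n, rate),
                     died = TRUE)
  cens <- rexp(n, 0.03)
  clin$died <- clin$followup_time <= cens
  clin$followup_time <- pmin(clin$followup_time, cens)
  ss <- survivalSurface(coords, clin, gridN = 20)
  g <- ss$grid
  # at the central y row, survival decreases monotonically in x
  yMid <- unique(g$y)[10]
  row <- g[g$y == yMid, ]
  expect_true(all(diff(row$prob[order(row$x)]) <= 1e-8))
  expect_true(all(g$prob >= 0 & g$prob <= 1))
  # evaluation below every observed age gives survival ~ 1
  ss0 <- survivalSurface(coords, clin, evalAge = 10, gridN = 5)
  expect_true(all(ss0$grid$prob > 0.999))
})

test_that("flat hazards give a flat surface", {
  set.seed(5)
  n <- 400
  coords <- matrix(rnorm(2 * n), n, 2)
  clin <- data.frame(age = runif(n, 40, 70),
                     followup_time = rexp(n, 0.05), died = TRUE)
  ss <- survivalSurface(coords, clin, gridN = 10)
  expect_lt(diff(range(ss$grid$prob)), 0.35)   # Monte-Carlo noise only
})

test_that("Kaplan-Meier steps equal hand-computed product limits", {
  # all events: S = 4/5, 3/5, 2/5, 1/5, 0
  clin <- data.frame(followup_time = 1:5, died = TRUE)
  km <- kmCumulativeHazard(clin, rep("a", 5))
  expect_equal(km$curves$surv, c(4, 3, 2, 1, 0) / 5)
  # with one censor at t=2: S(1)=4/5, S(3)=4/5*2/3, S(4)=..*1/2, S(5)=0
  clin2 <- data.frame(followup_time = 1:5,
                      died = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  km2 <- kmCumulativeHazard(clin2, rep("a", 5))
  ev <- km2$curves[km2$curves$nEvent > 0, ]
  expect_equal(ev$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 15, 0))
  # Nelson-Aalen is non-decreasing, KM non-increasing
  expect_true(all(diff(km2$curves$cumhaz) >= 0))
  expect_true(all(diff(km2$curves$surv) <= 0))
})

test_that("censoring-only groups and empty groups are handled", {
  clin <- data.frame(followup_time = runif(20, 1, 5), died = FALSE)
  km <- kmCumulativeHazard(clin, rep("a", 20))
  expect_true(all(km$curves$surv == 1))
  g <- factor(rep("a", 20), levels = c("a", "b"))
  expect_warning(kmCumulativeHazard(clin, g), "dropped")
})

test_that("log-rank p is not anti-conservative for identical groups", {
  set.seed(9)
  ps <- replicate(20, {
    clin <- data.frame(followup_time = rexp(120, 0.1),
                       died = runif(120) < 0.7)
    kmCumulativeHazard(clin, rep(c("a", "b"), each = 60))$logrankP
  })
  expect_lte(sum(ps < 0.05), 4)
})
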