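test_that("vertexwise fit matches an independent lm() solve", {
  set.seed(1)
  n <- 60; v <- 12
  maps <- matrix(rnorm(n * v, 10), n, v)
  pred <- rnorm(n)
  cov <- data.frame(age = runif(n, 30, 80), sex = sample(c("F", "M"), n, TRUE),
                    race = sample(c("Eur", "Asn", "Oth"), n, TRUE))
  a <- vertexwiseGLM(maps, pred, cov)
  for (j in c(1, 5, 12)) {
    fit <- lm(maps[, j] ~ cov$age + cov$sex + cov$race + pred)
    sm <- summary(fit)$coefficients["pred", ]
    expect_equal(a$beta[j], unname(sm["Estimate"]), tolerance = 1e-8)
    expect_equal(a$tstat[j], unname(sm["t value"]), tolerance = 1e-8)
    expect_equal(a$p_raw[j], unname(sm["Pr(>|t|)"]), tolerance = 1e-8)
    expect_equal(a$beta_std[j],
                 unname(sm["Estimate"]) * sd(pred) / sd(maps[, j]),
                 tolerance = 1e-10)
  }
})

test_that("a perfectly predictive vertex gets beta_std 1 and p ~ 0", {
  set.seed(2)
  pred <- rnorm(80)
  maps <- cbind(pred, matrix(rnorm(80 * 4), 80, 4))
  a <- vertexwiseGLM(maps, pred)
  expect_equal(a$beta_std[1], 1, tolerance = 1e-12)
  expect_lt(a$p_raw[1], 1e-12)
})

test_that("raw p values are calibrated under a permuted predictor", {
  set.seed(5)
  n <- 200; v <- 500
  maps <- matrix(rnorm(n * v), n, v)
  pred <- sample(rep(0:1, each = n / 2))
  cov <- data.frame(age = runif(n, 30, 80), sex = sample(c("F", "M"), n, TRUE))
  a <- vertexwiseGLM(maps, pred, cov)
  frac <- mean(a$p_raw < 0.05)
  band <- qbinom(c(0.005, 0.995), v, 0.05) / v
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("design problems raise informative errors", {
  maps <- matrix(rnorm(40), 10, 4)
  pred <- rep(1, 10)          # collinear with intercept
  expect_error(vertexwiseGLM(maps, pred), "collinear")
  expect_error(vertexwiseGLM(maps[1:4, ], rnorm(4)), "rank")
})

test_that("standardized beta is invariant to affine response rescaling", {
  set.seed(6)
  maps <- matrix(rnorm(50 * 8, 10), 50, 8)
  pred <- rnorm(50)
  a1 <- vertexwiseGLM(maps, pred)
  a2 <- vertexwiseGLM(3.7 * maps + 11, pred)
  expect_equal(a1$beta_std, a2$beta_std, tolerance = 1e-10)
  expect_equal(a1$tstat, a2$tstat, tolerance = 1e-10)
})

test_that("multiplicity masks behave at the extremes and are monotone", {
  set.seed(7)
  n <- 60; v <- 40
  maps <- matrix(rep(5, n * v), n, v)     # constant: p_raw = 1 everywhere
  pred <- rnorm(n)
  a <- vertexwiseGLM(maps, pred)
  expect_true(all(a$p_raw == 1))
  expect_false(any(correctMultiplicity(a, "BH")$sig_mask))
  expect_false(any(correctMultiplicity(a, "maxT", nPerm = 150)$sig_mask))
  # monotone in alpha on noisy data with an effect
  maps2 <- matrix(rnorm(n * v), n, v)
  maps2[, 1:5] <- maps2[, 1:5] + pred
  a2 <- vertexwiseGLM(maps2, pred)
  for (m in c("maxT", "BH")) {
    c1 <- correctMultiplicity(a2, m, nPerm = 200, seed = 1, alpha = 0.01)
    c2 <- correctMultiplicity(a2, m, nPerm = 200, seed = 1, alpha = 0.10)
    expect_true(all(c2$sig_mask[c1$sig_mask]))
    expect_true(all(c1$sig_mask == (c1$p_corr < 0.01)))
  }
})

test_that("maxT detects a strong planted regional effect", {
  set.seed(8)
  tpl <- buildTemplateMesh(300)
  n <- 100
  pred <- rep(0:1, each = n / 2)
  planted <- tpl@region == "basal-septal"
  maps <- matrix(rnorm(n * 300), n, 300)
  maps[, planted] <- maps[, planted] + outer(pred, rep(1.2, sum(planted)))
  a <- correctMultiplicity(vertexwiseGLM(maps, pred), "maxT", nPerm = 300,
                           seed = 2)
  expect_gte(mean(a$sig_mask[planted]), 0.9)
  expect_lt(mean(a$sig_mask[!planted]), 0.05)
})

test_that("significance contours are the mask boundary edges", {
  tpl <- buildTemplateMesh(200)
  nv <- nrow(tpl@vertices)
  expect_identical(nrow(significanceContour(rep(FALSE, nv), tpl)), 0L)
  expect_identical(nrow(significanceContour(rep(TRUE, nv), tpl)), 0L)
  mask <- rep(FALSE, nv); mask[57] <- TRUE
  got <- significanceContour(mask, tpl)
  # oracle: enumerate edges incident to vertex 57 from the face list
  e <- rbind(tpl@faces[, c(1, 2)], tpl@faces[, c(2, 3)], tpl@faces[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  inc <- e[e[, 1] == 57 | e[, 2] == 57, , drop = FALSE]
  expect_identical(got[order(got[, 1], got[, 2]), , drop = FALSE],
                   inc[order(inc[, 1], inc[, 2]), , drop = FALSE])
})

test_that("branch contrasts delegate to the vertexwise engine", {
  set.seed(9)
  n <- 60; v <- 50
  maps <- matrix(rnorm(n * v), n, v)
  br <- sample(1:2, n, TRUE)
  cov <- data.frame(age = runif(n, 30, 80))
  got <- branchShapeContrast(br, maps, cov, method = "BH")
  direct <- correctMultiplicity(
    vertexwiseGLM(maps, as.numeric(br == 1), cov), "BH")
  expect_equal(got$branch1$beta, direct$beta)
  expect_equal(got$branch1$p_corr, direct$p_corr)
  # identical morphologies in all branches -> empty masks
  flat <- matrix(rnorm(v), n, v, byrow = TRUE) +
    matrix(rnorm(n * v, 0, 1e-8), n, v)
  g2 <- branchShapeContrast(br, flat, method = "BH")
  expect_false(any(g2$branch1$sig_mask))
  # tiny branches are skipped with a warning
  br3 <- c(rep(1, 57), rep(2, 3))
  expect_warning(g3 <- branchShapeContrast(br3, maps, method = "BH"),
                 "fewer than")
  expect_named(g3, "branch1")
})
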