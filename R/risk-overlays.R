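## Overlays of genetic and survival risk on the learned tree coordinates:
## logistic probability surfaces, branch-level bootstrap odds ratios, Cox
## proportional-hazards models, survival surfaces at median age, and
## Kaplan-Meier / Nelson-Aalen curves.

#' Logistic probability surface over tree coordinates
#'
#' Maximum-likelihood logistic regression of a binary outcome on the two
#' tree coordinates, with per-axis Wald p values and the fitted
#' probability evaluated on a regular grid over the coordinate bounding
#' box.  Complete separation triggers a ridge-penalized refit (tiny
#' penalty) with a warning.
#'
#' @param coords n x 2 tree coordinates.
#' @param outcome logical/0-1 outcome; both classes must be present.
#' @param gridN grid resolution per axis.
#' @return list of class \code{"OverlaySurface"}: coefficients, per-axis p
#'   values, fitted per-patient probabilities, and the grid data.frame
#'   (x, y, prob).
#' @export
overlayLogistic <- function(coords, outcome, gridN = 100L) {
  coords <- as.matrix(coords)
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  df <- data.frame(y = y, x = coords[, 1], yc = coords[, 2])
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x + yc, binomial(), df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged ||
      any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    sep <- TRUE
  if (sep || any(abs(coef(fit)[-1]) > 15)) {
    warning("separation detected; refitting with a small ridge penalty")
    g <- glmnet::glmnet(coords, y, family = "binomial", alpha = 0,
                        lambda = 1e-3)
    cf <- as.numeric(coef(g))
    pv <- c(NA, NA)
  } else {
    cf <- unname(coef(fit))
    pv <- summary(fit)$coefficients[-1, "Pr(>|z|)"]
  }
  eta <- function(x1, x2) cf[1] + cf[2] * x1 + cf[3] * x2
  gx <- seq(min(coords[, 1]), max(coords[, 1]), length.out = gridN)
  gy <- seq(min(coords[, 2]), max(coords[, 2]), length.out = gridN)
  grid <- expand.grid(x = gx, y = gy)
  grid$prob <- stats::plogis(eta(grid$x, grid$y))
  structure(list(type = "logistic", coefficients = cf,
                 p_x = unname(pv[1]), p_y = unname(pv[2]),
                 fitted = stats::plogis(eta(coords[, 1], coords[, 2])),
                 grid = grid, separation = sep),
            class = "OverlaySurface")
}

#' Branch-level bootstrap odds ratio
#'
#' Median odds ratio for carrier status in one branch versus a reference
#' branch, over bootstrap resamples drawn within each branch, with the
#' Haldane-Anscombe 0.5 continuity correction whenever a 2x2 cell is
#' empty.  The p value is a permutation test of OR != 1 (carrier labels
#' permuted across the two branches).
#'
#' @param branchLabels per-patient branch labels.
#' @param carrier logical carrier flags.
#' @param branch,reference the two branch ids to compare.
#' @param nBoot bootstrap resamples.
#' @param seed integer seed.
#' @return list with \code{or} (median), \code{ci} (2.5/97.5 percentiles),
#'   \code{p}, \code{corrected} (whether any resample needed the
#'   continuity correction).
#' @export
branchOddsRatio <- function(branchLabels, carrier, branch, reference,
                            nBoot = 1000L, seed = 0L) {
  inA <- which(branchLabels == branch)
  inR <- which(branchLabels == reference)
  if (!length(inA) || !length(inR)) stop("invalid input: empty branch")
  carrier <- as.logical(carrier)
  orOf <- function(a, r) {
    x <- c(sum(a), sum(!a), sum(r), sum(!r))
    if (any(x == 0)) x <- x + 0.5
    (x[1] / x[2]) / (x[3] / x[4])
  }
  set.seed(seed)
  ors <- vapply(seq_len(nBoot), function(b) {
    orOf(carrier[sample(inA, replace = TRUE)],
         carrier[sample(inR, replace = TRUE)])
  }, numeric(1))
  obs <- orOf(carrier[inA], carrier[inR])
  pool <- c(inA, inR)
  nA <- length(inA)
  perm <- vapply(seq_len(nBoot), function(b) {
    s <- sample(pool)
    orOf(carrier[s[seq_len(nA)]], carrier[s[-seq_len(nA)]])
  }, numeric(1))
  p <- (1 + sum(abs(log(perm)) >= abs(log(obs)))) / (1 + nBoot)
  corrected <- any(c(sum(carrier[inA]), sum(!carrier[inA]),
                     sum(carrier[inR]), sum(!carrier[inR])) == 0)
  if (corrected)
    message("zero cell encountered; Haldane-Anscombe correction applied")
  list(or = median(ors), ci = unname(quantile(ors, c(0.025, 0.975))),
       p = p, observed = obs, corrected = corrected)
}

#' Cox proportional-hazards model for genotype (or any grouping)
#'
#' Partial-likelihood fit with Efron tie handling, Schoenfeld-residual
#' proportional-hazards diagnostic, unadjusted or covariate-adjusted.
#'
#' @param clinical data.frame with \code{followup_time}, \code{died} and
#'   the model variables.
#' @param formulaRHS right-hand side, e.g. \code{"genotype"} or
#'   \code{"genotype + sex + race"}.
#' @return list with \code{hr} (named hazard ratios), \code{ci} (2-col
#'   matrix), \code{p}, \code{phTestP} (global Schoenfeld p), \code{fit}.
#' @export
coxHazard <- function(clinical, formulaRHS = "genotype") {
  if (sum(clinical$died, na.rm = TRUE) < 10)
    stop("invalid input: need at least 10 events")
  f <- stats::as.formula(paste("survival::Surv(followup_time, died) ~",
                               formulaRHS))
  fit <- survival::coxph(f, data = clinical, ties = "efron")
  if (!fit$iter || any(!is.finite(coef(fit))))
    stop("Cox model failed to converge")
  s <- summary(fit)
  zph <- try(survival::cox.zph(fit), silent = TRUE)
  phP <- if (inherits(zph, "try-error")) NA_real_
         else unname(zph$table["GLOBAL", "p"])
  list(hr = s$coefficients[, "exp(coef)"],
       ci = s$conf.int[, c("lower .95", "upper .95"), drop = FALSE],
       p = s$coefficients[, "Pr(>|z|)"],
       phTestP = phP, fit = fit)
}

#' Predicted-survival surface over tree coordinates
#'
#' Cox model on the age scale (entry at age at scan, exit at age +
#' follow-up; left truncation makes "survival at median age" well
#' defined) with the two tree coordinates as covariates.  Returns the
#' predicted survival probability at \code{evalAge} per patient and on a
#' coordinate grid.
#'
#' @param coords n x 2 tree coordinates.
#' @param clinical data.frame with age, followup_time, died.
#' @param evalAge evaluation age; default the cohort median age.
#' @param gridN grid resolution per axis.
#' @return list of class \code{"OverlaySurface"} with \code{fitted}
#'   per-patient survival probabilities and \code{grid} (x, y, prob).
#' @export
survivalSurface <- function(coords, clinical, evalAge = NULL, gridN = 50L) {
  if (sum(clinical$died, na.rm = TRUE) < 10)
    stop("invalid input: need at least 10 events")
  coords <- as.matrix(coords)
  if (is.null(evalAge)) evalAge <- median(clinical$age)
  df <- data.frame(a0 = clinical$age,
                   a1 = clinical$age + clinical$followup_time,
                   died = clinical$died,
                   x = coords[, 1], yc = coords[, 2])
  fit <- survival::coxph(survival::Surv(a0, a1, died) ~ x + yc, data = df,
                         ties = "efron")
  survAt <- function(newdf) {
    sf <- survival::survfit(fit, newdata = newdf)
    sm <- summary(sf, times = evalAge, extend = TRUE)
    as.numeric(sm$surv)
  }
  fitted <- survAt(data.frame(x = df$x, yc = df$yc))
  gx <- seq(min(df$x), max(df$x), length.out = gridN)
  gy <- seq(min(df$yc), max(df$yc), length.out = gridN)
  grid <- expand.grid(x = gx, y = gy)
  grid$prob <- survAt(data.frame(x = grid$x, yc = grid$y))
  structure(list(type = "survival", evalAge = evalAge,
                 coefficients = coef(fit), fitted = fitted, grid = grid,
                 fit = fit),
            class = "OverlaySurface")
}

#' Kaplan-Meier and Nelson-Aalen curves by group
#'
#' Product-limit survival with Greenwood standard errors, the Nelson-Aalen
#' cumulative hazard, and the log-rank test across groups.  Empty groups
#' are dropped with a warning.
#'
#' @param clinical data.frame with followup_time and died.
#' @param group grouping vector (non-degenerate).
#' @return list with \code{curves} (data.frame: group, time, nRisk,
#'   nEvent, surv, se, cumhaz) and \code{logrankP}.
#' @export
kmCumulativeHazard <- function(clinical, group) {
  if (!is.factor(group)) group <- factor(group)
  empty <- levels(group)[table(group) == 0]
  if (length(empty)) {
    warning("empty group(s) dropped: ", paste(empty, collapse = ", "))
    group <- droplevels(group)
  }
  df <- data.frame(time = clinical$followup_time, died = clinical$died,
                   group = group)
  sf <- survival::survfit(survival::Surv(time, died) ~ group, data = df)
  grp <- if (is.null(sf$strata)) rep(levels(group)[1], length(sf$time))
         else rep(sub("^group=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = grp, time = sf$time, nRisk = sf$n.risk,
                       nEvent = sf$n.event, surv = sf$surv,
                       se = sf$std.err * sf$surv)
  ## Nelson-Aalen within each group
  curves$cumhaz <- stats::ave(curves$nEvent / curves$nRisk, curves$group,
                              FUN = cumsum)
  lr <- if (nlevels(group) > 1)
    survival::survdiff(survival::Surv(time, died) ~ group, data = df)
  else NULL
  logrankP <- if (is.null(lr)) NA_real_
              else stats::pchisq(lr$chisq, df = nlevels(group) - 1,
                                 lower.tail = FALSE)
  list(curves = curves, logrankP = logrankP)
}
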