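fitRidge0 <- function(d) fitCoxModel(d, penaltySpec("ridge", lambda = 0),
                                     standardize = FALSE)

test_that("prognostic index is the linear predictor", {
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(prognosticIndex(X, rep(0, 4)), rep(0, 5))
  expect_equal(prognosticIndex(X, c(1, 0, 0, 0)), X[, 1], ignore_attr = TRUE)
  beta <- rnorm(4)
  expect_equal(prognosticIndex(X, beta),
               vapply(1:5, function(i) sum(X[i, ] * beta), numeric(1)))
  # model route applies the stored standardization
  d <- randomSurvData(30, 3, seed = 3)
  m <- fitCoxModel(d, penaltySpec("ridge", 0.5))
  pi <- prognosticIndex(m, d)
  Xs <- scale(covariates(d))
  expect_equal(unname(pi), as.numeric(Xs %*% coef(m)), tolerance = 1e-10)
})

test_that("deviance residuals match the martingale-based formula and survival", {
  d <- randomSurvData(15, 3, seed = 12, censorProb = 0.3)
  m <- fitRidge0(d)
  dres <- devianceResiduals(m, d)
  # independent textbook route: martingale residuals from the Breslow
  # cumulative hazard, then the signed square-root transform
  bl <- breslowBaseline(coef(m), d)
  H0 <- vapply(survTime(d), function(t) sum(bl@h0[bl@time <= t]), numeric(1))
  mg <- survStatus(d) - H0 * exp(as.numeric(covariates(d) %*% coef(m)))
  dlt <- survStatus(d)
  expected <- sign(mg) * sqrt(-2 * (mg + ifelse(dlt == 1, log(dlt - mg), 0)))
  expect_equal(unname(dres), expected, tolerance = 1e-8)
  # and against survival's own implementation at the unpenalized fit
  cph <- survival::coxph(
    survival::Surv(survTime(d), survStatus(d)) ~ covariates(d),
    ties = "breslow")
  expect_equal(unname(dres), unname(residuals(cph, type = "deviance")),
               tolerance = 1e-6)
})

test_that("a zero martingale residual gives a zero deviance residual", {
  # single subject with an event: H0*exp(eta) = 1 exactly, so m = 0
  d1 <- CoxSurvivalData(matrix(0.5, 1, 1), time = 2, status = 1)
  bl <- breslowBaseline(0, list(X = matrix(0.5, 1, 1), time = 2, status = 1))
  m <- new("PenalizedCoxModel", beta = c(f1 = 0), center = c(f1 = 0),
           scale = c(f1 = 1), baseline = bl,
           penalty = penaltySpec("ridge", 0), objectiveTrace = 0,
           converged = TRUE, nIter = 1L)
  expect_equal(unname(devianceResiduals(m, d1)), 0)
})

test_that("rmse is the root mean square", {
  expect_equal(rmse(c(3, 4)), sqrt(12.5))
  expect_equal(rmse(rep(0, 5)), 0)
  expect_equal(rmse(rep(-2.5, 7)), 2.5)
  expect_error(rmse(numeric()), "non-empty")
})

test_that("concordance index honors both counting rules", {
  # perfect anti-ordering: higher risk, shorter time, no censoring
  time <- c(5, 4, 3, 2, 1); pi <- 1:5; status <- rep(1, 5)
  expect_equal(concordanceIndex(pi, time, status, "standard"), 1)
  expect_equal(concordanceIndex(pi, time, status, "paper_literal"), 1)
  # flat risks: every pair is a risk tie
  expect_equal(concordanceIndex(rep(1, 5), time, status, "standard"), 0.5)
  # antisymmetry without ties
  set.seed(8)
  piR <- rnorm(10); t10 <- rexp(10) + 0.1; s10 <- rep(1, 10)
  expect_equal(concordanceIndex(-piR, t10, s10),
               1 - concordanceIndex(piR, t10, s10))
  expect_error(concordanceIndex(c(1, 2), c(1, 2), c(0, 0)), "permissible")
})

test_that("concordance matches exhaustive pair enumeration under censoring", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:10, 1)
    pi <- sample(seq_len(6), n, replace = TRUE) / 2   # forces some risk ties
    time <- sample(seq_len(8), n, replace = TRUE) / 2 # and some time ties
    status <- rbinom(n, 1, 0.6)
    if (sum(status) == 0) status[1] <- 1
    for (rule in c("standard", "paper_literal")) {
      expect_equal(concordanceIndex(pi, time, status, rule),
                   bruteCindex(pi, time, status, rule),
                   info = paste(seed, rule))
    }
  }
})

test_that("concordance agrees with the survival package on tie-free data", {
  set.seed(19)
  n <- 40
  pi <- rnorm(n); time <- rexp(n) + 0.01; status <- rbinom(n, 1, 0.7)
  cs <- survival::concordance(survival::Surv(time, status) ~ pi,
                              reverse = TRUE)
  expect_equal(concordanceIndex(pi, time, status, "standard"),
               unname(cs$concordance), tolerance = 1e-12)
})

test_that("Kaplan-Meier reproduces product-limit hand computations", {
  # all events, distinct times: S drops by 1/n each time
  km <- kaplanMeier(1:4, rep(1, 4))
  expect_equal(km@survival, (4 - 1:4) / 4)
  expect_equal(km@atRisk, 4:1)
  # events at 1 and 3, censored at 2 and 4: S(1)=3/4, S(3)=(3/4)(1/2)=3/8
  km2 <- kaplanMeier(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km2@time, c(1, 3))
  expect_equal(km2@survival, c(3 / 4, 3 / 8))
  expect_equal(kmSurvivalAt(km2, c(0.5, 1, 2.5, 10)),
               c(1, 3 / 4, 3 / 4, 3 / 8))
  # no events: survival identically 1
  km3 <- kaplanMeier(c(1, 2), c(0, 0))
  expect_length(km3@time, 0)
  expect_equal(kmSurvivalAt(km3, 5), 1)
})

test_that("KM equals exp(-Nelson-Aalen) exactly on single-event data", {
  km <- kaplanMeier(c(3, 1, 2), c(0, 1, 0))
  bl <- breslowBaseline(0, list(X = matrix(0, 3, 1), time = c(3, 1, 2),
                                status = c(0, 1, 0)))
  expect_equal(km@survival, 1 - bl@h0)   # single event: 1 - 1/n = exp approx
  # first-order agreement on multi-event data
  time <- c(1, 2, 3, 4, 5, 6); status <- c(1, 1, 0, 1, 0, 1)
  km2 <- kaplanMeier(time, status)
  bl2 <- breslowBaseline(0, list(X = matrix(0, 6, 1), time = time,
                                 status = status))
  expect_equal(km2@survival, exp(-bl2@H0), tolerance = 0.15)
})

test_that("log-rank test matches observed-minus-expected accumulation", {
  # duplicated groups: no difference at all
  time <- c(1, 2, 3, 4); status <- c(1, 0, 1, 1)
  lr <- logrankTest(c(time, time), c(status, status), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1, tolerance = 1e-12)
  # 8-subject worked example against the hand accumulation oracle
  t8 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  s8 <- c(1, 1, 1, 0, 1, 1, 0, 1)
  g8 <- rep(c("x", "y"), 4)
  lr8 <- logrankTest(t8, s8, g8)
  expect_equal(lr8$statistic, bruteLogrank(t8, s8, g8), tolerance = 1e-10)
  # invariance to relabeling
  lrSwap <- logrankTest(t8, s8, ifelse(g8 == "x", "y", "x"))
  expect_equal(lr8$statistic, lrSwap$statistic, tolerance = 1e-12)
  expect_error(logrankTest(t8, s8, rep("x", 8)), "2 groups")
})

test_that("risk stratification implements the three schemes", {
  set.seed(41)
  pi <- rnorm(10); time <- rexp(10) + 0.1; status <- rbinom(10, 1, 0.8)
  status[1] <- 1L
  s40 <- stratifyRisk(pi, time, status, "q40")
  expect_equal(unname(table(s40@groups)), c(4L, 4L, 2L), ignore_attr = TRUE)
  expect_true(max(pi[s40@groups == "low"]) < min(pi[s40@groups == "high"]))
  s50 <- stratifyRisk(pi, time, status, "q50")
  expect_equal(unname(table(s50@groups)), c(5L, 5L, 0L), ignore_attr = TRUE)
  expect_error(stratifyRisk(rep(1, 10), time, status, "q40"), "degenerate")
})

test_that("optimal stratification recovers the exhaustively best threshold", {
  set.seed(51)
  n <- 40
  grp <- rep(c(0, 1), each = n / 2)
  pi <- grp * 3 + rnorm(n, sd = 0.3)            # two well separated clusters
  time <- rexp(n, rate = exp(grp))              # higher risk, shorter time
  status <- rep(1L, n)
  s <- stratifyRisk(pi, time, status, "optimal")
  # exhaustive oracle over every midpoint with the 10% constraint
  su <- sort(unique(pi))
  mids <- (su[-1] + su[-length(su)]) / 2
  ps <- vapply(mids, function(thr) {
    hi <- pi > thr
    if (sum(hi) < 4 || sum(!hi) < 4) return(NA_real_)
    logrankTest(time, status, ifelse(hi, "h", "l"))$p.value
  }, numeric(1))
  expect_equal(s@threshold, mids[which.min(ps)])
  expect_equal(s@logrankP, min(ps, na.rm = TRUE))
  # the split separates risk: the high-PI group fails sooner on average
  expect_lt(mean(time[s@groups == "high"]), mean(time[s@groups == "low"]))
})
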