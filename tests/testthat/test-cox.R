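test_that("partial log-likelihood has its closed forms at beta = 0", {
  d2 <- list(X = matrix(0, 2, 1), time = c(1, 2), status = c(1, 1))
  expect_equal(partialLogLik(0, d2), -log(2))
  expect_equal(partialLogLik(0, list(X = matrix(0, 3, 1), time = 1:3,
                                     status = c(0, 0, 0))), 0)
  # -sum log|risk set| over events, by direct counting
  d <- randomSurvData(15, 3, seed = 1)
  expected <- -sum(vapply(which(survStatus(d) == 1), function(i)
    log(sum(survTime(d) >= survTime(d)[i])), numeric(1)))
  expect_equal(partialLogLik(rep(0, 3), d), expected, tolerance = 1e-12)
})

test_that("partial log-likelihood matches term-by-term evaluation", {
  for (seed in 1:10) {
    d <- randomSurvData(10, 3, seed = seed, ties = seed %% 2 == 0)
    beta <- rnorm(3, sd = 0.7)
    expect_equal(partialLogLik(beta, d),
                 brutePartialLogLik(beta, covariates(d), survTime(d),
                                    survStatus(d)),
                 tolerance = 1e-10)
  }
})

test_that("Breslow baseline increments are event counts over risk sums", {
  # all events, distinct times, beta = 0: k-th increment is 1/(n-k+1)
  n <- 6
  d <- list(X = matrix(0, n, 1), time = seq_len(n), status = rep(1, n))
  bl <- breslowBaseline(0, d)
  expect_equal(bl@h0, 1 / (n - seq_len(n) + 1))
  expect_equal(bl@H0, cumsum(bl@h0))

  # hand-computed mixed censoring: risk sets {4 at t=1, 2 at t=2}
  d4 <- list(X = matrix(0, 4, 1), time = c(1, 1.5, 2, 3),
             status = c(1, 0, 1, 0))
  bl4 <- breslowBaseline(0, d4)
  expect_equal(bl4@time, c(1, 2))
  expect_equal(bl4@h0, c(1 / 4, 1 / 2))

  # single subject: h0 = exp(-X'beta)
  d1 <- list(X = matrix(2, 1, 1), time = 5, status = 1)
  expect_equal(breslowBaseline(0.3, d1)@h0, exp(-2 * 0.3))

  # random data against the definition, including tied event times
  for (seed in 11:15) {
    d <- randomSurvData(12, 2, seed = seed, ties = TRUE)
    beta <- rnorm(2, sd = 0.5)
    oracle <- bruteBreslow(beta, covariates(d), survTime(d), survStatus(d))
    bl <- breslowBaseline(beta, d)
    expect_equal(bl@time, oracle$time)
    expect_equal(bl@h0, oracle$h0, tolerance = 1e-10)
  }
})

test_that("beta = 0 Breslow increments reproduce Nelson-Aalen with ties", {
  time <- c(1, 1, 1, 2, 2, 3, 4)
  status <- c(1, 1, 0, 1, 1, 0, 1)
  bl <- breslowBaseline(0, list(X = matrix(0, 7, 1), time = time,
                                status = status))
  # d_k / |risk set|: 2/7, 2/4, 1/1
  expect_equal(bl@h0, c(2 / 7, 2 / 4, 1 / 1))
})

test_that("total log-likelihood evaluates the Breslow-plugged objective", {
  d1 <- list(X = matrix(0, 1, 1), time = 1, status = 1)
  bl <- new("BaselineHazard", time = 1, h0 = 1, H0 = 1, nEvents = 1L)
  expect_equal(totalLogLik(0, bl, d1), -1)
  # all censored with H0 = 0 before any event time
  dc <- list(X = matrix(0, 2, 1), time = c(0.1, 0.2), status = c(0, 0))
  expect_equal(totalLogLik(0, bl, dc), 0)
  # event at a time with no increment is undefined
  dbad <- list(X = matrix(0, 1, 1), time = 0.5, status = 1)
  expect_error(totalLogLik(0, bl, dbad), "increment")
})

test_that("profile (partial) and total likelihood have the same argmax", {
  d <- randomSurvData(20, 3, seed = 21)
  fit <- fitCoxModel(d, penaltySpec("ridge", lambda = 0),
                     standardize = FALSE)
  # independent route: maximize the total log-likelihood with the Breslow
  # baseline re-plugged at every evaluation
  prof <- function(b) totalLogLik(b, breslowBaseline(b, d), d)
  opt <- optim(rep(0, 3), function(b) -prof(b), method = "BFGS",
               control = list(reltol = 1e-12))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-4)
})

test_that("unpenalized fit matches an independent Newton maximization", {
  d <- randomSurvData(30, 3, seed = 30, censorProb = 0.25)
  fit <- fitCoxModel(d, penaltySpec("ridge", lambda = 0), standardize = FALSE)
  cph <- survival::coxph(
    survival::Surv(survTime(d), survStatus(d)) ~ covariates(d),
    ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(cph)), tolerance = 1e-4)
  # and on the standardized path, back-transformed coefficients agree
  fit2 <- fitCoxModel(d, penaltySpec("ridge", lambda = 0))
  expect_equal(unname(coef(fit2, scale = "original")), unname(coef(cph)),
               tolerance = 1e-4)
})

test_that("the objective trace is non-decreasing and convergence is flagged", {
  d <- randomSurvData(40, 5, seed = 5)
  S <- normalizeAdjacency(GeneNetwork(
    as.matrix(adjacency(simulateNetwork(5, "erdos_renyi", seed = 3))),
    paste0("f", 1:5)))
  for (spec in list(penaltySpec("ridge", 0.5),
                    penaltySpec("lasso", 0.5),
                    penaltySpec("elastic_net", 0.5, alpha = 0.5),
                    penaltySpec("degree", 0.5, network = S))) {
    fit <- fitCoxModel(d, spec)
    expect_true(fit@converged)
    expect_true(all(diff(fit@objectiveTrace) >= -1e-8))
  }
})

test_that("a dominant quadratic penalty shrinks coefficients to zero", {
  d <- randomSurvData(40, 4, seed = 8)
  fit <- fitCoxModel(d, penaltySpec("ridge", lambda = 1e8))
  expect_lt(max(abs(coef(fit))), 1e-5)
})

test_that("degree penalty with unit weighted degrees is exactly ridge", {
  P <- 10
  W <- matrix(0, P, P)
  for (i in seq_len(P / 2)) W[2 * i - 1, 2 * i] <- W[2 * i, 2 * i - 1] <- 1
  S <- normalizeAdjacency(GeneNetwork(W, paste0("f", seq_len(P))))
  d <- randomSurvData(50, P, seed = 13)
  fdeg <- fitCoxModel(d, penaltySpec("degree", lambda = 2, network = S))
  fridge <- fitCoxModel(d, penaltySpec("ridge", lambda = 2))
  expect_equal(coef(fdeg), coef(fridge), tolerance = 1e-8)
})

test_that("quadratic fits are unique: random initializations converge together", {
  d <- randomSurvData(35, 4, seed = 44)
  S <- normalizeAdjacency(GeneNetwork(
    as.matrix(adjacency(simulateNetwork(4, "erdos_renyi", seed = 4))),
    paste0("f", 1:4)))
  spec <- penaltySpec("degree", lambda = 1, network = S)
  ref <- coef(fitCoxModel(d, spec))
  set.seed(99)
  for (rep in 1:10) {
    fit <- fitCoxModel(d, spec, initBeta = rnorm(4, sd = 2))
    expect_equal(coef(fit), ref, tolerance = 1e-4)
  }
})

test_that("coefficient norms shrink monotonically in lambda", {
  d <- randomSurvData(40, 5, seed = 55)
  S <- normalizeAdjacency(GeneNetwork(
    as.matrix(adjacency(simulateNetwork(5, "erdos_renyi", seed = 5))),
    paste0("f", 1:5)))
  lambdas <- 10^seq(-2, 2, length.out = 10)
  for (mk in list(function(l) penaltySpec("ridge", l),
                  function(l) penaltySpec("laplacian", l, alpha = 0.3,
                                          network = S),
                  function(l) penaltySpec("degree", l, network = S))) {
    norms <- vapply(lambdas, function(l)
      sqrt(sum(coef(fitCoxModel(d, mk(l)))^2)), numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("covariate shifts do not change the fit beyond tolerance", {
  d <- randomSurvData(30, 3, seed = 66)
  X2 <- covariates(d); X2[, 2] <- X2[, 2] + 100
  d2 <- CoxSurvivalData(X2, survTime(d), survStatus(d), sampleIds(d))
  f1 <- fitCoxModel(d, penaltySpec("ridge", lambda = 1))
  f2 <- fitCoxModel(d2, penaltySpec("ridge", lambda = 1))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  # the partial likelihood itself is invariant under column shifts
  expect_equal(partialLogLik(c(1, 2, 3),
                             list(X = sweep(covariates(d), 2, c(5, -2, 0)),
                                  time = survTime(d),
                                  status = survStatus(d))),
               partialLogLik(c(1, 2, 3), d), tolerance = 1e-10)
})

test_that("fit errors and warnings are raised on degenerate input", {
  d <- randomSurvData(20, 3, seed = 70)
  expect_warning(fitCoxModel(d, penaltySpec("ridge", 0.1), maxIter = 1L),
                 "did not converge")
  Xc <- covariates(d); Xc[, 1] <- 1
  dc <- CoxSurvivalData(Xc, survTime(d), survStatus(d), sampleIds(d))
  expect_error(fitCoxModel(dc, penaltySpec("ridge", 1)), "constant")
})

test_that("ridge and lasso solutions agree with glmnet at the matched penalty scale", {
  # objective here: pl - (lambda/2)(alpha|b|_1 + (1-alpha)|b|_2^2);
  # glmnet's coxnet: (1/n) pl - lambda_g (alpha_g|b|_1 + (1-alpha_g)/2 |b|_2^2)
  # so lambda_g = lambda/n for ridge and lambda/(2n) for lasso
  d <- randomSurvData(60, 5, seed = 91, censorProb = 0.25)
  Xs <- scale(covariates(d))
  ds <- CoxSurvivalData(Xs, survTime(d), survStatus(d), sampleIds(d))
  y <- survival::Surv(survTime(d), survStatus(d))
  fitR <- fitCoxModel(ds, penaltySpec("ridge", 2), standardize = FALSE)
  gR <- glmnet::glmnet(Xs, y, family = "cox", alpha = 0, lambda = 2 / 60,
                       standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(coef(fitR)), as.numeric(gR$beta), tolerance = 1e-5)
  fitL <- fitCoxModel(ds, penaltySpec("lasso", 2), standardize = FALSE)
  gL <- glmnet::glmnet(Xs, y, family = "cox", alpha = 1, lambda = 2 / 120,
                       standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(coef(fitL)), as.numeric(gL$beta), tolerance = 1e-5)
})
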