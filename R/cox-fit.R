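#' @include AllClasses.R AllGenerics.R penalties.R cox-likelihood.R
NULL

#' Fit a penalized Cox proportional hazards model
#'
#' Maximizes the penalized Cox objective
#' \deqn{l(\beta) - \tfrac{1}{2}\lambda\,\mathrm{pen}(\beta)}
#' where \eqn{l} is the partial log-likelihood (the profile of the total
#' log-likelihood over the Breslow baseline, so maximizing it is the fixed
#' point of alternating \eqn{\beta} / \eqn{h_0} updates) and the penalty is
#' given by a [PenaltySpec-class]. Quadratic penalties (ridge, laplacian,
#' degree) use damped Newton steps with backtracking line search; families
#' with an L1 part (lasso, elastic net) use a proximal Newton scheme with
#' cyclic coordinate descent and soft-thresholding on the local quadratic
#' model. The Breslow baseline is computed at the solution.
#'
#' Covariates are standardized (mean 0, variance 1) by default before
#' fitting, because the penalties are scale sensitive; coefficients are
#' stored on the standardized scale (see [coef,PenalizedCoxModel-method]).
#'
#' @param data a [CoxSurvivalData-class].
#' @param penalty a [PenaltySpec-class]; its network's node ids (if any)
#'   must match the data's feature ids (see [alignNetwork()]).
#' @param initBeta starting coefficients (default all zero).
#' @param tol relative objective-change convergence tolerance.
#' @param maxIter maximum number of outer iterations.
#' @param standardize center and scale covariates before fitting.
#' @return a [PenalizedCoxModel-class]. If `maxIter` is reached first, the
#'   model is returned with `converged = FALSE` and a warning.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' d <- CoxSurvivalData(X, time = rexp(20, exp(X[, 1] / 4)),
#'                      status = rbinom(20, 1, 0.8))
#' fitCoxModel(d, penaltySpec("ridge", lambda = 0.5))
#' @export
fitCoxModel <- function(data, penalty, initBeta = NULL, tol = 1e-6,
                        maxIter = 500L, standardize = TRUE) {
  stopifnot(is(data, "CoxSurvivalData"), is(penalty, "PenaltySpec"))
  X <- data@X
  n <- nrow(X); P <- ncol(X)
  if (penalty@family %in% c("laplacian", "degree") &&
      !is(penalty@network, "NormalizedAdjacency"))
    stop("penalty family '", penalty@family, "' requires a network ",
         "(a deserialized spec cannot be refitted)")
  if (is(penalty@network, "NormalizedAdjacency")) {
    nid <- penalty@network@nodeIds
    if (length(nid) != P || !identical(nid, colnames(X)))
      stop("penalty network nodes do not match data features; ",
           "run alignNetwork() first")
  }
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    if (any(scl == 0))
      stop("constant covariate(s) cannot be standardized: ",
           paste(utils::head(colnames(X)[scl == 0], 10), collapse = ", "))
    X <- sweep(sweep(X, 2, center), 2, scl, "/")
  } else {
    center <- rep(0, P); scl <- rep(1, P)
  }
  time <- data@time; status <- as.integer(data@status)
  beta <- if (is.null(initBeta)) rep(0, P) else as.numeric(initBeta)
  stopifnot(length(beta) == P)

  lam <- penalty@lambda
  l1w <- .penaltyL1Weight(penalty)            # lambda * alpha of the L1 part
  Mq <- .penaltyQuadratic(penalty, P)         # quadratic part (vector or matrix)
  qform <- function(b) if (is.matrix(Mq)) as.numeric(t(b) %*% Mq %*% b)
                       else sum(Mq * b^2)
  qgrad <- function(b) if (is.matrix(Mq)) as.numeric(Mq %*% b) else Mq * b
  objective <- function(b)
    .coxRisk(X, time, status, b)$loglik -
      0.5 * lam * qform(b) - 0.5 * l1w * sum(abs(b))

  obj <- objective(beta)
  if (!is.finite(obj)) stop("objective is not finite at the starting point")
  trace <- obj
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    r <- .coxRisk(X, time, status, beta, need = "hess")
    gSmooth <- r$grad - lam * qgrad(beta)
    H <- r$info + lam * (if (is.matrix(Mq)) Mq else diag(Mq, P))
    dH <- mean(diag(H))
    if (!is.finite(dH) || dH <= 0) dH <- 1
    H <- H + diag(1e-10 * dH, P)              # guard exact singularity
    if (l1w == 0) {
      step <- tryCatch(solve(H, gSmooth),
                       error = function(e) gSmooth / diag(H))
      dir <- step
    } else {
      dir <- .cdQuadraticL1(beta, gSmooth, H, 0.5 * l1w) - beta
    }
    t <- 1
    newObj <- -Inf
    for (ls in 1:40) {
      cand <- beta + t * dir
      newObj <- objective(cand)
      if (is.nan(newObj)) stop("objective became NaN during line search")
      if (is.finite(newObj) && newObj >= obj - 1e-12 * (abs(obj) + 1)) break
      t <- t / 2
    }
    if (newObj < obj - 1e-12 * (abs(obj) + 1)) {  # no ascent possible
      converged <- TRUE
      break
    }
    beta <- beta + t * dir
    trace <- c(trace, newObj)
    if (abs(newObj - obj) < tol * (abs(obj) + 1e-8)) {
      obj <- newObj
      converged <- TRUE
      break
    }
    obj <- newObj
  }
  if (!converged)
    warning("fitCoxModel did not converge in ", maxIter, " iterations")
  names(beta) <- colnames(data@X)
  bl <- breslowBaseline(beta, list(X = X, time = time, status = status))
  new("PenalizedCoxModel", beta = beta,
      center = stats::setNames(center, colnames(data@X)),
      scale = stats::setNames(scl, colnames(data@X)),
      baseline = bl, penalty = penalty, objectiveTrace = trace,
      converged = converged, nIter = iter)
}

# Maximize g'(b - b0) - (1/2)(b - b0)' H (b - b0) - t1 * |b|_1 by cyclic
# coordinate descent with soft-thresholding (proximal Newton inner loop,
# compiled kernel).
.cdQuadraticL1 <- function(b0, g, H, t1, maxCycles = 200L, tol = 1e-9) {
  as.numeric(.cdQuadraticL1Cpp(b0, g, H, t1, as.integer(maxCycles), tol))
}

# apply a model's standardization to a raw covariate matrix
.standardizeNew <- function(model, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), names(model@beta)))
    stop("feature ids of the new data do not match the model")
  sweep(sweep(X, 2, model@center), 2, model@scale, "/")
}
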