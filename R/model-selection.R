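#' @include AllClasses.R AllGenerics.R cox-fit.R
NULL

#' Assign samples to cross-validation folds
#'
#' Balanced random partition: fold sizes differ by at most one, deterministic
#' given `seed`. With `stratify`, randomization is done separately within
#' events and censored samples, which guards against folds with no events
#' while keeping sizes balanced.
#'
#' @param n number of samples.
#' @param k number of folds (default 5).
#' @param seed integer seed for the assignment.
#' @param stratify optional 0/1 event vector of length `n` for
#'   event-stratified assignment.
#' @return integer vector of fold labels in `1..k`.
#' @export
assignFolds <- function(n, k = 5L, seed = 1L, stratify = NULL) {
  if (n < k) stop("need at least as many samples (", n, ") as folds (", k, ")")
  set.seed(seed)
  if (is.null(stratify)) return(sample(rep_len(seq_len(k), n)))
  stopifnot(length(stratify) == n)
  folds <- integer(n)
  for (g in unique(stratify)) {
    idx <- which(stratify == g)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Build a penalty grid for cross-validation
#'
#' Expands a family over a \eqn{\lambda} grid (default 20 points log-spaced
#' on \eqn{[10^{-3}, 10^3]}) and, where the family takes one, an
#' \eqn{\alpha} grid (default \eqn{\{0, 0.25, 0.5, 0.75, 1\}}).
#'
#' @param family penalty family (see [penaltySpec()]).
#' @param lambda numeric vector of penalty strengths.
#' @param alpha numeric vector of mixing values (ignored for families
#'   without \eqn{\alpha}).
#' @param network [NormalizedAdjacency-class] for the network families.
#' @return list of [PenaltySpec-class] objects.
#' @export
penaltyGrid <- function(family, lambda = 10^seq(-3, 3, length.out = 20),
                        alpha = c(0, 0.25, 0.5, 0.75, 1), network = NULL) {
  hasAlpha <- family %in% c("elastic_net", "laplacian")
  if (!hasAlpha) alpha <- NA_real_
  grid <- expand.grid(lambda = lambda, alpha = alpha)
  lapply(seq_len(nrow(grid)), function(i)
    penaltySpec(family, lambda = grid$lambda[i],
                alpha = if (hasAlpha) grid$alpha[i] else NULL,
                network = network))
}

#' Cross-validated partial-likelihood model selection
#'
#' For each candidate penalty, each fold \eqn{i} is held out, the model is
#' fitted on the remaining folds giving \eqn{\hat\beta^{(-i)}}, and the fold
#' contributes
#' \deqn{pl(X, \hat\beta^{(-i)}) - pl(X_{(-i)}, \hat\beta^{(-i)}),}
#' the partial log-likelihood of the full data minus that of the training
#' data at the held-out-trained coefficients (the cross-validated partial
#' likelihood). The criterion is the sum over folds; larger is better. Ties
#' are broken toward larger \eqn{\lambda}, then larger \eqn{\alpha}
#' (parsimony).
#'
#' @param data a [CoxSurvivalData-class].
#' @param penalties list of [PenaltySpec-class] candidates (see
#'   [penaltyGrid()]).
#' @param folds integer fold assignment per sample, or `NULL` to draw one
#'   with [assignFolds()].
#' @param k,seed used when `folds` is `NULL`.
#' @param ... passed to [fitCoxModel()].
#' @return a [CoxCVResult-class].
#' @export
cvCox <- function(data, penalties, folds = NULL, k = 5L, seed = 1L, ...) {
  stopifnot(is(data, "CoxSurvivalData"), length(penalties) >= 1L)
  if (is(penalties, "PenaltySpec")) penalties <- list(penalties)
  n <- length(data)
  if (is.null(folds)) folds <- assignFolds(n, k, seed)
  stopifnot(length(folds) == n)
  nf <- max(folds)
  for (i in seq_len(nf)) {
    if (sum(data@status[folds == i]) == 0L)
      stop("fold ", i, " contains no events; use stratified fold assignment")
    if (sum(data@status[folds != i]) == 0L)
      stop("training split for fold ", i, " contains no events")
  }
  fullParts <- list(X = data@X, time = data@time, status = data@status)
  scores <- vapply(penalties, function(spec) {
    cv <- 0
    for (i in seq_len(nf)) {
      train <- data[folds != i]
      fit <- fitCoxModel(train, spec, ...)
      bOrig <- coef(fit, scale = "original")
      plFull <- partialLogLik(bOrig, fullParts)
      plTrain <- partialLogLik(bOrig, list(X = train@X, time = train@time,
                                           status = train@status))
      cv <- cv + (plFull - plTrain)
    }
    cv
  }, numeric(1))
  grid <- data.frame(
    family = vapply(penalties, function(s) s@family, character(1)),
    lambda = vapply(penalties, function(s) s@lambda, numeric(1)),
    alpha = vapply(penalties, function(s)
      if (length(s@alpha)) s@alpha else NA_real_, numeric(1)))
  # best = max score; ties resolved toward more regularization
  o <- order(-scores, -grid$lambda,
             ifelse(is.na(grid$alpha), -Inf, -grid$alpha))
  best <- o[1]
  new("CoxCVResult", grid = grid, cvScores = scores,
      folds = as.integer(folds), best = as.integer(best),
      penalties = penalties)
}

#' Penalty specification selected by cross-validation
#'
#' @param cv a [CoxCVResult-class] from [cvCox()].
#' @return the winning [PenaltySpec-class].
#' @export
bestPenalty <- function(cv) {
  stopifnot(is(cv, "CoxCVResult"))
  cv@penalties[[cv@best]]
}
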