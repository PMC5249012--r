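#' @import methods
NULL

# W and S may be dense (base) or sparse (Matrix) depending on problem size;
# every consumer goes through the same accessors so the contract is identical.
setClassUnion("AnyMatrix", c("matrix", "Matrix"))

#' GeneNetwork: a weighted, undirected feature network
#'
#' Holds an ordered vector of node (feature) identifiers and the symmetric
#' non-negative adjacency matrix \eqn{W} of edge weights. Self loops are not
#' allowed (\eqn{W_{ii} = 0}).
#'
#' @slot nodeIds character vector of unique node labels, length \eqn{P}.
#' @slot W \eqn{P \times P} symmetric non-negative matrix of edge weights
#'   (dense \code{matrix} or sparse \code{Matrix}).
#'
#' @seealso [GeneNetwork()] for the validating constructor,
#'   [normalizeAdjacency()], [buildGCN()], [simulateNetwork()].
#' @export
setClass("GeneNetwork",
  representation(nodeIds = "character", W = "AnyMatrix"))

setValidity("GeneNetwork", function(object) {
  W <- object@W
  p <- length(object@nodeIds)
  msg <- character()
  if (nrow(W) != ncol(W)) msg <- c(msg, "W must be square")
  if (nrow(W) != p) msg <- c(msg, "dim(W) must equal length(nodeIds)")
  if (anyDuplicated(object@nodeIds)) msg <- c(msg, "nodeIds must be unique")
  if (length(msg) == 0L) {
    if (min(W) < 0) msg <- c(msg, "edge weights must be non-negative")
    if (any(Matrix::diag(W) != 0)) msg <- c(msg, "self loops (W[i,i] != 0) are not allowed")
    if (!isTRUE(all.equal(as.matrix(W), t(as.matrix(W)), tolerance = 1e-10,
                          check.attributes = FALSE)))
      msg <- c(msg, "W must be symmetric (undirected network)")
  }
  if (length(msg)) msg else TRUE
})

#' NormalizedAdjacency: degree-normalized network weights
#'
#' The normalized adjacency \eqn{S} with
#' \eqn{s_{ij} = w_{ij} (\sum_n w_{in})^{-1/2} (\sum_n w_{nj})^{-1/2}},
#' i.e. each weight divided by the square roots of its row and column sums.
#' Vertices whose row/column sums in \eqn{W} were zero have all-zero rows in
#' \eqn{S} and are recorded in \code{isolated}.
#'
#' @slot nodeIds character vector of node labels.
#' @slot S normalized weight matrix, entries in \eqn{[0, \infty)}; zero
#'   pattern identical to \eqn{W}.
#' @slot isolated integer indices of zero-degree vertices.
#'
#' @seealso [normalizeAdjacency()], [weightedDegree()], [degreeMatrix()].
#' @export
setClass("NormalizedAdjacency",
  representation(nodeIds = "character", S = "AnyMatrix", isolated = "integer"))

setValidity("NormalizedAdjacency", function(object) {
  msg <- character()
  if (nrow(object@S) != ncol(object@S)) msg <- c(msg, "S must be square")
  if (nrow(object@S) != length(object@nodeIds))
    msg <- c(msg, "dim(S) must equal length(nodeIds)")
  if (length(msg) == 0L && min(object@S) < 0)
    msg <- c(msg, "S entries must be non-negative")
  if (length(object@isolated) &&
      (min(object@isolated) < 1L || max(object@isolated) > nrow(object@S)))
    msg <- c(msg, "isolated indices out of range")
  if (length(msg)) msg else TRUE
})

#' CoxSurvivalData: right-censored survival outcomes with covariates
#'
#' Container for an \eqn{n \times P} covariate (expression) matrix together
#' with follow-up times and event indicators.
#'
#' @slot sampleIds character sample labels, length \eqn{n}.
#' @slot X numeric \eqn{n \times P} covariate matrix; column names are the
#'   feature (gene) identifiers.
#' @slot time positive follow-up times.
#' @slot status integer event indicators, 1 = event observed, 0 = censored.
#'
#' @seealso [CoxSurvivalData()], [loadDataset()], [simulateSurvival()].
#' @export
setClass("CoxSurvivalData",
  representation(sampleIds = "character", X = "matrix",
                 time = "numeric", status = "integer"))

setValidity("CoxSurvivalData", function(object) {
  n <- length(object@sampleIds)
  msg <- character()
  if (nrow(object@X) != n) msg <- c(msg, "nrow(X) must equal length(sampleIds)")
  if (length(object@time) != n) msg <- c(msg, "time must have one entry per sample")
  if (length(object@status) != n) msg <- c(msg, "status must have one entry per sample")
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "sampleIds must be unique")
  if (is.null(colnames(object@X))) msg <- c(msg, "X must have feature ids as colnames")
  if (length(object@time) && any(object@time <= 0))
    msg <- c(msg, "all follow-up times must be > 0")
  if (length(object@status) && !all(object@status %in% c(0L, 1L)))
    msg <- c(msg, "status must be 0 (censored) or 1 (event)")
  if (length(object@status) && sum(object@status) == 0L)
    msg <- c(msg, "at least one event is required (partial likelihood degenerate otherwise)")
  if (length(msg)) msg else TRUE
})

#' PenaltySpec: which regularizer, and with which parameters
#'
#' Families: \code{ridge}, \code{lasso}, \code{elastic_net} (mixing
#' \eqn{\alpha}), \code{laplacian} (network smoothness, mixing \eqn{\alpha}
#' with ridge) and \code{degree} (inverse weighted-degree quadratic penalty).
#' A network is required exactly for the \code{laplacian} and \code{degree}
#' families; \eqn{\alpha} is meaningful only for \code{elastic_net} and
#' \code{laplacian}.
#'
#' @slot family character, one of the five families.
#' @slot lambda non-negative penalty strength.
#' @slot alpha mixing parameter in \eqn{[0,1]} (length 0 when not applicable).
#' @slot network the [NormalizedAdjacency-class] the penalty references, or
#'   \code{NULL}.
#'
#' @seealso [penaltySpec()], [fitCoxModel()], [penaltyValue()].
#' @export
setClass("PenaltySpec",
  representation(family = "character", lambda = "numeric",
                 alpha = "numeric", network = "ANY"))

.penaltyFamilies <- c("ridge", "lasso", "elastic_net", "laplacian", "degree")

setValidity("PenaltySpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L || !object@family %in% .penaltyFamilies)
    msg <- c(msg, paste("family must be one of:",
                        paste(.penaltyFamilies, collapse = ", ")))
  if (length(object@lambda) != 1L || is.na(object@lambda) || object@lambda < 0)
    msg <- c(msg, "lambda must be a single non-negative number")
  needsAlpha <- object@family %in% c("elastic_net", "laplacian")
  if (needsAlpha) {
    if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
      msg <- c(msg, "alpha must be a single value in [0, 1] for this family")
  } else if (length(object@alpha) != 0L) {
    msg <- c(msg, sprintf("alpha must be absent for family '%s'", object@family))
  }
  needsNet <- object@family %in% c("laplacian", "degree")
  if (needsNet && !is.null(object@network) &&
      !is(object@network, "NormalizedAdjacency"))
    msg <- c(msg, sprintf("family '%s' requires a NormalizedAdjacency network",
                          object@family))
  if (!needsNet && !is.null(object@network))
    msg <- c(msg, sprintf("family '%s' must not carry a network", object@family))
  if (length(msg)) msg else TRUE
})

#' BaselineHazard: Breslow baseline hazard increments
#'
#' Nonparametric baseline hazard: one increment \eqn{h_0(t_k)} per distinct
#' event time, with the cumulative hazard
#' \eqn{H_0(t) = \sum_{t_k \le t} h_0(t_k)} as a non-decreasing step function.
#'
#' @slot time sorted distinct event times.
#' @slot h0 hazard increments (\eqn{\ge 0}).
#' @slot H0 cumulative baseline hazard at each event time.
#' @slot nEvents number of events at each event time.
#'
#' @seealso [breslowBaseline()], [totalLogLik()].
#' @export
setClass("BaselineHazard",
  representation(time = "numeric", h0 = "numeric", H0 = "numeric",
                 nEvents = "integer"))

setValidity("BaselineHazard", function(object) {
  msg <- character()
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "event times must be strictly increasing")
  if (any(object@h0 < 0)) msg <- c(msg, "hazard increments must be >= 0")
  if (length(object@h0) &&
      !isTRUE(all.equal(object@H0, cumsum(object@h0), tolerance = 1e-8)))
    msg <- c(msg, "H0 must be the running sum of h0")
  if (length(msg)) msg else TRUE
})

#' PenalizedCoxModel: a fitted network-regularized Cox model
#'
#' Coefficients are stored on the standardized-covariate scale (each column
#' of \eqn{X} centered and scaled during fitting); use
#' \code{coef(model, scale = "original")} to back-transform. The Breslow
#' baseline is estimated on the same standardized scale used internally for
#' prediction.
#'
#' @slot beta named coefficient vector (standardized scale).
#' @slot center,scale per-feature centering/scaling applied to \eqn{X}.
#' @slot baseline the [BaselineHazard-class] at the fitted coefficients.
#' @slot penalty the [PenaltySpec-class] used.
#' @slot objectiveTrace penalized objective per outer iteration
#'   (non-decreasing up to tolerance).
#' @slot converged logical; relative objective change fell below \code{tol}.
#' @slot nIter number of outer iterations used.
#'
#' @seealso [fitCoxModel()], [prognosticIndex()], [devianceResiduals()].
#' @export
setClass("PenalizedCoxModel",
  representation(beta = "numeric", center = "numeric", scale = "numeric",
                 baseline = "BaselineHazard", penalty = "PenaltySpec",
                 objectiveTrace = "numeric", converged = "logical",
                 nIter = "integer"))

#' CentralityRanking: per-vertex centrality scores and their ordering
#'
#' @slot metric one of \code{degree}, \code{weighted_degree},
#'   \code{betweenness}, \code{closeness}.
#' @slot nodeIds vertex labels.
#' @slot scores numeric centrality score per vertex.
#' @slot order permutation of \code{1:P} sorting scores descending (ties
#'   broken by vertex index).
#'
#' @seealso [weightedDegree()], [betweennessCentrality()],
#'   [closenessCentrality()], [topRankOverlap()].
#' @export
setClass("CentralityRanking",
  representation(metric = "character", nodeIds = "character",
                 scores = "numeric", order = "integer"))

setValidity("CentralityRanking", function(object) {
  p <- length(object@scores)
  msg <- character()
  if (length(object@nodeIds) != p) msg <- c(msg, "one score per node required")
  if (!identical(sort(object@order), seq_len(p)))
    msg <- c(msg, "order must be a permutation of 1..P")
  if (p && any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' CoxCVResult: cross-validated grid search result
#'
#' @slot grid data.frame with columns \code{family}, \code{lambda},
#'   \code{alpha} (NA where not applicable).
#' @slot cvScores cross-validated partial-likelihood criterion per grid row
#'   (larger is better).
#' @slot folds integer fold assignment per sample.
#' @slot best row index of the selected grid point.
#' @slot penalties the candidate [PenaltySpec-class] objects, in grid order.
#'
#' @seealso [cvCox()], [assignFolds()].
#' @export
setClass("CoxCVResult",
  representation(grid = "data.frame", cvScores = "numeric",
                 folds = "integer", best = "integer", penalties = "list"))

#' RiskStratification: prognostic-index risk groups and their log-rank test
#'
#' @slot pi per-sample prognostic index \eqn{PI_n = X_n' \beta}.
#' @slot scheme \code{q40} (top/bottom 40\%), \code{q50} (median split) or
#'   \code{optimal} (log-rank-minimizing threshold).
#' @slot groups factor with levels \code{low}, \code{high}, \code{excluded}.
#' @slot threshold the PI cut point actually used (NA for q40).
#' @slot logrankStat,logrankP two-group log-rank chi-square statistic and
#'   p-value for the high/low split.
#'
#' @seealso [stratifyRisk()], [logrankTest()].
#' @export
setClass("RiskStratification",
  representation(pi = "numeric", scheme = "character", groups = "factor",
                 threshold = "numeric", logrankStat = "numeric",
                 logrankP = "numeric"))

#' KMCurve: Kaplan-Meier product-limit survival estimate
#'
#' Step-function estimate of the survival function: starts at 1, drops only
#' at event times.
#'
#' @slot time sorted distinct event times.
#' @slot survival estimated survival just after each event time.
#' @slot atRisk number at risk just before each event time.
#' @slot nEvents events at each time.
#'
#' @seealso [kaplanMeier()].
#' @export
setClass("KMCurve",
  representation(time = "numeric", survival = "numeric",
                 atRisk = "integer", nEvents = "integer"))

setValidity("KMCurve", function(object) {
  msg <- character()
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "event times must be strictly increasing")
  if (length(object@survival)) {
    if (any(object@survival < 0 | object@survival > 1))
      msg <- c(msg, "survival values must lie in [0, 1]")
    if (is.unsorted(rev(object@survival)))
      msg <- c(msg, "survival must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})
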