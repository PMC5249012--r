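#' @include AllClasses.R
NULL

#' Node identifiers of a network object
#'
#' @param x a [GeneNetwork-class], [NormalizedAdjacency-class] or
#'   [CentralityRanking-class].
#' @return character vector of node labels.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "GeneNetwork", function(x) x@nodeIds)

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "NormalizedAdjacency", function(x) x@nodeIds)

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "CentralityRanking", function(x) x@nodeIds)

#' Adjacency / normalized weight matrix of a network object
#'
#' @param x a [GeneNetwork-class] (returns \eqn{W}) or
#'   [NormalizedAdjacency-class] (returns \eqn{S}).
#' @return the weight matrix, with node ids as dimnames.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname adjacency
#' @export
setMethod("adjacency", "GeneNetwork", function(x) {
  W <- x@W
  dimnames(W) <- list(x@nodeIds, x@nodeIds)
  W
})

#' @rdname adjacency
#' @export
setMethod("adjacency", "NormalizedAdjacency", function(x) {
  S <- x@S
  dimnames(S) <- list(x@nodeIds, x@nodeIds)
  S
})

#' Indices of isolated (zero weighted-degree) vertices
#'
#' @param x a [NormalizedAdjacency-class].
#' @return integer vector of vertex indices.
#' @export
setGeneric("isolatedVertices", function(x) standardGeneric("isolatedVertices"))

#' @rdname isolatedVertices
#' @export
setMethod("isolatedVertices", "NormalizedAdjacency", function(x) x@isolated)

#' Accessors for survival data
#'
#' `covariates()` returns the \eqn{n \times P} matrix, `survTime()` the
#' follow-up times, `survStatus()` the 0/1 event indicators, `sampleIds()`
#' the sample labels and `featureIds()` the feature (gene) labels.
#'
#' @param x a [CoxSurvivalData-class].
#' @return the corresponding component.
#' @name survival-accessors
NULL

#' @rdname survival-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname survival-accessors
#' @export
setMethod("covariates", "CoxSurvivalData", function(x) x@X)

#' @rdname survival-accessors
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname survival-accessors
#' @export
setMethod("survTime", "CoxSurvivalData", function(x) x@time)

#' @rdname survival-accessors
#' @export
setGeneric("survStatus", function(x) standardGeneric("survStatus"))

#' @rdname survival-accessors
#' @export
setMethod("survStatus", "CoxSurvivalData", function(x) x@status)

#' @rdname survival-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname survival-accessors
#' @export
setMethod("sampleIds", "CoxSurvivalData", function(x) x@sampleIds)

#' @rdname survival-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname survival-accessors
#' @export
setMethod("featureIds", "CoxSurvivalData", function(x) colnames(x@X))

#' @rdname survival-accessors
#' @export
setMethod("featureIds", "PenalizedCoxModel", function(x) names(x@beta))

#' Subset survival data by sample
#'
#' @param x a [CoxSurvivalData-class].
#' @param i sample index (integer/logical/character).
#' @param j,drop,... ignored (features are never dropped by `[`).
#' @return a [CoxSurvivalData-class] restricted to the selected samples.
#' @export
setMethod("[", "CoxSurvivalData", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIds)
  new("CoxSurvivalData",
      sampleIds = x@sampleIds[i],
      X = x@X[i, , drop = FALSE],
      time = x@time[i],
      status = x@status[i])
})

#' @describeIn CoxSurvivalData-class number of samples
#' @param x a CoxSurvivalData object.
#' @export
setMethod("length", "CoxSurvivalData", function(x) length(x@sampleIds))

#' Baseline hazard of a fitted model
#'
#' @param x a [PenalizedCoxModel-class].
#' @return the [BaselineHazard-class].
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))

#' @rdname baseline
#' @export
setMethod("baseline", "PenalizedCoxModel", function(x) x@baseline)

#' Coefficients of a fitted penalized Cox model
#'
#' @param object a [PenalizedCoxModel-class].
#' @param scale \code{"standardized"} (the scale used during fitting,
#'   default) or \code{"original"} (back-transformed,
#'   \eqn{\beta_j^{orig} = \beta_j^{std} / s_j}).
#' @param ... ignored.
#' @return named numeric coefficient vector.
#' @export
setMethod("coef", "PenalizedCoxModel",
  function(object, scale = c("standardized", "original"), ...) {
    scale <- match.arg(scale)
    if (scale == "standardized") object@beta else object@beta / object@scale
  })

#' Centrality scores and ranking order
#'
#' @param x a [CentralityRanking-class].
#' @return `centralityScores()`: named numeric scores;
#'   `rankingOrder()`: integer permutation sorting scores descending;
#'   `topRanked()`: the labels of the k top-ranked vertices.
#' @export
setGeneric("centralityScores", function(x) standardGeneric("centralityScores"))

#' @rdname centralityScores
#' @export
setMethod("centralityScores", "CentralityRanking",
  function(x) stats::setNames(x@scores, x@nodeIds))

#' @rdname centralityScores
#' @export
setGeneric("rankingOrder", function(x) standardGeneric("rankingOrder"))

#' @rdname centralityScores
#' @export
setMethod("rankingOrder", "CentralityRanking", function(x) x@order)

#' @rdname centralityScores
#' @param k number of top vertices.
#' @export
setGeneric("topRanked", function(x, k) standardGeneric("topRanked"))

#' @rdname centralityScores
#' @export
setMethod("topRanked", "CentralityRanking", function(x, k) {
  stopifnot(k >= 1, k <= length(x@scores))
  x@nodeIds[x@order[seq_len(k)]]
})

## --- show methods -----------------------------------------------------------

setMethod("show", "GeneNetwork", function(object) {
  W <- object@W
  nEdges <- if (is(W, "Matrix")) Matrix::nnzero(W) / 2 else sum(W != 0) / 2
  cat(sprintf("GeneNetwork: %d nodes, %d weighted edges\n",
              length(object@nodeIds), as.integer(nEdges)))
})

setMethod("show", "NormalizedAdjacency", function(object) {
  cat(sprintf("NormalizedAdjacency: %d nodes (%d isolated)\n",
              length(object@nodeIds), length(object@isolated)))
})

setMethod("show", "CoxSurvivalData", function(object) {
  cat(sprintf("CoxSurvivalData: %d samples x %d features; %d events (%.1f%% censored)\n",
              length(object@sampleIds), ncol(object@X), sum(object@status),
              100 * mean(object@status == 0L)))
})

setMethod("show", "PenaltySpec", function(object) {
  a <- if (length(object@alpha)) sprintf(", alpha = %g", object@alpha) else ""
  nw <- if (is(object@network, "NormalizedAdjacency"))
    sprintf(" [network: %d nodes]", length(object@network@nodeIds)) else ""
  cat(sprintf("PenaltySpec: %s, lambda = %g%s%s\n",
              object@family, object@lambda, a, nw))
})

setMethod("show", "PenalizedCoxModel", function(object) {
  cat(sprintf("PenalizedCoxModel (%s penalty, lambda = %g)\n",
              object@penalty@family, object@penalty@lambda))
  cat(sprintf("  %d coefficients (%d nonzero), %d iterations, converged: %s\n",
              length(object@beta), sum(object@beta != 0), object@nIter,
              object@converged))
  cat(sprintf("  baseline hazard over %d event times\n",
              length(object@baseline@time)))
})

setMethod("show", "CentralityRanking", function(object) {
  top <- object@nodeIds[object@order[seq_len(min(5L, length(object@order)))]]
  cat(sprintf("CentralityRanking (%s): %d vertices; top: %s\n",
              object@metric, length(object@scores),
              paste(top, collapse = ", ")))
})

setMethod("show", "CoxCVResult", function(object) {
  b <- object@grid[object@best, ]
  cat(sprintf("CoxCVResult: %d grid points, %d folds\n",
              nrow(object@grid), max(object@folds)))
  cat(sprintf("  best: %s lambda = %g%s (CV = %.4f)\n", b$family, b$lambda,
              if (is.na(b$alpha)) "" else sprintf(", alpha = %g", b$alpha),
              object@cvScores[object@best]))
})

setMethod("show", "RiskStratification", function(object) {
  tab <- table(object@groups)
  cat(sprintf("RiskStratification (%s): high %d / low %d / excluded %d\n",
              object@scheme, tab[["high"]], tab[["low"]], tab[["excluded"]]))
  cat(sprintf("  log-rank chi-square = %.4g, p = %.4g\n",
              object@logrankStat, object@logrankP))
})

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve: %d event times; S(max) = %.4f\n",
              length(object@time),
              if (length(object@survival)) min(object@survival) else 1))
})
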