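#' @include AllClasses.R AllGenerics.R network.R
NULL

#' Specify a penalty for Cox model fitting
#'
#' All penalties enter the objective as a subtracted term with an explicit
#' \eqn{\tfrac{1}{2}\lambda} factor, so \eqn{\lambda} values are comparable
#' across families:
#' \describe{
#'   \item{elastic_net}{\eqn{\tfrac{1}{2}\lambda(\alpha|\beta|_1 +
#'     (1-\alpha)|\beta|_2^2)}; \eqn{\alpha = 0} is ridge, \eqn{\alpha = 1}
#'     lasso.}
#'   \item{ridge / lasso}{aliases for the elastic-net endpoints with no
#'     \eqn{\alpha} parameter.}
#'   \item{laplacian}{\eqn{\tfrac{1}{2}\lambda\,
#'     \beta'((1-\alpha)(I - S) + \alpha I)\beta}: smoothness of
#'     coefficients across network edges, mixed with ridge by \eqn{\alpha}.}
#'   \item{degree}{\eqn{\tfrac{1}{2}\lambda\,\beta' D \beta} with
#'     \eqn{D_{ii} = 1/\sum_j s_{ij}} (inverse weighted degree), so
#'     well-connected features are penalized less.}
#' }
#'
#' @param family penalty family name.
#' @param lambda non-negative penalty strength.
#' @param alpha mixing parameter in \eqn{[0,1]}; required for
#'   `elastic_net` and `laplacian`, forbidden otherwise.
#' @param network a [NormalizedAdjacency-class]; required for `laplacian`
#'   and `degree`, forbidden otherwise. A [GeneNetwork-class] is normalized
#'   automatically.
#' @return a [PenaltySpec-class].
#' @examples
#' penaltySpec("ridge", lambda = 1)
#' @export
penaltySpec <- function(family = c("ridge", "lasso", "elastic_net",
                                   "laplacian", "degree"),
                        lambda, alpha = NULL, network = NULL) {
  family <- match.arg(family)
  if (!is.null(network) && is(network, "GeneNetwork"))
    network <- normalizeAdjacency(network)
  if (family %in% c("laplacian", "degree") && is.null(network))
    stop("family '", family, "' requires a network")
  new("PenaltySpec", family = family, lambda = as.numeric(lambda),
      alpha = if (is.null(alpha)) numeric() else as.numeric(alpha),
      network = network)
}

#' Elastic-net penalty value
#'
#' \eqn{\tfrac{1}{2}\lambda(\alpha|\beta|_1 + (1-\alpha)|\beta|_2^2)}.
#'
#' @param beta coefficient vector.
#' @param lambda penalty strength (\eqn{\ge 0}).
#' @param alpha L1/L2 balance in \eqn{[0,1]}.
#' @return the penalty value.
#' @export
elasticNetValue <- function(beta, lambda, alpha) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1)
  0.5 * lambda * (alpha * sum(abs(beta)) + (1 - alpha) * sum(beta^2))
}

#' Graph-Laplacian matrix of a normalized network
#'
#' \eqn{L = I - S}, the smoothness operator of the network-regularized
#' quadratic form \eqn{\beta' L \beta}. Note that the pairwise identity
#' \eqn{\tfrac{1}{2}\sum_{ij} S_{ij}(\beta_i-\beta_j)^2 = \beta'(I-S)\beta}
#' holds only when the row sums of \eqn{S} equal 1; the matrix form
#' \eqn{I - S} is the one used in the penalized objective regardless.
#'
#' @param S a [NormalizedAdjacency-class].
#' @return a symmetric \eqn{P \times P} matrix.
#' @export
laplacianMatrix <- function(S) {
  stopifnot(is(S, "NormalizedAdjacency"))
  M <- S@S
  if (is(M, "Matrix")) Matrix::Diagonal(nrow(M)) - M else diag(nrow(M)) - M
}

#' Laplacian (network smoothness) penalty value
#'
#' \eqn{\tfrac{1}{2}\lambda\,\beta'((1-\alpha)(I - S) + \alpha I)\beta}.
#' At \eqn{\alpha = 1} this is exactly the ridge penalty.
#'
#' @inheritParams elasticNetValue
#' @param S a [NormalizedAdjacency-class] (symmetric).
#' @return the penalty value.
#' @export
laplacianValue <- function(beta, S, lambda, alpha = 0) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1)
  if (length(beta) != nrow(S@S))
    stop("length(beta) must equal the network size")
  L <- laplacianMatrix(S)
  q <- as.numeric(t(beta) %*% L %*% beta)
  0.5 * lambda * ((1 - alpha) * q + alpha * sum(beta^2))
}

#' Inverse weighted-degree matrix
#'
#' Diagonal matrix with \eqn{D_{ii} = 1/\sum_j s_{ij}}, the inverse of the
#' vertex weighted degree. Isolated vertices (weighted degree 0) get
#' \eqn{D_{ii} = 1/\varepsilon} with \eqn{\varepsilon} the smallest positive
#' weighted degree in the network: they are penalized hardest, the
#' conservative reading of a penalty that favours well-connected features.
#' A network with no edges at all has no usable degrees and is rejected.
#'
#' @param S a [NormalizedAdjacency-class].
#' @return named numeric vector of the diagonal \eqn{D_{ii}} values.
#' @export
degreeMatrix <- function(S) {
  stopifnot(is(S, "NormalizedAdjacency"))
  wdeg <- Matrix::rowSums(S@S)
  pos <- wdeg[wdeg > 0]
  if (length(pos) == 0L)
    stop("network has no edges: weighted degrees are all zero")
  eps <- min(pos)
  d <- ifelse(wdeg > 0, 1 / wdeg, 1 / eps)
  stats::setNames(d, S@nodeIds)
}

#' Degree penalty quadratic form
#'
#' \eqn{\Upsilon(\beta) = \sum_i \beta_i^2 D_{ii} = \beta' D \beta} with
#' \eqn{D} from [degreeMatrix()]. In the fitted objective the penalty term
#' is \eqn{\tfrac{1}{2}\lambda\,\Upsilon(\beta)}. Hubs (large weighted
#' degree) contribute proportionally less for the same coefficient size.
#'
#' @param beta coefficient vector.
#' @param S a [NormalizedAdjacency-class].
#' @return the quadratic form value \eqn{\Upsilon(\beta)}.
#' @export
degreeValue <- function(beta, S) {
  d <- degreeMatrix(S)
  if (length(beta) != length(d))
    stop("length(beta) must equal the network size")
  sum(beta^2 * d)
}

#' Penalty value of a specification
#'
#' Evaluates the full penalty term \eqn{\tfrac{1}{2}\lambda(\cdot)} of a
#' [PenaltySpec-class] at `beta`.
#'
#' @param spec a [PenaltySpec-class].
#' @param beta coefficient vector.
#' @return the penalty value (0 at `beta = 0`).
#' @export
penaltyValue <- function(spec, beta) {
  stopifnot(is(spec, "PenaltySpec"))
  switch(spec@family,
    ridge = elasticNetValue(beta, spec@lambda, 0),
    lasso = elasticNetValue(beta, spec@lambda, 1),
    elastic_net = elasticNetValue(beta, spec@lambda, spec@alpha),
    laplacian = laplacianValue(beta, spec@network, spec@lambda, spec@alpha),
    degree = 0.5 * spec@lambda * degreeValue(beta, spec@network))
}

# Quadratic-part matrix M such that the smooth penalty is (1/2) lambda b'Mb.
# For elastic_net only the L2 part is returned; the L1 part goes through
# the prox. Diagonal matrices are returned as plain vectors.
.penaltyQuadratic <- function(spec, P) {
  switch(spec@family,
    ridge = rep(1, P),
    lasso = rep(0, P),
    elastic_net = rep(1 - spec@alpha, P),
    laplacian = {
      L <- as.matrix(laplacianMatrix(spec@network))
      (1 - spec@alpha) * L + spec@alpha * diag(P)
    },
    degree = as.numeric(degreeMatrix(spec@network)))
}

.penaltyL1Weight <- function(spec) {
  switch(spec@family,
    lasso = spec@lambda,
    elastic_net = spec@lambda * spec@alpha,
    0)
}

#' Gradient of a smooth penalty
#'
#' For the quadratic families (ridge, laplacian, degree, and the L2 part is
#' all there is when elastic_net has \eqn{\alpha = 0}), the gradient of
#' \eqn{\tfrac{1}{2}\lambda\,\beta' M \beta} is \eqn{\lambda M \beta}.
#' Families with an L1 component are not differentiable; use
#' [penaltyProx()].
#'
#' @param spec a [PenaltySpec-class].
#' @param beta coefficient vector.
#' @return gradient vector.
#' @export
penaltyGradient <- function(spec, beta) {
  stopifnot(is(spec, "PenaltySpec"))
  if (.penaltyL1Weight(spec) > 0)
    stop("penalty family '", spec@family,
         "' has an L1 component and is not differentiable; use penaltyProx()")
  M <- .penaltyQuadratic(spec, length(beta))
  if (is.matrix(M)) spec@lambda * as.numeric(M %*% beta)
  else spec@lambda * M * beta
}

#' Soft-thresholding proximal operator for the L1 part
#'
#' \eqn{prox(b) = sign(b)\,\max(|b| - t, 0)} applied elementwise with
#' threshold \eqn{t = step \cdot \tfrac{1}{2}\lambda\alpha} (the L1 weight of
#' the objective's \eqn{\tfrac{1}{2}\lambda\alpha|\beta|_1} term).
#'
#' @param spec a [PenaltySpec-class] with an L1 component.
#' @param beta coefficient vector.
#' @param step step size of the surrounding proximal update.
#' @return thresholded coefficient vector.
#' @export
penaltyProx <- function(spec, beta, step = 1) {
  stopifnot(is(spec, "PenaltySpec"))
  l1 <- .penaltyL1Weight(spec)
  if (l1 == 0)
    stop("penalty family '", spec@family,
         "' has no L1 component; use penaltyGradient()")
  softThreshold(beta, step * 0.5 * l1)
}

#' Elementwise soft threshold
#'
#' @param x numeric vector.
#' @param t non-negative threshold.
#' @return \eqn{sign(x)\max(|x| - t, 0)}.
#' @export
softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
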