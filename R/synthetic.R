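#' @include AllClasses.R AllGenerics.R network.R cox-likelihood.R
NULL

#' Simulate a weighted feature network
#'
#' Topologies: `scale_free` (preferential attachment, pronounced hubs),
#' `erdos_renyi` (uniform random edges), `star` and `path`. Edge weights are
#' drawn uniformly on \eqn{[0.25, 1]} so every topology is a positively
#' weighted network. Deterministic given `seed`.
#'
#' @param P number of vertices.
#' @param topology network topology.
#' @param edgeProb edge probability for `erdos_renyi` (default mean
#'   degree 4).
#' @param seed integer seed.
#' @return a [GeneNetwork-class] with nodes `g1..gP`.
#' @export
simulateNetwork <- function(P, topology = c("scale_free", "erdos_renyi",
                                            "star", "path"),
                            edgeProb = min(1, 4 / max(P - 1, 1)),
                            seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(P >= 2)
  set.seed(seed)
  g <- switch(topology,
    scale_free = igraph::sample_pa(P, power = 1, m = 2, directed = FALSE),
    erdos_renyi = igraph::sample_gnp(P, edgeProb),
    star = igraph::make_star(P, mode = "undirected"),
    path = igraph::make_ring(P, circular = FALSE))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  A[A > 1] <- 1
  ne <- sum(A) / 2
  if (ne > 0) {
    wts <- stats::runif(ne, 0.25, 1)
    W <- matrix(0, P, P)
    up <- which(upper.tri(A) & A > 0)
    W[up] <- wts
    W <- W + t(W)
  } else W <- matrix(0, P, P)
  GeneNetwork(W, paste0("g", seq_len(P)))
}

#' Simulate expression data correlated along network edges
#'
#' Draws samples from a multivariate normal whose correlation matrix places
#' \eqn{\rho} (default 0.6) on network-adjacent feature pairs, obtained by
#' eigenvalue-flooring \eqn{I + \rho A} to the nearest feasible correlation
#' matrix. Adjacent features are therefore strongly co-expressed (close to
#' \eqn{\rho}; hubs with many overlapping edges shrink it slightly), so
#' [buildGCN()] recovers planted edges on such data.
#'
#' @param n number of samples.
#' @param net a [GeneNetwork-class].
#' @param rho target correlation on edges.
#' @param seed integer seed.
#' @return an \eqn{n \times P} expression matrix with the network's node ids
#'   as column names.
#' @export
simulateExpression <- function(n, net, rho = 0.6, seed = 1L) {
  stopifnot(is(net, "GeneNetwork"), n >= 1)
  P <- length(net@nodeIds)
  A <- as.matrix(net@W)
  A[A > 0] <- 1
  Sigma <- diag(P) + rho * A
  ev <- eigen(Sigma, symmetric = TRUE)
  floorVal <- 0.05
  if (min(ev$values) < floorVal) {
    vals <- pmax(ev$values, floorVal)
    Sigma <- ev$vectors %*% (vals * t(ev$vectors))
    Sigma <- stats::cov2cor(Sigma)
  }
  set.seed(seed)
  X <- MASS::mvrnorm(n, mu = rep(0, P), Sigma = Sigma)
  X <- matrix(X, nrow = n)
  colnames(X) <- net@nodeIds
  X
}

#' Ground-truth coefficient patterns
#'
#' `hub_concentrated` places `effectSize` on the top-weighted-degree 10\% of
#' vertices (at least one); `random_sparse` places `effectSize` with random
#' signs on a random 10\% of vertices; `zero` is the null model.
#'
#' @param net a [GeneNetwork-class].
#' @param betaPattern pattern name.
#' @param effectSize coefficient magnitude.
#' @param seed integer seed (used by `random_sparse`).
#' @return named numeric coefficient vector over the network's vertices.
#' @export
trueBetaPattern <- function(net, betaPattern = c("hub_concentrated",
                                                 "random_sparse", "zero"),
                            effectSize = 1, seed = 1L) {
  betaPattern <- match.arg(betaPattern)
  P <- length(net@nodeIds)
  beta <- stats::setNames(rep(0, P), net@nodeIds)
  k <- max(1L, floor(0.1 * P))
  if (betaPattern == "hub_concentrated") {
    wd <- weightedDegree(normalizeAdjacency(net))
    beta[wd@order[seq_len(k)]] <- effectSize
  } else if (betaPattern == "random_sparse") {
    set.seed(seed)
    idx <- sample.int(P, k)
    beta[idx] <- effectSize * sample(c(-1, 1), k, replace = TRUE)
  }
  beta
}

#' Simulate right-censored survival times from a Cox model
#'
#' Event times are drawn by inverse-transform sampling from the proportional
#' hazards model \eqn{h(t|X) = h_0(t)\exp(X'\beta)} with a Weibull baseline
#' \eqn{H_0(t) = (t/scale)^{shape}}:
#' \eqn{T = scale\,(-\log U\,e^{-X'\beta})^{1/shape}}. Censoring times are
#' uniform on \eqn{[0, c]} with \eqn{c} calibrated by bisection so the
#' expected censored fraction matches `censorRate`.
#'
#' @param X expression matrix (samples by features).
#' @param beta true coefficient vector.
#' @param censorRate target censored fraction in \eqn{[0, 1)}.
#' @param weibullShape,weibullScale baseline hazard parameters
#'   (shape 1 = exponential baseline with mean `weibullScale` at
#'   \eqn{\beta = 0}).
#' @param seed integer seed.
#' @return a list with `data` (a [CoxSurvivalData-class]) and `trueBeta`.
#' @export
simulateSurvival <- function(X, beta, censorRate = 0.3, weibullShape = 1.5,
                             weibullScale = 1, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(ncol(X) == length(beta), censorRate >= 0, censorRate < 1)
  set.seed(seed)
  eta <- as.numeric(X %*% beta)
  U <- stats::runif(n)
  T <- weibullScale * (-log(U) * exp(-eta))^(1 / weibullShape)
  if (censorRate == 0) {
    time <- T
    status <- rep(1L, n)
  } else {
    # E[censored fraction | T] for C ~ U(0, c) is mean(min(T/c, 1));
    # decreasing in c, so bisect.
    expCens <- function(cc) mean(pmin(T / cc, 1))
    lo <- min(T) * 1e-3; hi <- max(T) * 1e3
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (expCens(mid) > censorRate) lo <- mid else hi <- mid
    }
    cmax <- (lo + hi) / 2
    C <- stats::runif(n, 0, cmax)
    status <- as.integer(T <= C)
    time <- pmin(T, C)
  }
  data <- CoxSurvivalData(X, time = time, status = status)
  list(data = data, trueBeta = beta)
}

#' Simulate a full study: network, expression and survival
#'
#' Convenience wrapper chaining [simulateNetwork()], [simulateExpression()],
#' [trueBetaPattern()] and [simulateSurvival()] with sub-seeds derived from
#' `seed`, giving bit-reproducible datasets with known ground truth.
#'
#' @param n samples; `P` features.
#' @param P number of features.
#' @param topology passed to [simulateNetwork()].
#' @param betaPattern,effectSize passed to [trueBetaPattern()].
#' @param censorRate,weibullShape,weibullScale passed to
#'   [simulateSurvival()].
#' @param rho edge correlation passed to [simulateExpression()].
#' @param seed master integer seed.
#' @return list with `network` ([GeneNetwork-class]), `data`
#'   ([CoxSurvivalData-class]) and `trueBeta`.
#' @export
simulateDataset <- function(n, P, topology = "scale_free",
                            betaPattern = "hub_concentrated",
                            effectSize = 1, censorRate = 0.3,
                            weibullShape = 1.5, weibullScale = 1,
                            rho = 0.6, seed = 1L) {
  seed <- as.integer(seed)
  net <- simulateNetwork(P, topology, seed = seed)
  X <- simulateExpression(n, net, rho = rho, seed = seed + 1L)
  beta <- trueBetaPattern(net, betaPattern, effectSize, seed = seed + 2L)
  sim <- simulateSurvival(X, beta, censorRate, weibullShape, weibullScale,
                          seed = seed + 3L)
  list(network = net, data = sim$data, trueBeta = beta)
}
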