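#' @include AllClasses.R AllGenerics.R network.R
NULL

# deterministic descending ranking; ties broken by vertex index
.makeRanking <- function(metric, nodeIds, scores) {
  ord <- order(-scores, seq_along(scores))
  new("CentralityRanking", metric = metric, nodeIds = nodeIds,
      scores = as.numeric(scores), order = as.integer(ord))
}

.centralityInput <- function(x) {
  if (is(x, "GeneNetwork")) normalizeAdjacency(x)
  else if (is(x, "NormalizedAdjacency")) x
  else normalizeAdjacency(GeneNetwork(x))
}

#' Degree centrality (edge count)
#'
#' \eqn{d_i = \sum_j a_{ij}} with \eqn{a_{ij} = 1} when an edge connects
#' \eqn{i} and \eqn{j}: the number of adjacent edges of each vertex.
#'
#' @param net a [GeneNetwork-class] or [NormalizedAdjacency-class].
#' @return a [CentralityRanking-class].
#' @export
degreeCentrality <- function(net) {
  S <- .centralityInput(net)
  M <- S@S
  d <- Matrix::rowSums(M != 0)
  .makeRanking("degree", S@nodeIds, d)
}

#' Weighted degree centrality
#'
#' \eqn{d_i = \sum_j s_{ij}}: the row sums of the normalized adjacency, the
#' weighted extension of the edge count.
#'
#' @inheritParams degreeCentrality
#' @return a [CentralityRanking-class].
#' @export
weightedDegree <- function(net) {
  S <- .centralityInput(net)
  .makeRanking("weighted_degree", S@nodeIds, Matrix::rowSums(S@S))
}

#' Betweenness centrality
#'
#' \eqn{B_i = \sum_{j < k} g_{jk}(y_i) / g_{jk}}, the frequency with which
#' vertex \eqn{i} lies on shortest paths between other vertex pairs, counting
#' all shortest paths with multiplicity (exact Brandes accumulation via
#' igraph, no sampling). With `distance = "transform"` edge lengths are
#' \eqn{\log(1/s_{ij})} (see [distanceWeights()]), so strongly connected
#' vertices sit on short paths; `"unit"` treats every edge as length 1.
#'
#' @inheritParams degreeCentrality
#' @param distance `"transform"` (default) or `"unit"`.
#' @return a [CentralityRanking-class].
#' @export
betweennessCentrality <- function(net, distance = c("transform", "unit")) {
  S <- .centralityInput(net)
  g <- .asIgraph(S, match.arg(distance))
  b <- if (igraph::ecount(g) == 0) numeric(length(S@nodeIds))
       else igraph::betweenness(g, weights = igraph::E(g)$length,
                                directed = FALSE)
  .makeRanking("betweenness", S@nodeIds, b)
}

#' Closeness centrality
#'
#' \eqn{c_i = 1 / \sum_{j \ne i} g_{ji}} where \eqn{g_{ji}} is the
#' shortest-path length from \eqn{j} to \eqn{i}. Requires a connected graph:
#' with `mode = "error"` (default) a disconnected input is rejected with the
#' component sizes named. `mode = "component"` instead computes closeness
#' within each connected component and scales by
#' \eqn{(|C_i| - 1)/(P - 1)} so scores remain comparable across components;
#' fully isolated vertices score 0.
#'
#' @inheritParams betweennessCentrality
#' @param mode `"error"` or `"component"`.
#' @return a [CentralityRanking-class].
#' @export
closenessCentrality <- function(net, distance = c("transform", "unit"),
                                mode = c("error", "component")) {
  S <- .centralityInput(net)
  mode <- match.arg(mode)
  g <- .asIgraph(S, match.arg(distance))
  P <- length(S@nodeIds)
  comp <- igraph::components(g)
  if (comp$no > 1 && mode == "error")
    stop("graph is disconnected (", comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "),
         "); use mode = \"component\" for per-component closeness")
  D <- igraph::distances(g, weights = igraph::E(g)$length)
  cl <- numeric(P)
  for (cid in seq_len(comp$no)) {
    idx <- which(comp$membership == cid)
    if (length(idx) == 1L) { cl[idx] <- 0; next }
    tot <- rowSums(D[idx, idx, drop = FALSE])
    ci <- ifelse(tot > 0, 1 / tot, 0)
    if (mode == "component" && P > 1)
      ci <- ci * (length(idx) - 1) / (P - 1)
    cl[idx] <- ci
  }
  .makeRanking("closeness", S@nodeIds, cl)
}

#' Overlap of two top-k centrality rankings
#'
#' The fraction \eqn{|top_k(A) \cap top_k(B)| / k} of shared vertices among
#' the k top-ranked of each metric; symmetric in its two arguments.
#'
#' @param rankA,rankB [CentralityRanking-class] objects over the same
#'   vertex set.
#' @param k number of top vertices to compare (\eqn{0 < k \le P}).
#' @return fraction in \eqn{[0, 1]}.
#' @export
topRankOverlap <- function(rankA, rankB, k) {
  stopifnot(is(rankA, "CentralityRanking"), is(rankB, "CentralityRanking"))
  if (k <= 0) stop("k must be positive")
  if (k > length(rankA@scores)) stop("k exceeds the number of vertices")
  length(intersect(topRanked(rankA, k), topRanked(rankB, k))) / k
}

#' Retention of top-ranked vertices under edge thresholding
#'
#' Computes the reference top-k of a centrality metric on the starting
#' network, then, for each ascending threshold, re-ranks the thresholded
#' sub-network and reports the fraction of the reference top-k still in the
#' new top-k. On sub-networks where every score is zero (fully
#' disconnected), ranking falls back to vertex index, so retention reflects
#' the index tie-break. Closeness is computed in per-component mode since
#' thresholding routinely disconnects the graph.
#'
#' @param S a [NormalizedAdjacency-class] (the starting network).
#' @param thresholds ascending numeric thresholds.
#' @param k reference top-k size.
#' @param metric one of `"degree"`, `"weighted_degree"`, `"betweenness"`,
#'   `"closeness"`.
#' @param distance passed to the shortest-path metrics.
#' @return data.frame with columns `threshold`, `nEdges`, `retained`.
#' @export
rankRetentionCurve <- function(S, thresholds, k,
                               metric = c("weighted_degree", "degree",
                                          "betweenness", "closeness"),
                               distance = "transform") {
  stopifnot(is(S, "NormalizedAdjacency"))
  metric <- match.arg(metric)
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  rankFun <- switch(metric,
    degree = degreeCentrality,
    weighted_degree = weightedDegree,
    betweenness = function(x) betweennessCentrality(x, distance),
    closeness = function(x) closenessCentrality(x, distance,
                                                mode = "component"))
  ref <- topRanked(rankFun(S), k)
  out <- lapply(thresholds, function(th) {
    sub <- thresholdNetwork(S, th)
    kept <- topRanked(rankFun(sub), k)
    data.frame(threshold = th, nEdges = attr(sub, "nEdges"),
               retained = length(intersect(ref, kept)) / k)
  })
  do.call(rbind, out)
}
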