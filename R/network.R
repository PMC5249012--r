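#' @include AllClasses.R AllGenerics.R
NULL

# sparse storage above this many nodes; contract identical either way
.SPARSE_THRESHOLD <- 2000L

.asStorage <- function(M) {
  if (nrow(M) > .SPARSE_THRESHOLD && !is(M, "Matrix"))
    Matrix::Matrix(M, sparse = TRUE)
  else M
}

#' Construct a weighted gene network
#'
#' Validating constructor for [GeneNetwork-class]. The adjacency must be
#' square, symmetric and non-negative; the diagonal must be zero (self loops
#' carry no meaning for the penalties built on the network).
#'
#' @param W square symmetric non-negative weight matrix (dense or sparse).
#' @param nodeIds node labels; defaults to `rownames(W)` or `v1..vP`.
#' @return a [GeneNetwork-class].
#' @examples
#' net <- GeneNetwork(rbind(c(0, 4), c(4, 0)), c("a", "b"))
#' adjacency(net)
#' @export
GeneNetwork <- function(W, nodeIds = NULL) {
  if (is.data.frame(W)) W <- as.matrix(W)
  if (nrow(W) != ncol(W))
    stop("adjacency matrix must be square, got ", nrow(W), " x ", ncol(W))
  if (is.null(nodeIds))
    nodeIds <- if (!is.null(rownames(W))) rownames(W)
               else paste0("v", seq_len(nrow(W)))
  W <- .asStorage(unname(as.matrix(W) * 1))
  new("GeneNetwork", nodeIds = as.character(nodeIds), W = .asStorage(W))
}

#' Normalize adjacency weights by row/column degree
#'
#' Computes \eqn{s_{ij} = w_{ij}\,(\sum_n w_{in})^{-1/2}(\sum_n w_{nj})^{-1/2}},
#' i.e. each weight divided by the square root of the sum over its row and of
#' the sum over its column. The result is scale invariant:
#' `normalizeAdjacency` of \eqn{cW} equals that of \eqn{W} for any
#' \eqn{c > 0}. Vertices with zero row/column sums get all-zero rows in
#' \eqn{S} and are recorded as isolated.
#'
#' @param net a [GeneNetwork-class] (or a raw adjacency matrix).
#' @return a [NormalizedAdjacency-class].
#' @examples
#' net <- GeneNetwork(rbind(c(0, 4), c(4, 0)))
#' adjacency(normalizeAdjacency(net))  # off-diagonal entries are 1
#' @export
normalizeAdjacency <- function(net) {
  if (!is(net, "GeneNetwork")) net <- GeneNetwork(net)
  W <- net@W
  rs <- Matrix::rowSums(W)
  cs <- Matrix::colSums(W)
  isolated <- which(rs + cs == 0)
  ri <- ifelse(rs > 0, 1 / sqrt(rs), 0)
  ci <- ifelse(cs > 0, 1 / sqrt(cs), 0)
  S <- if (is(W, "Matrix")) {
    Matrix::Diagonal(x = ri) %*% W %*% Matrix::Diagonal(x = ci)
  } else {
    W * outer(ri, ci)
  }
  new("NormalizedAdjacency", nodeIds = net@nodeIds, S = .asStorage(S),
      isolated = as.integer(isolated))
}

#' Build a gene co-expression network from mutual correlation ranks
#'
#' For each ordered gene pair \eqn{(i, j)}, \eqn{r_{ij}} is the rank position
#' (1 = strongest) of gene \eqn{j} among all correlates of gene \eqn{i}
#' (self excluded), by Pearson correlation. The edge weight is the mutual
#' rank product inverse \eqn{1 / (r_{ij} \cdot r_{ji})}, symmetric by
#' construction and in \eqn{(0, 1]}; mutual top correlates get weight 1.
#'
#' @param expr numeric matrix, rows = samples, columns = features (named).
#' @param signed if `FALSE` (default) rank by absolute correlation
#'   (co-expression strength); if `TRUE` rank by the signed coefficient.
#' @return a [GeneNetwork-class] on the expression features.
#' @examples
#' set.seed(1)
#' expr <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
#' buildGCN(expr)
#' @export
buildGCN <- function(expr, signed = FALSE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) stop("at least 3 samples are required to rank correlations")
  if (is.null(colnames(expr))) colnames(expr) <- paste0("g", seq_len(ncol(expr)))
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(expr)[sds == 0], 10), collapse = ", "))
  C <- stats::cor(expr)
  if (!signed) C <- abs(C)
  P <- ncol(C)
  diag(C) <- -Inf                       # self excluded from every ranking
  # R[i, j] = rank of gene j among correlates of gene i, ties by feature index
  R <- t(apply(C, 1, function(row) rank(-row, ties.method = "first")))
  W <- 1 / (R * t(R))
  diag(W) <- 0
  GeneNetwork(W, colnames(expr))
}

#' Drop weak edges from a normalized network
#'
#' Entries of \eqn{S} strictly below `theta` are set to zero; all others are
#' unchanged. Thresholding is monotone: a larger `theta` keeps a subset of
#' the edges kept by a smaller one.
#'
#' @param S a [NormalizedAdjacency-class].
#' @param theta non-negative threshold.
#' @return a [NormalizedAdjacency-class] with the surviving edges; the number
#'   of edges kept is attached as attribute `"nEdges"`.
#' @export
thresholdNetwork <- function(S, theta) {
  stopifnot(is(S, "NormalizedAdjacency"), theta >= 0)
  M <- S@S
  M[M < theta] <- 0
  rs <- Matrix::rowSums(M)
  out <- new("NormalizedAdjacency", nodeIds = S@nodeIds, S = M,
             isolated = as.integer(which(rs + Matrix::colSums(M) == 0)))
  attr(out, "nEdges") <- as.integer(sum(M != 0) / 2)
  out
}

#' Shortest-path edge lengths from normalized weights
#'
#' High normalized weights mean strong ties, so for shortest-path metrics
#' (betweenness, closeness) each edge weight is transformed to a length
#' \eqn{s'_{ij} = \log(1 / s_{ij})}: strong edges become short. Absent edges
#' (\eqn{s_{ij} = 0}) stay absent (infinite distance). Entries above 1, which
#' can arise from asymmetric row/column sums, would give negative lengths and
#' are clamped to 1 with a warning.
#'
#' @param S a [NormalizedAdjacency-class].
#' @return matrix of edge lengths; `Inf` marks "no edge", diagonal 0.
#' @export
distanceWeights <- function(S) {
  stopifnot(is(S, "NormalizedAdjacency"))
  M <- as.matrix(S@S)
  if (any(M > 1)) {
    warning(sum(M > 1), " normalized weight(s) exceed 1; clamped to 1 ",
            "(edge length 0)")
    M[M > 1] <- 1
  }
  D <- matrix(Inf, nrow(M), ncol(M), dimnames = list(S@nodeIds, S@nodeIds))
  D[M > 0] <- log(1 / M[M > 0])
  diag(D) <- 0
  D
}

# igraph view of a normalized network, with edge lengths for path metrics.
# distance = "transform" applies the log(1/s) mapping; "unit" uses length-1
# edges (unweighted shortest paths).
.asIgraph <- function(S, distance = c("transform", "unit")) {
  distance <- match.arg(distance)
  M <- as.matrix(S@S)
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  w <- igraph::E(g)$weight
  igraph::E(g)$length <- if (distance == "transform") {
    if (any(w > 1)) w[w > 1] <- 1
    # w = 1 gives length 0 (only mutual-degree-1 dyads); igraph requires
    # strictly positive weights, and a vanishing length leaves all shortest
    # paths unchanged
    pmax(log(1 / w), 1e-8)
  } else rep(1, length(w))
  g
}
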