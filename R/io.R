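#' @include AllClasses.R AllGenerics.R network.R cox-likelihood.R
NULL

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read an expression matrix
#'
#' TSV/CSV with a header of feature ids; first column holds the sample ids,
#' remaining cells the expression values (rows = samples).
#'
#' @param path file path (`.csv` uses comma, anything else tab).
#' @return numeric matrix, rownames = sample ids, colnames = feature ids.
#' @export
readExpressionMatrix <- function(path) {
  df <- .readTable(path)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric expression values in ", path)
  rownames(M) <- ids
  M
}

#' Write an expression matrix
#'
#' @param X matrix with sample rownames and feature colnames.
#' @param path output TSV path.
#' @export
writeExpressionMatrix <- function(X, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a survival table
#'
#' TSV/CSV with header `sample_id`, `time`, `status`; times must be
#' positive and status exactly 0 or 1 (anything else is a parse error).
#'
#' @param path file path.
#' @return data.frame with the three validated columns.
#' @export
readSurvivalTable <- function(path) {
  df <- .readTable(path)
  need <- c("sample_id", "time", "status")
  if (!all(need %in% names(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$time <- as.numeric(df$time)
  if (any(is.na(df$time) | df$time <= 0))
    stop("all survival times must be positive numbers")
  if (!all(df$status %in% c(0, 1)))
    stop("status values must be 0 or 1; offending values: ",
         paste(utils::head(unique(df$status[!df$status %in% c(0, 1)]), 5),
               collapse = ", "))
  df$status <- as.integer(df$status)
  df
}

#' Write a survival table
#'
#' @param data a [CoxSurvivalData-class].
#' @param path output TSV path.
#' @export
writeSurvivalTable <- function(data, path) {
  utils::write.table(
    data.frame(sample_id = data@sampleIds, time = data@time,
               status = data@status),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an undirected weighted edge list
#'
#' TSV with header `node_a`, `node_b`, `weight` (each undirected pair listed
#' once, positive weights). Node order follows first appearance.
#'
#' @param path file path.
#' @param nodeIds optional full node set (isolated vertices are kept).
#' @return a [GeneNetwork-class].
#' @export
readEdgeList <- function(path, nodeIds = NULL) {
  df <- .readTable(path)
  need <- c("node_a", "node_b", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  df$weight <- as.numeric(df$weight)
  if (any(is.na(df$weight) | df$weight <= 0))
    stop("edge weights must be positive")
  ids <- if (is.null(nodeIds))
    unique(c(rbind(as.character(df$node_a), as.character(df$node_b))))
  else as.character(nodeIds)
  P <- length(ids)
  W <- matrix(0, P, P)
  ia <- match(df$node_a, ids); ib <- match(df$node_b, ids)
  if (anyNA(ia) || anyNA(ib)) stop("edge references a node not in nodeIds")
  if (any(ia == ib)) stop("self loops are not allowed")
  W[cbind(ia, ib)] <- df$weight
  W[cbind(ib, ia)] <- df$weight
  GeneNetwork(W, ids)
}

#' Write a network as an undirected edge list
#'
#' @param net a [GeneNetwork-class].
#' @param path output TSV path.
#' @export
writeEdgeList <- function(net, path) {
  W <- as.matrix(net@W)
  up <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(node_a = net@nodeIds[up[, 1]],
                   node_b = net@nodeIds[up[, 2]],
                   weight = W[up])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a dense adjacency matrix
#'
#' CSV/TSV with node ids as both the header row and the first column.
#'
#' @param path file path.
#' @return a [GeneNetwork-class].
#' @export
readAdjacencyMatrix <- function(path) {
  df <- .readTable(path)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(M), ids))
    stop("header ids and first-column ids must match (same order)")
  GeneNetwork(unname(M), ids)
}

#' Load and match an expression matrix with a survival table
#'
#' Samples are matched by id; the intersection is kept in expression-file
#' order. Mismatches are reported (up to 10 examples each way); zero overlap
#' is an error.
#'
#' @param exprPath expression matrix file (see [readExpressionMatrix()]).
#' @param survPath survival table file (see [readSurvivalTable()]).
#' @return a [CoxSurvivalData-class].
#' @export
loadDataset <- function(exprPath, survPath) {
  X <- readExpressionMatrix(exprPath)
  surv <- readSurvivalTable(survPath)
  common <- intersect(rownames(X), surv$sample_id)
  if (length(common) == 0L)
    stop("no overlapping sample ids between expression and survival files")
  dropX <- setdiff(rownames(X), common)
  dropS <- setdiff(surv$sample_id, common)
  if (length(dropX))
    warning(length(dropX), " expression sample(s) without survival data ",
            "dropped (e.g. ", paste(utils::head(dropX, 10), collapse = ", "), ")")
  if (length(dropS))
    warning(length(dropS), " survival sample(s) without expression data ",
            "dropped (e.g. ", paste(utils::head(dropS, 10), collapse = ", "), ")")
  keep <- rownames(X)[rownames(X) %in% common]    # expression-file order
  idx <- match(keep, surv$sample_id)
  CoxSurvivalData(X[keep, , drop = FALSE], time = surv$time[idx],
                  status = surv$status[idx], sampleIds = keep)
}

#' Restrict a network and a dataset to their common features
#'
#' Both objects are reduced to the intersection of their feature ids, in the
#' dataset's feature order; an empty intersection is an error.
#'
#' @param net a [GeneNetwork-class] or [NormalizedAdjacency-class].
#' @param data a [CoxSurvivalData-class].
#' @return list with the aligned `network` and `data`.
#' @export
alignNetwork <- function(net, data) {
  stopifnot(is(data, "CoxSurvivalData"))
  nids <- nodeIds(net)
  fids <- featureIds(data)
  common <- fids[fids %in% nids]
  if (length(common) == 0L)
    stop("network and dataset share no feature ids")
  if (length(common) < length(fids) || length(common) < length(nids))
    message("alignNetwork: keeping ", length(common), " common features (",
            length(fids), " in data, ", length(nids), " in network)")
  idx <- match(common, nids)
  outNet <- if (is(net, "GeneNetwork"))
    GeneNetwork(as.matrix(net@W)[idx, idx, drop = FALSE], common)
  else new("NormalizedAdjacency", nodeIds = common,
           S = .asStorage(as.matrix(net@S)[idx, idx, drop = FALSE]),
           isolated = as.integer(which(Matrix::rowSums(
             as.matrix(net@S)[idx, idx, drop = FALSE]) == 0)))
  newData <- CoxSurvivalData(data@X[, common, drop = FALSE],
                             time = data@time, status = data@status,
                             sampleIds = data@sampleIds)
  list(network = outNet, data = newData)
}

#' Serialize a fitted model to structured text (JSON)
#'
#' Stores coefficients (feature id to value, standardized scale), the
#' centering/scaling, the Breslow baseline table, the penalty family and
#' parameters, and convergence metadata. The penalty's network is not
#' embedded; reload it from its own file if needed.
#'
#' @param model a [PenalizedCoxModel-class].
#' @param path output path.
#' @export
writeCoxModel <- function(model, path) {
  stopifnot(is(model, "PenalizedCoxModel"))
  obj <- list(
    format = "graphCox-model/1",
    penalty = list(family = model@penalty@family,
                   lambda = model@penalty@lambda,
                   alpha = if (length(model@penalty@alpha))
                     model@penalty@alpha else NULL),
    beta = as.list(model@beta),
    center = as.list(model@center),
    scale = as.list(model@scale),
    baseline = list(time = model@baseline@time, h0 = model@baseline@h0,
                    nEvents = model@baseline@nEvents),
    converged = model@converged,
    nIter = model@nIter,
    objectiveTrace = model@objectiveTrace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Read a serialized model back
#'
#' Restores a [PenalizedCoxModel-class] written by [writeCoxModel()]. The
#' penalty spec is restored without its network (network-based penalties get
#' a spec usable for inspection, not refitting).
#'
#' @param path model file path.
#' @return a [PenalizedCoxModel-class].
#' @export
readCoxModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "graphCox-model/1"))
    stop("not a graphCox model file: ", path)
  fam <- obj$penalty$family
  # network-based penalties are restored as a bare spec of the same family
  spec <- if (fam %in% c("laplacian", "degree")) {
    s <- new("PenaltySpec", family = fam, lambda = obj$penalty$lambda,
             alpha = if (!is.null(obj$penalty$alpha))
               as.numeric(obj$penalty$alpha) else numeric(),
             network = NULL)
    s
  } else {
    penaltySpec(fam, lambda = obj$penalty$lambda,
                alpha = obj$penalty$alpha)
  }
  h0 <- as.numeric(obj$baseline$h0)
  new("PenalizedCoxModel",
      beta = unlist(obj$beta),
      center = unlist(obj$center),
      scale = unlist(obj$scale),
      baseline = new("BaselineHazard", time = as.numeric(obj$baseline$time),
                     h0 = h0, H0 = cumsum(h0),
                     nEvents = as.integer(obj$baseline$nEvents)),
      penalty = spec,
      objectiveTrace = as.numeric(obj$objectiveTrace),
      converged = isTRUE(obj$converged),
      nIter = as.integer(obj$nIter))
}
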