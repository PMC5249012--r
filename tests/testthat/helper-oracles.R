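# Independent brute-force oracles and tiny fixture builders used across the
# suite. Everything here is deliberately naive (direct summation, exhaustive
# path enumeration, all-pairs loops) and shares no code with the package
# internals it checks.

# --- graphs -----------------------------------------------------------------

# random symmetric weighted adjacency on p vertices; weights bounded away
# from zero so shortest paths are well defined
randomAdjacency <- function(p, edgeProb = 0.45) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (stats::runif(1) < edgeProb) W[i, j] <- W[j, i] <- stats::runif(1, 0.2, 1)
  }
  W
}

# all-pairs shortest path lengths by Floyd-Warshall on an edge-length matrix
# (Inf = no edge, 0 diagonal)
floydWarshall <- function(L) {
  p <- nrow(L)
  D <- L
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# exhaustive enumeration of all shortest paths between every vertex pair by
# depth-first search over simple paths (pruned at the best known length);
# returns betweenness of every vertex counting path multiplicity
bruteBetweenness <- function(L) {
  p <- nrow(L)
  btw <- numeric(p)
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    best <- Inf
    paths <- list()
    stack <- list(list(v = j, len = 0, path = j))
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (nd$len > best + 1e-9) next
      if (nd$v == k) {
        if (nd$len < best - 1e-9) { best <- nd$len; paths <- list() }
        if (nd$len <= best + 1e-9) paths[[length(paths) + 1L]] <- nd$path
        next
      }
      nbr <- which(is.finite(L[nd$v, ]) & seq_len(p) != nd$v)
      for (w in nbr) {
        if (w %in% nd$path) next
        stack[[length(stack) + 1L]] <-
          list(v = w, len = nd$len + L[nd$v, w], path = c(nd$path, w))
      }
    }
    if (!length(paths)) next
    g_jk <- length(paths)
    for (v in seq_len(p)) {
      if (v == j || v == k) next
      g_through <- sum(vapply(paths, function(pp) v %in% pp, logical(1)))
      btw[v] <- btw[v] + g_through / g_jk
    }
  }
  btw
}

# closeness from Floyd-Warshall distances: 1 / sum of distances to others
bruteCloseness <- function(L) {
  D <- floydWarshall(L)
  1 / rowSums(D)
}

# --- Cox likelihood ----------------------------------------------------------

# term-by-term partial log-likelihood, straight from the definition
brutePartialLogLik <- function(beta, X, time, status) {
  eta <- as.numeric(X %*% beta)
  total <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    total <- total + eta[i] - log(sum(exp(eta[risk])))
  }
  total
}

# Breslow increments per distinct event time, straight from the definition
bruteBreslow <- function(beta, X, time, status) {
  eta <- as.numeric(X %*% beta)
  evt <- sort(unique(time[status == 1]))
  h0 <- vapply(evt, function(t) {
    d <- sum(status == 1 & time == t)
    d / sum(exp(eta[time >= t]))
  }, numeric(1))
  list(time = evt, h0 = h0)
}

# --- concordance -------------------------------------------------------------

# exhaustive pair enumeration following the printed case analysis
bruteCindex <- function(pi, time, status, rule = "standard") {
  n <- length(pi)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (status[i] == 0 && status[j] == 0) next
    if (status[i] != status[j]) {
      cens <- if (status[i] == 0) i else j
      ev <- if (cens == i) j else i
      if (time[cens] < time[ev]) next          # censored before the event
      den <- den + 1
      if (rule == "standard") {
        num <- num + (if (pi[ev] > pi[cens]) 1
                      else if (pi[ev] == pi[cens]) 0.5 else 0)
      } else {
        num <- num + (if (pi[ev] > pi[cens]) 1 else 0.5)
      }
    } else {                                    # both events
      den <- den + 1
      if (time[i] == time[j]) {
        num <- num + (if (rule == "paper_literal" && pi[i] == pi[j]) 1 else 0.5)
      } else {
        short <- if (time[i] < time[j]) i else j
        long <- if (short == i) j else i
        if (rule == "standard") {
          num <- num + (if (pi[short] > pi[long]) 1
                        else if (pi[short] == pi[long]) 0.5 else 0)
        } else {
          num <- num + (if (pi[short] > pi[long]) 1 else 0.5)
        }
      }
    }
  }
  num / den
}

# --- survival fixtures -------------------------------------------------------

randomSurvData <- function(n, P, seed, censorProb = 0.3, ties = FALSE) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * P), n, P,
              dimnames = list(NULL, paste0("f", seq_len(P))))
  time <- if (ties) sample(1:max(2, ceiling(n / 2)), n, replace = TRUE)
          else stats::rexp(n) + 0.05
  status <- stats::rbinom(n, 1, 1 - censorProb)
  if (sum(status) == 0) status[sample(n, 1)] <- 1L
  CoxSurvivalData(X, time = time, status = status)
}

# two-group log-rank statistic by direct observed-minus-expected accumulation
bruteLogrank <- function(time, status, group) {
  g <- as.integer(factor(group))
  evt <- sort(unique(time[status == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in evt) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1)
    d <- sum(status == 1 & time == t)
    d1 <- sum(status == 1 & time == t & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
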