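#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a right-censored survival dataset
#'
#' @param X numeric samples-by-features covariate matrix; feature ids are
#'   taken from `colnames` (defaults `f1..fP`).
#' @param time positive follow-up times.
#' @param status event indicators (1 = event, 0 = censored).
#' @param sampleIds sample labels; defaults to `rownames(X)` or `s1..sn`.
#' @return a [CoxSurvivalData-class].
#' @examples
#' d <- CoxSurvivalData(matrix(rnorm(6), 3, 2), time = c(1, 2, 3),
#'                      status = c(1, 0, 1))
#' survTime(d)
#' @export
CoxSurvivalData <- function(X, time, status, sampleIds = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(X))) rownames(X)
                 else paste0("s", seq_len(nrow(X)))
  rownames(X) <- NULL
  new("CoxSurvivalData", sampleIds = as.character(sampleIds), X = X,
      time = as.numeric(time), status = as.integer(status))
}

# Sorted-view risk-set quantities shared by likelihood, score, information
# and Breslow estimation. Breslow tie handling: events at a tied time share
# the risk set; censored subjects tied with an event time are at risk at that
# time (sorting is by time only, risk set = all with y_j >= t_k). A single
# log-sum-exp shift m = max(eta) guards exp overflow.
.coxRisk <- function(X, time, status, beta, need = "loglik") {
  ord <- order(time)
  X <- X[ord, , drop = FALSE]
  time <- time[ord]
  status <- status[ord]
  n <- length(time)
  eta <- as.numeric(X %*% beta)
  m <- max(eta)
  w <- exp(eta - m)
  evIdx <- which(status == 1L)
  evTimes <- sort(unique(time[evIdx]))
  K <- length(evTimes)
  f <- match(evTimes, time)                      # first index of risk set k
  revS0 <- rev(cumsum(rev(w)))
  S0 <- revS0[f]
  evGroup <- match(time[evIdx], evTimes)
  dks <- tabulate(evGroup, nbins = K)
  loglik <- sum(eta[evIdx]) - sum(dks * (m + log(S0)))
  out <- list(loglik = loglik, evTimes = evTimes, S0 = S0, d = dks,
              shift = m, order = ord)
  if (need == "loglik") return(out)

  WX <- X * w
  revS1 <- if (n == 1L) WX
           else apply(WX[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  S1 <- revS1[f, , drop = FALSE]                 # K x P
  sumXEv <- rowsum(X[evIdx, , drop = FALSE], evGroup, reorder = TRUE)
  xbar <- S1 / S0
  out$grad <- colSums(sumXEv) - colSums(dks * xbar)
  if (need == "grad") return(out)

  out$info <- .coxInfoCpp(X, w, as.integer(f), S0,
                          matrix(xbar, nrow = K), as.integer(dks))
  out
}

.dataParts <- function(data) {
  if (is(data, "CoxSurvivalData"))
    list(X = data@X, time = data@time, status = as.integer(data@status))
  else if (is.list(data) && all(c("X", "time", "status") %in% names(data)))
    list(X = as.matrix(data$X), time = as.numeric(data$time),
         status = as.integer(data$status))
  else stop("data must be a CoxSurvivalData or a list(X, time, status)")
}

#' Cox partial log-likelihood
#'
#' \deqn{l(\beta) = \sum_i \delta_i \{ X_i'\beta -
#'   \log \sum_{j: y_j \ge y_i} \exp(X_j'\beta) \}}
#' evaluated with Breslow handling of tied event times (shared risk sets)
#' and a log-sum-exp guard against overflow. With no events the sum is
#' empty and the value is 0.
#'
#' @param beta coefficient vector, length \eqn{P}.
#' @param data a [CoxSurvivalData-class], or a `list(X, time, status)` (the
#'   list form also admits degenerate inputs such as fully censored data).
#' @return the partial log-likelihood value.
#' @examples
#' d <- list(X = matrix(0, 2, 1), time = c(1, 2), status = c(1, 1))
#' partialLogLik(0, d)  # -log(2): risk sets of size 2, then 1
#' @export
partialLogLik <- function(beta, data) {
  p <- .dataParts(data)
  if (ncol(p$X) != length(beta))
    stop("length(beta) must equal ncol(X)")
  if (sum(p$status) == 0L) return(0)
  .coxRisk(p$X, p$time, p$status, beta)$loglik
}

#' Breslow baseline hazard estimator
#'
#' One hazard increment per distinct event time \eqn{t_k}:
#' \deqn{\hat h_0(t_k) = d_k / \sum_{j: y_j \ge t_k} \exp(X_j'\beta)}
#' where \eqn{d_k} is the number of events at \eqn{t_k} (Breslow tie
#' handling). The cumulative hazard is the running sum of the increments.
#'
#' @inheritParams partialLogLik
#' @return a [BaselineHazard-class].
#' @export
breslowBaseline <- function(beta, data) {
  p <- .dataParts(data)
  if (sum(p$status) == 0L) stop("at least one event is required")
  r <- .coxRisk(p$X, p$time, p$status, beta)
  h0 <- exp(log(r$d) - r$shift - log(r$S0))
  new("BaselineHazard", time = r$evTimes, h0 = h0, H0 = cumsum(h0),
      nEvents = r$d)
}

# Right-continuous step lookup of the cumulative baseline hazard
.H0at <- function(baseline, t) {
  idx <- findInterval(t, baseline@time)
  c(0, baseline@H0)[idx + 1L]
}

#' Total Cox log-likelihood at a given baseline
#'
#' \deqn{l(\beta, h_0) = \sum_i -\exp(X_i'\beta) H_0(t_i) +
#'   \delta_i [\log h_0(t_i) + X_i'\beta].}
#' Censored subjects observed before the first event time contribute a zero
#' \eqn{H_0}. An event whose time has no baseline increment is an error: the
#' likelihood is undefined there.
#'
#' @inheritParams partialLogLik
#' @param baseline a [BaselineHazard-class] defined at all event times of
#'   `data`.
#' @return the total log-likelihood value.
#' @export
totalLogLik <- function(beta, baseline, data) {
  stopifnot(is(baseline, "BaselineHazard"))
  p <- .dataParts(data)
  eta <- as.numeric(p$X %*% beta)
  H0 <- .H0at(baseline, p$time)
  ll <- sum(-exp(eta) * H0)
  ev <- which(p$status == 1L)
  if (length(ev)) {
    k <- match(p$time[ev], baseline@time)
    if (anyNA(k))
      stop("event time(s) without a baseline hazard increment: ",
           paste(utils::head(p$time[ev][is.na(k)], 5), collapse = ", "))
    ll <- ll + sum(log(baseline@h0[k]) + eta[ev])
  }
  ll
}
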