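#' @include AllClasses.R AllGenerics.R cox-fit.R
NULL

#' Prognostic index (linear predictor)
#'
#' \eqn{PI_n = \sum_i X_{i,n}\,\beta_i}, the per-sample linear predictor
#' used to rank patient risk. Given a fitted model and new data, the model's
#' stored standardization is applied to the covariates first, so indices are
#' comparable with the training fit.
#'
#' @param x covariate matrix (samples by features), or a
#'   [PenalizedCoxModel-class].
#' @param beta coefficient vector, or a [CoxSurvivalData-class] when `x` is
#'   a model.
#' @return numeric prognostic index per sample.
#' @export
setGeneric("prognosticIndex", function(x, beta) standardGeneric("prognosticIndex"))

#' @rdname prognosticIndex
#' @export
setMethod("prognosticIndex", signature("matrix", "numeric"),
  function(x, beta) {
    if (ncol(x) != length(beta)) stop("ncol(x) must equal length(beta)")
    as.numeric(x %*% beta)
  })

#' @rdname prognosticIndex
#' @export
setMethod("prognosticIndex", signature("PenalizedCoxModel", "CoxSurvivalData"),
  function(x, beta) {
    Xs <- .standardizeNew(x, beta@X)
    stats::setNames(as.numeric(Xs %*% x@beta), beta@sampleIds)
  })

#' Deviance residuals of a fitted Cox model
#'
#' Per-subject residuals generalizing the residual sum of squares: with
#' martingale residual \eqn{m_i = \delta_i - H_0(t_i)\exp(X_i'\beta)},
#' \deqn{d_i = \mathrm{sign}(m_i)\sqrt{-2\,[m_i +
#'   \delta_i \log(\delta_i - m_i)]}.}
#' Residuals are centered at zero and are exactly 0 where the martingale
#' residual is 0. The model's baseline hazard and standardization are
#' applied to `data`, which may be the training set or new samples; an
#' event observed before the model's first baseline increment has an
#' undefined residual and raises an error.
#'
#' @param model a [PenalizedCoxModel-class].
#' @param data a [CoxSurvivalData-class].
#' @return numeric residual vector, named by sample.
#' @export
devianceResiduals <- function(model, data) {
  stopifnot(is(model, "PenalizedCoxModel"), is(data, "CoxSurvivalData"))
  eta <- as.numeric(.standardizeNew(model, data@X) %*% model@beta)
  H0 <- .H0at(model@baseline, data@time)
  delta <- as.numeric(data@status)
  m <- delta - H0 * exp(eta)
  if (any(delta == 1 & m >= 1))
    stop("event time(s) precede the first baseline hazard increment; ",
         "deviance residual undefined there")
  inner <- m + ifelse(delta == 1, log(delta - m), 0)
  stats::setNames(sign(m) * sqrt(pmax(-2 * inner, 0)), data@sampleIds)
}

#' Root mean squared error of residuals
#'
#' @param residuals non-empty numeric vector.
#' @return \eqn{\sqrt{\mathrm{mean}(r^2)}}.
#' @export
rmse <- function(residuals) {
  if (length(residuals) == 0L) stop("residuals must be non-empty")
  sqrt(mean(residuals^2))
}

#' Concordance index for censored survival data
#'
#' Fraction of permissible subject pairs whose risk ordering agrees with
#' their survival ordering. Pairs where both subjects are censored, or where
#' the only censored subject has a shorter time than the uncensored one, are
#' not permissible.
#'
#' Two counting rules are provided:
#' \describe{
#'   \item{standard}{Harrell's rule: a pair counts 1 when the higher-risk
#'     subject has the shorter survival time (or, for a permissible
#'     censored pair, the censored subject has the lower risk), 0.5 on risk
#'     ties and on event-time ties between two events, 0 otherwise.}
#'   \item{paper_literal}{counts 1 for (a) higher risk with shorter time,
#'     (b) identical risks and identical times, (c) a permissible censored
#'     pair whose censored subject has the lower risk; every other
#'     permissible pair counts 0.5.}
#' }
#'
#' @param pi prognostic index (higher = higher risk).
#' @param time follow-up times.
#' @param status 0/1 event indicators.
#' @param rule `"standard"` (default) or `"paper_literal"`.
#' @return concordance in \eqn{[0, 1]}.
#' @export
concordanceIndex <- function(pi, time, status,
                             rule = c("standard", "paper_literal")) {
  rule <- match.arg(rule)
  n <- length(pi)
  stopifnot(length(time) == n, length(status) == n, n >= 2)
  count <- 0
  permissible <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      di <- status[i]; dj <- status[j]
      if (di == 0 && dj == 0) next
      if (di == 1 && dj == 0 && time[j] < time[i]) next
      if (dj == 1 && di == 0 && time[i] < time[j]) next
      permissible <- permissible + 1
      # orient: s = subject expected to fail first (shorter time)
      if (di == 1 && dj == 1) {
        if (time[i] == time[j]) {
          count <- count + (
            if (rule == "standard") 0.5
            else if (pi[i] == pi[j]) 1 else 0.5)
          next
        }
        s <- if (time[i] < time[j]) i else j
        o <- if (s == i) j else i
        agree <- pi[s] > pi[o]
        tied <- pi[s] == pi[o]
      } else {
        cens <- if (di == 0) i else j     # censored subject (longer time)
        ev <- if (cens == i) j else i
        agree <- pi[ev] > pi[cens]        # censored (survivor) has lower risk
        tied <- pi[ev] == pi[cens]
      }
      count <- count + (
        if (rule == "standard") { if (agree) 1 else if (tied) 0.5 else 0 }
        else { if (agree) 1 else 0.5 })
    }
  }
  if (permissible == 0) stop("no permissible pairs")
  count / permissible
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Nonparametric estimate of the survival function for right-censored data
#' (computed via \pkg{survival}); the curve starts at 1 and drops only at
#' event times. With no events the estimate is identically 1 and the curve
#' is empty.
#'
#' @param time follow-up times.
#' @param status 0/1 event indicators.
#' @return a [KMCurve-class].
#' @export
kaplanMeier <- function(time, status) {
  stopifnot(length(time) >= 1, length(time) == length(status))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  keep <- fit$n.event > 0
  new("KMCurve", time = fit$time[keep], survival = fit$surv[keep],
      atRisk = as.integer(fit$n.risk[keep]),
      nEvents = as.integer(fit$n.event[keep]))
}

#' Survival probability of a KM curve at given times
#'
#' @param curve a [KMCurve-class].
#' @param t evaluation times.
#' @return step-function values \eqn{S(t)}.
#' @export
kmSurvivalAt <- function(curve, t) {
  stopifnot(is(curve, "KMCurve"))
  idx <- findInterval(t, curve@time)
  c(1, curve@survival)[idx + 1L]
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square statistic comparing the survival
#' distributions of exactly two groups (via \pkg{survival}), with the
#' p-value from the chi-square distribution with 1 degree of freedom.
#' Identical groups give statistic 0 and p = 1.
#'
#' @param time follow-up times.
#' @param status 0/1 event indicators.
#' @param groups two-level grouping (factor/character/numeric).
#' @return list with `statistic` and `p.value`.
#' @export
logrankTest <- function(time, status, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly 2 groups are required, got ", nlevels(g))
  if (any(table(g) == 0)) stop("each group needs at least one subject")
  sd <- survival::survdiff(survival::Surv(time, status) ~ g)
  stat <- as.numeric(sd$chisq)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Stratify samples into high/low risk groups by prognostic index
#'
#' Schemes:
#' \describe{
#'   \item{q40}{the lowest 40\% of PI form the low-risk group, the top 40\%
#'     the high-risk group; the middle 20\% are excluded. Ties at the
#'     quantile boundary are broken by sample order (stable sort).}
#'   \item{q50}{median split: every sample is assigned, low = smaller PI
#'     half (the extra sample on odd n goes to the low group).}
#'   \item{optimal}{every midpoint between consecutive distinct sorted PI
#'     values leaving at least 10\% of samples on each side is tried, and
#'     the threshold with the smallest log-rank p-value is kept.}
#' }
#' The log-rank test for the resulting high/low split is computed on the
#' included samples.
#'
#' @param pi prognostic index per sample.
#' @param time follow-up times.
#' @param status 0/1 event indicators.
#' @param scheme `"q40"`, `"q50"` or `"optimal"`.
#' @return a [RiskStratification-class].
#' @export
stratifyRisk <- function(pi, time, status, scheme = c("q40", "q50", "optimal")) {
  scheme <- match.arg(scheme)
  n <- length(pi)
  stopifnot(length(time) == n, length(status) == n, n >= 2)
  if (length(unique(pi)) == 1L)
    stop("all prognostic indices are equal; stratification is degenerate")
  ord <- order(pi, seq_len(n))                 # stable: ties by sample order
  groups <- rep("excluded", n)
  threshold <- NA_real_
  if (scheme == "q40") {
    kk <- floor(0.4 * n)
    if (kk < 1) stop("too few samples for a 40%/40% split")
    groups[ord[seq_len(kk)]] <- "low"
    groups[ord[(n - kk + 1L):n]] <- "high"
  } else if (scheme == "q50") {
    half <- ceiling(n / 2)
    groups[ord[seq_len(half)]] <- "low"
    groups[ord[(half + 1L):n]] <- "high"
    threshold <- (pi[ord[half]] + pi[ord[half + 1L]]) / 2
  } else {
    su <- sort(unique(pi))
    mids <- (su[-1] + su[-length(su)]) / 2
    minSide <- max(1L, ceiling(0.1 * n))
    best <- NULL
    for (thr in mids) {
      hi <- pi > thr
      if (sum(hi) < minSide || sum(!hi) < minSide) next
      lr <- logrankTest(time, status, ifelse(hi, "high", "low"))
      if (is.null(best) || lr$p.value < best$p) best <- list(thr = thr, p = lr$p.value)
    }
    if (is.null(best))
      stop("no admissible threshold leaves 10% of samples on each side")
    threshold <- best$thr
    groups <- ifelse(pi > threshold, "high", "low")
  }
  inc <- groups != "excluded"
  lr <- logrankTest(time[inc], status[inc], groups[inc])
  new("RiskStratification", pi = as.numeric(pi), scheme = scheme,
      groups = factor(groups, levels = c("low", "high", "excluded")),
      threshold = threshold, logrankStat = lr$statistic,
      logrankP = lr$p.value)
}
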