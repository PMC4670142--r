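#' @include classes.R
NULL

logSumExp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

#' Marginal log-likelihood of one species' detection history at one site-year
#' (occupancy model)
#'
#' The latent occupancy indicator z is summed out:
#' `log[ psi * prod_l p^y (1-p)^(1-y)  +  (1-psi) * 1(all y = 0) ]`,
#' evaluated in log space. Visits flagged by `mask` (or with `NA` response)
#' are skipped. A detection under `psi = 0` gives `-Inf`, not an error.
#'
#' @param psi occupancy probability (scalar in `[0,1]`).
#' @param p per-visit detection probabilities.
#' @param y binary detection history (same length as `p`).
#' @param mask logical; `FALSE` drops a visit from the likelihood.
#' @return log-probability (scalar).
#' @export
occupancySiteLoglik <- function(psi, p, y, mask = NULL) {
  stopifnot(length(p) == length(y), psi >= 0, psi <= 1,
            all(p >= 0 & p <= 1))
  keep <- !is.na(y)
  if (!is.null(mask)) keep <- keep & mask
  p <- p[keep]; y <- y[keep]
  if (!length(y)) return(0)
  if (any(y != 0 & y != 1)) stop("occupancy responses must be binary")
  detLog <- sum(ifelse(y == 1, log(p), log1p(-p)))
  if (any(y == 1)) {
    if (psi == 0) return(-Inf)
    return(log(psi) + detLog)
  }
  logSumExp2(log(psi) + sum(log1p(-p)), log1p(-psi))
}

#' Marginal log-likelihood of one species' count history at one site-year
#' (N-mixture model)
#'
#' The latent abundance N is summed from `max(n)` to the truncation bound K:
#' `log sum_N Poisson(N; lambda) prod_l Binomial(n_l; N, p_l)`, in log space.
#'
#' @param lambda positive Poisson rate.
#' @param p per-visit detection probabilities.
#' @param n non-negative integer counts per visit (`NA` = missing visit).
#' @param K truncation bound; must be at least `max(n)`.
#' @return log-probability (scalar).
#' @export
nmixtureSiteLoglik <- function(lambda, p, n, K) {
  stopifnot(length(p) == length(n), lambda >= 0, all(p >= 0 & p <= 1))
  keep <- !is.na(n)
  p <- p[keep]; n <- n[keep]
  if (!length(n)) return(0)
  if (K < max(n)) stop("truncation bound K is below the largest count")
  Ns <- max(n):K
  terms <- dpois(Ns, lambda, log = TRUE) +
    vapply(Ns, function(N) sum(dbinom(n, N, p, log = TRUE)), 1)
  m <- max(terms)
  if (is.infinite(m)) return(-Inf)
  m + log(sum(exp(terms - m)))
}

paramsSkeleton <- function(data) {
  P <- ncol(processMatrix(data))
  Q <- dim(obsArray(data))[3L]
  list(P = P, Q = Q,
       procNames = colnames(processMatrix(data)),
       obsNames = dimnames(obsArray(data))[[3L]])
}

#' Marginalized model log-likelihood at a parameter set
#'
#' Sums [occupancySiteLoglik()] (or [nmixtureSiteLoglik()]) over all species
#' and surveyed site-years, with `psi` (or `lambda`) built from the process
#' linear predictor `Xproc . alpha_i + u[site]` and per-visit `p` from the
#' observation predictor. Site-years absent from the data (the mask)
#' contribute nothing by construction.
#'
#' @param params list with `alpha` (species x P), `beta` (species x Q),
#'   `siteEffects` (per site; optional, defaults to zeros).
#' @param data a [CommunityData-class] object.
#' @param K truncation bound for the abundance model.
#' @return total log-likelihood (scalar).
#' @export
modelLoglik <- function(params, data, K = defaultK(data)) {
  stopifnot(is(data, "CommunityData"))
  y <- responseArray(data)
  S <- dim(y)[1L]; M <- dim(y)[2L]; L <- dim(y)[3L]
  sk <- paramsSkeleton(data)
  alpha <- params$alpha; beta <- params$beta
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = S, byrow = TRUE)
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = S, byrow = TRUE)
  if (ncol(alpha) != sk$P || ncol(beta) != sk$Q || nrow(alpha) != S)
    stop("parameter dimensions do not match the data's design matrices")
  u <- params$siteEffects
  if (is.null(u)) u <- rep(0, max(data@siteIndex))
  etaProc <- alpha %*% t(processMatrix(data)) +
    matrix(u[data@siteIndex], S, M, byrow = TRUE)
  total <- 0
  for (i in seq_len(S)) {
    for (m in seq_len(M)) {
      Xm <- matrix(data@obsArray[m, , ], nrow = L, ncol = sk$Q)
      pv <- plogis(drop(Xm %*% beta[i, ]))
      total <- total +
        if (data@responseKind == "occupancy")
          occupancySiteLoglik(plogis(etaProc[i, m]), pv, y[i, m, ])
        else
          nmixtureSiteLoglik(exp(etaProc[i, m]), pv, y[i, m, ], K)
    }
  }
  unname(total)
}

#' Default truncation bound for the N-mixture likelihood
#'
#' `max(observed count) + 100`, grown (doubling the margin) until the
#' marginal likelihood of the most demanding site-year is insensitive to it
#' (change below `tol`), evaluated at a moment-matched rate. The chosen K is
#' recorded by [fitAbundance()].
#'
#' @param data a [CommunityData-class] object (abundance response).
#' @param margin initial margin above the maximum count.
#' @param tol insensitivity tolerance on the site log-likelihood.
#' @return integer bound K.
#' @export
defaultK <- function(data, margin = 100L, tol = 1e-8) {
  y <- responseArray(data)
  maxObs <- max(c(0, y), na.rm = TRUE)
  if (data@responseKind != "abundance") return(as.integer(maxObs))
  # crude upper rate: detection-corrected mean of the largest counts
  lamHi <- max(1, 2 * maxObs)
  repeat {
    K <- as.integer(maxObs + margin)
    l1 <- nmixtureSiteLoglik(lamHi, rep(0.2, 3L), rep(maxObs, 3L), K)
    l2 <- nmixtureSiteLoglik(lamHi, rep(0.2, 3L), rep(maxObs, 3L), 2L * K)
    if (abs(l1 - l2) < tol) return(K)
    margin <- margin * 2L
  }
}
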