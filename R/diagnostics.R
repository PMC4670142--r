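#' @include fit.R
NULL

#' Gelman-Rubin potential scale reduction factor (split-chain)
#'
#' Each chain is split in half (the split variant also flags within-chain
#' trends, and is never smaller than the 1992 original), then
#' `Rhat = sqrt( ((n-1)/n W + B/n) / W )` from the between- and within-chain
#' variances of the 2m half-chains.
#'
#' @param x matrix (iterations x chains) or list of equal-length numeric
#'   vectors for one parameter.
#' @return the statistic (>= sqrt((n-1)/n); ~1 indicates convergence).
#' @export
gelmanRubin <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (ncol(x) < 2L) stop("at least 2 chains are required")
  if (nrow(x) < 4L) stop("chains too short to split")
  half <- nrow(x) %/% 2L
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(c)
    cbind(x[seq_len(half), c], x[seq(nrow(x) - half + 1L, nrow(x)), c])))
  n <- nrow(splits); m <- ncol(splits)
  means <- colMeans(splits)
  W <- mean(apply(splits, 2L, var))
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size: pooled draws over autocorrelation sum
# (initial positive sequence truncation)
effectiveSize <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x); m <- ncol(x)
  if (var(as.vector(x)) == 0) return(n * m)
  rho <- rowMeans(sapply(seq_len(m), function(c) {
    a <- acf(x[, c], lag.max = min(n - 2L, 200L), plot = FALSE,
             demean = TRUE)$acf[-1L]
    as.vector(a)
  }))
  cut <- which(rho < 0)[1L]
  if (!is.na(cut)) rho <- rho[seq_len(max(cut - 1L, 0L))]
  max(1, n * m / (1 + 2 * sum(rho)))
}

#' Convergence report for every sampled parameter
#'
#' Split-chain [gelmanRubin()] statistic and a crude effective draw count
#' for each parameter, with warnings collected for parameters above the
#' threshold.
#'
#' @param chains a [CommunityChains-class] (needs >= 2 chains).
#' @param threshold warn above this Rhat (default 1.1).
#' @return list of class `convergence_report`: `table` (parameter, rhat,
#'   ess), `warnings` (character), `threshold`.
#' @export
convergenceReport <- function(chains, threshold = 1.1) {
  stopifnot(is(chains, "CommunityChains"))
  if (nChains(chains) < 2L)
    stop("convergence diagnostics need at least 2 chains")
  pn <- paramNames(chains)
  rhat <- vapply(seq_along(pn), function(j) {
    gelmanRubin(lapply(chains@draws, function(d) d[, j]))
  }, 1)
  ess <- vapply(seq_along(pn), function(j) {
    effectiveSize(lapply(chains@draws, function(d) d[, j]))
  }, 1)
  tab <- data.frame(parameter = pn, rhat = rhat, ess = ess)
  bad <- tab$parameter[!is.na(tab$rhat) & tab$rhat > threshold]
  warnings <- if (length(bad))
    sprintf("Rhat > %.2f for %s", threshold, bad) else character()
  structure(list(table = tab, warnings = warnings, threshold = threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence report: %d parameters, max Rhat %.3f\n",
              nrow(x$table), max(x$table$rhat, na.rm = TRUE)))
  if (length(x$warnings))
    cat(sprintf("  %d parameter(s) above %.2f\n", length(x$warnings),
                x$threshold))
  else cat("  no Rhat warnings\n")
  invisible(x)
}

discrepancyStat <- function(y, mu, discrepancy) {
  keep <- !is.na(y)
  switch(discrepancy,
    freeman_tukey = sum((sqrt(y[keep]) - sqrt(mu[keep]))^2),
    chisq = sum((y[keep] - mu[keep])^2 / pmax(mu[keep] * (1 - pmin(mu[keep],
      0.999)), 1e-6)),
    stop("unknown discrepancy: ", discrepancy))
}

#' Posterior predictive check (Bayesian p-value)
#'
#' For a subsample of retained draws, simulates a replicate dataset from the
#' fitted model at that draw, computes a discrepancy T on the observed and
#' replicate site-visit responses, and returns
#' `p = P(T(y_rep) >= T(y))`. Values near 0 or 1 indicate misfit. The
#' default discrepancy is the Freeman-Tukey statistic
#' `sum (sqrt(y) - sqrt(E y))^2` with `E y = psi p` (occupancy) or
#' `lambda p` (abundance).
#'
#' @param chains a fitted [CommunityChains-class].
#' @param data the fitted [CommunityData-class].
#' @param discrepancy `"freeman_tukey"` or `"chisq"`.
#' @param maxDraws posterior draws used (default 200).
#' @param seed seed for the replicate simulations.
#' @return list of class `ppc_result`: `pValue`, `discrepancy`, `realized`,
#'   `replicated` (vectors of T(y) and T(y_rep) per draw).
#' @export
ppcPvalue <- function(chains, data, discrepancy = c("freeman_tukey",
                                                    "chisq"),
                      maxDraws = 200L, seed = 1L) {
  discrepancy <- match.arg(discrepancy)
  stopifnot(is(data, "CommunityData"))
  pooled <- drawMatrix(chains)
  if (maxDraws < nrow(pooled))
    pooled <- pooled[round(seq(1L, nrow(pooled), length.out = maxDraws)), ,
                     drop = FALSE]
  D <- nrow(pooled)
  y <- responseArray(data)
  S <- dim(y)[1L]; M <- dim(y)[2L]; L <- dim(y)[3L]
  sDraws <- siteEffectDraws(chains, data, pooled)
  occ <- data@responseKind == "occupancy"
  set.seed(seed)
  Tobs <- Trep <- numeric(D)
  # per-species predictors once, then loop draws
  psiAll <- vector("list", S); pAll <- vector("list", S)
  for (i in seq_len(S)) {
    pr <- speciesPredictors(pooled, data, i, sDraws)
    psiAll[[i]] <- if (occ) plogis(pr$etaProc) else exp(pr$etaProc)
    pAll[[i]] <- pr$p
  }
  for (s in seq_len(D)) {
    to <- tr <- 0
    for (i in seq_len(S)) {
      proc <- psiAll[[i]][s, ]                   # psi or lambda, length M
      pmat <- matrix(pAll[[i]][s, , ], M, L)
      mu <- proc * pmat                          # E y per visit
      yi <- matrix(y[i, , ], M, L)
      if (occ) {
        z <- rbinom(M, 1L, proc)
        yrep <- matrix(rbinom(M * L, 1L, z * pmat), M, L)
      } else {
        Nlat <- rpois(M, proc)
        yrep <- matrix(rbinom(M * L, Nlat, pmat), M, L)
      }
      yrep[is.na(yi)] <- NA
      to <- to + discrepancyStat(yi, mu, discrepancy)
      tr <- tr + discrepancyStat(yrep, mu, discrepancy)
    }
    Tobs[s] <- to; Trep[s] <- tr
  }
  structure(list(pValue = mean(Trep >= Tobs), discrepancy = discrepancy,
                 realized = Tobs, replicated = Trep),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("posterior predictive check (%s): Bayesian p-value = %.3f\n",
              x$discrepancy, x$pValue))
  invisible(x)
}
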