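#' @include fit.R
NULL

# species-level linear-predictor pieces across pooled draws
# returns list(etaProc = D x M, logQ0 = D x M sum_l log(1-p)) for species i
speciesPredictors <- function(pooled, data, i, siteDraws) {
  sk <- paramsSkeleton(data)
  sp <- data@species[i]
  A <- pooled[, sprintf("alpha[%s,%s]", sp, sk$procNames), drop = FALSE]
  B <- pooled[, sprintf("beta[%s,%s]", sp, sk$obsNames), drop = FALSE]
  etaProc <- A %*% t(processMatrix(data))
  if (!is.null(siteDraws)) etaProc <- etaProc + siteDraws[, data@siteIndex]
  L <- dim(responseArray(data))[3L]
  M <- nrow(processMatrix(data))
  logQ0 <- matrix(0, nrow(pooled), M)
  pArr <- array(NA_real_, dim = c(nrow(pooled), M, L))
  for (l in seq_len(L)) {
    Xl <- matrix(data@obsArray[, l, ], M, sk$Q)
    etaObs <- B %*% t(Xl)
    pArr[, , l] <- plogis(etaObs)
    # only visits that happened contribute to the all-missed probability
    made <- !is.na(responseArray(data)[i, , l])
    lq <- plogis(etaObs, lower.tail = FALSE, log.p = TRUE)
    lq[, !made] <- 0
    logQ0 <- logQ0 + lq
  }
  list(etaProc = etaProc, logQ0 = logQ0, p = pArr)
}

siteEffectDraws <- function(chains, data, pooled) {
  if (!isTRUE(chains@config$siteEffects)) return(NULL)
  pooled[, sprintf("site[%s]", data@sites$site), drop = FALSE]
}

#' Conditional posterior draws of the latent occupancy states
#'
#' For every retained posterior draw, draws z(i, site-year) from its
#' conditional distribution given the data: z = 1 with certainty where the
#' species was detected at least once; for all-zero histories
#' `z ~ Bernoulli( psi q0 / (psi q0 + 1 - psi) )` with
#' `q0 = prod_l (1 - p_l)` over the visits made.
#'
#' @param chains a [CommunityChains-class] from [fitOccupancy()].
#' @param data the [CommunityData-class] the model was fitted to.
#' @param maxDraws cap on pooled draws used (`NULL` = all), subsampled
#'   evenly.
#' @param seed seed for the Bernoulli draws.
#' @return list of class `occupancy_draws`: `z` array (draw, species,
#'   site-year), `siteYears`, `species`.
#' @export
conditionalZDraws <- function(chains, data, maxDraws = NULL, seed = 1L) {
  stopifnot(data@responseKind == "occupancy")
  pooled <- drawMatrix(chains)
  if (!is.null(maxDraws) && maxDraws < nrow(pooled))
    pooled <- pooled[round(seq(1L, nrow(pooled), length.out = maxDraws)), ,
                     drop = FALSE]
  D <- nrow(pooled)
  y <- responseArray(data)
  S <- dim(y)[1L]; M <- dim(y)[2L]
  sDraws <- siteEffectDraws(chains, data, pooled)
  set.seed(seed)
  z <- array(NA_real_, dim = c(D, S, M))
  for (i in seq_len(S)) {
    pr <- speciesPredictors(pooled, data, i, sDraws)
    psi <- plogis(pr$etaProc)
    anyDet <- apply(y[i, , , drop = FALSE], 2L, function(v) any(v > 0,
                                                                na.rm = TRUE))
    surveyed <- apply(y[i, , , drop = FALSE], 2L, function(v) any(!is.na(v)))
    q0 <- exp(pr$logQ0)
    condP <- psi * q0 / (psi * q0 + (1 - psi))
    zi <- matrix(rbinom(D * M, 1L, condP), D, M)
    zi[, anyDet] <- 1
    zi[, !surveyed] <- NA_real_
    z[, i, ] <- zi
  }
  structure(list(z = z, siteYears = data@siteYears, species = data@species),
            class = "occupancy_draws")
}

#' Conditional posterior draws of the latent abundances
#'
#' For every retained posterior draw, draws N(i, site-year) from its discrete
#' conditional `P(N) ~ Poisson(N; lambda) prod_l Binomial(n_l; N, p_l)` on
#' support `max(n)..K`.
#'
#' @param chains a [CommunityChains-class] from [fitAbundance()].
#' @param data the fitted [CommunityData-class].
#' @param K truncation bound (defaults to the bound used in the fit).
#' @param maxDraws cap on pooled draws used (default 500; the draw is
#'   O(species x site-years x K) per posterior draw).
#' @param seed seed for the categorical draws.
#' @return list of class `abundance_draws`: `N` array (draw, species,
#'   site-year), `siteYears`, `species`.
#' @export
conditionalNDraws <- function(chains, data, K = chains@config$K,
                              maxDraws = 500L, seed = 1L) {
  stopifnot(data@responseKind == "abundance")
  if (is.na(K)) K <- defaultK(data)
  pooled <- drawMatrix(chains)
  if (!is.null(maxDraws) && maxDraws < nrow(pooled))
    pooled <- pooled[round(seq(1L, nrow(pooled), length.out = maxDraws)), ,
                     drop = FALSE]
  D <- nrow(pooled)
  y <- responseArray(data)
  S <- dim(y)[1L]; M <- dim(y)[2L]; L <- dim(y)[3L]
  sDraws <- siteEffectDraws(chains, data, pooled)
  set.seed(seed)
  N <- array(NA_real_, dim = c(D, S, M))
  for (i in seq_len(S)) {
    pr <- speciesPredictors(pooled, data, i, sDraws)
    lambda <- exp(pr$etaProc)              # D x M
    # cpp helper wants M x D and M x L x D
    pcube <- aperm(pr$p, c(2L, 3L, 1L))
    yi <- matrix(y[i, , ], M, L)
    pcube[is.na(array(yi, dim = dim(pcube)))] <- NA_real_
    Ndraw <- cpp_cond_N(t(lambda), pcube, yi, as.integer(K))
    surveyed <- apply(yi, 1L, function(v) any(!is.na(v)))
    Ndraw[!surveyed, ] <- NA_integer_
    N[, i, ] <- t(Ndraw)
  }
  structure(list(N = N, siteYears = data@siteYears, species = data@species),
            class = "abundance_draws")
}
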