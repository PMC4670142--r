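#' @include likelihood.R
NULL

#' MCMC configuration
#'
#' Desk-scale defaults: 3 chains of 4,000 iterations with a 2,000 burn-in and
#' thinning of 2 (1,000 retained draws per chain). The full field-study
#' protocol (3 chains of 400,000, burn-in 200,000, thinning 50) is obtained
#' with `mcmcConfig(nIter = 4e5, nBurn = 2e5, nThin = 50)`.
#'
#' @param nChains number of chains.
#' @param nIter iterations per chain (including burn-in).
#' @param nBurn burn-in iterations discarded per chain.
#' @param nThin keep every `nThin`-th post-burn-in iteration.
#' @param nSweeps species-block update sweeps per iteration (a sampler
#'   refinement: more sweeps, better mixing per retained draw, same draw
#'   count).
#' @param seed integer root seed; chain c runs under `seed + c - 1`.
#' @return list of class `mcmc_config`.
#' @export
mcmcConfig <- function(nChains = 3L, nIter = 4000L, nBurn = 2000L,
                       nThin = 2L, nSweeps = 2L, seed = 1L) {
  stopifnot(nChains >= 1L, nIter > nBurn, nBurn >= 0L, nThin >= 1L,
            nSweeps >= 1L)
  structure(list(nChains = as.integer(nChains), nIter = as.integer(nIter),
                 nBurn = as.integer(nBurn), nThin = as.integer(nThin),
                 nSweeps = as.integer(nSweeps),
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' Prior configuration
#'
#' Weakly informative defaults on the link scales: community hyper-means
#' N(0, 1.5^2) (N(0, 2^2) for the log-link abundance intercept), hyper-sds
#' and the site-effect sd half-Cauchy with scale 1.
#'
#' @param muSd prior sd of the hyper-means.
#' @param muSdLogIntercept prior sd of the abundance (log link) intercept
#'   hyper-mean.
#' @param sigmaScale half-Cauchy scale of the coefficient hyper-sds.
#' @param siteScale half-Cauchy scale of the site-effect sd.
#' @return list of class `prior_config`.
#' @export
priorConfig <- function(muSd = 1.5, muSdLogIntercept = 2,
                        sigmaScale = 1, siteScale = 1) {
  structure(list(muSd = muSd, muSdLogIntercept = muSdLogIntercept,
                 sigmaScale = sigmaScale, siteScale = siteScale),
            class = "prior_config")
}

chainParamNames <- function(data, siteEffects) {
  sk <- paramsSkeleton(data)
  sp <- data@species
  nm <- c(
    as.vector(outer(sp, sk$procNames,
                    function(s, c) sprintf("alpha[%s,%s]", s, c))),
    as.vector(outer(sp, sk$obsNames,
                    function(s, c) sprintf("beta[%s,%s]", s, c))))
  if (siteEffects)
    nm <- c(nm, sprintf("site[%s]", data@sites$site))
  nm <- c(nm,
          sprintf("mu_alpha[%s]", sk$procNames),
          sprintf("sd_alpha[%s]", sk$procNames),
          sprintf("mu_beta[%s]", sk$obsNames),
          sprintf("sd_beta[%s]", sk$obsNames))
  if (siteEffects) nm <- c(nm, "sd_site")
  nm
}

naiveInits <- function(data, siteEffects, chain) {
  y <- responseArray(data)
  sk <- paramsSkeleton(data)
  S <- dim(y)[1L]
  nsite <- nrow(data@sites)
  # data-informed intercepts, overdispersed across chains: start the process
  # intercept at the naive (any-detection) occupancy level, not the per-visit
  # detection frequency
  naive <- mean(apply(y > 0, c(1L, 2L), any, na.rm = TRUE), na.rm = TRUE)
  naive <- min(max(naive, 0.02), 0.98)
  int0 <- if (data@responseKind == "occupancy") qlogis(naive)
          else log(max(0.2, mean(y, na.rm = TRUE) * 2))
  jitter <- (chain - 1) * 0.5
  muA <- rep(0, sk$P); muA[1L] <- int0 + rnorm(1, 0, 0.3 + jitter * 0.2)
  muB <- rep(0, sk$Q); muB[1L] <- qlogis(0.3) + rnorm(1, 0, 0.3 + jitter * 0.2)
  list(A = matrix(rnorm(S * sk$P, rep(muA, each = S), 0.25), S, sk$P),
       B = matrix(rnorm(S * sk$Q, rep(muB, each = S), 0.25), S, sk$Q),
       u = if (siteEffects) rnorm(nsite, 0, 0.1) else rep(0, nsite),
       muA = muA, sdA = rep(0.5, sk$P),
       muB = muB, sdB = rep(0.5, sk$Q),
       sdSite = 0.3)
}

fitCommunity <- function(data, priors, mcmc, nmix, K, siteEffects) {
  stopifnot(is(data, "CommunityData"))
  y <- responseArray(data)
  if (!any(y > 0, na.rm = TRUE))
    stop("degenerate data: no detections at all")
  sk <- paramsSkeleton(data)
  muAPriorSd <- rep(priors$muSd, sk$P)
  if (nmix) muAPriorSd[1L] <- priors$muSdLogIntercept
  muBPriorSd <- rep(priors$muSd, sk$Q)

  draws <- vector("list", mcmc$nChains)
  logLik <- vector("list", mcmc$nChains)
  accP <- accO <- numeric(mcmc$nChains)
  for (chain in seq_len(mcmc$nChains)) {
    set.seed(mcmc$seed + chain - 1L)
    init <- naiveInits(data, siteEffects, chain)
    res <- cpp_fit_chain(
      yArr = y, Xproc = processMatrix(data), XobsArr = obsArray(data),
      siteIdx = data@siteIndex, nsite = nrow(data@sites), nmix = nmix,
      K = as.integer(K), siteEffects = siteEffects,
      nIter = mcmc$nIter, nBurn = mcmc$nBurn, nThin = mcmc$nThin,
      nSweeps = mcmc$nSweeps,
      muAPriorSd = muAPriorSd, muBPriorSd = muBPriorSd,
      sigmaScale = priors$sigmaScale, siteScale = priors$siteScale,
      init = init)
    colnames(res$draws) <- chainParamNames(data, siteEffects)
    draws[[chain]] <- res$draws
    logLik[[chain]] <- as.vector(res$logLik)
    accP[chain] <- res$acceptProcess
    accO[chain] <- res$acceptObs
  }
  new("CommunityChains", draws = draws, logLik = logLik,
      paramNames = colnames(draws[[1L]]),
      config = list(nChains = mcmc$nChains, nIter = mcmc$nIter,
                    nBurn = mcmc$nBurn, nThin = mcmc$nThin,
                    seed = mcmc$seed, K = if (nmix) as.integer(K) else NA_integer_,
                    siteEffects = siteEffects,
                    acceptProcess = mean(accP), acceptObs = mean(accO)),
      dataDims = list(species = data@species,
                      siteYears = data@siteYears,
                      sites = data@sites,
                      siteIndex = data@siteIndex,
                      procNames = sk$procNames, obsNames = sk$obsNames,
                      variant = data@variant,
                      responseKind = data@responseKind))
}

#' Fit the hierarchical multispecies occupancy model
#'
#' Adaptive block Metropolis-within-Gibbs on the marginalized likelihood
#' (the latent z summed out of every species-site-year term): species-level
#' process and observation coefficient blocks with Haario-style adapted
#' multivariate proposals, scalar random-walk updates for site effects and
#' (log) hyper-sds, and conjugate Gibbs draws for the hyper-means.
#' Adaptation runs during burn-in only. With a fixed `seed` the chains are
#' bit-reproducible.
#'
#' Non-convergence is not an error; inspect [convergenceReport()].
#'
#' @param data a [CommunityData-class] with occupancy responses.
#' @param priors a [priorConfig()].
#' @param mcmc an [mcmcConfig()].
#' @param siteEffects include the site-level random effect (default TRUE;
#'   turn off for single-site-per-row designs where it is not identifiable).
#' @return A [CommunityChains-class] object.
#' @export
fitOccupancy <- function(data, priors = priorConfig(), mcmc = mcmcConfig(),
                         siteEffects = TRUE) {
  stopifnot(data@responseKind == "occupancy")
  fitCommunity(data, priors, mcmc, nmix = FALSE, K = 1L,
               siteEffects = siteEffects)
}

#' Fit the hierarchical multispecies N-mixture abundance model
#'
#' Same sampler as [fitOccupancy()] with the latent site-year abundance N
#' summed to the truncation bound K in every likelihood term. The bound used
#' is recorded in the returned configuration.
#'
#' @param data a [CommunityData-class] with count responses.
#' @param priors a [priorConfig()].
#' @param mcmc an [mcmcConfig()].
#' @param K truncation bound; default [defaultK()] (max count + adaptive
#'   margin).
#' @param siteEffects include the site-level random effect.
#' @return A [CommunityChains-class] object.
#' @export
fitAbundance <- function(data, priors = priorConfig(), mcmc = mcmcConfig(),
                         K = defaultK(data), siteEffects = TRUE) {
  stopifnot(data@responseKind == "abundance")
  if (K < max(responseArray(data), na.rm = TRUE))
    stop("truncation bound K is below the largest observed count")
  fitCommunity(data, priors, mcmc, nmix = TRUE, K = K,
               siteEffects = siteEffects)
}

# extract species-level coefficient matrices at one pooled-draw index
paramsAtDraw <- function(chains, data, draw, pooled = NULL) {
  if (is.null(pooled)) pooled <- drawMatrix(chains)
  sp <- data@species
  sk <- paramsSkeleton(data)
  alpha <- matrix(pooled[draw, sprintf("alpha[%s,%s]",
                                       rep(sp, times = sk$P),
                                       rep(sk$procNames, each = length(sp)))],
                  nrow = length(sp))
  beta <- matrix(pooled[draw, sprintf("beta[%s,%s]",
                                      rep(sp, times = sk$Q),
                                      rep(sk$obsNames, each = length(sp)))],
                 nrow = length(sp))
  dimnames(alpha) <- list(sp, sk$procNames)
  dimnames(beta) <- list(sp, sk$obsNames)
  u <- if (isTRUE(chains@config$siteEffects))
    pooled[draw, sprintf("site[%s]", data@sites$site)]
  else rep(0, nrow(data@sites))
  list(alpha = alpha, beta = beta, siteEffects = unname(u))
}
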