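#' @include metrics.R
NULL

# pair weights over the "other covariates" v: w_jk = 1/(1 + d_jk) with d the
# Mahalanobis distance between v_j and v_k (uniform weights for oracle work)
apcWeights <- function(V, weights = c("mahalanobis", "uniform")) {
  weights <- match.arg(weights)
  n <- nrow(V)
  if (weights == "uniform" || ncol(V) == 0L)
    return(matrix(1, n, n))
  keep <- apply(V, 2L, function(col) length(unique(col)) > 1L)
  V <- V[, keep, drop = FALSE]
  if (ncol(V) == 0L) return(matrix(1, n, n))
  Sg <- cov(V)
  diag(Sg) <- diag(Sg) + 1e-8
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d2 <- mahalanobis(V, center = V[j, ], cov = Sg)
    W[j, ] <- 1 / (1 + sqrt(pmax(d2, 0)))
  }
  W
}

apcEngine <- function(pooled, data, u, speciesSet, linkinv, weights,
                      maxDraws, siteDraws) {
  X <- processMatrix(data)
  if (!u %in% colnames(X)) stop("unknown process covariate: ", u)
  uVals <- X[, u]
  if (length(unique(uVals)) < 2L)
    stop("covariate '", u, "' is constant: predictive comparison undefined")
  n <- nrow(X)
  D <- nrow(pooled)
  if (!is.null(maxDraws) && maxDraws < D) {
    idx <- round(seq(1L, D, length.out = maxDraws))
    pooled <- pooled[idx, , drop = FALSE]
    if (!is.null(siteDraws)) siteDraws <- siteDraws[idx, , drop = FALSE]
    D <- nrow(pooled)
  }
  V <- X[, setdiff(colnames(X), c(u, "Intercept")), drop = FALSE]
  W <- apcWeights(V, weights)

  du <- outer(uVals, uVals, function(a, b) b - a)    # [j,k] = u_k - u_j
  sgn <- sign(du)
  active <- sgn != 0
  denomBase <- sum(W[active] * du[active] * sgn[active])

  # per-draw numerator and per-pair mean comparison
  numDraw <- numeric(D)
  dPairMean <- matrix(0, n, n)
  for (i in speciesSet) {
    sp <- data@species[i]
    sk <- paramsSkeleton(data)
    A <- pooled[, sprintf("alpha[%s,%s]", sp, sk$procNames), drop = FALSE]
    aU <- A[, match(u, sk$procNames)]
    base <- A %*% t(X)                                # D x n at own u
    if (!is.null(siteDraws)) base <- base + siteDraws[, data@siteIndex]
    # eta with row j's v and row k's u: base_j - aU u_j + aU u_k
    for (s in seq_len(D)) {
      cj <- base[s, ] - aU[s] * uVals
      Ejk <- linkinv(outer(cj, aU[s] * uVals, `+`))   # [j,k]
      diffs <- (Ejk - diag(Ejk)[row(Ejk)]) * sgn      # E(.|u_k,v_j)-E(.|u_j,v_j)
      numDraw[s] <- numDraw[s] + sum(W[active] * diffs[active])
      dPairMean[active] <- dPairMean[active] +
        diffs[active] / (du[active] * sgn[active]) / D
    }
  }
  delta <- sum(numDraw) / (D * denomBase)
  deltaDraws <- numDraw / denomBase
  list(delta = delta, deltaDraws = deltaDraws, W = W, active = active,
       dPairMean = dPairMean, n = n)
}

#' Average predictive comparison for one process covariate
#'
#' The model-based expected change in the response per unit change of input
#' u, averaged over the observed distribution of the other inputs v and the
#' posterior draws:
#' `Delta_u = sum_{j,k,s} w_jk [E(y|u_k, v_j, theta_s) - E(y|u_j, v_j, theta_s)] sign(u_k - u_j)
#'            / sum_{j,k,s} w_jk (u_k - u_j) sign(u_k - u_j)`
#' over site-year pairs (j, k). Pairs with `u_j = u_k` contribute zero to
#' both sums and are skipped. Covariates enter scaled, so the unit is one
#' standard deviation of u unless the data were built unscaled.
#'
#' @param chains a [CommunityChains-class].
#' @param data the fitted [CommunityData-class].
#' @param u name of a continuous process design column.
#' @param response `"occupancy"` (expected response psi) or `"abundance"`
#'   (rate lambda); defaults to the data's kind.
#' @param species species code (default: first species).
#' @param weights `"mahalanobis"` (default; `w = 1/(1 + d)` on the other
#'   covariates) or `"uniform"`.
#' @param maxDraws cap on posterior draws entering the double sum
#'   (default 500).
#' @param linkinv optional response function overriding the link (e.g.
#'   `identity` for a linear model check).
#' @return list of class `predictive_comparison`: `input`, `delta`, `se`,
#'   `draws` (per-draw Delta), `lower`, `upper`.
#' @export
apcSingle <- function(chains, data, u, response = data@responseKind,
                      species = data@species[1L],
                      weights = c("mahalanobis", "uniform"), maxDraws = 500L,
                      linkinv = NULL) {
  weights <- match.arg(weights)
  if (is.null(linkinv))
    linkinv <- if (response == "occupancy") plogis else exp
  pooled <- drawMatrix(chains)
  sDraws <- siteEffectDraws(chains, data, pooled)
  i <- match(species, data@species)
  if (is.na(i)) stop("unknown species: ", species)
  eng <- apcEngine(pooled, data, u, i, linkinv, weights, maxDraws, sDraws)
  finishApc(eng, u, response, species)
}

#' Community-level average predictive comparison
#'
#' Extends [apcSingle()] to species richness (summing the species-specific
#' expected occupancies) or total abundance (summing the expected rates):
#' the response function becomes `sum_i E_i(.)`, everything else unchanged,
#' so the community comparison equals the sum of per-species comparisons
#' computed with shared weights.
#'
#' @inheritParams apcSingle
#' @param response `"richness"` or `"totalN"`.
#' @return `predictive_comparison`.
#' @export
apcCommunity <- function(chains, data, u,
                         response = c("richness", "totalN"),
                         weights = c("mahalanobis", "uniform"),
                         maxDraws = 500L, linkinv = NULL) {
  response <- match.arg(response)
  weights <- match.arg(weights)
  if (is.null(linkinv))
    linkinv <- if (response == "richness") plogis else exp
  pooled <- drawMatrix(chains)
  sDraws <- siteEffectDraws(chains, data, pooled)
  eng <- apcEngine(pooled, data, u, seq_along(data@species), linkinv,
                   weights, maxDraws, sDraws)
  finishApc(eng, u, response, "community")
}

finishApc <- function(eng, u, response, species) {
  se <- apcSeFromParts(eng)
  qs <- quantile(eng$deltaDraws, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(input = u, response = response, species = species,
                 delta = eng$delta, se = se,
                 lower = qs[1L], upper = qs[2L],
                 draws = eng$deltaDraws,
                 parts = eng[c("W", "active", "dPairMean", "delta")]),
            class = "predictive_comparison")
}

apcSeFromParts <- function(parts) {
  # documented SE: posterior variance of Delta across draws, plus the
  # weighted-mean estimation variance of the per-pair comparisons around
  # Delta (covariates treated as fixed)
  D <- length(parts$deltaDraws %||% NA)
  vPost <- if (!is.null(parts$deltaDraws) && length(parts$deltaDraws) > 1L)
    var(parts$deltaDraws) else 0
  W <- parts$W; act <- parts$active
  sw <- sum(W[act])
  vPair <- sum((W[act]^2) * (parts$dPairMean[act] - parts$delta)^2) / sw^2
  sqrt(vPost + vPair)
}

#' Standard error of an average predictive comparison
#'
#' Recomputes the SE from the components stored in a `predictive_comparison`:
#' `SE^2 = Var_s(Delta_s) + sum w^2 (dbar_jk - Delta)^2 / (sum w)^2`, the
#' posterior-uncertainty term plus the pairwise estimation-variance term (all
#' covariates fixed). With a single posterior draw the posterior term is 0
#' and a warning flags it.
#'
#' @param apc a `predictive_comparison`.
#' @return standard error (non-negative scalar).
#' @export
apcStandardError <- function(apc) {
  stopifnot(inherits(apc, "predictive_comparison"))
  if (length(apc$draws) < 2L)
    warning("single posterior draw: posterior-variance term is 0")
  parts <- apc$parts
  parts$deltaDraws <- apc$draws
  apcSeFromParts(parts)
}

#' @export
print.predictive_comparison <- function(x, ...) {
  cat(sprintf("APC for %s (%s, %s): Delta = %.4f (SE %.4f), 95%% [%.4f, %.4f]\n",
              x$input, x$response, x$species, x$delta, x$se, x$lower,
              x$upper))
  invisible(x)
}
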