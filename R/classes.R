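#' @include riparOcc-package.R
NULL

#' CommunityData: response arrays and design matrices for one model variant
#'
#' Container for everything one MCMC fit needs: the response array indexed
#' (species, site-year, visit), the process design matrix (one row per
#' surveyed site-year), the observation design array (one row per site-year
#' and visit), the site index for the site-level random effect, and the
#' scaling record for the continuous covariates.
#'
#' Missing visits are `NA` in the response array and are excluded from every
#' likelihood sum. Site-years that were never surveyed (the three sites lost
#' before 2003--2004) are simply absent: the mask is the set of rows present.
#'
#' @slot response numeric array `S x M x L` (species, site-year, visit);
#'   binary for occupancy, non-negative counts for abundance.
#' @slot processMatrix numeric matrix `M x P` with named columns.
#' @slot obsArray numeric array `M x L x Q` with named third dimension.
#' @slot siteIndex integer vector length `M`, 1-based site id per row.
#' @slot siteYears data.frame with columns `site`, `treatment`, `year`
#'   describing each of the `M` rows.
#' @slot sites data.frame with columns `site`, `treatment` (one row per site).
#' @slot species character vector of species codes (dimension 1 of response).
#' @slot scaling data.frame with columns `covariate`, `mean`, `sd` recording
#'   the centering/scaling applied to each continuous covariate.
#' @slot variant one of `"Design"`, `"Covariates"`, `"RandomEffects"`,
#'   `"Custom"`.
#' @slot responseKind `"occupancy"` or `"abundance"`.
#'
#' @seealso [communityData()], [buildModelData()]
#' @export
setClass("CommunityData", representation(
  response = "array",
  processMatrix = "matrix",
  obsArray = "array",
  siteIndex = "integer",
  siteYears = "data.frame",
  sites = "data.frame",
  species = "character",
  scaling = "data.frame",
  variant = "character",
  responseKind = "character"
))

setValidity("CommunityData", function(object) {
  msg <- character()
  dm <- dim(object@response)
  if (length(dm) != 3L) msg <- c(msg, "response must be a 3-d array")
  if (length(object@species) != dm[1L])
    msg <- c(msg, "species length must match dim 1 of response")
  if (nrow(object@processMatrix) != dm[2L])
    msg <- c(msg, "processMatrix rows must match dim 2 of response")
  od <- dim(object@obsArray)
  if (od[1L] != dm[2L] || od[2L] != dm[3L])
    msg <- c(msg, "obsArray dims 1:2 must match response dims 2:3")
  if (length(object@siteIndex) != dm[2L])
    msg <- c(msg, "siteIndex length must match dim 2 of response")
  if (nrow(object@siteYears) != dm[2L])
    msg <- c(msg, "siteYears must have one row per site-year")
  y <- object@response
  if (object@responseKind == "occupancy") {
    if (any(!is.na(y) & y != 0 & y != 1))
      msg <- c(msg, "occupancy responses must be binary")
  } else {
    if (any(!is.na(y) & (y < 0 | y != round(y))))
      msg <- c(msg, "abundance responses must be non-negative integers")
  }
  if (nrow(object@scaling) && any(object@scaling$sd <= 0))
    msg <- c(msg, "scaling sds must be > 0")
  if (!object@responseKind %in% c("occupancy", "abundance"))
    msg <- c(msg, "responseKind must be 'occupancy' or 'abundance'")
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityData object
#'
#' Low-level constructor; most users should call [buildModelData()], which
#' applies the variant-specific subsetting and dummy-coding rules. The
#' constructor is exported so that arbitrary designs (e.g. intercept-only
#' single-species data for calibration studies) can be fitted too.
#'
#' @param response numeric array `S x M x L`.
#' @param processMatrix numeric matrix `M x P` (named columns).
#' @param obsArray numeric array `M x L x Q` (named third dimension).
#' @param siteIndex integer site id (1-based) per site-year row.
#' @param siteYears data.frame (`site`, `treatment`, `year`), one row per
#'   site-year; built from `siteIndex` if omitted.
#' @param species species codes; defaults to `dimnames(response)[[1]]` or
#'   `sp1..spS`.
#' @param scaling covariate scaling record (may be empty).
#' @param variant,responseKind labels stored with the data.
#' @return A [CommunityData-class] object.
#' @export
communityData <- function(response, processMatrix, obsArray, siteIndex,
                          siteYears = NULL, species = NULL,
                          scaling = NULL, variant = "Custom",
                          responseKind = "occupancy") {
  dm <- dim(response)
  if (is.null(species)) {
    species <- dimnames(response)[[1L]]
    if (is.null(species)) species <- sprintf("sp%02d", seq_len(dm[1L]))
  }
  if (is.null(siteYears)) {
    siteYears <- data.frame(site = paste0("site", siteIndex),
                            treatment = "Control", year = 1L)
  }
  if (is.null(scaling)) {
    scaling <- data.frame(covariate = character(), mean = numeric(),
                          sd = numeric())
  }
  sites <- unique(siteYears[, c("site", "treatment")])
  rownames(sites) <- NULL
  new("CommunityData", response = response, processMatrix = processMatrix,
      obsArray = obsArray, siteIndex = as.integer(siteIndex),
      siteYears = siteYears, sites = sites, species = species,
      scaling = scaling, variant = variant, responseKind = responseKind)
}

#' @describeIn CommunityData-class number of species
#' @param object,x a `CommunityData`
#' @export
setGeneric("nSpecies", function(object) standardGeneric("nSpecies"))

#' @rdname CommunityData-class
#' @export
setMethod("nSpecies", "CommunityData", function(object) {
  length(object@species)
})

#' @describeIn CommunityData-class the response array
#' @export
setGeneric("responseArray", function(object) standardGeneric("responseArray"))

#' @rdname CommunityData-class
#' @export
setMethod("responseArray", "CommunityData", function(object) object@response)

#' @describeIn CommunityData-class the process design matrix
#' @export
setGeneric("processMatrix", function(object) standardGeneric("processMatrix"))

#' @rdname CommunityData-class
#' @export
setMethod("processMatrix", "CommunityData", function(object) {
  object@processMatrix
})

#' @describeIn CommunityData-class the observation design array
#' @export
setGeneric("obsArray", function(object) standardGeneric("obsArray"))

#' @rdname CommunityData-class
#' @export
setMethod("obsArray", "CommunityData", function(object) object@obsArray)

#' @describeIn CommunityData-class site-year bookkeeping table
#' @export
setGeneric("siteYears", function(object) standardGeneric("siteYears"))

#' @rdname CommunityData-class
#' @export
setMethod("siteYears", "CommunityData", function(object) object@siteYears)

setMethod("show", "CommunityData", function(object) {
  dm <- dim(object@response)
  cat(sprintf(
    "CommunityData (%s, %s variant)\n  %d species x %d site-years x %d visits\n",
    object@responseKind, object@variant, dm[1L], dm[2L], dm[3L]))
  cat(sprintf("  process coefficients: %d (%s)\n", ncol(object@processMatrix),
              paste(head(colnames(object@processMatrix), 5L), collapse = ", ")))
  cat(sprintf("  observation coefficients: %d\n", dim(object@obsArray)[3L]))
  cat(sprintf("  sites: %d (%s)\n", nrow(object@sites),
              paste(table(object@sites$treatment), collapse = "/")))
})

#' CommunityChains: posterior draws from a community model fit
#'
#' MCMC output of [fitOccupancy()] or [fitAbundance()]: a list of per-chain
#' draw matrices (retained iterations by parameters), parameter names, the
#' marginal log-likelihood at each retained draw, the MCMC configuration, and
#' the dimensions of the data the model was fitted to.
#'
#' Parameter naming: `alpha[<species>,<coef>]` and `beta[<species>,<coef>]`
#' for species-level process/observation coefficients, `site[<site>]` for the
#' site random effects, `mu_alpha[...]`/`sd_alpha[...]` and
#' `mu_beta[...]`/`sd_beta[...]` for the community hyper-parameters, and
#' `sd_site` for the site-effect standard deviation.
#'
#' @slot draws list of numeric matrices, one per chain, each
#'   `nKept x nParameters` with column names.
#' @slot logLik list of numeric vectors (marginal log-likelihood per draw).
#' @slot paramNames character vector of parameter names.
#' @slot config list: `nChains`, `nIter`, `nBurn`, `nThin`, `seed`, `K`,
#'   `siteEffects`, acceptance rates.
#' @slot dataDims list describing the fitted data (species, site-years,
#'   visits, coefficient names, site table).
#' @seealso [fitOccupancy()], [fitAbundance()], [convergenceReport()]
#' @export
setClass("CommunityChains", representation(
  draws = "list",
  logLik = "list",
  paramNames = "character",
  config = "list",
  dataDims = "list"
))

setValidity("CommunityChains", function(object) {
  msg <- character()
  if (!length(object@draws)) msg <- c(msg, "no chains")
  npar <- vapply(object@draws, ncol, 1L)
  if (length(unique(npar)) > 1L)
    msg <- c(msg, "chains disagree on parameter count")
  if (npar[1L] != length(object@paramNames))
    msg <- c(msg, "paramNames must match draw columns")
  cfg <- object@config
  if (all(c("nIter", "nBurn", "nThin") %in% names(cfg))) {
    expect <- (cfg$nIter - cfg$nBurn) %/% cfg$nThin
    if (any(vapply(object@draws, nrow, 1L) != expect))
      msg <- c(msg, "retained draw count must equal (nIter - nBurn)/nThin")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityChains object directly
#'
#' Mainly for tests and for deriving summaries from externally produced
#' draws; fits produce this object themselves.
#'
#' @param draws list of per-chain matrices with identical named columns.
#' @param config MCMC configuration list; sensible defaults are filled in.
#' @param dataDims data description list (see [CommunityChains-class]).
#' @param logLik optional list of per-chain log-likelihood vectors.
#' @return A [CommunityChains-class] object.
#' @export
communityChains <- function(draws, config = list(), dataDims = list(),
                            logLik = NULL) {
  if (is.matrix(draws)) draws <- list(draws)
  nms <- colnames(draws[[1L]])
  if (is.null(nms)) stop("draw matrices must have column names")
  nkept <- nrow(draws[[1L]])
  defaults <- list(nChains = length(draws), nIter = nkept, nBurn = 0L,
                   nThin = 1L, seed = NA_integer_, K = NA_integer_,
                   siteEffects = any(grepl("^site\\[", nms)))
  config <- modifyList(defaults, config)
  if (is.null(logLik)) logLik <- lapply(draws, function(d) rep(NA_real_, nrow(d)))
  new("CommunityChains", draws = draws, logLik = logLik, paramNames = nms,
      config = config, dataDims = dataDims)
}

#' @describeIn CommunityChains-class number of chains
#' @param object a `CommunityChains`
#' @export
setGeneric("nChains", function(object) standardGeneric("nChains"))

#' @rdname CommunityChains-class
#' @export
setMethod("nChains", "CommunityChains", function(object) length(object@draws))

#' @describeIn CommunityChains-class retained draws per chain
#' @export
setGeneric("nDraws", function(object) standardGeneric("nDraws"))

#' @rdname CommunityChains-class
#' @export
setMethod("nDraws", "CommunityChains", function(object) {
  nrow(object@draws[[1L]])
})

#' @describeIn CommunityChains-class parameter names
#' @export
setGeneric("paramNames", function(object) standardGeneric("paramNames"))

#' @rdname CommunityChains-class
#' @export
setMethod("paramNames", "CommunityChains", function(object) object@paramNames)

#' Pooled draw matrix
#'
#' Stacks all chains into one matrix, optionally selecting parameters by
#' exact name or regular expression.
#'
#' @param object a [CommunityChains-class] object.
#' @param pars parameter names (exact) or a single regular expression when
#'   `regex = TRUE`; `NULL` keeps everything.
#' @param regex interpret `pars` as a regular expression.
#' @return numeric matrix, `(chains x draws) x selected parameters`.
#' @export
drawMatrix <- function(object, pars = NULL, regex = FALSE) {
  stopifnot(is(object, "CommunityChains"))
  keep <- seq_along(object@paramNames)
  if (!is.null(pars)) {
    keep <- if (regex) grep(pars, object@paramNames)
            else match(pars, object@paramNames)
    if (anyNA(keep)) stop("unknown parameter(s): ",
                          paste(pars[is.na(keep)], collapse = ", "))
    if (!length(keep)) stop("no parameters match '", pars, "'")
  }
  out <- do.call(rbind, lapply(object@draws, function(d) d[, keep, drop = FALSE]))
  colnames(out) <- object@paramNames[keep]
  out
}

setMethod("show", "CommunityChains", function(object) {
  cat(sprintf("CommunityChains: %d chain(s) x %d retained draws, %d parameters\n",
              nChains(object), nDraws(object), length(object@paramNames)))
  cfg <- object@config
  cat(sprintf("  MCMC: %s iterations, burn-in %s, thin %s, seed %s\n",
              cfg$nIter, cfg$nBurn, cfg$nThin, cfg$seed))
  if (!is.null(cfg$acceptProcess))
    cat(sprintf("  acceptance (process/observation blocks): %.2f / %.2f\n",
                cfg$acceptProcess, cfg$acceptObs))
})

#' Posterior medians and equal-tailed 95% intervals for draw columns
#'
#' @param draws numeric vector or matrix (draws in rows).
#' @param names optional row labels.
#' @return data.frame with `parameter`, `median`, `lower`, `upper`
#'   (type-7 quantiles, 2.5% and 97.5%).
#' @export
summarizeDraws <- function(draws, names = NULL) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1L)
  qs <- apply(draws, 2L, quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE, type = 7)
  out <- data.frame(parameter = if (!is.null(names)) names
                    else colnames(draws) %||% paste0("V", seq_len(ncol(draws))),
                    median = qs[1L, ], lower = qs[2L, ], upper = qs[3L, ])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
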