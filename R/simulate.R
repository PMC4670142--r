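#' @include study_data.R
NULL

# truncated-normal draws by rejection (lower truncation only; the
# truncation point is far enough into the body that rejection is cheap)
rtruncnorm <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulation configuration for the BACI buffer experiment
#'
#' Encodes the experimental design being emulated: 3 treatments x 6 replicate
#' sites surveyed in 1993 (pre-harvest), 1995--1996 and 2003--2004 with 6
#' visits per season, one site per treatment lost before the long-term
#' resurvey (18 sites pre-, 15 post-loss), ~28 species whose coefficients are
#' drawn from community normal hyper-distributions, and a site-level random
#' effect.
#'
#' Community hyper-means default to a neutral world: occupancy intercept 0
#' (psi ~ 0.5), detection intercept `qlogis(0.3)`, abundance intercept
#' `log(1.5)`, every treatment/year/covariate slot 0; all hyper-sds 0.5 and
#' site-effect sd 0.3. Pass `effects` (a named vector of hyper-means, e.g.
#' from [colonizationEffects()]) to override individual slots.
#'
#' @param nSpecies number of species (default 28).
#' @param sitesPerTreatment replicate sites per treatment (default 6).
#' @param dropPerTreatment sites per treatment lost before 2003--2004
#'   (default 1; the last site of each treatment is dropped, a deterministic
#'   rule that keeps tests reproducible).
#' @param years survey years.
#' @param visits visits per season.
#' @param variant model variant generating the data.
#' @param responseKind `"occupancy"` or `"abundance"`.
#' @param effects named numeric vector overriding process hyper-means.
#' @param obsEffects named numeric vector overriding observation hyper-means.
#' @param hyperSd common hyper-sd for every coefficient slot (default 0.5),
#'   or a named vector for slot-specific values.
#' @param obsHyperSd as `hyperSd` for the observation model (defaults to
#'   `hyperSd`).
#' @param sigmaSite site random-effect sd (default 0.3).
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulationConfig <- function(nSpecies = 28L, sitesPerTreatment = 6L,
                             dropPerTreatment = 1L,
                             years = DESIGN_YEARS, visits = 6L,
                             variant = "Design",
                             responseKind = c("occupancy", "abundance"),
                             effects = NULL, obsEffects = NULL,
                             hyperSd = 0.5, obsHyperSd = hyperSd,
                             sigmaSite = 0.3, seed = 1L) {
  responseKind <- match.arg(responseKind)
  stopifnot(nSpecies >= 1L, sitesPerTreatment >= 1L,
            dropPerTreatment >= 0L, all(hyperSd >= 0), sigmaSite >= 0)
  coefs <- variantCoefficients(variant)
  muProc <- setNames(rep(0, length(coefs$process)), coefs$process)
  muProc["Intercept"] <- if (responseKind == "abundance") log(1.5) else 0
  muObs <- setNames(rep(0, length(coefs$obs)), coefs$obs)
  muObs["Intercept"] <- qlogis(0.3)
  if (!is.null(effects)) {
    bad <- setdiff(names(effects), names(muProc))
    if (length(bad)) stop("unknown process slot(s): ",
                          paste(bad, collapse = ", "))
    muProc[names(effects)] <- effects
  }
  if (!is.null(obsEffects)) {
    bad <- setdiff(names(obsEffects), names(muObs))
    if (length(bad)) stop("unknown observation slot(s): ",
                          paste(bad, collapse = ", "))
    muObs[names(obsEffects)] <- obsEffects
  }
  expandSd <- function(s, slots) {
    if (length(s) == 1L && is.null(names(s)))
      return(setNames(rep(s, length(slots)), slots))
    out <- setNames(rep(0.5, length(slots)), slots)
    out[names(s)] <- s
    out
  }
  structure(list(
    nSpecies = as.integer(nSpecies),
    sitesPerTreatment = as.integer(sitesPerTreatment),
    dropPerTreatment = as.integer(dropPerTreatment),
    years = as.integer(years), visits = as.integer(visits),
    variant = variant, responseKind = responseKind,
    muProc = muProc, sdProc = expandSd(hyperSd, coefs$process),
    muObs = muObs, sdObs = expandSd(obsHyperSd, coefs$obs),
    sigmaSite = sigmaSite, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Preset hyper-means mimicking the published long-term pattern
#'
#' Positive year-by-treatment interaction hyper-means that grow with time
#' since harvest, stronger on the Wide treatment: the occupancy world in
#' which buffer treatments gain species over a decade while controls do not.
#'
#' @return named numeric vector suitable for `simulationConfig(effects = )`.
#' @export
colonizationEffects <- function() {
  c(Year.1995xNarrow = 0.3, Year.1996xNarrow = 0.3,
    Year.2003xNarrow = 0.8, Year.2004xNarrow = 0.8,
    Year.1995xWide = 0.5, Year.1996xWide = 0.5,
    Year.2003xWide = 1.2, Year.2004xWide = 1.2)
}

simSiteTable <- function(config) {
  sites <- data.frame(
    site = c(sprintf("C%02d", seq_len(config$sitesPerTreatment)),
             sprintf("N%02d", seq_len(config$sitesPerTreatment)),
             sprintf("W%02d", seq_len(config$sitesPerTreatment))),
    treatment = rep(TREATMENTS, each = config$sitesPerTreatment),
    stringsAsFactors = FALSE)
  # deterministic loss rule: the last dropPerTreatment sites of each
  # treatment are unavailable in the long-term years
  lost <- unlist(lapply(TREATMENTS, function(tr) {
    s <- sites$site[sites$treatment == tr]
    if (config$dropPerTreatment > 0L)
      s[seq(length(s) - config$dropPerTreatment + 1L, length(s))]
    else character()
  }))
  sites$lost <- sites$site %in% lost
  sites
}

#' Simulate site-year habitat covariates and visit dates
#'
#' Buffer widths are drawn per treated site from normals truncated at 0.5 m:
#' Narrow ~ N(13.1, 9.1), Wide ~ N(29.9, 15.5) (the observed treatment-level
#' width distributions); one width per site, constant across years. Controls
#' have no buffer (width `NA`). Vegetation covariates are drawn within the
#' observed treatment-level ranges: shrub cover truncated-N(12, 6) clamped to
#' [0, 100]; deciduous and hemlock/cedar stem counts truncated-N(90, 25),
#' Douglas-fir truncated-N(25, 10), rounded to integers. The 6 visit dates
#' are evenly spaced over days 105--181 (mid-April to late June), identical
#' for all sites and years.
#'
#' @param config a [simulationConfig()].
#' @param seed overrides `config$seed`.
#' @return list with `covariates` (site-year data.frame), `sites` (site
#'   table with loss flags) and `visitDates` (integer vector).
#' @export
simulateCovariates <- function(config, seed = config$seed) {
  set.seed(seed)
  sites <- simSiteTable(config)
  n <- nrow(sites)
  width <- rep(NA_real_, n)
  isN <- sites$treatment == "Narrow"
  isW <- sites$treatment == "Wide"
  width[isN] <- rtruncnorm(sum(isN), 13.1, 9.1, 0.5)
  width[isW] <- rtruncnorm(sum(isW), 29.9, 15.5, 0.5)

  grid <- expand.grid(site = sites$site, year = config$years,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$site, grid$year), ]
  rownames(grid) <- NULL
  nsy <- nrow(grid)
  covariates <- data.frame(
    site = grid$site, year = grid$year,
    buffer_width_m = width[match(grid$site, sites$site)],
    shrub_pct = pmin(100, rtruncnorm(nsy, 12, 6, 0)),
    n_dougfir = round(rtruncnorm(nsy, 25, 10, 0)),
    n_decid = round(rtruncnorm(nsy, 90, 25, 0)),
    n_hemcedar = round(rtruncnorm(nsy, 90, 25, 0)))
  # pre-harvest there is no buffer edge to measure
  covariates$buffer_width_m[covariates$year == 1993L] <- NA_real_
  visitDates <- round(seq(105, 181, length.out = config$visits))
  list(covariates = covariates, sites = sites, visitDates = visitDates)
}

#' Draw species-level coefficients from the community hyper-distributions
#'
#' Every coefficient slot is i.i.d. normal across species with the
#' configured hyper-mean and hyper-sd; site effects are N(0, sigmaSite).
#'
#' @param config a [simulationConfig()].
#' @param seed overrides `config$seed`.
#' @return list with matrices `alpha` (species x process slots), `beta`
#'   (species x observation slots) and vector `siteEffects`.
#' @export
drawSpeciesParams <- function(config, seed = config$seed) {
  set.seed(seed)
  S <- config$nSpecies
  alpha <- sapply(names(config$muProc), function(j)
    rnorm(S, config$muProc[j], config$sdProc[j]))
  beta <- sapply(names(config$muObs), function(j)
    rnorm(S, config$muObs[j], config$sdObs[j]))
  alpha <- matrix(alpha, nrow = S,
                  dimnames = list(sprintf("SP%02d", seq_len(S)),
                                  names(config$muProc)))
  beta <- matrix(beta, nrow = S,
                 dimnames = list(rownames(alpha), names(config$muObs)))
  nsite <- 3L * config$sitesPerTreatment
  list(alpha = alpha, beta = beta,
       siteEffects = rnorm(nsite, 0, config$sigmaSite))
}

# internal: design skeleton shared by both simulators.  Builds the surveyed
# site-year grid and the same design matrices buildModelData() would build
# from the written tables, so simulated truth lives on the fitted scale.
simSkeleton <- function(config, seed) {
  covs <- simulateCovariates(config, seed = seed)
  sites <- covs$sites
  longTerm <- config$years >= 2003L
  sy <- do.call(rbind, lapply(seq_len(nrow(sites)), function(k) {
    yrs <- config$years[!(longTerm & sites$lost[k])]
    data.frame(site = sites$site[k], treatment = sites$treatment[k],
               year = yrs, stringsAsFactors = FALSE)
  }))
  sy <- sy[order(sy$site, sy$year), ]
  rownames(sy) <- NULL
  # the generating model only defines the process on the rows the variant
  # analyses, so restrict the surveyed grid the same way
  if (config$variant == "Covariates")
    sy <- sy[sy$treatment != "Control" & sy$year != 1993L, , drop = FALSE]
  if (config$variant == "RandomEffects")
    sy <- sy[sy$year %in% c(2003L, 2004L), , drop = FALSE]
  rownames(sy) <- NULL
  # long-format survey row skeleton (site-year x visit), counts filled later
  skel <- merge(sy, data.frame(visit = seq_len(config$visits)))
  skel$date <- covs$visitDates[skel$visit]
  skel <- skel[order(skel$site, skel$year, skel$visit), ]
  rownames(skel) <- NULL
  list(covs = covs, sites = sites, siteYears = sy, skeleton = skel)
}

# linear predictors for the simulated world: builds a CommunityData shell
# with a zero response to obtain Xproc/Xobs exactly as fitting would
simDesignArrays <- function(config, sk) {
  skel <- sk$skeleton
  zero <- skel
  zero$species <- "SP01"
  zero$count <- 0L
  md <- buildModelData(zero, covariates = sk$covs$covariates,
                       variant = config$variant,
                       responseKind = "occupancy", species = "SP01")
  list(Xproc = processMatrix(md), Xobs = obsArray(md), siteYears = siteYears(md),
       siteIndex = md@siteIndex, scaling = md@scaling)
}

#' Simulate a multispecies occupancy dataset with known truth
#'
#' Draws species coefficients and site effects from the community
#' hyper-distributions, computes psi and p through the configured variant's
#' linear predictors on the simulated covariates, draws the latent occupancy
#' z once per species-site-year and detections per visit (detections are
#' impossible where z = 0), and returns both the observed tables (in the
#' [loadSurveyTable()] formats) and the generating truth.
#'
#' @param config a [simulationConfig()] with `responseKind = "occupancy"`.
#' @param seed overrides `config$seed`.
#' @return list of class `simulated_dataset`: `observations`, `covariates`,
#'   `visitDates`, `truth` (alpha, beta, siteEffects, z array, psi, config)
#'   and `modelData` (ready-to-fit [CommunityData-class]).
#' @export
simulateOccupancyDataset <- function(config = simulationConfig(),
                                     seed = config$seed) {
  stopifnot(config$responseKind == "occupancy")
  sk <- simSkeleton(config, seed)
  # separate stream for parameters so covariate draws stay comparable
  pars <- drawSpeciesParams(config, seed = seed + 1000L)
  des <- simDesignArrays(config, sk)
  set.seed(seed + 2000L)

  S <- config$nSpecies; M <- nrow(des$siteYears); L <- config$visits
  etaProc <- pars$alpha %*% t(des$Xproc) +
    matrix(pars$siteEffects[des$siteIndex], S, M, byrow = TRUE)
  psi <- plogis(etaProc)
  z <- matrix(rbinom(S * M, 1L, psi), S, M)
  y <- array(0, dim = c(S, M, L),
             dimnames = list(rownames(pars$alpha), NULL, NULL))
  for (l in seq_len(L)) {
    p <- plogis(pars$beta %*% t(des$Xobs[, l, ]))
    y[, , l] <- rbinom(S * M, 1L, p * z)
  }
  buildSimulatedDataset(config, sk, des, pars,
                        latent = z, y = y, psi = psi, lambda = NULL)
}

#' Simulate a multispecies N-mixture (abundance) dataset with known truth
#'
#' As [simulateOccupancyDataset()] but the latent state is the site-year
#' abundance N ~ Poisson(lambda), constant over the season's visits, and the
#' visit counts are Binomial(N, p) (so counts never exceed N).
#'
#' @param config a [simulationConfig()] with `responseKind = "abundance"`.
#' @param seed overrides `config$seed`.
#' @return list of class `simulated_dataset`; `truth$N` holds the latent
#'   abundances.
#' @export
simulateAbundanceDataset <- function(config = simulationConfig(
                                       responseKind = "abundance"),
                                     seed = config$seed) {
  stopifnot(config$responseKind == "abundance")
  sk <- simSkeleton(config, seed)
  pars <- drawSpeciesParams(config, seed = seed + 1000L)
  des <- simDesignArrays(config, sk)
  set.seed(seed + 2000L)

  S <- config$nSpecies; M <- nrow(des$siteYears); L <- config$visits
  etaProc <- pars$alpha %*% t(des$Xproc) +
    matrix(pars$siteEffects[des$siteIndex], S, M, byrow = TRUE)
  lambda <- exp(etaProc)
  N <- matrix(rpois(S * M, lambda), S, M)
  y <- array(0, dim = c(S, M, L),
             dimnames = list(rownames(pars$alpha), NULL, NULL))
  for (l in seq_len(L)) {
    p <- plogis(pars$beta %*% t(des$Xobs[, l, ]))
    y[, , l] <- rbinom(S * M, N, p)
  }
  buildSimulatedDataset(config, sk, des, pars,
                        latent = N, y = y, psi = NULL, lambda = lambda)
}

buildSimulatedDataset <- function(config, sk, des, pars, latent, y, psi,
                                  lambda) {
  S <- dim(y)[1L]; M <- dim(y)[2L]; L <- dim(y)[3L]
  skel <- sk$skeleton
  rowOf <- match(paste(skel$site, skel$year),
                 paste(des$siteYears$site, des$siteYears$year))
  obs <- do.call(rbind, lapply(seq_len(S), function(i) {
    o <- skel
    o$species <- rownames(pars$alpha)[i]
    o$count <- as.integer(y[cbind(i, rowOf, skel$visit)])
    o
  }))
  obs <- obs[order(obs$site, obs$year, obs$visit, obs$species),
             c("site", "treatment", "year", "visit", "date", "species",
               "count")]
  rownames(obs) <- NULL

  md <- communityData(
    response = y, processMatrix = des$Xproc, obsArray = des$Xobs,
    siteIndex = des$siteIndex, siteYears = des$siteYears,
    species = rownames(pars$alpha), scaling = des$scaling,
    variant = config$variant, responseKind = config$responseKind)

  truth <- list(alpha = pars$alpha, beta = pars$beta,
                siteEffects = pars$siteEffects,
                muProc = config$muProc, sdProc = config$sdProc,
                muObs = config$muObs, sdObs = config$sdObs,
                sigmaSite = config$sigmaSite,
                siteYears = des$siteYears)
  if (config$responseKind == "occupancy") {
    truth$z <- latent; truth$psi <- psi
  } else {
    truth$N <- latent; truth$lambda <- lambda
  }
  structure(list(observations = obs, covariates = sk$covs$covariates,
                 visitDates = sk$covs$visitDates, sites = sk$sites,
                 truth = truth, config = config, modelData = md),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated %s dataset (%s variant): %d species, %d sites, %d site-years\n",
              x$config$responseKind, x$config$variant, x$config$nSpecies,
              nrow(x$sites), nrow(x$truth$siteYears)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the survey CSV, covariate CSV and a truth JSON next to each other.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the files written.
#' @export
writeSimulatedDataset <- function(dataset, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  surveyPath <- file.path(dir, paste0(prefix, "_survey.csv"))
  covPath <- file.path(dir, paste0(prefix, "_covariates.csv"))
  truthPath <- file.path(dir, paste0(prefix, "_truth.json"))
  write.csv(dataset$observations, surveyPath, row.names = FALSE)
  write.csv(dataset$covariates, covPath, row.names = FALSE)
  tr <- dataset$truth
  jsonlite::write_json(list(
    alpha = tr$alpha, beta = tr$beta, siteEffects = tr$siteEffects,
    muProc = as.list(tr$muProc), sdProc = as.list(tr$sdProc),
    muObs = as.list(tr$muObs), sdObs = as.list(tr$sdObs),
    sigmaSite = tr$sigmaSite,
    latent = if (!is.null(tr$z)) tr$z else tr$N,
    siteYears = tr$siteYears), truthPath, digits = NA, auto_unbox = TRUE)
  c(survey = surveyPath, covariates = covPath, truth = truthPath)
}
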