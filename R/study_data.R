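#' @include classes.R
NULL

TREATMENTS <- c("Control", "Narrow", "Wide")
DESIGN_YEARS <- c(1993L, 1995L, 1996L, 2003L, 2004L)
HABITAT_COVARIATES <- c("BufferWidth", "Shrub", "DougFir", "Decid", "HemCedar")

surveyColumns <- c(site = "site", treatment = "treatment", year = "year",
                   visit = "visit", date = "date", species = "species",
                   count = "count")

#' Load a survey table (and optional covariate table) from CSV
#'
#' Reads long-format point-count records (one row per site or station, visit
#' and species), validates them, and infers the study design (sites with
#' treatment labels, year set, visit count, species list, missing
#' site-years). If a `station` column is present the records are station
#' level and should be collapsed with [aggregateStations()].
#'
#' @param path CSV with header; columns `site`, `treatment`, `year`, `visit`,
#'   `date` (day-of-year integer), `species`, `count` (plus optional
#'   `station`). Override names via `schema`.
#' @param covariatesPath optional CSV with columns `site`, `year`,
#'   `buffer_width_m`, `shrub_pct`, `n_dougfir`, `n_decid`, `n_hemcedar`.
#' @param schema named character vector mapping the canonical column names to
#'   the file's column names.
#' @return list with `observations` (data.frame), `covariates` (data.frame or
#'   `NULL`) and `design` (a `study_design` list: `sites`, `years`, `visits`,
#'   `species`, `missingSiteYears`).
#' @export
loadSurveyTable <- function(path, covariatesPath = NULL,
                            schema = surveyColumns) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  schema <- modifyList(as.list(surveyColumns), as.list(schema))
  need <- unlist(schema[names(surveyColumns)])
  missingCols <- setdiff(need, names(raw))
  if (length(missingCols))
    stop("schema error: missing required column(s): ",
         paste(missingCols, collapse = ", "))
  obs <- data.frame(
    site = as.character(raw[[schema$site]]),
    treatment = as.character(raw[[schema$treatment]]),
    year = as.integer(raw[[schema$year]]),
    visit = as.integer(raw[[schema$visit]]),
    date = as.integer(raw[[schema$date]]),
    species = as.character(raw[[schema$species]]),
    count = suppressWarnings(as.numeric(raw[[schema$count]])),
    stringsAsFactors = FALSE)
  if ("station" %in% names(raw)) obs$station <- as.character(raw$station)
  validateObservations(obs)
  obs$count <- as.integer(obs$count)

  covariates <- NULL
  if (!is.null(covariatesPath)) {
    if (!file.exists(covariatesPath))
      stop("covariate file not found: ", covariatesPath)
    covariates <- read.csv(covariatesPath, stringsAsFactors = FALSE)
    needCov <- c("site", "year", "buffer_width_m", "shrub_pct", "n_dougfir",
                 "n_decid", "n_hemcedar")
    missingCov <- setdiff(needCov, names(covariates))
    if (length(missingCov))
      stop("schema error: covariate file missing column(s): ",
           paste(missingCov, collapse = ", "))
    bad <- !is.na(covariates$shrub_pct) &
      (covariates$shrub_pct < 0 | covariates$shrub_pct > 100)
    if (any(bad))
      stop("validation error: shrub_pct outside [0,100] in covariate row(s) ",
           paste(which(bad), collapse = ", "))
    if (any(!is.na(covariates$buffer_width_m) & covariates$buffer_width_m < 0))
      stop("validation error: negative buffer width")
  }
  list(observations = obs, covariates = covariates,
       design = inferDesign(obs))
}

validateObservations <- function(obs) {
  if (anyNA(obs$count) || any(obs$count < 0))
    stop("validation error: negative or non-numeric count in row(s) ",
         paste(head(which(is.na(obs$count) | obs$count < 0), 5L),
               collapse = ", "))
  badTrt <- !obs$treatment %in% TREATMENTS
  if (any(badTrt))
    stop("validation error: unknown treatment '",
         obs$treatment[which(badTrt)[1L]], "' in row ", which(badTrt)[1L])
  badYear <- !obs$year %in% DESIGN_YEARS
  if (any(badYear))
    stop("validation error: year outside design year set in row ",
         which(badYear)[1L])
  if (any(obs$visit < 1L))
    stop("validation error: visit must be a positive integer")
  if (any(obs$date < 1L | obs$date > 365L))
    stop("validation error: julian date outside 1..365")
  # treatment constant per site
  trtBySite <- unique(obs[, c("site", "treatment")])
  dup <- duplicated(trtBySite$site)
  if (any(dup))
    stop("validation error: site '", trtBySite$site[dup][1L],
         "' has more than one treatment label")
  invisible(TRUE)
}

inferDesign <- function(obs) {
  sites <- unique(obs[, c("site", "treatment")])
  sites <- sites[order(sites$site), ]
  rownames(sites) <- NULL
  years <- sort(unique(obs$year))
  surveyed <- unique(obs[, c("site", "year")])
  grid <- expand.grid(site = sites$site, year = years,
                      stringsAsFactors = FALSE)
  key <- paste(grid$site, grid$year)
  missing <- grid[!key %in% paste(surveyed$site, surveyed$year), ]
  rownames(missing) <- NULL
  structure(list(
    sites = sites,
    years = years,
    visits = max(obs$visit),
    species = sort(unique(obs$species)),
    missingSiteYears = missing
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study design: %d sites (%s), years %s, %d visits, %d species\n",
              nrow(x$sites), paste(table(x$sites$treatment), collapse = "/"),
              paste(x$years, collapse = ","), x$visits, length(x$species)))
  if (nrow(x$missingSiteYears))
    cat(sprintf("  %d missing site-year(s)\n", nrow(x$missingSiteYears)))
  invisible(x)
}

#' Pool and filter species
#'
#' Applies the two species rules used in this kind of community analysis:
#' (1) species that cannot be separated in the field (here Hermit and
#' Townsend's warbler, which hybridize and share song) are pooled into one
#' code; (2) species with fewer than `minDetections` total detections
#' (counts summed over every record, all years and treatments combined) are
#' dropped. Pooling happens first, so two rare species can survive the filter
#' jointly. A species with exactly `minDetections` detections is retained.
#'
#' @param observations data.frame as returned by [loadSurveyTable()].
#' @param poolingMap named character vector mapping original species codes to
#'   pooled codes; default merges `HEWA` and `TOWA` into `HETO`.
#' @param minDetections minimum total detections to retain a species.
#' @return list with `observations` (pooled, filtered, re-aggregated) and
#'   `species` (sorted retained species codes).
#' @export
applySpeciesRules <- function(observations,
                              poolingMap = c(HEWA = "HETO", TOWA = "HETO"),
                              minDetections = 10L) {
  obs <- observations
  if (length(poolingMap)) {
    hit <- obs$species %in% names(poolingMap)
    obs$species[hit] <- unname(poolingMap[obs$species[hit]])
    # collapse records that now share a key
    keyCols <- intersect(c("site", "treatment", "year", "visit", "date",
                           "station", "species"), names(obs))
    agg <- aggregate(count ~ ., data = obs[, c(keyCols, "count")], FUN = sum)
    # a pooled key must not straddle two treatments for one site
    trtBySite <- unique(agg[, c("site", "treatment")])
    if (anyDuplicated(trtBySite$site))
      stop("pooling created conflicting treatment labels for a site")
    obs <- agg
  }
  totals <- tapply(obs$count, obs$species, sum)
  keep <- names(totals)[totals >= minDetections]
  obs <- obs[obs$species %in% keep, , drop = FALSE]
  obs <- obs[do.call(order, obs[intersect(c("site", "year", "visit", "species"),
                                          names(obs))]), , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs, species = sort(keep))
}

#' Aggregate station-level counts to one response per site and visit
#'
#' Sums counts across the point-count stations of a site for each visit and
#' species, the site being the experimental unit. The occupancy response is
#' derived downstream as `count > 0`.
#'
#' @param stationRecords data.frame with a `station` column in addition to
#'   the survey columns.
#' @return data.frame of site-level observations (no `station` column).
#' @export
aggregateStations <- function(stationRecords) {
  if (!"station" %in% names(stationRecords))
    stop("stationRecords must have a 'station' column")
  siteByStation <- unique(stationRecords[, c("station", "site")])
  dup <- duplicated(siteByStation$station)
  if (any(dup))
    stop("station '", siteByStation$station[dup][1L],
         "' is mapped to more than one site")
  agg <- aggregate(count ~ site + treatment + year + visit + date + species,
                   data = stationRecords, FUN = sum)
  agg <- agg[order(agg$site, agg$year, agg$visit, agg$species), ]
  rownames(agg) <- NULL
  agg
}

#' Center and scale continuous covariates
#'
#' Each covariate is replaced by `(x - mean)/sd` with the sample mean and
#' sample standard deviation computed over the supplied analysis rows and
#' returned in the scaling record (so raw values can be recovered by the
#' inverse transform).
#'
#' @param values data.frame or named list of numeric vectors.
#' @param columns which columns to scale (default: all).
#' @return list with `values` (scaled data.frame) and `scaling` (data.frame
#'   `covariate`, `mean`, `sd`).
#' @export
standardizeCovariates <- function(values, columns = NULL) {
  values <- as.data.frame(values)
  if (is.null(columns)) columns <- names(values)
  scaling <- data.frame(covariate = columns, mean = NA_real_, sd = NA_real_)
  for (k in seq_along(columns)) {
    x <- values[[columns[k]]]
    xs <- x[!is.na(x)]
    if (length(unique(xs)) < 2L)
      stop("zero variance covariate: ", columns[k])
    m <- mean(xs); s <- sd(xs)
    scaling$mean[k] <- m; scaling$sd[k] <- s
    values[[columns[k]]] <- (x - m) / s
  }
  list(values = values, scaling = scaling)
}

#' Undo covariate scaling
#'
#' @param values scaled data.frame.
#' @param scaling scaling record from [standardizeCovariates()].
#' @return data.frame on the original scale.
#' @export
unscaleCovariates <- function(values, scaling) {
  for (k in seq_len(nrow(scaling))) {
    cv <- scaling$covariate[k]
    values[[cv]] <- values[[cv]] * scaling$sd[k] + scaling$mean[k]
  }
  values
}

# ---- variant definitions --------------------------------------------------

#' Coefficient slots of each model variant
#'
#' Returns the process and observation design-matrix column names of the
#' three model variants. `Design` codes the BACI structure itself (year
#' dummies with 1993 baseline, treatment dummies with Control baseline, all
#' eight year-by-treatment interactions); `Covariates` replaces treatment
#' with five continuous habitat covariates on the post-harvest treated sites
#' (1995 baseline year); `RandomEffects` is intercept + Year.2004 on the
#' 2003--2004 data, with the habitat covariates moved to the detection model.
#'
#' @param variant `"Design"`, `"Covariates"` or `"RandomEffects"`.
#' @return list with `process` and `obs` character vectors.
#' @export
variantCoefficients <- function(variant = c("Design", "Covariates",
                                            "RandomEffects")) {
  variant <- match.arg(variant)
  switch(variant,
    Design = list(
      process = c("Intercept", "Year.1995", "Year.1996", "Year.2003",
                  "Year.2004", "Narrow", "Wide",
                  "Year.1995xNarrow", "Year.1996xNarrow", "Year.2003xNarrow",
                  "Year.2004xNarrow", "Year.1995xWide", "Year.1996xWide",
                  "Year.2003xWide", "Year.2004xWide"),
      obs = c("Intercept", "Year.1995", "Year.1996", "Year.2003", "Year.2004",
              "Trt.Narrow.det", "Trt.Wide.det", "Date", "Date2")),
    Covariates = list(
      process = c("Intercept", "Year.1996", "Year.2003", "Year.2004",
                  HABITAT_COVARIATES),
      obs = c("Intercept", "Year.1996", "Year.2003", "Year.2004",
              HABITAT_COVARIATES, "Date", "Date2")),
    RandomEffects = list(
      process = c("Intercept", "Year.2004"),
      obs = c("Intercept", "Year.2004", HABITAT_COVARIATES, "Date", "Date2")))
}

# harvest happened in 1994; detection-model treatment coding uses the
# treatment at time of measurement, so every site is "control" in 1993
postHarvest <- function(year) year >= 1995L

#' Assemble model-ready arrays for one variant
#'
#' Subsets the observations per the variant's rules, builds the response
#' array (species x site-year x visit; occupancy indicator `count > 0` or the
#' summed count), the process design matrix and the observation design array,
#' and centers/scales the continuous covariates (Julian date always; the five
#' habitat covariates where the variant uses them).
#'
#' Variant subsetting: `Design` keeps everything; `Covariates` keeps treated
#' sites in post-harvest years only (1995--2004); `RandomEffects` keeps all
#' sites in 2003--2004.
#'
#' @param observations site-level observations (after [applySpeciesRules()]).
#' @param covariates site-year habitat covariates (needed for `Covariates`
#'   and `RandomEffects`).
#' @param variant model variant, see [variantCoefficients()].
#' @param responseKind `"occupancy"` or `"abundance"`.
#' @param species optional species vector fixing dimension 1 (defaults to the
#'   species present in `observations`, sorted).
#' @return A [CommunityData-class] object.
#' @export
buildModelData <- function(observations, covariates = NULL,
                           variant = c("Design", "Covariates",
                                       "RandomEffects"),
                           responseKind = c("occupancy", "abundance"),
                           species = NULL) {
  variant <- match.arg(variant)
  responseKind <- match.arg(responseKind)
  obs <- observations

  obs <- switch(variant,
    Design = obs,
    Covariates = obs[obs$treatment != "Control" & obs$year != 1993L, ,
                     drop = FALSE],
    RandomEffects = obs[obs$year %in% c(2003L, 2004L), , drop = FALSE])
  if (!nrow(obs))
    stop("empty-data error: no observations left after '", variant,
         "' variant subsetting")

  if (is.null(species)) species <- sort(unique(obs$species))
  nVisits <- max(obs$visit)
  sy <- unique(obs[, c("site", "treatment", "year")])
  sy <- sy[order(sy$site, sy$year), ]
  rownames(sy) <- NULL
  M <- nrow(sy)
  syKey <- paste(sy$site, sy$year)
  rowOf <- match(paste(obs$site, obs$year), syKey)

  y <- array(NA_real_, dim = c(length(species), M, nVisits),
             dimnames = list(species, NULL, NULL))
  # visits actually made: a visit exists for a site-year if any species row
  # has it; unobserved (site-year, visit, species) combinations are zeros
  visited <- matrix(FALSE, M, nVisits)
  dateMat <- matrix(NA_real_, M, nVisits)
  visited[cbind(rowOf, obs$visit)] <- TRUE
  dateMat[cbind(rowOf, obs$visit)] <- obs$date
  for (m in seq_len(M)) y[, m, visited[m, ]] <- 0
  spOf <- match(obs$species, species)
  keep <- !is.na(spOf)
  y[cbind(spOf[keep], rowOf[keep], obs$visit[keep])] <-
    if (responseKind == "occupancy") as.numeric(obs$count[keep] > 0)
    else as.numeric(obs$count[keep])

  coefs <- variantCoefficients(variant)
  scaling <- data.frame(covariate = character(), mean = numeric(),
                        sd = numeric())

  # scaled Julian date over all retained survey rows, then squared
  dts <- standardizeCovariates(
    data.frame(Date = dateMat[!is.na(dateMat)]))
  scaling <- rbind(scaling, dts$scaling)
  dateScaled <- (dateMat - dts$scaling$mean) / dts$scaling$sd

  # habitat covariates per site-year where the variant needs them
  hab <- NULL
  if (any(HABITAT_COVARIATES %in% c(coefs$process, coefs$obs))) {
    if (is.null(covariates))
      stop("variant '", variant, "' requires site-year habitat covariates")
    cv <- covariates
    idx <- match(paste(sy$site, sy$year), paste(cv$site, cv$year))
    if (anyNA(idx)) {
      # fall back to the site's nearest available covariate year
      for (m in which(is.na(idx))) {
        cand <- which(cv$site == sy$site[m])
        if (!length(cand))
          stop("no habitat covariates for site ", sy$site[m])
        idx[m] <- cand[which.min(abs(cv$year[cand] - sy$year[m]))]
      }
    }
    hab <- data.frame(BufferWidth = cv$buffer_width_m[idx],
                      Shrub = cv$shrub_pct[idx],
                      DougFir = cv$n_dougfir[idx],
                      Decid = cv$n_decid[idx],
                      HemCedar = cv$n_hemcedar[idx])
    for (cc in HABITAT_COVARIATES) {
      sc <- standardizeCovariates(hab[cc])
      hab[[cc]] <- sc$values[[cc]]
      scaling <- rbind(scaling, sc$scaling)
    }
    # control sites have no buffer; hold them at the treated-site mean
    hab$BufferWidth[is.na(hab$BufferWidth)] <- 0
  }

  yearDummy <- function(yr) as.numeric(sy$year == yr)
  trtDummy <- function(tr) as.numeric(sy$treatment == tr)
  columnValue <- function(nm) {
    switch(nm,
      Intercept = rep(1, M),
      Year.1995 = yearDummy(1995L), Year.1996 = yearDummy(1996L),
      Year.2003 = yearDummy(2003L), Year.2004 = yearDummy(2004L),
      Narrow = trtDummy("Narrow"), Wide = trtDummy("Wide"),
      Year.1995xNarrow = yearDummy(1995L) * trtDummy("Narrow"),
      Year.1996xNarrow = yearDummy(1996L) * trtDummy("Narrow"),
      Year.2003xNarrow = yearDummy(2003L) * trtDummy("Narrow"),
      Year.2004xNarrow = yearDummy(2004L) * trtDummy("Narrow"),
      Year.1995xWide = yearDummy(1995L) * trtDummy("Wide"),
      Year.1996xWide = yearDummy(1996L) * trtDummy("Wide"),
      Year.2003xWide = yearDummy(2003L) * trtDummy("Wide"),
      Year.2004xWide = yearDummy(2004L) * trtDummy("Wide"),
      Trt.Narrow.det = trtDummy("Narrow") * postHarvest(sy$year),
      Trt.Wide.det = trtDummy("Wide") * postHarvest(sy$year),
      BufferWidth = hab$BufferWidth, Shrub = hab$Shrub,
      DougFir = hab$DougFir, Decid = hab$Decid, HemCedar = hab$HemCedar,
      stop("unknown design column: ", nm))
  }

  Xproc <- vapply(coefs$process, columnValue, numeric(M))
  dimnames(Xproc) <- list(NULL, coefs$process)

  Q <- length(coefs$obs)
  Xobs <- array(0, dim = c(M, nVisits, Q),
                dimnames = list(NULL, NULL, coefs$obs))
  for (q in seq_len(Q)) {
    nm <- coefs$obs[q]
    Xobs[, , q] <- switch(nm,
      Date = ifelse(is.na(dateScaled), 0, dateScaled),
      Date2 = ifelse(is.na(dateScaled), 0, dateScaled^2),
      matrix(columnValue(nm), M, nVisits))
  }

  sitesTab <- unique(sy[, c("site", "treatment")])
  rownames(sitesTab) <- NULL
  communityData(response = y, processMatrix = Xproc, obsArray = Xobs,
                siteIndex = match(sy$site, sitesTab$site),
                siteYears = sy, species = species, scaling = scaling,
                variant = variant, responseKind = responseKind)
}

# ---- serialization --------------------------------------------------------

#' Serialize a CommunityData object to JSON
#'
#' Writes a documented JSON container: dimensions, flattened arrays (column
#' major), design-matrix column names, bookkeeping tables and the scaling
#' record. [readModelData()] restores an identical object.
#'
#' @param data a [CommunityData-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModelData <- function(data, path) {
  stopifnot(is(data, "CommunityData"))
  payload <- list(
    format = "riparOcc-model-data",
    version = 1L,
    dims = dim(data@response),
    species = data@species,
    response = as.vector(data@response),
    processColumns = colnames(data@processMatrix),
    processMatrix = as.vector(data@processMatrix),
    obsColumns = dimnames(data@obsArray)[[3L]],
    obsArray = as.vector(data@obsArray),
    siteIndex = data@siteIndex,
    siteYears = data@siteYears,
    sites = data@sites,
    scaling = data@scaling,
    variant = data@variant,
    responseKind = data@responseKind)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Restore a CommunityData object written by [writeModelData()]
#'
#' @param path JSON file.
#' @return A [CommunityData-class] object.
#' @export
readModelData <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "riparOcc-model-data"))
    stop("not a riparOcc model-data file: ", path)
  dm <- as.integer(p$dims)
  y <- array(as.numeric(p$response), dim = dm,
             dimnames = list(p$species, NULL, NULL))
  Xproc <- matrix(as.numeric(p$processMatrix), dm[2L],
                  length(p$processColumns),
                  dimnames = list(NULL, p$processColumns))
  Xobs <- array(as.numeric(p$obsArray),
                dim = c(dm[2L], dm[3L], length(p$obsColumns)),
                dimnames = list(NULL, NULL, p$obsColumns))
  communityData(response = y, processMatrix = Xproc, obsArray = Xobs,
                siteIndex = as.integer(p$siteIndex),
                siteYears = as.data.frame(p$siteYears),
                species = p$species, scaling = as.data.frame(p$scaling),
                variant = p$variant, responseKind = p$responseKind)
}

#' Printed per-site buffer width table
#'
#' The post-treatment average buffer widths (m) by site, treatment and
#' measurement year that ship with the package, plus a summary by treatment
#' (mean, sd, min, max of the per-site averages).
#'
#' @return list with `table` (site, treatment, year, average_m, sd_m) and
#'   `summary` (per-treatment mean/sd/min/max).
#' @export
bufferWidthTable <- function() {
  path <- system.file("extdata", "buffer_widths.csv", package = "riparOcc")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  spl <- split(tab$average_m, tab$treatment)
  summary <- data.frame(
    treatment = names(spl),
    mean = vapply(spl, mean, 1),
    sd = vapply(spl, sd, 1),
    min = vapply(spl, min, 1),
    max = vapply(spl, max, 1))
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}
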