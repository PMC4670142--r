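#' @include latent.R
NULL

metricSummary <- function(draws, labels = NULL, extra = NULL) {
  # draws: matrix (posterior draws x groups); returns tidy summary with the
  # draw matrix retained as an attribute
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1L)
  out <- data.frame(
    median = apply(draws, 2L, median, na.rm = TRUE),
    lower = apply(draws, 2L, quantile, probs = 0.025, na.rm = TRUE,
                  names = FALSE, type = 7),
    upper = apply(draws, 2L, quantile, probs = 0.975, na.rm = TRUE,
                  names = FALSE, type = 7))
  if (!is.null(labels)) out <- cbind(labels, out)
  if (!is.null(extra)) out <- cbind(out, extra)
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  class(out) <- c("metric_summary", "data.frame")
  out
}

#' Posterior draw matrix behind a metric summary
#' @param x a `metric_summary` returned by the metric functions.
#' @return matrix (posterior draws x groups).
#' @export
metricDraws <- function(x) attr(x, "draws")

zArray <- function(zDraws) {
  if (inherits(zDraws, "occupancy_draws")) zDraws$z
  else if (inherits(zDraws, "abundance_draws")) zDraws$N
  else stop("expected occupancy_draws or abundance_draws")
}

#' Posterior species richness by site-year or treatment-year
#'
#' Per posterior draw, site-year richness is the number of species with
#' z = 1 at that site-year; the treatment-year value is the mean of those
#' richnesses over the treatment's surveyed sites in that year (the "mean
#' species richness for the three treatment by five year combinations").
#'
#' @param zDraws an `occupancy_draws` object from [conditionalZDraws()].
#' @param grouping `"site-year"` or `"treatment-year"`.
#' @return `metric_summary` data.frame, one row per group, with the per-draw
#'   values retained (see [metricDraws()]).
#' @export
speciesRichness <- function(zDraws, grouping = c("site-year",
                                                 "treatment-year")) {
  grouping <- match.arg(grouping)
  z <- zArray(zDraws)
  sy <- zDraws$siteYears
  rich <- apply(z > 0, c(1L, 3L), sum)   # draws x site-years (NA-> handled)
  rich <- matrix(rich, nrow = dim(z)[1L])
  if (grouping == "site-year") {
    if (!ncol(rich)) stop("empty group: no site-years")
    return(metricSummary(rich, labels = sy))
  }
  groups <- unique(sy[, c("treatment", "year")])
  groups <- groups[order(groups$treatment, groups$year), ]
  rownames(groups) <- NULL
  vals <- sapply(seq_len(nrow(groups)), function(g) {
    cols <- which(sy$treatment == groups$treatment[g] &
                    sy$year == groups$year[g])
    if (!length(cols)) stop("empty group: ", groups$treatment[g], " ",
                            groups$year[g])
    rowMeans(rich[, cols, drop = FALSE])
  })
  metricSummary(matrix(vals, nrow = nrow(rich)), labels = groups)
}

#' Posterior species similarity between two sites in one year
#'
#' Sorensen-type overlap of the latent occupancy vectors,
#' `S = 2 sum_i z1 z2 / (sum_i z1 + sum_i z2)`, per posterior draw. Draws
#' where both sites host no species (0/0) are undefined: they are dropped
#' and the dropped fraction reported.
#'
#' @param zDraws an `occupancy_draws`.
#' @param year survey year.
#' @param sitePair character vector of two site ids.
#' @return one-row `metric_summary` with a `droppedFraction` column.
#' @export
speciesSimilarity <- function(zDraws, year, sitePair) {
  stopifnot(length(sitePair) == 2L)
  z <- zArray(zDraws)
  sy <- zDraws$siteYears
  m1 <- which(sy$site == sitePair[1L] & sy$year == year)
  m2 <- which(sy$site == sitePair[2L] & sy$year == year)
  if (!length(m1) || !length(m2))
    stop("site not surveyed in ", year, ": ",
         sitePair[c(!length(m1), !length(m2))][1L])
  z1 <- matrix(z[, , m1], nrow = dim(z)[1L]) > 0
  z2 <- matrix(z[, , m2], nrow = dim(z)[1L]) > 0
  shared <- rowSums(z1 & z2)
  denom <- rowSums(z1) + rowSums(z2)
  s <- ifelse(denom == 0, NA_real_, 2 * shared / denom)
  metricSummary(s,
                labels = data.frame(year = year, site1 = sitePair[1L],
                                    site2 = sitePair[2L]),
                extra = data.frame(droppedFraction = mean(denom == 0)))
}

#' Posterior species turnover and local extinction between two years
#'
#' Over the supplied sites (surveyed in both years), per posterior draw:
#' `tau = sum z_to (1 - z_from) / sum z_from` (probability a species drawn at
#' random from the earlier community is replaced by a new one, with the
#' estimator normalized by the earlier year) and
#' `eps = sum (1 - z_to) z_from / sum z_from` (local extinction). Draws with
#' an empty earlier community are dropped and flagged.
#'
#' @param zDraws an `occupancy_draws`.
#' @param yearFrom,yearTo the two years compared.
#' @param sites site ids; default all sites surveyed in both years (sites
#'   surveyed in only one year are excluded with a warning).
#' @return two-row `metric_summary` (metric = "turnover", "extinction") with
#'   `droppedFraction`.
#' @export
turnoverExtinction <- function(zDraws, yearFrom, yearTo, sites = NULL) {
  z <- zArray(zDraws)
  sy <- zDraws$siteYears
  inFrom <- unique(sy$site[sy$year == yearFrom])
  inTo <- unique(sy$site[sy$year == yearTo])
  both <- intersect(inFrom, inTo)
  if (is.null(sites)) sites <- both
  dropped <- setdiff(sites, both)
  if (length(dropped)) {
    warning("site(s) surveyed in only one year excluded: ",
            paste(dropped, collapse = ", "))
    sites <- intersect(sites, both)
  }
  if (!length(sites)) stop("no site surveyed in both years")
  mFrom <- match(paste(sites, yearFrom), paste(sy$site, sy$year))
  mTo <- match(paste(sites, yearTo), paste(sy$site, sy$year))
  zF <- z[, , mFrom, drop = FALSE] > 0
  zT <- z[, , mTo, drop = FALSE] > 0
  denom <- apply(zF, 1L, sum)
  gained <- apply(zT & !zF, 1L, sum)
  lost <- apply(!zT & zF, 1L, sum)
  tau <- ifelse(denom == 0, NA_real_, gained / denom)
  eps <- ifelse(denom == 0, NA_real_, lost / denom)
  metricSummary(cbind(tau, eps),
                labels = data.frame(metric = c("turnover", "extinction"),
                                    yearFrom = yearFrom, yearTo = yearTo),
                extra = data.frame(droppedFraction = mean(denom == 0)))
}

#' Posterior total abundance by treatment and year
#'
#' Per posterior draw, the total number of individuals across all species
#' and the treatment's surveyed sites: `sum_i sum_k N(i, k)`.
#'
#' @param nDraws an `abundance_draws` from [conditionalNDraws()].
#' @param grouping `"treatment-year"` (default) or `"site-year"`.
#' @return `metric_summary`, one row per group.
#' @export
totalAbundance <- function(nDraws, grouping = c("treatment-year",
                                                "site-year")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(nDraws, "abundance_draws"))
  N <- nDraws$N
  sy <- nDraws$siteYears
  tot <- apply(N, c(1L, 3L), sum)        # draws x site-years
  tot <- matrix(tot, nrow = dim(N)[1L])
  if (grouping == "site-year") {
    if (!ncol(tot)) stop("empty group: no site-years")
    return(metricSummary(tot, labels = sy))
  }
  groups <- unique(sy[, c("treatment", "year")])
  groups <- groups[order(groups$treatment, groups$year), ]
  rownames(groups) <- NULL
  vals <- sapply(seq_len(nrow(groups)), function(g) {
    cols <- which(sy$treatment == groups$treatment[g] &
                    sy$year == groups$year[g])
    if (!length(cols)) stop("empty group")
    rowSums(tot[, cols, drop = FALSE])
  })
  metricSummary(matrix(vals, nrow = nrow(tot)), labels = groups)
}

#' BACI treatment contrasts from a Design-variant fit
#'
#' The treatment effect for a given year is the treatment main effect plus
#' the year-by-treatment interaction (zero in the 1993 baseline year): the
#' log-odds (occupancy) or log-rate (abundance) difference between that
#' treatment and the Control, adjusted for year. On the response scale a
#' contrast c becomes the multiplicative odds/rate change `exp(c)` (a
#' link-scale contrast of 1 is ~2.7-fold odds).
#'
#' Returned per species and for the community hyper-means, with an
#' `evidence` flag marking 95% intervals that exclude 0 (link scale).
#'
#' @param chains Design-variant [CommunityChains-class].
#' @param year design year.
#' @param treatment `"Narrow"` or `"Wide"`.
#' @param scale `"link"` or `"response"`.
#' @return `metric_summary` with one row per species plus a `community` row.
#' @export
treatmentContrasts <- function(chains, year, treatment = c("Narrow", "Wide"),
                               scale = c("link", "response")) {
  treatment <- match.arg(treatment)
  scale <- match.arg(scale)
  if (!is.null(chains@dataDims$variant) &&
      chains@dataDims$variant != "Design")
    stop("treatment contrasts are defined for the Design variant")
  if (!year %in% DESIGN_YEARS) stop("year outside the design: ", year)
  pooled <- drawMatrix(chains)
  sp <- chains@dataDims$species
  main <- sprintf("alpha[%s,%s]", sp, treatment)
  cDraws <- pooled[, main, drop = FALSE]
  muDraw <- pooled[, sprintf("mu_alpha[%s]", treatment)]
  if (year != 1993L) {
    inter <- sprintf("Year.%dx%s", year, treatment)
    cDraws <- cDraws + pooled[, sprintf("alpha[%s,%s]", sp, inter),
                              drop = FALSE]
    muDraw <- muDraw + pooled[, sprintf("mu_alpha[%s]", inter)]
  }
  cDraws <- cbind(cDraws, community = muDraw)
  evid <- apply(cDraws, 2L, function(v) {
    q <- quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    q[1L] > 0 || q[2L] < 0
  })
  if (scale == "response") cDraws <- exp(cDraws)
  metricSummary(cDraws,
                labels = data.frame(species = c(sp, "community"),
                                    year = year, treatment = treatment,
                                    scale = scale),
                extra = data.frame(evidence = unname(evid)))
}

#' Site-level richness and abundance vs buffer width
#'
#' From RandomEffects-variant (2003--2004) latent draws: for each site the
#' per-draw mean across its surveyed years of richness (or total abundance),
#' summarized by posterior median and 95% quantile interval, paired with the
#' site's buffer width. Control sites (no buffer) are flagged as the
#' reference group. Sites missing both years are excluded.
#'
#' @param latentDraws an `occupancy_draws` (richness) or `abundance_draws`
#'   (total abundance).
#' @param covariates site-year covariate table with `buffer_width_m` (or
#'   `NULL` to skip widths).
#' @return `metric_summary`, one row per surviving site, columns `site`,
#'   `treatment`, `bufferWidth`, `reference`.
#' @export
siteLevelSummary <- function(latentDraws, covariates = NULL) {
  arr <- zArray(latentDraws)
  sy <- latentDraws$siteYears
  isAbund <- inherits(latentDraws, "abundance_draws")
  perSY <- if (isAbund) apply(arr, c(1L, 3L), sum)
           else apply(arr > 0, c(1L, 3L), sum)
  perSY <- matrix(perSY, nrow = dim(arr)[1L])
  sites <- unique(sy[, c("site", "treatment")])
  rownames(sites) <- NULL
  vals <- sapply(seq_len(nrow(sites)), function(k) {
    cols <- which(sy$site == sites$site[k])
    rowMeans(perSY[, cols, drop = FALSE])
  })
  width <- rep(NA_real_, nrow(sites))
  if (!is.null(covariates)) {
    byS <- tapply(covariates$buffer_width_m, covariates$site,
                  function(v) mean(v, na.rm = TRUE))
    width <- as.numeric(byS[sites$site])
  }
  metricSummary(matrix(vals, ncol = nrow(sites)),
                labels = data.frame(site = sites$site,
                                    treatment = sites$treatment,
                                    bufferWidth = width,
                                    reference = sites$treatment == "Control"))
}
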