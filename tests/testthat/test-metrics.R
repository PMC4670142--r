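toySiteYears <- function(sites = c("k1", "k2"), years = 1993L,
                         treatment = "Narrow") {
  g <- expand.grid(site = sites, year = years, stringsAsFactors = FALSE)
  g$treatment <- treatment
  g[, c("site", "treatment", "year")]
}

test_that("species richness counts latent occupancies per group", {
  sy <- toySiteYears()
  # saturation: every species everywhere
  zd <- fixedZDraws(matrix(1, 3, 2), sy, nDraws = 5)
  r <- speciesRichness(zd, "site-year")
  expect_equal(r$median, c(3, 3))
  # hand count: A at site1 only, B at both, C nowhere
  z <- rbind(A = c(1, 0), B = c(1, 1), C = c(0, 0))
  r2 <- speciesRichness(fixedZDraws(z, sy), "site-year")
  expect_equal(r2$median, c(2, 1))
  # treatment-year level is the mean over the treatment's sites
  r3 <- speciesRichness(fixedZDraws(z, sy), "treatment-year")
  expect_equal(r3$median, 1.5)
  # richness never exceeds the species count in any draw
  set.seed(1)
  zr <- fixedZDraws(matrix(rbinom(6, 1, 0.5), 3, 2), sy, nDraws = 20)
  expect_true(all(metricDraws(speciesRichness(zr, "site-year")) <= 3))
})

test_that("similarity follows the Sorensen overlap of latent communities", {
  sy <- toySiteYears()
  same <- rbind(c(1, 1), c(1, 1), c(0, 0))
  expect_equal(speciesSimilarity(fixedZDraws(same, sy), 1993L,
                                 c("k1", "k2"))$median, 1)
  disjoint <- rbind(c(1, 0), c(0, 1), c(0, 0))
  expect_equal(speciesSimilarity(fixedZDraws(disjoint, sy), 1993L,
                                 c("k1", "k2"))$median, 0)
  # z1 = (1,1,0), z2 = (1,0,1): 2*1/(2+2) = 0.5
  z <- cbind(c(1, 1, 0), c(1, 0, 1))
  s <- speciesSimilarity(fixedZDraws(z, sy), 1993L, c("k1", "k2"))
  expect_equal(s$median, 0.5)
  # symmetric under exchanging the pair
  s2 <- speciesSimilarity(fixedZDraws(z, sy), 1993L, c("k2", "k1"))
  expect_equal(s$median, s2$median)
  # both-empty draws are undefined and reported as dropped
  empty <- matrix(0, 3, 2)
  sE <- speciesSimilarity(fixedZDraws(empty, sy), 1993L, c("k1", "k2"))
  expect_true(is.na(sE$median))
  expect_equal(sE$droppedFraction, 1)
  expect_error(speciesSimilarity(fixedZDraws(z, sy), 1995L, c("k1", "k2")),
               "not surveyed")
})

test_that("turnover and extinction follow their defining estimators", {
  sy <- toySiteYears(sites = "k1", years = c(1993L, 1995L))
  # no change: both zero
  zSame <- array(NA_real_, c(1, 2, 2))
  zSame[1, , ] <- rbind(c(1, 1), c(0, 0))
  zdSame <- structure(list(z = zSame, siteYears = sy,
                           species = c("A", "B")),
                      class = "occupancy_draws")
  te <- turnoverExtinction(zdSame, 1993L, 1995L)
  expect_equal(te$median, c(0, 0))
  # from {A, B} to {A, C}: tau = 0.5, eps = 0.5
  z <- array(NA_real_, c(1, 3, 2))
  z[1, , 1] <- c(1, 1, 0)   # 1993: A, B
  z[1, , 2] <- c(1, 0, 1)   # 1995: A, C
  zd <- structure(list(z = z, siteYears = sy, species = c("A", "B", "C")),
                  class = "occupancy_draws")
  te2 <- turnoverExtinction(zd, 1993L, 1995L)
  expect_equal(te2$median[te2$metric == "turnover"], 0.5)
  expect_equal(te2$median[te2$metric == "extinction"], 0.5)
  # saturated community: no turnover possible
  zF <- array(1, c(1, 3, 2))
  zdF <- structure(list(z = zF, siteYears = sy, species = c("A", "B", "C")),
                   class = "occupancy_draws")
  expect_equal(turnoverExtinction(zdF, 1993L, 1995L)$median, c(0, 0))
  # a site surveyed in one year only is excluded with a warning
  sy2 <- rbind(sy, data.frame(site = "k9", treatment = "Narrow",
                              year = 1993L))
  z2 <- array(1, c(1, 3, 3))
  zd2 <- structure(list(z = z2, siteYears = sy2,
                        species = c("A", "B", "C")),
                   class = "occupancy_draws")
  expect_warning(turnoverExtinction(zd2, 1993L, 1995L,
                                    sites = c("k1", "k9")), "excluded")
})

test_that("total abundance sums individuals and partitions by treatment", {
  sy <- rbind(toySiteYears(c("n1", "n2", "n3"), 1995L, "Narrow"),
              toySiteYears(c("c1", "c2"), 1995L, "Control"))
  N <- matrix(2, 1, 5)
  nd <- fixedNDraws(N, sy, nDraws = 3)
  tot <- totalAbundance(nd, "treatment-year")
  expect_equal(tot$median[tot$treatment == "Narrow"], 6)
  expect_equal(sum(tot$median), 10)
  # brute-force oracle on a random fixture
  set.seed(5)
  N2 <- matrix(rpois(10, 4), 2, 5)
  nd2 <- fixedNDraws(N2, sy)
  t2 <- totalAbundance(nd2, "treatment-year")
  expect_equal(t2$median[t2$treatment == "Control"],
               sum(N2[, sy$treatment == "Control"]))
  # partition identity holds draw by draw
  d <- metricDraws(t2)
  expect_equal(rowSums(d), rep(sum(N2), nrow(d)))
})

test_that("richness and abundance are monotone in the latent states", {
  sy <- toySiteYears()
  set.seed(9)
  z <- matrix(rbinom(8, 1, 0.5), 4, 2)
  zUp <- pmin(z + matrix(rbinom(8, 1, 0.3), 4, 2), 1)
  r <- speciesRichness(fixedZDraws(z, sy), "site-year")$median
  rUp <- speciesRichness(fixedZDraws(zUp, sy), "site-year")$median
  expect_true(all(rUp >= r))
  N <- matrix(rpois(8, 3), 4, 2)
  tot <- totalAbundance(fixedNDraws(N, sy), "site-year")$median
  totUp <- totalAbundance(fixedNDraws(N + 1, sy), "site-year")$median
  expect_true(all(totUp > tot))
})

test_that("metric medians on a frozen fixture match an independent tally", {
  # spreadsheet-style oracle: explicit loops, no package code
  sy <- rbind(toySiteYears(c("a", "b"), c(1993L, 1995L), "Narrow"))
  set.seed(33)
  D <- 7; S <- 5; M <- nrow(sy)
  z <- array(rbinom(D * S * M, 1, 0.6), c(D, S, M))
  zd <- structure(list(z = z, siteYears = sy,
                       species = sprintf("s%d", 1:S)),
                  class = "occupancy_draws")
  rich <- speciesRichness(zd, "site-year")
  for (m in seq_len(M)) {
    vals <- sapply(seq_len(D), function(d) sum(z[d, , m]))
    expect_equal(rich$median[m], median(vals))
  }
  sim <- speciesSimilarity(zd, 1993L, c("a", "b"))
  m1 <- which(sy$site == "a" & sy$year == 1993L)
  m2 <- which(sy$site == "b" & sy$year == 1993L)
  vals <- sapply(seq_len(D), function(d) {
    den <- sum(z[d, , m1]) + sum(z[d, , m2])
    if (den == 0) NA_real_ else 2 * sum(z[d, , m1] * z[d, , m2]) / den
  })
  expect_equal(sim$median, median(vals, na.rm = TRUE))
  # S, tau, eps always within [0, 1]
  expect_true(all(metricDraws(sim) >= 0 & metricDraws(sim) <= 1,
                  na.rm = TRUE))
  te <- turnoverExtinction(zd, 1993L, 1995L)
  d <- metricDraws(te)
  # extinction is a proportion of the earlier community; turnover under the
  # year-(j-1) normalization is non-negative but may exceed 1 when more
  # species arrive than were present
  expect_true(all(d[, "eps"] >= 0 & d[, "eps"] <= 1, na.rm = TRUE))
  expect_true(all(d[, "tau"] >= 0, na.rm = TRUE))
})

test_that("treatment contrasts assemble main effects and interactions", {
  sim <- simulateOccupancyDataset(simulationConfig(nSpecies = 2L), seed = 3)
  md <- sim$modelData
  sp <- md@species
  P <- ncol(processMatrix(md)); Q <- dim(obsArray(md))[3]
  alpha <- matrix(0, 2, P, dimnames = list(sp, colnames(processMatrix(md))))
  alpha[, "Narrow"] <- c(0.4, 0.2)
  alpha[, "Year.2003xNarrow"] <- c(0.6, 0.1)
  beta <- matrix(0, 2, Q)
  ch <- chainsFromParams(md, alpha, beta)
  ch@dataDims$variant <- "Design"
  # 2003 Narrow: main + interaction
  ct <- treatmentContrasts(ch, 2003L, "Narrow")
  expect_equal(ct$median[1:2], c(1.0, 0.3))
  # 1993 baseline year: main effect only
  ct93 <- treatmentContrasts(ch, 1993L, "Narrow")
  expect_equal(ct93$median[1:2], c(0.4, 0.2))
  # response scale: a link contrast of 1 is an e-fold (~2.7x) odds change
  ctR <- treatmentContrasts(ch, 2003L, "Narrow", scale = "response")
  expect_equal(ctR$median[1], exp(1))
  # null contrast maps to multiplier 1
  ctW <- treatmentContrasts(ch, 2003L, "Wide", scale = "response")
  expect_equal(ctW$median[1:2], c(1, 1))
  expect_error(treatmentContrasts(ch, 1994L, "Narrow"), "outside")
})

test_that("site-level summaries average posterior draws across years", {
  sy <- rbind(data.frame(site = "n1", treatment = "Narrow",
                         year = c(2003L, 2004L)),
              data.frame(site = "c1", treatment = "Control",
                         year = c(2003L, 2004L)))
  z <- rbind(c(1, 1, 1, 0), c(0, 1, 1, 0))   # 2 species x 4 site-years
  zd <- fixedZDraws(z, sy, nDraws = 4)
  covs <- data.frame(site = c("n1", "c1"), year = 2003L,
                     buffer_width_m = c(12.5, NA))
  s <- siteLevelSummary(zd, covs)
  expect_equal(nrow(s), 2L)
  # identical year values: the average equals that value
  n1 <- s[s$site == "n1", ]
  expect_equal(n1$median, mean(c(sum(z[, 1]), sum(z[, 2]))))
  expect_equal(n1$bufferWidth, 12.5)
  expect_true(s$reference[s$site == "c1"])
})
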