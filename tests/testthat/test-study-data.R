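test_that("survey tables load, validate and round-trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "survey.csv")
  writeLines(c("site,treatment,year,visit,date,species,count",
               "A,Control,1993,1,120,WIWR,2",
               "A,Control,1993,2,135,WIWR,0",
               "B,Narrow,1995,1,120,WIWR,1"), f)
  got <- loadSurveyTable(f)
  expect_equal(nrow(got$observations), 3L)
  expect_equal(nrow(got$design$sites), 2L)
  expect_equal(got$design$visits, 2L)
  # sites not surveyed in a year are carried as the missing mask
  expect_true(nrow(got$design$missingSiteYears) == 2L)

  # negative count rejected with the row named
  writeLines(c("site,treatment,year,visit,date,species,count",
               "A,Control,1993,1,120,WIWR,-1"), f)
  expect_error(loadSurveyTable(f), "validation error.*1")

  # missing column is a schema error
  writeLines(c("site,treatment,year,visit,species,count",
               "A,Control,1993,1,WIWR,1"), f)
  expect_error(loadSurveyTable(f), "schema error")

  # unknown treatment and out-of-design year rejected
  writeLines(c("site,treatment,year,visit,date,species,count",
               "A,Buffer,1993,1,120,WIWR,1"), f)
  expect_error(loadSurveyTable(f), "unknown treatment")
  writeLines(c("site,treatment,year,visit,date,species,count",
               "A,Control,1994,1,120,WIWR,1"), f)
  expect_error(loadSurveyTable(f), "year outside")

  # full write-then-load round trip of a simulated dataset
  sim <- simulateOccupancyDataset(simulationConfig(nSpecies = 3L), seed = 5)
  files <- writeSimulatedDataset(sim, dir)
  back <- loadSurveyTable(files["survey"], covariatesPath = files["covariates"])
  expect_equal(back$observations[names(sim$observations)],
               sim$observations)
  expect_equal(nrow(back$design$sites), 18L)
})

test_that("species pooling and the minimum-detection filter follow the rules", {
  obs <- data.frame(
    site = "A", treatment = "Control", year = 1993L,
    visit = rep(1:6, times = 4),
    date = rep(c(105L, 120L, 135L, 151L, 166L, 181L), 4),
    species = rep(c("HEWA", "TOWA", "WIWR", "RARE"), each = 6),
    count = c(c(1, 1, 1, 1, 1, 1),      # HEWA: 6
              c(2, 1, 1, 1, 0, 0),      # TOWA: 5
              c(2, 2, 2, 2, 1, 1),      # WIWR: 10 exactly
              c(3, 3, 3, 0, 0, 0)))     # RARE: 9
  got <- applySpeciesRules(obs)
  # HEWA(6)+TOWA(5) pooled to HETO with 11 detections: retained only pooled
  expect_setequal(got$species, c("HETO", "WIWR"))
  expect_equal(sum(got$observations$count[got$observations$species == "HETO"]),
               11)
  # exactly 10 detections is retained, 9 is dropped
  expect_true("WIWR" %in% got$species)
  expect_false("RARE" %in% got$species)
  # empty pooling map with everything at/above threshold is the identity
  keepAll <- applySpeciesRules(obs[obs$species == "WIWR", ],
                               poolingMap = c(), minDetections = 10L)
  expect_equal(keepAll$observations$count, obs$count[obs$species == "WIWR"])
  # species list is sorted and deterministic
  expect_equal(got$species, sort(got$species))
})

test_that("station counts aggregate to one site response per visit", {
  st <- data.frame(
    site = rep("A", 3), station = c("a1", "a2", "a3"),
    treatment = "Control", year = 1993L, visit = 1L, date = 120L,
    species = "WIWR", count = c(0, 1, 2))
  agg <- aggregateStations(st)
  expect_equal(agg$count, 3L)
  # all-zero stations give a zero site count (occupancy indicator 0)
  st$count <- 0
  expect_equal(aggregateStations(st)$count, 0L)
  # a station cannot belong to two sites
  st2 <- st
  st2$site[2] <- "B"
  st2$station[2] <- "a1"
  expect_error(aggregateStations(st2), "more than one site")
})

test_that("covariate standardization is invertible and rejects degenerate input", {
  got <- standardizeCovariates(data.frame(x = c(10, 20, 30)))
  expect_equal(got$values$x, c(-1, 0, 1))   # sample sd = 10
  expect_equal(got$scaling$mean, 20)
  expect_equal(got$scaling$sd, 10)
  # inverse transform reproduces the raw values
  back <- unscaleCovariates(got$values, got$scaling)
  expect_equal(back$x, c(10, 20, 30), tolerance = 1e-12)
  # already-standardized input is (numerically) unchanged
  twice <- standardizeCovariates(got$values)
  expect_equal(twice$values$x, got$values$x, tolerance = 1e-12)
  expect_error(standardizeCovariates(data.frame(x = rep(4, 5))),
               "zero variance.*x")
})

test_that("Design-variant rows reproduce hand dummy coding", {
  sim <- simulateOccupancyDataset(simulationConfig(nSpecies = 2L), seed = 2)
  md <- sim$modelData
  sy <- siteYears(md)
  X <- processMatrix(md)
  # a Narrow site in 2003: Narrow = 1, Year.2003 = 1, their interaction = 1,
  # every Wide column 0
  m <- which(sy$treatment == "Narrow" & sy$year == 2003L)[1L]
  expect_equal(unname(X[m, c("Narrow", "Year.2003", "Year.2003xNarrow")]),
               c(1, 1, 1))
  expect_true(all(X[m, grep("Wide", colnames(X))] == 0))
  # hand-coded full row for a Control site in 1993: intercept only
  m0 <- which(sy$treatment == "Control" & sy$year == 1993L)[1L]
  expect_equal(unname(X[m0, ]), c(1, rep(0, 14)))
  # detection treatment coding is treatment-at-measurement: all sites are
  # control in the pre-harvest year
  Xo <- obsArray(md)
  n93 <- which(sy$treatment == "Narrow" & sy$year == 1993L)[1L]
  expect_true(all(Xo[n93, , "Trt.Narrow.det"] == 0))
  n95 <- which(sy$treatment == "Narrow" & sy$year == 1995L)[1L]
  expect_true(all(Xo[n95, , "Trt.Narrow.det"] == 1))
  # every process row reproduced by hand dummy-coding
  hand <- cbind(1,
                sy$year == 1995, sy$year == 1996, sy$year == 2003,
                sy$year == 2004,
                sy$treatment == "Narrow", sy$treatment == "Wide",
                (sy$year == 1995) * (sy$treatment == "Narrow"),
                (sy$year == 1996) * (sy$treatment == "Narrow"),
                (sy$year == 2003) * (sy$treatment == "Narrow"),
                (sy$year == 2004) * (sy$treatment == "Narrow"),
                (sy$year == 1995) * (sy$treatment == "Wide"),
                (sy$year == 1996) * (sy$treatment == "Wide"),
                (sy$year == 2003) * (sy$treatment == "Wide"),
                (sy$year == 2004) * (sy$treatment == "Wide"))
  expect_equal(unname(X), unname(hand) * 1)
})

test_that("Covariates and RandomEffects variants subset and scale correctly", {
  sim <- simulateOccupancyDataset(simulationConfig(nSpecies = 2L), seed = 4)
  obs <- sim$observations
  cov <- sim$covariates
  mdC <- buildModelData(obs, cov, variant = "Covariates")
  syC <- siteYears(mdC)
  expect_false(any(syC$treatment == "Control"))
  expect_false(any(syC$year == 1993L))
  expect_setequal(colnames(processMatrix(mdC)),
                  c("Intercept", "Year.1996", "Year.2003", "Year.2004",
                    "BufferWidth", "Shrub", "DougFir", "Decid", "HemCedar"))
  # scaled covariates have mean ~0, sd ~1 over the analysis rows
  expect_equal(mean(processMatrix(mdC)[, "Shrub"]), 0, tolerance = 1e-10)
  expect_equal(sd(processMatrix(mdC)[, "Shrub"]), 1, tolerance = 1e-10)
  # the scaling record inverts to the raw covariate values
  sc <- mdC@scaling
  shrubRow <- sc[sc$covariate == "Shrub", ][1L, ]
  raw <- processMatrix(mdC)[, "Shrub"] * shrubRow$sd + shrubRow$mean
  expect_equal(raw,
               cov$shrub_pct[match(paste(syC$site, syC$year),
                                   paste(cov$site, cov$year))],
               tolerance = 1e-12)

  mdR <- buildModelData(obs, cov, variant = "RandomEffects")
  expect_true(all(siteYears(mdR)$year %in% c(2003L, 2004L)))
  expect_equal(colnames(processMatrix(mdR)), c("Intercept", "Year.2004"))
  # records from other years are simply absent
  expect_false(1995L %in% siteYears(mdR)$year)

  # only-control data cannot support the Covariates variant
  onlyCtl <- obs[obs$treatment == "Control", ]
  expect_error(buildModelData(onlyCtl, cov, variant = "Covariates"),
               "empty-data")
})

test_that("model data serializes to JSON and back unchanged", {
  sim <- simulateOccupancyDataset(simulationConfig(nSpecies = 3L), seed = 9)
  md <- sim$modelData
  f <- withr::local_tempfile(fileext = ".json")
  writeModelData(md, f)
  back <- readModelData(f)
  expect_equal(responseArray(back), responseArray(md))
  expect_equal(processMatrix(back), processMatrix(md))
  expect_equal(obsArray(back), obsArray(md))
  expect_equal(back@siteIndex, md@siteIndex)
  expect_equal(back@scaling$sd, md@scaling$sd)
})

test_that("aggregation and species filtering commute", {
  set.seed(42)
  for (rep in 1:3) {
    st <- expand.grid(station = c("a1", "a2"), site = "A", visit = 1:3,
                      species = c("X", "Y", "Z"), stringsAsFactors = FALSE)
    st$treatment <- "Control"; st$year <- 1993L; st$date <- 120L
    st$count <- rpois(nrow(st), 2)
    a1 <- applySpeciesRules(aggregateStations(st), poolingMap = c(),
                            minDetections = 8L)
    f1 <- applySpeciesRules(st, poolingMap = c(), minDetections = 8L)
    a2 <- aggregateStations(f1$observations)
    expect_equal(a1$observations[order(a1$observations$species,
                                       a1$observations$visit), ]$count,
                 a2[order(a2$species, a2$visit), ]$count)
    expect_setequal(a1$species, f1$species)
  }
})

test_that("the shipped buffer-width table reproduces the treatment summaries", {
  bw <- bufferWidthTable()
  s <- bw$summary
  expect_equal(s$min[s$treatment == "Narrow"], 6.7)
  expect_equal(s$max[s$treatment == "Narrow"], 25.5)
  expect_equal(s$min[s$treatment == "Wide"], 21.7)
  expect_equal(s$max[s$treatment == "Wide"], 40.7)
})
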