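test_that("world generation is deterministic and conserves the deforestation trajectory", {
  cfg <- worldConfig(nLat = 6L, nLon = 8L, nYears = 3L, seed = 4L,
                     defTrajectory = c(100, 50, 200))
  w1 <- generateWorld(cfg)
  w2 <- generateWorld(cfg)
  expect_identical(gridData(w1@precip), gridData(w2@precip))
  expect_identical(gridData(w1@deforestation), gridData(w2@deforestation))
  expect_identical(w1@mask, w2@mask)

  tot <- annualTotals(w1@deforestation, worldMask(w1))
  expect_equal(unname(tot), c(100, 50, 200), tolerance = 1e-9)
  # nothing is deforested outside the biome mask
  for (y in 1:3) expect_true(all(gridData(w1@deforestation)[, , y][!w1@mask] == 0))
  expect_true(all(gridData(w1@precip) >= 0))
})

test_that("drought years have drier dry seasons and warmer temperatures than climatology", {
  cfg <- worldConfig(nLat = 6L, nLon = 8L, nYears = 5L, seed = 9L,
                     droughtYears = 3L,
                     defTrajectory = c(80, 70, 60, 50, 40))
  w <- generateWorld(cfg)
  # independent loop over the emitted arrays
  dryP <- dryT <- numeric(5)
  for (y in 1:5) {
    ps <- ts <- c()
    for (m in 6:10) {
      t <- (y - 1) * 12 + m
      ps <- c(ps, mean(gridData(w@precip)[, , t][w@mask]))
      ts <- c(ts, mean(gridData(w@temperature)[, , t][w@mask]))
    }
    dryP[y] <- mean(ps); dryT[y] <- mean(ts)
  }
  expect_lt(dryP[3], mean(dryP))
  expect_gt(dryT[3], mean(dryT[-3]))
})

test_that("world configuration errors are caught", {
  expect_error(worldConfig(nYears = 2L, defTrajectory = c(1, 2)),
               "nYears")
  expect_error(worldConfig(nLat = 0L), "grid dimensions")
  expect_error(worldConfig(nYears = 4L, defTrajectory = c(1, 2, 3)),
               "defTrajectory length")
})

test_that("expected fire rate reproduces its reference point and elasticities", {
  p <- fireRateParams()
  expect_equal(expectedFireRate(p@tRef, p@pRef, p@dRef, 0, 1, p), p@beta0)
  # doubling deforestation multiplies the rate by 2^0.44
  mu1 <- expectedFireRate(25, 120, 10, 0.2, 7, p)
  mu2 <- expectedFireRate(25, 120, 20, 0.2, 7, p)
  expect_equal(mu2 / mu1, 2^0.44, tolerance = 1e-12)
  # +0.1 K multiplies the rate by 1.035
  mu3 <- expectedFireRate(25.1, 120, 10, 0.2, 7, p)
  expect_equal(mu3 / mu1, 1.035, tolerance = 1e-12)
  # halving precipitation multiplies the rate by 2^0.8
  mu4 <- expectedFireRate(25, 60, 10, 0.2, 7, p)
  expect_equal(mu4 / mu1, 2^0.8, tolerance = 1e-12)
  expect_error(expectedFireRate(NA, 100, 1, 0, 1, p), "non-finite")
  expect_error(expectedFireRate(25, 0, 1, 0, 1, p), "precip")
})

test_that("fire detections are mean-faithful to the generative rate", {
  cfg <- tinyConfig(seed = 21L, nPersistentSources = 0L)
  w <- generateWorld(cfg)
  # pick three masked cell-months and compare Monte-Carlo means to mu
  mu <- fireburden:::expectedRateArray(w)
  idx <- which(w@mask)[1:3]
  tSel <- c(5L, 20L, 40L)
  nrep <- 250L
  draws <- matrix(0, nrep, 3)
  for (r in seq_len(nrep)) {
    dets <- generateFireDetections(w, seed = 1000L + r)
    counts <- gridMonthlyFireCounts(dets, w)
    for (j in 1:3) {
      a <- gridData(counts)[, , tSel[j]]
      draws[r, j] <- a[idx[j]]
    }
  }
  for (j in 1:3) {
    muj <- mu[, , tSel[j]][idx[j]]
    se <- sd(draws[, j]) / sqrt(nrep)
    expect_lt(abs(mean(draws[, j]) - muj), 3 * se + 1e-9)
  }
})

test_that("the Poisson limit of the count noise has variance close to its mean", {
  cfg <- tinyConfig(seed = 3L, nPersistentSources = 0L, nbDispersion = 1e9)
  w <- generateWorld(cfg)
  idx <- which(w@mask)[2]
  nrep <- 1000L
  x <- numeric(nrep)
  for (r in seq_len(nrep)) {
    dets <- generateFireDetections(w, seed = 5000L + r)
    counts <- gridMonthlyFireCounts(dets, w)
    x[r] <- gridData(counts)[, , 10L][idx]
  }
  expect_gt(mean(x), 0)
  expect_lt(abs(var(x) / mean(x) - 1), 0.2)
})

test_that("a vanishing vegetation rate leaves only persistent-source detections", {
  cfg <- tinyConfig(seed = 2L,
                    fireParams = fireRateParams(beta0 = 1e-12))
  w <- generateWorld(cfg)
  dets <- generateFireDetections(w)
  expect_true(all(dets$persistent))
  ps <- persistentSourceCells(w)
  expect_equal(nrow(dets),
               nrow(ps) * cfg@persistentMonthlyCount * 12L * cfg@nYears)
  expect_true(all(cellIds(dets$lon, dets$lat, cfg) %in% ps$cell))
})

test_that("detection generation is deterministic and k <= 0 is rejected", {
  w <- tinyWorld()
  d1 <- generateFireDetections(w, seed = 7L)
  d2 <- generateFireDetections(w, seed = 7L)
  expect_identical(d1, d2)
  expect_error(generateFireDetections(w, dispersion = 0), "dispersion")
  expect_true(all(d1$confidence >= 0 & d1$confidence <= 100))
})

test_that("toy PM fields are background plus an exactly linear kernel smoothing", {
  cfg <- tinyConfig()
  co <- gridCoords(cfg)
  tm <- data.frame(year = rep(2003:2004, each = 12), month = rep(1:12, 2))
  zero <- GriddedField(array(0, c(6, 8, 24)), co$lat, co$lon, tm, "kg",
                       "emissions")
  pm0 <- generatePmField(zero, cfg)
  expect_true(all(gridData(pm0) == cfg@pmBackground))

  e <- zero
  set.seed(1)
  e@data[] <- runif(length(e@data), 0, 100)
  pm1 <- generatePmField(e, cfg)
  e2 <- e; e2@data <- 2 * e@data
  pm2 <- generatePmField(e2, cfg)
  expect_equal(gridData(pm2) - cfg@pmBackground,
               2 * (gridData(pm1) - cfg@pmBackground), tolerance = 1e-12)

  # interior point source on a grid wide enough to hold the whole kernel:
  # PM excess integrates to mass x scaling
  big <- worldConfig()
  cob <- gridCoords(big)
  ptArr <- array(0, c(big@nLat, big@nLon, 12))
  ptArr[10, 15, 2] <- 1234
  pt <- GriddedField(ptArr, cob$lat, cob$lon,
                     data.frame(year = 2003L, month = 1:12), "kg",
                     "emissions")
  pmp <- generatePmField(pt, big)
  excess <- gridData(pmp)[, , 1] - big@pmBackground
  expect_equal(sum(excess), 1234 * big@pmPerEmission, tolerance = 1e-9)
  expect_error(generatePmField({e@data[1] <- -1; e}, cfg), "non-negative")
})

test_that("population generation conserves totals and regional splits", {
  cfg <- worldConfig(nLat = 6L, nLon = 10L, nYears = 3L, seed = 5L,
                     defTrajectory = c(10, 10, 10),
                     populationTotal = 1e6,
                     regionSplit = c(west = 0.6, east = 0.4))
  d1 <- generatePopulation(cfg)
  d2 <- generatePopulation(cfg)
  expect_identical(gridData(d1$population), gridData(d2$population))
  pop <- gridData(d1$population)
  expect_true(all(pop >= 0))
  expect_equal(sum(pop), 1e6, tolerance = 1e-9)
  regTotals <- c(sum(pop[d1$regionField == 1]), sum(pop[d1$regionField == 2]))
  expect_equal(regTotals / 1e6, c(0.6, 0.4), tolerance = 0.01)
  expect_true(all(d1$regionField %in% 1:2))
  expect_equal(sum(d1$ageFractions), 1, tolerance = 1e-12)
})
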