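test_that("GEMM relative risk is 1 at the threshold and increases continuously above it", {
  params <- loadGemmParams()
  ages <- unique(params$age)
  for (age in ages[1:2]) {
    expect_equal(gemmRelativeRisk(2.4, params, "ncd_lri", age), 1)
    expect_equal(gemmRelativeRisk(0, params, "ncd_lri", age), 1)
    expect_equal(gemmRelativeRisk(1.7, params, "ncd_lri", age), 1)
  }
  pm <- seq(0, 80, by = 0.05)
  rr <- gemmRelativeRisk(pm, params, "ncd_lri", ages[1])
  expect_true(all(diff(rr) >= 0))
  expect_true(all(diff(rr[pm > 2.4]) > 0))
  # continuity at the threshold
  expect_lt(gemmRelativeRisk(2.4 + 1e-9, params, "ncd_lri", ages[1]) - 1,
            1e-6)
  # tier ordering
  expect_lt(gemmRelativeRisk(20, params, "ncd_lri", ages[1], "lower"),
            gemmRelativeRisk(20, params, "ncd_lri", ages[1], "mean"))
  expect_gt(gemmRelativeRisk(20, params, "ncd_lri", ages[1], "upper"),
            gemmRelativeRisk(20, params, "ncd_lri", ages[1], "mean"))
  expect_error(gemmRelativeRisk(10, params, "ncd_lri", "no-such-age"),
               "configuration error")
})

test_that("GEMM closed form holds when the logistic weight is saturated", {
  params <- simpleGemm(theta = 0.2, alpha = 1.6)
  pm <- 2.4 + 1.6 * (exp(1) - 1)
  expect_equal(gemmRelativeRisk(pm, params, "ncd_lri", "25-64"),
               exp(0.2), tolerance = 1e-9)
})

test_that("morbidity adjustment and attributable burden follow their formulas", {
  expect_equal(adjustRrForMorbidity(2, 0.141), 1.141)
  expect_equal(adjustRrForMorbidity(1.8, 1), 1.8)
  expect_equal(adjustRrForMorbidity(3, 0), 1)
  expect_error(adjustRrForMorbidity(0.9, 0.5), "rr")

  expect_equal(attributableBurden(1e5, 0.01, 1.25), 200)
  expect_equal(attributableBurden(1e5, 0.01, 1), 0)
  # attributable fraction saturates at 1
  expect_equal(attributableBurden(1e5, 0.01, 1e12), 1000, tolerance = 1e-6)

  expect_equal(computeDalys(0, 0), 0)
  expect_equal(computeDalys(70, 30), 100)
  expect_error(computeDalys(-1, 0), ">= 0")
})

test_that("averted burden is zero at identity, below threshold, and antisymmetric", {
  demog <- flatDemographics()
  params <- simpleGemm(ages = "25-64")
  pmA <- matrix(20, 4, 6); pmB <- matrix(10, 4, 6)

  same <- avertedBurden(pmA, pmA, demog, params)
  metricCols <- grep("_(mean|lower|upper)$", names(same), value = TRUE)
  expect_true(all(abs(as.matrix(same[, metricCols])) < 1e-12, na.rm = TRUE))

  low <- avertedBurden(matrix(2, 4, 6), matrix(1, 4, 6), demog, params)
  expect_true(all(abs(as.matrix(low[, setdiff(metricCols,
    grep("rate", metricCols, value = TRUE))])) < 1e-12))

  ab <- avertedBurden(pmA, pmB, demog, params)
  ba <- avertedBurden(pmB, pmA, demog, params)
  for (cl in metricCols)
    expect_equal(ab[[cl]], -ba[[cl]], tolerance = 1e-12)

  # DALYs = YLL + YLD exactly, per stratum and tier
  for (tier in c("mean", "lower", "upper"))
    expect_equal(ab[[paste0("dalys_", tier)]],
                 ab[[paste0("yll_", tier)]] + ab[[paste0("yld_", tier)]])

  # tier ordering holds when theta_se > 0
  expect_true(all(ab$deaths_lower <= ab$deaths_mean + 1e-12))
  expect_true(all(ab$deaths_mean <= ab$deaths_upper + 1e-12))
})

test_that("averted deaths match a hand-computed single-region case", {
  # uniform world: population 100,000, base mortality 0.01, pm 20 -> 10
  demog <- flatDemographics(nr = 1L, nc = 2L, total = 1e5, mortality = 0.01)
  demog$regionField[] <- 1L
  demog$regions <- demog$regions[1, ]
  demog$baselineRates <- demog$baselineRates[1, ]
  params <- simpleGemm(theta = 0.2, se = 0.02, alpha = 1.6)
  out <- avertedBurden(matrix(20, 1, 2), matrix(10, 1, 2), demog, params)
  # spreadsheet-style oracle
  rrAt <- function(pm, th) exp(th * log(1 + (pm - 2.4) / 1.6))
  handed <- function(th) 1e5 * 0.01 *
    ((1 - 1 / rrAt(20, th)) - (1 - 1 / rrAt(10, th)))
  row <- out[out$region == "A", ]
  expect_equal(row$deaths_mean, handed(0.2), tolerance = 1e-9)
  expect_equal(row$deaths_lower, handed(0.2 - 1.96 * 0.02), tolerance = 1e-9)
  expect_equal(row$deaths_upper, handed(0.2 + 1.96 * 0.02), tolerance = 1e-9)
  # the total row equals the single region
  tot <- out[out$region == "total", ]
  expect_equal(tot$deaths_mean, row$deaths_mean)
  # per-100,000 rate
  expect_equal(row$deaths_rate_mean, 1e5 * row$deaths_mean / 1e5)
})

test_that("regional aggregation computes rates and tolerates empty regions", {
  burden <- data.frame(region = c("A", "B"), outcome = "ncd_lri",
                       age = "25-64",
                       deaths_mean = c(30, 70), deaths_lower = c(20, 60),
                       deaths_upper = c(40, 80),
                       yll_mean = c(300, 700), yll_lower = c(2, 6),
                       yll_upper = c(4, 8),
                       yld_mean = c(3, 7), yld_lower = c(1, 2),
                       yld_upper = c(5, 9),
                       dalys_mean = c(303, 707), dalys_lower = c(3, 8),
                       dalys_upper = c(9, 17))
  out <- aggregateByRegion(burden, c(A = 5e4, B = 5e4))
  tot <- out[out$region == "total", ]
  expect_equal(tot$deaths_mean, 100)
  expect_equal(tot$dalys_mean, 1010)
  # equal populations: rates in the 3:7 burden ratio
  rA <- out$deaths_rate_mean[out$region == "A"]
  rB <- out$deaths_rate_mean[out$region == "B"]
  expect_equal(rA / rB, 3 / 7)
  # zero-population region reports NA rates, not an error
  out2 <- aggregateByRegion(burden, c(A = 5e4, B = 0))
  expect_true(is.na(out2$deaths_rate_mean[out2$region == "B"]))

  # aggregation commutes with DALY addition
  expect_equal(tot$yll_mean + tot$yld_mean, tot$dalys_mean)
})

test_that("burden increases with the control exposure, scenario held fixed", {
  demog <- flatDemographics()
  params <- simpleGemm()
  pmS <- matrix(8, 4, 6)
  prev <- -Inf
  for (pmc in c(10, 20, 40)) {
    out <- avertedBurden(matrix(pmc, 4, 6), pmS, demog, params)
    cur <- out$deaths_mean[out$region == "total"]
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("population-weighted mean PM matches hand arithmetic", {
  expect_equal(populationWeightedMean(matrix(5, 2, 2), matrix(7, 2, 2)), 5)
  pm <- matrix(c(0, 10), 1, 2); pop <- matrix(c(1, 3), 1, 2)
  expect_equal(populationWeightedMean(pm, pop), 7.5)
  expect_equal(populationWeightedMean(pm, pop * 100), 7.5)
  expect_error(populationWeightedMean(pm, matrix(0, 1, 2)), "> 0")
  mask <- matrix(c(TRUE, FALSE), 1, 2)
  expect_equal(populationWeightedMean(pm, pop, mask), 0)
})
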