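test_that("policy-target derivation and percent change follow their definitions", {
  expect_identical(derivePolicyTarget(3925, 16.34), 3283.6)
  expect_equal(derivePolicyTarget(3925, 0), 3925)
  expect_equal(derivePolicyTarget(1000, 50), 500)
  expect_error(derivePolicyTarget(1000, 100), "areaDifference")

  expect_equal(percentChange(27772, 4571, round = TRUE), -84)
  expect_equal(percentChange(50, 50), 0)
  expect_equal(percentChange(50, 145), 190)
  expect_error(percentChange(0, 1), "non-zero")
})

test_that("deforestation rescaling preserves the spatial pattern exactly", {
  g <- matrix(c(2, 8, 0, 0), 2, 2)
  out <- scaleDeforestationToTotal(g, 5)
  expect_equal(out, matrix(c(1, 4, 0, 0), 2, 2))
  # identity when the target equals the observed total
  expect_equal(scaleDeforestationToTotal(g, 10), g)
  # published-scale example: 10,851 -> 3,283.6 is a ~0.3026 multiplier
  g2 <- matrix(runif(100, 0, 300), 10, 10)
  g2 <- g2 / sum(g2) * 10851
  out2 <- scaleDeforestationToTotal(g2, 3283.6)
  expect_equal(sum(out2), 3283.6, tolerance = 1e-9)
  ratios <- out2 / g2
  expect_lt(max(abs(ratios / (3283.6 / 10851) - 1)), 1e-12)
  expect_error(scaleDeforestationToTotal(matrix(0, 2, 2), 5),
               "undefined-pattern")
  expect_equal(scaleDeforestationToTotal(matrix(0, 2, 2), 0),
               matrix(0, 2, 2))
})

test_that("monthly climatology averages per cell-month and ignores year order", {
  co <- gridCoords(tinyConfig())
  tm <- data.frame(year = rep(2003:2004, each = 12), month = rep(1:12, 2))
  a <- array(0, c(6, 8, 24))
  a[1, 1, 1] <- 10; a[1, 1, 13] <- 30
  f <- GriddedField(a, co$lat, co$lon, tm, "mm", "precip")
  cl <- climatologicalClimate(f)
  expect_equal(gridData(cl)[1, 1, 1], 20)
  # identical years collapse to any single year
  a2 <- a; a2[, , 13:24] <- a[, , 1:12]
  f2 <- GriddedField(a2, co$lat, co$lon, tm, "mm", "precip")
  expect_equal(gridData(climatologicalClimate(f2)), a[, , 1:12],
               ignore_attr = TRUE)
  # order invariance
  perm <- GriddedField(a[, , c(13:24, 1:12)], co$lat, co$lon,
                       data.frame(year = rep(c(2004, 2003), each = 12),
                                  month = rep(1:12, 2)), "mm", "precip")
  expect_equal(gridData(climatologicalClimate(perm)), gridData(cl))
  expect_error(climatologicalClimate(f, 2003), ">= 2 years")
})

test_that("scenario panels override only the declared drivers", {
  w <- tinyWorld()
  counts <- tinyCounts()
  base <- tinyTable()
  # control reproduces the base panel bit for bit
  ctrl <- buildScenarioPanel(w, counts, scenarioSpec("control"))
  expect_identical(ctrl, base)

  scenYears <- 2005:2006
  tgt <- buildScenarioPanel(w, counts,
                            scenarioSpec("target_deforestation",
                                         defTotals = 30,
                                         scenarioYears = scenYears))
  # non-deforestation columns untouched
  expect_identical(tgt$precip, base$precip)
  expect_identical(tgt$temperature, base$temperature)
  # per-year annual totals hit the target in scenario years
  defPerYear <- function(world, spec) {
    ww <- fireburden:::applyScenarioToWorld(world, spec)
    annualTotals(ww@deforestation, worldMask(ww))
  }
  tot <- defPerYear(w, scenarioSpec("target_deforestation", defTotals = 30,
                                    scenarioYears = scenYears))
  expect_equal(unname(tot[c("2005", "2006")]), c(30, 30), tolerance = 1e-9)
  expect_equal(unname(tot["2003"]), w@config@defTrajectory[1])

  # minimum-deforestation copies the minimum year's gridded field
  minY <- 2003L + which.min(w@config@defTrajectory) - 1L
  mi <- scenarioSpec("minimum_deforestation", defPatternSourceYear = minY,
                     scenarioYears = scenYears)
  wmin <- fireburden:::applyScenarioToWorld(w, mi)
  expect_equal(gridData(wmin@deforestation)[, , 3],
               gridData(w@deforestation)[, , which.min(w@config@defTrajectory)])

  # average climate: zero interannual variance per (cell, month) in scenario years
  av <- buildScenarioPanel(w, counts,
                           scenarioSpec("average_climate",
                                        climateMode = "climatology",
                                        scenarioYears = 2005:2006))
  sub <- av[av$year %in% 2005:2006, ]
  v <- tapply(sub$precip, list(sub$cell, sub$month), var)
  expect_true(all(v < 1e-18, na.rm = TRUE))
  expect_identical(av[av$year == 2004, ], base[base$year == 2004, ])

  # a spec with two active deforestation rules is invalid
  expect_error(scenarioSpec("bad", defTotals = 10,
                            defPatternSourceYear = 2003L), "one deforestation")
})

test_that("oracle-backed scenario predictions follow the closed-form elasticity", {
  w <- tinyWorld()
  counts <- tinyCounts()
  base <- tinyTable()
  allYears <- 2003:2006
  halved <- buildScenarioPanel(w, counts,
                               scenarioSpec("halved",
                                            defTotals = w@config@defTrajectory / 2,
                                            scenarioYears = allYears))
  orc <- oracleModel()
  rep <- predictScenarios(orc, list(control = base, halved = halved))
  hv <- rep[rep$scenario == "halved", ]
  expect_equal(hv$pct_change_vs_control,
               rep(100 * (0.5^0.44 - 1), nrow(hv)), tolerance = 1e-6)
  expect_equal(rep[rep$scenario == "control", "pct_change_vs_control"],
               rep(0, nrow(hv)))

  # monotonicity: lowering deforestation never increases the oracle total
  for (frac in c(0.8, 0.5, 0.2)) {
    pan <- buildScenarioPanel(w, counts,
                              scenarioSpec("down",
                                           defTotals = w@config@defTrajectory * frac,
                                           scenarioYears = allYears))
    r <- predictScenarios(orc, list(control = base, down = pan))
    expect_true(all(r[r$scenario == "down", "pct_change_vs_control"] <= 1e-9))
  }
})

test_that("emission scaling follows the predicted fire-count ratio with a zero-control floor", {
  co <- gridCoords(tinyConfig())
  tm <- data.frame(year = 2003L, month = 1:3)
  mk <- function(vals) GriddedField(array(vals, c(6, 8, 3)), co$lat, co$lon,
                                    tm, "count", "ml")
  ctrl <- mk(2); finn <- GriddedField(array(10, c(6, 8, 3)), co$lat, co$lon,
                                      tm, "kg", "finn")
  # identity when scenario equals control
  expect_equal(gridData(scaleEmissions(ctrl, ctrl, finn)), gridData(finn))
  # uniform 0.68 ratio scales the total by 0.68
  scen <- mk(2 * 0.68)
  out <- scaleEmissions(ctrl, scen, finn)
  expect_equal(sum(gridData(out)), 0.68 * sum(gridData(finn)),
               tolerance = 1e-12)
  # zero-control cells pass emissions through unchanged, with a warning
  ctrl0 <- ctrl; ctrl0@data[1, 1, 1] <- 0
  scen0 <- scen; scen0@data[1, 1, 1] <- 5
  expect_warning(out0 <- scaleEmissions(ctrl0, scen0, finn), "floor")
  expect_equal(gridData(out0)[1, 1, 1], 10)
  # misaligned grids are an error
  tm2 <- data.frame(year = 2004L, month = 1:3)
  misaligned <- GriddedField(array(2, c(6, 8, 3)), co$lat, co$lon, tm2,
                             "count", "ml")
  expect_error(scaleEmissions(ctrl, misaligned, finn), "alignment")
})
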