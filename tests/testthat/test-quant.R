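test_that("collagen shares form a probability vector with bounded densities", {
  sec <- smallSection(seed = 6)
  an <- analyzeSection(sec$image)
  zc <- an$collagen
  expect_true(zc@defined)
  expect_equal(sum(zc@shares), 1)
  expect_true(all(zc@shares >= 0))
  expect_true(all(is.na(zc@densities) | (zc@densities >= 0 & zc@densities <= 1)))
  expect_gte(zc@totalFraction, 0)
})

test_that("an empty collagen mask is flagged undefined", {
  mask <- matrix(TRUE, 60, 60)
  zm <- buildZoneMap(mask, data.frame(class = "PT", x_um = 30, y_um = 30,
                                      radius_um = 6), 1, 15)
  zc <- collagenByZone(matrix(FALSE, 60, 60), zm)
  expect_false(zc@defined)
  expect_equal(zc@totalFraction, 0)
  expect_equal(sum(zc@shares), 0)
  expect_error(collagenByZone(matrix(FALSE, 10, 10), zm), "dimensions")
})

test_that("periportal-only collagen yields a periportal share of one", {
  p <- conditionProfile("PHx+Gln", 2, steatoticFraction = 0,
                        ptFociDensity = 8, cvFociDensity = 2,
                        collagenTotal = 0.02,
                        collagenZoneWeights = c(PT = 0, PP = 1, TS = 0,
                                                PC = 0, CV = 0))
  s <- generateSection(p, 0.5, 0.5, 1, seed = 5,
                       opts = sectionOptions(tissueMarginUm = 20,
                                             vesselsPerMm2 = 0, nCracks = 0))
  an <- analyzeSection(s$image)
  expect_gte(an$collagen@shares[["PP"]], 0.98)
})

test_that("collagen ratio behaves on identical and shifted groups", {
  sec <- smallSection(seed = 6)
  zc <- analyzeSection(sec$image)$collagen
  expect_equal(collagenRatio(list(zc, zc), list(zc)), 1)
  zc0 <- collagenByZone(matrix(FALSE, 60, 60),
                        suppressWarnings(buildZoneMap(matrix(TRUE, 60, 60),
                                                      data.frame(), 1, 15)))
  expect_error(collagenRatio(list(zc), list(zc0)), "denominator")
})

test_that("group collagen ratio recovers the day-2 contrast", {
  za <- lapply(1:3, function(s)
    analyzeSection(smallSection(getProfile("PHx+Gln", 2), seed = s)$image)$collagen)
  zb <- lapply(4:6, function(s)
    analyzeSection(smallSection(getProfile("PHx-Gln", 2), seed = 10 + s)$image)$collagen)
  r <- collagenRatio(za, zb)
  expect_lt(abs(r - 1.2) / 1.2, 0.10)
})

test_that("steatosis quantification matches the planted fraction", {
  sec <- smallSection(seed = 14)
  an <- analyzeSection(sec$image)
  st <- an$steatosis
  planted <- sec$truth@params$steatoticFraction
  expect_lt(abs(st@fraction - planted), 0.02)
  expect_gt(st@medianDiameterUm, 5)
  expect_lt(st@medianDiameterUm, 40)
  # zero vacuoles -> zero fraction
  s0 <- suppressWarnings(smallSection(getProfile("sham+Gln", 0), seed = 8))
  an0 <- suppressWarnings(analyzeSection(s0$image))
  expect_equal(an0$steatosis@fraction, 0)
  expect_equal(an0$steatosis@nVacuoles, 0L)
  expect_error(steatosis(an$cavities, an$masks@support, 1, cellAreaUm2 = 0),
               "positive")
})

test_that("steatosis recovery is linear across the condition range", {
  fracs <- c(0.01, 0.06, 0.11, 0.16, 0.21, 0.26, 0.31, 0.35)
  grid <- expand.grid(f = fracs, s = 1:2)
  est <- mapply(function(f, s) {
    p <- conditionProfile("PHx+Gln", 2, steatoticFraction = f,
                          ptFociDensity = 4, cvFociDensity = 2,
                          collagenTotal = 0.01)
    sec <- generateSection(p, 0.6, 0.6, 1, seed = 100 * s + round(1000 * f),
                           opts = sectionOptions(tissueMarginUm = 20))
    c(planted = sec$truth@params$steatoticFraction,
      est = analyzeSection(sec$image)$steatosis@fraction)
  }, grid$f, grid$s)
  fit <- lm(est["est", ] ~ est["planted", ])
  expect_lt(abs(coef(fit)[2] - 1), 0.1)
  expect_lt(abs(coef(fit)[1]), 0.01)
})

test_that("foci density counts planted landmarks exactly", {
  lm <- plantLandmarks(1, 5, 2, 150, seed = 2)
  fd <- fociDensity(lm, 1)
  expect_equal(fd@ptPerMm2, 5)
  expect_equal(fd@cvPerMm2, 2)
  # doubling the area halves densities
  fd2 <- fociDensity(lm, 2)
  expect_equal(fd2@ptPerMm2, 2.5)
  fd0 <- fociDensity(lm[0, ], 1)
  expect_equal(c(fd0@ptPerMm2, fd0@cvPerMm2), c(0, 0))
  expect_error(fociDensity(lm, 0), "positive")
})

test_that("well-separated foci are counted exactly through the full pipeline", {
  for (s in 1:2) {
    lm <- plantLandmarks(0.49, 3, 1, minSepUm = 150, seed = s)
    g <- generateSection(getProfile("PHx+Gln", 4), 0.7, 0.7, 1,
                         seed = 30 + s, landmarks = lm,
                         opts = sectionOptions(tissueMarginUm = 0,
                                               saltCount = 0))
    an <- analyzeSection(g$image)
    tab <- cavityTable(an$cavities)
    expect_equal(sum(tab$class == "PT"), 3L)
    expect_equal(sum(tab$class == "CV"), 1L)
  }
})
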