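test_that("built-in profiles carry the reported condition values", {
  expect_equal(steatoticFraction(getProfile("PHx+Gln", 2)), 0.333)
  expect_equal(ptFociDensity(getProfile("PHx-Gln", 2)), 3.2)
  expect_equal(steatoticFraction(getProfile("sham-Gln", 0)), 0)
  em <- endpointMeans(getProfile("PHx+Gln", 2))
  expect_equal(em$mean[em$endpoint == "rlw_bw_pct"], 3.0)
  expect_equal(em$mean[em$endpoint == "pcna_pct"], 34.3)
  em1 <- endpointMeans(getProfile("PHx+Gln", 1))
  expect_equal(em1$mean[em1$endpoint == "ast_UL"], 11393)
  # the day-4 collagen totals encode the reported 4.9x group ratio
  expect_equal(collagenTotal(getProfile("PHx+Gln", 4)) /
                 collagenTotal(getProfile("PHx-Gln", 4)), 4.9)
  expect_error(getProfile("PHx+Gln", 3), "no profile")
})

test_that("landmark planting honors counts, separation and determinism", {
  lm <- plantLandmarks(1, 5, 2, 80, seed = 1)
  expect_equal(nrow(lm), 7L)
  expect_equal(sum(lm$class == "PT"), 5L)
  d <- as.matrix(dist(lm[, c("x_um", "y_um")]))
  expect_gte(min(d[upper.tri(d)]), 80)
  expect_equal(nrow(plantLandmarks(1, 0, 0, 80, seed = 1)), 0L)
  expect_identical(lm, plantLandmarks(1, 5, 2, 80, seed = 1))
  # separation invariant across seeds
  for (s in 2:5) {
    l <- plantLandmarks(0.25, 4, 2, 60, seed = s)
    dd <- as.matrix(dist(l[, c("x_um", "y_um")]))
    expect_gte(min(dd[upper.tri(dd)]), 60)
  }
  expect_error(plantLandmarks(0.25, 60, 0, 200, seed = 1), "infeasible")
})

test_that("section generation is deterministic and conserves planted counts", {
  a <- smallSection(seed = 21)
  b <- smallSection(seed = 21)
  expect_identical(shgChannel(a$image), shgChannel(b$image))
  expect_identical(tpefChannel(a$image), tpefChannel(b$image))
  expect_identical(a$truth@landmarks, b$truth@landmarks)
  expect_identical(a$truth@vacuoleMask, b$truth@vacuoleMask)
  p <- a$truth@params
  expect_equal(p$ptCount, sum(a$truth@landmarks$class == "PT"))
  expect_equal(p$cvCount, sum(a$truth@landmarks$class == "CV"))
  c_ <- smallSection(seed = 22)
  expect_false(identical(shgChannel(a$image), shgChannel(c_$image)))
})

test_that("zero steatosis renders no vacuoles", {
  s0 <- suppressWarnings(smallSection(getProfile("sham+Gln", 0), seed = 8))
  expect_equal(sum(s0$truth@vacuoleMask), 0)
  expect_equal(s0$truth@params$nVacuoles, 0L)
})

test_that("collagen confined to the periportal band stays within 100 um of a PT", {
  p <- conditionProfile("PHx+Gln", 2, steatoticFraction = 0,
                        ptFociDensity = 8, cvFociDensity = 2,
                        collagenTotal = 0.02,
                        collagenZoneWeights = c(PT = 0, PP = 1, TS = 0,
                                                PC = 0, CV = 0))
  s <- generateSection(p, 0.5, 0.5, 1, seed = 5,
                       opts = sectionOptions(tissueMarginUm = 20,
                                             vesselsPerMm2 = 0, nCracks = 0))
  lm <- s$truth@landmarks
  pt <- matrix(FALSE, 500, 500)
  for (i in which(lm$class == "PT"))
    pt <- hepzone:::stampDisc(pt, lm$x_um[i] + 0.5, lm$y_um[i] + 0.5,
                              lm$radius_um[i])
  d <- hepzone:::distToSet(pt, 1)
  expect_lte(max(d[s$truth@collagenMask]), 100)
})

test_that("realized steatotic fraction follows the binomial placement model", {
  s <- smallSection(seed = 13)
  p <- s$truth@params
  se <- sqrt(0.333 * 0.667 / p$nSites)
  expect_lt(abs(p$steatoticFraction - 0.333), 3 * se)
  # vacuole diameters respect the truncation range
  expect_true(all(p$vacuoleDiametersUm >= 5 - 1e-9))
  expect_true(all(p$vacuoleDiametersUm <= 40 + 1e-9))
})

test_that("degenerate generator inputs error", {
  p <- getProfile("PHx+Gln", 2)
  expect_error(generateSection(p, 0, 1, 1), "positive")
  expect_error(generateSection(p, 1, 1, 20), "smallest structure")
})
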