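sec <- smallSection()
tp <- tpefChannel(sec$image); sh <- shgChannel(sec$image)
truthTissue <- sec$truth@zoneMapTrue > 0
tis <- tissueMask(tp, 1)
sup <- sectionSupport(tis, 1)
col <- collagenMask(sh, tis, 1)

test_that("tissue support recovers the planted section geometry", {
  recall <- sum(sup & truthTissue) / sum(truthTissue)
  expect_gte(recall, 0.98)
  precision <- sum(sup & truthTissue) / sum(sup)
  expect_gte(precision, 0.98)
})

test_that("tissue masking is idempotent and rejects blank images", {
  tis2 <- tissueMask(tis * 255, 1)
  expect_equal(tis2 & TRUE, tis & TRUE, ignore_attr = TRUE)
  expect_error(tissueMask(matrix(0, 50, 50), 1), "degenerate")
})

test_that("collagen mask recovers planted fibrils and drops outside noise", {
  truthCol <- sec$truth@collagenMask
  tp_ <- sum(col & truthCol)
  f1 <- 2 * tp_ / (sum(col) + sum(truthCol))
  expect_gte(f1, 0.9)
  # salt specks planted outside the tissue never reach the mask
  expect_equal(sum(col & !truthTissue), 0)
  # collagen is always a subset of tissue
  expect_true(all(tis[col]))
})

test_that("a zero-collagen condition yields an empty collagen mask", {
  p0 <- conditionProfile("sham-Gln", 0, steatoticFraction = 0,
                         ptFociDensity = 0, cvFociDensity = 0,
                         collagenTotal = 0)
  s0 <- suppressWarnings(  # zero landmark densities: all-TS zone map
    generateSection(p0, 0.5, 0.5, 1, seed = 3,
                    opts = sectionOptions(tissueMarginUm = 20,
                                          vesselsPerMm2 = 0,
                                          nCracks = 0, saltCount = 200)))
  t0 <- tissueMask(tpefChannel(s0$image), 1)
  c0 <- collagenMask(shgChannel(s0$image), t0, 1)
  expect_equal(sum(c0), 0)
  expect_equal(sum(s0$truth@collagenMask), 0)
})

test_that("cavity detection recovers planted objects with correct areas", {
  cav <- detectCavities(tp, tis, col, 1, support = sup)
  tab <- cavityTable(cav)
  lm <- sec$truth@landmarks
  for (i in seq_len(nrow(lm))) {
    d <- sqrt((tab$centroid_x_um - lm$x_um[i])^2 +
                (tab$centroid_y_um - lm$y_um[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 5)
    trueArea <- pi * lm$radius_um[i]^2
    expect_lt(abs(tab$area_um2[j] - trueArea) / trueArea, 0.10)
  }
  # total detected vacuole-ish area tracks the planted vacuole mask
  vacArea <- sum(sec$truth@vacuoleMask)
  small <- tab$area_um2[tab$area_um2 < 1300 & !tab$border_flag]
  expect_lt(abs(sum(small) - vacArea) / vacArea, 0.10)
})

test_that("cavity features behave on constructed shapes", {
  # clean disc: circularity near 1, not border-flagged
  tp1 <- matrix(200, 120, 120)
  tp1 <- hepzone:::stampDisc(tp1, 60, 60, 15, 20)
  tis1 <- tissueMask(tp1, 1, minTissueUm2 = 100)
  cav1 <- detectCavities(tp1, tis1, matrix(FALSE, 120, 120), 1)
  tab1 <- cavityTable(cav1)
  expect_equal(nrow(tab1), 1L)
  expect_gte(tab1$circularity, 0.9)
  expect_lte(tab1$circularity, 1.05)
  expect_false(tab1$border_flag)
  expect_gte(tab1$solidity, 0.9)
  # elongated crack spanning the border: low circularity, flagged
  tp2 <- matrix(200, 120, 120)
  tp2[55:62, 1:80] <- 20
  tis2 <- tissueMask(tp2, 1, minTissueUm2 = 100)
  cav2 <- detectCavities(tp2, tis2, matrix(FALSE, 120, 120), 1)
  tab2 <- cavityTable(cav2)
  expect_equal(nrow(tab2), 1L)
  expect_lt(tab2$circularity, 0.4)
  expect_true(tab2$border_flag)
})

test_that("cavity areas are invariant to monotone intensity rescaling", {
  gamma <- function(x) round(255 * (x / 255)^0.7)
  cav <- detectCavities(tp, tis, col, 1, support = sup)
  tpg <- gamma(tp)
  tisg <- tissueMask(tpg, 1)
  supg <- sectionSupport(tisg, 1)
  cavg <- detectCavities(tpg, tisg, col, 1, support = supg)
  a1 <- sort(cavityTable(cav)$area_um2)
  a2 <- sort(cavityTable(cavg)$area_um2)
  expect_equal(a1, a2)
})
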