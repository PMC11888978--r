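test_that("the default rule tree encodes the class contrasts", {
  tree <- defaultClassTree()
  cls <- function(row) cavityTable(classifyCavities(
    new("CavitySet", table = row, labels = matrix(1L, 1, 1), pixelSize = 1),
    tree))$class
  # 12 um circular hollow without surrounding collagen -> lipid vacuole
  expect_equal(cls(featureRow(pi * 6^2, circularity = 0.95, ring = 0)),
               "vacuole")
  # 25 um lumen wrapped in collagen -> portal tract
  expect_equal(cls(featureRow(pi * 12.5^2, circularity = 0.9, ring = 0.6)),
               "PT")
  # large lumen without a ring -> central vein
  expect_equal(cls(featureRow(5000, circularity = 0.9, ring = 0.05)), "CV")
  # round mid-size hollow with a sparse ring -> vessel/duct
  expect_equal(cls(featureRow(700, circularity = 0.9, ring = 0.35)),
               "vessel_duct")
  # border contact dominates everything, and border objects are never vacuoles
  expect_equal(cls(featureRow(pi * 6^2, circularity = 0.95, ring = 0,
                              border = TRUE)), "crack")
})

test_that("classification errors name the object with the missing feature", {
  row <- featureRow(100)
  row$circularity <- NA
  cs <- new("CavitySet", table = row, labels = matrix(1L, 1, 1), pixelSize = 1)
  expect_error(classifyCavities(cs), "circularity")
})

test_that("CART fitting separates classes and handles degenerate input", {
  set.seed(2)
  n <- 60
  vac <- featureRow(100)[rep(1, n), ]
  vac$area_um2 <- runif(n, 30, 400); vac$collagen_ring_fraction <- runif(n, 0, 0.1)
  vac$class <- "vacuole"
  pt <- featureRow(100)[rep(1, n), ]
  pt$area_um2 <- runif(n, 1500, 3000); pt$collagen_ring_fraction <- runif(n, 0.5, 0.9)
  pt$class <- "PT"
  d <- rbind(vac, pt)
  d$equiv_diameter_um <- 2 * sqrt(d$area_um2 / pi)
  tree <- fitTree(d, maxDepth = 3, seed = 1)
  pred <- cavityTable(classifyCavities(
    new("CavitySet", table = d[, setdiff(names(d), "class")],
        labels = matrix(seq_len(2 * n), 2 * n, 1), pixelSize = 1),
    tree))$class
  expect_equal(mean(pred == d$class), 1)
  expect_warning(t1 <- fitTree(d[d$class == "PT", ], seed = 1), "one-leaf")
  expect_equal(t1@classes, "PT")
})

test_that("a trained tree matches the rule-based default on fresh sections", {
  train <- lapply(1:2, function(s) {
    sec <- smallSection(seed = s)
    an <- analyzeSection(sec$image)
    tab <- cavityTable(an$cavities)
    tab$truth <- truthClasses(sec, an$cavities)
    tab
  })
  train <- do.call(rbind, train)
  train$class <- train$truth
  fitted <- fitTree(train[, !(names(train) %in% c("truth"))], seed = 1)
  sec <- smallSection(seed = 77)
  an <- analyzeSection(sec$image)
  truth <- truthClasses(sec, an$cavities)
  predFit <- cavityTable(classifyCavities(an$cavities, fitted))$class
  predDef <- cavityTable(an$cavities)$class  # default tree via analyzeSection
  keep <- truth %in% c("PT", "CV", "vacuole")
  accFit <- mean(predFit[keep] == truth[keep])
  accDef <- mean(predDef[keep] == truth[keep])
  expect_gte(accDef, 0.95)
  expect_gte(accFit, accDef - 0.01)
})

test_that("zone bands follow the distance rules", {
  mask <- matrix(TRUE, 400, 400)
  lm <- data.frame(class = c("PT", "CV"), x_um = c(100, 300),
                   y_um = c(200, 200), radius_um = c(25, 40))
  zm <- buildZoneMap(mask, lm, 1, 100)
  zl <- zoneLabels(zm)
  # 50 um from the PT boundary -> periportal
  expect_equal(zl[100 + 25 + 50, 200], zoneCodes()[["PP"]])
  # inside the lumen -> PT
  expect_equal(zl[100, 200], zoneCodes()[["PT"]])
  # within band of both, nearer the PT -> periportal (60 vs 90 um)
  # PT boundary at x=125 (radius 25), CV boundary at x=260 (radius 40)
  expect_equal(zl[185, 200], zoneCodes()[["PP"]])  # 60 from PT, 75 from CV
  expect_equal(zl[230, 200], zoneCodes()[["PC"]])  # 105 from PT, 30 from CV
  # single PT, pixel beyond the band -> transitional
  zmSolo <- buildZoneMap(mask, lm[1, ], 1, 100)
  expect_equal(zoneLabels(zmSolo)[100 + 25 + 150, 200], zoneCodes()[["TS"]])
})

test_that("zones partition the mask and grow monotonically with the band", {
  sec <- smallSection(seed = 9)
  mask <- sec$truth@zoneMapTrue > 0
  lm <- sec$truth@landmarks
  zm100 <- buildZoneMap(mask, lm, 1, 100)
  expect_equal(sum(zoneAreas(zm100)), sum(mask))
  expect_true(all((zoneLabels(zm100) > 0) == mask))
  zm50 <- buildZoneMap(mask, lm, 1, 50)
  a50 <- zoneAreas(zm50); a100 <- zoneAreas(zm100)
  expect_gte(a100[["PP"]], a50[["PP"]])
  expect_gte(a100[["PC"]], a50[["PC"]])
  expect_warning(zm0 <- buildZoneMap(mask, lm[0, ], 1, 100), "landmark")
  a0 <- zoneAreas(zm0)
  expect_equal(unname(a0[["TS"]]), sum(mask))
})

test_that("zone labels match the brute-force nearest-boundary oracle", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 110
    mask <- matrix(runif(n * n) > 0.05, n, n)
    lm <- data.frame(class = c("PT", "PT", "CV"),
                     x_um = runif(3, 15, n - 15), y_um = runif(3, 15, n - 15),
                     radius_um = c(7, 5, 9))
    zl <- zoneLabels(buildZoneMap(mask, lm, 1, 28))
    ptm <- cvm <- matrix(FALSE, n, n)
    for (i in 1:3) {
      m <- hepzone:::stampDisc(matrix(FALSE, n, n),
                               lm$x_um[i] + 0.5, lm$y_um[i] + 0.5,
                               lm$radius_um[i])
      if (lm$class[i] == "PT") ptm <- ptm | m else cvm <- cvm | m
    }
    zb <- bruteZones(mask, ptm & mask, cvm & mask, 28)
    expect_identical(zl, zb)
  }
})

test_that("analysis zone map equals generator ground truth on planted landmarks", {
  sec <- smallSection(seed = 4)
  mask <- sec$truth@zoneMapTrue > 0
  zm <- buildZoneMap(mask, sec$truth@landmarks, 1, 100)
  expect_identical(zoneLabels(zm), sec$truth@zoneMapTrue)
})

test_that("object classification on synthetic sections is reliable", {
  accs <- vapply(c(11, 12), function(s) {
    sec <- smallSection(seed = s)
    an <- analyzeSection(sec$image)
    truth <- truthClasses(sec, an$cavities)
    pred <- cavityTable(an$cavities)$class
    keep <- truth %in% c("PT", "CV", "vacuole")
    mean(pred[keep] == truth[keep])
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("rule trees survive a JSON round trip", {
  tree <- defaultClassTree()
  path <- file.path(tempdir(), "tree.json")
  treeToJSON(tree, path)
  back <- treeFromJSON(path)
  row <- featureRow(pi * 6^2, circularity = 0.95, ring = 0)
  cs <- new("CavitySet", table = row, labels = matrix(1L, 1, 1), pixelSize = 1)
  expect_equal(cavityTable(classifyCavities(cs, back))$class, "vacuole")
})
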