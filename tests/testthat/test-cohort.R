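test_that("simulated endpoints are deterministic and match profile moments", {
  tab <- simulateEndpoints(nPerGroup = 1000, seed = 42)
  expect_identical(tab, simulateEndpoints(nPerGroup = 1000, seed = 42))
  m <- tab[tab$group == "PHx+Gln" & tab$day == 2, ]
  se <- sd(m$rlw_bw_pct) / sqrt(nrow(m))
  expect_lt(abs(mean(m$rlw_bw_pct) - 3.0), 3 * se)
  se2 <- sd(m$pcna_pct) / sqrt(nrow(m))
  expect_lt(abs(mean(m$pcna_pct) - 34.3), 3 * se2)
  # log-normal AST still matches the printed mean (law of large numbers)
  a <- tab[tab$group == "PHx+Gln" & tab$day == 1, ]
  expect_lt(abs(mean(a$ast_UL) - 11393) / 11393, 0.02)
  expect_true(all(a$ast_UL > 0))
  # unreported endpoints stay NA
  expect_true(all(is.na(a$rlw_bw_pct)))
  expect_error(simulateEndpoints(nPerGroup = 1), "at least 2")
})

test_that("group means converge to profile means at large n", {
  tab <- simulateEndpoints(nPerGroup = 10000, seed = 3)
  m <- tab[tab$group == "PHx-Gln" & tab$day == 4, ]
  se <- sd(m$rlw_bw_pct) / sqrt(nrow(m))
  expect_lt(abs(mean(m$rlw_bw_pct) - 2.7), 3 * se)
})

test_that("two identical groups give t near zero and p near one", {
  x <- rnorm(8, 10)
  tab <- data.frame(mouse_id = sprintf("m%02d", 1:16),
                    group = rep(c("A", "B"), each = 8), day = 2,
                    pcna_pct = c(x, x))
  cg <- compareGroups(tab, "pcna_pct", 2)
  expect_lt(abs(cg$statistic), 1e-8)
  expect_equal(cg$p_value, 1)
  expect_error(compareGroups(tab[1:9, ], "pcna_pct", 2), "replication")
})

test_that("the day-2 group separation is detected with high power", {
  prof <- builtinProfiles()[c("PHx+Gln:D2", "PHx-Gln:D2", "PHx+Gln:D4",
                              "PHx-Gln:D4")]
  hits <- vapply(1:200, function(i) {
    tab <- simulateEndpoints(prof, nPerGroup = 6, seed = i)
    compareGroups(tab, "rlw_bw_pct", 2)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Tukey HSD flags only pairs involving the shifted group", {
  mk <- function(g, m) conditionProfile(g, 2, endpointMeans = data.frame(
    endpoint = "pcna_pct", mean = m, sem = 1, n = 6))
  prof <- list(mk("sham+Gln", 10), mk("sham-Gln", 10), mk("PHx+Gln", 16))
  names(prof) <- c("sham+Gln:D2", "sham-Gln:D2", "PHx+Gln:D2")
  tab <- simulateEndpoints(prof, nPerGroup = 40, seed = 11)
  cg <- compareGroups(tab, "pcna_pct", 2)
  expect_equal(cg$method, "anova_tukey")
  tk <- cg$tukey
  shifted <- grepl("PHx\\+Gln", tk$pair)
  expect_true(all(tk$p_adj[shifted] < 0.05))
  expect_true(all(tk$p_adj[!shifted] > 0.05))
})

test_that("repeated measures require longitudinal data and detect group effects", {
  prof <- builtinProfiles()[c("PHx+Gln:D2", "PHx-Gln:D2")]
  tab1 <- simulateEndpoints(prof, nPerGroup = 6, seed = 1)
  expect_error(repeatedMeasures(tab1, "rlw_bw_pct"), "2 days")
  prof2 <- builtinProfiles()[c("PHx+Gln:D2", "PHx+Gln:D4",
                               "PHx-Gln:D2", "PHx-Gln:D4")]
  hits <- vapply(1:30, function(i) {
    tab <- simulateEndpoints(prof2, nPerGroup = 6, seed = i)
    repeatedMeasures(tab, "rlw_bw_pct")$p_group < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("the repeated-measures p value is uniform under the null", {
  ps <- vapply(1:300, function(i) {
    tab <- simulateEndpoints(nullProfiles(), nPerGroup = 6, seed = i)
    repeatedMeasures(tab, "pcna_pct")$p_group
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
})

test_that("singular or non-convergent fits are reported, not swallowed", {
  # two days, tiny n, zero between-mouse variance: singular fits are common
  found <- FALSE
  for (i in 1:10) {
    tab <- simulateEndpoints(nullProfiles(), nPerGroup = 3, seed = i, icc = 0)
    r <- repeatedMeasures(tab, "pcna_pct")
    if (length(r$messages)) { found <- TRUE; break }
  }
  expect_true(found)
})
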