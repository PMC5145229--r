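# Threshold-sweep engine and quality metrics.

test_that("confusion counts cross-tabulate decisions against labels", {
  labels <- c(rep("FALL", 3), rep("ADL", 4))
  allCorrect <- c(rep(TRUE, 3), rep(FALSE, 4))
  expect_equal(confusionCounts(allCorrect, labels),
               c(tp = 3L, fn = 0L, tn = 4L, fp = 0L))
  allPos <- rep(TRUE, 7)
  cc <- confusionCounts(allPos, labels)
  expect_equal(cc[["fn"]], 0L)
  expect_equal(cc[["tn"]], 0L)

  set.seed(41)
  dec <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  lab <- sample(c("FALL", "ADL"), 50, replace = TRUE, prob = c(0.3, 0.7))
  cc <- confusionCounts(dec, lab)
  expect_equal(cc[["tp"]], sum(dec & lab == "FALL"))
  expect_equal(cc[["fp"]], sum(dec & lab == "ADL"))
  expect_equal(sum(cc), 50L)

  expect_error(confusionCounts(TRUE, c("FALL", "ADL")), "equal length")
  expect_error(confusionCounts(c(TRUE, TRUE), c("FALL", "FALL")),
               "at least one")
})

test_that("degenerate grid values pin the sweep at the ROC corners", {
  d <- separableDataset()
  low <- sweepThresholds(d, "bt", "waist", grid = 0.01)
  expect_equal(sensitivity(low), 1)
  expect_equal(specificity(low), 0)
  high <- sweepThresholds(d, "bt", "waist", grid = 1e6)
  expect_equal(sensitivity(high), 0)
  expect_equal(specificity(high), 1)
})

test_that("a separable dataset admits a perfect operating point", {
  d <- separableDataset(adlPeak = 1.5, fallPeak = 4)
  sw <- sweepThresholds(d, "bt", "waist", n = 100)
  se <- sensitivity(sw); sp <- specificity(sw)
  expect_true(any(se == 1 & sp == 1))
  expect_equal(aucTrapezoid(rocPoints(sw)), 1)
  expect_equal(maxGeomean(sw)$maxGeomean, 1)
})

test_that("sweep confusion counts agree with running detectors and fusing
           by hand", {
  d <- genDataset(generatorConfig(nSubjects = 2, trialsPerMovement = 1,
                                  nNonFallSubjects = 0, seed = 5))
  combo <- c("waist", "wrist")
  grid <- c(gToMs2(1.5), gToMs2(2.5))
  for (alg in c("bt", "ifall")) {
    sw <- sweepThresholds(d, alg, combo, grid = grid)
    for (k in seq_along(grid)) {
      dec <- vapply(trials(d), function(tr) {
        per <- vapply(combo, function(p)
          fallfusion:::runDetector(streams(tr)[[p]], alg, grid[k]),
          logical(1))
        fuseAnd(setNames(per, combo), combo)
      }, logical(1))
      cc <- confusionCounts(dec, fixtureLabels(d))
      expect_equal(c(sw@tp[k], sw@fn[k], sw@tn[k], sw@fp[k]),
                   unname(cc[c("tp", "fn", "tn", "fp")]),
                   label = sprintf("%s threshold %d", alg, k))
    }
  }
})

test_that("sensitivity falls and specificity rises along the grid", {
  d <- genDataset(generatorConfig(nSubjects = 2, trialsPerMovement = 1,
                                  nNonFallSubjects = 0, seed = 6))
  for (alg in algorithmIds()) {
    sw <- sweepThresholds(d, alg, "waist", n = 60)
    expect_true(all(diff(sensitivity(sw)) <= 0), label = alg)
    expect_true(all(diff(specificity(sw)) >= 0), label = alg)
  }
})

test_that("ROC points are sorted, anchored, and integrate correctly", {
  pts <- data.frame(fpr = c(0, 0, 1), se = c(0, 1, 1))
  expect_equal(aucTrapezoid(pts), 1)
  expect_equal(aucTrapezoid(data.frame(fpr = c(0, 1), se = c(0, 1))), 0.5)
  expect_error(aucTrapezoid(data.frame(fpr = c(0.5, 0.2), se = c(0, 1))),
               "sorted")

  d <- separableDataset()
  roc <- rocPoints(sweepThresholds(d, "bt", "waist", n = 50))
  expect_equal(roc[1, ], data.frame(fpr = 0, se = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, se = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(any(roc$fpr == 0 & roc$se == 1))  # perfect separation
})

test_that("trapezoidal AUC equals the rectangle decomposition of a
           monotone staircase", {
  set.seed(42)
  for (rep in 1:20) {
    nStep <- sample(2:8, 1)
    x <- sort(c(0, runif(nStep - 1), 1))
    y <- sort(c(0, runif(nStep - 1), 1))
    # staircase polyline: right step at each x, then rise
    pts <- data.frame(fpr = c(rep(x, each = 2)[-1]),
                      se = c(rep(y, each = 2)[-(2 * nStep + 2)]))
    rectangles <- sum(diff(x) * y[-length(y)])
    expect_equal(aucTrapezoid(pts), rectangles)
  }
})

test_that("sweep AUC agrees with an independent ROC implementation", {
  set.seed(43)
  scores <- c(rnorm(60, 10, 2), rnorm(40, 14, 2))
  labels <- c(rep("ADL", 60), rep("FALL", 40))
  trialsList <- lapply(seq_along(scores), function(i)
    makeTrial(abs(scores[i]), if (labels[i] == "FALL") "lateral" else "walk",
              trialIndex = i))
  d <- FallDataset(trialsList)
  cuts <- sort(unique(abs(scores)))
  grid <- (head(cuts, -1) + tail(cuts, -1)) / 2  # all midpoints
  sw <- sweepThresholds(d, "bt", "waist", grid = grid)
  auc <- aucTrapezoid(rocPoints(sw))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, abs(scores), levels = c("ADL", "FALL"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc, ref, tolerance = 1e-10)
})

test_that("AUC is near 1/2 when the classes share one distribution", {
  set.seed(44)
  nF <- 120; nA <- 120
  scores <- abs(rnorm(nF + nA, 12, 3))
  labels <- c(rep("FALL", nF), rep("ADL", nA))
  trialsList <- lapply(seq_along(scores), function(i)
    makeTrial(scores[i], if (labels[i] == "FALL") "lateral" else "walk",
              trialIndex = i))
  sw <- sweepThresholds(FallDataset(trialsList), "bt", "waist", n = 300)
  auc <- aucTrapezoid(rocPoints(sw))
  sdAuc <- sqrt((nF + nA + 1) / (12 * nF * nA))  # null-case approximation
  expect_lt(abs(auc - 0.5), 3 * sdAuc + 0.02)
})

test_that("maximum geometric mean scans the sweep exhaustively", {
  d <- separableDataset()
  sw <- sweepThresholds(d, "bt", "waist", n = 80)
  gm <- maxGeomean(sw)
  se <- sensitivity(sw); sp <- specificity(sw)
  expect_equal(gm$maxGeomean, max(sqrt(se * sp)))
  expect_equal(gm$maxProduct, gm$maxGeomean^2)
  expect_true(all(gm$maxGeomean >= sqrt(se * sp)))

  # degenerate corners only -> geometric mean 0
  sw0 <- new("SweepResult", algorithm = "bt", positions = "waist",
             thresholds = c(1, 2), tp = c(3L, 0L), fn = c(0L, 3L),
             tn = c(0L, 4L), fp = c(4L, 0L))
  expect_equal(maxGeomean(sw0)$maxGeomean, 0)
})

test_that("constrained sensitivity respects the strict specificity bound", {
  # Sp .96/.92/.85 paired with Se .7/.8/.9 (threshold decreasing Se order)
  sw <- new("SweepResult", algorithm = "bt", positions = "waist",
            thresholds = c(1, 2, 3),
            tp = c(9L, 8L, 7L), fn = c(1L, 2L, 3L),
            tn = c(85L, 92L, 96L), fp = c(15L, 8L, 4L))
  expect_equal(seMaxAtMinSp(sw, 0.90), 0.8)
  expect_equal(seMaxAtMinSp(sw, 0.99), 0)   # empty feasible set
  expect_equal(seMaxAtMinSp(sw, 0), 0.9)    # unconstrained max Se
  # the bound is strict: Sp exactly 0.92 does not qualify at spMin = 0.92
  expect_equal(seMaxAtMinSp(sw, 0.92), 0.7)
})

test_that("activity filtering removes only the excluded ADL subtypes", {
  d <- genDataset(generatorConfig(nSubjects = 2, trialsPerMovement = 1,
                                  nNonFallSubjects = 0, seed = 7))
  sub <- vapply(trials(d), activitySubtype, character(1))
  nHop <- sum(sub == "hop")
  expect_gt(nHop, 0)
  f <- filterActivities(d, "hop")
  expect_equal(nTrials(f), nTrials(d) - nHop)
  labs <- fixtureLabels(d)
  expect_equal(sum(fixtureLabels(f) == "FALL"), sum(labs == "FALL"))
  expect_identical(filterActivities(d, character(0)), d)
  # removing every ADL subtype leaves a single class: metrics must refuse
  allAdl <- filterActivities(d, adlSubtypes())
  expect_error(sweepThresholds(allAdl, "bt", "waist"), "ADL")
})

test_that("the results table has one row per combination and is
           reproducible", {
  d <- genDataset(generatorConfig(nSubjects = 2, trialsPerMovement = 1,
                                  positions = c("waist", "wrist"),
                                  nNonFallSubjects = 0, seed = 8))
  tab <- buildResultsTable(d, algorithms = c("bt", "fi"), n = 40)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$combination, c("waist", "wrist", "waist+wrist"))
  expect_true(all(c("bt_auc", "bt_max_geomean", "bt_max_product",
                    "bt_se_at_sp90", "bt_se_at_sp95", "fi_auc") %in%
                    names(tab)))
  metric <- unlist(tab[grep("_(auc|max_geomean|se_at)", names(tab))])
  expect_true(all(metric >= 0 & metric <= 1))
  tab2 <- buildResultsTable(d, algorithms = c("bt", "fi"), n = 40)
  expect_identical(tab, tab2)
})
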