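# Threshold-sweep evaluation: confusion counts per (algorithm, sensor
# combination) over a threshold grid, and the four quality metrics
# (trapezoidal AUC, maximum geometric mean of Se and Sp, and the maximum
# sensitivity under a minimum-specificity constraint).

#' Trial-level confusion counts
#'
#' Cross-tabulates binary fall decisions against trial labels: tp = falls
#' declared falls, fn = falls missed, tn = ADLs correctly rejected, fp =
#' ADLs declared falls.
#'
#' @param decisions logical vector of fused trial decisions.
#' @param labels character vector of activity categories ("FALL"/"ADL"),
#'   same length; both classes must be present.
#' @return Named integer vector `c(tp, fn, tn, fp)`.
#' @export
confusionCounts <- function(decisions, labels) {
  if (length(decisions) != length(labels))
    stop("decisions and labels must have equal length")
  if (anyNA(decisions) || anyNA(labels)) stop("NA in decisions or labels")
  fall <- labels == "FALL"
  if (!any(fall) || all(fall))
    stop("labels must contain at least one FALL and one ADL trial")
  c(tp = sum(decisions & fall), fn = sum(!decisions & fall),
    tn = sum(!decisions & !fall), fp = sum(decisions & !fall))
}

# ---- internal: dataset-level decision statistics -------------------------

# positions present in the dataset (union over trials, canonical order);
# a trial missing one of these raises when its statistics are requested
datasetPositions <- function(dataset) {
  canonicalPositions(unique(unlist(lapply(trials(dataset),
                                          function(tr) names(streams(tr))))))
}

# matrix [trial x position] of decision statistics for one algorithm;
# errors if a trial lacks a requested position's stream.
statisticMatrix <- function(dataset, algorithm, positions,
                            control = detectorControl()) {
  trs <- trials(dataset)
  out <- matrix(NA_real_, nrow = length(trs), ncol = length(positions),
                dimnames = list(NULL, positions))
  for (i in seq_along(trs)) {
    st <- streams(trs[[i]])
    missing <- setdiff(positions, names(st))
    if (length(missing))
      stop(sprintf("trial %d lacks stream(s): %s", i,
                   paste(missing, collapse = ", ")))
    for (p in positions)
      out[i, p] <- decisionStatistic(st[[p]], algorithm, control)
  }
  out
}

datasetLabels <- function(dataset) {
  vapply(trials(dataset), activityCategory, character(1))
}

checkTwoClasses <- function(labels) {
  if (!any(labels == "FALL") || !any(labels == "ADL"))
    stop("evaluation requires at least one FALL and one ADL trial")
}

#' Default threshold grid for a sweep
#'
#' Linearly spaced grid of primary-threshold values spanning the operative
#' range of one algorithm on one dataset: from the 1st to the 99.9th
#' percentile of the per-trial decision statistics pooled over all trials
#' and positions. Non-finite statistics (iFall trials with no free-fall
#' trigger) are excluded from the percentiles.
#'
#' @param dataset a [FallDataset-class].
#' @param algorithm one of [algorithmIds()].
#' @param n number of grid points, default 200.
#' @param positions positions to pool over (default: all present in every
#'   trial).
#' @param control secondary parameters, see [detectorControl()].
#' @return Strictly increasing numeric vector.
#' @export
defaultThresholdGrid <- function(dataset, algorithm, n = 200,
                                 positions = NULL,
                                 control = detectorControl()) {
  if (is.null(positions)) positions <- datasetPositions(dataset)
  stats <- statisticMatrix(dataset, algorithm, positions, control)
  pooled <- stats[is.finite(stats)]
  if (!length(pooled)) stop("no finite decision statistics to build a grid from")
  lo <- stats::quantile(pooled, 0.01, names = FALSE)
  hi <- stats::quantile(pooled, 0.999, names = FALSE)
  if (hi <= lo) hi <- lo + max(abs(lo), 1) * 1e-6
  seq(lo, hi, length.out = n)
}

#' Sweep a detector's primary threshold over a dataset
#'
#' For every grid value, instantiates the algorithm's parameters with the
#' primary threshold at that value (secondary parameters fixed, see
#' [detectorControl()]; for PerFallD the vertical threshold is tied as
#' `avThP = rho * smvThP`), runs the detector on every stream of the
#' combination, AND-fuses the per-sensor decisions, and tabulates
#' trial-level confusion counts.
#'
#' @param dataset a [FallDataset-class] containing both classes.
#' @param algorithm one of [algorithmIds()].
#' @param combination character vector of positions to fuse (default: all
#'   positions present).
#' @param grid strictly increasing numeric threshold grid, or `NULL` for
#'   [defaultThresholdGrid()] (pooled over `gridPositions`, which defaults
#'   to all positions present so that a shared grid can serve several
#'   combinations).
#' @param n grid size when `grid` is `NULL`.
#' @param control secondary parameters, see [detectorControl()].
#' @param policy fusion policy, `"and"` (default) or `"or"`.
#' @param gridPositions positions pooled for the default grid.
#' @return A [SweepResult-class].
#' @export
sweepThresholds <- function(dataset, algorithm = algorithmIds(),
                            combination = NULL, grid = NULL, n = 200,
                            control = detectorControl(),
                            policy = c("and", "or"),
                            gridPositions = NULL) {
  algorithm <- match.arg(algorithm)
  policy <- match.arg(policy)
  labels <- datasetLabels(dataset)
  checkTwoClasses(labels)
  if (is.null(combination)) combination <- datasetPositions(dataset)
  combination <- canonicalPositions(combination)
  stats <- statisticMatrix(dataset, algorithm, combination, control)
  if (is.null(grid))
    grid <- defaultThresholdGrid(dataset, algorithm, n,
                                 positions = gridPositions, control = control)
  if (length(grid) < 1L || (length(grid) > 1L && any(diff(grid) <= 0)))
    stop("grid must be a non-empty strictly increasing vector")
  fused <- if (policy == "and") {
    apply(stats, 1L, min)  # AND: all sensors must exceed the threshold
  } else {
    apply(stats, 1L, max)
  }
  sweepFromStatistics(fused, labels, grid, algorithm, combination)
}

# build a SweepResult from per-trial fused statistics (decision = stat > th)
sweepFromStatistics <- function(fused, labels, grid, algorithm, combination) {
  fall <- labels == "FALL"
  nF <- sum(fall); nA <- sum(!fall)
  tp <- vapply(grid, function(th) sum(fused[fall] > th), numeric(1))
  fp <- vapply(grid, function(th) sum(fused[!fall] > th), numeric(1))
  new("SweepResult", algorithm = algorithm, positions = combination,
      thresholds = as.numeric(grid),
      tp = as.integer(tp), fn = as.integer(nF - tp),
      tn = as.integer(nA - fp), fp = as.integer(fp))
}

#' ROC points of a sweep
#'
#' Sensitivity versus false positive rate (1 - specificity) for every
#' threshold, sorted by ascending false positive rate and anchored at
#' (0, 0) and (1, 1) so the curve spans the unit square.
#'
#' @param sweep a [SweepResult-class].
#' @return A data.frame with columns `fpr` and `se`, sorted, anchored.
#' @export
rocPoints <- function(sweep) {
  stopifnot(is(sweep, "SweepResult"))
  fpr <- 1 - specificity(sweep)
  se <- sensitivity(sweep)
  o <- order(fpr, se)
  pts <- data.frame(fpr = fpr[o], se = se[o])
  if (nrow(pts) == 0L || pts$fpr[1L] > 0 || pts$se[1L] > 0)
    pts <- rbind(data.frame(fpr = 0, se = 0), pts)
  nlast <- nrow(pts)
  if (pts$fpr[nlast] < 1 || pts$se[nlast] < 1)
    pts <- rbind(pts, data.frame(fpr = 1, se = 1))
  rownames(pts) <- NULL
  pts
}

#' Trapezoidal area under the ROC curve
#'
#' @param points a data.frame as returned by [rocPoints()]: columns `fpr`
#'   and `se`, `fpr` non-decreasing, anchored at (0,0) and (1,1). Unsorted
#'   input is an error.
#' @return numeric(1) in [0, 1].
#' @examples
#' aucTrapezoid(data.frame(fpr = c(0, 0, 1), se = c(0, 1, 1)))  # 1
#' aucTrapezoid(data.frame(fpr = c(0, 1), se = c(0, 1)))        # 0.5
#' @export
aucTrapezoid <- function(points) {
  fpr <- points$fpr; se <- points$se
  if (length(fpr) < 2L) stop("need at least two ROC points")
  if (any(diff(fpr) < 0)) stop("ROC points must be sorted by ascending fpr")
  sum(diff(fpr) * (head(se, -1L) + tail(se, -1L)) / 2)
}

#' Maximum geometric mean of sensitivity and specificity
#'
#' Scans the sweep for the threshold maximising `sqrt(Se * Sp)`. Whether a
#' published summary of this kind reports the geometric mean or the raw
#' product is ambiguous in parts of the literature; both are returned (the
#' argmax is the same), with the geometric mean as the headline value. Ties
#' resolve to the smallest qualifying threshold.
#'
#' @param sweep a [SweepResult-class].
#' @return A list: `maxGeomean`, `maxProduct`, `threshold`.
#' @export
maxGeomean <- function(sweep) {
  se <- sensitivity(sweep); sp <- specificity(sweep)
  prod <- se * sp
  i <- which.max(prod)  # first index at ties -> smallest threshold
  list(maxGeomean = sqrt(prod[i]), maxProduct = prod[i],
       threshold = sweep@thresholds[i])
}

#' Maximum sensitivity under a minimum-specificity constraint
#'
#' The largest sensitivity attained at any threshold whose specificity
#' strictly exceeds `spMin`. Falls and ADLs occur with very different
#' frequencies in deployment, so a detector is only useful at high
#' specificity; this metric scores that regime directly. Returns 0 when no
#' threshold qualifies.
#'
#' @param sweep a [SweepResult-class].
#' @param spMin minimum specificity in [0, 1] (strict bound).
#' @return numeric(1) in [0, 1].
#' @export
seMaxAtMinSp <- function(sweep, spMin) {
  stopifnot(length(spMin) == 1L, spMin >= 0, spMin <= 1)
  se <- sensitivity(sweep)[specificity(sweep) > spMin]
  if (!length(se)) 0 else max(se)
}

#' Exclude ADL subtypes from a dataset
#'
#' Drops ADL trials whose subtype is in `excludedSubtypes`; fall trials are
#' never removed. Used for re-analyses that exclude deliberately confusable
#' activities (e.g. hopping) from the negative class.
#'
#' @param dataset a [FallDataset-class].
#' @param excludedSubtypes character vector of ADL subtypes to drop (may be
#'   empty).
#' @return A [FallDataset-class].
#' @export
filterActivities <- function(dataset, excludedSubtypes = character(0)) {
  if (!length(excludedSubtypes)) return(dataset)
  excludedSubtypes <- tolower(excludedSubtypes)
  keep <- vapply(trials(dataset), function(tr) {
    isFall(tr) || !activitySubtype(tr) %in% excludedSubtypes
  }, logical(1))
  FallDataset(trials(dataset)[keep])
}

#' Combination-by-algorithm results table
#'
#' The package's principal output: one row per sensor combination (all
#' non-empty subsets of the positions present, in canonical order — 31 rows
#' for five positions), with, per algorithm, the trapezoidal AUC, the
#' maximum geometric mean of Se and Sp (and the raw Se*Sp product), and the
#' maximum sensitivity at each minimum-specificity bound. One shared
#' per-algorithm grid (pooled over all positions) is used for every
#' combination so rows are comparable.
#'
#' @param dataset a [FallDataset-class] with both classes.
#' @param algorithms subset of [algorithmIds()].
#' @param grid named list of per-algorithm grids, or `NULL` for defaults.
#' @param excludedSubtypes ADL subtypes to exclude before evaluating.
#' @param spBounds minimum-specificity bounds (default 0.90 and 0.95).
#' @param n grid size for default grids.
#' @param control secondary parameters, see [detectorControl()].
#' @return A data.frame: position flag columns (one per canonical position),
#'   a `combination` label, and `<algorithm>_<metric>` columns.
#' @export
buildResultsTable <- function(dataset, algorithms = algorithmIds(),
                              grid = NULL, excludedSubtypes = character(0),
                              spBounds = c(0.90, 0.95), n = 200,
                              control = detectorControl()) {
  stopifnot(all(algorithms %in% algorithmIds()),
            all(spBounds >= 0 & spBounds <= 1))
  dataset <- filterActivities(dataset, excludedSubtypes)
  labels <- datasetLabels(dataset)
  checkTwoClasses(labels)
  positions <- datasetPositions(dataset)
  combos <- enumerateCombinations(positions)

  flagCols <- sensorPositions()
  rows <- data.frame(matrix(FALSE, nrow = length(combos),
                            ncol = length(flagCols),
                            dimnames = list(NULL, flagCols)))
  rows$combination <- vapply(combos, paste, character(1), collapse = "+")
  for (i in seq_along(combos)) rows[i, combos[[i]]] <- TRUE

  spCols <- sprintf("se_at_sp%02d", round(spBounds * 100))
  for (alg in algorithms) {
    stats <- statisticMatrix(dataset, alg, positions, control)
    pooled <- stats[is.finite(stats)]
    g <- if (!is.null(grid) && !is.null(grid[[alg]])) grid[[alg]] else {
      if (!length(pooled)) stop("no finite statistics for algorithm ", alg)
      lo <- stats::quantile(pooled, 0.01, names = FALSE)
      hi <- stats::quantile(pooled, 0.999, names = FALSE)
      if (hi <= lo) hi <- lo + max(abs(lo), 1) * 1e-6
      seq(lo, hi, length.out = n)
    }
    for (i in seq_along(combos)) {
      fused <- apply(stats[, combos[[i]], drop = FALSE], 1L, min)
      sw <- sweepFromStatistics(fused, labels, g, alg, combos[[i]])
      gm <- maxGeomean(sw)
      rows[i, paste0(alg, "_auc")] <- aucTrapezoid(rocPoints(sw))
      rows[i, paste0(alg, "_max_geomean")] <- gm$maxGeomean
      rows[i, paste0(alg, "_max_product")] <- gm$maxProduct
      for (j in seq_along(spBounds))
        rows[i, paste0(alg, "_", spCols[j])] <- seMaxAtMinSp(sw, spBounds[j])
    }
  }
  rows
}
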