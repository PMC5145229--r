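#' Accessors for the data model
#'
#' Small read-only accessors: `nSamples()` and `sensorPosition()` on a
#' stream, `samplingRate()`/`accelRange()` on a stream or spec, `trials()`,
#' `nTrials()` on a dataset, `streams()`, `activityCategory()`,
#' `activitySubtype()` and `isFall()` on a trial, `thresholds()` on a sweep
#' result.
#'
#' @param x the object.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nSamples", "SensorStream", function(x) length(x@t))

#' @rdname accessors
setMethod("sensorPosition", "SensorStream", function(x) x@position)

#' @rdname accessors
setMethod("samplingRate", "SensorSpec", function(x) x@samplingRate)

#' @rdname accessors
setMethod("samplingRate", "SensorStream", function(x) x@spec@samplingRate)

#' @rdname accessors
setMethod("accelRange", "SensorSpec", function(x) x@accelRange)

#' @rdname accessors
setMethod("accelRange", "SensorStream", function(x) x@spec@accelRange)

#' @rdname accessors
setMethod("trials", "FallDataset", function(x) x@trials)

#' @rdname accessors
setMethod("nTrials", "FallDataset", function(x) length(x@trials))

#' @rdname accessors
setMethod("streams", "TrialRecording", function(x) x@streams)

#' @rdname accessors
setMethod("activityCategory", "TrialRecording", function(x) x@activityCategory)

#' @rdname accessors
setMethod("activitySubtype", "TrialRecording", function(x) x@activitySubtype)

#' @rdname accessors
setMethod("isFall", "TrialRecording", function(x) x@activityCategory == "FALL")

#' @rdname accessors
setMethod("thresholds", "SweepResult", function(x) x@thresholds)

#' Sensitivity and specificity of a threshold sweep
#'
#' `sensitivity()` returns tp/(tp+fn) and `specificity()` tn/(tn+fp) for
#' every threshold of a [SweepResult-class].
#'
#' @param object a [SweepResult-class].
#' @return Numeric vector in [0, 1], parallel to `thresholds(object)`.
#' @name sensitivity
NULL

#' @rdname sensitivity
setMethod("sensitivity", "SweepResult",
  function(object) object@tp / (object@tp + object@fn))

#' @rdname sensitivity
setMethod("specificity", "SweepResult",
  function(object) object@tn / (object@tn + object@fp))

#' @describeIn SweepResult-class per-threshold counts and rates as a
#'   data.frame with columns threshold, tp, fn, tn, fp, se, sp.
#' @param x a `SweepResult`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.SweepResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(threshold = x@thresholds, tp = x@tp, fn = x@fn,
             tn = x@tn, fp = x@fp,
             se = sensitivity(x), sp = specificity(x))
}

setMethod("show", "SensorSpec", function(object) {
  cat(sprintf("SensorSpec %s (%s): %g Hz, +/-%g g\n", object@deviceId,
              object@vendor, object@samplingRate, object@accelRange))
})

setMethod("show", "SensorStream", function(object) {
  cat(sprintf("SensorStream at %s: %d samples, %g Hz, +/-%g g, %.2f s\n",
              object@position, length(object@t), samplingRate(object),
              accelRange(object),
              if (length(object@t)) diff(range(object@t)) else 0))
})

setMethod("show", "TrialRecording", function(object) {
  cat(sprintf("TrialRecording: subject %s, %s/%s, trial %d, %d stream(s): %s\n",
              object@subject@subjectId, object@activityCategory,
              object@activitySubtype, object@trialIndex,
              length(object@streams),
              paste(names(object@streams), collapse = ", ")))
})

setMethod("show", "FallDataset", function(object) {
  cats <- vapply(object@trials, activityCategory, character(1))
  cat(sprintf("FallDataset: %d trials (%d FALL, %d ADL)\n",
              length(object@trials), sum(cats == "FALL"), sum(cats == "ADL")))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %s over {%s}, %d thresholds [%.3g, %.3g]\n",
              object@algorithm, paste(object@positions, collapse = ", "),
              length(object@thresholds), min(object@thresholds),
              max(object@thresholds)))
})

setMethod("show", "FeatureSeries", function(object) {
  cat(sprintf("FeatureSeries (%s): %d points\n", object@feature,
              length(object@t)))
})
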