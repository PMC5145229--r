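# Generics. Feature extraction and detection dispatch on the stream class;
# evaluation summaries dispatch on SweepResult.

#' @rdname computeSMV
#' @export
setGeneric("computeSMV", function(x) standardGeneric("computeSMV"))

#' @rdname computeFallIndex
#' @export
setGeneric("computeFallIndex",
  function(x, windowLen = 20L) standardGeneric("computeFallIndex"))

#' @rdname computeVerticalAccel
#' @export
setGeneric("computeVerticalAccel",
  function(x) standardGeneric("computeVerticalAccel"))

#' @rdname detectBasic
#' @export
setGeneric("detectBasic", function(x, params) standardGeneric("detectBasic"))

#' @rdname detectBasic
#' @export
setGeneric("detectFallIndex",
  function(x, params) standardGeneric("detectFallIndex"))

#' @rdname detectBasic
#' @export
setGeneric("detectPerFallD",
  function(x, params) standardGeneric("detectPerFallD"))

#' @rdname detectBasic
#' @export
setGeneric("detectIFall", function(x, params) standardGeneric("detectIFall"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("sensorPosition", function(x) standardGeneric("sensorPosition"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("accelRange", function(x) standardGeneric("accelRange"))

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("streams", function(x) standardGeneric("streams"))

#' @rdname accessors
#' @export
setGeneric("activityCategory", function(x) standardGeneric("activityCategory"))

#' @rdname accessors
#' @export
setGeneric("activitySubtype", function(x) standardGeneric("activitySubtype"))

#' @rdname accessors
#' @export
setGeneric("isFall", function(x) standardGeneric("isFall"))

#' @rdname sensitivity
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @rdname sensitivity
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
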