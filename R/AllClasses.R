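# S4 classes for the multi-sensor mobility-trial data model and the
# evaluation results. All accelerations are in m/s^2, timestamps in seconds
# from trial start.

#' SensorSpec: description of one wearable accelerometer device
#'
#' Holds the identity and acquisition characteristics of a device: an opaque
#' device identifier (standing in for a radio MAC address), vendor string,
#' sampling rate in Hz, and the accelerometer full-scale half-range in g
#' (e.g. 2 for a +/-2 g sensor).
#'
#' @slot deviceId character(1), opaque device identifier.
#' @slot vendor character(1).
#' @slot samplingRate numeric(1), Hz, strictly positive.
#' @slot accelRange numeric(1), g, strictly positive.
#' @export
setClass("SensorSpec",
  slots = c(deviceId = "character", vendor = "character",
            samplingRate = "numeric", accelRange = "numeric"))

setValidity("SensorSpec", function(object) {
  msg <- character(0)
  if (length(object@deviceId) != 1L || !nzchar(object@deviceId))
    msg <- c(msg, "deviceId must be a non-empty string")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive number (Hz)")
  if (length(object@accelRange) != 1L || !is.finite(object@accelRange) ||
      object@accelRange <= 0)
    msg <- c(msg, "accelRange must be a positive number (g)")
  if (length(msg)) msg else TRUE
})

#' @rdname SensorSpec-class
#' @param deviceId,vendor,samplingRate,accelRange see slots.
#' @return A validated `SensorSpec` object.
#' @examples
#' SensorSpec("phone-01", vendor = "generic", samplingRate = 200, accelRange = 2)
#' @export
SensorSpec <- function(deviceId, vendor = "generic", samplingRate, accelRange) {
  new("SensorSpec", deviceId = as.character(deviceId),
      vendor = as.character(vendor),
      samplingRate = as.numeric(samplingRate),
      accelRange = as.numeric(accelRange))
}

#' SubjectMeta: anthropometric metadata of an experimental subject
#'
#' @slot subjectId character(1).
#' @slot age integer(1), years, > 0.
#' @slot height numeric(1), cm, > 0.
#' @slot weight numeric(1), kg, > 0.
#' @slot gender character(1), "F" or "M".
#' @export
setClass("SubjectMeta",
  slots = c(subjectId = "character", age = "integer", height = "numeric",
            weight = "numeric", gender = "character"))

setValidity("SubjectMeta", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a non-empty string")
  if (length(object@age) != 1L || is.na(object@age) || object@age <= 0L)
    msg <- c(msg, "age must be a positive integer")
  if (length(object@height) != 1L || !is.finite(object@height) ||
      object@height <= 0)
    msg <- c(msg, "height must be positive (cm)")
  if (length(object@weight) != 1L || !is.finite(object@weight) ||
      object@weight <= 0)
    msg <- c(msg, "weight must be positive (kg)")
  if (length(object@gender) != 1L || !object@gender %in% c("F", "M"))
    msg <- c(msg, "gender must be \"F\" or \"M\"")
  if (length(msg)) msg else TRUE
})

#' @rdname SubjectMeta-class
#' @param subjectId,age,height,weight,gender see slots.
#' @return A validated `SubjectMeta` object.
#' @export
SubjectMeta <- function(subjectId, age, height, weight, gender) {
  new("SubjectMeta", subjectId = as.character(subjectId),
      age = as.integer(age), height = as.numeric(height),
      weight = as.numeric(weight), gender = as.character(gender))
}

#' SensorStream: tri-axial samples from one device at one body position
#'
#' Time-ordered accelerometer samples from a single worn device. Timestamps
#' must be strictly increasing and their median spacing must agree with the
#' device's nominal sampling interval to within 20%. Acceleration components
#' may not exceed the device range by more than 1% (the generator clips at
#' the range; the tolerance absorbs rounding in serialised files). Gyroscope
#' (deg/s) and magnetometer (uT) channels are optional (length 0 when
#' absent) and are ignored by every detector.
#'
#' @slot position character(1), one of [sensorPositions()].
#' @slot spec a [SensorSpec-class] object.
#' @slot t numeric, seconds from trial start, strictly increasing, >= 0.
#' @slot ax,ay,az numeric, acceleration components in m/s^2.
#' @slot gx,gy,gz numeric, optional gyroscope channels (deg/s).
#' @slot mx,my,mz numeric, optional magnetometer channels (uT).
#' @export
setClass("SensorStream",
  slots = c(position = "character", spec = "SensorSpec",
            t = "numeric", ax = "numeric", ay = "numeric", az = "numeric",
            gx = "numeric", gy = "numeric", gz = "numeric",
            mx = "numeric", my = "numeric", mz = "numeric"))

setValidity("SensorStream", function(object) {
  msg <- character(0)
  n <- length(object@t)
  if (length(object@position) != 1L ||
      !object@position %in% sensorPositions())
    msg <- c(msg, "position must be one of the five canonical positions")
  if (n < 1L) msg <- c(msg, "stream must contain at least one sample")
  if (n >= 1L && (any(!is.finite(object@t)) || object@t[1L] < 0))
    msg <- c(msg, "timestamps must be finite and non-negative")
  if (n >= 2L && any(diff(object@t) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  for (ax in c("ax", "ay", "az")) {
    v <- slot(object, ax)
    if (length(v) != n) msg <- c(msg, sprintf("%s must have one value per timestamp", ax))
  }
  if (n >= 2L) {
    nominal <- 1 / object@spec@samplingRate
    med <- stats::median(diff(object@t))
    if (abs(med - nominal) > 0.2 * nominal)
      msg <- c(msg, "median sample spacing deviates more than 20% from the nominal rate")
  }
  lim <- object@spec@accelRange * STANDARD_GRAVITY * 1.01
  if (length(object@ax) == n &&
      any(abs(c(object@ax, object@ay, object@az)) > lim))
    msg <- c(msg, "acceleration component exceeds the device range by more than 1%")
  for (opt in c("gx", "gy", "gz", "mx", "my", "mz")) {
    v <- slot(object, opt)
    if (!length(v) %in% c(0L, n))
      msg <- c(msg, sprintf("%s must be empty or have one value per timestamp", opt))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SensorStream-class
#' @param position,spec,t,ax,ay,az,gx,gy,gz,mx,my,mz see slots.
#' @return A validated `SensorStream`.
#' @export
SensorStream <- function(position, spec, t, ax, ay, az,
                         gx = numeric(0), gy = numeric(0), gz = numeric(0),
                         mx = numeric(0), my = numeric(0), mz = numeric(0)) {
  new("SensorStream", position = as.character(position), spec = spec,
      t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
      az = as.numeric(az), gx = as.numeric(gx), gy = as.numeric(gy),
      gz = as.numeric(gz), mx = as.numeric(mx), my = as.numeric(my),
      mz = as.numeric(mz))
}

#' TrialRecording: one labelled movement execution
#'
#' A single labelled trial: subject metadata, an activity label (category
#' ADL or FALL plus a matching subtype), a trial index, and one
#' [SensorStream-class] per worn body position (1 to 5 streams, unique
#' positions). The `extra` slot preserves unknown metadata keys found when
#' reading trace files.
#'
#' @slot subject a [SubjectMeta-class].
#' @slot activityCategory character(1), "ADL" or "FALL".
#' @slot activitySubtype character(1), a member of [adlSubtypes()] or
#'   [fallSubtypes()] matching the category.
#' @slot trialIndex integer(1) >= 1.
#' @slot streams named list of [SensorStream-class], names are positions.
#' @slot extra named character vector of preserved unknown metadata.
#' @export
setClass("TrialRecording",
  slots = c(subject = "SubjectMeta", activityCategory = "character",
            activitySubtype = "character", trialIndex = "integer",
            streams = "list", extra = "character"))

setValidity("TrialRecording", function(object) {
  msg <- character(0)
  cat. <- object@activityCategory
  sub. <- object@activitySubtype
  if (length(cat.) != 1L || !cat. %in% c("ADL", "FALL"))
    msg <- c(msg, "activityCategory must be \"ADL\" or \"FALL\"")
  else {
    allowed <- if (cat. == "ADL") adlSubtypes() else fallSubtypes()
    if (length(sub.) != 1L || !sub. %in% allowed)
      msg <- c(msg, sprintf("activitySubtype \"%s\" does not belong to category %s",
                            sub., cat.))
  }
  if (length(object@trialIndex) != 1L || is.na(object@trialIndex) ||
      object@trialIndex < 1L)
    msg <- c(msg, "trialIndex must be a positive integer")
  if (length(object@streams) < 1L)
    msg <- c(msg, "trial must contain at least one stream")
  else {
    if (!all(vapply(object@streams, is, logical(1), "SensorStream")))
      msg <- c(msg, "streams must all be SensorStream objects")
    else {
      pos <- vapply(object@streams, function(s) s@position, character(1))
      if (anyDuplicated(pos))
        msg <- c(msg, "duplicate sensor positions in trial")
      if (!identical(names(object@streams), unname(pos)))
        msg <- c(msg, "stream list names must equal stream positions")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname TrialRecording-class
#' @param subject,activityCategory,activitySubtype,trialIndex,extra see slots.
#' @param streams list of [SensorStream-class]; names are set from the
#'   streams' positions.
#' @return A validated `TrialRecording`.
#' @export
TrialRecording <- function(subject, activityCategory, activitySubtype,
                           trialIndex, streams, extra = character(0)) {
  if (!is.list(streams)) streams <- list(streams)
  nm <- vapply(streams, function(s) s@position, character(1))
  names(streams) <- nm
  new("TrialRecording", subject = subject,
      activityCategory = toupper(as.character(activityCategory)),
      activitySubtype = tolower(as.character(activitySubtype)),
      trialIndex = as.integer(trialIndex), streams = streams,
      extra = extra)
}

#' FallDataset: a collection of labelled trials
#'
#' @slot trials list of [TrialRecording-class].
#' @export
setClass("FallDataset", slots = c(trials = "list"))

setValidity("FallDataset", function(object) {
  if (length(object@trials) < 1L) return("dataset must contain at least one trial")
  if (!all(vapply(object@trials, is, logical(1), "TrialRecording")))
    return("trials must all be TrialRecording objects")
  TRUE
})

#' @rdname FallDataset-class
#' @param trials list of [TrialRecording-class].
#' @return A validated `FallDataset`.
#' @export
FallDataset <- function(trials) new("FallDataset", trials = trials)

# ---- detector parameter bundles ------------------------------------------

#' Detector parameter bundles
#'
#' One small S4 class per detection algorithm, holding its thresholds and
#' window lengths. All thresholds are in m/s^2 (the Fall Index threshold in
#' (m/s^2)^2); use [gToMs2()] for values quoted in g.
#'
#' * `BasicParams(smvTh)` — basic thresholding: alarm when the signal
#'   magnitude vector exceeds `smvTh`.
#' * `FIParams(fiTh, windowLen = 20)` — Fall Index: trailing sum over
#'   `windowLen` samples of squared per-axis first differences, compared
#'   with `fiTh`.
#' * `PerFallDParams(smvThP, avThP, winP = 0.5)` — PerFallD: within one
#'   sliding window of `winP` seconds, the ranges of the magnitude vector
#'   and of the vertical acceleration must simultaneously exceed their
#'   thresholds.
#' * `IFallParams(smvU, smvL = gToMs2(0.65), winO = 0.5)` — two-phase iFall:
#'   a dip below `smvL` (free fall) followed within `winO` seconds by a peak
#'   above `smvU` (impact).
#'
#' @slot smvTh,fiTh,smvThP,avThP,smvU,smvL numeric(1) thresholds, > 0.
#' @slot windowLen integer(1) >= 2, Fall Index window in samples.
#' @slot winP,winO numeric(1) > 0, window durations in seconds.
#' @name DetectorParams
NULL

#' @rdname DetectorParams
#' @export
setClass("BasicParams", slots = c(smvTh = "numeric"))
setValidity("BasicParams", function(object) {
  if (length(object@smvTh) != 1L || !is.finite(object@smvTh) ||
      object@smvTh <= 0) "smvTh must be a positive number (m/s^2)" else TRUE
})

#' @rdname DetectorParams
#' @param smvTh threshold on the signal magnitude vector, m/s^2.
#' @export
BasicParams <- function(smvTh) new("BasicParams", smvTh = as.numeric(smvTh))

#' @rdname DetectorParams
#' @export
setClass("FIParams", slots = c(fiTh = "numeric", windowLen = "integer"))
setValidity("FIParams", function(object) {
  msg <- character(0)
  if (length(object@fiTh) != 1L || !is.finite(object@fiTh) || object@fiTh <= 0)
    msg <- c(msg, "fiTh must be a positive number ((m/s^2)^2)")
  if (length(object@windowLen) != 1L || is.na(object@windowLen) ||
      object@windowLen < 2L)
    msg <- c(msg, "windowLen must be an integer >= 2")
  if (length(msg)) msg else TRUE
})

#' @rdname DetectorParams
#' @param fiTh Fall Index decision threshold, (m/s^2)^2.
#' @param windowLen trailing window length in samples (default 20).
#' @export
FIParams <- function(fiTh, windowLen = 20L) {
  new("FIParams", fiTh = as.numeric(fiTh), windowLen = as.integer(windowLen))
}

#' @rdname DetectorParams
#' @export
setClass("PerFallDParams",
  slots = c(smvThP = "numeric", avThP = "numeric", winP = "numeric"))
setValidity("PerFallDParams", function(object) {
  ok <- function(x) length(x) == 1L && is.finite(x) && x > 0
  msg <- character(0)
  if (!ok(object@smvThP)) msg <- c(msg, "smvThP must be positive (m/s^2)")
  if (!ok(object@avThP)) msg <- c(msg, "avThP must be positive (m/s^2)")
  if (!ok(object@winP)) msg <- c(msg, "winP must be positive (seconds)")
  if (length(msg)) msg else TRUE
})

#' @rdname DetectorParams
#' @param smvThP,avThP PerFallD range thresholds for the magnitude vector
#'   and the vertical acceleration, m/s^2.
#' @param winP sliding window duration, seconds (default 0.5).
#' @export
PerFallDParams <- function(smvThP, avThP, winP = 0.5) {
  new("PerFallDParams", smvThP = as.numeric(smvThP),
      avThP = as.numeric(avThP), winP = as.numeric(winP))
}

#' @rdname DetectorParams
#' @export
setClass("IFallParams",
  slots = c(smvL = "numeric", smvU = "numeric", winO = "numeric"))
setValidity("IFallParams", function(object) {
  msg <- character(0)
  if (length(object@smvL) != 1L || !is.finite(object@smvL) || object@smvL <= 0)
    msg <- c(msg, "smvL must be positive (m/s^2)")
  if (length(object@smvU) != 1L || !is.finite(object@smvU) ||
      object@smvU <= object@smvL)
    msg <- c(msg, "smvU must exceed smvL")
  if (length(object@winO) != 1L || !is.finite(object@winO) || object@winO <= 0)
    msg <- c(msg, "winO must be positive (seconds)")
  if (length(msg)) msg else TRUE
})

#' @rdname DetectorParams
#' @param smvU iFall impact (upper) threshold, m/s^2.
#' @param smvL iFall free-fall (lower) threshold, m/s^2; default 0.65 g.
#' @param winO observation window after a free-fall trigger, seconds.
#' @export
IFallParams <- function(smvU, smvL = gToMs2(0.65), winO = 0.5) {
  new("IFallParams", smvL = as.numeric(smvL), smvU = as.numeric(smvU),
      winO = as.numeric(winO))
}

# ---- derived series and evaluation results -------------------------------

#' FeatureSeries: a per-sample feature derived from one stream
#'
#' Holds a feature trace (signal magnitude vector, Fall Index, or vertical
#' acceleration) with its time base. For the vertical acceleration the
#' estimated roll and pitch angles (radians) are carried along.
#'
#' @slot t numeric, seconds.
#' @slot values numeric, same length as `t`; non-negative for all three
#'   feature kinds.
#' @slot feature character(1), one of "smv", "fi", "av".
#' @slot roll,pitch numeric, radians; length 0 unless feature == "av".
#' @export
setClass("FeatureSeries",
  slots = c(t = "numeric", values = "numeric", feature = "character",
            roll = "numeric", pitch = "numeric"))

setValidity("FeatureSeries", function(object) {
  msg <- character(0)
  if (length(object@values) != length(object@t))
    msg <- c(msg, "values and t must have equal length")
  if (length(object@feature) != 1L ||
      !object@feature %in% c("smv", "fi", "av"))
    msg <- c(msg, "feature must be one of \"smv\", \"fi\", \"av\"")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "feature values must be non-negative")
  for (a in c("roll", "pitch"))
    if (!length(slot(object, a)) %in% c(0L, length(object@t)))
      msg <- c(msg, sprintf("%s must be empty or parallel to t", a))
  if (length(msg)) msg else TRUE
})

FeatureSeries <- function(t, values, feature,
                          roll = numeric(0), pitch = numeric(0)) {
  new("FeatureSeries", t = as.numeric(t), values = as.numeric(values),
      feature = feature, roll = as.numeric(roll), pitch = as.numeric(pitch))
}

#' SweepResult: confusion counts of one detector over a threshold grid
#'
#' One object per (algorithm, sensor combination): for every value of the
#' primary decision threshold, the trial-level confusion counts obtained
#' after AND-fusing the per-sensor decisions. Sensitivity and specificity
#' derive as tp/(tp+fn) and tn/(tn+fp).
#'
#' @slot algorithm character(1), one of [algorithmIds()].
#' @slot positions character, the fused sensor combination (canonical order).
#' @slot thresholds numeric, strictly increasing primary-threshold grid.
#' @slot tp,fn,tn,fp integer vectors parallel to `thresholds`.
#' @export
setClass("SweepResult",
  slots = c(algorithm = "character", positions = "character",
            thresholds = "numeric", tp = "integer", fn = "integer",
            tn = "integer", fp = "integer"))

setValidity("SweepResult", function(object) {
  msg <- character(0)
  k <- length(object@thresholds)
  if (k < 1L) msg <- c(msg, "threshold grid must be non-empty")
  if (k >= 2L && any(diff(object@thresholds) <= 0))
    msg <- c(msg, "thresholds must be strictly increasing")
  for (a in c("tp", "fn", "tn", "fp")) {
    v <- slot(object, a)
    if (length(v) != k) msg <- c(msg, sprintf("%s must be parallel to thresholds", a))
    else if (any(v < 0L)) msg <- c(msg, sprintf("%s must be non-negative", a))
  }
  if (k >= 1L && length(object@tp) == k && length(object@fn) == k &&
      length(unique(object@tp + object@fn)) > 1L)
    msg <- c(msg, "tp+fn must be constant (number of fall trials)")
  if (k >= 1L && length(object@tn) == k && length(object@fp) == k &&
      length(unique(object@tn + object@fp)) > 1L)
    msg <- c(msg, "tn+fp must be constant (number of ADL trials)")
  if (length(msg)) msg else TRUE
})
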