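# Per-sample feature series underlying the detectors: the signal magnitude
# vector, the Yoshida Fall Index, and the vertical acceleration obtained by
# projecting the reading on the gravity direction estimated from roll and
# pitch under a static-pose assumption.

#' Signal magnitude vector (SMV)
#'
#' The Euclidean norm of the tri-axial acceleration at every sample:
#' `SMV_i = sqrt(ax_i^2 + ay_i^2 + az_i^2)` (m/s^2). This is the feature
#' behind basic threshold monitoring and both windowed detectors.
#'
#' @param x a [SensorStream-class].
#' @return A [FeatureSeries-class] with one point per sample.
#' @examples
#' s <- SensorStream("waist", SensorSpec("m1", samplingRate = 20, accelRange = 8),
#'                   t = c(0, 0.05), ax = c(3, 0), ay = c(4, 0), az = c(0, -9.81))
#' computeSMV(s)@values  # 5, 9.81
#' @rdname computeSMV
#' @export
setMethod("computeSMV", "SensorStream", function(x) {
  if (nSamples(x) < 1L) stop("empty stream")
  FeatureSeries(x@t, sqrt(x@ax^2 + x@ay^2 + x@az^2), "smv")
})

#' Fall Index
#'
#' The Yoshida Fall Index: at sample i, the sum over the three axes of the
#' squared first differences of the acceleration over the trailing window of
#' `windowLen` samples,
#' `FI_i = sum_k sum_{j = i-windowLen+1..i} (A_kj - A_k,j-1)^2`.
#' No square root is taken: the index is used exactly in this quadratic
#' form (some published variants differ; the threshold unit here is
#' (m/s^2)^2). The first `windowLen` samples have no defined index and are
#' omitted from the series rather than zero-filled.
#'
#' @param x a [SensorStream-class] with more than `windowLen` samples.
#' @param windowLen trailing window length in samples, default 20. The
#'   window is defined in samples, not seconds, so its temporal span depends
#'   on the device rate (1 s at 20 Hz, 0.1 s at 200 Hz).
#' @return A [FeatureSeries-class] starting at sample `windowLen + 1`.
#' @rdname computeFallIndex
#' @export
setMethod("computeFallIndex", "SensorStream", function(x, windowLen = 20L) {
  windowLen <- as.integer(windowLen)
  if (windowLen < 2L) stop("windowLen must be >= 2")
  n <- nSamples(x)
  if (n <= windowLen) stop("stream too short for the Fall Index window")
  d <- diff(x@ax)^2 + diff(x@ay)^2 + diff(x@az)^2        # length n-1
  roll <- stats::filter(d, rep(1, windowLen), sides = 1)  # trailing sums
  vals <- as.numeric(roll)[windowLen:(n - 1L)]            # FI at samples (w+1)..n
  vals[vals < 0] <- 0  # guard against tiny negative rounding
  FeatureSeries(x@t[(windowLen + 1L):n], vals, "fi")
})

#' Roll and pitch from a static accelerometer reading
#'
#' Tilt angles estimated from a single tri-axial reading under the
#' assumption that only gravity acts on the sensor:
#' `roll = atan(ax / sqrt(ay^2 + az^2))` and `pitch = atan(-ay / az)`.
#' When `az = 0` the printed pitch expression is undefined; the continuous
#' extension `pitch = sign(-ay) * pi/2` (0 if `ay` is also 0) is used so a
#' stream can be processed without mid-stream exceptions. The static
#' assumption does not hold during a fall; the detectors use these angles
#' anyway, as the published procedures do.
#'
#' @param ax,ay,az numeric vectors of equal length, m/s^2. A zero vector
#'   sample is an error (angles undefined).
#' @return A list with numeric components `roll` and `pitch` in radians.
#' @examples
#' estimateRollPitch(0, 0, -9.80665)  # flat: roll 0, pitch 0
#' @export
estimateRollPitch <- function(ax, ay, az) {
  if (any(ax == 0 & ay == 0 & az == 0))
    stop("tilt angles undefined for an all-zero acceleration sample")
  roll <- atan(ax / sqrt(ay^2 + az^2))  # ay=az=0 -> atan(+/-Inf) = +/-pi/2
  pitch <- ifelse(az != 0, atan(-ay / az),
                  ifelse(ay == 0, 0, sign(-ay) * pi / 2))
  list(roll = roll, pitch = pitch)
}

#' Vertical acceleration magnitude
#'
#' The magnitude of the acceleration along the estimated absolute vertical,
#' `|A_v| = |ax sin(roll) + ay sin(pitch) - az cos(pitch) cos(roll)|`,
#' with roll and pitch from [estimateRollPitch()] applied to the same
#' sample. For samples with `ax = 0` and `az < 0` this reduces to the
#' Euclidean norm of the sample.
#'
#' @param x a [SensorStream-class] without all-zero samples.
#' @return A [FeatureSeries-class]; the roll and pitch series are carried in
#'   the result's `roll`/`pitch` slots.
#' @rdname computeVerticalAccel
#' @export
setMethod("computeVerticalAccel", "SensorStream", function(x) {
  if (nSamples(x) < 1L) stop("empty stream")
  ang <- estimateRollPitch(x@ax, x@ay, x@az)
  av <- abs(x@ax * sin(ang$roll) + x@ay * sin(ang$pitch) -
            x@az * cos(ang$pitch) * cos(ang$roll))
  FeatureSeries(x@t, av, "av", roll = ang$roll, pitch = ang$pitch)
})
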