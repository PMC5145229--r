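# The four trial-level detectors. Each returns one boolean per stream:
# multiple within-trial threshold crossings count once. "Exceeds" is a
# strict `>` everywhere; a value equal to the threshold is a negative.
# Every detector reduces to a per-stream scalar decision statistic compared
# with its primary threshold (see decisionStatistic), which is what the
# threshold-sweep engine exploits.

#' Trial-level fall detectors
#'
#' Binary fall/no-fall decisions for one [SensorStream-class] over a whole
#' trial:
#'
#' * `detectBasic`: fall iff the signal magnitude vector exceeds
#'   `smvTh` anywhere in the trial.
#' * `detectFallIndex`: fall iff the Fall Index (trailing-window sum of
#'   squared first differences, see [computeFallIndex()]) exceeds `fiTh`
#'   at any defined sample.
#' * `detectPerFallD`: fall iff within some sliding window of `winP`
#'   seconds (converted to samples at the stream's rate, sliding sample by
#'   sample) the range (max - min) of the magnitude vector exceeds `smvThP`
#'   AND the range of the vertical acceleration exceeds `avThP`,
#'   simultaneously in the same window.
#' * `detectIFall`: two-phase detection; scanning in time order, a sample
#'   below `smvL` (free fall) opens an observation window of `winO` seconds;
#'   fall iff some later sample inside that window exceeds `smvU` (impact).
#'   If a window expires without impact, scanning resumes at the first
#'   sample after the window (samples inside it are not re-examined as
#'   triggers).
#'
#' All comparisons are strict; decisions are therefore monotone
#' non-increasing in the primary threshold.
#'
#' @param x a [SensorStream-class].
#' @param params the matching parameter bundle ([DetectorParams]).
#' @return logical(1): `TRUE` if a fall is detected anywhere in the trial.
#' @seealso [decisionStatistic()] for the sweep-ready scalar form.
#' @name detectBasic
NULL

#' @rdname detectBasic
setMethod("detectBasic", signature("SensorStream", "BasicParams"),
  function(x, params) {
    max(computeSMV(x)@values) > params@smvTh
  })

#' @rdname detectBasic
setMethod("detectFallIndex", signature("SensorStream", "FIParams"),
  function(x, params) {
    max(computeFallIndex(x, params@windowLen)@values) > params@fiTh
  })

# rolling range (max - min) over all k-sample left-aligned windows
rollRange <- function(v, k) .rollMaxLeft(v, k) - .rollMinLeft(v, k)

#' @rdname detectBasic
setMethod("detectPerFallD", signature("SensorStream", "PerFallDParams"),
  function(x, params) {
    k <- winSamples(params@winP, samplingRate(x))
    if (nSamples(x) < k)
      stop("stream shorter than the PerFallD window")
    smv <- computeSMV(x)@values
    av <- computeVerticalAccel(x)@values
    any(rollRange(smv, k) > params@smvThP &
        rollRange(av, k) > params@avThP)
  })

# Greedy free-fall trigger scan: returns the per-observation-window maximum
# of SMV for the window sequence obtained when no impact is ever found
# (first trigger, then first trigger after that window's expiry, ...).
# For any upper threshold u, the two-phase detector fires iff some value in
# this sequence exceeds u: scanning under u proceeds identically to the
# "all windows fail" scan up to the first window whose maximum exceeds u.
ifallWindowMaxima <- function(t, smv, smvL, winO) {
  trig <- which(smv < smvL)
  maxima <- numeric(0)
  while (length(trig)) {
    i <- trig[1L]
    inWin <- t > t[i] & t <= t[i] + winO
    if (any(inWin)) maxima <- c(maxima, max(smv[inWin]))
    trig <- trig[t[trig] > t[i] + winO]
  }
  maxima
}

#' @rdname detectBasic
setMethod("detectIFall", signature("SensorStream", "IFallParams"),
  function(x, params) {
    smv <- computeSMV(x)@values
    m <- ifallWindowMaxima(x@t, smv, params@smvL, params@winO)
    length(m) > 0L && max(m) > params@smvU
  })

#' Scalar decision statistic of a detector on one stream
#'
#' Every detector's trial decision can be written as
#' `statistic(stream) > threshold` for its primary threshold:
#'
#' * `bt`: max of the signal magnitude vector;
#' * `fi`: max of the Fall Index over its defined samples;
#' * `perfalld`: max over sliding windows of
#'   `min(range(SMV), range(|A_v|)/rho)`, where the secondary threshold is
#'   tied to the primary as `avThP = rho * smvThP`;
#' * `ifall`: max impact peak over the free-fall observation windows
#'   (`-Inf` when no sample ever drops below `smvL`).
#'
#' The threshold-sweep engine evaluates each stream once via this function
#' and then compares against the whole grid, instead of re-running the
#' detectors per threshold.
#'
#' @param x a [SensorStream-class].
#' @param algorithm one of [algorithmIds()].
#' @param control secondary parameters, see [detectorControl()].
#' @return numeric(1); possibly `-Inf` for `ifall`.
#' @export
decisionStatistic <- function(x, algorithm = algorithmIds(),
                              control = detectorControl()) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    bt = max(computeSMV(x)@values),
    fi = max(computeFallIndex(x, control$windowLen)@values),
    perfalld = {
      k <- winSamples(control$winP, samplingRate(x))
      if (nSamples(x) < k) stop("stream shorter than the PerFallD window")
      smv <- computeSMV(x)@values
      av <- computeVerticalAccel(x)@values
      max(pmin(rollRange(smv, k), rollRange(av, k) / control$rho))
    },
    ifall = {
      m <- ifallWindowMaxima(x@t, computeSMV(x)@values,
                             control$smvL, control$winO)
      if (length(m)) max(m) else -Inf
    })
}

#' Secondary detector parameters for threshold sweeps
#'
#' The sweep varies each algorithm's primary threshold only; the remaining
#' parameters are fixed here at their defaults: the Fall Index window of 20
#' samples, the PerFallD window of 0.5 s with the vertical-acceleration
#' threshold tied to the primary by the ratio `rho` (default 1), and the
#' iFall observation window of 0.5 s with the lower threshold at 0.65 g.
#'
#' @param windowLen Fall Index window, samples.
#' @param winP PerFallD sliding window, seconds.
#' @param winO iFall observation window, seconds.
#' @param smvL iFall free-fall threshold, m/s^2.
#' @param rho PerFallD coupling `avThP = rho * smvThP`, > 0.
#' @return A named list.
#' @export
detectorControl <- function(windowLen = 20L, winP = 0.5, winO = 0.5,
                            smvL = gToMs2(0.65), rho = 1) {
  stopifnot(windowLen >= 2L, winP > 0, winO > 0, smvL > 0, rho > 0)
  list(windowLen = as.integer(windowLen), winP = winP, winO = winO,
       smvL = smvL, rho = rho)
}

# Instantiate the parameter bundle of `algorithm` with primary threshold th
# and secondary parameters from `control`.
paramsForThreshold <- function(algorithm, th, control = detectorControl()) {
  switch(algorithm,
    bt = BasicParams(th),
    fi = FIParams(th, control$windowLen),
    perfalld = PerFallDParams(th, control$rho * th, control$winP),
    ifall = IFallParams(smvU = th, smvL = control$smvL, winO = control$winO),
    stop("unknown algorithm: ", algorithm))
}

# Run one named detector on one stream with a primary threshold.
runDetector <- function(x, algorithm, th, control = detectorControl()) {
  p <- paramsForThreshold(algorithm, th, control)
  switch(algorithm,
    bt = detectBasic(x, p),
    fi = detectFallIndex(x, p),
    perfalld = detectPerFallD(x, p),
    ifall = detectIFall(x, p))
}
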