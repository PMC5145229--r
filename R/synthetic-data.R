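# Synthetic multi-sensor trial generator. Emulates the statistical
# structure of a five-position wearable testbed (thigh-pocket smartphone at
# 200 Hz, four 20 Hz motes at chest, waist, wrist, ankle): seven ADL types,
# three fall types, quiet standing at trial start, device-range clipping
# and additive Gaussian noise. All movement templates and amplitudes are
# invented synthetic stand-ins — they are not a reproduction of any
# recorded dataset — but they are shaped so the detectors face the
# qualitative structure the analysis assumes: fall traces contain a quiet
# phase, a free-fall dip (magnitude below 0.35 g for 0.1-0.3 s), an impact
# transient (3-6 g) and a post-impact rest with rotated gravity; hops are
# the deliberately confusable ADL, with impact peaks (2.5-4 g) overlapping
# the fall range but only a brief, shallower flight dip.

#' GeneratorConfig: parameters of the synthetic testbed
#'
#' Defaults mirror the emulated study protocol: 17 subjects, at least 3
#' trials per movement, 7 ADL and 3 fall subtypes, all five positions, a
#' 200 Hz smartphone (default +/-2 g, the low-range variant that exercises
#' clipping; +/-16 g selectable) and 20 Hz +/-8 g motes, 10 s trials, 2
#' (older) subjects performing no falls.
#'
#' @slot nSubjects integer(1) > 0.
#' @slot trialsPerMovement integer(1) > 0.
#' @slot adlSubtypes,fallSubtypes character, movement subtypes to generate.
#' @slot positions character, worn positions.
#' @slot deviceSpecs named list of [SensorSpec-class], one per position.
#' @slot trialDuration numeric(1), seconds, > 2.
#' @slot noiseSd numeric(1) >= 0, additive Gaussian noise per axis, m/s^2.
#' @slot nNonFallSubjects integer(1) >= 0, subjects who perform no falls.
#' @slot transferGains data.frame, per-position amplitude gains and lags,
#'   see [defaultTransferGains()].
#' @slot seed integer(1), master seed.
#' @export
setClass("GeneratorConfig",
  slots = c(nSubjects = "integer", trialsPerMovement = "integer",
            adlSubtypes = "character", fallSubtypes = "character",
            positions = "character", deviceSpecs = "list",
            trialDuration = "numeric", noiseSd = "numeric",
            nNonFallSubjects = "integer", transferGains = "data.frame",
            seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character(0)
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (object@trialsPerMovement < 1L)
    msg <- c(msg, "trialsPerMovement must be positive")
  if (object@trialDuration <= 2)
    msg <- c(msg, "trialDuration must exceed 2 s")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@nNonFallSubjects < 0L ||
      object@nNonFallSubjects > object@nSubjects)
    msg <- c(msg, "nNonFallSubjects must be in [0, nSubjects]")
  if (!all(object@positions %in% sensorPositions()))
    msg <- c(msg, "unknown position in config")
  if (!all(object@positions %in% names(object@deviceSpecs)))
    msg <- c(msg, "every position needs a device spec")
  if (!all(object@adlSubtypes %in% adlSubtypes()) ||
      !all(object@fallSubtypes %in% fallSubtypes()))
    msg <- c(msg, "unknown activity subtype in config")
  if (length(msg)) msg else TRUE
})

#' Default device specs per position
#'
#' The thigh-pocket smartphone samples at 200 Hz with a +/-2 g accelerometer
#' by default (`phoneRange = 16` selects the wide-range variant); the four
#' motes sample at 20 Hz with +/-8 g.
#'
#' @param phoneRange accelerometer half-range of the smartphone, g.
#' @return Named list of [SensorSpec-class], one per canonical position.
#' @export
defaultDeviceSpecs <- function(phoneRange = 2) {
  specs <- list(
    thigh_pocket = SensorSpec("phone-01", "phone", 200, phoneRange),
    chest = SensorSpec("mote-chest", "mote", 20, 8),
    waist = SensorSpec("mote-waist", "mote", 20, 8),
    wrist = SensorSpec("mote-wrist", "mote", 20, 8),
    ankle = SensorSpec("mote-ankle", "mote", 20, 8))
  specs
}

#' Default per-position transfer gains
#'
#' Per-position multipliers applied to the dynamic (non-gravity) part of a
#' movement template, plus a small mechanical lag in seconds. The wrist
#' carries the largest fall-impact gain (protective arm motion amplifies
#' the transient there), the trunk positions (waist, chest) are faithful,
#' and the ankle and the loosely coupled thigh pocket are attenuated. Hop
#' impacts are amplified at the ankle (the striking limb) and less at the
#' wrist. Override with uniform gains (all 1) for ablation runs.
#'
#' @return A data.frame with columns `position`, `fall`, `hop`, `adl`,
#'   `lag`.
#' @export
defaultTransferGains <- function() {
  data.frame(
    position = sensorPositions(),
    fall = c(0.85, 0.95, 1.00, 1.25, 0.80),
    hop  = c(0.90, 0.95, 1.00, 1.10, 1.20),
    adl  = c(0.90, 0.95, 1.00, 1.05, 1.15),
    lag  = c(0.030, 0.010, 0.000, 0.020, 0.030))
}

#' @rdname GeneratorConfig-class
#' @param nSubjects,trialsPerMovement,trialDuration,noiseSd,nNonFallSubjects,seed
#'   see slots.
#' @param adlSubtypes,fallSubtypes,positions subsets of the canonical sets.
#' @param deviceSpecs named list of [SensorSpec-class] per position.
#' @param transferGains data.frame as from [defaultTransferGains()].
#' @param phoneRange smartphone accelerometer half-range in g, forwarded to
#'   [defaultDeviceSpecs()] when `deviceSpecs` is not given.
#' @return A validated `GeneratorConfig`.
#' @export
generatorConfig <- function(nSubjects = 17, trialsPerMovement = 3,
                            adlSubtypes = fallfusion::adlSubtypes(),
                            fallSubtypes = fallfusion::fallSubtypes(),
                            positions = sensorPositions(),
                            deviceSpecs = defaultDeviceSpecs(phoneRange),
                            trialDuration = 10, noiseSd = 0.3,
                            nNonFallSubjects = 2, seed = 1,
                            transferGains = defaultTransferGains(),
                            phoneRange = 2) {
  new("GeneratorConfig", nSubjects = as.integer(nSubjects),
      trialsPerMovement = as.integer(trialsPerMovement),
      adlSubtypes = tolower(adlSubtypes), fallSubtypes = tolower(fallSubtypes),
      positions = canonicalPositions(positions), deviceSpecs = deviceSpecs,
      trialDuration = as.numeric(trialDuration), noiseSd = as.numeric(noiseSd),
      nNonFallSubjects = as.integer(nNonFallSubjects),
      transferGains = transferGains, seed = as.integer(seed))
}

# ---- deterministic per-trial seeding -------------------------------------

hashString <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

trialSeed <- function(seed, subjectId, subtype, trialIndex) {
  h <- hashString(subjectId)
  k <- hashString(subtype)
  as.integer((abs(seed) * 2654435 + h * 97 + k * 1009 +
                trialIndex * 9176) %% 2147483647)
}

# ---- movement templates --------------------------------------------------

# gravity reading in the sensor frame after tilting by chi about the x axis;
# standing upright reads (0, 0, -g0)
gravityVec <- function(chi) {
  cbind(0, STANDARD_GRAVITY * sin(chi), -STANDARD_GRAVITY * cos(chi))
}

unitVec <- function(v) v / sqrt(sum(v^2))

# cosine ease from 0 to 1 over [0, 1]
ease <- function(u) 0.5 * (1 - cos(pi * pmin(pmax(u, 0), 1)))

# Draw the per-trial random template parameters. RNG state must already be
# set; parameters are shared by all positions of the trial.
drawTemplateParams <- function(subtype, category, duration) {
  g0 <- STANDARD_GRAVITY
  if (category == "FALL") {
    base <- switch(subtype,
      lateral = c(1, 0.2, -0.3), frontal = c(0.2, 1, -0.3),
      backward = c(0.2, -1, -0.3))
    tQuiet <- runif(1, 2, 4)
    dipDur <- runif(1, 0.12, 0.28)
    return(list(kind = "fall",
      tQuiet = tQuiet, dipDur = dipDur,
      dipLevel = runif(1, 0.12, 0.30),
      impStart = tQuiet + dipDur,
      impDur = runif(1, 0.06, 0.14),
      peak = runif(1, 3, 6) * g0,
      impDir = unitVec(base + 0.2 * rnorm(3)),
      chiEnd = runif(1, 75, 95) * pi / 180))
  }
  switch(subtype,
    walk = list(kind = "periodic", tStart = 1,
                freq = runif(1, 1.6, 2.2), amp = runif(1, 0.2, 0.4) * g0,
                sway = 0.05 * g0, phase = runif(1, 0, 2 * pi),
                sharp = 1, asym = 1),
    jog = list(kind = "periodic", tStart = 1,
               freq = runif(1, 2.2, 2.8), amp = runif(1, 0.85, 1.05) * g0,
               sway = 0.08 * g0, phase = runif(1, 0, 2 * pi),
               sharp = 2, asym = 1),
    stairs = list(kind = "periodic", tStart = 1,
                  freq = runif(1, 1.4, 1.8), amp = runif(1, 0.3, 0.6) * g0,
                  sway = 0.06 * g0, phase = runif(1, 0, 2 * pi),
                  sharp = 1, asym = 0.6),
    bend = list(kind = "tilt", tStart = runif(1, 2, 3),
                moveDur = runif(1, 1.5, 2.5), holdDur = 1,
                chiEnd = runif(1, 50, 70) * pi / 180, back = TRUE,
                bumpAmp = runif(1, 0.05, 0.12) * g0),
    lie_down = list(kind = "tilt", tStart = runif(1, 2, 4),
                    moveDur = runif(1, 2, 3.5), holdDur = Inf,
                    chiEnd = runif(1, 80, 95) * pi / 180, back = FALSE,
                    bumpAmp = runif(1, 0.05, 0.15) * g0),
    sit_down = list(kind = "sit", tSit = runif(1, 3, 5),
                    bumpAmp = runif(1, 0.1, 0.3) * g0,
                    bumpDur = 0.25, chiEnd = runif(1, 10, 20) * pi / 180),
    hop = {
      nHops <- sample(3:5, 1)
      tStart <- runif(1, 1.2, 2.0)
      period <- runif(1, 1.0, 1.4)
      peak <- runif(1, 2.5, 4.0) * g0
      list(kind = "hop", nHops = nHops, tStart = tStart, period = period,
           dipDur = runif(nHops, 0.06, 0.12),
           dipLevel = runif(nHops, 0.36, 0.60),
           impDur = runif(nHops, 0.06, 0.12),
           # first landing carries the trial's peak; later ones a fraction
           peaks = peak * c(1, runif(nHops - 1, 0.8, 1)),
           impDirs = t(vapply(seq_len(nHops), function(i)
             unitVec(c(0.15 * rnorm(2), -1)), numeric(3))))
    },
    stop("no movement template for subtype: ", subtype))
}

# Evaluate a template at times tvec (base envelope, unit gains): returns
# gravFactor (n), chi (n), dyn (n x 3), imp (n), impDir (n x 3).
templateSeries <- function(params, tvec) {
  n <- length(tvec)
  gf <- rep(1, n); chi <- rep(0, n)
  dyn <- matrix(0, n, 3); imp <- rep(0, n); impDir <- matrix(0, n, 3)
  g0 <- STANDARD_GRAVITY
  switch(params$kind,
    fall = {
      inDip <- tvec >= params$tQuiet & tvec < params$impStart
      gf[inDip] <- params$dipLevel
      chi <- ifelse(tvec < params$tQuiet, 0,
              ifelse(tvec < params$impStart,
                params$chiEnd * 0.4 * ease((tvec - params$tQuiet) / params$dipDur),
                params$chiEnd))
      tImpEnd <- params$impStart + params$impDur
      inImp <- tvec >= params$impStart & tvec < tImpEnd
      imp[inImp] <- params$peak
      impDir[inImp, ] <- matrix(params$impDir, sum(inImp), 3, byrow = TRUE)
      after <- tvec >= tImpEnd
      dyn[after, 3] <- 0.25 * g0 * exp(-3 * (tvec[after] - tImpEnd)) *
        sin(2 * pi * 4 * (tvec[after] - tImpEnd))
    },
    periodic = {
      act <- tvec >= params$tStart
      tt <- tvec[act] - params$tStart
      h <- (0.5 * (1 - cos(2 * pi * params$freq * tt)))^params$sharp
      stepAmp <- ifelse(floor(params$freq * tt) %% 2 == 0, 1, params$asym)
      dyn[act, 3] <- -params$amp * h * stepAmp
      dyn[act, 1] <- params$sway * sin(2 * pi * params$freq * tt + params$phase)
    },
    tilt = {
      tEndMove <- params$tStart + params$moveDur
      u <- (tvec - params$tStart) / params$moveDur
      chi <- params$chiEnd * ease(u)
      if (params$back && is.finite(params$holdDur)) {
        tBack <- tEndMove + params$holdDur
        goingBack <- tvec >= tBack
        chi[goingBack] <- params$chiEnd *
          (1 - ease((tvec[goingBack] - tBack) / params$moveDur))
      }
      moving <- (tvec >= params$tStart & tvec < tEndMove) |
        (params$back & tvec >= tEndMove + params$holdDur &
           tvec < tEndMove + params$holdDur + params$moveDur)
      dyn[moving, 3] <- -params$bumpAmp *
        sin(pi * ((tvec[moving] - params$tStart) %% params$moveDur) /
              params$moveDur)
    },
    sit = {
      after <- tvec >= params$tSit
      chi[after] <- params$chiEnd
      inBump <- tvec >= params$tSit & tvec < params$tSit + params$bumpDur
      dyn[inBump, 3] <- -params$bumpAmp *
        sin(pi * (tvec[inBump] - params$tSit) / params$bumpDur)
    },
    hop = {
      for (j in seq_len(params$nHops)) {
        tj <- params$tStart + (j - 1) * params$period
        inDip <- tvec >= tj & tvec < tj + params$dipDur[j]
        gf[inDip] <- params$dipLevel[j]
        tImp <- tj + params$dipDur[j]
        inImp <- tvec >= tImp & tvec < tImp + params$impDur[j]
        imp[inImp] <- params$peaks[j]
        impDir[inImp, ] <- matrix(params$impDirs[j, ], sum(inImp), 3,
                                  byrow = TRUE)
      }
    },
    stop("unknown template kind"))
  list(gravFactor = gf, chi = chi, dyn = dyn, imp = imp, impDir = impDir)
}

#' Apply a per-position transfer gain to a dynamic envelope
#'
#' Scales the dynamic (non-gravity) part of a movement envelope by the
#' position's gain for the given activity: fall impacts are amplified at
#' the wrist (protective arm motion) and attenuated at the ankle and the
#' loosely coupled thigh pocket; hop impacts are amplified at the ankle.
#' With uniform gains (all 1) the base envelope is reproduced unchanged.
#'
#' @param envelope numeric vector, dynamic amplitude envelope (any unit).
#' @param position one of [sensorPositions()].
#' @param activity an activity subtype (e.g. "lateral", "hop", "walk").
#' @param gains data.frame as from [defaultTransferGains()].
#' @return `envelope * gain(position, activity)`.
#' @export
positionTransfer <- function(envelope, position, activity,
                             gains = defaultTransferGains()) {
  envelope * transferGain(position, activity, gains)
}

transferGain <- function(position, activity, gains = defaultTransferGains()) {
  row <- match(position, gains$position)
  if (is.na(row)) stop("no transfer gains for position ", position)
  col <- if (activity %in% fallSubtypes()) "fall"
         else if (activity == "hop") "hop" else "adl"
  gains[[col]][row]
}

# ---- trial and dataset generation ----------------------------------------

#' Generate one synthetic trial
#'
#' Builds a [TrialRecording-class] with one stream per configured position.
#' The per-trial RNG substream is derived from (config seed, subject id,
#' subtype, trial index), so any single trial is reproducible in isolation.
#' Template parameters are drawn once per trial and shared by all
#' positions; each position then applies its transfer gain and lag, samples
#' at its device rate, adds Gaussian noise (`noiseSd` per axis) and clips
#' to the device range. Gyroscope cells carry the tilt rate and
#' magnetometer cells a fixed field rotated with the tilt (placeholders
#' consistent with the orientation trajectory; no detector reads them).
#'
#' @param subject a [SubjectMeta-class].
#' @param activity list with `category` and `subtype`, or a subtype string.
#' @param trialIndex integer >= 1.
#' @param config a [GeneratorConfig-class].
#' @return A validated [TrialRecording-class].
#' @export
genTrial <- function(subject, activity, trialIndex, config) {
  if (is.character(activity)) {
    subtype <- tolower(activity)
    category <- if (subtype %in% fallSubtypes()) "FALL" else "ADL"
  } else {
    category <- toupper(activity$category); subtype <- tolower(activity$subtype)
  }
  allowed <- if (category == "FALL") fallSubtypes() else adlSubtypes()
  if (!subtype %in% allowed)
    stop(sprintf("no template for %s subtype \"%s\"", category, subtype))

  seed <- trialSeed(config@seed, subject@subjectId, subtype,
                    as.integer(trialIndex))
  old <- .Random.seed__save()
  on.exit(.Random.seed__restore(old), add = TRUE)
  set.seed(seed)

  params <- drawTemplateParams(subtype, category, config@trialDuration)
  gains <- config@transferGains
  streamsOut <- list()
  for (pos in config@positions) {
    spec <- config@deviceSpecs[[pos]]
    rate <- samplingRate(spec)
    tvec <- seq(0, config@trialDuration - 1 / rate, by = 1 / rate)
    lag <- gains$lag[match(pos, gains$position)]
    if (is.na(lag)) lag <- 0
    ts <- templateSeries(params, pmax(tvec - lag, 0))
    gain <- transferGain(pos, subtype, gains)

    grav <- gravityVec(ts$chi) * ts$gravFactor
    acc <- grav + gain * ts$dyn
    hit <- ts$imp > 0
    if (any(hit))  # impact transient replaces the (weightless) gravity term
      acc[hit, ] <- gain * ts$imp[hit] * ts$impDir[hit, , drop = FALSE]
    if (config@noiseSd > 0)
      acc <- acc + matrix(rnorm(3 * length(tvec), 0, config@noiseSd),
                          ncol = 3)
    lim <- accelRange(spec) * STANDARD_GRAVITY
    acc <- pmin(pmax(acc, -lim), lim)

    chiRate <- c(0, diff(ts$chi)) * rate * 180 / pi
    streamsOut[[pos]] <- SensorStream(
      position = pos, spec = spec, t = tvec,
      ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
      gx = chiRate, gy = rep(0, length(tvec)), gz = rep(0, length(tvec)),
      mx = rep(0, length(tvec)),
      my = 20 * cos(ts$chi) + 40 * sin(ts$chi),
      mz = 20 * sin(ts$chi) - 40 * cos(ts$chi))
  }
  TrialRecording(subject = subject, activityCategory = category,
                 activitySubtype = subtype, trialIndex = trialIndex,
                 streams = streamsOut)
}

# save/restore the global RNG state so generation is side-effect free
.Random.seed__save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed__restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate the subject pool
#'
#' Subject metadata emulating the testbed's pool: ages 14-55 (the
#' configured number of non-falling subjects are the oldest, over 50),
#' heights 155-195 cm, weights 50-93 kg, and a roughly 6:11
#' female-to-male ratio.
#'
#' @param config a [GeneratorConfig-class].
#' @return List of [SubjectMeta-class], non-falling subjects last.
#' @export
genSubjects <- function(config) {
  old <- .Random.seed__save()
  on.exit(.Random.seed__restore(old), add = TRUE)
  set.seed(as.integer((abs(config@seed) * 7919 + 13) %% 2147483647))
  n <- config@nSubjects
  nNF <- config@nNonFallSubjects
  nF <- round(6 / 17 * n)
  genders <- sample(rep(c("F", "M"), c(nF, n - nF)))
  ages <- integer(n)
  if (n > nNF) ages[seq_len(n - nNF)] <- sample(14:50, n - nNF, replace = TRUE)
  if (nNF > 0) ages[seq.int(n - nNF + 1L, n)] <- sample(51:55, nNF, replace = TRUE)
  lapply(seq_len(n), function(i)
    SubjectMeta(sprintf("s%02d", i), ages[i],
                round(runif(1, 155, 195), 1), round(runif(1, 50, 93), 1),
                genders[i]))
}

#' Generate a full synthetic dataset
#'
#' The full crossing of subjects x movement subtypes x trial repetitions:
#' every subject performs every ADL subtype; all but the configured
#' non-falling subjects additionally perform every fall subtype. With
#' defaults this yields 17*7*3 = 357 ADL trials and 15*3*3 = 135 fall
#' trials. The dataset is a pure function of the config (including its
#' seed); per-trial substreams make any subset reproducible in isolation.
#'
#' @param config a [GeneratorConfig-class].
#' @return A [FallDataset-class].
#' @examples
#' cfg <- generatorConfig(nSubjects = 2, trialsPerMovement = 1,
#'                        adlSubtypes = "walk", fallSubtypes = "lateral",
#'                        nNonFallSubjects = 0, seed = 7)
#' nTrials(genDataset(cfg))  # 4
#' @export
genDataset <- function(config) {
  validObject(config)
  subjects <- genSubjects(config)
  fallers <- seq_len(config@nSubjects - config@nNonFallSubjects)
  out <- list()
  for (i in seq_along(subjects)) {
    subtypes <- c(config@adlSubtypes,
                  if (i %in% fallers) config@fallSubtypes)
    for (sub in subtypes)
      for (k in seq_len(config@trialsPerMovement))
        out[[length(out) + 1L]] <- genTrial(subjects[[i]], sub, k, config)
  }
  FallDataset(out)
}
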