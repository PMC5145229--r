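# Shared builders and memoised datasets. All fixtures are constructed in
# code; the default-condition datasets are generated once per test run.

g0 <- fallfusion::STANDARD_GRAVITY

moteSpec <- function(id = "m1", rate = 20, range = 8) {
  SensorSpec(id, "mote", samplingRate = rate, accelRange = range)
}

# stream from explicit axis vectors on a regular time grid
makeStream <- function(ax, ay, az, rate = 20, position = "waist", range = 8) {
  n <- length(ax)
  SensorStream(position, moteSpec(paste0("dev-", position), rate, range),
               t = seq(0, by = 1 / rate, length.out = n),
               ax = ax, ay = ay, az = az)
}

# stream whose SMV follows `smv` exactly (all acceleration along -z)
smvStream <- function(smv, rate = 20, position = "waist", range = 8) {
  z <- numeric(length(smv))
  makeStream(z, z, -abs(smv), rate, position, range)
}

randomStream <- function(n = 200, rate = 20, sd = 3, position = "waist") {
  makeStream(rnorm(n, 0, sd), rnorm(n, 0, sd), rnorm(n, -g0, sd),
             rate = rate, position = position, range = 16)
}

testSubject <- function(id = "s01") SubjectMeta(id, 30L, 175, 70, "M")

# single- or multi-stream trial around an SMV profile
makeTrial <- function(smv, subtype = "walk", positions = "waist",
                      trialIndex = 1L, rate = 20) {
  category <- if (subtype %in% fallSubtypes()) "FALL" else "ADL"
  TrialRecording(testSubject(), category, subtype, trialIndex,
                 lapply(positions, function(p) smvStream(smv, rate, p)))
}

# tiny two-class dataset: ADL peaks at `adlPeak` g, falls at `fallPeak` g
separableDataset <- function(nAdl = 4, nFall = 3, adlPeak = 1.5,
                             fallPeak = 4, positions = "waist") {
  adl <- lapply(seq_len(nAdl), function(i) {
    prof <- c(rep(g0, 10), adlPeak * g0, rep(g0, 10))
    makeTrial(prof, "walk", positions, i)
  })
  fall <- lapply(seq_len(nFall), function(i) {
    prof <- c(rep(g0, 10), 0.2 * g0, fallPeak * g0, rep(g0, 10))
    makeTrial(prof, "lateral", positions, i)
  })
  FallDataset(c(adl, fall))
}

# memoised study-condition datasets (defaults; noiseless variant for the
# separability checks)
.fixtures <- new.env(parent = emptyenv())

fixtureDefaultDataset <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- genDataset(generatorConfig())
  .fixtures$default
}

fixtureNoiselessDataset <- function() {
  if (is.null(.fixtures$noiseless))
    .fixtures$noiseless <- genDataset(generatorConfig(noiseSd = 0))
  .fixtures$noiseless
}

# matrix [trial x position] of decision statistics, via the public API
fixtureStatMatrix <- function(dataset, algorithm,
                              positions = sensorPositions()) {
  trs <- trials(dataset)
  sapply(positions, function(p)
    vapply(trs, function(tr) decisionStatistic(streams(tr)[[p]], algorithm),
           numeric(1)))
}

fixtureLabels <- function(dataset) {
  vapply(trials(dataset), activityCategory, character(1))
}
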