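# Trial-level detectors: worked examples, constructed traces, threshold
# monotonicity, and agreement between the scalar decision statistics and
# the boolean detectors.

test_that("basic thresholding fires on any exceedance of the SMV threshold", {
  quiet <- smvStream(rep(g0, 40))
  expect_false(detectBasic(quiet, BasicParams(gToMs2(2.5))))
  spike <- smvStream(c(rep(g0, 20), 3 * g0, rep(g0, 19)))
  expect_true(detectBasic(spike, BasicParams(gToMs2(2.5))))
  # ties at the threshold are negatives (strict comparison)
  expect_false(detectBasic(spike, BasicParams(3 * g0)))
})

test_that("detector decisions are monotone non-increasing in their primary
           threshold", {
  set.seed(21)
  ctrl <- detectorControl()
  for (rep in 1:5) {
    s <- randomStream(200)
    for (alg in algorithmIds()) {
      grid <- seq(0.1, 80, length.out = 30)
      if (alg == "fi") grid <- seq(1, 4000, length.out = 30)
      if (alg == "ifall") grid <- seq(7, 80, length.out = 30)  # above smvL
      dec <- vapply(grid, function(th)
        fallfusion:::runDetector(s, alg, th, ctrl), logical(1))
      expect_true(all(diff(dec) <= 0),
                  label = sprintf("%s decisions monotone", alg))
    }
  }
})

test_that("Fall Index detector sees steps but not slow ramps that basic
           thresholding catches", {
  const <- smvStream(rep(g0, 60))
  expect_false(detectFallIndex(const, FIParams(1e-6)))

  delta <- 4
  s <- makeStream(rep(0, 60), rep(0, 60), c(rep(-9, 30), rep(-9 - delta, 30)))
  expect_true(detectFallIndex(s, FIParams(delta^2 * 0.9)))
  expect_false(detectFallIndex(s, FIParams(delta^2 * 1.1)))

  # slow ramp: per-sample increment small, final SMV large
  inc <- 0.05
  az <- -(g0 + cumsum(rep(inc, 400)))  # drifts to ~3 g
  ramp <- makeStream(rep(0, 400), rep(0, 400), az, rate = 20, range = 16)
  fiTh <- 20 * 3 * inc^2 * 10  # well above the ramp's FI plateau
  expect_false(detectFallIndex(ramp, FIParams(fiTh)))
  expect_true(detectBasic(ramp, BasicParams(gToMs2(2.5))))
})

test_that("PerFallD requires both window conditions simultaneously", {
  const <- smvStream(rep(g0, 40))
  expect_false(detectPerFallD(const, PerFallDParams(1e-3, 1e-3)))

  # simultaneous 4 g steps in SMV and |A_v| inside one window
  prof <- c(rep(g0, 10), rep(5 * g0, 10), rep(g0, 20))
  s <- smvStream(prof)  # ax = 0, az < 0: |A_v| tracks SMV exactly
  expect_true(detectPerFallD(s, PerFallDParams(gToMs2(3), gToMs2(3))))

  # SMV condition satisfied only early, |A_v| condition only late -> FALSE.
  # Early: 4 g swings along -z (SMV and AV ranges both 4 g). Middle: slow
  # ramp to 8 g. Late: rotation at constant 8 g norm between -z and the
  # (1,-1,1) direction, whose vertical projection is ~0.41 of the norm:
  # AV range ~4.7 g at zero SMV range.
  rate <- 20
  nA <- 10; nRamp <- 30; nB <- 10
  azA <- rep(c(-g0, -5 * g0), length.out = nA)
  axA <- ayA <- rep(0, nA)
  ramp <- seq(3 * g0, 8 * g0, length.out = nRamp)
  azR <- -ramp; axR <- ayR <- rep(0, nRamp)
  u <- c(1, -1, 1) / sqrt(3)
  odd <- rep(c(TRUE, FALSE), length.out = nB)
  axB <- ifelse(odd, 0, 8 * g0 * u[1])
  ayB <- ifelse(odd, 0, 8 * g0 * u[2])
  azB <- ifelse(odd, -8 * g0, 8 * g0 * u[3])
  s2 <- makeStream(c(axA, axR, axB), c(ayA, ayR, ayB), c(azA, azR, azB),
                   rate = rate, range = 16)
  smvTh <- gToMs2(3); avTh <- gToMs2(4.3)
  # sanity on the construction: each condition is attainable on its own
  expect_true(detectPerFallD(s2, PerFallDParams(smvTh, gToMs2(3.9))))
  expect_true(detectPerFallD(s2, PerFallDParams(gToMs2(0.5), avTh)))
  # but never simultaneously in the same window
  expect_false(detectPerFallD(s2, PerFallDParams(smvTh, avTh)))
})

test_that("PerFallD window ranges match naive recomputation on random
           streams", {
  set.seed(22)
  rollRangeOracle <- function(v, k)
    vapply(seq_len(length(v) - k + 1), function(i)
      max(v[i:(i + k - 1)]) - min(v[i:(i + k - 1)]), numeric(1))
  for (rep in 1:5) {
    s <- randomStream(150)
    smv <- computeSMV(s)@values
    k <- 10
    expect_equal(fallfusion:::rollRange(smv, k), rollRangeOracle(smv, k))
  }
})

test_that("iFall needs a free-fall dip followed by an impact within the
           observation window", {
  p <- IFallParams(smvU = gToMs2(2))
  expect_equal(p@smvL, 6.374323, tolerance = 1e-6)

  # canonical fall: dip to 0.2 g for 0.15 s, 3 g peak 0.3 s later
  prof <- c(rep(g0, 20), rep(0.2 * g0, 3), rep(g0, 6), 3 * g0, rep(g0, 10))
  expect_true(detectIFall(smvStream(prof), p))

  # impact before any dip: phase order matters
  prof <- c(rep(g0, 10), 3 * g0, rep(g0, 10), rep(0.2 * g0, 3), rep(g0, 20))
  expect_false(detectIFall(smvStream(prof), p))

  # dip, but the peak arrives 0.8 s later: window expired
  prof <- c(rep(g0, 20), rep(0.2 * g0, 3), rep(g0, 15), 3 * g0, rep(g0, 10))
  expect_false(detectIFall(smvStream(prof), p))

  # after an expired window, scanning resumes and a later dip+impact fires
  prof <- c(rep(g0, 20), rep(0.2 * g0, 3), rep(g0, 20),
            rep(0.2 * g0, 3), rep(g0, 5), 3 * g0, rep(g0, 5))
  expect_true(detectIFall(smvStream(prof), p))
})

test_that("decision statistics reproduce the boolean detectors at any
           threshold", {
  set.seed(23)
  ctrl <- detectorControl()
  for (rep in 1:5) {
    s <- randomStream(200)
    for (alg in algorithmIds()) {
      stat <- decisionStatistic(s, alg, ctrl)
      ths <- sort(c(stat * c(0.5, 0.99, 1.01, 2), abs(rnorm(4, 20, 10))))
      ths <- ths[ths > 0 & is.finite(ths)]
      if (alg == "ifall") ths <- ths[ths > ctrl$smvL]
      for (th in ths)
        expect_identical(fallfusion:::runDetector(s, alg, th, ctrl),
                         stat > th,
                         label = sprintf("%s at %.3f", alg, th))
    }
  }
})

test_that("detectors are deterministic and error on invalid input", {
  s <- randomStream(100)
  expect_identical(detectPerFallD(s, PerFallDParams(5, 5)),
                   detectPerFallD(s, PerFallDParams(5, 5)))
  short <- smvStream(rep(g0, 5))
  expect_error(detectPerFallD(short, PerFallDParams(5, 5)), "shorter")
  expect_error(detectFallIndex(short, FIParams(1)), "short")
  expect_error(BasicParams(-1))
  expect_error(IFallParams(smvU = 3, smvL = 5))
})
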