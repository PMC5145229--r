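# Synthetic trial generator: determinism, protocol shape, clipping and the
# engineered contrast between ordinary ADLs, hops and falls.

smallCfg <- function(...) {
  generatorConfig(nSubjects = 2, trialsPerMovement = 1,
                  nNonFallSubjects = 0, seed = 11, ...)
}

test_that("generation is a pure function of the config and seed", {
  cfg <- smallCfg()
  subj <- genSubjects(cfg)[[1]]
  t1 <- genTrial(subj, "lateral", 1L, cfg)
  t2 <- genTrial(subj, "lateral", 1L, cfg)
  expect_identical(t1, t2)
  # different trial index -> different noise realisation
  t3 <- genTrial(subj, "lateral", 2L, cfg)
  expect_false(identical(streams(t1)$waist@az, streams(t3)$waist@az))

  d1 <- genDataset(smallCfg(adlSubtypes = c("walk", "hop"),
                            fallSubtypes = "frontal"))
  d2 <- genDataset(smallCfg(adlSubtypes = c("walk", "hop"),
                            fallSubtypes = "frontal"))
  expect_identical(d1, d2)
})

test_that("trial files from the same seed are byte-identical", {
  cfg <- smallCfg(adlSubtypes = "jog", fallSubtypes = character(0))
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  writeDataset(genDataset(cfg), dirA)
  writeDataset(genDataset(cfg), dirB)
  for (f in list.files(dirA))
    expect_identical(readLines(file.path(dirA, f)),
                     readLines(file.path(dirB, f)), label = f)
})

test_that("the protocol crossing yields the expected trial counts", {
  cfg <- generatorConfig(nSubjects = 4, trialsPerMovement = 2,
                         nNonFallSubjects = 1, seed = 12)
  d <- genDataset(cfg)
  labs <- fixtureLabels(d)
  expect_equal(sum(labs == "ADL"), 4 * 7 * 2)
  expect_equal(sum(labs == "FALL"), 3 * 3 * 2)

  tiny <- genDataset(smallCfg(adlSubtypes = "walk", fallSubtypes = "lateral"))
  expect_equal(nTrials(tiny), 4)  # 2 subjects x (1 ADL + 1 fall)
})

test_that("fall trials at the narrow-range phone are clipped to the
           device limit", {
  cfg <- smallCfg(adlSubtypes = character(0))
  d <- genDataset(cfg)  # 2 subjects x 3 fall subtypes
  lim <- 2 * g0
  phoneMax <- vapply(trials(d), function(tr) {
    s <- streams(tr)$thigh_pocket
    max(abs(c(s@ax, s@ay, s@az)))
  }, numeric(1))
  expect_true(all(phoneMax <= lim + 1e-9))
  expect_equal(max(phoneMax), lim)  # some impact actually saturates
  # the wide-range motes keep the full transient somewhere
  moteMax <- vapply(trials(d), function(tr)
    max(computeSMV(streams(tr)$waist)@values), numeric(1))
  expect_gt(max(moteMax), gToMs2(2.5))
})

test_that("noiseless templates order walk < 2 g < hop and give falls a
           free-fall dip that hops lack", {
  cfg <- smallCfg(noiseSd = 0)
  subj <- genSubjects(cfg)[[1]]
  walk <- streams(genTrial(subj, "walk", 1L, cfg))$waist
  hop <- streams(genTrial(subj, "hop", 1L, cfg))$waist
  fall <- streams(genTrial(subj, "lateral", 1L, cfg))$waist
  expect_lt(max(computeSMV(walk)@values), gToMs2(2))
  expect_gt(max(computeSMV(hop)@values), gToMs2(2))

  # fall dip: below 0.35 g for a sustained stretch; hop dips never that deep
  smvFall <- computeSMV(fall)@values
  expect_gte(sum(smvFall < 0.35 * g0), 2)
  expect_equal(sum(computeSMV(hop)@values < 0.35 * g0), 0)
  # quiet standing start in every template
  expect_equal(smvFall[1:10], rep(g0, 10), tolerance = 1e-9)
})

test_that("position transfer shapes per-position amplitudes as configured", {
  env <- c(0, 1, 2)
  expect_equal(positionTransfer(env, "waist", "lateral"), env)
  gains <- defaultTransferGains()
  gains[gains$position == "wrist", "fall"] <- 1
  expect_equal(positionTransfer(env, "wrist", "lateral", gains), env)

  cfg <- smallCfg(noiseSd = 0)
  subj <- genSubjects(cfg)[[1]]
  tr <- genTrial(subj, "frontal", 1L, cfg)
  peak <- function(p) max(computeSMV(streams(tr)[[p]])@values)
  expect_gt(peak("wrist"), peak("waist"))   # protective arm transient
  expect_gt(peak("waist"), peak("ankle"))   # attenuated distal coupling
})

test_that("generated subjects match the pool structure", {
  cfg <- generatorConfig(nSubjects = 17, seed = 13)
  subs <- genSubjects(cfg)
  expect_length(subs, 17)
  ages <- vapply(subs, function(s) s@age, integer(1))
  expect_true(all(ages >= 14 & ages <= 55))
  expect_true(all(ages[16:17] > 50))  # the non-falling subjects are oldest
  expect_equal(sum(vapply(subs, function(s) s@gender, character(1)) == "F"), 6)
  for (s in subs) expect_true(validObject(s))
})

test_that("every generated stream satisfies the data-model invariants", {
  d <- genDataset(smallCfg(adlSubtypes = c("bend", "stairs", "sit_down",
                                           "lie_down"),
                           fallSubtypes = "lateral"))
  for (tr in trials(d)) {
    expect_true(validObject(tr))
    for (s in streams(tr)) {
      expect_true(validObject(s))
      expect_true(all(diff(s@t) > 0))
    }
  }
  expect_error(genTrial(testSubject(), "cartwheel", 1L, smallCfg()),
               "no template")
})
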