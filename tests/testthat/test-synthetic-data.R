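# Task-event generator, forward model and behavioral-score construction.

test_that("task events respect the paradigm timing exactly", {
  ev <- generateTaskEvents(400, seed = 1)
  expect_equal(nrow(ev), 400)
  expect_true(all(ev$secondOnsetMs - ev$cueOnsetMs == 1000))
  expect_true(all(diff(ev$cueOnsetMs) - 4000 == 0))  # 3000 ms after second
  expect_true(all(ev$stimulusDurationMs == 100))
  expect_true(all(ev$pairType %in% c("aa", "ap", "pp", "ph")))
  expect_true(all(is.na(ev$responseTimeMs[ev$pairType != "aa"])))
  expect_true(all(!is.na(ev$responseTimeMs[ev$pairType == "aa"])))
})

test_that("empty and invalid trial counts are handled", {
  expect_equal(nrow(generateTaskEvents(0, seed = 1)), 0)
  expect_error(generateTaskEvents(-1), "non-negative")
})

test_that("pair types are sampled with equal probability", {
  ev <- generateTaskEvents(4000, seed = 7)
  counts <- table(factor(ev$pairType, c("aa", "ap", "pp", "ph")))
  # Binomial(4000, 1/4): 3 SD band around 1000
  sdBin <- sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 1000) <= 3 * sdBin))
})

test_that("generation is bit-reproducible for a fixed seed", {
  r1 <- synthesizeSession(patientRow(), "task", seed = 11, nTrials = 5)
  r2 <- synthesizeSession(patientRow(), "task", seed = 11, nTrials = 5)
  expect_identical(r1@data, r2@data)
  expect_identical(r1@events, r2@events)
  r3 <- synthesizeSession(patientRow(), "task", seed = 12, nTrials = 5)
  expect_false(identical(r1@data, r3@data))
})

test_that("null forward model yields an all-zero recording", {
  eff <- quietEffects(earlyAmplitude = 0, goP3Amplitude = 0)
  rec <- synthesizeSession(patientRow(amp = 0), "eyes_open", effects = eff,
                           seed = 1, restDurationSec = 10)
  expect_true(all(rec@data == 0))
  expect_error(synthesizeSession(patientRow(), "nap"), "unknown condition")
})

test_that("patient task spectra peak near 7.6 Hz at F7, controls at 9.0 Hz at O2", {
  rec <- synthesizeSession(patientRow(), "task", seed = 5, nTrials = 20)
  ep <- markArtifactEpochs(rec)
  sp <- computeSpectrum(ep)
  sel <- sp@freq >= 4 & sp@freq <= 13
  pk <- sp@freq[sel][which.max(sp@power["F7", sel])]
  expect_lte(abs(pk - 7.6), 0.2)

  recC <- synthesizeSession(controlRow(), "eyes_closed", seed = 5,
                            restDurationSec = 60)
  spC <- computeSpectrum(markArtifactEpochs(recC))
  selC <- spC@freq >= 4 & spC@freq <= 13
  pkC <- spC@freq[selC][which.max(spC@power["O2", selC])]
  expect_lte(abs(pkC - 9.0), 0.2)
})

test_that("eyes-closed posterior alpha exceeds eyes-open at O2", {
  alphaBandPower <- function(cond) {
    rec <- synthesizeSession(controlRow(), cond, seed = 9,
                             restDurationSec = 60)
    sp <- computeSpectrum(markArtifactEpochs(rec))
    sum(sp@power["O2", sp@freq >= 8 & sp@freq <= 10])
  }
  expect_gt(alphaBandPower("eyes_closed"), alphaBandPower("eyes_open"))
})

test_that("low-alpha band effect at F7/T3/T5 has the injected sign per seed", {
  for (s in 1:3) {
    bp <- function(row, cond) {
      rec <- synthesizeSession(row, cond, seed = s + 100,
                               restDurationSec = 60)
      sp <- computeSpectrum(markArtifactEpochs(rec))
      mean(sp@power[c("F7", "T3", "T5"), sp@freq >= 6.5 & sp@freq <= 9.5])
    }
    expect_gt(bp(patientRow(), "eyes_open"), bp(controlRow(), "eyes_open"))
  }
})

test_that("behavioral scores recover the target correlation", {
  big <- do.call(rbind, lapply(1:2000, function(i) patientRow(sprintf("P%04d", i))))
  big$trueNogoAmplitude <- withr::with_seed(1, rnorm(2000, 2, 0.8))

  s1 <- generateBehavioralScores(big, trueR = 1, seed = 2)
  expect_equal(cor(s1$behavioralScore, s1$trueNogoAmplitude), 1)

  s2 <- generateBehavioralScores(big, trueR = 0.78, seed = 3)
  expect_lt(abs(cor(s2$behavioralScore, s2$trueNogoAmplitude) - 0.78), 0.03)

  s3 <- generateBehavioralScores(big, trueR = 0, seed = 4)
  expect_lt(abs(cor(s3$behavioralScore, s3$trueNogoAmplitude)), 0.1)

  expect_error(generateBehavioralScores(big, trueR = 1.2), "<= 1")
  expect_error(generateBehavioralScores(big[0, ], trueR = 0.5), ">= 2")
})

test_that("cohort table has the requested composition and score structure", {
  subj <- simulateCohort(cohortSpec(), effectSpec(), seed = 4)
  expect_equal(sum(subj$group == "patient"), 9)
  expect_equal(sum(subj$group == "control"), 50)
  expect_true(all(is.na(subj$behavioralScore[subj$group == "control"])))
  expect_true(all(is.finite(subj$behavioralScore[subj$group == "patient"])))
  expect_true(all(subj$trueNogoAmplitude > 0))
  # patient suppression of the latent NOGO amplitude
  expect_lt(mean(subj$trueNogoAmplitude[subj$group == "patient"]),
            mean(subj$trueNogoAmplitude[subj$group == "control"]))
})

test_that("cohort and effect validity rules fire", {
  expect_error(cohortSpec(nPatients = 1), "2 subjects")
  expect_error(cohortSpec(channelLabels = c("F7", "T3")), "10-20")
  expect_error(effectSpec(behavioralTrueR = 1.5), "behavioralTrueR")
  expect_error(effectSpec(patientLowAlphaPeak = 0.5), "1-30")
})
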