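# Filtering, re-referencing, ICA ocular correction and artifact rules.

test_that("band-pass attenuates stop-band and preserves pass-band sinusoids", {
  r60 <- bandpassFilter(sineRecording(60, fs = 250), 0.5, 30)
  in60 <- sineRecording(60)@data[1, ]
  expect_lt(sd(r60@data[1, ]), 0.05 * sd(in60))

  r10 <- bandpassFilter(sineRecording(10), 0.5, 30)
  in10 <- sineRecording(10)@data[1, ]
  # interior samples (edge transients excluded)
  mid <- 1000:4000
  expect_lt(abs(sd(r10@data[1, mid]) / sd(in10[mid]) - 1), 0.02)

  z <- bandpassFilter(asRecording(matrix(0, 2, 1000)), 0.5, 30)
  expect_true(all(z@data == 0))
  expect_error(bandpassFilter(sineRecording(10), 30, 20), "invalid band")
  expect_error(bandpassFilter(sineRecording(10), 1, 200), "invalid band")
})

test_that("notch removes 50 Hz and leaves 10 Hz intact", {
  r50 <- notchFilter(sineRecording(50))
  expect_lt(sd(r50@data[1, ]), 0.10 * sd(sineRecording(50)@data[1, ]))
  r10 <- notchFilter(sineRecording(10))
  mid <- 1000:4000
  expect_lt(abs(sd(r10@data[1, mid]) / sd(sineRecording(10)@data[1, mid]) - 1),
            0.02)
  z <- notchFilter(asRecording(matrix(0, 2, 1000)))
  expect_true(all(z@data == 0))
})

test_that("filters are linear operators", {
  set.seed(42)
  x <- matrix(rnorm(2 * 2000), 2, 2000)
  y <- matrix(rnorm(2 * 2000), 2, 2000)
  fa <- bandpassFilter(asRecording(2 * x + 3 * y), 1, 30)@data
  fb <- 2 * bandpassFilter(asRecording(x), 1, 30)@data +
    3 * bandpassFilter(asRecording(y), 1, 30)@data
  expect_equal(fa, fb, tolerance = 1e-8)
})

test_that("average re-reference zeroes the channel sum and keeps bipolar derivations", {
  set.seed(7)
  x <- matrix(rnorm(19 * 500, sd = 10), 19, 500)
  rownames(x) <- tenTwentyLabels()
  rec <- asRecording(x)
  rr <- rerefWeightedAverage(rec)
  expect_equal(max(abs(colSums(rr@data))), 0, tolerance = 1e-9)
  expect_identical(rr@reference, "weighted_average")
  # reference invariance of channel differences
  expect_equal(rr@data["F7", ] - rr@data["O2", ],
               x["F7", ] - x["O2", ], tolerance = 1e-9)
  # re-referencing twice is a state error
  expect_error(rerefWeightedAverage(rr), "already")
})

test_that("single nonzero channel retains 18/19 of its value under uniform weights", {
  x <- matrix(0, 19, 100, dimnames = list(tenTwentyLabels(), NULL))
  x["Cz", ] <- 19
  rr <- rerefWeightedAverage(asRecording(x))
  expect_equal(unname(rr@data["Cz", 1]), 19 * 18 / 19)
  expect_equal(unname(rr@data["Fz", 1]), -1)
  # constant offset on all channels is removed entirely
  xo <- matrix(5, 19, 100, dimnames = list(tenTwentyLabels(), NULL))
  expect_equal(max(abs(rerefWeightedAverage(asRecording(xo))@data)), 0)
})

test_that("ICA removes exactly the injected blink component", {
  eff <- effectSpec(artifactRatePerMin = 0)
  rec <- synthesizeSession(controlRow(), "eyes_open", effects = eff,
                           seed = 21, restDurationSec = 120)
  res <- removeOcularICA(rec, seed = 3)
  expect_equal(sum(res$report$removed), 1)
  expect_gte(max(abs(res$report$templateCorrelation)), 0.8)

  # variance in blink windows at Fp1 drops by >= 70%
  noBlink <- synthesizeSession(controlRow(), "eyes_open",
                               effects = effectSpec(blinkAmplitude = 0),
                               seed = 21, restDurationSec = 120)
  blinkPart <- rec@data["Fp1", ] - noBlink@data["Fp1", ]
  win <- which(abs(blinkPart) > 20)   # samples inside blinks
  expect_gt(length(win), 100)
  vBefore <- var(rec@data["Fp1", win])
  vAfter <- var(res$recording@data["Fp1", win])
  expect_lt(vAfter, 0.3 * vBefore)
})

test_that("ICA removes nothing without blinks and rejects short recordings", {
  rec <- synthesizeSession(controlRow(), "eyes_open",
                           effects = effectSpec(blinkAmplitude = 0),
                           seed = 22, restDurationSec = 90)
  res <- removeOcularICA(rec, seed = 2)
  expect_equal(sum(res$report$removed), 0)
  short <- synthesizeSession(controlRow(), "eyes_open", seed = 1,
                             restDurationSec = 30)
  expect_error(removeOcularICA(short), ">= 60 s")
})

test_that("posterior alpha topography never matches the frontal ocular template", {
  topo <- effectSpec()@controlAlphaTopography
  expect_lt(abs(cor(topo, ocularTemplate(names(topo)))), 0.8)
})

test_that("artifact rules flag abs, slow and fast epochs as specified", {
  fs <- 250
  n <- fs * 20                          # 4 epochs of 5 s
  x <- matrix(0, 19, n, dimnames = list(tenTwentyLabels(), NULL))
  x["Cz", 100] <- 101                   # abs in epoch 1
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x["O1", (fs * 5 + 1):(fs * 10)] <- 60 * sin(2 * pi * 0.5 * t)  # slow, ep 2
  x["F3", (fs * 10 + 1):(fs * 15)] <- 40 * sin(2 * pi * 25 * t)  # fast, ep 3
  ep <- markArtifactEpochs(asRecording(x))
  expect_equal(unname(ep@flags[, "abs"]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(ep@flags[1, ]), c(TRUE, FALSE, FALSE))
  expect_true(ep@flags[2, "slow"] && !ep@flags[2, "abs"] && !ep@flags[2, "fast"])
  expect_true(ep@flags[3, "fast"] && !ep@flags[3, "abs"])
  expect_equal(unname(isClean(ep)), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("a 100.0 uV sample does not trip the strict threshold but 101 does", {
  x <- matrix(0, 19, 250 * 5, dimnames = list(tenTwentyLabels(), NULL))
  x["Cz", 10] <- 100
  expect_true(isClean(markArtifactEpochs(asRecording(x)))[1])
})

test_that("flagged epochs coincide exactly with inserted gross artifacts", {
  eff <- effectSpec(blinkAmplitude = 0)
  rec <- synthesizeSession(controlRow(), "eyes_open", effects = eff,
                           seed = 31, restDurationSec = 60,
                           artifactOnsetsSec = c(7, 31))
  ep <- markArtifactEpochs(rec)
  # 5 s epochs: artifacts starting at 7 s and 31 s hit epochs 2 and 7
  expect_equal(unname(which(!isClean(ep))), c(2L, 7L))
})

test_that("artifact flagging is idempotent and order-independent", {
  rec <- synthesizeSession(controlRow(), "eyes_open", seed = 33,
                           restDurationSec = 60,
                           artifactOnsetsSec = c(12))
  f1 <- markArtifactEpochs(rec)@flags
  f2 <- markArtifactEpochs(rec)@flags
  expect_identical(f1, f2)
  # flags computed on the reversed-channel recording agree
  rev <- rec
  rev@data <- rec@data[rev(rownames(rec@data)), ]
  expect_identical(unname(markArtifactEpochs(rev)@flags), unname(f1))
})

test_that("the eight-clean-epoch quality gate is enforced at the boundary", {
  mk <- function(nBad) {
    x <- matrix(0, 19, 250 * 50, dimnames = list(tenTwentyLabels(), NULL))
    for (k in seq_len(nBad)) x["Cz", (k - 1) * 1250 + 5] <- 150
    markArtifactEpochs(asRecording(x))
  }
  ok <- requireMinClean(mk(2))          # 8 clean of 10
  expect_equal(dim(ok@epochs)[1], 8)
  expect_error(requireMinClean(mk(3)), class = "qualityGateError")  # 7 clean
  empty <- markArtifactEpochs(asRecording(matrix(0, 19, 100,
    dimnames = list(tenTwentyLabels(), NULL))))
  expect_error(requireMinClean(empty), class = "qualityGateError")
})
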