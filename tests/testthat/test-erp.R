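# Trial labeling, event-locked averaging, component extraction, reaction
# times.

test_that("pair types map to GO/NOGO/Ignore", {
  ev <- data.frame(trial = 1:4, pairType = c("aa", "ap", "pp", "ph"),
                   cueOnsetMs = c(0, 4000, 8000, 12000),
                   secondOnsetMs = c(1000, 5000, 9000, 13000),
                   stimulusDurationMs = 100, responseTimeMs = NA)
  lab <- assignTrialConditions(ev)
  expect_equal(lab$condition, c("GO", "NOGO", "Ignore", "Ignore"))
  expect_equal(nrow(assignTrialConditions(generateTaskEvents(0))), 0)
  ev$pairType[2] <- "xx"
  expect_error(assignTrialConditions(ev), "unknown pair type")
  lab400 <- assignTrialConditions(generateTaskEvents(400, seed = 2))
  expect_equal(sum(table(lab400$condition)), 400)
})

test_that("noise-free generator with zero ERP amplitudes gives flat waveforms", {
  eff <- quietEffects(earlyAmplitude = 0, goP3Amplitude = 0)
  rec <- synthesizeSession(patientRow(amp = 0), "task", effects = eff,
                           seed = 1, nTrials = 12)
  erps <- epochAndAverage(rec)
  for (e in erps) expect_equal(max(abs(e@waveform)), 0)
})

test_that("NOGO average at Cz peaks in the late window for the generator", {
  rec <- synthesizeSession(controlRow(), "task", effects = quietEffects(),
                           seed = 2, nTrials = 24)
  erps <- epochAndAverage(rec)
  wf <- erps$NOGO@waveform["Cz", ]
  tm <- erps$NOGO@timeMs
  # window means over sliding 200 ms windows: maximal in 300-500 ms
  wins <- seq(0, 600, by = 100)
  wm <- vapply(wins, function(w0)
    mean(wf[tm >= w0 & tm <= w0 + 200]), numeric(1))
  expect_true(wins[which.max(wm)] %in% c(300, 400))
  # baseline mean is ~0 after correction
  expect_lt(abs(mean(wf[tm >= -200 & tm <= 0])), 1e-9)
})

test_that("baseline correction is idempotent and averaging is trivially stable", {
  rec <- synthesizeSession(controlRow(), "task", effects = quietEffects(),
                           seed = 3, nTrials = 16)
  erps <- epochAndAverage(rec)
  e1 <- erps[[1]]
  # identical trials (quiet model): average equals any single trial shape
  e2 <- epochAndAverage(rec)[[1]]
  expect_equal(e1@waveform, e2@waveform)
  # re-applying baseline subtraction changes nothing
  blSel <- e1@timeMs >= -200 & e1@timeMs <= 0
  again <- e1@waveform - rowMeans(e1@waveform[, blSel])
  expect_equal(again, e1@waveform, tolerance = 1e-12)
})

test_that("trials overlapping artifact segments are excluded", {
  eff <- quietEffects()
  # artifact at 10 s hits trials whose epochs cross the 10-15 s flagged epoch
  rec <- synthesizeSession(controlRow(), "task", effects = eff, seed = 4,
                           nTrials = 20, artifactOnsetsSec = 11)
  recNo <- synthesizeSession(controlRow(), "task", effects = eff, seed = 4,
                             nTrials = 20)
  nAll <- sum(vapply(epochAndAverage(recNo), function(e) e@nTrials,
                     integer(1)))
  nArt <- sum(vapply(epochAndAverage(rec), function(e) e@nTrials,
                     integer(1)))
  expect_lt(nArt, nAll)
  expect_equal(nAll, 20)
})

test_that("component extraction equals analytic window means", {
  # constant 5 uV waveform
  wf <- matrix(5, 19, 251, dimnames = list(tenTwentyLabels(), NULL))
  erp <- new("ERPSet", waveform = wf, timeMs = seq(-200, 800, by = 4),
             nTrials = 10L, baselineMs = c(-200, 0), subjectId = "S",
             condition = "NOGO")
  expect_equal(extractComponent(erp, "Cz", c(300, 500))$amplitude, 5)
  # triangular pulse of height 10 over 300-500 ms: window mean = height/2
  tm <- seq(-200, 800, by = 4)
  tri <- pmax(0, 10 * (1 - abs(tm - 400) / 100))
  erp@waveform["Cz", ] <- tri
  got <- extractComponent(erp, "Cz", c(300, 500))$amplitude
  expect_lt(abs(got - 5), 0.1)
  expect_error(extractComponent(erp, "Cz", c(700, 900)), "outside")
  expect_error(extractComponent(erp, "XX", c(300, 500)), "unknown channel")
})

test_that("ERP averaging reduces noise variance like 1/nTrials", {
  # white-noise-only task sessions; measure residual variance of the average
  eff <- effectSpec(noiseSdPink = 0, noiseSdWhite = 5, blinkAmplitude = 0,
                    alphaAmplitude = 0, lowAlphaAmplitude = 0,
                    earlyAmplitude = 0, goP3Amplitude = 0)
  res <- lapply(c(8, 16, 32, 64), function(k) {
    rec <- synthesizeSession(patientRow(amp = 0), "task", effects = eff,
                             seed = 77 + k, nTrials = k)
    erp <- epochAndAverage(rec)$Ignore
    c(n = erp@nTrials, v = mean(apply(erp@waveform, 1, var)))
  })
  n <- vapply(res, `[`, numeric(1), "n")
  v <- vapply(res, `[`, numeric(1), "v")
  fit <- lm(log(v) ~ log(n))
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.2)
})

test_that("grand-average ERP equals the mean of per-subject ERPs", {
  erps <- lapply(1:3, function(i) {
    rec <- synthesizeSession(controlRow(sprintf("C%02d", i)), "task",
                             seed = 60 + i, nTrials = 12)
    epochAndAverage(rec)$NOGO
  })
  g <- grandAverageERP(erps)
  manual <- (erps[[1]]@waveform + erps[[2]]@waveform + erps[[3]]@waveform) / 3
  expect_equal(g@waveform, manual)
  expect_equal(g@nTrials, 3L)
})

test_that("reaction times recover the simulated presses and bookkeeping", {
  rec <- synthesizeSession(controlRow(), "task", seed = 8, nTrials = 40)
  ev <- assignTrialConditions(rec@events)
  res <- reactionTimes(rec)
  nGo <- sum(ev$condition == "GO")
  expect_equal(nrow(res$rt) + res$misses, nGo)
  expect_equal(res$misses, 0)
  expect_equal(res$falseAlarms, 0)
  # recovered RTs match the generating values to one sample
  gen <- ev$responseTimeMs[match(res$rt$trial, ev$trial)]
  expect_lt(max(abs(res$rt$rtMs - gen)), 1000 / rec@samplingRate + 1e-9)
  # no button channel -> input error
  rest <- synthesizeSession(controlRow(), "eyes_open", seed = 8,
                            restDurationSec = 10)
  expect_error(reactionTimes(rest), "button channel")
})

test_that("presses on NOGO trials count as false alarms, not RTs", {
  rec <- synthesizeSession(controlRow(), "task", seed = 9, nTrials = 30)
  ev <- assignTrialConditions(rec@events)
  # forge a press inside the first NOGO trial window
  k <- which(ev$condition == "NOGO")[1]
  t0 <- round((ev$secondOnsetMs[k] + 300) * rec@samplingRate / 1000)
  rec@data["Button", t0:(t0 + 10)] <- 100
  res <- reactionTimes(rec, ev)
  expect_equal(res$falseAlarms, 1)
  expect_false(ev$trial[k] %in% res$rt$trial)
})
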