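# Shared fixtures, built in code. The expensive default-cohort pipeline run
# is computed once per test session and reused by the spectral, ERP and
# acceptance tests (sizes: 60 s resting sessions, 48-trial task sessions --
# >= 12 clean 5 s epochs per condition, ~12 NOGO trials per subject).

.fixtureEnv <- new.env(parent = emptyenv())

defaultStudyRun <- function() {
  if (is.null(.fixtureEnv$run)) {
    .fixtureEnv$run <- runStudy(seed = 1, restDurationSec = 60,
                                nTrials = 48, nPerm = 500)
  }
  .fixtureEnv$run
}

patientRow <- function(id = "P01", amp = 2) {
  data.frame(subjectId = id, group = "patient", trueNogoAmplitude = amp,
             behavioralScore = NA_real_)
}

controlRow <- function(id = "C01", amp = 5) {
  data.frame(subjectId = id, group = "control", trueNogoAmplitude = amp,
             behavioralScore = NA_real_)
}

# quiet forward model: no noise, no alpha, no blinks
quietEffects <- function(...) {
  effectSpec(noiseSdPink = 0, noiseSdWhite = 0, blinkAmplitude = 0,
             alphaAmplitude = 0, lowAlphaAmplitude = 0, ...)
}

# wrap a channels x samples matrix as a recording
asRecording <- function(x, fs = 250, condition = "eyes_open",
                        reference = "linked_ears", subjectId = "S01") {
  if (is.null(rownames(x)))
    rownames(x) <- tenTwentyLabels()[seq_len(nrow(x))]
  new("EEGRecording", data = x, samplingRate = fs, reference = reference,
      events = generateTaskEvents(0), subjectId = subjectId,
      condition = condition)
}

sineRecording <- function(freqHz, ampUV = 20, durSec = 20, fs = 250,
                          nCh = 3) {
  t <- seq(0, durSec - 1 / fs, by = 1 / fs)
  x <- matrix(rep(ampUV * sin(2 * pi * freqHz * t), each = nCh), nCh)
  asRecording(x, fs = fs)
}

# bind two subject x channel x bin arrays along the subject dimension
abind_local <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# exact signed-rank p by enumerating all sign assignments (no ties assumed
# handled by mid-ranks; valid for any d with zeros dropped)
exactSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ws <- vapply(0:(2^n - 1), function(k) {
    s <- as.integer(intToBits(k)[seq_len(n)])
    sum(r[s == 1])
  }, numeric(1))
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}
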