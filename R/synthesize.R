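## Seeded synthetic EEG cohorts for a cued GO/NOGO study: 1/f background,
## narrow-band alpha sources with fixed scalp gain maps, stimulus-locked ERP
## components, blinks, optional gross artifacts, and behavioral scores with
## controlled correlation to the late NOGO amplitude.

withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Cohort design of a simulated study
#'
#' Holds the study-design constants: group sizes (9 affected family members
#' against the 50 age-matched normative controls), the 19-channel 10-20
#' montage, 250 Hz sampling, 3-minute resting sessions and a 400-trial cued
#' GO/NOGO task.
#'
#' @slot nPatients,nControls group sizes (each >= 2).
#' @slot samplingRate Hz.
#' @slot channelLabels the 19 10-20 labels.
#' @slot restDurationSec seconds per resting condition (eyes open/closed).
#' @slot nTrials task trial count.
#' @export
setClass("CohortSpec",
  representation(
    nPatients = "integer", nControls = "integer",
    samplingRate = "numeric", channelLabels = "character",
    restDurationSec = "numeric", nTrials = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 2L || object@nControls < 2L)
    msg <- c(msg, "need >= 2 subjects per group")
  need <- c("F7", "T3", "T5", "Cz", "Pz", "O1", "O2")
  if (length(object@channelLabels) != 19L ||
      !all(need %in% object@channelLabels))
    msg <- c(msg, "channelLabels must be the 19-channel 10-20 set")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname CohortSpec-class
#' @param nPatients,nControls group sizes
#' @param samplingRate Hz
#' @param channelLabels montage labels
#' @param restDurationSec duration of each resting condition, seconds
#' @param nTrials task trials
#' @return a validated `CohortSpec`
#' @export
cohortSpec <- function(nPatients = 9, nControls = 50, samplingRate = 250,
                       channelLabels = tenTwentyLabels(),
                       restDurationSec = 180, nTrials = 400) {
  new("CohortSpec", nPatients = as.integer(nPatients),
      nControls = as.integer(nControls), samplingRate = samplingRate,
      channelLabels = channelLabels, restDurationSec = restDurationSec,
      nTrials = as.integer(nTrials))
}

.namedGain <- function(labels, high, default = 0.1) {
  g <- setNames(rep(default, length(labels)), labels)
  g[names(high)] <- unlist(high)
  g
}

.defaultLowAlphaTopo <- function(labels = tenTwentyLabels()) {
  .namedGain(labels, c(F7 = 1, T3 = 0.95, T5 = 0.8, F3 = 0.5, Fp1 = 0.45,
                       C3 = 0.4, P3 = 0.25, Fz = 0.25, F8 = 0.2, T4 = 0.2),
             default = 0.1)
}

.defaultControlAlphaTopo <- function(labels = tenTwentyLabels()) {
  .namedGain(labels, c(O2 = 1, T6 = 0.9, O1 = 0.85, P4 = 0.7, Pz = 0.6,
                       P3 = 0.55, T5 = 0.5, T4 = 0.3, C4 = 0.25),
             default = 0.15)
}

.nogoTopo <- function(labels) {
  .namedGain(labels, c(Cz = 1, Fz = 0.7, C3 = 0.6, C4 = 0.6, Pz = 0.5,
                       F3 = 0.4, F4 = 0.4))
}

.goP3Topo <- function(labels) {
  .namedGain(labels, c(Pz = 1, P3 = 0.7, P4 = 0.7, Cz = 0.5, O1 = 0.3,
                       O2 = 0.3))
}

.earlyTopo <- function(labels) {
  .namedGain(labels, c(O1 = 1, O2 = 1, T5 = 0.6, T6 = 0.6, Pz = 0.4))
}

#' Frontal ocular gain map
#'
#' Stereotyped blink/eye-movement scalp topography: maximal at Fp1/Fp2,
#' declining to zero posteriorly. Used both as the generator's blink mixing
#' map and as the matching template for ICA component selection.
#'
#' @param labels channel labels
#' @return named gain vector, max 1 at the frontopolar pair
#' @export
ocularTemplate <- function(labels = tenTwentyLabels()) {
  .namedGain(labels, c(Fp1 = 1, Fp2 = 1, F3 = 0.45, F4 = 0.45, Fz = 0.4,
                       F7 = 0.35, F8 = 0.35), default = 0)
}

#' Injected group effects of the simulated disease
#'
#' Parameters of the forward model: the patient-specific low-alpha source
#' (7.6 Hz, left temporofrontal), the normative posterior alpha (9.0 Hz,
#' right occipito-temporal maximum), ERP component amplitudes including the
#' suppressed late NOGO positivity in patients (40% of the control mean by
#' default), background-noise levels, blink and gross-artifact parameters,
#' and the target correlation between NOGO amplitude and the behavioral
#' memory score.
#'
#' @slot patientLowAlphaPeak,controlAlphaPeak Hz, within 1-30.
#' @slot lowAlphaTopography,controlAlphaTopography named non-negative gain
#'   maps over the montage.
#' @slot lowAlphaAmplitude uV, patient low-alpha source amplitude.
#' @slot alphaAmplitude uV, posterior alpha amplitude (eyes open); scaled by
#'   \code{eyesClosedGain} when eyes are closed and \code{taskGain} in task.
#' @slot eyesClosedGain,taskGain unitless condition gains.
#' @slot nogoAmplitudeControl,nogoAmplitudePatient uV, group means of the
#'   late NOGO positivity at the vertex; \code{nogoSdControl},
#'   \code{nogoSdPatient} their between-subject SDs.
#' @slot goP3Amplitude uV, GO P3 at Pz (identical between groups).
#' @slot earlyAmplitude uV, early occipital sensory response.
#' @slot behavioralTrueR population correlation between NOGO amplitude and
#'   behavioral score, in [-1, 1].
#' @slot noiseSdPink,noiseSdWhite uV, background 1/f and white noise SDs.
#' @slot blinkAmplitude uV at the frontopolar sites; \code{blinkRatePerMin}
#'   mean blink rate.
#' @slot artifactRatePerMin rate of inserted gross-amplitude segments
#'   (default 0); \code{artifactAmplitude} their uV scale.
#' @export
setClass("EffectSpec",
  representation(
    patientLowAlphaPeak = "numeric", controlAlphaPeak = "numeric",
    lowAlphaTopography = "numeric", controlAlphaTopography = "numeric",
    lowAlphaAmplitude = "numeric", alphaAmplitude = "numeric",
    eyesClosedGain = "numeric", taskGain = "numeric",
    nogoAmplitudeControl = "numeric", nogoAmplitudePatient = "numeric",
    nogoSdControl = "numeric", nogoSdPatient = "numeric",
    goP3Amplitude = "numeric", earlyAmplitude = "numeric",
    behavioralTrueR = "numeric",
    noiseSdPink = "numeric", noiseSdWhite = "numeric",
    blinkAmplitude = "numeric", blinkRatePerMin = "numeric",
    artifactRatePerMin = "numeric", artifactAmplitude = "numeric"
  )
)

setValidity("EffectSpec", function(object) {
  msg <- character()
  pk <- c(object@patientLowAlphaPeak, object@controlAlphaPeak)
  if (any(pk < 1 | pk > 30)) msg <- c(msg, "peaks must be within 1-30 Hz")
  if (any(object@lowAlphaTopography < 0) ||
      any(object@controlAlphaTopography < 0))
    msg <- c(msg, "gain maps must be non-negative")
  if (abs(object@behavioralTrueR) > 1)
    msg <- c(msg, "|behavioralTrueR| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname EffectSpec-class
#' @param patientLowAlphaPeak,controlAlphaPeak,lowAlphaTopography,controlAlphaTopography,lowAlphaAmplitude,alphaAmplitude,eyesClosedGain,taskGain,nogoAmplitudeControl,nogoAmplitudePatient,nogoSdControl,nogoSdPatient,goP3Amplitude,earlyAmplitude,behavioralTrueR,noiseSdPink,noiseSdWhite,blinkAmplitude,blinkRatePerMin,artifactRatePerMin,artifactAmplitude see slot documentation
#' @return a validated `EffectSpec`
#' @export
effectSpec <- function(patientLowAlphaPeak = 7.6, controlAlphaPeak = 9.0,
                       lowAlphaTopography = .defaultLowAlphaTopo(),
                       controlAlphaTopography = .defaultControlAlphaTopo(),
                       lowAlphaAmplitude = 12, alphaAmplitude = 8,
                       eyesClosedGain = 2.5, taskGain = 0.8,
                       nogoAmplitudeControl = 5, nogoAmplitudePatient = 2,
                       nogoSdControl = 1, nogoSdPatient = 0.8,
                       goP3Amplitude = 8, earlyAmplitude = 6,
                       behavioralTrueR = 0.78,
                       noiseSdPink = 8, noiseSdWhite = 2,
                       blinkAmplitude = 70, blinkRatePerMin = 8,
                       artifactRatePerMin = 0, artifactAmplitude = 300) {
  new("EffectSpec",
      patientLowAlphaPeak = patientLowAlphaPeak,
      controlAlphaPeak = controlAlphaPeak,
      lowAlphaTopography = lowAlphaTopography,
      controlAlphaTopography = controlAlphaTopography,
      lowAlphaAmplitude = lowAlphaAmplitude, alphaAmplitude = alphaAmplitude,
      eyesClosedGain = eyesClosedGain, taskGain = taskGain,
      nogoAmplitudeControl = nogoAmplitudeControl,
      nogoAmplitudePatient = nogoAmplitudePatient,
      nogoSdControl = nogoSdControl, nogoSdPatient = nogoSdPatient,
      goP3Amplitude = goP3Amplitude, earlyAmplitude = earlyAmplitude,
      behavioralTrueR = behavioralTrueR,
      noiseSdPink = noiseSdPink, noiseSdWhite = noiseSdWhite,
      blinkAmplitude = blinkAmplitude, blinkRatePerMin = blinkRatePerMin,
      artifactRatePerMin = artifactRatePerMin,
      artifactAmplitude = artifactAmplitude)
}

#' Generate the cued GO/NOGO trial sequence
#'
#' Trials are pairs of visual stimuli (animals `a`, plants `p`, humans `h`)
#' presented as `aa`, `ap`, `pp` or `ph` with equal probability in random
#' order. Within a pair the cue-to-second interval is exactly 1000 ms, the
#' second stimulus of one pair and the cue of the next are 3000 ms apart,
#' and every stimulus lasts 100 ms. `aa` trials (GO) carry a simulated
#' button-press reaction time.
#'
#' @param nTrials number of trials (>= 0); the task uses 400.
#' @param seed integer seed.
#' @param meanRtMs,sdRtMs reaction-time distribution for compliant presses.
#' @return data.frame with columns `trial`, `pairType`, `cueOnsetMs`,
#'   `secondOnsetMs`, `stimulusDurationMs`, `responseTimeMs` (NA on non-GO
#'   trials).
#' @examples
#' ev <- generateTaskEvents(400, seed = 1)
#' stopifnot(all(ev$secondOnsetMs - ev$cueOnsetMs == 1000))
#' @export
generateTaskEvents <- function(nTrials, seed = 1, meanRtMs = 380,
                               sdRtMs = 50) {
  if (length(nTrials) != 1L || is.na(nTrials) || nTrials < 0)
    stop("nTrials must be a single non-negative number")
  nTrials <- as.integer(nTrials)
  types <- c("aa", "ap", "pp", "ph")
  if (nTrials == 0L)
    return(data.frame(trial = integer(), pairType = character(),
                      cueOnsetMs = numeric(), secondOnsetMs = numeric(),
                      stimulusDurationMs = numeric(),
                      responseTimeMs = numeric()))
  withSeed(seed, {
    pairType <- sample(types, nTrials, replace = TRUE)
    cueOnsetMs <- 2000 + (seq_len(nTrials) - 1) * 4000
    rt <- ifelse(pairType == "aa",
                 pmin(pmax(rnorm(nTrials, meanRtMs, sdRtMs), 200), 900),
                 NA_real_)
    data.frame(trial = seq_len(nTrials), pairType = pairType,
               cueOnsetMs = cueOnsetMs, secondOnsetMs = cueOnsetMs + 1000,
               stimulusDurationMs = 100, responseTimeMs = rt)
  })
}

#' Build the subject table of a simulated cohort
#'
#' Draws each subject's latent late-NOGO amplitude from their group's
#' distribution (patients suppressed relative to controls) and assigns
#' behavioral delayed-recall T-scores to patients with the configured
#' population correlation (see [generateBehavioralScores()]).
#'
#' @param cohort a [CohortSpec-class]
#' @param effects an [EffectSpec-class]
#' @param seed integer seed
#' @param scores also draw behavioral scores for patients?
#' @return data.frame with `subjectId`, `group`, `trueNogoAmplitude`,
#'   `behavioralScore` (NA for controls)
#' @export
simulateCohort <- function(cohort = cohortSpec(), effects = effectSpec(),
                           seed = 1, scores = TRUE) {
  subjects <- withSeed(seed, {
    n <- cohort@nPatients + cohort@nControls
    group <- rep(c("patient", "control"),
                 c(cohort@nPatients, cohort@nControls))
    mu <- ifelse(group == "patient", effects@nogoAmplitudePatient,
                 effects@nogoAmplitudeControl)
    s <- ifelse(group == "patient", effects@nogoSdPatient,
                effects@nogoSdControl)
    amp <- pmax(rnorm(n, mu, s), 0.2)
    data.frame(
      subjectId = sprintf("%s%02d", ifelse(group == "patient", "P", "C"),
                          c(seq_len(cohort@nPatients),
                            seq_len(cohort@nControls))),
      group = group, trueNogoAmplitude = amp,
      behavioralScore = NA_real_)
  })
  if (scores)
    subjects <- generateBehavioralScores(subjects, effects@behavioralTrueR,
                                         seed = seed + 7919L)
  subjects
}

#' Assign behavioral scores correlated with the NOGO amplitude
#'
#' Patient delayed-recall T-scores are built by the bivariate-normal
#' construction `z_y = r z_x + sqrt(1-r^2) e`, which makes the population
#' correlation with `trueNogoAmplitude` exactly `trueR`. Scores are centered
#' on the patient-group mean of 29.6 with SD 11.5 (severely impaired on the
#' T-score scale where 50 is the population mean). Controls keep NA: the
#' normative database provides no behavioral scores, so correlation analyses
#' are patient-only.
#'
#' @param subjects subject table from [simulateCohort()]
#' @param trueR target population correlation, |trueR| <= 1
#' @param seed integer seed
#' @param scoreMean,scoreSd patient score distribution
#' @param clip clip scores into the observed 15-50 range? (default FALSE;
#'   clipping biases correlation recovery)
#' @return the subject table with patient `behavioralScore` filled in
#' @export
generateBehavioralScores <- function(subjects, trueR = 0.78, seed = 1,
                                     scoreMean = 29.6, scoreSd = 11.5,
                                     clip = FALSE) {
  if (abs(trueR) > 1) stop("|trueR| must be <= 1")
  ip <- which(subjects$group == "patient")
  if (length(ip) < 2L) stop("need >= 2 patient subjects")
  x <- subjects$trueNogoAmplitude[ip]
  zx <- (x - mean(x)) / sd(x)
  y <- withSeed(seed, {
    e <- rnorm(length(ip))
    trueR * zx + sqrt(1 - trueR^2) * e
  })
  score <- scoreMean + scoreSd * y
  if (clip) score <- pmin(pmax(score, 15), 50)
  subjects$behavioralScore[ip] <- score
  subjects
}

## 1/f^1 ("pink") noise of sd `sdTarget`, built in the frequency domain.
.pinkNoise <- function(n, fs, sdTarget) {
  if (sdTarget <= 0) return(numeric(n))
  white <- rnorm(n)
  sp <- fft(white)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                   # two-sided axis
  h <- 1 / sqrt(pmax(f, 0.1))            # flat below 0.1 Hz
  h[1L] <- 0                             # zero mean
  x <- Re(fft(sp * h, inverse = TRUE)) / n
  x * sdTarget / sd(x)
}

## slow amplitude-modulated sinusoid source, mean envelope 1
.alphaSource <- function(n, fs, freq) {
  t <- (seq_len(n) - 1) / fs
  env <- 1 + 0.5 * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi))
  env * sin(2 * pi * freq * t + runif(1, 0, 2 * pi))
}

## gaussian bump, unit peak, centered muMs after onsetMs
.addBump <- function(sig, topo, fs, onsetMs, muMs, sdMs, amp) {
  n <- ncol(sig)
  i0 <- round((onsetMs + muMs - 4 * sdMs) * fs / 1000)
  i1 <- round((onsetMs + muMs + 4 * sdMs) * fs / 1000)
  idx <- max(1L, i0):min(n, i1)
  if (!length(idx) || idx[1L] > n) return(sig)
  tMs <- (idx - 1) * 1000 / fs
  bump <- amp * exp(-((tMs - onsetMs - muMs)^2) / (2 * sdMs^2))
  sig[, idx] <- sig[, idx] + outer(topo, bump)
  sig
}

.blinkWave <- function(fs) {
  ## biphasic ~400 ms: 250 ms positive lobe, 150 ms negative undershoot
  t1 <- seq(0, 0.25, by = 1 / fs)
  t2 <- seq(1 / fs, 0.15, by = 1 / fs)
  c(sin(pi * t1 / 0.25), -0.4 * sin(pi * t2 / 0.15))
}

#' Synthesize one EEG session
#'
#' Forward model for a single subject and condition: per-channel 1/f plus
#' white background noise, a posterior alpha source at the normative peak
#' frequency for every subject (larger with eyes closed), an additional
#' left-temporofrontal low-alpha source for patients, blinks mixed through
#' the frontal ocular map, and -- for the task condition -- stimulus-locked
#' ERP components (early occipital response to every stimulus, GO P3 at Pz
#' on `aa` second stimuli, a late central positivity at Cz on `ap` second
#' stimuli scaled by the subject's latent NOGO amplitude) plus a button
#' channel registering GO presses. Topographies are direct per-channel gain
#' maps; no volume-conduction model is attempted.
#'
#' @param subject one row of the [simulateCohort()] table
#' @param condition `"eyes_open"`, `"eyes_closed"` or `"task"`
#' @param cohort a [CohortSpec-class]
#' @param effects an [EffectSpec-class]
#' @param seed integer seed
#' @param nTrials task trial-count override (default `cohort@nTrials`)
#' @param restDurationSec resting-duration override, seconds
#' @param artifactOnsetsSec explicit start times (s) of inserted 1-s
#'   gross-amplitude segments; overrides `effects@artifactRatePerMin`
#' @return an [EEGRecording-class]; task recordings carry the event table
#'   and a `"Button"` channel
#' @export
synthesizeSession <- function(subject, condition, cohort = cohortSpec(),
                              effects = effectSpec(), seed = 1,
                              nTrials = NULL, restDurationSec = NULL,
                              artifactOnsetsSec = NULL) {
  if (!condition %in% c("eyes_open", "eyes_closed", "task"))
    stop("unknown condition: ", condition)
  fs <- cohort@samplingRate
  labels <- cohort@channelLabels
  isPatient <- identical(subject$group, "patient")

  if (condition == "task") {
    nT <- if (is.null(nTrials)) cohort@nTrials else as.integer(nTrials)
    events <- generateTaskEvents(nT, seed = seed + 13L)
    durSec <- if (nT > 0) (max(events$secondOnsetMs) + 2000) / 1000 else 10
  } else {
    events <- generateTaskEvents(0)
    durSec <- if (is.null(restDurationSec)) cohort@restDurationSec
              else restDurationSec
  }
  n <- round(durSec * fs)

  sig <- withSeed(seed, {
    sig <- matrix(0, length(labels), n, dimnames = list(labels, NULL))
    for (i in seq_along(labels))
      sig[i, ] <- .pinkNoise(n, fs, effects@noiseSdPink) +
        (if (effects@noiseSdWhite > 0) rnorm(n, 0, effects@noiseSdWhite)
         else 0)

    condGain <- switch(condition, eyes_open = 1,
                       eyes_closed = effects@eyesClosedGain,
                       task = effects@taskGain)
    if (effects@alphaAmplitude > 0) {
      src <- .alphaSource(n, fs, effects@controlAlphaPeak)
      topo <- effects@controlAlphaTopography[labels]
      sig <- sig + outer(topo, src) * (effects@alphaAmplitude * condGain)
    }
    if (isPatient && effects@lowAlphaAmplitude > 0) {
      src <- .alphaSource(n, fs, effects@patientLowAlphaPeak)
      topo <- effects@lowAlphaTopography[labels]
      sig <- sig + outer(topo, src) * effects@lowAlphaAmplitude
    }

    if (condition == "task" && nrow(events) > 0) {
      eTopo <- .earlyTopo(labels)
      if (effects@earlyAmplitude > 0) {
        for (k in seq_len(nrow(events))) {
          sig <- .addBump(sig, eTopo, fs, events$cueOnsetMs[k], 140, 25,
                          effects@earlyAmplitude)
          sig <- .addBump(sig, eTopo, fs, events$secondOnsetMs[k], 140, 25,
                          effects@earlyAmplitude)
        }
      }
      gTopo <- .goP3Topo(labels)
      nTopo <- .nogoTopo(labels)
      for (k in seq_len(nrow(events))) {
        if (events$pairType[k] == "aa" && effects@goP3Amplitude > 0)
          sig <- .addBump(sig, gTopo, fs, events$secondOnsetMs[k], 330, 60,
                          effects@goP3Amplitude)
        if (events$pairType[k] == "ap" && subject$trueNogoAmplitude > 0)
          sig <- .addBump(sig, nTopo, fs, events$secondOnsetMs[k], 400, 70,
                          subject$trueNogoAmplitude)
      }
    }

    if (effects@blinkAmplitude > 0 && effects@blinkRatePerMin > 0) {
      wave <- .blinkWave(fs)
      topo <- ocularTemplate(labels)
      nBlink <- rbinom(1, n, effects@blinkRatePerMin / 60 / fs)
      starts <- sort(sample.int(max(1L, n - length(wave)), nBlink))
      for (s in starts) {
        idx <- s:(s + length(wave) - 1L)
        sig[, idx] <- sig[, idx] + outer(topo, wave) * effects@blinkAmplitude
      }
    }

    onsets <- artifactOnsetsSec
    if (is.null(onsets) && effects@artifactRatePerMin > 0) {
      nArt <- rbinom(1, ceiling(durSec), effects@artifactRatePerMin / 60)
      onsets <- sort(runif(nArt, 0, max(durSec - 1, 0)))
    }
    for (s in onsets %||% numeric()) {
      idx <- (round(s * fs) + 1L):min(n, round((s + 1) * fs))
      tLoc <- (seq_along(idx) - 1) / fs
      burst <- effects@artifactAmplitude * sin(2 * pi * 4 * tLoc) *
        sin(pi * tLoc / max(tLoc[length(tLoc)], 1e-9))
      sig[, idx] <- sig[, idx] + matrix(burst, nrow(sig), length(idx),
                                        byrow = TRUE)
    }
    sig
  })

  if (condition == "task") {
    button <- numeric(n)
    press <- events[events$pairType == "aa" & !is.na(events$responseTimeMs), ]
    for (k in seq_len(nrow(press))) {
      t0 <- round((press$secondOnsetMs[k] + press$responseTimeMs[k]) *
                    fs / 1000) + 1L
      idx <- t0:min(n, t0 + round(0.05 * fs))
      button[idx] <- 100
    }
    sig <- rbind(sig, Button = button)
  }

  new("EEGRecording", data = sig, samplingRate = fs,
      reference = "linked_ears", events = events,
      subjectId = as.character(subject$subjectId), condition = condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
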