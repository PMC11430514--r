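## Signal-conditioning chain: zero-phase Butterworth filtering, 45-55 Hz
## notch, weighted-average re-referencing, seeded FastICA ocular correction,
## and the three-rule amplitude artifact flagging with its >= 8 clean-epoch
## quality gate.

.applyFilter <- function(x, filt) {
  ## x: channels x samples; forward-backward (zero-phase) application
  out <- t(apply(x, 1L, function(ch) signal::filtfilt(filt, ch)))
  dimnames(out) <- dimnames(x)
  out
}

.eegRows <- function(rec) setdiff(rownames(rec@data), "Button")

.replaceData <- function(rec, newEEG, reference = rec@reference) {
  d <- rec@data
  d[rownames(newEEG), ] <- newEEG
  initialize(rec, data = d, reference = reference)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth applied forward and backward per channel, so ERP
#' latencies are not shifted. The button channel, events and metadata pass
#' through untouched.
#'
#' @param rec an [EEGRecording-class]
#' @param low,high band edges in Hz, `0 < low < high < samplingRate/2`
#' @param order filter order (default 4)
#' @return the filtered [EEGRecording-class]
#' @export
bandpassFilter <- function(rec, low = 0.53, high = 30, order = 4) {
  fs <- rec@samplingRate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band: need 0 < low < high < samplingRate/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  ch <- .eegRows(rec)
  .replaceData(rec, .applyFilter(rec@data[ch, , drop = FALSE], bf))
}

#' Zero-phase notch (band-stop) filter for mains artifacts
#'
#' Default 45-55 Hz band-stop removing 50 Hz line noise.
#'
#' @param rec an [EEGRecording-class]
#' @param band two-element stop band in Hz, within Nyquist
#' @param order filter order (default 4)
#' @return the filtered [EEGRecording-class]
#' @export
notchFilter <- function(rec, band = c(45, 55), order = 4) {
  fs <- rec@samplingRate
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L] ||
      band[2L] >= fs / 2)
    stop("invalid notch band")
  bf <- signal::butter(order, band / (fs / 2), type = "stop")
  ch <- .eegRows(rec)
  .replaceData(rec, .applyFilter(rec@data[ch, , drop = FALSE], bf))
}

#' Re-reference to the weighted average montage
#'
#' Subtracts a weighted mean over the EEG channels from every channel at
#' every sample. With the default uniform weights this is the plain average
#' reference (per-sample channel sum exactly zero); a custom non-negative
#' weight vector can be supplied since published weighted-average schemes
#' differ.
#'
#' @param rec an [EEGRecording-class], reference must still be `linked_ears`
#' @param weights optional named non-negative weights over the EEG channels
#' @return the re-referenced [EEGRecording-class]
#' @export
rerefWeightedAverage <- function(rec, weights = NULL) {
  if (rec@reference != "linked_ears")
    stop("recording is already re-referenced (", rec@reference, ")")
  ch <- .eegRows(rec)
  if (is.null(weights)) weights <- setNames(rep(1, length(ch)), ch)
  if (!all(ch %in% names(weights)) || any(weights < 0))
    stop("weights must be non-negative and cover all EEG channels")
  w <- weights[ch] / sum(weights[ch])
  x <- rec@data[ch, , drop = FALSE]
  ref <- drop(crossprod(x, w))           # weighted mean per sample
  .replaceData(rec, sweep(x, 2L, ref), reference = "weighted_average")
}

## FastICA with logcosh contrast and symmetric decorrelation. Deterministic
## for a fixed seed. x: channels x samples. Returns unmixing (comp x chan),
## mixing (chan x comp), sources and the row means removed.
fastICA <- function(x, nComp = nrow(x), seed = 1, maxit = 100, tol = 1e-5) {
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(nComp)
  K <- diag(1 / sqrt(pmax(eg$values[keep], 1e-12)), nComp) %*%
    t(eg$vectors[, keep, drop = FALSE])
  z <- K %*% xc
  W <- withSeed(seed, matrix(rnorm(nComp * nComp), nComp))
  sym <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nComp) %*%
      t(e$vectors) %*% W
  }
  W <- sym(W)
  for (it in seq_len(maxit)) {
    wOld <- W
    u <- W %*% z
    g <- tanh(u)
    gp <- 1 - g^2
    W <- (g %*% t(z)) / n - diag(rowMeans(gp), nComp) %*% W
    W <- sym(W)
    if (max(abs(1 - abs(diag(W %*% t(wOld))))) < tol) break
  }
  unmix <- W %*% K                        # comp x chan
  sv <- svd(unmix)
  mix <- sv$v %*% diag(1 / sv$d, length(sv$d)) %*% t(sv$u)  # chan x comp
  list(unmixing = unmix, mixing = mix, sources = unmix %*% xc,
       center = mu, iterations = it)
}

#' Remove ocular ICA components
#'
#' Fits FastICA on a 2-30 Hz band-passed copy of the recording (narrowing
#' the band reduces the ICA overlearning problem on short recordings),
#' correlates every component topography with the frontal ocular template
#' ([ocularTemplate()]), zeroes components whose absolute correlation meets
#' the threshold, and reconstructs the original-band signal without them.
#'
#' @param rec an [EEGRecording-class] with at least 60 s of data
#' @param prefilterBand band (Hz) for the ICA fitting copy
#' @param threshold minimum |Pearson correlation| with the ocular template
#'   for a component to be removed (default 0.8)
#' @param seed integer seed for the ICA initialisation
#' @param nComp number of components; the default retains the 15 largest
#'   principal components before rotation, which suppresses overlearned
#'   noise components on short recordings
#' @param fitSeconds if non-NULL, fit the unmixing on only the first
#'   `fitSeconds` seconds of the (filtered) data; the whole recording is
#'   still corrected
#' @return list with `recording` (corrected [EEGRecording-class]) and
#'   `report` (data.frame: component, templateCorrelation, removed)
#' @export
removeOcularICA <- function(rec, prefilterBand = c(2, 30), threshold = 0.8,
                            seed = 1, nComp = NULL, fitSeconds = NULL) {
  ch <- .eegRows(rec)
  if (ncol(rec@data) / rec@samplingRate < 60)
    stop("need >= 60 s of data for a stable ICA unmixing")
  nComp <- nComp %||% min(length(ch), 15L)
  fitRec <- rec
  if (!is.null(fitSeconds)) {
    nFit <- min(ncol(rec@data), round(fitSeconds * rec@samplingRate))
    if (nFit / rec@samplingRate < 60) nFit <- ncol(rec@data)
    fitRec <- initialize(rec, data = rec@data[, seq_len(nFit), drop = FALSE])
  }
  fitRec <- bandpassFilter(fitRec, prefilterBand[1L], prefilterBand[2L])
  fit <- fastICA(fitRec@data[ch, , drop = FALSE], nComp = nComp, seed = seed)
  tmpl <- ocularTemplate(ch)
  rho <- apply(fit$mixing, 2L, function(a) cor(a, tmpl))
  removed <- which(abs(rho) >= threshold)
  report <- data.frame(component = seq_len(nComp),
                       templateCorrelation = rho,
                       removed = seq_len(nComp) %in% removed)
  out <- rec
  if (length(removed)) {
    x <- rec@data[ch, , drop = FALSE]
    xc <- x - rowMeans(x)
    contrib <- fit$mixing[, removed, drop = FALSE] %*%
      (fit$unmixing[removed, , drop = FALSE] %*% xc)
    out <- .replaceData(rec, x - contrib)
  }
  list(recording = out, report = report)
}

#' Amplitude artifact-rejection rules
#'
#' The three exclusion thresholds applied to consecutive epochs: (a) 100 uV
#' on the unfiltered signal, (b) 50 uV on the 0-1 Hz (slow-wave) band,
#' (c) 35 uV on the 20-35 Hz (fast-wave) band; and the minimum number of
#' artifact-free epochs (8, about 40 s at the 5 s epoch length) required
#' before a subject's condition enters the analysis.
#'
#' @slot absThreshold,slowThreshold,fastThreshold uV, all > 0.
#' @slot epochLengthSec epoch length in seconds.
#' @slot minCleanEpochs required clean-epoch count (>= 1).
#' @export
setClass("ArtifactRules",
  representation(absThreshold = "numeric", slowThreshold = "numeric",
                 fastThreshold = "numeric", epochLengthSec = "numeric",
                 minCleanEpochs = "integer"))

setValidity("ArtifactRules", function(object) {
  msg <- character()
  if (any(c(object@absThreshold, object@slowThreshold, object@fastThreshold,
            object@epochLengthSec) <= 0))
    msg <- c(msg, "thresholds and epoch length must be > 0")
  if (object@minCleanEpochs < 1L) msg <- c(msg, "minCleanEpochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ArtifactRules-class
#' @param absThreshold,slowThreshold,fastThreshold,epochLengthSec,minCleanEpochs
#'   see slot documentation
#' @return a validated `ArtifactRules`
#' @export
artifactRules <- function(absThreshold = 100, slowThreshold = 50,
                          fastThreshold = 35, epochLengthSec = 5,
                          minCleanEpochs = 8) {
  new("ArtifactRules", absThreshold = absThreshold,
      slowThreshold = slowThreshold, fastThreshold = fastThreshold,
      epochLengthSec = epochLengthSec,
      minCleanEpochs = as.integer(minCleanEpochs))
}

#' Cut a recording into epochs and flag amplitude artifacts
#'
#' The recording is cut into consecutive non-overlapping epochs. An epoch is
#' flagged `abs` when any EEG channel of the unfiltered signal strictly
#' exceeds the absolute threshold, `slow` when the 0-1 Hz low-passed signal
#' exceeds the slow threshold, and `fast` when the 20-35 Hz band-passed
#' signal exceeds the fast threshold; the flags are unioned and an epoch is
#' clean only if none fired. Flagging is total: no input errors.
#'
#' @param rec an [EEGRecording-class]
#' @param rules an [ArtifactRules-class]
#' @return an [EpochSet-class]
#' @export
markArtifactEpochs <- function(rec, rules = artifactRules()) {
  fs <- rec@samplingRate
  ch <- .eegRows(rec)
  x <- rec@data[ch, , drop = FALSE]
  epochLen <- round(rules@epochLengthSec * fs)
  nEpoch <- floor(ncol(x) / epochLen)

  lpf <- signal::butter(2, 1 / (fs / 2), type = "low")
  bpf <- signal::butter(4, c(20, 35) / (fs / 2), type = "pass")
  xSlow <- .applyFilter(x, lpf)
  xFast <- .applyFilter(x, bpf)

  epochs <- array(0, c(max(nEpoch, 0L), length(ch), epochLen),
                  dimnames = list(NULL, ch, NULL))
  flags <- matrix(FALSE, max(nEpoch, 0L), 3L,
                  dimnames = list(NULL, c("abs", "slow", "fast")))
  onset <- integer(max(nEpoch, 0L))
  for (e in seq_len(nEpoch)) {
    idx <- ((e - 1L) * epochLen + 1L):(e * epochLen)
    onset[e] <- idx[1L]
    epochs[e, , ] <- x[, idx]
    flags[e, "abs"] <- any(abs(x[, idx]) > rules@absThreshold)
    flags[e, "slow"] <- any(abs(xSlow[, idx]) > rules@slowThreshold)
    flags[e, "fast"] <- any(abs(xFast[, idx]) > rules@fastThreshold)
  }
  new("EpochSet", epochs = epochs, flags = flags,
      labels = rep(rec@condition, max(nEpoch, 0L)), onsetSample = onset,
      timeMs = (seq_len(epochLen) - 1) * 1000 / fs, samplingRate = fs,
      subjectId = rec@subjectId, condition = rec@condition)
}

#' Enforce the minimum clean-epoch quality gate
#'
#' Keeps only artifact-free epochs and errors (with a condition of class
#' `qualityGateError` naming subject and condition) when fewer than
#' `rules@minCleanEpochs` survive.
#'
#' @param epochs an [EpochSet-class]
#' @param rules an [ArtifactRules-class]
#' @return the [EpochSet-class] restricted to clean epochs
#' @export
requireMinClean <- function(epochs, rules = artifactRules()) {
  keep <- which(isClean(epochs))
  if (length(keep) < rules@minCleanEpochs)
    stop(errorCondition(
      sprintf("subject %s, condition %s: only %d artifact-free epochs (need %d)",
              epochs@subjectId, epochs@condition, length(keep),
              rules@minCleanEpochs),
      class = c("qualityGateError", "error", "condition")))
  initialize(epochs,
             epochs = epochs@epochs[keep, , , drop = FALSE],
             flags = epochs@flags[keep, , drop = FALSE],
             labels = epochs@labels[keep],
             onsetSample = epochs@onsetSample[keep])
}
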