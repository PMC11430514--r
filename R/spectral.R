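## Welch spectra on clean 5 s epochs, relative amplitudes, group grand
## averages, difference spectra and scalp maps at a chosen frequency.

#' Welch power spectrum of the clean epochs
#'
#' Per-channel Welch estimate: each clean epoch is demeaned, Hann-tapered
#' and Fourier-transformed; one-sided periodograms are averaged over epochs.
#' Power is normalized so that its sum over all bins equals the signal
#' variance (Parseval), in uV^2 per bin; amplitude is its square root and
#' relative amplitude is amplitude in percent of the channel's summed
#' amplitude over the analysis band. The frequency resolution is the
#' reciprocal of the epoch length (0.2 Hz for 5 s epochs).
#'
#' @param epochs an [EpochSet-class]; only clean epochs are used
#' @param band analysis band in Hz (default 0-30)
#' @return a [SpectrumSet-class]
#' @export
computeSpectrum <- function(epochs, band = c(0, 30)) {
  keep <- which(isClean(epochs))
  if (!length(keep))
    stop(errorCondition(
      sprintf("subject %s, condition %s: no clean epochs",
              epochs@subjectId, epochs@condition),
      class = c("qualityGateError", "error", "condition")))
  fs <- epochs@samplingRate
  n <- dim(epochs@epochs)[3L]
  nCh <- dim(epochs@epochs)[2L]
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # periodic Hann
  wNorm <- sum(w^2)
  nHalf <- floor(n / 2)
  freqAll <- (0:nHalf) * fs / n
  scale <- 2 / (fs * wNorm)               # one-sided PSD scaling
  pw <- matrix(0, nCh, nHalf + 1L)
  for (e in keep) {
    x <- epochs@epochs[e, , , drop = TRUE]
    if (nCh == 1L) x <- matrix(x, 1L)
    x <- x - rowMeans(x)
    xw <- sweep(x, 2L, w, `*`)
    sp <- t(apply(xw, 1L, function(v) Mod(fft(v))[1:(nHalf + 1L)]^2))
    sp <- sp * scale
    sp[, 1L] <- sp[, 1L] / 2              # DC not doubled
    if (n %% 2 == 0) sp[, nHalf + 1L] <- sp[, nHalf + 1L] / 2
    pw <- pw + sp
  }
  pw <- pw / length(keep)
  pw <- pw * fs / n                       # PSD -> power per bin (uV^2)

  sel <- which(freqAll >= band[1L] & freqAll <= band[2L])
  pw <- pw[, sel, drop = FALSE]
  rownames(pw) <- dimnames(epochs@epochs)[[2L]]
  amp <- sqrt(pw)
  tot <- rowSums(amp)
  rel <- 100 * amp / tot
  rel[tot == 0, ] <- 100 / ncol(amp)      # flat for an all-zero channel
  new("SpectrumSet", freq = freqAll[sel], power = pw, amplitude = amp,
      relAmplitude = rel, nEpochs = length(keep),
      subjectId = epochs@subjectId, condition = epochs@condition)
}

#' Collect per-subject spectra of one group
#'
#' @param spectra list of [SpectrumSet-class] with a common frequency axis
#'   and condition
#' @return a [GroupSpectra-class] retaining the per-subject sample arrays
#' @export
groupSpectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  freq <- spectra[[1L]]@freq
  for (s in spectra)
    if (!isTRUE(all.equal(s@freq, freq)))
      stop("frequency axes differ across subjects")
  labels <- rownames(spectra[[1L]]@power)
  pow <- array(0, c(length(spectra), length(labels), length(freq)),
               dimnames = list(NULL, labels, NULL))
  rel <- pow
  for (i in seq_along(spectra)) {
    pow[i, , ] <- spectra[[i]]@power
    rel[i, , ] <- spectra[[i]]@relAmplitude
  }
  new("GroupSpectra", freq = freq, power = pow, relAmplitude = rel,
      subjects = vapply(spectra, function(s) s@subjectId, character(1)),
      condition = spectra[[1L]]@condition)
}

#' Patient-minus-control difference spectra
#'
#' Grand-average difference curves per channel, plus the retained
#' per-subject samples that the cluster permutation test consumes.
#'
#' @param patients,controls [GroupSpectra-class] objects on the same
#'   frequency axis
#' @param measure `"relAmplitude"` (default, percent) or `"power"` (uV^2)
#' @return list with `difference` (channel x bin matrix), `freq`,
#'   `measure`, `patientSamples` and `controlSamples` (subject x channel x
#'   bin arrays)
#' @export
groupDifferenceSpectra <- function(patients, controls,
                                   measure = c("relAmplitude", "power")) {
  measure <- match.arg(measure)
  if (!isTRUE(all.equal(patients@freq, controls@freq)))
    stop("frequency axes do not match")
  diff <- grandAverage(patients, measure) - grandAverage(controls, measure)
  list(difference = diff, freq = patients@freq, measure = measure,
       condition = patients@condition,
       patientSamples = slot(patients, measure),
       controlSamples = slot(controls, measure))
}

#' Scalp-map values at one frequency
#'
#' Grand-average value per channel at the bin nearest the requested
#' frequency, for scalp-map rendering.
#'
#' @param spectra a [GroupSpectra-class]
#' @param freq frequency in Hz, inside the analysis band
#' @param measure `"relAmplitude"` or `"power"`
#' @return named numeric vector, one value per channel
#' @export
topographicMap <- function(spectra, freq,
                           measure = c("relAmplitude", "power")) {
  measure <- match.arg(measure)
  if (freq < min(spectra@freq) || freq > max(spectra@freq))
    stop("frequency outside the analysis band")
  bin <- which.min(abs(spectra@freq - freq))
  ga <- grandAverage(spectra, measure)
  setNames(ga[, bin], rownames(ga))
}
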