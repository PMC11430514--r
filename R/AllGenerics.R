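#' Channel labels of an EEG object
#' @param x an object with channels
#' @param ... unused
#' @return character vector of channel labels
#' @export
setGeneric("channelLabels", function(x, ...) standardGeneric("channelLabels"))

#' Sampling rate in Hz
#' @param x an object with a sampling rate
#' @return numeric scalar, Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Raw signal matrix (channels x samples, uV)
#' @param x an [EEGRecording-class]
#' @param eegOnly drop non-EEG channels (e.g. the button channel)?
#' @return numeric matrix
#' @export
setGeneric("eegData", function(x, eegOnly = FALSE) standardGeneric("eegData"))

#' Logical clean-epoch indicator
#' @param x an [EpochSet-class]
#' @return logical vector, TRUE where no artifact rule fired
#' @export
setGeneric("isClean", function(x) standardGeneric("isClean"))

#' Grand average over subjects
#' @param x a [GroupSpectra-class]
#' @param measure \code{"relAmplitude"} (default) or \code{"power"}
#' @return channel x bin matrix, mean over subjects
#' @export
setGeneric("grandAverage", function(x, measure = "relAmplitude")
  standardGeneric("grandAverage"))

#' @describeIn EEGRecording-class channel labels (optionally EEG-only)
#' @param x,... see generic
#' @param eegOnly drop non-EEG channels
#' @export
setMethod("channelLabels", "EEGRecording", function(x, eegOnly = FALSE, ...) {
  lab <- rownames(x@data)
  if (eegOnly) lab <- setdiff(lab, "Button")
  lab
})

#' @describeIn EpochSet-class channel labels
#' @export
setMethod("channelLabels", "EpochSet", function(x, ...) dimnames(x@epochs)[[2L]])

#' @describeIn MontageGraph-class channel labels
#' @export
setMethod("channelLabels", "MontageGraph", function(x, ...) rownames(x@positions))

#' @describeIn EEGRecording-class sampling rate (Hz)
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)

#' @describeIn EpochSet-class sampling rate (Hz)
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)

#' @describeIn EEGRecording-class signal matrix
#' @export
setMethod("eegData", "EEGRecording", function(x, eegOnly = FALSE) {
  if (eegOnly) x@data[setdiff(rownames(x@data), "Button"), , drop = FALSE]
  else x@data
})

#' @describeIn EpochSet-class TRUE for epochs with no artifact flag
#' @export
setMethod("isClean", "EpochSet", function(x) rowSums(x@flags) == 0)

#' @describeIn GroupSpectra-class grand average, mean of the retained
#'   per-subject spectra
#' @param measure \code{"relAmplitude"} or \code{"power"}
#' @export
setMethod("grandAverage", "GroupSpectra", function(x, measure = "relAmplitude") {
  arr <- slot(x, match.arg(measure, c("relAmplitude", "power")))
  out <- apply(arr, c(2L, 3L), mean)
  dimnames(out) <- dimnames(arr)[2:3]
  out
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz, ref=%s, %d events\n",
    object@subjectId, object@condition, nrow(object@data), ncol(object@data),
    object@samplingRate, object@reference, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf(
    "EpochSet '%s' (%s): %d epochs (%d clean) x %d channels x %d samples\n",
    object@subjectId, object@condition, dim(object@epochs)[1L],
    sum(isClean(object)), dim(object@epochs)[2L], dim(object@epochs)[3L]))
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf(
    "SpectrumSet '%s' (%s): %d channels, %d bins (%.2g-%.2g Hz), %d epochs\n",
    object@subjectId, object@condition, nrow(object@power),
    length(object@freq), min(object@freq), max(object@freq), object@nEpochs))
})

setMethod("show", "ERPSet", function(object) {
  cat(sprintf(
    "ERPSet '%s' %s: %d channels x %d samples (%g..%g ms), %d trials\n",
    object@subjectId, object@condition, nrow(object@waveform),
    length(object@timeMs), min(object@timeMs), max(object@timeMs),
    object@nTrials))
})

setMethod("show", "ClusterTestResult", function(object) {
  ns <- sum(vapply(object@clusters, function(cl) cl$permP < 0.05, logical(1)))
  cat(sprintf(
    "ClusterTestResult: %d clusters (%d with perm p < 0.05), %d permutations%s\n",
    length(object@clusters), ns, object@nPerm,
    if (object@exhaustive) " (exhaustive)" else ""))
  if (length(object@clusters)) {
    sm <- clusterSummary(object)
    print(utils::head(sm, 10L))
  }
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: r(%s, %s) = %.3f, n = %d, p = %.4g%s\n",
    object@xName, object@yName, object@r, object@n, object@p,
    if (is.finite(object@permP)) sprintf(", perm p = %.4g", object@permP) else ""))
})
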