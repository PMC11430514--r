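#' @import methods
#' @importFrom stats approx cor cor.test fft median pnorm pt qnorm quantile
#'   rbinom rnorm runif sd setNames var
NULL

#' EEGRecording: continuous multichannel EEG
#'
#' Container for a continuous multichannel EEG session: a channels x samples
#' matrix in microvolts, the montage labels (matrix rownames), the sampling
#' rate, the current reference state, and the event table for task sessions.
#'
#' @slot data numeric matrix, channels x samples, in uV; rownames are channel
#'   labels. May include a non-EEG \code{"Button"} channel for task sessions.
#' @slot samplingRate sampling rate in Hz.
#' @slot reference reference state, \code{"linked_ears"} or
#'   \code{"weighted_average"}.
#' @slot events data.frame of task events (possibly 0-row); see
#'   [generateTaskEvents()] for the column contract.
#' @slot subjectId subject identifier.
#' @slot condition recording condition: \code{"eyes_open"},
#'   \code{"eyes_closed"} or \code{"task"}.
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    reference = "character",
    events = "data.frame",
    subjectId = "character",
    condition = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (is.null(rownames(object@data)))
    msg <- c(msg, "data must have channel labels as rownames")
  if (anyDuplicated(rownames(object@data)))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!object@reference %in% c("linked_ears", "weighted_average"))
    msg <- c(msg, "reference must be 'linked_ears' or 'weighted_average'")
  if (!object@condition %in% c("eyes_open", "eyes_closed", "task"))
    msg <- c(msg, "condition must be eyes_open, eyes_closed or task")
  if (length(msg)) msg else TRUE
})

#' EpochSet: fixed-length epochs with artifact flags
#'
#' A recording cut into consecutive, non-overlapping epochs, with per-epoch
#' artifact flags from the three amplitude rules (see [markArtifactEpochs()]).
#'
#' @slot epochs numeric array, epoch x channel x sample, in uV.
#' @slot flags logical matrix, epoch x rule, columns \code{abs}, \code{slow},
#'   \code{fast}; an epoch is clean iff its row is all-FALSE.
#' @slot labels character vector of per-epoch condition labels.
#' @slot onsetSample integer start sample (1-based) of each epoch in the
#'   source recording.
#' @slot timeMs numeric time axis in ms relative to epoch start (or stimulus
#'   onset for event-locked epochs).
#' @slot samplingRate Hz.
#' @slot subjectId,condition provenance of the source recording.
#' @export
setClass("EpochSet",
  representation(
    epochs = "array",
    flags = "matrix",
    labels = "character",
    onsetSample = "integer",
    timeMs = "numeric",
    samplingRate = "numeric",
    subjectId = "character",
    condition = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-d array")
  else {
    if (nrow(object@flags) != d[1L]) msg <- c(msg, "flags rows != epochs")
    if (length(object@labels) != d[1L]) msg <- c(msg, "labels != epochs")
    if (length(object@timeMs) != d[3L]) msg <- c(msg, "timeMs != samples")
  }
  if (!identical(colnames(object@flags), c("abs", "slow", "fast")))
    msg <- c(msg, "flags columns must be abs, slow, fast")
  if (length(msg)) msg else TRUE
})

#' SpectrumSet: per-channel spectra of one subject/condition
#'
#' Welch power spectra per channel with derived amplitude and relative
#' amplitude. Relative amplitude is each channel's amplitude expressed in
#' percent of that channel's summed amplitude over the analysis band, so it
#' sums to 100 per channel.
#'
#' @slot freq frequency axis in Hz.
#' @slot power channel x bin matrix, uV^2 (integrates to signal variance).
#' @slot amplitude channel x bin matrix, uV (sqrt of power).
#' @slot relAmplitude channel x bin matrix, percent.
#' @slot nEpochs number of clean epochs averaged.
#' @slot subjectId,condition provenance.
#' @export
setClass("SpectrumSet",
  representation(
    freq = "numeric",
    power = "matrix",
    amplitude = "matrix",
    relAmplitude = "matrix",
    nEpochs = "integer",
    subjectId = "character",
    condition = "character"
  )
)

setValidity("SpectrumSet", function(object) {
  msg <- character()
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (ncol(object@power) != length(object@freq))
    msg <- c(msg, "power columns != freq bins")
  rs <- rowSums(object@relAmplitude)
  if (any(abs(rs - 100) > 1e-6))
    msg <- c(msg, "relAmplitude must sum to 100 per channel")
  if (length(msg)) msg else TRUE
})

#' GroupSpectra: per-subject spectra of one group and condition
#'
#' Retains the per-subject channel x bin arrays (both power-derived measures)
#' so that grand averages and pointwise group statistics use the same samples.
#'
#' @slot freq frequency axis in Hz.
#' @slot power subject x channel x bin array, uV^2.
#' @slot relAmplitude subject x channel x bin array, percent.
#' @slot subjects subject identifiers (first array dimension).
#' @slot condition recording condition.
#' @export
setClass("GroupSpectra",
  representation(
    freq = "numeric",
    power = "array",
    relAmplitude = "array",
    subjects = "character",
    condition = "character"
  )
)

setValidity("GroupSpectra", function(object) {
  d <- dim(object@power)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "power must be subject x channel x bin")
  else {
    if (d[1L] != length(object@subjects)) msg <- c(msg, "subjects mismatch")
    if (d[3L] != length(object@freq)) msg <- c(msg, "freq mismatch")
    if (!identical(dim(object@relAmplitude), d))
      msg <- c(msg, "relAmplitude dim mismatch")
  }
  if (length(msg)) msg else TRUE
})

#' ERPSet: averaged event-related potential of one subject/condition
#'
#' @slot waveform channel x time matrix, uV, baseline-corrected average.
#' @slot timeMs time axis in ms relative to the time-locking stimulus onset.
#' @slot nTrials number of artifact-free trials averaged (> 0).
#' @slot baselineMs two-element baseline window in ms.
#' @slot subjectId,condition provenance; condition one of \code{"GO"},
#'   \code{"NOGO"}, \code{"Ignore"}.
#' @export
setClass("ERPSet",
  representation(
    waveform = "matrix",
    timeMs = "numeric",
    nTrials = "integer",
    baselineMs = "numeric",
    subjectId = "character",
    condition = "character"
  )
)

setValidity("ERPSet", function(object) {
  msg <- character()
  if (ncol(object@waveform) != length(object@timeMs))
    msg <- c(msg, "waveform columns != timeMs")
  if (object@nTrials <= 0L) msg <- c(msg, "nTrials must be > 0")
  if (length(object@baselineMs) != 2L) msg <- c(msg, "baselineMs must be length 2")
  if (length(msg)) msg else TRUE
})

#' MontageGraph: 2-D electrode layout with spatial adjacency
#'
#' Projected 10-20 electrode coordinates (head scaled to unit diameter, nose
#' up) and a symmetric, irreflexive neighbor relation used for spatial
#' clustering.
#'
#' @slot positions channel x 2 coordinate matrix, rownames are labels.
#' @slot adjacency symmetric logical channel x channel matrix, FALSE diagonal.
#' @export
setClass("MontageGraph",
  representation(positions = "matrix", adjacency = "matrix")
)

setValidity("MontageGraph", function(object) {
  msg <- character()
  a <- object@adjacency
  if (!isSymmetric(a * 1)) msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(a))) msg <- c(msg, "adjacency must be irreflexive")
  if (any(rowSums(a) < 1)) msg <- c(msg, "every channel needs >= 1 neighbor")
  if (!identical(rownames(object@positions), rownames(a)))
    msg <- c(msg, "positions/adjacency labels mismatch")
  if (length(msg)) msg else TRUE
})

#' PointStatMap: pointwise Wilcoxon z and p per (channel, bin)
#'
#' @slot z channel x bin matrix of normal-approximation Wilcoxon z-scores;
#'   positive z means the first group/condition is larger.
#' @slot p channel x bin matrix of two-sided normal-approximation p-values.
#' @slot testType \code{"signed_rank_paired"} or \code{"rank_sum_independent"}.
#' @slot binAxis numeric axis of the bin dimension (Hz or ms).
#' @slot degenerate logical matrix flagging points where all observations were
#'   identical across groups (z set to 0, p to 1).
#' @export
setClass("PointStatMap",
  representation(
    z = "matrix",
    p = "matrix",
    testType = "character",
    binAxis = "numeric",
    degenerate = "matrix"
  )
)

setValidity("PointStatMap", function(object) {
  msg <- character()
  if (!identical(dim(object@z), dim(object@p))) msg <- c(msg, "z/p dim mismatch")
  if (any(!is.finite(object@z))) msg <- c(msg, "z must be finite")
  if (any(object@p <= 0 | object@p > 1)) msg <- c(msg, "p must be in (0,1]")
  if (!object@testType %in% c("signed_rank_paired", "rank_sum_independent"))
    msg <- c(msg, "unknown testType")
  if (length(msg)) msg else TRUE
})

#' ClusterTestResult: clusters with summed-z mass and permutation p-values
#'
#' Result of the cluster-based permutation test: candidate clusters of
#' spatio-temporally adjacent supra-threshold points of uniform sign, each
#' scored by its summed z (mass) and calibrated against the permutation null
#' distribution of the maximum absolute cluster mass.
#'
#' @slot clusters list; each element has \code{points} (data.frame with
#'   \code{channel}, \code{bin}), \code{mass}, \code{sign}, \code{permP}.
#' @slot pointMap the [PointStatMap-class] the clusters were formed from.
#' @slot nullMax permutation null distribution of max |mass|.
#' @slot nPerm number of permutations actually used.
#' @slot exhaustive TRUE if all distinct relabelings were enumerated.
#' @slot seed integer seed used for Monte-Carlo permutation draws.
#' @slot settings list of test settings (design, thresholds, ...).
#' @export
setClass("ClusterTestResult",
  representation(
    clusters = "list",
    pointMap = "PointStatMap",
    nullMax = "numeric",
    nPerm = "integer",
    exhaustive = "logical",
    seed = "integer",
    settings = "list"
  )
)

setValidity("ClusterTestResult", function(object) {
  msg <- character()
  for (cl in object@clusters) {
    if (!all(c("points", "mass", "sign", "permP") %in% names(cl))) {
      msg <- c(msg, "malformed cluster entry")
      break
    }
    if (cl$permP <= 0 || cl$permP > 1) msg <- c(msg, "permP must be in (0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationResult: Pearson correlation of two per-subject variables
#'
#' @slot r Pearson coefficient.
#' @slot p two-sided p-value from the t transform
#'   \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#' @slot permP optional permutation p-value (NA if not computed).
#' @slot n number of subjects.
#' @slot xName,yName variable names.
#' @slot pairs data.frame of the retained (subject, x, y) triples.
#' @export
setClass("CorrelationResult",
  representation(
    r = "numeric",
    p = "numeric",
    permP = "numeric",
    n = "integer",
    xName = "character",
    yName = "character",
    pairs = "data.frame"
  )
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "|r| must be <= 1")
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (length(msg)) msg else TRUE
})
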