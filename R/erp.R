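## Event-locked averaging for the cued GO/NOGO task: trial labeling, epoch
## extraction with artifact exclusion and baseline correction, component
## quantification, and reaction-time bookkeeping.

#' Label trials as GO / NOGO / Ignore
#'
#' `aa` pairs require a button press (GO), `ap` pairs present the animal cue
#' but a plant second stimulus (NOGO, response must be withheld), and `pp`
#' and `ph` pairs carry no response demand (Ignore).
#'
#' @param events event table from [generateTaskEvents()]
#' @return the table with an added `condition` column
#' @export
assignTrialConditions <- function(events) {
  map <- c(aa = "GO", ap = "NOGO", pp = "Ignore", ph = "Ignore")
  bad <- setdiff(unique(events$pairType), names(map))
  if (length(bad)) stop("unknown pair type(s): ", paste(bad, collapse = ", "))
  events$condition <- unname(map[events$pairType])
  events
}

#' Epoch the task EEG and average per condition
#'
#' GO and NOGO epochs are time-locked to the second stimulus of `aa` and
#' `ap` pairs; Ignore epochs to the first stimulus of `pp`/`ph` pairs.
#' Trials overlapping artifact-flagged segments of the recording (per the
#' three amplitude rules) are excluded; surviving trials are baseline-
#' corrected (mean of the baseline window subtracted per channel) and
#' averaged.
#'
#' @param rec the task [EEGRecording-class]
#' @param events labeled events from [assignTrialConditions()] (default:
#'   label the recording's own event table)
#' @param windowMs epoch window around the time-locking stimulus, ms
#' @param baselineMs baseline window, ms
#' @param rules an [ArtifactRules-class] for artifact exclusion
#' @return named list of [ERPSet-class], one per condition present
#' @export
epochAndAverage <- function(rec, events = NULL, windowMs = c(-200, 800),
                            baselineMs = c(-200, 0),
                            rules = artifactRules()) {
  if (is.null(events)) events <- assignTrialConditions(rec@events)
  if (windowMs[1L] > baselineMs[1L] || windowMs[2L] < baselineMs[2L])
    stop("window must cover the baseline")
  fs <- rec@samplingRate
  ch <- setdiff(rownames(rec@data), "Button")
  x <- rec@data[ch, , drop = FALSE]

  flagged <- markArtifactEpochs(rec, rules)
  epochLen <- dim(flagged@epochs)[3L]
  badStart <- flagged@onsetSample[!isClean(flagged)]

  i0 <- round(windowMs[1L] * fs / 1000)
  i1 <- round(windowMs[2L] * fs / 1000)
  timeMs <- (i0:i1) * 1000 / fs
  blSel <- which(timeMs >= baselineMs[1L] & timeMs <= baselineMs[2L])

  lockMs <- ifelse(events$condition == "Ignore", events$cueOnsetMs,
                   events$secondOnsetMs)
  out <- list()
  for (cond in intersect(c("GO", "NOGO", "Ignore"), events$condition)) {
    rows <- which(events$condition == cond)
    acc <- matrix(0, length(ch), length(timeMs), dimnames = list(ch, NULL))
    nUsed <- 0L
    for (k in rows) {
      c0 <- round(lockMs[k] * fs / 1000) + 1L
      idx <- (c0 + i0):(c0 + i1)
      if (idx[1L] < 1L || idx[length(idx)] > ncol(x)) next
      if (length(badStart) &&
          any(idx[1L] <= badStart + epochLen - 1L & idx[length(idx)] >= badStart))
        next
      tr <- x[, idx, drop = FALSE]
      tr <- tr - rowMeans(tr[, blSel, drop = FALSE])
      acc <- acc + tr
      nUsed <- nUsed + 1L
    }
    if (nUsed == 0L)
      stop(errorCondition(
        sprintf("subject %s: no artifact-free %s trials", rec@subjectId, cond),
        class = c("qualityGateError", "error", "condition")))
    out[[cond]] <- new("ERPSet", waveform = acc / nUsed, timeMs = timeMs,
                       nTrials = nUsed, baselineMs = baselineMs,
                       subjectId = rec@subjectId, condition = cond)
  }
  out
}

#' Grand-average ERP over subjects
#'
#' @param erps list of [ERPSet-class] of the same condition and time axis
#' @return an [ERPSet-class] with `subjectId = "grand"`; `nTrials` is the
#'   number of subjects averaged
#' @export
grandAverageERP <- function(erps) {
  stopifnot(length(erps) >= 1L)
  wf <- Reduce(`+`, lapply(erps, function(e) e@waveform)) / length(erps)
  e1 <- erps[[1L]]
  new("ERPSet", waveform = wf, timeMs = e1@timeMs,
      nTrials = length(erps), baselineMs = e1@baselineMs,
      subjectId = "grand", condition = e1@condition)
}

#' Quantify an ERP component as a window mean (or peak)
#'
#' @param erp an [ERPSet-class]
#' @param channel channel label
#' @param windowMs two-element window in ms, inside the epoch
#' @param name component name for the output row
#' @param type `"mean"` (default) window mean or `"peak"` maximum
#' @return one-row data.frame: subjectId, component, channel, windowStartMs,
#'   windowEndMs, amplitude (uV)
#' @export
extractComponent <- function(erp, channel, windowMs, name = "component",
                             type = c("mean", "peak")) {
  type <- match.arg(type)
  if (!channel %in% rownames(erp@waveform)) stop("unknown channel ", channel)
  if (windowMs[1L] < min(erp@timeMs) || windowMs[2L] > max(erp@timeMs))
    stop("window outside the epoch")
  sel <- which(erp@timeMs >= windowMs[1L] & erp@timeMs <= windowMs[2L])
  v <- erp@waveform[channel, sel]
  data.frame(subjectId = erp@subjectId, component = name, channel = channel,
             windowStartMs = windowMs[1L], windowEndMs = windowMs[2L],
             amplitude = if (type == "mean") mean(v) else max(v))
}

#' Standard component definitions
#'
#' The three components quantified by the pipeline: the late NOGO positivity
#' (window mean 300-500 ms at Cz, covering the 340 ms map latency), the GO
#' P3 (250-450 ms at Pz) and the early occipital sensory response
#' (80-180 ms at O1, measured on Ignore trials).
#'
#' @return data.frame: component, condition, channel, startMs, endMs
#' @export
standardComponents <- function() {
  data.frame(
    component = c("late_NOGO_Cz", "GO_P3_Pz", "early_sensory_O1"),
    condition = c("NOGO", "GO", "Ignore"),
    channel = c("Cz", "Pz", "O1"),
    startMs = c(300, 250, 80), endMs = c(500, 450, 180))
}

#' Reaction times and response bookkeeping for the GO task
#'
#' Presses are rising edges on the button channel. The reaction time of a GO
#' trial is the press onset minus the second-stimulus onset (first press
#' within the response window); GO trials without a press are misses and
#' responses inside the window of NOGO/Ignore trials are false alarms.
#'
#' @param rec task [EEGRecording-class] containing a `"Button"` channel
#' @param events labeled events (default: label the recording's own table)
#' @param windowMs response window after stimulus onset, ms
#' @return list with `rt` (data.frame trial, rtMs), `misses`, `falseAlarms`
#' @export
reactionTimes <- function(rec, events = NULL, windowMs = c(0, 1000)) {
  if (!"Button" %in% rownames(rec@data)) stop("no button channel present")
  if (is.null(events)) events <- assignTrialConditions(rec@events)
  fs <- rec@samplingRate
  b <- rec@data["Button", ]
  on <- which(diff(c(0, b > 50)) == 1)    # rising edges, samples
  pressMs <- (on - 1) * 1000 / fs
  lockMs <- ifelse(events$condition == "Ignore", events$cueOnsetMs,
                   events$secondOnsetMs)
  rt <- data.frame(trial = integer(), rtMs = numeric())
  misses <- 0L; falseAlarms <- 0L
  for (k in seq_len(nrow(events))) {
    hits <- pressMs[pressMs > lockMs[k] + windowMs[1L] &
                    pressMs <= lockMs[k] + windowMs[2L]]
    if (events$condition[k] == "GO") {
      if (length(hits))
        rt <- rbind(rt, data.frame(trial = events$trial[k],
                                   rtMs = hits[1L] - lockMs[k]))
      else misses <- misses + 1L
    } else if (length(hits)) falseAlarms <- falseAlarms + 1L
  }
  list(rt = rt, misses = misses, falseAlarms = falseAlarms)
}
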