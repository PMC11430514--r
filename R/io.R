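## File interchange: minimal EDF writer/reader for continuous recordings,
## tab-separated event files, subject tables and tidy spectra export.

.edfPad <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = -width)
}

#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: one data record per second, 16-bit
#' samples with per-channel physical scaling chosen from the data range.
#' The tail of the recording beyond the last whole second is dropped, as is
#' usual for the format.
#'
#' @param rec an [EEGRecording-class]
#' @param path output file path
#' @return invisibly, `path`
#' @export
writeEDF <- function(rec, path) {
  fs <- rec@samplingRate
  stopifnot(fs == round(fs))
  x <- rec@data
  nRec <- floor(ncol(x) / fs)
  if (nRec < 1) stop("recording shorter than one EDF record (1 s)")
  x <- x[, seq_len(nRec * fs), drop = FALSE]
  ns <- nrow(x)
  # 6 significant digits so the printed header value is the scaling value
  physMax <- signif(pmax(apply(abs(x), 1L, max), 1) * 1.0001, 6)
  digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8),
    .edfPad(rec@subjectId, 80),
    .edfPad(rec@condition, 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(256 + 256 * ns, 8),
    .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad(1, 8), .edfPad(ns, 4),
    paste(.edfPad(rownames(x), 16), collapse = ""),
    paste(rep(.edfPad("", 80), ns), collapse = ""),
    paste(rep(.edfPad("uV", 8), ns), collapse = ""),
    paste(.edfPad(sprintf("%.6g", -physMax), 8), collapse = ""),
    paste(.edfPad(sprintf("%.6g", physMax), 8), collapse = ""),
    paste(rep(.edfPad(-digMax, 8), ns), collapse = ""),
    paste(rep(.edfPad(digMax, 8), ns), collapse = ""),
    paste(rep(.edfPad(rec@reference, 80), ns), collapse = ""),
    paste(rep(.edfPad(fs, 8), ns), collapse = ""),
    paste(rep(.edfPad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  scale <- digMax / physMax
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round(x[, idx, drop = FALSE] * scale)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [writeEDF()]
#'
#' @param path EDF file path
#' @return an [EEGRecording-class] (events empty; attach them separately
#'   from the event file)
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  subjectId <- trimws(rd(80))
  condition <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  rd(8)
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  rd(80 * ns); rd(8 * ns)
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  reference <- trimws(rd(80)); if (ns > 1) rd(80 * (ns - 1L))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)

  fs <- spr[1L]
  out <- matrix(0, ns, nRec * fs, dimnames = list(labels, NULL))
  for (r in seq_len(nRec)) {
    raw <- readBin(con, "integer", n = ns * fs, size = 2L, signed = TRUE,
                   endian = "little")
    block <- matrix(raw, nrow = fs)      # samples x channels
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    out[, idx] <- t(block)
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  out <- out * gain
  new("EEGRecording", data = out, samplingRate = fs,
      reference = if (reference %in% c("linked_ears", "weighted_average"))
        reference else "linked_ears",
      events = generateTaskEvents(0), subjectId = subjectId,
      condition = if (condition %in% c("eyes_open", "eyes_closed", "task"))
        condition else "task")
}

#' Write / read the tab-separated event file
#'
#' Columns: `onset_ms`, `type` (stimulus role and pair type), `trial_index`.
#' Each trial contributes its cue and second-stimulus onsets.
#'
#' @param events event table from [generateTaskEvents()]
#' @param path file path
#' @return invisibly `path` (write) / the event table (read)
#' @export
writeEvents <- function(events, path) {
  long <- rbind(
    data.frame(onset_ms = events$cueOnsetMs,
               type = paste0("cue_", events$pairType),
               trial_index = events$trial),
    data.frame(onset_ms = events$secondOnsetMs,
               type = paste0("second_", events$pairType),
               trial_index = events$trial))
  long <- long[order(long$onset_ms), ]
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  long <- utils::read.delim(path)
  sec <- long[startsWith(long$type, "second_"), ]
  cue <- long[startsWith(long$type, "cue_"), ]
  o <- order(cue$trial_index)
  data.frame(trial = cue$trial_index[o],
             pairType = sub("cue_", "", cue$type[o]),
             cueOnsetMs = cue$onset_ms[o],
             secondOnsetMs = sec$onset_ms[order(sec$trial_index)],
             stimulusDurationMs = 100, responseTimeMs = NA_real_)
}

#' Read a cohort/effects study configuration file
#'
#' A YAML (or JSON) file with optional top-level `cohort` and `effects`
#' blocks whose keys are the arguments of [cohortSpec()] and
#' [effectSpec()]; omitted keys keep their defaults. Topography gain maps
#' may be given as named channel:gain mappings.
#'
#' @param path configuration file path
#' @return list with validated `cohort` ([CohortSpec-class]) and `effects`
#'   ([EffectSpec-class])
#' @export
readStudyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c("cohort", "effects"))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  co <- cfg$cohort %||% list()
  ef <- cfg$effects %||% list()
  defaults <- list(lowAlphaTopography = .defaultLowAlphaTopo(),
                   controlAlphaTopography = .defaultControlAlphaTopo())
  for (k in names(defaults)) {
    if (!is.null(ef[[k]])) {
      g <- defaults[[k]]
      v <- unlist(ef[[k]])
      bad <- setdiff(names(v), names(g))
      if (length(bad)) stop("unknown channel(s) in ", k, ": ",
                            paste(bad, collapse = ", "))
      g[names(v)] <- v
      ef[[k]] <- g
    }
  }
  list(cohort = do.call(cohortSpec, co), effects = do.call(effectSpec, ef))
}

#' Per-subject preprocessing report as JSON
#'
#' Summarizes the artifact flagging (epochs total, clean, and per rule) and
#' the ICA ocular correction (components removed with their template
#' correlations) for one subject and condition.
#'
#' @param epochs an [EpochSet-class] from [markArtifactEpochs()]
#' @param icaReport the `report` element of [removeOcularICA()] (or NULL)
#' @param path output JSON path
#' @return invisibly `path`
#' @export
writePreprocessingReport <- function(epochs, icaReport, path) {
  rep <- list(
    subject = epochs@subjectId,
    condition = epochs@condition,
    epochsTotal = dim(epochs@epochs)[1L],
    epochsClean = sum(isClean(epochs)),
    flaggedByRule = as.list(colSums(epochs@flags)),
    icaComponentsRemoved = if (is.null(icaReport)) integer() else
      icaReport$component[icaReport$removed],
    icaTemplateCorrelations = if (is.null(icaReport)) numeric() else
      icaReport$templateCorrelation[icaReport$removed]
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tidy CSV export of spectra
#'
#' One row per (subject, condition, channel, frequency bin).
#'
#' @param spectra list of [SpectrumSet-class]
#' @param path output CSV path
#' @return invisibly `path`
#' @export
exportSpectraCSV <- function(spectra, path) {
  rows <- lapply(spectra, function(s) {
    data.frame(subject = s@subjectId, condition = s@condition,
               channel = rep(rownames(s@power), ncol(s@power)),
               freq_hz = rep(s@freq, each = nrow(s@power)),
               power = as.vector(s@power),
               rel_amp_pct = as.vector(s@relAmplitude))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
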