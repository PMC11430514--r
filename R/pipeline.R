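## End-to-end study driver: simulate the cohort, preprocess every session,
## compute spectra and ERPs, run the cluster permutation tests, correlate
## the late NOGO amplitude with behavior, and (optionally) write the report.

#' Preprocess one recording with the standard chain
#'
#' Digital band-pass (0.53-30 Hz), 45-55 Hz notch, weighted-average
#' re-reference, then ICA ocular correction (fitted on a 2-30 Hz copy).
#'
#' @param rec an [EEGRecording-class] (linked-ears referenced)
#' @param band digital band-pass edges, Hz
#' @param notch apply the 45-55 Hz notch?
#' @param ica apply ICA ocular correction?
#' @param icaSeed seed for the ICA initialisation
#' @param icaFitSeconds seconds of data used to fit the unmixing (the full
#'   recording is corrected)
#' @return list with `recording` and `icaReport` (NULL when `ica = FALSE`)
#' @export
preprocessRecording <- function(rec, band = c(0.53, 30), notch = TRUE,
                                ica = TRUE, icaSeed = 1,
                                icaFitSeconds = 60) {
  if (notch) rec <- notchFilter(rec)
  rec <- bandpassFilter(rec, band[1L], band[2L])
  rec <- rerefWeightedAverage(rec)
  report <- NULL
  if (ica) {
    res <- removeOcularICA(rec, seed = icaSeed,
                           fitSeconds = icaFitSeconds)
    rec <- res$recording
    report <- res$report
  }
  list(recording = rec, icaReport = report)
}

#' Run the full simulated study
#'
#' Simulates the cohort, synthesizes and preprocesses every session,
#' computes Welch spectra per condition and per-condition patient-minus-
#' control cluster permutation tests, averages the task ERPs, tests the
#' NOGO waveforms between groups, extracts the standard components, and
#' correlates the patients' late NOGO amplitude at Cz with their behavioral
#' score.
#'
#' @param cohort a [CohortSpec-class]
#' @param effects an [EffectSpec-class]
#' @param seed master integer seed; all per-subject seeds derive from it
#' @param conditions conditions to simulate and analyze
#' @param restDurationSec,nTrials optional overrides passed to
#'   [synthesizeSession()] to shorten sessions
#' @param ica apply ICA ocular correction?
#' @param rules an [ArtifactRules-class]
#' @param nPerm permutations for each cluster test
#' @param pThreshold cluster-forming threshold
#' @param measure spectral measure compared across groups
#' @param doSpectra compute spectra and their group cluster tests
#' @param doErp compute ERPs and the NOGO cluster test (task condition only)
#' @param erpTestLowpassHz zero-phase low-pass (Hz) applied to the
#'   per-subject ERP waveforms before the group cluster test, as is usual
#'   for late slow components; it suppresses residual alpha that is
#'   phase-locked to the fixed trial grid and would otherwise inflate
#'   pointwise between-subject variance. NULL disables. Component
#'   amplitudes and stored waveforms stay unfiltered.
#' @param doCorrelation correlate late NOGO amplitude with behavior
#' @param reportDir if non-NULL, write the markdown report there
#' @return list with `subjects`, `spectra` (per condition: `patients`,
#'   `controls` [GroupSpectra-class], `contrast`, `test`), `erp` (`grand`,
#'   `components`, `test`), `correlation`, `settings`
#' @export
runStudy <- function(cohort = cohortSpec(), effects = effectSpec(),
                     seed = 1,
                     conditions = c("eyes_open", "eyes_closed", "task"),
                     restDurationSec = NULL, nTrials = NULL, ica = TRUE,
                     rules = artifactRules(), nPerm = 500,
                     pThreshold = 0.05, measure = "relAmplitude",
                     doSpectra = TRUE, doErp = TRUE, erpTestLowpassHz = 6,
                     doCorrelation = TRUE, reportDir = NULL) {
  subjects <- simulateCohort(cohort, effects, seed)
  montage <- standardMontage(cohort@channelLabels)
  doErp <- doErp && "task" %in% conditions
  ## independent per-session seeds drawn from the master stream (arithmetic
  ## seed progressions give detectably correlated generator streams)
  allConds <- c("eyes_open", "eyes_closed", "task")
  seedMat <- matrix(withSeed(seed + 101L,
                             sample.int(2147483646L,
                                        nrow(subjects) * length(allConds))),
                    nrow(subjects), length(allConds),
                    dimnames = list(NULL, allConds))

  specs <- list()
  nogoWf <- list(patient = list(), control = list())
  erpBySubj <- list()
  components <- list()

  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    for (cond in conditions) {
      cSeed <- seedMat[i, cond]
      rec <- synthesizeSession(subj, cond, cohort, effects, seed = cSeed,
                               nTrials = nTrials,
                               restDurationSec = restDurationSec)
      pp <- preprocessRecording(rec, ica = ica, icaSeed = cSeed)
      if (doSpectra) {
        epochs <- markArtifactEpochs(pp$recording, rules)
        clean <- requireMinClean(epochs, rules)
        specs[[cond]][[subj$group]][[subj$subjectId]] <-
          computeSpectrum(clean)
      }
      if (doErp && cond == "task") {
        erps <- epochAndAverage(pp$recording, rules = rules)
        erpBySubj[[subj$subjectId]] <- erps
        if ("NOGO" %in% names(erps))
          nogoWf[[subj$group]][[subj$subjectId]] <- erps$NOGO@waveform
        sc <- standardComponents()
        for (k in seq_len(nrow(sc))) {
          if (!sc$condition[k] %in% names(erps)) next
          components[[length(components) + 1L]] <- extractComponent(
            erps[[sc$condition[k]]], sc$channel[k],
            c(sc$startMs[k], sc$endMs[k]), name = sc$component[k])
        }
      }
    }
  }

  spectra <- list()
  for (cond in if (doSpectra) conditions else character()) {
    gp <- groupSpectra(specs[[cond]]$patient)
    gc <- groupSpectra(specs[[cond]]$control)
    contrast <- groupDifferenceSpectra(gp, gc, measure)
    test <- permutationTest(slot(gp, measure), slot(gc, measure),
                            design = "independent", montage = montage,
                            nPerm = nPerm, pThreshold = pThreshold,
                            seed = seed + 17L, binAxis = gp@freq)
    spectra[[cond]] <- list(patients = gp, controls = gc,
                            contrast = contrast, test = test)
  }

  erp <- NULL
  compTab <- NULL
  if (doErp) {
    compTab <- do.call(rbind, components)
    compTab$group <- subjects$group[match(compTab$subjectId,
                                          subjects$subjectId)]
    toArray <- function(lst) {
      wf1 <- lst[[1L]]
      arr <- array(0, c(length(lst), nrow(wf1), ncol(wf1)),
                   dimnames = list(NULL, rownames(wf1), NULL))
      for (j in seq_along(lst)) arr[j, , ] <- lst[[j]]
      arr
    }
    timeMs <- erpBySubj[[1L]]$NOGO@timeMs
    patArr <- toArray(nogoWf$patient)
    conArr <- toArray(nogoWf$control)
    if (!is.null(erpTestLowpassHz)) {
      lpf <- signal::butter(4, erpTestLowpassHz / (cohort@samplingRate / 2),
                            type = "low")
      smooth <- function(arr) {
        for (j in seq_len(dim(arr)[1L]))
          arr[j, , ] <- t(apply(arr[j, , , drop = TRUE], 1L,
                                function(v) signal::filtfilt(lpf, v)))
        arr
      }
      patArr <- smooth(patArr)
      conArr <- smooth(conArr)
    }
    erpTest <- permutationTest(patArr, conArr,
                               design = "independent", montage = montage,
                               nPerm = nPerm, pThreshold = pThreshold,
                               seed = seed + 23L, binAxis = timeMs)
    grand <- list()
    for (cond in c("NOGO", "GO", "Ignore")) {
      for (grp in c("patient", "control")) {
        ids <- subjects$subjectId[subjects$group == grp]
        sets <- lapply(erpBySubj[ids], `[[`, cond)
        sets <- sets[!vapply(sets, is.null, logical(1))]
        if (length(sets))
          grand[[paste(cond, grp, sep = "_")]] <- grandAverageERP(sets)
      }
    }
    erp <- list(grand = grand, components = compTab, test = erpTest,
                timeMs = timeMs)
  }

  correlation <- NULL
  if (doCorrelation && doErp) {
    pat <- compTab[compTab$component == "late_NOGO_Cz" &
                     compTab$group == "patient", ]
    score <- subjects$behavioralScore[match(pat$subjectId,
                                            subjects$subjectId)]
    correlation <- correlateAmplitudeScore(
      pat$amplitude, score, xName = "late_NOGO_Cz_uV",
      yName = "delayed_recall_T", nPerm = 2000, seed = seed + 29L)
  }

  settings <- list(seed = seed, nPatients = cohort@nPatients,
                   nControls = cohort@nControls,
                   conditions = paste(conditions, collapse = ","),
                   nPerm = nPerm, pThreshold = pThreshold,
                   measure = measure, ica = ica,
                   nTrials = nTrials %||% cohort@nTrials,
                   restDurationSec = restDurationSec %||%
                     cohort@restDurationSec)
  out <- list(subjects = subjects, spectra = spectra, erp = erp,
              correlation = correlation, settings = settings)
  if (!is.null(reportDir))
    buildReport(list(spectra = spectra, erp = erp,
                     correlation = correlation, settings = settings),
                reportDir)
  out
}
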