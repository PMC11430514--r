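## Final stage: Pearson correlation of the late NOGO amplitude at Cz with
## the behavioral delayed-recall score, plus the pipeline's summary report.

#' Pearson correlation with t-transform p-value
#'
#' Computes Pearson r and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. Because
#' patient cohorts of this kind are tiny (n = 9 strains the t
#' approximation), an optional seeded permutation p-value (shuffling `y`)
#' can be requested.
#'
#' @param x,y equal-length finite numeric vectors (n >= 3), e.g. per-patient
#'   NOGO amplitudes (uV) and delayed-recall T-scores
#' @param xName,yName variable names for reporting
#' @param nPerm if > 0, also compute a permutation p-value with this many
#'   shuffles
#' @param seed integer seed for the permutation p-value
#' @return a [CorrelationResult-class]
#' @export
correlateAmplitudeScore <- function(x, y, xName = "amplitude",
                                    yName = "score", nPerm = 0, seed = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop(errorCondition("undefined correlation: zero variance",
                        class = c("undefinedCorrelationError", "error",
                                  "condition")))
  n <- length(x)
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tStat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tStat), df = n - 2)
  }
  permP <- NA_real_
  if (nPerm > 0) {
    rPerm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
      cor(x, sample(y)), numeric(1)))
    permP <- (1 + sum(abs(rPerm) >= abs(r))) / (1 + nPerm)
  }
  new("CorrelationResult", r = r, p = p, permP = permP, n = as.integer(n),
      xName = xName, yName = yName,
      pairs = data.frame(subject = seq_len(n), x = x, y = y))
}

#' Fisher-z confidence interval for a correlation
#'
#' @param r sample Pearson correlation, |r| < 1
#' @param n sample size (> 3)
#' @param level confidence level, default 0.95
#' @return two-element vector, the CI on the correlation scale
#' @export
fisherCI <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

.fmtNum <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

.writeTable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) .fmtNum(v, 10))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Assemble the pipeline summary report
#'
#' Writes a markdown report plus CSV tables: grand-average difference
#' spectra with per-channel significance bars, grand-average ERPs with the
#' component table, cluster-test summaries, the amplitude-score correlation
#' scatter, and a provenance block with all settings and seeds. Numeric
#' tables are written with fixed formatting, so two runs from the same
#' intermediates are byte-identical.
#'
#' @param results list with elements `spectra` (per-condition list with
#'   `contrast` from [groupDifferenceSpectra()] and `test`, a
#'   [ClusterTestResult-class]), `erp` (list with `grand`, a list of
#'   [ERPSet-class], `components`, a data.frame, and optionally `test`),
#'   `correlation` (a [CorrelationResult-class] or NULL to omit that
#'   section) and `settings` (a list; must include `seed`)
#' @param dir output directory, created if needed
#' @return invisibly, the path of the markdown report
#' @export
buildReport <- function(results, dir) {
  for (stage in c("spectra", "erp", "settings"))
    if (is.null(results[[stage]]))
      stop("missing stage output: ", stage)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- c("# QEEG/ERP group comparison report", "")

  md <- c(md, "## Group difference spectra", "")
  for (cond in names(results$spectra)) {
    st <- results$spectra[[cond]]
    sm <- clusterSummary(st$test)
    tab <- file.path(dir, paste0("spectra_clusters_", cond, ".csv"))
    .writeTable(sm, tab)
    diffCsv <- file.path(dir, paste0("difference_spectrum_", cond, ".csv"))
    dd <- data.frame(channel = rep(rownames(st$contrast$difference),
                                   ncol(st$contrast$difference)),
                     freqHz = rep(st$contrast$freq,
                                  each = nrow(st$contrast$difference)),
                     difference = as.vector(st$contrast$difference))
    .writeTable(dd, diffCsv)
    nSig <- sum(sm$permP < 0.05)
    md <- c(md, sprintf(
      "- **%s** (%s): %d cluster(s), %d with permutation p < 0.05 (tables: `%s`, `%s`)",
      cond, st$contrast$measure, nrow(sm), nSig, basename(tab),
      basename(diffCsv)))
  }
  md <- c(md, "")

  md <- c(md, "## Event-related potentials", "")
  if (!is.null(results$erp$components)) {
    compCsv <- file.path(dir, "components.csv")
    .writeTable(results$erp$components, compCsv)
    md <- c(md, sprintf("- Component table: `%s`", basename(compCsv)))
  }
  for (cond in names(results$erp$grand)) {
    g <- results$erp$grand[[cond]]
    erpCsv <- file.path(dir, paste0("grand_erp_", cond, ".csv"))
    dd <- data.frame(channel = rep(rownames(g@waveform), ncol(g@waveform)),
                     timeMs = rep(g@timeMs, each = nrow(g@waveform)),
                     uV = as.vector(g@waveform))
    .writeTable(dd, erpCsv)
    md <- c(md, sprintf("- Grand-average %s ERP (`%s`)", cond,
                        basename(erpCsv)))
  }
  if (!is.null(results$erp$test)) {
    sm <- clusterSummary(results$erp$test)
    .writeTable(sm, file.path(dir, "erp_clusters.csv"))
    md <- c(md, sprintf(
      "- ERP cluster test: %d cluster(s), %d with permutation p < 0.05 (`erp_clusters.csv`)",
      nrow(sm), sum(sm$permP < 0.05)))
  }
  md <- c(md, "")

  md <- c(md, "## Cluster statistics", "",
          sprintf("- Pointwise statistic: Wilcoxon normal-approximation z; cluster mass: summed z; null: max |mass| over %s permutations.",
                  paste(unique(vapply(results$spectra, function(s)
                    s$test@nPerm, integer(1))), collapse = "/")), "")

  md <- c(md, "## Correlation with behavior", "")
  if (is.null(results$correlation)) {
    md <- c(md, "- Correlation stage disabled; section omitted.", "")
  } else {
    cr <- results$correlation
    .writeTable(cr@pairs, file.path(dir, "correlation_pairs.csv"))
    md <- c(md, sprintf(
      "- r(%s, %s) = %s, n = %d, p = %s%s (scatter data: `correlation_pairs.csv`)",
      cr@xName, cr@yName, .fmtNum(cr@r, 4), cr@n, .fmtNum(cr@p, 4),
      if (is.finite(cr@permP))
        sprintf(", permutation p = %s", .fmtNum(cr@permP, 4)) else ""), "")
  }

  md <- c(md, "## Provenance", "")
  st <- results$settings
  md <- c(md, vapply(names(st), function(k)
    sprintf("- %s: %s", k, paste(format(st[[k]]), collapse = " ")),
    character(1)), "")

  path <- file.path(dir, "report.md")
  writeLines(md, path)
  invisible(path)
}
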