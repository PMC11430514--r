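## Nonparametric cluster-based permutation comparison of channel x bin maps
## (spectra or ERP waveforms). Pointwise statistic: normal-approximation
## Wilcoxon z (rank-sum for independent groups, signed-rank for paired
## conditions, both tie-corrected). Cluster mass: summed z over spatio-
## temporally adjacent supra-threshold points of uniform sign. Calibration:
## permutation null of the maximum absolute cluster mass (max-statistic
## multiple-comparison correction).

.flatten3 <- function(a) {
  d <- dim(a)
  stopifnot(length(d) == 3L)
  m <- matrix(a, d[1L], d[2L] * d[3L])
  attr(m, "nChan") <- d[2L]
  attr(m, "nBin") <- d[3L]
  attr(m, "channels") <- dimnames(a)[[2L]]
  m
}

## Rank-sum machinery: everything that is permutation-invariant is
## precomputed once (per-point ranks and tie-corrected sigma).
.rankSumPrep <- function(X, nA) {
  N <- nrow(X)
  nB <- N - nA
  R <- apply(X, 2L, rank)                # mid-ranks
  ties <- apply(X, 2L, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  mu <- nA * (N + 1) / 2
  sig2 <- nA * nB / 12 * ((N + 1) - ties / (N * (N - 1)))
  sigma <- sqrt(pmax(sig2, 0))
  list(R = R, mu = mu, sigma = sigma, nA = nA,
       cc = ifelse(sigma > 0, 0.5 / sigma, 0),
       degenerate = sig2 <= 0)
}

.rankSumZ <- function(prep, idxA) {
  W <- colSums(prep$R[idxA, , drop = FALSE])
  z <- (W - prep$mu) / prep$sigma
  z[prep$degenerate] <- 0
  z
}

## Signed-rank machinery on per-subject difference maps D. |d| (and hence
## the ranks and sigma) are invariant under sign flips.
.signedRankPrep <- function(D) {
  absD <- abs(D)
  RK <- apply(absD, 2L, function(v) {
    r <- numeric(length(v))
    nz <- v > 0
    r[nz] <- rank(v[nz])
    r
  })
  if (is.null(dim(RK))) RK <- matrix(RK, nrow(D))
  nEff <- colSums(absD > 0)
  ties <- apply(absD, 2L, function(v) {
    t <- table(v[v > 0])
    sum(t^3 - t)
  })
  mu <- nEff * (nEff + 1) / 4
  sig2 <- nEff * (nEff + 1) * (2 * nEff + 1) / 24 - ties / 48
  sigma <- sqrt(pmax(sig2, 0))
  list(RK = RK, pos = D > 0, mu = mu, sigma = sigma,
       cc = ifelse(sigma > 0, 0.5 / sigma, 0),
       degenerate = sig2 <= 0)
}

## two-sided p from the normal approximation with continuity correction
## (on the W scale: (|W - mu| - 1/2) / sigma); degenerate points get p = 1
.zToP <- function(z, prep) {
  p <- pmin(2 * pnorm(-pmax(abs(z) - prep$cc, 0)), 1)
  p[prep$degenerate] <- 1
  p
}

.signedRankZ <- function(prep, flips) {
  ## flips: +-1 per subject; flipped difference positive iff pos XOR (flip<0)
  pos <- prep$pos
  if (any(flips < 0)) pos[flips < 0, ] <- !pos[flips < 0, , drop = FALSE]
  W <- colSums(prep$RK * pos)
  z <- (W - prep$mu) / prep$sigma
  z[prep$degenerate] <- 0
  z
}

#' Pointwise Wilcoxon z and p maps
#'
#' Computes, for every (channel, bin) point, the normal-approximation
#' Wilcoxon z-score and its two-sided p-value. For independent groups this
#' is the rank-sum (Mann-Whitney) statistic, `z = (W - mu_W) / sigma_W` with
#' the tie-corrected variance; for paired data the signed-rank statistic
#' with zero differences dropped and ties mid-ranked. Positive z means the
#' first argument is larger. The two-sided p applies the standard continuity
#' correction, `2 * Phi(-(|W - mu| - 1/2) / sigma)`, which keeps the normal
#' approximation within 0.05 of the exact enumeration p down to n = 4;
#' z itself is the uncorrected `(W - mu) / sigma`, since it is also the
#' cluster-mass ingredient. Points where all observations are identical
#' across both groups are flagged degenerate and assigned z = 0, p = 1.
#'
#' @param a,b subject x channel x bin arrays; for `paired = TRUE`, `b` may
#'   be NULL, in which case `a` is taken as per-subject difference maps
#' @param paired paired (signed-rank) or independent (rank-sum) design
#' @param binAxis optional numeric axis of the bin dimension (Hz or ms)
#' @return a [PointStatMap-class]
#' @export
pointwiseWilcoxon <- function(a, b = NULL, paired = FALSE, binAxis = NULL) {
  if (paired) {
    D <- if (is.null(b)) a else a - b
    if (dim(D)[1L] < 2L) stop("need >= 2 subjects")
    Df <- .flatten3(D)
    prep <- .signedRankPrep(Df)
    z <- .signedRankZ(prep, rep(1, nrow(Df)))
    deg <- prep$degenerate
    testType <- "signed_rank_paired"
    nChan <- attr(Df, "nChan"); nBin <- attr(Df, "nBin")
    channels <- attr(Df, "channels")
  } else {
    if (is.null(b)) stop("independent design needs both groups")
    if (dim(a)[1L] < 2L || dim(b)[1L] < 2L)
      stop("need >= 2 observations per group")
    Af <- .flatten3(a); Bf <- .flatten3(b)
    prep <- .rankSumPrep(rbind(Af, Bf), nrow(Af))
    z <- .rankSumZ(prep, seq_len(nrow(Af)))
    deg <- prep$degenerate
    testType <- "rank_sum_independent"
    nChan <- attr(Af, "nChan"); nBin <- attr(Af, "nBin")
    channels <- attr(Af, "channels")
  }
  p <- .zToP(z, prep)
  dimn <- list(channels, NULL)
  new("PointStatMap",
      z = matrix(z, nChan, nBin, dimnames = dimn),
      p = matrix(p, nChan, nBin, dimnames = dimn),
      testType = testType,
      binAxis = binAxis %||% as.numeric(seq_len(nBin)),
      degenerate = matrix(deg, nChan, nBin, dimnames = dimn))
}

## Lattice edges of the channel x bin grid: same-bin neighboring channels
## plus same-channel adjacent bins. Node id = chan + (bin-1)*nChan.
.latticeEdges <- function(adj, nBin) {
  nChan <- nrow(adj)
  pr <- which(adj & upper.tri(adj), arr.ind = TRUE)
  spatial <- NULL
  if (nrow(pr)) {
    off <- rep((seq_len(nBin) - 1L) * nChan, each = nrow(pr))
    spatial <- cbind(rep(pr[, 1L], nBin) + off, rep(pr[, 2L], nBin) + off)
  }
  temporal <- NULL
  if (nBin > 1L) {
    ids <- seq_len(nChan * (nBin - 1L))
    temporal <- cbind(ids, ids + nChan)
  }
  e <- rbind(spatial, temporal)
  if (is.null(e)) e <- matrix(integer(), 0L, 2L)
  e
}

## Cluster masses for one z map (fast path shared with the permutation
## loop). Returns list(mass, membership, supra).
.clusterMasses <- function(z, p, pThreshold, edges, nChan) {
  supra <- which(p < pThreshold)
  if (!length(supra)) return(list(mass = numeric(), membership = integer(),
                                  supra = integer()))
  pos <- z > 0
  inSup <- logical(length(z))
  inSup[supra] <- TRUE
  e1 <- edges[, 1L]; e2 <- edges[, 2L]
  keep <- inSup[e1] & inSup[e2] & (pos[e1] == pos[e2])
  map <- integer(length(z))
  map[supra] <- seq_along(supra)
  g <- igraph::make_graph(
    edges = as.vector(rbind(map[e1[keep]], map[e2[keep]])),
    n = length(supra), directed = FALSE)
  memb <- igraph::components(g)$membership
  mass <- as.vector(rowsum(z[supra], memb))
  list(mass = mass, membership = memb, supra = supra)
}

#' Form candidate clusters from a pointwise statistic map
#'
#' Points with p below the cluster-forming threshold become nodes; edges
#' connect same-channel adjacent bins and same-bin spatially neighboring
#' channels (per the montage graph); connected components are split by the
#' sign of z. Clusters are ordered deterministically by their first point
#' (channel index, then bin).
#'
#' @param map a [PointStatMap-class]
#' @param montage a [MontageGraph-class] covering the map's channels
#' @param pThreshold cluster-forming threshold in (0,1), default 0.05
#' @return list of clusters, each with `points` (data.frame channel, bin,
#'   z), `mass` (summed z), `sign`; `permP` is NA until scored by
#'   [permutationTest()]
#' @export
formClusters <- function(map, montage, pThreshold = 0.05) {
  stopifnot(pThreshold > 0, pThreshold < 1)
  channels <- rownames(map@z)
  if (!all(channels %in% rownames(montage@adjacency)))
    stop("montage does not cover the map's channels")
  adj <- montage@adjacency[channels, channels]
  nChan <- length(channels)
  nBin <- ncol(map@z)
  edges <- .latticeEdges(adj, nBin)
  cm <- .clusterMasses(as.vector(map@z), as.vector(map@p), pThreshold,
                       edges, nChan)
  if (!length(cm$supra)) return(list())
  out <- lapply(seq_along(cm$mass), function(ci) {
    ids <- cm$supra[cm$membership == ci]
    chanIdx <- (ids - 1L) %% nChan + 1L
    binIdx <- (ids - 1L) %/% nChan + 1L
    o <- order(chanIdx, binIdx)
    list(points = data.frame(channel = channels[chanIdx[o]],
                             bin = binIdx[o],
                             z = map@z[cbind(chanIdx[o], binIdx[o])]),
         mass = cm$mass[ci], sign = sign(cm$mass[ci]), permP = NA_real_)
  })
  first <- vapply(out, function(cl) {
    ci <- match(cl$points$channel[1L], channels)
    ci * 1e6 + cl$points$bin[1L]
  }, numeric(1))
  out[order(first)]
}

#' Cluster-based permutation test with summed-z cluster mass
#'
#' The observed map of pointwise Wilcoxon z-scores is thresholded and
#' clustered ([formClusters()]); each cluster's mass is its summed z. The
#' null distribution of the maximum absolute cluster mass is built by
#' relabeling: group labels are permuted for the independent design, per-
#' subject condition signs are flipped for the paired design. The Monte-
#' Carlo cluster p-value uses the +1 correction,
#' `(1 + #{null >= |mass|}) / (1 + nPerm)`, so it is never exactly zero;
#' with `exhaustive = TRUE` all distinct relabelings are enumerated instead
#' (including the identity) and the p-value is the exact proportion.
#'
#' @param a,b subject x channel x bin arrays (see [pointwiseWilcoxon()])
#' @param design `"independent"` or `"paired"`
#' @param montage a [MontageGraph-class]
#' @param nPerm Monte-Carlo permutations (>= 100)
#' @param pThreshold cluster-forming threshold (two-sided), default 0.05
#' @param seed integer seed for the permutation draws
#' @param exhaustive enumerate all relabelings (paired: 2^n sign patterns;
#'   independent: all label assignments); errors beyond `maxEnum`
#' @param maxEnum safety cap on exhaustive enumeration size
#' @param binAxis optional numeric bin axis (Hz or ms)
#' @return a [ClusterTestResult-class]
#' @export
permutationTest <- function(a, b = NULL,
                            design = c("independent", "paired"),
                            montage = standardMontage(), nPerm = 1000,
                            pThreshold = 0.05, seed = 1,
                            exhaustive = FALSE, maxEnum = 2^20,
                            binAxis = NULL) {
  design <- match.arg(design)
  paired <- design == "paired"
  map <- pointwiseWilcoxon(a, b, paired = paired, binAxis = binAxis)
  channels <- rownames(map@z)
  adj <- montage@adjacency[channels, channels]
  nChan <- length(channels)
  nBin <- ncol(map@z)
  edges <- .latticeEdges(adj, nBin)
  clusters <- formClusters(map, montage, pThreshold)

  if (paired) {
    D <- if (is.null(b)) a else a - b
    Df <- .flatten3(D)
    N <- nrow(Df)
    if (2^N < 2) stop("insufficient subjects for any distinct permutation")
    prep <- .signedRankPrep(Df)
    zFun <- function(lab) .signedRankZ(prep, lab)
    if (exhaustive) {
      if (2^N > maxEnum) stop("exhaustive enumeration too large")
      labs <- lapply(0:(2^N - 1), function(k)
        1 - 2 * as.integer(intToBits(k)[seq_len(N)]))
    }
    drawLab <- function() sample(c(-1, 1), N, replace = TRUE)
  } else {
    if (is.null(b)) stop("independent design needs both groups")
    Af <- .flatten3(a); Bf <- .flatten3(b)
    nA <- nrow(Af)
    N <- nA + nrow(Bf)
    if (choose(N, nA) < 2)
      stop("insufficient subjects for any distinct permutation")
    prep <- .rankSumPrep(rbind(Af, Bf), nA)
    zFun <- function(lab) .rankSumZ(prep, lab)
    if (exhaustive) {
      if (choose(N, nA) > maxEnum) stop("exhaustive enumeration too large")
      labs <- asplit(utils::combn(N, nA), 2L)
    }
    drawLab <- function() sample.int(N, nA)
  }

  nullStat <- function(lab) {
    z <- zFun(lab)
    cm <- .clusterMasses(z, .zToP(z, prep), pThreshold, edges, nChan)
    if (length(cm$mass)) max(abs(cm$mass)) else 0
  }

  if (exhaustive) {
    nullMax <- vapply(labs, nullStat, numeric(1))
    nUsed <- length(labs)
    pFun <- function(m) mean(nullMax >= abs(m))
  } else {
    if (nPerm < 100) stop("nPerm must be >= 100")
    nullMax <- withSeed(seed, vapply(seq_len(nPerm), function(i)
      nullStat(drawLab()), numeric(1)))
    nUsed <- as.integer(nPerm)
    pFun <- function(m) (1 + sum(nullMax >= abs(m))) / (1 + nPerm)
  }
  clusters <- lapply(clusters, function(cl) {
    cl$permP <- pFun(cl$mass)
    cl
  })
  new("ClusterTestResult", clusters = clusters, pointMap = map,
      nullMax = nullMax, nPerm = nUsed, exhaustive = exhaustive,
      seed = as.integer(seed),
      settings = list(design = design, pThreshold = pThreshold,
                      channels = channels, nBins = nBin))
}

#' Tabular summary of a cluster test
#'
#' @param result a [ClusterTestResult-class]
#' @return data.frame: cluster, nPoints, channels, binMin, binMax, mass,
#'   sign, permP
#' @export
clusterSummary <- function(result) {
  if (!length(result@clusters))
    return(data.frame(cluster = integer(), nPoints = integer(),
                      channels = character(), binMin = integer(),
                      binMax = integer(), mass = numeric(),
                      sign = numeric(), permP = numeric()))
  do.call(rbind, lapply(seq_along(result@clusters), function(i) {
    cl <- result@clusters[[i]]
    data.frame(cluster = i, nPoints = nrow(cl$points),
               channels = paste(unique(cl$points$channel), collapse = ","),
               binMin = min(cl$points$bin), binMax = max(cl$points$bin),
               mass = cl$mass, sign = cl$sign, permP = cl$permP)
  }))
}

#' Per-channel significance bars
#'
#' Bin intervals of one channel covered by clusters below each significance
#' level, in the convention of difference-spectrum plots (small bars at
#' p < 0.05, larger bars at p < 0.01).
#'
#' @param result a [ClusterTestResult-class]
#' @param channel channel label
#' @param levels significance levels, default 0.05 and 0.01
#' @return data.frame: level, binStart, binEnd (contiguous runs merged)
#' @export
significanceBars <- function(result, channel, levels = c(0.05, 0.01)) {
  if (!channel %in% result@settings$channels) stop("unknown channel ", channel)
  out <- data.frame(level = numeric(), binStart = integer(),
                    binEnd = integer())
  for (lev in levels) {
    bins <- sort(unique(unlist(lapply(result@clusters, function(cl)
      if (cl$permP < lev) cl$points$bin[cl$points$channel == channel]))))
    if (!length(bins)) next
    runStart <- bins[c(TRUE, diff(bins) > 1)]
    runEnd <- bins[c(diff(bins) > 1, TRUE)]
    out <- rbind(out, data.frame(level = lev, binStart = runStart,
                                 binEnd = runEnd))
  }
  out
}
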