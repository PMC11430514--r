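# Wilcoxon z maps, cluster formation, and the summed-z permutation test.

# small helper: wrap a subjects x points matrix as subjects x channels x bins
asMaps <- function(m, nChan, channels = tenTwentyLabels()[seq_len(nChan)]) {
  nBin <- ncol(m) / nChan
  array(m, c(nrow(m), nChan, nBin), dimnames = list(NULL, channels, NULL))
}

test_that("signed-rank z matches the closed form for all-positive differences", {
  # paired differences 1..8, no ties: W = 36, mu = 18, sigma = sqrt(51)
  d <- matrix(1:8, 8, 1)
  a <- array(d, c(8, 1, 1), dimnames = list(NULL, "Cz", NULL))
  map <- pointwiseWilcoxon(a, paired = TRUE)
  expect_equal(unname(map@z[1, 1]), (36 - 18) / sqrt(8 * 9 * 17 / 24))
  expect_equal(unname(map@z[1, 1]), 2.5205, tolerance = 1e-4)
  # sign reflects direction: negated differences flip z
  mapNeg <- pointwiseWilcoxon(-a, paired = TRUE)
  expect_equal(mapNeg@z, -map@z)
})

test_that("identical paired groups are degenerate with p = 1", {
  a <- array(rnorm(6 * 2 * 3), c(6, 2, 3),
             dimnames = list(NULL, c("Cz", "Pz"), NULL))
  map <- pointwiseWilcoxon(a, a, paired = TRUE)
  expect_true(all(map@p == 1))
  expect_true(all(map@z == 0))
  expect_true(all(map@degenerate))
})

test_that("normal-approximation p is within 0.05 of exact enumeration (n <= 9)", {
  set.seed(31)
  for (n in c(6, 8, 9)) {
    for (rep in 1:5) {
      d <- round(rnorm(n, 0.4, 1), 2)
      if (all(d == 0)) next
      a <- array(d, c(n, 1, 1), dimnames = list(NULL, "Cz", NULL))
      map <- pointwiseWilcoxon(a, paired = TRUE)
      expect_lt(abs(map@p[1, 1] - exactSignedRankP(d)), 0.05)
    }
  }
})

test_that("rank-sum z agrees with the reference implementation", {
  set.seed(8)
  x <- rnorm(9, 1); y <- rnorm(12)
  a <- array(x, c(9, 1, 1), dimnames = list(NULL, "Cz", NULL))
  b <- array(y, c(12, 1, 1), dimnames = list(NULL, "Cz", NULL))
  map <- pointwiseWilcoxon(a, b)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(unname(map@p[1, 1]), ref$p.value, tolerance = 1e-10)
  # direction: a shifted up gives positive z
  expect_gt(map@z[1, 1], 0)
  # tie correction: heavily tied data still matches
  xt <- rep(c(1, 2), c(4, 4)); yt <- rep(c(1, 2, 3), c(2, 4, 2))
  at <- array(xt, c(8, 1, 1), dimnames = list(NULL, "Cz", NULL))
  bt <- array(yt, c(8, 1, 1), dimnames = list(NULL, "Cz", NULL))
  mt <- pointwiseWilcoxon(at, bt)
  rt <- wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
  expect_equal(unname(mt@p[1, 1]), rt$p.value, tolerance = 1e-10)
})

test_that("cluster formation follows adjacency, sign and determinism rules", {
  m <- standardMontage()
  nChan <- 19; nBin <- 5
  z <- matrix(0, nChan, nBin, dimnames = list(tenTwentyLabels(), NULL))
  # single supra-threshold point
  z["Cz", 3] <- 4
  p <- pmin(2 * pnorm(-abs(z)), 1)
  map <- new("PointStatMap", z = z, p = p, testType = "rank_sum_independent",
             binAxis = as.numeric(1:nBin),
             degenerate = matrix(FALSE, nChan, nBin,
                                 dimnames = dimnames(z)))
  cl <- formClusters(map, m, 0.05)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 4)
  expect_equal(nrow(cl[[1]]$points), 1)

  # two supra points on non-adjacent channels, same bin -> two clusters
  z[] <- 0; z["F7", 2] <- 4; z["O2", 2] <- 4
  map@z <- z; map@p <- pmin(2 * pnorm(-abs(z)), 1)
  cl2 <- formClusters(map, m, 0.05)
  expect_length(cl2, 2)

  # 3-bin run on one channel: one cluster, additive mass
  z[] <- 0; z["Pz", 2:4] <- c(3, 4, 5)
  map@z <- z; map@p <- pmin(2 * pnorm(-abs(z)), 1)
  cl3 <- formClusters(map, m, 0.05)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$mass, 12)

  # opposite signs on adjacent points split clusters
  z[] <- 0; z["Pz", 2] <- 4; z["Pz", 3] <- -4
  map@z <- z; map@p <- pmin(2 * pnorm(-abs(z)), 1)
  expect_length(formClusters(map, m, 0.05), 2)
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration (paired)", {
  set.seed(5)
  n <- 6   # smallest n where a paired point can pass the 0.05 threshold
  m <- standardMontage()
  eff <- matrix(rep(c(3, 0), c(3, 16)), 19, 6)  # effect on 3 channels
  dat <- asMaps(matrix(rnorm(n * 19 * 6, sd = 1), n), 19)
  dat <- dat + rep(1, n) %o% eff
  exh <- permutationTest(dat, design = "paired", montage = m,
                         exhaustive = TRUE)
  mc <- permutationTest(dat, design = "paired", montage = m,
                        nPerm = 10000, seed = 4)
  expect_gt(length(exh@clusters), 0)
  expect_equal(exh@nPerm, 2^n)
  for (i in seq_along(exh@clusters)) {
    expect_lt(abs(exh@clusters[[i]]$permP - mc@clusters[[i]]$permP),
              2 / sqrt(10000) + 1e-12)
  }
})

test_that("null distribution is invariant to subject relabeling (exhaustive)", {
  set.seed(6)
  dat <- asMaps(matrix(rnorm(6 * 4 * 5), 6), 4)
  m <- standardMontage()
  r1 <- permutationTest(dat, design = "paired", montage = m,
                        exhaustive = TRUE)
  r2 <- permutationTest(dat[c(3, 1, 6, 2, 5, 4), , , drop = FALSE],
                        design = "paired", montage = m, exhaustive = TRUE)
  expect_equal(sort(r1@nullMax), sort(r2@nullMax), tolerance = 1e-12)
})

test_that("stronger injected effects never increase the cluster p (matched seeds)", {
  set.seed(9)
  base <- matrix(rnorm(16 * 19 * 8), 16)
  m <- standardMontage()
  pAtEffect <- vapply(c(0.5, 1.0, 2.0), function(es) {
    shift <- matrix(0, 19, 8); shift[1:4, 3:6] <- es
    a <- asMaps(base[1:8, , drop = FALSE], 19) + rep(1, 8) %o% shift
    b <- asMaps(base[9:16, , drop = FALSE], 19)
    r <- permutationTest(a, b, design = "independent", montage = m,
                         nPerm = 400, seed = 11)
    if (length(r@clusters))
      min(vapply(r@clusters, `[[`, numeric(1), "permP")) else 1
  }, numeric(1))
  expect_true(all(diff(pAtEffect) <= 0))
})

test_that("input contract errors fire", {
  m <- standardMontage()
  a <- asMaps(matrix(rnorm(4 * 19 * 3), 4), 19)
  expect_error(permutationTest(a, design = "independent", montage = m),
               "both groups")
  expect_error(permutationTest(a, a, design = "independent", montage = m,
                               nPerm = 10), ">= 100")
  one <- asMaps(matrix(rnorm(19 * 3), 1), 19)
  expect_error(pointwiseWilcoxon(one, paired = TRUE), ">= 2")
})

test_that("significance bars follow the two threshold levels", {
  mkResult <- function(permPs) {
    pts <- function(bins) data.frame(channel = "Cz", bin = bins,
                                     z = rep(3, length(bins)))
    clusters <- Map(function(p, bins)
      list(points = pts(bins), mass = 3 * length(bins), sign = 1, permP = p),
      permPs, list(1:3, 6:7))
    z <- matrix(0, 1, 10, dimnames = list("Cz", NULL))
    map <- new("PointStatMap", z = z, p = z + 1,
               testType = "rank_sum_independent", binAxis = as.numeric(1:10),
               degenerate = z == 1)
    new("ClusterTestResult", clusters = unname(clusters), pointMap = map,
        nullMax = numeric(0), nPerm = 100L, exhaustive = FALSE,
        seed = 1L, settings = list(channels = "Cz", nBins = 10))
  }
  r <- mkResult(c(0.003, 0.03))
  bars <- significanceBars(r, "Cz")
  expect_equal(nrow(bars[bars$level == 0.05, ]), 2)  # both clusters
  expect_equal(nrow(bars[bars$level == 0.01, ]), 1)  # only the 0.003 one
  expect_equal(bars[bars$level == 0.01, ]$binStart, 1)
  rNone <- mkResult(c(0.2, 0.6))
  expect_equal(nrow(significanceBars(rNone, "Cz")), 0)
  expect_error(significanceBars(r, "O1"), "unknown channel")
})
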