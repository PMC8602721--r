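test_that("Pearson correlation matches hand arithmetic", {
  fx <- getFixtures()
  h <- fx$histories[[1]]
  ## truth against itself: r = 1 on every defined channel
  r <- pearsonR(h, h)
  expect_true(all(abs(r[!is.na(r)] - 1) < 1e-12))

  ## 5-point toy vectors vs the covariance/sd definition
  x <- c(1, 2, 4, 7, 11); y <- c(2, 1, 5, 8, 9)
  byHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cor(x, y), byHand)

  ## anti-correlated centered series
  expect_equal(cor(x, -x), -1)
})

test_that("rank-statistic AUC matches its contracts and the trapezoid", {
  ## perfect separation
  expect_equal(rocAuc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  ## label-independent scores on large n
  set.seed(14)
  s <- rnorm(4000); y <- sample(c(0, 1), 4000, replace = TRUE)
  expect_lt(abs(rocAuc(s, y) - 0.5), 0.05)
  ## 6-point toy with one tie vs exhaustive pair counting
  s <- c(0.1, 0.4, 0.4, 0.6, 0.8, 0.9)
  y <- c(0, 0, 1, 0, 1, 1)
  pairs <- 0
  for (i in which(y == 1)) for (j in which(y == 0))
    pairs <- pairs + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(rocAuc(s, y), pairs / (3 * 3))
  ## single-class truth is undefined
  expect_true(is.na(rocAuc(s, rep(1, 6))))
  ## rank AUC equals trapezoidal ROC integration on random toy sets
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    s <- round(runif(n), 1)                     # provokes ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    rc <- rocCurve(s, y)
    trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    expect_equal(rocAuc(s, y), trap, tolerance = 1e-12)
  }
})

test_that("pixel accuracy counts matches within the ROI", {
  a <- PhenotypeMap(matrix(c(10L, 11L, 12L, 13L, 14L, 10L, 11L, 12L, 13L,
                             14L), 2, 5))
  expect_equal(pixelAccuracy(a, a, matrix(TRUE, 2, 5)), 1)
  b <- PhenotypeMap(matrix(c(11L, 10L, 13L, 12L, 10L, 14L, 12L, 11L, 14L,
                             13L), 2, 5))
  expect_equal(pixelAccuracy(a, b, matrix(TRUE, 2, 5)), 0)
  ## 10-pixel toy with 7 matches
  c1 <- phenotypeMatrix(a)
  c1[1, 1] <- 11L; c1[2, 2] <- 10L; c1[1, 3] <- 10L
  expect_equal(pixelAccuracy(a, PhenotypeMap(c1), matrix(TRUE, 2, 5)), 0.7)
  ## empty mask undefined
  expect_true(is.na(pixelAccuracy(a, a, matrix(FALSE, 2, 5))))
  ## invariance under simultaneous palette permutation
  perm <- function(m) {
    x <- phenotypeMatrix(m)
    y <- x
    y[x == 10L] <- 14L; y[x == 14L] <- 10L
    PhenotypeMap(y)
  }
  expect_equal(pixelAccuracy(perm(a), perm(b), matrix(TRUE, 2, 5)),
               pixelAccuracy(a, b, matrix(TRUE, 2, 5)))
})

test_that("performance indexes match hand counts on a toy domain", {
  d <- toyCallusDomain(8, 8)
  cal <- callusMask(d)

  allOf <- function(code) {
    codes <- regionMap(d)
    codes[cal] <- code
    PhenotypeMap(codes, d)
  }
  pi1 <- performanceIndexes(allOf(11L), d)      # all mature
  expect_equal(pi1$FM, 1); expect_equal(pi1$FR, 0)
  expect_equal(pi1$BIC, 1)
  expect_true(is.na(pi1$MBL))                   # unthreaded toy: undefined
  pi2 <- performanceIndexes(allOf(14L), d)      # all fibrous
  expect_equal(pi2$FS, 1); expect_equal(pi2$BA, 0)

  ## hand-placed phenotypes, audited by an independent pixel loop
  set.seed(16)
  codes <- regionMap(d)
  codes[cal] <- sample(c(10L, 11L, 12L, 13L, 14L), sum(cal), replace = TRUE)
  map <- PhenotypeMap(codes, d)
  got <- performanceIndexes(map, d)
  nM <- nR <- nS <- nBA <- nIface <- nIfaceBone <- 0L
  imp <- implantMask(d)
  for (i in 1:8) for (j in 1:8) {
    if (!cal[i, j]) next
    v <- codes[i, j]
    if (v == 11L) nM <- nM + 1L
    if (v == 10L) nR <- nR + 1L
    if (v %in% c(13L, 14L)) nS <- nS + 1L
    if (v %in% c(11L, 12L)) nBA <- nBA + 1L
    nbr <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    nbr <- nbr[nbr[, 1] >= 1 & nbr[, 1] <= 8 &
               nbr[, 2] >= 1 & nbr[, 2] <= 8, , drop = FALSE]
    if (any(imp[nbr])) {
      nIface <- nIface + 1L
      if (v %in% c(11L, 12L)) nIfaceBone <- nIfaceBone + 1L
    }
  }
  expect_equal(got$FM, nM / sum(cal))
  expect_equal(got$FR, nR / sum(cal))
  expect_equal(got$FS, nS / sum(cal))
  expect_equal(got$BA, nBA)
  expect_equal(got$BIC, nIfaceBone / nIface)
})

test_that("MBL counts resorption above the first thread near the implant", {
  p <- ImplantParams(bodyLength = 20, bodyRadius = 4, threadPitch = 6,
                     threadDepth = 2, collarHeight = 2)
  d <- buildImplantProfile(p, GridSpec(32, 16, 0.3), callusWidth = 2)
  ftr <- firstThreadRow(d)
  expect_false(is.na(ftr))
  cal <- callusMask(d)
  codes <- regionMap(d)
  codes[cal] <- 11L
  band <- cal & MechanoHeal:::.dilate(implantMask(d), 2L)
  above <- which(band & row(codes) < ftr)
  expect_gt(length(above), 0)
  codes[above[1]] <- 10L                        # one marginal resorption pixel
  got <- performanceIndexes(PhenotypeMap(codes, d), d)
  expect_equal(got$MBL, 1)
  expect_equal(got$FM, mean(codes[cal] == 11L))
})

test_that("evaluateRun aggregates and audits its bookkeeping", {
  fx <- getFixtures()
  hs <- unname(fx$histories)
  rep <- evaluateRun(hs, hs)                    # truth vs itself
  expect_true(all(abs(rep$fieldR[!is.na(rep$fieldR)] - 1) < 1e-12))
  expect_equal(rep$finalAccuracy, 1)
  expect_true(all(rep$accuracyPerDay == 1))
  ## index-level r needs >= 2 cases; with 2 identical runs it is 1 or NA
  expect_true(all(is.na(rep$indexR) | abs(rep$indexR - 1) < 1e-12))
  ## single-case report: cross-case correlation undefined
  rep1 <- evaluateRun(hs[1], hs[1])
  expect_true(all(is.na(rep1$indexR)))
  ## mismatched day counts are an explicit failure
  short <- runHealing(fx$domains[[1]], healingConfig(days = 1))
  expect_error(evaluateRun(list(short), hs[1]), "day counts differ")
  ## scatter bookkeeping at the full-scale frame
  expect_equal(scatterRecordCount(GridSpec(), 35, 14), 5350800)
  expect_equal(rep$counts$scatterRecords, 32 * 16 * 5 * 2)
})
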