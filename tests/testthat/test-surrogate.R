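test_that("the day-pair builder enumerates ordered pairs", {
  ## a 36-state history (days 0..35) yields 630 pairs
  h36 <- dummyHistory(35)
  dp <- makeDayPairs(h36)
  expect_equal(nrow(dp$pairs), 630L)
  expect_true(all(dp$pairs$i < dp$pairs$j))

  ## 2-day history: a single pair
  expect_equal(nrow(makeDayPairs(dummyHistory(1))$pairs), 1L)

  ## 11-day history vs brute-force enumeration
  h11 <- dummyHistory(10)
  dp11 <- makeDayPairs(h11)
  brute <- 0L
  for (i in 0:10) for (j in 0:10) if (i < j) brute <- brute + 1L
  expect_equal(nrow(dp11$pairs), brute)         # choose(11, 2) = 55

  ## gap cap
  dpg <- makeDayPairs(h11, maxGap = 1)
  expect_equal(nrow(dpg$pairs), 10L)
  expect_true(all(dpg$pairs$gap == 1L))

  ## sub-2-day history: empty dataset, not an error
  expect_equal(nrow(makeDayPairs(dummyHistory(0))$pairs), 0L)
})

test_that("field net honors the channel contracts", {
  b <- getToyBundle()
  fx <- getFixtures()
  m <- materialDay(fx$histories[[1]], 0)
  p <- predictFieldNet(b@fieldNet, m)
  expect_named(p, c("eps1", "eps2", "eps3", "vx", "vy", "nNext"))
  expect_identical(dim(p$eps1), dim(m@E))
  ## sorted principal-strain contract on the prediction
  expect_true(all(p$eps1 >= p$eps2 & p$eps2 >= p$eps3))
  expect_true(all(p$nNext >= 0 & p$nNext <= 1))
  ## input side: a 210 x 52 image flattens to 10,920 feature vectors
  z <- matrix(0.1, 210, 52)
  f <- PhysicalFields(z, z, z, z, z, z * 0)
  F <- MechanoHeal:::.pixelFeatures(f, matrix(TRUE, 210, 52))
  expect_identical(dim(F), c(10920L, 5L))
})

test_that("a single-class problem is learned everywhere", {
  ## history with one phenotype in every callus label
  d <- toyCallusDomain(10, 10)
  h <- dummyHistory(2, d)
  cal <- callusMask(d)
  for (t in 1:3) {
    codes <- regionMap(d)
    codes[cal] <- 13L                           # all cartilage
    h@days[[t]]$phenotype <- PhenotypeMap(codes, d)
  }
  pc <- trainPixelClassifier(list(h), list(epochs = 15L, seed = 1L))
  pr <- predictPixelClassifier(pc, fieldsDay(h, 0), d)
  expect_true(all(phenotypeMatrix(pr$map)[cal] == 13L))
})

test_that("linearly separable pixels reach perfect held-out accuracy", {
  d <- toyCallusDomain(12, 10)
  cal <- callusMask(d)
  set.seed(99)
  mk <- function() {
    e1 <- matrix(rnorm(120, 0, 1), 12, 10)
    z <- matrix(0, 12, 10)
    flds <- PhysicalFields(eps1 = pmax(e1, 0) + abs(e1),
                           eps2 = z, eps3 = -abs(e1) - pmax(-e1, 0),
                           vx = z, vy = z, nNext = z)
    codes <- regionMap(d)
    codes[cal] <- ifelse(e1[cal] > 0, 11L, 13L) # sign separates the classes
    list(fields = flds, map = PhenotypeMap(codes, d))
  }
  ## features of day t-1 predict the label of day t (gap-1 pairs)
  h <- dummyHistory(4, d)
  states <- lapply(1:5, function(i) mk())
  for (t in 0:4) h@days[[t + 1]]$fields <- states[[t + 1]]$fields
  for (t in 1:4) h@days[[t + 1]]$phenotype <- states[[t]]$map
  pc <- trainPixelClassifier(list(h), list(epochs = 30L, seed = 2L))
  hold <- mk()
  pr <- predictPixelClassifier(pc, hold$fields, d)
  truth <- phenotypeMatrix(hold$map)[cal]
  expect_equal(mean(phenotypeMatrix(pr$map)[cal] == truth), 1.0)
})

test_that("the denoiser restores singular pixels and respects masks", {
  b <- getToyBundle()
  fx <- getFixtures()
  d <- fx$domains[[1]]
  cal <- callusMask(d)
  calIdx <- which(cal, arr.ind = TRUE)

  ## find a training-distribution map with a pixel whose 4-neighborhood is
  ## phenotype-uniform, and inject one singular pixel there
  target <- NULL
  for (day in 1:5) {
    codes <- phenotypeMatrix(phenotypeDay(fx$histories[[1]], day))
    for (r in seq_len(nrow(calIdx))) {
      i <- calIdx[r, 1]; j <- calIdx[r, 2]
      nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(codes) &
               nb[, 2] >= 1 & nb[, 2] <= ncol(codes), , drop = FALSE]
      if (all(codes[nb] == codes[i, j])) { target <- c(i, j); break }
    }
    if (!is.null(target)) break
  }
  expect_false(is.null(target))                 # fixtures guarantee one
  v <- codes[target[1], target[2]]
  other <- setdiff(c(10L, 11L, 12L, 13L, 14L), v)[1]
  corrupted <- codes
  corrupted[target[1], target[2]] <- other
  den <- denoiseMap(PhenotypeMap(corrupted, d), b@denoiserNet, d)
  expect_identical(phenotypeMatrix(den)[target[1], target[2]], v)

  ## non-callus pixels are never touched
  expect_identical(phenotypeMatrix(den)[!cal], codes[!cal])

  ## singular-pixel count does not increase on training-distribution maps
  countSingular <- function(m) {
    cnt <- 0L
    for (r in seq_len(nrow(calIdx))) {
      i <- calIdx[r, 1]; j <- calIdx[r, 2]
      nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(m) &
               nb[, 2] >= 1 & nb[, 2] <= ncol(m), , drop = FALSE]
      if (all(m[nb] != m[i, j])) cnt <- cnt + 1L
    }
    cnt
  }
  raw <- predictPixelClassifier(b@pixelClassifier,
                                fieldsDay(fx$histories[[1]], 3),
                                d)$map
  denRaw <- denoiseMap(raw, b@denoiserNet, d)
  expect_lte(countSingular(phenotypeMatrix(denRaw)),
             countSingular(phenotypeMatrix(raw)))
})

test_that("the resorption corrector only moves between its two classes", {
  b <- getToyBundle()
  fx <- getFixtures()
  d <- fx$domains[[1]]
  f <- fieldsDay(fx$histories[[1]], 3)
  map <- phenotypeDay(fx$histories[[1]], 4)
  out <- correctResorption(map, f, b@resorptionForest, d)
  m0 <- phenotypeMatrix(map); m1 <- phenotypeMatrix(out)
  cand <- m0 == 10L | m0 == 11L
  expect_identical(m1[!cand], m0[!cand])        # audit: others untouched
  expect_true(all(m1[cand] %in% c(10L, 11L)))

  ## no candidates -> unchanged
  codes <- m0
  codes[codes %in% c(10L, 11L)] <- 13L
  noCand <- PhenotypeMap(codes, d)
  out2 <- correctResorption(noCand, f, b@resorptionForest, d)
  expect_identical(phenotypeMatrix(out2), codes)

  ## standard forest property, logged by the trainer
  if (!is.null(b@resorptionForest))
    expect_gte(b@resorptionForest$trainAccuracy,
               b@resorptionForest$oobAccuracy)
})

test_that("rollout is deterministic and beats an untrained bundle", {
  b <- getToyBundle()
  fx <- getFixtures()
  d <- fx$domains[[1]]
  h <- fx$histories[[1]]
  m0 <- materialDay(h, 0)

  r1 <- rollout(m0, d, b, T = 5, config = healingConfig(days = 5))
  r2 <- rollout(m0, d, b, T = 5, config = healingConfig(days = 5))
  expect_equal(nDays(r1), 6L)
  expect_true(isSurrogate(r1))
  expect_identical(phenotypeMatrix(phenotypeDay(r1, 5)),
                   phenotypeMatrix(phenotypeDay(r2, 5)))
  expect_identical(fieldsDay(r1, 5)@eps1, fieldsDay(r2, 5)@eps1)

  ## untrained baseline: same architecture, random weights
  b0 <- b
  set.seed(1234)
  b0@fieldNet$model <- MechanoHeal:::.unetInit(4L, 6L, 9L, 2L)
  b0@pixelClassifier$model <- MechanoHeal:::.mlpInit(5L, c(64L, 64L, 64L),
                                                     5L)
  cal <- callusMask(d)
  truth <- phenotypeMatrix(phenotypeDay(h, 5))
  accT <- mean(phenotypeMatrix(phenotypeDay(r1, 5))[cal] == truth[cal])
  r0 <- rollout(m0, d, b0, T = 5, config = healingConfig(days = 5))
  acc0 <- mean(phenotypeMatrix(phenotypeDay(r0, 5))[cal] == truth[cal])
  expect_gt(accT, acc0)
})

test_that("the case split leaks no day pair across train and test", {
  fx <- getFixtures()
  hs <- unname(fx$histories)
  b <- trainSurrogate(hs, surrogateConfig(
    seed = 3, testFraction = 0.5,
    fieldNet = list(epochs = 1L, baseFilters = 3L),
    pixelClassifier = list(epochs = 1L),
    denoiser = list(epochs = 1L, baseFilters = 3L, curriculumGap = 1L)))
  ids <- vapply(hs, caseId, character(1))
  expect_setequal(c(b@meta$trainCases, b@meta$testCases), ids)
  expect_length(intersect(b@meta$trainCases, b@meta$testCases), 0L)
})

test_that("denoise + correction do not hurt raw classifier accuracy", {
  ## pipeline monotonicity at desk scale, averaged over the fixture cases
  b <- getToyBundle()
  fx <- getFixtures()
  rawAcc <- c(); fullAcc <- c()
  for (ci in 1:2) {
    d <- fx$domains[[ci]]
    cal <- callusMask(d)
    h <- fx$histories[[ci]]
    for (t in 1:5) {
      f <- fieldsDay(h, t - 1)
      truth <- phenotypeMatrix(phenotypeDay(h, t))
      raw <- predictPixelClassifier(b@pixelClassifier, f, d)$map
      den <- denoiseMap(raw, b@denoiserNet, d)
      cor <- correctResorption(den, f, b@resorptionForest, d)
      rawAcc <- c(rawAcc, mean(phenotypeMatrix(raw)[cal] == truth[cal]))
      fullAcc <- c(fullAcc, mean(phenotypeMatrix(cor)[cal] == truth[cal]))
    }
  }
  expect_gte(mean(fullAcc), mean(rawAcc) - 0.02)
})
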