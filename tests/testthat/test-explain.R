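test_that("a single positive linear layer puts all relevance on the active input", {
  m <- list(kind = "mlp", din = 3, dout = 2,
            layers = list(list(W = matrix(c(2, 1, 3, 1, 2, 1), 3, 2),
                               b = c(0, 0))))
  x <- matrix(c(0, 1, 0), 1, 3)                 # one-hot
  r <- dtdRelevanceMLP(m, x, target = 1L, inputRule = "zplus")
  expect_equal(r$relevance[1, ], c(0, 1, 0))    # all on the active input
  expect_equal(r$score, 1)                      # = x . W[,1]
})

test_that("two-layer relevance equals the hand-computed z+ propagation", {
  ## x = (1, 2); W1 = [[1, .5], [.25, 1]]; W2 = (2, 1)
  ## z1 = (1.5, 2.5); out = 3 + 2.5 = 5.5
  ## layer 2 z+: contributions (3, 2.5)      -> R_hidden = (3, 2.5)
  ## layer 1 z+: j1 (1, .5)/1.5, j2 (.5, 2)/2.5 -> R_input = (2.5, 3)
  m <- list(kind = "mlp", din = 2, dout = 1,
            layers = list(list(W = matrix(c(1, 0.25, 0.5, 1), 2, 2),
                               b = c(0, 0)),
                          list(W = matrix(c(2, 1), 2, 1), b = 0)))
  r <- dtdRelevanceMLP(m, matrix(c(1, 2), 1), target = 1L,
                       inputRule = "zplus")
  expect_equal(r$score, 5.5)
  expect_equal(r$relevance[1, ], c(2.5, 3))
  expect_equal(sum(r$relevance), r$score)       # conservation
})

test_that("relevance is conserved on random small networks", {
  set.seed(77)
  worst <- 0
  for (rep in 1:100) {
    sizes <- sample(3:6, 3, replace = TRUE)
    m <- MechanoHeal:::.mlpInit(sizes[1], sizes[2], sizes[3])
    for (l in seq_along(m$layers)) m$layers[[l]]$b[] <- 0
    X <- matrix(runif(2 * sizes[1]), 2, sizes[1])
    r <- dtdRelevanceMLP(m, X, target = "predicted", inputRule = "zplus")
    ok <- r$score > 1e-6
    if (any(ok)) {
      rel <- abs(rowSums(r$relevance)[ok] - r$score[ok]) / r$score[ok]
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("z+ relevance is non-negative", {
  set.seed(78)
  m <- MechanoHeal:::.mlpInit(4, c(5, 5), 3)
  for (l in seq_along(m$layers)) m$layers[[l]]$b[] <- 0
  X <- matrix(runif(40), 10, 4)
  r <- dtdRelevanceMLP(m, X, inputRule = "zplus")
  expect_true(all(r$relevance >= -1e-12))
})

test_that("U-Net relevance is conserved through the full graph", {
  set.seed(79)
  for (rep in 1:3) {
    u <- MechanoHeal:::.unetInit(2, 3, baseFilters = 6, depth = 2)
    strip <- function(node) {
      for (i in seq_along(node$branches)) node$branches[[i]]$b[] <- 0
      node
    }
    for (l in 1:2) { u$enc[[l]] <- strip(u$enc[[l]])
                     u$dec[[l]] <- strip(u$dec[[l]]) }
    u$bottom <- strip(u$bottom)
    u$out$b[] <- 0
    x <- array(runif(8 * 8 * 2), c(8, 8, 2))    # non-negative inputs
    r <- dtdRelevanceUnet(u, x, channel = 1)
    if (r$score > 1e-8)
      expect_lt(abs(sum(r$relevance) - r$score) / r$score, 1e-3)
  }
})

test_that("dominant property follows argmax with documented tie-breaks", {
  expect_equal(as.character(dominantProperty(matrix(c(0, 0, 0, 1, 0), 1))),
               "vx")
  expect_equal(as.character(dominantProperty(matrix(c(1, 1, 0, 0, 0), 1))),
               "epsI")                          # tie -> channel order
  expect_equal(as.character(dominantProperty(matrix(0, 1, 5))),
               "undetermined")
  ## brute-force agreement on random fields
  set.seed(80)
  R <- matrix(runif(500), 100, 5)
  got <- dominantProperty(R)
  want <- apply(R, 1, which.max)
  expect_equal(as.integer(got), want)
  ## invariant to positive rescaling
  expect_equal(as.character(dominantProperty(R * 37.5)),
               as.character(got))
})

test_that("the phase diagram is consistent with the classifier and audited", {
  fx <- getFixtures()
  h <- fx$histories[[1]]
  th <- phenotypeThresholds()
  pd <- phaseDiagram(h, th)
  cal <- sum(callusMask(domain(h)))
  T <- nDays(h) - 1L
  ## counting audit: records + dropped zeros = callus pixels x days
  expect_equal(nrow(pd$data) + pd$nDropped, cal * T)
  ## region assignment matches classifyPhenotype's left-closed rule
  iv <- findInterval(pd$data$S, c(0, th$breaks))
  expect_identical(pd$data$phenotype, names(MechanoHeal:::.PHEN_DIFF)[iv])
  ## boundary value: S exactly on a break goes to the interval it opens
  expect_equal(findInterval(0.267, c(0, th$breaks)), 3L)  # immature

  ## dominant-property attribution rides along per record
  b <- getToyBundle()
  cal <- callusMask(domain(h))
  dominantFun <- function(fields, day) {
    F <- MechanoHeal:::.pixelFeatures(fields, cal)
    st <- b@pixelClassifier$stats
    Fs <- sweep(sweep(F, 2, st$mu), 2, st$sd, `/`)
    dominantProperty(dtdRelevanceMLP(b@pixelClassifier$model,
                                     Fs)$relevance)
  }
  pd2 <- phaseDiagram(h, th, dominantFun = dominantFun, days = 1:2)
  expect_true("dominant" %in% names(pd2$data))
  expect_true(all(pd2$data$dominant %in%
                  c("epsI", "epsII", "epsIII", "vx", "vy", "undetermined")))
})

test_that("geometry importance equals a brute-force sort of relevance", {
  b <- getToyBundle()
  fx <- getFixtures()
  r <- rollout(materialDay(fx$histories[[1]], 0), fx$domains[[1]], b,
               T = 2, config = healingConfig(days = 2))
  gi <- geometryImportance(r, b, topFraction = 0.05)
  for (t in 1:3) {
    tot <- gi$relevance[[t]]
    k <- max(1L, ceiling(0.05 * length(tot)))
    want <- order(tot, decreasing = TRUE)[seq_len(k)]
    want <- want[tot[want] > 0]
    got <- which(gi$masks[[t]])
    expect_setequal(got, want)
  }
  ## identical inputs give identical pixel sets
  gi2 <- geometryImportance(r, b, topFraction = 0.05)
  expect_identical(gi$masks, gi2$masks)
  ## topFraction = 1 selects every positive-relevance pixel
  giAll <- geometryImportance(r, b, topFraction = 1)
  expect_true(all(which(gi$masks[[1]]) %in% which(giAll$masks[[1]])))
})

test_that("swapping identical implants changes nothing outside (or inside)", {
  b <- getToyBundle()
  fx <- getFixtures()
  d <- fx$domains[[1]]
  ext <- range(which(rowSums(implantMask(d)) > 0))
  rr <- c(ext[1] + 3L, ext[2] - 3L)
  rep <- swapExperiment(d, d, rr, b, T = 2,
                        config = healingConfig(days = 2))
  expect_equal(unname(rep$agreement["aVsAba"]), 1)
  expect_equal(unname(rep$agreement["bVsBab"]), 1)
  expect_equal(unname(rep$agreement["aVsB"]), 1)

  ## double bookkeeping: agreement by mask arithmetic vs pixel loop
  r1 <- rep$rollouts$a; r2 <- rep$rollouts$aba
  outside <- setdiff(seq_len(gridSpec(d)@nrow), (rr[1] + 1L):rr[2])
  m1 <- phenotypeMatrix(phenotypeDay(r1, 2))
  m2 <- phenotypeMatrix(phenotypeDay(r2, 2))
  agreeLoop <- 0L; tot <- 0L
  for (i in outside) for (j in seq_len(ncol(m1))) {
    tot <- tot + 1L
    if (m1[i, j] == m2[i, j]) agreeLoop <- agreeLoop + 1L
  }
  expect_equal(unname(rep$agreement["aVsAba"]), agreeLoop / tot)
})
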