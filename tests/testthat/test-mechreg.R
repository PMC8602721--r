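test_that("octahedral shear strain is the standard invariant", {
  expect_equal(octahedralShearStrain(0.02, 0.02, 0.02), 0)
  expect_equal(octahedralShearStrain(0.03, 0, -0.03),
               (2 / 3) * sqrt(0.0009 + 0.0009 + 0.0036))
  ## symmetric under permutation
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  v <- c(0.04, -0.01, -0.05)
  ref <- octahedralShearStrain(v[1], v[2], v[3])
  for (p in perms)
    expect_equal(octahedralShearStrain(v[p[1]], v[p[2]], v[p[3]]), ref)
})

test_that("the stimulus follows S = gamma/a + nu/b", {
  expect_equal(stimulus(0, 0), 0)
  expect_equal(stimulus(0.0375, 0), 1)
  expect_equal(stimulus(0, 3), 1)
  expect_equal(stimulus(0.075, 1.5), 2.5)
  expect_error(stimulus(-0.01, 0), "non-negative")
  expect_error(stimulus(0, -1), "non-negative")
})

test_that("the stimulus is monotone in both inputs", {
  set.seed(8)
  g1 <- matrix(runif(64, 0, 0.1), 8); v1 <- matrix(runif(64, 0, 5), 8)
  g2 <- g1 + matrix(runif(64, 0, 0.05), 8)
  v2 <- v1 + matrix(runif(64, 0, 2), 8)
  expect_true(all(stimulus(g2, v2) >= stimulus(g1, v1)))
})

test_that("phenotype classification matches a brute-force interval rule", {
  d <- toyCallusDomain(8, 8)
  th <- phenotypeThresholds()
  cal <- callusMask(d)

  S <- matrix(0, 8, 8)
  m <- classifyPhenotype(S, th, d)
  expect_true(all(phenotypeMatrix(m)[cal] == phenotypeCodes()[["resorption"]]))

  S[] <- 10
  m <- classifyPhenotype(S, th, d)
  expect_true(all(phenotypeMatrix(m)[cal] == phenotypeCodes()[["fibrous"]]))

  ## random field vs per-pixel if/else oracle
  set.seed(13)
  S <- matrix(exp(runif(64, log(1e-4), log(30))), 8, 8)
  m <- phenotypeMatrix(classifyPhenotype(S, th, d))
  for (p in which(cal)) {
    s <- S[p]
    want <- if (s < 0.01) 10L else if (s < 0.267) 11L else if (s < 1) 12L
            else if (s < 3) 13L else 14L
    expect_identical(m[p], want)
  }
  ## non-callus pixels keep the fixed region code
  expect_identical(m[!cal], regionMap(d)[!cal])

  ## boundary values belong to the interval they open (left-closed)
  S[] <- 0.01
  m <- classifyPhenotype(S, th, d)
  expect_true(all(phenotypeMatrix(m)[cal] == phenotypeCodes()[["mature"]]))
})

test_that("property blending is the exact convex combination", {
  n <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  Xg <- list(E = 0.2, nuP = 0.167, k = 1e-14)
  Xd <- list(E = matrix(6000, 2, 2), nuP = matrix(0.3, 2, 2),
             k = matrix(3.7e-13, 2, 2))
  out <- blendProperties(n, Xg, Xd)
  expect_identical(out$E[1, 1], 0.2)            # n = 0 -> X_g bit-exact
  expect_identical(out$E[2, 1], 6000)           # n = 1 -> X_d bit-exact
  expect_equal(out$E[1, 2], (0.2 + 6000) / 2)   # midpoint
  expect_equal(out$nuP[2, 2], 0.75 * 0.167 + 0.25 * 0.3)
  ## convexity: every value inside [min, max] of the endpoints
  for (p in c("E", "nuP", "k"))
    expect_true(all(out[[p]] >= min(Xg[[p]], Xd[[p]]) - 1e-15 &
                    out[[p]] <= max(Xg[[p]], Xd[[p]]) + 1e-15))
  expect_error(blendProperties(matrix(1.5, 1, 1), Xg,
                               lapply(Xd, function(m) m[1, 1, drop = FALSE])),
               "\\[0, 1\\]")
})

test_that("history smoothing averages over a window of at most 10", {
  mk <- function(E) MaterialField(E = matrix(E, 2, 2),
                                  nuP = matrix(0.3, 2, 2),
                                  k = matrix(1e-14, 2, 2),
                                  n = matrix(0, 2, 2))
  cur <- mk(10)
  ## empty history: identity
  expect_identical(smoothHistory(cur)@E, cur@E)
  ## constants: identity
  out <- smoothHistory(cur, rep(list(cur), 9))
  expect_equal(out@E, cur@E)
  ## E = 1..10 -> mean 5.5
  out <- smoothHistory(mk(10), lapply(9:1, mk))
  expect_equal(out@E[1, 1], 5.5)
  ## more than 9 previous days: only the most recent 9 are used
  out <- smoothHistory(mk(10), lapply(c(999, 9:1), mk))
  expect_equal(out@E[1, 1], 5.5)
  ## convex hull: smoothed values never exit the window's range
  set.seed(4)
  prev <- lapply(runif(5, 1, 100), mk)
  cur <- mk(50)
  out <- smoothHistory(cur, prev)
  rng <- range(c(50, vapply(prev, function(m) m@E[1, 1], numeric(1))))
  expect_true(all(out@E >= rng[1] & out@E <= rng[2]))
})

test_that("materialFromPhenotype uses the table and the blend", {
  d <- toyCallusDomain(8, 8)
  tab <- defaultMaterialTable()
  codes <- regionMap(d)
  codes[callusMask(d)] <- 11L                   # all mature
  map <- PhenotypeMap(codes, d)
  n <- matrix(0.5, 8, 8)
  m <- materialFromPhenotype(map, d, n, tab)
  gE <- tab$E[tab$name == "granulation"]
  matE <- tab$E[tab$name == "mature"]
  expect_equal(m@E[callusMask(d)][1], (gE + matE) / 2)
  expect_equal(m@E[implantMask(d)][1], tab$E[tab$name == "implant"])
})

test_that("the healing driver produces a valid, deterministic history", {
  fx <- getFixtures()
  d <- fx$domains[[1]]
  ## T = 0: only the day-0 state
  h0 <- runHealing(d, healingConfig(days = 0))
  expect_equal(nDays(h0), 1L)
  ## day-0 contract: granulation callus, zero concentration
  p0 <- phenotypeMatrix(phenotypeDay(h0, 0))
  expect_true(all(p0[callusMask(d)] == phenotypeCodes()[["granulation"]]))
  expect_equal(max(materialDay(h0, 0)@n), 0)

  h <- fx$histories[[1]]
  expect_equal(nDays(h), 6L)
  ## regions conserved: fixed codes never change across days
  cal <- callusMask(d)
  for (t in 0:5)
    expect_identical(phenotypeMatrix(phenotypeDay(h, t))[!cal],
                     regionMap(d)[!cal])
  ## determinism: an independent rerun is identical
  h2 <- runHealing(d, healingConfig(days = 5), caseId = caseId(h))
  expect_identical(phenotypeMatrix(phenotypeDay(h2, 5)),
                   phenotypeMatrix(phenotypeDay(h, 5)))
  expect_identical(fieldsDay(h2, 5)@eps1, fieldsDay(h, 5)@eps1)
})

test_that("a 36-record history covers days 0 through 35", {
  ## structural check on the driver's day indexing without a full-scale run
  fxh <- dummyHistory(35)
  expect_equal(nDays(fxh), 36L)
  expect_identical(names(fxh@days)[1], "day0")
  expect_identical(names(fxh@days)[36], "day35")
  expect_error(dayRecord(fxh, 36), "no record")
})
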