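## Solver checks: closed-form patch test, dense loop-assembled oracles on
## tiny grids (helper-oracles.R), and the physical contracts of the
## three solves.

test_that("uniform compression patch test recovers the closed form", {
  d <- toyCallusDomain(16, 12)
  m <- uniformMaterial(d, E = 1000, nuP = 0.3, k = 1e-14)
  s <- solveElasticity(d, m, loadDisplacement = 8, bcMode = "patch")
  H <- 16 * 0.3e-3
  eyy <- -8e-6 / H
  exx <- 0.3 * 8e-6 / H
  expect_equal(max(abs(s$eps3 - eyy)) / abs(eyy), 0, tolerance = 1e-6)
  expect_equal(max(abs(s$eps1 - exx)) / abs(exx), 0, tolerance = 1e-6)
  ## out-of-plane channel is the plane-stress value
  ez <- -0.3 / 0.7 * (exx + eyy)
  expect_equal(s$eps2[3, 3], ez, tolerance = 1e-6)
})

test_that("zero applied displacement yields zero strain", {
  d <- toyCallusDomain(10, 8)
  m <- uniformMaterial(d, E = 500, nuP = 0.25, k = 1e-14)
  s <- solveElasticity(d, m, loadDisplacement = 0)
  expect_equal(max(abs(s$eps1)), 0, tolerance = 1e-15)
  expect_equal(max(abs(s$eps3)), 0, tolerance = 1e-15)
})

test_that("principal strains are sorted everywhere on a real case", {
  fx <- getFixtures()
  f <- fieldsDay(fx$histories[[1]], 2)
  expect_true(all(f@eps1 >= f@eps2 - 1e-12))
  expect_true(all(f@eps2 >= f@eps3 - 1e-12))
})

test_that("sparse elasticity matches the dense loop-assembled oracle", {
  d <- buildImplantProfile(ImplantParams(8, 3, 4, 1), GridSpec(16, 12, 0.3),
                           callusWidth = 2, corticalThickness = 2)
  set.seed(31)
  g <- gridSpec(d)
  E <- matrix(exp(runif(16 * 12, log(1), log(1000))), 16, 12)
  nu <- matrix(runif(16 * 12, 0.1, 0.45), 16, 12)
  m <- MaterialField(E = E, nuP = nu, k = matrix(1e-14, 16, 12),
                     n = matrix(0, 16, 12))
  s <- solveElasticity(d, m, loadDisplacement = 8)
  o <- denseElasticOracle(d, m, loadDisplacement = 8)
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(rel(s$exx, o$exx), 1e-8)
  expect_lt(rel(s$eyy, o$eyy), 1e-8)
  expect_lt(rel(s$gxy, o$gxy), 1e-8)
})

test_that("implant pixels carry exactly zero fluid velocity", {
  fx <- getFixtures()
  h <- fx$histories[[1]]
  for (t in c(0, 3)) {
    f <- fieldsDay(h, t)
    imp <- implantMask(domain(h))
    expect_identical(max(abs(f@vx[imp])), 0)
    expect_identical(max(abs(f@vy[imp])), 0)
  }
})

test_that("zero volumetric strain in a homogeneous medium gives no flow", {
  d <- toyCallusDomain(10, 8)
  m <- uniformMaterial(d, E = 10, nuP = 0.3, k = 1e-14,
                       respectImplant = FALSE)
  strains <- list(epsVol = matrix(0, 10, 8))
  f <- solveFluid(d, m, strains)
  expect_equal(max(abs(f$p)), 0, tolerance = 1e-18)
  expect_equal(max(abs(f$vx)) + max(abs(f$vy)), 0, tolerance = 1e-18)
})

test_that("sparse consolidation matches a dense direct solve on 8x8", {
  d <- toyCallusDomain(8, 8)
  set.seed(5)
  k <- matrix(exp(runif(64, log(1e-15), log(1e-13))), 8, 8)
  k[implantMask(d)] <- 0
  m <- MaterialField(E = matrix(10, 8, 8), nuP = matrix(0.3, 8, 8),
                     k = k, n = matrix(0, 8, 8))
  src <- matrix(0, 8, 8)
  src[5, 5] <- -0.01                      # single source pixel
  strains <- list(epsVol = src)
  f <- solveFluid(d, m, strains)
  pOracle <- denseFluidOracle(d, m, strains)
  expect_lt(max(abs(f$p - pOracle)) / max(abs(pOracle)), 1e-8)
})

test_that("all-zero permeability is an explicit failure", {
  d <- toyCallusDomain(8, 8)
  m <- MaterialField(E = matrix(10, 8, 8), nuP = matrix(0.3, 8, 8),
                     k = matrix(0, 8, 8), n = matrix(0, 8, 8))
  expect_error(solveFluid(d, m, list(epsVol = matrix(0, 8, 8))),
               "permeability")
})

test_that("stem-cell diffusion honors its contracts", {
  d <- toyCallusDomain(12, 10)
  cal <- callusMask(d)
  ## saturation is a steady state
  n1 <- matrix(0, 12, 10); n1[cal] <- 1
  out <- diffuseStemCells(d, n1)
  expect_equal(out[cal], n1[cal], tolerance = 1e-12)
  ## non-callus pixels never change
  n0 <- matrix(runif(120), 12, 10)
  out <- diffuseStemCells(d, n0)
  expect_identical(out[!cal & !cellOriginMask(d)],
                   n0[!cal & !cellOriginMask(d)])
  ## maximum principle
  expect_true(all(out[cal] >= 0 & out[cal] <= 1))
})

test_that("concentration decreases monotonically with distance from the origin", {
  ## homogeneous strip: callus rows 2..11 in one column block, origin at the
  ## bottom row of the callus
  nr <- 14L; nc <- 6L
  codes <- regionCodes()
  region <- matrix(codes[["cancellous"]], nr, nc)
  region[, 1:2] <- codes[["implant"]]
  region[2:11, 3:4] <- codes[["callus"]]
  origin <- matrix(FALSE, nr, nc); origin[11, 3:4] <- TRUE
  load <- matrix(FALSE, nr, nc); load[1, 1:2] <- TRUE
  d <- new("ImplantDomain", grid = GridSpec(nr, nc, 0.3), region = region,
           cellOriginMask = origin, loadMask = load,
           firstThreadRow = NA_integer_, params = NULL)
  n <- matrix(0, nr, nc)
  for (t in 1:3) n <- diffuseStemCells(d, n, D = 0.01)
  prof <- n[11:2, 3]                      # increasing distance from origin
  expect_true(all(diff(prof) <= 1e-12))
  expect_equal(prof[1], 1)                # clamped at the origin
})

test_that("per-pixel concentration is non-decreasing over days", {
  fx <- getFixtures()
  h <- fx$histories[[1]]
  for (t in 0:(nDays(h) - 2)) {
    a <- materialDay(h, t)@n
    b <- materialDay(h, t + 1)@n
    expect_true(all(b - a >= -1e-10))
  }
})

test_that("a mirrored domain diffuses to the mirrored concentration", {
  d <- toyCallusDomain(12, 10)
  flip <- function(m) m[, ncol(m):1]
  dm <- new("ImplantDomain", grid = d@grid, region = flip(regionMap(d)),
            cellOriginMask = flip(cellOriginMask(d)),
            loadMask = flip(loadMask(d)),
            firstThreadRow = NA_integer_, params = NULL)
  n0 <- matrix(runif(120), 12, 10)
  a <- diffuseStemCells(d, n0)
  b <- diffuseStemCells(dm, flip(n0))
  expect_equal(flip(b), a, tolerance = 1e-12)
})
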