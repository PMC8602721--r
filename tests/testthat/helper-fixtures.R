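## Shared fixtures, built in code and cached for the session.

.fixtureEnv <- new.env(parent = emptyenv())

## two tiny simulated cases (32 x 16, 5 days)
getFixtures <- function() {
  if (is.null(.fixtureEnv$fx)) .fixtureEnv$fx <- makeFixtures(days = 5L,
                                                              seed = 42L)
  .fixtureEnv$fx
}

## a modestly trained surrogate bundle on the fixture cases (memorization
## regime: both cases in training)
getToyBundle <- function() {
  if (is.null(.fixtureEnv$bundle)) {
    fx <- getFixtures()
    cfg <- surrogateConfig(seed = 7, testFraction = 0,
                           fieldNet = list(epochs = 25L, baseFilters = 9L,
                                           patience = 10L),
                           pixelClassifier = list(epochs = 40L),
                           denoiser = list(epochs = 8L,
                                           curriculumGap = 2L))
    .fixtureEnv$bundle <- trainSurrogate(unname(fx$histories), cfg)
  }
  .fixtureEnv$bundle
}

## a minimal all-callus domain for synthetic classifier/denoiser problems
toyCallusDomain <- function(nr = 12L, nc = 10L) {
  codes <- regionCodes()
  region <- matrix(codes[["callus"]], nr, nc)
  region[, 1:2] <- codes[["implant"]]
  region[nr, ] <- codes[["cancellous"]]
  region[, nc] <- codes[["cancellous"]]
  origin <- matrix(FALSE, nr, nc)
  origin[nr - 1L, 3:(nc - 1L)] <- TRUE
  load <- matrix(FALSE, nr, nc)
  load[1L, 1:2] <- TRUE
  new("ImplantDomain", grid = GridSpec(nr, nc, 0.3), region = region,
      cellOriginMask = origin, loadMask = load,
      firstThreadRow = NA_integer_, params = NULL)
}

## a lightweight fake history: T+1 day records sharing small dummy objects
## (for combinatorial checks that never touch the record contents)
dummyHistory <- function(T, domain = NULL) {
  if (is.null(domain)) domain <- toyCallusDomain()
  g <- gridSpec(domain)
  z <- matrix(0.1, g@nrow, g@ncol)
  mat <- MaterialField(E = z + 1, nuP = z * 0 + 0.3, k = z * 0, n = z * 0)
  flds <- PhysicalFields(z, z, z, z, z, z * 0)
  phen <- PhenotypeMap(regionMap(domain))
  days <- rep(list(list(material = mat, fields = flds, phenotype = phen)),
              T + 1L)
  names(days) <- paste0("day", 0:T)
  new("HealingHistory", caseId = "dummy", domain = domain, days = days,
      params = list(), surrogate = FALSE)
}

## generic even-odd point-in-polygon (ray cast in +x), used as the
## rasterization oracle
pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## staircase polygon of an implant profile (rounded radii), y downward
profilePolygon <- function(params) {
  r <- pmax(1L, as.integer(round(MechanoHeal:::.radiusProfile(params))))
  L <- length(r)
  vx <- c(0); vy <- c(0)
  for (i in seq_len(L)) {
    vx <- c(vx, r[i], r[i])
    vy <- c(vy, i - 1L, i)
  }
  vx <- c(vx, 0)
  vy <- c(vy, L)
  list(x = vx, y = vy)
}
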