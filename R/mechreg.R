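## The mechano-regulatory update loop: biophysical stimulus, phenotype
## classification, material blending by stem-cell concentration, history
## smoothing, and the day-0..35 ground-truth driver.

#' Stimulus constants
#'
#' The cell stimulus factor is `S = gamma / a + nu / b`, where `gamma` is the
#' octahedral shear strain and `nu` the interstitial fluid speed.  Defaults
#' are the established mechano-regulation constants `a = 0.0375`
#' (dimensionless) and `b = 3` um/s.
#'
#' @param a strain stimulus constant (> 0).
#' @param b fluid stimulus constant in um/s (> 0).
#' @return validated list with elements `a` and `b`.
#' @export
stimulusParams <- function(a = 0.0375, b = 3) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L, b > 0)
  list(a = a, b = b)
}

#' Phenotype thresholds on the stimulus S
#'
#' Strictly increasing breakpoints partitioning `[0, Inf)` into the five
#' tissue phenotypes, ordered by increasing stimulus: resorption, mature
#' bone, immature bone, cartilage, fibrous tissue.  Intervals are
#' left-closed: a value equal to a breakpoint belongs to the interval that
#' the breakpoint opens.  Defaults follow the established
#' mechano-regulation literature: resorption `S < 0.01`, mature bone
#' `0.01 <= S < 0.267`, immature bone `0.267 <= S < 1`, cartilage
#' `1 <= S < 3`, fibrous tissue `S >= 3`.
#'
#' @param breaks four strictly increasing positive breakpoints.
#' @return validated list with `breaks` and the ordered `codes`.
#' @export
phenotypeThresholds <- function(breaks = c(0.01, 0.267, 1, 3)) {
  stopifnot(length(breaks) == 4L, all(is.finite(breaks)),
            all(diff(breaks) > 0), all(breaks > 0))
  list(breaks = breaks, codes = unname(.PHEN_DIFF))
}

#' Octahedral shear strain
#'
#' The standard distortional invariant
#' `gamma = (2/3) sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)`, applied
#' elementwise to the three principal strain fields.  Symmetric in its
#' arguments and zero for hydrostatic states.
#'
#' @param eps1,eps2,eps3 principal strain matrices (or scalars).
#' @return matrix (or scalar) of non-negative shear strains.
#' @examples
#' octahedralShearStrain(0.03, 0, -0.03)
#' @export
octahedralShearStrain <- function(eps1, eps2, eps3) {
  (2 / 3) * sqrt((eps1 - eps2)^2 + (eps2 - eps3)^2 + (eps3 - eps1)^2)
}

#' Cell stimulus factor
#'
#' `S = gamma / a + nu / b` with `gamma` the octahedral shear strain and
#' `nu` the fluid speed magnitude `sqrt(vx^2 + vy^2)` in um/s.
#'
#' @param gamma octahedral shear strain (>= 0), matrix or scalar.
#' @param nu fluid speed in um/s (>= 0), matrix or scalar.
#' @param params a [stimulusParams()] list.
#' @return the stimulus field.
#' @examples
#' stimulus(0.0375, 0)  # == 1
#' stimulus(0, 3)       # == 1
#' @export
stimulus <- function(gamma, nu, params = stimulusParams()) {
  if (any(gamma < 0)) stop("gamma must be non-negative")
  if (any(nu < 0)) stop("nu must be non-negative")
  gamma / params$a + nu / params$b
}

#' Classify tissue phenotypes from the stimulus field
#'
#' Assigns each callus pixel the phenotype of its left-closed stimulus
#' interval; all non-callus pixels keep their fixed region code.
#'
#' @param S stimulus matrix, finite on callus pixels.
#' @param thresholds a [phenotypeThresholds()] list.
#' @param domain the [ImplantDomain-class].
#' @return a [PhenotypeMap-class].
#' @export
classifyPhenotype <- function(S, thresholds, domain) {
  cal <- callusMask(domain)
  if (any(!is.finite(S[cal]))) stop("S must be finite on callus pixels")
  codes <- regionMap(domain)
  iv <- findInterval(S[cal], c(0, thresholds$breaks),
                     left.open = FALSE)         # 1..5, left-closed
  codes[cal] <- thresholds$codes[iv]
  PhenotypeMap(codes, domain)
}

#' Default per-phenotype material table
#'
#' Literature-standard poroelastic properties for each tissue phenotype and
#' each fixed region (E in MPa, Poisson's ratio, permeability in m^4/(N s)).
#' Resorption pixels are assigned granulation-like low stiffness so they
#' remain in the differentiation loop and can re-differentiate.  The implant
#' is Ti-6Al-4V (E = 110 GPa, nu = 0.3, impermeable); "outside" pixels carry
#' a near-void stiffness so the global stiffness matrix stays definite.
#'
#' @return data.frame with columns `code`, `name`, `E`, `nuP`, `k`, keyed by
#'   phenotype code.
#' @export
defaultMaterialTable <- function() {
  data.frame(
    code = c(0L, 1L, 2L, 3L, 4L, 10L, 11L, 12L, 13L, 14L),
    name = c("outside", "implant", "cortical", "cancellous", "granulation",
             "resorption", "mature", "immature", "cartilage", "fibrous"),
    E   = c(1e-3, 110000, 14800, 1850, 0.2, 0.2, 6000, 1000, 10, 2),
    nuP = c(0.3, 0.3, 0.3, 0.3, 0.167, 0.167, 0.3, 0.3, 0.167, 0.167),
    k   = c(0, 0, 1e-17, 3.7e-13, 1e-14, 1e-14, 3.7e-13, 1e-13, 5e-15,
            1e-14),
    stringsAsFactors = FALSE)
}

.tableLookup <- function(table, codes, prop) {
  m <- match(as.vector(codes), table$code)
  if (anyNA(m)) stop("material table is missing phenotype code(s): ",
                     paste(unique(codes[is.na(m)]), collapse = ", "))
  matrix(table[[prop]][m], nrow(codes), ncol(codes))
}

#' Blend granulation and differentiated material properties
#'
#' The effective property at each callus pixel is the convex combination
#' `X = (1 - n) X_g + n X_d` of the granulation-tissue property `X_g` and
#' the property `X_d` of the locally differentiated phenotype, weighted by
#' the stem-cell concentration `n` (a fraction of saturation, so the
#' saturation concentration is normalized to 1).
#'
#' @param n concentration matrix in `[0, 1]`.
#' @param Xg named list (`E`, `nuP`, `k`) of granulation properties
#'   (scalars or matrices).
#' @param Xd named list (`E`, `nuP`, `k`) of per-pixel differentiated
#'   properties (matrices).
#' @return named list (`E`, `nuP`, `k`) of blended matrices.
#' @export
blendProperties <- function(n, Xg, Xd) {
  if (any(n < 0 | n > 1)) stop("n must lie in [0, 1]")
  lapply(stats::setNames(nm = c("E", "nuP", "k")),
         function(p) (1 - n) * Xg[[p]] + n * Xd[[p]])
}

#' Smooth material properties over the recent history
#'
#' Per-pixel arithmetic mean of the current properties with those of up to
#' the nine previous days (window <= 10), applied to `E`, `nuP` and `k` to
#' avoid numerical instability of the day-to-day update.  The concentration
#' channel is not smoothed (it is governed by the diffusion solve).  With an
#' empty history the current field is returned unchanged.
#'
#' @param current a [MaterialField-class].
#' @param previous list of up to 9 most recent [MaterialField-class]s.
#' @return the smoothed [MaterialField-class].
#' @export
smoothHistory <- function(current, previous = list()) {
  if (length(previous) > 9L)
    previous <- previous[(length(previous) - 8L):length(previous)]
  all <- c(list(current), previous)
  w <- length(all)
  avg <- function(slotName)
    Reduce(`+`, lapply(all, function(m) slot(m, slotName))) / w
  MaterialField(E = avg("E"), nuP = avg("nuP"), k = avg("k"),
                n = current@n)
}

#' Assemble a material field from a phenotype map
#'
#' Fixed regions take their tabulated properties; callus pixels take the
#' blend of granulation and their differentiated phenotype's properties,
#' weighted by the local stem-cell concentration.
#'
#' @param map a [PhenotypeMap-class].
#' @param domain the [ImplantDomain-class].
#' @param n concentration matrix.
#' @param table material table (see [defaultMaterialTable()]).
#' @return a [MaterialField-class].
#' @export
materialFromPhenotype <- function(map, domain, n,
                                  table = defaultMaterialTable()) {
  codes <- phenotypeMatrix(map)
  cal <- callusMask(domain)
  gRow <- table[table$name == "granulation", ]
  Xd <- lapply(stats::setNames(nm = c("E", "nuP", "k")),
               function(p) .tableLookup(table, codes, p))
  bl <- blendProperties(n, Xg = list(E = gRow$E, nuP = gRow$nuP, k = gRow$k),
                        Xd = Xd)
  out <- Xd
  for (p in c("E", "nuP", "k")) out[[p]][cal] <- bl[[p]][cal]
  MaterialField(E = out$E, nuP = out$nuP, k = out$k, n = n)
}

#' Configuration for a healing simulation
#'
#' Bundles every tunable of the ground-truth simulator.  All entries have
#' documented defaults; the list is embedded in each produced history.
#'
#' @param days simulated days T (history covers days 0..T; default 35).
#' @param loadDisplacement occlusal displacement in um (default 8).
#' @param stimulus a [stimulusParams()] list.
#' @param thresholds a [phenotypeThresholds()] list.
#' @param materials material table (see [defaultMaterialTable()]).
#' @param D stem-cell diffusion coefficient, mm^2/day.
#' @param loadPeriod biting-cycle loading period in seconds (see
#'   [solveFluid()]).
#' @param dt time step in days.
#' @param smoothWindow number of previous days averaged into the material
#'   smoothing (default 9).
#' @return named list of settings.
#' @export
healingConfig <- function(days = 35L, loadDisplacement = 8,
                          stimulus = stimulusParams(),
                          thresholds = phenotypeThresholds(),
                          materials = defaultMaterialTable(),
                          D = 0.001, loadPeriod = 1, dt = 1,
                          smoothWindow = 9L) {
  list(days = as.integer(days), loadDisplacement = loadDisplacement,
       stimulus = stimulus, thresholds = thresholds, materials = materials,
       D = D, loadPeriod = loadPeriod, dt = dt,
       smoothWindow = as.integer(smoothWindow))
}

#' Run the mechano-regulatory healing simulation
#'
#' The ground-truth driver.  Day 0 starts with granulation tissue and zero
#' stem-cell concentration in the callus.  Each day the elastic and fluid
#' fields are solved for the current material state, the stimulus
#' `S = gamma/a + nu/b` classifies the next day's phenotypes, stem cells
#' diffuse one step, the material is re-blended from granulation and the
#' differentiated properties, and the properties are smoothed over the
#' recent history.  The run is fully deterministic.
#'
#' @param domain an [ImplantDomain-class].
#' @param config a [healingConfig()] list.
#' @param caseId case identifier stored in the history.
#' @return a [HealingHistory-class] with `days + 1` records.
#' @examples
#' d <- buildImplantProfile(ImplantParams(18, 4, 6, 2), GridSpec(32, 16))
#' h <- runHealing(d, healingConfig(days = 2))
#' nDays(h)
#' @export
runHealing <- function(domain, config = healingConfig(),
                       caseId = "case01") {
  cfg <- config
  codes <- regionMap(domain)
  cal <- callusMask(domain)
  phen <- codes
  phen[cal] <- phenotypeCodes()[["granulation"]]
  map <- PhenotypeMap(phen, domain)
  n <- matrix(0, nrow(codes), ncol(codes))
  mat <- materialFromPhenotype(map, domain, n, cfg$materials)
  rawHist <- list(mat)                     # unsmoothed blends, for smoothing
  records <- vector("list", cfg$days + 1L)

  for (t in 0:cfg$days) {
    el <- solveElasticity(domain, mat, cfg$loadDisplacement)
    fl <- solveFluid(domain, mat, el, cfg$loadPeriod)
    nNext <- diffuseStemCells(domain, n, cfg$dt, cfg$D)
    fields <- PhysicalFields(el$eps1, el$eps2, el$eps3, fl$vx, fl$vy, nNext)
    records[[t + 1L]] <- list(material = mat, fields = fields,
                              phenotype = map)
    if (t == cfg$days) break

    gam <- octahedralShearStrain(el$eps1, el$eps2, el$eps3)
    spd <- sqrt(fl$vx^2 + fl$vy^2)
    S <- stimulus(gam, spd, cfg$stimulus)
    map <- classifyPhenotype(S, cfg$thresholds, domain)
    raw <- materialFromPhenotype(map, domain, nNext, cfg$materials)
    prev <- tail(rawHist, cfg$smoothWindow)
    mat <- smoothHistory(raw, prev)
    rawHist <- c(rawHist, list(raw))
    n <- nNext
  }
  names(records) <- paste0("day", 0:cfg$days)
  new("HealingHistory", caseId = caseId, domain = domain, days = records,
      params = cfg, surrogate = FALSE)
}
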