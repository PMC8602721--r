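#' @import methods
#' @importFrom stats rnorm runif quantile sd var cor density dnorm predict
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

## ---- region / phenotype integer palettes -----------------------------------

#' Region and phenotype integer codes
#'
#' The structured grid carries two categorical layers with a shared, fixed
#' integer palette.  Region codes label the static anatomy; phenotype codes
#' label the tissue state that evolves in the callus during healing.
#'
#' Region codes: `0` outside, `1` implant, `2` cortical bone, `3` cancellous
#' bone, `4` callus (the cell-differentiation region).
#'
#' Phenotype codes: `0`--`3` mirror the fixed (non-differentiating) regions,
#' `4` is granulation tissue (the day-0 state of the callus), and the five
#' mechano-regulated phenotypes are `10` resorption, `11` mature bone,
#' `12` immature bone, `13` cartilage, `14` fibrous tissue.
#'
#' @return `regionCodes()` and `phenotypeCodes()` return named integer vectors.
#' @examples
#' regionCodes()
#' phenotypeCodes()
#' @export
regionCodes <- function() {
  c(outside = 0L, implant = 1L, cortical = 2L, cancellous = 3L, callus = 4L)
}

#' @rdname regionCodes
#' @export
phenotypeCodes <- function() {
  c(outside = 0L, implant = 1L, cortical = 2L, cancellous = 3L,
    granulation = 4L,
    resorption = 10L, mature = 11L, immature = 12L,
    cartilage = 13L, fibrous = 14L)
}

## the five S-driven phenotypes, in fixed channel order used everywhere
## (classifier classes, one-hot encodings, ROC curves)
.PHEN_DIFF <- c(resorption = 10L, mature = 11L, immature = 12L,
                cartilage = 13L, fibrous = 14L)

## ---- GridSpec ---------------------------------------------------------------

#' Structured grid specification
#'
#' The healing domain is a structured rectangular pixel grid: rows run axially
#' from the occlusal crest (row 1 at the top) downward, columns run radially
#' from the implant axis (column 1, the axisymmetric left edge) outward.  The
#' full-scale default is a 210 x 52 grid; desk-scale work uses smaller grids.
#'
#' @slot nrow integer, axial pixel count (>= 4).
#' @slot ncol integer, radial pixel count (>= 4).
#' @slot pixelSize numeric, physical edge length of one square pixel in mm.
#' @export
setClass("GridSpec",
  representation(nrow = "integer", ncol = "integer", pixelSize = "numeric"),
  prototype(nrow = 210L, ncol = 52L, pixelSize = 0.055)
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrow) != 1L || is.na(object@nrow) || object@nrow < 4L)
    msg <- c(msg, "nrow must be a single integer >= 4")
  if (length(object@ncol) != 1L || is.na(object@ncol) || object@ncol < 4L)
    msg <- c(msg, "ncol must be a single integer >= 4")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nrow,ncol grid dimensions in pixels (axial x radial).
#' @param pixelSize pixel edge length in mm.  The default (0.055 mm) makes a
#'   default-length implant span roughly 180 of the 210 axial rows, which keeps
#'   peri-implant strain magnitudes in the regime the stimulus thresholds
#'   expect.
#' @return A [GridSpec-class] object.
#' @examples
#' GridSpec(64, 32)
#' @export
GridSpec <- function(nrow = 210L, ncol = 52L, pixelSize = 0.055) {
  new("GridSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      pixelSize = as.numeric(pixelSize))
}

## ---- ImplantParams ----------------------------------------------------------

#' Parametric implant geometry
#'
#' Degrees of freedom of the axisymmetric half-profile, all lengths in pixels.
#' The implant is a core cylinder of radius `bodyRadius` with threads that
#' protrude outward by up to `threadDepth`, repeating every `threadPitch` rows.
#' `threadDepth` may be a vector (recycled over thread periods) so depth can
#' vary along the implant length.
#'
#' @slot bodyLength integer, rows of the threaded body below the collar.
#' @slot bodyRadius integer, columns of the implant core.
#' @slot threadPitch integer, rows per thread period.
#' @slot threadDepth numeric vector, outward thread protrusion in pixels
#'   (one value per thread, recycled).
#' @slot threadProfile `"triangular"`, `"trapezoidal"` or `"buttress"`.
#' @slot apexShape `"flat"`, `"rounded"` or `"pointed"`.
#' @slot collarHeight integer, rows of unthreaded collar at the top.
#' @export
setClass("ImplantParams",
  representation(bodyLength = "integer", bodyRadius = "integer",
                 threadPitch = "integer", threadDepth = "numeric",
                 threadProfile = "character", apexShape = "character",
                 collarHeight = "integer")
)

setValidity("ImplantParams", function(object) {
  msg <- character()
  if (object@bodyLength < 1L) msg <- c(msg, "bodyLength must be >= 1")
  if (object@bodyRadius < 1L) msg <- c(msg, "bodyRadius must be >= 1")
  if (object@threadPitch < 1L) msg <- c(msg, "threadPitch must be >= 1")
  if (any(object@threadDepth < 0))
    msg <- c(msg, "threadDepth must be non-negative")
  if (any(object@threadDepth >= object@bodyRadius))
    msg <- c(msg, "threadDepth must be < bodyRadius")
  if (!object@threadProfile %in% c("triangular", "trapezoidal", "buttress"))
    msg <- c(msg, "threadProfile must be triangular, trapezoidal or buttress")
  if (!object@apexShape %in% c("flat", "rounded", "pointed"))
    msg <- c(msg, "apexShape must be flat, rounded or pointed")
  if (object@collarHeight < 0L) msg <- c(msg, "collarHeight must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct implant geometry parameters
#'
#' @param bodyLength,bodyRadius,threadPitch,collarHeight lengths in pixels.
#' @param threadDepth outward thread protrusion in pixels; scalar or a vector
#'   giving one depth per thread (recycled along the body).  `0` degenerates
#'   to a straight cylinder.
#' @param threadProfile thread flank shape.
#' @param apexShape shape of the implant tip.
#' @return An [ImplantParams-class] object.
#' @examples
#' ImplantParams(bodyLength = 40, bodyRadius = 8, threadPitch = 8,
#'               threadDepth = 3)
#' @export
ImplantParams <- function(bodyLength, bodyRadius, threadPitch,
                          threadDepth = 0,
                          threadProfile = c("triangular", "trapezoidal",
                                            "buttress"),
                          apexShape = c("flat", "rounded", "pointed"),
                          collarHeight = 0L) {
  new("ImplantParams",
      bodyLength = as.integer(bodyLength),
      bodyRadius = as.integer(bodyRadius),
      threadPitch = as.integer(threadPitch),
      threadDepth = as.numeric(threadDepth),
      threadProfile = match.arg(threadProfile),
      apexShape = match.arg(apexShape),
      collarHeight = as.integer(collarHeight))
}

## ---- ImplantDomain ----------------------------------------------------------

#' Rasterized implant healing domain
#'
#' Per-pixel region labels for one implant case, plus the two boundary masks
#' the solvers need: the stem-cell Dirichlet source (`cellOriginMask`, the
#' callus boundary facing host bone) and the loading surface (`loadMask`, the
#' top row of implant pixels that receives the occlusal micro-displacement).
#'
#' @slot grid the [GridSpec-class].
#' @slot region integer matrix of [regionCodes()].
#' @slot cellOriginMask logical matrix, subset of the callus boundary.
#' @slot loadMask logical matrix, subset of the implant top row.
#' @slot firstThreadRow integer row index of the first thread crest (used by
#'   the marginal-bone-loss ROI), or `NA` for an unthreaded implant.
#' @slot params the generating [ImplantParams-class] (geometry provenance),
#'   or `NULL` for hand-built / swapped domains.
#' @export
setClass("ImplantDomain",
  representation(grid = "GridSpec", region = "matrix",
                 cellOriginMask = "matrix", loadMask = "matrix",
                 firstThreadRow = "integer", params = "ANY")
)

setValidity("ImplantDomain", function(object) {
  msg <- character()
  nr <- object@grid@nrow; nc <- object@grid@ncol
  if (!identical(dim(object@region), c(nr, nc)))
    msg <- c(msg, "region dims must match grid")
  if (!all(object@region %in% regionCodes()))
    msg <- c(msg, "region contains codes outside the palette")
  for (s in c("cellOriginMask", "loadMask")) {
    m <- slot(object, s)
    if (!is.logical(m) || !identical(dim(m), c(nr, nc)))
      msg <- c(msg, paste(s, "must be a logical matrix matching the grid"))
  }
  imp <- object@region == regionCodes()[["implant"]]
  if (!any(imp)) {
    msg <- c(msg, "domain has no implant pixels")
  } else {
    if (.nComponents4(imp) != 1L)
      msg <- c(msg, "implant pixels must form one 4-connected component")
    topImp <- min(which(rowSums(imp) > 0))
    if (any(object@loadMask & !imp) ||
        any(object@loadMask[-topImp, , drop = FALSE]))
      msg <- c(msg, "loadMask must lie on the top row of the implant")
  }
  cal <- object@region == regionCodes()[["callus"]]
  if (any(object@cellOriginMask & !cal))
    msg <- c(msg, "cellOriginMask must be a subset of the callus region")
  if (length(msg)) msg else TRUE
})

## count 4-connected components of a logical matrix (label propagation;
## no graph package needed at these sizes)
.nComponents4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nlab <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] > 0L) next
    nlab <- nlab + 1L
    queue <- p
    lab[p] <- nlab
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      i <- ((q - 1L) %% nr) + 1L
      j <- ((q - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          qq <- (jj - 1L) * nr + ii
          if (mask[qq] && lab[qq] == 0L) {
            lab[qq] <- nlab
            queue <- c(queue, qq)
          }
        }
      }
    }
  }
  nlab
}

## ---- MaterialField -----------------------------------------------------------

#' Per-pixel material state (the 4 input channels)
#'
#' Young's modulus `E` (MPa), Poisson's ratio `nuP`, permeability `k`
#' (m^4/(N s)) and stem-cell concentration `n` (fraction of the saturation
#' concentration, so `n` is dimensionless in \[0, 1\] and the material blend is
#' `X = (1 - n) X_g + n X_d`).
#'
#' @slot E,nuP,k,n numeric matrices of identical dimension.
#' @export
setClass("MaterialField",
  representation(E = "matrix", nuP = "matrix", k = "matrix", n = "matrix")
)

setValidity("MaterialField", function(object) {
  msg <- character()
  d <- dim(object@E)
  for (s in c("nuP", "k", "n"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, paste(s, "dims differ from E"))
  if (any(object@E <= 0)) msg <- c(msg, "E must be positive everywhere")
  if (any(object@nuP < 0 | object@nuP >= 0.5))
    msg <- c(msg, "nuP must lie in [0, 0.5)")
  if (any(object@k < 0)) msg <- c(msg, "k must be non-negative")
  if (any(object@n < -1e-12 | object@n > 1 + 1e-12))
    msg <- c(msg, "n must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname MaterialField-class
#' @param E,nuP,k,n numeric matrices (see class slots).
#' @return A [MaterialField-class].
#' @export
MaterialField <- function(E, nuP, k, n) {
  new("MaterialField", E = E, nuP = nuP, k = k,
      n = pmin(pmax(n, 0), 1))
}

## ---- PhysicalFields ----------------------------------------------------------

#' Per-pixel solved fields (the 6 output channels)
#'
#' Principal strains sorted descending (`eps1 >= eps2 >= eps3`,
#' dimensionless), Darcy fluid velocity components `vx` (radial) and `vy`
#' (axial) in micrometres per second, and the stem-cell concentration `nNext`
#' for the next day.
#'
#' @slot eps1,eps2,eps3,vx,vy,nNext numeric matrices of identical dimension.
#' @export
setClass("PhysicalFields",
  representation(eps1 = "matrix", eps2 = "matrix", eps3 = "matrix",
                 vx = "matrix", vy = "matrix", nNext = "matrix")
)

setValidity("PhysicalFields", function(object) {
  msg <- character()
  d <- dim(object@eps1)
  for (s in c("eps2", "eps3", "vx", "vy", "nNext"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, paste(s, "dims differ from eps1"))
  tol <- 1e-9
  if (any(object@eps1 < object@eps2 - tol) ||
      any(object@eps2 < object@eps3 - tol))
    msg <- c(msg, "principal strains must satisfy eps1 >= eps2 >= eps3")
  if (any(object@nNext < -1e-9 | object@nNext > 1 + 1e-9))
    msg <- c(msg, "nNext must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname PhysicalFields-class
#' @param eps1,eps2,eps3,vx,vy,nNext numeric matrices (see class slots).
#' @return A [PhysicalFields-class].
#' @export
PhysicalFields <- function(eps1, eps2, eps3, vx, vy, nNext) {
  new("PhysicalFields", eps1 = eps1, eps2 = eps2, eps3 = eps3,
      vx = vx, vy = vy, nNext = pmin(pmax(nNext, 0), 1))
}

## ---- PhenotypeMap ------------------------------------------------------------

#' Per-pixel tissue phenotype map
#'
#' Integer matrix over [phenotypeCodes()].  Differentiated codes (10--14) and
#' granulation (4) may occur only on callus pixels; all other pixels carry
#' their immutable region code.
#'
#' @slot codes integer matrix of phenotype codes.
#' @export
setClass("PhenotypeMap", representation(codes = "matrix"))

setValidity("PhenotypeMap", function(object) {
  if (!all(object@codes %in% phenotypeCodes()))
    "codes contains values outside the phenotype palette"
  else TRUE
})

#' @rdname PhenotypeMap-class
#' @param codes integer matrix of phenotype codes.
#' @param domain optional [ImplantDomain-class]; when given, the map is checked
#'   for consistency (differentiated codes only on callus, fixed codes equal to
#'   the region labels elsewhere).
#' @return A [PhenotypeMap-class].
#' @export
PhenotypeMap <- function(codes, domain = NULL) {
  storage.mode(codes) <- "integer"
  obj <- new("PhenotypeMap", codes = codes)
  if (!is.null(domain)) .checkMapAgainstDomain(obj, domain)
  obj
}

.checkMapAgainstDomain <- function(map, domain) {
  cal <- regionMap(domain) == regionCodes()[["callus"]]
  mut <- map@codes %in% c(4L, .PHEN_DIFF)
  if (any(mut & !cal))
    stop("differentiated phenotype codes occur outside the callus region")
  if (!all(map@codes[!cal] == regionMap(domain)[!cal]))
    stop("fixed-region phenotype codes disagree with the domain's regions")
  invisible(TRUE)
}

## ---- HealingHistory ----------------------------------------------------------

#' A full healing history for one implant case
#'
#' Ordered day records (day 0 .. day T).  Each record is a list with elements
#' `material` ([MaterialField-class]), `fields` ([PhysicalFields-class]) and
#' `phenotype` ([PhenotypeMap-class]).  Day 0 carries granulation tissue in
#' the callus and `n = 0`.
#'
#' @slot caseId character case identifier.
#' @slot domain the [ImplantDomain-class].
#' @slot days list of day records, names `"day0"`, `"day1"`, ...
#' @slot params list snapshot of the run parameters (thresholds, material
#'   table, solver settings, seeds) sufficient to reproduce the run.
#' @slot surrogate logical, `TRUE` when the record was produced by the neural
#'   rollout rather than the simulator.
#' @export
setClass("HealingHistory",
  representation(caseId = "character", domain = "ImplantDomain",
                 days = "list", params = "list", surrogate = "logical"),
  prototype(surrogate = FALSE)
)

setValidity("HealingHistory", function(object) {
  msg <- character()
  if (!length(object@days)) msg <- c(msg, "history must contain day 0")
  want <- paste0("day", seq_along(object@days) - 1L)
  if (!identical(names(object@days), want))
    msg <- c(msg, "day records must be named day0, day1, ... in order")
  for (d in object@days) {
    if (!all(c("material", "fields", "phenotype") %in% names(d)))
      msg <- c(msg, "each day record needs material, fields and phenotype")
  }
  if (length(msg)) msg else TRUE
})

## ---- SurrogateBundle ---------------------------------------------------------

#' Trained surrogate component bundle
#'
#' Holds the four trained components of the surrogate pipeline and the
#' metadata needed to reproduce their training: the image-to-image field
#' regressor (4 material channels in, 6 physical channels out), the per-pixel
#' 5-feature phenotype classifier, the structured map denoiser and the binary
#' resorption-vs-mature-bone random forest, plus the case split, seeds and
#' hyperparameters.
#'
#' @slot fieldNet,pixelClassifier,denoiserNet,resorptionForest trained model
#'   lists (see [trainSurrogate()]); `resorptionForest` may be `NULL`.
#' @slot meta list: seeds, train/test case ids, config, standardization stats.
#' @export
setClass("SurrogateBundle",
  representation(fieldNet = "ANY", pixelClassifier = "ANY",
                 denoiserNet = "ANY", resorptionForest = "ANY",
                 meta = "list")
)

setValidity("SurrogateBundle", function(object) {
  need <- c("seed", "trainCases", "testCases")
  if (!all(need %in% names(object@meta)))
    "meta must record seed, trainCases and testCases"
  else TRUE
})
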