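## Geometry: parametric implant profiles rasterized onto the structured grid,
## the segment-swap construction, and the random implant library.
##
## Coordinate convention: row 1 = occlusal top, column 1 = implant axis (the
## axisymmetric left edge); the half-model is the right half-plane.  Public
## row ranges are 0-based half-open [from, to) to match the day indexing.

#' Continuous radius profile of a parametric implant
#'
#' Radius (in pixel units, measured from the axis) at each implant row,
#' before rasterization.  Row 1 is the implant top.  Collar rows carry the
#' bare body radius; body rows add the periodic thread protrusion; apex rows
#' taper according to `apexShape`.
#'
#' @param params an [ImplantParams-class].
#' @return numeric vector of length `collarHeight + bodyLength`.
#' @keywords internal
.radiusProfile <- function(params) {
  L <- params@collarHeight + params@bodyLength
  r <- rep(as.numeric(params@bodyRadius), L)
  if (params@bodyLength > 0L) {
    b <- seq_len(params@bodyLength) - 1L          # 0-based body row
    phase <- (b %% params@threadPitch) / params@threadPitch
    tooth <- b %/% params@threadPitch
    depth <- params@threadDepth[(tooth %% length(params@threadDepth)) + 1L]
    w <- switch(params@threadProfile,
      triangular  = 1 - abs(2 * phase - 1),
      trapezoidal = pmin(1, 4 * phase, 4 * (1 - phase)),
      buttress    = phase)
    r[params@collarHeight + b + 1L] <- params@bodyRadius + depth * w
  }
  ## apex taper over the last rows
  nApex <- min(params@bodyRadius, max(0L, params@bodyLength %/% 4L))
  if (nApex > 0L && params@apexShape != "flat") {
    i <- seq_len(nApex)                            # 1 .. nApex, bottom last
    frac <- i / nApex
    cap <- switch(params@apexShape,
      pointed = params@bodyRadius * (1 - frac) + 1,
      rounded = sqrt(pmax(0, 1 - frac^2)) * params@bodyRadius)
    rows <- L - nApex + i
    r[rows] <- pmin(r[rows], pmax(cap, 1))
  }
  r
}

#' Rasterize a parametric implant with its bone and callus surroundings
#'
#' Builds the per-pixel region partition for one implant case: the implant
#' half-profile (no interpolation -- a pixel is implant when its column index
#' does not exceed the rounded profile radius at its row), a callus band of
#' `callusWidth` pixels wrapping the embedded implant, a cortical layer of
#' `corticalThickness` rows at the top of the bone, and cancellous bone
#' elsewhere.  Rows above the bone crest that are not implant collar are
#' outside the model.
#'
#' @param params an [ImplantParams-class].
#' @param grid a [GridSpec-class].
#' @param callusWidth width of the cell-differentiation band around the
#'   implant, pixels (default 3).
#' @param corticalThickness cortical layer thickness, rows (default
#'   `max(3, round(0.06 * nrow))`).
#' @return An [ImplantDomain-class].  The stem-cell origin is the callus
#'   boundary facing host bone; the load surface is the implant's top row.
#' @examples
#' p <- ImplantParams(bodyLength = 40, bodyRadius = 6, threadPitch = 8,
#'                    threadDepth = 3)
#' d <- buildImplantProfile(p, GridSpec(64, 32))
#' d
#' @export
buildImplantProfile <- function(params, grid, callusWidth = 3L,
                                corticalThickness = NULL) {
  stopifnot(is(params, "ImplantParams"), is(grid, "GridSpec"))
  validObject(params)
  nr <- grid@nrow; nc <- grid@ncol
  if (is.null(corticalThickness))
    corticalThickness <- max(3L, round(0.06 * nr))
  callusWidth <- as.integer(callusWidth)

  prof <- .radiusProfile(params)
  L <- length(prof)
  rInt <- pmax(1L, as.integer(round(prof)))

  ## fit checks, naming the violated dimension
  if (L + callusWidth + 1L > nr)
    stop("implant length ", L, " + callus band exceeds grid rows (", nr, ")")
  if (max(rInt) + callusWidth + 1L > nc)
    stop("implant radius ", max(rInt),
         " + callus band exceeds grid columns (", nc, ")")

  codes <- regionCodes()
  region <- matrix(codes[["cancellous"]], nr, nc)

  boneTop <- params@collarHeight + 1L           # first bone row
  if (boneTop > 1L)
    region[seq_len(boneTop - 1L), ] <- codes[["outside"]]
  cortRows <- seq(boneTop, min(nr, boneTop + corticalThickness - 1L))
  region[cortRows, ] <- codes[["cortical"]]

  imp <- matrix(FALSE, nr, nc)
  for (i in seq_len(L)) imp[i, seq_len(rInt[i])] <- TRUE

  ## callus: Chebyshev dilation of the embedded implant, in bone rows only
  cal <- .dilate(imp, callusWidth) & !imp
  cal[seq_len(boneTop - 1L), ] <- FALSE
  region[cal] <- codes[["callus"]]
  region[imp] <- codes[["implant"]]

  .finalizeDomain(grid, region, params)
}

## Chebyshev (box) dilation of a logical mask by w pixels
.dilate <- function(mask, w) {
  if (w <= 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (di in -w:w) {
    rs <- (1L + max(0L, di)):(nr + min(0L, di))
    rt <- rs - di
    for (dj in -w:w) {
      cs <- (1L + max(0L, dj)):(nc + min(0L, dj))
      ct <- cs - dj
      out[rt, ct] <- out[rt, ct] | mask[rs, cs]
    }
  }
  out
}

## Derive masks + first thread row from a finished region matrix and wrap as a
## validated ImplantDomain.  Shared by the builder and swapSegment so that
## hybrids and originals use identical definitions.
.finalizeDomain <- function(grid, region, params = NULL) {
  codes <- regionCodes()
  imp <- region == codes[["implant"]]
  cal <- region == codes[["callus"]]
  bone <- region == codes[["cortical"]] | region == codes[["cancellous"]]

  load <- matrix(FALSE, nrow(region), ncol(region))
  topRow <- min(which(rowSums(imp) > 0))
  load[topRow, ] <- imp[topRow, ]

  origin <- cal & .adjacent4(bone)

  widths <- rowSums(imp)
  wider <- which(widths > widths[topRow])
  ftr <- if (length(wider)) as.integer(min(wider)) else NA_integer_

  new("ImplantDomain", grid = grid, region = region,
      cellOriginMask = origin, loadMask = load,
      firstThreadRow = ftr, params = params)
}

## pixels 4-adjacent to TRUE pixels of mask
.adjacent4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  out[-1, ] <- out[-1, ] | mask[-nr, ]
  out[-nr, ] <- out[-nr, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -nc]
  out[, -nc] <- out[, -nc] | mask[, -1]
  out
}

#' Swap an axial segment between two implant domains
#'
#' Exchanges all region labels in the 0-based half-open row interval
#' `rowRange` between two domains on the same grid, producing the two hybrid
#' designs (conventionally "ABA" and "BAB").  Only pixels inside `rowRange`
#' differ from the respective source; masks and the first-thread row are
#' re-derived and implant connectivity is re-validated.
#'
#' @param domainA,domainB [ImplantDomain-class] objects sharing a grid.
#' @param rowRange integer length-2, 0-based half-open `[from, to)` row
#'   interval; must lie strictly inside both implants' axial extent.
#' @return list with elements `aba` and `bab`.
#' @examples
#' pA <- ImplantParams(40, 6, 8, 3); pB <- ImplantParams(40, 8, 10, 2)
#' g  <- GridSpec(64, 32)
#' hy <- swapSegment(buildImplantProfile(pA, g), buildImplantProfile(pB, g),
#'                   c(20, 40))
#' @export
swapSegment <- function(domainA, domainB, rowRange) {
  stopifnot(is(domainA, "ImplantDomain"), is(domainB, "ImplantDomain"))
  if (!identical(domainA@grid, domainB@grid))
    stop("domains must share the same GridSpec")
  rowRange <- as.integer(rowRange)
  stopifnot(length(rowRange) == 2L, rowRange[1] <= rowRange[2])

  if (rowRange[1] == rowRange[2])
    return(list(aba = domainA, bab = domainB))

  rows <- (rowRange[1] + 1L):rowRange[2]      # 1-based grid rows
  for (d in list(domainA, domainB)) {
    ext <- range(which(rowSums(implantMask(d)) > 0))
    if (rowRange[1] + 1L <= ext[1] || rowRange[2] >= ext[2])
      stop("rowRange [", rowRange[1], ", ", rowRange[2],
           ") must lie strictly inside the implant's axial extent [",
           ext[1] - 1L, ", ", ext[2], ")")
  }

  regA <- regionMap(domainA); regB <- regionMap(domainB)
  newA <- regA; newB <- regB
  newA[rows, ] <- regB[rows, ]
  newB[rows, ] <- regA[rows, ]

  out <- lapply(list(aba = newA, bab = newB), function(reg) {
    tryCatch(.finalizeDomain(domainA@grid, reg, params = NULL),
             error = function(e)
               stop("segment swap produced an invalid implant: ",
                    conditionMessage(e), call. = FALSE))
  })
  out
}

#' Generate a random library of valid implant domains
#'
#' Draws implant parameters from documented ranges (scaled to the grid),
#' rasterizes each and keeps only valid domains; invalid draws are resampled
#' with a logged warning.  Deterministic for a fixed seed.
#'
#' Parameter ranges (fractions of the grid): body length 0.62--0.85 of the
#' rows, body radius 0.12--0.24 of the columns, thread pitch 6--14 rows,
#' thread depth 0--0.5 of the body radius (with a 30% chance of a two-zone
#' depth profile, emulating dual-thread designs), collar 0--4 rows; thread
#' profile and apex shape uniform over their levels.
#'
#' @param nCases number of domains (>= 1).
#' @param seed integer RNG seed.
#' @param grid a [GridSpec-class] shared by all cases.
#' @param callusWidth,corticalThickness forwarded to [buildImplantProfile()].
#' @return named list of [ImplantDomain-class] objects (`case01`, ...).
#' @examples
#' lib <- generateImplantLibrary(3, seed = 7, grid = GridSpec(64, 32))
#' names(lib)
#' @export
generateImplantLibrary <- function(nCases, seed, grid = GridSpec(),
                                   callusWidth = 3L,
                                   corticalThickness = NULL) {
  stopifnot(nCases >= 1)
  .withSeed(seed, {
    out <- vector("list", nCases)
    for (i in seq_len(nCases)) {
      dom <- NULL
      for (try in 1:50) {
        p <- .sampleImplantParams(grid)
        dom <- tryCatch(
          buildImplantProfile(p, grid, callusWidth, corticalThickness),
          error = function(e) {
            warning("resampling case ", i, ": ", conditionMessage(e),
                    call. = FALSE)
            NULL
          })
        if (!is.null(dom)) break
      }
      if (is.null(dom))
        stop("could not generate a valid implant for case ", i,
             " after 50 attempts")
      out[[i]] <- dom
    }
    names(out) <- sprintf("case%02d", seq_len(nCases))
    out
  })
}

.sampleImplantParams <- function(grid) {
  nr <- grid@nrow; nc <- grid@ncol
  bodyLength <- round(runif(1, 0.62, 0.85) * nr)
  bodyRadius <- max(2L, round(runif(1, 0.12, 0.24) * nc))
  pitch <- sample(6:14, 1)
  maxDepth <- max(1, 0.5 * bodyRadius)
  depth <- if (runif(1) < 0.3) {
    round(runif(2, 0, maxDepth), 1)              # two-zone depth profile
  } else round(runif(1, 0, maxDepth), 1)
  depth <- pmin(depth, bodyRadius - 1)
  ImplantParams(bodyLength = bodyLength, bodyRadius = bodyRadius,
                threadPitch = pitch, threadDepth = depth,
                threadProfile = sample(c("triangular", "trapezoidal",
                                         "buttress"), 1),
                apexShape = sample(c("flat", "rounded", "pointed"), 1),
                collarHeight = sample(0:4, 1))
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
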