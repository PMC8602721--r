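## Per-day field solves on the pixel grid.
##
## The original workflow used a commercial axisymmetric poroelastic FE model;
## here the same two biophysical stimuli are produced by a simplified,
## decoupled chain on the structured grid:
##   1. quasi-static plane-stress elasticity (bilinear quad per pixel,
##      heterogeneous E and nu) under the occlusal micro-displacement,
##   2. a one-step consolidation solve for pore pressure with the day's
##      volumetric strain rate as source, Darcy velocity v = -k grad p,
##   3. an implicit diffusion step for the stem-cell concentration with the
##      cell-origin boundary clamped at saturation.
## All three are sparse direct solves; on tiny grids they are cross-checked
## against dense loop-assembled oracles in the test suite.

## ---- element stiffness building blocks -------------------------------------
## Plane-stress D = E/(1-nu^2) * [ [1, nu, 0], [nu, 1, 0], [0, 0, (1-nu)/2] ]
## so Ke = f1*K1 + f2*K2 + f3*K3 with f1 = E/(1-nu^2), f2 = f1*nu,
## f3 = f1*(1-nu)/2, and K1..K3 element matrices of the three unit D-modes.
## For a square bilinear quad Ke is independent of the pixel size.
## Local node order: top-left, top-right, bottom-right, bottom-left
## (x rightward along columns, y downward along rows).

.keCache <- new.env(parent = emptyenv())

.keModes <- function() {
  if (!is.null(.keCache$K)) return(.keCache$K)
  gp <- c(-1, 1) / sqrt(3)
  modes <- list(diag(c(1, 1, 0)),
                matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3),
                diag(c(0, 0, 1)))
  K <- lapply(modes, function(D) matrix(0, 8, 8))
  for (xi in gp) for (eta in gp) {
    ## dN/dxi, dN/deta for nodes tl, tr, br, bl at (xi,eta) in [-1,1]^2,
    ## N_tl peaking at (-1,-1), N_tr at (1,-1), N_br at (1,1), N_bl at (-1,1)
    dNdXi  <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdEta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    ## J = h/2 * I  =>  dN/dx = (2/h) dN/dxi; detJ = h^2/4; h cancels
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdXi
    B[2, seq(2, 8, 2)] <- dNdEta
    B[3, seq(1, 8, 2)] <- dNdEta
    B[3, seq(2, 8, 2)] <- dNdXi
    for (m in 1:3) K[[m]] <- K[[m]] + t(B) %*% modes[[m]] %*% B
  }
  .keCache$K <- K
  K
}

## element -> global dof map (nE x 8), nodes (nr+1) x (nc+1), node id
## (j-1)*(nr+1)+i, dofs (2 id - 1, 2 id) = (ux, uy)
.elementDofs <- function(nr, nc) {
  el <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  tl <- (el$j - 1L) * (nr + 1L) + el$i
  tr <- el$j * (nr + 1L) + el$i
  br <- tr + 1L
  bl <- tl + 1L
  nodes <- cbind(tl, tr, br, bl)
  dofs <- matrix(0L, nrow(nodes), 8L)
  dofs[, seq(1, 8, 2)] <- 2L * nodes - 1L
  dofs[, seq(2, 8, 2)] <- 2L * nodes
  dofs
}

#' Quasi-static elasticity solve under the occlusal micro-displacement
#'
#' Solves plane-stress equilibrium with per-pixel heterogeneous stiffness on
#' bilinear quadrilateral pixel elements and returns sorted principal strain
#' fields.  The default boundary conditions (`bcMode = "domain"`) press the
#' implant's top surface down by `loadDisplacement`, hold the outer bone
#' boundary (right column and bottom row of nodes) fixed and impose symmetry
#' (`u_x = 0`) on the implant axis.  `bcMode = "patch"` replaces these with a
#' uniform-compression patch setup (top edge displaced, bottom edge on
#' vertical rollers, left edge on horizontal rollers, right edge free), whose
#' exact solution is a uniform strain state.
#'
#' The two in-plane principal strains come from the displacement gradient at
#' each pixel center; the out-of-plane channel is the plane-stress value
#' `eps_z = -nu/(1 - nu) * (eps_x + eps_y)` so that three principal strain
#' channels exist.  Channels are sorted to `eps1 >= eps2 >= eps3` per pixel.
#'
#' @param domain an [ImplantDomain-class] (supplies the grid and masks).
#' @param material a [MaterialField-class] (E in MPa, nuP dimensionless).
#' @param loadDisplacement applied top displacement in micrometres
#'   (default 8).
#' @param bcMode `"domain"` (implant loading) or `"patch"` (patch test).
#' @return list with matrices `eps1`, `eps2`, `eps3` (sorted principal
#'   strains), `epsVol` (volumetric strain, their sum) and `exx`, `eyy`,
#'   `gxy` (raw in-plane components).
#' @examples
#' d <- buildImplantProfile(ImplantParams(20, 4, 6, 2), GridSpec(32, 16))
#' m <- uniformMaterial(d, E = 1000, nuP = 0.3, k = 1e-14)
#' s <- solveElasticity(d, m)
#' range(s$eps3)
#' @export
solveElasticity <- function(domain, material, loadDisplacement = 8,
                            bcMode = c("domain", "patch")) {
  bcMode <- match.arg(bcMode)
  g <- gridSpec(domain)
  nr <- g@nrow; nc <- g@ncol
  stopifnot(identical(dim(material@E), c(nr, nc)))
  h <- g@pixelSize * 1e-3                       # m
  delta <- loadDisplacement * 1e-6              # m

  Kk <- .keModes()
  Epa <- as.vector(material@E) * 1e6            # MPa -> Pa, element (pixel) wise
  nu <- as.vector(material@nuP)
  f1 <- Epa / (1 - nu^2)
  vals <- f1 %o% as.vector(Kk[[1]]) +
    (f1 * nu) %o% as.vector(Kk[[2]]) +
    (f1 * (1 - nu) / 2) %o% as.vector(Kk[[3]])

  edof <- .elementDofs(nr, nc)
  iIdx <- edof[, rep(1:8, times = 8)]
  jIdx <- edof[, rep(1:8, each = 8)]
  ndof <- 2L * (nr + 1L) * (nc + 1L)
  K <- Matrix::sparseMatrix(i = as.vector(iIdx), j = as.vector(jIdx),
                            x = as.vector(vals), dims = c(ndof, ndof))

  ## constraints: NA = free, otherwise prescribed value (metres)
  u <- rep(NA_real_, ndof)
  nodeId <- function(i, j) (j - 1L) * (nr + 1L) + i
  allI <- seq_len(nr + 1L); allJ <- seq_len(nc + 1L)
  if (bcMode == "domain") {
    ax <- nodeId(allI, 1L)
    u[2L * ax - 1L] <- 0                        # symmetry axis: ux = 0
    fixed <- c(nodeId(allI, nc + 1L), nodeId(nr + 1L, allJ))
    u[2L * fixed - 1L] <- 0; u[2L * fixed] <- 0 # outer bone boundary
    lp <- which(loadMask(domain), arr.ind = TRUE)
    if (nrow(lp) == 0L) stop("domain has no load surface")
    ln <- unique(c(nodeId(lp[, 1], lp[, 2]), nodeId(lp[, 1], lp[, 2] + 1L)))
    u[2L * ln] <- delta                         # pressed down (y is down)
    u[2L * ln - 1L] <- 0
  } else {
    top <- nodeId(1L, allJ); bot <- nodeId(nr + 1L, allJ)
    u[2L * top] <- delta
    u[2L * bot] <- 0
    lft <- nodeId(allI, 1L)
    u[2L * lft - 1L] <- 0
  }

  cons <- which(!is.na(u))
  free <- which(is.na(u))
  rhs <- -K[free, cons, drop = FALSE] %*% u[cons]
  sol <- tryCatch(
    Matrix::solve(K[free, free, drop = FALSE], rhs),
    error = function(e)
      stop("elastic system is singular (disconnected load path?): ",
           conditionMessage(e), call. = FALSE))
  u[free] <- as.vector(sol)

  ## strains at element centers
  ux <- matrix(u[seq(1, ndof, 2)], nr + 1L, nc + 1L)
  uy <- matrix(u[seq(2, ndof, 2)], nr + 1L, nc + 1L)
  ri <- seq_len(nr); rj <- seq_len(nc)
  exx <- ((ux[ri, rj + 1L] + ux[ri + 1L, rj + 1L]) -
          (ux[ri, rj] + ux[ri + 1L, rj])) / (2 * h)
  eyy <- ((uy[ri + 1L, rj] + uy[ri + 1L, rj + 1L]) -
          (uy[ri, rj] + uy[ri, rj + 1L])) / (2 * h)
  gxy <- ((ux[ri + 1L, rj] + ux[ri + 1L, rj + 1L]) -
          (ux[ri, rj] + ux[ri, rj + 1L])) / (2 * h) +
         ((uy[ri, rj + 1L] + uy[ri + 1L, rj + 1L]) -
          (uy[ri, rj] + uy[ri + 1L, rj])) / (2 * h)

  cc <- (exx + eyy) / 2
  rr <- sqrt(((exx - eyy) / 2)^2 + (gxy / 2)^2)
  ea <- cc + rr; eb <- cc - rr
  nuM <- material@nuP
  ez <- -nuM / (1 - nuM) * (exx + eyy)
  eps1 <- pmax(ea, ez)
  eps3 <- pmin(eb, ez)
  eps2 <- ea + eb + ez - eps1 - eps3
  list(eps1 = eps1, eps2 = eps2, eps3 = eps3,
       epsVol = eps1 + eps2 + eps3, exx = exx, eyy = eyy, gxy = gxy)
}

#' Pore-pressure and Darcy velocity from a one-step consolidation solve
#'
#' Solves `div(k grad p) = epsVol / loadPeriod` on the porous pixels (those
#' with `k > 0`) by a cell-centered finite-volume scheme with harmonic-mean
#' face permeabilities, drained (`p = 0`) outer boundaries (top, right,
#' bottom of the grid) and a no-flux symmetry axis; impermeable pixels
#' (implant, outside) enforce no-flux faces.  Velocities are the Darcy flux
#' `v = -k grad p` evaluated at pixel centers from the face fluxes, reported
#' in micrometres per second.  Implant pixels carry `k = 0` and exactly zero
#' velocity.
#'
#' The relevant interstitial flow for the stimulus is the one induced during
#' a single biting cycle, so the volumetric strain rate is the day's strain
#' state applied over the masticatory loading period (~1 s), not over the
#' 1-day iteration step.
#'
#' @param domain an [ImplantDomain-class].
#' @param material a [MaterialField-class] (k in m^4/(N s)).
#' @param strains result of [solveElasticity()] for the same day (its
#'   `epsVol` is the consolidation source).
#' @param loadPeriod biting-cycle loading period in seconds (default 1).
#' @return list with matrices `vx`, `vy` (um/s) and `p` (pore pressure, Pa).
#' @export
solveFluid <- function(domain, material, strains, loadPeriod = 1) {
  g <- gridSpec(domain)
  nr <- g@nrow; nc <- g@ncol
  h <- g@pixelSize * 1e-3
  k <- material@k
  porous <- k > 0
  if (!any(porous))
    stop("all-zero permeability: no porous region to solve")
  src <- strains$epsVol / loadPeriod                # 1/s

  idx <- matrix(0L, nr, nc)
  idx[porous] <- seq_len(sum(porous))
  np <- sum(porous)

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  diag <- numeric(np)
  rhs <- src[porous] * h^2                      # scaled by h^2

  addFace <- function(pi, pj, qi, qj) {
    ## face between porous pixel (pi,pj) and neighbor (qi,qj) inside grid
    ok <- porous[cbind(pi, pj)]
    pi <- pi[ok]; pj <- pj[ok]; qi <- qi[ok]; qj <- qj[ok]
    kp <- k[cbind(pi, pj)]; kq <- k[cbind(qi, qj)]
    cf <- ifelse(kp + kq > 0, 2 * kp * kq / (kp + kq), 0)  # harmonic mean
    act <- cf > 0
    p <- idx[cbind(pi, pj)][act]
    q <- idx[cbind(qi, qj)][act]
    cf <- cf[act]
    diag[p] <<- diag[p] - cf
    ti <<- c(ti, p); tj <<- c(tj, q); tx <<- c(tx, cf)
  }
  pij <- which(porous, arr.ind = TRUE)
  pi <- pij[, 1]; pj <- pij[, 2]
  sel <- pi > 1L;  addFace(pi[sel], pj[sel], pi[sel] - 1L, pj[sel])
  sel <- pi < nr;  addFace(pi[sel], pj[sel], pi[sel] + 1L, pj[sel])
  sel <- pj > 1L;  addFace(pi[sel], pj[sel], pi[sel], pj[sel] - 1L)
  sel <- pj < nc;  addFace(pi[sel], pj[sel], pi[sel], pj[sel] + 1L)

  ## drained grid boundaries (ghost p = 0 with the pixel's own k);
  ## the left edge (symmetry axis) stays no-flux
  for (edge in list(list(sel = pi == 1L), list(sel = pi == nr),
                    list(sel = pj == nc))) {
    s <- edge$sel
    p <- idx[cbind(pi[s], pj[s])]
    diag[p] <- diag[p] - k[cbind(pi[s], pj[s])]
  }

  A <- Matrix::sparseMatrix(i = c(ti, seq_len(np)), j = c(tj, seq_len(np)),
                            x = c(tx, diag), dims = c(np, np))
  pvec <- tryCatch(as.vector(Matrix::solve(A, rhs)),
                   error = function(e)
                     stop("consolidation system is singular: ",
                          conditionMessage(e), call. = FALSE))
  p <- matrix(0, nr, nc)
  p[porous] <- pvec

  ## face fluxes -> center velocities; impermeable faces carry zero flux
  flux <- function(di, dj, ghostDirichlet) {
    out <- matrix(0, nr, nc)
    qi <- pmin(pmax(pi + di, 1L), nr); qj <- pmin(pmax(pj + dj, 1L), nc)
    inside <- (pi + di >= 1L) & (pi + di <= nr) &
              (pj + dj >= 1L) & (pj + dj <= nc)
    kp <- k[cbind(pi, pj)]
    f <- numeric(length(pi))
    kq <- ifelse(inside, k[cbind(qi, qj)], 0)
    cf <- ifelse(inside & (kp + kq > 0), 2 * kp * kq / (kp + kq), 0)
    pn <- ifelse(inside, p[cbind(qi, qj)], 0)
    f <- -cf * (pn - p[cbind(pi, pj)]) / h
    if (ghostDirichlet) {                        # drained ghost cell, p = 0
      f[!inside] <- -kp[!inside] * (0 - p[cbind(pi, pj)][!inside]) / h
    } else f[!inside] <- 0                       # symmetry: no flux
    out[cbind(pi, pj)] <- f
    out
  }
  fN <- flux(-1L, 0L, TRUE); fS <- flux(1L, 0L, TRUE)
  fW <- flux(0L, -1L, FALSE); fE <- flux(0L, 1L, TRUE)
  vx <- (fE - fW) / 2 * 1e6                      # m/s -> um/s
  vy <- (fS - fN) / 2 * 1e6
  vx[!porous] <- 0; vy[!porous] <- 0
  list(vx = vx, vy = vy, p = p)
}

#' One implicit diffusion step for the stem-cell concentration
#'
#' Backward-Euler diffusion on the callus pixels with the concentration
#' clamped at saturation (`n = 1`) on the cell-origin boundary and no-flux
#' conditions on every other callus boundary face.  Pixels outside the callus
#' are returned unchanged.  The implicit step is unconditionally stable and
#' satisfies the discrete maximum principle, so `n` stays in `[0, 1]`.
#'
#' @param domain an [ImplantDomain-class].
#' @param n current concentration matrix (fractions of saturation).
#' @param dt step in days (default 1).
#' @param D diffusion coefficient in mm^2/day.  The default (0.001) brings
#'   the mean callus concentration of the default full-scale geometry to
#'   0.90 of saturation by day 35.
#' @return the next-day concentration matrix.
#' @export
diffuseStemCells <- function(domain, n, dt = 1, D = 0.001) {
  g <- gridSpec(domain)
  nr <- g@nrow; nc <- g@ncol
  stopifnot(identical(dim(n), c(nr, nc)))
  cal <- callusMask(domain)
  org <- cellOriginMask(domain)
  out <- n
  out[org] <- 1
  unk <- cal & !org
  nu <- sum(unk)
  if (nu == 0L) return(out)

  idx <- matrix(0L, nr, nc)
  idx[unk] <- seq_len(nu)
  lam <- D * dt / g@pixelSize^2

  pij <- which(unk, arr.ind = TRUE)
  pi <- pij[, 1]; pj <- pij[, 2]
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  diag <- rep(1, nu)
  rhs <- n[unk]
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    qi <- pi + d[1]; qj <- pj + d[2]
    inside <- qi >= 1L & qi <= nr & qj >= 1L & qj <= nc
    isCal <- rep(FALSE, length(pi))
    isCal[inside] <- cal[cbind(qi[inside], qj[inside])]
    ## only faces to callus pixels diffuse; all others are no-flux
    pSel <- which(isCal)
    if (!length(pSel)) next
    pId <- idx[cbind(pi[pSel], pj[pSel])]
    diag[pId] <- diag[pId] + lam
    qUnk <- unk[cbind(qi[pSel], qj[pSel])]
    ## neighbor is an unknown callus pixel -> off-diagonal
    p1 <- pId[qUnk]; q1 <- idx[cbind(qi[pSel][qUnk], qj[pSel][qUnk])]
    ti <- c(ti, p1); tj <- c(tj, q1); tx <- c(tx, rep(-lam, length(p1)))
    ## neighbor is a clamped origin pixel -> rhs
    p0 <- pId[!qUnk]
    rhs[p0] <- rhs[p0] + lam * 1
  }
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(nu)), j = c(tj, seq_len(nu)),
                            x = c(tx, diag), dims = c(nu, nu))
  sol <- as.vector(Matrix::solve(A, rhs))
  out[unk] <- pmin(pmax(sol, 0), 1)
  out
}

#' Uniform material field over a domain
#'
#' Convenience constructor used by tests and patch setups: every pixel gets
#' the same properties (the implant keeps `k = 0` unless `respectImplant` is
#' `FALSE`).
#'
#' @param domain an [ImplantDomain-class].
#' @param E,nuP,k,n scalar property values.
#' @param respectImplant zero the permeability on implant pixels (default
#'   `TRUE`).
#' @return a [MaterialField-class].
#' @export
uniformMaterial <- function(domain, E, nuP, k, n = 0,
                            respectImplant = TRUE) {
  g <- gridSpec(domain)
  mk <- function(v) matrix(v, g@nrow, g@ncol)
  kMat <- mk(k)
  if (respectImplant) kMat[implantMask(domain)] <- 0
  MaterialField(E = mk(E), nuP = mk(nuP), k = kMat, n = mk(n))
}
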