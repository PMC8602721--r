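## Independent dense loop-assembled oracles for the tiny-grid solver
## equivalence checks (own quadrature, assembly and boundary code).

denseElasticOracle <- function(domain, material, loadDisplacement = 8,
                               bcMode = "domain") {
  g <- gridSpec(domain)
  nr <- g@nrow; nc <- g@ncol
  h <- g@pixelSize * 1e-3
  delta <- loadDisplacement * 1e-6
  nn <- (nr + 1) * (nc + 1); ndof <- 2 * nn
  nodeId <- function(i, j) (j - 1) * (nr + 1) + i
  K <- matrix(0, ndof, ndof)
  gp <- c(-1, 1) / sqrt(3)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    E <- material@E[i, j] * 1e6; nu <- material@nuP[i, j]
    D <- E / (1 - nu^2) *
      matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
    ke <- matrix(0, 8, 8)
    for (xi in gp) for (eta in gp) {
      dNx <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4 * (2 / h)
      dNy <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4 * (2 / h)
      B <- matrix(0, 3, 8)
      B[1, c(1, 3, 5, 7)] <- dNx
      B[2, c(2, 4, 6, 8)] <- dNy
      B[3, c(1, 3, 5, 7)] <- dNy
      B[3, c(2, 4, 6, 8)] <- dNx
      ke <- ke + t(B) %*% D %*% B * (h^2 / 4)
    }
    nd <- c(nodeId(i, j), nodeId(i, j + 1), nodeId(i + 1, j + 1),
            nodeId(i + 1, j))
    dofs <- as.vector(rbind(2 * nd - 1, 2 * nd))
    K[dofs, dofs] <- K[dofs, dofs] + ke
  }
  u <- rep(NA_real_, ndof)
  allI <- seq_len(nr + 1); allJ <- seq_len(nc + 1)
  if (bcMode == "domain") {
    u[2 * nodeId(allI, 1) - 1] <- 0
    fixed <- c(nodeId(allI, nc + 1), nodeId(nr + 1, allJ))
    u[2 * fixed - 1] <- 0; u[2 * fixed] <- 0
    lp <- which(loadMask(domain), arr.ind = TRUE)
    ln <- unique(c(nodeId(lp[, 1], lp[, 2]), nodeId(lp[, 1], lp[, 2] + 1)))
    u[2 * ln] <- delta; u[2 * ln - 1] <- 0
  } else {
    u[2 * nodeId(1, allJ)] <- delta
    u[2 * nodeId(nr + 1, allJ)] <- 0
    u[2 * nodeId(allI, 1) - 1] <- 0
  }
  cons <- which(!is.na(u)); free <- which(is.na(u))
  u[free] <- solve(K[free, free], -K[free, cons] %*% u[cons])
  ux <- matrix(u[seq(1, ndof, 2)], nr + 1, nc + 1)
  uy <- matrix(u[seq(2, ndof, 2)], nr + 1, nc + 1)
  exx <- eyy <- gxy <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    exx[i, j] <- (ux[i, j + 1] + ux[i + 1, j + 1] -
                  ux[i, j] - ux[i + 1, j]) / (2 * h)
    eyy[i, j] <- (uy[i + 1, j] + uy[i + 1, j + 1] -
                  uy[i, j] - uy[i, j + 1]) / (2 * h)
    gxy[i, j] <- (ux[i + 1, j] + ux[i + 1, j + 1] -
                  ux[i, j] - ux[i, j + 1]) / (2 * h) +
                 (uy[i, j + 1] + uy[i + 1, j + 1] -
                  uy[i, j] - uy[i + 1, j]) / (2 * h)
  }
  list(exx = exx, eyy = eyy, gxy = gxy)
}

## -- independent dense consolidation oracle ----------------------------------
denseFluidOracle <- function(domain, material, strains, loadPeriod = 1) {
  g <- gridSpec(domain)
  nr <- g@nrow; nc <- g@ncol
  h <- g@pixelSize * 1e-3
  k <- material@k
  porous <- which(k > 0)
  np <- length(porous)
  idx <- rep(0L, nr * nc); idx[porous] <- seq_len(np)
  A <- matrix(0, np, np)
  rhs <- (strains$epsVol / loadPeriod)[porous] * h^2
  harm <- function(a, b) if (a + b > 0) 2 * a * b / (a + b) else 0
  for (q in seq_len(np)) {
    p <- porous[q]
    i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        cf <- harm(k[i, j], k[ii, jj])
        if (cf > 0) {
          A[q, q] <- A[q, q] - cf
          A[q, idx[(jj - 1) * nr + ii]] <-
            A[q, idx[(jj - 1) * nr + ii]] + cf
        }
      } else if (!(jj == 0)) {
        ## drained ghost (p = 0) on top/bottom/right; axis (jj == 0) no-flux
        A[q, q] <- A[q, q] - k[i, j]
      }
    }
  }
  pv <- solve(A, rhs)
  p <- matrix(0, nr, nc); p[porous] <- pv
  p
}

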