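## A small neural-network engine in base R (BLAS matrix products), sized for
## desk-scale grids.  It provides exactly what the surrogate stack needs:
## "same"-padded 2-D convolutions via im2col, inception-style multi-kernel
## blocks, a 2-level encoder-decoder with skip connections (U-Net), a dense
## MLP, ReLU, softmax, mean-squared-error and focal losses, and Adam.
## Layer caches keep the im2col matrices so that backprop and Deep Taylor
## relevance propagation share one code path.
##
## Tensor convention: single samples are [H, W, C] arrays; dense data are
## N x d matrices.  Minibatches are lists of samples (gradients averaged).

## ---- primitive layers -------------------------------------------------------

.convInit <- function(kh, kw, cin, cout, scale = NULL) {
  fanIn <- kh * kw * cin
  if (is.null(scale)) scale <- sqrt(2 / fanIn)       # He initialization
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       W = matrix(rnorm(fanIn * cout, sd = scale), fanIn, cout),
       b = rep(0, cout))
}

## im2col: padded [H+kh-1, W+kw-1, C] -> (H*W) x (kh*kw*C); column order
## (di fastest, then dj, then channel) matches the conv weight layout.
.im2col <- function(xp, kh, kw, H, W) {
  C <- dim(xp)[3]
  out <- matrix(0, H * W, kh * kw * C)
  col <- 0L
  for (c in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    col <- col + 1L
    out[, col] <- xp[di:(di + H - 1L), dj:(dj + W - 1L), c]
  }
  out
}

.pad2d <- function(x, ph, pw) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * ph, d[2] + 2L * pw, d[3]))
  xp[ph + seq_len(d[1]), pw + seq_len(d[2]), ] <- x
  xp
}

.convFwd <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  ph <- (layer$kh - 1L) %/% 2L; pw <- (layer$kw - 1L) %/% 2L
  xp <- if (ph || pw) .pad2d(x, ph, pw) else x
  cols <- .im2col(xp, layer$kh, layer$kw, H, W)
  y <- cols %*% layer$W
  y <- sweep(y, 2L, layer$b, `+`)
  list(y = array(y, c(H, W, layer$cout)),
       cache = list(cols = cols, H = H, W = W, ph = ph, pw = pw))
}

.convBwd <- function(layer, cache, dy) {
  H <- cache$H; W <- cache$W
  dyM <- matrix(dy, H * W, layer$cout)
  dW <- crossprod(cache$cols, dyM)
  db <- colSums(dyM)
  dcols <- tcrossprod(dyM, layer$W)                  # (H*W) x (kh*kw*cin)
  dx <- .col2im(dcols, layer, H, W, cache$ph, cache$pw)
  list(dx = dx, dW = dW, db = db)
}

## scatter-add the column gradient back onto the (padded) input
.col2im <- function(dcols, layer, H, W, ph, pw) {
  dxp <- array(0, c(H + 2L * ph, W + 2L * pw, layer$cin))
  col <- 0L
  for (c in seq_len(layer$cin)) for (dj in seq_len(layer$kw))
    for (di in seq_len(layer$kh)) {
      col <- col + 1L
      dxp[di:(di + H - 1L), dj:(dj + W - 1L), c] <-
        dxp[di:(di + H - 1L), dj:(dj + W - 1L), c] +
        matrix(dcols[, col], H, W)
    }
  dxp[ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
}

.relu <- function(x) pmax(x, 0)

.avgpoolFwd <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[1], 2L); e <- seq(2L, d[1], 2L)
  oc <- seq(1L, d[2], 2L); ec <- seq(2L, d[2], 2L)
  y <- (x[o, oc, , drop = FALSE] + x[e, oc, , drop = FALSE] +
        x[o, ec, , drop = FALSE] + x[e, ec, , drop = FALSE]) / 4
  y
}

.avgpoolBwd <- function(dy, dIn) {
  dx <- array(0, dIn)
  d <- dim(dy)
  o <- seq(1L, dIn[1], 2L); e <- seq(2L, dIn[1], 2L)
  oc <- seq(1L, dIn[2], 2L); ec <- seq(2L, dIn[2], 2L)
  q <- dy / 4
  dx[o, oc, ] <- q; dx[e, oc, ] <- q; dx[o, ec, ] <- q; dx[e, ec, ] <- q
  dx
}

.upsampleFwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  o <- seq(1L, 2L * d[1], 2L); e <- o + 1L
  oc <- seq(1L, 2L * d[2], 2L); ec <- oc + 1L
  y[o, oc, ] <- x; y[e, oc, ] <- x; y[o, ec, ] <- x; y[e, ec, ] <- x
  y
}

.upsampleBwd <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[1], 2L); e <- o + 1L
  oc <- seq(1L, d[2], 2L); ec <- oc + 1L
  dy[o, oc, , drop = FALSE] + dy[e, oc, , drop = FALSE] +
    dy[o, ec, , drop = FALSE] + dy[e, ec, , drop = FALSE]
}

## ---- inception block --------------------------------------------------------
## Parallel convolutions with different kernel sizes, channel-concatenated,
## then a shared ReLU.

.incepInit <- function(cin, filtersPerBranch, kernels = c(1L, 3L, 5L)) {
  list(type = "incep",
       branches = lapply(kernels, function(k)
         .convInit(k, k, cin, filtersPerBranch)),
       cout = filtersPerBranch * length(kernels))
}

.incepFwd <- function(block, x) {
  outs <- lapply(block$branches, .convFwd, x = x)
  z <- array(0, c(dim(x)[1], dim(x)[2], block$cout))
  at <- 0L
  for (o in outs) {
    cw <- dim(o$y)[3]
    z[, , at + seq_len(cw)] <- o$y
    at <- at + cw
  }
  a <- .relu(z)
  list(y = a, cache = list(convs = lapply(outs, `[[`, "cache"), z = z))
}

.incepBwd <- function(block, cache, dy) {
  dz <- dy * (cache$z > 0)
  at <- 0L
  dx <- NULL
  grads <- vector("list", length(block$branches))
  for (i in seq_along(block$branches)) {
    br <- block$branches[[i]]
    g <- .convBwd(br, cache$convs[[i]], dz[, , at + seq_len(br$cout),
                                          drop = FALSE])
    at <- at + br$cout
    grads[[i]] <- list(W = g$dW, b = g$db)
    dx <- if (is.null(dx)) g$dx else dx + g$dx
  }
  list(dx = dx, branches = grads)
}

## ---- U-Net ------------------------------------------------------------------
## depth pooling levels; encoder block -> pool, bottom block, then per level
## upsample -> concat skip -> decoder block; final 1x1 linear conv.

#' @keywords internal
.unetInit <- function(cin, cout, baseFilters = 8L, depth = 2L,
                      kernels = c(1L, 3L, 5L)) {
  nb <- length(kernels)
  bf <- function(level) max(2L, as.integer(round(baseFilters * 2^(level - 1) / nb)))
  enc <- list(); chans <- cin
  encOut <- integer(depth)
  for (l in seq_len(depth)) {
    enc[[l]] <- .incepInit(chans, bf(l), kernels)
    chans <- enc[[l]]$cout
    encOut[l] <- chans
  }
  bottom <- .incepInit(chans, bf(depth + 1L), kernels)
  chans <- bottom$cout
  dec <- list()
  for (l in rev(seq_len(depth))) {
    dec[[l]] <- .incepInit(chans + encOut[l], bf(l), kernels)
    chans <- dec[[l]]$cout
  }
  out <- .convInit(1L, 1L, chans, cout, scale = sqrt(1 / chans))
  list(kind = "unet", cin = cin, cout = cout, depth = depth,
       enc = enc, bottom = bottom, dec = dec, out = out)
}

## pad H,W up to a multiple of 2^depth (zeros), remembering the crop
.unetPad <- function(x, depth) {
  d <- dim(x); m <- 2L^depth
  H2 <- as.integer(ceiling(d[1] / m) * m); W2 <- as.integer(ceiling(d[2] / m) * m)
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, H = d[1], W = d[2]))
  xp <- array(0, c(H2, W2, d[3]))
  xp[seq_len(d[1]), seq_len(d[2]), ] <- x
  list(x = xp, H = d[1], W = d[2])
}

.unetFwd <- function(model, x) {
  pd <- .unetPad(x, model$depth)
  z <- pd$x
  skips <- list(); caches <- list(enc = list(), dec = list())
  for (l in seq_len(model$depth)) {
    f <- .incepFwd(model$enc[[l]], z)
    caches$enc[[l]] <- f$cache
    skips[[l]] <- f$y
    caches$poolIn[[l]] <- dim(f$y)
    z <- .avgpoolFwd(f$y)
  }
  f <- .incepFwd(model$bottom, z)
  caches$bottom <- f$cache
  z <- f$y
  for (l in rev(seq_len(model$depth))) {
    z <- .upsampleFwd(z)
    zc <- array(0, c(dim(z)[1], dim(z)[2], dim(z)[3] + dim(skips[[l]])[3]))
    zc[, , seq_len(dim(z)[3])] <- z
    zc[, , dim(z)[3] + seq_len(dim(skips[[l]])[3])] <- skips[[l]]
    caches$upC[[l]] <- dim(z)[3]
    f <- .incepFwd(model$dec[[l]], zc)
    caches$dec[[l]] <- f$cache
    z <- f$y
  }
  f <- .convFwd(model$out, z)
  caches$out <- f$cache
  y <- f$y[seq_len(pd$H), seq_len(pd$W), , drop = FALSE]
  list(y = y, caches = caches, padH = dim(pd$x)[1], padW = dim(pd$x)[2])
}

.unetBwd <- function(model, fwd, dy) {
  ## dy on the cropped output; re-embed into padded frame
  dyp <- array(0, c(fwd$padH, fwd$padW, model$cout))
  dyp[seq_len(dim(dy)[1]), seq_len(dim(dy)[2]), ] <- dy
  grads <- list(enc = vector("list", model$depth),
                dec = vector("list", model$depth))
  g <- .convBwd(model$out, fwd$caches$out, dyp)
  grads$out <- list(W = g$dW, b = g$db)
  dz <- g$dx
  dskips <- vector("list", model$depth)
  for (l in seq_len(model$depth)) {            # decoder, top to bottom
    bb <- .incepBwd(model$dec[[l]], fwd$caches$dec[[l]], dz)
    grads$dec[[l]] <- list(branches = bb$branches)
    upC <- fwd$caches$upC[[l]]
    dskips[[l]] <- bb$dx[, , upC + seq_len(dim(bb$dx)[3] - upC), drop = FALSE]
    dz <- .upsampleBwd(bb$dx[, , seq_len(upC), drop = FALSE])
  }
  bb <- .incepBwd(model$bottom, fwd$caches$bottom, dz)
  grads$bottom <- list(branches = bb$branches)
  dz <- bb$dx
  for (l in rev(seq_len(model$depth))) {       # encoder, bottom to top
    dpool <- .avgpoolBwd(dz, fwd$caches$poolIn[[l]])
    dsum <- dpool + dskips[[l]]
    bb <- .incepBwd(model$enc[[l]], fwd$caches$enc[[l]], dsum)
    grads$enc[[l]] <- list(branches = bb$branches)
    dz <- bb$dx
  }
  grads
}

## ---- dense MLP --------------------------------------------------------------

.mlpInit <- function(din, hidden, dout) {
  sizes <- c(din, hidden, dout)
  layers <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    layers[[i]] <- list(W = matrix(rnorm(sizes[i] * sizes[i + 1],
                                         sd = sqrt(2 / sizes[i])),
                                   sizes[i], sizes[i + 1]),
                        b = rep(0, sizes[i + 1]))
  }
  list(kind = "mlp", layers = layers, din = din, dout = dout)
}

.mlpFwd <- function(model, X) {
  acts <- list(X)
  nl <- length(model$layers)
  for (i in seq_len(nl)) {
    Z <- sweep(acts[[i]] %*% model$layers[[i]]$W, 2L,
               model$layers[[i]]$b, `+`)
    acts[[i + 1L]] <- if (i < nl) .relu(Z) else Z
  }
  list(out = acts[[nl + 1L]], acts = acts)
}

.mlpBwd <- function(model, fwd, dOut) {
  nl <- length(model$layers)
  grads <- vector("list", nl)
  delta <- dOut
  for (i in nl:1) {
    grads[[i]] <- list(W = crossprod(fwd$acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1L)
      delta <- tcrossprod(delta, model$layers[[i]]$W) * (fwd$acts[[i]] > 0)
  }
  list(layers = grads)
}

## ---- losses -----------------------------------------------------------------

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Focal loss
#'
#' `FL = -alpha_c (1 - p_t)^gamma log(p_t)` averaged over pixels, the
#' class-imbalance-robust generalization of cross-entropy (`gamma = 0`,
#' `alpha = 1` reduces to cross-entropy exactly).  `p_t`, the probability
#' assigned to the true class, is clamped below at `eps`.
#'
#' @param probs N x C matrix of class probabilities (rows sum to 1).
#' @param trueClass integer vector of true class indices (1..C).
#' @param params list with `alpha` (length-C positive class weights) and
#'   `gamma` (focusing exponent >= 0); see [focalLossParams()].
#' @param eps probability clamp (default 1e-8).
#' @return scalar mean loss.
#' @examples
#' p <- matrix(c(0.5, 0.5), 1)
#' focalLoss(p, 1L, focalLossParams(alpha = c(1, 1), gamma = 2))  # 0.25*log(2)
#' @export
focalLoss <- function(probs, trueClass, params, eps = 1e-8) {
  stopifnot(all(trueClass >= 1L), all(trueClass <= ncol(probs)))
  pt <- pmax(probs[cbind(seq_len(nrow(probs)), trueClass)], eps)
  al <- params$alpha[trueClass]
  mean(-al * (1 - pt)^params$gamma * log(pt))
}

#' Focal loss parameters
#'
#' @param alpha positive per-class weights.
#' @param gamma focusing exponent (>= 0); 2 is the common default.
#' @return validated list.
#' @export
focalLossParams <- function(alpha, gamma = 2) {
  stopifnot(all(alpha > 0), gamma >= 0)
  list(alpha = alpha, gamma = gamma)
}

## gradient of mean focal loss wrt logits (via softmax)
.focalGradLogits <- function(probs, trueClass, params, eps = 1e-8) {
  N <- nrow(probs)
  pt <- pmax(probs[cbind(seq_len(N), trueClass)], eps)
  al <- params$alpha[trueClass]
  g <- params$gamma
  ## dFL/dpt
  dpt <- -al * (-g * (1 - pt)^(pmax(g - 1, 0)) * log(pt) + (1 - pt)^g / pt)
  ## dpt/dz_j = pt (1[y=j] - p_j)
  onehot <- matrix(0, N, ncol(probs))
  onehot[cbind(seq_len(N), trueClass)] <- 1
  (dpt * pt) * (onehot - probs) / N
}

## ---- Adam -------------------------------------------------------------------
## Walks arbitrary nested lists, updating numeric leaves named W or b with
## the gradient leaf at the same path.

.walkParams <- function(model, grads, state, fn) {
  rec <- function(m, g, s) {
    if (is.list(m)) {
      nms <- names(m)
      if (length(s) == 0L) s <- vector("list", length(m))
      for (ii in seq_along(m)) {
        nm <- if (is.null(nms)) "" else nms[ii]
        gg <- if (nzchar(nm)) g[[nm]] else g[[ii]]
        if (is.null(gg)) next
        if (nm %in% c("W", "b")) {
          r <- fn(m[[ii]], gg, s[[ii]])
          m[[ii]] <- r$p
          s[[ii]] <- r$s
        } else if (is.list(m[[ii]])) {
          r <- rec(m[[ii]], gg, if (is.null(s[[ii]])) list() else s[[ii]])
          m[[ii]] <- r$m
          s[[ii]] <- r$s
        }
      }
      if (!is.null(nms)) names(s) <- nms
    }
    list(m = m, s = s)
  }
  rec(model, grads, state)
}

.adamStep <- function(model, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    if (is.null(s)) s <- list(m = 0 * p, v = 0 * p)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  .walkParams(model, grads, state, upd)
}

## elementwise sum of two gradient structures (for minibatch averaging)
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  rec <- function(x, y) {
    if (is.list(x)) {
      for (nm in names(x)) x[[nm]] <- rec(x[[nm]], y[[nm]])
      x
    } else x + y
  }
  rec(a, b)
}

.scaleGrads <- function(g, f) {
  rec <- function(x) {
    if (is.list(x)) { for (nm in names(x)) x[[nm]] <- rec(x[[nm]]); x }
    else x * f
  }
  rec(g)
}

## ---- channel standardization ------------------------------------------------

## per-channel mean/sd over a list of [H,W,C] arrays; epsilon-guarded so a
## zero-variance channel contributes no gradient
.channelStats <- function(samples, eps = 1e-8) {
  C <- dim(samples[[1]])[3]
  mu <- numeric(C); sdv <- numeric(C)
  for (c in seq_len(C)) {
    v <- unlist(lapply(samples, function(s) as.vector(s[, , c])))
    mu[c] <- mean(v)
    sdv[c] <- max(sd(v), eps)
  }
  list(mu = mu, sd = sdv, eps = eps)
}

.standardize <- function(x, stats) {
  for (c in seq_len(dim(x)[3]))
    x[, , c] <- (x[, , c] - stats$mu[c]) / stats$sd[c]
  x
}

.unstandardize <- function(x, stats) {
  for (c in seq_len(dim(x)[3]))
    x[, , c] <- x[, , c] * stats$sd[c] + stats$mu[c]
  x
}
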