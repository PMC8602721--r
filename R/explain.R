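## Deep Taylor decomposition (DTD) relevance propagation and the two
## attribution analyses built on it: the dominant physical property per
## stimulus phase-diagram point, and the time-resolved geometry importance
## with the segment-swap comparison.
##
## Rules: the z+ rule for hidden layers (relevance redistributed along
## positive-weight contributions of the non-negative post-ReLU activations)
## and the box-constrained z^B rule for the (possibly negative, bounded)
## input layer.  Biases take no relevance, so the propagated relevance is
## conserved layer by layer up to the epsilon guards.

.DTD_EPS <- 1e-12

## z+ through a dense layer: aPrev (N x din, >= 0), R (N x dout)
.dtdDenseZplus <- function(W, aPrev, R) {
  Wp <- pmax(W, 0)
  Z <- aPrev %*% Wp
  M <- R / (Z + .DTD_EPS)
  aPrev * tcrossprod(M, Wp)
}

## z^B through the input dense layer with per-feature bounds lo <= x <= hi
.dtdDenseZB <- function(W, X, R, lo, hi) {
  Wp <- pmax(W, 0); Wn <- pmin(W, 0)
  Z <- X %*% W - matrix(lo, nrow(X), length(lo), byrow = TRUE) %*% Wp -
       matrix(hi, nrow(X), length(hi), byrow = TRUE) %*% Wn
  M <- R / (Z + .DTD_EPS)
  X * tcrossprod(M, W) -
    matrix(lo, nrow(X), length(lo), byrow = TRUE) * tcrossprod(M, Wp) -
    matrix(hi, nrow(X), length(hi), byrow = TRUE) * tcrossprod(M, Wn)
}

#' Deep Taylor relevance for a dense classifier
#'
#' Propagates the (non-negative part of the) selected output score back to
#' the input features with the z+ rule on hidden layers and, optionally, the
#' z^B rule on the input layer.
#'
#' @param model an internal MLP (e.g. `pixelClassifier$model`).
#' @param X input matrix (rows = samples, standardized scale).
#' @param target integer class column, or `"predicted"` (default) for each
#'   row's argmax.
#' @param inputRule `"zB"` (default) or `"zplus"` (requires non-negative
#'   inputs).
#' @param lo,hi per-feature bounds for z^B; default = column min/max of `X`
#'   (widened to include 0).
#' @return list with `relevance` (same shape as `X`), `score` (explained
#'   output per row) and `target` (class column per row).
#' @export
dtdRelevanceMLP <- function(model, X, target = "predicted",
                            inputRule = c("zB", "zplus"),
                            lo = NULL, hi = NULL) {
  inputRule <- match.arg(inputRule)
  X <- as.matrix(X)
  fwd <- .mlpFwd(model, X)
  logits <- fwd$out
  tgt <- if (identical(target, "predicted"))
    max.col(logits, ties.method = "first") else rep_len(as.integer(target),
                                                        nrow(X))
  score <- pmax(logits[cbind(seq_len(nrow(X)), tgt)], 0)
  R <- matrix(0, nrow(X), ncol(logits))
  R[cbind(seq_len(nrow(X)), tgt)] <- score
  nl <- length(model$layers)
  for (l in nl:1) {
    aPrev <- fwd$acts[[l]]
    W <- model$layers[[l]]$W
    if (l > 1L) {
      R <- .dtdDenseZplus(W, aPrev, R)
    } else if (inputRule == "zplus") {
      if (any(aPrev < 0))
        stop("zplus input rule requires non-negative inputs; use zB")
      R <- .dtdDenseZplus(W, aPrev, R)
    } else {
      if (is.null(lo)) lo <- pmin(apply(X, 2, min), 0)
      if (is.null(hi)) hi <- pmax(apply(X, 2, max), 0)
      R <- .dtdDenseZB(W, aPrev, R, lo, hi)
    }
  }
  list(relevance = R, score = score, target = tgt)
}

## z+ (or zB for the first layer) through a conv layer, using the cached
## im2col patches.  R comes in as [H,W,cout]; returns [H,W,cin].
.dtdConv <- function(layer, cache, R, first = FALSE, lo = NULL, hi = NULL) {
  H <- cache$H; W <- cache$W
  RM <- matrix(R, H * W, layer$cout)
  cols <- cache$cols
  if (!first) {
    Wp <- pmax(layer$W, 0)
    Z <- cols %*% Wp
    M <- RM / (Z + .DTD_EPS)
    Rcols <- cols * tcrossprod(M, Wp)
  } else {
    ## per-entry bounds via the same pad + im2col path so that padding
    ## entries carry lo = hi = 0 and take no relevance
    mkBound <- function(v) {
      a <- array(rep(v, each = H * W), c(H, W, layer$cin))
      ap <- if (cache$ph || cache$pw) .pad2d(a, cache$ph, cache$pw) else a
      .im2col(ap, layer$kh, layer$kw, H, W)
    }
    loCols <- mkBound(pmin(lo, 0))
    hiCols <- mkBound(pmax(hi, 0))
    Wp <- pmax(layer$W, 0); Wn <- pmin(layer$W, 0)
    Z <- cols %*% layer$W - loCols %*% Wp - hiCols %*% Wn
    M <- RM / (Z + .DTD_EPS)
    Rcols <- cols * tcrossprod(M, layer$W) -
      loCols * tcrossprod(M, Wp) -
      hiCols * tcrossprod(M, Wn)
  }
  .col2im(Rcols, layer, H, W, cache$ph, cache$pw)
}

## relevance through an inception block (concat split, conv back, sum)
.dtdIncep <- function(block, cache, R, first = FALSE, lo = NULL, hi = NULL) {
  at <- 0L
  Rin <- NULL
  for (i in seq_along(block$branches)) {
    br <- block$branches[[i]]
    Rb <- .dtdConv(br, cache$convs[[i]],
                   R[, , at + seq_len(br$cout), drop = FALSE],
                   first = first, lo = lo, hi = hi)
    at <- at + br$cout
    Rin <- if (is.null(Rin)) Rb else Rin + Rb
  }
  Rin
}

#' Deep Taylor relevance for the field U-Net
#'
#' Explains a scalar target -- the positive part of one output channel
#' summed over a pixel mask -- by propagating relevance back through the
#' decoder, skip connections, pooling and encoder to the input channels.
#' The input layer uses the z^B rule with per-channel bounds taken from the
#' actual input (widened to include 0).
#'
#' @param model an internal U-Net (e.g. `fieldNet$model`).
#' @param x input array `[H, W, Cin]` (standardized scale).
#' @param channel output channel to explain, or `"all"` to sum all channels.
#' @param mask logical matrix of target pixels (default: all).
#' @return list with `relevance` (`[H, W, Cin]`, the per-input-pixel/channel
#'   scores) and `score` (the explained output sum).
#' @export
dtdRelevanceUnet <- function(model, x, channel = "all", mask = NULL) {
  fwd <- .unetFwd(model, x)
  y <- fwd$y
  d <- dim(y)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  sel <- if (identical(channel, "all")) seq_len(d[3]) else as.integer(channel)
  Ry <- array(0, d)
  for (c in sel) Ry[, , c] <- pmax(y[, , c], 0) * mask
  score <- sum(Ry)

  ## embed into the padded frame the forward pass used
  Rp <- array(0, c(fwd$padH, fwd$padW, d[3]))
  Rp[seq_len(d[1]), seq_len(d[2]), ] <- Ry

  ## output 1x1 conv (z+; its input is post-ReLU)
  R <- .dtdConv(model$out, fwd$caches$out, Rp)
  Rskips <- vector("list", model$depth)
  for (l in seq_len(model$depth)) {             # decoder, top to bottom
    R <- .dtdIncep(model$dec[[l]], fwd$caches$dec[[l]], R)
    upC <- fwd$caches$upC[[l]]
    Rskips[[l]] <- R[, , upC + seq_len(dim(R)[3] - upC), drop = FALSE]
    R <- .upsampleBwd(R[, , seq_len(upC), drop = FALSE])
  }
  R <- .dtdIncep(model$bottom, fwd$caches$bottom, R)
  for (l in rev(seq_len(model$depth))) {        # encoder, bottom to top
    a <- .relu(fwd$caches$enc[[l]]$z)           # pool input activations
    pooled <- .avgpoolFwd(a)
    ratio <- .upsampleFwd(R / (pooled + .DTD_EPS)) / 4
    Rpool <- a * ratio
    Rsum <- Rpool + Rskips[[l]]
    if (l > 1L) {
      R <- .dtdIncep(model$enc[[l]], fwd$caches$enc[[l]], Rsum)
    } else {
      lo <- apply(x, 3, min); hi <- apply(x, 3, max)
      R <- .dtdIncep(model$enc[[l]], fwd$caches$enc[[l]], Rsum,
                     first = TRUE, lo = lo, hi = hi)
    }
  }
  list(relevance = R[seq_len(d[1]), seq_len(d[2]), , drop = FALSE],
       score = score)
}

#' Dominant input property per pixel
#'
#' The argmax relevance channel per row; ties broken by channel order,
#' all-zero rows labelled `"undetermined"`.  Invariant to positive rescaling
#' of the relevance vectors.
#'
#' @param relevance matrix (rows = pixels, columns = input channels).
#' @param channels channel names (default the five physical features).
#' @return factor vector with levels `channels` plus `"undetermined"`.
#' @export
dominantProperty <- function(relevance,
                             channels = c("epsI", "epsII", "epsIII",
                                          "vx", "vy")) {
  relevance <- as.matrix(relevance)
  stopifnot(ncol(relevance) == length(channels))
  idx <- max.col(relevance, ties.method = "first")
  idx[rowSums(abs(relevance)) == 0] <- length(channels) + 1L
  lab <- c(channels, "undetermined")
  factor(lab[idx], levels = lab)
}

#' Stimulus phase diagram dataset
#'
#' One record per callus pixel-day: octahedral shear strain `gamma`, fluid
#' speed `nu`, the stimulus `S`, the phenotype of the left-closed stimulus
#' interval, and (optionally) the DTD-dominant property.  Pixels with
#' `gamma == 0` or `nu == 0` are dropped (log axes) and counted.
#'
#' @param history a [HealingHistory-class] (simulator or rollout).
#' @param thresholds a [phenotypeThresholds()] list.
#' @param dominantFun optional `function(fields, day)` returning a factor of
#'   dominant properties for the callus pixels of that day (e.g. from
#'   [dtdRelevanceMLP()] on the pixel classifier).
#' @param params a [stimulusParams()] list.
#' @param days day indices to include (default `1:T`).
#' @return list with `data` (data.frame: `day`, `gamma`, `nu`, `S`,
#'   `phenotype`, optionally `dominant`) and `nDropped`.
#' @export
phaseDiagram <- function(history, thresholds = phenotypeThresholds(),
                         dominantFun = NULL, params = stimulusParams(),
                         days = NULL) {
  dom <- domain(history)
  cal <- callusMask(dom)
  T <- nDays(history) - 1L
  if (is.null(days)) days <- seq_len(T)
  phenNames <- names(.PHEN_DIFF)
  out <- list(); dropped <- 0L
  for (t in days) {
    f <- fieldsDay(history, t)
    gam <- octahedralShearStrain(f@eps1, f@eps2, f@eps3)[cal]
    spd <- sqrt(f@vx^2 + f@vy^2)[cal]
    S <- stimulus(gam, spd, params)
    keep <- gam > 0 & spd > 0
    dropped <- dropped + sum(!keep)
    iv <- findInterval(S[keep], c(0, thresholds$breaks))
    rec <- data.frame(day = t, gamma = gam[keep], nu = spd[keep],
                      S = S[keep], phenotype = phenNames[iv])
    if (!is.null(dominantFun)) {
      dmn <- dominantFun(f, t)
      rec$dominant <- dmn[keep]
    }
    out[[length(out) + 1L]] <- rec
  }
  list(data = do.call(rbind, out), nDropped = dropped)
}

#' Per-day geometry importance from field-net relevance
#'
#' For each day of a history, applies DTD to the field net (target: the
#' day's summed positive output evidence over the callus region) and keeps
#' the `topFraction` most relevant pixels (relevance summed over input
#' channels).  The result is a day-stamped stack of masks -- the pixels of
#' the geometry that influence that day's prediction the most.
#'
#' @param history a [HealingHistory-class] (typically a rollout).
#' @param bundle the [SurrogateBundle-class] whose field net is explained.
#' @param topFraction fraction of pixels kept per day (default 0.05).
#' @param channel output channel for the target (default `"all"`).
#' @return list with `masks` (list of logical matrices per day), `relevance`
#'   (list of summed relevance matrices) and `days`.
#' @export
geometryImportance <- function(history, bundle, topFraction = 0.05,
                               channel = "all") {
  dom <- domain(history)
  cal <- callusMask(dom)
  T <- nDays(history) - 1L
  masks <- list(); rels <- list()
  for (t in 0:T) {
    x <- .standardize(.fieldInput(materialDay(history, t)),
                      bundle@fieldNet$inStats)
    r <- dtdRelevanceUnet(bundle@fieldNet$model, x, channel = channel,
                          mask = cal)
    tot <- apply(r$relevance, c(1, 2), sum)
    k <- max(1L, as.integer(ceiling(topFraction * length(tot))))
    thr <- sort(tot, decreasing = TRUE)[k]
    masks[[t + 1L]] <- tot >= thr & tot > 0
    rels[[t + 1L]] <- tot
  }
  list(masks = masks, relevance = rels, days = 0:T)
}

#' Segment-swap experiment
#'
#' Builds the two hybrid implants by swapping `rowRange` between A and B,
#' rolls out all four designs with the same surrogate bundle, and reports
#' the day-T phenotype agreement outside the swapped rows between each
#' original and its hybrid, against the cross-design baseline (A vs B), plus
#' the per-day geometry-importance overlap.
#'
#' @param domainA,domainB source [ImplantDomain-class] objects.
#' @param rowRange 0-based half-open row interval that was swapped.
#' @param bundle a trained [SurrogateBundle-class].
#' @param T rollout days.
#' @param config a [healingConfig()].
#' @param topFraction forwarded to [geometryImportance()].
#' @return list: `agreement` (named: `aVsAba`, `bVsBab`, `aVsB` computed
#'   outside `rowRange`), `importanceOverlap` (mean per-day Jaccard of
#'   top-pixel masks between original and hybrid), `rollouts`.
#' @export
swapExperiment <- function(domainA, domainB, rowRange, bundle, T = 35L,
                           config = healingConfig(days = T),
                           topFraction = 0.05) {
  hy <- swapSegment(domainA, domainB, rowRange)
  doms <- list(a = domainA, b = domainB, aba = hy$aba, bab = hy$bab)
  rolls <- lapply(names(doms), function(nm) {
    d <- doms[[nm]]
    codes <- regionMap(d); cal <- callusMask(d)
    phen <- codes; phen[cal] <- phenotypeCodes()[["granulation"]]
    m0 <- materialFromPhenotype(PhenotypeMap(phen, d), d,
                                matrix(0, nrow(codes), ncol(codes)),
                                config$materials)
    rollout(m0, d, bundle, T = T, config = config, caseId = nm)
  })
  names(rolls) <- names(doms)

  outside <- rep(TRUE, gridSpec(domainA)@nrow)
  if (rowRange[2] > rowRange[1]) outside[(rowRange[1] + 1L):rowRange[2]] <- FALSE
  agree <- function(h1, h2) {
    m1 <- phenotypeMatrix(phenotypeDay(h1, T))[outside, , drop = FALSE]
    m2 <- phenotypeMatrix(phenotypeDay(h2, T))[outside, , drop = FALSE]
    mean(m1 == m2)
  }
  gi <- lapply(rolls, geometryImportance, bundle = bundle,
               topFraction = topFraction)
  jacc <- function(g1, g2) {
    mean(vapply(seq_along(g1$masks), function(i) {
      u <- sum(g1$masks[[i]] | g2$masks[[i]])
      if (u == 0) return(1)
      sum(g1$masks[[i]] & g2$masks[[i]]) / u
    }, numeric(1)))
  }
  list(agreement = c(aVsAba = agree(rolls$a, rolls$aba),
                     bVsBab = agree(rolls$b, rolls$bab),
                     aVsB = agree(rolls$a, rolls$b)),
       importanceOverlap = c(aVsAba = jacc(gi$a, gi$aba),
                             bVsBab = jacc(gi$b, gi$bab)),
       rollouts = rolls)
}
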