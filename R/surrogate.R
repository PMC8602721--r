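## The multi-network surrogate for the mechano-regulatory loop:
##   Network 1 ("field net", U-Net + inception blocks): 4 material channels
##     -> the 6 physical channels (3 principal strains, 2 fluid velocity
##     components, next-day stem-cell concentration);
##   Network 2 ("pixel classifier", MLP): the 5 mechanical/fluid channels at
##     one pixel -> the 5 differentiated phenotypes, trained with focal loss
##     against class imbalance;
##   Network 3 ("denoiser", U-Net): structured cleanup of the assembled
##     phenotype map (removes singular pixels);
##   plus a binary random-forest corrector for the frequent
##   resorption-vs-mature-bone confusion, and the autoregressive 35-day
##   rollout that alternates these learned steps with the analytic material
##   blend and history smoothing.

## ---- day pairs --------------------------------------------------------------

#' Build the day-pair dataset from a healing history
#'
#' All ordered day pairs `(i, j)` with `i < j <= T` and `j - i <= maxGap`.
#' A (T+1)-day history with unlimited gap yields `(T+1) T / 2` pairs (630
#' for days 0..35).  Pairs with gap 1 carry the single-step supervision for
#' the field net and pixel classifier; larger gaps serve as curriculum
#' augmentation for the denoiser (see [trainDenoiser()]).
#'
#' @param history a [HealingHistory-class].
#' @param maxGap largest day gap to include (default `Inf`).
#' @return list with `caseId`, `T`, and `pairs` (data.frame `i`, `j`, `gap`).
#'   A history with fewer than 2 days yields zero pairs.
#' @examples
#' # a 36-state history produces choose(36, 2) = 630 pairs
#' @export
makeDayPairs <- function(history, maxGap = Inf) {
  T <- nDays(history) - 1L
  if (T < 1L)
    return(list(caseId = caseId(history), T = T,
                pairs = data.frame(i = integer(), j = integer(),
                                   gap = integer())))
  ij <- expand.grid(i = 0:T, j = 0:T)
  ij <- ij[ij$i < ij$j & (ij$j - ij$i) <= maxGap, ]
  ij <- ij[order(ij$i, ij$j), ]
  rownames(ij) <- NULL
  list(caseId = caseId(history), T = T,
       pairs = data.frame(i = ij$i, j = ij$j, gap = ij$j - ij$i))
}

## ---- tensor encodings -------------------------------------------------------

## the 4 material input channels; stiffness and permeability are log10-scaled
## before z-scoring because they span many decades
.K_FLOOR <- 1e-18

.fieldInput <- function(material) {
  d <- dim(material@E)
  x <- array(0, c(d[1], d[2], 4L))
  x[, , 1] <- log10(material@E)
  x[, , 2] <- material@nuP
  x[, , 3] <- log10(material@k + .K_FLOOR)
  x[, , 4] <- material@n
  x
}

.fieldTarget <- function(fields) {
  d <- dim(fields@eps1)
  y <- array(0, c(d[1], d[2], 6L))
  y[, , 1] <- fields@eps1; y[, , 2] <- fields@eps2; y[, , 3] <- fields@eps3
  y[, , 4] <- fields@vx;   y[, , 5] <- fields@vy;   y[, , 6] <- fields@nNext
  y
}

## per-pixel 5-feature matrix (strains + velocities) for masked pixels
.pixelFeatures <- function(fields, mask) {
  cbind(fields@eps1[mask], fields@eps2[mask], fields@eps3[mask],
        fields@vx[mask], fields@vy[mask])
}

## ---- field net (Network 1) --------------------------------------------------

#' Train the field-regression network (Network 1)
#'
#' An encoder-decoder with inception-style multi-kernel blocks and skip
#' connections maps the 4 standardized material channels of day `i` to the 6
#' standardized physical channels of that day (strains and fluid velocities
#' of day `i`, concentration of day `i+1`).  Gap-1 day pairs supply the
#' supervision.  Targets are z-scored per channel with training-split
#' statistics; a zero-variance channel receives loss weight 0 (epsilon guard
#' 1e-8).  Adam with early stopping (patience in epochs) on a held-out
#' fraction of the samples.
#'
#' @param histories list of [HealingHistory-class] (training cases).
#' @param config list; see [surrogateConfig()] element `fieldNet`
#'   (`baseFilters`, `depth`, `kernels`, `epochs`, `lr`, `batchSize`,
#'   `patience`, `valFraction`, `seed`).
#' @return list with the trained `model`, `inStats`, `outStats`,
#'   `lossWeights`, `log` (per-epoch losses) and `config`.
#' @export
trainFieldNet <- function(histories, config = list()) {
  cfg <- modifyList(list(baseFilters = 9L, depth = 2L, kernels = c(1L, 3L, 5L),
                         epochs = 80L, lr = 2e-3, batchSize = 4L,
                         patience = 20L, valFraction = 0.2, seed = 1L),
                    config)
  xs <- list(); ys <- list()
  for (h in histories) {
    T <- nDays(h) - 1L
    for (i in 0:(T - 1L)) {
      xs[[length(xs) + 1L]] <- .fieldInput(materialDay(h, i))
      ys[[length(ys) + 1L]] <- .fieldTarget(fieldsDay(h, i))
    }
  }
  if (!length(xs)) stop("no gap-1 day pairs available for training")
  inStats <- .channelStats(xs)
  outStats <- .channelStats(ys)
  lw <- as.numeric(outStats$sd > outStats$eps)       # zero-variance guard
  xs <- lapply(xs, .standardize, stats = inStats)
  ys <- lapply(ys, .standardize, stats = outStats)

  .withSeed(cfg$seed, {
    model <- .unetInit(4L, 6L, cfg$baseFilters, cfg$depth, cfg$kernels)
    n <- length(xs)
    nVal <- max(1L, min(n - 1L, round(cfg$valFraction * n)))
    perm <- sample.int(n)
    valId <- perm[seq_len(nVal)]
    trId <- setdiff(perm, valId)
    if (!length(trId)) { trId <- valId }             # single-sample corner

    wArr <- function(d) {
      a <- array(0, d)
      for (c in seq_len(d[3])) a[, , c] <- lw[c]
      a
    }
    lossOf <- function(mdl, ids) {
      mean(vapply(ids, function(s) {
        f <- .unetFwd(mdl, xs[[s]])
        w <- wArr(dim(ys[[s]]))
        sum(w * (f$y - ys[[s]])^2) / max(sum(w), 1)
      }, numeric(1)))
    }

    st <- list(); tstep <- 0L
    best <- model; bestVal <- Inf; wait <- 0L
    log <- data.frame(epoch = integer(), train = numeric(), val = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(trId)
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batchSize))) {
        g <- NULL
        for (s in b) {
          f <- .unetFwd(model, xs[[s]])
          w <- wArr(dim(ys[[s]]))
          dy <- 2 * w * (f$y - ys[[s]]) / max(sum(w), 1)
          g <- .addGrads(g, .unetBwd(model, f, dy))
        }
        g <- .scaleGrads(g, 1 / length(b))
        tstep <- tstep + 1L
        r <- .adamStep(model, g, st, cfg$lr, tstep)
        model <- r$m; st <- r$s
      }
      trL <- lossOf(model, trId); vaL <- lossOf(model, valId)
      log <- rbind(log, data.frame(epoch = ep, train = trL, val = vaL))
      if (!is.finite(trL)) stop("non-finite field-net loss at epoch ", ep)
      if (vaL < bestVal - 1e-12) {
        bestVal <- vaL; best <- model; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    list(kind = "fieldNet", model = best, inStats = inStats,
         outStats = outStats, lossWeights = lw, log = log, config = cfg)
  })
}

#' Predict the six physical fields from a material state
#'
#' Applies the trained field net and undoes the target standardization.
#' The three strain channels are re-sorted per pixel to maintain the
#' principal-strain ordering contract and the concentration channel is
#' clamped to `[0, 1]`.
#'
#' @param fieldNet result of [trainFieldNet()].
#' @param material a [MaterialField-class].
#' @return list of matrices `eps1`, `eps2`, `eps3`, `vx`, `vy`, `nNext`.
#' @export
predictFieldNet <- function(fieldNet, material) {
  x <- .standardize(.fieldInput(material), fieldNet$inStats)
  y <- .unetFwd(fieldNet$model, x)$y
  y <- .unstandardize(y, fieldNet$outStats)
  e1 <- pmax(y[, , 1], y[, , 2], y[, , 3])
  e3 <- pmin(y[, , 1], y[, , 2], y[, , 3])
  e2 <- y[, , 1] + y[, , 2] + y[, , 3] - e1 - e3
  if (any(!is.finite(y))) stop("non-finite field-net prediction")
  list(eps1 = e1, eps2 = e2, eps3 = e3, vx = y[, , 4], vy = y[, , 5],
       nNext = pmin(pmax(y[, , 6], 0), 1))
}

## ---- pixel classifier (Network 2) ------------------------------------------

#' Train the per-pixel phenotype classifier (Network 2)
#'
#' A multilayer perceptron maps the 5 physical features of a callus pixel on
#' day `i` (three principal strains and two velocity components -- the
#' concentration channel is not used) to the phenotype the mechano-regulatory
#' rule assigns on day `i+1`.  Trained with focal loss; the default class
#' weights are inverse training-class frequencies and `gamma = 2`.
#' Day pairs with gap greater than `curriculumGap` are excluded; gaps above 1
#' act as curriculum augmentation, down-weighted by `1/gap`.
#'
#' @param histories list of training [HealingHistory-class] objects.
#' @param config see [surrogateConfig()] element `pixelClassifier`
#'   (`hidden`, `epochs`, `lr`, `batchSize`, `gamma`, `alpha`,
#'   `curriculumGap`, `maxPixels`, `seed`).
#' @return list with `model`, `stats`, `focal` parameters, `classes`,
#'   `log`, `config`.
#' @export
trainPixelClassifier <- function(histories, config = list()) {
  cfg <- modifyList(list(hidden = c(64L, 64L, 64L), epochs = 60L, lr = 2e-3,
                         batchSize = 4096L, gamma = 2, alpha = NULL,
                         curriculumGap = 1L, maxPixels = 2e5, seed = 1L),
                    config)
  feats <- list(); labs <- list(); wts <- list()
  for (h in histories) {
    cal <- callusMask(domain(h))
    T <- nDays(h) - 1L
    pr <- makeDayPairs(h, maxGap = cfg$curriculumGap)$pairs
    for (r in seq_len(nrow(pr))) {
      i <- pr$i[r]; j <- pr$j[r]
      lab <- phenotypeMatrix(phenotypeDay(h, j))[cal]
      keep <- lab %in% .PHEN_DIFF
      if (!any(keep)) next
      feats[[length(feats) + 1L]] <-
        .pixelFeatures(fieldsDay(h, i), cal)[keep, , drop = FALSE]
      labs[[length(labs) + 1L]] <- match(lab[keep], .PHEN_DIFF)
      wts[[length(wts) + 1L]] <- rep(1 / pr$gap[r], sum(keep))
    }
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  w <- unlist(wts)
  if (is.null(X) || !nrow(X)) stop("no labelled callus pixels to train on")

  .withSeed(cfg$seed, {
    if (nrow(X) > cfg$maxPixels) {
      keep <- sample.int(nrow(X), cfg$maxPixels)
      X <- X[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
    }
    mu <- colMeans(X); sdv <- pmax(apply(X, 2, sd), 1e-8)
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
    alpha <- cfg$alpha
    if (is.null(alpha)) {
      cnt <- tabulate(y, 5L)
      alpha <- length(y) / (5 * pmax(cnt, 1))        # inverse frequency
      alpha <- alpha / mean(alpha)
    }
    fp <- focalLossParams(alpha = alpha, gamma = cfg$gamma)
    model <- .mlpInit(5L, cfg$hidden, 5L)
    st <- list(); tstep <- 0L
    log <- data.frame(epoch = integer(), loss = numeric())
    n <- nrow(Xs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batchSize))) {
        f <- .mlpFwd(model, Xs[b, , drop = FALSE])
        p <- .softmax(f$out)
        dz <- .focalGradLogits(p, y[b], fp) * w[b]
        g <- .mlpBwd(model, f, dz)
        tstep <- tstep + 1L
        r <- .adamStep(model, g, st, cfg$lr, tstep)
        model <- r$m; st <- r$s
      }
      p <- .softmax(.mlpFwd(model, Xs)$out)
      L <- focalLoss(p, y, fp)
      if (!is.finite(L)) stop("non-finite classifier loss at epoch ", ep)
      log <- rbind(log, data.frame(epoch = ep, loss = L))
    }
    list(kind = "pixelClassifier", model = model,
         stats = list(mu = mu, sd = sdv), focal = fp,
         classes = .PHEN_DIFF, log = log, config = cfg)
  })
}

#' Per-pixel phenotype scores and map from predicted fields
#'
#' Flattens the masked pixels of the field prediction to 1 x 5 feature
#' vectors (a 210 x 52 grid yields 10,920 vectors when unmasked), scores
#' them with the classifier, and assembles the argmax map; non-callus pixels
#' keep their fixed region codes.
#'
#' @param classifier result of [trainPixelClassifier()].
#' @param fields list or [PhysicalFields-class] with the 5 feature channels.
#' @param domain the [ImplantDomain-class].
#' @return list with `map` (a [PhenotypeMap-class]) and `probs`
#'   (callus-pixel score matrix, columns in the fixed phenotype order).
#' @export
predictPixelClassifier <- function(classifier, fields, domain) {
  cal <- callusMask(domain)
  F <- if (is(fields, "PhysicalFields")) {
    .pixelFeatures(fields, cal)
  } else {
    cbind(fields$eps1[cal], fields$eps2[cal], fields$eps3[cal],
          fields$vx[cal], fields$vy[cal])
  }
  Fs <- sweep(sweep(F, 2, classifier$stats$mu), 2, classifier$stats$sd, `/`)
  p <- .softmax(.mlpFwd(classifier$model, Fs)$out)
  codes <- regionMap(domain)
  codes[cal] <- .PHEN_DIFF[max.col(p, ties.method = "first")]
  list(map = PhenotypeMap(codes, domain), probs = p)
}

## ---- denoiser (Network 3) ---------------------------------------------------

.oneHotMap <- function(map, domain) {
  cal <- callusMask(domain)
  codes <- phenotypeMatrix(map)
  d <- dim(codes)
  x <- array(0, c(d[1], d[2], 6L))
  for (c in seq_len(5L)) x[, , c] <- (codes == .PHEN_DIFF[c]) * 1
  x[, , 6] <- cal * 1
  x
}

#' Train the structured denoising network (Network 3)
#'
#' A U-Net consumes the one-hot-encoded phenotype map assembled from the
#' pixel classifier (plus a callus-mask channel) and is trained with focal
#' loss to reproduce the simulator's map for the same day, removing the
#' singular pixels the per-pixel classifier leaves behind.  Training inputs
#' are of two kinds: the classifier's own predictions on day pairs up to
#' `curriculumGap` (larger gaps give noisier inputs -- the curriculum), and
#' ground-truth maps with a fraction `corruptFraction` of callus pixels
#' flipped to random other phenotypes (the canonical singular-pixel
#' removal task, which also teaches the network to preserve clean maps).
#' Targets are always the simulator's maps.
#'
#' @param histories training histories.
#' @param classifier the trained pixel classifier whose outputs are denoised.
#' @param config see [surrogateConfig()] element `denoiser` (`baseFilters`,
#'   `depth`, `kernels`, `epochs`, `lr`, `gamma`, `curriculumGap`,
#'   `corruptFraction`, `seed`).
#' @return list with `model`, `focal`, `log`, `config`.
#' @export
trainDenoiser <- function(histories, classifier, config = list()) {
  cfg <- modifyList(list(baseFilters = 9L, depth = 2L, kernels = c(1L, 3L, 5L),
                         epochs = 40L, lr = 2e-3, gamma = 2,
                         curriculumGap = 3L, corruptFraction = 0.07,
                         seed = 1L),
                    config)
  xs <- list(); ts <- list(); doms <- list()
  for (h in histories) {
    dom <- domain(h)
    pr <- makeDayPairs(h, maxGap = cfg$curriculumGap)$pairs
    for (r in seq_len(nrow(pr))) {
      noisy <- predictPixelClassifier(classifier, fieldsDay(h, pr$i[r]),
                                      dom)$map
      truth <- phenotypeDay(h, pr$j[r])
      if (!any(phenotypeMatrix(truth) %in% .PHEN_DIFF)) next
      xs[[length(xs) + 1L]] <- .oneHotMap(noisy, dom)
      ts[[length(ts) + 1L]] <- truth
      doms[[length(doms) + 1L]] <- dom
    }
  }
  if (!length(xs)) stop("no denoiser training pairs")
  .withSeed(cfg$seed, {
    ## singular-pixel corruption pairs from the ground-truth maps
    for (h in histories) {
      dom <- domain(h)
      cal <- which(callusMask(dom))
      for (j in seq_len(nDays(h) - 1L)) {
        truth <- phenotypeDay(h, j)
        codes <- phenotypeMatrix(truth)
        if (!any(codes %in% .PHEN_DIFF)) next
        nFlip <- max(1L, round(cfg$corruptFraction * length(cal)))
        flip <- sample(cal, nFlip)
        codes[flip] <- vapply(codes[flip], function(v)
          sample(setdiff(.PHEN_DIFF, v), 1L), integer(1))
        xs[[length(xs) + 1L]] <- .oneHotMap(PhenotypeMap(codes, dom), dom)
        ts[[length(ts) + 1L]] <- truth
        doms[[length(doms) + 1L]] <- dom
      }
    }
    ## class weights over all targets (inverse frequency)
    allLab <- unlist(lapply(seq_along(ts), function(s) {
      lab <- phenotypeMatrix(ts[[s]])[callusMask(doms[[s]])]
      match(lab[lab %in% .PHEN_DIFF], .PHEN_DIFF)
    }))
    cnt <- tabulate(allLab, 5L)
    alpha <- length(allLab) / (5 * pmax(cnt, 1))
    fp <- focalLossParams(alpha = alpha / mean(alpha), gamma = cfg$gamma)

    model <- .unetInit(6L, 5L, cfg$baseFilters, cfg$depth, cfg$kernels)
    st <- list(); tstep <- 0L
    log <- data.frame(epoch = integer(), loss = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(xs))
      epLoss <- 0
      for (s in ord) {
        dom <- doms[[s]]; cal <- callusMask(dom)
        lab <- phenotypeMatrix(ts[[s]])[cal]
        keep <- lab %in% .PHEN_DIFF
        f <- .unetFwd(model, xs[[s]])
        d <- dim(f$y)
        logits <- matrix(f$y, d[1] * d[2], d[3])[which(cal)[keep], ,
                                                 drop = FALSE]
        p <- .softmax(logits)
        yy <- match(lab[keep], .PHEN_DIFF)
        epLoss <- epLoss + focalLoss(p, yy, fp)
        dz <- .focalGradLogits(p, yy, fp)
        dy <- array(0, d)
        dyM <- matrix(0, d[1] * d[2], d[3])
        dyM[which(cal)[keep], ] <- dz
        dy[] <- dyM
        g <- .unetBwd(model, f, dy)
        tstep <- tstep + 1L
        r <- .adamStep(model, g, st, cfg$lr, tstep)
        model <- r$m; st <- r$s
      }
      L <- epLoss / length(xs)
      if (!is.finite(L)) stop("non-finite denoiser loss at epoch ", ep)
      log <- rbind(log, data.frame(epoch = ep, loss = L))
    }
    list(kind = "denoiser", model = model, focal = fp, log = log,
         config = cfg)
  })
}

#' Denoise a phenotype map
#'
#' Runs the structured denoiser and replaces the differentiated phenotype of
#' each callus pixel by the network's argmax; all non-callus pixels are
#' untouched (post-masking).
#'
#' @param noisy a [PhenotypeMap-class].
#' @param denoiserNet result of [trainDenoiser()].
#' @param domain the [ImplantDomain-class].
#' @return the denoised [PhenotypeMap-class].
#' @export
denoiseMap <- function(noisy, denoiserNet, domain) {
  cal <- callusMask(domain)
  x <- .oneHotMap(noisy, domain)
  y <- .unetFwd(denoiserNet$model, x)$y
  d <- dim(y)
  logits <- matrix(y, d[1] * d[2], d[3])
  codes <- phenotypeMatrix(noisy)
  sel <- which(cal & matrix(codes %in% .PHEN_DIFF, d[1], d[2]))
  codes[sel] <- .PHEN_DIFF[max.col(logits[sel, , drop = FALSE],
                                   ties.method = "first")]
  PhenotypeMap(codes, domain)
}

## ---- resorption forest ------------------------------------------------------

## per-pixel forest features: the 5 field values plus the 4-neighbor mean of
## each channel
.forestFeatures <- function(fields, domain) {
  get <- function(nm) if (is(fields, "PhysicalFields")) slot(fields, nm)
                      else fields[[nm]]
  chans <- lapply(c("eps1", "eps2", "eps3", "vx", "vy"), get)
  nbrMean <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    s <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
    s[-1, ] <- s[-1, ] + m[-nr, ]; cnt[-1, ] <- cnt[-1, ] + 1
    s[-nr, ] <- s[-nr, ] + m[-1, ]; cnt[-nr, ] <- cnt[-nr, ] + 1
    s[, -1] <- s[, -1] + m[, -nc]; cnt[, -1] <- cnt[, -1] + 1
    s[, -nc] <- s[, -nc] + m[, -1]; cnt[, -nc] <- cnt[, -nc] + 1
    s / cnt
  }
  cal <- callusMask(domain)
  do.call(cbind, c(lapply(chans, function(m) m[cal]),
                   lapply(chans, function(m) nbrMean(m)[cal])))
}

#' Train the resorption-vs-mature-bone corrector forest
#'
#' The stimulus values of resorption and mature bone are adjacent, which
#' makes the pixel classifier confuse them (a type II error on resorption).
#' A bagged CART forest retrained on exactly this two-class subproblem
#' (features: the 5 physical values at the pixel and their 4-neighborhood
#' means) corrects those pixels.
#'
#' @param histories training histories.
#' @param config list (`nTrees`, `maxDepth`, `maxPixels`, `seed`).
#' @return a [randomForestBinary()] fit (label 1 = resorption), or `NULL`
#'   when the training data contain no resorption/mature pixels.
#' @export
trainResorptionForest <- function(histories, config = list()) {
  cfg <- modifyList(list(nTrees = 25L, maxDepth = 8L, maxPixels = 5e4,
                         seed = 1L), config)
  Xs <- list(); ys <- list()
  resC <- .PHEN_DIFF[["resorption"]]; matC <- .PHEN_DIFF[["mature"]]
  for (h in histories) {
    dom <- domain(h)
    cal <- callusMask(dom)
    T <- nDays(h) - 1L
    for (i in 0:(T - 1L)) {
      lab <- phenotypeMatrix(phenotypeDay(h, i + 1L))[cal]
      keep <- lab %in% c(resC, matC)
      if (!any(keep)) next
      Xs[[length(Xs) + 1L]] <-
        .forestFeatures(fieldsDay(h, i), dom)[keep, , drop = FALSE]
      ys[[length(ys) + 1L]] <- as.integer(lab[keep] == resC)
    }
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  if (is.null(X) || !nrow(X) || length(unique(y)) < 2L) return(NULL)
  if (nrow(X) > cfg$maxPixels) {
    keep <- .withSeed(cfg$seed, sample.int(nrow(X), cfg$maxPixels))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  randomForestBinary(X, y, nTrees = cfg$nTrees, maxDepth = cfg$maxDepth,
                     seed = cfg$seed)
}

#' Apply the resorption corrector to a phenotype map
#'
#' Only callus pixels currently labelled resorption or mature bone may
#' change, and only between those two classes; every other pixel is
#' untouched.
#'
#' @param map a [PhenotypeMap-class].
#' @param fields the day's physical fields (list or
#'   [PhysicalFields-class]).
#' @param forest result of [trainResorptionForest()] (`NULL` passes the map
#'   through).
#' @param domain the [ImplantDomain-class].
#' @return the corrected [PhenotypeMap-class].
#' @export
correctResorption <- function(map, fields, forest, domain) {
  if (is.null(forest)) return(map)
  codes <- phenotypeMatrix(map)
  cal <- callusMask(domain)
  resC <- .PHEN_DIFF[["resorption"]]; matC <- .PHEN_DIFF[["mature"]]
  cand <- cal & (codes == resC | codes == matC)
  if (!any(cand)) return(map)
  F <- .forestFeatures(fields, domain)
  rows <- match(which(cand), which(cal))
  pred <- predictForest(forest, F[rows, , drop = FALSE])
  codes[cand] <- ifelse(pred == 1L, resC, matC)
  PhenotypeMap(codes, domain)
}

## ---- bundle + rollout -------------------------------------------------------

#' Surrogate training configuration
#'
#' Nested defaults for the four components plus the case split.  Every
#' network seed fans out deterministically from `seed`.
#'
#' @param seed master seed.
#' @param testFraction fraction of cases held out (case-level split,
#'   default 0.2).
#' @param fieldNet,pixelClassifier,denoiser,forest per-component overrides.
#' @return nested config list.
#' @export
surrogateConfig <- function(seed = 1L, testFraction = 0.2,
                            fieldNet = list(), pixelClassifier = list(),
                            denoiser = list(), forest = list()) {
  list(seed = as.integer(seed), testFraction = testFraction,
       fieldNet = fieldNet, pixelClassifier = pixelClassifier,
       denoiser = denoiser, forest = forest)
}

#' Train the full surrogate bundle
#'
#' Splits the cases 80/20 at case level (so no day pair of a test case ever
#' enters training), then trains the field net, the pixel classifier, the
#' denoiser and the resorption forest on the training cases.  Component
#' seeds fan out from the master seed.
#'
#' @param histories named list of simulator [HealingHistory-class] objects.
#' @param config a [surrogateConfig()].
#' @return a [SurrogateBundle-class].
#' @export
trainSurrogate <- function(histories, config = surrogateConfig()) {
  stopifnot(length(histories) >= 1L)
  ids <- vapply(histories, caseId, character(1))
  names(histories) <- ids
  nTest <- if (length(ids) >= 2L)
    max(0L, round(config$testFraction * length(ids))) else 0L
  testIds <- .withSeed(config$seed,
                       if (nTest > 0) sample(ids, nTest) else character(0))
  trainIds <- setdiff(ids, testIds)
  trainH <- histories[trainIds]

  fn <- trainFieldNet(trainH, modifyList(list(seed = config$seed + 101L),
                                         config$fieldNet))
  pc <- trainPixelClassifier(trainH,
                             modifyList(list(seed = config$seed + 202L),
                                        config$pixelClassifier))
  dn <- trainDenoiser(trainH, pc,
                      modifyList(list(seed = config$seed + 303L),
                                 config$denoiser))
  rf <- trainResorptionForest(trainH,
                              modifyList(list(seed = config$seed + 404L),
                                         config$forest))
  new("SurrogateBundle", fieldNet = fn, pixelClassifier = pc,
      denoiserNet = dn, resorptionForest = rf,
      meta = list(seed = config$seed, trainCases = trainIds,
                  testCases = testIds, config = config))
}

#' Autoregressive surrogate rollout
#'
#' Predicts the whole healing history from the day-0 material state alone.
#' Each day: field net -> per-pixel classifier -> structured denoiser ->
#' resorption corrector -> analytic material blend (granulation vs
#' differentiated properties, weighted by the predicted next-day
#' concentration) -> history smoothing -> next day's input.
#'
#' @param day0 the day-0 [MaterialField-class] (granulation callus, n = 0).
#' @param domain the [ImplantDomain-class].
#' @param bundle a trained [SurrogateBundle-class].
#' @param T days to roll out (default 35).
#' @param config a [healingConfig()] (material table, thresholds and
#'   smoothing shared with the simulator).
#' @param caseId identifier for the returned history.
#' @return a [HealingHistory-class] with `surrogate = TRUE`.
#' @export
rollout <- function(day0, domain, bundle, T = 35L,
                    config = healingConfig(days = T), caseId = "rollout") {
  stopifnot(T >= 1L)
  cfg <- config
  codes <- regionMap(domain)
  cal <- callusMask(domain)
  phen <- codes
  phen[cal] <- phenotypeCodes()[["granulation"]]
  map <- PhenotypeMap(phen, domain)
  mat <- day0
  rawHist <- list(mat)
  records <- vector("list", T + 1L)
  for (t in 0:T) {
    pf <- predictFieldNet(bundle@fieldNet, mat)
    if (any(!vapply(pf, function(m) all(is.finite(m)), logical(1))))
      stop("non-finite surrogate prediction at day ", t)
    fields <- PhysicalFields(pf$eps1, pf$eps2, pf$eps3, pf$vx, pf$vy,
                             pf$nNext)
    records[[t + 1L]] <- list(material = mat, fields = fields,
                              phenotype = map)
    if (t == T) break
    map <- predictPixelClassifier(bundle@pixelClassifier, pf, domain)$map
    map <- denoiseMap(map, bundle@denoiserNet, domain)
    map <- correctResorption(map, pf, bundle@resorptionForest, domain)
    raw <- materialFromPhenotype(map, domain, pf$nNext, cfg$materials)
    prev <- tail(rawHist, cfg$smoothWindow)
    mat <- smoothHistory(raw, prev)
    rawHist <- c(rawHist, list(raw))
  }
  names(records) <- paste0("day", 0:T)
  new("HealingHistory", caseId = caseId, domain = domain, days = records,
      params = cfg, surrogate = TRUE)
}
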