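## Quantitative comparison of surrogate and simulator: per-channel Pearson
## correlation of the six physical fields, one-vs-rest ROC/AUC per tissue
## phenotype, pixel accuracy, and the six bone-implant performance indexes
## (F_M, F_R, F_S, BA, BIC, MBL).

#' Per-channel Pearson correlation between predicted and true field series
#'
#' Pools every masked pixel over the given days of every case pair and
#' computes the product-moment correlation per channel.  A channel with
#' fewer than 2 values or zero variance is reported as `NA`.
#'
#' @param pred,truth lists of matched [HealingHistory-class] objects (or two
#'   single histories).
#' @param mask logical matrix, or `NULL` for all pixels.
#' @param days day indices pooled (default `1:T`).
#' @return named numeric vector of correlations for channels `eps1`, `eps2`,
#'   `eps3`, `vx`, `vy`, `n`.
#' @export
pearsonR <- function(pred, truth, mask = NULL, days = NULL) {
  if (is(pred, "HealingHistory")) pred <- list(pred)
  if (is(truth, "HealingHistory")) truth <- list(truth)
  stopifnot(length(pred) == length(truth))
  chans <- c("eps1", "eps2", "eps3", "vx", "vy", "nNext")
  acc <- stats::setNames(rep(list(list(p = list(), t = list())), 6), chans)
  for (ci in seq_along(pred)) {
    T <- min(nDays(pred[[ci]]), nDays(truth[[ci]])) - 1L
    dd <- if (is.null(days)) seq_len(T) else days
    m <- mask
    if (is.null(m)) {
      g <- gridSpec(pred[[ci]])
      m <- matrix(TRUE, g@nrow, g@ncol)
    }
    for (t in dd) {
      fp <- fieldsDay(pred[[ci]], t); ft <- fieldsDay(truth[[ci]], t)
      for (ch in chans) {
        acc[[ch]]$p[[length(acc[[ch]]$p) + 1L]] <- slot(fp, ch)[m]
        acc[[ch]]$t[[length(acc[[ch]]$t) + 1L]] <- slot(ft, ch)[m]
      }
    }
  }
  out <- vapply(chans, function(ch) {
    p <- unlist(acc[[ch]]$p); tt <- unlist(acc[[ch]]$t)
    if (length(p) < 2L || sd(p) == 0 || sd(tt) == 0) return(NA_real_)
    cor(p, tt)
  }, numeric(1))
  names(out) <- c("eps1", "eps2", "eps3", "vx", "vy", "n")
  out
}

#' One-vs-rest ROC AUC by the rank statistic
#'
#' AUC computed as the Wilcoxon rank statistic with midranks for ties
#' (equivalent to trapezoidal integration of the ROC curve).  Undefined
#' (`NA`) when the truth contains a single class.
#'
#' @param scores numeric vector of scores for the positive class.
#' @param positive logical/0-1 vector of true positives.
#' @return scalar AUC in `[0, 1]`, or `NA`.
#' @export
rocAuc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points for one phenotype
#'
#' @param scores positive-class scores.
#' @param positive true positive indicator.
#' @return data.frame with `fpr`, `tpr` sorted along the curve.
#' @export
rocCurve <- function(scores, positive) {
  positive <- as.logical(positive)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- positive[o]
  ## one curve vertex per distinct threshold (ties advance diagonally)
  last <- c(diff(s) != 0, TRUE)
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  data.frame(fpr = c(0, fp / max(sum(!positive), 1)),
             tpr = c(0, tp / max(sum(positive), 1)))
}

#' Pixel accuracy between two phenotype maps
#'
#' Fraction of matching pixels within the region of interest (conventionally
#' the callus, implant excluded).  Empty masks give `NA`.
#'
#' @param predicted,truth [PhenotypeMap-class] objects on the same grid.
#' @param roiMask logical matrix.
#' @return scalar fraction, or `NA`.
#' @export
pixelAccuracy <- function(predicted, truth, roiMask) {
  p <- phenotypeMatrix(predicted); t <- phenotypeMatrix(truth)
  stopifnot(identical(dim(p), dim(t)))
  if (!any(roiMask)) return(NA_real_)
  mean(p[roiMask] == t[roiMask])
}

#' The six bone-implant performance indexes
#'
#' Computed from a (typically day-35) phenotype map:
#' \itemize{
#'   \item `FM`, `FR`: mature-bone and resorption fractions of the callus
#'     ROI; `FS`: soft-tissue fraction (cartilage + fibrous).
#'   \item `BA`: bone area -- mature + immature pixel count in the ROI
#'     (`BAmm2` in mm^2).
#'   \item `BIC`: fraction of callus pixels 4-adjacent to the implant whose
#'     phenotype is bone (mature or immature).
#'   \item `MBL`: marginal bone loss -- resorption pixel area in the
#'     interface band above the first thread (`NA` without a thread row).
#' }
#'
#' @param map a [PhenotypeMap-class].
#' @param domain the [ImplantDomain-class].
#' @param roiMask callus ROI (default: the whole callus).
#' @param interfaceBand width in pixels of the implant-adjacent band used
#'   for MBL (default 2).
#' @return named list with `FM`, `FR`, `FS`, `BA`, `BAmm2`, `BIC`, `MBL`.
#' @export
performanceIndexes <- function(map, domain, roiMask = NULL,
                               interfaceBand = 2L) {
  codes <- phenotypeMatrix(map)
  cal <- callusMask(domain)
  if (is.null(roiMask)) roiMask <- cal
  pc <- .PHEN_DIFF
  nRoi <- sum(roiMask)
  frac <- function(sel) if (nRoi) sum(sel & roiMask) / nRoi else NA_real_
  FM <- frac(codes == pc[["mature"]])
  FR <- frac(codes == pc[["resorption"]])
  FS <- frac(codes == pc[["cartilage"]] | codes == pc[["fibrous"]])
  bone <- codes == pc[["mature"]] | codes == pc[["immature"]]
  BA <- sum(bone & roiMask)
  ps <- gridSpec(domain)@pixelSize
  iface <- cal & .adjacent4(implantMask(domain))
  BIC <- if (any(iface)) mean(bone[iface]) else NA_real_
  ftr <- firstThreadRow(domain)
  MBL <- if (is.na(ftr)) NA_real_ else {
    band <- cal & .dilate(implantMask(domain), interfaceBand)
    above <- row(codes) < ftr
    sum((codes == pc[["resorption"]]) & band & above)
  }
  list(FM = FM, FR = FR, FS = FS, BA = BA, BAmm2 = BA * ps^2, BIC = BIC,
       MBL = MBL)
}

#' Scatter-record bookkeeping
#'
#' Number of pooled pixel-day-case records entering the field scatter
#' (e.g. a 210 x 52 grid over 35 days and 14 cases pools 5,350,800 points).
#'
#' @param grid a [GridSpec-class].
#' @param days number of pooled days.
#' @param cases number of cases.
#' @return integer record count.
#' @export
scatterRecordCount <- function(grid, days, cases) {
  as.numeric(grid@nrow) * grid@ncol * days * cases
}

#' Full evaluation of a surrogate run against the simulator
#'
#' Aggregates, over matched case pairs: per-channel Pearson r of the six
#' fields (pooled pixel-day-case), one-vs-rest AUC per phenotype (pooled
#' callus pixel-days; scores from the bundle's pixel classifier applied to
#' the predicted fields), per-day mean pixel accuracy in the callus ROI, and
#' the six performance indexes per case with their cross-case correlation.
#'
#' @param pred list of rollout histories.
#' @param truth list of matching simulator histories.
#' @param bundle the [SurrogateBundle-class] (for classification scores);
#'   `NULL` skips the AUC block.
#' @return report list with elements `fieldR`, `auc`, `accuracyPerDay`,
#'   `finalAccuracy`, `indexes` (per-case data.frame), `indexR`, `counts`.
#' @export
evaluateRun <- function(pred, truth, bundle = NULL) {
  if (is(pred, "HealingHistory")) pred <- list(pred)
  if (is(truth, "HealingHistory")) truth <- list(truth)
  stopifnot(length(pred) == length(truth))
  for (ci in seq_along(pred))
    if (nDays(pred[[ci]]) != nDays(truth[[ci]]))
      stop("case ", ci, ": day counts differ (",
           nDays(pred[[ci]]), " vs ", nDays(truth[[ci]]), ")")
  T <- nDays(pred[[1]]) - 1L

  fieldR <- pearsonR(pred, truth)

  ## per-phenotype AUC over pooled callus pixel-days
  auc <- rep(NA_real_, 5L)
  names(auc) <- names(.PHEN_DIFF)
  if (!is.null(bundle)) {
    sc <- list(); lb <- list()
    for (ci in seq_along(pred)) {
      dom <- domain(truth[[ci]])
      cal <- callusMask(dom)
      for (t in seq_len(T)) {
        pr <- predictPixelClassifier(bundle@pixelClassifier,
                                     fieldsDay(pred[[ci]], t - 1L), dom)
        lab <- phenotypeMatrix(phenotypeDay(truth[[ci]], t))[cal]
        keep <- lab %in% .PHEN_DIFF
        sc[[length(sc) + 1L]] <- pr$probs[keep, , drop = FALSE]
        lb[[length(lb) + 1L]] <- lab[keep]
      }
    }
    S <- do.call(rbind, sc); L <- unlist(lb)
    for (k in seq_len(5L))
      auc[k] <- rocAuc(S[, k], L == .PHEN_DIFF[k])
  }

  accDay <- matrix(NA_real_, length(pred), T + 1L)
  for (ci in seq_along(pred)) {
    cal <- callusMask(domain(truth[[ci]]))
    for (t in 0:T)
      accDay[ci, t + 1L] <- pixelAccuracy(phenotypeDay(pred[[ci]], t),
                                          phenotypeDay(truth[[ci]], t), cal)
  }

  idxNames <- c("FM", "FR", "FS", "BA", "BIC", "MBL")
  rows <- list()
  for (ci in seq_along(pred)) {
    dom <- domain(truth[[ci]])
    ip <- performanceIndexes(phenotypeDay(pred[[ci]], T), dom)
    it <- performanceIndexes(phenotypeDay(truth[[ci]], T), dom)
    for (nm in idxNames)
      rows[[length(rows) + 1L]] <-
        data.frame(case = caseId(truth[[ci]]), index = nm,
                   pred = ip[[nm]], truth = it[[nm]])
  }
  idx <- do.call(rbind, rows)
  indexR <- vapply(idxNames, function(nm) {
    d <- idx[idx$index == nm & is.finite(idx$pred) & is.finite(idx$truth), ]
    if (nrow(d) < 2L || sd(d$pred) == 0 || sd(d$truth) == 0) return(NA_real_)
    cor(d$pred, d$truth)
  }, numeric(1))

  g <- gridSpec(truth[[1]])
  list(fieldR = fieldR, auc = auc,
       accuracyPerDay = colMeans(accDay),
       finalAccuracy = mean(accDay[, T + 1L]),
       indexes = idx, indexR = indexR,
       counts = list(cases = length(pred), days = T,
                     pixels = as.integer(g@nrow) * g@ncol,
                     scatterRecords = scatterRecordCount(g, T, length(pred))))
}
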