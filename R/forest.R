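## A compact bagged CART forest for the binary resorption-vs-mature-bone
## correction step.  Gini splits, bootstrap resampling, feature subsampling,
## out-of-bag accuracy.  No random-forest package ships with the target
## environment, and the corrector only ever sees two classes and ~10
## features, so a purpose-built implementation is appropriate.

#' Train a binary random forest
#'
#' @param X numeric feature matrix (n x d).
#' @param y integer/logical labels coded 0/1.
#' @param nTrees number of trees (default 25).
#' @param mtry features tried per split (default `ceiling(sqrt(d))`).
#' @param maxDepth maximum tree depth (default 8).
#' @param minNode minimum node size to attempt a split (default 5).
#' @param seed RNG seed.
#' @return list with `trees`, `oobAccuracy`, `trainAccuracy`, `mtry`, `d`.
#' @export
randomForestBinary <- function(X, y, nTrees = 25L, mtry = NULL,
                               maxDepth = 8L, minNode = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  n <- nrow(X); d <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(d)))
  .withSeed(seed, {
    trees <- vector("list", nTrees)
    oobVotes <- matrix(0, n, 2)
    for (t in seq_len(nTrees)) {
      bag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(bag))
      trees[[t]] <- .growTree(X[bag, , drop = FALSE], y[bag],
                              mtry, maxDepth, minNode)
      if (length(oob)) {
        pv <- .predictTree(trees[[t]], X[oob, , drop = FALSE])
        oobVotes[cbind(oob, pv + 1L)] <- oobVotes[cbind(oob, pv + 1L)] + 1
      }
    }
    hasOob <- rowSums(oobVotes) > 0
    oobPred <- max.col(oobVotes, ties.method = "first") - 1L
    oobAcc <- if (any(hasOob)) mean(oobPred[hasOob] == y[hasOob]) else NA_real_
    fit <- list(trees = trees, mtry = mtry, d = d,
                oobAccuracy = oobAcc)
    fit$trainAccuracy <- mean(predictForest(fit, X) == y)
    fit
  })
}

## grow one CART; nodes accumulated in a flat list
.growTree <- function(X, y, mtry, maxDepth, minNode) {
  nodes <- list()
  newNode <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  build <- function(idx, depth) {
    ys <- y[idx]
    p1 <- mean(ys)
    if (depth >= maxDepth || length(idx) < minNode || p1 == 0 || p1 == 1)
      return(newNode(list(leaf = TRUE, pred = as.integer(p1 >= 0.5))))
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL
    for (f in feats) {
      sp <- .bestGiniSplit(X[idx, f], ys)
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
        best <- sp; best$feature <- f
      }
    }
    if (is.null(best) || best$gain <= 0)
      return(newNode(list(leaf = TRUE, pred = as.integer(p1 >= 0.5))))
    goL <- X[idx, best$feature] <= best$threshold
    id <- newNode(list(leaf = FALSE, feature = best$feature,
                       threshold = best$threshold, left = NA, right = NA))
    l <- build(idx[goL], depth + 1L)
    r <- build(idx[!goL], depth + 1L)
    nodes[[id]]$left <<- l
    nodes[[id]]$right <<- r
    id
  }
  root <- build(seq_along(y), 0L)
  list(nodes = nodes, root = root)
}

## best split of numeric x for binary labels by gini impurity decrease
.bestGiniSplit <- function(x, y) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  cut <- which(diff(xs) > 0)                  # split between distinct values
  if (!length(cut)) return(NULL)
  cumPos <- cumsum(ys)
  nL <- cut; nR <- n - cut
  posL <- cumPos[cut]; posR <- cumPos[n] - posL
  giniL <- 1 - (posL / nL)^2 - (1 - posL / nL)^2
  giniR <- 1 - (posR / nR)^2 - (1 - posR / nR)^2
  parent <- 1 - (cumPos[n] / n)^2 - (1 - cumPos[n] / n)^2
  gain <- parent - (nL * giniL + nR * giniR) / n
  bi <- which.max(gain)
  list(threshold = (xs[cut[bi]] + xs[cut[bi] + 1L]) / 2, gain = gain[bi])
}

.predictTree <- function(tree, X) {
  n <- nrow(X)
  at <- rep(tree$root, n)
  out <- integer(n)
  active <- seq_len(n)
  while (length(active)) {
    done <- logical(length(active))
    for (u in unique(at[active])) {
      nd <- tree$nodes[[u]]
      sel <- active[at[active] == u]
      if (nd$leaf) {
        out[sel] <- nd$pred
        done[match(sel, active)] <- TRUE
      } else {
        goL <- X[sel, nd$feature] <= nd$threshold
        at[sel[goL]] <- nd$left
        at[sel[!goL]] <- nd$right
      }
    }
    active <- active[!done]
  }
  out
}

#' Predict with a binary random forest
#'
#' @param fit result of [randomForestBinary()].
#' @param X feature matrix.
#' @return integer vector of 0/1 majority votes.
#' @export
predictForest <- function(fit, X) {
  X <- as.matrix(X)
  votes <- matrix(0, nrow(X), 2)
  for (tr in fit$trees) {
    p <- .predictTree(tr, X)
    votes[cbind(seq_len(nrow(X)), p + 1L)] <-
      votes[cbind(seq_len(nrow(X)), p + 1L)] + 1
  }
  max.col(votes, ties.method = "first") - 1L
}
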