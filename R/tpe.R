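## Tree-structured Parzen estimator for hyperparameter search.  Completed
## trials are split at the gamma-quantile of the objective into "good" and
## "bad" sets; each parameter is modeled by a kernel density (numeric) or a
## smoothed category frequency (choice), candidates are drawn from the good
## model and ranked by the density ratio l(x)/g(x).

#' Describe a hyperparameter search space
#'
#' Each entry is created by one of the helpers: `hpUniform(name, lo, hi)`,
#' `hpLogUniform(name, lo, hi)`, `hpInt(name, lo, hi)` or
#' `hpChoice(name, values)`.
#'
#' @param name parameter name.
#' @param lo,hi numeric bounds (inclusive).
#' @param values vector of categorical levels.
#' @return a parameter description list.
#' @name searchSpace
NULL

#' @rdname searchSpace
#' @export
hpUniform <- function(name, lo, hi)
  list(name = name, type = "uniform", lo = lo, hi = hi)

#' @rdname searchSpace
#' @export
hpLogUniform <- function(name, lo, hi) {
  stopifnot(lo > 0, hi > lo)
  list(name = name, type = "loguniform", lo = lo, hi = hi)
}

#' @rdname searchSpace
#' @export
hpInt <- function(name, lo, hi)
  list(name = name, type = "int", lo = as.integer(lo), hi = as.integer(hi))

#' @rdname searchSpace
#' @export
hpChoice <- function(name, values)
  list(name = name, type = "choice", values = values)

.hpSampleRandom <- function(spec) {
  switch(spec$type,
    uniform = runif(1, spec$lo, spec$hi),
    loguniform = exp(runif(1, log(spec$lo), log(spec$hi))),
    int = sample(spec$lo:spec$hi, 1),
    choice = spec$values[[sample.int(length(spec$values), 1)]])
}

## KDE value at x for observations obs (numeric, possibly log-scaled)
.kdeVal <- function(x, obs, lo, hi) {
  if (!length(obs)) return(rep(1 / (hi - lo), length(x)))
  bw <- max(1.06 * sd(obs) * length(obs)^(-1 / 5), (hi - lo) / 50, 1e-12)
  vapply(x, function(xx) mean(dnorm(xx, obs, bw)) + 1e-12, numeric(1))
}

.hpSampleTPE <- function(spec, goodVals, badVals, nCandidates) {
  if (spec$type == "choice") {
    lv <- vapply(spec$values, function(v) as.character(v), character(1))
    cg <- table(factor(as.character(goodVals), levels = lv)) + 1
    cb <- table(factor(as.character(badVals), levels = lv)) + 1
    pg <- cg / sum(cg); pb <- cb / sum(cb)
    pick <- sample.int(length(lv), nCandidates, replace = TRUE, prob = pg)
    best <- pick[which.max((pg / pb)[pick])]
    return(spec$values[[best]])
  }
  logScale <- spec$type == "loguniform"
  tf <- if (logScale) log else identity
  itf <- if (logScale) exp else identity
  lo <- tf(spec$lo); hi <- tf(spec$hi)
  gv <- tf(as.numeric(goodVals)); bv <- tf(as.numeric(badVals))
  cand <- if (length(gv)) {
    bw <- max(1.06 * sd(gv) * length(gv)^(-1 / 5), (hi - lo) / 50, 1e-12)
    pmin(pmax(sample(gv, nCandidates, replace = TRUE) +
                rnorm(nCandidates, 0, bw), lo), hi)
  } else runif(nCandidates, lo, hi)
  score <- .kdeVal(cand, gv, lo, hi) / .kdeVal(cand, bv, lo, hi)
  out <- itf(cand[which.max(score)])
  if (spec$type == "int") out <- as.integer(round(out))
  out
}

#' Bayesian hyperparameter optimization (tree-structured Parzen estimator)
#'
#' Minimizes `objective(config)` over the given search space.  The first
#' `nStartup` trials are random; later trials sample each parameter from a
#' density model of the best `gammaQ` fraction of completed trials and pick
#' the candidate maximizing the good/bad density ratio.  Failed trials are
#' logged and skipped.  Deterministic for a fixed seed (assuming a
#' deterministic objective).
#'
#' @param objective function taking a named config list, returning a scalar
#'   loss (lower is better).
#' @param searchSpace list of parameter descriptions (see [hpUniform()]).
#' @param budget number of trials (default 50, reducible).
#' @param seed RNG seed.
#' @param nStartup random trials before TPE kicks in (default 5).
#' @param gammaQ quantile separating good from bad trials (default 0.25).
#' @param nCandidates candidates scored per parameter per trial (default 24).
#' @return list with `best` (config), `bestValue`, `bestTrial`, and `trials`
#'   (data.frame log with one row per trial).
#' @export
tuneHyperparameters <- function(objective, searchSpace, budget = 50L,
                                seed = 1L, nStartup = 5L, gammaQ = 0.25,
                                nCandidates = 24L) {
  stopifnot(budget >= 1L)
  names(searchSpace) <- vapply(searchSpace, `[[`, character(1), "name")
  .withSeed(seed, {
    configs <- vector("list", budget)
    losses <- rep(NA_real_, budget)
    for (tr in seq_len(budget)) {
      done <- which(!is.na(losses[seq_len(tr - 1L)]))
      cfg <- list()
      if (length(done) < nStartup) {
        for (sp in searchSpace) cfg[[sp$name]] <- .hpSampleRandom(sp)
      } else {
        q <- quantile(losses[done], gammaQ, names = FALSE)
        good <- done[losses[done] <= q]
        bad <- setdiff(done, good)
        for (sp in searchSpace) {
          gv <- lapply(configs[good], `[[`, sp$name)
          bv <- lapply(configs[bad], `[[`, sp$name)
          cfg[[sp$name]] <- .hpSampleTPE(sp, unlist(gv), unlist(bv),
                                         nCandidates)
        }
      }
      configs[[tr]] <- cfg
      losses[tr] <- tryCatch(as.numeric(objective(cfg)),
                             error = function(e) {
                               warning("trial ", tr, " failed: ",
                                       conditionMessage(e), call. = FALSE)
                               NA_real_
                             })
    }
    if (all(is.na(losses))) stop("every trial failed")
    bestTrial <- which.min(losses)
    list(best = configs[[bestTrial]], bestValue = losses[bestTrial],
         bestTrial = bestTrial,
         trials = data.frame(trial = seq_len(budget), loss = losses))
  })
}
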