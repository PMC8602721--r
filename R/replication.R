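#' Scaled-down surrogate replication study
#'
#' The headline fidelity figures of the original workflow (held-out field
#' correlations above 0.980, cross-case performance-index correlations above
#' 0.947, 88% day-35 pixel accuracy, per-phenotype AUC of 0.90 or better)
#' were measured on a 65-case commercial-solver dataset that cannot be
#' regenerated here.  This function reruns the whole pipeline at a reduced
#' scale on self-generated simulator data -- generate a parametric implant
#' library, simulate every case, train the surrogate with a case-level
#' hold-out, roll the held-out cases out from day 0 and score them -- and
#' reports the four summary metrics with a pass/warn status against the
#' reference bounds.  Because the in-house solver stands in for the original
#' FE package, the statuses are reported, not asserted.
#'
#' At the default settings (20 cases, half-resolution grid, 35 days) the
#' study takes on the order of hours on one CPU; all sizes are reducible.
#'
#' @param nCases implant library size (default 20).
#' @param grid reduced-resolution [GridSpec-class] (default 106 x 26 at
#'   0.11 mm/pixel, half the full-scale frame).
#' @param days simulated days (default 35).
#' @param seed master seed.
#' @param surrogate a [surrogateConfig()]; its `testFraction` controls the
#'   hold-out.
#' @param healing a [healingConfig()] (days overridden by `days`).
#' @param callusWidth geometry setting forwarded to the library generator.
#' @param bounds named reference bounds for the pass/warn report.
#' @param verbose print progress.
#' @return list with `metrics` (named: `minFieldR`, `minIndexR`,
#'   `meanFinalAccuracy`, `minAuc`), `status` (named `"pass"`/`"warn"`),
#'   `report` (the full [evaluateRun()] output on the held-out cases),
#'   `heldOut` (case ids) and `bounds`.
#' @export
replicationStudy <- function(nCases = 20L,
                             grid = GridSpec(106L, 26L, 0.11),
                             days = 35L, seed = 1L,
                             surrogate = surrogateConfig(seed = seed),
                             healing = healingConfig(days = days),
                             callusWidth = 3L,
                             bounds = c(minFieldR = 0.980,
                                        minIndexR = 0.947,
                                        meanFinalAccuracy = 0.88,
                                        minAuc = 0.90),
                             verbose = TRUE) {
  say <- function(...) if (verbose) message("[replication] ", ...)
  healing$days <- as.integer(days)

  say("generating ", nCases, "-case implant library")
  lib <- generateImplantLibrary(nCases, seed = seed, grid = grid,
                                callusWidth = callusWidth)
  say("simulating ", days, " days per case")
  hs <- lapply(seq_along(lib), function(i)
    runHealing(lib[[i]], healing, caseId = names(lib)[i]))
  names(hs) <- names(lib)

  say("training surrogate bundle")
  bundle <- trainSurrogate(unname(hs), surrogate)
  held <- bundle@meta$testCases
  if (!length(held)) stop("no held-out cases; increase testFraction")

  say("rolling out ", length(held), " held-out case(s)")
  preds <- lapply(held, function(id)
    rollout(materialDay(hs[[id]], 0), lib[[id]], bundle, T = days,
            config = healing, caseId = id))
  report <- evaluateRun(preds, hs[held], bundle = bundle)

  metrics <- c(minFieldR = min(report$fieldR, na.rm = TRUE),
               minIndexR = if (all(is.na(report$indexR))) NA_real_
                           else min(report$indexR, na.rm = TRUE),
               meanFinalAccuracy = report$finalAccuracy,
               minAuc = if (all(is.na(report$auc))) NA_real_
                        else min(report$auc, na.rm = TRUE))
  status <- ifelse(!is.na(metrics) & metrics >= bounds[names(metrics)],
                   "pass", "warn")
  for (nm in names(metrics))
    say(sprintf("%-18s %.4f  [bound %.3f] %s", nm, metrics[nm],
                bounds[nm], status[nm]))
  list(metrics = metrics, status = status, report = report,
       heldOut = held, bounds = bounds)
}
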