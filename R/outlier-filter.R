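#' Percentile thresholds of the centre-displacement distribution
#'
#' Computes displacement thresholds at the requested percentiles under the
#' package-wide linear-interpolation quantile rule. The percentile method
#' is preferred over IQR fences here because the per-frame displacement
#' distribution is right-skewed with a long tail, and the graded 90/95/99
#' choices allow a sensitivity analysis of the cleaning step.
#'
#' @param displacements Non-negative numeric vector of per-frame centre
#'   displacements (pixels).
#' @param percentiles Percentiles in (0, 100); default `c(90, 95, 99)`.
#' @return Named numeric vector of thresholds, one per percentile,
#'   non-decreasing in the percentile.
#' @export
percentileThresholds <- function(displacements,
                                 percentiles = c(90, 95, 99)) {
  displacements <- displacements[!is.na(displacements)]
  if (!length(displacements)) stop("no displacement values supplied")
  if (any(displacements < 0)) stop("displacements must be non-negative")
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly between 0 and 100")
  stats::setNames(linearQuantile(displacements, percentiles / 100),
                  paste0("p", format(percentiles, trim = TRUE)))
}

#' Remove high-displacement frame pairs
#'
#' Drops every dynamics entry whose centre displacement strictly exceeds
#' the threshold ("exceeding" is strict: values equal to the threshold
#' are kept). The directional-shift value of a removed frame pair is
#' removed with it -- a corrupted displacement implies a corrupted angle
#' for the same pair -- so filtering precedes all aggregation.
#'
#' @param dyn data.frame from [computeDynamics()] (one or several
#'   participants row-bound together).
#' @param threshold Displacement threshold in pixels (>= 0).
#' @param percentile The percentile the threshold came from, recorded in
#'   the report (`NA` for a custom threshold).
#' @param scope `"pooled"` or `"per_participant"`, recorded in the report.
#' @return List with `dynamics` (retained rows) and `report`
#'   (a [ThresholdReport-class]).
#' @export
applyThresholdFilter <- function(dyn, threshold, percentile = NA_real_,
                                 scope = "pooled") {
  stopifnot(is.data.frame(dyn), threshold >= 0)
  keep <- dyn$center_dis <= threshold
  if (!any(keep))
    stop("all ", nrow(dyn), " dynamics entries removed at threshold ",
         threshold)
  report <- new("ThresholdReport", percentile = as.numeric(percentile),
                threshold = as.numeric(threshold), nTotal = nrow(dyn),
                nRemoved = sum(!keep), scope = scope)
  list(dynamics = dyn[keep, , drop = FALSE], report = report)
}

#' Percentile-filter cohort dynamics
#'
#' Convenience wrapper combining [percentileThresholds()] and
#' [applyThresholdFilter()]. With `scope = "pooled"` (default, matching a
#' single cohort-wide displacement distribution) one threshold is computed
#' from all participants' displacements and applied everywhere; with
#' `scope = "per_participant"` each participant is thresholded on their
#' own distribution.
#'
#' @param dynList List of per-participant dynamics data.frames.
#' @param percentile Single percentile in (0, 100); default 95, which
#'   removes the top 5% of frame pairs.
#' @param scope `"pooled"` or `"per_participant"`.
#' @return List with `dynamics` (filtered list, same order),
#'   `reports` (list of [ThresholdReport-class], one per threshold) and
#'   `threshold` (named numeric, pooled scope only).
#' @export
filterDynamics <- function(dynList, percentile = 95,
                           scope = c("pooled", "per_participant")) {
  scope <- match.arg(scope)
  stopifnot(length(percentile) == 1L)
  if (scope == "pooled") {
    pooled <- unlist(lapply(dynList, `[[`, "center_dis"))
    thr <- percentileThresholds(pooled, percentile)
    filtered <- lapply(dynList, applyThresholdFilter, threshold = thr,
                       percentile = percentile, scope = scope)
    rep <- new("ThresholdReport", percentile = as.numeric(percentile),
               threshold = unname(thr),
               nTotal = sum(vapply(filtered, function(f) f$report@nTotal,
                                   integer(1))),
               nRemoved = sum(vapply(filtered, function(f)
                                     f$report@nRemoved, integer(1))),
               scope = scope)
    list(dynamics = lapply(filtered, `[[`, "dynamics"),
         reports = list(rep), threshold = thr)
  } else {
    filtered <- lapply(dynList, function(d) {
      thr <- percentileThresholds(d$center_dis, percentile)
      applyThresholdFilter(d, threshold = thr, percentile = percentile,
                           scope = scope)
    })
    list(dynamics = lapply(filtered, `[[`, "dynamics"),
         reports = lapply(filtered, `[[`, "report"),
         threshold = NULL)
  }
}
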