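#' @describeIn computeCoM The CoM of each frame is the unweighted mean of
#'   the five keypoints nose, left/right shoulder and left/right hip
#'   (|K| = 5). A frame whose CoM keypoints include a missing coordinate
#'   is marked invalid and excluded from downstream dynamics.
#' @export
setMethod("computeCoM", "PoseSequence", function(x, ...) {
  idx <- comKeypointIndices() + 1L
  xs <- x@coords[, idx, 1L, drop = FALSE]
  ys <- x@coords[, idx, 2L, drop = FALSE]
  dim(xs) <- dim(ys) <- c(nFrames(x), length(idx))
  valid <- rowSums(is.finite(xs)) == length(idx) &
           rowSums(is.finite(ys)) == length(idx)
  cx <- rowMeans(xs)
  cy <- rowMeans(ys)
  cx[!valid] <- NA_real_
  cy[!valid] <- NA_real_
  new("CoMTrajectory", participantId = participantId(x),
      frameIndex = x@frameIndex, x = cx, y = cy, valid = valid)
})

#' Frame-to-frame CoM dynamics: centre displacement and directional shift
#'
#' For every pair of consecutive frames (frame indices differing by 1)
#' whose CoM points are both valid, computes the coordinate steps
#' `dx`, `dy`, the centre displacement
#' `center_dis = sqrt(dx^2 + dy^2)` (Euclidean distance in pixels), and
#' the directional shift `theta = arctan(dy / dx)` in radians. Pairs that
#' span an invalid or dropped frame produce no entry: gaps are not
#' bridged, so a single dropped frame costs the two dynamics entries it
#' participates in (this avoids inflating displacement across gaps).
#'
#' The arctangent of the ratio has range (-pi/2, pi/2); for a purely
#' vertical step (`dx = 0`) the convention is `theta = +pi/2` if
#' `dy > 0`, `-pi/2` if `dy < 0`, and `0` for a stationary CoM.
#' `angleMethod = "atan2"` is available for the full signed angle in
#' (-pi, pi], but the ratio form is the default definition.
#'
#' @param com A [CoMTrajectory-class].
#' @param angleMethod `"ratio"` (default, arctan of dy/dx) or `"atan2"`.
#' @return data.frame with columns `participant_id`, `frame` (the later
#'   frame of each pair), `dx`, `dy`, `center_dis`, `theta`.
#' @export
computeDynamics <- function(com, angleMethod = c("ratio", "atan2")) {
  stopifnot(is(com, "CoMTrajectory"))
  angleMethod <- match.arg(angleMethod)
  n <- length(com@frameIndex)
  if (sum(com@valid) < 2L)
    stop("empty dynamics: fewer than 2 valid CoM points for participant ",
         com@participantId)
  i <- 2:n
  ok <- com@valid[i] & com@valid[i - 1L] &
        (com@frameIndex[i] - com@frameIndex[i - 1L]) == 1L
  i <- i[ok]
  if (!length(i))
    stop("empty dynamics: no consecutive valid frame pairs for ",
         com@participantId)
  dx <- com@x[i] - com@x[i - 1L]
  dy <- com@y[i] - com@y[i - 1L]
  dis <- sqrt(dx^2 + dy^2)
  theta <- if (angleMethod == "atan2") atan2(dy, dx)
           else ifelse(dx == 0,
                       ifelse(dy > 0, pi / 2, ifelse(dy < 0, -pi / 2, 0)),
                       atan(dy / dx))
  data.frame(participant_id = com@participantId,
             frame = com@frameIndex[i], dx = dx, dy = dy,
             center_dis = dis, theta = theta,
             stringsAsFactors = FALSE)
}

#' Aggregate frame dynamics into a per-participant feature set
#'
#' Computes the participant-level gait features from (optionally filtered)
#' frame dynamics. The directional shift is summarised as the mean of
#' `|theta|` in radians (`mode = "angular"`, default) or as the mean of
#' `|dx|` in pixel/frame (`mode = "horizontal"`); its sample variance uses
#' the n - 1 denominator (a single frame pair yields variance 0 with a
#' warning rather than failing). The mean centre displacement is always in
#' pixel/frame.
#'
#' @param dyn data.frame from [computeDynamics()] (possibly filtered by
#'   [applyThresholdFilter()]).
#' @param mode `"angular"` or `"horizontal"`.
#' @param participantId Identifier recorded in the result; defaults to the
#'   `participant_id` column of `dyn`.
#' @param filterThreshold Displacement threshold applied upstream, for the
#'   audit trail (`NA` if none).
#' @return A [GaitFeatureSet-class].
#' @export
aggregateFeatures <- function(dyn, mode = c("angular", "horizontal"),
                              participantId = NULL,
                              filterThreshold = NA_real_) {
  mode <- match.arg(mode)
  if (is.null(dyn) || !nrow(dyn))
    stop("no dynamics to aggregate",
         if (is.finite(filterThreshold))
           paste0(" after filtering at threshold ", filterThreshold)
         else "")
  if (is.null(participantId))
    participantId <- as.character(dyn$participant_id[1])
  shift <- if (mode == "angular") abs(dyn$theta) else abs(dyn$dx)
  v <- if (length(shift) > 1L) stats::var(shift) else {
    warning("single frame pair for participant ", participantId,
            ": variance reported as 0")
    0
  }
  new("GaitFeatureSet", participantId = participantId,
      meanDirectionalShift = mean(shift), varDirectionalShift = v,
      meanDisplacement = mean(dyn$center_dis),
      nFramesUsed = nrow(dyn), mode = mode,
      filterThreshold = as.numeric(filterThreshold))
}

#' Cohort feature table
#'
#' Binds a list of [GaitFeatureSet-class] objects into the per-participant
#' feature table used by the statistics layer.
#'
#' @param features List of [GaitFeatureSet-class] objects.
#' @return data.frame with one row per participant.
#' @export
featureTable <- function(features) {
  do.call(rbind, lapply(features, as.data.frame))
}

#' 2-D density histogram of pooled CoM positions
#'
#' Pools the valid CoM points of one or more trajectories and counts them
#' on a `bins x bins` grid spanning the pooled coordinate range (walking
#' path density). Bin edges are equally spaced; points on an interior
#' right edge fall in the higher bin and the maximum falls in the last
#' bin, so counts always sum to the number of pooled points.
#'
#' @param com A [CoMTrajectory-class] or list of them.
#' @param bins Number of bins per axis (>= 1).
#' @param xlim,ylim Optional axis limits; default is the pooled range.
#' @return List with `counts` (`bins x bins` matrix, x by y), `xbreaks`,
#'   `ybreaks` and `n` (points counted).
#' @export
pathDensity <- function(com, bins = 50L, xlim = NULL, ylim = NULL) {
  if (is(com, "CoMTrajectory")) com <- list(com)
  if (bins < 1L) stop("bins must be >= 1")
  xs <- unlist(lapply(com, function(tr) tr@x[tr@valid]))
  ys <- unlist(lapply(com, function(tr) tr@y[tr@valid]))
  if (!length(xs)) stop("no valid CoM points to bin")
  if (is.null(xlim)) xlim <- range(xs)
  if (is.null(ylim)) ylim <- range(ys)
  xb <- seq(xlim[1], xlim[2], length.out = bins + 1L)
  yb <- seq(ylim[1], ylim[2], length.out = bins + 1L)
  bx <- pmin(pmax(findInterval(xs, xb, rightmost.closed = TRUE), 1L), bins)
  by <- pmin(pmax(findInterval(ys, yb, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(bx, levels = 1:bins), factor(by, levels = 1:bins))
  counts[] <- as.integer(tab)
  list(counts = counts, xbreaks = xb, ybreaks = yb, n = length(xs))
}
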