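#' @import methods
NULL

#' Keypoints used for the centre-of-mass estimate
#'
#' COCO-style indices of the five upper-body keypoints whose unweighted
#' pixel-space mean defines the centre of mass (CoM): nose (0), left
#' shoulder (5), right shoulder (6), left hip (11), right hip (12).
#'
#' @return Named integer vector of length 5.
#' @examples
#' comKeypointIndices()
#' @export
comKeypointIndices <- function() {
  c(nose = 0L, left_shoulder = 5L, right_shoulder = 6L,
    left_hip = 11L, right_hip = 12L)
}

.KP_NAMES <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
               "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
               "left_wrist", "right_wrist", "left_hip", "right_hip",
               "left_knee", "right_knee", "left_ankle", "right_ankle")

#' PoseSequence: a 17-keypoint pose time series for one participant
#'
#' Stores, for one walking trial of one participant, the per-frame output
#' of a PoseNet-style pose estimator: 17 COCO-numbered keypoints, each
#' with pixel coordinates (origin top-left, x rightward, y downward) and a
#' detection confidence in \[0, 1\]. Coordinates may be `NA` where a
#' keypoint is missing or has been dropped during repair.
#'
#' @slot participantId Opaque participant identifier.
#' @slot fps Frames per second of the source video (default 30).
#' @slot imageSize Integer `(width, height)` of the source frames, pixels.
#' @slot frameIndex Strictly increasing integer vector of 0-based frame
#'   indices, one per retained frame.
#' @slot coords Numeric array `n_frames x 17 x 3` with the third dimension
#'   named `x`, `y`, `score`.
#'
#' @export
setClass("PoseSequence",
  representation(participantId = "character",
                 fps = "numeric",
                 imageSize = "integer",
                 frameIndex = "integer",
                 coords = "array"))

setValidity("PoseSequence", function(object) {
  msg <- character(0)
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 17L || d[3] != 3L)
    msg <- c(msg, "coords must be an n x 17 x 3 array")
  if (length(object@frameIndex) != d[1])
    msg <- c(msg, "frameIndex length must equal the number of frames")
  if (anyNA(object@frameIndex) || any(object@frameIndex < 0))
    msg <- c(msg, "frame indices must be non-negative")
  if (length(object@frameIndex) > 1 && any(diff(object@frameIndex) <= 0))
    msg <- c(msg, "frame indices must be strictly increasing")
  if (length(object@fps) != 1L || is.na(object@fps) || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  if (length(object@imageSize) != 2L || any(object@imageSize <= 0))
    msg <- c(msg, "imageSize must be two positive integers (width, height)")
  sc <- object@coords[, , 3L]
  if (any(sc < 0 | sc > 1, na.rm = TRUE))
    msg <- c(msg, "keypoint scores must lie in [0, 1]")
  xy <- object@coords[, , 1:2, drop = FALSE]
  if (any(is.infinite(xy)))
    msg <- c(msg, "keypoint coordinates must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a PoseSequence
#'
#' @param coords Numeric array `n_frames x 17 x 3` (`x`, `y`, `score`).
#' @param frameIndex Integer frame indices; default `0:(n-1)`.
#' @param participantId Participant identifier.
#' @param fps Frames per second.
#' @param imageSize Integer `(width, height)` in pixels.
#' @return A [PoseSequence-class] object.
#' @examples
#' co <- array(runif(2 * 17 * 3), dim = c(2, 17, 3))
#' PoseSequence(co, participantId = "P1")
#' @export
PoseSequence <- function(coords, frameIndex = seq_len(dim(coords)[1]) - 1L,
                         participantId = "unknown", fps = 30,
                         imageSize = c(1280L, 720L)) {
  dimnames(coords) <- list(NULL, .KP_NAMES, c("x", "y", "score"))
  new("PoseSequence", participantId = as.character(participantId),
      fps = as.numeric(fps), imageSize = as.integer(imageSize),
      frameIndex = as.integer(frameIndex), coords = coords)
}

#' CoMTrajectory: per-frame centre-of-mass positions
#'
#' Ordered centre-of-mass (CoM) coordinates for one participant, one point
#' per retained frame, with a validity mask. A point is invalid when any
#' of the five CoM keypoints had missing coordinates in that frame.
#'
#' @slot participantId Participant identifier.
#' @slot frameIndex Integer frame indices.
#' @slot x,y Numeric CoM pixel coordinates (`NA` where invalid).
#' @slot valid Logical validity mask.
#' @export
setClass("CoMTrajectory",
  representation(participantId = "character", frameIndex = "integer",
                 x = "numeric", y = "numeric", valid = "logical"))

setValidity("CoMTrajectory", function(object) {
  n <- length(object@frameIndex)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@valid) != n)
    return("frameIndex, x, y and valid must have equal length")
  if (any(object@valid & (!is.finite(object@x) | !is.finite(object@y))))
    return("valid points must have finite coordinates")
  TRUE
})

#' GaitFeatureSet: per-participant aggregated gait dynamics
#'
#' Aggregates of the frame-to-frame CoM dynamics for one participant:
#' the mean and sample variance of the directional shift, the mean centre
#' displacement (pixel/frame), the number of frame pairs used, and the
#' displacement threshold applied before aggregation (if any).
#'
#' The directional-shift definition depends on `mode`: `"angular"` is the
#' mean absolute arctangent angle (radians); `"horizontal"` is the mean
#' absolute horizontal step `|dx|` (pixel/frame).
#'
#' @slot participantId Participant identifier.
#' @slot meanDirectionalShift,varDirectionalShift Mean and sample variance
#'   (n - 1 denominator) of the directional shift.
#' @slot meanDisplacement Mean centre displacement, pixel/frame.
#' @slot nFramesUsed Number of frame pairs aggregated.
#' @slot mode `"angular"` or `"horizontal"`.
#' @slot filterThreshold Displacement threshold applied upstream (pixels),
#'   `NA` if none.
#' @export
setClass("GaitFeatureSet",
  representation(participantId = "character",
                 meanDirectionalShift = "numeric",
                 varDirectionalShift = "numeric",
                 meanDisplacement = "numeric",
                 nFramesUsed = "integer",
                 mode = "character",
                 filterThreshold = "numeric"))

setValidity("GaitFeatureSet", function(object) {
  msg <- character(0)
  if (object@nFramesUsed < 1L) msg <- c(msg, "nFramesUsed must be >= 1")
  if (is.finite(object@meanDisplacement) && object@meanDisplacement < 0)
    msg <- c(msg, "meanDisplacement must be non-negative")
  if (is.finite(object@varDirectionalShift) && object@varDirectionalShift < 0)
    msg <- c(msg, "varDirectionalShift must be non-negative")
  if (!object@mode %in% c("angular", "horizontal"))
    msg <- c(msg, "mode must be 'angular' or 'horizontal'")
  if (length(msg)) msg else TRUE
})

#' ThresholdReport: audit record of a percentile displacement filter
#'
#' @slot percentile Percentile that defined the threshold (`NA` for a
#'   user-supplied threshold).
#' @slot threshold Displacement threshold in pixels.
#' @slot nTotal,nRemoved Counts of frame pairs before filtering and removed.
#' @slot scope `"pooled"` (one cohort-wide threshold) or
#'   `"per_participant"`.
#' @export
setClass("ThresholdReport",
  representation(percentile = "numeric", threshold = "numeric",
                 nTotal = "integer", nRemoved = "integer",
                 scope = "character"))

setValidity("ThresholdReport", function(object) {
  if (object@nRemoved < 0 || object@nRemoved > object@nTotal)
    return("nRemoved must lie in [0, nTotal]")
  if (!object@scope %in% c("pooled", "per_participant"))
    return("scope must be 'pooled' or 'per_participant'")
  TRUE
})

setMethod("show", "PoseSequence", function(object) {
  cat("PoseSequence for participant", object@participantId, "\n")
  cat(" ", length(object@frameIndex), "frames at", object@fps, "fps;",
      "image", paste(object@imageSize, collapse = "x"), "px\n")
  sc <- object@coords[, , "score"]
  cat("  keypoint score: mean", round(mean(sc, na.rm = TRUE), 3),
      " missing coords:",
      sum(!is.finite(object@coords[, , "x"])), "\n")
})

setMethod("show", "CoMTrajectory", function(object) {
  cat("CoMTrajectory for participant", object@participantId, "\n")
  cat(" ", length(object@frameIndex), "points,",
      sum(object@valid), "valid\n")
})

setMethod("show", "GaitFeatureSet", function(object) {
  cat("GaitFeatureSet for participant", object@participantId,
      sprintf("(mode = %s)\n", object@mode))
  cat(sprintf("  mean directional shift: %.4f  variance: %.4f\n",
              object@meanDirectionalShift, object@varDirectionalShift))
  cat(sprintf("  mean displacement: %.4f px/frame over %d frame pairs\n",
              object@meanDisplacement, object@nFramesUsed))
  if (is.finite(object@filterThreshold))
    cat(sprintf("  displacement filter threshold: %.4f px\n",
                object@filterThreshold))
})

setMethod("show", "ThresholdReport", function(object) {
  cat(sprintf(
    "ThresholdReport: %s threshold %.4f px (percentile %s); removed %d of %d (%.2f%%)\n",
    object@scope, object@threshold,
    ifelse(is.na(object@percentile), "custom", format(object@percentile)),
    object@nRemoved, object@nTotal,
    100 * object@nRemoved / max(1L, object@nTotal)))
})
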