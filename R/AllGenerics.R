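#' Accessors for comgait classes
#'
#' `participantId()`, `nFrames()`, `frameIndices()`, `keypointArray()`,
#' `imageFps()` and `imageSize()` extract the corresponding slots without
#' touching the representation directly.
#'
#' @param x A [PoseSequence-class], [CoMTrajectory-class] or
#'   [GaitFeatureSet-class] object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameIndices", function(x) standardGeneric("frameIndices"))

#' @rdname accessors
#' @export
setGeneric("keypointArray", function(x) standardGeneric("keypointArray"))

#' @rdname accessors
#' @export
setGeneric("imageFps", function(x) standardGeneric("imageFps"))

#' @rdname accessors
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))

#' @rdname accessors
setMethod("participantId", "PoseSequence", function(x) x@participantId)
#' @rdname accessors
setMethod("participantId", "CoMTrajectory", function(x) x@participantId)
#' @rdname accessors
setMethod("participantId", "GaitFeatureSet", function(x) x@participantId)
#' @rdname accessors
setMethod("nFrames", "PoseSequence", function(x) length(x@frameIndex))
#' @rdname accessors
setMethod("nFrames", "CoMTrajectory", function(x) length(x@frameIndex))
#' @rdname accessors
setMethod("frameIndices", "PoseSequence", function(x) x@frameIndex)
#' @rdname accessors
setMethod("frameIndices", "CoMTrajectory", function(x) x@frameIndex)
#' @rdname accessors
setMethod("keypointArray", "PoseSequence", function(x) x@coords)
#' @rdname accessors
setMethod("imageFps", "PoseSequence", function(x) x@fps)
#' @rdname accessors
setMethod("imageSize", "PoseSequence", function(x) x@imageSize)

#' Compute the centre-of-mass trajectory of a pose sequence
#'
#' @param x A [PoseSequence-class].
#' @param ... Passed to methods.
#' @return A [CoMTrajectory-class].
#' @export
setGeneric("computeCoM", function(x, ...) standardGeneric("computeCoM"))

#' Coerce a CoMTrajectory or GaitFeatureSet to a data.frame
#'
#' @param x Object to coerce.
#' @param row.names,optional Ignored; present for generic consistency.
#' @param ... Ignored.
#' @return A data.frame.
#' @name as.data.frame-methods
NULL

#' @rdname as.data.frame-methods
#' @export
setMethod("as.data.frame", "CoMTrajectory",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(participant_id = x@participantId, frame = x@frameIndex,
               x = x@x, y = x@y, valid = x@valid,
               stringsAsFactors = FALSE)
  })

#' @rdname as.data.frame-methods
#' @export
setMethod("as.data.frame", "GaitFeatureSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(participant_id = x@participantId,
               mean_directional_shift = x@meanDirectionalShift,
               var_directional_shift = x@varDirectionalShift,
               mean_displacement = x@meanDisplacement,
               n_frames_used = x@nFramesUsed,
               mode = x@mode,
               threshold = x@filterThreshold,
               stringsAsFactors = FALSE)
  })

#' @rdname as.data.frame-methods
#' @export
setMethod("as.data.frame", "ThresholdReport",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(percentile = x@percentile, threshold = x@threshold,
               n_total = x@nTotal, n_removed = x@nRemoved,
               scope = x@scope, stringsAsFactors = FALSE)
  })
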