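#' Read a pose-keypoint time series
#'
#' Reads the per-frame output of a PoseNet-style 17-keypoint pose
#' estimator for one participant. Two plain-text layouts are supported:
#'
#' * **JSON**: an object with fields `participant_id`, `fps`,
#'   `image_size` (`[width, height]`) and `frames`, the latter an array of
#'   objects `{"frame": <int>, "keypoints": [[x, y, score], ... 17]}` in
#'   COCO keypoint order (0 = nose ... 16 = right ankle).
#' * **CSV**: long format, one row per (frame, keypoint) with columns
#'   `frame,keypoint,x,y,score`; optional comment lines
#'   `# participant_id: ...`, `# fps: ...`, `# image_size: WxH` carry the
#'   sequence metadata.
#'
#' Frames are sorted by frame index on read; duplicate frame indices,
#' keypoint indices outside 0--16, or a frame without exactly 17 keypoints
#' raise an error naming the offending frame.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @param participantId Optional override for the stored participant id.
#' @param fps,imageSize Defaults used when the file does not carry them.
#' @return A [PoseSequence-class].
#' @seealso [writePoseSequence()], [interpolateMissing()]
#' @export
readPoseSequence <- function(path, format = c("auto", "json", "csv"),
                             participantId = NULL, fps = 30,
                             imageSize = c(1280L, 720L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    if (is.null(obj$frames) || !length(obj$frames))
      stop("malformed pose JSON: no 'frames' field in ", path)
    fi <- vapply(obj$frames, function(f) {
      if (is.null(f$frame)) stop("malformed pose JSON: frame without ",
                                 "'frame' index in ", path)
      as.integer(f$frame)
    }, integer(1))
    if (anyDuplicated(fi))
      stop("duplicate frame_index ", fi[duplicated(fi)][1], " in ", path)
    co <- array(NA_real_, dim = c(length(fi), 17L, 3L))
    for (i in seq_along(obj$frames)) {
      kp <- obj$frames[[i]]$keypoints
      if (is.list(kp)) kp <- do.call(rbind, kp)
      if (is.null(dim(kp)) || nrow(kp) != 17L || ncol(kp) != 3L)
        stop("frame ", fi[i], ": expected 17 keypoints of [x, y, score]")
      co[i, , ] <- as.numeric(kp)
    }
    ord <- order(fi)
    seq <- PoseSequence(co[ord, , , drop = FALSE], frameIndex = fi[ord],
      participantId = if (!is.null(obj$participant_id)) obj$participant_id
                      else "unknown",
      fps = if (!is.null(obj$fps)) obj$fps else fps,
      imageSize = if (!is.null(obj$image_size)) as.integer(obj$image_size)
                  else as.integer(imageSize))
  } else {
    hdr <- .readCsvHeaderMeta(path)
    df <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    need <- c("frame", "keypoint", "x", "y", "score")
    if (!all(need %in% names(df)))
      stop("pose CSV ", path, " is missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    for (col in need)
      if (!is.numeric(df[[col]]))
        stop("non-numeric values in column '", col, "' of ", path)
    if (any(df$keypoint < 0 | df$keypoint > 16))
      stop("keypoint index out of range 0-16 at frame ",
           df$frame[which(df$keypoint < 0 | df$keypoint > 16)[1]])
    fi <- sort(unique(as.integer(df$frame)))
    tab <- table(df$frame)
    if (any(tab != 17L))
      stop("frame ", names(tab)[tab != 17L][1],
           ": expected exactly 17 keypoint rows, found ",
           tab[tab != 17L][1])
    co <- array(NA_real_, dim = c(length(fi), 17L, 3L))
    ridx <- cbind(match(df$frame, fi), as.integer(df$keypoint) + 1L)
    if (anyDuplicated(ridx))
      stop("duplicate (frame, keypoint) row at frame ",
           df$frame[duplicated(as.data.frame(ridx))][1])
    co[cbind(ridx, 1L)] <- df$x
    co[cbind(ridx, 2L)] <- df$y
    co[cbind(ridx, 3L)] <- df$score
    seq <- PoseSequence(co, frameIndex = fi,
      participantId = if (!is.null(hdr$participant_id)) hdr$participant_id
                      else "unknown",
      fps = if (!is.null(hdr$fps)) as.numeric(hdr$fps) else fps,
      imageSize = if (!is.null(hdr$image_size)) hdr$image_size
                  else as.integer(imageSize))
  }
  if (!is.null(participantId)) seq@participantId <- as.character(participantId)
  validObject(seq)
  seq
}

.readCsvHeaderMeta <- function(path) {
  out <- list()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.+)$", line))[[1]]
    if (length(m) == 3L) {
      key <- m[2]; val <- trimws(m[3])
      if (key == "image_size")
        val <- as.integer(strsplit(val, "x", fixed = TRUE)[[1]])
      out[[key]] <- val
    }
  }
  out
}

#' Write a pose sequence to JSON or long CSV
#'
#' Writes the layouts documented in [readPoseSequence()]; numbers are
#' written with full double precision so that a write/read round trip
#' preserves every field.
#'
#' @param x A [PoseSequence-class].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writePoseSequence <- function(x, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  co <- keypointArray(x)
  if (format == "json") {
    frames <- lapply(seq_len(nFrames(x)), function(i)
      list(frame = x@frameIndex[i],
           keypoints = unname(co[i, , , drop = TRUE])))
    obj <- list(participant_id = participantId(x), fps = imageFps(x),
                image_size = imageSize(x), frames = frames)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                         na = "null")
  } else {
    n <- nFrames(x)
    df <- data.frame(
      frame = rep(x@frameIndex, each = 17L),
      keypoint = rep(0:16, times = n),
      x = as.vector(t(co[, , 1L])),
      y = as.vector(t(co[, , 2L])),
      score = as.vector(t(co[, , 3L])))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(paste0("# participant_id: ", participantId(x)),
                 paste0("# fps: ", format(imageFps(x), digits = 17)),
                 paste0("# image_size: ", paste(imageSize(x),
                                                collapse = "x")),
                 "frame,keypoint,x,y,score"), con)
    writeLines(sprintf("%d,%d,%.17g,%.17g,%.17g", df$frame,
                       df$keypoint, df$x, df$y, df$score), con)
  }
  invisible(path)
}

#' Extract the five centre-of-mass keypoints of one frame
#'
#' Returns the nose, left/right shoulder and left/right hip keypoints
#' (COCO indices 0, 5, 6, 11, 12) of one frame, in that fixed order.
#'
#' @param x A [PoseSequence-class].
#' @param frame A frame index present in `frameIndices(x)`.
#' @return A 5-row data.frame with columns `keypoint`, `name`, `x`, `y`,
#'   `score`.
#' @export
selectComKeypoints <- function(x, frame) {
  stopifnot(is(x, "PoseSequence"))
  i <- match(frame, x@frameIndex)
  if (is.na(i)) stop("frame ", frame, " not present in sequence")
  idx <- comKeypointIndices()
  co <- x@coords[i, idx + 1L, , drop = TRUE]
  data.frame(keypoint = unname(idx), name = names(idx),
             x = co[, 1L], y = co[, 2L], score = co[, 3L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Repair low-confidence centre-of-mass keypoints by linear interpolation
#'
#' A CoM keypoint observation is invalid when its confidence is below
#' `minScore` or its coordinates are missing. Runs of invalid frames of
#' length at most `maxGap` that are flanked by valid observations of the
#' same keypoint are repaired by per-coordinate linear interpolation
#' between the nearest valid neighbours; longer runs, and runs touching
#' the sequence boundary, are dropped (coordinates set to `NA`, so the
#' affected frames are excluded from CoM computation). Only the five CoM
#' keypoints are touched.
#'
#' @param x A [PoseSequence-class].
#' @param minScore Confidence threshold in \[0, 1\] below which a keypoint
#'   is considered missing (default 0.3).
#' @param maxGap Longest run of consecutive invalid frames that is still
#'   interpolated (default 5); longer gaps are dropped, not extrapolated.
#' @return A list with elements `sequence` (the repaired
#'   [PoseSequence-class]) and `log` (data.frame with columns `frame`,
#'   `keypoint`, `action` in `repaired`/`dropped`).
#' @export
interpolateMissing <- function(x, minScore = 0.3, maxGap = 5L) {
  stopifnot(is(x, "PoseSequence"), minScore >= 0, minScore <= 1,
            maxGap >= 0)
  co <- x@coords
  idx <- comKeypointIndices() + 1L
  validMat <- sapply(idx, function(k) {
    sc <- co[, k, 3L]
    is.finite(co[, k, 1L]) & is.finite(co[, k, 2L]) &
      is.finite(sc) & sc >= minScore
  })
  validMat <- matrix(validMat, ncol = length(idx))
  if (sum(rowSums(validMat) == length(idx)) < 2L)
    stop("unrecoverable sequence for participant ", x@participantId,
         ": fewer than 2 frames with all five CoM keypoints above ",
         minScore)
  logs <- list()
  fi <- x@frameIndex
  for (j in seq_along(idx)) {
    k <- idx[j]
    bad <- !validMat[, j]
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (run in which(r$values)) {
      s <- starts[run]; e <- ends[run]
      repairable <- s > 1L && e < nrow(validMat) && (e - s + 1L) <= maxGap
      if (repairable) {
        for (d in 1:2)
          co[s:e, k, d] <- stats::approx(
            x = fi[c(s - 1L, e + 1L)], y = co[c(s - 1L, e + 1L), k, d],
            xout = fi[s:e])$y
        act <- "repaired"
      } else {
        co[s:e, k, 1:2] <- NA_real_
        act <- "dropped"
      }
      logs[[length(logs) + 1L]] <- data.frame(
        frame = fi[s:e], keypoint = names(comKeypointIndices())[j],
        action = act, stringsAsFactors = FALSE)
    }
  }
  log <- if (length(logs)) do.call(rbind, logs)
         else data.frame(frame = integer(0), keypoint = character(0),
                         action = character(0), stringsAsFactors = FALSE)
  out <- x
  out@coords <- co
  validObject(out)
  list(sequence = out, log = log[order(log$frame), , drop = FALSE])
}

#' Summarise keypoint confidence over the CoM keypoints
#'
#' Pools the confidence scores of the five CoM keypoints across all
#' frames of a sequence and reports mean, median, max and quartiles
#' (linear-interpolation quantiles).
#'
#' @param x A [PoseSequence-class].
#' @return One-row data.frame with columns `participant_id`, `mean`,
#'   `median`, `max`, `q1`, `q3`.
#' @export
summarizeConfidence <- function(x) {
  stopifnot(is(x, "PoseSequence"), nFrames(x) >= 1L)
  sc <- as.vector(x@coords[, comKeypointIndices() + 1L, 3L])
  sc <- sc[is.finite(sc)]
  if (!length(sc))
    stop("all CoM keypoint scores missing for participant ",
         x@participantId)
  q <- linearQuantile(sc, c(0.25, 0.5, 0.75))
  data.frame(participant_id = participantId(x), mean = mean(sc),
             median = q[2], max = max(sc), q1 = q[1], q3 = q[3],
             stringsAsFactors = FALSE)
}
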