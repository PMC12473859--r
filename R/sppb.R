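#' Default SPPB 4-metre walk cut points
#'
#' The standard SPPB gait-speed categories for the 4-m course: 4 points
#' for a time of at most 4.82 s, 3 for 4.83-6.20 s, 2 for 6.21-8.70 s,
#' 1 for any slower completed walk, 0 for unable to complete. The cut
#' points are a package default and fully overridable -- protocols differ
#' in the exact boundaries.
#'
#' @return data.frame with columns `max_time` (upper bound in seconds,
#'   `Inf` for the slowest completed category) and `score`.
#' @export
sppbCutpoints <- function() {
  data.frame(max_time = c(4.82, 6.20, 8.70, Inf),
             score = c(4L, 3L, 2L, 1L))
}

#' Score a 4-m walk time
#'
#' @param time Numeric vector of walk times in seconds (`NA` = unable /
#'   missing, scored 0).
#' @param cutpoints Cut-point table as in [sppbCutpoints()]; must have
#'   strictly increasing `max_time` and strictly decreasing `score`.
#' @return Integer scores 0-4.
#' @examples
#' scoreGaitTime(c(3, 5, 7, 100, NA))
#' @export
scoreGaitTime <- function(time, cutpoints = sppbCutpoints()) {
  stopifnot(all(diff(cutpoints$max_time) > 0),
            all(diff(cutpoints$score) < 0))
  if (any(time <= 0, na.rm = TRUE))
    stop("walk times must be positive (got ",
         min(time, na.rm = TRUE), ")")
  idx <- vapply(time, function(t) {
    if (is.na(t)) return(NA_integer_)
    which(t <= cutpoints$max_time)[1]
  }, integer(1))
  out <- cutpoints$score[idx]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Score the SPPB 4-metre walking test from trial times
#'
#' Each of the two recorded trials is scored on the cut-point table, and
#' a combined score is computed from the mean of the available trial
#' times (the protocol records the average of two measurements). A
#' participant with both trials missing scores 0 throughout. The mean of
#' the two per-trial scores is logged as an alternative combined score in
#' attribute `"score_mean_of_trials"`.
#'
#' @param trials data.frame with columns `participant_id`, `time_1`,
#'   `time_2` (seconds, `NA` allowed).
#' @param cutpoints Cut-point table, see [sppbCutpoints()].
#' @return data.frame with columns `participant_id`, `mean_time`,
#'   `test2_1_score`, `test2_2_score`, `test2_score`.
#' @export
scoreWalk <- function(trials, cutpoints = sppbCutpoints()) {
  stopifnot(all(c("participant_id", "time_1", "time_2") %in%
                names(trials)))
  meanTime <- rowMeans(cbind(trials$time_1, trials$time_2), na.rm = TRUE)
  meanTime[is.nan(meanTime)] <- NA_real_
  out <- data.frame(
    participant_id = as.character(trials$participant_id),
    mean_time = meanTime,
    test2_1_score = scoreGaitTime(trials$time_1, cutpoints),
    test2_2_score = scoreGaitTime(trials$time_2, cutpoints),
    test2_score = scoreGaitTime(meanTime, cutpoints),
    stringsAsFactors = FALSE)
  attr(out, "score_mean_of_trials") <-
    rowMeans(cbind(out$test2_1_score, out$test2_2_score))
  out
}
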