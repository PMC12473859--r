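test_that("write/read round trip preserves every field in both formats", {
  seq <- randomPoseSeq(7, id = "RT1", seed = 101)
  for (fmt in c("json", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writePoseSequence(seq, f, format = fmt)
    back <- readPoseSequence(f, format = fmt)
    expect_identical(participantId(back), "RT1")
    expect_identical(frameIndices(back), frameIndices(seq))
    expect_equal(imageFps(back), imageFps(seq))
    expect_identical(imageSize(back), imageSize(seq))
    expect_equal(keypointArray(back), keypointArray(seq),
                 tolerance = 0, ignore_attr = FALSE)
  }
})

test_that("round trip preserves missing coordinates", {
  seq <- randomPoseSeq(4, seed = 7)
  co <- keypointArray(seq)
  co[2, 1, 1:2] <- NA_real_
  co[3, 6, 3] <- NA_real_
  seq2 <- PoseSequence(co, participantId = "M1")
  for (fmt in c("json", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writePoseSequence(seq2, f, format = fmt)
    back <- readPoseSequence(f, format = fmt)
    expect_equal(keypointArray(back), keypointArray(seq2))
  }
})

test_that("frames are sorted on read and schema violations are caught", {
  f <- withr::local_tempfile(fileext = ".json")
  frames <- lapply(c(2L, 0L, 1L), function(i)
    list(frame = i, keypoints = lapply(1:17, function(k)
      c(k, k + 1, 0.5))))
  jsonlite::write_json(list(participant_id = "S1", fps = 30,
                            image_size = c(1280, 720), frames = frames),
                       f, auto_unbox = TRUE)
  seq <- readPoseSequence(f)
  expect_identical(frameIndices(seq), 0:2)

  # duplicate frame index
  frames2 <- frames
  frames2[[2]]$frame <- 2L
  jsonlite::write_json(list(frames = frames2), f, auto_unbox = TRUE)
  expect_error(readPoseSequence(f), "duplicate frame_index")

  # wrong keypoint count
  frames3 <- frames
  frames3[[1]]$keypoints <- frames3[[1]]$keypoints[1:16]
  jsonlite::write_json(list(frames = frames3), f, auto_unbox = TRUE)
  expect_error(readPoseSequence(f), "expected 17 keypoints")

  # CSV with keypoint index 17
  g <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(frame = 0, keypoint = c(0:15, 17), x = 1, y = 2,
                   score = 0.5)
  write.csv(df, g, row.names = FALSE)
  expect_error(readPoseSequence(g), "keypoint index out of range")
})

test_that("participant id override and csv metadata header work", {
  seq <- randomPoseSeq(3, id = "Orig", seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writePoseSequence(seq, f)
  expect_identical(participantId(readPoseSequence(f)), "Orig")
  expect_identical(
    participantId(readPoseSequence(f, participantId = "Over")), "Over")
})

test_that("selectComKeypoints returns exactly the five CoM keypoints", {
  seq <- randomPoseSeq(5, seed = 11)
  kp <- selectComKeypoints(seq, frame = 2L)
  expect_identical(kp$keypoint, c(0L, 5L, 6L, 11L, 12L))
  # brute-force membership filter over the raw array
  co <- keypointArray(seq)[3, , ]
  want <- co[(0:16) %in% c(0, 5, 6, 11, 12), ]
  expect_equal(unname(cbind(kp$x, kp$y, kp$score)), unname(want))
  # coincident keypoints give five identical points
  com <- matrix(rep(c(50, 60), each = 4), ncol = 2)
  s2 <- makePoseSeq(com)
  co2 <- keypointArray(s2)
  co2[, , 1] <- 50
  co2[, , 2] <- 60
  kp2 <- selectComKeypoints(PoseSequence(co2), 0L)
  expect_true(all(kp2$x == 50) && all(kp2$y == 60))
})

test_that("interpolation fills an interior gap at the midpoint", {
  com <- cbind(c(0, 100, 10), c(0, -50, 20))  # middle frame to be repaired
  seq <- makePoseSeq(com)
  co <- keypointArray(seq)
  co[2, , 3] <- 0.1  # all keypoints low confidence in frame 1
  seq <- PoseSequence(co, participantId = "I1")
  out <- interpolateMissing(seq, minScore = 0.3, maxGap = 5)
  tr <- computeCoM(out$sequence)
  expect_equal(tr@x[2], 5)   # midpoint of 0 and 10
  expect_equal(tr@y[2], 10)  # midpoint of 0 and 20
  expect_setequal(unique(out$log$action), "repaired")
  expect_identical(sort(unique(out$log$frame)), 1L)
})

test_that("interpolation is a no-op when nothing is below threshold", {
  seq <- makePoseSeq(cbind(1:6, 1:6), scores = 0.9)
  out <- interpolateMissing(seq)
  expect_identical(keypointArray(out$sequence), keypointArray(seq))
  expect_identical(nrow(out$log), 0L)
})

test_that("gaps longer than maxGap are dropped, not extrapolated", {
  com <- cbind(as.numeric(1:10), as.numeric(1:10))
  seq <- makePoseSeq(com)
  co <- keypointArray(seq)
  co[3:6, 1, 3] <- 0.05          # 4-frame gap in the nose keypoint
  co[9, 7, 3] <- 0.05            # 1-frame gap in right shoulder
  seq <- PoseSequence(co, participantId = "G1")
  out <- interpolateMissing(seq, minScore = 0.3, maxGap = 2)
  lg <- out$log
  expect_setequal(lg$action[lg$keypoint == "nose"], "dropped")
  expect_setequal(lg$action[lg$keypoint == "right_shoulder"], "repaired")
  arr <- keypointArray(out$sequence)
  expect_true(all(is.na(arr[3:6, 1, 1])))
  # leading/trailing invalid frames are dropped (no extrapolation)
  co2 <- keypointArray(makePoseSeq(com))
  co2[1, 1, 3] <- 0.05
  out2 <- interpolateMissing(PoseSequence(co2), maxGap = 5)
  expect_identical(out2$log$action, "dropped")
})

test_that("random masking repair equals an independent per-gap linear fit", {
  set.seed(202)
  n <- 120
  com <- cbind(cumsum(runif(n, 1, 3)), cumsum(rnorm(n)))
  seq <- makePoseSeq(com)
  co <- keypointArray(seq)
  comIdx <- comKeypointIndices() + 1L
  masked <- which(runif(n) < 0.05)
  masked <- setdiff(masked, c(1, n))
  kmask <- sample(comIdx, length(masked), replace = TRUE)
  co[cbind(masked, kmask, 3)] <- 0.01
  seq <- PoseSequence(co, participantId = "RM1")
  out <- interpolateMissing(seq, minScore = 0.3, maxGap = 5)
  arr <- keypointArray(out$sequence)
  orig <- keypointArray(seq)
  for (i in seq_along(masked)) {
    fr <- masked[i]; k <- kmask[i]
    lo <- max(which(orig[1:(fr - 1), k, 3] >= 0.3))
    hirel <- which(orig[(fr + 1):n, k, 3] >= 0.3)[1]
    hi <- fr + hirel
    w <- (fr - lo) / (hi - lo)
    for (d in 1:2) {
      want <- (1 - w) * orig[lo, k, d] + w * orig[hi, k, d]
      expect_equal(arr[fr, k, d], want, tolerance = 1e-12)
    }
  }
  # frames outside the logged gaps are untouched
  untouched <- setdiff(seq_len(n), out$log$frame + 1L)
  expect_identical(arr[untouched, , ], orig[untouched, , ])
})

test_that("unrecoverable sequences raise an error", {
  seq <- makePoseSeq(cbind(1:4, 1:4), scores = 0.1)
  expect_error(interpolateMissing(seq), "unrecoverable")
})

test_that("confidence summary matches constant and two-point data", {
  seq <- makePoseSeq(cbind(1:5, 1:5), scores = 0.7)
  s <- summarizeConfidence(seq)
  expect_equal(unlist(s[c("mean", "median", "max", "q1", "q3")]),
               c(mean = 0.7, median = 0.7, max = 0.7, q1 = 0.7,
                 q3 = 0.7))
  seq6 <- makePoseSeq(cbind(1:6, 1:6))
  co <- keypointArray(seq6)
  co[, , 3] <- rep(c(0.5, 0.7), length.out = length(co[, , 3]))
  s2 <- summarizeConfidence(PoseSequence(co))
  expect_equal(s2$mean, 0.6)
})

test_that("confidence summary ordering invariant holds on random input", {
  for (k in 1:20) {
    s <- summarizeConfidence(randomPoseSeq(8, seed = 300 + k))
    expect_true(s$q1 <= s$median && s$median <= s$q3 && s$q3 <= s$max)
    expect_true(all(unlist(s[-1]) >= 0 & unlist(s[-1]) <= 1))
  }
})
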