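# Build a PoseSequence from a matrix of CoM-keypoint coordinates.
# comXY: n x 2 matrix of intended CoM positions; the five CoM keypoints
# are placed at zero-sum offsets around each position so the frame CoM
# equals comXY exactly; the other 12 keypoints get arbitrary positions.
makePoseSeq <- function(comXY, scores = 0.9, id = "T1", fps = 30) {
  n <- nrow(comXY)
  off <- rbind(c(0, -40), c(20, -10), c(-20, -10), c(10, 30), c(-10, 30))
  co <- array(NA_real_, dim = c(n, 17, 3))
  comIdx <- comKeypointIndices() + 1L
  for (j in seq_along(comIdx)) {
    co[, comIdx[j], 1] <- comXY[, 1] + off[j, 1]
    co[, comIdx[j], 2] <- comXY[, 2] + off[j, 2]
  }
  others <- setdiff(1:17, comIdx)
  for (k in others) {
    co[, k, 1] <- comXY[, 1] + k
    co[, k, 2] <- comXY[, 2] - k
  }
  co[, , 3] <- scores
  PoseSequence(co, participantId = id, fps = fps)
}

# Random full-coordinate sequence (all keypoints uniform in the image).
randomPoseSeq <- function(n = 10, id = "R1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  co <- array(NA_real_, dim = c(n, 17, 3))
  co[, , 1] <- runif(n * 17, 0, 1280)
  co[, , 2] <- runif(n * 17, 0, 720)
  co[, , 3] <- runif(n * 17)
  PoseSequence(co, participantId = id)
}

# Tiny cohort config for fast tests.
tinyConfig <- function(seed = 42, ...) {
  synthCohortConfig(nParticipants = 6L, framesPerParticipant = 60L,
                    seed = seed, ...)
}

# One-row body-composition record consistent with its own identities.
makeBodyRecord <- function(id = "B1", sex = "male", height = 165,
                           icw = 21.216, ecw = 13.8, smi = 8.1,
                           bmi = 22.7) {
  tbw <- icw + ecw
  data.frame(participant_id = id, sex = sex, age = 75, height = height,
             weight = bmi * (height / 100)^2, ICW = icw, ECW = ecw,
             TBW = tbw, ECW_TBW = ecw / tbw, BMI = bmi, SMI = smi,
             SMM = 25.6, PBF = 19.7, FAT = 11.8, VFA = 46.3,
             stringsAsFactors = FALSE)
}
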