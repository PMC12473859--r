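test_that("CoM equals the unweighted mean of the five keypoints", {
  # constant keypoints
  co <- array(0.9, dim = c(1, 17, 3))
  co[1, , 1] <- 10; co[1, , 2] <- 20
  tr <- computeCoM(PoseSequence(co))
  expect_equal(c(tr@x, tr@y), c(10, 20))

  # symmetric cross: keypoints (0,0),(2,0),(0,2),(2,2),(1,1) -> CoM (1,1)
  co2 <- array(0.9, dim = c(1, 17, 3))
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2), c(1, 1))
  comIdx <- comKeypointIndices() + 1L
  co2[1, , 1] <- 99; co2[1, , 2] <- 99
  for (j in 1:5) co2[1, comIdx[j], 1:2] <- pts[j, ]
  tr2 <- computeCoM(PoseSequence(co2))
  expect_equal(c(tr2@x, tr2@y), c(1, 1))
})

test_that("CoM matches a brute-force arithmetic-mean oracle on random frames", {
  seq <- randomPoseSeq(100, seed = 500)
  tr <- computeCoM(seq)
  co <- keypointArray(seq)
  comIdx <- comKeypointIndices() + 1L
  for (i in seq_len(100)) {
    expect_equal(tr@x[i], sum(co[i, comIdx, 1]) / 5, tolerance = 1e-12)
    expect_equal(tr@y[i], sum(co[i, comIdx, 2]) / 5, tolerance = 1e-12)
  }
})

test_that("frames with missing CoM keypoints are invalid and not bridged", {
  co <- array(0.9, dim = c(4, 17, 3))
  co[, , 1] <- matrix(1:4, 4, 17)
  co[, , 2] <- 0
  co[2, 6, 1] <- NA  # left shoulder x missing in frame 1
  tr <- computeCoM(PoseSequence(co))
  expect_identical(tr@valid, c(TRUE, FALSE, TRUE, TRUE))
  dyn <- computeDynamics(tr)
  # pairs (0,1) and (1,2) vanish with the single invalid frame
  expect_identical(dyn$frame, 3L)
})

test_that("dynamics reproduce hand-computed displacement and angles", {
  com <- rbind(c(0, 0), c(3, 4), c(3, 4), c(4, 5), c(4, 7), c(3, 6))
  tr <- computeCoM(makePoseSeq(com))
  dyn <- computeDynamics(tr)
  expect_equal(dyn$center_dis[1], 5)              # 3-4-5 triangle
  expect_equal(dyn$theta[2], 0)                   # stationary -> 0
  expect_equal(dyn$center_dis[2], 0)
  expect_equal(dyn$theta[3], pi / 4)              # delta (1,1)
  expect_equal(dyn$theta[4], pi / 2)              # delta (0,2), dy > 0
  expect_equal(dyn$theta[5], atan(-1 / -1))       # ratio convention
  expect_equal(dyn$center_dis, sqrt(dyn$dx^2 + dyn$dy^2))
})

test_that("vertical steps follow the stated sign convention", {
  com <- rbind(c(0, 0), c(0, -2), c(0, -2))
  dyn <- computeDynamics(computeCoM(makePoseSeq(com)))
  expect_equal(dyn$theta, c(-pi / 2, 0))
})

test_that("dynamics are invariant under translation and scale correctly", {
  set.seed(77)
  com <- cbind(cumsum(runif(30, 0.5, 3)), cumsum(rnorm(30)))
  d0 <- computeDynamics(computeCoM(makePoseSeq(com)))
  d1 <- computeDynamics(computeCoM(makePoseSeq(com + 500)))
  expect_equal(d1$center_dis, d0$center_dis, tolerance = 1e-9)
  expect_equal(d1$theta, d0$theta, tolerance = 1e-9)
  s <- 2.5
  d2 <- computeDynamics(computeCoM(makePoseSeq(com * s)))
  expect_equal(d2$center_dis, s * d0$center_dis, tolerance = 1e-9)
  expect_equal(d2$theta, d0$theta, tolerance = 1e-9)
  # aggregate-level scaling: displacement and horizontal shift scale by s,
  # angular shift unchanged
  a0 <- aggregateFeatures(d0, mode = "angular")
  a2 <- aggregateFeatures(d2, mode = "angular")
  expect_equal(a2@meanDirectionalShift, a0@meanDirectionalShift,
               tolerance = 1e-9)
  expect_equal(a2@meanDisplacement, s * a0@meanDisplacement,
               tolerance = 1e-9)
  h0 <- aggregateFeatures(d0, mode = "horizontal")
  h2 <- aggregateFeatures(d2, mode = "horizontal")
  expect_equal(h2@meanDirectionalShift, s * h0@meanDirectionalShift,
               tolerance = 1e-9)
})

test_that("path length dominates straight-line CoM displacement", {
  for (k in 1:10) {
    set.seed(600 + k)
    com <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40)))
    dyn <- computeDynamics(computeCoM(makePoseSeq(com)))
    straight <- sqrt(diff(range(com[c(1, 40), 1]))^2 +
                     (com[40, 2] - com[1, 2])^2)
    expect_gte(sum(dyn$center_dis) + 1e-9, straight)
  }
})

test_that("aggregation matches an independent flat re-implementation", {
  set.seed(88)
  com <- cbind(cumsum(runif(200, 0.5, 3)), cumsum(rnorm(200)))
  dyn <- computeDynamics(computeCoM(makePoseSeq(com)))
  for (mode in c("angular", "horizontal")) {
    f <- aggregateFeatures(dyn, mode = mode)
    v <- if (mode == "angular") abs(dyn$theta) else abs(dyn$dx)
    m <- sum(v) / length(v)
    s2 <- sum((v - m)^2) / (length(v) - 1)
    expect_equal(f@meanDirectionalShift, m, tolerance = 1e-12)
    expect_equal(f@varDirectionalShift, s2, tolerance = 1e-12)
    expect_equal(f@meanDisplacement,
                 sum(dyn$center_dis) / nrow(dyn), tolerance = 1e-12)
    expect_identical(f@nFramesUsed, nrow(dyn))
  }
})

test_that("angular shift is bounded and absolute-valued", {
  dyn <- data.frame(participant_id = "A", frame = 1:2,
                    dx = c(1, 1), dy = c(0.309, -0.309),
                    center_dis = sqrt(1 + 0.309^2),
                    theta = c(0.3, -0.3))
  f <- aggregateFeatures(dyn)
  expect_equal(f@meanDirectionalShift, 0.3)
  for (k in 1:5) {
    set.seed(700 + k)
    com <- cbind(cumsum(runif(50, 0.1, 2)), cumsum(rnorm(50, 0, 2)))
    f <- aggregateFeatures(computeDynamics(computeCoM(makePoseSeq(com))))
    expect_true(f@meanDirectionalShift >= 0 &&
                f@meanDirectionalShift <= pi / 2)
  }
})

test_that("a single frame pair reports variance 0 with a warning", {
  dyn <- data.frame(participant_id = "A", frame = 1L, dx = 1, dy = 0.546,
                    center_dis = sqrt(1 + 0.546^2), theta = 0.5)
  expect_warning(f <- aggregateFeatures(dyn), "variance")
  expect_equal(f@meanDirectionalShift, 0.5)
  expect_equal(f@varDirectionalShift, 0)
})

test_that("empty dynamics raise errors naming the context", {
  co <- array(NA_real_, dim = c(3, 17, 3))
  tr <- computeCoM(PoseSequence(co, participantId = "E1"))
  expect_error(computeDynamics(tr), "empty dynamics")
  expect_error(aggregateFeatures(data.frame(), filterThreshold = 3),
               "threshold 3")
})

test_that("path density counts every point exactly once", {
  # one point
  tr1 <- computeCoM(makePoseSeq(rbind(c(5, 5))))
  h1 <- pathDensity(tr1, bins = 4)
  expect_equal(sum(h1$counts), 1)
  # aligned uniform grid: equal counts per bin
  g <- as.matrix(expand.grid(x = seq(0.5, 3.5, 1), y = seq(0.5, 3.5, 1)))
  h2 <- pathDensity(computeCoM(makePoseSeq(g)), bins = 4,
                    xlim = c(0, 4), ylim = c(0, 4))
  expect_true(all(h2$counts == 1))
  # random points match brute-force binning
  set.seed(900)
  pts <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  tr <- computeCoM(makePoseSeq(pts))
  bins <- 7
  h <- pathDensity(tr, bins = bins)
  xb <- h$xbreaks; yb <- h$ybreaks
  brute <- matrix(0L, bins, bins)
  for (i in seq_len(nrow(pts))) {
    bx <- min(bins, max(1, findInterval(pts[i, 1], xb,
                                        rightmost.closed = TRUE)))
    by <- min(bins, max(1, findInterval(pts[i, 2], yb,
                                        rightmost.closed = TRUE)))
    brute[bx, by] <- brute[bx, by] + 1L
  }
  expect_identical(h$counts, brute)
  expect_equal(sum(h$counts), 300)
  expect_error(pathDensity(tr, bins = 0), "bins")
})
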