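#' Default indicator parameters of the synthetic cohort
#'
#' Population means and standard deviations for the 21 body-composition
#' indicators, together with the planted correlation `rho` between each
#' indicator and the latent mobility factor and the loading `lambda` on a
#' shared body-size factor (which produces the strong mutual correlations
#' bioimpedance indicators have in real cohorts). Muscle and water
#' indicators carry positive plantings (about +0.41 to +0.56), fat
#' indicators negative ones (about -0.05 to -0.26).
#'
#' `TBW` and `ECW_TBW` are derived inside the generator (`TBW = ICW +
#' ECW` exactly; `ECW_TBW = ECW / TBW`), so their rows are marked
#' `derived` and their effective correlations are implied, not planted;
#' see [impliedCorrelations()].
#'
#' @return data.frame with columns `indicator`, `mean`, `sd`, `rho`,
#'   `lambda`, `derived`.
#' @export
defaultIndicatorParams <- function() {
  p <- function(indicator, mean, sd, rho, lambda, derived = FALSE)
    data.frame(indicator = indicator, mean = mean, sd = sd, rho = rho,
               lambda = lambda, derived = derived,
               stringsAsFactors = FALSE)
  rbind(
    p("ICW",          21.216,   3.863,   0.409, 0.80),
    p("ECW",          13.800,   2.446,   0.480, 0.80),
    p("TBW",          35.016,   6.288,   NA,    NA,   derived = TRUE),
    p("PM",            9.163,   1.670,   0.494, 0.80),
    p("MM",            3.246,   0.575,   0.485, 0.75),
    p("FAT",          11.811,   5.794,  -0.045, 0.55),
    p("SLM",          44.721,   8.066,   0.495, 0.80),
    p("FFM",          47.416,   8.507,   0.493, 0.80),
    p("SMM",          25.653,   5.025,   0.496, 0.80),
    p("DLM",          12.400,   2.227,   0.492, 0.80),
    p("PBF",          19.700,   8.228,  -0.256, 0.30),
    p("BMI",          22.695,   2.933,   0.261, 0.60),
    p("ECW_TBW",       0.394,   0.007,   NA,    NA,   derived = TRUE),
    p("BFM_control",  -2.421,   5.507,  -0.005, 0.10),
    p("FFM_control",   1.679,   2.525,  -0.296, 0.10),
    p("BCM",          30.384,   5.534,   0.497, 0.80),
    p("BMC",           2.687,   0.465,   0.447, 0.70),
    p("VFA",          46.316,  21.765,  -0.132, 0.50),
    p("BMR",        1394.368, 183.521,   0.493, 0.80),
    p("TBW_FFM",      73.789,   0.380,   0.174, 0.10),
    p("SMI",           8.132,   1.322,   0.561, 0.80))
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles and validates every tunable of [generateCohort()]. The
#' defaults are the study conditions the generator emulates: 19
#' participants (16 male, 3 female), 30 fps video, a right-skewed
#' long-tailed per-frame displacement with about 5% abnormal frames,
#' CoM keypoint confidences with per-participant means in 0.59-0.68 and
#' maxima in 0.77-0.83, indicator distributions per
#' [defaultIndicatorParams()], and a per-participant mean directional
#' shift of about 0.36 +/- 0.15 radians.
#'
#' @param nParticipants Cohort size.
#' @param seed Integer master seed; all randomness flows from it through
#'   named substreams.
#' @param framesPerParticipant Frames per walking trial (default 150,
#'   about 5 s at 30 fps).
#' @param fps Frames per second.
#' @param imageSize Image `(width, height)` in pixels.
#' @param indicatorParams Indicator parameter table, see
#'   [defaultIndicatorParams()].
#' @param outlierRate Fraction of frames carrying a displacement spike
#'   (default 0.05).
#' @param outlierScale Multiplicative scale of a spike: a spiked frame's
#'   displacement is multiplied by `outlierScale * U(0.8, 2.5)`
#'   (default 10), mimicking pixel jumps from frame freezing.
#' @param displacementMeanlog,displacementSdlog Log-normal parameters of
#'   the clean per-frame displacement (pixels).
#' @param jitterSd Pixel jitter of each CoM keypoint around its
#'   anatomical offset.
#' @param lowConfRate Fraction of frames in which one CoM keypoint is
#'   emitted with confidence below 0.3 (exercises interpolation repair).
#' @param mdsMean,mdsSd Population mean and SD of the per-participant
#'   true mean directional shift (radians).
#' @param sexMdsOffset Additive shift of the female mean directional
#'   shift (default -0.03, females slightly less mobile).
#' @param swayAmplitude,swayFreq Relative amplitude and frequency (Hz) of
#'   the sinusoidal gait-sway component of the step angle.
#' @param walkCoupling Correlation between latent mobility and latent
#'   walking speed (default 0.15: walk times are nearly uncoupled from
#'   the directional shift).
#' @param femaleFraction Fraction of female participants.
#' @param confMeanRange,confMaxRange Ranges from which each participant's
#'   target confidence mean and upper bound are drawn.
#' @return Validated config object of class `SynthCohortConfig`.
#' @export
synthCohortConfig <- function(nParticipants = 19L, seed = 1L,
                              framesPerParticipant = 150L, fps = 30,
                              imageSize = c(1280L, 720L),
                              indicatorParams = defaultIndicatorParams(),
                              outlierRate = 0.05, outlierScale = 10,
                              displacementMeanlog = log(2.6),
                              displacementSdlog = 0.35,
                              jitterSd = 0.3, lowConfRate = 0.02,
                              mdsMean = 0.36, mdsSd = 0.15,
                              sexMdsOffset = -0.03,
                              swayAmplitude = 0.2, swayFreq = 1.8,
                              walkCoupling = 0.15,
                              femaleFraction = 3 / 19,
                              confMeanRange = c(0.60, 0.67),
                              confMaxRange = c(0.805, 0.825)) {
  cfg <- list(nParticipants = as.integer(nParticipants),
              seed = as.integer(seed),
              framesPerParticipant = as.integer(framesPerParticipant),
              fps = fps, imageSize = as.integer(imageSize),
              indicatorParams = indicatorParams,
              outlierRate = outlierRate, outlierScale = outlierScale,
              displacementMeanlog = displacementMeanlog,
              displacementSdlog = displacementSdlog,
              jitterSd = jitterSd, lowConfRate = lowConfRate,
              mdsMean = mdsMean, mdsSd = mdsSd,
              sexMdsOffset = sexMdsOffset,
              swayAmplitude = swayAmplitude, swayFreq = swayFreq,
              walkCoupling = walkCoupling,
              femaleFraction = femaleFraction,
              confMeanRange = confMeanRange, confMaxRange = confMaxRange)
  stopifnot(cfg$nParticipants >= 1L, cfg$framesPerParticipant >= 3L,
            cfg$fps > 0)
  if (cfg$outlierRate < 0 || cfg$outlierRate > 1 ||
      cfg$lowConfRate < 0 || cfg$lowConfRate > 1)
    stop("rates must lie in [0, 1]")
  ip <- cfg$indicatorParams
  planted <- !ip$derived
  if (any(abs(ip$rho[planted]) >= 1))
    stop("planted correlations must satisfy |rho| < 1")
  infeasible <- planted & (ip$rho^2 + ip$lambda^2 >= 1)
  if (any(infeasible))
    stop("infeasible planted correlation for ",
         paste(ip$indicator[infeasible], collapse = ", "),
         ": rho^2 + lambda^2 must be < 1")
  if (abs(cfg$walkCoupling) >= 1)
    stop("walkCoupling must lie in (-1, 1)")
  class(cfg) <- "SynthCohortConfig"
  cfg
}

#' Planted and implied indicator-mobility correlations
#'
#' For directly planted indicators the population correlation with the
#' latent mobility factor is the configured `rho`. For derived
#' indicators it is implied by the construction: for `TBW = ICW + ECW`,
#' `rho_TBW = (sd_ICW rho_ICW + sd_ECW rho_ECW) / sd_TBW` with the
#' implied `sd_TBW`; for the ratio `ECW/TBW` a first-order (delta
#' method) linearisation at the means is used.
#'
#' @param cfg A `SynthCohortConfig`.
#' @return data.frame with columns `indicator`, `rho` (the effective
#'   population correlation) and `planted` (`FALSE` for derived rows).
#' @export
impliedCorrelations <- function(cfg) {
  ip <- cfg$indicatorParams
  get <- function(ind, col) ip[[col]][ip$indicator == ind]
  out <- data.frame(indicator = ip$indicator, rho = ip$rho,
                    planted = !ip$derived, stringsAsFactors = FALSE)
  sI <- get("ICW", "sd"); sE <- get("ECW", "sd")
  rI <- get("ICW", "rho"); rE <- get("ECW", "rho")
  lI <- get("ICW", "lambda"); lE <- get("ECW", "lambda")
  covIE <- sI * sE * (rI * rE + lI * lE)
  sT <- sqrt(sI^2 + sE^2 + 2 * covIE)
  if ("TBW" %in% ip$indicator)
    out$rho[out$indicator == "TBW"] <- (sI * rI + sE * rE) / sT
  if ("ECW_TBW" %in% ip$indicator) {
    mI <- get("ICW", "mean"); mE <- get("ECW", "mean")
    mT <- mI + mE
    fI <- -mE / mT^2
    fE <- mI / mT^2
    covFM <- fI * sI * rI + fE * sE * rE
    vF <- fI^2 * sI^2 + fE^2 * sE^2 + 2 * fI * fE * covIE
    out$rho[out$indicator == "ECW_TBW"] <- covFM / sqrt(vF)
  }
  out
}

# anatomical keypoint offsets (pixels at reference stature); the five CoM
# keypoint offsets sum to zero per coordinate so the designed CoM is exact
.kpOffsets <- function(scale = 1) {
  off <- rbind(
    nose = c(0, -60), left_eye = c(4, -66), right_eye = c(-4, -66),
    left_ear = c(9, -63), right_ear = c(-9, -63),
    left_shoulder = c(25, -25), right_shoulder = c(-25, -25),
    left_elbow = c(33, 5), right_elbow = c(-33, 5),
    left_wrist = c(36, 35), right_wrist = c(-36, 35),
    left_hip = c(15, 55), right_hip = c(-15, 55),
    left_knee = c(17, 115), right_knee = c(-17, 115),
    left_ankle = c(18, 175), right_ankle = c(-18, 175))
  off * scale
}

.simDisplacementStream <- function(cfg, nSteps) {
  d <- stats::rlnorm(nSteps, cfg$displacementMeanlog,
                     cfg$displacementSdlog)
  spike <- stats::runif(nSteps) < cfg$outlierRate
  d[spike] <- d[spike] * cfg$outlierScale * stats::runif(sum(spike),
                                                         0.8, 2.5)
  list(d = d, spike = spike)
}

.simThetaStream <- function(cfg, nSteps, sTheta, spike) {
  tt <- seq_len(nSteps) / cfg$fps
  theta <- sTheta * (stats::rnorm(nSteps) +
                     cfg$swayAmplitude * sin(2 * pi * cfg$swayFreq * tt))
  theta <- pmin(pmax(theta, -1.45), 1.45)
  # a frame-freeze jump has an arbitrary direction
  theta[spike] <- stats::runif(sum(spike), -1.45, 1.45)
  theta
}

.simConfidence <- function(cfg, n) {
  hi <- stats::runif(1, cfg$confMaxRange[1], cfg$confMaxRange[2])
  target <- stats::runif(1, cfg$confMeanRange[1], cfg$confMeanRange[2])
  muB <- (target - 0.3) / (hi - 0.3)
  sc <- 0.3 + (hi - 0.3) * stats::rbeta(n, 10 * muB, 10 * (1 - muB))
  # a few near-ceiling detections per trial (clean frontal frames), so
  # the per-participant maximum sits just under the participant bound
  nTop <- max(2L, stats::rbinom(1, n, 0.02))
  sc[sample.int(n, nTop)] <- 0.3 + (hi - 0.3) *
    stats::runif(nTop, 0.96, 0.995)
  sc
}

.simPoseParticipant <- function(cfg, id, mdsTrue, height, level) {
  F <- cfg$framesPerParticipant
  nSteps <- F - 1L
  disp <- .simDisplacementStream(cfg, nSteps)
  sTheta <- mdsTrue / sqrt(2 / pi)
  theta <- .simThetaStream(cfg, nSteps, sTheta, disp$spike)
  dx <- disp$d * cos(theta)
  dy <- disp$d * sin(theta)
  x0 <- 120 + stats::runif(1, 0, 60)
  y0 <- cfg$imageSize[2] / 2 + stats::runif(1, -40, 40)
  cx <- cumsum(c(x0, dx))
  cy <- cumsum(c(y0, dy))
  if (level == "dynamics") {
    # jitter of the 5 averaged keypoints perturbs the observed CoM
    ex <- stats::rnorm(F, 0, cfg$jitterSd / sqrt(5))
    ey <- stats::rnorm(F, 0, cfg$jitterSd / sqrt(5))
    ox <- cx + ex
    oy <- cy + ey
    ddx <- diff(ox)
    ddy <- diff(oy)
    return(data.frame(participant_id = id, frame = 1:nSteps,
                      dx = ddx, dy = ddy,
                      center_dis = sqrt(ddx^2 + ddy^2),
                      theta = ifelse(ddx == 0,
                                     sign(ddy) * pi / 2, atan(ddy / ddx)),
                      stringsAsFactors = FALSE))
  }
  off <- .kpOffsets(scale = height / 162)
  co <- array(NA_real_, dim = c(F, 17L, 3L))
  comIdx <- comKeypointIndices() + 1L
  for (k in 1:17) {
    jsd <- if (k %in% comIdx) cfg$jitterSd else 1.0
    co[, k, 1L] <- cx + off[k, 1] + stats::rnorm(F, 0, jsd)
    co[, k, 2L] <- cy + off[k, 2] + stats::rnorm(F, 0, jsd)
  }
  co[, comIdx, 3L] <- .simConfidence(cfg, F * length(comIdx))
  co[, -comIdx, 3L] <- pmax(0.05, co[, sample(comIdx, 1), 3L] *
                              stats::runif(F * 12, 0.75, 0.95))
  nLow <- stats::rbinom(1, F, cfg$lowConfRate)
  if (nLow > 0) {
    lowF <- sample.int(F, nLow)
    lowK <- sample(comIdx, nLow, replace = TRUE)
    co[cbind(lowF, lowK, 3L)] <- stats::runif(nLow, 0.05, 0.25)
  }
  PoseSequence(co, frameIndex = 0:(F - 1L), participantId = id,
               fps = cfg$fps, imageSize = cfg$imageSize)
}

#' Generate a synthetic multimodal mobility cohort
#'
#' Produces, from one seed, everything the analysis pipeline consumes:
#' pose-keypoint sequences, a body-composition table, SPPB walk-trial
#' times, and a ground-truth table for recovery tests.
#'
#' The construction: each participant has a latent mobility factor `m ~
#' N(0, 1)`. Indicators are drawn as `mean + sd * (rho m + lambda b +
#' sqrt(1 - rho^2 - lambda^2) e)` with a shared body-size factor `b`
#' (single-factor coupling, the simplest structure that realises the
#' planted pattern of signed correlations); `TBW = ICW + ECW` exactly,
#' `ECW_TBW = ECW/TBW`, and `weight = BMI (height/100)^2`, so generated
#' records pass every [validateBodyComp()] identity. Non-control
#' indicators are floored just above zero. Latent mobility sets each
#' participant's true mean directional shift, which drives the step-angle
#' dispersion of a simulated CoM walk (forward drift, Gaussian step
#' angles plus sinusoidal sway, log-normal step lengths, heavy-tailed
#' displacement spikes on a fraction `outlierRate` of frames). Keypoints
#' are placed around the CoM with anthropometric offsets and pixel
#' jitter; confidences are drawn to sit in the configured ranges. Walk
#' times are inversely related to a latent walking speed only weakly
#' coupled to mobility.
#'
#' @param cfg A `SynthCohortConfig` from [synthCohortConfig()].
#' @param level `"pose"` (default) materialises full
#'   [PoseSequence-class] objects; `"dynamics"` skips the keypoint layer
#'   and returns equivalent per-participant frame dynamics directly
#'   (fast path for simulation studies such as type-I-error
#'   calibration).
#' @return Object of class `SynthCohort`: a list with `poses` (or
#'   `dynamics`), `bodyComp`, `walkTrials`, `truth` (columns
#'   `participant_id`, `latent_mobility`, `mds_true`, `latent_walk`;
#'   attribute `"correlations"` holds [impliedCorrelations()]), and
#'   `config`.
#' @export
generateCohort <- function(cfg = synthCohortConfig(),
                           level = c("pose", "dynamics")) {
  stopifnot(inherits(cfg, "SynthCohortConfig"))
  level <- match.arg(level)
  n <- cfg$nParticipants
  ids <- sprintf("P%03d", seq_len(n))

  set.seed(.substreamSeed(cfg$seed, "demographics"))
  nFem <- round(n * cfg$femaleFraction)
  sex <- rep("male", n)
  if (nFem > 0) sex[sample.int(n, nFem)] <- "female"
  height <- ifelse(sex == "male", stats::rnorm(n, 164, 6.5),
                   stats::rnorm(n, 150.5, 5.5))
  age <- pmin(89, pmax(60, round(stats::rnorm(n, 77.9, 7.8))))

  set.seed(.substreamSeed(cfg$seed, "latent"))
  m <- stats::rnorm(n)
  b <- stats::rnorm(n)

  ip <- cfg$indicatorParams
  set.seed(.substreamSeed(cfg$seed, "indicators"))
  body <- data.frame(participant_id = ids, sex = sex, age = age,
                     height = height, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ip))) {
    if (ip$derived[i]) next
    rho <- ip$rho[i]; lam <- ip$lambda[i]
    z <- rho * m + lam * b +
      sqrt(1 - rho^2 - lam^2) * stats::rnorm(n)
    v <- ip$mean[i] + ip$sd[i] * z
    if (!ip$indicator[i] %in% c("BFM_control", "FFM_control"))
      v <- pmax(v, pmax(0.01 * abs(ip$mean[i]), 0.1))
    if (ip$indicator[i] == "PBF") v <- pmin(v, 100)
    body[[ip$indicator[i]]] <- v
  }
  body$TBW <- body$ICW + body$ECW
  body$ECW_TBW <- body$ECW / body$TBW
  body$weight <- body$BMI * (body$height / 100)^2
  ord <- c("participant_id", "sex", "age", "height", "weight",
           intersect(bodyCompColumns()$column, names(body)))
  body <- body[, unique(ord)]

  mdsTrue <- pmin(1.2, pmax(0.05,
    cfg$mdsMean + cfg$mdsSd * m +
      ifelse(sex == "female", cfg$sexMdsOffset, 0)))

  poses <- vector("list", n)
  for (j in seq_len(n)) {
    set.seed(.substreamSeed(cfg$seed, "pose", j))
    poses[[j]] <- .simPoseParticipant(cfg, ids[j], mdsTrue[j],
                                      height[j], level)
  }
  names(poses) <- ids

  set.seed(.substreamSeed(cfg$seed, "walk"))
  wc <- cfg$walkCoupling
  w <- wc * m + sqrt(1 - wc^2) * stats::rnorm(n)
  speed <- 0.95 * exp(0.18 * w)
  baseTime <- 4 / speed
  walk <- data.frame(participant_id = ids,
                     time_1 = baseTime * exp(stats::rnorm(n, 0, 0.04)),
                     time_2 = baseTime * exp(stats::rnorm(n, 0, 0.04)),
                     distance = 4, stringsAsFactors = FALSE)

  truth <- data.frame(participant_id = ids, latent_mobility = m,
                      mds_true = mdsTrue, latent_walk = w,
                      stringsAsFactors = FALSE)
  attr(truth, "correlations") <- impliedCorrelations(cfg)

  out <- list(bodyComp = body, walkTrials = walk, truth = truth,
              config = cfg)
  if (level == "pose") out$poses <- poses else out$dynamics <- poses
  class(out) <- "SynthCohort"
  out
}

#' Generate a null cohort (no mobility-indicator coupling)
#'
#' Identical to [generateCohort()] but with every planted correlation and
#' the walk coupling set to zero, so indicators, directional shift and
#' walk times are mutually independent. Used for type-I-error
#' calibration of the correlation battery.
#'
#' @inheritParams generateCohort
#' @return A `SynthCohort`, see [generateCohort()].
#' @export
generateNullCohort <- function(cfg = synthCohortConfig(),
                               level = c("pose", "dynamics")) {
  cfg$indicatorParams$rho[!cfg$indicatorParams$derived] <- 0
  cfg$walkCoupling <- 0
  generateCohort(cfg, level = level)
}

#' Write a synthetic cohort to disk
#'
#' Writes the same plain-text layouts the readers consume: one pose file
#' per participant (JSON or long CSV), `body_comp.csv`,
#' `walk_trials.csv`, and a `ground_truth.json` sidecar.
#'
#' @param cohort A `SynthCohort` generated at `level = "pose"`.
#' @param dir Output directory (created if needed).
#' @param poseFormat `"json"` or `"csv"`.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, poseFormat = c("json", "csv")) {
  poseFormat <- match.arg(poseFormat)
  stopifnot(inherits(cohort, "SynthCohort"), !is.null(cohort$poses))
  dir.create(file.path(dir, "poses"), recursive = TRUE,
             showWarnings = FALSE)
  for (p in cohort$poses)
    writePoseSequence(p, file.path(dir, "poses",
      paste0(participantId(p), ".", poseFormat)), format = poseFormat)
  writeBodyComp(cohort$bodyComp, file.path(dir, "body_comp.csv"))
  utils::write.csv(cohort$walkTrials, file.path(dir, "walk_trials.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(participants = truth,
         correlations = attr(truth, "correlations"),
         seed = cohort$config$seed),
    file.path(dir, "ground_truth.json"), digits = I(17),
    auto_unbox = TRUE)
  invisible(dir)
}
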