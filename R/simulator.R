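#' @include AllClasses.R graph.R
NULL

#' Simulator parameters
#'
#' @param gaitClass one of [gaitClasses()].
#' @param affectedSide which side carries the impairment.
#' @param severity effect size in `[0, 1]`; every class-specific deviation
#'   scales linearly with it, and at 0 all six classes produce the identical
#'   normal walk for a given seed and anthropometry.
#' @param cadenceHz stride (full gait cycle) frequency.
#' @param nFrames number of frames at 30 fps.
#' @param noiseSd additive Gaussian sensor noise, meters (0.005 is a
#'   Kinect-like jitter).
#' @param limbScale global anthropometric scale.
#' @param seed RNG seed (phase and amplitude jitter, noise).
#' @return a [GaitParams-class]
#' @export
gaitParams <- function(gaitClass = "normal", affectedSide = "left",
                       severity = 0.7, cadenceHz = 0.9, nFrames = 64L,
                       noiseSd = 0.005, limbScale = 1, seed = 1L) {
  methods::new("GaitParams",
    gaitClass = gaitClass, affectedSide = affectedSide,
    severity = as.numeric(severity), cadenceHz = as.numeric(cadenceHz),
    nFrames = as.integer(nFrames), noiseSd = as.numeric(noiseSd),
    limbScale = as.numeric(limbScale), seed = as.integer(seed)
  )
}

# rotation matrices: Rx pitches about the lateral axis, Rz rolls about the
# direction of progression. Coordinates: x lateral (left +), y up, z forward.
.rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
.rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# piecewise-linear phase warp: maps a cycle with stance duty d onto the
# nominal duty d0, compressing a shortened stance
.phase_warp <- function(u, d, d0) {
  ifelse(u < d, u * d0 / d, d0 + (u - d) * (1 - d0) / (1 - d))
}

# raised-sine bump over the stance interval [0, d0) of the warped cycle
.stance_bump <- function(u, d0) ifelse(u < d0, sin(pi * u / d0)^2, 0)

#' Simulate one walking sequence
#'
#' A stylized kinematic oscillator on the 25-joint Kinect-V2 tree: the pelvis
#' progresses forward at the stride cadence while hip/knee phase-offset
#' profiles drive the legs (knee flexion confined to the swing phase) and the
#' arms swing in anti-phase. All joints are placed by forward kinematics from
#' rigid segment vectors, so bone lengths are constant over time up to the
#' added sensor noise. Class-specific deviations, all scaled by `severity`
#' and applied to `affectedSide`:
#' \describe{
#'   \item{antalgic}{stance duty factor of the affected leg reduced
#'     (shortened weight-bearing time).}
#'   \item{lurch}{backward trunk pitch during affected stance.}
#'   \item{steppage}{amplified hip flexion and knee lift of the affected leg.}
#'   \item{stiff_legged}{affected knee flexion suppressed plus a lateral
#'     circumduction arc of the whole leg.}
#'   \item{trendelenburg}{lateral trunk (and partial pelvis) roll towards
#'     the affected side during its stance.}
#' }
#'
#' @param params a [GaitParams-class]
#' @return a [SkeletonSequence-class] (T frames, 25 joints), deterministic in
#'   `params@seed`
#' @examples
#' s <- simulateSequence(gaitParams(gaitClass = "lurch", seed = 7))
#' s
#' @export
simulateSequence <- function(params) {
  methods::validObject(params)
  .with_seed(params@seed, .simulate_sequence_impl(params))
}

.simulate_sequence_impl <- function(params) {
  s <- params@limbScale
  sev <- params@severity
  cls <- params@gaitClass
  affLeft <- params@affectedSide == "left"
  tN <- params@nFrames
  fps <- 30
  f <- params@cadenceHz

  # trial-level jitter (identical draw structure for every class)
  phase0 <- stats::runif(1)
  ampJit <- stats::runif(3, 0.95, 1.05)

  # segment lengths (meters, scaled)
  l <- list(
    spine1 = 0.26 * s, spine2 = 0.22 * s, neck = 0.06 * s, head = 0.16 * s,
    shoulderW = 0.19 * s, upperArm = 0.28 * s, foreArm = 0.26 * s,
    hand = 0.08 * s, handTip = 0.09 * s,
    hipW = 0.095 * s, hipDrop = 0.07 * s,
    thigh = 0.42 * s, shank = 0.41 * s
  )
  footVec <- c(0, -0.05, 0.14) * s
  thumbVec <- c(0.03, -0.04, 0.04) * s

  # gait profile amplitudes
  ampHip <- 0.40 * ampJit[1L]
  ampKnee <- 1.10 * ampJit[2L]
  ampArm <- 0.35 * ampJit[3L]
  d0 <- 0.60 # nominal stance duty factor
  h0 <- 0.98 * s # pelvis height
  strideLen <- 1.15 * s
  elbowFlex <- 0.35

  # class modifiers (all vanish at severity 0)
  dutyAff <- if (cls == "antalgic") d0 * (1 - 0.35 * sev) else d0
  hipGainAff <- if (cls == "steppage") 1 + 0.6 * sev else 1
  kneeGainAff <- if (cls == "steppage") 1 + 1.0 * sev else if (cls == "stiff_legged") 1 - 0.85 * sev else 1
  circAmpAff <- if (cls == "stiff_legged") 0.35 * sev else 0
  lurchAmp <- if (cls == "lurch") 0.45 * sev else 0
  rollAmp <- if (cls == "trendelenburg") 0.35 * sev else 0

  leg <- function(u, affected, sideSign) {
    d <- if (affected) dutyAff else d0
    uu <- .phase_warp(u, d, d0)
    w <- pmax(0, (uu - d0) / (1 - d0)) # swing progress
    hip <- ampHip * (if (affected) hipGainAff else 1) * cos(2 * pi * uu)
    knee <- ampKnee * (if (affected) kneeGainAff else 1) * sin(pi * w)^2
    circ <- sideSign * (if (affected) circAmpAff else 0) * sin(pi * w)^2
    list(hip = hip, knee = knee, circ = circ, uu = uu)
  }

  pos <- array(NA_real_, c(tN, 25L, 3L))
  for (t in seq_len(tN)) {
    tt <- (t - 1) / fps
    uL <- (phase0 + f * tt) %% 1
    uR <- (uL + 0.5) %% 1
    L <- leg(uL, affLeft, +1)
    R <- leg(uR, !affLeft, -1)
    uAff <- if (affLeft) L$uu else R$uu
    bump <- .stance_bump(uAff, d0)

    pitch <- -lurchAmp * bump
    roll <- (if (affLeft) -1 else +1) * rollAmp * bump
    Rt <- .rz(roll) %*% .rx(pitch) # trunk frame
    Rp <- .rz(0.4 * roll) # pelvis frame (partial drop)

    p0 <- c(
      0.02 * s * sin(2 * pi * uL + pi),
      h0 + 0.015 * s * cos(4 * pi * uL),
      strideLen * f * tt
    )

    J <- matrix(NA_real_, 25L, 3L)
    J[1L, ] <- p0 # SpineBase
    J[2L, ] <- p0 + Rt %*% c(0, l$spine1, 0) # SpineMid
    J[21L, ] <- p0 + Rt %*% c(0, l$spine1 + l$spine2, 0) # SpineShoulder
    J[3L, ] <- J[21L, ] + Rt %*% c(0, l$neck, 0) # Neck
    J[4L, ] <- J[3L, ] + Rt %*% c(0, l$head, 0) # Head

    for (side in c("L", "R")) {
      sgn <- if (side == "L") +1 else -1
      u <- if (side == "L") uL else uR
      sh <- if (side == "L") 5L else 9L # ShoulderLeft/Right
      el <- sh + 1L; wr <- sh + 2L; ha <- sh + 3L
      tip <- if (side == "L") 22L else 24L
      th <- if (side == "L") 23L else 25L
      arm <- -ampArm * cos(2 * pi * u)
      J[sh, ] <- J[21L, ] + Rt %*% c(sgn * l$shoulderW, -0.02 * s, 0)
      Ru <- Rt %*% .rx(arm)
      Rf <- Rt %*% .rx(arm + elbowFlex)
      J[el, ] <- J[sh, ] + Ru %*% c(0, -l$upperArm, 0)
      J[wr, ] <- J[el, ] + Rf %*% c(0, -l$foreArm, 0)
      J[ha, ] <- J[wr, ] + Rf %*% c(0, -l$hand, 0)
      J[tip, ] <- J[ha, ] + Rf %*% c(0, -l$handTip, 0)
      J[th, ] <- J[wr, ] + Rf %*% (thumbVec * c(sgn, 1, 1))

      hp <- if (side == "L") 13L else 17L # HipLeft/Right
      kn <- hp + 1L; an <- hp + 2L; ft <- hp + 3L
      lg <- if (side == "L") L else R
      J[hp, ] <- p0 + Rp %*% c(sgn * l$hipW, -l$hipDrop, 0)
      Rthigh <- Rp %*% .rz(lg$circ) %*% .rx(lg$hip)
      Rshank <- Rp %*% .rz(lg$circ) %*% .rx(lg$hip - lg$knee)
      J[kn, ] <- J[hp, ] + Rthigh %*% c(0, -l$thigh, 0)
      J[an, ] <- J[kn, ] + Rshank %*% c(0, -l$shank, 0)
      J[ft, ] <- J[an, ] + Rshank %*% footVec
    }
    pos[t, , ] <- J
  }
  if (params@noiseSd > 0) {
    pos <- pos + array(stats::rnorm(length(pos), sd = params@noiseSd), dim(pos))
  }
  skeletonSequence(pos,
    subjectId = "sim", classLabel = match(cls, gaitClasses()) - 1L,
    sampleId = sprintf("%s_s%d", cls, params@seed), fps = fps
  )
}

#' Simulate a multi-subject gait dataset
#'
#' Emulates a pathological-gait study design: each subject receives
#' randomized anthropometry (limb scale, cadence, amplitude habits) and an
#' affected side, then contributes `trialsPerClass` walks of every class.
#' Trials differ in starting phase, small amplitude jitter, and sensor noise.
#'
#' @param nSubjects number of subjects (at least 2)
#' @param trialsPerClass trials per subject and class
#' @param classes gait classes to include
#' @param nFrames frames per sequence
#' @param severity class-effect severity shared by all pathological trials
#' @param noiseSd sensor noise (m)
#' @param cadenceRange,limbScaleRange uniform sampling ranges of the
#'   per-subject anthropometry
#' @param seed root seed; the full dataset is deterministic in it
#' @return a [GaitDataset-class] with `nSubjects * length(classes) *
#'   trialsPerClass` sequences
#' @examples
#' ds <- simulateDataset(nSubjects = 2, trialsPerClass = 1, nFrames = 16)
#' ds
#' @export
simulateDataset <- function(nSubjects = 8L, trialsPerClass = 10L,
                            classes = gaitClasses(), nFrames = 64L,
                            severity = 0.7, noiseSd = 0.005,
                            cadenceRange = c(0.8, 1.0),
                            limbScaleRange = c(0.9, 1.1),
                            seed = 1L) {
  if (nSubjects < 2L) stop("validation error: at least 2 subjects required")
  .with_seed(seed, {
    seqs <- list()
    # affected sides are balanced across subjects (randomized order): under
    # leave-one-subject-out evaluation every training set must contain both
    # sides, otherwise held-out subjects with the minority side ask for
    # extrapolation to laterality never seen in training
    sides <- sample(rep(c("left", "right"), length.out = nSubjects))
    for (i in seq_len(nSubjects)) {
      limb <- stats::runif(1, limbScaleRange[1L], limbScaleRange[2L])
      cad <- stats::runif(1, cadenceRange[1L], cadenceRange[2L])
      side <- sides[i]
      subSeed <- sample.int(2^20, 1L)
      sid <- sprintf("S%02d", i)
      for (cls in classes) {
        for (r in seq_len(trialsPerClass)) {
          trialSeed <- subSeed + 1009L * match(cls, gaitClasses()) + r
          p <- gaitParams(
            gaitClass = cls, affectedSide = side, severity = severity,
            cadenceHz = cad, nFrames = nFrames, noiseSd = noiseSd,
            limbScale = limb, seed = trialSeed
          )
          sq <- simulateSequence(p)
          sq@subjectId <- sid
          sq@sampleId <- sprintf("%s_%s_t%02d", sid, cls, r)
          seqs[[length(seqs) + 1L]] <- sq
        }
      }
    }
    gaitDataset(seqs, classNames = gaitClasses())
  })
}

#' Class-discriminating gait statistics of a sequence
#'
#' Simple kinematic summaries used to verify that the simulator injects each
#' class signature where expected: trunk pitch/roll ranges (radians), knee
#' flexion range and foot lift per side, stance duty factors estimated from
#' foot height, and their asymmetry.
#'
#' @param seq a [SkeletonSequence-class] on the Kinect-V2 topology
#' @return named numeric vector
#' @export
gaitStatistics <- function(seq) {
  p <- seq@positions
  trunk <- p[, 21L, ] - p[, 1L, ] # SpineShoulder - SpineBase
  pitch <- atan2(trunk[, 3L], trunk[, 2L])
  roll <- atan2(trunk[, 1L], trunk[, 2L])
  kneeFlex <- function(hp, kn, an) {
    thigh <- p[, kn, ] - p[, hp, ]
    shank <- p[, an, ] - p[, kn, ]
    cosang <- rowSums(thigh * shank) /
      (sqrt(rowSums(thigh^2)) * sqrt(rowSums(shank^2)))
    acos(pmin(pmax(cosang, -1), 1))
  }
  kfL <- kneeFlex(13L, 14L, 15L)
  kfR <- kneeFlex(17L, 18L, 19L)
  # stance fraction estimated from the knee-flexion phase: the knee is near
  # extension throughout stance and flexes only in swing
  duty <- function(kf) {
    mean(kf < min(kf) + 0.25 * (max(kf) - min(kf)))
  }
  c(
    trunkPitchRange = diff(range(pitch)),
    trunkRollRange = diff(range(roll)),
    kneeFlexRangeL = diff(range(kfL)),
    kneeFlexRangeR = diff(range(kfR)),
    footLiftL = diff(range(p[, 16L, 2L])),
    footLiftR = diff(range(p[, 20L, 2L])),
    dutyL = duty(kfL),
    dutyR = duty(kfR),
    dutyAsymmetry = abs(duty(kfL) - duty(kfR))
  )
}
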