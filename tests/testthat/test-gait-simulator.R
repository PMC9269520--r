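test_that("simulation is deterministic and class effects vanish at severity zero", {
  p <- gaitParams(gaitClass = "lurch", severity = 0.6, seed = 42)
  s1 <- simulateSequence(p)
  s2 <- simulateSequence(p)
  expect_identical(positions(s1), positions(s2))

  # severity 0, no noise: every class collapses onto the same normal walk
  base <- simulateSequence(gaitParams(gaitClass = "normal", severity = 0,
                                      noiseSd = 0, seed = 7))
  for (cls in gaitClasses()[-1]) {
    s <- simulateSequence(gaitParams(gaitClass = cls, severity = 0,
                                     noiseSd = 0, seed = 7))
    expect_equal(positions(s), positions(base), tolerance = 1e-12)
  }
})

test_that("bone lengths are constant over time without sensor noise", {
  g <- kinectV2Graph()
  p <- parentOf(g)
  for (cls in c("normal", "stiff_legged", "trendelenburg")) {
    s <- simulateSequence(gaitParams(gaitClass = cls, noiseSd = 0, seed = 3))
    pos <- positions(s)
    for (j in which(!is.na(p))) {
      len <- sqrt(rowSums((pos[, j, ] - pos[, p[j], ])^2))
      expect_lt(diff(range(len)), 1e-6)
    }
  }
})

test_that("each class injects its signature where expected", {
  stat <- function(cls, sev, seed = 5) {
    gaitStatistics(simulateSequence(gaitParams(
      gaitClass = cls, severity = sev, noiseSd = 0, seed = seed
    )))
  }
  s0 <- stat("normal", 0.7)
  expect_gt(stat("lurch", 0.7)["trunkPitchRange"], s0["trunkPitchRange"] + 0.1)
  expect_gt(stat("trendelenburg", 0.7)["trunkRollRange"], s0["trunkRollRange"] + 0.1)
  expect_gt(max(stat("steppage", 0.7)[c("footLiftL", "footLiftR")]),
            max(s0[c("footLiftL", "footLiftR")]) + 0.03)
  expect_lt(min(stat("stiff_legged", 0.7)[c("kneeFlexRangeL", "kneeFlexRangeR")]),
            min(s0[c("kneeFlexRangeL", "kneeFlexRangeR")]) - 0.2)
  expect_gt(stat("antalgic", 0.7)["dutyAsymmetry"], s0["dutyAsymmetry"] + 0.05)
})

test_that("class-defining statistics are monotone in severity", {
  sevs <- c(0.2, 0.5, 0.9)
  pick <- list(
    antalgic = function(st) st["dutyAsymmetry"],
    lurch = function(st) st["trunkPitchRange"],
    steppage = function(st) max(st[c("footLiftL", "footLiftR")]),
    stiff_legged = function(st) -min(st[c("kneeFlexRangeL", "kneeFlexRangeR")]),
    trendelenburg = function(st) st["trunkRollRange"]
  )
  for (cls in names(pick)) {
    vals <- vapply(sevs, function(sv) {
      unname(pick[[cls]](gaitStatistics(simulateSequence(
        gaitParams(gaitClass = cls, severity = sv, noiseSd = 0, seed = 11)
      ))))
    }, numeric(1))
    expect_true(all(diff(vals) > 0),
                info = sprintf("%s: %s", cls, paste(round(vals, 3), collapse = " ")))
  }
})

test_that("datasets have the designed size, balance, and determinism", {
  ds <- simulateDataset(nSubjects = 3, trialsPerClass = 2, nFrames = 16, seed = 4)
  expect_equal(length(ds), 3 * 6 * 2)
  labs <- vapply(ds@sequences, classLabel, integer(1))
  subj <- vapply(ds@sequences, subjectId, character(1))
  counts <- table(subj, labs)
  expect_true(all(counts == 2))
  # determinism of the whole dataset
  ds2 <- simulateDataset(nSubjects = 3, trialsPerClass = 2, nFrames = 16, seed = 4)
  expect_identical(positions(ds[[10]]), positions(ds2[[10]]))
  # per-subject anthropometry differs
  expect_false(isTRUE(all.equal(positions(ds[[1]]), positions(ds[[13]]))))
  expect_error(simulateDataset(nSubjects = 1), "at least 2")
})

test_that("lurch samples pitch the trunk more than normal samples at high severity", {
  ds <- simulateDataset(nSubjects = 3, trialsPerClass = 3, nFrames = 32,
                        severity = 0.8, seed = 10)
  labs <- vapply(ds@sequences, classLabel, integer(1))
  pitch <- vapply(ds@sequences, function(s) gaitStatistics(s)["trunkPitchRange"],
                  numeric(1))
  lurchLab <- match("lurch", gaitClasses()) - 1L
  expect_gt(mean(pitch[labs == lurchLab]), mean(pitch[labs == 0]))
})

test_that("invalid simulator parameters are rejected", {
  expect_error(gaitParams(gaitClass = "limp"), "unknown gait class")
  expect_error(gaitParams(severity = 1.5), "severity")
  expect_error(gaitParams(nFrames = 1), "nFrames")
})
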