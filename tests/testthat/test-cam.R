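# a tiny trained-ish model shared by the CAM tests (weights random; CAM is a
# deterministic function of weights and features, so training is not needed
# for the algebraic properties)
camModel <- function() {
  cfg <- modelConfig(
    branchChannels = c(4L, 4L, 4L, 4L), mainChannels = c(6L, 8L),
    blockDepth = 1L, temporalKernel = 3L, attentionReduction = 2L,
    numClasses = 6L, seed = 31L
  )
  buildMIBNetwork(cfg, kinectV2Graph())
}

test_that("activation maps are normalized, nonnegative saliency", {
  model <- camModel()
  s <- simulateSequence(gaitParams(gaitClass = "lurch", nFrames = 16, seed = 2))
  map <- skeletonCAM(model, s, targetClass = 2L)
  expect_s4_class(map, "ActivationMap")
  expect_true(all(map@values >= 0))
  expect_equal(sum(map@values), 1, tolerance = 1e-9)
  expect_equal(ncol(map@values), 25L)
  expect_equal(nrow(map@values), 4L) # 16 frames / two stride-2 layers
  expect_error(skeletonCAM(model, s, targetClass = 9L), "targetClass")
})

test_that("the map matches an explicit channel-loop oracle", {
  model <- camModel()
  s <- simulateSequence(gaitParams(gaitClass = "steppage", nFrames = 16, seed = 5))
  target <- 3L
  map <- skeletonCAM(model, s, targetClass = target)
  # oracle: walk the channels of the final feature map one by one
  bf <- assembleBranches(s, model@graph)
  tN <- dim(bf@joint)[2L]
  xl <- list(
    joint = array(bf@joint, c(6L, tN, 1L, 25L)),
    velocity = array(bf@velocity, c(6L, tN, 1L, 25L)),
    bone = array(bf@bone, c(6L, tN, 1L, 25L))
  )
  options(stgait.engine = "ref")
  fwd <- stgait:::.net_forward(model, xl, train = FALSE, collectFeatures = TRUE)
  options(stgait.engine = "cpp")
  Fmap <- fwd$features # C x T' x 1 x V
  w <- model@params[["fc.W"]][, target + 1L]
  M <- matrix(0, dim(Fmap)[2L], dim(Fmap)[4L])
  for (c in seq_along(w)) {
    M <- M + w[c] * Fmap[c, , 1L, ]
  }
  M <- pmax(M, 0)
  M <- M / sum(M)
  expect_lt(max(abs(map@values - M)), 1e-6)
})

test_that("CAM is invariant to positive weight rescaling and bias shifts", {
  model <- camModel()
  s <- simulateSequence(gaitParams(gaitClass = "normal", nFrames = 16, seed = 7))
  # an untrained head can rectify a class map to zero, in which case the
  # documented uniform fallback fires (with a warning) on both sides and
  # invariance still holds
  m1 <- suppressWarnings(skeletonCAM(model, s, targetClass = 0L))
  model2 <- model
  model2@params[["fc.W"]] <- model2@params[["fc.W"]] * 2
  model2@params[["fc.b"]] <- model2@params[["fc.b"]] + 3
  m2 <- suppressWarnings(skeletonCAM(model2, s, targetClass = 0L))
  expect_lt(max(abs(m1@values - m2@values)), 1e-9)
})

test_that("uniform feature importance spreads evenly and mass is conserved", {
  vals <- matrix(1 / (4 * 25), 4, 25)
  map <- methods::new("ActivationMap", values = vals, classQueried = 0L,
                      sampleId = "u")
  ji <- jointImportance(map)
  expect_equal(ji, rep(1 / 25, 25), tolerance = 1e-12)
  expect_equal(sum(ji), 1, tolerance = 1e-12)
  # upsampling to the input frame grid preserves total mass
  up <- upsampleActivationMap(map, 16L)
  expect_equal(dim(up), c(16L, 25L))
  expect_equal(sum(up), 1, tolerance = 1e-9)
})

test_that("joint importance of a real map sums to one", {
  model <- camModel()
  s <- simulateSequence(gaitParams(gaitClass = "trendelenburg", nFrames = 16, seed = 9))
  map <- skeletonCAM(model, s, targetClass = 5L)
  expect_equal(sum(jointImportance(map)), 1, tolerance = 1e-9)
})

test_that("activation maps export to CSV and render to PNG", {
  model <- camModel()
  s <- simulateSequence(gaitParams(gaitClass = "lurch", nFrames = 16, seed = 3))
  map <- skeletonCAM(model, s, targetClass = 2L)
  csv <- withr::local_tempfile(fileext = ".csv")
  exportActivationCSV(map, csv, model@graph)
  df <- read.csv(csv)
  expect_named(df, c("frame", "joint", "weight"))
  expect_equal(nrow(df), nrow(map@values) * 25L)
  expect_equal(sum(df$weight), 1, tolerance = 1e-9)
  png <- withr::local_tempfile(fileext = ".png")
  plotActivationMap(map, s, model@graph, png)
  expect_true(file.exists(png) && file.size(png) > 0)
})
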