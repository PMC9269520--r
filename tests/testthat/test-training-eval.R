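test_that("leave-one-subject-out folds partition the data without leakage", {
  ds <- simulateDataset(nSubjects = 4, trialsPerClass = 1, nFrames = 8, seed = 2)
  folds <- losoSplits(ds)
  expect_length(folds, 4L)
  allTest <- unlist(lapply(folds, `[[`, "testIds"))
  ids <- vapply(ds@sequences, sampleId, character(1))
  expect_setequal(allTest, ids)
  expect_equal(anyDuplicated(allTest), 0L)
  subj <- vapply(ds@sequences, subjectId, character(1))
  for (f in folds) {
    expect_length(intersect(subj[f$trainIdx], subj[f$testIdx]), 0L)
    expect_setequal(subj[f$testIdx], f$heldOutSubject)
  }
  one <- gaitDataset(ds@sequences[subj == "S01"])
  expect_error(losoSplits(one), "at least 2")
})

test_that("evaluation reports are internally consistent", {
  # perfect predictions: identity confusion, accuracy 1
  r <- stgait:::.eval_report(c(0L, 1L, 2L), c(0L, 1L, 2L), 3L)
  expect_equal(accuracy(r), 1)
  expect_equal(unname(diag(confusion(r))), c(1L, 1L, 1L))
  # confusion row sums equal per-class test counts; accuracy = trace / total
  set.seed(4)
  truth <- sample(0:5, 300, replace = TRUE)
  pred <- sample(0:5, 300, replace = TRUE)
  r2 <- stgait:::.eval_report(pred, truth, 6L)
  expect_equal(unname(rowSums(confusion(r2))), unname(as.vector(table(factor(truth, 0:5)))))
  expect_equal(accuracy(r2), sum(diag(confusion(r2))) / 300)
})

test_that("a uniformly random six-class predictor scores near chance", {
  # binomial check on the bookkeeping path with balanced truth
  set.seed(9)
  truth <- rep(0:5, each = 80)
  accs <- replicate(20, {
    accuracy(stgait:::.eval_report(sample(0:5, 480, replace = TRUE), truth, 6L))
  })
  p <- 1 / 6
  expect_lt(abs(mean(accs) - p), 3 * sqrt(p * (1 - p) / 480) / sqrt(20))
})

test_that("training is deterministic and reduces the loss", {
  ds <- simulateDataset(nSubjects = 2, trialsPerClass = 2, nFrames = 16, seed = 3)
  g <- kinectV2Graph()
  prep <- prepareBranchData(ds, g)
  cfg <- modelConfig(branchChannels = c(4L, 4L, 4L, 4L), mainChannels = c(6L, 8L),
                     blockDepth = 1L, temporalKernel = 3L, attentionReduction = 2L,
                     numClasses = 6L, seed = 2L)
  m1 <- buildMIBNetwork(cfg, g)
  f1 <- trainModel(m1, prep, epochs = 3, lr = 0.02, batchSize = 8, seed = 5)
  f2 <- trainModel(buildMIBNetwork(cfg, g), prep, epochs = 3, lr = 0.02,
                   batchSize = 8, seed = 5)
  expect_identical(f1$model@params, f2$model@params)
  expect_identical(f1$history, f2$history)
  expect_lte(tail(f1$history$loss, 1), f1$history$loss[1])
  # different shuffling seed changes the outcome
  f3 <- trainModel(buildMIBNetwork(cfg, g), prep, epochs = 3, lr = 0.02,
                   batchSize = 8, seed = 6)
  expect_false(identical(f1$model@params, f3$model@params))
})

test_that("a small model can memorize a tiny dataset", {
  ds <- simulateDataset(nSubjects = 2, trialsPerClass = 1, nFrames = 24,
                        classes = c("normal", "lurch", "trendelenburg"),
                        noiseSd = 0, seed = 8)
  g <- kinectV2Graph()
  prep <- prepareBranchData(ds, g)
  prep$labels <- match(prep$labels, sort(unique(prep$labels))) - 1L
  cfg <- modelConfig(branchChannels = c(6L, 6L, 6L, 6L), mainChannels = c(8L, 12L),
                     blockDepth = 1L, temporalKernel = 3L, attentionReduction = 3L,
                     numClasses = 3L, seed = 4L)
  fit <- trainModel(buildMIBNetwork(cfg, g), prep, epochs = 30, lr = 0.02,
                    batchSize = 6, seed = 1)
  rep <- evaluateModel(fit$model, prep)
  expect_gte(accuracy(rep), 0.99)
})

test_that("branch-ablated models drop the branch from the architecture", {
  g <- kinectV2Graph()
  cfg <- modelConfig(branchChannels = c(4L, 4L, 4L, 4L), mainChannels = c(6L, 8L),
                     blockDepth = 1L, temporalKernel = 3L, attentionReduction = 2L,
                     numClasses = 6L, seed = 1L)
  m <- buildMIBNetwork(cfg, g, branches = "bone")
  expect_false(any(grepl("^joint\\.", names(m@params))))
  expect_false(any(grepl("^velocity\\.", names(m@params))))
  expect_lt(countParameters(m)$total,
            countParameters(buildMIBNetwork(cfg, g))$total)
  expect_error(buildMIBNetwork(cfg, g, branches = character(0)), "branch")
})

test_that("out-of-range labels are rejected at training and evaluation", {
  ds <- simulateDataset(nSubjects = 2, trialsPerClass = 1, nFrames = 8, seed = 1)
  g <- kinectV2Graph()
  prep <- prepareBranchData(ds, g)
  cfg <- modelConfig(branchChannels = c(4L, 4L, 4L, 4L), mainChannels = c(6L, 8L),
                     blockDepth = 1L, temporalKernel = 3L, attentionReduction = 2L,
                     numClasses = 3L, seed = 1L) # labels 3..5 fall outside
  m <- buildMIBNetwork(cfg, g)
  expect_error(trainModel(m, prep, epochs = 1), "labels")
  expect_error(evaluateModel(m, prep), "label")
})
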