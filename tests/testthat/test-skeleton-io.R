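test_that("the NTU skeleton dialect parses with exact coordinates", {
  set.seed(3)
  frames <- list(matrix(rnorm(75), 25, 3), matrix(rnorm(75), 25, 3))
  path <- withr::local_tempfile(fileext = ".skeleton")
  writeNTUFixture(path, frames)
  s <- readNTUSkeleton(path)
  expect_equal(numFrames(s), 2L)
  expect_equal(dim(positions(s)), c(2L, 25L, 3L))
  expect_equal(positions(s)[1, , ], frames[[1]], tolerance = 1e-6)
  expect_equal(positions(s)[2, , ], frames[[2]], tolerance = 1e-6)
})

test_that("NTU filenames provide subject and class metadata", {
  frames <- list(matrix(0.1, 25, 3), matrix(0.2, 25, 3))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "S001C002P007R001A043.skeleton")
  writeNTUFixture(path, frames)
  s <- readNTUSkeleton(path)
  expect_equal(subjectId(s), "P007")
  expect_equal(classLabel(s), 42L) # 0-based: action 43 -> 42
})

test_that("malformed skeleton files raise parse errors that name the frame", {
  frames <- list(matrix(0.1, 25, 3), matrix(0.2, 25, 3))
  path <- withr::local_tempfile(fileext = ".skeleton")
  writeNTUFixture(path, frames)
  lines <- readLines(path)

  # declared joint count of 24 in frame 1
  bad <- lines
  bad[4] <- "24"
  p1 <- withr::local_tempfile(lines = bad)
  expect_error(readNTUSkeleton(p1), "frame 1 declares 24 joints")

  # truncated file
  p2 <- withr::local_tempfile(lines = lines[1:10])
  expect_error(readNTUSkeleton(p2), "parse error")

  # zero bodies everywhere
  p3 <- withr::local_tempfile(lines = c("2", "0", "0"))
  expect_error(readNTUSkeleton(p3), "empty-sequence")
})

test_that("multi-body frames keep the best-tracked body and gaps are filled", {
  # two bodies: body 2 gets a higher tracking confidence via its joint states
  f1 <- matrix(1, 25, 3)
  f2 <- matrix(2, 25, 3)
  lines <- c("2",
    # frame 1: two bodies; second body has trackingState 2 vs 1
    "2",
    paste(c(1001, rep(0, 8), 2), collapse = " "), "25",
    replicate(25, paste(c(sprintf("%.4f", f1[1, ]), rep("0", 8), "1"), collapse = " ")),
    paste(c(1002, rep(0, 8), 2), collapse = " "), "25",
    replicate(25, paste(c(sprintf("%.4f", f2[1, ]), rep("0", 8), "2"), collapse = " ")),
    # frame 2: no bodies -> repeat the last observed frame
    "0"
  )
  path <- withr::local_tempfile(lines = unlist(lines))
  expect_warning(s <- readNTUSkeleton(path), "without a tracked body")
  expect_equal(positions(s)[1, 1, 1], 2) # best-tracked body kept
  expect_equal(positions(s)[2, , ], positions(s)[1, , ]) # gap filled
})

test_that("the sequence container round-trips bit-identically", {
  set.seed(11)
  seqs <- lapply(1:3, function(i) {
    skeletonSequence(array(rnorm(4 * 25 * 3), c(4, 25, 3)),
      subjectId = paste0("S", i), classLabel = i - 1L,
      sampleId = paste0("sample", i), fps = 30
    )
  })
  ds <- gaitDataset(seqs)
  path <- withr::local_tempfile(fileext = ".rds")
  writeSkeletonContainer(ds, path)
  ds2 <- readSkeletonContainer(path)
  expect_equal(length(ds2), 3L)
  for (i in 1:3) {
    expect_identical(positions(ds2[[i]]), positions(ds[[i]]))
    expect_identical(classLabel(ds2[[i]]), classLabel(ds[[i]]))
    expect_identical(subjectId(ds2[[i]]), subjectId(ds[[i]]))
    expect_identical(frameRate(ds2[[i]]), frameRate(ds[[i]]))
  }
  # cached features round-trip too
  g <- kinectV2Graph()
  feats <- list(sample1 = assembleBranches(seqs[[1]], g))
  writeSkeletonContainer(ds, path, features = feats)
  ds3 <- readSkeletonContainer(path)
  expect_identical(attr(ds3, "features")$sample1@joint, feats$sample1@joint)
})

test_that("resampling preserves endpoints, interpolates linearly, and is idempotent", {
  set.seed(5)
  s <- randomSequence(6, 4)
  expect_identical(resampleSequence(s, 6), s) # identity at equal length

  # two frames to three: middle frame is the average
  s2 <- randomSequence(2, 3)
  r <- resampleSequence(s2, 3)
  expect_equal(positions(r)[1, , ], positions(s2)[1, , ])
  expect_equal(positions(r)[3, , ], positions(s2)[2, , ])
  expect_equal(positions(r)[2, , ], (positions(s2)[1, , ] + positions(s2)[2, , ]) / 2)

  # constant sequences stay constant
  sc <- skeletonSequence(array(1.5, c(5, 3, 3)))
  expect_true(all(positions(resampleSequence(sc, 9)) == 1.5))

  # idempotence at a fixed target
  r1 <- resampleSequence(s, 11)
  r2 <- resampleSequence(r1, 11)
  expect_lt(max(abs(positions(r1) - positions(r2))), 1e-12)

  expect_error(resampleSequence(s, 1), "at least 2")
})

test_that("CSV export writes one row per frame and joint", {
  s <- randomSequence(3, 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  exportSequenceCSV(s, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 12L)
  expect_named(df, c("frame", "joint", "x", "y", "z"))
  expect_equal(df$x[df$frame == 2 & df$joint == "J1"], positions(s)[2, 2, 1])
})
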