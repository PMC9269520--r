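test_that("relative coordinates subtract the center joint per frame", {
  pos <- array(0, c(2, 3, 3))
  pos[1, 1, ] <- c(1, 2, 3)
  pos[1, 2, ] <- c(1, 0, 0) # center
  s <- skeletonSequence(pos)
  r <- relativeCoordinates(s, 2L)
  expect_equal(r[1, 1, ], c(0, 2, 3))
  expect_true(all(r[, 2, ] == 0)) # center row is exactly zero

  # translation invariance
  s2 <- skeletonSequence(pos + 5)
  expect_identical(relativeCoordinates(s2, 2L), r)
  expect_error(relativeCoordinates(s, 9L), "out of range")
})

test_that("velocities follow one- and two-frame displacements with zero-padded tails", {
  # linear motion: v1 = d, v2 = 2d on all defined frames
  d <- c(0.1, -0.2, 0.3)
  pos <- array(0, c(5, 2, 3))
  for (t in 1:5) pos[t, , ] <- matrix(rep((t - 1) * d, each = 2), 2, 3)
  v <- motionVelocity(skeletonSequence(pos))
  for (t in 1:4) expect_equal(v$v1[t, 1, ], d)
  for (t in 1:3) expect_equal(v$v2[t, 1, ], 2 * d)
  expect_true(all(v$v1[5, , ] == 0))
  expect_true(all(v$v2[4:5, , ] == 0))

  # constant sequence: everything zero
  vc <- motionVelocity(skeletonSequence(array(2, c(4, 2, 3))))
  expect_true(all(vc$v1 == 0) && all(vc$v2 == 0))

  # T = 2: v2 has no defined frame at all
  v2 <- motionVelocity(randomSequence(2, 3, seed = 1))
  expect_true(all(v2$v2 == 0))
})

test_that("bone vectors and angles follow the tree orientation", {
  g <- skeletonGraph(rbind(c(1, 2)), centerJoint = 1)
  pos <- array(0, c(2, 2, 3))
  pos[, 2, 1] <- 1 # child at (1,0,0), parent at origin
  b <- boneFeatures(skeletonSequence(pos), g)
  expect_equal(b$b[1, 2, ], c(1, 0, 0))
  expect_equal(b$a[1, 2, ], c(0, pi / 2, pi / 2))
  # the root bone is zero with neutral angles
  expect_true(all(b$b[, 1, ] == 0))
  expect_true(all(b$a[, 1, ] == pi / 2))
})

test_that("bone vectors telescope from root to leaf", {
  g <- kinectV2Graph()
  s <- randomSequence(4, 25, seed = 8)
  b <- boneFeatures(s, g)
  # path from the center to the left foot tip
  p <- parentOf(g)
  leaf <- 16L # FootLeft
  path <- leaf
  while (!is.na(p[path[1]])) path <- c(p[path[1]], path)
  acc <- array(0, c(4, 3))
  for (j in path[-1]) acc <- acc + b$b[, j, ]
  expect_equal(acc, positions(s)[, leaf, ] - positions(s)[, centerJoint(g), ],
               tolerance = 1e-12)
})

test_that("bone angle cosines have unit norm and angles lie in [0, pi]", {
  g <- kinectV2Graph()
  s <- randomSequence(5, 25, seed = 13)
  b <- boneFeatures(s, g)
  expect_true(all(b$a >= 0 & b$a <= pi))
  # for joints with a parent: sum of squared direction cosines is 1
  hasParent <- which(!is.na(parentOf(g)))
  cs <- cos(b$a[, hasParent, , drop = FALSE])
  expect_lt(max(abs(apply(cs^2, c(1, 2), sum) - 1)), 1e-9)
})

test_that("positions are recoverable from the root trajectory and bones", {
  g <- kinectV2Graph()
  s <- randomSequence(6, 25, seed = 21)
  b <- boneFeatures(s, g)
  rec <- reconstructFromBones(positions(s)[, centerJoint(g), ], b$b, g)
  expect_lt(max(abs(rec - positions(s))), 1e-9)
})

test_that("assembled branches have the contracted shapes and invariances", {
  g <- kinectV2Graph()
  s <- randomSequence(7, 25, seed = 2)
  bf <- assembleBranches(s, g)
  expect_equal(dim(bf@joint), c(6L, 7L, 25L))
  expect_equal(dim(bf@velocity), c(6L, 7L, 25L))
  expect_equal(dim(bf@bone), c(6L, 7L, 25L))
  # center-joint relative channels are zero
  expect_true(all(bf@joint[4:6, , centerJoint(g)] == 0))

  # constant sequence: zero velocity, frame-constant joint and bone streams
  sc <- skeletonSequence(array(rep(rnorm(25 * 3), each = 4), c(4, 25, 3)))
  bfc <- assembleBranches(sc, g)
  expect_true(all(bfc@velocity == 0))
  expect_lt(max(abs(sweep(bfc@joint, c(1, 3), bfc@joint[, 1, ]))), 1e-12)
  expect_lt(max(abs(sweep(bfc@bone, c(1, 3), bfc@bone[, 1, ]))), 1e-12)

  # whole-skeleton translation shifts only the absolute joint channels
  # (differences of shifted coordinates agree to the last floating-point ulp)
  s2 <- skeletonSequence(sweep(positions(s), 3, c(1, -2, 3), "+"))
  bf2 <- assembleBranches(s2, g)
  expect_false(isTRUE(all.equal(bf2@joint[1:3, , ], bf@joint[1:3, , ])))
  expect_equal(bf2@joint[4:6, , ], bf@joint[4:6, , ], tolerance = 1e-12)
  expect_equal(bf2@velocity, bf@velocity, tolerance = 1e-12)
  expect_equal(bf2@bone, bf@bone, tolerance = 1e-12)
})
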