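test_that("adjacency construction matches the edge set", {
  g2 <- skeletonGraph(rbind(c(1, 2)), centerJoint = 1)
  expect_equal(unname(adjacencyFromEdges(g2)), matrix(c(0, 1, 1, 0), 2))

  g0 <- skeletonGraph(matrix(integer(), ncol = 2), numJoints = 3, centerJoint = 1)
  expect_equal(unname(adjacencyFromEdges(g0)), matrix(0, 3, 3))

  A <- adjacencyFromEdges(kinectV2Graph())
  expect_equal(sum(A != 0), 48) # 2 * (V - 1) for the 25-joint tree
  expect_true(all(diag(A) == 0))
  expect_equal(A, t(A))
})

test_that("edge indices out of range raise a topology error", {
  expect_error(skeletonGraph(rbind(c(1, 5)), numJoints = 3), "out of range")
})

test_that("normalized adjacency matches closed forms and the brute-force oracle", {
  # single node: A~ = [1], D~ = [1]
  expect_equal(normalizeAdjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  # two connected nodes: all degrees 2, every entry 1/2
  expect_equal(normalizeAdjacency(matrix(c(0, 1, 1, 0), 2)), matrix(0.5, 2, 2))
  # path 0-1-2: degrees 2,3,2 after self-loops; entry [1,2] = 1/sqrt(6)
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  N <- normalizeAdjacency(P)
  expect_equal(N[1, 2], 1 / sqrt(6))
  expect_lt(max(abs(N - bruteNormalizeAdjacency(P))), 1e-12)

  # random symmetric binary matrices against the brute-force oracle
  set.seed(101)
  for (i in 1:25) {
    v <- sample(2:25, 1)
    A <- matrix(rbinom(v * v, 1, 0.3), v, v)
    A <- 1 * ((A + t(A)) > 0)
    diag(A) <- 0
    expect_lt(max(abs(normalizeAdjacency(A) - bruteNormalizeAdjacency(A))), 1e-10)
  }

  expect_error(normalizeAdjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("normalized adjacency has unit spectral radius and entries in [0,1]", {
  set.seed(7)
  for (i in 1:5) {
    g <- randomTree(sample(3:25, 1))
    N <- normalizeAdjacency(adjacencyFromEdges(g))
    expect_true(all(N >= 0 & N <= 1))
    expect_lt(abs(max(eigen(N, symmetric = TRUE, only.values = TRUE)$values) - 1), 1e-9)
  }
})

test_that("uni-label partitioning reduces to the normalized adjacency", {
  g <- tinyGraph()
  adj <- partitionAdjacency(g, "uni-label")
  expect_length(partitions(adj), 1)
  expect_equal(partitions(adj)[[1]],
               normalizeAdjacency(adjacencyFromEdges(g)))
})

test_that("spatial-configuration partitioning follows hop distances to the center", {
  # 3-joint chain centered at joint 1 (0-based: center 0)
  g <- skeletonGraph(rbind(c(1, 2), c(2, 3)), centerJoint = 1)
  A <- adjacencyFromEdges(g)
  hops <- bruteHops(A, 1)
  expect_equal(hopDistances(g), hops)
  adj <- partitionAdjacency(g, "spatial-configuration")
  parts <- partitions(adj)
  expect_length(parts, 3)
  # self partition: only diagonal entries
  expect_true(all(parts[[1]][row(parts[[1]]) != col(parts[[1]])] == 0))
  expect_true(all(diag(parts[[1]]) > 0))
  # connection 2->1 heads towards the center (centripetal), 2->3 away
  expect_gt(parts[[2]][2, 1], 0)
  expect_equal(parts[[3]][2, 1], 0)
  expect_gt(parts[[3]][2, 3], 0)
  expect_equal(parts[[2]][2, 3], 0)
})

test_that("partition supports tile the augmented adjacency for every strategy", {
  set.seed(42)
  for (i in 1:15) {
    g <- randomTree(sample(3:25, 1), center = 1L)
    At <- adjacencyFromEdges(g) + diag(numJoints(g))
    for (strat in c("uni-label", "distance", "spatial-configuration")) {
      adj <- partitionAdjacency(g, strat)
      supp <- Reduce(`+`, lapply(partitions(adj), function(P) 1 * (P != 0)))
      expect_equal(unname(supp > 0), unname(At > 0))
      expect_true(all(supp <= 1)) # no connection claimed twice
    }
  }
})

test_that("unknown strategies are rejected", {
  expect_error(partitionAdjacency(tinyGraph(), "banana"))
})

test_that("joint relabeling permutes the normalized adjacency as P A P'", {
  set.seed(9)
  for (i in 1:10) {
    v <- sample(3:25, 1)
    g <- randomTree(v)
    perm <- sample.int(v)
    g2 <- stgait:::.permute_graph(g, perm)
    N1 <- normalizeAdjacency(adjacencyFromEdges(g))
    N2 <- normalizeAdjacency(adjacencyFromEdges(g2))
    P <- diag(v)[perm, , drop = FALSE] # P[perm[i], i] = 1
    expect_lt(max(abs(unname(N2) - unname(t(P) %*% N1 %*% P))), 1e-12)
  }
})

test_that("graph files round-trip through the edge-list format", {
  g <- kinectV2Graph()
  path <- withr::local_tempfile(fileext = ".txt")
  writeGraphFile(g, path)
  g2 <- readGraphFile(path)
  expect_equal(numJoints(g2), 25L)
  expect_equal(centerJoint(g2), centerJoint(g))
  expect_equal(adjacencyFromEdges(g2)[, ], adjacencyFromEdges(g)[, ],
               ignore_attr = TRUE)
  expect_error(readGraphFile(withr::local_tempfile(lines = "nonsense")), "header")
})

test_that("tree orientation roots at the center joint", {
  g <- kinectV2Graph()
  p <- parentOf(g)
  expect_true(is.na(p[centerJoint(g)]))
  expect_equal(sum(is.na(p)), 1L)
  # walking up from any joint reaches the center
  for (j in seq_len(25)) {
    cur <- j
    for (step in 1:25) {
      if (cur == centerJoint(g)) break
      cur <- p[cur]
    }
    expect_equal(cur, centerJoint(g))
  }
})
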