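# Shared fixtures, all generated in code.

# a small labeled tree graph: 0-1-2 chain plus a branch 1-3 (1-based indices)
tinyGraph <- function() {
  skeletonGraph(rbind(c(1, 2), c(2, 3), c(2, 4)), centerJoint = 2)
}

# random connected tree on v joints (Pruefer-free: attach each node to a
# random earlier node)
randomTree <- function(v, center = 1L) {
  edges <- cbind(2:v, vapply(2:v, function(i) sample.int(i - 1L, 1L), integer(1)))
  skeletonGraph(edges, numJoints = v, centerJoint = center)
}

# random skeleton sequence on a given graph
randomSequence <- function(tN, v, seed = NULL, fps = 30) {
  if (!is.null(seed)) set.seed(seed)
  skeletonSequence(array(rnorm(tN * v * 3), c(tN, v, 3)), fps = fps)
}

# brute-force symmetric normalized adjacency, written independently of the
# package implementation: explicit matrix products
bruteNormalizeAdjacency <- function(A) {
  At <- A + diag(nrow(A))
  D <- diag(rowSums(At))
  Dh <- diag(1 / sqrt(diag(D)))
  Dh %*% At %*% Dh
}

# hop distances by plain breadth-first search over an adjacency matrix
bruteHops <- function(A, start) {
  v <- nrow(A)
  dist <- rep(NA_integer_, v)
  dist[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- integer()
    for (f in frontier) {
      for (j in which(A[f, ] > 0)) {
        if (is.na(dist[j])) {
          dist[j] <- dist[f] + 1L
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# write an NTU-dialect .skeleton file; joints is a list of T matrices (25x3)
writeNTUFixture <- function(path, joints, bodiesPerFrame = 1L,
                            jointCount = 25L) {
  lines <- c(as.character(length(joints)))
  for (fr in joints) {
    lines <- c(lines, as.character(bodiesPerFrame))
    for (b in seq_len(bodiesPerFrame)) {
      lines <- c(lines, paste(c(1000 + b, rep(0, 8), 2), collapse = " "))
      lines <- c(lines, as.character(jointCount))
      for (j in seq_len(nrow(fr))) {
        # x y z depthX depthY colorX colorY qw qx qy qz trackingState
        lines <- c(lines, paste(
          c(sprintf("%.6f", fr[j, ]), rep("0", 8), "2"),
          collapse = " "
        ))
      }
    }
  }
  writeLines(lines, path)
  path
}

# tiny network configuration used across model tests
tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(
      branchChannels = c(4L, 4L, 4L, 4L), mainChannels = c(6L, 8L),
      blockDepth = 2L, temporalKernel = 3L, attentionReduction = 2L,
      numClasses = 3L, seed = 5L
    ),
    list(...)
  )
  do.call(modelConfig, args)
}

randomBranchInputs <- function(tN, n, v, seed = 1) {
  set.seed(seed)
  list(
    joint = array(rnorm(6 * tN * n * v), c(6, tN, n, v)),
    velocity = array(rnorm(6 * tN * n * v), c(6, tN, n, v)),
    bone = array(rnorm(6 * tN * n * v), c(6, tN, n, v))
  )
}
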