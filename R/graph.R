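#' @include AllClasses.R
NULL

#' The 25-joint Kinect-V2 skeleton graph
#'
#' The standard Kinect V2 SDK joint set (0-based indices in parentheses):
#' SpineBase (0) ... ThumbRight (24), connected as the usual 24-bone tree and
#' rooted at SpineMid, which also serves as the center joint for relative
#' coordinates and spatial partitioning.
#'
#' @return a [SkeletonGraph-class] with 25 joints.
#' @examples
#' g <- kinectV2Graph()
#' sum(adjacencyFromEdges(g) != 0) # 48 = 2 * 24 directed entries
#' @export
kinectV2Graph <- function() {
  names <- c(
    "SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight"
  )
  # 0-based bone list of the Kinect V2 SDK
  e0 <- rbind(
    c(0, 1), c(1, 20), c(20, 2), c(2, 3),
    c(20, 4), c(4, 5), c(5, 6), c(6, 7), c(7, 21), c(6, 22),
    c(20, 8), c(8, 9), c(9, 10), c(10, 11), c(11, 23), c(10, 24),
    c(0, 12), c(12, 13), c(13, 14), c(14, 15),
    c(0, 16), c(16, 17), c(17, 18), c(18, 19)
  )
  skeletonGraph(e0 + 1L, numJoints = 25L, centerJoint = 2L, jointNames = names)
}

#' Class labels of the gait simulator
#'
#' @return character vector of the six gait classes, ordered so that the
#'   0-based class label of class `k` is `k - 1`.
#' @export
gaitClasses <- function() {
  c("normal", "antalgic", "lurch", "steppage", "stiff_legged", "trendelenburg")
}

#' Binary adjacency matrix from the edge set
#'
#' `A[i, j] = 1` iff joints i and j are connected; symmetric with a zero
#' diagonal.
#'
#' @param graph a [SkeletonGraph-class]
#' @return V-by-V binary matrix
#' @export
adjacencyFromEdges <- function(graph) {
  v <- graph@numJoints
  A <- matrix(0, v, v)
  e <- graph@edges
  if (nrow(e)) {
    if (any(e < 1L | e > v)) stop("topology error: edge index out of range")
    A[e] <- 1
    A[e[, 2:1, drop = FALSE]] <- 1
  }
  dimnames(A) <- list(graph@jointNames, graph@jointNames)
  A
}

#' Symmetric normalized adjacency with self-loops
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `D` is the diagonal degree
#' matrix of `A + I`. Every node has degree at least one after the self-loop,
#' so the normalization is always defined; the result is symmetric with
#' entries in `[0, 1]` and spectral radius one.
#'
#' @param A symmetric binary (or nonnegative) matrix with zero diagonal
#' @return V-by-V symmetric matrix
#' @examples
#' normalizeAdjacency(matrix(c(0, 1, 1, 0), 2)) # all entries 1/2
#' @export
normalizeAdjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("validation error: A must be a square matrix")
  if (max(abs(A - t(A))) > 1e-12)
    stop("validation error: A must be symmetric")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * (dinv %o% dinv)
}

#' Partitioned, normalized adjacency stack
#'
#' Splits the self-loop-augmented adjacency into K groups that receive
#' separate graph-convolution weights:
#' \describe{
#'   \item{uni-label}{K = 1, all connections in one group.}
#'   \item{distance}{K = 2: self-loops vs. neighbor connections.}
#'   \item{spatial-configuration}{K = 3: self-loops; centripetal connections
#'     (towards a neighbor at most as far from the center joint, by hop
#'     distance); centrifugal connections (towards a farther neighbor).}
#' }
#' Each partition is the masked augmented adjacency normalized with its own
#' degree matrix, `L_k^(-1/2) M_k L_k^(-1/2)`; entries whose partition degree
#' is zero stay zero. Ties in hop distance go to the centripetal group.
#'
#' @param graph a [SkeletonGraph-class]
#' @param strategy partition strategy name
#' @return an [AdjacencySet-class] with the invariant that the partition
#'   supports tile the support of `A + I` exactly
#' @export
partitionAdjacency <- function(graph,
                               strategy = c("spatial-configuration", "uni-label", "distance")) {
  strategy <- match.arg(strategy)
  A <- adjacencyFromEdges(graph)
  v <- nrow(A)
  At <- A + diag(v)
  masks <- switch(strategy,
    "uni-label" = list(At),
    "distance" = list(diag(v), A),
    "spatial-configuration" = {
      hop <- hopDistances(graph)
      centripetal <- matrix(0, v, v)
      centrifugal <- matrix(0, v, v)
      idx <- which(A > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1L]; j <- idx[r, 2L]
        # connection i -> j: centripetal when the target is at most as close
        # to the center as the source (ties centripetal)
        if (hop[j] <= hop[i]) centripetal[i, j] <- 1 else centrifugal[i, j] <- 1
      }
      list(diag(v), centripetal, centrifugal)
    }
  )
  parts <- lapply(masks, .normalize_partition)
  methods::new("AdjacencySet",
    strategy = strategy, partitions = parts,
    normalizedFull = normalizeAdjacency(A)
  )
}

# Per-partition symmetric degree normalization. Degrees are taken over the
# partition's symmetrized support so that directional masks (centripetal /
# centrifugal) keep every one of their entries: with raw row degrees an entry
# whose target joint has no outgoing member in the same partition would be
# annihilated, breaking the support-tiling invariant. For symmetric masks
# this reduces to the usual D^(-1/2) M D^(-1/2).
.normalize_partition <- function(M) {
  S <- (M != 0) | (t(M) != 0)
  deg <- rowSums(S)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  M * (dinv %o% dinv)
}

#' Read a skeleton graph from a plain-text edge-list file
#'
#' Format: a header line `V=<n> center=<c>` followed by one `i j` pair per
#' line, all 0-based.
#'
#' @param path file path
#' @return a [SkeletonGraph-class]
#' @export
readGraphFile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty graph file: ", path)
  hdr <- regmatches(lines[1L], regexec("^V=(\\d+)\\s+center=(\\d+)$", lines[1L]))[[1L]]
  if (length(hdr) != 3L)
    stop("graph file must start with a 'V=<n> center=<c>' header: ", path)
  v <- as.integer(hdr[2L])
  center <- as.integer(hdr[3L]) + 1L
  body <- lines[-1L]
  edges <- if (length(body)) {
    do.call(rbind, lapply(strsplit(body, "\\s+"), function(p) as.integer(p[1:2]))) + 1L
  } else {
    matrix(integer(), ncol = 2L)
  }
  skeletonGraph(edges, numJoints = v, centerJoint = center)
}

#' Write a skeleton graph to the plain-text edge-list format
#' @param graph a [SkeletonGraph-class]
#' @param path file path
#' @return `path`, invisibly
#' @export
writeGraphFile <- function(graph, path) {
  lines <- c(
    sprintf("V=%d center=%d", graph@numJoints, graph@centerJoint - 1L),
    sprintf("%d %d", graph@edges[, 1L] - 1L, graph@edges[, 2L] - 1L)
  )
  writeLines(lines, path)
  invisible(path)
}

# relabel joints by permutation perm (new index = position of old index in perm):
# joint i of `graph` becomes joint perm[i] of the result
.permute_graph <- function(graph, perm) {
  inv <- order(perm)
  e <- graph@edges
  e2 <- cbind(perm[e[, 1L]], perm[e[, 2L]])
  skeletonGraph(e2,
    numJoints = graph@numJoints,
    centerJoint = perm[graph@centerJoint],
    jointNames = graph@jointNames[inv]
  )
}
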