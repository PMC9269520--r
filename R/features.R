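#' @include AllClasses.R
NULL

#' Center-relative joint coordinates
#'
#' `r_i(t) = x_i(t) - x_center(t)`: per-frame coordinates relative to the
#' center joint, invariant to whole-skeleton translation.
#'
#' @param seq a [SkeletonSequence-class]
#' @param centerJoint 1-based center joint index
#' @return T-by-V-by-3 array
#' @export
relativeCoordinates <- function(seq, centerJoint) {
  pos <- seq@positions
  v <- dim(pos)[2L]
  if (centerJoint < 1L || centerJoint > v)
    stop("validation error: centerJoint out of range")
  ctr <- pos[, centerJoint, , drop = FALSE] # T x 1 x 3
  pos - ctr[, rep(1L, v), , drop = FALSE]
}

#' One- and two-frame motion velocities
#'
#' `v1(t) = x(t+1) - x(t)` and `v2(t) = x(t+2) - x(t)`. Frames without a
#' defined forward difference (the last one or two) are zero-filled so every
#' feature stream keeps the full length T.
#'
#' @param seq a [SkeletonSequence-class]
#' @return list with T-by-V-by-3 arrays `v1` and `v2`
#' @export
motionVelocity <- function(seq) {
  pos <- seq@positions
  tN <- dim(pos)[1L]
  if (tN < 2L) stop("validation error: at least 2 frames required")
  v1 <- array(0, dim(pos))
  v2 <- array(0, dim(pos))
  v1[seq_len(tN - 1L), , ] <- pos[2:tN, , , drop = FALSE] - pos[seq_len(tN - 1L), , , drop = FALSE]
  if (tN >= 3L)
    v2[seq_len(tN - 2L), , ] <- pos[3:tN, , , drop = FALSE] - pos[seq_len(tN - 2L), , , drop = FALSE]
  list(v1 = v1, v2 = v2)
}

#' Bone vectors and bone angles
#'
#' The bone vector of joint i is `b_i = x_i - x_parent(i)` (the tree is
#' oriented towards the center joint; the root's bone is the zero vector).
#' The bone angle is the componentwise arc-cosine of the unit bone direction,
#' `a_i = arccos(b_i / |b_i|)`, with the argument clamped to `[-1, 1]`;
#' zero-length bones take the neutral value `arccos(0) = pi/2` in all three
#' components.
#'
#' @param seq a [SkeletonSequence-class]
#' @param graph a [SkeletonGraph-class] with a tree orientation
#' @return list with T-by-V-by-3 arrays `b` (vectors) and `a` (angles, radians)
#' @export
boneFeatures <- function(seq, graph) {
  pos <- seq@positions
  parent <- graph@parentOf
  if (all(is.na(parent)) && graph@numJoints > 1L)
    stop("validation error: graph has no tree orientation (not a connected tree)")
  v <- dim(pos)[2L]
  if (v != graph@numJoints) stop("validation error: V mismatch between sequence and graph")
  b <- array(0, dim(pos))
  hasParent <- which(!is.na(parent))
  b[, hasParent, ] <- pos[, hasParent, , drop = FALSE] - pos[, parent[hasParent], , drop = FALSE]
  nrm <- sqrt(b[, , 1L]^2 + b[, , 2L]^2 + b[, , 3L]^2) # T x V
  nrmA <- array(ifelse(nrm > 0, nrm, 1), dim(b)) # recycled over the 3rd dim
  arg <- pmin(pmax(b / nrmA, -1), 1)
  a <- acos(arg)
  zero <- array(nrm == 0, dim(b))
  if (any(zero)) a[zero] <- pi / 2
  list(b = b, a = a)
}

#' Assemble the three 6-channel input branches
#'
#' Builds the [BranchFeatures-class] streams from a sequence: the joint
#' branch stacks absolute over center-relative coordinates, the velocity
#' branch one-frame over two-frame displacements, and the bone branch bone
#' vectors over bone angles. All three streams are 6-by-T-by-V.
#'
#' @param seq a [SkeletonSequence-class]
#' @param graph a [SkeletonGraph-class]
#' @return a [BranchFeatures-class]
#' @examples
#' g <- kinectV2Graph()
#' s <- simulateSequence(gaitParams(seed = 1))
#' bf <- assembleBranches(s, g)
#' dim(bf@joint)
#' @export
assembleBranches <- function(seq, graph) {
  pos <- seq@positions
  if (dim(pos)[2L] != graph@numJoints)
    stop("validation error: V mismatch between sequence and graph")
  rel <- relativeCoordinates(seq, graph@centerJoint)
  vel <- motionVelocity(seq)
  bone <- boneFeatures(seq, graph)
  methods::new("BranchFeatures",
    joint = .stack6(pos, rel),
    velocity = .stack6(vel$v1, vel$v2),
    bone = .stack6(bone$b, bone$a)
  )
}

# two T x V x 3 arrays -> one 6 x T x V array (channels first)
.stack6 <- function(a, b) {
  tN <- dim(a)[1L]; vN <- dim(a)[2L]
  out <- array(0, c(6L, tN, vN))
  out[1:3, , ] <- aperm(a, c(3, 1, 2))
  out[4:6, , ] <- aperm(b, c(3, 1, 2))
  out
}

#' Reconstruct absolute positions from the root trajectory and bone vectors
#'
#' Inverse of the bone transform: walking the tree from the center joint
#' outwards, `x_i = x_parent(i) + b_i`. Used to verify that the bone stream
#' is information-preserving.
#'
#' @param root T-by-3 matrix of center-joint positions
#' @param b T-by-V-by-3 bone-vector array
#' @param graph the [SkeletonGraph-class] that produced `b`
#' @return T-by-V-by-3 array of absolute positions
#' @export
reconstructFromBones <- function(root, b, graph) {
  parent <- graph@parentOf
  v <- graph@numJoints
  out <- array(NA_real_, dim(b))
  out[, graph@centerJoint, ] <- root
  # process joints in increasing hop distance so parents are filled first
  ord <- order(hopDistances(graph))
  for (j in ord) {
    if (is.na(parent[j])) next
    out[, j, ] <- out[, parent[j], ] + b[, j, ]
  }
  out
}
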