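#' @include AllGenerics.R
NULL

#' Skeleton graph topology
#'
#' An undirected joint-connectivity graph for a skeletal model, oriented as a
#' tree rooted at a designated center joint. Joint indices are 1-based inside
#' R; edge-list files on disk use 0-based indices (see [readGraphFile()]).
#'
#' @slot numJoints number of joints V.
#' @slot edges integer matrix with two columns, one row per undirected edge.
#' @slot centerJoint index of the center (root) joint.
#' @slot jointNames character vector of length V.
#' @slot parentOf integer vector of length V mapping each joint to its parent
#'   in the tree rooted at `centerJoint`; `NA` for the root (and for all
#'   joints when the graph is not a tree).
#'
#' @seealso [skeletonGraph()], [kinectV2Graph()], [adjacencyFromEdges()]
#' @aliases numJoints graphEdges centerJoint jointNames parentOf
#' @export
setClass("SkeletonGraph",
  slots = c(
    numJoints  = "integer",
    edges      = "matrix",
    centerJoint = "integer",
    jointNames = "character",
    parentOf   = "integer"
  )
)

setValidity("SkeletonGraph", function(object) {
  v <- object@numJoints
  e <- object@edges
  msg <- character()
  if (length(v) != 1L || is.na(v) || v < 1L) msg <- c(msg, "numJoints must be a positive integer")
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e < 1L | e > v)) msg <- c(msg, "edge indices out of range")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
  }
  if (object@centerJoint < 1L || object@centerJoint > v)
    msg <- c(msg, "centerJoint out of range")
  if (length(object@jointNames) != v) msg <- c(msg, "jointNames must have length numJoints")
  if (length(object@parentOf) != v) msg <- c(msg, "parentOf must have length numJoints")
  if (length(msg)) msg else TRUE
})

#' Construct a skeleton graph
#'
#' @param edges two-column matrix (or list of length-2 vectors) of 1-based
#'   joint index pairs.
#' @param numJoints number of joints V; defaults to the largest index seen.
#' @param centerJoint 1-based index of the center joint (tree root).
#' @param jointNames optional character vector of joint labels.
#'
#' @details When the edge set forms a spanning tree (V-1 edges, connected),
#' the parent orientation towards `centerJoint` is derived by breadth-first
#' search and bone features become available; otherwise `parentOf` is `NA`.
#'
#' @return a [SkeletonGraph-class] object.
#' @examples
#' g <- skeletonGraph(rbind(c(1, 2), c(2, 3)), centerJoint = 1)
#' adjacencyFromEdges(g)
#' @export
skeletonGraph <- function(edges, numJoints = NULL, centerJoint = 1L,
                          jointNames = NULL) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  }
  storage.mode(edges) <- "integer"
  if (is.null(numJoints)) {
    if (nrow(edges) == 0L) stop("numJoints required for an edgeless graph")
    numJoints <- max(edges)
  }
  numJoints <- as.integer(numJoints)
  if (nrow(edges) > 0L && (any(edges < 1L) || any(edges > numJoints)))
    stop("topology error: edge index out of range [1, ", numJoints, "]")
  if (is.null(jointNames)) jointNames <- paste0("J", seq_len(numJoints) - 1L)
  parent <- .tree_parents(edges, numJoints, as.integer(centerJoint))
  methods::new("SkeletonGraph",
    numJoints = numJoints, edges = edges,
    centerJoint = as.integer(centerJoint),
    jointNames = jointNames, parentOf = parent
  )
}

# BFS orientation from the center; all-NA when not a connected tree.
.tree_parents <- function(edges, v, center) {
  parent <- rep(NA_integer_, v)
  if (nrow(edges) != v - 1L) return(parent)
  nbr <- vector("list", v)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  seen <- logical(v)
  seen[center] <- TRUE
  queue <- center
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nx in nbr[[cur]]) {
      if (!seen[nx]) {
        seen[nx] <- TRUE
        parent[nx] <- cur
        queue <- c(queue, nx)
      }
    }
  }
  if (!all(seen)) return(rep(NA_integer_, v))
  parent
}

#' Hop distances from every joint to the center joint
#' @param graph a [SkeletonGraph-class]
#' @return integer vector of length V (`Inf` never occurs for connected graphs)
#' @export
hopDistances <- function(graph) {
  v <- graph@numJoints
  adj <- adjacencyFromEdges(graph)
  dist <- rep(NA_integer_, v)
  dist[graph@centerJoint] <- 0L
  frontier <- graph@centerJoint
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer()
    for (f in frontier) {
      nb <- which(adj[f, ] > 0)
      nb <- nb[is.na(dist[nb])]
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

#' Normalized, partitioned adjacency matrices
#'
#' Holds the spatial-partition adjacency stack consumed by the graph
#' convolution: K nonnegative V-by-V matrices whose binary supports tile the
#' support of the self-loop-augmented adjacency exactly, plus the symmetric
#' normalized full adjacency.
#'
#' @slot strategy one of `"uni-label"`, `"distance"`, `"spatial-configuration"`.
#' @slot partitions list of K V-by-V matrices (per-partition symmetric
#'   degree normalization).
#' @slot normalizedFull the V-by-V symmetric normalized adjacency.
#' @seealso [partitionAdjacency()], [normalizeAdjacency()]
#' @aliases partitions normalizedFull partitionStrategy
#' @export
setClass("AdjacencySet",
  slots = c(
    strategy = "character",
    partitions = "list",
    normalizedFull = "matrix"
  )
)

setValidity("AdjacencySet", function(object) {
  msg <- character()
  A <- object@normalizedFull
  if (nrow(A) != ncol(A)) msg <- c(msg, "normalizedFull must be square")
  if (max(abs(A - t(A))) > 1e-12) msg <- c(msg, "normalizedFull must be symmetric")
  for (P in object@partitions) {
    if (any(P < 0)) msg <- c(msg, "partition matrices must be nonnegative")
    if (!all(dim(P) == dim(A))) msg <- c(msg, "partition dimensions must match")
  }
  supp <- Reduce(`+`, lapply(object@partitions, function(P) (P != 0) * 1L))
  full <- (A != 0) * 1L
  # every nonzero of the normalized full matrix claimed by exactly one partition
  if (length(object@partitions) && any(supp > 1L))
    msg <- c(msg, "partition supports overlap")
  if (length(object@partitions) && any((supp > 0L) != (full > 0L)))
    msg <- c(msg, "partition supports do not tile the augmented adjacency")
  if (length(msg)) msg else TRUE
})

#' A 3D skeleton sequence
#'
#' @slot positions T-by-V-by-3 array of joint coordinates in meters.
#' @slot subjectId subject identifier.
#' @slot classLabel 0-based integer class label (`NA` when unknown).
#' @slot sampleId sample identifier.
#' @slot fps frames per second.
#' @seealso [skeletonSequence()], [resampleSequence()], [assembleBranches()]
#' @aliases positions subjectId classLabel sampleId frameRate numFrames
#' @export
setClass("SkeletonSequence",
  slots = c(
    positions = "array",
    subjectId = "character",
    classLabel = "integer",
    sampleId = "character",
    fps = "numeric"
  )
)

setValidity("SkeletonSequence", function(object) {
  p <- object@positions
  msg <- character()
  if (length(dim(p)) != 3L || dim(p)[3L] != 3L)
    msg <- c(msg, "positions must be a T x V x 3 array")
  if (dim(p)[1L] < 2L) msg <- c(msg, "a sequence needs at least 2 frames")
  if (!all(is.finite(p))) msg <- c(msg, "all coordinates must be finite")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a skeleton sequence
#' @param positions T-by-V-by-3 numeric array (meters).
#' @param subjectId,sampleId identifiers.
#' @param classLabel 0-based integer class label, or `NA`.
#' @param fps frames per second.
#' @return a [SkeletonSequence-class]
#' @export
skeletonSequence <- function(positions, subjectId = "S0", classLabel = NA_integer_,
                             sampleId = "sample", fps = 30) {
  methods::new("SkeletonSequence",
    positions = positions, subjectId = as.character(subjectId),
    classLabel = as.integer(classLabel), sampleId = as.character(sampleId),
    fps = as.numeric(fps)
  )
}

#' Three-branch input features
#'
#' The three 6-channel input streams derived from a skeleton sequence:
#' `joint` stacks absolute coordinates (channels 1-3) over center-relative
#' coordinates (4-6); `velocity` stacks one-frame over two-frame
#' displacements; `bone` stacks parent-relative bone vectors over their
#' componentwise arc-cosine angles (radians).
#'
#' @slot joint,velocity,bone 6-by-T-by-V arrays.
#' @seealso [assembleBranches()]
#' @export
setClass("BranchFeatures",
  slots = c(joint = "array", velocity = "array", bone = "array")
)

setValidity("BranchFeatures", function(object) {
  d <- dim(object@joint)
  msg <- character()
  for (nm in c("joint", "velocity", "bone")) {
    s <- methods::slot(object, nm)
    if (length(dim(s)) != 3L || dim(s)[1L] != 6L)
      msg <- c(msg, sprintf("%s stream must be 6 x T x V", nm))
    if (!identical(dim(s), d)) msg <- c(msg, "streams must share T and V")
  }
  ang <- object@bone[4:6, , , drop = FALSE]
  if (any(ang < -1e-9 | ang > pi + 1e-9)) msg <- c(msg, "angle channels must lie in [0, pi]")
  if (length(msg)) msg else TRUE
})

#' A collection of skeleton sequences with class metadata
#'
#' @slot sequences list of [SkeletonSequence-class] objects.
#' @slot classNames character vector mapping 0-based labels to names.
#' @seealso [simulateDataset()], [losoSplits()]
#' @export
setClass("GaitDataset",
  slots = c(sequences = "list", classNames = "character")
)

#' @rdname GaitDataset-class
#' @param sequences list of [SkeletonSequence-class]
#' @param classNames label names (index = 0-based label + 1)
#' @export
gaitDataset <- function(sequences, classNames = gaitClasses()) {
  methods::new("GaitDataset", sequences = sequences, classNames = classNames)
}

#' Simulator parameters for one gait sequence
#'
#' @slot gaitClass one of [gaitClasses()].
#' @slot affectedSide `"left"` or `"right"`.
#' @slot severity effect size in `[0, 1]`; 0 collapses every class onto the
#'   normal gait.
#' @slot cadenceHz stride cycles per second.
#' @slot nFrames frames to generate.
#' @slot noiseSd standard deviation of additive Gaussian sensor noise (m).
#' @slot limbScale global anthropometric scale factor.
#' @slot seed RNG seed making the sequence reproducible.
#' @seealso [gaitParams()], [simulateSequence()]
#' @export
setClass("GaitParams",
  slots = c(
    gaitClass = "character", affectedSide = "character", severity = "numeric",
    cadenceHz = "numeric", nFrames = "integer", noiseSd = "numeric",
    limbScale = "numeric", seed = "integer"
  )
)

setValidity("GaitParams", function(object) {
  msg <- character()
  if (!object@gaitClass %in% gaitClasses())
    msg <- c(msg, paste("unknown gait class:", object@gaitClass))
  if (!object@affectedSide %in% c("left", "right"))
    msg <- c(msg, "affectedSide must be 'left' or 'right'")
  if (object@severity < 0 || object@severity > 1) msg <- c(msg, "severity must lie in [0, 1]")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be at least 2")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@cadenceHz <= 0) msg <- c(msg, "cadenceHz must be positive")
  if (object@limbScale <= 0) msg <- c(msg, "limbScale must be positive")
  if (length(msg)) msg else TRUE
})

#' Network architecture configuration
#'
#' @slot branchChannels integer vector of the four per-branch block widths
#'   (initial block then three attention blocks).
#' @slot mainChannels integer vector of the two mainstream block widths.
#' @slot blockDepth temporal layers per block.
#' @slot temporalKernel odd temporal kernel size (frames).
#' @slot attentionReduction channel-reduction divisor r of the attention
#'   bottleneck.
#' @slot strategy spatial partition strategy.
#' @slot numClasses number of output classes.
#' @slot separable use depthwise-separable temporal convolutions.
#' @slot attentionOn enable spatiotemporal joint attention in branch blocks.
#' @slot attentionMainstream also apply attention in mainstream blocks.
#' @slot edgeImportance learnable elementwise mask on each partition matrix.
#' @slot seed weight-initialization seed.
#' @seealso [modelConfig()], [buildMIBNetwork()]
#' @export
setClass("ModelConfig",
  slots = c(
    branchChannels = "integer", mainChannels = "integer",
    blockDepth = "integer", temporalKernel = "integer",
    attentionReduction = "integer", strategy = "character",
    numClasses = "integer", separable = "logical",
    attentionOn = "logical", attentionMainstream = "logical",
    edgeImportance = "logical", seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (length(object@branchChannels) != 4L) msg <- c(msg, "branchChannels must have length 4")
  if (length(object@mainChannels) != 2L) msg <- c(msg, "mainChannels must have length 2")
  if (object@temporalKernel %% 2L == 0L) msg <- c(msg, "temporalKernel must be odd")
  if (object@blockDepth < 1L) msg <- c(msg, "blockDepth must be at least 1")
  if (object@numClasses < 2L) msg <- c(msg, "numClasses must be at least 2")
  if (!object@strategy %in% c("uni-label", "distance", "spatial-configuration"))
    msg <- c(msg, "unknown partition strategy")
  r <- object@attentionReduction
  if (r < 1L) msg <- c(msg, "attentionReduction must be positive")
  if (object@attentionOn) {
    sites <- object@branchChannels[2:4]
    if (object@attentionMainstream) sites <- c(sites, object@mainChannels)
    if (any(sites %% r != 0L))
      msg <- c(msg, "attentionReduction must divide the channel width at every attention site")
  }
  if (length(msg)) msg else TRUE
})

#' Per-frame per-joint class-activation map
#'
#' @slot values T'-by-V nonnegative matrix summing to one, on the temporal
#'   grid of the mainstream's final feature map.
#' @slot classQueried 0-based class index the map explains.
#' @slot sampleId identifier of the explained sample.
#' @seealso [skeletonCAM()], [jointImportance()]
#' @export
setClass("ActivationMap",
  slots = c(values = "matrix", classQueried = "integer", sampleId = "character")
)

setValidity("ActivationMap", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "activation values must be nonnegative")
  if (abs(sum(object@values) - 1) > 1e-9) msg <- c(msg, "activation values must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Classification evaluation report
#'
#' @slot accuracy pooled accuracy, `trace(confusion)/sum(confusion)`.
#' @slot confusion numClasses-by-numClasses count matrix (rows = truth).
#' @slot perFold named numeric vector of per-fold accuracies (empty for a
#'   single split).
#' @aliases accuracy confusion foldAccuracies
#' @export
setClass("EvalReport",
  slots = c(accuracy = "numeric", confusion = "matrix", perFold = "numeric")
)

setValidity("EvalReport", function(object) {
  msg <- character()
  cm <- object@confusion
  if (any(cm < 0) || any(cm != round(cm))) msg <- c(msg, "confusion entries must be nonnegative integers")
  if (sum(cm) > 0 && abs(object@accuracy - sum(diag(cm)) / sum(cm)) > 1e-12)
    msg <- c(msg, "accuracy must equal trace(confusion)/sum(confusion)")
  if (length(msg)) msg else TRUE
})

#' Trained (or initialized) multiple-input-branch ST-GCN model
#'
#' @slot config the [ModelConfig-class] used to build the network.
#' @slot graph the skeleton graph.
#' @slot adj the partitioned adjacency stack.
#' @slot branches active input branches, subset of
#'   `c("joint", "velocity", "bone")`.
#' @slot params flat named list of weight arrays.
#' @slot state flat named list of non-trainable state (batch-norm running
#'   moments).
#' @slot classNames class label names.
#' @seealso [buildMIBNetwork()], [trainModel()], [predictClasses()]
#' @export
setClass("MIBModel",
  slots = c(
    config = "ModelConfig", graph = "SkeletonGraph", adj = "AdjacencySet",
    branches = "character", params = "list", state = "list",
    classNames = "character"
  )
)

## ---- accessors ----

#' @rdname SkeletonGraph-class
#' @export
setMethod("numJoints", "SkeletonGraph", function(x) x@numJoints)
#' @rdname SkeletonGraph-class
#' @export
setMethod("graphEdges", "SkeletonGraph", function(x) x@edges)
#' @rdname SkeletonGraph-class
#' @export
setMethod("centerJoint", "SkeletonGraph", function(x) x@centerJoint)
#' @rdname SkeletonGraph-class
#' @export
setMethod("jointNames", "SkeletonGraph", function(x) x@jointNames)
#' @rdname SkeletonGraph-class
#' @export
setMethod("parentOf", "SkeletonGraph", function(x) x@parentOf)

#' @rdname SkeletonSequence-class
#' @export
setMethod("positions", "SkeletonSequence", function(x) x@positions)
#' @rdname SkeletonSequence-class
#' @export
setMethod("subjectId", "SkeletonSequence", function(x) x@subjectId)
#' @rdname SkeletonSequence-class
#' @export
setMethod("classLabel", "SkeletonSequence", function(x) x@classLabel)
#' @rdname SkeletonSequence-class
#' @export
setMethod("sampleId", "SkeletonSequence", function(x) x@sampleId)
#' @rdname SkeletonSequence-class
#' @export
setMethod("frameRate", "SkeletonSequence", function(x) x@fps)
#' @rdname SkeletonSequence-class
#' @export
setMethod("numFrames", "SkeletonSequence", function(x) dim(x@positions)[1L])

#' @rdname AdjacencySet-class
#' @export
setMethod("partitions", "AdjacencySet", function(x) x@partitions)
#' @rdname AdjacencySet-class
#' @export
setMethod("normalizedFull", "AdjacencySet", function(x) x@normalizedFull)
#' @rdname AdjacencySet-class
#' @export
setMethod("partitionStrategy", "AdjacencySet", function(x) x@strategy)

#' @rdname EvalReport-class
#' @export
setMethod("accuracy", "EvalReport", function(x) x@accuracy)
#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(x) x@confusion)
#' @rdname EvalReport-class
#' @export
setMethod("foldAccuracies", "EvalReport", function(x) x@perFold)

#' @rdname GaitDataset-class
#' @param x a `GaitDataset`
#' @param i index
#' @export
setMethod("length", "GaitDataset", function(x) length(x@sequences))
#' @rdname GaitDataset-class
#' @export
setMethod("[[", "GaitDataset", function(x, i) x@sequences[[i]])

## ---- show methods ----

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf(
    "SkeletonGraph: %d joints, %d edges, center = %s (%d)\n",
    object@numJoints, nrow(object@edges),
    object@jointNames[object@centerJoint], object@centerJoint
  ))
})

setMethod("show", "SkeletonSequence", function(object) {
  d <- dim(object@positions)
  cat(sprintf(
    "SkeletonSequence '%s': %d frames x %d joints @ %.3g fps, subject %s, label %s\n",
    object@sampleId, d[1L], d[2L], object@fps, object@subjectId,
    ifelse(is.na(object@classLabel), "NA", object@classLabel)
  ))
})

setMethod("show", "AdjacencySet", function(object) {
  cat(sprintf(
    "AdjacencySet (%s): %d partition(s) of a %d-joint graph\n",
    object@strategy, length(object@partitions), nrow(object@normalizedFull)
  ))
})

setMethod("show", "GaitDataset", function(object) {
  labs <- vapply(object@sequences, function(s) s@classLabel, integer(1))
  subj <- vapply(object@sequences, function(s) s@subjectId, character(1))
  cat(sprintf(
    "GaitDataset: %d sequences, %d subjects, %d classes\n",
    length(object@sequences), length(unique(subj)),
    length(unique(labs[!is.na(labs)]))
  ))
})

setMethod("show", "MIBModel", function(object) {
  n <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "MIBModel: branches [%s], %d classes, %d trainable parameters\n",
    paste(object@branches, collapse = ", "),
    object@config@numClasses, n
  ))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.4f over %d samples", object@accuracy, sum(object@confusion)))
  if (length(object@perFold))
    cat(sprintf(" (%d folds, fold-mean %.4f)", length(object@perFold), mean(object@perFold)))
  cat("\n")
})

setMethod("show", "ActivationMap", function(object) {
  cat(sprintf(
    "ActivationMap for class %d, sample '%s': %d frames x %d joints\n",
    object@classQueried, object@sampleId, nrow(object@values), ncol(object@values)
  ))
})

setMethod("show", "GaitParams", function(object) {
  cat(sprintf(
    "GaitParams: %s (%s side), severity %.2f, %d frames @ %.2f Hz, noise %.3g m\n",
    object@gaitClass, object@affectedSide, object@severity,
    object@nFrames, object@cadenceHz, object@noiseSd
  ))
})
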