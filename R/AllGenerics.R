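NULL

#' @rdname SkeletonGraph-class
#' @param x,object a `SkeletonGraph`
#' @export
setGeneric("numJoints", function(x) standardGeneric("numJoints"))

#' @rdname SkeletonGraph-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname SkeletonGraph-class
#' @export
setGeneric("centerJoint", function(x) standardGeneric("centerJoint"))

#' @rdname SkeletonGraph-class
#' @export
setGeneric("jointNames", function(x) standardGeneric("jointNames"))

#' @rdname SkeletonGraph-class
#' @export
setGeneric("parentOf", function(x) standardGeneric("parentOf"))

#' @rdname SkeletonSequence-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname SkeletonSequence-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname SkeletonSequence-class
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname SkeletonSequence-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SkeletonSequence-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname SkeletonSequence-class
#' @export
setGeneric("numFrames", function(x) standardGeneric("numFrames"))

#' @rdname AdjacencySet-class
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' @rdname AdjacencySet-class
#' @export
setGeneric("normalizedFull", function(x) standardGeneric("normalizedFull"))

#' @rdname AdjacencySet-class
#' @export
setGeneric("partitionStrategy", function(x) standardGeneric("partitionStrategy"))

#' @rdname EvalReport-class
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname EvalReport-class
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname EvalReport-class
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))
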