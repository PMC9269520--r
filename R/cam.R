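#' @include model.R train.R
NULL

#' Class-activation map on the skeleton
#'
#' Projects the classifier weights of the queried class onto the mainstream's
#' final (post-attention) feature map: `M(t, v) = sum_c w_c F_c(t, v)`,
#' rectified at zero and normalized to sum to one. Because every channel's
#' global average feeds the fully connected classifier, this weighted sum
#' marks the frames and joints that drive the class score. The temporal grid
#' is the final feature map's (T' = T / 4 after the two stride-2 mainstream
#' blocks); [upsampleActivationMap()] maps it back to input frames.
#'
#' @param model a trained [MIBModel-class]
#' @param seq a [SkeletonSequence-class] (resampled if needed)
#' @param targetClass 0-based class index to explain (default: the model's
#'   prediction)
#' @param tTarget optional resampling length
#' @return an [ActivationMap-class]; if the rectified map is identically
#'   zero, the uniform map is returned with a warning
#' @export
skeletonCAM <- function(model, seq, targetClass = NULL, tTarget = NULL) {
  if (!is.null(tTarget)) seq <- resampleSequence(seq, tTarget)
  bf <- assembleBranches(seq, model@graph)
  tN <- dim(bf@joint)[2L]
  v <- dim(bf@joint)[3L]
  xlist <- list(
    joint = array(bf@joint, c(6L, tN, 1L, v)),
    velocity = array(bf@velocity, c(6L, tN, 1L, v)),
    bone = array(bf@bone, c(6L, tN, 1L, v))
  )[model@branches]
  fwd <- .net_forward(model, xlist, train = FALSE, collectFeatures = TRUE)
  if (is.null(targetClass)) {
    targetClass <- which.max(fwd$logits[, 1L]) - 1L
  }
  ncls <- model@config@numClasses
  if (targetClass < 0L || targetClass >= ncls)
    stop("validation error: targetClass outside [0, ", ncls, ")")
  Fmap <- fwd$features # C x T' x 1 x V
  d <- dim(Fmap)
  w <- model@params[["fc.W"]][, targetClass + 1L]
  M <- matrix(crossprod(matrix(Fmap, d[1L], d[2L] * d[4L]), w), d[2L], d[4L])
  M <- pmax(M, 0)
  total <- sum(M)
  if (total <= 0) {
    warning("all-zero activation map; returning the uniform map")
    M <- matrix(1 / length(M), nrow(M), ncol(M))
  } else {
    M <- M / total
  }
  methods::new("ActivationMap",
    values = M, classQueried = as.integer(targetClass), sampleId = seq@sampleId
  )
}

#' Per-joint importance mass
#'
#' Sums the activation map over frames; the result is a V-vector summing to
#' one.
#'
#' @param map an [ActivationMap-class]
#' @return numeric vector of length V
#' @export
jointImportance <- function(map) {
  colSums(map@values)
}

#' Upsample an activation map to the input frame grid
#'
#' Nearest-neighbor assignment of the final-feature-map frames back onto
#' `tTarget` input frames (each stride-2 layer halves the temporal length),
#' preserving total mass.
#'
#' @param map an [ActivationMap-class]
#' @param tTarget input frame count
#' @return tTarget-by-V matrix summing to one
#' @export
upsampleActivationMap <- function(map, tTarget) {
  tSmall <- nrow(map@values)
  src <- pmin(tSmall, pmax(1L, round((seq_len(tTarget) - 0.5) * tSmall / tTarget + 0.5)))
  out <- map@values[src, , drop = FALSE]
  out / sum(out)
}

#' Render an activation map as a skeleton overlay
#'
#' Draws the skeleton at a chosen frame with marker areas proportional to
#' per-joint importance, writing a PNG.
#'
#' @param map an [ActivationMap-class]
#' @param seq the explained [SkeletonSequence-class]
#' @param graph the skeleton graph
#' @param path output PNG path
#' @param frame input frame to draw (default: mid-sequence)
#' @return `path`, invisibly
#' @export
plotActivationMap <- function(map, seq, graph, path, frame = NULL) {
  pos <- seq@positions
  tN <- dim(pos)[1L]
  if (is.null(frame)) frame <- max(1L, tN %/% 2L)
  imp <- jointImportance(map)
  xy <- pos[frame, , c(3L, 2L)] # sagittal view: forward vs up
  grDevices::png(path, width = 600, height = 700)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(xy[, 1L], xy[, 2L],
    asp = 1, xlab = "forward (m)", ylab = "up (m)",
    main = sprintf("Joint importance, class '%s'",
                   .class_name(map@classQueried)),
    pch = 19, col = "grey40",
    cex = 0.5 + 6 * sqrt(imp / max(imp))
  )
  e <- graph@edges
  graphics::segments(xy[e[, 1L], 1L], xy[e[, 1L], 2L],
                     xy[e[, 2L], 1L], xy[e[, 2L], 2L], col = "grey70")
  invisible(path)
}

.class_name <- function(label0) {
  cls <- gaitClasses()
  if (label0 + 1L <= length(cls)) cls[label0 + 1L] else as.character(label0)
}

#' Export an activation map as CSV
#'
#' Tidy long format with columns `frame` (final-feature-map grid), `joint`,
#' `weight`.
#'
#' @param map an [ActivationMap-class]
#' @param path output path
#' @param graph optional graph supplying joint names
#' @return `path`, invisibly
#' @export
exportActivationCSV <- function(map, path, graph = NULL) {
  M <- map@values
  jn <- if (!is.null(graph)) graph@jointNames else paste0("J", seq_len(ncol(M)) - 1L)
  df <- data.frame(
    frame = rep(seq_len(nrow(M)), times = ncol(M)),
    joint = rep(jn, each = nrow(M)),
    weight = as.vector(M)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mean pelvis/shoulder activation mass over a dataset
#'
#' Helper for the qualitative CAM analysis of lateral-trunk gaits: for each
#' correctly classified sequence of `classLabel`, computes the summed
#' importance of a joint group (default: pelvis + shoulders) and averages.
#'
#' @param model a trained [MIBModel-class]
#' @param dataset a [GaitDataset-class]
#' @param classLabel 0-based class whose samples are explained
#' @param joints 1-based joint indices of the group (default SpineBase, both
#'   hips, both shoulders, SpineShoulder)
#' @param tTarget optional resampling length
#' @return list with `mass` (mean group mass), `n` (number of samples used)
#'   and `correct` (whether only correctly classified samples were used; if
#'   the model classifies no sample of the class correctly, the maps of all
#'   its samples are averaged instead)
#' @export
camGroupMass <- function(model, dataset, classLabel,
                         joints = c(1L, 13L, 17L, 5L, 9L, 21L),
                         tTarget = NULL) {
  seqs <- Filter(function(s) identical(s@classLabel, as.integer(classLabel)),
                 dataset@sequences)
  groupMass <- function(onlyCorrect) {
    masses <- numeric()
    for (s in seqs) {
      sq <- if (is.null(tTarget)) s else resampleSequence(s, tTarget)
      if (onlyCorrect) {
        pred <- predictClasses(model, prepareBranchData(
          gaitDataset(list(sq), dataset@classNames), model@graph
        ))
        if (pred$labels[1L] != classLabel) next
      }
      map <- skeletonCAM(model, sq, targetClass = classLabel)
      masses <- c(masses, sum(jointImportance(map)[joints]))
    }
    masses
  }
  masses <- groupMass(TRUE)
  correct <- length(masses) > 0
  if (!correct) masses <- groupMass(FALSE)
  list(mass = if (length(masses)) mean(masses) else NA_real_,
       n = length(masses), correct = correct)
}
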