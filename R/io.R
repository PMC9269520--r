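#' @include AllClasses.R
NULL

#' Read an NTU-dialect `.skeleton` file
#'
#' Parses the plain-text skeleton dialect: line 1 is the frame count; each
#' frame holds a body count, then per body one body-info line, a joint-count
#' line (25), and 25 joint lines whose first three whitespace-separated
#' fields are x, y, z in meters. When a frame contains several bodies the
#' body with the highest summed tracking confidence (last field of each joint
#' line) is kept, falling back to the first body. Frames with no body are
#' filled by repeating the last observed frame, with a warning.
#'
#' Subject and class metadata are recovered from the canonical
#' `SsssCcccPpppRrrrAaaa` filename pattern when present (subject = `Pppp`,
#' 0-based class label = `aaa - 1`).
#'
#' @param path file path
#' @param fps frame rate to record (the format does not store one)
#' @return a [SkeletonSequence-class] with V = 25
#' @export
readNTUSkeleton <- function(path, fps = 30) {
  lines <- readLines(path)
  n <- length(lines)
  cursor <- 0L
  nextLine <- function(what) {
    cursor <<- cursor + 1L
    if (cursor > n)
      stop(sprintf("parse error in '%s': expected %s at line %d but file ended",
                   basename(path), what, cursor))
    lines[[cursor]]
  }
  numFromLine <- function(what) {
    val <- suppressWarnings(as.numeric(strsplit(trimws(nextLine(what)), "\\s+")[[1L]][1L]))
    if (is.na(val))
      stop(sprintf("parse error in '%s' at line %d: expected %s", basename(path), cursor, what))
    val
  }
  nFrames <- as.integer(numFromLine("frame count"))
  if (is.na(nFrames) || nFrames < 1L)
    stop("parse error: invalid frame count in ", basename(path))
  frames <- vector("list", nFrames)
  lastSeen <- NULL
  nMissing <- 0L
  for (f in seq_len(nFrames)) {
    nBodies <- as.integer(numFromLine(sprintf("body count (frame %d)", f)))
    best <- NULL
    bestConf <- -Inf
    for (b in seq_len(nBodies)) {
      nextLine(sprintf("body info (frame %d, body %d)", f, b))
      nJoints <- as.integer(numFromLine(sprintf("joint count (frame %d, body %d)", f, b)))
      if (nJoints != 25L)
        stop(sprintf("parse error in '%s' at line %d: frame %d declares %d joints, expected 25",
                     basename(path), cursor, f, nJoints))
      xyz <- matrix(NA_real_, 25L, 3L)
      conf <- 0
      for (j in seq_len(25L)) {
        fields <- strsplit(trimws(nextLine(sprintf("joint %d (frame %d)", j, f))), "\\s+")[[1L]]
        vals <- suppressWarnings(as.numeric(fields))
        if (length(vals) < 3L || anyNA(vals[1:3]))
          stop(sprintf("parse error in '%s' at line %d: malformed joint line", basename(path), cursor))
        xyz[j, ] <- vals[1:3]
        if (!is.na(vals[length(vals)])) conf <- conf + vals[length(vals)]
      }
      if (is.null(best) || conf > bestConf) {
        best <- xyz
        bestConf <- conf
      }
    }
    if (is.null(best)) {
      nMissing <- nMissing + 1L
      frames[[f]] <- lastSeen # possibly NULL; fixed up below
    } else {
      frames[[f]] <- best
      lastSeen <- best
    }
  }
  if (is.null(lastSeen)) stop("empty-sequence error: no tracked body in any frame of ", basename(path))
  # leading missing frames (before the first observed body): back-fill
  firstObs <- which(!vapply(frames, is.null, logical(1)))[1L]
  for (f in seq_len(nFrames)) if (is.null(frames[[f]])) frames[[f]] <- frames[[firstObs]]
  if (nMissing > 0L)
    warning(sprintf("%d frame(s) without a tracked body in '%s'; repeated the nearest observed frame",
                    nMissing, basename(path)))
  pos <- array(NA_real_, c(nFrames, 25L, 3L))
  for (f in seq_len(nFrames)) pos[f, , ] <- frames[[f]]
  meta <- .parse_ntu_name(basename(path))
  skeletonSequence(pos,
    subjectId = meta$subject, classLabel = meta$label,
    sampleId = meta$sample, fps = fps
  )
}

.parse_ntu_name <- function(name) {
  m <- regmatches(name, regexec("S(\\d{3})C(\\d{3})P(\\d{3})R(\\d{3})A(\\d{3})", name))[[1L]]
  if (length(m) == 6L) {
    list(
      subject = paste0("P", m[4L]),
      label = as.integer(m[6L]) - 1L,
      sample = sub("\\.skeleton$", "", name)
    )
  } else {
    list(subject = "unknown", label = NA_integer_, sample = sub("\\.skeleton$", "", name))
  }
}

#' Write/read a sequence container
#'
#' Serializes a set of skeleton sequences (optionally with cached branch
#' features) to a single container file, one record per sample carrying the
#' position array and the subject/class/fps attributes. The container is the
#' package's native serialized format; [exportSequenceCSV()] provides a
#' plain-text alternative for single sequences.
#'
#' @param x a [GaitDataset-class], or a list of [SkeletonSequence-class]
#' @param path file path
#' @param features optional named list (by sample id) of
#'   [BranchFeatures-class] to cache alongside the raw positions
#' @return `path` invisibly for the writer; a [GaitDataset-class] for the
#'   reader (cached features, if any, in `attr(, "features")`)
#' @export
writeSkeletonContainer <- function(x, path, features = NULL) {
  if (methods::is(x, "GaitDataset")) {
    seqs <- x@sequences
    classNames <- x@classNames
  } else {
    seqs <- x
    classNames <- gaitClasses()
  }
  samples <- lapply(seqs, function(s) {
    list(
      positions = s@positions, subject_id = s@subjectId,
      class_label = s@classLabel, sample_id = s@sampleId, fps = s@fps
    )
  })
  names(samples) <- vapply(seqs, function(s) s@sampleId, character(1))
  feat <- NULL
  if (!is.null(features)) {
    feat <- lapply(features, function(bf) {
      list(joint = bf@joint, velocity = bf@velocity, bone = bf@bone)
    })
  }
  obj <- list(format = "stgait-container", version = 1L,
              class_names = classNames, samples = samples, features = feat)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeSkeletonContainer
#' @export
readSkeletonContainer <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "stgait-container"))
    stop("not a stgait sequence container: ", path)
  seqs <- lapply(obj$samples, function(s) {
    skeletonSequence(s$positions,
      subjectId = s$subject_id, classLabel = s$class_label,
      sampleId = s$sample_id, fps = s$fps
    )
  })
  names(seqs) <- NULL
  ds <- gaitDataset(seqs, classNames = obj$class_names)
  if (!is.null(obj$features)) {
    attr(ds, "features") <- lapply(obj$features, function(f) {
      methods::new("BranchFeatures", joint = f$joint, velocity = f$velocity, bone = f$bone)
    })
  }
  ds
}

#' Resample a sequence to a fixed number of frames
#'
#' Linear interpolation of every joint coordinate onto `tTarget` uniformly
#' spaced time points spanning the original frame range; the first and last
#' frames are preserved exactly, and resampling is idempotent at a fixed
#' target length.
#'
#' @param seq a [SkeletonSequence-class]
#' @param tTarget target frame count (at least 2)
#' @return a resampled [SkeletonSequence-class]
#' @export
resampleSequence <- function(seq, tTarget) {
  pos <- seq@positions
  tOld <- dim(pos)[1L]
  if (tTarget < 2L) stop("validation error: tTarget must be at least 2")
  if (!all(is.finite(pos))) stop("validation error: non-finite coordinates")
  if (tTarget == tOld) return(seq)
  u <- seq.int(0, tOld - 1L, length.out = tTarget)
  lo <- pmin(floor(u), tOld - 2)
  w <- u - lo
  out <- (1 - w) * pos[lo + 1L, , , drop = FALSE] + w * pos[lo + 2L, , , drop = FALSE]
  newFps <- seq@fps * (tTarget - 1) / (tOld - 1)
  skeletonSequence(out,
    subjectId = seq@subjectId, classLabel = seq@classLabel,
    sampleId = seq@sampleId, fps = newFps
  )
}

#' Export one sequence as a tidy CSV (frame, joint, x, y, z)
#'
#' @param seq a [SkeletonSequence-class]
#' @param path output path
#' @param graph optional graph supplying joint names
#' @return `path`, invisibly
#' @export
exportSequenceCSV <- function(seq, path, graph = NULL) {
  pos <- seq@positions
  tN <- dim(pos)[1L]; vN <- dim(pos)[2L]
  jn <- if (!is.null(graph)) graph@jointNames else paste0("J", seq_len(vN) - 1L)
  df <- data.frame(
    frame = rep(seq_len(tN), times = vN),
    joint = rep(jn, each = tN),
    x = as.vector(pos[, , 1L]),
    y = as.vector(pos[, , 2L]),
    z = as.vector(pos[, , 3L])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
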