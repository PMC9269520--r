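#' @include model.R features.R io.R
NULL

#' Precompute stacked branch tensors for a dataset
#'
#' Assembles the three 6-channel feature streams of every sequence (after
#' optional resampling to a common length) into dense `(6, T, N, V)` arrays,
#' the layout consumed by the network. Computing this once and reusing it
#' across folds and seeds avoids repeating the feature algebra.
#'
#' @param dataset a [GaitDataset-class]
#' @param graph a [SkeletonGraph-class]
#' @param tTarget common frame count (`NULL` keeps the native length, which
#'   must then be identical across sequences)
#' @return list with `x` (named list of branch arrays), `labels` (0-based),
#'   `subjects`, `sampleIds`, `classNames`
#' @export
prepareBranchData <- function(dataset, graph, tTarget = NULL) {
  n <- length(dataset@sequences)
  if (n == 0L) stop("validation error: empty dataset")
  seqs <- dataset@sequences
  if (!is.null(tTarget)) seqs <- lapply(seqs, resampleSequence, tTarget = tTarget)
  tLens <- vapply(seqs, function(s) dim(s@positions)[1L], integer(1))
  if (length(unique(tLens)) != 1L)
    stop("validation error: sequences have unequal lengths; supply tTarget")
  tN <- tLens[1L]
  v <- graph@numJoints
  x <- list(
    joint = array(0, c(6L, tN, n, v)),
    velocity = array(0, c(6L, tN, n, v)),
    bone = array(0, c(6L, tN, n, v))
  )
  for (i in seq_len(n)) {
    bf <- assembleBranches(seqs[[i]], graph)
    x$joint[, , i, ] <- bf@joint
    x$velocity[, , i, ] <- bf@velocity
    x$bone[, , i, ] <- bf@bone
  }
  list(
    x = x,
    labels = vapply(seqs, function(s) s@classLabel, integer(1)),
    subjects = vapply(seqs, function(s) s@subjectId, character(1)),
    sampleIds = vapply(seqs, function(s) s@sampleId, character(1)),
    classNames = dataset@classNames
  )
}

.subset_prepared <- function(data, idx) {
  list(
    x = lapply(data$x, function(a) a[, , idx, , drop = FALSE]),
    labels = data$labels[idx],
    subjects = data$subjects[idx],
    sampleIds = data$sampleIds[idx],
    classNames = data$classNames
  )
}

.as_prepared <- function(data, graph, tTarget = NULL) {
  if (methods::is(data, "GaitDataset")) prepareBranchData(data, graph, tTarget) else data
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is exactly that subject's
#' samples, the training set everything else, so train and test subject sets
#' are always disjoint and the test sets partition the dataset.
#'
#' @param dataset a [GaitDataset-class] or a [prepareBranchData()] result
#' @return list of folds, each with `heldOutSubject`, `trainIdx`, `testIdx`,
#'   `trainIds`, `testIds`
#' @export
losoSplits <- function(dataset) {
  if (methods::is(dataset, "GaitDataset")) {
    subjects <- vapply(dataset@sequences, function(s) s@subjectId, character(1))
    ids <- vapply(dataset@sequences, function(s) s@sampleId, character(1))
  } else {
    subjects <- dataset$subjects
    ids <- dataset$sampleIds
  }
  uniq <- unique(subjects)
  if (length(uniq) < 2L)
    stop("validation error: leave-one-subject-out needs at least 2 subjects")
  lapply(uniq, function(s) {
    test <- which(subjects == s)
    train <- which(subjects != s)
    list(
      heldOutSubject = s,
      trainIdx = train, testIdx = test,
      trainIds = ids[train], testIds = ids[test]
    )
  })
}

# Whether the fused compiled training path applies to this model
.use_fused <- function(model) {
  .engine_backend() == "cpp" && !model@config@edgeImportance
}

# Block descriptors (with parameter-name prefixes) for the fused engine
.fused_plans <- function(model) {
  meta <- .build_meta(model@config, model@graph@numJoints, model@branches)
  branchPlans <- lapply(model@branches, function(b) {
    lapply(seq_along(meta$branchBlocks), function(i) {
      c(meta$branchBlocks[[i]], list(prefix = sprintf("%s.blk%d.", b, i)))
    })
  })
  names(branchPlans) <- model@branches
  mainPlan <- lapply(seq_along(meta$mainBlocks), function(i) {
    c(meta$mainBlocks[[i]], list(prefix = sprintf("main.blk%d.", i)))
  })
  list(branch = branchPlans, main = mainPlan)
}

# One fused training step: exact batch-level batch norm outside, per-sample
# fused network forward/backward inside. Returns loss, logits, gradients for
# every parameter, and the updated batch-norm running state.
.fused_train_batch <- function(model, plans, dataX, idx, labels1,
                               statsOnly = FALSE, dropMask = NULL) {
  if (is.null(dropMask)) dropMask <- matrix(0, 0L, 0L)
  nb <- .cpp_net_batch(dataX[model@branches], as.integer(idx), plans$branch,
                       plans$main, model@params, model@state,
                       model@adj@partitions,
                       if (statsOnly) integer(0) else labels1,
                       !statsOnly, TRUE, FALSE, dropMask)
  state <- model@state
  for (site in names(nb$stats)) {
    state <- .ns_update_from(state, site, nb$stats[[site]]$mean, nb$stats[[site]]$var)
  }
  for (b in model@branches) {
    state <- .ns_update_from(state, paste0(b, ".bn."),
                             nb$bnStats[[b]]$mean, nb$bnStats[[b]]$var)
  }
  if (statsOnly) return(list(state = state))
  list(loss = nb$loss, logits = nb$logits, grads = nb$grads, state = state)
}

.fused_predict <- function(model, plans, dataX, idx, returnFeatures = FALSE) {
  nb <- .cpp_net_batch(dataX[model@branches], as.integer(idx), plans$branch,
                       plans$main, model@params, model@state,
                       model@adj@partitions, integer(0), FALSE, FALSE,
                       returnFeatures, matrix(0, 0L, 0L))
  if (returnFeatures) nb else nb$logits
}

.eval_report <- function(pred, truth, numClasses, perFold = numeric()) {
  cm <- matrix(0L, numClasses, numClasses)
  for (i in seq_along(pred)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  methods::new("EvalReport",
    accuracy = sum(diag(cm)) / max(1L, sum(cm)), confusion = cm, perFold = perFold
  )
}

#' Train an MIB ST-GCN
#'
#' Minimizes the softmax cross-entropy with Adam over shuffled minibatches.
#' Fully deterministic for a fixed `seed` (shuffling and the model's own
#' initialization seed are the only random elements). Branches absent from
#' the model are never materialized — a branch-ablated model is a smaller
#' architecture, not a zero-filled one.
#'
#' @param model an initialized [MIBModel-class]
#' @param data a [GaitDataset-class] or a [prepareBranchData()] result
#' @param epochs passes over the training set
#' @param lr Adam step size
#' @param batchSize minibatch size
#' @param weightDecay L2 coefficient
#' @param lrDecay apply step decay (rate quartered at each `decayAt`
#'   breakpoint)
#' @param decayAt epoch fractions at which the rate is quartered
#' @param dropout inverted-dropout probability on the pooled classifier
#'   features during training (0 disables)
#' @param seed shuffling seed
#' @param tTarget resampling length when `data` is a raw dataset
#' @param verbose print per-epoch loss/accuracy
#' @return list with the trained `model` and a `history` data frame
#'   (epoch, loss, accuracy)
#' @export
trainModel <- function(model, data, epochs = 6L, lr = 0.01, batchSize = 64L,
                       weightDecay = 1e-4, lrDecay = TRUE,
                       decayAt = c(0.6, 0.85), dropout = 0.3,
                       seed = 1L, tTarget = NULL, verbose = FALSE) {
  data <- .as_prepared(data, model@graph, tTarget)
  if (!all(model@branches %in% names(data$x)))
    stop("configuration error: data lacks branches required by the model")
  bad <- data$labels < 0L | data$labels >= model@config@numClasses
  if (any(is.na(data$labels)) || any(bad))
    stop("validation error: class labels outside [0, numClasses)")
  n <- length(data$labels)
  labels1 <- data$labels + 1L
  opt <- .adam_init(model@params)
  fused <- .use_fused(model)
  plans <- if (fused) .fused_plans(model)
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      # step decay: quarter the rate at each breakpoint fraction of epochs
      epLR <- if (lrDecay) {
        lr * 0.25^findInterval(ep / epochs, decayAt + 1e-9)
      } else {
        lr
      }
      ord <- sample.int(n)
      losses <- numeric()
      hits <- 0L
      cf <- model@config@mainChannels[2L]
      for (start in seq.int(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        dropMask <- if (dropout > 0) {
          matrix(stats::rbinom(cf * length(idx), 1L, 1 - dropout) / (1 - dropout),
                 cf, length(idx))
        }
        if (fused) {
          fb <- .fused_train_batch(model, plans, data$x, idx, labels1[idx],
                                   dropMask = dropMask)
          model@state <- fb$state
          losses <- c(losses, fb$loss)
          hits <- hits + sum(max.col(t(fb$logits), ties.method = "first") == labels1[idx])
          grads <- fb$grads
        } else {
          xb <- lapply(data$x[model@branches], function(a) a[, , idx, , drop = FALSE])
          fwd <- .net_forward(model, xb, train = TRUE, dropMask = dropMask)
          model@state <- fwd$state
          lo <- .softmax_xent(fwd$logits, labels1[idx])
          losses <- c(losses, lo$loss)
          hits <- hits + sum(max.col(t(fwd$logits), ties.method = "first") == labels1[idx])
          grads <- .net_backward(model, fwd, lo$dlogits)
        }
        step <- .adam_step(model@params, grads, opt, epLR, weightDecay = weightDecay)
        model@params <- step$params
        opt <- step$opt
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = mean(losses), accuracy = hits / n
      ))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, train accuracy %.4f",
                        ep, mean(losses), hits / n))
    }
  })
  list(model = model, history = history)
}

#' Predict class labels
#'
#' Argmax of the logits in evaluation mode (batch-norm running moments); at
#' exactly tied logits the lowest class index wins.
#'
#' @param model a trained [MIBModel-class]
#' @param data a [GaitDataset-class] or prepared data
#' @param batchSize evaluation batch size
#' @param tTarget resampling length for raw datasets
#' @return list with `labels` (0-based predictions) and `logits`
#'   (numClasses-by-N)
#' @export
predictClasses <- function(model, data, batchSize = 128L, tTarget = NULL) {
  data <- .as_prepared(data, model@graph, tTarget)
  n <- length(data$labels)
  fused <- .use_fused(model)
  plans <- if (fused) .fused_plans(model)
  logits <- matrix(NA_real_, model@config@numClasses, n)
  if (fused) {
    for (start in seq.int(1L, n, by = batchSize)) {
      idx <- start:min(start + batchSize - 1L, n)
      logits[, idx] <- .fused_predict(model, plans, data$x, idx)
    }
  } else {
    for (start in seq.int(1L, n, by = batchSize)) {
      idx <- start:min(start + batchSize - 1L, n)
      xb <- lapply(data$x[model@branches], function(a) a[, , idx, , drop = FALSE])
      fwd <- .net_forward(model, xb, train = FALSE)
      logits[, idx] <- fwd$logits
    }
  }
  list(labels = max.col(t(logits), ties.method = "first") - 1L, logits = logits)
}

#' Evaluate a trained model
#'
#' @param model a trained [MIBModel-class]
#' @param data a [GaitDataset-class] or prepared data
#' @param tTarget resampling length for raw datasets
#' @return an [EvalReport-class]
#' @export
evaluateModel <- function(model, data, tTarget = NULL) {
  data <- .as_prepared(data, model@graph, tTarget)
  if (any(is.na(data$labels)) ||
      any(data$labels < 0L | data$labels >= model@config@numClasses))
    stop("validation error: test labels outside the training label set")
  pred <- predictClasses(model, data)
  .eval_report(pred$labels, data$labels, model@config@numClasses)
}

#' Leave-one-subject-out cross-validation of the MIB ST-GCN
#'
#' Trains one model per fold on all remaining subjects and evaluates on the
#' held-out subject, pooling the confusion matrix across folds. Reports both
#' the pooled-sample accuracy and the per-fold accuracies (whose mean is the
#' fold-mean accuracy).
#'
#' @param data a [GaitDataset-class] or a [prepareBranchData()] result
#' @param config a [ModelConfig-class] (its seed is combined with `seed` per
#'   fold)
#' @param graph skeleton graph
#' @param branches active input branches
#' @param seed root seed for fold-model initialization and shuffling
#' @param returnModels keep the per-fold trained models (in `attr(,
#'   "models")`)
#' @param tTarget resampling length for raw datasets
#' @param verbose print per-fold accuracy
#' @param ... passed to [trainModel()] (epochs, lr, batchSize, ...)
#' @return an [EvalReport-class] with per-fold accuracies
#' @export
losoCrossValidate <- function(data, config, graph = kinectV2Graph(),
                              branches = c("joint", "velocity", "bone"),
                              seed = 1L, returnModels = FALSE, tTarget = NULL,
                              verbose = FALSE, ...) {
  data <- .as_prepared(data, graph, tTarget)
  folds <- losoSplits(data)
  preds <- integer(length(data$labels))
  perFold <- numeric(length(folds))
  names(perFold) <- vapply(folds, `[[`, character(1), "heldOutSubject")
  models <- if (returnModels) vector("list", length(folds)) else NULL
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    cfg <- config
    cfg@seed <- as.integer((config@seed + 7919L * fi + seed) %% .Machine$integer.max)
    model <- buildMIBNetwork(cfg, graph, branches = branches,
                             classNames = data$classNames)
    fit <- trainModel(model, .subset_prepared(data, fold$trainIdx),
                      seed = seed + fi, ...)
    pr <- predictClasses(fit$model, .subset_prepared(data, fold$testIdx))
    preds[fold$testIdx] <- pr$labels
    perFold[fi] <- mean(pr$labels == data$labels[fold$testIdx])
    if (returnModels) models[[fi]] <- fit$model
    if (verbose)
      message(sprintf("fold %s: accuracy %.4f", fold$heldOutSubject, perFold[fi]))
  }
  rep <- .eval_report(preds, data$labels, config@numClasses, perFold = perFold)
  if (returnModels) attr(rep, "models") <- models
  rep
}

#' Branch-ablation study
#'
#' Runs leave-one-subject-out cross-validation for every nonempty combination
#' of the three input branches (3 singles, 3 pairs, 1 triple) and tabulates
#' the accuracies.
#'
#' @param data a [GaitDataset-class] or prepared data
#' @param config a [ModelConfig-class]
#' @param graph skeleton graph
#' @param seed root seed
#' @param combos list of branch combinations (default: all 7)
#' @param verbose print progress
#' @param ... passed to [trainModel()]
#' @return data frame with columns `branches`, `accuracy`, `foldMean`
#' @export
branchAblation <- function(data, config, graph = kinectV2Graph(), seed = 1L,
                           combos = NULL, verbose = FALSE, ...) {
  data <- .as_prepared(data, graph)
  if (is.null(combos)) {
    b <- c("joint", "velocity", "bone")
    combos <- c(
      lapply(b, identity),
      list(b[1:2], b[c(1, 3)], b[2:3], b)
    )
  }
  rows <- lapply(combos, function(cb) {
    rep <- losoCrossValidate(data, config, graph, branches = cb, seed = seed, ...)
    if (verbose)
      message(sprintf("[%s] accuracy %.4f", paste(cb, collapse = "+"), rep@accuracy))
    data.frame(
      branches = paste(cb, collapse = "+"),
      accuracy = rep@accuracy,
      foldMean = mean(rep@perFold),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
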