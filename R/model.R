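#' @include AllClasses.R engine.R
NULL

#' Create a network configuration
#'
#' Defaults describe the full-size architecture: per-branch widths
#' 64-32-32-64 with a narrow middle (a bottleneck that keeps the model
#' compact), mainstream widths 128 and 256, temporal kernel 9, two temporal
#' layers per block, separable temporal convolutions and branch-block
#' attention. All widths are configurable; [benchmarkModelConfig()] returns
#' the reduced setting used on the synthetic benchmark.
#'
#' @param branchChannels four per-branch block output widths.
#' @param mainChannels two mainstream block output widths.
#' @param blockDepth temporal layers per block.
#' @param temporalKernel odd temporal kernel size.
#' @param attentionReduction bottleneck divisor r of the attention module.
#' @param strategy spatial partition strategy.
#' @param numClasses number of output classes.
#' @param separable depthwise-separable temporal convolutions.
#' @param attentionOn attention in the three upper branch blocks.
#' @param attentionMainstream also attend in the mainstream.
#' @param edgeImportance learnable mask on each partition matrix.
#' @param seed weight-initialization seed.
#' @return a [ModelConfig-class]
#' @export
modelConfig <- function(branchChannels = c(64L, 32L, 32L, 64L),
                        mainChannels = c(128L, 256L),
                        blockDepth = 2L,
                        temporalKernel = 9L,
                        attentionReduction = 4L,
                        strategy = "spatial-configuration",
                        numClasses = 6L,
                        separable = TRUE,
                        attentionOn = TRUE,
                        attentionMainstream = FALSE,
                        edgeImportance = FALSE,
                        seed = 1L) {
  methods::new("ModelConfig",
    branchChannels = as.integer(branchChannels),
    mainChannels = as.integer(mainChannels),
    blockDepth = as.integer(blockDepth),
    temporalKernel = as.integer(temporalKernel),
    attentionReduction = as.integer(attentionReduction),
    strategy = strategy,
    numClasses = as.integer(numClasses),
    separable = isTRUE(separable),
    attentionOn = isTRUE(attentionOn),
    attentionMainstream = isTRUE(attentionMainstream),
    edgeImportance = isTRUE(edgeImportance),
    seed = as.integer(seed)
  )
}

#' Reduced configuration for the synthetic benchmark
#'
#' A narrow variant of the architecture (branch width 8, mainstream 16 then
#' 64, kernel 5, one temporal layer per block) sized so that the full
#' leave-one-subject-out harness runs in minutes on a single CPU while
#' keeping every architectural element: three branches, partitioned graph
#' convolution, striding mainstream, attention, separable temporal layers.
#' The mainstream widens into its final block: after global average pooling
#' over all frames and joints the classifier sees only one number per
#' channel, so the width of the last feature map bounds how many joint- and
#' phase-selective statistics survive the pooling — and that block runs at a
#' quarter of the input length, where width is cheap.
#'
#' @param numClasses number of classes
#' @param seed weight-initialization seed
#' @return a [ModelConfig-class]
#' @export
benchmarkModelConfig <- function(numClasses = 6L, seed = 1L) {
  modelConfig(
    branchChannels = c(8L, 8L, 8L, 8L),
    mainChannels = c(16L, 64L),
    blockDepth = 1L,
    temporalKernel = 5L,
    attentionReduction = 4L,
    numClasses = numClasses,
    seed = seed
  )
}

# layer plan: dimensions and flags per block, derived from config + branches
.build_meta <- function(config, nJoints, branches) {
  K <- switch(config@strategy,
    "uni-label" = 1L, "distance" = 2L, "spatial-configuration" = 3L
  )
  blockMeta <- function(cin, cout, stride, attention) {
    list(
      cin = cin, cout = cout, stride = stride,
      kernel = config@temporalKernel, depth = config@blockDepth,
      separable = config@separable, attention = attention,
      r = config@attentionReduction, K = K,
      edgeImportance = config@edgeImportance,
      needProj = (cin != cout) || (stride > 1L)
    )
  }
  bc <- config@branchChannels
  branchBlocks <- list(
    blockMeta(6L, bc[1L], 1L, FALSE),
    blockMeta(bc[1L], bc[2L], 1L, config@attentionOn),
    blockMeta(bc[2L], bc[3L], 1L, config@attentionOn),
    blockMeta(bc[3L], bc[4L], 1L, config@attentionOn)
  )
  cc <- length(branches) * bc[4L]
  mc <- config@mainChannels
  attMain <- config@attentionOn && config@attentionMainstream
  mainBlocks <- list(
    blockMeta(cc, mc[1L], 2L, attMain),
    blockMeta(mc[1L], mc[2L], 2L, attMain)
  )
  list(
    branches = branches, branchBlocks = branchBlocks, mainBlocks = mainBlocks,
    K = K, nJoints = nJoints, concatChannels = cc,
    numClasses = config@numClasses
  )
}

.init_block_params <- function(params, prefix, mb, nJoints) {
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan)), nr, nc)
  for (k in seq_len(mb$K)) {
    params[[paste0(prefix, "gcn.W", k)]] <- he(mb$cin, mb$cout, mb$cin)
    if (mb$edgeImportance) {
      params[[paste0(prefix, "gcn.mask", k)]] <- matrix(1, nJoints, nJoints)
    }
  }
  params[[paste0(prefix, "gcn.b")]] <- numeric(mb$cout)
  for (j in seq_len(mb$depth)) {
    p <- sprintf("%stc%d.", prefix, j)
    if (mb$separable) {
      params[[paste0(p, "Wd")]] <- matrix(stats::rnorm(mb$cout * mb$kernel, sd = sqrt(2 / mb$kernel)), mb$cout, mb$kernel)
      params[[paste0(p, "Wp")]] <- he(mb$cout, mb$cout, mb$cout)
    } else {
      params[[paste0(p, "W")]] <- array(
        stats::rnorm(mb$cout * mb$cout * mb$kernel, sd = sqrt(2 / (mb$cout * mb$kernel))),
        c(mb$cout, mb$cout, mb$kernel)
      )
    }
    params[[paste0(p, "b")]] <- numeric(mb$cout)
  }
  if (mb$needProj) {
    params[[paste0(prefix, "res.W")]] <- he(mb$cin, mb$cout, mb$cin)
  }
  if (mb$attention) {
    cr <- mb$cout %/% mb$r
    params[[paste0(prefix, "att.W1")]] <- he(mb$cout, cr, mb$cout)
    params[[paste0(prefix, "att.b1")]] <- numeric(cr)
    params[[paste0(prefix, "att.Wt")]] <- he(cr, mb$cout, cr)
    # gates start nearly open (sigmoid(3) ~ 0.95): the block behaves like its
    # attention-free ablation early in training and the gates engage as the
    # attention heads learn, which stabilizes optimization
    params[[paste0(prefix, "att.bt")]] <- rep(3, mb$cout)
    params[[paste0(prefix, "att.Wv")]] <- he(cr, mb$cout, cr)
    params[[paste0(prefix, "att.bv")]] <- rep(3, mb$cout)
  }
  params
}

# running-statistics state entries for every standardization site of a block
.init_block_state <- function(state, prefix, mb) {
  sites <- c(paste0(prefix, "gcn.ns."), sprintf("%stc%d.ns.", prefix, seq_len(mb$depth)))
  if (mb$needProj) sites <- c(sites, paste0(prefix, "res.ns."))
  for (s in sites) {
    state[[paste0(s, "mean")]] <- numeric(mb$cout)
    state[[paste0(s, "var")]] <- rep(1, mb$cout)
    state[[paste0(s, "n")]] <- 0L
  }
  state
}

.init_mib_params <- function(config, graph, branches) {
  meta <- .build_meta(config, graph@numJoints, branches)
  .with_seed(config@seed, {
    params <- list()
    state <- list()
    for (b in branches) {
      params[[paste0(b, ".bn.gamma")]] <- matrix(1, 6L, graph@numJoints)
      params[[paste0(b, ".bn.beta")]] <- matrix(0, 6L, graph@numJoints)
      state[[paste0(b, ".bn.mean")]] <- matrix(0, 6L, graph@numJoints)
      state[[paste0(b, ".bn.var")]] <- matrix(1, 6L, graph@numJoints)
      state[[paste0(b, ".bn.n")]] <- 0L
      for (i in seq_along(meta$branchBlocks)) {
        params <- .init_block_params(
          params, sprintf("%s.blk%d.", b, i), meta$branchBlocks[[i]], graph@numJoints
        )
        state <- .init_block_state(state, sprintf("%s.blk%d.", b, i), meta$branchBlocks[[i]])
      }
    }
    for (i in seq_along(meta$mainBlocks)) {
      params <- .init_block_params(
        params, sprintf("main.blk%d.", i), meta$mainBlocks[[i]], graph@numJoints
      )
      state <- .init_block_state(state, sprintf("main.blk%d.", i), meta$mainBlocks[[i]])
    }
    cLast <- meta$mainBlocks[[2L]]$cout
    params[["fc.W"]] <- matrix(stats::rnorm(cLast * config@numClasses, sd = sqrt(1 / cLast)),
                               cLast, config@numClasses)
    params[["fc.b"]] <- numeric(config@numClasses)
    list(params = params, state = state, meta = meta)
  })
}

#' Build the multiple-input-branch ST-GCN
#'
#' Assembles the full network: per-branch input batch normalization (over the
#' flattened channel-joint axis), an initial ST-GCN block, three
#' attention-equipped ST-GCN blocks per branch, channel concatenation of the
#' active branches, a two-block mainstream whose first temporal layer in each
#' block strides by 2, and a global-average-pool plus fully-connected
#' classifier.
#'
#' @param config a [ModelConfig-class]
#' @param graph a [SkeletonGraph-class]
#' @param branches active input branches (nonempty subset of
#'   `c("joint", "velocity", "bone")`)
#' @param classNames optional class label names
#' @return an initialized [MIBModel-class]
#' @examples
#' model <- buildMIBNetwork(benchmarkModelConfig(), kinectV2Graph())
#' model
#' @export
buildMIBNetwork <- function(config, graph,
                            branches = c("joint", "velocity", "bone"),
                            classNames = NULL) {
  if (!length(branches)) stop("configuration error: empty branch selection")
  branches <- match.arg(branches, c("joint", "velocity", "bone"), several.ok = TRUE)
  methods::validObject(config)
  init <- .init_mib_params(config, graph, branches)
  if (is.null(classNames)) {
    classNames <- if (config@numClasses == 6L) gaitClasses() else paste0("class", seq_len(config@numClasses) - 1L)
  }
  methods::new("MIBModel",
    config = config, graph = graph,
    adj = partitionAdjacency(graph, config@strategy),
    branches = branches, params = init$params, state = init$state,
    classNames = classNames
  )
}

# full network forward pass.
# xlist: named list of (6, T, N, V) arrays for the active branches.
.net_forward <- function(model, xlist, train = FALSE, forceAttIdentity = FALSE,
                         collectFeatures = FALSE, collectScores = FALSE,
                         dropMask = NULL) {
  params <- model@params
  state <- model@state
  meta <- .build_meta(model@config, model@graph@numJoints, model@branches)
  A <- model@adj@partitions
  caches <- list(branches = list(), main = list())
  scores <- if (collectScores) list() else NULL
  outs <- vector("list", length(model@branches))
  names(outs) <- model@branches
  for (b in model@branches) {
    bn <- .fw_bn_any(params, state, paste0(b, ".bn."), xlist[[b]], train)
    state <- bn$state
    h <- bn$out
    bcaches <- list(bn = bn$cache, blocks = vector("list", length(meta$branchBlocks)))
    for (i in seq_along(meta$branchBlocks)) {
      blk <- .fw_block(params, state, sprintf("%s.blk%d.", b, i), h, A,
                       meta$branchBlocks[[i]], train, forceAttIdentity)
      state <- blk$state
      h <- blk$out
      bcaches$blocks[[i]] <- blk$cache
      if (collectScores && !is.null(blk$frameScores)) {
        scores[[sprintf("%s.blk%d", b, i)]] <-
          list(frame = blk$frameScores, joint = blk$jointScores)
      }
    }
    outs[[b]] <- h
    caches$branches[[b]] <- bcaches
  }
  # concatenate along the channel axis
  d1 <- dim(outs[[1L]])
  cc <- meta$concatChannels
  H <- array(0, c(cc, d1[2L], d1[3L], d1[4L]))
  off <- 0L
  for (b in model@branches) {
    cb <- dim(outs[[b]])[1L]
    H[off + seq_len(cb), , , ] <- outs[[b]]
    off <- off + cb
  }
  caches$concatDims <- lapply(outs, function(o) dim(o)[1L])
  for (i in seq_along(meta$mainBlocks)) {
    blk <- .fw_block(params, state, sprintf("main.blk%d.", i), H, A,
                     meta$mainBlocks[[i]], train, forceAttIdentity)
    state <- blk$state
    H <- blk$out
    caches$main[[i]] <- blk$cache
    if (collectScores && !is.null(blk$frameScores)) {
      scores[[sprintf("main.blk%d", i)]] <-
        list(frame = blk$frameScores, joint = blk$jointScores)
    }
  }
  head <- .fw_head(params, H, dropMask = if (train) dropMask)
  list(
    logits = head$out, caches = caches, headCache = head$cache,
    state = state, meta = meta,
    features = if (collectFeatures) H else NULL,
    scores = scores
  )
}

.net_backward <- function(model, fwd, dLogits, forceAttIdentity = FALSE) {
  params <- model@params
  meta <- fwd$meta
  A <- model@adj@partitions
  hb <- .bw_head(params, fwd$headCache, dLogits)
  grads <- hb$grads
  dH <- hb$dx
  for (i in rev(seq_along(meta$mainBlocks))) {
    bb <- .bw_block(params, sprintf("main.blk%d.", i), fwd$caches$main[[i]],
                    dH, A, meta$mainBlocks[[i]])
    dH <- bb$dx
    grads <- .merge_grads(grads, bb$grads)
  }
  off <- 0L
  for (b in model@branches) {
    cb <- fwd$caches$concatDims[[b]]
    dBranch <- dH[off + seq_len(cb), , , , drop = FALSE]
    off <- off + cb
    for (i in rev(seq_along(meta$branchBlocks))) {
      bb <- .bw_block(params, sprintf("%s.blk%d.", b, i),
                      fwd$caches$branches[[b]]$blocks[[i]],
                      dBranch, A, meta$branchBlocks[[i]])
      dBranch <- bb$dx
      grads <- .merge_grads(grads, bb$grads)
    }
    bnb <- .bw_bn_any(params, paste0(b, ".bn."), fwd$caches$branches[[b]]$bn, dBranch)
    grads <- .merge_grads(grads, bnb$grads)
  }
  grads
}

#' Count trainable parameters
#'
#' Enumerates every weight array of the model with its shape and size. With
#' `separableComparison = TRUE` the report also lists, for each temporal
#' layer, the weight count of a standard convolution (`kernel * Cin * Cout`)
#' against its depthwise-separable factorization (`kernel * Cin + Cin * Cout`,
#' biases excluded from both).
#'
#' @param model an [MIBModel-class]
#' @param separableComparison also report standard-vs-separable counts
#' @return a list with `layers` (data frame of name/shape/count), `total`,
#'   and optionally `temporalComparison`
#' @export
countParameters <- function(model, separableComparison = FALSE) {
  params <- model@params
  shapes <- vapply(params, function(p) {
    paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x")
  }, character(1))
  counts <- vapply(params, length, integer(1))
  out <- list(
    layers = data.frame(
      name = names(params), shape = unname(shapes), count = unname(counts),
      stringsAsFactors = FALSE
    ),
    total = sum(counts)
  )
  if (separableComparison) {
    meta <- .build_meta(model@config, model@graph@numJoints, model@branches)
    rows <- list()
    addBlocks <- function(blocks, label) {
      for (i in seq_along(blocks)) {
        mb <- blocks[[i]]
        for (j in seq_len(mb$depth)) {
          rows[[length(rows) + 1L]] <<- data.frame(
            layer = sprintf("%s.blk%d.tc%d", label, i, j),
            kernel = mb$kernel, cin = mb$cout, cout = mb$cout,
            standard = mb$kernel * mb$cout * mb$cout,
            separable = mb$kernel * mb$cout + mb$cout * mb$cout,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    for (b in model@branches) addBlocks(meta$branchBlocks, b)
    addBlocks(meta$mainBlocks, "main")
    out$temporalComparison <- do.call(rbind, rows)
  }
  out
}

#' Weight count of one temporal layer, standard vs separable
#'
#' Closed-form weight counts (biases excluded): a standard temporal
#' convolution holds `kernel * cin * cout` weights; its depthwise-separable
#' factorization holds `kernel * cin` depthwise plus `cin * cout` pointwise
#' weights.
#'
#' @param cin,cout channel widths
#' @param kernel temporal kernel size
#' @return named numeric vector with elements `standard` and `separable`
#' @examples
#' temporalLayerWeights(64, 64, 9) # 36864 vs 4672
#' @export
temporalLayerWeights <- function(cin, cout, kernel) {
  c(standard = kernel * cin * cout, separable = kernel * cin + cin * cout)
}

# relabel the joints of a model by permutation perm (joint i -> perm[i]),
# permuting every V-indexed parameter consistently
.permute_model <- function(model, perm) {
  inv <- order(perm)
  params <- model@params
  for (nm in names(params)) {
    if (grepl("\\.bn\\.(gamma|beta)$", nm)) {
      params[[nm]] <- params[[nm]][, inv, drop = FALSE]
    }
    if (grepl("\\.gcn\\.mask\\d+$", nm)) {
      params[[nm]] <- params[[nm]][inv, inv, drop = FALSE]
    }
  }
  state <- model@state
  for (nm in grep("\\.bn\\.(mean|var)$", names(state), value = TRUE)) {
    state[[nm]] <- state[[nm]][, inv, drop = FALSE]
  }
  graph2 <- .permute_graph(model@graph, perm)
  methods::new("MIBModel",
    config = model@config, graph = graph2,
    adj = partitionAdjacency(graph2, model@config@strategy),
    branches = model@branches, params = params, state = state,
    classNames = model@classNames
  )
}
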