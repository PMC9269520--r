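test_that("spatial graph convolution reduces to known closed forms", {
  # edgeless graph: A_norm = I, so W = I and b = 0 is the identity map
  g <- skeletonGraph(matrix(integer(), ncol = 2), numJoints = 3, centerJoint = 1)
  adj <- partitionAdjacency(g, "uni-label")
  x <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  out <- spatialGraphConv(x, adj, list(diag(2)), activation = "identity")
  expect_equal(out, x, tolerance = 1e-12)

  # single joint: a per-frame linear map of the channel vector
  g1 <- skeletonGraph(matrix(integer(), ncol = 2), numJoints = 1, centerJoint = 1)
  adj1 <- partitionAdjacency(g1, "uni-label")
  W <- matrix(rnorm(6), 2, 3)
  b <- rnorm(3)
  x1 <- array(rnorm(2 * 5 * 1), c(2, 5, 1))
  out1 <- spatialGraphConv(x1, adj1, list(W), b, activation = "identity")
  expect_equal(out1[, , 1], t(W) %*% x1[, , 1] + b, tolerance = 1e-12)
})

test_that("graph convolution matches a per-node neighbor-sum loop oracle", {
  set.seed(31)
  for (rep in 1:5) {
    g <- randomTree(6)
    adj <- partitionAdjacency(g, "uni-label")
    A <- partitions(adj)[[1]]
    C <- 3L; Tn <- 4L
    W <- matrix(rnorm(C * C), C, C)
    b <- rnorm(C)
    x <- array(rnorm(C * Tn * 6), c(C, Tn, 6))
    out <- spatialGraphConv(x, adj, list(W), b, activation = "identity")
    # oracle: explicit loop over nodes and weighted neighbors
    expected <- array(0, dim(out))
    for (t in seq_len(Tn)) {
      for (i in 1:6) {
        acc <- numeric(C)
        for (j in 1:6) {
          if (A[j, i] != 0) acc <- acc + A[j, i] * as.numeric(t(W) %*% x[, t, j])
        }
        expected[, t, i] <- acc + b
      }
    }
    expect_lt(max(abs(out - expected)), 1e-5)
  }
})

test_that("temporal convolution passes identity configurations through", {
  C <- 3L; Tn <- 6L; V <- 2L
  x <- array(rnorm(C * Tn * V), c(C, Tn, V))
  # kernel 1, identity weights
  W <- array(0, c(C, C, 1))
  W[, , 1] <- diag(C)
  expect_equal(temporalConv(x, W, kernel = 1L), x, tolerance = 1e-12)
  # separable: centered delta depthwise + identity pointwise
  Wd <- matrix(0, C, 3)
  Wd[, 2] <- 1
  out <- temporalConv(x, list(Wd = Wd, Wp = diag(C)), kernel = 3L, separable = TRUE)
  expect_equal(out, x, tolerance = 1e-12)
  # stride 2 halves the length, ceiling(T / stride)
  out2 <- temporalConv(x, W, kernel = 1L, stride = 2L)
  expect_equal(dim(out2), c(C, 3L, V))
  x64 <- array(0, c(1, 64, 1))
  expect_equal(dim(temporalConv(x64, array(1, c(1, 1, 1)), 1L, stride = 2L))[2], 32L)
  expect_error(temporalConv(x, W, kernel = 2L), "odd")
})

test_that("attention scores stay inside (0,1) and the mask factorizes", {
  set.seed(17)
  C <- 8L; Tn <- 10L; V <- 5L
  x <- array(rnorm(C * Tn * V), c(C, Tn, V))
  p <- initAttentionParams(C, r = 4L, seed = 2)
  res <- stJointAttention(x, p)
  expect_true(all(res$frameScores > 0 & res$frameScores < 1))
  expect_true(all(res$jointScores > 0 & res$jointScores < 1))
  # output / input recovers the outer-product mask wherever x != 0
  mask <- res$output / x
  for (t in c(1L, 4L)) {
    for (v in c(2L, 5L)) {
      expect_equal(mask[, t, v], res$frameScores[, t] * res$jointScores[, v],
                   tolerance = 1e-6)
    }
  }
  # identity mode returns the input exactly
  idres <- stJointAttention(x, p, forceIdentity = TRUE)
  expect_identical(idres$output, x)
  # constant input: scores constant over frames and joints
  xc <- array(rep(rnorm(C), Tn * V), c(C, Tn, V))
  resc <- stJointAttention(xc, p)
  expect_lt(max(abs(resc$frameScores - resc$frameScores[, 1])), 1e-12)
  expect_lt(max(abs(resc$jointScores - resc$jointScores[, 1])), 1e-12)
  expect_error(initAttentionParams(6L, r = 4L), "divide")
})

test_that("an ST-GCN block honors its shape and degenerate contracts", {
  g <- tinyGraph()
  adj <- partitionAdjacency(g)
  cfg <- tinyConfig()
  x <- array(rnorm(4 * 8 * 4), c(4, 8, 4))
  # zero input with zero biases gives zero output
  blk <- stgcnBlock(array(0, dim(x)), adj, cout = 5L, config = cfg, seed = 3)
  expect_true(all(blk$output == 0))
  # stride-2 block halves T and moves to the requested width
  blk2 <- stgcnBlock(x, adj, cout = 6L, stride = 2L, config = cfg, seed = 3)
  expect_equal(dim(blk2$output), c(6L, 4L, 4L))
  # disabling attention equals forcing the identity mask, bit for bit
  off <- stgcnBlock(x, adj, cout = 4L, config = cfg, attention = FALSE, seed = 4)
  forced <- stgcnBlock(x, adj, cout = 4L, config = cfg, attention = TRUE,
                       seed = 4, params = c(off$params,
                         stgait:::.with_seed(4, stgait:::.init_block_params(
                           list(), "blk.",
                           list(cin = 4L, cout = 4L, stride = 1L,
                                kernel = cfg@temporalKernel, depth = cfg@blockDepth,
                                separable = cfg@separable, attention = TRUE,
                                r = cfg@attentionReduction, K = 3L,
                                edgeImportance = FALSE, needProj = FALSE),
                           4L))[c("blk.att.W1", "blk.att.b1", "blk.att.Wt",
                                  "blk.att.bt", "blk.att.Wv", "blk.att.bv")]),
                       forceAttIdentity = TRUE)
  expect_identical(off$output, forced$output)
})

test_that("network logits have the right shape and are finite", {
  g <- tinyGraph()
  model <- buildMIBNetwork(tinyConfig(), g)
  xl <- randomBranchInputs(8L, 5L, 4L, seed = 6)
  fwd <- stgait:::.net_forward(model, xl, train = FALSE)
  expect_equal(dim(fwd$logits), c(3L, 5L))
  expect_true(all(is.finite(fwd$logits)))
})

test_that("parameter counts match independent enumeration", {
  g <- tinyGraph()
  cfg <- tinyConfig()
  model <- buildMIBNetwork(cfg, g)
  counted <- countParameters(model)
  # independent closed-form enumeration of the declared layout
  blockCount <- function(cin, cout, K, kernel, depth, sep, att, r, proj) {
    n <- K * cin * cout + cout # gcn weights + bias
    for (j in seq_len(depth)) {
      n <- n + (if (sep) cout * kernel + cout * cout else cout * cout * kernel) + cout
    }
    if (proj) n <- n + cin * cout
    if (att) {
      cr <- cout / r
      n <- n + cout * cr + cr + 2 * (cr * cout + cout)
    }
    n
  }
  bc <- cfg@branchChannels
  mc <- cfg@mainChannels
  K <- 3
  total <- 0
  for (b in 1:3) {
    total <- total + 2 * 6 * 4 # input batch-norm gamma/beta over 6 x V
    chain <- c(6L, bc)
    for (i in 1:4) {
      total <- total + blockCount(chain[i], chain[i + 1], K, cfg@temporalKernel,
                                  cfg@blockDepth, cfg@separable, i > 1,
                                  cfg@attentionReduction, chain[i] != chain[i + 1])
    }
  }
  cc <- 3 * bc[4]
  mchain <- c(cc, mc)
  for (i in 1:2) {
    total <- total + blockCount(mchain[i], mchain[i + 1], K, cfg@temporalKernel,
                                cfg@blockDepth, cfg@separable, FALSE,
                                cfg@attentionReduction, TRUE)
  }
  total <- total + mc[2] * cfg@numClasses + cfg@numClasses
  expect_equal(counted$total, total)
})

test_that("separable temporal layers have the closed-form weight counts", {
  w <- temporalLayerWeights(64, 64, 9)
  expect_equal(unname(w["standard"]), 36864)
  expect_equal(unname(w["separable"]), 4672)
  # separable is smaller whenever kernel > 1 and cout > 1
  for (k in c(3, 5, 9)) {
    for (co in c(2, 8, 32)) {
      ww <- temporalLayerWeights(16, co, k)
      expect_lt(ww["separable"], ww["standard"])
    }
  }
  # 1x1 kernel: no reduction, only depthwise overhead
  w1 <- temporalLayerWeights(16, 16, 1)
  expect_equal(unname(w1["separable"] - w1["standard"]), 16)
})

test_that("doubling widths strictly increases the parameter count", {
  g <- tinyGraph()
  m1 <- buildMIBNetwork(tinyConfig(), g)
  m2 <- buildMIBNetwork(tinyConfig(branchChannels = c(8L, 8L, 8L, 8L),
                                   mainChannels = c(12L, 16L)), g)
  expect_gt(countParameters(m2)$total, countParameters(m1)$total)
})

test_that("logits are invariant under consistent joint relabeling", {
  set.seed(23)
  g <- kinectV2Graph()
  cfg <- modelConfig(branchChannels = c(4L, 4L, 4L, 4L), mainChannels = c(6L, 8L),
                     blockDepth = 1L, temporalKernel = 3L, attentionReduction = 2L,
                     numClasses = 4L, seed = 2L)
  model <- buildMIBNetwork(cfg, g)
  xl <- randomBranchInputs(6L, 2L, 25L, seed = 3)
  fwd <- stgait:::.net_forward(model, xl, train = FALSE)
  perm <- sample.int(25L)
  model2 <- stgait:::.permute_model(model, perm)
  xl2 <- lapply(xl, function(a) {
    out <- a
    out[, , , perm] <- a
    out
  })
  fwd2 <- stgait:::.net_forward(model2, xl2, train = FALSE)
  expect_lt(max(abs(fwd$logits - fwd2$logits)), 1e-4)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  g <- tinyGraph()
  for (sep in c(TRUE, FALSE)) {
    cfg <- tinyConfig(separable = sep, edgeImportance = TRUE)
    model <- buildMIBNetwork(cfg, g)
    # jitter away from exact rectifier kinks where the loss is not smooth
    model@params <- lapply(model@params, function(p) p + rnorm(length(p), sd = 0.05))
    xl <- randomBranchInputs(6L, 3L, 4L, seed = 7)
    labels <- c(1L, 2L, 3L)
    lossAt <- function(params) {
      m <- model
      m@params <- params
      fwd <- stgait:::.net_forward(m, xl, train = TRUE)
      stgait:::.softmax_xent(fwd$logits, labels)$loss
    }
    fwd <- stgait:::.net_forward(model, xl, train = TRUE)
    lo <- stgait:::.softmax_xent(fwd$logits, labels)
    grads <- stgait:::.net_backward(model, fwd, lo$dlogits)
    expect_setequal(names(grads), names(model@params))
    worst <- 0
    for (nm in names(model@params)) {
      idx <- sample(length(model@params[[nm]]), min(2L, length(model@params[[nm]])))
      for (i in idx) {
        eps <- 1e-6
        pp <- model@params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- model@params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
        ana <- grads[[nm]][i]
        worst <- max(worst, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
      }
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("the fused compiled engine agrees with the reference engine", {
  skip_if_not(stgait:::.engine_backend() == "cpp")
  set.seed(2)
  g <- tinyGraph()
  cfg <- tinyConfig()
  model <- buildMIBNetwork(cfg, g)
  model@params <- lapply(model@params, function(p) p + rnorm(length(p), sd = 0.05))
  xl <- randomBranchInputs(8L, 4L, 4L, seed = 9)
  labels1 <- c(1L, 2L, 3L, 1L)
  plans <- stgait:::.fused_plans(model)
  fb <- stgait:::.fused_train_batch(model, plans, xl, seq_len(4L), labels1)
  fwd <- stgait:::.net_forward(model, xl, train = TRUE)
  lo <- stgait:::.softmax_xent(fwd$logits, labels1)
  grads <- stgait:::.net_backward(model, fwd, lo$dlogits)
  expect_lt(max(abs(fb$logits - fwd$logits)), 1e-4)
  expect_lt(abs(fb$loss - lo$loss), 1e-5)
  for (nm in names(grads)) {
    expect_lt(max(abs(fb$grads[[nm]] - grads[[nm]])), 1e-3)
  }
})
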