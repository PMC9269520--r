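## Internal neural-network engine.
##
## Feature maps are dense arrays laid out as (C, T, N, V): channels first so
## 1x1/channel-mixing products are single BLAS calls, joints last so graph
## contractions are single (C*T*N) x V by V x V products, with no transposes
## in the hot path. Trainable parameters live in one flat named list; every
## layer has a forward returning (out, cache) and a backward returning
## (dx, grads) with gradient names matching parameter names. Gradients are
## verified against finite differences in the test suite.

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# run expr with a private RNG stream, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# reduce an (C,T,N,V) array over (T,N) -> C x V
.reduce_cv <- function(X, d) {
  colSums(aperm(array(X, c(d[1L], d[2L] * d[3L], d[4L])), c(2, 1, 3)))
}

# broadcast a C x V matrix over (T,N) -> (C,T,N,V)
.bc_cv <- function(M, d) {
  aperm(array(M, c(d[1L], d[4L], d[2L], d[3L])), c(1, 3, 4, 2))
}

## ---- batch normalization over the (channel, joint) axis ----

.fw_bn <- function(params, state, prefix, X, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  nred <- d[2L] * d[3L]
  if (train) {
    m <- .reduce_cv(X, d) / nred
    ex2 <- .reduce_cv(X * X, d) / nred
    v <- pmax(ex2 - m * m, 0)
    state <- .ns_update_from(state, prefix, m, v, momentum)
  } else {
    m <- state[[paste0(prefix, "mean")]]
    v <- state[[paste0(prefix, "var")]]
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (X - .bc_cv(m, d)) * .bc_cv(istd, d)
  g <- params[[paste0(prefix, "gamma")]]
  out <- xhat * .bc_cv(g, d) + .bc_cv(params[[paste0(prefix, "beta")]], d)
  list(out = out, cache = list(xhat = xhat, istd = istd, g = g, d = d, train = train), state = state)
}

.bw_bn <- function(params, prefix, cache, dY) {
  d <- cache$d
  nred <- d[2L] * d[3L]
  dgamma <- .reduce_cv(dY * cache$xhat, d)
  dbeta <- .reduce_cv(dY, d)
  dxhat <- dY * .bc_cv(cache$g, d)
  if (cache$train) {
    mh <- .reduce_cv(dxhat, d) / nred
    mx <- .reduce_cv(dxhat * cache$xhat, d) / nred
    dx <- (dxhat - .bc_cv(mh, d) - cache$xhat * .bc_cv(mx, d)) * .bc_cv(cache$istd, d)
  } else {
    dx <- dxhat * .bc_cv(cache$istd, d)
  }
  grads <- list(dgamma, dbeta)
  names(grads) <- paste0(prefix, c("gamma", "beta"))
  list(dx = dx, grads = grads)
}

## ---- per-channel standardization sites (batch normalization) ----

# Every convolution output inside a block is standardized per channel with
# the batch moments during training (true batch normalization; the layer
# bias is applied after the standardization, and a learnable gain is
# omitted because the next convolution absorbs it) and with running moments
# at evaluation. The running moments follow the momentum schedule
# max(momentum, 1/(n+1)): the first updates average cumulatively so the
# evaluation statistics converge onto the data quickly from their (0, 1)
# start — a slow-converging estimate here leaves a train/eval normalization
# gap that a deep stack amplifies into large logit errors.
.ns_scale <- function(state, prefix, eps = 1e-5) {
  1 / sqrt(state[[paste0(prefix, "var")]] + eps)
}

# channel moments of an (C,T,N,V) activation map
.ns_moments <- function(X, d) {
  m <- rowMeans(matrix(X, d[1L]))
  ex2 <- rowMeans(matrix(X, d[1L])^2)
  list(mean = m, var = pmax(ex2 - m * m, 0))
}

.ns_update_from <- function(state, prefix, mean, var, momentum = 0.1) {
  n <- state[[paste0(prefix, "n")]]
  w <- max(momentum, 1 / (n + 1))
  state[[paste0(prefix, "mean")]] <- (1 - w) * state[[paste0(prefix, "mean")]] + w * mean
  state[[paste0(prefix, "var")]] <- (1 - w) * state[[paste0(prefix, "var")]] + w * var
  state[[paste0(prefix, "n")]] <- n + 1
  state
}

.ns_update <- function(state, prefix, X, momentum = 0.1) {
  mom <- .ns_moments(X, dim(X))
  .ns_update_from(state, prefix, mom$mean, mom$var, momentum)
}

# forward of one standardization site: batch moments in training mode
# (running stats updated), running moments in eval mode.
# Returns the normalized map plus what the backward pass needs.
.ns_site_fw <- function(X, state, prefix, b, train) {
  if (train) {
    mom <- .ns_moments(X, dim(X))
    m <- mom$mean
    v <- mom$var
    state <- .ns_update_from(state, prefix, m, v)
  } else {
    m <- state[[paste0(prefix, "mean")]]
    v <- state[[paste0(prefix, "var")]]
  }
  istd <- 1 / sqrt(v + 1e-5)
  xhat <- (X - m) * istd # recycles over the channel axis
  list(out = xhat + b, xhat = xhat, istd = istd, state = state, train = train)
}

# backward: full batch-norm gradient in training mode (the moments are
# functions of the batch), frozen-statistics gradient in eval mode
.ns_site_bw <- function(cache, dY) {
  C <- dim(dY)[1L]
  db <- rowSums(matrix(dY, C))
  if (cache$train) {
    nred <- length(dY) / C
    mh <- rowMeans(matrix(dY, C))
    mx <- rowMeans(matrix(dY * cache$xhat, C))
    dx <- (dY - mh - cache$xhat * mx) * cache$istd
  } else {
    dx <- dY * cache$istd
  }
  list(dx = dx, db = db)
}

## ---- spatial graph convolution (partitioned) ----

.fw_gcn <- function(params, prefix, X, A, edgeImportance = FALSE, bias = TRUE) {
  d <- dim(X)
  K <- length(A)
  W1 <- params[[paste0(prefix, "W1")]]
  cout <- ncol(W1)
  Xmat <- matrix(X, d[1L], d[2L] * d[3L] * d[4L])
  acc <- NULL
  Zs <- if (edgeImportance) vector("list", K) else NULL
  for (k in seq_len(K)) {
    Wk <- params[[paste0(prefix, "W", k)]]
    Z <- crossprod(Wk, Xmat) # cout x (T N V)
    Ak <- A[[k]]
    if (edgeImportance) {
      Ak <- Ak * params[[paste0(prefix, "mask", k)]]
      Zs[[k]] <- Z
    }
    Yk <- matrix(Z, cout * d[2L] * d[3L], d[4L]) %*% Ak
    acc <- if (is.null(acc)) Yk else acc + Yk
  }
  if (bias) acc <- acc + params[[paste0(prefix, "b")]] # recycles over channels
  out <- array(acc, c(cout, d[2L], d[3L], d[4L]))
  list(out = out, cache = list(X = X, d = d, cout = cout, Zs = Zs))
}

.bw_gcn <- function(params, prefix, cache, dY, A, edgeImportance = FALSE, bias = TRUE) {
  d <- cache$d
  K <- length(A)
  cout <- cache$cout
  m <- d[2L] * d[3L]
  Xmat <- matrix(cache$X, d[1L], m * d[4L])
  dYv <- matrix(dY, cout * m, d[4L])
  dYc <- matrix(dY, cout, m * d[4L])
  dXmat <- NULL
  grads <- list()
  for (k in seq_len(K)) {
    Wk <- params[[paste0(prefix, "W", k)]]
    Ak <- A[[k]]
    if (edgeImportance) Ak <- Ak * params[[paste0(prefix, "mask", k)]]
    dZ <- dYv %*% t(Ak) # (cout m) x V
    dZc <- matrix(array(dZ, c(cout, m, d[4L])), cout, m * d[4L])
    grads[[paste0(prefix, "W", k)]] <- Xmat %*% t(dZc)
    if (edgeImportance) {
      Zk <- matrix(cache$Zs[[k]], cout * m, d[4L])
      grads[[paste0(prefix, "mask", k)]] <- A[[k]] * crossprod(Zk, dYv)
    }
    upd <- Wk %*% dZc
    dXmat <- if (is.null(dXmat)) upd else dXmat + upd
  }
  if (bias) grads[[paste0(prefix, "b")]] <- rowSums(dYc)
  list(dx = array(dXmat, d), grads = grads)
}

## ---- temporal convolution (standard or depthwise-separable) ----

.tc_geometry <- function(tIn, kernel, stride) {
  pad <- (kernel - 1L) %/% 2L
  tOut <- as.integer(ceiling(tIn / stride))
  # padded input index read by tap j at output position t'
  taps <- lapply(seq_len(kernel), function(j) seq.int(j, by = stride, length.out = tOut))
  list(pad = pad, tOut = tOut, taps = taps)
}

.fw_tc <- function(params, prefix, X, kernel, stride, separable, bias = TRUE) {
  d <- dim(X)
  geo <- .tc_geometry(d[2L], kernel, stride)
  Xpad <- array(0, c(d[1L], d[2L] + 2L * geo$pad, d[3L], d[4L]))
  Xpad[, geo$pad + seq_len(d[2L]), , ] <- X
  m <- geo$tOut * d[3L] * d[4L]
  b <- if (bias) params[[paste0(prefix, "b")]] else 0
  if (separable) {
    Wd <- params[[paste0(prefix, "Wd")]]
    Yd <- array(0, c(d[1L], geo$tOut, d[3L], d[4L]))
    for (j in seq_len(kernel)) {
      Yd <- Yd + Xpad[, geo$taps[[j]], , , drop = FALSE] * Wd[, j]
    }
    Wp <- params[[paste0(prefix, "Wp")]]
    out <- crossprod(Wp, matrix(Yd, d[1L], m)) + b
    out <- array(out, c(ncol(Wp), geo$tOut, d[3L], d[4L]))
    cache <- list(Xpad = Xpad, Yd = Yd, d = d, geo = geo, kernel = kernel)
  } else {
    W <- params[[paste0(prefix, "W")]] # cout x cin x kernel
    acc <- NULL
    for (j in seq_len(kernel)) {
      Xs <- matrix(Xpad[, geo$taps[[j]], , , drop = FALSE], d[1L], m)
      contrib <- matrix(W[, , j], dim(W)[1L], dim(W)[2L]) %*% Xs
      acc <- if (is.null(acc)) contrib else acc + contrib
    }
    acc <- acc + b
    out <- array(acc, c(dim(W)[1L], geo$tOut, d[3L], d[4L]))
    cache <- list(Xpad = Xpad, d = d, geo = geo, kernel = kernel)
  }
  list(out = out, cache = cache)
}

.bw_tc <- function(params, prefix, cache, dY, separable, bias = TRUE) {
  d <- cache$d
  geo <- cache$geo
  kernel <- cache$kernel
  m <- geo$tOut * d[3L] * d[4L]
  grads <- list()
  dXpad <- array(0, dim(cache$Xpad))
  if (separable) {
    Wp <- params[[paste0(prefix, "Wp")]]
    Wd <- params[[paste0(prefix, "Wd")]]
    dYmat <- matrix(dY, ncol(Wp), m)
    grads[[paste0(prefix, "Wp")]] <- matrix(cache$Yd, d[1L], m) %*% t(dYmat)
    if (bias) grads[[paste0(prefix, "b")]] <- rowSums(dYmat)
    dYd <- array(Wp %*% dYmat, c(d[1L], geo$tOut, d[3L], d[4L]))
    dWd <- matrix(0, d[1L], kernel)
    for (j in seq_len(kernel)) {
      Xs <- cache$Xpad[, geo$taps[[j]], , , drop = FALSE]
      dWd[, j] <- rowSums(matrix(dYd * Xs, d[1L], m))
      dXpad[, geo$taps[[j]], , ] <- dXpad[, geo$taps[[j]], , , drop = FALSE] + dYd * Wd[, j]
    }
    grads[[paste0(prefix, "Wd")]] <- dWd
  } else {
    W <- params[[paste0(prefix, "W")]]
    cout <- dim(W)[1L]
    dYmat <- matrix(dY, cout, m)
    dW <- array(0, dim(W))
    for (j in seq_len(kernel)) {
      Xs <- matrix(cache$Xpad[, geo$taps[[j]], , , drop = FALSE], d[1L], m)
      dW[, , j] <- dYmat %*% t(Xs)
      Wj <- matrix(W[, , j], dim(W)[1L], dim(W)[2L])
      upd <- array(crossprod(Wj, dYmat), c(d[1L], geo$tOut, d[3L], d[4L]))
      dXpad[, geo$taps[[j]], , ] <- dXpad[, geo$taps[[j]], , , drop = FALSE] + upd
    }
    grads[[paste0(prefix, "W")]] <- dW
    if (bias) grads[[paste0(prefix, "b")]] <- rowSums(dYmat)
  }
  list(dx = dXpad[, geo$pad + seq_len(d[2L]), , , drop = FALSE], grads = grads)
}

## ---- spatiotemporal joint attention ----

# Pool over joints (-> C x T) and over frames (-> C x V), compress the
# concatenated pooled vector through a shared channel bottleneck, map back to
# per-frame and per-joint channel scores through two independent heads, and
# gate the input with the channel-wise outer product of the two sigmoid
# score sets.
.fw_att <- function(params, prefix, X, forceIdentity = FALSE) {
  d <- dim(X)
  C <- d[1L]; Tn <- d[2L]; N <- d[3L]; V <- d[4L]
  if (forceIdentity) {
    St <- array(1, c(C, Tn, N))
    Sv <- array(1, c(C, N, V))
    return(list(
      out = X, frameScores = St, jointScores = Sv,
      cache = list(identity = TRUE, d = d)
    ))
  }
  Pt <- array(rowMeans(matrix(X, C * Tn * N, V)), c(C, Tn, N)) # pool over joints
  Pv <- array(
    colMeans(aperm(array(X, c(C, Tn, N * V)), c(2, 1, 3))), # pool over frames
    c(C, N, V)
  )
  W1 <- params[[paste0(prefix, "W1")]]
  b1 <- params[[paste0(prefix, "b1")]]
  Zt0 <- crossprod(W1, matrix(Pt, C, Tn * N)) + b1
  Zv0 <- crossprod(W1, matrix(Pv, C, N * V)) + b1
  Zt <- .relu(Zt0)
  Zv <- .relu(Zv0)
  St <- .sigmoid(crossprod(params[[paste0(prefix, "Wt")]], Zt) + params[[paste0(prefix, "bt")]])
  Sv <- .sigmoid(crossprod(params[[paste0(prefix, "Wv")]], Zv) + params[[paste0(prefix, "bv")]])
  StA <- array(St, c(C, Tn, N))
  SvA <- array(Sv, c(C, N, V))
  Mt <- array(StA, c(C, Tn, N, V)) # recycle over V
  Mv <- aperm(array(SvA, c(C, N, V, Tn)), c(1, 4, 2, 3)) # expand over T
  out <- X * Mt * Mv
  list(
    out = out, frameScores = StA, jointScores = SvA,
    cache = list(
      identity = FALSE, d = d, X = X, Pt = Pt, Pv = Pv,
      Zt = Zt, Zv = Zv, St = St, Sv = Sv, Mt = Mt, Mv = Mv
    )
  )
}

.bw_att <- function(params, prefix, cache, dY) {
  if (cache$identity) return(list(dx = dY, grads = list()))
  d <- cache$d
  C <- d[1L]; Tn <- d[2L]; N <- d[3L]; V <- d[4L]
  X <- cache$X
  dX <- dY * cache$Mt * cache$Mv
  dMt <- dY * X * cache$Mv
  dMv <- dY * X * cache$Mt
  dSt <- matrix(rowSums(matrix(dMt, C * Tn * N, V)), C, Tn * N)
  dSv <- matrix(
    colSums(aperm(array(dMv, c(C, Tn, N * V)), c(2, 1, 3))),
    C, N * V
  )
  # sigmoid
  dPreT <- dSt * cache$St * (1 - cache$St)
  dPreV <- dSv * cache$Sv * (1 - cache$Sv)
  Wt <- params[[paste0(prefix, "Wt")]]
  Wv <- params[[paste0(prefix, "Wv")]]
  grads <- list()
  grads[[paste0(prefix, "Wt")]] <- cache$Zt %*% t(dPreT)
  grads[[paste0(prefix, "bt")]] <- rowSums(dPreT)
  grads[[paste0(prefix, "Wv")]] <- cache$Zv %*% t(dPreV)
  grads[[paste0(prefix, "bv")]] <- rowSums(dPreV)
  dZt <- (Wt %*% dPreT) * (cache$Zt > 0)
  dZv <- (Wv %*% dPreV) * (cache$Zv > 0)
  W1 <- params[[paste0(prefix, "W1")]]
  grads[[paste0(prefix, "W1")]] <- matrix(cache$Pt, C, Tn * N) %*% t(dZt) +
    matrix(cache$Pv, C, N * V) %*% t(dZv)
  grads[[paste0(prefix, "b1")]] <- rowSums(dZt) + rowSums(dZv)
  dPt <- array(W1 %*% dZt, c(C, Tn, N))
  dPv <- array(W1 %*% dZv, c(C, N, V))
  # un-pool: joint pooling spread over V, frame pooling spread over T
  dX <- dX + array(dPt, c(C, Tn, N, V)) / V
  dX <- dX + aperm(array(dPv, c(C, N, V, Tn)), c(1, 4, 2, 3)) / Tn
  list(dx = dX, grads = grads)
}

## ---- residual path ----

.fw_res <- function(params, prefix, X, stride, needProj) {
  if (!needProj) {
    return(list(out = X, cache = list(identity = TRUE)))
  }
  d <- dim(X)
  geo <- .tc_geometry(d[2L], 1L, stride)
  centers <- geo$taps[[1L]]
  Xs <- X[, centers, , , drop = FALSE]
  W <- params[[paste0(prefix, "W")]]
  out <- array(
    crossprod(W, matrix(Xs, d[1L], length(centers) * d[3L] * d[4L])),
    c(ncol(W), length(centers), d[3L], d[4L])
  )
  list(out = out, cache = list(identity = FALSE, Xs = Xs, d = d, centers = centers))
}

.bw_res <- function(params, prefix, cache, dY) {
  if (cache$identity) return(list(dx = dY, grads = list()))
  d <- cache$d
  W <- params[[paste0(prefix, "W")]]
  m <- length(cache$centers) * d[3L] * d[4L]
  dYmat <- matrix(dY, ncol(W), m)
  grads <- list()
  grads[[paste0(prefix, "W")]] <- matrix(cache$Xs, d[1L], m) %*% t(dYmat)
  dX <- array(0, d)
  dX[, cache$centers, , ] <- array(W %*% dYmat, c(d[1L], length(cache$centers), d[3L], d[4L]))
  list(dx = dX, grads = grads)
}

## ---- ST-GCN block ----

# spatial graph conv -> batch standardization (+bias) -> rectifier ->
# blockDepth temporal layers (standardized, first may stride) -> residual
# add (projection standardized) -> rectifier -> attention gate
.fw_block <- function(params, state, prefix, X, A, mb, train = FALSE,
                      forceAttIdentity = FALSE) {
  g <- .fw_gcn(params, paste0(prefix, "gcn."), X, A, mb$edgeImportance, bias = FALSE)
  gs <- .ns_site_fw(g$out, state, paste0(prefix, "gcn.ns."),
                    params[[paste0(prefix, "gcn.b")]], train)
  state <- gs$state
  h <- .relu(gs$out)
  gmask <- gs$out > 0
  tcaches <- vector("list", mb$depth)
  tsites <- vector("list", mb$depth)
  tmasks <- vector("list", mb$depth)
  for (j in seq_len(mb$depth)) {
    s <- if (j == 1L) mb$stride else 1L
    tc <- .fw_tc(params, sprintf("%stc%d.", prefix, j), h, mb$kernel, s,
                 mb$separable, bias = FALSE)
    ts <- .ns_site_fw(tc$out, state, sprintf("%stc%d.ns.", prefix, j),
                      params[[sprintf("%stc%d.b", prefix, j)]], train)
    state <- ts$state
    h <- ts$out
    tcaches[[j]] <- tc$cache
    tsites[[j]] <- ts
    if (j < mb$depth) {
      tmasks[[j]] <- h > 0
      h <- .relu(h)
    }
  }
  r <- .fw_res(params, paste0(prefix, "res."), X, mb$stride, mb$needProj)
  rout <- r$out
  rsite <- NULL
  if (mb$needProj) {
    rsite <- .ns_site_fw(rout, state, paste0(prefix, "res.ns."), 0, train)
    state <- rsite$state
    rout <- rsite$out
  }
  s0 <- h + rout
  y <- .relu(s0)
  smask <- s0 > 0
  att <- NULL
  if (mb$attention) {
    att <- .fw_att(params, paste0(prefix, "att."), y, forceIdentity = forceAttIdentity)
    y <- att$out
  }
  list(
    out = y, state = state,
    frameScores = if (!is.null(att)) att$frameScores,
    jointScores = if (!is.null(att)) att$jointScores,
    cache = list(
      gcn = g$cache, gmask = gmask, gsite = gs[c("xhat", "istd", "train")],
      tcaches = tcaches, tsites = lapply(tsites, function(z) z[c("xhat", "istd", "train")]),
      tmasks = tmasks,
      res = r$cache, rsite = if (!is.null(rsite)) rsite[c("xhat", "istd", "train")],
      smask = smask, att = if (!is.null(att)) att$cache
    )
  )
}

.bw_block <- function(params, prefix, cache, dY, A, mb) {
  grads <- list()
  if (mb$attention) {
    ab <- .bw_att(params, paste0(prefix, "att."), cache$att, dY)
    dY <- ab$dx
    grads <- c(grads, ab$grads)
  }
  dS <- dY * cache$smask
  dRes <- dS
  if (mb$needProj) {
    rs <- .ns_site_bw(cache$rsite, dS)
    dRes <- rs$dx
  }
  rb <- .bw_res(params, paste0(prefix, "res."), cache$res, dRes)
  grads <- c(grads, rb$grads)
  dh <- dS
  for (j in rev(seq_len(mb$depth))) {
    if (j < mb$depth) dh <- dh * cache$tmasks[[j]]
    ts <- .ns_site_bw(cache$tsites[[j]], dh)
    grads[[sprintf("%stc%d.b", prefix, j)]] <- ts$db
    tb <- .bw_tc(params, sprintf("%stc%d.", prefix, j), cache$tcaches[[j]], ts$dx,
                 mb$separable, bias = FALSE)
    dh <- tb$dx
    grads <- c(grads, tb$grads)
  }
  dz <- dh * cache$gmask
  gs <- .ns_site_bw(cache$gsite, dz)
  grads[[paste0(prefix, "gcn.b")]] <- gs$db
  gb <- .bw_gcn(params, paste0(prefix, "gcn."), cache$gcn, gs$dx, A,
                mb$edgeImportance, bias = FALSE)
  grads <- c(grads, gb$grads)
  list(dx = gb$dx + rb$dx, grads = grads)
}

## ---- classifier head: global average pool + fully connected ----

.fw_head <- function(params, X, dropMask = NULL) {
  d <- dim(X)
  g <- matrix(
    rowMeans(matrix(aperm(X, c(1, 3, 2, 4)), d[1L] * d[3L], d[2L] * d[4L])),
    d[1L], d[3L]
  )
  if (!is.null(dropMask)) g <- g * dropMask # inverted dropout, training only
  W <- params[["fc.W"]]
  logits <- crossprod(W, g) + params[["fc.b"]]
  list(out = logits, cache = list(g = g, d = d, dropMask = dropMask))
}

.bw_head <- function(params, cache, dLogits) {
  d <- cache$d
  W <- params[["fc.W"]]
  grads <- list(
    "fc.W" = cache$g %*% t(dLogits),
    "fc.b" = rowSums(dLogits)
  )
  dg <- W %*% dLogits # C x N
  if (!is.null(cache$dropMask)) dg <- dg * cache$dropMask
  dX <- aperm(
    array(dg / (d[2L] * d[4L]), c(d[1L], d[3L], d[2L], d[4L])),
    c(1, 3, 2, 4)
  )
  list(dx = dX, grads = grads)
}

## ---- softmax cross-entropy ----

# logits: K x N; labels: 1-based integer vector of length N
.softmax_xent <- function(logits, labels) {
  K <- nrow(logits)
  N <- ncol(logits)
  mx <- apply(logits, 2L, max)
  z <- exp(sweep(logits, 2L, mx))
  p <- sweep(z, 2L, colSums(z), "/")
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- p
  dlogits[cbind(labels, seq_len(N))] <- dlogits[cbind(labels, seq_len(N))] - 1
  list(loss = loss, dlogits = dlogits / N, probs = p)
}

## ---- Adam optimizer ----

.adam_init <- function(params) {
  # p * 0 preserves the exact shape (vector vs matrix vs array)
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weightDecay = 0) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# merge gradient lists, summing duplicates (none expected, but safe)
.merge_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
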