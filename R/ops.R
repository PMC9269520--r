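#' @include engine.R model.R
NULL

# insert/remove a singleton batch axis; (C,T,V) <-> (C,T,1,V) share memory order
.as_batch1 <- function(x) array(x, c(dim(x)[1L], dim(x)[2L], 1L, dim(x)[3L]))
.drop_batch1 <- function(x) array(x, c(dim(x)[1L], dim(x)[2L], dim(x)[4L]))

#' Spatial graph convolution over a partitioned adjacency
#'
#' Applies the partition-summed graph convolution
#' `sigma( sum_k A_k' X' W_k + b )` frame-wise to a single feature map,
#' where `A_k` are the normalized partition matrices of `adj`.
#'
#' @param x C-by-T-by-V feature array
#' @param adj an [AdjacencySet-class]
#' @param weights list of K matrices, each Cin-by-Cout
#' @param bias numeric vector of length Cout (default zeros)
#' @param activation `"relu"` (hidden-layer rectifier) or `"identity"`
#' @return Cout-by-T-by-V array
#' @export
spatialGraphConv <- function(x, adj, weights, bias = NULL,
                             activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  K <- length(adj@partitions)
  if (length(weights) != K)
    stop("validation error: need one weight matrix per partition (K = ", K, ")")
  v <- nrow(adj@normalizedFull)
  if (dim(x)[3L] != v)
    stop("validation error: joint dimension of x (", dim(x)[3L],
         ") does not match the adjacency (", v, ")")
  cin <- dim(x)[1L]
  if (nrow(weights[[1L]]) != cin)
    stop("validation error: weight rows must match input channels")
  cout <- ncol(weights[[1L]])
  params <- list()
  for (k in seq_len(K)) params[[paste0("op.W", k)]] <- weights[[k]]
  params[["op.b"]] <- if (is.null(bias)) numeric(cout) else bias
  out <- .fw_gcn(params, "op.", .as_batch1(x), adj@partitions)$out
  out <- .drop_batch1(out)
  if (activation == "relu") out <- .relu(out)
  out
}

#' Temporal convolution along the frame axis
#'
#' Convolution over T only (kernel x 1 over the T-by-V grid) with symmetric
#' zero padding of `(kernel - 1) / 2`, so the output length is
#' `ceiling(T / stride)`. The separable form factorizes the layer into a
#' depthwise convolution (one filter per channel) followed by a 1x1
#' channel-mixing convolution.
#'
#' @param x C-by-T-by-V feature array
#' @param weights for the standard form a Cout-by-Cin-by-kernel array (named
#'   `W`); for the separable form a list with `Wd` (Cin-by-kernel) and `Wp`
#'   (Cin-by-Cout). A list element `b` supplies the bias (default zeros).
#' @param kernel odd temporal kernel size
#' @param stride temporal stride (1 or 2)
#' @param separable use the depthwise-separable factorization
#' @return Cout-by-ceiling(T/stride)-by-V array
#' @export
temporalConv <- function(x, weights, kernel, stride = 1L, separable = FALSE) {
  if (kernel %% 2L == 0L) stop("configuration error: kernel must be odd")
  params <- list()
  if (separable) {
    if (!all(c("Wd", "Wp") %in% names(weights)))
      stop("validation error: separable weights need elements 'Wd' and 'Wp'")
    params[["op.Wd"]] <- weights$Wd
    params[["op.Wp"]] <- weights$Wp
    cout <- ncol(weights$Wp)
  } else {
    W <- if (is.list(weights)) weights$W else weights
    if (length(dim(W)) != 3L || dim(W)[3L] != kernel)
      stop("validation error: standard weights must be Cout x Cin x kernel")
    params[["op.W"]] <- W
    cout <- dim(W)[1L]
  }
  b <- if (is.list(weights) && !is.null(weights$b)) weights$b else numeric(cout)
  params[["op.b"]] <- b
  .drop_batch1(.fw_tc(params, "op.", .as_batch1(x), kernel, as.integer(stride), separable)$out)
}

#' Spatiotemporal joint attention
#'
#' Pools the feature map over joints (giving a C-by-T frame descriptor) and
#' over frames (a C-by-V joint descriptor), compresses the concatenated
#' descriptors through a shared C-to-C/r channel bottleneck, maps back to C
#' through two independent heads, and squashes with a sigmoid. The returned
#' map is the input gated by the channel-wise outer product
#' `M[c,t,v] = frame[c,t] * joint[c,v]`.
#'
#' @param x C-by-T-by-V feature array
#' @param params named list with `W1` (C-by-C/r), `b1`, `Wt` (C/r-by-C),
#'   `bt`, `Wv` (C/r-by-C), `bv`; see [initAttentionParams()]
#' @param forceIdentity test/ablation mode: both score sets are forced to 1
#'   so the output equals the input exactly
#' @return list with `frameScores` (C-by-T, in (0,1)), `jointScores`
#'   (C-by-V), and `output` (C-by-T-by-V)
#' @export
stJointAttention <- function(x, params, forceIdentity = FALSE) {
  C <- dim(x)[1L]
  if (!forceIdentity) {
    cr <- ncol(params$W1)
    if (C %% cr != 0L && nrow(params$W1) != C)
      stop("configuration error: attention bottleneck incompatible with C")
  }
  p <- list()
  for (nm in names(params)) p[[paste0("op.", nm)]] <- params[[nm]]
  res <- .fw_att(p, "op.", .as_batch1(x), forceIdentity = forceIdentity)
  list(
    frameScores = matrix(res$frameScores, C, dim(x)[2L]),
    jointScores = matrix(res$jointScores, C, dim(x)[3L]),
    output = .drop_batch1(res$out)
  )
}

#' Initialize attention parameters
#'
#' @param C channel width at the attention site
#' @param r bottleneck reduction divisor (must divide C)
#' @param seed RNG seed
#' @return named parameter list for [stJointAttention()]
#' @export
initAttentionParams <- function(C, r = 4L, seed = 1L) {
  if (C %% r != 0L) stop("configuration error: r must divide C")
  cr <- C %/% r
  .with_seed(seed, list(
    W1 = matrix(stats::rnorm(C * cr, sd = sqrt(2 / C)), C, cr),
    b1 = numeric(cr),
    Wt = matrix(stats::rnorm(cr * C, sd = sqrt(2 / cr)), cr, C),
    bt = rep(3, C),
    Wv = matrix(stats::rnorm(cr * C, sd = sqrt(2 / cr)), cr, C),
    bv = rep(3, C)
  ))
}

#' Run one ST-GCN block on a single feature map
#'
#' Executes a block exactly as inside the network: spatial graph convolution,
#' rectifier, `blockDepth` temporal layers (the first at the given stride),
#' residual connection (1x1-projected when the channel width or stride
#' changes), rectifier, and the attention gate when enabled.
#'
#' @param x Cin-by-T-by-V feature array
#' @param adj an [AdjacencySet-class]
#' @param cin,cout input/output channel widths
#' @param stride temporal stride of the first temporal layer
#' @param config a [ModelConfig-class] supplying kernel, depth, separable,
#'   attention and reduction settings
#' @param attention override the config's attention flag for this block
#' @param seed weight-initialization seed
#' @param params optional pre-built flat parameter list (prefix `"blk."`);
#'   when supplied, `seed` is ignored
#' @param forceAttIdentity force the attention gate to the identity mask
#' @return list with `output` and the flat `params` used
#' @export
stgcnBlock <- function(x, adj, cin = dim(x)[1L], cout, stride = 1L,
                       config = benchmarkModelConfig(), attention = config@attentionOn,
                       seed = 1L, params = NULL, forceAttIdentity = FALSE) {
  K <- length(adj@partitions)
  mb <- list(
    cin = cin, cout = cout, stride = as.integer(stride),
    kernel = config@temporalKernel, depth = config@blockDepth,
    separable = config@separable, attention = isTRUE(attention),
    r = config@attentionReduction, K = K,
    edgeImportance = config@edgeImportance,
    needProj = (cin != cout) || (stride > 1L)
  )
  if (is.null(params)) {
    params <- .with_seed(seed, .init_block_params(list(), "blk.", mb, nrow(adj@normalizedFull)))
  }
  state <- .init_block_state(list(), "blk.", mb)
  res <- .fw_block(params, state, "blk.", .as_batch1(x), adj@partitions, mb,
                   train = FALSE, forceAttIdentity = forceAttIdentity)
  list(output = .drop_batch1(res$out), params = params)
}
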