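## Backend dispatch for the input batch normalization: a compiled kernel by
## default, the pure-R reference under options(stgait.engine = "ref"). The
## rest of the network runs either through the pure-R reference layers
## (single samples, oracle tests, CAM) or the fused per-sample compiled
## engine in src/netbatch.cpp (training and batch prediction).

.engine_backend <- function() getOption("stgait.engine", "cpp")

.fw_bn_any <- function(params, state, prefix, X, train) {
  if (.engine_backend() == "cpp") {
    r <- .cpp_bn_fwd(
      X, dim(X),
      params[[paste0(prefix, "gamma")]], params[[paste0(prefix, "beta")]],
      state[[paste0(prefix, "mean")]], state[[paste0(prefix, "var")]],
      train, 1e-5
    )
    if (train) state <- .ns_update_from(state, prefix, r$bmean, r$bvar)
    list(
      out = r$out,
      cache = list(backend = "cpp", xhat = r$xhat, istd = r$istd, train = train),
      state = state
    )
  } else {
    .fw_bn(params, state, prefix, X, train)
  }
}

.bw_bn_any <- function(params, prefix, cache, dY) {
  if (identical(cache$backend, "cpp")) {
    r <- .cpp_bn_bwd(dY, cache$xhat, dim(dY), params[[paste0(prefix, "gamma")]],
                     cache$istd, cache$train)
    grads <- list(r$dgamma, r$dbeta)
    names(grads) <- paste0(prefix, c("gamma", "beta"))
    list(dx = r$dx, grads = grads)
  } else {
    .bw_bn(params, prefix, cache, dY)
  }
}
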