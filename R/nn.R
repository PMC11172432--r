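# Internal neural-network primitives for the fusion model. Everything is
# plain base-R matrix algebra (BLAS does the heavy lifting); layers follow
# the block order dense -> relu -> batch normalization -> dropout. All
# stochastic steps (initialization, shuffling, dropout masks) draw from the
# session RNG, which the public API seeds, so single-threaded training is
# bitwise-reproducible.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# broadcast a length-p vector over n rows
rowrep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# one dense+relu+norm+drop layer's trainable parameters
layer_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out),
       gamma = rep(1, n_out),
       beta = numeric(n_out))
}

layer_stats_init <- function(n_out) list(rmean = numeric(n_out),
                                         rvar = rep(1, n_out))

stack_init <- function(n_in, sizes) {
  dims <- c(n_in, sizes)
  params <- vector("list", length(sizes))
  stats <- vector("list", length(sizes))
  for (l in seq_along(sizes)) {
    params[[l]] <- layer_init(dims[l], dims[l + 1L])
    stats[[l]] <- layer_stats_init(dims[l + 1L])
  }
  list(params = params, stats = stats)
}

# forward through one dense->relu->norm->drop layer.
# Returns output, cache for backprop, and updated running stats.
layer_forward <- function(p, s, X, training, drop_rate) {
  Z <- X %*% p$W
  Z <- Z + rowrep(p$b, nrow(Z))
  A <- Z * (Z > 0)
  if (training) {
    mu <- colMeans(A)
    va <- colMeans(A * A) - mu * mu
    va[va < 0] <- 0
    s$rmean <- (1 - BN_MOMENTUM) * s$rmean + BN_MOMENTUM * mu
    s$rvar <- (1 - BN_MOMENTUM) * s$rvar + BN_MOMENTUM * va
  } else {
    mu <- s$rmean
    va <- s$rvar
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- (A - rowrep(mu, nrow(A))) * rowrep(invstd, nrow(A))
  out <- xhat * rowrep(p$gamma, nrow(A)) + rowrep(p$beta, nrow(A))
  mask <- NULL
  if (training && drop_rate > 0) {
    mask <- matrix((stats::runif(length(out)) >= drop_rate) / (1 - drop_rate),
                   nrow(out), ncol(out))
    out <- out * mask
  }
  list(out = out, stats = s,
       cache = list(X = X, Z = Z, xhat = xhat, invstd = invstd, mask = mask))
}

# backward through the same layer; returns parameter gradients and dX
layer_backward <- function(p, cache, dOut) {
  if (!is.null(cache$mask)) dOut <- dOut * cache$mask
  m <- nrow(dOut)
  dbeta <- colSums(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dxhat <- dOut * rowrep(p$gamma, m)
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_x <- colSums(dxhat * cache$xhat)
  dA <- rowrep(cache$invstd / m, m) *
    (m * dxhat - rowrep(sum_dxhat, m) - cache$xhat * rowrep(sum_dxhat_x, m))
  dZ <- dA * (cache$Z > 0)
  list(grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ),
                    gamma = dgamma, beta = dbeta),
       dX = tcrossprod(dZ, p$W))
}

stack_forward <- function(stack, X, training, drop_rate) {
  caches <- vector("list", length(stack$params))
  for (l in seq_along(stack$params)) {
    fw <- layer_forward(stack$params[[l]], stack$stats[[l]], X,
                        training, drop_rate)
    X <- fw$out
    stack$stats[[l]] <- fw$stats
    caches[[l]] <- fw$cache
  }
  list(out = X, stats = stack$stats, caches = caches)
}

stack_backward <- function(stack, caches, dOut) {
  grads <- vector("list", length(stack$params))
  for (l in rev(seq_along(stack$params))) {
    bw <- layer_backward(stack$params[[l]], caches[[l]], dOut)
    grads[[l]] <- bw$grads
    dOut <- bw$dX
  }
  list(grads = grads, dX = dOut)
}

# ---- parameter-tree utilities (nested lists of numeric arrays) ----------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, tree_map, f = f) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

tree_copy <- function(a) tree_map(function(x) x + 0, a)

# elementwise sum of two gradient trees; NULL subtrees (inactive channels)
# stay NULL
tree_add <- function(a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    for (i in seq_along(a))
      if (!is.null(a[[i]])) a[[i]] <- tree_add(a[[i]], b[[i]])
    a
  } else a + b
}

# Adam step over a parameter tree. Mutates params and the moment trees in
# place through the fused C kernel, so the caller must own them exclusively
# (train_model deep-copies the model's parameters before optimizing).
adam_step_inplace <- function(params, grads, state, lr,
                              beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  walk <- function(p, m, v, g) {
    if (is.null(g)) return(invisible())  # inactive channel
    if (is.list(p)) {
      for (i in seq_along(p)) walk(p[[i]], m[[i]], v[[i]], g[[i]])
    } else {
      .Call("dfppi_adam_step", p, m, v, g, lr, beta1, beta2, c1, c2, eps,
            PACKAGE = "dfppi")
    }
    invisible()
  }
  walk(params, state$m, state$v, grads)
  state
}

# ---- embedding lookup ----------------------------------------------------

# tokens: n x N integer matrix (0-based); emb: 26 x d.
# Returns n x (N*d) matrix, position-major within a row.
embed_flatten <- function(emb, tokens) {
  idx <- as.vector(t(tokens)) + 1L
  M <- emb[idx, , drop = FALSE]
  matrix(as.vector(t(M)), nrow = nrow(tokens), byrow = TRUE)
}

# gradient of embed_flatten: dX is n x (N*d); returns 26 x d matrix of
# accumulated gradients (padding row zeroed)
embed_flatten_grad <- function(dX, tokens, d) {
  dM <- matrix(as.vector(t(dX)), ncol = d, byrow = TRUE)
  idx <- as.vector(t(tokens)) + 1L
  g <- rowsum(dM, idx)
  out <- matrix(0, TOKEN_VOCAB_SIZE, d)
  out[as.integer(rownames(g)), ] <- g
  out[TOKEN_PAD + 1L, ] <- 0
  out
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
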