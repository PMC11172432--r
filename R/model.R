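# The fusion model: a trainable embedding layer feeding a flattened-token
# channel, a handcrafted-descriptor channel, per-protein fusion of the two
# 128-dimensional channel outputs by a convex weight omega, and an
# averaging classification head with a two-class softmax.

#' Model configuration
#'
#' @param omega Channel weight in `[0, 1]`: the handcrafted channel
#'   contributes `omega`, the embedding channel `1 - omega` (default 0.5,
#'   the best value of the sweep over \{0.1, 0.3, 0.5, 0.7, 0.9\}).
#' @param embed_dim Embedding dimension (default 32).
#' @param n_tokens Fixed token-sequence length N fed to the embedding layer.
#' @param channel1_sizes Dense-layer widths of the handcrafted channel
#'   (default 1024, 512, 256, 128).
#' @param channel2_sizes Dense-layer widths of the embedding channel
#'   (default 2048, 512, 256, 128). The last width must equal channel 1's.
#' @param head_size Width of the classification block's hidden layer
#'   (default 16).
#' @param dropout Dropout rate after every normalized layer (default 0.2).
#' @param share_block_weights If `TRUE` the two protein blocks share
#'   parameters (a siamese model, making predictions symmetric in the pair
#'   order); default `FALSE`, two independently initialized blocks.
#' @param seed Integer seed for parameter initialization.
#' @return A list with class `model_config`.
#' @export
model_config <- function(omega = 0.5, embed_dim = 32L, n_tokens = 100L,
                         channel1_sizes = c(1024L, 512L, 256L, 128L),
                         channel2_sizes = c(2048L, 512L, 256L, 128L),
                         head_size = 16L, dropout = 0.2,
                         share_block_weights = FALSE, seed = 1L) {
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  if (tail_of(channel1_sizes) != tail_of(channel2_sizes))
    stop("the final widths of the two channels must match for fusion")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(omega = omega, embed_dim = as.integer(embed_dim),
                 n_tokens = as.integer(n_tokens),
                 channel1_sizes = as.integer(channel1_sizes),
                 channel2_sizes = as.integer(channel2_sizes),
                 head_size = as.integer(head_size), dropout = dropout,
                 share_block_weights = isTRUE(share_block_weights),
                 seed = as.integer(seed)),
            class = "model_config")
}

tail_of <- function(x) x[length(x)]

#' Training configuration
#'
#' @param epochs Training epochs (default 45).
#' @param batch_size Minibatch size (default 128).
#' @param learning_rate Initial Adam learning rate (default 0.001).
#' @param decay Time-based decay coefficient: the learning rate at epoch t
#'   (1-based) is `learning_rate / (1 + decay * (t - 1))`. Default
#'   `learning_rate / epochs`.
#' @param seed Integer seed for shuffling and dropout.
#' @return A list with class `train_config`.
#' @export
train_config <- function(epochs = 45L, batch_size = 128L,
                         learning_rate = 0.001, decay = NULL, seed = 1L) {
  epochs <- as.integer(epochs)
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0)
    stop("epochs, batch_size and learning_rate must be positive")
  if (is.null(decay)) decay <- learning_rate / epochs
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, decay = decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

block_init <- function(handcrafted_dim, flat_dim, cfg) {
  list(ch1 = stack_init(handcrafted_dim, cfg$channel1_sizes),
       ch2 = stack_init(flat_dim, cfg$channel2_sizes))
}

#' Build the fusion model
#'
#' Initializes the network: an embedding layer seeded from a pre-trained
#' embedding matrix (trainable during model training; the padding row stays
#' zero), one two-channel block per protein (or a single shared block), and
#' the classification head. Initialization is deterministic in `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @param embeddings An `embedding_matrix` (26 x `cfg$embed_dim`), e.g. from
#'   [train_embeddings()].
#' @param handcrafted_dim Width of the handcrafted input vector
#'   (default 910 = 630 + 140 + 140).
#' @return An object of class `dfppi_model`.
#' @export
build_model <- function(cfg, embeddings, handcrafted_dim = 910L) {
  check_embedding_matrix(embeddings)
  if (ncol(embeddings) != cfg$embed_dim)
    stop("embedding matrix dimension ", ncol(embeddings),
         " does not match config embed_dim ", cfg$embed_dim)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  flat_dim <- cfg$n_tokens * cfg$embed_dim
  emb <- unclass(embeddings)
  blocks <- list(A = block_init(handcrafted_dim, flat_dim, cfg))
  if (!cfg$share_block_weights)
    blocks$B <- block_init(handcrafted_dim, flat_dim, cfg)
  fused_dim <- tail_of(cfg$channel1_sizes)
  head_l1 <- layer_init(fused_dim, cfg$head_size)
  head_out <- list(W = matrix(stats::rnorm(cfg$head_size * 2L,
                                           sd = sqrt(2 / cfg$head_size)),
                              cfg$head_size, 2L),
                   b = numeric(2L))
  params <- list(
    emb = emb,
    blocks = lapply(blocks, function(b) lapply(b, function(s) s$params)),
    head = list(l1 = head_l1, out = head_out))
  stats <- list(
    blocks = lapply(blocks, function(b) lapply(b, function(s) s$stats)),
    head = list(l1 = layer_stats_init(cfg$head_size)))
  structure(list(config = cfg, params = params, stats = stats,
                 handcrafted_dim = as.integer(handcrafted_dim),
                 scaler = NULL, loss_history = NULL),
            class = "dfppi_model")
}

#' Fuse the two channel outputs of one protein
#'
#' Elementwise convex combination `omega * h_prime + (1 - omega) * e_prime`
#' of the handcrafted-channel and embedding-channel outputs.
#'
#' @param h_prime,e_prime Equal-length numeric vectors (or matrices).
#' @param omega Real in `[0, 1]`.
#' @return The fused vector (or matrix).
#' @export
fuse <- function(h_prime, e_prime, omega) {
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  if (length(h_prime) != length(e_prime))
    stop("fusion requires equal dimensions")
  omega * h_prime + (1 - omega) * e_prime
}

#' Run one channel of a protein block
#'
#' @param model A `dfppi_model`.
#' @param input Numeric vector or matrix (rows = samples): the handcrafted
#'   vector for channel 1, the flattened `N x embed_dim` embedding output
#'   for channel 2.
#' @param channel 1 (handcrafted) or 2 (embedding).
#' @param side `"A"` or `"B"` (ignored when blocks are shared).
#' @return Matrix of channel outputs (final layer width, default 128), one
#'   row per sample. Inference mode: dropout off, normalization uses
#'   running statistics.
#' @export
channel_forward <- function(model, input, channel = 1L, side = "A") {
  side <- block_side(model, side)
  ch <- paste0("ch", channel)
  if (is.null(dim(input))) input <- matrix(input, nrow = 1L)
  stack <- list(params = model$params$blocks[[side]][[ch]],
                stats = model$stats$blocks[[side]][[ch]])
  stack_forward(stack, input, training = FALSE, drop_rate = 0)$out
}

block_side <- function(model, side) {
  if (model$config$share_block_weights) "A"
  else match.arg(side, c("A", "B"))
}

# forward pass for one side's block; ha pre-scaled; returns fused output,
# caches, updated stats
side_forward <- function(params, stats, emb, cfg, h, tokens, training) {
  n <- nrow(h)
  omega <- cfg$omega
  fused_dim <- tail_of(cfg$channel1_sizes)
  hp <- ep <- matrix(0, n, fused_dim)
  c1 <- c2 <- NULL
  eflat <- NULL
  if (omega > 0) {
    c1 <- stack_forward(list(params = params$ch1, stats = stats$ch1),
                        h, training, if (training) cfg$dropout else 0)
    stats$ch1 <- c1$stats
    hp <- c1$out
  }
  if (omega < 1) {
    eflat <- embed_flatten(emb, tokens)
    c2 <- stack_forward(list(params = params$ch2, stats = stats$ch2),
                        eflat, training, if (training) cfg$dropout else 0)
    stats$ch2 <- c2$stats
    ep <- c2$out
  }
  list(f = omega * hp + (1 - omega) * ep, stats = stats,
       cache = list(c1 = c1, c2 = c2, h = h, tokens = tokens))
}

# backward for one side; df is gradient w.r.t. the fused output.
# Returns gradients for the block's parameter tree and the embedding matrix.
side_backward <- function(params, cache, cfg, df, d) {
  omega <- cfg$omega
  g <- list(ch1 = NULL, ch2 = NULL)
  demb <- NULL
  if (omega > 0) {
    bw <- stack_backward(list(params = params$ch1), cache$c1$caches,
                         omega * df)
    g$ch1 <- bw$grads
  }
  if (omega < 1) {
    bw <- stack_backward(list(params = params$ch2), cache$c2$caches,
                         (1 - omega) * df)
    g$ch2 <- bw$grads
    demb <- embed_flatten_grad(bw$dX, cache$tokens, d)
  }
  # an inactive channel's gradient stays NULL; the optimizer skips it
  list(grads = g, demb = demb)
}

# full forward (and optional backward) over a minibatch of pairs.
# ha/hb already standardized; y in {0,1} or NULL.
pair_step <- function(model, ha, hb, ta, tb, y = NULL, training = FALSE,
                      want_grads = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$stats
  shared <- cfg$share_block_weights
  sideA <- "A"; sideB <- if (shared) "A" else "B"
  fa <- side_forward(p$blocks[[sideA]], st$blocks[[sideA]], p$emb, cfg,
                     ha, ta, training)
  st$blocks[[sideA]] <- fa$stats
  fb <- side_forward(p$blocks[[sideB]], st$blocks[[sideB]], p$emb, cfg,
                     hb, tb, training)
  st$blocks[[sideB]] <- fb$stats
  fab <- (fa$f + fb$f) / 2
  h1 <- layer_forward(p$head$l1, st$head$l1, fab, training,
                      if (training) cfg$dropout else 0)
  st$head$l1 <- h1$stats
  logits <- h1$out %*% p$head$out$W + rowrep(p$head$out$b, nrow(h1$out))
  probs <- softmax_rows(logits)
  out <- list(probs = probs, stats = st)
  if (!is.null(y)) {
    eps <- 1e-12
    out$loss <- -mean(y * log(probs[, 2L] + eps) +
                        (1 - y) * log(probs[, 1L] + eps))
  }
  if (want_grads) {
    n <- nrow(probs)
    Y <- cbind(1 - y, y)
    dlogits <- (probs - Y) / n
    gW2 <- crossprod(h1$out, dlogits)
    gb2 <- colSums(dlogits)
    dh1 <- dlogits %*% t(p$head$out$W)
    bw_h1 <- layer_backward(p$head$l1, h1$cache, dh1)
    dfab <- bw_h1$dX / 2
    bwa <- side_backward(p$blocks[[sideA]], fa$cache, cfg, dfab,
                         cfg$embed_dim)
    bwb <- side_backward(p$blocks[[sideB]], fb$cache, cfg, dfab,
                         cfg$embed_dim)
    demb <- matrix(0, TOKEN_VOCAB_SIZE, cfg$embed_dim)
    if (!is.null(bwa$demb)) demb <- demb + bwa$demb
    if (!is.null(bwb$demb)) demb <- demb + bwb$demb
    gblocks <- if (shared) {
      list(A = tree_add(bwa$grads, bwb$grads))
    } else {
      list(A = bwa$grads, B = bwb$grads)
    }
    out$grads <- list(emb = demb, blocks = gblocks,
                      head = list(l1 = bw_h1$grads,
                                  out = list(W = gW2, b = gb2)))
  }
  out
}

apply_scaler <- function(scaler, x) {
  (x - rowrep(scaler$center, nrow(x))) * rowrep(scaler$scale_inv, nrow(x))
}

#' Train the fusion model
#'
#' Minimizes the binary cross-entropy of the interaction probability with
#' Adam (default settings) under time-based learning-rate decay. The
#' handcrafted inputs are standardized feature-wise using statistics of the
#' supplied training data (stored in the model and reapplied at prediction
#' time). With fixed seeds the trajectory is bitwise-reproducible on a
#' single worker.
#'
#' @param model A [build_model()] result.
#' @param batch A labeled [encode_pairs()] result.
#' @param tc A [train_config()].
#' @return The trained model; `$loss_history` holds the mean training loss
#'   per epoch.
#' @export
train_model <- function(model, batch, tc = train_config()) {
  if (is.null(batch$labels)) stop("training requires labeled pairs")
  n <- length(batch$labels)
  cfg <- model$config
  if (ncol(batch$ta) != cfg$n_tokens)
    stop("batch token length ", ncol(batch$ta),
         " does not match config n_tokens ", cfg$n_tokens)
  allh <- rbind(batch$ha, batch$hb)
  center <- colMeans(allh)
  sds <- sqrt(colMeans(allh^2) - center^2)
  sds[sds < 1e-8] <- 1
  model$scaler <- list(center = center, scale_inv = 1 / sds)
  ha <- apply_scaler(model$scaler, batch$ha)
  hb <- apply_scaler(model$scaler, batch$hb)
  y <- batch$labels
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(tc$seed)
  # the optimizer mutates parameters in place; deep-copy so the caller's
  # untrained model is untouched
  model$params <- tree_copy(model$params)
  state <- list(t = 0L, m = tree_zeros(model$params),
                v = tree_zeros(model$params))
  history <- numeric(tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    lr <- tc$learning_rate / (1 + tc$decay * (epoch - 1))
    idx <- sample.int(n)
    starts <- seq(1L, n, by = tc$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      take <- idx[starts[bi]:min(starts[bi] + tc$batch_size - 1L, n)]
      stepres <- pair_step(model, ha[take, , drop = FALSE],
                           hb[take, , drop = FALSE],
                           batch$ta[take, , drop = FALSE],
                           batch$tb[take, , drop = FALSE],
                           y[take], training = TRUE, want_grads = TRUE)
      model$stats <- stepres$stats
      losses[bi] <- stepres$loss
      # the padding row's gradient is identically zero (embed_flatten_grad
      # zeroes it), so Adam never moves it off zero
      state <- adam_step_inplace(model$params, stepres$grads, state, lr)
    }
    history[epoch] <- mean(losses)
  }
  model$loss_history <- history
  model
}

# interaction probabilities for an encoded pair batch (chunked to bound
# the memory of the flattened embedding input)
predict_prob <- function(model, batch, chunk = 512L) {
  if (is.null(model$scaler))
    stop("model has not been trained (no feature scaler)")
  n <- nrow(batch$ha)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    take <- s:min(s + chunk - 1L, n)
    res <- pair_step(model,
                     apply_scaler(model$scaler, batch$ha[take, , drop = FALSE]),
                     apply_scaler(model$scaler, batch$hb[take, , drop = FALSE]),
                     batch$ta[take, , drop = FALSE],
                     batch$tb[take, , drop = FALSE])
    out[take] <- res$probs[, 2L]
  }
  out
}

#' Predict interactions for encoded pairs
#'
#' @param model A trained `dfppi_model`.
#' @param batch An [encode_pairs()] result.
#' @param threshold Decision threshold in `[0, 1]`; a pair is called
#'   interacting when its probability is greater than or equal to the
#'   threshold (default 0.5).
#' @return data.frame with `id_a`, `id_b`, `probability` and predicted
#'   `label`.
#' @export
predict_pairs <- function(model, batch, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  prob <- predict_prob(model, batch)
  data.frame(id_a = batch$ids$id_a, id_b = batch$ids$id_b,
             probability = prob,
             label = as.integer(prob >= threshold),
             stringsAsFactors = FALSE)
}

#' Encode a pair table into model inputs
#'
#' Featurizes every distinct protein once (handcrafted vector plus token
#' sequence) and assembles the per-pair input blocks.
#'
#' @param pairs Pair table (`id_a`, `id_b`, optional `label`).
#' @param records Protein records covering every id in `pairs`.
#' @param n_tokens Fixed token length N; defaults to the floored mean
#'   sequence length of `records`.
#' @param descriptors,groups,scheme,cfg,props Passed to
#'   [featurize_records()].
#' @return An object of class `pair_batch` with elements `ha`, `hb`
#'   (handcrafted matrices), `ta`, `tb` (token matrices), `labels` (or
#'   `NULL`), `ids` and `n_tokens`.
#' @export
encode_pairs <- function(pairs, records, n_tokens = NULL,
                         descriptors = c("ld", "fvector", "apaacplus"),
                         groups = group_alphabet(), scheme = region_scheme(),
                         cfg = apaac_config(), props = property_table()) {
  records <- as_protein_records(records)
  used <- unique(c(pairs$id_a, pairs$id_b))
  missing <- setdiff(used, records$id)
  if (length(missing) > 0L)
    stop("no sequence for id: ", paste(utils::head(missing, 5), collapse = ", "))
  recs <- records[match(used, records$id), ]
  if (is.null(n_tokens)) n_tokens <- mean_sequence_length(records)
  feats <- featurize_records(recs, descriptors, groups, scheme, cfg, props)
  toks <- tokenize_and_pad(recs$sequence, n_tokens)
  rownames(toks) <- recs$id
  ia <- match(pairs$id_a, recs$id)
  ib <- match(pairs$id_b, recs$id)
  structure(list(ha = feats[ia, , drop = FALSE],
                 hb = feats[ib, , drop = FALSE],
                 ta = toks[ia, , drop = FALSE],
                 tb = toks[ib, , drop = FALSE],
                 labels = pairs$label,
                 ids = data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                                  stringsAsFactors = FALSE),
                 n_tokens = as.integer(n_tokens)),
            class = "pair_batch")
}

# subset an encoded batch by row indices (used by cross-validation)
batch_subset <- function(batch, idx) {
  structure(list(ha = batch$ha[idx, , drop = FALSE],
                 hb = batch$hb[idx, , drop = FALSE],
                 ta = batch$ta[idx, , drop = FALSE],
                 tb = batch$tb[idx, , drop = FALSE],
                 labels = batch$labels[idx],
                 ids = batch$ids[idx, , drop = FALSE],
                 n_tokens = batch$n_tokens),
            class = "pair_batch")
}
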