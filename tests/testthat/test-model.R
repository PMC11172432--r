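test_that("configuration contracts are enforced", {
  expect_error(model_config(omega = 1.2), "omega")
  expect_error(model_config(channel1_sizes = c(32, 16),
                            channel2_sizes = c(32, 8)), "match")
  expect_error(train_config(epochs = 0), "positive")
  emb <- tiny_embedding(d = 4)
  expect_error(build_model(model_config(embed_dim = 8, n_tokens = 10), emb),
               "does not match")
})

test_that("channel outputs and the fused representation have the contracted
           widths", {
  m <- tiny_model(sizes = c(32L, 16L), hdim = 10L)
  x <- rnorm(10)
  out <- channel_forward(m, x, channel = 1)
  expect_identical(dim(out), c(1L, 16L))
  expect_true(all(is.finite(out)))
  # zero input still yields finite output (normalization shift only)
  expect_true(all(is.finite(channel_forward(m, numeric(10), channel = 1))))
  # inference is deterministic
  expect_identical(channel_forward(m, x), channel_forward(m, x))
})

test_that("model initialization is deterministic in the seed", {
  m1 <- tiny_model(seed = 9)
  m2 <- tiny_model(seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_model(seed = 10)
  expect_false(identical(m3$params, m1$params))
})

test_that("fusion is the convex combination with exact extremes", {
  h <- rnorm(128); e <- rnorm(128)
  expect_identical(fuse(h, e, 1), h)
  expect_identical(fuse(h, e, 0), e)
  expect_equal(fuse(rep(2, 4), rep(0, 4), 0.5), rep(1, 4))
  expect_error(fuse(h, e, 1.5), "omega")
  expect_error(fuse(h, e[-1], 0.5), "equal dimensions")
})

test_that("pair forward produces normalized probabilities", {
  m <- tiny_model()
  inp <- tiny_inputs()
  res <- dfppi:::pair_step(m, inp$ha, inp$hb, inp$ta, inp$tb)
  expect_equal(rowSums(res$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(res$probs >= 0 & res$probs <= 1))
})

test_that("shared-block models are symmetric under swapping the pair", {
  m <- tiny_model(share = TRUE)
  inp <- tiny_inputs()
  p1 <- dfppi:::pair_step(m, inp$ha, inp$hb, inp$ta, inp$tb)$probs
  p2 <- dfppi:::pair_step(m, inp$hb, inp$ha, inp$tb, inp$ta)$probs
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("analytic gradients match numeric differentiation on a micro-batch", {
  m <- tiny_model(omega = 0.4, sizes = c(8L, 8L, 8L, 8L), dropout = 0)
  inp <- tiny_inputs(n = 3)
  res <- dfppi:::pair_step(m, inp$ha, inp$hb, inp$ta, inp$tb, inp$y,
                           training = TRUE, want_grads = TRUE)
  loss_at <- function(model) {
    dfppi:::pair_step(model, inp$ha, inp$hb, inp$ta, inp$tb, inp$y,
                      training = TRUE)$loss
  }
  poke <- function(tree, path, i, delta) {
    if (length(path) == 0) { tree[i] <- tree[i] + delta; return(tree) }
    tree[[path[1]]] <- poke(tree[[path[1]]], path[-1], i, delta)
    tree
  }
  h <- 1e-5
  checked <- 0
  walk <- function(g, path = integer()) {
    if (is.null(g)) return(invisible())
    if (is.list(g)) {
      for (i in seq_along(g)) walk(g[[i]], c(path, i))
      return(invisible())
    }
    for (i in sample(length(g), min(2, length(g)))) {
      mp <- m; mp$params <- poke(m$params, path, i, h)
      mm <- m; mm$params <- poke(m$params, path, i, -h)
      num <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      expect_equal(unname(g[i]), num, tolerance = 1e-4)
      checked <<- checked + 1
    }
  }
  set.seed(77)
  walk(res$grads)
  expect_gt(checked, 50)
})

test_that("training reduces the loss and is bitwise reproducible", {
  sm <- small_encoded_dataset(n_pairs = 40)
  cfg <- model_config(omega = 0.5, embed_dim = 4, n_tokens = sm$batch$n_tokens,
                      channel1_sizes = c(16L, 8L), channel2_sizes = c(16L, 8L),
                      head_size = 8L, seed = 2)
  m <- build_model(cfg, tiny_embedding(4), handcrafted_dim = ncol(sm$batch$ha))
  tc <- train_config(epochs = 4, batch_size = 16, seed = 6)
  t1 <- train_model(m, sm$batch, tc)
  expect_lt(t1$loss_history[4], t1$loss_history[1])
  t2 <- train_model(m, sm$batch, tc)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$loss_history, t2$loss_history)
  # the caller's untrained model must be untouched by in-place optimization
  expect_identical(m$params, build_model(cfg, tiny_embedding(4),
                                         handcrafted_dim = ncol(sm$batch$ha))$params)
  # padding embedding row stays pinned at zero through training
  expect_equal(unname(t1$params$emb[26, ]), rep(0, 4))
  unlabeled <- sm$batch
  unlabeled$labels <- NULL
  expect_error(train_model(m, unlabeled, tc), "label")
})

test_that("extreme channel weights make predictions ignore the other
           channel end-to-end", {
  sm <- small_encoded_dataset(n_pairs = 24)
  batch <- sm$batch
  for (om in c(1, 0)) {
    cfg <- model_config(omega = om, embed_dim = 4,
                        n_tokens = batch$n_tokens,
                        channel1_sizes = c(16L, 8L),
                        channel2_sizes = c(16L, 8L), head_size = 8L, seed = 4)
    m <- build_model(cfg, tiny_embedding(4),
                     handcrafted_dim = ncol(batch$ha))
    m <- train_model(m, batch, train_config(epochs = 2, batch_size = 8,
                                            seed = 3))
    p0 <- dfppi:::predict_prob(m, batch)
    mangled <- batch
    if (om == 1) {  # scramble tokens; handcrafted untouched
      mangled$ta <- matrix(sample(0:24, length(batch$ta), TRUE),
                           nrow(batch$ta))
      mangled$tb <- matrix(sample(0:24, length(batch$tb), TRUE),
                           nrow(batch$tb))
    } else {        # scramble handcrafted; tokens untouched
      mangled$ha <- matrix(rnorm(length(batch$ha)), nrow(batch$ha))
      mangled$hb <- matrix(rnorm(length(batch$hb)), nrow(batch$hb))
    }
    expect_equal(dfppi:::predict_prob(m, mangled), p0, tolerance = 1e-6)
  }
})

test_that("thresholding follows the >= convention and is monotone", {
  sm <- small_encoded_dataset(n_pairs = 24)
  cfg <- model_config(embed_dim = 4, n_tokens = sm$batch$n_tokens,
                      channel1_sizes = c(8L, 8L), channel2_sizes = c(8L, 8L),
                      head_size = 8L, seed = 2)
  m <- build_model(cfg, tiny_embedding(4), handcrafted_dim = ncol(sm$batch$ha))
  m <- train_model(m, sm$batch, train_config(epochs = 1, batch_size = 8))
  preds <- predict_pairs(m, sm$batch, threshold = 0.5)
  expect_identical(preds$label, as.integer(preds$probability >= 0.5))
  npos <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                 function(t) sum(predict_pairs(m, sm$batch, t)$label), 0L)
  expect_true(all(diff(npos) <= 0))
  expect_error(predict_pairs(m, sm$batch, threshold = 1.2), "threshold")
})

test_that("encoding resolves ids and flags missing sequences", {
  sm <- small_encoded_dataset(n_pairs = 12)
  expect_identical(nrow(sm$batch$ha), 12L)
  expect_identical(ncol(sm$batch$ha), 910L)
  expect_identical(dim(sm$batch$ta), dim(sm$batch$tb))
  bad <- sm$ds$pairs
  bad$id_a[1] <- "nonexistent"
  expect_error(encode_pairs(bad, sm$ds$records), "nonexistent")
})
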