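# Shared builders for small models and datasets used across test files.

tiny_embedding <- function(d = 4L, seed = 11L) {
  set.seed(seed)
  emb <- matrix(rnorm(26 * d, sd = 0.1), 26, d)
  emb[26, ] <- 0
  rownames(emb) <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                     "B", "O", "U", "X", "Z", "-")
  structure(emb, class = "embedding_matrix")
}

tiny_model <- function(omega = 0.5, d = 4L, n_tok = 12L, hdim = 10L,
                       sizes = c(8L, 8L), dropout = 0, seed = 3L,
                       share = FALSE) {
  cfg <- model_config(omega = omega, embed_dim = d, n_tokens = n_tok,
                      channel1_sizes = sizes, channel2_sizes = sizes,
                      head_size = 8L, dropout = dropout,
                      share_block_weights = share, seed = seed)
  build_model(cfg, tiny_embedding(d), handcrafted_dim = hdim)
}

tiny_inputs <- function(n = 3L, hdim = 10L, n_tok = 12L, seed = 21L) {
  set.seed(seed)
  list(ha = matrix(rnorm(n * hdim), n), hb = matrix(rnorm(n * hdim), n),
       ta = matrix(sample(0:25, n * n_tok, TRUE), n),
       tb = matrix(sample(0:25, n * n_tok, TRUE), n),
       y = rep_len(c(1, 0), n))
}

# a small planted-motif dataset encoded with a short token length so model
# tests stay fast
small_encoded_dataset <- function(n_pairs = 80L, seed = 5L) {
  scfg <- synthetic_config(n_pairs = n_pairs, length_range = c(50L, 70L),
                           seed = seed)
  ds <- gen_pair_dataset(scfg)
  batch <- encode_pairs(ds$pairs, ds$records)
  list(cfg = scfg, ds = ds, batch = batch)
}
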