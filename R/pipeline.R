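# End-to-end conveniences tying the modules together: fit a model from a
# pair table, run the cross-validation protocol, and select an operating
# threshold on a holdout split.

#' Fit the fusion model on a labeled pair table
#'
#' Encodes the pairs (handcrafted descriptors + token sequences), builds
#' the network from the supplied embedding matrix and trains it.
#'
#' @param pairs Labeled pair table (`id_a`, `id_b`, `label`).
#' @param records Protein records covering all pair ids.
#' @param embeddings An `embedding_matrix` used to initialize the embedding
#'   layer.
#' @param cfg A [model_config()]; its `n_tokens` is set to the floored mean
#'   sequence length of `records` unless `n_tokens` is given.
#' @param tc A [train_config()].
#' @param n_tokens Optional fixed token length.
#' @param ... Passed to [encode_pairs()].
#' @return The trained `dfppi_model` (the encoded batch is attached as
#'   attribute `"batch"` for reuse).
#' @export
dfppi_fit <- function(pairs, records, embeddings, cfg = model_config(),
                      tc = train_config(), n_tokens = NULL, ...) {
  if (is.null(n_tokens)) n_tokens <- mean_sequence_length(records)
  cfg$n_tokens <- as.integer(n_tokens)
  batch <- encode_pairs(pairs, records, n_tokens = n_tokens, ...)
  model <- build_model(cfg, embeddings, handcrafted_dim = ncol(batch$ha))
  model <- train_model(model, batch, tc)
  attr(model, "batch") <- batch
  model
}

#' Cross-validate the fusion model
#'
#' Runs stratified k-fold cross-validation of the full pipeline: per fold,
#' a freshly initialized model (seed offset by the fold index) is trained
#' on the k-1 training folds and evaluated on the held-out fold. Feature
#' standardization uses training-fold statistics only. The fixed token
#' length is the floored mean sequence length over all records.
#'
#' @param pairs Labeled pair table.
#' @param records Protein records.
#' @param embeddings An `embedding_matrix`.
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param cfg,tc Model and training configuration templates.
#' @param ... Passed to [encode_pairs()].
#' @return A `cv_result` (see [cross_validate()]).
#' @export
dfppi_crossval <- function(pairs, records, embeddings, k = 5L, seed = 1L,
                           cfg = model_config(), tc = train_config(), ...) {
  cfg$n_tokens <- mean_sequence_length(records)
  batch <- encode_pairs(pairs, records, n_tokens = cfg$n_tokens, ...)
  fold_fit <- function(train_idx, test_idx) {
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + min(test_idx)  # distinct init per fold
    fold_tc <- tc
    fold_tc$seed <- tc$seed + min(test_idx)
    model <- build_model(fold_cfg, embeddings,
                         handcrafted_dim = ncol(batch$ha))
    model <- train_model(model, batch_subset(batch, train_idx), fold_tc)
    predict_prob(model, batch_subset(batch, test_idx))
  }
  cross_validate(batch$labels, fold_fit, k = k, seed = seed)
}

#' Select an operating threshold on a holdout split
#'
#' Splits the labeled pairs into training and holdout parts (default ratio
#' 8:1, stratified), trains the model on the training part and selects the
#' F1-maximizing threshold in `[0.5, 1]` on the holdout part.
#'
#' @param pairs Labeled pair table.
#' @param records Protein records.
#' @param embeddings An `embedding_matrix`.
#' @param cfg,tc Model and training configurations.
#' @param split Train:holdout ratio as a length-2 numeric (default
#'   `c(8, 1)`).
#' @param seed Split seed.
#' @param step Threshold grid step (default 0.001).
#' @return List with the trained `model`, the selected `threshold` and the
#'   holdout `f1` at that threshold.
#' @export
holdout_threshold <- function(pairs, records, embeddings,
                              cfg = model_config(), tc = train_config(),
                              split = c(8, 1), seed = 1L, step = 0.001) {
  nparts <- sum(split)
  folds <- stratified_folds(pairs$label, k = nparts, seed = seed)
  hold <- folds > split[1]
  model <- dfppi_fit(pairs[!hold, ], records, embeddings, cfg, tc)
  hold_batch <- encode_pairs(pairs[hold, ], records,
                             n_tokens = attr(model, "batch")$n_tokens)
  prob <- predict_prob(model, hold_batch)
  thr <- select_threshold(pairs$label[hold], prob, step = step)
  f1 <- metrics(confusion(pairs$label[hold],
                          as.integer(prob >= thr)))[["f1"]]
  list(model = model, threshold = thr, f1 = f1)
}
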