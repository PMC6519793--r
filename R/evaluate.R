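# Evaluation protocols: precision/recall/F, stratified k-fold
# cross-validation, and the class-imbalance experiment.

#' Precision, recall and F-measure of predicted labels
#'
#' Computed with respect to the positive class. `f = 2PR/(P+R)` when
#' `P + R > 0`, else 0.
#'
#' @param predicted,truth Vectors of `"positive"`/`"negative"` labels.
#' @return A `relation_metrics` list: `precision`, `recall`, `f_measure`,
#'   and confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  p <- predicted == "positive"
  t <- truth == "positive"
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(precision = precision, recall = recall, f_measure = f,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "relation_metrics")
}

#' @export
print.relation_metrics <- function(x, ...) {
  cat(sprintf("P %.3f  R %.3f  F %.3f  (tp %d fp %d fn %d tn %d)\n",
              x$precision, x$recall, x$f_measure, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# Seeded stratified fold assignment; per-class fold sizes differ by <= 1.
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2L)
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has %d members, fewer than k = %d",
                   cls, length(idx), k))
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' k-fold cross-validation of the relation classifier
#'
#' Seeded stratified partition into `k` folds (per-class fold sizes differ
#' by at most one); each fold is scored by a model trained from scratch on
#' the remaining folds. Reports per-fold and unweighted-mean precision,
#' recall and F.
#'
#' @param features A `feature_set` from [encode_pairs()].
#' @param labels Gold labels; defaults to the labels in `features`.
#' @param k Number of folds (default 10).
#' @param config A [model_config()].
#' @param table The [embedding_table()] used to encode `features`.
#' @param epochs Optional override of `config$epochs`.
#' @return A `cv_metrics` object: `folds` (data.frame with columns fold,
#'   precision, recall, f) and `mean` (`relation_metrics` of the pooled
#'   confusion counts plus unweighted means).
#' @export
cross_validate <- function(features, labels = NULL, k = 10L, config,
                           table, epochs = NULL) {
  if (is.null(labels)) {
    labels <- vapply(features, function(f) f$label %||% NA_character_, "")
  }
  y <- ifelse(.label_to_int(labels) == 1L, "positive", "negative")
  stopifnot(length(y) == length(features), k >= 2L, length(y) >= k)
  fold <- stratified_folds(y, k, seed = config$seed + 97L)
  rows <- vector("list", k)
  pooled_pred <- character(length(y))
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    clf <- build_classifier(config, input_dim = nrow(features[[1]]$values),
                            table = table)
    clf <- train_classifier(clf, features[train], labels = y[train],
                            epochs = epochs)
    pred <- predict(clf, features[test], type = "class")
    pooled_pred[test] <- pred
    m <- evaluate_metrics(pred, y[test])
    rows[[f]] <- data.frame(fold = f, precision = m$precision,
                            recall = m$recall, f = m$f_measure)
  }
  folds <- do.call(rbind, rows)
  structure(list(
    folds = folds,
    mean = list(precision = mean(folds$precision),
                recall = mean(folds$recall),
                f_measure = mean(folds$f)),
    pooled = evaluate_metrics(pooled_pred, y),
    k = k
  ), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mean P %.3f  R %.3f  F %.3f\n",
              x$k, x$mean$precision, x$mean$recall, x$mean$f_measure))
  invisible(x)
}

#' Write per-fold metrics to TSV
#' @param cv A `cv_metrics` object.
#' @param path Destination (columns fold, precision, recall, f).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(cv, path) {
  utils::write.table(cv$folds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Class-imbalance experiment
#'
#' For each requested (n_pos, n_neg) ratio, subsamples the two pools with
#' a seed, runs [cross_validate()] and tabulates the mean metrics —
#' probing how sensitive training is to the positive:negative ratio.
#'
#' @param pos_features,neg_features `feature_set`s of positive and
#'   negative examples (the pools).
#' @param ratios List of integer pairs `c(n_pos, n_neg)`.
#' @param k Folds passed to [cross_validate()].
#' @param config A [model_config()].
#' @param table The encoding [embedding_table()].
#' @param seed Subsampling seed.
#' @param epochs Optional override of `config$epochs`.
#' @return data.frame with columns `n_pos`, `n_neg`, `precision`,
#'   `recall`, `f` (one row per ratio).
#' @export
imbalance_experiment <- function(pos_features, neg_features, ratios,
                                 k = 10L, config, table, seed = 1L,
                                 epochs = NULL) {
  rows <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    np <- ratios[[i]][1L]; nn <- ratios[[i]][2L]
    if (np < 1L || nn < 1L) {
      stop("each ratio needs at least one example of both classes")
    }
    if (np > length(pos_features) || nn > length(neg_features)) {
      stop(sprintf("ratio (%d, %d) exceeds pool sizes (%d, %d)",
                   np, nn, length(pos_features), length(neg_features)))
    }
    set.seed(seed + i)
    feats <- c(pos_features[sample.int(length(pos_features), np)],
               neg_features[sample.int(length(neg_features), nn)])
    labels <- c(rep("positive", np), rep("negative", nn))
    cv <- cross_validate(structure(feats, class = "feature_set"),
                         labels = labels, k = k, config = config,
                         table = table, epochs = epochs)
    rows[[i]] <- data.frame(n_pos = np, n_neg = nn,
                            precision = cv$mean$precision,
                            recall = cv$mean$recall,
                            f = cv$mean$f_measure)
  }
  do.call(rbind, rows)
}
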