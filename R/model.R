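# Binary relation classifiers over encoded sentence pairs.
#
# The default architecture is a bi-LSTM reading the columns of the feature
# matrix (each column one time step); its forward and backward hidden
# states (hidden_units each) are concatenated per step, passed through a
# per-step fully-connected layer, reduced over time (max by default) and
# fed to a 2-way softmax. LSTM, GRU, bi-GRU and CNN comparators accept the
# identical encoded inputs and emit the identical output shape; only the
# sequence layer changes.

ARCHITECTURES <- c("bilstm", "lstm", "gru", "bigru", "cnn")

#' Model configuration
#'
#' Defaults follow the reference hyperparameter setting: 100 hidden units,
#' learning rate 0.80 (plain mini-batch SGD), fully-connected layer of
#' 1,000, mini-batches of 200, decision threshold 0.5.
#'
#' @param architecture One of `"bilstm"` (default), `"lstm"`, `"gru"`,
#'   `"bigru"`, `"cnn"`.
#' @param hidden_units Hidden state size of each recurrent direction (or
#'   number of convolution filters).
#' @param learning_rate SGD learning rate.
#' @param fc_size Width of the fully-connected layer.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (no early stopping).
#' @param seed Seed controlling parameter initialization and shuffling.
#' @param optimizer Only `"sgd"` is implemented.
#' @param threshold Positive-class decision threshold in (0, 1).
#' @param reduction Sequence-to-decision reduction: `"max"` (default,
#'   max-over-time of the per-step fully-connected outputs), `"mean"`, or
#'   `"final"`.
#' @param clip Global gradient-norm clip (numerical safeguard for the
#'   large learning rate); `Inf` disables.
#' @param freeze_word_vectors Keep word vectors fixed during training
#'   (entity-type vectors are always trainable).
#' @return A `model_config` list.
#' @export
model_config <- function(architecture = "bilstm", hidden_units = 100L,
                         learning_rate = 0.80, fc_size = 1000L,
                         batch_size = 200L, epochs = 30L, seed = 1L,
                         optimizer = "sgd", threshold = 0.5,
                         reduction = "max", clip = 5,
                         freeze_word_vectors = TRUE) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  optimizer <- match.arg(optimizer, "sgd")
  reduction <- match.arg(reduction, c("max", "mean", "final"))
  stopifnot(hidden_units >= 1L, fc_size >= 1L, batch_size >= 1L,
            epochs >= 1L, threshold > 0, threshold < 1, learning_rate > 0,
            clip > 0)
  structure(list(
    architecture = architecture, hidden_units = as.integer(hidden_units),
    learning_rate = learning_rate, fc_size = as.integer(fc_size),
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    seed = as.integer(seed), optimizer = optimizer, threshold = threshold,
    reduction = reduction, clip = clip,
    freeze_word_vectors = isTRUE(freeze_word_vectors)
  ), class = "model_config")
}

# Glorot-uniform matrix; biases zero except the LSTM forget gate (+1).
.glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

.init_recurrent <- function(H, n_in, gates, forget_rows = NULL) {
  W <- .glorot(gates * H, n_in)
  U <- .glorot(gates * H, H)
  b <- numeric(gates * H)
  if (!is.null(forget_rows)) b[forget_rows] <- 1
  list(W = W, U = U, b = b)
}

.init_params <- function(config, n_in) {
  H <- config$hidden_units
  fc <- config$fc_size
  arch <- config$architecture
  params <- list()
  rep_width <- if (arch %in% c("bilstm", "bigru")) 2L * H else H
  if (arch %in% c("lstm", "gru")) {
    gates <- if (arch == "lstm") 4L else 3L
    fr <- if (arch == "lstm") (H + 1L):(2L * H) else NULL
    p <- .init_recurrent(H, n_in, gates, fr)
    params$W <- p$W; params$U <- p$U; params$b <- p$b
  } else if (arch %in% c("bilstm", "bigru")) {
    gates <- if (arch == "bilstm") 4L else 3L
    fr <- if (arch == "bilstm") (H + 1L):(2L * H) else NULL
    pf <- .init_recurrent(H, n_in, gates, fr)
    pb <- .init_recurrent(H, n_in, gates, fr)
    params$Wfw <- pf$W; params$Ufw <- pf$U; params$bfw <- pf$b
    params$Wbw <- pb$W; params$Ubw <- pb$U; params$bbw <- pb$b
  } else {  # cnn
    params$Wc <- .glorot(H, 3L * n_in)
    params$bc <- numeric(H)
    rep_width <- H
  }
  params$Wf <- .glorot(fc, rep_width)
  params$bf <- numeric(fc)
  params$Wo <- .glorot(2L, fc)
  params$bo <- numeric(2L)
  params
}

# arch name used by the C++ layer
.cpp_arch <- function(architecture) architecture

#' Build an (untrained) relation classifier
#'
#' Initializes parameters reproducibly from `config$seed` (Glorot-uniform
#' weights, zero biases, LSTM forget-gate bias 1).
#'
#' @param config A [model_config()].
#' @param input_dim Number of rows of the encoded feature matrices
#'   (`2 * d` for parallel strategies, `d` for sequential).
#' @param table The [embedding_table()] the features were encoded with;
#'   the classifier keeps trainable copies of its vectors and records its
#'   fingerprint.
#' @return A `relation_classifier` object.
#' @export
build_classifier <- function(config, input_dim, table) {
  stopifnot(inherits(config, "model_config"),
            inherits(table, "embedding_table"), input_dim >= 1L)
  if (input_dim %% table$d != 0L) {
    stop(sprintf("input_dim %d is not a multiple of the per-token dimension %d",
                 input_dim, table$d))
  }
  set.seed(config$seed)
  params <- .init_params(config, as.integer(input_dim))
  structure(list(
    config = config, params = params, input_dim = as.integer(input_dim),
    word_vectors = table$word_vectors, tag_vectors = table$tag_vectors,
    d_word = table$d_word, d_ent = table$d_ent,
    table = table, table_fingerprint = table$fingerprint,
    trained = FALSE, loss_history = numeric(0)
  ), class = "relation_classifier")
}

.check_features <- function(clf, features) {
  stopifnot(length(features) >= 1L)
  for (f in features) {
    if (nrow(f$values) != clf$input_dim) {
      stop(sprintf("feature matrix has %d rows; classifier expects %d",
                   nrow(f$values), clf$input_dim))
    }
    if (!identical(f$table_fingerprint, clf$table_fingerprint)) {
      stop("feature matrix was encoded with a different embedding table ",
           "than this classifier")
    }
  }
  invisible(TRUE)
}

.label_to_int <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) labels <- ifelse(labels > 0, "positive", "negative")
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad)) stop("labels must be positive/negative; got: ",
                        paste(bad, collapse = ", "))
  as.integer(labels == "positive")  # 0 = negative, 1 = positive
}

.global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
}

#' Train a relation classifier
#'
#' Minimizes two-class cross-entropy by plain mini-batch stochastic
#' gradient descent with seeded shuffling. Entity-type embedding vectors
#' are updated along with the network parameters; word vectors are frozen
#' unless `config$freeze_word_vectors` is `FALSE`. Gradients are averaged
#' over each mini-batch and globally norm-clipped at `config$clip`.
#'
#' @param clf A classifier from [build_classifier()].
#' @param features A `feature_set` from [encode_pairs()].
#' @param labels Gold labels (`"positive"`/`"negative"`, logical or 0/1);
#'   defaults to the labels stored in the features. Both classes must be
#'   present.
#' @param epochs Optional override of `config$epochs`.
#' @param verbose Print the per-epoch mean loss.
#' @return The trained classifier with `loss_history` (mean loss per
#'   epoch) filled in.
#' @export
train_classifier <- function(clf, features, labels = NULL, epochs = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(clf, "relation_classifier"))
  .check_features(clf, features)
  if (is.null(labels)) {
    labels <- vapply(features, function(f) f$label %||% NA_character_, "")
  }
  y <- .label_to_int(labels)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes")
  }
  stopifnot(length(y) == length(features))
  n <- length(features)
  cfg <- clf$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  widx <- lapply(features, `[[`, "word_idx")
  tidx <- lapply(features, `[[`, "tag_idx")
  update_words <- !cfg$freeze_word_vectors

  set.seed(cfg$seed + 1L)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      bs <- length(idx)
      res <- nn_batch_grad(.cpp_arch(cfg$architecture), clf$params,
                           clf$word_vectors, clf$tag_vectors,
                           widx[idx], tidx[idx], y[idx],
                           cfg$reduction, update_words)
      total_loss <- total_loss + res$loss
      grads <- lapply(res$grads, function(g) g / bs)
      dT <- res$dTemb / bs
      dW <- if (update_words) res$dWemb / bs else NULL
      gn <- sqrt(.global_norm(grads)^2 + sum(dT^2) +
                 if (update_words) sum(dW^2) else 0)
      scale <- if (is.finite(cfg$clip) && gn > cfg$clip) cfg$clip / gn else 1
      lr <- cfg$learning_rate * scale
      for (nm in names(clf$params)) {
        clf$params[[nm]] <- clf$params[[nm]] - lr * grads[[nm]]
      }
      clf$tag_vectors <- clf$tag_vectors - lr * dT
      if (update_words) clf$word_vectors <- clf$word_vectors - lr * dW
    }
    history[ep] <- total_loss / n
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, history[ep]))
  }
  clf$loss_history <- c(clf$loss_history, history)
  clf$trained <- TRUE
  clf
}

#' Predict class probabilities for encoded pairs
#'
#' @param object A trained `relation_classifier`.
#' @param features A `feature_set` or a single `feature_matrix`.
#' @param type `"prob"` for a two-column matrix (`p_negative`,
#'   `p_positive`), `"class"` for `"positive"`/`"negative"` labels at the
#'   configured threshold (positive iff `p_positive >= threshold`), or
#'   `"score"` for the positive-class probability vector.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.relation_classifier <- function(object, features, type = "prob",
                                        ...) {
  type <- match.arg(type, c("prob", "class", "score"))
  if (inherits(features, "feature_matrix")) features <- list(features)
  .check_features(object, features)
  probs <- nn_predict_batch(.cpp_arch(object$config$architecture),
                            object$params, object$word_vectors,
                            object$tag_vectors,
                            lapply(features, `[[`, "word_idx"),
                            lapply(features, `[[`, "tag_idx"),
                            object$config$reduction)
  colnames(probs) <- c("p_negative", "p_positive")
  switch(type,
    prob = probs,
    score = probs[, "p_positive"],
    class = ifelse(probs[, "p_positive"] >= object$config$threshold,
                   "positive", "negative"))
}

#' @export
print.relation_classifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Relation classifier (%s)\n", cfg$architecture))
  cat(sprintf("  input dim %d, hidden %d, fc %d, threshold %.2f, %s\n",
              x$input_dim, cfg$hidden_units, cfg$fc_size, cfg$threshold,
              if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                                     length(x$loss_history),
                                     tail(x$loss_history, 1))
              else "untrained"))
  invisible(x)
}

#' @export
summary.relation_classifier <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, 0L)) +
    length(object$tag_vectors) +
    if (object$config$freeze_word_vectors) 0L else length(object$word_vectors)
  out <- list(architecture = object$config$architecture,
              input_dim = object$input_dim,
              n_parameters = n_par,
              trained = object$trained,
              loss_history = object$loss_history,
              config = object$config)
  class(out) <- "summary.relation_classifier"
  out
}

#' @export
print.summary.relation_classifier <- function(x, ...) {
  cat(sprintf("Relation classifier: %s, %d trainable parameters (%s)\n",
              x$architecture, x$n_parameters,
              if (x$trained) "trained" else "untrained"))
  if (length(x$loss_history)) {
    cat(sprintf("  loss: initial %.4f, final %.4f over %d epochs\n",
                x$loss_history[1], tail(x$loss_history, 1),
                length(x$loss_history)))
  }
  invisible(x)
}

#' @export
coef.relation_classifier <- function(object, ...) object$params

#' Save / load a classifier checkpoint
#'
#' A single-file serialized parameter set with the embedded configuration
#' and the fingerprint of the embedding table it was trained against.
#' [read_checkpoint()] refuses to load against a mismatched encoder
#' configuration.
#'
#' @param clf A `relation_classifier`.
#' @param path Checkpoint file path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   the restored classifier.
#' @export
write_checkpoint <- function(clf, path) {
  stopifnot(inherits(clf, "relation_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @param table Optional [embedding_table()]; when given, the checkpoint's
#'   stored fingerprint must match it.
#' @export
read_checkpoint <- function(path, table = NULL) {
  clf <- readRDS(path)
  if (!inherits(clf, "relation_classifier")) {
    stop("not a relation_classifier checkpoint: ", path)
  }
  if (!is.null(table) &&
      !identical(clf$table_fingerprint, table$fingerprint)) {
    stop("checkpoint was trained against a different embedding table")
  }
  clf
}
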