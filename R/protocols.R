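# End-to-end experiment protocols on synthetic corpora: pattern-recovery
# (can the pipeline recover planted relations?) and the class-imbalance
# direction study. Both are used by the acceptance machinery and are
# exported so users can rerun them.

# corpus -> labeled encoded features (embedding table built from the
# corpus tokens; no pretrained vectors)
.protocol_setup <- function(seed, n_documents, fraction_positive,
                            d_word, d_ent, hardness = 0) {
  corp <- generate_corpus(sim_config(seed = seed,
                                     n_documents = n_documents,
                                     fraction_positive = fraction_positive,
                                     hardness = hardness))
  docs <- lapply(parse_pubtator(corp$pubtator), split_sentences)
  pairs <- unlist(lapply(docs, extract_candidate_pairs), recursive = FALSE)
  key <- function(d, g, c_, dd) paste(d, g, c_, dd, sep = "|")
  gk <- key(corp$gold$doc_id, corp$gold$gene_id, corp$gold$chemical_id,
            corp$gold$disease_id)
  labels <- corp$gold$label[match(
    vapply(pairs, function(p) key(p$doc_id, p$gene_id, p$chemical_id,
                                  p$disease_id), ""), gk)]
  keep <- !is.na(labels)
  pairs <- pairs[keep]; labels <- labels[keep]
  tokens <- unlist(lapply(pairs, function(p) {
    c(p$relation_tokens$text, p$context_tokens$text)
  }), use.names = FALSE)
  table <- embedding_table(tokens, d_word = d_word, d_ent = d_ent,
                           seed = seed + 11L)
  features <- encode_pairs(pairs, table, labels = labels)
  list(pairs = pairs, labels = labels, features = features, table = table)
}

#' Bag-of-words logistic baseline
#'
#' Ridge-penalized logistic regression over token counts of both
#' sentences; an independent check that a corpus is lexically separable
#' before any sequence model is credited with learning it.
#'
#' @param pairs List of `candidate_pair`.
#' @param labels `"positive"`/`"negative"` labels.
#' @param test_idx Indices of the held-out set.
#' @param lambda Ridge penalty.
#' @return A `relation_metrics` for the held-out set.
#' @export
bow_baseline <- function(pairs, labels, test_idx, lambda = 0.01) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop("bow_baseline requires the glmnet package")
  }
  texts <- vapply(pairs, function(p) {
    paste(c(p$relation_tokens$text, p$context_tokens$text), collapse = " ")
  }, "")
  toks <- strsplit(tolower(texts), " ", fixed = TRUE)
  vocab <- sort(unique(unlist(toks)))
  X <- matrix(0, length(texts), length(vocab))
  for (i in seq_along(toks)) {
    tb <- table(toks[[i]])
    X[i, match(names(tb), vocab)] <- as.numeric(tb)
  }
  y <- as.integer(labels == "positive")
  fit <- glmnet::glmnet(X[-test_idx, ], y[-test_idx], family = "binomial",
                        alpha = 0, lambda = lambda)
  pred <- as.integer(
    stats::predict(fit, X[test_idx, ], type = "response") >= 0.5)
  evaluate_metrics(ifelse(pred == 1, "positive", "negative"),
                   ifelse(y[test_idx] == 1, "positive", "negative"))
}

#' Pattern-recovery experiment
#'
#' Generates a balanced synthetic corpus (default 500 positive + 500
#' negative candidate pairs), certifies its lexical separability with the
#' bag-of-words baseline, then trains the default bi-LSTM with the
#' reference hyperparameters (100 hidden units, learning rate 0.80,
#' fully-connected size 1,000, mini-batches of 200) and scores a held-out
#' split.
#'
#' @param seed Master seed (corpus, table, model, split).
#' @param n_documents Corpus size (one candidate pair per document).
#' @param holdout Held-out pair count.
#' @param epochs Training epochs.
#' @param d_word,d_ent Embedding sizes.
#' @return List: `bow` and `bilstm` (`relation_metrics` on the same
#'   held-out set), `n` (total pairs).
#' @export
pattern_recovery_run <- function(seed = 1L, n_documents = 1000L,
                                 holdout = 200L, epochs = 100L,
                                 d_word = 200L, d_ent = 20L) {
  setup <- .protocol_setup(seed, n_documents, fraction_positive = 0.5,
                           d_word = d_word, d_ent = d_ent)
  set.seed(seed + 29L)
  test_idx <- sample(length(setup$features), holdout)
  bow <- bow_baseline(setup$pairs, setup$labels, test_idx)
  cfg <- model_config(architecture = "bilstm", hidden_units = 100L,
                      learning_rate = 0.80, fc_size = 1000L,
                      batch_size = 200L, epochs = epochs,
                      seed = seed + 43L)
  clf <- build_classifier(cfg, input_dim = 2L * setup$table$d,
                          table = setup$table)
  clf <- train_classifier(
    clf, structure(setup$features[-test_idx], class = "feature_set"),
    labels = setup$labels[-test_idx])
  pred <- predict(clf, structure(setup$features[test_idx],
                                 class = "feature_set"), type = "class")
  list(bow = bow, bilstm = evaluate_metrics(pred, setup$labels[test_idx]),
       n = length(setup$features))
}

#' Class-imbalance direction experiment
#'
#' Repeats the balanced-versus-imbalanced comparison over several seeds:
#' pools of 500 positive and 1,000 negative synthetic pairs, mean
#' cross-validated F for the (500, 500) and (500, 1000) training ratios.
#' Run at a reduced scale (3 folds, a compact bi-LSTM) so the comparison
#' is repeatable on a desktop; the claim probed is the direction of the
#' difference, not its magnitude.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param n_pos,n_neg Pool sizes.
#' @param k Cross-validation folds per ratio.
#' @param config Model configuration for each fold (default: bi-LSTM,
#'   32 hidden units, fully-connected 64, mini-batches of 32, 25 epochs).
#' @param d_word,d_ent Embedding sizes (compact by default).
#' @return data.frame: `seed`, `f_balanced`, `f_imbalanced`.
#' @export
imbalance_direction_run <- function(seeds = 1:5, n_pos = 500L,
                                    n_neg = 1000L, k = 3L, config = NULL,
                                    d_word = 50L, d_ent = 10L) {
  rows <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    seed <- seeds[i]
    setup <- .protocol_setup(seed, n_documents = n_pos + n_neg,
                             fraction_positive = n_pos / (n_pos + n_neg),
                             d_word = d_word, d_ent = d_ent)
    cfg <- config %||% model_config(architecture = "bilstm",
                                    hidden_units = 32L, fc_size = 64L,
                                    batch_size = 32L, epochs = 25L,
                                    seed = seed + 7L)
    pos <- structure(setup$features[setup$labels == "positive"],
                     class = "feature_set")
    neg <- structure(setup$features[setup$labels == "negative"],
                     class = "feature_set")
    n_pos_avail <- min(n_pos, length(pos))
    n_neg_half <- min(n_pos_avail, length(neg))
    res <- imbalance_experiment(
      pos, neg,
      list(c(n_pos_avail, n_neg_half),
           c(n_pos_avail, min(n_neg, length(neg)))),
      k = k, config = cfg, table = setup$table, seed = seed + 13L)
    rows[[i]] <- data.frame(seed = seed, f_balanced = res$f[1],
                            f_imbalanced = res$f[2])
  }
  do.call(rbind, rows)
}
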