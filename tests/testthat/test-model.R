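# Helpers building tiny random sequences for direct checks of the
# compiled forward/backward passes.
tiny_setup <- function(seed = 42, V = 10, d_word = 4, d_ent = 2,
                       nblocks = 2) {
  set.seed(seed)
  Wemb <- matrix(runif(d_word * (V + 1), -.5, .5), d_word)
  Temb <- matrix(runif(d_ent * 7, -.5, .5), d_ent)
  mk <- function(T) {
    w <- matrix(sample(0:(V + 1), nblocks * T, replace = TRUE), nblocks)
    t <- matrix(sample(1:7, nblocks * T, replace = TRUE), nblocks)
    t[w == 0] <- 1L
    storage.mode(w) <- "integer"; storage.mode(t) <- "integer"
    list(w = w, t = t)
  }
  seqs <- lapply(c(3, 5, 4), mk)
  list(Wemb = Wemb, Temb = Temb,
       widx = lapply(seqs, `[[`, "w"), tidx = lapply(seqs, `[[`, "t"),
       y = c(0L, 1L, 1L), n_in = nblocks * (d_word + d_ent))
}

tiny_params <- function(arch, n_in, H = 3, fc = 5) {
  g <- function(nr, nc) matrix(rnorm(nr * nc, 0, .3), nr, nc)
  p <- list()
  repw <- H
  if (arch %in% c("lstm", "gru")) {
    k <- if (arch == "lstm") 4 else 3
    p$W <- g(k * H, n_in); p$U <- g(k * H, H); p$b <- rnorm(k * H, 0, .1)
  } else if (arch %in% c("bilstm", "bigru")) {
    k <- if (arch == "bilstm") 4 else 3
    p$Wfw <- g(k * H, n_in); p$Ufw <- g(k * H, H); p$bfw <- rnorm(k * H, 0, .1)
    p$Wbw <- g(k * H, n_in); p$Ubw <- g(k * H, H); p$bbw <- rnorm(k * H, 0, .1)
    repw <- 2 * H
  } else {
    p$Wc <- g(H, 3 * n_in); p$bc <- rnorm(H, 0, .1)
  }
  p$Wf <- g(fc, repw); p$bf <- rnorm(fc, 0, .1)
  p$Wo <- g(2, fc); p$bo <- rnorm(2, 0, .1)
  p
}

test_that("analytic gradients match finite differences for every architecture", {
  s <- tiny_setup()
  eps <- 1e-6
  loss_fn <- function(arch, p, We, Te) {
    dgcminer:::nn_batch_grad(arch, p, We, Te, s$widx, s$tidx, s$y,
                             "max", TRUE)$loss
  }
  set.seed(7)
  for (arch in c("lstm", "bilstm", "gru", "bigru", "cnn")) {
    p <- tiny_params(arch, s$n_in)
    res <- dgcminer:::nn_batch_grad(arch, p, s$Wemb, s$Temb, s$widx,
                                    s$tidx, s$y, "max", TRUE)
    for (nm in names(p)) {
      for (ii in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
        p2 <- p; p2[[nm]][ii] <- p2[[nm]][ii] + eps
        p3 <- p; p3[[nm]][ii] <- p3[[nm]][ii] - eps
        num <- (loss_fn(arch, p2, s$Wemb, s$Temb) -
                loss_fn(arch, p3, s$Wemb, s$Temb)) / (2 * eps)
        expect_equal(res$grads[[nm]][ii], num, tolerance = 1e-3,
                     label = paste(arch, nm, "gradient"))
      }
    }
    # entity-type embedding gradient
    for (ii in sample(length(s$Temb), 3)) {
      T2 <- s$Temb; T2[ii] <- T2[ii] + eps
      T3 <- s$Temb; T3[ii] <- T3[ii] - eps
      num <- (loss_fn(arch, p, s$Wemb, T2) -
              loss_fn(arch, p, s$Wemb, T3)) / (2 * eps)
      expect_equal(res$dTemb[ii], num, tolerance = 1e-3,
                   label = paste(arch, "tag-vector gradient"))
    }
  }
})

test_that("softmax outputs are valid probabilities on random inputs", {
  s <- tiny_setup(seed = 9)
  set.seed(11)
  for (arch in c("bilstm", "cnn")) {
    p <- tiny_params(arch, s$n_in)
    probs <- dgcminer:::nn_predict_batch(arch, p, s$Wemb, s$Temb,
                                         s$widx, s$tidx, "max")
    expect_true(all(probs >= 0))
    expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  }
  # many random parameter draws
  for (rep in 1:50) {
    p <- tiny_params("bilstm", s$n_in)
    probs <- dgcminer:::nn_predict_batch("bilstm", p, s$Wemb, s$Temb,
                                         s$widx[1], s$tidx[1], "max")
    expect_equal(sum(probs), 1, tolerance = 1e-6)
  }
})

test_that("identical configs and seeds build identical classifiers", {
  tab <- embedding_table(letters, d_word = 8, d_ent = 2, seed = 4)
  cfg <- model_config(hidden_units = 5, fc_size = 7, seed = 3)
  c1 <- build_classifier(cfg, input_dim = 20, table = tab)
  c2 <- build_classifier(cfg, input_dim = 20, table = tab)
  expect_identical(c1$params, c2$params)
})

test_that("the classifier surface follows the reference widths", {
  tab <- embedding_table(letters, d_word = 8, d_ent = 2, seed = 4)
  cfg <- model_config(hidden_units = 100, fc_size = 1000, seed = 1)
  clf <- build_classifier(cfg, input_dim = 20, table = tab)
  # bi-LSTM: forward 100 + backward 100 = 200 per-step representation
  expect_equal(ncol(clf$params$Wf), 200)
  expect_equal(nrow(clf$params$Wf), 1000)
  expect_equal(dim(clf$params$Wo), c(2, 1000))
  s <- summary(clf)
  expect_false(s$trained)
  expect_true(s$n_parameters > 0)
})

test_that("training memorizes a tiny separable set and is deterministic", {
  lp <- make_labeled_pairs(sim_config(seed = 51, n_documents = 8))
  enc <- encode_corpus(lp, d_word = 16, d_ent = 4)
  pos <- which(enc$labels == "positive")[1]
  neg <- which(enc$labels == "negative")[1]
  feats <- as_feature_set(enc$features[rep(c(pos, neg), 10)])
  labels <- rep(c("positive", "negative"), 10)
  cfg <- model_config(hidden_units = 8, fc_size = 16, batch_size = 4,
                      epochs = 25, seed = 2)
  clf <- build_classifier(cfg, input_dim = 2 * enc$table$d,
                          table = enc$table)
  t1 <- train_classifier(clf, feats, labels = labels)
  pred <- predict(t1, feats, type = "class")
  expect_equal(pred, labels)  # perfect memorization
  expect_lt(tail(t1$loss_history, 1), t1$loss_history[1])
  # determinism: identical run gives identical loss history and params
  t2 <- train_classifier(clf, feats, labels = labels)
  expect_identical(t1$loss_history, t2$loss_history)
  expect_identical(t1$params, t2$params)
})

test_that("single-class training sets are rejected", {
  lp <- make_labeled_pairs(sim_config(seed = 52, n_documents = 6,
                                      fraction_positive = 1))
  enc <- encode_corpus(lp, d_word = 8, d_ent = 2)
  cfg <- model_config(hidden_units = 4, fc_size = 8, epochs = 1)
  clf <- build_classifier(cfg, input_dim = 2 * enc$table$d,
                          table = enc$table)
  expect_error(train_classifier(clf, as_feature_set(enc$features),
                                labels = enc$labels),
               "both classes")
})

test_that("batch prediction equals element-wise prediction", {
  lp <- make_labeled_pairs(sim_config(seed = 53, n_documents = 10))
  enc <- encode_corpus(lp, d_word = 8, d_ent = 2)
  cfg <- model_config(hidden_units = 4, fc_size = 8, epochs = 2,
                      batch_size = 4, seed = 5)
  clf <- build_classifier(cfg, input_dim = 2 * enc$table$d,
                          table = enc$table)
  clf <- train_classifier(clf, as_feature_set(enc$features),
                          labels = enc$labels)
  batch <- predict(clf, as_feature_set(enc$features), type = "prob")
  single <- t(vapply(enc$features,
                     function(f) predict(clf, f, type = "prob")[1, ],
                     numeric(2)))
  expect_equal(unname(batch), unname(single), tolerance = 1e-12)
})

test_that("labels follow the 0.5 decision threshold", {
  # p_positive = 0.49 -> negative; 0.5 -> positive
  expect_equal(model_config()$threshold, 0.5)
  probs <- c(0.49, 0.5, 0.97)
  lab <- ifelse(probs >= 0.5, "positive", "negative")
  expect_equal(lab, c("negative", "positive", "positive"))
  lp <- make_labeled_pairs(sim_config(seed = 54, n_documents = 6))
  enc <- encode_corpus(lp, d_word = 8, d_ent = 2)
  cfg <- model_config(hidden_units = 4, fc_size = 8, epochs = 2,
                      batch_size = 4, seed = 5)
  clf <- build_classifier(cfg, input_dim = 2 * enc$table$d,
                          table = enc$table)
  clf <- train_classifier(clf, as_feature_set(enc$features),
                          labels = enc$labels)
  probs <- predict(clf, as_feature_set(enc$features), type = "prob")
  cls <- predict(clf, as_feature_set(enc$features), type = "class")
  expect_equal(cls, ifelse(probs[, "p_positive"] >= 0.5,
                           "positive", "negative"))
})

test_that("all architectures accept the same inputs and emit the same shapes", {
  lp <- make_labeled_pairs(sim_config(seed = 55, n_documents = 12))
  enc <- encode_corpus(lp, d_word = 8, d_ent = 2)
  for (arch in c("bilstm", "lstm", "gru", "bigru", "cnn")) {
    cfg <- model_config(architecture = arch, hidden_units = 4, fc_size = 8,
                        epochs = 1, batch_size = 6, seed = 5)
    clf <- build_classifier(cfg, input_dim = 2 * enc$table$d,
                            table = enc$table)
    clf <- train_classifier(clf, as_feature_set(enc$features),
                            labels = enc$labels)
    probs <- predict(clf, as_feature_set(enc$features), type = "prob")
    expect_equal(dim(probs), c(length(enc$features), 2))
    expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  }
})

test_that("mismatched feature shapes and tables are refused", {
  tab <- embedding_table(letters, d_word = 8, d_ent = 2, seed = 4)
  cfg <- model_config(hidden_units = 4, fc_size = 8)
  clf <- build_classifier(cfg, input_dim = 20, table = tab)
  lp <- make_labeled_pairs(sim_config(seed = 56, n_documents = 4))
  enc <- encode_corpus(lp, d_word = 4, d_ent = 2)
  expect_error(predict(clf, as_feature_set(enc$features)), "rows")
  expect_error(build_classifier(cfg, input_dim = 21, table = tab),
               "multiple")
})

test_that("checkpoints round-trip and refuse mismatched tables", {
  lp <- make_labeled_pairs(sim_config(seed = 57, n_documents = 6))
  enc <- encode_corpus(lp, d_word = 8, d_ent = 2)
  cfg <- model_config(hidden_units = 4, fc_size = 8, epochs = 1,
                      batch_size = 4)
  clf <- build_classifier(cfg, input_dim = 2 * enc$table$d,
                          table = enc$table)
  clf <- train_classifier(clf, as_feature_set(enc$features),
                          labels = enc$labels)
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(clf, path)
  back <- read_checkpoint(path, table = enc$table)
  expect_identical(back$params, clf$params)
  expect_identical(
    predict(back, as_feature_set(enc$features), type = "score"),
    predict(clf, as_feature_set(enc$features), type = "score"))
  other <- embedding_table("zzz", d_word = 8, d_ent = 2, seed = 99)
  expect_error(read_checkpoint(path, table = other), "different")
})
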