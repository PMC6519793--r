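test_that("embedding dimensions follow the 200 + 20 = 220 scheme", {
  tab <- embedding_table(c("sun", "increased", "bnp"), seed = 1)
  expect_equal(tab$d_word, 200L)
  expect_equal(tab$d_ent, 20L)
  expect_equal(tab$d, 220L)
  expect_equal(nrow(tab$tag_vectors), 20)
  expect_equal(ncol(tab$tag_vectors), 7)
  v <- embed_token("sun", "B-chemical", tab)
  expect_length(v, 220)
})

test_that("tables are reproducible from the seed", {
  toks <- c("alpha", "beta", "gamma")
  t1 <- embedding_table(toks, d_word = 16, d_ent = 4, seed = 42)
  t2 <- embedding_table(toks, d_word = 16, d_ent = 4, seed = 42)
  expect_identical(t1$word_vectors, t2$word_vectors)
  expect_identical(t1$tag_vectors, t2$tag_vectors)
  expect_identical(t1$fingerprint, t2$fingerprint)
  t3 <- embedding_table(toks, d_word = 16, d_ent = 4, seed = 43)
  expect_false(identical(t1$word_vectors, t3$word_vectors))
})

test_that("pretrained vectors override random rows for covered tokens", {
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c(paste("alpha", paste(rep("0.25", 6), collapse = " ")),
               paste("gamma", paste(rep("-1.5", 6), collapse = " "))),
             path)
  tab <- embedding_table(c("alpha", "beta", "gamma"), pretrained = path,
                         d_word = 6, d_ent = 2, seed = 1)
  expect_equal(unname(tab$word_vectors[, tab$vocab[["alpha"]]]),
               rep(0.25, 6))
  expect_equal(unname(tab$word_vectors[, tab$vocab[["gamma"]]]),
               rep(-1.5, 6))
  # uncovered token keeps its random row
  expect_true(all(abs(tab$word_vectors[, tab$vocab[["beta"]]]) <= 0.05))

  bad <- withr::local_tempfile(fileext = ".vec")
  writeLines("alpha 0.1 0.2", bad)
  expect_error(embedding_table("alpha", pretrained = bad, d_word = 6,
                               d_ent = 2),
               "expected 6")
})

test_that("embed_token concatenates word and tag parts", {
  tab <- embedding_table(c("sun", "bnp"), d_word = 10, d_ent = 3, seed = 2)
  v_o <- embed_token("sun", "O", tab)
  expect_equal(v_o[1:10],
               unname(tab$word_vectors[, tab$vocab[["sun"]]]))
  # same token, different tag: only the last d_ent entries change
  v_b <- embed_token("sun", "B-chemical", tab)
  expect_equal(v_b[1:10], v_o[1:10])
  expect_false(identical(v_b[11:13], v_o[11:13]))
  # padding pseudo-token is all-zero
  expect_equal(embed_token(NA, "O", tab), rep(0, 13))
  # unknown words share the unknown row
  expect_equal(embed_token("zzzz", "O", tab)[1:10],
               embed_token("qqqq", "O", tab)[1:10])
  expect_error(embed_token("sun", "B-foo", tab), "unknown BIO tag")
})

test_that("parallel encodings align anchors and zero the padding", {
  lp <- make_labeled_pairs(sim_config(seed = 31, n_documents = 40))
  enc <- encode_corpus(lp, d_word = 12, d_ent = 4)
  d <- enc$table$d
  for (i in seq_along(enc$features)) {
    f <- enc$features[[i]]
    p <- lp$pairs[[i]]
    expect_equal(nrow(f$values), 2 * d)
    # anchor embeddings occupy the anchor column in both halves
    a <- f$anchor_col
    rel_anchor <- embed_token(
      p$relation_tokens$text[p$anchor_relation],
      p$relation_tokens$bio_tag[p$anchor_relation], enc$table)
    ctx_anchor <- embed_token(
      p$context_tokens$text[p$anchor_context],
      p$context_tokens$bio_tag[p$anchor_context], enc$table)
    expect_equal(f$values[1:d, a], rel_anchor)
    expect_equal(f$values[(d + 1):(2 * d), a], ctx_anchor)
    # mask-false cells are exactly zero; mask-true counts = token counts
    expect_true(all(f$values[!f$mask] == 0))
    expect_equal(sum(f$mask[1:d, ]) / d, nrow(p$relation_tokens))
    expect_equal(sum(f$mask[(d + 1):(2 * d), ]) / d,
                 nrow(p$context_tokens))
  }
})

test_that("hand-computed alignment for a 6/8-token pair", {
  lines <- c("21|t|T.",
             "21|a|Small GENE1 rose fast after CHEM1. Bad DIS1 killed many patients slowly on.",
             "21\t9\t14\tGENE1\tGene\tG1",
             "21\t31\t36\tCHEM1\tChemical\tC1",
             "21\t42\t46\tDIS1\tDisease\tD1")
  doc <- parse_and_segment(lines)[[1]]
  p <- extract_candidate_pairs(doc)[[1]]
  # relation sentence: Small GENE1 rose fast after CHEM1 .  (anchor = 2)
  # context sentence:  Bad DIS1 killed many patients slowly on .  (anchor = 2)
  expect_equal(p$anchor_relation, 2L)
  expect_equal(p$anchor_context, 2L)
  tab <- embedding_table(c(p$relation_tokens$text, p$context_tokens$text),
                         d_word = 8, d_ent = 2, seed = 1)
  f <- encode_pair(p, tab)
  expect_equal(f$anchor_col, 2L)
  expect_equal(ncol(f$values), 8L)  # max(0+7, 0+8)
  expect_equal(unname(f$word_idx[1, 8]), 0L)  # relation right-padded
})

test_that("sequential encoding concatenates with one separator column", {
  lp <- make_labeled_pairs(sim_config(seed = 32, n_documents = 10))
  tab <- embedding_table(
    unlist(lapply(lp$pairs, function(p) p$relation_tokens$text)),
    d_word = 10, d_ent = 2, seed = 3)
  for (p in lp$pairs[1:5]) {
    f <- encode_pair(p, tab, strategy = "sequential")
    m <- nrow(p$relation_tokens); n <- nrow(p$context_tokens)
    expect_equal(nrow(f$values), tab$d)
    expect_equal(ncol(f$values), m + 1L + n)
    expect_true(all(f$values[, m + 1L] == 0))
    expect_false(f$mask[1, m + 1L])
  }
})

test_that("encoding is a pure function of its inputs", {
  lp <- make_labeled_pairs(sim_config(seed = 33, n_documents = 5))
  tab <- embedding_table(
    unlist(lapply(lp$pairs, function(p) p$relation_tokens$text)),
    d_word = 10, d_ent = 2, seed = 3)
  f1 <- encode_pair(lp$pairs[[1]], tab)
  f2 <- encode_pair(lp$pairs[[1]], tab)
  expect_identical(f1, f2)
})

test_that("strategies requiring absent anchors error out", {
  lines <- c("22|t|T.",
             "22|a|CHEM9 worsened DIS9 via GENE9 signaling.",
             "22\t3\t8\tCHEM9\tChemical\tC9",
             "22\t18\t22\tDIS9\tDisease\tD9",
             "22\t27\t32\tGENE9\tGene\tG9")
  doc <- parse_and_segment(lines)[[1]]
  p_cd <- extract_candidate_pairs(doc, configuration = "cd+g")[[1]]
  expect_error(encode_pair(p_cd, embedding_table("x", d_word = 4, d_ent = 2),
                           strategy = "parallel_chem_disease"),
               "disease mention")
})

test_that("long sentences are truncated without dropping mention tokens", {
  filler <- paste(rep("word", 40), collapse = " ")
  abstract <- paste0(filler, " CHEM2 hit GENE2 in DIS2 cases.")
  off <- nchar("T. ") + nchar(filler)
  lines <- c("23|t|T.", paste0("23|a|", abstract),
             sprintf("23\t%d\t%d\tCHEM2\tChemical\tC2", off + 1, off + 6),
             sprintf("23\t%d\t%d\tGENE2\tGene\tG2", off + 11, off + 16),
             sprintf("23\t%d\t%d\tDIS2\tDisease\tD2", off + 20, off + 24))
  doc <- parse_and_segment(lines)[[1]]
  p <- extract_candidate_pairs(doc)[[1]]
  tab <- embedding_table(p$relation_tokens$text, d_word = 4, d_ent = 2)
  f <- encode_pair(p, tab, max_tokens = 10L)
  # all mention tokens survive even though the cap is 10
  gene_col <- f$anchor_col
  expect_true(gene_col <= ncol(f$values))
  expect_true(all(f$word_idx[1, ][f$tag_idx[1, ] %in% 1:6] > 0))
})
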