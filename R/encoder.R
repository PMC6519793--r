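# Mapping candidate pairs to fixed-shape 2-D feature matrices.
#
# Each token is embedded as the concatenation of a word vector (d_word,
# default 200) and a BIO entity-type vector (d_ent, default 20), giving a
# per-token dimension of 220 by default. A parallel encoding stacks the
# relation and context sentences as two row blocks of one matrix, the
# sentences left-padded so their anchor mentions share a column; a
# sequential encoding appends the context sentence after the relation
# sentence with one padding column between them.

ENCODING_STRATEGIES <- c("parallel_gene_disease", "parallel_first",
                         "parallel_chem_disease", "sequential")

#' Build a word + entity-type embedding table
#'
#' Tokens present in an optional pretrained vector file take their vectors
#' from it; all other word rows, the unknown-word row and the 7 entity-tag
#' rows are drawn from a seeded uniform(-0.05, 0.05). The padding row is
#' exactly zero. Vocabulary lookup is case-insensitive (tokens are
#' case-folded).
#'
#' @param tokens Character vector of corpus tokens (duplicates fine).
#' @param pretrained Optional path to a plain-text vector file: one token
#'   per line followed by `d_word` whitespace-separated decimals.
#' @param d_word Word-vector size (default 200).
#' @param d_ent Entity-type vector size (default 20).
#' @param seed Integer seed controlling all random rows.
#' @return An `embedding_table` with elements `vocab` (token -> column),
#'   `word_vectors` (`d_word` x (|V|+1), column 1 = unknown), `tag_vectors`
#'   (`d_ent` x 7), `d_word`, `d_ent`, `d` and a `fingerprint`.
#' @export
embedding_table <- function(tokens, pretrained = NULL, d_word = 200L,
                            d_ent = 20L, seed = 1L) {
  stopifnot(d_word >= 1L, d_ent >= 1L)
  vocab_tokens <- sort(unique(tolower(tokens)))
  V <- length(vocab_tokens)
  set.seed(seed)
  word_vectors <- matrix(runif((V + 1L) * d_word, -0.05, 0.05),
                         nrow = d_word)  # col 1 = unknown word
  tag_vectors <- matrix(runif(7L * d_ent, -0.05, 0.05), nrow = d_ent)
  colnames(tag_vectors) <- bio_tagset()
  if (!is.null(pretrained)) {
    pv <- read_pretrained_vectors(pretrained, d_word)
    hit <- match(vocab_tokens, names(pv))
    for (i in which(!is.na(hit))) {
      word_vectors[, i + 1L] <- pv[[hit[i]]]
    }
  }
  vocab <- stats::setNames(seq_len(V) + 1L, vocab_tokens)
  tab <- structure(
    list(vocab = vocab, word_vectors = word_vectors,
         tag_vectors = tag_vectors, d_word = as.integer(d_word),
         d_ent = as.integer(d_ent), d = as.integer(d_word + d_ent),
         seed = as.integer(seed)),
    class = "embedding_table")
  tab$fingerprint <- .table_fingerprint(tab)
  tab
}

.table_fingerprint <- function(tab) {
  sprintf("v%d:w%d:e%d:%.10e:%.10e", length(tab$vocab), tab$d_word,
          tab$d_ent, sum(tab$word_vectors), sum(tab$tag_vectors))
}

#' Read a plain-text pretrained word-vector file
#'
#' One token per line, followed by `d_word` whitespace-separated decimals.
#'
#' @param path File path.
#' @param d_word Expected vector length; a line with a different length is
#'   a fatal format error.
#' @return Named list of numeric vectors (names case-folded).
#' @export
read_pretrained_vectors <- function(path, d_word) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (length(v) != d_word || anyNA(v)) {
      stop(sprintf("pretrained vector file %s: line %d has %d values, expected %d",
                   path, i, length(f) - 1L, d_word))
    }
    nms[i] <- tolower(f[1])
    out[[i]] <- v
  }
  stats::setNames(out, nms)
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table |V|=%d d_word=%d d_ent=%d d=%d>\n",
              length(x$vocab), x$d_word, x$d_ent, x$d))
  invisible(x)
}

# word column indices for tokens (0 reserved for padding, 1 = unknown)
.word_index <- function(table, tokens) {
  idx <- unname(table$vocab[tolower(tokens)])
  idx[is.na(idx)] <- 1L
  as.integer(idx)
}

.tag_index <- function(tags) {
  idx <- match(tags, bio_tagset())
  if (anyNA(idx)) stop("unknown BIO tag(s): ",
                       paste(unique(tags[is.na(idx)]), collapse = ", "))
  as.integer(idx)
}

#' Embed a single token
#'
#' Concatenation of the token's word vector (or the unknown-word row) with
#' the BIO tag's entity-type vector. The padding pseudo-token (`NA`) maps
#' to the all-zero vector.
#'
#' @param token Character scalar, or `NA` for padding.
#' @param tag One of [bio_tagset()] (ignored for padding).
#' @param table An [embedding_table()].
#' @return Numeric vector of length `table$d`.
#' @export
embed_token <- function(token, tag, table) {
  if (length(token) != 1L) stop("embed_token is scalar")
  if (is.na(token)) return(numeric(table$d))
  w <- .word_index(table, token)
  g <- .tag_index(tag)
  c(table$word_vectors[, w], table$tag_vectors[, g])
}

# resolve (anchor_relation, anchor_context) token indices for a strategy
.resolve_anchors <- function(pair, strategy) {
  roles <- .config_roles(pair$configuration)
  switch(strategy,
    parallel_gene_disease = c(pair$anchor_relation, pair$anchor_context),
    parallel_first = c(1L, 1L),
    parallel_chem_disease = {
      if (!"chemical" %in% roles$relation) {
        stop("strategy parallel_chem_disease requires a chemical mention ",
             "in the relation sentence (configuration ", pair$configuration,
             ")")
      }
      if (roles$context != "disease") {
        stop("strategy parallel_chem_disease requires the disease mention ",
             "in the context sentence (configuration ", pair$configuration,
             ")")
      }
      c(pair$mention_tokens$chemical[1L], pair$mention_tokens$disease[1L])
    },
    stop("unknown strategy: ", strategy)
  )
}

# truncate a token table from the right, never dropping an anchor or any
# mention token belonging to it
.truncate_tokens <- function(n_tokens, keep_at_least, max_tokens) {
  if (n_tokens <= max_tokens) return(n_tokens)
  max(max_tokens, keep_at_least)
}

#' Encode a candidate pair as a 2-D feature matrix
#'
#' Parallel strategies left-pad each sentence so the two anchor tokens
#' occupy the same column, then right-pad both to a common length `L`;
#' column `j` stacks the relation-sentence token embedding (rows `1..d`)
#' over the context-sentence token embedding (rows `d+1..2d`). The
#' sequential strategy appends the context sentence after the relation
#' sentence with one all-zero separator column (`d` rows). Padded cells
#' are zero and mask-false.
#'
#' @param pair A `candidate_pair` with BIO-tagged tokens.
#' @param table An [embedding_table()].
#' @param strategy One of `"parallel_gene_disease"` (the default: anchors
#'   at the stored relation/context anchor mentions), `"parallel_first"`
#'   (anchors at the first tokens), `"parallel_chem_disease"` (anchors at
#'   the chemical and disease mentions) or `"sequential"`.
#' @param max_tokens Hard cap on tokens per sentence (truncated from the
#'   right, never removing an anchor or mention token).
#' @return A `feature_matrix`: list with `values` (rows x L), `mask`
#'   (logical, same shape), `word_idx`/`tag_idx` (index matrices, one row
#'   per sentence block, 0 = padding), `strategy`, `anchor_col`, and the
#'   table fingerprint.
#' @export
encode_pair <- function(pair, table, strategy = "parallel_gene_disease",
                        max_tokens = 128L) {
  stopifnot(inherits(pair, "candidate_pair"),
            inherits(table, "embedding_table"))
  strategy <- match.arg(strategy, ENCODING_STRATEGIES)
  rel <- pair$relation_tokens
  ctx <- pair$context_tokens
  roles <- .config_roles(pair$configuration)
  keep_rel <- max(pair$mention_tokens[[roles$relation[1L]]][2L],
                  pair$mention_tokens[[roles$relation[2L]]][2L],
                  pair$anchor_relation)
  keep_ctx <- max(pair$mention_tokens[[roles$context]][2L],
                  pair$anchor_context)
  m <- .truncate_tokens(nrow(rel), keep_rel, max_tokens)
  n <- .truncate_tokens(nrow(ctx), keep_ctx, max_tokens)
  rel <- rel[seq_len(m), , drop = FALSE]
  ctx <- ctx[seq_len(n), , drop = FALSE]
  rw <- .word_index(table, rel$text); rt <- .tag_index(rel$bio_tag)
  cw <- .word_index(table, ctx$text); ct <- .tag_index(ctx$bio_tag)

  if (strategy == "sequential") {
    L <- m + 1L + n
    word_idx <- matrix(0L, 1L, L)
    tag_idx <- matrix(0L, 1L, L)
    word_idx[1L, seq_len(m)] <- rw
    tag_idx[1L, seq_len(m)] <- rt
    word_idx[1L, m + 1L + seq_len(n)] <- cw
    tag_idx[1L, m + 1L + seq_len(n)] <- ct
    anchor_col <- NA_integer_
  } else {
    anch <- .resolve_anchors(pair, strategy)
    ar <- min(anch[1L], m); ac <- min(anch[2L], n)
    A <- max(ar, ac)
    pad_r <- A - ar; pad_c <- A - ac
    L <- max(pad_r + m, pad_c + n)
    word_idx <- matrix(0L, 2L, L)
    tag_idx <- matrix(0L, 2L, L)
    word_idx[1L, pad_r + seq_len(m)] <- rw
    tag_idx[1L, pad_r + seq_len(m)] <- rt
    word_idx[2L, pad_c + seq_len(n)] <- cw
    tag_idx[2L, pad_c + seq_len(n)] <- ct
    anchor_col <- A
  }
  values <- nn_build_input(word_idx, tag_idx, table$word_vectors,
                           table$tag_vectors)
  d <- table$d
  mask <- matrix(FALSE, nrow(values), ncol(values))
  for (b in seq_len(nrow(word_idx))) {
    real <- word_idx[b, ] > 0L
    mask[(b - 1L) * d + seq_len(d), real] <- TRUE
  }
  structure(
    list(values = values, mask = mask, word_idx = word_idx,
         tag_idx = tag_idx, strategy = strategy,
         anchor_col = anchor_col, d_word = table$d_word,
         d_ent = table$d_ent, n_in = nrow(values),
         table_fingerprint = table$fingerprint,
         label = pair$label %||% NULL),
    class = "feature_matrix")
}

#' Encode a list of candidate pairs
#'
#' @param pairs List of `candidate_pair`.
#' @inheritParams encode_pair
#' @param labels Optional vector of `"positive"`/`"negative"` gold labels
#'   attached to the returned features (defaults to each pair's own label).
#' @return A `feature_set`: list of `feature_matrix` objects sharing one
#'   strategy and table fingerprint.
#' @export
encode_pairs <- function(pairs, table, strategy = "parallel_gene_disease",
                         max_tokens = 128L, labels = NULL) {
  feats <- lapply(pairs, encode_pair, table = table, strategy = strategy,
                  max_tokens = max_tokens)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(feats))
    for (i in seq_along(feats)) feats[[i]]$label <- labels[i]
  }
  structure(feats, class = "feature_set")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s %dx%d anchor_col=%s>\n", x$strategy,
              nrow(x$values), ncol(x$values),
              if (is.na(x$anchor_col)) "-" else x$anchor_col))
  invisible(x)
}
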