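# Candidate evidence sentence-pair construction and BIO tagging.
#
# An evidence candidate is a relation sentence holding two of the three
# entity mentions (by default gene + chemical) plus a context sentence
# holding the third (by default disease). When all three mentions share a
# sentence the relation and context sentences are identical token-for-token
# (the duplication rule).

CONFIGURATIONS <- c("gene_chemical+disease", "chemical_disease+gene",
                    "gene_disease+chemical")

.config_aliases <- c(
  "gc+d" = "gene_chemical+disease",
  "cd+g" = "chemical_disease+gene",
  "gd+c" = "gene_disease+chemical"
)

.resolve_configuration <- function(configuration) {
  if (configuration %in% names(.config_aliases)) {
    configuration <- .config_aliases[[configuration]]
  }
  if (!configuration %in% CONFIGURATIONS) {
    stop("unknown configuration: ", configuration)
  }
  configuration
}

# entity roles for a configuration: relation-sentence pair (first element is
# the anchoring entity) and the context entity
.config_roles <- function(configuration) {
  switch(configuration,
    "gene_chemical+disease" = list(relation = c("gene", "chemical"),
                                   context = "disease"),
    "chemical_disease+gene" = list(relation = c("chemical", "disease"),
                                   context = "gene"),
    "gene_disease+chemical" = list(relation = c("gene", "disease"),
                                   context = "chemical")
  )
}

#' BIO-tag the tokens of a sentence
#'
#' Assigns each token one of the 7 tags ([bio_tagset()]): the first token
#' overlapping an entity mention gets `B-<type>`, subsequent overlapping
#' tokens `I-<type>`, all others `O`. When mentions of different types
#' overlap, token ownership follows the precedence gene > chemical >
#' disease (earlier mention wins ties) and runs are re-segmented so the tag
#' sequence stays well-formed.
#'
#' @param tokens data.frame of tokens (`text`, `start`, `end`) as produced
#'   by [tokenize_text()], spans in the same coordinates as `mentions`.
#' @param mentions data.frame of mentions lying within the sentence
#'   (`start`, `end`, `etype`).
#' @return `tokens` with a `bio_tag` column added.
#' @export
#' @examples
#' toks <- tokenize_text("SUN increased BNP")
#' ments <- data.frame(start = c(0L, 14L), end = c(3L, 17L),
#'                     etype = c("chemical", "gene"))
#' bio_tag(toks, ments)$bio_tag
bio_tag <- function(tokens, mentions) {
  n <- nrow(tokens)
  owner <- rep(0L, n)
  if (nrow(mentions)) {
    prec <- match(mentions$etype, ENTITY_TYPES)  # gene=1 < chemical=2 < disease=3
    ord <- order(prec, mentions$start)
    claimed <- rep(FALSE, n)
    for (mi in ord) {
      hit <- which(tokens$start < mentions$end[mi] &
                   tokens$end > mentions$start[mi])
      if (!length(hit)) {
        stop(sprintf("mention [%d,%d) '%s' overlaps no token",
                     mentions$start[mi], mentions$end[mi],
                     mentions$etype[mi]))
      }
      free <- hit[!claimed[hit]]
      owner[free] <- mi
      claimed[hit] <- TRUE
    }
  }
  tags <- rep("O", n)
  prev_owner <- 0L
  for (i in seq_len(n)) {
    if (owner[i] == 0L) { prev_owner <- 0L; next }
    et <- mentions$etype[owner[i]]
    tags[i] <- if (owner[i] == prev_owner) paste0("I-", et) else paste0("B-", et)
    prev_owner <- owner[i]
  }
  tokens$bio_tag <- tags
  tokens
}

#' Decode a BIO tag sequence back to typed token spans
#'
#' Inverse of [bio_tag()] on its output.
#'
#' @param tags Character vector of tags from [bio_tagset()].
#' @return data.frame with columns `etype`, `from`, `to` (1-based inclusive
#'   token indices).
#' @export
#' @examples
#' decode_bio(c("B-chemical", "O", "B-gene"))
decode_bio <- function(tags) {
  bad <- setdiff(tags, bio_tagset())
  if (length(bad)) stop("unknown BIO tag(s): ", paste(bad, collapse = ", "))
  out <- list()
  open <- NULL
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      if (!is.null(open)) { out[[length(out) + 1L]] <- open; open <- NULL }
    } else if (startsWith(t, "B-")) {
      if (!is.null(open)) out[[length(out) + 1L]] <- open
      open <- list(etype = substring(t, 3L), from = i, to = i)
    } else {  # I-
      et <- substring(t, 3L)
      if (is.null(open) || open$etype != et) {
        stop(sprintf("ill-formed BIO sequence: '%s' at index %d follows %s",
                     t, i, if (is.null(open)) "O" else paste0("entity ",
                                                              open$etype)))
      }
      open$to <- i
    }
  }
  if (!is.null(open)) out[[length(out) + 1L]] <- open
  if (!length(out)) {
    return(data.frame(etype = character(), from = integer(), to = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(etype = vapply(out, `[[`, "", "etype"),
             from = vapply(out, function(x) as.integer(x$from), 1L),
             to = vapply(out, function(x) as.integer(x$to), 1L),
             stringsAsFactors = FALSE)
}

# Tokenize and BIO-tag one sentence of a segmented document.
.sentence_tokens <- function(doc, s_idx) {
  span <- doc$sentences[s_idx, ]
  toks <- tokenize_text(substr(doc$text, span$start + 1L, span$end),
                        offset = span$start)
  in_sent <- doc$mentions[doc$mentions$start >= span$start &
                          doc$mentions$end <= span$end, , drop = FALSE]
  bio_tag(toks, in_sent)
}

# 1-based token index range covered by a mention within a token table.
.mention_token_range <- function(tokens, m_start, m_end) {
  hit <- which(tokens$start < m_end & tokens$end > m_start)
  c(hit[1L], hit[length(hit)])
}

# Does mention row `i` overlap any doc mention of a different entity type?
.multi_type_mention <- function(mentions, i) {
  any(mentions$start < mentions$end[i] & mentions$end > mentions$start[i] &
      mentions$etype != mentions$etype[i])
}

#' Extract candidate evidence sentence pairs from a document
#'
#' Under the default configuration, emits one candidate per (gene mention,
#' chemical mention) co-occurring in a sentence, crossed with every disease
#' mention in any sentence within `max_sentence_distance`. When the
#' context mention lies in the relation sentence itself the context
#' sentence is a duplicate of it. Alignment anchors are the first token of
#' the configuration's leading relation entity and of the context entity.
#' The two non-default configurations are handled symmetrically.
#'
#' @param doc A sentence-segmented `annotated_document`.
#' @param configuration `"gene_chemical+disease"` (default),
#'   `"chemical_disease+gene"`, `"gene_disease+chemical"`, or the short
#'   aliases `"gc+d"`, `"cd+g"`, `"gd+c"`.
#' @param max_sentence_distance Maximum absolute difference between the
#'   relation and context sentence ordinals (default unlimited within the
#'   abstract).
#' @return List of `candidate_pair` objects.
#' @export
extract_candidate_pairs <- function(doc,
                                    configuration = "gene_chemical+disease",
                                    max_sentence_distance = Inf) {
  stopifnot(inherits(doc, "annotated_document"))
  configuration <- .resolve_configuration(configuration)
  roles <- .config_roles(configuration)
  if (!nrow(doc$sentences)) stop("document must be sentence-segmented first")
  m <- doc$mentions
  if (!nrow(m)) return(list())
  m$sent <- sentence_of(doc, m$start, m$end)
  tok_cache <- list()
  get_tokens <- function(s) {
    key <- as.character(s)
    if (is.null(tok_cache[[key]])) tok_cache[[key]] <<- .sentence_tokens(doc, s)
    tok_cache[[key]]
  }

  t1 <- roles$relation[1]; t2 <- roles$relation[2]; t3 <- roles$context
  pairs <- list()
  seen <- character(0)
  for (s in seq_len(nrow(doc$sentences))) {
    i1s <- which(m$etype == t1 & m$sent == s)
    i2s <- which(m$etype == t2 & m$sent == s)
    if (!length(i1s) || !length(i2s)) next
    ctx <- which(m$etype == t3 &
                 abs(m$sent - s) <= max_sentence_distance)
    if (!length(ctx)) next
    rel_tokens <- get_tokens(s)
    for (i1 in i1s) for (i2 in i2s) {
      if (i1 == i2) next
      for (i3 in ctx) {
        key <- paste(s, i1, i2, i3, sep = ":")
        if (key %in% seen) next
        seen <- c(seen, key)
        s_ctx <- m$sent[i3]
        ctx_tokens <- if (s_ctx == s) rel_tokens else get_tokens(s_ctx)
        ids <- list(); ids[[t1]] <- m$norm_id[i1]; ids[[t2]] <- m$norm_id[i2]
        ids[[t3]] <- m$norm_id[i3]
        surf <- list(); surf[[t1]] <- m$surface[i1]; surf[[t2]] <- m$surface[i2]
        surf[[t3]] <- m$surface[i3]
        nrm <- list(); nrm[[t1]] <- m$normalized[i1]; nrm[[t2]] <- m$normalized[i2]
        nrm[[t3]] <- m$normalized[i3]
        mt <- list()
        mt[[t1]] <- .mention_token_range(rel_tokens, m$start[i1], m$end[i1])
        mt[[t2]] <- .mention_token_range(rel_tokens, m$start[i2], m$end[i2])
        mt[[t3]] <- .mention_token_range(ctx_tokens, m$start[i3], m$end[i3])
        pair <- structure(list(
          doc_id = doc$doc_id,
          configuration = configuration,
          relation_sentence_index = s,
          context_sentence_index = s_ctx,
          relation_tokens = rel_tokens,
          context_tokens = ctx_tokens,
          gene_id = ids$gene, chemical_id = ids$chemical,
          disease_id = ids$disease,
          gene_surface = surf$gene, chemical_surface = surf$chemical,
          disease_surface = surf$disease,
          gene_normalized = nrm$gene, chemical_normalized = nrm$chemical,
          disease_normalized = nrm$disease,
          mention_tokens = mt,
          anchor_relation = mt[[t1]][1L],
          anchor_context = mt[[t3]][1L],
          flag_multi_type = .multi_type_mention(m, i1) ||
            .multi_type_mention(m, i2) || .multi_type_mention(m, i3),
          label = NULL, score = NULL
        ), class = "candidate_pair")
        pairs[[length(pairs) + 1L]] <- pair
      }
    }
  }
  pairs
}

#' @export
print.candidate_pair <- function(x, ...) {
  cat(sprintf(
    "<candidate_pair %s s%d/s%d gene=%s chemical=%s disease=%s%s%s>\n",
    x$doc_id, x$relation_sentence_index, x$context_sentence_index,
    x$gene_id, x$chemical_id, x$disease_id,
    if (!is.null(x$label)) paste0(" label=", x$label) else "",
    if (!is.null(x$score)) sprintf(" score=%.3f", x$score) else ""))
  invisible(x)
}
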