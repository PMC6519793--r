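# Seeded generator of PubTator-format corpora with planted positive and
# negative disease-gene-chemical patterns, matching gold labels and synonym
# dictionaries, so every pipeline stage is testable offline.
#
# Positive documents realize chemical-gene interaction templates tied to a
# disease; negatives realize four patterns mirroring the major
# false-positive classes: co-occurrence-only sentences, negated sentences,
# study-purpose sentences, and interaction sentences paired with an
# unrelated-disease context.

NEGATIVE_TYPES <- c("cooccurrence", "negated", "study_purpose",
                    "unrelated_disease")

#' Configuration for the synthetic corpus generator
#'
#' @param seed Master seed; identical configurations generate
#'   byte-identical corpora.
#' @param n_documents Number of abstracts (one planted candidate pair
#'   each).
#' @param fraction_positive Fraction of documents with a positive triplet.
#' @param fraction_single_sentence Fraction of triplets whose three
#'   mentions share one sentence (the relation and context sentences are
#'   then identical); default 0.5, mirroring the gold-corpus construction.
#' @param n_genes,n_chemicals,n_diseases Entity vocabulary sizes.
#' @param negative_mix Named weights over the four negative patterns
#'   (must sum to 1).
#' @param synonyms_per_entity Number of surface forms per entity
#'   identifier (1-5).
#' @param hardness In \[0, 1\]: probability that a document receives an
#'   extra filler sentence containing cue words of the opposite class,
#'   reducing lexical separability to stress the classifier.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_documents = 100L,
                       fraction_positive = 0.5,
                       fraction_single_sentence = 0.5,
                       n_genes = 30L, n_chemicals = 30L, n_diseases = 20L,
                       negative_mix = c(cooccurrence = 0.4, negated = 0.25,
                                        study_purpose = 0.25,
                                        unrelated_disease = 0.1),
                       synonyms_per_entity = 3L, hardness = 0) {
  stopifnot(n_documents >= 1L, fraction_positive >= 0, fraction_positive <= 1,
            fraction_single_sentence >= 0, fraction_single_sentence <= 1,
            n_genes >= 1L, n_chemicals >= 1L, n_diseases >= 1L,
            synonyms_per_entity >= 1L, synonyms_per_entity <= 5L,
            hardness >= 0, hardness <= 1)
  if (!setequal(names(negative_mix), NEGATIVE_TYPES)) {
    stop("negative_mix must have weights for exactly: ",
         paste(NEGATIVE_TYPES, collapse = ", "))
  }
  if (abs(sum(negative_mix) - 1) > 1e-9) {
    stop("negative_mix weights must sum to 1")
  }
  structure(list(
    seed = as.integer(seed), n_documents = as.integer(n_documents),
    fraction_positive = fraction_positive,
    fraction_single_sentence = fraction_single_sentence,
    n_genes = as.integer(n_genes), n_chemicals = as.integer(n_chemicals),
    n_diseases = as.integer(n_diseases),
    negative_mix = negative_mix[NEGATIVE_TYPES],
    synonyms_per_entity = as.integer(synonyms_per_entity),
    hardness = hardness
  ), class = "sim_config")
}

.surface_prefixes <- list(
  gene = c("gen", "gp", "kns", "orf", "rgx"),
  chemical = c("chem", "cpd", "drg", "cmx", "lig"),
  disease = c("dis", "morb", "opath", "dz", "illn")
)

.synthetic_dictionaries <- function(config) {
  mk <- function(etype, prefix_letter, n) {
    ids <- paste0(prefix_letter, seq_len(n))
    stats::setNames(lapply(seq_len(n), function(i) {
      .surface_prefixes[[etype]][seq_len(config$synonyms_per_entity)] |>
        paste0(i)
    }), ids)
  }
  list(gene = mk("gene", "G", config$n_genes),
       chemical = mk("chemical", "C", config$n_chemicals),
       disease = mk("disease", "D", config$n_diseases))
}

.filler_words <- function() {
  path <- system.file("extdata", "filler_words.txt", package = "dgcminer")
  readLines(path, warn = FALSE)
}

# A template is a character vector of tokens; the placeholders <gene>,
# <chemical>, <disease> are replaced by sampled entity surfaces.
.tpl <- function(s) strsplit(s, " ", fixed = TRUE)[[1]]

.templates <- list(
  positive_relation = list(
    .tpl("<chemical> significantly increased <gene> expression in treated cells ."),
    .tpl("<chemical> markedly inhibited <gene> activity in a dose dependent manner ."),
    .tpl("treatment with <chemical> upregulated <gene> levels in vivo ."),
    .tpl("exposure to <chemical> suppressed <gene> signaling in cultured cells .")
  ),
  positive_single = list(
    .tpl("<chemical> significantly increased <gene> expression in patients with <disease> ."),
    .tpl("<chemical> inhibited <gene> activity in experimental <disease> models ."),
    .tpl("treatment of <disease> with <chemical> upregulated <gene> levels .")
  ),
  disease_context = list(
    .tpl("patients with <disease> showed marked clinical improvement ."),
    .tpl("<disease> remains a major therapeutic challenge worldwide ."),
    .tpl("these findings are highly relevant for <disease> therapy .")
  ),
  cooccurrence_relation = list(
    .tpl("<gene> and <chemical> were measured in serum samples from all groups ."),
    .tpl("circulating <gene> , <chemical> and creatinine were quantified at baseline ."),
    .tpl("<chemical> and <gene> concentrations were recorded during follow up .")
  ),
  cooccurrence_single = list(
    .tpl("<gene> and <chemical> were measured in serum from <disease> subjects ."),
    .tpl("baseline <chemical> and <gene> concentrations were recorded in <disease> cohorts .")
  ),
  negated_relation = list(
    .tpl("<chemical> did not alter <gene> expression in control cells ."),
    .tpl("<chemical> never changed <gene> levels under these conditions .")
  ),
  negated_single = list(
    .tpl("<chemical> did not alter <gene> expression in <disease> tissue ."),
    .tpl("<chemical> never changed <gene> levels in <disease> samples .")
  ),
  study_relation = list(
    .tpl("the aim of this study was to examine <gene> and <chemical> in detail ."),
    .tpl("we designed an investigation of <gene> and <chemical> interactions ."),
    .tpl("this trial evaluated <gene> together with <chemical> over two years .")
  ),
  study_single = list(
    .tpl("the aim of this study was to examine <gene> and <chemical> in <disease> ."),
    .tpl("we designed an investigation of <gene> and <chemical> in <disease> cohorts .")
  ),
  unrelated_context = list(
    .tpl("an unrelated cohort with <disease> was described previously ."),
    .tpl("earlier reports described <disease> in a separate unrelated population .")
  )
)

# cue words of the opposite class, used by the hardness knob
.hard_cues <- list(
  positive = c("measured", "detected", "baseline", "recorded"),
  negative = c("increased", "inhibited", "upregulated", "suppressed")
)

# build one sentence: returns list(tokens, entities) where entities is a
# data.frame (token_pos, etype, id, surface)
.fill_template <- function(template, picks, dict) {
  ents <- list()
  tokens <- template
  for (i in seq_along(tokens)) {
    t <- tokens[i]
    if (t %in% c("<gene>", "<chemical>", "<disease>")) {
      et <- substring(t, 2L, nchar(t) - 1L)
      id <- picks[[et]]
      surface <- sample(dict[[et]][[id]], 1L)
      tokens[i] <- surface
      ents[[length(ents) + 1L]] <- data.frame(
        token_pos = i, etype = et, id = id, surface = surface,
        stringsAsFactors = FALSE)
    }
  }
  list(tokens = tokens,
       entities = if (length(ents)) do.call(rbind, ents) else NULL)
}

.filler_sentence <- function(fillers, extra = character(0)) {
  n <- sample(5:8, 1L)
  toks <- c(sample(fillers, n, replace = TRUE), extra, ".")
  list(tokens = toks, entities = NULL)
}

#' Generate a synthetic annotated corpus
#'
#' Each document plants exactly one candidate triplet (positive or one of
#' the four negative patterns), with mention offsets and normalized
#' synthetic identifiers (`G#`, `C#`, `D#` namespaces), plus synonym
#' dictionaries from which all mention surfaces are drawn. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `pubtator` (character vector of PubTator
#'   lines), `gold` (data.frame: `doc_id`, `rel_sent`, `ctx_sent`,
#'   `gene_id`, `chemical_id`, `disease_id`, `label`, `negative_type`;
#'   sentence ordinals count the title as sentence 1), and `dictionaries`
#'   (nested synonym list as used by [filter_resources()]).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dict <- .synthetic_dictionaries(config)
  fillers <- .filler_words()
  n_pos <- round(config$n_documents * config$fraction_positive)
  labels <- c(rep("positive", n_pos),
              rep("negative", config$n_documents - n_pos))
  neg_types <- if (config$n_documents - n_pos > 0) {
    sample(NEGATIVE_TYPES, config$n_documents - n_pos, replace = TRUE,
           prob = config$negative_mix)
  } else character(0)
  labels <- sample(labels)  # shuffle positive/negative order
  neg_iter <- 0L

  lines <- character(0)
  gold <- vector("list", config$n_documents)
  for (di in seq_len(config$n_documents)) {
    doc_id <- sprintf("SYN%05d", di)
    label <- labels[di]
    ntype <- NA_character_
    if (label == "negative") {
      neg_iter <- neg_iter + 1L
      ntype <- neg_types[neg_iter]
    }
    single <- runif(1) < config$fraction_single_sentence
    picks <- list(gene = sample(names(dict$gene), 1L),
                  chemical = sample(names(dict$chemical), 1L),
                  disease = sample(names(dict$disease), 1L))

    rel_tpl_pool <- if (label == "positive") {
      if (single) .templates$positive_single else .templates$positive_relation
    } else {
      switch(ntype,
        cooccurrence = if (single) .templates$cooccurrence_single
                       else .templates$cooccurrence_relation,
        negated = if (single) .templates$negated_single
                  else .templates$negated_relation,
        study_purpose = if (single) .templates$study_single
                        else .templates$study_relation,
        unrelated_disease = if (single) .templates$positive_relation
                            else .templates$positive_relation)
    }
    # an unrelated-disease pattern is inherently two-sentence
    if (identical(ntype, "unrelated_disease")) single <- FALSE
    rel <- .fill_template(rel_tpl_pool[[sample.int(length(rel_tpl_pool), 1L)]],
                          picks, dict)
    sentences <- list()
    if (single) {
      sentences <- list(rel)
      rel_pos <- 1L; ctx_pos <- 1L
    } else {
      ctx_pool <- if (identical(ntype, "unrelated_disease")) {
        .templates$unrelated_context
      } else {
        .templates$disease_context
      }
      ctx <- .fill_template(ctx_pool[[sample.int(length(ctx_pool), 1L)]],
                            picks, dict)
      if (runif(1) < 0.5) {
        sentences <- list(rel, ctx); rel_pos <- 1L; ctx_pos <- 2L
      } else {
        sentences <- list(ctx, rel); rel_pos <- 2L; ctx_pos <- 1L
      }
    }
    # optional filler sentences (mention-free)
    if (runif(1) < 0.5) {
      sentences <- c(sentences, list(.filler_sentence(fillers)))
    }
    if (config$hardness > 0 && runif(1) < config$hardness) {
      cue <- sample(.hard_cues[[if (label == "positive") "positive"
                                else "negative"]], 1L)
      sentences <- c(sentences, list(.filler_sentence(fillers, cue)))
    }

    title <- paste("Synthetic abstract", di, "on molecular profiles .")
    # assemble text + global offsets (title is sentence 1)
    abstract_parts <- character(length(sentences))
    mention_rows <- list()
    cursor <- nchar(title) + 1L  # title + single space
    for (si in seq_along(sentences)) {
      s <- sentences[[si]]
      toks <- s$tokens
      toks[1] <- paste0(toupper(substring(toks[1], 1L, 1L)),
                        substring(toks[1], 2L))
      sent_text <- paste(toks, collapse = " ")
      if (!is.null(s$entities)) {
        tok_starts <- cursor +
          c(0L, cumsum(nchar(toks) + 1L))[seq_along(toks)]
        for (ei in seq_len(nrow(s$entities))) {
          pos <- s$entities$token_pos[ei]
          surf <- toks[pos]  # possibly capitalized
          mention_rows[[length(mention_rows) + 1L]] <- data.frame(
            start = tok_starts[pos],
            end = tok_starts[pos] + nchar(surf),
            surface = surf, etype = s$entities$etype[ei],
            id = s$entities$id[ei], stringsAsFactors = FALSE)
        }
      }
      abstract_parts[si] <- sent_text
      cursor <- cursor + nchar(sent_text) + 1L
    }
    abstract <- paste(abstract_parts, collapse = " ")
    ptype <- c(gene = "Gene", chemical = "Chemical", disease = "Disease")
    lines <- c(lines, paste0(doc_id, "|t|", title),
               paste0(doc_id, "|a|", abstract))
    for (mr in mention_rows) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%s\t%s", doc_id, mr$start,
                                mr$end, mr$surface, ptype[[mr$etype]],
                                mr$id))
    }
    lines <- c(lines, "")
    gold[[di]] <- data.frame(
      doc_id = doc_id,
      rel_sent = rel_pos + 1L,   # title is sentence 1
      ctx_sent = ctx_pos + 1L,
      gene_id = picks$gene, chemical_id = picks$chemical,
      disease_id = picks$disease, label = label,
      negative_type = ntype, stringsAsFactors = FALSE)
  }
  list(pubtator = lines, gold = do.call(rbind, gold), dictionaries = dict)
}

#' Inject NER-style annotation errors into a parsed corpus
#'
#' A seeded fraction of mentions is corrupted: either the surface is
#' replaced by an off-dictionary string of the same length (a target for
#' filtering rule i) or the span is duplicated with a conflicting entity
#' type (a target for rule ii).
#'
#' @param docs List of `annotated_document` (parsed, need not be
#'   segmented).
#' @param rate Fraction of mentions to corrupt in \[0, 1\].
#' @param seed Seed for the corruption draws.
#' @return List with `docs` (corrupted copies) and `manifest` (data.frame:
#'   `doc_id`, `mention`, `kind` in `off_dictionary`/`type_conflict`).
#' @export
corrupt_annotations <- function(docs, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  manifest <- list()
  out <- vector("list", length(docs))
  for (k in seq_along(docs)) {
    doc <- docs[[k]]
    m <- doc$mentions
    if (nrow(m)) {
      hit <- which(runif(nrow(m)) < rate)
      for (i in hit) {
        kind <- sample(c("off_dictionary", "type_conflict"), 1L)
        if (kind == "off_dictionary") {
          len <- nchar(m$surface[i])
          junk <- paste(c("z", sample(letters, max(len - 1L, 1L),
                                      replace = TRUE)), collapse = "")
          junk <- substr(junk, 1L, len)
          # splice into the text so offsets stay valid
          doc$text <- paste0(substr(doc$text, 1L, m$start[i]), junk,
                             substring(doc$text, m$end[i] + 1L))
          title_len <- nchar(doc$title)
          if (m$end[i] <= title_len) {
            doc$title <- substr(doc$text, 1L, title_len)
          } else {
            doc$abstract <- substring(doc$text, title_len + 2L)
          }
          m$surface[i] <- junk
        } else {
          other <- setdiff(ENTITY_TYPES, m$etype[i])
          dup <- m[i, , drop = FALSE]
          dup$etype <- sample(other, 1L)
          m <- rbind(m, dup)
        }
        manifest[[length(manifest) + 1L]] <- data.frame(
          doc_id = doc$doc_id, mention = i, kind = kind,
          stringsAsFactors = FALSE)
      }
      rownames(m) <- NULL
      doc$mentions <- m
    }
    out[[k]] <- doc
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else {
    data.frame(doc_id = character(), mention = integer(),
               kind = character(), stringsAsFactors = FALSE)
  }
  list(docs = out, manifest = manifest)
}
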