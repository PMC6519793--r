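# Rule-based false-positive filtering of predicted-positive candidate
# pairs. Five rules:
#   i   a mention surface is absent from the synonym dictionary of its
#       normalized identifier (dictionary validation; unnormalized
#       mentions fire automatically);
#   ii  a mention span was recognized as more than one entity type;
#   iii either sentence contains a study-purpose noun (a frozen snapshot
#       of hyponyms of "study");
#   iv  either sentence contains a negation keyword ("not", "never", ...;
#       whole-token, case-insensitive);
#   v   the gene and chemical mentions are coordinated (linked by a
#       conjunction) in the relation sentence's dependency parse.

RULE_IDS <- c("i", "ii", "iii", "iv", "v")

#' Load a synonym dictionary TSV
#'
#' Format: `etype<TAB>norm_id<TAB>synonym`, one synonym per line. Matching
#' is case-insensitive (synonyms are case-folded on load).
#'
#' @param path File path.
#' @return Nested list: `dict[[etype]][[norm_id]]` = character vector of
#'   case-folded synonyms.
#' @export
read_synonym_dict <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          col.names = c("etype", "norm_id", "synonym"),
                          colClasses = "character")
  dict <- list()
  for (et in unique(df$etype)) {
    sub <- df[df$etype == et, ]
    dict[[et]] <- lapply(split(tolower(sub$synonym), sub$norm_id), unique)
  }
  dict
}

#' Write a synonym dictionary TSV
#' @param dict Nested list as returned by [read_synonym_dict()].
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_synonym_dict <- function(dict, path) {
  rows <- list()
  for (et in names(dict)) {
    for (id in names(dict[[et]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        etype = et, norm_id = id, synonym = dict[[et]][[id]],
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble the resources used by the filtering rules
#'
#' @param synonyms Synonym dictionaries: nested list
#'   `[[etype]][[norm_id]]` of synonym strings, or a path passed to
#'   [read_synonym_dict()]. Required for rule i.
#' @param study_hyponyms Character vector of study-purpose nouns, or path
#'   to a one-term-per-line file; defaults to the frozen snapshot shipped
#'   with the package (`inst/extdata/study_hyponyms.txt`).
#' @param negation_keywords Extra negation keywords added to the defaults
#'   `"not"`, `"never"`, `"n't"`.
#' @param dependency_parser Function mapping a token data.frame (column
#'   `text`) to a data.frame with columns `head` (1-based index of each
#'   token's head, 0 for root) and `label` (relation name, coordination
#'   links labelled `"conj"`). Defaults to the bundled deterministic
#'   coordination-pattern parser ([coordination_parser()]).
#' @return A `filter_resources` list.
#' @export
filter_resources <- function(synonyms = NULL, study_hyponyms = NULL,
                             negation_keywords = character(0),
                             dependency_parser = coordination_parser) {
  if (is.character(synonyms) && length(synonyms) == 1L) {
    synonyms <- read_synonym_dict(synonyms)
  }
  if (is.null(study_hyponyms)) {
    study_hyponyms <- system.file("extdata", "study_hyponyms.txt",
                                  package = "dgcminer")
  }
  if (is.character(study_hyponyms) && length(study_hyponyms) == 1L &&
      file.exists(study_hyponyms)) {
    study_hyponyms <- readLines(study_hyponyms, warn = FALSE)
  }
  study_hyponyms <- tolower(trimws(study_hyponyms))
  study_hyponyms <- study_hyponyms[nzchar(study_hyponyms)]
  structure(list(
    synonyms = synonyms,
    study_hyponyms = study_hyponyms,
    negation_keywords = unique(tolower(c("not", "never", "n't",
                                         negation_keywords))),
    dependency_parser = dependency_parser
  ), class = "filter_resources")
}

# crude lemma normalization for hyponym lookup: strip plural endings
.lemma <- function(w) {
  w <- tolower(w)
  w <- sub("ies$", "y", w)
  w <- sub("(s|x|z|ch|sh)es$", "\\1", w)
  w <- sub("([^su])s$", "\\1", w)
  w
}

#' Bundled deterministic coordination parser
#'
#' A rule-based stand-in for a full dependency parser that detects only
#' coordination: for every pattern `token A (, )* (and|or) token B` where
#' the connecting tokens are commas plus a single conjunction, it links B
#' to A with label `"conj"`. All other tokens are attached to the root
#' with label `"dep"`. Sufficient to drive filtering rule v; replaceable
#' via the `dependency_parser` resource.
#'
#' @param tokens data.frame with a `text` column.
#' @return data.frame with columns `head` (0 = root) and `label`.
#' @export
coordination_parser <- function(tokens) {
  n <- nrow(tokens)
  head <- integer(n)
  label <- rep("dep", n)
  txt <- tolower(tokens$text)
  is_sep <- txt %in% c(",", "and", "or")
  i <- 1L
  while (i <= n) {
    if (is_sep[i]) { i <- i + 1L; next }
    j <- i + 1L
    while (j <= n && is_sep[j]) j <- j + 1L
    if (j <= n && j > i + 1L && !is_sep[j]) {
      # at least one separator between word tokens i and j
      head[j] <- i
      label[j] <- "conj"
    }
    i <- j
  }
  data.frame(head = head, label = label, stringsAsFactors = FALSE)
}

# head token index of a mention: the last token of the mention span
# (right-headed compounds), per the bundled parser's convention the
# conj link attaches to content tokens directly.
.mention_head <- function(range) range[2L]

# are token indices a and b connected by a coordination path? True when
# one is a (possibly transitive) conjunct of the other or both climb to a
# shared coordination head.
.coordinated <- function(parse, a, b) {
  if (a == b) return(FALSE)
  climb <- function(x) {
    while (parse$label[x] == "conj" && parse$head[x] > 0L) x <- parse$head[x]
    x
  }
  climb(a) == climb(b)
}

.surface_in_dict <- function(resources, etype, norm_id, surface,
                             normalized) {
  if (!isTRUE(normalized) || is.null(norm_id) || identical(norm_id, "-")) {
    return(FALSE)  # unnormalized mentions fail dictionary validation
  }
  syn <- resources$synonyms[[etype]][[norm_id]]
  if (is.null(syn)) return(FALSE)
  tolower(surface) %in% tolower(syn)
}

#' Apply one filtering rule to a candidate pair
#'
#' @param pair A `candidate_pair` (with tagged tokens and, for rule i,
#'   normalized identifiers).
#' @param rule_id One of `"i"`, `"ii"`, `"iii"`, `"iv"`, `"v"`.
#' @param resources A [filter_resources()] object.
#' @return `TRUE` if the rule fires (the pair should be filtered out).
#' @export
apply_rule <- function(pair, rule_id, resources) {
  stopifnot(inherits(pair, "candidate_pair"),
            inherits(resources, "filter_resources"))
  if (!rule_id %in% RULE_IDS) stop("unknown rule_id: ", rule_id)
  both_tokens <- function() {
    toks <- pair$relation_tokens$text
    if (pair$context_sentence_index != pair$relation_sentence_index) {
      toks <- c(toks, pair$context_tokens$text)
    }
    toks
  }
  switch(rule_id,
    i = {
      if (is.null(resources$synonyms)) {
        stop("rule i requires synonym dictionaries in the resources")
      }
      !(.surface_in_dict(resources, "gene", pair$gene_id,
                         pair$gene_surface, pair$gene_normalized %||% TRUE) &&
        .surface_in_dict(resources, "chemical", pair$chemical_id,
                         pair$chemical_surface,
                         pair$chemical_normalized %||% TRUE) &&
        .surface_in_dict(resources, "disease", pair$disease_id,
                         pair$disease_surface,
                         pair$disease_normalized %||% TRUE))
    },
    ii = isTRUE(pair$flag_multi_type),
    iii = any(.lemma(both_tokens()) %in% resources$study_hyponyms),
    iv = any(tolower(both_tokens()) %in% resources$negation_keywords),
    v = {
      if (is.null(resources$dependency_parser)) {
        stop("rule v requires a dependency parser in the resources")
      }
      roles <- .config_roles(pair$configuration)
      if (!all(c("gene", "chemical") %in% roles$relation)) {
        return(FALSE)  # gene and chemical not in one sentence
      }
      parse <- resources$dependency_parser(pair$relation_tokens)
      g <- .mention_head(pair$mention_tokens$gene)
      c_ <- .mention_head(pair$mention_tokens$chemical)
      .coordinated(parse, g, c_)
    }
  )
}

#' Apply the post-processing rules to predicted-positive pairs
#'
#' Every pair is evaluated against all enabled rules (no short-circuit, so
#' the fired-rule sets are complete); a pair is kept iff no rule fires.
#' Kept pairs preserve their input order.
#'
#' @param pairs List of `candidate_pair`.
#' @param resources A [filter_resources()] object.
#' @param enabled_rules Subset of `c("i","ii","iii","iv","v")`.
#' @return List with `kept` (the surviving pairs), `decisions` (data.frame
#'   with columns `pair`, `kept`, `fired_rules`), and `summary` (named
#'   firing count per enabled rule).
#' @export
apply_postprocessing <- function(pairs, resources,
                                 enabled_rules = RULE_IDS) {
  stopifnot(all(enabled_rules %in% RULE_IDS))
  n <- length(pairs)
  fired <- vector("list", n)
  for (idx in seq_len(n)) {
    fr <- character(0)
    for (r in enabled_rules) {
      if (apply_rule(pairs[[idx]], r, resources)) fr <- c(fr, r)
    }
    fired[[idx]] <- fr
  }
  keep <- lengths(fired) == 0L
  summary <- vapply(enabled_rules, function(r) {
    sum(vapply(fired, function(fr) r %in% fr, TRUE))
  }, 0L)
  decisions <- data.frame(
    pair = seq_len(n),
    kept = keep,
    fired_rules = vapply(fired, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  list(kept = pairs[keep], decisions = decisions, summary = summary)
}

#' Write filtering decisions to TSV
#' @param decisions The `decisions` element of [apply_postprocessing()].
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.table(decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
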