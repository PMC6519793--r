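# Inverted index over positive evidence pairs and ranked triplet search.
#
# Per entity type the index maps a normalized identifier to the set of
# evidence-pair identifiers mentioning it; an evidence store keeps each
# pair's triplet record and sentence texts inline so searching needs no
# corpus access. Query semantics: conjunction across the three fields,
# disjunction within a field; results are ranked by classifier score.

#' Build an inverted index over positive evidence pairs
#'
#' @param records data.frame of triplet records with columns `gene_id`,
#'   `chemical_id`, `disease_id`, `score`, `doc_id`, `rel_sent`,
#'   `ctx_sent`, and optionally `rel_text`, `ctx_text` (sentence texts,
#'   stored inline). Rows missing any of the three identifiers (empty or
#'   `"-"`) are skipped with a warning count.
#' @return An `evidence_index`: `postings` (per entity type, named list
#'   id -> integer vector of evidence ids), `evidence` (the stored
#'   records, one row per evidence id), `n_skipped`.
#' @export
build_index <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("gene_id", "chemical_id", "disease_id", "score", "doc_id",
            "rel_sent", "ctx_sent")
  stopifnot(all(need %in% names(records)))
  if (!"rel_text" %in% names(records)) records$rel_text <- ""
  if (!"ctx_text" %in% names(records)) records$ctx_text <- ""
  ok <- nzchar(records$gene_id) & records$gene_id != "-" &
    nzchar(records$chemical_id) & records$chemical_id != "-" &
    nzchar(records$disease_id) & records$disease_id != "-"
  n_skipped <- sum(!ok)
  if (n_skipped) {
    warning(sprintf("skipped %d pair(s) missing a normalized identifier",
                    n_skipped))
  }
  ev <- records[ok, c(need, "rel_text", "ctx_text"), drop = FALSE]
  rownames(ev) <- NULL
  stopifnot(all(ev$score >= 0 & ev$score <= 1))
  postings <- list(
    gene = split(seq_len(nrow(ev)), ev$gene_id),
    chemical = split(seq_len(nrow(ev)), ev$chemical_id),
    disease = split(seq_len(nrow(ev)), ev$disease_id)
  )
  structure(list(postings = postings, evidence = ev,
                 n_skipped = n_skipped),
            class = "evidence_index")
}

#' @export
print.evidence_index <- function(x, ...) {
  cat(sprintf(
    "<evidence_index: %d pairs, %d genes, %d chemicals, %d diseases>\n",
    nrow(x$evidence), length(x$postings$gene), length(x$postings$chemical),
    length(x$postings$disease)))
  invisible(x)
}

#' Persist / reload an evidence index
#'
#' Line-oriented directory layout: one postings TSV per entity type
#' (`postings_<etype>.tsv`: id, space-separated evidence ids) plus the
#' evidence store (`evidence.tsv`).
#'
#' @param index An `evidence_index`.
#' @param dir Directory (created if missing).
#' @return `save_index` returns `dir` invisibly; `load_index` the restored
#'   index.
#' @export
save_index <- function(index, dir) {
  stopifnot(inherits(index, "evidence_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (et in ENTITY_TYPES) {
    pl <- index$postings[[et]]
    df <- data.frame(
      id = names(pl),
      evidence = vapply(pl, paste, "", collapse = " "),
      stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0("postings_", et, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ev <- index$evidence
  ev$score <- sprintf("%.6f", ev$score)
  utils::write.table(ev, file.path(dir, "evidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_index
#' @export
load_index <- function(dir) {
  ev <- utils::read.table(file.path(dir, "evidence.tsv"), sep = "\t",
                          header = TRUE, quote = "", comment.char = "",
                          colClasses = c("character", "character",
                                         "character", "numeric", "character",
                                         "integer", "integer", "character",
                                         "character"))
  postings <- list()
  for (et in ENTITY_TYPES) {
    df <- utils::read.table(file.path(dir, paste0("postings_", et, ".tsv")),
                            sep = "\t", header = TRUE, quote = "",
                            comment.char = "", colClasses = "character")
    postings[[et]] <- stats::setNames(
      lapply(strsplit(df$evidence, " ", fixed = TRUE), as.integer), df$id)
  }
  structure(list(postings = postings, evidence = ev, n_skipped = 0L),
            class = "evidence_index")
}

#' Expand query terms to normalized identifiers
#'
#' A term that is already a known identifier maps to itself; otherwise a
#' case-insensitive exact match against the synonym dictionary collects
#' every identifier sharing that synonym. Unknown terms yield an empty
#' set with a warning.
#'
#' @param terms Character vector of identifiers or names.
#' @param dictionary One entity type's synonym dictionary: named list
#'   id -> synonyms (one element of [read_synonym_dict()]'s result).
#' @param known_ids Identifiers known to the index (any term in this set
#'   maps to itself even without a dictionary entry).
#' @return Character vector of normalized identifiers.
#' @export
expand_terms <- function(terms, dictionary = NULL, known_ids = character(0)) {
  out <- character(0)
  for (term in terms) {
    if (term %in% names(dictionary) || term %in% known_ids) {
      out <- c(out, term)
      next
    }
    hit <- character(0)
    if (!is.null(dictionary)) {
      match_ids <- names(dictionary)[vapply(dictionary, function(syn) {
        tolower(term) %in% tolower(syn)
      }, TRUE)]
      hit <- match_ids
    }
    if (!length(hit)) {
      warning("query term not found in dictionaries or index: ", term)
    }
    out <- c(out, hit)
  }
  unique(out)
}

#' Search the evidence index
#'
#' Result set = intersection over the non-empty query fields of the union
#' of the expanded identifiers' posting lists; empty fields are
#' unconstrained. Results are sorted by classifier score descending, ties
#' broken by (doc_id, relation sentence index) ascending, and truncated to
#' `limit`.
#'
#' @param index An `evidence_index`.
#' @param genes,chemicals,diseases Optional character vectors of
#'   identifiers or (dictionary-resolvable) names; at least one must be
#'   non-empty.
#' @param dictionaries Optional synonym dictionaries (nested list as from
#'   [read_synonym_dict()]) used to resolve names to identifiers.
#' @param limit Maximum number of rows returned (default all).
#' @param group_by_triplet Collapse results to unique triplets, keeping
#'   each triplet's best evidence score and pair count.
#' @return data.frame of evidence rows (or grouped triplets), ranked.
#' @export
search_evidence <- function(index, genes = character(0),
                            chemicals = character(0),
                            diseases = character(0), dictionaries = NULL,
                            limit = Inf, group_by_triplet = FALSE) {
  stopifnot(inherits(index, "evidence_index"))
  fields <- list(gene = genes, chemical = chemicals, disease = diseases)
  if (all(lengths(fields) == 0L)) {
    stop("query must constrain at least one of genes, chemicals, diseases")
  }
  cand <- seq_len(nrow(index$evidence))
  for (et in names(fields)) {
    terms <- fields[[et]]
    if (!length(terms)) next
    ids <- expand_terms(terms, dictionary = dictionaries[[et]],
                        known_ids = names(index$postings[[et]]))
    hits <- unlist(index$postings[[et]][ids], use.names = FALSE)
    cand <- intersect(cand, unique(hits %||% integer(0)))
  }
  out <- index$evidence[cand, , drop = FALSE]
  ord <- order(-out$score, out$doc_id, out$rel_sent)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (group_by_triplet && nrow(out)) {
    key <- paste(out$gene_id, out$chemical_id, out$disease_id, sep = "\r")
    first <- !duplicated(key)
    grouped <- out[first, c("gene_id", "chemical_id", "disease_id",
                            "score"), drop = FALSE]
    grouped$n_pairs <- as.integer(table(key)[key[first]])
    out <- grouped[order(-grouped$score, grouped$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (is.finite(limit)) out <- head(out, limit)
  out
}
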