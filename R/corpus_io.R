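# PubTator-format corpus I/O and pipeline output serialization.
#
# Conventions used throughout the package:
#   * document text is title + single space + abstract, and all character
#     offsets are 0-based half-open spans into that concatenation (the
#     PubTator offset scheme);
#   * entity types are exactly {gene, chemical, disease}.

new_annotated_document <- function(doc_id, title, abstract, mentions = NULL,
                                   sentences = NULL) {
  stopifnot(nzchar(doc_id))
  text <- if (nzchar(abstract)) paste(title, abstract) else title
  if (is.null(mentions)) {
    mentions <- data.frame(start = integer(), end = integer(),
                           surface = character(), etype = character(),
                           norm_id = character(), normalized = logical(),
                           source_tool = character(), stringsAsFactors = FALSE)
  }
  if (is.null(sentences)) {
    sentences <- data.frame(start = integer(), end = integer())
  }
  structure(
    list(doc_id = doc_id, title = title, abstract = abstract, text = text,
         sentences = sentences, mentions = mentions),
    class = "annotated_document"
  )
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document %s: %d chars, %d sentences, %d mentions>\n",
              x$doc_id, nchar(x$text), nrow(x$sentences), nrow(x$mentions)))
  invisible(x)
}

.canonical_etype <- function(x) {
  x <- tolower(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("gene", "protein")] <- "gene"
  out[x %in% c("chemical", "drug")] <- "chemical"
  out[x == "disease"] <- "disease"
  out
}

#' Parse a PubTator-format corpus
#'
#' Reads blocks of `PMID|t|title`, `PMID|a|abstract` lines followed by
#' tab-separated annotation lines
#' `PMID<TAB>start<TAB>end<TAB>surface<TAB>type<TAB>normID`, with blocks
#' separated by blank lines. Annotation types are mapped case-insensitively
#' onto gene/chemical/disease; other types (Species, Mutation, ...) are
#' dropped with a warning. Annotations whose offsets do not reproduce the
#' surface string are skipped and counted. Mentions with a missing or `"-"`
#' identifier are retained but flagged unnormalized.
#'
#' @param source Path to a PubTator file, or a character vector of lines
#'   (anything with an embedded newline is split).
#' @return A list of `annotated_document` objects (sentences not yet
#'   segmented; see [split_sentences()]). The integer attribute
#'   `skipped_annotations` counts malformed annotation lines.
#' @export
#' @examples
#' lines <- c("1|t|BNP study.",
#'            "1|a|SUN increased BNP.",
#'            "1\t11\t14\tSUN\tChemical\tC473478",
#'            "1\t25\t28\tBNP\tGene\t4879")
#' docs <- parse_pubtator(lines)
#' docs[[1]]$mentions
parse_pubtator <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    # split embedded newlines, preserving blank block-separator lines
    unlist(lapply(source, function(s) {
      if (!nzchar(s)) "" else strsplit(s, "\n", fixed = TRUE)[[1]]
    }), use.names = FALSE)
  }
  docs <- list()
  skipped <- 0L
  dropped_types <- character(0)

  block <- character(0)
  flush_block <- function(block) {
    if (!length(block)) return(NULL)
    tl <- grep("^[^\t|]+\\|t\\|", block, value = TRUE)
    if (!length(tl)) stop("PubTator block without a title line: ",
                          substr(block[1], 1, 60))
    doc_id <- sub("\\|.*$", "", tl[1])
    title <- sub("^[^|]*\\|t\\|", "", tl[1])
    al <- grep("^[^\t|]+\\|a\\|", block, value = TRUE)
    abstract <- if (length(al)) sub("^[^|]*\\|a\\|", "", al[1]) else ""
    doc <- new_annotated_document(doc_id, title, abstract)

    ann <- grep("\t", block, fixed = TRUE, value = TRUE)
    rows <- list()
    for (line in ann) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) < 5L) { skipped <<- skipped + 1L; next }
      et <- .canonical_etype(f[5])
      if (is.na(et)) { dropped_types <<- c(dropped_types, f[5]); next }
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end) || start < 0L || end <= start ||
          end > nchar(doc$text) ||
          substr(doc$text, start + 1L, end) != f[4]) {
        skipped <<- skipped + 1L
        next
      }
      norm_id <- if (length(f) >= 6L && nzchar(f[6])) f[6] else "-"
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = end, surface = f[4], etype = et,
        norm_id = norm_id, normalized = norm_id != "-",
        source_tool = "pubtator", stringsAsFactors = FALSE)
    }
    if (length(rows)) doc$mentions <- do.call(rbind, rows)
    doc
  }

  for (line in c(lines, "")) {
    if (!nzchar(trimws(line))) {
      d <- flush_block(block)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      block <- character(0)
    } else {
      block <- c(block, line)
    }
  }
  if (length(dropped_types)) {
    warning(sprintf("dropped %d annotation(s) with unused types: %s",
                    length(dropped_types),
                    paste(unique(dropped_types), collapse = ", ")))
  }
  attr(docs, "skipped_annotations") <- skipped
  docs
}

#' Serialize documents back to PubTator format
#'
#' Inverse of [parse_pubtator()]: re-parsing the output yields documents
#' equal to the input (sentence spans are not part of the format and are
#' recomputed by [split_sentences()]).
#'
#' @param docs List of `annotated_document`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the character
#'   vector of lines.
#' @export
write_pubtator <- function(docs, path = NULL) {
  out <- character(0)
  for (doc in docs) {
    out <- c(out, paste0(doc$doc_id, "|t|", doc$title),
             paste0(doc$doc_id, "|a|", doc$abstract))
    m <- doc$mentions
    if (nrow(m)) {
      # PubTator types are capitalized
      ptype <- c(gene = "Gene", chemical = "Chemical", disease = "Disease")
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s", doc$doc_id,
                            m$start, m$end, m$surface, ptype[m$etype],
                            m$norm_id))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Segment a document into sentences
#'
#' Populates the sentence spans of an annotated document with a
#' deterministic rule-based segmenter that is abbreviation-safe on common
#' biomedical patterns ("Fig.", "et al.", decimal numbers). The
#' title/abstract junction is always a boundary. Any candidate boundary
#' falling strictly inside a mention is dropped, merging the flanking
#' sentences, so that every mention lies inside exactly one sentence span.
#'
#' @param doc An `annotated_document`.
#' @return The document with `sentences` populated (a data.frame of
#'   0-based half-open `start`, `end` spans, ordered and non-overlapping).
#' @export
split_sentences <- function(doc) {
  stopifnot(inherits(doc, "annotated_document"))
  hard <- if (nzchar(doc$abstract)) as.integer(nchar(doc$title)) else integer(0)
  protected <- if (nrow(doc$mentions)) {
    cbind(doc$mentions$start, doc$mentions$end)
  } else NULL
  doc$sentences <- segment_text(doc$text, hard_breaks = hard,
                                protected = protected)
  # safety: a mention must sit inside exactly one sentence span
  if (nrow(doc$mentions)) {
    idx <- sentence_of(doc, doc$mentions$start, doc$mentions$end)
    if (anyNA(idx)) {
      stop("mention crosses all candidate sentence boundaries in document ",
           doc$doc_id)
    }
  }
  doc
}

# Sentence index (1-based) containing each [start,end) span, NA if none.
sentence_of <- function(doc, start, end) {
  vapply(seq_along(start), function(i) {
    hit <- which(doc$sentences$start <= start[i] & end[i] <= doc$sentences$end)
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1))
}

#' Write extracted triplet records to TSV
#'
#' @param records data.frame with columns `gene_id`, `chemical_id`,
#'   `disease_id`, `score`, `doc_id`, `rel_sent`, `ctx_sent`.
#' @param path Destination file.
#' @return Number of data rows written.
#' @seealso [read_triplets()]
#' @export
write_triplets <- function(records, path) {
  cols <- c("gene_id", "chemical_id", "disease_id", "score", "doc_id",
            "rel_sent", "ctx_sent")
  stopifnot(all(cols %in% names(records)))
  out <- records[, cols, drop = FALSE]
  stopifnot(all(out$score >= 0 & out$score <= 1),
            all(nzchar(out$gene_id)), all(nzchar(out$chemical_id)),
            all(nzchar(out$disease_id)))
  out$score <- sprintf("%.4f", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  nrow(out)
}

#' Read a triplet TSV written by [write_triplets()]
#' @param path File path.
#' @return data.frame of triplet records.
#' @export
read_triplets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "numeric", "character", "integer",
                                         "integer"), quote = "")
  df
}

#' Dump candidate pairs as JSON lines
#'
#' One JSON object per pair: document id, sentence indices, mention token
#' spans, configuration, label and score. Round-trips through
#' [read_pairs_jsonl()] (token tables are reconstructed from the stored
#' fields).
#'
#' @param pairs List of `candidate_pair` objects.
#' @param path Destination file.
#' @return Number of lines written, invisibly.
#' @export
write_pairs_jsonl <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pairs) {
    obj <- list(
      doc_id = p$doc_id,
      configuration = p$configuration,
      relation_sentence_index = p$relation_sentence_index,
      context_sentence_index = p$context_sentence_index,
      gene_id = p$gene_id, chemical_id = p$chemical_id,
      disease_id = p$disease_id,
      relation_tokens = p$relation_tokens,
      context_tokens = p$context_tokens,
      mention_tokens = p$mention_tokens,
      anchor_relation = p$anchor_relation,
      anchor_context = p$anchor_context,
      flag_multi_type = isTRUE(p$flag_multi_type),
      label = p$label, score = p$score
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(length(pairs))
}

#' Read a JSON-lines candidate-pair dump
#' @param path File written by [write_pairs_jsonl()].
#' @return List of `candidate_pair` objects.
#' @export
read_pairs_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines, function(line) {
    o <- jsonlite::fromJSON(line, simplifyDataFrame = TRUE)
    o$relation_tokens <- as.data.frame(o$relation_tokens,
                                       stringsAsFactors = FALSE)
    o$context_tokens <- as.data.frame(o$context_tokens,
                                      stringsAsFactors = FALSE)
    o$mention_tokens <- lapply(o$mention_tokens, as.integer)
    o$label <- o$label %||% NULL
    structure(o, class = "candidate_pair")
  })
}
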