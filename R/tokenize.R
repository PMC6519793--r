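# Deterministic tokenizer and sentence segmenter. Both are rule-based and
# dependency-free so that corpus I/O never requires a parsing model.

# Word characters may include internal hyphens/apostrophes and decimal points
# (a '.' is part of a token only when followed by a digit, so "0.5" is one
# token but a sentence-final period is not).
.token_pattern <- "[A-Za-z0-9](?:[A-Za-z0-9'_-]|\\.(?=[0-9]))*|\\S"

#' Tokenize a text span
#'
#' Whitespace and punctuation splitting with hyphens, apostrophes and
#' decimal points kept inside tokens; every other non-space character is a
#' single-character token. Deterministic and frozen by fixture tests.
#'
#' @param text Character scalar to tokenize.
#' @param offset 0-based character offset of `text` within a larger
#'   document; added to the reported spans.
#' @return A data.frame with columns `text`, `start`, `end` (0-based,
#'   half-open spans into the enclosing document).
#' @export
#' @examples
#' tokenize_text("SUN-induced BNP (0.5 mg/kg).")
tokenize_text <- function(text, offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr(.token_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(
    text = substring(text, m, m + len - 1L),
    start = as.integer(m - 1L + offset),
    end = as.integer(m - 1L + len + offset),
    stringsAsFactors = FALSE
  )
}

# Abbreviations that never terminate a sentence when followed by a period.
.abbreviations <- c(
  "fig", "figs", "et", "al", "e.g", "i.e", "vs", "cf", "dr", "mr", "mrs",
  "ms", "prof", "no", "nos", "ref", "refs", "approx", "ca", "sp", "spp",
  "inc", "ltd", "st", "jr", "sr", "wt", "resp"
)

# Candidate sentence boundaries: positions just after [.?!] that are followed
# by whitespace and then an upper-case letter or digit, excluding periods
# that close a known abbreviation or a single initial.
.candidate_boundaries <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (!(ch %in% c(".", "?", "!"))) next
    if (i == n) next
    # require whitespace after the terminator (possibly after closing quotes)
    j <- i + 1L
    while (j <= n && chars[j] %in% c("\"", "'", ")", "]")) j <- j + 1L
    if (j > n || !grepl("[[:space:]]", chars[j])) next
    k <- j
    while (k <= n && grepl("[[:space:]]", chars[k])) k <- k + 1L
    if (k > n || !grepl("[A-Z0-9(\"]", chars[k])) next
    if (ch == ".") {
      # word immediately before the period
      m <- regmatches(substr(text, max(1L, i - 12L), i - 1L),
                      regexpr("[A-Za-z.]+$", substr(text, max(1L, i - 12L), i - 1L)))
      w <- if (length(m)) tolower(m) else ""
      if (w %in% .abbreviations) next
      if (grepl("^[a-z]$", w)) next  # single lower-case initial, e.g. "s. aureus"
    }
    out <- c(out, i)  # 0-based offset of first char after the terminator
  }
  out
}

# Split `text` into sentence spans. `hard_breaks` are 0-based offsets that
# always end a sentence (the title/abstract junction). `protected` is a
# two-column matrix of 0-based half-open spans (mentions) that no boundary
# may fall strictly inside; offending boundaries are dropped (merging the
# flanking sentences).
segment_text <- function(text, hard_breaks = integer(0),
                         protected = NULL) {
  n <- nchar(text)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  b <- sort(unique(c(.candidate_boundaries(text), hard_breaks)))
  b <- b[b > 0L & b < n]
  if (!is.null(protected) && nrow(protected) > 0L && length(b) > 0L) {
    keep <- vapply(b, function(pos) {
      !any(pos > protected[, 1L] & pos < protected[, 2L])
    }, logical(1))
    b <- b[keep]
  }
  bounds <- c(0L, b, n)
  spans <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
  # trim surrounding whitespace from each span
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    while (s < e && grepl("[[:space:]]", substr(text, s + 1L, s + 1L))) s <- s + 1L
    while (e > s && grepl("[[:space:]]", substr(text, e, e))) e <- e - 1L
    spans$start[i] <- s; spans$end[i] <- e
  }
  spans[spans$end > spans$start, , drop = FALSE]
}
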