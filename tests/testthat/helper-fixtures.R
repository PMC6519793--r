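# Shared fixtures: small hand-built PubTator blocks and a labeled encoded
# corpus builder used by the model and acceptance tests.

# A PubTator block fashioned after the printed positive example: a
# gene-chemical sentence (SUN increased BNP) and a disease sentence
# (renal cell carcinoma), PMID 24984876.
fixture_positive_block <- function() {
  title <- "Sunitinib effects on cardiomyocytes."
  abstract <- paste(
    "Western blot analysis showed that SUN increased BNP protein levels.",
    "Sunitinib (SUN) is used for the treatment of renal cell carcinoma.")
  text <- paste(title, abstract)
  find <- function(s, from = 1L) {
    at <- regexpr(s, substring(text, from), fixed = TRUE)[1] + from - 1L
    c(at - 1L, at - 1L + nchar(s))
  }
  sun1 <- find("SUN")
  bnp <- find("BNP")
  sun2 <- find("SUN", from = sun1[2] + 2L)
  rcc <- find("renal cell carcinoma")
  c(paste0("24984876|t|", title),
    paste0("24984876|a|", abstract),
    sprintf("24984876\t%d\t%d\tSUN\tChemical\tC473478", sun1[1], sun1[2]),
    sprintf("24984876\t%d\t%d\tBNP\tGene\t4879", bnp[1], bnp[2]),
    sprintf("24984876\t%d\t%d\tSUN\tChemical\tC473478", sun2[1], sun2[2]),
    sprintf("24984876\t%d\t%d\trenal cell carcinoma\tDisease\tD002292",
            rcc[1], rcc[2]))
}

# Block after the printed negative example: "...ACE-inhibition but not
# hydralazine..." with a glomerulosclerosis context sentence, PMID 25143333.
fixture_negative_block <- function() {
  title <- "Podocyte number after ACE inhibition."
  abstract <- paste(
    "The initiation of ACE inhibition but not hydralazine was accompanied",
    "by higher podocyte number.",
    "We test the effects of ACE inhibition in a model of focal segmental",
    "glomerulosclerosis.")
  text <- paste(title, abstract)
  find <- function(s, from = 1L) {
    at <- regexpr(s, substring(text, from), fixed = TRUE)[1] + from - 1L
    c(at - 1L, at - 1L + nchar(s))
  }
  ace1 <- find("ACE", from = nchar(title) + 1L)
  hyd <- find("hydralazine")
  ace2 <- find("ACE", from = hyd[2])
  glo <- find("glomerulosclerosis")
  c(paste0("25143333|t|", title),
    paste0("25143333|a|", abstract),
    sprintf("25143333\t%d\t%d\tACE\tGene\t1636", ace1[1], ace1[2]),
    sprintf("25143333\t%d\t%d\thydralazine\tChemical\tD006830",
            hyd[1], hyd[2]),
    sprintf("25143333\t%d\t%d\tACE\tGene\t1636", ace2[1], ace2[2]),
    sprintf("25143333\t%d\t%d\tglomerulosclerosis\tDisease\tD005923",
            glo[1], glo[2]))
}

# Dictionaries covering every mention surface of the two fixture blocks.
fixture_dictionaries <- function() {
  list(
    gene = list("4879" = c("bnp", "natriuretic peptide b"),
                "1636" = c("ace", "angiotensin-converting enzyme")),
    chemical = list("C473478" = c("sun", "sunitinib"),
                    "D006830" = "hydralazine"),
    disease = list("D002292" = c("renal cell carcinoma", "rcc"),
                   "D005923" = "glomerulosclerosis")
  )
}

parse_and_segment <- function(lines) {
  lapply(parse_pubtator(lines), split_sentences)
}

# Build a labeled candidate-pair corpus from the synthetic generator.
make_labeled_pairs <- function(config) {
  corp <- generate_corpus(config)
  docs <- parse_and_segment(corp$pubtator)
  pairs <- unlist(lapply(docs, extract_candidate_pairs), recursive = FALSE)
  key <- function(d, g, c_, dd) paste(d, g, c_, dd, sep = "|")
  gk <- key(corp$gold$doc_id, corp$gold$gene_id, corp$gold$chemical_id,
            corp$gold$disease_id)
  labels <- corp$gold$label[match(
    vapply(pairs, function(p) key(p$doc_id, p$gene_id, p$chemical_id,
                                  p$disease_id), ""), gk)]
  list(pairs = pairs, labels = labels, gold = corp$gold,
       dictionaries = corp$dictionaries, docs = docs,
       pubtator = corp$pubtator)
}

# Encode a labeled corpus with a compact embedding table (small dimensions
# keep the model tests fast; the acceptance suite uses the full 200+20).
encode_corpus <- function(lp, d_word = 32L, d_ent = 8L, seed = 5L,
                          strategy = "parallel_gene_disease") {
  tokens <- unlist(lapply(lp$pairs, function(p) {
    c(p$relation_tokens$text, p$context_tokens$text)
  }), use.names = FALSE)
  table <- embedding_table(tokens, d_word = d_word, d_ent = d_ent,
                           seed = seed)
  feats <- encode_pairs(lp$pairs, table, strategy = strategy,
                        labels = lp$labels)
  list(table = table, features = feats, labels = lp$labels)
}

as_feature_set <- function(x) structure(x, class = "feature_set")

# Brute-force candidate-pair count: triple loop over mentions (oracle for
# extract_candidate_pairs under the default configuration).
oracle_pair_count <- function(doc, max_sentence_distance = Inf) {
  m <- doc$mentions
  if (!nrow(m)) return(0L)
  m$sent <- dgcminer:::sentence_of(doc, m$start, m$end)
  n <- 0L
  seen <- character(0)
  for (g in which(m$etype == "gene")) {
    for (c_ in which(m$etype == "chemical")) {
      if (m$sent[g] != m$sent[c_]) next
      for (d in which(m$etype == "disease")) {
        if (abs(m$sent[d] - m$sent[g]) > max_sentence_distance) next
        key <- paste(m$sent[g], g, c_, d)
        if (!key %in% seen) {
          seen <- c(seen, key)
          n <- n + 1L
        }
      }
    }
  }
  n
}

# Random well-formed BIO tag sequence generator (for round-trip checks).
random_bio_sequence <- function(len) {
  tags <- character(len)
  i <- 1L
  while (i <= len) {
    if (runif(1) < 0.6) {
      tags[i] <- "O"
      i <- i + 1L
    } else {
      et <- sample(c("gene", "chemical", "disease"), 1L)
      span <- min(sample(1:3, 1L), len - i + 1L)
      tags[i] <- paste0("B-", et)
      if (span > 1L) {
        tags[(i + 1L):(i + span - 1L)] <- paste0("I-", et)
      }
      i <- i + span
    }
  }
  tags
}

# Linear-scan search oracle with the same semantics as search_evidence().
oracle_search <- function(records, genes = character(0),
                          chemicals = character(0),
                          diseases = character(0)) {
  keep <- rep(TRUE, nrow(records))
  if (length(genes)) keep <- keep & records$gene_id %in% genes
  if (length(chemicals)) keep <- keep & records$chemical_id %in% chemicals
  if (length(diseases)) keep <- keep & records$disease_id %in% diseases
  out <- records[keep, , drop = FALSE]
  out <- out[order(-out$score, out$doc_id, out$rel_sent), , drop = FALSE]
  rownames(out) <- NULL
  out
}
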