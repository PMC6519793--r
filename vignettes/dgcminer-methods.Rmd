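---
title: "Mining disease-gene-chemical relationships: models and methods"
author: "dgcminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease-gene-chemical relationships: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The extraction problem

Associations among a chemical, a gene and a disease are the currency of
mechanistic pharmacology, yet they are mostly asserted across *pairs* of
sentences in an abstract: one sentence describes the chemical acting on
the gene, another ties the finding to a disease. `dgcminer` therefore
extracts **evidence sentence pairs**: a relation sentence containing a
gene mention and a chemical mention, and a context sentence containing a
disease mention. When all three mentions share one sentence, that
sentence is duplicated into both roles, so single-sentence and
two-sentence evidence flow through one uniform representation. Within a
sentence holding several gene or chemical mentions, every
(gene, chemical) combination forms its own candidate, each crossed with
every disease mention in range; the maximum sentence distance between
relation and context sentence is unlimited within the abstract by
default and configurable. The context sentence may precede or follow the
relation sentence — published abstracts do both, and the printed example
that motivated the design has the disease sentence first.

The pipeline consumes entity annotations rather than producing them:
input is the PubTator exchange format (title and abstract lines plus
tab-separated mention annotations with character offsets, entity types,
and normalized identifiers — Entrez for genes, MeSH/ChEBI for chemicals,
MEDIC/MeSH for diseases). Offsets are 0-based half-open into
`title + " " + abstract` throughout the package; every parsed mention is
validated against its text slice, and malformed annotations are skipped
and counted rather than corrupting downstream stages. Annotation types
outside gene/chemical/disease (Species, Mutation, ...) are dropped
silently-with-a-warning because PubTator streams routinely carry them.

Sentence segmentation is a deterministic rule-based splitter
(abbreviation-safe for "Fig.", "et al.", decimal numbers; the
title/abstract junction is always a boundary). A candidate boundary that
would fall inside an entity mention is discarded, merging the flanking
sentences — the format itself does not say how mentions crossing
boundaries should be treated, and merging guarantees the invariant that
every mention lies in exactly one sentence. The splitter is deliberately
dependency-free: corpus I/O must not require a parsing model.

## Feature encoding

Tokens (whitespace/punctuation split, hyphens and decimal points kept
inside tokens) are BIO-tagged from the mention annotations: 3 entity
types yield 7 tags. Each token is embedded as the concatenation of a
word vector (`d_word` = 200) and an entity-type vector indexed by its
BIO tag (`d_ent` = 20), so the per-token dimension is d = 220. Word
vectors for tokens found in an optional pretrained plain-text vector
file use those vectors; all other rows are drawn once from a seeded
uniform(−0.05, 0.05). Out-of-vocabulary tokens share one unknown-word
row, for reproducibility without a full-corpus embedding file. The
entity-type vectors are always trainable; word vectors are frozen by
default (`freeze_word_vectors = FALSE` unfreezes them).

A candidate pair becomes a 2-D array whose columns are time steps. The
two sentences are stacked as two row blocks (2d = 440 rows) and
left-padded so that the two **anchor** tokens — by default the first
token of the gene mention and the first token of the disease mention —
share a column; both sentences are then right-padded to a common length.
Padding cells are exactly zero and mask-false. Alternative strategies
are available for comparison: anchoring at the first tokens or at the
chemical/disease mentions, and plain sequential concatenation (d rows,
one zero separator column). The aligned length is computed per pair;
a hard cap (128 tokens per sentence) truncates pathological sentences
from the right but never removes an anchor or mention token.

## Classifier

The default classifier is a bidirectional LSTM over the column sequence:
forward and backward hidden states (100 units each) are concatenated per
step, passed through a per-step fully-connected layer (width 1,000, tanh
activation), reduced over time, and fed to a 2-way softmax. How the
per-step outputs become one decision is genuinely open in this design
space; the package's choice is max-over-time, isolated behind the
`reduction` switch (`"mean"` and `"final"` are the alternatives).
Unidirectional LSTM, GRU, bi-GRU and a CNN comparator (one convolution
of window 3 over columns, `hidden_units` filters, ReLU, max-over-time,
then the same fully-connected head) accept identical inputs and emit
identical output shapes, so architecture comparisons change exactly one
layer.

Training minimizes 2-class cross-entropy by plain mini-batch SGD with
seeded shuffling — a learning rate of 0.80 is only plausible for
un-adaptive SGD, so no adaptive optimizer is offered, and no class
weighting is applied (imbalance is studied by subsampling instead).
Reference hyperparameters: 100 hidden units, learning rate 0.80,
fully-connected width 1,000, mini-batches of 200, decision threshold
0.5. Two numerical choices are the package's own:

* **Gradient clipping** (global norm, default 5). At learning rate 0.80
  occasional large batch gradients otherwise destabilize late training;
  the clip is inactive for typical gradient norms (~0.5 at
  initialization).
* **Epochs default to 100.** With pretrained word vectors a few dozen
  epochs suffice; with the seeded random initialization used when no
  vector file is supplied, the input signal is small (entries within
  ±0.05) and SGD spends roughly 50 epochs traversing a plateau before
  converging. On the synthetic task the loss trajectory is flat near
  0.69 (chance) until about epoch 45 and reaches ~10⁻³ by epoch 90.
  Everything is config-overridable.

Initialization is Glorot-uniform with zero biases (LSTM forget-gate bias
1). All randomness — initialization, shuffling, fold assignment —
derives from R's RNG under recorded seeds; the compiled layer is purely
deterministic, so identical configurations reproduce identical loss
histories bitwise. Gradients of every architecture, including the
embedding-table gradients, are checked against central finite
differences in the test suite.

Evaluation follows standard protocol: seeded stratified k-fold
cross-validation (per-class fold sizes differ by at most one; whether
the original protocol stratified is unstated, stratification is this
package's choice), precision/recall/F with respect to the positive
class, and an imbalance experiment that subsamples (n_pos, n_neg) pools
and cross-validates each ratio.

## False-positive filtering

Five deterministic rules screen predicted positives; each pair is
evaluated against all enabled rules with no short-circuit, so reported
rule firings are complete and the kept set is order-independent:

1. **Dictionary validation** — a mention surface (case-folded) absent
   from the synonym set of its normalized identifier fires; mentions
   with no identifier fire automatically, since the rule's purpose is
   dictionary validation.
2. **Type conflict** — a mention span overlapping a mention of a
   different entity type fires.
3. **Study-purpose vocabulary** — any token of either sentence whose
   lemma (plural stripping) is in the study-noun list fires. The list
   ships as a frozen snapshot file (`inst/extdata/study_hyponyms.txt`)
   so behavior cannot drift with lexicon versions; it deliberately
   excludes "analysis"/"assay", which are routine in methods phrasing
   ("Western blot analysis") inside genuine relation sentences.
4. **Negation keywords** — whole-token, case-insensitive match against
   "not", "never", "n't" plus configured additions ("note" never
   fires).
5. **Gene–chemical coordination** — the gene and chemical mention heads
   are linked by a conjunction in the relation sentence's dependency
   parse. The parser is an injected interface; the bundled default is a
   deterministic coordination-only parser (word tokens separated solely
   by commas/"and"/"or" are chained as conjuncts), so the rule is
   testable without a parsing model and a real parser can be plugged in
   unchanged.

Rules 3 and 4 are applied to both sentences of the pair — the scope is
ambiguous in prose descriptions of such filters, and the both-sentence
reading is the conservative one (documented here as this package's
reading). Filtering is monotone by construction: enabling more rules
never enlarges the kept set.

## Indexing and search

Positive evidence pairs are indexed by their three normalized
identifiers: one posting list per identifier per entity type, plus an
evidence store holding each pair's record and sentence texts inline, so
queries need no corpus access. Query semantics are conjunction across
the gene/chemical/disease fields and disjunction within a field; empty
fields are unconstrained (a disease-only query returns all its evidence
pairs). Name terms resolve through flat synonym dictionaries by exact
case-insensitive match — no fuzzy matching, no hierarchy expansion.
Results are ranked by classifier score with deterministic tie-breaking
by (document, sentence) coordinates, and `--group-by-triplet` collapses
to unique triplets with each triplet's best evidence score. The index
persists to a line-oriented directory format and reloads losslessly.

## Synthetic data: what it emulates, and what it does not

The generator emits PubTator-format corpora in which every document
plants exactly one candidate triplet with gold label and bookkeeping
(sentence ordinals, identifiers, negative subtype). Positives realize
interaction templates ("<chem> increased <gene> ... patients with
<disease>"); negatives realize the four major false-positive patterns:
co-occurrence-only sentences ("<gene> and <chem> were measured ..."),
negated sentences, study-purpose sentences, and interaction sentences
paired with an unrelated-disease context. Half the triplets are
single-sentence by default, mirroring the balanced construction of
curated evidence corpora. Entity identifiers use disjoint namespaces
(`G#`, `C#`, `D#`); every mention surface is drawn from the generated
synonym dictionaries, so dictionary-based components are exercised
end-to-end, and `corrupt_annotations()` injects the two NER error modes
(off-dictionary surfaces, conflicting-type duplicates) that rules 1-2
target. Generation is byte-reproducible from the seed.

The templates keep the two classes separable by lexical cues, and a
bag-of-words logistic baseline certifies that separability (F ≥ 0.9)
before any claim about the sequence model is tested; a `hardness` knob
injects opposite-class cue words to stress the classifier. This is
deliberate and bounds what passing means: the synthetic task
demonstrates that the pipeline's plumbing, encoding, optimization and
protocols recover planted structure, not that the architecture attains
any particular accuracy on real literature, where the decision boundary
is far from lexical. Absolute published F-scores on curated corpora are
not reproduction targets of this package.

## Problem sizes of the shipped experiments

The pattern-recovery experiment uses 500 positive + 500 negative
documents, a 200-pair holdout, and the full reference model (about six
minutes on one core). The imbalance-direction experiment compares
(500, 500) against (500, 1000) training pairs over five seeds with
3-fold cross-validation and a compact bi-LSTM (32 hidden units,
fully-connected 64, mini-batches of 32, 25 epochs, 50+10-d embeddings,
about one minute per seed) — sizes chosen so the full suite runs on a
desktop while keeping the quantity of interest (the *direction* of the
balanced-versus-imbalanced difference) well resolved; the magnitude of
the difference at this scale is smaller than with the full model and is
not the claim.

## Known limitations

* The sentence splitter and the bundled coordination parser are
  rule-based approximations; both are pluggable, and rule 5 inherits
  any replacement parser's notion of conjuncts.
* Synonym dictionaries are flat; no hierarchy-aware expansion.
* Deduplication of candidate pairs is per-document; identical sentence
  pairs appearing in different abstracts index separately.
* The unknown-word row makes all out-of-vocabulary tokens
  indistinguishable to the classifier.
* Tokenization is frozen by fixture tests; texts with exotic Unicode
  segmentation are outside its design envelope.
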