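---
title: "Normalizing free-text radiation treatment-site names to coded concepts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing free-text radiation treatment-site names to coded concepts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtsites)
```

## The problem

Radiation oncology record-and-verify systems accept the treatment site of
each radiation field as free text. In a large department with many physicians
and no enforced nomenclature, the same anatomical target accumulates dozens
of spellings: casing variants ("Whole Brain", "whole brain", "WHOLE BRAIN"),
idiosyncratic abbreviations ("SCV", "SCL", "S/C", "SC", "S Clav", "Sc V",
"Sclav", "SCLV" all meaning *supraclavicular*), typos ("wbxrt"), decorations
("Whole Brain #2", "Whole Brain Retreat") and separator quirks
("whole brain-2"). Cohort assembly, registry reporting and data-warehouse
integration all need those strings collapsed onto coded concepts — concept
unique identifiers (CUIs) with semantic-type codes, in the style of the UMLS
Metathesaurus.

`rtsites` implements a complete, deterministic pipeline for that task:

1. **lexicon** — build a task-specific terminology from a semantic-type-
   filtered concept source merged with a curated supplement of radiotherapy
   abbreviations;
2. **normalizer** — tokenize a raw site name into classified tokens;
3. **resolver** — resolve unknown tokens with bigram-context candidate
   generation ranked by Levenshtein distance;
4. **mapper** — assemble resolved tokens into maximal lexicon terms and emit
   the concept annotation;
5. **evaluation** — entity-level recall `TP/(TP+FN)` and precision
   `TP/(TP+FP)` against gold annotations;
6. **corpus statistics** and a **synthetic corruption generator** for
   end-to-end testing without access to protected clinical data.

## The lexicon

A general-purpose concept source is consumed as two pipe-delimited tables,
`string|CUI` and `CUI|semantic type` (a deliberate two-column subset of the
18-column MRCONSO dialect; column positions are configurable so wider RRF
exports can be read). Strings are admitted when their CUI carries at least
one admitted semantic type — by default the topographical types T023 (Body
Part, Organ, or Organ Component), T029 (Body Location or Region), T030 (Body
Space or Junction) and T082 (Spatial Concept). Terms are normalized
(lowercase, collapsed whitespace) and strings sharing a normalized term merge
into one entry with ordered, de-duplicated CUI and semantic-type lists; no
disambiguation among a term's multiple CUIs is attempted, all are emitted.

Topographical vocabularies miss radiotherapy-specific concepts (midline
block, boost, whole-brain radiotherapy) and essentially all local
abbreviations. These live in a *supplement* TSV
(`surface  expansion  cuis  semtypes`): each record's surface **and**
expansion become lookup keys for the same entry, and supplement entries
shadow concept-source entries on surface collision — manual curation exists
precisely to correct gaps in the general source, so it wins. Supplement
concepts may carry an empty CUI list (rendered `[:T169]`), since a curated
concept need not exist in the source vocabulary.

Lookup keys additionally absorb whitespace around punctuation, so "S/C",
"s / c" and "s/c" address one entry, and the hyphenated term "whole-brain
radiotherapy" is matched as a single concept.

The package ships a self-contained demonstration lexicon
(`build_fixture_lexicon()`) covering the most frequent site labels of a
radiation oncology department together with their abbreviation surfaces, so
every example in this vignette runs without any licensed resource.

## Tokenization

`tokenize()` splits on whitespace and emits every non-alphanumeric character
as its own punctuation token, with one exception: `#` followed by digits is a
single number token, because decorated entries such as "Whole Brain #2" are
common. Digit-only runs are number tokens; everything else is a word. Both
hyphen and slash become punctuation tokens uniformly — what to do with them
is policy that lives in the mapper, not the tokenizer. Input is case-folded
with the default locale and non-ASCII letters count as word characters.
Trailing digits ("whole brain 2") are preserved as number tokens and left
unannotated rather than dropped, so no information is destroyed before the
mapping stage.

## Resolving unknown tokens

Each word token is first looked up in the lexicon vocabulary (exact hit),
then in a general-English wordlist. An English hit marks the token as a known
word but produces no concept unless the word is also a lexicon token — filler
words ("retreat", "photons") should neither block the pipeline nor invent
concepts. The wordlist source is configurable; the bundled list is a small
set of filler words seen in site labels, and any newline-delimited wordlist
can be supplied instead.

What remains is typically an arbitrary abbreviation. For an unknown token the
resolver collects **candidates** from a bigram model trained on the lexicon's
own term token sequences: the words observed after the resolved left
neighbour, united with the words observed before the resolved right
neighbour. Only when both contexts are absent or yield nothing does it fall
back to the full vocabulary, scored by unigram relative frequency. Each
candidate carries its Levenshtein distance to the unknown token (computed in
C) and its conditional bigram probability.

Selection is **distance first**: among candidates within the threshold, the
minimum edit distance wins, ties broken by the higher context probability,
then lexicographically. "Closest word with the highest probability" admits a
probability-first reading too, so that alternative is exposed as
`rank_order = "probability_first"` in `resolver_config()`; distance-first is
the default because it preserves "closest" as the primary criterion. The
distance threshold defaults to `max(1, floor(nchar(candidate)/3))` per
candidate — one edit tolerated on short abbreviations, proportionally more on
long words; no fixed global threshold is assumed.

Two deliberate consequences of this design: resolution is completely
deterministic (ties always break the same way), and a token equal to a
vocabulary word can never be beaten by a more probable non-identical word
under the default ranking (distance 0 dominates).

By default the bigram model is trained on lexicon term tokenizations only;
`train_bigrams()` accepts any list of token sequences, so development-set
strings can be added where they are available.

## Assembling terms

`assemble_terms()` performs greedy leftmost-longest segmentation: at each
position, the longest contiguous token run whose joined, normalized form is a
lexicon term becomes one concept annotation, and matching restarts after it.
Greedy matching is chosen over global optimization because it is
deterministic, linear-time, and provably identical to exhaustive
leftmost-longest search (a property the test suite checks against an
enumeration oracle on random small lexicons). A run may span punctuation
tokens only when a punctuation-bearing term exists for it, so "SCV-MLB"
yields two concepts around a punctuation annotation while "whole-brain
radiotherapy" stays one concept.

Punctuation annotations are emitted (serialized `/ [PUNC:T000]`, with `T000`
a reserved sentinel code) but carry `kind = "punctuation"` and are excluded
from concept-level evaluation; reference displays print the slash between
distinct prescription parts yet no punctuation for hyphenated abbreviation
chains, and this policy reconciles both. The display label of a matched term
is the lexicon's `preferred_label` verbatim, which preserves the casing of
curated labels.

## Evaluation

`match_concepts()` compares the predicted concepts of one site against gold:
a prediction matches an unused gold concept when they share at least one CUI,
with case-insensitive label equality as the fallback for CUI-less supplement
concepts. What counts as a true positive is genuinely underdetermined in
entity-level evaluation (exact CUI? any CUI overlap? span match?); the
CUI-overlap rule is this package's choice and is stated here explicitly.

Matching is implemented as maximum bipartite matching (augmenting paths,
predictions processed in order so ties resolve deterministically) rather than
greedy first-fit: greedy matching is order-sensitive and can under-count true
positives when one prediction is compatible with several gold concepts. On
every evaluation, `tp + fn` equals the number of gold concepts and `tp + fp`
the number of (non-punctuation, non-unmapped) predictions.

Corpus scores are micro-averaged: counts are pooled over sites and a single
corpus-level recall and precision are reported. A zero denominator reports
`n/a` rather than 0 — silently coercing undefined precision to a number
inflates or deflates scores depending on convention.

## Corpus statistics

`build_frequency_table()` counts raw strings **case-sensitively** (usage
statistics must distinguish "Whole Brain" from "whole brain" even though
annotation does not). `top_k_share()` reports the usage mass of the top *k*
labels; the denominator is an explicit argument because "share" can
reasonably be taken against total entries or against the unique-label count
of a larger corpus, and the bundled corpus summary uses the latter basis.
`variant_group()` runs each row through the full annotation pipeline and
keeps the rows containing a target concept — this is how the 27 observed
whole-brain spellings are shown to collapse onto the brain /
whole-brain-radiotherapy concepts (1063 uses).

## The synthetic generator

Protected clinical corpora cannot ship with a package, so `generate_corpus()`
fabricates labeled test data: canonical site names are drawn uniformly and
corrupted with the noise taxonomy actually observed in departmental data —
case mangling, known-abbreviation substitution, single-character edits,
decoration appends, separator swaps — rather than a generic typo model. The
default probabilities (`p_case = 0.4`, `p_abbrev = 0.15`, `p_edit = 0.05`,
`p_decor = 0.3`, `p_sep = 0.1`) roughly follow the relative frequency of
those variant classes among the observed whole-brain spellings, where casing
and decoration variants dominate and true typos are rare.

Two guarantees make the generator a trustworthy oracle. First, gold
annotations are computed from the **clean canonical string** and frozen, so
they are independent of any resolver behaviour on the corrupted side.
Second, every case carries a complete operation log and
`apply_corruption_ops()` replays it exactly; determinism under
`(seed, config)` is tested byte-for-byte. Abbreviation substitution only
replaces an expansion that equals a whole matched concept of the canonical's
annotation — substituting a sub-phrase (e.g. the "radiotherapy" inside
"whole-brain radiotherapy") would change the expected annotation and break
the label-preservation guarantee.

Because case mangling and known-abbreviation substitution are pure
exact-lookup paths, corpora corrupted only by those two operations must
evaluate at recall = precision = 1.0; the test suite asserts this at
1,000 cases. Corpora with one character edit per word token exercise the
fuzzy resolver; recall stays above 0.95 (observed ≈ 0.998 averaged over five
seeds of 1,000 cases). These problem sizes were chosen as the point where the
binomial noise on a recall estimate drops below a percentage point.

What passing these tests does **not** show: the generator draws from a small
canonical set over a small lexicon, with independent corruption per case. A
real institutional lexicon is orders of magnitude larger (denser edit-
distance neighbourhoods, more ambiguous abbreviations), real noise is
correlated with physicians and services, and real entries contain dose,
fractionation and device text that is out of scope here. Synthetic recall is
therefore an upper bound on field performance, not an estimate of it.

## Numerical and degenerate-input choices

* Edit distance is unit-cost insert/delete/substitute over bytes of the
  UTF-8 representation; `NA` input propagates `NA`.
* Empty input string → empty annotation, never an error; unresolved tokens
  are values, not errors.
* Frequency-table ties preserve first-occurrence order (stable sort).
* Percent shares are rounded to one decimal, means to two — matching the
  precision at which such corpus summaries are conventionally reported.
* Candidate ties in the resolver break lexicographically as the final
  criterion, so no code path depends on hash or insertion order.
* The RNG is touched only inside the synthetic generator, under a
  save/restore wrapper, so library calls never perturb a user's random
  state.

## Limitations

* One annotation per matched run: among a term's multiple CUIs, all are
  emitted and none preferred.
* No negation, laterality inference beyond literal tokens, or
  dose/fractionation parsing.
* The English wordlist is a stub sufficient for the bundled data; production
  use should supply a full wordlist via `resolver_config()`.
* Greedy segmentation can differ from a globally optimal segmentation on
  adversarial lexicons (it is exactly leftmost-longest, no more).

## A worked example

```{r example}
lex <- build_fixture_lexicon()
model <- train_bigrams(lexicon_token_sequences(lex))
cfg <- resolver_config(english_words = fixture_english_words())

annotate_site("Prostate/Prox SV", lex, model, cfg)
annotate_site("SCV-MLB", lex, model, cfg)

# the fuzzy path: "brin" is one edit from "brain", in context of "whole"
site_concept_strings(annotate_site("whole brin", lex, model, cfg))

# "brian" is two edits away -- beyond the auto threshold for a 5-letter
# candidate, so it stays unresolved rather than being guessed
annotate_site("whole brian", lex, model, cfg)$unresolved_tokens
```

```{r stats}
wb <- build_frequency_table(fixture_whole_brain_variants())
vg <- variant_group(wb, lex, c("C0006104", "C1520143"), model, cfg)
c(variants = n_unique(vg), uses = total_entries(vg))
```
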