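# rtsites

Normalization of free-text radiation treatment-site names to coded concepts.

Radiation oncology record-and-verify systems (the EMRs that control
treatment delivery) accept the treatment site of each radiation field as
free text. Without an enforced nomenclature the same target accumulates
dozens of spellings — "Whole Brain", "whole brain", "WBRT", "wbxrt",
"Whole Brain #2" — and a single anatomical abbreviation like
*supraclavicular* appears as SCV, SCL, S/C, SC, S Clav, Sc V, Sclav or SCLV.
That heterogeneity blocks cohort assembly, registry reporting and
data-warehouse integration. `rtsites` is for the informatics teams and
researchers who need those strings collapsed onto coded concepts: UMLS-style
concept unique identifiers (CUIs) with semantic-type codes.

## Method

The pipeline is deterministic and dictionary-driven:

1. **Lexicon.** A concept source (pipe-delimited `string|CUI` plus
   `CUI|semantic type`) is filtered to topographical semantic types — T023
   (Body Part, Organ, or Organ Component), T029 (Body Location or Region),
   T030 (Body Space or Junction), T082 (Spatial Concept) — and merged with a
   curated supplement of radiotherapy abbreviations and concepts that shadow
   the general source on collision.
2. **Tokenization.** Site names split into word / number / punctuation
   tokens (`#2` is one number token).
3. **Token resolution.** Unknown tokens (arbitrary abbreviations, typos) are
   resolved by generating candidate words from bigram context — words
   observed after the left neighbour or before the right neighbour in the
   terminology, with the full vocabulary as fallback — and ranking
   candidates by Levenshtein distance *d*, ties by conditional bigram
   probability. A candidate qualifies when
   *d* ≤ max(1, ⌊len(candidate)/3⌋).
4. **Term assembly.** Greedy leftmost-longest matching of resolved token
   runs against the lexicon emits concept annotations, e.g.
   `Prostate/Prox SV` → `Prostate [C0033572,C1278980,C1882832:T023]`
   `/ [PUNC:T000]` `Proximal [C0205107:T082]`
   `Seminal Vesicle [C1278984:T023]`.
5. **Evaluation.** Entity-level recall TP/(TP+FN) and precision TP/(TP+FP)
   against gold annotations, with TP defined by CUI overlap (label equality
   for CUI-less supplement concepts) under maximum bipartite matching.

A seeded synthetic-corruption generator reproduces the observed noise
taxonomy (case mangling, abbreviation substitution, character edits,
decorations, separator swaps) with replayable operation logs, so the whole
pipeline is testable end to end without protected clinical data. See the
methods vignette (`vignettes/treatment-site-normalization.Rmd`) for the full
design rationale.

## Worked example

```r
library(rtsites)

lex   <- build_fixture_lexicon()                       # bundled demo lexicon
model <- train_bigrams(lexicon_token_sequences(lex))
cfg   <- resolver_config(english_words = fixture_english_words())

annotate_site("SCV-MLB", lex, model, cfg)
#> <site> SCV-MLB
#>   supraclavicular region [C0446461:T029]
#>   - [PUNC:T000]
#>   midline block [:T169]

annotate_site("WBRT", lex, model, cfg)
#> <site> WBRT
#>   whole-brain radiotherapy [C1520143:T061]

# usage statistics of the bundled whole-brain spelling table
wb <- build_frequency_table(fixture_whole_brain_variants())
vg <- variant_group(wb, lex, c("C0006104", "C1520143"), model, cfg)
c(variants = n_unique(vg), uses = total_entries(vg))
#> variants     uses
#>       27     1063
```

The first call shows an abbreviation chain resolving to two concepts around
a punctuation marker (punctuation is annotated but excluded from
evaluation); the `[:T169]` payload is a curated supplement concept with no
CUI in the source vocabulary. The last result shows all 27 observed
whole-brain spellings (1063 total uses) collapsing onto the brain /
whole-brain-radiotherapy concepts.

## Command line

An executable script is installed at `exec/rtsites`:

```sh
rtsites annotate --in sites.txt --fixture --format gold --out annotations.tsv
rtsites stats    --in corpus.tsv --top-k 20
rtsites synth    --out-dir synth/ --n 1000 --seed 7
rtsites evaluate --pred annotations.tsv --gold gold.tsv
rtsites build-lexicon --concepts mrconso.psv --semtypes mrsty.psv \
    --filter T023,T029,T030,T082 --supplement supplement.tsv --out lexicon.tsv
```

All commands are byte-reproducible given the same inputs, config and seed.

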