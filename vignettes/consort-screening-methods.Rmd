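---
title: "Screening RCT publications for CONSORT reporting: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening RCT publications for CONSORT reporting: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consortcheck)
```

## The screening problem

The CONSORT 2010 statement lists the minimum information a randomized
controlled trial (RCT) publication should report. At fine granularity the
checklist decomposes into 37 items (e.g., 3a *Trial Design*, 6a *Outcomes*,
17a *Outcome Results*). Journals that enforce the checklist do so by manual
screening, which is slow; `consortcheck` automates the first step — deciding,
for each sentence and each article, which checklist items are reported and
which are missing.

Three item-level regimes are handled differently:

* **Items 1a and 1b** (randomized wording in the title; structured abstract)
  are properties of the whole article and are decided by deterministic rules.
* **Item 2a** (*Background*) is excluded: it is so broad that essentially
  every publication reports it, so a prediction carries no information.
* The remaining **34 items** are decided per sentence by a multi-label
  classifier; article-level decisions are derived from sentence-level ones.

## The sentence classifier

Each sentence is classified in context. The input is a three-segment window —
preceding sentence, target sentence, trailing sentence — where each segment
is prefixed with its own (nested) section headers, e.g.
`Methods Patients <sentence>`. Windows never cross article boundaries;
missing neighbours remain as empty segments so the layout is stable. A
sentence-position feature (absolute index, clipped at 512, or the relative
position binned into tenths with denominator $n-1$ so the last sentence
lands in the top bin) can be appended.

The window is embedded by a pluggable *encoder*: any function mapping the
segment list to a fixed-width pooled vector (the analogue of a transformer's
classification-token representation). The pooled vector, standardized on the
training set and concatenated with the position encoding, feeds a fully
connected layer with an independent sigmoid per label:

$$ p_\ell(x) = \sigma\!\left(w_\ell^\top \tilde{x} + b_\ell\right),
\qquad \tilde{x} = \gamma\, \frac{x - \mu}{s}, $$

with $\mu, s$ the training feature means and standard deviations and
$\gamma = 3$ a fixed input gain. Labels with $p_\ell \ge 0.5$ (configurable)
are predicted; the threshold is inclusive, and lowering it can only add
labels.

Training minimizes the mean binary cross-entropy over labels with AdamW
(decoupled weight decay 0.01), mini-batches of 4, encoder learning rate
1e-5, head learning rate 1e-3, dropout 0.1 on the pooled representation,
and a fixed 20 epochs with no scheduler, early stopping, or checkpoint
selection. Per-label biases are initialized at the label's training
log-odds, the standard initialization for rare-class sigmoid heads: the
base rate lives in the intercept from the first step instead of drifting
into the feature weights, which matters when most labels are rare.

### The reference encoder

Real deployments would plug in a pretrained biomedical transformer through
the encoder contract. The package ships a *reference encoder* so that the
entire pipeline — training, prediction, cross-validation, reporting — is
exercisable and testable offline: a deterministic hashed bag-of-tokens
embedder. Tokens are lowercased, salted with their segment role (preceding /
target / trailing — so the same word in the target and in a neighbour are
different features), and written into two signed hash buckets of a
1024-dimensional vector. Double hashing means a single bucket collision
never destroys a feature; signed hashing makes colliding contributions
cancel in expectation. The head's feature standardization then gives rare
informative tokens a magnitude of order $1/\sqrt{p}$, which is what lets a
sparse lexical cue outweigh the background at the configured learning rate
within the fixed epoch budget. The gain $\gamma$ sets that evidence scale;
$\gamma = 3$ was fixed at design time and is not data-dependent.

The reference encoder is a bag of tokens: it models lexical evidence, not
word order or syntax. Results obtained with it certify the pipeline and the
evaluation machinery, not biomedical language understanding.

### Section-specific models

`fit_section_model()` restricts training to the sentences of one article
section (Methods, Results or Discussion) and to the checklist items of that
section group. There is deliberately no Introduction-specific model — the
Introduction carries a single relevant item (2b, *Objectives*) — and the
item-to-section mapping ships as a data table
(`inst/extdata/consort_items.tsv`) following the checklist's own section
organization, so users can override it.

## Rules for items 1a and 1b

Item 1a: the title is searched, case-insensitively, for the stems `random`,
`randomis`, `randomiz`. Substring (not word-boundary) matching is used, so
"randomization", "randomised", "non-randomized" all match; since `random`
is a prefix of the other stems their matches are redundant, which is
harmless and documented. Item 1b: the abstract's leading token sequence —
the text before the first colon or period, or the first word — is uppercased
and looked up in a structured-abstract header list. Only the first header
position is examined, because the rule asks whether the abstract *starts*
structured. The packaged header list is a curated synthetic stand-in for the
National Library of Medicine's label list (assembled offline from common
labels); the full NLM list can be supplied via the `headers` argument, and
the list version is therefore configurable.

## Data augmentation for rare items

Eight items occur fewer than 100 times corpus-wide (3b, 6b, 7b, 9, 11b,
12b, 14b, 21). Only sentences carrying exactly one label, that label rare,
are augmentation candidates. Two families are implemented:

* **EDA** — synonym replacement, random insertion, random swap, random
  deletion at rate $\alpha = 0.1$ (the conventional EDA default; deletion
  always retains at least one word). Six variations per candidate are
  generated, each by one randomly chosen operation. Synonyms come from a
  provider contract with two backends: a small built-in general-English
  lexicon and a table-driven adapter usable with a UMLS-style clinical
  synonym table (full UMLS licensing cannot be assumed, so no UMLS data
  ships). EDA instances reuse the candidate's real neighbours and section
  path.
* **LLM prompting** — deterministic builders for a rephrasing prompt (N
  rephrasings of a labelled sentence, default 6) and a generative prompt (N
  one-sentence examples of an edited item description, N of 6 or 8,
  iterated until 100 instances accumulate). Item descriptions are edited
  before prompting: "with reasons" becomes "with specifics", hedges ("when
  applicable", "if relevant") and "such as ..." example spans are removed —
  the deletion span runs to the closing parenthesis or the next comma,
  which is the judgment call made here. Completions flow through an
  abstract provider (a function from prompt to text), so no network code
  exists in the package; tests use canned responses. Rephrased instances
  inherit the source instance's label; generative instances take the label
  of the description in the prompt, with a canonical section header for the
  item's group.

Augmented instances enter only training folds: instances traceable to a
source article are dropped from any fold where that article is under test,
and `cross_validate()` asserts this invariant at run time.

## Evaluation protocol

Articles are the cross-validation groups: a grouped k-fold plan (default
k = 5) shuffles articles under a seed and deals them round-robin, so no
article contributes sentences to both training and test data. Metrics:

* **Sentence level** — per-(sentence, label) binary confusions pooled for
  micro precision/recall/F1; macro-F1 as the unweighted mean of per-label
  F1. Labels absent from both gold and predictions in a fold have undefined
  F1 and are excluded from that fold's macro average (rare items can vanish
  from small folds). AUC is micro-averaged over the pooled
  (sentence, label) probability scores via the rank identity.
* **Article (ANY)** — an item counts as predicted for an article if any
  sentence is flagged for it, and as reported if any gold sentence carries
  it; confusion over article-by-item units. Thresholded sentence decisions
  are used; probabilities are not re-aggregated.
* **Article (1+)** — as ANY, but a true positive additionally requires at
  least one sentence shared between the predicted and gold supporting sets.
  A unit where both sides are present with zero overlap counts as one false
  positive plus one false negative (the model points at wrong evidence and
  misses the real evidence); this convention is isolated in one function.
* **McNemar** — two systems are compared on identical pooled
  (sentence, label) binary decisions (the multi-label "correct" unit is the
  single binary decision). With discordant counts $n_{01}, n_{10}$, the
  continuity-corrected statistic $(|n_{01}-n_{10}|-1)^2/(n_{01}+n_{10})$ is
  referred to $\chi^2_1$; below 20 discordant pairs the exact two-sided
  binomial test is used, and $p = 1$ with no discordant pairs.

Fold aggregation is the unweighted mean ± standard deviation over folds
(not pooled counts), matching how cross-validated results are convention-
ally tabulated.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical shape of a sentence-annotated
RCT corpus, not its prose. Defaults (fixed once, at design time): 50
articles of 100–300 body sentences with a title and a structured or
unstructured abstract; nested IMRaD section paths including Methods
subsections; per-item label frequencies defined over the item's section
group and skewed so roughly half of all sentences are labelled, about 5,200
label instances arise at default scale, and each of the eight rare items
stays under 100 instances corpus-wide; `multi_label_rate = 0.08` extra
same-section labels (about 1.08 labels per labelled sentence);
`p_randomized_title = 0.85` and `p_structured_abstract = 0.7`. Every item
owns a reserved cue token (`itemcue<code>`); a labelled sentence carries its
items' cues with probability `cue_strength` (default 0.9), and the
`cue_position` knob can plant the cue in a neighbouring sentence instead,
which makes the value of context windows directly testable. With
`cue_strength = 1` the task is separable by construction; with
`cue_strength = 0` no classifier can beat the label-frequency baseline,
which bounds what a sanity check can claim.

What passing tests on generated data do **not** show: robustness to real
clinical prose, paraphrase, cross-sentence semantics, or annotation noise —
the generator has none of these. They certify the pipeline's mechanics:
representation assembly, optimization, leakage-free evaluation, and the
exact arithmetic of the metrics.

## Problem sizes and numerical choices

The packaged experiments (test suite and `scripts/acceptance.R`) run at
desk scale, chosen once: memorization on a ~50-sentence two-article corpus;
grouped 5-fold cross-validation on 30 articles of 40–60 sentences (cued and
cue-free); and the context experiment on 20 articles of 30–45 sentences
with cues planted in the preceding sentence. At these sizes the full
acceptance run completes in minutes on one CPU. Other numerical choices:
the decision threshold is inclusive (≥); probabilities are serialized at
full double precision and a saved-then-loaded model reproduces predictions
bit for bit (parameters are written as 17-significant-digit decimals, which
round-trip IEEE doubles exactly); degenerate inputs are pinned by tests
(empty neighbours, single-sentence articles, rate-0 perturbations, empty
prediction sets, zero discordant pairs).

## Known limitations

* The reference encoder is lexical; its scores say nothing about real
  transformer performance beyond pipeline correctness.
* The rule for item 1b depends on the header list version; the packaged
  list is a curated subset.
* Sentence segmentation of raw XML uses a simple rule-based splitter;
  corpora with authoritative segmentation should be ingested pre-split via
  the CSV schema.
* Probabilities are not calibrated; the 0.5 threshold is a convention, not
  an optimum.
* The GPT-style in-context-learning and generative-sequence routes are
  prompt/format builders and parsers only; completion providers are the
  caller's responsibility.
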