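---
title: "Symptom-network herb recommendation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom-network herb recommendation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbrec)
```

## The problem

In traditional Chinese medicine a prescription is a *set* of herbs chosen
for a patient's symptom presentation, so recommending a prescription is a
multi-label ranking problem: given the free-text symptom terms recorded at
one encounter, rank every herb in the vocabulary by how likely it is to
appear in the prescription. Two features of real clinical text make this
hard. First, symptom phenotypes are described inconsistently — "foot pain"
and "foot sore" name the same phenotype but are distinct strings. Second,
no knowledge base precodes every phrasing, so a working system constantly
meets *unrecorded* terms: strings it has never seen, though almost always
composed of words it has. `herbrec` implements a pipeline built around
that observation.

## The knowledge graph and the symptom network

The starting point is a typed knowledge graph with entities for symptoms
(SY), herbs (HB) and three herb attributes — efficacy (EF, therapeutic
function), property (PP, e.g. hot/cold nature) and meridian (MD, channel
tropism) — and undirected relations HB–SY, SY–SY (synonymy), HB–EF,
HB–PP, HB–MD.

The graph is collapsed into a **symptom network** with two node roles
(whole symptom *terms* and sub-lexical symptom *words*) and five edge
provenances:

* **WORD** edges from word disassembly: every term is tokenized and joined
  to each of its distinct words, so "foot sore" contributes the edges
  "foot sore"–"foot" and "foot sore"–"sore". Shared words then connect
  related terms.
* **SYNONYMY** edges ingested from the graph's SY–SY relation.
* **EF_PATH / PP_PATH / MD_PATH** edges derived by metapaths: for bridge
  type X, an instance for the pair (SY1, SY2) is a triple (HB1, X, HB2)
  with HB1 ≠ HB2 and relations SY1–HB1, HB1–X, X–HB2, HB2–SY2 — two
  different herbs treating the two symptoms and sharing the attribute.
  Path counts are computed with sparse matrix products
  $A_{sh}(A_{hx}A_{hx}^\top - \mathrm{diag})A_{sh}^\top$ and an edge is
  kept only when its count reaches a frequency threshold, because the raw
  relation is extremely dense. A "metapath instance" is the full
  (HB1, X, HB2) triple; counting distinct herb *pairs* instead is a
  plausible alternative reading, and the triple was chosen as the minimal
  unambiguous one.

Tokenization is pluggable: character, whitespace, forward/backward maximum
matching against a lexicon (the standard greedy dictionary segmenters for
unsegmented Chinese), or n-grams, plus an optional stopword list for
function words such as conjunctions. Path-count weights are stored on the
edges but random walks treat the network as unweighted by default — no
weighting scheme is part of the method's definition — with weighted
first-order sampling available behind a flag.

## Embedding

Node vectors come from random-walk skip-gram: `generate_walks()` starts
`num_walks` walks of up to `walk_length` nodes from every node, with
node2vec's second-order p/q bias (p = q = 1 recovers uniform DeepWalk
walks), and `train_skipgram()` runs skip-gram with negative sampling over
the walk corpus (dynamic context window, unigram^0.75 negative table,
linearly decaying learning rate; implemented in C++ inside the package).
Defaults — 10 walks per node, length 40, window 5, 5 epochs, 5 negatives —
are the community-standard DeepWalk settings; the method itself does not
prescribe any. Training is single-threaded by design so a fixed seed is
bit-reproducible on one platform. `one_hot()` provides the structure-free
baseline encoding, and `load_embeddings()` accepts any word2vec-text file,
which is the provider interface for externally computed embeddings (e.g.
LINE or TransE from another toolkit; neither is implemented natively).

## Subnetwork term mapping

`map_term()` maps an arbitrary symptom term — recorded or not — onto a
concept subnetwork:

1. disassemble the term into distinct words;
2. look each word up in the network and collect the first-order neighbors
   of the words that are present (first-order only; no multi-hop
   expansion);
3. count for each candidate node how many distinct words it neighbors;
4. retain the present words plus every candidate whose frequency reaches
   `threshold`; the induced subnetwork is the network restricted to the
   retained set.

With threshold 2 ("frequency greater than 1") the canonical example
"foot sore and pain" → {foot, sore, pain} retains
{foot, sore, pain, foot sore, foot pain} and drops the single-word
neighbors "itchy feet" and "hand sore"; threshold 1 keeps all seven.
Threshold semantics are unified as `freq >= threshold`, which makes the
worked example (threshold 2) and the threshold sweep {1, 2, 3} coherent:
1 keeps every neighbor. Two deliberate readings are worth recording: the
filter is implemented on cross-word *frequency* (within the token-star
subgraph this coincides with the candidate's degree, which is how the
discussion sections of the literature sometimes phrase it), and only the
retained *node set* feeds the downstream model — the induced edges are
reported for inspection but not consumed. Words of the term that are
themselves network nodes are always retained regardless of frequency,
matching the worked example.

`fuse()` pools the retained nodes' embedding vectors coordinate-wise into
one d-vector: average pooling
$F(SY_i) = \tfrac1n \sum_{j=1}^n f_j$ or max pooling
$F(SY_i) = \max_j f_j$ (coordinate-wise). The max-pooling formula is
sometimes printed as an argmax, which returns an index; since the fused
object must be a d-vector comparable with the average, coordinate-wise
max — standard max pooling — is implemented. An empty mapped set fuses to
the zero vector with a warning so wholly unknown terms degrade gracefully.

## The recommender

`embed_case()` stacks the fused vectors of a case's symptoms into a
`(max_terms × d)` matrix (zero-padded, truncated with a warning beyond
`max_terms`). The model is:

* **attention** over rows: a single learned projection scores each row,
  a softmax over the *non-padded* rows converts scores to weights, and
  rows are rescaled by their weights (padding is masked out so it cannot
  attract weight);
* **1-D convolution** along the term axis, k kernels of width 3 with
  "same" zero padding (the width/count are not prescribed by the method;
  64 kernels of width 3 is the declared default);
* **global max pooling** per kernel;
* a fully connected head 256 → 64 → n_herbs with ReLU activations and a
  final softmax.

Training uses Adam at learning rate 1e-4 with a default cap of 100
epochs. The loss is cross-entropy between the softmax output and the
sum-normalized multi-hot herb vector (`SOFTMAX_CE`); since multi-label
practice often prefers independent sigmoids, `SIGMOID_BCE` replaces the
final softmax by element-wise sigmoids with binary cross-entropy. The
softmax default follows directly from the model's final layer being a
softmax. Early stopping monitors validation Recall@10 with patience 10;
monitoring the *test* set would leak information and is not done —
training either uses a held-out validation slice or runs to the epoch
cap. Recommendations are the K highest-probability herbs, ties broken by
herb-index order; probabilities are ranked, never thresholded.

All forward/backward passes are dense matrix algebra in R (BLAS-bound);
the backward pass is verified against numerical differentiation in the
test suite.

## Evaluation

`topk_metrics()` computes micro-averaged Top-K metrics with sums before
division:
$$\mathrm{Precision@K} = \frac{\sum_i |R(i)\cap T(i)|}{\sum_i |R(i)|},\quad
\mathrm{Recall@K} = \frac{\sum_i |R(i)\cap T(i)|}{\sum_i |T(i)|},$$
and F1 as their harmonic mean — micro, not macro, because the defining
equations sum over cases in both numerator and denominator.

`similarity_correlation()` checks the corpus premise that similar
prescriptions accompany similar symptoms: case pairs are binned by
prescription cosine similarity into ten 0.1-wide intervals and the mean
symptom-representation similarity (terms raw, tokenized, or mapped
through the subnetwork) is reported per bin. All-pairs comparison is
O(N²), so a seeded sample of pairs (default 200,000, or all pairs if
fewer) is used; the mapped representation of a case is the *set union* of
its terms' retained concept sets.

## The synthetic corpus generator

Real curated corpora of this kind are not redistributable, so the
package ships a generator that emulates their statistical shape with a
shared latent structure, making end-to-end signal recovery testable:

* herbs and symptoms are partitioned into `n_efficacy` latent groups;
  HB–EF edges tie each herb to its group's efficacy entity, HB–SY edges
  stay within group with probability `1 - noise_rate`, and PP/MD
  attributes are uniform noise;
* symptom surface strings are composed of 2–3 words drawn mostly from a
  per-group word pool (with a 20% shared pool), so the *word level*
  carries the same group signal as the graph — the premise that makes
  subnetwork mapping work;
* cases draw a two-group mixture (weights 0.85/0.15) and sample both
  their symptoms and their herbs from it, so the symptom–herb link is
  learnable; symptom and herb counts are Poisson at the post-screening
  corpus means 11.45 and 11.31, resampled into the screening bounds
  (1–39 symptoms, 1–19 herbs) so generated corpora always pass
  `screen_cases()` at the standard thresholds (< 40 symptoms, < 20
  herbs, strict);
* with `unrecorded_fraction`, a case's symptom is replaced by a novel
  string composed of in-group words that appear in recorded terms:
  absent from the knowledge graph, yet mappable through its words.

Two generator choices deserve their rationale. Cases always mix *two*
groups because a single group's herb pool (n_herbs / n_efficacy) can be
smaller than a Poisson(11.31) draw. And the mixture weights matter more
than they look: herbs within a group are exchangeable given the case's
groups, so the best achievable Recall@10 is bounded by how concentrated
the mixture is. An oracle that ranks herbs by their true draw
probabilities attains ≈ 0.72 under the default 0.85/0.15 weights on the
easy preset (it attains only ≈ 0.63 under 0.7/0.3 — too low a ceiling to
demonstrate "strong signal"). Passing recovery tests therefore shows the
pipeline extracts most of the available signal; it does not show
performance on real clinical text, whose vocabulary, synonymy structure
and label correlations are far richer than the generator's.

`recovery_benchmark()` runs the whole chain — graph, corpus, network,
DeepWalk embedding, subnetwork featurization, training, held-out Top-10
scoring — and reports recall next to the K/n_herbs random baseline.
Variant rows (avg vs max fusion, threshold 1 vs 2, subnetwork mapping vs
whole-term lookup, label shuffling as the no-signal control) share one
generated corpus and embedding.

### Problem sizes and numerical choices

The shipped presets use 150 symptoms, 50–100 herbs, 60 words, 625 cases
(a 500/125 split at 8:2 with a 440/60 train/validation carve), embedding
dimension 32 and 64 convolution kernels — sizes chosen so a full recovery
run is a coffee-sip on one CPU while leaving the signal structure intact;
embedding dimension has little effect beyond ~32 here, consistent with
the flat dimension response of the method itself. Metapath thresholds at
this scale are EF 3, MD 40, PP 40: efficacy paths carry the latent-group
signal (within-group pairs share bridges roughly an order of magnitude
more often than chance), while property/meridian paths are uninformative
by construction and their thresholds sit above typical counts. At
full-corpus scale the corresponding thresholds in the literature are
three orders of magnitude larger (1000/1000/100), matching their much
denser graphs.

Other numerical details: vocabularies sort by Unicode code point in the C
locale so label indices are reproducible everywhere; `split_cases()`
assigns `round(N(1-f))` cases to training (8,218 cases at 8:2 give
exactly 6,574/1,644) and freezes the herb vocabulary *before* splitting
so the output layer covers the full label space; Glorot-uniform
initialization from the configuration seed; softmax computations subtract
the row maximum; ties in Top-K break by index order; and every stochastic
step (graph, corpus, walks, negative sampling, batching) is a
deterministic function of its seed.

## Known limitations

* The attention form, convolution geometry and loss are under-determined
  by the method's published description; the declared defaults above are
  one reasonable instantiation, and the permutation-invariance of the
  width-1 configuration is the only architecture property asserted
  exactly.
* LINE and TransE embeddings are not implemented; only the word2vec-file
  provider interface is offered.
* The generator does not emulate real Chinese medical vocabulary, herb
  pharmacology, or long-range label correlations; recovery results are
  statements about the pipeline, not about clinical performance.
* Walks are unweighted by default even when path edges carry counts; the
  weighted flag changes only first-order proposals.
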