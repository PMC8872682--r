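# herbrec

Herb recommendation from symptom knowledge networks, for computational
researchers working with traditional Chinese medicine (TCM) clinical
records. A TCM prescription is a set of herbs chosen for a patient's
symptom presentation; `herbrec` ranks every herb in a vocabulary for a
given list of free-text symptom terms — including *unrecorded* terms that
appear in no knowledge base but are composed of known words.

The pipeline:

1. **Knowledge graph → symptom network.** A typed graph over symptoms
   (SY), herbs (HB), efficacy (EF), property (PP) and meridian (MD)
   entities is collapsed into a network of symptom terms and symptom
   words via (a) word disassembly — each term is linked to its words, so
   "foot sore" yields edges to "foot" and "sore"; (b) synonymy edges; and
   (c) metapath-derived edges: for the template SY1–HB1–EF–HB2–SY2, two
   herbs treating two symptoms while sharing an efficacy make the symptom
   pair related, with a frequency threshold keeping only well-supported
   pairs.
2. **Embedding.** DeepWalk / node2vec random walks + skip-gram with
   negative sampling (native C++ core), or one-hot; any word2vec-format
   file can be loaded as an external provider.
3. **Subnetwork term mapping.** A term is tokenized; its words' first-order
   neighbors are collected; candidates adjacent to at least `threshold`
   distinct words are retained together with the words, and the term is
   represented by the retained concept set — this is what gives unseen
   phrasings a usable representation.
4. **Fusion + recommender.** Retained sets are pooled (average or max)
   into per-symptom vectors, stacked into a case matrix, and fed through
   attention → 1-D convolution → global max pooling → a 256/64/n_herbs
   fully connected head with softmax, trained with Adam (lr 1e-4).
5. **Evaluation.** Micro-averaged Top-K metrics
   `Precision@K = Σ|R(i)∩T(i)| / Σ|R(i)|`,
   `Recall@K = Σ|R(i)∩T(i)| / Σ|T(i)|`, F1 their harmonic mean; plus a
   prescription–symptom similarity correlation analysis.
6. **Synthetic corpora.** A latent-group generator emulating the
   statistical shape of curated clinical corpora (Poisson case sizes at
   means 11.45 symptoms / 11.31 herbs, long-tail screening at < 40
   symptoms and < 20 herbs, compositional unrecorded terms) so the whole
   chain is testable end to end without any external data.

## Worked example

```r
library(herbrec)

# a toy symptom network: four recorded terms and their words
net <- assemble_network(tibble::tibble(
  u = c("foot sore", "foot sore", "foot pain", "foot pain",
        "itchy feet", "hand sore"),
  v = c("foot", "sore", "foot", "pain", "foot", "sore")))
#> symptom network: 7 nodes (4 TERM, 3 WORD); edges SYNONYMY=0 WORD=6 ...

tok <- tokenizer("WHITESPACE", stopwords = "and")
map_term("foot sore and pain", net, tok, threshold = 2)
#> <mapped_term_set> 'foot sore and pain' -> {foot, sore, pain, foot pain,
#>   foot sore} (threshold 2, 4 edges)
```

The unseen term "foot sore and pain" is represented by the consensus
subnetwork sore–"foot sore"–foot–"foot pain"–pain; the single-word
neighbors "itchy feet" and "hand sore" are filtered out at threshold 2
(kept at threshold 1).

End-to-end on a synthetic corpus (50 herbs in 5 latent efficacy groups,
625 cases split 500/125):

```r
rep <- recovery_benchmark(preset_config("easy"))
rep[, c("featurizer", "fusion", "threshold", "recall", "baseline_recall")]
#> # A tibble: 1 × 5
#>   featurizer fusion threshold recall baseline_recall
#>   <chr>      <chr>      <dbl>  <dbl>           <dbl>
#> 1 sstm       AVG            2  0.734             0.2
```

Held-out Recall@10 of 0.73 against a random baseline of 0.20 (10/50):
the model recovers most of the latent group structure that links
symptoms to herbs. An oracle knowing the true group mixture of every
case attains ≈ 0.72–0.75 here, so the pipeline is close to the ceiling
the corpus admits.

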