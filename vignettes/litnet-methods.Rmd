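---
title: "Methods: co-occurrence features, rare-event classifiers and centrality ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence features, rare-event classifiers and centrality ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnet)
```

## The model in brief

litnet infers gene–gene interactions from how often two genes — or a gene and
the Gene Ontology (GO) terms annotating its partner — appear together in
biomedical abstracts, and then prioritizes disease genes by network
centrality. Three text granularities are distinguished:

* **abstract level** — both entities occur anywhere in the same abstract;
* **sentence level** — both occur in the same sentence;
* **semantic level** — both occur in the same sentence *and* an interaction
  cue phrase ("binds with", "interacts with", "and", "or", ...) links them.

Each unordered gene pair $(g_1, g_2)$ is summarised by nine ratios
$\langle W_1,\dots,W_9\rangle$: the three levels crossed with three entity
pairings — $(g_1, g_2)$, $(g_1, \mathrm{GO}(g_2))$ and
$(g_2, \mathrm{GO}(g_1))$. With $c$ the number of shared units and $n_a$,
$n_b$ the individual unit counts, the default feature is the Jaccard ratio

$$W = \frac{c}{n_a + n_b - c} \in [0, 1],$$

defined as 0 when the denominator vanishes. Pairs are classified as
interacting or not with weighted logistic regression, whose logit is linear
($X_i\beta$, WLR) or kernelised ($k_i\alpha$ with a Gaussian RBF kernel,
WKLR), maximising the weighted, ridge-penalised log-likelihood

$$\ln L(\beta)=\sum_i w_i\!\left[y_i\eta_i-\ln(1+e^{\eta_i})\right]
  -\frac{\lambda}{2}\|\beta\|^2 .$$

The case weights $w_i$ carry the rare-event correction: true interactions
are a small minority of all pairs, so events are up-weighted. Predicted
positive pairs form an undirected simple graph; a disease subnetwork is the
set of edges touching at least one curated seed gene, and candidate genes
are ranked by degree, closeness, betweenness or eigenvector centrality.

## Decisions the sources left open

Several choices were under-determined and are fixed here as package policy:

* **Feature normalisation.** "Co-occurrence over individual appearance" is
  ambiguous; we use the Jaccard form because it is bounded, symmetric and
  interpretable as set overlap. `feature_normalization` also offers
  `"min"` ($c/\min(n_a,n_b)$) and `"product"` ($c/(n_a n_b)$) for
  sensitivity analysis.
* **Semantic denominators.** A cue-linked relation has no "individual
  appearance" of its own; since semantic links are a subset of sentence
  co-occurrences, the sentence-level individual counts are used.
* **GO composites.** The GO terms of a gene act as one composite entity: a
  unit counts when *any* of the gene's GO terms occurs in it. Summing per
  term would push features outside $[0,1]$.
* **The between-rule for cues.** A cue must lie strictly between the two
  mention spans *with no third entity mention between them*. The purely
  positional reading would link distant pairs through intervening mentions
  (in "A was studied; B and C rose", A–C would be linked by the "and"),
  which contradicts how a reader parses the sentence; requiring direct
  linkage reproduces the intended behaviour on all worked examples.
* **Token matching.** Tokens are maximal alphanumeric runs. Gene symbols
  match case-sensitively (official symbols only; synonym lists can be added
  as extra lexicon rows but are off by default — alias resolution is a known
  gap). GO term names and literal GO ids match case-insensitively. Longest
  match wins at each position, scanning left to right, and a token belongs
  to at most one mention. Multi-token phrases tolerate any non-alphanumeric
  separator between tokens ("cell division" also matches "cell-division").
* **Sentences.** The title is sentence 0; the body is split at `.`/`!`/`?`
  followed by whitespace and an uppercase letter or digit, with a
  configurable abbreviation guard ("E.", "i.e.", "et al.", ...). All
  offsets are 0-based, half-open.
* **Counting semantics.** Units are counted as sets (an entity mentioned
  twice in one sentence counts once). Whether the original system counted
  mentions or units is unknown; set semantics is the declared choice here.

## The classifiers

* **Weights.** Without a known population event rate, balanced weights
  $n/(2n_1)$, $n/(2n_0)$; with a rate $\tau$, the prior-correction form
  $\tau/\bar y$ and $(1-\tau)/(1-\bar y)$. Either way weights are rescaled
  to sum to $n$. Weighting by class shifts only the intercept of the
  population optimum (the slope estimates stay consistent), which is why
  the rare-event parameter-recovery tests compare slopes.
* **Intercept.** Added and never penalised: under rare events the
  prevalence must be absorbable without shrinkage.
* **Optimisation.** WLR: Newton–Raphson with step-halving from a zero
  start, converged at gradient $\infty$-norm $\le 10^{-8}$ or 100
  iterations. WKLR: damped Newton on the dual vector, tolerance $10^{-6}$,
  500 iterations, the $n\times n$ RBF kernel carrying a $10^{-10}$ diagonal
  jitter. Perfectly separable data at $\lambda = 0$ raise an error advising
  a positive penalty.
* **RBF kernel.** $k(x_i,x_j)=\exp(-\|x_i-x_j\|^2/2\sigma^2)$ — the
  standard Gaussian kernel (the printed formula in the source material has
  inconsistent parenthesisation).
* **Thresholding.** A pair is positive iff $p >$ threshold, ties to class
  0. Raising the threshold through $0.5 \to 0.8$ can only shrink the
  positive set; the highest threshold a pair survives is its
  *persistence*, a useful strength ranking (`threshold_persistence()`).
* **Tuning.** `bootstrap_tune()` scores each $(\lambda[,\sigma])$ grid
  point by mean out-of-bag balanced accuracy over stratified bootstrap
  resamples (shared across grid points as common random numbers), ties
  broken toward more shrinkage. Balanced accuracy is used because both
  class-conditional accuracies matter under heavy imbalance. Whether the
  original bootstrap accuracy was out-of-bag or in-sample is unstated;
  out-of-bag is the defensible default. Reference hyperparameters from a
  large-corpus fit are shipped as `preset_hyperparameters()` — documented
  starting points, not targets.

## Network analysis

Centrality is computed on the unweighted, undirected simple graph; predicted
probabilities ride along as edge annotations only. Conventions (all
switchable where noted):

* degree: raw neighbour counts;
* closeness: per connected component, $(|C|-1)/\sum_{u \in C} d(v,u)$ —
  "distance to every other node" is ill-defined across components, so
  disconnected graphs are scored within components and isolated nodes get 0;
* betweenness: endpoints excluded, unordered pairs counted once,
  unnormalised by default (the common analyzer default);
* eigenvector: power iteration, all-ones start, L2 normalisation,
  tolerance $10^{-10}$, cap 1000. The iteration runs on $A + I$: the
  spectral shift leaves eigenvectors unchanged but makes the Perron vector
  strictly dominant, without which the iteration oscillates on bipartite
  graphs (stars, paths). On disconnected graphs the scores reflect the
  dominant component; others decay to 0.

`network_stats()` reports node/edge counts, the diameter of the largest
component and the mean local clustering coefficient (degree-< 2 nodes
contribute 0). All four centralities are verified against a library-free
brute-force oracle (`oracle_centrality()`: Floyd–Warshall distances,
exhaustive shortest-path enumeration, direct eigen-decomposition with the
degenerate dominant eigenspace handled as the projection of the start
vector).

## What the synthetic generator emulates — and what it does not

`simulate_corpus()` stands in for a multi-million-abstract corpus that
cannot ship with a package. A hidden graph (Erdős–Rényi background plus a
planted clique "disease module" around designated seed genes) drives
sentence construction: each sentence focuses on one pair — interacting with
probability `edge_sentence_prob` (default 0.5), otherwise a uniform
non-interacting pair — and jointly mentions it with probability
`p_cooccur_pos` (default 0.3) or `p_cooccur_neg` (default 0.005); joint
mentions carry a cue with probability `p_cue` (default 0.8), and mentioned
genes drag in a GO term name with probability 0.3. Defaults (200 genes,
2000 abstracts of 5 sentences, ~1.5 expected background partners per gene,
a 10-gene module with 3 seeds) give a corpus in which interacting pairs
co-occur repeatedly while spurious pairs co-occur mostly once, and the
induced label prevalence among co-occurring pairs is 1–2% — a genuine
rare-event regime that one CPU processes in seconds.

The sentence-per-pair design was chosen over applying the joint-mention
probabilities independently to every pair per sentence: with $\sim n^2/2$
non-interacting pairs even a tiny `p_cooccur_neg` would flood each sentence
with mentions. A corollary: with `p_cooccur_pos == p_cooccur_neg` the
generator is exchangeable across pairs only when `edge_sentence_prob`
equals the realized edge fraction, which is how the null-signal
self-consistency test is configured.

Deliberately *not* emulated: real PubMed prose (syntax, negation,
anaphora), gene-symbol ambiguity with common English words, shared GO terms
across genes (synthetic annotations are gene-specific), MEDLINE metadata,
and cross-sentence relations. A green end-to-end test therefore establishes
that the machinery — NER, indexing, features, classifier, ranking —
composes correctly and recovers a planted signal; it does not establish
real-world NER accuracy or benchmark precision.

`simulate_feature_table()` bypasses text entirely: features i.i.d. on
$[0,1]$, labels from a known logistic model, the intercept solved
numerically for a target prevalence (5% by default). It is the ground truth
for coefficient-recovery and tuning tests. All generators are deterministic
functions of one explicit integer seed.

## Numerical choices and degenerate inputs

* $\ln(1+e^\eta)$ is evaluated as $\eta + \ln(1+e^{-\eta})$ for
  $\eta > 30$; likelihoods stay finite for any linear predictor.
* Feature ratios with zero denominators are 0 by definition.
* Empty corpora, edgeless graphs and absent entities yield empty tibbles,
  zero counts or `NA` diameters rather than errors; empty seed lists and
  single-class labels are errors.
* Ranking ties break by ascending gene symbol, so all rankings are total
  and reproducible; tuning ties prefer larger $\lambda$ (then larger
  $\sigma$).
* Duplicate edges keep the maximum predicted probability; self-pairs are
  dropped with a warning.

## Known limitations

Dictionary NER misses synonyms, misspellings and symbol/word ambiguity
(matching is deliberately exact); semantic linkage is surface-level — no
dependency parsing, negation handling or cross-sentence relations; the
WKLR kernel matrix is dense ($O(n^2)$ memory), so kernel fits are for
moderate training sets; eigenvector centrality on graphs whose two largest
components tie in dominant eigenvalue is ambiguous (the iteration returns
the balanced projection); and benchmark evaluation is exact-symbol, so
precision against real benchmark lists is conservative under aliasing.
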