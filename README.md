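# litnet

Gene–gene interaction networks from biomedical abstracts, and disease-gene
prioritization by network centrality.

## What it does, and for whom

Most of what is known about gene interactions sits in free text. litnet is
for computational biologists who want to turn a corpus of abstracts into a
ranked list of disease-gene candidates without any external services: it

1. finds gene symbols and Gene Ontology (GO) term names in abstracts by
   dictionary named-entity recognition;
2. summarises every gene pair (g₁, g₂) by nine co-occurrence ratios
   ⟨W₁…W₉⟩ — the entity pairings (g₁, g₂), (g₁, GO(g₂)), (g₂, GO(g₁))
   crossed with three text levels (same abstract, same sentence, same
   sentence linked by an interaction cue phrase such as "binds with").
   Each feature is a Jaccard ratio `c / (n_a + n_b − c) ∈ [0, 1]` of shared
   over individual occurrence units;
3. classifies pairs with **rare-event weighted logistic regression** —
   linear (WLR, logit `X β`) or RBF-kernelised (WKLR, logit `k α`,
   `k(x_i, x_j) = exp(−‖x_i − x_j‖²/2σ²)`) — maximising the weighted
   ridge-penalised log-likelihood
   `Σ w_i [y_i η_i − ln(1 + e^{η_i})] − (λ/2)‖β‖²`, with case weights
   correcting for the extreme scarcity of true interactions, and λ (and σ)
   tuned by stratified bootstrap with out-of-bag balanced accuracy;
4. builds the predicted interaction network, extracts the subnetwork of
   edges touching curated **seed genes** (e.g. OMIM disease genes), and
   ranks candidates by degree, closeness, betweenness or eigenvector
   centrality, evaluated as precision@n against benchmark gene sets and
   seed recall.

A seeded synthetic-corpus generator with a planted interaction graph and
disease module (`simulate_corpus()`) exercises the whole pipeline offline.

## Worked example

A synthetic corpus of 600 abstracts over 80 genes, with a hidden interaction
graph and a planted 8-gene disease module around 3 seed genes:

```r
library(litnet)

sim <- simulate_corpus(n_genes = 80, n_abstracts = 600, module_size = 8,
                       n_module_seeds = 3, seed = 42)
mentions <- find_mentions(sim$abstracts, sim$lexicon, sim$annotations)
index <- build_occurrence_index(mentions, sim$abstracts)
feats <- all_pair_features(index, eligible_genes(sim$lexicon, sim$annotations),
                           sim$annotations)

key <- function(a, b) paste(pmin(a, b), pmax(a, b))
feats$label <- as.integer(key(feats$g1, feats$g2) %in%
                            key(sim$true_edges$g1, sim$true_edges$g2))
fit <- fit_wlr(feats, lambda = 0.1)
glance(fit)
#>   lambda loglik converged iterations     n
#>      0.1  -363. TRUE               7  2203
```

2203 co-occurring pairs were scored; the sentence- and semantic-level
gene–gene features (W₂, W₃) carry most of the signal, as they should —
repeated same-sentence, cue-linked mentions are what distinguishes true
interactions:

```r
feats$prob <- predict(fit, feats)
auc(roc_curve(feats, "label", "prob"))
#> [1] 0.9993168

pred <- dplyr::filter(feats, classify_interactions(prob) == 1)
net <- build_network(pred[c("g1", "g2", "prob")])
network_stats(net)
#>   nodes edges diameter clustering
#>      51    69       10      0.129

sub <- extract_disease_subnetwork(net, sim$seed_genes)
rank_top_n(centrality_scores(sub, "degree"), 10)
#>     rank gene  score
#>  1     1 G0025    10
#>  2     2 G0049     9
#>  3     3 G0065     7
#>  4     4 G0018     3
#>  5     5 G0024     3
#>  ...

precision_at_n(rank_top_n(centrality_scores(sub, "degree"), 10),
               sim$module_genes, 10)
#> <precision@10> 8/10 = 80.0%
seed_recall(net, sim$seed_genes)
#> [1] 1
```

All 8 planted module genes land in the first 8 ranks (the three seeds on
top, their module partners at degree 3), giving precision@10 of 80% against
the module benchmark, and every seed gene is covered by the predicted
network (seed recall 1).

Bundled reference data: `cancer_seed_genes()` (OMIM seed lists for
prostate/breast/lung cancer) and `breast_validation_table()` (a published
top-30 breast-cancer prediction list with validation flags, summarised by
`summarize_validation()`).

A thin command-line wrapper over the same functions ships at
`inst/scripts/litnet.R` (`simulate`, `extract-features`, `train`,
`predict`, `rank`, `stats`).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — simulating a 2000-abstract corpus, extracting mentions
and features, fitting WLR, building the network, extracting the
seed-anchored subnetwork and ranking by centrality — and writes its JSON
result object to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/litnet-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, the
numerical choices (tolerances, tie-breaks, degenerate inputs) and known
limitations.
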