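# hlanet

Network analysis and neighbor-edge prediction of qualitative HLA-peptide
binding.

Class I human leukocyte antigens (HLAs) present short peptides to T cells;
curated assay databases describe tens of thousands of (allele, peptide)
pairs as binding or not. `hlanet` represents such data as a weighted
bipartite network — edge weight 2 for positive binding, 1 for negative —
and provides, for immunoinformaticians and systems biologists:

* **Data preparation**: source-label harmonization (IEDB graded positives,
  SYFPEITHI ligands, AntiJen weak binders), inclusive majority-vote
  deduplication, and iterative removal of singleton nodes (the bipartite
  2-core).
* **Binding modules**: fast greedy (Clauset–Newman–Moore) modularity
  optimization on the weighted graph, with a conservative significance
  test that shuffles only the edge weights across a fixed topology — by
  default 1,000 random networks — and reports where the real modularity
  falls in that null.
* **Module profiles**: peptide length tables with column percentages,
  position-wise residue-category profiles (polar charged / polar
  uncharged / apolar), HLA contact-residue pseudo-sequences, and
  within- vs between-module identity testing.
* **Nebula**, a two-sided neighbor-edge collaborative filter. For a pair
  $(h_i, p_x)$ it predicts from each side, e.g.

  $$P_{h_i,p_x} = \bar w_{h_i} + \frac{\sum_j (w_{h_j,p_x} - \bar w_{h_j})\,S_{h_i,h_j}}{\sum_j S_{h_i,h_j}},$$

  with $S_{h_i,h_j}$ the Pearson correlation of the two alleles' weights
  over shared peptides and $\bar w$ a node's mean edge weight; the final
  score $F$ is the mean of the two sides and the call is positive when
  $F \ge \mathrm{UL}$ (unbiased leverage, default 1.5, inclusive).
* **Validation**: leave-one-out (with true exclusion of the held-out edge
  from every mean, similarity and neighbor sum) and repeated k-fold
  cross-validation split by edges, with rank-based (midrank) ROC/AUC.
* **A planted-module synthetic generator**, so the whole pipeline is
  testable and demonstrable without any external download.

## Worked example

```r
library(hlanet)

# a planted 3-module dataset: 21 HLAs x 600 peptides, ~42% positive edges
sim <- do.call(simulate_binding_data,
               c(synthetic_preset("paper_like"), list(seed = 1)))
records <- degree_filter(sim$records[c("hla", "peptide", "label")])
net <- binding_network(records)
net
#> Weighted bipartite HLA-peptide binding network
#>   21 HLA alleles, 600 peptides, 2214 edges (41.5% positive)

modules <- fast_greedy_modules(net)
modules
#> Module partition: 3 modules, modularity Q = 0.6441 (weighted)

permutation_null(net, replicates = 200, base_seed = 1)
#> Permutation null (weights, 200 replicates): real Q = 0.6441
#>   null Q: mean 0.6377, sd 0.0013, range [0.6340, 0.6414]
#>   empirical p = 0.004975 (0 of 200 null values >= real)

fit <- nebula(net)
loo_validate(fit)
#> Leave-one-out validation over 2214 edges
#>   sensitivity 0.903, specificity 0.924, accuracy 0.916, AUC 0.925

# score unobserved pairs: a planted binder and a planted non-binder
q <- data.frame(hla = "HLA-S1*03:01",
                peptide = c("MIKVWNIGM", "WWCFNDVQV"))
predict(fit, newdata = q)[, c("hla", "peptide", "F", "C")]
#>            hla   peptide        F        C
#> 1 HLA-S1*03:01 MIKVWNIGM 2.001550 positive
#> 2 HLA-S1*03:01 WWCFNDVQV 0.999639 negative
```

The modularity (0.644) sits above every one of the 200 weight-shuffled
null values: the within-module concentration of positive bindings is not
explainable by the network's topology plus label counts alone. The two
queried pairs were never assayed in the training data; Nebula places the
planted binder at $F \approx 2$ (positive) and the non-binder at
$F \approx 1$ (negative) purely from neighboring edges.

The same steps run on real data: read your records with
`read_binding_records()`, harmonize with `harmonize_labels()`, aggregate
with `aggregate_records()`, and proceed as above. `run_pipeline()` (or the
thin CLI wrapper in `inst/cli/hlanet.R`) chains every stage with a
resumable manifest and serialized configuration.

## Documentation

The methods vignette (`vignettes/hla-peptide-network-analysis.Rmd`)
documents the model, every tunable parameter and default, the design
decisions behind the open formulation choices (denominator convention,
mean convention, fallback cascade), what the synthetic generator does and
does not emulate, and known limitations.
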