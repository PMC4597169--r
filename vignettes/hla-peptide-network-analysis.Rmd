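---
title: "Methods: HLA-peptide binding networks, modules and Nebula prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA-peptide binding networks, modules and Nebula prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlanet)
```

## The problem

Class I human leukocyte antigens (HLAs) present short peptides — mostly
8-11-mers, dominated by 9-mers — to T cells. Decades of binding assays,
curated by databases such as IEDB, SYFPEITHI, MHCBN and AntiJen, yield a
large but sparse table of qualitative outcomes: allele $h$, peptide $p$,
binds or does not bind. `hlanet` treats this table as a **weighted bipartite
network**: alleles on one side, peptides on the other, an edge for every
assayed pair, weighted

$$w_{h,p} = \begin{cases} 2 & \text{positive binding} \\ 1 & \text{negative binding} \end{cases}$$

Two questions drive the package. First, does the network contain *binding
modules* — groups of alleles and peptides that preferentially bind each
other — and are they statistically real? Second, can the label of an
unobserved (or held-out) pair be predicted from the network alone, with no
sequence features and no fixed peptide length?

## Data preparation

Raw records pass through three stages before any analysis:

1. **Label harmonization.** Graded IEDB calls (`positive-high`,
   `positive-intermediate`, `positive-low`) all count as positive;
   SYFPEITHI entries (eluted ligands/epitopes) are positive; AntiJen
   "weak binder" entries are negative, following that database's own
   description. Allele names are normalized to `HLA-X*nn:nn` so that
   formatting differences between sources do not split one allele into
   several nodes; peptides are upper-cased and restricted to the 20
   standard residues (ambiguity codes are rejected, not translated,
   because the category scheme below covers only the standard alphabet).
2. **Majority-vote aggregation.** Each distinct (allele, peptide) pair
   becomes one record carrying its proportion of positive entries; the
   pair is positive when that proportion is $\ge 0.5$ (the boundary is
   deliberately inclusive). Every raw row counts once with equal weight:
   the sources do not document per-database reliability, so any weighting
   would be invented.
3. **Sparsity filtering.** Alleles and peptides with fewer than two
   records are removed, and removal is iterated to a fixed point. The
   result is the bipartite 2-core — the unique maximal subnetwork with all
   degrees $\ge 2$ — so the outcome does not depend on deletion order. A
   singleton node carries no neighbor information for a collaborative
   filter and cannot be evaluated in leave-one-out, which is why the
   default `min_count` is 2.

## Modules and their significance

Modules are found by fast greedy (Clauset–Newman–Moore) modularity
optimization, delegated to `igraph::cluster_fast_greedy()` and cut at the
maximum-modularity point of the merge dendrogram. Modularity is the general
Newman–Girvan $Q = \sum_c (e_c - a_c^2)$ applied to the bipartite graph —
the same convention igraph uses — rather than a bipartite-specific variant;
`modularity_q()` recomputes $Q$ independently of igraph from the returned
assignment, and the two implementations are cross-checked in the tests.
The **weighted** form (weights 1/2) is the default: the null model below
permutes weights, which is only meaningful if weights enter the statistic.
An unweighted flag is kept for sensitivity analysis. Tie-breaking among
equal-gain merges follows igraph's deterministic internal order; we did not
re-implement the agglomeration just to impose a lexicographic rule, since
identical inputs still give identical outputs.

Significance is assessed with a deliberately conservative permutation null:
`shuffle_weights()` keeps every node and every edge in place and permutes
only the 1/2 weights, conserving the counts of positives and negatives;
`permutation_null()` reruns module detection on each of (by default) 1,000
shuffled networks with the same algorithm and parameters and reports the
empirical $p = (1 + \#\{Q_\text{null} \ge Q_\text{real}\}) / (1 + R)$.
Replicate $i$ uses seed `base_seed + i` and the seeds are stored, so the
null histogram is exactly reproducible. A harsher alternative that redraws
the edges themselves (`rewire_edges()`, preserving node and weight counts)
is available but is not the default null.

## Module characterization

Peptides are profiled by length (7- to 11-mers, everything longer pooled
as ">11") with column percentages that sum to 100% over modules, and by
position-wise residue category for a fixed length, using the three-way
physicochemical scheme: polar charged (R, D, E, H, K), polar uncharged
(N, C, Q, G, S, T, Y) and apolar (A, I, L, M, F, P, W, V). Positions 2 and
the C-terminus (P2/P$\Omega$) are the classical anchors and carry most of
the between-module contrast.

HLAs are profiled through **position-specific pseudo-sequences**: the
groove residues contacting each 9-mer position are extracted from a
gapless alignment of the peptide-binding region (mature-chain residues
2-182, so alignment column $i$ is residue $i+1$) and concatenated. The
shipped contact-residue table
(`inst/extdata/contact_residues_9mer_reconstructed.tsv`) is a
reconstruction assembled from the classical A-F pocket literature — the
original uniform contact list is not reproduced in any source available to
the package — and is deliberately an editable configuration file, so users
can substitute e.g. NetMHCpan pseudo-sequence positions.

Within- versus between-module pseudo-sequence identity is compared per
module with a one-sided Mann–Whitney test by default. Pair identities are
not independent observations, so a label-permutation mode is provided; for
small module counts note the permutation p-value is bounded below by the
number of distinguishable label arrangements, which with very few alleles
cannot reach 0.05 at all. Modules with a single allele have no within-pairs
and are reported as `NA` and excluded from testing.

## Nebula

Nebula (neighbor-edges based and unbiased leverage algorithm) scores a
pair $(h_i, p_x)$ from the edges adjacent to it. With $\bar w_{h_i}$ the
mean weight of all edges incident to $h_i$, the HLA-side prediction is

$$P_{h_i,p_x} = \bar w_{h_i} +
  \frac{\sum_j (w_{h_j,p_x} - \bar w_{h_j})\, S_{h_i,h_j}}
       {\sum_j S_{h_i,h_j}},$$

where $j$ runs over the HLAs connected to $p_x$ and $S_{h_i,h_j}$ is the
Pearson correlation of the two alleles' weights over their shared
peptides, centered at each allele's overall mean. $S = 0$ when no peptide
is shared or when either profile is degenerate over the shared set. The
peptide-side $P_{p_x,h_i}$ is the exact mirror; the final score is
$F = (P_{h_i,p_x} + P_{p_x,h_i})/2$ and the call is positive when
$F \ge \mathrm{UL}$, the *unbiased leverage*, by default the midpoint 1.5
of the two weight codes. The threshold is inclusive.

Design choices where the formulation is genuinely open:

* **Denominator.** The literal formula divides by $\sum_j S$, which can
  cancel toward zero (or go negative) and then produce unbounded scores.
  The default follows the literal formula, guarded: when
  $|\sum_j S| < \varepsilon$ (default $10^{-12}$) the deviation term is
  dropped and the side falls back to the node mean, flagged. A
  `denominator = "absolute"` mode divides by $\sum_j |S|$ — the classical
  Resnick collaborative-filtering convention — for users who prefer
  bounded behaviour; both modes are oracle-tested.
* **Means.** $\bar w$ is always a node's mean over *all* its incident
  edges (minus any excluded edge), both in the prediction formula and
  inside the Pearson similarities. The classical co-rated-only variant
  would change $F$; the all-edges reading is the plainer one and is
  applied consistently.
* **Exclusion semantics.** For validation, the edge under prediction is
  removed from every mean, similarity and neighbor sum. Exclusion is a
  parameter of the computation, not a graph mutation, so leave-one-out
  never copies the network and runs in a single pass over the edges.
* **Fallback cascade.** An undefined side (isolated endpoint after
  exclusion, unknown node) falls back to: the other side alone, then the
  global training-mean weight. Every fallback is flagged per edge in the
  output, and validation reports include these edges in the metrics — the
  evaluation covers all data, with coverage visible rather than silent.
* **No clamping.** $F$ is not clipped to $[1,2]$; only the UL threshold
  matters for the categorical call.

## Validation

`loo_validate()` predicts every edge with itself excluded.
`kfold_validate()` splits the *edges* (not the nodes) into k near-equal
random folds — sizes differ by at most one — and predicts each fold from a
model fitted to the others; with $k$ equal to the edge count it reduces
exactly to leave-one-out, which is asserted in the tests. Iteration $i$
uses seed `base_seed + i`. Metrics are sensitivity, specificity, accuracy
(positive = binder) and the area under the ROC curve computed by the
Mann–Whitney rank formulation with midranks, so tied scores contribute
half-concordances and any strictly monotone transform of $F$ leaves the
AUC unchanged. Splitting is unstratified: the even halves of the two-fold
protocol refer to edge counts, not class balance.

## The synthetic generator

Because the full curated compilation cannot be redistributed, every stage
is exercised on generated data with the structure the pipeline assumes
(`simulate_binding_data()`, `simulate_peptides()`,
`simulate_hla_alignment()`). The `paper_like` preset plants 3 modules of
7 HLAs and 200 peptides each; peptide lengths follow the real compilation's
mix (~69% 9-mers, ~26% 10-mers, the rest spread over 7-13); the marginal
positive rate is ~42% within modules and 10% across, near the real
compilation's 39.6% positives; and 9-mer anchors P2/P$\Omega$ carry
module-specific category biases.

Labels follow a **latent-binder model**: a fraction of each module's
peptides are cognate binders of their module's alleles (positive with
probability 0.97 at full signal) and the rest are not (0.03); the binder
fraction is set so the marginal rate stays at the configured value. This
per-peptide label correlation is what makes edge labels *predictable* —
with labels drawn independently given module membership alone, no
edge-level predictor can beat the module base rates (an AUC ceiling near
0.6 here), which would say nothing about the predictor. A `signal`
parameter anneals the binder contrast to zero while preserving the
marginal rate, giving a controlled path from strong structure
(LOO AUC $\approx 0.93$) to chance (AUC $\approx 0.5$). Each peptide is
guaranteed at least two within-module edges, so the default preset passes
the degree-2 filter unchanged; `edge_prob_within = 0.5` gives ~3.7 records
per peptide, sparser than the real compilation's ~6.4 but of the same
order.

What the generator does *not* emulate: assay noise correlated across
databases, allele-frequency-driven sampling bias (real HLA degrees span
orders of magnitude), sequence-determined binding (labels are conditionally
independent of the peptide sequence given the module and binder state,
though anchor composition is module-biased), and any quantitative affinity
scale. Passing tests on generated data therefore demonstrate algorithmic
correctness and the expected qualitative behaviour, not real-data
performance figures.

One identifiability caveat: with cross-module edges at probability 0.01,
occasionally a generated peptide realizes edges that genuinely favor a
foreign module (about 1 in 600 at the default preset). Its planted label is
then unrecoverable from the graph by any method, so module-recovery checks
require exact recovery on the HLA side and $\ge$ 99.5% peptide agreement
rather than literal 100%.

## Problem sizes and numerical choices

The shipped analyses run at desk scale: the paper-like preset
(~21 × 600 nodes, ~2,200 edges) completes leave-one-out in under a second
and a 1,000-replicate permutation null in seconds; `scripts/acceptance.R`
runs the whole pipeline — generation, filtering, modules, 1,000-replicate
null, LOO, and 100 iterations of two-fold cross-validation — in about a
minute. The same code paths scale to the full public compilation
(118,959 edges), where leave-one-out is expected to take hours on one CPU;
the pipeline's resumable stages and the flagged fallback accounting are
designed with that run in mind. Degenerate inputs are contracts, not
accidents: empty networks refuse module detection, single-class labels
yield `NA` AUC with a warning, an isolated node's mean is an explicit
undefined signal for the caller, and $\varepsilon = 10^{-12}$ guards every
denominator.

## Known limitations

* Qualitative labels only; no IC50 regression or ranking calibration.
* The general Newman–Girvan modularity is used on a bipartite graph, as
  the delegated igraph implementation does; Barber's bipartite modularity
  is out of scope.
* The contact-residue table is a literature reconstruction (flagged in its
  filename); pseudo-sequence analyses inherit its choices.
* Pair identities in the within/between test are dependent; p-values are
  indicative, and the permutation mode is preferable when module counts
  allow it.
* The NBI comparator is supported only through the generic validation
  machinery (any scorer producing per-edge $F$ can be evaluated); no NBI
  formula ships with the package.
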