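---
title: "Descriptor-based diversity, structure and phenoprinting: models and methods"
author: "phenoprint package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based diversity, structure and phenoprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprint)
```

# The data model

`phenoprint` treats qualitative phenotypic descriptors the way population
genetics treats single-locus markers. A **trait catalogue** fixes the
universe: each trait (descriptor) has an ordered set of allowed states
("variables"), and every variable carries a global integer code. The bundled
catalogue for an Odisha aromatic short-grain rice collection defines 24
traits and 70 variables, numbered 1–70; that numbering fixes the phenoprint
bar order once and for all, so barcodes remain comparable even if traits are
ever re-ordered.

A **trait matrix** is N genotypes scored once per trait (one categorical
state, no heterogeneous scoring), with optional group labels such as the
collection district. Its **one-hot encoding** expands each trait into its
catalogue variables: exactly one 1 per fully scored trait, with the missing
trait masked as `NA` rather than zero-filled. Every downstream statistic is
computed from this encoding or from the per-trait state frequencies, with
per-trait denominators so that missingness in one trait never contaminates
another.

# Diversity statistics

For a trait with state frequencies $p_i$ scored in $n$ genotypes:

* observed state number $N_a = \#\{p_i > 0\}$;
* effective state number $N_e = 1 / \sum p_i^2$;
* gene diversity $h = 1 - \sum p_i^2$ (so $h = 1 - 1/N_e$ identically);
* Shannon index $I = -\sum p_i \ln p_i$, with $0 \ln 0 := 0$.

The plug-in estimator of $h$ is the default. The small-sample correction
$\frac{n}{n-1}(1 - \sum \hat p_i^2)$ is available via `unbiased = TRUE`, but
is *not* the default: for a 125/1 split of 126 both forms round to 0.016,
while for highly polymorphic traits the corrected value drifts visibly above
the plug-in values that published descriptor tables in this field report.
Nothing is rounded internally; presentation-style rounding (half-up, 3
decimals) is left to the caller.

Percent polymorphism (%P) is the share of variables with within-group column
frequency strictly between 0 and 1. The denominator is configurable: the
full catalogue count (default) or only the variables observed in the subset.
The choice matters when published denominators are ambiguous (70 vs 71
variables in the source material for the bundled catalogue); the package
ships the 70-variable catalogue and leaves the denominator a parameter.

The **probability of identity** multiplies $\sum_i p_{ti}^2$ over polymorphic
traits — the chance that two independent draws from the panel's frequencies
agree everywhere. This assumes independence across traits, which one-hot
descriptor data does not guarantee; PI is therefore a capacity summary
(1/PI = how many genotypes the descriptor set can in principle tell apart),
not a forensic match probability.

# Distances and trees

Between genotypes the default metric is the **trait mismatch proportion**:
the fraction of co-scored traits at which two genotypes differ. For one-hot
categorical profiles, any Nei-type identity is a monotone function of this
proportion, so neighbour-joining topologies are invariant to that choice;
`-log(1-m)` is available for users who want a Nei-style scale. Pairs with no
co-scored trait get `NA` and must be imputed or dropped before tree building
— the package refuses to guess.

Between groups the package computes Nei's identity
$I = J_{xy} / \sqrt{J_x J_y}$ with the $J$ terms averaged across traits, and
$D = -\ln I$; a haploid small-sample correction
$(n \sum x_i^2 - 1)/(n-1)$ per trait is available (floored at $10^{-12}$ so
the logarithm stays defined). Groups fixed for disjoint states give $I = 0$
and an infinite distance with a warning, rather than silent truncation.

**Neighbour joining** is the classic agglomeration: minimize
$Q_{ij} = (n-2)d_{ij} - r_i - r_j$, join, compute branch lengths, reduce.
Two numerical choices are deliberate:

* ties in $Q$ are broken by the lexicographically smallest pair of
  representative labels (the smallest leaf label in each subtree), so runs
  are reproducible across platforms;
* a negative branch length is clamped to zero and its deficit moved to the
  sister edge, preserving path lengths through the joined node.

On additive matrices the reconstruction is exact (the test suite checks path
lengths to $10^{-9}$ up to 8 taxa, and cross-checks topologies against an
independent implementation). `clusterReport()` bipartitions a tree at its
longest internal edge, a transparent stand-in for eyeballing two major
clusters in a dendrogram.

# AMOVA

The one-level analysis of molecular variance works on squared Euclidean
distances between one-hot rows: $SS_{total} = \sum_{i<j} d_{ij}^2 / N$,
within-group sums analogously per group, among-group by subtraction, with
df $(G-1, N-G, N-1)$. Variance components use the standard unequal-size
coefficient $n_0$; $\Phi_{ST} = \sigma_a^2 / (\sigma_a^2 + \sigma_w^2)$.
Significance comes from permuting group labels with the add-one rule
$p = (\#\{\Phi^* \ge \Phi\} + 1)/(B + 1)$, so $p$ is never exactly zero and
a seed is mandatory. A negative among-group component is floored at zero
only in the percentage column; the raw component is kept. Published AMOVA
tables for binary-coded descriptor data sometimes carry degrees of freedom
implying twice the sample count (diploid coding); this package always uses
the haploid row count and documents the difference rather than emulating it.

# Admixture-model clustering

`fitStructure()` implements the haploid admixture model: genotype $i$ has
ancestry $q_i \sim \mathrm{Dirichlet}(\alpha \mathbf{1}_K)$, cluster $k$ has
state frequencies $p_{k,t}$ per trait with uniform Dirichlet priors, and the
state at trait $t$ is drawn from the cluster indicated by a latent origin
$z_{it} \sim q_i$. A Gibbs sampler (compiled, seeded through R's RNG)
alternates $z$, $q$ and $p$; posterior means over post-burn-in sweeps give
$Q$ and $P$. Deliberate simplifications, stated rather than hidden:

* $\alpha$ is fixed (default 1.0), not sampled;
* the prior on cluster frequencies is uncorrelated (no F-model);
* $\ln P(D)$ uses the deviance approximation
  $\bar L - \tfrac{1}{2}\mathrm{var}(L)$ over the complete-data
  log-likelihood draws — an estimator adequate for *comparing* K, not an
  exact marginal likelihood.

Defaults are desk-scale — burn-in 2,000 and 5,000 retained sweeps, 4
replicate runs per K — which recover strongly diverged two-cluster panels of
~120 genotypes in seconds per run; the classical 100,000/100,000 × 10-run
schedule is available by argument for production analyses. Model choice uses
the Evanno second-order statistic
$\Delta K = |L(K{+}1) - 2L(K) + L(K{-}1)| / \mathrm{sd}(L(K))$ over runs;
$\Delta K$ is undefined at the boundary K values and wherever the
between-run sd is zero, and is reported as missing there. Label switching
between runs is resolved by exhaustive permutation matching on $Q$ (K ≤ 8),
minimizing mean absolute difference. Genotypes are assigned to their
maximum-membership cluster only when membership exceeds 0.80 (inclusive
rule: exactly 0.80 is admixed). Per-cluster fixation indices are computed as
the variance-component $\Phi_{ST}$ of "this cluster vs the rest" on hard
assignments — a descriptive proxy for the model-based quantity, consistent
by construction with the AMOVA module.

# PCA and trait importance

PCA runs on the column-centered (unscaled) one-hot matrix. The one-hot
columns of a trait sum to 1, so the matrix is rank-deficient by construction;
all columns are kept because dropping a reference state would make loadings
depend on an arbitrary choice. Missing cells are mean-imputed and flagged.
Signs follow a fixed convention (dominant loading positive). Trait
importance is the eigenvalue-weighted sum of squared loadings of a trait's
variables over the retained components; summed over everything it equals the
total variance, which makes the scores interpretable as variance shares.
This is the package's documented stand-in for a subset-regression style
screening whose exact procedure published work rarely specifies; it ranks a
trait highly when its states separate genotypes along the dominant axes.
Note one behaviour visible in the tests: a many-state trait spreads its
variance over many axes, so with few retained components a two-state trait
with balanced frequencies can outrank it — importance is about the retained
subspace, not total entropy.

# Phenoprints, duplicates and core subsets

A phenoprint is the ordered presence/absence bit vector over all catalogue
variables, rendered as one row of black (present) / grey (absent) bars in
SVG; missing traits render white. The geometry and number formatting are
fixed and the writer uses a binary connection with fixed newlines, so
identical inputs give byte-identical files — the golden-file and
determinism tests depend on exactly this.

Duplicate detection groups identical bit vectors (including the missingness
pattern). Core selection is greedy set cover over the variables observed in
the panel: repeatedly add the genotype covering the most uncovered
variables, ties broken by panel order, until the covered fraction reaches
the threshold (default 0.98). Greedy was chosen for determinism and its
$(\ln V + 1)$ approximation guarantee; it is *not* exact. On random 12-
genotype panels it needs one genotype more than the exhaustive optimum
roughly half the time — the test suite asserts the provable bound, coverage
and determinism, and the package makes no optimality claim beyond the bound.
Coverage is defined over observed variables because unobserved states cannot
be covered by any subset.

# The simulator

`simulatePanel()` draws each genotype's state per trait independently from a
frequency vector; `odishaPanelSpec()` encodes every printed frequency of the
126-genotype Odisha aromatic short-grain collection (the full 8-state
lemma-palea colour profile, all two-state splits, the modal frequencies of
the remaining polymorphic traits), spreads unprinted residual mass uniformly
over the remaining states, fixes the six invariant traits, and uses the 19
reported district sizes. Traits with no printed mode (leaf angle) default to
uniform. With `exactCounts = TRUE`, per-trait counts are fixed by
largest-remainder rounding of $p \times N$ and only the assignment to
genotypes is random, making every frequency-based statistic deterministic
for a given spec — the convention used by the determinism tests and the
acceptance script.

Two structure knobs exist. `groupDivergence` perturbs each group's
frequencies with a Dirichlet centred on the base vector
(concentration $p/\delta$), giving expected among-group fixation of roughly
$\delta/(1+\delta)$; $\delta = 1/12$ emulates the single-digit
district-level differentiation typical of landrace collections.
`simulateAdmixed()` instead builds K subpopulation frequency sets
(divergence on the same scale) and mixes them through per-genotype Dirichlet
ancestries, returning the true $Q$ and $P$ for recovery tests.

What the simulator does **not** emulate: correlations between traits
(pleiotropy, shared pigmentation pathways), missing data patterns, scoring
error, or spatial/temporal collection structure. Passing recovery tests on
simulated panels therefore demonstrates algorithmic correctness under the
stated model, not robustness to the full messiness of real descriptor data.
One interaction worth knowing: exact-count rounding is applied per group
when `groupDivergence > 0`, and with very small groups (districts of 2) the
rounding collapses each group onto the modal states and suppresses the
planted divergence — use i.i.d. sampling when the divergence itself is the
object of study.

# Problem sizes and numerical conventions

The test-suite and acceptance-script workloads are sized for a single CPU:
panels of 126 genotypes for pipeline checks, 120 for admixture recovery
(burn-in 2,000 / 5,000 sweeps, K ∈ 1..5, 4 runs per K), 12-genotype panels
for exhaustive oracles, 10,000-genotype panels only for law-of-large-numbers
checks. Frequency vectors must sum to 1 within $10^{-9}$; distance matrices
must be symmetric within $10^{-12}$; Q rows are checked to $10^{-9}$;
branch-length output is formatted with 15 significant digits so additivity
survives a newick round trip at $10^{-9}$.

# Known limitations

* No rarefaction or richness standardization across unequal group sizes —
  district-level diversity comparisons inherit sample-size bias.
* PI assumes trait independence; correlated traits make it optimistic.
* The admixture sampler's $\ln P(D)$ is an approximation; $\Delta K$
  comparisons are meaningful, absolute values are not.
* Greedy core subsets can exceed the optimum by a small margin (bounded).
* Bootstrap support for trees and multi-level AMOVA are out of scope.

# A worked mini-example

```{r example, eval = FALSE}
tm <- simulatePanel(odishaPanelSpec(), seed = 42, exactCounts = TRUE)
dt <- diversityTable(tm)
attr(dt, "summary")$means[["He"]]      # mean gene diversity over 24 traits
bm <- encodeBinary(tm)
core <- coreSubset(bm, threshold = 0.98)
length(core$ids)                        # core accessions covering >= 98%
res <- amova(bm, nPermutations = 999, seed = 1)
res@phiST
```
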