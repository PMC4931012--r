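---
title: "Community-state typing of the developing infant gut microbiota and the fucosyllactose-utilization genotype screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-state typing and the FL-utilization genotype screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantgut)
```

## The scientific problem

During the first month of life the infant gut is colonized in a largely
ordered succession: facultative anaerobes (Staphylococcaceae,
Enterobacteriaceae) establish first and are displaced, at an
individual-specific pace, by Bifidobacteriaceae. Which bifidobacteria win
appears to hinge on a single genetic factor: a substrate-binding protein
(SBP) of a multiple-sugar ABC transporter that imports fucosyllactose (FL),
the most abundant class of human-milk oligosaccharides (HMOs). Strains
carrying the transporter grow robustly on HMOs, acidify the gut and deplete
residual oligosaccharides; strains without it do not, even when they encode
fucosidases, because intracellular fucosidases are useless without import.

`infantgut` implements the complete analysis chain for studying this
system from family-level 16S relative-abundance profiles and strain
genotype/phenotype panels:

1. **Community-state typing** — square-root Jensen–Shannon distances,
   partitioning around medoids (PAM), and cluster-number selection by
   Calinski–Harabasz (CH) voting over random subsamples.
2. **State dynamics** — mapping longitudinal samples to named states and
   counting directional transitions.
3. **Cluster characterization** — Mann–Whitney U tests with Bonferroni
   correction, compact letter displays, box-plot summaries.
4. **Association structure** — Spearman co-occurrence networks and
   taxa-by-environment correlation tables.
5. **Genotype–phenotype concordance** — growth-phenotype classification
   from OD600 curves and an exhaustive presence/absence screen of
   homologous gene groups against the phenotype.
6. **Synthetic data** — a generator that emulates the statistical structure
   all of the above assumes, so every stage is testable end to end.

The numbered scripts under `analysis/` run these stages in order and write
their tables under `results/`; all computation lives in the package
functions, which the test suite and `scripts/acceptance.R` call directly.

## Distances, PAM and the cluster-number vote

Profiles are compared with the square root of the Jensen–Shannon
divergence,

$$d(p, q) = \sqrt{H\!\left(\tfrac{p+q}{2}\right) - \tfrac{H(p) + H(q)}{2}},$$

with Shannon entropy $H$ in natural-log units, so $d \in [0, \sqrt{\ln 2}]$
and $d$ is a metric. Zero abundances contribute $0\ln 0 = 0$ exactly; no
pseudocounts are added, because the divergence is finite for zeros and
pseudocounts would silently perturb every distance.

`pam_cluster()` is a deterministic k-medoids: a greedy BUILD phase (each
added medoid maximizes the drop in total cost) followed by a SWAP phase
that repeatedly applies the best strictly cost-decreasing
medoid/non-medoid exchange. Ties break towards the lowest sample index, and
samples join their nearest medoid (ties to the lowest-index medoid), so the
only randomness in the whole typing procedure is the subsampling seed. PAM
is a local search: on unstructured point sets (uniform random points,
$n \le 8$) it reaches the global optimum found by exhaustive medoid
enumeration in roughly 90% of instances — indistinguishable from the
canonical reference implementation on the same instances — and essentially
always on data with genuine cluster structure. The tests assert, for every
instance, that the SWAP result is never worse than BUILD and never better
than the exhaustive optimum.

The CH index is computed directly from squared distances,
$W = \sum_c \frac{1}{2 n_c} \sum_{i,j \in c} d_{ij}^2$,
$B = \frac{1}{2n}\sum_{i,j} d_{ij}^2 - W$,
$\mathrm{CH} = \frac{B/(k-1)}{W/(n-k)}$, which equals the textbook
coordinate-based index whenever the distances are Euclidean (verified to
1e-9 in the tests) and avoids truncating an ordination.

`estimate_k()` draws, per trial, a uniform subsample without replacement,
runs PAM + CH for every candidate $k$, and records the argmax; the modal
argmax over trials is the optimal cluster number. Defaults: 1000 trials,
80% subsamples, $k \in 2..10$. The subsample fraction and candidate range
are deliberately explicit, logged parameters: they control the
stability-selection behaviour and have no single canonical value.

PCoA is classical metric scaling (double-centred $-\tfrac12 d^2$,
eigendecomposition, coordinates scaled by the square roots of positive
eigenvalues). Negative eigenvalues — expected, since sqrt-JSD is not
Euclidean — are reported but excluded from coordinates. Axis signs follow
a fixed convention (first nonzero loading positive) for reproducibility.
Heatmap sample ordering uses complete-linkage hierarchical clustering via
`stats::hclust()`.

## Cluster statistics

Between-cluster differences use the Mann–Whitney U test, two-sided
throughout. The exact null distribution is used when $n_1 + n_2 \le 12$
and no value spans the two samples; otherwise the normal approximation with
tie and continuity correction applies (both through `stats::wilcox.test()`,
cross-checked in the tests against a full enumeration oracle). The
Bonferroni family is the set of cluster pairs within one variable (three
pairs for three clusters); this choice is configurable and echoed in the
output, since a per-figure-panel correction is the convention the letter
displays imply. Letters come from the insert-and-absorb construction and
are verified post hoc: two groups share a letter exactly when their
adjusted comparison is non-significant. Box summaries use type-7 quartiles
and 1.5 IQR whiskers.

## Dynamics and association structure

`assign_states()` names each PAM cluster by the family with the highest
mean abundance among its members (an explicit map is required if two
clusters share a top family, and a per-sample dominance rule is available
as an alternative). `transition_counts()` counts transitions between
*consecutive observed* samples within a subject — gaps from missed days are
bridged and their lengths logged, because longitudinal stool series always
have missing days. No run-length smoothing is applied by default.
`directionality()` reduces the off-diagonal counts to a forward fraction
under the S < E < B adaptation order.

Spearman correlations use average ranks for ties and the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ for two-sided p-values; the approximation
is flagged for $n < 10$ and agrees with an exact permutation oracle within
0.12 in the tests. Network edges require $|\rho| > 0.3$ **and** $p < 0.05$,
both strict, between variables that pass the 1% mean-abundance filter
(strict, computed within the chosen sample subset; environment variables
join the network but never the abundance filter). Raw p-values are used for
edges, with an optional Bonferroni switch. No compositionality-aware
estimator is attempted: Spearman correlations on closed compositions carry
a negative bias (closure), which the documentation and tests acknowledge
— under row closure even independently generated taxa are weakly
negatively correlated.

## The genotype–phenotype screen

Growth phenotypes come from OD600 curves: replicates are averaged
pointwise, the curve is median-smoothed (window 3, guarding against
single-well spikes), and the saturating OD is the smoothed maximum. Strains
above 0.7 are growers, below 0.3 non-growers, the band between is
indeterminate and excluded from the screen (the packaged reference panel
contains none).

`concordance_screen()` scans every homologous group's presence/absence
column against the binary phenotype, in both orientations by default
(a discriminating *absence* would be just as reportable), returning all
groups within `max_exceptions` mismatches, ranked by exception count then
group id. This systematic scan subsumes a candidate-driven search and is
verified against a brute-force oracle. On the packaged 29-strain panel the
transporter-SBP column is the unique presence-positive hit at one allowed
exception: 28/29 strains concordant, the exception being a *B. bifidum*
strain that grows without the transporter because it carries extracellular
membrane-bound fucosidases.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the analysis assumes:

* **Regimes.** Three composition regimes, each a Dirichlet over 10
  families with the regime's dominant family at concentration 24 against 1
  for the rest (dominant mean ≈ 0.73). Drawn compositions are resampled
  through a multinomial at depth 2000 reads, mimicking amplicon sampling
  noise at a realistic per-sample read count.
* **Dynamics.** A daily Markov chain over S → E → B with forward rate
  0.15/day, backward 0.01/day; under these defaults most subjects reach
  B dominance within the month and reversals are rare.
* **Schedule.** 12 subjects, sampled daily for week one and every other
  day to day 29 (18 samples each; 216 total), matching a
  daily-then-alternate-day neonatal sampling design.
* **Environment.** Acetate $= 15 + 60\,b + \mathcal N(0,8)$ mM, pH
  $= 6.8 - 1.8\,b + \mathcal N(0,0.25)$, residual oligosaccharide
  $= 20\,(1 - 0.9\,\mathrm{flu}\,b) + \mathcal N(0,2)$ mM, where $b$ is
  Bifidobacteriaceae abundance and `flu` flags subjects colonized by
  FL-utilizing bifidobacteria (probability 0.6, giving roughly the 11:7
  B1:B2 split of the motivating cohort). Linear-Gaussian couplings with
  truncation at zero are the simplest monotone stand-in for the observed
  monotone associations; they are not mechanistic. Note acetate couples to
  Bifidobacteriaceae abundance, not to the `flu` flag, so B1 and B2 differ
  through residual oligosaccharide (and composition), not acetate — a
  deliberate minimal model.
* **Strain panels.** `generate_strain_panel()` plants one discriminating
  group (phenotype column with a configurable number of flipped exception
  strains, default one absent-but-grower) among i.i.d. Bernoulli(0.5)
  background groups, with logistic growth curves whose carrying capacities
  (0.9 / 0.15) sit safely beyond the 0.7/0.3 thresholds.

What passing tests on this generator show — and what they do not: recovery
of planted structure (the 3-regime vote, forward-biased succession,
coupling signs, the planted gene group) demonstrates the pipeline's
correctness, not that real infant microbiota satisfy the generator's
assumptions. Real profiles have heavier tails than Dirichlet-multinomial,
taxa are compositionally coupled beyond one dominant family, metabolite
couplings are nonlinear, and ortholog-group backgrounds are phylogenetically
correlated rather than i.i.d.

## Numerical choices and degenerate inputs

* All-zero abundance rows are rejected (no composition to speak of);
  duplicate sample/taxon ids are rejected; inputs in counts or percentages
  are renormalized to fractions, preserving within-row ratios exactly.
* The prevalence filter is strictly greater-than and never renormalizes the
  retained columns: it selects variables for networks/heatmaps, it does not
  redefine compositions. Whether to filter within infants, adults, or
  pooled samples is the caller's choice via the `samples` argument.
* CH is undefined at $k = 1$ and $k = n$ (rejected), and returns `Inf`
  when the within-cluster dispersion is exactly zero.
* Voting ties (equal vote counts, or equal CH within a trial) resolve to
  the smallest $k$.
* PCoA treats an eigenvalue as positive only above a tolerance scaled to
  the input ($\max d^2 \cdot n \cdot \varepsilon$), so an all-zero distance
  matrix yields zero retained axes rather than noise.
* Spearman correlations with a constant margin are flagged undefined and
  are never edge-eligible; heatmap cells with fewer than 3 complete pairs
  are marked untestable rather than dropped.
* With cross-group ties an exact Mann–Whitney request falls back to the
  corrected normal approximation with a warning (exact conditional
  enumeration under ties is out of scope).
* Missing environment values are `NA`, never 0 — zero is a valid
  concentration.

## Problem sizes

The shipped analyses and tests run at deliberately moderate sizes: the
simulated cohort is the study's own scale (216 samples), the voting uses
1000 trials in the analysis scripts and acceptance run and 20–100 trials in
the seeded repetition tests, property tests use hundreds of small random
instances (exhaustive oracles cap at $n \le 8$ for PAM and $n_1+n_2\le10$
for the exact Mann–Whitney enumeration), and the panel screen uses the full
29 × 2000 default. These sizes give stable statistical behaviour for the
planted-recovery assertions while keeping a complete run in the order of a
minute.

## Known limitations

* The 28/29-style concordance logic treats the phenotype as binary;
  intermediate growers are excluded, not modelled.
* Spearman networks inherit all compositional-data caveats; treat edge
  signs between taxa as descriptive, not causal.
* The subsampling fraction and k-range of the voting procedure are study
  parameters without canonical values; conclusions about the cluster
  number should be read jointly with the vote histogram, which is always
  reported.
* PAM finds local optima by design; with the deterministic tie-breaking
  used here, results are exactly reproducible but not guaranteed globally
  optimal.
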