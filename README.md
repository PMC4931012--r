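# infantgut

Community-state typing of the developing infant gut microbiota, and a
pan-genome screen for the genetic factor behind fucosyllactose utilization
in infant bifidobacteria.

## What this package is for

In the first month of life the infant gut microbiota typically passes
through three community states — Staphylococcaceae-, Enterobacteriaceae-
and Bifidobacteriaceae-dominated — with transitions running almost
exclusively "forward" towards Bifidobacteriaceae. Which bifidobacteria take
over, and what that does to the gut environment (acetate, pH, residual
milk oligosaccharides), depends on whether the colonizing strains can
import fucosyllactose (FL), the major human-milk oligosaccharide class.
Across a panel of bifidobacterial isolates, the presence of one homologous
gene group — the substrate-binding protein (SBP) of a multiple-sugar ABC
transporter — separates strains that grow on milk oligosaccharides from
strains that do not, with a single exception strain that digests FL
extracellularly instead.

`infantgut` provides the full analysis chain for this kind of study, for
microbiome researchers working from family-level relative-abundance tables
and strain genotype/phenotype panels:

* **Distances and clustering.** Square-root Jensen–Shannon distance
  (`jsd_matrix()`), deterministic PAM k-medoids (`pam_cluster()`), and the
  Calinski–Harabasz index computed directly on distances (`ch_index()`),
  CH = [B/(k−1)] / [W/(n−k)] with W, B from squared pairwise distances.
* **Cluster-number voting.** `estimate_k()` repeats PAM + CH on random
  subsamples (default 1000 trials, 80% subsamples, k = 2..10) and takes the
  modal argmax.
* **Ordination and heatmap ordering.** `pcoa()`, `hclust_complete()`.
* **Longitudinal dynamics.** `assign_states()`, `transition_counts()`,
  `directionality()`.
* **Cluster statistics.** `mann_whitney_u()`, `bonferroni()`,
  `compare_clusters()` with compact letter displays (`letter_display()`),
  `box_summary()`.
* **Association structure.** `spearman_cor()`, thresholded co-occurrence
  networks (`build_network()`, edges need |rho| > 0.3 and p < 0.05),
  taxa-by-environment tables (`correlation_heatmap_table()`), GraphML/TSV
  export.
* **Genotype–phenotype screen.** `classify_growth()` (grower above
  saturating OD600 0.7, non-grower below 0.3), OrthoMCL-style groups-file
  parsing (`read_ortholog_groups()`), and the exhaustive concordance screen
  (`concordance_screen()`); `table1_panel()` ships the 29-strain reference
  panel.
* **Synthetic data.** `generate_cohort()` / `generate_strain_panel()`
  produce cohorts and strain panels with planted, recoverable structure.

The `analysis/` directory holds the numbered workflow
(`01_simulate_cohort.R` … `06_genotype_screen.R`); each script is a thin
driver over the package functions and writes its tables under `results/`.

## Worked example

```r
library(infantgut)

# a synthetic cohort at the study's scale: 12 subjects, 18 samples each
coh <- generate_cohort(cohort_config(), seed = 1)
d <- jsd_matrix(coh$table)

vote <- estimate_k(d, k_range = 2:10, trials = 1000,
                   subsample_fraction = 0.8, seed = 2)
vote
#> CH voting over 1000 trials (subsample 172 of fraction 0.80): optimal k = 3
#>    2    3    4    5    6    7    8    9   10
#>   10  990    0    0    0    0    0    0    0

sol <- pam_cluster(d, vote$optimal_k)
series <- assign_states(coh$table, coh$meta, sol)
trans <- transition_counts(series)
directionality(trans, order = c("Staphylococcaceae", "Enterobacteriaceae",
                                "Bifidobacteriaceae"))$forward_fraction
#> [1] 1
```

The vote histogram concentrates on k = 3 — the three community states —
and every observed state change runs forward along the
S → E → B succession for this seed.

The genotype screen on the packaged 29-strain panel:

```r
panel <- table1_panel()
concordance_screen(panel$presence, panel$phenotype, max_exceptions = 1,
                   orientations = "presence_positive")
#> concordance screen over 29 strains (<= 1 exceptions): 1 hit(s)
#>   group_id            orientation n_match n_exceptions
#> 1      SBP presence_with_positive      28            1
#>                  exceptions constant
#> 1 BI-14 (absent_but_grower)    FALSE
```

Of the 29 strains, 14 are growers and 15 non-growers; 6 of the non-growers
carry a fucosidase gene (GH29 or GH95) yet fail to grow, and only the
ABC-transporter SBP column matches the phenotype — 28 of 29 strains, the
lone exception being the *B. bifidum* strain with extracellular
fucosidases.

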