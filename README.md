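# coabund

Weighted co-abundance network analysis for multiplexed longitudinal
proteomics, with a ground-truth simulator for end-to-end validation.

`coabund` is aimed at proteomics analysts working with isobaric-label (TMT)
experiments that span several plexes and timepoints — for example a
disease-course study in which control and transgenic mouse cortex is sampled
at pre-onset, onset, early disease, late disease and recovery, five animals
per group, spread over five TMT10 plexes with a pooled reference in channel
131 of every plex.  The package covers the full computational chain such a
study needs:

* **Quantitation** — per-plex ratios to the pooled reference channel,
  merging plexes over the protein union, explicit missingness, and log2
  transformation.
* **Differential abundance** — per-protein two-sample Student *t* tests on
  log2 ratios with the joint gate *FC > 1.20 (or < 1/1.20) and p < 0.05*,
  geometric-mean fold changes, per-protein one-way ANOVA across all groups,
  exclusive set intersections (Venn/UpSet cells), and sample-level PCA.
* **Co-abundance networks** — signed soft-thresholded adjacency
  a<sub>ij</sub> = ((1 + cor<sub>ij</sub>)/2)<sup>β</sup> with β chosen by
  the scale-free topology criterion (signed R² ≥ 0.85), the topological
  overlap measure

  TOM<sub>ij</sub> = (ℓ<sub>ij</sub> + a<sub>ij</sub>) / (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>),  ℓ<sub>ij</sub> = Σ<sub>u≠i,j</sub> a<sub>iu</sub> a<sub>uj</sub>,

  average-linkage clustering of 1 − TOM, a dynamic hybrid tree cut
  (minimum module size 20, unassigned proteins labelled `grey`), module
  eigenproteins (first right-singular vector of the standardized member
  matrix), kME module membership, hub ranking and module temporal profiles.
* **Enrichment** — marker-set enrichment per module with the enrichment
  ratio x·N/(m·K) and a two-sided Fisher exact test against an explicit
  background, plus generic hypergeometric over-representation of GMT
  collections with Benjamini–Hochberg adjustment.
* **Cross-dataset concordance** — case-insensitive gene-symbol
  harmonization, alteration-set intersections, direction-of-change
  concordance, and cluster-to-cluster association between two independent
  module maps (two-sided Fisher, Holm correction, flags at adjusted
  p < 0.001).
* **Simulation** — a latent-factor generator that plants co-abundance
  modules with genotype x timepoint profile templates into a multi-plex
  design, with plex batch offsets, protein-by-plex dropout and log-normal
  noise, emitting the ground truth every downstream stage is validated
  against.

Everything is tibble-first: functions take data frames or the
`abundance_matrix` container and return tibbles, `tidy()`/`glance()`
methods cover the fitted objects, and `autoplot()`/`plot_*()` give
ggplot2 diagnostics.

## Worked example

```r
library(coabund)

cfg <- default_synth_config(seed = 42)       # 2000 proteins, 6 planted modules,
sim <- simulate_dataset(cfg)                 # 45 samples across 5 TMT10 plexes

ratios <- purrr::imap(sim$plexes,
                      ~ reference_ratios(.x, cfg$design$reference_channels[[.y]]))
mat <- merge_plexes(ratios, cfg$design) |>
  filter_missing(0) |>
  log_transform()
mat
#> <abundance_matrix> 2000 proteins x 45 samples [log2_ratio], 0.0% missing

de <- pairwise_de(mat, default_comparisons(cfg$design)[["6wk"]]) |>
  classify_de()
#> classify_de [rNLS8_6wk_vs_control]: 227 up, 170 down of 2000 testable

fit <- wcna(mat)
fit
#> <wcna_fit> beta = 17; 533 of 2000 proteins in 6 modules (1467 grey)
#>   module     size
#> 1 turquoise   152
#> 2 blue        123
#> 3 brown       101
#> 4 yellow       78
#> 5 green        49
#> 6 red          30

head(hub_proteins(fit$kme, n = 3))
#>   protein_id module   kme own_module rank_own
#> 1 P00262     blue   0.951 blue              1
#> 2 P00196     blue   0.946 blue              2
#> 3 P00215     blue   0.937 blue              3
#> ...
```

The DE line says that at the late-disease timepoint 227 proteins pass the
joint up-gate (fold change > 1.20 at p < 0.05 versus pooled controls) and
170 pass the down-gate.  The network step recovers six modules whose sizes
match the planted 150/120/100/80/50/30 structure up to boundary proteins;
the remaining proteins are unassigned background (`grey`).  Hub proteins
are the members most correlated with their module's eigenprotein.

With ground truth in hand the whole chain can be scored in one call:

```r
simulate_and_validate(default_synth_config(1))
#>                 check      value threshold  pass
#> 1      de_sensitivity 0.54736842      0.90 FALSE
#> 2  de_false_call_rate 0.04708798      0.06  TRUE
#> 3 module_recovery_ari 1.00000000      0.80  TRUE
#> 4  kme_separation_min 0.87065380      0.00  TRUE
```

Note the failing sensitivity line is informative, not a bug: in the default
configuration module members share a latent factor, and that co-abundance
variance counts as biological variance in the per-protein *t* test, so
per-protein power at n = 5 vs 20 is genuinely about 0.55.  With independent
planted effects (`module_correlation = 0`, noise sd 0.2) sensitivity
exceeds 0.99 — that calibration is part of the acceptance checks below.

`run_pipeline(pipeline_config(...))` executes the same chain from TSV
inputs, writes every stage's tables to an output directory and returns a
hash manifest; runs are byte-identical for identical config and seed.
A thin command-line wrapper over these functions is installed at
`inst/cli/coabund.R` (subcommands `simulate`, `run`, `validate`).

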