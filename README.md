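# vesiclekit

Analysis of single-vesicle TIRF assays probing how α-synuclein acts on
synaptic-vesicle mimics. The package implements the two complementary
experiments end to end, plus a synthetic microscope with planted ground
truth so every stage is testable without raw imaging data:

* **Ca²⁺-triggered content-mixing fusion** — docked v-vesicles
  (synaptobrevin-2/synaptotagmin-1 proteoliposomes with self-quenched
  content dye) fuse with immobilized t-vesicles (syntaxin-1A/SNAP-25A);
  each fusion is a stepwise ~2× dequenching of one spot's intensity trace.
  The pipeline detects docked spots, excludes the few very large spots,
  extracts per-spot traces, detects dequenching steps, post-synchronizes
  events by the first event per field of view, builds the self-normalized
  1-s event histogram and cumulative distribution over the 50-s window,
  and fits the bi-exponential decay
  f(t) = y₀ + A₁·e^(−t/τ₁) + A₂·e^(−t/τ₂).
* **v-/v-vesicle clustering** — free-floating DiI-labeled v-vesicles dock
  onto a saturated DiD-labeled surface layer; clustering activity per
  condition (± α-synuclein, PD mutants A30P/E46K/A53T, truncations,
  lipid/protein controls) is the mean DiI spot count over 10–20 random
  imaging locations, compared across conditions with the pooled-variance
  Student's t-test. Spot intensities, normalized so the single-vesicle
  mode sits at 1 a.u., classify spots into singles (< 1.5 a.u.) and small
  clusters (≥ 2 a.u., up to ~6 a.u.).

Everything is tidyverse-shaped: spot tables, traces, events and
comparisons are tibbles; fitted objects support `tidy()`/`glance()`;
results plot with `autoplot()` and `plot_*()` helpers.

## Worked example

The fusion condition presets are the study conditions themselves: the
no-α-synuclein preset plants exactly 166 fusion events among ~2000 docked
vesicles with event times drawn from the published kinetics, at a fixed
seed.

```r
library(vesiclekit)

rep <- run_fusion_pipeline("fusion_noSyn", quiet = TRUE)
rep
#> <vk_fusion_report> preset fusion_noSyn, 1 FOV, seed 101
#>   docked (after exclusion): 1985, events: 166, fusion probability: 0.08363
#> <vk_biexp_fit> f(t) = -0.184 + 0.21 exp(-t/500) + 0.287 exp(-t/0.719)
#>   residual SS: 0.003007
```

The pipeline recovers every planted event: 166 events over 1985 docked
spots, a fusion probability of 0.084 (the published ratio is 166/~2000 ≈
0.083). The fast time constant (τ₂ ≈ 0.72 s) lands near the published
0.58 s; the slow component of a 166-event histogram is intrinsically
poorly determined (see the methods vignette), which is why the fit report
should always be read together with `glance()` and the event counts.

The clustering assay compares conditions directly:

```r
clus <- run_clustering_pipeline(
  list("cluster_noSyn", "cluster_WT_20uM", "cluster_A30P"),
  n_locations = 10, seed = 1, quiet = TRUE)
clus
#> <vk_clustering_report> 3 condition(s), 10 locations each, seed 1
#>   condition       n_locations  mean    sd
#> 1 cluster_noSyn            10   54   7.35
#> 2 cluster_WT_20uM          10  296. 17.3
#> 3 cluster_A30P             10  153. 13.2
#>   condition_a     condition_b       t    df        p stars
#> 1 cluster_WT_20uM cluster_noSyn  40.7    18 3.61e-19 ***
#> 2 cluster_A30P    cluster_noSyn  20.7    18 5.34e-14 ***
```

Wildtype α-synuclein at 20 µM raises clustering ~5.5-fold over the
no-protein background (p < 0.001), and the lipid-binding-deficient A30P
mutant shows the ~50% reduction relative to wildtype
(100 × (1 − 153/296) ≈ 48%). `plot_condition_counts(clus)` draws the
bar-and-stars figure; `autoplot(rep$histogram, fit = rep$fit)` draws the
event histogram with its fit.

A thin CLI over the same functions is installed at
`inst/scripts/vesiclekit` (subcommands `generate`, `fusion`, `cluster`,
`report`; YAML configs via `read_run_config()`).

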