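# sedapipe

Authentication and taxonomic profiling of sedimentary ancient DNA
(sedaDNA) from deep marine cores, as a tested, reusable R pipeline.

Trace amounts of degraded DNA preserved in sediment can reconstruct
whole past ecosystems — but only after the signal is authenticated
against contamination from drilling, laboratory work and modern
organisms. `sedapipe` implements the full authentication and profiling
chain used for deep-core shotgun sedaDNA, plus a ground-truthed
synthetic sediment-core generator so every stage is testable without any
external sequencing data. It is aimed at palaeogenomicists and method
developers who want an auditable, end-to-end implementation of this
workflow whose every threshold is a named, tested parameter.

The stages:

1. **Read QC** — remove reads < 25 bp, low-complexity reads
   (distinct-k-mer fraction < 0.55, k = 4) and exact per-library
   duplicates, with a conserving per-library count report.
2. **Alignment & LCA assignment** — k-mer-seeded *semiglobal* alignment
   (read global, reference local; +1/−1, gap −2) against merged SSU/LSU
   marker references indexed on both strands; hits filtered at ≥ 95%
   identity within a 10% score window; naive lowest-common-ancestor
   assignment with the ancestor-drop rule; rank projection with
   explicit unclassified buckets.
3. **Control subtraction** — taxa observed in extraction-blank, air or
   drill-fluid control libraries are removed from same-site samples
   (whole-taxon default, count-subtraction mode available).
4. **Damage authentication** — positional substitution spectra
   `f5[i] = P(C→T at 5′ position i)` fitted to the geometric decay model
   `f[i] = d·rⁱ + ε`; reads classified *ancient* (≥ 1 terminal C→T/G→A
   within 5 bp of an end) vs *default*; per-sample/taxon damage
   proportions with a 50-read low-confidence flag.
5. **Tracer QC** — drill-fluid tracer runs blank-corrected by the run's
   mean blank, detection limit 3×SD(blanks) with the lowest-standard
   fallback, stereoisomer calibration (×0.88), per-sample
   clean / periphery / centre verdicts.
6. **Statistics** — relative abundances (marker profiles are not
   rarefied), 1%-mean rare-taxon grouping, exact hypergeometric
   rarefaction with data-driven depth, pairwise Pearson correlations and
   between-table regressions.

The synthetic generator emulates a dated 12-sample core whose diatom
fraction steps from 0.08 to 0.50 at a 14.5 ka boundary, with damage
amplitude rising from 0.03 near the surface to 0.33 at depth
(`d5(age)`, decay ratio r = 0.5, background ε = 0.005), lognormal
fragment lengths (mode 56 bp), undamaged fungal contaminants shared
between samples and controls, tracer runs with injected contamination
classes, and geochemistry with configured correlations against the
damage driver. Every read carries a truth record.

## Worked example

```r
library(sedapipe)

cfg <- pipeline_config(simulation_config(seed = 11, library_size = 800))
res <- run_pipeline(cfg)
res
#> <pipeline_result>
#>   reads simulated: 10700 | QC retained: 10670 | assigned: 10619
#>   damage fit: d = 0.101, r = 0.452, eps = 0.0018

head(res$diatom_table, 8)
#>   sample_id age_ka diatom_fraction
#> 1       S01    1.4      0.48627451
#> 2       S02    2.8      0.49868074
#> 3       S03    4.4      0.48620237
#> 4       S04    7.1      0.52242744
#> 5       S05    9.8      0.50200267
#> 6       S06   12.7      0.50065703
#> 7       S07   34.0      0.07076101
#> 8       S08   74.0      0.09587217
```

Post-subtraction diatom relative abundance sits around 50% in the six
samples younger than the 14.5 ka boundary and below 10% in the older
ones — the configured step change, recovered through QC, alignment, LCA
assignment and control subtraction. The core-wide damage fit `d = 0.101`
is the read-weighted average amplitude across samples whose configured
`d5` spans 0.031–0.324. Damage rises with age sample by sample:

```r
head(res$damage_by_sample[, c("sample_id", "n_ancient", "n_default", "proportion")], 4)
#>   sample_id n_ancient n_default proportion
#> 1       S01        23       742 0.03006536
#> 2       S02        24       734 0.03166227
#> 3       S03        30       731 0.03942181
#> 4       S04        30       728 0.03957784

head(res$correlations, 4)
#>                var1       var2         r  n
#> 1 damage_proportion     age_ka 0.9754348 12
#> 2 damage_proportion   ammonium 0.6652198 12
#> 3 damage_proportion alkalinity 0.3832452 12
#> 4 damage_proportion  phosphate 0.7091288 12
```

All four injected fungal contaminant taxa are flagged from the control
libraries and removed (`res$subtraction$contaminants`).

The numbered scripts under `analysis/` run the same stages as a
file-based workflow (`Rscript analysis/01_simulate_core.R`, then `02`
… `07`), writing each stage's tables under `results/`.

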