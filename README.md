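# proteoflux

Quantify changes in **protein turnover and abundance** from pulsed
heavy-lysine (SILAM / pulsed-SILAC) labeling experiments in live animals.

Feeding mice a ^13^C₆-lysine (K6) diet for a labeling window marks every
newly synthesized protein molecule; each lysine-containing tryptic peptide
appears as an ion pair spaced 6.02 Da ÷ charge apart, and its relative
incorporation `I = H / (H + L)` measures the fraction of molecules made
during the window. Under first-order turnover with degradation rate constant
`k` and precursor-pool heavy fraction `q`,

```
I(k) = q (1 − e^(−k t)),        A = s / k  (steady-state abundance)
```

so incorporation reads out degradation, label-free abundance reads out the
synthesis/degradation balance, and the two together resolve the *mechanism*
of any proteome change: net synthesis up/down, net degradation up/down, or
an uncoupled change in repair flux ("dynaplot" classification).

The package is written for proteomics analysts comparing disease and
control cohorts (and age series) downstream of spectral processing: it
consumes peptide-level evidence tables (native TSV or MaxQuant-dialect
`evidence.txt` / `proteinGroups.txt`) and implements

* pair quantification with the **double-count rule** (≥ 2 scans per pair),
* the **2-of-3-replicates-in-both-cohorts** rule and median
  peptide-to-protein aggregation,
* the nonredundant **greatest-difference fraction merge**,
* the **precursor-pool control** from two-lysine peptides
  (`q̂ = 2·HH / (2·HH + HL)`),
* **six-of-six completeness filtering** and mouse-by-mouse integration of
  label-free abundances,
* per-protein two-tailed t-tests, the **global average protein turnover
  (GAPT)** contrast, mechanism classification and the dynaplot figure,
* an **aging trend** analysis across ordered age cohorts, and
* a fully parameterized **forward simulator** with known kinetics
  (ground truth included in every bundle), plus an unlabeled-decoy
  benchmark of the false pair-detection rate.

## Worked example

A packaged scenario reproduces a uniform −6.1 % global turnover slowdown
across 1392 proteins (3 vs 3 mice, 6-day label, three detergent fractions,
10 % intensity CV):

```r
library(proteoflux)
cfg <- load_run_config(
  system.file("extdata", "scenario-slowdown.yaml", package = "proteoflux"))
bundle <- run_pipeline(cfg)
bundle$gapt
#> # A tibble: 1 × 5
#>   gapt_control gapt_disease percent_change p_value n_proteins
#>          <dbl>        <dbl>          <dbl>   <dbl>      <int>
#> 1        0.150        0.140          -6.79 0.00368       1392
```

The injected slowdown is recovered: mean incorporation falls from 0.150 to
0.140 (−6.8 %, unpaired two-sided t-test p = 0.0037 across per-protein
cohort means; the slight excess over −6.1 % is the selection bias of the
greatest-difference fraction merge, see the vignette). Per-protein results
carry both axes and the mechanism call:

```r
dplyr::select(bundle$results, protein_id, turnover_delta, turnover_p,
              abundance_log2_ratio, abundance_p, mechanism_class)[1:3, ]
#>   protein_id turnover_delta turnover_p abundance_log2_ratio abundance_p mechanism_class
#> 1 P00002          -0.0218     0.00512               0.102        0.429  repair_down
#> 2 P00003          -0.0185     0.0382               -0.0916       0.542  unchanged
#> 3 P00004          -0.00286    0.0469                0.0979       0.537  unchanged

table(bundle$results$mechanism_class)
#> degradation_down  repair_down  synthesis_down  synthesis_up  unchanged
#>                1          192               3             1        974

dynaplot(bundle$results)   # turnover change vs log2 abundance ratio
```

A pure turnover slowdown shows up, correctly, as `repair_down` calls at the
stringent 0.01 threshold with abundance untouched. Scenario files for a
+15.7 % speedup and a null experiment ship alongside, and
`aging_trend()` handles ordered age series. A thin command-line front end
(`inst/scripts/proteoflux`) exposes `simulate`, `validate`,
`quantify-turnover`, `integrate-abundance`, `compare`, `decoy` and `run`.

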