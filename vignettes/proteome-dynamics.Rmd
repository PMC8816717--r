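---
title: "Measuring proteome turnover and abundance dynamics with proteoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring proteome turnover and abundance dynamics with proteoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Feeding a mouse a diet in which lysine is replaced by its ^13^C~6~ isotopologue
(K6) labels every protein molecule synthesized during the feeding window.
Tryptic peptides containing lysine then appear in the mass spectrometer as
ion pairs separated by 6.02 Da divided by the charge state (`k6_mass_shift()`),
and the relative incorporation of a peptide,

$$I = \frac{H}{H + L},$$

is the fraction of its molecules made during the window. Under first-order
turnover with degradation rate constant $k$ (1/day) and a precursor pool whose
heavy fraction is $q$, the expected incorporation after $t$ days of feeding is

$$I(k) = q\,\bigl(1 - e^{-kt}\bigr),$$

which `expected_incorporation()` implements, together with the two-compartment
generalization for a pool that itself equilibrates with time constant $\tau$:

$$I(k) = q\left(1 - \frac{k\,e^{-t/\tau} - \tau^{-1} e^{-kt}}{k - \tau^{-1}}\right),$$

with the $k = 1/\tau$ degeneracy handled analytically. Steady-state abundance
is $A = s/k$ for synthesis rate $s$ (`steady_state_abundance()`); incorporation
therefore reads out degradation while label-free abundance reads out the
synthesis/degradation balance, and the two together resolve the mechanism of
any change.

The pipeline mirrors the reference experimental design end to end:

1. **Pair quantification with the double-count rule** — a heavy/light pair
   must be supported by at least two scans (`compute_incorporation()`,
   `min_observations = 2`). A single-scan rule admits spurious pairs in ~2%
   of proteins of a fully unlabeled sample; requiring two independent scans
   suppresses that rate to roughly its square
   (`run_decoy_benchmark()`).
2. **Protein aggregation and the replicate rule** — peptide incorporations
   are summarized per (protein, fraction, mouse) by the median and kept only
   when supported in at least 2 of 3 mice in *both* cohorts
   (`aggregate_to_protein()`).
3. **Nonredundant fraction merge** — a protein measured in several detergent
   fractions keeps the fraction with the greatest absolute cohort difference
   in mean incorporation (`merge_fractions()`).
4. **Precursor-pool control** — among newly made molecules of a two-lysine
   peptide each site is heavy independently with probability $q$, so the
   fully heavy and mixed species obey $HH : HL = q^2 : 2q(1-q)$ and
   $\hat q = 2\,HH / (2\,HH + HL)$ per peptide, independent of the unknown
   old-molecule fraction (`estimate_precursor_pool()`). A cohort difference
   in $\hat q$ would mean incorporation changes partly reflect precursor
   availability rather than turnover; cohort comparisons themselves use the
   uncorrected $H/(H+L)$, and $\hat q$ enters only the absolute-rate
   inversion `fit_rate_constant()`.
5. **Abundance integration** — label-free protein intensities are forwarded
   per fraction only when quantified in every mouse (six of six in the
   reference design) and then averaged across fractions mouse by mouse
   (`fraction_completeness_filter()`, `integrate_abundance()`).
6. **Cohort statistics and the dynaplot** — per-protein two-tailed
   t-tests on incorporation and on abundance, the global average protein
   turnover (GAPT) contrast, and classification of each protein into six
   mechanistic regimes (`compare_dynamics()`, `compute_gapt()`,
   `classify_mechanism()`, `dynaplot()`).

## The mechanistic regimes

With turnover change on one axis and abundance change on the other, six
scenarios arise. Writing $\uparrow/\downarrow$ for a significant change:

| turnover | abundance | class | meaning |
|---|---|---|---|
| $\uparrow$ | $\uparrow$ | `synthesis_up` | net synthesis rate increased |
| $\downarrow$ | $\downarrow$ | `synthesis_down` | net synthesis rate decreased |
| $\uparrow$ | $\downarrow$ | `degradation_up` | net degradation increased |
| $\downarrow$ | $\uparrow$ | `degradation_down` | net degradation decreased |
| $\uparrow$ | — | `repair_up` | repair flux increased (futile cycle) |
| $\downarrow$ | — | `repair_down` | repair flux decreased |

A significant abundance change without a significant turnover change is a
net-synthesis change inferred from one axis only and carries an `uncoupled`
flag. For simulated ground truth the same mapping is applied directly to the
rate ratios (`assign_mechanism_label()`), with a 5% multiplicative dead-band
around unity so that numerical noise is never labeled as mechanism.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `label_days` | 6 | days | K6 feeding window (8 for aged cohorts) |
| `precursor_plateau` | 1 | — | asymptotic heavy fraction of the free lysine pool |
| `precursor_rise_time` | 0 | days | pool equilibration time constant |
| `min_observations` | 2 | scans | double-count rule |
| `min_replicates` | 2 | mice | replicate rule, per cohort |
| `alpha_table` | 0.05 | — | per-axis significance for tables |
| `alpha_dynaplot` | 0.01 | — | mechanism classification threshold |
| `dead_band` | 0.05 | — | ground-truth ratio dead-band |
| `summary_statistic` | median | — | peptide-to-protein summary |
| `pooled_variance` | FALSE | — | pooled Student instead of Welch |

No multiple-testing correction is applied by default because the method
reports nominal per-protein p-values; `stats::p.adjust` can be applied to any
result column by the caller.

## What the simulator emulates

`simulate_ground_truth()` and `simulate_cohorts()` generate the full
experiment forward from known kinetics so that every stage has a recovery
oracle:

* **Rate distribution.** Control degradation rates are log-normal with
  `meanlog = log(0.022)`, `sdlog = 0.70` (median half-life ≈ 31 days). Over
  ~1400 proteins a 6-day label then spans incorporations of roughly 1.4–71%,
  the dynamic range observed in brain tissue, and gives a between-protein
  incorporation spread that reproduces the sensitivity of the global GAPT
  contrast at this cohort size.
* **Fractionation at the protein level.** Tissue is fractionated before
  digestion, so a protein partitions into 1–3 detergent fractions with
  log-normal loadings (half the proteins effectively live in one fraction)
  and *all* of its peptides appear in each fraction where it is present.
* **Peptides.** A Poisson number per protein with mean 10 — the ratio of
  quantified peptides to quantified proteins in the reference dataset — 80%
  with one lysine and 20% with a missed-cleavage second lysine; the
  two-lysine peptides carry the `LL`/`HL`/`HH` isotopologue triple that
  drives the pool estimator.
* **Intensities.** Exact isotopologue shares of the peptide's total
  intensity, perturbed by mean-one log-normal noise with CV 10%; a pair
  supported by $n$ scans is the sum of $n$ scans, so its relative noise
  shrinks by $\sqrt n$. In the noise-free limit every observed incorporation
  equals the kinetic expectation to machine precision, which is what makes
  exact recovery tests possible.
* **Perturbations.** Either a uniform incorporation scaling (the disease
  rate is obtained by inverting the labeling model, with synthesis
  co-adjusted so abundance is untouched — a pure global turnover effect), or
  a mix of the seven mechanism archetypes at a configurable fold change
  (default 2, chosen so each archetype is decisively outside the dead-band
  and resolvable at the 3-versus-3 design).
* **Decoys.** An unlabeled sample in which spurious heavy matches arise as
  independent single-scan events at `decoy_pair_rate`, so double-scan
  spurious pairs occur at the squared rate.

The simulator does **not** emulate chromatography, isotope envelopes,
peptide-level identification error, shared peptides between protein groups,
correlated mouse-level biology (cage, sex, genotype background), or
intensity-dependent missingness — dropout is uniform. Passing recovery tests
therefore demonstrates that the pipeline's statistics and filters are
correct under the stated generative model, not that any particular real
dataset satisfies that model.

## Numerical and design choices

* **Turnover tests use Welch's t-test by default.** The pooled-variance
  Student test ("strict replication" mode, `pooled_variance = TRUE`) is
  anti-conservative downstream of the greatest-difference fraction merge:
  selecting the most extreme of several noisy per-fraction contrasts
  inflates the selected contrast relative to its variance, and on null
  simulations the pooled test flags ~8% of proteins at the nominal 5% level
  while Welch's small-sample conservatism compensates almost exactly
  (measured 5–6%). This selection effect is intrinsic to the merge rule and
  worth knowing about when interpreting marginal p-values.
* **Abundance significance is tested on log2 intensities.** Intensity noise
  is multiplicative, so on the raw scale cohort variances scale with squared
  means; with three mice per cohort the resulting Welch degrees of freedom
  collapse toward 2 and even two-fold changes cannot reach the 0.01 dynaplot
  threshold. On the log scale the variances are comparable and the test is
  calibrated and powered. Deltas and ratios are still reported on the
  natural scales, and the plot's y-axis is the log2 ratio.
* **The GAPT contrast is an unpaired two-sided t-test across per-protein
  cohort means** (a paired option exists). Its sensitivity is limited by the
  between-protein spread of incorporation, not by measurement noise; at 1392
  proteins a uniform −6.1% scaling gives p ≈ 0.004.
* **Degenerate variance.** Exact simulations produce zero within-cohort
  variance; tests then return p = 1 for equal means and the smallest
  positive double for unequal means, flagged `degenerate`, instead of
  failing.
* **Merge tie-breaks** are: larger total peptide support, then lexicographic
  fraction identifier — so output is a deterministic function of the input
  set regardless of row order.
* **Saturated incorporation** (at or above the precursor pool estimate)
  cannot be inverted to a rate and returns `NA` with a warning rather than
  an infinite rate.
* **Aging trend.** The headline fraction uses the oldest-versus-youngest
  endpoint comparison per protein (matching how such series are reported),
  with a two-sided sign test for the trend p-value; least-squares slopes
  over age are reported alongside as the graded alternative.
* **Problem sizes.** The verification suite simulates 300–1400 proteins per
  run and 20 independent experiments for the global-effect check; these
  sizes make every recovery quantity stable to well inside its tolerance
  while keeping a full run in minutes on a laptop.

## Known limitations

* The one-pool inversion `fit_rate_constant()` assumes the precursor pool is
  at its plateau from day zero; with a slowly rising pool it underestimates
  rates. The forward model supports $\tau > 0$, so the bias can be
  quantified by simulation.
* Relative cohort contrasts are the design target; absolute half-lives
  are only as good as the one-pool model and the pool estimate.
* With three mice per cohort, per-protein power at the 0.01 dynaplot
  threshold is limited; regime counts should be read as a conservative
  lower bound on affected proteins.
* The decoy model treats spurious matches as independent across scans;
  correlated interference (e.g. a co-eluting contaminant) would make the
  double-count rate higher than the squared single-count rate.

## A minimal run

```{r, eval = FALSE}
library(proteoflux)

config <- load_run_config(
  system.file("extdata", "scenario-slowdown.yaml", package = "proteoflux"))
bundle <- run_pipeline(config, out_dir = "slowdown-run")

bundle$gapt                      # global turnover contrast
table(bundle$results$mechanism_class)
dynaplot(bundle$results)
```
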