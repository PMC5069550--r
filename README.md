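# silacturn

Quantifying how proteasome inhibition affects protein degradation and
synthesis from dynamic SILAC (stable isotope labeling with amino acids in
cell culture) mass-spectrometry experiments — for proteomics analysts working
with slowly dividing or postmitotic cells (e.g. neurons), where protein
half-lives span days and inhibitor effects on synthesis and degradation are
easily conflated.

## What it computes

Two labeling designs, one kinetic model:

* **Pulsed SILAC.** Heavy amino acids added in 5:1 excess at inhibitor
  addition; the per-protein H/L ratio after time *t* is converted to a
  corrected fractional incorporation and a single-point half-life:

  F_t = (1/F_max) · R/(R+1),  τ = −t / ln(1 − F_t),  t½ = ln 2 · τ,

  with F_max = 5/6. The apparent half-life fold change between treated and
  control is τ_treated/τ_control — *apparent*, because the estimate assumes
  synthesis balances degradation, which the inhibitor itself violates.

* **Multiplexed SILAC.** Heavy- and medium-pre-labeled populations (treated
  vs control) chased with light media, mixed, and measured together. The
  residual-pool ratio is selective for degradation; if inhibition slows a
  protein's degradation time constant by a factor α,

  log2(H/M) = t(α − 1) / (α · t½),

  which predicts expected ratios from known half-lives, yields a detection
  limit t½* = t(α − 1)/(α · threshold), and is compared against measured
  values by correlation.

Around the model: peptide-to-protein geometric-mean aggregation with a
2-peptide floor, label-swap orientation, normalization to seven designated
long-lived reference proteins, stringent completeness filters, t = 0
variability estimation with 3-SD effect thresholds, per-protein two-tailed
Welch tests and five-way classification, joint inference of synthesis
suppression, and a fully deterministic synthetic-data generator with known
ground truth for both designs.

## Worked example

Simulate a 600-protein cohort (10% proteasome substrates with α = 10, 10%
synthesis-suppressed with β = 0.2, 5 multiplexed replicates, 2 pulsed
replicates) and run all three pipelines:

```r
library(silacturn)

cfg <- sim_config(n_proteins = 600, seed = 42)
mux <- run_multiplexed_pipeline(cfg)
mux
#> <multiplexed_bundle> 551 proteins classified; t0 SD 0.0724; r(measured, expected) = 0.047 (n = 336)
tidy(mux$variability)
#> # A tibble: 1 × 5
#>   sd_log2_t0 n_proteins threshold_log2 ratio_lower ratio_upper
#>        <dbl>      <int>          <dbl>       <dbl>       <dbl>
#> 1     0.0724        551          0.217       0.860        1.16
mux$counts
#> # A tibble: 5 × 3
#>   class                       n    pct
#>   <chr>                   <int>  <dbl>
#> 1 slowed_significant_3sd     25  4.54
#> 2 slowed_significant          4  0.726
#> 3 trend                      18  3.27
#> 4 unaffected                494 89.7
#> 5 accelerated_significant    10  1.81

pul <- run_pulsed_pipeline(cfg)
pul
#> <pulsed_bundle> 551 proteins with fold changes (0 saturated excluded); median fold change 1.04

run_joint_inference(mux, pul)
#> <joint_bundle> 57 candidates with >3-SD H/L reduction; 3 degradation-affected (5%); 54 attributed to synthesis suppression
```

Reading the output: of 551 proteins surviving the completeness filter, the
t = 0 spread of 0.072 log2 units sets a 3-SD threshold of 0.217 (H/M ratios
outside 0.86–1.16 are beyond chance); 25 proteins are confidently slowed
(`slowed_significant_3sd`) — mostly the short-lived substrates, since
longer-lived substrates fall under the detection limit. The pulsed design
alone reports 57 proteins with apparently prolonged half-lives, but the
joint inference shows only 3 of them are actually degraded more slowly: the
other 54 are synthesis-suppressed, the central confound the package
quantifies.

Single estimates work the same way at any scale:

```r
estimate_half_life(1, t_h = 24)   # H/L = 1 after 24 h
#>     f_t tau_h half_life_h   t_h status
#> 1   0.6  26.2        18.2    24 ok
expected_log2_hm(24, 5 * 24, 10)  # 5-day protein, 10-fold inhibition
#> [1] 0.18
```

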