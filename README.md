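# mvarconn

Directed connectivity for multichannel electrophysiology: frequency-domain
Granger causality, the Directed Transfer Function (DTF) and Partial
Directed Coherence (PDC) from multivariate autoregressive (MVAR) models of
ongoing intracranial EEG, plus N1 z-score quantification of single-pulse
stimulation (SPES) evoked potentials, and the region-pair directionality
statistics that compare the two. A synthetic generator of region-structured
MVAR networks with known directed coupling makes every stage testable
without patient data.

The package is aimed at electrophysiologists and methods researchers who
work with depth-electrode (SEEG) recordings of small anatomical networks —
the motivating case is the human mesiotemporal network (amygdala,
hippocampus, temporal pole, parahippocampal cortex) — and want a
reproducible, ground-truth-validated pipeline from raw multichannel signal
to "which region drives which, in which frequency band".

## The model

An `n`-channel recording is modelled as an MVAR process of order `p`:

    x(t) = Σₖ A(k) x(t−k) + ε(t),   cov(ε) = C

with the frequency-domain objects (ω = 2πf/fs)

    Ā(ω) = I − Σₖ A(k) e^(−ikω),   H(ω) = Ā(ω)⁻¹,   S(ω) = H(ω) C H*(ω)

from which three directed metrics follow on a 1–40 Hz integer grid:

| metric | formula | reads as |
|---|---|---|
| Granger causality | `ln[S_tt / (S_tt − (C_ss − C_ts²/C_tt)\|H_ts\|²)]` | total predictive influence s→t |
| DTF² | `\|H_ts\|² / Σ_m \|H_tm\|²` | inflow into t from s, relative to all inflows (includes cascades) |
| PDC | `\|Ā_ts\| / √(a_s* a_s)` | direct coupling s→t, normalized per source |

Metrics are averaged over independent per-epoch model fits and aggregated
into the classical bands (delta 1–4, theta 5–8, alpha 9–12, beta 13–24,
low gamma 25–40 Hz). Directionality per region pair is tested by a
two-level ANOVA (forward vs reverse contact-pair values, Bonferroni
corrected) and a one-sample t-test on matrix asymmetries. The evoked arm
scores each channel's averaged CCEP as the maximum absolute amplitude in
the 10–110 ms post-stimulus window divided by the baseline SD.

## Worked example

Simulate a 4-region network with three seeded directed edges
(AMG→HPC, TP→HPC, TP→PHP), run the full pipeline, and test
directionality:

```r
library(mvarconn)

spec  <- region_spec(AMG = 2, HPC = 2, TP = 2, PHP = 2)
edges <- dplyr::bind_rows(
  coupling_edge("AMG", "HPC", 0.4, lag = 1),
  coupling_edge("TP",  "HPC", 0.4, lag = 1),
  coupling_edge("TP",  "PHP", 0.4, lag = 1))

gt  <- make_ground_truth_mvar(spec, edges, order = 2, seed = 1,
                              sampling_rate = 250)
rec <- simulate_mvar_recording(gt, duration = 600, seed = 2)
rec
#> <mc_recording> 8 channels x 150000 samples (600.0 s @ 250 Hz)
#>   regions: AMG(2) HPC(2) PHP(2) TP(2)

epochs <- preprocess_recording(rec, highpass = 0.5, target_rate = 250)
conn   <- epoch_connectivity(epochs, order = 8, metric = "pdc")
conn
#> <connectivity_result> PDC: 8 x 8 channels, 40 frequencies, 5 bands (avg of 60 epoch[s])
#>   values[source, target, ] quantifies source -> target

stats <- directionality_anova(pool_region_pairs(conn))
summarize_directionality(stats[stats$band == "beta", ])
#> AMG-HPC      beta       AMG → HPC  F(1,6) = 19097.56, p_corr = 2.9e-10 ***
#> AMG-PHP      beta       PHP → AMG  F(1,6) = 0.28, p_corr = 1
#> AMG-TP       beta       TP → AMG  F(1,6) = 0.48, p_corr = 1
#> HPC-PHP      beta       HPC → PHP  F(1,6) = 0.07, p_corr = 1
#> HPC-TP       beta       TP → HPC  F(1,6) = 16139.18, p_corr = 4.81e-10 ***
#> PHP-TP       beta       TP → PHP  F(1,6) = 40679.12, p_corr = 3.01e-11 ***
```

The three seeded edges are recovered in the correct direction with
Bonferroni-corrected significance (the family is all 6 pairs × 5 bands);
the three uncoupled pairs stay silent. `autoplot(conn)` draws the band
matrices (sources on y, targets on x), `tidy(stats)`-style tibbles come
out of every stage, and `soz_contrast()` compares runs with and without
seizure-onset-zone channels.

For the evoked arm:

```r
ss  <- spes_session_spec(c("STIM1", "STIM2"),
                         n1_amplitude_map = c(HPC1 = 10, HPC2 = 0, AMG1 = 0))
sim <- simulate_spes_session(ss, sampling_rate = 2000, seed = 5)
ccep_table(sim$recording, sim$events)
#> # A tibble: 3 × 7
#>   stim_pair   channel source_region target_region      z latency_s flat
#>   <chr>       <chr>   <chr>         <chr>          <dbl>     <dbl> <lgl>
#> 1 STIM1-STIM2 HPC1    STIM          HPC           10.2      0.0255 FALSE
#> 2 STIM1-STIM2 HPC2    STIM          HPC            0.353    0.064  FALSE
#> 3 STIM1-STIM2 AMG1    STIM          AMG            0.489    0.104  FALSE
```

A 10-σ deflection planted at 25 ms scores z ≈ 10 at the right latency;
unconnected channels stay near the noise floor, and the saturating
stimulation artifact (first 10 ms) never enters the score.

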