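---
title: "Directed connectivity from MVAR models and stimulation-evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity from MVAR models and stimulation-evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r load}
library(mvarconn)
```

## The problem

Depth-electrode (SEEG) recordings from the mesiotemporal network — amygdala
(AMG), hippocampus (HPC), temporal pole (TP), parahippocampal cortex (PHP) —
allow two complementary views of how these structures drive each other:

* **functional (directed) connectivity** from ongoing activity, estimated by
  fitting multivariate autoregressive (MVAR) models and reading direction
  out of their frequency-domain representation; and
* **effective connectivity** from single-pulse electrical stimulation
  (SPES), quantified as the N1 component of averaged cortico-cortical
  evoked potentials (CCEPs).

`mvarconn` implements both arms, the preprocessing chain that feeds the
first, the region-pair directionality statistics applied to both, and a
synthetic generator of networks with known directed coupling so that every
stage can be validated against ground truth.

## Model and metrics

An `n`-channel recording is modelled as an MVAR process of order `p`,

$$x(t) = \sum_{k=1}^{p} A(k)\, x(t-k) + \varepsilon(t),
  \qquad \operatorname{cov}(\varepsilon) = C,$$

with lag-coefficient matrices `A(k)` (rows index the target channel) and
white innovations. In the frequency domain, with
$\omega = 2\pi f / f_s$,

$$\bar A(\omega) = I - \sum_k A(k) e^{-ik\omega}, \qquad
  H(\omega) = \bar A(\omega)^{-1}, \qquad
  S(\omega) = H(\omega)\, C\, H^*(\omega),$$

computed by `evaluate_spectral()` on an integer grid of 1–40 Hz (the
transfer matrix by linear solve, not explicit inversion). Three directed
metrics derive from these objects:

* **Granger causality** (`granger_spectral()`): the pairwise Geweke
  measure evaluated from the full model,
  $f_{s \to t}(\omega) = \ln \left[ S_{tt} / (S_{tt} - (C_{ss} -
  C_{ts}^2 / C_{tt})\, |H_{ts}|^2) \right]$, clipped at zero against
  round-off. The measure is *pairwise-from-full-model*: no per-pair
  refitting is done. This follows the parametric toolbox lineage; it means
  that influence reaching the target through intermediate channels also
  counts (see the discussion of cascades below).
* **Directed Transfer Function** (`dtf()`), reported squared:
  $\mathrm{DTF}^2_{s \to t} = |H_{ts}|^2 / \sum_m |H_{tm}|^2$ — inflow into
  the target normalized by all its inflows; values in $[0,1]$, target-wise
  sums equal 1.
* **Partial Directed Coherence** (`pdc()`), reported as magnitude:
  $\mathrm{PDC}_{s \to t} = |\bar A_{ts}| / \sqrt{a_s^* a_s}$ with $a_s$
  the source column of $\bar A$; source-wise squared sums equal 1. PDC sees
  only *direct* coefficients, not cascades.

All result cubes are stored `[source, target, frequency]`; plotting
transposes so targets run along x. Band aggregation
(`band_aggregate()`) is the arithmetic mean over the inclusive integer
band edges: delta 1–4, theta 5–8, alpha 9–12, beta 13–24, low gamma
25–40 Hz.

## Preprocessing chain

`preprocess_recording()` chains the conditioning steps for ongoing
activity:

1. zero-phase high-pass at 0.5 Hz (`filter_highpass()`), removing DC and
   drift. The filter is a 4th-order Butterworth applied forward–backward
   as second-order sections. Sections matter: at 0.5 Hz on 2000 Hz data
   the normalized cutoff is 5·10⁻⁴, where a single expanded polynomial
   loses the passband to round-off (we measured a 57 % amplitude error
   with a transfer-function design; the SOS cascade is exact to
   double precision).
2. anti-aliased downsampling to 250 Hz (`downsample()`): zero-phase
   8th-order Butterworth at 0.8 × the new Nyquist, then integer
   subsampling. 250 Hz keeps the 1–40 Hz analysis band far from the new
   Nyquist while allowing reasonable model orders.
3. division into 10 s epochs (`make_epochs()`), trailing remainder
   dropped.
4. epoch selection (`select_epochs()`): visual artifact screening is
   replaced by a reproducible surrogate — an epoch is rejected when any
   channel's peak amplitude exceeds a robust z of 6 across epochs, or when
   a channel is flat (variance < 1e-12). Both thresholds are arguments.
5. optional seizure-onset-zone (SOZ) exclusion (`exclude_channels()`),
   which shrinks every downstream matrix and warns when a region loses
   all its contacts.

Models are then fitted **independently per epoch** and the metric cubes
averaged (`epoch_connectivity()`), which tolerates slow nonstationarity;
`fit_mvar()` also supports pooling all epochs into one model (used by
order selection). Per-epoch means are removed; lagged regressors never
cross epoch boundaries. `select_order()` evaluates Schwarz's Bayesian
Criterion $\ln\det C(p) + (\ln N / N)\, p\, n^2$ over an inclusive range
(default 8–40), scoring *all candidate orders on the identical sample* —
the regression starts `max_order` samples into each epoch — so criterion
differences reflect the model alone; `N` is that common residual count.
Ties break toward the smaller order.

## The evoked arm

`extract_trials()` cuts −1 s / +2 s windows around each stimulus onset,
excluding the stimulated pair and its immediate shaft neighbors.
`baseline_average()` subtracts each trial's baseline mean (window −1 to
−0.01 s; the last 10 ms are a guard against pre-trigger artifact) and
averages. `n1_zscore()` scores each channel as

$$z = \max_{t \in [10, 110)\,\mathrm{ms}} |\bar x(t)| \; / \; \hat\sigma_{\mathrm{baseline}},$$

starting 10 ms after the stimulus so the stimulation artifact is excluded
by construction, with the absolute value because N1 polarity depends on
the referential montage. Two conventions exist for
$\hat\sigma_{\mathrm{baseline}}$: the SD of the *averaged* waveform's
baseline (which scales like $\sigma/\sqrt{T}$ for $T$ trials) and the
pooled SD of *single-trial* baselines. We use the single-trial convention:
$z$ then measures the response against the ongoing-activity noise floor,
is directly interpretable as a signal-to-noise ratio in trial units
(a 10-σ deflection scores $z \approx 10$ at any trial count), and is
comparable across sessions with different trial counts. Under this
convention adding trials *tightens* $z$ around amplitude/σ rather than
growing it; detection reliability, not the score itself, is what improves
with trial count.

## Directionality statistics

For every unordered region pair, `pool_region_pairs()` collects one value
per ordered contact pair per direction (within-region elements and the
diagonal are excluded; 4 regions give 6 pair groups).
`directionality_anova()` runs, per pair and band, a one-way two-level
ANOVA of forward against reverse values — algebraically the square of the
pooled two-sample t test, giving F with $(1, n_f + n_r - 2)$ degrees of
freedom — with Bonferroni correction over the whole tested family (all
pairs × all five bands by default; the family size is an argument). The
element-wise asymmetries $M_{ij} - M_{ji}$ are additionally tested
against zero mean by a one-sample t test (`ttest_zero_mean()`).
`soz_contrast()` compares two such tables (with and without SOZ channels)
and flags favored-direction flips and significance changes.

## The synthetic generator and its design constraints

`make_ground_truth_mvar()` assembles a stable MVAR network: each contact
carries a damped AR(2) oscillator, and each declared `coupling_edge()`
writes lag coefficients from all source-region contacts onto all
target-region contacts (total inflow per target contact equals the edge
strength). Undeclared cross-region blocks are exactly zero, so the ground
truth of every directed question is known. If the assembled model is
unstable, all lag matrices are shrunk by 0.95 (at most 50 times) —
note that purely feed-forward coupling of any size is stable (the
companion spectrum is block-triangular); only feedback loops can require
shrinkage or fail it. `simulate_mvar_recording()` draws Gaussian
innovations and discards a burn-in of `10 · order · n_channels` samples.
Oscillators are parameterized by pole *frequency* (Hz) and *bandwidth*
(Hz; pole radius $e^{-\pi \cdot \mathrm{bw} / f_s}$), so spectra are
invariant to the simulation rate.

Three defaults deserve explanation, because they were forced by an
analysis of when the directionality statistics can work at all:

* **One common oscillator profile for all contacts** (`osc_mode =
  "common"`, a network-wide background rhythm with independent
  per-contact innovations). The contact-pair ANOVA treats the 4 forward
  and 4 reverse values of a pair group as exchangeable observations.
  Every directed metric has a finite-sample noise floor whose size
  depends on the source and target spectra; if regions have *different*
  characteristic spectra, the floors differ systematically between the
  two directions while the within-group variance stays tiny (all
  contact pairs share the region profiles), and the F statistic diverges
  on truly uncoupled pairs as data accumulate. We measured null-pair F
  values in the hundreds with per-region rhythms. With one shared
  profile the floors are direction-exchangeable and the test calibrates.
  The `per_region` and `per_contact` modes remain available precisely to
  demonstrate this failure mode.
* **A theta rhythm (4–8 Hz)** rather than a draw across the whole EEG
  range. PDC normalizes outflows by the source column of $\bar A$, which
  includes the source's true outgoing coefficients; a connected source
  therefore has a *smaller* outflow noise floor than a pure sink, and
  the distortion is largest where $|\bar a_{ss}(\omega)|$ dips — i.e. in
  the band containing the resonance. Placing the background rhythm below
  the beta/low-gamma test bands keeps those bands calibrated. A
  pervasive theta rhythm is also the physiologically natural choice for
  the mesiotemporal network.
* **Validation at the analysis rate (250 Hz).** Subsampling a
  white-noise-driven VAR yields a VARMA process that no finite VAR
  represents; the truncation error appears as *systematic,
  direction-asymmetric* spurious coefficients, so the decimation stage
  destroys null calibration for every metric (we measured null-pair F in
  the thousands through a 2000 → 250 Hz chain, with zero-phase and with
  causal anti-alias filters alike — consistent with the known
  non-identifiability of Granger structure under subsampling). The
  validation studies therefore define the ground truth at 250 Hz and run
  the full chain without rate conversion, while the 2000 → 250 Hz chain
  is exercised by a direction-*ordering* test, which survives decimation.

What passing these studies does and does not show: the pipeline recovers
directed structure, controls false positives, and scores evoked responses
correctly **under the stated conditions** — stationary Gaussian dynamics,
spectrally homogeneous contacts, couplings representable at the analysis
rate. Real iEEG offers none of these guarantees: contacts are spectrally
heterogeneous (which makes the contact-pair ANOVA anticonservative on
uncoupled pairs — a dyadic-pseudoreplication effect), spectra are 1/f
with epileptiform transients, and the recorded process is not a
finite-order VAR. The synthetic generator deliberately does not emulate
epileptiform morphology, volume conduction, or 1/f-matched spectra.

`simulate_spes_session()` generates the evoked arm's ground truth: 40
biphasic pulses at 4 s ± 10 % jitter, a saturating artifact in the first
10 ms after each pulse on all channels (so artifact exclusion is
exercised), and a negative Gaussian N1-like deflection of mapped
amplitude at a controllable latency on connected channels, over white
noise. Amplitudes are in arbitrary units relative to the noise SD; the
amplitude distribution of real interictal iEEG is not modelled.

## A worked example

```{r example}
spec <- region_spec(AMG = 2, HPC = 2, TP = 2, PHP = 2)
edges <- dplyr::bind_rows(
  coupling_edge("AMG", "HPC", 0.4, lag = 1),
  coupling_edge("TP",  "HPC", 0.4, lag = 1),
  coupling_edge("TP",  "PHP", 0.4, lag = 1)
)
gt <- make_ground_truth_mvar(spec, edges, order = 2, seed = 1,
                             sampling_rate = 250)
rec <- simulate_mvar_recording(gt, duration = 600, seed = 2)
epochs <- preprocess_recording(rec, highpass = 0.5, target_rate = 250)
conn <- epoch_connectivity(epochs, order = 8, metric = "pdc")
stats <- directionality_anova(pool_region_pairs(conn))
summarize_directionality(stats[stats$band == "beta", ])
```

The three seeded edges should be called in the correct direction with
Bonferroni-corrected significance, and the three uncoupled pairs should
stay silent.

```{r plot, fig.width = 7, fig.height = 5}
autoplot(conn)
```

## Numerical choices, degenerate inputs, problem sizes

* Transfer matrices come from `solve()` per frequency; a numerically
  singular $\bar A(\omega)$ aborts with the offending frequency named.
* Negative GC round-off is clipped at zero; the GC denominator is floored
  at machine precision relative to $S_{tt}$.
* Normal equations are solved by Cholesky; failure is reported as a
  rank-deficient regressor matrix (e.g. duplicated channels).
* Degenerate inputs error early and specifically: empty epoch sets, zero
  thresholds, baselines with zero variance on every channel (single flat
  channels are flagged and scored 0 instead), empty direction groups,
  mismatched pair sets in `soz_contrast()`.
* The validation studies use 600 s recordings (60 ten-second epochs) for
  direction recovery and split-half stability, 120 s for the 200-seed
  null calibration, and 10⁶ samples for the spectral Monte-Carlo oracle;
  these sizes give the reported statistical resolution while keeping the
  full suite in the minutes range.

## Known limitations

* GC is pairwise-from-full-model; fully conditional (per-pair refit)
  Geweke measures and nonparametric (Fourier/multitaper) spectral GC are
  out of scope.
* No surrogate-based significance thresholds for raw metric values; the
  statistics test directional asymmetries only.
* The EDF support is minimal (16-bit, uniform rate, no annotations).
* Lattice (Vieira–Morf) MVAR estimation is not implemented; the OLS
  estimator is used throughout.
* The contact-pair ANOVA assumes exchangeable observations; with
  spectrally heterogeneous real contacts it is anticonservative, and its
  p values should be read as descriptive there.
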