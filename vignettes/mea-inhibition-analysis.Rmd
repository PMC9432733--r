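---
title: "Quantifying inhibition of cultured cortical networks on MEAs"
author: "meaburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inhibition of cultured cortical networks on MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`meaburst` implements, end to end, the analysis by which inhibition of a
spontaneously active cortical culture on a 60-channel microelectrode array
(MEA) is quantified: spike detection on the raw extracellular voltages,
per-channel burst detection, a panel of network activity metrics with
baseline normalisation, synchrony and spatial-variability statistics, binned
rate time courses with initial-inhibition and rebound quantification, spike
sorting with action-potential (AP) waveform features, four-parameter
logistic dose-response fitting, and a nonparametric group-comparison layer.
Because no public recordings accompany this kind of experiment, the package
ships a first-class synthetic-data generator that emulates the recording
protocol and the mechanistic fingerprints of the treatments, so that every
stage is testable and the pipeline's ability to recover known effect sizes
can be measured.

## The recording protocol and data model

A recording follows a three-phase protocol — 30 min baseline, 15 min
exposure (treatment), 45 min washout — on 60 channels sampled at 10 kHz
(`mea_protocol()`). All times are seconds, sample indices are 0-based, and
intervals are half-open `[start, end)`; these conventions remove the
off-by-one ambiguities that plague window-based spike analysis. Recordings
are exchanged as HDF5 (16-bit integers per channel with a uV-per-LSB scale
factor; sampling rate and phase boundaries as root attributes), spike trains
and burst tables as plain CSV.

## The synthetic network model

Mature cortical cultures fire in near-synchronous *network bursts* riding on
tonic background spiking; network bursts typically account for 60--80% of
all bursts. `network_model()` encodes this structure:

| parameter | default | meaning |
|---|---|---|
| `network_burst_rate` | 10 /min | Poisson rate of network burst events |
| `burst_participation` | 0.85 | P(channel recruited by an event) |
| `intra_burst_rate` | 60 sp/s | flat within-burst firing rate |
| `burst_duration_mean`, `burst_duration_cv` | 0.3 s, 0.3 | log-normal burst durations |
| `isolated_burst_fraction` | 0.3 | share of single-channel bursts (network fraction ~0.7) |
| `background_rate` | 0.8 sp/s | outside-burst tonic firing |
| `channel_rate_heterogeneity` | 0.25 | CV of per-channel log-normal rate multipliers |
| `burst_jitter_sd` | 20 ms | cross-channel burst-onset jitter |

The defaults describe a mature (~3 weeks in vitro), strongly bursting
culture; rates and durations sit in the middle of the ranges routinely
reported for dissociated cortical cultures on planar MEAs. Within a burst,
spikes are drawn as a flat-rate Poisson process (no accommodation): the
metric panel below is insensitive to intra-burst rate shape, so the simplest
model suffices.

Treatments are *effect presets* (`effect_preset()`): multiplicative scalings
of the burst rate, background rate, burst duration, intra-burst rate,
onset jitter (desynchronisation) and AP half-width, entered with an
exponential transition of time constant 30 s (activity collapses within the
first minute of exposure, consistent with a perfusion-coupled treatment
onset). A muscimol-like preset additionally carries a *rebound*: a
transient multiplicative boost of the network burst rate (not the
background, since rebound excitation is a collective bursting phenomenon)
for ~60 s after exposure ends, emulating post-inhibitory rebound after the
withdrawal of tonic GABAergic hyperpolarisation. `builtin_presets()` ships
three arms: `sham` (all scalings 1), `rf` (RF-field-like: moderate,
burst-preferring inhibition, mild desynchronisation, no rebound) and `mu`
(muscimol-like: strong, near-equal inhibition of bursting and spiking,
strong desynchronisation, rebound on). The preset numbers are *calibration
defaults*: they were set so that the reductions **measured by the full
pipeline** (after burst detection and the metric panel, not a pass-through
of the preset values) land on the reference effect sizes of roughly 35%
(RF) and 57% (MU) for burst rate and 14% / 58% for outside-burst spiking.
Because detection, burst-boundary estimation and the fractional-variation
normalisation each introduce small systematic offsets, the background-rate
scalings (0.843, 0.386) differ slightly from the naive closed-form values;
they were fixed once, by matching the measured medians over 30 simulated
cultures, and are user-overridable.

What the generator does *not* emulate: electrode drift and unit
instability, bursts with internal rate structure (accommodation,
reverberations), spatially structured propagation of network bursts,
correlated noise across channels, and stimulation or perfusion artifacts.
Passing the recovery tests therefore shows that the analysis code measures
what it claims on data satisfying its statistical assumptions — not that
those assumptions hold for any particular real culture.

## Spike detection

The raw signal is conditioned with a 4th-order Butterworth high-pass at
70 Hz applied forward-backward (zero-phase, so spike times are not
displaced; DC is removed exactly). Channel noise is estimated robustly as
`median(|x - median(x)|)/0.6745`, which is insensitive to the spikes
themselves at realistic firing rates. Detection uses the differential
threshold of the precision-timing family: a local negative extremum is a
spike when the peak-to-peak excursion to the opposite extremum within a
2 ms *peak lifetime period* exceeds 8 x the noise sd; the spike time is
the trough sample and events within a 1 ms refractory period collapse to
the deeper trough. The three constants (8 sd, 2 ms, 1 ms) are the common
defaults of this detector family and are all exposed in
`detection_params()`.

The waveform path is deliberately separate (mirroring the common two-tool
practice): snippets of exactly 40 samples (0.8 ms before the trough,
3.1 ms after, at 10 kHz) are cut only for spikes whose trough exceeds 5 x
the noise sd, and these feed sorting and waveform features only — burst
and rate metrics always use the detector path.

## Burst detection (logISI)

Per channel, the histogram of log10 inter-spike intervals (10 bins per
decade, 3-bin moving-average smoothing) is searched for the intra-burst
peak below 100 ms and the next slower peak; if the valley between them is
deep enough (void parameter >= 0.7) the valley ISI becomes the burst
threshold, otherwise 100 ms is used, and the threshold is capped at
100 ms. Maximal runs of ISIs at or below the threshold with at least 5
spikes become bursts. This is the single-threshold variant of the logISI
method: the burst-core extension by a second, looser threshold is omitted
for determinism, because at the effect sizes of interest the metric panel
is insensitive to sub-threshold edge spikes. Network-burst labelling
(starts coinciding within 100 ms on >= 20% of active channels) exists for
generator validation; the metric panel pools all bursts without
distinguishing isolated from network bursts, as is standard.

## The metric panel and derived statistics

Per channel and phase: MBR (bursts/min), IBI (mean gap from burst end to
next burst start — defined as the *gap*, not start-to-start, so that IBI
and BD are not redundant; a start-to-start variant would be `IBI + BD`),
BD (mean burst duration, s), IBSR (in-burst spikes / in-burst time, sp/s)
and MSR (outside-burst spikes / outside-burst time, sp/s). MEA-level
values are unweighted means over *active* channels — channels showing
both spiking and bursting at baseline, concretised as >= 0.02 sp/s and
>= 2 bursts. Treatment effects are fractional variations
`R = M_exposure / M_baseline` (undefined and excluded when the baseline
is zero). Synchrony is the CV: 100 x mean within-channel sd of IBI, BD or
IBSR over the pooled mean — the lower, the more stereotyped the bursting
across the array. Spatial variability is the normalised RMSE
`sqrt(mean((Y - y_k)^2))/Y` of channel-level normalised values `y_k`
around the MEA-level value `Y`; 0.5 means a mean inter-channel deviation
of 50%.

Time courses bin pooled burst or spike counts (60 s bins for arm-level
analysis, 10 s for single-culture traces) and normalise by the
baseline-mean rate. The *initial inhibitory rate* is the OLS slope of the
normalised course over the first five exposure minutes (fraction/min).

**Post-inhibitory rebound.** PIR is the maximum of the first two
post-exposure minute bins over a reference level. Two references are
implemented. Dividing by the *exposure floor* (the mean of the last five
exposure bins) is a natural reading of "regain relative to the inhibited
state", but it scores above 1 for any inhibition that merely washes out —
an RF-like arm with ~35% inhibition and no rebound would score ~1.5 by
recovery alone, contradicting the defining observation that rebound
follows the withdrawal of hyperpolarising (GABAergic) inhibition only.
The package therefore defaults to the *baseline* reference (the
normalised course's baseline mean, i.e. 1), under which simple recovery
scores ~1 and only genuine overshoot scores higher; the exposure-floor
variant remains available via `reference = "exposure"`.

## Spike sorting and AP waveform features

Snippets are projected onto their first three principal components and
clustered with Gaussian mixtures (1--4 components, BIC-selected,
deterministic hierarchical initialisation); snippets whose squared
Mahalanobis distance to their component exceeds 1.5 x the 0.99 chi-square
quantile remain unsorted. This is an open, deterministic stand-in for the
proprietary t-distribution EM sorters commonly used with commercial
acquisition systems. Clusters are ranked by their share of the channel's
sorted spikes: the largest is MAJ, others with >= 15% are AUX, the rest
MIN; the 15% cutoff is a pragmatic concretisation and is exposed as an
argument. Only MAJ and AUX units (which hold the large majority of sorted
spikes) enter waveform statistics.

Features are measured on cluster-mean snippets against a baseline defined
as the mean of the first four samples: anti-peak (trough) and peak
amplitudes, trough FWHM by linear interpolation at half depth, and the
maximum slopes of the pre-trough downstroke and the trough-to-peak
recovery. Because the extracellular AP is inverted, the pre-trough
downstroke is the depolarisation equivalent ("rising edge") and the
recovery the repolarisation equivalent ("falling edge"); both are
reported as positive magnitudes in uV/ms, and the convention is fixed
here to avoid sign ambiguity. Baseline and exposure snippets are sorted
*together* (merged), and each unit's exposure/baseline feature ratios are
averaged over MAJ and AUX units. A deliberate limitation follows from the
merged sort: if a treatment changes the waveform so strongly that the two
phases separate into distinct mixture components, the unit is excluded as
untracked rather than mismatched; at the ~7% width changes of interest
this does not occur with realistic noise.

## Dose-response fitting

Normalised MBR against dose is fitted with the four-parameter logistic
`R(d) = floor + (ceiling - floor)/(1 + (d/d50)^h)` by
Levenberg--Marquardt from five deterministic starts (d50 at dose
quantiles), the best kept. Concentration fits run on log10 dose,
SAR (power) fits on the linear axis, matching the axes on which each is
conventionally plotted; the lower plateau may be fixed at 0 for agonist
fits, where full suppression at saturating dose is expected (default:
free). Goodness of fit is a Pearson-type lack-of-fit chi-square: per dose
level, `n_j` x the squared deviation of the replicate mean from the
fitted value, scaled by the pure-error (within-dose) variance, with
`levels - 4` degrees of freedom. The built-in dose models generate
normalised-MBR panels with multiplicative log-normal noise (sd 0.05):
an agonist model (half-effect 0.25 uM, Hill slope 1.5 — typical GABA-A
agonist receptor pharmacology; 14 recordings over 8 concentrations) and a
SAR model (half-effect 28.6 W/kg, Hill slope 8, so inhibition only
becomes apparent above ~25 W/kg; 21 exposed recordings over 8 levels,
each contributing a zero-dose reference).

## Group statistics

Between-arm contrasts use the Kruskal--Wallis omnibus test
(ties-corrected, via `stats::kruskal.test`), Conover--Iman all-pairs t
statistics on ranks with pooled variance (unadjusted p by default — the
common reporting style for this design — with Holm available), the
epsilon-squared rank effect size `H/((n^2-1)/(n+1))`, and a compact
letter display computed by insert-and-absorb: groups sharing a letter are
not significantly different at alpha = 0.05. The Conover and letter
implementations are verified in the test suite against Monte-Carlo
permutation and hand-enumerated oracles.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed; per-channel substreams are
  derived deterministically from (seed, channel), so runs are
  byte-reproducible and channel results do not depend on channel count.
* Inhomogeneous rates are sampled by thinning against the rate maximum.
* Overlapping generated bursts within a channel are resolved by dropping
  the later burst (rare at realistic rates, ~5% at baseline defaults).
* Channels with < 2 bursts in a phase have undefined IBI; zero baselines
  flag the normalised metric as undefined; both are excluded from pooling
  rather than imputed.
* Degenerate mixture fits fall back to a single cluster; ties in cluster
  size resolve to the lower cluster index.
* The logISI histogram leaves edge bins unsmoothed; histograms with fewer
  than three bins skip smoothing.

## Problem sizes

The test suite exercises full-length (90 min, 60-channel) simulations for
the arm-level recovery checks — 8 muscimol-like, 15 RF-like and 8 sham
cultures, the canonical arm sizes for this design — and desk-scale
protocols (10--20 min, 2--12 channels) for unit and property tests;
waveform-path tests render short segments (1--3 channels, 1--5 min per
phase), which is ample for cluster-mean features. The acceptance script
re-simulates the two treatment arms at full scale and both dose panels.

## Known limitations

* The generator's simplifications listed above; in particular, sham-arm
  variability across simulated cultures comes only from Poisson counting
  and channel heterogeneity, so real between-culture variability (age,
  density, lineage) is understated.
* The logISI variant is single-threshold; burst edges are defined by the
  detector's ISI run, not by a burst-core/halo decomposition.
* Spike sorting is not a general-purpose sorter: no overlap resolution,
  no drift tracking, 1--4 units per channel.
* The dose-response layer fits independent observations; replicate
  structure (several recordings from one culture) is not modelled.
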