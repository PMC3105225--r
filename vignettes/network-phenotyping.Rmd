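---
title: "Quantifying neuronal-network phenotypes on multielectrode arrays"
author: "meaburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal-network phenotypes on multielectrode arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## The measurement problem

Dissociated hippocampal neurons plated on a multielectrode array (MEA)
spontaneously wire themselves into a network. Over the first two weeks in
vitro the activity recorded at the extracellular electrodes changes
character: isolated spikes give way to rapid within-electrode bursts, and
bursts become synchronized across the array as the network matures. A
perturbation of a synaptic gene — here, an siRNA knockdown applied at day in
vitro (DIV) 4 — leaves a fingerprint on this developmental program that can
be read out as a small set of network-activity parameters computed from
daily 15-minute recordings between DIV 5 and DIV 12.

`meaburst` implements that readout end to end: spike detection on raw
voltage traces, max-interval burst detection per electrode, seven network
parameters per recording, a three-condition statistical comparison per
parameter and per day, and a compact "barcode" summary of which parameters a
knockdown pushes up or down, and when. Because raw culture recordings are
bulky and rarely shareable, the package also ships a seeded generative
simulator of developing network activity that serves as a test bed for every
stage.

## From voltage to spikes

Extracellular spikes are detected on the negative-going phase of the
waveform by a fixed threshold, by default -20 uV — on a typical MEA
recording about 6-8 standard deviations below baseline noise, sampled at
25 kHz. Each accepted crossing yields a waveform cutout spanning 1 ms before
to 2 ms after the crossing; a dead time equal to the post-crossing window
suppresses re-triggering, so cutouts never overlap. Crossings without room
for a complete cutout at either end of the trace are discarded. Spike time
is the crossing sample itself, in seconds from the first sample. One
consequence of the dead-time rule worth knowing: a signal that *stays* below
threshold re-triggers once per dead time, which is the intended behaviour
for a fixed-threshold detector and makes saturation artifacts visible rather
than silent.

Most users will start from spike timestamps instead; the canonical
interchange format is a two-column CSV (`electrode_id,time_s`), written at
microsecond precision so a read/write round trip is lossless.

## Burst detection: the max-interval method

Each electrode's spike train is parsed independently in three phases:

1. **Scan.** A candidate burst opens at a spike whose interspike interval
   (ISI) to the next spike is at most `max_isi_start` (default 0.17 s) and
   extends while successive ISIs stay at or below `max_isi_end` (0.30 s).
2. **Merge.** Consecutive candidates closer than `min_ibi_merge` (0.20 s),
   measured from the end of one to the start of the next, are merged. Any
   spike inside the merged span counts as a member. Merging runs *before*
   the size filter, so two small candidates can survive only as their union.
3. **Filter.** Candidates shorter than `min_burst_duration` (0.01 s) or with
   fewer than `min_spikes_in_burst` (3) members are discarded.

The threshold defaults are the conventional ones for this algorithm family;
all five are mandatory, explicit configuration recorded in the output
provenance, because burst counts are quite sensitive to them. Two properties
are useful to keep in mind when choosing values: loosening `max_isi_end`
never removes spikes from bursts, and raising `min_spikes_in_burst` never
adds bursts. Note also that a tonic Poisson train produces chance clusters
that satisfy the default thresholds at a non-trivial rate once firing
exceeds roughly 0.5 Hz; burst statistics on weakly bursting, high-rate
electrodes should be interpreted with that in mind.

## The seven network parameters

For one recording of duration $T$ (default 900 s), with bursts detected per
electrode as above:

| parameter | definition |
|---|---|
| total spikes | all spikes summed over electrodes |
| % spikes in bursts | $100 \cdot$ (spikes inside any burst) / (all spikes) |
| burst rate | mean bursts/min over electrodes with **more than** 1 burst/min |
| burst duration | mean duration over bursts pooled from those same electrodes |
| burst pattern | CV across electrodes of the per-electrode mean inter-burst interval |
| network size | number of electrodes with **at least** 1 burst/min |
| correlation index | mean pairwise coincidence index at $\Delta t = 0.1$ ms |

The asymmetry between the strict (`>`) threshold for burst rate/duration and
the inclusive (`>=`) one for network size is preserved exactly as the
parameter set is conventionally defined. Parameters that are undefined on a
given recording — burst rate with no qualifying electrode, burst pattern
with fewer than two contributing electrodes, the correlation index on a
silent array — are reported as missing (`NA`), never as zero, and missing
values are dropped (not imputed) in downstream statistics.

**Inter-burst intervals** are onset-to-onset by default; an end-to-next-onset
mode is available (`ibi_mode = "gap"`). **Burst pattern** implements the
across-electrode reading of the IBI CV — each electrode with at least two
bursts contributes its mean IBI, and the CV (sample SD over mean) is taken
across electrodes; a within-electrode variant (average of per-electrode IBI
CVs) is available behind `mode = "within_electrode"` because the definition
admits either reading. The across-electrode form is the default here since
it is the literal reading of the parameter's definition.

**Correlation index.** For two event trains $a, b$ on $[0, T]$,

$$\mathrm{CI} = \frac{N_{ab} \, T}{N_a N_b \, 2\Delta t},$$

where $N_{ab}$ counts event pairs with $|x - y| \le \Delta t$. Two
independent stationary trains score 1 in expectation; identical trains of
$N$ isolated events score $T / (2 N \Delta t)$. The network value is the
mean over all unordered electrode pairs where both electrodes have at least
one event (optionally: at least one burst). With $\Delta t = 0.1$ ms the
statistic is extremely sharp, which is why the default event source is *all
spikes*: burst onsets at that window are almost never coincident, and the
estimate would be both degenerate and noisy. Burst-member spikes and burst
onsets are selectable event sources (`event_source`) for users who want the
burst-restricted reading.

## The generative simulator

`simulate_recording()` draws from a deliberately simple stochastic model
that reproduces the *statistics* the pipeline measures, not the biophysics
that produce them:

* tonic firing: homogeneous Poisson per electrode;
* network events: a Poisson process shared by the array; each electrode
  joins each event with probability `participation_prob`, its onset shifted
  by Gaussian jitter, then emits $\max(3, \mathrm{Pois}(\mu))$ spikes with
  exponential intra-burst ISIs;
* asynchronous bursts: per-electrode Poisson events of the same shape;
* excitability spread: a lognormal multiplier of unit mean and chosen CV
  applied per electrode to the tonic and asynchronous-burst rates. The
  spread deliberately covers both processes: heterogeneity confined to tonic
  rates would barely move per-electrode burst timing, and the burst-pattern
  statistic is supposed to respond to rate heterogeneity.

All spikes are clipped to the epoch, merged, sorted and de-duplicated at
1 us; a seed fixes everything.

Maturation between DIV 5 and DIV 12 is a linear interpolation between two
endpoint configurations (`default_trajectory()`): tonic rate 0.2 to 1.0 Hz,
network events 0.5 to 3 per minute, participation 0.3 to 0.9, onset jitter
50 to 20 ms, 6 to 12 spikes per burst at 20 to 10 ms ISIs, asynchronous
bursts 0.2 to 0.5 per minute, 15-minute epochs on the standard 60-electrode
8x8-minus-corners layout. These endpoints were chosen once to produce the
canonical developmental picture — a sparse, asynchronous array at DIV 5 and
a dense, synchronized one at DIV 12 with network size saturating near 60 —
at spike counts typical of such cultures (roughly 1e4 to 1e5 spikes per
epoch).

**Condition presets** perturb the trajectory from an onset day, optionally
recovering later. Only one preset magnitude is anchored by a published
number: the Dctn5-like preset pins the network event rate at 5.8 bursts per
minute with full participation from DIV 7 onward. The others (Tnik-like:
tighter, shorter bursts, reduced jitter and tonic firing from DIV 8;
Dlg2-like: more, longer bursts from DIV 6 recovering by DIV 12; Disc1-like:
longer bursts at DIV 12 only) are *qualitative* fixtures: the multipliers
are package constants chosen to be comfortably detectable at 8 cultures per
condition, not published effect sizes. The non-targeting control is modelled
as identical to the untransfected control.

What the simulator does **not** emulate — and hence what green tests do and
do not certify: no spatial structure on the grid (synchrony is
all-to-all), no refractoriness beyond 1 us de-duplication, no
electrode-level noise or unit multiplicity, no within-condition biological
variability beyond sampling (cultures differ only by seed), and no
per-electrode network-membership heterogeneity — which is why the
Dctn5-like preset reproduces the elevated burst rate but not the arrested
network-size growth seen with that knockdown. Passing recovery and power
checks therefore certify the *pipeline's* correctness on data with known
ground truth; they are not evidence about any real culture.

## Statistics and the barcode

The experimental unit is the culture (one MEA), not the electrode: each
culture contributes one value per parameter per day. For every
(parameter, DIV) cell the three conditions — untransfected, non-targeting
control (NTC), knockdown — are compared by a one-way fixed-effects ANOVA,
followed by Fisher's least significant difference pairwise tests using the
pooled error term. By default the LSD is *protected* (pairwise calls
interpreted only when the omnibus F is significant); an unprotected mode is
available since the gating convention varies between labs. Alpha is 0.05
per cell with no multiple-testing correction across the 7-parameter x 8-day
grid, matching the per-cell reporting convention of this assay.

A cell is called an **increase** when the knockdown differs from *both*
controls (p < 0.05 each), the two controls do not differ from each other
(p >= 0.05), and the knockdown mean lies above both control means; a
**decrease** is the mirror image; anything else, including cells where a
group has fewer than two non-missing cultures or all values are identical,
is **none**. The compound rule makes the null false-positive rate per cell
well below the nominal alpha (the controls-similar gate alone vetoes 5% of
cells). The barcode object renders as a parameter x DIV matrix (red =
increase, blue = decrease, gray = none).

## Numerical choices and degenerate inputs

* Time is seconds throughout; windows are half-open `[t0, t1)`, except that
  a window ending exactly at the epoch end is closed there so partitions
  conserve spike counts.
* Coincidence counting uses closed bounds ($|x-y| \le \Delta t$) with exact
  tie handling via sorted-search, identical to the brute-force definition.
* CVs use the sample (n-1) standard deviation.
* Dead-time comparisons in spike detection are done in sample units to
  avoid floating-point drift over long traces.
* Degenerate statistical cells (all values equal, or fewer than two values
  per group) are reported as no-test rather than p = NaN.
* Sub-seeds for experiment simulation are drawn once from the master seed,
  so cultures are mutually independent yet the full dataset is reproducible.

## Problem sizes used by the test suite

The packaged checks exercise the pipeline at the design scale of the assay:
60 electrodes, 900-second epochs, 8 cultures per condition, DIV 5-12.
Detector-versus-oracle equivalence runs on 1000 random trains under 5 random
configurations; the null false-positive rate of the barcode rule is
estimated from 200 simulated three-condition experiments at a single DIV;
preset power uses 20 simulated experiments across DIV 7-12. Parameter
recovery is averaged over replicate recordings (10 in the test suite, 30 in
the reproduction script) because the network-event count of a single epoch
is one shared Poisson draw (45 expected events, so a single recording has
~15% sampling error on the burst rate before the detector ever sees it);
the residual few-percent shortfall of the recovered burst rate is the
detector's merge rule collapsing network events that arrive within a burst
length plus the extension ISI of each other.

## Known limitations

* Burst-threshold defaults are conventions, not fitted values; quantitative
  burst statistics are only comparable between analyses sharing a
  configuration (which is why every output bundle embeds its provenance).
* The correlation index normalization assumes stationarity within the
  epoch; strongly non-stationary recordings inflate it.
* Chance clusters in high-rate tonic firing register as bursts under the
  default thresholds (see above), inflating burst rate at mature DIVs.
* No proprietary acquisition formats are read; timestamps must be exported
  to the CSV interchange format first.
* Cross-DIV dependence is ignored by design: each day is tested
  cross-sectionally, so the barcode makes no longitudinal claim about
  trajectories, only a per-day one.
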