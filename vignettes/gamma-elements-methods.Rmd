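---
title: "Detecting and decoding theta-nested gamma elements: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and decoding theta-nested gamma elements: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gammel)
```

## Overview

`gammel` treats hippocampal gamma activity not as a small set of narrow
frequency bands but as a population of transient oscillatory events —
*gamma elements* — each living inside one cycle of the ongoing 4–12 Hz
theta rhythm. An element is parameterized by six numbers: the amplitude,
frequency and theta phase of the gamma event itself, and the amplitude,
frequency and rise/decay asymmetry of its host theta cycle. The package
implements the full chain from multichannel local field potentials (LFPs)
to element tables, plus three downstream analyses (behavioral decoding,
partial information decomposition, and a spiking-network model of element
generation) and a synthetic-data generator that provides ground truth for
every stage.

## Signal decomposition

Band composites are built by ensemble empirical mode decomposition (EEMD)
rather than bandpass filtering: white noise scaled to `noise_level` (0.3)
times the signal standard deviation is added in each of `n_realizations`
realizations, each noisy copy is sifted into ten intrinsic mode functions
(IMFs), and the ensemble mean is taken per IMF index. A composite for a
band (theta 4–12 Hz, gamma 30–250 Hz, infra-theta 1–4 Hz) is the sum of
the IMFs whose mean Hilbert instantaneous frequency falls inside the
band. The residual is defined as input minus the summed IMFs, so
reconstruction is exact by construction.

Numerical choices: sifting uses natural cubic spline envelopes through
the local extrema, with the two outermost extrema mirrored about each
signal end; a Cauchy-type criterion (`sd_tol = 0.2`, at most 12 sifts per
IMF) stops each sift. The "mean" instantaneous frequency of an IMF is the
mean of the phase-derivative over the interior 98% of samples (the edges
carry unwrap artifacts); a median variant is available via `freq_stat`.

Two properties of this construction matter downstream:

* *Band-limitation symmetrizes asymmetric theta.* An asymmetric theta
  wave has harmonic content near twice its fundamental; with added
  ensemble noise, EEMD behaves as a dyadic filter bank and places that
  harmonic in an IMF whose mean frequency (about 16–21 Hz for an 8 Hz
  carrier) lies outside the 4–12 Hz band. The theta composite of a
  strongly asymmetric carrier is therefore partially symmetrized, which
  shifts the detected trough and flanks by one or two milliseconds — a
  few degrees of waveform phase. This is a property of the composite
  definition, not of the cycle detector (which is exact on the raw
  wave); it is why the burst-recovery fixture uses a symmetric carrier
  (see below).
* *Ensemble size trades residual noise for time.* The ensemble-mean of
  the added noise decays as `1/sqrt(n_realizations)`. The analyses in
  the test-suite and acceptance script use 40–100 realizations, which
  keeps the full pipeline on a one-minute recording within a few
  minutes of CPU; the 2000-realization default is the recommended
  setting for production analyses of real recordings.

## Anatomical reference and CSD

The theta reference channel is the hippocampal fissure, located at the
peak of a Gaussian fit to the per-channel theta power profile (1–14 Hz
Morlet bank on the 4–12 Hz zero-phase FIR-filtered trace); the peak may
fall between electrodes. Degenerate profiles (monotone or flat) fall back
to the argmax with a warning. Gamma amplitude is always measured on the
current source density (CSD), the discrete second spatial derivative
across the 50 µm-spaced channels, which suppresses volume conduction;
linear-in-depth potentials map to exactly zero.

## Theta cycles and waveform phase

Cycles run peak-to-peak on the fissure theta composite. Peaks are local
maxima at least 80 ms apart (just below the 83 ms minimum cycle
duration, so ripple-induced double peaks are suppressed); the trough is
the minimum between peaks and the flanks are the half-amplitude
crossings on each side. Phase is piecewise linear through the five
landmarks (peak 0°, descending flank 90°, trough 180°, ascending flank
270°, next peak 360°), which respects waveform asymmetry better than
Hilbert phase. A candidate cycle is kept if its duration lies in 83–250
ms, the theta envelope exceeds the infra-theta envelope at the cycle
start, midpoint and end (envelopes are analytic-signal moduli; the
"midpoint" is the temporal midpoint by default, switchable to the
trough), and a behavior sample falls inside the cycle. Cycles that start
or end within `edge_margin_s` (0.5 s) of the recording edges are
excluded: sifting envelopes and wavelet kernels are unreliable there.

## Snippets and patch detection

The CSD trace is convolved with complex Morlet wavelets (0.5 s kernels,
15–200 Hz in 5 Hz steps, cycle count linear from 6 to 20) and the
amplitude of each frequency row is averaged within 10° phase bins,
producing one 38 × 36 snippet per cycle. Empty bins (possible for short
cycles) are filled by linear interpolation across phase, circularly at
the edges.

Patch detection scans the threshold downward through every distinct
amplitude value of the snippet — an exact sweep with no step-size
parameter, which also makes the independent brute-force oracle used in
the tests exactly comparable. Supra-threshold cells form connected
components under 4-neighborhood adjacency. Components that would merge as
the threshold drops retain their pre-merge extents and are stored as
separate patches (a merged blob spans distinct power peaks and must not
be counted as one element). The scan stops at the first threshold at
which four patches belong to the cycle, and the four strongest by mean
amplitude are kept (ties break by earlier phase, then lower frequency —
a deterministic ordering).

Rows below 30 Hz are excluded from patch formation by default: the gamma
composite starts at 30 Hz, so amplitude in the 15–25 Hz rows is kernel
leakage, not gamma. The switch `min_row_freq = NULL` restores the full
grid.

Boundary handling: a component touching the first or last phase bin may
continue into the adjacent cycle, so detection runs on the concatenation
of the previous, current and next snippets along the phase axis. A
cross-boundary patch is assigned to the cycle holding the larger share of
its summed amplitude, ties to the earlier cycle, so each patch is counted
exactly once.

Element parameterization follows the patch: amplitude is the mean over
cells, frequency and phase are the amplitude-weighted means over the cell
row frequencies and bin centers, the phase mean circular (linear
averaging is wrong across the 0/360 wrap). Theta features are copied
from the host cycle; theta amplitude is the mean voltage difference
between the trough and the two adjacent peaks (positive for a normal
cycle).

Element tables are filtered per trial and channel: the top and bottom 1%
of gamma amplitudes are removed, as are elements from cycles whose
running speed exceeds 100 cm/s.

## The synthetic generator

`generate_behavior()` emulates an eight-arm radial-maze reference-memory
task at 20 Hz: each trial departs from a pseudo-random arm, visits a
number of wrong arms that declines linearly across days (4 on day one to
0 on day ten by default — the learning schedule), runs to the target arm
and dwells 5 s at the reward. Speed follows an Ornstein–Uhlenbeck process
around 25 cm/s, capped at 90 cm/s, and is reported as central differences
smoothed by a 0.5 s moving average. Sections partition the maze into
`reward_RF`, `target_arm`, `other_RF` and `other`.

`generate_recording()` builds 1 kHz multichannel traces as: a theta
carrier warped cycle-by-cycle to the requested rise/decay asymmetry
(default 1.25, in the range reported for hippocampal theta), scaled by a
Gaussian depth profile peaking at the fissure channel and sign-inverted
above the pyramidal layer; plus Gaussian-windowed cosine bursts
(default 6 cycles under the envelope — the same family as the analysis
wavelets, making recovery tolerances predictable) drawn per cycle and
layer from configurable frequency/phase/amplitude distributions,
optionally modulated by the current maze section; plus white noise.
Default layer distributions place slow-gamma-like bursts (45 ± 10 Hz) on
the radiatum channels at the ascending theta phase (315°, the
fissure-referenced image of the descending-phase preference reported for
CA3-driven gamma) and medium-gamma-like bursts (85 ± 10 Hz) on the
lacunosum-moleculare channels at the trough (180°). Burst rates per cycle
are free parameters (default 1 per layer channel): the in-vivo rates per
layer are not quantified in the source literature.

What the generator does **not** emulate: volume conduction and realistic
depth profiles of gamma (bursts are injected locally per channel),
place-cell spiking, theta frequency/amplitude fluctuations, movement
artifacts, and 50 Hz noise. Passing tests on synthetic data therefore
validate the algorithmic chain, not robustness to every property of real
recordings.

## Validation fixtures

`validation_recording()` freezes the burst-recovery fixture: two
spatially isolated burst channels (so the CSD does not duplicate one
channel's bursts onto another detection channel), exactly one
high-amplitude burst per cycle per channel, low noise, a symmetric
carrier (see the band-limitation note above), 60 s. Recovery is scored on
bursts at least 60 ms from their nearest same-channel neighbor —
overlapping wavelet responses cannot be attributed to a single burst —
and inside the edge margins. Matching pairs each injected burst with the
nearest-in-time detected element after discarding candidates below half
the local maximum amplitude (residual-noise patches). With these
conditions the pipeline recovers frequency within ±2.5 Hz and phase
within ±5° (half a spectrogram cell) for over 90% of bursts.

`decoding_fixture()` freezes the decoding null/signal pair: one burst
channel, identical behavior, and either no section modulation or strong
per-section shifts of the burst mean frequency. Decoding is evaluated
per channel, as in the in-vivo analysis: pooling channels with different
frequency distributions would let a classifier read the per-section
channel mixture — with only a few dozen theta cycles in the rarest
section, such frozen sampling fluctuations are genuinely decodable and
would lift the null above chance.

`regime_points()` freezes the two network working points used for the
reduced-scale regime contrast (below).

## Decoding

The location decoder is an ensemble of depth-limited classification
trees fitted by boosting (SAMME weighting) with per-iteration random
undersampling to class balance: every tree sees a draw in which class
counts differ by at most one, drawn with the current boosting weights.
This follows the class-balancing logic of RUSBoost; the exact original
weighting variant is not re-implemented, as the scientific content is
balance plus slow boosted trees (learning rate 0.01, up to 500 trees of
up to 500 splits by default; the tree budget is mapped to an equivalent
`rpart` depth cap).

Cross-validation folds partition theta cycles, never elements: all
elements of one cycle — on every channel — share the cycle's theta
features, so any finer split would leak cycle fingerprints into the test
fold. Performance is reported per class and summarized as the mean of
per-class correct fractions, whose chance level under balanced training
is 1/(number of classes) regardless of how unevenly the animal occupies
the sections; 95% confidence intervals come from a 1000-replica bootstrap
over elements. Conditioned performance restricts the held-out predictions
to one quartile of a feature (or speed) distribution. Cross-classification
evaluates a trained model directly on another table (resubstitution on
the diagonal of cross matrices, direct evaluation off it); learning
windows group consecutive trials to approximately 3000 elements each, and
the early/late pivot balances cumulative counts.

## Information decomposition

Features are discretized into sample quartiles (lower-closed bins, ties
to the lower bin — deterministic; phase is binned on its linear value by
default with a circular option). Mutual information is the plug-in
estimate from the joint frequency histogram, normalized by the section
entropy H(L). The partial information decomposition uses the
minimal-mutual-information ansatz: redundancy is the minimum of the two
marginal informations, the unique information of the less informative
input is exactly zero, and synergy completes the total. Parts are
nonnegative and sum to the total by construction. No small-sample bias
correction is applied (bootstrap intervals quantify uncertainty
instead); at n of a few thousand elements the plug-in bias of the joint
term is of order 0.01–0.02 bits and inflates the synergy component
accordingly — comparisons should be made at matched n.

## The spiking network model

The model is a theta-driven quadratic integrate-and-fire (QIF) network:
80% excitatory and 20% inhibitory neurons with membrane constants 10 and
4.5 ms, quenched Gaussian in-degrees within populations (mean K, SDs 2K
and 0.2K — the final-value reading of the heterogeneity parameters),
all-to-all cross-population coupling, Gaussian excitabilities, DC
currents scaled by sqrt(K) and couplings by 1/sqrt(K), and a sinusoidal
10 Hz drive of amplitude 0.042·sqrt(K). Synapses are delta pulses: a
presynaptic spike through coupling g shifts the postsynaptic potential
by 2g instantly. Spike and reset use a symmetric boundary at ±100 on the
QIF phase variable; the escape-time correction is omitted (it is below
0.7% of the period at the default drive) and the boundary is
configurable. Integration is plain Euler at dt = 0.001 ms; the published
I-to-I coupling chain is ambiguous and both readings are implemented
(`gii_reading`, default the large-coupling reading, which supports
interneuron-gamma-like rhythms).

The model LFP is the sum over excitatory neurons of the absolute AMPA
and GABA currents, each a double-exponential (rise 0.4/0.25 ms, decay
2/5 ms) driven by the same spike trains, high-passed at 1 Hz with a
4th-order Butterworth filter. Because the cross-population coupling is
all-to-all, the GABA current is identical across excitatory neurons,
which the implementation exploits; an event-based closed-form
reconstruction (`synthesize_model_lfp()`) provides an independent check
of the online integration.

Regime indicators: spectral entropy of the 25–125 Hz power density at
0.1 Hz resolution normalized by log2(1000); the low/high gamma power
ratio exactly as printed, (P_low − P_high)/(P_high + P_low) over
25–50/50–100 Hz (positive values therefore indicate low-gamma
dominance); the SD over time of the mean inhibitory membrane potential;
and the mean excitatory spike-train entropy, the binary entropy of
p = rate/gamma-frequency with the gamma frequency taken at the LFP
spectral peak.

Model gamma elements are extracted by the same wavelet/snippet/patch
chain, with theta cycles taken from the known 10 Hz forcing phase (the
model has no fissure channel) and the spectrogram computed on the model
LFP directly. Spike-presence decoding trains one balanced boosted-tree
binary classifier per excitatory neuron to predict whether the neuron
fires within a window centered on each element, cross-validated over
cycles; a neuron is "decodable" when both its true-positive and
true-negative fractions exceed 0.6. The window is 100 ms by default but
must be matched to the firing rate to keep the label informative — a
neuron firing at rate r leaves a window of width w empty with
probability about exp(-r w), so windows much wider than 1/r are always
"spike". By default the decoded neurons are those whose spike-presence
fraction across element windows is nearest one half.

## Problem sizes used in the tests and acceptance script

The published simulation scale (2000 neurons at dt = 0.001 ms, long
runs) reproduces the model results in a matter of hours on one CPU. The
packaged checks run the identical code at a reduced scale chosen to keep
the full suite in the tens of minutes: 500 neurons, dt = 0.01 ms, 20 s
per working point, a 60 s recovery recording at 100 EEMD realizations,
and 60 s decoding recordings at 40 realizations. At this scale the
regime contrast is qualitative (entropy and synchrony orderings between
the fringe and synchronous points) and the spike-decoding check
validates the decoding chain and segmentation rule rather than the size
of the decodable subgroup: excitatory rates at n = 500 are high relative
to the gamma frequency, a 100 ms window is then always occupied, and
even with a rate-matched 15 ms window the individual-neuron coupling to
single gamma elements is weaker than in the sparse full-scale regime, so
the decodable subgroup can be empty at desk scale. The dt sensitivity is documented by the
tonic-rate test: the closed-form QIF rate is matched within 2% at
dt = 0.001 ms and within 10% at dt = 0.01 ms.

## Known limitations

* The EEMD composite slightly symmetrizes strongly asymmetric theta
  (quantified above), biasing waveform phase by a few degrees when the
  asymmetry ratio departs far from 1; asymmetry itself is still
  recovered to within a few percent.
* Elements below ~35 Hz lean on the lower edge of the snippet grid;
  their weighted frequencies are biased upward by the 30 Hz row cutoff.
* Bursts closer than about one wavelet width merge into single patches
  by construction — the algorithm assigns one element to what is, in the
  generator's bookkeeping, two events.
* The plug-in information estimates are biased upward at small n; only
  matched-n comparisons are meaningful.
* The alternative-arm label scheme merges the target arm into `other`
  but cannot promote a specific opposite arm with the default behavior
  generator, which does not label individual non-target arms; tables
  carrying their own arm labels can use the scheme fully.
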