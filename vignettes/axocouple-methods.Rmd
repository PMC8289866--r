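---
title: "Detecting propagation signals and synaptic coupling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting propagation signals and synaptic coupling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Planar multi-electrode arrays record extracellular action potentials
(eAPs) from cultured neuronal networks, but a single electrode cannot
attribute a spike to a particular neuron: several cells may lie within
detection range, and spike sorting brings its own unverifiable
assumptions. Axonal propagation offers a way out. When one axon crosses
several electrodes, each of its action potentials appears on that cohort
of electrodes in a fixed order with fixed sub-millisecond delays and very
low jitter. Spikes carrying that spatiotemporal fingerprint are therefore
self-classified as coming from a single identifiable neuron. With one
neuron's spike times in hand, short-latency spike clusters at other
electrodes — milliseconds after, at latencies typical of excitatory
synaptic transmission — become detectable and quantifiable.

`axocouple` implements this chain: spike extraction from raw voltage,
propagation-signal detection, coupling detection with configurable
acceptance criteria, statistical controls, and condition-level network
graphs, plus a simulator that generates recordings with known ground
truth.

## Spike extraction

Raw voltage is bandpass filtered with a 2nd-order Butterworth filter
(200–4000 Hz), applied forward–backward. The zero-phase pass is a
deliberate choice: a causal filter would delay spike peaks by a
frequency-dependent amount and bias every latency downstream. Spikes are
negative deflections; the per-channel noise scale is estimated as
`median(|v|)/0.6745`, the median-based estimator that is insensitive to
the spikes themselves (a plain standard deviation is inflated on active
channels, raising the threshold exactly where it should not be). A spike
is recorded at each local minimum below −k·σ (default k = 6), with the
minimum's value as its amplitude and its sample time as the spike time —
consistent with the amplitude definition. A configurable dead time
(default 1 ms) suppresses re-detections within one multiphasic waveform;
the earlier detection wins.

## Propagation-signal detection

For each reference electrode a cross-correlogram (CCG) over a ±2 ms
window is computed against every other electrode: every (reference,
target) spike pair with latency inside the window contributes one count.
Windows are half-open `(lo, hi]`; for continuous spike times the
convention is immaterial, but it makes the binning exact and testable
against a brute-force oracle. The bin width is 0.05 ms — one sample at
20 kHz, the finest resolution the data support — and the 0.5 ms scan
window slides one bin at a time.

The propagation ratio is `n_win / n_all`, the largest 0.5 ms window count
over the number of reference spikes. A ratio strictly above 0.3 marks a
consistent delay. The delay estimate is the mean of the raw latencies
inside the maximizing window (not the modal bin): it is robust to
bin-edge effects and exact in the small-jitter regime. If every
co-firing electrode lags the reference, the reference is the earliest
electrode of a cohort and a signal is emitted.

Numerical edge cases handled explicitly:

* **Near-zero delays.** Jitter can make a genuinely simultaneous
  cohort-mate measure an epsilon-negative delay, which would wrongly veto
  the cohort under the all-non-negative rule. Delays down to −bin/2 are
  treated as non-negative and clamped to zero.
* **Duplicate cohorts.** Two electrodes with identical delay both pass
  the all-non-negative test and emit the same cohort. Cohorts sharing ≥ 2
  electrodes whose delay profiles agree within 0.2 ms after removing a
  constant offset are merged, keeping the variant with more electrodes
  and, on ties, the earlier origin.
* **Sparse references.** The count ratio is meaningless on nearly empty
  trains (one chance coincidence on a 3-spike train exceeds 0.3), so
  electrodes with fewer than `min_ref_spikes` (default 5) spikes are not
  used.

Signal spike times are computed from two anchors — the earliest electrode
and the most active of the rest. Anchor spikes within 2 ms of each other
(the same scale as the detection window) are matched greedily one-to-one
in time order, and each signal spike time is the mean of the matched
pair. One-to-one matching prevents a single burst on one anchor from
claiming several partners; unmatched spikes are dropped.

## Coupling detection

Each signal's spike times serve as reference events for a one-sided CCG
over 0.5–10 ms against every other signal and every electrode outside the
signal's own cohort. With `n` reference spikes, `n1` total counts and
`n2` the largest count in any 3 ms sliding window, acceptance requires:

| criterion | default | meaning |
|---|---|---|
| `n1/n > v1` | 0.1 | enough coupled spikes to rule out flukes |
| `n2/n1 > v2` | 0.57 | counts concentrated in one peak, not spread over the window |
| `v3 ≤ mean peak latency ≤ v4` | 1–5 ms | the latency band of excitatory coupling between neighbouring neurons |
| `sd(all Δt) < v5` | 2.7 ms | rejects multi-neuron target electrodes with broad latency scatter |

All thresholds are user-configurable (`coupling_criteria()`). Two
interpretive choices deserve note. First, the peak-concentration
criterion is bound to the numeric value 0.57 (a verbal "60% of the area"
description rounds it; the numeric value is authoritative here). Second,
the "delay time" of a coupling is defined as the mean of the latencies in
the maximizing 3 ms window rather than the modal bin position — the mean
is stable under binning choices and is what the latency band is compared
against.

The coupling probability is `n2/n`: spikes in the CCG peak over reference
spikes. `n1` enters only the criteria. The standard all-pairs CCG counts
every target spike after a reference spike, so the probability can in
principle exceed the per-event response fraction when the target bursts;
at the firing rates the detector is calibrated for the difference is
negligible. The reverse analysis (`upstream_inputs()`) is the one place
where at-least-one counting is used — the fraction of postsynaptic spikes
preceded by ≥ 1 candidate spike in the 9.5 ms window — because there the
question is "how often was the postsynaptic spike preceded by this
input", not "how often does this input evoke a spike".

Electrode targets carry a verification flag: if the CV of the absolute
amplitudes of *all* spikes on the electrode exceeds `v6` (default 0.25),
the electrode likely records several units, and the coupling should be
reviewed by eye. The full evaluation log — including rejected candidates
and the first criterion each failed, with their sub-threshold probability
— is returned, so criterion settings can be audited.

In stimulation mode the reference events are stimulation onsets; latency
is measured from onset, and target spikes inside the post-stimulus
blanking period (default 1.5 ms), during which no usable voltage exists,
are masked.

## Statistical controls

**Amplitude KS comparison.** If the coupled spikes at an electrode come
from one postsynaptic neuron while the electrode records several, their
amplitude distribution is a discrete subset of the electrode's full
distribution. `coupled_vs_random_amplitude_test()` draws random subsets
of matching size (without replacement — the natural model for "randomly
chosen groups" of recorded spikes) and KS-compares each with the coupled
set; the random-vs-random mode provides the null reference in which about
95% of comparisons exceed a 5% threshold. P-values use the asymptotic
two-sample formula: the discriminations of interest are many orders of
magnitude beyond any exact/asymptotic difference.

**ISI shuffle.** Surrogate target trains are built by permuting the
inter-spike intervals and cumulating from the first spike: spike count,
ISI multiset, first spike and total span are preserved exactly (asserted
per repetition in the tests), while fine timing relative to the reference
is destroyed. Amplitudes keep their original order — the control concerns
timing only. The chance-coupling ratio (target spikes within 0.5–10 ms of
any reference spike, each counted once, over reference spikes) collapses
by well over an order of magnitude for genuine couplings and is
statistically unchanged for independent trains. All stochastic operations
take explicit integer seeds.

## Network graphs

Signal→signal couplings form a directed graph per condition; isolated
signals remain as nodes and reciprocal pairs are two edges. Across
conditions, signals are re-identified by their cohorts: ≥ 2 shared
electrodes with delay profiles agreeing within 0.2 ms after offsetting.
An explicit rule is needed because cohorts can gain or lose electrodes
between recordings; ambiguous matches are an error rather than a silent
guess. `diff_graphs()` partitions the edge union into retained, lost and
gained — the quantities of interest when a manipulation changes synaptic
efficacy.

## The simulator and what passing tests mean

`simulate_recording()` generates: Poisson unit trains with a 2 ms
refractory period (enforced by thinning; cultured neurons impose this
biologically); cohort broadcasting with per-electrode delay, Gaussian
jitter and detection probability; couplings in which each presynaptic
spike triggers a postsynaptic spike with fixed probability and jittered
latency, merged into the follower's train under the refractory period
(the triggered spike wins exact ties); per-(unit, electrode) Gaussian
amplitude modes, so multimodal electrodes arise when units share an
electrode; and independent background spikes per electrode with their own
amplitude mode. Raw traces can be rendered by placing a biphasic template
(peak = spike amplitude) at each spike time plus Gaussian noise, closing
the loop through filtering and threshold detection.

Default parameters are the regime the detectors are calibrated for:
300 s recordings (typical session length), 2 Hz unit firing, 3-electrode
cohorts with 0.2 ms delay spacing and 0.02 ms jitter (propagation latency
CV ≲ 0.1), coupling latencies near 2.5 ms, ~45 µV unit spikes over
~20 µV background, 0.5 Hz background per electrode.

The planted-recovery benchmark (`benchmark_config()`) uses the full
120-electrode array, 5 units, and 4 couplings spanning probabilities
0.2–0.8 with latency jitter sd 0.3–0.5 ms. Two sizing choices matter:

* **Latency jitter.** The 3 ms peak window captures essentially all of a
  latency distribution with sd ≤ 0.5 ms, so the peak-window probability
  estimator is unbiased and recovery can be held to ±0.05. With much
  broader latency jitter (sd ≳ 2 ms, which pooled biological data can
  show across couplings), a 3 ms window necessarily truncates the
  distribution and the estimator reports the peak mass, not the full
  response fraction — an intrinsic property of windowed CCG estimators,
  not an implementation artifact.
* **Wiring.** Two postsynaptic neurons driven by the same presynaptic
  neuron with high probabilities co-fire tightly, and a CCG method will
  report a spurious post→post coupling — the classic common-input
  confound, which criteria v1–v5 do not screen out. The benchmark
  network therefore keeps presynaptic fan-out probability products small
  (≤ 0.24) with matched latencies, so every common-input coincidence
  rate stays well below v1. Users analysing densely connected cultures
  should expect common-input edges and treat the graph as functional,
  not anatomical.

What the simulator does **not** emulate: bursting and network-wide
synchronised events, non-stationary firing rates, electrode drift,
overlapping spike waveforms on raw traces (spikes add linearly),
inhibition, and indirect (polysynaptic) coupling chains. Passing the
recovery benchmark therefore demonstrates correctness of the detection
chain in its calibrated regime, not robustness to every pathology of real
cultures.

Problem sizes in the shipped tests and reproduction script — 10–20
simulation seeds, 100 CCG oracle instances, 100–200 KS draws, 1000
shuffle checks — were chosen to give comfortable statistical margins for
each property while keeping a full run in the minutes range.

## Known limitations

* Couplings are *putatively* synaptic: indirect chains and common input
  can satisfy all criteria (see above); direct stimulation or
  pharmacology is needed for causal claims.
* No multiple-testing correction is applied across the many
  (signal, target) pairs; the criteria themselves act as the filter, and
  the KS/shuffle controls are per-coupling diagnostics.
* Spike tables are read and written as plain CSV with commented header
  metadata; the layout is documented in `read_spike_table()`.
* Cross-condition node matching assumes cohorts overlap on ≥ 2
  electrodes; a neuron whose cohort changes completely between
  recordings appears as a lost plus a gained node.
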