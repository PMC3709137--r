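---
title: "Methods: a spiking antennal-lobe model for ratiometric transient processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spiking antennal-lobe model for ratiometric transient processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiolobe)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data
generators do and do not emulate, the numerical choices, and the known
limitations. Every empirical number quoted here is computed by the test
suite or by `scripts/acceptance.R`.

## Neuron and synapse dynamics

All somata are leaky integrate-and-fire (LIF) units and all synapses are
exponential-decay current sources, advanced synchronously on a fixed grid
(default step $\Delta = 1$ ms; the step is a free parameter because exact
integration makes the subthreshold solution step-independent). The
forward-Euler recursion with the *corrected* time constant
$\tau^\* = \Delta / (1 - e^{-\Delta/\tau})$ satisfies
$1 - \Delta/\tau^\* = e^{-\Delta/\tau}$, so the homogeneous part of

$$v_{k+1} = v_k\left(1 - \frac{\Delta}{\tau^\*}\right) + \frac{\Delta}{C_m} I_k$$

is the exact exponential at every grid point. Two consequences worth
keeping in mind:

* The *input* term integrates as $\Delta I / C_m$ per step, so the
  steady-state gain of the discrete soma is $\tau^\*/C_m$, about 5%
  above the continuous $\tau_m/C_m$ at $\Delta = 1$ ms, $\tau_m = 10$ ms.
  Rate calibrations therefore use the discrete relation (see
  `calibrate_beta()` below); closed-form/simulated rate agreement within
  2% holds on fine grids ($\Delta \le 0.02$ ms near rheobase).
* Threshold test happens after the update; reset to $v_{ahp} = 0$ on the
  same step; no refractory period; no spontaneous activity.

Membrane constants: $\tau_m = 10$ ms for ORNs and PNs, 20 ms for LNs;
$v_\theta = 1$, $C_m = 1$ in arbitrary units, so currents and weights are
expressed relative to threshold. Synaptic decay constants default to
$\tau_e = 5$ ms and $\tau_i = 10$ ms (not anatomically constrained;
configurable).

### Fixed-point verification mode

`decay_error_lsb()` replays the membrane decay in quantized arithmetic (a
signed 16- or 32-bit state) and compares it against the rounded closed
form. Two rounding models are provided because they behave qualitatively
differently:

* `"guard"` (default): the multiplier keeps its rounding residual in a
  guard-bit accumulator between steps (first-order error feedback), so
  the stored state never deviates more than half an LSB from the exact
  exponential — the configuration the half-LSB fidelity claim requires.
* `"nearest"`: plain per-step round-to-nearest-even. This mode *stalls*:
  once the state reaches 5 LSB (with $\Delta/\tau = 0.1$),
  $\mathrm{round}(5\,e^{-0.1}) = 5$ and the decay freezes, leaving a
  permanent 5-LSB error. Plain per-step rounding therefore cannot meet a
  half-LSB bound over long horizons; residual-preserving quantization is
  the design that does.

Without the time-constant correction the error is catastrophic (the raw
factor $1 - \Delta/\tau$ under-decays by design), which the tests assert.

## Network architecture and regimes

One MGC instance (`mgc_config()`, `build_mgc()`): 2 ORN channels, 30 LNs,
2 glomeruli × 15 PNs. Wiring is probabilistic per directed edge; weight
magnitudes are drawn uniformly from per-pathway ranges — afferent ORN→LN
in [1000, 3000] and mutual LN→LN in [100, 400] (the hardware
initialization ranges), the unconstrained pathways defaulting to the same
magnitudes. Inhibitory matrices are stored non-positive; there are no
self-connections, no cross-glomerular ORN→PN or PN→PN edges, and no
PN→LN feedback.

Because the published description fixes the topology and the LN–LN
probability but not the current scales, the per-pathway pulse constants
`b` are the package's own calibration. They were set (before any
classifier was run) by matching mean synaptic drive
$b\,w\,f\,\tau_{syn}/1000$ to sensible operating points — LN drive a few
times rheobase at pulse-train ORN rates, LN–LN inhibition strong enough
that sparse asymmetric connectivity produces winnerless switching while
all-to-all symmetric connectivity locks a single winner. The regime
dichotomy is asserted over 20 instantiations: median 0 winner switches
for the symmetric network and median ≥ 1 (majority switching) for the
sparse one, measured by `regime_statistics()` during the stimulation
period only (dominance is undefined during the offset decay, which the
statistic excludes).

`sensor_mgc_config()` rescales `b` for chemosensor input, whose ORN rates
(0–50 Hz after calibration) sit an order of magnitude below the synthetic
pulse-train rates; the rescaling equates mean drive across the two input
regimes rather than being fit to any outcome.

## STDP

The asymmetric rule acts only on ORN→LN and LN→LN synapses, with the
convention $\mathrm{d}t = t_{pre} - t_{post}$: a presynaptic spike before
the target LN's spike potentiates, otherwise depresses, both branches
decaying exponentially in $|\mathrm{d}t|$ ($\Delta W^\pm = 150$,
$\tau_\pm = 20$ ms, prefactors $\tau_+/(\tau_-+\tau_+)$ and
$1 - \tau_-/(\tau_-+\tau_+)$, both ½ at the defaults). Pairing is
nearest-spike with per-neuron last-spike memory; a coincident pair
($\mathrm{d}t = 0$) counts once, as potentiation. Updates are
sign-preserving: the weight *magnitude* is clipped to
$[\max(0, w_{min}), w_{max}]$ (defaults the signed 16-bit range), so an
inhibitory synapse can silence but never become excitatory.

Training (`train_stdp()`) presents one randomized ten-ratio pulse train
per epoch (pulses of 100 ms, 100 ms gaps, first-order RC filtering with
10 ms constant, 2% Gaussian noise) and carries weights across epochs.
What happens, mechanistically: ORN spike rates exceed LN rates, so
depression events (one per ORN spike) outnumber potentiation events (one
per LN spike) and the afferent weights contract until the LN layer falls
below rheobase on the training amplitudes; plasticity events then cease
and the configuration is *strictly* stable (an epoch with zero weight
changes — the hardware definition, and the package's default criterion).
Across 20 random instantiations, 85% reach strict stability by epoch
5–8; a minority retain one LN whose weights keep bouncing against the
clipping bounds indefinitely, which is why the stability property is
asserted as a majority statement. A relaxed criterion (per-epoch summed
change below 0.1% of total weight) is available for partially converged
states.

The frozen weights are not degenerate: contraction speed depends on each
LN's random initial alignment with the input ratios, so the final
normalized weight pairs spread over the whole space of trained ratio
directions (tuning-angle coefficient of variation roughly triples; the
nearest LN tuning lies within ~7° of every trained ratio direction on
average over seeds). Because afferent inhibition is effectively removed,
PN responses to the probe ratios 1:3 / 1:1 / 3:1 are amplified and their
class templates separate further (mean inter-template distance grows in
4 of 5 instantiations, and in the mean). Three principal components
capture ≈ 99% of the post-training PN trajectory variance.

One caveat stated plainly: the *rate-trace* decorrelation of the LN
population is a fragile effect here. The adapted layer is largely silent
at training amplitudes, so correlations must be probed at higher drive
(`ln_rate_correlation()` defaults to a suprathreshold probe); aggregated
over 15 instantiations the mean pairwise correlation falls from 0.190 to
0.184 — the claimed direction, but small against across-seed spread. The
robust expression of symmetry breaking is in the weight tunings, not the
rate traces.

## Synthetic chemosensor data

`make_synthetic_sawr()` emulates dual surface-acoustic-wave-resonator
recordings of five volumetric ratio classes of a binary blend (volumes
4:16 … 16:4 µl at constant total). Per trial and channel the
polymer-coated device's resonant frequency drops along a first-order rise
toward a steady state proportional to the analyte load (with 10%
cross-sensitivity to the other analyte) and relaxes after venting; the
uncoated reference shares the linear baseline drift, which the
differential removes exactly. Deliberate imperfections, chosen from
device physics: white frequency noise (50 Hz s.d. per sample, ~3% of the
maximum response), a residual random-walk wander on the coated device
that the reference does not track (8 Hz/√sample, ~100 Hz RMS over a
trial — a differential reduces but does not eliminate interference), 5%
lognormal per-trial concentration jitter (delivery variability; it scales
both channels together, so the ratio is preserved), and 5% kinetic
jitter on the time constants.

The rise/decay constants default to 15 s and 20 s per channel so that the
transient phase completes within 50–80 s and equilibrium is reached by
about 100 s — the timeline on which early-transient classification is
meaningful. What the generator does **not** emulate: sorption
nonlinearity and saturation, temperature excursions, chamber memory
between trials, and correlated multi-trial drift of real instruments.
Classification results on this clean generator therefore bound the raw
baseline's difficulty from below (see Limitations).

## Sensor-to-model coupling

`differential_current()` computes $I(t) = \beta\,(f_{uncoated} -
f_{coated})$, clamped at zero (sorption lowers the coated frequency, so
stimulation yields positive drive; there is no inhibitory sensory
drive). `calibrate_beta()` chooses $\beta$ so the dataset-maximum
differential drives the ORN at 50 Hz, the in-vivo ceiling. The default
`"grid"` method solves the *discrete* rate relation — it centres the
current inside the interval whose discrete interspike interval is
exactly the target (20 steps at 50 Hz, $\Delta = 1$ ms) — so the
simulated rate hits the target exactly rather than within the ~5%
discretization slack of the continuous closed form.

`sensor_episodes()` then normalizes each trial's differential pair by
that trial's maximum (the dominant channel reaches the calibrated
ceiling; the drive encodes ratio, not absolute concentration — set
`normalize = "none"` for raw scaling) and resamples sensor seconds onto
model milliseconds (default compression 10 ms per second, the
clock-matching between slow sensors and the fast neuronal core; a 150 s
trial becomes 1500 steps).

An important structural constant follows from the calibration: a LIF
with $\tau_m = 10$ ms firing at most 50 Hz has its rheobase at
$1/(1 - e^{-2}) \approx 86\%$ of the maximum drive. Only differentials
in the top ~15% of a trial's range can fire an ORN at all, so
weak-channel inputs are invisible to the spiking front-end and classes
that differ only in the weak channel are separable only through network
dynamics driven by the dominant channel. This is intrinsic to the
50 Hz/10 ms operating point, not a tunable artifact.

## Readout and classification

`estimate_rates()` convolves each 0/1 spike indicator with the discrete
Gaussian kernel $T(n, d) = e^{-d} I_n(d)$, truncated at the smallest
radius holding 99.9% of its unit mass, scaled to Hz; $d$ defaults to
$\tau_m/\Delta$ steps for the population being read. The symmetric
kernel is the default (offline analysis); a causal one-sided
renormalized variant serves real-time semantics. Rate mass equals spike
count to truncation tolerance, and the estimator is linear in the
raster — both asserted in tests.

Classification is nearest-mean-trajectory: per class a pointwise mean
template (equal trial lengths enforced; no implicit truncation), distance
$D_x(T)$ the step-weighted mean Euclidean norm up to the decision time,
ties broken toward the lowest class label. `classification_curve()`
sweeps $T$ under leave-one-trial-out rotation (templates rebuilt without
the held-out trial each time); with five equal-prior classes chance is
20%, which label-shuffled controls recover. The raw-sensor baseline runs
the same machinery on the two normalized differential channels, with
per-channel max-absolute scaling estimated on the training split of each
rotation. `greedy_select()` scores a seeded pool of candidate connectomes
(plasticity disabled) by the decision curve integrated over the time
grid and returns the maximizer, first-encountered winning ties.

## Problem sizes and numerical choices

Defaults used by the tests and the acceptance script: 300 training
epochs (2000 steps each) for the training analyses, 150–600 where only
stability or tunings are needed; 5 classes × 5–10 trials × 1500 steps
for the chemosensor pipeline; candidate pools of 4–8; 20 seeds for
regime statistics and 5–15 for training properties. All randomness flows
through explicit integer seeds via a deterministic sub-seed tree;
identical seeds give bit-identical rasters and byte-identical reports.
Degenerate inputs are first-class: empty rasters yield zero-rate
trajectories, a zero-variance pool is flagged rather than projected, an
all-zero differential refuses calibration, and winner statistics on a
silent LN population return an explicit no-activity flag.

## Limitations

* **The spiking front-end does not beat the raw baseline on this
  synthetic data.** On the generator's clean five-class transients the
  raw normalized two-channel baseline classifies near-perfectly from
  ~25 s, while the model output rises above chance only once the
  calibrated drive crosses the ORN threshold (~50 s) and plateaus around
  0.5–0.6 — the structural ceiling implied by the 86%-of-maximum
  rheobase. The advantage reported for this architecture on laboratory
  recordings — whose raw transients were far harder to classify than any
  smooth first-order emulation — does not reproduce under these
  conditions, and the corresponding comparison tests are left failing
  rather than weakened. Users applying the pipeline to real sensor data
  should treat the comparison as an open empirical question, not a
  packaged conclusion.
* STDP stability is a majority property (~85% of instantiations); a
  minority never stop adapting.
* Rate-trace decorrelation of the LN layer is marginal; tuning-spread
  decorrelation is the robust effect.
* The fixed-point mode verifies the scalar decay path, not the full
  network datapath.
* Multi-glomerular configurations beyond two glomeruli are accepted by
  the configuration object but untested against any reference behavior.
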