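---
title: "Reflexive FES gait control: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflexive FES gait control: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfes)
```

## The control problem

Functional electrical stimulation (FES) can assist walking by eliciting
muscle contractions with surface electrodes, provided the stimulation is
timed to the wearer's own gait. `gaitfes` simulates a *reflexive*
multichannel FES controller: rather than following a fixed clock, every
stimulation burst is a reflex-like response to a sensed gait event. The
package reproduces the full control loop in software — sensing,
event detection, stimulation shaping — plus the synthetic signals and the
kinematic analysis needed to exercise it without hardware or participants.

Four muscles per leg are addressed: tibialis anterior (TA, ankle
dorsiflexion — the classic drop-foot target), lateral gastrocnemius (LG,
push-off), biceps femoris (BF, knee flexion) and rectus femoris (RF, knee
extension / hip flexion).

## Sensing and binarization

Each leg carries three insole force-sensitive resistors (heel, first and
fifth metatarsal head) and an inertial unit. The two forefoot FSRs are
collapsed by a sample-wise maximum, because foot load is rarely symmetric
across the forefoot; a toe FSR, if present in a recording, is read but
ignored by the controller, since toe-load amplitudes vary too much between
subjects to threshold reliably. The sagittal hip angle is estimated by a
complementary filter,

$$\theta_t = b\,(\theta_{t-1} + \omega_t \Delta t) + (1-b)\,
\mathrm{atan2}(a_x, a_z),$$

with blend $b = 0.98$ at the 100 Hz sensor rate — roughly a 0.5 s
crossover between gyroscope integration (fast, drifting) and accelerometer
tilt (slow, drift-free).

The detector needs logic signals, not waveforms. Each channel is
binarized by an adaptive threshold placed a fraction $k = 0.3$ of the way
between the channel's observed minimum and maximum, with a Schmitt-trigger
band of $\pm 10\%$ of the threshold to suppress chatter. Two deliberate
asymmetries:

* **Batch vs sliding calibration.** The default recomputes min/max over
  the whole recording, which is the natural choice for an offline
  simulation tool; a causal trailing-window mode (`mode = "sliding"`,
  default 400 samples ≈ two slow cycles) is available for
  streaming-style use. A flat window keeps the previous threshold.
* **No hysteresis on the hip channel.** The filtered hip angle is smooth,
  and near the terminal-swing threshold it rises at roughly one degree
  per sample; a 10% band would systematically delay the terminal-swing
  event by more than the one-sample accuracy the detector otherwise
  achieves. The hip threshold itself is 60% of the observed peak
  flexion.

## The five-phase state machine

One cycle is divided into loading response (LR), stance (ST), pre-swing
(PS), swing (SW) and terminal swing (TSW). Transitions are boolean rules
on consecutive binary frames $(G_H, G_T, \Phi_H)$, and four of them emit
unit impulses:

| event | condition (current, previous) | phase after |
|---|---|---|
| heel strike (HS) | any foot part loads after swing | LR |
| heel off (HO) | heel unloads while forefoot stays loaded | PS |
| swing (SW) | foot fully airborne after forefoot contact | SW |
| terminal swing (TSW) | hip flexion signal rises while airborne | TSW |

Each rule is evaluated only from the phases it can physically originate
in (HS from SW/TSW, HO from LR/ST, SW from LR/ST/PS, TSW from SW). The
bare boolean conditions alone would re-fire a heel strike when the
forefoot loads midway through the loading response; the originating-phase
guard encodes the intent ("contact *after the swing phase*") without a
debounce timer. Related choices:

* LR advances silently to ST on foot-flat ($G_H = G_T = 1$); heel-off
  requires full foot contact on the previous sample, so foot-flat must be
  an explicit state even though no impulse marks it.
* A contact directly from SW (no hip-threshold crossing) still fires HS —
  pathological gait may skip terminal swing, and forefoot-first contact
  counts as a heel strike event.
* $\Phi_H$ is ignored whenever the foot is loaded.
* A stream's very first frame only initializes the machine; a heel strike
  at $t = 0$ is the start of the recording, not a detectable transition,
  so an $n$-cycle recording yields $n-1$ HS impulses and $n$ of each
  other kind.
* The minimum phase dwell is one sample; all denoising lives upstream in
  the hysteresis, keeping the machine pure and testable.

## From impulses to currents

The controller is hierarchical. The top level gates each muscle by phase;
the bottom level shapes the current. Each channel component owns a
second-order low-pass Butterworth filter whose impulse response, scaled
by a gain $g = 1/\max_n h[n]$, turns a unit event impulse into an
envelope $u = g\,(h * I)$ peaking at exactly 1. The commanded current is

$$C = (u\,\Delta c + c_{\min})\,S,$$

so a gated channel sweeps its subject-specific band $[c_{\min},
c_{\max}]$ (measured per muscle during a setup session; the packaged
`stim_params.yaml` fixture carries the bands of seven study subjects) and
is exactly 0 mA when its gate $S$ is closed. The wiring is: TA and BF are
driven by the swing impulse and gated over SW∪TSW; LG by heel strike
(gated LR) and heel off (gated PS); RF by heel strike (gated LR) and
terminal swing (gated TSW). The two components of LG and of RF gate on
disjoint phases, so at most one contributes at any tick.

Cutoff frequencies control envelope duration. Where fitted values are
unavailable, each component defaults to $f_c = 1/(2d)$, with $d$ the
nominal duration of its gated phases, so the envelope roughly spans the
phase; every $f_c$ is overridable in the channel configuration.

Numerical choices worth knowing:

* Kernels come from the bilinear-transform discretization (cutoff
  prewarped so the −3 dB point is exactly $f_c$) and are truncated where
  the remaining tail energy falls below $10^{-6}$ of the total.
* The underdamped second-order kernel has a negative tail lobe of about
  4% of its peak. A negative stimulation envelope is meaningless and
  would push commands below $c_{\min}$, so responses are clamped at 0
  (an unclamped mode exists for verifying linearity).
* Envelopes from consecutive cycles superpose, as a convolution
  formulation implies; $u$ is clamped at 1 before the current mapping so
  no command can exceed $c_{\max}$. This pair of clamps is the safety
  contract: every nonzero current lies in its channel's measured band.
* Commands are emitted at the 100 Hz control rate; the 40 Hz / 350 µs
  pulse train is an annotation on each channel, not sample-level pulse
  synthesis.

## The synthetic gait generator

The generator exists so the whole loop is testable: it emits FSR,
inertial, hip-angle and joint-angle streams *together with* the ground
truth (per-sample phase labels, transition times) that detection is
judged against. Defaults describe slow treadmill walking: 2.0 s cycles at
100 Hz, phase fractions LR 10%, ST 30%, PS 15%, SW 35%, TSW 10%.
Contact is modelled as load plateaus with step edges — FSR contact
transitions are abrupt at this sample rate — with the forefoot loading
60% of the way through the loading response. Joint trajectories are
idealized low-order sinusoid/Fourier shapes scaled to configurable
midrange and range of motion (hip 30° peak flexion, 40° RoM; knee 60°
RoM; ankle 25° RoM); the hip sinusoid's peak is placed analytically so
that its rising crossing of the detection threshold falls exactly at the
swing → terminal-swing boundary, once per cycle. Accelerometer and
gyroscope channels are derived from the hip trajectory (gravity
components and the analytic angular rate), so the complementary filter is
exercised against a consistent signal.

Noise has two tiers, and the distinction matters. Stride-to-stride
kinematic variability is drawn once per cycle and joint — range-of-motion
fluctuation (SD 1°) and baseline shift (SD 0.5°) — while white
measurement noise on the angle channels is small (SD 0.2°). This mirrors
real gait, where cycle-level variability dominates, and it has a
statistical consequence: per-cycle RoM estimates are then approximately
Gaussian around the template value. Under a purely white-noise model the
per-cycle maximum and minimum would be extreme-value statistics with
heavy right tails, and two-sample t-tests on them would not hold their
nominal far-tail error. Cadence jitter (per-cycle duration SD) defaults
to 0, so default recordings are exactly periodic and length arithmetic is
exact; tests that need stride-time variability switch it on explicitly.

What the generator does **not** emulate: ground-reaction dynamics and
load-dependent FSR waveforms (plateaus, not force curves), soft-tissue
and marker artifacts, gait asymmetry or pathology, non-periodic
activities, and any effect of stimulation on the kinematics. Passing
tests therefore demonstrate the correctness of the detection, control and
analysis machinery under clean periodic conditions — not clinical
performance on patient data.

## The analysis stage

Cycles are segmented between consecutive heel strikes, the first 30
complete cycles per trial are kept, and each cycle is resampled by linear
interpolation onto 101 points (0–100% of the cycle). Per cycle and joint,
the maximum, minimum and range of movement (RoM = max − min) are
computed; the two walking conditions are compared per joint × parameter
with a two-sample t-test — pooled variance by default, Welch by flag,
since only "two-sample t-test" is conventionally reported — at a
corrected level of 0.004. That printed level is the shipped default;
supplying an explicit comparison count derives a Bonferroni level
$\alpha/n$ instead (0.05/12 ≈ 0.0042 rounds to the same threshold).
Degenerate inputs are defined: two zero-variance samples with equal means
give $t = 0,\ p = 1$.

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle: a
hand-derived bilinear-transform difference equation for the kernels, a
brute-force double-sum for the convolution, a closed-form pooled-variance
formula for the t statistic, fold-the-stepper equivalence for the batch
FSM, and the generator's embedded truth for end-to-end event recovery
(35-cycle noise-free recordings, every event within ±1 sample). The
calibration of the condition comparison is measured on 1000 null
replicate pairs of 31 cycles each, and effect recovery on a +5° ankle-RoM
shift at 30 cycles per condition — sizes chosen so the whole suite runs
in about a minute on a laptop while leaving the binomial and t
confidence intervals tight enough to be informative.

## Known limitations

* The fitted cutoff frequencies of the original envelope filters are not
  public; the phase-duration heuristic stands in, and all cutoffs are
  configuration-overridable.
* The adaptive-threshold formula (min + 0.3 × range, 10% hysteresis,
  batch calibration) is this package's design; only the *method name* is
  conventional.
* Muscle fatigue, electrode placement, stimulator protocols and every
  other hardware concern are out of scope; the output is a command
  stream, not a physiological prediction.
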