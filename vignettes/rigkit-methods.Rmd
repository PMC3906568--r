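---
title: "rigkit: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rigkit: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigkit)
```

rigkit is a hardware-free acquisition engine for episodic neurophysiology
experiments: a rig model with a global 3D sample coordinate system, a set of
simulated devices (patch-clamp amplifier, camera, galvanometric scanner,
stage, microscope, laser, DAQ), a synchronized task executor, scanner and
laser calibration, hierarchical session storage, and the analysis routines
that typically accompany such experiments. This vignette documents the
models, the conventions chosen where several were defensible, and what the
simulations do and do not capture about real recordings.

## Coordinates and the optomechanical hierarchy

All physical quantities are SI (meters, seconds, volts, amperes, ohms,
farads, watts, joules); configuration files may use unit suffixes
(`"100 um"`, `"40 kHz"`, `"10 MOhm"`), normalized on load by `si_value()`.

Transforms are 4x4 homogeneous matrices in the column-vector convention,
applied left-of-vector; `tf_compose(A, B)` applies `B` first. A device's
local transform is built as `translate(offset) o rotate_z(angle) o
scale(scale)`, i.e. offsets are expressed in the parent frame
(*post*-scale). The same holds for objective offsets: an objective's offset
is a physical displacement in the stage/sample frame, not a pixel count —
that is the natural reading for a lens-turret offset measured with a
calibration target, and it keeps offsets meaningful when the scale changes.

Camera pixel coordinates are 0-based, `(x = column, y = row)`, with pixel
centers at integer coordinates. Global mapping of a pixel therefore goes
pixel -> camera local -> (microscope: objective scale and offset) ->
(stage: current position translation) -> global. Stage motion is a pure
translation, so it shifts every descendant's mapped points by exactly the
motion delta; an objective switch rescales only the microscope's subtree.
Both operations emit events (`rig_on_event()`) so calibration consumers can
switch stored calibrations; on a physical rig the switch would be reported
by a turret microswitch, here it is an explicit call to `set_objective()`.

## Simulated devices

**Patch-clamp amplifier.** The cell is a single compartment: membrane
resistance $R_m$ and capacitance $C_m$ to rest $V_{rest}$, accessed through
a series (pipette) resistance $R_a$. In voltage clamp a step $\Delta V$
produces

$$I(t) = I_{hold} + \frac{\Delta V}{R_a+R_m} +
  \left(\frac{\Delta V}{R_a} - \frac{\Delta V}{R_a+R_m}\right)
  e^{-t/\tau}, \qquad \tau = \frac{C_m R_a R_m}{R_a + R_m},$$

and in current clamp a step $\Delta I$ gives
$V(t) = V_{rest} + \Delta I R_m (1 - e^{-t/R_m C_m}) + \Delta I R_a$, the
electrode drop being instantaneous. The simulator integrates the circuit
with an exact per-sample exponential update (the command is
piecewise-constant over a sample), so the noiseless output matches these
closed forms at machine precision — which is what lets the analysis suite
demand sub-percent parameter recovery rather than "roughly right". Noise is
white Gaussian with an explicit seed; there is no amplifier filtering,
bridge balance or pipette-capacitance compensation. Spiking in current
clamp, used to exercise spike metrics, is a deliberately synthetic leaky
integrate-and-fire mechanism (threshold $-40$ mV, reset $-65$ mV,
refractory 2 ms, an inserted spike-peak sample at $+30$ mV); no
voltage-gated conductances are modeled. Mode changes between voltage and
current clamp always pass through I=0 with the holding output zeroed
(`clamp_set_mode()` keeps an auditable history).

**Camera.** Frames are rendered by evaluating an analytic scene function at
the global coordinates of each pixel center through the camera's current
global transform (nearest-sample lookup, no point-spread function or
readout-noise model). The camera also produces the exposure TTL signal real
cameras export: high during each exposure, with frame start times lying
exactly on TTL rising edges — the timing contract the frame-timing analysis
relies on. In triggered mode the first exposure starts at the trigger time.

**Scanner.** The ground-truth optics are a quadratic map from sample-plane
position to mirror voltages (see below). `sim_scanner_observe()` plays the
role of the calibration camera: given commanded voltages it returns the
spot position that the true map sends to those voltages (Newton inversion
from the linear part, error if the command leaves the invertible range),
plus Gaussian localization noise.

**Reservations.** All devices of a request are claimed atomically under one
registry update, so hold-and-wait — and therefore deadlock — cannot occur.
Waiting requests are served first-come-first-served; a later request cannot
overtake an earlier one on any device the earlier one is waiting for. In a
single-threaded R session, `wait = TRUE` on busy devices fails immediately
with a starvation timeout (nothing could release them while we block);
cooperative schedules use `wait = FALSE` pending handles that are promoted
when a release frees their devices. A claim/release ledger supports the
safety property test (no device ever held by two owners).

## Task execution

A task is a list with a `protocol` block (`duration`, `storeData`,
`continuous`, which must be `FALSE`: only episodic acquisition is
supported) and one block per device. Only the protocol block is interpreted
by the engine; device blocks are interpreted by the devices, which is what
lets one task description run on any rig that defines the same device
names. `triggerDevice: X` in device D's block means D arms and waits for a
hardware edge from X, hence D must start before X.

Ordering is planned in two stages. Configure order is a topological sort of
configure-before preferences — a device whose channels are hosted on a DAQ
configures before that DAQ, so its waveforms are in place when the DAQ
programs buffers — with ties broken by descending arming latency (defaults:
camera 50 ms, DAQ 10 ms, clamp 5 ms, scanner 2 ms), so slow-arming devices
are configured as early as the constraints allow. Start order is a
topological sort of the trigger edges (triggered device before its source)
plus host edges (passive DAQ-hosted channel devices arm before their DAQ);
among unconstrained choices, devices that are trigger sources are scheduled
as late as possible, so free-running masters start last. Both sorts reject
cycles. Completion timeout defaults to `10 * duration + 5 s`; aborts stop
devices in reverse start order. Waveforms are specified as combinations of
square pulses, pulse trains, ramps, sines or explicit sample arrays —
arbitrary expression evaluation is deliberately excluded.

Sequences (`run_sequence()`) execute the base task over the Cartesian grid
of one or more parameter axes, first axis outermost, all points sharing the
base duration; per-point parameter values and seeds (`seed + k`) are
recorded, and per-point failures are recorded without halting unless
requested.

## Scanner and laser calibration

The mirror map is quadratic in position for each voltage channel:

$$V_x = A x^2 + B y^2 + C x + D y + E, \qquad
  V_y = F x^2 + G y^2 + H x + I y + J.$$

Because the model is linear in its ten coefficients, the least-squares
optimum is obtained directly by QR on the design matrix
$[x^2, y^2, x, y, 1]$ — identical to what an iterative least-squares
optimizer would converge to, without iteration. Calibration commands a
rectangular voltage grid (default 5x5), observes the spot positions, and
fits; the fit is exact (machine precision) on noise-free data for any
non-degenerate sample set, and rank deficiency (e.g. collinear points) is a
hard error. Calibrations are stored per (laser, objective) pair, since both
change the optical path. Two residuals are reported: volts RMS in the
fitted space and meters RMS through the inverted map.

Scan patterns: rasters scan rows left-to-right (alternating when
bidirectional; reversed rows may be shifted by a configurable integer field
shift, default 0, to cancel the comb artifact, and
`estimate_field_shift()` recovers it by maximizing adjacent-row
correlation — an optional convenience, not part of the core contract).
Overscan extends each line by `round(cols * overscan)` samples at both
ends, flagged `keep = FALSE` so reconstruction can drop turnarounds and
recover exactly `rows x cols` kept samples. Spirals are Archimedean
($r = \text{pitch} \cdot \theta / 2\pi$) at constant angular sampling —
one of several plausible "spiral" definitions, chosen for testability.
Laser flash energy is delivered by duration:
$t = E / (P_{out} \cdot \text{attenuation})$, with the attenuation factor
looked up per optical configuration.

## Electrophysiology analyses

**Frame timing** thresholds the exposure TTL at the midpoint of its dynamic
range with a 10%-of-amplitude hysteresis band, so band-limited noise cannot
double-count edges; a constant trace yields an empty result with a warning.

**Membrane properties** from a voltage-clamp test pulse: $R_a = \Delta
V/(I_{peak}-I_0)$, $R_{in} = \Delta V/(I_{ss}-I_0)$, $R_m = R_{in}-R_a$,
$\tau$ from a single-exponential fit to the capacitive decay (log-linear
least squares over the initial run above 1% of the starting amplitude,
optional `nls` refinement), and $C_m = \tau R_{in}/(R_a R_m)$. When the
transient is sub-sample (very small $R_a C$), the fit fails with a warning
and $\tau$, $C_m$ are NA while the resistances remain valid. In current
clamp, $R_{in} = \Delta V_{ss}/\Delta I$ (total, electrode included) and
the resting potential is the pre-pulse mean.

**IV metrics**: resting potential is the mean pre-step voltage across
traces; input resistance the least-squares slope of steady-state deflection
vs current over subthreshold (spike-free) steps; membrane time constant an
exponential fit to the onset of the smallest hyperpolarizing step; sag
ratio $(V_{min}-V_{ss})/(V_{min}-V_{baseline})$ on the largest
hyperpolarizing step (0 for a passive cell, clamped to [0, 1]). Spikes are
upward crossings of $-20$ mV with a 2 ms refractory; interspike intervals
and latency are taken from the trace with the most spikes (smallest step on
ties), and the adaptation ratio is mean(last two ISIs)/first ISI, defined
from three spikes up. The spike criterion, sag definition and adaptation
formula are field-standard conventions fixed here for determinism.

**Event detection** is a fixed, deterministic pipeline (in place of a
user-configurable filter graph): zero-phase Butterworth low-pass at 0.4 of
Nyquist; frequency-domain deconvolution with a single-exponential kernel of
the expected decay time (division regularized by adding $10^{-6}$ of the
peak spectral magnitude); a robust threshold at `threshold_k` times the MAD
of the deconvolved signal; onsets at fresh upward crossings separated by at
least `min_interval`. Events are then measured on the raw trace: baseline
(median of the preceding 5 ms), signed amplitude, 10–90% rise time, and
decay tau by exponential fit after the peak. The default `threshold_k = 6`
is a family-wise choice: on multi-second traces (tens of thousands of
samples) the expected number of noise crossings at 6 MAD is far below one,
while a synaptic event at signal-to-noise 10 stands at 10 MAD or more, so
recall is unaffected. Detection is equivariant to time shifts and to
amplitude scaling, since both the deconvolved signal and its MAD scale
together.

**Charge transfer** is the trapezoidal integral of baseline-subtracted
current; both window endpoints snap to samples, making the integral exactly
additive over adjacent windows.

**Map classification**: the spontaneous event rate $\hat\lambda$ is pooled
over all sites and trials (total baseline-window counts over total baseline
time), and each site's pooled post-stimulus count $n$ over its trials is
tested against $P(\mathrm{Pois}(\hat\lambda \cdot w \cdot
n_{trials}) \ge n)$, with Benjamini–Hochberg control at `alpha` across
sites. If $\hat\lambda = 0$, any post-stimulus event gives $p = 0$. The
Poisson null with plug-in rate and FDR correction is this package's
statistical choice for "is this site evoked?"; Poisson p-values are
discrete and therefore slightly conservative, which the null-calibration
test (per-map false-flag rate at or below $\alpha$ plus binomial error)
reflects. The post-stimulus window length is a required analysis parameter
(tests use 50 ms with a 500 ms baseline); no claim is made that any
particular window is canonical.

## Imaging analyses

The continuously-updating background is an exponential running mean,
$B_t = (1-\alpha) B_{t-1} + \alpha F_t$ with $\alpha = \Delta t / \tau_{bg}$
(clamped to 1) and $B_0 = F_0$; the output $F_t - B_{t-1}$ is a temporal
high-pass: static structure decays with $\tau_{bg}$ while fast transients
pass. The update rule is a documented choice; frame intervals varying by
more than 10% trigger a warning and per-frame $\alpha$.

Bleaching correction fits $\hat F(t) = A e^{-t/\tau_b} + C$ (log-linear
starting values, `nls` refinement, then one robust re-fit excluding
positive excursions beyond 2 robust SDs so transients do not bias the
baseline) and corrects multiplicatively,
$F \cdot \hat F(0)/\hat F(t)$ — multiplicative rather than subtractive so
that fractional (dF/F) amplitudes are preserved. On failure the series is
returned unchanged and flagged.

Registration is integer-pixel by FFT cross-correlation against the first
(or mean) frame, with circular peak unwrapping and zero-padded shifting;
flat frames get zero shift with a warning. Subpixel refinement is out of
scope. ROI dF/F selects pixels through the frame transform (rectangles or
ellipses in global coordinates), $F_0$ is the mean over a user-specified
baseline window, and the series is invariant under global intensity
scaling; ratiometric indicators divide two ROI series before dF/F.
Event-triggered averages skip (and count) events whose window leaves the
series. Mosaics resample each frame into a global-coordinate canvas through
`adjustment o transform` by nearest neighbor (exactly testable to the
half-pixel bound; bilinear would trade testability for smoothness), later
frames on top or averaged; manual alignment adjustments are stored apart
from the data and applied to whole groups of frames, never modifying the
original transforms.

## Session storage

A session is a tree of typed directories, each with a pretty-printed JSON
index (`.index.json`) holding its metadata and one entry per child and
dataset; directory types declare required metadata fields, enforced on
creation, and index updates are atomic (temp file + rename). Array payloads
(traces, frame series, arrays) are stored one file per dataset in R's
native serialization with their metadata and an MD5 checksum — chosen
because it guarantees bit-exact round trips for every numeric type with no
external dependency, while the index remains greppable text. Name
collisions get `_000`-style suffixes. `verify_session()` is an fsck-style
sweep comparing every index against the directory contents.

## What the simulations do and do not show

The generators reproduce the *contracts* real hardware provides — exact RC
responses, TTL edges aligned to frame starts, a quadratic mirror map,
Poisson spontaneous activity, exponential PSC shapes and bleaching — with
white Gaussian noise and explicit seeds everywhere. Passing tests therefore
demonstrate correctness of the analysis pipeline against its own model
class, not robustness to the things real rigs add: correlated and
non-stationary noise, amplifier filtering, camera readout artifacts, mirror
settling dynamics, overlapping events with variable kinetics, and drift.
Default validation sizes (chosen to characterize behavior well while
keeping the suite quick): 200 random cells for parameter recovery, 5x20
injected events at SNR 10 for detector characteristics, 500 null maps of
100 sites x 10 trials for classifier calibration, 1000 random trigger
graphs, and 1000 coordinate round trips.

## Known limitations

Continuous (non-episodic) acquisition, closed-loop control, non-affine
optical distortion, analog laser-power servoing, subpixel registration,
spatially correlated site statistics, and any graphical interface are out
of scope. The spiking cell is a synthetic exerciser, not a neuron model;
the AxoPatch-style telegraph scaling constants are configuration inputs,
not computed.
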