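# rigkit

A hardware-free acquisition engine and analysis toolkit for episodic
neurophysiology experiments, written for experimenters and tool developers
who combine patch-clamp electrophysiology, laser-scanning photostimulation
and fluorescence imaging — and for anyone who needs to develop and test
acquisition or analysis code without a rig attached.

rigkit models the rig as a hierarchy of *optomechanical devices* — stage,
microscope (with switchable objectives), camera, scan mirrors — each with a
3D affine transform into its parent's frame, so that every pixel,
photostimulation site and trace is expressed in one global sample
coordinate system:

    global = T_stage ∘ T_microscope(objective) ∘ T_camera · pixel

On top of that sit simulated devices (an RC model cell behind a patch
amplifier, a camera with an exposure-TTL contract, galvo mirrors with
quadratic voltage optics, lasers, a DAQ), a task engine that executes
declarative multi-device task specifications with trigger-aware start
ordering and atomic device reservation, and analysis routines:

- membrane properties from a test pulse: `Ra = ΔV/(Ipeak−I0)`,
  `Rin = ΔV/(Iss−I0)`, `Rm = Rin − Ra`, `Cm = τ·Rin/(Ra·Rm)`;
- current-step IV metrics (resting potential, input resistance, membrane
  time constant, sag ratio, ISIs, latency, adaptation ratio);
- synaptic event detection by low-pass → exponential deconvolution →
  MAD-threshold, with per-event amplitude, rise time and decay τ;
- photostimulation map classification against a pooled-rate Poisson null
  with Benjamini–Hochberg correction across sites;
- mirror calibration `Vx = Ax² + By² + Cx + Dy + E` (and similarly `Vy`)
  by linear least squares, stored per (laser, objective);
- imaging: rolling background subtraction, bleach correction, integer-pixel
  registration, ROI ΔF/F, event-triggered averages, mosaic composition;
- hierarchical session storage with human-readable JSON indices.

## Worked example

Build the demonstration rig (stage → microscope → {camera, scanner}, a DAQ,
a model cell on `Clamp1`), run the canonical camera-triggered task — record
100 ms at 40 kHz from the amplifier while the free-running camera triggers
the DAQ — then measure the cell from a voltage-clamp test pulse:

```r
library(rigkit)

demo <- build_demo_rig("demo_session")
mgr  <- rig_manager(demo$rig)
res  <- execute_task(mgr, demo$task, seed = 1)
res
#> <task_result> completed - 3 device entries
res$results$Clamp1$primary
#> <trace> 4000 samples @ 40000 Hz, t0=0 s [V] primary

cell <- cell_model()                       # Ra 10 MΩ, Rm 100 MΩ, Cm 30 pF
rate <- 2e5; n <- round(0.05 * rate)
cmd  <- new_trace(build_waveform(list(type = "squarePulse", start = 0.01,
                                      duration = 0.03, amplitude = 0.01),
                                 rate, n, holding = cell$Vrest),
                  rate, 0, "V")
membrane_properties(sim_clamp_response(cell, cmd, "vc"), cmd, "vc")
#> <membrane_props> Rin=110 MOhm Ra=10 MOhm Rm=100 MOhm Cm=30 pF tau=273 us
```

The recovered values are the model cell's ground truth: a 10 mV step sees
the 10 MΩ pipette alone at its peak (1 nA), the full 110 MΩ series at
steady state (90.9 pA), and the capacitive transient decays with
τ = Cm·Ra·Rm/(Ra+Rm) ≈ 273 µs.

Calibrating the scanner against simulated optics and asking for mirror
voltages at a sample position:

```r
tm  <- list(A = 2e4, B = -1e4, C = 3e3, D = 5e2, E = -1.2,
            F = 1.5e4, G = 2.5e4, H = 4e2, I = 2.8e3, J = 0.7)
cal <- calibrate_scanner(tm, grid_n = 5)   # 5x5 voltage grid, no noise
cal
#> <scanner_calibration> laser / obj, residual 1.22e-14 V (6.03e-18 m)
position_to_voltage(cal, 1e-4, 2e-4)       # x = 100 um, y = 200 um
#>        Vx      Vy
#> 1 -0.8002 1.30115
```

A command-line wrapper with the same functionality lives at
`inst/cli/rigkit.R`:

```sh
Rscript inst/cli/rigkit.R demo --out s1
Rscript inst/cli/rigkit.R task run s1/example_task.yaml --rig s1/rig.yaml
Rscript inst/cli/rigkit.R analyze patch --seed 2
```

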