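# mipqpi

Simulation and analysis tools for wide-field **mid-infrared photothermal
(MIP) quantitative phase imaging (QPI)** — a label-free microscopy in
which a nanosecond mid-IR pulse heats absorbing structures in a live
cell by a few kelvin, and the resulting thermo-optic phase shift of a
visible probe is read out holographically. The package is aimed at
instrument designers and analysts who need to (i) choose pulse
durations, probe delays and repetition rates from heat-conduction
physics, (ii) budget the phase precision of a high-full-well-capacity
off-axis holographic detector, and (iii) analyse the two headline
live-cell experiments this modality enables: aquaporin-mediated water
exchange and hyperspectral chemical unmixing.

## What it computes

**Thermal design.** The photothermal phase is
Δθ(x,y) = (2π/λ)(dn/dT)∫ΔT dz. Explicit FTCS solvers integrate
∂ΔT/∂t = ν∇²ΔT + q in spherical symmetry (a heated organelle-sized
sphere in water) and in an axisymmetric CaF₂/water/CaF₂ stack, with
energy-conserving conservative stencils, partial-volume sources, and
flux-continuous material interfaces. Abel projection turns radial
fields into image profiles, from which the design metrics follow:
resolution degradation vs pulse duration, signal decay vs probe delay,
the continuous-heating (steady-state) thermal spread, and the decay of
the excited spot that sets the usable repetition rate.

**Phase-noise budget.** For off-axis holography with sideband
reconstruction, the temporal phase noise of frame differences is

σ_phase = 2 √[(N_e + σ_sensor²) A_aperture / (v² N_e² A_sensor)]

with N_e electrons per pixel, fringe visibility v and the
aperture/sensor pixel counts of the Fourier crop. The package predicts
it, inverts it for v, and validates it end-to-end by Monte-Carlo
hologram synthesis and reconstruction.

**Water permeability.** During an H₂O/D₂O exchange imaged at 50 fps,
each pixel decays as A(h)·exp(−(t−t₀)/τ_ext) + (1−A(h))·exp(−(t−t₀)/τ),
where A(h) = (e^{−h/D_z} − e^{−L/D_z})/(1 − e^{−L/D_z}) is the
extracellular signal share for cell height h under Lambert–Beer
attenuation. Fitting τ per pixel and combining with QPI-derived
morphology gives the diffusional membrane permeability
P_d = 1/(τ·S/V).

**Spectral unmixing.** Hyperspectral MIP stacks are normalized
(beam profile, pulse energy) and factorized as H ≈ CS by alternating
non-negative least squares (MCR-ALS), with exact per-component
contribution maps R_i = C_iS_i/ΣC_jS_j · Δθ.

**Synthetic data.** Phantom cells with organelles, component spectra
(CH₂/CH₃/OH bands), exchange movies, and Poisson-noise hologram stacks
— each returning its ground truth, so every pipeline stage has a
round-trip test.

## Worked example

```r
library(mipqpi)

# How far does heat smear a 500-nm organelle during and after the pulse?
resolution_degradation(0.25, pulse_duration = 0.1)  # 100-ns pulse
#> [1] 1.312994
probe_delay_metrics(0.25, delays = c(0.01, 0.1), mir_duration = 0.01)
#>   delay radius_ratio phase_fraction
#> 1  0.00     1.044929      1.0000000
#> 2  0.01     1.137144      0.9454874
#> 3  0.10     1.686263      0.4791398
```

A 100-ns pulse inflates the e⁻² image radius of a 500-nm sphere by
1.31×; delaying the probe 100 ns after a 10-ns pulse inflates it 1.69×
and halves the signal (47.9% remains) — hence the design rule: ~10-ns
pulses, probe delay shorter than the pulse.

```r
# Phase precision of the 2M-electron camera
v <- infer_visibility(0.9, 3.6e5, sensor_2M(), aperture_diameter = 245)
v
#> [1] 0.7715645
cfg <- offaxis_config(aperture_diameter = 245, visibility = v)
predict_phase_noise(1e6, sensor_model(2e6, 11, 1.73, 0, c(1440, 1440)), cfg)
#> [1] 0.3908485   # mrad, shot-noise limit at full capacity
```

```r
# Membrane water permeability from printed morphology and decay time
permeability(420, S = 1404, V = 3779)
#> [1] 0.000640856   # cm/s

# ... and from a full synthetic exchange movie with 2% frame noise
ph  <- make_phantom_cell(size = 48, seed = 6)
gen <- make_exchange_series(ph, tau = 420, noise = 0.02, seed = 3,
                            t_range = c(-100, 1500))
fit_water_exchange(gen$series, ph$phase, lowpass_sigma = 2)
#> <permeability_result> P_d = 0.000499 cm/s (tau = 414 ms, S = 291 um^2, V = 600 um^3)
```

The vignette (`vignettes/mipqpi-methods.Rmd`) documents the models,
discretizations, conventions and known limitations.

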