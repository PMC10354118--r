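---
title: "Models and numerical methods in mipqpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in mipqpi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipqpi)
```

`mipqpi` models the physics and analysis chain of wide-field mid-infrared
photothermal (MIP) quantitative phase imaging (QPI): a nanosecond MIR pulse
is absorbed by a microscopic object in water, the local temperature rise
changes the refractive index through the thermo-optic coefficient dn/dT,
and a visible probe reads the resulting optical phase delay with an
off-axis holographic microscope. This vignette explains each model, its
assumptions, the numerical choices behind the implementation, and the
limitations a user should know about.

## Heat conduction after pulsed absorption

The temperature field obeys the heat equation with a source term
$$\frac{\partial \Delta T}{\partial t} = \nu \nabla^2 \Delta T +
  \frac{I\alpha}{\rho c_p},$$
where $\nu$ is the thermal diffusivity and the absorbed power density is
lumped into a volumetric deposition rate in K/µs. The observable is the
phase change
$$\Delta\theta(x, y) = \frac{2\pi}{\lambda}\frac{dn}{dT}
  \int \Delta T \, dz,$$
reported as a magnitude: water's dn/dT is negative ($-1.4\times10^{-4}$
K$^{-1}$ by default, configurable), but MIP phase-change images are
conventionally displayed positive. The dn/dT value only scales absolute
phases; every design metric below is a normalized ratio in which it
cancels.

Two geometries are implemented:

* **Spherically symmetric** (`solve_thermal_radial()`): a uniformly heated
  sphere of water-like material in water, for the pulse-duration and
  probe-delay design metrics. Material constants are
  $\nu = 0.146\ \mu m^2/\mu s$, $K = 0.618$ W m$^{-1}$ K$^{-1}$.
* **Axisymmetric layered** (`solve_layered_decay()`): a 10-µm water layer
  between CaF$_2$ windows ($\nu = 2.92\ \mu m^2/\mu s$, $K = 9.71$
  W m$^{-1}$ K$^{-1}$), impulsively heated with a Gaussian lateral profile
  (FWHM 91 µm) and an exponential axial deposition (1/e depth 16 µm,
  Lambert–Beer; a hard-cutoff alternative is selectable via
  `axial_cutoff`), for the repetition-rate design.

### Discretization

Both solvers use the explicit Forward-Time Centered-Space (FTCS) scheme in
conservative (flux) form, with the time step fixed at 40% of the stability
bound ($dt = 0.4\,dx^2/(2 d\,\nu_{max})$ for dimensionality $d$); an
explicitly supplied `dt` above the bound is refused with the computed
limit. In the radial solver, node $i$ owns the shell
$[r_i - dr/2,\, r_i + dr/2]$ and node 0 the central ball of radius
$dr/2$, which makes the $r = 0$ update the symmetric stencil
$6\nu(T_1 - T_0)/dr^2$ and conserves
$\int \rho c_p \Delta T\,dV$ to machine precision under adiabatic
boundaries (the test suite asserts this, and checks free diffusion of a
Gaussian against the closed-form width $\sigma^2(t) = \sigma_0^2 + 2\nu t$
to 1%). The heated sphere is discretized with partial-volume weights at
its rim, so the deposited energy matches $\frac{4}{3}\pi R^3$ bookkeeping
to a few tenths of a percent at the default resolution of 20 nodes per
sphere radius (40 in the acceptance script).

In the layered solver, material interfaces coincide with control-volume
faces and face conductivities are harmonic means, which enforces the flux
continuity condition $K_w \partial_z T_w = K_c \partial_z T_c$ discretely.
The solver was validated against a closed-form convolution oracle in the
material-identity limit (all layers water), where it agrees with the
analytic layer integral to better than 0.1%.

### Why the layered solver is axisymmetric, not 1D

The centre phase decays by conduction into the CaF$_2$ windows. Because
CaF$_2$ diffuses heat twenty times faster than water, the heat that
crosses the interface also spreads *laterally* under the 91-µm spot fast
enough to matter on the 100-µs scale: a purely axial (1D) model returns a
1/e decay time of ~97 µs and a 7% residual at 1 ms, while the full
axisymmetric solve returns 89.8 µs and a 1.9% residual (grid-converged to
0.2% between dz = 0.5/dr = 4 µm and dz = 0.25/dr = 2 µm). The package
therefore solves the (r, z) problem by default; setting
`lateral_fwhm = Inf` recovers the 1D axial limit for comparison. At these
numbers, the heated volume has relaxed almost completely after 1 ms,
supporting a ~1 kHz excitation repetition rate without thermal pile-up.

### Design metrics and their conventions

* `resolution_degradation()` — the e$^{-2}$ radius of the Abel-projected
  phase profile over the true sphere radius, probed at pulse end. The
  zero-duration limit is the projection geometry alone,
  $\sqrt{1 - e^{-4}} \approx 0.991$. For the 500-nm sphere at 100 ns the
  solver gives 1.31, matching an independent Green's-function evaluation
  (1.3112) to 0.1%.
* `probe_delay_metrics()` — the same radius ratio plus the centre phase
  relative to zero delay, after a 10-ns pulse and a free-diffusion delay.
  At a 100-ns delay the exact-diffusion values are 1.684 and 48.0%; the
  solver reproduces both to 0.1%. The normalization uses the centre of
  the projected phase image.
* `cw_resolution_limit()` — under continuous heating the temperature
  approaches the conduction steady state, whose far field falls off as
  $1/r$. The line integral of $1/r$ diverges logarithmically, so the
  *projected phase* image has no finite e$^{-2}$ radius in this limit
  (numerically its radius keeps growing ~30% per doubling of duration
  with no plateau). The continuous-heating spread is therefore quantified
  on the temperature field itself: the steady state of the discretized
  operator is obtained by a direct tridiagonal solve with a Dirichlet
  (bath) far boundary, and its e$^{-2}$ radius is ~4.9 sphere radii
  (the infinite-medium closed form; finite bath radii give slightly
  less, with a weak logarithmic dependence on the bath radius — the
  default is 200 sphere radii).
* `saturation_onset()` — the projected centre phase retains the same
  logarithmically growing halo term, so saturation is quantified on the
  centre temperature. The default definition is half-saturation: the
  first duration at which further heating adds less than half of what an
  unsaturated (linear) response would add, ~0.11 µs for the 500-nm
  sphere. By the diffusion scaling $(r, t) \to (sr, s^2t)$ the onset
  time scales exactly with the sphere radius squared, which the tests
  assert; the choice of threshold does not affect that scaling.

Microscope resolution is deliberately not applied to simulated phase maps,
and convection, radiation and temperature-dependent material properties
are outside the model. The sphere simulations ignore background water
absorption (the wide, shallow background temperature profile adds a
near-constant offset over a sub-µm object).

## Off-axis holography and the phase-noise budget

The forward model of the camera frame is
$I(x) = N_e[1 + v\cos(2\pi k\cdot x + \phi(x))]$ scaled to a mean of
$N_e$ electrons per pixel, with Poisson shot noise, Gaussian read noise
$\sigma_{sensor}$, and optional ADC quantization (round-half-even;
clipping at full well warns rather than fails). Reconstruction is the
standard Fourier sideband method: a hard circular crop of diameter $D$
centred on the carrier — the pixel-count convention is
$A_{aperture} = \mathrm{round}(\pi D^2/4)$, so 245 px → 47,144 and
201 px → 31,731 — recentred and inverse-transformed, with the phase taken
as the principal value (no spatial unwrapping). No apodization is applied,
matching the pixel-count bookkeeping; carriers are specified explicitly
and must lie outside the aperture radius.

The temporal phase noise of adjacent-frame differences follows the closed
form
$$\sigma_{phase} = 2\sqrt{\frac{(N_e + \sigma_{sensor}^2)\,A_{aperture}}
  {v^2 N_e^2 A_{sensor}}},$$
whose prefactor combines the $\sqrt2$ of the frame difference with the
$\sqrt2$ quadrature split of complex noise. `infer_visibility()` inverts
this for the fringe visibility at a stated operating point (0.9 mrad at
$N_e = 3.6\times10^5$ with $\sigma_{sensor} = 572$ e$^-$ gives
$v = 0.772$); inversions implying $v > 1$ — a claimed noise below the
shot limit — are rejected. Monte-Carlo experiments
(synthesize → reconstruct → measure, 16–24 frames at 128–256 px) agree
with the closed form to a few percent across $v \in [0.5, 1]$,
$N_e \in [10^3, 10^5]$ and $\sigma_{sensor} \in \{0, 572\}$; the
acceptance suite runs the full grid at a 10% gate. Speckle, aberrations
and timing jitter are not modelled.

Random streams: a hologram stack uses one integer seed; frame $f$ draws
from the substream `seed*1000 + f`, so stacks are reproducible and frames
independent (tested via adjacent-frame correlation).

## MIP image formation

A MIP image is the ON−OFF phase difference of a chopped frame stream
(`demodulate_stream()` pairs alternating frames; the image rate is half
the sensor rate). Subtracting a water-only MIP background reveals
intracellular contrast and inflates noise by $\sqrt2$ (asserted over 100
synthetic realizations); dividing by the peak-normalized water image
flattens the excitation-beam envelope, with pixels below 5% of the water
maximum masked to `NA` (configurable) because the division would amplify
noise at the beam skirts. SNR reports use the spatial standard deviation
of a 20 × 20 pixel box as the noise. Boxes and pixels are addressed
1-based, `(row, col)` with origin + size, the R convention. The noise-box
location is a required input — there is no canonical placement. Frame
registration and drift correction are not implemented (the common-path
design is assumed stable).

## Water-permeability analysis

During an H$_2$O/D$_2$O exchange, each pixel's MIP trace, normalized to
its pre-exchange plateau, follows the two-compartment model
$$I(t) = A(h)\,e^{-(t-t_0)/\tau_{ext}} + (1 - A(h))\,e^{-(t-t_0)/\tau},$$
where the contribution ratio
$$A(h) = \frac{e^{-h/D_z} - e^{-L/D_z}}{1 - e^{-L/D_z}}$$
is the extracellular share of the signal for a cell of height $h$ in a
channel of depth $L = 20$ µm under Lambert–Beer attenuation with
$D_z = 6.73$ µm (3014 cm$^{-1}$). The test suite checks $A$ against
direct numerical integration of its defining integrals to $10^{-10}$.

Heights come from the MIR-OFF phase image via
$h = \phi\lambda/(2\pi\,\Delta n)$ with the literature index difference
$\Delta n = 0.0323$, low-pass filtered with a Gaussian of $\sigma = 5$ µm
(the filter scale is a free choice — only "low-pass" is physically
required — and is configurable; heights are clipped to the channel
depth). The extracellular constants $(t_0, \tau_{ext})$ are pre-fitted on
a cell-free region with $A = 1$. The per-pixel fit then has a single free
parameter, $\tau$, minimized by bounded scalar least squares on
$\log\tau$ over (10, 5000] ms — a golden-section search, which needs no
derivatives and cannot diverge. Fitting starts at 120 ms by default, past
the liquid-exchange agitation artifact near 100 ms (configurable). Pixels
with $A > 0.99$ carry no identifiable intracellular amplitude and are
flagged; the cell mask defaults to $h > 0.5$ µm.

Morphology integrals use central differences:
$S = \sum\sqrt{1 + h_x^2 + h_y^2}\,\Delta x\Delta y$ and
$V = \sum h\,\Delta x\Delta y$ (hemisphere test solids agree with the
closed forms to 3%; the rim of a hemisphere has an integrable gradient
singularity that dominates the remaining error). The permeability is
$$P_d = \frac{1}{\tau\,(S/V)},$$
converted to cm/s (1 µm/ms = 0.1 cm/s); the printed morphology
($\tau = 420$ ms, $S = 1404$ µm$^2$, $V = 3779$ µm$^3$) gives
$6.4\times10^{-4}$ cm/s. On synthetic cells with 2% frame noise the whole
pipeline (phase → height → $A$ → $\tau$ map → $S, V$ → $P_d$) recovers a
known permeability within 10%. Osmotic permeability and inhibitor
comparisons are out of scope.

## Hyperspectral unmixing (MCR-ALS)

A hyperspectral MIP stack (one image per wavenumber, 40 wavenumbers over
2800–3250 cm$^{-1}$ by default) is first normalized: per-wavenumber
beam-profile division by the water-only stack and scaling by the
pulse-energy ratio $E(k_{ref})/E(k)$. The pixels-by-wavenumbers matrix is
then factorized as $H \approx CS$ with non-negative concentration maps
and spectra by alternating exact non-negative least squares: each
alternation solves the unconstrained problem first and refines only the
rows that violate non-negativity with Lawson–Hanson NNLS (an active-set
method, deterministic and parameter-free). The residual is non-increasing
by construction; iteration stops when its relative change falls below
$10^{-8}$ (or it reaches the data's numerical floor), capped at 500
iterations. Components keep their initialization order; permutation
matching is used only in tests. Three components (CH$_2$-dominated lipid,
CH$_3$-dominated protein, OH-dominated water) are the default.

Initial spectra come from user regions: lipid-droplet and nucleolus
regions on the background-subtracted stack, an extracellular region on
the raw stack (its spectrum *is* the water background). A fitted model
distributes the raw signal among components as
$$R_i(x,k) = \frac{C_i(x)S_i(k)}{\sum_j C_j(x)S_j(k)}\,\Delta\theta(x,k),$$
which conserves $\sum_i R_i = \Delta\theta$ exactly wherever the model is
nonzero; all-zero-model entries are flagged `NA`.

A caveat the tests make explicit: with only non-negativity constraints,
the factorization carries a rotational ambiguity unless the scene
contains (near-)pure pixels for each component. Recovered spectra match
ground truth by cosine similarity > 0.999 on noiseless mixtures, but
pointwise contribution maps are only pinned when pure pixels exist —
which they do in real cell images (extracellular water, droplet cores)
and in the default generator.

## Synthetic data: what it emulates and what it does not

The generators give every pipeline stage an input with known ground
truth: a dome-shaped phantom cell (256 × 256 px at 0.44 µm/px by default,
a 110-µm field) with disjoint organelle masks and extranuclear lipid
droplets; three-component spectra with the CH$_2$ 2854/2925 cm$^{-1}$
doublet, a CH$_3$ 2945 cm$^{-1}$ band and a rising OH band (peak widths
at or above the ~10 cm$^{-1}$ source linewidth); exchange series at
50 fps generated directly from the two-compartment decay model with
$t_0 = 99$ ms and $\tau_{ext} = 82$ ms; and Poisson-noise hologram
stacks. Signal scales follow the measured regime (tens of mrad of MIP
phase at lipid droplets against ~1–2 mrad noise).

Passing tests on these inputs demonstrates that the *algorithms* are
correct under the model's own assumptions. They do not demonstrate
robustness to what the generators omit: optical diffraction and the
microscope transfer function, speckle, focus drift, halo artifacts,
non-exponential exchange kinetics, or spectral distortion by the strong
water background. The decay-model generator and the decay-map fitter
share the biexponential family by design — that round trip validates the
estimator, not the model.

## Problem sizes and runtimes

Defaults were chosen so the whole suite runs comfortably on one CPU: the
radial solver uses 20 nodes per sphere radius in tests and 40 in the
acceptance script (the Fig-style metrics move by <1% between the two);
the layered solve uses dz = 0.5 µm, dr = 4 µm over a 410 × 300 µm
half-plane (~6 × 10$^4$ nodes, ~2 × 10$^4$ steps, a few seconds in
compiled code); Monte-Carlo noise checks use 16–24 frames of 128–256 px;
synthetic cells in tests are 32–96 px. All stochastic results derive
from explicit integer seeds.
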