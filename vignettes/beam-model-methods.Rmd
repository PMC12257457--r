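---
title: "Convolution-based beam modeling and simplified Monte Carlo transport: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolution-based beam modeling and simplified Monte Carlo transport: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

beamforge implements a machine-agnostic, measurement-driven photon beam
model for independent Monte Carlo dose calculation, together with the
automatic commissioning workflow that fits it from standard water-phantom
beam data and a simplified voxel transport engine to exercise it end to
end.  This vignette is the package's account of the science: the model,
its parameters, the numerical choices, what the synthetic test machine
does and does not emulate, and the known limitations.

## The model

A treatment beam is represented by four commissioned components:

1. **Energy spectrum** `g(E)` — a binned photon spectrum.  Starting from a
   packaged representative 6 MV table `g0(E)` (any spectrum of a similar
   nominal energy will do), a single slope parameter `s` (per MeV) adjusts
   it:

   `gs(E) = g0(E) (1 + s (E - Ebar))`, with `Ebar` the mean of `g0`.

   The adjustment is linear in `E - Ebar`, so the total weight is conserved
   exactly and the mean energy shifts by `s Var(g0)`; positive `s` hardens
   the beam.  The admissible range of `s` is set by positivity of the
   multiplicative factor on every bin (about (-0.23, 0.7) per MeV for the
   packaged table); commissioning searches the conservative default
   interval (-0.15, 0.15).

2. **Electron contamination weight** `we` — contaminant electrons are
   modeled as carrying the same energy fluence as the photons; their dose
   component `De`, normalized to its maximum, is added to the photon
   component as `D = Dx + we De`.  Electron contamination mainly affects
   the buildup region.

3. **Off-axis scale (OAS)** `C(x, y)` — the open-field fluence of the
   largest field normalized to the central axis, a circularly symmetric
   2-D map on the SAD plane (1 mm pixels) built from the measured
   diagonal profile and refined once against a calculated profile.

4. **Collimator-scatter kernel** `K(x, y)` — a circularly symmetric
   convolution kernel encoding the machine's output factors.  Its defining
   property is that the convolved fluence at the center of a collimated
   field equals the in-air output factor of that field:

   `Sc(fx, fy) = int int_field K(x, y) C(x, y) dx dy`.

Plan fluence is computed per beam on the SAD plane at 1 mm resolution in
three steps: segment intensity `I = sum_i Mi Ti` with the tongue-and-groove
factor `alpha = 0.75` on aperture-boundary pixels along y (leaf motion is
along x; boundary width one pixel) and a leakage factor `beta = 0` outside
the aperture; off-axis scaling `I <- I C`; and convolution `f = I (x) K`.
Energy-weighting with `g(E)` yields the separable density the particle
source samples from, and a point source at the SAD back-projects each
particle to a start plane 5 cm above the phantom surface.

## Commissioning

The four parameters are fitted in a fixed order — spectrum, electron
weight, OAS, kernel — because earlier factors depend least on later ones.
All forward calculations run at 10^6 photon histories with fixed per-stage
seeds, on a water phantom sized to the largest field plus a 5 cm margin
per side and 32 cm depth, at 2 mm voxels.  Central-axis depth curves are
averaged over a 1.4 x 1.4 cm chamber-like region; point doses (output
factors, phantom scatter) over a 1 cm^3 central block.

**Spectrum.**  The slope minimizes the trapezoidal mean-square deviation
between the calculated and measured 10 x 10 cm^2 PDD over the falloff
region (depths at or beyond d_max), with a free least-squares scale factor
on the calculated curve, using bounded Brent search (absolute tolerance
1e-3 on `s`).  Two departures from the naive "integrate everything"
objective deserve explanation.  The free scale removes the arbitrary
max-100 normalization: the measured maximum contains the
electron-contamination contribution while the photon-only forward curve
does not, and without the scale this mismatch leaks into the fitted slope.
Restricting the fit to depths beyond the contaminant-electron practical
range (5 cm and beyond, or d_max + 2 cm if larger) keeps the
electron-contaminated shallow region — which the spectrum stage cannot
yet model, and which is fitted by the next stage — out of the objective;
in closed-loop experiments the contaminated buildup biased the recovered
slope by about -0.03 per MeV and the contamination tail between d_max
and its practical range by a further +0.01, while the restricted fit
recovers the slope to within a few thousandths.  (A log-dose variant of
the objective is also provided; it weights the deep region more strongly
and proved more sensitive to residual model mismatch there, so the
linear form is the default.)

**Electron weight.**  The photon-only curve at the fitted slope is scaled
onto the measured PDD by least squares over depths of 5 cm and beyond
(past the contaminant-electron practical range), and the buildup
discrepancy at depths up to d_max is attributed to electrons: a
closed-form nonnegative least-squares weight against the max-normalized
electron depth curve, divided by the tail scale so that a noiseless loop
recovers the true weight exactly.

**OAS.**  The initial map rotates the measured diagonal profile about the
axis, after the standard dose-to-incident-fluence divergence correction
(off-axis points lie farther from the point source, so the dose profile
is multiplied by `1 + (r/SAD)^2` before use as a fluence map).
Refinement multiplies the map by the radial ratio of measured to
calculated diagonal profiles.  By default this single refinement runs
after the kernel stage with the convolution included, and the kernel is
re-derived on the refined map: the measured diagonal contains the
collimator scatter the kernel models, so refining against a
convolution-free calculation (available through `oas_iterations`) folds
that scatter into the OAS and double-counts it once the kernel is
applied.  Several numerical choices
keep this refinement stable at the 10^6-history budget: the calculated
profile is extracted by annulus averaging over the full plane (the model
OAS is circularly symmetric, so this is exact and suppresses Monte Carlo
noise far below a single line-out) and normalized to the mean over the
central 1 cm disk rather than the single axis pixel (a lone pixel's
statistical error would rescale the whole curve); both the measured and
calculated profiles pass through the identical in-field smoothing and
axis normalization; the consistency-pass calculation is averaged over
three independent runs; and the measured/calculated ratio is fitted with
an annulus-count-weighted quadratic in radius over the field interior
only.  The interior restriction matters because the initial map, seeded
from a measured dose profile, carries the penumbra, which the calculated
profile applies a second time — the tail ratio is steep and large and
would wreck any global fit — and the weighting matters because the
innermost annuli average only a handful of voxels, right where the map is
renormalized to 1.

**Kernel.**  Phantom scatter `Sp` is calculated per measured field with
the convolution omitted, `Sc = Scp / Sp` (both normalized to 10 x 10), the
square-field values are interpolated with a monotone Hyman spline anchored
at `Sc(0) = 0` and extended to rectangles by the equivalent square
`sqrt(fx fy)`.  The unscattered component is split off first: the in-air
factor extrapolated linearly to zero field size from the two smallest
measurements becomes a central impulse (the primary fluence passes the
collimators unconvolved), because pure differencing can only localize
that sharp component to the scale of the smallest measured field, which
would blur every calculated penumbra by about a centimetre.  The scatter
tail then follows from the mixed second field-size difference of the
residual surface sampled at twice the kernel coordinate — the
field-corner convention under which the integral equation round-trips —
divided by the OAS.  Noisy extracted `Sc` values are projected onto the
nondecreasing cone (isotonic regression) before interpolation.

Three numerical details of the kernel derivation matter.  First, on the
axes the difference stencil is shifted one-sided so it never samples
negative field sizes (a centered stencil clamped at zero halves the axis
values).  Second, the equivalent-square surface has a mixed derivative
that is a function of `fx fy`, i.e. not radial; circular symmetrization of
the raw difference map redistributes its axis ridges and breaks the
integral equation at the percent level.  The derived kernel is therefore
recalibrated: radial bands bounded by half the measured field sizes are
rescaled (or, where clipping emptied a band, given a flat plateau)
band-by-band, alternating with an isotonic radially-nonincreasing
projection of the tail, until the integral over every measured field
reproduces its `Sc` (to < 0.1%) and the radial falloff is monotone.
Third, the data constrain the kernel only at the measured-field
resolution: the sharp central component cannot be localized below the
smallest measured field, so pointwise comparisons with a ground-truth
kernel are made relative to the kernel peak.

## Transport engine

The engine is a deliberately simplified voxel Monte Carlo written for
closed-loop testing of the beam model, not a clinical dose engine.  All
media are water with density scaling; packaged attenuation, energy
absorption and stopping-power tables cover 0.01–10 MeV.

*Photons* undergo analog interaction sampling — Compton scattering from
Kahn's Klein–Nishina rejection method, with photoelectric absorption and
pair production lumped into local absorption — but dose is scored with a
track-length collision-kerma estimator: every flight segment deposits
`E mu_en(E) / V` per unit track length.  To reproduce the buildup region
in this expected-value mode, primary-fluence deposits are advanced along
the flight direction by half the CSDA range of the mean Compton electron
(the mean forward displacement of the secondaries); the spectrum's mix of
ranges smooths the resulting ramp.  Scattered-photon kerma is diffuse and
deposited locally.  Multiply-scattered photons (second generation and
higher) undergo unbiased 50% survival roulette with a weight cap of 8 —
without the cap, rare long low-energy chains carry exponentially growing
weights and deposit pathological local blobs.  Analog secondary-electron
transport is available as an engine option (`transport_secondaries`) and
is used in the energy-bookkeeping tests; it is far noisier at equal
histories, which is why expected-value scoring is the default for
commissioning.

*Electrons* use condensed-history steps (1 mm) under the continuous
slowing down approximation with Highland multiple scattering and, when a
magnetic field volume is present, a first-order Lorentz deflection
`v' = normalize(v + (s/R) (v x B)/|v x B|)` with `R` the relativistic
gyroradius of the perpendicular field component.  The field is defined on
the phantom grid and vanishes outside it.  Cutoffs are 10 keV (photons)
and 100 keV kinetic (electrons), with simple termination and local
deposition below cutoff.

Per-voxel statistical uncertainty comes from 10-batch statistics.
Randomness comes from self-contained xoshiro256+ generators seeded
through splitmix64, with an independent substream per history: rejection
sampling consumes a variable number of draws, so a single shared stream
would decohere every downstream history after any parameter change,
which destroys the common-random-numbers smoothness the spectrum
optimizer relies on.  Every calculation is bit-identical for a given
seed on any platform.

Particle positions are sampled from the fluence by inverse-CDF
(independence) sampling by default.  A Metropolis–Hastings backend
(Gaussian pixel-jump proposal, sigma 5 mm, 1000-sample burn-in, single
chain) is provided and agrees with the target distribution in total
variation; it is not the default because a 5 mm random walk over a
~400 mm fluence map mixes in O((L/sigma)^2) steps, which inflates the
effective Monte Carlo variance well past what the closed-loop gamma
budget tolerates.

## The synthetic golden machine

Because no public machine measurements ship with the package, a "golden
machine" generates the commissioning triplet from known ground truth: a
true slope (0.03 per MeV) applied to the packaged spectrum, a true
electron weight (0.04), a polynomial off-axis scale
(`1 + 0.002 r - 1e-4 r^2`, a mildly non-flat profile), and a true kernel
consisting of a central impulse (mass 0.95) plus an exponential tail
(mass 0.05, range 1 cm) — the smallest family with the sharp central drop
real kernels show.  Geometry is SAD = SSD = 100 cm, reference depth
10 cm, largest field 20 x 20 cm^2, output-factor fields 2/3/5/10/20 cm.
The PDD and diagonal profile are calculated by the same engine used in
commissioning (so recovery tests isolate the commissioning mathematics
from physics fidelity), the in-field part of the diagonal is
spline-smoothed as a scanned measurement would be, and the output factors
combine the analytic kernel integral with engine-calculated phantom
scatter, `Scp = Sc* x Sp`, normalized to 10 x 10.  Optional multiplicative
Gaussian noise emulates measurement scatter; if it breaks output-factor
monotonicity the table is redrawn with a warning.

Study conditions, chosen once: the generated 10 x 10 reference PDD — the
curve the spectrum slope is tuned against — uses 4 x 10^6 photons; all
other generated and closed-loop validation curves use 2 x 10^6 photons
and 2 x 10^5 electrons (the desk-scale analogue of the 10^9–10^10
histories a production engine would use); commissioning forwards use
10^6 photons; phantom-scatter and output-factor points use a 14 cm deep
phantom (only the region above and somewhat below the 10 cm reference
depth matters for a central-axis point dose) averaged over a central
block whose half-width grows with field size up to 1.5 cm (capped at a
quarter of the field side).  The adaptive block matters: every primary
through the block is near-vertical, so the point-dose estimator is
limited by the number of rays through the block's footprint — a fixed
1 cm^2 block in a 20 x 20 cm^2 field sees only ~2 500 rays per 10^6
histories (2% noise), while the wide flat center of a large field
supports a wider chamber at no bias.  The same block definition is used
wherever output factors or phantom scatter are computed, so the
convention cancels in closed loops.  Output factors in the generated
beam data are full-model central-dose ratios — what an ion chamber
measures — rather than the separable in-air x phantom-scatter product,
which differs from the full calculation by a percent-level coupling at
large fields.  Cross-profiles of the symmetric open field are
averaged over the two lateral directions and mirrored, which quarters
their Monte Carlo variance.

What passing closed-loop tests shows — and what it does not.  The loop
validates the commissioning mathematics: that the four-stage workflow
recovers spectrum slope, electron weight, off-axis scale and
output-factor-consistent kernel from curve data produced by the same
forward model, at realistic statistical noise.  It cannot certify the
simplified engine's absolute dosimetric fidelity against real water-tank
data: the engine omits material composition, bremsstrahlung, annihilation
photons and in-air contamination buildup, and its buildup shape comes from
a first-order kerma-displacement model.  Real measured data would exercise
the same code paths but stress the physics, not just the fitting.

## Degenerate inputs and tie-breaks

Aperture masks that rasterize to nothing produce a warning and zero
fluence.  PDDs are renormalized to max 100 on construction; depths must be
strictly increasing and reach 30 cm.  Output-factor tables must contain
the 10 x 10 entry and be strictly increasing; the commissioned `Sc` is
isotonically projected instead when statistical noise inverts near-equal
neighbors.  The deep reference point breaks ties by the lowest flat index.
Gamma searches are exhaustive within 3x the DTA radius: at quarter-DTA
steps in 1-D (effectively exact; the brute-force comparison in the test
suite agrees to the search resolution) and quarter-voxel steps in 3-D,
exactness at desk scale being preferred over speed.

## Limitations

Gantry angle is recorded per beam but transport is along the beam axis in
BEV coordinates; multi-beam plans are summed on a common grid without
rotating the phantom.  Leaf-tip and rounded-leaf-end effects are folded
into the uniform leakage factor.  The kernel is a single composite
point-spread function; source occlusion and jaw-vs-MLC scatter are not
separated.  Wedges, blocks and dynamic-leaf interpolation between control
points are out of scope.
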