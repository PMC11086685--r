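---
title: "Methods: microwheel physics, aerosol partition statistics and the synthetic benchmarks"
author: "aerowheel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microwheel physics, aerosol partition statistics and the synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerowheel)
```

# The system

Superparamagnetic beads (4.5 µm diameter, density 1.5 g/cm³) suspended in
a liquid film assemble, under a weak rotating magnetic field, into
disk-shaped clusters — microwheels — that spin with the field and, when
the rotation axis is cambered off the surface normal, roll along the
surface. Because the individual beads are small enough to ride in
nebulized droplets, wheels can be delivered to the airway as an aerosol
and assembled *in situ*. This package implements the quantitative chain
behind that route: the torque-balance model of wheel motion, the
statistics of partitioning beads into droplets, synthetic benchmarks for
the two measurement pipelines (droplet macroscans and particle tracking),
and a minimal routing model for heading-controlled transport through a
branching airway.

# Torque-balance model

A rotating field of strength $H$ exerts a time-averaged torque on an
$N$-bead wheel

$$\tau_m = N \nu \mu_0 \chi'' H^2,$$

with $\nu$ the single-bead volume and $\chi''$ the imaginary
(out-of-phase) part of the magnetic susceptibility. The hydrodynamic
resistance of the spinning wheel is approximated by the rotational drag of
a thin disk of radius $R$,

$$\tau_v = \tfrac{32}{3}\,\eta\,\omega R^3,$$

and equating the two gives the steady rotation rate

$$\omega = \frac{3 N \nu \mu_0 \chi'' H^2}{32\,\eta R^3}.$$

Wheel radius is estimated from planar packing: the disk area $\pi R^2$
holds $N$ bead cross-sections, so $R = a\sqrt N$ with $a$ the bead radius.
Substituting gives the three size scalings the model is used for:
$\omega \propto 1/R$, $P = \tau\omega \propto R$, and — through the
wet-friction rolling coupling $V = \beta\,\omega N$ — $V \propto R$:
larger wheels are faster and more powerful. All three are verified to
$10^{-9}$ relative over $R \in [5, 40]$ µm by the test suite, and the
torque balance itself to $10^{-12}$ over randomized parameter sweeps.

Assumptions worth keeping in mind: the disk-drag form ignores wall
lubrication corrections; $\omega$ is the wheel's actual steady rate, with
no synchronous-rotation or step-out model tying it to the field frequency
$2\pi f$; and no magnetophoretic (field-gradient) forces are included —
the method is expressly a weak-uniform-field one.

## Parameters

| Parameter | Symbol | Default | Why |
|---|---|---|---|
| flux density | $B$ | 3.4 mT | translation-study field amplitude; $H = B/\mu_0$ (vacuum/dilute-suspension relation) |
| frequency | $f$ | 40 Hz | the fixed drive frequency; informational in the model (see above) |
| rotation axis | $\hat\Omega$ | $[0, \cos(\pi/6), -\tfrac12]$ | cambered axis that rolls wheels in $+x$ |
| bead diameter | $2a$ | 4.5 µm | epoxy Dynabead class |
| bead density | $\rho$ | 1.5 g/cm³ | same |
| imaginary susceptibility | $\chi''$ | 0.1 | vendors do not quote it; order-of-magnitude typical for these beads. It is a config key, and `fit_scaling()` recovers it from data |
| viscosity | $\eta$ | 1 mPa·s | water |
| coupling length | $\beta$ | 0.05 µm | sets $V = \beta\omega N$; chosen so that typical wheels ($N \approx 7$–$300$) roll at tens to hundreds of µm/s, the experimentally observed range. Only the proportionality is physical |

`rolling_direction()` maps the axis to the in-plane rolling heading by a
$-90^\circ$ rotation of the axis's $xy$ component; the sign is fixed so
the default axis yields $+x$, which also fixes the convention that an
axis tilted along $+x$ rolls toward $-y$. If a coil system uses the
opposite handedness, negate the result. The default axis makes a
$60^\circ$ angle with $-z$ even though the camber is nominally described
as $30^\circ$; the axis vector, not the angle, is taken as authoritative
since only it enters the model.

# Aerosol partition statistics

A jet nebulizer is rated by its mass median diameter (MMD, default
3.5 µm); droplet numbers follow a lognormal distribution, for which the
count median diameter obeys the Hatch–Choate relation
$\mathrm{CMD} = \mathrm{MMD}\,e^{-3\ln^2\sigma_g}$. The geometric
standard deviation is not part of the nebulizer rating; $\sigma_g = 2.0$
is used as a typical jet-nebulizer value, and both are config keys.

Beads at number concentration $c$ partition into droplets as a Poisson
process on droplet volume (dilute, well-mixed):
$\mathrm{count}_i \sim \mathrm{Poisson}(c \tfrac{\pi}{6} d_i^3)$. The
expected fraction of droplets holding at least one bead,
$E[1 - e^{-cV(d)}]$, is evaluated by adaptive quadrature over the
lognormal (relative tolerance $10^{-9}$, integrating in the
standard-normal variable so the tails are handled well); the test suite
checks it against direct Monte-Carlo seeding across a
$\sigma_g \times c$ grid at three binomial standard errors. Two physical
effects are deliberately ignored in the Poisson model — excluded bead
volume and any correlation between droplet size and capture probability —
except for a hard fit constraint: a droplet smaller than the bead cannot
contain it, so such counts are forced to zero (flag on by default).

Deposition is summarized by the standard aerodynamic-diameter regimes
($d_a = d\sqrt{\rho/\rho_w}$): above 5 µm particles impact in the upper
airway, 0.1–5 µm particles sediment in the conducting airways (the 1–5 µm
therapeutic window), sub-0.1 µm particles penetrate deep but are mostly
exhaled, and only ~10 nm particles reach the alveoli by diffusion. A
4.5 µm bead of density 1.5 has $d_a = 5.5$ µm — just above the window,
which is exactly why delivery as droplet-borne single beads with *in
situ* assembly is attractive.

# Synthetic macroscans

`generate_macroscan()` emulates a stitched brightfield survey of droplets
sprayed into oil: circular droplets from the lognormal population,
rendered as bright disks (interior 210, rim 160 on a background of 100,
8-bit) with dark (20) beads, plus additive Gaussian noise
($\sigma = 3$ grey levels) and 0.323 µm/px sampling (20× objective
class). Droplets are laid out largest-first by rejection sampling with a
cell-list search, in a field sized for a 6% packing fraction; residual
overlap above a 2% area budget triggers regeneration in a larger field.
Ground truth is recorded exactly, and the generator is a pure function of
its arguments and seed.

Two seeding modes are provided. The *Poisson* mode is the physical model
above. The *Bernoulli* mode seeds each recordable droplet (diameter
≥ 1 µm, i.e. above the 0.5 µm radius recording floor used downstream)
with exactly one bead at a prescribed probability; it exists for
pipeline-recovery benchmarks where the bead-containing fraction among
recorded droplets is the quantity being recovered, and it makes the
post-floor detected fraction an unbiased estimator of the seeded
probability. In both modes a droplet that captures a bead is given a
liquid envelope of at least 1.45× the bead diameter: a 4.5 µm bead cannot
sit in a smaller droplet, and the ~1 µm shell also keeps the bright rim
optically resolvable at this pixel size. Bead centres are
rejection-sampled to stay fully inside the host with the rim unbroken,
and sibling beads keep two pixels of separation when space permits.

What the generator does *not* emulate: diffraction and depth-of-field
blur, illumination gradients and stitching seams, droplet coalescence in
the oil layer, and merged/touching droplets beyond the small overlap
budget. Passing the recovery benchmarks therefore demonstrates that the
analysis chain is unbiased and correctly plumbed, not that it is robust
to every artifact of real macroscans. Bead appearance (dark on bright) is
a rendering decision.

# Macroscan analysis

`segment_droplets()` binarizes with a global Otsu threshold (a fixed
threshold is available for reproducibility studies), fills holes so
embedded dark beads do not bite into droplet areas, labels connected
components (EBImage) and reports equivalent-circle radii from pixel
areas, dropping detections with radius < 0.5 µm — the recording floor of
the measurement this emulates. Touching droplets are not split; the
generator's overlap budget keeps that regime rare, and no declumping is
attempted. `detect_beads()` thresholds dark pixels and keeps components
whose equivalent diameter is within ±25% of the bead diameter — so two
genuinely overlapping beads merge into one over-sized component and are
dropped, a known limitation that the Bernoulli benchmark mode sidesteps
by construction.

`assign_beads()` gives each bead to the droplet circle containing its
centre (nearest centre on overlap, lowest id on exact ties), or to the
nearest droplet within one bead radius of its edge, else leaves it
unassigned; the rule is deterministic and input-order invariant. The
bead-containing fraction is reported over detected (post-floor) droplets;
that denominator choice is part of the package's definition of the
statistic. Coordinates put pixel centres at half-integer physical
positions, origin at the image top-left, $x$ right, $y$ down, all in µm.

# Synthetic tracks and track analysis

`generate_tracks()` writes the table a particle-tracking pipeline would
produce — per frame: position, equivalent diameter, orientation — for
three object classes: wheels obeying the torque-balance model (bead
counts log-uniform over [5, 320], i.e. radii ≈ 5–40 µm), stuck objects
drifting below 3 µm/s, and 4.5 µm monomers. Orientation is reported
wrapped to $(-\pi,\pi]$, as a tracker would measure it; the default
200 fps over 1 s keeps the per-frame phase step below $\pi$ for all
default parameter combinations (the generator warns when a configuration
would alias). Localization noise defaults: 0.1 µm in position
(≈ 1% of a typical radius), 0.1 rad in orientation, 0.05 µm in diameter.

`measure_objects()` recovers speed as the magnitude of the straight-line
position-versus-time fit, diameter as the per-frame median, rotation rate
as the slope of the unwrapped phase, and power as the viscous-disk
estimate $(32/3)\eta\omega^2 R^3$. The exclusion filter then removes the
two nuisance classes with the standard thresholds: velocity < 5 µm/s
(stuck) or diameter < 6.75 µm (monomer). The two rules are read as
per-class criteria joined by OR — an object failing either is excluded —
because each class is defined by its own single criterion; an AND mode is
provided for comparison. Thresholds use strict `<`, so boundary objects
are kept. The filter is idempotent.

`fit_scaling()` fits $V$–$R$, $P$–$R$ and $\omega$–$1/R$ by least squares
through the origin — the model's claims are proportionalities, so a free
intercept is offered only as a diagnostic — and inverts the
$\omega$–$1/R$ slope for the susceptibility:
$\chi'' = 32\eta a^2\,\mathrm{slope}_\omega / (3\nu\mu_0 H^2)$. With 200
wheels at the default noise, the median relative error of $\hat\chi''$
over 20 seeded replicates is below 5% (acceptance suite). Reported $R^2$
is the uncentered version appropriate to through-origin fits.
`compare_populations()` adds a seeded bootstrap (2000 resamples by
default) on the difference of $V$–$R$ slopes, quantifying the pre/post
aerosolization comparison that is otherwise made visually.

# Airway routing

`build_tree()` makes a symmetric planar binary tree: inlet diameter 8 mm
(infant trachea scale), child/parent diameter and length ratios 0.78 (a
standard regular-dichotomy value), branching half-angle 35°. `route()`
rolls a wheel at constant speed, choosing at each bifurcation the child
edge best aligned with the current rolling direction (ties to the lower
child id), with the heading supplied by a timed schedule of field axes;
the plan running out, or an uncambered axis, returns a partial path. The
model is 2D and horizontal — gravity, inclines, mucus rheology and
magnet-capture bolus formation are out of scope — and bronchial transit
times are *reported*, not asserted, because physical path lengths of any
particular printed model are not part of the package. The image-frame
meaning of "lower branches" ($-y$ here) is a convention; reflecting the
in-plane heading reflects the routed path, which the tests verify.
`viscosity_slowdown()` applies the $V \propto 1/\eta$ rescaling for
transport in thicker fluids.

# Numerical choices and problem sizes

Quadrature: `stats::integrate` at $10^{-9}$ relative tolerance on the
standard-normal scale. Seeding: every stochastic function takes an
explicit `seed` and restores the caller's RNG state; generators are pure
functions of (config, seed). Degenerate inputs: single-frame tracks are
skipped with a warning; scaling fits refuse fewer than 3 objects or a
radii span under 2×; empty droplet tables are an error for summaries and
an empty table for upstream steps.

The benchmark sizes the package tests itself at — $10^6$ diameter draws
for the MMD calibration, $10^5$ droplets (≈ 39 000 above the recording
floor, a ~2.4 mm² field) for the fraction-recovery pipeline, $3\times10^5$
droplets per cell of the quadrature/Monte-Carlo grid, and 20 replicates
of 200 wheels for susceptibility recovery — were chosen to make the
acceptance tolerances (two or three standard errors, or stated relative
errors) statistically meaningful at desk scale. Headline experimental
magnitudes that depend on unmeasured constants ($\chi''$, effective
viscosity) are exercised as scalings and recovery problems, not asserted
as absolute numbers.

# Known limitations

* The disk-drag coefficient and the wet-friction coupling $\beta$ absorb
  all near-wall hydrodynamics; absolute speeds and powers are only as
  good as those two constants.
* The Poisson partition ignores bead-size exclusion beyond the hard fit
  cutoff, and droplet coalescence between spraying and imaging is not
  modelled, so measured bead-containing fractions in oil may differ from
  the idealized partition for physical reasons the package does not
  capture.
* Bead detection by size-gated thresholding cannot separate truly
  overlapping beads.
* The airway model is geometric; it contains no deposition physics — the
  deposition classifier and the routing model are deliberately separate
  abstractions.
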