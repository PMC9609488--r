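---
title: "Stochastic modeling of fibrous biomaterial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic modeling of fibrous biomaterial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(fibrenet)
```

Fibrous biomaterials — fibrin clots, collagen gels, electrospun scaffolds,
nonwovens, metal felts — are characterized experimentally by a handful of
statistical descriptors: fiber diameter and length distributions, a fiber
orientation distribution, a tortuosity distribution, and the pore-size
distribution of the void space. `fibrenet` builds three-dimensional model
networks whose fibers are drawn from prescribed versions of those
distributions, enforces fiber–fiber non-penetration by damped bead-spring
dynamics, and measures the resulting pore structure. This vignette is the
package's account of the underlying models, the calibrations behind the
defaults, and the limits of what the package's tests demonstrate.

## The generative model

A network lives in a periodic cube of side $L$. Given a target fiber
volume fraction $\phi_f$ and mean fiber length and diameter
$\langle l_f\rangle,\ \langle d_f\rangle$, the fiber count is the
cylinder-volume estimate
$N_f \approx 4L^3\phi_f/(\pi \langle l_f\rangle \langle d_f\rangle^2)$,
rounded. Each fiber then draws:

* **diameter and length** from gamma distributions moment-matched to the
  prescribed mean and standard deviation
  ($k = \mu^2/\sigma^2$, $\theta = \sigma^2/\mu$). Diameters below
  $\langle d_f\rangle/5$ are redrawn by default; the floor exists because
  the pore analysis voxel edge is tied to the *smallest* diameter, and an
  unbounded left tail would make the voxel grid explode. Disable it with
  `diameter_floor = 0` for strict distribution fidelity.
* **mean orientation** from a de la Vallée Poussin (VP) mixture
  $p(\hat n) = \sum_i \frac{2k_i+1}{4\pi N}(\hat n\cdot\hat m_i)^{2k_i}$,
  antipodally symmetric, with one kernel for transverse isotropy, two for
  orthotropy, three for hexagonal symmetry. Sampling is exact spherical
  rejection with the mixture's aligned-density maximum as envelope.
* **tortuosity** from a lognormal truncated at 1 (moment matching is then
  approximate, and the constructor says so), or directly from a supplied
  histogram via rejection sampling with linear interpolation between bin
  centers — preferable when digitized experimental histograms exist,
  since no simple closed family fits measured tortuosity well.

The fiber's centerline is a von Mises–Fisher (VMF) random walk about the
drawn orientation, smoothed by a cubic spline (chord-length
parameterization, resampled at approximately equal arc-length intervals)
and screened: a walk whose realized tortuosity misses the target by more
than 5% (relative) is discarded and redrawn.

## Selecting the walk concentration for a target tortuosity

The VMF walk takes $N$ steps of size $\Delta = l_f/N$ with directions
drawn from $p(\hat n) \propto e^{\kappa\,\hat n\cdot\hat m}$. Two
structural rules fix $N$: a walk cannot realize tortuosity $\tau$ with
fewer than $N^\ast = \lceil \tau^2/2 + 1\rceil$ steps (below this,
reducing $\kappa$ no longer raises the realized tortuosity — the
"inaccessible region"), and the working count is $N = \lceil \beta
N^\ast\rceil$ with $\beta = 20$ by default; larger $\beta$ narrows the
spread of realized tortuosity, at the cost of more beads.

The concentration is chosen by inverting the walk's own end-to-end
statistics. For i.i.d. steps with mean resultant
$\rho(\kappa) = \coth\kappa - 1/\kappa$ (the Langevin function),

$$E\!\left[\lVert ee\rVert^2\right] = \Delta^2\!\left(N^2\rho^2 +
N(1-\rho^2)\right),$$

so the expected tortuosity is approximately
$\tau(\rho) = (\rho^2 + (1-\rho^2)/N)^{-1/2}\,
\bigl(1 + (1-\rho^2)/(N\rho^2)\bigr)$, where the last factor is a
first-order correction for the fluctuation (and skew) of the end-to-end
distance — without it the selector undershoots by up to ~10% at high
tortuosity. `kappa_for_tortuosity()` solves $\tau(\rho) = \tau^\ast$ and
then $\rho(\kappa) = \rho$ by root finding; both inversions are exact for
this model. Simulation places the unscreened mean realized tortuosity
within about 1% of target over $\tau \in [1.05, 3]$ (a few percent by
3.5, the calibrated limit — beyond it the function warns). Screening then
bounds every individual fiber at 5% and brings ensemble means within
~0.5%, with rejection rates around 1–2 walks per accepted fiber.

Two practical couplings matter:

* **Bead resolution vs walk step.** Networks discretize fibers at spacing
  `spline_factor * d` (default half a diameter, so consecutive beads of
  the contact representation overlap). If the nominal walk step
  $l_f/\lceil\beta N^\ast\rceil$ would be finer than that spacing, the
  step count is capped at the resolution limit (never below $N^\ast$):
  resampling coarser than the walk would cut corners and bias tortuosity
  low. Short, thick fibers therefore run at an effective $\beta$ below
  the requested one and screen slightly more often.
* **Spline overshoot.** An interpolating cubic through walk points is a
  little longer than the chord polyline, so realized contour lengths run
  ~2–3% above the nominal $N\Delta$ (and the finest resamplings keep the
  most of that extra arc — which is also why the spline step has a ~2%,
  not exactly 0%, influence on measured tortuosity). This is the
  package's construction tolerance. `rescale_length = TRUE` scales each
  accepted fiber to its drawn length exactly (tortuosity is scale
  invariant); it is off by default so that the geometry remains the
  untouched smoothed walk.

```{r kappa}
kappa_for_tortuosity(c(1.1, 1.5, 2.2))
steps_for_walk(1.5, beta = 20)
```

## Orientation measurement, projection distortion, and the 2D-to-3D correction

Experimental orientation data usually arrive as a 2D angle histogram
measured from images: each fiber's 3D orientation is projected onto the
imaging plane and binned on $[0,\pi)$. `fit_vp_2d()` fits the in-plane VP
mixture $p(\theta) = \sum_i \frac{\Gamma(k_i+1)}{\sqrt{\pi}\,
\Gamma(k_i+1/2)\,N}\cos^{2k_i}(\theta-\theta_i)$ (this constant, not any
other, integrates to 1 on $[0,\pi)$) by unweighted least squares on the
unit-mass-renormalized histogram, multi-started from the histogram's
peaks because the objective is multimodal in the kernel angles.

Projection distorts the measurement: when the distribution's mean axis is
tilted $\psi$ out of the measurement plane, the fitted 2D strength
shrinks as $\cos^2\psi$ — the same distribution looks more isotropic when
viewed obliquely. `correct_k2d_to_k3d()` applies the published correction
$k^{3D} = \tfrac{3\sqrt{N_{VP}}}{8\cos^2\psi}\,k^{2D}$ (default
"table-consistent" mode; the alternative "literal" mode replaces
$\sqrt{N_{VP}}$ by $1/N_{VP}$ — the two disagree for multi-kernel
mixtures and only the former reproduces the published material table, so
it is the default and the mode used is recorded on the result).
`average_k2d_over_psi()` gives the expected measured strength when
measurements average over a range of tilts; over any half-turn it reduces
to $4k^{3D}/(3N_{VP})$.

**A calibration caveat that matters.** The package's own measurement
simulation (`measure_projected_k2d()`: sample, project, bin, fit) shows
the fitted 2D strength to be $\approx k^{3D}\cos^2\psi$ — linear in
$k^{3D}$ (regression $R^2 > 0.98$) and with exactly the $\cos^2\psi$ tilt
dependence, but with unit proportionality, not the $8/3$ amplification
embedded in the published correction. This is not a sampling artifact:
the azimuth marginal of $(\hat n\cdot\hat m)^{2k}$ with an in-plane mean
axis is *exactly* $\propto\cos^{2k}\theta$ (any weighting that depends
only on the out-of-plane angle preserves this), so a shape fit must
return $k^{2D} = k^{3D}$ at $\psi = 0$. The $8/3$ factor therefore
belongs to the original measurement pipeline's conventions, which cannot
be reconstructed from its description. Consequences for users: corrected
values from `correct_k2d_to_k3d()` are mutually consistent and
tilt-invariant (dividing out $\cos^2\psi$ is the part that matters when
comparing measurements at different tilts), and they reproduce the
published material corrections; but chaining this package's *own*
simulated measurement with the published correction underestimates the
true 3D strength by the constant factor $3/8$. The package keeps both
halves faithful to their sources and documents the seam rather than
silently rescaling either.

```{r correction}
round(as.numeric(correct_k2d_to_k3d(c(0.98), n_vp = 1)), 2)  # fibrin-like
round(as.numeric(correct_k2d_to_k3d(c(5.25), n_vp = 3)), 2)  # stone-wool-like
```

## Non-penetration relaxation

Randomly seeded fibers overlap. Each fiber becomes a chain of spherical
beads (radius $d/2$, spacing $\approx d/2$): harmonic bonds
$f = -2k_b(R - R_0)\hat r$ with $k_b = EA/R_0$, cosine angle potentials
with stiffness $k_\theta = EI/R_0$ (second moment $I = \pi d^4/32$ to
match the source convention; `standard_inertia = TRUE` switches to
$\pi d^4/64$), and a soft repulsive contact
$f = \frac{\pi k_c}{R_c}\sin(\pi R/R_c)$ acting below the cutoff
$R_c = (d_i+d_j)/2$ between all bead pairs except bonded pairs and angle
trios. The contact stiffness uses a Hertz-like form
$k_c = (E/16)\,\nu^{1/3}\sqrt{R}$ with $1/R = 1/d_i + 1/d_j$; the
relaxation outcome is insensitive to its prefactor because the goal is
penetration removal, not contact-force accuracy. The soft sinusoid is
finite everywhere and vanishes at zero separation, avoiding the
accelerations a Hertzian contact would produce on deeply overlapped
initial states. Stokes drag $f = -3\pi\eta d\,v$ dissipates energy.

Velocity-Verlet integration uses $\Delta t = 0.02\sqrt{m/k_b^{max}}$
(halved and restarted on instability), with fiber ends frozen for the
first 10,000 steps to restrain rigid rotations during the energetic early
phase. All parameters are normalized ($E = 1$, $m = 1$, $\nu = 0.3$); the
default viscosity makes a bonded dimer lightly damped (damping ratio
~0.1), which removes overlap fastest. The run stops when the percent
fiber overlap (PFO — total pairwise sphere-lens overlap volume over total
sphere volume, ×100) falls below `stop_below` (default 0.05%) or
plateaus in relative terms, with both checks deferred until the ends are
released, or at `max_steps`. PFO traces decrease monotonically on
average; the relaxed network reports per-fiber absolute percent changes
in contour length, tortuosity, and orientation (orientation change is the
angle between the before/after mean orientations as a percentage of 90°,
a convention recorded here because the source never defines its own).

Run to this endpoint, the relaxation is strongly structure-preserving:
because every bond and angle's rest state is the prescribed geometry,
fibers spring back once contacts separate, and ensemble mean changes are
only ~0.5–2.5% even at 40% volume fraction. Published change statistics
for the equivalent procedure are markedly larger (~14% in tortuosity),
which is only reachable if the statistics are taken from states that
never elastically recover — a fixed-duration run or a jammed overlap
plateau under much softer elastic constants. Users who want the
prescribed distributions preserved should regard the small changes as the
desirable outcome; the acceptance suite keeps the published bands and
reports the discrepancy rather than imitating an unspecified endpoint.

## Pore-size analysis

The relaxed network is voxelized on the periodic box with edge
$h \le \min(d_f)/5$. Occupancy uses center containment by default: a
voxel is occupied when its center lies inside a bead. The literal
any-contact ("partial containment") rule is available but pads every bead
radius by half a voxel diagonal (~17% at $h = d/5$), which inflates the
occupied volume by ~60% at high volume fraction, biases mean pore
diameters low by up to ~55% at $\phi_f = 0.4$, and steepens the measured
$\langle d_p\rangle$–$\phi_f$ scaling to roughly $\phi_f^{-1}$. With
center containment the package reproduces the expected scaling laws
(measured exponents ~1 on diameter and ~−0.6 on volume fraction); this
calibration fixed the default.

The exact periodic Euclidean distance transform (computed separably by
the lower-envelope algorithm on periodically tripled rows, and tested
voxel-for-voxel against a brute-force oracle) assigns each empty voxel
its distance to the nearest occupied voxel. Pores are the watershed
basins of the negated distance field under 26-connectivity: processing
empty voxels in order of decreasing distance, a voxel with no
higher-valued neighbor founds a basin at a local maximum, and when basins
meet, any basin rising less than `merge_depth` (default one voxel edge)
above the meeting level is absorbed — suppressing the spurious
single-voxel maxima that raw voxelized distance fields produce. With zero
merge depth the surviving basins are exactly the strict 26-neighborhood
local maxima, which is how the implementation is oracle-tested. The pore
diameter is $2\times$ the distance value at the basin peak (an
inscribed-sphere diameter); the raw-distance convention is selectable,
but halves every diameter and was rejected by the same scaling-law
calibration. Because the default merge depth shrinks with $h$, grid
refinement studies should hold `merge_depth` fixed; even then, means over
a few dozen pores move by one pore's worth (~5%) under refinement —
count-weighted pore means at small network sizes are intrinsically
discrete.

Closed-form predictors are provided for quick estimates:
$\langle d_p\rangle \approx 2\langle d_f\rangle$ (~60% error),
$\langle d_f\rangle/\sqrt{\phi_f}$ (~40%), and
$\langle d_f\rangle(1/\sqrt{\phi_f} - 0.05\langle\tau_f\rangle)$ (~20%).

```{r pores-predict}
predict_mean_pore(0.5, phi = 0.15, model = "diameter-phi")
```

## A worked example

```{r example}
spec <- network_spec(
  box_length = 6, volume_fraction = 0.12,
  diameter_mean = 0.5, diameter_std = 0.05,
  length_mean = 3, length_std = 0.4,
  orientation = vp_params(vp_kernel(c(0, 0, 1), 2)),
  tau_mean = 1.25, tau_std = 0.1)
net <- build_network(spec)
net
rx <- relax(net, mechanics_params(fixed_end_steps = 2000, max_steps = 15000))
round(rx$mean_changes, 2)
pr <- measure_pores(rx$network)
c(mean_pore = pr$mean_diameter,
  predicted = as.numeric(predict_mean_pore(0.5, 0.12, model = "diameter-phi")))
```

## Synthetic data, randomness, and reproducibility

All randomness flows through R's global generator: `set.seed()` before a
pipeline makes the entire network, relaxation, and pore measurement
bit-reproducible. `make_fixtures()` synthesizes the kind of digitized
orientation and tortuosity histograms that accompany published material
characterizations (single-kernel fibrin-like, hexagonal stone-wool-like,
orthotropic polyester-like, asymmetric collagen-like orientation cases;
low-, mid-, and high-tortuosity cases) from known ground truth with
multiplicative noise, so fitting and recovery are exercised without any
external data. What these fixtures do *not* emulate: measurement-specific
distortions (finite imaging depth, segment-length weighting, edge
effects), correlated noise between bins, and the asymmetric-orientation
regime where the 2D-to-3D correction is known not to apply.

The test suite and the acceptance script run on deliberately small
problems — networks of tens to a few hundred fibers, $10^5$-sample
orientation studies, 10–20-network ensembles — chosen so the full suite
completes in minutes. Passing them demonstrates distributional
correctness, the calibrations described above, and exactness of the
discrete geometry kernels; it does not demonstrate behavior at
experimental scale (thousands of fibers, voxel grids beyond ~$200^3$),
where only the runtime, not the algorithms, changes.

## Known limitations

* The 2D-to-3D correction constant is faithful to its published form but
  not derivable from the package's own projection simulation (see the
  calibration caveat above); corrections for *asymmetric* orientation
  mixtures are out of scope entirely.
* The tortuosity selector is calibrated for $\tau \le 3.5$; beyond that
  it extrapolates and warns. Tortuosity prescriptions interact with bead
  resolution for short, thick fibers (effective $\beta$ drops).
* Relaxation reports geometry changes at a well-defined equilibrated
  endpoint; procedures that stop mid-relaxation will see larger changes.
* Pore statistics are count-weighted means over watershed basins; at
  small network sizes they carry one-pore discreteness, and the merge
  depth is a real modeling choice, not a nuisance parameter.
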