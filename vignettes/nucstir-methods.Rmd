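---
title: "Models and methods in nucstir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nucstir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucstir)
```

## The physical picture

Growing oocytes stir their cytoplasm with actomyosin-generated forces.  The
fluctuating nuclear membrane transduces this activity into the nucleoplasm,
where it acts as an effective temperature: micron-scale liquid-like
condensates (nuclear speckles, the nucleolus) diffuse faster than thermal
motion alone would allow, collide, and coalesce.  `nucstir` implements this
picture at two levels:

* an **agent-based simulation** of droplets, a nucleolus and chromatin-like
  obstacles inside a spherical nucleus, driven by activity-dependent
  Brownian dynamics with collision-coalescence; and
* the **quantification toolbox** used on such data: time-averaged MSD with
  anomalous-exponent and effective-diffusion fits, radial contour
  fluctuation variance, one-phase FRAP fits with apparent diffusion and
  mobile fractions, optical-trap stiffness from Boltzmann statistics, a
  Stokeslet model of membrane-driven flow with Peclet numbers, and an
  image-correlation stirring metric.

Everything runs on simulated or synthetic inputs with known ground truth;
no external data are needed.

## Agent dynamics

Each agent is a sphere with position, radius $r_i$ and a dimensionless
friction multiplier $f_i$.  Its velocity follows an overdamped force
balance: pairwise overlap repulsion plus membrane confinement plus a
Brownian term, divided by a Stokes friction $\eta_i \propto r_i f_i$.  We
normalise $\eta_i = (r_i/r_{\mathrm{ref}}) f_i$ with
$r_{\mathrm{ref}} = 4.5\ \mu m$ (the nucleolus), so forces are expressed in
units of $\gamma\,\mu m^2/s$ with $\gamma = 1$.

The diffusion coefficient couples to the cytoplasmic stirring activity $A$:

$$D_i = (D_0 + \alpha A)\,\frac{r_{\mathrm{ref}}}{r_i}\,\frac{1}{f_i},$$

with $D_0 = 0.01$ (minimal mobility) and $\alpha = 0.11$ (coefficient of
mobility), both calibrated on nucleolus mobility regressions at
$r_{\mathrm{ref}}$.  This preserves Stokes $1/r$ scaling and the per-type
empirical frictions (nucleolus 1, droplets 0.55, obstacles 5)
simultaneously.  Activity values per condition: SN control 1, SN +
nocodazole 1.9, SN FMN2$^{-/-}$ 0.2, NSN control 0.55; other NSN values are
the SN value divided by 1.8, the NSN-to-SN activity ratio.

Force laws are linear overlap penalties — the strengths are prescribed
(nucleus confinement 30, obstacle/nucleolus repulsion 30, droplet repulsion
10) but not their functional form, so we use the simplest continuous choice
consistent with "repulsion grows with overlap".  Droplet pairs exert no
force on each other: when two droplets touch they coalesce instantly into
one sphere of summed volume at the volume-weighted centroid.  With
simultaneous contacts the deepest overlap merges first; total volume is
conserved regardless of order (the per-merge position does depend on order,
which we accept and note).

### Numerical scheme

Explicit Euler–Maruyama at $dt = 0.01$ s, the step used for numerical
stability at full fidelity.  Two safeguards keep the penalty forces
well-behaved:

* each per-pair (and membrane) drift contribution is capped at the current
  overlap, so an agent is never pushed past the point of contact in one
  step; and
* the summed drift per agent per step is capped (default 0.5 µm), which
  only binds while strong transient overlaps relax.

At $dt = 0.01$ s the caps almost never bind in normal dynamics
($k\,dt/\eta \le 0.91$ for droplets).  Initial placement is uniform at
random (droplets redrawn until contact-free); placement overlaps among
obstacles are then settled by a short athermal drift-only relaxation during
which droplets repel softly instead of coalescing, so dynamics start from a
contact-consistent state rather than an artificial merge burst.  The same
settling pass follows obstacle compaction at the NSN-to-SN transition.

Anchored obstacles ride on the nucleolus at a recorded offset plus a small
Ornstein–Uhlenbeck tether fluctuation capped at 0.1 µm (the amplitude is a
configuration knob; the cap implements "small random fluctuations around
this position").

Obstacle radii are drawn from a Gaussian (0.85 ± 0.4 µm) truncated below at
0.05 µm, since the distribution's negative tail is unphysical and
unspecified.

### Simulation series

* **Series 1 (NSN-like)**: obstacles dispersed, activity constant, 20 h.
* **Series 2 (NSN-to-SN)**: at 12 h the 40% of obstacles nearest the
  nucleolus surface (ties by id) anchor to it and activity is multiplied by
  1.8; horizon 40 h.
* **Series 3 (SN-like)**: 40% anchored from the start, activity constant,
  20 h.

At the transition, chromatin condensation means obstacles are attracted
towards and adhere to the nucleolus.  We compact the selected
obstacles radially — rank-preserving remap of their distances into a
packing shell around the nucleolus at packing fraction 0.55, keeping each
obstacle's angular position — then record offsets and settle the
configuration athermally.  Residual static overlap among anchored obstacles
is accepted: they act as one condensed mass.

The time to reach $n$ droplets returns the first crossing when the count
reaches $n$ in-horizon; otherwise a decreasing exponential
$c(t) = a\,e^{-t/\tau} + 1$ (floor fixed at one droplet, the absorbing
state) is fitted to the last 5 h by log-linear least squares on $c-1$ and
the crossing extrapolated, capped in reporting at "> 100 h".  A
non-decreasing tail raises a degeneracy flag instead of a number.  For
series 2 the time measured from the transition is reported alongside, since
benchmark times for this protocol are conventionally measured from the
NSN-to-SN transition.

### Scaled-down mode and problem sizes

Full-fidelity runs (931 agents, $dt = 0.01$ s, 14.4 M steps for 40 h) take
on the order of an hour or more each; they are how headline numbers should
be produced.  For routine testing the package provides a scaled-down mode,
always flagged in summary metadata: a coarser step (up to 0.1 s) and an
obstacle count reduced by `obstacle_scale` with radii rescaled by
`scale^(-1/3)`.  The rescaling preserves the total obstacle volume
fraction, hence the crowding level.  (Preserving total cross-section
instead would push the volume fraction above random close packing and jam
the nucleus, so it is not usable.)  Scaled runs preserve subdiffusion
(droplet $\alpha < 1$) and the ordering of conditions, but coarser steps
weaken obstacle caging — Brownian kicks comparable to inter-obstacle gaps
let droplets slip between obstacles — so absolute coalescence times shrink
relative to full fidelity.  The test suite therefore checks desk-scale
physics exactly, and the long-timescale behaviour on scaled problems
(obstacle scale ~0.3, $dt$ 0.02–0.1 s, horizons as in the series specs),
with orderings and windows asserted at the scale the runs support.

## Quantification methods

**MSD and exponents.**  The time-averaged MSD uses all overlapping start
points per lag (chosen for variance reduction).  The anomalous exponent
fits $\mathrm{MSD} = C\tau^\alpha$ by Nelder–Mead least squares initialised
from a log-log regression.  The effective diffusion coefficient is the
slope of an unconstrained linear fit of the first 40 MSD points (20 s at
0.5 s sampling) divided by $2d$ — $d = 2$ for single-plane experimental
tracks, $d = 3$ for simulation tracks; the fit is not forced through the
origin (the convention is unstated upstream; unconstrained is robust to a
noise intercept).  $D_{\mathrm{eff}}$ is normalised by droplet size as
$D_{\mathrm{eff}} \times \tfrac{3}{2}\pi r$.

**Contour fluctuations.**  Radii are extracted along 360 rays (1°) from the
droplet center; for binary masks the boundary is located sub-pixel by
linear interpolation along the ray, taking the first crossing (matching a
radial scan of a thresholded mask).  Per angle, the temporal mean radius
$R(\theta)$ is subtracted and the population variance
$\langle (r-R)^2 \rangle$ over frames (30 at 0.5 s in the standard
protocol) is reported, plus its mean over angles.  Analyses admit droplets
with radii 2–2.7 µm.

**FRAP.**  Raw intensities are background-corrected and prebleach
normalised; the one-phase association $I(t) = A(1 - e^{-t/\tau})$ is fitted
by Levenberg–Marquardt, initialised with $A$ = last-quartile mean and
$\tau$ = time to $A(1 - 1/e)$.  The fitted plateau — not the noisy last
sample — is the full-recovery reference for 0-to-1 rescaling.  Apparent
diffusion is $D_{\mathrm{app}} = r^2/\tau$ with proportionality constant 1
(the omitted constant is order one, so $D_{\mathrm{app}}$ values are
comparable among themselves but carry that convention).  Mobile fractions
are the normalised recovery at 120 s (NSN) or 60 s (SN).

**Trap stiffness.**  The position histogram (Freedman–Diaconis bins, empty
bins masked) is fitted on the log scale with a count-weighted parabola
(the variance of $\log N$ scales as $1/N$); curvature converts to
$\kappa = -2 k_B T c_2$.  A non-concave or poorly fitting log-histogram
raises a non-Gaussian flag.

**Stokeslet model.**  A uniform density of independent fluctuating point
forces on the spherical membrane gives the mean-square nucleoplasmic flow
$\langle v^2 \rangle(u) = (v_{nm}^2/u)\ln\frac{1+u}{1-u}$ at radial
fraction $u$, with the analytic limit $2v_{nm}^2$ at the center; its volume
average is exactly $3 v_{nm}^2$.  All order-one proportionality constants
are taken as 1 and exposed as parameters.  Peclet numbers are
$Pe = v\,\ell/D$.

**Stirring metric.**  Pearson correlation of pixel intensities per region,
against the preceding frame and against the first frame (both shipped,
since the upstream reference convention is unstated); the stirring
intensity is $1 - \mathrm{correlation}$, averaged over regions and
timepoints.

## Synthetic generators

Every analysis stage has a seeded generator with known ground truth:

* `gen_track`: fractional-Gaussian-increment tracks with ensemble MSD
  $2 d D \tau^\alpha$ by construction (chosen over obstacle-based walks so
  the target exponent is exact; the simulator itself provides the
  mechanistically faithful subdiffusion).
* `gen_contour_movie`: whole-period sinusoidal contour perturbations with
  exact per-angle variance $a^2/2$.
* `gen_frap_curve`: one-phase recovery with plateau = mobile-fraction
  ground truth and relative Gaussian noise.
* `gen_trap_positions`: Boltzmann-Gaussian positions with variance
  $k_BT/\kappa$.
* `gen_pixel_stack`: per-frame pixel resampling at rate $p$, so the
  consecutive-frame correlation is $1-p$ and the stirring intensity
  recovers $p$.

These emulate the statistical structure of the real measurements — not
their imaging artifacts (no point-spread function, photobleaching or
segmentation noise) — so parameter-recovery tests validate the estimators,
not the microscopy.

## Known limitations

* No hydrodynamic coupling between agents, no droplet deformation,
  nucleation or dissolution.
* The force functional form, the tether amplitude and the friction-to-
  diffusion coupling are declared package choices where the upstream
  description is silent.
* Scaled-down runs compress absolute coalescence timescales (see above);
  orderings across activities and chromatin states are preserved.
* The FMN2-mutant non-spherical-nucleus and decompacted-chromatin variants
  are out of scope.
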