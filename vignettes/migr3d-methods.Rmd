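---
title: "Methods: quantifying 3D cell migration in fibrous hydrogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying 3D cell migration in fibrous hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migr3d)
```

# Scope

`migr3d` analyzes single-cell 3D migration experiments in porous
fibrous gels (the motivating system is an invasive breast-cancer line
in collagen) along three measurement axes, plus the cohort statistics
that tie them together:

1. **Per-track motility** from center-of-mass trajectories: mean
   squared displacement (MSD), the anomalous-diffusion exponent, speed,
   turning angles and end-to-end track displacement.
2. **Gel microstructure** from binary fiber masks: pore size (and cell
   size) via the largest-inscribed-sphere local-thickness transform.
3. **Fiber stiffness** from AFM force-distance grids: contact-point
   detection, quadratic-pyramid Hertz fits, slope maps, and the
   conversion of bulk rheometer shear moduli to Young's moduli.

Tracks, masks and force curves are *inputs*: segmentation and tracking
of raw movies, and visual phenotype classification, are out of scope.
A synthetic-data module generates all three input kinds with known
ground truth, so every analysis stage is testable without external
data.

# Motility statistics

## Time-averaged MSD and the anomalous exponent

For a track $r(t)$ sampled at a uniform frame interval $\Delta t$
(default 1200 s, i.e. 20-minute frames over 50 frames), the
time-averaged MSD at lag $k$ uses all overlapping pairs,

$$\mathrm{MSD}(\tau_k) = \big\langle |r(t+\tau_k) - r(t)|^2
\big\rangle_t, \qquad \tau_k = k \,\Delta t .$$

Overlapping windows are standard single-particle-tracking practice and
matter on 50-frame tracks, where disjoint windows would leave very few
pairs at larger lags.

The anomalous-diffusion model $\mathrm{MSD}(\tau) = D\,\tau^\alpha$ is
fitted over the **first 5 lags** (configurable).  The canonical fit is
ordinary least squares of $\log \mathrm{MSD}$ on $\log \tau$: it is
deterministic, needs no initialization, and is exact on pure power
laws.  A direct nonlinear least-squares option (`method = "nls"`) is
provided for sensitivity checks; on exact power laws the two agree to
numerical tolerance.  Tracks that are stationary over the fit lags
have an undefined exponent and are reported as `NA` rather than
$-\infty$.  Interpretation: $\alpha \approx 1$ diffusive, $\alpha < 1$
subdiffusive (confinement by pores or adhesion), $\alpha > 1$
superdiffusive (persistent motion through channels).

## Speed, angles, displacement

*Speed* is defined from the first-lag MSD,
$v = \sqrt{\mathrm{MSD}(\Delta t)}/\Delta t$, reported in nm/s.  The
phrase "MSD at zero time lag" that sometimes labels this quantity is
read as the first *nonzero* lag: the literal zero-lag MSD vanishes
identically, and only the first-lag reading produces the nm/s scale on
which fast-cell thresholds (about 3.2 nm/s at the pooled 75th
percentile) live.  This reading is a documented convention of the
package, not a claim about any particular instrument's definition.

*Turning angles* are the angles between successive displacement
vectors, in $[0^\circ, 180^\circ]$; $180^\circ$ means backtracking,
the signature of a cell bouncing inside a pore.  Zero-length steps
have no direction and are skipped (they still contribute zero squared
displacement to the MSD).  For an isotropic 3D walk the cosine of the
turning angle is uniform on $[-1, 1]$, which the tests exploit as a
closed-form oracle.

*Track displacement* is the Euclidean distance between the first and
last positions (end-to-end distance), bounded above by the summed step
lengths.

All features are invariant under global rotation and translation of a
track; the suite checks this to $10^{-9}$ relative.

# Pore and cell size: local thickness

Pore size is quantified by the local-thickness transform: the value at
a point of the pore (background) phase is the diameter of the largest
sphere that fits entirely inside that phase and covers the point.  The
same transform applied to the foreground of a cell mask yields a cell
size.  The discrete model is defined on voxel centers:

* the maximal sphere radius centered at phase voxel $c$ is
  $R(c) = d(c) - h/2$, where $d(c)$ is the Euclidean distance to the
  nearest complement voxel center and $h$ the (required isotropic)
  voxel size;
* the sphere at $c$ covers every voxel within $R(c)$ of $c$;
* the map value is $2\max R(c)$ over covering spheres.

The $h/2$ offset makes an isolated single-voxel pore read one voxel
diameter, and a slab of $n$ voxels read $n h$ up to one-voxel
discretization.  Spheres may protrude through the volume faces — the
border is *not* treated as fiber — so slab and channel fixtures are
unbiased near the edges; the flip side is that an entirely empty
volume reads the (capped) volume diagonal.  The implementation is an
exact squared Euclidean distance transform (separable lower-envelope
algorithm) followed by sphere-covering propagation, in compiled code;
a brute-force oracle built from naive distance matrices reproduces it
*exactly* (not approximately) on randomized small volumes, which is
the main correctness guarantee.

The pore-size summary is the voxel-weighted mean of the background
thickness map (every background voxel contributes its value), matching
the convention of the standard local-thickness implementations; no
per-pore watershed is attempted.  Cells are mapped to pores by the
enclosing voxel of their position, with physical position
$(i + 0.5)h$ for 0-based index $i$; if that voxel happens to lie on a
fiber, the 1-voxel neighborhood maximum is used, since a cell occupies
the pore around it.

# Fiber stiffness from AFM force curves

Approach curves (force $F$ in nN versus piezo extension $z$ in µm,
one curve per pixel of a quantitative-imaging grid) are analyzed in
three steps.

**Contact point.**  The baseline level and noise are estimated from
the first 40% of samples; the detected contact is the first distance
where $F$ exceeds baseline mean $+\ \kappa \cdot$ baseline sd
(default $\kappa = 3$) for at least 5 consecutive samples.  On soft
samples this crossing is systematically late — the Hertz force must
climb above the noise — so it is only the initializer for the fit.

**Hertz fit.**  For a quadratic (four-sided) pyramidal tip the
Bilodeau closed form is used,

$$F = \underbrace{0.7453\,\frac{\tan\theta}{1-\nu^2}}_{C}\;E\,\delta^2,$$

with half-front angle $\theta = 15^\circ$ and Poisson ratio
$\nu = 0.5$ by default, and indentation
$\delta = (z - z_c) - F/k$ corrected for cantilever deflection
(spring constant $k$, default 0.03 N/m — non-negligible for gels of
tens of Pa).  For fixed contact point $z_c$ the modulus enters
linearly and is profiled out in closed form; $z_c$ itself is refined
by minimizing the full-curve piecewise residual (zero before contact,
Hertz after) with a coarse grid plus golden-section polish.  On
noiseless synthetic curves this recovers the generating modulus to
better than $10^{-4}$ relative; negative fitted moduli are clipped to
zero with a flag.  The linear slope of $F$ versus $z$ over the contact
region is reported alongside, since slope maps are the conventional
"local stiffness" images.

**Maps and summaries.**  Per-pixel fits are assembled into slope and
modulus maps; pixels with no detectable contact are excluded (an
error is raised if more than half fail).  Optional 3×3 median
filtering and background subtraction mirror common AFM
post-processing; they are off by default because all acceptance
fixtures are synthetic and clean.  Fiber/background segmentation uses
an Otsu threshold on the slope map with a manual override, and the
fiber-to-background contrast is the ratio of mean moduli.  Bulk
rheometer readings convert as $E = 2G'(1+\nu)$, i.e. $E = 3G'$ at the
incompressible default, consistent with the AFM Poisson ratio.

A physical consequence worth knowing: at baseline noise 0.05 nN, a
10 Pa sample indented ~3 µm generates a maximal Hertz force of about
0.02 nN, below the $3\sigma$ detection threshold.  Such curves
*correctly* fail with a no-contact error; in the recovery summaries
they are counted as total misses (relative error 1).  The pooled
median recovery error over the 10–1000 Pa grid stays well under 10%
because the failures are confined to that lowest-modulus corner.

# Cohort statistics

* **Percentile thresholds** ("fast" / "high-displacement" cells) are
  pooled over all conditions and use linear interpolation between
  order statistics ($h = (n-1)q + 1$), the most common quantile
  convention; default $q = 0.75$.
* **Pore-size bins** are anchored at 0 µm, left-closed right-open,
  default width 4 µm (2 µm variant).  Empty bins report $n = 0$ and an
  *undefined* (not zero) fraction.
* **Fraction comparisons between bins** use the exact conditional
  two-proportion test: conditioning on the total success count, the
  first bin's count is hypergeometric under the null, and the
  two-sided p-value sums all tables with probability not exceeding the
  observed one (minimum-likelihood method).  "Binomial test" is
  ambiguous between one- and two-sample readings; the two-sample form
  is the default because fractions are compared *between* bins, and a
  one-sample binomial-versus-pooled option is kept behind a flag.
  The implementation is written directly on the hypergeometric mass
  and is tested against both full table enumeration and the
  independent conditional-exact routine in base R.
* **Group comparisons** are normality-gated: Shapiro-Wilk per group at
  gate level 0.05 (the gate level is a package convention, recorded in
  the routing trail); if all groups pass and there are exactly two, a
  Welch t-test, otherwise Mann-Whitney (two groups) or Kruskal-Wallis
  (more).  The full routing trail is returned so a reader can audit
  which gate fired.
* **Boxplot summaries** follow the mean / median / quartile box /
  5th–95th whisker convention, with outliers beyond the whiskers.
* Raw per-comparison p-values are reported (no multiple-testing
  correction by default, matching per-comparison reporting style); a
  Benjamini-Hochberg adjustment can be applied by the caller via
  `p.adjust`.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults mirror the acquisition they emulate and are
not tuned per test.

* **Trajectories** (default 50 frames at 1200 s): *fBm* — each
  coordinate an independent fractional Brownian motion with Hurst
  exponent $H$, generated exactly in covariance by a Cholesky factor
  of the fractional-Gaussian-noise covariance (no approximate
  cascades), so the ensemble MSD is $\propto \tau^{2H}$ and the
  exponent-recovery tests have an unbiased oracle; *confined_box* — a
  Gaussian walk with reflecting boundaries (reflection, not absorption
  or wrapping, mimics a cell trapped in a pore and produces the MSD
  plateau and backtracking excess); *persistent* — a correlated walk,
  direction$(t{+}1) \propto p\,$direction$(t) + (1-p)\,u$ with $u$
  uniform on the sphere and fixed step length, superdiffusive over the
  first 5 lags for $p$ near 1; *ballistic* — a straight line.  Each
  spec carries exactly one phenotype/condition label; cohorts are
  concatenations of specs, keeping per-track ground truth unambiguous.
* **Fiber networks**: voxels within a radius of straight random lines
  (isotropic gel) or of two dense parallel fiber walls with a known
  clear gap (the migration-channel geometry).  Pore diameters in the
  12–18 µm range at sub-µm voxels are reached with a handful of
  fibers per (20 µm)³.
* **Force curves**: baseline noise before the contact point; past it
  the force solves the *implicit* deflection-corrected Hertz relation
  $F = C E ((z - z_c) - F/k)^2$ — the generated curve is therefore
  consistent with the quantity the fitter estimates, and the smaller
  quadratic root is evaluated in the cancellation-free conjugate form
  (the naive root formula loses all precision for stiff cantilevers).
  Moduli may be a per-pixel matrix, which is how two-region
  (fiber/background) maps are built.

What the generators deliberately do **not** emulate: cell–fiber
mechanical interaction, matrix remodeling, division events, curved or
bundled fibers, instrument drift, or tip wear.  Passing tests
therefore demonstrate correctness of the *estimators* under clean,
known-truth conditions — not that real gels satisfy the models.

# Numerical choices and degenerate inputs

* Errors are classed conditions (`migr3d_validation_error`,
  `migr3d_degenerate_input`, `migr3d_no_contact`, ...) so callers and
  tests can route on type.
* Problem sizes in the shipped tests and acceptance script: 300-track
  cohorts of 50 frames for exponent recovery; 16³ volumes for the
  exact oracle comparison (20 random masks) and ≤ 40×20×20 µm volumes
  at 0.5 µm voxels for slab fixtures; 6×6 force grids of 512-sample
  curves, 250 noisy-recovery fits.  These sizes give stable statistics
  at interactive runtimes; all scale linearly.
* CSV track tables are written with 17 significant digits so a
  write/read round trip reproduces doubles bit-exactly.  TIFF volumes
  are stored 16-bit with a JSON sidecar carrying voxel size and value
  scale: masks round-trip exactly, continuous maps to ~10⁻⁴ relative.
* Quantile type is fixed (type 7) everywhere a percentile is taken.
* Seeds: every simulator takes a `seed` and restores the caller's RNG
  state (`withr::with_seed`); identical spec + seed is bit-identical.

# Known limitations

* Local thickness requires isotropic voxels; anisotropic stacks must
  be resampled upstream.
* The Hertz model assumes a clean elastic contact: no adhesion
  (JKR/DMT), no viscoelasticity, a single contact event per curve.
* The pore-size summary is voxel-weighted, so large pores dominate the
  mean by volume; a per-pore statistic would need a watershed, which
  is out of scope.
* Phenotype labels are taken as given; no classification is attempted.
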