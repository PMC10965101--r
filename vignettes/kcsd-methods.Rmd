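---
title: "Kernel CSD estimation: model, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel CSD estimation: model, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcsdr)
```

## The estimation model

Extracellular potential and current source density (CSD) are linked by the
Poisson equation in a conducting medium; with conductivity $\sigma$ assumed
constant and isotropic, the potential of a source distribution $C$ in 3D is
the Coulomb integral $V(x) = \frac{1}{4\pi\sigma}\int
\frac{C(x')}{|x-x'|}\,dx'$.  Measuring $V$ at only $N$ contacts makes the
inversion ill-posed, so kCSD restricts the reconstruction to the span of
$M$ elementary sources $\tilde b_i$ with forward-modelled potentials
$b_i$, and solves the ridge problem in the induced reproducing-kernel
space.  With

$$K(x,x') = \sum_i b_i(x)\,b_i(x'), \qquad
  \tilde K(x,y) = \sum_i \tilde b_i(x)\,b_i(y),$$

the estimate from measurements $V$ is $\beta = (K+\lambda I)^{-1}V$ and
$C^*(x) = \tilde K(x,\cdot)\,\beta$.  At $\lambda = 0$ the interpolant
passes through the data (noise-free assumption); large $\lambda$ flattens
the solution toward zero.  Everything downstream — parameter selection,
error propagation, eigensources — exploits the linearity of the resolvent
$E = \tilde K (K+\lambda I)^{-1}$.

### Basis sources and their potentials

Two isotropic families are provided, both normalised to unit integral so
they are interchangeable up to the fitted coefficients:

* Gaussian of scale $R$: $\tilde b(r) = (2\pi R^2)^{-k/2}
  e^{-r^2/2R^2}$ in $k$ dimensions.  We use the standard probability
  normalisation throughout; it is the one consistent with the closed-form
  3D potential $b(r) = \mathrm{erf}(r/\sqrt2 R)/(4\pi\sigma r)$, which the
  package uses directly in 3D (with the analytic limit
  $\sqrt{2/\pi}/(4\pi\sigma R)$ at $r=0$).  Since the coefficients absorb
  any constant, estimates are invariant to this choice; the tests verify
  the invariance indirectly through in-span recovery.
* Step (indicator of radius $R$) scaled to unit integral.

The forward models by dimensionality:

* **1D (laminar probes).**  Sources are assumed rotationally symmetric
  within a cylindrical sheath of radius $h$ around the probe axis, giving
  $b(z) = \frac{1}{2\sigma}\int \big(\sqrt{(z-z')^2+h^2} - |z-z'|\big)
  \tilde b(z')\,dz'$.
* **2D (planar arrays).**  A tissue layer of thickness $2h$ contributes
  through the integrable kernel $\operatorname{arsinh}(2h/\rho)$:
  $b(x,y) = \frac{1}{2\pi\sigma}\iint \operatorname{arsinh}
  \frac{2h}{|r - r'|}\,\tilde b(r')\,dr'$.
* **3D.**  Closed form for Gaussians; for steps the angular part of the
  Coulomb integral is done exactly (spherical mean value) leaving a radial
  quadrature.

Units are the user's: positions, $R$, $h$ and estimation bounds must share
one length unit and $\sigma$ the matching conductivity unit; nothing is
converted.

### The Method-of-Images slice variant

For a slice of thickness $d$ on a planar array, the conductivity jump at
the slice faces is approximated by mirror images.  Our geometric
convention: the electrode plane at $z=0$ is the lower slice face, the
contributing layer occupies $z \in [0, 2h]$ (which reproduces the
$\operatorname{arsinh}(2h/\rho)$ direct term exactly), and both faces
border the bathing medium with reflection coefficient
$W = (\sigma_{tissue}-\sigma_{saline})/(\sigma_{tissue}+\sigma_{saline})$.
Each image of the layer integrates in closed form to a difference of
arsinh terms, so the ladder truncated at `n_images` reflections is cheap.
With $W=0$ or `n_images = 0` the variant reduces identically to the
infinite-tissue 2D basis.  The ladder tail is geometric in $W$ but its
terms decay only like $1/m$ in the reflection count $m$, so convergence at
$|W|$ near 1 is slow — the tests bound the truncation error by the actual
tail sum rather than a fixed constant, and for $|W| \le 1/3$ twenty images
are converged below $10^{-8}$.  An insulating (glass) lower boundary is a
different convention; the image enumeration is isolated in one function so
it can be swapped.

## Numerical choices

* **Quadrature.**  1D and radial 3D integrals use adaptive quadrature
  (`stats::integrate`, relative tolerance $10^{-10}$) with the integrand
  split at the kink of the kernel.  The 2D double integral is written in
  polar coordinates around the *source* center: the radial Gaussian factor
  is then one-dimensional, and the angular integral — which has an
  integrable logarithmic singularity when the field point lies on the
  integration circle — is mapped by $v = \sin(\alpha/2)$ and evaluated
  with a tanh–sinh (double-exponential) rule, which absorbs endpoint
  singularities.  The radial integral is split at the singular radius and
  each panel also uses a tanh–sinh rule.  This fixed scheme was validated
  against an independent Bessel-ring oracle to $\sim 10^{-8}$ relative.
* **Support truncation.**  Gaussian sources are truncated where they fall
  below $10^{-12}$ of their peak ($\approx 7.43R$).
* **Lookup tables.**  All bases are isotropic, so kernel assembly needs
  potential values only as a function of distance.  `build_kernels`
  tabulates the radial potential on a uniform grid with spacing $R/20$
  (bounded to 129–4097 nodes) and interpolates with a cubic spline;
  interpolation error is below $10^{-6}$ relative (tested), and tables are
  cached per parameter set for the session.  `lookup = FALSE` switches to
  direct quadrature per value for verification work.
* **Solvers.**  $(K+\lambda I)\beta = V$ is solved through the stored
  eigendecomposition of $K$; modes with $\mathrm{eig} + \lambda$ below
  $10^{-12}$ of the largest are dropped (minimum-norm pseudo-inverse) with
  a warning recorded on the fit.  Leave-one-out systems are solved the
  same way: a Cholesky factorisation can succeed numerically on an
  effectively singular reduced kernel and silently amplify round-off,
  which the eigendecomposition route avoids.
* **Archives.**  Map archives are JSON with 17 significant digits, which
  round-trips IEEE doubles bit-exactly.

## Parameter selection

Cross-validation minimises the summed squared leave-one-out residuals over
all $N$ folds; the L-curve maximises the signed triangle area between each
point of the $(\log_{10}\rho, \log_{10}\eta)$ curve and the two *global*
endpoints of the λ grid (clockwise negative, so the corner of the L is the
maximum).  Ties break toward larger λ — the more regularised, more
conservative solution.  $\rho$ and $\eta$ are floored at $10^{-300}$
before taking logs.

Default grids: λ runs from the smallest eigenvalue of $K$ (floored at
machine precision relative to the largest) up to the population standard
deviation of the eigenvalues, 25 log-spaced points; $R$ runs from the
minimum to half the maximum interelectrode distance, 9 log-spaced points.
A winner on a grid edge sets `boundary_flag`, since extending the range
might do better.  Scans rebuild the kernel model per $R$; basis centers
default to a regular grid refined 4× per axis over the electrode bounding
box, which oversamples the electrodes enough that estimates are stable in
$M$.

## Diagnostics

* **Error propagation and uncertainty.**  Column $i$ of $E$ is the CSD
  response to a unit potential at electrode $i$; for electrode noise with
  covariance $\Sigma_V$ the estimated CSD has covariance $E\Sigma_V E^T$,
  whose diagonal is the uncertainty map (scalar shorthand
  $\sigma^2\,\mathrm{diag}(EE^T)$).
* **Eigensources.**  From $K = U\Lambda U^T$ (relative rank cutoff
  $10^{-12}$), eigensource $j$ is the field $\tilde K u_j$ — the estimate
  produced by the unit coefficient vector $u_j$.  We report fields
  unnormalised in CSD units with their eigenvalues; only directions matter
  for span and recoverability arguments, and each eigensource survives the
  forward-model/re-estimate round trip at $\lambda = 0$ by construction,
  which the tests verify to $10^{-6}$.
* **Point-wise error.**  The reliability machinery scores a
  reconstruction by the point-wise relative-difference measure
  $\mathrm{err}(x) = \big|\hat C(x)/\lVert\hat C\rVert -
  C(x)/\lVert C\rVert\big| \cdot \lVert C\rVert / \max_x |C|$.  The norm
  is the Euclidean norm over the estimation points — the natural discrete
  proxy for the function norm on a fixed grid; any quadrature-weighted
  alternative differs only by a constant on a regular grid.  The measure
  is invariant under positive rescaling of the estimate and scores a sign
  flip as $2|C(x)|/\max|C|$.

### Reliability maps and broken-contact studies

A reliability map averages the error field over a seeded family of test
profiles.  The generator's defaults are the study conditions: each profile
is a mixture of 4 Gaussian components with centers uniform in the
electrode bounding box, amplitudes alternating $\pm 1$ (dipolar
structure), and scales uniform in $[0.1, 0.5]$ ("small") or $[1, 2]$
("large") times the minimum interelectrode distance; the `both` family
alternates the two.  Forward modelling is noise-free, matching the
scenario the maps are meant to characterise, so λ is pinned at the
spectral floor of each kernel and only $R$ is selected, by
cross-validation per profile over the default $R$ grid.  On square grids
the error fields can optionally be averaged over the eight mirror
symmetries.  Maps are bit-deterministic given (seed, configuration): all
randomness derives from one seed through labelled 32-bit sub-streams, so
profiles, noise and removal sets can be replayed independently.

Broken-contact studies remove nested random subsets (the removal order is
one seeded permutation, so the 5 broken contacts are contained in the 10,
and those in the 20) and recompute the maps on the same estimation space
and profile set.  Each profile's $R$ stays pinned at its intact-grid CV
choice: re-selecting $R$ per broken count lets the estimator's smoothing
change along with the information loss, and the difference maps then
confound the two effects (in our experiments they even became
non-monotone in the number of broken contacts).  With the estimator held
fixed the difference maps isolate what the lost contacts cost.

### What the synthetic harness does and does not emulate

The harness generates smooth Gaussian-mixture sources, their exact forward
potentials, and i.i.d. uniform or multivariate normal electrode noise
(the demo fixture uses uniform noise at 5% of the peak potential — a
magnitude chosen once as a realistic "small noise" level).  It does not
emulate temporal dynamics (time samples are independent columns),
per-electrode noise heterogeneity, electrode position errors, conductivity
anisotropy or inhomogeneity, or sources outside the basis span other than
through the mixture families.  Passing tests therefore demonstrate
correctness of the estimator and its diagnostics under the stated physical
models, not robustness to violations of those models; the diagnostics
themselves (reliability maps in particular) are the tools to probe such
violations for a concrete setup.

### Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about a minute: reliability and broken-contact
studies use the 10×10 unit grid with 20 test profiles on a 15×15
estimation grid; Monte-Carlo validation of the uncertainty map uses
$10^4$ noise draws on the 3×3 grid; oracle comparisons use 6-electrode
fixtures where brute-force assembly is exact.  Larger grids change
nothing structurally — kernel assembly is $O(NM)$ spline evaluations and
the solves are $O(N^3)$.

## Known limitations

The MoI variant implements one boundary convention (symmetric saline,
layer on the electrode plane) as an explicit approximation; FEM-grade
geometry is out of scope.  There is no mechanism to weight electrodes by
individual noise levels — the practical recommendation is to drop clearly
bad channels, which the broken-contact tooling quantifies.  Reliability
maps depend on the chosen test-function family; they are heuristics for
building intuition, not guarantees for arbitrary sources.
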