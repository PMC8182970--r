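---
title: "Forward model and Bayesian calibration of a layered 2D vocal fold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward model and Bayesian calibration of a layered 2D vocal fold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

vfbayes implements a synthetic twin of a classic estimation problem in
computational phonation: given high-speed-video kinematics of a vibrating
silicone vocal fold — reduced to a length-averaged glottal width waveform —
infer the material properties of a layered finite-element fold model and the
driving subglottal pressure, and ask how sensitive those estimates are to
the glottal flow model used in the forward simulations.  Because no such video
observations are publicly deposited, the package generates its own
ground-truth observations by running the forward model at known parameters
and adding the observation noise model of the reference experiments; every estimation
experiment is therefore a calibration study with known truth.

## The solid model

The fold cross-section is a two-dimensional domain with four material
layers — body, superficial lamina propria (SLP), ligament, and a thin stiff
epithelium — meshed with 3-node linear triangles.  Linear isotropic
elasticity in plane strain is used, with the constitutive operator written
in terms of the shear modulus $\mu = E / (2(1+\nu))$; Kelvin–Voigt damping
replaces $\mu$ by $\mu + \eta\, d/dt$, which at element level makes the
damping matrix a rescaled element stiffness, $D_e = (\eta/\mu_e) K_e$.
Density and viscosity are shared across layers; each layer has its own
Young's modulus.  The semi-discrete system
$M\ddot\theta + D\dot\theta + K\theta = F$ is integrated with the implicit
Newmark average-acceleration rule ($\gamma = 1/2$, $\beta = 1/4$),
unconditionally stable for this linear system, with the time step fixed at
0.01 ms.

Collision with the hemilaryngeal contact plane is handled by projection:
after each step, any node whose deformed $x$ exceeds the plane is placed
exactly on the plane and its $x$-velocity and $x$-acceleration are zeroed
(a perfectly inelastic wall; the choice of velocity treatment is exposed in
the code and documented here because the alternative — keeping the
tangential-only reset — produces numerical chatter).  Medial compression
$m$ is applied before flow starts: the mount (and with it the stress-free
reference configuration) advances $m$ mm toward the plane and the
pre-phonatory equilibrium is the solution of the unilateral contact problem.
The package solves it with an active-set method; the literal incremental
path (advance in $10^{-4}$ mm steps, penalize crossing nodes with a fixed
$10^{-4}$ N force) is available as `method = "incremental"` and reaches the
same equilibrium, which for a linear-elastic solid is the unique minimizer
of a convex energy.

### Units

All mechanics run in a self-consistent mm–mg–ms–kPa system (force in mN).
This makes densities in mg/mm$^3$ numerically equal to g/cm$^3$, velocities
in mm/ms equal to m/s, and Kelvin–Voigt viscosities in kPa·ms numerically
equal to Pa·s, so user-facing values keep the field's customary units while
the stiffness assembly stays well-scaled at $\nu = 0.4995$.

### Geometry

No published coordinates exist for such cross-sections beyond schematics, so the package
ships its own modified-M5 four-layer cross-section
(`inst/extdata/m5_geometry.json`, generated by `tools/make_geometry.R` and
labelled synthetic).  The air-exposed surface runs from the inferior-medial
corner up a subglottal slope into a convergent entry, a flat medial contact
strip 0.2 mm short of the contact plane, and a mildly divergent exit; the
glottal channel spans $z \in [-3.6, 0]$ mm and the anterior–posterior depth
used to convert widths to areas is 14 mm.  Layer bands are inward offsets of
the surface chain: epithelium 0–0.35 mm, SLP 0.35–2.35 mm, ligament
2.35–3.35 mm, body inside.  The epithelium band is thicker than a real
silicone skin (~0.1 mm) so that it remains meshable at the default 0.3 mm
resolution; the cover is deliberately generous because the soft SLP carries
the mucosal-wave motion that feeds flow-induced oscillation.  The mesher is
a structured row mesher for z-monotone outlines: mesh rows follow the
outline's z-breakpoints, each row spans the domain width with a fixed column
count, and each quad is split along the diagonal that maximizes the minimum
angle (>15 degrees at all tested resolutions).  Triangulation quality and
per-layer area convergence are tested against shoelace polygon areas.

## The flow models

Both models act on a discretized channel: 50 stations between the glottal
inlet and outlet, each with a gap (fold surface to plane, clamped at zero),
an area (gap x depth), and a perimeter taken as $2 \times$ depth — the two
wide faces of a high-aspect-ratio rectangular duct.  Surface pressure is
applied as a consistent inward-normal load on the fluid-loaded boundary;
below the channel inlet the surface sees the full subglottal pressure, above
the outlet the supraglottal pressure (0 kPa).

**Bernoulli with separation ratio.**  The intraglottal pressure is
$p = p_{sub} - (p_{sub}-p_{sup})(A_{sep}/A)^2$ up to the separation point
and $p_{sup}$ beyond it, with $A_{sep} = r_{sep} A_{min}$.  The separation
point is the first station downstream of the minimum-area station where
$A \ge A_{sep}$; stations upstream of the minimum always use the Bernoulli
branch, and ties in the minimum resolve to the most superior station.  The
two branches agree where $A = A_{sep}$, so the distribution is continuous.

**1D viscous collapsible-tube flow.**  Steady continuity fixes $w = q/A$
with $A = \alpha(z) A_0(z)$, where $\alpha$ is the quadratic vena-contracta
correction equal to 1 at the inlet and 0.75 at the outlet.  The momentum
balance integrates $dp/dz = -\chi \rho_f w\, dw/dz - 2\mu (S/A)^2 w$, where
the separation-loss closure multiplies the advection by the recovery
constant $\chi$ ($\chi = 1$ at and upstream of the minimum-area station,
$\chi_{min} = 0.2$ downstream; the closure's published prefactor is read as
$A/S$ so that the shear stress has the dimensions of a stress), and the
friction term is the fully developed constant-section closure.  The flow
rate is found by shooting: the pressure profile is integrated from the
inlet (where $p = p_{sub}$) and a bracketed root solve drives the outlet
pressure to $p_{sup}$, the bracket grown geometrically from the
inviscid-orifice estimate; the result is independent of the bracket.  The
quasi-steady reduction (dropping the time derivatives within each 0.01 ms
structural step) is what makes the boundary-value-problem reading
well-posed per time instant; an optional mode retains $\rho_f \partial w /
\partial t$ by backward difference.  The integration is split exactly at the
minimum-area station so the $\chi$ discontinuity is never smeared.

A closed glottis (minimum area zero) stops the flow: the pressure is
assigned hydrostatically, $p_{sub}$ upstream of the first closed station,
zero over the contact zone, $p_{sup}$ downstream, and the solution is
flagged.  This is the driving that re-opens the glottis after collision.

## The observable

The model is two-dimensional, so the observable is a glottal *width*: the
exact minimum over the channel window of the piecewise-linear deformed
surface's distance to the plane (attained at surface nodes; the 50-station
grid is only the flow discretization).  This corresponds to the segmented
glottal area divided by the glottal length in such experiments.
Waveforms are sampled at 0.25 ms (a 4 kHz high-speed-video analogue) and the
first 50 ms of start-up transient is discarded.  Simulations start from the
precompressed contact equilibrium with the pressure switched on at $t = 0$;
no artificial kick is needed because that state is not a flow equilibrium.

## Study conditions of the synthetic twin

The generator's defaults are the study conditions: layer moduli
$E_b = 11.8$, $E_s = 0.6$, $E_l = 2.0$, $E_e = 45$ kPa (uniaxial-test
values; the epithelium modulus and $\nu = 0.4995$ and $p_{sup} = 0$ are
fixed, not estimated), medial compression $m = 0.4$ mm, subglottal pressures
0.910, 1.001, 1.092, 1.183 kPa, observation noise unbiased Gaussian with
1 mm$^2$ area-equivalent standard deviation (width sd $= 1/14$ mm), clipped
at zero width with the clip count recorded.

Two generator quantities are not fixed by the reference experiments and are the
package's own choices, fixed here once: density $\rho_b = 1070$ kg/m$^3$
(typical addition-cure silicone) and Kelvin–Voigt viscosity
$\eta = 0.002$ Pa·s with nominal separation ratio $r_{sep} = 1.4$.  The
viscosity deserves comment: real silicone loss is one to two orders larger,
but the 2D linear model's flow-to-structure energy transfer is weak — its
flutter threshold at ~1 kPa driving sits near $\eta \approx 0.01$ Pa·s — so
the twin adopts the damping at which it reproduces the experimentally
observed regime: sustained, regular ~76 Hz oscillation with collision in
every cycle.  This is a documented limitation of the model class (constant
strain triangles at $\nu = 0.4995$ additionally lock volumetrically,
stiffening the cover), not a statement about silicone rheology.  The nominal
$r_{sep}$ lies in the 1.2–1.4 range such estimation studies find most accurate.

On closure: the width reaches exactly zero whenever a surface node collides
with the plane, which happens in the large majority of cycles at nominal
driving; in the remaining cycles the minimum is of order 0.01 mm, below
anything the emulated segmentation could resolve (the observation noise
floor alone is 0.07 mm).  The package therefore defines *observational
closure* as width below 0.02 mm (`cycle_stats(closure_tol = 0.02)`) and
reports exact node contact separately.

## Importance-sampling inference

Bayes' rule with the prior as proposal: draw $n$ parameter vectors from
independent priors, run the forward model for each, weight by the Gaussian
likelihood of the observed waveform (prior densities cancel; weights are
computed from stabilized exponentials so any constant in the log-likelihood
drops out), resample multinomially with a seed stream decoupled from the
prior draws, and summarize with weighted means and standard deviations;
relative uncertainty is the standard deviation as a percentage of the
estimate, and the effective sample size $1/\sum w_i^2$ guards against
degenerate ensembles.  Forward-run failures at extreme prior draws receive
weight zero and are counted rather than aborting the study.  Simulated and
observed waveforms are registered by an integer-lag search (lags in
observation samples, lowest sum of squared residuals) before residuals are
formed, because there is no canonical way simulated and measured
waveforms were aligned; for periodic waveforms a one-sided search over at
least one period is sufficient.

Default priors (none are canonical): independent uniforms, moduli
within ±50% of nominal, $p_{sub}$ within ±20%, $\rho_b \in [900, 1200]$
kg/m$^3$, $\eta \in [0, 10]$ Pa·s, $m \in [0.2, 0.6]$ mm, and $r_{sep} \in
[1.0, 1.6]$ for the estimated-separation permutation (matching the swept
range).  All are configurable.

### Scaled-down problem sizes

Full-scale studies of this kind use ensembles of order 15 000 samples per estimate; the package's
test suite and the worked examples run a scaled-down twin chosen to complete
on a single CPU: a coarse mesh (~370 triangles at 0.75 mm resolution),
100 ms of simulated time per forward run, ensembles of a few hundred
samples, and narrowed uniform priors produced by `default_prior(scale =
0.25, eta_max = 0.02)` (moduli ±12.5%, $p_{sub}$ ±5%, $\rho_b$ ±37.5
kg/m$^3$, $m$ ±0.05 mm, $\eta \in [0, 0.005]$ Pa·s).  The likelihood is evaluated on a
30 ms fit window with a 10 ms registration overhang: at the 1 mm$^2$
noise level, longer windows make the Gaussian likelihood so sharp that a
few-hundred-sample prior ensemble cannot resolve the posterior (the
effective sample size collapses) — the same "whitening" consideration that
motivates inflating the noise in such studies.  These sizes are stated here as
the package's choices; scaling the ensemble up tightens the Monte-Carlo
error of the summaries but does not change the mechanics.

The flow-model sensitivity experiment deliberately fits a *mismatched*
model (Bernoulli permutations against a viscous-generated observation).
Under mismatch the 1 mm$^2$ likelihood is far sharper than the residual
model error, so a small prior ensemble degenerates onto its single best
draw; the experiment therefore inflates the likelihood scale to 3 mm$^2$ —
the smallest whole-number level keeping the effective sample size above 10
in both extreme permutations — which is precisely the whitening role such
observation models assign to their noise level.  It uses the
half-scale priors (moduli ±25%) so that mismatch biases of the expected
magnitude are expressible, and the 0.910 kPa observation, where the viscous
generator's waveform is most regular (full per-cycle closure, lag
registration cleanest).  In this twin the body modulus carries the
over/under-estimation signature strongly (normalized estimate ≈ 1.04 at
$r_{sep} = 1$ falling to ≈ 0.81 at $r_{sep} = 1.6$); the two soft cover
moduli are weakly identified and move in the same direction but from just
below truth, so the package's test asserts the aggregate pattern and the
per-modulus monotonic decrease rather than strict overestimation of every
modulus.

### What the synthetic twin does and does not show

Passing recovery tests on synthetic observations demonstrates that the
inference machinery is consistent: the forward model, noise model, and
likelihood agree, so posteriors cover the truth.  It does not validate the
physical fidelity of the 2D model against real silicone folds — the
generator and the fitter share every modelling idealization (2D plane
strain, linear elasticity, the flow closures, the contact rule).  The
flow-model sensitivity experiment is the exception: there the observation is
generated by the viscous model and fitted with the Bernoulli permutations,
so the estimate biases measure genuine model mismatch of the kind such
estimation studies report.

## Numerical choices and degenerate inputs

* Static contact solves converge to a 1e-8 relative residual; the shooting
  solver drives the outlet pressure to 1e-8 kPa.
* The Newmark effective operator and the banded Cholesky factorization are
  built once per run; a singular operator raises an integration error.
* Blow-ups (non-finite or >50 mm displacements) and channel fold-over
  (surface no longer single-valued in z) terminate a run with a diagnostic;
  during inference such runs are zero-weighted and counted.
* A fully closed channel short-circuits both flow solvers to the
  hydrostatic closed-glottis assignment (flagged in the solution).
* Ties in the minimum-area station break toward the most superior station;
  the recovery-constant switch sits exactly at that station.
* `n_stations = 50` resolves the area minimum without dominating cost;
  halving the station spacing changes nominal waveforms imperceptibly next
  to the structural discretization error.

## Known limitations

* Constant-strain triangles at $\nu = 0.4995$ lock volumetrically; the
  effective stiffness of the soft layers is therefore resolution-dependent
  (the twin always fits with the same mesh it generated with, so this does
  not bias the recovery experiments).
* The spatial resolution of closure is set by the surface node spacing;
  see the observational-closure definition above.
* No acoustic loading, no anterior-posterior variation or tension, no
  geometric or material nonlinearity: all are outside the model class by
  design.
* The effective viscosity is a stand-in for all unmodelled dissipation and
  should not be read as a silicone material property.
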