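---
title: "Modelling vascular smooth muscle tone: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vascular smooth muscle tone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasotone)
```

## The mechanical picture

An artery held at fixed axial stretch $\lambda_z$ and inflated to transmural
pressure $P$ is modelled as an incompressible thick-walled cylinder. With a
purely radial momentum balance, the pressure is carried by the integral of
the circumferential-radial stress difference across the loaded wall
$[a, b]$:

$$P = \int_a^b \frac{t_{\theta\theta} - t_{rr}}{r}\,\mathrm{d}r
    = \Gamma^{\mathrm{pas}} + \Gamma^{\mathrm{act}},$$

where the additive split follows from writing the Cauchy stress as a
passive hyperelastic extra stress plus an active extra stress contributed
by vascular smooth muscle cells (VSMCs), assumed purely circumferentially
oriented. Incompressibility ties the loaded outer radius to the inner one,
$b = \sqrt{(B^2 - A^2)/\lambda_z + a^2}$, and makes the deformation
gradient diagonal with $\lambda_\theta = r/R$,
$\lambda_r = 1/(\lambda_\theta \lambda_z)$.

The reference configuration is the unloaded, traction-free tube with inner
and outer radii $A$ and $B$: residual stress (opening angle) is not
modelled, axial force balance is not solved (the axial stretch is imposed,
matching inflation protocols at in vivo axial length), and torsion is
excluded.

## Passive wall

The passive wall is a four-fibre family hyperelastic solid,

$$\Psi^{\mathrm{pas}} = \frac{\mu}{2}(I_1 - 3)
  + \sum_{i=1}^4 \frac{k_1^i}{4 k_2^i}
  \left[e^{k_2^i (I_{4,i} - 1)^2} - 1\right],
  \qquad
  I_{4,i} = \lambda_\theta^2 \sin^2\alpha^i + \lambda_z^2 \cos^2\alpha^i,$$

with an elastin-like isotropic term ($\mu$, kPa) and exponential collagen
families at $0^\circ$ (axial), $90^\circ$ (circumferential) and
$\pm\alpha$ (diagonal), angles measured from the axial direction. The
Cauchy extra stress is the push-forward $2\mathbf{F}\,
\partial\Psi/\partial\mathbf{C}\,\mathbf{F}^{\mathsf T}$; with the
$k_1/(4k_2)$ energy prefactor the circumferential fibre stress is
$k_1 (I_4 - 1) e^{k_2 (I_4-1)^2} \lambda_\theta^2 \sin^2\alpha$. The test
suite verifies this against a central-difference push-forward of the
energy, which is the authoritative definition; note that a factor-2
variant of this expression circulates when the energy is written with a
$k_1/(2k_2)$ prefactor, so the pair (energy, stress) must be kept
consistent.

Fibre terms are evaluated literally: no tension-only switch is applied by
default, because the constitutive statement being implemented has none. A
`tension_only` flag exists for users who want compressed fibres excluded;
it is off by default and untouched by every fixture.

## The six active models

Each model supplies the circumferential active Cauchy stress
$t^{\mathrm{act}*}_{\theta\theta}(\lambda_\theta)$ and, through
$\Gamma^{\mathrm{act}} = \int_a^b t^{\mathrm{act}*}_{\theta\theta}/r\,
\mathrm{d}r$, its load bearing:

| family | stress | closed-form $\Gamma^{\mathrm{act}}$ | $\partial\Gamma^{\mathrm{act}}/\partial a$ |
|---|---|---|---|
| constant Cauchy | $T_c$ | $T_c \ln(b/a)$ | $<0$ always |
| constant 1st PK | $T_i\lambda_\theta$ | $\tfrac{T_i}{\sqrt{\lambda_z}}\ln\tfrac{B+\sqrt{\lambda_z}b}{A+\sqrt{\lambda_z}a}$ | $<0$ always |
| constant 2nd PK | $T_r\lambda_\theta^2$ | $\tfrac{T_r}{2\lambda_z}\ln\tfrac{B^2}{A^2}$ | $=0$ exactly |
| Rachev–Hayashi | $T_{Rv}\lambda_\theta f(\lambda_\theta)$ | polynomial/log form on the bell support | sign by inequality |
| Zulliger | $S_1 S_2 T_{Zr}(\lambda_\theta\lambda_{pre}-1)$ | $\lambda_{pre}$-weighted 1st PK minus Cauchy | sign by inequality |
| Franchini | $2 S_1 T_{Fr,1}\lambda_\theta^2[1+\alpha_1 E-\beta_1 E^{m_1}]$, $E=\lambda_\theta^2-1$ | closed form for $m_1=2$ | sign by inequality |

The three stress measures express the same idea referred to different
configurations: a constant Cauchy stress (current area), a constant 1st
Piola–Kirchhoff stress (force unchanged by deformation) and a constant 2nd
Piola–Kirchhoff stress (fully referential, scaling as $\lambda_\theta^2$
in Cauchy terms). The 2nd PK case is special: its load bearing is
independent of the deformed configuration, so contraction shifts the
pressure–diameter curve vertically by
$\tfrac{T_r}{2\lambda_z}\ln(B^2/A^2)$ and can never create a limit point.

The bell-shaped Rachev force–length function
$f(\lambda_\theta) = 1 - \left(\tfrac{\lambda_m - \lambda_\theta}{\lambda_m -
\lambda_0}\right)^2$ on $[\lambda_0,\, 2\lambda_m - \lambda_0]$ (zero
outside, peak $f(\lambda_m) = 1$) encodes the actin–myosin overlap
optimum. Zulliger's model keeps only the ascending limb, sensed at the
muscle-level stretch $\hat\lambda_\theta = \lambda_\theta\lambda_{pre}$
(deposition stretch $\lambda_{pre}$) and gated by
$S_2 \in \{0, 1\}$ on $[\hat\lambda_{lb}, \hat\lambda_{ub}]$; gates
default to $\pm\infty$. Franchini's polynomial allows asymmetric
force–length shapes; the axial muscle family and in-plane dispersion are
fixed at zero here so all six models are comparable as purely
circumferential. Activation $S_1$ defaults to 1 (maximal contraction),
where instability is most likely.

### Closed forms vs quadrature

Closed-form $\Gamma^{\mathrm{act}}$ expressions are used only when their
derivation is valid for the whole wall: the Rachev bell support and the
Zulliger gate must contain the full transmural stretch range, and the
Franchini closed form requires $m_1 = 2$. Otherwise
`active_pressure_closed_form()` raises a typed condition and
`active_pressure_quadrature()` integrates adaptively, splitting the
interval at the radii where the support or gate switches (the transmural
stretch profile is monotone in $r$, so each threshold crosses at most
once, located by bisection to $10^{-12}$). Closed forms and quadrature are
cross-checked to $10^{-8}$ relative on a $20\times20$ grid of
$(a, \lambda_z)$ states in the acceptance suite.

For the gated Zulliger energy, the implementation extends the on-gate
energy branch continuously (constant) outside the gate rather than
dropping it to zero; this keeps the stress — the physically meaningful
derivative — exactly zero outside the gate while avoiding a spurious
energy discontinuity. Inside the gate the printed expression is evaluated
verbatim, and differentiation of the gated energy was checked to
reproduce the gated stress exactly, resolving a question about their
mutual consistency: there is no discrepancy.

## Instability

A limit point appears when $\partial P/\partial a < 0$ somewhere:
a pressure then maps to multiple equilibrium diameters and the vessel can
snap between branches. Since hyperelastic passive walls give
$\partial\Gamma^{\mathrm{pas}}/\partial a > 0$, the active term decides.
The package provides both the analytic per-family inequalities (model
parameters on one side, geometry and deformation on the other) via
`stability_condition()` and a numerical scan via
`find_instability_regions()`: $\mathrm{d}P/\mathrm{d}a$ is sampled on a
400-point grid (default; folds in practice are wide relative to this),
sign changes are bisected to $10^{-6}$ mm, and negative intervals are
reported. `solve_radius()` returns *all* roots of $P(a) = P^\ast$ with no
silent branch selection — downstream consumers decide, with the stability
report in hand.

## Thin-wall mode

When only the zero-pressure radius-to-thickness ratio $b_0/h_0$ is known
(the situation for published canine contraction curves), the wall is
treated as a membrane: the modelled active pressure is

$$\Gamma^{\mathrm{act}}_{\mathrm{mod}} =
  t^{\mathrm{act}*}_{\theta\theta}(\lambda_\theta)\,
  \frac{h_0}{b_0\,\lambda_\theta^2\,\lambda_z},$$

with the average wall stretch approximated by the normalised outer
diameter $b/b_0$. The experimental counterpart resamples paired fully
relaxed and maximally contracted pressure–diameter curves at common
normalised diameters and subtracts the pressures. Numerical choices here,
stated because the procedure itself does not prescribe them:

* both curves are normalised by the **relaxed** zero-pressure diameter, so
  the diameter axis approximates one common stretch axis;
* resampling is uniform in normalised diameter over the overlap of the two
  curve ranges;
* pressure is interpolated as a function of diameter with the monotone
  Fritsch–Carlson piecewise cubic (no overshoot on the stiff high-pressure
  limb); a linear fallback is selectable.

The thick-wall active pressure converges to the thin-wall expression as
$(B-A)/A \to 0$ at rate $O(h)$; the tests verify the limit on a sequence
of thinning geometries.

## Parameter estimation

**Sparse data (single contraction point).** Given a held pressure, an
axial stretch, and a fractional outer-diameter reduction, exactly one
stress-like parameter $T$ is free; shape parameters are imposed. The
shipped `preset_table1_mouse()` carries the imposed values used in the
murine protocol this mode replicates: $\lambda_m = 1.60$,
$\lambda_0 = 0.80$ (Rachev; peak muscle stress at physiological pressure,
support continuous over the working range), $\lambda_{pre} = 1.83$ with
gates $1.20/3.83$ (Zulliger), $\alpha_1 = 2.3$, $\beta_1 = 0.95$,
$m_1 = 2$ (Franchini). The fit drives
$\Pi = b_{\mathrm{measured}} - b_{\mathrm{modelled}}$ to zero with a
bracketing search in $T$ (the passive load-bearing curve is cached on a
spline over the scan grid, so each trial $T$ costs only closed-form active
evaluations). The match is on **outer** diameter, as measured. When the
contracted relation folds, all roots are found, the branch closest to the
target is used, `instability_flag` is raised, and the result records
whether the matched equilibrium lies on a rising (stable) branch —
a datum inside the fold can be matched only on the descending branch,
which is the "unfittable" constant-Cauchy situation.

**Dense data (active pressure curve).** Bounded nonlinear least squares of
$\Pi = \sum_i (\Gamma^{\mathrm{act}}_{\mathrm{exp},i} -
\Gamma^{\mathrm{act}}_{\mathrm{mod},i})^2$. Default boxes: stress-like
parameters in $[0, 1000]$ kPa, $\lambda_m \in [1, 3]$,
$\lambda_0 \in [0, \lambda_m)$ (enforced by penalty, since a box cannot
express the ordering), $\lambda_{pre} \in [0.5, 3]$,
$\alpha_1 \in [0, 5]$, $\beta_1 \in [0, 2]$ — no bounds are inherent to
the models; these cover published fits with margin. Multi-parameter
families use 8 Latin-hypercube starts (seed 1234 by default; the fit is a
deterministic function of the seed, and the session RNG stream is left
untouched) refined by `nlminb`; the integer Franchini exponent is handled
by a discrete sweep over $m_1 \in \{1,2,3,4\}$ with a continuous inner
solve. With 3–4 free parameters against ~13 resampled points,
identifiability is marginal by construction; the result reports which
bounds were hit and the best start rather than pretending the optimum is
unique.

## What the synthetic generators emulate — and what they do not

`make_mouse_like_vessel()` returns a frozen stand-in: geometry
$A = 0.55$, $B = 0.70$ mm, $\mu = 20$ kPa, fibre families
$(k_1, k_2, \alpha) = (12, 0.25, 0^\circ), (8, 0.6, 90^\circ),
(6, 0.9, \pm45^\circ)$ kPa, at in vivo axial stretch 1.60. The parameters
were tuned **once** so that the relaxed curve is compliant below ~60 mmHg,
stiffens above ~120 mmHg, passes the frozen sanity window (5–40 kPa at
inner-wall stretch 1.8), and reproduces the qualitative sparse-data
phenomenology: a strong constant-Cauchy tone folds the curve and the
29%-at-90-mmHg contraction target falls inside that fold, while the other
five families remain monotone at published-scale parameters. They are
*not* the passive parameters of any real animal: a green test on this
fixture establishes correctness of the machinery (equilibrium, splits,
closed forms, fitting), not agreement with measured murine stress values,
which would require the original supplementary passive parameters.

`generate_cox_like_curves()` emulates the canine protocol: 13 pressures,
0–240 mmHg in 20 mmHg steps, diameters normalised to the zero-pressure
relaxed diameter, with a frozen monotone thin-wall passive law (linear +
extension-exponential + compression-exponential, the latter so that
contracted equilibria below the unloaded diameter exist). Measurement
noise, when requested, is Gaussian on the **pressure** axis (the
measurement axis in inflation myography), seeded and byte-reproducible;
the zero-pressure anchor is kept exact so normalisation stays defined.
Real contracted arteries add transient tone dynamics, axial coupling and
history effects that this generator deliberately omits.

## Degenerate inputs, tie-breaks, tolerances

* Quadrature: adaptive Gauss–Kronrod (`stats::integrate`), relative
  tolerance $10^{-10}$ (passive) and $10^{-11}$ (active), with explicit
  breakpoints at support/gate switches; a failed passive quadrature aborts
  with the estimated error in the message.
* Passive radius derivative: central differences with one Richardson
  (step-halving) extrapolation, step $10^{-4}\max(a, A)$.
* Root finding: `uniroot` to $10^{-12}$ inside scan-grid brackets; roots
  re-evaluate to the target pressure within $10^{-8}$ kPa.
* Fits report `converged = FALSE` (never an exception) when the target is
  unattainable — e.g. a diameter inside a fold gap; degenerate inputs
  (all-equal diameters, fewer samples than parameters, non-monotone
  curves) are rejected with named validation errors.
* Pressure unit: kPa everywhere internally; mmHg accepted and produced at
  the I/O boundary with 1 mmHg = 0.133322 kPa exactly.

## Known limitations

No residual stress/opening angle; no axial force balance; no calcium or
cross-bridge kinetics (all models are phenomenological in the activation);
no dispersion or axial muscle family in the Franchini model; no joint
passive+active estimation; no uncertainty quantification beyond residuals
and bound-activity diagnostics. The thin-wall mode keeps $b_0/h_0$ fixed
(no thickness update with pressure). Published dense-data parameter sets
cannot be reproduced here because the underlying experimental curves are
external; the package covers that regime with generator round trips
instead.
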