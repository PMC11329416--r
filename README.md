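# vasotone

Constitutive modelling of vascular smooth muscle cell (VSMC) contraction
in arteries.

Vascular smooth muscle tone shifts the pressure–diameter behaviour of a
blood vessel, but contraction experiments typically record very little of
that shift — often a single point (hold the pressure, add a
vasoconstrictor, watch the diameter fall). Choosing an active stress model
that both fits such sparse data and behaves sensibly across the
physiological deformation range is the problem this package addresses, for
vascular biomechanicists fitting myography data and for modellers who need
an active wall law that will not fold under them.

## Model

The artery is an incompressible thick-walled cylinder at fixed axial
stretch λ_z. The transmural pressure splits additively into passive and
active load bearing:

    P = Γ_pas + Γ_act
      = ∫_a^b (t_θθ^pas* − t_rr^pas*)/r dr + ∫_a^b t_θθ^act*/r dr

The passive wall is a four-fibre family hyperelastic solid (elastin-like
neo-Hookean term + exponential collagen families at 0°, 90°, ±α). The
active circumferential Cauchy stress t_θθ^act*(λ_θ) comes from one of six
constitutive families:

| family            | stress                                             | behaviour of Γ_act(a)     |
|-------------------|----------------------------------------------------|---------------------------|
| constant Cauchy   | T_c                                                | decreasing (destabilising)|
| constant 1st PK   | T_i λ_θ                                            | decreasing (destabilising)|
| constant 2nd PK   | T_r λ_θ²                                           | constant (neutral)        |
| Rachev–Hayashi    | T_Rv λ_θ f(λ_θ), bell-shaped f                     | sign from an inequality   |
| Zulliger          | S₁S₂ T_Zr (λ_θ λ_pre − 1), gated                   | sign from an inequality   |
| Franchini         | 2S₁ T_Fr1 λ_θ² [1 + α₁E − β₁E^m1], E = λ_θ² − 1    | sign from an inequality   |

Every family ships with its closed-form Γ_act (where one exists), an
adaptive-quadrature fallback, the analytic ∂Γ_act/∂a, and the analytic
limit-point stability condition. Where ∂P/∂a < 0 the pressure–radius
relation folds: one pressure has several equilibrium diameters and the
vessel can snap between them — the package detects these regions and
returns every root, never silently picking a branch.

Two estimation regimes mirror the two kinds of experiments: a
single-contraction-point fit (one free stress-like parameter, shapes
imposed) and a thin-wall active-pressure-curve fit (bounded nonlinear
least squares with seeded multi-start). Deterministic synthetic-data
generators stand in for the experimental inputs.

## Worked example

Sparse-data regime: a mouse-aorta-like synthetic vessel is held at
90 mmHg and λ_z = 1.60, and contraction reduces the outer diameter by
29%. Fit the constant 2nd Piola–Kirchhoff model:

```r
library(vasotone)

vessel <- make_mouse_like_vessel()
datum  <- contraction_datum(P_mmHg = 90, lambda_z = 1.60, reduction = 0.29)

fit <- fit_single_point(vessel$geom, vessel$passive, datum, "constant_2pk")
fit
#> <fit_result>
#>   parameters: Tr = 60.5048
#>   residual = 2.12e-14, converged = TRUE, instability_flag = FALSE
```

A 2nd PK stress of ~60.5 kPa reproduces the measured contraction exactly
(residual is the diameter mismatch in mm), and the contracted
pressure–radius relation stays single-valued:

```r
model <- active_model("constant_2pk", Tr = fit$parameters$Tr)
find_instability_regions(vessel$geom, vessel$lambda_z, vessel$passive, model)
#> <stability_report> monotone pressure-radius relation (no folds)
```

The constant Cauchy model, by contrast, folds the curve; the only
equilibrium matching the datum sits on the descending (unstable) branch,
so the datum is not physically attainable under this model:

```r
cauchy <- fit_single_point(vessel$geom, vessel$passive, datum, "constant_cauchy")
cauchy
#> <fit_result>
#>   parameters: Tc = 58.4113
#>   residual = 3.55e-09, converged = TRUE, instability_flag = TRUE
cauchy$diagnostics$stable_match
#> [1] FALSE
```

Dense-data regime: paired relaxed/contracted curves (13 pressures,
0–240 mmHg) are reduced to the experimental active pressure
Γ_exp = P_contracted − P_relaxed at common normalised diameters and
refit:

```r
tw     <- thin_wall_vessel(radius_to_thickness = 8, lambda_z = 1)
curves <- generate_cox_like_curves(tw, active_model("constant_2pk", Tr = 60))
gexp   <- experimental_active_pressure(curves$relaxed, curves$contracted)
head(as.data.frame(gexp), 3)
#>   normalised_diameter gamma_act_kPa
#> 1            1.000000      7.453580
#> 2            1.046773      7.480594
#> 3            1.093547      7.530703

fit_active_curve(gexp, tw, "constant_2pk")
#> <fit_result>
#>   parameters: Tr = 59.9943
#>   residual = 0.00448, converged = TRUE, instability_flag = FALSE
```

The generating stress (60 kPa) is recovered to 0.01%; the residual is the
sum of squared pressure misfits (kPa²), limited here by interpolating the
13-point curves.

## Command line

```sh
Rscript inst/cli/vasotone.R synth     --out runs/demo --seed 3
Rscript inst/cli/vasotone.R gamma-exp --relaxed runs/demo/relaxed.csv \
        --contracted runs/demo/contracted.csv --out runs/demo
Rscript inst/cli/vasotone.R case-study --mode mouse --out runs/mouse
```

Subcommands: `simulate`, `stability`, `gamma-exp`, `fit-point`,
`fit-curve`, `synth`, `case-study`. Curves travel as CSV
(`pressure_mmHg`, `outer_diameter_mm`, `normalised_outer_diameter`),
configurations and fit results as JSON with seeds and input hashes.

## Caveats

The bundled "mouse-like" vessel is a documented synthetic stand-in, tuned
once to physiological curve shape and frozen — it is not a measured
parameter set, and numbers fitted on it (like the 60.5 kPa above) are
fixture properties, not biology. See the methods vignette
(`vignettes/active-stress-models.Rmd`) for the model assumptions,
numerical choices and limitations in full.
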