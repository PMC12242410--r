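# glycotube

Equilibrium energetics of membrane tube formation driven by the
glycocalyx — the dense, sugar-rich polymer brush coating the outside of
most cell membranes. The package is for membrane biophysicists and
modellers who want to ask, quantitatively: *when does a grafted polymer
brush, by itself or helped by actin forces, line tension and spontaneous
curvature, make a membrane tube energetically favorable?*

## The model

A brush-coated membrane patch of fixed area πR₀² deforms into a cylinder
of radius R_t and length L_t capped by a hemisphere of the same radius.
The single shape variable is χ = L_t/R_t, with R_t = R₀/√(2(1+χ)) fixed
by area conservation; χ = 0 is the nontubular (hemispherical-cap) state.
The normalized total free energy,

    F/πκ =  χR_t²(1/R_t − c₀)² + R_t²(2/R_t − c₀)²     (Canham-Helfrich bending)
          + (σ/κ)(2χ+1)R_t²                             (tension × excess area)
          + 2(λ/κ)R_t                                   (domain-boundary line tension)
          − f·R_t(1+χ)/(πκ)                             (vertical actin point force)
          + [N_p^cap·E_cap + N_p^tube·E_tube]/(πκ)      (brush, cap + tube)

couples membrane elasticity (κ, σ, λ, c₀), a point load f, and the
curvature-dependent free energy per brush chain E_cap, E_tube (closed
forms for chains of N monomers of size a, excluded volume v = a³, grafting
distance ξ, density ρ = 1/ξ²; see the methods vignette in
`vignettes/glycotube-model.Rmd`). Minimizing F over χ yields the
equilibrium morphology. The transition from the nontubular to the tubular
state is **first order**: the optimal χ jumps discontinuously at a
critical grafting density ρ_c (or chain length N_c), with binodal
(equal-energy) and spinodal (minimum-appearance) branches and an energy
barrier between the basins.

## Worked example

```r
library(glycotube)

# reference density-sweep conditions: kappa = 10 kBT, sigma = 0.012 kBT/nm^2,
# no line tension, spontaneous curvature or actin force, N = 20 monomers
p <- update_params(model_params(), lam = 0, c0 = 0, f = 0)

scan_landscape(update_params(p, rho = 0.009))
#> Energy landscape over chi in [0, 30] (3001 points)
#>   state: tubular
#>   global minimum: chi_min = 24.1204, F = 191.82 pi-kappa
#>   2 local minima; F(0) = 199.579
#>   barrier: 12.8429 pi-kappa at chi = 1.445
```

At ρ = 0.009 nm⁻² the tubular basin (χ ≈ 24, i.e. a tube of radius
≈ 14 nm and length ≈ 340 nm) lies 7.8 πκ below the hemispherical cap, but
forming it requires crossing a 12.8 πκ (≈ 400 kBT) barrier. The critical
densities bracketing the metastable window:

```r
critical_density(p, "binodal")
#> Critical rho (binodal): 0.00758837 1/nm^2
#>   bracket [0.00758837, 0.00758837], chi at transition = 17.81
critical_density(p, "spinodal")
#> Critical rho (spinodal): 0.00475253 1/nm^2
#>   bracket [0.00475253, 0.00475253], chi at transition = 4.181

sweep_1d(p, "rho", c(0.005, 0.007, 0.0076, 0.008, 0.009))[1:4]
#>      rho  chi_min     F_min              state
#> 1 0.0050  0.00000  86.58842 metastable-tubular
#> 2 0.0070  0.00000 138.75672 metastable-tubular
#> 3 0.0076 17.85663 156.09527            tubular
#> 4 0.0080 19.61868 166.14288            tubular
#> 5 0.0090 24.12039 191.81967            tubular
```

The jump of χ_min from 0 to ≈ 18 across ρ_c ≈ 0.0076 nm⁻² is the
first-order signature. Two-dimensional phase diagrams over chain number
and length, and critical-value curves against actin force, line tension
and spontaneous curvature, are driven by `sweep_2d()`,
`critical_curve()` and the ready-made `builtin_scenarios()` /
`run_experiment()` pair; a thin command-line wrapper lives at
`inst/cli/glycotube.R`.

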