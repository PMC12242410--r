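---
title: "Energetics of glycocalyx-driven membrane tubulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics of glycocalyx-driven membrane tubulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotube)
```

## The model

Many cell-surface protrusions — microvilli, filopodia, tubular extensions —
carry a dense, sugar-rich polymer coat, the glycocalyx. Chains grafted at
high density crowd one another; bending the membrane away from the chains
dilutes the brush and lowers its free energy, so a sufficiently dense or
long brush can pay the elastic cost of pulling a membrane tube. `glycotube`
implements the equilibrium energetics of this competition for a fixed
geometric family: a membrane patch of fixed area $\pi R_0^2$ deformed into a
cylinder of radius $R_t$ and length $L_t$ closed by a hemispherical cap of
the same radius. The single shape degree of freedom is the dimensionless
shape parameter

$$\chi = L_t / R_t, \qquad R_t = \frac{R_0}{\sqrt{2(1+\chi)}},$$

where the radius follows from area conservation
$2\pi R_t L_t + 2\pi R_t^2 = \pi R_0^2$. $\chi = 0$ is the *nontubular*
reference state — a hemispherical cap, not a flat patch — and growing
$\chi$ describes progressively longer, thinner tubes.

The total free energy, normalized by $\pi\kappa$, is the sum of six terms:

* **bending** (Canham-Helfrich): $\chi R_t^2(1/R_t - c_0)^2 +
  R_t^2(2/R_t - c_0)^2$ for the tube and cap, with bending rigidity
  $\kappa$ and bilayer spontaneous curvature $c_0$ (kept distinct from any
  brush effect);
* **membrane tension**: $(\sigma/\kappa)(2\chi + 1)R_t^2$, tension
  $\sigma$ times the excess area $\Delta A = (2\chi+1)\pi R_t^2$;
* **line tension**: $2(\lambda/\kappa) R_t$ along the boundary of the
  brush-coated domain;
* **actin force work**: $-f R_t (1 + \chi)/(\pi\kappa)$, a vertical point
  force $f$ acting over the patch height $Z = R_t(1+\chi)$;
* **brush energy on the cap and on the tube** (below).

All energies are handled internally in units of $k_BT$ and reported in
units of $\pi\kappa$; `energy_to_kBT()` converts.

## The brush energy on curved surfaces

Each chain has $N$ monomers of size $a$ with excluded volume $v$ (default
$v = a^3$ for a neutral brush) and occupies area $\xi^2$ at the grafting
surface; the grafting density is $\rho = 1/\xi^2$. The brush free-energy
density combines Gaussian stretching and binary monomer contacts,
$\tfrac{3}{2a^2 c_p s^2} + v c_p^2$ per unit volume, where $c_p(r)$ is the
monomer concentration and $s(r)$ the area per chain at radial distance $r$.
On a sphere $s(r) = \xi^2 (r/R_t)^2$ and on a cylinder
$s(r) = \xi^2 (r/R_t)$: outward curvature opens space for the chains.

Closing the model requires a concentration profile. We evaluate the density
at the local flat-brush equilibrium concentration
$c_p(r) = (3/(v a^2))^{1/3}\, s(r)^{-2/3}$ — the profile whose planar limit
reproduces the classical brush height $h_0 = N (v a^2 / 3\xi^2)^{1/3}$ —
and fix the brush edge by monomer conservation $\int c_p\, s\, dr = N$.
Carrying out the radial integrals gives closed forms for the energy per
chain,

$$E_{\mathrm{cap}} = \frac{9R_t}{2}\, 3^{2/3}
  \Big(\frac{v}{a^4\xi^2}\Big)^{1/3}
  \Big[\Big(1 + \frac{5N}{3R_t}\Big(\frac{v a^2}{3\xi^2}\Big)^{1/3}
  \Big)^{1/5} - 1\Big],$$

$$E_{\mathrm{tube}} = \frac{9R_t}{4}\, 3^{2/3}
  \Big(\frac{v}{a^4\xi^2}\Big)^{1/3}
  \Big[\Big(1 + \frac{4N}{3R_t}\Big(\frac{v a^2}{3\xi^2}\Big)^{1/3}
  \Big)^{1/2} - 1\Big],$$

in $k_BT$. Three independent checks pin these expressions down and are
enforced in the test suite: (i) both reduce, as $R_t \to \infty$, to the
same planar-brush energy
$\tfrac{3N}{2}\, 3^{1/3} v^{2/3} a^{-2/3} \xi^{-4/3}$, which is exactly the
uniform-stretching planar result; (ii) they match direct numerical
quadrature of the energy density with the edge found by root finding; and
(iii) they are dimensionless multiples of $k_BT$, as an energy must be.
The total brush contribution multiplies the per-chain energies by the chain
counts $N_p^{\mathrm{cap}} = 2\pi R_t^2/\xi^2$ and
$N_p^{\mathrm{tube}} = 2\pi R_t L_t/\xi^2$; the total chain number
$\pi R_0^2/\xi^2$ is conserved for every $\chi$. Ternary (third-virial)
contacts, electrostatics (mucins are in reality charged), brush
polydispersity and lateral chain diffusion are all outside the model.

## Landscapes, states and critical points

`scan_landscape()` samples $F(\chi)$ on a dense grid over $[0, \chi_{max}]$
(default $[0, 30]$ with 3001 points), refines every interior minimum by
golden-section search to better than $10^{-6}$ in $\chi$, and treats
$\chi = 0$ as a boundary candidate via a one-sided test. If the energy is
still decreasing at $\chi_{max}$ the scan errors out and asks for a larger
range rather than report a truncated minimum; the sweep and root-finding
drivers retry automatically with a fourfold range. Landscapes are labelled

* `nontubular` — only minimum at $\chi = 0$;
* `metastable-tubular` — a tubular minimum exists above $F(0)$;
* `coexistence` — tubular and nontubular minima equal within a tolerance
  (default $10^{-3}\,\pi\kappa$: two orders below the unit bending scale,
  comfortably above refinement error);
* `tubular` — the tubular minimum is the global one.

The transition is first order: the optimal $\chi$ jumps discontinuously
and the two basins are separated by an energy barrier
(`energy_barrier()`), the refined interior maximum measured from $F(0)$.
A degenerate tie between two tubular minima is resolved toward the smaller
$\chi$ with a warning.

Two critical points are exposed, because both phenomena are natural
"critical values": the **binodal** (coexistence) density or chain length,
where the basin energies cross, and the **spinodal**, where the secondary
minimum first appears. Both are located by bisection on a state predicate
(`critical_density()`, `critical_length()`), with the bracket auto-expanded
once in the failing direction before raising a "no transition in range"
error. The default density tolerance is $10^{-10}$ nm$^{-2}$ so the basin
equality at the root is resolved below $10^{-6}\,\pi\kappa$. $N$ is treated
as a continuous variable for root finding (its integer ceiling is also
reported). Under the reference density-sweep conditions ($\kappa = 10$,
$\sigma = 0.012$, $\lambda = c_0 = f = 0$, $N = 20$) the binodal computes
to $\rho_c \approx 0.0076$ nm$^{-2}$ and the spinodal to
$\approx 0.0048$ nm$^{-2}$; the length transition at
$\rho = 0.0064$ nm$^{-2}$ sits near $N_c \approx 38$.

A genuine feature of the model worth knowing: at sparse grafting (e.g.
$\xi = 15$ nm, $\rho \approx 0.0044$ nm$^{-2}$, with no facilitating
factors) the basin gap *saturates* as $N \to \infty$ and no chain length
triggers coexistence — `critical_length()` then raises its documented
error. Length-driven transitions require a sufficiently dense brush, which
is why the length analyses here fix $\rho = 0.0064$ nm$^{-2}$.

## Parameters

| key | meaning | units | default |
|-----|---------|-------|---------|
| `kappa` | bending rigidity | kBT | 10 |
| `sigma` | membrane tension | kBT/nm² | 0.012 |
| `lam` | line tension | kBT/nm | 0.5 |
| `c0` | spontaneous curvature | 1/nm | 0.02 |
| `f` | vertical actin force | kBT/nm | 1 |
| `R0` | patch radius | nm | 100 |
| `xi` (`rho`, `Np`) | grafting distance (density, chain count) | nm | 15 |
| `N` | monomers per chain | — | 20 |
| `a` | monomer size | nm | 10 |
| `v` | excluded volume | nm³ | `a^3` |
| `chi_max`, `n_grid` | scan range / resolution | — | 30 / 3001 |

`xi` is canonical storage; `rho = 1/xi^2` and the total chain count
`Np = pi R0^2 / xi^2` are accepted everywhere as equivalent keys
(`update_params()`), since sweeps and phase maps are most naturally
parameterized by density or chain number. Note that updating `a` does not
silently rescale `v`.

The facilitating factors enter the defaults switched *on*; the
density-sweep reference conditions switch `lam`, `c0` and `f` to zero, as
do the `fig2`/`fig3` scenarios in `builtin_scenarios()`.

## Phase diagrams and numerical choices

`sweep_1d()` and `sweep_2d()` tabulate $\chi_{min}$ and the state label
over parameter grids; the 2D driver extracts the nontubular/tubular
boundary as midpoints of label-changing grid edges (no sub-grid polish).
For the chain-number axis the mapping $\xi = R_0\sqrt{\pi/N_p}$ is applied
per cell. The shipped phase-map scenarios use the window
$N_p \in [\pi, 100\pi]$ (from the plausible grafting-distance range
$\xi \in [10, 100]$ nm on the default patch) and $N \in [10, 50]$, at
41×41 resolution (the acceptance checks use 21×21, which resolves the
same containment relations in well under a minute per map). Everything in
the pipeline is deterministic — repeated runs produce byte-identical CSV
output.

Increasing any facilitating factor ($f$, $\lambda$, $c_0$) lowers both
critical values and grows the tubular region pointwise; with
$\lambda = 0.5$ kBT/nm, $c_0 = 0.02$ nm$^{-1}$ and $f = 1$ kBT/nm no
nontubular cell remains in the shipped window — the cells at very low
chain number are metastable rather than nontubular, i.e. a tubular local
minimum always exists there even though it is not global.

## What the tests do and do not show

The test suite verifies the implementation against independent oracles —
algebraic equivalence of factored and expanded mechanical forms, radial
quadrature of the brush energy density, brute-force fine-grid minimization,
scaling invariance under uniform length rescaling — and reproduces the
model's critical densities at their reported two-significant-figure
precision. Passing these tests validates the mathematics of this model,
not its biology: the geometry family is prescribed (no free-boundary shape
solving), the brush is neutral and laterally homogeneous, and membrane-
cortex attachment is ignored. Real glycocalyx layers are polydisperse,
charged and spatially heterogeneous; the model's claims should be read as
equilibrium statements about an idealized brush-membrane composite.

## A worked example

```{r example, eval = FALSE}
p <- update_params(model_params(), lam = 0, c0 = 0, f = 0)

scan_landscape(update_params(p, rho = 0.009))
#> Energy landscape over chi in [0, 30] (3001 points)
#>   state: tubular
#>   global minimum: chi_min = 24.1204, F = 191.82 pi-kappa
#>   2 local minima; F(0) = 199.579
#>   barrier: 12.8429 pi-kappa at chi = 1.445

critical_density(p, "binodal")
#> Critical rho (binodal): 0.00758837 1/nm^2
#>   bracket [0.00758837, 0.00758837], chi at transition = 17.81
```
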