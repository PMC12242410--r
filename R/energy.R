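#' Mechanical (membrane + line tension + force) energy components
#'
#' Components of the normalized free energy of the bare membrane at shape
#' parameter `chi`, in units of `pi * kappa`:
#' \itemize{
#'   \item bending: `chi*Rt^2*(1/Rt - c0)^2 + Rt^2*(2/Rt - c0)^2` (tube plus
#'     hemispherical cap, Canham-Helfrich with spontaneous curvature `c0`),
#'   \item tension: `(sigma/kappa)*(2*chi + 1)*Rt^2` (tension times excess
#'     area),
#'   \item line_tension: `2*(lam/kappa)*Rt` (boundary of the brush domain),
#'   \item force_work: `-f*Rt*(1 + chi)/(pi*kappa)` (work of the vertical
#'     actin point force over the patch height `Z = Rt*(1 + chi)`).
#' }
#'
#' @param chi shape parameter, vectorised, non-negative.
#' @param params a [model_params()] object.
#' @return A data.frame with columns `chi`, `bending`, `tension`,
#'   `line_tension`, `force_work` (all in units of pi*kappa).
#' @export
mechanical_energy <- function(chi, params) {
  stopifnot(inherits(params, "model_params"), is.numeric(chi))
  m <- params$membrane
  Rt <- tube_radius(chi, params$geometry$R0)
  data.frame(
    chi = chi,
    bending = chi * Rt^2 * (1 / Rt - m$c0)^2 + Rt^2 * (2 / Rt - m$c0)^2,
    tension = (m$sigma / m$kappa) * (2 * chi + 1) * Rt^2,
    line_tension = 2 * (m$lam / m$kappa) * Rt,
    force_work = -params$load$f * Rt * (1 + chi) / (pi * m$kappa)
  )
}

# Dimensionless brush prefactor 3^(2/3) * (v / (a^4 xi^2))^(1/3), the
# coefficient of the per-chain energy integral C' = (3/2) 3^(2/3) v^(1/3)
# a^(-4/3) of the local energy density evaluated at the flat-brush local
# concentration cp(r) = (3/(v a^2))^(1/3) s(r)^(-2/3).
.brush_prefactor <- function(glyco) {
  3^(2 / 3) * (glyco$v / (glyco$a^4 * glyco$xi^2))^(1 / 3)
}

# Inner bracket argument scale (v a^2 / (3 xi^2))^(1/3) = h0 / N, the
# flat-brush height per monomer.
.brush_inner <- function(glyco) {
  (glyco$v * glyco$a^2 / (3 * glyco$xi^2))^(1 / 3)
}

#' Per-chain brush energy on the hemispherical cap
#'
#' Free energy (stretching plus binary excluded-volume interactions) of one
#' chain grafted on a sphere of radius `Rt`, in kBT:
#' \deqn{E_{cap} = \frac{9 R_t}{2}\,3^{2/3}\Big(\frac{v}{a^4\xi^2}\Big)^{1/3}
#'   \Big[\Big(1 + \frac{5N}{3R_t}\Big(\frac{v a^2}{3\xi^2}\Big)^{1/3}\Big)^{1/5} - 1\Big]}
#' The expression follows from integrating the brush energy density radially
#' from `Rt` to the brush edge with the local area per chain growing as
#' `(r/Rt)^2` on a sphere. Outward curvature dilutes the brush, so the energy
#' decreases with decreasing `Rt` and converges to the flat-brush value
#' [flat_brush_energy_per_chain()] as `Rt` grows.
#'
#' @param Rt cap radius (nm), positive; vectorised.
#' @param glyco a [glycocalyx_params()] object.
#' @return Energy per chain in kBT (non-negative; zero when `N = 0`).
#' @export
brush_energy_cap_per_chain <- function(Rt, glyco) {
  stopifnot(inherits(glyco, "glycocalyx_params"), is.numeric(Rt))
  if (any(Rt <= 0)) stop("'Rt' must be positive", call. = FALSE)
  x <- (5 * glyco$N / (3 * Rt)) * .brush_inner(glyco)
  (9 * Rt / 2) * .brush_prefactor(glyco) * ((1 + x)^(1 / 5) - 1)
}

#' Per-chain brush energy on the cylindrical tube
#'
#' As [brush_energy_cap_per_chain()], for a chain grafted on a cylinder of
#' radius `Rt` (area per chain grows as `r/Rt`), in kBT:
#' \deqn{E_{tube} = \frac{9 R_t}{4}\,3^{2/3}\Big(\frac{v}{a^4\xi^2}\Big)^{1/3}
#'   \Big[\Big(1 + \frac{4N}{3R_t}\Big(\frac{v a^2}{3\xi^2}\Big)^{1/3}\Big)^{1/2} - 1\Big]}
#'
#' @inheritParams brush_energy_cap_per_chain
#' @return Energy per chain in kBT (non-negative; zero when `N = 0`).
#' @export
brush_energy_tube_per_chain <- function(Rt, glyco) {
  stopifnot(inherits(glyco, "glycocalyx_params"), is.numeric(Rt))
  if (any(Rt <= 0)) stop("'Rt' must be positive", call. = FALSE)
  x <- (4 * glyco$N / (3 * Rt)) * .brush_inner(glyco)
  (9 * Rt / 4) * .brush_prefactor(glyco) * ((1 + x)^(1 / 2) - 1)
}

#' Flat-brush limit of the per-chain energy
#'
#' Closed-form energy of one chain in a planar brush,
#' `(3N/2) * 3^(1/3) * v^(2/3) * a^(-2/3) * xi^(-4/3)` kBT. Both curved
#' per-chain energies converge to this value as `Rt` tends to infinity; it is
#' also the classical uniform-stretching planar-brush result obtained by
#' minimising `(3/(2a^2)) h^2/N + v N^2/(xi^2 h)` over the brush height `h`,
#' with minimiser `h0 = N * (v a^2 / (3 xi^2))^(1/3)` (see
#' [flat_brush_height()]).
#'
#' @param glyco a [glycocalyx_params()] object.
#' @return Energy per chain in kBT.
#' @export
flat_brush_energy_per_chain <- function(glyco) {
  stopifnot(inherits(glyco, "glycocalyx_params"))
  (3 * glyco$N / 2) * 3^(1 / 3) * glyco$v^(2 / 3) *
    glyco$a^(-2 / 3) * glyco$xi^(-4 / 3)
}

#' Flat-brush height
#'
#' Equilibrium height `h0 = N * (v a^2 / (3 xi^2))^(1/3)` of a planar brush,
#' the per-monomer factor appearing inside the curved-brush brackets.
#'
#' @inheritParams flat_brush_energy_per_chain
#' @return Height in nm.
#' @export
flat_brush_height <- function(glyco) {
  stopifnot(inherits(glyco, "glycocalyx_params"))
  glyco$N * .brush_inner(glyco)
}

#' Glycocalyx energy of the deformed patch
#'
#' Total brush energy split between the hemispherical cap and the
#' cylindrical tube, in units of `pi * kappa`:
#' `glyco_cap = Np_cap * E_cap / (pi * kappa)` with
#' `Np_cap = 2*pi*Rt^2/xi^2`, and
#' `glyco_tube = Np_tube * E_tube / (pi * kappa)` with
#' `Np_tube = 2*pi*Rt*Lt/xi^2`.
#'
#' @param chi shape parameter, vectorised, non-negative.
#' @param params a [model_params()] object.
#' @return A data.frame with columns `chi`, `glyco_cap`, `glyco_tube`.
#' @export
glycocalyx_energy <- function(chi, params) {
  stopifnot(inherits(params, "model_params"), is.numeric(chi))
  g <- params$glyco
  kappa <- params$membrane$kappa
  Rt <- tube_radius(chi, params$geometry$R0)
  Np_cap <- 2 * pi * Rt^2 / g$xi^2
  Np_tube <- 2 * pi * Rt^2 * chi / g$xi^2
  data.frame(
    chi = chi,
    glyco_cap = Np_cap * brush_energy_cap_per_chain(Rt, g) / (pi * kappa),
    glyco_tube = Np_tube * brush_energy_tube_per_chain(Rt, g) / (pi * kappa)
  )
}

#' Component-wise total free energy
#'
#' All six components of the normalized free energy at each `chi`, plus their
#' sum, in units of `pi * kappa`.
#'
#' @param chi shape parameter, vectorised, non-negative.
#' @param params a [model_params()] object.
#' @return A data.frame with columns `chi`, `bending`, `tension`,
#'   `line_tension`, `force_work`, `glyco_cap`, `glyco_tube`, `total`.
#' @export
#' @examples
#' energy_breakdown(c(0, 1, 5), model_params())
energy_breakdown <- function(chi, params) {
  mech <- mechanical_energy(chi, params)
  gly <- glycocalyx_energy(chi, params)
  out <- cbind(mech, gly[c("glyco_cap", "glyco_tube")])
  out$total <- out$bending + out$tension + out$line_tension +
    out$force_work + out$glyco_cap + out$glyco_tube
  out
}

#' Total free energy of the glycocalyx-membrane system
#'
#' The scalar objective minimised over `chi`: sum of bending, tension, line
#' tension, actin-force work and cap/tube brush energies, in units of
#' `pi * kappa` (multiply by `pi * kappa` for kBT, see [energy_to_kBT()]).
#'
#' @param chi shape parameter, vectorised, non-negative.
#' @param params a [model_params()] object.
#' @return Numeric vector of normalized energies.
#' @export
total_energy <- function(chi, params) {
  energy_breakdown(chi, params)$total
}

#' Convert between pi-kappa units and kBT
#'
#' Energies in this package are normalized by `pi * kappa`. These helpers
#' convert to and from kBT.
#'
#' @param x energy value(s).
#' @param params a [model_params()] object supplying `kappa`.
#' @return Converted value(s).
#' @export
energy_to_kBT <- function(x, params) {
  stopifnot(inherits(params, "model_params"))
  x * pi * params$membrane$kappa
}

#' @rdname energy_to_kBT
#' @export
energy_from_kBT <- function(x, params) {
  stopifnot(inherits(params, "model_params"))
  x / (pi * params$membrane$kappa)
}
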