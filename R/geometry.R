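#' Tube radius at fixed patch area
#'
#' The brush-coated patch of initial radius `R0` (area `pi * R0^2`) deforms
#' into a cylinder of radius `Rt` and length `Lt = chi * Rt` capped by a
#' hemisphere of the same radius. Conservation of the grafting area,
#' `2*pi*Rt*Lt + 2*pi*Rt^2 = pi*R0^2`, fixes the radius:
#' `Rt = R0 / sqrt(2 * (1 + chi))`.
#'
#' @param chi shape parameter Lt/Rt (dimensionless), non-negative; vectorised.
#' @param R0 flat-patch radius (nm), positive scalar.
#' @return Tube/cap radius in nm, same length as `chi`; strictly decreasing
#'   in `chi`.
#' @export
#' @examples
#' tube_radius(0, 100)  # hemispherical cap: R0/sqrt(2)
#' tube_radius(7, 100)  # 25 nm
tube_radius <- function(chi, R0) {
  stopifnot(is.numeric(chi), is.numeric(R0), length(R0) == 1L)
  if (R0 <= 0) stop("'R0' must be positive", call. = FALSE)
  if (any(chi < 0)) stop("'chi' must be non-negative", call. = FALSE)
  R0 / sqrt(2 * (1 + chi))
}

#' Derived geometry of the tube-plus-cap shape
#'
#' Computes all geometric quantities at a given shape parameter: the radius
#' `Rt`, tube length `Lt`, total and excess membrane area, boundary length,
#' patch height `Z = Rt * (1 + chi)` and the chain counts on the cap
#' (`Np_cap = 2*pi*Rt^2 / xi^2`) and on the tube
#' (`Np_tube = 2*pi*Rt*Lt / xi^2`). The total area is conserved at
#' `pi * R0^2` for every chi; the excess area (deformed minus projected) is
#' `(2*chi + 1) * pi * Rt^2`.
#'
#' @param chi shape parameter (scalar, non-negative).
#' @param params a [model_params()] object.
#' @return A list of class `tube_geometry`.
#' @export
#' @examples
#' g <- tube_geometry(1, model_params())
#' g$area_total  # == pi * 100^2
tube_geometry <- function(chi, params) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(chi), length(chi) == 1L)
  R0 <- params$geometry$R0
  xi <- params$glyco$xi
  Rt <- tube_radius(chi, R0)
  Lt <- chi * Rt
  structure(list(
    chi = chi,
    Rt = Rt,
    Lt = Lt,
    area_total = 2 * pi * Rt^2 * (1 + chi),
    excess_area = (2 * chi + 1) * pi * Rt^2,
    boundary_length = 2 * pi * Rt,
    height_Z = Rt * (1 + chi),
    Np_cap = 2 * pi * Rt^2 / xi^2,
    Np_tube = 2 * pi * Rt * Lt / xi^2
  ), class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("Tube geometry at chi = %g\n", x$chi))
  cat(sprintf("  Rt = %.4f nm, Lt = %.4f nm, height Z = %.4f nm\n",
              x$Rt, x$Lt, x$height_Z))
  cat(sprintf("  area = %.6g nm^2 (excess %.6g nm^2), boundary = %.4f nm\n",
              x$area_total, x$excess_area, x$boundary_length))
  cat(sprintf("  chains: %.2f on cap, %.2f on tube\n", x$Np_cap, x$Np_tube))
  invisible(x)
}
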