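#' Membrane parameters
#'
#' Elastic constants of the lipid bilayer patch. All energies in the package
#' are expressed in units of the thermal energy kBT, so the bending rigidity
#' is given in kBT, tension in kBT/nm^2, line tension in kBT/nm and
#' spontaneous curvature in 1/nm.
#'
#' @param kappa bending rigidity (kBT), must be positive.
#' @param sigma membrane tension (kBT/nm^2), non-negative.
#' @param lam line tension along the boundary of the brush-coated domain
#'   (kBT/nm), non-negative.
#' @param c0 spontaneous curvature of the bilayer (1/nm), non-negative.
#'   This is a bilayer-asymmetry property, independent of the brush.
#' @return An object of class `membrane_params`.
#' @export
#' @examples
#' membrane_params(kappa = 10, sigma = 0.012)
membrane_params <- function(kappa = 10, sigma = 0.012, lam = 0.5, c0 = 0.02) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(lam), length(lam) == 1L, is.finite(lam),
            is.numeric(c0), length(c0) == 1L, is.finite(c0))
  if (kappa <= 0) stop("'kappa' must be positive", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (lam < 0) stop("'lam' must be non-negative", call. = FALSE)
  if (c0 < 0) stop("'c0' must be non-negative", call. = FALSE)
  structure(list(kappa = kappa, sigma = sigma, lam = lam, c0 = c0),
            class = "membrane_params")
}

#' Glycocalyx (polymer brush) parameters
#'
#' The brush is characterised by the mean spacing `xi` between grafting
#' points (equivalently the grafting density `rho = 1/xi^2`), the number of
#' monomers per chain `N`, the monomer size `a` and the excluded-volume
#' (second virial) coefficient `v`. For a neutral brush `v` defaults to
#' `a^3`. `N` is allowed to be non-integer so that the critical chain length
#' can be located by continuous root finding.
#'
#' Exactly one of `xi` or `rho` may be supplied; the other is derived.
#'
#' @param xi grafting distance (nm), positive.
#' @param N monomers per chain (dimensionless), non-negative real.
#' @param a monomer size (nm), positive.
#' @param v excluded volume (nm^3); defaults to `a^3`.
#' @param rho grafting density (1/nm^2); alternative to `xi`.
#' @return An object of class `glycocalyx_params` with fields `xi`, `N`,
#'   `a`, `v` and the derived `rho`.
#' @export
#' @examples
#' glycocalyx_params(xi = 15, N = 20)
#' glycocalyx_params(rho = 0.0077, N = 20)  # same brush, given as a density
glycocalyx_params <- function(xi = 15, N = 20, a = 10, v = a^3, rho = NULL) {
  if (!is.null(rho)) {
    stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
    if (rho <= 0) stop("'rho' must be positive", call. = FALSE)
    if (!missing(xi)) stop("supply either 'xi' or 'rho', not both", call. = FALSE)
    xi <- 1 / sqrt(rho)
  }
  stopifnot(is.numeric(xi), length(xi) == 1L, is.finite(xi),
            is.numeric(N), length(N) == 1L, is.finite(N),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(v), length(v) == 1L, is.finite(v))
  if (xi <= 0) stop("'xi' must be positive", call. = FALSE)
  if (N < 0) stop("'N' must be non-negative", call. = FALSE)
  if (a <= 0) stop("'a' must be positive", call. = FALSE)
  if (v <= 0) stop("'v' must be positive", call. = FALSE)
  structure(list(xi = xi, N = N, a = a, v = v, rho = 1 / xi^2),
            class = "glycocalyx_params")
}

#' Actin load parameters
#'
#' A vertical point force applied at the tube tip, modelling the push of a
#' filamentous-actin core.
#'
#' @param f vertical point force (kBT/nm), non-negative.
#' @return An object of class `load_params`.
#' @export
load_params <- function(f = 1) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f))
  if (f < 0) stop("'f' must be non-negative", call. = FALSE)
  structure(list(f = f), class = "load_params")
}

#' Patch geometry and scan settings
#'
#' The membrane patch has fixed area `pi * R0^2`, where `R0` is the radius of
#' the initially flat brush-coated patch. `chi_max` and `n_grid` control the
#' default scan range and resolution of the energy landscape over the shape
#' parameter chi = Lt/Rt.
#'
#' @param R0 flat-patch radius (nm), positive.
#' @param chi_max upper bound of the chi scan (dimensionless), positive.
#' @param n_grid number of chi samples, at least 3.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(R0 = 100, chi_max = 30, n_grid = 3001) {
  stopifnot(is.numeric(R0), length(R0) == 1L, is.finite(R0),
            is.numeric(chi_max), length(chi_max) == 1L, is.finite(chi_max),
            is.numeric(n_grid), length(n_grid) == 1L, is.finite(n_grid))
  if (R0 <= 0) stop("'R0' must be positive", call. = FALSE)
  if (chi_max <= 0) stop("'chi_max' must be positive", call. = FALSE)
  if (n_grid < 3) stop("'n_grid' must be at least 3", call. = FALSE)
  structure(list(R0 = R0, chi_max = chi_max, n_grid = as.integer(n_grid)),
            class = "geometry_params")
}

#' Full model parameter set
#'
#' Bundles membrane, glycocalyx, load and geometry parameters. The defaults
#' are the biologically motivated reference values of the model: kappa = 10
#' kBT, sigma = 0.012 kBT/nm^2, lam = 0.5 kBT/nm, c0 = 0.02 1/nm, f = 1
#' kBT/nm, R0 = 100 nm, xi = 15 nm, a = 10 nm, N = 20, v = a^3.
#'
#' @param membrane a [membrane_params()] object.
#' @param glyco a [glycocalyx_params()] object.
#' @param load a [load_params()] object.
#' @param geometry a [geometry_params()] object.
#' @return An object of class `model_params`.
#' @seealso [update_params()] for modifying single parameters by name.
#' @export
#' @examples
#' p <- model_params()
#' p$glyco$rho  # grafting density derived from xi
model_params <- function(membrane = membrane_params(),
                         glyco = glycocalyx_params(),
                         load = load_params(),
                         geometry = geometry_params()) {
  stopifnot(inherits(membrane, "membrane_params"),
            inherits(glyco, "glycocalyx_params"),
            inherits(load, "load_params"),
            inherits(geometry, "geometry_params"))
  structure(list(membrane = membrane, glyco = glyco, load = load,
                 geometry = geometry),
            class = "model_params")
}

# Flat parameter names accepted by update_params() / config files.
.flat_param_names <- c("kappa", "sigma", "lam", "c0", "f",
                       "R0", "chi_max", "n_grid",
                       "xi", "rho", "N", "a", "v", "Np")

#' Update a model parameter set by flat key
#'
#' Convenience modifier used by sweeps, root finding and the config layer.
#' Keys mirror the standard parameter names: `kappa`, `sigma`, `lam`, `c0`,
#' `f`, `R0`, `chi_max`, `n_grid`, `xi`, `rho`, `N`, `a`, `v`. Setting `rho`
#' stores the equivalent grafting distance `xi = 1/sqrt(rho)`; setting `Np`
#' (total number of chains on the patch) stores `xi = R0 * sqrt(pi / Np)`,
#' since `Np = pi * R0^2 * rho`. Setting `a` does not silently rescale `v`;
#' pass `v` explicitly if the excluded volume should track the monomer size.
#'
#' @param params a [model_params()] object.
#' @param ... named scalar values among the keys above.
#' @return The modified `model_params` object (re-validated).
#' @export
#' @examples
#' p <- update_params(model_params(), rho = 0.0077, f = 0)
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  upd <- list(...)
  if (length(upd) == 0L) return(params)
  nm <- names(upd)
  if (is.null(nm) || any(nm == "")) {
    stop("all arguments to update_params() must be named", call. = FALSE)
  }
  bad <- setdiff(nm, .flat_param_names)
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (sum(c("xi", "rho", "Np") %in% nm) > 1L) {
    stop("supply at most one of 'xi', 'rho', 'Np'", call. = FALSE)
  }
  m <- params$membrane; g <- params$glyco; l <- params$load
  geo <- params$geometry
  take <- function(key, old) if (key %in% nm) upd[[key]] else old
  geo <- geometry_params(R0 = take("R0", geo$R0),
                         chi_max = take("chi_max", geo$chi_max),
                         n_grid = take("n_grid", geo$n_grid))
  m <- membrane_params(kappa = take("kappa", m$kappa),
                       sigma = take("sigma", m$sigma),
                       lam = take("lam", m$lam),
                       c0 = take("c0", m$c0))
  l <- load_params(f = take("f", l$f))
  xi <- g$xi
  if ("rho" %in% nm) {
    rho <- upd[["rho"]]
    if (!is.numeric(rho) || rho <= 0) stop("'rho' must be positive", call. = FALSE)
    xi <- 1 / sqrt(rho)
  } else if ("Np" %in% nm) {
    Np <- upd[["Np"]]
    if (!is.numeric(Np) || Np <= 0) stop("'Np' must be positive", call. = FALSE)
    xi <- geo$R0 * sqrt(pi / Np)
  } else if ("xi" %in% nm) {
    xi <- upd[["xi"]]
  }
  g <- glycocalyx_params(xi = xi, N = take("N", g$N),
                         a = take("a", g$a), v = take("v", g$v))
  model_params(membrane = m, glyco = g, load = l, geometry = geo)
}

#' Total number of grafted chains on the patch
#'
#' The patch area is fixed at `pi * R0^2` and the grafting density is
#' `rho = 1/xi^2`, so the chain count `Np = pi * R0^2 / xi^2` is conserved
#' across all shapes chi.
#'
#' @param params a [model_params()] object.
#' @return Total chain number (dimensionless, real-valued).
#' @export
total_chain_count <- function(params) {
  stopifnot(inherits(params, "model_params"))
  pi * params$geometry$R0^2 / params$glyco$xi^2
}

#' @export
print.model_params <- function(x, ...) {
  cat("Glycocalyx-membrane model parameters\n")
  cat(sprintf("  membrane: kappa = %g kBT, sigma = %g kBT/nm^2, lam = %g kBT/nm, c0 = %g 1/nm\n",
              x$membrane$kappa, x$membrane$sigma, x$membrane$lam, x$membrane$c0))
  cat(sprintf("  brush:    xi = %g nm (rho = %.5g 1/nm^2), N = %g, a = %g nm, v = %g nm^3\n",
              x$glyco$xi, x$glyco$rho, x$glyco$N, x$glyco$a, x$glyco$v))
  cat(sprintf("  load:     f = %g kBT/nm\n", x$load$f))
  cat(sprintf("  geometry: R0 = %g nm (area %.5g nm^2), chi scan [0, %g] with %d points\n",
              x$geometry$R0, pi * x$geometry$R0^2, x$geometry$chi_max,
              x$geometry$n_grid))
  invisible(x)
}

#' Flatten a model parameter set to a named list
#'
#' Used by the config reader/writer and by run metadata. Keys are the flat
#' names accepted by [update_params()] (with `xi` canonical; `rho` is
#' included for readability but is redundant).
#'
#' @param params a [model_params()] object.
#' @return Named list of scalars.
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  list(kappa = params$membrane$kappa, sigma = params$membrane$sigma,
       lam = params$membrane$lam, c0 = params$membrane$c0,
       f = params$load$f,
       R0 = params$geometry$R0, chi_max = params$geometry$chi_max,
       n_grid = params$geometry$n_grid,
       xi = params$glyco$xi, rho = params$glyco$rho,
       N = params$glyco$N, a = params$glyco$a, v = params$glyco$v)
}

#' Read/write model parameters as a flat JSON config
#'
#' The config is a flat key-value JSON object with the keys of
#' [flatten_params()]. Unknown keys are rejected. If both `xi` and `rho` are
#' present they must agree to within 1e-8 relative tolerance (`xi` wins).
#'
#' @param path file path.
#' @param params a [model_params()] object (for writing).
#' @return `read_model_params()` returns a [model_params()] object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(x), .flat_param_names)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(x$xi) && !is.null(x$rho)) {
    if (abs(x$rho - 1 / x$xi^2) > 1e-8 * max(x$rho, 1 / x$xi^2)) {
      stop("config supplies inconsistent 'xi' and 'rho'", call. = FALSE)
    }
    x$rho <- NULL
  }
  do.call(update_params, c(list(params = model_params()), x))
}

#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  jsonlite::write_json(flatten_params(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
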