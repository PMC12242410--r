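#' Scan and refine the total-energy landscape F(chi)
#'
#' Evaluates the normalized total energy on a dense grid over
#' `[0, chi_max]`, refines every interior local minimum by golden-section
#' search ([stats::optimize()]) to better than 1e-6 in chi, treats `chi = 0`
#' as a boundary candidate minimum (one-sided test `F(delta) > F(0)` with
#' `delta` the grid spacing), and classifies the landscape. If the energy is
#' still decreasing at the right edge the scan range cannot contain the
#' tubular minimum and an error asks for a larger `chi_max`.
#'
#' @param params a [model_params()] object.
#' @param chi_max,n_grid optional overrides of the scan settings in
#'   `params$geometry`.
#' @param tol coexistence tolerance (pi-kappa units) passed to
#'   [classify_landscape()].
#' @return An object of class `glyco_landscape` with fields
#'   \describe{
#'     \item{chi_grid, F_grid}{the sampled profile (chi dimensionless, F in
#'       pi-kappa units),}
#'     \item{minima}{data.frame of refined local minima (`chi`, `F`),
#'       including the chi = 0 boundary minimum when present,}
#'     \item{chi_min, F_min}{the global minimum,}
#'     \item{barrier}{energy barrier from the chi = 0 basin to the tubular
#'       basin (pi-kappa units), `NA` when there is no tubular minimum,}
#'     \item{barrier_chi}{location of the intervening maximum,}
#'     \item{state}{one of `"nontubular"`, `"metastable-tubular"`,
#'       `"coexistence"`, `"tubular"`,}
#'     \item{params}{the parameter set used.}
#'   }
#' @export
#' @examples
#' ls <- scan_landscape(update_params(model_params(), lam = 0, c0 = 0, f = 0,
#'                                    rho = 0.009))
#' ls$state
scan_landscape <- function(params, chi_max = NULL, n_grid = NULL,
                           tol = 1e-3) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(chi_max) || !is.null(n_grid)) {
    params <- update_params(params,
      chi_max = if (is.null(chi_max)) params$geometry$chi_max else chi_max,
      n_grid = if (is.null(n_grid)) params$geometry$n_grid else n_grid)
  }
  chi_hi <- params$geometry$chi_max
  n <- params$geometry$n_grid
  chi_grid <- seq(0, chi_hi, length.out = n)
  F_grid <- total_energy(chi_grid, params)
  if (F_grid[n] < F_grid[n - 1L]) {
    stop("energy still decreasing at chi_max = ", chi_hi,
         "; enlarge 'chi_max' to contain the tubular minimum",
         call. = FALSE)
  }

  # interior minima: strict sign change of the finite difference
  d <- diff(F_grid)
  cand <- which(d[-1L] > 0 & d[-(n - 1L)] < 0) + 1L
  minima <- data.frame(chi = numeric(0), F = numeric(0))
  fobj <- function(chi) total_energy(chi, params)
  for (i in cand) {
    opt <- stats::optimize(fobj, lower = chi_grid[i - 1L],
                           upper = chi_grid[i + 1L], tol = 1e-9)
    minima <- rbind(minima, data.frame(chi = opt$minimum, F = opt$objective))
  }

  # chi = 0 boundary candidate: one-sided derivative test
  delta <- chi_grid[2L] - chi_grid[1L]
  if (F_grid[2L] > F_grid[1L]) {
    minima <- rbind(data.frame(chi = 0, F = F_grid[1L]), minima)
  }
  if (nrow(minima) == 0L) {
    # monotonically decreasing profiles are excluded by the edge check, and
    # increasing ones always keep the chi = 0 candidate; degenerate flat
    # profiles fall back to the grid argmin
    i <- which.min(F_grid)
    minima <- data.frame(chi = chi_grid[i], F = F_grid[i])
  }
  minima <- minima[order(minima$chi), , drop = FALSE]
  rownames(minima) <- NULL

  tubular <- minima[minima$chi > delta, , drop = FALSE]
  F0 <- F_grid[1L]

  # global minimum; ties between tubular minima resolved toward smaller chi
  best <- which(minima$F <= min(minima$F) + .Machine$double.eps * abs(min(minima$F)))
  if (length(best) > 1L) {
    warning("degenerate tie between minima; reporting the smaller chi",
            call. = FALSE)
  }
  ibest <- best[1L]

  barrier <- NA_real_
  barrier_chi <- NA_real_
  if (nrow(tubular) > 0L) {
    chi_tub <- tubular$chi[1L]
    # intervening maximum between the chi = 0 basin and the first tubular basin
    seg <- which(chi_grid <= chi_tub)
    imax <- seg[which.max(F_grid[seg])]
    if (imax > 1L && imax < n) {
      opt <- stats::optimize(fobj, lower = chi_grid[imax - 1L],
                             upper = chi_grid[imax + 1L],
                             maximum = TRUE, tol = 1e-9)
      barrier <- opt$objective - F0
      barrier_chi <- opt$maximum
    } else {
      barrier <- F_grid[imax] - F0
      barrier_chi <- chi_grid[imax]
    }
    barrier <- max(barrier, 0)
  }

  out <- structure(list(
    chi_grid = chi_grid, F_grid = F_grid,
    minima = minima,
    chi_min = minima$chi[ibest], F_min = minima$F[ibest],
    F0 = F0,
    barrier = barrier, barrier_chi = barrier_chi,
    state = NA_character_,
    tol = tol,
    params = params
  ), class = "glyco_landscape")
  out$state <- classify_landscape(out, tol = tol)
  out
}

# Internal: scan, retrying with a fourfold chi range (same resolution) when
# the tubular minimum escapes chi_max. Used by sweeps and root finders so
# that strong-drive parameter combinations do not abort a whole sweep.
.scan_extend <- function(params, tol = 1e-3, tries = 2L) {
  for (k in 0:tries) {
    out <- tryCatch(scan_landscape(params, tol = tol), error = identity)
    if (!inherits(out, "error")) return(out)
    if (!grepl("enlarge 'chi_max'", conditionMessage(out))) stop(out)
    params <- update_params(params,
                            chi_max = 4 * params$geometry$chi_max,
                            n_grid = 4L * params$geometry$n_grid - 3L)
  }
  stop(out)
}

#' Classify a landscape as nontubular, metastable, coexisting or tubular
#'
#' States are decided by comparing the energy of the lowest tubular local
#' minimum `F_tub` with the chi = 0 energy `F(0)`:
#' `"nontubular"` when no tubular minimum exists; `"metastable-tubular"`
#' when `F_tub > F(0) + tol`; `"coexistence"` when `|F_tub - F(0)| <= tol`;
#' `"tubular"` when `F_tub < F(0) - tol`.
#'
#' @param landscape a `glyco_landscape` from [scan_landscape()].
#' @param tol coexistence tolerance in pi-kappa units (default 1e-3, two
#'   orders of magnitude below the unit bending scale and above the
#'   refinement error).
#' @return A character state label.
#' @export
classify_landscape <- function(landscape, tol = 1e-3) {
  stopifnot(inherits(landscape, "glyco_landscape"))
  delta <- landscape$chi_grid[2L] - landscape$chi_grid[1L]
  tubular <- landscape$minima[landscape$minima$chi > delta, , drop = FALSE]
  if (nrow(tubular) == 0L) return("nontubular")
  F0 <- landscape$F0
  F_tub <- min(tubular$F)
  if (abs(F_tub - F0) <= tol) "coexistence"
  else if (F_tub < F0) "tubular"
  else "metastable-tubular"
}

#' Energy barrier between the nontubular and tubular basins
#'
#' Height of the landscape maximum separating the chi = 0 basin from the
#' tubular basin, measured from `F(0)`, in pi-kappa units. `NA` (absent, not
#' an error) when the landscape has no tubular minimum.
#'
#' @param landscape a `glyco_landscape` from [scan_landscape()].
#' @return Barrier in pi-kappa units, or `NA_real_`.
#' @export
energy_barrier <- function(landscape) {
  stopifnot(inherits(landscape, "glyco_landscape"))
  landscape$barrier
}

#' @export
print.glyco_landscape <- function(x, ...) {
  cat(sprintf("Energy landscape over chi in [0, %g] (%d points)\n",
              max(x$chi_grid), length(x$chi_grid)))
  cat(sprintf("  state: %s\n", x$state))
  cat(sprintf("  global minimum: chi_min = %.6g, F = %.6g pi-kappa\n",
              x$chi_min, x$F_min))
  if (nrow(x$minima) > 1L) {
    cat(sprintf("  %d local minima; F(0) = %.6g\n", nrow(x$minima), x$F0))
  }
  if (!is.na(x$barrier)) {
    cat(sprintf("  barrier: %.6g pi-kappa at chi = %.4g\n",
                x$barrier, x$barrier_chi))
  }
  invisible(x)
}

#' @export
plot.glyco_landscape <- function(x, ...) {
  graphics::plot(x$chi_grid, x$F_grid, type = "l",
                 xlab = expression(chi), ylab = expression(F / (pi * kappa)),
                 main = sprintf("state: %s", x$state), ...)
  graphics::points(x$minima$chi, x$minima$F, pch = 19, col = "red")
  invisible(x)
}

#' Export a landscape as CSV plus JSON sidecar
#'
#' Writes the sampled profile as a two-column CSV
#' (`chi`, `F_over_pi_kappa`) and a JSON sidecar holding the refined minima,
#' barrier, state and the full parameter set.
#'
#' @param landscape a `glyco_landscape`.
#' @param csv_path,json_path output file paths.
#' @return `csv_path`, invisibly.
#' @export
write_landscape <- function(landscape, csv_path, json_path = NULL) {
  stopifnot(inherits(landscape, "glyco_landscape"))
  utils::write.csv(
    data.frame(chi = landscape$chi_grid,
               F_over_pi_kappa = landscape$F_grid),
    csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      minima = landscape$minima,
      chi_min = landscape$chi_min,
      F_min = landscape$F_min,
      barrier = landscape$barrier,
      barrier_chi = landscape$barrier_chi,
      state = landscape$state,
      params = flatten_params(landscape$params)
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(csv_path)
}
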