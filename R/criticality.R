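# Internal: landscape summary used by the root finders. Returns the basin
# gap F_tub - F(0) (NA when no tubular minimum) and the tubular minimum
# location. Landscapes whose tubular minimum escapes chi_max are retried
# with a larger range before the error propagates.
.basin_gap <- function(params) {
  ls <- .scan_extend(params)
  delta <- ls$chi_grid[2L] - ls$chi_grid[1L]
  tubular <- ls$minima[ls$minima$chi > delta, , drop = FALSE]
  if (nrow(tubular) == 0L) {
    list(gap = NA_real_, chi_tub = NA_real_)
  } else {
    list(gap = min(tubular$F) - ls$F0,
         chi_tub = tubular$chi[which.min(tubular$F)])
  }
}

# Internal: generic bisection on a monotone state predicate.
# pred(value) must be TRUE on the "transitioned" (high) side. Returns the
# final bracket (lo = FALSE side, hi = TRUE side).
.bisect_predicate <- function(pred, lo, hi, tol, max_iter = 200L) {
  for (i in seq_len(max_iter)) {
    if (hi - lo < tol) break
    mid <- (lo + hi) / 2
    if (pred(mid)) hi <- mid else lo <- mid
  }
  c(lo, hi)
}

# Internal: shared implementation of the critical-parameter search.
.critical_point <- function(params, parameter = c("rho", "N"),
                            kind = c("binodal", "spinodal"),
                            bracket, tol) {
  parameter <- match.arg(parameter)
  kind <- match.arg(kind)
  at <- function(value) {
    do.call(update_params, stats::setNames(list(params, value),
                                           c("params", parameter)))
  }
  pred <- if (kind == "spinodal") {
    function(value) {
      g <- .basin_gap(at(value))
      !is.na(g$gap)
    }
  } else {
    function(value) {
      g <- .basin_gap(at(value))
      !is.na(g$gap) && g$gap < 0
    }
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  if (pred(lo)) {
    # auto-expand downward once before failing
    lo2 <- lo / 4
    if (lo2 <= 0 || pred(lo2)) {
      stop("transition of '", parameter, "' already occurred at the lower ",
           "bracket end ", lo, call. = FALSE)
    }
    hi <- lo; lo <- lo2
  } else if (!pred(hi)) {
    # auto-expand upward once before failing
    hi2 <- hi + (hi - lo)
    if (!pred(hi2)) {
      stop("no ", kind, " transition of '", parameter, "' in range [",
           lo, ", ", hi2, "]", call. = FALSE)
    }
    lo <- hi; hi <- hi2
  }
  br <- .bisect_predicate(pred, lo, hi, tol)
  value <- (br[1L] + br[2L]) / 2
  g <- .basin_gap(at(br[2L]))
  structure(list(parameter = parameter, kind = kind, value = value,
                 bracket = br, chi_at_transition = g$chi_tub,
                 tol = tol), class = "critical_point")
}

#' Critical grafting density for the nontubular-to-tubular transition
#'
#' Locates by bisection the grafting density `rho` at which the landscape
#' changes character, with every other parameter held at its value in
#' `params`:
#' \describe{
#'   \item{binodal}{the coexistence point: the smallest `rho` at which the
#'     tubular basin energy drops below the chi = 0 energy
#'     (`F_tub = F(0)`, both including the brush energy of their shapes).
#'     The optimal shape jumps discontinuously there — the transition is
#'     first order.}
#'   \item{spinodal}{the smallest `rho` at which a second (tubular) local
#'     minimum first appears; between spinodal and binodal the tube is
#'     metastable.}
#' }
#'
#' @param params a [model_params()] object (its `rho`/`xi` entry is the
#'   swept variable and is ignored).
#' @param kind `"binodal"` (default) or `"spinodal"`.
#' @param bracket initial search interval in 1/nm^2; expanded upward once if
#'   the transition lies above it.
#' @param tol bisection tolerance on rho (1/nm^2).
#' @return An object of class `critical_point` with fields `parameter`,
#'   `kind`, `value`, `bracket` (final bisection bracket),
#'   `chi_at_transition` (tubular-minimum location just above the
#'   transition).
#' @export
#' @examples
#' \donttest{
#' p <- update_params(model_params(), lam = 0, c0 = 0, f = 0, N = 20)
#' critical_density(p)$value  # ~0.0076 1/nm^2
#' }
critical_density <- function(params, kind = c("binodal", "spinodal"),
                             bracket = c(1e-4, 1e-2), tol = 1e-10) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(bracket), length(bracket) == 2L,
            bracket[1L] > 0, bracket[2L] > bracket[1L], tol > 0)
  .critical_point(params, "rho", match.arg(kind), bracket, tol)
}

#' Critical polymer length for the nontubular-to-tubular transition
#'
#' As [critical_density()], with the monomer number `N` as the continuous
#' search variable. The integer ceiling is reported alongside the continuous
#' root.
#'
#' @inheritParams critical_density
#' @param bracket initial search interval in monomers.
#' @param tol bisection tolerance on N.
#' @return A `critical_point`; for `N` the field `value_int` holds
#'   `ceiling(value)`.
#' @export
critical_length <- function(params, kind = c("binodal", "spinodal"),
                            bracket = c(1, 60), tol = 1e-6) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(bracket), length(bracket) == 2L,
            bracket[1L] >= 0, bracket[2L] > bracket[1L], tol > 0)
  cp <- .critical_point(params, "N", match.arg(kind), bracket, tol)
  cp$value_int <- ceiling(cp$value)
  cp
}

#' @export
print.critical_point <- function(x, ...) {
  unit <- if (x$parameter == "rho") "1/nm^2" else "monomers"
  cat(sprintf("Critical %s (%s): %.6g %s\n", x$parameter, x$kind, x$value, unit))
  cat(sprintf("  bracket [%.6g, %.6g], chi at transition = %.4g\n",
              x$bracket[1L], x$bracket[2L], x$chi_at_transition))
  invisible(x)
}

#' Critical value as a function of a second parameter
#'
#' Recomputes [critical_density()] or [critical_length()] along a grid of a
#' facilitating parameter (`f`, `lam` or `c0`). Per-point failures (no
#' transition in range) are recorded as `NA` with the reason kept in the
#' `reason` column, and the sweep continues.
#'
#' @param params base [model_params()] object.
#' @param critical which critical value to track: `"rho"` or `"N"`.
#' @param sweep name of the swept parameter: `"f"`, `"lam"` or `"c0"`.
#' @param values numeric grid of swept values.
#' @param kind `"binodal"` or `"spinodal"`.
#' @param ... passed to [critical_density()] / [critical_length()]
#'   (`bracket`, `tol`).
#' @return A data.frame with columns `<sweep>`, `critical_value`,
#'   `chi_at_transition`, `reason` (`NA` on success).
#' @export
critical_curve <- function(params, critical = c("rho", "N"),
                           sweep = c("f", "lam", "c0"), values,
                           kind = c("binodal", "spinodal"), ...) {
  stopifnot(inherits(params, "model_params"), is.numeric(values),
            length(values) >= 1L)
  critical <- match.arg(critical)
  sweep <- match.arg(sweep)
  kind <- match.arg(kind)
  fn <- if (critical == "rho") critical_density else critical_length
  rows <- lapply(values, function(v) {
    p <- do.call(update_params,
                 stats::setNames(list(params, v), c("params", sweep)))
    res <- tryCatch(fn(p, kind = kind, ...),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(sweep = v, critical_value = NA_real_,
                 chi_at_transition = NA_real_, reason = res)
    } else {
      data.frame(sweep = v, critical_value = res$value,
                 chi_at_transition = res$chi_at_transition,
                 reason = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- sweep
  out
}

#' Export a critical curve as CSV
#'
#' @param curve a data.frame from [critical_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_critical_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
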