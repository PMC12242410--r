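#' One-dimensional parameter sweep of the energy landscape
#'
#' Runs [scan_landscape()] at each value of a single swept parameter and
#' tabulates the optimal shape parameter, state label and barrier. Per-point
#' failures (e.g. a chi range too small for an extreme parameter value) are
#' recorded in the `reason` column and the sweep continues.
#'
#' @param params base [model_params()] object.
#' @param parameter flat parameter name (see [update_params()]); `"rho"` and
#'   `"Np"` are accepted alongside `"xi"`.
#' @param values numeric grid of swept values.
#' @param tol coexistence tolerance passed to the classifier.
#' @return A data.frame with columns `<parameter>`, `chi_min`, `F_min`,
#'   `state`, `barrier`, `reason`.
#' @export
#' @examples
#' p <- update_params(model_params(), lam = 0, c0 = 0, f = 0)
#' sweep_1d(p, "rho", c(0.004, 0.009))
sweep_1d <- function(params, parameter, values, tol = 1e-3) {
  stopifnot(inherits(params, "model_params"),
            is.character(parameter), length(parameter) == 1L,
            is.numeric(values), length(values) >= 1L)
  if (!parameter %in% .flat_param_names) {
    stop("unknown parameter name: ", parameter, call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    res <- tryCatch({
      p <- do.call(update_params,
                   stats::setNames(list(params, v), c("params", parameter)))
      ls <- .scan_extend(p, tol = tol)
      data.frame(value = v, chi_min = ls$chi_min, F_min = ls$F_min,
                 state = ls$state, barrier = ls$barrier,
                 reason = NA_character_)
    }, error = function(e) {
      data.frame(value = v, chi_min = NA_real_, F_min = NA_real_,
                 state = NA_character_, barrier = NA_real_,
                 reason = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- parameter
  out
}

#' Two-dimensional phase diagram
#'
#' Sweeps two parameters on a rectangular grid, recording the optimal shape
#' parameter and state label in each cell, and extracts the
#' nontubular/tubular phase boundary as the midpoints of label-changing grid
#' edges. The chain-count axis `"Np"` (total chains on the patch) is mapped
#' to the grafting distance via `xi = R0 * sqrt(pi / Np)`.
#'
#' @param params base [model_params()] object.
#' @param x_name,y_name flat parameter names for the two axes.
#' @param x_values,y_values numeric axis grids (sorted ascending).
#' @param tol coexistence tolerance passed to the classifier.
#' @return An object of class `glyco_phasemap`: axis definitions, a
#'   `chi_min` matrix and `state` character matrix (rows index `x_values`,
#'   columns `y_values`), and `boundary`, a data.frame of (x, y) boundary
#'   points.
#' @export
sweep_2d <- function(params, x_name, y_name, x_values, y_values,
                     tol = 1e-3) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(x_values), is.numeric(y_values),
            length(x_values) >= 2L, length(y_values) >= 2L,
            !is.unsorted(x_values), !is.unsorted(y_values))
  for (nm in c(x_name, y_name)) {
    if (!nm %in% .flat_param_names) {
      stop("unknown parameter name: ", nm, call. = FALSE)
    }
  }
  nx <- length(x_values); ny <- length(y_values)
  chi_min <- matrix(NA_real_, nx, ny)
  state <- matrix(NA_character_, nx, ny)
  for (j in seq_len(ny)) {
    pj <- do.call(update_params,
                  stats::setNames(list(params, y_values[j]),
                                  c("params", y_name)))
    for (i in seq_len(nx)) {
      res <- tryCatch({
        p <- do.call(update_params,
                     stats::setNames(list(pj, x_values[i]),
                                     c("params", x_name)))
        ls <- .scan_extend(p, tol = tol)
        list(chi = ls$chi_min, st = ls$state)
      }, error = function(e) list(chi = NA_real_, st = NA_character_))
      chi_min[i, j] <- res$chi
      state[i, j] <- res$st
    }
  }
  out <- structure(list(
    x_name = x_name, y_name = y_name,
    x_values = x_values, y_values = y_values,
    chi_min = chi_min, state = state,
    boundary = NULL, params = params, tol = tol
  ), class = "glyco_phasemap")
  out$boundary <- phase_boundary(out)
  out
}

# A cell counts as tube-forming when its global minimum is at chi > 0
# (tubular or coexistence label).
.is_tubular_cell <- function(map) {
  map$state %in% c("tubular", "coexistence") &
    !is.na(map$chi_min) & map$chi_min > 0
}

#' Extract the nontubular/tubular boundary of a phase map
#'
#' Marches over grid edges and reports the midpoint of every edge whose two
#' cells carry different tube-forming labels (global minimum at chi > 0
#' versus chi = 0).
#'
#' @param map a `glyco_phasemap` from [sweep_2d()].
#' @return A data.frame with columns `x`, `y` of boundary midpoints (possibly
#'   empty).
#' @export
phase_boundary <- function(map) {
  stopifnot(inherits(map, "glyco_phasemap"))
  tub <- matrix(.is_tubular_cell(map), nrow = nrow(map$state))
  xs <- map$x_values; ys <- map$y_values
  bx <- numeric(0); by <- numeric(0)
  nx <- length(xs); ny <- length(ys)
  if (nx > 1L) {
    for (j in seq_len(ny)) for (i in seq_len(nx - 1L)) {
      if (!is.na(tub[i, j]) && !is.na(tub[i + 1L, j]) &&
          tub[i, j] != tub[i + 1L, j]) {
        bx <- c(bx, (xs[i] + xs[i + 1L]) / 2); by <- c(by, ys[j])
      }
    }
  }
  if (ny > 1L) {
    for (i in seq_len(nx)) for (j in seq_len(ny - 1L)) {
      if (!is.na(tub[i, j]) && !is.na(tub[i, j + 1L]) &&
          tub[i, j] != tub[i, j + 1L]) {
        bx <- c(bx, xs[i]); by <- c(by, (ys[j] + ys[j + 1L]) / 2)
      }
    }
  }
  data.frame(x = bx, y = by)
}

#' @export
print.glyco_phasemap <- function(x, ...) {
  tub <- .is_tubular_cell(x)
  cat(sprintf("Phase map %s x %s (%d x %d cells)\n",
              x$x_name, x$y_name, length(x$x_values), length(x$y_values)))
  cat(sprintf("  tubular cells: %d / %d; boundary points: %d\n",
              sum(tub, na.rm = TRUE), length(tub), nrow(x$boundary)))
  invisible(x)
}

#' @export
plot.glyco_phasemap <- function(x, ...) {
  graphics::image(x$x_values, x$y_values, x$chi_min,
                  xlab = x$x_name, ylab = x$y_name,
                  main = expression(chi[min]),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  if (nrow(x$boundary)) {
    graphics::points(x$boundary$x, x$boundary$y, pch = 20, cex = 0.5)
  }
  invisible(x)
}

#' Export a phase map in long format
#'
#' Writes a long-format CSV (`x`, `y`, `chi_min`, `state`, with the axis
#' names recorded in the header comment-free JSON metadata sidecar) and an
#' optional PNG heatmap.
#'
#' @param map a `glyco_phasemap`.
#' @param csv_path,json_path,png_path output paths (`json_path` and
#'   `png_path` optional).
#' @return `csv_path`, invisibly.
#' @export
write_phase_map <- function(map, csv_path, json_path = NULL,
                            png_path = NULL) {
  stopifnot(inherits(map, "glyco_phasemap"))
  long <- expand.grid(x = map$x_values, y = map$y_values,
                      KEEP.OUT.ATTRS = FALSE)
  long$chi_min <- as.vector(map$chi_min)
  long$state <- as.vector(map$state)
  names(long)[1:2] <- c(map$x_name, map$y_name)
  utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      x_name = map$x_name, y_name = map$y_name,
      x_values = map$x_values, y_values = map$y_values,
      boundary = map$boundary,
      params = flatten_params(map$params), tol = map$tol
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(map)
  }
  invisible(csv_path)
}
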