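#' Define a reproducible experiment
#'
#' An experiment spec bundles a base parameter set with one analysis to run:
#' \describe{
#'   \item{`landscape`}{one [scan_landscape()] per value of `parameter`
#'     (one CSV each plus a classification JSON),}
#'   \item{`sweep1d`}{a [sweep_1d()] table,}
#'   \item{`sweep2d`}{a [sweep_2d()] phase map,}
#'   \item{`critical`}{a single [critical_density()] / [critical_length()],}
#'   \item{`critical-curve`}{a [critical_curve()] table.}
#' }
#'
#' @param name short identifier used as output file prefix.
#' @param experiment one of `"landscape"`, `"sweep1d"`, `"sweep2d"`,
#'   `"critical"`, `"critical-curve"`.
#' @param params base [model_params()] object.
#' @param parameter swept parameter name (landscape / sweep1d).
#' @param values numeric grid (landscape / sweep1d / critical-curve).
#' @param x_name,y_name,x_values,y_values axes (sweep2d).
#' @param critical `"rho"` or `"N"` (critical / critical-curve).
#' @param sweep facilitating parameter (critical-curve).
#' @param kind `"binodal"` or `"spinodal"` (critical / critical-curve).
#' @param tol coexistence tolerance override (pi-kappa units).
#' @return A validated object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, experiment, params = model_params(),
                            parameter = NULL, values = NULL,
                            x_name = NULL, y_name = NULL,
                            x_values = NULL, y_values = NULL,
                            critical = NULL, sweep = NULL,
                            kind = "binodal", tol = 1e-3) {
  spec <- structure(list(
    name = name, experiment = experiment, params = params,
    parameter = parameter, values = values,
    x_name = x_name, y_name = y_name,
    x_values = x_values, y_values = y_values,
    critical = critical, sweep = sweep, kind = kind, tol = tol
  ), class = "experiment_spec")
  validate_experiment_spec(spec)
  spec
}

#' Validate an experiment spec
#'
#' Checks that the experiment type is known, that every referenced parameter
#' name is a valid flat parameter key, and that grids are non-empty, sorted
#' and numeric. Invalid specs raise an error listing the offending keys.
#'
#' @param spec an `experiment_spec`.
#' @return `spec`, invisibly, on success.
#' @export
validate_experiment_spec <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  problems <- character(0)
  if (!is.character(spec$name) || length(spec$name) != 1L || !nzchar(spec$name)) {
    problems <- c(problems, "name: must be a non-empty string")
  }
  kinds <- c("landscape", "sweep1d", "sweep2d", "critical", "critical-curve")
  if (!spec$experiment %in% kinds) {
    problems <- c(problems, paste0("experiment: unknown type '",
                                   spec$experiment, "'"))
  }
  if (!inherits(spec$params, "model_params")) {
    problems <- c(problems, "params: not a model_params object")
  }
  chk_name <- function(nm, field) {
    if (is.null(nm) || !is.character(nm) || !nm %in% .flat_param_names) {
      paste0(field, ": must be one of ", paste(.flat_param_names, collapse = ", "))
    } else character(0)
  }
  chk_grid <- function(g, field) {
    if (is.null(g) || !is.numeric(g) || length(g) == 0L || is.unsorted(g)) {
      paste0(field, ": must be a non-empty sorted numeric grid")
    } else character(0)
  }
  if (spec$experiment %in% c("landscape", "sweep1d")) {
    problems <- c(problems, chk_name(spec$parameter, "parameter"),
                  chk_grid(spec$values, "values"))
  }
  if (identical(spec$experiment, "sweep2d")) {
    problems <- c(problems, chk_name(spec$x_name, "x_name"),
                  chk_name(spec$y_name, "y_name"),
                  chk_grid(spec$x_values, "x_values"),
                  chk_grid(spec$y_values, "y_values"))
  }
  if (spec$experiment %in% c("critical", "critical-curve")) {
    if (is.null(spec$critical) || !spec$critical %in% c("rho", "N")) {
      problems <- c(problems, "critical: must be 'rho' or 'N'")
    }
    if (!spec$kind %in% c("binodal", "spinodal")) {
      problems <- c(problems, "kind: must be 'binodal' or 'spinodal'")
    }
  }
  if (identical(spec$experiment, "critical-curve")) {
    if (is.null(spec$sweep) || !spec$sweep %in% c("f", "lam", "c0")) {
      problems <- c(problems, "sweep: must be 'f', 'lam' or 'c0'")
    }
    problems <- c(problems, chk_grid(spec$values, "values"))
  }
  if (length(problems)) {
    stop("invalid experiment spec:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(spec)
}

#' Built-in scenarios for the model's standard analyses
#'
#' Ready-made experiment specs for the reference figures of the model:
#' energy profiles versus grafting density (`fig2a`) and polymer length
#' (`fig2b`), the optimal-shape curves (`fig3a`, `fig3b`), the critical-value
#' curves against actin force, line tension and spontaneous curvature
#' (`fig3c_rho`, `fig3d_N`), and the four (Np, N) phase diagrams with the
#' facilitating factors switched off and on (`fig4a`-`fig4d`).
#'
#' The density-sweep profiles use the reference membrane (kappa = 10 kBT,
#' sigma = 0.012 kBT/nm^2) with line tension, spontaneous curvature and
#' actin force switched off; the length sweeps fix rho = 0.0064 1/nm^2.
#'
#' @return Named list of `experiment_spec` objects.
#' @export
builtin_scenarios <- function() {
  base <- update_params(model_params(), lam = 0, c0 = 0, f = 0)
  rho64 <- update_params(base, rho = 0.0064)
  # Np window from the grafting-distance range xi in [10, 100] nm on the
  # default R0 = 100 nm patch: Np = pi R0^2 / xi^2
  np_grid <- seq(pi * 100^2 / 100^2, pi * 100^2 / 10^2, length.out = 41)
  n_grid_ax <- seq(10, 50, length.out = 41)
  on <- list(lam = 0.5, c0 = 0.02, f = 1)
  specs <- list(
    fig2a = experiment_spec("fig2a", "landscape", base,
      parameter = "rho",
      values = c(0.0047, 0.0060, 0.0070, 0.0077, 0.0090)),
    fig2b = experiment_spec("fig2b", "landscape", rho64,
      parameter = "N", values = c(10, 20, 30, 40, 50)),
    fig3a = experiment_spec("fig3a", "sweep1d", base,
      parameter = "rho", values = seq(0.004, 0.010, length.out = 61)),
    fig3b = experiment_spec("fig3b", "sweep1d", rho64,
      parameter = "N", values = seq(10, 50, length.out = 41)),
    fig3c_rho_f = experiment_spec("fig3c_rho_f", "critical-curve", base,
      critical = "rho", sweep = "f", values = seq(0, 1, length.out = 5)),
    fig3c_rho_lam = experiment_spec("fig3c_rho_lam", "critical-curve", base,
      critical = "rho", sweep = "lam", values = seq(0, 0.5, length.out = 5)),
    fig3c_rho_c0 = experiment_spec("fig3c_rho_c0", "critical-curve", base,
      critical = "rho", sweep = "c0", values = seq(0, 0.02, length.out = 5)),
    fig3d_N_f = experiment_spec("fig3d_N_f", "critical-curve", rho64,
      critical = "N", sweep = "f", values = seq(0, 1, length.out = 5)),
    fig3d_N_lam = experiment_spec("fig3d_N_lam", "critical-curve", rho64,
      critical = "N", sweep = "lam", values = seq(0, 0.5, length.out = 5)),
    fig3d_N_c0 = experiment_spec("fig3d_N_c0", "critical-curve", rho64,
      critical = "N", sweep = "c0", values = seq(0, 0.02, length.out = 5)),
    fig4a = experiment_spec("fig4a", "sweep2d", base,
      x_name = "Np", y_name = "N",
      x_values = np_grid, y_values = n_grid_ax),
    fig4b = experiment_spec("fig4b", "sweep2d",
      update_params(base, f = on$f),
      x_name = "Np", y_name = "N",
      x_values = np_grid, y_values = n_grid_ax),
    fig4c = experiment_spec("fig4c", "sweep2d",
      update_params(base, lam = on$lam, c0 = on$c0),
      x_name = "Np", y_name = "N",
      x_values = np_grid, y_values = n_grid_ax),
    fig4d = experiment_spec("fig4d", "sweep2d",
      update_params(base, lam = on$lam, c0 = on$c0, f = on$f),
      x_name = "Np", y_name = "N",
      x_values = np_grid, y_values = n_grid_ax)
  )
  specs
}

#' Run an experiment and write its outputs
#'
#' Executes the analysis described by `spec` and writes deterministic CSV
#' and JSON outputs plus a `<name>_run.json` metadata file recording the
#' full parameter set and package version. Re-running produces byte-identical
#' CSV content.
#'
#' @param spec an `experiment_spec`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a character vector of the files written.
#' @export
run_experiment <- function(spec, out_dir) {
  validate_experiment_spec(spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pfx <- file.path(out_dir, spec$name)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  if (spec$experiment == "landscape") {
    class_rows <- list()
    for (v in spec$values) {
      p <- do.call(update_params, stats::setNames(list(spec$params, v),
                                                  c("params", spec$parameter)))
      ls <- scan_landscape(p, tol = spec$tol)
      tag <- formatC(v, format = "g", digits = 6)
      csv <- sprintf("%s_%s_%s.csv", pfx, spec$parameter, tag)
      write_landscape(ls, csv)
      emit(csv)
      class_rows[[tag]] <- list(value = v, chi_min = ls$chi_min,
                                F_min = ls$F_min, barrier = ls$barrier,
                                state = ls$state)
    }
    js <- paste0(pfx, "_classification.json")
    jsonlite::write_json(class_rows, js, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    emit(js)
  } else if (spec$experiment == "sweep1d") {
    tab <- sweep_1d(spec$params, spec$parameter, spec$values, tol = spec$tol)
    csv <- paste0(pfx, "_sweep1d.csv")
    utils::write.csv(tab, csv, row.names = FALSE)
    emit(csv)
  } else if (spec$experiment == "sweep2d") {
    map <- sweep_2d(spec$params, spec$x_name, spec$y_name,
                    spec$x_values, spec$y_values, tol = spec$tol)
    csv <- paste0(pfx, "_phasemap.csv")
    write_phase_map(map, csv, json_path = paste0(pfx, "_phasemap.json"))
    emit(csv); emit(paste0(pfx, "_phasemap.json"))
  } else if (spec$experiment == "critical") {
    fn <- if (spec$critical == "rho") critical_density else critical_length
    cp <- fn(spec$params, kind = spec$kind)
    js <- paste0(pfx, "_critical.json")
    jsonlite::write_json(cp[c("parameter", "kind", "value", "bracket",
                              "chi_at_transition")],
                         js, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    emit(js)
  } else if (spec$experiment == "critical-curve") {
    tab <- critical_curve(spec$params, critical = spec$critical,
                          sweep = spec$sweep, values = spec$values,
                          kind = spec$kind)
    csv <- paste0(pfx, "_critical_curve.csv")
    write_critical_curve(tab, csv)
    emit(csv)
  }

  meta <- paste0(pfx, "_run.json")
  jsonlite::write_json(list(
    name = spec$name, experiment = spec$experiment,
    package_version = as.character(utils::packageVersion("glycotube")),
    params = flatten_params(spec$params),
    kind = spec$kind, tol = spec$tol
  ), meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit(meta)
  invisible(written)
}

#' Read/write an experiment spec as JSON
#'
#' The on-disk form holds the flat parameter set plus the experiment fields;
#' `read_experiment_spec(write_experiment_spec(spec, path))` reproduces the
#' spec exactly.
#'
#' @param spec an `experiment_spec` (for writing).
#' @param path file path.
#' @return `read_experiment_spec()` returns an `experiment_spec`;
#'   `write_experiment_spec()` returns `path` invisibly.
#' @export
write_experiment_spec <- function(spec, path) {
  validate_experiment_spec(spec)
  x <- unclass(spec)
  x$params <- flatten_params(spec$params)
  x$params$rho <- NULL  # xi is canonical
  x <- Filter(Negate(is.null), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_experiment_spec
#' @export
read_experiment_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(update_params, c(list(params = model_params()), x$params))
  experiment_spec(
    name = x$name, experiment = x$experiment, params = params,
    parameter = x$parameter, values = x$values,
    x_name = x$x_name, y_name = x$y_name,
    x_values = x$x_values, y_values = x$y_values,
    critical = x$critical, sweep = x$sweep,
    kind = if (is.null(x$kind)) "binodal" else x$kind,
    tol = if (is.null(x$tol)) 1e-3 else x$tol
  )
}
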