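test_that("parameter constructors enforce their invariants", {
  expect_error(membrane_params(kappa = 0), "positive")
  expect_error(membrane_params(sigma = -1), "non-negative")
  expect_error(glycocalyx_params(xi = -1), "positive")
  expect_error(glycocalyx_params(N = -2), "non-negative")
  expect_error(glycocalyx_params(xi = 10, rho = 0.01), "not both")
  expect_error(load_params(-0.1), "non-negative")
  expect_error(geometry_params(n_grid = 2), "at least 3")
  # rho constructor and derived density agree
  g <- glycocalyx_params(rho = 0.0064)
  expect_equal(g$xi, 1 / sqrt(0.0064))
  expect_equal(g$rho, 0.0064)
})

test_that("update_params round-trips flat keys and rejects unknown ones", {
  p <- model_params()
  q <- update_params(p, rho = 0.009, f = 0, kappa = 20)
  expect_equal(q$glyco$rho, 0.009, tolerance = 1e-12)
  expect_equal(q$membrane$kappa, 20)
  expect_error(update_params(p, banana = 1), "unknown parameter")
  expect_error(update_params(p, xi = 10, rho = 0.01), "at most one")
  # Np mapping: Np = pi R0^2 / xi^2
  r <- update_params(p, Np = 100)
  expect_equal(total_chain_count(r), 100, tolerance = 1e-12)
  expect_equal(r$glyco$xi, 100 * sqrt(pi / 100))
})

test_that("model parameter config files round-trip", {
  p <- update_params(model_params(), rho = 0.0077, lam = 0.3, N = 35)
  path <- tempfile(fileext = ".json")
  write_model_params(p, path)
  q <- read_model_params(path)
  expect_equal(flatten_params(q), flatten_params(p), tolerance = 1e-12)
  # unknown keys rejected
  jsonlite::write_json(list(kappa = 10, banana = 1), path, auto_unbox = TRUE)
  expect_error(read_model_params(path), "unknown config key")
  unlink(path)
})

test_that("experiment specs validate their fields", {
  expect_error(experiment_spec("x", "dance"), "unknown type")
  expect_error(experiment_spec("s", "sweep1d", parameter = "banana",
                               values = 1:3), "parameter")
  expect_error(experiment_spec("s", "sweep1d", parameter = "rho",
                               values = c(3, 2, 1)), "sorted")
  expect_error(experiment_spec("s", "critical", critical = "banana"),
               "critical")
  spec <- experiment_spec("ok", "sweep1d", parameter = "rho",
                          values = c(0.004, 0.008))
  expect_s3_class(spec, "experiment_spec")
})

test_that("all builtin scenarios are valid and carry their documented parameter values", {
  sc <- builtin_scenarios()
  for (s in sc) expect_silent(validate_experiment_spec(s))
  expect_equal(sc$fig2a$values,
               c(0.0047, 0.0060, 0.0070, 0.0077, 0.0090))
  expect_equal(sc$fig3b$params$glyco$rho, 0.0064, tolerance = 1e-12)
  # the fully facilitated phase map carries lam, c0 and f switched on
  expect_equal(sc$fig4d$params$membrane$lam, 0.5)
  expect_equal(sc$fig4d$params$membrane$c0, 0.02)
  expect_equal(sc$fig4d$params$load$f, 1)
  # and its off-state partner switches them off
  expect_equal(sc$fig4a$params$membrane$lam, 0)
  expect_equal(sc$fig4a$params$load$f, 0)
})

test_that("experiment specs round-trip through JSON", {
  sc <- builtin_scenarios()
  for (s in sc[c("fig2a", "fig3c_rho_f", "fig4d")]) {
    path <- tempfile(fileext = ".json")
    write_experiment_spec(s, path)
    r <- read_experiment_spec(path)
    expect_identical(r$name, s$name)
    expect_identical(r$experiment, s$experiment)
    expect_equal(flatten_params(r$params), flatten_params(s$params),
                 tolerance = 1e-12)
    expect_equal(r$values, s$values)
    expect_equal(r$x_values, s$x_values)
    unlink(path)
  }
})

test_that("run_experiment writes deterministic outputs with metadata", {
  spec <- experiment_spec("demo", "landscape",
                          density_sweep_params(),
                          parameter = "rho", values = c(0.0047, 0.009))
  d1 <- file.path(tempdir(), "gt-run1"); d2 <- file.path(tempdir(), "gt-run2")
  f1 <- run_experiment(spec, d1)
  f2 <- run_experiment(spec, d2)
  expect_true(all(file.exists(f1)))
  # classification JSON reports one entry per density
  cls <- jsonlite::read_json(file.path(d1, "demo_classification.json"),
                             simplifyVector = TRUE)
  expect_length(cls, 2L)
  expect_identical(cls[[1]]$state, "nontubular")
  expect_identical(cls[[2]]$state, "tubular")
  # metadata records the parameter set and version
  meta <- jsonlite::read_json(file.path(d1, "demo_run.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$params$kappa, 10)
  # repeated runs yield byte-identical CSVs
  csvs <- basename(f1[grepl("[.]csv$", f1)])
  for (csv in csvs) {
    expect_identical(readLines(file.path(d1, csv)),
                     readLines(file.path(d2, csv)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("sweep experiments run end to end", {
  spec <- experiment_spec("mini", "sweep1d", density_sweep_params(),
                          parameter = "rho",
                          values = c(0.005, 0.009))
  d <- file.path(tempdir(), "gt-sweep")
  files <- run_experiment(spec, d)
  tab <- utils::read.csv(file.path(d, "mini_sweep1d.csv"))
  expect_named(tab, c("rho", "chi_min", "F_min", "state", "barrier",
                      "reason"))
  expect_equal(tab$chi_min[1], 0)
  expect_gt(tab$chi_min[2], 1)
  unlink(d, recursive = TRUE)
})
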