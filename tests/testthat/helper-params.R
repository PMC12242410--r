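# Reference parameter sets and random generators shared across tests.

# Density-sweep conditions: kappa = 10 kBT, sigma = 0.012 kBT/nm^2,
# lam = c0 = f = 0, N = 20, a = 10 nm, v = a^3, R0 = 100 nm.
density_sweep_params <- function(rho = NULL) {
  p <- model_params(
    membrane = membrane_params(kappa = 10, sigma = 0.012, lam = 0, c0 = 0),
    glyco = glycocalyx_params(xi = 15, N = 20, a = 10),
    load = load_params(f = 0),
    geometry = geometry_params(R0 = 100, chi_max = 30, n_grid = 3001)
  )
  if (!is.null(rho)) p <- update_params(p, rho = rho)
  p
}

# Length-sweep conditions: same membrane, rho = 0.0064 1/nm^2.
length_sweep_params <- function(N = 20) {
  update_params(density_sweep_params(rho = 0.0064), N = N)
}

# Random admissible parameter sets drawn from the biologically motivated
# ranges (kappa 5-50 kBT, sigma up to 0.05 kBT/nm^2, xi 8-40 nm, N 5-50,
# a 5-15 nm with v = a^3).
random_params <- function(n, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- stats::runif(1, 5, 15)
    model_params(
      membrane = membrane_params(kappa = stats::runif(1, 5, 50),
                                 sigma = stats::runif(1, 0.001, 0.05),
                                 lam = stats::runif(1, 0, 0.5),
                                 c0 = stats::runif(1, 0, 0.02)),
      glyco = glycocalyx_params(xi = stats::runif(1, 8, 40),
                                N = stats::runif(1, 5, 50),
                                a = a, v = a^3),
      load = load_params(f = stats::runif(1, 0, 2)),
      geometry = geometry_params(R0 = stats::runif(1, 50, 150))
    )
  })
}
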