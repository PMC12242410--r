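# Independent transcription of the expanded polynomial form of the
# mechanical energy, used as an oracle against the component-wise
# (factored) implementation.
expanded_mechanical <- function(chi, params) {
  m <- params$membrane
  Rt <- tube_radius(chi, params$geometry$R0)
  ((chi + 1) * m$c0^2 + (m$sigma / m$kappa) * (2 * chi + 1)) * Rt^2 +
    2 * Rt * (m$lam / m$kappa - chi * m$c0 - 2 * m$c0) + chi + 4 -
    params$load$f * Rt * (1 + chi) / (pi * m$kappa)
}

test_that("hemispherical cap bending energy is 4 pi kappa", {
  p <- density_sweep_params()
  mech <- mechanical_energy(0, p)
  expect_equal(mech$bending, 4, tolerance = 1e-12)
  # tension term: (sigma/kappa) * Rt^2 with Rt^2 = 5000
  expect_equal(mech$tension, 0.0012 * 5000, tolerance = 1e-12)
  expect_equal(mech$line_tension, 0)
  expect_equal(mech$force_work, 0)
})

test_that("factored and expanded mechanical forms agree", {
  chi <- seq(0, 25, length.out = 40)
  for (p in random_params(12, seed = 11L)) {
    mech <- mechanical_energy(chi, p)
    total <- mech$bending + mech$tension + mech$line_tension + mech$force_work
    expect_equal(total, expanded_mechanical(chi, p), tolerance = 1e-10)
  }
})

test_that("per-chain brush energies vanish for zero-length chains", {
  g0 <- glycocalyx_params(xi = 15, N = 0, a = 10)
  expect_equal(brush_energy_cap_per_chain(c(10, 70, 500), g0), rep(0, 3))
  expect_equal(brush_energy_tube_per_chain(c(10, 70, 500), g0), rep(0, 3))
  expect_error(brush_energy_cap_per_chain(0, g0), "positive")
  expect_error(brush_energy_tube_per_chain(-1, g0), "positive")
})

test_that("cap and tube brush energies share the flat-brush limit", {
  g <- glycocalyx_params(xi = 15, N = 20, a = 10)
  flat <- flat_brush_energy_per_chain(g)
  # closed form: (3N/2) 3^(1/3) v^(2/3) a^(-2/3) xi^(-4/3)
  expect_equal(flat, (3 * 20 / 2) * 3^(1 / 3) * 1000^(2 / 3) *
                 10^(-2 / 3) * 15^(-4 / 3), tolerance = 1e-12)
  cap_inf <- brush_energy_cap_per_chain(1e6, g)
  tube_inf <- brush_energy_tube_per_chain(1e6, g)
  expect_lt(abs(cap_inf - flat) / flat, 1e-3)
  expect_lt(abs(tube_inf - flat) / flat, 1e-3)
  # curvature relieves crowding: curved values sit below the flat limit
  expect_lt(brush_energy_cap_per_chain(50, g), flat)
  expect_lt(brush_energy_tube_per_chain(50, g), flat)
  # the flat-brush height scale enters the brackets
  expect_equal(flat_brush_height(g), 20 * (1000 * 100 / (3 * 225))^(1 / 3))
})

# Quadrature oracle: integrate the brush energy density radially with the
# local concentration cp(r) = (3/(v a^2))^(1/3) s(r)^(-2/3), where the area
# per chain grows as (r/Rt)^2 on a sphere and r/Rt on a cylinder, and the
# brush edge t is fixed by monomer conservation integral(cp * s) = N.
brush_quadrature <- function(Rt, glyco, surface = c("cap", "tube")) {
  surface <- match.arg(surface)
  a <- glyco$a; v <- glyco$v; xi <- glyco$xi; N <- glyco$N
  pw <- if (surface == "cap") 2 else 1
  s <- function(r) xi^2 * (r / Rt)^pw
  cp <- function(r) (3 / (v * a^2))^(1 / 3) * s(r)^(-2 / 3)
  conserved <- function(t) {
    stats::integrate(function(r) cp(r) * s(r), Rt, t,
                     rel.tol = 1e-12)$value - N
  }
  t_edge <- stats::uniroot(conserved, c(Rt * (1 + 1e-12), Rt + 100 * a * N),
                           tol = 1e-12)$root
  stats::integrate(function(r) {
    (3 / (2 * a^2)) / (cp(r) * s(r)) + v * cp(r)^2 * s(r)
  }, Rt, t_edge, rel.tol = 1e-12)$value
}

test_that("closed-form per-chain energies match radial quadrature", {
  g <- glycocalyx_params(xi = 15, N = 20, a = 10)
  for (Rt in c(100 / sqrt(2), 50, 20)) {
    expect_equal(brush_energy_cap_per_chain(Rt, g),
                 brush_quadrature(Rt, g, "cap"), tolerance = 1e-8)
    expect_equal(brush_energy_tube_per_chain(Rt, g),
                 brush_quadrature(Rt, g, "tube"), tolerance = 1e-8)
  }
  # and on a different brush
  g2 <- glycocalyx_params(xi = 22, N = 35, a = 7)
  expect_equal(brush_energy_cap_per_chain(40, g2),
               brush_quadrature(40, g2, "cap"), tolerance = 1e-8)
  expect_equal(brush_energy_tube_per_chain(40, g2),
               brush_quadrature(40, g2, "tube"), tolerance = 1e-8)
})

test_that("per-chain-times-count equals the closed block form", {
  chi <- c(0, 0.5, 2, 7, 19)
  for (p in random_params(12, seed = 23L)) {
    g <- p$glyco; kappa <- p$membrane$kappa
    Rt <- tube_radius(chi, p$geometry$R0)
    # independent single-expression transcription of the glycocalyx block
    inner <- (g$v * g$a^2 / (3 * g$xi^2))^(1 / 3)
    K <- 3^(2 / 3) * (g$v / (g$a^4 * g$xi^2))^(1 / 3)
    block <- (9 * Rt^3 / (2 * kappa * g$xi^2)) * K *
      (2 * ((1 + (5 * g$N / (3 * Rt)) * inner)^(1 / 5) - 1) +
         chi * ((1 + (4 * g$N / (3 * Rt)) * inner)^(1 / 2) - 1))
    gly <- glycocalyx_energy(chi, p)
    expect_equal(gly$glyco_cap + gly$glyco_tube, block, tolerance = 1e-10)
  }
})

test_that("glycocalyx energy is zero on the tube at chi = 0 and vanishes for sparse brushes", {
  p <- density_sweep_params()
  gly <- glycocalyx_energy(0, p)
  expect_equal(gly$glyco_tube, 0)
  expect_gt(gly$glyco_cap, 0)
  sparse <- update_params(p, xi = 1e6)
  gly2 <- glycocalyx_energy(c(0, 3), sparse)
  expect_true(all(abs(gly2$glyco_cap) < 1e-8))
  expect_true(all(abs(gly2$glyco_tube) < 1e-8))
})

test_that("brush energy grows with chain length and grafting density", {
  p <- density_sweep_params()
  chi <- 2
  for (col in c("glyco_cap", "glyco_tube")) {
    en_N <- vapply(c(5, 10, 20, 40), function(N) {
      glycocalyx_energy(chi, update_params(p, N = N))[[col]]
    }, numeric(1))
    expect_true(all(diff(en_N) > 0))
    en_rho <- vapply(c(0.002, 0.004, 0.008, 0.016), function(rho) {
      glycocalyx_energy(chi, update_params(p, rho = rho))[[col]]
    }, numeric(1))
    expect_true(all(diff(en_rho) > 0))
  }
})

test_that("total energy sums its components and honours simple limits", {
  chi <- seq(0, 20, length.out = 25)
  for (p in random_params(8, seed = 31L)) {
    br <- energy_breakdown(chi, p)
    expect_equal(br$total,
                 br$bending + br$tension + br$line_tension + br$force_work +
                   br$glyco_cap + br$glyco_tube, tolerance = 1e-10)
    expect_equal(total_energy(chi, p), br$total)
  }
  # bare hemisphere with tension only: F = 4 + sigma R0^2 / (2 kappa)
  p0 <- update_params(density_sweep_params(), N = 0)
  expect_equal(total_energy(0, p0),
               4 + 0.012 * 100^2 / (2 * 10), tolerance = 1e-12)
  # kBT conversion
  expect_equal(energy_to_kBT(1, p0), pi * 10)
  expect_equal(energy_from_kBT(energy_to_kBT(2.5, p0), p0), 2.5)
})

test_that("bare membrane under tension is monotonically unstable to tubes", {
  p <- update_params(density_sweep_params(), N = 0)
  chi <- seq(0, 30, length.out = 2000)
  F <- total_energy(chi, p)
  expect_true(all(diff(F) > 0))
  # closed-form slope dF/dchi = 1 + (sigma R0^2 / (2 kappa)) / (1 + chi)^2
  slope <- 1 + (0.012 * 1e4 / (2 * 10)) / (1 + chi)^2
  num_slope <- diff(F) / diff(chi)
  expect_equal(num_slope, (slope[-1] + slope[-length(chi)]) / 2,
               tolerance = 1e-4)
})

test_that("normalized energy is invariant under uniform length rescaling", {
  chi <- c(0, 1, 4, 11)
  for (p in random_params(6, seed = 47L)) {
    for (s in c(0.5, 2, 3.7)) {
      ps <- model_params(
        membrane = membrane_params(kappa = p$membrane$kappa,
                                   sigma = p$membrane$sigma / s^2,
                                   lam = p$membrane$lam / s,
                                   c0 = p$membrane$c0 / s),
        glyco = glycocalyx_params(xi = p$glyco$xi * s, N = p$glyco$N,
                                  a = p$glyco$a * s, v = p$glyco$v * s^3),
        load = load_params(f = p$load$f / s),
        geometry = geometry_params(R0 = p$geometry$R0 * s)
      )
      expect_equal(total_energy(chi, ps), total_energy(chi, p),
                   tolerance = 1e-10)
    }
  }
})
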