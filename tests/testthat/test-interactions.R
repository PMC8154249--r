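mk_state <- function(m_mean, inv_m_mean = 1 / m_mean) {
  structure(list(m_mean = m_mean, inv_m_mean = inv_m_mean),
            class = "population_state")
}

test_that("effective parameter scalings with the aggregation number", {
  base <- interaction_params(R1 = 10, Z1 = -6, J1 = 30, d = 3, nu = 2)
  # all-monomer state: identity
  e1 <- effective_params(base, mk_state(1), n0 = 1e17, temperature = 298.15)
  expect_equal(e1$n, 1e17)
  expect_equal(e1$R, 10)
  expect_equal(e1$Z, -6)
  expect_equal(e1$J, 30)
  # pure tetramer
  e4 <- effective_params(base, mk_state(4, 0.25), 1e17, 298.15)
  expect_equal(e4$n, 0.25e17)
  expect_equal(e4$Z, -24)
  expect_equal(e4$J, 30 * 4^(2 / 3))
  expect_equal(e4$R, 10 * 4^(1 / 3))
  # mixed state omega = {1: 0.5, 4: 0.5} -> <m> = 2.5, <1/m> = 0.625
  em <- effective_params(base, mk_state(2.5, 0.625), 1e17, 298.15)
  expect_equal(em$n, 0.625e17)
  expect_equal(em$Z, -15)
  expect_equal(em$J, 30 * 2.5^(2 / 3))
  # unphysical volume fraction rejected
  expect_error(effective_params(interaction_params(60, 0, 0, 3), mk_state(4),
                                1e19, 298.15), "volume fraction")
})

test_that("Percus-Yevick structure factor limits", {
  R <- 20
  # ideal-gas limit
  expect_equal(py_structure_factor(seq(0.01, 0.3, 0.01), R, 1), rep(1, 30),
               tolerance = 1e-6)
  # compressibility limit at eta = 0.1
  eta <- 0.1
  n <- eta / ((4 / 3) * pi * R^3 * 1e-24)
  s0 <- py_structure_factor(1e-8, R, n)
  expect_equal(s0, (1 - eta)^4 / (1 + 2 * eta)^2, tolerance = 1e-8)
  # high-q tail -> 1 beyond q 2R = 50 (dilute enough that the x^-2
  # oscillation envelope is below the tolerance there)
  n05 <- 0.05 / ((4 / 3) * pi * R^3 * 1e-24)
  qtail <- seq(50, 80, length.out = 100) / (2 * R)
  expect_true(all(abs(py_structure_factor(qtail, R, n05) - 1) < 1e-3))
})

test_that("RPA reduces to PY at zero perturbation and reacts with its sign", {
  base <- interaction_params(R1 = 15, Z1 = 0, J1 = 0, d = 3, nu = 1)
  st <- mk_state(1)
  n0 <- 2e17
  eff <- effective_params(base, st, n0, 298.15, ionic_strength = 0.02)
  q <- seq(0.005, 0.4, length.out = 80)
  expect_identical(rpa_structure_factor(q, eff),
                   py_structure_factor(q, eff$R, eff$n))
  # pure repulsion suppresses forward scattering
  effZ <- effective_params(interaction_params(15, -8, 0, 3, 1), st, n0,
                           298.15, 0.02)
  expect_lt(rpa_structure_factor(q, effZ)[1],
            py_structure_factor(q, effZ$R, effZ$n)[1])
})

test_that("truncated-Yukawa transform matches adaptive quadrature", {
  K <- 150; kap <- 0.08; rc <- 24
  for (q in c(0.02, 0.1, 0.3)) {
    num <- stats::integrate(function(r) {
      4 * pi * r^2 * K * exp(-kap * r) / r * sin(q * r) / (q * r)
    }, rc, Inf, rel.tol = 1e-10)$value
    expect_equal(vbwsas:::yukawa_ft(q, K, kap, rc), num,
                 tolerance = 1e-6)
  }
})

test_that("ellipsoidal decoupling function limits and quadrature accuracy", {
  q <- seq(0.01, 0.4, length.out = 50)
  expect_equal(coupling_beta_ell(q, 10, 2, 1), rep(1, 50))
  expect_equal(coupling_beta_ell(1e-9, 10, 3, 5), 1, tolerance = 1e-8)
  b_def <- coupling_beta_ell(q, 10, 2.5, 5)
  # independent 10^4-node reference: composite Simpson in cos(theta)
  nn <- 1e4
  mu <- seq(0, 1, length.out = nn + 1)
  wt <- c(1, rep(c(4, 2), length.out = nn - 1), 1)
  b <- 10 * (2.5 / 5)^(1 / 3)
  r_th <- b * sqrt(1 - mu^2 + 25 * mu^2)
  A <- vbwsas:::sphere_amp(outer(q, r_th))
  num <- (A %*% wt)^2 / sum(wt)^2
  den <- (A^2) %*% wt / sum(wt)
  b_ref <- as.numeric(num / den)
  expect_equal(b_def, b_ref, tolerance = 1e-6)
  expect_true(all(b_def >= 0 & b_def <= 1))
})

test_that("measured structure factor identities", {
  S <- c(0.8, 1, 1.4)
  expect_equal(measured_structure_factor(S, rep(1, 3)), S)
  expect_equal(measured_structure_factor(rep(1, 3), c(0.2, 0.5, 0.9)),
               rep(1, 3))
  expect_equal(measured_structure_factor(0.8, 0.5), 0.9)
})

test_that("damping by the coupling function grows with anisometry", {
  base_nu <- c(1.5, 3, 6)
  st <- mk_state(2.5, 0.625)
  n0 <- 3e17
  q <- seq(0.005, 0.3, length.out = 60)
  damp <- vapply(base_nu, function(nu) {
    eff <- effective_params(interaction_params(12, -8, 20, 3, nu), st, n0,
                            298.15, 0.02)
    S <- rpa_structure_factor(q, eff)
    beta <- coupling_beta_ell(q, 12, st$m_mean, nu)
    max(abs(measured_structure_factor(S, beta) - S))
  }, numeric(1))
  expect_true(all(diff(damp) > 0))
})

test_that("pair potential profile: contact values and decay", {
  st <- mk_state(1)
  eff <- effective_params(interaction_params(12, -6, 25, 3, 1), st, 1e17,
                          298.15, 0.02)
  r <- seq(2 * eff$R, 2 * eff$R + 200, length.out = 400)
  pp <- pair_potential_profile(r, eff)
  kT <- 8.31446261815324 * 298.15 / 1000  # kJ/mol
  expect_equal(pp$u_A[1], -eff$J / kT, tolerance = 1e-10)
  expect_lt(abs(pp$u[length(r)]), 1e-3)
  # zero charge: no repulsive term
  eff0 <- effective_params(interaction_params(12, 0, 25, 3, 1), st, 1e17,
                           298.15, 0.02)
  pp0 <- pair_potential_profile(r, eff0)
  expect_true(all(pp0$u_C == 0))
  # inside the core: NA
  expect_true(all(is.na(pair_potential_profile(c(1, 5), eff)$u)))
})
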