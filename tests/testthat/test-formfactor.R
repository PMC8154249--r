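test_that("excess amplitude limits and independent Cromer-Mann evaluation", {
  r_e <- 2.8179403262e-13
  # zero-solvent limit: f(0) = Z to the accuracy of the parameterization
  expect_equal(excess_amplitude("C", 0, solvent_sld = 0) / r_e, 6,
               tolerance = 1e-3)
  # contrast matching: rho_s v = f(0) makes the amplitude exactly zero
  f0 <- atomic_form_factor("O", 0) * r_e
  v <- 9.13
  sld_match <- f0 / (v * 1e-8)
  expect_equal(excess_amplitude("O", 0, displaced_volume = v,
                                solvent_sld = sld_match), 0,
               tolerance = 1e-25)
  # independent evaluation of the published 4-Gaussian form at q = 0.2
  a <- c(2.31000, 1.02000, 1.58860, 0.865000)
  b <- c(20.8439, 10.2075, 0.568700, 51.6512)
  cc <- 0.215600
  q <- 0.2
  oracle <- sum(a * exp(-b * (q / (4 * pi))^2)) + cc
  expect_equal(atomic_form_factor("C", q), oracle, tolerance = 1e-6)
  expect_error(atomic_form_factor("Xx", 0.1), "unknown element")
})

test_that("hydration shell geometry and the d_h = 1 null case", {
  tf <- toy_fixture()
  cf <- tf$ensemble$conformers[[1]]
  expect_equal(nrow(hydration_shell(cf, d_h = 1)), 0)
  expect_error(hydration_shell(cf, d_h = 1.2), "range")
  # single atom: all shell points inside [r_atom, r_atom + thickness]
  one <- conformer("one", 1L, "x", data.frame(
    chain = 1L, resno = c(1, 1, 2), resname = "ALA",
    elety = c("N", "CA", "N2"), element = c("C", "C", "C"),
    x = c(0, 100, 0), y = c(0, 100, 100), z = 0))
  sh <- hydration_shell(one, d_h = 1.05, pool = FALSE)
  r_c <- (3 * 16.44 / (4 * pi))^(1 / 3)
  dmin <- vapply(seq_len(nrow(sh)), function(i) {
    min(sqrt((sh$x[i] - c(0, 100, 0))^2 + (sh$y[i] - c(0, 100, 100))^2 +
               sh$z[i]^2))
  }, numeric(1))
  expect_true(all(dmin >= r_c - 1e-9 & dmin <= r_c + 3 + 1e-9))
  # buried atom: center of an icosahedral cage contributes no shell points
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    expand.grid(x = c(-1, 1), y = c(-phi, phi), z = 0)[, c("x", "y", "z")],
    expand.grid(x = 0, y = c(-1, 1), z = c(-phi, phi))[, c("x", "y", "z")],
    expand.grid(x = c(-phi, phi), y = 0, z = c(-1, 1))[, c("x", "y", "z")])
  ico <- as.matrix(ico) / sqrt(1 + phi^2) * 2 * r_c  # neighbors at contact
  cage <- data.frame(chain = 1L, resno = 1:13, resname = "ALA",
                     elety = "CA", element = "C",
                     x = c(0, ico[, 1]), y = c(0, ico[, 2]),
                     z = c(0, ico[, 3]))
  shc <- hydration_shell(conformer("cage", 1L, "x", cage), d_h = 1.05,
                         pool = FALSE)
  d_center <- sqrt(shc$x^2 + shc$y^2 + shc$z^2)
  # brute-force accessibility: no kept point may sit in the buried center's
  # own shell band while being closer to the center than to all neighbors
  expect_true(all(d_center > r_c + 1.5 |
                    vapply(seq_len(nrow(shc)), function(i) {
                      p <- c(shc$x[i], shc$y[i], shc$z[i])
                      any(sqrt(colSums((t(ico) - p)^2)) <
                            sqrt(sum(p^2)))
                    }, logical(1))))
})

test_that("Debye sum: closed forms and the forward-scattering identity", {
  q <- c(0.05, 0.1, 0.3)
  one <- suppressWarnings(conformer("one", 1L, "x", data.frame(
    chain = 1L, resno = 1, resname = "ALA", elety = "CA", element = "C",
    x = 0, y = 0, z = 0)))  # single-atom Rg warning is expected
  f_c <- excess_amplitude("C", q, solvent_sld = 0)
  expect_equal(squared_form_factor(one, q, solvent_sld = 0), f_c^2)
  # two identical scatterers at distance r: 2 f^2 (1 + sinc(qr))
  r <- 8
  two <- conformer("two", 1L, "x", data.frame(
    chain = 1L, resno = 1:2, resname = "ALA", elety = "CA", element = "C",
    x = c(0, r), y = 0, z = 0))
  got <- squared_form_factor(two, q, solvent_sld = 0)
  expect_equal(got, 2 * f_c^2 * (1 + sin(q * r) / (q * r)),
               tolerance = 1e-12)
  # <|F(0)|^2> = (sum f(0))^2 on an arbitrary fixture
  tf <- toy_fixture()
  cf <- tf$ensemble$conformers[[2]]
  qq <- 1e-8
  fsum <- sum(vapply(cf$atoms$element, function(e) {
    excess_amplitude(e, qq, solvent_sld = tf$ff$solvent_sld)
  }, numeric(1)))
  expect_equal(squared_form_factor(cf, qq, solvent_sld = tf$ff$solvent_sld),
               fsum^2, tolerance = 1e-6)
})

test_that("Debye sum equals the Monte-Carlo orientational average", {
  cf <- conformer("cloud", 1L, "x", random_cloud_conformer(20, seed = 4))
  xyz <- as.matrix(cf$atoms[, c("x", "y", "z")])
  for (q in c(0.08, 0.2, 0.35)) {
    f <- vapply(cf$atoms$element, function(e) {
      excess_amplitude(e, q, solvent_sld = 0)
    }, numeric(1))
    mc <- mc_orientation_average(xyz, f, q, n_mc = 1e5)
    debye <- squared_form_factor(cf, q, solvent_sld = 0)
    expect_lt(abs(debye - mc$mean), 3 * mc$se)
  }
})

test_that("form factor is invariant under rigid transforms", {
  cf <- conformer("cloud", 1L, "x", random_cloud_conformer(15, seed = 6))
  q <- seq(0.03, 0.4, length.out = 20)
  base <- squared_form_factor(cf, q, solvent_sld = 0)
  set.seed(12)
  at <- cf$atoms
  xyz <- rigid_transform(as.matrix(at[, c("x", "y", "z")]),
                         random_rotation(), stats::rnorm(3, 0, 30))
  at[, c("x", "y", "z")] <- xyz
  moved <- squared_form_factor(conformer("mv", 1L, "x", at), q,
                               solvent_sld = 0)
  expect_equal(moved, base, tolerance = 1e-10)
})

test_that("Kratky plots: extended chains plateau, compact globules peak", {
  q <- seq(0.02, 0.35, length.out = 60)
  # extended chain fixture
  strand <- conformer("s", 1L, "x", build_chain(rep(-120, 30), rep(130, 30)))
  # compact globular fixture: atoms filling a sphere
  set.seed(2)
  n <- 150
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- 12 * stats::runif(n)^(1 / 3)
  ball <- conformer("ball", 1L, "x", data.frame(
    chain = 1L, resno = rep(1:38, each = 4, length.out = n), resname = "ALA",
    elety = "CA", element = "C",
    x = u[, 1] * r, y = u[, 2] * r, z = u[, 3] * r))
  kr_s <- q^2 * squared_form_factor(strand, q, solvent_sld = 0)
  kr_b <- q^2 * squared_form_factor(ball, q, solvent_sld = 0)
  # peak presence: interior maximum well above the high-q end
  expect_lt(which.max(kr_b), length(q))
  expect_gt(max(kr_b) / kr_b[length(q)], 1.5)
  # plateau: the extended curve shows no strong interior peak
  expect_gt(kr_s[length(q)] / max(kr_s), 0.66)
})

test_that("residue-level coarse graining tracks the atomic sum at low q", {
  tf <- toy_fixture()
  cf <- tf$ensemble$conformers[[1]]
  q <- seq(0.03, 0.25, length.out = 30)
  at <- squared_form_factor(cf, q, solvent_sld = tf$ff$solvent_sld)
  res <- squared_form_factor(cf, q, solvent_sld = tf$ff$solvent_sld,
                             granularity = "residue")
  expect_true(all(abs(res - at) / at < 0.05))
})
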