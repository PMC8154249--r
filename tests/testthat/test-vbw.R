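test_that("Dirichlet moments: prior formulas, degenerate case, MC oracle", {
  for (N in c(2, 4, 15)) {
    mo <- dirichlet_moments(rep(0.5, N))
    expect_equal(mo$mean, rep(1 / N, N))
    expect_equal(diag(mo$cov), rep(2 * (N - 1) / (N^2 * (N + 2)), N))
  }
  mo1 <- dirichlet_moments(3)
  expect_equal(mo1$mean, 1)
  expect_equal(as.numeric(mo1$cov), 0)
  expect_error(dirichlet_moments(c(1, -1)), "positive")
  # Monte-Carlo oracle for alpha = (2, 1, 1)
  set.seed(21)
  n <- 1e6
  g <- cbind(stats::rgamma(n, 2), stats::rgamma(n, 1), stats::rgamma(n, 1))
  w <- g / rowSums(g)
  mo <- dirichlet_moments(c(2, 1, 1))
  for (j in 1:3) {
    se_m <- stats::sd(w[, j]) / sqrt(n)
    expect_lt(abs(mean(w[, j]) - mo$mean[j]), 3 * se_m)
    v <- w[, j] - mean(w[, j])
    se_v <- stats::sd(v^2) / sqrt(n)
    expect_lt(abs(stats::var(w[, j]) - mo$cov[j, j]), 3 * se_v)
  }
})

test_that("reduced chi2 arithmetic", {
  cu <- toy_curves()[[1]]
  expect_equal(reduced_chi2(cu, cu$intensity), 0)
  expect_equal(reduced_chi2(cu, cu$intensity + cu$sigma), 1)
  cu3 <- saxs_curve(c(0.1, 0.2, 0.3), c(1, 1, 1), c(0.1, 0.1, 0.1),
                    condition(298.15, 5))
  model <- c(1 - 0.1, 1 + 0.2, 1)
  expect_equal(reduced_chi2(cu3, model), (1 + 4 + 0) / 3)
})

test_that("model intensity: single-species limit, linearity, hand mixture", {
  tf <- toy_fixture()
  ens <- tf$ensemble
  q <- tf$spec$q
  n0 <- 2e17
  # single monomeric conformer dominant: w = (1, ~0, ~0, ~0)
  w <- c(1 - 3e-12, 1e-12, 1e-12, 1e-12)
  st <- vbwsas:::population_state(w, ens)
  I <- model_intensity(st, tf$ff, ens, S_M = 1, B = 0, n0 = n0)
  expect_equal(I, n0 * tf$ff$F2[, 1], tolerance = 1e-9)
  # linearity in n0
  I2 <- model_intensity(st, tf$ff, ens, S_M = 1, B = 0, n0 = 2 * n0)
  expect_equal(I2, 2 * I, tolerance = 1e-12)
  # 50/50 monomer/tetramer with the 1/m number-concentration factors
  w <- c(0.5, 0, 0, 0.5)
  st <- vbwsas:::population_state(w, ens)
  Im <- model_intensity(st, tf$ff, ens, S_M = 1, B = 1e-4, n0 = n0)
  hand <- n0 * (0.5 * tf$ff$F2[, 1] + (0.5 / 4) * tf$ff$F2[, 4]) + 1e-4
  expect_equal(Im, hand, tolerance = 1e-12)
})

# assemble the per-curve model pieces at given thermo parameters
curve_pieces <- function(k, th, alpha0 = NULL) {
  tf <- toy_fixture()
  cu <- toy_curves()[[k]]
  st <- solve_equilibrium(th, tf$ensemble, cu$condition)
  n0 <- number_density(cu$condition$c_T, tf$M1)
  eff <- effective_params(tf$spec$inter_true, st, n0,
                          cu$condition$temperature, tf$spec$ionic_strength)
  S <- rpa_structure_factor(cu$q, eff)
  beta <- coupling_beta_ell(cu$q, tf$spec$inter_true$R1, st$m_mean,
                            tf$spec$inter_true$nu)
  S_M <- measured_structure_factor(S, beta)
  G <- vbwsas:::intensity_basis(st, tf$ff$F2, tf$ensemble, S_M, n0)
  if (is.null(alpha0)) {
    alpha0 <- vbwsas:::profile_alpha0(cu, st, G, tf$ensemble)
  }
  list(curve = cu, state = st, n0 = n0, S_M = S_M, G = G,
       dirichlet = dirichlet_state(alpha0, st), ff = tf$ff,
       ens = tf$ensemble, B = tf$spec$inter_true$B)
}

truth_thermo <- function() {
  tf <- toy_fixture()
  thermo_params(tf$spec$thermo_true$dH, tf$spec$thermo_true$dS,
                tf$spec$thermo_true$dCp, M1 = tf$M1)
}

test_that("functional gradient in alpha0 matches central finite differences", {
  th <- truth_thermo()
  tf <- toy_fixture()
  set.seed(31)
  for (a0 in c(0.7, 5, 60)) {
    p <- curve_pieces(2, th, alpha0 = c("1" = a0, "3" = a0, "4" = a0))
    Lfun <- function(a) {
      d <- dirichlet_state(c("1" = a, "3" = a0, "4" = a0), p$state)
      functional_L(p$curve, d, p$state, p$ff, p$ens, p$S_M, p$B, p$n0)$L
    }
    h <- 1e-4 * a0
    fd <- (Lfun(a0 + h) - Lfun(a0 - h)) / (2 * h)
    # analytic oracle: d/da0 [ D/(a0+1) + KL(a0 mu || 1/2) ]
    mu <- p$state$W[["1"]]
    idx <- tf$ensemble$members[["1"]]
    Gm <- p$G[, idx, drop = FALSE]
    s1 <- as.numeric((Gm^2) %*% mu)
    s2 <- as.numeric(Gm %*% mu)^2
    D <- 0.5 * sum((s1 - s2) / p$curve$sigma^2)
    al <- a0 * mu
    grad_kl <- sum(mu * (al - 0.5) * trigamma(al)) -
      (a0 - length(mu) / 2) * trigamma(a0)
    oracle <- -D / (a0 + 1)^2 + grad_kl
    expect_equal(fd, oracle, tolerance = 1e-5 * max(1, abs(oracle)))
  }
})

test_that("chi2 contribution of the functional vanishes on perfect data", {
  th <- truth_thermo()
  tf <- toy_fixture()
  nl <- toy_curves(noiseless = TRUE)
  p <- curve_pieces(1, th)
  cu_nl <- nl[[1]]
  fl <- functional_L(cu_nl, p$dirichlet, p$state, p$ff, p$ens, p$S_M, p$B,
                     p$n0)
  expect_lt(fl$chi2, 1e-18)
})

test_that("functional is invariant to permuting conformers within a class", {
  th <- truth_thermo()
  tf <- toy_fixture()
  p <- curve_pieces(3, th)
  L0 <- functional_L(p$curve, p$dirichlet, p$state, p$ff, p$ens, p$S_M, p$B,
                     p$n0)$L
  # swap the two monomeric conformers everywhere
  perm <- c(2, 1, 3, 4)
  ens2 <- tf$ensemble
  ens2$conformers <- ens2$conformers[perm]
  ff2 <- tf$ff
  ff2$F2 <- ff2$F2[, perm]
  st2 <- p$state
  st2$w <- st2$w[perm]
  st2$W[["1"]] <- st2$W[["1"]][c(2, 1)]
  d2 <- p$dirichlet
  d2$alpha[["1"]] <- d2$alpha[["1"]][c(2, 1)]
  L1 <- functional_L(p$curve, d2, st2, ff2, ens2, p$S_M, p$B, p$n0)$L
  expect_equal(L1, L0, tolerance = 1e-12)
})

test_that("multi-curve functional is additive", {
  th <- truth_thermo()
  ps <- lapply(1:3, curve_pieces, th = th)
  curves <- lapply(ps, `[[`, "curve")
  pieces <- lapply(ps, function(p) {
    list(dirichlet = p$dirichlet, state = p$state, ff = p$ff, ens = p$ens,
         S_M = p$S_M, B = p$B, n0 = p$n0)
  })
  ov <- overall_functional(curves, pieces)
  expect_equal(ov$Lambda, sum(ov$L), tolerance = 1e-12)
  # single curve
  ov1 <- overall_functional(curves[1], pieces[1])
  expect_equal(ov1$Lambda, ov$L[1])
  # duplicated curve doubles
  ov2 <- overall_functional(curves[c(1, 1)], pieces[c(1, 1)])
  expect_equal(ov2$Lambda, 2 * ov$L[1], tolerance = 1e-12)
})

test_that("adjacency regularization arithmetic", {
  tab <- data.frame(J1 = c(100, 100), d = c(3, 3), R1 = c(10, 10),
                    nu = c(2, 2))
  expect_equal(regularization_V(tab), 0)
  scales <- c(J1 = 10, d = 1, R1 = 1, nu = 1)
  tab2 <- data.frame(J1 = c(100, 110), d = c(3, 3), R1 = c(10, 10),
                     nu = c(2, 2))
  expect_equal(regularization_V(tab2, scales), 1)
  # three conditions: consecutive-pair sum
  tab3 <- data.frame(J1 = c(100, 110, 130), d = 3, R1 = 10, nu = 2)
  expect_equal(regularization_V(tab3, scales), 1 + 4)
})
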