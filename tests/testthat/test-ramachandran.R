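test_that("region map covers the torus with disjoint labels", {
  for (res in c(2, 5)) {
    map <- build_region_map(ramachandran_density(res))
    expect_true(all(map$labels %in% ramachandran_regions))
    expect_false(any(is.na(map$labels)))
    # every canonical region is present
    expect_true(all(c("beta_fav", "alphaR_fav", "alphaL_fav", "gly",
                      "uns") %in% unique(as.vector(map$labels))))
  }
})

test_that("helical peak, density normalization, and boundary closedness", {
  map <- region_map_fixture()
  expect_equal(assign_region(map, -63, -43), "alphaR_fav")
  bad <- ramachandran_density()
  bad$general <- bad$general * 0.5
  expect_error(build_region_map(bad), "normalized")
  # closed alphaR band at psi = -120 / -50, beta immediately outside, with a
  # handcrafted density that is allowed-level everywhere
  dens <- ramachandran_density(2)
  dens$general[] <- 0.001
  dens$general[1, 1] <- 1   # normalization anchor
  dens$gly[] <- 1e-6
  dens$gly[1, 1] <- 1
  m2 <- build_region_map(dens)
  expect_equal(assign_region(m2, -90, -120), "alphaR_all")
  expect_equal(assign_region(m2, -90, -50), "alphaR_all")
  expect_equal(assign_region(m2, -90, -122), "beta_all")
  expect_equal(assign_region(m2, -90, 52), "beta_all")
  expect_equal(assign_region(m2, -90, 0), "alphaR_all")
  expect_equal(assign_region(m2, 90, 0), "alphaL_all")
})

test_that("degenerate density: everything else is unstructured", {
  dens <- ramachandran_density(5)
  dens$general[] <- 0
  dens$general[10, 60] <- 1  # one favored beta cell (phi < 0, psi > 50)
  dens$gly[] <- 0
  dens$gly[1, 1] <- 1
  map <- build_region_map(dens)
  tb <- table(map$labels)
  expect_equal(unname(tb[["beta_fav"]]), 1)
  # everything except the one favored cell and the gly anchor is uns
  expect_gte(unname(tb[["uns"]]), length(map$labels) - 2)
})

test_that("region assignment is periodic and matches brute-force lookup", {
  map <- region_map_fixture()
  set.seed(17)
  phi <- stats::runif(1e4, -720, 720)
  psi <- stats::runif(1e4, -720, 720)
  lab <- assign_region(map, phi, psi)
  expect_identical(lab, assign_region(map, phi + 360, psi - 360))
  # brute force: wrap, then find the nearest cell center on the torus
  brute <- vapply(seq_along(phi), function(i) {
    p1 <- (phi[i] + 180) %% 360 - 180
    p2 <- (psi[i] + 180) %% 360 - 180
    d1 <- pmin(abs(map$phi - p1), 360 - abs(map$phi - p1))
    d2 <- pmin(abs(map$psi - p2), 360 - abs(map$psi - p2))
    map$labels[which.min(d1), which.min(d2)]
  }, character(1))
  expect_identical(lab, brute)
  # grid nodes map to their own cells
  idx <- cbind(sample(length(map$phi), 50, TRUE),
               sample(length(map$psi), 50, TRUE))
  expect_identical(assign_region(map, map$phi[idx[, 1]], map$psi[idx[, 2]]),
                   map$labels[idx])
})

test_that("propensities: indicators, mixtures, and chain averaging", {
  map <- region_map_fixture()
  helix <- conformer("h", 1L, "1A", build_chain(rep(-60, 8), rep(-45, 8)))
  strand <- conformer("s", 1L, "1A", build_chain(rep(-120, 8), rep(130, 8)))
  ens1 <- ensemble(list(helix))
  pt <- propensities(ens1, 1, map)
  expect_true(all(pt$p[, "alphaR_fav"] == 1))
  expect_true(all(pt$var == 0))
  expect_equal(rowSums(pt$p), rep(1, nrow(pt$p)), ignore_attr = TRUE)
  # two monomers with weights 0.3 / 0.7 disagreeing everywhere
  ens2 <- ensemble(list(helix, strand))
  pt2 <- propensities(ens2, c(0.3, 0.7), map)
  expect_true(all(abs(pt2$p[, "alphaR_fav"] - 0.3) < 1e-12))
  expect_true(all(abs(pt2$p[, "beta_fav"] - 0.7) < 1e-12))
  # a trimer whose three chains fall in three regions: 1/3 each
  ch_h <- build_chain(rep(-60, 8), rep(-45, 8))
  ch_b <- build_chain(rep(-120, 8), rep(130, 8))
  ch_l <- build_chain(rep(57, 8), rep(47, 8))
  ch_b$chain <- 2L; ch_l$chain <- 3L
  tri <- conformer("tri", 3L, "3X", rbind(ch_h, ch_b, ch_l))
  # reference monomer keeps the equilibrium solver's convention happy
  ens3 <- ensemble(list(helix, tri))
  pt3 <- propensities(ens3, c(0, 1), map)
  lab_l <- assign_region(map, 57, 47)
  expect_true(all(abs(pt3$p[, "alphaR_fav"] - 1 / 3) < 1e-12))
  expect_true(all(abs(pt3$p[, "beta_fav"] - 1 / 3) < 1e-12))
  expect_true(all(abs(pt3$p[, lab_l] - 1 / 3) < 1e-12))
})

test_that("propensity normalization holds for random weights", {
  map <- region_map_fixture()
  tf <- toy_fixture()
  dihedrals <- lapply(tf$ensemble$conformers, compute_dihedrals)
  set.seed(23)
  for (k in 1:5) {
    w <- stats::runif(4); w <- w / sum(w)
    pt <- propensities(tf$ensemble, w, map, dihedrals = dihedrals)
    expect_equal(rowSums(pt$p), rep(1, nrow(pt$p)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("propensity variance propagates the weight covariance", {
  map <- region_map_fixture()
  helix <- conformer("h", 1L, "1A", build_chain(rep(-60, 8), rep(-45, 8)))
  strand <- conformer("s", 1L, "1A", build_chain(rep(-120, 8), rep(130, 8)))
  ens <- ensemble(list(helix, strand))
  w <- c(0.4, 0.6)
  st <- vbwsas:::population_state(w, ens)
  dir <- dirichlet_state(c("1" = 10), st)
  V <- weight_covariance(st, dir, ens)
  pt <- propensities(ens, w, map, w_cov = V)
  # p(alphaR_fav) = w1 -> var = Var(w1)
  expect_equal(unname(pt$var[1, "alphaR_fav"]), V[1, 1], tolerance = 1e-12)
  expect_true(all(pt$var >= 0))
})

test_that("run filter: fixture blocks, threshold edge, antisymmetry", {
  map <- region_map_fixture()
  n_res <- 100
  mk_table <- function(p_beta) {
    p <- matrix(0, n_res, 8, dimnames = list(2:(n_res + 1),
                                             ramachandran_regions))
    p[, "beta_fav"] <- p_beta
    p[, "alphaR_fav"] <- 1 - p_beta
    structure(list(p = p, var = p * 0, residues = 2:(n_res + 1),
                   regions = ramachandran_regions),
              class = "propensity_table")
  }
  base <- rep(0.3, n_res)
  # mutant: +0.2 on residues 51..64 (run of 14), alternating signs elsewhere
  delta <- rep(c(0.01, -0.01), length.out = n_res)
  resn <- 2:(n_res + 1)
  delta[resn >= 51 & resn <= 64] <- 0.2
  delta[resn %in% c(50, 65)] <- -0.01  # opposite sign flanks end the run
  wt <- mk_table(base)
  mut <- mk_table(base + delta)
  bars <- delta_propensity_runs(mut, wt, "beta_fav", min_run = 8)
  in_run <- bars$resno >= 51 & bars$resno <= 64
  expect_true(all(abs(bars$mean[in_run] - 0.2) < 1e-12))
  expect_true(all(bars$mean[!in_run] == 0))
  # bars are constant within the run
  expect_equal(length(unique(bars$mean[in_run])), 1)
  # a 7-residue run stays silent
  delta7 <- rep(c(0.01, -0.01), length.out = n_res)
  delta7[resn >= 51 & resn <= 57] <- 0.2
  delta7[resn %in% c(50, 58)] <- -0.01
  bars7 <- delta_propensity_runs(mk_table(base + delta7), wt, "beta_fav")
  expect_true(all(bars7$mean[bars7$resno >= 51 & bars7$resno <= 57] == 0))
  # antisymmetry under swapping the tables
  rev_bars <- delta_propensity_runs(wt, mut, "beta_fav")
  expect_equal(rev_bars$mean, -bars$mean)
  expect_equal(rev_bars$delta, -bars$delta)
  # all-zero difference
  z <- delta_propensity_runs(wt, wt, "beta_fav")
  expect_true(all(z$mean == 0) && all(z$delta == 0))
})
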