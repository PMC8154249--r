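# Shared fixtures, built once per test session (everything is generated in
# code; no stored data).
.fixtures <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fixtures$toy)) {
    spec <- synthetic_spec()
    toy <- make_toy_ensemble(spec)
    ff <- formfactor_set(toy$ensemble, spec$q, d_h = spec$d_h)
    .fixtures$toy <- list(spec = spec, ensemble = toy$ensemble,
                          manifest = toy$manifest, M1 = toy$M1, ff = ff)
  }
  .fixtures$toy
}

toy_curves <- function(noiseless = FALSE) {
  key <- if (noiseless) "curves_nl" else "curves"
  if (is.null(.fixtures[[key]])) {
    tf <- toy_fixture()
    .fixtures[[key]] <- simulate_dataset(tf$spec, tf$ensemble, tf$ff, tf$M1,
                                         noiseless = noiseless)
  }
  .fixtures[[key]]
}

region_map_fixture <- function() {
  if (is.null(.fixtures$map)) .fixtures$map <- build_region_map()
  .fixtures$map
}

# A small conformer: n_atoms random heavy atoms in a blob.
random_cloud_conformer <- function(n_atoms = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    chain = 1L, resno = rep(seq_len(ceiling(n_atoms / 4)), each = 4,
                            length.out = n_atoms),
    resname = "ALA",
    elety = rep(c("N", "CA", "C", "O"), length.out = n_atoms),
    element = rep(c("N", "C", "C", "O"), length.out = n_atoms),
    x = stats::rnorm(n_atoms, 0, 5), y = stats::rnorm(n_atoms, 0, 5),
    z = stats::rnorm(n_atoms, 0, 5), stringsAsFactors = FALSE)
}

# Monte-Carlo orientational average of |sum_a f_a exp(i q.r_a)|^2 for one q,
# with per-scatterer amplitudes f (n_mc random directions). Returns the MC
# mean and its standard error.
mc_orientation_average <- function(xyz, f, q, n_mc = 1e5, seed = 99) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  phase <- (u %*% t(xyz)) * q          # n_mc x n_atoms
  re <- cos(phase) %*% f
  im <- sin(phase) %*% f
  v <- as.numeric(re^2 + im^2)
  list(mean = mean(v), se = stats::sd(v) / sqrt(n_mc))
}
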