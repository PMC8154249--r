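# Ideal backbone geometry (Engh-Huber-style values) used by the toy builder.
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5, omega = 180
)

#' Build a poly-alanine chain at prescribed backbone dihedrals
#'
#' Places N, CA, C, O and CB atoms residue by residue with ideal bond
#' geometry and trans peptide bonds, so that the resulting phi and psi
#' angles equal the prescription exactly (round trip through
#' [compute_dihedrals()] to < 0.1 degree).
#'
#' @param phi,psi numeric vectors of length `n_res` in degrees; `phi[1]` and
#'   `psi[n_res]` are not defined by the construction and are ignored.
#' @return atoms data.frame in the [conformer()] layout (single chain).
#' @export
build_chain <- function(phi, psi) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, n_res >= 2)
  g <- .bb
  atoms <- list()
  # first residue in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C <- CA + c(-g$b_ca_c * cos(th), g$b_ca_c * sin(th), 0)
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N <- place_atom(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA <- place_atom(prevCA, prevC, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- place_atom(prevC, N, CA, g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    CB <- place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, 122.5)
    psi_here <- if (i < n_res) psi[i] else 180
    O <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi_here + 180)
    atoms[[i]] <- data.frame(
      chain = 1L, resno = i, resname = "ALA",
      elety = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = c(N[1], CA[1], C[1], O[1], CB[1]),
      y = c(N[2], CA[2], C[2], O[2], CB[2]),
      z = c(N[3], CA[3], C[3], O[3], CB[3]),
      stringsAsFactors = FALSE
    )
    prevN <- N; prevCA <- CA; prevC <- C
  }
  do.call(rbind, atoms)
}

# Dihedral recipes for the toy conformers.
recipe_angles <- function(recipe, n_res) {
  switch(recipe,
    helix = list(phi = rep(-60, n_res), psi = rep(-45, n_res)),
    strand = list(phi = rep(-120, n_res), psi = rep(130, n_res)),
    coil = {
      # seeded draws from broadly allowed backbone regions
      pick <- sample(c("b", "a"), n_res, replace = TRUE, prob = c(0.6, 0.4))
      phi <- ifelse(pick == "b", stats::rnorm(n_res, -120, 20),
                    stats::rnorm(n_res, -63, 12))
      psi <- ifelse(pick == "b", stats::rnorm(n_res, 135, 20),
                    stats::rnorm(n_res, -43, 10))
      list(phi = phi, psi = psi)
    },
    stop("unknown recipe: ", recipe))
}

#' Specification of a synthetic study
#'
#' Defines the toy ensemble (conformer recipes and aggregation numbers), the
#' generating thermodynamic and interaction parameters, the (T, c) grid and
#' the noise model of the simulated curves. The defaults are the desk-scale
#' study conditions used throughout the test-suite: 4 conformers (2
#' monomers, 1 trimer, 1 tetramer) of 30 residues, 9 curves on a 3x3 grid
#' of temperatures (25, 37, 45 C) and concentrations (2, 5, 10 g/L), about
#' 1% relative Gaussian noise.
#'
#' @param conformers data.frame with columns `m`, `subclass`, `recipe`
#'   (helix/strand/coil).
#' @param n_res residues per chain.
#' @param thermo_true list with `dH`, `dS`, `dCp` (length-N, first entries
#'   0).
#' @param inter_true an [interaction_params()] shared by all conditions.
#' @param temperatures K; concentrations g/L (full grid is simulated).
#' @param ionic_strength mol/L; `pH` of all conditions.
#' @param q q grid of the simulated curves, Angstrom^-1.
#' @param noise list with `a` (relative) and `b` (counting-statistics
#'   coefficient): sigma(q) = a I(q) + b sqrt(I(q)).
#' @param d_h hydration-shell density used in the generation.
#' @param seed master seed for all synthetic randomness.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    conformers = data.frame(
      m = c(1L, 1L, 3L, 4L),
      subclass = c("1A", "1A", "3B", "4E"),
      recipe = c("helix", "strand", "helix", "strand"),
      stringsAsFactors = FALSE),
    n_res = 30,
    thermo_true = list(dH = c(0, 1.5, -8, 2), dS = c(0, 1.2, -4.4, 5.97),
                       dCp = c(0, 0, 0, 0)),
    inter_true = interaction_params(R1 = 10, Z1 = -6, J1 = 30, d = 3,
                                    nu = 2, B = 5e-4),
    temperatures = 273.15 + c(25, 37, 45),
    concentrations = c(2, 5, 10),
    ionic_strength = 0.02, pH = 7.0,
    q = seq(0.022, 0.41, length.out = 120),
    noise = list(a = 0.01, b = 0),
    d_h = 1.0,
    seed = 42) {
  stopifnot(nrow(conformers) >= 2, all(conformers$m >= 1),
            conformers$m[1] == 1, n_res >= 5,
            noise$a > 0 || noise$b > 0)
  structure(list(conformers = conformers, n_res = n_res,
                 thermo_true = thermo_true, inter_true = inter_true,
                 temperatures = temperatures,
                 concentrations = concentrations,
                 ionic_strength = ionic_strength, pH = pH, q = q,
                 noise = noise, d_h = d_h, seed = seed),
            class = "synthetic_spec")
}

#' Generate the toy multimeric ensemble of a synthetic spec
#'
#' Builds each conformer from its dihedral recipe; multimers are rigid
#' copies of the chain placed on a ring (radius 1.2 x chain Rg, enlarged on
#' steric overlap) and rotated evenly. Fully deterministic given the spec
#' seed. Optionally writes PDB files and a TSV manifest.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory for PDBs + `manifest.tsv`.
#' @return list with `ensemble`, `manifest` (data.frame) and `M1` (the
#'   poly-alanine monomer molecular weight, g/mol).
#' @export
make_toy_ensemble <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  confs <- vector("list", nrow(spec$conformers))
  for (i in seq_len(nrow(spec$conformers))) {
    rec <- recipe_angles(spec$conformers$recipe[i], spec$n_res)
    chain <- build_chain(rec$phi, rec$psi)
    m <- spec$conformers$m[i]
    atoms <- multimerize(chain, m, id = sprintf("conf%02d", i))
    confs[[i]] <- conformer(sprintf("conf%02d", i), m,
                            spec$conformers$subclass[i], atoms)
  }
  ens <- ensemble(confs)
  manifest <- data.frame(path = paste0(vapply(confs, `[[`, character(1), "id"),
                                       ".pdb"),
                         m = spec$conformers$m,
                         subclass = spec$conformers$subclass,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(confs)) {
      write_conformer_pdb(confs[[i]], file.path(dir, manifest$path[i]))
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # poly-ALA monomer: residue mass 71.0788 + water
  M1 <- spec$n_res * 71.0788 + 18.015
  list(ensemble = ens, manifest = manifest, M1 = M1)
}

# Place m rigid copies of a chain on a ring, checking steric overlap.
multimerize <- function(chain, m, id, min_dist = 2, max_tries = 6) {
  if (m == 1) return(chain)
  xyz <- as.matrix(chain[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  rg <- radius_of_gyration(xyz)
  radius <- 1.2 * rg
  for (try in seq_len(max_tries)) {
    parts <- lapply(seq_len(m), function(k) {
      ang <- 2 * pi * (k - 1) / m
      p <- rigid_transform(xyz, rot_z(ang),
                           c(radius * cos(ang), radius * sin(ang), 0))
      out <- chain
      out$chain <- k
      out[, c("x", "y", "z")] <- p
      out
    })
    all_atoms <- do.call(rbind, parts)
    ok <- TRUE
    for (k in seq_len(m - 1)) {
      a <- as.matrix(parts[[k]][, c("x", "y", "z")])
      b <- as.matrix(parts[[k + 1]][, c("x", "y", "z")])
      dmin <- min(sqrt(outer(rowSums(a^2), rowSums(b^2), `+`) -
                         2 * a %*% t(b)))
      if (dmin < min_dist) { ok <- FALSE; break }
    }
    if (ok) return(all_atoms)
    radius <- radius * 1.3
  }
  stop("conformer '", id, "': could not place ", m,
       " chains without steric overlap")
}

#' Write a conformer as a PDB file
#'
#' @param conf a [conformer()].
#' @param path output path.
#' @export
write_conformer_pdb <- function(conf, path) {
  at <- conf$atoms
  n <- nrow(at)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   eleno = seq_len(n), resno = at$resno, resid = at$resname,
                   chain = LETTERS[at$chain], elety = at$elety,
                   elesy = at$element, o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Simulate a multi-condition SAXS dataset
#'
#' For every (T, c) of the spec grid: solve the mass-action equilibrium at
#' the generating thermodynamic parameters, build the measured structure
#' factor from the generating interaction parameters, evaluate the forward
#' model on the q grid and add Gaussian noise with
#' sigma(q) = a I(q) + b sqrt(I(q)). The stored sigma is the true noise sd.
#'
#' @param spec a [synthetic_spec()].
#' @param ens the toy [ensemble()] from [make_toy_ensemble()].
#' @param ff a [formfactor_set()] for `ens` on the spec's q grid.
#' @param M1 monomer molecular weight, g/mol.
#' @param noiseless logical: skip the noise (for self-consistency checks).
#' @return list of [saxs_curve()] objects (one per grid point, ordered by
#'   concentration then temperature).
#' @export
simulate_dataset <- function(spec, ens, ff, M1, noiseless = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(ens, "ensemble"))
  th <- thermo_params(spec$thermo_true$dH, spec$thermo_true$dS,
                      spec$thermo_true$dCp, M1 = M1)
  set.seed(spec$seed + 1L)
  curves <- list()
  for (cc in spec$concentrations) {
    for (tt in spec$temperatures) {
      cond <- condition(tt, cc, spec$ionic_strength, spec$pH)
      state <- solve_equilibrium(th, ens, cond)
      n0 <- number_density(cond$c_T, M1)
      eff <- effective_params(spec$inter_true, state, n0, tt,
                              spec$ionic_strength)
      S <- rpa_structure_factor(spec$q, eff)
      beta <- coupling_beta_ell(spec$q, spec$inter_true$R1, state$m_mean,
                                spec$inter_true$nu)
      S_M <- measured_structure_factor(S, beta)
      I <- model_intensity(state, ff, ens, S_M, spec$inter_true$B, n0)
      sigma <- spec$noise$a * abs(I) + spec$noise$b * sqrt(abs(I))
      y <- if (noiseless) I else stats::rnorm(length(I), I, sigma)
      curves[[length(curves) + 1]] <- saxs_curve(
        spec$q, y, sigma, cond,
        label = sprintf("T%.0f_c%g", tt - 273.15, cc))
    }
  }
  curves
}

#' Parameter-recovery experiment
#'
#' The desk-scale acceptance harness: generate the toy ensemble and the
#' simulated dataset from a [synthetic_spec()], fit it blind with
#' [fit_global()] (starting from the center of the parameter box) and
#' compare the recovered thermodynamic parameters and class populations
#' with the generating truth.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [fit_config()]; its default here shares the interaction
#'   parameters across curves, matching the generator.
#' @param bootstrap_R bootstrap replicates for parameter uncertainties
#'   (0 = skip).
#' @return list with the `fit`, a `thermo` comparison table (truth,
#'   estimate, and |error|), an `omega` table per condition (truth vs
#'   fitted), and the per-curve chi2.
#' @export
recovery_experiment <- function(spec = synthetic_spec(),
                                config = fit_config(interactions = "shared",
                                                    seed = spec$seed),
                                bootstrap_R = 0) {
  toy <- make_toy_ensemble(spec)
  ens <- toy$ensemble
  ff <- formfactor_set(ens, spec$q, d_h = spec$d_h)
  curves <- simulate_dataset(spec, ens, ff, toy$M1)
  fit <- fit_global(curves, ens, ff, toy$M1, Z1 = spec$inter_true$Z1,
                    config = config)
  if (bootstrap_R >= 2) fit <- bootstrap_fit(fit, R = bootstrap_R)
  th_true <- thermo_params(spec$thermo_true$dH, spec$thermo_true$dS,
                           spec$thermo_true$dCp, M1 = toy$M1)
  thermo_tab <- data.frame(
    conformer = rep(seq_len(ens$n)[-1], 2),
    param = rep(c("dH", "dS"), each = ens$n - 1),
    truth = c(th_true$dH[-1], th_true$dS[-1]),
    estimate = c(fit$thermo$dH[-1], fit$thermo$dS[-1]))
  thermo_tab$abs_error <- abs(thermo_tab$estimate - thermo_tab$truth)
  omega_rows <- list()
  for (k in seq_along(fit$curves)) {
    cond <- fit$curves[[k]]$condition
    st_true <- solve_equilibrium(th_true, ens, cond)
    st_fit <- fit$states[[k]]
    for (m in names(st_true$omega)) {
      omega_rows[[length(omega_rows) + 1]] <- data.frame(
        curve = k, temperature = cond$temperature, c = cond$c_nominal,
        m = as.integer(m), truth = st_true$omega[[m]],
        estimate = st_fit$omega[[m]])
    }
  }
  omega_tab <- do.call(rbind, omega_rows)
  omega_tab$abs_error <- abs(omega_tab$estimate - omega_tab$truth)
  list(fit = fit, thermo = thermo_tab, omega = omega_tab, chi2 = fit$chi2,
       spec = spec)
}
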