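# Cromer-Mann 4-Gaussian X-ray atomic form factors,
# f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c, in electrons.
.cromer_mann <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

# Displaced solvent volumes (A^3, Fraser-style) and the matching hard radii.
.displaced_volume <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13, P = 5.73,
                       S = 19.86)
.atom_radius <- (3 * .displaced_volume / (4 * pi))^(1 / 3)

#' X-ray atomic form factor
#'
#' Cromer-Mann 4-Gaussian parameterization, in electrons; f(0) equals the
#' atomic number to the accuracy of the published coefficients.
#'
#' @param element element symbol (H, C, N, O, P, S).
#' @param q scattering vector moduli, Angstrom^-1.
#' @return numeric vector of f(q) in electrons.
#' @export
atomic_form_factor <- function(element, q) {
  cm <- .cromer_mann[[toupper(element)]]
  if (is.null(cm)) stop("unknown element: ", element)
  s2 <- (q / (4 * pi))^2
  res <- rep(cm$c, length(q))
  for (i in 1:4) res <- res + cm$a[i] * exp(-cm$b[i] * s2)
  res
}

#' Effective (excess) atomic scattering amplitude
#'
#' Dummy-atom contrast model: f_atom(q) minus the amplitude of the solvent
#' displaced by the atom, rho_s v g(q), with a Gaussian excluded-volume
#' profile g(q) = exp(-v^(2/3) q^2 / (4 pi)). Returned in cm (electron units
#' times the classical electron radius).
#'
#' @param element element symbol.
#' @param q Angstrom^-1.
#' @param displaced_volume solvent volume displaced by the atom, A^3;
#'   defaults to the packaged Fraser-style table.
#' @param solvent_sld solvent scattering length density in Angstrom^-2.
#' @return numeric vector, effective scattering length in cm.
#' @export
excess_amplitude <- function(element, q,
                             displaced_volume = .displaced_volume[[toupper(element)]],
                             solvent_sld = solvent_properties(298.15)$sld) {
  stopifnot(all(q >= 0))
  f_e <- atomic_form_factor(element, q) * .const$r_e_cm
  g <- exp(-displaced_volume^(2 / 3) * q^2 / (4 * pi))
  # solvent_sld [A^-2] * volume [A^3] = amplitude in A -> cm
  f_e - solvent_sld * displaced_volume * g * 1e-8
}

#' Hydration-shell dummy scatterers
#'
#' Samples the solvent-accessible surface of a conformer with points in a
#' shell of the given thickness and assigns each an excess scattering length
#' proportional to (d_h - 1), d_h being the mass density of first-shell
#' water relative to bulk. Points falling inside the shell of another atom
#' closer to the protein interior are rejected, so fully buried atoms
#' contribute nothing. To keep the downstream Debye sums tractable the kept
#' points are pooled per residue (centroid position, summed amplitude).
#'
#' @param conf a [conformer()].
#' @param d_h relative shell density, in [0.95, 1.05]; d_h = 1 gives an
#'   exactly empty contribution.
#' @param shell_thickness shell width in Angstrom (default 3).
#' @param solvent_sld bulk solvent SLD in Angstrom^-2.
#' @param n_points sphere sample points per atom (default 30).
#' @param pool pool kept points per residue (default TRUE).
#' @return data.frame with columns `x`, `y`, `z`, `b` (excess scattering
#'   length in cm); zero rows when d_h = 1.
#' @export
hydration_shell <- function(conf, d_h, shell_thickness = 3,
                            solvent_sld = solvent_properties(298.15)$sld,
                            n_points = 30, pool = TRUE) {
  stopifnot(inherits(conf, "conformer"), shell_thickness > 0)
  if (d_h < 0.95 || d_h > 1.05) {
    stop("d_h outside the supported range [0.95, 1.05]")
  }
  if (d_h == 1) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      b = numeric(0)))
  }
  at <- conf$atoms[conf$atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .atom_radius[at$element]
  rad[is.na(rad)] <- .atom_radius[["C"]]
  sphere <- fibonacci_sphere(n_points)
  half <- shell_thickness / 2
  pts <- list(); vols <- list(); resid <- list()
  for (i in seq_len(nrow(xyz))) {
    p <- sweep(sphere * (rad[i] + half), 2, xyz[i, ], "+")
    # reject points inside the shell interior of any other atom
    keep <- rep(TRUE, nrow(p))
    for (jblk in seq_len(nrow(xyz))) {
      if (jblk == i) next
      dd <- sqrt(colSums((t(p) - xyz[jblk, ])^2))
      keep <- keep & dd > (rad[jblk] + half)
      if (!any(keep)) break
    }
    if (!any(keep)) next
    v_shell <- (4 / 3) * pi * ((rad[i] + shell_thickness)^3 - rad[i]^3)
    pts[[length(pts) + 1]] <- p[keep, , drop = FALSE]
    vols[[length(vols) + 1]] <- rep(v_shell / n_points, sum(keep))
    resid[[length(resid) + 1]] <- rep(paste(at$chain[i], at$resno[i]),
                                      sum(keep))
  }
  if (length(pts) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      b = numeric(0)))
  }
  p <- do.call(rbind, pts)
  v <- unlist(vols)
  b <- (d_h - 1) * solvent_sld * v * 1e-8  # cm
  out <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3], b = b,
                    res = unlist(resid), stringsAsFactors = FALSE)
  if (pool) {
    agg <- split(out, out$res)
    out <- do.call(rbind, lapply(agg, function(g) {
      data.frame(x = sum(g$x * abs(g$b)) / sum(abs(g$b)),
                 y = sum(g$y * abs(g$b)) / sum(abs(g$b)),
                 z = sum(g$z * abs(g$b)) / sum(abs(g$b)),
                 b = sum(g$b))
    }))
    rownames(out) <- NULL
  } else {
    out$res <- NULL
  }
  out
}

# Near-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# sinc(x) = sin(x)/x with a series fallback below 1e-4 to avoid 0/0.
sinc <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 6
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

#' Orientationally averaged squared form factor of a conformer
#'
#' Debye double sum over the effective scatterers (protein atoms with
#' excess amplitudes plus hydration-shell dummies):
#' <|F(q)|^2> = sum_ab f_a(q) f_b(q) sinc(q r_ab), in cm^2 per multimer.
#' Multiplied by a number density in cm^-3 this gives an absolute-scale
#' intensity in cm^-1.
#'
#' @param conf a [conformer()].
#' @param q q grid, Angstrom^-1, positive.
#' @param d_h relative hydration-shell density (1 = no shell).
#' @param solvent_sld solvent SLD in Angstrom^-2.
#' @param granularity "atomic" or "residue"; residue-level pooling places the
#'   summed excess amplitude of each residue at its heavy-atom centroid (a
#'   documented speed approximation good to a few percent at low q).
#' @return numeric vector <|F(q)|^2> in cm^2.
#' @export
squared_form_factor <- function(conf, q, d_h = 1,
                                solvent_sld = solvent_properties(298.15)$sld,
                                granularity = c("atomic", "residue")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(conf, "conformer"), all(q > 0))
  at <- conf$atoms
  known <- at$element %in% names(.cromer_mann)
  if (!all(known)) {
    stop("unknown element(s): ", paste(unique(at$element[!known]), collapse = ", "))
  }
  n_q <- length(q)
  # per-element excess amplitudes (cm), n_q x n_elements
  elems <- unique(at$element)
  amp_e <- vapply(elems, function(e) excess_amplitude(e, q, solvent_sld = solvent_sld),
                  numeric(n_q))
  amp_e <- matrix(amp_e, nrow = n_q)
  if (granularity == "atomic") {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    famp <- amp_e[, match(at$element, elems), drop = FALSE]  # n_q x n_atoms
  } else {
    key <- paste(at$chain, at$resno)
    groups <- split(seq_len(nrow(at)), key)
    xyz <- t(vapply(groups, function(ix) {
      heavy <- ix[at$element[ix] != "H"]
      if (length(heavy) == 0) heavy <- ix
      colMeans(as.matrix(at[heavy, c("x", "y", "z")]))
    }, numeric(3)))
    famp <- vapply(groups, function(ix) {
      rowSums(amp_e[, match(at$element[ix], elems), drop = FALSE])
    }, numeric(n_q))
    famp <- matrix(famp, nrow = n_q)
  }
  shell <- hydration_shell(conf, d_h, solvent_sld = solvent_sld)
  if (nrow(shell) > 0) {
    xyz <- rbind(xyz, as.matrix(shell[, c("x", "y", "z")]))
    famp <- cbind(famp, matrix(rep(shell$b, each = n_q), nrow = n_q))
  }
  if (ncol(famp) == 0) stop("empty scatterer set")
  debye_sum(xyz, famp, q)
}

# Core Debye sum: xyz n x 3, famp n_q x n (amplitude of scatterer j at q_k).
debye_sum <- function(xyz, famp, q) {
  n <- nrow(xyz)
  if (n == 1) return(as.numeric(famp^2))
  d <- as.matrix(stats::dist(xyz))
  iu <- which(upper.tri(d))
  dv <- d[iu]
  rowi <- row(d)[iu]
  coli <- col(d)[iu]
  out <- numeric(length(q))
  for (k in seq_along(q)) {
    f <- famp[k, ]
    out[k] <- sum(f^2) + 2 * sum(f[rowi] * f[coli] * sinc(q[k] * dv))
  }
  out
}

#' Precompute form factors for a whole ensemble
#'
#' Evaluates [squared_form_factor()] for every conformer on a common q grid
#' and returns them as a matrix, together with the settings used. This is
#' the cached quantity the fitting loop consumes.
#'
#' @param ens an [ensemble()].
#' @param q q grid, Angstrom^-1.
#' @param d_h relative hydration-shell density.
#' @param solvent_sld solvent SLD, Angstrom^-2.
#' @param granularity passed to [squared_form_factor()].
#' @return object of class `formfactor_set`: list with `q`, `F2` (n_q x N
#'   matrix, cm^2), `d_h`, `solvent_sld`, `granularity`, `ids`.
#' @export
formfactor_set <- function(ens, q, d_h = 1,
                           solvent_sld = solvent_properties(298.15)$sld,
                           granularity = "atomic") {
  stopifnot(inherits(ens, "ensemble"))
  F2 <- vapply(ens$conformers, squared_form_factor, numeric(length(q)),
               q = q, d_h = d_h, solvent_sld = solvent_sld,
               granularity = granularity)
  structure(list(q = q, F2 = matrix(F2, nrow = length(q)), d_h = d_h,
                 solvent_sld = solvent_sld, granularity = granularity,
                 ids = vapply(ens$conformers, `[[`, character(1), "id")),
            class = "formfactor_set")
}

#' @export
print.formfactor_set <- function(x, ...) {
  cat(sprintf("<formfactor_set>  %d conformers, %d q points, d_h = %.3f (%s)\n",
              ncol(x$F2), length(x$q), x$d_h, x$granularity))
  invisible(x)
}
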