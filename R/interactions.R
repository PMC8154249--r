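#' Monomer-level interaction parameters
#'
#' Parameters of the protein-protein pair potential referred to the monomer:
#' average radius R1, net charge Z1, attractive contact energy J1, attraction
#' range d, ellipsoid anisometry nu (ratio of the unique to the two equal
#' semiaxes) and the flat incoherent background B.
#'
#' @param R1 Angstrom, > 0.
#' @param Z1 elementary charges (signed).
#' @param J1 kJ/mol, >= 0 (magnitude of the attraction; the sign is applied
#'   internally).
#' @param d Angstrom, > 0.
#' @param nu dimensionless, > 0.
#' @param B cm^-1.
#' @return object of class `interaction_params`.
#' @export
interaction_params <- function(R1, Z1, J1, d, nu = 1, B = 0) {
  stopifnot(R1 > 0, d > 0, nu > 0, J1 >= 0)
  structure(list(R1 = R1, Z1 = Z1, J1 = J1, d = d, nu = nu, B = B),
            class = "interaction_params")
}

#' Effective structure-factor parameters of the multimer mixture
#'
#' The interacting solution is described by a single "effective particle"
#' whose parameters scale with the average aggregation number:
#' n = n0 <1/m>, Z = Z1 <m>, J = J1 <m>^(2/3), R = R1 <m>^(1/3). The charge
#' scales with the number of chains, the contact attraction with the surface
#' and the radius with the cube root of the volume.
#'
#' @param base an [interaction_params()].
#' @param state a `population_state` (for `<m>` and `<1/m>`).
#' @param n0 total nominal monomer number density, cm^-3.
#' @param temperature K.
#' @param ionic_strength mol/L.
#' @param eps_r relative dielectric constant; default pure water at
#'   `temperature`.
#' @return list with `n` (cm^-3), `R` (A), `Z`, `J` (kJ/mol), `kappa_D`
#'   (A^-1), `eps_r`, `eta`, `d`, `nu`, `temperature`.
#' @export
effective_params <- function(base, state, n0, temperature,
                             ionic_strength = 0,
                             eps_r = solvent_properties(temperature)$eps_r) {
  stopifnot(inherits(base, "interaction_params"),
            inherits(state, "population_state"))
  m_mean <- state$m_mean
  n <- n0 * state$inv_m_mean
  R <- base$R1 * m_mean^(1 / 3)
  eta <- n * (4 / 3) * pi * R^3 * 1e-24  # R in A, n in cm^-3
  if (eta >= 0.5) {
    stop(sprintf("unphysical volume fraction eta = %.3f >= 0.5", eta))
  }
  list(n = n, R = R, Z = base$Z1 * m_mean, J = base$J1 * m_mean^(2 / 3),
       kappa_D = debye_kappa(ionic_strength, temperature, eps_r),
       eps_r = eps_r, eta = eta, d = base$d, nu = base$nu,
       temperature = temperature)
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic solution for hard spheres of radius R at number density n
#' (volume fraction eta). S0(0) equals the PY compressibility limit
#' (1-eta)^4/(1+2 eta)^2 and S0 -> 1 at large q.
#'
#' @param q Angstrom^-1.
#' @param R sphere radius, Angstrom.
#' @param n number density, cm^-3.
#' @return S0(q).
#' @export
py_structure_factor <- function(q, R, n) {
  eta <- n * (4 / 3) * pi * R^3 * 1e-24
  if (eta >= 0.5) stop("PY solution requires eta < 0.5")
  if (eta <= 0) return(rep(1, length(q)))
  1 / (1 - n_ctilde_py(q, R, eta))
}

# n * FT of the PY direct correlation function for hard spheres (diameter
# 2R), the standard Ashcroft-Lekner closed form with series limits at small
# x = 2 q R.
n_ctilde_py <- function(q, R, eta) {
  x <- q * 2 * R
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  ga <- eta * (1 + 2 * eta)^2 / (2 * (1 - eta)^4)
  f1 <- f2 <- f3 <- numeric(length(x))
  small <- x < 1e-3
  xs <- x[small]
  f1[small] <- 1 / 3 - xs^2 / 30
  f2[small] <- 1 / 4 - xs^2 / 36
  f3[small] <- 1 / 6 - xs^2 / 48
  xl <- x[!small]
  sx <- sin(xl); cx <- cos(xl)
  f1[!small] <- (sx - xl * cx) / xl^3
  f2[!small] <- (2 * xl * sx + (2 - xl^2) * cx - 2) / xl^4
  f3[!small] <- (-xl^4 * cx + 4 * ((3 * xl^2 - 6) * cx +
                                     (xl^3 - 6 * xl) * sx + 6)) / xl^6
  -24 * eta * (al * f1 + be * f2 + ga * f3)
}

# 3-D Fourier transform of a truncated Yukawa K exp(-kappa r)/r for r > rc,
# zero inside: u~(q) = (4 pi K / q) Im[ exp(-s rc)/s ], s = kappa - i q.
# Returns A^3 (for K in units of k_B T * Angstrom).
yukawa_ft <- function(q, K, kappa, rc) {
  s <- complex(real = kappa, imaginary = -q)
  4 * pi * K / q * Im(exp(-s * rc) / s)
}

# Perturbing pair potential in k_B T units for r > 2R: DLVO screened-Coulomb
# repulsion plus an attractive Yukawa with contact value -J.
# Returns the two Yukawa prefactors (K, in k_B T * Angstrom) and decays.
pair_potential_terms <- function(eff) {
  kT_kJmol <- .const$R_gas * eff$temperature / 1000
  lb <- bjerrum_length(eff$temperature, eff$eps_r)
  sig <- 2 * eff$R
  K_C <- eff$Z^2 * lb * exp(eff$kappa_D * sig) / (1 + eff$kappa_D * eff$R)^2
  K_A <- -(eff$J / kT_kJmol) * sig * exp(sig / eff$d)
  list(K_C = K_C, kappa_C = eff$kappa_D, K_A = K_A, kappa_A = 1 / eff$d,
       rc = sig)
}

#' RPA-perturbed structure factor
#'
#' Random-phase-approximation correction of the Percus-Yevick reference:
#' S(q)^-1 = S0(q)^-1 + n u~(q)/(k_B T), where u~ is the analytic Fourier
#' transform of the pair potential outside the hard core at 2R: a DLVO
#' screened-Coulomb Yukawa (strength from Z, eps_r, kappa_D, with the
#' (1 + kappa_D R)^-2 denominator) plus an attractive Yukawa with contact
#' value -J and range d.
#'
#' @param q Angstrom^-1.
#' @param eff effective parameters from [effective_params()].
#' @return S(q); an error is raised if the RPA breaks down (S <= 0).
#' @export
rpa_structure_factor <- function(q, eff) {
  s0 <- py_structure_factor(q, eff$R, eff$n)
  pt <- pair_potential_terms(eff)
  u_t <- yukawa_ft(q, pt$K_C, pt$kappa_C, pt$rc) +
    yukawa_ft(q, pt$K_A, pt$kappa_A, pt$rc)
  n_A3 <- eff$n * 1e-24
  s_inv <- 1 / s0 + n_A3 * u_t
  if (any(s_inv <= 0)) {
    stop(sprintf(paste0("RPA breakdown (S(q) <= 0) at q = %.4g with Z = %.3g,",
                        " J = %.3g kJ/mol, R = %.3g A, eta = %.3g"),
                 q[which(s_inv <= 0)[1]], eff$Z, eff$J, eff$R, eff$eta))
  }
  1 / s_inv
}

#' Ellipsoidal decoupling (coupling) function
#'
#' beta_ell(q) = |<F_ell>|^2 / <|F_ell|^2> for a biaxial ellipsoid of
#' anisometry nu whose volume equals (4/3) pi R1^3 <m>, evaluated with the
#' sphere-amplitude kernel at the orientation-dependent effective radius
#' r(theta) = b sqrt(sin^2 theta + nu^2 cos^2 theta), b = R1 (<m>/nu)^(1/3).
#' Orientational averages use fixed-order Gauss-Legendre quadrature in
#' cos(theta). beta = 1 identically for a sphere (nu = 1) and at q = 0.
#'
#' @param q Angstrom^-1.
#' @param R1 monomer radius, Angstrom.
#' @param m_mean average aggregation number `<m>`.
#' @param nu anisometry (> 0).
#' @param n_nodes quadrature order (default 128).
#' @return beta(q) in \[0, 1\].
#' @export
coupling_beta_ell <- function(q, R1, m_mean, nu, n_nodes = 128) {
  stopifnot(nu > 0, R1 > 0, m_mean > 0)
  if (nu == 1) return(rep(1, length(q)))
  b <- R1 * (m_mean / nu)^(1 / 3)
  gl <- gauss_legendre_cached(n_nodes)
  mu <- gl$x; wt <- gl$w
  r_th <- b * sqrt(1 - mu^2 + nu^2 * mu^2)
  A <- sphere_amp(outer(q, r_th))  # n_q x nodes
  wsum <- sum(wt)
  num <- (A %*% wt / wsum)^2
  den <- (A^2) %*% wt / wsum
  beta <- as.numeric(num / den)
  pmin(pmax(beta, 0), 1)
}

# Normalized sphere scattering amplitude 3 (sin x - x cos x)/x^3
# (dimension-preserving; series limit below x = 1e-4).
sphere_amp <- function(x) {
  out <- 3 * (sin(x) - x * cos(x)) / (x * x * x)
  small <- abs(x) < 1e-4
  if (any(small)) out[small] <- 1 - x[small]^2 / 10
  out
}

#' Measured structure factor
#'
#' Decoupling approximation for anisometric or polydisperse particles:
#' S_M(q) = 1 + beta(q) (S(q) - 1).
#'
#' @param S structure factor values.
#' @param beta coupling function values on the same grid.
#' @return S_M(q).
#' @export
measured_structure_factor <- function(S, beta) {
  stopifnot(length(S) == length(beta))
  1 + beta * (S - 1)
}

#' Pair interaction potential profile
#'
#' The two-Yukawa potential used in [rpa_structure_factor()], evaluated on a
#' radial grid outside the hard core and reported in k_B T units:
#' u(r) = u_C(r) + u_A(r), with u_A(2R) = -J/k_B T at contact.
#'
#' @param r radial grid in Angstrom (values inside the core 2R get NA).
#' @param eff effective parameters from [effective_params()].
#' @return data.frame with columns `r`, `u`, `u_C`, `u_A` (k_B T units).
#' @export
pair_potential_profile <- function(r, eff) {
  pt <- pair_potential_terms(eff)
  u_C <- ifelse(r >= pt$rc, pt$K_C * exp(-pt$kappa_C * r) / r, NA_real_)
  u_A <- ifelse(r >= pt$rc, pt$K_A * exp(-pt$kappa_A * r) / r, NA_real_)
  data.frame(r = r, u = u_C + u_A, u_C = u_C, u_A = u_A)
}


# Gauss-Legendre nodes on [0, 1], memoized (pracma recomputes them via an
# eigendecomposition on every call).
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .gl_cache[[key]]
}
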