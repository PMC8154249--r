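#' Thermodynamic parameters of an ensemble
#'
#' Dimensionless standard-state differences of every conformer i = 2..N
#' relative to conformer 1 (which must be a monomer and has all three values
#' identically zero): `dH` = Delta H / (R T0), `dS` = Delta S / R,
#' `dCp` = Delta Cp / R, with T0 = 298.15 K. `M1` is the monomer molecular
#' weight in g/mol, needed to convert w/v concentration to molarity.
#'
#' @param dH,dS,dCp numeric vectors of length N (first entries must be 0) or
#'   length N-1 (values for conformers 2..N).
#' @param M1 monomer molecular weight (g/mol).
#' @param n number of conformers N (required when length N-1 vectors are
#'   given).
#' @return object of class `thermo_params`.
#' @export
thermo_params <- function(dH, dS, dCp = NULL, M1, n = NULL) {
  len <- unique(c(length(dH), length(dS), if (!is.null(dCp)) length(dCp)))
  if (length(len) != 1) stop("dH, dS, dCp must have equal length")
  if (is.null(n)) n <- len
  if (len == n - 1) {
    dH <- c(0, dH); dS <- c(0, dS)
    dCp <- if (is.null(dCp)) numeric(n) else c(0, dCp)
  } else if (len == n) {
    if (is.null(dCp)) dCp <- numeric(n)
    if (dH[1] != 0 || dS[1] != 0 || dCp[1] != 0) {
      stop("conformer 1 is the reference: dH[1], dS[1], dCp[1] must be 0")
    }
  } else stop("parameter vectors must have length n or n-1")
  stopifnot(all(is.finite(dH)), all(is.finite(dS)), all(is.finite(dCp)),
            M1 > 0)
  structure(list(dH = dH, dS = dS, dCp = dCp, M1 = M1, T0 = 298.15, n = n),
            class = "thermo_params")
}

#' Dimensionless standard free-energy change at temperature T
#'
#' Gibbs-Helmholtz form with temperature-independent Delta Cp:
#' Delta G(T)/(R T) = dH (T0/T) - dS + dCp [(T - T0)/T - ln(T/T0)].
#' At T = T0 this reduces to dH - dS and the heat-capacity term drops out.
#'
#' @param params a [thermo_params()].
#' @param temperature absolute temperature in K.
#' @return numeric vector of Delta G_(i,1)(T)/(R T), one entry per conformer.
#' @export
delta_g <- function(params, temperature) {
  stopifnot(inherits(params, "thermo_params"), temperature > 0)
  T0 <- params$T0
  tt <- temperature
  params$dH * (T0 / tt) - params$dS +
    params$dCp * ((tt - T0) / tt - log(tt / T0))
}

#' Solve the mass-action equilibrium among all conformers
#'
#' At equilibrium the per-chain chemical potentials of all conformers are
#' equal. With the molarity of the i-multimer C_i = (c/M1)(w_i/m_i), the
#' population weight of conformer i follows
#' w_i = A_i w_1^(m_i),  A_i = m_i (c/M1)^(m_i - 1) exp(-m_i dG_i),
#' where dG_i = Delta G_(i,1)(T)/(R T). The normalization sum_i w_i = 1 is a
#' polynomial of degree gamma = max(m_i) in w_1 with a unique root in (0, 1],
#' found by bracketed Brent iteration.
#'
#' @param params a [thermo_params()].
#' @param ens an [ensemble()] whose first conformer is a monomer.
#' @param cond a [condition()]; its thermal-expansion-corrected concentration
#'   `c_T` enters the molar scale.
#' @param tol tolerance on |sum w - 1| (default 1e-12).
#' @return object of class `population_state` with fields `w`, `omega`
#'   (named by class m), `W` (list per class), `m_mean`, `inv_m_mean`,
#'   `temperature`, `c_T`.
#' @export
solve_equilibrium <- function(params, ens, cond, tol = 1e-12) {
  stopifnot(inherits(params, "thermo_params"), inherits(ens, "ensemble"),
            inherits(cond, "sample_condition"))
  if (params$n != ens$n) stop("thermo_params length does not match ensemble")
  if (ens$class_of[1] != 1) {
    stop("the first (reference) conformer must be a monomer (m = 1)")
  }
  m_i <- ens$class_of
  dg <- delta_g(params, cond$temperature)
  # clip extreme free energies to avoid overflow in exp()
  clip <- abs(dg) > 500
  if (any(clip)) {
    warning("clipped ", sum(clip), " |dG|/RT values at 500")
    dg <- pmin(pmax(dg, -500), 500)
  }
  cm <- cond$c_T / params$M1  # molar scale, mol/L
  logA <- log(m_i) + (m_i - 1) * log(cm) - m_i * dg
  f <- function(w1) sum(exp(logA + m_i * log(w1))) - 1
  # f is strictly increasing on (0, 1] with f(0+) = -1 and f(1) >= 0
  # (A_1 = 1 guarantees the sign change); bracket and solve by Brent
  if (f(1) < 0) stop("no root in (0, 1]: broken coefficients")  # unreachable
  root <- stats::uniroot(f, c(1e-300, 1), tol = .Machine$double.eps^0.75)
  w1 <- root$root
  w <- exp(logA + m_i * log(w1))
  w <- w / sum(w)  # remove residual root-finder error
  if (abs(sum(w) - 1) > tol) stop("equilibrium normalization failed")
  population_state(w, ens, cond$temperature, cond$c_T)
}

# Build a population_state from a weight vector (assumed normalized).
population_state <- function(w, ens, temperature = NA, c_T = NA) {
  ms <- ens$classes$m
  omega <- vapply(seq_along(ms), function(k) sum(w[ens$members[[k]]]),
                  numeric(1))
  names(omega) <- as.character(ms)
  W <- lapply(seq_along(ms), function(k) {
    wk <- w[ens$members[[k]]]
    if (sum(wk) > 0) wk / sum(wk) else rep(1 / length(wk), length(wk))
  })
  names(W) <- as.character(ms)
  structure(list(
    w = w, omega = omega, W = W,
    m_mean = sum(w * ens$class_of),
    inv_m_mean = sum(w / ens$class_of),
    temperature = temperature, c_T = c_T
  ), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state>  T = %.2f K, c(T) = %.3f g/L\n",
              x$temperature, x$c_T))
  cat("  omega:", paste(sprintf("m=%s: %.4f", names(x$omega), x$omega),
                        collapse = ", "), "\n")
  cat(sprintf("  <m> = %.4f, <1/m> = %.4f\n", x$m_mean, x$inv_m_mean))
  invisible(x)
}

#' Class-level moments of a population state
#'
#' Returns the class weights omega_m, the within-class weights W_m, and the
#' monomer-weighted averages <m> = sum_i w_i m_i and <1/m> = sum_i w_i / m_i
#' used for the effective structure-factor parameters.
#'
#' @param state a `population_state`.
#' @return list with `omega`, `W`, `m_mean`, `inv_m_mean`.
#' @export
class_moments <- function(state) {
  stopifnot(inherits(state, "population_state"))
  list(omega = state$omega, W = state$W, m_mean = state$m_mean,
       inv_m_mean = state$inv_m_mean)
}

#' Nominal monomer number density
#'
#' Converts w/v concentration (g/L) and monomer molecular weight (g/mol) to
#' the total nominal number density of monomer chains in cm^-3.
#'
#' @param c_gL concentration in g/L.
#' @param M1 monomer molecular weight in g/mol.
#' @return number density in cm^-3.
#' @export
number_density <- function(c_gL, M1) {
  c_gL / M1 * .const$N_A * 1e-3
}
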