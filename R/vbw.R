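#' Moments of a Dirichlet distribution
#'
#' Mean and covariance of Dir(alpha): mean_j = alpha_j / alpha_0 and
#' Cov_jk = (delta_jk mean_j - mean_j mean_k) / (alpha_0 + 1), with
#' alpha_0 = sum(alpha). With the unbiased prior alpha_j = 1/2 on N
#' components the mean is 1/N and the variance 2 N^-2 (N-1)/(N+2).
#'
#' @param alpha positive concentration parameters.
#' @return list with `mean` and `cov`.
#' @export
dirichlet_moments <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  a0 <- sum(alpha)
  mu <- alpha / a0
  cov <- (diag(mu, length(mu)) - outer(mu, mu)) / (a0 + 1)
  list(mean = mu, cov = cov)
}

# KL divergence KL( Dir(alpha) || Dir(beta) ) — the digamma-bearing term of
# the variational functional. beta defaults to the unbiased 1/2 prior.
dirichlet_kl <- function(alpha, beta = rep(0.5, length(alpha))) {
  if (length(alpha) < 2) return(0)  # degenerate one-component simplex
  a0 <- sum(alpha); b0 <- sum(beta)
  lgamma(a0) - sum(lgamma(alpha)) - lgamma(b0) + sum(lgamma(beta)) +
    sum((alpha - beta) * (digamma(alpha) - digamma(a0)))
}

#' Curve-specific Dirichlet state
#'
#' Per class of conformers m the posterior Dirichlet is parameterized as
#' alpha_m = alpha_m0 * <W_m>, so its mean is pinned to the thermodynamic
#' within-class weights and the curve-specific concentration alpha_m0 sets
#' its sharpness.
#'
#' @param alpha0 named numeric vector of concentrations, one per class
#'   (names = class m as character).
#' @param state a `population_state` providing `<W_m>`.
#' @return object of class `dirichlet_state`: list of alpha vectors per
#'   class.
#' @export
dirichlet_state <- function(alpha0, state) {
  stopifnot(inherits(state, "population_state"))
  if (any(alpha0 <= 0)) stop("alpha0 must be positive")
  cls <- names(state$W)
  if (!all(cls %in% names(alpha0))) stop("alpha0 must be named by class m")
  alpha <- lapply(cls, function(m) alpha0[[m]] * state$W[[m]])
  names(alpha) <- cls
  structure(list(alpha = alpha, alpha0 = alpha0[cls]),
            class = "dirichlet_state")
}

#' Model scattering intensity (absolute scale)
#'
#' The forward model for the macroscopic differential scattering cross
#' section of the multimeric mixture:
#' I(q) = n0 \[sum_m (omega_m / m) sum_j W_mj <|F_mj(q)|^2>\] S_M(q) + B,
#' i.e. every multimer enters with its number concentration
#' n0 omega_m W_mj / m, and a flat incoherent background B.
#'
#' @param state `population_state` giving omega_m and W_m.
#' @param ff a [formfactor_set()] evaluated on the curve's q grid (or an
#'   n_q x N matrix of form factors in cm^2).
#' @param ens the [ensemble()] the form factors refer to.
#' @param S_M measured structure factor on the same grid (scalar 1 allowed).
#' @param B flat background, cm^-1.
#' @param n0 nominal monomer number density, cm^-3.
#' @return intensity in cm^-1.
#' @export
model_intensity <- function(state, ff, ens, S_M = 1, B = 0, n0) {
  G <- intensity_basis(state, ff, ens, S_M, n0)
  wflat <- flat_within_class_weights(state, ens)
  I <- as.numeric(G %*% wflat) + B
  if (any(I < 0)) stop("negative model intensity: broken structure factor")
  I
}

# n_q x N basis matrix G with G[, i] = n0 (omega_{m_i}/m_i) F2_i S_M, so that
# I = G %*% W_flat + B with W_flat the within-class weights.
intensity_basis <- function(state, ff, ens, S_M, n0) {
  F2 <- if (inherits(ff, "formfactor_set")) ff$F2 else ff
  if (ncol(F2) != ens$n) stop("form-factor set does not match ensemble")
  m_i <- ens$class_of
  om <- state$omega[as.character(m_i)]
  F2 * rep(n0 * om / m_i, each = nrow(F2)) * S_M
}

flat_within_class_weights <- function(state, ens) {
  wflat <- numeric(ens$n)
  for (m in names(state$W)) wflat[ens$members[[m]]] <- state$W[[m]]
  wflat
}

#' Reduced chi-square of a model curve
#'
#' Mean squared standardized residual over the N_cq points of the curve
#' (per-point normalization).
#'
#' @param curve a [saxs_curve()].
#' @param model model intensities on the curve's grid, cm^-1.
#' @return chi-square per point.
#' @export
reduced_chi2 <- function(curve, model) {
  stopifnot(inherits(curve, "saxs_curve"), length(model) == length(curve$q))
  mean(((curve$intensity - model) / curve$sigma)^2)
}

#' Single-curve variational functional
#'
#' The negative evidence lower bound of one curve under the factorized
#' Dirichlet posterior:
#' L = (N_cq/2) E\[chi2\] + sum_m KL( Dir(alpha_m0 <W_m>) || Dir(1/2) ).
#' Because the model intensity is linear in the within-class weights, the
#' posterior expectation of chi2 is the chi2 at the thermodynamic means plus
#' a covariance correction assembled from the Dirichlet pair factors
#' E\[W_j W_k\] = (alpha_m0 <W_j><W_k> + delta_jk <W_j>)/(alpha_m0 + 1);
#' the KL term carries the digamma functions.
#'
#' @param curve a [saxs_curve()].
#' @param dirichlet a [dirichlet_state()] for this curve.
#' @param state the `population_state` at the curve's condition.
#' @param ff form factors on the curve's grid ([formfactor_set()] or
#'   matrix).
#' @param ens the [ensemble()].
#' @param S_M measured structure factor on the grid.
#' @param B flat background, cm^-1.
#' @param n0 monomer number density, cm^-3.
#' @return list with `L`, `chi2` (at the means), `E_chi2`, `kl`, `model`.
#' @export
functional_L <- function(curve, dirichlet, state, ff, ens, S_M = 1, B = 0,
                         n0) {
  stopifnot(inherits(dirichlet, "dirichlet_state"))
  G <- intensity_basis(state, ff, ens, S_M, n0)
  wflat <- flat_within_class_weights(state, ens)
  model <- as.numeric(G %*% wflat) + B
  chi2 <- reduced_chi2(curve, model)
  n_q <- length(curve$q)
  # covariance correction: sum_k Var[I_k]/sigma_k^2, classes independent
  var_term <- 0
  kl <- 0
  for (m in names(state$W)) {
    idx <- ens$members[[m]]
    if (length(idx) < 2) next
    mu <- state$W[[m]]
    a0 <- dirichlet$alpha0[[m]]
    Gm <- G[, idx, drop = FALSE]
    s1 <- as.numeric((Gm^2) %*% mu)       # sum_j G^2 mu_j
    s2 <- as.numeric(Gm %*% mu)^2        # (sum_j G mu_j)^2
    var_term <- var_term + sum((s1 - s2) / curve$sigma^2) / (a0 + 1)
    kl <- kl + dirichlet_kl(dirichlet$alpha[[m]])
  }
  e_chi2 <- chi2 + var_term / n_q
  list(L = n_q / 2 * e_chi2 + kl, chi2 = chi2, E_chi2 = e_chi2, kl = kl,
       model = model)
}

# Profile the optimal alpha_m0 of every class for one curve: the
# alpha0-dependent part of L separates per class into
# D_m/(alpha0 + 1) + KL_m(alpha0), minimized in log alpha0.
profile_alpha0 <- function(curve, state, G, ens) {
  cls <- names(state$W)
  alpha0 <- stats::setNames(rep(1, length(cls)), cls)
  for (m in cls) {
    idx <- ens$members[[m]]
    if (length(idx) < 2) { alpha0[[m]] <- length(idx) / 2; next }
    mu <- state$W[[m]]
    Gm <- G[, idx, drop = FALSE]
    s1 <- as.numeric((Gm^2) %*% mu)
    s2 <- as.numeric(Gm %*% mu)^2
    D <- 0.5 * sum((s1 - s2) / curve$sigma^2)
    obj <- function(la) {
      a0 <- exp(la)
      D / (a0 + 1) + dirichlet_kl(a0 * mu)
    }
    opt <- stats::optimize(obj, c(log(1e-3), log(1e8)))
    alpha0[[m]] <- exp(opt$minimum)
  }
  alpha0
}

#' Multi-curve functional
#'
#' Lambda = sum_c L_c with the thermodynamic parameters shared across curves
#' and the Dirichlet concentrations (and interaction parameters) allowed to
#' be curve-specific. `pieces` is a list with one entry per curve, each a
#' list of arguments for [functional_L()] minus the curve itself.
#'
#' @param curves list of [saxs_curve()].
#' @param pieces list parallel to `curves`; each element holds `dirichlet`,
#'   `state`, `ff`, `ens`, `S_M`, `B`, `n0`.
#' @return list with `Lambda` and per-curve `L` values.
#' @export
overall_functional <- function(curves, pieces) {
  stopifnot(length(curves) == length(pieces))
  Ls <- vapply(seq_along(curves), function(i) {
    p <- pieces[[i]]
    functional_L(curves[[i]], p$dirichlet, p$state, p$ff, p$ens,
                 S_M = p$S_M, B = p$B, n0 = p$n0)$L
  }, numeric(1))
  list(Lambda = sum(Ls), L = Ls)
}

#' Adjacency regularization of per-curve parameters
#'
#' V = sum_k sum_(adjacent pairs) ((X_k,c - X_k,c')/scale_k)^2 over the
#' single-curve interaction parameters k in (J1, d, R1, nu). Curves are
#' neighbors when consecutive after lexicographic ordering by
#' (concentration, temperature), i.e. close chemical-physical conditions.
#'
#' @param params data.frame with one row per curve (already in condition
#'   order) and columns `J1`, `d`, `R1`, `nu`.
#' @param scales named numeric scales per parameter; defaults to the
#'   mid-range of the default fit bounds.
#' @return the scalar V.
#' @export
regularization_V <- function(params, scales = NULL) {
  keys <- c("J1", "d", "R1", "nu")
  stopifnot(all(keys %in% names(params)))
  if (is.null(scales)) {
    bb <- default_fit_bounds()
    scales <- vapply(keys, function(k) mean(bb[[k]]), numeric(1))
  }
  if (nrow(params) < 2) return(0)
  V <- 0
  for (k in keys) {
    dx <- diff(params[[k]]) / scales[[k]]
    V <- V + sum(dx^2)
  }
  V
}
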