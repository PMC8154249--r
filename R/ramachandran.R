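#' Region labels of the Ramachandran partition
#' @export
ramachandran_regions <- c("beta_fav", "beta_all", "alphaR_fav", "alphaR_all",
                          "alphaL_fav", "alphaL_all", "gly", "uns")

# Wrapped squared distance on the angle torus (degrees).
wrap_diff <- function(x, c0) {
  d <- (x - c0) %% 360
  ifelse(d > 180, d - 360, d)
}

# Analytic stand-in for an empirical backbone-dihedral density: a mixture of
# periodic 2-D Gaussians, normalized to a maximum of 1 on the grid. The
# contour-and-subdivision rules that build the region map are exact; the
# density source is this packaged mixture and is swappable.
.density_mixture <- function(phi, psi, comps) {
  z <- matrix(0, length(phi), length(psi))
  for (cp in comps) {
    dphi <- wrap_diff(phi, cp$c[1]) / cp$s[1]
    dpsi <- wrap_diff(psi, cp$c[2]) / cp$s[2]
    z <- z + cp$A * exp(-0.5 * outer(dphi^2, dpsi^2, `+`))
  }
  z / max(z)
}

# general (non-glycine) backbone density: beta sheet, polyproline-II,
# right- and left-handed helical lobes
.general_components <- list(
  list(A = 1.00, c = c(-120, 130), s = c(28, 28)),
  list(A = 0.80, c = c(-65, 145), s = c(18, 22)),
  list(A = 1.00, c = c(-63, -43), s = c(14, 12)),
  list(A = 0.20, c = c(-95, -10), s = c(22, 22)),
  list(A = 0.30, c = c(57, 47), s = c(13, 13))
)

# glycine-specific mirror lobes at positive phi not covered by alpha-left
.glycine_components <- list(
  list(A = 1.00, c = c(82, -170), s = c(20, 22)),
  list(A = 1.00, c = c(82, 175), s = c(20, 22)),
  list(A = 0.60, c = c(95, -10), s = c(18, 20))
)

#' Packaged Ramachandran density tables
#'
#' Evaluates the packaged analytic density mixtures (general and
#' glycine-specific), each normalized to a maximum of 1, on a regular grid
#' of cell centers over the torus.
#'
#' @param res grid resolution in degrees (default 2).
#' @return list with `phi`, `psi` (cell centers in \[-180, 180)), `general`
#'   and `gly` matrices.
#' @export
ramachandran_density <- function(res = 2) {
  stopifnot(res > 0, 360 %% res == 0)
  phi <- seq(-180, 180 - res, by = res)
  psi <- phi
  list(phi = phi, psi = psi,
       general = .density_mixture(phi, psi, .general_components),
       gly = .density_mixture(phi, psi, .glycine_components))
}

#' Build the eight-region Ramachandran map
#'
#' Cells with general density >= the upper contour level are favored, cells
#' in \[lower, upper) are allowed, the rest are unstructured unless the
#' glycine-specific density reaches the allowed level there (gly region).
#' Favored/allowed areas at phi <= 0 are subdivided into the alpha-right
#' band for -120 <= psi <= -50 (closed interval), the beta band for
#' psi < -120 or psi > 50, and the helical bridge (-50, 50\] which joins
#' alpha-right; phi > 0 cells are alpha-left.
#'
#' @param density density tables from [ramachandran_density()] (list with
#'   `phi`, `psi`, `general`, `gly`, all normalized to max 1).
#' @param contour_levels increasing (allowed, favored) levels; default
#'   c(0.0005, 0.02).
#' @return object of class `ramachandran_map`: list with `phi`, `psi`,
#'   `res`, `labels` (character matrix) and `levels`.
#' @export
build_region_map <- function(density = ramachandran_density(),
                             contour_levels = c(0.0005, 0.02)) {
  stopifnot(length(contour_levels) == 2, diff(contour_levels) > 0)
  for (nm in c("general", "gly")) {
    if (abs(max(density[[nm]]) - 1) > 1e-9) {
      stop("density '", nm, "' must be normalized to a maximum of 1")
    }
  }
  phi <- density$phi; psi <- density$psi
  lv_all <- contour_levels[1]; lv_fav <- contour_levels[2]
  lab <- matrix("uns", length(phi), length(psi))
  g <- density$general
  fav <- g >= lv_fav
  allow <- g >= lv_all & !fav
  base <- matrix("", length(phi), length(psi))
  phi_m <- matrix(phi, length(phi), length(psi))
  psi_m <- matrix(psi, length(phi), length(psi), byrow = TRUE)
  neg <- phi_m <= 0
  in_aR <- neg & psi_m >= -120 & psi_m <= 50   # closed alphaR band + bridge
  in_beta <- neg & !in_aR
  base[in_aR] <- "alphaR"
  base[in_beta] <- "beta"
  base[!neg] <- "alphaL"
  lab[fav] <- paste0(base[fav], "_fav")
  lab[allow] <- paste0(base[allow], "_all")
  gly_only <- !fav & !allow & density$gly >= lv_all
  lab[gly_only] <- "gly"
  structure(list(phi = phi, psi = psi, res = phi[2] - phi[1], labels = lab,
                 levels = contour_levels), class = "ramachandran_map")
}

#' @export
print.ramachandran_map <- function(x, ...) {
  tb <- table(factor(x$labels, levels = ramachandran_regions))
  cat(sprintf("<ramachandran_map>  %g deg grid, levels (%.4g, %.4g)\n",
              x$res, x$levels[1], x$levels[2]))
  print(round(tb / length(x$labels), 3))
  invisible(x)
}

#' Assign a (phi, psi) pair to its Ramachandran region
#'
#' Angles are wrapped to \[-180, 180) and looked up in the map cell whose
#' center is nearest.
#'
#' @param map a [build_region_map()] result.
#' @param phi,psi angles in degrees (vectors, any real values).
#' @return character vector of region labels.
#' @export
assign_region <- function(map, phi, psi) {
  stopifnot(inherits(map, "ramachandran_map"))
  w <- function(x) {
    x <- (x + 180) %% 360 - 180
    i <- round((x + 180) / map$res) + 1
    i[i > length(map$phi)] <- 1  # wrap the top edge
    i
  }
  map$labels[cbind(w(phi), w(psi))]
}

#' Ensemble-weighted Ramachandran propensities
#'
#' For every inner residue a (2..N_aa-1) and region r:
#' p_a(r) = sum_i w_i (1/m_i) sum_g delta(r_(i,g,a), r), i.e. the chains of a
#' multimer are averaged with weight 1/m_i so that sum_r p_a(r) = 1.
#' Chains with missing dihedrals at a residue are excluded for that residue
#' with renormalization over the remaining chains. When a weight covariance
#' is supplied, Var p_a(r) = c' Cov c is propagated from the (linear)
#' dependence on the weights.
#'
#' @param ens an [ensemble()]; all conformers must share the chain length.
#' @param w monomer population weights (length N, summing to 1).
#' @param map a [build_region_map()] result.
#' @param w_cov optional N x N covariance matrix of the weights (see
#'   [weight_covariance()]).
#' @param dihedrals optional precomputed list of [compute_dihedrals()]
#'   outputs per conformer (cached by callers in loops).
#' @return object of class `propensity_table`: list with `p` and `var`
#'   (n_residue x 8 matrices), `residues`, `regions`.
#' @export
propensities <- function(ens, w, map, w_cov = NULL, dihedrals = NULL) {
  stopifnot(inherits(ens, "ensemble"), length(w) == ens$n)
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  n_res <- unique(vapply(ens$conformers, `[[`, integer(1), "n_res"))
  if (length(n_res) != 1) {
    stop("all conformers must share the same chain length")
  }
  if (is.null(dihedrals)) {
    dihedrals <- lapply(ens$conformers, compute_dihedrals)
  }
  residues <- 2:(n_res - 1)
  n_in <- length(residues)
  regions <- ramachandran_regions
  # indicator fractions c[i, a, r]: chain-averaged region membership
  cfrac <- array(0, dim = c(ens$n, n_in, length(regions)),
                 dimnames = list(NULL, NULL, regions))
  for (i in seq_len(ens$n)) {
    dh <- dihedrals[[i]]
    dh <- dh[order(dh$chain, dh$resno), , drop = FALSE]
    ok <- !is.na(dh$phi) & !is.na(dh$psi)
    dh$region <- NA_character_
    dh$region[ok] <- assign_region(map, dh$phi[ok], dh$psi[ok])
    for (a in seq_len(n_in)) {
      rows <- dh[dh$resno == residues[a] & !is.na(dh$region), , drop = FALSE]
      if (nrow(rows) == 0) next
      tab <- table(factor(rows$region, levels = regions))
      cfrac[i, a, ] <- as.numeric(tab) / nrow(rows)
    }
  }
  p <- matrix(0, n_in, length(regions), dimnames = list(residues, regions))
  v <- matrix(0, n_in, length(regions), dimnames = list(residues, regions))
  for (a in seq_len(n_in)) {
    C <- cfrac[, a, , drop = TRUE]
    if (is.null(dim(C))) C <- matrix(C, nrow = ens$n)
    p[a, ] <- as.numeric(t(C) %*% w)
    if (!is.null(w_cov)) {
      for (r in seq_along(regions)) {
        v[a, r] <- as.numeric(t(C[, r]) %*% w_cov %*% C[, r])
      }
    }
  }
  structure(list(p = p, var = pmax(v, 0), residues = residues,
                 regions = regions), class = "propensity_table")
}

#' Covariance of the monomer population weights
#'
#' Assembles the N x N covariance of the w_i from the per-class Dirichlet
#' posteriors of one curve, holding the class weights omega_m at their
#' thermodynamic values: Cov(w_i, w_i') = omega_m^2 Cov(W_mj, W_mj') for
#' conformers in the same class and 0 across classes.
#'
#' @param state a `population_state`.
#' @param dirichlet a [dirichlet_state()].
#' @param ens the [ensemble()].
#' @return N x N covariance matrix.
#' @export
weight_covariance <- function(state, dirichlet, ens) {
  V <- matrix(0, ens$n, ens$n)
  for (m in names(state$W)) {
    idx <- ens$members[[m]]
    if (length(idx) < 2) next
    cw <- dirichlet_moments(dirichlet$alpha[[m]])$cov
    V[idx, idx] <- state$omega[[m]]^2 * cw
  }
  V
}

#' Mutant-minus-wild-type propensity change with run filtering
#'
#' Computes Delta p_a(r) = p_a^mut(r) - p_a^wt(r) for one region and keeps
#' only maximal runs of at least `min_run` consecutive residues in which all
#' changes share a strict sign (a zero breaks a run). Each residue of a kept
#' run is assigned the run's mean change and standard deviation; all other
#' residues get 0.
#'
#' @param mut,wt `propensity_table`s over the same residues.
#' @param region one of [ramachandran_regions].
#' @param min_run minimum run length (default 8).
#' @return data.frame with columns `resno`, `delta`, `mean`, `sd` (the bar
#'   values).
#' @export
delta_propensity_runs <- function(mut, wt, region, min_run = 8) {
  stopifnot(inherits(mut, "propensity_table"),
            inherits(wt, "propensity_table"),
            region %in% mut$regions)
  if (!identical(mut$residues, wt$residues)) {
    stop("mutant and wild-type tables cover different residues")
  }
  dp <- mut$p[, region] - wt$p[, region]
  n <- length(dp)
  bar_mean <- bar_sd <- numeric(n)
  sgn <- sign(dp)
  i <- 1
  while (i <= n) {
    if (sgn[i] == 0) { i <- i + 1; next }
    j <- i
    while (j < n && sgn[j + 1] == sgn[i]) j <- j + 1
    if (j - i + 1 >= min_run) {
      bar_mean[i:j] <- mean(dp[i:j])
      bar_sd[i:j] <- stats::sd(dp[i:j])
    }
    i <- j + 1
  }
  data.frame(resno = mut$residues, delta = dp, mean = bar_mean, sd = bar_sd)
}
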