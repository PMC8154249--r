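#' Default box constraints for the global fit
#'
#' Bounds for the dimensionless thermodynamic differences, the interaction
#' parameters and the flat background. The monomer-radius window is generous
#' around typical protein values; the background window is tight around zero
#' because the data are absolutely calibrated.
#'
#' @return named list of length-2 numeric vectors.
#' @export
default_fit_bounds <- function() {
  list(dH = c(-20, 20), dS = c(-20, 20), dG0 = c(-20, 20), dCp = c(-50, 50),
       J1 = c(1e-3, 2000), d = c(0.5, 30), R1 = c(5, 60), nu = c(0.2, 10),
       B = c(-0.005, 0.005))
}

#' Configuration of the global fit
#'
#' @param fit_dCp fit the heat-capacity differences (default FALSE: frozen
#'   at 0, which removes one parameter per conformer on small problems).
#' @param interactions "shared" (one interaction-parameter set for all
#'   curves), "per_curve" (curve-specific with adjacency regularization), or
#'   "fixed" (held at `start$interactions`).
#' @param bounds box constraints; see [default_fit_bounds()].
#' @param sa simulated-annealing schedule: list with `n_stages`,
#'   `moves_per_stage`, `t_start` (NULL = auto from the initial merit),
#'   `cool` (stage-to-stage temperature factor), `polish_maxit`
#'   (Nelder-Mead iterations after each stage), `n_restarts`
#'   (independent annealing runs; the best end point wins), `warm_start`
#'   (block-coordinate polish of the thermodynamic and interaction blocks
#'   before the anneal) and `n_warm_starts` (number of starting points for
#'   that polish; the first is the supplied start, the rest are seeded
#'   random draws).
#' @param final_maxit Nelder-Mead iterations of the final polish.
#' @param polish_rounds maximum alternating block/joint polish rounds after
#'   the anneal.
#' @param alpha_V initial regularization constant; auto-tuned downward at
#'   every annealing stage so that alpha_V * V stays below ~10% of the merit.
#' @param bootstrap_R default number of bootstrap replicates.
#' @param seed master RNG seed, recorded in every result.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(fit_dCp = FALSE,
                       interactions = c("shared", "per_curve", "fixed"),
                       bounds = default_fit_bounds(),
                       sa = list(n_stages = 5, moves_per_stage = 150,
                                 t_start = NULL, cool = 0.45,
                                 polish_maxit = 100, n_restarts = 1,
                                 warm_start = TRUE, n_warm_starts = 2),
                       final_maxit = 1500, polish_rounds = 8, alpha_V = 1,
                       bootstrap_R = 20, seed = 1) {
  interactions <- match.arg(interactions)
  sa_def <- list(n_stages = 8, moves_per_stage = 220, t_start = NULL,
                 cool = 0.45, polish_maxit = 150, n_restarts = 1,
                 warm_start = TRUE, n_warm_starts = 3)
  sa <- utils::modifyList(sa_def, sa)
  stopifnot(sa$n_stages >= 0, sa$moves_per_stage > 0, sa$cool > 0,
            sa$cool < 1, final_maxit > 0, polish_rounds >= 1, alpha_V >= 0)
  structure(list(fit_dCp = fit_dCp, interactions = interactions,
                 bounds = bounds, sa = sa, final_maxit = final_maxit,
                 polish_rounds = polish_rounds, alpha_V = alpha_V,
                 bootstrap_R = bootstrap_R, seed = seed),
            class = "fit_config")
}

# --- parameter vector encoding -------------------------------------------

# Log-space for strictly positive interaction parameters, linear for the
# thermodynamic differences and the background. All coordinates are scaled
# to [0, 1] over their box.
.log_params <- c("J1", "d", "R1", "nu")

par_layout <- function(n_conf, n_curves, config) {
  lay <- list()
  add <- function(lay, name, kind, count) {
    if (count < 1) return(lay)
    c(lay, list(data.frame(name = name, kind = kind, idx = seq_len(count),
                           stringsAsFactors = FALSE)))
  }
  # (dG0, dH) coordinates: dG0 = dH - dS is tightly determined by the
  # populations at the reference temperature, dH only by the T-trend --
  # fitting them directly decorrelates the enthalpy/entropy compensation
  lay <- add(lay, "dG0", "thermo", n_conf - 1)
  lay <- add(lay, "dH", "thermo", n_conf - 1)
  if (config$fit_dCp) lay <- add(lay, "dCp", "thermo", n_conf - 1)
  n_blocks <- switch(config$interactions, shared = 1, per_curve = n_curves,
                     fixed = 0)
  if (n_blocks > 0) {
    for (b in seq_len(n_blocks)) {
      for (p in c("J1", "d", "R1", "nu", "B")) {
        df <- data.frame(name = p, kind = "inter", idx = b,
                         stringsAsFactors = FALSE)
        lay <- c(lay, list(df))
      }
    }
  }
  do.call(rbind, lay)
}

encode_pars <- function(values, layout, bounds) {
  x <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    nm <- layout$name[i]
    b <- bounds[[nm]]
    v <- values[i]
    if (nm %in% .log_params) {
      x[i] <- (log(v) - log(b[1])) / (log(b[2]) - log(b[1]))
    } else {
      x[i] <- (v - b[1]) / (b[2] - b[1])
    }
  }
  pmin(pmax(x, 0), 1)
}

decode_pars <- function(x, layout, bounds) {
  x <- pmin(pmax(x, 0), 1)
  v <- numeric(length(x))
  for (i in seq_along(x)) {
    nm <- layout$name[i]
    b <- bounds[[nm]]
    if (nm %in% .log_params) {
      v[i] <- exp(log(b[1]) + x[i] * (log(b[2]) - log(b[1])))
    } else {
      v[i] <- b[1] + x[i] * (b[2] - b[1])
    }
  }
  v
}

# --- global fit -----------------------------------------------------------

#' Global variational Bayesian fit of a SAXS series
#'
#' Minimizes the merit F = Lambda + alpha_V V over the shared thermodynamic
#' differences and the interaction parameters, with the per-curve Dirichlet
#' concentrations alpha_m0 profiled out analytically at every evaluation.
#' The optimizer is simulated annealing over the scaled parameter box with
#' periodic Nelder-Mead polish, fully reproducible from the recorded seed.
#'
#' @param curves list of [saxs_curve()] objects, automatically ordered by
#'   (concentration, temperature) for the adjacency regularization.
#' @param ens the [ensemble()].
#' @param ff a [formfactor_set()] on a grid covering the curves' q ranges
#'   (interpolated per curve).
#' @param M1 monomer molecular weight, g/mol.
#' @param Z1 monomer net charge (elementary charges), computed from the
#'   sequence with [net_charge()] and held fixed during the fit (it is an
#'   input of the screened-Coulomb repulsion, not a free parameter).
#' @param config a [fit_config()].
#' @param start optional named list with elements `thermo`
#'   ([thermo_params()]) and `interactions` (an [interaction_params()] or a
#'   list of them per curve) used as the starting point; defaults to the
#'   center of the parameter box.
#' @return object of class `vbwsas_fit`.
#' @export
fit_global <- function(curves, ens, ff, M1, Z1 = 0, config = fit_config(),
                       start = NULL) {
  stopifnot(length(curves) >= 1, inherits(ens, "ensemble"),
            inherits(ff, "formfactor_set"))
  # order curves by (c, T): adjacency for the regularization
  ord <- order(vapply(curves, function(cu) cu$condition$c_nominal, numeric(1)),
               vapply(curves, function(cu) cu$condition$temperature, numeric(1)))
  curves <- curves[ord]
  n_curves <- length(curves)
  # per-curve interpolated form factors and fixed condition-derived numbers
  curve_data <- lapply(curves, function(cu) {
    F2 <- apply(ff$F2, 2, function(col) {
      stats::approx(ff$q, col, xout = cu$q, rule = 2)$y
    })
    # high-q window where interparticle interference is negligible; used to
    # warm-start the thermodynamic block with the structure factor off
    hi <- which(cu$q >= 0.12)
    if (length(hi) < 20) hi <- which(cu$q >= stats::median(cu$q))
    list(F2 = matrix(F2, nrow = length(cu$q)),
         n0 = number_density(cu$condition$c_T, M1), hi = hi)
  })
  layout <- par_layout(ens$n, n_curves, config)
  bounds <- config$bounds

  build_values <- function(start) {
    v <- numeric(nrow(layout))
    for (i in seq_len(nrow(layout))) {
      nm <- layout$name[i]
      v[i] <- switch(nm,
        dH = if (!is.null(start$thermo)) start$thermo$dH[layout$idx[i] + 1] else 0,
        dG0 = if (!is.null(start$thermo)) {
          start$thermo$dH[layout$idx[i] + 1] - start$thermo$dS[layout$idx[i] + 1]
        } else 0,
        dCp = if (!is.null(start$thermo)) start$thermo$dCp[layout$idx[i] + 1] else 0,
        {
          ip <- start$interactions
          if (is.null(ip)) {
            b <- bounds[[nm]]
            if (nm %in% .log_params) exp(mean(log(b))) else mean(b)
          } else {
            if (inherits(ip, "interaction_params")) ip[[nm]]
            else ip[[layout$idx[i]]][[nm]]
          }
        })
    }
    v
  }

  fixed_ip <- NULL
  if (config$interactions == "fixed") {
    if (is.null(start$interactions)) {
      stop("interactions = 'fixed' requires start$interactions")
    }
    fixed_ip <- start$interactions
    if (inherits(fixed_ip, "interaction_params")) {
      fixed_ip <- rep(list(fixed_ip), n_curves)
    }
  }

  decode_model <- function(x) {
    v <- decode_pars(x, layout, bounds)
    dH <- dG0 <- dCp <- numeric(ens$n)
    ips <- vector("list", n_curves)
    blocks <- list()
    for (i in seq_len(nrow(layout))) {
      nm <- layout$name[i]; id <- layout$idx[i]
      if (nm == "dH") dH[id + 1] <- v[i]
      else if (nm == "dG0") dG0[id + 1] <- v[i]
      else if (nm == "dCp") dCp[id + 1] <- v[i]
      else {
        key <- as.character(id)
        if (is.null(blocks[[key]])) blocks[[key]] <- list()
        blocks[[key]][[nm]] <- v[i]
      }
    }
    th <- thermo_params(dH, dH - dG0, dCp, M1 = M1)  # dS = dH - dG0
    if (config$interactions == "fixed") {
      ips <- fixed_ip
    } else if (config$interactions == "shared") {
      b <- blocks[["1"]]
      ip <- interaction_params(b$R1, Z1 = z1_for_curves, b$J1, b$d, b$nu, b$B)
      ips <- rep(list(ip), n_curves)
    } else {
      for (k in seq_len(n_curves)) {
        b <- blocks[[as.character(k)]]
        ips[[k]] <- interaction_params(b$R1, Z1 = z1_for_curves, b$J1, b$d,
                                       b$nu, b$B)
      }
    }
    list(thermo = th, ips = ips)
  }

  z1_for_curves <- Z1

  eval_curves <- function(th, ips) {
    out <- vector("list", n_curves)
    for (k in seq_len(n_curves)) {
      cu <- curves[[k]]; cd <- curve_data[[k]]
      state <- solve_equilibrium(th, ens, cu$condition)
      eff <- effective_params(ips[[k]], state, cd$n0, cu$condition$temperature,
                              cu$condition$ionic_strength)
      S <- rpa_structure_factor(cu$q, eff)
      beta <- coupling_beta_ell(cu$q, ips[[k]]$R1, state$m_mean,
                                ips[[k]]$nu, n_nodes = 64)
      S_M <- measured_structure_factor(S, beta)
      G <- intensity_basis(state, cd$F2, ens, S_M, cd$n0)
      alpha0 <- profile_alpha0(cu, state, G, ens)
      dir <- dirichlet_state(alpha0, state)
      fl <- functional_L(cu, dir, state, cd$F2, ens, S_M, ips[[k]]$B, cd$n0)
      out[[k]] <- list(state = state, S = S, S_M = S_M, alpha0 = alpha0,
                       dirichlet = dir, L = fl$L, chi2 = fl$chi2,
                       model = fl$model)
    }
    out
  }

  # high-q chi2 with S_M = 1: fast, structure-factor-free objective for the
  # thermodynamic warm start (the class populations set the curve shapes at
  # high q; interactions mostly reshape low q)
  merit_hi <- function(x) {
    md <- tryCatch(decode_model(x), error = function(e) NULL)
    if (is.null(md)) return(Inf)
    tot <- 0
    for (k in seq_len(n_curves)) {
      cu <- curves[[k]]; cd <- curve_data[[k]]
      state <- tryCatch(solve_equilibrium(md$thermo, ens, cu$condition),
                        error = function(e) NULL)
      if (is.null(state)) return(Inf)
      G <- intensity_basis(state, cd$F2[cd$hi, , drop = FALSE], ens, 1,
                           cd$n0)
      wflat <- flat_within_class_weights(state, ens)
      model <- as.numeric(G %*% wflat) + md$ips[[k]]$B
      tot <- tot + sum(((cu$intensity[cd$hi] - model) / cu$sigma[cd$hi])^2)
    }
    if (!is.finite(tot)) Inf else tot
  }

  alpha_V <- config$alpha_V
  merit <- function(x) {
    md <- tryCatch(decode_model(x), error = function(e) NULL)
    if (is.null(md)) return(Inf)
    ev <- tryCatch(eval_curves(md$thermo, md$ips), error = function(e) NULL)
    if (is.null(ev)) return(Inf)
    Lam <- sum(vapply(ev, `[[`, numeric(1), "L"))
    V <- if (config$interactions == "per_curve") {
      tab <- as.data.frame(do.call(rbind, lapply(md$ips, function(ip) {
        unlist(ip[c("J1", "d", "R1", "nu")])
      })))
      regularization_V(tab)
    } else 0
    F <- Lam + alpha_V * V
    if (!is.finite(F)) return(Inf)
    attr(F, "Lambda") <- Lam
    attr(F, "V") <- V
    F
  }

  set.seed(config$seed)
  x0 <- encode_pars(build_values(start), layout, bounds)
  f0 <- merit(x0)
  if (!is.finite(f0)) stop("initial merit is non-finite; check the start point")
  best_x <- x0; best_f <- f0
  x_warm <- NULL
  n_par <- length(x0)
  sa <- config$sa
  # block-coordinate warm start: alternately polish the thermodynamic and
  # the interaction blocks (each a small, well-conditioned subproblem)
  # before the joint anneal
  block_polish <- function(x, idx, maxit) {
    if (length(idx) == 0) return(x)
    op <- stats::optim(x[idx], function(xi) {
      xx <- x; xx[idx] <- xi; as.numeric(merit(xx))
    }, method = "Nelder-Mead", control = list(maxit = maxit))
    x[idx] <- pmin(pmax(op$par, 0), 1)
    x
  }
  if (sa$n_stages > 0 && isTRUE(sa$warm_start)) {
    th_idx <- which(layout$kind == "thermo")
    in_idx <- which(layout$kind == "inter")
    b_idx <- which(layout$name == "B")
    # staged, multi-start warm start: (i) thermodynamic block (+ background)
    # against the high-q window with the structure factor off, (ii) the
    # interaction block on the full model, (iii) alternating block polish
    for (ws in seq_len(sa$n_warm_starts)) {
      xw <- if (ws == 1) x0 else stats::runif(n_par)
      if (!is.finite(merit(xw))) next
      if (length(th_idx) > 0) {
        ti <- c(th_idx, b_idx)
        op0 <- stats::optim(xw[ti], function(xi) {
          xx <- xw; xx[ti] <- xi; merit_hi(xx)
        }, method = "Nelder-Mead",
        control = list(maxit = 150 * length(ti)))
        xw[ti] <- pmin(pmax(op0$par, 0), 1)
      }
      for (pass in 1:2) {
        xw <- block_polish(xw, in_idx, 120 * max(1, length(in_idx)))
        xw <- block_polish(xw, th_idx, 120 * max(1, length(th_idx)))
      }
      fw <- merit(xw)
      if (getOption("vbwsas.debug", FALSE)) {
        message(sprintf("warm start %d: merit %.4g", ws, as.numeric(fw)))
      }
      if (is.finite(fw) && fw < best_f) { best_x <- xw; best_f <- fw; x0 <- xw }
    }
    x_warm <- best_x  # kept as an independent candidate for the final polish
  }
  t_sa <- if (is.null(sa$t_start)) max(1, 0.02 * abs(as.numeric(f0))) else sa$t_start
  if (sa$n_stages > 0) {
    t_start <- t_sa
    for (restart in seq_len(sa$n_restarts)) {
      # restart 1 starts from the supplied point, later ones from random
      # corners of the box (all draws flow from the master seed)
      x_cur <- if (restart == 1) x0 else stats::runif(n_par)
      f_cur <- merit(x_cur)
      tries <- 0
      while (!is.finite(f_cur) && tries < 20) {
        x_cur <- stats::runif(n_par); f_cur <- merit(x_cur); tries <- tries + 1
      }
      if (!is.finite(f_cur)) next
      if (f_cur < best_f) { best_x <- x_cur; best_f <- f_cur }
      t_sa <- t_start
      x_loc <- x_cur; f_loc <- f_cur  # restart-local incumbent
      for (stage in seq_len(sa$n_stages)) {
        step <- 0.25 * sa$cool^(stage - 1) + 0.02
        for (mv in seq_len(sa$moves_per_stage)) {
          x_new <- x_cur
          if (stats::runif(1) < 0.2) {
            x_new <- x_new + stats::rnorm(n_par, 0, step / 3)
          } else {
            j <- sample.int(n_par, 1)
            x_new[j] <- x_new[j] + stats::rnorm(1, 0, step)
          }
          x_new <- pmin(pmax(x_new, 0), 1)
          f_new <- merit(x_new)
          if (is.finite(f_new) &&
              (f_new <= f_cur ||
               stats::runif(1) < exp((as.numeric(f_cur) - as.numeric(f_new)) / t_sa))) {
            x_cur <- x_new; f_cur <- f_new
            if (f_new < f_loc) { x_loc <- x_new; f_loc <- f_new }
            if (f_new < best_f) { best_x <- x_new; best_f <- f_new }
          }
        }
        # simplex polish from the restart-local best
        op <- stats::optim(x_loc, function(x) as.numeric(merit(x)),
                           method = "Nelder-Mead",
                           control = list(maxit = sa$polish_maxit))
        if (op$value < as.numeric(f_loc)) {
          x_loc <- pmin(pmax(op$par, 0), 1)
          f_loc <- merit(x_loc)
          x_cur <- x_loc; f_cur <- f_loc
          if (as.numeric(f_loc) < as.numeric(best_f)) {
            best_x <- x_loc; best_f <- f_loc
          }
        }
        # alpha_V auto-tune: keep the regularization below ~10% of the merit
        V_best <- attr(best_f, "V")
        if (!is.null(V_best) && V_best > 0) {
          alpha_V <- min(alpha_V, 0.1 * as.numeric(best_f) / V_best)
          best_f <- merit(best_x); f_loc <- merit(x_loc); f_cur <- merit(x_cur)
        }
        t_sa <- t_sa * sa$cool
      }
    }
  }
  # final polish: alternate block-wise and joint Nelder-Mead rounds (fresh
  # simplices escape collapse; the small blocks are well conditioned),
  # applied to both the annealing best and the warm-start best — the
  # anneal's raw incumbent can sit in a worse basin than the warm start
  th_idx <- which(layout$kind == "thermo")
  in_idx <- which(layout$kind == "inter")
  # final polish: alternating block/joint Nelder-Mead rounds per candidate,
  # then basin-hopping kicks on the winner (a stalled incumbent is perturbed
  # by a small seeded step and re-polished; the best point ever seen wins)
  polish_rounds <- function(xc, fc, max_rounds, max_kicks) {
    xb <- xc; fb <- fc
    kicks <- 0
    for (round in seq_len(max_rounds)) {
      f_before <- as.numeric(fc)
      xx <- block_polish(xc, th_idx, 100 * max(1, length(th_idx)))
      xx <- block_polish(xx, in_idx, 100 * max(1, length(in_idx)))
      op <- stats::optim(xx, function(x) as.numeric(merit(x)),
                         method = "Nelder-Mead",
                         control = list(maxit = config$final_maxit,
                                        reltol = 1e-10))
      if (op$value < as.numeric(fc)) {
        xc <- pmin(pmax(op$par, 0), 1)
        fc <- merit(xc)
      }
      if (as.numeric(fc) < as.numeric(fb)) { xb <- xc; fb <- fc }
      if (f_before - as.numeric(fc) < 0.5) {
        if (kicks >= max_kicks) break
        kicks <- kicks + 1
        for (try in 1:10) {
          xk <- pmin(pmax(xb + stats::rnorm(n_par, 0, 0.07), 0), 1)
          fk <- merit(xk)
          if (is.finite(fk)) break
        }
        if (is.finite(fk)) { xc <- xk; fc <- fk }
      }
    }
    list(x = xb, f = fb)
  }
  candidates <- list(best_x)
  if (!is.null(x_warm) && any(x_warm != best_x)) {
    candidates <- c(candidates, list(x_warm))
  }
  if (getOption("vbwsas.debug", FALSE)) {
    message(sprintf("pre-polish best merit %.4g, %d candidate(s)",
                    as.numeric(best_f), length(candidates)))
  }
  # statistical floor: merit ~ (1/2) sum N_cq chi2 (+ small KL terms), so a
  # merit below 0.65 * total points means mean chi2 < ~1.3 -- near the noise
  # floor, where further basin exploration cannot pay off
  n_points_total <- sum(vapply(curves, function(cu) length(cu$q), numeric(1)))
  at_floor <- function(f) as.numeric(f) < 0.65 * n_points_total
  for (cand in candidates) {
    if (at_floor(best_f)) break
    pc <- polish_rounds(cand, merit(cand),
                        max_rounds = config$polish_rounds, max_kicks = 0)
    if (getOption("vbwsas.debug", FALSE)) {
      message(sprintf("candidate polished merit %.4g", as.numeric(pc$f)))
    }
    if (as.numeric(pc$f) < as.numeric(best_f)) {
      best_x <- pc$x
      best_f <- pc$f
    }
  }
  if (sa$n_stages > 0 && !at_floor(best_f)) {
    # basin hopping on the winner only
    pc <- polish_rounds(best_x, best_f, max_rounds = config$polish_rounds,
                        max_kicks = 4)
    if (getOption("vbwsas.debug", FALSE)) {
      message(sprintf("after basin hopping: merit %.4g", as.numeric(pc$f)))
    }
    if (as.numeric(pc$f) < as.numeric(best_f)) {
      best_x <- pc$x
      best_f <- pc$f
    }
  }
  # ensure at least one joint refinement has run even when the anneal or the
  # warm start already sits at the floor
  pc <- polish_rounds(best_x, best_f, max_rounds = 2, max_kicks = 0)
  if (as.numeric(pc$f) < as.numeric(best_f)) {
    best_x <- pc$x
    best_f <- pc$f
  }
  stopifnot(as.numeric(best_f) <= as.numeric(f0) + 1e-9)

  md <- decode_model(best_x)
  ev <- eval_curves(md$thermo, md$ips)
  Lam <- sum(vapply(ev, `[[`, numeric(1), "L"))
  V <- attr(merit(best_x), "V")
  structure(list(
    thermo = md$thermo,
    interactions = md$ips,
    alpha0 = lapply(ev, `[[`, "alpha0"),
    dirichlet = lapply(ev, `[[`, "dirichlet"),
    states = lapply(ev, `[[`, "state"),
    chi2 = vapply(ev, `[[`, numeric(1), "chi2"),
    models = lapply(ev, `[[`, "model"),
    S = lapply(ev, `[[`, "S"),
    S_M = lapply(ev, `[[`, "S_M"),
    Lambda = Lam, V = V, alpha_V = alpha_V,
    merit = as.numeric(best_f), merit_initial = as.numeric(f0),
    curves = curves, ens = ens, ff = ff, M1 = M1, Z1 = Z1,
    par = best_x, layout = layout, config = config, seed = config$seed,
    sd = NULL
  ), class = "vbwsas_fit")
}

#' @export
print.vbwsas_fit <- function(x, ...) {
  cat(sprintf("<vbwsas_fit>  %d curves, %d conformers, merit = %.4g (Lambda = %.4g, alpha_V V = %.4g)\n",
              length(x$curves), x$ens$n, x$merit, x$Lambda,
              x$alpha_V * x$V))
  cat("  per-curve chi2:", paste(sprintf("%.3f", x$chi2), collapse = ", "),
      "\n")
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

# --- bootstrap ------------------------------------------------------------

#' Parametric bootstrap of fit uncertainties
#'
#' Repeats a fit on curves whose intensities are resampled pointwise from
#' Normal(I_exp, sigma^2) and reports per-parameter standard deviations
#' across replicates. Replicate seeds derive deterministically from `seed`.
#'
#' @param curves list of [saxs_curve()].
#' @param fit_fun function(curves) returning a named numeric vector of
#'   fitted parameters.
#' @param R number of replicates (>= 2).
#' @param seed master seed.
#' @param resample_sd NULL to use each curve's own sigma, or a numeric
#'   (e.g. 0) overriding it for every point.
#' @return list with `sd` (named numeric) and `replicates` (R x n matrix).
#' @export
bootstrap_errors <- function(curves, fit_fun, R = 20, seed = 1,
                             resample_sd = NULL) {
  if (R < 2) stop("R must be >= 2")
  reps <- NULL
  for (r in seq_len(R)) {
    set.seed(seed + 7919L * r)
    cc <- lapply(curves, function(cu) {
      sdv <- if (is.null(resample_sd)) cu$sigma else rep(resample_sd,
                                                         length(cu$sigma))
      cu$intensity <- stats::rnorm(length(cu$intensity), cu$intensity, sdv)
      cu
    })
    pv <- fit_fun(cc)
    if (is.null(reps)) {
      reps <- matrix(NA_real_, R, length(pv),
                     dimnames = list(NULL, names(pv)))
    }
    reps[r, ] <- pv
  }
  list(sd = apply(reps, 2, stats::sd), replicates = reps)
}

#' Bootstrap standard deviations of a global fit
#'
#' Applies [bootstrap_errors()] to a converged [fit_global()] result: each
#' replicate re-polishes the merit from the converged optimum (Nelder-Mead,
#' no annealing) on resampled curves.
#'
#' @param fit a `vbwsas_fit`.
#' @param R replicates; defaults to the fit config's `bootstrap_R`.
#' @param seed master seed; defaults to the fit seed + 1.
#' @return the fit with `sd` (named numeric vector over the parameter
#'   layout) and `bootstrap` (replicate matrix) filled in.
#' @export
bootstrap_fit <- function(fit, R = NULL, seed = NULL) {
  stopifnot(inherits(fit, "vbwsas_fit"))
  if (is.null(R)) R <- fit$config$bootstrap_R
  if (is.null(seed)) seed <- fit$seed + 1L
  cfg <- fit$config
  cfg$sa$n_stages <- 0
  cfg$polish_rounds <- 1
  cfg$final_maxit <- 300
  start <- list(thermo = fit$thermo, interactions = fit$interactions)
  nm <- paste0(fit$layout$name, "_", fit$layout$idx)
  fit_fun <- function(cc) {
    f <- fit_global(cc, fit$ens, fit$ff, fit$M1, fit$Z1, cfg, start = start)
    stats::setNames(decode_pars(f$par, f$layout, cfg$bounds), nm)
  }
  bs <- bootstrap_errors(fit$curves, fit_fun, R = R, seed = seed)
  fit$sd <- bs$sd
  fit$bootstrap <- bs$replicates
  fit
}

#' Fitted parameter table
#'
#' @param fit a `vbwsas_fit`, optionally after [bootstrap_fit()].
#' @return data.frame with columns `name`, `idx`, `value` and (when
#'   available) `sd`.
#' @export
fit_parameters <- function(fit) {
  stopifnot(inherits(fit, "vbwsas_fit"))
  out <- data.frame(name = fit$layout$name, idx = fit$layout$idx,
                    value = decode_pars(fit$par, fit$layout,
                                        fit$config$bounds))
  if (!is.null(fit$sd)) out$sd <- unname(fit$sd)
  out
}
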