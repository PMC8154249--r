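#' Experimental condition of a scattering curve
#'
#' Holds temperature, nominal w/v protein concentration, ionic strength and
#' pH, together with the temperature-corrected derived quantities used by the
#' forward model: the concentration rescaled by the thermal expansion of
#' water, the solvent (X-ray) scattering length density and the relative
#' dielectric constant of water at `temperature`.
#'
#' @param temperature absolute temperature in K.
#' @param c_nominal w/v protein concentration in g/L at the reference
#'   temperature 298.15 K.
#' @param ionic_strength mol/L.
#' @param pH solution pH (the default 7.0 is a documented assumption: pure
#'   water samples with no stated pH).
#' @return object of class `condition` with derived fields `c_T` (g/L),
#'   `solvent_sld` (Angstrom^-2) and `eps_r`.
#' @export
condition <- function(temperature, c_nominal, ionic_strength = 0, pH = 7.0) {
  stopifnot(temperature > 0, c_nominal > 0, ionic_strength >= 0)
  sp <- solvent_properties(temperature)
  structure(list(
    temperature = temperature,
    c_nominal = c_nominal,
    ionic_strength = ionic_strength,
    pH = pH,
    c_T = c_nominal * sp$density / solvent_properties(298.15)$density,
    solvent_sld = sp$sld,
    eps_r = sp$eps_r
  ), class = "sample_condition")
}

#' @export
print.sample_condition <- function(x, ...) {
  cat(sprintf("<condition>  T = %.2f K, c = %.2f g/L (c(T) = %.3f), I = %.3g M, pH = %.1f\n",
              x$temperature, x$c_nominal, x$c_T, x$ionic_strength, x$pH))
  invisible(x)
}

#' Construct a SAXS curve object
#'
#' @param q scattering-vector moduli in Angstrom^-1, strictly increasing.
#' @param intensity macroscopic differential scattering cross section in
#'   cm^-1 (absolute calibration; no free scale factor is permitted anywhere
#'   in the model).
#' @param sigma standard deviations in cm^-1, strictly positive.
#' @param condition a [condition()].
#' @param label curve label.
#' @return object of class `saxs_curve`.
#' @export
saxs_curve <- function(q, intensity, sigma, condition, label = "") {
  stopifnot(length(q) == length(intensity), length(q) == length(sigma))
  if (length(q) < 2) stop("curve must have at least 2 points")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be positive")
  stopifnot(inherits(condition, "sample_condition"))
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 condition = condition, label = label), class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("<saxs_curve %s>  %d points, q in [%.4g, %.4g] A^-1\n",
              x$label, length(x$q), min(x$q), max(x$q)))
  print(x$condition)
  invisible(x)
}

#' Read a SAXS curve from a 3-column ASCII file
#'
#' The file holds whitespace-separated columns `q I sigma` (Angstrom^-1,
#' cm^-1, cm^-1). '#'-prefixed header lines may carry the condition metadata
#' as `# key=value` pairs with keys `temperature_C`, `concentration_g_per_L`,
#' `ionic_strength_M` and `pH`; header values override the arguments. Rows
#' with non-positive sigma or non-finite entries are dropped with a message.
#'
#' @param path file path.
#' @param temperature_C,concentration_g_per_L,ionic_strength_M,pH defaults
#'   used when the header does not provide them.
#' @param q_range optional length-2 window (Angstrom^-1) to restrict q; the
#'   default keeps the full range. (A typical synchrotron window is
#'   0.022-0.41 Angstrom^-1.)
#' @param label curve label; defaults to the file name.
#' @return a [saxs_curve()].
#' @export
read_saxs_curve <- function(path, temperature_C = 25, concentration_g_per_L = NULL,
                            ionic_strength_M = 0, pH = 7.0, q_range = NULL,
                            label = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty curve file: ", path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    mt <- regmatches(h, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*([-0-9.eE+]+)", h))[[1]]
    if (length(mt) == 3) meta[[mt[2]]] <- as.numeric(mt[3])
  }
  if (!is.null(meta$temperature_C)) temperature_C <- meta$temperature_C
  if (!is.null(meta$concentration_g_per_L)) concentration_g_per_L <- meta$concentration_g_per_L
  if (!is.null(meta$ionic_strength_M)) ionic_strength_M <- meta$ionic_strength_M
  if (!is.null(meta$pH)) pH <- meta$pH
  if (is.null(concentration_g_per_L)) {
    stop("concentration_g_per_L missing from both header and arguments")
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no data rows in ", path)
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- unique(lengths(fields))
  if (any(ncol < 3)) stop("curve file must have 3 numeric columns: ", path)
  dat <- matrix(as.numeric(unlist(lapply(fields, `[`, 1:3))), ncol = 3,
                byrow = TRUE)
  keep <- is.finite(dat[, 1]) & is.finite(dat[, 2]) & is.finite(dat[, 3]) &
    dat[, 3] > 0 & dat[, 1] > 0
  if (any(!keep)) {
    message("read_saxs_curve: dropped ", sum(!keep),
            " rows with non-finite values or sigma <= 0")
    dat <- dat[keep, , drop = FALSE]
  }
  dat <- dat[order(dat[, 1]), , drop = FALSE]
  if (anyDuplicated(dat[, 1])) stop("non-monotone q grid (duplicated values)")
  if (!is.null(q_range)) {
    sel <- dat[, 1] >= q_range[1] & dat[, 1] <= q_range[2]
    dat <- dat[sel, , drop = FALSE]
  }
  cond <- condition(273.15 + temperature_C, concentration_g_per_L,
                    ionic_strength_M, pH)
  saxs_curve(dat[, 1], dat[, 2], dat[, 3], cond,
             label = if (is.null(label)) basename(path) else label)
}

#' Write a SAXS curve to the 3-column ASCII format
#'
#' Inverse of [read_saxs_curve()]; full double precision so a read/write
#' round trip is lossless.
#'
#' @param curve a [saxs_curve()].
#' @param path output path.
#' @export
write_saxs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  cond <- curve$condition
  hdr <- c(
    sprintf("# temperature_C=%.17g", cond$temperature - 273.15),
    sprintf("# concentration_g_per_L=%.17g", cond$c_nominal),
    sprintf("# ionic_strength_M=%.17g", cond$ionic_strength),
    sprintf("# pH=%.17g", cond$pH),
    "# q[A^-1]  I[cm^-1]  sigma[cm^-1]"
  )
  rows <- sprintf("%.17g %.17g %.17g", curve$q, curve$intensity, curve$sigma)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
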