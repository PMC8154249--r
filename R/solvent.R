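# Physical constants (CODATA); lengths in Angstrom, energies SI unless noted.
.const <- list(
  r_e_cm = 2.8179403262e-13,   # classical electron radius, cm
  N_A = 6.02214076e23,
  k_B = 1.380649e-23,          # J/K
  e_charge = 1.602176634e-19,  # C
  eps0 = 8.8541878128e-12,     # F/m
  R_gas = 8.31446261815324,    # J/mol/K
  M_water = 18.01528,          # g/mol
  Z_water = 10                 # electrons per molecule
)

#' Temperature-dependent properties of pure water
#'
#' Density from the Kell (1975) polynomial equation of state at atmospheric
#' pressure, X-ray scattering length density from the electron density, and
#' the relative dielectric constant from the Malmberg-Maryott empirical fit.
#' These feed the temperature corrections of the protein concentration, the
#' solvent contrast and the screened-Coulomb potential.
#'
#' @param temperature absolute temperature in K, in (273, 373).
#' @return list with `density` (g/cm^3), `sld` (Angstrom^-2), `eps_r`.
#' @export
solvent_properties <- function(temperature) {
  if (any(temperature <= 273) || any(temperature >= 373)) {
    stop("temperature out of the liquid-water range (273, 373) K")
  }
  t <- temperature - 273.15
  dens <- (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
             46.170461e-6 * t^3 + 105.56302e-9 * t^4 -
             280.54253e-12 * t^5) / (1 + 16.879850e-3 * t) / 1000
  # electron density in e/A^3, times r_e (in A) gives SLD in A^-2
  e_dens <- dens * (.const$Z_water / .const$M_water) * .const$N_A * 1e-24
  sld <- e_dens * (.const$r_e_cm * 1e8)
  eps_r <- 87.740 - 0.40008 * t + 9.398e-4 * t^2 - 1.410e-6 * t^3
  list(density = dens, sld = sld, eps_r = eps_r)
}

#' Inverse Debye screening length
#'
#' Standard Debye-Hueckel expression for a 1:1 electrolyte of ionic strength
#' `ionic_strength`: kappa_D^2 = 8 pi lambda_B n_ion, with lambda_B the
#' Bjerrum length at (`temperature`, `eps_r`).
#'
#' @param ionic_strength mol/L.
#' @param temperature K.
#' @param eps_r relative dielectric constant; defaults to pure water at
#'   `temperature`.
#' @return kappa_D in Angstrom^-1 (0 at zero ionic strength).
#' @export
debye_kappa <- function(ionic_strength, temperature,
                        eps_r = solvent_properties(temperature)$eps_r) {
  stopifnot(ionic_strength >= 0)
  lb <- bjerrum_length(temperature, eps_r)
  n_ion <- ionic_strength * .const$N_A * 1e-27  # ions per A^3
  sqrt(8 * pi * lb * n_ion)
}

# Bjerrum length in Angstrom.
bjerrum_length <- function(temperature, eps_r) {
  .const$e_charge^2 /
    (4 * pi * .const$eps0 * eps_r * .const$k_B * temperature) * 1e10
}

# Intrinsic side-chain / terminal pKa values at the reference temperature
# (Nozaki-Tanford style table). Swappable through the pKa_table argument of
# net_charge().
.default_pka <- c(D = 4.0, E = 4.4, H = 6.3, C = 8.3, Y = 9.6,
                  K = 10.4, R = 12.0, Nterm = 9.0, Cterm = 3.6)

#' Net charge of a protein from its sequence
#'
#' Henderson-Hasselbalch sum over the titratable side chains (D, E, H, C, Y,
#' K, R) and the two termini:
#' Z = sum_basic 1/(1+10^(pH-pKa)) - sum_acidic 1/(1+10^(pKa-pH)).
#' The pKa values are taken at the reference temperature; no explicit
#' temperature correction of pKa is applied.
#'
#' @param sequence one-letter amino-acid string.
#' @param pH solution pH.
#' @param pKa_table named numeric vector with entries D, E, H, C, Y, K, R,
#'   Nterm, Cterm.
#' @param termini include the terminal groups (default TRUE).
#' @return net charge in elementary charges (signed).
#' @export
net_charge <- function(sequence, pH = 7.0, pKa_table = .default_pka,
                       termini = TRUE) {
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  ok <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  if (!all(aa %in% ok)) {
    stop("unknown residue letter(s): ",
         paste(unique(aa[!aa %in% ok]), collapse = ", "))
  }
  basic_frac <- function(pka) 1 / (1 + 10^(pH - pka))
  acid_frac <- function(pka) -1 / (1 + 10^(pka - pH))
  z <- 0
  for (r in c("K", "R", "H")) z <- z + sum(aa == r) * basic_frac(pKa_table[[r]])
  for (r in c("D", "E", "C", "Y")) z <- z + sum(aa == r) * acid_frac(pKa_table[[r]])
  if (termini) {
    z <- z + basic_frac(pKa_table[["Nterm"]]) + acid_frac(pKa_table[["Cterm"]])
  }
  unname(z)
}

#' Canonical alpha-synuclein sequence with optional point mutations
#'
#' Returns the 140-residue human alpha-synuclein primary sequence (UniProt
#' P37840), optionally with point mutations applied ("E46K" style notation).
#'
#' @param mutations character vector like `c("E46K")`; empty for wild type.
#' @return one-letter sequence string.
#' @export
alpha_synuclein_sequence <- function(mutations = character()) {
  seq <- paste0(
    "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTK",
    "EQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP",
    "DNEAYEMPSEEGYQDYEPEA")
  aa <- strsplit(seq, "")[[1]]
  for (mut in mutations) {
    mt <- regmatches(mut, regexec("^([A-Z])(\\d+)([A-Z])$", mut))[[1]]
    if (length(mt) != 4) stop("malformed mutation: ", mut)
    pos <- as.integer(mt[3])
    if (pos < 1 || pos > length(aa)) stop("mutation out of range: ", mut)
    if (aa[pos] != mt[2]) {
      stop("mutation ", mut, ": position ", pos, " is ", aa[pos], " not ", mt[2])
    }
    aa[pos] <- mt[4]
  }
  paste(aa, collapse = "")
}
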