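# Physical constants and element data used package-wide.
# Units fixed repo-wide: coordinates Angstrom, energies kcal/mol,
# frequencies cm^-1, torsions degrees in [-180, 180), masses amu (Da).

# CODATA-2018 derived
.const <- list(
  kB_J      = 1.380649e-23,        # J/K
  h_J       = 6.62607015e-34,      # J s
  c_cm      = 2.99792458e10,       # cm/s
  N_A       = 6.02214076e23,
  amu_kg    = 1.66053906660e-27,
  R_kcal    = 1.987204259e-3,      # kcal/mol/K
  hc_kcal   = 2.859144e-3,         # kcal/mol per cm^-1
  proton_Da = 1.007276466621,
  atm_Pa    = 101325
)

# sqrt(kcal/mol / (A^2 amu)) -> cm^-1 for harmonic frequencies
.freq_conv <- local({
  kcal_per_mol_J <- 4184 / .const$N_A
  lam <- kcal_per_mol_J / (1e-20 * .const$amu_kg)  # s^-2 per unit eigenvalue
  sqrt(lam) / (2 * pi * .const$c_cm)
})

# Monoisotopic masses (most abundant isotope), standard atomic weights, and
# IUPAC isotopic compositions (mass Da, abundance) for the CHNOS elements
# relevant to peptides.
.elements <- list(
  H = list(
    weight = 1.008, mono = 1.0078250319,
    isotopes = data.frame(mass = c(1.0078250319, 2.0141017781),
                          abundance = c(0.999885, 0.000115))
  ),
  C = list(
    weight = 12.011, mono = 12.0,
    isotopes = data.frame(mass = c(12.0, 13.0033548351),
                          abundance = c(0.9893, 0.0107))
  ),
  N = list(
    weight = 14.007, mono = 14.0030740052,
    isotopes = data.frame(mass = c(14.0030740052, 15.0001088989),
                          abundance = c(0.99636, 0.00364))
  ),
  O = list(
    weight = 15.999, mono = 15.9949146221,
    isotopes = data.frame(mass = c(15.9949146221, 16.9991315, 17.9991604),
                          abundance = c(0.99757, 0.00038, 0.00205))
  ),
  S = list(
    weight = 32.06, mono = 31.97207069,
    isotopes = data.frame(mass = c(31.97207069, 32.9714585, 33.96786683, 35.96708088),
                          abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
  )
)

# Covalent radii (A) for bond-length references in the internal force field
.cov_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

# Lennard-Jones parameters (sigma A, epsilon kcal/mol), UFF-flavoured
.lj_params <- list(
  H = c(sigma = 2.57, eps = 0.044),
  C = c(sigma = 3.43, eps = 0.105),
  N = c(sigma = 3.26, eps = 0.069),
  O = c(sigma = 3.12, eps = 0.060),
  S = c(sigma = 3.59, eps = 0.274)
)

.element_mass <- function(sym) {
  el <- .elements[[sym]]
  if (is.null(el)) stop("unknown element: ", sym)
  el$weight
}

#' Degrees wrapped into \[-180, 180)
#' @param x angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap_angle <- function(x) ((x + 180) %% 360) - 180
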