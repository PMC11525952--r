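# Rigid-rotor / harmonic-oscillator thermochemistry and the free-energy
# crossover analysis between conformers. The mechanism of interest: a
# salt-bridge (zwitterionic) conformer is stiffer than a charge-solvated
# one, so its entropy grows more slowly with temperature and its free
# energy can cross above the softer conformer's at finite T.

#' Thermochemistry input for one conformer
#'
#' @param energy electronic energy (kcal/mol)
#' @param frequencies vibrational frequencies (cm^-1), all > 0
#' @param mass total mass (amu); required for translational terms
#' @param inertia principal moments of inertia (amu A^2, length 3 for a
#'   nonlinear top); NULL drops rotational contributions
#' @param symmetry rotational symmetry number (default 1)
#' @param quasi_harmonic raise frequencies below 50 cm^-1 to 50 cm^-1
#'   before evaluating partition functions (default FALSE)
#' @return object of class `thermo_input`
#' @export
thermo_input <- function(energy, frequencies, mass = NULL, inertia = NULL,
                         symmetry = 1, quasi_harmonic = FALSE) {
  if (any(frequencies <= 0))
    stop("all vibrational frequencies must be positive")
  structure(list(energy = energy, frequencies = frequencies, mass = mass,
                 inertia = inertia, symmetry = symmetry,
                 quasi_harmonic = quasi_harmonic),
            class = "thermo_input")
}

.effective_freqs <- function(inp) {
  f <- inp$frequencies
  if (isTRUE(inp$quasi_harmonic)) pmax(f, 50) else f
}

#' Zero-point vibrational energy
#' @param inp a `thermo_input`
#' @return ZPE (kcal/mol), sum of hc nu / 2 over modes
#' @export
zpe <- function(inp) sum(.const$hc_kcal * .effective_freqs(inp)) / 2

# vibrational Helmholtz contribution beyond ZPE and entropy (kcal/mol)
.vib_terms <- function(freqs, T) {
  x <- .const$hc_kcal * freqs / (.const$R_kcal * T)  # hv/kT
  # thermal energy and entropy, standard HO closed forms
  ex <- exp(-x)
  U <- .const$R_kcal * T * sum(x * ex / (1 - ex))
  S <- .const$R_kcal * sum(x * ex / (1 - ex) - log(1 - ex))
  list(U = U, S = S)
}

.trans_terms <- function(mass, T) {
  # Sackur-Tetrode at 1 atm
  m <- mass * .const$amu_kg
  lambda <- .const$h_J / sqrt(2 * pi * m * .const$kB_J * T)
  V <- .const$kB_J * T / .const$atm_Pa
  q <- V / lambda^3
  S <- .const$R_kcal * (log(q) + 5 / 2)
  U <- 1.5 * .const$R_kcal * T
  list(U = U, S = S)
}

.rot_terms <- function(inertia, symmetry, T) {
  I_SI <- inertia * .const$amu_kg * 1e-20
  theta <- .const$h_J^2 / (8 * pi^2 * I_SI * .const$kB_J)  # K per axis
  q <- sqrt(pi) / symmetry * sqrt(T^3 / prod(theta))
  S <- .const$R_kcal * (log(q) + 3 / 2)
  U <- 1.5 * .const$R_kcal * T
  list(U = U, S = S)
}

#' Entropy at temperature T
#' @param inp a `thermo_input`
#' @param T temperature (K)
#' @return entropy (kcal/mol/K)
#' @export
entropy <- function(inp, T) {
  stopifnot(all(T > 0))
  vapply(T, function(t) {
    S <- .vib_terms(.effective_freqs(inp), t)$S
    if (!is.null(inp$mass)) S <- S + .trans_terms(inp$mass, t)$S
    if (!is.null(inp$inertia))
      S <- S + .rot_terms(inp$inertia, inp$symmetry, t)$S
    S
  }, numeric(1))
}

#' Gibbs free energy at temperature T
#'
#' G = E_elec + ZPE + U_thermal + pV(= RT) - T S, with harmonic-oscillator
#' vibrational, rigid-rotor rotational (when inertia given) and ideal-gas
#' translational (when mass given) contributions at 1 atm.
#'
#' @param inp a `thermo_input`
#' @param T temperature(s) (K)
#' @return G (kcal/mol), vectorized over T
#' @export
free_energy <- function(inp, T) {
  stopifnot(all(T > 0))
  vapply(T, function(t) {
    freqs <- .effective_freqs(inp)
    v <- .vib_terms(freqs, t)
    U <- v$U; S <- v$S
    pV <- 0
    if (!is.null(inp$mass)) {
      tr <- .trans_terms(inp$mass, t)
      U <- U + tr$U; S <- S + tr$S
      pV <- .const$R_kcal * t
    }
    if (!is.null(inp$inertia)) {
      ro <- .rot_terms(inp$inertia, inp$symmetry, t)
      U <- U + ro$U; S <- S + ro$S
    }
    inp$energy + zpe(inp) + U + pV - t * S
  }, numeric(1))
}

#' Free-energy crossover between two conformers
#'
#' Scans dG(T) = G_b(T) - G_a(T) on a 1 K grid over the range, refines each
#' sign change by bisection, and reports the crossover temperature(s). Both
#' inputs must describe the same complex (equal total mass when given).
#'
#' @param a,b `thermo_input`s
#' @param range temperature range (K), default `c(10, 400)`
#' @param tol bisection tolerance (K, default 0.01)
#' @return object of class `crossover_result`: `temperature` (first
#'   crossover or NA), `all_temperatures`, `multiple` flag, `dG` function
#'   and components `dE`, `dZPE`
#' @export
crossover_temperature <- function(a, b, range = c(10, 400), tol = 0.01) {
  if (!is.null(a$mass) && !is.null(b$mass) &&
      abs(a$mass - b$mass) > 1e-6)
    stop("conformers differ in total mass; not the same complex")
  dG <- function(T) free_energy(b, T) - free_energy(a, T)
  Ts <- seq(range[1], range[2], by = 1)
  if (Ts[length(Ts)] != range[2]) Ts <- c(Ts, range[2])
  vals <- dG(Ts)
  sgn <- sign(vals)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- numeric(0)
  for (k in flips) {
    lo <- Ts[k]; hi <- Ts[k + 1]
    flo <- vals[k]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- dG(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  # exact grid hits
  roots <- sort(unique(c(roots, Ts[vals == 0])))
  structure(list(
    temperature = if (length(roots)) roots[1] else NA_real_,
    all_temperatures = roots,
    multiple = length(roots) > 1,
    dG = dG,
    dE = b$energy - a$energy,
    dZPE = zpe(b) - zpe(a),
    range = range), class = "crossover_result")
}

#' Principal moments of inertia of a conformation
#' @param conf a `conformation`
#' @return length-3 numeric (amu A^2), ascending
#' @export
moments_of_inertia <- function(conf) {
  m <- vapply(conf$topology$atoms$element, .element_mass, numeric(1))
  xyz <- sweep(conf$coords, 2, colSums(conf$coords * m) / sum(m))
  I <- matrix(0, 3, 3)
  r2 <- rowSums(xyz^2)
  for (a_ in 1:3) for (b_ in 1:3)
    I[a_, b_] <- sum(m * ((a_ == b_) * r2 - xyz[, a_] * xyz[, b_]))
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}
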