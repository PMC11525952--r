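# Harmonic IR prediction and matching: stick spectra from mass-weighted
# Hessians, region-wise empirical frequency scaling (0.955 for the 3 um
# hydride-stretch region, 0.983 for the 6 um fingerprint region), Gaussian
# broadening, cosine-similarity matching against experimental traces and
# the free-OH-stretch diagnostic that separates charge-solvated from
# zwitterionic conformers.

#' Region-wise frequency scaling scheme
#'
#' Harmonic frequencies above the boundary (hydride-stretch, ~3 um region)
#' are multiplied by `high_factor`; below (fingerprint, ~6 um region) by
#' `low_factor`. The default boundary of 2500 cm^-1 separates the two
#' regions cleanly.
#'
#' @param boundary region boundary (cm^-1), in (1800, 2800)
#' @param high_factor scale factor for the 3 um region (default 0.955)
#' @param low_factor scale factor for the 6 um region (default 0.983)
#' @return object of class `scaling_scheme`
#' @export
scaling_scheme <- function(boundary = 2500, high_factor = 0.955,
                           low_factor = 0.983) {
  stopifnot(boundary > 1800, boundary < 2800,
            high_factor > 0.8, high_factor < 1.05,
            low_factor > 0.8, low_factor < 1.05)
  structure(list(boundary = boundary, high_factor = high_factor,
                 low_factor = low_factor), class = "scaling_scheme")
}

#' Construct a stick spectrum
#' @param frequency vibrational frequencies (cm^-1)
#' @param intensity intensities (km/mol or arbitrary), default unit
#' @param conformer conformer label for provenance
#' @param scaled whether empirical scaling has been applied
#' @return object of class `stick_spectrum`
#' @export
stick_spectrum <- function(frequency, intensity = NULL, conformer = "",
                           scaled = FALSE) {
  if (is.null(intensity)) intensity <- rep(1, length(frequency))
  stopifnot(length(frequency) == length(intensity), all(intensity >= 0))
  ord <- order(frequency)
  structure(list(frequency = frequency[ord], intensity = intensity[ord],
                 provenance = list(conformer = conformer, scaled = scaled)),
            class = "stick_spectrum")
}

#' Experimental trace container
#' @param wavenumber strictly ascending grid (cm^-1)
#' @param intensity intensity array, same length
#' @param kind "gain" or "depletion"
#' @return object of class `experimental_trace`
#' @export
experimental_trace <- function(wavenumber, intensity,
                               kind = c("gain", "depletion")) {
  kind <- match.arg(kind)
  stopifnot(length(wavenumber) == length(intensity),
            all(diff(wavenumber) > 0))
  structure(list(wavenumber = wavenumber, intensity = intensity, kind = kind),
            class = "experimental_trace")
}

#' Harmonic stick spectrum from a mass-weighted Hessian
#'
#' Frequencies are the square roots of the positive eigenvalues converted to
#' cm^-1; the 6 smallest-magnitude modes (5 for linear systems) are dropped
#' as translations/rotations. Any remaining significantly imaginary mode
#' means the geometry is not a minimum and is an error.
#'
#' @param hess a `hessian_result` (or a mass-weighted 3N x 3N matrix)
#' @param intensities optional per-mode intensities after dropping
#'   trans/rot modes; default unit intensities
#' @param linear TRUE for linear systems (5 zero modes)
#' @param imag_tol threshold (cm^-1) above which an imaginary frequency is
#'   significant (default 5)
#' @param conformer provenance label
#' @return an unscaled `stick_spectrum`
#' @export
harmonic_spectrum <- function(hess, intensities = NULL, linear = FALSE,
                              imag_tol = 5, conformer = "") {
  H <- if (inherits(hess, "hessian_result")) hess$matrix else hess
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  freqs <- sign(ev) * sqrt(abs(ev)) * .freq_conv
  nzero <- if (linear) 5L else 6L
  ord <- order(abs(freqs))
  vib <- freqs[ord][-seq_len(nzero)]
  imag <- vib[vib < -imag_tol]
  if (length(imag))
    stop("not a minimum: imaginary frequencies ",
         paste(sprintf("%.1fi", abs(imag)), collapse = ", "), " cm^-1")
  vib <- sort(vib[vib > 0])
  if (!is.null(intensities) && length(intensities) != length(vib))
    stop("expected ", length(vib), " intensities")
  stick_spectrum(vib, intensities, conformer = conformer, scaled = FALSE)
}

#' Apply region-wise empirical scaling to a stick spectrum
#'
#' Refuses to scale twice.
#'
#' @param s an unscaled `stick_spectrum`
#' @param scheme a [scaling_scheme()]
#' @return the scaled `stick_spectrum`
#' @export
apply_scaling <- function(s, scheme = scaling_scheme()) {
  if (isTRUE(s$provenance$scaled))
    stop("spectrum is already scaled; refusing to scale twice")
  f <- ifelse(s$frequency >= scheme$boundary, scheme$high_factor,
              scheme$low_factor)
  stick_spectrum(s$frequency * f, s$intensity,
                 conformer = s$provenance$conformer, scaled = TRUE)
}

#' Broaden a stick spectrum into a continuous curve
#'
#' Sum of unit-area Gaussians (one per stick, weighted by stick intensity)
#' evaluated on the given wavenumber grid; on a grid wide enough to cover
#' all sticks the integral equals the total stick intensity.
#'
#' @param s a `stick_spectrum`
#' @param fwhm Gaussian full width at half maximum (cm^-1, default 8)
#' @param grid wavenumber grid; default covers sticks with a 5*fwhm margin
#'   at 0.5 cm^-1 spacing
#' @return an `experimental_trace`-shaped curve (kind "gain")
#' @export
broaden <- function(s, fwhm = 8, grid = NULL) {
  stopifnot(fwhm > 0)
  if (is.null(grid)) {
    if (!length(s$frequency)) grid <- seq(0, 1, length.out = 2)
    else grid <- seq(min(s$frequency) - 5 * fwhm, max(s$frequency) + 5 * fwhm,
                     by = 0.5)
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  y <- numeric(length(grid))
  for (k in seq_along(s$frequency)) {
    y <- y + s$intensity[k] *
      exp(-(grid - s$frequency[k])^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  }
  if (length(s$frequency) &&
      (min(s$frequency) < min(grid) || max(s$frequency) > max(grid)))
    warning("grid does not cover all sticks")
  experimental_trace(grid, y, kind = "gain")
}

#' Match a computed curve against an experimental trace
#'
#' Both inputs are interpolated to the common wavenumber range, baseline
#' subtracted (mean-centered) and max-normalized; the score is the cosine
#' similarity, in \[-1, 1\] (a trace against its own negation scores -1).
#' Depletion traces are inverted to positive-going before scoring.
#'
#' @param curve computed curve (`experimental_trace` from [broaden()])
#' @param trace measured `experimental_trace`
#' @return scalar in \[-1, 1\]
#' @export
match_score <- function(curve, trace) {
  lo <- max(min(curve$wavenumber), min(trace$wavenumber))
  hi <- min(max(curve$wavenumber), max(trace$wavenumber))
  if (lo >= hi) stop("no overlap between curve and trace wavenumber ranges")
  grid <- seq(lo, hi, length.out = 512)
  yt <- trace$intensity
  if (trace$kind == "depletion") yt <- -yt
  a <- stats::approx(curve$wavenumber, curve$intensity, grid)$y
  b <- stats::approx(trace$wavenumber, yt, grid)$y
  norm_prep <- function(v) {
    v <- v - mean(v)
    m <- max(abs(v))
    if (m > 0) v / m else v
  }
  a <- norm_prep(a); b <- norm_prep(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Free-OH-stretch diagnostic
#'
#' TRUE iff at least one stick of a scaled spectrum lies in the free-OH
#' window (closed interval, default 3550-3600 cm^-1). Charge-solvated (pn)
#' conformers with an unbound carboxyl OH show this band; zwitterionic (pz)
#' ones do not.
#'
#' @param s a scaled `stick_spectrum`
#' @param window length-2 numeric, default `c(3550, 3600)`
#' @return logical
#' @export
free_oh_diagnostic <- function(s, window = c(3550, 3600)) {
  any(s$frequency >= window[1] & s$frequency <= window[2])
}
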