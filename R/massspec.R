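# Electrospray MS arithmetic for the [nM + zH]^z+ oligomer series:
# monoisotopic/average m/z, exact isotope-envelope computation by
# convolution over element isotope tables, non-negative mixture
# decomposition of overlapping peaks, and (n, z) assignment.

#' Ion formula
#'
#' @param counts named integer vector of element counts (e.g.
#'   `c(C = 18, H = 20, N = 2, O = 3)`) of the *neutral* molecule
#' @param z number of added protons = ion charge (>= 1 for ions, 0 allowed
#'   for neutral-mass queries)
#' @return object of class `ion_formula`
#' @export
ion_formula <- function(counts, z = 1L) {
  stopifnot(all(counts >= 0), z >= 0)
  unknown <- setdiff(names(counts), names(.elements))
  if (length(unknown)) stop("unknown element: ", paste(unknown, collapse = ", "))
  structure(list(counts = counts[counts > 0], z = as.integer(z)),
            class = "ion_formula")
}

#' Formula of the oligomer ion \[n M + z H\]^z+
#' @param monomer named element-count vector of the neutral monomer unit
#'   (default diphenylalanine C18H20N2O3)
#' @param n oligomer size
#' @param z charge (added protons)
#' @return an `ion_formula`
#' @export
oligomer_ion <- function(n, z, monomer = c(C = 18, H = 20, N = 2, O = 3)) {
  ion_formula(monomer * n, z = z)
}

#' m/z of an ion formula
#'
#' (sum of atomic masses + z * proton mass) / z using monoisotopic masses or
#' standard atomic weights. The electron mass is neglected.
#'
#' @param formula an `ion_formula`
#' @param mode "monoisotopic" or "average"
#' @return m/z in Th (for z = 0, the neutral mass in Da)
#' @export
mz <- function(formula, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (!length(formula$counts) && formula$z == 0) stop("empty formula")
  masses <- vapply(names(formula$counts), function(e)
    if (mode == "monoisotopic") .elements[[e]]$mono else .elements[[e]]$weight,
    numeric(1))
  total <- sum(masses * formula$counts) + formula$z * .const$proton_Da
  if (formula$z >= 1) total / formula$z else total
}

#' Round-half-up to the nearest integer Th
#' @param x m/z value(s)
#' @return integer(s)
#' @export
nominal_mz <- function(x) floor(x + 0.5)

# ---- isotope envelopes --------------------------------------------------

# distribution of one element with n atoms: data.frame(mass, prob), exact
# multinomial expansion via n-fold convolution with pruning
.element_distribution <- function(element, n, prune = 1e-16) {
  iso <- .elements[[element]]$isotopes
  base <- data.frame(mass = iso$mass, prob = iso$abundance)
  if (n == 0) return(data.frame(mass = 0, prob = 1))
  acc <- base
  for (k in seq_len(n - 1)) {
    acc <- .convolve_dist(acc, base, prune)
  }
  acc
}

# convolve two (mass, prob) distributions, aggregating at 1e-6 Da resolution
.convolve_dist <- function(a, b, prune = 1e-16) {
  mass <- outer(a$mass, b$mass, "+")
  prob <- outer(a$prob, b$prob)
  key <- round(mass * 1e6)
  agg_p <- tapply(as.vector(prob), as.vector(key), sum)
  agg_m <- tapply(as.vector(mass * prob), as.vector(key), sum) / agg_p
  out <- data.frame(mass = as.numeric(agg_m), prob = as.numeric(agg_p))
  out <- out[out$prob > prune, ]
  out[order(out$mass), ]
}

#' Isotope envelope of an ion formula
#'
#' Exact convolution over the element isotope tables; isotopologues are
#' aggregated into unit nominal-mass bins (spacing 1/z Th on the m/z axis),
#' pruned below `prune` and renormalized to sum 1. With `profile = TRUE`
#' the unaggregated isotopologue list is returned instead.
#'
#' @param formula an `ion_formula` with z >= 1
#' @param prune relative-abundance prune threshold, in (0, 1e-3\]
#' @param profile return unbinned isotopologues
#' @return object of class `isotope_envelope`: data.frame `peaks` with
#'   columns `mz`, `abundance` (ascending m/z, abundances summing to 1)
#' @export
isotope_envelope <- function(formula, prune = 1e-6, profile = FALSE) {
  stopifnot(prune > 0, prune <= 1e-3, formula$z >= 1)
  dist <- data.frame(mass = formula$z * .const$proton_Da, prob = 1)
  for (e in names(formula$counts))
    dist <- .convolve_dist(dist, .element_distribution(e, formula$counts[[e]]),
                           prune = 1e-15)
  if (!profile) {
    mono <- min(dist$mass)
    bin <- round(dist$mass - mono)        # extra-neutron count
    p <- tapply(dist$prob, bin, sum)
    m <- tapply(dist$mass * dist$prob, bin, sum) / p
    dist <- data.frame(mass = as.numeric(m), prob = as.numeric(p))
  }
  dist <- dist[dist$prob / max(dist$prob) > prune, ]
  dist$prob <- dist$prob / sum(dist$prob)
  structure(list(peaks = data.frame(mz = dist$mass / formula$z,
                                    abundance = dist$prob),
                 z = formula$z),
            class = "isotope_envelope")
}

#' Align component envelopes onto a measured m/z grid
#'
#' Each component's peaks are accumulated into the nearest measured grid
#' position (within `tol` Th); peaks matching no grid point are dropped.
#'
#' @param components list of `isotope_envelope`
#' @param grid measured m/z values (ascending)
#' @param tol matching tolerance (Th, default 0.5 / max z)
#' @return matrix, length(grid) x length(components)
#' @export
align_envelopes <- function(components, grid, tol = NULL) {
  if (is.null(tol))
    tol <- 0.5 / max(vapply(components, `[[`, 1L, "z"))
  A <- matrix(0, length(grid), length(components))
  for (c_ in seq_along(components)) {
    pk <- components[[c_]]$peaks
    for (r in seq_len(nrow(pk))) {
      d <- abs(grid - pk$mz[r])
      k <- which.min(d)
      if (d[k] <= tol) A[k, c_] <- A[k, c_] + pk$abundance[r]
    }
  }
  A
}

# Lawson-Hanson active-set non-negative least squares
.nnls <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.vector(t(A) %*% (b - A %*% x))
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      s <- numeric(n)
      s[passive] <- qr.solve(Ap, b)
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- as.vector(t(A) %*% (b - A %*% x))
  }
  x
}

#' Decompose a measured envelope into a mixture of calculated envelopes
#'
#' Non-negative least squares of the measured abundances against the
#' aligned component envelopes, with fractions renormalized to sum to 1.
#' The fit is scale-invariant in the measured intensities.
#'
#' @param measured `isotope_envelope` or data.frame with `mz`, `abundance`
#' @param components list of `isotope_envelope`
#' @param tol alignment tolerance passed to [align_envelopes()]
#' @return object of class `mixture_fit`: `fractions`, `residual` (relative
#'   L2 residual), `degenerate` flag, `design` matrix
#' @export
fit_mixture <- function(measured, components, tol = NULL) {
  pk <- if (inherits(measured, "isotope_envelope")) measured$peaks
        else as.data.frame(measured)
  b <- pk$abundance / sum(pk$abundance)
  A <- align_envelopes(components, pk$mz, tol = tol)
  degenerate <- FALSE
  if (ncol(A) > 1) {
    cc <- suppressWarnings(stats::cor(A))
    degenerate <- any(cc[upper.tri(cc)] > 1 - 1e-9, na.rm = TRUE)
    if (degenerate)
      warning("degenerate (near-identical) components; fit still returned")
  }
  x <- .nnls(A, b)
  res <- sqrt(sum((b - A %*% x)^2)) / sqrt(sum(b^2))
  fr <- if (sum(x) > 0) x / sum(x) else x
  structure(list(fractions = fr, residual = res, degenerate = degenerate,
                 design = A), class = "mixture_fit")
}

#' Assign oligomer size and charge to a peak
#'
#' Enumerates (n, z) over the given ranges and returns candidates whose
#' computed m/z (both monoisotopic and average conventions) falls within
#' `tol` Th of the observed value, ordered by |error|.
#'
#' @param mz_obs observed m/z (Th)
#' @param monomer neutral monomer element counts
#' @param n_range,z_range candidate ranges
#' @param tol matching tolerance (Th, default 1)
#' @return data.frame with columns `n`, `z`, `mode`, `mz`, `error`
#' @export
assign_peak <- function(mz_obs, monomer = c(C = 18, H = 20, N = 2, O = 3),
                        n_range = 1:14, z_range = 1:3, tol = 1) {
  out <- NULL
  for (z_ in z_range) for (n_ in n_range) {
    f <- oligomer_ion(n_, z_, monomer)
    for (mode in c("monoisotopic", "average")) {
      m <- mz(f, mode)
      if (abs(m - mz_obs) <= tol)
        out <- rbind(out, data.frame(n = n_, z = z_, mode = mode, mz = m,
                                     error = m - mz_obs))
    }
  }
  if (is.null(out))
    return(data.frame(n = integer(), z = integer(), mode = character(),
                      mz = numeric(), error = numeric()))
  out[order(abs(out$error)), ]
}
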