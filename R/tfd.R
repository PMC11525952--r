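# Torsion fingerprint deviation (TFD): normalized weighted mean of periodic
# torsion-angle deviations between conformers of the same molecule, and the
# greedy uniqueness filter built on it.

#' Construct a torsion fingerprint
#'
#' @param values torsion angles in degrees (wrapped into \[-180, 180))
#' @param weights per-torsion non-negative weights (default uniform)
#' @param periods per-torsion symmetry periods in degrees: 180 for torsions
#'   ending on 2-fold symmetric groups (phenyl, carboxylate), else 360
#' @return object of class `torsion_fingerprint`
#' @export
torsion_fingerprint <- function(values, weights = NULL, periods = NULL) {
  values <- wrap_angle(as.numeric(values))
  n <- length(values)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(periods)) periods <- rep(360, n)
  stopifnot(length(weights) == n, length(periods) == n,
            all(weights >= 0), any(weights > 0))
  structure(list(values = values, weights = weights, periods = periods),
            class = "torsion_fingerprint")
}

#' Fingerprint of a conformation
#'
#' Measures all rotatable torsions and attaches the topology's
#' auto-assigned symmetry periods.
#'
#' @param conf a `conformation`
#' @param weights optional per-torsion weights
#' @return a `torsion_fingerprint`
#' @export
conf_fingerprint <- function(conf, weights = NULL) {
  torsion_fingerprint(get_torsions(conf), weights = weights,
                      periods = conf$topology$torsion_periods)
}

# minimal periodic deviation respecting a symmetry period
.periodic_dev <- function(da, period) {
  d <- abs(da) %% period
  pmin(d, period - d)
}

#' Torsion fingerprint deviation between two conformers
#'
#' TFD = sum_i w_i d_i / 180 / sum_i w_i with d_i the minimal periodic
#' angular deviation of torsion i under its symmetry period. Symmetric,
#' bounded in \[0, 1\], and 0 iff all deviations vanish.
#'
#' @param a,b `torsion_fingerprint`s (or `conformation`s) over the same
#'   torsion list
#' @return scalar in \[0, 1\]
#' @export
tfd <- function(a, b) {
  if (inherits(a, "conformation")) a <- conf_fingerprint(a)
  if (inherits(b, "conformation")) b <- conf_fingerprint(b)
  if (length(a$values) != length(b$values))
    stop("mismatched torsion counts: ", length(a$values), " vs ",
         length(b$values))
  d <- .periodic_dev(a$values - b$values, a$periods)
  sum(a$weights * d / 180) / sum(a$weights)
}

#' Greedy uniqueness filter by TFD
#'
#' One pass in input order: a conformer is kept iff its TFD to every
#' already-kept conformer is at least `threshold`. Output preserves input
#' order.
#'
#' @param confs list of `conformation`
#' @param threshold uniqueness threshold in (0, 1), default 0.05
#' @return the unique sub-list
#' @export
dedupe <- function(confs, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  kept <- list(); kept_fp <- list()
  for (conf in confs) {
    fp <- conf_fingerprint(conf)
    unique_ <- TRUE
    for (kf in kept_fp) {
      if (tfd(fp, kf) < threshold) { unique_ <- FALSE; break }
    }
    if (unique_) {
      kept[[length(kept) + 1]] <- conf
      kept_fp[[length(kept_fp) + 1]] <- fp
    }
  }
  kept
}
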