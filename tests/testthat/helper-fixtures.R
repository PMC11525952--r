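# Shared fixtures built in code: tiny constructed geometries with known
# interaction patterns, a diatomic spring backend, and independent oracle
# implementations used to cross-check package routines.

# 4-atom N-H ... O=C fragment with adjustable D-A distance and D-H-A angle
hbond_fixture <- function(d_DA = 2.9, angle = 180) {
  el <- c("N", "H", "O", "C")
  # donor at origin, H along +x; acceptor placed so the D-H-A angle at H
  # takes the requested value with |D-A| = d_DA
  dh <- 1.0
  # law of cosines for |H-A| given |D-A|, |D-H| and the angle at H
  th <- angle * pi / 180
  ha <- dh * cos(th) + sqrt(d_DA^2 - dh^2 * sin(th)^2)
  a_pos <- c(dh, 0, 0) + ha * c(cos(pi - th), sin(pi - th), 0)
  coords <- rbind(c(0, 0, 0), c(dh, 0, 0), a_pos, a_pos + c(1.2, 0, 0))
  topo <- simple_topology(el, coords,
                          data.frame(i = c(1, 3), j = c(2, 4),
                                     order = c(1, 2)))
  conformation(topo, coords)
}

# diatomic with a single harmonic bond spring (analytic gradient)
diatomic_backend <- function(k = 500, d0 = 1.2) {
  energy_backend(
    name = "diatomic-spring",
    energy = function(conf) {
      d <- sqrt(sum((conf$coords[1, ] - conf$coords[2, ])^2))
      k * (d - d0)^2
    },
    gradient = function(conf) {
      v <- conf$coords[1, ] - conf$coords[2, ]
      d <- sqrt(sum(v^2))
      g <- 2 * k * (d - d0) * v / d
      rbind(g, -g)
    },
    space = "cartesian")
}

diatomic_conf <- function(d = 1.2, elements = c("C", "O")) {
  topo <- simple_topology(elements, rbind(c(0, 0, 0), c(d, 0, 0)),
                          data.frame(i = 1, j = 2, order = 1))
  conformation(topo)
}

# independent frequency-conversion constant (kcal/mol/A^2/amu -> cm^-1),
# written from physical constants without touching package internals
FREQ_CONV_ORACLE <- sqrt(4184 / (6.02214076e23 * 1e-20 * 1.66053906660e-27)) /
  (2 * pi * 2.99792458e10)

# independent O(n^2) greedy TFD dedupe oracle on raw torsion matrices
greedy_dedupe_oracle <- function(theta_mat, periods, threshold) {
  tfd_pair <- function(a, b) {
    d <- abs(a - b) %% periods
    d <- pmin(d, periods - d)
    mean(d / 180)
  }
  kept <- integer(0)
  for (i in seq_len(nrow(theta_mat))) {
    ok <- TRUE
    for (j in kept) {
      if (tfd_pair(theta_mat[i, ], theta_mat[j, ]) < threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# independently coded single-oscillator thermal free energy (kcal/mol):
# G_vib(T) = hv/2 + RT log(1 - exp(-hv/kT)) via the partition function
oscillator_G_oracle <- function(nu, T) {
  hc <- 2.859144e-3   # kcal/mol per cm^-1
  R <- 1.987204259e-3
  hc * nu / 2 + R * T * log(1 - exp(-hc * nu / (R * T)))
}

# true-minimum check against the landscape itself: grid point is a minimum
# iff no +-10 degree axis neighbour is lower (discards saddles that local
# optimization can legitimately stop on)
is_landscape_minimum <- function(landscape, theta, step = 10) {
  E0 <- landscape$fn(theta)
  for (d in seq_along(theta)) {
    for (s in c(-step, step)) {
      tn <- theta
      tn[d] <- tn[d] + s
      if (landscape$fn(tn) < E0 - 1e-9) return(FALSE)
    }
  }
  TRUE
}

# random conformers of a toy chain, uniform torsions, fixed seed
random_chain_confs <- function(topo, n, seed) {
  ref <- conformation(topo)
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    set_torsions(ref, stats::runif(length(topo$torsions), -180, 180))))
}
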