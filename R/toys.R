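# Toy systems for testing and fixtures: ad-hoc topologies, an alkane-like
# torsion chain, and analytic torsion landscapes with known minima.

#' Build a minimal topology from atoms and bonds
#'
#' For toy systems and tests: constructs a single-unit topology (charge 0,
#' all-neutral protonation) with derived torsions, periods and moved-sets.
#'
#' @param elements character vector of element symbols
#' @param coords N x 3 coordinates
#' @param bonds data.frame/matrix with columns i, j (order optional)
#' @param charge formal charge (default 0)
#' @return a `topology`
#' @export
simple_topology <- function(elements, coords, bonds, charge = 0L) {
  coords <- as.matrix(coords)
  bonds <- as.data.frame(bonds)
  names(bonds)[1:2] <- c("i", "j")
  if (is.null(bonds$order)) bonds$order <- 1L
  atoms <- data.frame(name = make.unique(elements, sep = ""),
                      element = elements,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      resid = 1L, unit = 1L, resid_global = 1L)
  topo <- structure(list(
    atoms = atoms, bonds = bonds, rings = list(),
    n_units = 1L, charge = as.integer(charge),
    protonation = protonation_state("neutral"),
    charged_N = data.frame(atom = integer(), unit = integer(),
                           resid = integer()),
    carboxylate_C = data.frame(atom = integer(), unit = integer(),
                               resid = integer()),
    formula = .formula_of(elements), n_rigid_dof = 0L), class = "topology")
  topo$graph <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                            directed = FALSE)
  if (igraph::vcount(topo$graph) < nrow(atoms))
    topo$graph <- igraph::add_vertices(topo$graph,
                                       nrow(atoms) - igraph::vcount(topo$graph))
  topo$torsions <- .topology_torsions(topo)
  topo$torsion_periods <- .torsion_periods(topo)
  topo$torsion_moved <- lapply(topo$torsions, function(t) .moved_set(topo, t))
  topo
}

#' Carbon-chain toy topology with a given number of rotatable torsions
#'
#' A zigzag chain of `n_torsions + 3` carbons (bond 1.53 Angstrom, angle
#' 111 degrees): each internal C-C bond is one rotatable torsion, so the
#' torsion vector maps directly onto chain dihedrals.
#'
#' @param n_torsions number of rotatable torsions (>= 1)
#' @return a `topology`
#' @export
toy_chain_topology <- function(n_torsions) {
  stopifnot(n_torsions >= 1)
  n <- n_torsions + 3L
  # build zigzag in the xy plane
  coords <- matrix(0, n, 3)
  bond <- 1.53; ang <- 111 * pi / 180
  dirs <- list(c(cos((pi - ang) / 2), sin((pi - ang) / 2), 0),
               c(cos((pi - ang) / 2), -sin((pi - ang) / 2), 0))
  for (i in 2:n)
    coords[i, ] <- coords[i - 1, ] + bond * unlist(dirs[(i %% 2) + 1])
  bonds <- data.frame(i = 1:(n - 1), j = 2:n, order = 1L)
  simple_topology(rep("C", n), coords, bonds)
}

#' Per-torsion double-well landscape
#'
#' Each torsion contributes V(u) = a1 (1 - cos u) + a2 (1 - cos 2u) with
#' u = theta - theta_g: global minimum at `theta_g` (V = 0), local minimum
#' at `theta_g + 180` (V = 2 a1), maxima at u = +/-120 when a2 = a1 / 2 is
#' exceeded. The landscape total is the sum over torsions, so the global
#' minimum basin is `|u_i| < 120` for every i.
#'
#' @param n_torsions number of torsions
#' @param theta_g global-minimum angle per torsion (recycled)
#' @param a1,a2 Fourier amplitudes (kcal/mol); defaults 2 and 1
#' @return list with `fn(theta)`, `grad(theta)`, `n_torsions`, `theta_g`,
#'   `minima` (matrix of all 2^n torsion minima) and
#'   `in_global_basin(theta)`
#' @export
toy_double_well <- function(n_torsions = 2, theta_g = -60, a1 = 2, a2 = 1) {
  theta_g <- rep_len(theta_g, n_torsions)
  fn <- function(theta) {
    u <- (theta - theta_g) * pi / 180
    sum(a1 * (1 - cos(u)) + a2 * (1 - cos(2 * u)))
  }
  grad <- function(theta) {
    u <- (theta - theta_g) * pi / 180
    (a1 * sin(u) + 2 * a2 * sin(2 * u)) * pi / 180
  }
  combos <- as.matrix(expand.grid(rep(list(c(0, 180)), n_torsions)))
  minima <- wrap_angle(sweep(combos, 2, theta_g, "+"))
  list(fn = fn, grad = grad, n_torsions = n_torsions, theta_g = theta_g,
       minima = minima,
       in_global_basin = function(theta)
         all(abs(wrap_angle(theta - theta_g)) < 120))
}

#' Exhaustive grid search over a torsion landscape
#'
#' Evaluates the landscape on a regular torsion grid and returns all local
#' minima (grid points below all their axis neighbours, periodic).
#'
#' @param landscape a [toy_double_well()]-style list with `fn`
#' @param step grid spacing in degrees (default 10)
#' @return list with `grid` (matrix), `energies`, `minima` (matrix of local
#'   minima grid points), `global` (row index of global minimum)
#' @export
grid_search <- function(landscape, step = 10) {
  n <- landscape$n_torsions
  axis <- seq(-180, 180 - step, by = step)
  grid <- as.matrix(expand.grid(rep(list(axis), n)))
  E <- apply(grid, 1, landscape$fn)
  m <- length(axis)
  dims <- rep(m, n)
  is_min <- rep(TRUE, nrow(grid))
  idx <- arrayInd(seq_len(nrow(grid)), dims)
  lin <- function(ix) {
    # column-major linear index
    as.vector((ix - 1) %*% cumprod(c(1, dims[-n]))) + 1
  }
  for (d in seq_len(n)) {
    for (shift in c(-1, 1)) {
      ix <- idx
      ix[, d] <- ((ix[, d] - 1 + shift) %% m) + 1
      is_min <- is_min & (E <= E[lin(ix)])
    }
  }
  minima <- grid[is_min, , drop = FALSE]
  list(grid = grid, energies = E, minima = minima,
       minima_energies = E[is_min],
       global = minima[which.min(E[is_min]), , drop = FALSE])
}
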