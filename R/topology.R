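# Oligomer topology construction: peptide-bond condensation of residue
# templates into dipeptide units, explicit protonation states (neutral,
# protonated, zwitterion), non-covalent placement of n units, and the
# conformation container with torsion-space manipulation.

#' Per-unit protonation state
#'
#' Each unit of an oligomer is labelled `neutral`, `protonated` (ammonium
#' N-terminus, +1) or `zwitterion` (ammonium N-terminus plus deprotonated
#' C-terminal carboxylate, net 0). A protonated-neutral pair is the
#' charge-solvated (pn) dimer form; a protonated-zwitterion pair is the
#' salt-bridge (pz) form.
#'
#' @param labels character vector, one entry per unit
#' @return object of class `protonation_state`
#' @export
protonation_state <- function(labels) {
  ok <- c("neutral", "protonated", "zwitterion")
  if (!all(labels %in% ok))
    stop("protonation labels must be in {", paste(ok, collapse = ", "), "}")
  structure(list(labels = labels,
                 net_charge = sum(labels == "protonated")),
            class = "protonation_state")
}

#' Oligomer specification
#'
#' @param n_units number of monomer units (the n of an \[nM + zH\]^z+ series)
#' @param charge total charge z
#' @param protonation a [protonation_state()] with one label per unit
#' @return object of class `oligomer_spec`
#' @export
oligomer_spec <- function(n_units, charge, protonation) {
  stopifnot(n_units >= 1)
  if (length(protonation$labels) != n_units)
    stop("protonation state has ", length(protonation$labels),
         " labels for ", n_units, " units")
  if (protonation$net_charge != charge)
    stop("inconsistent charge: protonation implies ", protonation$net_charge,
         " but spec says ", charge)
  structure(list(n_units = n_units, charge = charge, protonation = protonation),
            class = "oligomer_spec")
}

# evaluate expr with a locally-seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.formula_of <- function(elements) {
  tab <- table(elements)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

#' Format an element-count map as a Hill-order formula string
#' @param formula named integer vector
#' @return string such as "C18H21N2O3"
#' @export
formula_string <- function(formula) {
  formula <- formula[formula > 0]
  hill <- c(intersect(c("C", "H"), names(formula)),
            sort(setdiff(names(formula), c("C", "H"))))
  paste0(vapply(hill, function(e)
    paste0(e, if (formula[[e]] > 1) formula[[e]] else ""), ""), collapse = "")
}

#' Add element-count maps
#' @param ... named integer vectors
#' @return combined named integer vector
#' @export
formula_add <- function(...) {
  fl <- list(...)
  els <- sort(unique(unlist(lapply(fl, names))))
  out <- stats::setNames(integer(length(els)), els)
  for (f in fl) out[names(f)] <- out[names(f)] + f
  out
}

# ---- dipeptide condensation --------------------------------------------

# Condense res1 (N-terminal) and res2 (C-terminal): res1 loses OXT+HXT,
# res2 loses one amine H; new amide bond res1:C -- res2:N.
.condense_dipeptide <- function(tmpl) {
  a1 <- tmpl$atoms; a2 <- tmpl$atoms
  b1 <- tmpl$bonds; b2 <- tmpl$bonds
  idx <- function(atoms, nm) which(atoms$name == nm)

  drop1 <- c(idx(a1, "OXT"), idx(a1, "HXT"))
  drop2 <- idx(a2, "H2")                     # one amine hydrogen
  c1 <- idx(a1, "C"); oxt1 <- idx(a1, "OXT"); n2 <- idx(a2, "N")

  # place res2 so its N sits 1.33 A from res1's carbonyl C along C->OXT
  dir <- as.numeric(a1[oxt1, c("x", "y", "z")] - a1[c1, c("x", "y", "z")])
  dir <- dir / .vnorm(dir)
  target_n <- as.numeric(a1[c1, c("x", "y", "z")]) + 1.33 * dir
  xyz2 <- as.matrix(a2[, c("x", "y", "z")])
  xyz2 <- sweep(xyz2, 2, as.numeric(a2[n2, c("x", "y", "z")]) - target_n, "-")

  # rotate res2 about the new C-N axis to relieve clashes (deterministic scan)
  xyz1 <- as.matrix(a1[, c("x", "y", "z")])
  keep1 <- setdiff(seq_len(nrow(a1)), drop1)
  keep2 <- setdiff(seq_len(nrow(a2)), drop2)
  best <- NULL; best_min <- -Inf
  for (ang in seq(0, 330, by = 30)) {
    R <- .rotation_matrix(dir, ang)
    cand <- sweep((sweep(xyz2, 2, target_n, "-")) %*% t(R), 2, target_n, "+")
    dmin <- min(as.matrix(stats::dist(rbind(xyz1[keep1, ], cand[keep2, ])))[
      seq_along(keep1), length(keep1) + seq_along(keep2)])
    if (dmin > best_min) { best_min <- dmin; best <- cand }
  }
  xyz2 <- best

  a1$resid <- 1L; a2$resid <- 2L
  a2[, c("x", "y", "z")] <- xyz2
  map1 <- match(seq_len(nrow(a1)), keep1)
  map2 <- match(seq_len(nrow(a2)), keep2) + length(keep1)
  atoms <- rbind(a1[keep1, ], a2[keep2, ])
  rownames(atoms) <- NULL
  rb <- function(b, map) {
    b$i <- map[b$i]; b$j <- map[b$j]
    b[stats::complete.cases(b[, c("i", "j")]), ]
  }
  bonds <- rbind(rb(b1, map1), rb(b2, map2),
                 data.frame(i = map1[c1], j = map2[n2] , order = 1L))
  list(atoms = atoms, bonds = bonds,
       rings = c(lapply(tmpl$rings, function(r) list(atoms = map1[r], resid = 1L)),
                 lapply(tmpl$rings, function(r) list(atoms = map2[r], resid = 2L))))
}

# add an H to atom i, direction away from existing neighbours
.add_hydrogen <- function(atoms, bonds, i, name, dist = 1.02) {
  g_nb <- unique(c(bonds$j[bonds$i == i], bonds$i[bonds$j == i]))
  p <- as.numeric(atoms[i, c("x", "y", "z")])
  dirs <- t(vapply(g_nb, function(j)
    as.numeric(atoms[j, c("x", "y", "z")]) - p, numeric(3)))
  v <- -colSums(dirs / apply(dirs, 1, .vnorm))
  if (.vnorm(v) < 1e-8) v <- c(0, 0, 1)
  v <- v / .vnorm(v)
  new_atom <- atoms[i, ]
  new_atom$name <- name; new_atom$element <- "H"
  new_atom[, c("x", "y", "z")] <- p + dist * v
  atoms <- rbind(atoms, new_atom)
  rownames(atoms) <- NULL
  bonds <- rbind(bonds, data.frame(i = i, j = nrow(atoms), order = 1L))
  list(atoms = atoms, bonds = bonds, h_index = nrow(atoms))
}

# ---- oligomer builder ---------------------------------------------------

#' Build an oligomer topology from a specification
#'
#' Constructs `n_units` dipeptide units by peptide-bond condensation of the
#' residue template (for "Phe", two phenylalanines condense to the
#' diphenylalanine unit C18H20N2O3), applies the per-unit protonation state,
#' and places the units as a non-covalent complex on a 6 Angstrom grid with
#' seeded random orientations.
#'
#' @param spec an [oligomer_spec()]
#' @param templates named template table (default [builtin_templates()])
#' @param residue residue name to condense into the repeating unit
#' @param seed seed for initial unit orientations
#' @return object of class `topology`
#' @export
build_oligomer <- function(spec, templates = builtin_templates(),
                           residue = "Phe", seed = 1L) {
  if (!residue %in% names(templates))
    stop("unknown residue name: ", residue)
  tmpl <- templates[[residue]]
  unit <- .condense_dipeptide(tmpl)

  atoms_all <- NULL; bonds_all <- NULL; rings_all <- list()
  charged_N <- data.frame(atom = integer(), unit = integer(), resid = integer())
  carboxylate_C <- data.frame(atom = integer(), unit = integer(), resid = integer())
  uxyz <- as.matrix(unit$atoms[, c("x", "y", "z")])
  uxyz <- sweep(uxyz, 2, colMeans(uxyz))
  unit_radius <- max(sqrt(rowSums(uxyz^2)))
  offsets <- .unit_grid_offsets(spec$n_units, spacing = 6,
                                unit_radius = unit_radius)

  .with_seed(seed, {
    for (u in seq_len(spec$n_units)) {
      a <- unit$atoms; b <- unit$bonds
      local_rings <- unit$rings
      local_cN <- integer(0); local_cC <- integer(0)
      lab <- spec$protonation$labels[u]
      if (lab %in% c("protonated", "zwitterion")) {
        ni <- which(a$name == "N" & a$resid == 1L)
        added <- .add_hydrogen(a, b, ni, "H3")
        a <- added$atoms; b <- added$bonds
        local_cN <- ni
      }
      if (lab == "zwitterion") {
        hxt <- which(a$name == "HXT" & a$resid == 2L)
        ci <- which(a$name == "C" & a$resid == 2L)
        keep <- setdiff(seq_len(nrow(a)), hxt)
        map <- match(seq_len(nrow(a)), keep)
        a <- a[keep, ]; rownames(a) <- NULL
        b$i <- map[b$i]; b$j <- map[b$j]
        b <- b[stats::complete.cases(b[, c("i", "j")]), ]
        local_cN <- map[local_cN]
        local_cC <- map[ci]
        local_rings <- lapply(local_rings, function(r) {
          r$atoms <- map[r$atoms]; r
        })
      }
      xyz <- as.matrix(a[, c("x", "y", "z")])
      xyz <- sweep(xyz, 2, colMeans(xyz))
      R <- if (spec$n_units > 1) .random_rotation() else diag(3)
      xyz <- rigid_transform(xyz, R, offsets[u, ])
      a[, c("x", "y", "z")] <- xyz
      off <- if (is.null(atoms_all)) 0L else nrow(atoms_all)
      a$unit <- u
      a$resid_global <- (u - 1L) * 2L + a$resid
      b$i <- b$i + off; b$j <- b$j + off
      for (r in local_rings)
        rings_all[[length(rings_all) + 1]] <-
          list(atoms = r$atoms + off, unit = u, resid = r$resid)
      if (length(local_cN))
        charged_N <- rbind(charged_N,
                           data.frame(atom = local_cN + off, unit = u, resid = 1L))
      if (length(local_cC))
        carboxylate_C <- rbind(carboxylate_C,
                               data.frame(atom = local_cC + off, unit = u, resid = 2L))
      atoms_all <- rbind(atoms_all, a)
      bonds_all <- rbind(bonds_all, b)
    }
  })
  rownames(atoms_all) <- NULL

  formula <- .formula_of(atoms_all$element)
  topo <- structure(list(
    atoms = atoms_all, bonds = bonds_all, rings = rings_all,
    n_units = spec$n_units, charge = spec$charge,
    protonation = spec$protonation,
    charged_N = charged_N, carboxylate_C = carboxylate_C,
    formula = formula,
    n_rigid_dof = 6L * (spec$n_units - 1L)
  ), class = "topology")
  topo$graph <- igraph::graph_from_edgelist(
    as.matrix(bonds_all[, c("i", "j")]), directed = FALSE)
  if (igraph::vcount(topo$graph) < nrow(atoms_all))
    topo$graph <- igraph::add_vertices(topo$graph,
                                       nrow(atoms_all) - igraph::vcount(topo$graph))
  topo$torsions <- .topology_torsions(topo)
  topo$torsion_periods <- .torsion_periods(topo)
  topo$torsion_moved <- lapply(topo$torsions, function(t) .moved_set(topo, t))
  topo
}

.unit_grid_offsets <- function(n, spacing = 6, unit_radius = 0) {
  # grid pitch: the nominal spacing, widened when the units themselves are
  # larger than the pitch (steric overlap would otherwise be unavoidable)
  pitch <- max(spacing, 2 * unit_radius + 2)
  k <- ceiling(n^(1 / 3))
  pts <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
  as.matrix(pts[seq_len(n), ]) * pitch
}

.topology_torsions <- function(topo) {
  ring_atoms <- unique(unlist(lapply(topo$rings, `[[`, "atoms")))
  el <- topo$atoms$element
  out <- list()
  for (k in seq_len(nrow(topo$bonds))) {
    b <- topo$bonds[k, ]
    if (b$order != 1) next
    i <- b$i; j <- b$j
    if (el[i] == "H" || el[j] == "H") next
    if (i %in% ring_atoms && j %in% ring_atoms) next
    nb_i <- setdiff(as.integer(igraph::neighbors(topo$graph, i)), j)
    nb_j <- setdiff(as.integer(igraph::neighbors(topo$graph, j)), i)
    if (!length(nb_i) || !length(nb_j)) next
    pick <- function(nb) {
      heavy <- nb[el[nb] != "H"]
      if (length(heavy)) min(heavy) else min(nb)
    }
    out[[length(out) + 1]] <- c(pick(nb_i), i, j, pick(nb_j))
  }
  out
}

# symmetry period per torsion: 180 deg when the far atom belongs to a
# 2-fold symmetric group (aromatic ring or carboxylate), else 360
.torsion_periods <- function(topo) {
  ring_atoms <- unique(unlist(lapply(topo$rings, `[[`, "atoms")))
  el <- topo$atoms$element
  vapply(topo$torsions, function(t) {
    d <- t[4]
    if (d %in% ring_atoms) return(180)
    if (el[d] == "O") {
      cnb <- as.integer(igraph::neighbors(topo$graph, d))
      cc <- cnb[el[cnb] == "C"]
      for (c_ in cc) {
        onb <- as.integer(igraph::neighbors(topo$graph, c_))
        os <- onb[el[onb] == "O"]
        if (length(os) == 2) {
          has_h <- any(vapply(os, function(o)
            any(el[as.integer(igraph::neighbors(topo$graph, o))] == "H"),
            logical(1)))
          if (!has_h) return(180)  # carboxylate
        }
      }
    }
    360
  }, numeric(1))
}

# atoms moved when rotating about bond (b[2], b[3]): the component holding
# atom 3 after deleting the central bond
.moved_set <- function(topo, torsion) {
  g <- igraph::delete_edges(topo$graph,
    igraph::get_edge_ids(topo$graph, c(torsion[2], torsion[3])))
  comp <- igraph::components(g)
  which(comp$membership == comp$membership[torsion[3]])
}

# ---- conformation -------------------------------------------------------

#' Construct a conformation
#'
#' @param topology a `topology`
#' @param coords N x 3 Cartesian matrix (Angstrom); defaults to the
#'   topology's reference coordinates
#' @param energy optional energy (kcal/mol)
#' @param label conformer label (e.g. "pn1", "pz1")
#' @param provenance free-text provenance string
#' @return object of class `conformation`
#' @export
conformation <- function(topology, coords = NULL, energy = NULL,
                         label = "", provenance = "") {
  if (is.null(coords))
    coords <- as.matrix(topology$atoms[, c("x", "y", "z")])
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topology$atoms))
    stop("coordinate count (", nrow(coords), ") does not match topology (",
         nrow(topology$atoms), " atoms)")
  structure(list(topology = topology, coords = unname(coords),
                 energy = energy, label = label, provenance = provenance),
            class = "conformation")
}

#' Check the minimum-interatomic-distance validity of a conformation
#' @param conf a `conformation`
#' @param min_dist minimum allowed distance (default 0.7 Angstrom)
#' @return logical
#' @export
is_valid_conformation <- function(conf, min_dist = 0.7) {
  .min_interatomic_distance(conf$coords) > min_dist
}

#' Measure all rotatable torsions of a conformation
#' @param conf a `conformation`
#' @return numeric vector of torsion angles (degrees, in \[-180, 180))
#' @export
get_torsions <- function(conf) {
  vapply(conf$topology$torsions, function(t)
    wrap_angle(.dihedral_deg(conf$coords[t[1], ], conf$coords[t[2], ],
                             conf$coords[t[3], ], conf$coords[t[4], ])),
    numeric(1))
}

#' Set rotatable torsions of a conformation
#'
#' Rotates, for each listed torsion, the atoms on the far side of the central
#' bond so the dihedral takes the requested value. Each rotation affects only
#' its own torsion.
#'
#' @param conf a `conformation`
#' @param values numeric vector of target angles (degrees), one per torsion
#' @return the updated `conformation` (energy invalidated)
#' @export
set_torsions <- function(conf, values) {
  topo <- conf$topology
  if (length(values) != length(topo$torsions))
    stop("expected ", length(topo$torsions), " torsion values")
  xyz <- conf$coords
  for (k in seq_along(values)) {
    t <- topo$torsions[[k]]
    cur <- .dihedral_deg(xyz[t[1], ], xyz[t[2], ], xyz[t[3], ], xyz[t[4], ])
    delta <- wrap_angle(values[k] - cur)
    if (abs(delta) < 1e-12) next
    axis <- xyz[t[3], ] - xyz[t[2], ]
    R <- .rotation_matrix(axis, -delta)
    mv <- topo$torsion_moved[[k]]
    origin <- xyz[t[2], ]
    xyz[mv, ] <- sweep(sweep(xyz[mv, , drop = FALSE], 2, origin) %*% t(R),
                       2, origin, "+")
  }
  conf$coords <- xyz
  conf$energy <- NULL
  conf
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology>", formula_string(x$formula),
      sprintf("(charge %+d)", x$charge), "-", nrow(x$atoms), "atoms,",
      x$n_units, "unit(s),", length(x$torsions), "rotatable torsions\n")
  invisible(x)
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation>", if (nzchar(x$label)) x$label else "(unlabelled)",
      "-", nrow(x$coords), "atoms",
      if (!is.null(x$energy)) sprintf(", E = %.4f kcal/mol", x$energy) else "",
      "\n", sep = " ")
  invisible(x)
}
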