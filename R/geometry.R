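# Geometric predicates used throughout the pipeline: hydrogen bonds,
# proton-pi (charged amino group to aromatic ring face) contacts, the
# free-OH diagnostic, and the UV-derived structural constraint filter.

#' Geometric criteria for non-covalent interactions
#'
#' Thresholds for hydrogen-bond and proton-pi detection. Defaults are
#' standard structural-biology values: donor-acceptor heavy-atom distance
#' <= 3.5 Angstrom with D-H...A angle >= 120 degrees for hydrogen bonds, and
#' charged-N-to-ring-centroid distance <= 5.0 Angstrom for proton-pi
#' contacts (chosen so that a 4.8 Angstrom ammonium-ring contact qualifies).
#'
#' @param hbond_max_DA_distance maximum donor-acceptor distance (Angstrom)
#' @param hbond_min_DHA_angle minimum donor-H-acceptor angle (degrees)
#' @param pion_max_centroid_distance maximum charged-site-to-ring-centroid
#'   distance (Angstrom)
#' @return object of class `geometric_criteria`
#' @export
geometric_criteria <- function(hbond_max_DA_distance = 3.5,
                               hbond_min_DHA_angle = 120,
                               pion_max_centroid_distance = 5.0) {
  stopifnot(hbond_max_DA_distance > 0, pion_max_centroid_distance > 0,
            hbond_min_DHA_angle > 0, hbond_min_DHA_angle < 180)
  structure(list(hbond_max_DA_distance = hbond_max_DA_distance,
                 hbond_min_DHA_angle = hbond_min_DHA_angle,
                 pion_max_centroid_distance = pion_max_centroid_distance),
            class = "geometric_criteria")
}

.donor_h_pairs <- function(topo) {
  el <- topo$atoms$element
  polar <- which(el %in% c("N", "O"))
  out <- NULL
  for (d in polar) {
    hs <- as.integer(igraph::neighbors(topo$graph, d))
    hs <- hs[el[hs] == "H"]
    if (length(hs))
      out <- rbind(out, data.frame(donor = d, h = hs))
  }
  out
}

#' Detect hydrogen bonds in a conformation
#'
#' A hydrogen bond is reported for every donor(N/O with H) -> acceptor(N/O)
#' pair with heavy-atom distance within the cutoff and D-H...A angle above
#' the threshold. Donor and acceptor must not be covalently bonded.
#'
#' @param conf a `conformation`
#' @param crit a [geometric_criteria()]
#' @return data.frame with columns `donor`, `h`, `acceptor`, `distance`,
#'   `angle`, ordered by (donor, h, acceptor) atom index
#' @export
find_hbonds <- function(conf, crit = geometric_criteria()) {
  topo <- conf$topology
  xyz <- conf$coords
  el <- topo$atoms$element
  dh <- .donor_h_pairs(topo)
  acceptors <- which(el %in% c("N", "O"))
  empty <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric())
  if (is.null(dh) || !length(acceptors)) return(empty)
  out <- empty
  for (k in seq_len(nrow(dh))) {
    d <- dh$donor[k]; h <- dh$h[k]
    bonded <- as.integer(igraph::neighbors(topo$graph, d))
    for (a in acceptors) {
      if (a == d || a %in% bonded) next
      dist <- .vnorm(xyz[d, ] - xyz[a, ])
      if (dist > crit$hbond_max_DA_distance + 1e-9) next
      ang <- .angle_deg(xyz[d, ], xyz[h, ], xyz[a, ])
      if (ang < crit$hbond_min_DHA_angle - 1e-9) next  # closed boundary
      out <- rbind(out, data.frame(donor = d, h = h, acceptor = a,
                                   distance = dist, angle = ang))
    }
  }
  out[order(out$donor, out$h, out$acceptor), , drop = FALSE]
}

#' Detect proton-pi contacts
#'
#' Reports every (charged ammonium N, aromatic ring) pair whose
#' N-to-ring-centroid distance is within the cutoff, sorted by distance
#' (ties broken by ring id). `same_residue` is TRUE when ring and charged
#' site belong to the same residue of the same unit.
#'
#' @param conf a `conformation`
#' @param crit a [geometric_criteria()]
#' @return data.frame with columns `site`, `ring`, `distance`, `same_residue`,
#'   `same_unit`
#' @export
find_pion_contacts <- function(conf, crit = geometric_criteria()) {
  topo <- conf$topology
  if (!length(topo$rings)) stop("topology has no aromatic rings")
  if (!nrow(topo$charged_N)) stop("topology has no charged sites")
  xyz <- conf$coords
  out <- data.frame(site = integer(), ring = integer(), distance = numeric(),
                    same_residue = logical(), same_unit = logical())
  for (k in seq_len(nrow(topo$charged_N))) {
    s <- topo$charged_N[k, ]
    for (r in seq_along(topo$rings)) {
      ring <- topo$rings[[r]]
      centroid <- colMeans(xyz[ring$atoms, , drop = FALSE])
      dist <- .vnorm(xyz[s$atom, ] - centroid)
      if (dist > crit$pion_max_centroid_distance) next
      out <- rbind(out, data.frame(
        site = s$atom, ring = r, distance = dist,
        same_residue = (ring$unit == s$unit && ring$resid == s$resid),
        same_unit = ring$unit == s$unit))
    }
  }
  # near-ties (< 1e-9 A) resolved deterministically by ring id
  out[order(round(out$distance, 9), out$ring), , drop = FALSE]
}

# carboxyl hydroxyl hydrogens: H bonded to O bonded to C carrying a =O
.carboxyl_oh_hydrogens <- function(topo) {
  el <- topo$atoms$element
  out <- integer(0)
  for (h in which(el == "H")) {
    o <- as.integer(igraph::neighbors(topo$graph, h))
    if (length(o) != 1 || el[o] != "O") next
    cs <- as.integer(igraph::neighbors(topo$graph, o))
    cs <- cs[el[cs] == "C"]
    for (c_ in cs) {
      dbl <- topo$bonds[(topo$bonds$i == c_ | topo$bonds$j == c_) &
                          topo$bonds$order == 2, ]
      others <- setdiff(c(dbl$i, dbl$j), c_)
      if (any(el[others] == "O")) out <- c(out, h)
    }
  }
  unique(out)
}

#' Free carboxyl OH diagnostic
#'
#' TRUE iff no carboxyl OH hydrogen of the conformation participates as the
#' shared hydrogen in any detected hydrogen bond. A zwitterionic unit has no
#' OH on its carboxylate and contributes nothing.
#'
#' @param conf a `conformation`
#' @param crit a [geometric_criteria()]
#' @return logical
#' @export
has_free_OH <- function(conf, crit = geometric_criteria()) {
  ohs <- .carboxyl_oh_hydrogens(conf$topology)
  if (!length(ohs)) stop("topology contains no carboxylic OH group")
  hb <- find_hbonds(conf, crit)
  !any(ohs %in% hb$h)
}

#' UV-derived structural constraint filter
#'
#' Partitions conformers by the charge-chromophore proximity predicate
#' established from UV band-origin shifts: in `monomer` mode the protonated
#' N-terminus must be in proton-pi contact with the ring of the C-terminal
#' residue of its own unit; in `dimer` mode at least one ring belonging to a
#' *different* residue than the charged N-terminus must be in contact.
#'
#' @param confs list of `conformation`
#' @param mode "monomer" or "dimer"
#' @param crit a [geometric_criteria()]
#' @return list with elements `pass` and `fail` (both lists of conformations)
#' @export
uv_constraint_filter <- function(confs, mode = c("monomer", "dimer"),
                                 crit = geometric_criteria()) {
  mode <- match.arg(mode)
  pass <- list(); fail <- list()
  for (conf in confs) {
    contacts <- find_pion_contacts(conf, crit)
    ok <- if (mode == "monomer") {
      any(contacts$same_unit &
            vapply(contacts$ring, function(r)
              conf$topology$rings[[r]]$resid == 2L, logical(1)))
    } else {
      any(!contacts$same_residue)
    }
    if (ok) pass[[length(pass) + 1]] <- conf
    else fail[[length(fail) + 1]] <- conf
  }
  list(pass = pass, fail = fail)
}
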