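# Interaction-fingerprint family clustering: the funnel from thousands of
# optimized conformers to a targeted candidate pool. Family identity is
# exact equality of the hydrogen-bond pattern, the proton-pi pattern and
# the charge location; per family only the lowest-energy member below the
# energy cutoff survives.

#' Interaction fingerprint of a conformation
#'
#' The family-clustering key: the sorted set of hydrogen-bond
#' (donor, acceptor) atom pairs, the sorted set of proton-pi
#' (charged site, ring) pairs, and the charge-location label derived from
#' the topology's protonation state.
#'
#' @param conf a `conformation`
#' @param crit a [geometric_criteria()]
#' @return object of class `interaction_fingerprint` with a canonical
#'   `key` string usable for hashing/grouping
#' @export
fingerprint <- function(conf, crit = geometric_criteria()) {
  hb <- find_hbonds(conf, crit)
  hb_pairs <- unique(hb[, c("donor", "acceptor")])
  hb_pairs <- hb_pairs[order(hb_pairs$donor, hb_pairs$acceptor), , drop = FALSE]
  pio <- if (length(conf$topology$rings) && nrow(conf$topology$charged_N)) {
    p <- find_pion_contacts(conf, crit)
    p <- unique(p[, c("site", "ring")])
    p[order(p$site, p$ring), , drop = FALSE]
  } else data.frame(site = integer(), ring = integer())
  charge_label <- paste(conf$topology$protonation$labels, collapse = "/")
  key <- paste(
    paste(sprintf("%d>%d", hb_pairs$donor, hb_pairs$acceptor), collapse = ","),
    paste(sprintf("%d@%d", pio$site, pio$ring), collapse = ","),
    charge_label, sep = "|")
  structure(list(hbonds = hb_pairs, pion = pio,
                 charge_label = charge_label, key = key),
            class = "interaction_fingerprint")
}

#' Family clustering configuration
#' @param cutoff energy cutoff above the pool minimum (kcal/mol, default 10)
#' @return object of class `family_config`
#' @export
family_config <- function(cutoff = 10) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff), class = "family_config")
}

#' Cluster conformers into interaction-fingerprint families
#'
#' Partitions the input by exact fingerprint equality. Within each family
#' members are ordered strictly by energy, ties broken by provenance id
#' (input position).
#'
#' @param confs list of `conformation` with energies set
#' @param crit a [geometric_criteria()]
#' @return named list of families (name = fingerprint key); each family is
#'   a list with `fingerprint`, `members` (conformations) and `energies`
#' @export
cluster_families <- function(confs, crit = geometric_criteria()) {
  for (k in seq_along(confs))
    if (is.null(confs[[k]]$energy))
      stop("conformer ", k,
           if (nzchar(confs[[k]]$label)) paste0(" (", confs[[k]]$label, ")"),
           " has no energy")
  keys <- vapply(confs, function(cf) fingerprint(cf, crit)$key, "")
  fams <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    en <- vapply(confs[idx], `[[`, 0, "energy")
    ord <- order(en, idx)
    fams[[key]] <- list(fingerprint = fingerprint(confs[[idx[1]]], crit),
                        members = confs[idx[ord]],
                        energies = en[ord])
  }
  fams
}

#' Select the candidate pool from clustered families
#'
#' Keeps each family's minimum-energy member iff its energy relative to the
#' reference (the global minimum over all families by default) is within
#' the cutoff; the output is sorted by relative energy. Relative energies
#' are also reported per charge-location stratum.
#'
#' @param families output of [cluster_families()]
#' @param config a [family_config()]
#' @return data-frame-backed list of class `candidate_pool`: `conformers`,
#'   `relative_energy` (global), `relative_energy_stratum`, `charge_label`
#' @export
select_candidates <- function(families, config = family_config()) {
  mins <- lapply(families, function(f) f$members[[1]])
  en <- vapply(mins, `[[`, 0, "energy")
  labels <- vapply(families, function(f) f$fingerprint$charge_label, "")
  gmin <- min(en)
  rel <- en - gmin
  rel_strat <- stats::ave(en, labels, FUN = function(x) x - min(x))
  keep <- rel <= config$cutoff
  ord <- order(rel[keep])
  structure(list(conformers = mins[keep][ord],
                 relative_energy = unname(rel[keep][ord]),
                 relative_energy_stratum = unname(rel_strat[keep][ord]),
                 charge_label = unname(labels[keep][ord]),
                 reference_energy = gmin),
            class = "candidate_pool")
}

#' Write a family report as JSON plus a multi-frame XYZ of candidates
#' @param families output of [cluster_families()]
#' @param pool output of [select_candidates()]
#' @param dir output directory
#' @return invisibly, the report file paths
#' @export
write_family_report <- function(families, pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_ <- lapply(names(families), function(key) {
    f <- families[[key]]
    list(fingerprint = key,
         charge_label = f$fingerprint$charge_label,
         size = length(f$members),
         energies = f$energies,
         relative_energy = f$energies[1] - pool$reference_energy)
  })
  json_path <- file.path(dir, "families.json")
  jsonlite::write_json(rep_, json_path, auto_unbox = TRUE, digits = NA)
  xyz_path <- file.path(dir, "candidates.xyz")
  write_xyz(pool$conformers, xyz_path)
  invisible(c(json = json_path, xyz = xyz_path))
}
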