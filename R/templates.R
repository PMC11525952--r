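# Residue templates: chemical table entries with reference geometry,
# bond graph, rotatable torsions, donor/acceptor lists and aromatic rings.
# Templates are shipped as plain-text files under inst/extdata/templates and
# user templates are loadable by path.

#' Construct a residue template
#'
#' A residue template holds the reference chemistry of one monomer unit:
#' element symbols and reference Cartesian positions (Angstrom), the bond
#' graph, rotatable torsions, hydrogen-bond donor and acceptor atoms, and
#' aromatic rings. Rings, donors/acceptors and rotatable torsions are derived
#' from the bond graph when not supplied.
#'
#' @param name residue name (e.g. "Phe")
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`
#' @param bonds matrix/data.frame with columns `i`, `j`, `order` (1-based)
#' @return object of class `residue_template`
#' @export
residue_template <- function(name, atoms, bonds) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  bonds <- as.data.frame(bonds)
  names(bonds)[1:2] <- c("i", "j")
  if (is.null(bonds$order)) bonds$order <- 1L
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < nrow(atoms))
    g <- igraph::add_vertices(g, nrow(atoms) - igraph::vcount(g))
  if (igraph::components(g)$no != 1)
    stop("template '", name, "': bond graph is not connected")
  tmpl <- structure(list(name = name, atoms = atoms, bonds = bonds, graph = g),
                    class = "residue_template")
  tmpl$rings <- .find_aromatic_rings(tmpl)
  da <- .donors_acceptors(tmpl)
  tmpl$donor_atoms <- da$donors
  tmpl$acceptor_atoms <- da$acceptors
  tmpl$rotatable_torsions <- .rotatable_torsions(tmpl)
  .validate_template(tmpl)
  tmpl
}

.validate_template <- function(tmpl) {
  for (tor in tmpl$rotatable_torsions) {
    for (k in 1:3) {
      hit <- any((tmpl$bonds$i == tor[k] & tmpl$bonds$j == tor[k + 1]) |
                 (tmpl$bonds$j == tor[k] & tmpl$bonds$i == tor[k + 1]))
      if (!hit) stop("torsion atoms not bonded in chain: ",
                     paste(tor, collapse = "-"))
    }
  }
  for (r in tmpl$rings)
    if (length(r) < 5) stop("ring with fewer than 5 atoms")
  invisible(tmpl)
}

# carbocycles of size 5-6 where every member is carbon with exactly 3 heavy
# or ring neighbours -> treated as aromatic (sufficient for Phe chemistry)
.find_aromatic_rings <- function(tmpl) {
  g <- tmpl$graph
  el <- tmpl$atoms$element
  rings <- list()
  # minimum cycle basis via igraph: use fundamental cycles of a spanning tree
  for (sz in c(5L, 6L)) {
    subs <- tryCatch(
      igraph::subgraph_isomorphisms(igraph::make_ring(sz), g, induced = FALSE),
      error = function(e) list())
    for (m in subs) {
      idx <- sort(as.integer(m))
      if (length(idx) != sz) next
      if (!all(el[idx] == "C")) next
      key <- paste(idx, collapse = ",")
      if (!key %in% names(rings)) rings[[key]] <- idx
    }
  }
  unname(rings)
}

.heavy_neighbors <- function(tmpl, i) {
  nb <- as.integer(igraph::neighbors(tmpl$graph, i))
  nb[tmpl$atoms$element[nb] != "H"]
}

.h_neighbors <- function(tmpl, i) {
  nb <- as.integer(igraph::neighbors(tmpl$graph, i))
  nb[tmpl$atoms$element[nb] == "H"]
}

.donors_acceptors <- function(tmpl) {
  el <- tmpl$atoms$element
  polar <- which(el %in% c("N", "O"))
  donors <- polar[vapply(polar, function(i) length(.h_neighbors(tmpl, i)) > 0,
                         logical(1))]
  list(donors = donors, acceptors = polar)
}

# rotatable = non-ring single bond between two heavy atoms, each with at
# least one additional neighbour; torsion reference atoms chosen as the
# lowest-index heavy (or any) neighbour on each side
.rotatable_torsions <- function(tmpl) {
  ring_atoms <- unique(unlist(tmpl$rings))
  out <- list()
  for (k in seq_len(nrow(tmpl$bonds))) {
    b <- tmpl$bonds[k, ]
    if (b$order != 1) next
    i <- b$i; j <- b$j
    if (tmpl$atoms$element[i] == "H" || tmpl$atoms$element[j] == "H") next
    if (i %in% ring_atoms && j %in% ring_atoms) next
    nb_i <- setdiff(as.integer(igraph::neighbors(tmpl$graph, i)), j)
    nb_j <- setdiff(as.integer(igraph::neighbors(tmpl$graph, j)), i)
    if (!length(nb_i) || !length(nb_j)) next
    pick <- function(nb) {
      heavy <- nb[tmpl$atoms$element[nb] != "H"]
      if (length(heavy)) min(heavy) else min(nb)
    }
    out[[length(out) + 1]] <- c(pick(nb_i), i, j, pick(nb_j))
  }
  out
}

#' Read a residue template from a plain-text file
#'
#' Format: `name <residue>` line, `atom <idx> <name> <element> <x> <y> <z>`
#' lines and `bond <i> <j> <order>` lines; `#` starts a comment.
#'
#' @param path file path
#' @return a `residue_template`
#' @export
read_template <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  name <- NULL; atoms <- list(); bonds <- list()
  for (tk in toks) {
    switch(tk[1],
      name = { name <- tk[2] },
      atom = { atoms[[length(atoms) + 1]] <-
                 data.frame(name = tk[3], element = tk[4],
                            x = as.numeric(tk[5]), y = as.numeric(tk[6]),
                            z = as.numeric(tk[7])) },
      bond = { bonds[[length(bonds) + 1]] <-
                 data.frame(i = as.integer(tk[2]), j = as.integer(tk[3]),
                            order = as.integer(tk[4])) },
      stop("unrecognized template record: ", tk[1]))
  }
  residue_template(name, do.call(rbind, atoms), do.call(rbind, bonds))
}

.template_cache <- new.env(parent = emptyenv())

#' Built-in residue template table
#'
#' Returns the shipped chemical table (currently the phenylalanine residue),
#' a named list of `residue_template` objects.
#'
#' @return named list of templates
#' @export
builtin_templates <- function() {
  if (is.null(.template_cache$tbl)) {
    dir <- system.file("extdata", "templates", package = "oligoconf")
    files <- list.files(dir, pattern = "\\.tmpl$", full.names = TRUE)
    tbl <- lapply(files, read_template)
    names(tbl) <- vapply(tbl, `[[`, "", "name")
    .template_cache$tbl <- tbl
  }
  .template_cache$tbl
}

#' @export
print.residue_template <- function(x, ...) {
  cat("<residue_template>", x$name, "-", nrow(x$atoms), "atoms,",
      nrow(x$bonds), "bonds,", length(x$rings), "aromatic ring(s),",
      length(x$rotatable_torsions), "rotatable torsions\n")
  invisible(x)
}
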