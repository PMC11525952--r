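# Readers/writers for the exchange formats: multi-frame XYZ, single-model
# PDB, two-column spectral trace CSV and stick-spectrum CSV.

#' Write conformations to a multi-frame XYZ file
#'
#' The comment line of each frame carries `label=... energy=...` when
#' available, so round-tripping preserves provenance.
#'
#' @param confs a `conformation` or list of them
#' @param path output path
#' @export
write_xyz <- function(confs, path) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- file(path, "w"); on.exit(close(con))
  for (conf in confs) {
    el <- conf$topology$atoms$element
    writeLines(as.character(length(el)), con)
    meta <- sprintf("label=%s energy=%s",
                    if (nzchar(conf$label)) conf$label else "NA",
                    if (!is.null(conf$energy)) format(conf$energy, digits = 12)
                    else "NA")
    writeLines(meta, con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", el,
                       conf$coords[, 1], conf$coords[, 2], conf$coords[, 3]),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path input path
#' @param topology optional `topology`; when given, element symbols are
#'   checked against it and full conformations are returned
#' @return list of `conformation` (with topology) or list of
#'   `list(elements, coords, label, energy)` frames
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  out <- list(); i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    meta <- lines[i + 1]
    block <- lines[(i + 2):(i + 1 + n)]
    toks <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    el <- toks[, 1]
    coords <- matrix(as.numeric(toks[, 2:4]), ncol = 3)
    lab <- sub(".*label=(\\S+).*", "\\1", meta)
    if (identical(lab, meta) || lab == "NA") lab <- ""
    en <- sub(".*energy=(\\S+).*", "\\1", meta)
    en <- if (identical(en, meta) || en == "NA") NULL else as.numeric(en)
    if (!is.null(topology)) {
      if (!identical(el, topology$atoms$element))
        stop("XYZ elements do not match topology")
      out[[length(out) + 1]] <- conformation(topology, coords, energy = en,
                                             label = lab,
                                             provenance = paste0("read:", path))
    } else {
      out[[length(out) + 1]] <- list(elements = el, coords = coords,
                                     label = lab, energy = en)
    }
    i <- i + 2 + n
  }
  out
}

#' Write a conformation as a single-model PDB (HETATM records)
#' @param conf a `conformation`
#' @param path output path
#' @export
write_pdb <- function(conf, path) {
  a <- conf$topology$atoms
  res <- if (!is.null(a$resid_global)) a$resid_global else 1L
  lines <- sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), substr(a$name, 1, 4), "UNL", res,
    conf$coords[, 1], conf$coords[, 2], conf$coords[, 3], a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a two-column wavenumber/intensity trace CSV
#' @param path CSV with columns wavenumber, intensity (header optional)
#' @param kind "gain" or "depletion"
#' @return an `experimental_trace`
#' @export
read_trace <- function(path, kind = "gain") {
  first <- readLines(path, n = 1)
  header <- !grepl("^\\s*[0-9.+-]", first)
  df <- utils::read.csv(path, header = header)
  experimental_trace(df[[1]], df[[2]], kind = kind)
}

#' Write a trace to CSV
#' @param trace an `experimental_trace`
#' @param path output path
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(wavenumber = trace$wavenumber,
                              intensity = trace$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a stick spectrum to CSV with a provenance header
#' @param s a `stick_spectrum`
#' @param path output path
#' @export
write_sticks <- function(s, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# conformer=%s scaled=%s", s$provenance$conformer,
                     s$provenance$scaled), con)
  writeLines("frequency,intensity", con)
  writeLines(sprintf("%.6f,%.6f", s$frequency, s$intensity), con)
  invisible(path)
}

#' Read a stick spectrum written by [write_sticks()]
#' @param path input path
#' @return a `stick_spectrum`
#' @export
read_sticks <- function(path) {
  lines <- readLines(path)
  meta <- lines[1]
  conformer <- sub("# conformer=(\\S+) .*", "\\1", meta)
  scaled <- as.logical(sub(".*scaled=(\\S+)", "\\1", meta))
  df <- utils::read.csv(text = lines[-1])
  stick_spectrum(df$frequency, df$intensity, conformer = conformer,
                 scaled = scaled)
}
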