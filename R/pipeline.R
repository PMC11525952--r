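# Pipeline orchestration (generate -> dedupe -> optimize -> cluster ->
# spectra -> rank) and synthetic fixtures so every stage is testable
# without downloads.

#' Pipeline configuration
#'
#' A single master seed deterministically derives per-stage seeds.
#'
#' @param topology a `topology`
#' @param landscape torsion landscape supplying the energy surface (a
#'   [toy_double_well()]-style list) or NULL to use the internal force field
#' @param generator a [generator_config()]
#' @param dedupe_threshold TFD uniqueness threshold
#' @param family a [family_config()]
#' @param scaling a [scaling_scheme()]
#' @param count conformers to generate
#' @param crit a [geometric_criteria()]
#' @param seed master seed
#' @param outdir output directory (NULL = no files written)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(topology, landscape = NULL,
                            generator = generator_config(),
                            dedupe_threshold = 0.05,
                            family = family_config(),
                            scaling = scaling_scheme(),
                            count = 50, crit = geometric_criteria(),
                            seed = 1L, outdir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

.derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + stage * 104729) %% 2147483647)
}

#' Run the full conformer pipeline
#'
#' Stages: train policy -> generate -> dedupe (TFD) -> local optimization
#' -> family clustering -> candidate selection. Each stage records its
#' seed; any stage failure marks the report and preserves upstream output.
#'
#' @param config a [pipeline_config()]
#' @return run report (list) with per-stage artifacts and a `candidates`
#'   pool, plus candidate counts per charge-location stratum
#' @export
run_pipeline <- function(config) {
  topo <- config$topology
  report <- list(stages = list(), seed = config$seed)
  stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e)
                      list(ok = FALSE, error = conditionMessage(e)))
    report$stages[[name]] <<- res[setdiff(names(res), "value")]
    if (!res$ok) stop("stage '", name, "' failed: ", res$error)
    res$value
  }

  backend <- if (!is.null(config$landscape))
    backend_torsion(config$landscape$fn, config$landscape$grad)
  else backend_mm(topo)
  env <- if (!is.null(config$landscape))
    generator_env(config$landscape$n_torsions, config$landscape$fn,
                  periods = topo$torsion_periods)
  else env_from_topology(topo, backend)

  gen_cfg <- config$generator
  gen_cfg$seed <- .derive_seed(config$seed, 1L)

  state <- stage("train", train_generator(env, gen_cfg))
  confs <- stage("generate",
                 generate(topo, state, config$count,
                          seed = .derive_seed(config$seed, 2L)))
  unique_confs <- stage("dedupe", dedupe(confs, config$dedupe_threshold))
  optimized <- stage("optimize", lapply(unique_confs, function(cf) {
    res <- minimize(cf, backend, tol = 1e-4, max_steps = 500)
    res$conformation
  }))
  fams <- stage("cluster", cluster_families(optimized, config$crit))
  pool <- stage("select", select_candidates(fams, config$family))

  per_stratum <- table(pool$charge_label)
  report$candidates <- pool
  report$families <- fams
  report$n_generated <- length(confs)
  report$n_unique <- length(unique_confs)
  report$candidates_per_charge_location <- as.list(per_stratum)
  report$provenance <- list(
    master_seed = config$seed,
    stage_seeds = list(train = .derive_seed(config$seed, 1L),
                       generate = .derive_seed(config$seed, 2L)),
    version = as.character(utils::packageVersion("oligoconf")))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_family_report(fams, pool, config$outdir)
    jsonlite::write_json(
      report[c("seed", "n_generated", "n_unique",
               "candidates_per_charge_location", "provenance")],
      file.path(config$outdir, "report.json"), auto_unbox = TRUE)
  }
  report
}

#' Synthetic fixture bundle
#'
#' Emits, reproducibly from one seed: a toy chain topology with a
#' double-well landscape and its reference grid-search minima; a synthetic
#' IR trace built from a chosen conformer's sticks plus decoys; and a
#' synthetic isotope-envelope mixture with ground-truth fractions.
#'
#' @param n_torsions toy molecule size (2-6 torsions)
#' @param trace_conformer which synthetic conformer's sticks build the
#'   "experimental" trace
#' @param n_decoys number of decoy stick spectra
#' @param mixture_fractions ground-truth envelope mixture fractions
#'   (default the trimer/hexamer overlap: 0.33 / 0.67)
#' @param noise relative Gaussian noise on the synthetic trace/envelope
#' @param seed master seed
#' @return list with `topology`, `landscape`, `reference_minima`,
#'   `sticks` (list of stick spectra), `trace`, `trace_truth`,
#'   `envelope_components`, `measured_envelope`, `mixture_truth`
#' @export
make_fixture <- function(n_torsions = 2, trace_conformer = 1, n_decoys = 5,
                         mixture_fractions = c(0.33, 0.67), noise = 0,
                         seed = 1L) {
  stopifnot(n_torsions >= 2, n_torsions <= 6)
  topo <- toy_chain_topology(n_torsions)
  landscape <- toy_double_well(n_torsions)
  ref <- grid_search(landscape, step = 10)

  sticks <- .with_seed(.derive_seed(seed, 11L), {
    lapply(seq_len(n_decoys + 1), function(k) {
      nf <- 8
      f <- sort(stats::runif(nf, 1000, 3700))
      stick_spectrum(f, stats::runif(nf, 0.2, 1), conformer = paste0("c", k),
                     scaled = TRUE)
    })
  })
  truth_sticks <- sticks[[trace_conformer]]
  curve <- broaden(truth_sticks, fwhm = 8,
                   grid = seq(900, 3800, by = 1))
  y <- curve$intensity
  if (noise > 0)
    y <- .with_seed(.derive_seed(seed, 12L),
                    y + stats::rnorm(length(y), sd = noise * max(y)))
  trace <- experimental_trace(curve$wavenumber, y, kind = "gain")

  comps <- list(isotope_envelope(oligomer_ion(3, 1)),
                isotope_envelope(oligomer_ion(6, 2)))
  grid <- sort(unique(round(c(comps[[1]]$peaks$mz, comps[[2]]$peaks$mz) * 10) / 10))
  A <- align_envelopes(comps, grid)
  meas <- as.vector(A %*% mixture_fractions)
  if (noise > 0)
    meas <- .with_seed(.derive_seed(seed, 13L),
                       pmax(0, meas + stats::rnorm(length(meas),
                                                   sd = noise * max(meas))))
  measured <- data.frame(mz = grid, abundance = meas)

  list(topology = topo, landscape = landscape, reference_minima = ref,
       sticks = sticks, trace = trace, trace_truth = trace_conformer,
       envelope_components = comps, measured_envelope = measured,
       mixture_truth = mixture_fractions, seed = seed)
}
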