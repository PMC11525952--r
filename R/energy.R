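# Pluggable energy backends, monotone quasi-Newton local minimization,
# numerical mass-weighted Hessians and the external-optimizer adapter.
#
# The internal backend is force-field-level (harmonic bonds/angles +
# Lennard-Jones + Coulomb with crude charges); quantum-chemistry energetics
# are reached only through the external adapter contract.

#' Construct an energy backend
#'
#' A backend evaluates energies (kcal/mol) and gradients (kcal/mol/Angstrom
#' for Cartesian backends, kcal/mol/degree for torsion-space backends) of a
#' conformation. `space` declares whether the backend works on Cartesian
#' coordinates or on the torsion vector.
#'
#' @param name backend name (recorded in provenance)
#' @param energy function of a `conformation` returning a scalar
#' @param gradient function of a `conformation` returning the gradient in
#'   the backend's space (N x 3 matrix for cartesian, vector for torsion);
#'   NULL disables gradient capability
#' @param space "cartesian" or "torsion"
#' @return object of class `energy_backend`
#' @export
energy_backend <- function(name, energy, gradient = NULL,
                           space = c("cartesian", "torsion")) {
  space <- match.arg(space)
  structure(list(name = name, energy = energy, gradient = gradient,
                 space = space,
                 capabilities = c(energy = TRUE, gradient = !is.null(gradient))),
            class = "energy_backend")
}

#' Harmonic toy backend E = k * |x - x0|^2
#' @param x0 reference N x 3 coordinates
#' @param k force constant (kcal/mol/A^2)
#' @return an `energy_backend`
#' @export
backend_harmonic <- function(x0, k = 1) {
  x0 <- as.matrix(x0)
  energy_backend(
    name = sprintf("harmonic(k=%g)", k),
    energy = function(conf) k * sum((conf$coords - x0)^2),
    gradient = function(conf) 2 * k * (conf$coords - x0),
    space = "cartesian")
}

#' Torsion-space backend from an analytic landscape
#'
#' @param fn function of a torsion vector (degrees) returning kcal/mol
#' @param grad optional analytic gradient; default central finite differences
#' @param name backend name
#' @return an `energy_backend`
#' @export
backend_torsion <- function(fn, grad = NULL, name = "torsion-landscape") {
  if (is.null(grad)) {
    grad <- function(theta) {
      h <- 1e-4
      vapply(seq_along(theta), function(i) {
        tp <- theta; tm <- theta
        tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
        (fn(tp) - fn(tm)) / (2 * h)
      }, numeric(1))
    }
  }
  energy_backend(
    name = name,
    energy = function(conf) fn(.theta_of(conf)),
    gradient = function(conf) grad(.theta_of(conf)),
    space = "torsion")
}

.theta_of <- function(conf) {
  if (is.numeric(conf)) conf else get_torsions(conf)
}

# ---- internal force field ----------------------------------------------

# crude partial charges: polar-H/heteroatom increments, residual spread
# uniformly so the total matches the formal charge
.assign_charges <- function(topo) {
  el <- topo$atoms$element
  q <- numeric(length(el))
  for (i in seq_along(el)) {
    q[i] <- switch(el[i],
      H = {
        nb <- as.integer(igraph::neighbors(topo$graph, i))
        if (length(nb) && el[nb[1]] %in% c("N", "O")) 0.35 else 0.06
      },
      N = -0.6, O = -0.45, C = 0, S = -0.2, 0)
  }
  # carbonyl / carboxyl carbons are positive
  for (i in which(el == "C")) {
    nb <- as.integer(igraph::neighbors(topo$graph, i))
    if (sum(el[nb] == "O") >= 1) q[i] <- 0.4
  }
  q + (topo$charge - sum(q)) / length(el)
}

# pair lists with bonded exclusions (1-2, 1-3 excluded; 1-4 scaled 0.5)
.nb_pairs <- function(topo) {
  n <- nrow(topo$atoms)
  sp <- igraph::distances(topo$graph)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  bd <- sp[idx]
  keep <- bd >= 3
  data.frame(i = idx[keep, 1], j = idx[keep, 2],
             scale = ifelse(bd[keep] == 3, 0.5, 1))
}

.angle_triples <- function(topo) {
  out <- NULL
  for (j in seq_len(nrow(topo$atoms))) {
    nb <- as.integer(igraph::neighbors(topo$graph, j))
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    out <- rbind(out, data.frame(i = cmb[1, ], j = j, k = cmb[2, ]))
  }
  out
}

#' Internal molecular-mechanics backend
#'
#' Harmonic bonds (reference lengths from covalent radii), harmonic angles
#' (sp2/sp3 reference angles), Lennard-Jones and Coulomb terms with crude
#' formal-charge-constrained partial charges. Force-field-level only: it
#' orders conformers sensibly but does not reproduce quantum-chemistry
#' energy gaps.
#'
#' @param topo a `topology`
#' @param k_bond,k_angle force constants (kcal/mol/A^2, kcal/mol/rad^2)
#' @param dielectric relative dielectric for the Coulomb term
#' @return an `energy_backend`
#' @export
backend_mm <- function(topo, k_bond = 300, k_angle = 50, dielectric = 1) {
  el <- topo$atoms$element
  bonds <- topo$bonds
  r0 <- .cov_radius[el[bonds$i]] + .cov_radius[el[bonds$j]]
  r0 <- ifelse(bonds$order == 2, 0.87 * r0, r0)

  ring_atoms <- unique(unlist(lapply(topo$rings, `[[`, "atoms")))
  deg <- igraph::degree(topo$graph)
  sp2 <- seq_len(nrow(topo$atoms)) %in% ring_atoms |
    vapply(seq_len(nrow(topo$atoms)), function(i)
      any(bonds$order[bonds$i == i | bonds$j == i] == 2), logical(1))
  ang <- .angle_triples(topo)
  theta0 <- ifelse(sp2[ang$j], 120, 109.5) * pi / 180

  q <- .assign_charges(topo)
  nb <- .nb_pairs(topo)
  sig_i <- vapply(el, function(e) .lj_params[[e]]["sigma"], numeric(1))
  eps_i <- vapply(el, function(e) .lj_params[[e]]["eps"], numeric(1))
  nb$sigma <- (sig_i[nb$i] + sig_i[nb$j]) / 2
  nb$eps <- sqrt(eps_i[nb$i] * eps_i[nb$j])
  nb$qq <- 332.0637 * q[nb$i] * q[nb$j] / dielectric

  eval_ff <- function(xyz, want_grad = FALSE) {
    g <- if (want_grad) matrix(0, nrow(xyz), 3) else NULL
    E <- 0
    # bonds
    dvec <- xyz[bonds$i, , drop = FALSE] - xyz[bonds$j, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    E <- E + sum(k_bond * (d - r0)^2)
    if (want_grad) {
      f <- 2 * k_bond * (d - r0) / d
      gb <- dvec * f
      for (c_ in 1:3) {
        add <- tapply(c(gb[, c_], -gb[, c_]), c(bonds$i, bonds$j), sum)
        ids <- as.integer(names(add))
        g[ids, c_] <- g[ids, c_] + add
      }
    }
    # angles
    if (!is.null(ang)) {
      for (t in seq_len(nrow(ang))) {
        i <- ang$i[t]; j <- ang$j[t]; k <- ang$k[t]
        u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
        nu <- .vnorm(u); nv <- .vnorm(v)
        cth <- max(-1, min(1, sum(u * v) / (nu * nv)))
        th <- acos(cth)
        dth <- th - theta0[t]
        E <- E + k_angle * dth^2
        if (want_grad && abs(cth) < 0.9999) {
          sth <- sqrt(1 - cth^2)
          dcos_i <- (v / (nu * nv)) - cth * u / nu^2
          dcos_k <- (u / (nu * nv)) - cth * v / nv^2
          pref <- -2 * k_angle * dth / sth
          g[i, ] <- g[i, ] + pref * dcos_i
          g[k, ] <- g[k, ] + pref * dcos_k
          g[j, ] <- g[j, ] - pref * (dcos_i + dcos_k)
        }
      }
    }
    # nonbonded
    if (nrow(nb)) {
      dvec <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
      d2 <- rowSums(dvec^2); d <- sqrt(d2)
      sr6 <- (nb$sigma^2 / d2)^3
      Elj <- 4 * nb$eps * (sr6^2 - sr6)
      Eq <- nb$qq / d
      E <- E + sum(nb$scale * (Elj + Eq))
      if (want_grad) {
        # dE/dd
        dE <- nb$scale * (4 * nb$eps * (-12 * sr6^2 + 6 * sr6) / d - Eq / d)
        f <- dE / d
        gnb <- dvec * f
        for (c_ in 1:3) {
          add <- tapply(c(gnb[, c_], -gnb[, c_]), c(nb$i, nb$j), sum)
          ids <- as.integer(names(add))
          g[ids, c_] <- g[ids, c_] + add
        }
      }
    }
    list(E = E, g = g)
  }

  energy_backend(
    name = "internal-mm",
    energy = function(conf) eval_ff(conf$coords)$E,
    gradient = function(conf) eval_ff(conf$coords, want_grad = TRUE)$g,
    space = "cartesian")
}

# ---- minimization -------------------------------------------------------

#' Local geometry optimization
#'
#' Monotone quasi-Newton (BFGS with Armijo backtracking line search) in the
#' backend's space. The energy trace is non-increasing over accepted steps;
#' non-convergence within `max_steps` flags the result but keeps it.
#'
#' @param conf starting `conformation`
#' @param backend an `energy_backend` with gradient capability
#' @param tol gradient infinity-norm tolerance (default 1e-4)
#' @param max_steps maximum accepted steps (default 2000)
#' @return object of class `optimization_result` with fields `conformation`,
#'   `energy_trace`, `converged`, `gradient_norm`, `steps`
#' @export
minimize <- function(conf, backend, tol = 1e-4, max_steps = 2000) {
  if (!backend$capabilities["gradient"])
    stop("backend '", backend$name, "' does not provide gradients")
  torsion_space <- backend$space == "torsion"
  x <- if (torsion_space) get_torsions(conf) else as.vector(conf$coords)

  to_conf <- function(x) {
    if (torsion_space) set_torsions(conf, x)
    else conformation(conf$topology, matrix(x, ncol = 3),
                      label = conf$label, provenance = conf$provenance)
  }
  fE <- function(x) backend$energy(to_conf(x))
  fG <- function(x) as.vector(backend$gradient(to_conf(x)))

  n <- length(x)
  H <- diag(n)                      # inverse-Hessian approximation
  E <- fE(x); g <- fG(x)
  trace <- E
  steps <- 0L
  converged <- max(abs(g)) <= tol
  while (!converged && steps < max_steps) {
    p <- -as.vector(H %*% g)
    if (sum(p * g) > 0) { H <- diag(n); p <- -g }  # reset on bad curvature
    alpha <- 1; accepted <- FALSE
    for (ls in 1:40) {
      xn <- x + alpha * p
      En <- fE(xn)
      if (is.finite(En) && En <= E + 1e-4 * alpha * sum(g * p)) {
        accepted <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    gn <- fG(xn)
    s <- xn - x; y <- gn - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(n)
      H <- (I - rho * outer(s, y)) %*% H %*% (I - rho * outer(y, s)) +
        rho * outer(s, s)
    }
    x <- xn; E <- En; g <- gn
    steps <- steps + 1L
    trace <- c(trace, E)
    converged <- max(abs(g)) <= tol
  }
  out_conf <- to_conf(x)
  out_conf$energy <- E
  out_conf$provenance <- paste0(out_conf$provenance,
                                "|min:", backend$name)
  structure(list(conformation = out_conf, energy_trace = trace,
                 converged = converged, gradient_norm = max(abs(g)),
                 steps = steps),
            class = "optimization_result")
}

#' Mass-weighted numerical Hessian at a minimum
#'
#' Central finite differences of the backend gradient, symmetrized, then
#' mass-weighted (H_mw = M^-1/2 H M^-1/2, amu).
#'
#' @param conf a converged `conformation`
#' @param backend a Cartesian `energy_backend` with gradients
#' @param step displacement step (Angstrom, default 0.005)
#' @param masses optional per-atom masses (amu) overriding the element
#'   defaults, e.g. for isotope-substitution studies
#' @return object of class `hessian_result` with `matrix` (3N x 3N,
#'   kcal/mol/A^2/amu), `masses` and the conformation
#' @export
numerical_hessian <- function(conf, backend, step = 0.005, masses = NULL) {
  if (backend$space != "cartesian")
    stop("numerical_hessian requires a Cartesian backend")
  xyz <- conf$coords
  n3 <- 3 * nrow(xyz)
  H <- matrix(0, n3, n3)
  flat <- function(g) as.vector(t(g))   # atom-major (x1,y1,z1,x2,...)
  for (d in seq_len(n3)) {
    at <- (d - 1) %/% 3 + 1; cc <- (d - 1) %% 3 + 1
    xp <- xyz; xp[at, cc] <- xp[at, cc] + step
    xm <- xyz; xm[at, cc] <- xm[at, cc] - step
    gp <- flat(backend$gradient(conformation(conf$topology, xp)))
    gm <- flat(backend$gradient(conformation(conf$topology, xm)))
    if (any(!is.finite(gp)) || any(!is.finite(gm)))
      stop("gradient failure at displacement of coordinate ", d)
    H[d, ] <- (gp - gm) / (2 * step)
  }
  H <- (H + t(H)) / 2
  if (is.null(masses))
    masses <- vapply(conf$topology$atoms$element, .element_mass, numeric(1))
  stopifnot(length(masses) == nrow(xyz))
  mvec <- rep(masses, each = 3)
  Hmw <- H / sqrt(outer(mvec, mvec))
  structure(list(matrix = Hmw, masses = masses, conformation = conf,
                 step = step, backend = backend$name),
            class = "hessian_result")
}

# ---- external optimizer adapter ----------------------------------------

#' Run an external geometry optimizer through the adapter contract
#'
#' Writes the conformation as XYZ, invokes the configured command in a work
#' directory, and parses the optimized geometry (XYZ with `energy=` on the
#' comment line) back. Never falls back to an internal backend.
#'
#' @param conf a `conformation`
#' @param adapter list with `command` (string, run via a shell), `name`,
#'   optional `workdir`, `input` and `output` file names
#' @return an `optimization_result` with adapter provenance
#' @export
external_optimize <- function(conf, adapter) {
  stopifnot(is.list(adapter), !is.null(adapter$command))
  name <- adapter$name %||% "external"
  wd <- adapter$workdir %||% tempfile("extopt")
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  input <- file.path(wd, adapter$input %||% "input.xyz")
  output <- file.path(wd, adapter$output %||% "output.xyz")
  write_xyz(conf, input)
  exe <- strsplit(adapter$command, "\\s+")[[1]][1]
  if (Sys.which(exe) == "" && !file.exists(exe))
    stop("external backend unavailable: executable '", exe, "' not found")
  status <- system(sprintf("cd %s && %s", shQuote(wd), adapter$command),
                   ignore.stdout = TRUE, ignore.stderr = TRUE)
  if (status != 0 || !file.exists(output))
    stop("external backend failed (exit ", status, "), expected output: ",
         output)
  frames <- tryCatch(read_xyz(output, topology = conf$topology),
                     error = function(e)
                       stop("malformed adapter output in ", output, ": ",
                            conditionMessage(e)))
  if (!length(frames))
    stop("malformed adapter output in ", output, ": no frames")
  final <- frames[[length(frames)]]
  final$label <- conf$label
  final$provenance <- paste0(conf$provenance, "|external:", name)
  structure(list(conformation = final,
                 energy_trace = final$energy %||% NA_real_,
                 converged = TRUE, gradient_norm = NA_real_,
                 steps = NA_integer_),
            class = "optimization_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
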