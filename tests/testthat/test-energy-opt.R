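# Energy backends, local minimization, numerical Hessians, external adapter.

test_that("minimize handles exact and harmonic minima", {
  topo <- simple_topology(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)),
                          data.frame(i = 1, j = 2))
  x0 <- rbind(c(0, 0, 0), c(2, 0, 0))
  be <- backend_harmonic(x0, k = 3)

  # start at the exact minimum: zero accepted steps
  res0 <- minimize(conformation(topo, x0), be)
  expect_true(res0$converged)
  expect_equal(res0$steps, 0L)

  # from a displaced start: converges to x0
  start <- x0 + matrix(c(0.5, -0.3, 0.2, -0.1, 0.4, 0.3), 2, 3)
  res <- minimize(conformation(topo, start), be, tol = 1e-8)
  expect_true(res$converged)
  expect_equal(res$conformation$coords, x0, tolerance = 1e-5)
  expect_true(all(diff(res$energy_trace) <= 1e-12))
  expect_error(minimize(conformation(topo, x0),
                        energy_backend("nograd", function(conf) 0)),
               "does not provide gradients")
})

test_that("multistart minimization recovers the exhaustive grid minima set", {
  lw <- toy_double_well(2)
  gs <- grid_search(lw, step = 10)
  expect_equal(nrow(gs$minima), 4L)

  bt <- backend_torsion(lw$fn, lw$grad)
  topo <- toy_chain_topology(2)
  ref <- conformation(topo)
  # gradient-only optimization can stop on ridge saddles; a stationary
  # point counts as a found minimum only if the landscape confirms it
  found <- withr::with_seed(17, {
    pts <- do.call(rbind, lapply(1:100, function(i) {
      c0 <- set_torsions(ref, runif(2, -180, 180))
      round(wrap_angle(get_torsions(
        minimize(c0, bt, tol = 1e-8)$conformation)) / 5) * 5
    }))
    unique(pts[apply(pts, 1, function(p) is_landscape_minimum(lw, p)), ,
               drop = FALSE])
  })
  found <- found[order(found[, 1], found[, 2]), , drop = FALSE]
  expected <- gs$minima[order(gs$minima[, 1], gs$minima[, 2]), , drop = FALSE]
  expect_equal(unname(found), unname(expected))
})

test_that("internal force field is rigid-motion invariant to 1e-6", {
  topo <- build_oligomer(oligomer_spec(1, 1, protonation_state("protonated")))
  be <- backend_mm(topo)
  conf <- conformation(topo)
  E0 <- be$energy(conf)
  withr::with_seed(5, {
    for (k in 1:5) {
      R <- qr.Q(qr(matrix(rnorm(9), 3)))
      if (det(R) < 0) R[, 1] <- -R[, 1]
      moved <- conformation(topo, rigid_transform(conf$coords, R,
                                                  rnorm(3, sd = 10)))
      expect_equal(be$energy(moved), E0, tolerance = 1e-6)
    }
  })
})

test_that("diatomic Hessian reproduces the closed-form frequency", {
  k <- 500; d0 <- 1.2
  conf <- diatomic_conf(d0)
  be <- diatomic_backend(k, d0)
  h <- numerical_hessian(conf, be)
  expect_equal(h$matrix, t(h$matrix))              # symmetric
  s <- harmonic_spectrum(h, linear = TRUE)
  mu <- 12.011 * 15.999 / (12.011 + 15.999)
  closed_form <- sqrt(2 * k / mu) * FREQ_CONV_ORACLE
  expect_equal(s$frequency, closed_form, tolerance = 1e-3)

  # step halving changes the frequency by < 0.1%
  s2 <- harmonic_spectrum(numerical_hessian(conf, be, step = 0.0025),
                          linear = TRUE)
  expect_lt(abs(s2$frequency - s$frequency) / s$frequency, 1e-3)

  # doubling all masses scales frequencies by 1/sqrt(2)
  sd2 <- harmonic_spectrum(
    numerical_hessian(conf, be, masses = 2 * c(12.011, 15.999)),
    linear = TRUE)
  expect_equal(sd2$frequency, s$frequency / sqrt(2), tolerance = 1e-6)
})

test_that("nonlinear minimum has 6 near-zero modes and real eigenvalues", {
  # bent triatomic under the internal force field
  topo <- simple_topology(c("O", "H", "H"),
                          rbind(c(0, 0, 0), c(0.97, 0, 0),
                                c(-0.3, 0.92, 0)),
                          data.frame(i = c(1, 1), j = c(2, 3)))
  be <- backend_mm(topo)
  res <- minimize(conformation(topo), be, tol = 1e-8)
  expect_true(res$converged)
  # small step: the soft rotational modes carry O(step) FD contamination
  h <- numerical_hessian(res$conformation, be, step = 0.001)
  ev <- eigen(h$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(abs(Im(ev)) == 0))
  freqs <- sign(ev) * sqrt(abs(ev)) * FREQ_CONV_ORACLE
  near_zero <- sum(abs(freqs) < 5)
  expect_equal(near_zero, 6L)
  expect_equal(length(harmonic_spectrum(h)$frequency), 3L)  # 3N - 6
})

test_that("external adapter round-trips, errors on bad output/executable", {
  topo <- toy_chain_topology(2)
  conf <- conformation(topo, label = "ext")

  wd <- withr::local_tempdir()
  ok <- external_optimize(conf, list(command = "cp input.xyz output.xyz",
                                     name = "mock", workdir = wd))
  expect_equal(ok$conformation$coords, conf$coords, tolerance = 1e-6)
  expect_match(ok$conformation$provenance, "external:mock")

  wd2 <- withr::local_tempdir()
  expect_error(
    external_optimize(conf, list(command = "echo garbage > output.xyz",
                                 workdir = wd2)),
    "malformed adapter output")

  expect_error(
    external_optimize(conf, list(command = "no_such_program_xyz input")),
    "external backend unavailable")
})
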