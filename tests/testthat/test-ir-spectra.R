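# Harmonic spectra, region-wise scaling, broadening, matching, free-OH.

# mass-weighted Hessian with prescribed vibrational frequencies (cm^-1)
# plus 6 zero modes, as a plain diagonal matrix
hessian_with_freqs <- function(freqs) {
  lam <- (freqs / FREQ_CONV_ORACLE)^2 * sign(freqs)
  diag(c(rep(0, 6), lam))
}

test_that("harmonic_spectrum converts eigenvalues and rejects saddles", {
  s <- harmonic_spectrum(hessian_with_freqs(c(500, 1500, 3600)))
  expect_equal(s$frequency, c(500, 1500, 3600), tolerance = 1e-9)
  expect_false(s$provenance$scaled)

  expect_error(harmonic_spectrum(hessian_with_freqs(c(-50, 1500, 3600))),
               "not a minimum")
  # sub-threshold imaginary contamination is tolerated as numerical noise
  expect_silent(harmonic_spectrum(hessian_with_freqs(c(-3, 1500, 3600))))
})

test_that("apply_scaling uses 0.955/0.983 by region and refuses reuse", {
  s <- stick_spectrum(c(1700, 3600), c(1, 2))
  ss <- apply_scaling(s)
  expect_equal(ss$frequency, c(1700 * 0.983, 3600 * 0.955))
  expect_equal(ss$frequency, c(1671.1, 3438.0))
  expect_equal(ss$intensity, c(1, 2))          # count and order preserved
  expect_true(ss$provenance$scaled)
  expect_error(apply_scaling(ss), "already scaled")

  empty <- apply_scaling(stick_spectrum(numeric(0)))
  expect_length(empty$frequency, 0L)

  # ordering preserved for many sticks
  withr::with_seed(2, {
    f <- sort(runif(20, 1000, 3700))
    sc <- apply_scaling(stick_spectrum(f))
    expect_length(sc$frequency, 20L)
    expect_true(!is.unsorted(sc$frequency))
  })
})

test_that("broaden peaks at sticks and conserves area", {
  one <- broaden(stick_spectrum(2000, 3), fwhm = 8)
  expect_equal(one$wavenumber[which.max(one$intensity)], 2000,
               tolerance = 0.5)
  # area equals total stick intensity (unit-area Gaussians)
  area <- sum(one$intensity) * diff(one$wavenumber[1:2])
  expect_equal(area, 3, tolerance = 0.01)

  two <- broaden(stick_spectrum(c(1500, 3000)), fwhm = 8)
  # two resolved maxima
  y <- two$intensity
  local_max <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- two$wavenumber[local_max[y[local_max] > 0.5 * max(y)]]
  expect_length(peaks, 2L)

  expect_warning(broaden(stick_spectrum(c(1000, 3000)), fwhm = 8,
                         grid = seq(900, 1100, 1)), "cover")
})

test_that("match_score: identity, negation, scale invariance", {
  tr <- broaden(stick_spectrum(c(1200, 1800, 3500), c(1, 0.5, 0.8)),
                fwhm = 8, grid = seq(1000, 3700, 1))
  expect_equal(match_score(tr, tr), 1.0, tolerance = 1e-9)

  neg <- experimental_trace(tr$wavenumber, -tr$intensity)
  expect_equal(match_score(tr, neg), -1.0, tolerance = 1e-9)

  scaled <- experimental_trace(tr$wavenumber, 7.3 * tr$intensity)
  expect_equal(match_score(tr, scaled), 1.0, tolerance = 1e-9)

  # depletion traces are inverted before scoring
  dep <- experimental_trace(tr$wavenumber, -tr$intensity, kind = "depletion")
  expect_equal(match_score(tr, dep), 1.0, tolerance = 1e-9)

  far <- experimental_trace(seq(4000, 4100, 1), rep(1, 101))
  expect_error(match_score(tr, far), "overlap")
})

test_that("generating conformer outranks decoys on synthetic traces", {
  fx <- make_fixture(seed = 42, n_decoys = 5)
  scores <- vapply(fx$sticks, function(s)
    match_score(broaden(s, 8, seq(900, 3800, 1)), fx$trace), numeric(1))
  expect_equal(which.max(scores), fx$trace_truth)
})

test_that("free-OH diagnostic window is a closed interval", {
  expect_true(free_oh_diagnostic(stick_spectrum(3571, scaled = TRUE)))
  expect_false(free_oh_diagnostic(stick_spectrum(c(1600, 3400),
                                                 scaled = TRUE)))
  expect_true(free_oh_diagnostic(stick_spectrum(3550, scaled = TRUE)))
  expect_true(free_oh_diagnostic(stick_spectrum(3600, scaled = TRUE)))
  expect_false(free_oh_diagnostic(stick_spectrum(3601, scaled = TRUE)))
  # configurable window
  expect_true(free_oh_diagnostic(stick_spectrum(3450, scaled = TRUE),
                                 window = c(3400, 3500)))
})

test_that("trace and stick CSV round-trip through their readers", {
  tr <- broaden(stick_spectrum(c(1500, 2000)), fwhm = 10)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, p1)
  back <- read_trace(p1)
  expect_equal(back$wavenumber, tr$wavenumber)
  expect_equal(back$intensity, tr$intensity, tolerance = 1e-12)

  s <- stick_spectrum(c(1500.5, 3600.25), c(0.4, 1), conformer = "pn1",
                      scaled = TRUE)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sticks(s, p2)
  s2 <- read_sticks(p2)
  expect_equal(s2$frequency, s$frequency)
  expect_equal(s2$provenance$conformer, "pn1")
  expect_true(s2$provenance$scaled)
})
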