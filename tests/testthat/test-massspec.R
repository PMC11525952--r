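# Formula arithmetic, isotope envelopes, mixture decomposition, assignment.

test_that("mz reproduces reference masses and peak labels", {
  # bare proton
  expect_equal(mz(ion_formula(c(H = 0), z = 1)), 1.00728, tolerance = 1e-5)
  # carbon-12 neutral mass is exactly 12 on the unified scale
  expect_equal(mz(ion_formula(c(C = 1), z = 0)), 12)

  expect_error(ion_formula(c(Zz = 1)), "unknown element")

  # the oligomer series peak labels (monoisotopic)
  expect_equal(nominal_mz(mz(oligomer_ion(1, 1))), 313)
  expect_equal(nominal_mz(mz(oligomer_ion(2, 1))), 625)
  expect_equal(nominal_mz(mz(oligomer_ion(8, 2))), 1250)
  # the trimer/hexamer overlap peak reported on the average-mass convention
  expect_equal(nominal_mz(mz(oligomer_ion(3, 1), "average")), 938)

  # homologous series: nominal m/z from formula arithmetic for n = 1..13
  for (n in 1:13) {
    f1 <- oligomer_ion(n, 1)
    m_neutral <- mz(ion_formula(c(C = 18, H = 20, N = 2, O = 3), z = 0))
    expect_equal(mz(f1), n * m_neutral + 1.00728, tolerance = 1e-4)
  }
})

test_that("isotope envelopes match binomial closed forms and normalize", {
  p13 <- 0.0107; p12 <- 0.9893
  e1 <- isotope_envelope(ion_formula(c(C = 1), z = 1))
  expect_equal(e1$peaks$abundance[2] / e1$peaks$abundance[1], p13 / p12,
               tolerance = 1e-9)

  e2 <- isotope_envelope(ion_formula(c(C = 2), z = 1))
  expect_equal(e2$peaks$abundance[2] / e2$peaks$abundance[1],
               2 * p12 * p13 / p12^2, tolerance = 1e-9)

  for (f in list(oligomer_ion(1, 1), oligomer_ion(3, 1), oligomer_ion(6, 2))) {
    env <- isotope_envelope(f)
    expect_equal(sum(env$peaks$abundance), 1, tolerance = 1e-9)
    expect_true(!is.unsorted(env$peaks$mz))
    expect_true(all(env$peaks$abundance >= 0))
  }

  # peak spacing identifies the charge state: 1/z Th
  e_z2 <- isotope_envelope(oligomer_ion(6, 2))
  expect_equal(mean(diff(e_z2$peaks$mz)), 0.5017, tolerance = 1e-3)
})

test_that("envelope of a combined formula equals the convolution", {
  pa <- isotope_envelope(ion_formula(c(C = 3), z = 1), prune = 1e-12,
                         profile = TRUE)$peaks
  pb <- isotope_envelope(ion_formula(c(N = 2), z = 1), prune = 1e-12,
                         profile = TRUE)$peaks
  pab <- isotope_envelope(ion_formula(c(C = 3, N = 2), z = 1), prune = 1e-12,
                          profile = TRUE)$peaks
  # independent convolution of the two profiles (one proton double-counted:
  # subtract its mass once from the sum)
  proton <- 1.007276466621
  conv <- outer(pa$abundance, pb$abundance)
  mass <- outer(pa$mz, pb$mz, "+") - proton
  agg <- tapply(as.vector(conv), round(as.vector(mass) * 1e5), sum)
  ours <- tapply(pab$abundance, round(pab$mz * 1e5), sum)
  common <- intersect(names(agg), names(ours))
  expect_gte(length(common), 3L)
  expect_equal(as.numeric(ours[common]), as.numeric(agg[common]),
               tolerance = 1e-9)
})

test_that("fit_mixture recovers fractions and reports degeneracy", {
  comps <- list(isotope_envelope(oligomer_ion(3, 1)),
                isotope_envelope(oligomer_ion(6, 2)))

  # pure component
  pure <- comps[[2]]
  ft <- fit_mixture(pure, comps)
  expect_equal(ft$fractions[2], 1.0, tolerance = 1e-6)
  expect_lt(ft$residual, 1e-6)

  # forward-model round trip at the overlap peak
  fx <- make_fixture(seed = 1)
  ft2 <- fit_mixture(fx$measured_envelope, fx$envelope_components)
  expect_equal(ft2$fractions, fx$mixture_truth, tolerance = 0.01)

  # scale invariance of measured intensities
  scaled <- fx$measured_envelope
  scaled$abundance <- scaled$abundance * 1234
  ft3 <- fit_mixture(scaled, fx$envelope_components)
  expect_equal(ft3$fractions, ft2$fractions, tolerance = 1e-9)

  # degenerate components flagged, fit still returned
  expect_warning(ftd <- fit_mixture(pure, list(comps[[2]], comps[[2]])),
                 "degenerate")
  expect_true(ftd$degenerate)
  expect_equal(sum(ftd$fractions), 1, tolerance = 1e-9)
})

test_that("assign_peak resolves the 938 Th trimer/hexamer ambiguity", {
  res <- assign_peak(938, tol = 1)
  expect_true(any(res$n == 3 & res$z == 1))
  expect_true(any(res$n == 6 & res$z == 2))
  # 313 is singly protonated monomer
  res313 <- assign_peak(313, tol = 1)
  expect_true(any(res313$n == 1 & res313$z == 1))
  # far from any series member
  expect_equal(nrow(assign_peak(400, tol = 0.5)), 0L)
})
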