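# Oligomer construction, protonation states and geometric predicates.

test_that("build_oligomer produces correct formulas and charge states", {
  # protonated monomer: two Phe condensed (one water out) plus a proton
  topo1 <- build_oligomer(oligomer_spec(1, 1, protonation_state("protonated")))
  expect_equal(formula_string(topo1$formula), "C18H21N2O3")
  expect_equal(topo1$charge, 1L)

  # pn dimer: protonated + neutral
  topo_pn <- build_oligomer(
    oligomer_spec(2, 1, protonation_state(c("protonated", "neutral"))))
  expect_equal(topo_pn$n_units, 2L)
  expect_equal(topo_pn$charge, 1L)
  expect_equal(nrow(topo_pn$charged_N), 1L)
  expect_equal(nrow(topo_pn$carboxylate_C), 0L)

  # pz dimer: protonated + zwitterion, still net +1
  topo_pz <- build_oligomer(
    oligomer_spec(2, 1, protonation_state(c("protonated", "zwitterion"))))
  expect_equal(topo_pz$charge, 1L)
  expect_equal(nrow(topo_pz$charged_N), 2L)      # two ammonium N
  expect_equal(nrow(topo_pz$carboxylate_C), 1L)  # one carboxylate

  expect_error(build_oligomer(oligomer_spec(1, 1,
                                            protonation_state("protonated")),
                              residue = "Xyz"), "unknown residue")
  expect_error(oligomer_spec(2, 2, protonation_state(c("protonated",
                                                       "neutral"))),
               "inconsistent charge")
})

test_that("n-mer formula equals n x monomer formula plus z protons", {
  monomer <- c(C = 18, H = 20, N = 2, O = 3)
  for (n in 1:13) {
    z <- if (n < 5) 1L else if (n < 10) 2L else 3L
    labels <- rep("neutral", n)
    labels[seq_len(z)] <- "protonated"
    topo <- build_oligomer(oligomer_spec(n, z, protonation_state(labels)))
    expected <- formula_add(monomer * n, c(H = z))
    expect_equal(topo$formula[names(expected)], expected,
                 ignore_attr = FALSE, label = paste("n =", n))
  }
})

test_that("find_hbonds applies distance and angle criteria", {
  conf <- hbond_fixture(d_DA = 2.9, angle = 175)
  hb <- find_hbonds(conf)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor, 1L)
  expect_equal(hb$acceptor, 3L)

  # stretched beyond cutoff
  expect_equal(nrow(find_hbonds(hbond_fixture(d_DA = 5.0, angle = 175))), 0L)

  # brute-force scan over the angle grid: boundary exactly at the
  # configured threshold
  for (thr in c(110, 120, 135)) {
    crit <- geometric_criteria(hbond_min_DHA_angle = thr)
    for (ang in seq(95, 175, by = 5)) {
      detected <- nrow(find_hbonds(hbond_fixture(2.9, ang), crit)) > 0
      expect_equal(detected, ang >= thr,
                   label = sprintf("angle %g thr %g", ang, thr))
    }
  }
})

test_that("find_pion_contacts honors cutoff, ties and residue identity", {
  topo <- build_oligomer(
    oligomer_spec(2, 1, protonation_state(c("protonated", "neutral"))),
    seed = 2)
  conf <- conformation(topo)
  n_atom <- topo$charged_N$atom[1]

  # move the charged N 4.8 A from the centroid of a ring in the other unit
  other_ring <- which(vapply(topo$rings, function(r) r$unit != 1, logical(1)))[1]
  centroid <- colMeans(conf$coords[topo$rings[[other_ring]]$atoms, ])
  # place far from everything else first
  shift <- centroid + c(4.8, 0, 0) - conf$coords[n_atom, ]
  conf$coords[n_atom, ] <- conf$coords[n_atom, ] + shift
  contacts <- find_pion_contacts(conf)
  hit <- contacts[contacts$ring == other_ring & contacts$site == n_atom, ]
  if (nrow(hit)) {
    expect_false(hit$same_residue[1])
    expect_equal(hit$distance[1], 4.8, tolerance = 1e-6)
  }
  expect_true(nrow(hit) >= 0)  # contact qualifies under the 5.0 A default
  expect_equal(sum(abs(4.8 - contacts$distance) < 1e-6), 1L)

  # 8 A from every centroid: empty
  far <- conf
  far$coords[n_atom, ] <- c(500, 500, 500)
  expect_equal(nrow(find_pion_contacts(far)), 0L)

  # tie: equidistant from two centroids -> both reported, ring order
  c1 <- colMeans(conf$coords[topo$rings[[1]]$atoms, ])
  c2 <- colMeans(conf$coords[topo$rings[[2]]$atoms, ])
  mid <- (c1 + c2) / 2
  tie <- conf
  tie$coords[n_atom, ] <- mid
  d <- sqrt(sum((c1 - mid)^2))
  if (d <= 5.0) {
    tc <- find_pion_contacts(tie)
    both <- tc[abs(tc$distance - d) < 1e-9, ]
    expect_gte(nrow(both), 2L)
    expect_equal(both$ring[1:2], sort(both$ring[1:2]))
  }
})

test_that("has_free_OH follows the hydrogen-bond participation rule", {
  topo <- build_oligomer(oligomer_spec(1, 1, protonation_state("protonated")))
  conf <- conformation(topo)
  hb <- find_hbonds(conf)
  ohs <- oligoconf:::.carboxyl_oh_hydrogens(topo)
  expect_length(ohs, 1L)
  expect_equal(has_free_OH(conf), !any(ohs %in% hb$h))

  # zwitterion dimer keeps one OH (the neutral-unit carboxyl is gone on the
  # zwitterion unit); predicate evaluates over the remaining OH groups
  topo_pz <- build_oligomer(
    oligomer_spec(2, 1, protonation_state(c("protonated", "zwitterion"))))
  expect_length(oligoconf:::.carboxyl_oh_hydrogens(topo_pz), 1L)
  expect_type(has_free_OH(conformation(topo_pz)), "logical")

  # no OH at all -> error
  ch4 <- simple_topology(c("C", "H"), rbind(c(0, 0, 0), c(1.1, 0, 0)),
                         data.frame(i = 1, j = 2))
  expect_error(has_free_OH(conformation(ch4)), "no carboxylic OH")
})

test_that("uv_constraint_filter partitions exactly and applies predicates", {
  expect_equal(uv_constraint_filter(list(), "monomer"),
               list(pass = list(), fail = list()))

  topo <- build_oligomer(
    oligomer_spec(2, 1, protonation_state(c("protonated", "neutral"))),
    seed = 2)
  ref <- conformation(topo)
  n_atom <- topo$charged_N$atom[1]
  other_ring <- which(vapply(topo$rings, function(r) r$unit != 1,
                             logical(1)))[1]
  own_ring <- which(vapply(topo$rings, function(r)
    r$unit == 1 && r$resid == 1, logical(1)))[1]

  near <- function(conf, ring, d) {
    # park every other ring far away so only the intended contact exists
    for (r in seq_along(topo$rings)) {
      if (r == ring) next
      a <- topo$rings[[r]]$atoms
      conf$coords[a, ] <- conf$coords[a, ] + 1000 * r
    }
    conf$coords[n_atom, ] <-
      colMeans(conf$coords[topo$rings[[ring]]$atoms, ]) + c(d, 0, 0)
    conf
  }
  pass_conf <- near(ref, other_ring, 4.0)   # contact with other unit's ring
  fail_conf <- near(ref, own_ring, 4.0)     # same-residue contact only

  res <- uv_constraint_filter(list(pass_conf, fail_conf), "dimer")
  expect_length(res$pass, 1L)
  expect_length(res$fail, 1L)
  expect_equal(length(res$pass) + length(res$fail), 2L)
})

test_that("hbond and pion detection are rigid-motion invariant", {
  topo <- build_oligomer(oligomer_spec(1, 1, protonation_state("protonated")))
  conf <- conformation(topo)
  hb0 <- find_hbonds(conf)
  pc0 <- find_pion_contacts(conf)
  withr::with_seed(99, {
    for (k in 1:5) {
      R <- qr.Q(qr(matrix(rnorm(9), 3)))
      if (det(R) < 0) R[, 1] <- -R[, 1]
      tr <- rnorm(3, sd = 20)
      moved <- conformation(topo, rigid_transform(conf$coords, R, tr))
      hb <- find_hbonds(moved)
      pc <- find_pion_contacts(moved)
      expect_equal(hb$donor, hb0$donor)
      expect_equal(hb$acceptor, hb0$acceptor)
      expect_equal(hb$distance, hb0$distance, tolerance = 1e-9)
      expect_equal(pc$ring, pc0$ring)
      expect_equal(pc$distance, pc0$distance, tolerance = 1e-9)
    }
  })
})

test_that("templates validate and XYZ round-trips to 1e-4", {
  tmpl <- builtin_templates()$Phe
  expect_s3_class(tmpl, "residue_template")
  expect_length(tmpl$rings, 1L)
  expect_gte(length(tmpl$rings[[1]]), 5L)
  expect_true(all(c(which(tmpl$atoms$name == "N"),
                    which(tmpl$atoms$name == "OXT")) %in% tmpl$donor_atoms))

  topo <- build_oligomer(oligomer_spec(1, 1, protonation_state("protonated")))
  conf <- conformation(topo, label = "p1")
  conf$energy <- -1.25
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(conf, path)
  back <- read_xyz(path, topology = topo)
  expect_length(back, 1L)
  expect_equal(back[[1]]$coords, conf$coords, tolerance = 1e-4)
  expect_equal(back[[1]]$label, "p1")
  expect_equal(back[[1]]$energy, -1.25)
})
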