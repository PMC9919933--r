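test_that("binding energy is minus the interaction energy and vanishes for non-interacting sums", {
  expect_equal(binding_energy(-100, -30, -50)$e_binding, 20)
  expect_equal(binding_energy(0, 0, 0)$e_binding, 0)
  set.seed(4)
  for (rep in 1:20) {
    a <- rnorm(1, 0, 100); b <- rnorm(1, 0, 100)
    expect_equal(binding_energy(a + b, a, b)$e_binding, 0, tolerance = 1e-10)
  }
})

test_that("pairwise energies hit the analytic LJ/Coulomb landmarks", {
  # two neutral atoms at r = sigma: LJ term crosses zero
  p <- nonbonded_params(epsilon = c(Q = 0.2), sigma = c(Q = 3.0))
  f <- md_frame(rbind(c(0, 0, 0), c(3.0, 0, 0)), element = "Q", charge = 0)
  expect_equal(pairwise_energy(f, p), 0, tolerance = 1e-12)
  # unit charges at k/100 Angstrom with the LJ zero placed at the same r:
  # pure Coulomb = -100 kcal/mol
  p2 <- nonbonded_params(epsilon = c(Q = 0.2), sigma = c(Q = 3.320637))
  f2 <- md_frame(rbind(c(0, 0, 0), c(3.320637, 0, 0)), element = "Q",
                 charge = c(1, -1))
  expect_equal(pairwise_energy(f2, p2), -100, tolerance = 1e-9)
  # beyond the cutoff nothing contributes
  f3 <- md_frame(rbind(c(0, 0, 0), c(20, 0, 0)), element = "Q", charge = c(1, -1))
  expect_equal(pairwise_energy(f3, p), 0)
  # coincident atoms are a degenerate geometry
  f4 <- md_frame(rbind(c(0, 0, 0), c(0, 0, 0)), element = "Q")
  expect_error(pairwise_energy(f4, p), "degenerate")
  expect_error(pairwise_energy(
    md_frame(rbind(c(0, 0, 0), c(2, 0, 0)), element = "Zz"), p),
    "no LJ parameters")
})

test_that("vectorised pairwise energy equals the double-loop oracle", {
  params <- nonbonded_params()
  set.seed(12)
  for (rep in 1:5) {
    n <- 20
    f <- md_frame(matrix(runif(n * 3, 0, 12), n, 3),
                  element = sample(c("O", "H", "C"), n, replace = TRUE),
                  charge = runif(n, -0.5, 0.5),
                  cell = periodic_cell(15))
    expect_equal(pairwise_energy(f, params),
                 brute_pair_energy(f, params),
                 tolerance = 1e-10)
  }
})

test_that("binding energy from totals equals the direct cross-pair sum on two-cluster toys", {
  for (s in c(7, 19, 33)) {
    sys <- two_cluster_system(n_host = 8, n_guest = 6, separation = 5, seed = s)
    be <- binding_energy(sys$energies$e_total, sys$energies$e_guest,
                         sys$energies$e_host)
    expect_equal(be$e_binding, -sys$energies$cross,
                 tolerance = 1e-8 * max(1, abs(sys$energies$cross)))
    # and the package route reproduces the generator's totals
    expect_equal(pairwise_energy(sys$frame), sys$energies$e_total,
                 tolerance = 1e-8 * max(1, abs(sys$energies$e_total)))
    expect_equal(pairwise_energy(sys$frame, subset = "role=host"),
                 sys$energies$e_host,
                 tolerance = 1e-8 * max(1, abs(sys$energies$e_host)))
  }
})

test_that("trailing-window binding energy averages the last frames", {
  tab <- data.frame(frame = rep(1:10, each = 3),
                    component = rep(c("total", "guest", "host"), 10),
                    value_kcal_mol = c(rbind(-(1:10), rep(-2, 10), rep(-3, 10))))
  be <- binding_energy_from_table(tab, window = 5)
  expect_equal(attr(be, "frames_used"), 6:10)
  expect_equal(be$e_total, mean(-(6:10)))
  expect_equal(be$e_binding, -(mean(-(6:10)) + 2 + 3))
  expect_error(binding_energy_from_table(tab[tab$component != "host", ]),
               "must contain components")
})

test_that("the solubility parameter is the square root of the cohesive energy density", {
  # delta 12.650 corresponds to CED = 12.650^2 = 160.0225 cal/cm^3
  r <- solubility_parameter(cohesive_energy = 160.0225 * 50, molar_volume = 50)
  expect_equal(r$delta, 12.650, tolerance = 1e-9)
  expect_equal(solubility_parameter(0, 100)$delta, 0)
  # heat-of-vaporisation path subtracts the RT expansion work
  r2 <- solubility_parameter(delta_h = 10000, molar_volume = 100,
                             temperature = 298)
  expect_equal(r2$delta, sqrt((10000 - 1.9872 * 298) / 100), tolerance = 1e-12)
  expect_equal(r2$delta, 9.699, tolerance = 1e-3)
  # reconstruction and monotonicity
  set.seed(5)
  for (rep in 1:10) {
    de <- runif(1, 10, 5e4); v <- runif(1, 10, 500)
    r3 <- solubility_parameter(de, v)
    expect_equal(r3$delta^2 * v, de, tolerance = 1e-9)
  }
  d_up <- vapply(c(1, 2, 4, 8) * 1000,
                 function(de) solubility_parameter(de, 100)$delta, numeric(1))
  expect_true(all(diff(d_up) > 0))
  d_down <- vapply(c(50, 100, 200),
                   function(v) solubility_parameter(1000, v)$delta, numeric(1))
  expect_true(all(diff(d_down) < 0))
  expect_error(solubility_parameter(-5, 100), "cohesive energy")
  expect_error(solubility_parameter(100, -1), "> 0")
})

test_that("compatibility categories follow the published thresholds with an explicit gap class", {
  v <- compatibility(12.650, 9.658)
  expect_equal(v$difference, 2.992, tolerance = 1e-9)
  expect_identical(v$category, "may_be_compatible")
  expect_identical(compatibility(12.650, 10.677)$category, "may_be_compatible")
  v3 <- compatibility(12.650, 12.422)
  expect_equal(v3$difference, 0.228, tolerance = 1e-9)
  expect_identical(v3$category, "compatible")
  expect_identical(compatibility(10, 4)$category, "incompatible")
  # boundaries: 1.0 and 3.4 fall into may_be_compatible, 4.9 into the gap
  expect_identical(compatibility(1.0, 0)$category, "may_be_compatible")
  expect_identical(compatibility(3.4, 0)$category, "may_be_compatible")
  expect_identical(compatibility(4.0, 0)$category, "indeterminate")
  expect_identical(compatibility(4.9, 0)$category, "indeterminate")
  expect_identical(compatibility(4.91, 0)$category, "incompatible")
  # symmetry in the two arguments
  expect_identical(compatibility(9.658, 12.650)$category, "may_be_compatible")
  # partition: every difference maps to exactly one category
  set.seed(6)
  for (d in runif(50, 0, 10))
    expect_length(compatibility(d, 0)$category, 1)
})

test_that("hydrogen-bond type enumeration reproduces the A-H catalogue", {
  classes <- read_atom_classes(study_table("atom_classes"))
  cat8 <- enumerate_hbond_types(classes)
  expect_equal(nrow(cat8), 8)
  expect_identical(cat8$type, LETTERS[1:8])
  expect_identical(cat8$acceptor_class, c(paste0("O", 1:6), "O7", "O8"))
  expect_identical(cat8$donor_class, c(rep("H2", 6), rep("H1", 2)))
  # count formula: guest acceptors x host donor-H + host acceptors x guest donor-H
  n_ga <- sum(classes$role == "guest" & classes$kind == "acceptor")
  n_hd <- sum(classes$role == "host" & classes$kind == "donorH")
  n_ha <- sum(classes$role == "host" & classes$kind == "acceptor")
  n_gd <- sum(classes$role == "guest" & classes$kind == "donorH")
  expect_equal(nrow(cat8), n_ga * n_hd + n_ha * n_gd)

  # one-sided: host without donor-H
  one <- atom_class_table(c("O1", "H1", "O7"), c("guest", "guest", "host"),
                          c(-0.5, 0.4, -0.3), c("acceptor", "donorH", "acceptor"))
  cat1 <- enumerate_hbond_types(one)
  expect_equal(nrow(cat1), 1)
  expect_identical(cat1$acceptor_class, "O7")
  expect_identical(cat1$donor_class, "H1")
  # empty table -> empty catalogue
  empty <- atom_class_table(character(), character(), numeric(), character())
  expect_equal(nrow(enumerate_hbond_types(empty)), 0)
  # charge-sign invariants
  expect_error(atom_class_table("O1", "guest", 0.2, "acceptor"),
               "negative charge")
  expect_error(atom_class_table("H1", "guest", -0.2, "donorH"),
               "positive charge")
})

test_that("detected bonds get catalogue types; intramolecular and unknown pairs stay untyped", {
  classes <- read_atom_classes(study_table("atom_classes"))
  cat8 <- enumerate_hbond_types(classes)
  fx <- hbond_fixture(3, box_edge = 40, seed = 15)   # O1 acceptor, H2 donor
  hb <- detect_hbonds(fx$frame)
  expect_identical(assign_hbond_type(hb, fx$frame, cat8), rep("A", 3))

  fx2 <- hbond_fixture(2, box_edge = 40, seed = 16,
                       acceptor_label = "O4", h_label = "H2")
  hb2 <- detect_hbonds(fx2$frame)
  expect_identical(assign_hbond_type(hb2, fx2$frame, cat8), rep("D", 2))

  # intramolecular record -> untyped
  fr <- fx$frame; fr$atoms$molecule_id[] <- 0L
  hb3 <- detect_hbonds(fr)
  expect_identical(unique(assign_hbond_type(hb3, fr, cat8)), "untyped")
  # class absent from the catalogue -> untyped
  fx4 <- hbond_fixture(1, box_edge = 40, seed = 17, acceptor_label = "O9")
  hb4 <- detect_hbonds(fx4$frame)
  expect_identical(assign_hbond_type(hb4, fx4$frame, cat8), "untyped")
  # missing labels -> labeling error
  fr5 <- fx$frame; fr5$atoms$class_label[] <- NA_character_
  expect_error(assign_hbond_type(detect_hbonds(fr5), fr5, cat8),
               "labeling error")
})

test_that("per-type RDFs peak at the constructed contact distances", {
  classes <- read_atom_classes(study_table("atom_classes"))
  cat8 <- enumerate_hbond_types(classes)
  # a single O1...H2 contact at 2.8 A inside a 30 A box
  f <- md_frame(rbind(c(10, 10, 10), c(12.8, 10, 10)),
                element = c("O", "H"), molecule_id = c(1, 0),
                role = c("guest", "host"), class_label = c("O1", "H2"),
                cell = periodic_cell(30))
  per <- rdf_per_type(md_trajectory(list(f)), cat8, dr = 0.1)
  expect_named(per, LETTERS[1:8])
  a_curve <- per[["A"]]
  pk <- a_curve$r[which.max(a_curve$g)]
  expect_true(abs(pk - 2.8) <= 0.05 + 1e-9)
  expect_identical(classify_interaction(pk), "hydrogen_bond")
  # the other types see no O-pair partners at all
  expect_true(all(per[["B"]]$counts == 0))
  # empty catalogue -> empty map
  empty <- atom_class_table(character(), character(), numeric(), character())
  expect_length(rdf_per_type(md_trajectory(list(f)),
                             enumerate_hbond_types(empty)), 0)
})
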