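test_that("MSD is zero for static atoms and quadratic for ballistic motion", {
  frames <- lapply(0:5, function(t)
    md_frame(matrix(1:15, 5, 3), time = t))
  tr <- md_trajectory(frames)
  m <- mean_square_displacement(tr, origins = "multiple")
  expect_true(all(m$msd == 0))
  expect_equal(m$msd[1], 0)
  expect_equal(estimate_diffusion(m), 0)

  # one particle moving (t, 0, 0): msd(t) = t^2 under a single origin
  frames <- lapply(0:8, function(t)
    md_frame(matrix(c(t, 0, 0), 1, 3), time = t))
  m1 <- mean_square_displacement(md_trajectory(frames), origins = "single")
  expect_equal(m1$msd, (0:8)^2)
  expect_true(all(diff(m1$lag_ps) > 0))
})

test_that("Brownian MSD recovers 6D through the Einstein relation", {
  tr <- brownian_trajectory(n_particles = 300, d = 0.1, dt = 1,
                            n_steps = 400, seed = 42)
  m <- mean_square_displacement(tr, origins = "multiple", max_lag = 100)
  d_hat <- estimate_diffusion(m, fit_window = c(10, 100))
  expect_equal(d_hat, 0.1, tolerance = 0.05)
  # exact line: msd = 0.6 t -> D = 0.1
  mline <- structure(data.frame(lag_ps = 0:10, msd = 0.6 * (0:10)),
                     class = c("msd_result", "data.frame"))
  expect_equal(estimate_diffusion(mline), 0.1, tolerance = 1e-12)
  expect_error(estimate_diffusion(m, fit_window = c(500, 600)),
               "fewer than 2")
  expect_error(mean_square_displacement(tr, selection = "role=guest"),
               "empty atom selection")
})

test_that("multiple-origin MSD estimates are less variable than single-origin", {
  d_multi <- d_single <- numeric(12)
  for (s in seq_along(d_multi)) {
    tr <- brownian_trajectory(n_particles = 30, d = 0.1, dt = 1,
                              n_steps = 150, seed = 100 + s)
    m_m <- mean_square_displacement(tr, origins = "multiple", max_lag = 50)
    m_s <- mean_square_displacement(tr, origins = "single", max_lag = 50)
    d_multi[s] <- estimate_diffusion(m_m, c(5, 50))
    d_single[s] <- estimate_diffusion(m_s, c(5, 50))
  }
  expect_lt(var(d_multi), var(d_single))
})

test_that("wrapped-looking coordinates trigger the MSD warning", {
  f0 <- md_frame(matrix(c(0.5, 0, 0), 1, 3), cell = periodic_cell(10), time = 0)
  f1 <- md_frame(matrix(c(9.5, 0, 0), 1, 3), cell = periodic_cell(10), time = 1)
  expect_warning(mean_square_displacement(md_trajectory(list(f0, f1))),
                 "wrapped")
})

test_that("RDF of a fixed pair lands in exactly one bin", {
  f <- md_frame(rbind(c(5, 5, 5), c(8, 5, 5)), cell = periodic_cell(30))
  g <- radial_distribution(f, dr = 0.1)
  nz <- which(g$counts > 0)
  expect_length(nz, 1)
  expect_true(g$r[nz] - 0.05 <= 3.0 && 3.0 < g$r[nz] + 0.05)
  expect_true(all(g$g >= 0))
})

test_that("RDF of a simple-cubic lattice has no counts below the spacing and a first peak there", {
  a <- 3
  pts <- as.matrix(expand.grid(x = (0:4) * a, y = (0:4) * a, z = (0:4) * a))
  f <- md_frame(pts, cell = periodic_cell(5 * a))
  g <- radial_distribution(f, dr = 0.1, r_max = 6)
  expect_true(all(g$counts[g$r < a - 0.05] == 0))
  first_nz <- which(g$counts > 0)[1]
  expect_true(abs(g$r[first_nz] - a) <= 0.05 + 1e-9)
  # brute-force pair enumeration agrees with the histogram total
  dmat <- cross_dist_oracle(pts, 5 * a)
  expect_equal(sum(g$counts), sum(dmat > 0 & dmat < 6) )
})

test_that("ideal-gas RDF plateaus at one and integrates to the expected neighbour count", {
  tr <- ideal_gas_frames(n = 400, box_edge = 20, n_frames = 20, seed = 7)
  g <- radial_distribution(tr, dr = 0.25)
  plateau <- mean(g$g[g$r >= 2 & g$r <= 5])
  expect_gt(plateau, 0.95); expect_lt(plateau, 1.05)
  # sum over bins of g rho 4 pi r^2 dr ~ (4/3) pi r_max^3 rho
  rho <- attr(g, "density")
  n_in <- sum(g$g * rho * 4 * pi * g$r^2 * attr(g, "dr"))
  expect_equal(n_in, 4 / 3 * pi * max(g$r + attr(g, "dr") / 2)^3 * rho,
               tolerance = 0.02)
  expect_error(radial_distribution(tr, dr = 0.1, r_max = 15),
               "half the smallest cell edge")
  f_open <- md_frame(matrix(rnorm(9), 3, 3))
  expect_error(radial_distribution(f_open), "periodic cell")
})

test_that("interaction bands partition the positive axis as published", {
  expect_identical(classify_interaction(2.7), "hydrogen_bond")
  expect_identical(classify_interaction(4.0), "strong_vdw")
  expect_identical(classify_interaction(6.0), "weak_vdw")
  expect_identical(classify_interaction(c(2.5, 3.0, 5.0)),
                   c("hydrogen_bond", "strong_vdw", "weak_vdw"))
  expect_warning(out <- classify_interaction(1.8), "unusually short")
  expect_identical(out, "hydrogen_bond")
  expect_error(classify_interaction(0), "> 0")
  # every positive r maps to exactly one band
  set.seed(3)
  r <- runif(200, 0.01, 12)
  bands <- suppressWarnings(classify_interaction(r))
  expect_true(all(bands %in% c("hydrogen_bond", "strong_vdw", "weak_vdw")))
  expect_length(bands, length(r))
})

test_that("a canonical donor-H-acceptor geometry is detected once, and broken geometries are not", {
  # water-dimer-like O-H...O: H...A = 1.9 A, angle 170 deg
  mk <- function(r_ha, angle_deg) {
    phi <- (180 - angle_deg) * pi / 180
    a_pos <- c(0.96 + r_ha * cos(phi), r_ha * sin(phi), 0)
    md_frame(rbind(c(0, 0, 0), c(0.96, 0, 0), a_pos),
             element = c("O", "H", "O"), molecule_id = c(0, 0, 1))
  }
  hb <- detect_hbonds(mk(1.9, 170))
  expect_equal(nrow(hb), 1)
  expect_identical(hb$kind, "intermolecular")
  expect_equal(hb$distance, 1.9, tolerance = 1e-9)
  expect_equal(hb$angle, 170, tolerance = 1e-6)
  expect_equal(nrow(detect_hbonds(mk(3.5, 170))), 0)   # distance fail
  expect_equal(nrow(detect_hbonds(mk(1.9, 100))), 0)   # angle fail
  # same-molecule copy flags intramolecular
  f_intra <- mk(1.9, 170); f_intra$atoms$molecule_id <- c(0L, 0L, 0L)
  expect_identical(detect_hbonds(f_intra)$kind, "intramolecular")
  # no oxygens at all -> empty, not an error
  f_none <- md_frame(matrix(rnorm(6), 2, 3), element = c("C", "C"))
  expect_equal(nrow(detect_hbonds(f_none)), 0)
})

test_that("the detector equals the exhaustive triple-loop oracle on random fixtures", {
  for (s in 1:12) {
    k <- s %% 5L
    fx <- hbond_fixture(max(k, 1L), decoys = 2 + s %% 4L, box_edge = 40,
                        seed = 2000 + s)
    hb <- detect_hbonds(fx$frame)
    orc <- brute_hbonds(fx$frame)
    expect_equal(nrow(hb), nrow(orc))
    expect_equal(hb[, c("donor", "hydrogen", "acceptor")], orc,
                 ignore_attr = TRUE)
    # and the construction bookkeeping matches too
    expect_equal(hb$donor, fx$bonds$donor)
    expect_equal(hb$acceptor, fx$bonds$acceptor)
  }
})

test_that("hydrogen-bond concentration follows Eq-style arithmetic and scaling", {
  expect_equal(hbond_concentration(0, periodic_cell(10))$c_hbs, 0)
  expect_equal(hbond_concentration(100, periodic_cell(10))$c_hbs, 0.16606,
               tolerance = 1e-4)
  # 143 bonds in the 19.2 A cubic cell
  expect_equal(hbond_concentration(143, periodic_cell(19.2))$c_hbs, 3.355e-2,
               tolerance = 1e-3)
  expect_error(hbond_concentration(1, periodic_cell(periodic = FALSE)),
               "periodic cell")
  expect_error(hbond_concentration(-1, periodic_cell(10)), ">= 0")
  # linear in N, inversely proportional to V
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(1:500, 1); edge <- runif(1, 5, 50); fac <- sample(2:5, 1)
    c1 <- hbond_concentration(n, periodic_cell(edge))$c_hbs
    expect_equal(hbond_concentration(fac * n, periodic_cell(edge))$c_hbs,
                 fac * c1, tolerance = 1e-12)
    expect_equal(hbond_concentration(n, periodic_cell(edge * fac^(1 / 3)))$c_hbs,
                 c1 / fac, tolerance = 1e-9)
  }
})

test_that("per-frame hydrogen-bond counting summarises a trajectory", {
  fx <- hbond_fixture(3, decoys = 2, box_edge = 40, seed = 77)
  f2 <- fx$frame
  tr <- md_trajectory(list(fx$frame, local({ f2$time <- 1; f2 })))
  ct <- count_hbonds(tr)
  expect_equal(ct$per_frame, c(3L, 3L))
  expect_equal(ct$mean, 3)
  expect_equal(ct$n_rounded, 3L)
  conc <- hbond_concentration(ct$n_rounded, tr$cell)
  expect_gt(conc$c_hbs, 0)
})
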