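# Generators with planted ground truth: limiting cases, closed-form
# moments, determinism.

test_that("crooks work generator has the planted Gaussian structure", {
  # zero-dissipation limit: delta distributions at +/- dG_true
  ws0 <- gen_crooks_work(-2.9, 0, 50, 50, T = 298, seed = 1)
  expect_true(all(ws0$forward == -2.9))
  expect_true(all(ws0$reverse == 2.9))

  # closed-form mean: E[W_F] = dG_true + dissipation
  ws <- gen_crooks_work(-2.9, 4, 1e4, 1e4, T = 298, seed = 42)
  s <- sqrt(2 * condx_constants$kB * 298 * 4)
  expect_lt(abs(mean(ws$forward) - 1.1), 3 * s / sqrt(1e4))
  expect_lt(abs(mean(ws$reverse) - (2.9 + 4)), 3 * s / sqrt(1e4))
  expect_lt(abs(sd(ws$forward) - s), 4 * s / sqrt(2e4))

  # same seed, same samples; different seed, different samples
  expect_identical(gen_crooks_work(-2.9, 4, 100, 100, seed = 7),
                   gen_crooks_work(-2.9, 4, 100, 100, seed = 7))
  expect_false(identical(gen_crooks_work(-2.9, 4, 100, 100, seed = 7)$forward,
                         gen_crooks_work(-2.9, 4, 100, 100, seed = 8)$forward))

  expect_error(gen_crooks_work(-2.9, -1, 10, 10), "dissipation")
})

test_that("forward/reverse swap with negated dG leaves the work law invariant", {
  # swapping directions and negating dG_true gives the same joint law:
  # with a common seed the normal draws land on mirrored parameters
  a <- gen_crooks_work(3.0, 2, 500, 500, seed = 5)
  b <- gen_crooks_work(-3.0, 2, 500, 500, seed = 5)
  expect_equal(mean(a$forward) - 5, -(mean(b$reverse) - 5), tolerance = 0.2)
  expect_equal(sd(a$forward), sd(b$reverse), tolerance = 0.1)
})

test_that("crooks crossing point of the generated densities converges to dG_true", {
  errs <- vapply(c(500, 5000, 50000), function(n) {
    ws <- gen_crooks_work(-2.9, 4, n, n, seed = 11)
    abs(crooks_crossing(ws, n_bins = 60) - (-2.9))
  }, numeric(1))
  expect_lt(errs[3], 0.15)
  expect_lt(errs[3], errs[1] + 0.05)  # shrinking with n, up to histogram noise
})

test_that("slab generator reproduces the planted tanh profile and conserves particles", {
  frames <- gen_slab_frames(800, 20, 4, 0.5, box = c(20, 4.5, 4.5),
                            n_frames = 200, seed = 3)
  planted <- attr(frames, "planted")
  # particle count: floor(mean density * V / particle mass), identical per frame
  counts <- vapply(frames, n_particles, integer(1))
  expect_true(all(counts == counts[1]))
  xs <- seq(-10, 10, length.out = 4001)
  mean_rho <- mean((20 + 800) / 2 + (20 - 800) / 2 * tanh((abs(xs) - 4) / 0.5))
  expect_equal(counts[1],
               floor(mean_rho * prod(c(20, 4.5, 4.5)) /
                       (120 * condx_constants$gmol_nm3_to_mgml)))

  # binned histogram matches the analytic profile within counting noise
  prof <- density_profile(frames, bin_width = 0.25, recenter = FALSE)
  expected <- (20 + 800) / 2 + (20 - 800) / 2 * tanh((abs(prof$x) - 4) / 0.5)
  bin_vol <- attr(prof, "bin_volume")
  # per-bin Poisson sd in density units
  n_per_bin <- expected * bin_vol / (120 * condx_constants$gmol_nm3_to_mgml)
  sd_rho <- sqrt(pmax(n_per_bin, 1) / 200) * 120 *
    condx_constants$gmol_nm3_to_mgml / bin_vol
  expect_true(all(abs(prof$rho - expected) < 5 * sd_rho))

  # rejection of infeasible geometry
  expect_error(gen_slab_frames(800, 20, 9, 0.5), "slab does not fit")
  expect_error(gen_slab_frames(20, 800, 4, 0.5), "rho_dense")
})

test_that("uniform-density slab request places particles uniformly", {
  # rho_dilute == rho_dense is rejected by the two-phase precondition, so
  # approach it: a 1 mg/mL contrast is flat to within noise
  frames <- gen_slab_frames(401, 400, 4, 0.5, n_frames = 50, seed = 9)
  prof <- density_profile(frames, bin_width = 0.5, recenter = FALSE)
  expect_lt(diff(range(prof$rho)) / mean(prof$rho), 0.25)
})

test_that("coexistence curve generator follows the scaling laws exactly at zero noise", {
  pts <- gen_coexistence_curve(400, 350, 600, 1.2, c(300, 340, 380),
                               noise_sd = 0, seed = 1)
  expect_equal(pts$rho_H - pts$rho_L, 600 * (400 - pts$T)^0.325)
  expect_equal((pts$rho_H + pts$rho_L) / 2, 350 + 1.2 * (400 - pts$T))
  # limit toward Tc: gap closes, diameter tends to rhoc
  near <- gen_coexistence_curve(400, 350, 600, 1.2, 400 - 1e-9, noise_sd = 0)
  expect_lt(near$rho_H - near$rho_L, 1)
  expect_equal((near$rho_H + near$rho_L) / 2, 350, tolerance = 1e-4)
  expect_identical(gen_coexistence_curve(400, 350, 600, 1.2, c(300, 350), seed = 2),
                   gen_coexistence_curve(400, 350, 600, 1.2, c(300, 350), seed = 2))
  expect_error(gen_coexistence_curve(400, 350, 600, 1.2, c(300, 400)), "< Tc")
})

test_that("dipole series generator plants the target dielectric", {
  ds <- gen_dipole_series(80, V = 405, T = 298, n_frames = 1e5, seed = 13)
  est <- dielectric_constant(ds)
  expect_lt(abs(est$epsilon - 80), 3 * est$se)
  # doubling V at fixed fluctuation halves eps - 1
  ds2 <- dipole_series(ds$M, V = 2 * ds$V, T = 298)
  est2 <- dielectric_constant(ds2, n_blocks = 0)
  expect_equal(est2$epsilon - 1, (est$epsilon - 1) / 2, tolerance = 1e-10)
})

test_that("ring pair generator round-trips planted geometry", {
  fr <- gen_ring_pair(0.4, 0, "stacked")
  g <- ring_geometry(fr, cutoff = 1)
  expect_equal(g$distance, 0.4, tolerance = 1e-9)
  expect_equal(g$theta, 0, tolerance = 1e-9)

  g2 <- ring_geometry(gen_ring_pair(0.55, pi / 2, "t_shaped"), cutoff = 1)
  expect_equal(g2$theta, pi / 2, tolerance = 1e-9)

  for (d in c(0.35, 0.6, 0.85)) for (th in c(0.1, 1.0, 2.0, pi)) {
    g <- ring_geometry(gen_ring_pair(d, th, "arbitrary"), cutoff = 1)
    expect_equal(g$distance, d, tolerance = 1e-6)
    expect_equal(g$theta, th, tolerance = 1e-6)
  }
  expect_error(gen_ring_pair(-1, 0), "distance")
  expect_error(gen_ring_pair(0.4, 4), "theta")
})

test_that("ideal gas generator is uniform and accepts degenerate input", {
  expect_equal(n_particles(gen_ideal_gas(0)), 0L)
  frames <- lapply(1:20, function(s) gen_ideal_gas(300, c(5, 5, 5), seed = s))
  gr <- rdf(frames, r_max = 1.25, bin_width = 0.05)
  sd_bin <- sqrt(pmax(gr$count, 1)) / pmax(gr$count, 1)
  expect_true(all(abs(gr$g[gr$count > 0] - 1) <
                    5 * sd_bin[gr$count > 0] + 0.05))
  # cross-species g(r) of two independent uniform species is also flat
  mixed <- lapply(1:20, function(s)
    gen_ideal_gas(300, c(5, 5, 5), seed = 100 + s, species = c("A", "B")))
  gx <- rdf(mixed, "A", "B", r_max = 1.25, bin_width = 0.05)
  expect_lt(abs(mean(gx$g[gx$r > 0.3]) - 1), 0.05)
})

test_that("energy-table generator plants the rational dielectric model", {
  tab <- gen_energy_tables(
    pair_params = list("Y-Y" = c(-12, -40), "F-F" = c(-8, -20)),
    transfer_params = list(Y = c(4, 80), F = c(-2, 10)),
    eps_grid = c(5, 20, 60))
  # dimer rows satisfy the interaction-energy identity with planted a + b/eps
  yy <- tab$dimers[tab$dimers$pair == "Y-Y", ]
  expect_equal(yy$E_ij - (yy$E_i + yy$E_j), -12 - 40 / yy$epsilon)
  # monomer rows encode the planted transfer model against the water row
  yt <- tab$monomers[tab$monomers$species == "Y" & tab$monomers$solvent != "water", ]
  yw <- tab$monomers[tab$monomers$species == "Y" & tab$monomers$solvent == "water", ]
  expect_equal(yt$dG_solv - yw$dG_solv, 4 + 80 / yt$epsilon)
  # CSV round trip is bit-identical
  d <- tempfile(fileext = ".csv"); m <- tempfile(fileext = ".csv")
  write_energy_tables(tab, d, m)
  back <- read_energy_tables(d, m)
  expect_identical(back$dimers$E_ij, tab$dimers$E_ij)
  expect_identical(back$monomers$dG_solv, tab$monomers$dG_solv)
})
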