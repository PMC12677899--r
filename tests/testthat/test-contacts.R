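# Contact matrices, ring / amide geometry, g(r), SASA.

two_particle_frame <- function(d, box = c(5, 5, 5), species = c("A", "B")) {
  configuration_frame(rbind(c(1, 1, 1), c(1 + d, 1, 1)), box, species,
                      residue_id = 1:2)
}

test_that("contact matrix counts direct contacts and respects the cutoff", {
  fr <- two_particle_frame(0.4)
  cm <- contact_matrix(fr, cutoff = 0.45)
  expect_equal(cm$raw["A", "B"], 1)
  expect_equal(cm$normalized["A", "B"], 1)
  cm2 <- contact_matrix(two_particle_frame(0.5), cutoff = 0.45)
  expect_equal(cm2$raw["A", "B"], 0)
  # minimum image: particles close through the boundary touch
  frw <- configuration_frame(rbind(c(0.1, 1, 1), c(4.9, 1, 1)), c(5, 5, 5),
                             c("A", "B"), residue_id = 1:2)
  expect_equal(contact_matrix(frw, cutoff = 0.45)$raw["A", "B"], 1)
})

test_that("contact matrix equals the brute-force oracle on random frames", {
  for (s in 1:3) {
    fr <- gen_ideal_gas(80, c(3, 3, 3), seed = s, species = c("G", "S", "Y"))
    cm <- contact_matrix(fr, cutoff = 0.45)
    events <- oracle_contact_events(fr, 0.45)
    sp <- sort(unique(fr$species))
    raw_o <- matrix(0, 3, 3, dimnames = list(sp, sp))
    for (ev in events) {
      raw_o[ev[1], ev[2]] <- raw_o[ev[1], ev[2]] + 1
      if (ev[1] != ev[2]) raw_o[ev[2], ev[1]] <- raw_o[ev[2], ev[1]] + 1
    }
    expect_identical(cm$raw, raw_o)
  }
})

test_that("contact matrix is symmetric, bounded and label-equivariant", {
  frames <- lapply(1:4, function(s)
    gen_ideal_gas(60, c(3, 3, 3), seed = s, species = c("G", "S", "Y")))
  cm <- contact_matrix(frames, cutoff = 0.45)
  expect_identical(cm$normalized, t(cm$normalized))
  expect_true(all(cm$normalized >= 0 & cm$normalized <= 1, na.rm = TRUE))
  # relabeling species permutes rows/columns consistently
  swapped <- lapply(frames, function(fr) {
    fr$species <- chartr("GY", "YG", fr$species); fr
  })
  cms <- contact_matrix(swapped, cutoff = 0.45)
  perm <- c("Y", "S", "G")
  expect_equal(cms$raw[perm, perm], unname(cm$raw)[], tolerance = 0,
               ignore_attr = TRUE)
})

test_that("ring geometry is invariant under rigid motion", {
  fr <- gen_ring_pair(0.5, 1.1, "arbitrary", box = c(30, 30, 30))
  g0 <- ring_geometry(fr, cutoff = 1)
  for (s in 1:5) {
    rm <- apply_rigid_motion(fr, seed = s)
    fr2 <- fr
    ctr <- colMeans(fr$coords)
    fr2$coords <- sweep(sweep(fr$coords, 2, ctr) %*% t(rm$R), 2,
                        ctr + rm$shift, "+")
    g <- ring_geometry(fr2, cutoff = 1)
    expect_equal(g$distance, g0$distance, tolerance = 1e-8)
    expect_equal(g$theta, g0$theta, tolerance = 1e-8)
  }
})

test_that("amide-ring geometry recovers parallel and perpendicular planes", {
  ring <- gen_ring_pair(0.5, 0, "stacked", box = c(10, 10, 10))
  ring1 <- ring$coords[1:6, ]
  # amide plane: three atoms in the xy-plane (parallel to the ring) 0.4 nm up
  amide_xyz <- rbind(c(5, 5, 5.4), c(5.12, 5, 5.4), c(5, 5.1, 5.4))
  fr <- configuration_frame(rbind(ring1, amide_xyz), c(10, 10, 10),
                            species = c(rep("RC", 6), rep("AM", 3)),
                            residue_id = c(rep(1L, 6), rep(2L, 3)))
  g <- sp2_pi_geometry(fr, cutoff = 1)
  expect_equal(nrow(g), 1L)
  expect_true(min(g$theta, pi - g$theta) < 1e-9)  # parallel planes
  d_expected <- sqrt(sum((colMeans(amide_xyz) - c(5, 5, 5))^2))
  expect_equal(g$distance, d_expected, tolerance = 1e-9)
  # perpendicular amide plane (xz-plane)
  amide_perp <- rbind(c(5, 5, 5.4), c(5.12, 5, 5.4), c(5, 5, 5.5))
  fr2 <- configuration_frame(rbind(ring1, amide_perp), c(10, 10, 10),
                             species = c(rep("RC", 6), rep("AM", 3)),
                             residue_id = c(rep(1L, 6), rep(2L, 3)))
  g2 <- sp2_pi_geometry(fr2, cutoff = 1)
  expect_equal(g2$theta, pi / 2, tolerance = 1e-9)
  # density map bins cover the observations
  dm <- geometry_density_map(rbind(g, g2))
  expect_equal(sum(dm), 2)
})

test_that("rdf matches the brute-force histogram exactly and normalizes to 1", {
  fr <- gen_ideal_gas(200, c(4, 4, 4), seed = 6, species = c("A", "B"))
  edges <- seq(0, 1.5, by = 0.05)
  gr <- rdf(fr, "A", "B", r_max = 1.5, bin_width = 0.05)
  expect_identical(gr$count, oracle_rdf_counts(fr, edges, "A", "B"))
  gr_all <- rdf(fr, r_max = 1.5, bin_width = 0.05)
  expect_identical(gr_all$count, oracle_rdf_counts(fr, edges, "all", "all"))
  # two particles at fixed distance: a single occupied bin at d
  fr2 <- two_particle_frame(0.62)
  g2 <- rdf(fr2, "A", "B", r_max = 1, bin_width = 0.05)
  expect_equal(sum(g2$count), 1)
  expect_equal(g2$r[g2$count == 1], 0.625)
  expect_error(rdf(fr, r_max = 3), "half the smallest")
})

test_that("rdf is translation-invariant under periodic wrap", {
  fr <- gen_ideal_gas(150, c(4, 4, 4), seed = 7)
  g0 <- rdf(fr, r_max = 1.2)
  fr2 <- fr
  fr2$coords <- sweep(fr$coords, 2, c(1.3, 2.1, 0.7), "+") %% 4
  expect_equal(rdf(fr2, r_max = 1.2)$count, g0$count)
})

test_that("SASA reproduces the isolated-sphere closed form and additivity", {
  lone <- configuration_frame(matrix(c(2, 2, 2), 1), c(6, 6, 6), "X",
                              mass = 12)
  radii <- c(X = 0.15, default = 0.17)
  s1 <- sasa_series(lone, radii = radii, probe = 0.14)
  expect_equal(s1$sasa, 4 * pi * 0.29^2, tolerance = 1e-6)
  # two distant spheres: areas add
  pairfr <- configuration_frame(rbind(c(1, 1, 1), c(4, 4, 4)), c(6, 6, 6),
                                c("X", "X"), residue_id = 1:2, mass = c(12, 12))
  s2 <- sasa_series(pairfr, radii = radii)
  expect_equal(s2$sasa, 2 * 4 * pi * 0.29^2, tolerance = 1e-6)
  # a particle buried under a dense shell exposes ~ nothing
  sp <- condx:::sphere_points(200)
  shell <- sweep(sp * 0.32, 2, c(3, 3, 3), "+")
  buried <- configuration_frame(rbind(c(3, 3, 3), shell), c(6, 6, 6),
                                c("X", rep("S", 200)),
                                residue_id = seq_len(201),
                                mass = rep(12, 201))
  s3 <- sasa_series(buried, radii = c(X = 0.15, S = 0.17, default = 0.17),
                    selection = "X")
  expect_lt(s3$sasa, 0.01 * 4 * pi * 0.29^2)
})

test_that("SASA converges with the number of sphere points", {
  set.seed(20)
  cl <- configuration_frame(matrix(rnorm(30, 3, 0.12), ncol = 3), c(6, 6, 6),
                            rep("X", 10), residue_id = 1:10, mass = rep(12, 10))
  radii <- c(X = 0.15, default = 0.17)
  s960 <- sasa_series(cl, radii = radii, n_sphere_points = 960)$sasa
  s3840 <- sasa_series(cl, radii = radii, n_sphere_points = 3840)$sasa
  expect_lt(abs(s960 - s3840) / s3840, 0.01)
})

test_that("SASA is invariant under rigid motion of the cluster", {
  set.seed(21)
  cl <- configuration_frame(matrix(rnorm(24, 5, 0.1), ncol = 3), c(10, 10, 10),
                            rep("X", 8), residue_id = 1:8, mass = rep(12, 8))
  radii <- c(X = 0.15, default = 0.17)
  # translation: exact (test-point grid moves with each atom)
  s0 <- sasa_series(cl, radii = radii, n_sphere_points = 960)$sasa
  clt <- cl; clt$coords <- sweep(cl$coords, 2, c(0.8, -0.3, 1.1), "+")
  expect_equal(sasa_series(clt, radii = radii, n_sphere_points = 960)$sasa,
               s0, tolerance = 1e-10)
  # rotation: invariant up to the sphere-point discretization
  rm <- apply_rigid_motion(cl, seed = 3)
  cl2 <- cl
  ctr <- colMeans(cl$coords)
  cl2$coords <- sweep(sweep(cl$coords, 2, ctr) %*% t(rm$R), 2, ctr, "+")
  s1 <- sasa_series(cl2, radii = radii, n_sphere_points = 960)$sasa
  expect_equal(s1, s0, tolerance = 0.02)
})
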