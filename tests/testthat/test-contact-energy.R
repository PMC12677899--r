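# Contact-energy decomposition and the dielectric crossover.

planted_table <- function() {
  gen_energy_tables(
    pair_params = list("Y-Y" = c(-12, -40), "F-F" = c(-8, -20),
                       "Y-A" = c(-14, -55)),
    transfer_params = list(Y = c(4, 80), F = c(-2, 10), A = c(1, 30)),
    eps_grid = c(2, 5, 10, 20, 40, 60, 78))
}

test_that("interaction energy and transfer free energy are exact arithmetic", {
  expect_equal(interaction_energy(-100, -45, -45), -10)
  expect_equal(interaction_energy(-90, -45, -45), 0)
  expect_equal(interaction_energy(100, 45, 45), 10)  # antisymmetric under sign flip
  expect_equal(transfer_free_energy(-20, -25), 5)
  expect_equal(transfer_free_energy(-25, -25), 0)
  # path independence: water->s1 + s1->s2 = water->s2
  g <- c(water = -25, s1 = -20, s2 = -12)
  expect_equal(transfer_free_energy(g["s1"], g["water"]) +
                 (g[["s2"]] - g[["s1"]]),
               transfer_free_energy(g["s2"], g["water"]), ignore_attr = TRUE)
})

test_that("contact energy is the exact sum of interaction and transfer terms", {
  tab <- planted_table()
  res <- contact_energy_all(tab)
  # additivity holds bit-exactly in every row
  expect_identical(res$dE_contact,
                   res$dE_int + res$dG_transfer_i + res$dG_transfer_j)
  # and matches the planted closed form a + b/eps + p_i + q_i/eps + p_j + q_j/eps
  yy <- res[res$pair == "Y-Y", ]
  expect_equal(yy$dE_contact, (-12 + 4 + 4) + (-40 + 80 + 80) / yy$epsilon)
  # in water the transfers vanish and dE_contact = dE_int
  one <- contact_energy(tab, "Y-Y", "opt", tab$dimers$solvent[1])
  expect_true(is.finite(one$dE_contact))
  expect_error(contact_energy(tab, "Z-Z", "opt", tab$dimers$solvent[1]),
               "no dimer row")
  expect_error(contact_energy(tab, "Y-Y", "opt", "nonexistent"), "no dimer row")
})

test_that("ddE against the reference pair matches the analytic difference", {
  tab <- planted_table()
  res <- delta_delta_contact(contact_energy_all(tab), "F-F")
  # reference against itself is identically zero
  expect_true(all(res$ddE_contact[res$pair == "F-F"] == 0))
  yy <- res[res$pair == "Y-Y", ]
  # analytic: (aYY + 2pY - aFF - 2pF) + (bYY + 2qY - bFF - 2qF)/eps
  da <- (-12 + 8) + 2 * 4 - 2 * (-2)
  db <- (-40 + 20) + 2 * 80 - 2 * 10
  expect_equal(yy$ddE_contact, da + db / yy$epsilon)
  # antisymmetry under swapping pair and reference
  res2 <- delta_delta_contact(contact_energy_all(tab), "Y-Y")
  ff <- res2[res2$pair == "F-F", ]
  expect_equal(ff$ddE_contact, -(yy$ddE_contact))
  # constant offset propagates verbatim
  shifted <- res
  expect_equal(shifted$ddE_contact[shifted$pair == "Y-A"] -
                 shifted$ddE_contact[shifted$pair == "Y-Y"],
               ((-14 + 1 + 4) - (-12 + 8)) + ((-55 + 30 + 80) - (-40 + 160)) /
                 shifted$epsilon[shifted$pair == "Y-Y"])
})

test_that("crossover finder returns piecewise-linear sign-change roots", {
  expect_equal(find_crossover(c(20, 60), c(3, -1)), 50)
  expect_identical(find_crossover(c(20, 60), c(3, 1)), numeric(0))
  expect_identical(find_crossover(c(20, 60), c(-3, -1)), numeric(0))
  expect_error(find_crossover(5, 1), ">= 2 points")
  # unsorted input is ordered by epsilon first
  expect_equal(find_crossover(c(60, 20), c(-1, 3)), 50)
})

test_that("planted crossover converges to the analytic root as the grid refines", {
  # ddE(eps) = da + db/eps with sign change: root at eps = -db/da
  pair_params <- list("Y-Y" = c(-13, -40), "F-F" = c(-8, -20))
  transfer_params <- list(Y = c(4, 80), F = c(3, 10))
  da <- (-13 - (-8)) + 2 * 4 - 2 * 3    # -3
  db <- (-40 - (-20)) + 2 * 80 - 2 * 10 # 120 -> root at eps = 40
  root <- -db / da
  errs <- vapply(c(8, 30, 200), function(ng) {
    tab <- gen_energy_tables(pair_params, transfer_params,
                             eps_grid = seq(2, 90, length.out = ng))
    res <- delta_delta_contact(contact_energy_all(tab), "F-F")
    cr <- crossover_by_class(res, "Y-Y")$water_like
    abs(cr - root)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[3], 0.05)
})

test_that("eps-independent transfer terms give an eps-independent preference", {
  # q = 0 for all monomers: interaction-energy curvature alone never flips
  # the sign of ddE, mirroring the transfer-driven origin of the crossover
  tab <- gen_energy_tables(
    pair_params = list("Y-Y" = c(-12, -40), "F-F" = c(-8, -20)),
    transfer_params = list(Y = c(4, 0), F = c(3, 0)),
    eps_grid = seq(2, 90, length.out = 40))
  res <- delta_delta_contact(contact_energy_all(tab), "F-F")
  yy <- res[res$pair == "Y-Y", ]
  expect_true(all(sign(yy$ddE_contact) == sign(yy$ddE_contact[1])))
  # flat model (b = q = 0): no crossover reported
  tab0 <- gen_energy_tables(
    pair_params = list("Y-Y" = c(-12, 0), "F-F" = c(-8, 0)),
    transfer_params = list(Y = c(4, 0), F = c(-2, 0)),
    eps_grid = c(5, 40, 78))
  res0 <- delta_delta_contact(contact_energy_all(tab0), "F-F")
  expect_identical(crossover_by_class(res0, "Y-Y")$water_like, numeric(0))
})

test_that("min-max normalization spans [0, 1] and is affine-invariant", {
  expect_equal(minmax_normalize(c(a = 1, b = 3))$lambda, c(0, 1))
  kd <- reference_lookup("hydropathy_kd")
  sc <- setNames(kd$value, kd$key)
  lam <- minmax_normalize(sc)
  expect_equal(range(lam$lambda), c(0, 1))
  lam2 <- minmax_normalize(2.5 * sc + 7)
  expect_equal(lam2$lambda, lam$lambda)
  expect_error(minmax_normalize(c(a = 2, b = 2)), "zero range")
})

test_that("reference lookups return bundled literature values with sources", {
  expect_equal(reference_lookup("mj_self", "F")$value, -7.26)
  expect_equal(reference_lookup("mj_self", "Y")$value, -4.17)
  expect_equal(reference_lookup("solubility", "Y")$value, 0.045)
  expect_equal(reference_lookup("solubility", "F")$value, 2.79)
  expect_match(reference_lookup("mj_self", "F")$source, "Miyazawa")
  expect_error(reference_lookup("mj_self", "Q"), "not found")
  eps <- reference_lookup("water_model_eps")
  expect_true(all(c("TIP3P", "TIP4P-Ew") %in% eps$key))
})

test_that("kcal inputs are converted on read", {
  tab <- planted_table()
  d <- tempfile(fileext = ".csv"); m <- tempfile(fileext = ".csv")
  dim_kcal <- tab$dimers
  dim_kcal[c("E_ij", "E_i", "E_j")] <- dim_kcal[c("E_ij", "E_i", "E_j")] / 4.184
  dim_kcal$unit <- "kcal/mol"
  write.csv(dim_kcal, d, row.names = FALSE)
  write.csv(tab$monomers, m, row.names = FALSE)
  back <- read_energy_tables(d, m)
  expect_equal(back$dimers$E_ij, tab$dimers$E_ij, tolerance = 1e-12)
})
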