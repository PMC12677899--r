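# Synthetic generators with planted ground truth. Every generator is a pure
# function of its arguments plus the seed, so the same call reproduces
# byte-identical output.

#' Generate a Crooks-consistent pair of work distributions
#'
#' Draws forward works from Normal(dG_true + dissipation, sigma^2) and
#' backward (1 -> 0) works from Normal(-dG_true + dissipation, sigma^2) with
#' sigma^2 = 2 kB T dissipation. This Gaussian pair satisfies the Crooks
#' fluctuation theorem with free-energy difference `dG_true`, so estimators
#' run on the output should recover `dG_true`.
#'
#' @param dG_true planted free-energy difference (kJ/mol).
#' @param dissipation mean dissipated work (kJ/mol), >= 0; 0 gives
#'   delta-function work distributions.
#' @param n_forward,n_reverse numbers of switches per direction.
#' @param T temperature (K).
#' @param seed RNG seed.
#' @param medium,mutation optional labels passed to [work_set()].
#' @return A [work_set].
#' @export
gen_crooks_work <- function(dG_true, dissipation, n_forward = 100L,
                            n_reverse = 100L, T = DEFAULT_T, seed = 1L,
                            medium = NA_character_, mutation = NA_character_) {
  if (dissipation < 0) stop("dissipation must be >= 0")
  if (n_forward < 1L || n_reverse < 1L) stop("need >= 1 switch per direction")
  if (T <= 0) stop("T must be > 0")
  set.seed(as.integer(seed))
  s <- sqrt(2 * condx_constants$kB * T * dissipation)
  wf <- stats::rnorm(n_forward, dG_true + dissipation, s)
  wr <- stats::rnorm(n_reverse, -dG_true + dissipation, s)
  work_set(wf, wr, T = T, medium = medium, mutation = mutation)
}

# Planted symmetric two-phase density profile (mg/mL) along the recentred
# slab coordinate x (nm from box center).
tanh_profile <- function(x, rho_L, rho_H, x_DS, t) {
  (rho_L + rho_H) / 2 + (rho_L - rho_H) / 2 * tanh((abs(x) - x_DS) / t)
}

#' Generate slab configurations with a planted density profile
#'
#' Places pseudo-particles (one per residue, default mass 120 g/mol) by
#' rejection sampling along the longest box axis against the symmetric
#' hyperbolic-tangent two-phase profile with the planted parameters, and
#' uniformly in the transverse axes. The slab is centered at the box middle.
#' The per-frame particle count is `floor(mean_density * V / mass)` where
#' `mean_density` is the axis-average of the planted profile, so total mass
#' is conserved across frames.
#'
#' @param rho_dense,rho_dilute planted dense/dilute densities (mg/mL).
#' @param slab_halfwidth planted dividing-surface position x_DS (nm).
#' @param interface_width planted interface width t (nm).
#' @param box length-3 box edges (nm); the profile runs along the longest.
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param mass pseudo-particle mass (g/mol).
#' @param species species label given to all particles.
#' @return List of [configuration_frame], with the planted parameters in
#'   attribute `"planted"`.
#' @export
gen_slab_frames <- function(rho_dense, rho_dilute, slab_halfwidth,
                            interface_width, box = c(20, 4.5, 4.5),
                            n_frames = 10L, seed = 1L, mass = 120,
                            species = "G") {
  if (!(rho_dense > rho_dilute) || rho_dilute < 0)
    stop("need rho_dense > rho_dilute >= 0")
  axis <- which.max(box)
  L <- box[axis]
  if (slab_halfwidth + 3 * interface_width >= L / 2)
    stop("slab does not fit: slab_halfwidth + 3*interface_width must be < half the longest edge")
  V <- prod(box)
  xs <- seq(-L / 2, L / 2, length.out = 2048L)
  prof <- tanh_profile(xs, rho_dilute, rho_dense, slab_halfwidth, interface_width)
  mean_rho <- mean(prof)                       # mg/mL
  # mean_rho [mg/mL] * V [nm^3] / particle mass, via the (g/mol)/nm^3 unit factor
  n_part <- floor(mean_rho * V / (mass * condx_constants$gmol_nm3_to_mgml))
  if (n_part < 1) stop("infeasible densities: fewer than one particle in the box")
  if (mean_rho > 2000) stop("infeasible densities: more mass than the box volume can hold")
  set.seed(as.integer(seed))
  pmax_ <- max(prof)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    ax <- numeric(0)
    while (length(ax) < n_part) {
      m <- 2L * (n_part - length(ax)) + 16L
      cand <- stats::runif(m, -L / 2, L / 2)
      keep <- stats::runif(m) < tanh_profile(cand, rho_dilute, rho_dense,
                                             slab_halfwidth, interface_width) / pmax_
      ax <- c(ax, cand[keep])
    }
    ax <- ax[seq_len(n_part)]
    xyz <- matrix(0, n_part, 3)
    xyz[, axis] <- ax + L / 2                 # store in [0, L)
    for (k in setdiff(1:3, axis)) xyz[, k] <- stats::runif(n_part, 0, box[k])
    frames[[f]] <- configuration_frame(xyz, box, rep(species, n_part),
                                       mass = mass)
  }
  attr(frames, "planted") <- list(rho_H = rho_dense, rho_L = rho_dilute,
                                  x_DS = slab_halfwidth, t = interface_width,
                                  axis = axis, n_particles = n_part)
  frames
}

#' Generate a coexistence curve from planted critical parameters
#'
#' Evaluates the order-parameter scaling law
#' rho_H - rho_L = A (Tc - T)^beta with beta = 0.325 and the law of
#' rectilinear diameters (rho_H + rho_L)/2 = rho_c + c (Tc - T) exactly at
#' the requested temperatures, then perturbs both branch densities with
#' independent Gaussian noise.
#'
#' @param Tc,rhoc planted critical temperature (K) and density (mg/mL).
#' @param A amplitude (mg/mL/K^beta); `c` rectilinear slope (mg/mL/K).
#' @param temperatures temperatures (K), all strictly below `Tc`.
#' @param noise_sd Gaussian noise sd (mg/mL) added to each branch.
#' @param seed RNG seed.
#' @param beta critical exponent (fixed 3D-Ising value).
#' @return Data frame of class `coexistence_points` with columns
#'   `T`, `rho_L`, `rho_H`, `usable`.
#' @export
gen_coexistence_curve <- function(Tc, rhoc, A, c, temperatures,
                                  noise_sd = 0, seed = 1L, beta = 0.325) {
  if (any(temperatures >= Tc)) stop("all temperatures must be < Tc")
  set.seed(as.integer(seed))
  dT <- Tc - temperatures
  gap <- A * dT^beta
  mid <- rhoc + c * dT
  rho_H <- mid + gap / 2 + stats::rnorm(length(dT), 0, noise_sd)
  rho_L <- mid - gap / 2 + stats::rnorm(length(dT), 0, noise_sd)
  structure(data.frame(T = temperatures, rho_L = rho_L, rho_H = rho_H,
                       usable = TRUE),
            class = c("coexistence_points", "data.frame"),
            planted = list(Tc = Tc, rhoc = rhoc, A = A, c = c, beta = beta))
}

#' Generate a stationary box-dipole series with a planted dielectric
#'
#' Dipole components are iid Normal(0, s^2) with s^2 chosen so that the
#' fluctuation formula eps = 1 + var(M) / (3 eps0 kB T V) evaluates to
#' `eps_target` in expectation. Volume is constant.
#'
#' @param eps_target planted dielectric constant, > 1.
#' @param V box volume (nm^3).
#' @param T temperature (K).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return A [dipole_series] with dipoles in e*nm.
#' @export
gen_dipole_series <- function(eps_target, V = 405, T = DEFAULT_T,
                              n_frames = 1e4L, seed = 1L) {
  if (eps_target <= 1) stop("eps_target must be > 1")
  kc <- condx_constants
  # per-component variance in SI (C*m)^2, then back to e*nm
  s2_SI <- (eps_target - 1) * kc$eps0 * kc$kB_SI * T * (V * 1e-27)
  s_enm <- sqrt(s2_SI) / (kc$e * 1e-9)
  set.seed(as.integer(seed))
  M <- matrix(stats::rnorm(3 * n_frames, 0, s_enm), ncol = 3)
  dipole_series(M, V = rep(V, n_frames), T = T, unit = "e.nm")
}

# vertices of an ideal planar hexagon of given C-C bond length, in its own
# frame (normal along z, centroid at origin)
hexagon_ring <- function(bond = 0.139) {
  ang <- (0:5) * pi / 3
  cbind(bond * cos(ang), bond * sin(ang), 0)
}

rotation_about_y <- function(theta) {
  matrix(c(cos(theta), 0, sin(theta),
           0, 1, 0,
           -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
}

#' Generate a pair of aromatic rings with planted geometry
#'
#' Builds two ideal hexagonal 6-carbon rings with centroid separation
#' `distance` and planted angle `theta` between the ring-plane normals.
#' `mode = "stacked"` separates the rings along the first ring's normal
#' (face-to-face at theta = 0), `"t_shaped"` along an in-plane axis, and
#' `"arbitrary"` along a tilted direction.
#'
#' @param distance centroid-centroid separation (nm), > 0.
#' @param theta planted inter-normal angle (radians, in \[0, pi\]).
#' @param mode placement of the second centroid.
#' @param box box edges (nm).
#' @return A [configuration_frame] with 12 carbon particles; ring membership
#'   is encoded in `residue_id` (1 and 2).
#' @export
gen_ring_pair <- function(distance, theta, mode = c("stacked", "t_shaped", "arbitrary"),
                          box = c(10, 10, 10)) {
  mode <- match.arg(mode)
  if (distance <= 0) stop("distance must be > 0")
  if (theta < 0 || theta > pi) stop("theta must lie in [0, pi]")
  ring1 <- hexagon_ring()
  ring2 <- hexagon_ring() %*% t(rotation_about_y(theta))
  sep <- switch(mode,
    stacked  = c(0, 0, 1),
    t_shaped = c(1, 0, 0),
    arbitrary = c(1, 1, 1) / sqrt(3))
  center <- box / 2
  ring1 <- sweep(ring1, 2, center, "+")
  ring2 <- sweep(ring2, 2, center + distance * sep, "+")
  configuration_frame(rbind(ring1, ring2), box,
                      species = rep("RC", 12L),
                      residue_id = rep(1:2, each = 6L),
                      mass = rep(12.011, 12L))
}

#' Generate an ideal-gas configuration
#'
#' Uniform random placement in the box: the null model with g(r) = 1 and no
#' density structure.
#'
#' @param n_particles particle count (0 gives an empty frame).
#' @param box box edges (nm).
#' @param seed RNG seed.
#' @param species recycled per-particle labels.
#' @return A [configuration_frame].
#' @export
gen_ideal_gas <- function(n_particles, box = c(5, 5, 5), seed = 1L,
                          species = "W") {
  set.seed(as.integer(seed))
  xyz <- matrix(stats::runif(3 * n_particles), ncol = 3)
  xyz <- sweep(xyz, 2, box, "*")
  configuration_frame(xyz, box, rep_len(species, n_particles))
}

#' Generate solvent energy tables with a planted dielectric dependence
#'
#' Builds dimer and monomer tables over a dielectric grid from the planted
#' rational model: interaction energy dE_int(eps) = a + b/eps per pair and
#' transfer free energy dG_transfer(eps) = p + q/eps per monomer. Dimer rows
#' carry electronic energies with E_ij - (E_i + E_j) equal to the planted
#' interaction energy; monomer rows carry solvation free energies whose
#' difference to the water row equals the planted transfer term. The
#' crossover dielectric between two pairs is the analytic root of the
#' difference of their contact-energy sums.
#'
#' @param pair_params named list: pair label -> c(a, b) (kJ/mol; b in
#'   kJ/mol, divided by eps).
#' @param transfer_params named list: monomer id -> c(p, q).
#' @param eps_grid dielectric values of the solvent grid.
#' @param pair_monomers named list: pair label -> the two monomer ids it is
#'   built from; defaults to splitting the label on `"-"`.
#' @param eps_water dielectric assigned to the water reference rows.
#' @param solvent_class class label for the grid solvents.
#' @return List of class `solvent_energy_table` with data frames `dimers`
#'   (solvent, class, epsilon, pair, orientation, E_ij, E_i, E_j) and
#'   `monomers` (solvent, class, epsilon, species, dG_solv); planted
#'   parameters kept in attribute `"planted"`.
#' @export
gen_energy_tables <- function(pair_params, transfer_params,
                              eps_grid = c(2, 5, 10, 20, 40, 60, 78),
                              pair_monomers = NULL,
                              eps_water = 78.4,
                              solvent_class = "water_like") {
  if (is.null(pair_monomers))
    pair_monomers <- lapply(strsplit(names(pair_params), "-", fixed = TRUE),
                            function(p) p[1:2])
  if (is.null(names(pair_monomers)))
    names(pair_monomers) <- names(pair_params)
  monomers <- names(transfer_params)
  E_mono <- stats::setNames(-100 - 10 * seq_along(monomers), monomers)
  g_water <- stats::setNames(-20 - 2 * seq_along(monomers), monomers)
  solvent_names <- sprintf("%s_eps%g", solvent_class, eps_grid)

  dim_rows <- do.call(rbind, lapply(names(pair_params), function(pr) {
    ab <- pair_params[[pr]]
    mo <- pair_monomers[[pr]]
    dE <- ab[1] + ab[2] / eps_grid
    data.frame(solvent = solvent_names, class = solvent_class,
               epsilon = eps_grid, pair = pr, orientation = "opt",
               E_ij = unname(dE + E_mono[mo[1]] + E_mono[mo[2]]),
               E_i = unname(E_mono[mo[1]]), E_j = unname(E_mono[mo[2]]))
  }))
  mono_rows <- do.call(rbind, lapply(monomers, function(sp) {
    pq <- transfer_params[[sp]]
    data.frame(solvent = solvent_names, class = solvent_class,
               epsilon = eps_grid, species = sp,
               dG_solv = unname(g_water[sp] + pq[1] + pq[2] / eps_grid))
  }))
  mono_water <- data.frame(solvent = "water", class = "water_like",
                           epsilon = eps_water, species = monomers,
                           dG_solv = unname(g_water))
  structure(list(dimers = dim_rows,
                 monomers = rbind(mono_rows, mono_water)),
            class = "solvent_energy_table",
            planted = list(pair_params = pair_params,
                           transfer_params = transfer_params,
                           pair_monomers = pair_monomers,
                           eps_grid = eps_grid))
}
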