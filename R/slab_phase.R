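#' Mass-density profile along a box axis
#'
#' Histograms particle mass along the chosen axis, averaged over frames, in
#' mg/mL. Before histogramming, each frame is recentred periodically so the
#' centre of mass of all particles sits at the box middle; the profile
#' coordinate `x` is then reported relative to the box centre, matching the
#' symmetric `|x|` form of the two-phase tanh profile. The periodic centre
#' of mass uses the circular-mean construction.
#'
#' @param frames list of [configuration_frame] (or a single frame).
#' @param species species label to profile, or `"all"`.
#' @param bin_width histogram bin width (nm), default 0.1.
#' @param axis `"longest"` (default), `"x"`, `"y"` or `"z"`.
#' @param T temperature tag carried in the result (K).
#' @param recenter recentre each frame on the all-particle periodic centre
#'   of mass (default TRUE).
#' @return A `density_profile`: data frame with columns `x` (bin centres,
#'   nm from box centre) and `rho` (mg/mL), plus attributes `species`, `T`,
#'   `n_frames`, `bin_width`, `bin_volume`.
#' @export
density_profile <- function(frames, species = "all", bin_width = 0.1,
                            axis = c("longest", "x", "y", "z"),
                            T = NA_real_, recenter = TRUE) {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  if (!length(frames)) stop("need >= 1 frame")
  if (bin_width <= 0) stop("bin_width must be > 0")
  axis <- match.arg(axis)
  box <- frames[[1]]$box
  ax <- switch(axis, longest = which.max(box), x = 1L, y = 2L, z = 3L)
  L <- box[ax]
  n_bins <- max(2L, round(L / bin_width))
  edges <- seq(0, L, length.out = n_bins + 1L)
  area <- prod(box[-ax])
  bin_vol <- diff(edges)[1] * area            # nm^3
  counts <- numeric(n_bins)
  for (fr in frames) {
    if (!identical(fr$box, box))
      stop("all frames must share the same box")
    keep <- if (identical(species, "all")) rep(TRUE, length(fr$species))
            else fr$species == species
    if (!any(keep) && !identical(species, "all"))
      stop(sprintf("species '%s' absent; available: %s", species,
                   paste(sort(unique(fr$species)), collapse = ", ")))
    pos <- fr$coords[, ax] %% L
    if (recenter) {
      # periodic (circular-mean) centre of mass of ALL particles
      ang <- pos / L * 2 * pi
      w <- fr$mass / sum(fr$mass)
      com <- (atan2(sum(w * sin(ang)), sum(w * cos(ang))) / (2 * pi)) %% 1 * L
      pos <- (pos - com + L / 2) %% L
    }
    idx <- pmin(n_bins, pmax(1L, ceiling(pos / L * n_bins)))
    idx[pos == 0] <- 1L
    m <- fr$mass[keep]
    counts <- counts + as.numeric(
      tapply(m, factor(idx[keep], levels = seq_len(n_bins)), sum, default = 0))
  }
  rho <- counts / length(frames) / bin_vol * condx_constants$gmol_nm3_to_mgml
  x <- (edges[-1] + edges[-length(edges)]) / 2 - L / 2
  structure(data.frame(x = x, rho = rho),
            class = c("density_profile", "data.frame"),
            species = species, T = T, n_frames = length(frames),
            bin_width = diff(edges)[1], bin_volume = bin_vol)
}

#' Fit the two-phase hyperbolic-tangent profile
#'
#' Nonlinear least squares of
#' rho(x) = (rho_L + rho_H)/2 + (rho_L - rho_H)/2 * tanh((|x| - x_DS)/t)
#' to a density profile, jointly over both half-boxes via `|x|`. Initial
#' guesses: rho_H and rho_L from the 95th/5th percentile bins, x_DS at the
#' half-maximum crossing, t = 2 bins. Non-convergence or a dense/dilute gap
#' indistinguishable from zero is reported through `converged = FALSE`, not
#' an error.
#'
#' @param profile a [density_profile] with >= 8 bins.
#' @return A `tanh_fit`: list with `rho_L`, `rho_H`, `x_DS`, `t`, standard
#'   errors `se` (named), and `converged`.
#' @export
fit_tanh <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  if (nrow(profile) < 8L) stop("need >= 8 bins to fit")
  x <- profile$x; rho <- profile$rho
  q <- stats::quantile(rho, c(0.05, 0.95), names = FALSE)
  rho_L0 <- q[1]; rho_H0 <- q[2]
  half <- (rho_L0 + rho_H0) / 2
  ax <- abs(x)
  ord <- order(ax)
  cross <- ax[ord][which(rho[ord] < half)[1]]
  if (is.na(cross)) cross <- stats::median(ax)
  t0 <- 2 * attr(profile, "bin_width")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rho ~ (rho_L + rho_H) / 2 + (rho_L - rho_H) / 2 * tanh((abs(x) - x_DS) / t),
      data = data.frame(x = x, rho = rho),
      start = list(rho_L = rho_L0, rho_H = rho_H0, x_DS = cross, t = t0),
      lower = c(0, 0, 0, 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(rho_L = NA_real_, rho_H = NA_real_, x_DS = NA_real_,
                          t = NA_real_, se = c(rho_L = NA, rho_H = NA,
                                               x_DS = NA, t = NA),
                          converged = FALSE),
                     class = "tanh_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, 4), names(cf)))
  gap <- cf[["rho_H"]] - cf[["rho_L"]]
  gap_se <- if (all(is.finite(se[c("rho_H", "rho_L")])))
    sqrt(sum(se[c("rho_H", "rho_L")]^2)) else NA_real_
  # a gap indistinguishable from zero (or with no usable covariance) means a
  # single phase, not a failure
  converged <- fit$convInfo$isConv && is.finite(gap) && gap > 0 &&
    !is.na(gap_se) && gap > 2 * gap_se
  structure(list(rho_L = cf[["rho_L"]], rho_H = cf[["rho_H"]],
                 x_DS = cf[["x_DS"]], t = cf[["t"]],
                 se = se, converged = converged),
            class = "tanh_fit")
}

#' @export
print.tanh_fit <- function(x, ...) {
  cat(sprintf("tanh fit: rho_L = %.2f, rho_H = %.2f mg/mL, x_DS = %.3f nm, t = %.3f nm (%s)\n",
              x$rho_L, x$rho_H, x$x_DS, x$t,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Coexistence densities across a temperature scan
#'
#' Fits the tanh profile at each temperature and flags points as usable when
#' the fit converged, the dense/dilute gap exceeds 100 mg/mL and both
#' branch parameters have relative errors below 50% — the machine-checkable
#' version of requiring clearly distinguishable dense and dilute phases.
#'
#' @param profiles list of [density_profile], each carrying its temperature
#'   in attribute `T` (or supply `temperatures`).
#' @param temperatures optional numeric overriding the per-profile tags.
#' @param min_gap usable threshold on rho_H - rho_L (mg/mL).
#' @param max_rel_err usable threshold on relative parameter errors.
#' @return Data frame of class `coexistence_points`: columns `T`, `rho_L`,
#'   `rho_H`, `usable`; per-point fits in attribute `fits`.
#' @export
coexistence_scan <- function(profiles, temperatures = NULL,
                             min_gap = 100, max_rel_err = 0.5) {
  if (is.null(temperatures))
    temperatures <- vapply(profiles, function(p) as.numeric(attr(p, "T")),
                           numeric(1))
  if (anyNA(temperatures)) stop("every profile needs a temperature")
  fits <- lapply(profiles, fit_tanh)
  usable <- vapply(fits, function(f) {
    if (!isTRUE(f$converged)) return(FALSE)
    gap <- f$rho_H - f$rho_L
    if (!is.finite(gap) || gap <= min_gap) return(FALSE)
    rel <- abs(f$se[c("rho_L", "rho_H")] / c(f$rho_L, f$rho_H))
    rel[!is.finite(rel)] <- 0   # zero-valued branch with zero error
    all(rel < max_rel_err, na.rm = TRUE)
  }, logical(1))
  structure(data.frame(T = temperatures,
                       rho_L = vapply(fits, `[[`, numeric(1), "rho_L"),
                       rho_H = vapply(fits, `[[`, numeric(1), "rho_H"),
                       usable = usable),
            class = c("coexistence_points", "data.frame"),
            fits = fits)
}

#' Critical point from coexistence densities
#'
#' Two-stage fit. Stage 1: nonlinear least squares of the order parameter
#' rho_H - rho_L = A (Tc - T)^beta with the 3D-Ising exponent beta = 0.325
#' held fixed, yielding A and the critical temperature Tc. Stage 2: with Tc
#' fixed, linear regression of the coexistence diameter (rho_H + rho_L)/2 on
#' (Tc - T) — the law of rectilinear diameters — yielding the critical
#' density rho_c and slope c.
#'
#' @param points a `coexistence_points` data frame; only rows with
#'   `usable = TRUE` enter the fit (>= 3 required).
#' @param beta critical exponent, fixed (never fitted).
#' @return A `critical_fit`: list with `Tc`, `rhoc`, `A`, `c`,
#'   `beta_exponent`, and standard errors `se` (named).
#' @export
fit_critical <- function(points, beta = 0.325) {
  pts <- points[points$usable %in% TRUE, , drop = FALSE]
  if (nrow(pts) < 3L) stop("need >= 3 usable coexistence points")
  gap <- pts$rho_H - pts$rho_L
  Tc0 <- max(pts$T) + diff(range(pts$T)) * 0.2 + 1
  A0 <- gap[which.min(pts$T)] / (Tc0 - min(pts$T))^beta
  st1 <- minpack.lm::nlsLM(gap ~ A * (Tc - T)^beta,
                           data = data.frame(T = pts$T, gap = gap),
                           start = list(A = A0, Tc = Tc0),
                           lower = c(0, max(pts$T) + 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf1 <- stats::coef(st1)
  se1 <- sqrt(diag(stats::vcov(st1)))
  Tc <- cf1[["Tc"]]
  dia <- (pts$rho_H + pts$rho_L) / 2
  dT <- Tc - pts$T
  st2 <- stats::lm(dia ~ dT)
  cf2 <- stats::coef(st2)
  # suppress the "essentially perfect fit" warning on noiseless input
  se2 <- suppressWarnings(sqrt(diag(stats::vcov(st2))))
  structure(list(Tc = Tc, rhoc = unname(cf2[1]), A = cf1[["A"]],
                 c = unname(cf2[2]), beta_exponent = beta,
                 se = c(Tc = unname(se1["Tc"]), A = unname(se1["A"]),
                        rhoc = unname(se2[1]), c = unname(se2[2])),
                 n_points = nrow(pts)),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat(sprintf("critical point: Tc = %.2f +/- %.2f K, rhoc = %.1f +/- %.1f mg/mL (beta = %.3f fixed)\n",
              x$Tc, x$se["Tc"], x$rhoc, x$se["rhoc"], x$beta_exponent))
  invisible(x)
}

#' Dilute-phase (saturation) density of a species
#'
#' Averages the species profile over the dilute region |x| > x_DS + 3 t,
#' with the dividing surface taken from a fit to the all-species profile.
#' The saturation density is the amount of material left in the dilute
#' phase at coexistence; lower values mean stronger phase separation.
#'
#' @param profile a [density_profile] for the species of interest.
#' @param fit a [fit_tanh] result defining the dilute region.
#' @return Saturation density (mg/mL).
#' @export
saturation_density <- function(profile, fit) {
  stopifnot(inherits(profile, "density_profile"), inherits(fit, "tanh_fit"))
  cutoff <- fit$x_DS + 3 * fit$t
  sel <- abs(profile$x) > cutoff
  if (!any(sel))
    stop("dilute region empty: x_DS + 3 t reaches beyond the box")
  mean(profile$rho[sel])
}

#' Write a density profile to CSV (columns x, rho)
#' @param profile a [density_profile]; @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("x", "rho")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read/write coexistence points as CSV (columns T, rho_L, rho_H, usable)
#' @param points coexistence data frame; @param path file path.
#' @export
write_coexistence_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coexistence_csv
#' @export
read_coexistence_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("coexistence_points", "data.frame"))
}
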