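#' Bidirectional non-equilibrium work samples
#'
#' Holds work values from forward (coupling parameter 0 -> 1) and backward
#' (1 -> 0) alchemical switching trajectories at a common temperature.
#' Backward works are stored in the 1 -> 0 sign convention, i.e. the work
#' done on the system during the backward switch.
#'
#' @param forward numeric, forward work values (kJ/mol).
#' @param reverse numeric, backward work values (kJ/mol), 1 -> 0 convention.
#' @param T temperature (K).
#' @param medium optional label for the medium (e.g. `"GSY"`, `"water"`).
#' @param mutation optional label for the transformation (e.g. `"F->Y"`).
#' @return Object of class `work_set`.
#' @export
work_set <- function(forward, reverse, T = DEFAULT_T,
                     medium = NA_character_, mutation = NA_character_) {
  forward <- as.numeric(forward); reverse <- as.numeric(reverse)
  if (any(!is.finite(forward)) || any(!is.finite(reverse)))
    stop("all work values must be finite")
  if (!is.numeric(T) || length(T) != 1L || T <= 0) stop("T must be > 0")
  structure(list(forward = forward, reverse = reverse, T = T,
                 medium = medium, mutation = mutation),
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("work_set: %d forward / %d backward switches at %g K\n",
              length(x$forward), length(x$reverse), x$T))
  if (!is.na(x$medium)) cat("  medium:", x$medium, "\n")
  invisible(x)
}

#' Integrate dH/dlambda over a switching trajectory
#'
#' The work performed during one alchemical switch is the integral of the
#' Hamiltonian derivative over the coupling parameter,
#' W = integral of dH/dlambda over lambda. Trapezoidal quadrature; the sign
#' follows the direction of the lambda series, so a 1 -> 0 series yields the
#' negated integral of its 0 -> 1 counterpart.
#'
#' @param dhdl two-column numeric table: lambda (dimensionless, strictly
#'   monotonic within \[0, 1\]) and dH/dlambda (kJ/mol).
#' @return Work in kJ/mol.
#' @export
integrate_work <- function(dhdl) {
  dhdl <- as.matrix(dhdl)
  if (ncol(dhdl) < 2L || nrow(dhdl) < 2L)
    stop("dhdl needs >= 2 rows of (lambda, dH/dlambda)")
  lam <- dhdl[, 1]; y <- dhdl[, 2]
  d <- diff(lam)
  if (any(d == 0) || (any(d > 0) && any(d < 0))) {
    bad <- which(if (d[1] >= 0) d <= 0 else d >= 0)[1]
    stop(sprintf("lambda values must be strictly monotonic; first violation at index %d",
                 bad + 1L))
  }
  if (min(lam) < -1e-12 || max(lam) > 1 + 1e-12)
    stop("lambda values must lie within [0, 1]")
  sum(d * (y[-1] + y[-length(y)]) / 2)
}

# Implicit BAR equation: difference of the two Fermi-function sums as a
# function of the trial free energy (monotone decreasing in dG).
bar_imbalance <- function(dG, wf, wr, kT) {
  M <- log(length(wf) / length(wr))
  sum(stats::plogis(-(M + (wf - dG) / kT))) -
    sum(stats::plogis(-(-M + (wr + dG) / kT)))
}

#' Bennett acceptance ratio estimate from bidirectional work
#'
#' Solves the implicit maximum-likelihood equation equating the forward and
#' backward Fermi-function sums for the free-energy difference dG between the
#' end states. The equation is monotone in dG, so a guaranteed-convergence
#' bisection on a bracket spanning both work distributions is used.
#'
#' @param work a [work_set].
#' @param tol convergence tolerance on dG (kJ/mol), default 1e-8.
#' @param max_iter maximum bisection iterations.
#' @param n_bootstrap bootstrap resamples for the standard error; 0 skips
#'   the bootstrap (se = NA).
#' @param seed RNG seed for the bootstrap.
#' @return A `free_energy_estimate`: list with `dG`, `se`, `n_forward`,
#'   `n_reverse`, `method = "bar"`, `n_bootstrap`.
#' @export
bar_estimate <- function(work, tol = 1e-8, max_iter = 200L,
                         n_bootstrap = 0L, seed = 1L) {
  stopifnot(inherits(work, "work_set"))
  wf <- work$forward; wr <- work$reverse
  if (!length(wf) || !length(wr))
    stop("BAR needs at least one work value in each direction")
  kT <- condx_constants$kB * work$T
  # the implicit equation always has a root, but with non-overlapping work
  # distributions the estimate is meaningless: demand support overlap
  gap <- max(min(wf) - max(-wr), min(-wr) - max(wf))
  if (gap > 10 * kT)
    stop(sprintf(paste0(
      "forward and mirrored backward work distributions do not overlap ",
      "(gap %.3g kJ/mol): forward range [%.4g, %.4g], backward range ",
      "[%.4g, %.4g] kJ/mol"), gap, min(wf), max(wf), min(wr), max(wr)))
  spread <- 10 * max(stats::sd(wf), stats::sd(wr), kT, na.rm = TRUE)
  lo <- min(-wr) - spread
  hi <- max(wf) + spread
  flo <- bar_imbalance(lo, wf, wr, kT)
  fhi <- bar_imbalance(hi, wf, wr, kT)
  if (sign(flo) == sign(fhi) && flo != 0 && fhi != 0)
    stop(sprintf(paste0(
      "BAR bracket has no sign change: forward work range [%.4g, %.4g], ",
      "backward range [%.4g, %.4g] kJ/mol; the work distributions do not overlap"),
      min(wf), max(wf), min(wr), max(wr)))
  # bar_imbalance is monotone increasing in dG: f(lo) <= 0 <= f(hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- bar_imbalance(mid, wf, wr, kT)
    if (fm < 0) lo <- mid else hi <- mid
    if ((hi - lo) < tol) break
  }
  dG <- (lo + hi) / 2
  se <- NA_real_
  if (n_bootstrap > 0L)
    se <- bootstrap_error(work, n_bootstrap = n_bootstrap, seed = seed,
                          tol = tol, max_iter = max_iter)
  structure(list(dG = dG, se = se,
                 n_forward = length(wf), n_reverse = length(wr),
                 method = "bar", n_bootstrap = as.integer(n_bootstrap),
                 T = work$T, medium = work$medium, mutation = work$mutation),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("BAR dG = %.4f %s kJ/mol  (n = %d/%d%s)\n", x$dG,
              if (is.na(x$se)) "" else sprintf("+/- %.4f", x$se),
              x$n_forward, x$n_reverse,
              if (is.na(x$medium)) "" else paste0(", ", x$medium)))
  invisible(x)
}

#' Bootstrap standard error of the BAR estimate
#'
#' Resamples forward and backward work values independently with
#' replacement, re-estimates dG on each resample and returns the standard
#' deviation across resamples.
#'
#' @inheritParams bar_estimate
#' @param n_bootstrap number of resamples (default 1000).
#' @return Standard error (kJ/mol).
#' @export
bootstrap_error <- function(work, n_bootstrap = 1000L, seed = 1L,
                            tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(work, "work_set"))
  set.seed(as.integer(seed))
  nf <- length(work$forward); nr <- length(work$reverse)
  reps <- vapply(seq_len(n_bootstrap), function(b) {
    ws <- work_set(work$forward[sample.int(nf, nf, replace = TRUE)],
                   work$reverse[sample.int(nr, nr, replace = TRUE)],
                   T = work$T)
    bar_estimate(ws, tol = tol, max_iter = max_iter)$dG
  }, numeric(1))
  stats::sd(reps)
}

#' Transfer free-energy difference from a thermodynamic cycle
#'
#' Closes the thermodynamic cycle relating the alchemical mutation in two
#' media: ddG_transfer = dG(medium) - dG(water). A negative value means
#' transferring the mutated (e.g. Tyr) species into the medium is more
#' favourable than transferring the original (e.g. Phe) species. Errors
#' combine in quadrature.
#'
#' @param dG_medium,dG_water `free_energy_estimate` objects for the mutation
#'   in the medium and in water.
#' @return A `transfer_cycle`: list with `ddG_transfer`, `se` and both
#'   branch estimates.
#' @export
ddg_transfer <- function(dG_medium, dG_water) {
  stopifnot(inherits(dG_medium, "free_energy_estimate"),
            inherits(dG_water, "free_energy_estimate"))
  structure(list(
    dG_medium = dG_medium, dG_water = dG_water,
    ddG_transfer = dG_medium$dG - dG_water$dG,
    se = sqrt(sum(c(dG_medium$se, dG_water$se)^2))),
    class = "transfer_cycle")
}

#' @export
print.transfer_cycle <- function(x, ...) {
  cat(sprintf("ddG_transfer = %.4f %s kJ/mol\n", x$ddG_transfer,
              if (is.na(x$se)) "" else sprintf("+/- %.4f", x$se)))
  invisible(x)
}

#' Average transfer cycles over replicate simulations
#'
#' Per-replicate ddG values are averaged; the error is the standard error of
#' the mean across replicates, the convention used when independent replicate
#' trajectories are available instead of a single bootstrap.
#'
#' @param cycles list of [ddg_transfer] results.
#' @return A `transfer_cycle` with the replicate mean and SEM.
#' @export
replicate_mean_cycle <- function(cycles) {
  vals <- vapply(cycles, function(cc) cc$ddG_transfer, numeric(1))
  structure(list(dG_medium = NULL, dG_water = NULL,
                 ddG_transfer = mean(vals),
                 se = stats::sd(vals) / sqrt(length(vals)),
                 n_replicates = length(vals)),
            class = "transfer_cycle")
}

#' Crossing point of forward and mirrored backward work densities
#'
#' Overlap diagnostic for BAR input: by the Crooks fluctuation theorem the
#' forward work density and the mirrored (negated) backward work density
#' cross exactly at the free-energy difference. Both are histogrammed on a
#' common grid and the crossing located by piecewise-linear interpolation.
#'
#' @param work a [work_set].
#' @param n_bins histogram bins over the joint work range.
#' @return Crossing location (kJ/mol), or `NA` with a warning when the
#'   supports do not overlap.
#' @export
crooks_crossing <- function(work, n_bins = 40L) {
  stopifnot(inherits(work, "work_set"))
  wf <- work$forward; wm <- -work$reverse   # mirror backward works
  if (min(wf) > max(wm) || min(wm) > max(wf)) {
    warning("forward and mirrored backward work distributions do not overlap; crossing undefined")
    return(NA_real_)
  }
  rng <- range(c(wf, wm))
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  hf <- graphics::hist(wf, breaks = br, plot = FALSE)$density
  hm <- graphics::hist(wm, breaks = br, plot = FALSE)$density
  mid <- (br[-1] + br[-length(br)]) / 2
  dd <- hf - hm
  # restrict to the overlap region where both densities are populated
  occ <- which(hf > 0 | hm > 0)
  sgn <- sign(dd)
  cross <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  cross <- cross[cross %in% occ]
  if (!length(cross)) {
    warning("no density crossing found within the histogram range")
    return(NA_real_)
  }
  # crossing nearest the midpoint of the two distribution means
  guess <- (mean(wf) + mean(wm)) / 2
  i <- cross[which.min(abs(mid[cross] - guess))]
  x0 <- mid[i]; x1 <- mid[i + 1L]
  y0 <- dd[i]; y1 <- dd[i + 1L]
  x0 - y0 * (x1 - x0) / (y1 - y0)
}

#' Read work values from plain text (one value per line) or XVG
#' @param path file path; `#`/`@` comment lines ignored.
#' @return numeric vector of works (kJ/mol); for multi-column input the last
#'   column is used.
#' @export
read_work_values <- function(path) {
  m <- read_xvg(path)
  if (!length(m)) return(numeric(0))
  m[, ncol(m)]
}
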