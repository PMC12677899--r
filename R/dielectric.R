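#' Box-dipole time series
#'
#' Per-frame total dipole moment of the simulation box and box volume,
#' from which the static dielectric constant follows via the fluctuation
#' formula.
#'
#' @param M n x 3 numeric matrix of dipole vectors.
#' @param V per-frame volumes (nm^3); a scalar is recycled.
#' @param T temperature (K).
#' @param unit dipole unit, `"e.nm"` or `"Debye"`.
#' @return Object of class `dipole_series`.
#' @export
dipole_series <- function(M, V, T = DEFAULT_T, unit = c("e.nm", "Debye")) {
  unit <- match.arg(unit)
  M <- as.matrix(M)
  if (ncol(M) != 3L) stop("M must have 3 columns")
  V <- as.numeric(V)
  if (length(V) == 1L) V <- rep(V, nrow(M))
  if (length(V) != nrow(M)) stop("M and V series lengths differ")
  if (any(V <= 0)) stop("volumes must be > 0")
  if (T <= 0) stop("T must be > 0")
  structure(list(M = M, V = V, T = T, unit = unit), class = "dipole_series")
}

#' @export
print.dipole_series <- function(x, ...) {
  cat(sprintf("dipole_series: %d frames, <V> = %.2f nm^3, unit %s\n",
              nrow(x$M), mean(x$V), x$unit))
  invisible(x)
}

# dipole matrix in SI units (C*m)
dipole_SI <- function(series) {
  f <- switch(series$unit,
              "e.nm" = condx_constants$e * 1e-9,
              "Debye" = condx_constants$debye,
              stop("unknown dipole unit_system: ", series$unit))
  series$M * f
}

eps_from_moments <- function(M_SI, V_nm3, T) {
  mean_M2 <- mean(rowSums(M_SI^2))
  mean_M <- colMeans(M_SI)
  fluct <- mean_M2 - sum(mean_M^2)
  1 + fluct / (3 * condx_constants$eps0 * condx_constants$kB_SI * T *
                 mean(V_nm3) * 1e-27)
}

#' Static dielectric constant from box-dipole fluctuations
#'
#' Evaluates eps = 1 + (<M^2> - <M>^2) / (3 eps0 kB T <V>), with the dipole
#' converted to SI internally. <M^2> is the mean squared dipole norm and
#' <M> the mean dipole vector. The standard error comes from blocking
#' (see [blocking_error()]).
#'
#' @param series a [dipole_series] with >= 2 frames.
#' @param n_blocks blocks used for the error estimate; `0` skips it.
#' @return A `dielectric_estimate`: list with `epsilon`, `se`, `n_blocks`,
#'   `n_frames`.
#' @export
dielectric_constant <- function(series, n_blocks = 5L) {
  stopifnot(inherits(series, "dipole_series"))
  if (nrow(series$M) < 2L) stop("need >= 2 frames")
  eps <- eps_from_moments(dipole_SI(series), series$V, series$T)
  se <- if (n_blocks > 0L) blocking_error(series, n_blocks) else NA_real_
  structure(list(epsilon = eps, se = se, n_blocks = as.integer(n_blocks),
                 n_frames = nrow(series$M)),
            class = "dielectric_estimate")
}

#' @export
print.dielectric_estimate <- function(x, ...) {
  cat(sprintf("epsilon = %.3f %s (%d frames, %d blocks)\n", x$epsilon,
              if (is.na(x$se)) "" else sprintf("+/- %.3f", x$se),
              x$n_frames, x$n_blocks))
  invisible(x)
}

#' Blocking standard error of the dielectric constant
#'
#' Splits the series into `n_blocks` contiguous blocks, evaluates the
#' fluctuation formula per block and returns sd(blocks)/sqrt(n_blocks).
#' Blocking absorbs the time correlation a naive per-frame error ignores.
#'
#' @param series a [dipole_series].
#' @param n_blocks number of contiguous blocks; each must hold >= 2 frames.
#' @return Standard error (dimensionless).
#' @export
blocking_error <- function(series, n_blocks = 5L) {
  stopifnot(inherits(series, "dipole_series"))
  n <- nrow(series$M)
  if (n_blocks < 2L) stop("need >= 2 blocks")
  if (n %/% n_blocks < 2L)
    stop("blocks of fewer than 2 frames: reduce n_blocks")
  M_SI <- dipole_SI(series)
  idx <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  vals <- vapply(idx, function(ii)
    eps_from_moments(M_SI[ii, , drop = FALSE], series$V[ii], series$T),
    numeric(1))
  stats::sd(vals) / sqrt(length(vals))
}

#' Box dipole from charged configuration frames
#'
#' Computes M = sum(q_i r_i) per frame. Charges must sum to ~0 for the
#' dipole to be origin-independent; a warning is emitted otherwise.
#' Coordinates are used as stored (molecules are assumed whole).
#'
#' @param frames list of [configuration_frame] carrying charges.
#' @param T temperature (K).
#' @return A [dipole_series] in e*nm with per-frame box volumes.
#' @export
box_dipole <- function(frames, T = DEFAULT_T) {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  M <- t(vapply(frames, function(fr) {
    if (is.null(fr$charge)) stop("frames must carry charges")
    if (abs(sum(fr$charge)) > 1e-6)
      warning("net charge != 0: box dipole depends on the origin")
    colSums(fr$coords * fr$charge)
  }, numeric(3)))
  V <- vapply(frames, function(fr) prod(fr$box), numeric(1))
  dipole_series(M, V, T = T, unit = "e.nm")
}

#' Read a dipole series from an XVG-style file
#'
#' Expects columns (t, Mx, My, Mz) and optionally a fifth volume column;
#' with four columns a constant volume must be supplied.
#'
#' @param path file path.
#' @param volume constant box volume (nm^3) when the file has no volume column.
#' @param T temperature (K).
#' @param unit dipole unit in the file.
#' @return A [dipole_series].
#' @export
read_dipole_xvg <- function(path, volume = NULL, T = DEFAULT_T,
                            unit = c("e.nm", "Debye")) {
  m <- read_xvg(path)
  if (ncol(m) < 4L) stop("need columns (t, Mx, My, Mz[, V])")
  V <- if (ncol(m) >= 5L) m[, 5] else {
    if (is.null(volume)) stop("no volume column: supply `volume`")
    volume
  }
  dipole_series(m[, 2:4], V, T = T, unit = match.arg(unit))
}
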