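# Contact statistics and geometry of aromatic / amide interactions.

# split particle indices into residue groups, optionally restricted to a
# species label
residue_groups <- function(frame, species = NULL) {
  idx <- seq_len(nrow(frame$coords))
  if (!is.null(species)) idx <- idx[frame$species %in% species]
  if (!length(idx)) return(list())
  unname(split(idx, frame$residue_id[idx]))
}

#' Residue-residue contact matrix by species pair
#'
#' Two residues are in contact in a frame when any inter-residue particle
#' distance is at or below `cutoff` under minimum image. Contact events are
#' accumulated per species pair, averaged per frame, and normalized by the
#' number of available molecule pairs n_i * n_j (n_i (n_i - 1) / 2 within a
#' species), then scaled by the matrix maximum to \[0, 1\]. Both the raw and
#' the normalized matrices are returned.
#'
#' @param frames list of [configuration_frame].
#' @param cutoff contact cutoff (nm), default 0.45.
#' @return A `contact_matrix`: list with symmetric matrices `normalized`,
#'   `per_pair` (per-frame contacts divided by pair counts), `raw`
#'   (mean contacts per frame), plus `cutoff` and `n_frames`.
#' @export
contact_matrix <- function(frames, cutoff = 0.45) {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  sp_all <- sort(unique(unlist(lapply(frames, `[[`, "species"))))
  ns <- length(sp_all)
  raw <- matrix(0, ns, ns, dimnames = list(sp_all, sp_all))
  for (fr in frames) {
    groups <- residue_groups(fr)
    # species of each residue = species of its first particle
    gsp <- vapply(groups, function(ii) fr$species[ii[1]], "")
    cent <- t(vapply(groups, function(ii)
      colMeans(fr$coords[ii, , drop = FALSE]), numeric(3)))
    ng <- length(groups)
    if (ng < 2L) next
    # residue-pair prefilter on centroid distance before the atom test
    reach <- vapply(groups, function(ii) {
      ci <- colMeans(fr$coords[ii, , drop = FALSE])
      sqrt(max(rowSums(sweep(fr$coords[ii, , drop = FALSE], 2, ci)^2)))
    }, numeric(1))
    dc <- pair_distances(cent, cent, fr$box)
    for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
      if (dc[i, j] > cutoff + reach[i] + reach[j]) next
      dij <- pair_distances(fr$coords[groups[[i]], , drop = FALSE],
                            fr$coords[groups[[j]], , drop = FALSE], fr$box)
      if (min(dij) <= cutoff) {
        a <- gsp[i]; b <- gsp[j]
        raw[a, b] <- raw[a, b] + 1
        if (a != b) raw[b, a] <- raw[b, a] + 1
      }
    }
  }
  raw <- raw / length(frames)
  # molecule counts per species (residues, from the first frame)
  g1 <- residue_groups(frames[[1]])
  n_mol <- table(factor(vapply(g1, function(ii) frames[[1]]$species[ii[1]], ""),
                        levels = sp_all))
  denom <- outer(as.numeric(n_mol), as.numeric(n_mol))
  diag(denom) <- as.numeric(n_mol) * (as.numeric(n_mol) - 1) / 2
  denom[denom == 0] <- NA
  per_pair <- raw / denom
  norm <- per_pair / max(per_pair, na.rm = TRUE)
  structure(list(normalized = norm, per_pair = per_pair, raw = raw,
                 cutoff = cutoff, n_frames = length(frames),
                 normalization = "pair-count product, scaled by matrix max"),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: cutoff %.2f nm, %d frames\n", x$cutoff, x$n_frames))
  print(round(x$normalized, 3))
  invisible(x)
}

# oriented best-fit normal of an ordered planar group: sum of consecutive
# vertex cross products about the centroid (Newell's method). Orientation
# follows atom ordering, so antiparallel planes give theta near pi.
oriented_normal <- function(xyz) {
  cen <- colMeans(xyz)
  v <- sweep(xyz, 2, cen)
  n <- nrow(v)
  nrm <- c(0, 0, 0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    nrm <- nrm + c(v[i, 2] * v[j, 3] - v[i, 3] * v[j, 2],
                   v[i, 3] * v[j, 1] - v[i, 1] * v[j, 3],
                   v[i, 1] * v[j, 2] - v[i, 2] * v[j, 1])
  }
  nrm / sqrt(sum(nrm^2))
}

# make a residue group whole across periodic boundaries (min image wrt the
# first atom), returning coordinates
whole_group <- function(frame, idx) {
  x <- frame$coords[idx, , drop = FALSE]
  ref <- x[1, ]
  for (k in 1:3) {
    d <- x[, k] - ref[k]
    x[, k] <- x[, k] - frame$box[k] * round(d / frame$box[k])
  }
  x
}

angle_between <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(a * b))))
}

pair_geometry_list <- function(frame, groups_a, groups_b, cutoff, same) {
  out <- list()
  cents_a <- lapply(groups_a, function(ii) colMeans(whole_group(frame, ii)))
  cents_b <- if (same) cents_a else
    lapply(groups_b, function(ii) colMeans(whole_group(frame, ii)))
  norms_a <- lapply(groups_a, function(ii) oriented_normal(whole_group(frame, ii)))
  norms_b <- if (same) norms_a else
    lapply(groups_b, function(ii) oriented_normal(whole_group(frame, ii)))
  na_ <- length(groups_a); nb_ <- length(groups_b)
  for (i in seq_len(na_)) {
    jj <- if (same) seq_len(nb_)[-seq_len(i)] else seq_len(nb_)
    for (j in jj) {
      d <- cents_b[[j]] - cents_a[[i]]
      d <- d - frame$box * round(d / frame$box)
      dist <- sqrt(sum(d^2))
      if (dist <= cutoff)
        out[[length(out) + 1L]] <-
          c(distance = dist, theta = angle_between(norms_a[[i]], norms_b[[j]]))
    }
  }
  out
}

#' Ring-pair geometry: centroid distance and inter-normal angle
#'
#' For every pair of aromatic rings within the reporting cutoff, returns the
#' centroid-centroid distance (minimum image) and the angle theta between
#' the oriented ring-plane normals. Normals come from the ordered ring
#' vertices (Newell construction), so their orientation is fixed by atom
#' ordering and theta spans \[0, pi\]: values near 0 or pi indicate parallel
#' (stacked) arrangements, values near pi/2 T-shaped ones.
#'
#' @param frames list of [configuration_frame].
#' @param ring_species species label(s) marking ring atoms (default `"RC"`);
#'   each residue made of these atoms is one ring.
#' @param cutoff reporting cutoff on centroid distance (nm).
#' @return Data frame with columns `distance` (nm) and `theta` (radians).
#' @export
ring_geometry <- function(frames, ring_species = "RC", cutoff = 0.9) {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  rows <- list()
  for (fr in frames) {
    rings <- residue_groups(fr, ring_species)
    rings <- rings[vapply(rings, length, 0L) >= 3L]
    rows <- c(rows, pair_geometry_list(fr, rings, rings, cutoff, same = TRUE))
  }
  as.data.frame(do.call(rbind, rows) %||% matrix(numeric(0), 0, 2,
                dimnames = list(NULL, c("distance", "theta"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Amide-ring (sp2-pi) geometry
#'
#' Same contract as [ring_geometry()], but pairing each planar amide group
#' (defined by its three C, O, N atoms) with each aromatic ring: distance is
#' amide-centroid to ring-centroid, theta the angle between the amide-plane
#' and ring-plane oriented normals.
#'
#' @param frames list of [configuration_frame].
#' @param ring_species species label(s) marking ring atoms.
#' @param amide_species species label(s) marking amide C/O/N atoms; each
#'   residue made of exactly three such atoms is one amide plane.
#' @param cutoff reporting cutoff on centroid distance (nm).
#' @return Data frame with columns `distance` (nm) and `theta` (radians).
#' @export
sp2_pi_geometry <- function(frames, ring_species = "RC",
                            amide_species = "AM", cutoff = 0.9) {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  rows <- list()
  for (fr in frames) {
    rings <- residue_groups(fr, ring_species)
    rings <- rings[vapply(rings, length, 0L) >= 3L]
    amides <- residue_groups(fr, amide_species)
    amides <- amides[vapply(amides, length, 0L) == 3L]
    rows <- c(rows, pair_geometry_list(fr, amides, rings, cutoff, same = FALSE))
  }
  as.data.frame(do.call(rbind, rows) %||% matrix(numeric(0), 0, 2,
                dimnames = list(NULL, c("distance", "theta"))))
}

#' 2-D (distance, theta) density histogram
#'
#' Bins a geometry pair list into the (distance, theta) plane.
#'
#' @param geoms data frame from [ring_geometry()] or [sp2_pi_geometry()].
#' @param d_max maximum distance (nm); @param d_bin distance bin (nm).
#' @param theta_bin angle bin (radians; default 5 degrees).
#' @return Matrix of counts, distance bins in rows, theta bins in columns.
#' @export
geometry_density_map <- function(geoms, d_max = 0.9, d_bin = 0.02,
                                 theta_bin = 5 * pi / 180) {
  d_edges <- seq(0, d_max, by = d_bin)
  t_edges <- seq(0, pi + 1e-12, by = theta_bin)
  if (t_edges[length(t_edges)] < pi) t_edges <- c(t_edges, pi)
  di <- cut(geoms$distance, d_edges, include.lowest = TRUE)
  ti <- cut(geoms$theta, t_edges, include.lowest = TRUE)
  table(distance = di, theta = ti)
}

#' Radial distribution function between two species
#'
#' Minimum-image pair-distance histogram normalized by the exact spherical
#' shell volume (4/3) pi (r+^3 - r-^3) and the ideal-gas pair density, so a
#' homogeneous system gives g(r) = 1.
#'
#' @param frames list of [configuration_frame].
#' @param species_a,species_b species labels ("all" selects everything).
#' @param r_max histogram range (nm); must not exceed half the smallest box
#'   edge.
#' @param bin_width bin width (nm).
#' @return A `rdf_result`: data frame with columns `r` (bin centres) and
#'   `g`; attributes `species`, `n_frames`.
#' @export
rdf <- function(frames, species_a = "all", species_b = "all",
                r_max = NULL, bin_width = 0.02) {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  box <- frames[[1]]$box
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max must be <= half the smallest box edge")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  norm_acc <- 0
  for (fr in frames) {
    ia <- if (identical(species_a, "all")) seq_len(nrow(fr$coords))
          else which(fr$species %in% species_a)
    ib <- if (identical(species_b, "all")) seq_len(nrow(fr$coords))
          else which(fr$species %in% species_b)
    same <- identical(sort(ia), sort(ib))
    V <- prod(fr$box)
    d <- pair_distances(fr$coords[ia, , drop = FALSE],
                        fr$coords[ib, , drop = FALSE], fr$box)
    if (same) {
      d <- d[upper.tri(d)]
      n_pairs <- length(ia) * (length(ia) - 1) / 2
    } else {
      d <- as.numeric(d)
      n_pairs <- length(ia) * length(ib)
    }
    counts <- counts + graphics::hist(d[d <= r_max & d > 0],
                                      breaks = edges, plot = FALSE)$counts
    norm_acc <- norm_acc + n_pairs / V
  }
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1L)]^3)
  g <- counts / (norm_acc * shell)
  structure(data.frame(r = (edges[-1] + edges[-(nb + 1L)]) / 2, g = g,
                       count = counts),
            class = c("rdf_result", "data.frame"),
            species = c(species_a, species_b), n_frames = length(frames))
}

#' Bundled van der Waals radii (nm)
#'
#' Bondi-style radii used by [sasa_series()]; species labels not listed fall
#' back to the `"default"` entry (carbon-like 0.17 nm).
#' @export
condx_vdw_radii <- c(C = 0.170, RC = 0.170, N = 0.155, O = 0.152,
                     S = 0.180, H = 0.120, P = 0.180, AM = 0.160,
                     default = 0.170)

# quasi-uniform points on the unit sphere (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area time series (Shrake-Rupley)
#'
#' For each particle, distributes `n_sphere_points` quasi-uniform test
#' points on the sphere of radius r_i + probe and counts the fraction not
#' buried inside any neighbour's expanded sphere; the particle SASA is that
#' fraction times 4 pi (r_i + probe)^2. Per-frame totals are summed over the
#' selection (all particles still act as occluders).
#'
#' @param frames list of [configuration_frame].
#' @param radii named radii table (nm) with a `"default"` entry.
#' @param probe probe radius (nm), default 0.14 (water).
#' @param n_sphere_points test points per sphere, default 960.
#' @param selection species labels to report (default all).
#' @return A `sasa_series`: data frame with columns `frame` and `sasa`
#'   (nm^2); attributes `probe`, `n_sphere_points`, `selection`.
#' @export
sasa_series <- function(frames, radii = condx_vdw_radii, probe = 0.14,
                        n_sphere_points = 960L, selection = "all") {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  pts <- sphere_points(n_sphere_points)
  sasa <- vapply(frames, function(fr) {
    n <- nrow(fr$coords)
    if (n == 0L) return(0)
    r <- radii[fr$species]
    r[is.na(r)] <- radii[["default"]]
    r <- unname(r) + probe
    sel <- if (identical(selection, "all")) seq_len(n)
           else which(fr$species %in% selection)
    dall <- pair_distances(fr$coords, fr$coords, fr$box)
    total <- 0
    for (i in sel) {
      nb <- setdiff(which(dall[i, ] < r[i] + r), i)
      if (!length(nb)) { total <- total + 4 * pi * r[i]^2; next }
      surf <- sweep(pts * r[i], 2, fr$coords[i, ], "+")
      free <- rep(TRUE, nrow(surf))
      for (j in nb) {
        d <- sweep(surf[free, , drop = FALSE], 2, fr$coords[j, ])
        d <- d - sweep(matrix(round(sweep(d, 2, fr$box, "/")), ncol = 3),
                       2, fr$box, "*")
        free[free] <- rowSums(d^2) > r[j]^2
        if (!any(free)) break
      }
      total <- total + sum(free) / n_sphere_points * 4 * pi * r[i]^2
    }
    total
  }, numeric(1))
  structure(data.frame(frame = seq_along(frames), sasa = sasa),
            class = c("sasa_series", "data.frame"),
            probe = probe, n_sphere_points = n_sphere_points,
            selection = selection)
}
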