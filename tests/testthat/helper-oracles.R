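# Independent oracles used for cross-checks. These deliberately share no
# code with the package: the BAR oracle is a Newton iteration on the
# tanh form of the acceptance-ratio equation, and the structural oracles
# are direct O(N^2) loops.

kB_ORACLE <- 0.00831446

# Independent BAR: stats::uniroot on the tanh form of the acceptance-ratio
# equation,
#   g(C) = sum_F (1/2)(1 - tanh((M + (wf - C)/kT)/2))
#        - sum_R (1/2)(1 - tanh((-M + (wr + C)/kT)/2)) = 0
# where M = ln(nF/nR); same estimator, independent formulation, solver and
# code path from the package's bisection on the Fermi-function form.
oracle_bar <- function(wf, wr, T = 298, tol = 1e-12) {
  kT <- kB_ORACLE * T
  M <- log(length(wf) / length(wr))
  g <- function(C) {
    sum(0.5 * (1 - tanh((M + (wf - C) / kT) / 2))) -
      sum(0.5 * (1 - tanh((-M + (wr + C) / kT) / 2)))
  }
  lo <- min(c(wf, -wr)) - 50
  hi <- max(c(wf, -wr)) + 50
  stats::uniroot(g, c(lo, hi), tol = tol)$root
}

# Brute-force residue-residue contact events for a single frame: plain
# double loop over residues and atoms with explicit minimum image.
oracle_contact_events <- function(frame, cutoff) {
  ids <- sort(unique(frame$residue_id))
  events <- list()
  for (ai in seq_along(ids)) {
    for (bi in seq_along(ids)) {
      if (bi <= ai) next
      ia <- which(frame$residue_id == ids[ai])
      ib <- which(frame$residue_id == ids[bi])
      hit <- FALSE
      for (p in ia) {
        for (q in ib) {
          d <- frame$coords[p, ] - frame$coords[q, ]
          d <- d - frame$box * round(d / frame$box)
          if (sqrt(sum(d^2)) <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit)
        events[[length(events) + 1L]] <-
          c(frame$species[ia[1]], frame$species[ib[1]])
    }
  }
  events
}

# Brute-force pair-distance histogram counts for the rdf check.
oracle_rdf_counts <- function(frame, edges, species_a, species_b) {
  ia <- if (identical(species_a, "all")) seq_len(nrow(frame$coords))
        else which(frame$species %in% species_a)
  ib <- if (identical(species_b, "all")) seq_len(nrow(frame$coords))
        else which(frame$species %in% species_b)
  same <- identical(sort(ia), sort(ib))
  counts <- numeric(length(edges) - 1L)
  for (p in ia) {
    for (q in ib) {
      if (same && q <= p) next
      d <- frame$coords[p, ] - frame$coords[q, ]
      d <- d - frame$box * round(d / frame$box)
      r <- sqrt(sum(d^2))
      if (r > 0 && r <= edges[length(edges)]) {
        k <- findInterval(r, edges, rightmost.closed = TRUE, left.open = TRUE)
        if (k >= 1 && k <= length(counts)) counts[k] <- counts[k] + 1
      }
    }
  }
  counts
}

# random rigid motion applied to a frame (recentering disabled downstream)
apply_rigid_motion <- function(frame, seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  R <- Rx %*% Ry %*% Rz
  list(R = R, shift = runif(3, -1, 1))
}
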