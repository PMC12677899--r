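#' Labeled particle configuration in an orthorhombic box
#'
#' Container for a single coordinate frame: particle positions, per-particle
#' species labels, residue ids, masses and (optionally) partial charges, plus
#' the orthorhombic box edge lengths. All lengths are in nm, masses in g/mol,
#' charges in units of the elementary charge.
#'
#' @param coords numeric matrix, n x 3, particle coordinates (nm).
#' @param box numeric length-3, box edge lengths (nm), all > 0.
#' @param species character vector of per-particle species labels
#'   (e.g. `"G"`, `"S"`, `"Y"`, `"F"`, `"W"`).
#' @param residue_id integer vector grouping particles into residues;
#'   defaults to one residue per particle.
#' @param mass numeric per-particle masses (g/mol), default 120 (one
#'   pseudo-particle per residue).
#' @param charge optional numeric per-particle charges (e).
#'
#' @return Object of class `configuration_frame`.
#' @export
configuration_frame <- function(coords, box, species,
                                residue_id = seq_len(nrow(coords)),
                                mass = rep(120, nrow(coords)),
                                charge = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), 0, 3)
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  n <- nrow(coords)
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive finite edge lengths (nm)")
  if (any(!is.finite(coords))) stop("all coordinates must be finite")
  species <- as.character(species)
  if (length(species) != n) stop("species must label every particle")
  if (n > 0 && anyNA(species)) stop("species labels may not be NA")
  residue_id <- as.integer(residue_id)
  if (length(residue_id) != n) stop("residue_id must cover every particle")
  mass <- as.numeric(mass)
  if (length(mass) == 1L) mass <- rep(mass, n)
  if (length(mass) != n || any(mass <= 0)) stop("mass must be positive per particle")
  if (!is.null(charge)) {
    charge <- as.numeric(charge)
    if (length(charge) != n) stop("charge must cover every particle")
  }
  structure(
    list(coords = coords, box = box, species = species,
         residue_id = residue_id, mass = mass, charge = charge),
    class = "configuration_frame")
}

#' @export
print.configuration_frame <- function(x, ...) {
  cat(sprintf("configuration_frame: %d particles, box %.3f x %.3f x %.3f nm\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3]))
  tab <- table(x$species)
  if (length(tab)) cat("  species:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
n_particles <- function(frame) UseMethod("n_particles")

#' @export
n_particles.configuration_frame <- function(frame) nrow(frame$coords)

#' Minimum-image pairwise distances between two coordinate sets
#'
#' @param xa,xb n x 3 coordinate matrices (nm).
#' @param box length-3 box edges (nm).
#' @return length(a) x length(b) distance matrix.
#' @keywords internal
pair_distances <- function(xa, xb, box) {
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0L || nb == 0L) return(matrix(numeric(0), na, nb))
  d2 <- matrix(0, na, nb)
  for (k in 1:3) {
    dk <- outer(xa[, k], xb[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Write frames to a GRO-format trajectory file
#'
#' Writes one or more `configuration_frame` objects as concatenated GRO
#' blocks (title, atom count, fixed-width atom records, box line). Species
#' labels are stored as residue/atom names. The paired reader
#' [read_gro()] accepts the output unchanged.
#'
#' @param frames a `configuration_frame` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, path) {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$coords)
    writeLines(sprintf("condx frame; mass=%s",
                       paste(format(fr$mass, trim = TRUE), collapse = ",")), con)
    writeLines(sprintf("%5d", n), con)
    if (n > 0) {
      lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       fr$residue_id %% 100000L, substr(fr$species, 1, 5),
                       substr(fr$species, 1, 5), seq_len(n) %% 100000L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3])
      writeLines(lines, con)
    }
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

#' Read a GRO-format trajectory file
#'
#' Parses concatenated GRO blocks into a list of
#' [configuration_frame] objects. Only orthorhombic box lines (three
#' numbers) are supported. Masses are recovered from the title line when it
#' carries a `mass=` field written by [write_gro()], else default to 120.
#'
#' @param path file path.
#' @return list of `configuration_frame`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    n <- as.integer(trimws(lines[i + 1L]))
    atom_lines <- if (n > 0) lines[(i + 2L):(i + 1L + n)] else character(0)
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3]
    if (n > 0) {
      resid <- as.integer(substr(atom_lines, 1, 5))
      species <- trimws(substr(atom_lines, 6, 10))
      xyz <- cbind(as.numeric(substr(atom_lines, 21, 28)),
                   as.numeric(substr(atom_lines, 29, 36)),
                   as.numeric(substr(atom_lines, 37, 44)))
    } else {
      resid <- integer(0); species <- character(0)
      xyz <- matrix(numeric(0), 0, 3)
    }
    mass <- 120
    m <- regmatches(title, regexpr("mass=[-0-9.,eE+]+", title))
    if (length(m) == 1L)
      mass <- as.numeric(strsplit(sub("mass=", "", m), ",")[[1]])
    frames[[length(frames) + 1L]] <-
      configuration_frame(xyz, box, species, resid, mass)
    i <- i + 3L + n
  }
  frames
}

#' Write frames in extended XYZ format
#'
#' Column layout: species x y z (nm). The comment line carries
#' `box="lx ly lz"`. [read_xyz()] accepts the output unchanged.
#'
#' @inheritParams write_gro
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "configuration_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf('box="%.6f %.6f %.6f"', fr$box[1], fr$box[2], fr$box[3]), con)
    if (nrow(fr$coords) > 0)
      writeLines(sprintf("%s %.6f %.6f %.6f", fr$species,
                         fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#' @param path file path.
#' @return list of [configuration_frame].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    boxstr <- sub('".*$', "", sub('.*box="', "", lines[i + 1L]))
    box <- as.numeric(strsplit(trimws(boxstr), "\\s+")[[1]])[1:3]
    if (n > 0) {
      parts <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
      species <- vapply(parts, `[[`, "", 1L)
      xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    } else {
      species <- character(0); xyz <- matrix(numeric(0), 0, 3)
    }
    frames[[length(frames) + 1L]] <- configuration_frame(xyz, box, species)
    i <- i + 2L + n
  }
  frames
}

#' Read an XVG-style numeric table
#'
#' Whitespace-separated numeric columns; lines starting with `#` or `@`
#' (Grace headers) are ignored.
#'
#' @param path file path.
#' @return numeric matrix (one row per data line).
#' @export
read_xvg <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(matrix(numeric(0), 0, 0))
  do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
}

#' Write an XVG-style numeric table
#'
#' @param x numeric matrix or data frame.
#' @param path file path.
#' @param header optional character vector written as `#` comment lines.
#' @export
write_xvg <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  write.table(as.matrix(x), con, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
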