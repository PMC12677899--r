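# Contact-energy decomposition: quantum interaction energies plus monomer
# transfer free energies, and the dielectric crossover they imply.
# Monomer ids follow the side-chain analogues: Y = p-cresol (Tyr side
# chain), F = toluene (Phe), A = N-methyl-acetamide (amide bond).

#' Dimer interaction energy in a solvent
#'
#' dE_int = E_dimer - (E_i + E_j): the electronic interaction energy of a
#' dimer relative to its isolated monomers, all evaluated in the same
#' solvent model.
#'
#' @param E_dimer,E_i,E_j electronic energies (kJ/mol).
#' @return Interaction energy (kJ/mol); negative = attractive.
#' @export
interaction_energy <- function(E_dimer, E_i, E_j) E_dimer - (E_i + E_j)

#' Transfer free energy of a monomer from water into a solvent
#'
#' dG_transfer = dG_solv(solvent) - dG_solv(water). Positive values mean
#' the monomer prefers water; for apolar solvents this term recapitulates a
#' hydrophobicity scale.
#'
#' @param dG_solvent,dG_water solvation free energies (kJ/mol).
#' @return Transfer free energy (kJ/mol).
#' @export
transfer_free_energy <- function(dG_solvent, dG_water) dG_solvent - dG_water

# locate the water reference row for a species
water_dG <- function(monomers, species) {
  w <- monomers[monomers$solvent == "water" & monomers$species == species, ]
  if (!nrow(w))
    stop(sprintf("no water reference row for monomer '%s'", species))
  w$dG_solv[1]
}

#' Contact energy of a dimer in a solvent
#'
#' Total energy of contact formation: the transfer of both monomers from
#' water into the solvent plus their interaction there,
#' dE_contact = dE_int + dG_transfer_i + dG_transfer_j. The additivity of
#' the three terms is exact by construction.
#'
#' @param table a `solvent_energy_table` (list with `dimers` and `monomers`
#'   data frames; see [gen_energy_tables()] / [read_energy_tables()]).
#' @param pair dimer pair label (e.g. `"Y-Y"`, `"F-F"`).
#' @param orientation orientation label (e.g. `"opt"`, `"cross"`).
#' @param solvent solvent name.
#' @param monomer_ids the two monomer species forming the pair; defaults to
#'   splitting `pair` on `"-"`.
#' @return A one-row data frame: `pair`, `orientation`, `solvent`, `class`,
#'   `epsilon`, `dE_int`, `dG_transfer_i`, `dG_transfer_j`, `dE_contact`.
#' @export
contact_energy <- function(table, pair, orientation, solvent,
                           monomer_ids = strsplit(pair, "-", fixed = TRUE)[[1]]) {
  d <- table$dimers
  row <- d[d$pair == pair & d$orientation == orientation &
             d$solvent == solvent, ]
  if (!nrow(row))
    stop(sprintf("no dimer row for pair '%s' orientation '%s' in solvent '%s'",
                 pair, orientation, solvent))
  row <- row[1, ]
  dE_int <- if ("dE_int" %in% names(row) && !is.na(row$dE_int)) row$dE_int
            else interaction_energy(row$E_ij, row$E_i, row$E_j)
  m <- table$monomers
  tr <- vapply(monomer_ids, function(sp) {
    s <- m[m$solvent == solvent & m$species == sp, ]
    if (!nrow(s))
      stop(sprintf("no monomer row for species '%s' in solvent '%s'", sp, solvent))
    transfer_free_energy(s$dG_solv[1], water_dG(m, sp))
  }, numeric(1))
  data.frame(pair = pair, orientation = orientation, solvent = solvent,
             class = row$class, epsilon = row$epsilon, dE_int = dE_int,
             dG_transfer_i = tr[1], dG_transfer_j = tr[2],
             dE_contact = dE_int + tr[1] + tr[2])
}

#' Contact energies for every dimer row of a table
#'
#' @param table a `solvent_energy_table`.
#' @return Data frame of per-row [contact_energy()] results.
#' @export
contact_energy_all <- function(table) {
  d <- unique(table$dimers[, c("pair", "orientation", "solvent")])
  do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    contact_energy(table, d$pair[i], d$orientation[i], d$solvent[i])))
}

#' Contact energies relative to a reference pair
#'
#' Per solvent, ddE = dE_contact(pair) - dE_contact(reference), with the
#' reference re-evaluated in each solvent. Negative values mean the pair is
#' preferred over the reference (conventionally the pi-stacked F-F cross
#' configuration) in that solvent.
#'
#' @param results data frame from [contact_energy_all()] (or rbind of
#'   [contact_energy()] rows).
#' @param reference_pair,reference_orientation identify the reference rows.
#' @return `results` with an added `ddE_contact` column; reference rows get 0.
#' @export
delta_delta_contact <- function(results, reference_pair,
                                reference_orientation = unique(results$orientation)[1]) {
  ref <- results[results$pair == reference_pair &
                   results$orientation == reference_orientation, ]
  if (!nrow(ref))
    stop(sprintf("reference pair '%s'/'%s' not present", reference_pair,
                 reference_orientation))
  ref_by_solvent <- stats::setNames(ref$dE_contact, ref$solvent)
  missing <- setdiff(unique(results$solvent), names(ref_by_solvent))
  if (length(missing))
    stop("reference pair missing in solvents: ", paste(missing, collapse = ", "))
  results$ddE_contact <- results$dE_contact -
    ref_by_solvent[results$solvent]
  rownames(results) <- NULL
  results
}

#' Crossover dielectric constants of a ddE curve
#'
#' Orders the (epsilon, ddE) points of one solvent class by epsilon and
#' returns every sign-change root located by piecewise-linear interpolation
#' in epsilon. An empty vector means the preference never reverses within
#' the sampled dielectric range. Points from different solvent classes must
#' not be mixed: crossover behaviour is class-dependent.
#'
#' @param epsilon,ddE numeric vectors of equal length (>= 2) from a single
#'   solvent class.
#' @return Numeric vector of crossover dielectric values (possibly empty).
#' @export
find_crossover <- function(epsilon, ddE) {
  if (length(epsilon) != length(ddE)) stop("epsilon and ddE lengths differ")
  if (length(epsilon) < 2L) stop("need >= 2 points within one solvent class")
  o <- order(epsilon)
  e <- epsilon[o]; y <- ddE[o]
  roots <- numeric(0)
  for (i in seq_len(length(e) - 1L)) {
    if (y[i] == 0) { roots <- c(roots, e[i]); next }
    if (y[i] * y[i + 1L] < 0)
      roots <- c(roots, e[i] - y[i] * (e[i + 1L] - e[i]) / (y[i + 1L] - y[i]))
  }
  if (length(y) && y[length(y)] == 0) roots <- c(roots, e[length(e)])
  unique(roots)
}

#' Crossovers per solvent class of a ddE result table
#'
#' @param results output of [delta_delta_contact()].
#' @param pair,orientation the dimer whose ddE curve to scan.
#' @return Named list: solvent class -> numeric vector of crossover epsilon.
#' @export
crossover_by_class <- function(results, pair,
                               orientation = unique(results$orientation)[1]) {
  sel <- results[results$pair == pair & results$orientation == orientation, ]
  out <- lapply(split(sel, sel$class), function(s)
    if (nrow(s) >= 2L) find_crossover(s$epsilon, s$ddE_contact) else numeric(0))
  out
}

#' Min-max normalization of a hydropathy scale
#'
#' lambda_i = (h_i - min h) / (max h - min h), mapping any hydropathy scale
#' onto \[0, 1\].
#'
#' @param scale named numeric vector, residue -> raw hydropathy.
#' @return A `hydropathy_scale`: data frame with `residue`, `raw`,
#'   `lambda`.
#' @export
minmax_normalize <- function(scale) {
  if (!length(scale) || is.null(names(scale))) stop("scale must be named")
  rng <- range(scale)
  if (diff(rng) == 0) stop("degenerate scale: zero range, cannot min-max normalize")
  structure(data.frame(residue = names(scale), raw = unname(scale),
                       lambda = unname((scale - rng[1]) / diff(rng))),
            class = c("hydropathy_scale", "data.frame"))
}

ref_table_env <- new.env(parent = emptyenv())

load_reference_table <- function(name) {
  if (!is.null(ref_table_env[[name]])) return(ref_table_env[[name]])
  path <- system.file("extdata", paste0(name, ".csv"), package = "condx",
                      mustWork = TRUE)
  ref_table_env[[name]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  ref_table_env[[name]]
}

#' Bundled literature reference values
#'
#' Versioned lookup of bundled reference tables: `"mj_self"` -- diagonal
#' (self-interaction) entries of the Miyazawa-Jernigan statistical contact
#' potential, in RT units; `"solubility"` -- amino-acid solubilities in
#' water at 25 C, g per 100 g water; `"water_model_eps"` -- static
#' dielectric constants of common water models; `"hydropathy_kd"` -- the
#' Kyte-Doolittle hydropathy scale. Each value is returned with its source
#' string.
#'
#' @param table one of `"mj_self"`, `"solubility"`, `"water_model_eps"`,
#'   `"hydropathy_kd"`.
#' @param key row key (residue one-letter code or water-model name);
#'   omit for the full table.
#' @return For a single key, list with `value`, `units`, `source`;
#'   otherwise the whole data frame.
#' @export
reference_lookup <- function(table = c("mj_self", "solubility",
                                       "water_model_eps", "hydropathy_kd"),
                             key = NULL) {
  table <- match.arg(table)
  df <- load_reference_table(table)
  if (is.null(key)) return(df)
  row <- df[df$key == key, ]
  if (!nrow(row)) stop(sprintf("key '%s' not found in table '%s'", key, table))
  list(value = row$value[1], units = row$units[1], source = row$source[1])
}

#' Read dimer and monomer energy tables from CSV
#'
#' Dimer schema: solvent, class, epsilon, pair, orientation, E_ij, E_i, E_j
#' (or a precomputed dE_int column). Monomer schema: solvent, class,
#' epsilon, species, dG_solv. Energies are kJ/mol; a `unit` column equal to
#' `"kcal/mol"` triggers conversion at 4.184.
#'
#' @param dimer_path,monomer_path CSV paths.
#' @return A `solvent_energy_table`.
#' @export
read_energy_tables <- function(dimer_path, monomer_path) {
  conv <- function(df, cols) {
    if ("unit" %in% names(df)) {
      k <- df$unit == "kcal/mol"
      for (cc in intersect(cols, names(df))) df[[cc]][k] <- df[[cc]][k] * condx_constants$kcal
      df$unit <- NULL
    }
    df
  }
  dimers <- conv(utils::read.csv(dimer_path, stringsAsFactors = FALSE),
                 c("E_ij", "E_i", "E_j", "dE_int"))
  monomers <- conv(utils::read.csv(monomer_path, stringsAsFactors = FALSE),
                   "dG_solv")
  if (any(!is.finite(as.matrix(dimers[intersect(c("E_ij", "E_i", "E_j"),
                                                names(dimers))]))))
    stop("non-finite dimer energies")
  structure(list(dimers = dimers, monomers = monomers),
            class = "solvent_energy_table")
}

#' Write a `solvent_energy_table` to a pair of CSV files
#'
#' Numeric columns are serialized with 17 significant digits so the paired
#' reader recovers them bit-identically.
#'
#' @param table a `solvent_energy_table`.
#' @param dimer_path,monomer_path output CSV paths.
#' @export
write_energy_tables <- function(table, dimer_path, monomer_path) {
  full_precision <- function(df) {
    for (cc in names(df)) if (is.numeric(df[[cc]]))
      df[[cc]] <- sprintf("%.17g", df[[cc]])
    df
  }
  utils::write.csv(full_precision(table$dimers), dimer_path,
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(full_precision(table$monomers), monomer_path,
                   row.names = FALSE, quote = TRUE)
  invisible(c(dimer_path, monomer_path))
}
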