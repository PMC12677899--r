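# Configuration-driven orchestration: a YAML config lists stages that are
# executed in order through the package functions, every artifact stamped
# with the config hash, seed and package version.

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

stage_schema <- list(
  simulate_work  = c("dG_true", "dissipation"),
  bar            = c("forward", "reverse"),
  simulate_slab  = c("rho_dense", "rho_dilute", "slab_halfwidth", "interface_width"),
  phase          = c("frames"),
  simulate_dipoles = c("eps_target"),
  dielectric     = c("series"),
  contacts       = c("frames"),
  rdf            = c("frames"),
  sasa           = c("frames"),
  contact_energy = c("dimers", "monomers", "reference_pair"),
  critical_fit   = c("coexistence")
)

validate_config <- function(config) {
  if (is.null(config$stages) || !length(config$stages))
    stop("config violation: field 'stages' must be a non-empty list")
  for (st in config$stages) {
    if (is.null(st$stage))
      stop("config violation: every stage entry needs a 'stage' name")
    if (!st$stage %in% names(stage_schema))
      stop(sprintf("config violation: unknown stage '%s' (known: %s)",
                   st$stage, paste(names(stage_schema), collapse = ", ")))
    need <- stage_schema[[st$stage]]
    miss <- setdiff(need, names(st))
    if (length(miss))
      stop(sprintf("config violation: stage '%s' missing required field(s) %s",
                   st$stage, paste(miss, collapse = ", ")))
    for (f in intersect(c("forward", "reverse", "frames", "series",
                          "dimers", "monomers", "coexistence"), names(st)))
      if (is.character(st[[f]]) && !file.exists(st[[f]]))
        stop(sprintf("config violation: stage '%s' input path '%s' does not exist",
                     st$stage, st[[f]]))
  }
  invisible(TRUE)
}

stamp <- function(obj, meta) c(obj, list(meta = meta))

write_stage_json <- function(obj, meta, path) {
  jsonlite::write_json(stamp(obj, meta), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  path
}

#' Run a configured analysis pipeline
#'
#' Executes the stages of a YAML (or list) configuration in declared order.
#' Supported stages: `simulate_work`, `bar`, `simulate_slab`, `phase`,
#' `critical_fit`, `simulate_dipoles`, `dielectric`, `contacts`, `rdf`,
#' `sasa`, `contact_energy`. Each stage reads files produced upstream (or
#' listed paths), runs the corresponding package function and writes
#' JSON/CSV outputs into `out_dir`; every JSON artifact carries the config
#' hash, the seed and the package version. Schema violations and stage
#' errors raise immediately.
#'
#' @param config path to a YAML config, or an equivalent list. Top-level
#'   fields: `seed` (integer), `out_dir` (optional, overridden by the
#'   argument), `stages` (list of stage entries; each has `stage`, a `name`
#'   used as output prefix, and stage parameters).
#' @param out_dir output directory (created if missing).
#' @return Named list of per-stage output file paths, invisibly.
#' @export
run_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% "condx_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config_hash = config_hash(config), seed = seed,
               package_version = as.character(utils::packageVersion("condx")))
  outputs <- list()
  for (k in seq_along(config$stages)) {
    st <- config$stages[[k]]
    nm <- st$name %||% sprintf("%02d_%s", k, st$stage)
    pfx <- file.path(out_dir, nm)
    outputs[[nm]] <- switch(st$stage,
      simulate_work = {
        ws <- gen_crooks_work(st$dG_true, st$dissipation,
                              st$n_forward %||% 100L, st$n_reverse %||% 100L,
                              st$T %||% DEFAULT_T, seed = seed + k)
        write_xvg(cbind(seq_along(ws$forward), ws$forward),
                  paste0(pfx, "_forward.xvg"),
                  header = sprintf("forward works kJ/mol; seed %d", seed + k))
        write_xvg(cbind(seq_along(ws$reverse), ws$reverse),
                  paste0(pfx, "_reverse.xvg"),
                  header = sprintf("backward works kJ/mol; seed %d", seed + k))
        paste0(pfx, c("_forward.xvg", "_reverse.xvg"))
      },
      bar = {
        ws <- work_set(read_work_values(st$forward),
                       read_work_values(st$reverse), T = st$T %||% DEFAULT_T)
        est <- bar_estimate(ws, n_bootstrap = st$n_bootstrap %||% 1000L,
                            seed = seed + k)
        write_stage_json(list(dG = est$dG, se = est$se,
                              n_forward = est$n_forward,
                              n_reverse = est$n_reverse,
                              crossing = suppressWarnings(crooks_crossing(ws))),
                         meta, paste0(pfx, ".json"))
      },
      simulate_slab = {
        frames <- gen_slab_frames(st$rho_dense, st$rho_dilute,
                                  st$slab_halfwidth, st$interface_width,
                                  box = unlist(st$box %||% c(20, 4.5, 4.5)),
                                  n_frames = st$n_frames %||% 10L,
                                  seed = seed + k)
        write_gro(frames, paste0(pfx, ".gro"))
        paste0(pfx, ".gro")
      },
      phase = {
        frames <- read_gro(st$frames)
        prof <- density_profile(frames, species = st$species %||% "all",
                                bin_width = st$bin_width %||% 0.1,
                                T = st$T %||% NA_real_)
        write_profile_csv(prof, paste0(pfx, "_profile.csv"))
        fit <- fit_tanh(prof)
        write_stage_json(list(rho_L = fit$rho_L, rho_H = fit$rho_H,
                              x_DS = fit$x_DS, t = fit$t,
                              se = as.list(fit$se), converged = fit$converged),
                         meta, paste0(pfx, ".json"))
      },
      critical_fit = {
        pts <- read_coexistence_csv(st$coexistence)
        cf <- fit_critical(pts)
        write_stage_json(list(Tc = cf$Tc, rhoc = cf$rhoc, A = cf$A, c = cf$c,
                              beta_exponent = cf$beta_exponent,
                              se = as.list(cf$se)),
                         meta, paste0(pfx, ".json"))
      },
      simulate_dipoles = {
        ds <- gen_dipole_series(st$eps_target, V = st$V %||% 405,
                                T = st$T %||% DEFAULT_T,
                                n_frames = st$n_frames %||% 1e4L,
                                seed = seed + k)
        write_xvg(cbind(seq_len(nrow(ds$M)), ds$M, ds$V),
                  paste0(pfx, ".xvg"),
                  header = "t Mx My Mz V (e nm; nm^3)")
        paste0(pfx, ".xvg")
      },
      dielectric = {
        ds <- read_dipole_xvg(st$series, volume = st$volume,
                              T = st$T %||% DEFAULT_T)
        est <- dielectric_constant(ds, n_blocks = st$n_blocks %||% 5L)
        write_stage_json(list(epsilon = est$epsilon, se = est$se,
                              n_blocks = est$n_blocks,
                              n_frames = est$n_frames),
                         meta, paste0(pfx, ".json"))
      },
      contacts = {
        cm <- contact_matrix(read_gro(st$frames), cutoff = st$cutoff %||% 0.45)
        utils::write.csv(cm$normalized, paste0(pfx, "_normalized.csv"))
        utils::write.csv(cm$raw, paste0(pfx, "_raw.csv"))
        paste0(pfx, c("_normalized.csv", "_raw.csv"))
      },
      rdf = {
        gr <- rdf(read_gro(st$frames), st$species_a %||% "all",
                  st$species_b %||% "all", r_max = st$r_max,
                  bin_width = st$bin_width %||% 0.02)
        utils::write.csv(as.data.frame(gr)[, c("r", "g")],
                         paste0(pfx, ".csv"), row.names = FALSE)
        paste0(pfx, ".csv")
      },
      sasa = {
        ss <- sasa_series(read_gro(st$frames), probe = st$probe %||% 0.14,
                          n_sphere_points = st$n_sphere_points %||% 960L,
                          selection = st$selection %||% "all")
        utils::write.csv(as.data.frame(ss), paste0(pfx, ".csv"),
                         row.names = FALSE)
        paste0(pfx, ".csv")
      },
      contact_energy = {
        tab <- read_energy_tables(st$dimers, st$monomers)
        res <- delta_delta_contact(contact_energy_all(tab),
                                   st$reference_pair,
                                   st$reference_orientation %||%
                                     unique(tab$dimers$orientation)[1])
        utils::write.csv(res, paste0(pfx, "_ddE.csv"), row.names = FALSE)
        pairs <- setdiff(unique(res$pair), st$reference_pair)
        cross <- lapply(stats::setNames(pairs, pairs), function(p)
          crossover_by_class(res, p))
        write_stage_json(list(crossover_epsilon = cross,
                              reference = st$reference_pair,
                              interpolation = "piecewise-linear in epsilon"),
                         meta, paste0(pfx, ".json"))
      })
    message(sprintf("[condx] stage %s (%s) done", nm, st$stage))
  }
  invisible(outputs)
}

#' Aggregate stage outputs into a summary table
#'
#' Collects the JSON artifacts written by [run_config()] and flattens their
#' scalar numeric fields into one long table (stage, quantity, value),
#' written to CSV when `path` is given. Values are passed through
#' unmodified.
#'
#' @param results_dir directory holding stage JSON outputs (or explicit
#'   character vector of JSON paths).
#' @param path optional CSV output path.
#' @return Data frame with columns `stage`, `quantity`, `value`.
#' @export
report <- function(results_dir, path = NULL) {
  files <- if (length(results_dir) == 1L && dir.exists(results_dir))
    list.files(results_dir, "\\.json$", full.names = TRUE) else results_dir
  rows <- list()
  for (f in files) {
    obj <- jsonlite::read_json(f, simplifyVector = TRUE)
    obj$meta <- NULL
    flat <- unlist(obj)
    num <- suppressWarnings(as.numeric(flat))
    keep <- !is.na(num)
    if (any(keep))
      rows[[f]] <- data.frame(stage = sub("\\.json$", "", basename(f)),
                              quantity = names(flat)[keep],
                              value = num[keep])
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(stage = character(0), quantity = character(0),
                         value = numeric(0))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
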