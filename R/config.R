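# Model configuration: defaults, YAML/JSON I/O, validation, fixtures.

#' Full model configuration
#'
#' Bundles every parameter group of the model into one validated record.
#' All defaults reproduce the baseline parameterization: a 10-compartment
#' cylinder (sigma 10 um, vessel diameter 60 um, necrotic cuff 100 um),
#' linear vascularization at 0.101/day, density 1e6 cells/mm^3 with packing
#' fraction 0.2, vessel-wall oxygen 16% with an 18 um half-distance, anchor
#' rates from 1% and 20% O2 cultures, motility 0.10/0.05/0.10, daily steps
#' over 12 years from a single seeded cell, and a matched pair of baseline
#' proteins (EC with phi = 4.5e-4, non-EC with psi = 4.5e-4, both with
#' half-life 6.4 days and healthy influx 456 U/day).
#'
#' @param spatial A [spatial_config()].
#' @param vascular A [vascular_params()].
#' @param density A [density_params()].
#' @param oxygen An [oxygen_profile()].
#' @param anchors A [rate_anchors()].
#' @param motility A [motility_params()].
#' @param simulation List with `dt_days`, `t_end_days`, `p0_cells`.
#' @param proteins List of [protein_params()].
#' @return An object of class `model_config`.
#' @export
model_config <- function(spatial = spatial_config(),
                         vascular = vascular_params(),
                         density = density_params(),
                         oxygen = oxygen_profile(),
                         anchors = rate_anchors(),
                         motility = motility_params(),
                         simulation = list(dt_days = 1, t_end_days = 4380,
                                           p0_cells = 1),
                         proteins = default_proteins()) {
  stopifnot(inherits(spatial, "spatial_config"),
            inherits(vascular, "vascular_params"),
            inherits(density, "density_params"),
            inherits(oxygen, "oxygen_profile"),
            inherits(anchors, "rate_anchors"),
            inherits(motility, "motility_params"),
            is.list(simulation), is.list(proteins))
  sim_fields <- c("dt_days", "t_end_days", "p0_cells")
  missing_f <- setdiff(sim_fields, names(simulation))
  if (length(missing_f)) {
    stop("simulation is missing field(s): ", paste(missing_f, collapse = ", "))
  }
  unknown <- setdiff(names(simulation), sim_fields)
  if (length(unknown)) {
    stop("unknown simulation field(s): ", paste(unknown, collapse = ", "))
  }
  stopifnot(simulation$dt_days > 0, simulation$t_end_days >= 0,
            simulation$p0_cells > 0)
  for (p in proteins) stopifnot(inherits(p, "protein_params"))
  structure(list(spatial = spatial, vascular = vascular, density = density,
                 oxygen = oxygen, anchors = anchors, motility = motility,
                 simulation = simulation, proteins = proteins),
            class = "model_config")
}

#' Baseline protein pair
#'
#' A matched extracellular / non-extracellular pair with identical
#' half-life and healthy influx, differing only in source (shedding by
#' viable cells vs release on death).
#'
#' @return List of two [protein_params()].
#' @export
default_proteins <- function() {
  list(
    protein_params("EC_baseline", ec = 1, phi = 4.5e-4, psi = 0,
                   t_half_days = 6.4, u_h = 456),
    protein_params("nonEC_baseline", ec = 0, phi = 0, psi = 4.5e-4,
                   t_half_days = 6.4, u_h = 456)
  )
}

# group -> (constructor, allowed field names)
config_schema <- function() {
  list(
    spatial = list(fn = spatial_config,
                   fields = c("sigma_um", "mvd_um", "epsilon_um")),
    vascular = list(fn = vascular_params,
                    fields = c("k_v", "unit_length_mm")),
    density = list(fn = density_params,
                   fields = c("rho_cells_per_mm3", "p_fraction")),
    oxygen = list(fn = oxygen_profile, fields = c("c0_pct", "r_half_mm")),
    anchors = list(fn = rate_anchors,
                   fields = c("c_low_pct", "c_high_pct", "kb_low", "kb_high",
                              "kd_low", "kd_high")),
    motility = list(fn = motility_params,
                    fields = c("p_in", "p_out", "p_out_boost",
                               "fold_threshold"))
  )
}

#' Load a model configuration from a YAML or JSON file
#'
#' Absent keys fall back to the defaults of [model_config()]; unknown keys
#' are rejected with an error naming them. Every constructor invariant is
#' re-validated on load.
#'
#' @param path Path to a YAML (or JSON; YAML is a superset) file, or `NULL`
#'   for the full defaults.
#' @return A validated [model_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(model_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(model_config())
  schema <- config_schema()
  known <- c(names(schema), "simulation", "proteins")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config group(s): ", paste(unknown, collapse = ", "))
  }
  args <- list()
  for (g in names(schema)) {
    if (is.null(raw[[g]])) next
    fields <- raw[[g]]
    bad <- setdiff(names(fields), schema[[g]]$fields)
    if (length(bad)) {
      stop("unknown field(s) in '", g, "': ", paste(bad, collapse = ", "))
    }
    args[[g]] <- do.call(schema[[g]]$fn, fields)
  }
  if (!is.null(raw$simulation)) {
    sim <- list(dt_days = 1, t_end_days = 4380, p0_cells = 1)
    bad <- setdiff(names(raw$simulation), names(sim))
    if (length(bad)) {
      stop("unknown field(s) in 'simulation': ", paste(bad, collapse = ", "))
    }
    sim[names(raw$simulation)] <- raw$simulation
    args$simulation <- sim
  }
  if (!is.null(raw$proteins)) {
    allowed <- c("name", "ec", "phi", "psi", "t_half_days", "u_h", "q0")
    args$proteins <- lapply(raw$proteins, function(p) {
      bad <- setdiff(names(p), allowed)
      if (length(bad)) {
        stop("unknown protein field(s): ", paste(bad, collapse = ", "))
      }
      do.call(protein_params, p)
    })
  }
  do.call(model_config, args)
}

#' Write a model configuration to YAML
#'
#' The written file round-trips through [load_config()] to an equal
#' configuration.
#'
#' @param config A [model_config()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  out <- list(
    spatial = unclass(config$spatial)[c("sigma_um", "mvd_um", "epsilon_um")],
    vascular = unclass(config$vascular),
    density = unclass(config$density),
    oxygen = unclass(config$oxygen),
    anchors = unclass(config$anchors),
    motility = unclass(config$motility),
    simulation = config$simulation,
    proteins = lapply(config$proteins, function(p) {
      unclass(p)[c("name", "ec", "phi", "psi", "t_half_days", "u_h", "q0")]
    })
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Convenience copy-with-overrides for configurations
#'
#' Rebuilds a [model_config()] with selected scalar parameters replaced;
#' used heavily by the scan and sensitivity drivers.
#'
#' @param config A [model_config()].
#' @param k_v,c0_pct,t_end_days,p0_cells Optional replacement values.
#' @return A new [model_config()].
#' @export
update_config <- function(config, k_v = NULL, c0_pct = NULL,
                          t_end_days = NULL, p0_cells = NULL) {
  stopifnot(inherits(config, "model_config"))
  vp <- config$vascular
  if (!is.null(k_v)) vp <- vascular_params(k_v, vp$unit_length_mm)
  ox <- config$oxygen
  if (!is.null(c0_pct)) ox <- oxygen_profile(c0_pct, ox$r_half_mm)
  sim <- config$simulation
  if (!is.null(t_end_days)) sim$t_end_days <- t_end_days
  if (!is.null(p0_cells)) sim$p0_cells <- p0_cells
  model_config(spatial = config$spatial, vascular = vp,
               density = config$density, oxygen = ox,
               anchors = config$anchors, motility = config$motility,
               simulation = sim, proteins = config$proteins)
}

#' Prebuilt scenario configurations
#'
#' Small configurations used throughout the test suite and examples:
#' \describe{
#'   \item{table1_defaults}{The full baseline configuration.}
#'   \item{single_compartment_malthusian}{One compartment, death-free
#'     anchors, intended for closed-form exponential-growth checks with
#'     capacity and motility disabled.}
#'   \item{xenograft_no_uh}{Baseline with both proteins' healthy influx set
#'     to zero (non-endogenous human proteins in a mouse host).}
#'   \item{fig8_corner_scan}{Baseline plus the three-point protein scan
#'     grids (u_h 4.56e0/4.56e2/4.56e4; t_half 0.64/20.24/640; psi
#'     1.423e-2/2.531/4.5e2) attached as attribute `scan_grids`.}
#' }
#'
#' @param scenario Scenario name.
#' @return A [model_config()] (with attribute `scan_grids` for
#'   `fig8_corner_scan`).
#' @export
make_fixture_config <- function(scenario = c("table1_defaults",
                                             "single_compartment_malthusian",
                                             "xenograft_no_uh",
                                             "fig8_corner_scan")) {
  scenario <- tryCatch(match.arg(scenario), error = function(e) {
    stop("unknown scenario; valid scenarios: table1_defaults, ",
         "single_compartment_malthusian, xenograft_no_uh, fig8_corner_scan")
  })
  switch(scenario,
    table1_defaults = model_config(),
    single_compartment_malthusian = model_config(
      spatial = spatial_config(sigma_um = 10, mvd_um = 60, epsilon_um = 10),
      anchors = rate_anchors(kb_low = 5e-3, kb_high = 5e-3,
                             kd_low = 0, kd_high = 0),
      simulation = list(dt_days = 1, t_end_days = 100, p0_cells = 1000)
    ),
    xenograft_no_uh = {
      cfg <- model_config()
      cfg$proteins <- list(
        protein_params("EC_xeno", ec = 1, phi = 4.5e-4, psi = 0,
                       t_half_days = 6.4, u_h = 0),
        protein_params("nonEC_xeno", ec = 0, phi = 0, psi = 4.5e-4,
                       t_half_days = 6.4, u_h = 0)
      )
      cfg
    },
    fig8_corner_scan = {
      cfg <- model_config()
      attr(cfg, "scan_grids") <- list(
        u_h = c(4.56e0, 4.56e2, 4.56e4),
        t_half = c(0.64, 20.24, 640),
        psi = c(1.423e-2, 2.531e0, 4.5e2)
      )
      cfg
    }
  )
}

#' Write standard run outputs
#'
#' Writes the growth summary, per-compartment growth table, one shedding
#' table per protein, and a manifest JSON capturing the fully resolved
#' configuration (sufficient to reproduce every file exactly).
#'
#' @param traj A [simulate_growth()] trajectory.
#' @param sheds Optional named list of shedding trajectories.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of file paths written, invisibly.
#' @export
write_outputs <- function(traj, sheds = NULL, out_dir) {
  stopifnot(inherits(traj, "growth_trajectory"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    c(paths, p)
  }
  paths <- wr(growth_summary(traj), "growth_summary.csv")
  paths <- wr(as.data.frame(traj), "growth_by_compartment.csv")
  for (nm in names(sheds)) {
    paths <- wr(as.data.frame(sheds[[nm]]), paste0("shedding_", nm, ".csv"))
  }
  manifest <- list(
    tool = "tumorshed",
    version = as.character(utils::packageVersion("tumorshed")),
    config = jsonlite::fromJSON(jsonlite::toJSON(
      lapply(unclass(traj$config), function(x) {
        if (is.list(x) && !is.null(names(x))) lapply(x, unclass) else unclass(x)
      }), auto_unbox = TRUE, digits = NA, force = TRUE))
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(paths, mpath))
}

#' @export
print.model_config <- function(x, ...) {
  cat("tumorshed model configuration\n")
  print(x$spatial)
  cat("  k_V =", x$vascular$k_v, "/day; C_0 =", x$oxygen$c0_pct,
      "%; rho =", x$density$rho_cells_per_mm3, "cells/mm^3; p =",
      x$density$p_fraction, "\n")
  cat("  simulation:", x$simulation$t_end_days, "days at dt =",
      x$simulation$dt_days, "day;", length(x$proteins), "protein(s)\n")
  invisible(x)
}
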