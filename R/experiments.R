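# Computational experiments: validity grid scan, run selection, sensitivity
# sweeps, per-compartment decomposition, protein scan envelopes.

#' Validity criteria for the growth grid scan
#'
#' A simulated tumor is considered biologically realistic if, at the end of
#' a 12-year run, it supports a large population and all compartments are
#' populated (heterogeneous subpopulations have formed).
#'
#' @param min_final_population Minimum final total population, cells.
#'   Default 1e7.
#' @param require_all_compartments Require `P_i` above the populated
#'   threshold in every compartment. Default TRUE.
#' @param populated_threshold Cells above which a compartment counts as
#'   populated. Default 1.
#' @param t_end_days Simulation horizon, days. Default 4380 (12 years).
#' @return An object of class `validity_criteria`.
#' @export
validity_criteria <- function(min_final_population = 1e7,
                              require_all_compartments = TRUE,
                              populated_threshold = 1,
                              t_end_days = 4380) {
  stopifnot(min_final_population > 0, t_end_days >= 1)
  structure(list(min_final_population = min_final_population,
                 require_all_compartments = require_all_compartments,
                 populated_threshold = populated_threshold,
                 t_end_days = t_end_days),
            class = "validity_criteria")
}

#' Grid scan over vascularization rate and vessel-wall oxygen
#'
#' Runs one growth simulation per `(k_V, C_0)` pair, recording final total
#' population, number of populated compartments and validity. A failing
#' simulation marks its grid cell invalid (with the failure message) rather
#' than aborting the scan.
#'
#' @param kv_values Vascularization rates to scan, per day.
#' @param c0_values Vessel-wall oxygen concentrations to scan, percent.
#' @param criteria A [validity_criteria()].
#' @param config Baseline [model_config()].
#' @return An object of class `scan_result`: list with a `grid` data.frame
#'   (`k_v`, `c0_pct`, `final_population`, `n_populated`, `valid`,
#'   `reason`) and `selected` (see [select_valid_run()]).
#' @export
grid_scan_growth <- function(kv_values, c0_values,
                             criteria = validity_criteria(),
                             config = model_config()) {
  stopifnot(length(kv_values) >= 1, length(c0_values) >= 1,
            inherits(criteria, "validity_criteria"),
            inherits(config, "model_config"))
  grid <- expand.grid(k_v = kv_values, c0_pct = c0_values,
                      KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(grid)
  final_pop <- numeric(n_cells)
  n_pop <- integer(n_cells)
  valid <- logical(n_cells)
  reason <- character(n_cells)
  for (j in seq_len(n_cells)) {
    res <- tryCatch({
      cj <- update_config(config, k_v = grid$k_v[j], c0_pct = grid$c0_pct[j],
                          t_end_days = criteria$t_end_days)
      traj <- simulate_growth(cj)
      nt <- length(traj$t)
      list(fp = sum(traj$P[nt, ]),
           np = sum(traj$P[nt, ] > criteria$populated_threshold))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      final_pop[j] <- NA_real_
      n_pop[j] <- NA_integer_
      valid[j] <- FALSE
      reason[j] <- conditionMessage(res)
    } else {
      final_pop[j] <- res$fp
      n_pop[j] <- res$np
      ok <- res$fp >= criteria$min_final_population
      if (criteria$require_all_compartments) {
        ok <- ok && res$np == config$spatial$n
      }
      valid[j] <- ok
      reason[j] <- if (ok) "" else "criteria not met"
    }
  }
  grid$final_population <- final_pop
  grid$n_populated <- n_pop
  grid$valid <- valid
  grid$reason <- reason
  out <- structure(list(grid = grid, criteria = criteria), class = "scan_result")
  out$selected <- select_valid_run(out)
  out
}

#' Select the run used for downstream shedding experiments
#'
#' Among valid grid cells, picks the one with the smallest final population
#' (selecting for more necrotic tumors); ties break toward smaller `k_V`,
#' then smaller `C_0`.
#'
#' @param scan A [grid_scan_growth()] result.
#' @return List with `valid` (logical); when `TRUE` also `k_v`, `c0_pct`,
#'   `final_population`; when `FALSE` a `message` ("no valid tumor").
#' @export
select_valid_run <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  g <- scan$grid[which(scan$grid$valid), , drop = FALSE]
  if (nrow(g) == 0L) {
    return(list(valid = FALSE, message = "no valid tumor"))
  }
  g <- g[order(g$final_population, g$k_v, g$c0_pct), , drop = FALSE]
  list(valid = TRUE, k_v = g$k_v[1L], c0_pct = g$c0_pct[1L],
       final_population = g$final_population[1L])
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Growth grid scan:", nrow(x$grid), "cells,",
      sum(x$grid$valid), "valid\n")
  if (isTRUE(x$selected$valid)) {
    cat("  selected: k_V =", x$selected$k_v, ", C_0 =", x$selected$c0_pct,
        "(final population", format(x$selected$final_population, digits = 4),
        ")\n")
  } else {
    cat("  ", x$selected$message, "\n")
  }
  invisible(x)
}

#' One-at-a-time sensitivity sweep
#'
#' Varies one parameter over a value grid while pinning everything else to
#' the baseline configuration. Growth parameters (`k_V`, `C_0`) trigger one
#' growth simulation per value; protein parameters (`phi_or_psi`, `t_half`,
#' `u_h`) reuse a single cached baseline growth trajectory and re-run only
#' the shedding stage, for a matched EC / non-EC protein pair.
#'
#' @param param_name One of `"k_V"`, `"C_0"`, `"phi_or_psi"`, `"t_half"`,
#'   `"u_h"`.
#' @param values Parameter values to sweep.
#' @param config Baseline [model_config()].
#' @param t_end_days Simulation horizon; defaults to the config's.
#' @param growth_traj Optional precomputed baseline growth trajectory
#'   (protein sweeps only).
#' @return An object of class `sensitivity_sweep`: list with `param_name`,
#'   `values`, and `runs` — per value either a `growth_trajectory` or a
#'   list of EC/non-EC `shedding_trajectory` objects.
#' @export
sensitivity_sweep <- function(param_name, values, config = model_config(),
                              t_end_days = NULL, growth_traj = NULL) {
  valid_names <- c("k_V", "C_0", "phi_or_psi", "t_half", "u_h")
  if (!param_name %in% valid_names) {
    stop("unknown parameter '", param_name, "'; valid names: ",
         paste(valid_names, collapse = ", "))
  }
  stopifnot(length(values) >= 1, inherits(config, "model_config"))
  if (!is.null(t_end_days)) {
    config <- update_config(config, t_end_days = t_end_days)
  }
  growth_mode <- param_name %in% c("k_V", "C_0")
  runs <- vector("list", length(values))
  if (growth_mode) {
    for (j in seq_along(values)) {
      cj <- switch(param_name,
                   k_V = update_config(config, k_v = values[j]),
                   C_0 = update_config(config, c0_pct = values[j]))
      runs[[j]] <- simulate_growth(cj)
    }
  } else {
    if (is.null(growth_traj)) growth_traj <- simulate_growth(config)
    base <- list(t_half = 6.4, u_h = 456, rate = 4.5e-4)
    for (j in seq_along(values)) {
      v <- values[j]
      pars <- switch(param_name,
        phi_or_psi = list(phi = v, psi = v, t_half = base$t_half,
                          u_h = base$u_h),
        t_half = list(phi = base$rate, psi = base$rate, t_half = v,
                      u_h = base$u_h),
        u_h = list(phi = base$rate, psi = base$rate, t_half = base$t_half,
                   u_h = v))
      ec <- protein_params("EC", ec = 1, phi = pars$phi, psi = 0,
                           t_half_days = pars$t_half, u_h = pars$u_h)
      nonec <- protein_params("nonEC", ec = 0, phi = 0, psi = pars$psi,
                              t_half_days = pars$t_half, u_h = pars$u_h)
      runs[[j]] <- list(EC = simulate_shedding(growth_traj, ec),
                        nonEC = simulate_shedding(growth_traj, nonec))
    }
  }
  names(runs) <- paste0(param_name, "=", format(values, digits = 6))
  structure(list(param_name = param_name, values = values, runs = runs,
                 mode = if (growth_mode) "growth" else "shedding"),
            class = "sensitivity_sweep")
}

#' Per-compartment contribution decomposition
#'
#' Long-format table of each compartment's contribution to, and share of,
#' the total proliferative population, instantaneous deaths and (when a
#' shedding trajectory is supplied) protein outflux at every time point.
#' Shares are defined as 0 when the corresponding total is 0; contributions
#' sum to the totals exactly.
#'
#' @param traj A [simulate_growth()] trajectory.
#' @param shed Optional aligned [simulate_shedding()] trajectory.
#' @return Data.frame with columns `t_day`, `comp`, `P`, `P_share`,
#'   `D_inst`, `D_share` (and `u`, `u_share`).
#' @export
per_compartment_decomposition <- function(traj, shed = NULL) {
  stopifnot(inherits(traj, "growth_trajectory"))
  nt <- length(traj$t)
  share <- function(m) {
    tot <- rowSums(m)
    sh <- m / ifelse(tot > 0, tot, 1)
    sh[tot == 0, ] <- 0
    sh
  }
  out <- data.frame(
    t_day = rep(traj$t, times = traj$n),
    comp = rep(seq_len(traj$n), each = nt),
    P = as.vector(traj$P),
    P_share = as.vector(share(traj$P)),
    D_inst = as.vector(traj$D_inst),
    D_share = as.vector(share(traj$D_inst))
  )
  if (!is.null(shed)) {
    stopifnot(inherits(shed, "shedding_trajectory"))
    if (!isTRUE(all.equal(shed$t, traj$t))) {
      stop("shedding trajectory is not aligned with the growth trajectory")
    }
    out$u <- as.vector(shed$u)
    out$u_share <- as.vector(share(shed$u))
  }
  out
}

#' Protein parameter scan with dynamic-range envelopes
#'
#' For each healthy-influx value, simulates a non-extracellular protein at
#' every `(psi, t_half)` grid point against one cached growth trajectory
#' and records the pointwise minimum and maximum plasma-mass envelope. By
#' monotonicity the bounds coincide with the extreme-corner trajectories;
#' the corner identities are verified against the brute-force envelope and
#' reported. Also reports, per influx value, the first day the envelope's
#' upper bound exceeds the extracellular reference trajectory.
#'
#' @param psi_values Non-EC per-cell contributions to scan, U/cell.
#' @param uh_values Healthy influx values to scan, U/day.
#' @param thalf_values Blood half-lives to scan, days.
#' @param traj A [simulate_growth()] trajectory.
#' @param ec_reference A [protein_params()] for the EC reference protein.
#' @return An object of class `protein_scan`: list with `envelopes` (per
#'   `u_h`: `t`, `q_min`, `q_max`, corner identities, `crossover_day`),
#'   `ec_reference_q`, and the scan grids.
#' @export
protein_scan_envelopes <- function(psi_values, uh_values, thalf_values,
                                   traj, ec_reference) {
  stopifnot(length(psi_values) >= 1, length(uh_values) >= 1,
            length(thalf_values) >= 1,
            inherits(traj, "growth_trajectory"),
            inherits(ec_reference, "protein_params"))
  ec_q <- simulate_shedding(traj, ec_reference)$q
  envelopes <- vector("list", length(uh_values))
  for (a in seq_along(uh_values)) {
    uh <- uh_values[a]
    combos <- expand.grid(psi = psi_values, t_half = thalf_values,
                          KEEP.OUT.ATTRS = FALSE)
    qs <- matrix(0, nrow = length(traj$t), ncol = nrow(combos))
    for (j in seq_len(nrow(combos))) {
      pp <- protein_params("scan", ec = 0, phi = 0, psi = combos$psi[j],
                           t_half_days = combos$t_half[j], u_h = uh)
      qs[, j] <- simulate_shedding(traj, pp)$q
    }
    q_min <- apply(qs, 1L, min)
    q_max <- apply(qs, 1L, max)
    corner_min <- which(combos$psi == min(psi_values) &
                          combos$t_half == min(thalf_values))
    corner_max <- which(combos$psi == max(psi_values) &
                          combos$t_half == max(thalf_values))
    cross <- which(q_max > ec_q)
    envelopes[[a]] <- list(
      u_h = uh,
      t = traj$t,
      q_min = q_min,
      q_max = q_max,
      min_is_corner = isTRUE(all.equal(q_min, qs[, corner_min])),
      max_is_corner = isTRUE(all.equal(q_max, qs[, corner_max])),
      crossover_day = if (length(cross)) traj$t[cross[1L]] else NA_real_
    )
  }
  names(envelopes) <- paste0("u_h=", format(uh_values, digits = 6))
  structure(list(envelopes = envelopes, ec_reference_q = ec_q, t = traj$t,
                 grids = list(psi = psi_values, u_h = uh_values,
                              t_half = thalf_values)),
            class = "protein_scan")
}

#' @export
print.protein_scan <- function(x, ...) {
  cat("Protein scan:", length(x$grids$psi), "x", length(x$grids$t_half),
      "(psi x t_half) grid at", length(x$grids$u_h), "u_H value(s)\n")
  for (e in x$envelopes) {
    cat("  u_H =", format(e$u_h), ": corners",
        if (e$min_is_corner && e$max_is_corner) "confirmed" else "NOT confirmed",
        "; non-EC max crosses EC reference",
        if (is.na(e$crossover_day)) "never" else
          paste0("at day ", e$crossover_day), "\n")
  }
  invisible(x)
}
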