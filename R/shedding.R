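# Protein outflux from tumor compartments and the one-compartment plasma
# mass equation with first-order elimination.

#' Protein parameter set
#'
#' Describes one protein species. Extracellular proteins (`ec = 1`) are
#' shed actively by viable cells at `phi` units per cell per day;
#' non-extracellular proteins (`ec = 0`) are released at `psi` units per
#' cell upon death. Plasma elimination is first-order with rate
#' `ln(2)/t_half_days`. `q0` defaults to the healthy steady state
#' `u_h / k_E` (zero when `u_h = 0`, the xenograft convention) so that
#' tumor-free runs are flat.
#'
#' @param name Label used in outputs.
#' @param ec Localization flag: 1 extracellular, 0 non-extracellular.
#' @param phi Per-cell shedding rate, U/cell/day.
#' @param psi Per-cell contribution on death, U/cell.
#' @param t_half_days Blood half-life, days. Default 6.4.
#' @param u_h Healthy-tissue influx, U/day. Default 456.
#' @param q0 Initial plasma mass, U. Default `u_h / k_E`.
#' @return An object of class `protein_params`.
#' @export
protein_params <- function(name = "protein", ec = 1, phi = 0, psi = 0,
                           t_half_days = 6.4, u_h = 456, q0 = NULL) {
  stopifnot(ec %in% c(0, 1), phi >= 0, psi >= 0, t_half_days > 0, u_h >= 0)
  k_e <- elimination_rate(t_half_days)
  if (is.null(q0)) q0 <- if (u_h > 0) u_h / k_e else 0
  stopifnot(q0 >= 0)
  structure(list(name = name, ec = ec, phi = phi, psi = psi,
                 t_half_days = t_half_days, k_e = k_e, u_h = u_h, q0 = q0),
            class = "protein_params")
}

#' Plasma elimination rate from half-life
#'
#' @param t_half_days Blood half-life, days (> 0).
#' @return Elimination rate `k_E = ln(2)/t_half`, per day.
#' @export
elimination_rate <- function(t_half_days) {
  stopifnot(is.numeric(t_half_days))
  if (any(t_half_days <= 0)) stop("half-life must be positive")
  log(2) / t_half_days
}

#' Number of plasma substeps needed for Euler stability
#'
#' The daily plasma recurrence is stable only when `k_E * dt < 1`. For
#' short half-lives the day is split into the smallest number of uniform
#' substeps bringing `k_E * dt / m` to at most 0.5, keeping populations on
#' the daily grid.
#'
#' @param k_e Elimination rate, per day.
#' @param dt Time step, days.
#' @return Integer substep count (1 when no substepping is required).
#' @export
plasma_substeps <- function(k_e, dt = 1) {
  stopifnot(k_e >= 0, dt > 0)
  if (k_e * dt < 1) 1L else as.integer(ceiling(k_e * dt / 0.5))
}

#' Per-compartment protein outflux
#'
#' `u_i = w_i * phi * P_i` for extracellular proteins;
#' `u_i = w_i * psi * D_inst_i / dt` for non-extracellular proteins
#' (necrosis-sourced).
#'
#' @param P Per-compartment proliferative populations, cells.
#' @param D_inst Per-compartment deaths this step, cells.
#' @param rates A [compartment_rate_table()] (supplies the weights `w`).
#' @param pp A [protein_params()].
#' @param dt Time step, days. Default 1.
#' @return Outflux vector, U/day, all nonnegative.
#' @export
compartment_outflux <- function(P, D_inst, rates, pp, dt = 1) {
  stopifnot(inherits(pp, "protein_params"),
            length(P) == length(rates$w), length(D_inst) == length(P))
  if (pp$ec == 1) rates$w * pp$phi * P else rates$w * pp$psi * D_inst / dt
}

#' Advance the plasma mass by one day
#'
#' Forward-Euler update `q' = u_total*dt + u_H*dt + (1 - k_E*dt)*q`. When
#' `k_E*dt >= 1` the update is sub-stepped internally (see
#' [plasma_substeps()]); with `substep = FALSE` such a call is an error
#' instead, since the unsplit scheme would oscillate or diverge.
#'
#' @param q Current plasma mass, U.
#' @param u_total Total tumor outflux this day, U/day.
#' @param pp A [protein_params()].
#' @param dt Time step, days.
#' @param substep Allow internal sub-stepping for stability. Default TRUE.
#' @return Updated plasma mass, U.
#' @export
step_plasma <- function(q, u_total, pp, dt = 1, substep = TRUE) {
  stopifnot(inherits(pp, "protein_params"), q >= 0, u_total >= 0)
  m <- plasma_substeps(pp$k_e, dt)
  if (m > 1L && !substep) {
    stop("k_E * dt = ", format(pp$k_e * dt, digits = 4),
         " >= 1: unstable Euler step (enable substepping or reduce dt)")
  }
  d <- dt / m
  a <- (u_total + pp$u_h) * d
  b <- 1 - pp$k_e * d
  for (j in seq_len(m)) q <- a + b * q
  q
}

#' Simulate plasma protein shedding over a growth trajectory
#'
#' Converts a cached growth trajectory into per-compartment protein
#' outflux and integrates the plasma mass equation. Growth and shedding
#' are computed in series: the plasma compartment never feeds back on the
#' tumor, so many proteins can be evaluated against one trajectory.
#'
#' @param traj A [simulate_growth()] trajectory.
#' @param pp A [protein_params()].
#' @param rates Optional rate table; defaults to the trajectory's own.
#' @return An object of class `shedding_trajectory`: list with `t`, plasma
#'   mass `q`, outflux matrix `u` (time x compartment), totals `u_total`,
#'   and the `protein` parameters.
#' @export
simulate_shedding <- function(traj, pp, rates = NULL) {
  stopifnot(inherits(traj, "growth_trajectory"),
            inherits(pp, "protein_params"))
  if (is.null(rates)) rates <- traj$rates
  if (length(rates$w) != traj$n) stop("rate table does not match trajectory")
  dt <- traj$dt
  nt <- length(traj$t)
  u <- if (pp$ec == 1) {
    traj$P * rep(rates$w * pp$phi, each = nt)
  } else {
    traj$D_inst / dt * rep(rates$w * pp$psi, each = nt)
  }
  u_total <- rowSums(u)
  q <- numeric(nt)
  q[1L] <- pp$q0
  m <- plasma_substeps(pp$k_e, dt)
  d <- dt / m
  b <- 1 - pp$k_e * d
  for (k in seq_len(nt - 1L)) {
    qk <- q[k]
    a <- (u_total[k] + pp$u_h) * d
    for (j in seq_len(m)) qk <- a + b * qk
    q[k + 1L] <- qk
  }
  structure(list(t = traj$t, q = q, u = u, u_total = u_total, protein = pp),
            class = "shedding_trajectory")
}

#' Simulate several proteins against one growth trajectory
#'
#' @param traj A [simulate_growth()] trajectory.
#' @param proteins List of [protein_params()].
#' @return Named list of `shedding_trajectory` objects.
#' @export
simulate_shedding_batch <- function(traj, proteins) {
  stopifnot(is.list(proteins))
  out <- lapply(proteins, simulate_shedding, traj = traj)
  names(out) <- vapply(proteins, function(p) p$name, character(1))
  out
}

#' @export
as.data.frame.shedding_trajectory <- function(x, ...) {
  df <- data.frame(t_day = x$t, q = x$q, u_total = x$u_total)
  u <- as.data.frame(x$u)
  names(u) <- paste0("u_", seq_len(ncol(u)))
  cbind(df, u)
}

#' @export
print.shedding_trajectory <- function(x, ...) {
  nt <- length(x$t)
  cat("Shedding trajectory for", x$protein$name,
      if (x$protein$ec == 1) "(EC)" else "(non-EC)", "\n")
  cat("  final plasma mass:", format(x$q[nt], digits = 4), "U after",
      nt - 1L, "days\n")
  invisible(x)
}
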